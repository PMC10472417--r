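#' Agreement metrics between visual and (semi-)automated detection
#'
#' Sensitivity, positive predictive value, success rate over cluster ranks,
#' and Cohen's kappa. Sensitivity is the fraction of reference ("visual")
#' marks also found by the detector; PPV is the fraction of true discharges
#' among all detected events; the success rate is the percentage of
#' recordings in which a cluster of a given rank holds at least a minimum
#' number of reviewed discharges; kappa is chance-corrected agreement,
#' kappa = (Pr(a) - Pr(e)) / (1 - Pr(e)).
#'
#' @name hdesi-agreement
NULL

#' Detection sensitivity
#'
#' Percentage of reference (visually marked) events that the automated
#' detector also found: 100 * n(matched reference marks) / n(reference).
#'
#' @param visual Reference `mark_list` (non-empty).
#' @param auto Automated `mark_list`.
#' @param tol_ms Matching tolerance, ms.
#' @return Percentage in [0, 100].
#' @export
detection_sensitivity <- function(visual, auto, tol_ms = 100) {
  n_vis <- if (is.data.frame(visual)) nrow(visual) else length(visual)
  if (n_vis == 0) {
    stop("sensitivity undefined: reference mark list is empty", call. = FALSE)
  }
  m <- match_events(visual, auto, tol_ms)
  100 * m$n_matched / n_vis
}

#' Positive predictive value
#'
#' Percentage of true discharges among all detected events.
#'
#' @param all_detected Total number of detected events (> 0).
#' @param true_ieds Number of those that are true discharges
#'   (<= all_detected).
#' @return Percentage in [0, 100].
#' @export
positive_predictive_value <- function(all_detected, true_ieds) {
  if (all_detected <= 0) {
    stop("PPV undefined: no detections", call. = FALSE)
  }
  if (true_ieds > all_detected || true_ieds < 0) {
    stop("true_ieds must be between 0 and all_detected", call. = FALSE)
  }
  100 * true_ieds / all_detected
}

#' Success rate of reaching a minimum cluster size
#'
#' Percentage of recordings whose cluster at the given rank (mode "exact")
#' or at any rank up to the given rank (mode "within", default) holds at
#' least `min_ieds` events.
#'
#' @param per_recording_clusters List (one entry per recording) of cluster
#'   lists as returned by [cluster_by_peak_electrode()]. Entries may also be
#'   plain integer vectors of per-cluster event counts (rank order).
#' @param cluster_rank Rank >= 1.
#' @param min_ieds Minimum event count (>= 1). Default 30.
#' @param mode "within" or "exact".
#' @return Percentage in [0, 100].
#' @export
success_rate <- function(per_recording_clusters, cluster_rank, min_ieds = 30,
                         mode = c("within", "exact")) {
  mode <- match.arg(mode)
  if (length(per_recording_clusters) == 0) {
    stop("success rate undefined: no recordings", call. = FALSE)
  }
  if (cluster_rank < 1 || min_ieds < 1) {
    stop("cluster_rank and min_ieds must be >= 1", call. = FALSE)
  }
  qualifies <- vapply(per_recording_clusters, function(clusters) {
    counts <- if (is.numeric(clusters)) as.integer(clusters) else
      vapply(clusters, function(cl) cl$n, integer(1))
    if (mode == "exact") {
      length(counts) >= cluster_rank && counts[cluster_rank] >= min_ieds
    } else {
      any(utils::head(counts, cluster_rank) >= min_ieds)
    }
  }, logical(1))
  100 * mean(qualifies)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement kappa = (Pr(a) - Pr(e)) / (1 - Pr(e)), where
#' Pr(a) is the observed agreement and Pr(e) the chance agreement.
#'
#' @param pr_a Observed agreement, in [0, 1].
#' @param pr_e Chance agreement, in [0, 1).
#' @return kappa (<= 1).
#' @export
cohens_kappa <- function(pr_a, pr_e) {
  if (pr_a < 0 || pr_a > 1 || pr_e < 0 || pr_e > 1) {
    stop("pr_a and pr_e must be proportions", call. = FALSE)
  }
  if (pr_e >= 1) stop("kappa undefined: chance agreement is 1", call. = FALSE)
  (pr_a - pr_e) / (1 - pr_e)
}

#' Cohen's kappa between two mark lists
#'
#' Point processes carry no trial structure, so the recording is divided
#' into non-overlapping decision epochs (default 2 s, mirroring the event
#' epochs used for review); each epoch is scored spike / no-spike per rater
#' and kappa computed from the resulting 2x2 agreement table.
#'
#' @param a,b `mark_list` objects.
#' @param duration_s Recording duration, s.
#' @param epoch_s Decision-epoch length, s. Default 2.
#' @return List: `kappa`, `pr_a`, `pr_e`, `table` (2x2: rows = rater a
#'   spike/no, cols = rater b), `n_epochs`.
#' @export
kappa_from_marklists <- function(a, b, duration_s, epoch_s = 2) {
  if (duration_s <= 0 || epoch_s <= 0) {
    stop("duration_s and epoch_s must be positive", call. = FALSE)
  }
  n_ep <- floor(duration_s / epoch_s)
  if (n_ep < 1) stop("no complete decision epochs", call. = FALSE)
  bin <- function(m) {
    t <- if (is.data.frame(m)) m$time_s else as.numeric(m)
    t <- t[t < n_ep * epoch_s]
    tabulate(pmin(floor(t / epoch_s) + 1L, n_ep), nbins = n_ep) > 0
  }
  ba <- bin(a); bb <- bin(b)
  tab <- matrix(c(sum(ba & bb), sum(ba & !bb),
                  sum(!ba & bb), sum(!ba & !bb)), 2, 2,
                dimnames = list(a = c("spike", "no"), b = c("spike", "no")))
  pr_a <- (tab[1, 1] + tab[2, 2]) / n_ep
  p1 <- mean(ba); p2 <- mean(bb)
  pr_e <- p1 * p2 + (1 - p1) * (1 - p2)
  list(kappa = cohens_kappa(pr_a, pr_e), pr_a = pr_a, pr_e = pr_e,
       table = tab, n_epochs = n_ep)
}

#' Full agreement report between reference and automated marking
#'
#' Bundles sensitivity, PPV, kappa (both for raw automated output and, when
#' given, the reviewed selection) and the matched/unmatched counts.
#'
#' @param reference Reference `mark_list`.
#' @param automated Automated `mark_list` (all detections).
#' @param reviewed Optional reviewed `mark_list` (true-discharge subset).
#' @param duration_s Recording duration, s.
#' @param tol_ms Matching tolerance, ms.
#' @return Object of class `agreement_result`.
#' @export
agreement_report <- function(reference, automated, reviewed = NULL,
                             duration_s, tol_ms = 100) {
  m_auto <- match_events(reference, automated, tol_ms)
  sens <- detection_sensitivity(reference, automated, tol_ms)
  ppv <- if (m_auto$n_b > 0) {
    positive_predictive_value(m_auto$n_b, m_auto$n_matched)
  } else NA_real_
  k_auto <- kappa_from_marklists(reference, automated, duration_s)
  k_rev <- if (!is.null(reviewed)) {
    kappa_from_marklists(reference, reviewed, duration_s)
  } else NULL
  structure(
    list(sensitivity_pct = sens, ppv_pct = ppv,
         kappa_automated = k_auto$kappa,
         kappa_reviewed = if (is.null(k_rev)) NA_real_ else k_rev$kappa,
         pr_a = k_auto$pr_a, pr_e = k_auto$pr_e,
         n_reference = m_auto$n_a, n_automated = m_auto$n_b,
         n_matched = m_auto$n_matched,
         n_unmatched_reference = m_auto$n_a - m_auto$n_matched,
         n_unmatched_automated = m_auto$n_b - m_auto$n_matched),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> sensitivity %.2f%%, PPV %s, kappa(auto) %.3f%s\n",
    x$sensitivity_pct,
    if (is.na(x$ppv_pct)) "NA" else sprintf("%.2f%%", x$ppv_pct),
    x$kappa_automated,
    if (is.na(x$kappa_reviewed)) "" else
      sprintf(", kappa(reviewed) %.3f", x$kappa_reviewed)))
  invisible(x)
}
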
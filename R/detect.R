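#' Automated spike detection and event clustering
#'
#' Surrogate for a commercial spike detector: per-channel normalized
#' matched filtering against the template's sharp transient, candidate
#' peaks at local maxima of the best-channel correlation, and a probability
#' score obtained by logistic squashing of correlation x robust amplitude
#' z-score. Downstream: probability thresholding (default 0.9), clustering
#' by the electrode with the highest amplitude, and a simulated reviewer.
#'
#' @name hdesi-detect
NULL

# Logistic squashing constants for the probability score. Fitted once on a
# calibration simulation (clean spikes at nominal amplitude score ~4-6,
# background peaks ~1-2) so that the 0.9 probability threshold separates
# the two regimes; see the methods vignette.
PROB_MIDPOINT <- 2.5
PROB_SLOPE <- 2.0

#' Detect spike candidates by normalized matched filtering
#'
#' @param recording A `sim_recording` (or any list with `data`,
#'   `sampling_rate_hz`, `channel_ids`).
#' @param template An `ied_template` at the recording's sampling rate.
#' @param min_separation_ms Minimum distance between candidate peaks, ms.
#' @param score_floor Minimum best-channel |correlation| for a candidate to
#'   be emitted (keeps the candidate list finite on pure noise). Default 0.4.
#' @return A `detected_events` data frame: peak_time_s, peak_sample,
#'   peak_channel, probability, peak_amplitude_uV, correlation, score.
#' @export
detect_events <- function(recording, template, min_separation_ms = 200,
                          score_floor = 0.4) {
  stopifnot(inherits(template, "ied_template"))
  rate <- recording$sampling_rate_hz
  if (template$sampling_rate_hz != rate) {
    stop("template rate does not match recording rate", call. = FALSE)
  }
  x <- recording$data
  if (is.null(x) || length(x) == 0) stop("empty recording", call. = FALSE)
  if (ncol(x) < 10 * rate) {
    stop("recording must be at least 10 s long", call. = FALSE)
  }
  x <- apply_average_reference(x)
  n_ch <- nrow(x); n_s <- ncol(x)

  # correlation and amplitude scoring run on band-passed data: the 1/f
  # background concentrates below a few Hz, the spike's energy band does
  # not, so the band-pass stops slow fluctuations from mimicking the bump
  xf <- t(apply(x, 1, bandpass_fft, rate = rate))
  w <- template$waveform[template$spike_segment]
  w <- bandpass_fft(w, rate)
  w <- w - mean(w)
  w <- w / sqrt(sum(w^2))
  L <- length(w)
  pk_off <- template$peak_sample - template$spike_segment[1] + 1L
  n_win <- n_s - L + 1L
  if (n_win < 1) stop("recording shorter than template", call. = FALSE)

  best <- rep(0, n_win)
  ones <- rep(1, L)
  for (ch in seq_len(n_ch)) {
    xc <- xf[ch, ]
    num <- cross_corr(xc, w)
    sums <- cross_corr(xc, ones)
    sumsq <- cross_corr(xc^2, ones)
    denom <- sqrt(pmax(sumsq - sums^2 / L, 1e-12))
    r <- abs(num / denom)
    best <- pmax(best, r)
  }

  min_sep <- max(1L, round(min_separation_ms / 1e3 * rate))
  cand <- local_maxima(best, min_sep, score_floor)
  if (length(cand) == 0) {
    return(empty_detected_events())
  }
  peak_sample <- cand + pk_off - 1L

  # amplitude statistic: global field power (across-channel RMS) of the
  # band-passed data -- a spike's coherent topography lifts the GFP on many
  # channels at once, which single-channel background peaks cannot do
  gfp <- sqrt(colMeans(xf^2))
  z_all <- pmax((gfp - stats::median(gfp)) / max(stats::mad(gfp), 1e-9), 0)

  ch_idx <- vapply(peak_sample, function(s) which.max(abs(xf[, s])), integer(1))
  amp <- x[cbind(ch_idx, peak_sample)]
  z <- z_all[peak_sample]
  corr <- best[cand]
  score <- corr * z
  ev <- data.frame(
    peak_time_s = (peak_sample - 1L) / rate,
    peak_sample = peak_sample,
    peak_channel = recording$channel_ids[ch_idx],
    probability = stats::plogis(PROB_SLOPE * (score - PROB_MIDPOINT)),
    peak_amplitude_uV = amp,
    correlation = corr,
    score = score)
  ev <- ev[order(ev$peak_time_s), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("detected_events", "data.frame")
  ev
}

empty_detected_events <- function() {
  ev <- data.frame(
    peak_time_s = numeric(0), peak_sample = integer(0),
    peak_channel = character(0), probability = numeric(0),
    peak_amplitude_uV = numeric(0), correlation = numeric(0),
    score = numeric(0))
  class(ev) <- c("detected_events", "data.frame")
  ev
}

# zero-phase FFT band-pass with raised-cosine edges (default 4-45 Hz)
bandpass_fft <- function(x, rate, lo = 4, hi = 45, roll = 2) {
  n <- length(x)
  f <- seq(0, n - 1) / n * rate
  f <- pmin(f, rate - f)
  g <- rep(1, n)
  g[f < lo - roll] <- 0
  ramp <- f >= lo - roll & f < lo + roll
  g[ramp] <- 0.5 * (1 - cos(pi * (f[ramp] - lo + roll) / (2 * roll)))
  g[f > hi + roll] <- 0
  ramp <- f > hi - roll & f <= hi + roll
  g[ramp] <- g[ramp] * 0.5 * (1 + cos(pi * (f[ramp] - hi + roll) / (2 * roll)))
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
}

# event times of a mark list, detected_events table, or numeric vector
mark_times <- function(m) {
  if (is.data.frame(m)) {
    if (!is.null(m$time_s)) m$time_s else m$peak_time_s
  } else {
    as.numeric(m)
  }
}

# sliding dot product of x with kernel w, length n - L + 1; index i aligns
# w[1] with x[i]; FFT with power-of-2 padding
cross_corr <- function(x, w) {
  n <- length(x); L <- length(w)
  nf <- stats::nextn(n + L - 1L, 2)
  fx <- stats::fft(c(x, numeric(nf - n)))
  fw <- stats::fft(c(w, numeric(nf - L)))
  full <- Re(stats::fft(fx * Conj(fw), inverse = TRUE)) / nf
  full[seq_len(n - L + 1L)]
}

# indices of local maxima above floor, greedily separated by min_sep
local_maxima <- function(v, min_sep, floor) {
  n <- length(v)
  if (n < 3) return(integer(0))
  is_pk <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n] &
                   v[2:(n - 1)] >= floor) + 1L
  if (length(is_pk) == 0) return(integer(0))
  is_pk <- is_pk[order(v[is_pk], decreasing = TRUE)]
  kept <- integer(0)
  for (p in is_pk) {
    if (all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Filter detections by probability score
#'
#' Retains events with probability greater than or equal to `p_min`
#' (boundary inclusive: only events strictly below the threshold are
#' excluded). Default threshold 0.9.
#'
#' @param events A `detected_events` data frame.
#' @param p_min Probability threshold in [0, 1].
#' @return The retained subset, same class.
#' @export
filter_by_probability <- function(events, p_min = 0.9) {
  if (p_min < 0 || p_min > 1) stop("p_min must be in [0, 1]", call. = FALSE)
  out <- events[events$probability >= p_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group detections into clusters by peak electrode
#'
#' One cluster per distinct peak channel; the cluster list is sorted by
#' descending event count with ties broken by channel id (lexicographic).
#' Events within a cluster are sorted by time.
#'
#' @param events A `detected_events` data frame.
#' @return List of `event_cluster` objects (`label`, `events`, `n`).
#' @export
cluster_by_peak_electrode <- function(events) {
  if (nrow(events) == 0) return(list())
  groups <- split(seq_len(nrow(events)), events$peak_channel)
  clusters <- lapply(names(groups), function(lab) {
    ev <- events[groups[[lab]], , drop = FALSE]
    ev <- ev[order(ev$peak_time_s), , drop = FALSE]
    rownames(ev) <- NULL
    structure(list(label = lab, events = ev, n = nrow(ev)),
              class = "event_cluster")
  })
  sizes <- vapply(clusters, function(cl) cl$n, integer(1))
  labels <- vapply(clusters, function(cl) cl$label, character(1))
  clusters[order(-sizes, labels)]
}

#' @export
print.event_cluster <- function(x, ...) {
  cat(sprintf("<event_cluster> %s: %d events\n", x$label, x$n))
  invisible(x)
}

#' Construct a mark list
#'
#' A sorted list of event times with optional channel labels and a
#' provenance tag, the common currency of all agreement metrics.
#'
#' @param times_s Non-negative event times, s.
#' @param channels Optional channel labels (recycled).
#' @param provenance One of "reference", "automated", "reviewed".
#' @return Object of class `mark_list` (a data frame with attribute
#'   `provenance`).
#' @export
mark_list <- function(times_s, channels = NULL,
                      provenance = c("reference", "automated", "reviewed")) {
  provenance <- match.arg(provenance)
  times_s <- as.numeric(times_s)
  if (any(times_s < 0)) stop("mark times must be non-negative", call. = FALSE)
  ord <- order(times_s)
  df <- data.frame(time_s = times_s[ord])
  df$channel <- if (is.null(channels)) {
    rep(NA_character_, length(times_s))
  } else {
    rep_len(as.character(channels), length(times_s))[ord]
  }
  attr(df, "provenance") <- provenance
  class(df) <- c("mark_list", "data.frame")
  df
}

#' Mark list helpers
#'
#' `marks_from_events` converts detector output, `marks_from_truth` the
#' ground-truth table of a simulated recording.
#'
#' @param events A `detected_events` data frame.
#' @param provenance Provenance tag.
#' @export
marks_from_events <- function(events, provenance = "automated") {
  mark_list(events$peak_time_s, events$peak_channel, provenance)
}

#' @rdname marks_from_events
#' @param recording A `sim_recording`.
#' @export
marks_from_truth <- function(recording, provenance = "reference") {
  mark_list(recording$events$time_s, provenance = provenance)
}

#' Greedy nearest-time one-to-one event matching
#'
#' Pairs events of two mark lists whose times differ by at most `tol_ms`,
#' closest pairs first, each event used at most once.
#'
#' @param a,b `mark_list` objects (or numeric time vectors, s).
#' @param tol_ms Matching tolerance, ms (>= 0). Default 100 (the marking
#'   convention is "on the peak"; the tolerance is a configuration choice).
#' @return List with `pairs` (data frame i, j, dt_s), `n_matched`,
#'   `n_a`, `n_b`.
#' @export
match_events <- function(a, b, tol_ms = 100) {
  if (tol_ms < 0) stop("tol_ms must be >= 0", call. = FALSE)
  ta <- mark_times(a)
  tb <- mark_times(b)
  tol <- tol_ms / 1e3
  if (length(ta) == 0 || length(tb) == 0) {
    return(list(pairs = data.frame(i = integer(0), j = integer(0),
                                   dt_s = numeric(0)),
                n_matched = 0L, n_a = length(ta), n_b = length(tb)))
  }
  dt <- abs(outer(ta, tb, "-"))
  cand <- which(dt <= tol, arr.ind = TRUE)
  if (nrow(cand) > 0) cand <- cand[order(dt[cand]), , drop = FALSE]
  used_a <- logical(length(ta)); used_b <- logical(length(tb))
  pi <- integer(0); pj <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pi <- c(pi, i); pj <- c(pj, j)
    }
  }
  list(pairs = data.frame(i = pi, j = pj, dt_s = ta[pi] - tb[pj]),
       n_matched = length(pi), n_a = length(ta), n_b = length(tb))
}

#' Simulated epoch review
#'
#' Emulates the clinician reviewing candidate epochs: candidates matching a
#' ground-truth mark within tolerance are kept (each with probability
#' 1 - miss rate); unmatched candidates (artifacts, background patterns)
#' are rejected.
#'
#' @param candidates A `detected_events` data frame or `mark_list`.
#' @param truth A `mark_list` of true events.
#' @param tol_ms Matching tolerance, ms.
#' @param reviewer_miss_rate Probability of wrongly rejecting a true
#'   candidate, in [0, 1].
#' @param seed RNG seed.
#' @return A `mark_list` with provenance "reviewed" (subset of candidate
#'   times).
#' @export
simulate_review <- function(candidates, truth, tol_ms = 100,
                            reviewer_miss_rate = 0, seed = 1) {
  if (reviewer_miss_rate < 0 || reviewer_miss_rate > 1) {
    stop("reviewer_miss_rate must be in [0, 1]", call. = FALSE)
  }
  tc <- if (is.data.frame(candidates)) {
    if ("peak_time_s" %in% names(candidates)) candidates$peak_time_s else
      candidates$time_s
  } else as.numeric(candidates)
  chans <- if (is.data.frame(candidates) && "peak_channel" %in% names(candidates)) {
    candidates$peak_channel
  } else NULL
  m <- match_events(tc, truth, tol_ms)
  keep_idx <- m$pairs$i
  if (length(keep_idx) > 0 && reviewer_miss_rate > 0) {
    kept <- with_seed(seed,
      stats::runif(length(keep_idx)) >= reviewer_miss_rate)
    keep_idx <- keep_idx[kept]
  }
  mark_list(tc[keep_idx],
            channels = if (is.null(chans)) NULL else chans[keep_idx],
            provenance = "reviewed")
}
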
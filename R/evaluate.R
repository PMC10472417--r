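#' Localization scoring and the spike-count subsampling experiment
#'
#' Distance from the source maximum to the resection mask, sublobar and
#' hemispheric concordance against a geometric parcellation surrogate, and
#' the experiment measuring how the number of averaged spikes affects the
#' stability of the source maximum.
#'
#' @name hdesi-evaluate
NULL

#' Shortest Euclidean distance from a grid point to a resection mask
#'
#' Zero if the point is a mask member, otherwise the minimum over mask
#' members of the Euclidean distance between grid positions.
#'
#' @param max_index 1-based grid index (e.g. from [find_source_maximum()]).
#' @param mask A `resection_mask`.
#' @param grid The matching `source_grid`.
#' @return Distance in mm (>= 0).
#' @export
distance_to_mask <- function(max_index, mask, grid) {
  stopifnot(inherits(mask, "resection_mask"), inherits(grid, "source_grid"))
  if (length(mask$members) == 0) stop("mask is empty", call. = FALSE)
  mi <- as.integer(max_index)
  if (length(mi) != 1 || is.na(mi) || mi < 1 || mi > grid$n_points) {
    stop("max_index out of grid range", call. = FALSE)
  }
  if (mi %in% mask$members) return(0)
  d2 <- rowSums(sweep(grid$positions[mask$members, , drop = FALSE], 2,
                      grid$positions[mi, ])^2)
  sqrt(min(d2))
}

#' Build a geometric sublobe atlas
#'
#' Surrogate for an anatomical parcellation: each hemisphere (split at
#' x = 0; x >= 0 is right) is partitioned into `n_per_hemisphere` regions by
#' k-means on grid-point coordinates, deterministic under the seed. Labels
#' are 1..n (left) and n+1..2n (right).
#'
#' @param grid A `source_grid`.
#' @param n_per_hemisphere Regions per hemisphere (>= 1). Default 19.
#' @param seed RNG seed for the k-means initialization.
#' @return Object of class `sublobe_atlas`: `labels` (one per grid point),
#'   `hemisphere` ("L"/"R"), `n_per_hemisphere`.
#' @export
build_sublobe_atlas <- function(grid, n_per_hemisphere = 19, seed = 1) {
  stopifnot(inherits(grid, "source_grid"))
  n <- as.integer(n_per_hemisphere)
  if (n < 1) stop("n_per_hemisphere must be >= 1", call. = FALSE)
  right <- grid$positions[, 1] >= 0
  labels <- integer(grid$n_points)
  for (hemi in c("L", "R")) {
    idx <- if (hemi == "R") which(right) else which(!right)
    if (length(idx) == 0) next
    pts <- grid$positions[idx, , drop = FALSE]
    if (n > nrow(unique(pts))) {
      stop(sprintf(
        "n_per_hemisphere = %d exceeds the %d distinct grid points in the %s hemisphere",
        n, nrow(unique(pts)), hemi), call. = FALSE)
    }
    cl <- if (n == 1) rep(1L, nrow(pts)) else with_seed(seed,
      stats::kmeans(pts, centers = n, nstart = 5, iter.max = 100)$cluster)
    labels[idx] <- cl + if (hemi == "R") n else 0L
  }
  structure(
    list(labels = labels, hemisphere = ifelse(right, "R", "L"),
         n_per_hemisphere = n, seed = seed),
    class = "sublobe_atlas")
}

#' @export
print.sublobe_atlas <- function(x, ...) {
  cat(sprintf("<sublobe_atlas> %d regions per hemisphere over %d grid points\n",
              x$n_per_hemisphere, length(x$labels)))
  invisible(x)
}

#' Sublobar and hemispheric concordance of a source maximum
#'
#' The maximum is concordant at sublobe level if its atlas label occurs
#' among the mask members' labels, and at hemisphere level analogously.
#'
#' @param max_index 1-based grid index.
#' @param atlas A `sublobe_atlas`.
#' @param mask A `resection_mask`.
#' @return List with logical `concordant_sublobe`, `concordant_hemisphere`.
#' @export
sublobar_concordance <- function(max_index, atlas, mask) {
  stopifnot(inherits(atlas, "sublobe_atlas"), inherits(mask, "resection_mask"))
  mi <- as.integer(max_index)
  if (mi < 1 || mi > length(atlas$labels)) {
    stop("max_index out of atlas range", call. = FALSE)
  }
  list(
    concordant_sublobe = atlas$labels[mi] %in% atlas$labels[mask$members],
    concordant_hemisphere =
      atlas$hemisphere[mi] %in% atlas$hemisphere[mask$members])
}

#' Spike-count subsampling experiment
#'
#' Quantifies the effect of the number of averaged spikes on localization:
#' the source maximum of the full-epoch average is computed once; for each
#' requested N and repetition, N epochs are drawn without replacement,
#' averaged, the half-rise sample found, the inverse applied there, and the
#' distances of the resulting maximum to the full-average maximum and to
#' the resection mask recorded.
#'
#' @param epochs List of `epoch` objects (the cluster's accepted epochs).
#' @param op An `inverse_operator`.
#' @param grid The matching `source_grid`.
#' @param mask A `resection_mask`.
#' @param Ns Strictly increasing spike counts, each <= length(epochs).
#' @param n_reps Repetitions per N (>= 1). Default 25.
#' @param seed RNG seed; one deterministic substream per (N, rep).
#' @param half_rise_args Optional list of extra arguments to
#'   [find_half_rise()].
#' @return Object of class `subsampling_curve`: data frame `curve` with
#'   columns N, n_reps, mean_dist_full_mm, sd_dist_full_mm,
#'   mean_dist_resection_mm, sd_dist_resection_mm; plus `full_max_index`,
#'   `full_dist_resection_mm`, `N_total`, `seed`, and the per-draw `draws`
#'   data frame.
#' @export
subsample_experiment <- function(epochs, op, grid, mask, Ns, n_reps = 25,
                                 seed = 1, half_rise_args = list()) {
  N_total <- length(epochs)
  Ns <- as.integer(Ns)
  if (length(Ns) == 0) stop("Ns must be non-empty", call. = FALSE)
  if (any(diff(Ns) <= 0)) {
    stop("Ns must be strictly increasing", call. = FALSE)
  }
  if (any(Ns < 1) || any(Ns > N_total)) {
    stop(sprintf("every N must be in [1, %d] (number of epochs)", N_total),
         call. = FALSE)
  }
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)

  localize <- function(eps) {
    avg <- average_epochs(eps)
    hr <- do.call(find_half_rise, c(list(avg), half_rise_args))
    find_source_maximum(apply_inverse(op, avg, hr))
  }
  full_max <- localize(epochs)
  full_pos <- grid$positions[full_max, ]
  full_dist_res <- distance_to_mask(full_max, mask, grid)

  draws <- vector("list", length(Ns) * n_reps)
  k <- 0L
  for (ni in seq_along(Ns)) {
    N <- Ns[ni]
    for (rep in seq_len(n_reps)) {
      pick <- with_seed(seed + 7919L * ni + rep,
                        sample.int(N_total, N))
      mi <- localize(epochs[pick])
      k <- k + 1L
      draws[[k]] <- data.frame(
        N = N, rep = rep, max_index = mi,
        dist_full_mm = sqrt(sum((grid$positions[mi, ] - full_pos)^2)),
        dist_resection_mm = distance_to_mask(mi, mask, grid))
    }
  }
  draws <- do.call(rbind, draws)
  agg <- do.call(rbind, lapply(split(draws, draws$N), function(d) {
    data.frame(N = d$N[1], n_reps = nrow(d),
               mean_dist_full_mm = mean(d$dist_full_mm),
               sd_dist_full_mm = stats::sd(d$dist_full_mm),
               mean_dist_resection_mm = mean(d$dist_resection_mm),
               sd_dist_resection_mm = stats::sd(d$dist_resection_mm))
  }))
  agg <- agg[order(agg$N), , drop = FALSE]
  rownames(agg) <- NULL
  structure(
    list(curve = agg, draws = draws, full_max_index = full_max,
         full_dist_resection_mm = full_dist_res, N_total = N_total,
         seed = seed),
    class = "subsampling_curve")
}

#' @export
print.subsampling_curve <- function(x, ...) {
  cat(sprintf("<subsampling_curve> N_total = %d, full max index %d (%.1f mm to resection)\n",
              x$N_total, x$full_max_index, x$full_dist_resection_mm))
  print(x$curve)
  invisible(x)
}

#' Smallest stable spike count below a distance threshold
#'
#' The smallest sampled N whose mean distance to the full-average maximum is
#' below the threshold, requiring all larger sampled N to be below it too
#' (a stability criterion); NA if no such N exists.
#'
#' @param curve A `subsampling_curve` (or its `curve` data frame).
#' @param threshold_mm Distance threshold, mm (> 0). Default 10 (1 cm).
#' @return Integer N, or NA_integer_ if absent.
#' @export
smallest_N_below <- function(curve, threshold_mm = 10) {
  if (threshold_mm <= 0) stop("threshold_mm must be > 0", call. = FALSE)
  df <- if (inherits(curve, "subsampling_curve")) curve$curve else curve
  below <- df$mean_dist_full_mm < threshold_mm
  n <- length(below)
  ok <- rev(cumprod(rev(below))) == 1   # below here and at all larger N
  if (!any(ok)) return(NA_integer_)
  as.integer(df$N[which(ok)[1]])
}
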
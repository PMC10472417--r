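#' Weighted minimum-norm (wMNE) source estimation
#'
#' Regularized linear inverse with per-source depth weights. The kernel is
#' M = W L' (L W L' + lambda^2 C)^-1 with depth weights
#' w_s = ||L_s||^(-2 gamma) (Frobenius norm of the source's 3-column gain
#' block), lambda^2 = trace(L W L') / (trace(C) * snr^2), noise covariance
#' C estimated from pre-event baselines with diagonal loading. Free source
#' orientation: the map value is the Euclidean norm of the 3-vector
#' estimate at one time sample.
#'
#' @name hdesi-inverse
NULL

#' Estimate the noise covariance from epoch baselines
#'
#' Sample covariance of baseline samples pooled across epochs (per-epoch
#' channel means removed), with diagonal loading
#' C <- (1 - alpha) C + alpha * mean(diag(C)) * I.
#'
#' @param epochs List of `epoch` objects.
#' @param baseline_window Window relative to the event, s.
#' @param loading_frac Diagonal-loading fraction alpha in [0, 1].
#' @return Object of class `noise_cov`: `cov` (channels x channels, uV^2),
#'   `loading_frac`, `n_samples`.
#' @export
estimate_noise_covariance <- function(epochs, baseline_window = c(-1.5, -0.5),
                                      loading_frac = 0.05) {
  if (length(epochs) == 0) stop("no epochs", call. = FALSE)
  if (loading_frac < 0 || loading_frac > 1) {
    stop("loading_frac must be in [0, 1]", call. = FALSE)
  }
  rate <- epochs[[1]]$sampling_rate_hz
  center <- epochs[[1]]$center_sample
  idx <- center + round(baseline_window[1] * rate):
    round(baseline_window[2] * rate)
  n_s <- ncol(epochs[[1]]$data)
  if (any(idx < 1) || any(idx > n_s)) {
    stop("baseline window outside epoch", call. = FALSE)
  }
  pooled <- do.call(cbind, lapply(epochs, function(ep) {
    b <- ep$data[, idx, drop = FALSE]
    b - rowMeans(b)
  }))
  if (ncol(pooled) < 50) {
    stop("too few baseline samples (< 50) for covariance estimation",
         call. = FALSE)
  }
  C <- tcrossprod(pooled) / (ncol(pooled) - 1)
  C <- (1 - loading_frac) * C +
    loading_frac * mean(diag(C)) * diag(nrow(C))
  structure(list(cov = C, loading_frac = loading_frac,
                 n_samples = ncol(pooled)),
            class = "noise_cov")
}

#' Compute the wMNE inverse operator
#'
#' @param leadfield A `leadfield`.
#' @param noise_cov A `noise_cov` (or a plain channels x channels matrix;
#'   identity scaled to 1 uV^2 if omitted).
#' @param snr Assumed amplitude signal-to-noise ratio (> 0); sets the
#'   regularization via lambda^2 = trace(L W L') / (trace(C) snr^2).
#'   Default 3.
#' @param depth_exponent Depth-weighting exponent gamma in [0, 1]; 0 gives
#'   plain (unweighted) MNE. Default 0.5.
#' @return Object of class `inverse_operator`: `kernel`
#'   ((3 n_sources) x channels), `lambda2`, `depth_exponent`, `weights`
#'   (per source), plus grid/channel references.
#' @export
compute_wmne_operator <- function(leadfield, noise_cov = NULL, snr = 3,
                                  depth_exponent = 0.5) {
  stopifnot(inherits(leadfield, "leadfield"))
  if (snr <= 0) stop("snr must be > 0", call. = FALSE)
  if (depth_exponent < 0 || depth_exponent > 1) {
    stop("depth_exponent must be in [0, 1]", call. = FALSE)
  }
  L <- leadfield$gain
  n_ch <- nrow(L)
  n_src <- ncol(L) / 3
  C <- if (is.null(noise_cov)) {
    diag(n_ch)
  } else if (inherits(noise_cov, "noise_cov")) {
    noise_cov$cov
  } else {
    as.matrix(noise_cov)
  }
  if (!identical(dim(C), c(n_ch, n_ch))) {
    stop("noise covariance does not match channel count", call. = FALSE)
  }
  blk_norm2 <- colSums(L^2)
  w <- (blk_norm2[seq(1, ncol(L), 3)] + blk_norm2[seq(2, ncol(L), 3)] +
          blk_norm2[seq(3, ncol(L), 3)])
  weights <- w^(-depth_exponent)            # ||L_s||^(-2 gamma)
  wfull <- rep(weights, each = 3)
  LW <- sweep(L, 2, wfull, "*")             # L W
  A <- tcrossprod(LW, L)                    # L W L'
  lambda2 <- sum(diag(A)) / (sum(diag(C)) * snr^2)
  S <- A + lambda2 * C
  kernel <- t(solve(S, LW))                 # W L' (L W L' + l2 C)^-1
  if (any(!is.finite(kernel))) {
    stop("inverse operator is not finite (singular system)", call. = FALSE)
  }
  structure(
    list(kernel = kernel, lambda2 = lambda2,
         depth_exponent = depth_exponent, snr = snr, weights = weights,
         n_sources = n_src, channel_ids = rownames(L), grid = leadfield$grid),
    class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf(
    "<inverse_operator> wMNE, %d sources x %d channels, lambda2 = %.4g, gamma = %g\n",
    x$n_sources, ncol(x$kernel), x$lambda2, x$depth_exponent))
  invisible(x)
}

#' Apply the inverse operator at one time sample
#'
#' The data column is average-referenced, multiplied by the kernel, and the
#' per-source 3-vector estimates reduced to their Euclidean norms.
#'
#' @param op An `inverse_operator`.
#' @param avg An `average_ied` (or a channels x samples matrix).
#' @param sample Sample index (e.g. from [find_half_rise()]).
#' @return Object of class `source_map`: `values` (nAm, >= 0, one per grid
#'   point), `sample`, `n_sources`.
#' @export
apply_inverse <- function(op, avg, sample) {
  stopifnot(inherits(op, "inverse_operator"))
  m <- if (inherits(avg, "average_ied")) avg$mean else as.matrix(avg)
  if (nrow(m) != ncol(op$kernel)) {
    stop("channel count does not match the inverse operator", call. = FALSE)
  }
  if (sample < 1 || sample > ncol(m)) {
    stop("sample index out of range", call. = FALSE)
  }
  d <- m[, sample]
  d <- d - mean(d)
  j <- matrix(op$kernel %*% d, nrow = 3)
  structure(
    list(values = sqrt(colSums(j^2)), sample = as.integer(sample),
         n_sources = op$n_sources),
    class = "source_map")
}

#' @export
print.source_map <- function(x, ...) {
  cat(sprintf("<source_map> %d sources @ sample %d, max %.4g nAm\n",
              x$n_sources, x$sample, max(x$values)))
  invisible(x)
}

#' Grid index of the source maximum
#'
#' @param map A `source_map` (non-empty, not all zero).
#' @return 1-based grid index of the maximum amplitude; ties broken by the
#'   lowest index.
#' @export
find_source_maximum <- function(map) {
  stopifnot(inherits(map, "source_map"))
  if (length(map$values) == 0 || all(map$values == 0)) {
    stop("source map has no maximum (all zero)", call. = FALSE)
  }
  which.max(map$values)
}

#' Export a source map as TSV
#'
#' Columns: grid_index, x, y, z (mm), amplitude (nAm).
#'
#' @param map A `source_map`.
#' @param grid The matching `source_grid`.
#' @param path Output file.
#' @export
write_source_map_tsv <- function(map, grid, path) {
  stopifnot(inherits(map, "source_map"), inherits(grid, "source_grid"))
  df <- data.frame(grid_index = seq_len(grid$n_points),
                   x = grid$positions[, 1], y = grid$positions[, 2],
                   z = grid$positions[, 3], amplitude = map$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
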
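#' Epoch extraction, artifact rejection, averaging and half-rise timing
#'
#' Event epochs of +-2 s around each mark are clipped from the recording,
#' cleaned of artifacts by a peak-to-peak criterion, and averaged within a
#' cluster to improve signal-to-noise ratio. Source reconstruction uses the
#' time point at the 50 percent rising phase of the averaged discharge.
#'
#' @name hdesi-epochs
NULL

#' Extract event epochs around marks
#'
#' One epoch of `2 * half_width_s` seconds (an odd number of samples,
#' centred on the mark) per mark lying fully inside the recording; marks
#' too close to an edge are skipped and counted.
#'
#' @param recording A `sim_recording` (or list with `data`,
#'   `sampling_rate_hz`, `channel_ids`).
#' @param marks A `mark_list` or numeric times, s.
#' @param half_width_s Half window, s (> 0). Default 2.
#' @return List of `epoch` objects (fields `data`, `sampling_rate_hz`,
#'   `event_time_s`, `center_sample`); attribute `n_skipped_edge` counts
#'   skipped marks.
#' @export
extract_epochs <- function(recording, marks, half_width_s = 2) {
  if (half_width_s <= 0) stop("half_width_s must be > 0", call. = FALSE)
  rate <- recording$sampling_rate_hz
  t <- if (is.data.frame(marks)) marks$time_s else as.numeric(marks)
  n_s <- ncol(recording$data)
  hw <- round(half_width_s * rate)
  center <- round(t * rate) + 1L
  ok <- center - hw >= 1L & center + hw <= n_s
  epochs <- lapply(which(ok), function(i) {
    idx <- (center[i] - hw):(center[i] + hw)
    structure(
      list(data = recording$data[, idx, drop = FALSE],
           sampling_rate_hz = rate, event_time_s = t[i],
           center_sample = hw + 1L, half_width_s = half_width_s),
      class = "epoch")
  })
  attr(epochs, "n_skipped_edge") <- sum(!ok)
  epochs
}

#' Reject artifact epochs by peak-to-peak amplitude
#'
#' Drops epochs whose maximum single-channel peak-to-peak amplitude exceeds
#' the threshold; order is preserved. The criterion is a pragmatic stand-in
#' for visual artifact cleaning.
#'
#' @param epochs List of `epoch` objects.
#' @param ptp_threshold_uV Threshold, microvolts (> 0). Default 300.
#' @return The retained epochs; attribute `n_rejected` counts drops.
#' @export
reject_artifact_epochs <- function(epochs, ptp_threshold_uV = 300) {
  if (ptp_threshold_uV <= 0) {
    stop("ptp_threshold_uV must be > 0", call. = FALSE)
  }
  ptp <- vapply(epochs, function(ep) {
    max(apply(ep$data, 1, function(x) diff(range(x))))
  }, numeric(1))
  keep <- ptp <= ptp_threshold_uV
  if (!any(keep) && length(epochs) > 0) {
    warning("all epochs rejected by peak-to-peak criterion", call. = FALSE)
  }
  out <- epochs[keep]
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Average epochs into a mean discharge
#'
#' Arithmetic mean across epochs of identical shape. The peak channel is
#' the channel with the largest absolute mean amplitude in the centre
#' region (+-150 ms around the mark).
#'
#' @param epochs Non-empty list of `epoch` objects with identical shapes.
#' @return Object of class `average_ied`: `mean` (channels x samples, uV),
#'   `n_epochs`, `sampling_rate_hz`, `center_sample`, `peak_channel_idx`,
#'   `peak_sample`.
#' @export
average_epochs <- function(epochs) {
  if (length(epochs) == 0) stop("no epochs to average", call. = FALSE)
  dims <- lapply(epochs, function(ep) dim(ep$data))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("epoch shapes differ", call. = FALSE)
  }
  m <- Reduce(`+`, lapply(epochs, `[[`, "data")) / length(epochs)
  rate <- epochs[[1]]$sampling_rate_hz
  center <- epochs[[1]]$center_sample
  halo <- round(0.150 * rate)
  win <- max(1L, center - halo):min(ncol(m), center + halo)
  sub <- abs(m[, win, drop = FALSE])
  pk <- arrayInd(which.max(sub), dim(sub))
  structure(
    list(mean = m, n_epochs = length(epochs), sampling_rate_hz = rate,
         center_sample = center,
         peak_channel_idx = pk[1], peak_sample = win[pk[2]]),
    class = "average_ied")
}

#' @export
print.average_ied <- function(x, ...) {
  cat(sprintf(
    "<average_ied> %d epochs, %d ch x %d samples, peak ch %d @ sample %d\n",
    x$n_epochs, nrow(x$mean), ncol(x$mean), x$peak_channel_idx,
    x$peak_sample))
  invisible(x)
}

#' Find the 50 percent rising-phase sample
#'
#' On the peak channel (default) or the global field power, the baseline is
#' the mean of a pre-event window; the rising phase runs from the last
#' baseline crossing before the peak to the peak; the function returns the
#' first sample at which the absolute excursion reaches half of
#' peak-minus-baseline. Polarity-agnostic; invariant to amplitude scaling
#' and DC offsets.
#'
#' @param avg An `average_ied`.
#' @param baseline_window Window relative to the event, s. Default
#'   c(-1.5, -0.5) (clear of both edges and the discharge's own rise).
#' @param mode "peak_channel" (default) or "gfp" (global field power).
#' @param min_snr Minimum |peak - baseline| in baseline SDs for a peak to
#'   count as detectable. Default 5.
#' @return Half-rise sample index (strictly before the peak sample).
#' @export
find_half_rise <- function(avg, baseline_window = c(-1.5, -0.5),
                           mode = c("peak_channel", "gfp"), min_snr = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(avg, "average_ied"))
  rate <- avg$sampling_rate_hz
  x <- if (mode == "gfp") {
    apply(apply_average_reference(avg$mean), 2, stats::sd)
  } else {
    avg$mean[avg$peak_channel_idx, ]
  }
  bidx <- avg$center_sample + round(baseline_window[1] * rate):
    round(baseline_window[2] * rate)
  bidx <- bidx[bidx >= 1 & bidx <= length(x)]
  if (length(bidx) < 2) stop("baseline window outside epoch", call. = FALSE)
  base <- mean(x[bidx])
  bsd <- stats::sd(x[bidx])
  pk <- if (mode == "gfp") which.max(x) else avg$peak_sample
  excur <- abs(x[pk] - base)
  if (!is.finite(excur) || excur == 0 || (bsd > 0 && excur < min_snr * bsd)) {
    stop("no detectable peak above baseline", call. = FALSE)
  }
  s <- sign(x[pk] - base)
  y <- s * (x - base)                 # positive-going excursion
  before <- y[seq_len(pk - 1)]
  crossings <- which(before <= 0)
  if (length(crossings) == 0) {
    stop("no baseline crossing before the peak", call. = FALSE)
  }
  onset <- max(crossings)
  seg <- onset:(pk - 1L)
  half <- seg[which(y[seg] >= 0.5 * y[pk])[1]]
  if (is.na(half)) stop("no half-rise point before the peak", call. = FALSE)
  half
}
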
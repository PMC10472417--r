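#' Synthetic hdEEG with ground-truthed spike-wave events
#'
#' Generator for the simulated recordings all downstream stages consume:
#' a spike-wave template, 1/f-like multichannel background, dipolar events
#' projected through the lead field at known grid locations, and a
#' synthetic resection mask around the true source.
#'
#' @name hdesi-synthetic
NULL

# run code under a fixed RNG seed without clobbering the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a spike-wave template
#'
#' Biphasic interictal-discharge morphology: a sharp Gaussian spike followed
#' by a slower wave of opposite sign at 30 percent relative amplitude,
#' normalized to unit peak. Widths are full widths at half maximum.
#'
#' @param rate Sampling rate in Hz; 250 or 1000.
#' @param spike_width_ms Spike FWHM, ms (> 0). Default 70.
#' @param slow_wave_width_ms Slow-wave FWHM, ms (> 0). Default 300.
#' @param polarity +1 or -1.
#' @return Object of class `ied_template`: `waveform` (unit peak),
#'   `sampling_rate_hz`, `peak_sample`, `spike_segment` (index range of the
#'   sharp transient, used as the matched-filter kernel), widths, polarity.
#' @export
generate_ied_template <- function(rate = 250, spike_width_ms = 70,
                                  slow_wave_width_ms = 300, polarity = 1) {
  if (!rate %in% c(250, 1000)) {
    stop("rate must be 250 or 1000 Hz", call. = FALSE)
  }
  if (spike_width_ms <= 0 || slow_wave_width_ms <= 0) {
    stop("widths must be positive", call. = FALSE)
  }
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1", call. = FALSE)
  sig_s <- spike_width_ms / 1e3 / (2 * sqrt(2 * log(2)))
  sig_w <- slow_wave_width_ms / 1e3 / (2 * sqrt(2 * log(2)))
  delta <- (spike_width_ms + slow_wave_width_ms) / 2 / 1e3  # wave peak offset
  pad <- 5.5  # Gaussian support: exp(-5.5^2/2) ~ 2.7e-7 < 1e-6 endpoint tol
  t0 <- min(-pad * sig_s, delta - pad * sig_w)
  t1 <- max(pad * sig_s, delta + pad * sig_w)
  t <- seq(floor(t0 * rate), ceiling(t1 * rate)) / rate
  w <- exp(-t^2 / (2 * sig_s^2)) - 0.3 * exp(-(t - delta)^2 / (2 * sig_w^2))
  peak <- which.max(abs(w))
  w <- polarity * w / abs(w[peak])
  half_spike <- round(spike_width_ms / 1e3 * rate)
  seg <- max(1, peak - half_spike):min(length(w), peak + half_spike)
  structure(
    list(waveform = w, sampling_rate_hz = rate, peak_sample = peak,
         spike_segment = seg, spike_width_ms = spike_width_ms,
         slow_wave_width_ms = slow_wave_width_ms, polarity = polarity),
    class = "ied_template"
  )
}

#' Generate 1/f-like multichannel background noise
#'
#' Independent per-channel Gaussian noise shaped in the frequency domain to
#' a power spectral density proportional to 1/f^exponent, scaled to a target
#' RMS. Reproducible bit-for-bit under a fixed seed.
#'
#' @param n_channels,n_samples Array dimensions.
#' @param rate Sampling rate, Hz.
#' @param spectral_exponent PSD exponent in [0, 2]; 0 gives white noise.
#' @param rms_uV Target per-channel RMS in microvolts (> 0).
#' @param seed RNG seed.
#' @return channels x samples matrix, microvolts.
#' @export
generate_background <- function(n_channels, n_samples, rate = 250,
                                spectral_exponent = 1, rms_uV = 15,
                                seed = 1) {
  if (!is.numeric(rms_uV) || rms_uV <= 0) {
    stop("rms_uV must be positive", call. = FALSE)
  }
  if (spectral_exponent < 0 || spectral_exponent > 2) {
    stop("spectral_exponent must be in [0, 2]", call. = FALSE)
  }
  with_seed(seed, {
    freqs <- seq(0, n_samples - 1) / n_samples * rate
    freqs <- pmin(freqs, rate - freqs)      # two-sided
    gains <- rep(1, n_samples)
    nz <- freqs > 0
    gains[nz] <- freqs[nz]^(-spectral_exponent / 2)
    gains[!nz] <- 0                          # zero-mean
    out <- matrix(0, n_channels, n_samples)
    for (ch in seq_len(n_channels)) {
      white <- rnorm(n_samples)
      shaped <- Re(stats::fft(stats::fft(white) * gains, inverse = TRUE)) /
        n_samples
      out[ch, ] <- shaped * (rms_uV / sqrt(mean(shaped^2)))
    }
    out
  })
}

#' Simulate an hdEEG recording with embedded spike-wave events
#'
#' Each event projects the template, scaled by `amplitude_nAm` with
#' multiplicative jitter, through the lead-field columns of its grid point
#' with a fixed moment orientation; 1/f background is added once. Ground
#' truth (times, grid index, moment) is carried with the recording.
#'
#' Events are placed on a jittered regular schedule keeping >= 4 s between
#' peaks and >= 2 s from the edges, so +-2 s epochs never overlap; pass
#' `event_times` to control placement exactly.
#'
#' @param leadfield A `leadfield`.
#' @param template An `ied_template` (its rate must equal `rate`).
#' @param n_events Number of events (>= 0).
#' @param event_grid_index 1-based grid index of the source (scalar or
#'   length `n_events`).
#' @param amplitude_nAm Dipole moment magnitude per event, nAm. Default 800
#'   (typical equivalent-dipole strength of a scalp-visible spike).
#' @param jitter_amplitude_frac Multiplicative amplitude jitter, uniform in
#'   +-frac. Default 0.2.
#' @param noise_rms_uV Background RMS per channel; 0 for noiseless.
#' @param duration_s Recording length, s.
#' @param rate Sampling rate, Hz (250 or 1000).
#' @param seed RNG seed controlling placement, jitter and background.
#' @param moment "radial" (default), "tangential", or a unit 3-vector.
#' @param event_times Optional explicit peak times (s), overrides placement.
#' @param spectral_exponent Background PSD exponent. Default 1.
#' @return Object of class `sim_recording`: `data` (channels x samples,
#'   uV), `sampling_rate_hz`, `events` data frame (time_s, sample,
#'   grid_index, mx, my, mz, amplitude_scale), `seed`, and geometry refs.
#' @export
simulate_recording <- function(leadfield, template, n_events,
                               event_grid_index, amplitude_nAm = 800,
                               jitter_amplitude_frac = 0.2,
                               noise_rms_uV = 15, duration_s = 120,
                               rate = 250, seed = 1, moment = "radial",
                               event_times = NULL, spectral_exponent = 1) {
  stopifnot(inherits(leadfield, "leadfield"), inherits(template, "ied_template"))
  if (template$sampling_rate_hz != rate) {
    stop("template rate does not match recording rate", call. = FALSE)
  }
  if (n_events < 0) stop("n_events must be >= 0", call. = FALSE)
  n_src <- ncol(leadfield$gain) / 3
  gi <- rep_len(as.integer(event_grid_index), max(n_events, 1L))
  if (n_events > 0 && (any(gi < 1) || any(gi > n_src))) {
    stop("event_grid_index out of grid range", call. = FALSE)
  }
  n_samples <- round(duration_s * rate)
  edge_s <- 2; gap_s <- 4

  if (is.null(event_times)) {
    if (n_events > 0) {
      avail <- duration_s - 2 * edge_s
      if (n_events * gap_s > avail || avail < 0) {
        stop(sprintf(
          "capacity: %d events with %g s spacing do not fit in %g s",
          n_events, gap_s, duration_s), call. = FALSE)
      }
      slot <- avail / max(n_events, 1)
      base <- edge_s + slot * (seq_len(n_events) - 0.5)
      jit_max <- max(0, (slot - gap_s) / 2)
      event_times <- with_seed(seed * 3L + 1L,
        base + stats::runif(n_events, -jit_max, jit_max))
    } else {
      event_times <- numeric(0)
    }
  } else {
    event_times <- as.numeric(event_times)
    if (length(event_times) != n_events) {
      stop("event_times length must equal n_events", call. = FALSE)
    }
    if (n_events > 0 &&
        (any(event_times < edge_s) || any(event_times > duration_s - edge_s) ||
         (n_events > 1 && min(diff(sort(event_times))) < gap_s))) {
      stop("capacity: event times violate 4 s spacing / 2 s edge margin",
           call. = FALSE)
    }
  }
  event_times <- round(event_times * rate) / rate

  data <- if (noise_rms_uV > 0) {
    generate_background(nrow(leadfield$gain), n_samples, rate,
                        spectral_exponent, noise_rms_uV, seed)
  } else {
    matrix(0, nrow(leadfield$gain), n_samples)
  }

  scales <- if (n_events > 0) {
    with_seed(seed * 3L + 2L,
      1 + stats::runif(n_events, -jitter_amplitude_frac, jitter_amplitude_frac))
  } else numeric(0)

  grid_pos <- leadfield$grid$positions
  moments <- matrix(0, max(n_events, 1L), 3)
  w <- template$waveform
  pk <- template$peak_sample
  if (n_events > 0) {
    for (e in seq_len(n_events)) {
      m <- event_moment(moment, grid_pos[gi[e], ])
      moments[e, ] <- m
      topo <- drop(leadfield_block(leadfield, gi[e]) %*% m) *
        amplitude_nAm * scales[e]
      s0 <- round(event_times[e] * rate) + 1L - (pk - 1L)
      idx <- s0:(s0 + length(w) - 1L)
      ok <- idx >= 1L & idx <= n_samples
      data[, idx[ok]] <- data[, idx[ok]] + outer(topo, w[ok])
    }
  }
  ord <- order(event_times)
  events <- data.frame(
    time_s = event_times[ord],
    sample = round(event_times[ord] * rate) + 1L,
    grid_index = if (n_events > 0) gi[ord] else integer(0),
    mx = if (n_events > 0) moments[ord, 1] else numeric(0),
    my = if (n_events > 0) moments[ord, 2] else numeric(0),
    mz = if (n_events > 0) moments[ord, 3] else numeric(0),
    amplitude_scale = if (n_events > 0) scales[ord] else numeric(0))
  structure(
    list(data = data, sampling_rate_hz = rate, events = events, seed = seed,
         amplitude_nAm = amplitude_nAm, noise_rms_uV = noise_rms_uV,
         electrodes = leadfield$electrodes, grid = leadfield$grid,
         channel_ids = leadfield$electrodes$channel_ids),
    class = "sim_recording"
  )
}

event_moment <- function(moment, pos) {
  if (is.character(moment)) {
    b <- sqrt(sum(pos^2))
    radial <- if (b > 0) pos / b else c(0, 0, 1)
    switch(moment,
      radial = radial,
      tangential = {
        ref <- if (abs(radial[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
        t1 <- ref - sum(ref * radial) * radial
        t1 / sqrt(sum(t1^2))
      },
      stop("moment must be 'radial', 'tangential' or a 3-vector",
           call. = FALSE))
  } else {
    m <- as.numeric(moment)
    if (length(m) != 3 || sum(m^2) == 0) {
      stop("moment must be a nonzero 3-vector", call. = FALSE)
    }
    m / sqrt(sum(m^2))
  }
}

#' @export
print.sim_recording <- function(x, ...) {
  cat(sprintf(
    "<sim_recording> %d ch x %d samples @ %g Hz, %d ground-truth events\n",
    nrow(x$data), ncol(x$data), x$sampling_rate_hz, nrow(x$events)))
  invisible(x)
}

#' Synthetic resection mask around a grid point
#'
#' All grid points within `radius_mm` of the centre point (the centre is
#' always a member). Stands in for the resected volume the evaluation
#' stages score against.
#'
#' @param grid A `source_grid`.
#' @param center_index 1-based grid index of the mask centre.
#' @param radius_mm Sphere radius, mm (>= 0).
#' @return Object of class `resection_mask`: `members` (sorted indices),
#'   `center_index`, `radius_mm`.
#' @export
make_resection_mask <- function(grid, center_index, radius_mm) {
  stopifnot(inherits(grid, "source_grid"))
  if (radius_mm < 0) stop("radius_mm must be >= 0", call. = FALSE)
  ci <- as.integer(center_index)
  if (length(ci) != 1 || is.na(ci) || ci < 1 || ci > grid$n_points) {
    stop("center_index out of grid range", call. = FALSE)
  }
  d2 <- rowSums(sweep(grid$positions, 2, grid$positions[ci, ])^2)
  members <- sort(unique(c(ci, which(d2 <= radius_mm^2))))
  structure(list(members = members, center_index = ci, radius_mm = radius_mm),
            class = "resection_mask")
}

#' @export
print.resection_mask <- function(x, ...) {
  cat(sprintf("<resection_mask> %d grid points, r = %g mm around index %d\n",
              length(x$members), x$radius_mm, x$center_index))
  invisible(x)
}
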
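# Shared fixtures, built once per test session and cached. All synthetic;
# nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 64-channel montage on the default head with a 10 mm grid: the workhorse
# for simulation-based tests (criteria that pin the 5 mm grid build their
# own context)
small_context <- function() {
  fixture("small_context", function() {
    head <- three_shell_head()
    electrodes <- build_electrode_array(64, 140)
    grid <- build_source_grid(head, 10)
    lf <- compute_leadfield(head, electrodes, grid)
    list(head = head, electrodes = electrodes, grid = grid, leadfield = lf)
  })
}

# 16-channel montage with a coarse 20 mm grid for cheap structural tests
tiny_context <- function() {
  fixture("tiny_context", function() {
    head <- three_shell_head()
    electrodes <- build_electrode_array(16, 140)
    grid <- build_source_grid(head, 20)
    lf <- compute_leadfield(head, electrodes, grid)
    list(head = head, electrodes = electrodes, grid = grid, leadfield = lf)
  })
}

# a source index near 0.6 brain radius under the cap, deterministic
fixture_source <- function(ctx, radius_frac = 0.6) {
  pos <- ctx$grid$positions
  r <- sqrt(rowSums(pos^2))
  target <- radius_frac * ctx$grid$brain_radius_mm
  upper <- pos[, 3] > 0
  cand <- which(upper)
  cand[which.min(abs(r[cand] - target))]
}

# simulated recording with default spike/noise calibration
fixture_recording <- function(ctx = small_context(), n_events = 10,
                              duration_s = 60, noise_rms_uV = 15,
                              amplitude_nAm = 800, seed = 42, ...) {
  tpl <- generate_ied_template(250)
  src <- fixture_source(ctx)
  rec <- simulate_recording(
    ctx$leadfield, tpl, n_events, src, amplitude_nAm,
    jitter_amplitude_frac = 0.2, noise_rms_uV = noise_rms_uV,
    duration_s = duration_s, rate = 250, seed = seed, ...)
  list(recording = rec, template = tpl, source = src, context = ctx)
}

# epochs of clean topography * template + white channel noise, built
# directly (no recording), for averaging-law tests
make_noisy_epochs <- function(n, topo, waveform, center, n_samples, rate,
                              noise_sd, seed) {
  clean <- matrix(0, length(topo), n_samples)
  idx <- (center - length(waveform) %/% 2):(center + (length(waveform) -
                                                        1) %/% 2)
  clean[, idx] <- outer(topo, waveform)
  withr_seed <- function(s, code) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); force(code)
  }
  eps <- withr_seed(seed, lapply(seq_len(n), function(i) {
    structure(
      list(data = clean + matrix(stats::rnorm(length(clean), sd = noise_sd),
                                 nrow(clean)),
           sampling_rate_hz = rate, event_time_s = center / rate,
           center_sample = center, half_width_s = (n_samples - 1) / 2 / rate),
      class = "epoch")
  }))
  list(epochs = eps, clean = clean)
}
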
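test_that("template is unit-peak, biphasic and polarity-symmetric", {
  tpl <- generate_ied_template(250, 70, 300, 1)
  expect_equal(max(abs(tpl$waveform)), 1)
  expect_equal(sum(abs(tpl$waveform) == 1), 1)
  expect_equal(abs(tpl$waveform[tpl$peak_sample]), 1)
  expect_lt(max(abs(tpl$waveform[c(1, length(tpl$waveform))])), 1e-6)
  # slow wave of opposite sign after the spike
  after <- tpl$waveform[(tpl$peak_sample + round(0.15 * 250)):
                          length(tpl$waveform)]
  expect_lt(min(after), -0.2)
  neg <- generate_ied_template(250, 70, 300, -1)
  expect_equal(neg$waveform, -tpl$waveform)
})

test_that("1000 Hz template resamples onto the 250 Hz template", {
  t250 <- generate_ied_template(250)
  t1000 <- generate_ied_template(1000)
  # align on peaks and compare on the common grid (every 4th sample)
  k <- seq_along(t250$waveform) - t250$peak_sample
  hi <- t1000$peak_sample + 4 * k
  ok <- hi >= 1 & hi <= length(t1000$waveform)
  expect_gt(cor(t250$waveform[ok], t1000$waveform[hi[ok]]), 0.999)
})

test_that("template rejects invalid parameters", {
  expect_error(generate_ied_template(500), "250 or 1000")
  expect_error(generate_ied_template(250, spike_width_ms = 0), "positive")
  expect_error(generate_ied_template(250, slow_wave_width_ms = -1), "positive")
})

test_that("background noise is reproducible and hits the target RMS", {
  b1 <- generate_background(4, 5000, 250, 1, 15, seed = 9)
  b2 <- generate_background(4, 5000, 250, 1, 15, seed = 9)
  expect_identical(b1, b2)
  expect_equal(apply(b1, 1, function(x) sqrt(mean(x^2))), rep(15, 4))
  expect_error(generate_background(2, 100, 250, 1, 0), "positive")
  expect_error(generate_background(2, 100, 250, 3, 10), "exponent")
})

test_that("background spectral slope matches the requested exponent", {
  b <- generate_background(1, 60 * 250, 250, 1, 10, seed = 3)[1, ]
  sp <- stats::spec.pgram(b, taper = 0, plot = FALSE, detrend = FALSE)
  sel <- sp$freq > 0.005 & sp$freq < 0.4  # away from DC and Nyquist
  slope <- coef(lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2]
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)
})

test_that("exponent 0 gives white noise", {
  b <- generate_background(1, 60 * 250, 250, 0, 10, seed = 4)[1, ]
  rho <- cor(b[-1], b[-length(b)])
  expect_lt(abs(rho), 0.05)
})

test_that("recording with zero events equals the background exactly", {
  ctx <- tiny_context()
  tpl <- generate_ied_template(250)
  src <- fixture_source(ctx)
  rec <- simulate_recording(ctx$leadfield, tpl, 0, src, noise_rms_uV = 12,
                            duration_s = 20, seed = 5)
  bg <- generate_background(16, 20 * 250, 250, 1, 12, seed = 5)
  expect_identical(rec$data, bg)
  expect_equal(nrow(rec$events), 0L)
})

test_that("noiseless single event is the exact lead-field projection", {
  ctx <- tiny_context()
  tpl <- generate_ied_template(250)
  src <- fixture_source(ctx)
  rec <- simulate_recording(ctx$leadfield, tpl, 1, src,
                            amplitude_nAm = 500, jitter_amplitude_frac = 0,
                            noise_rms_uV = 0, duration_s = 20, seed = 5,
                            event_times = 10)
  pos <- ctx$grid$positions[src, ]
  m <- pos / sqrt(sum(pos^2))
  topo <- drop(leadfield_block(ctx$leadfield, src) %*% m) * 500
  peak_sample <- round(10 * 250) + 1
  expect_lt(max(abs(rec$data[, peak_sample] - topo)), 1e-9)
})

test_that("event superposition is exact", {
  ctx <- tiny_context()
  tpl <- generate_ied_template(250)
  src <- fixture_source(ctx)
  a <- simulate_recording(ctx$leadfield, tpl, 1, src, 500, 0, 0, 40, 250,
                          seed = 6, event_times = 10)
  b <- simulate_recording(ctx$leadfield, tpl, 1, src, 500, 0, 0, 40, 250,
                          seed = 6, event_times = 25)
  ab <- simulate_recording(ctx$leadfield, tpl, 2, src, 500, 0, 0, 40, 250,
                           seed = 6, event_times = c(10, 25))
  expect_lt(max(abs(a$data + b$data - ab$data)), 1e-9)
})

test_that("event placement respects spacing, margins and capacity", {
  ctx <- tiny_context()
  tpl <- generate_ied_template(250)
  src <- fixture_source(ctx)
  rec <- simulate_recording(ctx$leadfield, tpl, 10, src, duration_s = 60,
                            noise_rms_uV = 0, seed = 8)
  t <- rec$events$time_s
  expect_equal(t, sort(t))
  expect_true(all(diff(t) >= 4 - 1e-9))
  expect_true(all(t >= 2 & t <= 58))
  expect_error(
    simulate_recording(ctx$leadfield, tpl, 30, src, duration_s = 60,
                       seed = 1),
    "capacity")
  expect_error(
    simulate_recording(ctx$leadfield, tpl, 2, src, duration_s = 60, seed = 1,
                       event_times = c(10, 12)),
    "capacity")
  expect_error(
    simulate_recording(ctx$leadfield, tpl, 1, 10^6, duration_s = 60,
                       seed = 1),
    "grid")
})

test_that("recordings are bit-for-bit reproducible under a fixed seed", {
  fx1 <- fixture_recording(tiny_context(), n_events = 4, duration_s = 30,
                           seed = 77)
  fx2 <- fixture_recording(tiny_context(), n_events = 4, duration_s = 30,
                           seed = 77)
  expect_identical(fx1$recording$data, fx2$recording$data)
  expect_identical(fx1$recording$events, fx2$recording$events)
})

test_that("resection mask matches a brute-force distance filter", {
  grid <- small_context()$grid
  center <- fixture_source(small_context())
  m0 <- make_resection_mask(grid, center, 0)
  expect_equal(m0$members, center)
  m12 <- make_resection_mask(grid, center, 12)
  brute <- which(sqrt(rowSums(sweep(grid$positions, 2,
                                    grid$positions[center, ])^2)) <= 12)
  expect_equal(m12$members, sort(brute))
  m_all <- make_resection_mask(grid, center, 1000)
  expect_equal(m_all$members, seq_len(grid$n_points))
  expect_error(make_resection_mask(grid, 0, 5), "center_index")
  expect_error(make_resection_mask(grid, center, -1), "radius")
})
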
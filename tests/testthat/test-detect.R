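test_that("noiseless events are all detected at the right times", {
  fx <- fixture_recording(small_context(), n_events = 10, duration_s = 60,
                          noise_rms_uV = 0)
  det <- detect_events(fx$recording, fx$template)
  truth <- fx$recording$events$time_s
  m <- match_events(truth, det, tol_ms = 20)
  expect_equal(m$n_matched, 10L)
})

test_that("all-zero data yields zero detections", {
  ctx <- tiny_context()
  rec <- structure(
    list(data = matrix(0, 16, 250 * 20), sampling_rate_hz = 250,
         channel_ids = ctx$electrodes$channel_ids),
    class = "sim_recording")
  det <- detect_events(rec, generate_ied_template(250))
  expect_equal(nrow(det), 0L)
})

test_that("0.9-threshold detections are rarer on pure noise than on spikes", {
  ctx <- small_context()
  tpl <- generate_ied_template(250)
  src <- fixture_source(ctx)
  spikes <- simulate_recording(ctx$leadfield, tpl, 10, src, duration_s = 60,
                               seed = 21)
  noise <- simulate_recording(ctx$leadfield, tpl, 0, src, duration_s = 60,
                              seed = 21)
  n_spk <- nrow(filter_by_probability(detect_events(spikes, tpl), 0.9))
  n_noise <- nrow(filter_by_probability(detect_events(noise, tpl), 0.9))
  expect_lt(n_noise, n_spk)
})

test_that("detector validates rate and recording length", {
  fx <- fixture_recording(tiny_context(), n_events = 2, duration_s = 30)
  expect_error(detect_events(fx$recording, generate_ied_template(1000)),
               "rate")
  short <- fx$recording
  short$data <- short$data[, 1:500]
  expect_error(detect_events(short, fx$template), "10 s")
})

test_that("probability filter keeps the boundary and is monotone", {
  ev <- data.frame(
    peak_time_s = c(1, 2, 3), peak_sample = c(250, 500, 750),
    peak_channel = c("E001", "E002", "E003"),
    probability = c(0.89, 0.90, 0.95),
    peak_amplitude_uV = c(10, 20, 30), correlation = 0.9, score = 3)
  class(ev) <- c("detected_events", "data.frame")
  kept <- filter_by_probability(ev, 0.9)
  expect_equal(nrow(kept), 2L)            # "less than 0.9" excluded
  expect_equal(kept$probability, c(0.90, 0.95))
  expect_equal(nrow(filter_by_probability(ev, 0)), 3L)
  expect_equal(nrow(filter_by_probability(ev, 1)), 0L)
  # idempotent and monotone in p_min
  expect_identical(filter_by_probability(kept, 0.9), kept)
  counts <- vapply(seq(0, 1, 0.1),
                   function(p) nrow(filter_by_probability(ev, p)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clusters sort by size with lexicographic tie-break", {
  mk <- function(n, ch, t0) data.frame(
    peak_time_s = t0 + seq_len(n), peak_sample = 1 + seq_len(n),
    peak_channel = ch, probability = 0.95, peak_amplitude_uV = 50,
    correlation = 0.9, score = 4)
  ev <- rbind(mk(5, "E1", 0), mk(7, "E3", 100), mk(5, "E2", 200))
  class(ev) <- c("detected_events", "data.frame")
  cl <- cluster_by_peak_electrode(ev)
  expect_equal(vapply(cl, function(x) x$label, character(1)),
               c("E3", "E1", "E2"))
  expect_equal(sum(vapply(cl, function(x) x$n, integer(1))), nrow(ev))
  # events within each cluster are time sorted and carry the cluster label
  for (x in cl) {
    expect_equal(x$events$peak_time_s, sort(x$events$peak_time_s))
    expect_true(all(x$events$peak_channel == x$label))
  }
  one <- cluster_by_peak_electrode(mk(4, "E101", 0))
  expect_length(one, 1)
  expect_equal(one[[1]]$n, 4L)
})

test_that("greedy matching is one-to-one and nearest-first", {
  a <- mark_list(c(1.00, 1.05))
  b <- mark_list(1.02)
  m <- match_events(a, b, tol_ms = 30)
  expect_equal(m$n_matched, 1L)
  expect_equal(m$pairs$i, 1L)             # 1.00 s is nearest
  # identical lists fully match
  x <- mark_list(c(1, 5, 9))
  expect_equal(match_events(x, x, 50)$n_matched, 3L)
  # disjoint beyond tolerance
  expect_equal(match_events(mark_list(1), mark_list(2), 100)$n_matched, 0L)
  expect_error(match_events(a, b, tol_ms = -1), "tol_ms")
})

test_that("simulated review keeps matched candidates minus misses", {
  cand <- mark_list(c(1, 5, 9, 13), provenance = "automated")
  truth <- mark_list(c(1.02, 5.01, 20))
  kept <- simulate_review(cand, truth, tol_ms = 100, reviewer_miss_rate = 0,
                          seed = 1)
  expect_equal(kept$time_s, c(1, 5))
  expect_identical(attr(kept, "provenance"), "reviewed")
  none <- simulate_review(cand, truth, 100, reviewer_miss_rate = 1, seed = 1)
  expect_equal(nrow(none), 0L)
  expect_error(simulate_review(cand, truth, 100, 1.5), "miss_rate")
})

test_that("review miss counts follow the binomial law", {
  cand <- mark_list(seq(5, 400, by = 5), provenance = "automated")
  truth <- mark_list(seq(5, 400, by = 5))
  n <- nrow(cand)
  miss <- 0.3
  kept <- vapply(1:200, function(s) {
    nrow(simulate_review(cand, truth, 50, miss, seed = s))
  }, numeric(1))
  mean_kept <- mean(kept)
  expected <- n * (1 - miss)
  se <- sqrt(n * miss * (1 - miss) / 200)
  expect_lt(abs(mean_kept - expected), 1.96 * se * 1.5)
})

test_that("detector output satisfies its contracts on noisy data", {
  fx <- fixture_recording(small_context(), n_events = 6, duration_s = 60,
                          seed = 33)
  det <- detect_events(fx$recording, fx$template, min_separation_ms = 200)
  expect_true(all(det$probability >= 0 & det$probability <= 1))
  expect_true(all(det$peak_sample >= 1 &
                    det$peak_sample <= ncol(fx$recording$data)))
  expect_true(all(diff(sort(det$peak_sample)) >= round(0.2 * 250)))
  expect_true(all(det$peak_channel %in% fx$recording$channel_ids))
})
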
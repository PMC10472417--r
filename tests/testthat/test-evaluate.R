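test_that("distance to mask is zero inside and exact outside", {
  grid <- small_context()$grid
  pos <- grid$positions
  center <- which(pos[, 1] == 0 & pos[, 2] == 0 & pos[, 3] == 0)
  mask <- make_resection_mask(grid, center, 10)
  inside <- mask$members[length(mask$members) %/% 2]
  expect_equal(distance_to_mask(inside, mask, grid), 0)
  # forced geometry: mask = single point at (0,0,0), max at (20,0,0)...
  m0 <- make_resection_mask(grid, center, 0)
  p20 <- which(pos[, 1] == 20 & pos[, 2] == 0 & pos[, 3] == 0)
  expect_equal(distance_to_mask(p20, m0, grid), 20)
  # ...and with the nearest member at (10,0,0) a 5 mm-offset mask edge
  m_edge <- make_resection_mask(grid, center, 10)
  expect_equal(distance_to_mask(p20, m_edge, grid), 10)
  expect_error(distance_to_mask(10^7, mask, grid), "range")
})

test_that("distance to mask equals a brute-force scan on random masks", {
  grid <- small_context()$grid
  set.seed(12)
  for (i in 1:10) {
    mask <- make_resection_mask(grid, sample(grid$n_points, 1),
                                runif(1, 0, 25))
    mx <- sample(grid$n_points, 1)
    brute <- min(sqrt(rowSums(
      sweep(grid$positions[mask$members, , drop = FALSE], 2,
            grid$positions[mx, ])^2)))
    if (mx %in% mask$members) brute <- 0
    expect_equal(distance_to_mask(mx, mask, grid), brute)
  }
})

test_that("distance to mask is translation invariant", {
  grid <- small_context()$grid
  mask <- make_resection_mask(grid, 100, 15)
  d0 <- distance_to_mask(1500, mask, grid)
  shifted <- grid
  shifted$positions <- sweep(grid$positions, 2, c(-7, 3, 11))
  expect_equal(distance_to_mask(1500, mask, shifted), d0)
})

test_that("sublobe atlas labels every point with n regions per hemisphere", {
  grid <- small_context()$grid
  atlas <- build_sublobe_atlas(grid, 19, seed = 1)
  expect_length(atlas$labels, grid$n_points)
  expect_true(all(atlas$labels >= 1))
  left <- atlas$hemisphere == "L"
  expect_equal(length(unique(atlas$labels[left])), 19L)
  expect_equal(length(unique(atlas$labels[!left])), 19L)
  expect_length(unique(atlas$labels), 38L)
  expect_true(all(grid$positions[atlas$hemisphere == "R", 1] >= 0))
  # determinism
  atlas2 <- build_sublobe_atlas(grid, 19, seed = 1)
  expect_identical(atlas$labels, atlas2$labels)
  # n = 1 reduces to hemisphere membership
  a1 <- build_sublobe_atlas(grid, 1, seed = 1)
  expect_length(unique(a1$labels), 2L)
  expect_error(build_sublobe_atlas(grid, 10^6, seed = 1), "exceeds")
})

test_that("concordance flags follow mask label membership", {
  grid <- small_context()$grid
  atlas <- build_sublobe_atlas(grid, 19, seed = 1)
  center <- fixture_source(small_context())
  mask <- make_resection_mask(grid, center, 12)
  inside <- sublobar_concordance(center, atlas, mask)
  expect_true(inside$concordant_sublobe)
  expect_true(inside$concordant_hemisphere)
  # mirrored across x = 0: the hemisphere flag must drop
  mpos <- grid$positions[center, ] * c(-1, 1, 1)
  mirror <- which.min(rowSums(sweep(grid$positions, 2, mpos)^2))
  if (sign(grid$positions[mirror, 1]) != sign(grid$positions[center, 1])) {
    out <- sublobar_concordance(mirror, atlas, mask)
    expect_false(out$concordant_hemisphere)
  }
  # brute-force membership on random cases
  set.seed(3)
  for (i in 1:10) {
    mx <- sample(grid$n_points, 1)
    got <- sublobar_concordance(mx, atlas, mask)
    expect_identical(got$concordant_sublobe,
                     atlas$labels[mx] %in% atlas$labels[mask$members])
  }
})

test_that("concordance is invariant to atlas label permutation", {
  grid <- small_context()$grid
  atlas <- build_sublobe_atlas(grid, 5, seed = 2)
  mask <- make_resection_mask(grid, 50, 20)
  perm <- sample(38)
  shuffled <- atlas
  shuffled$labels <- perm[atlas$labels]
  set.seed(4)
  for (mx in sample(grid$n_points, 10)) {
    expect_identical(sublobar_concordance(mx, atlas, mask)$concordant_sublobe,
                     sublobar_concordance(mx, shuffled, mask)$concordant_sublobe)
  }
})

test_that("subsampling with N = N_total reproduces the full maximum", {
  ctx <- small_context()
  fx <- fixture_recording(ctx, n_events = 8, duration_s = 60, seed = 50)
  eps <- extract_epochs(fx$recording, marks_from_truth(fx$recording), 2)
  op <- compute_wmne_operator(ctx$leadfield, NULL, snr = 3)
  mask <- make_resection_mask(ctx$grid, fx$source, 15)
  curve <- subsample_experiment(eps, op, ctx$grid, mask, Ns = c(4L, 8L),
                                n_reps = 3, seed = 9)
  expect_equal(curve$curve$mean_dist_full_mm[curve$curve$N == 8], 0)
  expect_equal(curve$N_total, 8L)
  # determinism
  curve2 <- subsample_experiment(eps, op, ctx$grid, mask, Ns = c(4L, 8L),
                                 n_reps = 3, seed = 9)
  expect_identical(curve$curve, curve2$curve)
  expect_identical(curve$draws, curve2$draws)
  # validation
  expect_error(subsample_experiment(eps, op, ctx$grid, mask, c(4L, 20L),
                                    3, 9), "epochs")
  expect_error(subsample_experiment(eps, op, ctx$grid, mask, integer(0),
                                    3, 9), "non-empty")
  expect_error(subsample_experiment(eps, op, ctx$grid, mask, c(8L, 4L),
                                    3, 9), "increasing")
})

test_that("smallest stable N below threshold follows its definition", {
  mk <- function(N, d) structure(
    list(curve = data.frame(N = N, mean_dist_full_mm = d)),
    class = "subsampling_curve")
  expect_equal(smallest_N_below(mk(c(5, 20, 35, 50), c(22, 14, 8, 6))), 35L)
  expect_equal(smallest_N_below(mk(c(5, 20), c(2, 3))), 5L)
  expect_true(is.na(smallest_N_below(mk(c(5, 20), c(30, 12)))))
  # non-monotone dip: an early crossing that later rises does not count
  expect_equal(smallest_N_below(mk(c(5, 10, 20, 40), c(8, 15, 9, 7))), 20L)
  expect_error(smallest_N_below(mk(5, 3), threshold_mm = 0), "threshold")
})
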
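test_that("equal-conductivity lead field matches the homogeneous closed form", {
  head <- three_shell_head(conductivities_S_per_m = c(0.33, 0.33, 0.33))
  arr <- build_electrode_array(32, 140)
  set.seed(101)
  n <- 25
  dirs <- matrix(rnorm(3 * n), n)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  src <- dirs * runif(n, 0, 0.9 * 80)
  grid <- structure(
    list(positions = src, spacing_mm = 5, margin_mm = 2,
         brain_radius_mm = 80, n_points = n), class = "source_grid")
  lf <- compute_leadfield(head, arr, grid, n_terms = 80)
  for (s in seq_len(n)) {
    p <- rnorm(3); p <- p / sqrt(sum(p^2))
    got <- drop(leadfield_block(lf, s) %*% p)
    want <- vapply(seq_len(32), function(e) {
      oracle_dipole_uV_per_nAm(arr$positions[e, ], src[s, ], p, 92, 0.33)
    }, numeric(1))
    want <- want - mean(want)
    expect_lt(max(abs(got - want)) / max(abs(want)), 0.01)
  }
})

test_that("lead field columns are average referenced with positive norms", {
  lf <- small_context()$leadfield
  expect_lt(max(abs(colSums(lf$gain))), 1e-9 * max(abs(lf$gain)))
  expect_true(all(colSums(lf$gain^2) > 0))
  expect_true(all(is.finite(lf$gain)))
})

test_that("z dipole at the origin produces an axially symmetric pattern", {
  # montage of three rings at fixed polar angles (8 azimuths each)
  polar <- rep(c(30, 60, 90) * pi / 180, each = 8)
  azim <- rep(2 * pi * (0:7) / 8, 3)
  pos <- 92 * cbind(sin(polar) * cos(azim), sin(polar) * sin(azim),
                    cos(polar))
  ids <- sprintf("R%02d", seq_len(24))
  rownames(pos) <- ids
  arr <- structure(
    list(channel_ids = ids, positions = pos,
         fiducials = build_electrode_array(8, 140)$fiducials,
         scalp_radius_mm = 92, center = c(0, 0, 0)),
    class = "electrode_array")
  grid <- structure(
    list(positions = matrix(0, 1, 3), spacing_mm = 5, margin_mm = 2,
         brain_radius_mm = 80, n_points = 1), class = "source_grid")
  lf <- compute_leadfield(three_shell_head(), arr, grid)
  v <- leadfield_block(lf, 1)[, 3]
  for (ring in split(seq_len(24), rep(1:3, each = 8))) {
    expect_lt(diff(range(v[ring])), 1e-8 * max(abs(v)))
  }
})

test_that("mirroring a dipole across the x-z plane mirrors the potentials", {
  head <- three_shell_head()
  arr <- build_electrode_array(64, 140)
  # mirror-symmetric electrode pair set: use electrodes plus their mirrors
  pos <- arr$positions
  mirrored <- pos
  mirrored[, 2] <- -mirrored[, 2]
  both <- rbind(pos, mirrored)
  ids <- c(arr$channel_ids, paste0(arr$channel_ids, "m"))
  arr2 <- structure(
    list(channel_ids = ids, positions = both, fiducials = arr$fiducials,
         scalp_radius_mm = 92, center = c(0, 0, 0)),
    class = "electrode_array")
  src <- rbind(c(20, 25, 30), c(20, -25, 30))
  grid <- structure(
    list(positions = src, spacing_mm = 5, margin_mm = 2,
         brain_radius_mm = 80, n_points = 2), class = "source_grid")
  lf <- compute_leadfield(head, arr2, grid)
  # dipole (px, py, pz) at y -> (px, -py, pz) at -y seen by mirrored sensors
  p <- c(0.5, 0.7, -0.3)
  pm <- c(0.5, -0.7, -0.3)
  v1 <- drop(leadfield_block(lf, 1) %*% p)
  v2 <- drop(leadfield_block(lf, 2) %*% pm)
  v2_mirrored <- c(v2[65:128], v2[1:64])
  expect_lt(max(abs(v1 - v2_mirrored)), 1e-8 * sqrt(sum(v1^2)))
})

test_that("skull conductivity attenuates scalp potentials", {
  arr <- build_electrode_array(32, 140)
  src <- matrix(c(30, 10, 25), 1)
  grid <- structure(
    list(positions = src, spacing_mm = 5, margin_mm = 2,
         brain_radius_mm = 80, n_points = 1), class = "source_grid")
  lf_skull <- compute_leadfield(three_shell_head(), arr, grid)
  lf_homog <- compute_leadfield(
    three_shell_head(conductivities_S_per_m = c(0.33, 0.33, 0.33)), arr, grid)
  p <- c(0, 0, 1)
  expect_lt(sqrt(sum((leadfield_block(lf_skull, 1) %*% p)^2)),
            sqrt(sum((leadfield_block(lf_homog, 1) %*% p)^2)))
})

test_that("series is converged by n_terms = 40 for sources within 0.8 R", {
  head <- three_shell_head()
  arr <- build_electrode_array(32, 140)
  set.seed(7)
  dirs <- matrix(rnorm(15), 5)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  src <- dirs * runif(5, 0, 0.8 * 80)
  grid <- structure(
    list(positions = src, spacing_mm = 5, margin_mm = 2,
         brain_radius_mm = 80, n_points = 5), class = "source_grid")
  g40 <- compute_leadfield(head, arr, grid, n_terms = 40)$gain
  g80 <- compute_leadfield(head, arr, grid, n_terms = 80)$gain
  expect_lt(max(abs(g40 - g80)) / max(abs(g80)), 1e-3)
})

test_that("lead field rejects out-of-domain sources and bad montages", {
  head <- three_shell_head()
  arr <- build_electrode_array(16, 140)
  bad <- structure(
    list(positions = matrix(c(79, 0, 0), 1), spacing_mm = 5, margin_mm = 2,
         brain_radius_mm = 80, n_points = 1), class = "source_grid")
  expect_error(compute_leadfield(head, arr, bad), "inside the brain")
  off <- arr
  off$positions <- off$positions * 1.1
  grid <- tiny_context()$grid
  expect_error(compute_leadfield(head, off, grid), "scalp sphere")
  expect_error(compute_leadfield(head, arr, grid, n_terms = 10), "n_terms")
})

test_that("lead field container round trips with metadata checks", {
  ctx <- tiny_context()
  path <- withr::local_tempfile(fileext = ".rds")
  save_leadfield(ctx$leadfield, path)
  back <- load_leadfield(path)
  expect_identical(back$gain, ctx$leadfield$gain)
  expect_identical(back$units, "uV/nAm")
  expect_identical(back$reference, "average")
  saveRDS(list(format = "other"), path)
  expect_error(load_leadfield(path), "container")
})
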
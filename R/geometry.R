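#' Electrode montages, head models and source grids
#'
#' Geometry primitives for the spherical forward model: a quasi-uniform
#' scalp electrode array, the three-shell concentric-sphere head model, and
#' the regular volumetric source grid used as the source space.
#'
#' Coordinate frame: RAS millimetres (x right, y anterior, z superior),
#' origin at the common sphere centre.
#'
#' @name hdesi-geometry
NULL

GOLDEN_ANGLE <- pi * (3 - sqrt(5))

#' Build a quasi-uniform scalp electrode array
#'
#' Places `n_channels` electrodes on the scalp sphere with a spherical
#' Fibonacci lattice restricted to a polar cap, emulating the coverage of a
#' geodesic sensor net. Fiducials (nasion, left/right preauricular) are
#' placed on the sphere equator.
#'
#' @param n_channels Number of electrodes (>= 8). Default 256.
#' @param coverage_polar_deg Polar angle of the cap in degrees, measured
#'   from the vertex (0 < angle <= 160). Default 140.
#' @param scalp_radius_mm Scalp sphere radius in mm. Default 92.
#' @return An object of class `electrode_array` with fields `channel_ids`,
#'   `positions` (n x 3, mm), `fiducials` (3 x 3, rows nasion/lpa/rpa),
#'   `scalp_radius_mm` and `center` (sphere centre, mm).
#' @export
build_electrode_array <- function(n_channels = 256, coverage_polar_deg = 140,
                                  scalp_radius_mm = 92) {
  if (!is.numeric(n_channels) || length(n_channels) != 1 || n_channels < 8) {
    stop("n_channels must be a single number >= 8", call. = FALSE)
  }
  if (!is.numeric(coverage_polar_deg) || coverage_polar_deg <= 0 ||
      coverage_polar_deg > 160) {
    stop("coverage_polar_deg must be in (0, 160]", call. = FALSE)
  }
  n <- as.integer(n_channels)
  R <- scalp_radius_mm
  # Fibonacci lattice on the cap: z uniform in [cos(theta_max), 1]
  z_min <- cos(coverage_polar_deg * pi / 180)
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - z_min) * i / n
  phi <- GOLDEN_ANGLE * (seq_len(n) - 1)
  s <- sqrt(pmax(0, 1 - z^2))
  pos <- R * cbind(s * cos(phi), s * sin(phi), z)
  ids <- sprintf("E%03d", seq_len(n))
  rownames(pos) <- ids
  colnames(pos) <- c("x", "y", "z")
  fid <- rbind(nasion = c(0, R, 0), lpa = c(-R, 0, 0), rpa = c(R, 0, 0))
  colnames(fid) <- c("x", "y", "z")
  structure(
    list(channel_ids = ids, positions = pos, fiducials = fid,
         scalp_radius_mm = R, center = c(0, 0, 0)),
    class = "electrode_array"
  )
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array> %d channels on scalp sphere r = %g mm\n",
              length(x$channel_ids), x$scalp_radius_mm))
  invisible(x)
}

#' Rigidly align an electrode array to target fiducials
#'
#' Finds the least-squares rigid transform (rotation + translation, no
#' scaling) mapping the array's stored fiducials onto the given targets and
#' applies it to all electrode positions and fiducials. This mirrors
#' sensor-model alignment to anatomical landmarks.
#'
#' @param array An `electrode_array`.
#' @param nasion,lpa,rpa Target fiducial positions, 3-vectors in mm.
#' @return The transformed `electrode_array`; the applied transform is
#'   attached as attributes `rotation` (3 x 3) and `translation`.
#' @export
align_to_fiducials <- function(array, nasion, lpa, rpa) {
  stopifnot(inherits(array, "electrode_array"))
  tgt <- rbind(nasion, lpa, rpa)
  if (any(!is.finite(tgt)) || ncol(tgt) != 3) {
    stop("fiducial targets must be finite 3-vectors", call. = FALSE)
  }
  check_noncollinear <- function(p) {
    v1 <- p[2, ] - p[1, ]
    v2 <- p[3, ] - p[1, ]
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    sqrt(sum(cr^2)) > 1e-6 * max(1, sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  }
  src <- array$fiducials
  if (!check_noncollinear(tgt) || !check_noncollinear(src)) {
    stop("fiducials are collinear: rigid alignment is degenerate",
         call. = FALSE)
  }
  fit <- kabsch_rigid(src, tgt)
  transform <- function(p) sweep(p %*% t(fit$R), 2, -fit$t)
  out <- array
  out$positions <- transform(array$positions)
  rownames(out$positions) <- array$channel_ids
  out$fiducials <- transform(array$fiducials)
  rownames(out$fiducials) <- rownames(array$fiducials)
  out$center <- drop(fit$R %*% array$center + fit$t)
  attr(out, "rotation") <- fit$R
  attr(out, "translation") <- fit$t
  out
}

# Least-squares rigid fit (Kabsch): returns R, t with tgt ~ src %*% t(R) + t
kabsch_rigid <- function(src, tgt) {
  cs <- colMeans(src)
  ct <- colMeans(tgt)
  H <- t(sweep(src, 2, cs)) %*% sweep(tgt, 2, ct)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- ct - drop(R %*% cs)
  list(R = R, t = t)
}

#' Three-shell spherical head model
#'
#' Concentric spheres for brain, skull and scalp with piecewise-constant
#' conductivities. Defaults follow the standard adult values used in
#' EEG source imaging (brain 0.33, skull 0.004, scalp 0.33 S/m).
#'
#' @param radii_mm Radii (brain, skull, scalp) in mm, strictly increasing.
#' @param conductivities_S_per_m Conductivities (brain, skull, scalp) in S/m.
#' @return Object of class `three_shell_head`.
#' @export
three_shell_head <- function(radii_mm = c(80, 85, 92),
                             conductivities_S_per_m = c(0.33, 0.004, 0.33)) {
  r <- as.numeric(radii_mm)
  s <- as.numeric(conductivities_S_per_m)
  if (length(r) != 3 || any(!is.finite(r)) || any(r <= 0) || any(diff(r) <= 0)) {
    stop("radii_mm must be three positive, strictly increasing values",
         call. = FALSE)
  }
  if (length(s) != 3 || any(!is.finite(s)) || any(s <= 0)) {
    stop("conductivities must be three positive values", call. = FALSE)
  }
  names(r) <- names(s) <- c("brain", "skull", "scalp")
  structure(list(radii_mm = r, conductivities_S_per_m = s),
            class = "three_shell_head")
}

#' @export
print.three_shell_head <- function(x, ...) {
  cat(sprintf(
    "<three_shell_head> radii %s mm; sigma %s S/m\n",
    paste(x$radii_mm, collapse = "/"),
    paste(x$conductivities_S_per_m, collapse = "/")))
  invisible(x)
}

#' Build a regular volumetric source grid
#'
#' Axis-aligned lattice centred on the sphere origin, restricted to points
#' strictly inside the brain shell minus a safety margin (sources too close
#' to the inner shell make the spherical-harmonic series diverge).
#'
#' @param head A `three_shell_head`.
#' @param spacing_mm Lattice spacing in mm (> 0). Default 5.
#' @param margin_mm Keep-out margin from the brain shell, mm. Default 2.
#' @return Object of class `source_grid` with `positions` (n x 3, mm),
#'   `spacing_mm` and `n_points`. Row order is row-major over (x, y, z):
#'   z varies fastest, then y, then x. Grid indices are 1-based.
#' @export
build_source_grid <- function(head, spacing_mm = 5, margin_mm = 2) {
  stopifnot(inherits(head, "three_shell_head"))
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 || spacing_mm <= 0) {
    stop("spacing_mm must be a single positive number", call. = FALSE)
  }
  rmax <- head$radii_mm[["brain"]] - margin_mm
  k <- floor(rmax / spacing_mm)
  ax <- spacing_mm * seq(-k, k)
  pts <- as.matrix(expand.grid(z = ax, y = ax, x = ax,
                               KEEP.OUT.ATTRS = FALSE))[, c("x", "y", "z"),
                                                        drop = FALSE]
  keep <- rowSums(pts^2) <= rmax^2
  pos <- pts[keep, , drop = FALSE]
  rownames(pos) <- NULL
  structure(
    list(positions = pos, spacing_mm = spacing_mm, margin_mm = margin_mm,
         brain_radius_mm = head$radii_mm[["brain"]], n_points = nrow(pos)),
    class = "source_grid"
  )
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d points, %g mm spacing, |r| <= %g mm\n",
              x$n_points, x$spacing_mm, x$brain_radius_mm - x$margin_mm))
  invisible(x)
}
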
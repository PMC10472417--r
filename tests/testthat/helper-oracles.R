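# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: the forward oracle is the closed-form
# insulated-sphere monopole surface potential differentiated by a finite
# two-monopole dipole, and the inverse oracle is a dense solve of the
# regularized normal equations.

# surface potential (V) of a unit point current source at r0 (m) inside an
# insulated homogeneous sphere of radius R (m), conductivity sigma (S/m),
# electrode at re on the surface; closed-form summation of the Legendre
# series
oracle_monopole_surface <- function(re, r0, R, sigma) {
  b <- sqrt(sum(r0^2))
  x <- b / R
  cth <- if (b > 0) sum(r0 * re) / (b * R) else 1
  g <- sqrt(1 - 2 * x * cth + x^2)
  (1 / (4 * pi * sigma * R)) * (2 / g - 2 + log(2 / (1 - x * cth + g)))
}

# dipole surface potential in uV per nAm by a finite monopole pair
# (separation h mm), positions in mm
oracle_dipole_uV_per_nAm <- function(re_mm, r0_mm, p_unit, R_mm, sigma,
                                     h_mm = 0.01) {
  f <- function(r0) {
    oracle_monopole_surface(re_mm * 1e-3, r0 * 1e-3, R_mm * 1e-3, sigma)
  }
  v_per_Am <- (f(r0_mm + h_mm / 2 * p_unit) -
                 f(r0_mm - h_mm / 2 * p_unit)) / (h_mm * 1e-3)
  v_per_Am * 1e-9 * 1e6
}

# dense wMNE oracle: minimize ||d - L j||^2_{C^-1} + lambda2 ||W^-1/2 j||^2
# via the (3n x 3n) normal equations, independent of the kernel identity
# used by the implementation
oracle_wmne_dense <- function(L, C, lambda2, w_block) {
  W <- diag(rep(w_block, each = 3))
  Ci <- solve(C)
  solve(t(L) %*% Ci %*% L + lambda2 * solve(W), t(L) %*% Ci)
}

# brute-force half-rise scan following the stated definition
oracle_half_rise <- function(x, center, rate, baseline_window = c(-1.5, -0.5),
                             peak) {
  bidx <- center + round(baseline_window[1] * rate):
    round(baseline_window[2] * rate)
  base <- mean(x[bidx])
  s <- sign(x[peak] - base)
  y <- s * (x - base)
  onset <- max(which(y[seq_len(peak - 1)] <= 0))
  for (i in onset:(peak - 1)) {
    if (y[i] >= 0.5 * y[peak]) return(i)
  }
  NA_integer_
}
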
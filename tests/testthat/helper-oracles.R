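# Independent oracles and shared fixtures.

# The characterized gray/white/translucent PLA coefficients used as known
# inputs throughout the suite.
ref_model <- function() pla_gwt_model()

REF_MUA_COEF <- c(A = 0.0078, B = 0.00095, C = 0.0056)
REF_MUSP_COEF <- c(A = 0.036, B = 0.034, C = 0.35)

# Independent ordinary-least-squares plane fit via the normal equations
# (oracle for the lm-backed fit).
ols_plane <- function(Rg, Rw, y) {
  X <- cbind(1, Rg, Rw)
  as.numeric(solve(t(X) %*% X, t(X) %*% y)) # (C, A, B)
}

# Steady-state dipole (extrapolated boundary) diffusion solution for the
# radially resolved diffuse reflectance of a point source on a semi-infinite
# medium; oracle for the Monte Carlo radial profile.
farrell_rd_radial <- function(rho, mua, musp, n = 1.4) {
  mutr <- mua + musp
  D <- 1 / (3 * mutr)
  z0 <- 1 / mutr
  mueff <- sqrt(3 * mua * mutr)
  Reff <- effective_reflection(n)
  zb <- 2 * D * (1 + Reff) / (1 - Reff)
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
     (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
}

# Region label -> target optical properties for the default QA phantom.
qa_region_props <- function(design = design_qa_phantom()) {
  props <- lapply(design$regions, function(r) r$target)
  props[!vapply(props, is.null, logical(1))]
}
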
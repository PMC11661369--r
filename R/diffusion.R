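# Closed-form diffusion-approximation reflectance for a semi-infinite medium
# under spatially modulated illumination; the independent oracle against which
# the Monte Carlo lookup table is checked.

#' Effective internal reflection coefficient from the refractive index
#'
#' Empirical polynomial (Groenhuis / Egan-Hilgeman form) for the effective
#' Fresnel reflection coefficient of diffuse light at an index-mismatched
#' boundary.
#'
#' @param n Relative refractive index (medium / outside).
#' @return \code{Reff}, dimensionless.
#' @export
effective_reflection <- function(n) {
  0.0636 * n + 0.668 + 0.710 / n - 1.440 / n^2
}

#' Diffusion-approximation diffuse reflectance at a spatial frequency
#'
#' Standard semi-infinite diffusion solution for sinusoidally modulated
#' illumination: with \code{mutr = mua + musp},
#' \code{mueff' = sqrt(3 mua mutr + (2 pi fx)^2)} and the proportionality
#' constant \code{A = (1 - Reff) / (2 (1 + Reff))},
#' \deqn{Rd(fx) = \frac{3 A a'}{(\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)}}
#' where \code{a' = musp/mutr} is the reduced albedo.  Valid in the diffusive
#' regime; a warning is issued when \code{musp/mua < 10}.
#'
#' @param mua Absorption coefficient, 1/mm.
#' @param musp Reduced scattering coefficient, 1/mm.
#' @param fx Spatial frequency, 1/mm.
#' @param n Refractive index of the medium (default 1.4).
#' @return Diffuse reflectance, dimensionless.  Vectorized over all arguments.
#' @export
diffusion_rd <- function(mua, musp, fx = 0, n = 1.4) {
  if (any(musp / mua < 10))
    warning("diffusion approximation is unreliable for musp/mua < 10")
  Reff <- effective_reflection(n)
  A <- (1 - Reff) / (2 * (1 + Reff))
  mutr <- mua + musp
  ap <- musp / mutr
  mueff <- sqrt(3 * mua * mutr + (2 * pi * fx)^2)
  x <- mueff / mutr
  3 * A * ap / ((x + 1) * (x + 3 * A))
}
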
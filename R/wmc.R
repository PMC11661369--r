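# White Monte Carlo photon transport in a semi-infinite turbid half-space and
# the spatial-frequency diffuse-reflectance machinery built on top of it.
#
# One baseline simulation is run at a reference scattering coefficient with no
# absorption; absorption is applied after the fact by weighting each detected
# photon by exp(-mua * L), and other reduced scattering values are reached by
# similarity rescaling of lengths.  This makes a whole (mua, musp) lookup
# table the product of a single simulation.

#' Semi-infinite medium description for the White Monte Carlo run
#'
#' @param n Refractive index of the medium (outside is 1.0). Default 1.4,
#'   typical for soft tissue and PLA-based phantoms.
#' @param g Henyey-Greenstein scattering anisotropy, in (-1, 1). Default 0.9.
#' @param mus_ref Scattering coefficient of the baseline run, 1/mm. The run's
#'   reduced scattering is \code{mus_ref * (1 - g)}.
#' @return A \code{medium_model} object.
#' @export
medium_model <- function(n = 1.4, g = 0.9, mus_ref = 10) {
  stopifnot_scalar_number(n, "n")
  stopifnot_scalar_number(g, "g")
  stopifnot_scalar_number(mus_ref, "mus_ref", positive = TRUE)
  if (n < 1) pf_usage_error("refractive index must be >= 1")
  if (g <= -1 || g >= 1) pf_usage_error("anisotropy g must be in (-1, 1)")
  structure(list(n = n, g = g, mus_ref = mus_ref, musp_ref = mus_ref * (1 - g)),
            class = "medium_model")
}

#' Run a White Monte Carlo simulation
#'
#' Pencil beam at normal incidence on a semi-infinite half-space.  Steps are
#' exponential at \code{mus_ref}, scattering is Henyey-Greenstein, the planar
#' boundary applies Fresnel reflection/transmission for the index mismatch
#' (specular reflection at launch is handled by weight deduction,
#' \code{((n-1)/(n+1))^2} exactly).  No absorption is applied during
#' transport.  Deterministic given \code{(seed, n_photons, medium)} and
#' independent of R's RNG state.
#'
#' @param medium A \code{\link{medium_model}}.
#' @param n_photons Number of photons to launch.
#' @param seed Integer seed for the internal generator.
#' @param max_path_mfp Termination cap on the total pathlength, in transport
#'   mean free paths \code{1/(mus_ref*(1-g))}.  Photons exceeding it are
#'   discarded; at the default 2e4 the discarded diffuse weight is below 1%
#'   even with zero absorption.
#' @param record_first_depth Also record the depth of each photon's first
#'   scattering event (used for sampling-law diagnostics).
#' @param iso_after After this many Henyey-Greenstein scattering events the
#'   photon's direction is fully decorrelated (correlation \code{g^n}); the
#'   walk then continues isotropically at the reduced rate
#'   \code{mus_ref*(1-g)}, which preserves the diffusion constant and
#'   pathlength statistics while cutting step count by \code{1/(1-g)}.
#'   Set \code{Inf} for a pure Henyey-Greenstein run.
#' @return A \code{wmc_run} object: vectors \code{r} (exit radius, mm),
#'   \code{L} (pathlength, mm), \code{w} (residual weight), plus
#'   \code{n_photons}, \code{seed}, \code{specular}, \code{medium}.
#' @export
simulate_white_mc <- function(medium = medium_model(), n_photons = 1e6,
                              seed = 1L, max_path_mfp = 2e4,
                              record_first_depth = FALSE, iso_after = 50) {
  stopifnot_scalar_number(n_photons, "n_photons", positive = TRUE)
  if (n_photons < 1) pf_usage_error("n_photons must be >= 1")
  max_path <- max_path_mfp / medium$musp_ref
  res <- wmc_simulate_cpp(medium$n, medium$g, medium$mus_ref,
                          as.double(n_photons), as.double(seed),
                          max_path, isTRUE(record_first_depth),
                          as.double(iso_after))
  structure(list(r = res$r, L = res$L, w = res$w,
                 first_depth = res$first_depth,
                 n_photons = as.integer(n_photons), seed = as.integer(seed),
                 specular = res$specular, max_path_mm = max_path,
                 medium = medium),
            class = "wmc_run")
}

#' @export
print.wmc_run <- function(x, ...) {
  cat(sprintf("<wmc_run> %d photons (seed %d), n = %g, g = %g, mus_ref = %g/mm\n",
              x$n_photons, x$seed, x$medium$n, x$medium$g, x$medium$mus_ref))
  cat(sprintf("  detected: %d (diffuse weight fraction %.4f, specular %.4f)\n",
              length(x$r), sum(x$w) / x$n_photons, x$specular))
  invisible(x)
}

similarity_scale <- function(run, musp) {
  # lengths scale by mus_ref / mus_target; with fixed g this equals
  # musp_ref / musp_target
  run$medium$musp_ref / musp
}

#' Radially resolved diffuse reflectance from a White MC run
#'
#' Rescales the baseline run to a target \code{(mua, musp)} by similarity
#' (lengths multiplied by \code{mus_ref/mus_target}), applies absorption as
#' \code{w * exp(-mua * L)}, and bins detected weight into radial annuli
#' normalized per launched photon and unit area.
#'
#' @param run A \code{\link{simulate_white_mc}} result.
#' @param mua Target absorption coefficient, 1/mm (>= 0).
#' @param musp Target reduced scattering coefficient, 1/mm (> 0).
#' @param breaks Uniform radial bin edges in mm (default 0-50 mm, 0.1 mm).
#' @return List: \code{breaks}, \code{mids}, \code{rd} (reflectance per unit
#'   area, 1/mm^2, per bin), \code{overflow} (weight fraction beyond the last
#'   edge), \code{total_detected} (all detected weight / launched, absorption
#'   applied, overflow included).
#' @export
radial_reflectance <- function(run, mua, musp, breaks = seq(0, 50, by = 0.1)) {
  if (!inherits(run, "wmc_run")) pf_usage_error("`run` must be a wmc_run")
  if (length(run$r) == 0) pf_error("empty run: no detected photons", "pf_usage_error")
  stopifnot_scalar_number(mua, "mua")
  stopifnot_scalar_number(musp, "musp", positive = TRUE)
  if (mua < 0) pf_usage_error("mua must be >= 0")
  k <- similarity_scale(run, musp)
  acc <- wmc_bin_cpp(run$r, run$L, run$w, k, mua, breaks)
  nb <- length(breaks)
  counts <- acc[seq_len(nb - 1)]
  overflow <- acc[nb]
  areas <- pi * (breaks[-1]^2 - breaks[-nb]^2)
  list(breaks = breaks, mids = (breaks[-1] + breaks[-nb]) / 2,
       rd = counts / (run$n_photons * areas),
       overflow = overflow / run$n_photons,
       total_detected = (sum(counts) + overflow) / run$n_photons)
}

#' Project radial reflectance into the spatial-frequency domain
#'
#' Order-zero Hankel transform by discrete quadrature over the radial bins:
#' \code{Rd(fx) = 2 pi sum Rd(rho) J0(2 pi fx rho) rho d rho}.  At
#' \code{fx = 0} this reduces to the plain radial integral (total binned
#' diffuse reflectance).  The overflow bin is excluded.
#'
#' @param rd_radial Result of \code{\link{radial_reflectance}}.
#' @param fx Spatial frequency (1/mm); may be a vector.
#' @return \code{Rd(fx)}, dimensionless, one value per frequency.
#' @export
hankel_transform <- function(rd_radial, fx) {
  mids <- rd_radial$mids
  drho <- diff(rd_radial$breaks)
  vapply(fx, function(f) {
    2 * pi * sum(rd_radial$rd * besselJ(2 * pi * f * mids, 0) * mids * drho)
  }, numeric(1))
}
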
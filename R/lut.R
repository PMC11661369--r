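# Reflectance lookup table over (mua, musp, fx), built from one White MC run.

#' Default LUT grids covering the printable filament range
#'
#' Absorption 0.001-0.8 1/mm (60 log-spaced values), reduced scattering
#' 0.2-4.5 1/mm (50 linear values), spatial frequencies 0 and 0.1 1/mm.
#'
#' @return List with \code{mua}, \code{musp}, \code{fx}.
#' @export
default_lut_grids <- function() {
  list(mua = exp(seq(log(0.001), log(0.8), length.out = 60)),
       musp = seq(0.2, 4.5, length.out = 50),
       fx = c(0, 0.1))
}

#' Build a diffuse-reflectance lookup table from a White MC run
#'
#' For every \code{(mua, musp)} grid node the baseline run is similarity
#' rescaled, absorption-weighted, radially binned and Hankel projected onto
#' each requested spatial frequency (see \code{\link{radial_reflectance}} and
#' \code{\link{hankel_transform}}).
#'
#' @param run A \code{\link{simulate_white_mc}} result (or \code{NULL} to run
#'   one internally with \code{n_photons} and \code{seed}).
#' @param mua_grid,musp_grid Strictly increasing positive grids, 1/mm.
#' @param fx_list Spatial frequencies, 1/mm (default \code{c(0, 0.1)}).
#' @param breaks Radial bin edges passed to \code{\link{radial_reflectance}}.
#' @param n_photons,seed Used only when \code{run} is \code{NULL}.
#' @param medium Used only when \code{run} is \code{NULL}.
#' @return A \code{reflectance_lut}: \code{mua_grid}, \code{musp_grid},
#'   \code{fx}, \code{rd} (array \code{[mua, musp, fx]}), and provenance
#'   metadata (seed, photon count, medium).
#' @export
build_lut <- function(run = NULL, mua_grid = default_lut_grids()$mua,
                      musp_grid = default_lut_grids()$musp,
                      fx_list = c(0, 0.1), breaks = seq(0, 50, by = 0.1),
                      n_photons = 1e6, seed = 1L, medium = medium_model()) {
  if (any(mua_grid <= 0) || any(musp_grid <= 0))
    pf_usage_error("LUT grid values must be > 0")
  if (is.unsorted(mua_grid, strictly = TRUE) || is.unsorted(musp_grid, strictly = TRUE))
    pf_usage_error("LUT grids must be strictly increasing")
  if (is.null(run)) run <- simulate_white_mc(medium, n_photons, seed)
  nm <- length(mua_grid); ns <- length(musp_grid); nf <- length(fx_list)
  rd <- array(NA_real_, dim = c(nm, ns, nf))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  drho <- diff(breaks)
  # J0 quadrature weights per frequency, shared across nodes
  Jw <- sapply(fx_list, function(f) 2 * pi * besselJ(2 * pi * f * mids, 0) * mids * drho)
  areas <- pi * (breaks[-1]^2 - breaks[-length(breaks)]^2)
  for (j in seq_len(ns)) {
    k <- similarity_scale(run, musp_grid[j])
    for (i in seq_len(nm)) {
      acc <- wmc_bin_cpp(run$r, run$L, run$w, k, mua_grid[i], breaks)
      dens <- acc[seq_along(mids)] / (run$n_photons * areas)
      rd[i, j, ] <- as.numeric(crossprod(Jw, dens))
    }
  }
  structure(list(mua_grid = mua_grid, musp_grid = musp_grid, fx = fx_list,
                 rd = rd,
                 meta = list(seed = run$seed, n_photons = run$n_photons,
                             n = run$medium$n, g = run$medium$g,
                             mus_ref = run$medium$mus_ref,
                             max_path_mm = run$max_path_mm,
                             radial_breaks = range(breaks),
                             radial_bin = breaks[2] - breaks[1])),
            class = "reflectance_lut")
}

#' @export
print.reflectance_lut <- function(x, ...) {
  cat(sprintf("<reflectance_lut> %d x %d nodes, fx = {%s} /mm\n",
              length(x$mua_grid), length(x$musp_grid),
              paste(x$fx, collapse = ", ")))
  cat(sprintf("  mua %g-%g /mm, musp %g-%g /mm; %g photons (seed %d), n = %g, g = %g\n",
              min(x$mua_grid), max(x$mua_grid), min(x$musp_grid), max(x$musp_grid),
              x$meta$n_photons, x$meta$seed, x$meta$n, x$meta$g))
  invisible(x)
}

lut_fx_index <- function(lut, fx) {
  i <- which(abs(lut$fx - fx) < 1e-9)
  if (length(i) != 1L)
    pf_usage_error(sprintf("LUT has no entry for fx = %g /mm", fx))
  i
}

#' Interpolate the LUT forward model at arbitrary (mua, musp)
#'
#' Bilinear interpolation of \code{Rd} at one spatial frequency; values must
#' lie within the grid bounds.
#'
#' @param lut A \code{reflectance_lut}.
#' @param mua,musp Query values, 1/mm (vectorized, recycled).
#' @param fx One of the LUT's spatial frequencies.
#' @return Interpolated \code{Rd}.
#' @export
lut_rd_at <- function(lut, mua, musp, fx) {
  fi <- lut_fx_index(lut, fx)
  n <- max(length(mua), length(musp))
  mua <- rep_len(mua, n); musp <- rep_len(musp, n)
  if (any(mua < min(lut$mua_grid) - 1e-12) || any(mua > max(lut$mua_grid) + 1e-12) ||
      any(musp < min(lut$musp_grid) - 1e-12) || any(musp > max(lut$musp_grid) + 1e-12))
    pf_usage_error("query outside LUT grid bounds")
  gi <- findInterval(mua, lut$mua_grid, rightmost.closed = TRUE, all.inside = TRUE)
  gj <- findInterval(musp, lut$musp_grid, rightmost.closed = TRUE, all.inside = TRUE)
  fa <- (mua - lut$mua_grid[gi]) / (lut$mua_grid[gi + 1] - lut$mua_grid[gi])
  fb <- (musp - lut$musp_grid[gj]) / (lut$musp_grid[gj + 1] - lut$musp_grid[gj])
  M <- lut$rd[, , fi]
  M[cbind(gi, gj)] * (1 - fa) * (1 - fb) +
    M[cbind(gi + 1, gj)] * fa * (1 - fb) +
    M[cbind(gi, gj + 1)] * (1 - fa) * fb +
    M[cbind(gi + 1, gj + 1)] * fa * fb
}
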
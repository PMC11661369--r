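# Linear filament-mixing model: mu = A*Rg + B*Rw + C for mu in {mua, musp},
# with (Rg, Rw, Rt) percentages of gray/white/translucent filament on the
# 100-simplex.  Fitting, forward prediction, constrained inverse design and
# validation-error arithmetic live here.

#' Filament mixing ratio on the percentage simplex
#'
#' A mixing ratio is the triple of gray, white and translucent filament
#' volume percentages \code{(Rg, Rw, Rt)} fed to the mixing extruder.  The
#' three components are non-negative and sum to 100; \code{Rt} defaults to
#' the remainder \code{100 - Rg - Rw}.
#'
#' @param Rg Gray filament percentage, 0-100.
#' @param Rw White filament percentage, 0-100.
#' @param Rt Translucent filament percentage; defaults to the simplex
#'   remainder.
#' @param tol Absolute tolerance on the simplex constraint.
#' @return An object of class \code{mixing_ratio}: a named numeric vector
#'   \code{c(Rg, Rw, Rt)}.
#' @examples
#' mixing_ratio(26, 40)      # (26/G, 40/W, 34/T)
#' mixing_ratio(0, 0, 100)   # pure translucent
#' @export
mixing_ratio <- function(Rg, Rw, Rt = 100 - Rg - Rw, tol = 1e-9) {
  for (v in list(Rg = Rg, Rw = Rw, Rt = Rt)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      pf_usage_error("mixing ratio components must be single finite numbers")
  }
  if (Rg < -tol || Rw < -tol || Rt < -tol ||
      Rg > 100 + tol || Rw > 100 + tol || Rt > 100 + tol)
    pf_usage_error("mixing ratio components must lie in [0, 100]")
  if (abs(Rg + Rw + Rt - 100) > tol)
    pf_usage_error(sprintf("mixing ratio must sum to 100 (got %.12g)", Rg + Rw + Rt))
  structure(c(Rg = Rg, Rw = Rw, Rt = Rt), class = "mixing_ratio")
}

#' @export
format.mixing_ratio <- function(x, ...) {
  sprintf("(%g/G, %g/W, %g/T)", x[["Rg"]], x[["Rw"]], x[["Rt"]])
}

#' @export
print.mixing_ratio <- function(x, ...) {
  cat("<mixing_ratio>", format(x), "\n")
  invisible(x)
}

#' Optical properties of a turbid medium
#'
#' Absorption coefficient \code{mua} and reduced scattering coefficient
#' \code{musp}, both in 1/mm, at a single wavelength (informational, default
#' 635 nm, the red LED used by the reference SFDI instrument).
#'
#' @param mua Absorption coefficient, 1/mm; must be > 0.
#' @param musp Reduced scattering coefficient, 1/mm; must be > 0.
#' @param wavelength Wavelength in nm (metadata only).
#' @return An object of class \code{optical_properties}.
#' @export
optical_properties <- function(mua, musp, wavelength = 635) {
  stopifnot_scalar_number(mua, "mua", positive = TRUE)
  stopifnot_scalar_number(musp, "musp", positive = TRUE)
  structure(list(mua = mua, musp = musp, wavelength = wavelength),
            class = "optical_properties")
}

#' @export
format.optical_properties <- function(x, ...) {
  sprintf("mua = %.4g mm^-1, musp = %.4g mm^-1 (%g nm)", x$mua, x$musp, x$wavelength)
}

#' @export
print.optical_properties <- function(x, ...) {
  cat("<optical_properties>", format(x), "\n")
  invisible(x)
}

#' Construct a mixing model directly from known coefficients
#'
#' Builds a fitted-model object from externally known plane coefficients,
#' e.g. a previously characterized filament set.  Coefficients are in
#' 1/mm per percent (\code{A}, \code{B}) and 1/mm (\code{C}).
#'
#' @param mua Numeric length-3 vector \code{c(A, B, C)} for the absorption fit.
#' @param musp Numeric length-3 vector \code{c(A, B, C)} for the reduced
#'   scattering fit.
#' @param filaments Optional character vector naming the gray/white/translucent
#'   filament products.
#' @return A \code{mixing_model} object with both property fits populated.
#' @export
mixing_model <- function(mua = NULL, musp = NULL, filaments = NULL) {
  as_fit <- function(v, prop) {
    if (is.null(v)) return(NULL)
    if (length(v) != 3L || !is.numeric(v))
      pf_usage_error(sprintf("`%s` coefficients must be c(A, B, C)", prop))
    if (v[[3]] <= 0)
      warning(sprintf("intercept C for %s is not > 0; the fit is not physically meaningful", prop))
    list(A = v[[1]], B = v[[2]], C = v[[3]], r_squared = NA_real_,
         residuals = numeric(0), n = NA_integer_, weighted = FALSE)
  }
  structure(list(mua = as_fit(mua, "mua"), musp = as_fit(musp, "musp"),
                 filaments = filaments),
            class = "mixing_model")
}

#' Bundled gray/white/translucent PLA characterization
#'
#' The linear-mixing coefficients for the gray, white and translucent PLA
#' filament set characterized with the titration workflow this package
#' implements: \code{mua = 0.0078 Rg + 0.00095 Rw + 0.0056} and
#' \code{musp = 0.036 Rg + 0.034 Rw + 0.35} (1/mm at 635 nm).  Useful as a
#' realistic default when designing phantoms without running a new titration.
#'
#' @return A \code{mixing_model}.
#' @examples
#' m <- pla_gwt_model()
#' predict(m, mixing_ratio(100, 0)) # upper end of the achievable mua range
#' @export
pla_gwt_model <- function() {
  mixing_model(mua = c(0.0078, 0.00095, 0.0056),
               musp = c(0.036, 0.034, 0.35),
               filaments = c(gray = "PLA gray", white = "PLA white",
                             translucent = "PLA translucent"))
}

has_fit <- function(model, property) {
  inherits(model, "mixing_model") && !is.null(model[[property]])
}

assert_full_model <- function(model) {
  if (!has_fit(model, "mua") || !has_fit(model, "musp"))
    pf_usage_error("model must have both mua and musp fits")
  invisible(model)
}

#' Fit the linear-mixing model to titration data
#'
#' Ordinary least squares fit of one optical property against the gray and
#' white mixing percentages with intercept: \code{mu = A Rg + B Rw + C}.
#' Requires at least 3 records and a non-collinear \code{(Rg, Rw)} design.
#' Optionally weights records by the inverse squared per-record dispersion
#' (off by default).
#'
#' @param records A titration table: data frame with columns \code{Rg},
#'   \code{Rw} and the measured property column (\code{mua} or \code{musp});
#'   see \code{\link{synth_titration}} and \code{\link{read_titration}}.
#' @param property Which property to fit, \code{"mua"} or \code{"musp"}.
#' @param weighted If \code{TRUE}, weight by \code{1/sd^2} using the
#'   \code{<property>_sd} column.
#' @return A \code{mixing_model} with the requested property's fit populated
#'   (\code{A}, \code{B}, \code{C}, \code{r_squared}, \code{residuals}).
#' @export
fit_linear_mixing <- function(records, property = c("mua", "musp"),
                              weighted = FALSE) {
  property <- match.arg(property)
  records <- as.data.frame(records)
  need <- c("Rg", "Rw", property)
  if (!all(need %in% names(records)))
    pf_usage_error(paste("titration records need columns:", paste(need, collapse = ", ")))
  if (nrow(records) < 3L)
    pf_error(sprintf("insufficient data: need >= 3 titration records, got %d",
                     nrow(records)), "pf_usage_error")
  X <- cbind(1, records$Rg, records$Rw)
  qrX <- qr(X)
  if (qrX$rank < 3L) {
    # name the degenerate direction for the error message
    dir <- if (length(unique(records$Rg)) == 1L) "Rg is constant"
           else if (length(unique(records$Rw)) == 1L) "Rw is constant"
           else "Rg and Rw are collinear"
    pf_error(sprintf("rank-deficient titration design: %s", dir), "pf_usage_error")
  }
  w <- NULL
  if (weighted) {
    sdcol <- paste0(property, "_sd")
    if (!sdcol %in% names(records))
      pf_usage_error(sprintf("weighted fit needs a `%s` column", sdcol))
    w <- 1 / pmax(records[[sdcol]], 1e-12)^2
  }
  df <- data.frame(y = records[[property]], Rg = records$Rg, Rw = records$Rw)
  fit <- if (is.null(w)) lm(y ~ Rg + Rw, data = df) else lm(y ~ Rg + Rw, data = df, weights = w)
  cf <- coef(fit)
  res <- df$y - (cf[["(Intercept)"]] + cf[["Rg"]] * df$Rg + cf[["Rw"]] * df$Rw)
  sst <- sum((df$y - mean(df$y))^2)
  r2 <- if (sst <= .Machine$double.eps * sum(df$y^2)) 1 else 1 - sum(res^2) / sst
  if (cf[["(Intercept)"]] <= 0)
    warning(sprintf("fitted intercept C = %.4g for %s is not > 0", cf[["(Intercept)"]], property))
  out <- mixing_model()
  out[[property]] <- list(A = unname(cf[["Rg"]]), B = unname(cf[["Rw"]]),
                          C = unname(cf[["(Intercept)"]]),
                          r_squared = r2, residuals = res,
                          n = nrow(records), weighted = weighted)
  out
}

#' Fit both optical properties of the mixing model
#'
#' Convenience wrapper calling \code{\link{fit_linear_mixing}} for
#' \code{mua} and \code{musp} and merging the two fits.
#'
#' @inheritParams fit_linear_mixing
#' @return A \code{mixing_model} with both fits populated.
#' @export
fit_mixing_model <- function(records, weighted = FALSE) {
  m <- fit_linear_mixing(records, "mua", weighted = weighted)
  m$musp <- fit_linear_mixing(records, "musp", weighted = weighted)$musp
  m
}

#' @export
print.mixing_model <- function(x, ...) {
  cat("<mixing_model>\n")
  for (p in c("mua", "musp")) {
    f <- x[[p]]
    if (is.null(f)) {
      cat(sprintf("  %-4s : <not fitted>\n", p))
    } else {
      cat(sprintf("  %-4s : %s = %.4g*Rg + %.4g*Rw + %.4g  (R^2 = %s)\n",
                  p, p, f$A, f$B, f$C,
                  if (is.na(f$r_squared)) "n/a" else sprintf("%.3f", f$r_squared)))
    }
  }
  invisible(x)
}

predict_one <- function(fit, ratio) {
  fit$A * ratio[["Rg"]] + fit$B * ratio[["Rw"]] + fit$C
}

#' Predict optical properties for a mixing ratio
#'
#' Evaluates the linear-mixing planes at a mixing ratio, returning the modeled
#' absorption and reduced scattering coefficients.
#'
#' @param object A fully fitted \code{mixing_model}.
#' @param ratio A \code{\link{mixing_ratio}}.
#' @param ... Unused.
#' @return An \code{\link{optical_properties}} object.
#' @export
predict.mixing_model <- function(object, ratio, ...) {
  assert_full_model(object)
  if (!inherits(ratio, "mixing_ratio"))
    ratio <- mixing_ratio(ratio[[1]], ratio[[2]], if (length(ratio) >= 3) ratio[[3]] else 100 - ratio[[1]] - ratio[[2]])
  optical_properties(predict_one(object$mua, ratio), predict_one(object$musp, ratio))
}

#' Relative validation error
#'
#' \code{|measured - predicted| / predicted}: the fraction by which a measured
#' optical property deviates from the model-predicted value.  Vectorized.
#'
#' @param measured Measured value(s), 1/mm.
#' @param predicted Model-predicted value(s), 1/mm; must be nonzero.
#' @return Relative error(s) as fractions (0.15 = 15%).
#' @examples
#' relative_error(0.115, 0.1) # 0.15
#' @export
relative_error <- function(measured, predicted) {
  if (any(predicted == 0))
    pf_error("relative error undefined for predicted value 0", "pf_usage_error")
  abs(measured - predicted) / abs(predicted)
}

#' Achievable optical-property range of a mixing model
#'
#' The linear model attains its extremes on the simplex vertices
#' \code{(0,0)}, \code{(100,0)}, \code{(0,100)}; the minimum sits at the pure
#' translucent vertex for positive coefficients.
#'
#' @param model A fully fitted \code{mixing_model}.
#' @return A 2x2 matrix with rows \code{mua}, \code{musp} and columns
#'   \code{min}, \code{max}, in 1/mm.
#' @export
feasible_range <- function(model) {
  assert_full_model(model)
  verts <- list(c(0, 0), c(100, 0), c(0, 100))
  out <- sapply(c("mua", "musp"), function(p) {
    vals <- sapply(verts, function(v) model[[p]]$A * v[1] + model[[p]]$B * v[2] + model[[p]]$C)
    c(min = min(vals), max = max(vals))
  })
  t(out)
}

# Continuous constrained minimizer of the inverse-design objective
#   f(Rg,Rw) = ((mua(R)-Tm)/Tm)^2 + ((musp(R)-Ts)/Ts)^2
# over the triangle Rg,Rw >= 0, Rg+Rw <= 100.  Exact: solve the unconstrained
# 2x2 normal equations; if outside, minimize the 1-D quadratic on each edge.
invert_continuous <- function(model, target) {
  Tm <- target$mua; Ts <- target$musp
  a1 <- model$mua$A / Tm; b1 <- model$mua$B / Tm; c1 <- (Tm - model$mua$C) / Tm
  a2 <- model$musp$A / Ts; b2 <- model$musp$B / Ts; c2 <- (Ts - model$musp$C) / Ts
  obj <- function(Rg, Rw) (a1 * Rg + b1 * Rw - c1)^2 + (a2 * Rg + b2 * Rw - c2)^2
  cands <- list()
  # unconstrained (normal equations)
  AtA <- matrix(c(a1^2 + a2^2, a1 * b1 + a2 * b2,
                  a1 * b1 + a2 * b2, b1^2 + b2^2), 2, 2)
  Atb <- c(a1 * c1 + a2 * c2, b1 * c1 + b2 * c2)
  if (abs(det(AtA)) > 1e-18) {
    u <- solve(AtA, Atb)
    if (u[1] >= 0 && u[2] >= 0 && sum(u) <= 100) cands[[length(cands) + 1]] <- u
  }
  # 1-D quadratic q(t) = (p t - r)^2 + (s t - v)^2 minimized at
  # t* = (p r + s v)/(p^2 + s^2), clamped to [0, 100]
  edge1d <- function(p, r, s, v) {
    den <- p^2 + s^2
    t <- if (den > 0) (p * r + s * v) / den else 0
    min(max(t, 0), 100)
  }
  # edge Rg = 0
  t <- edge1d(b1, c1, b2, c2); cands[[length(cands) + 1]] <- c(0, t)
  # edge Rw = 0
  t <- edge1d(a1, c1, a2, c2); cands[[length(cands) + 1]] <- c(t, 0)
  # edge Rg + Rw = 100: Rg = t, Rw = 100 - t
  t <- edge1d(a1 - b1, c1 - 100 * b1, a2 - b2, c2 - 100 * b2)
  cands[[length(cands) + 1]] <- c(t, 100 - t)
  vals <- vapply(cands, function(u) obj(u[1], u[2]), numeric(1))
  best <- cands[[which.min(vals)]]
  list(Rg = best[1], Rw = best[2], objective = min(vals), obj_fun = obj)
}

#' Inverse design: mixing ratio for target optical properties
#'
#' Finds the mixing ratio whose modeled properties best match a target, by
#' minimizing the sum of squared relative errors in \code{(mua, musp)} subject
#' to \code{Rg, Rw >= 0} and \code{Rg + Rw <= 100} (solved exactly; the
#' objective is quadratic on a triangle).  With \code{rounding = "integer"},
#' the up-to-four integer neighbors of the continuous optimum that stay on the
#' simplex are enumerated and the one with the smallest objective wins; ties
#' break toward larger \code{Rt} (less pigment).
#'
#' @param model A fully fitted \code{mixing_model}.
#' @param target Target \code{\link{optical_properties}}.
#' @param rounding \code{"integer"} (default) or \code{"none"}.
#' @param feasibility_tol A target is deemed feasible when both relative
#'   errors at the continuous optimum are below this fraction (default 0.05).
#' @return An \code{inverse_design} object: \code{ratio} (rounded, or the
#'   continuous one for \code{rounding = "none"}), \code{ratio_continuous},
#'   \code{achieved} (forward prediction at \code{ratio}), \code{target},
#'   \code{relative_errors} (per property, denominator = achieved model value),
#'   and \code{feasible}.
#' @examples
#' m <- pla_gwt_model()
#' invert_mixture(m, optical_properties(0.01, 0.5))
#' @export
invert_mixture <- function(model, target, rounding = c("integer", "none"),
                           feasibility_tol = 0.05) {
  rounding <- match.arg(rounding)
  assert_full_model(model)
  if (!inherits(target, "optical_properties"))
    pf_usage_error("`target` must be an optical_properties object")
  cont <- invert_continuous(model, target)
  ratio_cont <- mixing_ratio(cont$Rg, cont$Rw, tol = 1e-6)
  ach_cont <- predict(model, ratio_cont)
  err_cont <- c(mua = relative_error(target$mua, ach_cont$mua),
                musp = relative_error(target$musp, ach_cont$musp))
  feasible <- all(err_cont < feasibility_tol)
  if (rounding == "none") {
    ratio <- ratio_cont
    achieved <- ach_cont
    errs <- err_cont
  } else {
    gs <- unique(pmin(pmax(c(floor(cont$Rg), ceiling(cont$Rg)), 0), 100))
    ws <- unique(pmin(pmax(c(floor(cont$Rw), ceiling(cont$Rw)), 0), 100))
    cand <- expand.grid(Rg = gs, Rw = ws)
    cand <- cand[cand$Rg + cand$Rw <= 100, , drop = FALSE]
    ov <- mapply(cont$obj_fun, cand$Rg, cand$Rw)
    # tie-break: smallest objective, then largest Rt (= smallest Rg+Rw), then Rg
    ord <- order(round(ov, 12), cand$Rg + cand$Rw, cand$Rg)
    pick <- cand[ord[1], ]
    ratio <- mixing_ratio(pick$Rg, pick$Rw)
    achieved <- predict(model, ratio)
    errs <- c(mua = relative_error(target$mua, achieved$mua),
              musp = relative_error(target$musp, achieved$musp))
  }
  structure(list(ratio = ratio, ratio_continuous = ratio_cont,
                 achieved = achieved, target = target,
                 relative_errors = errs, feasible = feasible,
                 objective = cont$objective, feasibility_tol = feasibility_tol),
            class = "inverse_design")
}

#' @export
print.inverse_design <- function(x, ...) {
  cat("<inverse_design>\n")
  cat("  ratio     :", format(x$ratio), "\n")
  cat("  target    :", format(x$target), "\n")
  cat("  achieved  :", format(x$achieved), "\n")
  cat(sprintf("  rel. err  : mua %.2f%%, musp %.2f%%  (feasible: %s)\n",
              100 * x$relative_errors[["mua"]], 100 * x$relative_errors[["musp"]],
              x$feasible))
  invisible(x)
}

#' Summarize a rectangular region of interest of a property map
#'
#' Median and standard deviation of the pixels inside a rectangular ROI, plus
#' the physical area covered.  Mirrors the ROI reporting used when reading
#' recovered SFDI maps (e.g. a 45x45-pixel ROI at 0.035 mm^2 per pixel is
#' about 0.7 cm^2).
#'
#' @param property_map Numeric matrix of per-pixel values (1/mm).
#' @param roi List with integer ranges \code{rows = c(r1, r2)} and
#'   \code{cols = c(c1, c2)} (inclusive, 1-based).
#' @param pixel_area_mm2 Area of one camera pixel, mm^2.
#' @return List: \code{median}, \code{sd}, \code{n_pixels}, \code{area_mm2},
#'   \code{area_cm2}.
#' @export
summarize_roi <- function(property_map, roi, pixel_area_mm2 = 0.035) {
  stopifnot(is.matrix(property_map))
  r <- roi$rows; cc <- roi$cols
  if (length(r) != 2 || length(cc) != 2 || r[1] > r[2] || cc[1] > cc[2])
    pf_usage_error("roi must be list(rows = c(r1, r2), cols = c(c1, c2)) with r1 <= r2, c1 <= c2")
  if (r[1] < 1 || cc[1] < 1 || r[2] > nrow(property_map) || cc[2] > ncol(property_map))
    pf_usage_error("roi exceeds map bounds")
  px <- property_map[r[1]:r[2], cc[1]:cc[2]]
  if (length(px) == 0) pf_usage_error("empty roi")
  n <- length(px)
  list(median = median(as.numeric(px)), sd = sd(as.numeric(px)),
       n_pixels = n, area_mm2 = n * pixel_area_mm2,
       area_cm2 = n * pixel_area_mm2 / 100)
}
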
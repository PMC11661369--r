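# Linear-mixing model: fitting, prediction, inverse design, validation error.

test_that("mixing_ratio enforces the percentage simplex", {
  r <- mixing_ratio(26, 40)
  expect_equal(unname(unclass(r)), c(26, 40, 34))
  expect_error(mixing_ratio(30, 30, 50), "sum to 100")
  expect_error(mixing_ratio(60, 60), class = "pf_usage_error") # Rt would be negative
  expect_error(mixing_ratio(-1, 50, 51), class = "pf_usage_error")
  expect_error(mixing_ratio(101, 0, -1), class = "pf_usage_error")
  expect_silent(mixing_ratio(0, 0, 100))
})

test_that("noiseless fits recover generating coefficients exactly", {
  # 4 exact records at simplex-spanning ratios
  rg <- c(0, 100, 0, 50); rw <- c(0, 0, 100, 50)
  tab <- data.frame(Rg = rg, Rw = rw,
                    mua = REF_MUA_COEF["A"] * rg + REF_MUA_COEF["B"] * rw + REF_MUA_COEF["C"])
  f <- fit_linear_mixing(tab, "mua")
  expect_equal(c(f$mua$A, f$mua$B, f$mua$C), unname(REF_MUA_COEF), tolerance = 1e-12)
  expect_equal(f$mua$r_squared, 1)

  # the full 16-point titration design, both properties
  tab16 <- synth_titration(ref_model())
  f16 <- fit_mixing_model(tab16)
  expect_equal(c(f16$mua$A, f16$mua$B, f16$mua$C), unname(REF_MUA_COEF), tolerance = 1e-9)
  expect_equal(c(f16$musp$A, f16$musp$B, f16$musp$C), unname(REF_MUSP_COEF), tolerance = 1e-9)

  # property: arbitrary generating coefficients recovered to 1e-9 relative,
  # and agreement with the independent normal-equations oracle
  set.seed(7)
  for (k in 1:10) {
    coefs <- c(runif(1, 1e-4, 0.01), runif(1, 1e-4, 0.01), runif(1, 1e-3, 0.5))
    tab <- data.frame(Rg = tab16$Rg, Rw = tab16$Rw,
                      mua = coefs[1] * tab16$Rg + coefs[2] * tab16$Rw + coefs[3])
    f <- fit_linear_mixing(tab, "mua")
    expect_equal(c(f$mua$A, f$mua$B, f$mua$C), coefs, tolerance = 1e-9)
    orc <- ols_plane(tab$Rg, tab$Rw, tab$mua)
    expect_equal(c(f$mua$C, f$mua$A, f$mua$B), orc, tolerance = 1e-9)
  }
})

test_that("fit rejects degenerate titration designs", {
  base <- data.frame(Rg = c(0, 10), Rw = c(0, 10), mua = c(0.005, 0.09))
  expect_error(fit_linear_mixing(base, "mua"), "insufficient data",
               class = "pf_usage_error")
  coll <- data.frame(Rg = c(0, 10, 20, 30), Rw = c(0, 10, 20, 30),
                     mua = c(0.005, 0.09, 0.18, 0.26))
  expect_error(fit_linear_mixing(coll, "mua"), "collinear")
  const <- data.frame(Rg = c(5, 5, 5, 5), Rw = c(0, 10, 20, 30),
                      mua = c(0.05, 0.06, 0.07, 0.08))
  expect_error(fit_linear_mixing(const, "mua"), "Rg is constant")
})

test_that("noisy replicate fits recover coefficients on average", {
  # 5% multiplicative noise, 100 seeded replicates; OLS is unbiased so the
  # mean recovered coefficient lands within 5% of truth
  n_rep <- 100
  co <- matrix(0, n_rep, 3)
  for (s in seq_len(n_rep)) {
    tab <- synth_titration(ref_model(), config = synth_config(
      seed = 2000 + s, noise = list(type = "multiplicative", sigma = 0.05)))
    # noise can push the fitted intercept negative, which warns by design
    f <- suppressWarnings(fit_linear_mixing(tab, "mua"))
    co[s, ] <- c(f$mua$A, f$mua$B, f$mua$C)
  }
  expect_lt(abs(mean(co[, 1]) - REF_MUA_COEF["A"]) / REF_MUA_COEF["A"], 0.05)
  # the dominant coefficient is also tight per replicate
  expect_lt(mean(abs(co[, 1] - REF_MUA_COEF["A"]) / REF_MUA_COEF["A"]), 0.05)
})

test_that("predict evaluates the mixing planes", {
  m <- ref_model()
  p <- predict(m, mixing_ratio(100, 0))
  expect_equal(p$mua, 0.7856)
  expect_equal(p$musp, 3.95)
  p0 <- predict(m, mixing_ratio(0, 0))
  expect_equal(p0$mua, 0.0056)
  expect_equal(p0$musp, 0.35)
  ph <- predict(m, mixing_ratio(50, 50))
  expect_equal(ph$mua, 0.4431)
  expect_equal(ph$musp, 3.85)
  # monotonicity: mua strictly increasing in Rg at fixed Rw
  mua_seq <- vapply(seq(0, 60, by = 5), function(rg)
    predict(m, mixing_ratio(rg, 20))$mua, numeric(1))
  expect_true(all(diff(mua_seq) > 0))
  # prediction requires both fits
  half <- fit_linear_mixing(synth_titration(m), "mua")
  expect_error(predict(half, mixing_ratio(0, 0)), "both")
})

test_that("inverse design round-trips feasible targets", {
  m <- ref_model()
  set.seed(11)
  for (k in 1:15) {
    rg <- runif(1, 0, 80); rw <- runif(1, 0, 100 - rg)
    tgt <- predict(m, mixing_ratio(rg, rw))
    inv <- invert_mixture(m, tgt, rounding = "none")
    expect_equal(unname(unclass(inv$ratio_continuous))[1:2], c(rg, rw),
                 tolerance = 1e-6)
    expect_true(inv$feasible)
  }
  # integer rounding returns integer simplex points and exact forward values
  tgt <- predict(m, mixing_ratio(26, 40))
  inv <- invert_mixture(m, tgt)
  expect_identical(unname(round(unclass(inv$ratio))), unname(unclass(inv$ratio)))
  expect_equal(sum(inv$ratio), 100)
  expect_equal(inv$achieved$mua, predict(m, inv$ratio)$mua)
})

test_that("inverse design flags infeasible and handles boundary targets", {
  m <- ref_model()
  inv <- invert_mixture(m, optical_properties(2.0, 1.5))
  expect_false(inv$feasible)
  # soft-tissue target lands on the low-pigment edge
  inv2 <- invert_mixture(m, optical_properties(0.01, 0.5))
  expect_equal(unname(inv2$ratio[["Rg"]]), 0)
  expect_lte(abs(inv2$ratio[["Rw"]] - 5), 1)
  expect_error(invert_mixture(m, optical_properties(-0.1, 0.5)),
               class = "pf_usage_error")
})

test_that("relative_error implements |measured - predicted| / predicted", {
  expect_equal(relative_error(0.1, 0.1), 0)
  expect_equal(relative_error(0.115, 0.1), 0.15)
  expect_equal(relative_error(0.085, 0.1), 0.15)
  expect_error(relative_error(0.1, 0), class = "pf_usage_error")
  # symmetry property
  set.seed(3)
  for (k in 1:20) {
    p <- runif(1, 0.1, 2); d <- runif(1, 0, p * 0.99)
    expect_equal(relative_error(p + d, p), relative_error(p - d, p))
  }
})

test_that("feasible_range spans the simplex vertices", {
  m <- ref_model()
  fr <- feasible_range(m)
  expect_equal(unname(fr["mua", ]), c(0.0056, 0.7856))
  expect_equal(unname(fr["musp", ]), c(0.35, 3.95))
  flat <- mixing_model(mua = c(0, 0, 0.02), musp = c(0, 0, 0.5))
  expect_equal(unname(feasible_range(flat)["mua", ]), c(0.02, 0.02))
})

test_that("summarize_roi reports median, dispersion and physical area", {
  map <- matrix(0.5, 60, 60)
  s <- summarize_roi(map, list(rows = c(8, 52), cols = c(8, 52)),
                     pixel_area_mm2 = 0.035)
  expect_equal(s$n_pixels, 45 * 45)
  expect_equal(round(s$area_cm2, 1), 0.7)
  expect_equal(s$median, 0.5)
  expect_equal(s$sd, 0)
  m3 <- matrix(1:9, 3, 3)
  expect_equal(summarize_roi(m3, list(rows = c(1, 3), cols = c(1, 3)))$median, 5)
  expect_error(summarize_roi(m3, list(rows = c(1, 4), cols = c(1, 3))), "bounds")
  expect_error(summarize_roi(m3, list(rows = c(3, 1), cols = c(1, 3))),
               class = "pf_usage_error")
})
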
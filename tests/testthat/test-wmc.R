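# White Monte Carlo transport and the radial / frequency-domain reflectance
# machinery.

test_that("step sampling and boundary handling follow the stated laws", {
  run <- simulate_white_mc(medium_model(n = 1, g = 0, mus_ref = 2),
                           n_photons = 2e4, seed = 5, record_first_depth = TRUE,
                           max_path_mfp = 1e5)
  # first-interaction depth is exponential at mus_ref
  ks <- suppressWarnings(stats::ks.test(run$first_depth, "pexp", rate = 2))
  expect_gt(ks$p.value, 0.01)
  # conservation: detected weight never exceeds launched
  expect_lte(sum(run$w), run$n_photons)
  # matched boundary: no specular loss
  expect_equal(run$specular, 0)
})

test_that("specular reflection is the exact normal-incidence Fresnel value", {
  run <- simulate_white_mc(medium_model(1.4, 0.9, 10), n_photons = 1e3, seed = 2)
  expect_equal(run$specular, ((1.4 - 1) / (1.4 + 1))^2)
  expect_true(all(run$w == 1 - run$specular))
  expect_true(all(run$r >= 0) && all(run$L > 0))
})

test_that("energy is conserved at zero absorption with a matched boundary", {
  run <- simulate_white_mc(medium_model(n = 1, g = 0, mus_ref = 1),
                           n_photons = 2e5, seed = 7, max_path_mfp = 1e5)
  expect_equal(sum(run$w) / run$n_photons, 1, tolerance = 0.01)
})

test_that("seeded runs are bit-identical", {
  a <- simulate_white_mc(medium_model(1.4, 0.9, 10), 5e3, seed = 9)
  b <- simulate_white_mc(medium_model(1.4, 0.9, 10), 5e3, seed = 9)
  expect_identical(a$r, b$r)
  expect_identical(a$L, b$L)
  c <- simulate_white_mc(medium_model(1.4, 0.9, 10), 5e3, seed = 10)
  expect_false(identical(a$r, c$r))
})

test_that("radial reflectance responds monotonically to absorption", {
  run <- test_wmc_run()
  r1 <- radial_reflectance(run, mua = 0.01, musp = 1.42)
  r2 <- radial_reflectance(run, mua = 0.02, musp = 1.42)
  expect_true(all(r2$rd <= r1$rd))
  expect_lt(sum(r2$rd), sum(r1$rd))
  expect_error(radial_reflectance(structure(list(r = numeric(0)), class = "wmc_run"),
                                  0.01, 1), "empty run")
})

test_that("similarity rescaling is self-consistent where exact (g = 0)", {
  direct <- simulate_white_mc(medium_model(n = 1.4, g = 0, mus_ref = 2),
                              1e5, seed = 13)
  scaled <- simulate_white_mc(medium_model(n = 1.4, g = 0, mus_ref = 1),
                              1e5, seed = 14)
  for (mua in c(0.005, 0.05)) {
    rd_d <- hankel_transform(radial_reflectance(direct, mua, 2), c(0, 0.1))
    rd_s <- hankel_transform(radial_reflectance(scaled, mua, 2), c(0, 0.1))
    expect_equal(rd_s, rd_d, tolerance = 0.02)
  }
})

test_that("radial profile matches the dipole diffusion solution at 5-20 mm", {
  rr <- radial_reflectance(test_wmc_run(), 0.0064, 1.42,
                           breaks = seq(0, 30, by = 1))
  sel <- rr$mids >= 5 & rr$mids <= 20
  oracle <- farrell_rd_radial(rr$mids[sel], 0.0064, 1.42, n = 1.4)
  expect_true(all(abs(rr$rd[sel] / oracle - 1) < 0.15))
})

test_that("hankel transform has the right limits", {
  rr <- radial_reflectance(test_wmc_run(), 0.01, 1.42)
  # fx = 0 reduces to the plain radial integral
  plain <- sum(rr$rd * 2 * pi * rr$mids * diff(rr$breaks))
  expect_equal(hankel_transform(rr, 0), plain)
  # zero input -> zero output
  rr0 <- rr; rr0$rd <- rr$rd * 0
  expect_equal(hankel_transform(rr0, c(0, 0.1)), c(0, 0))
  # Rd decreases with frequency on a diffusive medium
  rd <- hankel_transform(rr, c(0, 0.05, 0.1, 0.2))
  expect_true(all(diff(rd) < 0))
})
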
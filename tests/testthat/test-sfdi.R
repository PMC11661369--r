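# Three-phase demodulation, calibration, LUT inversion and the composed
# recovery pipeline.

make_phase_frames <- function(offset, amp, fx = 0.05, pitch = 0.2, nr = 16, nc = 24) {
  x <- matrix(rep((seq_len(nc) - 1) * pitch, each = nr), nr, nc)
  lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(ph)
    offset + amp * cos(2 * pi * fx * x + ph))
}

test_that("three-phase demodulation is exact for sinusoidal frames", {
  off <- 120; amp <- 37.5
  fr <- make_phase_frames(off, amp)
  d <- demodulate(fr[[1]], fr[[2]], fr[[3]])
  expect_equal(d$ac, matrix(amp, 16, 24), tolerance = 1e-12)
  expect_equal(d$dc, matrix(off, 16, 24), tolerance = 1e-12)
  # constant frames: AC 0, DC c
  cf <- matrix(42, 8, 8)
  d0 <- demodulate(cf, cf, cf)
  expect_equal(d0$ac, matrix(0, 8, 8))
  expect_equal(d0$dc, cf)
  # homogeneity in gain
  d2 <- demodulate(3 * fr[[1]], 3 * fr[[2]], 3 * fr[[3]])
  expect_equal(d2$ac, 3 * d$ac)
  expect_equal(d2$dc, 3 * d$dc)
  expect_error(demodulate(cf, cf, matrix(1, 4, 4)), class = "pf_usage_error")
})

test_that("reference calibration is the stated amplitude ratio", {
  lut <- test_lut()
  ref_props <- optical_properties(0.0064, 1.42)
  ac <- matrix(500, 10, 10)
  rd <- sfdi_calibrate(list("0" = ac, "0.1" = ac),
                       list(ac, ac), ref_props, lut)
  expect_equal(rd[["0"]], matrix(lut_rd_at(lut, 0.0064, 1.42, 0), 10, 10))
  rd2 <- sfdi_calibrate(list("0" = ac / 2, "0.1" = ac / 2),
                        list(ac, ac), ref_props, lut)
  expect_equal(rd2[["0"]], rd[["0"]] / 2)
  # zero reference pixels are masked, not propagated
  acz <- ac; acz[1, 1] <- 0
  rd3 <- sfdi_calibrate(list("0" = ac, "0.1" = ac), list(acz, ac), ref_props, lut)
  expect_true(is.na(rd3[["0"]][1, 1]))
  expect_false(anyNA(rd3[["0"]][-1]))
})

test_that("LUT inversion is exact at nodes and masks unattainable pairs", {
  lut <- test_lut()
  opm <- invert_lut(matrix(lut$rd[10, 8, 1]), matrix(lut$rd[10, 8, 2]), lut)
  expect_equal(opm$mua[1, 1], lut$mua_grid[10], tolerance = 1e-10)
  expect_equal(opm$musp[1, 1], lut$musp_grid[8], tolerance = 1e-10)
  out <- invert_lut(matrix(0.99), matrix(0.99), lut)
  expect_false(out$valid[1, 1])
  expect_true(is.na(out$mua[1, 1]))
})

test_that("forward-inverse consistency holds on the grid interior", {
  lut <- test_lut()
  set.seed(31)
  mua <- runif(25, lut$mua_grid[2], lut$mua_grid[27])
  musp <- runif(25, lut$musp_grid[2], lut$musp_grid[21])
  rd0 <- lut_rd_at(lut, mua, musp, 0)
  rd1 <- lut_rd_at(lut, mua, musp, 0.1)
  opm <- invert_lut(matrix(rd0, 5, 5), matrix(rd1, 5, 5), lut)
  expect_true(all(opm$valid))
  expect_equal(as.numeric(opm$mua), mua, tolerance = 1e-3)
  expect_equal(as.numeric(opm$musp), musp, tolerance = 1e-3)
  # masking soundness: nothing valid outside the grid bounds
  expect_true(all(opm$mua[opm$valid] >= min(lut$mua_grid) - 1e-12))
  expect_true(all(opm$musp[opm$valid] <= max(lut$musp_grid) + 1e-12))
})

test_that("cross-model recovery of diffusion-synthesized frames lands close", {
  # frames built from the diffusion forward model, inverted through the
  # Monte Carlo LUT after reference calibration (which cancels most of the
  # forward-model mismatch)
  lut <- test_lut()
  cross <- function(mua, musp) {
    syn <- synth_sfdi_frames(matrix("a", 12, 12),
                             list(a = optical_properties(mua, musp)),
                             forward = "diffusion",
                             config = synth_config(seed = 2))
    opm <- sfdi_recover(syn$sample, syn$reference, lut)
    c(median(opm$mua[opm$valid]) / mua - 1,
      median(opm$musp[opm$valid]) / musp - 1)
  }
  # diffusive regime: both models agree to the stated 10% / 5%
  err <- cross(0.019, 1.42)
  expect_lt(abs(err[1]), 0.10)
  expect_lt(abs(err[2]), 0.05)
  # QA background (musp below 1/mm): the diffusion closed form itself
  # overestimates Rd at fx = 0.1 here, biasing cross-model musp by ~6%;
  # agreement within 10% for both properties
  err2 <- cross(0.019, 0.83)
  expect_lt(abs(err2[1]), 0.10)
  expect_lt(abs(err2[2]), 0.10)
})

test_that("self-calibrated homogeneous recovery returns the reference", {
  lut <- test_lut()
  syn <- synth_sfdi_frames(matrix("m", 20, 30),
                           list(m = optical_properties(0.0064, 1.42)),
                           forward = "lut", lut = lut,
                           config = synth_config(seed = 8, dim = c(20, 30)))
  opm <- sfdi_recover(syn$sample, syn$reference, lut)
  expect_true(all(opm$valid))
  expect_equal(median(opm$mua), 0.0064, tolerance = 0.02)
  expect_equal(median(opm$musp), 1.42, tolerance = 0.02)
})

test_that("recovery is invariant under global illumination gain", {
  lut <- test_lut()
  props <- list(bg = optical_properties(0.019, 0.83),
                inc = optical_properties(0.285, 2.49))
  rmp <- matrix("bg", 18, 18); rmp[6:12, 6:12] <- "inc"
  syn <- synth_sfdi_frames(rmp, props, forward = "lut", lut = lut,
                           config = synth_config(seed = 12))
  scale_fs <- function(fs, k) {
    fs$frames <- lapply(fs$frames, function(tr) lapply(tr, function(m) m * k))
    fs
  }
  o1 <- sfdi_recover(syn$sample, syn$reference, lut)
  ref2 <- syn$reference; ref2$frames <- scale_fs(ref2$frames, 2.7)
  o2 <- sfdi_recover(scale_fs(syn$sample, 2.7), ref2, lut)
  expect_equal(o2$mua, o1$mua)
  expect_equal(o2$musp, o1$musp)
})

test_that("1% frame noise shifts ROI medians by under 3%", {
  lut <- test_lut()
  props <- list(bg = optical_properties(0.019, 0.83),
                inc = optical_properties(0.114, 1.66))
  rmp <- matrix("bg", 24, 24); rmp[8:16, 8:16] <- "inc"
  clean <- synth_sfdi_frames(rmp, props, forward = "lut", lut = lut,
                             config = synth_config(seed = 4))
  noisy <- synth_sfdi_frames(rmp, props, forward = "lut", lut = lut,
                             config = synth_config(seed = 4,
                               noise = list(type = "multiplicative", sigma = 0.01)))
  oc <- sfdi_recover(clean$sample, clean$reference, lut)
  on <- sfdi_recover(noisy$sample, noisy$reference, lut)
  for (lab in c("bg", "inc")) {
    sel <- rmp == lab
    expect_lt(abs(median(on$mua[sel & on$valid]) / median(oc$mua[sel & oc$valid]) - 1), 0.03)
    expect_lt(abs(median(on$musp[sel & on$valid]) / median(oc$musp[sel & oc$valid]) - 1), 0.03)
  }
})
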
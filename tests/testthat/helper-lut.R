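# One White-MC baseline run and one LUT shared across the suite (built on
# first use; ~10 s).  Photon count is scaled down from production defaults to
# keep the suite fast; tolerances in the tests account for the extra Monte
# Carlo noise.

.pf_test_cache <- new.env(parent = emptyenv())

test_wmc_run <- function() {
  if (is.null(.pf_test_cache$run))
    .pf_test_cache$run <- simulate_white_mc(medium_model(1.4, 0.9, 10),
                                            n_photons = 1.5e5, seed = 42)
  .pf_test_cache$run
}

test_lut <- function() {
  if (is.null(.pf_test_cache$lut))
    .pf_test_cache$lut <- build_lut(
      test_wmc_run(),
      mua_grid = exp(seq(log(0.002), log(0.7), length.out = 28)),
      musp_grid = seq(0.3, 3.6, length.out = 22))
  .pf_test_cache$lut
}
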
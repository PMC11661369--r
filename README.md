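# phantomforge

Design and characterization tools for 3-D printed tissue-mimicking optical
phantoms made by on-the-fly mixing of gray (absorbing), white (scattering)
and translucent PLA filaments in a multi-filament fusion extruder.

Diffuse optical imaging groups need phantoms with known absorption (`mua`,
1/mm) and reduced scattering (`musp`, 1/mm) to validate instruments, and
heterogeneous phantoms with programmable inclusions to characterize
tomography and spatial-frequency-domain imaging (SFDI) systems.  phantomforge
implements the digital side of a printing workflow that produces such
phantoms from off-the-shelf filaments:

* **Linear mixing model** — calibrate `mu = A*Rg + B*Rw + C` for `mua` and
  `musp` from a titration study (`fit_mixing_model`), predict properties of
  any gray/white/translucent ratio on the percentage simplex, and
  inverse-design integer mixing ratios for target properties by exact
  constrained least squares (`invert_mixture`).
* **White Monte Carlo + LUT** — a compiled photon-transport kernel for the
  semi-infinite medium (Henyey-Greenstein scattering, Fresnel boundary, no
  absorption during transport); absorption applied post hoc via
  `exp(-mua*L)` and scattering spanned by similarity rescaling, so one run
  builds the whole reflectance lookup table `Rd(mua, musp, fx)`
  (`simulate_white_mc`, `build_lut`), cross-checked against the closed-form
  diffusion solution (`diffusion_rd`).
* **SFDI recovery** — three-phase demodulation, reference-phantom
  calibration and exact per-pixel two-frequency LUT inversion into `mua` /
  `musp` maps (`sfdi_recover`), with ROI reporting (`summarize_roi`).
* **Phantom designs** — parametric generators for titration rulers,
  benchmark tiles, a 9x9x0.5 cm quality-assurance slab (8 inclusions, 5
  property sets) and a 10x5x1.5 cm tomography slab (16 inclusions, 8
  property sets), resolved to printable mixtures and exported as watertight
  ASCII STL meshes plus a JSON manifest (`design_qa_phantom`,
  `resolve_mixtures`, `export_meshes`).
* **G-code post-processing** — purge-tower planning (one tower per unique
  mixture, deactivating after the last heterogeneous slice), purge-sequence
  insertion with 0.3 mm z-hop, axis-restricted travel rewriting, mixing-
  command injection and per-channel filament accounting (`parse_gcode`,
  `plan_purge_towers`, `insert_purge_sequences`).
* **Synthetic fixtures** — seeded generators for titration tables, SFDI
  frame sets with ground truth, and toy multi-region G-code, so everything
  tests without external data (`synth_titration`, `synth_sfdi_frames`,
  `toy_gcode`).

## Worked example

```r
library(phantomforge)

## 1. Calibrate the mixing model from a (here: synthesized) titration table
tab   <- synth_titration(pla_gwt_model())   # 16 ruler segments, noiseless
model <- fit_mixing_model(tab)
model
#> <mixing_model>
#>   mua  : mua = 0.0078*Rg + 0.00095*Rw + 0.0056  (R^2 = 1.000)
#>   musp : musp = 0.036*Rg + 0.034*Rw + 0.35  (R^2 = 1.000)

predict(model, mixing_ratio(100, 0))
#> <optical_properties> mua = 0.7856 mm^-1, musp = 3.95 mm^-1 (635 nm)

## 2. Inverse-design a soft-tissue mixture (target mua 0.01, musp 0.5 /mm)
invert_mixture(model, optical_properties(0.01, 0.5))
#> <inverse_design>
#>   ratio     : (0/G, 5/W, 95/T)
#>   target    : mua = 0.01 mm^-1, musp = 0.5 mm^-1 (635 nm)
#>   achieved  : mua = 0.01035 mm^-1, musp = 0.52 mm^-1 (635 nm)
#>   rel. err  : mua 3.38%, musp 3.85%  (feasible: TRUE)

## 3. Generate the QA phantom, resolve mixtures, export meshes + manifest
qa   <- design_qa_phantom()                   # background + 8 inclusions
plan <- resolve_mixtures(qa, model)           # 5 distinct integer mixtures
export_meshes(qa, dir = "qa-phantom", plan = plan)

## 4. Build a reflectance LUT and recover properties from synthetic frames
run <- simulate_white_mc(medium_model(n = 1.4, g = 0.9, mus_ref = 10),
                         n_photons = 2e5, seed = 42)
lut <- build_lut(run, mua_grid = exp(seq(log(0.002), log(0.7), length.out = 28)),
                 musp_grid = seq(0.3, 3.6, length.out = 22))
syn <- synth_sfdi_frames(region_map_from_design(qa), qa_props <- lapply(
         Filter(function(r) !is.null(r$target), qa$regions), `[[`, "target"),
       forward = "lut", lut = lut, config = synth_config(seed = 5))
opm <- sfdi_recover(syn$sample, syn$reference, lut)
opm
#> <optical_property_map> 90 x 90 pixels, 100.0% valid
#>   mua  median 0.019 /mm; musp median 0.83 /mm (valid pixels)
```

The recovered per-region medians equal the designed targets (background
`mua` 0.019, `musp` 0.83/mm; disk inclusions 15x/25x absorption contrast)
within the LUT interpolation error — the acceptance suite asserts 10%/5%
bands per region.

## Command line

A single dispatcher (also installed at `inst/cli/phantomforge`) exposes the
pipeline; exit codes distinguish usage errors (2), infeasible designs (3)
and internal failures (1):

```sh
phantomforge fit --titration titration.csv --out model.json
phantomforge predict --model model.json --Rg 100 --Rw 0
phantomforge design qa --model model.json --out qa/
phantomforge lut build --photons 200000 --seed 1 --out lut.json
phantomforge sfdi recover --sample DIR --reference DIR \
    --ref-mua 0.0064 --ref-musp 1.42 --lut lut.json
phantomforge gcode post --in sliced.gcode --plan qa/plan.json --zhop 0.3
```

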
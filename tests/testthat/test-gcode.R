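# G-code parsing and multi-material post-processing.

test_that("parser round-trips motion and derives layers", {
  toy <- toy_gcode("stripes", layers = 3, n_blocks = 4)
  prog <- parse_gcode(toy$text)
  expect_equal(n_layers(prog), 3)
  expect_equal(sum(prog$commands$de), toy$extrusion_total_mm)
  # emit -> reparse preserves motion and extrusion semantics
  re <- parse_gcode(emit_gcode(prog))
  keep <- prog$commands$code %in% c("G0", "G1")
  keep2 <- re$commands$code %in% c("G0", "G1")
  expect_equal(re$commands$px[keep2], prog$commands$px[keep])
  expect_equal(re$commands$py[keep2], prog$commands$py[keep])
  expect_equal(re$commands$pz[keep2], prog$commands$pz[keep])
  expect_equal(sum(re$commands$de), sum(prog$commands$de))
})

test_that("unsupported dialects are rejected by name", {
  expect_error(parse_gcode(c("G90", "G91", "G1 X1")), "G91",
               class = "pf_dialect_error")
  expect_error(parse_gcode(c("G20", "G1 X1")), "G20", class = "pf_dialect_error")
  expect_error(parse_gcode(c("M83", "G1 E1")), "M83", class = "pf_dialect_error")
})

test_that("purge tower planning counts unique mixtures and active range", {
  # three-mixture stand-in: 3 towers, active even on slices printing 2 mixtures
  ms <- design_mouse_standin()
  plan <- resolve_mixtures(ms, ref_model())
  towers <- plan_purge_towers(plan, design_bbox(ms))
  expect_length(towers, 3)
  lung_slice <- 50 # z = 10 mm: background + lung only
  expect_equal(towers_active(towers, lung_slice), 3)
  last_het <- towers[[1]]$active_layers[2]
  expect_equal(last_het, 250) # brain ends at z = 50 mm
  expect_equal(towers_active(towers, last_het + 1), 0)

  # single mixture: no towers
  single <- mixture_plan(list(A = mixing_ratio(10, 10)), layers = list("A", "A"))
  expect_length(plan_purge_towers(single, c(0, 0, 20, 20)), 0)

  # heterogeneous only in layers 1-10 of 50
  two <- mixture_plan(list(A = mixing_ratio(0, 0), B = mixing_ratio(50, 0)),
                      layers = c(rep(list(c("A", "B")), 10), rep(list("A"), 40)))
  tw <- plan_purge_towers(two, c(0, 0, 30, 30))
  expect_equal(tw[[1]]$active_layers, c(1L, 10L))
  expect_equal(towers_active(tw, 10), 2)
  expect_equal(towers_active(tw, 11), 0)

  # placement failure reports the required space
  expect_error(plan_purge_towers(two, c(0, 0, 280, 30)), "build area")
})

test_that("purge insertion hops, purges the configured volume, and conserves", {
  cfg <- postprocess_config()
  toy <- toy_gcode("stripes", layers = 2, n_blocks = 5) # A B A B A per layer
  expect_equal(toy$transitions_per_layer, 4)
  prog <- parse_gcode(toy$text)
  towers <- plan_purge_towers(toy$plan, toy$bbox, cfg)
  post <- insert_purge_sequences(prog, towers, toy$plan, cfg)
  df <- post$commands

  n_trans <- 2 * 4 # per-layer transitions; block order repeats so no extras
  expect_equal(sum(df$inserted & df$code == "M164 S0"), n_trans)

  # all tower-bound travels sit at layer Z + z_hop
  trav <- df[df$inserted & df$purpose %in% c("tower_travel", "return_travel"), ]
  expect_equal(sort(unique(round(trav$pz, 6))),
               round(c(0.2, 0.4) + cfg$z_hop, 6))

  # conservation: model moves untouched, added extrusion equals purge total
  expect_equal(sum(df$de[!df$inserted]), toy$extrusion_total_mm)
  pf_len <- cfg$purge_volume_per_transition / (pi * (cfg$filament_diameter / 2)^2)
  expect_equal(sum(df$de[df$inserted]), pf_len * n_trans, tolerance = 1e-9)
  # Z discipline: non-inserted commands keep their original Z states
  orig_z <- prog$commands$pz[prog$commands$code %in% c("G0", "G1")]
  post_z <- df$pz[!df$inserted & df$code %in% c("G0", "G1")]
  expect_equal(post_z, orig_z)

  # single-mixture program passes through unchanged
  toy1 <- toy_gcode("single")
  p1 <- parse_gcode(toy1$text)
  t1 <- plan_purge_towers(toy1$plan, toy1$bbox, cfg)
  expect_identical(insert_purge_sequences(p1, t1, toy1$plan, cfg)$commands,
                   p1$commands)
})

test_that("a transition beyond the active tower range is inconsistent", {
  plan <- mixture_plan(list(A = mixing_ratio(0, 0), B = mixing_ratio(50, 0)),
                       layers = list(c("A", "B"), "B"))
  # layer 1 prints A then B; layer 2 heterogeneity is over but mixture flips back
  lines <- c("G21", "G90", "M82", "G92 E0",
             "G1 Z0.2", ";REGION:A", "G0 X0 Y0", "G1 X5 E0.2",
             ";REGION:B", "G0 X10 Y0", "G1 X15 E0.4",
             "G1 Z0.4", ";REGION:A", "G0 X0 Y0", "G1 X5 E0.6")
  prog <- parse_gcode(lines)
  plan1 <- mixture_plan(plan$mixtures, layers = list(c("A", "B"), "A"))
  towers <- plan_purge_towers(plan1, c(0, 0, 20, 10))
  expect_equal(towers[[1]]$active_layers[2], 1L)
  expect_error(insert_purge_sequences(prog, towers, plan1),
               "planning consistency", class = "pf_usage_error")
})

test_that("travel rectilinearization splits diagonals and keeps endpoints", {
  prog <- parse_gcode(c("G21", "G90", "M82", "G92 E0", ";REGION:A",
                        "G0 X10 Y7", "G1 X20 E1", "G0 X5 Y30", "G0 X5 Y35"))
  out <- rectilinearize_travels(prog)
  df <- out$commands[out$commands$code %in% c("G0", "G1"), ]
  # first diagonal -> x-first pair
  expect_equal(df$px[1:2], c(10, 10))
  expect_equal(df$py[1:2], c(0, 7))
  # extruding move untouched
  expect_equal(df$de[3], 1)
  # axis-aligned travel unchanged (no extra rows for it)
  expect_equal(nrow(df), 4 + 2) # 4 moves, 2 diagonals split into +2 rows
  # endpoints of the whole program unchanged
  expect_equal(c(tail(df$px, 1), tail(df$py, 1)), c(5, 35))
})

test_that("mixture command injection is idempotent and checks the plan", {
  toy <- toy_gcode("stripes", layers = 1, n_blocks = 4)
  prog <- parse_gcode(toy$text)
  inj <- inject_mixing_commands(prog, toy$plan)
  # A B A B -> four mixture sets, weights normalized to 1
  sets <- inj$commands[grepl("^M163 S0", inj$commands$code), ]
  expect_equal(nrow(sets), 4)
  w0 <- as.numeric(sub(".*P", "", sets$code))
  expect_true(all(w0 %in% c(1, 0))) # pure gray / pure white fixtures
  # consecutive same-mixture blocks set once
  toy2 <- toy_gcode("stripes", layers = 1,
                    mixtures = list(A = mixing_ratio(20, 30)), n_blocks = 3)
  inj2 <- inject_mixing_commands(parse_gcode(toy2$text), toy2$plan)
  expect_equal(sum(grepl("^M164", inj2$commands$code)), 1)
  w <- as.numeric(sub(".*P", "", inj2$commands$code[grepl("^M163", inj2$commands$code)]))
  expect_equal(sum(w), 1)
  # missing label errors by name
  bad_plan <- mixture_plan(list(Z = mixing_ratio(1, 1)), layers = list("Z"))
  expect_error(inject_mixing_commands(prog, bad_plan), "`A`")
})

test_that("usage accounting splits filament across channels", {
  toy <- toy_gcode("single", layers = 2,
                   mixtures = list(A = mixing_ratio(100, 0)))
  prog <- parse_gcode(toy$text)
  use <- estimate_usage(prog, toy$plan)
  expect_equal(unname(use$length_mm["gray"]), toy$extrusion_total_mm)
  expect_equal(unname(use$length_mm["white"]), 0)
  # mass: length x cross-section x density
  area_cm2 <- pi * (1.75 / 20)^2
  expect_equal(use$total_mass_g, toy$extrusion_total_mm / 10 * area_cm2 * 1.24)
  # channel totals always sum to total extrusion
  toy2 <- toy_gcode("checkerboard", layers = 2,
                    mixtures = list(A = mixing_ratio(30, 20), B = mixing_ratio(5, 80)))
  use2 <- estimate_usage(parse_gcode(toy2$text), toy2$plan)
  expect_equal(use2$total_length_mm, toy2$extrusion_total_mm)
})
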
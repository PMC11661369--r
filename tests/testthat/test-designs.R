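# Parametric phantom designs, mixture resolution and mesh export.

test_that("titration ruler stacks four labeled segments", {
  ratios <- lapply(c(0, 6, 12, 18), function(g) mixing_ratio(g, 12))
  ruler <- design_titration_ruler(ratios, name = "ruler-1")
  expect_length(ruler$regions, 4)
  expect_equal(names(ruler$regions), paste0("ruler-1", LETTERS[1:4]))
  expect_equal(prod(ruler$size) / 1000, 18) # 18 cm^3
  plan <- resolve_mixtures(ruler)
  expect_length(unique(vapply(plan$mixtures, paste, character(1), collapse = "/")), 4)
  expect_error(design_titration_ruler(ratios[1:3]), "exactly 4")
})

test_that("benchmarks carry the stated mixtures and footprints", {
  b <- design_benchmarks()
  # #1: three segments along one axis, gray -> half -> white
  expect_equal(b$benchmark1$size[1:2], c(45, 15))
  expect_equal(unname(unclass(b$benchmark1$regions$seg1$ratio)), c(100, 0, 0))
  expect_equal(unname(unclass(b$benchmark1$regions$seg2$ratio)), c(50, 50, 0))
  expect_equal(unname(unclass(b$benchmark1$regions$seg3$ratio)), c(0, 100, 0))
  # #2: frame/inclusion mixtures inverted between the two frames
  expect_equal(unclass(b$benchmark2$regions$frame1$ratio),
               unclass(b$benchmark2$regions$inc2$ratio))
  expect_equal(unclass(b$benchmark2$regions$frame2$ratio),
               unclass(b$benchmark2$regions$inc1$ratio))
  # #3: nine unique mixtures
  keys <- vapply(b$benchmark3$regions, function(r) paste(r$ratio, collapse = "/"),
                 character(1))
  expect_length(unique(keys), 9)
})

test_that("QA phantom carries the published dimensions and contrasts", {
  qa <- design_qa_phantom()
  incl <- design_regions(qa, "inclusion")
  expect_length(incl, 8) # 4 disks + 4 bars
  expect_true(all(vapply(incl, function(r)
    isTRUE(all.equal(r$zrange, c(0, 1))), logical(1)))) # 1 mm at the bottom
  expect_equal(incl$C4$target$mua, 25 * 0.019)
  expect_equal(incl$C1$target$musp, 3 * 0.83)
  expect_equal(2 * c(incl$C1$radius, incl$C2$radius, incl$C3$radius), c(15, 10, 5))
  expect_equal(incl$B1$size[1:2], c(5, 20))
  # resolves to exactly 5 distinct integer mixtures under the reference model
  plan <- resolve_mixtures(qa, ref_model())
  keys <- vapply(plan$mixtures, paste, character(1), collapse = "/")
  expect_length(unique(keys), 5)
  expect_length(attr(plan, "infeasible"), 0)
})

test_that("DOT phantom has 16 inclusions over 8 property sets", {
  dot <- design_dot_phantom()
  incl <- design_regions(dot, "inclusion")
  expect_length(incl, 16)
  sets <- unique(vapply(dot$regions, function(r)
    paste(r$target$mua, r$target$musp), character(1)))
  expect_length(sets, 8)
  # largest cylinders stop short of the top surface
  expect_equal(diff(incl$C1$zrange), 13) # 2 mm below the 15 mm surface
  expect_equal(diff(incl$C2$zrange), 14)
  full <- setdiff(names(incl), c("C1", "C2"))
  expect_true(all(vapply(incl[full], function(r)
    isTRUE(all.equal(r$zrange, c(0, 15))), logical(1))))
  expect_length(attr(resolve_mixtures(dot, ref_model()), "infeasible"), 0)
})

test_that("mixture resolution deduplicates targets and reports infeasibility", {
  m <- ref_model()
  qa <- design_qa_phantom()
  plan <- resolve_mixtures(qa, m)
  # identical targets map to identical ratios
  expect_identical(plan$mixtures$C1, plan$mixtures$C2)
  expect_identical(plan$mixtures$B3, plan$mixtures$B4)
  # a background pushing inclusions past the model maximum is flagged
  bad <- design_qa_phantom(background = optical_properties(0.1, 0.83))
  expect_error(resolve_mixtures(bad, m), class = "pf_infeasible_error")
  rep <- resolve_mixtures(bad, m, on_infeasible = "report")
  expect_gt(length(attr(rep, "infeasible")), 0)
})

test_that("exported meshes are watertight with exact volumes", {
  qa <- design_qa_phantom()
  ex <- export_meshes(qa)
  expect_length(ex$meshes, 9)
  expect_true(all(vapply(ex$meshes, mesh_is_watertight, logical(1))))
  # background volume = slab minus inclusions (true circular volumes, 0.5%)
  vol <- mesh_volume(ex$meshes$background)
  true_vol <- 90 * 90 * 5 - (pi * (7.5^2 + 5^2 + 2.5^2 + 2.5^2) * 1 + 4 * 5 * 20 * 1)
  expect_lt(abs(vol / true_vol - 1), 0.005)
  # inclusion meshes match their analytic volumes
  expect_equal(mesh_volume(ex$meshes$B1), 100, tolerance = 1e-9)
  # manifest covers every region
  expect_length(ex$manifest, length(qa$regions))
  # geometry conservation across all regions
  total <- sum(vapply(ex$meshes, mesh_volume, numeric(1)))
  expect_lt(abs(total / (90 * 90 * 5) - 1), 0.005)
})

test_that("mesh export writes STL files and is deterministic", {
  dir <- withr::local_tempdir()
  ms <- design_mouse_standin()
  ex1 <- export_meshes(ms, dir = file.path(dir, "a"))
  ex2 <- export_meshes(ms, dir = file.path(dir, "b"))
  expect_identical(ex1$meshes, ex2$meshes)
  stl <- file.path(dir, "a", "soft.stl")
  expect_true(file.exists(stl))
  expect_identical(readLines(stl), readLines(file.path(dir, "b", "soft.stl")))
  expect_true(file.exists(file.path(dir, "a", "manifest.json")))
  # interior cavities (inclusions not touching a face) also close up
  expect_true(mesh_is_watertight(ex1$meshes$soft))
  expect_equal(mesh_volume(ex1$meshes$soft),
               30 * 30 * 60 - 12 * 12 * 20 - 10 * 10 * 15, tolerance = 1e-9)
})

test_that("through-hole frames (benchmark #2) export correctly", {
  b2 <- design_benchmarks()$benchmark2
  ex <- export_meshes(b2)
  expect_true(all(vapply(ex$meshes, mesh_is_watertight, logical(1))))
  expect_equal(mesh_volume(ex$meshes$frame1), 30 * 30 * 5 - 15 * 15 * 5,
               tolerance = 1e-9)
})
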
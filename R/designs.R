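# Parametric phantom geometry generators: titration rulers, the three
# filament-mixing benchmarks, the DOI quality-assurance slab, the DOT slab,
# and a three-mixture stand-in for complex anatomy prints.  Every dimension
# that is part of the published design (slab sizes, inclusion diameters, bar
# sizes, thicknesses, depths) is hard-coded; layout coordinates that are only
# shown graphically live in one editable place per design.

pf_region <- function(label, role, shape, origin = NULL, size = NULL,
                      center = NULL, radius = NULL, zrange, target = NULL,
                      ratio = NULL, parent = NA_character_) {
  structure(list(label = label, role = role, shape = shape, origin = origin,
                 size = size, center = center, radius = radius,
                 zrange = zrange, target = target, ratio = ratio,
                 parent = parent),
            class = "pf_region")
}

phantom_design <- function(name, size, regions) {
  labs <- vapply(regions, `[[`, character(1), "label")
  if (anyDuplicated(labs)) pf_usage_error("region labels must be unique")
  names(regions) <- labs
  structure(list(name = name, size = size, regions = regions),
            class = "phantom_design")
}

#' @export
print.phantom_design <- function(x, ...) {
  cat(sprintf("<phantom_design> %s: %g x %g x %g mm, %d regions (%d inclusions)\n",
              x$name, x$size[1], x$size[2], x$size[3], length(x$regions),
              sum(vapply(x$regions, function(r) r$role == "inclusion", logical(1)))))
  invisible(x)
}

#' Regions of a design by role
#' @param design A \code{phantom_design}.
#' @param role Role to filter by (\code{"inclusion"}, \code{"background"}, ...).
#' @return Named list of regions.
#' @export
design_regions <- function(design, role = NULL) {
  if (is.null(role)) return(design$regions)
  Filter(function(r) r$role == role, design$regions)
}

region_footprint <- function(region) {
  if (region$shape == "cylinder") circle_poly(region$center, region$radius)
  else rect_poly(region$origin[1], region$origin[2],
                 region$origin[1] + region$size[1],
                 region$origin[2] + region$size[2])
}

region_volume <- function(region) {
  h <- region$zrange[2] - region$zrange[1]
  if (region$shape == "cylinder") poly_area(region_footprint(region)) * h
  else region$size[1] * region$size[2] * h
}

#' Titration ruler: four stacked calibration segments
#'
#' Groups four cubic titration prints into one 1.5 x 2 x 6 cm ruler printed
#' vertically, each 1.5 x 2 x 1.5 cm segment at its own mixing ratio.
#'
#' @param segment_ratios List of exactly 4 \code{\link{mixing_ratio}}s,
#'   bottom to top (segments A-D).
#' @param name Design name (used for labels, e.g. \code{"ruler-1"}).
#' @return A \code{phantom_design} of 4 segment regions.
#' @export
design_titration_ruler <- function(segment_ratios, name = "ruler-1") {
  if (length(segment_ratios) != 4L)
    pf_usage_error("a titration ruler has exactly 4 segments")
  segs <- lapply(seq_len(4), function(i) {
    r <- segment_ratios[[i]]
    if (!inherits(r, "mixing_ratio")) pf_usage_error("segment ratios must be mixing_ratio objects")
    pf_region(label = paste0(name, LETTERS[i]), role = "segment", shape = "box",
              origin = c(0, 0, (i - 1) * 15), size = c(15, 20, 15),
              zrange = c((i - 1) * 15, i * 15), ratio = r)
  })
  phantom_design(name, size = c(15, 20, 60), regions = segs)
}

#' The three filament-mixing benchmark models
#'
#' Benchmark #1: three 1.5 x 1.5 x 0.5 cm solid segments in a row at
#' (100/G,0/W,0/T), (50/G,50/W,0/T), (0/G,100/W,0/T) — mixing along one axis.
#' Benchmark #2: two adjacent 3 x 3 x 0.5 cm square frames, each with a
#' concentric 1.5 x 1.5 x 0.5 cm square inclusion, frame/inclusion mixtures
#' (100/G,0/W,0/T) vs (0/G,100/W,0/T) inverted between the two frames —
#' embedded structures.  Benchmark #3: a 3 x 3 palette of 1.5 x 1.5 x 0.5 cm
#' tiles, each a unique mixture — 2-D heterogeneity.
#'
#' @return A named list of three \code{phantom_design}s.
#' @export
design_benchmarks <- function() {
  gray <- mixing_ratio(100, 0); white <- mixing_ratio(0, 100)
  half <- mixing_ratio(50, 50)
  b1 <- phantom_design("benchmark-1", c(45, 15, 5), lapply(1:3, function(i)
    pf_region(paste0("seg", i), "segment", "box",
              origin = c((i - 1) * 15, 0, 0), size = c(15, 15, 5),
              zrange = c(0, 5), ratio = list(gray, half, white)[[i]])))
  b2 <- phantom_design("benchmark-2", c(60, 30, 5), list(
    pf_region("frame1", "frame", "box", origin = c(0, 0, 0), size = c(30, 30, 5),
              zrange = c(0, 5), ratio = gray),
    pf_region("inc1", "inclusion", "box", origin = c(7.5, 7.5, 0),
              size = c(15, 15, 5), zrange = c(0, 5), ratio = white,
              parent = "frame1"),
    pf_region("frame2", "frame", "box", origin = c(30, 0, 0), size = c(30, 30, 5),
              zrange = c(0, 5), ratio = white),
    pf_region("inc2", "inclusion", "box", origin = c(37.5, 7.5, 0),
              size = c(15, 15, 5), zrange = c(0, 5), ratio = gray,
              parent = "frame2")))
  # nine distinct palette mixtures (the published palette is graphical only)
  pal <- list(mixing_ratio(0, 0), mixing_ratio(0, 50), mixing_ratio(0, 100),
              mixing_ratio(25, 25), mixing_ratio(50, 50), mixing_ratio(50, 0),
              mixing_ratio(100, 0), mixing_ratio(75, 0), mixing_ratio(0, 75))
  b3 <- phantom_design("benchmark-3", c(45, 45, 5), lapply(1:9, function(i) {
    rw <- (i - 1) %/% 3; cl <- (i - 1) %% 3
    pf_region(paste0("tile", i), "segment", "box",
              origin = c(cl * 15, rw * 15, 0), size = c(15, 15, 5),
              zrange = c(0, 5), ratio = pal[[i]])
  }))
  list(benchmark1 = b1, benchmark2 = b2, benchmark3 = b3)
}

#' DOI quality-assurance phantom
#'
#' A 9 x 9 x 0.5 cm slab with 4 cylindrical and 4 bar inclusions, all 1 mm
#' thick at the bottom face.  Background targets mua0 = 0.019, musp0 = 0.83
#' 1/mm (skull/scalp-like at 630 nm).  Disks C1-C3 (diameters 15/10/5 mm)
#' share 15 x mua0 and 3 x musp0; disk C4 (5 mm) is 25 x mua0, 3 x musp0;
#' two bar pairs (5 x 20 mm) share 2 x musp0 with 6 x mua0 and 12 x mua0
#' absorption.  Five distinct property sets in total (background + 4).
#'
#' @param background Background \code{\link{optical_properties}}.
#' @param layout Named list of layout coordinates (mm), editable; the
#'   inclusion dimensions themselves are fixed by the design.
#' @return A \code{phantom_design}.
#' @export
design_qa_phantom <- function(background = optical_properties(0.019, 0.83),
                              layout = list(
                                disk_row_y = 70,
                                disk_x = c(20, 45, 65),
                                c4_center = c(75, 20),
                                bar_y = 25,
                                bar_x = c(15, 25, 40, 50))) {
  mua0 <- background$mua; musp0 <- background$musp
  hi <- optical_properties(15 * mua0, 3 * musp0)
  c4p <- optical_properties(25 * mua0, 3 * musp0)
  bar6 <- optical_properties(6 * mua0, 2 * musp0)
  bar12 <- optical_properties(12 * mua0, 2 * musp0)
  zr <- c(0, 1) # 1 mm thick at the bottom face
  diam <- c(15, 10, 5)
  disks <- lapply(1:3, function(i)
    pf_region(paste0("C", i), "inclusion", "cylinder",
              center = c(layout$disk_x[i], layout$disk_row_y),
              radius = diam[i] / 2, zrange = zr, target = hi,
              parent = "background"))
  c4 <- pf_region("C4", "inclusion", "cylinder", center = layout$c4_center,
                  radius = 2.5, zrange = zr, target = c4p, parent = "background")
  bars <- lapply(1:4, function(i)
    pf_region(paste0("B", i), "inclusion", "box",
              origin = c(layout$bar_x[i] - 2.5, layout$bar_y - 10, 0),
              size = c(5, 20, 1), zrange = zr,
              target = if (i <= 2) bar6 else bar12, parent = "background"))
  bg <- pf_region("background", "background", "box", origin = c(0, 0, 0),
                  size = c(90, 90, 5), zrange = c(0, 5), target = background)
  phantom_design("qa-phantom", c(90, 90, 5), c(list(bg), disks, list(c4), bars))
}

#' Complex heterogeneous DOT phantom
#'
#' A 10 x 5 x 1.5 cm slab with 16 inclusions sharing 8 distinct target
#' optical-property sets over the whole model (background included).  All
#' inclusions span the full 15 mm thickness except the largest cylinder
#' (extends 13 mm, end-face 2 mm below the surface) and the second largest
#' (14 mm, 1 mm below).
#'
#' @param background Background \code{\link{optical_properties}}.
#' @return A \code{phantom_design} with 16 inclusion regions.
#' @export
design_dot_phantom <- function(background = optical_properties(0.019, 0.83)) {
  sets <- list(
    s1 = optical_properties(0.114, 1.66),
    s2 = optical_properties(0.228, 1.66),
    s3 = optical_properties(0.285, 2.49),
    s4 = optical_properties(0.475, 2.49),
    s5 = optical_properties(0.057, 1.25),
    s6 = optical_properties(0.038, 1.00),
    s7 = optical_properties(0.171, 2.00))
  cyl <- function(lab, cx, r, z1, tg)
    pf_region(lab, "inclusion", "cylinder", center = c(cx, 32), radius = r,
              zrange = c(0, z1), target = tg, parent = "background")
  cyls <- list(cyl("C1", 20, 10, 13, sets$s3),   # end-face 2 mm below surface
               cyl("C2", 45, 7.5, 14, sets$s3),  # end-face 1 mm below surface
               cyl("C3", 65, 4, 15, sets$s4),
               cyl("C4", 80, 2.5, 15, sets$s4))
  bar <- function(lab, cx, cy, tg)
    pf_region(lab, "inclusion", "box", origin = c(cx - 2.5, cy - 3, 0),
              size = c(5, 6, 15), zrange = c(0, 15), target = tg,
              parent = "background")
  bx <- c(10, 25, 40, 55, 70, 85)
  rowA <- lapply(1:6, function(i)
    bar(paste0("A", i), bx[i], 10, list(sets$s1, sets$s1, sets$s2,
                                        sets$s2, sets$s5, sets$s5)[[i]]))
  rowB <- lapply(1:6, function(i)
    bar(paste0("B", i), bx[i], 46, list(sets$s6, sets$s6, sets$s6,
                                        sets$s7, sets$s7, sets$s7)[[i]]))
  bg <- pf_region("background", "background", "box", origin = c(0, 0, 0),
                  size = c(100, 50, 15), zrange = c(0, 15), target = background)
  phantom_design("dot-phantom", c(100, 50, 15), c(list(bg), cyls, rowA, rowB))
}

#' Three-mixture stand-in for complex anatomical prints
#'
#' A tall slab with a lower inclusion (lung-like mixture) and an upper
#' inclusion (brain-like mixture) in a soft-tissue background — the purge
#' planning scenario of a three-tissue anatomical print (three towers on
#' every slice up to the last heterogeneous one, even where only two mixtures
#' print).  Mixtures are given explicitly: soft tissue (0/G, 5/W, 95/T),
#' lung (4/G, 11/W, 85/T), brain (26/G, 40/W, 34/T).
#'
#' @return A \code{phantom_design}.
#' @export
design_mouse_standin <- function() {
  bg <- pf_region("soft", "background", "box", origin = c(0, 0, 0),
                  size = c(30, 30, 60), zrange = c(0, 60),
                  ratio = mixing_ratio(0, 5))
  lung <- pf_region("lung", "inclusion", "box", origin = c(4, 4, 5),
                    size = c(12, 12, 20), zrange = c(5, 25),
                    ratio = mixing_ratio(4, 11), parent = "soft")
  brain <- pf_region("brain", "inclusion", "box", origin = c(18, 18, 35),
                     size = c(10, 10, 15), zrange = c(35, 50),
                     ratio = mixing_ratio(26, 40), parent = "soft")
  phantom_design("mouse-standin", c(30, 30, 60), list(bg, lung, brain))
}

#' Model bounding box of a design
#' @param design A \code{phantom_design}.
#' @return \code{c(xmin, ymin, xmax, ymax)} in mm.
#' @export
design_bbox <- function(design) c(0, 0, design$size[1], design$size[2])

#' Resolve region targets into a mixture plan
#'
#' Maps each region to an integer \code{\link{mixing_ratio}}: explicit ratios
#' are kept, target optical properties are inverted through the mixing model
#' (\code{\link{invert_mixture}}); identical targets resolve to identical
#' ratios.  Regions whose targets are infeasible (relative error above the
#' threshold at the continuous optimum) are collected and raised as an
#' infeasibility error naming them, unless \code{on_infeasible = "report"}.
#'
#' @param design A \code{phantom_design}.
#' @param model A fully fitted \code{mixing_model} (required when any region
#'   carries a target instead of an explicit ratio).
#' @param feasibility_tol Passed to \code{\link{invert_mixture}}.
#' @param layer_thickness Layer thickness used for the per-layer presence
#'   table, mm.
#' @param on_infeasible \code{"error"} (default) or \code{"report"}.
#' @return A \code{\link{mixture_plan}} with an \code{infeasible} attribute
#'   (character vector of region labels, empty when all resolve).
#' @export
resolve_mixtures <- function(design, model = NULL, feasibility_tol = 0.05,
                             layer_thickness = 0.2,
                             on_infeasible = c("error", "report")) {
  on_infeasible <- match.arg(on_infeasible)
  cache <- list()
  infeasible <- character(0)
  mixtures <- lapply(design$regions, function(r) {
    if (!is.null(r$ratio)) return(r$ratio)
    if (is.null(model))
      pf_usage_error(sprintf("region `%s` has a target but no mixing model was supplied", r$label))
    key <- sprintf("%.12g/%.12g", r$target$mua, r$target$musp)
    if (!is.null(cache[[key]])) return(cache[[key]])
    inv <- invert_mixture(model, r$target, rounding = "integer",
                          feasibility_tol = feasibility_tol)
    if (!inv$feasible) infeasible <<- c(infeasible, r$label)
    cache[[key]] <<- inv$ratio
    inv$ratio
  })
  if (length(infeasible) > 0 && on_infeasible == "error")
    pf_infeasible_error(sprintf("infeasible target(s) for region(s): %s",
                                paste(infeasible, collapse = ", ")),
                        data = infeasible)
  H <- design$size[3]
  nl <- max(1L, as.integer(round(H / layer_thickness)))
  layers <- lapply(seq_len(nl), function(l) {
    zlo <- (l - 1) * layer_thickness; zhi <- l * layer_thickness
    labs <- vapply(design$regions, function(r)
      r$zrange[1] < zhi - 1e-9 && r$zrange[2] > zlo + 1e-9, logical(1))
    names(design$regions)[labs]
  })
  plan <- mixture_plan(mixtures, layers)
  attr(plan, "infeasible") <- infeasible
  plan
}

#' Export a design as watertight surface meshes plus a manifest
#'
#' The background (or frame) mesh has all child inclusion volumes subtracted;
#' each inclusion becomes its own closed mesh.  Meshes are written as ASCII
#' STL in millimeters, z-up; the manifest (JSON) links every mesh file to its
#' region, shape, analytic volume and target/ratio.
#'
#' @param design A \code{phantom_design}.
#' @param dir Output directory (created if missing).  \code{NULL} skips
#'   writing and just returns the meshes.
#' @param plan Optional resolved \code{\link{mixture_plan}} to embed mixture
#'   ratios in the manifest.
#' @return Invisibly, a list with \code{meshes} (named \code{pf_mesh} list),
#'   \code{manifest} and \code{files}.
#' @export
export_meshes <- function(design, dir = NULL, plan = NULL) {
  regions <- design$regions
  meshes <- list()
  for (r in regions) {
    if (r$role %in% c("background", "frame")) {
      children <- Filter(function(q) identical(q$parent, r$label), regions)
      cavities <- lapply(children, function(q) {
        poly <- region_footprint(q)
        poly[, 1] <- poly[, 1] - r$origin[1]
        poly[, 2] <- poly[, 2] - r$origin[2]
        list(poly = poly, z0 = q$zrange[1] - r$zrange[1],
             z1 = q$zrange[2] - r$zrange[1])
      })
      m <- mesh_slab_with_cavities(r$size[1], r$size[2], r$size[3],
                                   unname(cavities))
      m$vertices <- sweep(m$vertices, 2, c(r$origin[1], r$origin[2], r$zrange[1]), "+")
    } else {
      m <- if (r$shape == "cylinder")
        mesh_prism(region_footprint(r), r$zrange[1], r$zrange[2])
      else mesh_box(c(r$origin[1], r$origin[2], r$zrange[1]),
                    c(r$size[1], r$size[2], r$zrange[2] - r$zrange[1]))
    }
    if (!mesh_is_watertight(m))
      pf_error(sprintf("mesh for region `%s` is not watertight", r$label), "pf_error")
    meshes[[r$label]] <- m
  }
  manifest <- lapply(regions, function(r) {
    child_vol <- sum(vapply(Filter(function(q) identical(q$parent, r$label), regions),
                            region_volume, numeric(1)))
    entry <- list(label = r$label, role = r$role, shape = r$shape,
                  file = paste0(r$label, ".stl"),
                  volume_mm3 = region_volume(r) - child_vol)
    if (!is.null(r$target))
      entry$target <- list(mua = r$target$mua, musp = r$target$musp)
    if (!is.null(r$ratio)) entry$ratio <- as.numeric(r$ratio)
    if (!is.null(plan) && !is.null(plan$mixtures[[r$label]]))
      entry$resolved_ratio <- as.numeric(plan$mixtures[[r$label]])
    entry
  })
  files <- character(0)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (lab in names(meshes)) {
      f <- file.path(dir, paste0(lab, ".stl"))
      write_stl(meshes[[lab]], f, name = lab)
      files <- c(files, f)
    }
    mf <- file.path(dir, "manifest.json")
    jsonlite::write_json(list(design = design$name,
                              size_mm = as.numeric(design$size),
                              regions = unname(manifest)),
                         mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, mf)
  }
  invisible(list(meshes = meshes, manifest = manifest, files = files))
}
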
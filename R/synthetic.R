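# Seeded synthetic data generators: titration tables, SFDI frame sets with
# known ground truth, and toy multi-region G-code.  Everything the test suite
# consumes is produced here — no external data.

#' Synthetic-data configuration
#'
#' @param seed Integer seed (all generators are deterministic given it).
#' @param noise \code{list(type = "none" | "multiplicative" | "additive" |
#'   "shot", sigma = ..., scale = ...)}.  Multiplicative/additive Gaussian
#'   sigma is a fraction / an absolute value; shot noise draws Poisson counts
#'   at \code{value * scale}.
#' @param dim Image dimensions \code{c(rows, cols)} for frame synthesis.
#' @param pixel_pitch Pixel pitch, mm (default sqrt(0.035), the reference
#'   camera's per-pixel area).
#' @param fx Spatial frequencies, 1/mm.
#' @param phases Phase offsets, radians.
#' @param gain Illumination gain (peak counts scale).
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(seed = 1L, noise = list(type = "none"),
                         dim = c(96, 96), pixel_pitch = sqrt(0.035),
                         fx = c(0, 0.1), phases = c(0, 2 * pi / 3, 4 * pi / 3),
                         gain = 30000) {
  if (is.null(noise$type)) noise$type <- "none"
  noise$type <- match.arg(noise$type, c("none", "multiplicative", "additive", "shot"))
  if (!is.null(noise$sigma) && noise$sigma < 0) pf_usage_error("noise sigma must be >= 0")
  if (any(dim < 1)) pf_usage_error("image dimensions must be >= 1")
  structure(list(seed = seed, noise = noise, dim = dim,
                 pixel_pitch = pixel_pitch, fx = fx, phases = phases,
                 gain = gain),
            class = "synth_config")
}

apply_noise <- function(x, noise) {
  switch(noise$type,
         none = x,
         multiplicative = x * (1 + rnorm(length(x), 0, noise$sigma)),
         additive = x + rnorm(length(x), 0, noise$sigma),
         shot = rpois(length(x), pmax(x, 0) * noise$scale) / noise$scale)
}

#' Default titration mixing-ratio design
#'
#' Sixteen (Rg, Rw) combinations — four rulers of four segments — spanning
#' the low-pigment corner of the simplex where the characterized filament
#' set produces tissue-typical properties.
#'
#' @return Data frame with columns \code{label}, \code{Rg}, \code{Rw},
#'   \code{Rt}.
#' @export
default_titration_ratios <- function() {
  g <- expand.grid(Rg = c(0, 6, 12, 18), Rw = c(0, 12, 24, 36))
  ruler <- rep(1:4, each = 4)
  seg <- rep(LETTERS[1:4], times = 4)
  data.frame(label = paste0(ruler, seg), Rg = g$Rg, Rw = g$Rw,
             Rt = 100 - g$Rg - g$Rw, stringsAsFactors = FALSE)
}

#' Synthesize a titration measurement table
#'
#' Measured properties are the linear-mixing forward values of a true model,
#' perturbed by the configured noise.  The dispersion columns carry the
#' noise scale actually applied (zero for noiseless data).
#'
#' @param true_model A fully fitted / constructed \code{mixing_model}.
#' @param ratios Data frame with \code{Rg}, \code{Rw} (and optionally
#'   \code{label}); default \code{\link{default_titration_ratios}}.
#' @param config A \code{\link{synth_config}}; its noise model applies to
#'   both properties independently.
#' @return A titration table: \code{label, Rg, Rw, Rt, mua, musp, mua_sd,
#'   musp_sd} (1/mm).
#' @export
synth_titration <- function(true_model, ratios = default_titration_ratios(),
                            config = synth_config()) {
  assert_full_model(true_model)
  set.seed(config$seed)
  n <- nrow(ratios)
  lab <- if ("label" %in% names(ratios)) ratios$label else sprintf("S%02d", seq_len(n))
  mua <- true_model$mua$A * ratios$Rg + true_model$mua$B * ratios$Rw + true_model$mua$C
  musp <- true_model$musp$A * ratios$Rg + true_model$musp$B * ratios$Rw + true_model$musp$C
  mua_n <- apply_noise(mua, config$noise)
  musp_n <- apply_noise(musp, config$noise)
  sd_of <- function(v) switch(config$noise$type,
                              none = rep(0, n),
                              multiplicative = v * config$noise$sigma,
                              additive = rep(config$noise$sigma, n),
                              shot = sqrt(v / config$noise$scale))
  data.frame(label = lab, Rg = ratios$Rg, Rw = ratios$Rw,
             Rt = 100 - ratios$Rg - ratios$Rw,
             mua = mua_n, musp = musp_n,
             mua_sd = sd_of(mua), musp_sd = sd_of(musp),
             stringsAsFactors = FALSE)
}

forward_rd <- function(props, fx, forward, lut, n_medium) {
  if (forward == "lut") lut_rd_at(lut, props$mua, props$musp, fx)
  else diffusion_rd(props$mua, props$musp, fx, n = n_medium)
}

#' Synthesize SFDI frame sets with ground truth
#'
#' Builds three-phase frames per spatial frequency for a labeled region map:
#' each pixel's intensity is \code{gain * Rd(fx; region properties) *
#' (1 + cos(2 pi fx x + phase)) / 2} (non-negative illumination convention),
#' plus configured noise.  A homogeneous reference frame set at the stated
#' reference properties is generated with the same gain and convention, so
#' the synthesized data calibrate exactly like a measurement.
#'
#' @param region_map Integer/character matrix of region labels.
#' @param region_props Named list mapping each region label to
#'   \code{\link{optical_properties}}.
#' @param forward \code{"lut"} (default; self-consistent with recovery) or
#'   \code{"diffusion"} (cross-model).
#' @param lut The \code{reflectance_lut} used when \code{forward = "lut"}
#'   and for the reference Rd during later recovery.
#' @param config A \code{\link{synth_config}}.
#' @param reference_properties Known properties of the synthetic reference
#'   phantom.
#' @return List: \code{sample} (\code{frame_set}), \code{reference}
#'   (\code{calibration_reference}), \code{truth} (mua/musp matrices).
#' @export
synth_sfdi_frames <- function(region_map, region_props, forward = c("lut", "diffusion"),
                              lut = NULL, config = synth_config(),
                              reference_properties = optical_properties(0.0064, 1.42)) {
  forward <- match.arg(forward)
  if (forward == "lut" && is.null(lut)) pf_usage_error("forward = 'lut' needs a lut")
  region_map <- as.matrix(region_map)
  labs <- unique(as.character(region_map))
  missing <- setdiff(labs, names(region_props))
  if (length(missing) > 0)
    pf_usage_error(paste("unknown region label(s):", paste(missing, collapse = ", ")))
  set.seed(config$seed)
  n_medium <- if (!is.null(lut)) lut$meta$n else 1.4
  nr <- nrow(region_map); ncl <- ncol(region_map)
  xpos <- matrix(rep((seq_len(ncl) - 1) * config$pixel_pitch, each = nr), nr, ncl)
  truth_mua <- truth_musp <- matrix(NA_real_, nr, ncl)
  rd_map <- setNames(vector("list", length(config$fx)), as.character(config$fx))
  for (f in seq_along(config$fx)) rd_map[[f]] <- matrix(NA_real_, nr, ncl)
  for (lab in labs) {
    sel <- region_map == lab
    p <- region_props[[lab]]
    truth_mua[sel] <- p$mua; truth_musp[sel] <- p$musp
    for (f in seq_along(config$fx))
      rd_map[[f]][sel] <- forward_rd(p, config$fx[f], forward, lut, n_medium)
  }
  make_frames <- function(rd_list) {
    frames <- lapply(seq_along(config$fx), function(f) {
      lapply(config$phases, function(ph) {
        img <- config$gain * rd_list[[f]] *
          (1 + cos(2 * pi * config$fx[f] * xpos + ph)) / 2
        img <- apply_noise(img, config$noise)
        pmax(img, 0)
      })
    })
    frame_set(frames, config$fx, pixel_pitch = config$pixel_pitch)
  }
  sample_fs <- make_frames(rd_map)
  ref_rd <- lapply(seq_along(config$fx), function(f)
    matrix(forward_rd(reference_properties, config$fx[f], forward, lut, n_medium),
           nr, ncl))
  reference <- calibration_reference(make_frames(ref_rd), reference_properties)
  list(sample = sample_fs, reference = reference,
       truth = list(mua = truth_mua, musp = truth_musp))
}

#' QA-phantom-layout region map
#'
#' A coarse raster of the QA slab's inclusion layout (background plus disk
#' and bar footprints) for end-to-end SFDI simulations.
#'
#' @param design A QA \code{phantom_design} (default
#'   \code{\link{design_qa_phantom}()}).
#' @param pixel_pitch Raster pitch, mm/pixel.
#' @return Character matrix of region labels.
#' @export
region_map_from_design <- function(design = design_qa_phantom(), pixel_pitch = 1) {
  L <- design$size[1]; W <- design$size[2]
  nx <- ceiling(L / pixel_pitch); ny <- ceiling(W / pixel_pitch)
  xs <- (seq_len(nx) - 0.5) * pixel_pitch
  ys <- (seq_len(ny) - 0.5) * pixel_pitch
  bg <- names(Filter(function(r) r$role == "background", design$regions))[1]
  m <- matrix(bg, ny, nx)
  for (r in design$regions) {
    if (r$role != "inclusion") next
    if (r$shape == "cylinder") {
      for (j in seq_len(nx)) for (i in seq_len(ny))
        if ((xs[j] - r$center[1])^2 + (ys[i] - r$center[2])^2 <= r$radius^2)
          m[i, j] <- r$label
    } else {
      jj <- which(xs >= r$origin[1] & xs <= r$origin[1] + r$size[1])
      ii <- which(ys >= r$origin[2] & ys <= r$origin[2] + r$size[2])
      m[ii, jj] <- r$label
    }
  }
  m
}

#' Generate a toy multi-region G-code program
#'
#' Minimal absolute-mode program with \code{;REGION:} markers, known
#' per-layer transition counts and exact extrusion totals, for exercising
#' the post-processing pipeline.  \code{"stripes"} lays \code{n_blocks}
#' adjacent blocks per layer cycling through the mixtures left to right;
#' \code{"checkerboard"} rasters an n x n tile grid in serpentine order with
#' alternating mixtures; \code{"single"} prints one region.
#'
#' @param pattern \code{"single"}, \code{"stripes"} or \code{"checkerboard"}.
#' @param layers Number of layers.
#' @param mixtures Named list of \code{\link{mixing_ratio}}s (>= 1).
#' @param n_blocks Blocks per layer (stripes) or grid side (checkerboard).
#' @param block_size Block edge length, mm.
#' @param layer_thickness Layer thickness, mm.
#' @param flow Extrusion mm of filament per mm of path.
#' @return List: \code{text} (G-code lines), \code{plan}
#'   (\code{\link{mixture_plan}}), \code{transitions_per_layer},
#'   \code{extrusion_total_mm}, \code{bbox}.
#' @export
toy_gcode <- function(pattern = c("stripes", "checkerboard", "single"),
                      layers = 2, mixtures = list(A = mixing_ratio(100, 0),
                                                  B = mixing_ratio(0, 100)),
                      n_blocks = NULL, block_size = 10, layer_thickness = 0.2,
                      flow = 0.05) {
  pattern <- match.arg(pattern)
  if (length(mixtures) < 1L) pf_usage_error("need at least one mixture")
  labs <- names(mixtures)
  if (pattern == "single") labs <- labs[1]
  if (is.null(n_blocks))
    n_blocks <- if (pattern == "checkerboard") 2L else length(labs)
  # sequence of (label, x-origin, y-origin) per layer
  if (pattern == "single") {
    seq_blocks <- data.frame(label = labs[1], bx = 0, by = 0)
  } else if (pattern == "stripes") {
    seq_blocks <- data.frame(label = rep_len(labs, n_blocks),
                             bx = (seq_len(n_blocks) - 1) * block_size, by = 0)
  } else {
    cells <- expand.grid(cx = seq_len(n_blocks), cy = seq_len(n_blocks))
    # serpentine print order: rows bottom-up, alternating direction
    ord <- order(cells$cy, ifelse(cells$cy %% 2 == 1, cells$cx, -cells$cx))
    cells <- cells[ord, ]
    seq_blocks <- data.frame(
      label = labs[(cells$cx + cells$cy) %% length(labs) + 1L],
      bx = (cells$cx - 1) * block_size, by = (cells$cy - 1) * block_size)
  }
  lines <- c("; phantomforge toy program", "G21", "G90", "M82", "G92 E0")
  e <- 0
  total_len <- 0
  n_pass <- 3L
  for (l in seq_len(layers)) {
    z <- l * layer_thickness
    lines <- c(lines, sprintf("G1 Z%.3f F600", z))
    for (b in seq_len(nrow(seq_blocks))) {
      bl <- seq_blocks[b, ]
      lines <- c(lines, sprintf(";REGION:%s", bl$label),
                 sprintf("G0 X%.3f Y%.3f", bl$bx, bl$by))
      for (p in seq_len(n_pass)) {
        xt <- bl$bx + if (p %% 2 == 1) block_size else 0
        yt <- bl$by + (p - 1) * block_size / (n_pass - 1)
        lines <- c(lines, sprintf("G0 Y%.3f", yt))
        e <- e + block_size * flow
        total_len <- total_len + block_size
        lines <- c(lines, sprintf("G1 X%.3f E%.5f F1320", xt, e))
      }
    }
  }
  key <- vapply(mixtures, mix_key, character(1))
  per_layer_labels <- unique(seq_blocks$label)
  trans <- sum(key[seq_blocks$label][-1] != key[seq_blocks$label][-nrow(seq_blocks)])
  plan <- mixture_plan(mixtures[unique(seq_blocks$label)],
                       layers = rep(list(per_layer_labels), layers))
  bbox <- c(0, 0, max(seq_blocks$bx) + block_size, max(seq_blocks$by) + block_size)
  list(text = lines, plan = plan, transitions_per_layer = trans,
       extrusion_total_mm = e, path_length_mm = total_len, bbox = bbox,
       block_sequence = seq_blocks$label)
}
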
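# Multi-material G-code post-processing: parsing, purge-tower planning and
# insertion, z-hop on tower transitions, axis-restricted travel rewriting,
# mixture command injection and per-channel filament accounting.
#
# Dialect: absolute positioning (G90), millimeter units (G21), absolute
# extrusion (M82, G92 E resets honored).  Region identity comes from
# ";REGION:<label>" comment markers emitted by the design/slicing manifest.

GC_WORD_RE <- "([A-Za-z])([-+]?[0-9]*\\.?[0-9]+)"

gc_words <- function(body) {
  m <- gregexpr(GC_WORD_RE, body)[[1]]
  if (m[1] == -1) return(list())
  toks <- regmatches(body, gregexpr(GC_WORD_RE, body))[[1]]
  vals <- as.numeric(sub(GC_WORD_RE, "\\2", toks))
  names(vals) <- toupper(sub(GC_WORD_RE, "\\1", toks))
  as.list(vals)
}

gc_empty_row <- function() {
  data.frame(raw = NA_character_, code = "", x = NA_real_, y = NA_real_,
             z = NA_real_, e = NA_real_, f = NA_real_, de = 0,
             region = NA_character_, inserted = FALSE, purpose = NA_character_,
             stringsAsFactors = FALSE)
}

GC_CORE_COLS <- c("raw", "code", "x", "y", "z", "e", "f", "de", "region",
                  "inserted", "purpose")

# rbind command-table pieces on the core columns (derived state columns are
# recomputed afterwards)
gc_bind <- function(pieces) {
  pieces <- Filter(function(p) nrow(p) > 0, pieces)
  do.call(rbind, lapply(pieces, function(p) p[, GC_CORE_COLS, drop = FALSE]))
}

gc_row <- function(code, x = NA, y = NA, z = NA, e = NA, f = NA, de = 0,
                   region = NA_character_, inserted = TRUE,
                   purpose = NA_character_, raw = NA_character_) {
  r <- gc_empty_row()
  r$code <- code; r$x <- x; r$y <- y; r$z <- z; r$e <- e; r$f <- f
  r$de <- de; r$region <- region; r$inserted <- inserted; r$purpose <- purpose
  r$raw <- raw
  r
}

# Fill the derived state columns: absolute position after each command,
# extrusion flags and layer index.
gc_recompute <- function(df, layer_thickness) {
  n <- nrow(df)
  px <- py <- pz <- numeric(n)
  cx <- cy <- cz <- 0
  for (i in seq_len(n)) {
    if (df$code[i] %in% c("G0", "G1")) {
      if (!is.na(df$x[i])) cx <- df$x[i]
      if (!is.na(df$y[i])) cy <- df$y[i]
      if (!is.na(df$z[i])) cz <- df$z[i]
    }
    px[i] <- cx; py[i] <- cy; pz[i] <- cz
  }
  df$px <- px; df$py <- py; df$pz <- pz
  df$extruding <- df$de > 1e-12
  df$layer <- pmax(0L, as.integer(round(pz / layer_thickness)))
  df
}

#' Parse a G-code program
#'
#' Parses an absolute-positioning, millimeter-unit G-code text into a command
#' table with derived absolute positions, extrusion deltas, region labels
#' (from \code{;REGION:<label>} markers) and layer indices (from Z at the
#' configured layer thickness).  Unknown commands are preserved verbatim as
#' opaque rows.  A relative-positioning (\code{G91}), inch-unit (\code{G20})
#' or relative-extrusion (\code{M83}) switch raises an unsupported-dialect
#' error naming the offending command.
#'
#' @param text G-code as a single string or character vector of lines.
#' @param layer_thickness Layer thickness in mm used to derive layer indices.
#' @return A \code{gcode_program}.
#' @export
parse_gcode <- function(text, layer_thickness = 0.2) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  rows <- vector("list", length(lines))
  region <- NA_character_
  e_state <- 0
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    body <- sub(";.*$", "", ln)
    comment <- if (grepl(";", ln, fixed = TRUE)) sub("^[^;]*;", "", ln) else NA_character_
    if (!is.na(comment) && grepl("^REGION:", comment))
      region <- sub("^REGION:", "", trimws(comment))
    body <- trimws(body)
    r <- gc_empty_row()
    r$raw <- ln
    r$inserted <- FALSE
    r$region <- region
    if (nzchar(body)) {
      w <- gc_words(body)
      code <- if (length(w)) paste0(names(w)[1], w[[1]]) else ""
      if (code %in% c("G91", "G20", "M83"))
        pf_error(sprintf("unsupported G-code dialect: `%s` (line %d: %s)", code, i, ln),
                 "pf_dialect_error")
      r$code <- code
      if (code %in% c("G0", "G1")) {
        if (!is.null(w$X)) r$x <- w$X
        if (!is.null(w$Y)) r$y <- w$Y
        if (!is.null(w$Z)) r$z <- w$Z
        if (!is.null(w$F)) r$f <- w$F
        if (!is.null(w$E)) {
          r$e <- w$E
          r$de <- w$E - e_state
          e_state <- w$E
        }
      } else if (code == "G92") {
        if (!is.null(w$E)) e_state <- w$E
      }
    }
    rows[[i]] <- r
  }
  df <- do.call(rbind, rows)
  df <- gc_recompute(df, layer_thickness)
  structure(list(commands = df, layer_thickness = layer_thickness,
                 modified = FALSE),
            class = "gcode_program")
}

#' @export
print.gcode_program <- function(x, ...) {
  df <- x$commands
  cat(sprintf("<gcode_program> %d commands, %d layers, extrusion total %.2f mm%s\n",
              nrow(df), n_layers(x), sum(df$de),
              if (x$modified) " (post-processed)" else ""))
  invisible(x)
}

#' Number of layers in a program
#' @param program A \code{gcode_program}.
#' @return Highest layer index reached.
#' @export
n_layers <- function(program) max(program$commands$layer)

#' Serialize a program back to G-code text
#'
#' Motion commands are regenerated from the parsed fields with a running
#' absolute extrusion axis (a \code{G92 E0} is emitted up front); all other
#' lines pass through verbatim.  The emitted program is semantically
#' identical in motion and extrusion to the parsed one.
#'
#' @param program A \code{gcode_program}.
#' @return Character vector of G-code lines.
#' @export
emit_gcode <- function(program) {
  df <- program$commands
  out <- character(0)
  out <- c(out, "G92 E0 ; extrusion axis reset (re-emitted)")
  e <- 0
  fmt <- function(v) formatC(v, format = "f", digits = 5, drop0trailing = TRUE)
  for (i in seq_len(nrow(df))) {
    code <- df$code[i]
    if (code %in% c("G0", "G1")) {
      parts <- code
      if (!is.na(df$x[i])) parts <- c(parts, paste0("X", fmt(df$x[i])))
      if (!is.na(df$y[i])) parts <- c(parts, paste0("Y", fmt(df$y[i])))
      if (!is.na(df$z[i])) parts <- c(parts, paste0("Z", fmt(df$z[i])))
      if (df$de[i] != 0) {
        e <- e + df$de[i]
        parts <- c(parts, paste0("E", fmt(e)))
      }
      if (!is.na(df$f[i])) parts <- c(parts, paste0("F", fmt(df$f[i])))
      out <- c(out, paste(parts, collapse = " "))
    } else if (code == "G92") {
      # folded into the regenerated extrusion axis
    } else if (!is.na(df$raw[i])) {
      out <- c(out, df$raw[i])
    } else {
      out <- c(out, code)
    }
  }
  out
}

mix_key <- function(ratio) paste(round(unclass(ratio), 6), collapse = "/")

#' Mixture plan: region label to mixing ratio, with per-layer presence
#'
#' @param mixtures Named list mapping region label to
#'   \code{\link{mixing_ratio}}.
#' @param layers List, one character vector of present region labels per
#'   layer (layer 1 first).
#' @return A \code{mixture_plan}.
#' @export
mixture_plan <- function(mixtures, layers) {
  if (is.null(names(mixtures)) || anyDuplicated(names(mixtures)))
    pf_usage_error("mixtures must be a uniquely named list of mixing ratios")
  for (m in mixtures) if (!inherits(m, "mixing_ratio"))
    pf_usage_error("every mixture must be a mixing_ratio")
  structure(list(mixtures = mixtures, layers = layers), class = "mixture_plan")
}

plan_unique_keys <- function(plan) unique(vapply(plan$mixtures, mix_key, character(1)))

plan_layer_keys <- function(plan, layer) {
  labs <- plan$layers[[layer]]
  unique(vapply(plan$mixtures[labs], mix_key, character(1)))
}

#' Print and purge configuration
#'
#' Printing defaults follow the characterized mixing-extruder workflow:
#' 0.2 mm layers, 0.3 mm line width, 22 mm/s maximum speed, 110% infill,
#' 205 C extruder temperature, 0.3 mm z-hop on mixture transitions.
#'
#' @param z_hop Nozzle lift during tower transitions, mm.
#' @param rectilinear_travel Restrict travels to x/y axis-aligned segments.
#' @param purge_volume_per_transition Purge volume, mm^3; default reproduces
#'   one full tower layer (footprint x layer thickness x infill ratio).
#' @param layer_thickness,line_width,max_speed,infill_ratio,extruder_temp
#'   Print parameters (mm, mm, mm/s, percent, degrees C).
#' @param filament_diameter Filament diameter, mm.
#' @param tower_size Purge tower footprint c(x, y), mm; towers within
#'   15x15 to 15x35 mm.
#' @param tower_gap Gap between model bounding box and first tower, mm.
#' @param tower_spacing Gap between towers, mm.
#' @param build_area Printable area c(x, y), mm.
#' @return A \code{postprocess_config} list.
#' @export
postprocess_config <- function(z_hop = 0.3, rectilinear_travel = TRUE,
                               purge_volume_per_transition = NULL,
                               layer_thickness = 0.2, line_width = 0.3,
                               max_speed = 22, infill_ratio = 110,
                               extruder_temp = 205, filament_diameter = 1.75,
                               tower_size = c(15, 15), tower_gap = 10,
                               tower_spacing = 5, build_area = c(300, 300)) {
  if (is.null(purge_volume_per_transition))
    purge_volume_per_transition <-
      tower_size[1] * tower_size[2] * layer_thickness * infill_ratio / 100
  cfg <- list(z_hop = z_hop, rectilinear_travel = rectilinear_travel,
              purge_volume_per_transition = purge_volume_per_transition,
              layer_thickness = layer_thickness, line_width = line_width,
              max_speed = max_speed, infill_ratio = infill_ratio,
              extruder_temp = extruder_temp,
              filament_diameter = filament_diameter,
              tower_size = tower_size, tower_gap = tower_gap,
              tower_spacing = tower_spacing, build_area = build_area)
  for (nm in c("z_hop", "purge_volume_per_transition", "layer_thickness",
               "line_width", "max_speed", "infill_ratio", "extruder_temp",
               "filament_diameter"))
    stopifnot_scalar_number(cfg[[nm]], nm, positive = TRUE)
  structure(cfg, class = "postprocess_config")
}

#' Plan purge towers for a multi-mixture print
#'
#' One tower per unique mixture in the contiguous model, placed in a row on
#' the +x side of the model bounding box.  Towers are active from the first
#' layer through the last heterogeneous layer (the last z-slice on which more
#' than one mixture is present); beyond it no purging is required and towers
#' deactivate.  A single-mixture model needs no towers.
#'
#' @param plan A \code{\link{mixture_plan}}.
#' @param model_bbox Numeric \code{c(xmin, ymin, xmax, ymax)} of the model, mm.
#' @param config A \code{\link{postprocess_config}}.
#' @return A \code{purge_towers} list; each element has \code{label} (mixture
#'   key), \code{mixture}, \code{footprint}, \code{anchor} (xy of the tower's
#'   min corner, mm) and \code{active_layers = c(first, last)}.
#' @export
plan_purge_towers <- function(plan, model_bbox, config = postprocess_config()) {
  if (length(plan$mixtures) < 1L) pf_usage_error("plan has no regions")
  keys <- plan_unique_keys(plan)
  if (length(keys) < 2L)
    return(structure(list(), class = "purge_towers"))
  fw <- config$tower_size[1]; fh <- config$tower_size[2]
  if (fw != 15 || fh < 15 || fh > 35)
    warning("tower footprint outside the recommended 15x15 to 15x35 mm range")
  het <- vapply(seq_along(plan$layers), function(l) length(plan_layer_keys(plan, l)) > 1,
                logical(1))
  last_het <- if (any(het)) max(which(het)) else 0L
  towers <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    ax <- model_bbox[3] + config$tower_gap + (i - 1) * (fw + config$tower_spacing)
    ay <- model_bbox[2]
    if (ax + fw > config$build_area[1] || ay + fh > config$build_area[2]) {
      need <- ax + fw - model_bbox[3]
      pf_error(sprintf(
        "purge towers do not fit in the build area: need %.1f mm beyond the model in x",
        need), "pf_usage_error")
    }
    mix <- plan$mixtures[[match(keys[i], vapply(plan$mixtures, mix_key, character(1)))]]
    towers[[i]] <- list(label = keys[i], mixture = mix,
                        footprint = c(fw, fh), anchor = c(ax, ay),
                        active_layers = c(1L, as.integer(last_het)))
  }
  names(towers) <- keys
  structure(towers, class = "purge_towers")
}

#' Count towers active on a given layer
#' @param towers A \code{purge_towers} plan.
#' @param layer Layer index (1-based).
#' @return Number of towers whose active range covers the layer.
#' @export
towers_active <- function(towers, layer) {
  if (length(towers) == 0) return(0L)
  sum(vapply(towers, function(tw) layer >= tw$active_layers[1] &&
               layer <= tw$active_layers[2], logical(1)))
}

# Identify maximal runs of commands sharing a region label that contain
# extrusion; returns first/last row index, region and layer per block.
gc_blocks <- function(program) {
  df <- program$commands
  reg <- df$region
  idx <- which(!is.na(reg))
  if (length(idx) == 0) return(NULL)
  runs <- rle(reg[idx])
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  blocks <- data.frame(region = runs$values,
                       first = idx[starts], last = idx[ends],
                       stringsAsFactors = FALSE)
  blocks$has_extrusion <- vapply(seq_len(nrow(blocks)), function(b)
    any(df$extruding[blocks$first[b]:blocks$last[b]]), logical(1))
  blocks <- blocks[blocks$has_extrusion, , drop = FALSE]
  blocks$layer <- df$layer[vapply(seq_len(nrow(blocks)), function(b) {
    rows <- blocks$first[b]:blocks$last[b]
    rows[which(df$extruding[rows])[1]]
  }, integer(1))]
  blocks
}

mixset_rows <- function(ratio, region) {
  w <- unclass(ratio) / 100
  rbind(
    gc_row(sprintf("M163 S0 P%.4f", w[["Rg"]]), region = region, purpose = "mixset",
           raw = sprintf("M163 S0 P%.4f ; gray", w[["Rg"]])),
    gc_row(sprintf("M163 S1 P%.4f", w[["Rw"]]), region = region, purpose = "mixset",
           raw = sprintf("M163 S1 P%.4f ; white", w[["Rw"]])),
    gc_row(sprintf("M163 S2 P%.4f", w[["Rt"]]), region = region, purpose = "mixset",
           raw = sprintf("M163 S2 P%.4f ; translucent", w[["Rt"]])),
    gc_row("M164 S0", region = region, purpose = "mixset", raw = "M164 S0 ; commit mix")
  )
}

purge_rows <- function(tower, z, config, region) {
  pf_len <- config$purge_volume_per_transition /
    (pi * (config$filament_diameter / 2)^2)
  n_pass <- 8L
  x0 <- tower$anchor[1]; y0 <- tower$anchor[2]
  fw <- tower$footprint[1]
  rows <- list()
  for (p in seq_len(n_pass)) {
    xt <- if (p %% 2 == 1) x0 + fw else x0
    yt <- y0 + (p - 1) * config$line_width
    rows[[p]] <- gc_row("G1", x = xt, y = yt, de = pf_len / n_pass,
                        region = region, purpose = "purge")
  }
  do.call(rbind, rows)
}

#' Insert purge sequences at mixture transitions
#'
#' At every mixture transition the nozzle is lifted by the configured z-hop,
#' travels (x then y) to the incoming mixture's purge tower, sets the new
#' mixture, extrudes the configured purge volume as tower infill, and travels
#' back before printing resumes at the layer Z.  Transitions are detected over
#' the extruding region blocks in program order (including across layer
#' boundaries).  A transition on a layer with no active tower raises a
#' planning-consistency error.  Model commands are never removed or
#' reordered; the added extrusion equals the purge volume per transition
#' (converted to filament length) times the number of transitions.
#'
#' @param program A parsed \code{gcode_program} with region markers.
#' @param towers A \code{\link{plan_purge_towers}} result.
#' @param plan The \code{\link{mixture_plan}}.
#' @param config A \code{\link{postprocess_config}}.
#' @return The post-processed \code{gcode_program}.
#' @export
insert_purge_sequences <- function(program, towers, plan,
                                   config = postprocess_config()) {
  blocks <- gc_blocks(program)
  if (is.null(blocks) || nrow(blocks) < 2L) return(program)
  keys <- vapply(blocks$region, function(rg) {
    if (is.null(plan$mixtures[[rg]]))
      pf_usage_error(sprintf("program region `%s` has no mixture in the plan", rg))
    mix_key(plan$mixtures[[rg]])
  }, character(1))
  transitions <- which(keys[-1] != keys[-length(keys)]) + 1L
  if (length(transitions) == 0) return(program)
  df <- program$commands
  pieces <- list()
  prev_end <- 0L
  for (b in transitions) {
    at <- blocks$first[b]
    layer <- blocks$layer[b]
    key <- keys[b]
    tw <- towers[[key]]
    if (is.null(tw) || layer < tw$active_layers[1] || layer > tw$active_layers[2])
      pf_error(sprintf(
        "planning consistency: mixture transition to %s on layer %d has no active purge tower",
        key, layer), "pf_usage_error")
    zl <- df$pz[at]
    back <- if (at > 1) c(df$px[at - 1], df$py[at - 1]) else c(0, 0)
    seqrows <- rbind(
      gc_row("G1", z = zl + config$z_hop, purpose = "zhop_up", region = blocks$region[b]),
      gc_row("G0", x = tw$anchor[1], purpose = "tower_travel", region = blocks$region[b]),
      gc_row("G0", y = tw$anchor[2], purpose = "tower_travel", region = blocks$region[b]),
      gc_row("G1", z = zl, purpose = "zhop_down", region = blocks$region[b]),
      mixset_rows(plan$mixtures[[blocks$region[b]]], blocks$region[b]),
      purge_rows(tw, zl, config, blocks$region[b]),
      gc_row("G1", z = zl + config$z_hop, purpose = "zhop_up", region = blocks$region[b]),
      gc_row("G0", x = back[1], purpose = "return_travel", region = blocks$region[b]),
      gc_row("G0", y = back[2], purpose = "return_travel", region = blocks$region[b]),
      gc_row("G1", z = zl, purpose = "zhop_down", region = blocks$region[b])
    )
    pieces[[length(pieces) + 1L]] <- df[(prev_end + 1L):(at - 1L), , drop = FALSE]
    pieces[[length(pieces) + 1L]] <- seqrows
    prev_end <- at - 1L
  }
  pieces[[length(pieces) + 1L]] <- df[(prev_end + 1L):nrow(df), , drop = FALSE]
  newdf <- gc_bind(pieces)
  program$commands <- gc_recompute(newdf, program$layer_thickness)
  program$modified <- TRUE
  program
}

#' Rewrite diagonal travel moves as axis-aligned segments
#'
#' Every non-extruding move that changes both x and y is replaced by two
#' moves, x first then y, preserving the endpoints exactly.  Extruding moves
#' are untouched.
#'
#' @param program A \code{gcode_program}.
#' @return The rewritten \code{gcode_program}.
#' @export
rectilinearize_travels <- function(program) {
  df <- program$commands
  diag_rows <- which(df$code %in% c("G0", "G1") & !df$extruding &
                       !is.na(df$x) & !is.na(df$y))
  prevx <- c(0, df$px[-nrow(df)])
  prevy <- c(0, df$py[-nrow(df)])
  diag_rows <- diag_rows[abs(df$x[diag_rows] - prevx[diag_rows]) > 1e-12 &
                           abs(df$y[diag_rows] - prevy[diag_rows]) > 1e-12]
  if (length(diag_rows) == 0) return(program)
  pieces <- list()
  prev_end <- 0L
  for (i in diag_rows) {
    pieces[[length(pieces) + 1L]] <- df[(prev_end + 1L):(i - 1L), , drop = FALSE]
    r1 <- df[i, , drop = FALSE]; r2 <- df[i, , drop = FALSE]
    r1$y <- NA_real_; r1$raw <- NA_character_; r1$inserted <- TRUE
    r1$purpose <- "rectilinear"
    r2$x <- NA_real_; r2$raw <- NA_character_; r2$inserted <- TRUE
    r2$purpose <- "rectilinear"
    pieces[[length(pieces) + 1L]] <- rbind(r1, r2)
    prev_end <- i
  }
  pieces[[length(pieces) + 1L]] <- df[(prev_end + 1L):nrow(df), , drop = FALSE]
  program$commands <- gc_recompute(gc_bind(pieces), program$layer_thickness)
  program$modified <- TRUE
  program
}

#' Inject per-channel mixture commands
#'
#' Before the first extrusion of each region occurrence, emits the mixing
#' hotend's per-channel weight commands (\code{M163 S<ch> P<weight>} for the
#' gray/white/translucent channels, weights summing to 1, followed by
#' \code{M164 S0}).  Consecutive blocks of the same mixture set it once, and
#' mixture-set rows already present (e.g. inserted by
#' \code{\link{insert_purge_sequences}}) are honored.
#'
#' @param program A \code{gcode_program}.
#' @param plan A \code{\link{mixture_plan}} covering every region label used.
#' @param dialect Currently only \code{"marlin"} (M163/M164).
#' @return The annotated \code{gcode_program}.
#' @export
inject_mixing_commands <- function(program, plan, dialect = "marlin") {
  dialect <- match.arg(dialect, "marlin")
  blocks <- gc_blocks(program)
  if (is.null(blocks)) return(program)
  df <- program$commands
  current <- NA_character_
  inserts <- list() # row index -> rows to insert before it
  for (b in seq_len(nrow(blocks))) {
    rg <- blocks$region[b]
    if (is.null(plan$mixtures[[rg]]))
      pf_usage_error(sprintf("program region `%s` has no mixture in the plan", rg))
    key <- mix_key(plan$mixtures[[rg]])
    rows <- blocks$first[b]:blocks$last[b]
    preset <- df$purpose[rows]
    if (any(!is.na(preset) & preset == "mixset")) { current <- key; next }
    if (!identical(current, key)) {
      first_ex <- rows[which(df$extruding[rows])[1]]
      inserts[[as.character(first_ex)]] <- mixset_rows(plan$mixtures[[rg]], rg)
      current <- key
    }
  }
  if (length(inserts) == 0) return(program)
  at <- sort(as.integer(names(inserts)))
  pieces <- list(); prev_end <- 0L
  for (i in at) {
    pieces[[length(pieces) + 1L]] <- df[(prev_end + 1L):(i - 1L), , drop = FALSE]
    pieces[[length(pieces) + 1L]] <- inserts[[as.character(i)]]
    prev_end <- i - 1L
  }
  pieces[[length(pieces) + 1L]] <- df[(prev_end + 1L):nrow(df), , drop = FALSE]
  program$commands <- gc_recompute(gc_bind(pieces), program$layer_thickness)
  program$modified <- TRUE
  program
}

#' Per-channel filament usage
#'
#' Splits the total extruded filament length across the gray/white/translucent
#' channels according to the active region's mixture weights, and converts to
#' mass from the filament diameter and density.
#'
#' @param program A \code{gcode_program} (extrusion amounts in mm of filament).
#' @param plan A \code{\link{mixture_plan}}.
#' @param density Filament density, g/cm^3 (default 1.24, PLA).
#' @param diameter Filament diameter, mm (default 1.75).
#' @return List: \code{length_mm} (named vector gray/white/translucent),
#'   \code{mass_g}, \code{total_length_mm}, \code{total_mass_g}.
#' @export
estimate_usage <- function(program, plan, density = 1.24, diameter = 1.75) {
  df <- program$commands
  ex <- df[df$extruding, , drop = FALSE]
  lens <- c(gray = 0, white = 0, translucent = 0)
  for (i in seq_len(nrow(ex))) {
    rg <- ex$region[i]
    if (is.na(rg))
      pf_usage_error("extrusion before any ;REGION: marker; cannot attribute filament")
    mix <- plan$mixtures[[rg]]
    if (is.null(mix))
      pf_usage_error(sprintf("program region `%s` has no mixture in the plan", rg))
    w <- unclass(mix) / 100
    lens <- lens + ex$de[i] * c(w[["Rg"]], w[["Rw"]], w[["Rt"]])
  }
  area_cm2 <- pi * (diameter / 20)^2
  mass <- lens / 10 * area_cm2 * density
  list(length_mm = lens, mass_g = mass,
       total_length_mm = sum(lens), total_mass_g = sum(mass))
}
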
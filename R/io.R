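# File formats: titration tables as commented CSV, models and LUTs as JSON,
# frames as 16-bit binary PGM (P5).  All plain, portable, dependency-light.

#' Write a titration table as CSV
#'
#' Columns \code{label, Rg, Rw, Rt, mua, musp, mua_sd, musp_sd}; a header
#' comment line states the units (1/mm).
#'
#' @param records Titration data frame.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_titration <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# titration table: optical properties in mm^-1, ratios in percent", con)
  write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Read a titration table
#' @param path CSV written by \code{\link{write_titration}} (or compatible).
#' @return Data frame.
#' @export
read_titration <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Serialize a mixing model to JSON
#' @param model A \code{mixing_model}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_mixing_model <- function(model, path) {
  enc <- function(f) if (is.null(f)) NULL else
    list(A = f$A, B = f$B, C = f$C, r_squared = f$r_squared, n = f$n,
         weighted = isTRUE(f$weighted))
  jsonlite::write_json(list(format = "phantomforge-mixing-model",
                            version = as.character(utils::packageVersion("phantomforge")),
                            mua = enc(model$mua), musp = enc(model$musp),
                            filaments = model$filaments),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a mixing model from JSON
#' @param path File written by \code{\link{write_mixing_model}}.
#' @return A \code{mixing_model}.
#' @export
read_mixing_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(f) if (is.null(f)) NULL else
    list(A = f$A, B = f$B, C = f$C,
         r_squared = if (is.null(f$r_squared)) NA_real_ else f$r_squared,
         residuals = numeric(0),
         n = if (is.null(f$n)) NA_integer_ else f$n,
         weighted = isTRUE(f$weighted))
  structure(list(mua = dec(j$mua), musp = dec(j$musp), filaments = j$filaments),
            class = "mixing_model")
}

#' Serialize a reflectance LUT to JSON
#'
#' Grids, the flattened Rd array (with dimensions) and full provenance
#' metadata (seed, photon count, medium, binning).
#'
#' @param lut A \code{reflectance_lut}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_lut <- function(lut, path) {
  jsonlite::write_json(list(format = "phantomforge-lut",
                            mua_grid = lut$mua_grid, musp_grid = lut$musp_grid,
                            fx = lut$fx, dim = dim(lut$rd),
                            rd = as.numeric(lut$rd), meta = lut$meta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a reflectance LUT from JSON
#' @param path File written by \code{\link{write_lut}}.
#' @return A \code{reflectance_lut}.
#' @export
read_lut <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mua_grid = j$mua_grid, musp_grid = j$musp_grid, fx = j$fx,
                 rd = array(j$rd, dim = j$dim), meta = as.list(j$meta)),
            class = "reflectance_lut")
}

#' Write a matrix as 16-bit binary PGM (P5)
#'
#' Big-endian 16-bit grayscale; values are clamped to [0, maxval] and
#' rounded.
#'
#' @param mat Numeric matrix.
#' @param path Output file.
#' @param maxval Maximum gray value (default 65535).
#' @return \code{path}, invisibly.
#' @export
write_pgm <- function(mat, path, maxval = 65535L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", sprintf("%d %d", ncol(mat), nrow(mat)), as.character(maxval)), con)
  v <- as.integer(round(pmin(pmax(t(mat), 0), maxval)))
  # 16-bit values exceed R's signed writeBin(size = 2) range; emit raw bytes
  writeBin(as.raw(as.vector(rbind(v %/% 256L, v %% 256L))), con)
  invisible(path)
}

#' Read a 16-bit binary PGM (P5)
#' @param path PGM file.
#' @return Numeric matrix.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") break
      if (grepl("^\\s$", ch)) { if (nzchar(tok)) break else next }
      if (ch == "#") { repeat { c2 <- readChar(con, 1, useBytes = TRUE)
                                if (length(c2) == 0 || c2 == "\n") break }; next }
      tok <- paste0(tok, ch)
    }
    tok
  }
  magic <- read_token()
  if (magic != "P5") pf_usage_error(sprintf("not a binary PGM (magic `%s`)", magic))
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  sz <- if (maxval > 255) 2L else 1L
  v <- readBin(con, "integer", n = w * h, size = sz, signed = FALSE, endian = "big")
  t(matrix(as.numeric(v), nrow = w, ncol = h))
}

#' Save a frame set to a directory of PGM files plus metadata
#'
#' One file per frequency/phase (\code{fx<i>_p<j>.pgm}) and a
#' \code{frameset.json} recording frequencies, phases, pixel pitch and bit
#' depth.
#'
#' @param fs A \code{\link{frame_set}}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
save_frameset <- function(fs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list()
  for (f in seq_along(fs$fx)) {
    for (p in 1:3) {
      fn <- sprintf("fx%d_p%d.pgm", f, p)
      write_pgm(fs$frames[[f]][[p]], file.path(dir, fn))
      files[[sprintf("fx%d_p%d", f, p)]] <- fn
    }
  }
  jsonlite::write_json(list(format = "phantomforge-frameset", fx = fs$fx,
                            pixel_pitch = fs$pixel_pitch,
                            bit_depth = fs$bit_depth, files = files),
                       file.path(dir, "frameset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a frame set saved by \code{\link{save_frameset}}
#' @param dir Directory containing \code{frameset.json} and PGM frames.
#' @return A \code{\link{frame_set}}.
#' @export
load_frameset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "frameset.json"), simplifyVector = TRUE)
  frames <- lapply(seq_along(meta$fx), function(f)
    lapply(1:3, function(p)
      read_pgm(file.path(dir, meta$files[[sprintf("fx%d_p%d", f, p)]]))))
  frame_set(frames, meta$fx, pixel_pitch = meta$pixel_pitch,
            bit_depth = meta$bit_depth)
}
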
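# Minimal exact triangle-mesh construction for the phantom geometries: boxes,
# convex prisms (bars, cylinder n-gons) and slabs with blind or through
# cavities opening on the bottom (and possibly top) face.  Meshes are built
# with shared grid vertices so they are closed and 2-manifold by construction;
# volumes are exact for the polygonal geometry.

pf_mesh <- function(vertices, faces) {
  structure(list(vertices = vertices, faces = faces), class = "pf_mesh")
}

#' @export
print.pf_mesh <- function(x, ...) {
  cat(sprintf("<pf_mesh> %d vertices, %d triangles, volume %.3f mm^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

# Accumulate triangles as a 3-column list of xyz triples; weld at the end.
new_tri_acc <- function() new.env(parent = emptyenv())

acc_tri <- function(acc, a, b, c) {
  n <- length(acc$tris <- c(acc$tris, list(rbind(a, b, c))))
  invisible(n)
}

weld_mesh <- function(acc, digits = 9) {
  tris <- acc$tris
  if (length(tris) == 0) return(pf_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  V <- do.call(rbind, tris)
  key <- apply(round(V, digits), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- V[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  pf_mesh(verts, faces[keep, , drop = FALSE])
}

#' Signed volume of a closed triangle mesh
#'
#' Divergence-theorem sum of signed tetrahedra; positive for outward-oriented
#' closed meshes.
#'
#' @param mesh A \code{pf_mesh}.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  a <- V[Fc[, 1], , drop = FALSE]
  b <- V[Fc[, 2], , drop = FALSE]
  c <- V[Fc[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Check that a mesh is closed and 2-manifold
#'
#' Every directed edge must occur exactly once and be matched by its reverse
#' (each undirected edge shared by exactly two consistently oriented
#' triangles).
#'
#' @param mesh A \code{pf_mesh}.
#' @return \code{TRUE} if watertight.
#' @export
mesh_is_watertight <- function(mesh) {
  Fc <- mesh$faces
  if (nrow(Fc) == 0) return(FALSE)
  ed <- rbind(Fc[, 1:2], Fc[, 2:3], Fc[, c(3, 1)])
  dkey <- paste(ed[, 1], ed[, 2])
  rkey <- paste(ed[, 2], ed[, 1])
  !anyDuplicated(dkey) && all(dkey %in% rkey)
}

# --- 2-D helpers -----------------------------------------------------------

# CCW circle approximation used for cylindrical inclusions
circle_poly <- function(center, radius, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

poly_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_centroid <- function(p) colMeans(p)

# Triangulate the annulus between a convex CCW outer loop and a convex CCW
# inner loop (both star-shaped about the inner centroid) by zipping the two
# loops in angular order.  Returns an n x 6 matrix of 2-D triangles
# (x1,y1,x2,y2,x3,y3) with CCW orientation, covering outer minus inner.
annulus_tris <- function(outer, inner) {
  c0 <- poly_centroid(inner)
  ang <- function(p) atan2(p[, 2] - c0[2], p[, 1] - c0[1]) %% (2 * pi)
  ao <- ang(outer); oo <- order(ao)
  outer <- outer[oo, , drop = FALSE]; ao <- ao[oo]
  ai <- ang(inner); oi <- order(ai)
  inner <- inner[oi, , drop = FALSE]; ai <- ai[oi]
  m <- nrow(outer); k <- nrow(inner)
  next_ao <- c(ao[-1], ao[1] + 2 * pi) # angle reached after advancing step s
  next_ai <- c(ai[-1], ai[1] + 2 * pi)
  tris <- matrix(0, m + k, 6)
  ni <- 0L; nj <- 0L; t <- 0L
  while (ni < m || nj < k) {
    t <- t + 1L
    ci <- if (ni < m) ni + 1L else 1L # current outer vertex (wraps at the end)
    cj <- if (nj < k) nj + 1L else 1L
    adv_outer <- if (ni == m) FALSE else if (nj == k) TRUE else
      next_ao[ni + 1L] <= next_ai[nj + 1L]
    if (adv_outer) {
      tris[t, ] <- c(outer[ci, ], outer[ci %% m + 1L, ], inner[cj, ])
      ni <- ni + 1L
    } else {
      tris[t, ] <- c(inner[cj %% k + 1L, ], inner[cj, ], outer[ci, ])
      nj <- nj + 1L
    }
  }
  # exactness guard: the strip must tile the annulus
  a_tri <- sum(vapply(seq_len(nrow(tris)), function(r)
    poly_area(matrix(tris[r, ], 3, 2, byrow = TRUE)), numeric(1)))
  a_ref <- poly_area(outer) - poly_area(inner)
  if (abs(a_tri - a_ref) > 1e-6 * max(1, a_ref))
    pf_error("internal: annulus triangulation failed to tile the region", "pf_error")
  tris
}

fan_tris <- function(poly) {
  # convex polygon fan about its centroid, CCW
  c0 <- poly_centroid(poly)
  k <- nrow(poly)
  tris <- matrix(0, k, 6)
  for (i in seq_len(k)) {
    j <- i %% k + 1L
    tris[i, ] <- c(c0, poly[i, ], poly[j, ])
  }
  tris
}

rect_tris <- function(xmin, ymin, xmax, ymax) {
  rbind(c(xmin, ymin, xmax, ymin, xmax, ymax),
        c(xmin, ymin, xmax, ymax, xmin, ymax))
}

# Emit a set of 2-D CCW triangles as a horizontal face at height z.
# up = TRUE for outward +z (keep CCW seen from above), FALSE to flip.
emit_face <- function(acc, tris2d, z, up) {
  for (r in seq_len(nrow(tris2d))) {
    tr <- tris2d[r, ]
    a <- c(tr[1], tr[2], z); b <- c(tr[3], tr[4], z); cc <- c(tr[5], tr[6], z)
    if (up) acc_tri(acc, a, b, cc) else acc_tri(acc, a, cc, b)
  }
}

# Vertical wall along a CCW polygon from z0 to z1; outward = TRUE points
# normals away from the polygon interior (outer surface), FALSE inward
# (cavity wall seen from the solid outside the polygon).
emit_wall <- function(acc, poly, z0, z1, outward) {
  k <- nrow(poly)
  for (i in seq_len(k)) {
    j <- i %% k + 1L
    p <- poly[i, ]; q <- poly[j, ]
    a0 <- c(p, z0); b0 <- c(q, z0); a1 <- c(p, z1); b1 <- c(q, z1)
    if (outward) {
      acc_tri(acc, a0, b0, b1); acc_tri(acc, a0, b1, a1)
    } else {
      acc_tri(acc, a0, b1, b0); acc_tri(acc, a0, a1, b1)
    }
  }
}

#' Axis-aligned box mesh
#'
#' @param origin Minimum corner, mm.
#' @param size Edge lengths c(dx, dy, dz), mm.
#' @return A closed \code{pf_mesh}.
#' @export
mesh_box <- function(origin, size) {
  p <- rect_poly(origin[1], origin[2], origin[1] + size[1], origin[2] + size[2])
  mesh_prism(p, origin[3], origin[3] + size[3])
}

#' Convex prism mesh from a CCW footprint polygon
#'
#' @param poly CCW convex footprint polygon (k x 2 matrix), mm.
#' @param z0,z1 Bottom and top heights, mm.
#' @return A closed \code{pf_mesh}.
#' @export
mesh_prism <- function(poly, z0, z1) {
  acc <- new_tri_acc()
  emit_face(acc, fan_tris(poly), z0, up = FALSE)
  emit_face(acc, fan_tris(poly), z1, up = TRUE)
  emit_wall(acc, poly, z0, z1, outward = TRUE)
  weld_mesh(acc)
}

# Slab of size (L, W, H) with origin at (0,0,0) minus cavities.  Each cavity:
# list(poly = CCW convex polygon, z0, z1) with z0 = 0 (opens on the bottom
# face); a cavity with z1 = H is a through hole (opens on both faces), z1 < H
# gets a ceiling.  Cavity bounding boxes must be pairwise disjoint and
# strictly inside the slab footprint.
mesh_slab_with_cavities <- function(L, W, H, cavities = list()) {
  bboxes <- lapply(cavities, function(cv)
    c(min(cv$poly[, 1]), min(cv$poly[, 2]), max(cv$poly[, 1]), max(cv$poly[, 2])))
  nc <- length(cavities)
  if (nc > 1) {
    for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
      a <- bboxes[[i]]; b <- bboxes[[j]]
      if (a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4])
        pf_error(sprintf("cavity bounding boxes %d and %d overlap", i, j),
                 "pf_usage_error")
    }
  }
  for (bb in bboxes)
    if (bb[1] <= 0 || bb[2] <= 0 || bb[3] >= L || bb[4] >= W)
      pf_usage_error("cavity must lie strictly inside the slab footprint")
  xs <- sort(unique(c(0, L, unlist(lapply(bboxes, function(b) b[c(1, 3)])))))
  ys <- sort(unique(c(0, W, unlist(lapply(bboxes, function(b) b[c(2, 4)])))))
  in_bbox <- function(xmid, ymid) {
    for (ci in seq_len(nc)) {
      b <- bboxes[[ci]]
      if (xmid > b[1] && xmid < b[3] && ymid > b[2] && ymid < b[4]) return(ci)
    }
    0L
  }
  # outer rectangle loop of a bbox including all grid vertices on its edges
  bbox_loop <- function(b) {
    xi <- xs[xs >= b[1] - 1e-12 & xs <= b[3] + 1e-12]
    yi <- ys[ys >= b[2] - 1e-12 & ys <= b[4] + 1e-12]
    bottom <- cbind(xi, b[2])
    right <- cbind(b[3], yi[-1])
    top <- cbind(rev(xi)[-1], b[4])
    left <- cbind(b[1], rev(yi)[-1])
    loop <- rbind(bottom, right, top, left)
    loop[-nrow(loop), , drop = FALSE]
  }
  face_tris <- function(open_idx) {
    # triangulate slab footprint minus the cavities in open_idx (grid cells
    # outside every bbox; bbox regions of open cavities as annuli; bbox
    # regions of closed cavities as plain annuli? no: closed cavities do not
    # perforate this face, their bbox cells are plain)
    tris <- list()
    done_bbox <- integer(0)
    for (ix in seq_len(length(xs) - 1)) {
      for (iy in seq_len(length(ys) - 1)) {
        xm <- (xs[ix] + xs[ix + 1]) / 2; ym <- (ys[iy] + ys[iy + 1]) / 2
        ci <- in_bbox(xm, ym)
        if (ci == 0L || !(ci %in% open_idx)) {
          tris[[length(tris) + 1]] <- rect_tris(xs[ix], ys[iy], xs[ix + 1], ys[iy + 1])
        } else if (!(ci %in% done_bbox)) {
          tris[[length(tris) + 1]] <- annulus_tris(bbox_loop(bboxes[[ci]]),
                                                   cavities[[ci]]$poly)
          done_bbox <- c(done_bbox, ci)
        }
      }
    }
    do.call(rbind, tris)
  }
  acc <- new_tri_acc()
  bottom_open <- which(vapply(cavities, function(cv) cv$z0 <= 1e-12, logical(1)))
  top_open <- which(vapply(cavities, function(cv) cv$z1 >= H - 1e-12, logical(1)))
  emit_face(acc, face_tris(bottom_open), 0, up = FALSE)
  emit_face(acc, face_tris(top_open), H, up = TRUE)
  # slab side walls, subdivided at the global grid lines so edges match the
  # top/bottom face triangulations exactly
  side_strip <- function(p, q) { # vertical quad strip, outward normal right of p->q
    a0 <- c(p, 0); b0 <- c(q, 0); a1 <- c(p, H); b1 <- c(q, H)
    acc_tri(acc, a0, b0, b1); acc_tri(acc, a0, b1, a1)
  }
  for (ix in seq_len(length(xs) - 1)) {
    side_strip(c(xs[ix], 0), c(xs[ix + 1], 0))        # y = 0, outward -y
    side_strip(c(xs[ix + 1], W), c(xs[ix], W))        # y = W, outward +y
  }
  for (iy in seq_len(length(ys) - 1)) {
    side_strip(c(0, ys[iy + 1]), c(0, ys[iy]))        # x = 0, outward -x
    side_strip(c(L, ys[iy]), c(L, ys[iy + 1]))        # x = L, outward +x
  }
  for (ci in seq_len(nc)) {
    cv <- cavities[[ci]]
    emit_wall(acc, cv$poly, cv$z0, cv$z1, outward = FALSE)
    if (cv$z1 < H - 1e-12) emit_face(acc, fan_tris(cv$poly), cv$z1, up = FALSE)
    if (cv$z0 > 1e-12) emit_face(acc, fan_tris(cv$poly), cv$z0, up = TRUE)
  }
  weld_mesh(acc)
}

#' Write a mesh as ASCII STL
#'
#' Millimeter units, z-up.  ASCII keeps exported geometry diffable and
#' portable; all slicers accept it.
#'
#' @param mesh A \code{pf_mesh}.
#' @param path Output file.
#' @param name Solid name recorded in the file.
#' @return \code{path}, invisibly.
#' @export
write_stl <- function(mesh, path, name = "phantomforge") {
  V <- mesh$vertices; Fc <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(Fc))) {
    a <- V[Fc[i, 1], ]; b <- V[Fc[i, 2], ]; cc <- V[Fc[i, 3], ]
    u <- b - a; v <- cc - a
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    nl <- sqrt(sum(nrm^2))
    if (nl > 0) nrm <- nrm / nl
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
      sprintf("      vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
      sprintf("      vertex %.9g %.9g %.9g", cc[1], cc[2], cc[3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
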
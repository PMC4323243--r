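# Triangle-mesh kernel for the volumetric module: containers, ASCII STL/PLY
# I/O, closed-manifold checks, exact volume/area, half-space clipping with
# cap fill, ray-parity voxelization and point-to-surface distances.
# Orientation convention: faces are counter-clockwise seen from outside, so
# the signed divergence-theorem volume of a closed model is positive.

#' Create a triangulated surface model
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices,
#'   counter-clockwise when seen from outside.
#' @param tissue `"soft"`, `"hard"` or `NA`.
#' @param session Free-text session label (e.g. `"preop"`, `"postop"`).
#' @param cap Optional logical vector (length m) marking faces that are
#'   artificial clip caps rather than anatomical surface.
#' @return Object of class `surface_model`.
#' @export
surface_model <- function(vertices, faces, tissue = NA_character_,
                          session = "", cap = NULL) {
  vertices <- as.matrix(vertices)
  if (length(vertices) == 0L) vertices <- matrix(numeric(0), 0L, 3L)
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (ncol(vertices) != 3L) stop_usage("vertices must be n x 3")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop_usage("face indices out of range")
  }
  if (is.null(cap)) cap <- rep(FALSE, nrow(faces))
  storage.mode(vertices) <- "double"
  structure(list(vertices = vertices, faces = faces,
                 tissue = tissue, session = session, cap = cap),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> %d vertices, %d faces%s%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.na(x$tissue)) paste0(", tissue=", x$tissue) else "",
              if (nzchar(x$session)) paste0(", session=", x$session) else ""))
  invisible(x)
}

face_matrix <- function(mesh, col) mesh$vertices[mesh$faces[, col], , drop = FALSE]

#' Surface area of a model
#' @param mesh A [surface_model()].
#' @param include_caps Include artificial clip-cap faces.
#' @return Total triangle area (mm^2).
#' @export
mesh_area <- function(mesh, include_caps = TRUE) {
  if (!nrow(mesh$faces)) return(0)
  A <- face_matrix(mesh, 1); B <- face_matrix(mesh, 2); C <- face_matrix(mesh, 3)
  u <- B - A; v <- C - A
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  a <- sqrt(cx^2 + cy^2 + cz^2) / 2
  if (!include_caps) a <- a[!mesh$cap]
  sum(a)
}

#' Enclosed volume of a closed model
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra to the
#' origin); positive for consistently outward-oriented closed surfaces.
#'
#' @param mesh A [surface_model()].
#' @return Volume (mm^3).
#' @export
mesh_volume <- function(mesh) {
  if (!nrow(mesh$faces)) return(0)
  A <- face_matrix(mesh, 1); B <- face_matrix(mesh, 2); C <- face_matrix(mesh, 3)
  sum(A[, 1] * (B[, 2] * C[, 3] - B[, 3] * C[, 2]) +
      A[, 2] * (B[, 3] * C[, 1] - B[, 1] * C[, 3]) +
      A[, 3] * (B[, 1] * C[, 2] - B[, 2] * C[, 1])) / 6
}

.directed_edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  list(fwd = paste(e[, 1], e[, 2]), rev = paste(e[, 2], e[, 1]), edges = e)
}

#' Is a model a closed, consistently oriented 2-manifold?
#'
#' Checks that every directed edge occurs exactly once and that its reverse
#' also occurs (each undirected edge shared by exactly two faces with
#' opposite orientation).
#'
#' @param mesh A [surface_model()].
#' @return Logical.
#' @export
is_closed_mesh <- function(mesh) {
  if (!nrow(mesh$faces)) return(FALSE)
  k <- .directed_edge_keys(mesh$faces)
  !anyDuplicated(k$fwd) && all(k$fwd %in% k$rev)
}

assert_closed <- function(mesh, what = "mesh") {
  if (!is_closed_mesh(mesh)) {
    stop_topology(sprintf("%s is not a closed, consistently oriented surface", what))
  }
  invisible(mesh)
}

#' Rigidly transform a surface model
#' @param mesh A [surface_model()].
#' @param transform A [rigid_transform()].
#' @return The transformed [surface_model()].
#' @export
transform_mesh <- function(mesh, transform) {
  out <- mesh
  out$vertices <- apply_rigid(transform, mesh$vertices)
  out
}

## ---- primitive meshes -----------------------------------------------------

#' Axis-aligned box mesh
#' @param min_corner,max_corner Length-3 corners (mm), min < max per axis.
#' @param tissue,session Passed to [surface_model()].
#' @return A closed [surface_model()] with 12 outward-oriented triangles.
#' @export
box_mesh <- function(min_corner, max_corner, tissue = NA_character_, session = "") {
  lo <- as.numeric(min_corner); hi <- as.numeric(max_corner)
  if (any(hi <= lo)) stop_usage("box needs max_corner > min_corner on every axis")
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex index bits: 1 + x + 2y + 4z
  f <- rbind(
    c(1, 7, 3), c(1, 5, 7),   # x = lo
    c(2, 4, 8), c(2, 8, 6),   # x = hi
    c(1, 6, 5), c(1, 2, 6),   # y = lo
    c(3, 8, 4), c(3, 7, 8),   # y = hi
    c(1, 4, 2), c(1, 3, 4),   # z = lo
    c(5, 8, 7), c(5, 6, 8))   # z = hi
  surface_model(v, f, tissue = tissue, session = session)
}

#' Ellipsoid mesh (UV sphere triangulation)
#' @param semiaxes Length-3 semi-axis lengths (mm).
#' @param center Length-3 center (mm).
#' @param n_theta,n_phi Longitudinal / latitudinal resolution.
#' @param tissue,session Passed to [surface_model()].
#' @return A closed [surface_model()].
#' @export
ellipsoid_mesh <- function(semiaxes = c(10, 10, 10), center = c(0, 0, 0),
                           n_theta = 48, n_phi = 24,
                           tissue = NA_character_, session = "") {
  a <- as.numeric(semiaxes)
  if (any(a <= 0)) stop_usage("semiaxes must be positive")
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ph <- seq(0, pi, length.out = n_phi + 1)[c(-1, -(n_phi + 1))]  # interior rings
  ring <- function(p) cbind(a[1] * sin(p) * cos(th), a[2] * cos(p),
                            a[3] * sin(p) * sin(th))
  v <- rbind(c(0, a[2], 0), do.call(rbind, lapply(ph, ring)), c(0, -a[2], 0))
  v <- sweep(v, 2L, as.numeric(center), "+")
  nr <- length(ph)
  idx <- function(i, j) 1L + (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  f <- list()
  for (j in seq_len(n_theta)) {   # top cap (north pole is +Y)
    f[[length(f) + 1L]] <- c(1L, idx(1, j), idx(1, j + 1))
  }
  if (nr > 1) {
    for (i in seq_len(nr - 1L)) for (j in seq_len(n_theta)) {
      f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
      f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  south <- nrow(v)
  for (j in seq_len(n_theta)) {
    f[[length(f) + 1L]] <- c(south, idx(nr, j + 1), idx(nr, j))
  }
  m <- surface_model(v, do.call(rbind, f), tissue = tissue, session = session)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

## ---- STL / PLY I/O --------------------------------------------------------

.merge_vertices <- function(v, tol = 1e-6) {
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  list(vertices = v[first, , drop = FALSE], map = match(key, key[first]))
}

#' Read an ASCII STL file
#'
#' STL stores independent facets; coincident vertices are merged (1e-6 mm
#' tolerance) to recover connectivity.
#'
#' @param path File path.
#' @param tissue,session Metadata attached to the result.
#' @return A [surface_model()].
#' @export
read_stl <- function(path, tissue = NA_character_, session = "") {
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vx)) stop_parse("no vertex records found (binary STL is not supported)")
  nums <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(tok) {
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(!is.finite(v))) stop_parse("non-numeric STL vertex")
    v
  }))
  if (nrow(nums) %% 3L != 0L) stop_parse("STL vertex count is not a multiple of 3")
  mg <- .merge_vertices(nums)
  faces <- matrix(mg$map, ncol = 3L, byrow = TRUE)
  surface_model(mg$vertices, faces, tissue = tissue, session = session)
}

#' Write an ASCII STL file
#' @param mesh A [surface_model()].
#' @param path Output path.
#' @param name Solid name written in the header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "cephaloplane") {
  A <- face_matrix(mesh, 1); B <- face_matrix(mesh, 2); C <- face_matrix(mesh, 3)
  u <- B - A; v <- C - A
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
  block <- paste0("  facet normal ", fmt(n), "\n    outer loop\n      vertex ",
                  fmt(A), "\n      vertex ", fmt(B), "\n      vertex ", fmt(C),
                  "\n    endloop\n  endfacet")
  writeLines(block, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Read an ASCII PLY file
#' @param path File path.
#' @param tissue,session Metadata attached to the result.
#' @return A [surface_model()].
#' @export
read_ply <- function(path, tissue = NA_character_, session = "") {
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply") stop_parse("not a PLY file")
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop_parse("PLY header has no end_header")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format ascii", hdr))) stop_parse("only ASCII PLY is supported")
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", hdr, value = TRUE)))
  if (!length(nv) || !length(nf)) stop_parse("PLY must declare vertex and face elements")
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vt <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                              function(t) as.numeric(t[1:3])))
  fc <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                              function(t) {
    cnt <- as.integer(t[1])
    if (cnt != 3L) stop_parse("only triangle faces are supported")
    as.integer(t[2:4]) + 1L
  }))
  surface_model(vt, fc, tissue = tissue, session = session)
}

#' Write an ASCII PLY file
#' @param mesh A [surface_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

## ---- half-space clipping --------------------------------------------------

# Clip a closed mesh against side * (n.p - d) >= 0, capping the cut with
# fan-triangulated boundary loops. Cap faces (and inherited caps) are marked.
clip_mesh_halfspace <- function(mesh, plane, side = 1, tol = 1e-9) {
  s <- side * point_plane_distance(mesh$vertices, plane, signed = TRUE)
  verts <- list(); vkey <- character(0)
  add_vertex <- function(p) {
    key <- paste(round(p[1] * 1e6), round(p[2] * 1e6), round(p[3] * 1e6))
    i <- match(key, vkey)
    if (!is.na(i)) return(i)
    verts[[length(verts) + 1L]] <<- p
    vkey[length(vkey) + 1L] <<- key
    length(verts)
  }
  faces <- list(); caps <- logical(0)
  add_face <- function(i, j, k, cap) {
    if (i == j || j == k || i == k) return(invisible())
    faces[[length(faces) + 1L]] <<- c(i, j, k)
    caps[length(caps) + 1L] <<- cap
  }
  V <- mesh$vertices
  for (fi in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[fi, ]
    sv <- s[tri]
    if (all(sv >= -tol)) {            # fully kept (on-plane counts as kept)
      ids <- vapply(tri, function(i) add_vertex(V[i, ]), 1L)
      add_face(ids[1], ids[2], ids[3], mesh$cap[fi])
      next
    }
    if (all(sv <= tol)) next          # fully dropped
    # Sutherland-Hodgman on the triangle polygon
    poly <- list()
    for (e in 1:3) {
      i <- tri[e]; j <- tri[if (e == 3) 1 else e + 1]
      si <- s[i]; sj <- s[j]
      if (si >= -tol) poly[[length(poly) + 1L]] <- V[i, ]
      if ((si > tol && sj < -tol) || (si < -tol && sj > tol)) {
        t <- si / (si - sj)
        poly[[length(poly) + 1L]] <- V[i, ] + t * (V[j, ] - V[i, ])
      }
    }
    if (length(poly) < 3L) next
    ids <- vapply(poly, add_vertex, 1L)
    ids <- ids[!duplicated(ids)]
    if (length(ids) < 3L) next
    for (t in 2:(length(ids) - 1L)) {
      add_face(ids[1], ids[t], ids[t + 1L], mesh$cap[fi])
    }
  }
  if (!length(faces)) {
    return(surface_model(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3),
                         tissue = mesh$tissue, session = mesh$session))
  }
  Fm <- do.call(rbind, faces)
  Vm <- do.call(rbind, verts)
  # cap the open boundary left by the cut
  k <- .directed_edge_keys(Fm)
  open <- !(k$fwd %in% k$rev)
  if (any(open)) {
    edges <- k$edges[open, , drop = FALSE]
    nxt <- stats::setNames(edges[, 2], as.character(edges[, 1]))
    used <- rep(FALSE, nrow(edges))
    starts <- edges[, 1]
    while (any(!used)) {
      e0 <- which(!used)[1]
      loop <- c(edges[e0, 1], edges[e0, 2]); used[e0] <- TRUE
      repeat {
        cand <- which(!used & edges[, 1] == loop[length(loop)])
        if (!length(cand)) break
        used[cand[1]] <- TRUE
        nx <- edges[cand[1], 2]
        if (nx == loop[1]) break
        loop <- c(loop, nx)
      }
      if (length(loop) >= 3L) {
        ctr <- colMeans(Vm[loop, , drop = FALSE])
        ci <- nrow(Vm) + 1L
        Vm <- rbind(Vm, ctr)
        for (q in seq_along(loop)) {
          a <- loop[q]; b <- loop[if (q == length(loop)) 1 else q + 1]
          Fm <- rbind(Fm, c(ci, b, a))   # reversed: cap closes the boundary
          caps <- c(caps, TRUE)
        }
      }
    }
  }
  surface_model(Vm, Fm, tissue = mesh$tissue, session = mesh$session, cap = caps)
}

## ---- voxelization ---------------------------------------------------------

# Ray-parity voxelization: for every (x, y) voxel-column the z-values where
# the column's ray crosses the surface are collected; voxel centers with an
# odd number of crossings below them are inside. Duplicate crossings from
# shared coplanar edges are merged; the grid is jittered off exact edge hits.
voxelize_mesh <- function(mesh, origin, n_cells, voxel, cell_budget = 4e7) {
  nx <- n_cells[1]; ny <- n_cells[2]; nz <- n_cells[3]
  if (as.double(nx) * ny * nz > cell_budget) {
    stop_usage(sprintf(
      "voxel grid %d x %d x %d exceeds the cell budget; use a larger voxel size",
      nx, ny, nz))
  }
  xs <- origin[1] + (seq_len(nx) - 0.5) * voxel
  ys <- origin[2] + (seq_len(ny) - 0.5) * voxel
  zs <- origin[3] + (seq_len(nz) - 0.5) * voxel
  hits_col <- integer(0); hits_z <- numeric(0)
  V <- mesh$vertices; Fm <- mesh$faces
  for (fi in seq_len(nrow(Fm))) {
    A <- V[Fm[fi, 1], ]; B <- V[Fm[fi, 2], ]; C <- V[Fm[fi, 3], ]
    det <- (B[2] - C[2]) * (A[1] - C[1]) + (C[1] - B[1]) * (A[2] - C[2])
    if (abs(det) < 1e-14) next                       # vertical triangle: tangent
    ix <- which(xs >= min(A[1], B[1], C[1]) - 1e-12 &
                xs <= max(A[1], B[1], C[1]) + 1e-12)
    iy <- which(ys >= min(A[2], B[2], C[2]) - 1e-12 &
                ys <= max(A[2], B[2], C[2]) + 1e-12)
    if (!length(ix) || !length(iy)) next
    px <- rep(xs[ix], times = length(iy))
    py <- rep(ys[iy], each = length(ix))
    l1 <- ((B[2] - C[2]) * (px - C[1]) + (C[1] - B[1]) * (py - C[2])) / det
    l2 <- ((C[2] - A[2]) * (px - C[1]) + (A[1] - C[1]) * (py - C[2])) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-12 & l2 >= -1e-12 & l3 >= -1e-12
    if (!any(inside)) next
    z <- l1[inside] * A[3] + l2[inside] * B[3] + l3[inside] * C[3]
    col <- (rep(ix, times = length(iy))[inside]) +
      (rep(iy, each = length(ix))[inside] - 1L) * nx
    hits_col <- c(hits_col, col)
    hits_z <- c(hits_z, z)
  }
  mask <- array(FALSE, dim = c(nx, ny, nz))
  if (!length(hits_col)) return(mask)
  o <- order(hits_col, hits_z)
  hits_col <- hits_col[o]; hits_z <- hits_z[o]
  grp <- split(hits_z, hits_col)
  for (cn in names(grp)) {
    z <- grp[[cn]]
    z <- z[c(TRUE, diff(z) > 1e-7)]      # merge duplicates from shared edges
    if (length(z) %% 2L == 1L) z <- z[-length(z)]  # tangent residue: drop
    if (!length(z)) next
    parity <- findInterval(zs, z) %% 2L == 1L
    col <- as.integer(cn)
    i <- (col - 1L) %% nx + 1L
    j <- (col - 1L) %/% nx + 1L
    mask[i, j, ] <- parity
  }
  mask
}

## ---- surface distances & color bins ---------------------------------------

# Closest-point-on-triangle distances from one point to all faces
# (Ericson's region classification, vectorised over triangles).
.point_mesh_distance <- function(p, V, Fm) {
  A <- V[Fm[, 1], , drop = FALSE]
  B <- V[Fm[, 2], , drop = FALSE]
  C <- V[Fm[, 3], , drop = FALSE]
  ab <- B - A; ac <- C - A
  ap <- sweep(-A, 2L, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-B, 2L, p, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-C, 2L, p, "+")
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  denom <- va + vb + vc
  v <- ifelse(abs(denom) > 0, vb / denom, 0)
  w <- ifelse(abs(denom) > 0, vc / denom, 0)
  close <- A + ab * v + ac * w                       # interior default
  # edge BC
  m <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  t_bc <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), 1e-300)
  close[m, ] <- (B + (C - B) * t_bc)[m, , drop = FALSE]
  # edge AC
  m <- vb <= 0 & d2 >= 0 & d6 <= 0
  t_ac <- d2 / pmax(d2 - d6, 1e-300)
  close[m, ] <- (A + ac * t_ac)[m, , drop = FALSE]
  # vertex C
  m <- d6 >= 0 & d5 <= d6; close[m, ] <- C[m, , drop = FALSE]
  # edge AB
  m <- vc <= 0 & d1 >= 0 & d3 <= 0
  t_ab <- d1 / pmax(d1 - d3, 1e-300)
  close[m, ] <- (A + ab * t_ab)[m, , drop = FALSE]
  # vertices B, A
  m <- d3 >= 0 & d4 <= d3; close[m, ] <- B[m, , drop = FALSE]
  m <- d1 <= 0 & d2 <= 0;  close[m, ] <- A[m, , drop = FALSE]
  sqrt(min(rowSums(sweep(-close, 2L, p, "+")^2)))
}

#' Per-vertex distance from one surface to another
#'
#' Minimum Euclidean distance from each vertex of `mesh` to the triangles of
#' `target` (exact closest-point-on-triangle, brute force over faces).
#'
#' @param mesh,target [surface_model()]s.
#' @return Numeric vector, one distance (mm) per vertex of `mesh`.
#' @export
vertex_surface_distances <- function(mesh, target) {
  if (!nrow(target$faces)) stop_usage("target mesh has no faces")
  vapply(seq_len(nrow(mesh$vertices)), function(i) {
    .point_mesh_distance(mesh$vertices[i, ], target$vertices, target$faces)
  }, numeric(1))
}

#' Color-bin classification of surface distances
#'
#' Bins per-vertex surface distances into the conventional 0.4 mm color
#' classes used in superimposition color maps: green (0-0.4 mm), yellow
#' (0.4-0.8), orange (0.8-1.2), red (1.2-1.6), purple (1.6-2.0), and
#' `"beyond"` for anything larger.
#'
#' @param distances_mm Numeric vector of distances.
#' @return Factor with levels green, yellow, orange, red, purple, beyond.
#' @export
movement_color_bins <- function(distances_mm) {
  cut(distances_mm, breaks = c(-Inf, 0.4, 0.8, 1.2, 1.6, 2.0, Inf),
      labels = c("green", "yellow", "orange", "red", "purple", "beyond"))
}

#' Write per-vertex color-bin labels
#'
#' CSV with the vertex index, its coordinates, the distance and its color
#' class.
#'
#' @param mesh A [surface_model()].
#' @param distances_mm Per-vertex distances, as from
#'   [vertex_surface_distances()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_color_bins_csv <- function(mesh, distances_mm, path) {
  df <- data.frame(vertex = seq_len(nrow(mesh$vertices)),
                   x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                   z = mesh$vertices[, 3], distance_mm = distances_mm,
                   class = as.character(movement_color_bins(distances_mm)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
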
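#' Valve mesh objects
#'
#' A `valve_mesh` is an indexed triangle surface of a single shell valve in
#' the standard hinge-aligned axes convention: x = anterior-posterior,
#' y = dorso-ventral, z = commissure-normal (the half-width direction).
#' Units are millimetres. Two roles are distinguished: `"shell_solid"`, the
#' closed surface bounding the shell material of one valve, and
#' `"interior_surface"`, the open surface of the shell interior (soft tissue
#' side) with a single boundary loop at the commissure.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param role `"shell_solid"` or `"interior_surface"`.
#' @return an object of class `valve_mesh`.
#' @export
valve_mesh <- function(vertices, faces,
                       role = c("shell_solid", "interior_surface")) {
  role <- match.arg(role)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces, role = role),
            class = "valve_mesh")
}

#' @export
print.valve_mesh <- function(x, ...) {
  cat(sprintf("valve_mesh (%s): %d vertices, %d faces\n",
              x$role, nrow(x$vertices), nrow(x$faces)))
  ext <- apply(x$vertices, 2L, range)
  cat(sprintf("  extents (mm): x %.4g  y %.4g  z %.4g\n",
              diff(ext[, 1]), diff(ext[, 2]), diff(ext[, 3])))
  invisible(x)
}

# ---- low-level geometry -----------------------------------------------------

triangle_corners <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  list(a = V[F[, 1L], , drop = FALSE],
       b = V[F[, 2L], , drop = FALSE],
       c = V[F[, 3L], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

triangle_areas <- function(mesh) {
  tc <- triangle_corners(mesh)
  n <- cross3(tc$b - tc$a, tc$c - tc$a)
  0.5 * sqrt(rowSums(n * n))
}

#' Signed volume of a triangle mesh
#'
#' Sum of signed tetrahedra volumes, one tetrahedron per triangle with its
#' apex at the origin: (1/6) * sum over faces of v0 . (v1 x v2). For a
#' closed, consistently outward-oriented mesh this is the exact enclosed
#' volume; for an open mesh the value depends on the position of the origin
#' (see [internal_volume()] for how that is exploited).
#'
#' @param mesh a [valve_mesh()].
#' @return signed volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  tc <- triangle_corners(mesh)
  sum(rowSums(tc$a * cross3(tc$b, tc$c))) / 6
}

#' Axis-aligned bounding-box extents
#'
#' Extents of the mesh along the standard axes: length along x
#' (anterior-posterior), height along y (dorso-ventral), half-width along z
#' (commissure-normal). Meshes are assumed pre-aligned to the hinge axis.
#'
#' @param mesh a [valve_mesh()].
#' @return named numeric vector `c(length_x, height_y, halfwidth_z)` in mm.
#' @export
aligned_extents <- function(mesh) {
  V <- mesh$vertices
  if (nrow(V) < 3L) stop("degenerate geometry: fewer than 3 vertices")
  # reject collinear vertex sets (zero area in every projection)
  ctr <- colMeans(V)
  Vc <- sweep(V, 2L, ctr)
  sv <- svd(Vc, nu = 0L, nv = 0L)$d
  if (sum(sv > max(sv) * 1e-12) < 2L) {
    stop("degenerate geometry: vertices are collinear")
  }
  ext <- apply(V, 2L, function(col) diff(range(col)))
  c(length_x = ext[1L], height_y = ext[2L], halfwidth_z = ext[3L])
}

#' Mirror a valve across the commissural plane
#'
#' Reflects z to -z (the right-valve to left-valve operation for equivalve
#' taxa) and flips the face winding so outward normals stay outward. All
#' downstream metrics of a mirrored valve equal those of the original.
#'
#' @param mesh a [valve_mesh()].
#' @return the mirrored `valve_mesh`.
#' @export
mirror_valve <- function(mesh) {
  mesh$vertices[, 3L] <- -mesh$vertices[, 3L]
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

# ---- edge bookkeeping -------------------------------------------------------

# undirected edge table: one row per face-edge occurrence
face_edges <- function(faces) {
  m <- nrow(faces)
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  lo <- pmin(e[, 1L], e[, 2L])
  hi <- pmax(e[, 1L], e[, 2L])
  list(from = e[, 1L], to = e[, 2L],
       key = paste(lo, hi, sep = "-"),
       face = rep.int(seq_len(m), 3L))
}

#' Validate a valve mesh
#'
#' Reports exact properties of the face-edge incidence structure: whether
#' every edge is shared by exactly two faces (closed), by at most two
#' (manifold), whether shared edges are traversed in opposite directions by
#' their two faces (consistently oriented), the number of open boundary
#' loops and connected components, and the total surface area. A
#' `shell_solid` mesh failing closed + manifold, or any mesh with more than
#' one connected component, is flagged for review.
#'
#' @param mesh a [valve_mesh()].
#' @return a list of class `mesh_validity`.
#' @export
validate_mesh <- function(mesh) {
  fe <- face_edges(mesh$faces)
  counts <- table(fe$key)
  closed <- all(counts == 2L)
  manifold <- all(counts <= 2L)
  boundary_keys <- names(counts)[counts == 1L]

  # orientation: each directed edge of a consistently wound mesh is unique
  dir_keys <- paste(fe$from, fe$to, sep = ">")
  oriented <- manifold && !anyDuplicated(dir_keys)

  n_loops <- count_boundary_loops(boundary_keys)
  n_comp <- count_components(mesh)
  flagged <- (mesh$role == "shell_solid" && !(closed && manifold)) ||
    n_comp > 1L
  structure(list(closed = closed, manifold = manifold, oriented = oriented,
                 n_boundary_loops = n_loops, n_components = n_comp,
                 area = sum(triangle_areas(mesh)), flagged = flagged),
            class = "mesh_validity")
}

#' @export
print.mesh_validity <- function(x, ...) {
  cat(sprintf(paste0("mesh validity: closed=%s manifold=%s oriented=%s ",
                     "boundary_loops=%d components=%d area=%.4g%s\n"),
              x$closed, x$manifold, x$oriented, x$n_boundary_loops,
              x$n_components, x$area, if (x$flagged) "  [FLAGGED]" else ""))
  invisible(x)
}

count_boundary_loops <- function(boundary_keys) {
  if (length(boundary_keys) == 0L) return(0L)
  ends <- matrix(as.integer(unlist(strsplit(boundary_keys, "-", fixed = TRUE))),
                 ncol = 2L, byrow = TRUE)
  verts <- sort(unique(as.vector(ends)))
  parent <- seq_along(verts)
  idx <- match(as.vector(ends), verts)
  dim(idx) <- dim(ends)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(idx))) {
    a <- find(idx[r, 1L]); b <- find(idx[r, 2L])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_along(verts), find, integer(1L))))
}

count_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  used <- sort(unique(as.vector(mesh$faces)))
  if (length(used) == 0L) return(0L)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  F <- mesh$faces
  for (r in seq_len(nrow(F))) {
    a <- find(F[r, 1L]); b <- find(F[r, 2L]); c <- find(F[r, 3L])
    if (a != b) parent[a] <- b
    b <- find(F[r, 2L])
    if (b != c) parent[b] <- c
  }
  length(unique(vapply(used, find, integer(1L))))
}

# ---- load-time cleaning -----------------------------------------------------

# merge duplicate vertices within tol (default 1e-6 x bbox diagonal)
merge_vertices <- function(vertices, faces, tol = NULL) {
  if (is.null(tol)) {
    diag_len <- sqrt(sum(apply(vertices, 2L, function(v) diff(range(v)))^2))
    tol <- 1e-6 * max(diag_len, .Machine$double.eps)
  }
  key <- paste(round(vertices[, 1L] / tol),
               round(vertices[, 2L] / tol),
               round(vertices[, 3L] / tol))
  first <- !duplicated(key)
  new_id <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  faces[] <- new_id[faces]
  list(vertices = vertices, faces = faces)
}

drop_degenerate <- function(vertices, faces, area_floor = 1e-12) {
  if (nrow(faces) == 0L) return(faces)
  dup <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
    faces[, 1L] == faces[, 3L]
  faces <- faces[!dup, , drop = FALSE]
  if (nrow(faces) == 0L) return(faces)
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c <- vertices[faces[, 3L], , drop = FALSE]
  n <- cross3(b - a, c - a)
  areas <- 0.5 * sqrt(rowSums(n * n))
  faces[areas > area_floor, , drop = FALSE]
}

# make winding consistent by flood fill across shared edges; for closed
# meshes, flip globally so the total signed volume is positive
orient_consistent <- function(vertices, faces) {
  m <- nrow(faces)
  if (m == 0L) return(faces)
  fe <- face_edges(faces)
  # adjacency: faces sharing an undirected edge
  ord <- order(fe$key)
  key_s <- fe$key[ord]
  face_s <- fe$face[ord]
  same_dir_s <- (fe$from < fe$to)[ord]  # direction of traversal of the edge
  runs <- rle(key_s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  adj <- vector("list", m)
  rel <- vector("list", m)  # TRUE if neighbour traverses edge in same direction
  for (k in seq_along(starts)) {
    if (runs$lengths[k] != 2L) next
    i <- face_s[starts[k]]; j <- face_s[ends[k]]
    same <- same_dir_s[starts[k]] == same_dir_s[ends[k]]
    adj[[i]] <- c(adj[[i]], j); rel[[i]] <- c(rel[[i]], same)
    adj[[j]] <- c(adj[[j]], i); rel[[j]] <- c(rel[[j]], same)
  }
  flip <- rep(NA, m)
  for (seed in seq_len(m)) {
    if (!is.na(flip[seed])) next
    flip[seed] <- FALSE
    queue <- seed
    while (length(queue)) {
      f <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[f]]
      if (is.null(nb)) next
      for (t in seq_along(nb)) {
        g <- nb[t]
        # consistent winding: shared edge traversed in opposite directions
        want <- if (rel[[f]][t]) !flip[f] else flip[f]
        if (is.na(flip[g])) {
          flip[g] <- want
          queue <- c(queue, g)
        }
      }
    }
  }
  faces[flip, ] <- faces[flip, c(1L, 3L, 2L), drop = FALSE]
  # global orientation: outward normals give positive enclosed volume
  fe2 <- face_edges(faces)
  if (all(table(fe2$key) == 2L)) {
    v6 <- sum(rowSums(vertices[faces[, 1L], , drop = FALSE] *
                        cross3(vertices[faces[, 2L], , drop = FALSE],
                               vertices[faces[, 3L], , drop = FALSE])))
    if (v6 < 0) faces <- faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  faces
}

clean_mesh <- function(vertices, faces, role) {
  if (nrow(faces) == 0L || nrow(vertices) == 0L) {
    stop("empty mesh: no geometry found in file")
  }
  mv <- merge_vertices(vertices, faces)
  faces <- drop_degenerate(mv$vertices, mv$faces)
  if (nrow(faces) == 0L) stop("empty mesh: all faces degenerate")
  faces <- orient_consistent(mv$vertices, faces)
  keep <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(mv$vertices))
  remap[keep] <- seq_along(keep)
  faces[] <- remap[faces]
  valve_mesh(mv$vertices[keep, , drop = FALSE], faces, role)
}

# ---- readers ----------------------------------------------------------------

#' Read a valve mesh from STL, OBJ or PLY
#'
#' Supports ASCII and binary STL, Wavefront OBJ (polygonal faces are fan
#' triangulated) and ASCII PLY. On load, duplicate vertices are merged
#' within 1e-6 of the bounding-box diagonal, zero-area triangles are
#' dropped, and the winding is made consistent (outward for closed meshes).
#' Coordinates are taken as millimetres as stored.
#'
#' @param path path to the mesh file.
#' @param role mesh role, `"shell_solid"` (default) or `"interior_surface"`.
#' @return a [valve_mesh()].
#' @export
read_mesh <- function(path, role = c("shell_solid", "interior_surface")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw_mesh <- switch(ext,
    stl = read_stl(path),
    obj = read_obj(path),
    ply = read_ply(path),
    stop("unsupported mesh format: .", ext,
         " (supported: .stl, .obj, .ply)")
  )
  clean_mesh(raw_mesh$vertices, raw_mesh$faces, role)
}

stl_is_binary <- function(path) {
  size <- file.info(path)$size
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  identical(size, 84 + 50 * as.numeric(ntri))
}

read_stl <- function(path) {
  if (stl_is_binary(path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80L))
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    rec <- readBin(con, "raw", 50L * ntri)
    if (length(rec) < 50L * ntri) stop("truncated binary STL: ", path)
    dim(rec) <- c(50L, ntri)
    vals <- readBin(as.vector(rec[1:48, ]), "numeric", size = 4L,
                    n = 12L * ntri, endian = "little")
    dim(vals) <- c(12L, ntri)
    verts <- t(vals[4:12, , drop = FALSE])  # drop normals
    dim(verts) <- c(ntri, 9L)
    vertices <- rbind(verts[, 1:3, drop = FALSE],
                      verts[, 4:6, drop = FALSE],
                      verts[, 7:9, drop = FALSE])
    # interleave back to per-triangle order
    idx <- as.vector(t(matrix(seq_len(3L * ntri), ntri, 3L)))
    vertices <- vertices[idx, , drop = FALSE]
  } else {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vlines) == 0L) stop("empty mesh: no geometry found in file")
    nums <- strsplit(trimws(vlines), "\\s+")
    vertices <- t(vapply(nums, function(x) as.numeric(x[2:4]), numeric(3L)))
  }
  ntri <- nrow(vertices) / 3L
  if (ntri != floor(ntri)) stop("malformed STL: vertex count not divisible by 3")
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(flines) == 0L) {
    stop("empty mesh: no geometry found in file")
  }
  vertices <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                       function(x) as.numeric(x[2:4]), numeric(3L)))
  faces_list <- lapply(strsplit(trimws(flines), "\\s+"), function(x) {
    ids <- as.integer(vapply(x[-1L],
                             function(tok) strsplit(tok, "/", fixed = TRUE)[[1L]][1L],
                             character(1L)))
    if (length(ids) < 3L) stop("malformed OBJ face: ", paste(x, collapse = " "))
    # fan triangulation of polygons
    cbind(ids[1L], ids[seq(2L, length(ids) - 1L)], ids[seq(3L, length(ids))])
  })
  list(vertices = vertices, faces = do.call(rbind, faces_list))
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1L]) != "ply") {
    stop("not a PLY file: ", path)
  }
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("malformed PLY header: ", path)
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (any(grepl("^format\\s+binary", hdr))) {
    stop("binary PLY is not supported; convert to ASCII PLY, OBJ or STL")
  }
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex\\s", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face\\s", hdr, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf) || nv == 0L || nf == 0L) {
    stop("empty mesh: no geometry found in file")
  }
  body <- trimws(lines[(hdr_end + 1L):length(lines)])
  body <- body[nzchar(body)]
  vtok <- strsplit(body[seq_len(nv)], "\\s+")
  vertices <- t(vapply(vtok, function(x) as.numeric(x[1:3]), numeric(3L)))
  ftok <- strsplit(body[nv + seq_len(nf)], "\\s+")
  faces_list <- lapply(ftok, function(x) {
    cnt <- as.integer(x[1L])
    ids <- as.integer(x[1L + seq_len(cnt)]) + 1L  # PLY is 0-based
    cbind(ids[1L], ids[seq(2L, cnt - 1L)], ids[seq(3L, cnt)])
  })
  list(vertices = vertices, faces = do.call(rbind, faces_list))
}

# ---- writers ----------------------------------------------------------------

#' Write a valve mesh to OBJ or ASCII STL
#'
#' @param mesh a [valve_mesh()].
#' @param path output path; format chosen by extension (`.obj` or `.stl`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    v <- sprintf("v %.9g %.9g %.9g",
                 mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L])
    f <- sprintf("f %d %d %d",
                 mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L])
    writeLines(c("# valvemorph mesh", v, f), path)
  } else if (ext == "stl") {
    tc <- triangle_corners(mesh)
    n <- cross3(tc$b - tc$a, tc$c - tc$a)
    len <- sqrt(rowSums(n * n))
    len[len == 0] <- 1
    n <- n / len
    body <- paste0(
      sprintf(" facet normal %.9g %.9g %.9g\n  outer loop\n", n[, 1L], n[, 2L], n[, 3L]),
      sprintf("   vertex %.9g %.9g %.9g\n", tc$a[, 1L], tc$a[, 2L], tc$a[, 3L]),
      sprintf("   vertex %.9g %.9g %.9g\n", tc$b[, 1L], tc$b[, 2L], tc$b[, 3L]),
      sprintf("   vertex %.9g %.9g %.9g\n", tc$c[, 1L], tc$c[, 2L], tc$c[, 3L]),
      "  endloop\n endfacet")
    writeLines(c("solid valvemorph", body, "endsolid valvemorph"), path)
  } else {
    stop("unsupported output format: .", ext, " (supported: .obj, .stl)")
  }
  invisible(path)
}

# ---- reference solids -------------------------------------------------------

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; a convenient closed,
#' manifold test solid whose volume converges to 4*pi*r^3/3.
#'
#' @param subdiv number of 4-to-1 subdivision rounds (0 = icosahedron).
#' @param radius sphere radius in mm.
#' @return a [valve_mesh()] with role `shell_solid`.
#' @export
make_icosphere <- function(subdiv = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      V <<- rbind(V, (V[i, ] + V[j, ]) / 2)
      id <- nrow(V)
      mid_cache[[key]] <- id
      id
    }
    Fnew <- matrix(0L, 4L * nrow(F), 3L)
    for (r in seq_len(nrow(F))) {
      a <- F[r, 1L]; b <- F[r, 2L]; c <- F[r, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      Fnew[(4L * r - 3L):(4L * r), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    F <- Fnew
  }
  V <- V / sqrt(rowSums(V * V)) * radius
  valve_mesh(V, F, "shell_solid")
}

#' Uniformly scale a mesh
#'
#' @param mesh a [valve_mesh()].
#' @param s positive scale factor.
#' @return the scaled mesh.
#' @export
scale_mesh <- function(mesh, s) {
  stopifnot(is.numeric(s), length(s) == 1L, s > 0)
  mesh$vertices <- mesh$vertices * s
  mesh
}
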
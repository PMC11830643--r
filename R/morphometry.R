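#' @section Morphometric variables:
#' Three variables summarise each specimen: proportional shell volume
#' (pSV = TSV / (TSV + TIV)), a proxy for shell thickness and weight
#' investment; shell length (SL), the anterior-posterior bounding-box
#' dimension; and the cross-sectional aspect ratio (XS = width / height),
#' where width is twice the single-valve half-width because these taxa are
#' equivalve. Volumes are measured on single valves and doubled to give the
#' totals TSV and TIV.
#' @name morphometry
#' @keywords internal
NULL

# area-weighted centroid of a triangulated surface
surface_centroid <- function(mesh) {
  tc <- triangle_corners(mesh)
  areas <- triangle_areas(mesh)
  centroids <- (tc$a + tc$b + tc$c) / 3
  colSums(centroids * areas) / sum(areas)
}

# ordered boundary loops as lists of vertex indices; relies on consistent
# winding (boundary directed edges then form directed cycles)
boundary_loop_vertices <- function(mesh) {
  fe <- face_edges(mesh$faces)
  counts <- table(fe$key)
  open_keys <- names(counts)[counts == 1L]
  if (length(open_keys) == 0L) return(list())
  sel <- fe$key %in% open_keys
  from <- fe$from[sel]
  to <- fe$to[sel]
  succ <- new.env(hash = TRUE)
  for (i in seq_along(from)) succ[[as.character(from[i])]] <- to[i]
  loops <- list()
  visited <- character(0L)
  for (start in from) {
    skey <- as.character(start)
    if (skey %in% visited) next
    loop <- integer(0L)
    v <- start
    repeat {
      loop <- c(loop, v)
      visited <- c(visited, as.character(v))
      v <- succ[[as.character(v)]]
      if (is.null(v) || v == start) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Internal (soft tissue + water) volume of one valve
#'
#' The interior surface is open at the commissure, so its signed-tetrahedra
#' sum depends on how the opening is treated. Two modes are provided:
#'
#' * `"capped"` (default): the boundary loop is closed with a triangle fan
#'   to the loop's own centroid and the signed volume of the resulting
#'   closed mesh is taken. This is the geometrically interpretable volume
#'   of the cavity below the commissural plane.
#' * `"origin_fan"`: the surface is translated so its area-weighted
#'   centroid sits at the origin and the raw signed-tetrahedra sum is
#'   taken. This is equivalent to closing the opening with a fan of
#'   triangles to the surface centroid; on a hemisphere of radius r it
#'   yields pi r^3 / 2 rather than the capped 2 pi r^3 / 3, the difference
#'   being the cone from the centroid to the boundary circle.
#'
#' The absolute value is returned in both modes.
#'
#' @param interior a [valve_mesh()] with role `interior_surface` and exactly
#'   one boundary loop (a closed surface is accepted with a warning).
#' @param mode `"capped"` or `"origin_fan"`.
#' @return volume in mm^3.
#' @export
internal_volume <- function(interior, mode = c("capped", "origin_fan")) {
  mode <- match.arg(mode)
  loops <- boundary_loop_vertices(interior)
  if (length(loops) > 1L) {
    stop("ambiguous opening: interior surface has ", length(loops),
         " boundary loops (expected 1)")
  }
  if (length(loops) == 0L) {
    if (interior$role == "interior_surface") {
      warning("interior_surface mesh is closed; treating as closed solid")
    }
    return(abs(signed_volume(interior)))
  }
  if (mode == "origin_fan") {
    ctr <- surface_centroid(interior)
    shifted <- interior
    shifted$vertices <- sweep(interior$vertices, 2L, ctr)
    return(abs(signed_volume(shifted)))
  }
  # capped: fan the boundary loop to its own centroid, then closed volume
  loop <- loops[[1L]]
  ctr <- colMeans(interior$vertices[loop, , drop = FALSE])
  V <- rbind(interior$vertices, ctr)
  apex <- nrow(V)
  k <- length(loop)
  # boundary loop runs along open directed edges; fan apex-first keeps the
  # cap winding opposite to the loop, i.e. consistent with the surface
  cap <- cbind(apex, loop[c(seq(2L, k), 1L)], loop)
  closed <- valve_mesh(V, rbind(interior$faces, cap), "shell_solid")
  abs(signed_volume(closed))
}

#' Compute the full set of valve metrics
#'
#' Measures one specimen from its closed shell-solid mesh and its open
#' interior surface: valve shell volume by signed tetrahedra, valve internal
#' volume via [internal_volume()], the doubled totals TSV and TIV
#' (equivalve taxa), pSV = TSV / (TSV + TIV), shell length SL (x extent),
#' height (y extent), width (twice the z extent), XS = width / height, and
#' log shell length in the configured base.
#'
#' @param shell_solid closed, manifold [valve_mesh()] of the shell material.
#' @param interior open [valve_mesh()] of the shell interior; pass
#'   `NULL` only if `interior_from_solid` is unavailable (not implemented).
#' @param mirror if `TRUE`, both meshes are mirrored (right valve read in as
#'   a left valve) before measurement; metrics are invariant to this.
#' @param internal_mode passed to [internal_volume()].
#' @param log_base base for logSL, `10` (default) or `exp(1)`.
#' @return a one-row data.frame of class `valve_metrics` with columns
#'   `valve_shell_volume`, `valve_internal_volume`, `TSV`, `TIV`, `pSV`,
#'   `SL`, `height`, `width`, `XS`, `logSL`, `internal_mode`.
#' @export
compute_metrics <- function(shell_solid, interior,
                            mirror = FALSE,
                            internal_mode = c("capped", "origin_fan"),
                            log_base = 10) {
  internal_mode <- match.arg(internal_mode)
  rep <- validate_mesh(shell_solid)
  if (!(rep$closed && rep$manifold)) {
    stop("shell_solid mesh is not closed+manifold; refusing to measure.\n",
         sprintf("  closed=%s manifold=%s boundary_loops=%d",
                 rep$closed, rep$manifold, rep$n_boundary_loops))
  }
  if (mirror) {
    shell_solid <- mirror_valve(shell_solid)
    interior <- mirror_valve(interior)
  }
  vsv <- abs(signed_volume(shell_solid))
  viv <- internal_volume(interior, mode = internal_mode)
  ext <- aligned_extents(shell_solid)
  tsv <- 2 * vsv
  tiv <- 2 * viv
  sl <- unname(ext[1L])
  height <- unname(ext[2L])
  width <- 2 * unname(ext[3L])
  out <- data.frame(
    valve_shell_volume = vsv,
    valve_internal_volume = viv,
    TSV = tsv,
    TIV = tiv,
    pSV = tsv / (tsv + tiv),
    SL = sl,
    height = height,
    width = width,
    XS = width / height,
    logSL = log(sl, base = log_base),
    internal_mode = internal_mode,
    stringsAsFactors = FALSE
  )
  class(out) <- c("valve_metrics", "data.frame")
  out
}
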
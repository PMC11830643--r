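# fixtures built in code: canonical solids and mesh-file writers

# axis-aligned cube [0,s]^3 as 12 outward-wound triangles
cube_mesh <- function(s = 1) {
  V <- as.matrix(expand.grid(x = c(0, s), y = c(0, s), z = c(0, s)))
  dimnames(V) <- NULL
  F <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = 0 (normal -z)
    c(5, 6, 8), c(5, 8, 7),   # z = s
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 7, 8), c(3, 8, 4),   # y = s
    c(1, 5, 7), c(1, 7, 3),   # x = 0
    c(2, 4, 8), c(2, 8, 6)    # x = s
  )
  valve_mesh(V, F, "shell_solid")
}

write_ascii_stl <- function(mesh, path) write_mesh(mesh, path)

# minimal binary STL writer (little-endian, 80-byte header, float32 records)
write_binary_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  ntri <- nrow(mesh$faces)
  writeBin(as.integer(ntri), con, size = 4L, endian = "little")
  V <- mesh$vertices
  F <- mesh$faces
  for (i in seq_len(ntri)) {
    tri <- V[F[i, ], , drop = FALSE]
    nrm <- c(0, 0, 0)  # readers recompute normals
    writeBin(as.numeric(c(nrm, t(tri))), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
  invisible(path)
}

write_ascii_ply <- function(mesh, path) {
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(mesh$vertices)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(mesh$faces)),
           "property list uchar int vertex_indices", "end_header")
  v <- sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
               mesh$vertices[, 3])
  f <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
               mesh$faces[, 3] - 1L)
  writeLines(c(hdr, v, f), path)
}

# open unit hemisphere surface (z >= 0), boundary circle in z = 0
hemisphere_mesh <- function(r = 1, n = 96L, m = 32L, role = "interior_surface") {
  hp <- shell_params(c(r, r, r), thickness = r / 2, subdiv = m)
  valve <- make_valve(hp)
  # the interior of a (r, r, r) valve with inner axes r/2 is a hemisphere of
  # radius r/2; easier to scale it up than rebuild the grid
  interior <- valve$interior
  interior$vertices <- interior$vertices * 2
  interior$role <- role
  interior
}

# four-row trait table, one specimen per family
trait_fixture <- function() {
  data.frame(
    taxon = c("Asta_x", "Card_x", "Cras_x", "Vene_x"),
    family = c("Astartidae", "Carditidae", "Crassatellidae", "Veneridae"),
    siphonate = c(FALSE, FALSE, FALSE, TRUE),
    habit = c("infaunal", "infaunal", "infaunal", "infaunal"),
    sinus_depth_fraction = c(NA, NA, NA, 0.5),
    SL = c(20, 30, 40, 45),
    stringsAsFactors = FALSE
  )
}

small_cohort_config <- function(seed = 11L, mode = "independent") {
  fams <- data.frame(
    family = c("Astartidae", "Carditidae", "Crassatellidae", "Veneridae"),
    n = c(8L, 12L, 10L, 20L),
    psv_logit_mean = stats::qlogis(c(0.32, 0.35, 0.38, 0.15)),
    psv_logit_sd = c(0.20, 0.45, 0.30, 0.90),
    logsl_mean = c(1.25, 1.30, 1.35, 1.55),
    logsl_sd = c(0.28, 0.30, 0.35, 0.18),
    xs_mean = c(0.95, 1.05, 0.90, 1.00),
    xs_sd = c(0.12, 0.20, 0.12, 0.15),
    stringsAsFactors = FALSE
  )
  cohort_config(families = fams, trait_mode = mode, seed = seed)
}
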
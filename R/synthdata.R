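#' Synthetic data generators
#'
#' Every input the pipeline needs can be generated in code: parametric
#' hemi-ellipsoid valve meshes with analytically known volumes, birth-death
#' trees, Brownian tip traits, and full synthetic cohorts emulating the
#' statistical structure of the study system (two clades of families with
#' family-level differences in pSV, log shell length more variable in the
#' less diverse clade, XS near 1, strong phylogenetic signal).
#'
#' @name synthdata
#' @keywords internal
NULL

#' Shell parameters for a synthetic hemi-ellipsoid valve
#'
#' The valve is the solid between two nested hemi-ellipsoids (z >= 0
#' halves) closed by an annular commissural face at z = 0. Outer semi-axes
#' are `(a, b, c)`; the shell has uniform thickness `t`, so the inner
#' semi-axes are `(a - t, b - t, c - t)`. The analytic proportional shell
#' volume is `(abc - a'b'c') / (abc)` (the hemisphere factor 2*pi/3 and the
#' valve doubling both cancel in the ratio).
#'
#' @param axes outer semi-axes `c(a, b, c)` in mm (x = half-length,
#'   y = half-height, z = half-width of one valve).
#' @param thickness uniform shell thickness t in mm, `0 < t < min(a, b, c)`
#'   (inner semi-axes `axes - t`); alternatively give `inner_axes`.
#' @param inner_axes explicit inner semi-axes, each strictly inside the
#'   corresponding outer semi-axis (overrides `thickness`).
#' @param subdiv subdivision level: number of latitude rings between the
#'   commissure and the pole (azimuth steps are `3 * subdiv`). Default 32.
#' @return a list of class `shell_params` with the axes, thickness, inner
#'   axes, subdivision and `analytic_pSV`.
#' @export
shell_params <- function(axes, thickness = NULL, inner_axes = NULL,
                         subdiv = 32L) {
  stopifnot(length(axes) == 3L, all(axes > 0))
  if (is.null(inner_axes)) {
    if (is.null(thickness)) stop("give either thickness or inner_axes")
    stopifnot(length(thickness) == 1L)
    if (thickness <= 0 || thickness >= min(axes)) {
      stop("thickness must lie strictly between 0 and min(axes)")
    }
    inner_axes <- axes - thickness
  } else {
    stopifnot(length(inner_axes) == 3L)
    if (any(inner_axes <= 0) || any(inner_axes >= axes)) {
      stop("inner_axes must lie strictly inside the outer axes")
    }
    thickness <- NA_real_
  }
  subdiv <- as.integer(subdiv)
  if (subdiv < 2L) stop("subdivision too low to close the annulus (need >= 2)")
  psv <- (prod(axes) - prod(inner_axes)) / prod(axes)
  structure(list(axes = axes, thickness = thickness,
                 inner_axes = inner_axes,
                 subdiv = subdiv, analytic_pSV = psv),
            class = "shell_params")
}

# open hemi-ellipsoid surface grid: latitude rings i = 0..m-1 at
# phi = i * (pi/2) / m, plus the pole; n azimuth steps per ring
hemi_surface <- function(a, b, c_ax, n, m) {
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  phi <- (seq_len(m) - 1L) * (pi / 2) / m
  V <- matrix(0, n * m + 1L, 3L)
  for (i in seq_len(m)) {
    rows <- (i - 1L) * n + seq_len(n)
    V[rows, 1L] <- a * cos(phi[i]) * cos(theta)
    V[rows, 2L] <- b * cos(phi[i]) * sin(theta)
    V[rows, 3L] <- c_ax * sin(phi[i])
  }
  pole <- n * m + 1L
  V[pole, ] <- c(0, 0, c_ax)
  faces <- vector("list", m)
  jn <- c(seq.int(2L, n), 1L)  # j + 1 cyclic
  for (i in seq_len(m - 1L)) {
    lo <- (i - 1L) * n + seq_len(n)
    hi <- i * n + seq_len(n)
    faces[[i]] <- rbind(cbind(lo, lo[jn], hi[jn]),
                        cbind(lo, hi[jn], hi))
  }
  top <- (m - 1L) * n + seq_len(n)
  faces[[m]] <- cbind(top, top[jn], pole)
  list(V = V, F = do.call(rbind, faces))
}

#' Generate a synthetic valve: shell solid plus interior surface
#'
#' Builds the closed shell-solid mesh (region between the outer and inner
#' hemi-ellipsoids, closed by the commissural annulus at z = 0) and the
#' open interior surface (the inner hemi-ellipsoid alone, one boundary
#' loop). Both follow the standard axes convention and pass
#' [validate_mesh()] as closed+manifold (solid) and single-loop (interior).
#'
#' @param params a [shell_params()] object.
#' @return list with elements `shell` and `interior` ([valve_mesh()]
#'   objects) and `params`.
#' @export
make_valve <- function(params) {
  stopifnot(inherits(params, "shell_params"))
  m <- params$subdiv
  n <- 3L * m
  a <- params$axes[1L]; b <- params$axes[2L]; c_ax <- params$axes[3L]
  ai <- params$inner_axes[1L]; bi <- params$inner_axes[2L]
  ci <- params$inner_axes[3L]

  outer <- hemi_surface(a, b, c_ax, n, m)
  inner <- hemi_surface(ai, bi, ci, n, m)
  off <- nrow(outer$V)
  V <- rbind(outer$V, inner$V)
  jn <- c(seq.int(2L, n), 1L)
  o0 <- seq_len(n)            # outer commissural ring
  i0 <- off + seq_len(n)      # inner commissural ring
  annulus <- rbind(cbind(o0, i0, o0[jn]),
                   cbind(o0[jn], i0, i0[jn]))
  faces <- rbind(outer$F, inner$F + off, annulus)
  # orientation assembled loosely; clean_mesh makes winding consistent and
  # outward (positive enclosed volume), and merges the duplicated pole ring
  shell <- clean_mesh(V, faces, "shell_solid")
  interior <- clean_mesh(inner$V, inner$F, "interior_surface")
  list(shell = shell, interior = interior, params = params)
}

# thickness giving a target analytic pSV for given outer semi-axes
thickness_for_psv <- function(axes, psv) {
  stopifnot(psv > 0, psv < 1)
  f <- function(t) (prod(axes) - prod(axes - t)) / prod(axes) - psv
  stats::uniroot(f, c(min(axes) * 1e-9, min(axes) * (1 - 1e-9)),
                 tol = .Machine$double.eps^0.5)$root
}

#' Simulate a birth-death tree conditioned on the number of tips
#'
#' Thin, seed-explicit wrapper around [ape::rphylo()] (complete
#' birth-death simulation conditioned on `n_tips` extant taxa).
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth speciation rate (> death).
#' @param death extinction rate (>= 0).
#' @param seed integer seed; the tree is reproducible from it.
#' @return a `phylo` object with branch lengths.
#' @export
simulate_tree <- function(n_tips, birth = 0.4, death = 0.1, seed = NULL) {
  stopifnot(n_tips >= 2L, birth > death, death >= 0)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(100L)) {
    tree <- tryCatch(ape::rphylo(n_tips, birth = birth, death = death),
                     error = function(e) NULL)
    if (!is.null(tree)) return(check_phylogeny(tree))
  }
  stop("birth-death simulation failed after 100 attempts")
}

#' Simulate a Brownian-motion trait on a tree
#'
#' The trait change along each branch is drawn from
#' Normal(0, sigma2 * branch length) and summed root-to-tip, so tip
#' covariance equals sigma2 times the phylogenetic covariance matrix.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param sigma2 Brownian rate (> 0).
#' @param root_value trait value at the root.
#' @param seed integer seed.
#' @return named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_value = 0, seed = NULL) {
  check_phylogeny(tree)
  stopifnot(sigma2 > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  vals <- numeric(n + tr$Nnode)
  vals[n + 1L] <- root_value
  inc <- stats::rnorm(nrow(tr$edge), 0, sqrt(sigma2 * tr$edge.length))
  for (k in seq_len(nrow(tr$edge))) {
    vals[tr$edge[k, 2L]] <- vals[tr$edge[k, 1L]] + inc[k]
  }
  stats::setNames(vals[seq_len(n)], tree$tip.label)
}

#' Default cohort configuration
#'
#' Family-level parameters emulating the study system: sample sizes
#' 12 / 72 / 40 / 126 (Astartidae / Carditidae / Crassatellidae /
#' Veneridae); archiheterodont pSV well above venerid pSV (simulated on the
#' logit scale to respect the (0, 1] bounds) with venerids the most
#' variable; log10 shell length largest but least variable in venerids and
#' most variable in crassatellids; XS near 1 everywhere with carditids the
#' most variable.
#'
#' @param families data.frame with columns `family`, `n`,
#'   `psv_logit_mean`, `psv_logit_sd`, `logsl_mean`, `logsl_sd`,
#'   `xs_mean`, `xs_sd`; the default encodes the structure above.
#' @param birth,death birth-death rates for the per-family subtrees.
#' @param trait_mode `"independent"` (iid draws per family) or
#'   `"brownian"` (Brownian motion on the tree plus family mean shifts).
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(families = NULL, birth = 0.4, death = 0.1,
                          trait_mode = c("independent", "brownian"),
                          seed = 42L) {
  trait_mode <- match.arg(trait_mode)
  if (is.null(families)) {
    families <- data.frame(
      family = c("Astartidae", "Carditidae", "Crassatellidae", "Veneridae"),
      n = c(12L, 72L, 40L, 126L),
      psv_logit_mean = stats::qlogis(c(0.32, 0.35, 0.38, 0.15)),
      psv_logit_sd = c(0.20, 0.45, 0.30, 0.90),
      logsl_mean = c(1.25, 1.30, 1.35, 1.55),
      logsl_sd = c(0.28, 0.30, 0.35, 0.18),
      xs_mean = c(0.95, 1.05, 0.90, 1.00),
      xs_sd = c(0.12, 0.20, 0.12, 0.15),
      stringsAsFactors = FALSE
    )
  }
  need <- c("family", "n", "psv_logit_mean", "psv_logit_sd",
            "logsl_mean", "logsl_sd", "xs_mean", "xs_sd")
  missing_cols <- setdiff(need, names(families))
  if (length(missing_cols)) {
    stop("families config lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(families[c("psv_logit_sd", "logsl_sd", "xs_sd")] <= 0)) {
    stop("all sds must be positive")
  }
  structure(list(families = families, birth = birth, death = death,
                 trait_mode = trait_mode, seed = as.integer(seed)),
            class = "cohort_config")
}

# two-clade backbone: ((Astartidae,(Carditidae,Crassatellidae)),Veneridae),
# each family a rescaled birth-death subtree grafted at a fixed crown age
cohort_tree <- function(config) {
  fam <- config$families
  crown <- c(Astartidae = 150, Carditidae = 200, Crassatellidae = 180,
             Veneridae = 150)
  node_age <- c(root = 450, arch = 350, cc = 300)
  sub_newick <- function(family, n, seed) {
    abbrev <- substr(family, 1L, 4L)
    if (n == 1L) {
      return(list(str = sprintf("%s_sp01:%g", abbrev, 0),
                  depth = 0))
    }
    tr <- simulate_tree(n, config$birth, config$death, seed = seed)
    tr$tip.label <- sprintf("%s_sp%02d", abbrev, seq_len(n))
    depth <- max(ape::node.depth.edgelength(tr))
    target <- crown[[family]]
    tr$edge.length <- tr$edge.length * (target / depth)
    str <- ape::write.tree(tr)
    list(str = sub(";$", "", str), depth = target)
  }
  subs <- lapply(seq_len(nrow(fam)), function(i) {
    sub_newick(fam$family[i], fam$n[i], config$seed + 1000L + i)
  })
  names(subs) <- fam$family
  stem <- function(parent_age, child) parent_age - child$depth
  nwk <- sprintf(
    "((%s:%g,(%s:%g,%s:%g):%g):%g,%s:%g);",
    subs$Astartidae$str, stem(node_age["arch"], subs$Astartidae),
    subs$Carditidae$str, stem(node_age["cc"], subs$Carditidae),
    subs$Crassatellidae$str, stem(node_age["cc"], subs$Crassatellidae),
    node_age["arch"] - node_age["cc"],
    node_age["root"] - node_age["arch"],
    subs$Veneridae$str, stem(node_age["root"], subs$Veneridae)
  )
  check_phylogeny(ape::read.tree(text = nwk))
}

#' Generate a full synthetic cohort
#'
#' Draws per-species pSV, logSL and XS according to the family
#' configuration (either independently or as Brownian motion on the cohort
#' tree plus family mean shifts), assigns the siphonate condition and habit
#' annotations by family, classifies substratum use with the burial-depth
#' rules, and optionally emits a hemi-ellipsoid valve mesh per species
#' whose analytic metrics match the drawn values. Everything is a
#' deterministic function of the configuration seed.
#'
#' @param config a [cohort_config()].
#' @param out_dir if non-`NULL`, `traits.csv` and `tree.nwk` (and
#'   `meshes/*.stl` when `emit_meshes`) are written there.
#' @param emit_meshes also build a valve mesh per species (slower).
#' @param mesh_subdiv subdivision level for emitted meshes.
#' @return list with `traits` (classified data.frame), `tree` (`phylo`),
#'   optional `valves` (named list of [make_valve()] results), and `paths`.
#' @export
make_cohort <- function(config = cohort_config(), out_dir = NULL,
                        emit_meshes = FALSE, mesh_subdiv = 12L) {
  stopifnot(inherits(config, "cohort_config"))
  fam <- config$families
  tree <- cohort_tree(config)
  if (length(tree$tip.label) != sum(fam$n)) {
    stop("config n-tip mismatch: tree has ", length(tree$tip.label),
         " tips but families sum to ", sum(fam$n))
  }
  set.seed(config$seed)
  family_of <- rep(fam$family, fam$n)
  taxa <- unlist(lapply(seq_len(nrow(fam)), function(i) {
    sprintf("%s_sp%02d", substr(fam$family[i], 1L, 4L), seq_len(fam$n[i]))
  }))
  # align to a fixed, reproducible order (alphabetical = tree-independent)
  ord <- order(taxa)
  taxa <- taxa[ord]
  family_of <- family_of[ord]
  fi <- match(family_of, fam$family)
  n_total <- length(taxa)

  draw_trait <- function(mean_by_fam, sd_by_fam, bm_seed) {
    if (config$trait_mode == "independent") {
      stats::rnorm(n_total, mean_by_fam[fi], sd_by_fam[fi])
    } else {
      z <- simulate_bm(tree, sigma2 = 1, root_value = 0, seed = bm_seed)
      z <- as.numeric(scale(z[taxa]))  # unit variance, then family scaling
      mean_by_fam[fi] + sd_by_fam[fi] * z
    }
  }
  psv <- stats::plogis(draw_trait(fam$psv_logit_mean, fam$psv_logit_sd,
                                  config$seed + 1L))
  logsl <- draw_trait(fam$logsl_mean, fam$logsl_sd, config$seed + 2L)
  xs <- pmax(0.2, draw_trait(fam$xs_mean, fam$xs_sd, config$seed + 3L))

  siphonate <- family_of == "Veneridae"
  habit <- rep("infaunal", n_total)
  ven <- which(siphonate)
  habit[ven] <- sample(c("borer", "nestler", "infaunal"), length(ven),
                       replace = TRUE, prob = c(0.03, 0.03, 0.94))
  card <- which(family_of == "Carditidae")
  habit[card] <- sample(c("epifaunal", "infaunal"), length(card),
                        replace = TRUE, prob = c(0.05, 0.95))
  sinus <- rep(NA_real_, n_total)
  sinus[ven] <- stats::rbeta(length(ven), 2, 2)

  traits <- data.frame(
    taxon = taxa,
    family = family_of,
    clade = clade_of_family(family_of),
    siphonate = siphonate,
    habit = habit,
    sinus_depth_fraction = sinus,
    pSV = psv,
    logSL = logsl,
    SL = 10^logsl,
    XS = xs,
    stringsAsFactors = FALSE
  )
  traits <- classify_records(traits)

  valves <- NULL
  if (emit_meshes) {
    valves <- lapply(seq_len(n_total), function(i) {
      a <- traits$SL[i] / 2
      b <- a * 0.75                      # generic valve proportions
      c_ax <- traits$XS[i] * b
      axes <- c(a, b, c_ax)
      make_valve(shell_params(axes, thickness_for_psv(axes, traits$pSV[i]),
                              subdiv = mesh_subdiv))
    })
    names(valves) <- taxa
  }

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    traits_path <- file.path(out_dir, "traits.csv")
    tree_path <- file.path(out_dir, "tree.nwk")
    write_trait_table(traits, traits_path)
    ape::write.tree(tree, tree_path)
    paths <- list(traits = traits_path, tree = tree_path)
    if (emit_meshes) {
      mesh_dir <- file.path(out_dir, "meshes")
      dir.create(mesh_dir, showWarnings = FALSE)
      for (tx in taxa) {
        write_mesh(valves[[tx]]$shell,
                   file.path(mesh_dir, paste0(tx, "_shell.stl")))
        write_mesh(valves[[tx]]$interior,
                   file.path(mesh_dir, paste0(tx, "_interior.stl")))
      }
      paths$meshes <- mesh_dir
    }
  }
  list(traits = traits, tree = tree, valves = valves, paths = paths)
}
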
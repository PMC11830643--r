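#' Pipeline orchestration
#'
#' One reproducible run chains the stages measure -> classify -> correlate
#' -> rarefy -> pgls and writes every result plus a JSON manifest recording
#' the configuration and the seeds, so any output can be regenerated.
#'
#' @name pipeline
#' @keywords internal
NULL

#' Build a pipeline run configuration
#'
#' @param trait_table path to the specimen trait CSV, or a data.frame.
#' @param tree path to the phylogeny (Newick or NEXUS), or a `phylo`
#'   object; `NULL` runs the non-phylogenetic stages only.
#' @param mesh_dir optional directory of `<taxon>_shell.stl` /
#'   `<taxon>_interior.stl` pairs to measure; metrics are merged into the
#'   trait table by taxon.
#' @param variables trait columns analysed (default `pSV`, `logSL`, `XS`).
#' @param models named list of model formulas for the ANOVA stage; the
#'   default fits each variable against
#'   `substratum + <other variables> + family`, mirroring the ordered
#'   sequential-SS design.
#' @param internal_mode interior-volume mode, `"capped"` or `"origin_fan"`.
#' @param log_base base for logSL.
#' @param mirror mirror meshes before measuring (right valves).
#' @param n_min,reps rarefaction settings.
#' @param n_perm ANOVA permutations.
#' @param rarefy_seed,perm_seed per-stage seeds (stages can be re-run
#'   independently).
#' @param out_dir output directory.
#' @return a list of class `run_config`.
#' @export
run_config <- function(trait_table, tree = NULL, mesh_dir = NULL,
                       variables = c("pSV", "logSL", "XS"),
                       models = NULL,
                       internal_mode = c("capped", "origin_fan"),
                       log_base = 10, mirror = FALSE,
                       n_min = 5L, reps = 1000L, n_perm = 999L,
                       rarefy_seed = 1L, perm_seed = 2L,
                       out_dir = tempfile("valvemorph_run_")) {
  internal_mode <- match.arg(internal_mode)
  for (p in c(if (is.character(trait_table)) trait_table,
              if (is.character(tree)) tree,
              mesh_dir)) {
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  }
  if (is.null(models)) {
    others <- function(v) setdiff(variables, v)
    models <- lapply(variables, function(v) {
      stats::as.formula(paste(v, "~ substratum +",
                              paste(others(v), collapse = " + "),
                              "+ family"))
    })
    names(models) <- variables
  }
  structure(list(trait_table = trait_table, tree = tree,
                 mesh_dir = mesh_dir, variables = variables,
                 models = models, internal_mode = internal_mode,
                 log_base = log_base, mirror = mirror,
                 n_min = n_min, reps = reps, n_perm = n_perm,
                 rarefy_seed = rarefy_seed, perm_seed = perm_seed,
                 out_dir = out_dir),
            class = "run_config")
}

measure_mesh_dir <- function(mesh_dir, internal_mode, log_base, mirror) {
  shells <- sort(list.files(mesh_dir, pattern = "_shell\\.(stl|obj|ply)$"))
  if (length(shells) == 0L) stop("no *_shell meshes found in ", mesh_dir)
  rows <- lapply(shells, function(f) {
    taxon <- sub("_shell\\.(stl|obj|ply)$", "", f)
    interior_file <- list.files(mesh_dir,
                                pattern = paste0("^", taxon,
                                                 "_interior\\.(stl|obj|ply)$"),
                                full.names = TRUE)
    if (length(interior_file) != 1L) {
      stop("no interior mesh for taxon ", taxon)
    }
    shell <- read_mesh(file.path(mesh_dir, f), role = "shell_solid")
    interior <- read_mesh(interior_file, role = "interior_surface")
    cbind(taxon = taxon,
          compute_metrics(shell, interior, mirror = mirror,
                          internal_mode = internal_mode,
                          log_base = log_base))
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (1) *measure* — if a mesh directory is configured,
#' valve metrics are computed and merged into the trait table; (2)
#' *classify* — substratum-use categories from the burial-depth rules; (3)
#' *correlate* — Pearson correlation matrix of the trait variables; (4)
#' *rarefy* — disparity rarefaction curves (variance and range) per family
#' and variable; (5) *pgls* — phylogenetically corrected permutation ANOVA
#' per model (skipped without a tree). A failure stops the run with the
#' failing stage named. All outputs and a JSON manifest are written to the
#' configured directory.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `records`, `correlations`, `curves`,
#'   `anova` (named list of `anova_rrpp` tables) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  records <- stage("measure", {
    tab <- if (is.character(config$trait_table)) {
      read_trait_table(config$trait_table)
    } else {
      validate_records(config$trait_table, allow_extra_families = TRUE)
    }
    if (!is.null(config$mesh_dir)) {
      metrics <- measure_mesh_dir(config$mesh_dir, config$internal_mode,
                                  config$log_base, config$mirror)
      keep <- setdiff(names(tab), setdiff(names(metrics), "taxon"))
      tab <- merge(tab[keep], metrics, by = "taxon", sort = TRUE)
    }
    tab
  })

  records <- stage("classify", classify_records(records))
  write_trait_table(records, file.path(config$out_dir, "classified.csv"))

  tree <- NULL
  if (!is.null(config$tree)) {
    tree <- stage("tree", {
      tr <- if (is.character(config$tree)) {
        read_phylogeny(config$tree)
      } else {
        check_phylogeny(config$tree)
      }
      absent <- setdiff(records$taxon, tr$tip.label)
      if (length(absent)) {
        stop("taxa missing from tree: ", paste(absent, collapse = ", "))
      }
      extra <- setdiff(tr$tip.label, records$taxon)
      if (length(extra)) tr <- ape::drop.tip(tr, extra)
      tr
    })
  }

  correlations <- stage("correlate",
                        pearson_matrix(records, config$variables))
  utils::write.csv(correlations,
                   file.path(config$out_dir, "correlations.csv"))

  curves <- stage("rarefy", rarefy_table(
    records, variables = config$variables,
    n_min = config$n_min, reps = config$reps, seed = config$rarefy_seed))
  utils::write.csv(curves, file.path(config$out_dir, "curves.csv"),
                   row.names = FALSE)

  anova_tables <- NULL
  if (!is.null(tree)) {
    anova_tables <- stage("pgls", {
      lapply(config$models, function(fm) {
        pgls_rrpp(fm, records, phy = tree, n_perm = config$n_perm,
                  seed = config$perm_seed)
      })
    })
    for (nm in names(anova_tables)) {
      utils::write.csv(as.data.frame(anova_tables[[nm]]),
                       file.path(config$out_dir,
                                 paste0("anova_", nm, ".csv")))
    }
  }

  manifest <- list(
    package = "valvemorph",
    version = as.character(utils::packageVersion("valvemorph")),
    timestamp = format(Sys.time(), tz = "UTC"),
    n_records = nrow(records),
    variables = config$variables,
    models = vapply(config$models, function(f) deparse1(f), character(1L)),
    internal_mode = config$internal_mode,
    log_base = config$log_base,
    rarefaction = list(n_min = config$n_min, reps = config$reps,
                       seed = config$rarefy_seed),
    anova = list(n_perm = config$n_perm, seed = config$perm_seed),
    config_hash = config_hash(config)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(records = records, correlations = correlations,
                 curves = curves, anova = anova_tables,
                 manifest = manifest))
}

# order-stable fingerprint of the configuration (file contents are not
# hashed, only settings)
config_hash <- function(config) {
  keep <- config[setdiff(names(config), "out_dir")]
  keep <- keep[order(names(keep))]
  txt <- paste(deparse(keep), collapse = "\n")
  # small FNV-1a style hash; avoids a digest dependency
  h <- 2166136261
  for (byte in utf8ToInt(txt)) {
    h <- bitwXor(h, byte)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}
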
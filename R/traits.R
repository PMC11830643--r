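#' Specimen trait tables and substratum-use classification
#'
#' The study system comprises two clades of heterodont bivalves: the
#' asiphonate Archiheterodonta (families Astartidae, Carditidae,
#' Crassatellidae) and the siphonate family Veneridae. Specimens are
#' classified into six substratum-use functional groups: infaunal
#' asiphonate, shallow infaunal siphonate, deep infaunal siphonate, borer,
#' nestler and epifaunal.
#'
#' @name traits_table
#' @keywords internal
NULL

KNOWN_FAMILIES <- c("Astartidae", "Carditidae", "Crassatellidae", "Veneridae")
ARCHIHETERODONT_FAMILIES <- c("Astartidae", "Carditidae", "Crassatellidae")
SUBSTRATUM_LEVELS <- c("infaunal_asiphonate", "shallow_siphonate",
                       "deep_siphonate", "borer", "nestler", "epifaunal")
HABIT_LEVELS <- c("borer", "nestler", "epifaunal", "infaunal")

#' Clade membership from family
#'
#' @param family character vector of family names.
#' @return `"Archiheterodonta"` or `"Veneridae"` per element.
#' @export
clade_of_family <- function(family) {
  ifelse(family %in% ARCHIHETERODONT_FAMILIES, "Archiheterodonta",
         ifelse(family == "Veneridae", "Veneridae", NA_character_))
}

#' Classify specimens into substratum-use functional groups
#'
#' Applies the burial-depth rules in order of precedence:
#' \enumerate{
#'   \item an explicit habit annotation of borer, nestler or epifaunal wins
#'     outright (these habits are defined by substrate, not depth);
#'   \item an asiphonate infaunal specimen is `infaunal_asiphonate`;
#'   \item a siphonate specimen under 50 mm shell length is assumed to
#'     burrow shallowly (`shallow_siphonate`);
#'   \item otherwise the siphon length is estimated as
#'     `sinus_depth_fraction * SL` (pallial-sinus depth as a fraction of
#'     shell length); an estimated posterior burial depth deeper than
#'     30 mm is `deep_siphonate`, else `shallow_siphonate`.
#' }
#' Boundaries are strict: SL = 50 mm goes to the sinus check, an estimated
#' depth of exactly 30 mm is shallow. An optional `substratum_override`
#' value wins over everything (for taxa classified deep on direct
#' observational evidence).
#'
#' @param siphonate logical vector.
#' @param SL shell length, mm.
#' @param sinus_depth_fraction pallial-sinus depth as a fraction of SL in
#'   `[0, 1]`; required for siphonate specimens with SL >= 50 mm.
#' @param habit optional habit annotation, one of `"borer"`, `"nestler"`,
#'   `"epifaunal"`, `"infaunal"`, or `NA`.
#' @param substratum_override optional manual category, or `NA`.
#' @return character vector of substratum categories.
#' @export
classify_substratum <- function(siphonate, SL,
                                sinus_depth_fraction = NA_real_,
                                habit = NA_character_,
                                substratum_override = NA_character_) {
  n <- length(siphonate)
  SL <- rep_len(SL, n)
  sinus_depth_fraction <- rep_len(sinus_depth_fraction, n)
  habit <- rep_len(habit, n)
  substratum_override <- rep_len(substratum_override, n)
  bad_habit <- !is.na(habit) & !(habit %in% HABIT_LEVELS)
  if (any(bad_habit)) {
    stop("unknown habit annotation: ", paste(unique(habit[bad_habit]),
                                             collapse = ", "))
  }
  bad_ovr <- !is.na(substratum_override) &
    !(substratum_override %in% SUBSTRATUM_LEVELS)
  if (any(bad_ovr)) {
    stop("unknown substratum override: ",
         paste(unique(substratum_override[bad_ovr]), collapse = ", "))
  }
  out <- rep(NA_character_, n)
  out[!is.na(substratum_override)] <-
    substratum_override[!is.na(substratum_override)]
  todo <- is.na(out)
  win <- todo & !is.na(habit) & habit %in% c("borer", "nestler", "epifaunal")
  out[win] <- habit[win]
  todo <- is.na(out)
  out[todo & !siphonate] <- "infaunal_asiphonate"
  todo <- is.na(out)
  out[todo & SL < 50] <- "shallow_siphonate"
  todo <- is.na(out)
  if (any(todo & is.na(sinus_depth_fraction))) {
    stop("unclassifiable: siphonate specimens with SL >= 50 mm lack ",
         "sinus_depth_fraction at rows ",
         paste(which(todo & is.na(sinus_depth_fraction)), collapse = ", "))
  }
  siphon_len <- sinus_depth_fraction * SL
  out[todo] <- ifelse(siphon_len[todo] > 30, "deep_siphonate",
                      "shallow_siphonate")
  out
}

validate_records <- function(df, allow_extra_families = FALSE) {
  required <- c("taxon", "family", "siphonate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("trait table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$siphonate <- as.logical(df$siphonate)
  unknown <- !(df$family %in% KNOWN_FAMILIES)
  if (any(unknown) && !allow_extra_families) {
    stop("unknown families (use allow_extra_families = TRUE to keep): ",
         paste(unique(df$family[unknown]), collapse = ", "))
  }
  if (!("clade" %in% names(df))) df$clade <- clade_of_family(df$family)
  bad_arch <- df$family %in% ARCHIHETERODONT_FAMILIES & df$siphonate
  if (any(bad_arch)) {
    stop("invariant violation: archiheterodont families are asiphonate; ",
         "offending taxa: ", paste(df$taxon[bad_arch], collapse = ", "))
  }
  bad_ven <- df$family == "Veneridae" & !df$siphonate
  if (any(bad_ven)) {
    stop("invariant violation: Veneridae are siphonate; offending taxa: ",
         paste(df$taxon[bad_ven], collapse = ", "))
  }
  if ("substratum" %in% names(df)) {
    sip_only <- c("shallow_siphonate", "deep_siphonate", "borer", "nestler")
    bad <- (df$substratum %in% sip_only & !df$siphonate) |
      (df$substratum == "infaunal_asiphonate" & df$siphonate)
    bad[is.na(bad)] <- FALSE
    if (any(bad)) {
      stop("invariant violation: substratum category inconsistent with ",
           "siphonate flag for taxa: ",
           paste(df$taxon[bad], collapse = ", "))
    }
  }
  df
}

#' Read a specimen trait table from CSV
#'
#' Required columns: `taxon`, `family`, `siphonate`. Recognised optional
#' columns include `habit`, `sinus_depth_fraction`, `substratum`,
#' `substratum_override` and any measured metrics (`TSV`, `TIV`, `pSV`,
#' `SL`, `height`, `width`, `XS`, `logSL`). The `clade` column is derived
#' from `family` when absent. Records are validated against the clade and
#' siphonate-condition invariants.
#'
#' @param path CSV path.
#' @param allow_extra_families keep rows whose family is outside the study
#'   set instead of erroring.
#' @return a data.frame of specimen records.
#' @export
read_trait_table <- function(path, allow_extra_families = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_records(df, allow_extra_families = allow_extra_families)
}

#' Write a specimen trait table to CSV
#'
#' @param records data.frame of specimen records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Classify every record of a trait table
#'
#' Adds (or overwrites) the `substratum` column by applying
#' [classify_substratum()] row-wise.
#'
#' @param records data.frame with `siphonate`, `SL` and optionally
#'   `sinus_depth_fraction`, `habit`, `substratum_override` columns.
#' @return the data.frame with a `substratum` column.
#' @export
classify_records <- function(records) {
  records <- validate_records(records, allow_extra_families = TRUE)
  get_col <- function(nm, default) {
    if (nm %in% names(records)) records[[nm]] else default
  }
  records$substratum <- classify_substratum(
    siphonate = records$siphonate,
    SL = get_col("SL", NA_real_),
    sinus_depth_fraction = get_col("sinus_depth_fraction", NA_real_),
    habit = get_col("habit", NA_character_),
    substratum_override = get_col("substratum_override", NA_character_)
  )
  validate_records(records, allow_extra_families = TRUE)
}
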
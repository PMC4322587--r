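# Taxon registry: species-level constants that are curated summaries rather
# than quantities derivable from the record files (expected gestation and its
# range, breeding pattern, activity pattern, active-breeding flag, biosample
# counts, and the mid-month of the breeding season in the country of origin
# used when estimating wild-caught dates of birth).

REGISTRY_COLS <- c(
  "taxon", "latin_name", "common_name", "expected_gestation_d",
  "gestation_lo_d", "gestation_hi_d", "breeding_pattern", "activity",
  "active_dlc_breeding", "n_biosample_individuals", "origin_breeding_midmonth"
)

#' Read a taxon registry CSV
#'
#' The registry holds one row per taxon code with the species constants used
#' by the derivation pipeline. See [default_registry()] for the shipped
#' defaults covering the 27 colony taxa.
#'
#' @param path Path to a registry CSV with columns
#'   `taxon, latin_name, common_name, expected_gestation_d, gestation_lo_d,
#'   gestation_hi_d, breeding_pattern (S/NS), activity (N/D),
#'   active_dlc_breeding (Y/N), n_biosample_individuals,
#'   origin_breeding_midmonth (1-12, empty for non-seasonal taxa)`.
#' @return A data.frame of class `taxon_registry`.
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(REGISTRY_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("registry is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[REGISTRY_COLS]
  for (col in c("expected_gestation_d", "gestation_lo_d", "gestation_hi_d",
                "n_biosample_individuals", "origin_breeding_midmonth")) {
    df[[col]] <- parse_int_col(df[[col]])
  }
  for (col in c("taxon", "latin_name", "common_name", "breeding_pattern",
                "activity", "active_dlc_breeding")) {
    df[[col]] <- parse_chr_col(df[[col]])
  }
  validate_registry(df)
  class(df) <- c("taxon_registry", "data.frame")
  df
}

#' Default taxon registry
#'
#' Registry of the 27 strepsirrhine taxa held in the colony archive, with
#' curated gestation constants, breeding pattern (seasonal/non-seasonal),
#' activity pattern (nocturnal/diurnal) and pass-through metadata.
#'
#' @return A data.frame of class `taxon_registry` with 27 rows.
#' @export
default_registry <- function() {
  read_registry(system.file("extdata", "taxon_registry.csv",
                            package = "lemurlife", mustWork = TRUE))
}

#' Validate a taxon registry
#'
#' Checks code uniqueness, gestation-range containment and that seasonal taxa
#' carry an origin breeding mid-month.
#'
#' @param reg Registry data.frame.
#' @return `reg` invisibly; errors on violation.
#' @export
validate_registry <- function(reg) {
  if (anyDuplicated(reg$taxon)) {
    stop("duplicate taxon code(s): ",
         paste(unique(reg$taxon[duplicated(reg$taxon)]), collapse = ", "))
  }
  bad <- !(reg$gestation_lo_d <= reg$expected_gestation_d &
             reg$expected_gestation_d <= reg$gestation_hi_d)
  if (any(bad)) {
    stop("expected gestation outside stated range for: ",
         paste(reg$taxon[bad], collapse = ", "))
  }
  if (!all(reg$breeding_pattern %in% c("S", "NS"))) {
    stop("breeding_pattern must be 'S' or 'NS'")
  }
  if (!all(reg$activity %in% c("N", "D"))) {
    stop("activity must be 'N' (nocturnal) or 'D' (diurnal)")
  }
  seasonal <- reg$breeding_pattern == "S"
  if (any(seasonal & is.na(reg$origin_breeding_midmonth))) {
    stop("seasonal taxa require origin_breeding_midmonth: ",
         paste(reg$taxon[seasonal & is.na(reg$origin_breeding_midmonth)],
               collapse = ", "))
  }
  mm <- reg$origin_breeding_midmonth
  if (any(!is.na(mm) & (mm < 1 | mm > 12))) {
    stop("origin_breeding_midmonth must be in 1..12")
  }
  invisible(reg)
}

registry_row <- function(reg, taxon) {
  i <- match(taxon, reg$taxon)
  if (is.na(i)) stop("taxon code not in registry: ", taxon)
  reg[i, , drop = FALSE]
}
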
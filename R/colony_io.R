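# Readers, writers and record-level validation for the two colony record
# schemas: the animal list (one row per individual, 32 columns) and the
# weight file (one row per weighing event, 33 columns). Column names follow
# the published layouts exactly; dates are ISO-8601 on write and ISO-8601 or
# M/D/YYYY on read; missing values are empty on write and '', '.' or 'NA'
# on read.

ANIMAL_COLS <- list(
  chr = c("Taxon", "DLC_ID", "Hybrid", "Sex", "Name", "Current_Resident",
          "StudBook", "Estimated_DOB", "Birth_Type", "Birth_Institution",
          "Dam_ID", "Dam_Name", "Dam_Taxon", "Sire_ID", "Sire_Name",
          "Sire_Taxon"),
  date = c("DOB", "Estimated_Concep", "Dam_DOB", "Sire_DOB", "DOD"),
  int = c("Birth_Month", "Concep_Month", "Litter_Size",
          "Expected_Gestation_d", "N_known_offspring"),
  num = c("Dam_AgeAtConcep_y", "Sire_AgeAtConcep_y", "AgeAtDeath_y",
          "AgeOfLiving_y", "AgeLastVerified_y", "AgeMax_LiveOrDead_y")
)

ANIMAL_COL_ORDER <- c(
  "Taxon", "DLC_ID", "Hybrid", "Sex", "Name", "Current_Resident", "StudBook",
  "DOB", "Birth_Month", "Estimated_DOB", "Birth_Type", "Birth_Institution",
  "Litter_Size", "Expected_Gestation_d", "Estimated_Concep", "Concep_Month",
  "Dam_ID", "Dam_Name", "Dam_Taxon", "Dam_DOB", "Dam_AgeAtConcep_y",
  "Sire_ID", "Sire_Name", "Sire_Taxon", "Sire_DOB", "Sire_AgeAtConcep_y",
  "DOD", "AgeAtDeath_y", "AgeOfLiving_y", "AgeLastVerified_y",
  "AgeMax_LiveOrDead_y", "N_known_offspring"
)

WEIGHT_COLS <- list(
  chr = c("Taxon", "Hybrid", "DLC_ID", "Sex", "Name", "Estimated_DOB",
          "Birth_Type", "Birth_Institution", "Age_Category",
          "Current_Resident", "Preg_Status"),
  date = c("DOB", "Weight_Date", "DOD", "ConcepDate_IfPreg",
           "InfantDOB_IfPreg"),
  int = c("MonthOfWeight", "AgeAtWt_d", "AgeAtWt_mo_NoDec",
          "Days_Since_PrevWt", "DaysBeforeDeath", "Litter_Size",
          "Expected_Gestation_d", "DaysBeforeInfBirth_IfPreg",
          "InfantLitSz_IfPreg"),
  num = c("Weight_g", "AgeAtWt_wk", "AgeAtWt_mo", "AgeAtWt_y",
          "Change_Since_PrevWt_g", "Avg_Daily_WtChange_g",
          "R_Min_Dam_AgeAtConcep_y", "Pct_PregRemain_IfPreg")
)

WEIGHT_COL_ORDER <- c(
  "Taxon", "Hybrid", "DLC_ID", "Sex", "Name", "DOB", "Estimated_DOB",
  "Weight_g", "Weight_Date", "MonthOfWeight", "AgeAtWt_d", "AgeAtWt_wk",
  "AgeAtWt_mo", "AgeAtWt_mo_NoDec", "AgeAtWt_y", "Days_Since_PrevWt",
  "Change_Since_PrevWt_g", "Avg_Daily_WtChange_g", "DOD", "DaysBeforeDeath",
  "Birth_Type", "Birth_Institution", "Litter_Size",
  "R_Min_Dam_AgeAtConcep_y", "Age_Category", "Current_Resident",
  "Preg_Status", "Expected_Gestation_d", "ConcepDate_IfPreg",
  "InfantDOB_IfPreg", "DaysBeforeInfBirth_IfPreg", "Pct_PregRemain_IfPreg",
  "InfantLitSz_IfPreg"
)

# Institution string identifying on-site births; used for DLC-born subsets.
DLC_INSTITUTION <- "Duke Prim"

read_schema_csv <- function(path, spec, order) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(order, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- raw[order]
  for (col in spec$chr) df[[col]] <- parse_chr_col(df[[col]])
  for (col in spec$int) df[[col]] <- parse_int_col(df[[col]])
  for (col in spec$num) df[[col]] <- parse_num_col(df[[col]])
  for (col in spec$date) {
    parsed <- parse_date_col(df[[col]])
    bad <- attr(parsed, "bad_rows")
    if (length(bad) > 0) {
      stop("unparseable date in column ", col, " at row(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
    attr(parsed, "bad_rows") <- NULL
    df[[col]] <- parsed
  }
  df
}

check_close <- function(stored, computed, tol = 1e-6) {
  both <- !is.na(stored) & !is.na(computed)
  idx <- which(both & abs(stored - computed) > tol)
  idx
}

#' Read an animal list CSV
#'
#' Parses and validates the 32-column per-individual schema. Derived columns
#' (estimated conception date, conception/birth month, parental ages at
#' conception, the three age columns) are recomputed and compared against the
#' stored values; disagreements beyond tolerance are collected into the
#' attached validation report (and overwritten when `recompute = TRUE`).
#'
#' @param path CSV file path.
#' @param registry Taxon registry (see [default_registry()]); used to flag
#'   unknown taxon codes.
#' @param recompute If `TRUE`, derived columns are replaced by recomputed
#'   values instead of merely compared.
#' @param tol Numeric tolerance for derived-column comparison.
#' @return Data.frame of animal records in published column order, with a
#'   character vector of issues in `attr(, "issues")`.
#' @export
read_animal_list <- function(path, registry = default_registry(),
                             recompute = FALSE, tol = 1e-6) {
  df <- read_schema_csv(path, ANIMAL_COLS, ANIMAL_COL_ORDER)
  issues <- character(0)

  unknown <- setdiff(unique(df$Taxon), registry$taxon)
  if (length(unknown) > 0) {
    issues <- c(issues, paste0("unknown taxon code(s): ",
                               paste(unknown, collapse = ", ")))
  }
  dup <- unique(df$DLC_ID[duplicated(df$DLC_ID)])
  if (length(dup) > 0) {
    issues <- c(issues, paste0("duplicate DLC_ID(s): ",
                               paste(dup, collapse = ", ")))
  }

  derived <- derive_animal_columns(df)
  for (col in names(derived)) {
    if (col %in% c("Estimated_Concep")) {
      bad <- which(!is.na(df[[col]]) & !is.na(derived[[col]]) &
                     df[[col]] != derived[[col]])
    } else {
      bad <- check_close(df[[col]], derived[[col]], tol)
    }
    if (length(bad) > 0) {
      issues <- c(issues, paste0("derived column ", col,
                                 " disagrees with recomputation at row(s): ",
                                 paste(utils::head(bad, 10), collapse = ", ")))
    }
    if (recompute) df[[col]] <- derived[[col]]
  }

  one_of_three <- rowSums(!is.na(df[c("AgeAtDeath_y", "AgeOfLiving_y",
                                      "AgeLastVerified_y")])) == 1
  if (any(!one_of_three)) {
    issues <- c(issues, paste0("one-of-three age rule violated at row(s): ",
                               paste(utils::head(which(!one_of_three), 10),
                                     collapse = ", ")))
  }

  attr(df, "issues") <- issues
  df
}

# Recompute the calculated animal-list columns from the direct ones.
derive_animal_columns <- function(df) {
  concep <- df$DOB - df$Expected_Gestation_d
  age_pick <- ifelse(!is.na(df$AgeAtDeath_y), df$AgeAtDeath_y,
                     ifelse(!is.na(df$AgeOfLiving_y), df$AgeOfLiving_y,
                            df$AgeLastVerified_y))
  list(
    Birth_Month = month_of(df$DOB),
    Estimated_Concep = concep,
    Concep_Month = month_of(concep),
    Dam_AgeAtConcep_y = round_or_na(age_years(df$Dam_DOB, concep), 2),
    Sire_AgeAtConcep_y = round_or_na(age_years(df$Sire_DOB, concep), 2),
    AgeAtDeath_y = round_or_na(age_years(df$DOB, df$DOD), 2),
    AgeMax_LiveOrDead_y = age_pick
  )
}

#' Read a weight file CSV
#'
#' Parses and validates the 33-column per-weighing schema. Records are sorted
#' by (`DLC_ID`, `Weight_Date`); age-at-weighing columns are recomputed and
#' compared (tolerance `tol`), disagreements reported via the attached issue
#' list.
#'
#' @inheritParams read_animal_list
#' @return Data.frame of weight records sorted by individual and date, with
#'   `attr(, "issues")`.
#' @export
read_weight_file <- function(path, registry = default_registry(),
                             recompute = FALSE, tol = 1e-6) {
  df <- read_schema_csv(path, WEIGHT_COLS, WEIGHT_COL_ORDER)
  df <- df[order(df$DLC_ID, df$Weight_Date), , drop = FALSE]
  rownames(df) <- NULL
  issues <- character(0)

  unknown <- setdiff(unique(df$Taxon), registry$taxon)
  if (length(unknown) > 0) {
    issues <- c(issues, paste0("unknown taxon code(s): ",
                               paste(unknown, collapse = ", ")))
  }

  neg <- which(!is.na(df$Weight_Date) & !is.na(df$DOB) &
                 as.numeric(df$Weight_Date - df$DOB) < 0)
  if (length(neg) > 0) {
    stop("negative age at weighing at row(s): ",
         paste(utils::head(neg, 10), collapse = ", "))
  }
  nonpos <- which(!is.na(df$Weight_g) & df$Weight_g <= 0)
  if (length(nonpos) > 0) {
    stop("non-positive weight at row(s): ",
         paste(utils::head(nonpos, 10), collapse = ", "))
  }

  d <- as.numeric(df$Weight_Date - df$DOB)
  derived <- list(
    MonthOfWeight = month_of(df$Weight_Date),
    AgeAtWt_d = d,
    AgeAtWt_wk = round_or_na(d / 7, 6),
    AgeAtWt_mo = round_or_na(d / DAYS_PER_YEAR * 12, 6),
    AgeAtWt_mo_NoDec = floor(d / DAYS_PER_YEAR * 12),
    AgeAtWt_y = round_or_na(d / DAYS_PER_YEAR, 6),
    DaysBeforeDeath = as.numeric(df$DOD - df$Weight_Date)
  )
  for (col in names(derived)) {
    bad <- check_close(df[[col]], derived[[col]], tol)
    if (length(bad) > 0) {
      issues <- c(issues, paste0("derived column ", col,
                                 " disagrees with recomputation at row(s): ",
                                 paste(utils::head(bad, 10), collapse = ", ")))
    }
    if (recompute) df[[col]] <- derived[[col]]
  }

  attr(df, "issues") <- issues
  df
}

write_schema_csv <- function(df, path, order) {
  out <- df[order]
  for (col in names(out)) {
    x <- out[[col]]
    if (inherits(x, "Date")) {
      out[[col]] <- ifelse(is.na(x), "", format(x, "%Y-%m-%d"))
    } else if (is.numeric(x)) {
      out[[col]] <- vapply(x, function(v) {
        if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE,
                                     digits = 15)
      }, character(1))
    } else {
      x <- as.character(x)
      x[is.na(x)] <- ""
      out[[col]] <- x
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write an animal list CSV
#'
#' @param animals Animal-record data.frame (published column set).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_animal_list <- function(animals, path) {
  write_schema_csv(animals, path, ANIMAL_COL_ORDER)
}

#' Write a weight file CSV
#'
#' @param weights Weight-record data.frame (published column set).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_file <- function(weights, path) {
  write_schema_csv(weights, path, WEIGHT_COL_ORDER)
}

#' Cross-file plausibility checks
#'
#' Report-producing validation over both record files: dates outside a
#' configurable project range, weights an order of magnitude away from the
#' taxon median, negative ages, weight records for unknown individuals, and
#' violations of the one-of-three age rule.
#'
#' @param animals Animal-record data.frame.
#' @param weights Weight-record data.frame.
#' @param project_range Length-2 `Date` (or coercible) vector of plausible
#'   event dates.
#' @param weight_band_multiplier Flag weights outside
#'   `[median / m, median * m]` within each taxon.
#' @return Data.frame of class `colony_validation` with columns
#'   `check`, `dlc_id`, `detail`; zero rows when clean.
#' @export
validate_colony <- function(animals, weights,
                            project_range = as.Date(c("1960-01-01",
                                                      "2030-12-31")),
                            weight_band_multiplier = 10) {
  project_range <- as.Date(project_range)
  flags <- list()
  add <- function(check, dlc_id, detail) {
    if (length(dlc_id) > 0) {
      flags[[length(flags) + 1]] <<- data.frame(
        check = check, dlc_id = as.character(dlc_id), detail = detail,
        stringsAsFactors = FALSE)
    }
  }

  for (col in c("DOB", "DOD")) {
    x <- animals[[col]]
    out <- !is.na(x) & (x < project_range[1] | x > project_range[2])
    add("date_out_of_range", animals$DLC_ID[out],
        paste0(col, "=", format(x[out])))
  }
  out <- !is.na(weights$Weight_Date) &
    (weights$Weight_Date < project_range[1] |
       weights$Weight_Date > project_range[2])
  add("date_out_of_range", weights$DLC_ID[out],
      paste0("Weight_Date=", format(weights$Weight_Date[out])))

  neg <- !is.na(animals$DOD) & !is.na(animals$DOB) &
    animals$DOD < animals$DOB
  add("negative_age", animals$DLC_ID[neg], "DOD precedes DOB")
  negw <- !is.na(weights$AgeAtWt_d) & weights$AgeAtWt_d < 0
  add("negative_age", weights$DLC_ID[negw], "negative age at weighing")

  for (tx in unique(weights$Taxon)) {
    w <- weights[weights$Taxon == tx & !is.na(weights$Weight_g), ]
    if (nrow(w) < 2) next
    med <- stats::median(w$Weight_g)
    # only the high side: juvenile weights legitimately sit far below the
    # taxon median, but nothing plausible sits an order of magnitude above
    out <- w$Weight_g > med * weight_band_multiplier
    add("weight_out_of_range", w$DLC_ID[out],
        paste0(tx, " weight ", w$Weight_g[out], " g vs median ", med, " g"))
  }

  orphan <- !(weights$DLC_ID %in% animals$DLC_ID)
  add("unknown_individual", unique(weights$DLC_ID[orphan]),
      "weight record without animal-list entry")

  n_ages <- rowSums(!is.na(animals[c("AgeAtDeath_y", "AgeOfLiving_y",
                                     "AgeLastVerified_y")]))
  bad <- n_ages != 1
  add("age_rule", animals$DLC_ID[bad],
      paste0(n_ages[bad], " of the three age columns populated"))

  report <- if (length(flags) == 0) {
    data.frame(check = character(0), dlc_id = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, flags)
  }
  class(report) <- c("colony_validation", "data.frame")
  report
}

#' @export
print.colony_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("colony validation: clean (no flags)\n")
  } else {
    cat("colony validation:", nrow(x), "flag(s)\n")
    print(as.data.frame(table(x$check)), row.names = FALSE)
  }
  invisible(x)
}

#' Record counts for a deposited file pair
#'
#' Convenience summary of the integration-tier record counts: animal records,
#' weight records and distinct weighed individuals, infant/juvenile-class
#' weight records and individuals, and hybrid-coded individuals whose hybrid
#' flag is 'N'.
#'
#' @param animals Animal-record data.frame.
#' @param weights Weight-record data.frame.
#' @return Named list of integer counts.
#' @export
check_deposited_counts <- function(animals, weights) {
  ij <- weights[!is.na(weights$Age_Category) & weights$Age_Category == "IJ", ]
  list(
    n_animals = nrow(animals),
    n_weights = nrow(weights),
    n_weighed_individuals = length(unique(weights$DLC_ID)),
    n_ij_weights = nrow(ij),
    n_ij_individuals = length(unique(ij$DLC_ID)),
    n_eul_hybrid_n = sum(animals$Taxon == "EUL" &
                           !is.na(animals$Hybrid) & animals$Hybrid == "N")
  )
}
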
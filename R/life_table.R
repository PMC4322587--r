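# Assembly of the 91-variable per-taxon life-history table from the two
# record files plus the taxon registry, and its two published layouts:
# a character reference layout (91 rows x one column per taxon) and an
# analysis layout (one row per taxon x 91 typed columns).

# The 91 variable names in published order. Category prefixes: S = sample
# size/count, R = reproduction, M = body mass, L = longevity/mortality,
# O = other.
LH_VARS <- c(
  "S_N_All_Historic", "S_N_M_Historic", "S_N_F_Historic", "S_N_ND_Historic",
  "S_N_All_CaptiveBorn", "S_N_M_CaptiveBorn", "S_N_F_CaptiveBorn",
  "S_N_All_WildBorn", "S_N_M_WildBorn", "S_N_F_WildBorn",
  "S_N_All_CurrentResident", "S_N_M_CurrentResident",
  "S_N_F_CurrentResident",
  "S_N_All_DLCBorn_Infant", "S_N_M_DLCBorn_Infant", "S_N_F_DLCBorn_Infant",
  "S_N_ND_DLCBorn_Infant",
  "R_Ratio_MtoF_DLCBirths",
  "S_N_All_DLCBorn_Litter",
  "R_Mean_LitterSize", "R_MostCommon_LitterSize",
  "R_Freq_MostCommon_LitterSize", "R_Min_LitterSize", "R_Max_LitterSize",
  "R_Expected_Gestation_d", "R_Range_Gestation_d", "R_Pattern_Breeding",
  "R_Peak_Breeding_Month", "R_Peak_Breeding_Season",
  "R_Peak_Birth_Month", "R_Peak_Birth_Season",
  "R_Min_Dam_AgeAtConcep_y", "R_Min_Sire_AgeAtConcep_y",
  "R_Max_Dam_AgeAtConcep_y", "R_Max_Sire_AgeAtConcep_y",
  "R_Active_DLCBreeding",
  "S_N_All_AdultsWeighed", "M_Mean_All_AdultWeight_g",
  "M_Min_All_AdultWeight_g", "M_Max_All_AdultWeight_g",
  "S_N_M_AdultsWeighed", "M_Mean_M_AdultWeight_g", "M_Min_M_AdultWeight_g",
  "M_Max_M_AdultWeight_g",
  "S_N_F_AdultsWeighed", "M_Mean_F_AdultWeight_g", "M_Min_F_AdultWeight_g",
  "M_Max_F_AdultWeight_g",
  "S_N_All_NeonatesWeighed", "M_Mean_All_NeonateWeight_g",
  "M_Min_All_NeonateWeight_g", "M_Max_All_NeonateWeight_g",
  "S_N_M_NeonatesWeighed", "M_Mean_M_NeonateWeight_g",
  "M_Min_M_NeonateWeight_g", "M_Max_M_NeonateWeight_g",
  "S_N_F_NeonatesWeighed", "M_Mean_F_NeonateWeight_g",
  "M_Min_F_NeonateWeight_g", "M_Max_F_NeonateWeight_g",
  "S_N_All_YngAdltsWeighed", "M_Mean_All_YngAdultWeight_g",
  "M_Min_All_YngAdultWeight_g", "M_Max_All_YngAdultWeight_g",
  "S_N_M_YngAdultsWeighed", "M_Mean_M_YngAdultWeight_g",
  "M_Min_M_YngAdultWeight_g", "M_Max_M_YngAdultWeight_g",
  "S_N_F_YngAdultsWeighed", "M_Mean_F_YngAdultWeight_g",
  "M_Min_F_YngAdultWeight_g", "M_Max_F_YngAdultWeight_g",
  "L_Max_All_Age_y", "L_Max_M_Age_y", "L_Max_F_Age_y",
  "L_Median_All_Longevity_gt30d_y", "L_Median_M_Longevity_gt30d_y",
  "L_Median_F_Longevity_gt30d_y",
  "S_N_All_Survival_gt30d", "S_N_M_Survival_gt30d", "S_N_F_Survival_gt30d",
  "L_Pct_All_InfMort_lt30d", "L_Pct_M_InfMort_lt30d",
  "L_Pct_F_InfMort_lt30d", "L_Pct_ND_InfMort_lt30d",
  "S_N_All_InfMort_lt30d", "S_N_M_InfMort_lt30d", "S_N_F_InfMort_lt30d",
  "S_N_ND_InfMort_lt30d",
  "O_NocturnalOrDiurnal", "O_N_All_Biosample_Individuals"
)

# Fixed decimal places for the character reference layout, by variable.
lh_digits <- function(var) {
  if (var == "R_Ratio_MtoF_DLCBirths") return(3L)
  if (grepl("^(M_|L_)", var) || var %in%
        c("R_Mean_LitterSize", "R_Freq_MostCommon_LitterSize",
          "R_Min_Dam_AgeAtConcep_y", "R_Min_Sire_AgeAtConcep_y",
          "R_Max_Dam_AgeAtConcep_y", "R_Max_Sire_AgeAtConcep_y")) {
    if (var %in% c("L_Max_All_Age_y", "L_Max_M_Age_y", "L_Max_F_Age_y",
                   "L_Median_All_Longevity_gt30d_y",
                   "L_Median_M_Longevity_gt30d_y",
                   "L_Median_F_Longevity_gt30d_y") ||
          grepl("^(M_Mean|M_Min|M_Max|L_Pct)", var) ||
          var %in% c("R_Mean_LitterSize", "R_Freq_MostCommon_LitterSize",
                     "R_Min_Dam_AgeAtConcep_y", "R_Min_Sire_AgeAtConcep_y",
                     "R_Max_Dam_AgeAtConcep_y", "R_Max_Sire_AgeAtConcep_y")) {
      return(2L)
    }
  }
  NA_integer_  # integer or character variable
}

count_by_sex <- function(df) {
  list(all = nrow(df),
       m = sum(!is.na(df$Sex) & df$Sex == "M"),
       f = sum(!is.na(df$Sex) & df$Sex == "F"),
       nd = sum(!is.na(df$Sex) & df$Sex == "ND"))
}

lh_row_for_taxon <- function(tx, animals, weights, registry, cfg) {
  reg <- registry_row(registry, tx)
  a <- animals[animals$Taxon == tx, , drop = FALSE]
  w <- weights[weights$Taxon == tx, , drop = FALSE]
  row <- stats::setNames(vector("list", length(LH_VARS)), LH_VARS)

  # --- S: counts ---
  hist_n <- count_by_sex(a)
  row$S_N_All_Historic <- hist_n$all
  row$S_N_M_Historic <- hist_n$m
  row$S_N_F_Historic <- hist_n$f
  row$S_N_ND_Historic <- hist_n$nd
  cb <- count_by_sex(a[!is.na(a$Birth_Type) & a$Birth_Type == "CB", ,
                       drop = FALSE])
  row$S_N_All_CaptiveBorn <- cb$all
  row$S_N_M_CaptiveBorn <- cb$m
  row$S_N_F_CaptiveBorn <- cb$f
  wb <- count_by_sex(a[!is.na(a$Birth_Type) & a$Birth_Type == "WB", ,
                       drop = FALSE])
  row$S_N_All_WildBorn <- wb$all
  row$S_N_M_WildBorn <- wb$m
  row$S_N_F_WildBorn <- wb$f
  cr <- count_by_sex(a[!is.na(a$Current_Resident) &
                         a$Current_Resident == "Y", , drop = FALSE])
  row$S_N_All_CurrentResident <- cr$all
  row$S_N_M_CurrentResident <- cr$m
  row$S_N_F_CurrentResident <- cr$f
  dlc <- count_by_sex(a[is_dlc_born(a), , drop = FALSE])
  row$S_N_All_DLCBorn_Infant <- dlc$all
  row$S_N_M_DLCBorn_Infant <- dlc$m
  row$S_N_F_DLCBorn_Infant <- dlc$f
  row$S_N_ND_DLCBorn_Infant <- dlc$nd

  # --- R: reproduction ---
  row$R_Ratio_MtoF_DLCBirths <- if (nrow(a) > 0) birth_sex_ratio(a, tx)
  else NA_real_
  litters <- build_litters(a, tx)
  row$S_N_All_DLCBorn_Litter <- nrow(litters)
  if (nrow(litters) > 0) {
    ls <- litter_stats(litters)
    row$R_Mean_LitterSize <- ls$mean
    row$R_MostCommon_LitterSize <- ls$most_common
    row$R_Freq_MostCommon_LitterSize <- ls$freq_most_common
    row$R_Min_LitterSize <- ls$min
    row$R_Max_LitterSize <- ls$max
  }
  row$R_Expected_Gestation_d <- reg$expected_gestation_d
  row$R_Range_Gestation_d <- paste0(reg$gestation_lo_d, "-",
                                    reg$gestation_hi_d)
  row$R_Pattern_Breeding <- reg$breeding_pattern
  seasonal <- reg$breeding_pattern == "S"
  if (!seasonal) {
    row$R_Peak_Breeding_Month <- 0L
    row$R_Peak_Breeding_Season <- "0"
    row$R_Peak_Birth_Month <- 0L
    row$R_Peak_Birth_Season <- "0"
  } else if (nrow(litters) > 0) {
    # conception-based stats exclude litters with no member surviving 1 day
    # (premature-birth control); birth-based stats use all litters
    concep_lit <- litters[litters$any_survived_1d, , drop = FALSE]
    if (nrow(concep_lit) > 0) {
      h <- month_histogram(month_of(concep_lit$conception_date))
      row$R_Peak_Breeding_Month <- peak_month(h)
      row$R_Peak_Breeding_Season <- format_season(peak_season(h), "S")
    }
    hb <- month_histogram(month_of(litters$birth_date))
    row$R_Peak_Birth_Month <- peak_month(hb)
    row$R_Peak_Birth_Season <- format_season(peak_season(hb), "S")
  }
  if (nrow(a) > 0) {
    ext <- parental_age_extremes(animals, tx)
    row$R_Min_Dam_AgeAtConcep_y <- round_or_na(ext$min_dam, 2)
    row$R_Min_Sire_AgeAtConcep_y <- round_or_na(ext$min_sire, 2)
    row$R_Max_Dam_AgeAtConcep_y <- round_or_na(ext$max_dam, 2)
    row$R_Max_Sire_AgeAtConcep_y <- round_or_na(ext$max_sire, 2)
  }
  row$R_Active_DLCBreeding <- reg$active_dlc_breeding

  # --- M: body mass ---
  if (nrow(w) > 0) {
    for (sx in list(list(NULL, "All"), list("M", "M"), list("F", "F"))) {
      neo <- neonate_summary(w, animals, tx, sex = sx[[1]], cfg = cfg)
      row[[paste0("S_N_", sx[[2]], "_NeonatesWeighed")]] <- neo$n
      row[[paste0("M_Mean_", sx[[2]], "_NeonateWeight_g")]] <- neo$mean_g
      row[[paste0("M_Min_", sx[[2]], "_NeonateWeight_g")]] <- neo$min_g
      row[[paste0("M_Max_", sx[[2]], "_NeonateWeight_g")]] <- neo$max_g
    }
    wf <- filter_weights(w, animals, cfg)
    for (cls in c("adult", "young_adult")) {
      inds <- individual_mass_means(wf, cls)
      kept <- obesity_filter(inds, cfg)$kept
      stem <- if (cls == "adult") "AdultWeight_g" else "YngAdultWeight_g"
      nname <- function(sx) {
        if (cls == "adult") paste0("S_N_", sx, "_AdultsWeighed")
        else if (sx == "All") "S_N_All_YngAdltsWeighed"
        else paste0("S_N_", sx, "_YngAdultsWeighed")
      }
      for (sx in list(list(NULL, "All"), list("M", "M"), list("F", "F"))) {
        sm <- species_mass_summary(kept, sex = sx[[1]])
        row[[nname(sx[[2]])]] <- sm$n
        row[[paste0("M_Mean_", sx[[2]], "_", stem)]] <- sm$mean_g
        row[[paste0("M_Min_", sx[[2]], "_", stem)]] <- sm$min_g
        row[[paste0("M_Max_", sx[[2]], "_", stem)]] <- sm$max_g
      }
    }
  }

  # --- L: longevity ---
  if (nrow(a) > 0) {
    for (sx in list(list(NULL, "All"), list("M", "M"), list("F", "F"))) {
      row[[paste0("L_Max_", sx[[2]], "_Age_y")]] <- max_age(a, tx, sx[[1]])
      curve <- tryCatch(fit_survivorship(a, tx, sx[[1]]),
                        error = function(e) NULL)
      if (!is.null(curve)) {
        row[[paste0("S_N_", sx[[2]], "_Survival_gt30d")]] <- curve$n
        row[[paste0("L_Median_", sx[[2]], "_Longevity_gt30d_y")]] <-
          round_or_na(weighted_median_longevity(curve), 2)
      } else {
        row[[paste0("S_N_", sx[[2]], "_Survival_gt30d")]] <- 0L
      }
    }
    for (sx in list(list(NULL, "All"), list("M", "M"), list("F", "F"),
                    list("ND", "ND"))) {
      im <- infant_mortality(a, tx, sx[[1]])
      row[[paste0("L_Pct_", sx[[2]], "_InfMort_lt30d")]] <- im$pct
      row[[paste0("S_N_", sx[[2]], "_InfMort_lt30d")]] <- im$n_died
    }
  }

  # --- O: other ---
  row$O_NocturnalOrDiurnal <- reg$activity
  row$O_N_All_Biosample_Individuals <- reg$n_biosample_individuals

  row
}

#' Build the per-taxon life-history table
#'
#' Computes all 91 summary variables for every taxon present in the animal
#' list (plus any registry taxa with no records, which yield rows of missing
#' values with the registry pass-through fields populated).
#'
#' @param animals Animal-record data.frame (e.g. from [read_animal_list()]).
#' @param weights Weight-record data.frame with derived columns filled.
#' @param registry Taxon registry.
#' @param cfg A [mass_config()].
#' @param taxa Taxon codes to include; defaults to all registry taxa that
#'   appear in `animals`, in registry order.
#' @return Data.frame of class `life_history_table`: column `Taxon` plus the
#'   91 variables, one row per taxon.
#' @export
build_life_history_table <- function(animals, weights,
                                     registry = default_registry(),
                                     cfg = mass_config(), taxa = NULL) {
  present <- unique(c(animals$Taxon, weights$Taxon))
  missing_reg <- setdiff(present, registry$taxon)
  if (length(missing_reg) > 0) {
    stop("taxon code(s) present in records but absent from registry: ",
         paste(missing_reg, collapse = ", "))
  }
  if (is.null(taxa)) taxa <- registry$taxon[registry$taxon %in% present]
  rows <- lapply(taxa, lh_row_for_taxon, animals = animals,
                 weights = weights, registry = registry, cfg = cfg)
  out <- data.frame(Taxon = taxa, stringsAsFactors = FALSE)
  for (v in LH_VARS) {
    vals <- lapply(rows, function(r) r[[v]] %||% NA)
    is_chr <- any(vapply(vals, is.character, logical(1)))
    out[[v]] <- if (is_chr) {
      vapply(vals, function(x) if (is.null(x) || all(is.na(x)))
        NA_character_ else as.character(x), character(1))
    } else {
      vapply(vals, function(x) if (is.null(x) || all(is.na(x)))
        NA_real_ else as.numeric(x), numeric(1))
    }
  }
  class(out) <- c("life_history_table", "data.frame")
  out
}

# Character columns of the table (everything else is numeric).
LH_CHR_VARS <- c("R_MostCommon_LitterSize", "R_Range_Gestation_d",
                 "R_Pattern_Breeding", "R_Peak_Breeding_Season",
                 "R_Peak_Birth_Season", "R_Active_DLCBreeding",
                 "O_NocturnalOrDiurnal")

format_lh_value <- function(var, x) {
  if (is.na(x)) return(".")
  # zero counts print as "." in the published reference layout
  if (grepl("^S_N_", var) && is.numeric(x) && x == 0) return(".")
  dg <- lh_digits(var)
  if (!is.na(dg) && is.numeric(x)) return(sprintf(paste0("%.", dg, "f"), x))
  if (is.numeric(x) && x == round(x)) return(format(as.integer(x)))
  as.character(x)
}

#' Serialize the reference layout
#'
#' Writes the character-format reference version: one row per variable (91
#' rows), one column per taxon, missing values printed as `"."`, fixed
#' decimal places per variable.
#'
#' @param table A `life_history_table`.
#' @param path Output CSV path.
#' @return The reference data.frame (column `Variable` + taxon columns),
#'   invisibly written to `path` when given.
#' @export
serialize_reference <- function(table, path = NULL) {
  ref <- data.frame(Variable = LH_VARS, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(table))) {
    ref[[table$Taxon[i]]] <- vapply(LH_VARS, function(v) {
      format_lh_value(v, table[[v]][i])
    }, character(1))
  }
  if (!is.null(path)) {
    utils::write.csv(ref, path, row.names = FALSE, quote = TRUE)
  }
  ref
}

#' Serialize the analysis layout
#'
#' Writes the analysis version: one row per taxon, the 91 variables as typed
#' columns (numeric columns numeric), ready for direct import into analysis
#' software.
#'
#' @param table A `life_history_table`.
#' @param path Output CSV path.
#' @return `table` as a plain data.frame; written to `path` when given.
#' @export
serialize_analysis <- function(table, path = NULL) {
  out <- as.data.frame(table)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = ".")
  }
  out
}

#' Read an analysis-layout table
#'
#' @param path CSV written by [serialize_analysis()].
#' @return A `life_history_table` data.frame.
#' @export
read_analysis_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = ".",
                        check.names = FALSE,
                        colClasses = c(Taxon = "character"))
  for (v in intersect(LH_CHR_VARS, names(df))) {
    df[[v]] <- as.character(df[[v]])
  }
  class(df) <- c("life_history_table", "data.frame")
  df
}

#' @export
print.life_history_table <- function(x, ...) {
  cat("life-history table:", nrow(x), "taxa x", ncol(x) - 1, "variables\n")
  print(utils::head(as.data.frame(x)[, 1:8]), row.names = FALSE)
  invisible(x)
}
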
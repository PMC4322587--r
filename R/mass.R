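# Body-mass derivations: the weight-file derived columns, neonate summaries,
# the adult/young-adult exclusion cascade (pre-death window, pregnancy,
# wild-caught juveniles), monthly-then-overall individual means, and the
# two-standard-deviation obesity screen.

#' Mass-summary configuration
#'
#' Tunable parameters of the body-mass exclusion cascade.
#'
#' @param predeath_exclusion_d Drop weights taken fewer than this many days
#'   before death (default 60).
#' @param obesity_sd_multiplier Individuals whose overall mean exceeds the
#'   group mean by more than this many sample standard deviations are flagged
#'   obese (default 2).
#' @param neonate_days Ages in days eligible for neonate weights (default
#'   0:1).
#' @param neonate_min_survival_d Minimum survival in days for neonate
#'   inclusion (default 1).
#' @param adult_age_multiplier Adult age cutoff as a multiple of the minimum
#'   dam age at conception (default 2).
#' @param seasonal_month_subset Optional integer months (1-12) restricting
#'   the weight records used, for season-specific summaries.
#' @return List of class `mass_config`.
#' @export
mass_config <- function(predeath_exclusion_d = 60, obesity_sd_multiplier = 2,
                        neonate_days = 0:1, neonate_min_survival_d = 1,
                        adult_age_multiplier = 2,
                        seasonal_month_subset = NULL) {
  stopifnot(predeath_exclusion_d > 0, obesity_sd_multiplier > 0,
            neonate_min_survival_d > 0, adult_age_multiplier > 0)
  structure(list(predeath_exclusion_d = predeath_exclusion_d,
                 obesity_sd_multiplier = obesity_sd_multiplier,
                 neonate_days = neonate_days,
                 neonate_min_survival_d = neonate_min_survival_d,
                 adult_age_multiplier = adult_age_multiplier,
                 seasonal_month_subset = seasonal_month_subset),
            class = "mass_config")
}

#' Age class at weighing
#'
#' Classifies an age against the species' minimum dam age at conception `m`:
#' infant/juvenile below `m`, young adult in `[m, 2m)`, adult at or above
#' `2m`.
#'
#' @param age_y Age(s) at weighing in years.
#' @param min_dam_aac_y Species minimum dam age at conception in years (> 0).
#' @param adult_age_multiplier Adult cutoff multiplier (default 2).
#' @return Character vector in `{"IJ", "young_adult", "adult"}`.
#' @export
classify_age <- function(age_y, min_dam_aac_y, adult_age_multiplier = 2) {
  stopifnot(min_dam_aac_y > 0)
  if (any(age_y < 0, na.rm = TRUE)) stop("negative age at weighing")
  ifelse(is.na(age_y), NA_character_,
         ifelse(age_y < min_dam_aac_y, "IJ",
                ifelse(age_y < adult_age_multiplier * min_dam_aac_y,
                       "young_adult", "adult")))
}

#' Fill the calculated weight-file columns
#'
#' Sorts records by individual and date, then fills ages at weighing,
#' between-weighing deltas, days before death, the age category (from the
#' supplied per-taxon minimum dam ages at conception), and the pregnancy
#' block: a dam is pregnant at a weighing iff the weighing date falls in
#' `[conception, birth)` of one of her litters. All males are coded `NP`.
#'
#' @param weights Weight-record data.frame (direct columns populated).
#' @param animals Animal-record data.frame (for dates of death).
#' @param litters Litter-event data.frame over all taxa
#'   (from [build_litters()]).
#' @param min_dam_aac Named numeric vector of minimum dam age at conception
#'   in years, by taxon code.
#' @return The weight data.frame with derived columns filled, sorted by
#'   (`DLC_ID`, `Weight_Date`).
#' @export
weight_derived_columns <- function(weights, animals, litters, min_dam_aac) {
  w <- weights[order(weights$DLC_ID, weights$Weight_Date), , drop = FALSE]
  rownames(w) <- NULL

  d <- as.numeric(w$Weight_Date - w$DOB)
  w$MonthOfWeight <- month_of(w$Weight_Date)
  w$AgeAtWt_d <- d
  w$AgeAtWt_wk <- round(d / 7, 6)
  w$AgeAtWt_mo <- round(d / DAYS_PER_YEAR * 12, 6)
  w$AgeAtWt_mo_NoDec <- floor(d / DAYS_PER_YEAR * 12)
  w$AgeAtWt_y <- round(d / DAYS_PER_YEAR, 6)

  ai <- match(w$DLC_ID, animals$DLC_ID)
  w$DOD <- animals$DOD[ai]
  w$DaysBeforeDeath <- as.numeric(w$DOD - w$Weight_Date)

  new_id <- c(TRUE, w$DLC_ID[-1] != w$DLC_ID[-nrow(w)])
  prev_date <- c(as.Date(NA), w$Weight_Date[-nrow(w)])
  prev_wt <- c(NA_real_, w$Weight_g[-nrow(w)])
  w$Days_Since_PrevWt <- ifelse(new_id, NA_real_,
                                as.numeric(w$Weight_Date - prev_date))
  w$Change_Since_PrevWt_g <- ifelse(new_id, NA_real_, w$Weight_g - prev_wt)
  w$Avg_Daily_WtChange_g <-
    round(ifelse(new_id | w$Days_Since_PrevWt == 0, NA_real_,
                 w$Change_Since_PrevWt_g / w$Days_Since_PrevWt), 6)

  w$R_Min_Dam_AgeAtConcep_y <- unname(min_dam_aac[w$Taxon])
  mm <- w$R_Min_Dam_AgeAtConcep_y
  cls <- classify_age(w$AgeAtWt_y, ifelse(is.na(mm), 1, mm))
  cls[is.na(mm)] <- NA_character_
  w$Age_Category <- cls

  w$Preg_Status <- "NP"
  w$ConcepDate_IfPreg <- as.Date(NA)
  w$InfantDOB_IfPreg <- as.Date(NA)
  w$DaysBeforeInfBirth_IfPreg <- NA_real_
  w$Pct_PregRemain_IfPreg <- NA_real_
  w$InfantLitSz_IfPreg <- NA_integer_

  if (nrow(litters) > 0) {
    lit <- litters[!is.na(litters$dam_id), , drop = FALSE]
    fem <- which(!is.na(w$Sex) & w$Sex == "F" & w$DLC_ID %in% lit$dam_id)
    for (i in fem) {
      dl <- lit[lit$dam_id == w$DLC_ID[i] &
                  lit$conception_date <= w$Weight_Date[i] &
                  w$Weight_Date[i] < lit$birth_date, , drop = FALSE]
      if (nrow(dl) == 0) next
      dl <- dl[1, ]
      w$Preg_Status[i] <- "P"
      w$ConcepDate_IfPreg[i] <- dl$conception_date
      w$InfantDOB_IfPreg[i] <- dl$birth_date
      dbb <- as.numeric(dl$birth_date - w$Weight_Date[i])
      w$DaysBeforeInfBirth_IfPreg[i] <- dbb
      w$Pct_PregRemain_IfPreg[i] <- round(dbb / w$Expected_Gestation_d[i], 6)
      w$InfantLitSz_IfPreg[i] <- dl$size
    }
  }
  w
}

#' Neonate mass summary
#'
#' Per-individual neonate value: the weight on the day of birth (day 0) or
#' day 1, averaged when both exist. Individuals that did not survive at
#' least one day are excluded so unviable stillborn weights cannot depress
#' species values.
#'
#' @param weights Weight-record data.frame.
#' @param animals Animal-record data.frame.
#' @param taxon Taxon code.
#' @param sex Optional sex filter.
#' @param cfg A [mass_config()].
#' @return List: `n` individuals, `mean_g`, `min_g`, `max_g` (2 dp; `NA`
#'   when no qualifying neonates).
#' @export
neonate_summary <- function(weights, animals, taxon, sex = NULL,
                            cfg = mass_config()) {
  w <- weights[weights$Taxon == taxon &
                 weights$AgeAtWt_d %in% cfg$neonate_days, , drop = FALSE]
  if (!is.null(sex)) w <- w[!is.na(w$Sex) & w$Sex == sex, , drop = FALSE]
  if (nrow(w) > 0) {
    ai <- match(w$DLC_ID, animals$DLC_ID)
    ok <- survived_at_least(animals, cfg$neonate_min_survival_d)[ai]
    w <- w[!is.na(ok) & ok, , drop = FALSE]
  }
  if (nrow(w) == 0) {
    return(list(n = 0L, mean_g = NA_real_, min_g = NA_real_,
                max_g = NA_real_))
  }
  # average within day (duplicate weighings), then across day 0/day 1
  day_means <- stats::aggregate(Weight_g ~ DLC_ID + AgeAtWt_d, data = w,
                                FUN = mean)
  ind <- stats::aggregate(Weight_g ~ DLC_ID, data = day_means, FUN = mean)
  list(n = nrow(ind), mean_g = round(mean(ind$Weight_g), 2),
       min_g = round(min(ind$Weight_g), 2),
       max_g = round(max(ind$Weight_g), 2))
}

#' Apply the adult-mass exclusion cascade
#'
#' Drops weights taken within the pre-death window, weights of pregnant
#' females, and weights of wild-born animals at estimated ages younger than
#' the species' minimum dam age at conception; optionally restricts to a set
#' of calendar months.
#'
#' @param weights Weight-record data.frame with derived columns filled.
#' @param animals Animal-record data.frame (unused directly; accepted for
#'   interface symmetry with other summaries).
#' @param cfg A [mass_config()].
#' @return Filtered weight data.frame.
#' @export
filter_weights <- function(weights, animals = NULL, cfg = mass_config()) {
  keep <- rep(TRUE, nrow(weights))
  keep <- keep & !(!is.na(weights$DaysBeforeDeath) &
                     weights$DaysBeforeDeath < cfg$predeath_exclusion_d)
  keep <- keep & !(!is.na(weights$Preg_Status) & weights$Preg_Status == "P")
  keep <- keep & !(!is.na(weights$Birth_Type) & weights$Birth_Type == "WB" &
                     !is.na(weights$AgeAtWt_y) &
                     !is.na(weights$R_Min_Dam_AgeAtConcep_y) &
                     weights$AgeAtWt_y < weights$R_Min_Dam_AgeAtConcep_y)
  if (!is.null(cfg$seasonal_month_subset)) {
    keep <- keep & weights$MonthOfWeight %in% cfg$seasonal_month_subset
  }
  weights[keep, , drop = FALSE]
}

#' Individual mean masses within an age class
#'
#' Weights are bucketed by calendar year-month and averaged within each
#' bucket, so periods of frequent weighing (research projects, health
#' concerns) cannot bias an individual's value; the individual mean is the
#' unweighted mean across its monthly means.
#'
#' @param weights Filtered weight data.frame.
#' @param age_class `"young_adult"` or `"adult"`.
#' @return Data.frame: `DLC_ID`, `Sex`, `n_months`, `mean_g`.
#' @export
individual_mass_means <- function(weights,
                                  age_class = c("adult", "young_adult")) {
  age_class <- match.arg(age_class)
  w <- weights[!is.na(weights$Age_Category) &
                 weights$Age_Category == age_class, , drop = FALSE]
  if (nrow(w) == 0) {
    return(data.frame(DLC_ID = character(0), Sex = character(0),
                      n_months = integer(0), mean_g = numeric(0),
                      stringsAsFactors = FALSE))
  }
  w$ym <- format(w$Weight_Date, "%Y-%m")
  monthly <- stats::aggregate(Weight_g ~ DLC_ID + ym, data = w, FUN = mean)
  ind <- stats::aggregate(Weight_g ~ DLC_ID, data = monthly, FUN = mean)
  nm <- stats::aggregate(ym ~ DLC_ID, data = monthly, FUN = length)
  sex <- w$Sex[match(ind$DLC_ID, w$DLC_ID)]
  out <- data.frame(DLC_ID = ind$DLC_ID, Sex = sex,
                    n_months = nm$ym[match(ind$DLC_ID, nm$DLC_ID)],
                    mean_g = ind$Weight_g, stringsAsFactors = FALSE)
  out[order(out$DLC_ID), , drop = FALSE]
}

#' Obesity screen
#'
#' Single-pass flagging of individuals whose overall mean mass lies strictly
#' more than `obesity_sd_multiplier` sample standard deviations above the
#' group mean; flagged individuals are removed so species means are not
#' skewed upward. Both sexes are pooled for the screen.
#'
#' @param inds Individual-means data.frame from [individual_mass_means()].
#' @param cfg A [mass_config()].
#' @return List with `kept` and `obese` data.frames.
#' @export
obesity_filter <- function(inds, cfg = mass_config()) {
  if (nrow(inds) < 2) {
    return(list(kept = inds, obese = inds[0, , drop = FALSE]))
  }
  m <- mean(inds$mean_g)
  s <- stats::sd(inds$mean_g)
  thr <- m + cfg$obesity_sd_multiplier * s
  obese <- inds$mean_g > thr
  list(kept = inds[!obese, , drop = FALSE],
       obese = inds[obese, , drop = FALSE])
}

#' Species mass summary over retained individuals
#'
#' Mean, minimum and maximum of the retained (non-obese) individual means,
#' optionally for one sex; `n` counts individuals, not weighings.
#'
#' @param kept Individual-means data.frame after [obesity_filter()].
#' @param sex Optional sex filter.
#' @return List: `n`, `mean_g`, `min_g`, `max_g` (2 dp).
#' @export
species_mass_summary <- function(kept, sex = NULL) {
  if (!is.null(sex)) kept <- kept[!is.na(kept$Sex) & kept$Sex == sex, ,
                                  drop = FALSE]
  if (nrow(kept) == 0) {
    return(list(n = 0L, mean_g = NA_real_, min_g = NA_real_,
                max_g = NA_real_))
  }
  list(n = nrow(kept), mean_g = round(mean(kept$mean_g), 2),
       min_g = round(min(kept$mean_g), 2),
       max_g = round(max(kept$mean_g), 2))
}
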
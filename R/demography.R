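# Reproduction-category derivations: conception back-calculation, estimated
# dates of birth for wild-caught animals, parental ages at conception,
# litter construction and litter/sex-ratio statistics.

#' Estimated conception date
#'
#' Back-calculates the expected conception date by subtracting the species'
#' expected gestation length from the infant's date of birth.
#'
#' @param dob `Date` of birth.
#' @param gestation_d Expected gestation length in days (>= 0).
#' @return `Date` of estimated conception.
#' @export
estimate_conception <- function(dob, gestation_d) {
  stopifnot(all(gestation_d >= 0, na.rm = TRUE))
  dob - gestation_d
}

#' Assign an estimated date of birth for a wild-caught animal
#'
#' Applies the colony estimation rule. When an estimated birth year is
#' documented: seasonal breeders receive the first day of the middle month of
#' the breeding season in the country of origin in that year; non-seasonal
#' breeders receive the acquisition month and day with the estimated year.
#' When only "adult" was recorded, the animal is assigned an age equal to the
#' species' minimum dam age at conception as of acquisition (estimate code
#' `"U"`), so all its derived ages are minima.
#'
#' @param acquisition_date `Date` the animal entered the colony.
#' @param est_birth_year Documented estimated year of birth, or `NULL`.
#' @param pattern Breeding pattern, `"S"` or `"NS"`.
#' @param origin_midmonth Middle month (1-12) of the breeding season in the
#'   country of origin; required for seasonal breeders with a year estimate.
#' @param adult_only `TRUE` when no year estimate exists and the animal was
#'   recorded only as adult.
#' @param min_dam_aac_y Species minimum dam age at conception in years;
#'   required when `adult_only`.
#' @return List with `dob` (`Date`) and `code` (estimate code `"Y"`/`"U"`).
#' @export
assign_estimated_dob <- function(acquisition_date, est_birth_year = NULL,
                                 pattern = c("S", "NS"),
                                 origin_midmonth = NULL, adult_only = FALSE,
                                 min_dam_aac_y = NULL) {
  pattern <- match.arg(pattern)
  acquisition_date <- as.Date(acquisition_date)
  if (adult_only) {
    if (is.null(min_dam_aac_y)) {
      stop("adult-only estimation requires min_dam_aac_y")
    }
    return(list(dob = acquisition_date - round(min_dam_aac_y * DAYS_PER_YEAR),
                code = "U"))
  }
  if (is.null(est_birth_year)) {
    stop("either est_birth_year or adult_only must be given")
  }
  if (pattern == "S") {
    if (is.null(origin_midmonth)) {
      stop("seasonal estimation requires origin_midmonth")
    }
    dob <- as.Date(sprintf("%04d-%02d-01", est_birth_year, origin_midmonth))
  } else {
    md <- format(acquisition_date, "%m-%d")
    if (md == "02-29" && is.na(as.Date(sprintf("%04d-02-29", est_birth_year)))) {
      md <- "02-28"
    }
    dob <- as.Date(sprintf("%04d-%s", est_birth_year, md))
  }
  list(dob = dob, code = "Y")
}

# Age at death in years at full precision, from dates where available,
# falling back on the stored (possibly rounded) column.
age_at_death_full <- function(animals) {
  ifelse(!is.na(animals$DOD) & !is.na(animals$DOB),
         age_years(animals$DOB, animals$DOD),
         animals$AgeAtDeath_y)
}

# TRUE when the animal is known to have survived at least `days` days
# (no recorded death, or death at or beyond the threshold).
survived_at_least <- function(animals, days) {
  aad <- age_at_death_full(animals)
  is.na(aad) | aad >= days / DAYS_PER_YEAR
}

has_exact_dob <- function(animals) {
  is.na(animals$Estimated_DOB) | animals$Estimated_DOB == ""
}

is_dlc_born <- function(animals) {
  !is.na(animals$Birth_Institution) &
    animals$Birth_Institution == DLC_INSTITUTION
}

# Sire identifiers that do not resolve to a unique known individual.
is_unresolved_sire <- function(sire_id) {
  is.na(sire_id) | grepl("^MULT", sire_id, ignore.case = TRUE) |
    toupper(sire_id) %in% c("UNK", "WILD")
}

#' Parental age extremes at conception
#'
#' Minimum and maximum dam and sire ages at (estimated) conception for one
#' taxon. Minima use only exact dates of birth for both the offspring and the
#' parent; maxima include estimated dates. Offspring that did not survive at
#' least one day are excluded (premature-birth control), as are offspring
#' whose sire is unknown or one of multiple candidates (sire statistics only).
#'
#' @param animals Animal-record data.frame (all taxa; parents may belong to a
#'   different taxon than the offspring).
#' @param taxon Taxon code selecting the offspring.
#' @return List with `min_dam`, `max_dam`, `min_sire`, `max_sire` in years
#'   (`NA` when no qualifying offspring).
#' @export
parental_age_extremes <- function(animals, taxon) {
  off <- animals[animals$Taxon == taxon & survived_at_least(animals, 1), ,
                 drop = FALSE]
  exact_parent <- function(ids) {
    i <- match(ids, animals$DLC_ID)
    ok <- !is.na(i) & has_exact_dob(animals)[ifelse(is.na(i), 1L, i)]
    ok & !is.na(ids)
  }
  ext <- function(ages, exact) {
    list(min = if (any(exact & !is.na(ages))) min(ages[exact], na.rm = TRUE)
         else NA_real_,
         max = if (any(!is.na(ages))) max(ages, na.rm = TRUE) else NA_real_)
  }

  off_exact <- has_exact_dob(off)
  dam_ages <- age_years(off$Dam_DOB, off$Estimated_Concep)
  dam_exact <- off_exact & exact_parent(off$Dam_ID)
  dam <- ext(dam_ages, dam_exact)

  sire_ok <- !is_unresolved_sire(off$Sire_ID)
  sire_ages <- ifelse(sire_ok, age_years(off$Sire_DOB, off$Estimated_Concep),
                      NA_real_)
  sire_exact <- off_exact & sire_ok & exact_parent(off$Sire_ID)
  sire <- ext(sire_ages, sire_exact)

  list(min_dam = dam$min, max_dam = dam$max,
       min_sire = sire$min, max_sire = sire$max)
}

#' Group DLC-born individuals into litter events
#'
#' A litter event is the set of infants born to one dam on one exact date;
#' the event (not the individual) is the unit for seasonality and litter-size
#' statistics. Records with no dam identifier become singleton events.
#'
#' @param animals Animal-record data.frame.
#' @param taxon Taxon code.
#' @return Data.frame with one row per litter: `taxon`, `dam_id`,
#'   `birth_date`, `conception_date`, `size`, `member_ids`
#'   (semicolon-joined), `any_survived_1d`, and `litter_size_mismatch`
#'   flagging disagreement between member count and the stored litter-size
#'   field.
#' @export
build_litters <- function(animals, taxon) {
  born <- animals[animals$Taxon == taxon & is_dlc_born(animals), ,
                  drop = FALSE]
  if (nrow(born) == 0) {
    return(data.frame(taxon = character(0), dam_id = character(0),
                      birth_date = as.Date(character(0)),
                      conception_date = as.Date(character(0)),
                      size = integer(0), member_ids = character(0),
                      any_survived_1d = logical(0),
                      litter_size_mismatch = logical(0),
                      stringsAsFactors = FALSE))
  }
  dam_key <- ifelse(is.na(born$Dam_ID),
                    paste0(".solo.", born$DLC_ID), born$Dam_ID)
  key <- paste(dam_key, format(born$DOB, "%Y-%m-%d"), sep = "|")
  surv1 <- survived_at_least(born, 1)
  groups <- split(seq_len(nrow(born)), key)
  rows <- lapply(groups, function(idx) {
    g <- born[idx, , drop = FALSE]
    data.frame(
      taxon = taxon,
      dam_id = if (is.na(g$Dam_ID[1])) NA_character_ else g$Dam_ID[1],
      birth_date = g$DOB[1],
      conception_date = estimate_conception(g$DOB[1],
                                            g$Expected_Gestation_d[1]),
      size = length(idx),
      member_ids = paste(g$DLC_ID, collapse = ";"),
      any_survived_1d = any(surv1[idx]),
      litter_size_mismatch = any(!is.na(g$Litter_Size) &
                                   g$Litter_Size != length(idx)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$birth_date, out$dam_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Litter-size statistics
#'
#' Mean, most common (ties reported together), frequency of the most common
#' size, minimum and maximum litter size over a set of litter events. All
#' births are included, whether or not the infants survived.
#'
#' @param litters Litter-event data.frame from [build_litters()], or a
#'   numeric vector of litter sizes.
#' @return List: `mean` (2 dp), `most_common` (comma-joined ascending string
#'   on ties), `freq_most_common` (per-size frequency, 2 dp), `min`, `max`.
#' @export
litter_stats <- function(litters) {
  sizes <- if (is.data.frame(litters)) litters$size else litters
  if (length(sizes) == 0) stop("litter_stats requires at least one litter")
  tab <- table(sizes)
  modal <- as.integer(names(tab)[tab == max(tab)])
  list(
    mean = round(mean(sizes), 2),
    most_common = paste(sort(modal), collapse = ","),
    freq_most_common = round(max(tab) / length(sizes), 2),
    min = min(sizes),
    max = max(sizes)
  )
}

#' Birth sex ratio among DLC births
#'
#' Males per one female among DLC-born individuals of the taxon; sex-
#' undetermined individuals are excluded. Only on-site births are used
#' because imported animals may have been selected by sex.
#'
#' @param animals Animal-record data.frame.
#' @param taxon Taxon code.
#' @return Ratio rounded to 3 decimals, or `NA` when no DLC-born females.
#' @export
birth_sex_ratio <- function(animals, taxon) {
  born <- animals[animals$Taxon == taxon & is_dlc_born(animals), ,
                  drop = FALSE]
  n_m <- sum(born$Sex == "M", na.rm = TRUE)
  n_f <- sum(born$Sex == "F", na.rm = TRUE)
  if (n_f == 0) return(NA_real_)
  round(n_m / n_f, 3)
}

#' Known offspring per individual
#'
#' Number of records naming each individual as dam, or uniquely as sire.
#' Offspring with multiple candidate sires (`MULT...`) are counted for none
#' of the candidates.
#'
#' @param animals Animal-record data.frame.
#' @return Named integer vector over `DLC_ID`.
#' @export
count_offspring <- function(animals) {
  ids <- animals$DLC_ID
  dam_tab <- table(animals$Dam_ID[!is.na(animals$Dam_ID)])
  sire_ok <- !is_unresolved_sire(animals$Sire_ID)
  sire_tab <- table(animals$Sire_ID[sire_ok])
  out <- integer(length(ids))
  names(out) <- ids
  d <- dam_tab[ids]
  s <- sire_tab[ids]
  out <- ifelse(is.na(d), 0L, as.integer(d)) +
    ifelse(is.na(s), 0L, as.integer(s))
  names(out) <- ids
  out
}
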
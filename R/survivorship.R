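# Longevity-category derivations: censored product-limit survivorship,
# the distance-weighted median longevity, infant mortality and maximum ages.
#
# Deaths before 30 days of age are excluded from survivorship entirely;
# living animals and animals last verified alive elsewhere enter as
# right-censored observations. Survivorship is the product-limit
# (Kaplan-Meier) estimate over distinct death ages, with deaths processed
# before censorings at tied times.

INFANT_CUTOFF_Y <- 30 / DAYS_PER_YEAR

#' Fit a censored survivorship curve
#'
#' Builds the product-limit survivorship estimate for one taxon (optionally
#' one sex) after excluding deaths before 30 days of age. Dead animals
#' contribute death ages; living animals are censored at their current age;
#' animals last verified alive elsewhere are censored at that age.
#'
#' @param animals Animal-record data.frame.
#' @param taxon Taxon code.
#' @param sex Optional `"M"`/`"F"`/`"ND"` filter.
#' @return Object of class `survivorship_curve`: list with `event_ages_y`,
#'   `survivorship` (step value after each event age), `n_event`, `n_risk`,
#'   `censored_ages_y` and `n` (risk-set size at age 0).
#' @export
fit_survivorship <- function(animals, taxon, sex = NULL) {
  grp <- animals[animals$Taxon == taxon, , drop = FALSE]
  if (!is.null(sex)) grp <- grp[!is.na(grp$Sex) & grp$Sex == sex, ,
                                drop = FALSE]
  aad <- age_at_death_full(grp)
  dead <- !is.na(aad)
  keep <- !(dead & aad < INFANT_CUTOFF_Y)
  grp <- grp[keep, , drop = FALSE]
  aad <- aad[keep]
  dead <- dead[keep]
  time <- ifelse(dead, aad,
                 ifelse(!is.na(grp$AgeOfLiving_y), grp$AgeOfLiving_y,
                        grp$AgeLastVerified_y))
  ok <- !is.na(time)
  time <- time[ok]
  dead <- dead[ok]
  if (length(time) == 0) {
    stop("empty risk set for taxon ", taxon,
         if (!is.null(sex)) paste0(" sex ", sex))
  }
  product_limit(time, dead)
}

#' Product-limit estimator
#'
#' Plain Kaplan-Meier over (time, event) pairs: at each distinct death time
#' the survival probability is multiplied by `1 - d/n` where `d` is the
#' number of deaths and `n` the number still at risk (observations censored
#' exactly at a death time count as at risk there).
#'
#' @param time Nonnegative observation times.
#' @param event Logical; `TRUE` for a death, `FALSE` for censoring.
#' @return Object of class `survivorship_curve`.
#' @export
product_limit <- function(time, event) {
  stopifnot(length(time) == length(event), all(time >= 0))
  death_ages <- sort(unique(time[event]))
  surv <- numeric(length(death_ages))
  n_event <- integer(length(death_ages))
  n_risk <- integer(length(death_ages))
  s <- 1
  for (i in seq_along(death_ages)) {
    t <- death_ages[i]
    n <- sum(time >= t)
    d <- sum(event & time == t)
    s <- s * (1 - d / n)
    surv[i] <- s
    n_event[i] <- d
    n_risk[i] <- n
  }
  structure(
    list(event_ages_y = death_ages, survivorship = surv, n_event = n_event,
         n_risk = n_risk, censored_ages_y = sort(time[!event]),
         n = length(time)),
    class = "survivorship_curve"
  )
}

#' @export
print.survivorship_curve <- function(x, ...) {
  cat("survivorship curve: n =", x$n, "at risk,",
      length(x$event_ages_y), "distinct death ages,",
      length(x$censored_ages_y), "censored\n")
  if (length(x$event_ages_y) > 0) {
    cat("  final survivorship", round(min(x$survivorship), 4),
        "at", round(max(x$event_ages_y), 2), "y\n")
  }
  invisible(x)
}

#' Distance-weighted median longevity
#'
#' Interpolated median of a survivorship curve: the nearest uncensored ages
#' above (`U`, first death age with survivorship at or below 0.5) and below
#' (`L`, last death age with survivorship above 0.5) the 50% crossing are
#' each weighted by their survivorship distance from the 0.5 midpoint and
#' averaged: `((U - U*dU) + (L + L*dL)) / 2`. When the curve never reaches
#' 50% the median is undefined (`NA`); when the first death age already
#' drops survivorship to 0.5 or less, `L = U`.
#'
#' @param curve A `survivorship_curve`.
#' @return Median longevity in years, or `NA`.
#' @export
weighted_median_longevity <- function(curve) {
  s <- curve$survivorship
  a <- curve$event_ages_y
  below <- which(s <= 0.5)
  if (length(below) == 0) return(NA_real_)
  iu <- below[1]
  upper <- a[iu]
  if (iu == 1) {
    lower <- upper
    s_lower <- s[iu]
  } else {
    lower <- a[iu - 1]
    s_lower <- s[iu - 1]
  }
  d_upper <- abs(s[iu] - 0.5)
  d_lower <- abs(s_lower - 0.5)
  ((upper - upper * d_upper) + (lower + lower * d_lower)) / 2
}

#' Infant mortality proportion
#'
#' Proportion of DLC-born individuals (stillbirths included) that died before
#' 30 days of age.
#'
#' @inheritParams fit_survivorship
#' @return List: `pct` (proportion, 2 dp), `n_died`, `n_born`.
#' @export
infant_mortality <- function(animals, taxon, sex = NULL) {
  grp <- animals[animals$Taxon == taxon & is_dlc_born(animals), ,
                 drop = FALSE]
  if (!is.null(sex)) grp <- grp[!is.na(grp$Sex) & grp$Sex == sex, ,
                                drop = FALSE]
  n <- nrow(grp)
  if (n == 0) return(list(pct = NA_real_, n_died = NA_integer_,
                          n_born = 0L))
  aad <- age_at_death_full(grp)
  died <- sum(!is.na(aad) & aad < INFANT_CUTOFF_Y)
  list(pct = round(died / n, 2), n_died = as.integer(died),
       n_born = as.integer(n))
}

#' Maximum recorded age
#'
#' Age of the oldest individual recorded, living or dead; animals with
#' estimated dates of birth are included (an estimated age cannot be
#' artificially older than the true age).
#'
#' @inheritParams fit_survivorship
#' @return Maximum age in years (2 dp), or `NA` for an empty group.
#' @export
max_age <- function(animals, taxon, sex = NULL) {
  grp <- animals[animals$Taxon == taxon, , drop = FALSE]
  if (!is.null(sex)) grp <- grp[!is.na(grp$Sex) & grp$Sex == sex, ,
                                drop = FALSE]
  ages <- grp$AgeMax_LiveOrDead_y
  if (all(is.na(ages))) return(NA_real_)
  round(max(ages, na.rm = TRUE), 2)
}
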
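# Age classification, neonate summaries, the exclusion cascade, monthly
# averaging and the obesity screen.

test_that("age classes split at one and two times the minimum dam age", {
  expect_equal(classify_age(0.5, 0.80), "IJ")
  expect_equal(classify_age(0.80, 0.80), "young_adult")
  expect_equal(classify_age(1.59, 0.80), "young_adult")
  expect_equal(classify_age(1.60, 0.80), "adult")
  expect_error(classify_age(-0.1, 0.80), "negative")
})

test_that("neonate values average day 0 and day 1 and exclude stillbirths", {
  a_ok <- make_animals("1", dob = "2000-05-01")
  a_still <- make_animals("2", dob = "2000-05-01", dod = "2000-05-01")
  animals <- rbind(a_ok, a_still)
  w <- rbind(make_weights("1", dob = "2000-05-01", age_d = c(0, 1),
                          weight_g = c(10, 12)),
             make_weights("2", dob = "2000-05-01", age_d = 0,
                          weight_g = 9))
  s <- neonate_summary(w, animals, "CMED")
  expect_equal(s$n, 1)
  expect_equal(s$mean_g, 11)

  # duplicate weighings within a day are averaged before the day average
  w2 <- make_weights("1", dob = "2000-05-01", age_d = c(0, 0, 1),
                     weight_g = c(10, 14, 12))
  s2 <- neonate_summary(w2, a_ok, "CMED")
  expect_equal(s2$mean_g, 12)

  empty <- neonate_summary(w[0, ], animals, "CMED")
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean_g))
})

test_that("the exclusion cascade drops pre-death, pregnant and wild-caught juvenile weights", {
  base <- make_weights("1", dob = "2000-01-01",
                       age_d = c(1000, 1100, 1200, 1300),
                       weight_g = c(100, 101, 102, 103),
                       dod = as.Date("2000-01-01") + 1330)
  # days before death: 330, 230, 130, 30 -> only the last is dropped
  kept <- filter_weights(base)
  expect_equal(kept$AgeAtWt_d, c(1000, 1100, 1200))

  # exactly 60 days before death is retained (strict < 60)
  at60 <- make_weights("2", dob = "2000-01-01", age_d = 1000,
                       weight_g = 100, dod = as.Date("2000-01-01") + 1060)
  expect_equal(nrow(filter_weights(at60)), 1)

  preg <- make_weights("3", dob = "2000-01-01", age_d = 1000,
                       weight_g = 120, preg_status = "P")
  expect_equal(nrow(filter_weights(preg)), 0)

  wb_juv <- make_weights("4", dob = "2000-01-01", age_d = round(0.5 * 365),
                         weight_g = 60, birth_type = "WB",
                         birth_inst = "Madagascar", min_dam_aac = 0.8)
  expect_equal(nrow(filter_weights(wb_juv)), 0)
  cb_juv <- make_weights("5", dob = "2000-01-01", age_d = round(0.5 * 365),
                         weight_g = 60, min_dam_aac = 0.8)
  expect_equal(nrow(filter_weights(cb_juv)), 1)

  # month subsetting for seasonal analyses
  cfg <- mass_config(seasonal_month_subset = c(11, 12, 1))
  sub <- filter_weights(base, cfg = cfg)
  expect_true(all(sub$MonthOfWeight %in% c(11, 12, 1)))
})

test_that("individual means weight each calendar month equally", {
  w <- make_weights("1", dob = "2000-01-01",
                    age_d = c(520, 530, 560),  # June 2001 x2, July 2001
                    weight_g = c(100, 110, 130))
  w$Age_Category <- "adult"
  ind <- individual_mass_means(w, "adult")
  expect_equal(ind$mean_g, 117.5)

  single <- make_weights("2", dob = "2000-01-01", age_d = 600,
                         weight_g = 250)
  single$Age_Category <- "adult"
  expect_equal(individual_mass_means(single, "adult")$mean_g, 250)

  # ten weighings in one month count as much as one in another
  w3 <- make_weights("3", dob = "2000-01-01",
                     age_d = c(rep(500:509), 560),
                     weight_g = c(rep(100, 10), 130))
  w3$Age_Category <- "adult"
  expect_equal(individual_mass_means(w3, "adult")$mean_g, 115)
})

test_that("the obesity screen flags strictly beyond mean + 2 SD, single pass", {
  inds <- data.frame(DLC_ID = as.character(1:10),
                     Sex = "F", n_months = 1,
                     mean_g = c(rep(100, 9), 300),
                     stringsAsFactors = FALSE)
  res <- obesity_filter(inds)
  expect_equal(res$obese$DLC_ID, "10")
  expect_equal(species_mass_summary(res$kept)$mean_g, 100)

  flat <- inds
  flat$mean_g <- 100
  expect_equal(nrow(obesity_filter(flat)$obese), 0)

  one <- inds[1, ]
  expect_equal(nrow(obesity_filter(one)$kept), 1)
})

test_that("species summaries and filtered means are order-invariant and bounded", {
  sim <- shared_sim()
  wf <- filter_weights(sim$weights)
  inds <- individual_mass_means(wf, "adult")
  res <- obesity_filter(inds)
  filtered_mean <- species_mass_summary(res$kept)$mean_g
  unfiltered_mean <- species_mass_summary(inds)$mean_g
  expect_lte(filtered_mean, unfiltered_mean)

  # shuffling input record order leaves the summary unchanged
  set.seed(7)
  shuffled <- sim$weights[sample.int(nrow(sim$weights)), ]
  inds2 <- individual_mass_means(filter_weights(shuffled), "adult")
  res2 <- obesity_filter(inds2)
  expect_equal(species_mass_summary(res2$kept), species_mass_summary(res$kept))

  # sex partition counts never exceed the pooled count
  sm_all <- species_mass_summary(res$kept)
  sm_m <- species_mass_summary(res$kept, "M")
  sm_f <- species_mass_summary(res$kept, "F")
  expect_lte(sm_m$n + sm_f$n, sm_all$n)
})

test_that("pregnancy columns are filled from litter intervals, males stay NP", {
  dam <- make_animals("D1", sex = "F", dob = "1995-01-01")
  infant <- make_animals("I1", dob = "2000-05-01", dam_id = "D1",
                         gestation = 120)
  animals <- rbind(dam, infant)
  litters <- build_litters(animals, "CMED")
  # weight 60 days before the birth, mid-pregnancy
  w <- make_weights("D1", dob = "1995-01-01",
                    age_d = as.numeric(as.Date("2000-05-01") - 60 -
                                         as.Date("1995-01-01")),
                    weight_g = 150, gestation = 120)
  w <- rbind(w, make_weights("M1", dob = "1995-01-01", age_d = 2000,
                             weight_g = 140, sex = "M", gestation = 120))
  filled <- weight_derived_columns(w, rbind(animals,
                                            make_animals("M1", sex = "M",
                                                         dob = "1995-01-01")),
                                   litters, c(CMED = 0.8))
  preg_row <- filled[filled$DLC_ID == "D1", ]
  expect_equal(preg_row$Preg_Status, "P")
  expect_equal(preg_row$DaysBeforeInfBirth_IfPreg, 60)
  expect_equal(preg_row$Pct_PregRemain_IfPreg, 0.5)
  expect_equal(preg_row$InfantDOB_IfPreg, as.Date("2000-05-01"))
  male_row <- filled[filled$DLC_ID == "M1", ]
  expect_equal(male_row$Preg_Status, "NP")
  expect_true(is.na(male_row$Pct_PregRemain_IfPreg))
})
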
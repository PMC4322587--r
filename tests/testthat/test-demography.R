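# Conception estimation, estimated DOBs, parental ages, litters and
# offspring counts.

test_that("conception back-calculation is exact calendar arithmetic", {
  expect_equal(estimate_conception(as.Date("2000-05-01"), 60),
               as.Date("2000-03-02"))
  expect_equal(estimate_conception(as.Date("2000-01-15"), 0),
               as.Date("2000-01-15"))
  # across a year boundary (2000 is a leap year)
  expect_equal(estimate_conception(as.Date("2000-03-01"), 120),
               as.Date("1999-11-02"))
})

test_that("estimated DOB assignment follows the seasonal/non-seasonal/adult rules", {
  s <- assign_estimated_dob(as.Date("1991-04-10"), est_birth_year = 1990,
                            pattern = "S", origin_midmonth = 11)
  expect_equal(s$dob, as.Date("1990-11-01"))
  expect_equal(s$code, "Y")

  ns <- assign_estimated_dob(as.Date("1985-06-17"), est_birth_year = 1982,
                             pattern = "NS")
  expect_equal(ns$dob, as.Date("1982-06-17"))

  ad <- assign_estimated_dob(as.Date("1980-01-01"), adult_only = TRUE,
                             pattern = "NS", min_dam_aac_y = 2.0)
  expect_equal(ad$dob, as.Date("1980-01-01") - 730)
  expect_equal(ad$code, "U")

  expect_error(assign_estimated_dob(as.Date("1980-01-01"), pattern = "NS"),
               "adult_only")
})

test_that("parental age extremes honour exact-DOB and survival rules", {
  dam <- make_animals("D1", sex = "F", dob = "1998-01-01")
  # offspring conceived exactly 730 d after dam's birth
  concep <- as.Date("1998-01-01") + 730
  off <- make_animals("O1", dob = concep + 60, dam_id = "D1",
                      dam_dob = "1998-01-01", sire_id = "S1",
                      sire_dob = "1995-01-01")
  sire <- make_animals("S1", sex = "M", dob = "1995-01-01")
  ext <- parental_age_extremes(rbind(dam, sire, off), "CMED")
  expect_equal(ext$min_dam, 2.0)
  expect_equal(ext$max_dam, 2.0)
  expect_equal(ext$min_sire, as.numeric(concep - as.Date("1995-01-01")) / 365)

  # estimated-DOB dam contributes to max only
  dam_est <- make_animals("D2", sex = "F", dob = "1990-11-01",
                          estimated_dob = "Y", birth_type = "WB")
  off2 <- make_animals("O2", dob = "1999-06-01", dam_id = "D2",
                       dam_dob = "1990-11-01")
  ext2 <- parental_age_extremes(rbind(dam_est, off2), "CMED")
  expect_true(is.na(ext2$min_dam))
  expect_false(is.na(ext2$max_dam))

  # offspring that died on its day of birth is excluded entirely
  off3 <- make_animals("O3", dob = concep + 60, dod = concep + 60,
                       dam_id = "D1", dam_dob = "1998-01-01")
  ext3 <- parental_age_extremes(rbind(dam, off3), "CMED")
  expect_true(is.na(ext3$min_dam))

  # MULT/UNK sires never enter sire statistics
  off4 <- make_animals("O4", dob = concep + 60, dam_id = "D1",
                       dam_dob = "1998-01-01", sire_id = "MULT2",
                       sire_dob = "1995-01-01")
  ext4 <- parental_age_extremes(rbind(dam, off4), "CMED")
  expect_true(is.na(ext4$min_sire) && is.na(ext4$max_sire))
})

test_that("litter events group by dam and exact birth date", {
  twins <- make_animals(c("T1", "T2"), dob = "2000-05-01", dam_id = "D1",
                        litter_size = 2)
  apart <- make_animals("T3", dob = "2001-05-01", dam_id = "D1")
  orphan <- make_animals("T4", dob = "2000-05-01")  # no dam -> singleton
  lit <- build_litters(rbind(twins, apart, orphan), "CMED")
  expect_equal(nrow(lit), 3)
  expect_equal(sort(lit$size), c(1, 1, 2))
  expect_equal(lit$conception_date, lit$birth_date - 60)
  expect_false(any(lit$litter_size_mismatch))

  # member count wins over an inconsistent stored litter size
  twins_bad <- twins
  twins_bad$Litter_Size <- 3L
  lit2 <- build_litters(twins_bad, "CMED")
  expect_equal(lit2$size, 2)
  expect_true(lit2$litter_size_mismatch)

  # partition: every DLC-born individual is in exactly one litter
  sim <- shared_sim()
  sl <- build_litters(sim$animals, "CMED")
  dlc_born <- sim$animals$Birth_Institution == "Duke Prim"
  expect_equal(sum(sl$size), sum(dlc_born))
  members <- unlist(strsplit(sl$member_ids, ";"))
  expect_setequal(members, sim$animals$DLC_ID[dlc_born])
})

test_that("litter statistics report ties in the printed comma-joined form", {
  s <- litter_stats(c(2, 2, 1, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$most_common, "2")
  expect_equal(s$freq_most_common, 0.5)
  expect_equal(c(s$min, s$max), c(1, 3))

  tie <- litter_stats(c(1, 2))
  expect_equal(tie$most_common, "1,2")
  expect_equal(tie$freq_most_common, 0.5)

  expect_error(litter_stats(numeric(0)), "at least one litter")
})

test_that("birth sex ratio counts DLC births only and excludes ND", {
  m <- make_animals(paste0("M", 1:5), sex = "M", dob = "2000-05-01")
  f <- make_animals(paste0("F", 1:5), sex = "F", dob = "2000-05-02")
  nd <- make_animals("N1", sex = "ND", dob = "2000-05-03")
  outside <- make_animals("X1", sex = "M", dob = "2000-05-04",
                          birth_inst = "Other Inst")
  expect_equal(birth_sex_ratio(rbind(m, f, nd, outside), "CMED"), 1.0)

  few <- rbind(make_animals(paste0("M", 1:4), sex = "M", dob = "2000-05-01"),
               make_animals("F1", sex = "F", dob = "2000-05-02"))
  expect_equal(birth_sex_ratio(few, "CMED"), 4.0)
  expect_true(is.na(birth_sex_ratio(m, "CMED")))  # no females
})

test_that("offspring counts skip multi-candidate sires", {
  dam <- make_animals("D1", sex = "F", dob = "1998-01-01")
  sires <- make_animals(c("S1", "S2"), sex = "M", dob = "1995-01-01")
  brood <- make_animals(paste0("O", 1:3), dob = "2001-05-01", dam_id = "D1",
                        sire_id = "MULT2")
  counts <- count_offspring(rbind(dam, sires, brood))
  expect_equal(unname(counts["D1"]), 3L)
  expect_equal(unname(counts["S1"]), 0L)
  expect_equal(unname(counts["S2"]), 0L)
  expect_equal(unname(counts["O1"]), 0L)
})
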
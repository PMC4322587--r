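# Reading, writing and validating the two record schemas.

test_that("animal list read recomputes conception date and flags schema problems", {
  a <- make_animals("1001", dob = "2000-05-01", gestation = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_animal_list(a, path)
  back <- read_animal_list(path)
  expect_equal(back$Estimated_Concep, as.Date("2000-03-02"))
  expect_length(attr(back, "issues"), 0)

  # missing mandatory column -> schema error naming it
  raw <- read.csv(path, check.names = FALSE)
  raw$DLC_ID <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, path2, row.names = FALSE)
  expect_error(read_animal_list(path2), "DLC_ID")

  # duplicate ids and unknown taxa are reported, not fatal
  a2 <- rbind(a, a)
  a2$Taxon[2] <- "XXXX"
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_animal_list(a2, path3)
  issues <- attr(read_animal_list(path3), "issues")
  expect_true(any(grepl("duplicate DLC_ID", issues)))
  expect_true(any(grepl("unknown taxon", issues)))
})

test_that("dates are accepted in ISO and M/D/YYYY forms with '.' missing tokens", {
  a <- make_animals("1001", dob = "2000-05-01")
  path <- withr::local_tempfile(fileext = ".csv")
  write_animal_list(a, path)
  txt <- readLines(path)
  txt <- gsub("2000-05-01", "5/1/2000", txt, fixed = TRUE)
  txt <- gsub('""', '"."', txt, fixed = TRUE)
  writeLines(txt, path)
  back <- read_animal_list(path)
  expect_equal(back$DOB, as.Date("2000-05-01"))
  expect_true(is.na(back$StudBook))

  txt2 <- gsub("5/1/2000", "not-a-date", txt, fixed = TRUE)
  writeLines(txt2, path)
  expect_error(read_animal_list(path), "unparseable date")
})

test_that("weight file derived columns follow the published definitions", {
  w <- make_weights("1001", dob = "2000-05-01", age_d = c(10, 15),
                    weight_g = c(100, 110))
  path <- withr::local_tempfile(fileext = ".csv")
  write_weight_file(w, path)
  back <- read_weight_file(path)
  expect_equal(back$AgeAtWt_d, c(10, 15))
  expect_equal(back$AgeAtWt_wk[1], round(10 / 7, 6))
  expect_length(attr(back, "issues"), 0)

  # deltas between consecutive weighings, via the derivation op
  filled <- weight_derived_columns(w, make_animals("1001", dob = "2000-05-01"),
                                   build_litters(make_animals("1001",
                                                              dob = "2000-05-01"),
                                                 "CMED"),
                                   c(CMED = 0.8))
  expect_equal(filled$Days_Since_PrevWt, c(NA, 5))
  expect_equal(filled$Change_Since_PrevWt_g, c(NA, 10))
  expect_equal(filled$Avg_Daily_WtChange_g, c(NA, 2))

  # negative age and non-positive weight are row-level errors
  w_bad <- w
  w_bad$Weight_Date[1] <- as.Date("1999-01-01")
  path_bad <- withr::local_tempfile(fileext = ".csv")
  write_weight_file(w_bad, path_bad)
  expect_error(read_weight_file(path_bad), "negative age")
  w_bad2 <- w
  w_bad2$Weight_g[2] <- 0
  write_weight_file(w_bad2, path_bad)
  expect_error(read_weight_file(path_bad), "non-positive weight")
})

test_that("write-then-read round-trips a simulated colony exactly", {
  sim <- shared_sim()
  ap <- withr::local_tempfile(fileext = ".csv")
  wp <- withr::local_tempfile(fileext = ".csv")
  write_animal_list(sim$animals, ap)
  write_weight_file(sim$weights, wp)
  a_back <- read_animal_list(ap)
  w_back <- read_weight_file(wp)
  attr(a_back, "issues") <- NULL
  attr(w_back, "issues") <- NULL
  expect_equal(a_back, sim$animals, ignore_attr = TRUE)
  w_sorted <- sim$weights[order(sim$weights$DLC_ID, sim$weights$Weight_Date), ]
  rownames(w_sorted) <- NULL
  expect_equal(w_back, w_sorted, ignore_attr = TRUE)
})

test_that("cross-file validation flags impossible outliers and is clean on clean data", {
  animals <- make_animals(c("1", "2"), dob = c("2000-05-01", "2001-05-01"),
                          dod = c("1999-01-01", NA))
  weights <- make_weights("3", dob = "2000-01-01", age_d = 3000,
                          weight_g = 8000)
  small <- make_weights("2", dob = "2001-05-01", age_d = c(400, 500, 600),
                        weight_g = c(80, 85, 82), taxon = "MMUR")
  rep <- validate_colony(animals, rbind(weights, small))
  expect_true("negative_age" %in% rep$check)
  expect_true(any(rep$check == "unknown_individual" & rep$dlc_id == "3"))

  mm <- make_weights("2", dob = "2001-05-01",
                     age_d = c(400, 500, 600, 700),
                     weight_g = c(80, 85, 82, 8000), taxon = "MMUR")
  rep2 <- validate_colony(animals, mm)
  expect_true(any(rep2$check == "weight_out_of_range" &
                    grepl("8000", rep2$detail)))

  sim <- shared_sim()
  expect_identical(nrow(validate_colony(sim$animals, sim$weights)), 0L)
})
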
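# Product-limit survivorship, the weighted median, infant mortality and
# maximum age.

test_that("product-limit steps match hand-computed survival", {
  c1 <- product_limit(c(2, 4, 6, 8), rep(TRUE, 4))
  expect_equal(c1$survivorship, c(0.75, 0.5, 0.25, 0))

  c2 <- product_limit(c(5, 10), c(TRUE, FALSE))
  expect_equal(c2$survivorship, 0.5)

  # deaths {2, 8} with a censoring at 4: S(2) = 2/3, S(8) = 0
  c3 <- product_limit(c(2, 4, 8), c(TRUE, FALSE, TRUE))
  expect_equal(c3$survivorship, c(2 / 3, 0))

  # censoring tied with a death stays at risk for that death
  c4 <- product_limit(c(3, 3), c(TRUE, FALSE))
  expect_equal(c4$survivorship, 0.5)
})

test_that("product-limit matches the survival package on random cohorts", {
  skip_if_not_installed("survival")
  set.seed(2077)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    time <- round(rexp(n, 0.1), 3) + 0.01
    event <- runif(n) < 0.7
    if (!any(event)) event[1] <- TRUE
    mine <- product_limit(time, event)
    km <- survival::survfit(survival::Surv(time, event) ~ 1)
    ref_s <- summary(km, times = mine$event_ages_y)$surv
    expect_equal(mine$survivorship, ref_s, tolerance = 1e-9)
  }
})

test_that("the weighted median evaluates the bracket formula", {
  curve <- structure(list(event_ages_y = c(12, 20),
                          survivorship = c(0.55, 0.45),
                          n_event = c(1L, 1L), n_risk = c(20L, 10L),
                          censored_ages_y = numeric(0), n = 20L),
                     class = "survivorship_curve")
  expect_equal(weighted_median_longevity(curve), 15.8)

  # degenerate bracket: the first death age already reaches exactly 0.5
  half <- product_limit(c(4, 8), c(TRUE, FALSE))
  expect_equal(weighted_median_longevity(half), 4)

  # curve that never reaches 50% survivorship has no median
  shallow <- structure(list(event_ages_y = c(3, 9),
                            survivorship = c(0.8, 0.6),
                            n_event = c(1L, 1L), n_risk = c(5L, 4L),
                            censored_ages_y = c(10, 11, 12), n = 5L),
                       class = "survivorship_curve")
  expect_true(is.na(weighted_median_longevity(shallow)))
})

test_that("weighted median recovers the exponential closed form over repeated seeds", {
  lambda <- log(2) / 10  # true median 10 y
  set.seed(515)
  est <- vapply(1:20, function(s) {
    t <- rexp(300, lambda)
    t <- t[t >= 30 / 365]
    weighted_median_longevity(product_limit(t, rep(TRUE, length(t))))
  }, numeric(1))
  # unbiased across seeds; per-seed spread is the sample-median SE (~0.8 y)
  expect_lt(abs(mean(est) - 10), 0.5)
  expect_true(all(abs(est - 10) < 3))
})

test_that("survivorship fitting excludes young infant deaths and applies censoring", {
  dead <- make_animals(c("1", "2"), dob = "1990-01-01",
                       dod = c("1995-01-01", "2000-01-01"))
  infant <- make_animals("3", dob = "1990-01-01", dod = "1990-01-10")
  living <- make_animals("4", dob = "1990-01-01")  # alive at file date
  curve <- fit_survivorship(rbind(dead, infant, living), "CMED")
  expect_equal(curve$n, 3)  # infant death excluded entirely
  expect_equal(length(curve$event_ages_y), 2)
  # exactly 30 days is retained, strictly less is excluded
  at30 <- make_animals("5", dob = "1990-01-01", dod = "1990-01-31")
  curve2 <- fit_survivorship(rbind(dead, at30), "CMED")
  expect_equal(curve2$n, 3)
  at29 <- make_animals("6", dob = "1990-01-01", dod = "1990-01-30")
  curve3 <- fit_survivorship(rbind(dead, at29), "CMED")
  expect_equal(curve3$n, 2)
})

test_that("infant mortality is the proportion of DLC births dying before 30 days", {
  set.seed(1)
  n_died <- 67
  n_tot <- 226
  dods <- c(rep("2000-05-10", n_died), rep(NA, n_tot - n_died))
  a <- make_animals(as.character(seq_len(n_tot)), dob = "2000-05-01",
                    dod = dods)
  im <- infant_mortality(a, "CMED")
  expect_equal(im$pct, 0.30)
  expect_equal(im$n_died, 67L)
  expect_equal(im$n_born, 226L)

  none <- make_animals(as.character(1:10), dob = "2000-05-01")
  expect_equal(infant_mortality(none, "CMED")$pct, 0)

  # an ND-sex group in which every member died as an infant
  nd <- make_animals(c("a", "b"), sex = "ND", dob = "2000-05-01",
                     dod = "2000-05-01")
  expect_equal(infant_mortality(rbind(a, nd), "CMED", sex = "ND")$pct, 1.00)
})

test_that("maximum age spans living and dead animals", {
  a <- rbind(make_animals("1", dob = "2005-01-01", dod = "2008-01-01"),
             make_animals("2", dob = "2006-12-01"),
             make_animals("3", dob = "2004-01-01", dod = "2009-01-01"))
  expect_equal(max_age(a, "CMED"), round(as.numeric(FILE_DATE -
                                                      as.Date("2006-12-01")) / 365, 2))
  single <- make_animals("9", dob = "2000-01-01", dod = "2003-01-01")
  expect_equal(max_age(single, "CMED"), round(3 * 365.25 / 365, 2),
               tolerance = 0.01)
})
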
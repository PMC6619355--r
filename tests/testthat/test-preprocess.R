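test_that("adjusted skewness matches hand-computed and theoretical values", {
  expect_equal(skewness(c(1, 2, 3, 4, 5)), 0)
  # n/((n-1)(n-2)) * sum(z^3) = 4/6 * 3 = 2 for (1,1,1,10)
  expect_equal(skewness(c(1, 1, 1, 10)), 2, tolerance = 1e-12)
  x <- with_seed(31, rexp(10000))
  expect_equal(skewness(x), 2, tolerance = 0.15)
  expect_error(skewness(c(1, 1, 1, 1)), "constant")
  expect_error(skewness(c(1, 2)), "at least 3")
})

test_that("log transform triggers only above the skewness bound", {
  xn <- with_seed(32, abs(rnorm(500, 10, 2)))
  out <- conditional_log_transform(xn)
  expect_false(out$applied)
  expect_identical(out$values, xn)
  xs <- c(rep(0, 400), with_seed(33, rexp(100, 1 / 20)))
  expect_gt(skewness(xs), 1)
  out2 <- conditional_log_transform(xs)
  expect_true(out2$applied)
  expect_equal(out2$values, log10(xs + 1))
  expect_lt(abs(skewness(out2$values)), abs(skewness(xs)))
  expect_equal(conditional_log_transform(c(0, 0, 5, 9))$values[1], 0)
  expect_error(conditional_log_transform(c(-1, 2, 3)), "non-negative")
})

test_that("residualization recovers covariate effects and standardizes", {
  n <- 2000
  dat <- with_seed(34, {
    age <- rnorm(n, 16, 0.7)
    sex <- sample(c("M", "F"), n, replace = TRUE)
    y <- 0.5 * age + 0.3 * (sex == "M") + rnorm(n)
    list(age = age, sex = sex, y = y)
  })
  rs <- residualize_standardize(dat$y, dat$age, dat$sex)
  se_age <- 1 / (sd(dat$age) * sqrt(n))
  expect_equal(unname(rs$coefficients["age"]), 0.5,
               tolerance = 3 * se_age / 0.5)
  expect_equal(mean(rs$residuals), 0, tolerance = 1e-8)
  expect_equal(sd(rs$residuals), 1, tolerance = 1e-8)
  # independent of covariates -> output is just the z-scored input
  y2 <- with_seed(35, rnorm(500))
  rs2 <- residualize_standardize(y2, rep(16, 250 * 2) + rnorm(500, 0, 0.5),
                                 rep(c("M", "F"), 250))
  expect_gt(cor(rs2$residuals, (y2 - mean(y2)) / sd(y2)), 0.99)
  # exact linear dependence -> zero residual variance
  age <- with_seed(36, rnorm(100, 16))
  expect_error(residualize_standardize(2 * age, age,
                                       rep(c("M", "F"), 50)),
               "zero variance")
  # missing values propagate
  y3 <- y2; y3[c(3, 7)] <- NA
  rs3 <- residualize_standardize(y3, seq(0, 1, length.out = 500),
                                 rep(c("M", "F"), 250))
  expect_true(all(is.na(rs3$residuals[c(3, 7)])))
})

test_that("preprocessing yields bounded skew and unit-variance residuals", {
  cfg <- simulation_config(
    n_pairs = c(MZM = 150, MZF = 150, DZM = 150, DZF = 150, DZOS = 150),
    subscales = default_subscale_truths()[c("paranoia", "cogdis")],
    wave2_retention = 0.5, seed = 41)
  ch <- generate_cohort(cfg)
  pp <- preprocess_cohort(ch)
  expect_true(all(abs(pp$report$skew_after) <= 1))
  # the skewed subscale needed the transform at both waves, the linear one
  # did not
  expect_true(all(pp$report$transform_applied[pp$report$subscale ==
                                                "paranoia"]))
  expect_false(any(pp$report$transform_applied[pp$report$subscale ==
                                                 "cogdis"]))
  for (s in c("paranoia", "cogdis")) {
    for (w in 1:2) {
      z <- c(pp$cohort[[paste0(s, "_z_t", w, "_1")]],
             pp$cohort[[paste0(s, "_z_t", w, "_2")]])
      expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-8)
      expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-8)
    }
  }
  # wave-2 missingness preserved
  expect_identical(is.na(pp$cohort$paranoia_z_t2_1),
                   is.na(ch$paranoia_t2_1))
})

test_that("preprocessing already-standardized residuals is idempotent", {
  ch <- quick_cohort(300, retention = 0.6, seed = 42, skewed = TRUE)
  pp1 <- preprocess_cohort(ch, "ph")
  ch2 <- ch
  for (col in c("_t1_1", "_t1_2", "_t2_1", "_t2_2")) {
    ch2[[paste0("ph", col)]] <- pp1$cohort[[paste0("ph_z", col)]]
  }
  # shift to a non-negative scale (a monotone affine map) so the
  # non-negativity contract holds; affine maps do not change skewness or
  # standardized residuals
  shift <- min(unlist(ch2[paste0("ph", c("_t1_1", "_t1_2", "_t2_1",
                                         "_t2_2"))]), na.rm = TRUE)
  for (col in c("_t1_1", "_t1_2", "_t2_1", "_t2_2")) {
    ch2[[paste0("ph", col)]] <- ch2[[paste0("ph", col)]] - shift
  }
  pp2 <- preprocess_cohort(ch2, "ph")
  expect_false(any(pp2$report$transform_applied))
  expect_equal(pp2$cohort$ph_z_t1_1, pp1$cohort$ph_z_t1_1,
               tolerance = 1e-8)
  expect_equal(pp2$cohort$ph_z_t2_2, pp1$cohort$ph_z_t2_2,
               tolerance = 1e-8)
})

test_that("one twin per pair is selected deterministically from complete pairs", {
  ch <- quick_cohort(120, retention = 0.5, seed = 43, distress = TRUE)
  ind <- select_one_twin_per_pair(ch, seed = 99)
  expect_equal(nrow(ind), sum(!is.na(ch$ph_t2_1)))
  expect_false(anyNA(ind$ph_t2))
  expect_identical(ind, select_one_twin_per_pair(ch, seed = 99))
  ind2 <- select_one_twin_per_pair(ch, seed = 100)
  expect_false(identical(ind$twin, ind2$twin))
  # selected values really come from the selected twin
  i <- which(ind$twin == 2)[1]
  row <- ch[ch$family_id == ind$family_id[i], ]
  expect_equal(ind$ph_t1[i], row$ph_t1_2)
  expect_equal(ind$ph_distress[i], row$ph_distress_2)
})
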
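test_that("pure-E truth yields uncorrelated twins at both waves", {
  truth <- cholesky_params(X = matrix(0, 2, 2), Y = matrix(0, 2, 2),
                           Z = diag(2))
  ch <- quick_cohort(2000, truth, groups = c(MZM = 1, MZF = 0, DZM = 0,
                                             DZF = 0, DZOS = 0), seed = 5)
  r1 <- cor(ch$ph_t1_1, ch$ph_t1_2)
  r2 <- cor(ch$ph_t2_1, ch$ph_t2_2)
  expect_lt(abs(r1), 3 / sqrt(2000))
  expect_lt(abs(r2), 3 / sqrt(2000))
})

test_that("pure-A truth makes MZ twins identical and DZ correlate ~0.5", {
  truth <- cholesky_params(X = diag(2), Y = matrix(0, 2, 2),
                           Z = matrix(0, 2, 2) + diag(c(1e-6, 1e-6)))
  ch <- quick_cohort(1500, truth, seed = 6)
  mz <- ch[ch$zygosity %in% c("MZM", "MZF"), ]
  dz <- ch[ch$zygosity %in% c("DZM", "DZF"), ]
  expect_equal(mz$ph_t1_1, mz$ph_t1_2, tolerance = 1e-3)
  expect_equal(mz$ph_t2_1, mz$ph_t2_2, tolerance = 1e-3)
  expect_equal(cor(dz$ph_t1_1, dz$ph_t1_2), 0.5, tolerance = 0.06)
})

test_that("standardized ACE truth reproduces the implied twin correlations", {
  # rMZ = a2 + c2 = 0.47, rDZ = a2/2 + c2 = 0.33 at wave 1
  ch <- quick_cohort(2500, seed = 11)
  mz <- ch[ch$zygosity %in% c("MZM", "MZF"), ]
  dz <- ch[ch$zygosity %in% c("DZM", "DZF", "DZOS"), ]
  expect_equal(cor(mz$ph_t1_1, mz$ph_t1_2), 0.47, tolerance = 0.04)
  expect_equal(cor(dz$ph_t1_1, dz$ph_t1_2), 0.33, tolerance = 0.04)
})

test_that("generation is deterministic given config and seed", {
  a <- quick_cohort(100, retention = 0.5, seed = 9)
  b <- quick_cohort(100, retention = 0.5, seed = 9)
  d <- quick_cohort(100, retention = 0.5, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$ph_t1_1, d$ph_t1_1))
})

test_that("DZOS pairs with rg = 1 match same-sex DZ covariance", {
  cfg <- simulation_config(
    n_pairs = c(MZM = 0, MZF = 0, DZM = 5000, DZF = 5000, DZOS = 10000),
    subscales = list(ph = list(params = paranoia_truth(), skewed = FALSE,
                               distress = FALSE)),
    rg_opposite_sex = 1, skew_transform = "none", wave2_retention = 1,
    seed = 21)
  ch <- generate_cohort(cfg)
  cols <- paste0("ph_", c("t1_1", "t2_1", "t1_2", "t2_2"))
  cov_ss <- cov(as.matrix(ch[ch$zygosity %in% c("DZM", "DZF"), cols]))
  cov_os <- cov(as.matrix(ch[ch$zygosity == "DZOS", cols]))
  expect_lt(max(abs(cov_ss - cov_os)), 0.05)
})

test_that("reduced rg weakens the DZOS genetic sharing", {
  cfg <- function(rg) simulation_config(
    n_pairs = c(MZM = 0, MZF = 0, DZM = 0, DZF = 0, DZOS = 8000),
    subscales = list(ph = list(params = paranoia_truth(), skewed = FALSE,
                               distress = FALSE)),
    rg_opposite_sex = rg, skew_transform = "none", wave2_retention = 1,
    seed = 22)
  ch0 <- generate_cohort(cfg(0))
  r0 <- cor(ch0$ph_t1_1, ch0$ph_t1_2)
  # with rg = 0 only C is shared: expected r = c2 = 0.19
  expect_lt(abs(r0 - 0.19), 0.035)
})

test_that("pair-level wave-2 retention matches the configured rate", {
  ch <- quick_cohort(1000, retention = 0.3, seed = 4)
  miss1 <- is.na(ch$ph_t2_1)
  miss2 <- is.na(ch$ph_t2_2)
  expect_identical(miss1, miss2) # pair-level missingness
  expect_identical(miss1, is.na(ch$age_t2))
  expect_equal(mean(!miss1), 0.30, tolerance = 0.02)
  full <- quick_cohort(200, retention = 1, seed = 4)
  expect_false(anyNA(full$ph_t2_1))
})

test_that("exponential warp produces skewness above 1, linear does not", {
  ch <- quick_cohort(1500, skewed = TRUE, seed = 12)
  expect_gt(skewness(ch$ph_t1_1), 1)
  expect_true(all(ch$ph_t1_1 >= 0))
  lin <- quick_cohort(1500, skewed = FALSE, skew_transform = "exponential",
                      seed = 12)
  expect_lt(abs(skewness(lin$ph_t1_1)), 1)
  latent <- quick_cohort(1500, skew_transform = "none", seed = 12)
  expect_lt(min(latent$ph_t1_1), 0) # untouched latent scale
})

test_that("zygosity groups carry consistent sexes and invalid configs fail", {
  ch <- quick_cohort(50, seed = 2)
  expect_true(all(ch$sex_1[ch$zygosity == "MZF"] == "F"))
  expect_true(all(ch$sex_2[ch$zygosity == "MZF"] == "F"))
  expect_true(all(ch$sex_1[ch$zygosity == "DZOS"] == "M" &
                    ch$sex_2[ch$zygosity == "DZOS"] == "F"))
  expect_error(simulation_config(n_pairs = c(MZM = -1, MZF = 1, DZM = 1,
                                             DZF = 1, DZOS = 1)),
               "non-negative")
  expect_error(simulation_config(wave2_retention = 0), "retention")
  expect_error(simulation_config(distress_thresholds = c(2, 1)),
               "increasing")
})

test_that("cohort CSV round-trips with a ground-truth sidecar", {
  cfg <- simulation_config(
    n_pairs = c(MZM = 30, MZF = 30, DZM = 30, DZF = 30, DZOS = 30),
    subscales = default_subscale_truths()[c("paranoia", "anhedonia")],
    wave2_retention = 0.5, seed = 8)
  ch <- generate_cohort(cfg)
  path <- file.path(tempdir(), "cohort_test.csv")
  write_cohort(ch, path, cfg)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 8)
  expect_equal(side$subscales$paranoia$truth$X[[1]][[1]], sqrt(0.28),
               tolerance = 1e-9)
  back <- read_cohort(path)
  expect_setequal(attr(back, "subscales"), c("paranoia", "anhedonia"))
  expect_equal(back$paranoia_t1_1, ch$paranoia_t1_1, tolerance = 1e-12)
})
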
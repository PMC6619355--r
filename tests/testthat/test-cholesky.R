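test_that("expected pair covariance encodes the twin sharing structure", {
  Z <- diag(2)
  pure_e <- cholesky_params(X = matrix(0, 2, 2), Y = matrix(0, 2, 2), Z = Z)
  S <- expected_pair_covariance(pure_e, "MZF")
  expect_equal(unname(S), diag(4))
  tru <- paranoia_truth()
  S_mz <- expected_pair_covariance(tru, "MZF")
  S_dz <- expected_pair_covariance(tru, "DZF")
  XXt <- tru$X %*% t(tru$X)
  expect_equal(S_mz[1:2, 3:4] - S_dz[1:2, 3:4], 0.5 * XXt,
               ignore_attr = TRUE)
  # within-person blocks identical across zygosity
  expect_equal(S_mz[1:2, 1:2], S_dz[1:2, 1:2])
  # ADE: MZ shares Y fully, DZ shares it at a quarter
  ade <- cholesky_params(X = tru$X, Y = tru$Y, Z = tru$Z,
                         components = "ADE")
  S_dz_ade <- expected_pair_covariance(ade, "DZF")
  YYt <- tru$Y %*% t(tru$Y)
  expect_equal(S_dz_ade[1:2, 3:4], 0.5 * XXt + 0.25 * YYt,
               ignore_attr = TRUE)
  # ADE and ACE coincide when the Y block is zero
  ae1 <- cholesky_params(X = tru$X, Z = tru$Z, components = "ACE")
  ae2 <- cholesky_params(X = tru$X, Z = tru$Z, components = "ADE")
  for (g in c("MZM", "DZF", "DZOS")) {
    expect_equal(expected_pair_covariance(ae1, g),
                 expected_pair_covariance(ae2, g))
  }
})

test_that("opposite-sex pairs use sex-specific paths and rg", {
  male <- paranoia_truth()
  female <- cholesky_params(X = 0.8 * male$X, Y = male$Y, Z = male$Z)
  sl <- sexlim_params(male, female, rg = 0.6)
  S <- expected_pair_covariance(sl, "DZOS")
  B_expected <- 0.5 * 0.6 * male$X %*% t(female$X) +
    male$Y %*% t(female$Y)
  expect_equal(S[1:2, 3:4], B_expected, ignore_attr = TRUE)
  W_m <- male$X %*% t(male$X) + male$Y %*% t(male$Y) +
    male$Z %*% t(male$Z)
  expect_equal(S[1:2, 1:2], W_m, ignore_attr = TRUE)
})

test_that("simulated group covariances match the closed form", {
  ch <- quick_cohort(4000, seed = 61, retention = 1)
  cols <- paste0("ph_", c("t1_1", "t2_1", "t1_2", "t2_2"))
  for (g in c("MZF", "DZM", "DZOS")) {
    emp <- cov(as.matrix(ch[ch$zygosity == g, cols]))
    expect_lt(max(abs(emp - expected_pair_covariance(paranoia_truth(), g))),
              0.07)
  }
})

test_that("FIML deviance matches closed forms and the density oracle", {
  tru <- paranoia_truth()
  # a single fully observed pair at the mean under an identity covariance
  Y1 <- matrix(0, 1, 4, dimnames = list(NULL, c("t1_1", "t2_1", "t1_2",
                                                "t2_2")))
  md1 <- twin_data_from_matrices(list(MZM = Y1))
  iso <- cholesky_params(X = matrix(0, 2, 2), Y = matrix(0, 2, 2),
                         Z = diag(2))
  expect_equal(fiml_minus2ll(iso, md1), 4 * log(2 * pi), tolerance = 1e-10)
  # complete data: equality with the direct density-summation oracle
  ch <- quick_cohort(200, retention = 1, seed = 62)
  md <- twin_model_data(ch, "ph", standardized = FALSE)
  orc <- oracle_m2ll(md$groups, function(g) expected_pair_means(tru, g),
                     function(g) expected_pair_covariance(tru, g))
  expect_equal(fiml_minus2ll(tru, md), orc, tolerance = 1e-6)
  # missing data: equality with the oracle marginalized per pattern
  ch2 <- quick_cohort(200, retention = 0.4, seed = 63)
  md2 <- twin_model_data(ch2, "ph", standardized = FALSE)
  orc2 <- oracle_m2ll(md2$groups, function(g) expected_pair_means(tru, g),
                      function(g) expected_pair_covariance(tru, g))
  expect_equal(fiml_minus2ll(tru, md2), orc2, tolerance = 1e-6)
  # deleting a pair's wave-2 entries equals the marginal 2x2 density
  Ym <- matrix(c(0.3, NA, -0.2, NA), 1, 4,
               dimnames = list(NULL, c("t1_1", "t2_1", "t1_2", "t2_2")))
  mdm <- twin_data_from_matrices(list(MZF = Ym))
  S <- expected_pair_covariance(tru, "MZF")[c(1, 3), c(1, 3)]
  x <- c(0.3, -0.2)
  manual <- 2 * log(2 * pi) + log(det(S)) + drop(t(x) %*% solve(S, x))
  expect_equal(fiml_minus2ll(tru, mdm), manual, tolerance = 1e-10)
})

test_that("the deviance is invariant to swapping twin order within pairs", {
  tru <- paranoia_truth()
  ch <- quick_cohort(150, retention = 0.5, seed = 64)
  md <- twin_model_data(ch, "ph", standardized = FALSE)
  swapped <- lapply(md$groups, function(Y) {
    Z <- Y[, c(3, 4, 1, 2)]
    colnames(Z) <- colnames(Y)
    Z
  })
  md_sw <- twin_data_from_matrices(swapped)
  expect_equal(fiml_minus2ll(tru, md), fiml_minus2ll(tru, md_sw),
               tolerance = 1e-8)
})

test_that("a pure-E truth is recovered as negligible A and C", {
  truth <- cholesky_params(X = matrix(0, 2, 2), Y = matrix(0, 2, 2),
                           Z = chol2x2(1, 0.3, 1))
  ch <- quick_cohort(2000, truth, retention = 1, seed = 65)
  md <- twin_model_data(ch, "ph", standardized = FALSE)
  fit <- fit_model(md, model_spec("ACE", "none"), n_starts = 4)
  est <- standardize(fit$params)
  expect_lte(est$a2_t1, 0.05)
  expect_lte(est$c2_t1, 0.05)
  expect_lte(est$a2_t2, 0.05)
  expect_lte(est$c2_t2, 0.05)
})

test_that("standardize reproduces published proportions and handles edges", {
  # bivariate components (0.25, 0.12, 0.23) -> proportions (0.42, 0.20,
  # 0.38) of the phenotypic correlation
  est <- standardize(paranoia_truth())
  expect_equal(round(est$prop_a, 2), 0.42)
  expect_equal(round(est$prop_c, 2), 0.20)
  expect_equal(round(est$prop_e, 2), 0.38)
  expect_equal(est$a2_t1, 0.28, tolerance = 1e-12)
  expect_equal(est$biv_a, 0.25 / sqrt(1 * 0.99), tolerance = 1e-12)
  # invariants
  expect_equal(est$a2_t1 + est$c2_t1 + est$e2_t1, 1, tolerance = 1e-6)
  expect_equal(est$prop_a + est$prop_c + est$prop_e, 1, tolerance = 1e-6)
  # no C: rC undefined, C proportion zero
  ae <- anhedonia_truth()
  est_ae <- standardize(ae)
  expect_true(is.na(est_ae$rC))
  expect_equal(est_ae$prop_c, 0)
  # no stability paths: all cross-wave components zero
  flat <- cholesky_params(X = chol2x2(0.3, 0, 0.3),
                          Y = chol2x2(0.2, 0, 0.2),
                          Z = chol2x2(0.5, 0, 0.5))
  est_f <- standardize(flat)
  expect_equal(est_f$r_phenotypic, 0)
  expect_equal(abs(est_f$biv_a) + abs(est_f$biv_c) + abs(est_f$biv_e), 0)
})

test_that("aetiological correlations satisfy the correlated-factors identity", {
  single <- cholesky_params(X = matrix(c(0.5, 0.5, 0, 0), 2, 2),
                            Y = chol2x2(0.2, 0.05, 0.2),
                            Z = chol2x2(0.5, 0.1, 0.5))
  expect_equal(unname(aetiological_correlations(single)["rA"]), 1)
  ortho <- cholesky_params(X = matrix(c(0.5, 0, 0, 0.5), 2, 2),
                           Y = chol2x2(0.2, 0.05, 0.2),
                           Z = chol2x2(0.5, 0.1, 0.5))
  expect_equal(unname(aetiological_correlations(ortho)["rA"]), 0)
  # rA * sqrt(a2_1 * a2_2) equals the standardized A cross-wave component
  draws <- with_seed(66, replicate(20, {
    L <- function() {
      m <- matrix(c(runif(1, 0.2, 0.8), runif(1, -0.4, 0.4), 0,
                    runif(1, 0.2, 0.8)), 2, 2)
      m
    }
    p <- cholesky_params(X = L(), Y = L(), Z = L())
    est <- standardize(p)
    r <- aetiological_correlations(p)
    c(est$biv_a - r[["rA"]] * sqrt(est$a2_t1 * est$a2_t2),
      est$biv_c - r[["rC"]] * sqrt(est$c2_t1 * est$c2_t2),
      est$biv_e - r[["rE"]] * sqrt(est$e2_t1 * est$e2_t2))
  }))
  expect_lt(max(abs(draws)), 1e-10)
})

test_that("model comparison applies the BIC-10 rule and guards nesting", {
  mk <- function(m2ll, k, label) {
    n <- 1000
    structure(list(minus2LL = m2ll, n_parameters = k,
                   AIC = m2ll + 2 * k, BIC = m2ll + k * log(n),
                   label = label, digest = "d", convergence = TRUE),
              class = "twin_fit")
  }
  same <- compare_models(list(mk(5000, 11, "a"), mk(5000, 11, "b")))
  expect_equal(same$delta_BIC, c(0, 0))
  expect_false(any(same$decisive))
  lad <- compare_models(list(mk(5000, 11, "full"), mk(5002, 8, "reduced")))
  expect_true(lad$best[2])
  expect_true(lad$decisive[2])
  expect_false(any(lad$nesting_violation))
  bad <- compare_models(list(mk(5000, 11, "full"),
                             mk(4995, 8, "impossible")))
  expect_true(bad$nesting_violation[2])
  other <- mk(7000, 11, "x"); other$digest <- "other"
  expect_error(compare_models(list(mk(5000, 11, "a"), other)),
               "different data")
})

test_that("fitting refuses unidentified or underpowered inputs", {
  ch <- quick_cohort(30, retention = 1, seed = 67)
  md <- twin_model_data(ch, "ph", standardized = FALSE)
  expect_error(fit_model(md, model_spec("ACE", "none", min_pairs = 50)),
               "minimum pair count")
  Y <- md$groups$MZM
  Y[, c(2, 4)] <- NA
  md_w1 <- twin_data_from_matrices(list(MZM = Y))
  expect_error(fit_model(md_w1, model_spec("ACE", "none", min_pairs = 0)),
               "wave-2")
})

test_that("sex-limitation fits recover a sexless truth without distortion", {
  ch <- quick_cohort(600, retention = 1, seed = 68)
  md <- twin_model_data(ch, "ph", standardized = FALSE)
  fit_q <- fit_model(md, model_spec("ACE", "quantitative"), n_starts = 2)
  est <- standardize(fit_q$params)
  expect_equal(est$male$a2_t1, est$female$a2_t1, tolerance = 0.15)
  fit_n <- fit_model(md, model_spec("ACE", "none"), n_starts = 2)
  # the nested no-sex-difference model cannot beat its parent on -2LL
  expect_gte(fit_n$minus2LL + 1e-4, fit_q$minus2LL)
  cmp <- compare_models(list(fit_q, fit_n))
  expect_false(any(cmp$nesting_violation))
  expect_true(cmp$best[2]) # BIC prefers the parsimonious truth
})
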
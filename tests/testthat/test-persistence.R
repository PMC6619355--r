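test_that("group assignment follows the top-decile rules", {
  s <- 1:100
  ga <- assign_groups(s, s)
  expect_equal(sum(ga$group %in% c("persistent", "decreasing")), 10)
  expect_equal(attr(ga, "cutoffs")[["t1"]], 91)
  expect_equal(as.integer(table(ga$group)),
               c(90L, 0L, 0L, 10L)) # identical waves: no movers
  mixed <- assign_groups(c(1:99, 50), c(2:100, 99.5))
  expect_equal(nrow(mixed), 100)
  # explicit rule application (top half: cutoffs 95 at wave 1, 96 at wave 2)
  ga2 <- assign_groups(c(1, 95, 2, 96), c(96, 2, 3, 97),
                       top_fraction = 0.5)
  expect_equal(as.character(ga2$group),
               c("increasing", "decreasing", "low_scoring", "persistent"))
  # ties at the cutoff are counted in the top group
  tied <- assign_groups(c(rep(0, 8), 5, 5), c(rep(0, 8), 5, 5))
  expect_equal(attr(tied, "realized_top_fraction")[["t1"]], 0.2)
  expect_equal(sum(tied$group == "persistent"), 2)
  expect_error(assign_groups(rep(3, 10), rep(3, 10)), "degenerate")
  # individuals missing either wave are excluded
  ga3 <- assign_groups(c(1:10, NA), c(NA, 2:10, 5))
  expect_equal(nrow(ga3), 9)
})

test_that("group counts are invariant to monotone transforms of scores", {
  x1 <- with_seed(71, rexp(500)); x2 <- with_seed(72, rexp(500))
  a <- assign_groups(x1, x2)
  b <- assign_groups(log10(x1 + 1), log10(x2 + 1))
  expect_identical(as.character(a$group), as.character(b$group))
})

test_that("top-decile severity matches the normal-theory benchmark", {
  z <- with_seed(73, rnorm(10000))
  ga <- assign_groups(z, with_seed(74, rnorm(10000)))
  top <- ga$score_t1[ga$score_t1 >= attr(ga, "cutoffs")[["t1"]]]
  # E[Z | Z > z_0.9] = dnorm(qnorm(0.9)) / 0.1 = 1.755
  expect_equal(mean(top), 1.755, tolerance = 0.05)
  # under a positively skewed warp the cutoff sits closer to the mean in
  # SD units, as with real questionnaire scores
  w <- exp(0.8 * z)
  gw <- assign_groups(w, exp(0.8 * with_seed(74, rnorm(10000))))
  dist_w <- (attr(gw, "cutoffs")[["t1"]] - mean(w)) / sd(w)
  expect_lt(dist_w, qnorm(0.9))
  expect_gt(dist_w, 0.5)
})

test_that("Cramer's V reproduces published contingency effect sizes", {
  expect_equal(round(cramers_v(rbind(c(620, 196, 38), c(9, 26, 31))), 2),
               0.45)
  expect_equal(round(cramers_v(rbind(c(484, 78, 10), c(22, 28, 15))), 2),
               0.43)
  expect_equal(round(cramers_v(rbind(c(556, 172, 37), c(17, 38, 41))), 2),
               0.46)
  expect_equal(round(cramers_v(rbind(c(699, 89, 22), c(55, 8, 3))), 2),
               0.03)
})

test_that("Cramer's V agrees with the chi-square oracle and edge cases", {
  expect_equal(cramers_v(rbind(c(10, 10), c(10, 10))), 0)
  tabs <- with_seed(75, replicate(50, {
    matrix(rpois(6, 20) + 1, 2, 3)
  }, simplify = FALSE))
  for (tab in tabs) {
    chisq <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    v_oracle <- sqrt(unname(chisq$statistic) / (sum(tab) * 1))
    expect_equal(cramers_v(tab), v_oracle, tolerance = 1e-10)
  }
  expect_warning(v <- cramers_v(rbind(c(5, 0, 5), c(5, 0, 5))), "zero-margin")
  expect_equal(v, 0)
  expect_error(cramers_v(rbind(c(1, 1), c(-1, 1))))
})

test_that("Monte-Carlo Fisher p matches full enumeration", {
  tab <- rbind(c(2, 0), c(0, 2)) # exact p = 1/3 over the 3 possible tables
  expect_equal(fisher_exact_2x2(tab), 1 / 3, tolerance = 1e-12)
  mc <- fisher_exact_montecarlo(tab, n_tables = 10000, seed = 7)
  expect_equal(mc$p, 1 / 3, tolerance = 3 * sqrt(1 / 3 * 2 / 3 / 10000))
  # proportional rows: every table at least as extreme
  prop_tab <- rbind(c(30, 60), c(10, 20))
  expect_gt(fisher_exact_montecarlo(prop_tab, seed = 8)$p, 0.9)
  # determinism
  expect_identical(fisher_exact_montecarlo(tab, seed = 3)$p,
                   fisher_exact_montecarlo(tab, seed = 3)$p)
  # random 2x2 tables against the enumeration oracle
  tabs <- with_seed(76, replicate(20, matrix(rpois(4, 8), 2, 2),
                                  simplify = FALSE))
  for (tab in tabs) {
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p_exact <- fisher_exact_2x2(tab)
    mc <- fisher_exact_montecarlo(tab, n_tables = 4000, seed = 11)
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(mc$p - p_exact), 4 * se + 1e-3)
  }
})

test_that("Cohen's d handles unequal groups and published summaries", {
  expect_equal(cohens_d_unequal_n(5, 2, 30, 5, 3, 50), 0)
  # persistent (45.73, SD 8.28, n 66) vs decreasing (42.91, SD 6.02, n 53)
  d <- cohens_d_unequal_n(45.73, 8.28, 66, 42.91, 6.02, 53)
  expect_equal(round(d, 2), 0.38)
  expect_gte(d, 0.31); expect_lte(d, 0.56)
  expect_equal(cohens_d_unequal_n(3, 2, 40, 1, 2, 40), 1)
  expect_error(cohens_d_unequal_n(3, 0, 10, 1, 0, 10), "infinite")
  expect_equal(cohens_d_unequal_n(3, 0, 10, 3, 0, 10), 0)
})

test_that("group contrasts are null when outcomes are independent of group", {
  # waves correlated ~0.65 as in stable phenotypes, so the persistent group
  # is a realistic ~5% of the sample rather than vanishingly small
  n <- 10000
  g <- with_seed(77, {
    z1 <- rnorm(n)
    z2 <- 0.65 * z1 + sqrt(1 - 0.65^2) * rnorm(n)
    ga <- assign_groups(z1, z2)
    out <- data.frame(y = rnorm(n))
    group_contrast_report(ga, out)
  })
  expect_true(all(abs(g$contrasts$d) < 0.1))
})

test_that("persistent individuals score highest on loaded co-occurring scales", {
  cfg <- simulation_config(
    n_pairs = c(MZM = 800, MZF = 800, DZM = 800, DZF = 800, DZOS = 800),
    subscales = list(ph = list(params = paranoia_truth(), skewed = TRUE,
                               distress = TRUE)),
    wave2_retention = 1, seed = 78)
  ch <- generate_cohort(cfg)
  ind <- select_one_twin_per_pair(ch, seed = 79)
  ga <- assign_groups(ind$ph_t1, ind$ph_t2, ids = seq_len(nrow(ind)))
  rep <- group_contrast_report(ga, ind[ga$id, "smfq", drop = FALSE])
  con <- rep$contrasts
  pvl <- con$d[con$group_1 == "persistent" & con$group_2 == "low_scoring"]
  expect_gt(pvl, 0.5) # strongly elevated co-occurring psychopathology
  # and larger than the contrast for the transient (increasing) group,
  # whose wave-1 severity is lower by construction
  ivl <- con$d[con$group_1 == "increasing" & con$group_2 == "low_scoring"]
  expect_gt(pvl, ivl)
  expect_gt(pvl, 0.9 * max(abs(con$d)))
  # and the distress gradient is monotone across groups
  dc <- distress_contingency(ga, ind$ph_distress[ga$id], n_tables = 2000,
                             seed = 80)
  pct <- dc$row_percent
  expect_gt(pct["persistent", "quite/very"], pct["low_scoring", "quite/very"])
  expect_gt(dc$comparisons$cramers_v[1], 0.1) # low-scoring vs persistent
  expect_lt(dc$comparisons$p_montecarlo[1], 0.01)
})

test_that("contrasts with singleton groups are skipped with a warning", {
  ga <- assign_groups(c(1:19, 100), c(1:19, 100), top_fraction = 0.05)
  expect_equal(sum(ga$group == "persistent"), 1)
  w <- capture_warnings(rep <- group_contrast_report(ga,
                                                     data.frame(y = rnorm(20))))
  expect_true(any(grepl("fewer than 2", w)))
  expect_false(any(rep$contrasts$group_1 == "persistent"))
})
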
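# Shared fixtures: ground truths and small simulated cohorts built in code.

# standardized ACE truth with wave-1 components (0.28, 0.19, 0.53), wave-2
# (0.32, 0.12, 0.55) and cross-wave covariance components (0.25, 0.12, 0.23)
paranoia_truth <- function() {
  cholesky_params(X = chol2x2(0.28, 0.25, 0.32),
                  Y = chol2x2(0.19, 0.12, 0.12),
                  Z = chol2x2(0.53, 0.23, 0.55))
}

anhedonia_truth <- function() {
  cholesky_params(X = chol2x2(0.47, 0.37, 0.46),
                  Z = chol2x2(0.53, 0.22, 0.54))
}

# one-subscale latent-scale cohort; equal pairs per group by default
quick_cohort <- function(n_per_group = 500, truth = paranoia_truth(),
                         retention = 1, seed = 1, skewed = FALSE,
                         distress = FALSE,
                         skew_transform = if (skewed) "exponential" else
                           "none",
                         groups = c(MZM = 1, MZF = 1, DZM = 1, DZF = 1,
                                    DZOS = 1)) {
  cfg <- simulation_config(
    n_pairs = groups * n_per_group,
    subscales = list(ph = list(params = truth, skewed = skewed,
                               distress = distress)),
    wave2_retention = retention, skew_transform = skew_transform,
    seed = seed)
  generate_cohort(cfg)
}

quick_model_data <- function(...) {
  twin_model_data(quick_cohort(...), "ph", standardized = FALSE)
}

# independent -2 log-likelihood oracle: direct per-pair density summation
# using solve()/determinant(), no sufficient statistics, no C++
oracle_m2ll <- function(groups, mu_fun, sigma_fun) {
  total <- 0
  for (g in names(groups)) {
    Y <- groups[[g]]
    mu <- mu_fun(g)
    S <- sigma_fun(g)
    for (i in seq_len(nrow(Y))) {
      obs <- which(!is.na(Y[i, ]))
      if (!length(obs)) next
      x <- Y[i, obs]
      Ss <- S[obs, obs, drop = FALSE]
      d <- x - mu[obs]
      total <- total + length(obs) * log(2 * pi) +
        as.numeric(determinant(Ss, logarithm = TRUE)$modulus) +
        drop(t(d) %*% solve(Ss, d))
    }
  }
  total
}

# full-enumeration Fisher exact p for a 2x2 table via the hypergeometric
# distribution (independent of the Monte-Carlo implementation)
fisher_exact_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  a_vals <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(a_vals, c1, N - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
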
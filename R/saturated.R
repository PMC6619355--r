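#' Equality-constraint set for the saturated twin model
#'
#' The saturated model estimates per-group means and full 4x4 covariance
#' matrices of the pair vector (twin 1 wave 1, twin 1 wave 2, twin 2 wave 1,
#' twin 2 wave 2). Constraints equate means / variances across twin order
#' and zygosity, the within-twin cross-time covariance (the phenotypic
#' stability) across twin order and zygosity, and the two cross-twin
#' cross-time covariances within a pair.
#'
#' @param eq_means_twin,eq_means_zyg equate means across twin order /
#'   zygosity groups.
#' @param eq_vars_twin,eq_vars_zyg likewise for variances.
#' @param eq_ct_twin,eq_ct_zyg likewise for the within-twin cross-time
#'   covariance.
#' @param eq_cross_sym equate the two cross-twin cross-time covariances.
#' @param by_sex pool means, variances and the cross-time covariance by the
#'   twin's sex instead (male/female), leaving cross-twin covariances free
#'   per group; used to obtain sex-specific phenotypic correlations.
#' @return a `saturated_constraints` list.
#' @export
saturated_constraints <- function(eq_means_twin = FALSE,
                                  eq_means_zyg = FALSE,
                                  eq_vars_twin = FALSE,
                                  eq_vars_zyg = FALSE,
                                  eq_ct_twin = FALSE,
                                  eq_ct_zyg = FALSE,
                                  eq_cross_sym = FALSE,
                                  by_sex = FALSE) {
  structure(list(eq_means_twin = eq_means_twin, eq_means_zyg = eq_means_zyg,
                 eq_vars_twin = eq_vars_twin, eq_vars_zyg = eq_vars_zyg,
                 eq_ct_twin = eq_ct_twin, eq_ct_zyg = eq_ct_zyg,
                 eq_cross_sym = eq_cross_sym, by_sex = by_sex),
            class = "saturated_constraints")
}

fully_constrained <- function(by_sex = FALSE) {
  saturated_constraints(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                        by_sex = by_sex)
}

sat_keys <- function(cn, groups) {
  mk <- function(prefix, g, tw, w, eq_twin, eq_zyg) {
    if (cn$by_sex) {
      paste0(prefix, "_", pair_sexes(g)[tw], if (!is.null(w)) paste0("_", w))
    } else {
      paste0(prefix,
             if (!eq_zyg) paste0("_", g) else "",
             if (!eq_twin) paste0("_tw", tw) else "",
             if (!is.null(w)) paste0("_", w) else "")
    }
  }
  keys <- list()
  for (g in groups) {
    km <- kv <- matrix("", 2, 2)
    kc <- character(2)
    for (tw in 1:2) {
      for (w in 1:2) {
        km[tw, w] <- mk("m", g, tw, w, cn$eq_means_twin, cn$eq_means_zyg)
        kv[tw, w] <- mk("v", g, tw, w, cn$eq_vars_twin, cn$eq_vars_zyg)
      }
      kc[tw] <- mk("cw", g, tw, NULL, cn$eq_ct_twin, cn$eq_ct_zyg)
    }
    kb <- c(b11 = paste0("b11_", g), b22 = paste0("b22_", g),
            bx14 = if (cn$eq_cross_sym) paste0("bx_", g) else
              paste0("bx14_", g),
            bx23 = if (cn$eq_cross_sym) paste0("bx_", g) else
              paste0("bx23_", g))
    keys[[g]] <- list(m = km, v = kv, cw = kc, b = kb)
  }
  keys
}

sat_sample_moments <- function(Y) {
  mu <- colMeans(Y, na.rm = TRUE)
  S <- suppressWarnings(cov(Y, use = "pairwise.complete.obs"))
  S[!is.finite(S)] <- 0
  mu[!is.finite(mu)] <- 0
  list(mu = mu, S = S)
}

sat_template <- function(keys, data) {
  acc <- list()
  add <- function(key, value) {
    if (!is.finite(value)) value <- 0
    acc[[key]] <<- c(acc[[key]], value)
  }
  for (g in names(keys)) {
    mom <- sat_sample_moments(data$groups[[g]])
    k <- keys[[g]]
    for (tw in 1:2) {
      for (w in 1:2) {
        pos <- (tw - 1) * 2 + w
        add(k$m[tw, w], mom$mu[pos])
        add(k$v[tw, w], log(max(mom$S[pos, pos], 1e-4)))
      }
      add(k$cw[tw], mom$S[(tw - 1) * 2 + 1, (tw - 1) * 2 + 2])
    }
    add(k$b[["b11"]], mom$S[1, 3])
    add(k$b[["b22"]], mom$S[2, 4])
    add(k$b[["bx14"]], mom$S[1, 4])
    add(k$b[["bx23"]], mom$S[2, 3])
  }
  vapply(acc, mean, numeric(1))
}

sat_build <- function(keys) {
  force(keys)
  function(par) {
    lapply(keys, function(k) {
      mu <- c(par[[k$m[1, 1]]], par[[k$m[1, 2]]],
              par[[k$m[2, 1]]], par[[k$m[2, 2]]])
      v <- exp(c(par[[k$v[1, 1]]], par[[k$v[1, 2]]],
                 par[[k$v[2, 1]]], par[[k$v[2, 2]]]))
      S <- diag(v)
      S[1, 2] <- S[2, 1] <- par[[k$cw[1]]]
      S[3, 4] <- S[4, 3] <- par[[k$cw[2]]]
      S[1, 3] <- S[3, 1] <- par[[k$b[["b11"]]]]
      S[2, 4] <- S[4, 2] <- par[[k$b[["b22"]]]]
      S[1, 4] <- S[4, 1] <- par[[k$b[["bx14"]]]]
      S[2, 3] <- S[3, 2] <- par[[k$b[["bx23"]]]]
      list(mu = mu, sigma = S)
    })
  }
}

#' Fit a (possibly constrained) saturated twin model by FIML
#'
#' @param data a [twin_model_data()].
#' @param constraints a [saturated_constraints()] set.
#' @param n_starts optimizer starts (moment-based start first; extra starts
#'   jitter it, used when the first does not converge).
#' @param seed jitter seed.
#' @return object of class `saturated_fit` with the -2LL, fit indices,
#'   implied per-group means/covariances, and the objective/build closures
#'   for profiling.
#' @export
fit_saturated <- function(data, constraints = saturated_constraints(),
                          n_starts = 3, seed = 1) {
  stopifnot(inherits(data, "twin_model_data"),
            inherits(constraints, "saturated_constraints"))
  stacked <- do.call(rbind, data$groups)
  for (w in 1:2) {
    vals <- c(stacked[, w], stacked[, w + 2])
    if (var(vals, na.rm = TRUE) < 1e-12) {
      stop("scores at wave ", w, " have (near-)zero variance", call. = FALSE)
    }
  }
  keys <- sat_keys(constraints, names(data$groups))
  start <- sat_template(keys, data)
  build <- sat_build(keys)
  stats <- unname(data$stats)
  objective <- function(par) {
    names(par) <- names(start)
    imp <- build(par)
    .fiml_m2ll_cpp(stats, lapply(imp, `[[`, "mu"),
                   lapply(imp, `[[`, "sigma"))
  }
  ctrl <- list(eval.max = 5000, iter.max = 2000, rel.tol = 1e-10)
  best <- NULL
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(i) {
    if (i == 1) start else start * (1 + 0.1 * rnorm(length(start))) +
      0.02 * rnorm(length(start))
  }))
  for (st in starts) {
    res <- tryCatch(nlminb(st, objective, control = ctrl),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective) best <- res
    if (best$convergence == 0) break
  }
  if (is.null(best)) stop("saturated model failed to converge", call. = FALSE)
  par <- best$par
  names(par) <- names(start)
  k <- length(par)
  n <- sum(data$n_pairs)
  implied <- build(par)
  structure(list(constraints = constraints, par = par,
                 minus2LL = best$objective, n_parameters = k,
                 n_pairs_used = n,
                 AIC = best$objective + 2 * k,
                 BIC = best$objective + k * log(n),
                 convergence = best$convergence == 0,
                 implied = implied, objective = objective, build = build,
                 digest = data$digest),
            class = "saturated_fit")
}

#' @export
print.saturated_fit <- function(x, ...) {
  cat("Saturated twin model:", x$n_parameters, "parameters,",
      x$n_pairs_used, "pairs\n")
  cat(sprintf("  -2LL %.3f | AIC %.3f | BIC %.3f%s\n", x$minus2LL, x$AIC,
              x$BIC, if (x$convergence) "" else " | NOT converged"))
  invisible(x)
}

cor_from_sigma <- function(S, i, j) S[i, j] / sqrt(S[i, i] * S[j, j])

#' Phenotypic and twin intraclass correlations from constrained saturated
#' models
#'
#' Fits the fully constrained saturated model (means, variances and the
#' phenotypic cross-time covariance equated across twin order and zygosity
#' within sex; cross-twin covariances free per group) to obtain sex-specific
#' phenotypic correlations and per-group twin intraclass correlations, plus
#' a reduced model pooling the sexes for the whole-sample phenotypic
#' correlation. Correlations are computed from the constrained model-implied
#' covariances, not from Pearson correlations on double-entered data.
#'
#' @param data a [twin_model_data()].
#' @param ci `"none"` or `"profile"` for 95% profile-likelihood intervals
#'   (slower).
#' @param level confidence level for profile intervals.
#' @param ci_types correlation types to profile when `ci = "profile"`
#'   (default all): any of `"phenotypic"`, `"cross_twin_t1"`,
#'   `"cross_twin_t2"`, `"cross_twin_cross_time"`.
#' @return object of class `saturated_correlations`: list with
#'   `correlations` (data frame: type, group, estimate, lower, upper),
#'   `fit_by_sex` and `fit_pooled`.
#' @export
fit_constrained_saturated <- function(data, ci = c("none", "profile"),
                                      level = 0.95, ci_types = NULL) {
  ci <- match.arg(ci)
  fit_sex <- fit_saturated(data, fully_constrained(by_sex = TRUE))
  fit_pool <- fit_saturated(data, fully_constrained(by_sex = FALSE))
  rows <- list()
  add <- function(fit, type, group, i, j, sigma_group = group) {
    S <- fit$implied[[sigma_group]]$sigma
    est <- cor_from_sigma(S, i, j)
    lo <- up <- NA_real_
    if (ci == "profile" && (is.null(ci_types) || type %in% ci_types)) {
      qf <- function(par) {
        imp <- fit$build(par)
        cor_from_sigma(imp[[sigma_group]]$sigma, i, j)
      }
      iv <- profile_interval(fit$objective, fit$par, fit$minus2LL, qf,
                             level = level, bounds = c(-1, 1))
      lo <- iv[["lower"]]; up <- iv[["upper"]]
    }
    rows[[length(rows) + 1]] <<- data.frame(
      type = type, group = group, estimate = est, lower = lo, upper = up,
      stringsAsFactors = FALSE)
  }
  gs <- names(fit_sex$implied)
  add(fit_pool, "phenotypic", "all", 1, 2, sigma_group = gs[1])
  female_g <- intersect(c("MZF", "DZF"), gs)
  male_g <- intersect(c("MZM", "DZM"), gs)
  if (length(female_g)) {
    add(fit_sex, "phenotypic", "female", 1, 2, sigma_group = female_g[1])
  }
  if (length(male_g)) {
    add(fit_sex, "phenotypic", "male", 1, 2, sigma_group = male_g[1])
  }
  for (g in gs) add(fit_sex, "cross_twin_t1", g, 1, 3)
  for (g in gs) add(fit_sex, "cross_twin_t2", g, 2, 4)
  for (g in gs) add(fit_sex, "cross_twin_cross_time", g, 1, 4)
  correlations <- do.call(rbind, rows)
  bad <- abs(correlations$estimate) > 1
  if (any(bad)) correlations$estimate[bad] <- sign(correlations$estimate[bad])
  structure(list(correlations = correlations, fit_by_sex = fit_sex,
                 fit_pooled = fit_pool),
            class = "saturated_correlations")
}

#' @export
print.saturated_correlations <- function(x, digits = 3, ...) {
  df <- x$correlations
  df$estimate <- round(df$estimate, digits)
  if (all(is.na(df$lower))) df$lower <- df$upper <- NULL
  print(df, row.names = FALSE)
  invisible(x)
}

#' Double-entry (intraclass) Pearson correlation
#'
#' Cross-check utility: the Pearson correlation between two coordinates of
#' the pair vector after entering each pair in both twin orders. The
#' model-based correlations from [fit_constrained_saturated()] are the
#' primary estimates; this exists to sanity-check them.
#'
#' @param Y n x 4 pair matrix (t1 twin1, t2 twin1, t1 twin2, t2 twin2).
#' @param cols length-2 column pair for twin 1, e.g. `c(1, 3)` for the
#'   wave-1 cross-twin correlation, `c(1, 4)` for cross-twin cross-time.
#' @return Pearson correlation on the double-entered data.
#' @export
double_entry_correlation <- function(Y, cols = c(1, 3)) {
  swap <- c(3, 4, 1, 2)
  x <- c(Y[, cols[1]], Y[, swap[cols[1]]])
  y <- c(Y[, cols[2]], Y[, swap[cols[2]]])
  stats::cor(x, y, use = "complete.obs")
}

#' Assumption tests for the twin model via a saturated-model ladder
#'
#' Tests the standard equality assumptions by fitting a sequence of nested
#' saturated models -- means equal across twin order, then across zygosity;
#' variances likewise; finally the cross-time covariance equalities of the
#' fully constrained model -- and comparing each to the previous (freer)
#' model by likelihood-ratio chi-square and BIC difference.
#'
#' @param data a [twin_model_data()].
#' @return object of class `assumption_tests`: data frame with one row per
#'   constraint step (chi-square, df, p, delta BIC).
#' @export
assumption_tests <- function(data) {
  steps <- list(
    list(label = "free saturated", cn = saturated_constraints()),
    list(label = "means equal across twin order",
         cn = saturated_constraints(eq_means_twin = TRUE)),
    list(label = "means equal across zygosity",
         cn = saturated_constraints(TRUE, TRUE)),
    list(label = "variances equal across twin order",
         cn = saturated_constraints(TRUE, TRUE, TRUE)),
    list(label = "variances equal across zygosity",
         cn = saturated_constraints(TRUE, TRUE, TRUE, TRUE)),
    list(label = "cross-time covariances equal (fully constrained)",
         cn = fully_constrained()))
  fits <- lapply(steps, function(s) fit_saturated(data, s$cn))
  rows <- list()
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (i == 1) {
      rows[[i]] <- data.frame(model = steps[[i]]$label,
                              minus2LL = f$minus2LL,
                              n_parameters = f$n_parameters,
                              lrt_chisq = NA_real_, df = NA_integer_,
                              p_value = NA_real_, delta_BIC = NA_real_,
                              stringsAsFactors = FALSE)
    } else {
      prev <- fits[[i - 1]]
      chi <- max(f$minus2LL - prev$minus2LL, 0)
      df <- prev$n_parameters - f$n_parameters
      rows[[i]] <- data.frame(model = steps[[i]]$label,
                              minus2LL = f$minus2LL,
                              n_parameters = f$n_parameters,
                              lrt_chisq = chi, df = df,
                              p_value = pchisq(chi, df, lower.tail = FALSE),
                              delta_BIC = f$BIC - prev$BIC,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("assumption_tests", "data.frame"))
}

#' @export
print.assumption_tests <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
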
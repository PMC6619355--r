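#' Specify a bivariate twin model
#'
#' @param components variance-component family: `"ACE"`, `"ADE"`, `"AE"`,
#'   `"CE"` or `"E"`. ADE replaces shared environment by dominance (co-twin
#'   sharing 1 for MZ, 0.25 for DZ); C and D are never estimated together.
#' @param sex_mode sex-limitation level, in decreasing generality:
#'   `"full"` (quantitative + qualitative: sex-specific path matrices plus a
#'   free opposite-sex DZ genetic correlation `rg`, bounded to \[0, 1\] by a
#'   logistic transform), `"quantitative"` (sex-specific paths, `rg = 1`),
#'   `"common_correlations"` (sex-specific component variances but
#'   aetiological cross-wave correlations rA/rC/rE equated across sex,
#'   `rg = 1`), or `"none"` (no sex differences).
#' @param free_means_by_sex estimate separate wave means per sex. Means are
#'   always estimated freely per wave: with missingness FIML observed means
#'   shift, so they are not fixed at zero despite standardization.
#' @param min_pairs minimum pairs required in each zygosity group present.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(components = c("ACE", "ADE", "AE", "CE", "E"),
                       sex_mode = c("none", "common_correlations",
                                    "quantitative", "full"),
                       free_means_by_sex = FALSE,
                       min_pairs = 20) {
  components <- match.arg(components)
  sex_mode <- match.arg(sex_mode)
  if (sex_mode == "full" && !(components %in% c("ACE", "ADE"))) {
    stop("qualitative sex limitation (free rg) requires an A component",
         call. = FALSE)
  }
  structure(list(components = components, sex_mode = sex_mode,
                 free_means_by_sex = free_means_by_sex,
                 min_pairs = min_pairs),
            class = "model_spec")
}

spec_label <- function(spec) {
  sx <- switch(spec$sex_mode,
               full = "qualitative + quantitative sex differences",
               quantitative = "quantitative sex differences",
               common_correlations =
                 "quantitative sex differences, equal aetiological correlations",
               none = "no sex differences")
  paste0(spec$components, ", ", sx)
}

# which factor matrices are free, and the Y-sharing family
spec_matrices <- function(components) {
  switch(components,
         ACE = list(free = c("X", "Y", "Z"), base = "ACE"),
         ADE = list(free = c("X", "Y", "Z"), base = "ADE"),
         AE  = list(free = c("X", "Z"), base = "ACE"),
         CE  = list(free = c("Y", "Z"), base = "ACE"),
         E   = list(free = "Z", base = "ACE"))
}

lower_tri_from <- function(v) matrix(c(v[1], v[2], 0, v[3]), 2, 2)

# moment-based start: pooled within-person covariance and means
start_moments <- function(data) {
  allY <- do.call(rbind, lapply(data$groups, function(Y) {
    rbind(Y[, 1:2, drop = FALSE], Y[, 3:4, drop = FALSE])
  }))
  m <- colMeans(allY, na.rm = TRUE)
  v1 <- var(allY[, 1], na.rm = TRUE)
  v2 <- var(allY[, 2], na.rm = TRUE)
  cc <- tryCatch(cov(allY, use = "pairwise.complete.obs")[1, 2],
                 error = function(e) NA_real_)
  if (!is.finite(v2)) v2 <- v1  # no wave-2 data at all (caught later)
  if (!is.finite(cc)) cc <- 0.5 * sqrt(v1 * v2)
  cc <- sign(cc) * min(abs(cc), 0.9 * sqrt(v1 * v2))
  W <- matrix(c(v1, cc, cc, v2), 2, 2)
  list(means = m, W = W)
}

chol_lower <- function(M) t(chol(M))

# build the parameter template (names + starts) for a spec
spec_template <- function(spec, data) {
  mom <- start_moments(data)
  mats <- spec_matrices(spec$components)
  frac <- c(X = 0.35, Y = 0.25, Z = 0.40)
  frac <- frac[mats$free] / sum(frac[mats$free])
  sexes <- if (spec$sex_mode == "none") "" else c("M", "F")
  par <- numeric(0)
  if (spec$sex_mode %in% c("none", "quantitative", "full")) {
    for (sx in sexes) {
      for (M in mats$free) {
        L <- chol_lower(frac[[M]] * mom$W)
        nm <- paste0(tolower(M), c("11", "21", "22"),
                     if (sx != "") paste0("_", sx))
        par[nm] <- c(L[1, 1], L[2, 1], L[2, 2])
      }
    }
    if (spec$sex_mode == "full") par["rg_raw"] <- 2  # logistic^-1(~0.88)
  } else { # common_correlations: per-sex scales, shared correlations
    for (M in mats$free) {
      for (sx in sexes) {
        nm <- paste0(tolower(M), c("1_", "2_"), sx)
        par[nm] <- sqrt(frac[[M]] * diag(mom$W))
      }
      par[paste0("r", tolower(M), "_raw")] <-
        atanh(min(max(mom$W[1, 2] / sqrt(prod(diag(mom$W))), -0.95), 0.95))
    }
  }
  if (spec$free_means_by_sex && spec$sex_mode != "none") {
    par[c("m1_M", "m2_M", "m1_F", "m2_F")] <- rep(mom$means, 2)
  } else {
    par[c("m1", "m2")] <- mom$means
  }
  par
}

# parameter vector -> cholesky_params / sexlim_params
spec_build <- function(spec) {
  mats <- spec_matrices(spec$components)
  force(spec)
  function(par) {
    get_means <- function(sx) {
      if (spec$free_means_by_sex && spec$sex_mode != "none") {
        c(par[[paste0("m1_", sx)]], par[[paste0("m2_", sx)]])
      } else {
        c(par[["m1"]], par[["m2"]])
      }
    }
    make_paths <- function(sx) {
      suffix <- if (spec$sex_mode == "none") "" else paste0("_", sx)
      M <- list(X = matrix(0, 2, 2), Y = matrix(0, 2, 2),
                Z = matrix(0, 2, 2))
      if (spec$sex_mode %in% c("none", "quantitative", "full")) {
        for (nm in mats$free) {
          keys <- paste0(tolower(nm), c("11", "21", "22"), suffix)
          M[[nm]] <- lower_tri_from(par[keys])
        }
      } else {
        for (nm in mats$free) {
          s1 <- par[[paste0(tolower(nm), "1_", sx)]]
          s2 <- par[[paste0(tolower(nm), "2_", sx)]]
          rho <- tanh(par[[paste0("r", tolower(nm), "_raw")]])
          M[[nm]] <- lower_tri_from(c(s1, rho * s2,
                                      sqrt(max(1 - rho^2, 0)) * s2))
        }
      }
      structure(list(X = M$X, Y = M$Y, Z = M$Z, components = mats$base,
                     means = get_means(sx)),
                class = "cholesky_params")
    }
    if (spec$sex_mode == "none") {
      make_paths("F")
    } else {
      rg <- if (spec$sex_mode == "full") plogis(par[["rg_raw"]]) else 1
      structure(list(male = make_paths("M"), female = make_paths("F"),
                     rg = rg, components = mats$base),
                class = "sexlim_params")
    }
  }
}

#' Fit a bivariate Cholesky twin model by FIML
#'
#' Minimizes the full-information -2 log-likelihood over the free path
#' coefficients (raw, unbounded; variances enter as squares, so no boundary
#' constraints are needed) across all zygosity groups present in the data,
#' from multiple seeded starts with jitter around a moment-based start. The
#' best converged solution wins.
#'
#' @param data a [twin_model_data()].
#' @param spec a [model_spec()].
#' @param n_starts number of optimizer starts (first is moment-based, the
#'   rest jittered).
#' @param seed seed for the start jitter.
#' @param control passed to [stats::nlminb()]; defaults request an objective
#'   tolerance of 1e-8.
#' @return object of class `twin_fit` with elements `minus2LL`, `AIC`,
#'   `BIC` (sample-size penalty uses the number of pairs contributing any
#'   data -- pairs being the independent units), `n_parameters`,
#'   `n_pairs_used`, `params` (fitted [cholesky_params()] /
#'   [sexlim_params()]), `convergence`, and the objective/build closures
#'   used for profile-likelihood intervals.
#' @export
fit_model <- function(data, spec, n_starts = 8, seed = 1, control = NULL) {
  stopifnot(inherits(data, "twin_model_data"), inherits(spec, "model_spec"))
  low <- data$n_pairs < spec$min_pairs
  if (any(low)) {
    stop("groups below the minimum pair count (", spec$min_pairs, "): ",
         paste(names(data$n_pairs)[low], collapse = ", "), call. = FALSE)
  }
  if (!any(vapply(unlist(data$stats, recursive = FALSE),
                  function(p) any(p$idx %in% c(2L, 4L)), TRUE))) {
    stop("no wave-2 observations in any group; the bivariate model is not ",
         "identified", call. = FALSE)
  }
  start <- spec_template(spec, data)
  build <- spec_build(spec)
  gs <- names(data$groups)
  stats <- unname(data$stats)
  if (spec$sex_mode == "none") {
    # compiled fast path: pair covariance assembled in C++
    mats <- spec_matrices(spec$components)
    kA <- vapply(gs, function(g) sharing_coefs(g, mats$base, 1)[["A"]], 1)
    kY <- vapply(gs, function(g) sharing_coefs(g, mats$base, 1)[["Y"]], 1)
    free_mats <- c("X", "Y", "Z") %in% mats$free
    objective <- function(par) {
      .m2ll_nosex_cpp(par, stats, kA, kY, free_mats)
    }
  } else {
    objective <- function(par) {
      names(par) <- names(start)
      params <- build(par)
      mu <- lapply(gs, function(g) expected_pair_means(params, g))
      sigma <- lapply(gs, function(g) expected_pair_covariance(params, g))
      .fiml_m2ll_cpp(stats, mu, sigma)
    }
  }
  control <- control %||% list(eval.max = 4000, iter.max = 1000,
                               rel.tol = 1e-10, abs.tol = 1e-8)
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1) start
      else start * (1 + 0.25 * rnorm(length(start))) +
        0.05 * rnorm(length(start))
    })
  })
  best <- NULL
  n_conv <- 0L
  for (st in starts) {
    res <- tryCatch(nlminb(st, objective, control = control),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    converged <- res$convergence == 0 ||
      grepl("relative convergence|both X|singular convergence",
            res$message %||% "")
    if (converged) n_conv <- n_conv + 1L
    if (is.null(best) || res$objective < best$objective) {
      best <- res
      best$converged <- converged
    }
  }
  if (is.null(best)) {
    return(structure(list(spec = spec, label = spec_label(spec),
                          convergence = FALSE, minus2LL = NA_real_,
                          diagnostics = "all starts failed"),
                     class = "twin_fit"))
  }
  par <- best$par
  names(par) <- names(start)
  k <- length(par)
  n <- sum(data$n_pairs)
  m2ll <- best$objective
  structure(list(
    spec = spec, label = spec_label(spec),
    par = par, params = build(par),
    minus2LL = m2ll, n_parameters = k, n_pairs_used = n,
    AIC = m2ll + 2 * k, BIC = m2ll + k * log(n),
    convergence = isTRUE(best$converged), n_converged_starts = n_conv,
    objective = objective, build = build,
    digest = data$digest, group_n = data$n_pairs,
    subscale = data$subscale),
    class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, digits = 3, ...) {
  cat("Bivariate twin model:", x$label, "\n")
  if (!isTRUE(x$convergence) && is.na(x$minus2LL)) {
    cat("  NOT CONVERGED:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf("  -2LL %.3f | AIC %.3f | BIC %.3f | %d parameters | %d pairs%s\n",
              x$minus2LL, x$AIC, x$BIC, x$n_parameters, x$n_pairs_used,
              if (x$convergence) "" else " | convergence not confirmed"))
  est <- standardize(x$params)
  if (inherits(est, "stability_estimates")) {
    print(est, digits = digits)
  } else {
    for (sx in names(est)) {
      cat("--", sx, "--\n")
      print(est[[sx]], digits = digits)
    }
  }
  invisible(x)
}
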
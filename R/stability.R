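#' Standardized stability estimates from Cholesky parameters
#'
#' Derives the full set of standardized quantities implied by fitted (or
#' true) path matrices, for one sex:
#' \itemize{
#' \item per-wave standardized variance components, e.g. wave-1
#'   heritability `a2_t1 = x11^2 / (x11^2 + y11^2 + z11^2)`;
#' \item bivariate covariance components: the A/C/E shares of the
#'   cross-wave covariance on the standardized scale,
#'   `biv_a = (XX')[1,2] / sqrt(v1 v2)` etc.;
#' \item proportions of the phenotypic correlation explained by A, C and E
#'   (each bivariate component divided by their sum);
#' \item aetiological correlations rA/rC/rE from the equivalent
#'   correlated-factors solution (see [aetiological_correlations()]);
#' \item the wave-2 variance split into influences carried over from wave 1
#'   (`x21^2 / v2`, ...) and influences novel to wave 2 (`x22^2 / v2`, ...).
#' }
#' The identity `biv_a = rA * sqrt(a2_t1 * a2_t2)` (and likewise for C and
#' E) ties the two parameterizations together.
#'
#' @param params `cholesky_params`, `sexlim_params`, or a fitted
#'   [fit_model()] result.
#' @param sex for sex-limited parameters, `"M"`, `"F"`, or `NULL` to return
#'   a named list with both sexes.
#' @return an object of class `stability_estimates` (named numeric list),
#'   or a list of two for sex-limited parameters with `sex = NULL`.
#' @export
standardize <- function(params, sex = NULL) {
  if (inherits(params, "twin_fit")) params <- params$params
  if (inherits(params, "sexlim_params")) {
    if (is.null(sex)) {
      return(list(male = standardize(params, "M"),
                  female = standardize(params, "F")))
    }
    p <- paths_for_sex(params, sex)
  } else {
    p <- params
  }
  cc <- component_covs(p)
  W <- cc$A + cc$Y + cc$E
  v1 <- W[1, 1]; v2 <- W[2, 2]
  if (v1 <= 0 || v2 <= 0) stop("zero implied variance", call. = FALSE)
  sv <- sqrt(v1 * v2)
  comp_r <- function(M) {
    if (M[1, 1] < 1e-12 || M[2, 2] < 1e-12) NA_real_
    else M[1, 2] / sqrt(M[1, 1] * M[2, 2])
  }
  biv <- c(a = cc$A[1, 2], c = cc$Y[1, 2], e = cc$E[1, 2]) / sv
  total_biv <- sum(biv)
  prop <- if (abs(total_biv) < 1e-12) rep(NA_real_, 3) else biv / total_biv
  structure(list(
    components = cc$components,
    a2_t1 = cc$A[1, 1] / v1, c2_t1 = cc$Y[1, 1] / v1,
    e2_t1 = cc$E[1, 1] / v1,
    a2_t2 = cc$A[2, 2] / v2, c2_t2 = cc$Y[2, 2] / v2,
    e2_t2 = cc$E[2, 2] / v2,
    biv_a = unname(biv["a"]), biv_c = unname(biv["c"]),
    biv_e = unname(biv["e"]),
    prop_a = unname(prop[1]), prop_c = unname(prop[2]),
    prop_e = unname(prop[3]),
    r_phenotypic = W[1, 2] / sv,
    rA = comp_r(cc$A), rC = comp_r(cc$Y), rE = comp_r(cc$E),
    carried_a2 = p$X[2, 1]^2 / v2, novel_a2 = p$X[2, 2]^2 / v2,
    carried_c2 = p$Y[2, 1]^2 / v2, novel_c2 = p$Y[2, 2]^2 / v2,
    carried_e2 = p$Z[2, 1]^2 / v2, novel_e2 = p$Z[2, 2]^2 / v2,
    var_t1 = v1, var_t2 = v2),
    class = "stability_estimates")
}

#' Aetiological correlations from the correlated-factors solution
#'
#' The cross-wave correlation of each variance component,
#' `rA = covA / sqrt(varA1 * varA2)` with `covA`, `varA` taken from `XX'`
#' (and analogously for the C/D and E blocks). These are the parameters of
#' the correlated-factors model, which is mathematically equivalent to the
#' Cholesky decomposition. A component with (near-)zero variance at either
#' wave has an undefined correlation, returned as `NA`.
#'
#' @inheritParams standardize
#' @return named numeric vector `c(rA, rC, rE)` (the middle entry is rD for
#'   ADE parameters).
#' @export
aetiological_correlations <- function(params, sex = "F") {
  if (inherits(params, "twin_fit")) params <- params$params
  est <- if (inherits(params, "sexlim_params")) {
    standardize(params, sex)
  } else {
    standardize(params)
  }
  c(rA = est$rA, rC = est$rC, rE = est$rE)
}

#' @export
print.stability_estimates <- function(x, digits = 3, ...) {
  f <- function(v) formatC(v, digits = digits, format = "f")
  lab <- if (x$components == "ACE") "c2" else "d2"
  cat(sprintf("  wave 1: a2 %s, %s %s, e2 %s\n",
              f(x$a2_t1), lab, f(x$c2_t1), f(x$e2_t1)))
  cat(sprintf("  wave 2: a2 %s, %s %s, e2 %s\n",
              f(x$a2_t2), lab, f(x$c2_t2), f(x$e2_t2)))
  cat(sprintf("  cross-wave r %s; bivariate A %s, C %s, E %s\n",
              f(x$r_phenotypic), f(x$biv_a), f(x$biv_c), f(x$biv_e)))
  cat(sprintf("  proportions of r: A %s, C %s, E %s\n",
              f(x$prop_a), f(x$prop_c), f(x$prop_e)))
  cat(sprintf("  rA %s, rC %s, rE %s\n", f(x$rA), f(x$rC), f(x$rE)))
  invisible(x)
}

# closed-form quantity extractor on the raw parameter vector for models
# without sex differences; avoids rebuilding parameter objects inside the
# profiling loop
nosex_quantity_fun <- function(spec, name) {
  mats <- spec_matrices(spec$components)
  idx <- list(X = NULL, Y = NULL, Z = NULL)
  off <- 0
  for (m in c("X", "Y", "Z")) {
    if (m %in% mats$free) {
      idx[[m]] <- off + 1:3
      off <- off + 3
    }
  }
  get3 <- function(par, id) if (is.null(id)) c(0, 0, 0) else par[id]
  function(par) {
    x <- get3(par, idx$X); y <- get3(par, idx$Y); z <- get3(par, idx$Z)
    v1 <- x[1]^2 + y[1]^2 + z[1]^2
    a22 <- x[2]^2 + x[3]^2; c22 <- y[2]^2 + y[3]^2; z22 <- z[2]^2 + z[3]^2
    v2 <- a22 + c22 + z22
    cva <- x[1] * x[2]; cvc <- y[1] * y[2]; cve <- z[1] * z[2]
    tot <- cva + cvc + cve
    switch(name,
           a2_t1 = x[1]^2 / v1, c2_t1 = y[1]^2 / v1, e2_t1 = z[1]^2 / v1,
           a2_t2 = a22 / v2, c2_t2 = c22 / v2, e2_t2 = z22 / v2,
           biv_a = cva / sqrt(v1 * v2), biv_c = cvc / sqrt(v1 * v2),
           biv_e = cve / sqrt(v1 * v2),
           prop_a = cva / tot, prop_c = cvc / tot, prop_e = cve / tot,
           r_phenotypic = tot / sqrt(v1 * v2),
           rA = cva / sqrt(x[1]^2 * a22), rC = cvc / sqrt(y[1]^2 * c22),
           rE = cve / sqrt(z[1]^2 * z22),
           carried_a2 = x[2]^2 / v2, novel_a2 = x[3]^2 / v2,
           carried_c2 = y[2]^2 / v2, novel_c2 = y[3]^2 / v2,
           carried_e2 = z[2]^2 / v2, novel_e2 = z[3]^2 / v2,
           stop("unknown quantity: ", name, call. = FALSE))
  }
}

# scalar quantity extractors for profile CIs
quantity_fun <- function(name, sex = "F") {
  force(name); force(sex)
  function(params) {
    est <- if (inherits(params, "sexlim_params")) {
      standardize(params, sex)
    } else {
      standardize(params)
    }
    est[[name]]
  }
}

#' Stability estimates with profile-likelihood confidence intervals
#'
#' Computes [standardize()] quantities for a fitted model and, optionally,
#' 95% profile-likelihood confidence intervals: each standardized quantity
#' is pinned at a trial value through a quadratic penalty on the -2LL while
#' all other parameters are re-optimized, and the interval endpoint is where
#' the profiled -2LL rises by the chi-square(1) critical value.
#'
#' @param fit a converged [fit_model()] result.
#' @param quantities character vector of quantity names (fields of
#'   [standardize()]); default covers the univariate components, bivariate
#'   components, proportions and aetiological correlations.
#' @param level confidence level.
#' @param sex sex to standardize for in sex-limited models.
#' @return data frame with columns `quantity`, `estimate`, `lower`,
#'   `upper`.
#' @export
stability_estimates <- function(fit,
                                quantities = c("a2_t1", "c2_t1", "e2_t1",
                                               "a2_t2", "c2_t2", "e2_t2",
                                               "biv_a", "biv_c", "biv_e",
                                               "prop_a", "prop_c", "prop_e",
                                               "rA", "rC", "rE"),
                                level = 0.95, sex = "F") {
  stopifnot(inherits(fit, "twin_fit"), isTRUE(fit$convergence) ||
              is.finite(fit$minus2LL))
  est <- if (inherits(fit$params, "sexlim_params")) {
    standardize(fit$params, sex)
  } else {
    standardize(fit$params)
  }
  rows <- lapply(quantities, function(q) {
    val <- est[[q]]
    if (is.null(val) || is.na(val)) {
      return(data.frame(quantity = q, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_))
    }
    qf_par <- if (fit$spec$sex_mode == "none") {
      nosex_quantity_fun(fit$spec, q)
    } else {
      qf <- quantity_fun(q, sex)
      function(p) qf(fit$build(p))
    }
    bounds <- if (grepl("^(a2|c2|e2|prop|biv|carried|novel)", q)) {
      c(if (grepl("^biv|^prop", q)) -1 else 0, 1)
    } else if (q %in% c("rA", "rC", "rE", "r_phenotypic")) {
      c(-1, 1)
    } else {
      c(-Inf, Inf)
    }
    ci <- profile_interval(fit$objective, fit$par, fit$minus2LL, qf_par,
                           level = level, bounds = bounds)
    data.frame(quantity = q, estimate = val,
               lower = ci[["lower"]], upper = ci[["upper"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
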
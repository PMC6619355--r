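# Sufficient statistics per missingness pattern. Rows sharing a pattern
# contribute to the FIML -2LL only through their count, mean and ML scatter
# on the observed coordinates, so the objective cost is independent of n.
pattern_stats <- function(Y) {
  obs <- !is.na(Y)
  any_obs <- rowSums(obs) > 0
  Y <- Y[any_obs, , drop = FALSE]
  obs <- obs[any_obs, , drop = FALSE]
  key <- apply(obs, 1, paste, collapse = "")
  lapply(split(seq_len(nrow(Y)), key), function(rows) {
    idx <- which(obs[rows[1], ])
    X <- Y[rows, idx, drop = FALSE]
    n <- nrow(X)
    xbar <- colMeans(X)
    ctr <- sweep(X, 2, xbar)
    list(idx = as.integer(idx), n = n, xbar = xbar,
         scatter = crossprod(ctr) / n)
  })
}

#' Assemble twin-pair data for model fitting
#'
#' Packages per-pair observation 4-vectors (twin 1 wave 1, twin 1 wave 2,
#' twin 2 wave 1, twin 2 wave 2) by zygosity group and precomputes the
#' per-missingness-pattern sufficient statistics used by the FIML engine.
#'
#' @param cohort preprocessed cohort data frame (see [preprocess_cohort()]),
#'   or any data frame holding the four score columns.
#' @param subscale subscale name; by default the standardized-residual
#'   columns `<subscale>_z_*` are used.
#' @param standardized use standardized residuals (`TRUE`) or raw scores.
#' @return object of class `twin_model_data`: list with `groups` (named
#'   list of n x 4 matrices), `stats`, pair counts and a digest used to
#'   refuse cross-data model comparisons.
#' @export
twin_model_data <- function(cohort, subscale, standardized = TRUE) {
  stub <- if (standardized) paste0(subscale, "_z") else subscale
  cols <- paste0(stub, c("_t1_1", "_t2_1", "_t1_2", "_t2_2"))
  if (!all(cols %in% names(cohort))) {
    stop("columns ", paste(setdiff(cols, names(cohort)), collapse = ", "),
         " not found; run preprocess_cohort() first?", call. = FALSE)
  }
  groups <- list()
  for (g in zygosity_groups()) {
    sel <- cohort$zygosity == g
    if (!any(sel)) next
    Y <- as.matrix(cohort[sel, cols])
    colnames(Y) <- c("t1_1", "t2_1", "t1_2", "t2_2")
    Y <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
    groups[[g]] <- Y
  }
  structure(list(groups = groups,
                 stats = lapply(groups, pattern_stats),
                 n_pairs = vapply(groups, nrow, 1L),
                 subscale = subscale,
                 digest = data_digest(groups)),
            class = "twin_model_data")
}

#' Construct twin model data directly from matrices
#'
#' Lower-level companion to [twin_model_data()] for simulated or external
#' inputs: takes a named list of per-group n x 4 matrices in the order
#' (t1 twin1, t2 twin1, t1 twin2, t2 twin2).
#'
#' @param groups named list of numeric matrices keyed by zygosity group.
#' @return `twin_model_data` object.
#' @export
twin_data_from_matrices <- function(groups) {
  stopifnot(all(names(groups) %in% zygosity_groups()),
            all(vapply(groups, ncol, 1L) == 4))
  groups <- groups[intersect(zygosity_groups(), names(groups))]
  structure(list(groups = groups,
                 stats = lapply(groups, pattern_stats),
                 n_pairs = vapply(groups, nrow, 1L),
                 subscale = "scores",
                 digest = data_digest(groups)),
            class = "twin_model_data")
}

#' @export
print.twin_model_data <- function(x, ...) {
  cat("Twin model data (", x$subscale, "): ",
      sum(x$n_pairs), " pairs\n", sep = "")
  print(x$n_pairs)
  invisible(x)
}

#' FIML -2 log-likelihood of twin-pair data
#'
#' Full-information maximum-likelihood deviance: each pair contributes the
#' multivariate-normal log density on its observed coordinates,
#' `k log(2 pi) + log|Sigma_obs| + (x - mu)' Sigma_obs^-1 (x - mu)`, where
#' `Sigma_obs` and `mu` are the rows/columns of the group's expected
#' covariance and mean present for that pair. Pairs with wave-2 data missing
#' therefore still inform the wave-1 parameters. A non-positive-definite
#' sub-covariance yields a large finite penalized value rather than an
#' error.
#'
#' @param params `cholesky_params` or `sexlim_params` (means taken from the
#'   object).
#' @param data `twin_model_data`.
#' @return scalar -2 log-likelihood.
#' @export
fiml_minus2ll <- function(params, data) {
  stopifnot(inherits(data, "twin_model_data"))
  gs <- names(data$groups)
  mu <- lapply(gs, function(g) expected_pair_means(params, g))
  sigma <- lapply(gs, function(g) expected_pair_covariance(params, g))
  .fiml_m2ll_cpp(unname(data$stats), mu, sigma)
}

# internal fast path: already-built per-group mean/covariance lists
fiml_m2ll_groups <- function(stats, mu, sigma) {
  .fiml_m2ll_cpp(unname(stats), mu, sigma)
}
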
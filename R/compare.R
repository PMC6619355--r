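#' Compare fitted twin models by -2LL, AIC and BIC
#'
#' Tabulates fit indices for a ladder of models fitted to the same data and
#' selects the model with the lowest BIC. A BIC advantage of at least 10
#' over the runner-up is flagged as decisive. Whenever a model with fewer
#' parameters achieves a -2LL more than a small optimizer tolerance below
#' that of a more general model fitted earlier in the ladder, the pair is
#' flagged as an optimization failure (a nested reduction can never truly
#' beat its parent on -2LL).
#'
#' @param fits list of [fit_model()] results (ladder order: most general
#'   first).
#' @param labels optional character vector overriding the model labels.
#' @param tol nesting tolerance on -2LL.
#' @return object of class `model_comparison`: data frame with fit indices,
#'   `delta_BIC` relative to the best model, `best` and `decisive` flags
#'   and a `nesting_violation` flag.
#' @export
compare_models <- function(fits, labels = NULL, tol = 1e-4) {
  stopifnot(is.list(fits), length(fits) >= 2)
  ok <- vapply(fits, function(f) inherits(f, "twin_fit") &&
                 is.finite(f$minus2LL), TRUE)
  if (!all(ok)) stop("all elements must be converged twin_fit objects",
                     call. = FALSE)
  digests <- vapply(fits, function(f) f$digest, "")
  if (length(unique(digests)) != 1) {
    stop("models were fitted to different data; refusing to compare",
         call. = FALSE)
  }
  labels <- labels %||% vapply(fits, function(f) f$label, "")
  tab <- data.frame(
    model = labels,
    minus2LL = vapply(fits, function(f) f$minus2LL, 1),
    n_parameters = vapply(fits, function(f) f$n_parameters, 1),
    AIC = vapply(fits, function(f) f$AIC, 1),
    BIC = vapply(fits, function(f) f$BIC, 1),
    stringsAsFactors = FALSE)
  tab$delta_BIC <- tab$BIC - min(tab$BIC)
  best <- which.min(tab$BIC)
  tab$best <- seq_len(nrow(tab)) == best
  gap <- sort(tab$BIC)
  tab$decisive <- tab$best & (length(gap) < 2 || gap[2] - gap[1] >= 10)
  viol <- logical(nrow(tab))
  for (j in seq_len(nrow(tab))) {
    for (i in seq_len(j - 1)) {
      if (tab$n_parameters[j] < tab$n_parameters[i] &&
          tab$minus2LL[j] < tab$minus2LL[i] - tol) {
        viol[j] <- TRUE
      }
    }
  }
  tab$nesting_violation <- viol
  structure(tab, class = c("model_comparison", "data.frame"))
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$minus2LL <- round(df$minus2LL, digits)
  df$AIC <- round(df$AIC, digits)
  df$BIC <- round(df$BIC, digits)
  df$delta_BIC <- round(df$delta_BIC, digits)
  print(df, row.names = FALSE)
  b <- which(x$best)
  cat("\nSelected (lowest BIC):", x$model[b],
      if (x$decisive[b]) "(decisive, delta BIC >= 10)" else
        "(not decisive, delta BIC < 10)", "\n")
  if (any(x$nesting_violation)) {
    cat("WARNING: nesting violation detected; re-run the flagged fits with",
        "more starts\n")
  }
  invisible(x)
}
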
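#' @keywords internal
"_PACKAGE"

#' @useDynLib twinstab, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cov lm median na.exclude optim pchisq pnorm qchisq
#'   qnorm quantile r2dtable residuals rbinom rnorm runif sd var nlminb
#' @importFrom utils read.csv write.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded internals do not disturb the
#' caller's random stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a stage seed from a master seed
#'
#' Counter-based fan-out so each pipeline stage has its own reproducible
#' stream and can be rerun in isolation. Results stay below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage integer stage counter (>= 0).
#' @return integer seed.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), is.numeric(stage), stage >= 0)
  as.integer((as.double(master) + 7919 * (as.double(stage) + 1)) %% 2147483629)
}

zygosity_groups <- function() c("MZM", "MZF", "DZM", "DZF", "DZOS")

is_lower_tri_2x2 <- function(M) {
  is.matrix(M) && all(dim(M) == c(2L, 2L)) && M[1, 2] == 0
}

# checksum used to refuse model comparisons across different data
data_digest <- function(groups) {
  parts <- vapply(names(groups), function(g) {
    Y <- groups[[g]]
    sum(Y, na.rm = TRUE) + 0.001 * sum(!is.na(Y)) + nrow(Y)
  }, numeric(1))
  paste0(signif(sum(parts), 12), ":", paste(vapply(groups, nrow, 1L),
                                            collapse = ","))
}
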
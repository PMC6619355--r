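#' Bivariate Cholesky path parameters
#'
#' Container for the lower-triangular 2x2 path matrices of a bivariate
#' (two-wave) variance-component decomposition: `X` loads the additive
#' genetic factors (A), `Y` the shared-environmental (C) or dominance (D)
#' factors depending on `components`, and `Z` the nonshared-environmental
#' factors (E). The implied within-person covariance is
#' `XX' + YY' + ZZ'`; rows index waves.
#'
#' @param X,Y,Z lower-triangular 2x2 numeric matrices (upper-right entry
#'   structurally zero). `Y` may be `NULL` for AE/E models.
#' @param components `"ACE"` or `"ADE"`; decides how `Y` is shared between
#'   dizygotic twins (fully, or at 0.25).
#' @param means length-2 numeric, the wave means.
#' @return an object of class `cholesky_params`.
#' @examples
#' p <- cholesky_params(X = chol2x2(0.28, 0.25, 0.32),
#'                      Y = chol2x2(0.19, 0.12, 0.12),
#'                      Z = chol2x2(0.53, 0.23, 0.55))
#' expected_pair_covariance(p, "MZF")
#' @export
cholesky_params <- function(X, Y = NULL, Z, components = c("ACE", "ADE"),
                            means = c(0, 0)) {
  components <- match.arg(components)
  if (is.null(Y)) Y <- matrix(0, 2, 2)
  for (M in list(X, Y, Z)) {
    if (!is_lower_tri_2x2(M)) {
      stop("path matrices must be lower-triangular 2x2", call. = FALSE)
    }
  }
  stopifnot(length(means) == 2, is.numeric(means))
  W <- X %*% t(X) + Y %*% t(Y) + Z %*% t(Z)
  if (min(eigen(W, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("implied within-person covariance XX'+YY'+ZZ' is not positive ",
         "definite", call. = FALSE)
  }
  structure(list(X = X, Y = Y, Z = Z, components = components,
                 means = as.numeric(means)),
            class = "cholesky_params")
}

#' Build a lower-triangular 2x2 path matrix from variance components
#'
#' Convenience constructor: given the wave-1 variance `v1`, the cross-wave
#' covariance `cov12` and the wave-2 variance `v2` contributed by one factor,
#' returns the lower-triangular matrix `M` with `MM'` equal to that 2x2
#' component covariance.
#'
#' @param v1,cov12,v2 component variance/covariance entries; must describe a
#'   positive semi-definite matrix.
#' @return 2x2 lower-triangular matrix.
#' @export
chol2x2 <- function(v1, cov12, v2) {
  stopifnot(v1 >= 0, v2 >= 0)
  if (v1 == 0) {
    if (cov12 != 0) stop("cov12 must be 0 when v1 is 0", call. = FALSE)
    return(matrix(c(0, 0, 0, sqrt(v2)), 2, 2))
  }
  m11 <- sqrt(v1)
  m21 <- cov12 / m11
  resid <- v2 - m21^2
  if (resid < -1e-12) {
    stop("component covariance (", v1, ", ", cov12, ", ", v2,
         ") is not positive semi-definite", call. = FALSE)
  }
  matrix(c(m11, m21, 0, sqrt(max(resid, 0))), 2, 2)
}

#' Sex-limited Cholesky parameters
#'
#' Pairs male and female `cholesky_params` with a genetic correlation `rg`
#' for opposite-sex dizygotic pairs. `rg < 1` encodes qualitative sex
#' limitation (partially different genetic factors operating in the sexes);
#' differing path magnitudes encode quantitative sex limitation.
#'
#' @param male,female `cholesky_params` objects with identical `components`.
#' @param rg DZ opposite-sex genetic correlation scalar in \[0, 1\].
#' @return an object of class `sexlim_params`.
#' @export
sexlim_params <- function(male, female, rg = 1) {
  stopifnot(inherits(male, "cholesky_params"),
            inherits(female, "cholesky_params"),
            identical(male$components, female$components),
            is.numeric(rg), length(rg) == 1, rg >= 0, rg <= 1)
  structure(list(male = male, female = female, rg = rg,
                 components = male$components),
            class = "sexlim_params")
}

# canonical access: paths for a given sex
paths_for_sex <- function(params, sex) {
  if (inherits(params, "sexlim_params")) {
    if (sex == "M") params$male else params$female
  } else {
    params
  }
}

params_rg <- function(params) {
  if (inherits(params, "sexlim_params")) params$rg else 1
}

#' Component covariance matrices implied by path parameters
#'
#' Returns the 2x2 covariance contributed by each factor (`A`, `Y` standing
#' for C or D, `E`) for one sex: `XX'`, `YY'`, `ZZ'`.
#'
#' @param params `cholesky_params` or `sexlim_params`.
#' @param sex `"M"` or `"F"` (ignored for unsexed parameters).
#' @return named list of 2x2 matrices `A`, `Y`, `E` plus `components`.
#' @export
component_covs <- function(params, sex = "F") {
  p <- paths_for_sex(params, sex)
  list(A = p$X %*% t(p$X), Y = p$Y %*% t(p$Y), E = p$Z %*% t(p$Z),
       components = p$components)
}

# sharing coefficients of the A and Y factors between co-twins
sharing_coefs <- function(zygosity, components, rg = 1) {
  kA <- switch(zygosity,
               MZM = 1, MZF = 1, DZM = 0.5, DZF = 0.5, DZOS = 0.5 * rg)
  kY <- if (components == "ACE") {
    1
  } else { # dominance: identical for MZ, shared 1/4 for any DZ
    switch(zygosity, MZM = 1, MZF = 1, DZM = 0.25, DZF = 0.25, DZOS = 0.25)
  }
  c(A = kA, Y = kY)
}

pair_sexes <- function(zygosity) {
  switch(zygosity,
         MZM = c("M", "M"), MZF = c("F", "F"),
         DZM = c("M", "M"), DZF = c("F", "F"),
         DZOS = c("M", "F"))
}

#' Expected 4x4 covariance of a twin pair
#'
#' The model-implied covariance of the observation vector
#' (twin1 wave1, twin1 wave2, twin2 wave1, twin2 wave2) for one zygosity
#' group: block matrix `[[W1, B], [B', W2]]` with within-person blocks
#' `W = XX' + YY' + ZZ'` (per that twin's sex) and cross-twin block
#' `B = kA * X1 X2' + kY * Y1 Y2'`, where the sharing coefficients are
#' kA = 1 (MZ), 0.5 (same-sex DZ) or `0.5 * rg` (opposite-sex DZ), and
#' kY = 1 for C or 1 (MZ) / 0.25 (DZ) for D. E factors are never shared.
#'
#' @param params `cholesky_params` or `sexlim_params`.
#' @param zygosity one of `"MZM"`, `"MZF"`, `"DZM"`, `"DZF"`, `"DZOS"`.
#' @return 4x4 covariance matrix.
#' @export
expected_pair_covariance <- function(params, zygosity) {
  zygosity <- match.arg(zygosity, zygosity_groups())
  sexes <- pair_sexes(zygosity)
  p1 <- paths_for_sex(params, sexes[1])
  p2 <- paths_for_sex(params, sexes[2])
  k <- sharing_coefs(zygosity, p1$components, params_rg(params))
  W1 <- p1$X %*% t(p1$X) + p1$Y %*% t(p1$Y) + p1$Z %*% t(p1$Z)
  W2 <- p2$X %*% t(p2$X) + p2$Y %*% t(p2$Y) + p2$Z %*% t(p2$Z)
  B <- k["A"] * p1$X %*% t(p2$X) + k["Y"] * p1$Y %*% t(p2$Y)
  out <- rbind(cbind(W1, B), cbind(t(B), W2))
  colnames(out) <- rownames(out) <- c("t1_1", "t2_1", "t1_2", "t2_2")
  out
}

#' Expected mean vector of a twin pair
#' @param params `cholesky_params` or `sexlim_params`.
#' @param zygosity zygosity group label.
#' @return length-4 mean vector in the order (t1 twin1, t2 twin1, t1 twin2,
#'   t2 twin2).
#' @export
expected_pair_means <- function(params, zygosity) {
  zygosity <- match.arg(zygosity, zygosity_groups())
  sexes <- pair_sexes(zygosity)
  c(paths_for_sex(params, sexes[1])$means,
    paths_for_sex(params, sexes[2])$means)
}

#' @export
print.cholesky_params <- function(x, ...) {
  cat("Bivariate Cholesky paths (", x$components, ")\n", sep = "")
  cc <- component_covs(x)
  w <- cc$A + cc$Y + cc$E
  lab <- if (x$components == "ACE") "C" else "D"
  cat(sprintf("  wave-1 variance %.3f  (A %.3f, %s %.3f, E %.3f)\n",
              w[1, 1], cc$A[1, 1], lab, cc$Y[1, 1], cc$E[1, 1]))
  cat(sprintf("  wave-2 variance %.3f  (A %.3f, %s %.3f, E %.3f)\n",
              w[2, 2], cc$A[2, 2], lab, cc$Y[2, 2], cc$E[2, 2]))
  cat(sprintf("  cross-wave cov  %.3f  (A %.3f, %s %.3f, E %.3f)\n",
              w[1, 2], cc$A[1, 2], lab, cc$Y[1, 2], cc$E[1, 2]))
  invisible(x)
}

#' @export
print.sexlim_params <- function(x, ...) {
  cat("Sex-limited bivariate Cholesky paths (rg =", format(x$rg), ")\n")
  cat("-- male --\n"); print(x$male)
  cat("-- female --\n"); print(x$female)
  invisible(x)
}
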
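#' Adjusted (sample-size-corrected) skewness
#'
#' The adjusted Fisher-Pearson standardized third-moment coefficient,
#' `n / ((n-1)(n-2)) * sum(((x - mean) / s)^3)` with `s` the sample SD --
#' the convention used by mainstream commercial statistics software, so the
#' transform trigger is reproducible against it.
#'
#' @param values numeric vector; missing values are dropped.
#' @return skewness coefficient.
#' @export
skewness <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3) stop("skewness needs at least 3 non-missing values",
                  call. = FALSE)
  s <- sd(x)
  if (s < 1e-12) stop("skewness undefined for (near-)constant input",
                      call. = FALSE)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

#' Conditionally log-transform a positively skewed score
#'
#' Applies `log10(x + 1)` when the absolute adjusted skewness exceeds
#' `bound`, mirroring the common practice of log-transforming questionnaire
#' subscales until all skew statistics lie within \[-1, 1\]. The +1 offset
#' accommodates zero scores (`log10(0 + 1) = 0`); the base is immaterial for
#' downstream standardized fits.
#'
#' @param values non-negative numeric vector (missing allowed).
#' @param bound skewness threshold triggering the transform.
#' @return list with `values` (possibly transformed) and `applied` flag.
#' @export
conditional_log_transform <- function(values, bound = 1.0) {
  if (any(values < 0, na.rm = TRUE)) {
    stop("conditional_log_transform requires non-negative values",
         call. = FALSE)
  }
  sk <- skewness(values)
  if (abs(sk) > bound) {
    list(values = log10(values + 1), applied = TRUE)
  } else {
    list(values = values, applied = FALSE)
  }
}

#' Regress scores on age and sex and standardize the residuals
#'
#' Ordinary least squares of `values` on intercept, age and sex (pooled over
#' twins and sexes, sex entering as a covariate); residuals are divided by
#' their sample SD. Missing values propagate as missing.
#'
#' @param values numeric vector.
#' @param age numeric covariate, non-missing wherever `values` is present.
#' @param sex factor or character covariate (e.g. "M"/"F").
#' @return list with `residuals` (standardized, same length as input),
#'   `coefficients` of the regression, and `residual_sd`.
#' @export
residualize_standardize <- function(values, age, sex) {
  ok <- !is.na(values)
  if (any(is.na(age[ok])) || any(is.na(sex[ok]))) {
    stop("age and sex must be non-missing wherever values are non-missing",
         call. = FALSE)
  }
  sex <- factor(sex)
  df <- data.frame(values = values, age = age, sex = sex)
  if (sum(ok) < 3 + nlevels(droplevels(sex[ok]))) {
    stop("too few observations to fit the age/sex regression",
         call. = FALSE)
  }
  fit <- lm(values ~ age + sex, data = df, na.action = na.exclude)
  r <- residuals(fit)
  s <- sd(r, na.rm = TRUE)
  if (!is.finite(s) || s < 1e-10) {
    stop("residuals have (near-)zero variance; cannot standardize",
         call. = FALSE)
  }
  r <- (r - mean(r, na.rm = TRUE)) / sd(r, na.rm = TRUE)
  list(residuals = as.numeric(r), coefficients = coef(fit), residual_sd = s)
}

#' Preprocess a cohort into analysis-ready standardized residuals
#'
#' For each subscale and wave independently: pool the two twins into an
#' individual-level vector, apply [conditional_log_transform()] with the
#' given skewness bound, regress on age and sex, and standardize the
#' residuals. Adds columns `<subscale>_z_t<wave>_<twin>` to the cohort.
#' Untransformed scores are kept untouched for descriptive and
#' frequency-based analyses.
#'
#' @param cohort cohort data frame (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param subscales character vector of subscale names; defaults to the
#'   cohort's `subscales` attribute.
#' @param skew_bound skewness bound for the conditional log transform.
#' @return list with `cohort` (augmented) and `report`, a data frame with
#'   one row per subscale x wave: skewness before/after, whether the
#'   transform was applied, regression coefficients and the residual SD
#'   used for standardization.
#' @export
preprocess_cohort <- function(cohort, subscales = NULL, skew_bound = 1.0) {
  subscales <- subscales %||% attr(cohort, "subscales")
  if (is.null(subscales)) stop("subscales not specified", call. = FALSE)
  rows <- list()
  for (s in subscales) {
    for (w in 1:2) {
      c1 <- paste0(s, "_t", w, "_1")
      c2 <- paste0(s, "_t", w, "_2")
      vals <- c(cohort[[c1]], cohort[[c2]])
      age <- rep(cohort[[paste0("age_t", w)]], 2)
      sex <- c(cohort$sex_1, cohort$sex_2)
      sk_before <- skewness(vals)
      tr <- conditional_log_transform(vals, bound = skew_bound)
      sk_after <- skewness(tr$values)
      rs <- residualize_standardize(tr$values, age, sex)
      n <- nrow(cohort)
      cohort[[paste0(s, "_z_t", w, "_1")]] <- rs$residuals[seq_len(n)]
      cohort[[paste0(s, "_z_t", w, "_2")]] <- rs$residuals[n + seq_len(n)]
      rows[[paste0(s, "_t", w)]] <- data.frame(
        subscale = s, wave = w,
        skew_before = sk_before, transform_applied = tr$applied,
        skew_after = sk_after,
        beta_intercept = unname(rs$coefficients[1]),
        beta_age = unname(rs$coefficients["age"]),
        beta_sex = unname(rs$coefficients[grep("^sex", names(rs$coefficients))][1]),
        residual_sd = rs$residual_sd,
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(cohort, "subscales") <- subscales
  list(cohort = cohort, report = report)
}

#' Select one twin at random per pair with both-wave data
#'
#' Restricts to pairs retained at wave 2 and picks twin 1 or twin 2 with
#' equal probability, deterministically given the seed. Used for the
#' individual-level phenotypic analyses (grouping, contingency tables,
#' contrasts), which require independent observations.
#'
#' @param cohort cohort data frame.
#' @param seed integer seed.
#' @param subscales subscales to carry over; defaults to the cohort
#'   attribute.
#' @return individual-level data frame with one row per retained pair:
#'   identifiers, zygosity, sex, ages, per-subscale `<subscale>_t1` /
#'   `<subscale>_t2` raw scores, per-subscale distress, and co-occurring
#'   scores.
#' @export
select_one_twin_per_pair <- function(cohort, seed, subscales = NULL) {
  subscales <- subscales %||% attr(cohort, "subscales")
  has_t2 <- !is.na(cohort[[paste0(subscales[1], "_t2_1")]]) |
    !is.na(cohort[[paste0(subscales[1], "_t2_2")]])
  kept <- cohort[has_t2, , drop = FALSE]
  pick <- with_seed(seed, rbinom(nrow(kept), 1, 0.5) + 1L)
  out <- data.frame(family_id = kept$family_id, twin = pick,
                    zygosity = kept$zygosity,
                    sex = ifelse(pick == 1, kept$sex_1, kept$sex_2),
                    age_t1 = kept$age_t1, age_t2 = kept$age_t2,
                    stringsAsFactors = FALSE)
  pull <- function(stub) {
    ifelse(pick == 1, kept[[paste0(stub, "_1")]], kept[[paste0(stub, "_2")]])
  }
  for (s in subscales) {
    out[[paste0(s, "_t1")]] <- pull(paste0(s, "_t1"))
    out[[paste0(s, "_t2")]] <- pull(paste0(s, "_t2"))
    dcol <- paste0(s, "_distress_1")
    if (dcol %in% names(kept)) {
      out[[paste0(s, "_distress")]] <- pull(paste0(s, "_distress"))
    }
  }
  copsych <- unique(sub("_[12]$", "",
                        grep("^(smfq|sdq_)", names(kept), value = TRUE)))
  for (cp in copsych) out[[cp]] <- pull(cp)
  out
}
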
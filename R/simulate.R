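#' Default subscale ground truths for the synthetic cohort
#'
#' Named list of per-subscale generating parameters emulating a two-wave
#' adolescent psychotic-experiences-and-negative-symptoms cohort: four
#' self-reported psychotic-experience subscales (paranoia, hallucinations,
#' cognitive disorganization, grandiosity), self-reported anhedonia and
#' parent-rated negative symptoms. Standardized variance components and
#' cross-wave covariance components are typical published magnitudes for
#' such scales: heritability 0.22-0.47 per wave, shared environment up to
#' 0.38 (absent for anhedonia, which is AE), the balance nonshared
#' environment, and cross-wave phenotypic correlations around 0.6.
#' Subscales flagged `skewed` are given a positively skewed raw-score
#' distribution by the exponential warp; `distress` marks subscales that
#' carry a wave-1 distress item.
#'
#' @return named list; each element has fields `params` (a
#'   [cholesky_params()] truth), `skewed` and `distress`.
#' @export
default_subscale_truths <- function() {
  tr <- function(a1, c1, e1, a2, c2, e2, bA, bC, bE,
                 components = "ACE", skewed = TRUE, distress = TRUE) {
    list(params = cholesky_params(X = chol2x2(a1, bA, a2),
                                  Y = chol2x2(c1, bC, c2),
                                  Z = chol2x2(e1, bE, e2),
                                  components = components),
         skewed = skewed, distress = distress)
  }
  list(
    paranoia       = tr(0.28, 0.19, 0.53, 0.32, 0.12, 0.55,
                        0.25, 0.12, 0.23),
    hallucinations = tr(0.22, 0.19, 0.59, 0.33, 0.16, 0.51,
                        0.22, 0.14, 0.22),
    cogdis         = tr(0.27, 0.15, 0.58, 0.38, 0.06, 0.56,
                        0.30, 0.09, 0.26, skewed = FALSE),
    grandiosity    = tr(0.26, 0.18, 0.57, 0.26, 0.19, 0.56,
                        0.25, 0.13, 0.19),
    anhedonia      = tr(0.47, 0.00, 0.53, 0.46, 0.00, 0.54,
                        0.37, 0.00, 0.22, skewed = FALSE, distress = FALSE),
    prns           = tr(0.46, 0.36, 0.18, 0.45, 0.38, 0.17,
                        0.34, 0.21, 0.08, distress = FALSE)
  )
}

#' Configuration for the synthetic twin-cohort generator
#'
#' Defaults describe the emulated study: 4,870 pairs at wave 1 across five
#' zygosity groups (~36% monozygotic, ~55% female), mean age 16.32 (SD 0.68)
#' years at wave 1 with a 0.75-year gap to wave 2, and pair-level wave-2
#' retention of 0.30 (~1,460 pairs with data at both waves).
#'
#' @param n_pairs named integer vector of pair counts per zygosity group
#'   (`MZM`, `MZF`, `DZM`, `DZF`, `DZOS`).
#' @param subscales named list of per-subscale truths as produced by
#'   [default_subscale_truths()].
#' @param rg_opposite_sex genetic correlation applied to opposite-sex DZ
#'   pairs, in \[0, 1\]; 1 means the same genetic factors operate in both
#'   sexes. Ignored for subscales whose truth is a [sexlim_params()] (those
#'   carry their own `rg`).
#' @param mean_age_wave1,age_sd,wave_gap age distribution, in years.
#' @param wave2_retention proportion of pairs retained at wave 2, in (0, 1].
#' @param skew_transform `"exponential"` maps latent scores onto a bounded
#'   non-negative questionnaire-like scale (positively skewed for subscales
#'   flagged `skewed`, linearly otherwise); `"none"` leaves scores on the
#'   latent standardized scale.
#' @param skew_lambda exponential warp rate; larger values give stronger
#'   positive skew. Default 0.8 yields raw-score skewness well above 1.
#' @param score_max upper bound of the warped score range.
#' @param distress_thresholds two strictly increasing cutpoints on the
#'   (latent severity + noise) scale separating the three ordinal distress
#'   levels.
#' @param distress_noise_sd SD of the noise added before thresholding.
#' @param copsych_loadings named regression weights of the co-occurring
#'   psychopathology scores (depression traits `smfq`, and the emotional /
#'   conduct / hyperactivity / peer problem scales) on the standardized
#'   wave-1 latent phenotype.
#' @param seed integer seed; the generator is deterministic given the
#'   configuration and seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_pairs = c(MZM = 750, MZF = 1000, DZM = 700, DZF = 950, DZOS = 1470),
    subscales = default_subscale_truths(),
    rg_opposite_sex = 1,
    mean_age_wave1 = 16.32, age_sd = 0.68, wave_gap = 0.75,
    wave2_retention = 0.30,
    skew_transform = c("exponential", "none"),
    skew_lambda = 0.8,
    score_max = 50,
    distress_thresholds = c(0.9, 1.9),
    distress_noise_sd = 1,
    copsych_loadings = c(smfq = 0.6, sdq_emo = 0.6, sdq_con = 0.3,
                         sdq_hyp = 0.3, sdq_peer = 0.35),
    seed = 1) {
  skew_transform <- match.arg(skew_transform)
  if (!all(zygosity_groups() %in% names(n_pairs))) {
    stop("n_pairs must name all five zygosity groups", call. = FALSE)
  }
  n_pairs <- n_pairs[zygosity_groups()]
  if (any(n_pairs < 0) || any(n_pairs != round(n_pairs))) {
    stop("pair counts must be non-negative integers", call. = FALSE)
  }
  if (!(wave2_retention > 0 && wave2_retention <= 1)) {
    stop("wave2_retention must be in (0, 1]", call. = FALSE)
  }
  if (!(rg_opposite_sex >= 0 && rg_opposite_sex <= 1)) {
    stop("rg_opposite_sex must be in [0, 1]", call. = FALSE)
  }
  if (length(distress_thresholds) != 2 ||
      diff(distress_thresholds) <= 0) {
    stop("distress_thresholds must be two strictly increasing cutpoints",
         call. = FALSE)
  }
  if (is.null(names(subscales)) || any(names(subscales) == "")) {
    stop("subscales must be a named list", call. = FALSE)
  }
  for (s in subscales) {
    if (!inherits(s$params, c("cholesky_params", "sexlim_params"))) {
      stop("each subscale needs a cholesky_params or sexlim_params truth",
           call. = FALSE)
    }
  }
  structure(list(n_pairs = n_pairs, subscales = subscales,
                 rg_opposite_sex = rg_opposite_sex,
                 mean_age_wave1 = mean_age_wave1, age_sd = age_sd,
                 wave_gap = wave_gap, wave2_retention = wave2_retention,
                 skew_transform = skew_transform, skew_lambda = skew_lambda,
                 score_max = score_max,
                 distress_thresholds = distress_thresholds,
                 distress_noise_sd = distress_noise_sd,
                 copsych_loadings = copsych_loadings,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

distress_levels <- function() c("not", "a bit", "quite/very")

# correlated bivariate standard-normal factor draws for a twin pair:
# componentwise cross-twin correlation k
draw_shared_factors <- function(n, k) {
  common <- matrix(rnorm(n * 2), n, 2)
  if (k >= 1) {
    list(common, common)
  } else if (k <= 0) {
    list(matrix(rnorm(n * 2), n, 2), matrix(rnorm(n * 2), n, 2))
  } else {
    u1 <- matrix(rnorm(n * 2), n, 2)
    u2 <- matrix(rnorm(n * 2), n, 2)
    list(sqrt(k) * common + sqrt(1 - k) * u1,
         sqrt(k) * common + sqrt(1 - k) * u2)
  }
}

#' Simulate a twin cohort on the latent scale
#'
#' Draws per-pair bivariate A, C (or D) and E factor vectors with the
#' sharing structure of the classical twin design -- A correlated 1 between
#' monozygotic co-twins, 0.5 between same-sex dizygotic co-twins and
#' `0.5 * rg` for opposite-sex pairs; C shared completely (D shared 1 / 0.25);
#' E independent -- and forms each twin's two-wave phenotype through the
#' subscale's Cholesky truth, `score = X A + Y C + Z E + means`. In this
#' no-transform state each zygosity group's population cross-twin covariance
#' block equals `kA XX' + kY YY'`.
#'
#' Wave-1 distress categories are generated by thresholding the twin's
#' wave-1 latent severity plus ordinal noise, and co-occurring
#' psychopathology scores regress on the standardized mean wave-1 latent
#' phenotype.
#'
#' @param config a [simulation_config()].
#' @return data frame, one row per pair, with identifier, zygosity, sexes,
#'   ages, per-subscale scores `<subscale>_t<wave>_<twin>` on the latent
#'   scale, per-subscale distress labels, and co-occurring scores.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(stage_seed(config$seed, 0), {
    out <- vector("list", length(zygosity_groups()))
    names(out) <- zygosity_groups()
    fam0 <- 0L
    for (g in zygosity_groups()) {
      n <- config$n_pairs[[g]]
      if (n == 0) next
      sexes <- pair_sexes(g)
      age1 <- rnorm(n, config$mean_age_wave1, config$age_sd)
      df <- data.frame(family_id = fam0 + seq_len(n), zygosity = g,
                       sex_1 = sexes[1], sex_2 = sexes[2],
                       age_t1 = round(age1, 2),
                       age_t2 = round(age1 + config$wave_gap, 2),
                       stringsAsFactors = FALSE)
      fam0 <- fam0 + n
      lat1 <- 0  # running sum of wave-1 latents for copsych outcomes
      lat2 <- 0
      for (s in names(config$subscales)) {
        sub <- config$subscales[[s]]
        rg <- if (inherits(sub$params, "sexlim_params")) {
          sub$params$rg
        } else {
          config$rg_opposite_sex
        }
        p1 <- paths_for_sex(sub$params, sexes[1])
        p2 <- paths_for_sex(sub$params, sexes[2])
        k <- sharing_coefs(g, p1$components, rg)
        A <- draw_shared_factors(n, k[["A"]])
        C <- draw_shared_factors(n, k[["Y"]])
        E1 <- matrix(rnorm(n * 2), n, 2)
        E2 <- matrix(rnorm(n * 2), n, 2)
        s1 <- A[[1]] %*% t(p1$X) + C[[1]] %*% t(p1$Y) + E1 %*% t(p1$Z)
        s2 <- A[[2]] %*% t(p2$X) + C[[2]] %*% t(p2$Y) + E2 %*% t(p2$Z)
        s1 <- sweep(s1, 2, p1$means, "+")
        s2 <- sweep(s2, 2, p2$means, "+")
        df[[paste0(s, "_t1_1")]] <- s1[, 1]
        df[[paste0(s, "_t2_1")]] <- s1[, 2]
        df[[paste0(s, "_t1_2")]] <- s2[, 1]
        df[[paste0(s, "_t2_2")]] <- s2[, 2]
        lat1 <- lat1 + s1[, 1]
        lat2 <- lat2 + s2[, 1]
        if (isTRUE(sub$distress)) {
          for (tw in 1:2) {
            sev <- if (tw == 1) s1[, 1] else s2[, 1]
            noisy <- sev + rnorm(n, 0, config$distress_noise_sd)
            lev <- cut(noisy, c(-Inf, config$distress_thresholds, Inf),
                       labels = distress_levels())
            df[[paste0(s, "_distress_", tw)]] <- as.character(lev)
          }
        }
      }
      nsub <- length(config$subscales)
      z1 <- lat1 / sqrt(nsub)
      z2 <- lat2 / sqrt(nsub)
      for (cp in names(config$copsych_loadings)) {
        b <- config$copsych_loadings[[cp]]
        df[[paste0(cp, "_1")]] <- pmax(0, 1 + b * z1 + rnorm(n))
        df[[paste0(cp, "_2")]] <- pmax(0, 1 + b * z2 + rnorm(n))
      }
      out[[g]] <- df
    }
    cohort <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    rownames(cohort) <- NULL
    attr(cohort, "subscales") <- names(config$subscales)
    cohort
  })
}

# monotone warps from the latent scale onto a bounded score scale
warp_exponential <- function(s, lambda, score_max) {
  s <- pmin(pmax(s, -4), 4)
  (exp(lambda * s) - exp(-4 * lambda)) /
    (exp(4 * lambda) - exp(-4 * lambda)) * score_max
}

warp_linear <- function(s, score_max) {
  s <- pmin(pmax(s, -4), 4)
  (s + 4) / 8 * score_max
}

#' Apply the raw-score warp and wave-2 missingness
#'
#' Maps latent scores onto a bounded non-negative questionnaire-like scale
#' (a monotone exponential warp for subscales flagged skewed, producing the
#' strong positive skew typical of such scores; a linear map otherwise) and
#' deletes wave-2 data completely at random at the pair level with
#' probability `1 - wave2_retention`. With `skew_transform = "none"` scores
#' are left on the latent scale and only missingness is applied.
#'
#' @param cohort data frame from [simulate_cohort()].
#' @param config the same [simulation_config()].
#' @return the cohort with warped scores and wave-2 missingness.
#' @export
apply_skew_and_missingness <- function(cohort, config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(stage_seed(config$seed, 1), {
    for (s in names(config$subscales)) {
      sub <- config$subscales[[s]]
      for (col in paste0(s, c("_t1_1", "_t1_2", "_t2_1", "_t2_2"))) {
        if (config$skew_transform == "none") next
        cohort[[col]] <- if (isTRUE(sub$skewed)) {
          warp_exponential(cohort[[col]], config$skew_lambda,
                           config$score_max)
        } else {
          warp_linear(cohort[[col]], config$score_max)
        }
      }
    }
    if (config$wave2_retention < 1) {
      keep <- runif(nrow(cohort)) < config$wave2_retention
      t2_cols <- c(grep("_t2_[12]$", names(cohort), value = TRUE), "age_t2")
      cohort[!keep, t2_cols] <- NA
    }
    cohort
  })
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: [simulate_cohort()] followed by
#' [apply_skew_and_missingness()].
#'
#' @inheritParams simulate_cohort
#' @return cohort data frame.
#' @export
generate_cohort <- function(config) {
  apply_skew_and_missingness(simulate_cohort(config), config)
}

serialize_params <- function(p) {
  if (inherits(p, "sexlim_params")) {
    list(type = "sexlim", rg = p$rg,
         male = serialize_params(p$male), female = serialize_params(p$female))
  } else {
    list(type = "cholesky", components = p$components, means = p$means,
         X = p$X, Y = p$Y, Z = p$Z)
  }
}

#' Write a cohort to CSV with a ground-truth JSON sidecar
#'
#' @param cohort cohort data frame.
#' @param path CSV output path; the sidecar is written to
#'   `paste0(path, ".json")` when `config` is supplied.
#' @param config optional [simulation_config()] recording ground truth and
#'   seed.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config = NULL) {
  write.csv(cohort, path, row.names = FALSE)
  if (!is.null(config)) {
    side <- list(
      seed = config$seed,
      n_pairs = as.list(config$n_pairs),
      wave2_retention = config$wave2_retention,
      rg_opposite_sex = config$rg_opposite_sex,
      skew_transform = config$skew_transform,
      skew_lambda = config$skew_lambda,
      score_max = config$score_max,
      distress_thresholds = config$distress_thresholds,
      copsych_loadings = as.list(config$copsych_loadings),
      subscales = lapply(config$subscales, function(s) {
        list(skewed = isTRUE(s$skewed), distress = isTRUE(s$distress),
             truth = serialize_params(s$params))
      }))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#' @param path CSV path.
#' @return cohort data frame.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sub <- unique(sub("_t1_1$", "", grep("_t1_1$", names(df), value = TRUE)))
  attr(df, "subscales") <- sub
  df
}
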
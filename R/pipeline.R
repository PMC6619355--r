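#' Fit the standard model ladder for one subscale
#'
#' Runs the conventional sequence: ACE (and optionally ADE) with full
#' qualitative + quantitative sex limitation; the family with the lower
#' -2LL is carried down the ladder of quantitative-only sex differences,
#' equal aetiological correlations, and no sex differences; finally the
#' component reductions (AE/CE/E from ACE; AE/E from ADE). Models are
#' compared by BIC with the delta >= 10 decisiveness rule.
#'
#' @param data a [twin_model_data()].
#' @param families component families to consider at the top of the ladder
#'   (`"ACE"`, or `c("ACE", "ADE")`).
#' @param sex_ladder fit the sex-limitation ladder; if `FALSE` only
#'   no-sex-difference models are fitted.
#' @param n_starts,seed optimizer starts per model and jitter seed.
#' @param min_pairs minimum pairs per group (passed to [model_spec()]).
#' @return list with `fits` (named list of `twin_fit`), `comparison` (a
#'   [compare_models()] table) and `best` (the selected fit).
#' @export
fit_model_ladder <- function(data, families = "ACE", sex_ladder = TRUE,
                             n_starts = 8, seed = 1, min_pairs = 20) {
  fits <- list()
  fit1 <- function(components, sex_mode, stage) {
    fit_model(data,
              model_spec(components, sex_mode, min_pairs = min_pairs),
              n_starts = n_starts, seed = stage_seed(seed, stage))
  }
  family <- families[1]
  if (sex_ladder) {
    tops <- list()
    for (i in seq_along(families)) {
      tops[[families[i]]] <- fit1(families[i], "full", i)
    }
    family <- names(tops)[which.min(vapply(tops, function(f)
      f$minus2LL, 1))]
    fits[[paste0(family, "_full_sex")]] <- tops[[family]]
    fits[[paste0(family, "_quantitative_sex")]] <-
      fit1(family, "quantitative", 10)
    fits[[paste0(family, "_equal_correlations")]] <-
      fit1(family, "common_correlations", 11)
  }
  fits[[paste0(family, "_no_sex_diff")]] <- fit1(family, "none", 12)
  reductions <- if (family == "ACE") c("AE", "CE", "E") else c("AE", "E")
  for (i in seq_along(reductions)) {
    fits[[paste0(reductions[i], "_no_sex_diff")]] <-
      fit1(reductions[i], "none", 20 + i)
  }
  keep <- vapply(fits, function(f) is.finite(f$minus2LL), TRUE)
  comparison <- compare_models(fits[keep], labels = names(fits)[keep])
  best <- fits[keep][[which(comparison$best)]]
  list(fits = fits, comparison = comparison, best = best)
}

#' Pipeline configuration
#'
#' @param simulation a [simulation_config()] describing the synthetic
#'   cohort, or `NULL` when `input_csv` is given.
#' @param input_csv optional path to an existing cohort CSV (see
#'   [read_cohort()]); overrides `simulation`.
#' @param subscales subscales to analyse; default: all available.
#' @param skew_bound skewness bound for the conditional log transform.
#' @param top_fraction nominal top fraction for persistence groups.
#' @param mc_tables Monte-Carlo replicates for the Fisher exact tests.
#' @param families model families for the ladder (`"ACE"` or
#'   `c("ACE", "ADE")`).
#' @param sex_ladder fit the sex-limitation ladder.
#' @param n_starts optimizer starts per model.
#' @param ci compute 95% profile-likelihood CIs for the best model's
#'   stability estimates (slower).
#' @param min_pairs minimum pairs per zygosity group.
#' @param seed master seed; all stage seeds are derived from it by a
#'   counter scheme, so stages are individually reproducible.
#' @param output_dir directory for all outputs.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            input_csv = NULL, subscales = NULL,
                            skew_bound = 1.0, top_fraction = 0.10,
                            mc_tables = 10000, families = "ACE",
                            sex_ladder = TRUE, n_starts = 4, ci = FALSE,
                            min_pairs = 20, seed = 1,
                            output_dir = tempfile("twinstab_run_")) {
  if (is.null(input_csv) && is.null(simulation)) {
    stop("either a simulation config or an input CSV is required",
         call. = FALSE)
  }
  structure(list(simulation = simulation, input_csv = input_csv,
                 subscales = subscales, skew_bound = skew_bound,
                 top_fraction = top_fraction, mc_tables = mc_tables,
                 families = families, sex_ladder = sex_ladder,
                 n_starts = n_starts, ci = ci, min_pairs = min_pairs,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

write_table <- function(df, dir, name, manifest) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  manifest$files <- c(manifest$files, name)
  manifest
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a cohort, preprocess it into standardized residuals,
#' estimate phenotypic and twin correlations from constrained saturated
#' models, fit the bivariate Cholesky model ladder per subscale, and run
#' the persistence-subgroup analyses. All outputs are written to
#' `config$output_dir` as CSV files plus a JSON manifest recording seeds,
#' versions and timings; rerunning with the same configuration and seed
#' reproduces the numerical outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the report bundle: a list with the cohort, reports,
#'   per-subscale results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = as.character(packageVersion("twinstab")),
                   r_version = R.version.string,
                   master_seed = config$seed, files = character(0),
                   started = format(Sys.time()))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <- name
      manifest$error <- conditionMessage(e)
      jsonlite::write_json(manifest,
                           file.path(config$output_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- simulate / load ------------------------------------------------------
  cohort <- stage("simulate", {
    if (!is.null(config$input_csv)) {
      read_cohort(config$input_csv)
    } else {
      ch <- generate_cohort(config$simulation)
      write_cohort(ch, file.path(config$output_dir, "cohort.csv"),
                   config$simulation)
      manifest$files <- c(manifest$files, "cohort.csv", "cohort.csv.json")
      ch
    }
  })
  subscales <- config$subscales %||% attr(cohort, "subscales")

  # -- preprocess -----------------------------------------------------------
  prep <- stage("preprocess", {
    preprocess_cohort(cohort, subscales, skew_bound = config$skew_bound)
  })
  manifest <- write_table(prep$report, config$output_dir,
                          "preprocess_report.csv", manifest)
  jsonlite::write_json(prep$report,
                       file.path(config$output_dir,
                                 "preprocess_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$files <- c(manifest$files, "preprocess_report.json")

  # -- correlations (constrained saturated) ---------------------------------
  correlations <- stage("correlations", {
    out <- list()
    for (s in subscales) {
      md <- twin_model_data(prep$cohort, s)
      sat <- fit_constrained_saturated(md)
      df <- sat$correlations
      df$subscale <- s
      out[[s]] <- df
    }
    do.call(rbind, out)
  })
  manifest <- write_table(correlations, config$output_dir,
                          "twin_correlations.csv", manifest)

  # -- model ladder ---------------------------------------------------------
  models <- stage("fit", {
    out <- list()
    for (i in seq_along(subscales)) {
      s <- subscales[i]
      md <- twin_model_data(prep$cohort, s)
      out[[s]] <- fit_model_ladder(
        md, families = config$families, sex_ladder = config$sex_ladder,
        n_starts = config$n_starts, min_pairs = config$min_pairs,
        seed = stage_seed(config$seed, 100 + i))
    }
    out
  })
  comparison <- do.call(rbind, lapply(names(models), function(s) {
    df <- as.data.frame(models[[s]]$comparison)
    cbind(subscale = s, df)
  }))
  manifest <- write_table(comparison, config$output_dir,
                          "model_comparison.csv", manifest)

  estimates <- do.call(rbind, lapply(names(models), function(s) {
    best <- models[[s]]$best
    if (config$ci) {
      df <- stability_estimates(best)
    } else {
      est <- standardize(best$params)
      if (!inherits(est, "stability_estimates")) est <- est$female
      keep <- setdiff(names(unclass(est)), "components")
      vals <- unlist(unclass(est)[keep])
      df <- data.frame(quantity = names(vals), estimate = unname(vals),
                       lower = NA_real_, upper = NA_real_)
    }
    cbind(subscale = s, model = best$label, df)
  }))
  manifest <- write_table(estimates, config$output_dir,
                          "stability_estimates.csv", manifest)
  decomp <- estimates[grepl("^(carried|novel)_", estimates$quantity), ]
  manifest <- write_table(decomp, config$output_dir,
                          "stability_decomposition.csv", manifest)
  aetcor <- estimates[estimates$quantity %in% c("rA", "rC", "rE"), ]
  manifest <- write_table(aetcor, config$output_dir,
                          "aetiological_correlations.csv", manifest)

  # -- persistence ----------------------------------------------------------
  persistence <- stage("persistence", {
    ind <- select_one_twin_per_pair(prep$cohort,
                                    seed = stage_seed(config$seed, 200),
                                    subscales = subscales)
    out <- list(individuals = ind, groups = list(), distress = list(),
                contrasts = list())
    copsych <- intersect(c("smfq", "sdq_emo", "sdq_con", "sdq_hyp",
                           "sdq_peer"), names(ind))
    for (i in seq_along(subscales)) {
      s <- subscales[i]
      ga <- assign_groups(ind[[paste0(s, "_t1")]],
                          ind[[paste0(s, "_t2")]],
                          top_fraction = config$top_fraction,
                          ids = ind$family_id)
      out$groups[[s]] <- ga
      dcol <- paste0(s, "_distress")
      if (dcol %in% names(ind)) {
        matched <- ind[match(ga$id, ind$family_id), dcol]
        out$distress[[s]] <- distress_contingency(
          ga, matched, n_tables = config$mc_tables,
          seed = stage_seed(config$seed, 300 + i))
      }
      oc <- ind[match(ga$id, ind$family_id), copsych, drop = FALSE]
      out$contrasts[[s]] <- group_contrast_report(ga, oc)
    }
    out
  })
  group_tab <- do.call(rbind, lapply(names(persistence$groups), function(s) {
    ga <- persistence$groups[[s]]
    data.frame(subscale = s, group = levels(ga$group),
               n = as.integer(table(ga$group)),
               cutoff_t1 = attr(ga, "cutoffs")[["t1"]],
               cutoff_t2 = attr(ga, "cutoffs")[["t2"]],
               realized_top_t1 = attr(ga, "realized_top_fraction")[["t1"]],
               realized_top_t2 = attr(ga, "realized_top_fraction")[["t2"]])
  }))
  manifest <- write_table(group_tab, config$output_dir,
                          "persistence_groups.csv", manifest)
  if (length(persistence$distress)) {
    distress_tab <- do.call(rbind, lapply(names(persistence$distress),
                                          function(s) {
      cbind(subscale = s, persistence$distress[[s]]$comparisons)
    }))
    manifest <- write_table(distress_tab, config$output_dir,
                            "distress_contingency.csv", manifest)
    count_tab <- do.call(rbind, lapply(names(persistence$distress),
                                       function(s) {
      cn <- persistence$distress[[s]]$counts
      pc <- persistence$distress[[s]]$row_percent
      df <- as.data.frame.matrix(cn)
      names(df) <- paste0("n_", gsub("[ /]", "_", names(df)))
      pdf <- as.data.frame.matrix(round(pc, 1))
      names(pdf) <- paste0("pct_", gsub("[ /]", "_", names(pdf)))
      cbind(subscale = s, group = rownames(df), df, pdf)
    }))
    manifest <- write_table(count_tab, config$output_dir,
                            "distress_counts.csv", manifest)
  }
  contrast_tab <- do.call(rbind, lapply(names(persistence$contrasts),
                                        function(s) {
    cbind(subscale = s, persistence$contrasts[[s]]$contrasts)
  }))
  manifest <- write_table(contrast_tab, config$output_dir,
                          "group_contrasts.csv", manifest)

  manifest$elapsed_seconds <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$stage_seeds <- list(
    simulate = if (is.null(config$input_csv)) config$simulation$seed else NA,
    one_twin_selection = stage_seed(config$seed, 200))
  bundle <- list(config = config, cohort = prep$cohort,
                 preprocess_report = prep$report,
                 correlations = correlations, models = models,
                 estimates = estimates, comparison = comparison,
                 persistence = persistence, group_table = group_tab,
                 manifest = manifest)
  summary_md <- render_summary(bundle)
  writeLines(summary_md, file.path(config$output_dir, "summary.md"))
  manifest$files <- c(manifest$files, "summary.md", "manifest.json")
  bundle$manifest <- manifest
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(bundle)
}

#' Render a human-readable markdown summary of a pipeline run
#'
#' @param bundle the report bundle returned by [run_pipeline()].
#' @return character vector of markdown lines; missing stages produce
#'   warnings and a partial summary.
#' @export
render_summary <- function(bundle) {
  lines <- c("# Twin stability analysis summary", "")
  if (is.null(bundle$models) || !length(bundle$models)) {
    warning("no model results in bundle; writing partial summary",
            call. = FALSE)
    lines <- c(lines, "*No model results available.*")
    return(lines)
  }
  for (s in names(bundle$models)) {
    m <- bundle$models[[s]]
    best <- m$best
    est <- standardize(best$params)
    if (!inherits(est, "stability_estimates")) est <- est$female
    lines <- c(lines, paste0("## ", s), "",
               paste0("Best-fitting model: **", best$label, "** (BIC ",
                      round(best$BIC, 1), ")"),
               sprintf("Phenotypic cross-time r = %.2f", est$r_phenotypic),
               sprintf(paste0("Proportions of the phenotypic correlation: ",
                              "A %.2f, C %.2f, E %.2f"),
                       est$prop_a, est$prop_c, est$prop_e),
               sprintf("Aetiological correlations: rA %.2f, rC %.2f, rE %.2f",
                       est$rA, est$rC, est$rE), "")
    ga <- bundle$persistence$groups[[s]]
    if (!is.null(ga)) {
      tab <- table(ga$group)
      lines <- c(lines,
                 paste0("Persistence groups (n): ",
                        paste(names(tab), as.integer(tab), sep = " ",
                              collapse = ", ")), "")
    }
  }
  if (!is.null(bundle$manifest$elapsed_seconds)) {
    lines <- c(lines, sprintf("*Elapsed: %.1f s; master seed %d.*",
                              bundle$manifest$elapsed_seconds,
                              bundle$config$seed))
  }
  lines
}
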
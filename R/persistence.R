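#' Classify individuals into persistence subgroups
#'
#' Splits individuals with scores at both waves into four groups by
#' top-decile membership at each wave: `low_scoring` (both waves in the
#' bottom 90%), `decreasing` (wave-1 top decile only), `increasing` (wave-2
#' top decile only) and `persistent` (both waves in the top decile).
#'
#' The cutoff at each wave is the `ceiling(n * top_fraction)`-th largest
#' observed score (a nearest-rank upper-tail quantile); scores equal to the
#' cutoff count as top. Discrete questionnaire scores produce ties, so the
#' realized top fraction can exceed the nominal one and is reported.
#'
#' @param scores_t1,scores_t2 untransformed scores; individuals missing
#'   either wave are dropped.
#' @param top_fraction nominal top fraction (default 0.10).
#' @param ids optional identifiers carried into the output.
#' @return object of class `group_assignment`: data frame with `id`,
#'   `score_t1`, `score_t2`, `group`, plus attributes `cutoffs` and
#'   `realized_top_fraction` (per wave).
#' @export
assign_groups <- function(scores_t1, scores_t2, top_fraction = 0.10,
                          ids = NULL) {
  stopifnot(length(scores_t1) == length(scores_t2),
            top_fraction > 0, top_fraction < 1)
  ids <- ids %||% seq_along(scores_t1)
  ok <- !is.na(scores_t1) & !is.na(scores_t2)
  s1 <- scores_t1[ok]; s2 <- scores_t2[ok]; ids <- ids[ok]
  n <- length(s1)
  if (n == 0) stop("no individuals with both-wave data", call. = FALSE)
  cutoff <- function(x) {
    if (max(x) == min(x)) {
      stop("degenerate cutoff: all scores equal", call. = FALSE)
    }
    k <- ceiling(n * top_fraction)
    sort(x, decreasing = TRUE)[k]
  }
  c1 <- cutoff(s1); c2 <- cutoff(s2)
  top1 <- s1 >= c1; top2 <- s2 >= c2
  group <- ifelse(top1 & top2, "persistent",
                  ifelse(top1, "decreasing",
                         ifelse(top2, "increasing", "low_scoring")))
  out <- data.frame(id = ids, score_t1 = s1, score_t2 = s2,
                    group = factor(group, levels = c("low_scoring",
                                                     "increasing",
                                                     "decreasing",
                                                     "persistent")),
                    stringsAsFactors = FALSE)
  attr(out, "cutoffs") <- c(t1 = c1, t2 = c2)
  attr(out, "realized_top_fraction") <- c(t1 = mean(top1), t2 = mean(top2))
  attr(out, "top_fraction") <- top_fraction
  class(out) <- c("group_assignment", "data.frame")
  out
}

drop_zero_margins <- function(table) {
  rz <- rowSums(table) == 0
  cz <- colSums(table) == 0
  if (any(rz) || any(cz)) {
    warning("dropping zero-margin rows/columns before computing the ",
            "statistic", call. = FALSE)
    table <- table[!rz, !cz, drop = FALSE]
  }
  table
}

pearson_chisq <- function(table) {
  N <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / N
  sum((table - expected)^2 / expected)
}

#' Cramer's V effect size for an r x c contingency table
#'
#' The square root of the Pearson chi-square statistic divided by the
#' sample size multiplied by one less than the smaller number of categories:
#' `V = sqrt(chisq / (N * (min(r, c) - 1)))`.
#'
#' @param table non-negative integer matrix with at least 2 rows and 2
#'   columns (after dropping zero-margin rows/columns, which is done with a
#'   warning).
#' @return Cramer's V in \[0, 1\].
#' @export
cramers_v <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), sum(table) >= 1)
  table <- drop_zero_margins(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("need at least 2 rows and 2 columns with non-zero margins",
         call. = FALSE)
  }
  chisq <- pearson_chisq(table)
  sqrt(chisq / (sum(table) * (min(dim(table)) - 1)))
}

# log probability (up to the fixed-margin constant) of a table under the
# multivariate hypergeometric null: -sum(lgamma(cell + 1))
table_log_prob_kernel <- function(table) -sum(lgamma(table + 1))

#' Monte-Carlo Fisher exact test for an r x c table
#'
#' Samples `n_tables` tables uniformly from the fixed-margins
#' (multivariate hypergeometric) null distribution with Patefield's
#' conditional-margins algorithm and estimates the exact p value as the
#' proportion of sampled tables -- plus the observed one -- whose null
#' probability does not exceed that of the observed table:
#' `p = (1 + #(P(T) <= P(obs))) / (n_tables + 1)`.
#'
#' @param table non-negative integer matrix.
#' @param n_tables number of sampled tables (default 10,000).
#' @param seed integer seed; the estimate is deterministic given the seed.
#' @return list with `p`, `n_tables`, `seed` and the observed
#'   `chisq`/`cramers_v` for convenience.
#' @export
fisher_exact_montecarlo <- function(table, n_tables = 10000, seed = 1) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), all(table == round(table)), n_tables >= 1)
  table <- drop_zero_margins(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("degenerate table: need 2x2 or larger after dropping zero margins",
         call. = FALSE)
  }
  if (sum(table) > 1e7) stop("table total too large", call. = FALSE)
  obs <- table_log_prob_kernel(table)
  sims <- with_seed(seed, r2dtable(n_tables, rowSums(table),
                                   colSums(table)))
  lp <- vapply(sims, table_log_prob_kernel, numeric(1))
  hits <- sum(lp <= obs + 1e-7)
  list(p = (1 + hits) / (n_tables + 1), n_tables = n_tables, seed = seed,
       chisq = pearson_chisq(table), cramers_v = cramers_v(table))
}

#' Cohen's d for unequal group sizes
#'
#' Standardized mean difference with the pooled standard deviation weighted
#' by degrees of freedom:
#' `d = (mean1 - mean2) / sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))`.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return Cohen's d.
#' @export
cohens_d_unequal_n <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (pooled == 0) {
    if (mean1 == mean2) return(0)
    stop("pooled SD is zero with unequal means; effect size infinite",
         call. = FALSE)
  }
  (mean1 - mean2) / pooled
}

# large-sample SE of d (normal-approximation CI; the report labels CIs, not
# significance stars)
cohens_d_se <- function(d, n1, n2) {
  sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
}

#' Distress-by-group contingency analyses
#'
#' For one subscale: cross-tabulates persistence group against the ordinal
#' distress level (not / a bit / quite-or-very distressed) among
#' individuals with a positive wave-1 subscale score and distress data,
#' then runs the standard pairwise comparisons (low-scoring vs persistent,
#' low-scoring vs increasing, decreasing vs persistent, increasing vs
#' persistent) with Pearson chi-square, Cramer's V and the Monte-Carlo
#' Fisher exact p.
#'
#' @param groups a [assign_groups()] result.
#' @param distress character/factor vector of distress levels aligned with
#'   `groups` rows (levels "not", "a bit", "quite/very"; `NA` allowed).
#' @param n_tables,seed Monte-Carlo settings for the exact test.
#' @return list with `counts` (group x distress table with row
#'   percentages) and `comparisons` (data frame of pairwise statistics).
#' @export
distress_contingency <- function(groups, distress, n_tables = 10000,
                                 seed = 1) {
  stopifnot(inherits(groups, "group_assignment"),
            length(distress) == nrow(groups))
  keep <- groups$score_t1 > 0 & !is.na(distress)
  g <- groups$group[keep]
  d <- factor(as.character(distress[keep]), levels = distress_levels())
  counts <- table(group = g, distress = d)
  pairs <- list(c("low_scoring", "persistent"),
                c("low_scoring", "increasing"),
                c("decreasing", "persistent"),
                c("increasing", "persistent"))
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    tab <- counts[pr, , drop = FALSE]
    if (any(rowSums(tab) == 0)) {
      return(data.frame(comparison = paste(pr, collapse = " vs "),
                        chisq = NA_real_, cramers_v = NA_real_,
                        p_montecarlo = NA_real_))
    }
    tab2 <- drop_zero_margins(unclass(tab))
    if (nrow(tab2) < 2 || ncol(tab2) < 2) {
      return(data.frame(comparison = paste(pr, collapse = " vs "),
                        chisq = NA_real_, cramers_v = NA_real_,
                        p_montecarlo = NA_real_))
    }
    mc <- fisher_exact_montecarlo(tab2, n_tables = n_tables,
                                  seed = stage_seed(seed, i))
    data.frame(comparison = paste(pr, collapse = " vs "),
               chisq = mc$chisq, cramers_v = mc$cramers_v,
               p_montecarlo = mc$p, stringsAsFactors = FALSE)
  })
  pct <- prop.table(counts, 1) * 100
  list(counts = counts, row_percent = pct,
       comparisons = do.call(rbind, rows))
}

#' Pairwise Cohen's d contrasts of outcome scores across persistence groups
#'
#' Descriptive means/SDs per group and all pairwise standardized mean
#' differences for each outcome, with large-sample 95% CIs on d. Contrasts
#' involving a group with fewer than 2 members are skipped with a warning.
#'
#' @param groups a [assign_groups()] result.
#' @param outcomes data frame of outcome scores aligned with `groups` rows
#'   (e.g. depression traits and the emotional / conduct / hyperactivity /
#'   peer problem scales at wave 1).
#' @return list with `descriptives` and `contrasts` data frames.
#' @export
group_contrast_report <- function(groups, outcomes) {
  stopifnot(inherits(groups, "group_assignment"),
            nrow(outcomes) == nrow(groups))
  g <- groups$group
  desc <- list()
  contrasts <- list()
  lev <- levels(g)
  for (oc in names(outcomes)) {
    y <- outcomes[[oc]]
    st <- lapply(lev, function(l) {
      yy <- y[g == l & !is.na(y)]
      c(n = length(yy), mean = mean(yy), sd = sd(yy))
    })
    names(st) <- lev
    for (l in lev) {
      desc[[paste(oc, l)]] <- data.frame(outcome = oc, group = l,
                                         n = st[[l]][["n"]],
                                         mean = st[[l]][["mean"]],
                                         sd = st[[l]][["sd"]])
    }
    for (i in seq_along(lev)) {
      for (j in seq_along(lev)) {
        if (j <= i) next
        s1 <- st[[lev[i]]]; s2 <- st[[lev[j]]]
        if (s1[["n"]] < 2 || s2[["n"]] < 2) {
          warning("skipping contrast ", lev[i], " vs ", lev[j], " for ",
                  oc, ": group with fewer than 2 members", call. = FALSE)
          next
        }
        d <- cohens_d_unequal_n(s2[["mean"]], s2[["sd"]], s2[["n"]],
                                s1[["mean"]], s1[["sd"]], s1[["n"]])
        se <- cohens_d_se(d, s1[["n"]], s2[["n"]])
        contrasts[[paste(oc, lev[i], lev[j])]] <- data.frame(
          outcome = oc, group_1 = lev[j], group_2 = lev[i], d = d,
          lower = d - qnorm(0.975) * se, upper = d + qnorm(0.975) * se,
          stringsAsFactors = FALSE)
      }
    }
  }
  bind <- function(rows, template) {
    if (!length(rows)) return(template)
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  empty_contrasts <- data.frame(outcome = character(0),
                                group_1 = character(0),
                                group_2 = character(0), d = numeric(0),
                                lower = numeric(0), upper = numeric(0))
  empty_desc <- data.frame(outcome = character(0), group = character(0),
                           n = numeric(0), mean = numeric(0),
                           sd = numeric(0))
  list(descriptives = bind(desc, empty_desc),
       contrasts = bind(contrasts, empty_contrasts))
}
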
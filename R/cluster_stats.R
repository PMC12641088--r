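#' One-way analysis of variance across groups
#'
#' Classical equal-variance one-way ANOVA (between/within decomposition,
#' F on g - 1 and N - g degrees of freedom), as used for the
#' demographic and cerebral-blood-flow comparisons across groups and
#' clusters. Wraps `stats::oneway.test(var.equal = TRUE)` and adds the
#' per-group summaries.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation (>= 2 groups, each with
#'   >= 2 observations).
#' @return list of class `anova_result`: `f`, `df_between`, `df_within`,
#'   `p`, `group_means`, `group_sds`, `group_ns`.
#' @export
anova_oneway <- function(values, groups) {
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  groups <- factor(groups)
  ns <- table(groups)
  if (nlevels(groups) < 2L) abort("need at least 2 groups")
  if (any(ns < 2L)) {
    abort("every group needs >= 2 observations; too small: ",
          paste(names(ns)[ns < 2], collapse = ", "))
  }
  ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  structure(list(
    f = unname(ht$statistic),
    df_between = unname(ht$parameter[1]),
    df_within = unname(ht$parameter[2]),
    p = unname(ht$p.value),
    group_means = tapply(values, groups, mean),
    group_sds = tapply(values, groups, stats::sd),
    group_ns = as.vector(ns)), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3g, P = %.3g\n",
              x$df_between, x$df_within, x$f, x$p))
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range pairwise comparisons after a one-way ANOVA, in the
#' unequal-n (Tukey-Kramer) form; wraps `stats::TukeyHSD` on an `aov`
#' fit.
#'
#' @inheritParams anova_oneway
#' @param conf_level family-wise confidence level (default 0.95).
#' @return data.frame: `comparison` ("B-A"), `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(values, groups, conf_level = 0.95) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  ns <- table(groups)
  if (nlevels(groups) < 2L || any(ns < 2L)) {
    abort("need >= 2 groups with >= 2 observations each")
  }
  tk <- stats::TukeyHSD(stats::aov(values ~ groups),
                        conf.level = conf_level)$groups
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}

#' Bonferroni-corrected ANOVA screen over the 24 CBF territories
#'
#' Runs a one-way ANOVA of CBF across clusters separately in each of
#' the m territories and flags a territory as significant when its
#' unadjusted p-value falls below `alpha / m` — the Bonferroni
#' correction for the 24 parallel regional tests.
#'
#' @param cbf a `cbf_table` (long format) or a participant x region
#'   matrix from [cbf_matrix()].
#' @param labels named vector (participant id -> cluster) or a vector
#'   aligned with the matrix rows.
#' @param alpha family-wise level (default 0.05).
#' @param m number of tests the correction divides alpha by; defaults
#'   to the number of regions screened.
#' @param strict in strict mode (default) a region with missing values
#'   is an error; otherwise it is dropped with a message.
#' @return list of class `region_screen`: `table` (data.frame region /
#'   f / df_between / df_within / p / significant), `bonferroni_alpha`,
#'   `significant_regions`, `anovas` (named list of `anova_result`).
#' @export
screen_regions <- function(cbf, labels, alpha = 0.05, m = NULL,
                           strict = TRUE) {
  mat <- if (is.matrix(cbf)) cbf else cbf_matrix(cbf, complete = strict)
  if (!is.null(names(labels))) {
    missing_lab <- setdiff(rownames(mat), names(labels))
    if (length(missing_lab)) {
      abort("no cluster label for participant(s): ",
            paste(missing_lab, collapse = ", "))
    }
    labels <- labels[rownames(mat)]
  }
  stopifnot(length(labels) == nrow(mat))
  if (length(unique(labels)) < 2L) abort("need >= 2 clusters")
  regions <- colnames(mat)
  keep <- !vapply(regions, function(r) anyNA(mat[, r]), TRUE)
  if (any(!keep)) {
    if (strict) abort("missing CBF in region(s): ",
                      paste(regions[!keep], collapse = ", "))
    message("dropping incomplete region(s): ",
            paste(regions[!keep], collapse = ", "))
  }
  regions <- regions[keep]
  if (is.null(m)) m <- length(regions)
  threshold <- alpha / m
  anovas <- lapply(regions, function(r) anova_oneway(mat[, r], labels))
  names(anovas) <- regions
  tab <- data.frame(
    region = regions,
    f = vapply(anovas, `[[`, 0, "f"),
    df_between = vapply(anovas, `[[`, 0, "df_between"),
    df_within = vapply(anovas, `[[`, 0, "df_within"),
    p = vapply(anovas, `[[`, 0, "p"),
    row.names = NULL)
  tab$significant <- tab$p < threshold
  structure(list(table = tab, bonferroni_alpha = threshold,
                 significant_regions = tab$region[tab$significant],
                 anovas = anovas), class = "region_screen")
}

#' @export
print.region_screen <- function(x, ...) {
  cat(sprintf("region screen: %d of %d regions significant at P < %.4g\n",
              sum(x$table$significant), nrow(x$table), x$bonferroni_alpha))
  if (any(x$table$significant)) {
    cat(" ", paste(x$significant_regions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Group summary table (mean +/- SD per group with ANOVA and Tukey)
#'
#' Convenience builder for demographic summaries in the style of
#' clinical cohort tables: per-variable group means and SDs, the
#' one-way ANOVA F and p, and Tukey-adjusted pairwise p-values.
#'
#' @param data data.frame of numeric variables.
#' @param groups group label per row.
#' @param variables column names to summarise (default: all numeric).
#' @return data.frame, one row per variable x group, plus columns
#'   `f`, `p` and a `pairwise` string of Tukey comparisons.
#' @export
group_summary <- function(data, groups, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, TRUE)]
  }
  groups <- factor(groups)
  do.call(rbind, lapply(variables, function(v) {
    a <- anova_oneway(data[[v]], groups)
    tk <- tukey_hsd(data[[v]], groups)
    data.frame(variable = v, group = names(a$group_means),
               mean = as.vector(a$group_means),
               sd = as.vector(a$group_sds), n = a$group_ns,
               f = a$f, p = a$p,
               pairwise = paste(sprintf("%s: P = %.3g", tk$comparison,
                                        tk$p_adj), collapse = "; "),
               row.names = NULL)
  }))
}
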
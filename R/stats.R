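#' Choose a two-sample test by a Shapiro-Wilk normality gate
#'
#' Parametric tests are used only when normality is not rejected at
#' `shapiro_alpha`: for unpaired data both groups must pass; for paired data
#' the per-individual differences must pass. Otherwise the rank-based
#' alternative is chosen.
#'
#' @param a,b numeric vectors; for `paired = TRUE` they must be aligned by
#'   individual.
#' @param paired logical; paired (side) comparison or independent groups.
#' @param shapiro_alpha significance level of the normality gate.
#' @return One of `"welch_t"`, `"mann_whitney_u"`, `"paired_t"`,
#'   `"wilcoxon_signed_rank"`.
#' @export
choose_test <- function(a, b, paired = FALSE, shapiro_alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L)
    stop("choose_test: each group needs at least 3 observations")
  if (paired) {
    if (length(a) != length(b))
      stop("choose_test: paired groups must have equal length")
    d <- a - b
    normal <- shapiro_p(d) >= shapiro_alpha
    if (normal) "paired_t" else "wilcoxon_signed_rank"
  } else {
    normal <- shapiro_p(a) >= shapiro_alpha && shapiro_p(b) >= shapiro_alpha
    if (normal) "welch_t" else "mann_whitney_u"
  }
}

# shapiro.test rejects constant input and n > 5000; treat constants as
# non-normal and subsample very large groups deterministically
shapiro_p <- function(x) {
  if (length(unique(x)) == 1L) return(0)
  if (length(x) > 5000L) x <- x[seq(1L, length(x), length.out = 5000L)]
  stats::shapiro.test(x)$p.value
}

run_test <- function(a, b, test) {
  switch(test,
    welch_t = stats::t.test(a, b, var.equal = FALSE),
    mann_whitney_u = stats::wilcox.test(a, b, exact = FALSE),
    paired_t = stats::t.test(a, b, paired = TRUE),
    wilcoxon_signed_rank = stats::wilcox.test(a, b, paired = TRUE, exact = FALSE),
    stop("unknown test: ", test))
}

#' Group comparisons for a measurement table
#'
#' Reproduces the per-measurement group-difference analysis: two-sided tests
#' at level `alpha`, with the parametric/rank-based choice gated by
#' Shapiro-Wilk normality ([choose_test()]) and no multiple-testing
#' correction.
#'
#' Stratification follows the factor: sex comparisons are run per side, side
#' comparisons per sex (paired within individual), and age-group comparisons
#' per sex per side, with the age groups split at `age_cutoff` (at or below
#' versus above). Signed differences are male minus female, right minus left,
#' and young group minus old group respectively.
#'
#' @param table measurement table with metadata columns.
#' @param factor one of `"sex"`, `"side"`, `"age_group"`.
#' @param age_cutoff age-group cut-off in years (default 45).
#' @param alpha significance level (default 0.05).
#' @param shapiro_alpha level of the normality gate.
#' @return A `comparison_table` data.frame: one row per measurement per
#'   stratum with group descriptives (n, mean, sd, min, max), the chosen test,
#'   its statistic and p-value, the signed mean difference, and a significance
#'   flag.
#' @export
compare_groups <- function(table, factor = c("sex", "side", "age_group"),
                           age_cutoff = 45, alpha = 0.05,
                           shapiro_alpha = 0.05) {
  factor <- match.arg(factor)
  cols <- measurement_columns(table)
  rows <- list()
  emit <- function(stratum, measurement, a, b, labels, paired) {
    test <- choose_test(a, b, paired = paired, shapiro_alpha = shapiro_alpha)
    ht <- run_test(a, b, test)
    data.frame(
      stratum = stratum, measurement = measurement,
      group_a = labels[1L], group_b = labels[2L],
      n_a = length(a), n_b = length(b),
      mean_a = mean(a), sd_a = stats::sd(a), min_a = min(a), max_a = max(a),
      mean_b = mean(b), sd_b = stats::sd(b), min_b = min(b), max_b = max(b),
      difference = mean(a) - mean(b),
      test = test, statistic = unname(ht$statistic), p_value = ht$p.value,
      significant = ht$p.value < alpha,
      stringsAsFactors = FALSE)
  }
  if (factor == "sex") {
    for (sd_ in unique(table$side)) {
      sub <- table[table$side == sd_, , drop = FALSE]
      for (m in cols) {
        a <- sub[[m]][sub$sex == "M"]
        b <- sub[[m]][sub$sex == "F"]
        rows[[length(rows) + 1L]] <-
          emit(paste0("side=", sd_), m, a, b, c("M", "F"), paired = FALSE)
      }
    }
  } else if (factor == "side") {
    for (sx in unique(table$sex)) {
      sub <- table[table$sex == sx, , drop = FALSE]
      r <- sub[sub$side == "right", , drop = FALSE]
      l <- sub[sub$side == "left", , drop = FALSE]
      common <- intersect(r$individual_id, l$individual_id)
      orphans <- setdiff(union(r$individual_id, l$individual_id), common)
      if (length(orphans))
        stop("compare_groups: unpairable individuals for side comparison: ",
             paste(utils::head(orphans, 10L), collapse = ", "))
      r <- r[match(common, r$individual_id), , drop = FALSE]
      l <- l[match(common, l$individual_id), , drop = FALSE]
      for (m in cols) {
        rows[[length(rows) + 1L]] <-
          emit(paste0("sex=", sx), m, r[[m]], l[[m]], c("right", "left"),
               paired = TRUE)
      }
    }
  } else {
    for (sx in unique(table$sex)) {
      for (sd_ in unique(table$side)) {
        sub <- table[table$sex == sx & table$side == sd_, , drop = FALSE]
        young <- sub$age <= age_cutoff
        for (m in cols) {
          rows[[length(rows) + 1L]] <-
            emit(sprintf("sex=%s,side=%s", sx, sd_), m,
                 sub[[m]][young], sub[[m]][!young],
                 c(sprintf("age<=%g", age_cutoff), sprintf("age>%g", age_cutoff)),
                 paired = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("comparison_table", class(out))
  out
}

#' Fraction of significant comparisons
#' @param comparison a `comparison_table` from [compare_groups()].
#' @return Proportion of rows with `significant == TRUE`.
#' @export
significant_fraction <- function(comparison) {
  if (!nrow(comparison)) return(0)
  mean(comparison$significant)
}

#' Measurements with significant sex differences
#'
#' The feature-screening rule used before classifier training: only
#' measurements showing a significant sex difference are retained. For tables
#' containing both sides, a measurement is kept when significant on at least
#' one side.
#'
#' @param table measurement table (typically the training portion of a split;
#'   screening on the full sample before splitting leaks test information and
#'   is available only by passing the full table explicitly).
#' @param alpha significance level.
#' @return Character vector of retained measurement names.
#' @export
sex_significant_features <- function(table, alpha = 0.05) {
  comp <- compare_groups(table, factor = "sex", alpha = alpha)
  keep <- unique(comp$measurement[comp$significant])
  # preserve registry order
  cols <- measurement_columns(table)
  cols[cols %in% keep]
}
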
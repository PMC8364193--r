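# Cohort-level statistics: prevalence of marker-positive samples,
# gene/transcript concordance, and Mann-Whitney U association of presence
# with metabolite levels or disease groups.

#' Fraction of positive samples per cohort or group
#'
#' @param table cohort tibble with one row per sample.
#' @param by optional grouping column (unquoted); omitted = one overall
#'   row.
#' @param col logical presence column (unquoted; default `gene_present`).
#' @return tibble of class `prevalence_df`: group, `n`, `n_positive`,
#'   `frac_positive`, `frac_negative` (the two fractions sum to 1).
#' @export
#' @examples
#' tbl <- tibble::tibble(cohort = rep(c("A", "B"), each = 10),
#'                       gene_present = rep(c(TRUE, FALSE), 10))
#' prevalence(tbl, cohort)
prevalence <- function(table, by = NULL, col = gene_present) {
  by <- enquo(by)
  col <- enquo(col)
  grouped <- if (quo_is_null(by)) table else {
    missing_grp <- is.na(dplyr::pull(table, !!by))
    if (any(missing_grp)) {
      warn(sprintf("%d sample(s) with missing group label excluded",
                   sum(missing_grp)))
      table <- table[!missing_grp, , drop = FALSE]
    }
    dplyr::group_by(table, !!by)
  }
  if (nrow(table) == 0) abort("prevalence needs at least one sample")
  out <- grouped |>
    dplyr::summarise(
      n = dplyr::n(),
      n_positive = sum(!!col, na.rm = TRUE),
      frac_positive = .data$n_positive / .data$n,
      frac_negative = 1 - .data$frac_positive,
      .groups = "drop")
  class(out) <- c("prevalence_df", class(out))
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. When `n1 + n2 <= 12` and the pooled values are
#' tie-free, the exact null distribution is used and the two-sided p-value
#' doubles the smaller tail (capped at 1); otherwise the normal
#' approximation with tie correction and continuity correction applies.
#' The reported statistic is `U` for the first sample, so
#' `U(a,b) + U(b,a) = n1 * n2` on tie-free data.
#'
#' @param values_a,values_b numeric vectors (both nonempty; `NA` dropped).
#' @return object of class `mwu_test` with fields `U`, `n1`, `n2`,
#'   `p_two_sided`, `method`.
#' @export
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6)) # exact two-sided p = 0.10
mwu_test <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) == 0 || length(b) == 0) {
    abort("both groups must be nonempty")
  }
  n1 <- length(a); n2 <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (n1 + n2) <= 12 && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE,
                                     alternative = "two.sided"))
  structure(list(
    U = unname(wt$statistic),
    n1 = n1, n2 = n2,
    p_two_sided = min(wt$p.value, 1),
    method = if (exact) "exact" else "normal-approximation-with-tie-correction"
  ), class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_two_sided, x$method))
  invisible(x)
}

#' @export
tidy.mwu_test <- function(x, ...) {
  tibble(U = x$U, n1 = x$n1, n2 = x$n2,
         p_value = x$p_two_sided, method = x$method)
}

#' @export
glance.mwu_test <- function(x, ...) tidy(x)

#' Associate marker presence with metabolite levels
#'
#' Per stratum, compares metabolite levels between marker-positive and
#' marker-negative samples with [mwu_test()] and reports group sizes,
#' medians and means (the mean is the yellow-diamond summary of the usual
#' cohort figure). Missing metabolite values are dropped pairwise; strata
#' with fewer than 2 non-missing values in either group are skipped with a
#' warning.
#'
#' @param table cohort tibble.
#' @param metabolite metabolite column (unquoted).
#' @param stratify_by optional stratum column (unquoted).
#' @param col logical presence column (unquoted; default `gene_present`).
#' @return tibble of class `assoc_df`, one row per stratum: `n_positive`,
#'   `n_negative`, `U`, `p_value`, `method`, medians and means per group.
#' @export
associate_presence_with_metabolite <- function(table, metabolite,
                                               stratify_by = NULL,
                                               col = gene_present) {
  metabolite <- enquo(metabolite)
  stratify_by <- enquo(stratify_by)
  col <- enquo(col)
  split_tbl <- if (quo_is_null(stratify_by)) {
    list(`all` = table)
  } else {
    split(table, dplyr::pull(table, !!stratify_by))
  }
  rows <- purrr::imap(split_tbl, function(tb, stratum) {
    vals <- dplyr::pull(tb, !!metabolite)
    pres <- dplyr::pull(tb, !!col)
    ok <- !is.na(vals) & !is.na(pres)
    pos <- vals[ok & pres]
    neg <- vals[ok & !pres]
    if (length(pos) < 2 || length(neg) < 2) {
      warn(sprintf("stratum '%s' skipped: fewer than 2 non-missing values in a group",
                   stratum))
      return(NULL)
    }
    wt <- mwu_test(pos, neg)
    tibble(stratum = stratum,
           n_positive = length(pos), n_negative = length(neg),
           U = wt$U, p_value = wt$p_two_sided, method = wt$method,
           median_positive = median(pos), median_negative = median(neg),
           mean_positive = mean(pos), mean_negative = mean(neg))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "metabolite") <- as_name(metabolite)
  class(out) <- c("assoc_df", class(out))
  out
}

#' Gene / transcript concordance
#'
#' Cross-tabulates metagenome gene presence against metatranscriptome
#' transcript presence and reports the two conditional fractions:
#' transcript-positive among gene-positive samples and transcript-positive
#' among gene-negative samples (the latter captures samples whose gene
#' abundance is below metagenomic detection while the transcript is
#' expressed). A fraction with an empty denominator is reported as `NA`
#' with its `n = 0`.
#'
#' @param table cohort tibble with logical `gene_present` and
#'   `transcript_present` columns (`NA` transcript rows are dropped).
#' @return one-row tibble with the 2x2 counts and both fractions.
#' @export
gene_transcript_concordance <- function(table) {
  if (!all(c("gene_present", "transcript_present") %in% names(table))) {
    abort("table must have gene_present and transcript_present columns")
  }
  tb <- table[!is.na(table$transcript_present) & !is.na(table$gene_present), ]
  if (nrow(tb) == 0) abort("no samples with non-missing transcript presence")
  gp_tp <- sum(tb$gene_present & tb$transcript_present)
  gp_tn <- sum(tb$gene_present & !tb$transcript_present)
  gn_tp <- sum(!tb$gene_present & tb$transcript_present)
  gn_tn <- sum(!tb$gene_present & !tb$transcript_present)
  n_gp <- gp_tp + gp_tn
  n_gn <- gn_tp + gn_tn
  tibble(
    n = nrow(tb),
    gene_pos_transcript_pos = gp_tp, gene_pos_transcript_neg = gp_tn,
    gene_neg_transcript_pos = gn_tp, gene_neg_transcript_neg = gn_tn,
    n_gene_positive = n_gp, n_gene_negative = n_gn,
    frac_transcript_pos_given_gene_pos =
      if (n_gp > 0) gp_tp / n_gp else NA_real_,
    frac_transcript_pos_given_gene_neg =
      if (n_gn > 0) gn_tp / n_gn else NA_real_)
}
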
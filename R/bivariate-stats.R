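# Bivariate prevalence tables and Pearson chi-square tests of association.

#' Cross-tabulate a covariate against CHE labels
#'
#' @param table A \code{survey_table}.
#' @param covariate Name of a categorical column in the table.
#' @param labels A \code{che_labels} table covering every household.
#' @return Integer matrix of counts, rows = observed covariate levels,
#'   columns = CHE 0/1.
#' @export
che_crosstab <- function(table, covariate, labels) {
  if (!covariate %in% names(table)) stop("unknown field: ", covariate)
  lab <- labels$che[match(table$hh_id, labels$hh_id)]
  if (any(is.na(lab))) stop("labels do not cover every household")
  ct <- table(table[[covariate]], factor(lab, levels = c(0L, 1L)))
  m <- matrix(as.integer(ct), nrow = nrow(ct),
              dimnames = list(rownames(ct), c("0", "1")))
  m[rowSums(m) > 0L, , drop = FALSE]
}

#' Row-wise CHE prevalence percentages
#'
#' @param ct Contingency matrix with CHE counts in the last column.
#' @return Named numeric vector, 100 x (CHE = 1 count) / (row total).
#' @export
row_percent <- function(ct) {
  totals <- rowSums(ct)
  if (any(totals == 0)) stop("zero row total")
  100 * ct[, ncol(ct)] / totals
}

#' Pearson chi-square test of independence
#'
#' The uncorrected Pearson statistic \eqn{\sum (O-E)^2/E} with expected
#' counts from the product of the margins, df = (r-1)(c-1), and an upper-tail
#' chi-square p-value. No continuity correction and no exact test.
#'
#' @param ct Nonnegative count matrix, at least 2 x 2.
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @export
chi_square <- function(ct) {
  ct <- as.matrix(ct)
  if (nrow(ct) < 2L || ncol(ct) < 2L) stop("need at least a 2x2 table")
  if (any(ct < 0)) stop("negative counts")
  n <- sum(ct)
  if (n <= 0) stop("empty table")
  rs <- rowSums(ct); cs <- colSums(ct)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal total: expected counts undefined")
  expected <- outer(rs, cs) / n
  stat <- sum((ct - expected)^2 / expected)
  df <- (nrow(ct) - 1L) * (ncol(ct) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Prevalence-by-covariate summary with chi-square tests
#'
#' One block per covariate: CHE prevalence per level and the Pearson
#' chi-square p-value for association with the CHE label.
#'
#' @param table A \code{survey_table}.
#' @param labels A \code{che_labels} table.
#' @param covariates Character vector of categorical column names.
#' @return Data frame with \code{covariate}, \code{level},
#'   \code{prevalence_pct}, \code{n}, \code{p_value} (repeated within block).
#' @export
bivariate_table <- function(table, labels,
                            covariates = c("old_age_present", "child_present",
                                           "wealth_quintile",
                                           "chronic_disease_present",
                                           "head_educated", "residence",
                                           "division", "head_sex",
                                           "head_age_over60")) {
  blocks <- lapply(covariates, function(cv) {
    ct <- che_crosstab(table, cv, labels)
    p <- if (nrow(ct) >= 2L) chi_square(ct)$p_value else NA_real_
    data.frame(covariate = cv, level = rownames(ct),
               prevalence_pct = unname(row_percent(ct)),
               n = unname(rowSums(ct)), p_value = p,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, blocks)
}
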
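# PCA wealth index from asset indicators.

#' Standardize asset columns
#'
#' Centers each asset column to mean 0 and scales to sample SD 1 (n - 1
#' denominator). Zero-variance columns carry no ranking information and are
#' dropped with a warning.
#'
#' @param table A \code{survey_table} (asset columns are those named
#'   \code{asset_*}), or a plain numeric matrix/data frame of assets.
#' @return Numeric matrix of standardized assets.
#' @export
standardize_assets <- function(table) {
  if (inherits(table, "survey_table")) {
    cols <- attr(table, "asset_cols")
    if (length(cols) < 2L) stop("need at least 2 asset columns")
    m <- as.matrix(as.data.frame(table)[, cols, drop = FALSE])
  } else {
    m <- as.matrix(table)
  }
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("need at least 2 households")
  sds <- apply(m, 2L, stats::sd)
  keep <- sds > 0
  if (any(!keep)) {
    warning("dropping zero-variance asset column(s): ",
            paste(colnames(m)[!keep], collapse = ", "))
  }
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 2L) stop("fewer than 2 asset columns with nonzero variance")
  scale(m, center = TRUE, scale = sds[keep])[, , drop = FALSE]
}

#' First principal component of a standardized matrix
#'
#' Loadings are the unit-norm eigenvector of the sample covariance (equal to
#' the correlation matrix after standardization) with the largest eigenvalue;
#' scores are the projection \code{X \%*\% loadings}. The sign is oriented so
#' the loading sum is positive (tie broken by making the first nonzero
#' loading positive), giving reproducible scores.
#'
#' @param X Standardized numeric matrix (rows = households).
#' @return List with \code{scores}, \code{loadings}, \code{explained_variance}
#'   (first eigenvalue of the n - 1 denominator covariance).
#' @export
first_pc <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows")
  sv <- svd(X, nu = 0L, nv = 1L)
  if (sv$d[1L] <= 0) stop("degenerate (rank-0) matrix")
  v <- drop(sv$v)
  s <- sum(v)
  if (abs(s) < 1e-12) {
    nz <- which(abs(v) > 1e-12)[1L]
    s <- v[nz]
  }
  if (s < 0) v <- -v
  list(scores = unname(drop(X %*% v)),
       loadings = stats::setNames(v, colnames(X)),
       explained_variance = sv$d[1L]^2 / (nrow(X) - 1L))
}

#' Rank-based quintile classes
#'
#' Households are ranked by score (ties broken by stable record order) and
#' rank r is assigned to group \code{ceiling(5 r / n)}, i.e. group k receives
#' the ranks in ((k-1)n/5, kn/5]. Group sizes differ by at most 1.
#'
#' @param scores Numeric vector, \code{length >= 5}.
#' @return Ordered factor with levels Poorest, Second, Third, Fourth,
#'   Richest.
#' @export
wealth_quintiles <- function(scores) {
  n <- length(scores)
  if (n < 5L) stop("need at least 5 households for quintiles")
  r <- rank(scores, ties.method = "first")
  k <- ceiling(5 * r / n)
  factor(c("Poorest", "Second", "Third", "Fourth", "Richest")[k],
         levels = c("Poorest", "Second", "Third", "Fourth", "Richest"),
         ordered = TRUE)
}

#' PCA wealth index with quintile classes
#'
#' Standardizes the asset columns, extracts first-principal-component scores
#' and cuts them into quintiles.
#'
#' @param table A \code{survey_table} with \code{asset_*} columns.
#' @return A \code{wealth_index} list with \code{scores}, \code{loadings},
#'   \code{explained_variance} and \code{quintile}.
#' @export
wealth_index <- function(table) {
  pc <- first_pc(standardize_assets(table))
  structure(c(pc, list(quintile = wealth_quintiles(pc$scores))),
            class = "wealth_index")
}

#' Append wealth index columns to a survey table
#'
#' @param table A \code{survey_table}.
#' @return The table with added \code{wealth_score} and \code{wealth_quintile}
#'   columns.
#' @export
add_wealth_index <- function(table) {
  wi <- wealth_index(table)
  table$wealth_score <- wi$scores
  table$wealth_quintile <- as.character(wi$quintile)
  table
}

#' @export
print.wealth_index <- function(x, ...) {
  cat("PCA wealth index:", length(x$scores), "households,",
      length(x$loadings), "assets; first eigenvalue",
      format(x$explained_variance, digits = 4), "\n")
  print(table(x$quintile))
  invisible(x)
}
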
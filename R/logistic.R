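# Design construction, fixed-effects logistic regression (IRLS), odds-ratio
# tables and generalized variance inflation factors.

#' Model design specification
#'
#' Declares the model terms, their reference levels and the clustering
#' variable. The default mirrors the determinant models of the CHE analysis:
#' indicator-coded categorical terms with references No / Poorest / City
#' Corporation / Barisal / Female / under-60, clustered on the primary
#' sampling unit.
#'
#' @param terms Named list mapping a term name to a list with \code{column}
#'   (source column), \code{ref} (reference level) and optionally
#'   \code{labels} (recode map applied to the column first, e.g. 0/1 to
#'   No/Yes).
#' @param cluster Column holding the level-2 cluster identifier.
#' @return A \code{design_spec}.
#' @export
design_spec <- function(terms = default_terms(), cluster = "psu_id") {
  structure(list(terms = terms, cluster = cluster), class = "design_spec")
}

#' @rdname design_spec
#' @export
default_terms <- function() {
  yn <- c("0" = "No", "1" = "Yes")
  list(
    old_age   = list(column = "old_age_present", ref = "No", labels = yn),
    child     = list(column = "child_present", ref = "No", labels = yn),
    wealth    = list(column = "wealth_quintile", ref = "Poorest"),
    chronic   = list(column = "chronic_disease_present", ref = "No", labels = yn),
    residence = list(column = "residence", ref = "city_corporation"),
    division  = list(column = "division", ref = "Barisal"),
    educated  = list(column = "head_educated", ref = "No", labels = yn),
    head_sex  = list(column = "head_sex", ref = "female"),
    head_age  = list(column = "head_age_over60", ref = "No", labels = yn)
  )
}

#' Build the indicator-coded design matrix
#'
#' One intercept column plus one indicator column per non-reference level of
#' each term, named \code{term:level}. Rows align with the table order.
#'
#' @param table A \code{survey_table} (after [add_wealth_index()] when the
#'   spec includes a wealth term).
#' @param spec A \code{design_spec}.
#' @return List with \code{X} (design matrix), \code{cluster} (vector) and
#'   \code{term_of_column} (named character vector mapping non-intercept
#'   columns to their term).
#' @export
build_design <- function(table, spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  cols <- list("(Intercept)" = rep(1, nrow(table)))
  term_of_column <- character(0)
  for (tname in names(spec$terms)) {
    tm <- spec$terms[[tname]]
    if (!tm$column %in% names(table)) stop("missing model column: ", tm$column)
    v <- as.character(table[[tm$column]])
    if (!is.null(tm$labels)) v <- unname(tm$labels[v])
    lev <- unique(v)
    if (!tm$ref %in% lev) {
      stop("reference level '", tm$ref, "' absent from observed levels of term '",
           tname, "'")
    }
    for (l in setdiff(sort(lev), tm$ref)) {
      nm <- paste0(tname, ":", l)
      cols[[nm]] <- as.numeric(v == l)
      term_of_column[nm] <- tname
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, cluster = table[[spec$cluster]], term_of_column = term_of_column)
}

#' Fixed-effects logistic regression by IRLS
#'
#' Maximum likelihood via iteratively reweighted least squares (Newton
#' scoring). Convergence when the largest score component falls below
#' \code{tol_score} or the relative log-likelihood change falls below
#' \code{tol_loglik}. The variance-covariance matrix is the inverse observed
#' information at the optimum. Diverging coefficients (complete or
#' quasi-complete separation) raise an explicit non-convergence error.
#'
#' @param X Design matrix (full column rank, including intercept).
#' @param y Binary 0/1 response.
#' @param tol_score,tol_loglik,max_iter Convergence controls.
#' @return A \code{logit_fit}: \code{coefficients}, \code{vcov},
#'   \code{loglik}, \code{fitted}, \code{n}, \code{converged},
#'   \code{iterations}.
#' @export
fit_logistic <- function(X, y, tol_score = 1e-8, tol_loglik = 1e-10,
                         max_iter = 200L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  p <- ncol(X)
  beta <- numeric(p)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    score <- drop(crossprod(X, y - mu))
    w <- mu * (1 - mu)
    info <- crossprod(X * w, X)
    ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (max(abs(score)) < tol_score ||
        (is.finite(ll_old) && abs(ll - ll_old) < tol_loglik * (abs(ll) + 1))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(beta)) > 30) {
      stop("logistic fit did not converge: diverging coefficients suggest separation")
    }
  }
  if (!converged) stop("logistic fit did not converge in ", max_iter, " iterations")
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 vcov = solve(info), loglik = ll, fitted = mu,
                 linear_predictor = eta, n = length(y),
                 converged = converged, iterations = it),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Logistic regression fit:", x$n, "observations,",
      length(x$coefficients), "coefficients; log-likelihood",
      format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' Adjusted odds ratios with Wald confidence intervals
#'
#' \code{exp(beta)} with \code{exp(beta +/- z * se)} limits and Wald
#' p-values. The intercept row is included; reference levels (absorbed into
#' the intercept) do not appear.
#'
#' @param fit A \code{logit_fit} or \code{mixed_logit_fit}.
#' @param level Confidence level (default 0.95).
#' @return Data frame with \code{term}, \code{estimate} (log-odds), \code{se},
#'   \code{aor}, \code{ci_lower}, \code{ci_upper}, \code{p_value}.
#' @export
odds_ratios <- function(fit, level = 0.95) {
  b <- fit$coefficients
  se <- sqrt(diag(fit$vcov)[seq_along(b)])
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(b), estimate = unname(b), se = unname(se),
             aor = exp(unname(b)),
             ci_lower = exp(unname(b) - zq * se),
             ci_upper = exp(unname(b) + zq * se),
             p_value = 2 * stats::pnorm(-abs(unname(b) / se)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generalized variance inflation factors
#'
#' For each term with design-column set A and complement B (all other
#' non-intercept columns), \code{GVIF = det(R_AA) det(R_BB) / det(R)} with R
#' the correlation matrix of the design columns. The adjusted value
#' \code{GVIF^(1/(2 df))} is comparable across terms of different df; its
#' square \code{GVIF^(1/df)} is reported alongside. For single-column terms
#' GVIF equals the classical VIF.
#'
#' @param X Design matrix including intercept (excluded from the correlation
#'   computation).
#' @param term_of_column Named character vector mapping non-intercept column
#'   names to term names, as returned by [build_design()].
#' @return Data frame with \code{term}, \code{gvif}, \code{df},
#'   \code{adjusted_gvif}, \code{squared_adjusted_gvif}.
#' @export
gvif <- function(X, term_of_column) {
  keep <- setdiff(colnames(X), "(Intercept)")
  if (length(unique(term_of_column[keep])) < 2L) stop("need at least 2 terms")
  R <- stats::cor(X[, keep, drop = FALSE])
  detR <- det(R)
  if (detR <= 0) stop("singular design correlation matrix")
  terms <- unique(term_of_column[keep])
  rows <- lapply(terms, function(tm) {
    A <- keep[term_of_column[keep] == tm]
    B <- setdiff(keep, A)
    g <- det(R[A, A, drop = FALSE]) * det(R[B, B, drop = FALSE]) / detR
    data.frame(term = tm, gvif = g, df = length(A),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- gvif_adjust(out$gvif, out$df)
  out$adjusted_gvif <- adj$adjusted_gvif
  out$squared_adjusted_gvif <- adj$squared_adjusted_gvif
  out
}

#' GVIF adjustment arithmetic
#'
#' \code{adjusted = GVIF^(1/(2 df))} and
#' \code{squared adjusted = GVIF^(1/df)}.
#'
#' @param gvif GVIF value(s).
#' @param df Term degrees of freedom (number of design columns).
#' @return Data frame with \code{adjusted_gvif} and
#'   \code{squared_adjusted_gvif}.
#' @export
gvif_adjust <- function(gvif, df) {
  stopifnot(all(gvif > 0), all(df >= 1))
  data.frame(adjusted_gvif = gvif^(1 / (2 * df)),
             squared_adjusted_gvif = gvif^(1 / df))
}
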
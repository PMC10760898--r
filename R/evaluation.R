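# ROC curves, Mann-Whitney AUC, and threshold sensitivity analysis.

#' ROC curve points
#'
#' One (false-positive rate, true-positive rate) point per distinct score
#' threshold (prediction rule: score >= threshold), preceded by the (0, 0)
#' endpoint, computed by sorting scores in decreasing order and accumulating
#' class counts. Both coordinates are non-decreasing and the curve ends at
#' (1, 1).
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return A \code{roc_curve}: data frame with \code{fpr}, \code{tpr} and
#'   attribute \code{auc}.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)
  out <- data.frame(fpr = c(0, fp[last_of_tie] / n0),
                    tpr = c(0, tp[last_of_tie] / n1))
  structure(out, auc = auc(scores, labels),
            class = c("roc_curve", "data.frame"))
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' The probability that a random positive outscores a random negative, ties
#' counted one half: computed from mid-ranks as
#' \code{(sum of positive ranks - n1 (n1 + 1) / 2) / (n1 n0)}.
#'
#' @inheritParams roc_points
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity of model discrimination to the CHE threshold policy
#'
#' For each policy: relabel CHE, fit the fixed-effects and the
#' random-intercept logistic model with the same design, and report each
#' model's in-sample AUC. The mixed-model score is the cluster-specific
#' linear predictor including the empirical-Bayes mode of the cluster
#' intercept; this is what gives the mixed model its extra discrimination.
#'
#' @param table A \code{survey_table} (with wealth columns when the spec
#'   needs them).
#' @param policies List of \code{threshold_policy} objects.
#' @param spec A \code{design_spec}.
#' @param thresholds A \code{region_thresholds} table for data-driven
#'   policies.
#' @param n_quad Quadrature nodes for the mixed fits.
#' @return Data frame with \code{policy}, \code{basis}, \code{level},
#'   \code{prevalence_pct}, \code{auc_fixed}, \code{auc_mixed}.
#' @export
threshold_sensitivity <- function(table, policies, spec = design_spec(),
                                  thresholds = NULL, n_quad = 15L) {
  d <- build_design(table, spec)
  rows <- lapply(policies, function(pol) {
    lab <- che_label(table, pol, thresholds)
    y <- lab$che[match(table$hh_id, lab$hh_id)]
    if (length(unique(y)) < 2L) {
      stop("degenerate labelling (single class) under policy ", pol$kind,
           if (!is.null(pol$level)) paste0(" at level ", pol$level))
    }
    aucs <- tryCatch({
      ffix <- fit_logistic(d$X, y)
      fmix <- fit_mixed_logit(d$X, y, d$cluster, n_quad = n_quad)
      c(auc(ffix$linear_predictor, y), auc(fmix$linear_predictor, y))
    }, error = function(e) {
      warning("model fit failed under policy ", pol$kind, ": ",
              conditionMessage(e), call. = FALSE)
      c(NA_real_, NA_real_)
    })
    data.frame(policy = pol$kind, basis = pol$basis,
               level = if (is.null(pol$level)) NA_real_ else pol$level,
               prevalence_pct = 100 * mean(y),
               auc_fixed = aucs[1], auc_mixed = aucs[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
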
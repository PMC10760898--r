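# Random-intercept logistic regression by adaptive Gauss-Hermite quadrature.
#
# The marginal likelihood integrates the cluster-level random intercept out
# of the conditional Bernoulli likelihood:
#   L_j(beta, sigma) = Int prod_i Bern(y_ij; plogis(x_ij beta + u)) phi(u; 0, sigma^2) du.
# Each cluster integral is approximated by Gauss-Hermite quadrature with the
# nodes recentered at the cluster's posterior mode and rescaled by the
# curvature there (adaptive GH). Non-adaptive GH is inaccurate at the
# cluster sizes (~20) this analysis uses.

gh_rule <- function(n_quad) {
  stopifnot(n_quad >= 5L)
  pracma::gaussHermite(n_quad)
}

log_sum_exp <- function(m) {
  # rows = clusters, cols = nodes
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

bern_loglik_by_cluster <- function(eta, y, cl, n_cl) {
  p <- stats::plogis(eta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  drop(rowsum(y * log(p) + (1 - y) * log(1 - p), cl, reorder = TRUE))
}

# Posterior modes of the random intercepts at fixed (beta, sigma): Newton
# iterations vectorised over clusters. Returns modes and the curvature scale
# tau_j = (-d2/du2 log posterior)^(-1/2).
posterior_modes <- function(eta, y, cl, n_cl, sigma) {
  s2 <- sigma^2
  u <- numeric(n_cl)
  for (it in 1:100) {
    p <- stats::plogis(eta + u[cl])
    g1 <- drop(rowsum(y - p, cl, reorder = TRUE)) - u / s2
    g2 <- -(drop(rowsum(p * (1 - p), cl, reorder = TRUE)) + 1 / s2)
    step <- -g1 / g2
    step <- pmin(pmax(step, -4), 4)
    u <- u + step
    if (max(abs(step)) < 1e-11) break
  }
  p <- stats::plogis(eta + u[cl])
  h <- drop(rowsum(p * (1 - p), cl, reorder = TRUE)) + 1 / s2
  list(u = u, tau = 1 / sqrt(h))
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' Evaluates the adaptive Gauss-Hermite approximation to the marginal
#' log-likelihood at fixed parameters. Exposed so the approximation can be
#' compared against dense numerical integration.
#'
#' @param beta Fixed-effect coefficient vector (\code{length == ncol(X)}).
#' @param sigma_u Random-intercept SD, \code{>= 0}. At \code{sigma_u = 0} the
#'   plain logistic log-likelihood is returned.
#' @param X Design matrix.
#' @param y Binary response.
#' @param cluster Cluster identifiers.
#' @param n_quad Number of quadrature nodes (default 15).
#' @return The marginal log-likelihood (scalar) with attribute \code{u_hat},
#'   the posterior modes per cluster.
#' @export
mixed_logit_loglik <- function(beta, sigma_u, X, y, cluster, n_quad = 15L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), length(cluster) == length(y),
            ncol(X) == length(beta), sigma_u >= 0)
  cl <- as.integer(factor(cluster))
  n_cl <- max(cl)
  eta <- drop(X %*% beta)
  if (sigma_u < 1e-8) {
    ll <- sum(bern_loglik_by_cluster(eta, y, cl, n_cl))
    return(structure(ll, u_hat = numeric(n_cl)))
  }
  gh <- gh_rule(n_quad)
  mode <- posterior_modes(eta, y, cl, n_cl, sigma_u)
  K <- length(gh$x)
  logint <- matrix(NA_real_, n_cl, K)
  for (k in seq_len(K)) {
    u_k <- mode$u + sqrt(2) * mode$tau * gh$x[k]
    g_k <- bern_loglik_by_cluster(eta + u_k[cl], y, cl, n_cl) +
      stats::dnorm(u_k, 0, sigma_u, log = TRUE)
    logint[, k] <- log(gh$w[k]) + gh$x[k]^2 + g_k
  }
  ll <- sum(log(sqrt(2) * mode$tau) + log_sum_exp(logint))
  structure(ll, u_hat = mode$u)
}

#' Fit the random-intercept logistic model
#'
#' Maximizes the adaptive-GH marginal likelihood over \code{(beta, log
#' sigma_u)} by quasi-Newton (L-BFGS-B, with \code{log sigma_u} bounded below
#' so a vanishing variance component is reported as a boundary fit rather
#' than a numerical failure). Standard errors come from the numerically
#' differentiated Hessian at the optimum. Empirical-Bayes modes of the
#' cluster intercepts are returned for cluster-specific prediction.
#'
#' @param X Design matrix including intercept.
#' @param y Binary 0/1 response.
#' @param cluster Cluster identifiers (level-2 units, e.g. PSUs).
#' @param n_quad Quadrature nodes, \code{>= 5} (default 15).
#' @param start Optional list with \code{beta} and \code{sigma_u} starting
#'   values; defaults to the fixed-effects fit and \code{sigma_u = 0.5}.
#' @param max_iter Maximum optimizer iterations.
#' @return A \code{mixed_logit_fit}: \code{coefficients}, \code{sigma_u},
#'   \code{icc_value} (latent-scale ICC of the fitted model), \code{vcov}
#'   (fixed effects), \code{loglik} (marginal), \code{u_hat}, \code{fitted}
#'   (cluster-specific probabilities), \code{n}, \code{n_clusters},
#'   \code{n_quad}, \code{converged}, \code{boundary}.
#' @export
fit_mixed_logit <- function(X, y, cluster, n_quad = 15L, start = NULL,
                            max_iter = 200L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  cl_f <- factor(cluster)
  cl <- as.integer(cl_f)
  n_cl <- max(cl)
  if (n_cl < 2L) stop("need at least 2 clusters")
  p <- ncol(X)

  if (is.null(start)) {
    beta0 <- tryCatch(fit_logistic(X, y)$coefficients,
                      error = function(e) numeric(p))
    start <- list(beta = beta0, sigma_u = 0.5)
  }
  par0 <- c(start$beta, log(max(start$sigma_u, 1e-3)))

  negll <- function(par) {
    -as.numeric(mixed_logit_loglik(par[seq_len(p)], exp(par[p + 1L]), X, y,
                                   cl, n_quad))
  }
  opt <- stats::optim(par0, negll, method = "L-BFGS-B",
                      lower = c(rep(-Inf, p), -8),
                      upper = c(rep(Inf, p), 3),
                      control = list(maxit = max_iter, factr = 1e7))
  beta <- stats::setNames(opt$par[seq_len(p)], colnames(X))
  sigma_u <- unname(exp(opt$par[p + 1L]))
  boundary <- opt$par[p + 1L] <= -8 + 1e-6 || sigma_u < 1e-3
  if (boundary) sigma_u <- 0

  H <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
  vc <- NULL
  if (!is.null(H)) {
    vc <- tryCatch(solve(H)[seq_len(p), seq_len(p), drop = FALSE],
                   error = function(e) NULL)
  }
  if (is.null(vc) || any(!is.finite(vc)) || any(diag(vc) <= 0)) {
    # boundary or near-singular curvature in the variance direction: fall
    # back to the fixed-effect block of the information
    vc <- tryCatch(solve(H[seq_len(p), seq_len(p), drop = FALSE]),
                   error = function(e) matrix(NA_real_, p, p))
  }
  dimnames(vc) <- list(colnames(X), colnames(X))

  final <- mixed_logit_loglik(beta, sigma_u, X, y, cl, n_quad)
  u_hat <- stats::setNames(attr(final, "u_hat"), levels(cl_f))
  eta_cond <- drop(X %*% beta) + u_hat[cl]
  structure(list(coefficients = beta, sigma_u = sigma_u,
                 icc_value = icc(sigma_u^2), vcov = vc,
                 loglik = as.numeric(final), u_hat = u_hat,
                 linear_predictor = unname(eta_cond),
                 fitted = unname(stats::plogis(eta_cond)),
                 n = length(y), n_clusters = n_cl, n_quad = n_quad,
                 converged = opt$convergence == 0L, iterations = opt$counts[["function"]],
                 boundary = boundary),
            class = c("mixed_logit_fit", "logit_fit"))
}

#' Fit the empty (intercept-only) random-intercept model
#'
#' The first step of the usual multilevel workflow: how much do the log odds
#' vary from cluster to cluster before any covariate enters. Its
#' \code{icc_value} is the ICC usually quoted for the outcome.
#'
#' @inheritParams fit_mixed_logit
#' @return A \code{mixed_logit_fit}.
#' @export
fit_empty_mixed <- function(y, cluster, n_quad = 15L) {
  X <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  fit_mixed_logit(X, y, cluster, n_quad = n_quad)
}

#' @export
print.mixed_logit_fit <- function(x, ...) {
  cat("Random-intercept logistic fit:", x$n, "observations in", x$n_clusters,
      "clusters\n  sigma_u =", format(x$sigma_u, digits = 4),
      if (x$boundary) "(boundary)" else "",
      "; ICC =", format(x$icc_value, digits = 4),
      "; marginal log-likelihood", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' Latent-scale intraclass correlation
#'
#' Share of latent outcome variance attributable to between-cluster
#' differences: \code{sigma_u^2 / (sigma_u^2 + pi^2/3)}, where pi^2/3 is the
#' variance of the standard logistic distribution.
#'
#' @param sigma_u2 Random-intercept variance, \code{>= 0}.
#' @return Proportion in [0, 1).
#' @export
icc <- function(sigma_u2) {
  if (any(sigma_u2 < 0)) stop("variance must be >= 0")
  sigma_u2 / (sigma_u2 + pi^2 / 3)
}

#' Likelihood-ratio test for nested models
#'
#' Statistic \code{2 (loglik_full - loglik_restricted)} against a chi-square
#' null with \code{df} degrees of freedom. When the tested parameter sits on
#' the boundary of its space (a variance component), the 50:50
#' chi-square(0)/chi-square(1) mixture p-value is reported alongside the
#' naive one; both are returned so either convention can be quoted.
#'
#' @param loglik_restricted,loglik_full Maximized log-likelihoods of the
#'   nested and the larger model.
#' @param df Difference in parameter count.
#' @param boundary Is the restriction on a variance-component boundary?
#' @return List with \code{statistic}, \code{df}, \code{p_value} (naive
#'   chi-square) and \code{p_boundary} (mixture; \code{NA} unless
#'   \code{boundary}).
#' @export
lrt <- function(loglik_restricted, loglik_full, df = 1L, boundary = FALSE) {
  stat <- 2 * (loglik_full - loglik_restricted)
  if (stat < -1e-6) stop("full model has lower log-likelihood than restricted model")
  stat <- max(stat, 0)
  p_naive <- stats::pchisq(stat, df, lower.tail = FALSE)
  p_bound <- if (boundary) {
    if (stat == 0) 1 else 0.5 * stats::pchisq(stat, 1L, lower.tail = FALSE)
  } else NA_real_
  list(statistic = stat, df = df, p_value = p_naive, p_boundary = p_bound)
}
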
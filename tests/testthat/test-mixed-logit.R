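sim_mixed_data <- function(seed, n_cl = 30L, m = 10L,
                           beta = c(-1, 1), sigma_u = 0.8) {
  set.seed(seed)
  n <- n_cl * m
  X <- cbind(1, x = rbinom(n, 1, 0.4))
  cl <- rep(seq_len(n_cl), each = m)
  y <- generate_logit_outcome(X, cl, beta, sigma_u, seed = seed + 1L)
  list(X = X, y = y, cl = cl)
}

test_that("latent-scale ICC follows the logistic-variance formula", {
  expect_equal(icc(0), 0)
  expect_equal(icc(pi^2 / 3), 0.5)
  expect_equal(icc(0.7224^2), 0.13691, tolerance = 2e-5)
  s <- seq(0, 5, by = 0.5)
  expect_true(!is.unsorted(icc(s)))
  expect_true(all(icc(s) >= 0 & icc(s) < 1))
  expect_error(icc(-0.1))
})

test_that("likelihood-ratio test arithmetic and boundary mixture", {
  eq <- lrt(-50, -50)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  out <- lrt(-100, -95, df = 1L)
  expect_equal(out$statistic, 10)
  expect_equal(out$p_value, pchisq(10, 1, lower.tail = FALSE))
  b <- lrt(-100, -95, df = 1L, boundary = TRUE)
  expect_equal(b$p_boundary, 0.5 * b$p_value)
  expect_error(lrt(-90, -95), "lower log-likelihood")
})

test_that("adaptive quadrature matches dense numeric integration", {
  d <- sim_mixed_data(11L, n_cl = 10L, m = 5L)
  for (pars in list(c(-1, 1, 0.72), c(0.5, -0.8, 1.5), c(0, 0, 0.3))) {
    agh <- as.numeric(mixed_logit_loglik(pars[1:2], pars[3], d$X, d$y, d$cl))
    dense <- oracle_mixed_loglik(pars[1:2], pars[3], d$X, d$y, d$cl)
    expect_equal(agh, dense, tolerance = 1e-6)
  }
  # refining the rule does not move the approximation
  a15 <- as.numeric(mixed_logit_loglik(c(-1, 1), 0.72, d$X, d$y, d$cl, n_quad = 15L))
  a25 <- as.numeric(mixed_logit_loglik(c(-1, 1), 0.72, d$X, d$y, d$cl, n_quad = 25L))
  expect_lt(abs(a15 - a25), 1e-6)
})

test_that("sigma_u = 0 data collapse to the plain logistic fit", {
  d <- sim_mixed_data(21L, n_cl = 60L, m = 20L, sigma_u = 0)
  mfit <- fit_mixed_logit(d$X, d$y, d$cl)
  ffit <- fit_logistic(d$X, d$y)
  expect_true(mfit$boundary)
  expect_equal(mfit$sigma_u, 0)
  expect_equal(unname(mfit$coefficients), unname(ffit$coefficients),
               tolerance = 1e-3)
  expect_equal(mfit$loglik, ffit$loglik, tolerance = 1e-4)
})

test_that("the marginal likelihood never falls below the nested fixed fit", {
  d <- sim_mixed_data(22L)
  mfit <- fit_mixed_logit(d$X, d$y, d$cl)
  ffit <- fit_logistic(d$X, d$y)
  expect_gte(mfit$loglik, ffit$loglik - 1e-6)
  expect_true(mfit$converged)
  expect_true(all(is.finite(diag(mfit$vcov))))
})

test_that("estimates agree with lme4::glmer at matched quadrature", {
  skip_if_not_installed("lme4")
  d <- sim_mixed_data(23L, n_cl = 40L, m = 12L, beta = c(-0.5, 0.9), sigma_u = 0.7)
  mfit <- fit_mixed_logit(d$X, d$y, d$cl)
  df <- data.frame(y = d$y, x = d$X[, "x"], cl = d$cl)
  ref <- lme4::glmer(y ~ x + (1 | cl), data = df, family = binomial, nAGQ = 15L)
  expect_equal(unname(mfit$coefficients), unname(lme4::fixef(ref)),
               tolerance = 5e-3)
  expect_equal(mfit$sigma_u, sqrt(unname(lme4::VarCorr(ref)$cl[1])),
               tolerance = 1e-2)
  expect_equal(mfit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-3)
  se_ref <- sqrt(diag(as.matrix(stats::vcov(ref))))
  expect_equal(sqrt(diag(mfit$vcov)), unname(se_ref), tolerance = 0.03,
               ignore_attr = TRUE)
})

test_that("the empty model is the intercept-only mixed fit", {
  d <- sim_mixed_data(24L, n_cl = 25L, m = 8L, beta = c(-0.5, 0), sigma_u = 0.6)
  emp <- fit_empty_mixed(d$y, d$cl)
  man <- fit_mixed_logit(matrix(1, length(d$y), 1L,
                                dimnames = list(NULL, "(Intercept)")),
                         d$y, d$cl)
  expect_equal(emp$coefficients, man$coefficients, tolerance = 1e-6)
  expect_equal(emp$sigma_u, man$sigma_u, tolerance = 1e-6)
  expect_equal(emp$icc_value, icc(emp$sigma_u^2))

  # clusters with identical outcome rates leave nothing for the intercept to absorb
  y0 <- rep(rep(c(1, 0), times = c(3, 7)), 10)
  cl0 <- rep(1:10, each = 10)
  emp0 <- fit_empty_mixed(y0, cl0)
  expect_true(emp0$boundary)
  expect_equal(emp0$sigma_u, 0)
})

test_that("empirical-Bayes modes track observed cluster deviations", {
  d <- sim_mixed_data(25L, n_cl = 30L, m = 20L, beta = c(0, 0), sigma_u = 1)
  mfit <- fit_mixed_logit(d$X, d$y, d$cl)
  rate <- tapply(d$y, d$cl, mean)
  expect_gt(cor(mfit$u_hat, rate), 0.8)
  expect_equal(length(mfit$u_hat), 30L)
})
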
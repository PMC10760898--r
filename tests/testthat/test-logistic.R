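full_design_df <- function() {
  div <- c("Barisal", "Chittagong", "Dhaka", "Khulna", "Mymensingh",
           "Rajshahi", "Rangpur", "Sylhet")
  wq <- c("Poorest", "Second", "Third", "Fourth", "Richest")
  n <- 120L
  set.seed(71)
  data.frame(
    old_age_present = rbinom(n, 1, 0.3), child_present = rbinom(n, 1, 0.5),
    wealth_quintile = sample(wq, n, TRUE),
    chronic_disease_present = rbinom(n, 1, 0.4),
    residence = sample(residence_levels(), n, TRUE),
    division = sample(div, n, TRUE),
    head_educated = rbinom(n, 1, 0.5),
    head_sex = sample(c("female", "male"), n, TRUE),
    head_age_over60 = rbinom(n, 1, 0.2),
    psu_id = sample(sprintf("p%02d", 1:10), n, TRUE),
    stringsAsFactors = FALSE
  )
}

test_that("indicator coding yields one column per non-reference level", {
  df <- full_design_df()
  d <- build_design(df, design_spec())
  expect_equal(ncol(d$X), 20L)  # intercept + 1+1+4+1+2+7+1+1+1
  expect_equal(colnames(d$X)[1], "(Intercept)")
  expect_equal(sum(d$term_of_column == "wealth"), 4L)
  expect_equal(sum(d$term_of_column == "division"), 7L)
  expect_false(any(grepl("Barisal|Poorest|city_corporation", colnames(d$X))))
  expect_equal(length(d$cluster), nrow(df))
  # reference level absent from the data is an error
  df2 <- df; df2$division <- "Dhaka"
  expect_error(build_design(df2, design_spec()), "reference level 'Barisal'")
})

test_that("intercept-only and saturated fits match their closed forms", {
  y <- c(rep(1, 30), rep(0, 70))
  X <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_logistic(X, y)
  expect_equal(unname(fit$coefficients), log(30 / 70), tolerance = 1e-8)

  # 2x2 cells (x=1: 20/80, x=0: 10/90): slope is the sample log odds ratio
  x <- c(rep(1, 100), rep(0, 100))
  y2 <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  fit2 <- fit_logistic(cbind(1, x = x), y2)
  expect_equal(unname(fit2$coefficients[2]), log((20 / 80) / (10 / 90)),
               tolerance = 1e-8)
  expect_equal(unname(fit2$coefficients[2]), log(2.25), tolerance = 1e-8)
})

test_that("IRLS matches stats::glm on random data", {
  set.seed(72)
  for (rep in 1:5) {
    n <- 300L
    X <- cbind(1, matrix(rnorm(n * 3), n, 3))
    colnames(X) <- c("(Intercept)", "x1", "x2", "x3")
    y <- rbinom(n, 1, plogis(drop(X %*% c(-0.5, 0.8, -0.4, 0.2))))
    fit <- fit_logistic(X, y)
    ref <- glm.fit(X, y, family = binomial())
    expect_equal(unname(fit$coefficients), unname(ref$coefficients),
                 tolerance = 1e-6)
    expect_equal(fit$loglik,
                 sum(dbinom(y, 1, ref$fitted.values, log = TRUE)),
                 tolerance = 1e-8)
    expect_true(isSymmetric(fit$vcov, tol = 1e-10))
    expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > 0))
  }
})

test_that("separation raises an explicit non-convergence error", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x
  expect_error(fit_logistic(cbind(1, x = x), y), "separation")
  expect_error(fit_logistic(cbind(1, x = x, x2 = x), y), "rank deficient")
})

test_that("odds ratios exponentiate with Wald limits", {
  fit <- structure(list(coefficients = c(a = 0, b = log(2)),
                        vcov = diag(c(0.01, 0.04))), class = "logit_fit")
  or <- odds_ratios(fit)
  expect_equal(or$aor, c(1, 2))
  expect_equal(or$ci_lower[1], exp(-qnorm(0.975) * 0.1), tolerance = 1e-10)
  expect_equal(round(or$ci_lower[1], 2), 0.82)
  expect_equal(round(or$ci_upper[1], 2), 1.22)
  expect_true(all(or$ci_lower <= or$aor & or$aor <= or$ci_upper))
})

test_that("orthogonal single-column terms have GVIF 1", {
  X <- cbind("(Intercept)" = 1,
             "a:Yes" = rep(c(1, -1), 50),
             "b:Yes" = rep(c(1, 1, -1, -1), 25))
  out <- gvif(X, c("a:Yes" = "a", "b:Yes" = "b"))
  expect_equal(out$gvif, c(1, 1), tolerance = 1e-12)
  expect_equal(out$squared_adjusted_gvif, out$gvif)
})

test_that("GVIF adjustment powers reproduce the published arithmetic", {
  adj <- gvif_adjust(c(1.12, 1.38), c(4L, 1L))
  expect_equal(round(adj$adjusted_gvif, 2), c(1.01, 1.17))
  expect_equal(round(adj$squared_adjusted_gvif, 2), c(1.03, 1.38))
})

test_that("GVIF matches car::vif on a categorical design", {
  skip_if_not_installed("car")
  df <- full_design_df()
  set.seed(73)
  df$y <- rnorm(nrow(df))
  d <- build_design(df, design_spec())
  out <- gvif(d$X, d$term_of_column)
  # the design-correlation GVIF is what car computes for a linear model
  ref <- car::vif(lm(y ~ factor(old_age_present) + factor(child_present) +
                       wealth_quintile + factor(chronic_disease_present) +
                       residence + division + factor(head_educated) +
                       head_sex + factor(head_age_over60),
                     data = df))
  expect_equal(out$gvif, unname(ref[, "GVIF"]), tolerance = 1e-6)
  expect_equal(out$df, unname(as.integer(ref[, "Df"])))
  # single-column terms: GVIF is the classical VIF, squared adjusted = GVIF
  single <- out$df == 1L
  expect_equal(out$squared_adjusted_gvif[single], out$gvif[single])
  expect_true(all(out$gvif >= 1 - 1e-8))
})
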
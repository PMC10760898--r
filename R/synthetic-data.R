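# Synthetic household-survey generator.
#
# Two generators are provided on purpose. The structural expenditure
# generator emulates the features the threshold pipeline needs from a
# stratified two-stage cluster expenditure survey: division-by-residence
# strata, PSUs nested in districts, lognormal per-capita total expenditure,
# a Beta food share, a two-part (any/amount) out-of-pocket health spending
# model with a PSU-level random effect, and a one-factor latent asset model
# so the first principal component is a meaningful wealth signal. The direct
# logit-outcome generator simulates exactly the random-intercept logistic
# law the regression module assumes, for estimator-recovery tests.

#' Simulation configuration for the expenditure survey generator
#'
#' @param strata Data frame with columns \code{stratum_id}, \code{division},
#'   \code{residence}; defaults to 16 division-by-residence strata.
#' @param districts_per_stratum,psus_per_district,hh_per_psu Design counts
#'   (all \code{>= 1}). The source survey drew 20 households per PSU.
#' @param seed Integer RNG seed.
#' @param prevalence Named list of covariate prevalences (probabilities):
#'   \code{old_age}, \code{child}, \code{chronic}, \code{head_educated},
#'   \code{head_male}, \code{head_over60}.
#' @param log_pc_total_mean Named vector, mean of log per-capita total
#'   expenditure by residence level (currency/person/month on log scale).
#' @param log_pc_total_sd SD of log per-capita total expenditure.
#' @param food_share_shape1,food_share_shape2 Beta parameters of the food
#'   share of total expenditure.
#' @param health_any Coefficients of the logistic any-spending model:
#'   intercept, chronic, old_age, wealth.
#' @param health_amount Coefficients of the lognormal positive-spending
#'   model: intercept (log currency), chronic, old_age, wealth, plus
#'   \code{sd} of the log-amount noise.
#' @param psu_sigma SD of the PSU-level random intercept on the latent
#'   health-spending scale (enters both parts of the two-part model).
#' @param n_assets Number of binary asset indicators (\code{>= 2}).
#' @param wealth_expenditure_cor Correlation between the latent wealth factor
#'   and log per-capita expenditure.
#' @param z Per-capita monthly poverty line.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(strata = default_strata(),
                       districts_per_stratum = 2L,
                       psus_per_district = 4L,
                       hh_per_psu = 20L,
                       seed = 20160401L,
                       prevalence = list(old_age = 0.18, child = 0.55,
                                         chronic = 0.35, head_educated = 0.50,
                                         head_male = 0.87, head_over60 = 0.20),
                       log_pc_total_mean = c(rural = log(2600),
                                             urban = log(2900),
                                             city_corporation = log(3200)),
                       log_pc_total_sd = 0.4,
                       food_share_shape1 = 11,
                       food_share_shape2 = 9,
                       health_any = c(intercept = 0.3, chronic = 1.2,
                                      old_age = 0.6, wealth = -0.1),
                       health_amount = c(intercept = log(50), chronic = 1.0,
                                         old_age = 0.5, wealth = 0.15,
                                         sd = 0.6),
                       psu_sigma = 0.3,
                       n_assets = 10L,
                       wealth_expenditure_cor = 0.6,
                       z = 2200) {
  cfg <- list(strata = strata,
              districts_per_stratum = as.integer(districts_per_stratum),
              psus_per_district = as.integer(psus_per_district),
              hh_per_psu = as.integer(hh_per_psu),
              seed = as.integer(seed),
              prevalence = prevalence,
              log_pc_total_mean = log_pc_total_mean,
              log_pc_total_sd = log_pc_total_sd,
              food_share_shape1 = food_share_shape1,
              food_share_shape2 = food_share_shape2,
              health_any = health_any,
              health_amount = health_amount,
              psu_sigma = psu_sigma,
              n_assets = as.integer(n_assets),
              wealth_expenditure_cor = wealth_expenditure_cor,
              z = z)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    is.data.frame(cfg$strata),
    all(c("stratum_id", "division", "residence") %in% names(cfg$strata)),
    nrow(cfg$strata) >= 1L,
    all(cfg$strata$residence %in% residence_levels()),
    cfg$districts_per_stratum >= 1L, cfg$psus_per_district >= 1L,
    cfg$hh_per_psu >= 1L,
    all(unlist(cfg$prevalence) >= 0), all(unlist(cfg$prevalence) <= 1),
    cfg$log_pc_total_sd >= 0,
    cfg$food_share_shape1 > 0, cfg$food_share_shape2 > 0,
    cfg$health_amount[["sd"]] >= 0,
    cfg$psu_sigma >= 0,
    cfg$n_assets >= 2L,
    abs(cfg$wealth_expenditure_cor) <= 1,
    cfg$z > 0
  )
  invisible(cfg)
}

#' Default division-by-residence strata
#'
#' Sixteen strata: rural and urban cells for six divisions plus city
#' corporation cells for the four divisions with one.
#'
#' @return Data frame with \code{stratum_id}, \code{division},
#'   \code{residence}.
#' @export
default_strata <- function() {
  div <- c("Barisal", "Chittagong", "Dhaka", "Khulna", "Rajshahi", "Sylhet")
  cc  <- c("Chittagong", "Dhaka", "Khulna", "Rajshahi")
  out <- rbind(
    data.frame(division = rep(div, each = 2L),
               residence = rep(c("rural", "urban"), times = length(div)),
               stringsAsFactors = FALSE),
    data.frame(division = cc, residence = "city_corporation",
               stringsAsFactors = FALSE)
  )
  pretty <- c(rural = "Rural", urban = "Urban", city_corporation = "City Corp.")
  out$stratum_id <- sprintf("%s (%s)", out$division, pretty[out$residence])
  out[order(out$division, out$residence), c("stratum_id", "division", "residence")]
}

#' Default desk-scale simulation configuration
#'
#' 16 strata x 2 districts x 4 PSUs x 20 households = 2,560 households.
#'
#' @param seed Integer RNG seed.
#' @return A \code{sim_config}.
#' @export
default_config <- function(seed = 20160401L) sim_config(seed = seed)

#' Generate a synthetic household expenditure survey
#'
#' Draws exactly \code{n_strata x districts_per_stratum x psus_per_district x
#' hh_per_psu} households satisfying every survey invariant. Health spending
#' is clamped to nonfood expenditure. The generator checks that a nonzero
#' fraction of households is pushed below the poverty line by health spending
#' and warns otherwise, since the data-driven thresholds are undefined in
#' that case.
#'
#' @param config A \code{sim_config}.
#' @return A \code{survey_table} with \code{asset_*} columns; the poverty
#'   line is attached as attribute \code{z}.
#' @export
generate_expenditure_survey <- function(config = default_config()) {
  validate_sim_config(config)
  with_seed(config$seed, generate_expenditure_survey_impl(config))
}

generate_expenditure_survey_impl <- function(cfg) {
  st <- cfg$strata
  n_strata <- nrow(st)
  n_districts <- n_strata * cfg$districts_per_stratum
  n_psus <- n_districts * cfg$psus_per_district
  n <- n_psus * cfg$hh_per_psu

  stratum_of_district <- rep(seq_len(n_strata), each = cfg$districts_per_stratum)
  district_of_psu <- rep(seq_len(n_districts), each = cfg$psus_per_district)
  psu_of_hh <- rep(seq_len(n_psus), each = cfg$hh_per_psu)
  district_of_hh <- district_of_psu[psu_of_hh]
  stratum_of_hh <- stratum_of_district[district_of_hh]

  district_lab <- sprintf("d%03d", seq_len(n_districts))
  psu_lab <- sprintf("psu%04d", seq_len(n_psus))

  hh_size <- 1L + stats::rpois(n, 3)
  prev <- cfg$prevalence
  old_age <- stats::rbinom(n, 1L, prev$old_age)
  child <- stats::rbinom(n, 1L, prev$child)
  chronic <- stats::rbinom(n, 1L, prev$chronic)
  head_educated <- stats::rbinom(n, 1L, prev$head_educated)
  head_sex <- ifelse(stats::rbinom(n, 1L, prev$head_male) == 1L, "male", "female")
  head_over60 <- stats::rbinom(n, 1L, prev$head_over60)

  res_of_hh <- st$residence[stratum_of_hh]
  log_pc_total <- stats::rnorm(n, cfg$log_pc_total_mean[res_of_hh], cfg$log_pc_total_sd)
  pc_total <- exp(log_pc_total)
  total_exp <- pc_total * hh_size

  # Latent wealth factor shares variance with log expenditure; drives both
  # asset ownership and health spending.
  rho <- cfg$wealth_expenditure_cor
  zscore <- (log_pc_total - mean(log_pc_total)) / stats::sd(log_pc_total)
  wealth <- rho * zscore + sqrt(1 - rho^2) * stats::rnorm(n)

  food_share <- stats::rbeta(n, cfg$food_share_shape1, cfg$food_share_shape2)
  food_exp <- food_share * total_exp
  nonfood <- total_exp - food_exp

  u_psu <- stats::rnorm(n_psus, 0, cfg$psu_sigma)
  u <- u_psu[psu_of_hh]
  a <- cfg$health_any
  p_any <- stats::plogis(a[["intercept"]] + a[["chronic"]] * chronic +
                           a[["old_age"]] * old_age + a[["wealth"]] * wealth + u)
  any_spend <- stats::rbinom(n, 1L, p_any)
  m <- cfg$health_amount
  log_amt <- m[["intercept"]] + m[["chronic"]] * chronic + m[["old_age"]] * old_age +
    m[["wealth"]] * wealth + u + stats::rnorm(n, 0, m[["sd"]])
  health_exp <- any_spend * hh_size * exp(log_amt)
  health_exp <- pmin(health_exp, nonfood)

  # Asset indicators from a one-factor model with spread difficulties.
  k <- cfg$n_assets
  lambda <- seq(0.8, 1.4, length.out = k)
  alpha <- seq(-1, 1, length.out = k)
  assets <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    assets[, j] <- as.integer(alpha[j] + lambda[j] * wealth + stats::rnorm(n) > 0)
  }
  colnames(assets) <- sprintf("asset_%02d", seq_len(k))

  df <- data.frame(
    hh_id = sprintf("hh%06d", seq_len(n)),
    stratum_id = st$stratum_id[stratum_of_hh],
    division = st$division[stratum_of_hh],
    residence = res_of_hh,
    district_id = district_lab[district_of_hh],
    psu_id = psu_lab[psu_of_hh],
    hh_size = hh_size,
    total_exp = total_exp,
    food_exp = food_exp,
    health_exp = health_exp,
    old_age_present = old_age,
    child_present = child,
    chronic_disease_present = chronic,
    head_educated = head_educated,
    head_sex = head_sex,
    head_age_over60 = head_over60,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(assets))
  tab <- as_survey_table(df)
  attr(tab, "z") <- cfg$z

  frac <- mean(impoverishing_flag(tab, cfg$z))
  if (frac == 0) {
    warning("no household is pushed below the poverty line by health spending; ",
            "data-driven thresholds will be undefined everywhere")
  }
  tab
}

#' Simulate binary outcomes from a random-intercept logistic model
#'
#' Draws one normal random intercept per cluster with SD \code{sigma_u} and
#' Bernoulli outcomes with success probability
#' \code{plogis(X beta + u[cluster])}. This is exactly the law the
#' multilevel fitting routines assume, so it is the reference generator for
#' parameter-recovery tests.
#'
#' @param X Design matrix (including the intercept column).
#' @param cluster Cluster identifier vector, \code{length(cluster) == nrow(X)}.
#' @param beta Fixed-effect coefficient vector, \code{length(beta) == ncol(X)}.
#' @param sigma_u Random-intercept SD, \code{>= 0}.
#' @param seed Integer RNG seed.
#' @return Integer 0/1 outcome vector.
#' @export
generate_logit_outcome <- function(X, cluster, beta, sigma_u, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) != length(cluster)) stop("cluster length must match design rows")
  if (ncol(X) != length(beta)) stop("beta length must match design columns")
  if (sigma_u < 0) stop("sigma_u must be >= 0")
  with_seed(seed, {
    cl <- as.integer(factor(cluster))
    u <- stats::rnorm(max(cl), 0, sigma_u)
    eta <- drop(X %*% beta) + u[cl]
    stats::rbinom(length(eta), 1L, stats::plogis(eta))
  })
}

#' Ground-truth parameters for recovery studies
#'
#' @param beta Named fixed-effect coefficient vector.
#' @param sigma_u Random-intercept SD.
#' @return A \code{true_params} list with the implied latent-scale ICC
#'   \code{sigma_u^2 / (sigma_u^2 + pi^2/3)}.
#' @export
true_params <- function(beta, sigma_u) {
  stopifnot(sigma_u >= 0)
  structure(list(beta = beta, sigma_u = sigma_u, icc = icc(sigma_u^2)),
            class = "true_params")
}
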
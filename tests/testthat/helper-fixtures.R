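# Fixture builders and independent oracles shared across tests. Oracles are
# deliberately written as naive loops with no code shared with the package.

# A small handcrafted survey data frame; override any column by name.
make_survey_df <- function(n = 4L, ...) {
  df <- data.frame(
    hh_id = sprintf("h%02d", seq_len(n)),
    stratum_id = "S1", division = "Barisal", residence = "rural",
    district_id = "d1", psu_id = "p1",
    hh_size = 4L, total_exp = 1200, food_exp = 600, health_exp = 100,
    old_age_present = 0L, child_present = 0L, chronic_disease_present = 0L,
    head_educated = 0L, head_sex = "male", head_age_over60 = 0L,
    asset_01 = rep(c(0L, 1L), length.out = n),
    asset_02 = rep(c(1L, 0L), length.out = n),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

small_sim <- function(seed, strata = default_strata()[1:4, ],
                      districts = 2L, psus = 2L, hh = 10L) {
  sim_config(strata = strata, districts_per_stratum = districts,
             psus_per_district = psus, hh_per_psu = hh, seed = seed)
}

# Brute-force re-implementation of the four-step data-driven threshold
# construction: per-household loops, no vectorised code from the package.
oracle_region_thresholds <- function(df, z) {
  strata <- unique(df$stratum_id)
  out <- data.frame(stratum_id = strata, t_nonfood = NA_real_,
                    t_total = NA_real_, n_qualifying = 0L,
                    stringsAsFactors = FALSE)
  for (si in seq_along(strata)) {
    shares_nf <- c(); shares_tt <- c()
    for (i in seq_len(nrow(df))) {
      if (df$stratum_id[i] != strata[si]) next
      pc_total <- df$total_exp[i] / df$hh_size[i]
      pc_netted <- (df$total_exp[i] - df$health_exp[i]) / df$hh_size[i]
      p <- if (pc_total < z) 1 else 0
      p_prime <- if (pc_netted < z) 1 else 0
      if (p == 0 && p_prime == 1) {
        shares_nf <- c(shares_nf, df$health_exp[i] / (df$total_exp[i] - df$food_exp[i]))
        shares_tt <- c(shares_tt, df$health_exp[i] / df$total_exp[i])
      }
    }
    out$n_qualifying[si] <- length(shares_tt)
    if (length(shares_tt) > 0L) {
      out$t_nonfood[si] <- sum(shares_nf) / length(shares_nf)
      out$t_total[si] <- sum(shares_tt) / length(shares_tt)
    }
  }
  out
}

# Pairwise-enumeration AUC with the 0.5 tie convention.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Textbook Pearson chi-square via explicit loops over cells.
oracle_chi_square <- function(ct) {
  n <- sum(ct)
  stat <- 0
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    e <- sum(ct[i, ]) * sum(ct[, j]) / n
    stat <- stat + (ct[i, j] - e)^2 / e
  }
  stat
}

# Dense trapezoid integration of the mixed-logit marginal likelihood, one
# cluster at a time, on a wide fixed grid in log space.
oracle_mixed_loglik <- function(beta, sigma_u, X, y, cluster, n_grid = 10000L,
                                width = 8) {
  cl <- as.integer(factor(cluster))
  eta <- drop(as.matrix(X) %*% beta)
  u_grid <- seq(-width, width, length.out = n_grid)
  du <- u_grid[2] - u_grid[1]
  total <- 0
  for (j in seq_len(max(cl))) {
    idx <- which(cl == j)
    lse <- -Inf
    vals <- numeric(n_grid)
    for (g in seq_len(n_grid)) {
      p <- plogis(eta[idx] + u_grid[g])
      vals[g] <- sum(y[idx] * log(p) + (1 - y[idx]) * log(1 - p)) +
        dnorm(u_grid[g], 0, sigma_u, log = TRUE)
    }
    m <- max(vals)
    # trapezoid weights in log space
    w <- rep(1, n_grid); w[c(1, n_grid)] <- 0.5
    total <- total + m + log(sum(w * exp(vals - m)) * du)
  }
  total
}
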
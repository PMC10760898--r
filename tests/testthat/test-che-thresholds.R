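test_that("poverty indicator uses a strict below-the-line comparison", {
  expect_equal(poverty_indicator(c(99.9, 100, 100.1), 100), c(1L, 0L, 0L))
  expect_error(poverty_indicator(-1, 100), "negative")
})

test_that("health-netted per-capita total follows the accounting identity", {
  df <- make_survey_df(3L, hh_size = c(4L, 2L, 2L),
                       total_exp = c(1200, 800, 1000),
                       food_exp = c(600, 400, 600),
                       health_exp = c(240, 0, 400))
  tab <- as_survey_table(df)
  expect_equal(health_netted_pc_total(tab), c(240, 400, 300))
  # zero health spending leaves per-capita total unchanged
  expect_equal(health_netted_pc_total(tab)[2], per_capita(tab, "total")[2])
  # health equal to all of nonfood leaves per-capita food expenditure
  expect_equal(health_netted_pc_total(tab)[3], tab$food_exp[3] / tab$hh_size[3])
})

test_that("impoverishment flags exactly the poverty-crossing households", {
  df <- make_survey_df(3L, hh_size = 1L,
                       total_exp = c(120, 90, 150),
                       food_exp = c(60, 45, 75),
                       health_exp = c(30, 10, 20))
  tab <- as_survey_table(df)
  # (120 >= 100, 90 < 100) -> TRUE; already poor -> FALSE; 130 >= 100 -> FALSE
  expect_equal(impoverishing_flag(tab, 100), c(TRUE, FALSE, FALSE))
})

test_that("region thresholds average shares over qualifying households only", {
  df <- make_survey_df(3L, hh_id = c("A", "B", "C"), hh_size = 1L,
                       total_exp = c(120, 150, 90),
                       food_exp = c(60, 75, 45),
                       health_exp = c(30, 20, 10))
  tab <- as_survey_table(df)
  # only A qualifies (120 >= 100 > 90); its total share is 30/120
  expect_equal(region_threshold(tab, "S1", 100, "total_share"), 0.25)
  expect_equal(region_threshold(tab, "S1", 100, "nonfood_share"), 30 / 60)
  # no qualifier -> undefined, never zero
  expect_true(is.na(region_threshold(tab, "S1", 1e6, "total_share")))
  thr <- all_region_thresholds(tab, 1e6)
  expect_equal(thr$n_qualifying, 0L)
  expect_true(is.na(thr$t_total))
})

test_that("threshold tables are order-invariant and undefined iff no qualifier", {
  tab <- generate_expenditure_survey(small_sim(101L))
  z <- attr(tab, "z")
  thr <- all_region_thresholds(tab, z)
  perm <- tab[sample(nrow(tab)), , drop = FALSE]
  thr2 <- all_region_thresholds(as_survey_table(as.data.frame(perm)), z)
  thr2 <- thr2[match(thr$stratum_id, thr2$stratum_id), ]
  rownames(thr2) <- NULL
  expect_equal(as.data.frame(thr), as.data.frame(thr2))
  expect_equal(is.na(thr$t_total), thr$n_qualifying == 0L)
  expect_equal(is.na(thr$t_nonfood), thr$n_qualifying == 0L)
  # for a common qualifying set, the total-basis mean cannot exceed nonfood
  defined <- !is.na(thr$t_total)
  expect_true(all(thr$t_total[defined] <= thr$t_nonfood[defined] + 1e-12))
})

test_that("threshold pipeline equals the brute-force oracle on random tables", {
  for (seed in c(201L, 202L, 203L)) {
    cfg <- small_sim(seed, strata = default_strata()[1:4, ], hh = 12L)
    tab <- generate_expenditure_survey(cfg)
    thr <- all_region_thresholds(tab, cfg$z)
    orc <- oracle_region_thresholds(as.data.frame(tab), cfg$z)
    orc <- orc[match(thr$stratum_id, orc$stratum_id), ]
    rownames(orc) <- NULL
    expect_equal(as.data.frame(thr), orc, tolerance = 1e-12)
  }
})

test_that("national average skips undefined strata and reports the count", {
  thr <- data.frame(stratum_id = c("a", "b", "c"),
                    t_nonfood = c(0.2, NA, 0.4), t_total = c(0.1, NA, 0.2),
                    n_qualifying = c(3L, 0L, 2L))
  avg <- national_average(thr, "nonfood_share")
  expect_equal(as.numeric(avg), 0.3)
  expect_equal(attr(avg, "n_skipped"), 1L)
  one <- national_average(thr[1, ], "total_share")
  expect_equal(as.numeric(one), 0.1)
  expect_error(national_average(data.frame(t_nonfood = NA_real_), "nonfood_share"))
})

test_that("published regional thresholds average to the reported national values", {
  pub <- published_region_thresholds()
  expect_equal(nrow(pub), 16L)
  expect_lt(abs(mean(pub$threshold_nonfood_pct) - 23.124), 1e-3)
  expect_lt(abs(mean(pub$threshold_total_pct) - 12.137), 1e-3)
})

test_that("CHE labelling uses a strict exceed rule on the policy basis", {
  df <- make_survey_df(3L, hh_size = 1L,
                       total_exp = c(200, 200, 100),
                       food_exp = c(100, 100, 0),
                       health_exp = c(50, 40, 15))
  tab <- as_survey_table(df)
  lab40 <- che_label(tab, threshold_policy("who_nonfood_40"))
  expect_equal(lab40$che, c(1L, 0L, 0L))  # 50/100 > 0.4; 40/100 not strict; 15/100
  lab10 <- che_label(tab, threshold_policy("total_10"))
  expect_equal(lab10$che, c(1L, 1L, 1L))
  # data-driven policy refuses strata without a defined threshold
  thr <- data.frame(stratum_id = "S1", t_nonfood = NA_real_, t_total = NA_real_,
                    n_qualifying = 0L)
  expect_error(che_label(tab, threshold_policy("data_driven", "nonfood_share"), thr),
               "fallback")
})

test_that("fill_undefined_thresholds substitutes the national average and records it", {
  thr <- data.frame(stratum_id = c("a", "b"), t_nonfood = c(0.2, NA),
                    t_total = c(0.1, NA), n_qualifying = c(2L, 0L))
  filled <- fill_undefined_thresholds(thr)
  expect_equal(filled$t_nonfood[2], 0.2)
  expect_equal(filled$t_total[2], 0.1)
  expect_equal(attr(filled, "filled")$nonfood, "b")
})

test_that("prevalence is non-increasing in the threshold level", {
  tab <- generate_expenditure_survey(small_sim(301L))
  levels <- c(0.05, 0.1, 0.2, 0.4, 0.6)
  for (basis in c("nonfood_share", "total_share")) {
    labs <- vapply(levels, function(l) {
      che_label(tab, custom_policy(basis, l))$che
    }, integer(nrow(tab)))
    # per-household monotone: raising the level never turns a 0 into a 1
    expect_true(all(apply(labs, 1L, function(r) !is.unsorted(rev(r)))))
    prev <- colMeans(labs)
    expect_true(!is.unsorted(rev(prev)))
  }
})

test_that("district prevalence matches a group-by-mean oracle", {
  df <- make_survey_df(4L, district_id = "d1", psu_id = "p1")
  tab <- as_survey_table(df)
  lab <- structure(data.frame(hh_id = df$hh_id, che = c(1L, 0L, 0L, 0L)),
                   class = c("che_labels", "data.frame"))
  out <- district_prevalence(tab, lab)
  expect_equal(out$prevalence_pct, 25)
  expect_equal(out$n_households, 4L)

  tab2 <- generate_expenditure_survey(small_sim(302L))
  lab2 <- che_label(tab2, threshold_policy("total_10"))
  out2 <- district_prevalence(tab2, lab2)
  for (i in seq_len(nrow(out2))) {
    sel <- tab2$district_id == out2$district_id[i]
    expect_equal(out2$prevalence_pct[i],
                 100 * mean(lab2$che[match(tab2$hh_id[sel], lab2$hh_id)]))
  }
  expect_equal(sum(out2$n_households), nrow(tab2))
})
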
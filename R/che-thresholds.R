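# Data-driven region-specific CHE thresholds and CHE classification.
#
# The threshold for a region is the mean health-expenditure share among its
# health-impoverished households: those above the per-capita poverty line on
# total expenditure but below it once out-of-pocket health spending is
# deducted. Classification then compares each household's share against
# either a fixed policy level (WHO 40% of nonfood, 10% of total) or the
# region's data-driven threshold.

#' Poverty indicator
#'
#' \code{1} when per-capita expenditure falls strictly below the poverty
#' line, \code{0} otherwise.
#'
#' @param pc_exp Per-capita monthly expenditure (vectorised).
#' @param z Per-capita monthly poverty line, \code{> 0}.
#' @return Integer vector of 0/1.
#' @export
poverty_indicator <- function(pc_exp, z) {
  stopifnot(is.numeric(pc_exp), length(z) == 1L, is.finite(z), z > 0)
  if (any(pc_exp < 0, na.rm = TRUE)) stop("negative per-capita expenditure")
  as.integer(pc_exp < z)
}

#' Per-capita total expenditure net of health spending
#'
#' The counterfactual per-capita consumption used to flag impoverishment by
#' health payments: \code{(total_exp - health_exp) / hh_size}. Non-negative
#' whenever health spending does not exceed nonfood consumption.
#'
#' @param table A \code{survey_table}.
#' @return Numeric vector.
#' @export
health_netted_pc_total <- function(table) {
  (table$total_exp - table$health_exp) / table$hh_size
}

#' Flag households impoverished by health spending
#'
#' \code{TRUE} for households that are non-poor on per-capita total
#' expenditure but poor once health spending is netted out (P = 0, P' = 1).
#' These households define the data-driven CHE thresholds.
#'
#' @param table A \code{survey_table}.
#' @param z Per-capita poverty line.
#' @return Logical vector.
#' @export
impoverishing_flag <- function(table, z) {
  p  <- poverty_indicator(per_capita(table, "total"), z)
  pp <- poverty_indicator(health_netted_pc_total(table), z)
  flag <- p == 0L & pp == 1L
  # Every qualifying household must satisfy pc_total >= z > pc_total - pc_health,
  # hence strictly positive health spending.
  if (any(flag & table$health_exp <= 0)) {
    stop("internal inconsistency: qualifying household with zero health spending")
  }
  flag
}

health_share <- function(table, basis = c("nonfood_share", "total_share")) {
  basis <- match.arg(basis)
  denom <- if (basis == "total_share") table$total_exp else nonfood_exp(table)
  table$health_exp / denom
}

#' Data-driven CHE threshold for one region
#'
#' The unweighted mean of the household-level health-expenditure share
#' (health/total or health/nonfood) over the region's health-impoverished
#' households. \code{NA} (never zero) when no household in the stratum
#' qualifies.
#'
#' @param table A \code{survey_table}.
#' @param stratum_id Stratum label present in the table.
#' @param z Per-capita poverty line.
#' @param basis \code{"nonfood_share"} or \code{"total_share"}.
#' @return A single proportion in (0, 1], or \code{NA_real_}.
#' @export
region_threshold <- function(table, stratum_id, z,
                             basis = c("nonfood_share", "total_share")) {
  basis <- match.arg(basis)
  if (!stratum_id %in% table$stratum_id) stop("unknown stratum: ", stratum_id)
  sel <- table$stratum_id == stratum_id & impoverishing_flag(table, z)
  if (!any(sel)) return(NA_real_)
  shares <- health_share(table[sel, , drop = FALSE], basis)
  if (any(!is.finite(shares))) {
    stop("zero ", sub("_share", "", basis), " expenditure for qualifying household(s) ",
         paste(utils::head(table$hh_id[sel][!is.finite(shares)], 3L), collapse = ", "))
  }
  mean(shares)
}

#' Data-driven CHE thresholds for every region
#'
#' Applies [region_threshold()] to every stratum for both share bases.
#'
#' @param table A \code{survey_table}.
#' @param z Per-capita poverty line.
#' @return A \code{region_thresholds} data frame with columns
#'   \code{stratum_id}, \code{t_nonfood}, \code{t_total} (proportions, \code{NA}
#'   when undefined) and \code{n_qualifying}.
#' @export
all_region_thresholds <- function(table, z) {
  strata <- unique(table$stratum_id)
  flag <- impoverishing_flag(table, z)
  res <- data.frame(
    stratum_id   = strata,
    t_nonfood    = vapply(strata, function(s) region_threshold(table, s, z, "nonfood_share"), numeric(1)),
    t_total      = vapply(strata, function(s) region_threshold(table, s, z, "total_share"), numeric(1)),
    n_qualifying = vapply(strata, function(s) sum(flag & table$stratum_id == s), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(res) <- c("region_thresholds", "data.frame")
  res
}

#' National average of regional thresholds
#'
#' Unweighted arithmetic mean over strata with a defined threshold; strata
#' without qualifying households are skipped and their count reported as an
#' attribute \code{n_skipped}.
#'
#' @param thresholds A \code{region_thresholds} data frame (or any data frame
#'   with \code{t_nonfood}/\code{t_total} columns).
#' @param basis \code{"nonfood_share"} or \code{"total_share"}.
#' @return Mean threshold (same scale as the inputs) with attribute
#'   \code{n_skipped}.
#' @export
national_average <- function(thresholds, basis = c("nonfood_share", "total_share")) {
  basis <- match.arg(basis)
  x <- if (basis == "nonfood_share") thresholds$t_nonfood else thresholds$t_total
  if (all(is.na(x))) stop("no region has a defined threshold")
  structure(mean(x, na.rm = TRUE), n_skipped = sum(is.na(x)))
}

#' Fill undefined regional thresholds with the national average
#'
#' Small samples can leave a stratum with no health-impoverished household
#' and hence no defined data-driven threshold. For pipeline use, such strata
#' can fall back to the national (unweighted) average of the defined
#' thresholds; the affected strata are recorded in the \code{filled}
#' attribute. [region_threshold()] itself never does this silently.
#'
#' @param thresholds A \code{region_thresholds} table.
#' @return The table with \code{NA} thresholds replaced, plus attribute
#'   \code{filled}: a named list of stratum ids per basis.
#' @export
fill_undefined_thresholds <- function(thresholds) {
  filled <- list(nonfood = thresholds$stratum_id[is.na(thresholds$t_nonfood)],
                 total = thresholds$stratum_id[is.na(thresholds$t_total)])
  if (length(filled$nonfood) > 0L) {
    thresholds$t_nonfood[is.na(thresholds$t_nonfood)] <-
      as.numeric(national_average(thresholds, "nonfood_share"))
  }
  if (length(filled$total) > 0L) {
    thresholds$t_total[is.na(thresholds$t_total)] <-
      as.numeric(national_average(thresholds, "total_share"))
  }
  attr(thresholds, "filled") <- filled
  thresholds
}

#' CHE threshold policies
#'
#' A policy maps a household to a binary CHE label by comparing its
#' health-spending share (strictly) against a level. The two fixed policies
#' are the WHO 40%-of-nonfood rule and the 10%-of-total rule; the data-driven
#' policy uses per-stratum thresholds from [all_region_thresholds()].
#'
#' @param kind \code{"who_nonfood_40"}, \code{"total_10"} or
#'   \code{"data_driven"}.
#' @param basis Share basis; fixed for the two named policies, required for
#'   \code{data_driven}.
#' @param level Custom global level (proportion). Only honoured for
#'   \code{kind = "custom"} via \code{custom_policy()}.
#' @return A \code{threshold_policy} object.
#' @export
threshold_policy <- function(kind = c("who_nonfood_40", "total_10", "data_driven"),
                             basis = c("nonfood_share", "total_share")) {
  kind <- match.arg(kind)
  p <- switch(kind,
    who_nonfood_40 = list(kind = kind, basis = "nonfood_share", level = 0.40),
    total_10       = list(kind = kind, basis = "total_share", level = 0.10),
    data_driven    = list(kind = kind, basis = match.arg(basis), level = NULL))
  structure(p, class = "threshold_policy")
}

#' Fixed-level CHE policy at an arbitrary threshold
#'
#' Used by the sensitivity analysis to sweep threshold levels on either basis.
#'
#' @param basis Share basis.
#' @param level Proportion in (0, 1).
#' @return A \code{threshold_policy}.
#' @export
custom_policy <- function(basis = c("nonfood_share", "total_share"), level) {
  basis <- match.arg(basis)
  stopifnot(is.numeric(level), length(level) == 1L, level > 0)
  structure(list(kind = "custom", basis = basis, level = level),
            class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat("CHE threshold policy:", x$kind, "| basis:", x$basis,
      if (!is.null(x$level)) paste("| level:", x$level) else "| level: per-stratum",
      "\n")
  invisible(x)
}

#' Label households as CHE / non-CHE under a policy
#'
#' A household is labelled 1 when its health-spending share strictly exceeds
#' the policy threshold. For the data-driven policy the threshold is the
#' household's stratum entry in \code{thresholds}; strata with an undefined
#' threshold raise an error directing the caller to a fixed fallback policy.
#'
#' @param table A \code{survey_table}.
#' @param policy A \code{threshold_policy}.
#' @param thresholds A \code{region_thresholds} table; required for the
#'   data-driven policy.
#' @return A \code{che_labels} data frame with \code{hh_id} and \code{che}
#'   (0/1), carrying the policy as an attribute.
#' @export
che_label <- function(table, policy, thresholds = NULL) {
  stopifnot(inherits(policy, "threshold_policy"))
  share <- health_share(table, policy$basis)
  if (policy$basis == "nonfood_share" && any(!is.finite(share))) {
    stop("zero nonfood expenditure prevents nonfood-share labelling for household(s) ",
         paste(utils::head(table$hh_id[!is.finite(share)], 3L), collapse = ", "))
  }
  if (policy$kind == "data_driven") {
    if (is.null(thresholds)) stop("data-driven policy requires a region_thresholds table")
    col <- if (policy$basis == "nonfood_share") "t_nonfood" else "t_total"
    lev <- thresholds[[col]][match(table$stratum_id, thresholds$stratum_id)]
    if (any(is.na(lev))) {
      stop("no defined data-driven threshold for stratum(s) ",
           paste(unique(table$stratum_id[is.na(lev)]), collapse = ", "),
           "; use a fixed policy (who_nonfood_40 or total_10) as fallback")
    }
  } else {
    lev <- policy$level
  }
  out <- data.frame(hh_id = table$hh_id, che = as.integer(share > lev),
                    stringsAsFactors = FALSE)
  structure(out, policy = policy, class = c("che_labels", "data.frame"))
}

#' District-level CHE prevalence
#'
#' @param table A \code{survey_table}.
#' @param labels A \code{che_labels} table covering every household.
#' @return Data frame with \code{district_id}, \code{n_households} and
#'   \code{prevalence_pct} (100 x mean label).
#' @export
district_prevalence <- function(table, labels) {
  lab <- labels$che[match(table$hh_id, labels$hh_id)]
  if (any(is.na(lab))) stop("labels do not cover every household")
  agg <- stats::aggregate(lab, by = list(district_id = table$district_id),
                          FUN = function(v) c(n = length(v), p = 100 * mean(v)))
  data.frame(district_id = agg$district_id,
             n_households = as.integer(agg$x[, "n"]),
             prevalence_pct = agg$x[, "p"],
             stringsAsFactors = FALSE)
}

#' Published region-specific CHE thresholds (Bangladesh HIES 2016)
#'
#' The 16 division-by-residence thresholds (percent of nonfood and of total
#' expenditure) published for the 2016 Bangladesh Household Income and
#' Expenditure Survey, shipped as a plain-text reference table. Their
#' unweighted means are the national average data-driven thresholds
#' (about 23.12% of nonfood and 12.14% of total expenditure).
#'
#' @return Data frame with \code{stratum_id}, \code{threshold_nonfood_pct},
#'   \code{threshold_total_pct}.
#' @export
published_region_thresholds <- function() {
  path <- system.file("extdata", "region_thresholds_hies2016.csv",
                      package = "chetools", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
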
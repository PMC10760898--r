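# End-to-end pipeline orchestration and choropleth export.

config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

pipeline_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full CHE analysis pipeline
#'
#' Composes the modules end to end: synthesize (or read) the survey, build
#' the wealth index, derive the data-driven regional thresholds, label CHE
#' under all four policies (WHO 40% of nonfood, 10% of total, data-driven on
#' each basis), tabulate prevalence by covariate with chi-square tests, fit
#' the fixed and random-intercept determinant models with odds ratios, GVIF
#' and LRT, compute district prevalences and the threshold sensitivity AUCs,
#' and write every table under \code{out_dir}. Fully reproducible from
#' (config, seed); the config hash and seed are recorded in the summary.
#'
#' @param config Either a path to a YAML file or a list; recognised entries
#'   are \code{seed}, \code{input} (CSV path; when absent a survey is
#'   generated), \code{z} (poverty line; defaults to the generator's),
#'   \code{sim} (named list of [sim_config()] overrides) and \code{n_quad}.
#' @param out_dir Output directory (created if needed); \code{NULL} skips
#'   writing.
#' @param quiet Suppress stage logging.
#' @return A \code{report_bundle} list with all tables, fits and metadata.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 20160401L)
  n_quad <- as.integer(config$n_quad %||% 15L)

  stage <- "synth"
  bundle <- tryCatch({
    if (!is.null(config$input)) {
      tab <- read_survey(config$input)
      z <- config$z
      if (is.null(z)) stop("config must name a poverty line 'z' with an input CSV")
      pipeline_log(quiet, stage, "read ", nrow(tab), " households from ", config$input)
    } else {
      sim_args <- config$sim %||% list()
      sim_args$seed <- seed
      cfg <- do.call(sim_config, sim_args)
      tab <- generate_expenditure_survey(cfg)
      z <- config$z %||% cfg$z
      pipeline_log(quiet, stage, "generated ", nrow(tab), " households (seed ", seed, ")")
    }

    stage <- "wealth"
    tab <- add_wealth_index(tab)
    pipeline_log(quiet, stage, "wealth index over ",
                 length(attr(tab, "asset_cols")), " assets")

    stage <- "thresholds"
    thr <- all_region_thresholds(tab, z)
    pipeline_log(quiet, stage, nrow(thr), " strata, ",
                 sum(is.na(thr$t_nonfood)), " undefined")
    thr_filled <- fill_undefined_thresholds(thr)
    n_filled <- length(unlist(attr(thr_filled, "filled")))
    if (n_filled > 0L) {
      pipeline_log(quiet, stage, "filled ", n_filled,
                   " undefined stratum threshold(s) with the national average")
    }

    stage <- "labels"
    policies <- list(who_nonfood_40 = threshold_policy("who_nonfood_40"),
                     total_10 = threshold_policy("total_10"),
                     data_driven_nonfood = threshold_policy("data_driven", "nonfood_share"),
                     data_driven_total = threshold_policy("data_driven", "total_share"))
    labels <- lapply(policies, function(p) che_label(tab, p, thr_filled))

    stage <- "bivariate"
    bivar <- lapply(labels, function(l) bivariate_table(tab, l))

    stage <- "fit"
    spec <- design_spec()
    d <- build_design(tab, spec)
    fits <- lapply(labels[c("data_driven_nonfood", "data_driven_total")], function(l) {
      y <- l$che[match(tab$hh_id, l$hh_id)]
      ffix <- fit_logistic(d$X, y)
      fmix <- fit_mixed_logit(d$X, y, d$cluster, n_quad = n_quad)
      femp <- fit_empty_mixed(y, d$cluster, n_quad = n_quad)
      list(fixed = ffix, mixed = fmix, empty = femp,
           or_fixed = odds_ratios(ffix), or_mixed = odds_ratios(fmix),
           gvif = gvif(d$X, d$term_of_column),
           lrt = lrt(ffix$loglik, fmix$loglik, df = 1L, boundary = TRUE))
    })
    pipeline_log(quiet, stage, "fitted fixed/mixed/empty models for both bases")

    stage <- "evaluate"
    prev <- lapply(labels, function(l) district_prevalence(tab, l))
    sens <- threshold_sensitivity(tab, unname(policies), spec, thr_filled, n_quad = n_quad)

    list(table = tab, z = z, thresholds = thr, labels = labels,
         bivariate = bivar, fits = fits, district_prevalence = prev,
         sensitivity = sens,
         metadata = list(seed = seed, n_households = nrow(tab),
                         config_hash = config_hash(config),
                         package_version = as.character(utils::packageVersion("chetools")),
                         r_version = R.version.string))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(bundle) <- "report_bundle"

  if (!is.null(out_dir)) write_bundle(bundle, out_dir, quiet = quiet)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_bundle <- function(bundle, out_dir, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(bundle$thresholds, "region_thresholds.csv")
  for (nm in names(bundle$labels)) wr(bundle$labels[[nm]], paste0("labels_", nm, ".csv"))
  for (nm in names(bundle$bivariate)) wr(bundle$bivariate[[nm]], paste0("bivariate_", nm, ".csv"))
  for (nm in names(bundle$fits)) {
    f <- bundle$fits[[nm]]
    wr(f$or_fixed, paste0("odds_ratios_fixed_", nm, ".csv"))
    wr(f$or_mixed, paste0("odds_ratios_mixed_", nm, ".csv"))
    wr(f$gvif, paste0("gvif_", nm, ".csv"))
  }
  for (nm in names(bundle$district_prevalence)) {
    wr(bundle$district_prevalence[[nm]], paste0("district_prevalence_", nm, ".csv"))
  }
  wr(bundle$sensitivity, "threshold_sensitivity.csv")
  summary <- c(bundle$metadata, list(
    z = bundle$z,
    national_threshold_nonfood = as.numeric(national_average(bundle$thresholds, "nonfood_share")),
    national_threshold_total = as.numeric(national_average(bundle$thresholds, "total_share")),
    models = lapply(bundle$fits, function(f) list(
      loglik_fixed = f$fixed$loglik, loglik_mixed = f$mixed$loglik,
      sigma_u = f$mixed$sigma_u, icc_final = f$mixed$icc_value,
      icc_empty = f$empty$icc_value,
      lrt_statistic = f$lrt$statistic, lrt_p_boundary = f$lrt$p_boundary))))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(quiet, "write", "bundle written to ", out_dir)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("CHE report bundle:", x$metadata$n_households, "households,",
      nrow(x$thresholds), "strata (seed ", x$metadata$seed, ")\n")
  invisible(x)
}

#' Join district CHE prevalence onto GeoJSON geometry
#'
#' Adds a \code{che_prevalence} property to every feature whose join-key
#' property matches a district in the prevalence table. Districts in the
#' prevalence table with no matching feature are written to a sidecar text
#' file (one per line) next to the output.
#'
#' @param prevalence Data frame from [district_prevalence()].
#' @param geometry_path Input GeoJSON file.
#' @param out_path Output GeoJSON path.
#' @param join_key Feature property holding the district identifier.
#' @return List with \code{out_path}, \code{unmatched} (district ids) and
#'   \code{sidecar} (path or NULL).
#' @export
export_choropleth <- function(prevalence, geometry_path, out_path,
                              join_key = "district_id") {
  gj <- tryCatch(jsonlite::fromJSON(geometry_path, simplifyVector = FALSE),
                 error = function(e) stop("malformed geometry file: ",
                                          conditionMessage(e)))
  if (is.null(gj$features)) stop("malformed geometry file: no 'features' array")
  matched <- character(0)
  gj$features <- lapply(gj$features, function(ft) {
    key <- ft$properties[[join_key]]
    i <- match(key, prevalence$district_id)
    if (!is.na(i)) {
      ft$properties$che_prevalence <- prevalence$prevalence_pct[i]
      matched <<- c(matched, prevalence$district_id[i])
    }
    ft
  })
  unmatched <- setdiff(prevalence$district_id, matched)
  jsonlite::write_json(gj, out_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  sidecar <- NULL
  if (length(unmatched) > 0L) {
    sidecar <- paste0(out_path, ".unmatched.txt")
    writeLines(unmatched, sidecar)
  }
  list(out_path = out_path, unmatched = unmatched, sidecar = sidecar)
}
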
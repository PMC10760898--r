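# Core survey container, validation, and delimited-text I/O.

#' Mandatory household-survey columns
#'
#' Column names every survey table must carry, in canonical order. Asset
#' indicator columns (prefix \code{asset_}) are discovered from the data and
#' may be absent.
#'
#' @return Character vector of column names.
#' @export
survey_columns <- function() {
  c("hh_id", "stratum_id", "division", "residence", "district_id", "psu_id",
    "hh_size", "total_exp", "food_exp", "health_exp",
    "old_age_present", "child_present", "chronic_disease_present",
    "head_educated", "head_sex", "head_age_over60")
}

#' Residence categories
#' @return Character vector of the three residence levels.
#' @export
residence_levels <- function() c("rural", "urban", "city_corporation")

binary_cols <- function() {
  c("old_age_present", "child_present", "chronic_disease_present",
    "head_educated", "head_age_over60")
}

#' Construct a validated survey table
#'
#' Wraps a data frame of household records into a \code{survey_table}. One row
#' is one surveyed household with hierarchy identifiers (stratum, division,
#' residence, district, primary sampling unit), household size, monthly
#' total/food/health expenditure, demographic covariates and any number of
#' binary/count asset columns named \code{asset_*}.
#'
#' Validation enforces the accounting identities the CHE analysis relies on:
#' \code{0 <= food_exp <= total_exp}, \code{health_exp <= total_exp - food_exp}
#' (out-of-pocket health spending is a component of nonfood consumption), and
#' a strict hierarchy (each PSU belongs to one district, each district to one
#' stratum and division).
#'
#' @param df Data frame with at least the columns of [survey_columns()].
#' @param drop_invalid If \code{TRUE}, rows violating row-level invariants are
#'   dropped with a message instead of failing.
#' @return A \code{survey_table}: a data frame with an \code{asset_cols}
#'   attribute listing the asset columns found.
#' @export
as_survey_table <- function(df, drop_invalid = FALSE) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(survey_columns(), names(df))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("survey table must be non-empty")
  for (col in c("hh_size", "total_exp", "food_exp", "health_exp")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
      stop("non-numeric values in '", col, "'",
           if (length(bad) > 0L) paste0(" at row(s) ", paste(utils::head(bad, 5L), collapse = ", ")))
    }
  }

  problems <- validate_survey_rows(df)
  if (length(problems) > 0L) {
    if (drop_invalid) {
      bad_rows <- as.integer(sub("^row ([0-9]+):.*$", "\\1", problems))
      bad_rows <- unique(bad_rows)
      message("dropping ", length(bad_rows), " invalid row(s)")
      df <- df[-bad_rows, , drop = FALSE]
      if (nrow(df) == 0L) stop("all rows invalid")
    } else {
      stop("invalid survey rows:\n  ",
           paste(utils::head(problems, 10L), collapse = "\n  "),
           if (length(problems) > 10L) sprintf("\n  ... and %d more", length(problems) - 10L))
    }
  }

  if (anyDuplicated(df$hh_id)) stop("hh_id values must be unique")
  check_hierarchy(df)

  rownames(df) <- NULL
  structure(df,
            asset_cols = grep("^asset_", names(df), value = TRUE),
            class = c("survey_table", "data.frame"))
}

# Row-level invariant checks; returns "row <i>: <problem>" strings.
validate_survey_rows <- function(df) {
  problems <- character(0)
  add <- function(rows, what) {
    if (length(rows) > 0L) c(problems, sprintf("row %d: %s", rows, what)) else problems
  }
  num_bad <- function(x) !is.finite(x)
  problems <- add(which(num_bad(df$hh_size) | df$hh_size < 1 | df$hh_size != round(df$hh_size)),
                  "hh_size must be an integer >= 1")
  problems <- add(which(num_bad(df$total_exp) | df$total_exp <= 0), "total_exp must be > 0")
  problems <- add(which(num_bad(df$food_exp) | df$food_exp < 0), "food_exp must be >= 0")
  problems <- add(which(num_bad(df$health_exp) | df$health_exp < 0), "health_exp must be >= 0")
  ok <- is.finite(df$total_exp) & is.finite(df$food_exp) & is.finite(df$health_exp)
  nonfood <- df$total_exp - df$food_exp
  problems <- add(which(ok & nonfood < 0), "food_exp exceeds total_exp")
  problems <- add(which(ok & nonfood >= 0 & df$health_exp > nonfood + 1e-9),
                  "health_exp exceeds nonfood expenditure (total_exp - food_exp)")
  problems <- add(which(!df$residence %in% residence_levels()),
                  "residence must be one of rural/urban/city_corporation")
  problems <- add(which(!df$head_sex %in% c("female", "male")),
                  "head_sex must be female or male")
  for (col in binary_cols()) {
    problems <- add(which(!df[[col]] %in% c(0, 1)), paste0(col, " must be 0 or 1"))
  }
  problems[order(as.integer(sub("^row ([0-9]+):.*$", "\\1", problems)))]
}

# Table-level hierarchy: psu -> district -> (stratum, division) is a function.
check_hierarchy <- function(df) {
  chk <- function(child, parent) {
    tab <- unique(df[, c(child, parent)])
    dup <- tab[[child]][duplicated(tab[[child]])]
    if (length(dup) > 0L) {
      stop(child, " '", dup[[1L]], "' maps to more than one ", parent)
    }
  }
  chk("psu_id", "district_id")
  chk("district_id", "stratum_id")
  chk("district_id", "division")
  invisible(TRUE)
}

#' Read a household survey table from CSV
#'
#' Comma-delimited, UTF-8, header row, \code{.} decimal mark. Rows violating
#' the survey invariants abort the read (with per-row diagnostics) unless
#' \code{drop_invalid = TRUE}.
#'
#' @param path Path to a CSV file.
#' @param drop_invalid Drop invalid rows instead of failing.
#' @return A \code{survey_table}.
#' @seealso [write_survey()]
#' @export
read_survey <- function(path, drop_invalid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  as_survey_table(df, drop_invalid = drop_invalid)
}

#' Write a household survey table to CSV
#'
#' @param table A \code{survey_table}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_survey <- function(table, path) {
  stopifnot(inherits(table, "survey_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-capita expenditure components
#'
#' Divides a household expenditure component by household size, yielding the
#' per-person monthly amounts that are compared against the per-capita poverty
#' line. Shares of spending are invariant to this scaling; poverty status is
#' not.
#'
#' @param table A \code{survey_table} (or any data frame with the expenditure
#'   columns).
#' @param component One of \code{"total"}, \code{"nonfood"}, \code{"health"}.
#' @return Numeric vector, one value per household.
#' @export
per_capita <- function(table, component = c("total", "nonfood", "health")) {
  component <- match.arg(component)
  x <- switch(component,
              total   = table$total_exp,
              nonfood = table$total_exp - table$food_exp,
              health  = table$health_exp)
  x / table$hh_size
}

#' Nonfood expenditure
#'
#' @param table A \code{survey_table}.
#' @return \code{total_exp - food_exp} per household.
#' @export
nonfood_exp <- function(table) table$total_exp - table$food_exp
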
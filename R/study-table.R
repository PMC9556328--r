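#' Bias covariate schema entry
#'
#' Describes one candidate dummy bias covariate attached to a study table.
#' The class determines where the covariate may enter the model: `"alpha"`
#' covariates modify the true exposure effect, `"beta"` covariates predict
#' bias in the reported measurement, and `"gamma_class"` covariates are
#' accepted in the schema but only logged (heterogeneity modification is out
#' of scope).
#'
#' @param name Covariate name; must match a 0/1 column of the study table.
#' @param klass One of `"alpha"`, `"beta"`, `"gamma_class"`.
#' @param description Free-text description.
#' @return A one-row `data.frame` with columns `name`, `klass`, `description`.
#' @export
bias_covariate <- function(name, klass = c("beta", "alpha", "gamma_class"),
                           description = "") {
  klass <- match.arg(klass)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  data.frame(name = name, klass = klass, description = description,
             stringsAsFactors = FALSE)
}

REQUIRED_COLUMNS <- c("study_id", "design", "ref_lower", "ref_upper",
                      "alt_lower", "alt_upper", "log_effect", "se_log_effect")

#' Construct a validated study table
#'
#' A study table holds one row per reported comparison: a reference exposure
#' range, an alternative exposure range (systolic blood pressure, mm Hg), the
#' log relative effect (log RR/OR/HR), its standard error, an optional event
#' count and 0/1 bias covariates. Multi-arm studies may contribute several
#' rows sharing a `study_id`; random effects are grouped by that id.
#'
#' Open-ended published categories are encoded as `NA` bounds and closed to a
#' configured plausible window before validation: a missing lower bound
#' becomes `floor`, a missing upper bound becomes `ceiling`.
#'
#' @param data A `data.frame` with columns `study_id`, `design`
#'   (`"cohort"`/`"rct"`), `ref_lower`, `ref_upper`, `alt_lower`, `alt_upper`,
#'   `log_effect`, `se_log_effect`, optionally `events`, plus one 0/1 column
#'   per covariate in `covariates`.
#' @param covariates Covariate schema: a `data.frame` as produced by
#'   [bias_covariate()] (rows may be concatenated with `rbind`), a character
#'   vector of names (treated as `"beta"` class), or `NULL` to infer from the
#'   extra columns of `data`.
#' @param floor,ceiling Plausible exposure window used to close open-ended
#'   categories and to validate bounds (defaults 70 and 250 mm Hg for
#'   validation; open-ended categories close to `open_floor`/`open_ceiling`).
#' @param open_floor,open_ceiling Values substituted for missing lower/upper
#'   bounds (defaults 100 and 200 mm Hg, the modeled plausible range).
#' @return An object of class `bop_table`: a list with elements `data`
#'   (validated `data.frame`) and `covariates` (schema `data.frame`).
#' @export
study_table <- function(data, covariates = NULL, floor = 70, ceiling = 250,
                        open_floor = 100, open_ceiling = 200) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(data))
  if (length(missing_cols)) {
    stop("study table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"events" %in% names(data)) data$events <- NA_real_

  covariates <- normalize_schema(covariates, data)
  keep <- c(REQUIRED_COLUMNS, "events", covariates$name)
  data <- data[, keep, drop = FALSE]

  # close open-ended categories before validation
  for (side in c("ref", "alt")) {
    lo <- paste0(side, "_lower"); up <- paste0(side, "_upper")
    data[[lo]][is.na(data[[lo]])] <- open_floor
    data[[up]][is.na(data[[up]])] <- open_ceiling
  }

  problems <- validate_rows(data, covariates, floor, ceiling)
  if (length(problems)) {
    stop("invalid study table:\n  ", paste(problems, collapse = "\n  "))
  }
  rownames(data) <- NULL
  structure(list(data = data, covariates = covariates), class = "bop_table")
}

normalize_schema <- function(covariates, data) {
  if (is.null(covariates)) {
    extra <- setdiff(names(data), c(REQUIRED_COLUMNS, "events"))
    covariates <- extra
  }
  if (is.character(covariates)) {
    covariates <- if (length(covariates)) {
      do.call(rbind, lapply(covariates, bias_covariate))
    } else {
      data.frame(name = character(), klass = character(),
                 description = character(), stringsAsFactors = FALSE)
    }
  }
  stopifnot(is.data.frame(covariates),
            all(c("name", "klass") %in% names(covariates)))
  if (!"description" %in% names(covariates)) covariates$description <- ""
  miss <- setdiff(covariates$name, names(data))
  if (length(miss)) {
    stop("covariate column(s) missing from data: ", paste(miss, collapse = ", "))
  }
  covariates
}

validate_rows <- function(data, covariates, floor, ceiling) {
  problems <- character()
  flag <- function(bad, msg) {
    if (any(bad)) {
      problems[[length(problems) + 1L]] <<-
        sprintf("%s (row %s)", msg, paste(which(bad), collapse = ", "))
    }
  }
  flag(!data$design %in% c("cohort", "rct"), "design must be 'cohort' or 'rct'")
  flag(!is.finite(data$se_log_effect) | data$se_log_effect <= 0,
       "se_log_effect must be a positive number")
  flag(!is.finite(data$log_effect), "log_effect must be finite")
  for (side in c("ref", "alt")) {
    lo <- data[[paste0(side, "_lower")]]; up <- data[[paste0(side, "_upper")]]
    flag(!is.finite(lo) | !is.finite(up), paste(side, "range must be numeric"))
    flag(is.finite(lo) & is.finite(up) & lo > up,
         paste(side, "range must have lower <= upper"))
    flag(is.finite(lo) & (lo < floor | up > ceiling),
         sprintf("%s range outside plausible window [%g, %g]", side, floor, ceiling))
  }
  flag(is.finite(data$events) & data$events < 0, "events must be nonnegative")
  for (nm in covariates$name) {
    flag(!data[[nm]] %in% c(0, 1), sprintf("covariate '%s' must be 0/1", nm))
  }
  problems
}

#' @export
print.bop_table <- function(x, ...) {
  cat(sprintf("<bop_table> %d rows, %d studies (%d rct, %d cohort), %d bias covariate(s)\n",
              nrow(x$data), length(unique(x$data$study_id)),
              length(unique(x$data$study_id[x$data$design == "rct"])),
              length(unique(x$data$study_id[x$data$design == "cohort"])),
              nrow(x$covariates)))
  invisible(x)
}

#' Number of rows / studies in a study table
#' @param t A `bop_table`.
#' @return Integer count.
#' @export
n_rows <- function(t) nrow(t$data)

#' @rdname n_rows
#' @export
n_studies <- function(t) length(unique(t$data$study_id))

#' Covariate names of a study table
#' @param t A `bop_table`.
#' @return Character vector.
#' @export
covariate_names <- function(t) t$covariates$name

#' Midpoint of an exposure range
#'
#' The mean exposure of a reported range/category, `(lower + upper) / 2`; a
#' point category `(x, x)` maps to `x`.
#'
#' @param lower,upper Numeric vectors of range bounds (mm Hg).
#' @return Numeric vector of midpoints.
#' @export
midpoint_exposure <- function(lower, upper) {
  stopifnot(length(lower) == length(upper), all(lower <= upper))
  (lower + upper) / 2
}

#' Pooled exposure midpoints of both arms
#'
#' One midpoint per arm per record: the reference-range midpoint and the
#' alternative-range midpoint of every row, concatenated. This pooled sample
#' defines the exposure distribution used for percentile bands and knot
#' placement.
#'
#' @param t A `bop_table`.
#' @return Numeric vector of length `2 * n_rows(t)`.
#' @export
pooled_midpoints <- function(t) {
  d <- t$data
  c(midpoint_exposure(d$ref_lower, d$ref_upper),
    midpoint_exposure(d$alt_lower, d$alt_upper))
}

#' Exposure percentiles of a study table
#'
#' Percentiles of the pooled distribution of arm midpoints (both reference
#' and alternative arms, unweighted), with linear interpolation between order
#' statistics. The default band (15th and 85th percentiles) delimits the
#' data-dense exposure region over which the risk-outcome score averages the
#' conservative risk curve.
#'
#' @param t A `bop_table`.
#' @param probs Pair of fractions in (0, 1).
#' @return Numeric vector of exposures (mm Hg), one per probability.
#' @export
exposure_percentiles <- function(t, probs = c(0.15, 0.85)) {
  if (n_rows(t) == 0L) stop("empty study table")
  stopifnot(all(probs > 0 & probs < 1))
  unname(stats::quantile(pooled_midpoints(t), probs = probs, type = 7))
}

#' Read a study table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row and the columns
#' documented in [study_table()]. A JSON sidecar (same path with extension
#' `.schema.json`) holding the covariate schema is read if present and no
#' explicit `schema` is given.
#'
#' @param path CSV file path.
#' @param schema Covariate schema (see [study_table()]); `NULL` to use the
#'   sidecar or infer from extra columns.
#' @param ... Passed on to [study_table()] (e.g. `open_floor`).
#' @return A `bop_table`.
#' @export
load_study_table <- function(path, schema = NULL, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(sub("\\.csv$", "", path), ".schema.json")
  if (is.null(schema) && file.exists(sidecar)) {
    schema <- as.data.frame(jsonlite::fromJSON(sidecar))
  }
  study_table(data, covariates = schema, ...)
}

#' Write a study table to CSV
#'
#' Writes the table (full numeric precision, 12+ significant digits) and a
#' JSON schema sidecar, so that [load_study_table()] round-trips losslessly.
#'
#' @param t A `bop_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(t, path) {
  utils::write.csv(format_numeric(t$data), path, row.names = FALSE, quote = TRUE)
  sidecar <- paste0(sub("\\.csv$", "", path), ".schema.json")
  jsonlite::write_json(t$covariates, sidecar, dataframe = "columns")
  invisible(path)
}

format_numeric <- function(d) {
  for (nm in names(d)) {
    if (is.numeric(d[[nm]])) d[[nm]] <- formatC(d[[nm]], digits = 15, format = "g")
  }
  d
}

#' Restrict a study table to a subset of rows
#' @param t A `bop_table`.
#' @param keep Logical or integer row index.
#' @return A `bop_table` with the selected rows.
#' @export
subset_table <- function(t, keep) {
  out <- t
  out$data <- t$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}
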
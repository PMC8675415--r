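REQUIRED_COVARIATES <- c("subject_id", "cohort", "sex", "age",
                         "field_strength", "software_version")

#' Read a subject-level morphometry table
#'
#' Reads a delimited text file with one row per subject: the covariate columns
#' `subject_id, cohort, sex, age, field_strength, software_version`
#' (optionally `global_cov`), followed by one numeric column per measure in
#' `catalog`.  The separator (comma or tab) is auto-detected from the header
#' line.  Unparseable measure cells become `NA` and are counted in the
#' validation report attached as `attr(x, "validation")`.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param catalog Region catalog (see [dk_catalog()]); measure columns in the
#'   file must be a subset of its `measure_id`s.
#' @param sex_map Optional named character vector mapping raw sex codes to
#'   `"M"`/`"F"`, e.g. `c("0" = "F", "1" = "M")`.  `male`/`female` (any case)
#'   and `m`/`f` are always accepted.  Numeric codings are refused unless a
#'   mapping is supplied, because no convention can be assumed.
#' @param age_range Length-2 numeric; ages outside it raise a validation
#'   error.
#'
#' @return A tibble (subject table) with canonical types: `sex` is a factor
#'   with levels `M`, `F`; measure columns are double.  Attributes:
#'   `catalog`, `validation` (per-column `NA` counts introduced by parsing).
#' @seealso [simulate_cohorts()] for generating tables with known ground
#'   truth, [adjust()] for covariate harmonization.
#' @export
read_subject_table <- function(path, catalog = dk_catalog(), sex_map = NULL,
                               age_range = c(0, 120)) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (stringr::str_count(header, "\t") >=
               stringr::str_count(header, ",")) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(REQUIRED_COVARIATES, names(raw))
  if (length(missing_cols)) {
    abort(paste0("required column(s) missing from ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  measures <- setdiff(names(raw), c(REQUIRED_COVARIATES, "global_cov"))
  unknown <- setdiff(measures, catalog$measure_id)
  if (length(unknown)) {
    abort(paste0("measure column(s) not in catalog: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }

  sex <- canonical_sex(raw$sex, sex_map)
  age <- suppressWarnings(as.numeric(raw$age))
  if (anyNA(age) || any(age < age_range[1] | age > age_range[2])) {
    abort("column `age` has non-numeric or out-of-range values")
  }
  if (anyDuplicated(raw$subject_id)) abort("`subject_id` values must be unique")

  out <- tibble::tibble(
    subject_id = raw$subject_id,
    cohort = raw$cohort,
    sex = sex,
    age = age,
    field_strength = raw$field_strength,
    software_version = raw$software_version
  )
  if ("global_cov" %in% names(raw)) {
    out$global_cov <- suppressWarnings(as.numeric(raw$global_cov))
  }
  n_bad <- integer(0)
  for (m in measures) {
    was_na <- is.na(raw[[m]]) | raw[[m]] == ""
    v <- suppressWarnings(as.numeric(raw[[m]]))
    n_bad[[m]] <- sum(is.na(v) & !was_na)
    out[[m]] <- v
  }
  attr(out, "catalog") <- catalog
  attr(out, "validation") <- tibble::tibble(
    measure_id = measures,
    n_missing = purrr::map_int(measures, ~ sum(is.na(out[[.x]]))),
    n_unparseable = unname(n_bad)
  )
  out
}

canonical_sex <- function(x, sex_map = NULL) {
  x_chr <- as.character(x)
  if (!is.null(sex_map)) {
    mapped <- unname(sex_map[x_chr])
    x_chr[!is.na(mapped)] <- mapped[!is.na(mapped)]
  }
  up <- toupper(trimws(x_chr))
  up[up %in% c("MALE", "MALES")] <- "M"
  up[up %in% c("FEMALE", "FEMALES")] <- "F"
  bad <- !up %in% c("M", "F")
  if (any(bad)) {
    abort(paste0("sex value(s) outside {M, F}: ",
                 paste(unique(x_chr[bad]), collapse = ", "),
                 if (is.null(sex_map)) " (numeric codes need an explicit `sex_map`)" else ""))
  }
  factor(up, levels = c("M", "F"))
}

#' Write a result table with a JSON metadata sidecar
#'
#' Writes any result tibble as a tab-separated file (full double precision)
#' plus `<path>.json` carrying the analysis metadata stored in the object's
#' attributes (seeds, permutation counts, adjustment recipe, ...), so that
#' every number is re-derivable.  [read_results()] reverses the operation;
#' numeric round-trip is exact to at least 12 significant digits.
#'
#' @param x A result tibble (or an object with a [tidy()] method).
#' @param path Output TSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  tbl <- if (inherits(x, "data.frame")) tibble::as_tibble(x) else tidy(x)
  meta <- result_meta(x)
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(tbl, path, progress = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  tbl <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attr(tbl, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  tbl
}

# serializable metadata from a result's attributes
result_meta <- function(x) {
  keep <- setdiff(names(attributes(x)),
                  c("names", "row.names", "class", "catalog"))
  meta <- attributes(x)[keep]
  meta <- purrr::map(meta, function(a) {
    if (inherits(a, "data.frame")) purrr::map(a, identity) else a
  })
  c(list(package = "brainvar", version = as.character(utils::packageVersion("brainvar"))),
    meta)
}
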
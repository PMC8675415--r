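#' Tidy and glance methods for brainvar results
#'
#' Result tables already are tibbles; `tidy()` returns them stripped of
#' analysis attributes, and `glance()` gives a one-row summary per object.
#'
#' @param x A brainvar result object.
#' @param ... Unused.
#' @return A tibble.
#' @name brainvar-tidiers
NULL

#' @rdname brainvar-tidiers
#' @export
tidy.brainvar_result <- function(x, ...) {
  out <- x
  for (nm in setdiff(names(attributes(out)), c("names", "row.names", "class"))) {
    attr(out, nm) <- NULL
  }
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @rdname brainvar-tidiers
#' @export
glance.brainvar_vartest <- function(x, ...) {
  tibble::tibble(n_measures = nrow(x), n_significant = sum(x$significant),
                 mean_log_vr = mean(x$log_vr), B = attr(x, "B"),
                 sided = attr(x, "sided"), alpha = attr(x, "alpha"))
}

#' @rdname brainvar-tidiers
#' @export
glance.brainvar_meantest <- function(x, ...) {
  tibble::tibble(n_measures = nrow(x), n_significant = sum(x$significant),
                 mean_d = mean(x$d), alpha = attr(x, "alpha"))
}

#' @rdname brainvar-tidiers
#' @export
glance.brainvar_ageint <- function(x, ...) {
  dplyr::count(tidy(x), .data$order, wt = .data$significant,
               name = "n_significant") |>
    dplyr::mutate(n_measures = nrow(x) / dplyr::n())
}

#' @rdname brainvar-tidiers
#' @export
tidy.brainvar_shift <- function(x, ...) x$table

#' @rdname brainvar-tidiers
#' @export
glance.brainvar_shift <- function(x, ...) {
  tibble::tibble(classification = x$classification, n_m = x$n_m, n_f = x$n_f,
                 n_boot = x$n_boot, estimator = x$estimator)
}

#' @rdname brainvar-tidiers
#' @export
tidy.brainvar_homogeneity <- function(x, ...) x$edges

#' @rdname brainvar-tidiers
#' @export
glance.brainvar_homogeneity <- function(x, ...) {
  dplyr::bind_cols(x$counts,
                   dplyr::rename(x$chisq, chi2_p = "p", chi2_df = "df",
                                 n_directional = "n"))
}

#' @export
print.brainvar_pipeline <- function(x, ...) {
  cat("<brainvar_pipeline>\n")
  cat(report_markdown(x))
  invisible(x)
}
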
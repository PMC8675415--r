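#' Published reference effect sizes for subcortical volumes
#'
#' The per-region Cohen's d and log variance-ratio values reported for the
#' 14 subcortical volumes in the large published lifespan mega-analysis this
#' pipeline reimplements, shipped as a plain-text table.  These were
#' computed on restricted cohort data and serve as simulation targets and as
#' inputs to summary recomputations (e.g. their mean d), never as outputs of
#' this package's own analyses.
#'
#' @return A tibble `measure_id, region_label, d, log_vr`.
#' @export
published_effects <- function() {
  readr::read_tsv(system.file("extdata", "published_effects.tsv",
                              package = "brainvar"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname published_effects
#' @return For `published_directional_counts()`: a tibble
#'   `measure_class, n_male_stronger, n_female_stronger` of the reported
#'   counts of inter-regional correlations significantly stronger in each
#'   sex (the two classes for which a directional chi-square was reported).
#' @export
published_directional_counts <- function() {
  readr::read_tsv(system.file("extdata", "published_directional_counts.tsv",
                              package = "brainvar"),
                  show_col_types = FALSE, progress = FALSE)
}
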
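#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis.  Exactly one of `data`
#' (a subject table) or `sim` (a [sim_config()], regenerated under the
#' master seed) must be supplied.  The master `seed` deterministically fixes
#' all child seeds (simulation, permutations, bootstrap, random forests), so
#' the whole run is bit-reproducible.
#'
#' @param data Subject table, or `NULL` to simulate.
#' @param sim A [sim_config()] used when `data` is `NULL`.
#' @param recipe An [adjustment_recipe()].
#' @param B Permutations for variance-ratio and edge tests.
#' @param n_boot Bootstrap replicates for shift functions.
#' @param alpha Significance/FDR level.
#' @param sided Sidedness of the variance-ratio test.
#' @param classes Measure classes to analyse.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(data = NULL, sim = NULL,
                            recipe = adjustment_recipe(),
                            B = 10000, n_boot = 1000, alpha = 0.05,
                            sided = "two", classes = MEASURE_CLASSES,
                            seed = 1L) {
  if (is.null(data) && is.null(sim)) sim <- sim_config()
  if (!is.null(data) && !is.null(sim)) abort("supply either `data` or `sim`, not both")
  structure(list(data = data, sim = sim, recipe = recipe, B = B,
                 n_boot = n_boot, alpha = alpha, sided = sided,
                 classes = match.arg(classes, MEASURE_CLASSES, several.ok = TRUE),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, per measure class: harmonization, mean-difference tests,
#' variance-ratio permutation tests with FDR, the log VR vs d correlation,
#' shift functions for the measures with FDR-significant variance
#' differences, age-by-sex dispersion regressions (orders 1 and 2), and the
#' anatomical-correlation comparison.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `brainvar_pipeline`: list with elements
#'   `subjects`, `adjusted`, `means`, `variances`, `vr_d`, `shifts`,
#'   `ageint`, `homogeneity` (per-class list), `summary` (plain list, JSON
#'   serializable), `seeds`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- withr::with_seed(config$seed, sample.int(10000000L, 5))
  names(seeds) <- c("sim", "vartest", "shift", "homogeneity", "rf")
  subjects <- config$data
  if (is.null(subjects)) {
    sim <- config$sim; sim$seed <- seeds[["sim"]]
    subjects <- simulate_cohorts(sim)
  }
  catalog <- attr(subjects, "catalog", exact = TRUE) %||% dk_catalog()
  catalog <- catalog[catalog$measure_class %in% config$classes, ]
  measures <- catalog_measures(subjects, catalog)
  if (!length(measures)) abort("no catalog measures of the requested classes in table")
  recipe <- config$recipe; recipe$rf_seed <- seeds[["rf"]]
  adjusted <- adjust(subjects, measures, recipe)
  attr(adjusted, "catalog") <- catalog

  means <- test_means(adjusted, measures, alpha = config$alpha)
  variances <- test_variances(adjusted, measures, B = config$B,
                              seed = seeds[["vartest"]], sided = config$sided,
                              alpha = config$alpha)
  vr_d <- dplyr::inner_join(
    dplyr::select(tidy(variances), "measure_id", "measure_class", "log_vr"),
    dplyr::select(tidy(means), "measure_id", "d"), by = "measure_id") |>
    dplyr::group_by(.data$measure_class) |>
    dplyr::group_modify(~ correlate_vr_with_d(.x$log_vr, .x$d)) |>
    dplyr::ungroup()

  sig_var <- variances$measure_id[variances$significant]
  shifts <- if (length(sig_var)) {
    shift_functions(adjusted, sig_var, n_boot = config$n_boot,
                    seed = seeds[["shift"]])
  } else NULL
  ageint <- test_age_interaction(adjusted, measures, orders = c(1, 2),
                                 alpha = config$alpha)
  homog <- purrr::map(rlang::set_names(intersect(config$classes,
                                                 unique(catalog$measure_class))),
                      function(cl) {
    ms <- catalog$measure_id[catalog$measure_class == cl]
    std <- standardize_by_sex(adjusted, ms)
    permutation_edge_test(std, ms, B = config$B,
                          seed = seeds[["homogeneity"]], alpha = config$alpha)
  })

  bundle <- structure(list(subjects = subjects, adjusted = adjusted,
                           means = means, variances = variances, vr_d = vr_d,
                           shifts = shifts, ageint = ageint,
                           homogeneity = homog, seeds = seeds,
                           config = config),
                      class = "brainvar_pipeline")
  bundle$summary <- pipeline_summary(bundle)
  bundle
}

# plain-list summary (counts per analysis); serializes to stable JSON
pipeline_summary <- function(bundle) {
  by_class <- function(tbl, flag = "significant") {
    split(tbl, tbl$measure_class) |>
      purrr::map(~ list(n_measures = length(unique(.x$measure_id)),
                        n_significant = sum(.x[[flag]])))
  }
  shifts <- if (!is.null(bundle$shifts)) {
    cls <- dplyr::distinct(bundle$shifts, .data$measure_id, .data$classification)
    as.list(table(cls$classification))
  } else list()
  list(
    n_subjects = nrow(bundle$subjects),
    alpha = bundle$config$alpha,
    B = bundle$config$B,
    seed = bundle$config$seed,
    mean_tests = by_class(bundle$means),
    variance_tests = by_class(bundle$variances),
    vr_d_correlation = purrr::transpose(as.list(bundle$vr_d))|>
      rlang::set_names(bundle$vr_d$measure_class),
    shift_classifications = shifts,
    age_interaction = split(bundle$ageint, bundle$ageint$order) |>
      purrr::map(by_class) |> rlang::set_names(paste0("order", sort(unique(bundle$ageint$order)))),
    homogeneity = purrr::map(bundle$homogeneity, function(h) {
      c(as.list(h$counts), list(chi2 = h$chisq$chi2, chi2_p = h$chisq$p))
    })
  )
}

#' Write a pipeline bundle to disk
#'
#' Emits one TSV (+ JSON sidecar) per result table, a `summary.json`, and a
#' plain-text log with every seed and parameter, into `dir`.
#'
#' @param bundle A `brainvar_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_results(bundle$means, file.path(dir, "mean_tests.tsv"))
  write_results(bundle$variances, file.path(dir, "variance_tests.tsv"))
  write_results(bundle$vr_d, file.path(dir, "vr_d_correlation.tsv"))
  if (!is.null(bundle$shifts)) {
    write_results(bundle$shifts, file.path(dir, "shift_functions.tsv"))
  }
  write_results(bundle$ageint, file.path(dir, "age_interaction.tsv"))
  for (cl in names(bundle$homogeneity)) {
    write_results(bundle$homogeneity[[cl]]$edges,
                  file.path(dir, paste0("homogeneity_", cl, ".tsv")))
  }
  jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    paste0("brainvar ", utils::packageVersion("brainvar")),
    paste0("master seed: ", bundle$config$seed),
    paste0("child seeds: ", paste(names(bundle$seeds), bundle$seeds,
                                  sep = "=", collapse = ", ")),
    paste0("B: ", bundle$config$B, ", n_boot: ", bundle$config$n_boot,
           ", alpha: ", bundle$config$alpha, ", sided: ", bundle$config$sided)
  ), file.path(dir, "log.txt"))
  invisible(dir)
}

#' Markdown report of a pipeline bundle
#'
#' Per-class tables of the mean-difference and variance-ratio tests and a
#' paragraph summarizing the directional anatomical-correlation counts.
#' Stages that were not run (e.g. no significant variance differences, so no
#' shift functions) are noted rather than omitted silently.
#'
#' @param bundle A `brainvar_pipeline` object.
#' @return A character scalar of markdown.
#' @export
report_markdown <- function(bundle) {
  lines <- c("# Sex differences in brain-structure mean and variability", "")
  for (cl in unique(bundle$variances$measure_class)) {
    mt <- dplyr::filter(bundle$means, .data$measure_class == cl)
    vt <- dplyr::filter(bundle$variances, .data$measure_class == cl)
    lines <- c(lines, paste0("## ", gsub("_", " ", cl)), "",
      sprintf("%d measures; %d with FDR-significant mean differences (mean d = %.2f); %d with FDR-significant variance differences (mean log VR = %.3f).",
              nrow(mt), sum(mt$significant), mean(mt$d), sum(vt$significant),
              mean(vt$log_vr)), "",
      "| measure | d | q(mean) | log VR | q(VR) |", "|---|---|---|---|---|",
      sprintf("| %s | %.3f | %.3g | %.3f | %.3g |",
              mt$measure_id, mt$d, mt$q, vt$log_vr, vt$q), "")
    h <- bundle$homogeneity[[cl]]
    if (!is.null(h)) {
      lines <- c(lines, sprintf(
        "Of the %d unique inter-regional correlations, %d were significantly stronger in males and %d in females (chi-square(1, N = %d) = %.3f, p = %.3g).",
        h$counts$n_edges, h$counts$n_male_stronger, h$counts$n_female_stronger,
        h$chisq$n, h$chisq$chi2, h$chisq$p), "")
    }
  }
  if (is.null(bundle$shifts)) {
    lines <- c(lines, "No measures had significant variance differences; shift functions were not computed.", "")
  } else {
    cls <- dplyr::distinct(bundle$shifts, .data$measure_id, .data$classification)
    lines <- c(lines, sprintf(
      "Shift functions were computed for %d measures: %d classified greater_male_variance, %d greater_female_variance, %d parallel.",
      nrow(cls), sum(cls$classification == "greater_male_variance"),
      sum(cls$classification == "greater_female_variance"),
      sum(cls$classification == "parallel")), "")
  }
  paste(lines, collapse = "\n")
}
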
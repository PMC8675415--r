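#' Region catalog for the Desikan-Killiany morphometry table
#'
#' The default measure set analysed by the pipeline: volumes of seven
#' subcortical structures per hemisphere (14 measures), and surface area and
#' mean thickness of the 34 Desikan-Killiany cortical regions per hemisphere
#' (68 + 68 measures).  Every column of a subject table beyond the covariates
#' must resolve to a `measure_id` in the attached catalog.
#'
#' @param classes Character vector of measure classes to include; any subset
#'   of `"subcortical_volume"`, `"cortical_area"`, `"cortical_thickness"`.
#' @param regions Optional character vector of region names used to restrict
#'   the catalog (e.g. a few regions for small simulations).
#'
#' @return A tibble with columns `measure_id`, `measure_class`, `hemisphere`,
#'   `region`, `atlas`.
#' @examples
#' dk_catalog()
#' dk_catalog("subcortical_volume")
#' @export
dk_catalog <- function(classes = MEASURE_CLASSES, regions = NULL) {
  classes <- match.arg(classes, MEASURE_CLASSES, several.ok = TRUE)
  hemis <- c(lh = "left", rh = "right")
  sub <- tidyr::expand_grid(hemi = names(hemis), region = SUBCORTICAL_STRUCTURES) |>
    dplyr::mutate(
      measure_id = paste0(.data$hemi, "_", .data$region, "_vol"),
      measure_class = "subcortical_volume",
      atlas = "aseg"
    )
  ctx <- function(suffix, class) {
    tidyr::expand_grid(hemi = names(hemis), region = DK_REGIONS) |>
      dplyr::mutate(
        measure_id = paste0(.data$hemi, "_", .data$region, "_", suffix),
        measure_class = class,
        atlas = "desikan_killiany"
      )
  }
  out <- dplyr::bind_rows(sub, ctx("area", "cortical_area"),
                          ctx("thick", "cortical_thickness")) |>
    dplyr::mutate(hemisphere = unname(hemis[.data$hemi])) |>
    dplyr::select("measure_id", "measure_class", "hemisphere", "region", "atlas") |>
    dplyr::filter(.data$measure_class %in% classes) |>
    dplyr::arrange(factor(.data$measure_class, MEASURE_CLASSES),
                   .data$hemisphere, .data$region)
  if (!is.null(regions)) out <- dplyr::filter(out, .data$region %in% regions)
  stopifnot(!anyDuplicated(out$measure_id))
  out
}

SUBCORTICAL_STRUCTURES <- c(
  "accumbens", "amygdala", "caudate", "hippocampus", "pallidum",
  "putamen", "thalamus"
)

DK_REGIONS <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal"
)

#' Number of unique unordered region pairs
#'
#' Convenience for bookkeeping inter-regional correlation analyses:
#' `n * (n - 1) / 2` edges among `n` regions (91 for the 14 subcortical
#' measures, 2,278 for the 68 cortical regions).
#'
#' @param n Number of regions (non-negative integer).
#' @return Integer count of unordered pairs.
#' @examples
#' n_region_pairs(14) # 91
#' n_region_pairs(68) # 2278
#' @export
n_region_pairs <- function(n) {
  stopifnot(is.numeric(n), n >= 0, n == round(n))
  as.integer(n * (n - 1) / 2)
}

# measure columns of `data` that resolve in `catalog`, in catalog order
catalog_measures <- function(data, catalog) {
  intersect(catalog$measure_id, names(data))
}

measure_class_of <- function(measures, catalog) {
  catalog$measure_class[match(measures, catalog$measure_id)]
}
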
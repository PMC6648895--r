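#' Normalize intensities to percent of per-purification total
#'
#' Scales each purification so that the sum of all protein intensities in
#' that purification is 100. The resulting relative intensity (percent of
#' total) is the unit of analysis for all downstream comparisons: it removes
#' differences in the absolute amount of material recovered per pull-down,
#' so purifications become directly comparable.
#'
#' @param x Long intensity tibble with columns `protein`, `purification`,
#'   `intensity` (non-negative).
#' @return A tibble with columns `protein`, `purification`, `relint`
#'   (percent). Each purification's `relint` sums to 100. The returned table
#'   carries the attribute `zero_replaced = FALSE`; see [replace_zeros()].
#' @seealso [replace_zeros()], [log10_relative()]
#' @export
#' @examples
#' x <- tibble::tibble(
#'   protein = c("a", "b", "c"), purification = "P1", intensity = c(1, 1, 2)
#' )
#' normalize_relative(x)
normalize_relative <- function(x) {
  require_columns(x, c("protein", "purification", "intensity"), "Intensity table")
  if (any(x$intensity < 0)) abort_validation("Intensities must be non-negative.")
  totals <- x |>
    group_by(.data$purification) |>
    summarise(total = sum(.data$intensity), .groups = "drop")
  empty <- totals$purification[totals$total <= 0]
  if (length(empty) > 0L) {
    abort_validation(sprintf(
      "Purification(s) with zero total intensity: %s.",
      paste0("'", empty, "'", collapse = ", ")
    ))
  }
  out <- x |>
    group_by(.data$purification) |>
    mutate(relint = 100 * .data$intensity / sum(.data$intensity)) |>
    ungroup() |>
    select("protein", "purification", "relint")
  attr(out, "zero_replaced") <- FALSE
  out
}

#' Replace exact zeros with a small constant
#'
#' Substitutes every exact 0 in a relative-intensity table with 0.0001
#' (percent scale) so that all values can be log-transformed. Nothing is
#' renormalized afterwards: a purification with `k` undetected proteins sums
#' to `100 + 0.0001 * k` after replacement. Applying the replacement twice
#' is an error.
#'
#' @param x Relative-intensity tibble from [normalize_relative()] (or
#'   [normalize_excluding_bait()]).
#' @return The same tibble with zeros replaced and attribute
#'   `zero_replaced = TRUE`.
#' @export
replace_zeros <- function(x) {
  require_columns(x, c("protein", "purification", "relint"),
                  "Relative-intensity table")
  if (is_zero_replaced(x)) {
    abort_validation("Zeros in this table have already been replaced.")
  }
  out <- mutate(x, relint = ifelse(.data$relint == 0, .zero_fill, .data$relint))
  attr(out, "zero_replaced") <- TRUE
  out
}

#' Base-10 log transform of relative intensities
#'
#' Adds a `log10_relint` column. Requires zero replacement to have been
#' applied, so the minimum attainable value is `log10(0.0001) = -4`.
#'
#' @param x Zero-replaced relative-intensity tibble.
#' @return The tibble with an additional `log10_relint` column.
#' @export
log10_relative <- function(x) {
  require_columns(x, c("protein", "purification", "relint"),
                  "Relative-intensity table")
  if (!is_zero_replaced(x)) {
    abort_validation("Apply replace_zeros() before log-transforming.")
  }
  if (any(x$relint <= 0)) {
    abort_validation("Non-positive relative intensity after zero replacement.")
  }
  out <- mutate(x, log10_relint = log10(.data$relint))
  attr(out, "zero_replaced") <- TRUE
  out
}

#' Order proteins for a grouped heat map
#'
#' Produces the deterministic row order used for the screen overview heat
#' map: proteins are blocked by their group assignment (in the fixed order
#' of [protein_groups()]) and, within each block, sorted by descending mean
#' log10 signal across all purifications, with ties broken lexicographically
#' by protein identifier. Proteins absent from the annotation default to
#' group "other" (with a warning).
#'
#' @param x Log-transformed relative-intensity tibble from
#'   [log10_relative()].
#' @param annotation Annotation tibble (columns `protein`, `group`, optional
#'   `contaminant`).
#' @return A long tibble with columns `protein` (a factor whose level order
#'   is the heat-map row order, top row first), `group`, `purification`,
#'   `log10_relint` and `mean_log10`. Pivot on `purification` to obtain the
#'   drawable matrix, or pass to [plot_heatmap()].
#' @export
heatmap_order <- function(x, annotation) {
  require_columns(x, c("protein", "purification", "log10_relint"),
                  "Log-transformed table")
  annotation <- complete_annotation(annotation, unique(x$protein))
  ordering <- x |>
    group_by(.data$protein) |>
    summarise(mean_log10 = mean(.data$log10_relint), .groups = "drop") |>
    left_join(annotation[, c("protein", "group")], by = "protein") |>
    arrange(match(.data$group, .group_levels),
            dplyr::desc(.data$mean_log10), .data$protein)
  out <- x |>
    left_join(ordering, by = "protein") |>
    arrange(match(.data$protein, ordering$protein),
            match(.data$purification, unique(x$purification))) |>
    mutate(protein = factor(.data$protein, levels = ordering$protein)) |>
    select("protein", "group", "purification", "log10_relint", "mean_log10")
  class(out) <- c("heatmap_matrix", class(out))
  out
}

#' Ribosomal-protein share of total intensity
#'
#' Sums the relative intensities of all proteins annotated as 40S or 60S
#' ribosomal proteins in each purification. In a pull-down of a ribosomal
#' protein that is efficiently incorporated into ribosomes this share is
#' high (typically 70-90 percent); a low share indicates poor incorporation
#' of the bait. Fractions are computed on true relative intensities, before
#' zero replacement.
#'
#' @param x Relative-intensity tibble with `zero_replaced = FALSE`.
#' @param annotation Annotation tibble.
#' @param purification Optional character vector of purifications to report;
#'   defaults to all. Unknown purifications are an error.
#' @return A tibble with columns `purification`, `rprotein_pct`.
#' @export
rprotein_fraction <- function(x, annotation, purification = NULL) {
  require_columns(x, c("protein", "purification", "relint"),
                  "Relative-intensity table")
  if (is_zero_replaced(x)) {
    abort_validation(
      "rprotein_fraction() expects relative intensities before zero replacement."
    )
  }
  annotation <- complete_annotation(annotation, unique(x$protein))
  keep <- purification %||% unique(x$purification)
  unknown <- setdiff(keep, unique(x$purification))
  if (length(unknown) > 0L) {
    abort_validation(sprintf(
      "Unknown purification(s): %s.",
      paste0("'", unknown, "'", collapse = ", ")
    ))
  }
  x |>
    filter(.data$purification %in% keep) |>
    left_join(annotation[, c("protein", "group")], by = "protein") |>
    group_by(.data$purification) |>
    summarise(
      rprotein_pct = sum(.data$relint[.data$group %in% .rprotein_groups]),
      .groups = "drop"
    ) |>
    arrange(match(.data$purification, keep))
}
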
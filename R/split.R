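#' Bait-excluded percent normalization
#'
#' Normalizes each purification so that the summed intensity of all proteins
#' *except the bait* is 100 percent. This is the scale used for split-tag
#' purification comparisons, where the bait is strongly over-stoichiometric
#' and would otherwise compress every other protein's share. The bait's own
#' relative value is reported against the same bait-excluded denominator and
#' can therefore exceed 100 percent; its share of the unexcluded total is
#' kept in `share_of_total`.
#'
#' With a bait intensity of 0 this reduces exactly to
#' [normalize_relative()].
#'
#' @param x Long intensity tibble (`protein`, `purification`, `intensity`).
#' @param bait Protein identifier of the bait; must be present in `x`.
#' @return A tibble with columns `protein`, `purification`, `relint`
#'   (bait-excluded percent) and `share_of_total` (percent of the full
#'   total), with attributes `zero_replaced = FALSE` and `bait`.
#' @export
normalize_excluding_bait <- function(x, bait) {
  require_columns(x, c("protein", "purification", "intensity"), "Intensity table")
  if (!bait %in% unique(x$protein)) {
    abort_validation(sprintf("Bait protein '%s' not found in the table.", bait))
  }
  if (any(x$intensity < 0)) abort_validation("Intensities must be non-negative.")
  out <- x |>
    group_by(.data$purification) |>
    mutate(
      .denominator = sum(.data$intensity) -
        sum(.data$intensity[.data$protein == bait]),
      .total = sum(.data$intensity)
    ) |>
    ungroup()
  bad <- unique(out$purification[out$.denominator <= 0])
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "Bait-excluded total is not positive in purification(s) %s.",
      paste0("'", bad, "'", collapse = ", ")
    ))
  }
  out <- out |>
    mutate(
      relint = 100 * .data$intensity / .data$.denominator,
      share_of_total = 100 * .data$intensity / .data$.total
    ) |>
    select("protein", "purification", "relint", "share_of_total")
  attr(out, "zero_replaced") <- FALSE
  attr(out, "bait") <- bait
  out
}

#' Compare the two pools of a split-tag purification
#'
#' Given the partner-enriched and partner-depleted pools of a split-tag
#' purification (for example a Nap1 pull-down split by a Flag tag on Rps6a
#' into Rps6a-containing and Rps6a-free complexes), normalizes both columns
#' on the bait-excluded percent scale, replaces zeros with 0.0001,
#' log-transforms, and reports the per-protein log10 difference
#' (enriched minus depleted). Proteins preferentially found in
#' partner-containing complexes have positive differences.
#'
#' Missing proteins in either pool are treated as not detected (intensity
#' 0), so the two columns share one protein universe.
#'
#' @param x Long intensity tibble containing (at least) the two pools.
#' @param enriched,depleted Purification identifiers of the
#'   partner-enriched and partner-depleted pools.
#' @param bait Bait protein identifier (excluded from both denominators).
#' @param annotation Optional annotation tibble; adds `group` and
#'   `contaminant` columns.
#' @return A `split_comparison` tibble with columns `protein`,
#'   `relint_enriched`, `relint_depleted` (zero-replaced, bait-excluded
#'   percent), `log10_enriched`, `log10_depleted`, `log10_diff`, `is_bait`
#'   and (if annotated) `group`, `contaminant`.
#' @export
split_compare <- function(x, enriched, depleted, bait, annotation = NULL) {
  require_columns(x, c("protein", "purification", "intensity"), "Intensity table")
  missing <- setdiff(c(enriched, depleted), unique(x$purification))
  if (length(missing) > 0L) {
    abort_validation(sprintf(
      "Purification(s) not found: %s.",
      paste0("'", missing, "'", collapse = ", ")
    ))
  }
  both <- x |>
    filter(.data$purification %in% c(enriched, depleted)) |>
    tidyr::complete(.data$protein, .data$purification,
                    fill = list(intensity = 0))
  rel <- normalize_excluding_bait(both, bait) |> replace_zeros()
  wide <- rel |>
    select("protein", "purification", "relint") |>
    tidyr::pivot_wider(names_from = "purification", values_from = "relint")
  out <- tibble(
    protein = wide$protein,
    relint_enriched = wide[[enriched]],
    relint_depleted = wide[[depleted]],
    log10_enriched = log10(wide[[enriched]]),
    log10_depleted = log10(wide[[depleted]]),
  ) |>
    mutate(log10_diff = .data$log10_enriched - .data$log10_depleted,
           is_bait = .data$protein == bait)
  if (!is.null(annotation)) {
    annotation <- complete_annotation(annotation, out$protein)
    out <- left_join(out, annotation[, c("protein", "group", "contaminant")],
                     by = "protein")
  }
  out <- arrange(out, dplyr::desc(.data$log10_diff), .data$protein)
  attr(out, "bait") <- bait
  attr(out, "enriched") <- enriched
  attr(out, "depleted") <- depleted
  class(out) <- c("split_comparison", class(out))
  out
}

#' Per-group intensity shares in a split comparison
#'
#' Summarises a [split_compare()] result by protein group: each group's
#' share of the bait-excluded total in the enriched and depleted pools.
#' The bait itself is excluded (its relative value is not part of either
#' 100-percent scale). Shares are computed from the zero-replaced values,
#' so pools with many undetected proteins may sum to slightly more than
#' 100.
#'
#' @param comparison A `split_comparison` tibble.
#' @return A tibble with columns `group`, `share_enriched`,
#'   `share_depleted` and `log10_diff` (log10 of the share ratio).
#' @export
split_group_summary <- function(comparison) {
  require_columns(comparison,
                  c("protein", "relint_enriched", "relint_depleted", "is_bait"),
                  "Split comparison")
  if (!"group" %in% names(comparison)) {
    abort_validation("Split comparison has no 'group' column; pass an annotation to split_compare().")
  }
  comparison |>
    filter(!.data$is_bait) |>
    group_by(.data$group) |>
    summarise(
      share_enriched = sum(.data$relint_enriched),
      share_depleted = sum(.data$relint_depleted),
      .groups = "drop"
    ) |>
    mutate(log10_diff = log10(.data$share_enriched / .data$share_depleted)) |>
    arrange(match(.data$group, .group_levels))
}

#' Scatter plot of a split comparison
#'
#' @param object A `split_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot object: enriched versus depleted log10 relative
#'   intensities with the identity diagonal, coloured by group when
#'   available.
#' @export
autoplot.split_comparison <- function(object, ...) {
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$log10_depleted, y = .data$log10_enriched)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50")
  if ("group" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p +
    ggplot2::geom_point(data = filter(object, .data$is_bait), colour = "red",
                        size = 3, shape = 1, stroke = 1.2) +
    ggplot2::labs(
      x = sprintf("log10 %% intensity, %s", attr(object, "depleted") %||% "depleted"),
      y = sprintf("log10 %% intensity, %s", attr(object, "enriched") %||% "enriched")
    )
}
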
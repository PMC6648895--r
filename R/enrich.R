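#' Per-protein reference mean across the purification panel
#'
#' For a focal purification, computes each protein's mean relative intensity
#' over the purification panel, excluding purifications flagged as outliers
#' in the screen design. The mean is taken over all remaining purifications
#' including the focal one. If the focal purification is itself an outlier,
#' it is re-included in its own reference so that its data can still be
#' displayed against the panel.
#'
#' The mean is the arithmetic mean of percent values (not of log values),
#' matching the scale on which purifications are plotted against the panel.
#'
#' @param x Zero-replaced relative-intensity tibble (see [replace_zeros()]).
#' @param design Screen design tibble (`purification`, `bait`, `outlier`).
#' @param focal Identifier of the focal purification.
#' @param leave_one_out If `TRUE`, additionally exclude the focal
#'   purification from its own reference mean. Off by default.
#' @return A tibble with columns `protein`, `reference_mean` (percent).
#' @export
reference_mean <- function(x, design, focal, leave_one_out = FALSE) {
  require_columns(x, c("protein", "purification", "relint"),
                  "Relative-intensity table")
  require_columns(design, c("purification", "bait", "outlier"), "Screen design")
  if (!is_zero_replaced(x)) {
    abort_validation("Apply replace_zeros() before computing reference means.")
  }
  purifs <- unique(x$purification)
  if (!focal %in% purifs) {
    abort_validation(sprintf("Focal purification '%s' not found.", focal))
  }
  outliers <- design$purification[design$outlier]
  included <- setdiff(purifs, outliers)
  if (focal %in% outliers) included <- union(included, focal)
  if (leave_one_out) included <- setdiff(included, focal)
  if (length(included) < 2L) {
    abort_validation(
      "Fewer than 2 purifications remain after outlier exclusion."
    )
  }
  x |>
    filter(.data$purification %in% included) |>
    group_by(.data$protein) |>
    summarise(reference_mean = mean(.data$relint), .groups = "drop") |>
    arrange(match(.data$protein, unique(x$protein)))
}

#' Enrichment of each protein in a focal purification
#'
#' Compares each protein's relative intensity in the focal purification with
#' its reference mean across the panel (see [reference_mean()]). On a
#' log-log scatter, proteins recovered at panel-typical levels lie along the
#' diagonal of slope 1; proteins specifically co-enriched with the focal
#' bait sit clearly above it. The `log10_ratio` column is the vertical
#' distance from that diagonal.
#'
#' @inheritParams reference_mean
#' @param annotation Optional annotation tibble; when supplied, `group` and
#'   `contaminant` columns are attached.
#' @return A tibble with one row per protein: `protein`, `relint_focal`,
#'   `reference_mean`, `log10_ratio`, `rank` (1 = most enriched; ties broken
#'   lexicographically by protein identifier) and `is_bait`. The focal
#'   purification identifier is stored in the `"focal"` attribute.
#' @export
enrichment_table <- function(x, design, focal, annotation = NULL,
                             leave_one_out = FALSE) {
  ref <- reference_mean(x, design, focal, leave_one_out = leave_one_out)
  bait <- design$bait[design$purification == focal]
  if (length(bait) != 1L) {
    abort_validation(sprintf(
      "Design must map focal purification '%s' to exactly one bait.", focal
    ))
  }
  out <- x |>
    filter(.data$purification == focal) |>
    select("protein", relint_focal = "relint") |>
    inner_join(ref, by = "protein") |>
    mutate(
      log10_ratio = log10(.data$relint_focal / .data$reference_mean),
      is_bait = .data$protein == bait
    )
  ord <- order(-out$log10_ratio, out$protein)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  if (!is.null(annotation)) {
    annotation <- complete_annotation(annotation, out$protein)
    out <- left_join(out, annotation[, c("protein", "group", "contaminant")],
                     by = "protein")
  }
  out <- arrange(out, .data$rank)
  attr(out, "focal") <- focal
  out
}

#' Rank candidate interaction partners
#'
#' Filters an enrichment table down to candidate bait-specific partners:
#' non-bait proteins whose enrichment over the panel mean and whose relative
#' intensity in the focal purification both exceed thresholds. The defaults
#' (10-fold enrichment, 0.01 percent of total) formalize "clearly above the
#' diagonal and actually detected". Contaminant-flagged proteins are
#' reported but labeled, so carbohydrate-metabolism enzymes and similar
#' recurring background can be discounted by eye.
#'
#' @param etable Enrichment tibble from [enrichment_table()].
#' @param min_log10_ratio Minimum `log10_ratio` (default 1, i.e. 10-fold).
#' @param min_relint Minimum relative intensity in the focal purification,
#'   percent (default 0.01).
#' @return The candidate rows, sorted by descending `log10_ratio`.
#' @export
rank_candidates <- function(etable, min_log10_ratio = 1, min_relint = 0.01) {
  require_columns(etable, c("protein", "relint_focal", "log10_ratio", "is_bait"),
                  "Enrichment table")
  if (min_log10_ratio < 0 || min_relint < 0) {
    abort_validation("Candidate thresholds must be non-negative.")
  }
  out <- etable |>
    filter(!.data$is_bait,
           .data$log10_ratio >= min_log10_ratio,
           .data$relint_focal >= min_relint) |>
    arrange(dplyr::desc(.data$log10_ratio), .data$protein)
  attr(out, "focal") <- attr(etable, "focal")
  out
}
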
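#' Run the full co-enrichment screen
#'
#' Chains the screen pipeline over every purification of a panel: percent
#' normalization, zero replacement, per-purification enrichment against the
#' outlier-excluded panel mean, and candidate ranking. This is the
#' data-frame-in, result-object-out entry point; the individual steps
#' ([normalize_relative()], [replace_zeros()], [enrichment_table()],
#' [rank_candidates()]) remain available for piecewise use.
#'
#' @param intensities Long intensity tibble (`protein`, `purification`,
#'   `intensity`), e.g. from [read_intensity_table()] or [simulate_screen()].
#' @param design Screen design tibble (`purification`, `bait`, `outlier`).
#' @param annotation Optional annotation tibble; enables group labels,
#'   contaminant flags and [rprotein_fraction()] summaries.
#' @param min_log10_ratio,min_relint Candidate thresholds, see
#'   [rank_candidates()].
#' @param leave_one_out Exclude each focal purification from its own
#'   reference mean (off by default; the panel mean normally includes the
#'   focal purification).
#' @return An object of class `chaperome_screen`: a list with elements
#'   `relative` (relative intensities before zero replacement), `enrichment`
#'   (per-protein enrichment rows for every focal purification, with a
#'   `focal` column), `candidates` (thresholded candidates across all
#'   purifications), `rprotein` (r-protein share per purification, if
#'   annotated), `design`, `annotation` and `params`. Use [tidy()],
#'   [glance()] and [autoplot()] on it.
#' @export
screen_enrichment <- function(intensities, design, annotation = NULL,
                              min_log10_ratio = 1, min_relint = 0.01,
                              leave_one_out = FALSE) {
  validate_design(design, intensities)
  if (!is.null(annotation)) {
    annotation <- complete_annotation(annotation, unique(intensities$protein))
  }
  relative <- normalize_relative(intensities)
  replaced <- replace_zeros(relative)
  purifs <- design$purification
  enrichment <- purrr::map(purifs, function(p) {
    enrichment_table(replaced, design, p, annotation = annotation,
                     leave_one_out = leave_one_out) |>
      mutate(focal = p)
  }) |>
    bind_rows() |>
    select("focal", dplyr::everything())
  candidates <- enrichment |>
    group_by(.data$focal) |>
    dplyr::group_modify(function(rows, key) {
      rank_candidates(rows, min_log10_ratio = min_log10_ratio,
                      min_relint = min_relint)
    }) |>
    ungroup()
  rprotein <- if (!is.null(annotation)) {
    rprotein_fraction(relative, annotation)
  }
  structure(
    list(
      relative = relative,
      enrichment = enrichment,
      candidates = candidates,
      rprotein = rprotein,
      design = design,
      annotation = annotation,
      params = list(min_log10_ratio = min_log10_ratio,
                    min_relint = min_relint,
                    leave_one_out = leave_one_out)
    ),
    class = "chaperome_screen"
  )
}

#' @export
print.chaperome_screen <- function(x, ...) {
  n_prot <- length(unique(x$relative$protein))
  n_purif <- length(unique(x$relative$purification))
  cat(sprintf(
    "<chaperome_screen> %d proteins x %d purifications (%d outlier(s))\n",
    n_prot, n_purif, sum(x$design$outlier)
  ))
  cat(sprintf(
    "candidates at log10 ratio >= %g and relint >= %g%%: %d\n",
    x$params$min_log10_ratio, x$params$min_relint, nrow(x$candidates)
  ))
  if (nrow(x$candidates) > 0L) {
    print(head(x$candidates[, c("focal", "protein", "relint_focal",
                                "log10_ratio")], 10L))
  }
  invisible(x)
}

#' Tidy a screen result
#'
#' @param x A `chaperome_screen` object.
#' @param ... Unused.
#' @return The per-protein, per-focal-purification enrichment tibble.
#' @export
tidy.chaperome_screen <- function(x, ...) x$enrichment

#' One-row summary of a screen result
#'
#' @param x A `chaperome_screen` object.
#' @param ... Unused.
#' @return A one-row tibble with panel dimensions, thresholds and candidate
#'   count.
#' @export
glance.chaperome_screen <- function(x, ...) {
  tibble(
    n_proteins = length(unique(x$relative$protein)),
    n_purifications = length(unique(x$relative$purification)),
    n_outliers = sum(x$design$outlier),
    min_log10_ratio = x$params$min_log10_ratio,
    min_relint = x$params$min_relint,
    leave_one_out = x$params$leave_one_out,
    n_candidates = nrow(x$candidates)
  )
}

#' Enrichment scatter for one purification
#'
#' Draws the focal purification against the panel: each protein's relative
#' intensity in the focal pull-down versus its reference mean, both on
#' log10 scales, with the slope-1 diagonal. Proteins co-enriched with the
#' bait rise above the diagonal; the bait itself is highlighted.
#'
#' @param object A `chaperome_screen` object.
#' @param focal Purification to plot (default: first in the design).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chaperome_screen <- function(object, focal = NULL, ...) {
  focal <- focal %||% object$design$purification[1L]
  rows <- filter(object$enrichment, .data$focal == !!focal)
  if (nrow(rows) == 0L) {
    abort_validation(sprintf("No enrichment rows for purification '%s'.", focal))
  }
  p <- ggplot2::ggplot(
    rows,
    ggplot2::aes(x = log10(.data$reference_mean),
                 y = log10(.data$relint_focal))
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = if ("group" %in% names(rows)) {
      .data$group
    } else {
      NULL
    }), alpha = 0.7) +
    ggplot2::geom_point(data = filter(rows, .data$is_bait), colour = "red",
                        size = 3, shape = 1, stroke = 1.2) +
    ggplot2::labs(
      x = "log10 mean relative intensity, all purifications (%)",
      y = sprintf("log10 relative intensity in %s (%%)", focal),
      colour = "group",
      title = sprintf("Co-enrichment in %s", focal)
    )
  p
}

#' Heat-map of the ordered screen matrix
#'
#' @param x A `heatmap_matrix` tibble from [heatmap_order()].
#' @return A ggplot tile plot with proteins in heat-map order (top row
#'   first) and group blocks preserved.
#' @export
plot_heatmap <- function(x) {
  require_columns(x, c("protein", "group", "purification", "log10_relint"),
                  "Heatmap matrix")
  ggplot2::ggplot(
    x,
    ggplot2::aes(x = .data$purification,
                 y = factor(.data$protein, levels = rev(levels(.data$protein))),
                 fill = .data$log10_relint)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(-4, 2)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log10 % intensity") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
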
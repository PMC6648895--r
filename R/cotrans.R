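#' TEV/total mRNA abundance ratios from N0 records
#'
#' For every purification x amplicon pair, averages the available technical
#' replicates of the TEV eluate and of the total extract separately, then
#' takes the ratio of the two means (ratio of means, not mean of ratios).
#' The ratio measures how strongly an mRNA is retained in the pull-down
#' relative to its level in the whole-cell extract.
#'
#' @param n0 N0 tibble (`purification`, `amplicon`, `fraction`, `replicate`,
#'   `n0`) from [read_n0()] or [simulate_cotrans()].
#' @param partners Partner tibble (`purification`, `amplicon`) naming each
#'   purification's cognate amplicon.
#' @return A tibble with columns `purification`, `amplicon`, `ratio`,
#'   `cognate` (logical), one row per pair. A warning is raised when
#'   replicate counts are unbalanced (means are then taken over the
#'   replicates that are present).
#' @export
replicate_ratios <- function(n0, partners) {
  validate_n0(n0, partners)
  if (any(n0$n0 <= 0)) abort_validation("All N0 values must be positive.")
  means <- n0 |>
    group_by(.data$purification, .data$amplicon, .data$fraction) |>
    summarise(mean_n0 = mean(.data$n0), n_rep = dplyr::n(), .groups = "drop")
  if (length(unique(means$n_rep)) > 1L) {
    warn(sprintf(
      "Unbalanced replicate counts (%s); means use the replicates present.",
      paste(sort(unique(means$n_rep)), collapse = "/")
    ))
  }
  wide <- tidyr::pivot_wider(means[, c("purification", "amplicon", "fraction",
                                       "mean_n0")],
                             names_from = "fraction", values_from = "mean_n0")
  for (fr in c("TEV", "total")) {
    if (!fr %in% names(wide)) wide[[fr]] <- NA_real_
  }
  incomplete <- wide[is.na(wide$TEV) | is.na(wide$total), ]
  if (nrow(incomplete) > 0L) {
    abort_validation(sprintf(
      "Missing TEV or total fraction for: %s.",
      paste0(sprintf("('%s', '%s')", incomplete$purification,
                     incomplete$amplicon), collapse = ", ")
    ))
  }
  out <- wide |>
    mutate(ratio = .data$TEV / .data$total) |>
    left_join(mutate(partners, cognate = TRUE),
              by = c("purification", "amplicon")) |>
    mutate(cognate = !is.na(.data$cognate)) |>
    select("purification", "amplicon", "ratio", "cognate")
  attr(out, "partners") <- partners
  out
}

#' Mean purification and amplicon background values
#'
#' Each chaperone purification pulls down every mRNA to some non-specific
#' extent, and each amplicon has its own non-specific recovery. The two
#' background levels are estimated as row and column means over the ratio
#' matrix after excluding every cognate cell (the pair of a purification
#' and the mRNA of its own client ribosomal protein).
#'
#' @param rm Ratio tibble from [replicate_ratios()] (columns `purification`,
#'   `amplicon`, `ratio`, `cognate`).
#' @return A list with elements `purification` (tibble `purification`,
#'   `background`) and `amplicon` (tibble `amplicon`, `background`).
#' @export
background_means <- function(rm) {
  require_columns(rm, c("purification", "amplicon", "ratio", "cognate"),
                  "Ratio table")
  if (any(rm$ratio <= 0)) abort_validation("All ratios must be positive.")
  bg <- filter(rm, !.data$cognate)
  pb <- bg |>
    group_by(.data$purification) |>
    summarise(background = mean(.data$ratio), .groups = "drop")
  ab <- bg |>
    group_by(.data$amplicon) |>
    summarise(background = mean(.data$ratio), .groups = "drop")
  empty_p <- setdiff(unique(rm$purification), pb$purification)
  empty_a <- setdiff(unique(rm$amplicon), ab$amplicon)
  if (length(empty_p) > 0L || length(empty_a) > 0L) {
    abort_validation(sprintf(
      "No background cells left for %s.",
      paste0("'", c(empty_p, empty_a), "'", collapse = ", ")
    ))
  }
  list(
    purification = arrange(pb, match(.data$purification,
                                     unique(rm$purification))),
    amplicon = arrange(ab, match(.data$amplicon, unique(rm$amplicon)))
  )
}

#' Two-way background normalization of mRNA abundance ratios
#'
#' Divides every TEV/total ratio by both its purification's and its
#' amplicon's mean background value (see [background_means()]), then scales
#' the corrected matrix so that the mean of all corrected background
#' (non-cognate) cells is exactly 1. On this scale a background cell reads
#' about 1, and a cognate cell reads the fold-enrichment of the client
#' mRNA in its chaperone's pull-down: the cognate score.
#'
#' @param rm Ratio tibble from [replicate_ratios()].
#' @return An object of class `cotrans_result`: a list with elements
#'   `table` (tibble `purification`, `amplicon`, `ratio`, `corrected`,
#'   `normalized`, `cognate`), `purification_background`,
#'   `amplicon_background`, and `cognate_scores` (tibble `purification`,
#'   `amplicon`, `score`, `rank_in_purification`, where rank 1 means the
#'   cognate mRNA is the most enriched amplicon in that purification's
#'   row). Supports [tidy()], [glance()] and [autoplot()].
#' @export
normalize_cotrans <- function(rm) {
  bg <- background_means(rm)
  tab <- rm |>
    left_join(rename(bg$purification, .pb = "background"), by = "purification") |>
    left_join(rename(bg$amplicon, .ab = "background"), by = "amplicon") |>
    mutate(corrected = .data$ratio / (.data$.pb * .data$.ab))
  scale_bg <- mean(tab$corrected[!tab$cognate])
  tab <- tab |>
    mutate(normalized = .data$corrected / scale_bg) |>
    select("purification", "amplicon", "ratio", "corrected", "normalized",
           "cognate")
  scores <- tab |>
    group_by(.data$purification) |>
    mutate(rank_in_purification = rank(-.data$normalized,
                                       ties.method = "first")) |>
    ungroup() |>
    filter(.data$cognate) |>
    select("purification", "amplicon", score = "normalized",
           "rank_in_purification")
  structure(
    list(
      table = tab,
      purification_background = bg$purification,
      amplicon_background = bg$amplicon,
      cognate_scores = scores
    ),
    class = "cotrans_result"
  )
}

#' @export
print.cotrans_result <- function(x, ...) {
  cat(sprintf(
    "<cotrans_result> %d purifications x %d amplicons\n",
    length(unique(x$table$purification)), length(unique(x$table$amplicon))
  ))
  cat("cognate scores (normalized mRNA abundance ratios):\n")
  print(x$cognate_scores)
  invisible(x)
}

#' Tidy a co-translational binding result
#'
#' @param x A `cotrans_result` object.
#' @param ... Unused.
#' @return The full cell-level tibble with raw, corrected and normalized
#'   ratios.
#' @export
tidy.cotrans_result <- function(x, ...) x$table

#' One-row summary of a co-translational binding result
#'
#' @param x A `cotrans_result` object.
#' @param ... Unused.
#' @return A one-row tibble: matrix dimensions, the realized background mean
#'   (1 by construction), and the smallest/largest cognate scores.
#' @export
glance.cotrans_result <- function(x, ...) {
  tibble(
    n_purifications = length(unique(x$table$purification)),
    n_amplicons = length(unique(x$table$amplicon)),
    background_mean = mean(x$table$normalized[!x$table$cognate]),
    min_cognate_score = min(x$cognate_scores$score),
    max_cognate_score = max(x$cognate_scores$score)
  )
}

#' Tile plot of normalized mRNA abundance ratios
#'
#' @param object A `cotrans_result` object.
#' @param ... Unused.
#' @return A ggplot tile plot on the log10 scale with cognate cells
#'   outlined.
#' @export
autoplot.cotrans_result <- function(object, ...) {
  ggplot2::ggplot(
    object$table,
    ggplot2::aes(x = .data$amplicon, y = .data$purification,
                 fill = log10(.data$normalized))
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = filter(object$table, .data$cognate),
                       colour = "red", linewidth = 1, fill = NA) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "mRNA amplicon", y = "purification",
                  fill = "log10 normalized\nabundance ratio")
}

#' Permutation test for cognate enrichment
#'
#' Optional significance assessment for cognate scores: the partner map is
#' repeatedly replaced by a random bijection of purifications onto the
#' cognate amplicon set, the two-way normalization is recomputed, and each
#' observed cognate score is compared with the scores the same purification
#' obtains under shuffled partner assignments. The p-value is the fraction
#' of permutations (including the observed assignment) whose score is at
#' least as large.
#'
#' @param rm Ratio tibble from [replicate_ratios()].
#' @param n_permutations Number of shuffled partner maps (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `purification`, `observed_score`,
#'   `p_value`.
#' @export
cotrans_permutation <- function(rm, n_permutations = 1000, seed = NULL) {
  partners <- attr(rm, "partners")
  if (is.null(partners)) {
    abort_validation("Ratio table carries no partner map; use replicate_ratios().")
  }
  observed <- normalize_cotrans(rm)$cognate_scores
  run_one <- function() {
    shuffled <- mutate(partners, amplicon = sample(.data$amplicon))
    rm_perm <- rm |>
      select(-"cognate") |>
      left_join(mutate(shuffled, cognate = TRUE),
                by = c("purification", "amplicon")) |>
      mutate(cognate = !is.na(.data$cognate))
    attr(rm_perm, "partners") <- shuffled
    normalize_cotrans(rm_perm)$cognate_scores |>
      select("purification", "score")
  }
  draw <- function() {
    perm <- purrr::map(seq_len(n_permutations), function(i) run_one()) |>
      bind_rows()
    observed |>
      select("purification", observed_score = "score") |>
      left_join(perm, by = "purification") |>
      group_by(.data$purification) |>
      summarise(
        observed_score = first(.data$observed_score),
        p_value = (sum(.data$score >= .data$observed_score) + 1) /
          (dplyr::n() + 1),
        .groups = "drop"
      )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
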
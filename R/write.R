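# Writers for the plain-text interchange formats. Each writer is the inverse
# of the corresponding reader: write-then-read reproduces values exactly.

#' Write an intensity (or relative-intensity) table as wide TSV
#'
#' Pivots a long intensity tibble to the wide dialect (first column
#' `protein`, one column per purification) and writes it tab-separated.
#' Proteins and purifications keep their current order of first appearance.
#'
#' @param x Long tibble with columns `protein`, `purification` and a value
#'   column.
#' @param path Output path.
#' @param value Name of the value column to spread (default `"intensity"`,
#'   use `"relint"` for relative intensities).
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(x, path, value = "intensity") {
  require_columns(x, c("protein", "purification", value), "Intensity table")
  wide <- tidyr::pivot_wider(
    x[, c("protein", "purification", value)],
    names_from = "purification", values_from = all_of(value)
  )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Write a protein annotation table
#'
#' @param annotation Tibble with columns `protein`, `group`, `contaminant`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  annotation <- validate_annotation(annotation)
  out <- tibble(
    protein = annotation$protein,
    group = annotation$group,
    contaminant = as.integer(annotation$contaminant)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a screen design as YAML
#'
#' @param design Tibble with columns `purification`, `bait`, `outlier`.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  require_columns(design, c("purification", "bait", "outlier"), "Screen design")
  spec <- list(
    baits = as.list(setNames(design$bait, design$purification)),
    outliers = as.list(design$purification[design$outlier])
  )
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Write qRT-PCR N0 records as CSV
#'
#' @param n0 Tibble with columns `purification`, `amplicon`, `fraction`,
#'   `replicate`, `n0`.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_n0 <- function(n0, path) {
  require_columns(n0, c("purification", "amplicon", "fraction", "replicate", "n0"),
                  "N0 table")
  readr::write_csv(
    n0[, c("purification", "amplicon", "fraction", "replicate", "n0")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Write a partner map as YAML
#'
#' @param partners Tibble with columns `purification`, `amplicon`.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_partners <- function(partners, path) {
  require_columns(partners, c("purification", "amplicon"), "Partner map")
  yaml::write_yaml(
    list(partners = as.list(setNames(partners$amplicon, partners$purification))),
    path
  )
  invisible(path)
}
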
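#' Read a protein intensity table
#'
#' Reads a table of label-free protein intensities, one row per protein and
#' one intensity value per purification, and returns it as a long tibble with
#' every protein x purification cell materialized. A missing cell means the
#' protein was not detected in that purification and is stored as 0, never
#' `NA`.
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`"wide"`}{Tab-separated, first column `protein`, one further
#'     column per purification. Sample identifiers are taken verbatim from
#'     the column headers.}
#'   \item{`"maxquant"`}{A MaxQuant-style `proteinGroups.txt`: protein
#'     identifiers come from the `Protein IDs` column (or the first column if
#'     absent) and one `Intensity <sample>` column per purification. Rows
#'     flagged as decoy or contaminant hits (identifier prefix `REV__` or
#'     `CON__`, or a `+` in the `Reverse` / `Potential contaminant` columns)
#'     are dropped; the number of dropped rows is reported via a message.}
#' }
#'
#' @param path Path to the file.
#' @param dialect Either `"wide"` or `"maxquant"`.
#' @return A tibble with columns `protein`, `purification`, `intensity`.
#'   Rows are grouped by purification in column order, proteins in file
#'   order within each purification.
#' @export
read_intensity_table <- function(path, dialect = c("wide", "maxquant")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_parse(sprintf("File '%s' does not exist.", path))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         name_repair = "minimal")
  if (dialect == "wide") {
    parse_wide_intensities(raw, path)
  } else {
    parse_maxquant_intensities(raw, path)
  }
}

parse_wide_intensities <- function(raw, path) {
  if (ncol(raw) < 2L || names(raw)[1L] != "protein") {
    abort_parse(sprintf(
      "Malformed header in '%s': first column must be named 'protein' (got '%s').",
      path, names(raw)[1L] %||% ""
    ))
  }
  samples <- names(raw)[-1L]
  dup_cols <- unique(samples[duplicated(samples)])
  if (length(dup_cols) > 0L) {
    abort_parse(sprintf(
      "Malformed header in '%s': duplicated purification column(s) %s.",
      path, paste0("'", dup_cols, "'", collapse = ", ")
    ))
  }
  build_intensity_tbl(raw$protein, raw[samples], samples)
}

parse_maxquant_intensities <- function(raw, path) {
  id_col <- if ("Protein IDs" %in% names(raw)) "Protein IDs" else names(raw)[1L]
  int_cols <- grep("^Intensity .+", names(raw), value = TRUE)
  if (length(int_cols) == 0L) {
    abort_parse(sprintf(
      "Malformed header in '%s': no 'Intensity <sample>' columns found.", path
    ))
  }
  ids <- as.character(raw[[id_col]])
  drop <- startsWith(ids, "REV__") | startsWith(ids, "CON__")
  for (flag_col in c("Reverse", "Potential contaminant")) {
    if (flag_col %in% names(raw)) {
      drop <- drop | (!is.na(raw[[flag_col]]) & raw[[flag_col]] == "+")
    }
  }
  if (any(drop)) {
    inform(sprintf(
      "Dropped %d reverse/contaminant row(s) from '%s'.", sum(drop), path
    ))
  }
  samples <- sub("^Intensity ", "", int_cols)
  values <- raw[!drop, int_cols]
  names(values) <- samples
  build_intensity_tbl(ids[!drop], values, samples)
}

build_intensity_tbl <- function(proteins, values, samples) {
  proteins <- as.character(proteins)
  dup <- unique(proteins[duplicated(proteins)])
  if (length(dup) > 0L) {
    abort_validation(sprintf(
      "Duplicate protein identifier(s): %s.",
      paste0("'", dup, "'", collapse = ", ")
    ))
  }
  values <- as_tibble(lapply(values, function(col) {
    col <- suppressWarnings(as.numeric(col))
    col[is.na(col)] <- 0
    col
  }))
  if (any(unlist(values) < 0)) {
    bad <- samples[vapply(values, function(col) any(col < 0), logical(1L))]
    abort_validation(sprintf(
      "Negative intensity in purification(s) %s.",
      paste0("'", bad, "'", collapse = ", ")
    ))
  }
  tibble(
    protein = rep(proteins, times = length(samples)),
    purification = rep(samples, each = length(proteins)),
    intensity = unlist(values, use.names = FALSE)
  )
}

#' Read a protein annotation table
#'
#' Reads a tab-separated annotation with columns `protein`, `group` and an
#' optional `contaminant` column (0/1). Group labels must come from the
#' closed vocabulary returned by [protein_groups()].
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `protein`, `group`, `contaminant` (logical).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("File '%s' does not exist.", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(raw, c("protein", "group"), "Annotation table")
  validate_annotation(tibble(
    protein = as.character(raw$protein),
    group = as.character(raw$group),
    contaminant = if ("contaminant" %in% names(raw)) {
      as.integer(raw$contaminant) == 1L
    } else {
      FALSE
    }
  ))
}

validate_annotation <- function(annotation) {
  require_columns(annotation, c("protein", "group"), "Annotation table")
  if (!"contaminant" %in% names(annotation)) annotation$contaminant <- FALSE
  unknown <- setdiff(unique(annotation$group), .group_levels)
  if (length(unknown) > 0L) {
    abort_validation(sprintf(
      "Unknown group label(s) %s; allowed labels are %s.",
      paste0("'", unknown, "'", collapse = ", "),
      paste0("'", .group_levels, "'", collapse = ", ")
    ))
  }
  dup <- unique(annotation$protein[duplicated(annotation$protein)])
  if (length(dup) > 0L) {
    abort_validation(sprintf(
      "Duplicate protein identifier(s) in annotation: %s.",
      paste0("'", dup, "'", collapse = ", ")
    ))
  }
  as_tibble(annotation)
}

# Fill in a default "other" annotation for proteins absent from the map,
# with a warning naming how many were defaulted.
complete_annotation <- function(annotation, proteins) {
  annotation <- validate_annotation(annotation)
  missing <- setdiff(proteins, annotation$protein)
  if (length(missing) > 0L) {
    warn(sprintf(
      "%d protein(s) absent from the annotation map were assigned to group 'other'.",
      length(missing)
    ))
    annotation <- bind_rows(
      annotation,
      tibble(protein = missing, group = "other", contaminant = FALSE)
    )
  }
  annotation
}

#' Read a screen design
#'
#' Reads a YAML screen design mapping each purification to its bait protein
#' and flagging outlier purifications that are excluded from the panel
#' reference mean. Expected layout:
#' ```yaml
#' baits:
#'   Rps2-TAP: Rps2
#'   Rps3-TAP: Rps3
#' outliers: [Rps3-TAP]
#' ```
#'
#' @param path Path to the YAML file.
#' @param intensities Optional intensity tibble (from
#'   [read_intensity_table()]); when supplied the design is validated
#'   against it (see [validate_design()]).
#' @return A tibble with columns `purification`, `bait`, `outlier`.
#' @export
read_design <- function(path, intensities = NULL) {
  if (!file.exists(path)) abort_parse(sprintf("File '%s' does not exist.", path))
  spec <- yaml::read_yaml(path)
  if (is.null(spec$baits) || length(spec$baits) == 0L) {
    abort_parse(sprintf("Design file '%s' has no 'baits' mapping.", path))
  }
  design <- tibble(
    purification = names(spec$baits),
    bait = as.character(unlist(spec$baits, use.names = FALSE)),
    outlier = names(spec$baits) %in% as.character(spec$outliers %||% character())
  )
  stray <- setdiff(as.character(spec$outliers %||% character()), design$purification)
  if (length(stray) > 0L) {
    abort_validation(sprintf(
      "Outlier purification(s) not present in the design: %s.",
      paste0("'", stray, "'", collapse = ", ")
    ))
  }
  if (!is.null(intensities)) validate_design(design, intensities)
  design
}

#' Validate a screen design against an intensity table
#'
#' Checks that every purification of the design exists in the intensity
#' table, that every bait protein exists in the table's protein universe, and
#' that outliers are a subset of the design's purifications.
#'
#' @param design Design tibble with columns `purification`, `bait`,
#'   `outlier`.
#' @param intensities Long intensity tibble.
#' @return The design, invisibly, if valid; otherwise an error.
#' @export
validate_design <- function(design, intensities) {
  require_columns(design, c("purification", "bait", "outlier"), "Screen design")
  require_columns(intensities, c("protein", "purification"), "Intensity table")
  missing_baits <- setdiff(design$bait, unique(intensities$protein))
  if (length(missing_baits) > 0L) {
    abort_validation(sprintf(
      "Bait protein(s) not found in the intensity table: %s.",
      paste0("'", missing_baits, "'", collapse = ", ")
    ))
  }
  missing_purifs <- setdiff(design$purification, unique(intensities$purification))
  if (length(missing_purifs) > 0L) {
    abort_validation(sprintf(
      "Design purification(s) not found in the intensity table: %s.",
      paste0("'", missing_purifs, "'", collapse = ", ")
    ))
  }
  invisible(design)
}

#' Read qRT-PCR starting-concentration (N0) records
#'
#' Reads a CSV of per-reaction starting concentrations with columns
#' `purification,amplicon,fraction,replicate,n0`. The `fraction` column must
#' contain only `TEV` (TEV eluate) and `total` (total extract); `n0` values
#' are arbitrary fluorescence units and must be positive.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `purification`, `amplicon`, `fraction`,
#'   `replicate`, `n0`.
#' @export
read_n0 <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("File '%s' does not exist.", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(raw, c("purification", "amplicon", "fraction", "replicate", "n0"),
                  "N0 table")
  n0 <- tibble(
    purification = as.character(raw$purification),
    amplicon = as.character(raw$amplicon),
    fraction = as.character(raw$fraction),
    replicate = as.integer(raw$replicate),
    n0 = as.numeric(raw$n0)
  )
  bad_fraction <- setdiff(unique(n0$fraction), c("TEV", "total"))
  if (length(bad_fraction) > 0L) {
    abort_validation(sprintf(
      "Unknown fraction label(s) %s; must be 'TEV' or 'total'.",
      paste0("'", bad_fraction, "'", collapse = ", ")
    ))
  }
  if (any(!is.finite(n0$n0)) || any(n0$n0 <= 0)) {
    abort_validation("All N0 values must be positive and finite.")
  }
  n0
}

#' Read a purification-to-amplicon partner map
#'
#' Reads a YAML mapping from each chaperone purification to the mRNA amplicon
#' of its cognate (client) ribosomal protein, either as a top-level mapping
#' or nested under a `partners:` key.
#'
#' @param path Path to the YAML file.
#' @return A tibble with columns `purification`, `amplicon`.
#' @export
read_partners <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("File '%s' does not exist.", path))
  spec <- yaml::read_yaml(path)
  if (!is.null(spec$partners)) spec <- spec$partners
  if (length(spec) == 0L) {
    abort_parse(sprintf("Partner file '%s' contains no mapping.", path))
  }
  tibble(
    purification = names(spec),
    amplicon = as.character(unlist(spec, use.names = FALSE))
  )
}

#' Validate N0 records against a partner map
#'
#' Checks that every purification has exactly one cognate amplicon, that the
#' cognate amplicon occurs in the N0 records, and that every
#' (purification, amplicon, fraction) combination has at least one replicate
#' for both fractions.
#'
#' @param n0 N0 tibble from [read_n0()].
#' @param partners Partner tibble from [read_partners()].
#' @return The partner map, invisibly, if valid.
#' @export
validate_n0 <- function(n0, partners) {
  require_columns(n0, c("purification", "amplicon", "fraction", "replicate", "n0"),
                  "N0 table")
  require_columns(partners, c("purification", "amplicon"), "Partner map")
  purifs <- unique(n0$purification)
  amps <- unique(n0$amplicon)
  counts <- table(factor(partners$purification, levels = purifs))
  bad <- names(counts)[counts != 1L]
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "Purification(s) with zero or multiple cognate amplicons: %s.",
      paste0("'", bad, "'", collapse = ", ")
    ))
  }
  absent <- setdiff(partners$amplicon, amps)
  if (length(absent) > 0L) {
    abort_validation(sprintf(
      "Cognate amplicon(s) absent from the N0 records: %s.",
      paste0("'", absent, "'", collapse = ", ")
    ))
  }
  invisible(partners)
}
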
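# End-to-end drivers: read inputs, run one analysis stage, write TSV
# artifacts plus a parameter echo and a checksummed manifest. All numeric
# output uses a fixed 9-significant-digit format so reruns are
# byte-identical; plots are deliberately not written here (TSV matrices are
# the contract).

write_result_tsv <- function(x, path) {
  out <- as_tibble(x)
  out[] <- lapply(out, format_signif)
  readr::write_tsv(out, path, progress = FALSE)
  path
}

finish_run <- function(out_dir, files, params) {
  params_path <- file.path(out_dir, "params.yaml")
  yaml::write_yaml(params, params_path)
  files <- c(files, params_path)
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files)
  )
  manifest_path <- file.path(out_dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path, progress = FALSE)
  invisible(c(files, manifest_path))
}

prepare_out_dir <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort_validation(sprintf("Could not create output directory '%s'.", out_dir))
  }
  out_dir
}

#' Run the co-enrichment screen from files on disk
#'
#' Reads an intensity table, screen design and annotation, runs
#' [screen_enrichment()] and writes `relative_intensities.tsv`,
#' `heatmap_matrix.tsv`, one `enrichment_<purification>.tsv` per
#' purification, `candidates.tsv`, a `params.yaml` parameter echo and a
#' checksummed `manifest.tsv` into `out_dir`.
#'
#' @param intensities Path to the intensity table.
#' @param design Path to the design YAML.
#' @param annotation Optional path to the annotation TSV.
#' @param out_dir Output directory (created if needed).
#' @param dialect Intensity dialect, see [read_intensity_table()].
#' @param min_log10_ratio,min_relint,leave_one_out See
#'   [screen_enrichment()].
#' @return The `chaperome_screen` object, invisibly.
#' @export
run_screen <- function(intensities, design, annotation = NULL, out_dir,
                       dialect = "wide", min_log10_ratio = 1,
                       min_relint = 0.01, leave_one_out = FALSE) {
  out_dir <- prepare_out_dir(out_dir)
  x <- read_intensity_table(intensities, dialect = dialect)
  dsg <- read_design(design, x)
  ann <- if (!is.null(annotation)) read_annotation(annotation)
  scr <- screen_enrichment(x, dsg, annotation = ann,
                           min_log10_ratio = min_log10_ratio,
                           min_relint = min_relint,
                           leave_one_out = leave_one_out)
  files <- character()
  rel_wide <- tidyr::pivot_wider(scr$relative, names_from = "purification",
                                 values_from = "relint")
  files <- c(files, write_result_tsv(
    rel_wide, file.path(out_dir, "relative_intensities.tsv")
  ))
  if (!is.null(ann)) {
    hm <- scr$relative |> replace_zeros() |> log10_relative() |>
      heatmap_order(ann)
    hm_wide <- hm |>
      mutate(protein = as.character(.data$protein)) |>
      select("protein", "group", "purification", "log10_relint") |>
      tidyr::pivot_wider(names_from = "purification",
                         values_from = "log10_relint")
    files <- c(files, write_result_tsv(
      hm_wide, file.path(out_dir, "heatmap_matrix.tsv")
    ))
  }
  for (p in dsg$purification) {
    etab <- filter(scr$enrichment, .data$focal == p)
    files <- c(files, write_result_tsv(
      etab, file.path(out_dir, sprintf("enrichment_%s.tsv", p))
    ))
  }
  files <- c(files, write_result_tsv(
    scr$candidates, file.path(out_dir, "candidates.tsv")
  ))
  finish_run(out_dir, files, list(
    subcommand = "run", intensities = intensities, design = design,
    annotation = annotation, dialect = dialect,
    min_log10_ratio = min_log10_ratio, min_relint = min_relint,
    leave_one_out = leave_one_out
  ))
  invisible(scr)
}

#' Run the split-tag purification comparison from files on disk
#'
#' Reads an intensity table, runs [split_compare()] for the given pools and
#' writes `split_comparison.tsv`, `group_summary.tsv` (when annotated),
#' `params.yaml` and `manifest.tsv`.
#'
#' @param intensities Path to the intensity table.
#' @param bait Bait protein identifier.
#' @param enriched,depleted Purification identifiers of the two pools.
#' @param annotation Optional path to the annotation TSV.
#' @param out_dir Output directory.
#' @param dialect Intensity dialect.
#' @return The `split_comparison` tibble, invisibly.
#' @export
run_split <- function(intensities, bait, enriched, depleted,
                      annotation = NULL, out_dir, dialect = "wide") {
  out_dir <- prepare_out_dir(out_dir)
  x <- read_intensity_table(intensities, dialect = dialect)
  ann <- if (!is.null(annotation)) read_annotation(annotation)
  cmp <- split_compare(x, enriched = enriched, depleted = depleted,
                       bait = bait, annotation = ann)
  files <- write_result_tsv(cmp, file.path(out_dir, "split_comparison.tsv"))
  if (!is.null(ann)) {
    files <- c(files, write_result_tsv(
      split_group_summary(cmp), file.path(out_dir, "group_summary.tsv")
    ))
  }
  finish_run(out_dir, files, list(
    subcommand = "split", intensities = intensities, bait = bait,
    enriched = enriched, depleted = depleted, annotation = annotation,
    dialect = dialect
  ))
  invisible(cmp)
}

#' Run the co-translational binding analysis from files on disk
#'
#' Reads N0 records and a partner map, runs [replicate_ratios()] and
#' [normalize_cotrans()], and writes `ratios.tsv`, `normalized.tsv`,
#' `cognate_scores.tsv`, optionally `permutation_pvalues.tsv`, plus
#' `params.yaml` and `manifest.tsv`.
#'
#' @param n0 Path to the N0 CSV.
#' @param partners Path to the partner-map YAML.
#' @param out_dir Output directory.
#' @param permutations Number of partner-map permutations for the optional
#'   significance assessment (0 = skip).
#' @param seed Seed for the permutation draw.
#' @return The `cotrans_result`, invisibly.
#' @export
run_cotrans <- function(n0, partners, out_dir, permutations = 0,
                        seed = NULL) {
  out_dir <- prepare_out_dir(out_dir)
  n0_tbl <- read_n0(n0)
  prt <- read_partners(partners)
  rm <- replicate_ratios(n0_tbl, prt)
  res <- normalize_cotrans(rm)
  files <- c(
    write_result_tsv(select(rm, -"cognate"), file.path(out_dir, "ratios.tsv")),
    write_result_tsv(res$table, file.path(out_dir, "normalized.tsv")),
    write_result_tsv(res$cognate_scores,
                     file.path(out_dir, "cognate_scores.tsv"))
  )
  if (permutations > 0) {
    files <- c(files, write_result_tsv(
      cotrans_permutation(rm, n_permutations = permutations, seed = seed),
      file.path(out_dir, "permutation_pvalues.tsv")
    ))
  }
  finish_run(out_dir, files, list(
    subcommand = "cotrans", n0 = n0, partners = partners,
    permutations = permutations, seed = seed
  ))
  invisible(res)
}

#' Generate synthetic inputs on disk
#'
#' Runs one of the synthetic generators and writes the standard input files
#' (intensity TSV, annotation TSV and design YAML for `"tapms"`; N0 CSV and
#' partner YAML for `"cotrans"`) plus `truth.yaml`, `params.yaml` and
#' `manifest.tsv`.
#'
#' @param type `"tapms"` or `"cotrans"`.
#' @param out_dir Output directory.
#' @param seed Integer seed (overrides the config's seed).
#' @param config Named list of overrides passed to [screen_sim_config()] or
#'   [cotrans_sim_config()].
#' @return The generator's result list, invisibly.
#' @export
run_simulate <- function(type = c("tapms", "cotrans"), out_dir, seed = 1L,
                         config = list()) {
  type <- match.arg(type)
  out_dir <- prepare_out_dir(out_dir)
  config$seed <- seed
  if (type == "tapms") {
    sim <- simulate_screen(do.call(screen_sim_config, config))
    files <- c(
      write_intensity_table(sim$intensities,
                            file.path(out_dir, "intensities.tsv")),
      write_annotation(sim$annotation, file.path(out_dir, "annotation.tsv")),
      write_design(sim$design, file.path(out_dir, "design.yaml"))
    )
    truth <- list(partners = lapply(
      seq_len(nrow(sim$truth$partners)),
      function(i) as.list(sim$truth$partners[i, ])
    ), zero_rate = sim$truth$zero_rate)
  } else {
    sim <- simulate_cotrans(do.call(cotrans_sim_config, config))
    files <- c(
      write_n0(sim$n0, file.path(out_dir, "n0.csv")),
      write_partners(sim$partners, file.path(out_dir, "partners.yaml"))
    )
    truth <- lapply(sim$truth, as.list)
  }
  truth_path <- file.path(out_dir, "truth.yaml")
  yaml::write_yaml(truth, truth_path)
  finish_run(out_dir, c(files, truth_path),
             c(list(subcommand = "simulate", type = type), config))
  invisible(sim)
}
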
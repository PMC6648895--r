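# Small in-code fixtures shared across tests.

# Convert a proteins x purifications matrix (with dimnames) to the long
# intensity tibble the package consumes.
as_long_intensity <- function(mat) {
  tibble::tibble(
    protein = rep(rownames(mat), times = ncol(mat)),
    purification = rep(colnames(mat), each = nrow(mat)),
    intensity = as.vector(mat)
  )
}

toy_matrix <- function(values, proteins = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- proteins %||% paste0("p", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  m
}

toy_design <- function(mat, outliers = character()) {
  tibble::tibble(
    purification = colnames(mat),
    bait = rownames(mat)[seq_len(ncol(mat))],
    outlier = colnames(mat) %in% outliers
  )
}

toy_annotation <- function(proteins, groups) {
  tibble::tibble(protein = proteins, group = groups, contaminant = FALSE)
}

# Relative-intensity tibble (already zero-replaced) from a matrix of
# percent values.
relint_tbl <- function(mat) {
  out <- as_long_intensity(mat)
  names(out)[names(out) == "intensity"] <- "relint"
  attr(out, "zero_replaced") <- TRUE
  out
}

# Ratio tibble for the co-translational analysis from a purifications x
# amplicons matrix with diagonal partners.
ratio_tbl_from_matrix <- function(mat, partner_idx = seq_len(nrow(mat))) {
  purifs <- rownames(mat) %||% paste0("P", seq_len(nrow(mat)))
  amps <- colnames(mat) %||% paste0("M", seq_len(ncol(mat)))
  rownames(mat) <- purifs
  colnames(mat) <- amps
  out <- tibble::tibble(
    purification = rep(purifs, times = ncol(mat)),
    amplicon = rep(amps, each = nrow(mat)),
    ratio = as.vector(mat)
  )
  partners <- tibble::tibble(purification = purifs,
                             amplicon = amps[partner_idx])
  out$cognate <- paste(out$purification, out$amplicon) %in%
    paste(partners$purification, partners$amplicon)
  attr(out, "partners") <- partners
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
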
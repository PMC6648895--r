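# Independent brute-force recomputations written directly from the method
# definitions in plain base R loops. They share no code with the package
# implementation and are used as oracles in the equivalence tests.

# Per-protein enrichment of `focal` against the outlier-excluded panel mean.
# mat: proteins x purifications intensity matrix with dimnames.
oracle_enrichment <- function(mat, focal, outliers = character(),
                              leave_one_out = FALSE) {
  relint <- mat
  for (j in seq_len(ncol(mat))) {
    relint[, j] <- 100 * mat[, j] / sum(mat[, j])
  }
  relint[relint == 0] <- 1e-4
  included <- setdiff(colnames(mat), outliers)
  if (focal %in% outliers) included <- union(included, focal)
  if (leave_one_out) included <- setdiff(included, focal)
  out <- data.frame(protein = rownames(mat), relint_focal = NA_real_,
                    reference_mean = NA_real_, log10_ratio = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mat))) {
    m <- 0
    for (j in included) m <- m + relint[i, j]
    m <- m / length(included)
    out$relint_focal[i] <- relint[i, focal]
    out$reference_mean[i] <- m
    out$log10_ratio[i] <- log10(relint[i, focal] / m)
  }
  ord <- order(-out$log10_ratio, out$protein)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out
}

# Two-way background normalization of a purifications x amplicons ratio
# matrix; partner_idx[p] gives the cognate amplicon column of row p.
oracle_cotrans <- function(ratio_mat, partner_idx = seq_len(nrow(ratio_mat))) {
  np <- nrow(ratio_mat)
  nm <- ncol(ratio_mat)
  cognate <- matrix(FALSE, np, nm)
  for (p in seq_len(np)) cognate[p, partner_idx[p]] <- TRUE
  pb <- numeric(np)
  for (p in seq_len(np)) {
    vals <- c()
    for (m in seq_len(nm)) if (!cognate[p, m]) vals <- c(vals, ratio_mat[p, m])
    pb[p] <- mean(vals)
  }
  ab <- numeric(nm)
  for (m in seq_len(nm)) {
    vals <- c()
    for (p in seq_len(np)) if (!cognate[p, m]) vals <- c(vals, ratio_mat[p, m])
    ab[m] <- mean(vals)
  }
  corrected <- matrix(NA_real_, np, nm)
  for (p in seq_len(np)) for (m in seq_len(nm)) {
    corrected[p, m] <- ratio_mat[p, m] / (pb[p] * ab[m])
  }
  bg_mean <- mean(corrected[!cognate])
  normalized <- corrected / bg_mean
  list(purification_background = pb, amplicon_background = ab,
       corrected = corrected, normalized = normalized,
       cognate_scores = normalized[cbind(seq_len(np), partner_idx)])
}
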
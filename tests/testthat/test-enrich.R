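# Reference means, enrichment tables, candidate ranking, and the
# oracle-equivalence and invariance properties of the screen.

test_that("reference mean averages the outlier-excluded panel", {
  mat <- toy_matrix(matrix(c(0.1, 0.1, 0.1, 10), nrow = 1),
                    proteins = "chp", samples = paste0("s", 1:4))
  x <- relint_tbl(mat)

  no_outliers <- toy_design(toy_matrix(matrix(1, 4, 4)), outliers = character())
  no_outliers$bait <- "chp"
  expect_equal(reference_mean(x, no_outliers, "s4")$reference_mean, 2.575)

  with_outlier <- no_outliers
  with_outlier$outlier <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(reference_mean(x, with_outlier, "s4")$reference_mean, 3.4)

  # a focal purification that is itself an outlier is re-included in its
  # own reference
  expect_equal(reference_mean(x, with_outlier, "s1")$reference_mean,
               mean(c(0.1, 0.1, 0.1, 10)))

  # leave-one-out mode excludes the focal purification
  expect_equal(
    reference_mean(x, no_outliers, "s4", leave_one_out = TRUE)$reference_mean,
    0.1
  )

  all_out <- no_outliers
  all_out$outlier <- c(FALSE, TRUE, TRUE, TRUE)
  expect_error(reference_mean(x, all_out, "s1"), "Fewer than 2",
               class = "chaperscreen_validation_error")
})

test_that("enrichment table reports log ratios, ranks and the bait flag", {
  mat <- toy_matrix(rbind(c(2, 2, 2, 2),
                          c(0.1, 0.1, 0.1, 10),
                          c(5, 5, 5, 5)),
                    proteins = c("bait4", "chp", "uni"),
                    samples = paste0("s", 1:4))
  x <- relint_tbl(mat)
  design <- tibble::tibble(purification = paste0("s", 1:4),
                           bait = "bait4", outlier = FALSE)
  et <- enrichment_table(x, design, "s4")
  chp <- et[et$protein == "chp", ]
  expect_equal(chp$reference_mean, 2.575)
  expect_equal(chp$log10_ratio, 0.58922, tolerance = 1e-4)
  expect_equal(chp$rank, 1L)
  # uniform proteins sit on the diagonal
  expect_equal(et$log10_ratio[et$protein == "uni"], 0)
  expect_true(et$is_bait[et$protein == "bait4"])
  expect_equal(sort(et$rank), 1:3)
})

test_that("a protein detected only in the focal purification tops the ranking", {
  n <- 12
  mat <- toy_matrix(rbind(rep(50, n),
                          c(rep(50, n - 1), 49.9),
                          c(rep(1e-4, n - 1), 0.1)),
                    proteins = c("bait", "rp", "only"))
  x <- relint_tbl(mat)
  design <- tibble::tibble(purification = colnames(mat), bait = "bait",
                           outlier = FALSE)
  et <- enrichment_table(x, design, paste0("s", n))
  expect_equal(et$protein[et$rank == 1L], "only")
  expect_gt(et$log10_ratio[et$protein == "only"], 1)
})

test_that("candidate ranking applies both thresholds and drops the bait", {
  n <- 12
  mat <- toy_matrix(rbind(rep(50, n),
                          c(rep(50, n - 1), 49.9),
                          c(rep(1e-4, n - 1), 0.1)),
                    proteins = c("bait", "rp", "only"))
  x <- relint_tbl(mat)
  design <- tibble::tibble(purification = colnames(mat), bait = "bait",
                           outlier = FALSE)
  et <- enrichment_table(x, design, paste0("s", n))
  cand <- rank_candidates(et)
  expect_equal(cand$protein, "only")
  expect_equal(nrow(rank_candidates(et, min_log10_ratio = Inf)), 0L)
  # the focal-specific protein fails the detection threshold if too faint
  expect_equal(nrow(rank_candidates(et, min_relint = 1)), 0L)
  expect_error(rank_candidates(et, min_log10_ratio = -1),
               class = "chaperscreen_validation_error")
})

test_that("enrichment matches the brute-force oracle on random small grids", {
  set.seed(421)
  vals <- c(0, 1, 2, 5, 10)
  for (i in 1:120) {
    nr <- sample(2:5, 1)
    nc <- sample(2:5, 1)
    repeat {
      m <- matrix(sample(vals, nr * nc, replace = TRUE), nr, nc)
      if (all(colSums(m) > 0)) break
    }
    mat <- toy_matrix(m)
    outliers <- if (nc > 2 && runif(1) < 0.3) "s1" else character()
    design <- toy_design(mat, outliers = outliers)
    x <- replace_zeros(normalize_relative(as_long_intensity(mat)))
    focal <- sample(colnames(mat), 1)
    got <- enrichment_table(x, design, focal)
    want <- oracle_enrichment(mat, focal, outliers)
    got <- got[order(got$protein), ]
    want <- want[order(want$protein), ]
    expect_equal(got$log10_ratio, want$log10_ratio, tolerance = 1e-12)
    expect_equal(got$reference_mean, want$reference_mean, tolerance = 1e-12)
    expect_equal(got$rank, want$rank)
  }
})

test_that("the screen is invariant to rescaling a raw purification column", {
  set.seed(7)
  m <- matrix(rexp(20) * 100, 5, 4)
  m[sample(20, 4)] <- 0
  mat <- toy_matrix(m)
  design <- toy_design(mat)
  scaled <- mat
  scaled[, 2] <- scaled[, 2] * 37.5

  pipeline <- function(mm) {
    replace_zeros(normalize_relative(as_long_intensity(mm)))
  }
  expect_equal(pipeline(mat)$relint, pipeline(scaled)$relint, tolerance = 1e-12)
  e1 <- enrichment_table(pipeline(mat), design, "s2")
  e2 <- enrichment_table(pipeline(scaled), design, "s2")
  expect_equal(e1$log10_ratio, e2$log10_ratio, tolerance = 1e-12)

  ann <- toy_annotation(rownames(mat), rep("other", 5))
  h1 <- heatmap_order(log10_relative(pipeline(mat)), ann)
  h2 <- heatmap_order(log10_relative(pipeline(scaled)), ann)
  expect_equal(levels(h1$protein), levels(h2$protein))
  expect_equal(h1$log10_relint, h2$log10_relint, tolerance = 1e-12)
})

test_that("uniform proteins have zero log ratio for every focal purification", {
  mat <- toy_matrix(matrix(3.2, 4, 5))
  design <- toy_design(mat, outliers = "s5")
  x <- replace_zeros(normalize_relative(as_long_intensity(mat)))
  for (focal in colnames(mat)) {
    expect_equal(enrichment_table(x, design, focal)$log10_ratio, rep(0, 4))
  }
})
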
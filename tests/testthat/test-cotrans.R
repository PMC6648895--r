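# TEV/total ratios, two-way background correction, unit-mean normalization
# and their exact properties.

test_that("replicate ratios are ratios of replicate means", {
  n0 <- tibble::tibble(
    purification = "P1", amplicon = "M1",
    fraction = rep(c("TEV", "total"), each = 2),
    replicate = c(1L, 2L, 1L, 2L),
    n0 = c(2, 4, 1, 3)
  )
  partners <- tibble::tibble(purification = "P1", amplicon = "M1")
  rm <- replicate_ratios(n0, partners)
  expect_equal(rm$ratio, 1.5)
  expect_true(rm$cognate)

  # identical triplicates give ratio 1; single replicates a plain quotient
  n0b <- tibble::tibble(
    purification = "P1", amplicon = "M1",
    fraction = rep(c("TEV", "total"), each = 3),
    replicate = rep(1:3, 2), n0 = rep(c(7, 7), each = 3)
  )
  expect_equal(replicate_ratios(n0b, partners)$ratio, 1)
  n0c <- tibble::tibble(purification = "P1", amplicon = "M1",
                        fraction = c("TEV", "total"), replicate = 1L,
                        n0 = c(5, 2))
  expect_equal(replicate_ratios(n0c, partners)$ratio, 2.5)
})

test_that("unbalanced replicates warn and missing fractions error", {
  n0 <- tibble::tibble(
    purification = "P1", amplicon = "M1",
    fraction = c("TEV", "TEV", "total"),
    replicate = c(1L, 2L, 1L), n0 = c(2, 4, 2)
  )
  partners <- tibble::tibble(purification = "P1", amplicon = "M1")
  expect_warning(rm <- replicate_ratios(n0, partners), "Unbalanced")
  expect_equal(rm$ratio, 1.5)

  n0m <- n0[n0$fraction == "TEV", ]
  expect_error(suppressWarnings(replicate_ratios(n0m, partners)),
               "Missing TEV or total",
               class = "chaperscreen_validation_error")
})

test_that("background means exclude exactly the cognate cells", {
  rm <- ratio_tbl_from_matrix(toy_matrix(rbind(c(8, 1), c(1, 1)),
                                         proteins = c("P1", "P2"),
                                         samples = c("M1", "M2")))
  bg <- background_means(rm)
  expect_equal(bg$purification$background, c(1, 1))
  expect_equal(bg$amplicon$background, c(1, 1))

  # constant matrix: both backgrounds equal that constant
  rmc <- ratio_tbl_from_matrix(toy_matrix(matrix(5, 3, 3)))
  bgc <- background_means(rmc)
  expect_equal(bgc$purification$background, rep(5, 3))
  expect_equal(bgc$amplicon$background, rep(5, 3))

  # an inflated cognate diagonal never touches the backgrounds
  m <- matrix(2, 5, 5)
  diag(m) <- c(100, 7, 50, 2, 1000)
  bg5 <- background_means(ratio_tbl_from_matrix(toy_matrix(m)))
  expect_equal(bg5$purification$background, rep(2, 5))
  expect_equal(bg5$amplicon$background, rep(2, 5))
})

test_that("worked examples: planted 2x2 matrix and uniform matrix", {
  rm <- ratio_tbl_from_matrix(toy_matrix(rbind(c(8, 1), c(1, 1))))
  res <- normalize_cotrans(rm)
  expect_equal(res$table$normalized,
               res$table$ratio, tolerance = 1e-12)
  expect_equal(res$cognate_scores$score, c(8, 1))
  expect_equal(res$cognate_scores$rank_in_purification, c(1L, 2L))

  uni <- normalize_cotrans(ratio_tbl_from_matrix(toy_matrix(matrix(5, 3, 3))))
  expect_equal(unique(round(uni$table$corrected, 12)), 0.2)
  expect_equal(uni$table$normalized, rep(1, 9), tolerance = 1e-12)
})

test_that("normalized background cells average exactly one", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    m <- matrix(rexp(n * n) + 0.05, n, n)
    res <- normalize_cotrans(ratio_tbl_from_matrix(toy_matrix(m)))
    expect_equal(mean(res$table$normalized[!res$table$cognate]), 1,
                 tolerance = 1e-9)
    expect_true(all(res$table$normalized > 0))
  }
})

test_that("two-way normalization matches the brute-force oracle", {
  set.seed(5)
  for (i in 1:150) {
    n <- sample(3:5, 1)
    m <- matrix(sample(1:10, n * n, replace = TRUE), n, n)
    res <- normalize_cotrans(ratio_tbl_from_matrix(toy_matrix(m)))
    want <- oracle_cotrans(m)
    expect_equal(res$purification_background$background,
                 want$purification_background, tolerance = 1e-12)
    expect_equal(res$amplicon_background$background,
                 want$amplicon_background, tolerance = 1e-12)
    got_norm <- matrix(res$table$normalized, n, n)
    expect_equal(got_norm, unname(want$normalized), tolerance = 1e-12)
    expect_equal(res$cognate_scores$score, want$cognate_scores,
                 tolerance = 1e-12)
  }
})

test_that("whole-matrix rescaling leaves normalized values unchanged", {
  set.seed(31)
  m <- matrix(rexp(25) + 0.1, 5, 5)
  a <- normalize_cotrans(ratio_tbl_from_matrix(toy_matrix(m)))
  b <- normalize_cotrans(ratio_tbl_from_matrix(toy_matrix(m * 123.4)))
  expect_equal(a$table$normalized, b$table$normalized, tolerance = 1e-12)
})

test_that("scaling one purification row preserves its own corrected cognate value", {
  # a per-purification efficiency factor cancels between the cognate cell
  # and that purification's own background mean
  m <- matrix(1, 4, 4)
  diag(m) <- c(6, 3, 2, 1.5)
  base <- normalize_cotrans(ratio_tbl_from_matrix(toy_matrix(m)))
  m2 <- m
  m2[2, ] <- m2[2, ] * 10
  scaled <- normalize_cotrans(ratio_tbl_from_matrix(toy_matrix(m2)))
  own <- function(res, p) {
    res$table$corrected[res$table$cognate][p]
  }
  expect_equal(own(scaled, 2), own(base, 2), tolerance = 1e-12)
})

test_that("permutation p-values single out a strongly enriched cognate pair", {
  m <- matrix(1, 4, 4)
  diag(m) <- c(20, 1, 1, 1)
  rm <- ratio_tbl_from_matrix(toy_matrix(m))
  pv <- cotrans_permutation(rm, n_permutations = 200, seed = 42)
  expect_lt(pv$p_value[1], 0.3)
  expect_equal(pv$observed_score[1],
               normalize_cotrans(rm)$cognate_scores$score[1])
  # reproducible under the same seed
  pv2 <- cotrans_permutation(rm, n_permutations = 200, seed = 42)
  expect_equal(pv, pv2)
})
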
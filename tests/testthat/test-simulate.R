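# Synthetic generators: determinism, validation, calibration and planted
# ground-truth recovery.

test_that("configurations are validated", {
  expect_error(screen_sim_config(n_purifications = 1),
               class = "chaperscreen_validation_error")
  expect_error(screen_sim_config(fold_enrichment = 0),
               class = "chaperscreen_validation_error")
  expect_error(screen_sim_config(dropout_rate = 1.2),
               class = "chaperscreen_validation_error")
  expect_error(screen_sim_config(n_specific_partners = 30),
               class = "chaperscreen_validation_error")
  expect_error(cotrans_sim_config(n_amplicons = 3, n_purifications = 5),
               class = "chaperscreen_validation_error")
  expect_error(cotrans_sim_config(enrichment = -1),
               class = "chaperscreen_validation_error")
  expect_error(simulate_screen(list()),
               class = "chaperscreen_validation_error")
})

test_that("generators are pure functions of configuration and seed", {
  cfg <- screen_sim_config(seed = 77)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a, b)
  c <- simulate_screen(screen_sim_config(seed = 78))
  expect_false(identical(a$intensities$intensity, c$intensities$intensity))

  ccfg <- cotrans_sim_config(seed = 5)
  expect_identical(simulate_cotrans(ccfg), simulate_cotrans(ccfg))
})

test_that("generated tables pass the input validations", {
  sim <- simulate_screen(screen_sim_config(seed = 2))
  expect_true(all(sim$intensities$intensity >= 0))
  expect_silent(validate_design(sim$design, sim$intensities))
  expect_identical(sim$annotation, validate_annotation(sim$annotation))
  expect_equal(nrow(sim$intensities), 200 * 25)

  csim <- simulate_cotrans(cotrans_sim_config(seed = 2))
  expect_silent(validate_n0(csim$n0, csim$partners))
})

test_that("the realized zero rate tracks the requested dropout rate", {
  rates <- vapply(1:5, function(s) {
    simulate_screen(screen_sim_config(seed = s))$truth$zero_rate
  }, numeric(1))
  expect_true(all(abs(rates - 0.2) < 0.03))
  none <- simulate_screen(screen_sim_config(dropout_rate = 0,
                                            n_trace = 0,
                                            n_contaminants = 0,
                                            n_core_proteins = 174,
                                            seed = 3))
  expect_equal(none$truth$zero_rate, mean(none$intensities$intensity == 0))
})

test_that("noise-free planted enrichment matches direct arithmetic", {
  cfg <- screen_sim_config(
    n_purifications = 4, n_core_proteins = 10, n_trace = 0,
    n_contaminants = 0, fold_enrichment = 10, noise_sigma_log10 = 0,
    dropout_rate = 0, seed = 9
  )
  sim <- simulate_screen(cfg)
  focal <- sim$truth$partners$purification[1]
  partner <- sim$truth$partners$partner[1]
  x <- replace_zeros(normalize_relative(sim$intensities))
  et <- enrichment_table(x, sim$design, focal)

  # recompute the planted cell's expected log ratio by direct arithmetic on
  # the generated intensities
  wide <- tapply(sim$intensities$intensity,
                 list(sim$intensities$protein, sim$intensities$purification),
                 sum)
  totals <- colSums(wide)
  rel <- 100 * sweep(wide, 2, totals, "/")
  rel[rel == 0] <- 1e-4
  expected <- log10(rel[partner, focal] / mean(rel[partner, ]))
  expect_equal(et$log10_ratio[et$protein == partner], expected,
               tolerance = 1e-12)
  expect_gt(et$log10_ratio[et$protein == partner], 0.5)
})

test_that("planted chaperones are recovered and null screens stay clean", {
  # interior point of the generator's operating range: fold 10 with
  # moderate measurement noise and the default 20% zero rate
  run_one <- function(seed, fold, sigma) {
    sim <- suppressWarnings(simulate_screen(screen_sim_config(
      fold_enrichment = fold, noise_sigma_log10 = sigma, seed = seed)))
    focal <- sim$truth$partners$purification[1]
    x <- replace_zeros(normalize_relative(sim$intensities))
    cand <- rank_candidates(enrichment_table(x, sim$design, focal))
    c(n = nrow(cand),
      hit = nrow(cand) > 0 &&
        cand$protein[1] == sim$truth$partners$partner[1])
  }
  hits <- vapply(1:60, function(s) run_one(s, 10, 0.2)["hit"], numeric(1))
  expect_gte(mean(hits), 0.9)
  nulls <- vapply(1:60, function(s) run_one(s + 500, 1, 0.2)["n"], numeric(1))
  expect_gte(mean(nulls == 0), 0.9)
})

test_that("noise-free cotrans simulation recovers the planted enrichment exactly", {
  cfg <- cotrans_sim_config(n_purifications = 2, n_amplicons = 2,
                            enrichment = c(8, 1), replicate_cv = 0,
                            sigma_row = 0, sigma_col = 0,
                            total_sigma_log10 = 0.3, seed = 4)
  sim <- simulate_cotrans(cfg)
  res <- normalize_cotrans(replicate_ratios(sim$n0, sim$partners))
  expect_equal(res$cognate_scores$score, c(8, 1), tolerance = 1e-9)

  # all enrichments 1 with zero noise: every normalized value is exactly 1
  flat <- simulate_cotrans(cotrans_sim_config(enrichment = 1,
                                              replicate_cv = 0,
                                              sigma_row = 0, sigma_col = 0,
                                              seed = 6))
  resf <- normalize_cotrans(replicate_ratios(flat$n0, flat$partners))
  expect_equal(resf$table$normalized, rep(1, 25), tolerance = 1e-9)
})

test_that("cotrans truth records carry the planted design", {
  cfg <- cotrans_sim_config(enrichment = c(10, 1, 1, 10, 1), seed = 12)
  sim <- simulate_cotrans(cfg)
  expect_equal(unname(sim$truth$enrichment), c(10, 1, 1, 10, 1))
  expect_equal(nrow(sim$partners), 5L)
  expect_equal(nrow(sim$n0), 5 * 5 * 3 * 2)
})
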
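# Seeded generators for synthetic screen and qPCR data with planted ground
# truth. The screen generator emulates the structure of a TAP-MS panel of
# ribosomal-protein pull-downs: a dominant shared ribosomal proteome, one
# over-represented bait per purification, a sub-stoichiometric dedicated
# chaperone specifically co-enriched with its client, a long tail of trace
# background proteins spanning the detection limit, sporadic contaminants,
# multiplicative log-normal measurement noise, and an abundance-dependent
# detection floor that drops low signals to zero.

#' Configuration for a synthetic TAP-MS screen
#'
#' Builds and validates the configuration of [simulate_screen()]. Defaults
#' describe a panel of 25 purifications x 200 proteins: 25 bait r-proteins,
#' 129 shared background proteins (66 further r-proteins plus assembly
#' factors, translation factors and other co-purifying proteins), 36 trace
#' background proteins whose abundances sit below the detection limit,
#' 9 sporadically appearing contaminants and one planted dedicated
#' chaperone.
#'
#' Abundances are in units of the median r-protein abundance. The planted
#' chaperone is bait-specific: it appears only in its client's purification
#' (a dedicated chaperone co-purifies with its client and is not recovered
#' by the other baits), at `fold_enrichment` times the detection-limit
#' baseline `partner_baseline`. A fold of 1 therefore plants a partner
#' whose recovery stays at the detection limit, the panel's null. Dropout
#' is Bernoulli per cell with probability following a decreasing logistic
#' in log10 relative intensity (width `dropout_scale_log10` decades), whose
#' location is calibrated so the overall zero rate of the table matches
#' `dropout_rate`; the log-uniform trace tail supplies the calibration with
#' a smooth mass of sub-limit cells, as in real label-free tables where
#' zeros concentrate among low-signal proteins.
#'
#' @param n_purifications Number of bait purifications (and baits).
#' @param n_core_proteins Shared background proteins present in every
#'   purification.
#' @param n_trace Trace background proteins, present in every purification
#'   with log-uniform abundances between `trace_min` and `trace_max`.
#' @param n_contaminants Sporadic contaminant proteins.
#' @param n_specific_partners Number of planted (bait, chaperone) pairs.
#' @param fold_enrichment Recovery of each planted chaperone in its bait's
#'   purification, as a multiple of the detection-limit baseline (scalar or
#'   one value per partner). 1 plants a null partner that never rises above
#'   the detection limit.
#' @param bait_boost Fold over-representation of each bait in its own
#'   purification.
#' @param contaminant_presence Probability that a contaminant appears in any
#'   given purification.
#' @param noise_sigma_log10 Cell-wise multiplicative log-normal noise
#'   (standard deviation in log10 units).
#' @param dropout_rate Target overall fraction of zero cells (structural
#'   absences plus abundance-dependent dropout).
#' @param core_sigma_log10 Spread of the shared abundance profile.
#' @param nonrp_abundance Abundance multiplier for non-ribosomal background
#'   proteins (assembly factors etc.) relative to r-proteins.
#' @param partner_baseline Baseline abundance of planted chaperones.
#' @param trace_min,trace_max Abundance range of the trace tail.
#' @param contaminant_abundance Median abundance of contaminants.
#' @param contaminant_sigma_log10 Spread of contaminant abundances.
#' @param dropout_scale_log10 Width (decades) of the logistic detection
#'   floor.
#' @param intensity_scale Arbitrary-unit scale of the emitted intensities.
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce identical tables.
#' @return A validated `screen_sim_config` object.
#' @export
screen_sim_config <- function(n_purifications = 25,
                              n_core_proteins = 129,
                              n_trace = 36,
                              n_contaminants = 9,
                              n_specific_partners = 1,
                              fold_enrichment = 10,
                              bait_boost = 20,
                              contaminant_presence = 0.5,
                              noise_sigma_log10 = 0.3,
                              dropout_rate = 0.2,
                              core_sigma_log10 = 0.5,
                              nonrp_abundance = 0.2,
                              partner_baseline = 0.007,
                              trace_min = 1e-4,
                              trace_max = 5e-3,
                              contaminant_abundance = 0.12,
                              contaminant_sigma_log10 = 0.5,
                              dropout_scale_log10 = 0.08,
                              intensity_scale = 1e7,
                              seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_purifications, n_core_proteins, n_trace, n_contaminants,
              n_specific_partners)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort_validation("Counts must be non-negative integers.")
  }
  if (n_purifications < 2L) {
    abort_validation("At least 2 purifications are required.")
  }
  if (n_specific_partners > n_purifications) {
    abort_validation("Cannot plant more partners than purifications.")
  }
  cfg$fold_enrichment <- rep_len(fold_enrichment, max(1L, n_specific_partners))
  if (any(cfg$fold_enrichment <= 0) || bait_boost <= 0) {
    abort_validation("Fold enrichments and bait boost must be positive.")
  }
  if (dropout_rate < 0 || dropout_rate > 1 ||
      contaminant_presence < 0 || contaminant_presence > 1) {
    abort_validation("Rates must lie in [0, 1].")
  }
  if (noise_sigma_log10 < 0) abort_validation("Noise sigma must be >= 0.")
  if (trace_min <= 0 || trace_max <= trace_min) {
    abort_validation("Need 0 < trace_min < trace_max.")
  }
  structure(cfg, class = "screen_sim_config")
}

#' Simulate a TAP-MS co-enrichment screen with planted ground truth
#'
#' Generates an intensity panel, annotation, screen design and a truth
#' record from a [screen_sim_config()]. The generator is a pure function of
#' its configuration (including the seed).
#'
#' @param cfg A `screen_sim_config`.
#' @return A list with elements `intensities` (long tibble), `annotation`,
#'   `design` (no outliers), and `truth` (list with a `partners` tibble of
#'   planted pairs and the realized `zero_rate`).
#' @export
simulate_screen <- function(cfg) {
  if (!inherits(cfg, "screen_sim_config")) {
    abort_validation("cfg must be created by screen_sim_config().")
  }
  withr::with_seed(cfg$seed, simulate_screen_impl(cfg))
}

simulate_screen_impl <- function(cfg) {
  n_p <- cfg$n_purifications
  baits <- sprintf("rps%02d", seq_len(n_p))
  purifs <- paste0(baits, "-TAP")
  cores <- if (cfg$n_core_proteins > 0) {
    sprintf("cor%03d", seq_len(cfg$n_core_proteins))
  } else {
    character()
  }
  traces <- if (cfg$n_trace > 0) {
    sprintf("trc%02d", seq_len(cfg$n_trace))
  } else {
    character()
  }
  contams <- if (cfg$n_contaminants > 0) {
    sprintf("ctm%02d", seq_len(cfg$n_contaminants))
  } else {
    character()
  }
  partners <- if (cfg$n_specific_partners > 0) {
    sprintf("chp%02d", seq_len(cfg$n_specific_partners))
  } else {
    character()
  }
  proteins <- c(baits, cores, traces, contams, partners)

  annotation <- build_screen_annotation(baits, cores, traces, contams, partners)
  rp <- annotation$group %in% .rprotein_groups

  # Shared abundance profile: one draw per protein, identical across
  # purifications. Non-ribosomal background proteins are scaled down; the
  # trace tail is log-uniform across the detection limit.
  abundance <- 10^rnorm(length(proteins), 0, cfg$core_sigma_log10)
  abundance[!rp] <- abundance[!rp] * cfg$nonrp_abundance
  trc_idx <- match(traces, proteins)
  abundance[trc_idx] <- 10^runif(length(traces), log10(cfg$trace_min),
                                 log10(cfg$trace_max))
  ctm_idx <- match(contams, proteins)
  abundance[ctm_idx] <- cfg$contaminant_abundance *
    10^rnorm(length(contams), 0, cfg$contaminant_sigma_log10)
  chp_idx <- match(partners, proteins)
  abundance[chp_idx] <- 0

  mean_mat <- matrix(abundance, nrow = length(proteins), ncol = n_p,
                     dimnames = list(proteins, purifs))
  # Bait over-representation in its own purification.
  for (i in seq_len(n_p)) {
    mean_mat[i, i] <- mean_mat[i, i] * cfg$bait_boost
  }
  # Sporadic contaminant presence.
  if (length(contams) > 0) {
    present <- matrix(
      rbinom(length(contams) * n_p, 1L, cfg$contaminant_presence),
      nrow = length(contams)
    )
    mean_mat[ctm_idx, ] <- mean_mat[ctm_idx, , drop = FALSE] * present
  }
  # Planted chaperones: bait-specific, recovered only in the client bait's
  # purification at fold_enrichment times the detection-limit baseline.
  partner_baits <- sample(seq_len(n_p), cfg$n_specific_partners)
  for (k in seq_along(partners)) {
    mean_mat[chp_idx[k], partner_baits[k]] <-
      cfg$partner_baseline * cfg$fold_enrichment[k]
  }

  # Multiplicative log-normal measurement noise on present cells.
  x <- mean_mat
  if (cfg$noise_sigma_log10 > 0) {
    noise <- 10^matrix(rnorm(length(x), 0, cfg$noise_sigma_log10),
                       nrow = nrow(x))
    x <- x * noise
  }
  x[mean_mat == 0] <- 0

  x <- apply_detection_floor(x, cfg$dropout_rate, cfg$dropout_scale_log10)

  intensities <- tibble(
    protein = rep(proteins, times = n_p),
    purification = rep(purifs, each = length(proteins)),
    intensity = as.vector(x * cfg$intensity_scale)
  )
  design <- tibble(purification = purifs, bait = baits, outlier = FALSE)
  truth <- list(
    partners = tibble(
      purification = purifs[partner_baits],
      bait = baits[partner_baits],
      partner = partners,
      fold = cfg$fold_enrichment[seq_along(partners)]
    ),
    zero_rate = mean(x == 0)
  )
  list(intensities = intensities, annotation = annotation, design = design,
       truth = truth)
}

build_screen_annotation <- function(baits, cores, traces, contams, partners) {
  # Deterministic group layout for the shared background: a further block of
  # r-proteins, then assembly factors, translation factors and "other".
  n_core <- length(cores)
  core_groups <- rep("other", n_core)
  if (n_core > 0) {
    cuts <- floor(n_core * c(0.2, 0.51, 0.72, 0.86))
    core_groups[seq_len(cuts[1])] <- "40S r-protein"
    if (cuts[2] > cuts[1]) core_groups[(cuts[1] + 1):cuts[2]] <- "60S r-protein"
    if (cuts[3] > cuts[2]) core_groups[(cuts[2] + 1):cuts[3]] <- "ribosome AF"
    if (cuts[4] > cuts[3]) {
      core_groups[(cuts[3] + 1):cuts[4]] <- "translation factor"
    }
  }
  tibble(
    protein = c(baits, cores, traces, contams, partners),
    group = c(rep("40S r-protein", length(baits)), core_groups,
              rep("other", length(traces)), rep("other", length(contams)),
              rep("other", length(partners))),
    contaminant = c(rep(FALSE, length(baits) + length(cores) + length(traces)),
                    rep(TRUE, length(contams)),
                    rep(FALSE, length(partners)))
  )
}

# Bernoulli dropout with probability decreasing in abundance: a logistic in
# log10 relative intensity whose location is solved (uniroot) so that the
# overall zero fraction, structural absences included, matches the target.
apply_detection_floor <- function(x, target_rate, scale_log10) {
  if (target_rate <= 0) return(x)
  relint <- sweep(x, 2L, colSums(x), "/") * 100
  present <- x > 0
  structural <- mean(!present)
  if (structural >= target_rate) {
    warn(sprintf(
      "Structural zero rate (%.3f) already exceeds the dropout target (%.3f); no dropout applied.",
      structural, target_rate
    ))
    return(x)
  }
  need <- (target_rate - structural) / (1 - structural)
  lr <- log10(relint[present])
  f <- function(theta) mean(plogis((theta - lr) / scale_log10)) - need
  theta <- uniroot(f, lower = min(lr) - 6, upper = max(lr) + 6)$root
  p_drop <- plogis((theta - log10(relint)) / scale_log10)
  drop <- matrix(runif(length(x)) < p_drop, nrow = nrow(x)) & present
  x[drop] <- 0
  x
}

#' Configuration for a synthetic co-translational binding assay
#'
#' Builds and validates the configuration of [simulate_cotrans()]. Defaults
#' emulate a 5 x 5 design (five TAP-tagged chaperones, five client mRNA
#' amplicons, diagonal cognate pairs, technical triplicates): each
#' purification recovers each mRNA at a non-specific background level
#' modulated by per-purification and per-amplicon nuisance factors, and a
#' cognate mRNA is additionally enriched by its planted factor.
#'
#' @param n_purifications,n_amplicons Matrix dimensions; cognate partners
#'   are assigned diagonally, so `n_amplicons >= n_purifications`.
#' @param enrichment Planted cognate enrichment (scalar or one value per
#'   purification; 1 means no specific binding).
#' @param replicates Technical replicates per reaction.
#' @param replicate_cv Coefficient of variation of replicate noise
#'   (log-normal, natural-log sd).
#' @param sigma_row,sigma_col Log10 sd of the per-purification and
#'   per-amplicon nuisance factors.
#' @param noise_sigma_log10 Cell-wise log-normal noise on the TEV/total
#'   relationship (log10 sd).
#' @param total_sigma_log10 Log10 sd of the total-extract N0 levels.
#' @param base_ratio Baseline TEV/total recovery of a non-cognate mRNA.
#' @param n0_scale Scale of N0 values (arbitrary fluorescence units).
#' @param seed Integer seed.
#' @return A validated `cotrans_sim_config` object.
#' @export
cotrans_sim_config <- function(n_purifications = 5,
                               n_amplicons = 5,
                               enrichment = 8,
                               replicates = 3,
                               replicate_cv = 0.05,
                               sigma_row = 0.25,
                               sigma_col = 0.25,
                               noise_sigma_log10 = 0,
                               total_sigma_log10 = 0.3,
                               base_ratio = 0.05,
                               n0_scale = 1000,
                               seed = 1L) {
  cfg <- as.list(environment())
  if (n_purifications < 2L || n_amplicons < n_purifications) {
    abort_validation(
      "Need >= 2 purifications and at least as many amplicons as purifications."
    )
  }
  if (replicates < 1L) abort_validation("At least one replicate is required.")
  cfg$enrichment <- rep_len(enrichment, n_purifications)
  if (any(cfg$enrichment <= 0)) abort_validation("Enrichments must be positive.")
  if (any(c(replicate_cv, sigma_row, sigma_col, noise_sigma_log10,
            total_sigma_log10) < 0)) {
    abort_validation("Noise parameters must be >= 0.")
  }
  if (base_ratio <= 0 || n0_scale <= 0) {
    abort_validation("base_ratio and n0_scale must be positive.")
  }
  structure(cfg, class = "cotrans_sim_config")
}

#' Simulate qRT-PCR N0 records with planted cognate enrichment
#'
#' @param cfg A `cotrans_sim_config`.
#' @return A list with elements `n0` (long tibble of per-replicate N0
#'   values), `partners` (cognate map), and `truth` (planted enrichments
#'   and nuisance factors).
#' @export
simulate_cotrans <- function(cfg) {
  if (!inherits(cfg, "cotrans_sim_config")) {
    abort_validation("cfg must be created by cotrans_sim_config().")
  }
  withr::with_seed(cfg$seed, simulate_cotrans_impl(cfg))
}

simulate_cotrans_impl <- function(cfg) {
  n_p <- cfg$n_purifications
  n_m <- cfg$n_amplicons
  purifs <- sprintf("chap%02d-TAP", seq_len(n_p))
  amps <- sprintf("mrna%02d", seq_len(n_m))
  partners <- tibble(purification = purifs, amplicon = amps[seq_len(n_p)])

  row_f <- 10^rnorm(n_p, 0, cfg$sigma_row)
  col_f <- 10^rnorm(n_m, 0, cfg$sigma_col)
  total_mean <- cfg$n0_scale *
    10^matrix(rnorm(n_p * n_m, 0, cfg$total_sigma_log10), n_p, n_m)
  enr <- matrix(1, n_p, n_m)
  enr[cbind(seq_len(n_p), seq_len(n_p))] <- cfg$enrichment
  tev_mean <- total_mean * cfg$base_ratio * outer(row_f, col_f) * enr
  if (cfg$noise_sigma_log10 > 0) {
    tev_mean <- tev_mean *
      10^matrix(rnorm(n_p * n_m, 0, cfg$noise_sigma_log10), n_p, n_m)
  }

  rep_values <- function(mean_mat, fraction) {
    cells <- tidyr::expand_grid(
      purification = purifs, amplicon = amps,
      replicate = seq_len(cfg$replicates)
    )
    mu <- mean_mat[cbind(match(cells$purification, purifs),
                         match(cells$amplicon, amps))]
    noise <- if (cfg$replicate_cv > 0) {
      exp(rnorm(nrow(cells), 0, cfg$replicate_cv))
    } else {
      1
    }
    mutate(cells, fraction = fraction, n0 = mu * noise)
  }
  n0 <- bind_rows(rep_values(tev_mean, "TEV"),
                  rep_values(total_mean, "total")) |>
    select("purification", "amplicon", "fraction", "replicate", "n0")

  truth <- list(
    enrichment = setNames(cfg$enrichment, purifs),
    row_factors = setNames(row_f, purifs),
    col_factors = setNames(col_f, amps)
  )
  list(n0 = n0, partners = partners, truth = truth)
}
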
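---
title: "Screening affinity purifications for dedicated ribosomal protein chaperones"
author: "chaperscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening affinity purifications for dedicated ribosomal protein chaperones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaperscreen)
library(dplyr)
```

## The scientific problem

Newly synthesized ribosomal proteins (r-proteins) are highly basic,
aggregation-prone, and must travel from the cytoplasm to the nucleolus
before they are assembled into pre-ribosomes. A small number of them are
guarded on this journey by *dedicated chaperones* — proteins that bind one
specific r-protein client (Yar1 for Rps3, Tsr2 for Rps26, Sqt1 for Rpl10,
and so on). Most r-proteins have no known chaperone.

A productive way to look for new ones is a panel of tandem-affinity
purifications (TAP): tag every small-subunit r-protein, pull each one down,
and quantify everything that co-purifies by label-free mass spectrometry.
Almost all of the recovered signal is simply the mature ribosome — every
bait pulls down every other r-protein — so a dedicated chaperone announces
itself as the rare protein that is *specifically* co-enriched with one bait
relative to the whole panel. `chaperscreen` implements the quantitative
core of such a screen, the comparison of split-tag purifications, and the
qRT-PCR analysis used to ask whether a chaperone binds its client while the
client is still being translated.

## The screen model

Let \(I_{ps}\) be the label-free intensity of protein \(p\) in purification
\(s\). The analysis works throughout on **relative intensities**, the
percent of the per-purification total:

\[ r_{ps} = 100 \cdot \frac{I_{ps}}{\sum_{p'} I_{p's}} . \]

This removes the (large, uninteresting) differences in total recovered
material between pull-downs. Undetected proteins are exact zeros; before
log-transformation every 0 is replaced by \(10^{-4}\) percent, so the
log-scale floor is \(-4\). The matrix is *not* renormalized after the
replacement — a purification with \(k\) undetected proteins sums to
\(100 + 10^{-4} k\) — because the replacement is a display convention, not
a redistribution of signal.

For an overview heat map, rows are blocked by a fixed group order (40S
r-proteins, 60S r-proteins, ribosome assembly factors, translation
factors, cell division, histones, transcription, other) and sorted within
each block by descending mean log-signal, ties broken lexicographically so
the order is a deterministic total order.

The screen statistic compares a focal purification \(f\) with the panel:

\[ E_{pf} = \log_{10} \frac{r_{pf}}{\bar r_p}, \qquad
   \bar r_p = \frac{1}{|S|} \sum_{s \in S} r_{ps}, \]

where \(S\) is the set of purifications minus those flagged as outliers in
the screen design (poorly incorporated baits distort the panel mean; when
an outlier purification is itself the focal one, it is re-included in its
own reference so it can still be displayed). On a log-log scatter of
\(r_{pf}\) against \(\bar r_p\), panel-typical proteins fall on the
diagonal of slope 1 and bait-specific partners rise above it; \(E_{pf}\)
is the vertical distance from that diagonal.

Two deliberate choices deserve a note:

* **The focal purification is part of its own reference mean.** The mean
  is a panel-wide summary, and for a panel of \(n\) purifications this
  caps the observable ratio of a panel-wide protein at \(n\): a protein
  found *only* in the focal pull-down has
  \(E \approx \log_{10} n\) (about 1.4 for \(n = 25\)), not infinity. A
  leave-one-out mode (`leave_one_out = TRUE`) is available but off by
  default.
* **The mean is arithmetic on the percent scale**, not on log values: the
  scatter is drawn in percent, and a log-scale mean would be a different
  (geometric) statistic.

Candidates are defined by two thresholds: \(E_{pf} \ge 1\) (10-fold above
the panel mean) and \(r_{pf} \ge 0.01\%\) (actually detected at a
meaningful level). The first formalizes "clearly above the diagonal", the
second suppresses proteins whose apparent enrichment is an artifact of the
zero-replacement floor. Bait proteins are flagged and excluded from
candidate lists; contaminant-flagged proteins (recurring carbohydrate-
metabolism enzymes and the like) are reported but labeled.

## Split-tag purification comparison

A split purification partitions one bait's complexes into a
partner-containing and a partner-free pool (for example, a Nap1 pull-down
split by a Flag tag on Rps6a). Because the bait is strongly
over-stoichiometric in both pools, both are normalized to a
**bait-excluded** 100 percent:

\[ r_{ps} = 100 \cdot \frac{I_{ps}}{\sum_{p' \neq \text{bait}} I_{p's}} . \]

The bait's own value is reported on the same scale (it may exceed 100%)
alongside its raw share of the unexcluded total. Zero replacement and the
log transform are identical to the screen's; the per-protein
\(\Delta = \log_{10} r_{p,\text{enriched}} - \log_{10} r_{p,\text{depleted}}\)
and per-group intensity shares summarize which functional classes follow
the partner.

## Co-translational binding

Whether a chaperone binds its client during translation is read out by
pulling down the chaperone after translation arrest and quantifying client
mRNAs by qRT-PCR. For each purification \(p\) and mRNA amplicon \(m\), the
starting concentrations \(N_0\) of technical replicates are averaged per
fraction and the **ratio of means** is formed:

\[ R_{pm} = \frac{\overline{N_0}^{\text{TEV}}_{pm}}
                  {\overline{N_0}^{\text{total}}_{pm}} . \]

Every purification recovers every mRNA to some extent, and every amplicon
has its own non-specific recovery, so the matrix is corrected two ways.
With the cognate cells (each purification paired with its own client's
mRNA) excluded, row means give the *purification background* \(b_p\) and
column means the *amplicon background* \(c_m\); then

\[ \tilde R_{pm} = \frac{R_{pm}}{b_p \, c_m}, \qquad
   \hat R_{pm} = \frac{\tilde R_{pm}}{\operatorname{mean}\{\tilde R_{p'm'} :
   (p',m') \text{ non-cognate}\}} . \]

The final scaling sets the mean of all corrected background values to
exactly 1 (assertable to \(10^{-9}\)); the cognate cell's normalized value
is the **cognate score**, the fold-enrichment of the client mRNA. The
global background mean is used for the final scaling; a per-purification
variant would also be defensible but is not implemented, because the
row-wise background is already removed by \(b_p\).

Three properties of this correction are worth knowing:

* It is exact for multiplicatively separable backgrounds: on a noise-free
  matrix \(R_{pm} = \rho_p \gamma_m (1 + (e_p - 1)[m = \text{partner}(p)])\)
  with uniform backgrounds, the cognate score recovers \(e_p\) exactly.
* Rescaling the whole matrix changes nothing.
* Rescaling a *single row* (a purification efficiency factor) is **not**
  perfectly absorbed: the exclusion sets of \(b_p\) and \(c_m\) are
  asymmetric, so a row factor leaks into other rows' amplicon backgrounds.
  The scaled row's own cognate *corrected* value is invariant, but other
  cells shift. With realistic nuisance factors (log-normal,
  \(\sigma_{\log_{10}} \approx 0.25\)) the distortion is small; the
  parameter-recovery simulations below quantify it.

Cell-wise exclusion of cognate pairs (rather than excluding whole rows or
columns) matches a design in which each amplicon is cognate to exactly one
purification.

No significance model is attached to cognate scores by default; an
optional permutation test (`cotrans_permutation()`) shuffles the partner
map and reports, per purification, how often a random partner assignment
produces a score at least as large.

## The synthetic data generators

All inputs can be generated with planted ground truth, so every stage of
the pipeline is exercisable end to end without any external data.

`simulate_screen()` emulates the observed structure of a TAP-MS r-protein
panel. Its defaults describe 25 purifications by 200 proteins:

* a shared **core proteome** (the ribosome and its entourage) drawn once
  from a log-normal profile (\(\sigma_{\log_{10}} = 0.5\)) and present in
  every purification, with non-ribosomal members (assembly factors,
  translation factors) scaled to one fifth of r-protein abundance — this
  reproduces the 72–93% r-protein intensity shares seen in efficient
  pull-downs;
* each **bait** boosted 20-fold in its own purification;
* a log-uniform tail of 36 **trace proteins** spanning the two decades
  below the detection limit — real label-free tables have a long tail of
  marginal identifications, and this mass is what the dropout calibration
  acts on;
* 9 sporadic **contaminants**, present in any purification with
  probability 0.5 at moderate abundance, flagged in the annotation;
* one planted **dedicated chaperone**, recovered *only* in its client's
  purification (as observed for real dedicated chaperones, which are not
  pulled down by non-client baits) at `fold_enrichment` times a
  detection-limit baseline; `fold_enrichment = 1` therefore plants a null
  partner that never rises above the detection limit;
* cell-wise multiplicative log-normal noise
  (\(\sigma_{\log_{10}} = 0.3\) by default) and Bernoulli **dropout**
  following a decreasing logistic in log relative intensity (width 0.08
  decades), whose location is solved numerically so that the realized
  overall zero rate — structural absences plus dropout — matches the
  requested 20%.

`simulate_cotrans()` generates N0 plates for a 5x5 chaperone-by-amplicon
design with diagonal cognate pairs, technical triplicates, log-normal
per-purification and per-amplicon nuisance factors, replicate-level noise,
and planted cognate enrichments. With all noise terms at zero the pipeline
recovers a planted enrichment of 8 exactly; with cell-wise noise of
\(\sigma_{\log_{10}} = 0.2\) the median recovered score over hundreds of
replicates stays within 15% of the planted value (a small downward bias is
expected, since the backgrounds average log-normal noise on the linear
scale).

What the generators deliberately do **not** emulate: peptide-level
quantification and protein inference, correlated co-variation of complex
members, batch or run-order effects, and ratio compression from
co-eluting species. Recovery rates measured on these simulations therefore
speak to the arithmetic of the screen, not to every failure mode of real
data.

## Power at the detection boundary

A useful way to read the candidate thresholds is as a detection problem:
the planted chaperone's focal cell carries one log-normal noise draw, and
the candidate rule is a conjunction of monotone thresholds on that draw.
Between a null partner (fold 1) and a planted one (fold \(k\)), every
threshold shifts by exactly \(\log_{10} k\). With
\(\sigma_{\log_{10}} = 0.3\), a 10-fold enrichment therefore sits *at* the
detection boundary: the sum of the miss rate and the false-alarm rate is
bounded below by \(2\Phi(-\tfrac{1}{2 \cdot 0.3}) \approx 9.6\%\),
however the generator or the thresholds' operating point are arranged.
In simulations at the default conditions this package recovers a 10-fold
planted chaperone as the top-ranked candidate in roughly 90–94% of
screens, with null screens candidate-free in roughly 94–97% — about the
best that boundary admits. A 20-fold enrichment (typical of the clearest
real hits) is recovered in ≈99% of screens, and at
\(\sigma_{\log_{10}} = 0.2\) even 10-fold planting is comfortable
(≈97–99% on both sides). Screens for weak enrichments near 10-fold
should expect borderline sensitivity at these thresholds — a property of
the ratio statistic and noise level, not of the implementation.

## Numerical conventions

* Ranks and orderings break ties lexicographically by protein identifier,
  so all outputs are deterministic.
* The drivers (`run_screen()` and friends) format every numeric column to
  9 significant digits, making reruns byte-identical, and write a
  checksummed manifest of all artifacts.
* Zero replacement uses 0.0001 on the percent scale everywhere; applying
  it twice is an error rather than a silent no-op.
* All-zero purifications, bait-excluded totals of zero, non-positive N0
  values, unknown group labels and partner maps that are not one-to-one
  are rejected with named validation errors.

## Problem sizes used in the test suite

The package's checks run the full study geometry where it matters —
200-replicate recovery simulations at 25 purifications by 200 proteins,
500-replicate qPCR parameter recovery — and exhaustive or randomized small
grids (2x2 to 5x5) for the oracle-equivalence checks against brute-force
reimplementations of the definitions. These sizes keep a complete run in
the low minutes on a single core.

## A worked run

```{r example, warning = FALSE}
sim <- simulate_screen(screen_sim_config(fold_enrichment = 20,
                                         noise_sigma_log10 = 0.2,
                                         seed = 42))
scr <- screen_enrichment(sim$intensities, sim$design, sim$annotation)
scr$candidates |>
  select(focal, protein, relint_focal, log10_ratio)
sim$truth$partners
```

The planted chaperone `chp01` is the single candidate, in the purification
of its client `rps19`, at about 25-fold above the panel mean.

```{r cotrans-example}
qs <- simulate_cotrans(cotrans_sim_config(enrichment = c(8, 1, 1, 1, 1),
                                          replicate_cv = 0, sigma_row = 0,
                                          sigma_col = 0, seed = 1))
normalize_cotrans(replicate_ratios(qs$n0, qs$partners))$cognate_scores
```

## Known limitations

* Candidate calling is a ratio heuristic, not an interaction-probability
  model; it has no notion of reproducibility across repeated pull-downs of
  the same bait (the panel here has one purification per bait).
* The two-way qPCR background correction is exact only for separable
  backgrounds; see the row-scaling caveat above.
* Published per-sample r-protein shares can only be recomputed from the
  original study's deposited relative-intensity table, which is not
  redistributable with the package; the corresponding check runs only
  when that table is supplied under `inst/extdata/`.
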
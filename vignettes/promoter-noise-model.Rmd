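---
title: "Promoter microstates, TBP competition and expression noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter microstates, TBP competition and expression noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbpnoise)
library(dplyr)
set.seed(1)
```

## The model

Every RNA polymerase II transcription event in yeast begins with the
TATA-box binding protein (TBP) occupying an accessible TBP-binding site
(TBS). What happens next depends on how TBP arrived. If it arrives as a
subunit of the ~1.2 MDa TFIID co-activator, it is buried inside the
complex, protected from the Mot1p remodeller, and stays bound for a long
time — a steady platform for initiation. If it binds as a monomer (which
requires a high-affinity, bendable TATA-box sequence), two partners
compete for the same surface on TBP: the SAGA co-activator, which
completes a transcription-competent assembly, and the Mot1p ATPase, which
evicts TBP and returns the promoter to its free state. When Mot1p usually
wins, a TATA-box promoter cycles futilely between free and
monomer-bound states, punctuated by rare, large SAGA-driven expression
bursts — a recipe for cell-to-cell variability.

`tbpnoise` formalises this as a discrete-time Markov chain over five
promoter microstates:

| state | assembly               | macrostate |
|-------|------------------------|------------|
| `f`   | free promoter          | Off        |
| `T`   | TBP:TBS (monomer)      | Off        |
| `M`   | TBS:TBP:Mot1p          | Off        |
| `S`   | TBS:TBP:SAGA           | On         |
| `D`   | TBS:TBP:TFIID          | On         |

The transition topology encodes the assembly decision tree: `f -> T`
(monomeric binding, probability `affinity` per step), `f -> D` (direct
holo-TFIID assembly, `tfiid_recruit`), `T -> f` (spontaneous
dissociation, `t_off`), `T -> M` / `T -> S` (partner engagement `engage`
split by `competition`, the probability that Mot1p wins), and `M, S, D ->
f` with per-step exit probability `1/r` for mean residence `r`. All
other transitions are zero. Two structural zeros deserve comment:
`f -> M` and `f -> S` are excluded because both Mot1p and SAGA act on
*DNA-bound monomeric* TBP, and `T -> D` is excluded because TFIID is
delivered as a pre-assembled holo-complex rather than assembling around
monomeric TBP already on the DNA. The second choice was genuinely open;
we fix it at zero because the structural picture (TBP buried inside
TFIID, extensive Taf1p contacts formed co-translationally) makes
completion around pre-bound TBP the least plausible route, and note that
a nonzero `T -> D` edge would only blur, not reverse, the regime
contrasts below.

Residence is geometric: a mean residence time `r` (in steps) maps to a
memoryless per-step exit probability `1/r`. This is the discrete-time
analogue of an exponential dwell time and keeps each complex's kinetics
a single interpretable parameter.

## Simulation and noise

`simulate_population()` runs 500 cells for 150 steps by default, each
cell starting cold in `f`. Expression accrues per step spent in an On
state — `b_S` units in `S`, `b_D` in `D` — with no degradation term; a
per-entry accrual rule is available as a switch (`accrual =
"per_entry"`) because total expression per cell, not the accrual
mechanism, is the modelled observable. The SAGA burst defaults to five
times the TFIID rate (`b_S = 5`, `b_D = 1`): SAGA output is bursty and
large, TFIID output steady; the ratio is a declared choice, its
magnitude being unknown. Noise is the coefficient of variation (CV) of
final per-cell totals, using the sample (n−1) standard deviation. A
population that never expresses has no defined CV and is flagged `NA`
rather than silently dividing by zero.

Randomness follows a per-cell stream contract: the master seed derives
one deterministic stream per cell, so enlarging the population never
reshuffles earlier cells and identical `(params, seed)` pairs are
bit-identical.

The two stock archetypes differ only in the TBP delivery route:
`params_tata_box()` (affinity 0.5, `tfiid_recruit` 0.05) and
`params_tata_like()` (affinity 0.02, `tfiid_recruit` 0.2). Both default
to Mot1p-dominant competition (`competition = 0.9`) with residences
`r_M = 2`, `r_S = 10`, `r_D = 50` — short-lived Mot1p (its ATPase
dissociates the complex quickly), intermediate SAGA, long-lived TFIID.

```{r archetypes}
bind_rows(
  glance(simulate_population(params_tata_box(), seed = 1)),
  glance(simulate_population(params_tata_like(), seed = 2))
)
```

The TATA-box archetype is several-fold noisier despite similar mean
expression, and its TBP turnover (rate of `f -> {T, D}` binding events)
is an order of magnitude higher — the futile Mot1p cycle in action.
`waiting_time_stats()` measures the Off-run lengths between On visits
(censored leading/trailing runs excluded by default), and
`sweep_phase_diagram()` maps the CV of both archetypes over a
competition × SAGA-residence grid. The diagram contains both regimes:
Mot1p-dominant cells where the TATA-box gene is the noisy one, and
SAGA-dominant, long-residence cells where the TATA-box gene is *less*
noisy than its TATA-like counterpart because SAGA occupancy becomes
stable while the TATA-like gene still waits on sparse TFIID arrivals.

`stationary_distribution()` (power iteration on the lazy chain
`(I + P)/2`, which preserves the fixed vector while removing
periodicity) exists as an internal oracle: long-run sampler frequencies
must match it, and `stationary_se()` supplies the correct comparison
scale via the Markov-chain CLT (fundamental-matrix asymptotic variance),
since autocorrelated occupancy makes the naive binomial standard error
an underestimate. With 20 parameter draws × 5 states checked at 3
standard errors, ~0.3 exceedances are expected by chance, so the
automated check demands at least 19 of 20 draws fully inside the band
rather than a literal 20/20.

## Sequence classification

The TBS classifier uses the 8-bp yeast consensus `TATAWAWR` (`W` = A/T,
`R` = A/G): an exact match is a TATA-box, one or two mismatches
TATA-like, three or more "other". Exact matches split by position 5
into the T5 (thymine) and A5 (adenine) subsets, which differ in DNA
bendability and hence monomeric TBP affinity. `scan_promoter()` reports
the minimal-mismatch window per promoter, breaking ties leftmost;
motif-internal positions are 1-based, promoter offsets 0-based. The
classification is sequence-only — a deliberate surrogate for
classifications that also require measured TBP binding, which a
synthetic pipeline cannot supply. Forward-strand scanning is the
default because experimentally anchored site calls fix the orientation;
a reverse-complement scan is a switch.

## Occupancy classes, PBM signal, noise metrics

`classify_coactivator()` implements the median-split convention: a gene
is regulated by a factor (Taf1p for TFIID, Spt20p for SAGA) when its
promoter occupancy is strictly above the across-gene median for that
factor, giving four classes (+/+, +/−, −/+, −/−). Ties sit at "not
regulated" so the rule is deterministic on tied data; genes missing
either factor are excluded, and each factor's median is taken over the
genes where it was measured. `rescale_center()` standardises columns
for display; the median split is invariant to it, which is tested, so
whether the split is computed before or after rescaling is immaterial.

PBM (protein-binding microarray) probes are aggregated per 8-mer by the
median over replicate probes (midpoint convention for even counts;
single-replicate motifs flagged). `class_signal_summary()` compares the
intensity distributions of the TBS classes with Wilcoxon rank-sum tests
under Benjamini–Hochberg correction. One convention matters here: the
`TATAWAWR` consensus has only eight exact instantiations (four T5, four
A5), so a motif-level T5 vs A5 comparison can never reach p < 0.01 (the
two-sided exact floor at 4 vs 4 is 2/70). Class-level significance
claims therefore follow the probe-level convention — the distribution
of all probe intensities for motifs in a class — while motif-level
medians are used for ordering statements. The function accepts either
granularity.

The abundance-independent noise measure DM is the residual of log CV
from a running median over genes ranked by mean abundance. The window
is 50 genes (shrunk symmetrically at the edges; the realised interior
window is 51) and the log base 10 — both configuration with declared
defaults, since the conventional values are not pinned down. The
running median over ranks is scale-free, so DM is invariant to
rescaling all means, and on data following `cv = k/sqrt(mean)` exactly
the residual is identically zero.

Statistical helpers delegate to the standard implementations:
`rank_sum_test()` wraps `stats::wilcox.test` (exact enumeration for
small untied samples, tie-corrected normal approximation otherwise, and
the exact branch is tested against a full permutation enumeration),
`bh_adjust()` wraps `stats::p.adjust`, and `boxplot_summary()` uses
type-7 interpolated quartiles with 1.5 × IQR fences — outliers are
flagged, never removed, because removal is a display convention only.

## Cytometry chain

The flow-cytometry pipeline is order-fixed: `filter_events()` (keep
events strictly inside the 18-bit ADC range (0, 262 143) on both
scatter channels, then drop the top and bottom 5% by total scatter),
`gate_small_cells()` (keep events strictly below the median
FSC-A × SSC-A product — the small, unbudded subpopulation),
`size_correct()` (OLS fit of GFP on FSC-A and SSC-A), then CV per
replicate with the across-replicate mean and standard error. Three
printed conventions required interpretation and are exposed as
configuration: the ADC bound "218−1" is read as 2^18 − 1; the "quintile
cutoff value of 0.5" as the 0.5 quantile (median) of total scatter; and
"the scattering" used for the 5% trim as the FSC-A × SSC-A product
(per-channel trimming is a switch).

The size correction ships in two variants. The default `"squared"` rule
divides the squared raw fluorescence by the fitted value, exactly as
the protocol prints it. It is, however, dimensionally unusual: if raw
fluorescence is size × expression and the fit captures size × mean,
the squared rule returns size · g²/mean(g), whose CV is roughly *twice*
the expression CV (the CV of g² is ~2c* for small c*) and still carries
the size confound. The conventional `"ratio"` rule (raw / fitted)
recovers the expression CV directly, which the recovery checks below
confirm to within a few tenths of a percent at 20,000 events; the
squared rule is retained as the printed default, and quantitative
CV-recovery statements in this package always name the ratio variant.

## The synthetic-data generators

Every generator is a pure function of `(config, seed)` and emits the
planted truth next to the observable, so each downstream classifier has
an exact recovery oracle. They emulate the statistical *structure* of
the real inputs, not their provenance; passing tests show the stages
recover constructions they were pointed at, not that any laboratory
dataset would behave as cleanly. Real ChIP occupancies have spatial
probe structure, PBM chips have sequence-overlap deconvolution issues,
and real cytometry has instrument drift — none of which is emulated.

Defaults, chosen once as plausible for the emulated assays:

* **Class mix** 15/15/30/40% (T5 / A5 / TATA-like / other): roughly the
  ~30% TATA-box share of yeast promoters split evenly between subsets.
* **Promoters** are 200 bp with a GC-rich (70%) background, which keeps
  spurious TATA-like windows rare; a planted motif of the assigned
  class is rejection-resampled until no non-planted window would change
  the scan result (strictly better, leftmost-equal, or class-flipping
  for "other" genes). The consensus overlaps a shifted copy of itself,
  so merely *similar* overlapping windows are expected and allowed;
  occasionally a motif draw is structurally shadowed by its own shifted
  frame, in which case the motif is redrawn within its class.
* **Occupancy** is lognormal (sdlog 0.15) with 2-fold planted shifts.
  SAGA (Spt20p) regulation is planted with class-ordered probabilities
  (0.85/0.70/0.45/0.35) whose mix-weighted mean is ~0.5, and TFIID
  (Taf1p) at 0.5 independent of class — so each median split lands
  between the two lognormal modes and the planted flags are recoverable,
  while Spt20p class medians order T5 > A5 > TATA-like and Taf1p stays
  flat. Mot1p tracks the realised Spt20p and TBP draws.
* **PBM** intensities are lognormal around class means 4000/2500/1200/500
  (T5/A5/TATA-like/other), 16 replicate probes per motif.
* **Noise tables** follow `cv = k/sqrt(mean)` exactly (k = 30, lognormal
  means), modulated by class DM offsets 0.12/0.09/0.03/0 log10 units
  plus residual noise (sd 0.05). The offsets are small enough that the
  offset mixture stays near-symmetric — the cohort mean DM remains
  within 0.02 of zero — while class medians are still separated by ~10
  standard errors at the default 2,000 genes.
* **Turnover** is a scaled Beta confined to 0.008–0.051 a.u. (the span
  of measured promoter turnover), TATA-box mean above TATA-like.
* **Cytometry** draws a lognormal cell size (sdlog 0.25) driving both
  scatter channels (5% channel noise, ADC-clipped) and multiplying a
  lognormal expression signal with CV 0.3; 20,000 events × 2
  replicates. The confound exponent is a dial; at 0 the raw CV already
  equals the expression CV.

## Problem sizes and reproducibility

The automated checks run at the study's native sizes — 500 cells × 150
steps per simulation, 8-point affinity grids × 3 replicate seeds, a
10 × 10 phase diagram × 2 archetypes × 3 replicates, 50,000-step single
trajectories for the ergodicity and stationarity checks, 2,000-gene
cohorts and 20,000-event × 2-replicate cytometry samples × 5 seeds —
sizes at which each check resolves its effect comfortably (the
vectorised sampler simulates the full phase diagram in seconds).
`scripts/acceptance.R` recomputes every headline quantity from scratch
under a caller-supplied seed, and `run_pipeline()` writes a manifest
(config, seed, version) beside its outputs so any bundle can be
regenerated exactly.

## Known limitations

The chain models a single, always-accessible promoter: transcription
factor binding, nucleosome dynamics, mRNA/protein degradation and
extrinsic noise sources are all outside it, so simulated CVs are
driven entirely by initiation-complex switching. Transition
probabilities are archetype-level declarations, not fits to data —
the package deliberately contains no inference machinery. The
sequence-only TBS classifier will disagree with classifications that
require measured TBP binding at composite or shadowed promoters, and
the synthetic generators make no attempt to reproduce assay-specific
artefacts beyond lognormal noise and a size confound.
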
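---
title: "Linking aphid host-race discrimination to leaf metabolomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking aphid host-race discrimination to leaf metabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostdiscrim)
```

## The scientific problem

Host-associated races of the pea aphid (*Acyrthosiphon pisum*) accept and
reject plant species in race-specific ways. Two races are considered here:
MS aphids, adapted to *Medicago sativa*, and TP aphids, adapted to
*Trifolium pratense*. When both races are tested on a panel of *Medicago*
and *Trifolium* species, two distinct per-species quantities emerge:

* **overall acceptability** — how much both races accept a plant, the *sum*
  of the two race-mean acceptance scores, and
* **discrimination** — how differently the races treat it, the *difference*
  of the race means (positive = preferred by MS aphids).

The package links these behavioural scores to untargeted MALDI-TOF leaf
metabolomes to ask which m/z bins (candidate compounds) explain variation
in acceptability, and which explain discrimination. The two questions have
different answers, and keeping them apart is the analytical point.

## The pipeline

### Acceptance from EPG recordings (`epg`, `scores`)

Electrical penetration graphs (EPG) wire an aphid and its test plant into a
circuit; resistance changes reveal stylet activity as interpretable
waveforms. Each 6-hour recording is condensed into ~119 behavioural
variables. Two per-recording summaries are used:

* **E2** — total duration of the E2 waveform (passive phloem-sap
  ingestion) in minutes, the most direct acceptance read-out; and
* **LD1** — the first axis of a Fisher linear discriminant analysis of the
  cleaned variables, fitted per race with plant species as the grouping
  factor, a broad behavioural summary.

Cleaning proceeds in the order imputation → zero filter → correlation
pruning:

1. `impute_missing()` fills missing cells by proximity-based
   random-forest imputation (median start, 3 iterations of 300 trees,
   fixed seed) with the species label as the grouping response.
2. `filter_zero_inflated()` drops variables with ≥ 50% zeros — waveforms
   most aphids never showed carry little comparative information.
3. `prune_correlated()` makes a greedy pass over variable pairs in column
   order and drops the later member of any pair with Pearson |r| > 0.80.
   Which member of a pair to drop is not determined by the science, so the
   rule is fixed for reproducibility and every decision is recorded in the
   cleaning report. The comparison carries a 1e-10 guard so a pair at
   exactly the threshold is kept, honouring the strict inequality.

Two numerical choices in `compute_ld1()` deserve note. The pooled
within-species covariance receives a ridge of `1e-8 * trace/p` on the
diagonal to guard near-singularity. And the discriminant is scaled so the
pooled within-species variance of the scores is 1, then *oriented against
E2*: each race's axis is flipped, if needed, so its scores correlate
non-negatively with E2. Orientation matters because Fisher axes are
sign-arbitrary and the two races are fitted separately; without a common
anchor, summing and differencing the race means can silently mix
acceptability into discrimination and vice versa. With E2 as the anchor,
LD1 reads as an acceptance score for both races. A purely mechanical
convention (largest-magnitude loading positive) is available as
`orient = "loading"` for tables without E2.

`summarize_profiles()` reduces recordings to species × race means with
standard errors, and `discrimination_acceptability()` forms the two scores.
By construction `discrimination + acceptability = 2 * mean_MS` (to the
last floating-point digit), a cheap integrity check on any score table.
For LD1 profiles, `scale_races = TRUE` additionally divides each race's
means and SEs by the standard deviation of its species means before
combining: the per-race axes have arbitrary gains, and summing raw means
would otherwise yield a gain-weighted mixture in which discrimination
leaks into acceptability. E2 profiles share physical units (minutes), so
they are combined unscaled.

### Metabolome matrices (`spectra`)

Peak lists from polar and non-polar leaf-extract fractions (three technical
spotting replicates per plant) are binned into 0.2-Da m/z bins anchored at
the range minimum (50 Da), half-open on the right; each spectrum is then
normalised to percent of total ion count (%TIC), which cancels the
arbitrary per-spot ionisation scale. Technical replicates are combined by
averaging %TIC per bin and renormalising; bins whose replicate coefficient
of variation exceeds 0.5 at non-trivial abundance (> 0.01 %TIC) are flagged
for inspection, never silently removed. Plants stack into a plants × bins
matrix per fraction, with absent bins as zero.

Bins are labelled by their left edge ("166.0") and also carry a nominal
integer bin (`floor(m/z)`, "bin 166"), the convention used when reporting
candidate compounds. `pca_overview()` (column-centred `prcomp`) provides
the variance overview; plants whose PC1–2 score distance has a robust
z-score above 3.5 are flagged as candidate outliers. `plsda()` (NIPALS
PLS2 on centred X and one-hot species indicators) gives the supervised
view with per-bin VIP scores.

### Importance ranking under response uncertainty (`rfrank`)

The core inference regresses the per-plant bin profiles on the behavioural
score of the plant's species with a random forest and ranks bins by
importance — the total decrease in node impurity (residual sum of squares)
attributable to splits on the bin, averaged over trees.

A single forest would ignore that the species scores are estimates with
standard errors. `resampled_ranking()` therefore repeats the fit R times
(default 500; 50 in the scaled test runs), each time drawing every
species' response from Normal(mean, SE²), and aggregates each bin's
*rank* across repeats: the median rank orders bins, the inter-quartile
range measures how stable each bin's importance is under response
uncertainty. `select_top_bins()` takes the k smallest median ranks, with
ties broken by IQR then label so the selection is deterministic.

Two stability companions: `jackknife_ranking()` deletes one random
recording per species × race cell, recomputes point-estimate scores and
refits, n_jack times; a common forest seed across iterations isolates the
effect of the deleted recordings from forest randomness (so a zero-noise
dataset shows zero rank IQR). `resampled_ranking(exclude_plants = ...)`
reruns the ranking without flagged outlier plants.

Downstream, `top_bins_r2()` reports the variance in the species-level
score explained by an OLS fit on the species-mean %TIC of the selected
bins, and `spearman_screen_fdr()` screens bins by Spearman correlation
with Benjamini–Hochberg q-values.

Forests use `ranger` (single-threaded, impurity importance — the
IncNodePurity convention) with the classic regression defaults
`mtry = floor(M/3)` and minimum node size 5; a master seed spawns
per-resample sub-seeds, so every ranking is exactly reproducible.

### Annotation (`annot`)

Top bins are putatively identified by accurate mass: a molecular formula is
parsed (`parse_formula()`), its neutral monoisotopic mass summed from a
bundled table of most-abundant-isotope masses (C, H, N, O, P, S, Na, K),
and the positive-mode [M+H]+ adduct m/z obtained by adding the proton mass
1.00727646 Da. `match_compound_to_bin()` reports both the 0.2-Da bin and
the nominal integer bin; `match_bin_to_compounds()` runs the reverse
query, optionally over [M+2H]+, [M+Na]+ and [M+K]+ adducts. A small
compound table for the phenylalanine–tyrosine pathway ships with the
package; accurate mass alone is *putative* identification — confirmatory
tandem MS is out of scope. `group_log_fold_change()` and
`group_lm_ftest()` compare a bin's (log) %TIC between species groups, with
degrees of freedom always derived from the data at hand.

## The synthetic-data generator

Real deposited data are not required by any test: `generate_dataset()`
manufactures a full study with known ground truth, so every stage is tested
by parameter recovery.

Per species j, an acceptability latent a_j ~ N(0, sigma_a²) and a
discrimination latent d_j ~ N(±delta_genus, sigma_d²) (positive shift for
*Medicago*, negative for *Trifolium*) define race means
m_MS = (a+d)/2 and m_TP = (a−d)/2, so the score algebra recovers the
latents exactly. Each aphid's latent adds a clone effect and individual
noise; its E2 duration is `360 * logistic(s)` minutes, which bounds E2
within the 6-hour recording. Behavioural variables are a mix of
informative (affine in the latent), zero-inflated, pure-noise and
near-duplicate columns, with MCAR missingness.

Spectra plant three compound classes, split between fractions, whose
species structure defines them: discriminative compounds vary with the
discrimination latent (log-abundance `±gamma_disc * d_j`),
acceptability-linked compounds with the acceptability latent
(`gamma_acc * a_j`), and nuisance compounds vary among species for reasons
unrelated to behaviour — a random species effect with per-compound SD
drawn uniformly between 0.25 and 2.5 times `sigma_species = 0.4`,
heterogeneous as in real metabolomes but bounded, because an unbounded
spread occasionally lets one compound carry essentially all of a species'
ion count, and the %TIC closure then drowns every other bin. The nuisance
variation matters: without it the planted compounds would be the only
species-structured predictors, and the known variance bias of
impurity-based forest importance would inflate their ranks even for
responses they have nothing to do with — the null model would be
degenerate and the discrimination/acceptability contrast untestable.
Biological (CV 0.3) and technical (CV 0.1) lognormal noise, a random
per-replicate total-ion-count scale (removed by %TIC), and Gaussian m/z
jitter (SD 0.03 Da) complete the picture. Planted m/z values keep at least
two jitter SDs away from bin edges by default; `edge_stress = TRUE` places
them on edges to probe bin-splitting. Fecundity is Poisson with log-rate
affine in the race mean.

Defaults mirror the study design: 19 species (9 *Medicago*), 2 clones per
race, 8 recordings per species × race cell, 119 behavioural variables,
6 plants per species, triplicate spectra, 50–1000 Da. Within-cell variance
components are not reported quantities, so the noise SDs (clone 0.2,
aphid 0.8) are plausible placeholders, not estimates: recovery tests show
what the *procedure* does under its assumptions, not what any real dataset
contains. The generator draws no real spectra artefacts (isotope patterns,
multiply charged ions, ion suppression, baseline), so passing tests say
nothing about peak picking or instrument effects.

## Problem sizes used in the tests

The packaged checks run the full procedure at a reduced scale chosen so
the whole suite completes comfortably on one CPU: recovery experiments use
~200 nuisance compounds (about 200 occupied bins per fraction), R = 50
response draws and 200-tree forests over 10 generator seeds; jack-knife
consistency uses 50 jack-knife datasets against 50 resamples. Production
analyses would use the defaults (R = 500, 1000 trees), which change
nothing structurally.

## Design choices that were genuinely open

* **Drop rule for correlated pairs** — the later column in order; recorded
  per pair in the report.
* **Pearson, not Spearman, for pruning**; Spearman P-values use the exact
  permutation distribution for n ≤ 10 (ties permitting) and the t
  approximation otherwise.
* **Replicate combination** — mean %TIC then renormalise, with a CV-based
  concordance flag; deliberately simple and inspectable.
* **Outlier rule** — robust z > 3.5 of the PC1–2 score distance; flags
  inform the `exclude_plants` rerun, nothing is auto-removed.
* **Response rows** — every plant inherits its species' drawn score, so
  the forest sees plants as replicates of the species-level response; a
  species-mean alternative would discard within-species metabolome
  variation.
* **Jack-knife cells** — one recording removed per species × race cell;
  species × race × clone is available via `cell = "clone"`.
* **Adducts** — [M+H]+ only by default (positive-mode MALDI with an
  α-CHCA matrix); other adducts opt-in.
* **log fold change** — base 2, configurable; a 1e-6 %TIC pseudo-count is
  added (and reported) when a group mean is zero.

## Known limitations

Impurity-based importance is biased toward high-variance, strongly
partitioned predictors; median-rank aggregation under response resampling
tempers but does not remove this, which is why the synthetic null carries
realistic species-level variance heterogeneity. LD1 orientation relies on
E2 being a meaningful acceptance anchor; for datasets where it is not, the
mechanical loading convention should be used and cross-race comparability
assessed by the user. Accurate-mass annotation cannot distinguish isomers
and is reported as putative only.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  out_dir = "hostdiscrim_demo",
  synthetic = synthetic_config(),
  rf = rf_run_config(n_trees = 200, n_resamples = 50),
  seed = 1)
report <- run_pipeline(cfg)
report$stages$rank$r2
```

The output directory then holds the score tables, the per-fraction
plants × bins matrices, the rank table with median ranks and IQRs, the
selected top bins, their annotations, and a JSON run report with seeds and
per-stage dimensions.
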
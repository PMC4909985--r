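---
title: "Detecting mosaic X-chromosome alterations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mosaic X-chromosome alterations: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicX)
```

## The measurement model

A mosaic structural event present in a fraction $f$ of sampled cells
changes two SNP-array summaries. At a heterozygous probe the B-allele
frequency (BAF) band splits from 0.5 to $0.5 \pm \Delta b$, with

$$\Delta b_{\mathrm{CNLOH}} = \tfrac{f}{2}, \qquad
  \Delta b_{\mathrm{loss}} = \frac{f/2}{2-f}, \qquad
  \Delta b_{\mathrm{gain}} = \frac{f/2}{2+f},$$

obtained by counting alleles in the cell mixture (e.g. a loss retaining
the B homolog gives band $\frac{(1-f)+f}{2(1-f)+f} = \frac{1}{2-f}$).
Inverting these gives the fraction estimators used by
`estimate_mosaic_fraction()`; they are verified in the test suite against
a brute-force allele-count oracle, and `delta_b_for_fraction()` exposes
the forward direction for the generator. The gain inversion
$f = 4\Delta b/(1-2\Delta b)$ reaches $f=1$ at the pure-trisomic limit
$\Delta b = 1/6$; larger deviations are capped at 1 with a warning.

The log R ratio (LRR) responds with $\log_2\frac{2-f}{2}$ (loss),
$\log_2\frac{2+f}{2}$ (gain) and 0 (copy-neutral). Array compression of
this ideal response exists on real platforms; the generator exposes a
`lrr_compression` multiplier (default 1, the uncompressed ideal) rather
than modelling a platform-specific value.

## Pipeline stages and their parameters

### Informative probes and mirroring

Only heterozygous probes carry band-split information.
`select_informative()` uses genotype calls (`AB`) when any calls exist,
else a BAF window $(0.10, 0.90)$. The window retains displaced het bands
up to $\Delta b \approx 0.33$ — high-fraction events — while excluding the
homozygote tails. Whether the original scan used calls or a window is not
derivable from its description; both are supported and calls are the
default. Pseudoautosomal (PAR) probes are always excluded: PARs are
diploid in both sexes, behave autosomally, and would dilute X dosage
statistics. Mirrored BAF, $\mathrm{mBAF} = \max(b, 1-b)$, folds the
symmetric split to one side so segmentation sees a single shifted mean.

Note one consequence of mirroring used throughout: for noise
$\sigma_{\mathrm{BAF}}$, a *null* het band has
$E[\mathrm{mBAF}] - 0.5 = \sigma_{\mathrm{BAF}}\sqrt{2/\pi} \approx 0.024$
at the default $\sigma_{\mathrm{BAF}} = 0.03$. The segment deviation
`delta_b = mean(mBAF) - 0.5` therefore carries a folding bias; the
candidate filter threshold (0.03) is calibrated against this folded scale,
while event typing uses the mixture estimate
$\hat{\Delta b} = (\mu_3-\mu_2)/2$, which is unbiased.

### Segmentation

`cbs_segment()` implements circular binary segmentation: the arc $(i,j)$
of the circularized current stretch maximizing the two-sample
$t$-statistic against its complement is a candidate change point, accepted
when its permutation $p$-value beats `alpha`, recursing into the pieces.
Defaults: `alpha = 0.01`, `n_perm = 1000`, `min_markers = 50`,
`merge_tol = 0.005` mBAF — common practice for this algorithm family; the
original analysis reports no settings. Permutations use a caller-supplied
seed; the permutation loop stops early once the exceedance count proves
$p \ge$ `alpha`, which makes null regions cheap without changing any
decision. `n_perm < 100` is rejected (p-resolution too coarse); series
shorter than `min_markers` return a single segment with a warning. An
all-constant series has zero pooled variance and is returned unsplit.
The compiled kernel's argmax is tested against exhaustive $R$-level
enumeration on short series; an arc and its complement describe the same
split and either representation is accepted.

Candidate filters: events must span `min_size_bp` = 2 Mb (the published
false-positive control) and `min_delta_b` = 0.03. With $f = 2\Delta b$ for
copy-neutral events the deviation floor corresponds to a ~6% detection
floor, consistent with the smallest validated mosaic proportion. Segment
base-pair bounds are the positions of the first/last informative probe in
the segment — conservative probe-support semantics, not midpoints.

### Band typing by Gaussian mixtures

For each candidate, `fit_baf_mixture()` fits univariate Gaussian mixtures
with $k = 2, 3, 4$ components to *all* probes in the segment (homozygotes
included) and selects by BIC ($-2\ell + (3k-1)\log n$), resolving ties
($\Delta\mathrm{BIC} < 2$) toward smaller $k$. Fixed initializations
anchor the fits — hom bands at 0.05/0.95, an undisplaced het band at 0.5
for $k=3$, a split band at $0.5 \mp \Delta$ for $k=4$ (with $\Delta$ the
segment deviation) — but all parameters are free afterwards; freezing the
hom means would misfit the much tighter hom bands real arrays produce.
Component SDs are floored at 0.005 to prevent degenerate spikes and are
*initialized* at 0.02: wider initial SDs let the two narrowly split
central components share responsibilities and collapse into the unsplit
$k=3$ basin, a pure local-optimum artifact.

Decision rules in `call_events()`: $k=4$ is a mosaic split and supplies
$\hat{\Delta b}$; $k=3$ (no split) is rejected as a genotyping artifact
even when the LRR is shifted — mixed evidence of that kind is logged, not
called; $k=2$ (no het band, complete LOH) is called only with a
corroborating LRR shift beyond the applicable threshold and reported at
the detection-ceiling fraction 0.88, the largest validated mosaic
proportion — without LRR support it is rejected.

### Copy state, location, constitutional screening

Copy state comes from the mean batch-adjusted LRR with strict thresholds:
$\pm 0.01$ for whole-chromosome events (thousands of probes average the
noise down) and a conservative $\pm 0.05$ for partial events; boundary
values are copy-neutral. The batch baseline is the median over female
controls of per-sample median X LRR — the median-of-medians is robust to
mosaic carriers among the controls — and requires ≥ 20 controls
(configurable).

Locations are assigned in a fixed precedence: `whole` (both bounds within
`end_tol_bp` = 1 Mb of the first/last assayed probe), `telomeric p` /
`telomeric q` (exactly one terminal bound), `spans centromere` (strictly
contains the centromere), else `interstitial`; the order makes the
categories mutually exclusive and exhaustive, which a 10^4-interval
property test asserts. Whole-chromosome loss/gain calls at fraction
≥ 0.95 are flagged XO / trisomy X — constitutional, not mosaic — and are
excluded from mosaic tallies while remaining in the output with their
flag. Copy-neutral events are never constitutional aneuploidies.

### Methylation phasing

Female X promoters carry one methylated (Xi) and one unmethylated (Xa)
copy; males carry Xa only. Control probes passing the
differential-methylation box — women mean β in $[0.35, 0.5]$, SD < 0.09;
men mean < 0.15, SD < 0.05; means inclusive, SDs strict — are Xi-marked
probes whose β responds to which homolog an event hits. With methylated
copy fraction $m$ (loss of Xi: $\frac{1-f}{2-f}$; loss of Xa:
$\frac{1}{2-f}$; gain of Xi: $\frac{1+f}{2+f}$; gain of Xa:
$\frac{1}{2+f}$; CNLOH, Xi replacing Xa: $\frac{1+f}{2}$; Xa replacing
Xi: $\frac{1-f}{2}$), the expected carrier β is $m \cdot \beta_0/0.5$,
anchored so $f=0$ returns the female control mean $\beta_0$. The model
assumes the duplicated homolog retains its methylation state — without
that assumption copy-neutral events would carry no signal.

`phase_event()` averages carrier z-scores against female-control
statistics (male statistics enter only the probe filter) over
passed-filter probes inside the event, requires ≥ 5 promoter regions, and
calls the homolog from the sign of the mean z given the copy state. A
call threshold $|\bar z| \ge 0.5$ guards against noise-dominated
direction calls; the original analysis reports direction by sign only, so
this threshold is a package choice (configurable). The Xi-preference test
pools losses and gains (copy-neutral events change both homologs and are
excluded) into a two-sided exact binomial test at $p_0 = 0.5$ by
tail-doubling capped at 1 — the construction that reproduces the printed
p-value from the printed counts. No outlier-removal rule is applied to
discordant phasings, since none is described.

### qPCR validation

Ct is linear in $\log_{10}$(template); `fit_standard_curve()` fits that
line (≥ 4 dilution points), with efficiency $10^{-1/\mathrm{slope}} - 1$
and a non-negative slope rejected as an invalid curve. Per target assay
the median triplicate Ct (median: robust to single-well dropout; a
triplicate range > 1 Ct warns) interpolates to a concentration; the
target:reference ratio is doubled — RNase P being autosomal and diploid —
and the 12 assay ratios are averaged. Calling is control-anchored: gains
above mean + 3 SD, losses below mean − 3 SD of normal-control ratios.
Array copy-neutral maps to qPCR `normal` in concordance scoring, and
discordant pairs are reported, not suppressed.

## The synthetic world

The generator's defaults encode the study conditions it stands in for:

* BAF noise SD 0.03 and LRR noise SD 0.15 (typical of the array family;
  the source is silent), het rate 0.30, hom bands at 0.01/0.99 clipped to
  $[0,1]$;
* 2,000 X probes uniform over non-PAR territory of the 154.9 Mb hg18 X
  (centromere 58.5–61.7 Mb, PAR1/PAR2 at the tips) — the sparse end of
  the array family, chosen once as a realism/runtime balance;
* carrier status Bernoulli on $\mathrm{logit}^{-1}(-8.58 + \ln(1.04)\,
  \mathrm{age})$, giving ~0.11% prevalence at age 45 and ~0.45% at 78
  with an odds ratio of 1.04 per year; ages Normal(62, 10) truncated to
  [30, 95] (adult cancer-GWAS age structure; a package choice);
* state mix 59:43:22 (loss : copy-neutral : gain), the published location
  mix, mosaic fractions Beta(1.6, 3.5) scaled to [0.06, 0.88] (mean
  ≈ 0.30, matching the reported mean X mosaic proportion), 15% of
  carriers with more than one event;
* four genotyping batches with male fractions 0–0.75 and LRR baselines
  following an attenuated mixed-sex clustering offset
  $0.3 \log_2\frac{2}{2-\mathrm{mf}}$;
* methylation: 212 promoter regions, ~9 probes each; in-box probe means
  drawn with margins (women mean 0.38–0.47, SD 0.04–0.07; men mean
  0.02–0.12, SD 0.02–0.04) wide enough that the *sample-statistic* filter
  recovers the in-box set exactly at the control sizes used (136 women,
  1,665 men); 30% decoys violate one box constraint far outside it, with
  the noisy-male-band decoy's mean raised so $[0,1]$ clipping cannot pull
  its sample SD back inside the box;
* qPCR: the RNase P reference is duplexed into every target well (one
  reference triplicate per target assay) and both internal standard
  curves (male/female pools) are simulated per plate, six 10-fold
  dilutions in triplicate each; per-sample DNA input varies 0.5–2×, which
  the standard curves must cancel (scale-freeness is tested).

Determinism: a mandatory master seed spawns per-sample child seeds through
a fixed arithmetic scheme; identical configurations give byte-identical
outputs, including through the command-line pipeline.

What the generator does **not** emulate: linkage disequilibrium and
population structure in genotypes, platform-specific LRR compression and
GC waves, probe-density heterogeneity, methylation array batch effects,
and raw two-channel intensities. A green synthetic test therefore
establishes correctness of the inference given the stated measurement
model, not robustness to artifacts the model omits.

## Numerical and interface choices

* Intervals are held 1-based inclusive in memory (the native R/IRanges
  convention, and what the input formats use); only the BED-like calls
  output converts to 0-based half-open, stated in its header.
* The Wilson interval uses the normal quantile at $(1+\mathrm{conf})/2$,
  never a hard-coded 1.96. The exact binomial test sums the pmf directly.
* Odds-ratio confidence intervals are Woolf (log-scale); zero cells error
  unless the Haldane–Anscombe 0.5 correction is explicitly enabled.
* Logistic regression is iteratively reweighted least squares, converging
  on max $|\mathrm{score}| < 10^{-8}$ (cap 50 iterations); complete
  separation (a coefficient diverging past 15) and rank deficiency are
  explicit errors naming the problem.
* The length-adjusted event rate is defined here as
  $n_{\mathrm{events}} / (n_{\mathrm{individuals}} \times
  \mathrm{territory_{Mb}} / 10^4)$. For the published X inputs (124
  events, 38,303 women, 154.9 Mb) this yields 0.209 events per 10,000 Mb
  and does **not** reproduce the published 1.07 — the published
  adjustment is not reconstructible from printed quantities, so this
  package documents its own definition rather than guessing.
* A per-sample failure inside a cohort run is logged and recorded; it
  never aborts the run. Outputs are written to a temporary file and
  renamed (atomic), each carrying a provenance header (package version,
  config hash, seed).

## Known limitations

* Partial-chromosome events near the detection floor are mixture-power
  limited: a 10 Mb interstitial CNLOH at $f = 0.10$ spans only ~40 het
  probes at the default density, where the BIC penalty for the split-band
  model is of the same order as its expected likelihood gain, so such
  events are detected in only a minority of replicates. The detection
  floor property is therefore assessed on whole-chromosome events, the
  class dominating the validated proportion range; short low-fraction
  events should be interpreted with this in mind. (The original study
  likewise reports weakest validation for partial-chromosome events.)
* Candidates spanning fewer than 50 probes are rejected at the mixture
  stage by construction, so events between 2 Mb and roughly twice the
  probe spacing × 50 require denser maps than the synthetic default.
* Male X mosaicism, autosome-tuned calling, raw-intensity normalization
  and multiple-testing control across outcomes are out of scope.
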
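---
title: "Reference-gene stability analysis for RT-qPCR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability analysis for RT-qPCR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

# Scope and model

`refstab` addresses a single, well-bounded statistical task: given
replicate-level cycle-threshold (CT) measurements of a panel of candidate
reference genes (plus target genes) across samples falling into two groups,
decide which candidates are stably expressed, how many are needed for
normalization, and quantify target-gene fold changes against the chosen
panel with amplification-efficiency correction.

The working model of a CT value is additive on the cycle scale:

$$CT_{sgr} = \mu_g + \delta_{g,\mathrm{group}(s)} + \ell_s +
\varepsilon_{sg} + \eta_{sgr}$$

with per-gene baseline $\mu_g$, group effect $\delta$, a *loading factor*
$\ell_s$ shared by all genes of a sample (differences in cDNA input and RT
yield — exactly the nuisance that reference-gene normalization removes),
per-gene stability noise $\varepsilon_{sg}$ (the quantity the stability
algorithms rank), and technical replicate noise $\eta_{sgr}$. Because CT is
a log2-scale readout (one cycle = one doubling at efficiency 1), Gaussian
noise on the cycle scale corresponds to log-normal noise on the abundance
scale, the standard qPCR error model.

# Replicate quality control

Technical replicates of one reaction are averaged outright when their
sample SD is below 0.2 cycles. Otherwise one replicate — the one with the
largest absolute deviation from the median — is removed and the remaining
set (at least 3 values) re-tested against the same threshold; if it still
fails, the measurement is flagged invalid rather than repaired further.
Two details are deliberate:

- the outlier is defined by distance from the *median*, which is robust to
  the outlier itself; distance ties remove the later replicate index so the
  rule is deterministic;
- only a *single* removal pass is attempted. Repeated trimming would let
  badly dispersed reactions masquerade as clean ones; a reaction that needs
  more than one exclusion is simply not trustworthy.

The comparison is strict (`SD < 0.2`), so a set sitting exactly on the
threshold goes to the removal pass.

# Amplification efficiency

Efficiency $E$ (fraction of templates copied per cycle; $E = 1$ is perfect
doubling) is estimated from a dilution-series standard curve by OLS of CT
on $\log_{10}$(input amount):

$$E = 10^{-1/\mathrm{slope}} - 1 .$$

The regressor is the actual input amount (pg), not the dilution index, so
the estimate is invariant to rescaling all amounts by a common factor. $R^2$
is the squared Pearson correlation of CT with log-amount. Curves need at
least three distinct amounts; a non-negative slope is an error (the assay is
not a standard curve at all), while efficiencies outside (0.8, 1.1) only
warn — real assays accepted in practice sit around 95–102%.

# The four stability algorithms

All four are computed by `ref_stability()`; they look at different aspects
of the data and their disagreements are informative, which is why the final
call is an aggregate.

## geNorm

CTs are first transformed to linear relative quantities anchored at each
gene's lowest CT, $Q_{sg} = (1+E_g)^{CT^{\min}_g - CT_{sg}}$, so the most
abundant sample of each gene has $Q = 1$. By default $E = 1$ for the
stability stage (the transform is then $2^{-\Delta CT}$); per-gene
efficiencies are opt-in (`use_efficiency = TRUE`), since anchoring is a
monotone per-gene rescaling and efficiency hardly moves the rankings.

For a gene pair $(j,k)$ the pairwise variation is the sample SD over
samples of $\log_2(Q_{sj}/Q_{sk})$; gene $j$'s stability value $M_j$ is its
mean over all partners. Ratios cancel the loading factor, so $M$ is
loading-invariant by construction. $M < 1$ is the usual acceptability
cut-off, $M < 0.5$ typical of good references. The full ranking removes the
highest-M gene and recomputes until two remain; those two are tied at
averaged rank 1.5 because the procedure cannot order them. M ties during
exclusion remove the later gene in column order (deterministic, and only
reachable in degenerate identical-profile inputs).

The optimal panel size uses normalization factors $NF_n$ (per-sample
geometric mean of the $n$ top-ranked genes): $V_{n/n+1} =
\mathrm{SD}_s[\log_2(NF_n/NF_{n+1})]$ for $n = 2..k-1$, and the
recommendation is the smallest $n$ with $V < 0.15$ (or $k$ if none) —
below that threshold an extra gene no longer changes the normalization
materially.

Log base 2 is used throughout; the choice only scales all $M$ and $V$
jointly, and base 2 is the qPCR convention (one cycle = one log2 unit).

## NormFinder-style estimator

The model-based method separates *within-group* noise from *between-group*
bias — a gene can be quiet within each group yet systematically shifted
between groups, which ratio methods under-penalise. Working on
log2-expression $x = -CT$, each sample is centred across genes
($z_{sg} = x_{sg} - \bar x_{s\cdot}$), removing the loading factor. The
centring biases naive per-gene variances, mixing every gene's noise into
every column: if $v_{ig}$ is the within-group sample variance of centred
values, its expectation is $\sigma^2_i (1 - 2/k) + \bar{\sigma}^2 / k$.
Solving gives the unbiased estimator used here ($k$ = number of genes):

$$\hat\sigma^2_{ig} = \frac{k}{k-2}\Big(v_{ig} - \frac{\bar v_{\cdot
g}}{k-1}\Big), \qquad \text{truncated at } 0 ,$$

which is why at least three genes are required. The intergroup difference
$d_{ig}$ (deviation of the gene's group mean of centred values from its
across-group mean) is shrunk towards zero by
$\hat\gamma^2 / (\hat\gamma^2 + \widehat{\mathrm{var}}(d_{ig}))$, with
$\hat\gamma^2$ a method-of-moments estimate of the variance of true group
differences across genes (truncated at zero): with few samples an observed
group difference is partly sampling noise, and shrinkage prevents ranking a
gene down for noise alone. The stability value combines both error sources,
averaged over groups:

$$\rho_i = \mathrm{mean}_g\Big(|\tilde d_{ig}| +
\sqrt{\hat\sigma^2_{ig}/n_g}\Big) .$$

Smaller is more stable; an all-constant matrix gives exactly 0. Without
group labels the value reduces to the bias-corrected SD of centred values.
The estimator is verified by simulation in the test suite: a 1-cycle group
shift injected into one of eight otherwise-equal genes receives the largest
stability value in ≥ 96% of seeds, and an all-constant panel scores exactly
zero under both the grouped and ungrouped variants.

## BestKeeper

BestKeeper stays on the raw CT scale deliberately: per gene it reports the
$n-1$ sample SD, CV% (SD over arithmetic mean CT), geometric/arithmetic
mean and range, and the Pearson $r$ of the gene against the *BestKeeper
index*, the per-sample geometric mean CT of all candidates. SD below 1
cycle and $r$ near 1 indicate a usable reference. Because it never forms
ratios, BestKeeper is the one method *not* invariant to the loading factor
— with noticeable loading variation all its SDs inflate together. That is a
property, not a defect: it measures total CT dispersion, which is what a
bench scientist sees. Ranking is by ascending SD; $r$ is reported for
inspection only, and a constant gene (SD 0) has undefined $r$ (`NA`) but
still ranks first by SD.

## Comparative ΔCT

For every gene pair the per-sample CT difference is formed and its SD over
samples computed; a gene's score is the mean SD over its pairs. Under
$E = 1$ this is algebraically identical to geNorm's $M$ (the log2 quantity
ratio *is* the CT difference up to sign) — the test suite asserts the
identity to 1e-10 — but it requires no transformation and is kept as an
independent method because the aggregate convention includes it.

## Aggregation

Each method yields a rank vector (averaged ranks on ties). The
comprehensive score is the geometric mean of the four ranks; final order is
ascending score with ties broken by geNorm rank and then gene symbol, so
output order is deterministic. The geometric mean is the conventional
choice for combining ranks across heterogeneous scales: it penalises a
single very bad rank more than an arithmetic mean would, while ignoring the
methods' incomparable units.

# Validation: efficiency-corrected multi-reference ΔΔCT

With references chosen, a target's relative expression per sample is

$$FV_s = \frac{(1+E_T)^{\Delta CT_s(T)}}
{\mathrm{geomean}_{R}\big[(1+E_R)^{\Delta CT_s(R)}\big]},
\qquad \Delta CT_s = \overline{CT}_{\mathrm{calibrator}} - CT_s ,$$

i.e. calibration against the *per-gene mean CT of the calibrator group*
(not a single sample — a single calibrator sample would inject its own
noise into every value), and normalization against the geometric mean of
the reference factors. Values are rescaled so the calibrator-group mean is
exactly 1; the reported fold change is the other group's mean, with SEM on
the linear scale for plotting parity with the usual bar-chart presentation.

The group comparison is a two-sided unpaired Student's t-test (pooled
variance) on log2 quantities: fold data are approximately log-normal, and
the log-scale test is invariant to the rescaling step (a multiplicative
constant is an additive constant in logs), so normalization cannot change
the p-value. `compare_groups(..., log = FALSE)` switches to the raw scale
if wanted. With exactly two groups, a Dunnett-type many-to-one comparison
degenerates to this same t-test up to the multiplicity step, so no separate
machinery is provided; p-values across several targets are reported
unadjusted.

# The simulator

`simulate_ct_dataset()` draws from exactly the additive model above, in a
fixed documented order (loading, gene noise, replicate noise,
contamination, metadata) from a single seeded generator, so a seed fully
determines the dataset and partial regeneration is impossible by
construction. The default configuration emulates a two-group reference-gene
study in red deer antler blood:

- 8 candidates (B2M, ACTB, RPLP0, SDHA, PGK1, GUSB, G6PD, GAPDH) with
  baselines spanning 18–31.5 cycles — B2M most abundant, G6PD least, SDHA
  intermediate — and noise SDs 0.08–0.60 cycles ordered so the true
  stability ranking runs B2M > ACTB > RPLP0 > … > GAPDH;
- 3 targets (ANXA2, APOD, TPM1) at baseline 22–26 cycles with adult-group
  CT drops of 1.35, 1.25 and 0.30 cycles (true folds ≈ 2.55, 2.38 and
  1.23 — two clear effects and one mild one);
- 5 young + 10 adult samples, quadruplicate replicates with SD 0.05
  cycles, loading SD 0.5 cycles, per-gene assay efficiencies in the
  95–102% band;
- metadata (ages, RIN ≥ 9, absorbance ratios 2.0–2.2) drawn within the
  QC-passing ranges.

Options add heavy-tailed replicate contamination (for exercising the QC
rule) and non-detect truncation above 40 cycles (off by default).

What the simulator does *not* emulate: PCR inhibition and efficiency drift
across samples, between-plate batch effects, correlated biological
co-regulation among candidates, and non-Gaussian biological variation.
Passing tests therefore demonstrate that the algorithms recover the truth
*under the model they assume*; on real data the aggregate ranking inherits
whatever violations of that model the experiment carries, which is exactly
why four methods with different sensitivities are aggregated rather than
trusting one.

# Numerical and design choices

- Sample SDs use the $n-1$ denominator everywhere.
- Relative quantities are anchored at the per-gene minimum CT, making the
  anchor sample's quantity exactly 1 and all quantities ≤ 1 within genes.
- Full-panel M values *and* the iterative exclusion trace are both
  reported, since conventions differ on which to quote.
- `aggregate_replicates` needs ≥ 2 replicates; wide-format input is treated
  as already aggregated and the SD rule is not re-applied to it.
- Degenerate inputs: constant genes give M = 0, NormFinder 0, BestKeeper
  SD 0 with `NA` correlation; identical-profile panels rank by the
  documented tie-breaks; zero variance in *both* groups makes the t-test an
  error rather than a silent `NaN`.
- The pipeline selects `max(min_references, recommended_n)` references,
  default minimum 3: panels commonly keep three stable genes even when
  $V$ says two suffice, trading a pipette step for robustness against any
  one gene misbehaving in a future experiment. Set `min_references = 2` to
  follow the V recommendation strictly.
- Thresholds (replicate SD 0.2, RIN 9.0, purity 2.0–2.2, M cut-off 1.0, V
  cut-off 0.15, α 0.05) are configurable, and the pipeline report always
  records the values actually applied.

## Simulation sizes used in verification

The test suite and the acceptance script size their simulations for
desk-scale runs while keeping estimates stable: 100 seeds for the
rank-recovery experiment (8 genes × 15 samples each), 2000 replicates for
the type-I-error check of the validation test (4 genes × 15 samples,
single-replicate), 50 for effect recovery, and 25 replicate studies for the
study-design bounds. In the rank-recovery experiment the candidate noise
SDs span 0.05–1.0 cycles on a *geometric* ladder: noise scales are
naturally log-spaced, and with 15 samples the sampling error of a variance
estimate (≈ 38% of the variance) means only a multiplicative gap before the
noisiest gene makes its bottom rank reliably identifiable.

# Known limitations

- The NormFinder-style estimator follows the published model's structure
  but is this package's own derivation (documented above); numerical output
  is not guaranteed to match any particular third-party implementation,
  and no exact-output compatibility with the RefFinder web service is
  attempted — its internal conventions are unpublished. The geomean-of-ranks
  rule is implemented as stated.
- Stability values come without confidence intervals; the simulation
  machinery is the supported way to judge their reliability at a given
  design size.
- Only two-group designs are supported in the validation stage; multi-group
  designs would need the multiplicity machinery deliberately left out.
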
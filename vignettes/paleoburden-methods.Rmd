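---
title: "Methods: burden trajectories, randomization nulls and the ABC selection-trend estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burden trajectories, randomization nulls and the ABC selection-trend estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`paleoburden` asks a population-genetic question about a polygenic trait:
have the alleles that today increase the trait's risk been drifting,
rising, or declining in frequency over the tens of millennia covered by
ancient human genomes? The package implements the whole chain of analyses
needed to answer it — burden computation, bespoke randomization nulls,
ancestral-state enrichment, a simulation-based estimator of the selection
trend, recent-adaptation testing with singleton density scores, and
archaic-introgression enrichment — together with a synthetic-data
generator that emulates every input, so the full pipeline is testable
without any restricted dataset.

## The burden statistic

For individual $i$ with genotype calls at $J_i$ trait-associated SNPs
(association $p < 0.01$ by default), the burden is the plain average of
risk-allele counts,

$$ f_i = \frac{1}{J_i} \sum_{j=1}^{J_i} G_{ij}, $$

where $G_{ij}$ counts copies of the risk allele — the allele whose GWAS
log-odds $\beta$ is positive after orientation (`orient_risk()`). Missing
calls are excluded from both numerator and count. The divisor is the
number of SNPs, not chromosomes: pseudo-haploid ancient genotypes (one
allele call per site) give $f \in [0,1]$ while diploids give
$f \in [0,2]$. We deliberately keep this un-normalised form as the
default because the analyses always compare like with like; mixing
ploidies without `normalise = TRUE` is refused rather than silently
rescaled. SNPs with $\beta = 0$ have no risk orientation and are dropped
deterministically.

## QC

The canonical filter order is fixed and matters: samples with more than
50% missing calls are removed first; then variants called in less than
90% of the *remaining* samples; then the GWAS-p subset; then greedy
windowed LD pruning with a variance-inflation-factor threshold
(window 50 variants, step 5, VIF 2 — the classic `indep 50 5 2`
parameterisation, with windows in variant counts). Inside a window the
variant with the largest VIF above threshold is removed first, ties
broken by lowest index, giving a deterministic result. Missing dosages
are mean-imputed within the window before the VIF regression:
pairwise-complete regression is ill-posed under the heavy missingness of
pseudo-haploid data. All three thresholds are strict inequalities
("above 50%", "below 90%", "below 0.01"), and the boundary cases are
kept accordingly.

## Trend tests and the risk-allele flip null

The trend statistic is Kendall's $\tau$-b between burden and *calendar
time* ($-\text{age}_{BP}$), so a burden declining toward the present is a
negative $\tau$; this sign convention matches how such results are
conventionally reported (time axes drawn reversed). Because GWAS effects
may not transport across environments, the null model of interest is not
"no correlation" but "these SNPs are ordinary SNPs of the same
frequencies": `flip_null_trend()` re-assigns each SNP's risk allele with
probability 1/2, recomputes every burden and the trend $\tau$, and
repeats (10,000 draws by default). Empirical p-values use the add-one
rule $(1+k)/(n+1)$ and can never be zero.

One design point deserves emphasis. Choosing the test's tail *after
seeing the sign of the observed $\tau$* doubles the type-I error of the
nominal level (both tails can reject). The function therefore supports
both conventions: `alternative = "observed"` reproduces the
read-the-direction-off-the-data usage, while a pre-specified
`"less"`/`"greater"` is what the pipeline and the calibration tests use —
the scientific hypothesis here (decline of risk alleles) is directional,
and only the pre-specified version can be, and is, calibrated at
$\alpha$.

Companion analyses follow standard practice: OLS of burden on sample age
with a two-level continent covariate; a first-order partial Kendall
correlation $\tau_{xy\cdot z}$ for burden versus hunter-gatherer ancestry
controlling for age (normal approximation for its p-value); one-tailed
Wilcoxon rank-sum comparisons of burden between population groups; and a
weighted Kendall $\tau$ (pair weights = product of per-SNP
$-\log_{10} p$) for cross-disorder effect-size concordance. The weighted
estimator is $\tau$-a-style so that equal weights reduce exactly to
$\tau$-a; tie pairs contribute weight but no sign.

## Ancestral-allele enrichment

SNPs are classified into strongly associated ($p \le 10^{-8}$) versus
non-associated ($p \ge 0.9$), and by whether the risk allele is the
ancestral (outgroup) state. A/T and C/G SNPs are excluded — without
strand information the outgroup base cannot be assigned to an allele —
as are SNPs whose ancestral call matches neither allele. The odds ratio
of "ancestral risk" between the two association classes is tested
against a null that *preserves the MAF spectrum*: SNPs are binned by MAF
(half-open bins of 0.02, top bin closed at 0.5) and category labels are
permuted within bins, keeping per-bin category counts exactly. The test
is one-tailed for enrichment (OR at least as large as observed). Empty
cells get a 0.5 continuity correction and a flag.

## The Brownian selection-trend model and its ABC estimator

Risk-allele frequencies evolve on a dated sample tree. Along a branch of
$\Delta t$ generations,

$$ f' \sim N(f + \gamma\,\Delta t,\; d\,\Delta t), $$

truncated to $[0,1]$: $\gamma$ is the per-generation selection trend
shared by all loci (negative = selection for protective alleles), $d$ the
per-generation drift variance. The model is deliberately minimal — it
asks only about the *average* trend, not per-locus selection. The default
tree has eight dated Upper-Palaeolithic/Mesolithic Eurasian leaves with
the published clustering of those genomes; internal-node ages are
plausible interpolations (no published branch lengths exist), converted
to generations at 29 years each. Over the ~45,000-year span this is
$\approx 1{,}552$ generations, so the prior bound
$|\gamma| \le 10^{-4}$ corresponds to a per-locus frequency change of at
most $\approx 0.155$.

Priors: $\gamma \sim U(-10^{-4}, 10^{-4})$ (symmetric about neutrality);
$d$ log-uniform on $(10^{-8}, 10^{-4})$ — these bounds are not printed in
the main text of the study this design follows, so the package default
spans negligible-to-strong drift without favouring either end; root
frequencies uniform on $(0.05, 0.95)$ per locus. All three are
configurable (`abc_priors()`).

The raw summary statistic of a simulated dataset is the vector of
per-leaf mean frequencies over loci (the expected burden at each leaf).
Because an eight-dimensional summary is already awkward for rejection
ABC, the package follows the neural-summary approach: ten independently
initialised feedforward nets (four hidden layers of five Elliott units,
slope 0.1, output rescaled to $[0,1]$) are trained on a 10,000-simulation
reference table with full-batch RPROP$^-$ and dropout 0.1, stopping at
training MSE $\le 0.01$ or 10,000 iterations. The consensus (mean)
prediction is a scalar summary that is then used in classical ABC:
simulate a fresh pool from the priors, retain the `n_retain` simulations
whose summary is closest to the observed one, and adjust the retained
$\gamma$ draws by weighted local-linear regression on the summary
(Epanechnikov weights), truncating to the prior support. With dropout the
training loss usually plateaus slightly above the 0.01 target and uses
the full iteration budget; "error" is interpreted as MSE on the scaled
target over the training pass used for the gradient. The training loop
itself is compiled (RcppArmadillo) with a bit-identical pure-R reference
backend retained and cross-checked in the tests.

Estimator quality is summarised by the *factor-2 statistic*: the fraction
of validation simulations whose posterior mean has the correct sign and
magnitude within 50–200% of the truth. Truths with $|\gamma| < 10^{-6}$
are excluded from the ratio (a fold-change criterion is meaningless at
zero) and counted separately. At desk scale (pool of 50,000 rather than
1,000,000) the acceptance suite requires this calibration to fall within
seven percentage points of the published full-scale value of 93.1%; the
exact number for a given seed is computed by `scripts/acceptance.R`,
never quoted from memory.

## Recent adaptation: trait-aligned SDS

The singleton density score measures very recent frequency change of one
designated allele. `align_tsds()` re-signs it to the trait's risk allele
(tSDS), drops SNPs whose score allele matches neither GWAS allele, and
`binned_spearman()` sorts SNPs by GWAS p, groups them into consecutive
bins of 1,000 (final partial bin kept), and correlates per-bin mean tSDS
with per-bin mean p. A positive $\rho$ means the strongly associated bins
carry *negative* tSDS — protective alleles rising recently. The null
respects linkage: 1-Mb physical blocks (per chromosome,
$[k\,\text{Mb}, (k+1)\,\text{Mb})$) have their tSDS signs flipped
together with probability 1/2 per draw (1,000 draws); the draw
distribution is summarised by a fitted normal and the one-tail p is
$P(N(\hat\mu,\hat\sigma) > \rho_{obs})$, with the add-one empirical p
also reported. Bins are fixed by the p-order, which sign flips do not
change, so observed and null statistics use identical binning.

## Introgression enrichment

Tag SNPs of archaic haplotypes are filtered to those whose archaic allele
is homozygous in the high-coverage Altai Neanderthal genome, joined to
the GWAS, and their $\beta$ oriented to the archaic allele. The statistic
is the mean oriented effect $\bar\beta$; the null flips each tag's
orientation independently (sign flip with probability 1/2), under which
the null mean has expectation 0 and variance $\sum\beta_j^2/m^2$
(checked against this closed form in the tests). The wording "permuted at
random" is ambiguous between sign flips and shuffling effects across
tags; sign flips are the default (the orientation is the quantity that is
exchangeable under the null), and a shuffle variant that permutes effect
sizes across tags while keeping orientations is available behind
`scheme = "shuffle"`.

## What the synthetic data does and does not emulate

The generator (`synth_config()` and the `make_*` functions) produces:
GWAS tables whose p-values, effect sizes and MAFs are mutually coherent
through a Wald construction with a realistic effective sample size
(~53,000); a folded-Beta(0.5, 0.5) MAF spectrum truncated to
$[0.01, 0.5]$; pseudo-haploid dated panels whose per-locus frequencies
evolve on the tree under the Brownian-plus-trend model (default
$\gamma = -7.72\times10^{-5}$, the published point estimate for the
motivating trait, and $d = 10^{-6}$, mid-range of the drift prior);
ancestral maps, SDS tables and tag-SNP sets with tunable enrichment and
coupling; and truth sidecars that analysis code never reads.

Missingness is *structured*, not i.i.d.: a U-shaped per-variant rate
(capture-style — a SNP is either covered in nearly everyone or missing in
most) multiplied by a per-sample quality factor, with the configured
value (default 0.4) as the overall rate. This is a deliberate deviation
from a simpler i.i.d. specification: under i.i.d. 40% missingness no
variant can pass a 90% call-rate filter, while real ancient-DNA panels
lose most *samples* and keep thousands of *variants* — only
variant-structured missingness reproduces that behaviour.

Hunter-gatherer ancestry is generated as a logistic function of sample
age plus noise, so the age-confounding scenario for the partial Kendall
correlation exists by construction. Positions sit on one synthetic
chromosome at 1-kb spacing by default (several 1-Mb blocks); block-based
analyses on small SNP counts should widen `spacing_bp`.

Not emulated: realistic LD (loci are exchangeable and independent given
the frequency path — LD pruning on synthetic panels is near-vacuous),
radiocarbon date uncertainty, reference bias, contamination and
post-mortem damage. A green test therefore establishes the statistical
machinery, not robustness to those artefacts.

## Numerical choices and degenerate inputs

* Empirical p-values always use the add-one rule; they lie in
  $[1/(n+1), 1]$.
* Frequencies are truncated (not reflected) at $[0,1]$ after each branch
  draw; with the default priors clamping is a second-order effect.
* `partial_kendall()` refuses a control variable whose association with
  either argument is numerically perfect ($1 - \tau^2 < 10^{-12}$-ish);
  the estimate is 0/0-unstable there. More generally the first-order
  partial-$\tau$ formula *shrinks* rather than exactly removes
  confounding (unlike partial Pearson correlation under normality,
  $\tau_{xy} \ne \tau_{xz}\tau_{yz}$ under conditional independence);
  interpret small residual partial correlations accordingly.
* Ties: GWAS-p sorting is stabilised by (chrom, pos); `which.max`
  tie-breaks by lowest index in LD pruning; $\tau$-b is used for data
  correlations and $\tau$-a inside the weighted estimator (the reduction
  property requires it).
* All stochastic entry points take a `seed`; the pipeline derives stage
  seeds deterministically from one global seed, and reruns are
  byte-identical.
* Mixed-ploidy burden comparisons require `normalise = TRUE`; the
  function refuses otherwise instead of producing incomparable numbers.

## Known limitations

The estimator's accuracy degrades for $|\gamma|$ below roughly the
drift-induced uncertainty ($\sim 5\times10^{-6}$ at the largest prior
drift), which is what keeps the factor-2 statistic below 100%. The
block-flip null needs enough blocks ($\ge 2$ enforced, $\gtrsim 20$
sensible) and the binned Spearman needs enough bins to have power. The
LD-pruning reimplementation is deterministic and oracle-checked, but
exact SNP-count equality with the original external pruning tool on real
data is not claimed, since that tool's handling of missing pseudo-haploid
calls is undocumented.
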
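# paleoburden

Temporal dynamics of GWAS risk-allele burden in ancient genomes.

`paleoburden` is for population geneticists who want to ask, with ancient
and modern human genotype panels plus GWAS summary statistics, whether
the alleles that increase a polygenic trait's risk today have been
rising, drifting, or declining over tens of millennia. It implements:

* **Burden**: the per-individual mean risk-allele dosage over called
  trait-associated SNPs, `f_i = (1/J_i) Σ_j G_ij`, on pseudo-haploid
  (ancient) or diploid panels, with GWAS-based risk orientation.
* **QC**: the canonical two-step missingness filter (samples > 50%
  missing, then variants < 90% call rate), GWAS-p subsetting (p < 0.01),
  and windowed variance-inflation LD pruning (`indep 50 5 2`-style).
* **Trend tests**: Kendall τ-b of burden against calendar time, with a
  risk-allele *flip* randomization null (equivalent to frequency-matched
  random SNP sets); OLS with a continental covariate; partial Kendall τ
  controlling for sampling age; Wilcoxon group contrasts; weighted
  Kendall τ for cross-disorder effect concordance.
* **Ancestral enrichment**: odds ratio of "risk allele is the ancestral
  state" between strongly associated (p ≤ 1e-8) and non-associated
  (p ≥ 0.9) SNPs, with a MAF-binned (0.02) label-permutation null.
* **Selection-trend estimation (ABC with neural summaries)**: allele
  frequencies evolve on a dated eight-leaf sample tree as
  `f' ~ N(f + γΔt, dΔt)`; an ensemble of ten small feedforward nets
  (4 × 5 Elliott units, RPROP⁻, dropout 0.1) trained on a
  10,000-simulation reference table compresses the per-leaf mean
  frequencies into a scalar summary; rejection ABC with local-linear
  adjustment yields the posterior of the per-generation trend
  γ ∈ (−1e-4, 1e-4). Validation via the *factor-2* statistic.
* **Recent adaptation**: trait-aligned singleton density scores (tSDS),
  binned Spearman correlation with GWAS p, and a 1-Mb block sign-flip
  null with normal-approximated one-tail p.
* **Introgression**: mean GWAS effect size oriented to the archaic
  allele over Altai-homozygous Neanderthal tag SNPs, with a sign-flip
  permutation null.
* **Synthetic data**: generators for every input (GWAS table, dated
  pseudo-haploid VCF panels evolving under the frequency model,
  ancestral BED, SDS and tag-SNP tables) with truth sidecars, so the
  whole pipeline runs and is tested without any external dataset.

See the methods vignette (`vignettes/paleoburden-methods.Rmd`) for the
models, parameter meanings, defaults and design decisions.

## Worked example

Everything below is computed from synthetic data; the numbers are the
actual output of the calls shown (seed 42).

```r
library(paleoburden)

cfg <- pipeline_config(
  seed = 42,
  synth = synth_config(n_snps = 1000, samples_per_leaf = 4,
                       spacing_bp = 20000, seed = 42),
  n_nulls = 2000, abc_ref_sims = 4000, abc_n_sims = 20000,
  abc_n_retain = 400)
res <- run_pipeline(cfg, "demo_out")

res$qc
#>                stage samples variants
#> 1              input      32     1000
#> 2 sample_missingness      26     1000
#> 3   variant_callrate      26      418
#> 4      gwas_p_subset      26       32
#> 5           ld_prune      26       16
```

Six of 32 pseudo-haploid samples exceed 50% missingness; 418 of 1,000
variants survive the call-rate filter, 32 are trait-associated at
p < 0.01, and LD pruning keeps 16. The generator simulated a true
selection trend of γ = −7.72e-5 per generation (the `synth_config()`
default), and the analyses recover it:

```r
str(res$trend[c("tau", "p_asymptotic")])
#> $ tau         : num -0.243
#> $ p_asymptotic: num 0.0935
res$trend$flip_null$p_empirical
#> [1] 0.05697151
```

Burden declines toward the present (τ = −0.24); with only 16 SNPs the
flip-null evidence is borderline (p ≈ 0.057) — small SNP sets are noisy,
which is exactly what the null quantifies.

```r
res$abcdl
#> $posterior_mean
#> [1] -8.32e-05
#> $ci
#> [1] -9.84e-05 -4.07e-05
```

The ABC posterior mean −8.3e-5 (95% credible interval −9.8e-5 to
−4.1e-5) brackets the true −7.72e-5. Over ~1,552 generations
(45,000 years at 29 years/generation) a trend of this size corresponds
to a per-locus frequency decay of about 0.12.

```r
res$ancestral$odds_ratio       # 1.95  (true enrichment 0.7 vs 0.5)
res$introgression$mean_beta    # 0.0048, p = 5e-04 (true enrichment 0.8)
```

Both enrichment analyses recover their generator settings; the tSDS
correlation is null here because the demo's coupling bin is larger than
the SNP set (see the vignette).

## Command line

```sh
Rscript -e 'paleoburden::cli_main()' run --out out/ --seed 7
Rscript -e 'paleoburden::cli_main()' qc  --out out/   # single stage
```

Stages: `synth qc burden trend ancestral sds introgression abcdl run`;
`--config cfg.json` supplies a full [pipeline_config] as JSON. Every run
writes a `manifest.json` with stage seeds and file hashes; reruns are
byte-identical.

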
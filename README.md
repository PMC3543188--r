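# omixvar

Bayesian integrative variance partitioning of genome and transcriptome
data, for quantitative geneticists who have pedigree, genome-wide SNP and
expression-microarray (or RNA-seq abundance) data on the same individuals
and want to know **where phenotypic variance comes from** — family
structure, the genome, or the transcriptome — and **which QTL signals are
mediated by transcript abundance** (eQTL-type loci) versus acting through
other routes.

## The model

The complete model regresses a phenotype jointly on all data layers:

```
y = 1 mu + X b + Z u + W a + Q g + e

u ~ N(0, A sigma_u^2)        polygenic (pedigree) effects
a ~ N(0, I sigma_s^2)        SNP effects          (mixed model)
g ~ N(0, I sigma_g^2)        transcript effects   (mixed model)
e ~ N(0, I sigma_e^2)
```

where `A` is the numerator relationship matrix from the pedigree, `X`
carries batch and sex, and `W`, `Q` are centered, unit-scaled SNP-dosage
and transcript-abundance covariates.  All variances carry flat priors and
the model is fitted by single-site Gibbs sampling (`run_mixed_model()`).
The variable-selection variant (`run_bvs()`) replaces the normal priors
on `a` and/or `g` with two-component normal mixtures

```
a_i ~ gamma_i N(0, tau1^2) + (1 - gamma_i) N(0, tau0^2),   gamma_i ~ Bern(pi)
```

with `tau1^2 > tau0^2` enforced by a rejection sampler — the sharper
prior used to localize signal along the genome.

Explained variances are posterior summaries of `var(W a^t)` (and
analogues) over MCMC cycles, partitioned per data layer, per chromosome
and per 5-SNP sliding window.  Comparing the SNP windows of a marginal
(SNP-only) and a conditional (SNP + expressions) fit classifies each
window as "mediated/eQTL-like" (variance collapses when transcripts enter
the model), "direct", or "intermediate" (`eqtl_contrast()`).

An F2-intercross simulator (`simulate_dataset()`) generates pedigree,
linked tag SNPs (mean adjacent-dosage R^2 calibrated to 0.55),
eQTL-controlled expression probes and phenotypes with exactly known
variance fractions, so the whole pipeline is testable without external
data.  Model quality tooling includes k-fold cross-validation
(`crossvalidate()`), effective sample sizes (`ess()`) and the
repeated-run Monte-Carlo accuracy check (`repeated_run_correlation()`).

## Worked example

```r
library(omixvar)

ds <- simulate_fixture(seed = 1)        # 200 F2, 100 SNPs, 200 probes
blocks <- design_blocks(ds$phenotypes, ds$pedigree, ds$genotypes,
                        ds$map, ds$expressions)
fit <- run_mixed_model(NULL, blocks, spec = model_spec(seed = 11))
variance_partition(fit, by_chromosome = FALSE)
```

```
ov_partition (PED+SNP+GEX model, 18000 cycles)
 component    pm    psd prop_total prop_explained
         E 0.131 0.0585      0.125          0.167
       PED 0.133 0.0628      0.126          0.169
       SNP 0.166 0.0508      0.158          0.212
       GEX 0.355 0.1101      0.338          0.452
  residual 0.265 0.0988      0.253             NA
total 1.048 (explained 0.7836)
```

The fixture was generated with variance fractions polygenic 0.2, direct
SNP 0.2, expression-mediated 0.4 and residual 0.2 (plus batch/sex on
top), and the partition recovers that structure: the `pm` column is the
posterior-mean explained variance of each layer in squared-phenotype
units (`E` = batch/sex, `PED` = polygenic, `SNP` = genomic, `GEX` =
transcriptomic), `psd` its posterior SD, and the two proportion columns
divide by the model total with and without the residual.

Chain accuracy, the way a production run should check it:

```r
repeated_run_correlation(blocks, spec = model_spec(), seed1 = 11, seed2 = 12)$correlations
#         u         a         g
# 0.9997031 0.9996866 0.9998256
```

All three posterior-mean effect vectors reproduce across independent
chains with correlation above 0.999.

Cross-validated prediction and calibration (slope of actual on predicted;
1 means the explained variances are correctly assessed):

```r
cv <- crossvalidate(ds, spec = model_spec(chain = chain_control(20000, 5000, 10),
                                          seed = 3), k = 11, fold_seed = 2)
round(c(rho = cv$rho, beta = cv$beta), 3)
#   rho  beta
# 0.583 0.925
```

For file-based workflows the same operations are available from the
shell through the installed `exec/omixvar` script
(`simulate`, `validate`, `fit`, `grid`, `cv`, `partition`, `diagnose`),
reading delimited text files plus a YAML run configuration, and
`run_grid()` fits the full seven-model grid (PED, SNP, GEX and their
combinations) and writes the master explained-variance table.

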
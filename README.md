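# vargwas

Quantitative-genetic analysis of a repeatedly recorded trait **and of the
heterogeneity of its residual variance**, with a genome-wide association
scan for both. The motivating application is litter size (total number
born, TNB) in pigs: sows differ genetically not only in how many piglets
they farrow on average but also in how much that number varies between
parities, and both signals matter for breeding.

The package provides the full chain:

1. **Phenotype editing** — drop litters below 4 piglets, cap at 27, pool
   parities 10+ (`edit_records()`, `summarize_sows()`).
2. **Pedigree machinery** — inbreeding by ancestor tracing, the numerator
   relationship matrix A and its sparse inverse (`compute_inbreeding()`,
   `build_relationship()`, `build_ainverse()`).
3. **A sparse AI-REML engine** for weighted univariate and bivariate animal
   models (`mixed_design()`, `estimate_reml()`, `solve_mme()`), built on a
   C++ selected inverse of the mixed-model coefficient matrix that yields
   exact score traces, leverages and prediction-error variances in one
   pass.
4. **The iterative double hierarchical GLM** coupling the mean model
   `y = Xb + Za + U pe + e` with a log-linear model for the residual
   variance, `log sigma2_e,i = mu_v + a_v + pe_v`, through the linearized
   working response
   `psi_i = log s2_i + (e_i^2/(1-h_i) - s2_i)/s2_i` and the weights
   `W = diag(exp(psi_hat))^-1`, `W_v = diag((1-h)/2)` (`run_dhglm()`,
   `working_response()`, `update_weights()`, `gcv_sde()`,
   `h2_residual_variance()`).
5. **Deregression** of both parts' EBVs into GWAS pseudo-phenotypes with
   reliabilities `r2 = 1 - s_i^2/((1+f_i) sigma2_a)` and
   heterogeneous-variance weights (`deregress()`, `filter_reliability()`).
6. **Genotype QC** — quality score, sex chromosome / unknown position,
   MAF, call rate, opposing-homozygote Mendelian conflicts
   (`qc_genotypes()` and friends).
7. **Multi-SNP Bayesian variable-selection GWAS** — every SNP effect from a
   two-component normal mixture with prior inclusion probability `pi1`
   (default 0.001), posterior inclusion probabilities, Bayes factors
   `BF = (p/(1-p))/(pi1/pi0)` with the 30 ("very strong") and 150
   ("decisive") reporting thresholds, allele substitution effects
   `alpha = sqrt(var_snp/(2pq))` and percent of genetic variance explained
   (`run_bvs()`, `bayes_factor()`, `classify_bf()`, `gelman_rubin()`).
8. **A synthetic-data generator** with planted mean QTL and variance QTL
   (vQTL) so every stage can be tested against known truth
   (`simulate_pedigree()`, `simulate_genotypes()`,
   `simulate_phenotypes()`), and **a pipeline driver** behind one YAML
   config (`run_pipeline()`; a thin CLI lives in `inst/scripts/vargwas.R`).

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods (component traces, genome-wide Bayes-factor plots).

## A worked example

```r
library(vargwas)

ped <- simulate_pedigree(n_founders = 300, n_generations = 2,
                         litters_per_dam = 3, seed = 1)
sim <- simulate_phenotypes(ped,
         sim_params(sigma2_a = 1.2, sigma2_av = 0.05, r_a = 0.5,
                    sigma2_pe = 0.7, sigma2_pev = 0.15, r_pe = -0.8),
         parities_per_sow = 6, seed = 2)

dh <- run_dhglm(sim$records, ped)
tidy(dh)
```

On this simulated herd (357 sows, 6 parities each) the component table
prints, among others:

```
   component              estimate      se
 1 sigma2_a_tnb             1.025   0.460
 2 cov_a_tnb_.psi           0.123   0.105
 3 sigma2_a_.psi            0.078   0.048
 4 r_a                      0.434   0.351
 8 r_pe                    -0.770   0.381
 ...
11 h2                       0.116   NA
12 GCV_SDe                  0.139   NA
```

`sigma2_a_tnb` is the additive genetic variance of litter size (truth 1.2),
`sigma2_a_.psi` the additive genetic variance of its log residual variance
(truth 0.05), and `r_a` their genetic correlation (truth 0.5): a positive
value means selection for larger litters also increases their variability.
All three sit within one approximate SE of their generating values at this
modest herd size. `GCV_SDe = 0.5 * sqrt(sigma2_av)` says by what fraction
one genetic standard deviation of selection could change the residual SD —
0.139 here, i.e. about 14%. `h2` is the narrow-sense heritability of the
trait, `sigma2_a / (sigma2_a + sigma2_pe + mean residual variance)`.

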
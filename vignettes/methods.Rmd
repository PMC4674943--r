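---
title: "Genetic analysis of a trait mean and its residual variance with vargwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic analysis of a trait mean and its residual variance with vargwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vargwas)
```

## The problem

In litter-bearing species, not only the level of litter size but also its
variation from parity to parity differs between sows, and part of that
variation in *variability* is heritable. vargwas implements a complete
analysis chain for this setting: the trait mean and the (log) residual
variance are modelled jointly as two correlated heritable traits, breeding
values for both are deregressed into pseudo-phenotypes for genotyped
animals, and a multi-SNP Bayesian variable-selection scan reports which
markers are associated with the mean (QTL) and which with the variability
(vQTL).

## The model

Repeated litter records $y_{ij}$ (sow $i$, parity $j$) follow a Gaussian
animal model

$$ y = Xb + Za + U\,pe + e, $$

with parity and farm-year-season as fixed effects, additive genetic effects
$a \sim N(0, A\sigma^2_a)$ over the numerator relationship matrix $A$,
permanent sow effects $pe \sim N(0, I\sigma^2_{pe})$, and heteroscedastic
residuals whose variance is itself modelled on the log scale,

$$ \log \sigma^2_{e,i} = \mu_v + a_{v,i} + pe_{v,i}, $$

with its own fixed effects, additive effects $a_v$ and permanent effects
$pe_v$. The two parts are coupled through unstructured $2\times2$
covariance blocks for $(a, a_v)$ over $A$ and $(pe, pe_v)$ over $I$. The
genetic correlation $r_a$ between $a$ and $a_v$ says whether selection on
litter size will drag its variability along; $r_{pe}$ captures non-genetic
mean-variance coupling.

Note that the permanent sow effect enters with an identity covariance:
permanent environment is non-genetic by definition, so a published variant
of the model equation showing $pe \sim N(0, A\sigma^2_{pe})$ is treated as
a typographical slip.

### The linearized dispersion response

The residual-variance model is fitted through the first-order linearization
of $\log\!\big(e_i^2/(1-h_i)\big)$ around the current predicted residual
variance $\hat\sigma^2_{e,i}$:

$$ \psi_i = \log \hat\sigma^2_{e,i} +
   \frac{e_i^2/(1-h_i) - \hat\sigma^2_{e,i}}{\hat\sigma^2_{e,i}}, $$

where $e_i$ is the mean-part residual and $h_i$ the leverage (hat-matrix
diagonal) of record $i$. The pair $(y, \psi)$ is then fitted as a weighted
bivariate linear mixed model: the mean part is weighted by
$w_i = \exp(\hat\psi_i)^{-1}$ (reciprocal predicted residual variance), the
dispersion part by $w_{v,i} = (1-h_i)/2$ (reciprocal asymptotic variance of
a linearized $\chi^2_1$ response). Residuals of the two parts are taken as
independent given the effects, so all non-genetic mean-variance covariance
must flow through the permanent-effect block — which is why constraining
that covariance to zero distorts the genetic correlation (see below). The
two residual *scaling* variances have expectation 1 at convergence and are
reported as a diagnostic.

`run_dhglm()` alternates (i) a weighted bivariate REML fit of $(y, \psi)$
and (ii) recomputation of $e$, $h$, $\hat\sigma^2_{e,i} = \exp(\hat\psi_i)$,
$\psi$ and both weight vectors, until the maximum relative change of every
variance component falls below `tol` (default $10^{-6}$, outer cap
`max_iter = 100`). Starting values come from a conventional univariate fit
of $y$, with $\hat\sigma^2_{e,i}$ initialized at that fit's constant
residual variance.

**Damping.** The plain alternation can enter a slowly contracting
period-two cycle when the dispersion variance is substantial: the fitted
$\hat\psi$ overshoots, the weights overcorrect, and successive REML fits
bounce between two states. `run_dhglm(damping = 0.5)` (the default)
relaxes the update of the dispersion predictor,
$\hat\psi \leftarrow \tfrac12 \hat\psi_{new} + \tfrac12 \hat\psi_{old}$,
which restores a clean geometric contraction (typically 5-15 outer
iterations at desk scale) without changing the fixed point. `damping = 1`
recovers the undamped alternation.

## The REML engine

All fits run through one sparse average-information (AI) REML engine
(`mixed_design()`, `estimate_reml()`, `solve_mme()`) for weighted
univariate and bivariate models with any mix of pedigree-structured and
identity-structured random terms:

* The mixed-model equations use Henderson's sparse $A^{-1}$ built from
  inbreeding coefficients (Meuwissen-Luo style ancestor tracing, in C++).
* Each iteration factors the coefficient matrix with CHOLMOD and computes a
  *selected inverse* (Takahashi equations, in C++) on the factor's
  sparsity pattern. That one pass yields exact REML score traces, every
  record's leverage $h_i$, and every EBV's prediction-error variance —
  no per-animal solves.
* Updates are AI steps with step halving; a step that would leave the
  parameter space (negative variance, non-positive-definite $2\times2$
  block) is shortened, and components heading to zero are pinned at
  $10^{-8}$. Convergence is declared at a relative restricted-likelihood
  change below $10^{-8}$. Approximate standard errors come from the inverse
  AI matrix; correlation SEs use the delta method.
* Fixed-effect rank deficiency (confounded factors) is detected at design
  construction and reported as an error, as are zero-variance responses.

The engine is verified against independent oracles in the test suite:
dense generalized-least-squares solutions, hat-matrix and prediction-error
variances from explicit dense inverses, closed-form ANOVA estimators on
balanced designs, `lme4` on weighted identity-structured models, and a
dense derivative-free bivariate REML oracle.

## Deregression

EBVs of genotyped animals are converted to deregressed proofs with the
two-equation information partition: from the reliability of the parent
average, $r^2_{PA} = (r^2_{sire} + r^2_{dam})/4$, and of the animal's EBV,
$r^2 = 1 - s_i^2 / ((1+f_i)\sigma^2_a)$, the effective information contents
of the parent average and of the animal's own-plus-progeny data are
reconstructed; the deregressed proof is the own-information right-hand side
divided by its information content. Animals whose own information content
is not positive are dropped and reported. Weights for the marker analysis
are $w = (1-h^2)\big/\big((c + (1-r^2_d)/r^2_d)\,h^2\big)$ with $c$ the
fraction of genetic variance not captured by markers (default 0.5,
configurable; recorded in the output metadata together with the fact that
weights are not renormalized). Deregressed proofs are unshrunken estimates
of the *full* breeding value, so they still correlate with the parent
average through genuinely transmitted genes; what deregression removes is
the double counting of parent *information*, and the test suite asserts
exactly that (the proof's error decorrelates from the parent average's
error) plus the exact algebraic self-consistency of the two-equation
system. EBVs fed into deregression come from univariate re-fits of each
part at the final DHGLM weights, so neither trait's proof borrows the
other trait's data.

## Genotype QC and the Bayesian variable-selection GWAS

SNP filters run in a fixed order (quality score < 0.15, sex-chromosome or
unknown position, minor allele frequency < 0.01), after animal filters
(call rate < 0.95, then opposing-homozygote Mendelian-conflict rate against
genotyped parents above 0.01 — the threshold quantifying "many
inconsistencies" is configurable since no standard number exists). Allele
frequencies are computed on retained animals; remaining missing calls are
imputed to the SNP mean dosage.

The association model is
$y = \mu + X_b\beta + e$, $e \sim N(0, \sigma^2_e W_t^{-1})$ on the
weighted deregressed proofs, with every SNP effect drawn from a
two-component normal mixture: a null component $N(0, \sigma^2_{g0})$ with
probability $\pi_0$ and a large-effect component $N(0, \sigma^2_{g1})$ with
probability $\pi_1$ (default 0.001; 500,000 cycles by default). Dosages
are centred per SNP; $\mu$ absorbs the centring. Indicators and effects
use conjugate single-site Gibbs draws with marginal (effect-integrated)
odds for the indicator. The residual variance uses a conjugate
scaled-inverse-chi-square draw; the large-component variance uses a
scale-invariant conditional with one pseudo-observation at a floor set two
orders of magnitude above $\sigma^2_{g0}$ (keeping the components
distinguishable and the draw proper when the large component is
momentarily empty), capped at the response variance, followed by one
random-walk Metropolis-Hastings refinement of size `mh_step` (default
0.003) on the log scale. A pure random-walk update for both variances was
rejected: with a step of 0.003 the chain cannot traverse the posterior in
any realistic number of cycles, and on null data it visibly breaks the
calibration property that the mean number of SNPs in the large component
per cycle is close to $\pi_1 p$. With the conjugate updates that
calibration holds within a few percent.

Per SNP the sampler reports the posterior inclusion probability $\hat p$
(post burn-in fraction of cycles in the large component; burn-in defaults
to 10%), the posterior mean effect $\bar\beta$, the Bayes factor
$BF = \big(\hat p/(1-\hat p)\big)\big/\big(\pi_1/\pi_0\big)$, the allele
substitution effect $|\bar\beta| = \sqrt{2pq\bar\beta^2/(2pq)}$, and the
percent of genetic variance explained,
$100\cdot 2pq\bar\beta^2 / \sigma^2_{g,tot}$, where the denominator
defaults to $\sum_j 2p_jq_j\bar\beta_j^2$ but can be set to the DHGLM
additive genetic variance. Significance labels follow the conventional
Bayes-factor thresholds (very strong at 30, decisive at 150; tables report
$BF \ge 30$). Convergence can be checked with multiple chains and the
between/within potential-scale-reduction factor (`gelman_rubin()`,
converged below 1.1). Given a seed, a chain is exactly reproducible.

## The synthetic-data generator

`simulate_pedigree()` builds non-overlapping generations under random
mating with heavy sire reuse (`sire_fraction = 0.05` of males serve as
sires), the structure of commercial pig populations. `simulate_genotypes()`
drops founder gametes (frequencies uniform in a configurable range) down
the pedigree, so Mendelian consistency holds by construction; planted mean
QTL and vQTL receive centred-dosage effects that are added to $a$ and
$a_v$. `simulate_phenotypes()` draws $(a, a_v)$ jointly over the pedigree
by Mendelian sampling of breeding values (exactly $N(0, G\otimes A)$),
$(pe, pe_v)$ per sow, and residuals $N(0, \exp(\mu_v + a_{v} + pe_{v}))$.
Default parameters are the variance structure of a commercial Large White
litter-size population: mean 13.5, $\sigma^2_a = 1.18$,
$\sigma^2_{av} = 0.03$, $r_a = 0.49$, $\sigma^2_{pe} = 0.69$,
$\sigma^2_{pev} = 0.15$, $r_{pe} = -0.83$, $\mu_v = \log 6.5$. Phenotypes
stay continuous by default (the mean model is Gaussian); an
`integer_tnb` mode rounds and truncates them so the editing rules
(drop below 4, cap at 27, pool parities at 10) have something to bite on.

What the generator does *not* emulate: linkage disequilibrium from
recombination maps (SNPs segregate independently given the pedigree),
selection across generations, cross-fostering, or seasonal confounding
between farm-year-season classes and parity. Passing tests therefore show
that the estimators recover the generating process they assume — not that
real litter records obey that process.

## Known limitations and numerical choices

* **Within-sow coupling of squared residuals.** With few records per sow,
  the residuals of one sow share the estimation error of her combined
  $(a + pe)$ BLUP, so their squares — and hence the $\psi_i$ — are
  positively correlated within sow beyond what the model carries. The
  linearized estimator books that extra covariance as permanent dispersion
  variance: at 5 records/sow a null simulation (no true heterogeneity)
  yields $\hat\sigma^2_{pev} \approx 0.06$ and a dispersion scaling
  variance near 0.73 rather than 1; at 15 records/sow the artifact
  essentially vanishes. Under strong true heterogeneity it also attenuates
  $r_{pe}$ toward zero. This is a property of the linearized working
  response itself, shared by any implementation of this estimator, and it
  is why the recovery checks at desk scale focus on
  $\sigma^2_a, \sigma^2_{av}, r_a, r_{pe}$ and why the scaling-variance
  diagnostic should be read alongside records-per-sow.
* **Problem sizes in the shipped checks.** The recovery checks run at
  2,000 sows with 5 parities each over a ~16,000-animal pedigree; the GWAS
  calibration and power checks use 500 animals, 2,000 SNPs and 20,000
  cycles with ten seed replicates; unit fixtures are smaller. These sizes
  were chosen so that each property is informative at desk scale.
* **Boundary behaviour.** Variance components are pinned at $10^{-8}$;
  correlation parameters can legitimately converge to $\pm 1$ on weakly
  identified data, where the AI surface is flat along the boundary —
  estimates there should be read as boundary solutions, not interior
  optima.
* **Conventional bivariate weights.** The per-sow mean uses weight
  $n$ and the per-sow log variance $\,(n-1)/2$, the reciprocals of the
  approximate sampling variances of a mean and of a log sample variance;
  since the exact published weighting is under-specified, the rule applied
  is recorded in the fit's metadata.
* **$h^2_v$ scale.** The heritability of residual variance at the
  squared-phenotype level is evaluated literally as
  $\sigma^2_{av}/(2\sigma_P^4 + 3(\sigma^2_{av}+\sigma^2_{pev}))$ with all
  inputs on the scales the model estimates them on; with desk-scale
  components it is of order $10^{-4}$, and published values an order of
  magnitude larger cannot be reproduced from printed components by this
  formula — the discrepancy is documented rather than resolved.
* **Parity pooling and capping order.** Records are dropped for small
  litters before capping large ones; the order is immaterial for the rules
  shipped (a record cannot trigger both).

## A small end-to-end run

```{r, eval = FALSE}
ped <- simulate_pedigree(n_founders = 300, n_generations = 2,
                         litters_per_dam = 3, seed = 1)
gen <- simulate_genotypes(ped, n_snps = 600, n_qtl = 1, n_vqtl = 1,
                          qtl_var = 0.6, vqtl_var = 0.05, seed = 2)
sim <- simulate_phenotypes(ped, sim_params(), genotypes = gen,
                           parities_per_sow = 6, integer_tnb = TRUE, seed = 3)

rec <- edit_records(sim$records)
dh  <- run_dhglm(rec, ped)
tidy(dh)
autoplot(dh)

eb  <- subset(dh$ebv, trait == "dispersion",
              select = c(animal, ebv, se))
names(eb) <- c("animal", "ebv", "se")
dd  <- deregress(eb, ped, sigma2_a = dh$refit$dispersion$G$a[1, 1],
                 h2 = 0.05)
dd  <- filter_reliability(dd, 0.05)

qc  <- qc_genotypes(gen$genotypes, gen$map, ped)
gw  <- run_bvs(dd, qc$genotypes, bvs_config(n_iter = 20000, seed = 4),
               map = qc$map)
tidy(gw)[tidy(gw)$bf >= 30, ]
autoplot(gw)
```

`run_pipeline()` wires these stages behind one YAML-serializable
configuration and writes self-describing stage TSVs (package version, seed
and config fingerprint in a header comment), running one GWAS for the mean
trait and one for the dispersion trait with their own reliability-filtered
proof sets.
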
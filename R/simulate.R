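#' Generative-model parameters for synthetic litter records
#'
#' Defaults reproduce the variance structure of a commercial Large White
#' litter-size population: trait mean ~13.5 piglets, additive genetic and
#' permanent-sow effects on the mean, and a log-linear residual-variance model
#' whose additive and permanent effects are correlated with those on the mean
#' (positive genetic, strongly negative permanent correlation).
#'
#' @param mu Trait mean.
#' @param sigma2_a,sigma2_av Additive genetic variance of the mean part
#'   (trait units squared) and of the log residual variance.
#' @param r_a Genetic correlation between mean and log-variance effects.
#' @param sigma2_pe,sigma2_pev Permanent-sow variances for the two parts.
#' @param r_pe Permanent-environment correlation between the parts.
#' @param mu_v Intercept of the log residual variance (so the average
#'   residual variance is about `exp(mu_v)`).
#' @param sigma2_parity,sigma2_fys Variances of the fixed parity and
#'   farm-year-season effect values drawn once per simulated population.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(mu = 13.5, sigma2_a = 1.18, sigma2_av = 0.03, r_a = 0.49,
                       sigma2_pe = 0.69, sigma2_pev = 0.15, r_pe = -0.83,
                       mu_v = log(6.5), sigma2_parity = 0.25, sigma2_fys = 0.25) {
  if (abs(r_a) > 1 || abs(r_pe) > 1) abort("correlations must lie in [-1, 1]")
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a multi-generation pedigree
#'
#' Non-overlapping generations with random mating: every dam of the previous
#' generation produces `litters_per_dam` offspring, each by a randomly drawn
#' sire of that generation; sexes are assigned at random. With
#' `litters_per_dam = 2` the population size stays roughly constant.
#'
#' @param n_founders Number of founder animals (>= 2; half of each sex).
#' @param n_generations Number of offspring generations (0 gives founders
#'   only).
#' @param litters_per_dam Offspring per dam per generation.
#' @param sire_fraction Fraction of each generation's males actually used as
#'   sires (default 0.05, mimicking the heavy sire reuse of commercial pig
#'   breeding, where few AI boars serve many sows); at least two sires are
#'   always used.
#' @param seed Integer seed; the same seed reproduces the same pedigree.
#' @return A `ped_tbl` (see [as_pedigree()]) with extra columns `sex`
#'   (`"M"`/`"F"`).
#' @export
simulate_pedigree <- function(n_founders = 100, n_generations = 4,
                              litters_per_dam = 2, sire_fraction = 0.05,
                              seed = 1) {
  if (n_founders < 2) abort("need at least 2 founders")
  set.seed(seed)
  id <- function(g, i) sprintf("G%d_%04d", g, i)
  sex0 <- rep(c("M", "F"), length.out = n_founders)
  ped <- tibble(animal = id(0, seq_len(n_founders)),
                sire = NA_character_, dam = NA_character_, sex = sex0)
  prev <- ped
  for (g in seq_len(n_generations)) {
    sires <- prev$animal[prev$sex == "M"]
    sires <- sample(sires, max(2, ceiling(sire_fraction * length(sires))))
    dams <- prev$animal[prev$sex == "F"]
    if (!length(sires) || !length(dams)) {
      abort("a generation ran out of sires or dams; increase n_founders")
    }
    n_off <- length(dams) * litters_per_dam
    off <- tibble(animal = id(g, seq_len(n_off)),
                  sire = sample(sires, n_off, replace = TRUE),
                  dam = rep(dams, each = litters_per_dam),
                  sex = sample(c("M", "F"), n_off, replace = TRUE))
    ped <- dplyr::bind_rows(ped, off)
    prev <- off
  }
  out <- as_pedigree(ped[c("animal", "sire", "dam")])
  out$sex <- ped$sex[match(out$animal, ped$animal)]
  out
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder gametes carry alleles drawn at per-SNP frequencies uniform in
#' `maf_range`; descendants inherit one random gamete from each parent
#' (Mendelian sampling), so parent-offspring genotypes are consistent by
#' construction. Optionally a subset of SNPs is planted as mean QTL and as
#' variance QTL (vQTL); their (centred) dosage effects are later added to the
#' additive genetic values of the mean part and of the log-variance part
#' respectively.
#'
#' @param ped A pedigree from [simulate_pedigree()] / [as_pedigree()].
#' @param n_snps Number of SNPs.
#' @param maf_range Range (within (0, 0.5]) for founder allele frequencies.
#' @param n_qtl,n_vqtl Number of planted mean QTL and variance QTL.
#' @param qtl_var Total additive variance (trait units squared) jointly
#'   explained by the planted mean QTL at founder frequencies.
#' @param vqtl_var Total variance on the log residual-variance scale jointly
#'   explained by the planted vQTL.
#' @param n_chrom Number of chromosome labels to spread SNPs over.
#' @param seed Integer seed.
#' @return A list with `genotypes` (animals x SNPs integer dosage matrix with
#'   dimnames), `map` (tibble `snp, chrom, pos, score`), and `qtl` (tibble
#'   `snp, part, effect, freq`); `part` is `"mean"` or `"var"`.
#' @export
simulate_genotypes <- function(ped, n_snps = 1000, maf_range = c(0.1, 0.5),
                               n_qtl = 0, n_vqtl = 0, qtl_var = 0, vqtl_var = 0,
                               n_chrom = 18, seed = 1) {
  if (!inherits(ped, "ped_tbl")) ped <- as_pedigree(ped)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("maf_range must lie within (0, 0.5]")
  }
  if (n_qtl + n_vqtl > n_snps) abort("n_qtl + n_vqtl must not exceed n_snps")
  set.seed(seed)
  n <- nrow(ped)
  pidx <- ped_indices(ped)
  p <- runif(n_snps, maf_range[1], maf_range[2])
  H1 <- matrix(0L, n, n_snps); H2 <- matrix(0L, n, n_snps)
  for (i in seq_len(n)) {
    s <- pidx$sire[i]; d <- pidx$dam[i]
    H1[i, ] <- if (s == 0) as.integer(runif(n_snps) < p) else
      ifelse(runif(n_snps) < 0.5, H1[s, ], H2[s, ])
    H2[i, ] <- if (d == 0) as.integer(runif(n_snps) < p) else
      ifelse(runif(n_snps) < 0.5, H1[d, ], H2[d, ])
  }
  G <- H1 + H2
  snp_ids <- sprintf("SNP%05d", seq_len(n_snps))
  dimnames(G) <- list(ped$animal, snp_ids)
  map <- tibble(snp = snp_ids,
                chrom = as.character(rep_len(seq_len(n_chrom), n_snps)),
                pos = as.integer(seq(1e5, 2e8, length.out = n_snps)),
                score = 1.0)
  qtl_idx <- sample.int(n_snps, n_qtl + n_vqtl)
  qtl <- tibble(snp = character(), part = character(),
                effect = numeric(), freq = numeric())
  mk_effects <- function(idx, total_var) {
    v2pq <- 2 * p[idx] * (1 - p[idx])
    b <- sqrt(total_var / length(idx) / v2pq) * sample(c(-1, 1), length(idx), TRUE)
    tibble(snp = snp_ids[idx], effect = b, freq = p[idx])
  }
  if (n_qtl > 0) {
    qtl <- dplyr::bind_rows(qtl, dplyr::mutate(
      mk_effects(qtl_idx[seq_len(n_qtl)], qtl_var), part = "mean"))
  }
  if (n_vqtl > 0) {
    qtl <- dplyr::bind_rows(qtl, dplyr::mutate(
      mk_effects(qtl_idx[n_qtl + seq_len(n_vqtl)], vqtl_var), part = "var"))
  }
  list(genotypes = G, map = map, qtl = qtl[c("snp", "part", "effect", "freq")])
}

# correlated (mean, variance-part) effects over the pedigree by Mendelian
# sampling: u_i = (u_s + u_d)/2 + m_i, m_i ~ N(0, d_i * G2), giving
# (u, u_v) ~ N(0, G2 kron A) exactly
sim_genetic_values <- function(ped, G2) {
  pidx <- ped_indices(ped)
  inb <- cpp_inbreeding(pidx$sire, pidx$dam)
  n <- nrow(ped)
  Lc <- chol(G2) # upper triangular
  U <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    s <- pidx$sire[i]; d <- pidx$dam[i]
    pa <- c(0, 0)
    if (s > 0) pa <- pa + 0.5 * U[s, ]
    if (d > 0) pa <- pa + 0.5 * U[d, ]
    U[i, ] <- pa + sqrt(inb$d[i]) * drop(rnorm(2) %*% Lc)
  }
  dimnames(U) <- list(ped$animal, c("u", "u_v"))
  U
}

#' Simulate repeated litter records under the mean + log-variance model
#'
#' Phenotypes follow
#' \deqn{y_{ij} = \mu + parity_j + fys_{ij} + a_i + pe_i + e_{ij},\quad
#'       e_{ij} \sim N(0, \exp(\eta_i)),\quad
#'       \eta_i = \mu_v + a_{v,i} + pe_{v,i},}
#' with \eqn{(a, a_v)} drawn jointly over the pedigree relationship structure
#' with correlation `r_a`, and \eqn{(pe, pe_v)} jointly per sow with
#' correlation `r_pe`. If planted QTL are supplied, their centred dosage
#' effects are added to \eqn{a} (mean QTL) and \eqn{a_v} (vQTL), on top of
#' the polygenic values.
#'
#' @param ped Pedigree; records are generated for females of the last
#'   generation ("sows").
#' @param params A [sim_params()] list.
#' @param genotypes Optional result of [simulate_genotypes()] carrying
#'   planted QTL.
#' @param parities_per_sow Either a single parity count per sow or a range
#'   `c(min, max)` sampled uniformly per sow.
#' @param n_fys_classes Number of farm-year-season classes, assigned randomly
#'   per litter.
#' @param integer_tnb If `TRUE`, round phenotypes to integer counts and
#'   truncate at 0 (mimicking recorded total-number-born values); default
#'   keeps them continuous.
#' @param seed Integer seed.
#' @return A list with `records` (tibble `sow, parity, fys, tnb`), `truth`
#'   (tibble of per-animal true `a`, `a_v` and per-sow `pe`, `pe_v`),
#'   `params`, and `fixed_effects` (the drawn parity and fys values).
#' @export
simulate_phenotypes <- function(ped, params = sim_params(), genotypes = NULL,
                                parities_per_sow = 5, n_fys_classes = 20,
                                integer_tnb = FALSE, seed = 1) {
  if (!inherits(ped, "ped_tbl")) ped <- as_pedigree(ped)
  set.seed(seed)
  pr <- params
  Ga <- matrix(c(pr$sigma2_a, rep(pr$r_a * sqrt(pr$sigma2_a * pr$sigma2_av), 2),
                 pr$sigma2_av), 2)
  Gpe <- matrix(c(pr$sigma2_pe, rep(pr$r_pe * sqrt(pr$sigma2_pe * pr$sigma2_pev), 2),
                  pr$sigma2_pev), 2)
  if (det(Ga) < 0 || det(Gpe) < 0) abort("requested covariance is not positive semidefinite")
  U <- sim_genetic_values(ped, Ga)
  a <- U[, 1]; a_v <- U[, 2]
  if (!is.null(genotypes) && nrow(genotypes$qtl)) {
    for (part in c("mean", "var")) {
      q <- genotypes$qtl[genotypes$qtl$part == part, ]
      if (!nrow(q)) next
      X <- genotypes$genotypes[ped$animal, q$snp, drop = FALSE]
      add <- drop(sweep(X, 2, 2 * q$freq) %*% q$effect)
      if (part == "mean") a <- a + add else a_v <- a_v + add
    }
  }
  sows <- ped$animal[ped$sex == "F" & ped$generation == max(ped$generation)]
  if (!length(sows)) sows <- ped$animal[ped$generation == max(ped$generation)]
  ns <- length(sows)
  PE <- matrix(rnorm(2 * ns), ns) %*% chol(Gpe)
  parity_eff <- rnorm(10, 0, sqrt(pr$sigma2_parity))
  fys_eff <- rnorm(n_fys_classes, 0, sqrt(pr$sigma2_fys))
  npar <- if (length(parities_per_sow) == 2) {
    sample(parities_per_sow[1]:parities_per_sow[2], ns, replace = TRUE)
  } else rep(parities_per_sow, ns)
  sow_i <- rep(seq_len(ns), npar)
  parity <- unlist(lapply(npar, seq_len))
  fys <- sample.int(n_fys_classes, length(sow_i), replace = TRUE)
  eta <- pr$mu_v + a_v[sows][sow_i] + PE[sow_i, 2]
  yy <- pr$mu + parity_eff[pmin(parity, 10)] + fys_eff[fys] +
    a[sows][sow_i] + PE[sow_i, 1] + rnorm(length(sow_i), 0, sqrt(exp(eta)))
  if (integer_tnb) yy <- pmax(0, round(yy))
  records <- tibble(sow = sows[sow_i], parity = parity,
                    fys = paste0("fys", fys), tnb = yy)
  truth <- tibble(animal = ped$animal, a = a, a_v = a_v,
                  pe = ifelse(ped$animal %in% sows,
                              PE[match(ped$animal, sows), 1], NA_real_),
                  pe_v = ifelse(ped$animal %in% sows,
                                PE[match(ped$animal, sows), 2], NA_real_))
  list(records = records, truth = truth, params = pr,
       fixed_effects = list(parity = parity_eff, fys = fys_eff), seed = seed)
}
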
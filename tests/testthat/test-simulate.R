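test_that("pedigree simulation is reproducible, generational, and drifts", {
  p0 <- simulate_pedigree(n_founders = 20, n_generations = 0, seed = TEST_SEED)
  expect_equal(nrow(p0), 20)
  expect_true(all(compute_inbreeding(p0)$f == 0))
  p1 <- simulate_pedigree(n_founders = 60, n_generations = 4,
                          litters_per_dam = 2, seed = TEST_SEED)
  p2 <- simulate_pedigree(n_founders = 60, n_generations = 4,
                          litters_per_dam = 2, seed = TEST_SEED)
  expect_identical(p1, p2)
  # small population with sire reuse accumulates inbreeding
  expect_gt(mean(compute_inbreeding(p1)$f), 0)
  # parents precede offspring after topological ordering
  idx <- stats::setNames(seq_len(nrow(p1)), p1$animal)
  ok <- is.na(p1$sire) | idx[p1$sire] < idx[p1$animal]
  expect_true(all(ok))
})

test_that("founder allele frequencies and Hardy-Weinberg proportions hold", {
  ped <- simulate_pedigree(n_founders = 400, n_generations = 0,
                           seed = TEST_SEED)
  g <- simulate_genotypes(ped, n_snps = 200, maf_range = c(0.2, 0.4),
                          seed = TEST_SEED)
  G <- g$genotypes
  phat <- colMeans(G) / 2
  expect_true(all(phat > 0.2 - 3 * sqrt(0.4 * 0.6 / 800) - 0.02))
  expect_true(all(phat < 0.4 + 3 * sqrt(0.4 * 0.6 / 800) + 0.02))
  # chi-square HW test at alpha = 0.01: about the nominal rejection rate
  pvals <- apply(G, 2, function(x) {
    p <- mean(x) / 2
    e <- 400 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    o <- tabulate(x + 1, 3)
    stats::pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
  })
  expect_lt(mean(pvals < 0.01), 0.05)
  expect_error(simulate_genotypes(ped, 10, maf_range = c(0, 0.6)), "maf_range")
  expect_error(simulate_genotypes(ped, 10, n_qtl = 8, n_vqtl = 8), "exceed")
})

test_that("joint genetic values reproduce the requested covariance over A", {
  ped <- simulate_pedigree(n_founders = 50, n_generations = 2,
                           litters_per_dam = 2, sire_fraction = 0.2,
                           seed = TEST_SEED)
  A <- build_relationship(ped)
  G2 <- matrix(c(1.2, 0.4, 0.4, 0.6), 2)
  set.seed(TEST_SEED)
  nrep <- 400
  cc <- matrix(0, 2, 2); va <- 0
  for (r in seq_len(nrep)) {
    U <- vargwas:::sim_genetic_values(ped, G2)
    cc <- cc + crossprod(U) / nrow(U)
    va <- va + var(U[, 1])
  }
  cc <- cc / nrep
  # E[U'U]/n = G2 * mean(diag(A))
  expect_equal(cc, G2 * mean(diag(A)), tolerance = 0.08, ignore_attr = TRUE)
})

test_that("phenotypes obey the log-linear dispersion model", {
  ped <- simulate_pedigree(n_founders = 600, n_generations = 1,
                           litters_per_dam = 2, seed = TEST_SEED)
  pr <- sim_params(sigma2_av = 0.2, sigma2_pev = 0.1, r_a = 0, r_pe = 0)
  sim <- simulate_phenotypes(ped, pr, parities_per_sow = 6, seed = TEST_SEED)
  # lognormal moment identity for the mean residual variance
  sows <- unique(sim$records$sow)
  tr <- sim$truth[match(sows, sim$truth$animal), ]
  eta <- pr$mu_v + tr$a_v + tr$pe_v
  expect_equal(mean(exp(eta)),
               exp(pr$mu_v + 0.5 * (pr$sigma2_av + pr$sigma2_pev)),
               tolerance = 0.15)
  # empirical within-sow variance matches exp(eta) per sow on average
  wv <- tapply(sim$records$tnb, sim$records$sow, var)
  fit <- lm(log(wv[sows]) ~ eta)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.25)
  # determinism
  sim2 <- simulate_phenotypes(ped, pr, parities_per_sow = 6, seed = TEST_SEED)
  expect_identical(sim$records, sim2$records)
})

test_that("homogeneous simulation rejects a dispersion test at the nominal rate", {
  ped <- simulate_pedigree(n_founders = 400, n_generations = 1,
                           litters_per_dam = 2, seed = TEST_SEED)
  pr <- sim_params(sigma2_av = 1e-12, sigma2_pev = 1e-12, r_a = 0, r_pe = 0)
  sim <- simulate_phenotypes(ped, pr, parities_per_sow = 8, seed = TEST_SEED)
  # Bartlett-type test of equal within-sow variances across random sow pairs
  rec <- sim$records
  sows <- unique(rec$sow)
  set.seed(TEST_SEED)
  rej <- vapply(seq_len(200), function(i) {
    pick <- sample(sows, 2)
    a <- rec$tnb[rec$sow == pick[1]]; b <- rec$tnb[rec$sow == pick[2]]
    stats::var.test(a - mean(a), b - mean(b))$p.value < 0.05
  }, TRUE)
  expect_lt(mean(rej), 0.12)
})

test_that("planted QTL enter the intended model part with the requested variance", {
  ped <- simulate_pedigree(n_founders = 500, n_generations = 0,
                           seed = TEST_SEED)
  g <- simulate_genotypes(ped, n_snps = 100, n_qtl = 4, n_vqtl = 3,
                          qtl_var = 0.4, vqtl_var = 0.02, seed = TEST_SEED)
  expect_equal(sum(g$qtl$part == "mean"), 4)
  expect_equal(sum(g$qtl$part == "var"), 3)
  q <- g$qtl[g$qtl$part == "mean", ]
  planted <- sum(q$effect^2 * 2 * q$freq * (1 - q$freq))
  expect_equal(planted, 0.4, tolerance = 1e-9)
  # genetic values with QTL carry the extra variance
  pr <- sim_params(sigma2_a = 0.5, sigma2_av = 0.01, r_a = 0, r_pe = 0)
  sim <- simulate_phenotypes(ped, pr, genotypes = g, parities_per_sow = 2,
                             seed = TEST_SEED)
  expect_equal(var(sim$truth$a), 0.5 + 0.4, tolerance = 0.15)
})
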
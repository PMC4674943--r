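test_that("Bayes factor is posterior odds over prior odds", {
  expect_equal(bayes_factor(0.001, 0.001), 1)     # posterior = prior
  expect_equal(bayes_factor(0.0292, 0.001),
               (0.0292 / 0.9708) / (0.001 / 0.999))
  expect_equal(round(bayes_factor(0.0292, 0.001), 1), 30.0, tolerance = 0.01)
  expect_equal(bayes_factor(0, 0.001), 0)
  expect_warning(bf1 <- bayes_factor(1, 0.001), "infinite")
  expect_true(is.infinite(bf1))
  # strictly increasing in p_hat
  p <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(bayes_factor(p, 0.001)) > 0))
})

test_that("significance labels follow the 30/150 thresholds", {
  expect_equal(as.character(classify_bf(c(29.9, 36.6, 295.5, 150))),
               c("not significant", "very strong", "decisive", "decisive"))
})

test_that("allele substitution effect inverts the genic variance", {
  expect_equal(allele_substitution_effect(0, 0.3), 0)
  # algebraic inversion of a published-style row: alpha 0.105 at p = 0.26
  v <- 0.105^2 * 2 * 0.26 * 0.74
  expect_equal(allele_substitution_effect(v, 0.26), 0.105)
  expect_equal(allele_substitution_effect(v, 0.74),
               allele_substitution_effect(v, 0.26))
  expect_error(allele_substitution_effect(1, 0), "strictly")
})

test_that("variance explained normalizes to 100 over its own total", {
  expect_equal(round(variance_explained(0.105, 0.26, 1.18), 2), 0.36)
  expect_equal(variance_explained(0, 0.3, 1), 0)
  set.seed(TEST_SEED)
  b <- rnorm(20); p <- runif(20, 0.05, 0.95)
  tot <- sum(2 * p * (1 - p) * b^2)
  expect_equal(sum(variance_explained(b, p, tot)), 100)
  expect_error(variance_explained(1, 0.5, 0), "positive")
})

test_that("Gelman-Rubin diagnostic behaves on constructed chains", {
  expect_equal(gelman_rubin(list(1:100, 1:100)), 1, tolerance = 0.06)
  # disjoint means, small within-variance
  set.seed(TEST_SEED)
  div <- list(rnorm(500, 0, 0.1), rnorm(500, 5, 0.1))
  expect_gt(gelman_rubin(div), 1.1)
  wn <- list(rnorm(10000), rnorm(10000))
  expect_gte(gelman_rubin(wn), 0.99)
  expect_lt(gelman_rubin(wn), 1.05)
  expect_error(gelman_rubin(list(rnorm(10))), "2 chains")
  # cross-check against the classic implementation
  if (requireNamespace("coda", quietly = TRUE)) {
    ch <- list(rnorm(2000, 0, 1), rnorm(2000, 0.15, 1.1))
    ml <- coda::mcmc.list(coda::mcmc(ch[[1]]), coda::mcmc(ch[[2]]))
    ref <- coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1]
    expect_equal(gelman_rubin(ch), ref, tolerance = 0.02)
  }
})

test_that("sampler is reproducible, calibrated on null data, and finds a planted QTL", {
  set.seed(TEST_SEED)
  n <- 250; p <- 400
  freq <- runif(p, 0.1, 0.5)
  X <- sapply(freq, function(q) rbinom(n, 2, q))
  colnames(X) <- sprintf("s%03d", seq_len(p))
  rownames(X) <- sprintf("a%03d", seq_len(n))
  y <- rnorm(n)
  debv <- tibble::tibble(animal = rownames(X), debv = y, weight = 1)
  cfg <- bvs_config(pi1 = 0.005, n_iter = 20000, burnin_frac = 0.25,
                    seed = TEST_SEED)
  f1 <- run_bvs(debv, X, cfg)
  f2 <- run_bvs(debv, X, cfg)
  expect_identical(tidy(f1)$pip, tidy(f2)$pip)   # exact seed reproducibility
  expect_lt(mean(tidy(f1)$bf >= 30), 0.005)      # null calibration
  # mean count in the large component tracks pi1 * p
  expect_lt(abs(glance(f1)$mean_n_large - cfg$pi1 * p) / (cfg$pi1 * p), 0.2)
  # planted SNP explaining ~15% of variance is found decisively
  yq <- y + (X[, 42] - mean(X[, 42])) * sqrt(0.15 * var(y) /
                                               (1 - 0.15) / var(X[, 42]))
  cfgq <- bvs_config(pi1 = 0.005, n_iter = 5000, burnin_frac = 0.25,
                     seed = TEST_SEED)
  fq <- suppressWarnings(run_bvs(dplyr::mutate(debv, debv = yq), X, cfgq))
  expect_equal(which.max(tidy(fq)$pip), 42L)
  expect_gte(tidy(fq)$bf[42], 30)
  # a looser prior finds the same top SNP
  fq2 <- suppressWarnings(run_bvs(dplyr::mutate(debv, debv = yq), X,
                                  bvs_config(pi1 = 0.001, n_iter = 5000,
                                             burnin_frac = 0.25, mh_step = 0.004,
                                             seed = TEST_SEED)))
  expect_equal(which.max(tidy(fq2)$pip), 42L)
})

test_that("pi1 = 1 reduces to always-included shrinkage regression", {
  set.seed(TEST_SEED)
  X <- matrix(rbinom(100 * 20, 2, 0.4), 100, 20,
              dimnames = list(sprintf("a%d", 1:100), sprintf("s%d", 1:20)))
  debv <- tibble::tibble(animal = rownames(X), debv = rnorm(100), weight = 1)
  f <- run_bvs(debv, X, bvs_config(pi1 = 1, n_iter = 500, burnin_frac = 0.2,
                                   seed = TEST_SEED))
  expect_true(all(tidy(f)$pip == 1))
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rbinom(200, 2, 0.4), 50, 4,
              dimnames = list(sprintf("a%d", 1:50), sprintf("s%d", 1:4)))
  X[, 2] <- 1
  debv <- tibble::tibble(animal = rownames(X), debv = rnorm(50), weight = 1)
  expect_error(run_bvs(debv, X, bvs_config(n_iter = 100)), "constant SNP")
  X[, 2] <- rbinom(50, 2, 0.4)
  expect_error(run_bvs(dplyr::mutate(debv, debv = replace(debv, 1, NA)),
                       X, bvs_config(n_iter = 100)), "non-finite")
})
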
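test_that("mixed-model equations reproduce dense generalized least squares", {
  set.seed(TEST_SEED)
  n <- 30
  ped <- tibble::tibble(
    animal = as.character(1:12),
    sire = c(rep(NA, 4), "1", "1", "3", "3", "5", "5", "7", "7"),
    dam = c(rep(NA, 4), "2", "2", "4", "4", "6", "6", "8", "8"))
  A <- build_relationship(ped)
  dat <- tibble::tibble(animal = as.character(sample(1:12, n, TRUE)),
                        sow = as.character(sample(1:8, n, TRUE)),
                        grp = sample(c("a", "b"), n, TRUE),
                        w = runif(n, 0.5, 2),
                        y = rnorm(n, 10, 2))
  des <- mixed_design(dat, "y", fixed = "grp", genetic = "animal",
                      pedigree = ped, permanent = "sow", weights = "w")
  fit <- solve_mme(des, list(G = list(a = matrix(1.5), pe = matrix(0.8)),
                             sigma_e = 2.5))
  ids <- des$terms$a$level_ids
  Za <- stats::model.matrix(~ 0 + factor(animal, levels = ids), dat)
  sows <- des$terms$pe$level_ids
  Zp <- stats::model.matrix(~ 0 + factor(sow, levels = sows), dat)
  X <- stats::model.matrix(~ grp, dat)
  V <- 1.5 * Za %*% A[ids, ids] %*% t(Za) + 0.8 * tcrossprod(Zp) +
    diag(2.5 / dat$w)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% dat$y)
  ua <- 1.5 * A[ids, ids] %*% t(Za) %*% Vi %*% (dat$y - X %*% b)
  up <- 0.8 * t(Zp) %*% Vi %*% (dat$y - X %*% b)
  expect_equal(fit$fixef$estimate, drop(b), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fit$ranef$a$value, drop(ua), tolerance = 1e-9,
               ignore_attr = TRUE)
  # leverage = diagonal of the observation-to-fitted-value influence map
  M <- cbind(X, Za, Zp)
  Ri <- diag(dat$w / 2.5)
  Cd <- t(M) %*% Ri %*% M
  ia <- 2 + seq_along(ids); ip <- max(ia) + seq_along(sows)
  Cd[ia, ia] <- Cd[ia, ia] + solve(A[ids, ids]) / 1.5
  Cd[ip, ip] <- Cd[ip, ip] + diag(length(sows)) / 0.8
  Cin <- solve(Cd)
  expect_equal(fit$leverage, diag(M %*% Cin %*% t(M) %*% Ri),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit$ranef$a$se, sqrt(diag(Cin)[ia]), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(fit$leverage >= 0 & fit$leverage < 1))
  expect_equal(sum(fit$leverage), sum(diag(M %*% Cin %*% t(M) %*% Ri)),
               tolerance = 1e-9)
})

test_that("intercept-only model has leverage 1/n and EBVs vanish as sigma2_a -> 0", {
  set.seed(TEST_SEED)
  dat <- tibble::tibble(y = rnorm(20, 5), animal = sprintf("a%d", 1:20))
  des0 <- mixed_design(dat, "y", genetic = NULL)
  f0 <- solve_mme(des0, list(G = list(), sigma_e = 1))
  expect_equal(f0$leverage, rep(1 / 20, 20))
  des1 <- mixed_design(dat, "y", genetic = "animal", pedigree = NULL)
  f1 <- solve_mme(des1, list(G = list(a = matrix(1e-9)), sigma_e = 1))
  expect_lt(max(abs(f1$ranef$a$value)), 1e-8)
})

test_that("REML equals ANOVA closed forms on a balanced design", {
  set.seed(TEST_SEED)
  s <- 30; k <- 10
  sire <- rep(sprintf("s%02d", 1:s), each = k)
  y <- 12 + rnorm(s, 0, sqrt(2))[match(sire, unique(sire))] +
    rnorm(s * k, 0, sqrt(6))
  dat <- tibble::tibble(sire = sire, y = y)
  fit <- estimate_reml(mixed_design(dat, "y", genetic = "sire",
                                    pedigree = NULL))
  msb <- k * var(tapply(y, sire, mean))
  msw <- sum((y - ave(y, sire))^2) / (s * (k - 1))
  expect_equal(fit$G$a[1, 1], (msb - msw) / k, tolerance = 1e-6)
  expect_equal(fit$sigma_e, msw, tolerance = 1e-6)
})

test_that("REML is invariant to record order and matches a dense oracle bivariately", {
  set.seed(TEST_SEED)
  ped <- simulate_pedigree(n_founders = 40, n_generations = 2,
                           litters_per_dam = 2, sire_fraction = 0.3,
                           seed = TEST_SEED)
  n <- nrow(ped)
  Ga <- matrix(c(1.2, 0.5 * sqrt(0.72), 0.5 * sqrt(0.72), 0.6), 2)
  U <- vargwas:::sim_genetic_values(ped, Ga)
  dat <- tibble::tibble(animal = ped$animal,
                        y1 = 10 + U[, 1] + rnorm(n, 0, sqrt(2)),
                        y2 = 5 + U[, 2] + rnorm(n, 0, sqrt(1.5)))
  fit <- estimate_reml(mixed_design(dat, c("y1", "y2"), genetic = "animal",
                                    pedigree = ped),
                       on_nonconvergence = "warn")
  # permuting records leaves the estimates unchanged
  datp <- dat[sample(nrow(dat)), ]
  fitp <- estimate_reml(mixed_design(datp, c("y1", "y2"), genetic = "animal",
                                     pedigree = ped),
                        on_nonconvergence = "warn")
  expect_equal(fit$G$a, fitp$G$a, tolerance = 1e-5)
  expect_equal(fit$sigma_e, fitp$sigma_e, tolerance = 1e-5)
  # dense derivative-free REML oracle on the same data
  A <- build_relationship(ped)[dat$animal, dat$animal]
  X <- as.matrix(Matrix::bdiag(matrix(1, n, 1), matrix(1, n, 1)))
  yy <- c(dat$y1, dat$y2)
  nll <- function(th) {
    Lc <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2)
    G <- Lc %*% t(Lc); se <- exp(th[4:5])
    V <- kronecker(G, A) + diag(rep(se, each = n))
    cv <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cv)) return(1e10)
    Vi <- chol2inv(cv)
    XtVi <- t(X) %*% Vi
    b <- solve(XtVi %*% X, XtVi %*% yy)
    r <- yy - X %*% b
    0.5 * (2 * sum(log(diag(cv))) + determinant(XtVi %*% X)$modulus +
             t(r) %*% Vi %*% r)
  }
  o <- stats::optim(c(0, 0.3, -0.5, 0.7, 0.4), nll, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-12))
  Lc <- matrix(c(exp(o$par[1]), o$par[2], 0, exp(o$par[3])), 2)
  Gor <- Lc %*% t(Lc)
  expect_equal(fit$G$a, Gor, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(fit$sigma_e, exp(o$par[4:5]), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("degenerate designs error informatively", {
  dat <- tibble::tibble(y = rep(1, 10), animal = sprintf("a%d", 1:10),
                        g1 = rep(c("u", "v"), 5), g2 = rep(c("u", "v"), 5))
  expect_error(mixed_design(dat, "y", genetic = "animal", pedigree = NULL),
               "zero empirical variance")
  dat$y <- rnorm(10)
  expect_error(mixed_design(dat, "y", fixed = c("g1", "g2"),
                            genetic = "animal", pedigree = NULL),
               "rank deficient")
  expect_error(suppressWarnings(
    mixed_design(dat, "y", genetic = "animal", pedigree = NULL,
                 weights = "g1")),
    "weights|NAs")
})

test_that("heritability and covariance identities evaluate exactly", {
  expect_equal(round(heritability(1.31, 0.87, 7.14), 2), 0.14)
  expect_equal(round(heritability(1.18, 0.69, 6.5), 2), 0.14)
  expect_equal(heritability(0, 0.5, 2), 0)
  expect_error(heritability(0, 0, 0), "total variance")
  expect_equal(round(covariance_from_correlation(-0.83, 0.69, 0.15), 2), -0.27)
  expect_equal(covariance_from_correlation(0, 3, 9), 0)
  expect_equal(covariance_from_correlation(1, 4, 9), 6)
  expect_error(covariance_from_correlation(1.2, 1, 1), "r")
  expect_error(covariance_from_correlation(0.5, -1, 1), "variances")
})

test_that("conventional bivariate analysis recovers a known genetic correlation", {
  set.seed(TEST_SEED)
  ped <- simulate_pedigree(n_founders = 500, n_generations = 2,
                           litters_per_dam = 3, seed = TEST_SEED + 4)
  sim <- simulate_phenotypes(ped, sim_params(sigma2_a = 1.2, sigma2_av = 0.08,
                                             r_a = 0.6, sigma2_pe = 0.5,
                                             sigma2_pev = 0.1, r_pe = -0.5),
                             parities_per_sow = 7, seed = TEST_SEED + 5)
  sm <- summarize_sows(edit_records(sim$records))
  fit <- fit_conventional_bivariate(sm, ped, on_nonconvergence = "warn")
  td <- tidy(fit)
  r_a <- td$estimate[td$component == "r_a"]
  se_r <- td$se[td$component == "r_a"]
  expect_lt(abs(r_a - 0.6), 2 * se_r)
  # constant weights are absorbed into the residual scale: same G, scaled
  # residual variances
  sm2 <- dplyr::mutate(sm, n_litters = 5)
  f_w <- fit_conventional_bivariate(sm2, ped, on_nonconvergence = "warn")
  des_u <- mixed_design(sm2, c("mean_tnb", "log_var_tnb"), fixed = "fys",
                        genetic = "sow", pedigree = ped)
  f_u <- estimate_reml(des_u, on_nonconvergence = "warn")
  expect_equal(f_w$G$a, f_u$G$a, tolerance = 5e-3, ignore_attr = TRUE)
  expect_equal(f_w$sigma_e * c(1 / 5, 1 / 2), f_u$sigma_e, tolerance = 5e-3)
})
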
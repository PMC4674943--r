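test_that("working response matches the first-order linearization", {
  # identity case of the expansion
  expect_equal(working_response(sqrt(0.7 * 3), 0.3, 3), log(3))
  expect_equal(working_response(0, 0.2, 2), log(2) - 1)
  expect_equal(working_response(sqrt(3), 0, 1), 2)
  expect_error(working_response(1, 1, 1), "leverage")
  expect_error(working_response(1, 0.5, 0), "positive")
})

test_that("iteration weights are the stated reciprocals", {
  w <- update_weights(c(0, log(4)), c(0, 0.5))
  expect_equal(w$w, c(1, 0.25))
  expect_equal(w$w_v, c(0.5, 0.25))
  expect_error(update_weights(0, 1), "leverage")
})

test_that("GCV_SDe is half the genetic SD in residual variance", {
  expect_equal(round(gcv_sde(0.03), 3), 0.087)
  expect_equal(gcv_sde(0), 0)
  expect_equal(gcv_sde(0.04), 0.1)
  expect_error(gcv_sde(-0.1), ">= 0")
})

test_that("h_v2 formula evaluates literally and is monotone in sigma2_av", {
  expect_equal(h2_residual_variance(0, 0.15, 8.37), 0)
  expect_equal(h2_residual_variance(0.03, 0.15, 8.37),
               0.03 / (2 * 8.37^2 + 3 * (0.03 + 0.15)))
  expect_equal(round(h2_residual_variance(0.03, 0.15, 8.37), 6), 2.13e-4,
               tolerance = 0.01)
  vals <- vapply(seq(0, 0.1, by = 0.02), h2_residual_variance,
                 0, sigma2_pev = 0.15, sigma2_P = 8.37)
  expect_true(all(diff(vals) > 0))
  expect_error(h2_residual_variance(0, 0, 0), "zero")
})

test_that("one manual iteration equals the hand-assembled weighted bivariate fit", {
  sm <- small_sim(n_founders = 120, n_generations = 2, parities = 4)
  rec <- sm$sim$records
  # by hand: univariate fit, working response, one weighted bivariate REML
  des_uni <- mixed_design(rec, "tnb", fixed = c("parity", "fys"),
                          genetic = "sow", pedigree = sm$ped, permanent = "sow")
  f0 <- estimate_reml(des_uni, on_nonconvergence = "warn")
  psi <- working_response(f0$residuals, f0$leverage, rep(f0$sigma_e, nrow(rec)))
  rec2 <- dplyr::mutate(rec, psi = psi, w = rep(1 / f0$sigma_e, nrow(rec)),
                        wv = (1 - f0$leverage) / 2)
  des_bi <- mixed_design(rec2, c("tnb", "psi"), fixed = c("parity", "fys"),
                         genetic = "sow", pedigree = sm$ped, permanent = "sow",
                         weights = c("w", "wv"))
  start <- list(G = list(a = diag(c(f0$G$a[1, 1], 0.01)),
                         pe = diag(c(f0$G$pe[1, 1], 0.01))),
                sigma_e = c(1, 1))
  f_hand <- estimate_reml(des_bi, start = start, on_nonconvergence = "warn")
  # package path, stopped after the first bivariate fit
  dh <- suppressWarnings(run_dhglm(rec, sm$ped, max_iter = 1,
                                   refit_univariate = FALSE))
  expect_equal(dh$trace[[1]],
               vargwas:::params_pack(f_hand$G, f_hand$sigma_e, 2),
               tolerance = 1e-6)
})

test_that("homogeneous-variance data give a near-zero genetic dispersion variance", {
  sm <- small_sim(n_founders = 240, n_generations = 2, parities = 5,
                  params = sim_params(sigma2_a = 1.2, sigma2_av = 1e-10,
                                      r_a = 0, sigma2_pe = 0.7,
                                      sigma2_pev = 1e-10, r_pe = 0))
  dh <- suppressWarnings(run_dhglm(sm$sim$records, sm$ped, max_iter = 15,
                                   refit_univariate = FALSE))
  td <- tidy(dh)
  sav2 <- td$estimate[td$component == "sigma2_a_.psi"]
  expect_lt(sav2, 0.005)
  # r_a indistinguishable from zero: its genetic covariance within 2 SEs of 0
  cov_a <- td$estimate[td$component == "cov_a_tnb_.psi"]
  se_cov <- td$se[td$component == "cov_a_tnb_.psi"]
  expect_lt(abs(cov_a), 2 * se_cov + 1e-8)
})

test_that("doubling deviations shifts the dispersion intercept by log 4", {
  sm <- small_sim(n_founders = 150, n_generations = 2, parities = 4)
  rec <- sm$sim$records
  mu <- mean(rec$tnb)
  rec2 <- dplyr::mutate(rec, tnb = mu + 2 * (tnb - mu))
  dh1 <- suppressWarnings(run_dhglm(rec, sm$ped, max_iter = 8,
                                    refit_univariate = FALSE))
  dh2 <- suppressWarnings(run_dhglm(rec2, sm$ped, max_iter = 8,
                                    refit_univariate = FALSE))
  # mean predicted residual variance scales by 4 ...
  expect_equal(mean(dh2$psi_hat) - mean(dh1$psi_hat), log(4), tolerance = 0.1)
  # ... while the genetic mean-dispersion correlation is scale-free
  r1 <- glance(dh1)$r_a
  r2 <- glance(dh2)$r_a
  expect_equal(r1, r2, tolerance = 0.15)
})

test_that("scaling variances sit near one and the standardized residuals are calibrated", {
  sm <- small_sim(n_founders = 240, n_generations = 2, parities = 5)
  dh <- suppressWarnings(run_dhglm(sm$sim$records, sm$ped, max_iter = 15,
                                   refit_univariate = FALSE))
  expect_gt(dh$fit$sigma_e[1], 0.8)
  expect_lt(dh$fit$sigma_e[1], 1.2)
  calib <- mean(dh$residuals^2 / ((1 - dh$leverage) * exp(dh$psi_hat)))
  expect_gt(calib, 0.9)
  expect_lt(calib, 1.1)
})
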
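#' Linearized working response for the log residual variance
#'
#' First-order Taylor linearization of `log(e^2/(1-h))` around the current
#' predicted residual variance `s2`:
#' \deqn{\psi = \log(s2) + (e^2/(1-h) - s2)/s2.}
#'
#' @param e Residual of the mean part.
#' @param h Leverage (hat-matrix diagonal) in `[0, 1)`.
#' @param s2 Predicted residual variance (> 0).
#' @return The working response, one value per record.
#' @export
working_response <- function(e, h, s2) {
  if (any(h < 0 | h >= 1)) abort("leverage must lie in [0, 1)")
  if (any(s2 <= 0)) abort("predicted residual variance must be positive")
  log(s2) + (e^2 / (1 - h) - s2) / s2
}

#' Iteration weights of the double hierarchical model
#'
#' The mean part is weighted by the reciprocal predicted residual variance,
#' `w = exp(psi_hat)^-1`; the dispersion part by `w_v = (1-h)/2`, the
#' reciprocal of the asymptotic variance of the linearized log chi-squared
#' response.
#'
#' @param psi_hat Fitted dispersion linear predictor per record.
#' @param h Leverage per record, in `[0, 1)`.
#' @return A list with `w` and `w_v`.
#' @export
update_weights <- function(psi_hat, h) {
  if (any(h < 0 | h >= 1)) abort("leverage must lie in [0, 1)")
  list(w = 1 / exp(psi_hat), w_v = (1 - h) / 2)
}

#' Genetic coefficient of variation at the residual-SD level
#'
#' `GCV_SDe = sigma_av / 2`: the genetic standard deviation in residual
#' standard deviation relative to the mean residual standard deviation, for a
#' model with additive genetic variance `sigma2_av` on the log residual
#' variance.
#'
#' @param sigma2_av Additive genetic variance of the log residual variance
#'   (>= 0).
#' @return `0.5 * sqrt(sigma2_av)`.
#' @export
gcv_sde <- function(sigma2_av) {
  if (any(sigma2_av < 0)) abort("sigma2_av must be >= 0")
  0.5 * sqrt(sigma2_av)
}

#' Heritability of residual variance at the squared-phenotype level
#'
#' `h_v^2 = sigma2_av / (2 sigma_P^4 + 3 (sigma2_av + sigma2_pev))`. This is
#' a measure of the reliability of a breeding value for residual variance
#' from a single observation, not of the scope for response to selection.
#'
#' @param sigma2_av,sigma2_pev Additive genetic and permanent-environment
#'   variances of the log residual variance (>= 0).
#' @param sigma2_P Phenotypic variance of the trait (>= 0).
#' @return Dimensionless heritability of residual variance.
#' @export
h2_residual_variance <- function(sigma2_av, sigma2_pev, sigma2_P) {
  if (any(c(sigma2_av, sigma2_pev, sigma2_P) < 0)) abort("inputs must be >= 0")
  den <- 2 * sigma2_P^2 + 3 * (sigma2_av + sigma2_pev)
  if (any(den <= 0)) abort("denominator is zero; all variances are zero")
  sigma2_av / den
}

#' Iterative double hierarchical GLM for a trait and its residual variance
#'
#' Couples a Gaussian animal model for the trait with a log-linear model for
#' its residual variance. The algorithm starts from a conventional univariate
#' fit, forms the linearized working response `psi` from its residuals and
#' leverages, and then alternates (i) a weighted bivariate REML fit of
#' `(y, psi)` with unstructured 2x2 additive genetic and permanent-sow
#' covariance blocks and (ii) recomputation of residuals, leverages,
#' per-record predicted residual variances `exp(psi_hat)`, the working
#' response and both weight vectors, until every variance component is
#' stable. The two scaling residual variances are expected to converge to
#' about 1.
#'
#' @param records A data frame of repeated records (one row per litter).
#' @param pedigree Pedigree covering all ids in `id`.
#' @param response Name of the trait column (default `"tnb"`).
#' @param fixed Fixed-effect factor columns (default `c("parity", "fys")`).
#' @param id Name of the column identifying the animal (sow), used for both
#'   the additive genetic term (over the pedigree) and the permanent
#'   environment term (identity).
#' @param tol Outer convergence tolerance: maximum relative change of any
#'   variance component between iterations (default 1e-6).
#' @param max_iter Maximum outer iterations (default 100).
#' @param damping Relaxation factor in `(0, 1]` applied to the update of the
#'   fitted dispersion predictor between outer iterations (default 0.5);
#'   1 is the undamped alternation, which can enter a slowly contracting
#'   two-cycle on strongly heterogeneous data.
#' @param constrain_pe_cov If `TRUE`, the permanent-environment covariance
#'   between the two parts is fixed at zero (used to study the sensitivity of
#'   the genetic correlation to this constraint).
#' @param refit_univariate If `TRUE` (default), after convergence the mean
#'   and dispersion parts are each refit as weighted univariate models at the
#'   final weights; their EBVs and SEs (not influenced by the other trait)
#'   are what deregression should use.
#' @param reml_control List of extra arguments for the inner
#'   [estimate_reml()] calls.
#' @return An object of class `dhglm_fit`: the final bivariate `mm_fit`
#'   (`$fit`), component tibble (`$components`, via `tidy()`), per-record
#'   working response and weights, per-animal EBV tables for mean and
#'   dispersion parts (`$ebv`), the univariate refits (`$refit`), derived
#'   summaries (`GCV_SDe`, `h_v2`, `h2`), and the iteration trace.
#' @export
run_dhglm <- function(records, pedigree, response = "tnb",
                      fixed = c("parity", "fys"), id = "sow",
                      tol = 1e-6, max_iter = 100, damping = 0.5,
                      constrain_pe_cov = FALSE, refit_univariate = TRUE,
                      reml_control = list()) {
  if (damping <= 0 || damping > 1) abort("damping must lie in (0, 1]")
  records <- as_tibble(records)
  if (!inherits(pedigree, "ped_tbl")) pedigree <- as_pedigree(pedigree)

  reml_args <- modifyList(list(tol = 1e-8, max_iter = 50,
                               on_nonconvergence = "warn"), reml_control)

  # 1. conventional univariate fit: starting values, residuals, leverages
  des_uni <- mixed_design(records, response, fixed = fixed, genetic = id,
                          pedigree = pedigree, permanent = id)
  fit_uni <- do.call(estimate_reml, c(list(des_uni), reml_args))
  e <- fit_uni$residuals
  h <- fit_uni$leverage
  s2 <- rep(fit_uni$sigma_e, length(e))
  psi <- working_response(e, h, s2)
  psi_hat <- log(s2)

  # 2. cached bivariate design; y and weights are refreshed in place
  rec2 <- records
  rec2$.psi <- psi
  rec2$.w <- 1 / exp(psi_hat)
  rec2$.wv <- (1 - h) / 2
  des <- mixed_design(rec2, c(response, ".psi"), fixed = fixed, genetic = id,
                      pedigree = pedigree, permanent = id,
                      weights = c(".w", ".wv"))
  n0 <- des$n0

  start <- list(G = list(a = diag(c(fit_uni$G$a[1, 1], 0.01)),
                         pe = diag(c(fit_uni$G$pe[1, 1], 0.01))),
                sigma_e = c(1, 1))
  if (constrain_pe_cov) start$G$pe[1, 2] <- start$G$pe[2, 1] <- 0
  fix_cov <- if (constrain_pe_cov) "pe" else character()

  trace <- list()
  converged <- FALSE
  fit <- NULL
  for (it in seq_len(max_iter)) {
    fit <- do.call(estimate_reml,
                   c(list(des, start = start, fix_cov = fix_cov), reml_args))
    theta_new <- params_pack(fit$G, fit$sigma_e, 2)
    trace[[it]] <- theta_new
    if (it > 1) {
      rel <- abs(theta_new - theta_old) / pmax(abs(theta_old), 1e-4)
      if (max(rel) < tol) { converged <- TRUE; break }
    }
    theta_old <- theta_new
    # refresh working response and weights from this iteration's fit,
    # relaxing the dispersion predictor toward its previous value
    e <- fit$residuals[seq_len(n0)]
    h <- fit$leverage[seq_len(n0)]
    psi_hat <- damping * fit$fitted[n0 + seq_len(n0)] + (1 - damping) * psi_hat
    s2 <- exp(psi_hat)
    psi <- working_response(e, h, s2)
    wts <- update_weights(psi_hat, h)
    des$y[n0 + seq_len(n0)] <- psi
    des$w <- c(wts$w, wts$w_v)
    start <- list(G = fit$G, sigma_e = fit$sigma_e)
  }
  if (!converged) {
    warn(paste0("DHGLM did not reach the component tolerance in ", max_iter,
                " iterations"))
  }

  mean_resvar <- mean(exp(psi_hat)) * fit$sigma_e[1]
  comp <- tidy(fit)
  sa2 <- fit$G$a[1, 1]; sav2 <- fit$G$a[2, 2]
  spe2 <- fit$G$pe[1, 1]; spev2 <- fit$G$pe[2, 2]
  sigma2_P <- sa2 + spe2 + mean_resvar
  derived <- tibble(
    quantity = c("h2", "GCV_SDe", "h_v2", "mean_residual_variance", "sigma2_P"),
    value = c(heritability(sa2, spe2, mean_resvar), gcv_sde(sav2),
              h2_residual_variance(sav2, spev2, sigma2_P),
              mean_resvar, sigma2_P))

  refit <- NULL
  ebv <- NULL
  if (refit_univariate) {
    rec2$.psi <- psi
    rec2$.w <- 1 / exp(psi_hat)
    rec2$.wv <- (1 - h) / 2
    du1 <- mixed_design(rec2, response, fixed = fixed, genetic = id,
                        pedigree = pedigree, permanent = id, weights = ".w")
    du2 <- mixed_design(rec2, ".psi", fixed = fixed, genetic = id,
                        pedigree = pedigree, permanent = id, weights = ".wv")
    f1 <- do.call(estimate_reml, c(list(du1), reml_args))
    f2 <- do.call(estimate_reml, c(list(du2), reml_args))
    refit <- list(mean = f1, dispersion = f2)
    ebv <- dplyr::bind_rows(
      dplyr::mutate(f1$ranef$a[c("id", "value", "se")], trait = "mean"),
      dplyr::mutate(f2$ranef$a[c("id", "value", "se")], trait = "dispersion"))
    ebv <- dplyr::rename(ebv, animal = "id", ebv = "value")[
      c("animal", "trait", "ebv", "se")]
  }

  structure(list(fit = fit, fit_univariate = fit_uni, components = comp,
                 derived = derived, psi = psi, psi_hat = psi_hat,
                 weights = list(w = des$w[seq_len(n0)], w_v = des$w[n0 + seq_len(n0)]),
                 leverage = h, residuals = e, ebv = ebv, refit = refit,
                 iterations = length(trace), converged = converged,
                 trace = trace, response = response, id = id),
            class = "dhglm_fit")
}

#' @export
tidy.dhglm_fit <- function(x, ...) {
  dplyr::bind_rows(x$components,
                   dplyr::transmute(x$derived, component = .data$quantity,
                                    estimate = .data$value, se = NA_real_))
}

#' @export
glance.dhglm_fit <- function(x, ...) {
  tibble(iterations = x$iterations, converged = x$converged,
         logLik = x$fit$logLik,
         scale_e_mean = x$fit$sigma_e[1], scale_e_disp = x$fit$sigma_e[2],
         r_a = x$fit$G$a[2, 1] / sqrt(prod(diag(x$fit$G$a))),
         r_pe = x$fit$G$pe[2, 1] / sqrt(prod(diag(x$fit$G$pe))))
}

#' @export
#' @method print dhglm_fit
print.dhglm_fit <- function(x, ...) {
  cat("DHGLM fit:", x$iterations, "outer iterations;",
      if (isTRUE(x$converged)) "converged" else "NOT converged", "\n")
  print(tidy(x), n = 30)
  invisible(x)
}

#' Component trace of a DHGLM fit
#'
#' Plots every variance component against the outer iteration number, a
#' quick convergence diagnostic.
#'
#' @param object A `dhglm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dhglm_fit <- function(object, ...) {
  tr <- do.call(rbind, object$trace)
  df <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(tr, .name_repair = "unique"),
                  iteration = dplyr::row_number()),
    -"iteration", names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "outer iteration", y = "estimate")
}
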
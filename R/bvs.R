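#' Configuration of the Bayesian variable-selection GWAS
#'
#' @param pi1 Prior probability that a SNP belongs to the large-effect
#'   mixture component (default 0.001).
#' @param n_iter Number of MCMC cycles (default 500,000).
#' @param burnin_frac Fraction of cycles discarded as burn-in (default 0.1).
#' @param mh_step Standard deviation of the random-walk Metropolis-Hastings
#'   step on the log variance scale (default 0.003).
#' @param seed Integer seed; chains are exactly reproducible.
#' @param n_chains Number of independent chains (the first chain's summaries
#'   are reported; extra chains feed the convergence diagnostic).
#' @param sigma2_g0 Small-component effect variance; `NULL` picks a value
#'   three orders of magnitude below the large-component starting scale.
#' @param dev_thin Thinning interval for the stored deviance trace.
#' @return A list of class `bvs_config`.
#' @export
bvs_config <- function(pi1 = 0.001, n_iter = 5e5, burnin_frac = 0.1,
                       mh_step = 0.003, seed = 1, n_chains = 1,
                       sigma2_g0 = NULL, dev_thin = 10) {
  if (pi1 <= 0 || pi1 > 1) abort("pi1 must lie in (0, 1]")
  if (burnin_frac < 0 || burnin_frac >= 1) abort("burnin_frac must lie in [0, 1)")
  if (n_iter < 10) abort("n_iter too small")
  structure(as.list(environment()), class = "bvs_config")
}

#' Multi-SNP Bayesian variable-selection GWAS
#'
#' Fits `y = mu + X beta + e` with all SNP effects simultaneously, where
#' each effect comes from a two-component normal mixture: a null component
#' with small variance (probability `1 - pi1`) and a large-effect component
#' (probability `pi1`). Residuals are `N(0, sigma2_e / w_i)` using the
#' deregression weights. Indicators and effects use conjugate Gibbs draws;
#' the large-component and residual variances move by random-walk
#' Metropolis-Hastings on the log scale. The per-SNP posterior inclusion
#' probability is the post-burn-in fraction of cycles spent in the large
#' component.
#'
#' @param debv A data frame with columns `animal`, `debv` and `weight`
#'   (e.g. from [deregress()] after [filter_reliability()]).
#' @param geno Animals x SNPs numeric dosage matrix (no missing values;
#'   QC and imputation are expected beforehand, see [qc_genotypes()]).
#' @param config A [bvs_config()].
#' @param map Optional SNP metadata (`snp, chrom, pos`, optionally `maf`)
#'   carried into the result table.
#' @param total_gvar Denominator for the percentage of genetic variance
#'   explained; default is the sum of `2 p q beta_bar^2` over all SNPs, but
#'   the additive genetic variance of the trait may be supplied instead.
#' @return A `bvs_fit`: `tidy()` gives the per-SNP table (posterior
#'   inclusion probability, posterior mean effect, allele substitution
#'   effect, Bayes factor, significance label, percent of genetic variance);
#'   `glance()` the global parameters and diagnostics; `autoplot()` a
#'   genome-wide Bayes-factor plot.
#' @export
run_bvs <- function(debv, geno, config = bvs_config(), map = NULL,
                    total_gvar = NULL) {
  debv <- as_tibble(debv)
  if (!all(c("animal", "debv", "weight") %in% names(debv))) {
    abort("debv must have columns animal, debv, weight")
  }
  if (anyNA(debv$debv) || any(!is.finite(debv$debv))) abort("non-finite dEBV")
  if (any(debv$weight <= 0)) abort("weights must be positive")
  ids <- intersect(debv$animal, rownames(geno))
  if (!length(ids)) abort("no animals shared between dEBVs and genotypes")
  debv <- debv[match(ids, debv$animal), ]
  X <- geno[ids, , drop = FALSE]
  if (anyNA(X)) abort("genotypes contain missing values; run qc_genotypes() first")
  p_freq <- colMeans(X) / 2
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("constant SNP column(s) after QC: ",
                 paste(head(colnames(X)[sds == 0], 5), collapse = ", ")))
  }
  Xc <- sweep(X, 2, colMeans(X))
  y <- debv$debv; w <- debv$weight
  vy <- stats::var(y)
  sum_vx <- sum(apply(Xc, 2, stats::var))
  s2g1_init <- 0.5 * vy / max(config$pi1 * sum_vx, 1e-12)
  s2g0 <- config$sigma2_g0 %||% (0.001 * vy / sum_vx)
  burnin <- floor(config$burnin_frac * config$n_iter)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    chains[[ch]] <- cpp_bvs_mcmc(Xc, y, w, config$pi1, as.integer(config$n_iter),
                                 as.integer(burnin), config$mh_step,
                                 s2g0, s2g1_init, vy / 2,
                                 as.integer(config$dev_thin))
  }
  res <- chains[[1]]
  pip <- as.numeric(res$pip)
  beta <- as.numeric(res$beta_bar)
  genic <- 2 * p_freq * (1 - p_freq) * beta^2
  tot <- total_gvar %||% sum(genic)
  snp_tbl <- tibble(snp = colnames(X),
                    maf = pmin(p_freq, 1 - p_freq),
                    pip = pip,
                    effect = beta,
                    allele_subst_effect = abs(beta),
                    bf = if (config$pi1 >= 1) NA_real_ else
                      bayes_factor(pip, config$pi1),
                    pct_genetic_variance = 100 * genic / tot)
  snp_tbl$significance <- classify_bf(snp_tbl$bf)
  if (!is.null(map)) {
    map <- as_tibble(map)
    map <- map[c("snp", setdiff(names(map), names(snp_tbl)))]
    snp_tbl <- dplyr::left_join(snp_tbl, map, by = "snp")
  }
  dev <- lapply(chains, function(chn) as.numeric(chn$deviance))
  rhat <- if (config$n_chains >= 2) {
    n_post <- floor((config$n_iter - burnin) / config$dev_thin)
    gelman_rubin(lapply(dev, function(d) utils::tail(d, n_post)))
  } else NA_real_
  structure(list(snp = snp_tbl,
                 globals = tibble(mu = res$mu, sigma2_e = res$sigma2_e,
                                  sigma2_g1 = res$sigma2_g1,
                                  mean_n_large = res$mean_n_large,
                                  accept_e = res$accept_e,
                                  accept_g1 = res$accept_g1,
                                  rhat = rhat),
                 deviance = dev, deviance_iter = as.numeric(res$deviance_iter),
                 total_gvar = tot, config = config,
                 n_animals = length(ids)),
            class = "bvs_fit")
}

#' @export
tidy.bvs_fit <- function(x, ...) x$snp

#' @export
glance.bvs_fit <- function(x, ...) {
  dplyr::mutate(x$globals, n_animals = x$n_animals, n_snps = nrow(x$snp),
                n_significant = sum(x$snp$bf >= 30, na.rm = TRUE))
}

#' @export
#' @method print bvs_fit
print.bvs_fit <- function(x, ...) {
  cat("Bayesian variable-selection GWAS:", x$n_animals, "animals,",
      nrow(x$snp), "SNPs\n")
  print(glance(x))
  sig <- x$snp[x$snp$bf >= 30, ]
  cat(nrow(sig), "SNP(s) with BF >= 30\n")
  if (nrow(sig)) print(sig)
  invisible(x)
}

#' Genome-wide Bayes-factor plot
#'
#' SNPs along the genome with their Bayes factors on a log scale, coloured
#' by the three reporting strata (BF >= 30, 10 <= BF < 30, BF < 10).
#'
#' @param object A `bvs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bvs_fit <- function(object, ...) {
  df <- object$snp
  df$stratum <- cut(df$bf, c(-Inf, 10, 30, Inf),
                    labels = c("BF < 10", "10 <= BF < 30", "BF >= 30"))
  has_pos <- "pos" %in% names(df) && !all(is.na(df$pos))
  df$x <- if (has_pos) df$pos else seq_len(nrow(df))
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$x, pmax(.data$bf, 1e-3),
                                         colour = .data$stratum)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(yintercept = c(30, 150), linetype = "dashed") +
    ggplot2::labs(x = "position", y = "Bayes factor", colour = NULL)
  if ("chrom" %in% names(df) && !all(is.na(df$chrom))) {
    gg <- gg + ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x")
  }
  gg
}

#' Bayes factor from a posterior inclusion probability
#'
#' Posterior odds of the large-effect component over its prior odds:
#' `BF = (p/(1-p)) / (pi1/pi0)`. A posterior probability of exactly 1 gives
#' an infinite Bayes factor (returned as `Inf` with a warning).
#'
#' @param p_hat Posterior inclusion probability in `[0, 1]`.
#' @param pi1 Prior inclusion probability in (0, 1).
#' @return Bayes factor (>= 0).
#' @export
bayes_factor <- function(p_hat, pi1) {
  if (any(p_hat < 0 | p_hat > 1)) abort("p_hat must lie in [0, 1]")
  if (pi1 <= 0 || pi1 >= 1) abort("pi1 must lie in (0, 1)")
  if (any(p_hat == 1)) warn("posterior inclusion probability of 1: infinite Bayes factor")
  (p_hat / (1 - p_hat)) / (pi1 / (1 - pi1))
}

#' Significance label for a Bayes factor
#'
#' Kass-Raftery style thresholds: `BF >= 150` is "decisive", `BF >= 30`
#' "very strong", anything lower "not significant" for reporting purposes.
#'
#' @param bf Bayes factor (>= 0).
#' @return Factor with levels `not significant`, `very strong`, `decisive`.
#' @export
classify_bf <- function(bf) {
  if (any(bf < 0, na.rm = TRUE)) abort("Bayes factors must be >= 0")
  cut(bf, c(-Inf, 30, 150, Inf), right = FALSE,
      labels = c("not significant", "very strong", "decisive"))
}

#' Allele substitution effect from a SNP's genic variance
#'
#' `alpha = sqrt(var_snp / (2 p q))`, the per-allele-copy effect implied by
#' the variance a SNP explains at allele frequency `p`.
#'
#' @param var_snp Genic variance attributed to the SNP (>= 0).
#' @param p Allele frequency strictly between 0 and 1.
#' @return Allele substitution effect (same units as the trait per allele
#'   copy); symmetric in `p` and `1 - p`.
#' @export
allele_substitution_effect <- function(var_snp, p) {
  if (any(var_snp < 0)) abort("var_snp must be >= 0")
  if (any(p <= 0 | p >= 1)) abort("p must lie strictly between 0 and 1")
  sqrt(var_snp / (2 * p * (1 - p)))
}

#' Percent of genetic variance explained by a SNP
#'
#' `100 * 2 p (1-p) beta^2 / total_gvar`.
#'
#' @param beta_bar Posterior mean allele substitution effect.
#' @param p Allele frequency in (0, 1).
#' @param total_gvar Total genetic variance (> 0).
#' @return Percentage.
#' @export
variance_explained <- function(beta_bar, p, total_gvar) {
  if (any(total_gvar <= 0)) abort("total_gvar must be positive")
  100 * 2 * p * (1 - p) * beta_bar^2 / total_gvar
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance ratio on two or more equal-length
#' (post burn-in) chains; values below 1.1 are conventionally taken as
#' converged.
#'
#' @param chains A list of two or more equal-length numeric vectors, or a
#'   matrix with one chain per column.
#' @return The potential scale reduction factor (>= 1 up to Monte Carlo
#'   error).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2) {
    abort("need at least 2 chains; run with n_chains >= 2 or split one chain")
  }
  len <- lengths(chains)
  if (length(unique(len)) != 1) abort("chains must have equal length")
  n <- len[1]; m <- length(chains)
  means <- vapply(chains, mean, 0)
  W <- mean(vapply(chains, stats::var, 0))
  B <- n * stats::var(means)
  if (W == 0) return(1)
  vhat <- (n - 1) / n * W + B / n
  sqrt(vhat / W)
}
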
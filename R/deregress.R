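#' Reliability of an estimated breeding value
#'
#' `r^2 = 1 - s^2 / ((1 + f) sigma2_a)`, clamped to `[0, 1]`: the squared
#' accuracy implied by the prediction-error SE `s`, the animal's inbreeding
#' coefficient `f` (so `1 + f` is its diagonal of the relationship matrix)
#' and the additive genetic variance.
#'
#' @param s Standard error of the EBV (>= 0).
#' @param f Inbreeding coefficient.
#' @param sigma2_a Additive genetic variance (> 0).
#' @return Reliability in `[0, 1]`.
#' @export
reliability <- function(s, f = 0, sigma2_a) {
  if (any(sigma2_a <= 0)) abort("sigma2_a must be positive")
  if (any(s < 0)) abort("EBV standard errors must be >= 0")
  pmin(1, pmax(0, 1 - s^2 / ((1 + f) * sigma2_a)))
}

# Garrick-style information partition for one animal: given the reliability
# of the parent average and of the animal's EBV, solve for the effective
# data contents (in lambda units) of the parent average and of the animal's
# own + progeny information.
garrick_information <- function(r2_pa, r2, h2) {
  lambda <- (1 - h2) / h2
  alpha <- 1 / (0.5 - r2_pa)
  delta <- (0.5 - r2_pa) / (1 - r2)
  zz_pa <- lambda * (0.5 * alpha - 4) + 0.5 * lambda * sqrt(alpha^2 + 16 / delta)
  zz_i <- delta * zz_pa + 2 * lambda * (2 * delta - 1)
  list(lambda = lambda, zz_pa = zz_pa, zz_i = zz_i)
}

#' Deregress estimated breeding values
#'
#' Removes the parent-average contribution from each genotyped animal's EBV
#' by the two-equation information-partition approach: the joint evaluation
#' of (parent average, individual) is reconstructed from the two
#' reliabilities, the right-hand side attributable to the animal's own and
#' progeny information is recovered, and dividing by its information content
#' yields the deregressed proof. Animals whose own + progeny information
#' content is not positive (their EBV is all parent average) are dropped and
#' listed in the `"drop_report"` attribute.
#'
#' Each record receives a weight for heterogeneous residual variances in a
#' marker analysis, `w = (1 - h2) / ((c + (1 - r2_d)/r2_d) * h2)`, where
#' `r2_d` is the post-deregression reliability and `c` is the fraction of
#' genetic variance not captured by markers.
#'
#' @param ebv A data frame with columns `animal`, `ebv`, `se` (one row per
#'   animal; may include non-genotyped ancestors, used only as parents).
#' @param pedigree Pedigree providing sire/dam links and inbreeding.
#' @param sigma2_a Additive genetic variance of the trait.
#' @param h2 Heritability used for the lambda ratio and the weights.
#' @param c Fraction of genetic variance not explained by markers (default
#'   0.5).
#' @param keep Optional character vector of animal ids to deregress (default
#'   all rows of `ebv`).
#' @return A tibble `animal, debv, reliability, weight` (class
#'   `debv_tbl`), with attributes `drop_report` (tibble of dropped animals
#'   and reasons) and `meta` (list recording `c` and the weighting rule).
#' @export
deregress <- function(ebv, pedigree, sigma2_a, h2, c = 0.5, keep = NULL) {
  if (missing(sigma2_a) || is.null(sigma2_a)) abort("sigma2_a is required")
  if (h2 <= 0 || h2 >= 1) abort("h2 must lie in (0, 1)")
  ebv <- as_tibble(ebv)
  if (!all(c("animal", "ebv", "se") %in% names(ebv))) {
    abort("ebv must have columns animal, ebv, se")
  }
  if (!inherits(pedigree, "ped_tbl")) pedigree <- as_pedigree(pedigree)
  inb <- compute_inbreeding(pedigree)
  f <- stats::setNames(inb$f, inb$animal)
  ebv$f <- unname(f[ebv$animal])
  ebv$f[is.na(ebv$f)] <- 0
  ebv$r2 <- reliability(ebv$se, ebv$f, sigma2_a)
  look_e <- stats::setNames(ebv$ebv, ebv$animal)
  look_r <- stats::setNames(ebv$r2, ebv$animal)
  sire <- stats::setNames(pedigree$sire, pedigree$animal)
  dam <- stats::setNames(pedigree$dam, pedigree$animal)
  if (is.null(keep)) keep <- ebv$animal
  out <- vector("list", length(keep))
  dropped <- list()
  for (k in seq_along(keep)) {
    an <- keep[k]
    g <- look_e[[an]]; r2 <- look_r[[an]]
    if (is.null(g) || is.na(g)) { dropped[[an]] <- "no EBV"; next }
    pe_ids <- c(sire[[an]] %||% NA, dam[[an]] %||% NA)
    pebv <- vapply(pe_ids, function(p) if (!is.na(p) && !is.na(look_e[p])) look_e[[p]] else 0, 0)
    pr2 <- vapply(pe_ids, function(p) if (!is.na(p) && !is.na(look_r[p])) look_r[[p]] else 0, 0)
    pa <- mean(pebv)
    r2_pa <- sum(pr2) / 4
    # guard the open interval the partition needs
    r2_use <- min(r2, 0.9999)
    r2_pa <- min(r2_pa, 0.4999)
    gi <- garrick_information(r2_pa, r2_use, h2)
    if (!is.finite(gi$zz_i) || gi$zz_i <= 0) {
      dropped[[an]] <- "no own or progeny information"
      next
    }
    y_i <- -2 * gi$lambda * pa + (gi$zz_i + 2 * gi$lambda) * g
    debv <- y_i / gi$zz_i
    r2_d <- gi$zz_i / (gi$zz_i + gi$lambda)
    w <- (1 - h2) / ((c + (1 - r2_d) / r2_d) * h2)
    out[[k]] <- tibble(animal = an, debv = debv, reliability = r2_d, weight = w)
  }
  res <- dplyr::bind_rows(out)
  report <- tibble(animal = names(dropped),
                   reason = unlist(dropped, use.names = FALSE))
  attr(res, "drop_report") <- report
  attr(res, "meta") <- list(c = c, h2 = h2, sigma2_a = sigma2_a,
                            weighting = "w = (1-h2)/((c + (1-r2d)/r2d) h2); no renormalization")
  class(res) <- c("debv_tbl", class(res))
  res
}

#' Filter deregressed proofs on reliability
#'
#' Keeps records whose deregressed reliability is at least `threshold`
#' (boundary inclusive).
#'
#' @param records A [deregress()] result.
#' @param threshold Minimum reliability (default 0.05).
#' @return The filtered tibble.
#' @export
filter_reliability <- function(records, threshold = 0.05) {
  records[records$reliability >= threshold, ]
}
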
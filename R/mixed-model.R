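#' Build a mixed-model design
#'
#' Assembles the design for a (possibly weighted, possibly bivariate) animal
#' model \eqn{y = Xb + Za + Upe + e}. Each element of `responses` becomes one
#' trait block; traits share the fixed-effect factors and the random-term id
#' columns but have their own fixed-effect solutions, their own residual
#' variance and their own weight column. Random effects across traits are
#' correlated through an unstructured t-by-t covariance block per term.
#'
#' @param data A data frame, one row per record.
#' @param responses Character vector (length 1 or 2) of response columns.
#' @param fixed Character vector of fixed-effect factor columns. An intercept
#'   is always included.
#' @param genetic Name of the id column for the additive genetic term, or
#'   `NULL` to omit it.
#' @param pedigree A pedigree ([as_pedigree()]) supplying the relationship
#'   structure for the genetic term; `NULL` uses an identity covariance
#'   (e.g. a sire model on unrelated sires).
#' @param permanent Name of the id column for the permanent-environment term
#'   (identity covariance), or `NULL`.
#' @param weights `NULL` (unit weights), a single column name used for every
#'   trait, or a character vector of one weight column per trait. Residual
#'   variance of record i is `sigma_e(trait)^2 / w_i`.
#' @return An object of class `mm_design`.
#' @export
mixed_design <- function(data, responses, fixed = character(), genetic = "animal",
                         pedigree = NULL, permanent = NULL, weights = NULL) {
  data <- as_tibble(data)
  t <- length(responses)
  if (!t %in% 1:2) abort("1 or 2 responses supported")
  for (cc in c(responses, fixed, genetic, permanent)) {
    if (!cc %in% names(data)) abort(paste0("column not found in data: ", cc))
  }
  n0 <- nrow(data)
  y_list <- lapply(responses, function(r) as.numeric(data[[r]]))
  for (k in seq_len(t)) {
    if (anyNA(y_list[[k]])) abort(paste0("missing values in response ", responses[k]))
    if (stats::var(y_list[[k]]) == 0)
      abort(paste0("response '", responses[k], "' has zero empirical variance"))
  }
  y <- unlist(y_list)
  trait <- rep(seq_len(t), each = n0)

  # fixed-effect block: one model matrix per trait, block-diagonal
  if (length(fixed)) {
    fdf <- data[fixed]
    fdf[] <- lapply(fdf, function(v) factor(v))
    X1 <- Matrix::sparse.model.matrix(
      stats::as.formula(paste("~", paste(fixed, collapse = "+"))), data = fdf)
  } else {
    X1 <- Matrix::Matrix(1, n0, 1, sparse = TRUE, dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- base::qr(as.matrix(Matrix::crossprod(X1)))
  if (qrX$rank < ncol(X1)) {
    abort(paste0("fixed effects are rank deficient (confounded factors among: ",
                 paste(c("(Intercept)", fixed), collapse = ", "), ")"))
  }
  X <- Matrix::bdiag(rep(list(X1), t))
  colnames(X) <- paste0(rep(colnames(X1), t), "_t", rep(seq_len(t), each = ncol(X1)))

  # weights
  if (is.null(weights)) {
    w <- rep(1, n0 * t)
  } else {
    if (length(weights) == 1L) weights <- rep(weights, t)
    w <- unlist(lapply(weights, function(wc) as.numeric(data[[wc]])))
  }
  if (any(!is.finite(w)) || any(w <= 0)) abort("weights must be strictly positive")

  terms <- list()
  add_term <- function(name, idcol, Kinv, logdetK, level_ids) {
    lev <- match(as.character(data[[idcol]]), level_ids)
    if (anyNA(lev)) {
      abort(paste0("ids in '", idcol, "' missing from covariance structure: ",
                   paste(head(unique(data[[idcol]][is.na(lev)]), 5), collapse = ", ")))
    }
    terms[[name]] <<- list(name = name, levels = rep(lev, t), n_levels = length(level_ids),
                           Kinv = Kinv, logdetK = logdetK, level_ids = level_ids)
  }
  if (!is.null(genetic)) {
    if (!is.null(pedigree)) {
      if (!inherits(pedigree, "ped_tbl")) pedigree <- as_pedigree(pedigree)
      Ainv <- build_ainverse(pedigree)
      add_term("a", genetic, methods::as(Ainv, "generalMatrix"),
               attr(Ainv, "logdet"), rownames(Ainv))
      f <- attr(Ainv, "f")
    } else {
      ids <- sort(unique(as.character(data[[genetic]])))
      add_term("a", genetic, Matrix::Diagonal(length(ids)), 0, ids)
      f <- stats::setNames(rep(0, length(ids)), ids)
    }
  } else f <- NULL
  if (!is.null(permanent)) {
    ids <- sort(unique(as.character(data[[permanent]])))
    add_term("pe", permanent, Matrix::Diagonal(length(ids)), 0, ids)
  }

  # random-effect incidence: trait-major columns per term
  Zs <- lapply(terms, function(tm) {
    Matrix::sparseMatrix(i = seq_len(n0 * t),
                         j = (trait - 1L) * tm$n_levels + tm$levels,
                         x = 1, dims = c(n0 * t, t * tm$n_levels))
  })
  M <- do.call(cbind, c(list(X), unname(Zs)))
  offs <- cumsum(c(ncol(X), vapply(terms, function(tm) tm$n_levels * t, 0)))
  offsets <- stats::setNames(c(0, offs[-length(offs)])[-1], names(terms))

  structure(list(y = y, trait = trait, n0 = n0, t = t, w = w,
                 X = X, M = M, p_fixed = ncol(X), terms = terms,
                 offsets = offsets, responses = responses, fixed = fixed,
                 f = f, data = data),
            class = "mm_design")
}

# ---- internal REML machinery -------------------------------------------------

# parameter bookkeeping: per term the lower triangle of G (column-major vech),
# then one residual variance per trait
vech_idx <- function(t) {
  idx <- which(lower.tri(matrix(0, t, t), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

params_pack <- function(G, sigma_e, t) {
  unlist(c(lapply(G, function(g) g[vech_idx(t)]), list(sigma_e)))
}

params_unpack <- function(theta, terms, t) {
  nv <- t * (t + 1) / 2
  G <- list(); k <- 0
  for (nm in names(terms)) {
    g <- matrix(0, t, t)
    g[vech_idx(t)] <- theta[k + seq_len(nv)]
    g[upper.tri(g)] <- t(g)[upper.tri(g)]
    G[[nm]] <- g
    k <- k + nv
  }
  list(G = G, sigma_e = unname(theta[k + seq_len(t)]))
}

params_valid <- function(par, t) {
  ok <- all(par$sigma_e > 1e-10)
  for (g in par$G) {
    ok <- ok && all(diag(g) > 1e-10)
    if (t == 2) ok <- ok && (det(g) > 0)
  }
  ok
}

mm_assemble_C <- function(design, par) {
  Rinv_diag <- design$w / par$sigma_e[design$trait]
  MtRi <- Matrix::crossprod(design$M, Matrix::Diagonal(x = Rinv_diag))
  C <- MtRi %*% design$M
  pf <- design$p_fixed; t <- design$t
  blocks <- lapply(names(design$terms), function(nm) {
    tm <- design$terms[[nm]]
    Gi <- solve(par$G[[nm]])
    # keep zero covariance blocks structurally present so the factor pattern
    # (and the selected-inverse coverage) is stable across iterations
    Gi[Gi == 0] <- 1e-300
    Matrix::kronecker(Gi, tm$Kinv)
  })
  Gpart <- Matrix::bdiag(c(list(Matrix::Matrix(0, pf, pf, sparse = TRUE)), blocks))
  C <- Matrix::forceSymmetric(C + Gpart)
  list(C = C, Rinv_diag = Rinv_diag, MtRi = MtRi)
}

mm_loglik_only <- function(design, par, Ch = NULL) {
  if (!params_valid(par, design$t)) return(list(ll = -Inf, Ch = Ch))
  asm <- mm_assemble_C(design, par)
  Ch <- tryCatch({
    if (is.null(Ch)) Matrix::Cholesky(asm$C, LDL = FALSE, super = FALSE, perm = TRUE)
    else Matrix::update(Ch, asm$C)
  }, error = function(e) NULL)
  if (is.null(Ch)) return(list(ll = -Inf, Ch = NULL))
  rhs <- asm$MtRi %*% design$y
  sol <- Matrix::solve(Ch, rhs)
  yPy <- sum(design$y^2 * asm$Rinv_diag) - sum(rhs * sol)
  L <- methods::as(Ch, "CsparseMatrix")
  logdetC <- 2 * sum(log(Matrix::diag(L)))
  logdetR <- sum(log(par$sigma_e[design$trait] / design$w))
  logdetG <- 0
  for (nm in names(design$terms)) {
    tm <- design$terms[[nm]]
    logdetG <- logdetG + tm$n_levels * log(det(as.matrix(par$G[[nm]]))) +
      design$t * tm$logdetK
  }
  ll <- -0.5 * (logdetC + logdetR + logdetG + yPy)
  list(ll = ll, Ch = Ch, L = L, sol = sol, rhs = rhs, asm = asm)
}

# exact C^-1 entries for positions that fell outside the factor pattern
selinv_fallback <- function(Ch, rows, cols) {
  vapply(seq_along(rows), function(k) {
    n <- Ch@Dim[1]
    e <- rep(0, n); e[cols[k] + 1] <- 1
    as.numeric(Matrix::solve(Ch, e))[rows[k] + 1]
  }, 0)
}

mm_trace_block <- function(B, roff, coff, L, Zx, iperm, Ch) {
  B <- methods::as(methods::as(B, "CsparseMatrix"), "generalMatrix")
  res <- cpp_selinv_trace(B@p, B@i, B@x, as.integer(roff), as.integer(coff),
                          L@p, L@i, Zx, iperm)
  tr <- res$trace
  if (length(res$miss_row)) {
    tr <- tr + sum(res$miss_val * selinv_fallback(Ch, res$miss_row, res$miss_col))
  }
  tr
}

# one full REML evaluation: log-likelihood, scores, AI matrix, solutions
mm_reml_step <- function(design, par, Ch = NULL, need_selinv = TRUE) {
  ev <- mm_loglik_only(design, par, Ch)
  if (!is.finite(ev$ll)) abort("non-finite REML log-likelihood; invalid parameters")
  tt <- design$t; n0 <- design$n0
  L <- ev$L
  iperm <- Matrix::invPerm(ev$Ch@perm + 1L) - 1L
  Zx <- cpp_selinv(L@p, L@i, L@x, nrow(L))

  ehat <- as.numeric(design$y - design$M %*% ev$sol)
  Py <- ev$asm$Rinv_diag * ehat
  uhat <- list()
  for (nm in names(design$terms)) {
    tm <- design$terms[[nm]]
    off <- design$offsets[[nm]]
    uhat[[nm]] <- matrix(as.numeric(ev$sol)[off + seq_len(tt * tm$n_levels)],
                         ncol = tt) # columns = traits
  }

  iv <- vech_idx(tt); nv <- nrow(iv)
  np <- length(design$terms) * nv + tt
  score <- numeric(np); Fmat <- matrix(0, length(design$y), np)
  k <- 0
  for (nm in names(design$terms)) {
    tm <- design$terms[[nm]]
    off <- design$offsets[[nm]]
    G <- par$G[[nm]]; Gi <- solve(G)
    # trait-pair traces tr(Kinv %*% Cinv-block(u,v)) and B[u,v] = u_u' Kinv u_v
    trK <- matrix(0, tt, tt); Bq <- matrix(0, tt, tt)
    for (u in seq_len(tt)) for (v in seq_len(tt)) {
      if (v < u) { trK[u, v] <- trK[v, u]; Bq[u, v] <- Bq[v, u]; next }
      trK[u, v] <- mm_trace_block(tm$Kinv,
                                  off + (u - 1) * tm$n_levels,
                                  off + (v - 1) * tm$n_levels, L, Zx, iperm, ev$Ch)
      Bq[u, v] <- sum(uhat[[nm]][, u] * (tm$Kinv %*% uhat[[nm]][, v]))
    }
    for (s in seq_len(nv)) {
      r <- iv[s, 1]; cc <- iv[s, 2]
      E <- matrix(0, tt, tt); E[r, cc] <- E[cc, r] <- 1
      H <- Gi %*% E %*% Gi
      tr1 <- tm$n_levels * sum(diag(E %*% Gi))
      tr2 <- sum(H * trK)
      dat <- sum(H * Bq)
      score[k + s] <- -0.5 * (tr1 - tr2 - dat)
      # AI working vector f = Z ((E Gi) %x% I) uhat
      EGu <- uhat[[nm]] %*% t(E %*% Gi)   # n_levels x t, col u = sum_v (EGi)[u,v] u_v
      Fmat[, k + s] <- EGu[cbind(tm$levels, design$trait)]
    }
    k <- k + nv
  }
  for (tau in seq_len(tt)) {
    sel <- design$trait == tau
    s2 <- par$sigma_e[tau]
    Msel <- design$M[sel, , drop = FALSE]
    Sb <- Matrix::crossprod(Msel, Matrix::Diagonal(x = design$w[sel]) %*% Msel)
    trS <- mm_trace_block(Sb, 0, 0, L, Zx, iperm, ev$Ch)
    score[k + tau] <- -0.5 * (sum(sel) / s2 - trS / s2^2 -
                                sum(design$w[sel] * ehat[sel]^2) / s2^2)
    Fmat[sel, k + tau] <- ehat[sel] / s2
  }
  # AI matrix: 0.5 * F' P F
  rhsF <- ev$asm$MtRi %*% Fmat
  solF <- Matrix::solve(ev$Ch, rhsF)
  PF <- ev$asm$Rinv_diag * (Fmat - as.matrix(design$M %*% solF))
  AI <- 0.5 * crossprod(Fmat, PF)
  AI <- (AI + t(AI)) / 2

  list(ll = ev$ll, score = score, AI = AI, Ch = ev$Ch, L = L, Zx = Zx,
       iperm = iperm, sol = ev$sol, ehat = ehat, Py = Py, uhat = uhat,
       Rinv_diag = ev$asm$Rinv_diag)
}

#' Estimate variance components by average-information REML
#'
#' Maximizes the restricted likelihood of a [mixed_design()] by
#' average-information (AI) updates with step halving; steps that would leave
#' the parameter space (negative variances, non-positive-definite 2x2
#' covariance blocks) are shortened, and components heading to zero are pinned
#' at a small positive boundary. Approximate standard errors come from the
#' inverse of the AI matrix at convergence.
#'
#' @param design A [mixed_design()].
#' @param start Optional list with elements `G` (named list of t-by-t starting
#'   covariance matrices per random term) and `sigma_e` (length-t residual
#'   scale variances). Defaults split the phenotypic variance evenly.
#' @param tol Convergence tolerance on the relative change in the restricted
#'   log-likelihood (default 1e-8).
#' @param max_iter Maximum AI iterations (default 50).
#' @param fix_cov Character vector of term names whose between-trait
#'   covariance is held fixed at its starting value (used to constrain e.g.
#'   the permanent-environment covariance to zero).
#' @param on_nonconvergence `"error"` (default) or `"warn"`.
#' @return An object of class `mm_fit`; see [solve_mme()] for its contents.
#'   `tidy()` returns the component table, `glance()` the fit summary.
#' @export
estimate_reml <- function(design, start = NULL, tol = 1e-8, max_iter = 50,
                          fix_cov = character(), on_nonconvergence = c("error", "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  t <- design$t
  if (is.null(start)) {
    vy <- vapply(seq_len(t), function(tau) stats::var(design$y[design$trait == tau]), 0)
    nrand <- length(design$terms)
    G <- lapply(design$terms, function(tm) diag(vy / (nrand + 1), t, t))
    start <- list(G = G, sigma_e = vy / (nrand + 1))
  }
  if (any(start$sigma_e <= 0)) abort("starting residual variances must be positive")
  iv <- vech_idx(t); nv <- nrow(iv)
  free <- rep(TRUE, length(design$terms) * nv + t)
  if (length(fix_cov) && t == 2) {
    for (nm in fix_cov) {
      ki <- (match(nm, names(design$terms)) - 1) * nv
      free[ki + which(iv[, 1] != iv[, 2])] <- FALSE
    }
  }
  theta <- params_pack(start$G, start$sigma_e, t)
  par <- params_unpack(theta, design$terms, t)
  Ch <- NULL
  ll_old <- -Inf
  trace <- list()
  converged <- FALSE
  step <- NULL
  for (it in seq_len(max_iter)) {
    step <- mm_reml_step(design, par, Ch)
    Ch <- step$Ch
    trace[[it]] <- c(ll = step$ll, theta)
    if (is.finite(ll_old) && abs(step$ll - ll_old) < tol * (1 + abs(step$ll))) {
      converged <- TRUE
      break
    }
    ll_old <- step$ll
    AIa <- step$AI[free, free, drop = FALSE]
    delta <- rep(0, length(theta))
    delta[free] <- tryCatch(solve(AIa, step$score[free]),
                            error = function(e) step$score[free] / (diag(AIa) + 1e-12))
    fac <- 1
    repeat {
      cand <- theta + fac * delta
      parc <- params_unpack(cand, design$terms, t)
      # pin boundary components rather than stepping outside
      for (nm in names(parc$G)) diag(parc$G[[nm]]) <- pmax(diag(parc$G[[nm]]), 1e-8)
      parc$sigma_e <- pmax(parc$sigma_e, 1e-8)
      if (params_valid(parc, t)) {
        llc <- mm_loglik_only(design, parc, Ch)$ll
        if (is.finite(llc) && (llc >= step$ll - 1e-6)) break
      }
      fac <- fac / 2
      if (fac < 1e-4) { parc <- par; break } # no usable step
    }
    theta <- params_pack(parc$G, parc$sigma_e, t)
    par <- parc
  }
  if (!converged) {
    msg <- paste0("AI-REML did not converge in ", max_iter, " iterations")
    tr_df <- do.call(rbind, trace)
    if (on_nonconvergence == "error") {
      abort(msg, class = "vargwas_reml_nonconvergence", trace = tr_df)
    } else {
      warn(msg)
    }
  }
  mm_finish_fit(design, par, step, free = free, trace = trace,
                iterations = length(trace), converged = converged)
}

#' Solve the mixed-model equations at given variance components
#'
#' BLUE/BLUP solutions, residuals, hat-matrix (leverage) diagonals and
#' prediction-error standard errors at fixed variance components, without
#' REML iteration.
#'
#' @param design A [mixed_design()].
#' @param varcomp List with `G` (named list of per-term covariance matrices)
#'   and `sigma_e` (per-trait residual scale variances).
#' @return An `mm_fit` with elements `varcomp` (tidy component table), `G`,
#'   `sigma_e`, `fixef` (tibble), `ranef` (named list of tibbles with EBV and
#'   prediction-error SE), `residuals`, `fitted`, `leverage` (all per stacked
#'   record), `logLik`, and the design.
#' @export
solve_mme <- function(design, varcomp) {
  par <- list(G = lapply(varcomp$G, as.matrix), sigma_e = varcomp$sigma_e)
  if (!params_valid(par, design$t)) abort("variance components must be positive definite")
  step <- mm_reml_step(design, par)
  mm_finish_fit(design, par, step, free = NULL, trace = list(),
                iterations = 1L, converged = NA)
}

mm_finish_fit <- function(design, par, step, free, trace, iterations, converged) {
  t <- design$t
  # leverage: diagonal of M Cinv M' Rinv
  Mr <- methods::as(methods::as(design$M, "CsparseMatrix"), "RsparseMatrix")
  qf <- cpp_rowwise_quadform(Mr@p, Mr@j, Mr@x, step$L@p, step$L@i, step$Zx, step$iperm)
  h <- qf$q
  if (length(qf$miss_rows)) {
    for (i in qf$miss_rows) {
      m_i <- design$M[i, , drop = FALSE]
      h[i] <- as.numeric(m_i %*% Matrix::solve(step$Ch, Matrix::t(m_i)))
    }
  }
  h <- h * step$Rinv_diag

  # prediction error SE of random-effect solutions: diag of Cinv
  ranef <- list()
  for (nm in names(design$terms)) {
    tm <- design$terms[[nm]]
    off <- design$offsets[[nm]]
    dg <- off + seq_len(t * tm$n_levels) - 1L
    pev <- cpp_selinv_lookup(step$L@p, step$L@i, step$Zx, step$iperm,
                             as.integer(dg), as.integer(dg))
    if (anyNA(pev)) {
      na_at <- which(is.na(pev))
      pev[na_at] <- selinv_fallback(step$Ch, dg[na_at], dg[na_at])
    }
    ranef[[nm]] <- tibble(
      id = rep(tm$level_ids, t),
      trait = rep(design$responses, each = tm$n_levels),
      value = as.numeric(step$uhat[[nm]]),
      se = sqrt(pmax(pev, 0)))
  }
  fixef <- tibble(term = colnames(design$X),
                  trait = rep(design$responses, each = design$p_fixed / t),
                  estimate = as.numeric(step$sol)[seq_len(design$p_fixed)])

  se <- rep(NA_real_, length(step$score))
  if (!is.null(free)) {
    Vp <- matrix(NA_real_, length(free), length(free))
    Vp[free, free] <- tryCatch(solve(step$AI[free, free, drop = FALSE]),
                               error = function(e) matrix(NA_real_, sum(free), sum(free)))
    se <- sqrt(pmax(diag(Vp), 0))
  } else Vp <- NULL

  vc <- mm_component_table(design, par, se, Vp)

  structure(list(varcomp = vc, G = par$G, sigma_e = par$sigma_e,
                 fixef = fixef, ranef = ranef,
                 residuals = step$ehat, fitted = design$y - step$ehat,
                 leverage = h, logLik = step$ll, AI = step$AI, Vp = Vp,
                 iterations = iterations, converged = converged,
                 trace = trace, design = design),
            class = "mm_fit")
}

# component table with SEs; correlations by the delta method
mm_component_table <- function(design, par, se, Vp) {
  tt <- design$t; iv <- vech_idx(tt); nv <- nrow(iv)
  rows <- list(); k <- 0
  for (nm in names(design$terms)) {
    G <- par$G[[nm]]
    for (s in seq_len(nv)) {
      r <- iv[s, 1]; cc <- iv[s, 2]
      lbl <- if (r == cc) paste0("sigma2_", nm, "_", design$responses[r])
             else paste0("cov_", nm, "_", design$responses[cc], "_", design$responses[r])
      rows[[length(rows) + 1]] <- tibble(component = lbl, estimate = G[r, cc],
                                         se = se[k + s])
    }
    if (tt == 2) {
      rr <- G[2, 1] / sqrt(G[1, 1] * G[2, 2])
      se_r <- NA_real_
      if (!is.null(Vp) && !anyNA(Vp[k + 1:3, k + 1:3])) {
        gvec <- c(-rr / (2 * G[1, 1]), 1 / sqrt(G[1, 1] * G[2, 2]), -rr / (2 * G[2, 2]))
        se_r <- sqrt(max(0, drop(crossprod(gvec, Vp[k + 1:3, k + 1:3] %*% gvec))))
      }
      rows[[length(rows) + 1]] <- tibble(component = paste0("r_", nm),
                                         estimate = rr, se = se_r)
    }
    k <- k + nv
  }
  for (tau in seq_len(tt)) {
    rows[[length(rows) + 1]] <- tibble(
      component = paste0("sigma2_e_", design$responses[tau]),
      estimate = par$sigma_e[tau], se = se[k + tau])
  }
  dplyr::bind_rows(rows)
}

#' @export
tidy.mm_fit <- function(x, ...) x$varcomp

#' @export
glance.mm_fit <- function(x, ...) {
  tibble(logLik = x$logLik, n = length(x$design$y), n_traits = x$design$t,
         iterations = x$iterations, converged = x$converged)
}

#' @export
#' @method print mm_fit
print.mm_fit <- function(x, ...) {
  cat("Mixed-model fit (", x$design$t, "trait(s),",
      length(x$design$y), "records )\n")
  cat("REML log-likelihood:", format(x$logLik), "\n")
  print(x$varcomp)
  invisible(x)
}

#' Narrow-sense heritability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_pe + sigma2_e)`.
#'
#' @param sigma2_a,sigma2_pe,sigma2_e Additive genetic, permanent-environment
#'   and residual variances (same squared trait units).
#' @return Heritability, dimensionless.
#' @export
heritability <- function(sigma2_a, sigma2_pe, sigma2_e) {
  tot <- sigma2_a + sigma2_pe + sigma2_e
  if (any(c(sigma2_a, sigma2_pe, sigma2_e) < 0)) abort("variances must be >= 0")
  if (any(tot <= 0)) abort("total variance must be positive")
  sigma2_a / tot
}

#' Covariance implied by a correlation and two variances
#'
#' @param r Correlation in `[-1, 1]`.
#' @param v1,v2 Variances (>= 0).
#' @return `r * sqrt(v1 * v2)`.
#' @export
covariance_from_correlation <- function(r, v1, v2) {
  if (any(abs(r) > 1)) abort("|r| must be <= 1")
  if (any(v1 < 0) || any(v2 < 0)) abort("variances must be >= 0")
  r * sqrt(v1 * v2)
}

#' Conventional bivariate analysis of per-sow mean and log-variance
#'
#' Fits the weighted bivariate animal model for `mean_tnb` and `log_var_tnb`
#' from [summarize_sows()]: additive genetic effects for the two traits share
#' the pedigree relationship structure with an unstructured 2x2 covariance,
#' residuals are weighted and uncorrelated across traits. Residual weights
#' are `n_litters` for the mean and `(n_litters - 1)/2` for the log-variance
#' (reciprocals of the approximate sampling variances of a mean and of a log
#' sample variance); the weighting rule is recorded in the fit.
#'
#' @param summaries Output of [summarize_sows()] (must include an `fys`
#'   column used as fixed effect).
#' @param pedigree Pedigree covering the sows.
#' @param ... Passed on to [estimate_reml()].
#' @return An `mm_fit` with attribute `weighting` describing the rule used.
#' @export
fit_conventional_bivariate <- function(summaries, pedigree, ...) {
  summaries <- dplyr::mutate(summaries,
                             .w_mean = .data$n_litters,
                             .w_var = (.data$n_litters - 1) / 2)
  des <- mixed_design(summaries, responses = c("mean_tnb", "log_var_tnb"),
                      fixed = intersect("fys", names(summaries)),
                      genetic = "sow", pedigree = pedigree,
                      weights = c(".w_mean", ".w_var"))
  fit <- estimate_reml(des, ...)
  attr(fit, "weighting") <- "w_mean = n_litters; w_logvar = (n_litters - 1)/2"
  fit
}
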
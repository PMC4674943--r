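#' Read a pedigree file
#'
#' Reads a pedigree CSV with columns `animal,sire,dam`. A literal `"0"`, an
#' empty field or `NA` marks an unknown parent. Ids are treated as opaque
#' strings.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble with character columns `animal`, `sire`, `dam` (`NA` for
#'   unknown parents), validated and topologically ordered (see
#'   [as_pedigree()]).
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df))) {
    abort(paste0("pedigree file must have columns animal,sire,dam; found: ",
                 paste(names(df), collapse = ",")))
  }
  as_pedigree(df[need])
}

#' Validate and topologically order a pedigree
#'
#' Checks that animal ids are unique, that every parent id refers to a listed
#' animal (parents appearing only as parents are added as founders), and that
#' the pedigree is acyclic. Rows are reordered so every parent precedes its
#' offspring.
#'
#' @param df A data frame with columns `animal`, `sire`, `dam`. `"0"`, `""`
#'   and `NA` denote unknown parents.
#' @param max_generations Optional depth truncation: ancestors more than this
#'   many generations above the youngest animals are cut loose (their parents
#'   set unknown). Default `Inf` keeps the full pedigree.
#' @return A tibble of class `ped_tbl` in topological order, with an integer
#'   `generation` column (founders are 0).
#' @export
as_pedigree <- function(df, max_generations = Inf) {
  df <- as_tibble(df)
  for (col in c("animal", "sire", "dam")) {
    v <- as.character(df[[col]])
    v[v %in% c("0", "")] <- NA_character_
    df[[col]] <- v
  }
  if (anyNA(df$animal)) abort("missing animal id in pedigree")
  if (anyDuplicated(df$animal)) {
    abort(paste0("duplicated animal id(s): ",
                 paste(unique(df$animal[duplicated(df$animal)]), collapse = ", ")))
  }
  # add parents that appear without their own record as founders
  parents <- setdiff(stats::na.omit(c(df$sire, df$dam)), df$animal)
  if (length(parents)) {
    df <- dplyr::bind_rows(
      tibble(animal = parents, sire = NA_character_, dam = NA_character_), df)
  }
  n <- nrow(df)
  idx <- seq_len(n)
  names(idx) <- df$animal
  si <- unname(idx[df$sire]); di <- unname(idx[df$dam])
  si[is.na(si)] <- 0L; di[is.na(di)] <- 0L
  # Kahn's algorithm for a topological order; a leftover node implies a cycle
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (p > 0L) {
      indeg[i] <- indeg[i] + 1L
      kids[[p]] <- c(kids[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  gen <- integer(n)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (k in kids[[i]]) {
      gen[k] <- max(gen[k], gen[i] + 1L)
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    bad <- df$animal[setdiff(seq_len(n), ord)]
    abort(paste0("pedigree contains a cycle involving: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  df$generation <- gen
  df <- df[ord, ]
  if (is.finite(max_generations)) {
    depth <- max(df$generation)
    df <- df[df$generation >= depth - max_generations, ]
    # sever parent links that now point outside the kept set
    df$sire[!(df$sire %in% df$animal)] <- NA_character_
    df$dam[!(df$dam %in% df$animal)] <- NA_character_
    df$generation <- df$generation - min(df$generation)
  }
  class(df) <- c("ped_tbl", class(df))
  df
}

# internal: 1-based parent indices in topological order (0 = unknown)
ped_indices <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$animal
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  si[is.na(si)] <- 0L; di[is.na(di)] <- 0L
  list(sire = si, dam = di, ids = ped$animal)
}

#' Inbreeding coefficients
#'
#' Computes the inbreeding coefficient of every animal with an ancestor
#' path-tracing algorithm (Meuwissen--Luo style): the diagonal of the
#' numerator relationship matrix is accumulated from Mendelian sampling
#' variances without ever forming the matrix. Animals with one or both
#' parents unknown get `f = 0` (unknown parents are taken as draws from an
#' unrelated base population).
#'
#' @param ped A pedigree from [as_pedigree()] (or a data frame coercible to
#'   one).
#' @return A tibble with columns `animal`, `f` (inbreeding coefficient in
#'   `[0, 1)`), and `d` (Mendelian sampling variance coefficient, used
#'   internally for the sparse inverse relationship matrix).
#' @export
compute_inbreeding <- function(ped) {
  if (!inherits(ped, "ped_tbl")) ped <- as_pedigree(ped)
  pi_ <- ped_indices(ped)
  res <- cpp_inbreeding(pi_$sire, pi_$dam)
  tibble(animal = pi_$ids, f = res$f, d = res$d)
}

#' Numerator relationship matrix
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' method: `A(i,j) = (A(sire(i),j) + A(dam(i),j)) / 2` for `j` preceding `i`,
#' and `A(i,i) = 1 + f_i`. Dense; intended for desk-scale pedigrees (a few
#' thousand animals). Mixed-model fitting uses the sparse inverse from
#' [build_ainverse()] instead.
#'
#' @inheritParams compute_inbreeding
#' @return A symmetric numeric matrix with animal ids as dimnames.
#' @export
build_relationship <- function(ped) {
  if (!inherits(ped, "ped_tbl")) ped <- as_pedigree(ped)
  pi_ <- ped_indices(ped)
  A <- cpp_tabular_A(pi_$sire, pi_$dam)
  dimnames(A) <- list(pi_$ids, pi_$ids)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: `A^-1 = sum_i (1/d_i) q_i q_i'` where
#' `q_i` has 1 at the animal and -1/2 at its known parents, and `d_i` is the
#' Mendelian sampling variance from [compute_inbreeding()].
#'
#' @inheritParams compute_inbreeding
#' @return A sparse symmetric `Matrix` with attributes `logdet` (log
#'   determinant of A, i.e. `sum(log d_i)`) and `f` (inbreeding coefficients).
#' @export
build_ainverse <- function(ped) {
  if (!inherits(ped, "ped_tbl")) ped <- as_pedigree(ped)
  pi_ <- ped_indices(ped)
  inb <- cpp_inbreeding(pi_$sire, pi_$dam)
  n <- nrow(ped)
  # triplet contributions per animal, vectorised
  s <- pi_$sire; d <- pi_$dam
  inv_d <- 1 / inb$d
  rows <- list(); cols <- list(); vals <- list()
  add <- function(r, c, v) {
    rows[[length(rows) + 1L]] <<- r
    cols[[length(cols) + 1L]] <<- c
    vals[[length(vals) + 1L]] <<- v
  }
  i <- seq_len(n)
  add(i, i, inv_d)
  hs <- s > 0L; hd <- d > 0L
  add(i[hs], s[hs], -0.5 * inv_d[hs]); add(s[hs], i[hs], -0.5 * inv_d[hs])
  add(i[hd], d[hd], -0.5 * inv_d[hd]); add(d[hd], i[hd], -0.5 * inv_d[hd])
  add(s[hs], s[hs], 0.25 * inv_d[hs])
  add(d[hd], d[hd], 0.25 * inv_d[hd])
  both <- hs & hd
  add(s[both], d[both], 0.25 * inv_d[both]); add(d[both], s[both], 0.25 * inv_d[both])
  Ainv <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols), x = unlist(vals),
                               dims = c(n, n), dimnames = list(pi_$ids, pi_$ids))
  Ainv <- Matrix::forceSymmetric(Matrix::drop0(Ainv))
  attr(Ainv, "logdet") <- sum(log(inb$d))
  attr(Ainv, "f") <- stats::setNames(inb$f, pi_$ids)
  Ainv
}
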
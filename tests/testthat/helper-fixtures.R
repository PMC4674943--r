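# Shared fixtures, built in code at test time.

# fixed seed for every stochastic test in the suite
TEST_SEED <- 20151209

# two unrelated founder couples; E is the offspring of two full sibs
ped_fullsib <- function() {
  tibble::tibble(
    animal = c("A", "B", "C", "D", "E"),
    sire = c(NA, NA, "A", "A", "C"),
    dam = c(NA, NA, "B", "B", "D"))
}

# random valid pedigree: founders plus `n_extra` animals with parents drawn
# from earlier animals
random_pedigree <- function(n_founders = 10, n_extra = 40, seed = TEST_SEED) {
  set.seed(seed)
  ids <- sprintf("a%02d", seq_len(n_founders + n_extra))
  sire <- dam <- rep(NA_character_, n_founders + n_extra)
  for (i in (n_founders + 1):(n_founders + n_extra)) {
    pick <- sample(i - 1, 2)
    sire[i] <- ids[pick[1]]
    dam[i] <- ids[pick[2]]
  }
  tibble::tibble(animal = ids, sire = sire, dam = dam)
}

# independent oracle: numerator relationship matrix by straightforward
# tabular recursion in plain R (kept separate from the package's C++ path)
tabular_A_oracle <- function(ped) {
  ped <- vargwas::as_pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      a <- 0
      if (!is.na(si[i])) a <- a + 0.5 * A[j, si[i]]
      if (!is.na(di[i])) a <- a + 0.5 * A[j, di[i]]
      A[i, j] <- A[j, i] <- a
    }
    A[i, i] <- 1 + if (!is.na(si[i]) && !is.na(di[i])) 0.5 * A[si[i], di[i]] else 0
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

# independent oracle: expected allele sharing by gene dropping
genedrop_A_oracle <- function(ped, n_rep = 2e5, seed = TEST_SEED) {
  ped <- vargwas::as_pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  set.seed(seed)
  H1 <- matrix(0L, n_rep, n); H2 <- matrix(0L, n_rep, n)
  next_allele <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      H1[, i] <- next_allele + 1L; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_rep) < 0.5
      H1[, i] <- ifelse(pick, H1[, si[i]], H2[, si[i]])
    }
    if (is.na(di[i])) {
      H2[, i] <- next_allele + 1L; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_rep) < 0.5
      H2[, i] <- ifelse(pick, H1[, di[i]], H2[, di[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) for (j in i:n) {
    s <- (H1[, i] == H1[, j]) + (H1[, i] == H2[, j]) +
      (H2[, i] == H1[, j]) + (H2[, i] == H2[, j])
    A[i, j] <- A[j, i] <- mean(s) / 2
  }
  A
}

# small repeated-records data set with known variance components
small_sim <- function(n_founders = 200, n_generations = 2, parities = 4,
                      params = vargwas::sim_params(), seed = TEST_SEED) {
  ped <- vargwas::simulate_pedigree(n_founders, n_generations,
                                    litters_per_dam = 3, seed = seed)
  sim <- vargwas::simulate_phenotypes(ped, params, parities_per_sow = parities,
                                      seed = seed + 1)
  list(ped = ped, sim = sim)
}
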
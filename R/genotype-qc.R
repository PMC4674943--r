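#' Read genotypes from PLINK text or dosage CSV
#'
#' Two plain-text layouts are accepted: a PLINK `.ped`/`.map` pair (alleles
#' as two columns per SNP, `0` = missing) or a dosage CSV with an `animal`
#' column and one 0/1/2 column per SNP. For PLINK input the counted allele
#' of each SNP is the lexicographically larger of its two observed alleles.
#'
#' @param path Path to a `.ped` file (with a `.map` next to it) or a CSV.
#' @return A list with `genotypes` (animals x SNPs integer matrix, `NA` for
#'   missing) and `map` (tibble `snp, chrom, pos`; positions `NA` when no
#'   map information is available).
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.ped$", path)) {
    map_path <- sub("\\.ped$", ".map", path)
    if (!file.exists(map_path)) abort(paste0("missing map file: ", map_path))
    map <- utils::read.table(map_path, colClasses = "character")
    names(map)[1:4] <- c("chrom", "snp", "cm", "pos")
    ped <- utils::read.table(path, colClasses = "character")
    n_snp <- nrow(map)
    if (ncol(ped) != 6 + 2 * n_snp) {
      abort("ped/map mismatch: ped must have 6 + 2*n_snps columns")
    }
    ids <- ped[[2]]
    G <- matrix(NA_integer_, length(ids), n_snp, dimnames = list(ids, map$snp))
    for (j in seq_len(n_snp)) {
      a1 <- ped[[5 + 2 * j]]; a2 <- ped[[6 + 2 * j]]
      alleles <- sort(setdiff(unique(c(a1, a2)), "0"))
      counted <- alleles[length(alleles)]
      miss <- a1 == "0" | a2 == "0"
      d <- (a1 == counted) + (a2 == counted)
      d[miss] <- NA_integer_
      G[, j] <- d
    }
    list(genotypes = G,
         map = tibble(snp = map$snp, chrom = map$chrom,
                      pos = suppressWarnings(as.integer(map$pos))))
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    if (!"animal" %in% names(df)) abort("dosage CSV must have an 'animal' column")
    G <- as.matrix(df[setdiff(names(df), "animal")])
    storage.mode(G) <- "integer"
    rownames(G) <- as.character(df$animal)
    list(genotypes = G,
         map = tibble(snp = colnames(G), chrom = NA_character_, pos = NA_integer_))
  }
}

#' Minor allele frequencies
#'
#' @param geno Animals x SNPs dosage matrix (0/1/2, `NA` missing).
#' @return Named vector of per-SNP minor allele frequencies in `[0, 0.5]`,
#'   computed on non-missing calls.
#' @export
snp_maf <- function(geno) {
  p <- colMeans(geno, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' SNP-level quality control
#'
#' Removes SNPs in three sequential passes: quality score below
#' `score_min`, sex-chromosome or unknown-position SNPs, and minor allele
#' frequency below `maf_min` (computed on the supplied animals, non-missing
#' calls). The report counts removals per rule in that order.
#'
#' @param geno Animals x SNPs dosage matrix.
#' @param meta SNP metadata tibble with columns `snp, chrom, pos, score`;
#'   must cover every column of `geno`.
#' @param score_min Minimum quality (GenCall-type) score (default 0.15).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param sex_chrom Chromosome labels treated as sex chromosomes.
#' @return Character vector of retained SNP ids, with a `"qc_report"`
#'   attribute (tibble of rule and count).
#' @export
filter_snps <- function(geno, meta, score_min = 0.15, maf_min = 0.01,
                        sex_chrom = c("X", "Y", "XY", "19", "20")) {
  meta <- as_tibble(meta)
  if (!all(colnames(geno) %in% meta$snp)) {
    abort("metadata does not cover all genotyped SNPs")
  }
  meta <- meta[match(colnames(geno), meta$snp), ]
  keep <- colnames(geno)
  n0 <- length(keep)
  ok_score <- !is.na(meta$score) & meta$score >= score_min
  keep1 <- keep[ok_score]
  ok_pos <- !(meta$chrom %in% sex_chrom) & !is.na(meta$pos)
  keep2 <- intersect(keep1, keep[ok_pos])
  maf <- snp_maf(geno[, keep2, drop = FALSE])
  keep3 <- keep2[maf >= maf_min]
  report <- tibble(rule = c(paste0("score_below_", score_min),
                            "sex_chromosome_or_unknown_position",
                            paste0("maf_below_", maf_min),
                            "retained"),
                   n = c(n0 - length(keep1), length(keep1) - length(keep2),
                         length(keep2) - length(keep3), length(keep3)))
  structure(keep3, qc_report = report)
}

# opposing-homozygote conflicts of each animal against its genotyped parents
mendel_conflicts <- function(geno, pedigree) {
  if (!inherits(pedigree, "ped_tbl")) pedigree <- as_pedigree(pedigree)
  ids <- rownames(geno)
  sire <- stats::setNames(pedigree$sire, pedigree$animal)
  dam <- stats::setNames(pedigree$dam, pedigree$animal)
  out <- tibble(animal = ids, n_compared = 0L, n_conflicts = 0L)
  for (k in seq_along(ids)) {
    an <- ids[k]
    for (p in c(sire[[an]] %||% NA, dam[[an]] %||% NA)) {
      if (is.na(p) || !(p %in% ids)) next
      go <- geno[an, ]; gp <- geno[p, ]
      cmp <- !is.na(go) & !is.na(gp)
      conf <- cmp & ((go == 0L & gp == 2L) | (go == 2L & gp == 0L))
      out$n_compared[k] <- out$n_compared[k] + sum(cmp)
      out$n_conflicts[k] <- out$n_conflicts[k] + sum(conf)
    }
  }
  out$rate <- ifelse(out$n_compared > 0, out$n_conflicts / out$n_compared, 0)
  out
}

#' Animal-level quality control
#'
#' Removes animals whose genotype call rate is below `call_threshold`, then
#' animals whose Mendelian-inconsistency rate (opposing-homozygote conflicts
#' with genotyped parents, per comparable locus) exceeds
#' `mendel_rate_threshold`.
#'
#' @param geno Animals x SNPs dosage matrix.
#' @param pedigree Pedigree used to locate genotyped parents; animals absent
#'   from it are only call-rate checked.
#' @param call_threshold Minimum call rate (default 0.95).
#' @param mendel_rate_threshold Maximum conflict rate (default 0.01).
#' @return Character vector of retained animal ids with a `"qc_report"`
#'   attribute; the per-animal conflict table is in attribute `"mendel"`.
#' @export
filter_animals <- function(geno, pedigree, call_threshold = 0.95,
                           mendel_rate_threshold = 0.01) {
  call_rate <- rowMeans(!is.na(geno))
  keep1 <- rownames(geno)[call_rate >= call_threshold]
  md <- mendel_conflicts(geno[keep1, , drop = FALSE], pedigree)
  keep2 <- md$animal[md$rate <= mendel_rate_threshold]
  report <- tibble(rule = c(paste0("call_rate_below_", call_threshold),
                            paste0("mendel_rate_above_", mendel_rate_threshold),
                            "retained"),
                   n = c(nrow(geno) - length(keep1), length(keep1) - length(keep2),
                         length(keep2)))
  structure(keep2, qc_report = report, mendel = md)
}

#' Full genotype quality control
#'
#' Applies [filter_animals()] then [filter_snps()] (so allele frequencies
#' reflect the retained animals) and imputes remaining missing calls to the
#' SNP mean dosage `2p`.
#'
#' @inheritParams filter_snps
#' @inheritParams filter_animals
#' @return A list with `genotypes` (numeric matrix, imputed), `map` (the
#'   retained metadata rows plus a `maf` column), and `report` (combined QC
#'   report tibble).
#' @export
qc_genotypes <- function(geno, meta, pedigree, score_min = 0.15, maf_min = 0.01,
                         sex_chrom = c("X", "Y", "XY", "19", "20"),
                         call_threshold = 0.95, mendel_rate_threshold = 0.01) {
  keep_an <- filter_animals(geno, pedigree, call_threshold, mendel_rate_threshold)
  g1 <- geno[keep_an, , drop = FALSE]
  keep_snp <- filter_snps(g1, meta, score_min, maf_min, sex_chrom)
  g2 <- g1[, keep_snp, drop = FALSE]
  maf <- snp_maf(g2)
  G <- apply(g2, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  rownames(G) <- rownames(g2)
  meta2 <- as_tibble(meta)[match(keep_snp, meta$snp), ]
  meta2$maf <- unname(maf)
  report <- dplyr::bind_rows(
    dplyr::mutate(attr(keep_an, "qc_report"), stage = "animals"),
    dplyr::mutate(attr(keep_snp, "qc_report"), stage = "snps"))
  list(genotypes = G, map = meta2, report = report[c("stage", "rule", "n")])
}
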
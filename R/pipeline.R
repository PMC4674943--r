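#' Assemble a pipeline configuration
#'
#' Collects file paths, editing thresholds, model and GWAS settings for
#' [run_pipeline()] into one serializable list. `write_pipeline_config()` /
#' `read_pipeline_config()` round-trip it through YAML.
#'
#' @param pedigree,phenotypes,genotypes,snp_metadata Input file paths
#'   (pedigree CSV; phenotype CSV; PLINK `.ped` or dosage CSV; SNP metadata
#'   CSV `snp,chrom,pos,score`).
#' @param output_dir Directory for stage outputs.
#' @param min_tnb,cap_tnb,max_parity Phenotype editing thresholds
#'   ([edit_records()]).
#' @param dhglm_tol,dhglm_max_iter DHGLM outer-loop controls.
#' @param dereg_c,reliability_min Deregression genomic fraction and the
#'   reliability cut applied to deregressed proofs.
#' @param qc Named list of genotype QC thresholds passed to
#'   [qc_genotypes()].
#' @param bvs A [bvs_config()].
#' @param seed Global seed; stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(pedigree, phenotypes, genotypes, snp_metadata = NULL,
                            output_dir = "vargwas_run",
                            min_tnb = 4, cap_tnb = 27, max_parity = 10,
                            dhglm_tol = 1e-6, dhglm_max_iter = 100,
                            dereg_c = 0.5, reliability_min = 0.05,
                            qc = list(), bvs = bvs_config(), seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$bvs <- unclass(cfg$bvs)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$bvs <- do.call(bvs_config, cfg$bvs)
  do.call(pipeline_config, cfg[setdiff(names(cfg), character())])
}

pipe_stage <- function(name, expr) {
  inform(paste0("[", name, "] started"))
  t0 <- Sys.time()
  res <- tryCatch(force(expr), error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          parent = e)
  })
  inform(paste0("[", name, "] done in ",
                format(round(difftime(Sys.time(), t0, units = "secs"), 1))))
  res
}

# cheap deterministic fingerprint of the scientific configuration (output
# location excluded), hex of a polynomial byte hash
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$output_dir <- NULL
  s <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 0
  for (b in s) h <- (h * 31 + b) %% 2^28
  sprintf("%07x", h)
}

write_stage_tsv <- function(df, path, seed, version, hash = "") {
  con <- file(path, "w")
  writeLines(paste0("# vargwas ", version, " seed=", seed,
                    " config=", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: phenotype editing, the conventional univariate fit
#' and the iterative DHGLM, deregression of both traits' EBVs, genotype QC,
#' and one Bayesian variable-selection GWAS per trait (mean and dispersion),
#' writing stage TSVs into the configured output directory. The two GWAS
#' runs share the genotype QC but use their own deregressed-EBV sets, so the
#' animal counts can differ after the reliability filter.
#'
#' @param config A [pipeline_config()] (or path to its YAML form).
#' @return A list of class `pipeline_result` with elements `edit_report`,
#'   `dhglm` (the `dhglm_fit`), `debv` (per trait), `qc`, `gwas` (per
#'   trait `bvs_fit`), and `tables` (component and significant-SNP tables).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  for (f in c(cfg$pedigree, cfg$phenotypes, cfg$genotypes)) {
    if (!file.exists(f)) abort(paste0("input file not found: ", f))
  }
  if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
  ver <- as.character(utils::packageVersion("vargwas"))
  chash <- config_hash(cfg)
  out <- function(name) file.path(cfg$output_dir, name)
  set.seed(cfg$seed)

  ped <- pipe_stage("pedigree", read_pedigree(cfg$pedigree))
  raw <- pipe_stage("phenotypes", read_litter_records(cfg$phenotypes))
  orphans <- setdiff(raw$sow, ped$animal)
  if (length(orphans)) {
    abort(paste0("sows missing from pedigree: ",
                 paste(head(orphans, 5), collapse = ", "),
                 if (length(orphans) > 5) paste0(" (+", length(orphans) - 5, " more)")))
  }

  rec <- pipe_stage("edit", edit_records(raw, cfg$min_tnb, cfg$cap_tnb, cfg$max_parity))
  write_stage_tsv(edit_report(rec), out("edit_report.tsv"), cfg$seed, ver, chash)

  dh <- pipe_stage("dhglm",
                   run_dhglm(rec, ped, tol = cfg$dhglm_tol,
                             max_iter = cfg$dhglm_max_iter))
  write_stage_tsv(tidy(dh), out("dhglm_components.tsv"), cfg$seed, ver, chash)
  write_stage_tsv(dh$ebv, out("dhglm_ebv.tsv"), cfg$seed, ver, chash)

  sa2_mean <- dh$refit$mean$G$a[1, 1]
  sa2_disp <- dh$refit$dispersion$G$a[1, 1]
  h2_mean <- unname(dh$derived$value[dh$derived$quantity == "h2"])
  # dispersion-trait "heritability" on the working-response scale
  h2_disp <- sa2_disp / (sa2_disp + dh$refit$dispersion$G$pe[1, 1] +
                           mean(dh$refit$dispersion$sigma_e /
                                  dh$weights$w_v))
  debv <- list()
  for (tr in c("mean", "dispersion")) {
    eb <- dh$ebv[dh$ebv$trait == tr, ]
    eb <- tibble(animal = eb$animal, ebv = eb$ebv, se = eb$se)
    dd <- pipe_stage(paste0("deregress_", tr),
                     deregress(eb, ped,
                               sigma2_a = if (tr == "mean") sa2_mean else sa2_disp,
                               h2 = max(min(if (tr == "mean") h2_mean else h2_disp,
                                            0.99), 0.01),
                               c = cfg$dereg_c))
    debv[[tr]] <- filter_reliability(dd, cfg$reliability_min)
    write_stage_tsv(debv[[tr]], out(paste0("debv_", tr, ".tsv")), cfg$seed, ver, chash)
  }

  gin <- pipe_stage("genotypes", read_genotypes(cfg$genotypes))
  meta <- if (!is.null(cfg$snp_metadata)) {
    md <- utils::read.csv(cfg$snp_metadata)
    tibble(snp = as.character(md$snp), chrom = as.character(md$chrom),
           pos = as.integer(md$pos), score = as.numeric(md$score))
  } else dplyr::mutate(gin$map, score = 1.0)
  qc_args <- modifyList(list(geno = gin$genotypes, meta = meta, pedigree = ped),
                        cfg$qc)
  qc <- pipe_stage("genotype_qc", do.call(qc_genotypes, qc_args))
  write_stage_tsv(qc$report, out("qc_report.tsv"), cfg$seed, ver, chash)

  gwas <- list()
  for (tr in c("mean", "dispersion")) {
    total <- if (tr == "mean") sa2_mean else sa2_disp
    gwas[[tr]] <- pipe_stage(paste0("gwas_", tr),
                             run_bvs(debv[[tr]], qc$genotypes, cfg$bvs,
                                     map = qc$map, total_gvar = total))
    write_stage_tsv(tidy(gwas[[tr]]), out(paste0("gwas_", tr, ".tsv")),
                    cfg$seed, ver, chash)
  }

  sig <- lapply(gwas, function(g) {
    tb <- tidy(g)
    tb[tb$bf >= 30, intersect(c("snp", "chrom", "pos", "maf",
                                "allele_subst_effect", "bf",
                                "pct_genetic_variance"), names(tb))]
  })
  for (tr in names(sig)) {
    write_stage_tsv(sig[[tr]], out(paste0("significant_", tr, ".tsv")),
                    cfg$seed, ver, chash)
  }
  write_pipeline_config(cfg, out("config_echo.yaml"))

  structure(list(edit_report = edit_report(rec), dhglm = dh, debv = debv,
                 qc = qc, gwas = gwas,
                 tables = list(components = tidy(dh), significant = sig),
                 config = cfg),
            class = "pipeline_result")
}

#' @export
#' @method print pipeline_result
print.pipeline_result <- function(x, ...) {
  cat("vargwas pipeline run\n")
  cat("  DHGLM:", x$dhglm$iterations, "outer iterations\n")
  cat("  dEBV sets: mean", nrow(x$debv$mean), "animals; dispersion",
      nrow(x$debv$dispersion), "animals\n")
  for (tr in names(x$tables$significant)) {
    cat("  significant SNPs (", tr, "): ", nrow(x$tables$significant[[tr]]),
        "\n", sep = "")
  }
  invisible(x)
}
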
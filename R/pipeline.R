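#' Run the full pipeline from a structured configuration file
#'
#' Executes the requested stages in dependency order — simulate, gwas, clump,
#' condfdr/conjfdr, ldsc, greml, clinical — writing every output as a
#' tab-separated table into the artifact directory together with a provenance
#' record (config hash, seed, package version).  A stage failure halts the
#' run; partial outputs are preserved.
#'
#' @param config path to a YAML file or a named list.  Recognized top-level
#'   keys: `seed` (required), `out_dir` (required), `simulate` (fields of
#'   [simulation_config()]), and logical/overriding sections `gwas`,
#'   `clump` (`p_threshold`), `overlap` (`conjfdr_threshold`, `prune_iter`),
#'   `ldsc`, `greml` (`h2`, `n`, `m`, `n_causal`), `clinical` (`n_cases`,
#'   `n_controls`).  Omitted sections are skipped.
#' @return invisibly, the artifact directory path.
#' @export
pipeline_run <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (key in c("seed", "out_dir")) {
    if (is.null(cfg[[key]])) stop("config key missing: ", key, call. = FALSE)
  }
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- check_count(cfg$seed, "seed", min = 0)
  log_path <- file.path(out_dir, "pipeline.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(line, "\n"); cat(line, "\n", file = log_path, append = TRUE)
  }
  prov <- list(config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
               seed = seed,
               package_version = as.character(utils::packageVersion("gwasoverlap")))
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))

  sim_args <- cfg$simulate %||% list()
  sim_args$seed <- seed
  sc <- do.call(simulation_config, sim_args)
  logmsg("simulate: %d variants, n1 = %d", sc$m_snps, sc$n1)
  # LD reference panel: a few thousand samples give stable r2 at any GWAS n
  panel <- simulate_ld_genotypes(sc, n_samples = min(2000L, max(sc$n1, sc$n2)))
  pair_raw <- simulate_sumstats_pair(sc, panel)
  write_sumstats(pair_raw$ss1, file.path(out_dir, "trait1.sumstats.tsv"))
  write_sumstats(pair_raw$ss2, file.path(out_dir, "trait2.sumstats.tsv"))

  if (!is.null(cfg$clump)) {
    params <- clump_params(p_threshold = cfg$clump$p_threshold %||% 5e-8)
    loci <- find_loci(pair_raw$ss1, panel, params)
    logmsg("clump: %d loci at p < %g", nrow(loci), params$p_threshold)
    utils::write.table(loci[, c("chr", "start", "end", "lead", "n_ind",
                                "n_cand", "top_p")],
                       file.path(out_dir, "loci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_loci_bed(loci, file.path(out_dir, "loci.bed"))
  }

  if (!is.null(cfg$overlap)) {
    pair <- harmonize_pair(pair_raw$ss1, pair_raw$ss2, panel)
    pair <- exclude_regions(pair)
    thr <- cfg$overlap$conjfdr_threshold %||% 0.05
    iters <- cfg$overlap$prune_iter %||% 20L
    cj <- conj_fdr(pair, prune_iter = iters, seed = seed)
    rep_tab <- data.frame(id = pair$variants$id, conjfdr = cj$fdr)
    utils::write.table(rep_tab, file.path(out_dir, "conjfdr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sl <- shared_loci(pair, cj, panel, threshold = thr)
    logmsg("overlap: %d shared loci at conjFDR < %g", nrow(sl$loci), thr)
    if (nrow(sl$loci)) {
      utils::write.table(sl$loci[, c("chr", "start", "end", "lead", "top_p",
                                     "direction")],
                         file.path(out_dir, "shared_loci.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  if (!is.null(cfg$ldsc)) {
    ld <- ld_scores(panel)
    h2a <- ldsc_h2(pair_raw$ss1, ld)
    h2b <- ldsc_h2(pair_raw$ss2, ld)
    rg <- ldsc_rg(pair_raw$ss1, pair_raw$ss2, ld)
    logmsg("ldsc: h2 = %.3f / %.3f, rg = %.3f", h2a$h2, h2b$h2, rg$rg)
    utils::write.table(
      data.frame(stat = c("h2_trait1", "h2_trait2", "rg", "rg_se"),
                 value = c(h2a$h2, h2b$h2, rg$rg, rg$se)),
      file.path(out_dir, "ldsc.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  if (!is.null(cfg$greml)) {
    g <- cfg$greml
    gcfg <- simulation_config(m_snps = g$m %||% 5000L, n1 = g$n %||% 2000L,
                              n2 = g$n %||% 2000L, seed = seed + 1L)
    gpanel <- simulate_ld_genotypes(gcfg)
    gpanel$dosages <- gpanel$dosages[seq_len(gcfg$n1), , drop = FALSE]
    gpanel$sample_ids <- gpanel$sample_ids[seq_len(gcfg$n1)]
    ph <- simulate_phenotype(gpanel, g$h2 %||% 0.5,
                             g$n_causal %||% 500L, seed + 2L)
    fit <- greml(ph$y, NULL, compute_grm(gpanel))
    logmsg("greml: h2 = %.3f (SE %.3f)", fit$h2, fit$se["h2"])
    utils::write.table(
      data.frame(stat = c("h2", "h2_se", "sigma2_g", "sigma2_e"),
                 value = c(fit$h2, fit$se["h2"], fit$sigma2_g, fit$sigma2_e)),
      file.path(out_dir, "greml.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  if (!is.null(cfg$clinical)) {
    cl <- cfg$clinical
    cohort <- simulate_clinical_cohort(n_cases = cl$n_cases %||% 300L,
                                       n_controls = cl$n_controls %||% 600L,
                                       seed = seed + 3L)
    mat <- clinical_matrix(cohort)
    logmsg("clinical: %d tests, %d significant", nrow(mat), sum(mat$significant))
    utils::write.table(mat, file.path(out_dir, "clinical_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
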
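# End-to-end orchestration: QC -> masks -> gene and single-variant tests ->
# leave-one-out -> candidate selection -> cross-stage meta -> gene-set
# enrichment. The analysis/ drivers call the same functions step by step;
# run_pipeline() wires them together for one-shot runs and smoke tests.

#' Run configuration
#'
#' @param select_p stage-2 selection threshold (default 1e-4).
#' @param bonferroni_p exome-wide significance (default 2.5e-6, Bonferroni
#'   for all genes in the genome).
#' @param loo_stop_p leave-one-out stop threshold (default 0.1).
#' @param nominal_p single-variant nominal significance (default 0.05).
#' @param n_perm gene-set permutations (default 20000).
#' @param seed top-level seed; every stochastic step derives its stream
#'   from it.
#' @param mask_cfg a [mask_config()].
#' @param skato_cfg a [skato_config()].
#' @param masks which masks to analyse.
#' @return a `run_config` object.
#' @export
run_config <- function(select_p = 1e-4, bonferroni_p = 2.5e-6,
                       loo_stop_p = 0.1, nominal_p = 0.05,
                       n_perm = 20000L, seed = 1L,
                       mask_cfg = mask_config(), skato_cfg = skato_config(),
                       masks = c("LOF", "STRICT", "BROAD")) {
  stopifnot(select_p > 0, bonferroni_p > 0, loo_stop_p > 0, n_perm >= 1)
  structure(list(select_p = select_p, bonferroni_p = bonferroni_p,
                 loo_stop_p = loo_stop_p, nominal_p = nominal_p,
                 n_perm = n_perm, seed = seed, mask_cfg = mask_cfg,
                 skato_cfg = skato_cfg, masks = masks),
            class = "run_config")
}

gene_test_for_mask <- function(mask) {
  # burden for the very-rare masks, SKAT-O for the broad mask
  if (mask == "BROAD") "skato" else "burden"
}

run_gene_tests <- function(x, setups, cfg) {
  res <- list()
  for (s in setups) {
    if (!s$testable) next
    out <- if (gene_test_for_mask(s$mask) == "burden")
      burden_score_test(s, x)
    else skato_test(s, x, config = cfg$skato_cfg)
    res[[paste0(s$gene, ":", s$mask)]] <- out
  }
  res
}

#' Run the full discovery pipeline on a two-stage dataset
#'
#' @param stage1,stage2 [cohort()] objects with annotations attached
#'   (stage2 may be NULL for a single-stage run).
#' @param cfg a [run_config()].
#' @param kinship1 optional kinship pairs for stage-1 sample QC.
#' @param gene_sets optional named list of gene sets for enrichment.
#' @param out_dir optional directory: when given, all result tables are
#'   written as TSVs plus a `manifest.txt`.
#' @return list with qc reports, mask tables, gene/variant/meta results,
#'   LOO traces, candidate decisions and enrichment results.
#' @export
run_pipeline <- function(stage1, stage2 = NULL, cfg = run_config(),
                         kinship1 = NULL, gene_sets = NULL, out_dir = NULL) {
  t0 <- Sys.time()
  qc1 <- apply_qc(stage1, qc_profile_stage1(), kinship = kinship1)
  s1 <- qc1$dataset
  qc2 <- NULL; s2 <- NULL
  if (!is.null(stage2)) {
    qc2 <- apply_qc(stage2, qc_profile_stage2())
    s2 <- qc2$dataset
  }

  setups1 <- lapply(cfg$masks, function(mk) build_mask(s1, mk, cfg$mask_cfg))
  names(setups1) <- cfg$masks
  gene_res1 <- list()
  for (mk in cfg$masks)
    gene_res1 <- c(gene_res1, run_gene_tests(s1, setups1[[mk]], cfg))

  sv1 <- lapply(seq_len(n_variants(s1)), function(j)
    tryCatch(single_variant_lrt(s1$geno[, j], s1$samples$status,
                                s1$variants$key[j]),
             error = function(e) NULL))
  sv1 <- Filter(Negate(is.null), sv1)

  # leave-one-out for BROAD hits
  loo <- list()
  if ("BROAD" %in% cfg$masks) {
    for (s in setups1$BROAD) {
      if (!s$testable) next
      r <- gene_res1[[paste0(s$gene, ":BROAD")]]
      if (!is.null(r) && r$result$p < cfg$select_p &&
          !is.na(r$result$or_freq) && r$result$or_freq > 1)
        loo[[s$gene]] <- leave_one_out(s, s1, "skato", cfg$skato_cfg,
                                       stop_p = cfg$loo_stop_p,
                                       nominal_p = cfg$nominal_p)
    }
  }
  decisions <- select_candidates(lapply(gene_res1, `[[`, "result"), loo, sv1,
                                 cfg$select_p, cfg$bonferroni_p)

  # stage-2 tests and cross-stage meta for genes carried forward
  meta_res <- list(); gene_res2 <- list()
  if (!is.null(s2)) {
    setups2 <- lapply(cfg$masks, function(mk) build_mask(s2, mk, cfg$mask_cfg))
    names(setups2) <- cfg$masks
    for (mk in cfg$masks)
      gene_res2 <- c(gene_res2, run_gene_tests(s2, setups2[[mk]], cfg))
    carried <- decisions$unit[decisions$kind == "gene" &
                                decisions$decision != "drop"]
    for (u in carried) {
      r1 <- gene_res1[[u]]; r2 <- gene_res2[[u]]
      if (is.null(r1) || is.null(r2)) next
      scores <- list(r1$score, r2$score)
      mk <- strsplit(u, ":", fixed = TRUE)[[1]][2]
      meta_res[[u]] <- if (gene_test_for_mask(mk) == "burden")
        meta_burden(scores)
      else meta_skato(scores, cfg$skato_cfg)
    }
  }

  enrich <- list()
  if (!is.null(gene_sets)) {
    for (mk in cfg$masks) {
      bm <- build_burden_matrix(s1, setups1[[mk]])
      for (sn in names(gene_sets)) {
        members <- intersect(gene_sets[[sn]], colnames(bm$counts))
        if (!length(members)) next
        enrich[[paste0(sn, ":", mk)]] <-
          enrichment_permutation(bm, gene_sets[[sn]], B = cfg$n_perm,
                                 seed = cfg$seed, set_name = sn)
      }
    }
  }

  out <- list(qc1 = qc1$report, qc2 = if (!is.null(qc2)) qc2$report,
              stage1 = s1, stage2 = s2,
              masks1 = setups1,
              gene_results1 = gene_res1, gene_results2 = gene_res2,
              variant_results1 = sv1, loo = loo, decisions = decisions,
              meta = meta_res, enrichment = enrich, config = cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, t0)
  out
}

write_pipeline_outputs <- function(out, out_dir, t0 = Sys.time()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wt(mask_table(do.call(c, unname(out$masks1))), "masks_stage1.tsv")
  if (length(out$gene_results1))
    wt(assoc_table(lapply(out$gene_results1, `[[`, "result")),
       "gene_tests_stage1.tsv")
  if (length(out$gene_results2))
    wt(assoc_table(lapply(out$gene_results2, `[[`, "result")),
       "gene_tests_stage2.tsv")
  if (length(out$variant_results1))
    wt(assoc_table(out$variant_results1), "single_variant_stage1.tsv")
  if (length(out$meta)) wt(assoc_table(out$meta), "gene_tests_meta.tsv")
  if (length(out$loo))
    wt(do.call(rbind, lapply(out$loo, loo_table)), "loo_traces.tsv")
  wt(out$decisions, "candidate_decisions.tsv")
  if (length(out$enrichment))
    wt(do.call(rbind, lapply(out$enrichment, function(e)
      data.frame(set = e$set, mask = e$mask, n_genes = e$n_genes,
                 T_obs = e$T_obs, b = e$b, B = e$B, p_emp = e$p_emp,
                 p_adj = e$p_adj, or = e$or$or_freq, seed = e$seed))),
      "enrichment.tsv")
  manifest <- c(
    sprintf("package: exburden %s",
            as.character(utils::packageVersion("exburden"))),
    sprintf("seed: %d", out$config$seed),
    sprintf("config_hash: %s",
            paste0(format(sum(utils::object.size(out$config))), "B")),
    sprintf("stage1: %d samples x %d variants (post-QC)",
            n_samples(out$stage1), n_variants(out$stage1)),
    if (!is.null(out$stage2))
      sprintf("stage2: %d samples x %d variants (post-QC)",
              n_samples(out$stage2), n_variants(out$stage2)),
    sprintf("gene_tests_stage1: %d", length(out$gene_results1)),
    sprintf("elapsed_s: %.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
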
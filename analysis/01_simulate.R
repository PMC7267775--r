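#!/usr/bin/env Rscript
# Generate the synthetic two-stage cohort used by the downstream drivers.
#
# The stage-1 cohort is drawn at a 1/5 shrink of the 927 / 4,057 design
# (sizes scale, effects do not) so the full workflow runs in seconds;
# three genes carry planted carrier relative risks spanning the effect
# sizes the discovery design targets, and a sprinkling of QC violations
# exercises every rule of the stage-1 cascade. Everything downstream reads
# from results/data/.

library(exburden)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  seed = 20260930L,
  n_cases = 185L, n_controls = 811L,          # 1/5 of 927 / 4,057
  n_genes = 40L, mean_variants_per_gene = 8,
  gene_rr = c(GENE001 = 30, GENE002 = 12, GENE003 = 5),
  dd_fraction = 0.24,
  plant_qc = list(n_low_gq = 40, n_low_dp1 = 15, n_bad_ab = 10,
                  n_high_missing_variants = 4, n_bad_samples = 5,
                  n_contaminated = 3, n_kin_pairs = 3))
ts <- simulate_two_stage(cfg)

for (st in c("stage1", "stage2")) {
  sim <- ts[[st]]
  write_vcf(sim$dataset, file.path(out, paste0(st, ".vcf")))
  utils::write.table(sim$dataset$samples, file.path(out, paste0(st, "_samples.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ann <- sim$dataset$annotations
  utils::write.table(ann[, setdiff(names(ann), "key")],
                     file.path(out, paste0(st, "_annotations.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth$variants, file.path(out, paste0(st, "_truth_variants.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth$genes, file.path(out, paste0(st, "_truth_genes.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
}
kin <- ts$stage1$truth$kinship
if (!is.null(kin))
  utils::write.table(kin, file.path(out, "stage1_kinship.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

# gene sets: the three planted genes plus neighbours, and a null set
writeLines(c(paste(c("planted", ".", sprintf("GENE%03d", 1:5)), collapse = "\t"),
             paste(c("null_set", ".", sprintf("GENE%03d", 21:30)), collapse = "\t")),
           file.path(out, "gene_sets.gmt"))

writeLines(c(sprintf("seed: %d", cfg$seed),
             sprintf("stage1: %d cases / %d controls",
                     cfg$n_cases, cfg$n_controls),
             sprintf("stage2: %d samples", n_samples(ts$stage2$dataset)),
             sprintf("genes: %d  planted RRs: GENE001=30 GENE002=12 GENE003=5",
                     cfg$n_genes)),
           file.path(out, "manifest.txt"))
cat("simulated two-stage cohort written to", out, "\n")
cat(sprintf("  stage1: %d samples x %d variants\n",
            n_samples(ts$stage1$dataset), n_variants(ts$stage1$dataset)))
cat(sprintf("  stage2: %d samples x %d variants\n",
            n_samples(ts$stage2$dataset), n_variants(ts$stage2$dataset)))
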
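#!/usr/bin/env Rscript
# Quality control of both stages: read the simulated VCFs + metadata back
# through the package's I/O layer (exactly as real data would arrive), run
# the stage-specific cascades, and record what each rule removed. The
# planted violation counts from 01_simulate.R are the truth this run
# should (and does) recover.

library(exburden)

dat <- "results/data"
out <- "results"
dir.create(out, showWarnings = FALSE)

load_stage <- function(st) {
  samples <- utils::read.delim(file.path(dat, paste0(st, "_samples.tsv")))
  co <- read_vcf(file.path(dat, paste0(st, ".vcf")), samples = samples)
  attach_annotations(co,
                     read_annotations(file.path(dat, paste0(st, "_annotations.tsv"))))
}

s1 <- load_stage("stage1")
kin_path <- file.path(dat, "stage1_kinship.tsv")
kin <- if (file.exists(kin_path)) read_kinship(kin_path) else NULL
qc1 <- apply_qc(s1, qc_profile_stage1(), kinship = kin)

s2 <- load_stage("stage2")
qc2 <- apply_qc(s2, qc_profile_stage2())

report_rows <- function(rep, stage) {
  do.call(rbind, lapply(c("genotype", "variant", "sample"), function(lvl) {
    if (!length(rep[[lvl]])) return(NULL)
    data.frame(stage = stage, level = lvl, rule = names(rep[[lvl]]),
               n_removed = unlist(rep[[lvl]], use.names = FALSE))
  }))
}
tab <- rbind(report_rows(qc1$report, "stage1"), report_rows(qc2$report, "stage2"))
utils::write.table(tab, file.path(out, "qc_report.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)

for (st in list(list("stage1", qc1), list("stage2", qc2))) {
  write_vcf(st[[2]]$dataset, file.path(dat, paste0(st[[1]], "_postqc.vcf")))
  utils::write.table(st[[2]]$dataset$samples,
                     file.path(dat, paste0(st[[1]], "_postqc_samples.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
}

cat("stage 1:", n_samples(s1), "->", n_samples(qc1$dataset), "samples;",
    n_variants(s1), "->", n_variants(qc1$dataset), "variants\n")
cat("stage 2:", n_samples(s2), "->", n_samples(qc2$dataset), "samples;",
    n_variants(s2), "->", n_variants(qc2$dataset), "variants\n")
print(qc1$report)
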
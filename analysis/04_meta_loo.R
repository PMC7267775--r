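#!/usr/bin/env Rscript
# Stage-2 follow-up and cross-stage evidence: re-test the stage-1
# candidate genes in the independent stage-2 cohort, then combine the two
# stages by score pooling (U and V summed for the burden masks; pooled
# score vectors and covariances under SKAT-O for BROAD). Winner's curse is
# expected: stage-2 ORs should sit below their stage-1 counterparts.

library(exburden)

dat <- "results/data"
out <- "results"

load_stage <- function(st) {
  samples <- utils::read.delim(file.path(dat, paste0(st, "_postqc_samples.tsv")))
  co <- read_vcf(file.path(dat, paste0(st, "_postqc.vcf")), samples = samples)
  attach_annotations(co, read_annotations(file.path(dat, paste0(st, "_annotations.tsv"))))
}
s1 <- load_stage("stage1")
s2 <- load_stage("stage2")
decisions <- utils::read.delim(file.path(out, "candidate_decisions.tsv"))
carried <- decisions$unit[decisions$kind == "gene" & decisions$decision != "drop"]

cfg <- run_config(seed = 20260930L,
                  mask_cfg = mask_config(very_rare_threshold = 0.00125))
masks2 <- lapply(c("LOF", "STRICT", "BROAD"), function(mk) build_mask(s2, mk, cfg$mask_cfg))
names(masks2) <- c("LOF", "STRICT", "BROAD")
masks1 <- lapply(c("LOF", "STRICT", "BROAD"), function(mk) build_mask(s1, mk, cfg$mask_cfg))
names(masks1) <- c("LOF", "STRICT", "BROAD")

find_setup <- function(masks, gene, mk)
  Filter(function(s) s$gene == gene && s$testable, masks[[mk]])

stage2_rows <- list(); meta_rows <- list()
for (u in carried) {
  parts <- strsplit(u, ":", fixed = TRUE)[[1]]
  gene <- parts[1]; mk <- parts[2]
  su1 <- find_setup(masks1, gene, mk); su2 <- find_setup(masks2, gene, mk)
  if (!length(su1) || !length(su2)) next
  runner <- function(su, x) if (mk == "BROAD")
    skato_test(su, x, config = cfg$skato_cfg) else burden_score_test(su, x)
  r1 <- runner(su1[[1]], s1); r2 <- runner(su2[[1]], s2)
  stage2_rows[[u]] <- r2$result
  meta_rows[[u]] <- if (mk == "BROAD")
    meta_skato(list(r1$score, r2$score), cfg$skato_cfg)
  else meta_burden(list(r1$score, r2$score))
}

if (length(stage2_rows)) {
  utils::write.table(assoc_table(stage2_rows),
                     file.path(out, "gene_tests_stage2.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(assoc_table(meta_rows),
                     file.path(out, "gene_tests_meta.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cat("stage 1+2 combined results for carried genes:\n")
  tab <- assoc_table(meta_rows)
  print(tab[order(tab$p), c("unit", "a", "b", "or_freq", "p")],
        row.names = FALSE)
} else {
  cat("no carried genes were testable in both stages\n")
}
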
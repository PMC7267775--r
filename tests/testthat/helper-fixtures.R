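# Fixtures built in code: tiny cohorts, annotation tables and the printed
# contingency constructions used across test files.

# cohort with explicit dosage matrix; defaults give a 4-sample 2-case toy
toy_cohort <- function(geno, status = NULL, ...) {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(status)) status <- rep(c(1L, 0L), length.out = n)
  cohort(
    samples = data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                         status = status),
    variants = data.frame(chrom = "chr1", pos = seq_len(m) * 100L,
                          ref = "A", alt = "G"),
    geno = geno, ...)
}

# cohort of n1 cases / n0 controls where the first `carriers_case` cases and
# first `carriers_ctrl` controls are heterozygous for one of `m` variants
# (round-robin) — the construction behind the printed gene-test tables
carrier_cohort <- function(n1, n0, carriers_case, carriers_ctrl = 0, m = NULL) {
  if (is.null(m)) m <- max(2L, carriers_case + carriers_ctrl)
  n <- n1 + n0
  geno <- matrix(0L, n, m)
  if (carriers_case > 0)
    for (i in seq_len(carriers_case)) geno[i, 1L + (i - 1L) %% m] <- 1L
  if (carriers_ctrl > 0)
    for (i in seq_len(carriers_ctrl)) geno[n1 + i, 1L + (i - 1L) %% m] <- 1L
  toy_cohort(geno, status = c(rep(1L, n1), rep(0L, n0)))
}

gene_setup <- function(x, variants = NULL, gene = "GENE", mask = "LOF") {
  list(gene = gene, mask = mask,
       variants = variants %||% x$variants$key, testable = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# annotation table builder with sane defaults
make_ann <- function(chrom, pos, ref = "A", alt = "G", gene = "GENE",
                     consequence = "missense_variant",
                     sift = "missing", pp2_hdiv = "missing",
                     pp2_hvar = "missing", lrt = "missing",
                     mutation_taster = "missing",
                     af_AFR = 0, af_AMR = 0, af_ASN = 0, af_EUR = 0,
                     af_UK10K = 0) {
  ann <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    gene = gene, consequence = consequence, sift = sift,
                    pp2_hdiv = pp2_hdiv, pp2_hvar = pp2_hvar, lrt = lrt,
                    mutation_taster = mutation_taster, af_AFR = af_AFR,
                    af_AMR = af_AMR, af_ASN = af_ASN, af_EUR = af_EUR,
                    af_UK10K = af_UK10K, stringsAsFactors = FALSE)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann
}

# exact permutation p-value of a statistic over all case-label assignments
perm_pvalue <- function(G, n1, stat_fn, obs = NULL) {
  perm_bracket(G, n1, stat_fn, obs)[2]
}

# strict / inclusive permutation tails [P(stat > obs), P(stat >= obs)]:
# at these sample sizes the permutation law is coarse, so the two tails
# bracket any continuity convention an asymptotic p can be compared to
perm_bracket <- function(G, n1, stat_fn, obs = NULL) {
  n <- nrow(G)
  combs <- utils::combn(n, n1)
  y0 <- c(rep(1L, n1), rep(0L, n - n1))
  if (is.null(obs)) obs <- stat_fn(y0)
  stats <- apply(combs, 2, function(ix) {
    y <- rep(0L, n); y[ix] <- 1L
    stat_fn(y)
  })
  c(mean(stats > obs + 1e-12), mean(stats >= obs - 1e-12))
}
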
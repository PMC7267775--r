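# Permutation gene-set enrichment with exome-wide control, set-level ORs
# and the constraint-overlap chi-square.

#' Per-sample, per-gene qualifying-allele burden matrix
#'
#' Counts qualifying minor alleles per sample in every gene of a mask
#' (genes with a single qualifying variant included: set-level aggregation
#' uses all qualifying variants) plus each sample's exome-wide total.
#'
#' @param x a [cohort()].
#' @param setups mask setups from [build_mask()].
#' @return a `burden_matrix`: list(counts = samples x genes matrix,
#'   exome_total = per-sample totals, status, dd_flag, mask).
#' @export
build_burden_matrix <- function(x, setups) {
  genes <- vapply(setups, `[[`, "", "gene")
  counts <- matrix(0, n_samples(x), length(genes),
                   dimnames = list(x$samples$sample_id, genes))
  for (i in seq_along(setups)) {
    j <- match(setups[[i]]$variants, x$variants$key)
    counts[, i] <- rowSums(x$geno[, j, drop = FALSE], na.rm = TRUE)
  }
  structure(list(counts = counts, exome_total = rowSums(counts),
                 status = x$samples$status, dd_flag = x$samples$dd_flag,
                 mask = if (length(setups)) setups[[1]]$mask else NA_character_),
            class = "burden_matrix")
}

# ratio-of-ratios enrichment statistic; 0.5 continuity on a zero control
# set-burden, and T = 0 when the case group carries no set burden at all
enrich_stat <- function(set_burden, exome_burden, is_case) {
  num <- mean(set_burden[is_case]) / max(mean(set_burden[!is_case]), .Machine$double.eps)
  den <- mean(exome_burden[is_case]) / max(mean(exome_burden[!is_case]), .Machine$double.eps)
  flag <- FALSE
  if (mean(set_burden[!is_case]) == 0) {
    n1 <- sum(is_case); n0 <- sum(!is_case)
    num <- ((sum(set_burden[is_case]) + 0.5) / n1) /
      ((sum(set_burden[!is_case]) + 0.5) / n0)
    flag <- TRUE
  }
  t <- if (mean(set_burden[is_case]) == 0 || den == 0) 0 else num / den
  list(t = t, continuity = flag)
}

#' Permutation test of gene-set enrichment
#'
#' Observed statistic T = (mean case set-burden / mean control set-burden)
#' divided by (mean case exome-burden / mean control exome-burden) — the
#' exome-wide ratio in the denominator controls for global case-control
#' burden differences. Case/control labels are permuted B times with the
#' burden matrix fixed; the empirical p is (1 + #\{T_perm >= T_obs\}) /
#' (1 + B), and the adjusted p applies a Bonferroni factor of 10 for the
#' primary gene sets. The set OR is [allele_or()] on the aggregated set
#' allele counts.
#'
#' @param bm a [build_burden_matrix()] result.
#' @param gene_set character vector of member genes (intersected with the
#'   matrix's genes; must overlap).
#' @param B number of permutations (study default 20000).
#' @param seed RNG seed, recorded in the result.
#' @param n_primary_sets Bonferroni factor for the adjusted p (default 10).
#' @param set_name label.
#' @return an `enrichment_result`.
#' @export
enrichment_permutation <- function(bm, gene_set, B = 20000L, seed = 1L,
                                   n_primary_sets = 10L,
                                   set_name = "set") {
  stopifnot(B >= 1)
  members <- intersect(gene_set, colnames(bm$counts))
  if (!length(members)) stop("gene set has no overlap with the burden matrix")
  set_burden <- rowSums(bm$counts[, members, drop = FALSE])
  is_case <- bm$status == 1L
  if (!any(is_case) || !any(!is_case)) stop("need both cases and controls")
  obs <- enrich_stat(set_burden, bm$exome_total, is_case)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  n <- length(is_case)
  n_case <- sum(is_case)
  exceed <- 0L
  for (b in seq_len(B)) {
    perm <- logical(n)
    perm[sample.int(n, n_case)] <- TRUE
    tp <- enrich_stat(set_burden, bm$exome_total, perm)$t
    if (tp >= obs$t) exceed <- exceed + 1L
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  p_emp <- (exceed + 1) / (B + 1)
  counts <- allele_counts(sum(set_burden[is_case]), sum(set_burden[!is_case]),
                          sum(is_case), sum(!is_case),
                          n_variants = max(1L, ncol(bm$counts)))
  structure(list(
    set = set_name, mask = bm$mask, n_genes = length(members),
    T_obs = obs$t, b = exceed, B = B, p_emp = p_emp,
    p_adj = min(1, n_primary_sets * p_emp),
    counts = counts, or = allele_or(counts), seed = seed,
    flags = if (obs$continuity) "continuity_corrected" else character()
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment> %s [%s] %d genes  T = %.3f  p_emp = %.4g (b=%d/B=%d)  OR = %.3f\n",
              x$set, x$mask, x$n_genes, x$T_obs, x$p_emp, x$b, x$B,
              x$or$or_freq))
  invisible(x)
}

#' Chi-square test of class overlap between a gene set and the genome
#'
#' 1-df chi-square of independence (no continuity correction) on the 2x2
#' of set membership x class membership, e.g. how often constrained genes
#' (pLI > 0.9) occur inside a gene set versus genome-wide.
#'
#' @param set_size number of genes in the set.
#' @param overlap genes in the set that belong to the class.
#' @param universe_size total genes in the genome/universe.
#' @param class_size genes in the universe belonging to the class.
#' @return list(percent_set, percent_universe, stat, p).
#' @export
set_overlap_chisq <- function(set_size, overlap, universe_size, class_size) {
  stopifnot(overlap <= set_size, set_size <= universe_size,
            class_size <= universe_size, overlap <= class_size)
  tab <- matrix(c(overlap, set_size - overlap,
                  class_size - overlap,
                  universe_size - set_size - class_size + overlap), 2, 2)
  percent_set <- 100 * overlap / set_size
  percent_universe <- 100 * class_size / universe_size
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(percent_set = percent_set,
                percent_universe = percent_universe, stat = 0, p = 1))
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expd)^2 / expd)
  list(percent_set = percent_set, percent_universe = percent_universe,
       stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Enrichment stratified by developmental delay
#'
#' Repeats the permutation enrichment twice: cases restricted to the
#' developmental-delay stratum (with all controls), then to the non-DD
#' stratum.
#'
#' @inheritParams enrichment_permutation
#' @return list(dd = enrichment_result, non_dd = enrichment_result).
#' @export
stratified_enrichment <- function(bm, gene_set, B = 20000L, seed = 1L,
                                  n_primary_sets = 10L, set_name = "set") {
  is_case <- bm$status == 1L
  if (any(is_case & is.na(bm$dd_flag)))
    stop("dd_flag must be defined for all cases")
  run <- function(keep_case, label) {
    keep <- !is_case | keep_case
    if (!any(is_case & keep_case))
      stop("empty case stratum: ", label)
    sub <- structure(list(counts = bm$counts[keep, , drop = FALSE],
                          exome_total = bm$exome_total[keep],
                          status = bm$status[keep],
                          dd_flag = bm$dd_flag[keep], mask = bm$mask),
                     class = "burden_matrix")
    enrichment_permutation(sub, gene_set, B, seed, n_primary_sets,
                           paste0(set_name, ":", label))
  }
  list(dd = run(!is.na(bm$dd_flag) & bm$dd_flag == 1L, "dd"),
       non_dd = run(!is.na(bm$dd_flag) & bm$dd_flag == 0L, "non_dd"))
}
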
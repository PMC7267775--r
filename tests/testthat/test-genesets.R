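make_bm <- function(counts, status, dd = NULL, mask = "STRICT") {
  structure(list(counts = counts, exome_total = rowSums(counts),
                 status = status,
                 dd_flag = dd %||% rep(NA_integer_, length(status)),
                 mask = mask), class = "burden_matrix")
}

test_that("burden matrix counts qualifying alleles per sample and gene", {
  geno <- matrix(0L, 6, 4)
  geno[1, 1] <- 1L; geno[1, 2] <- 1L    # sample 1: 2 alleles in gene A
  geno[2, 3] <- 2L                      # sample 2: hom in gene B
  co <- toy_cohort(geno)
  setups <- list(list(gene = "A", mask = "STRICT",
                      variants = co$variants$key[1:2], testable = TRUE),
                 list(gene = "B", mask = "STRICT",
                      variants = co$variants$key[3], testable = FALSE))
  bm <- build_burden_matrix(co, setups)
  expect_equal(unname(bm$counts[1, ]), c(2, 0))
  expect_equal(unname(bm$counts[2, ]), c(0, 2))
  expect_equal(unname(bm$exome_total), c(2, 2, 0, 0, 0, 0))
  # empty mask gives an empty matrix
  bm0 <- build_burden_matrix(co, list())
  expect_equal(ncol(bm0$counts), 0L)
})

test_that("the all-genes set is self-normalizing: T is exactly 1 and the
           permutation distribution degenerate", {
  set.seed(31)
  counts <- matrix(rpois(200 * 10, 0.2), 200, 10,
                   dimnames = list(NULL, paste0("G", 1:10)))
  status <- rep(c(1L, 0L), each = 100)
  bm <- make_bm(counts, status)
  r <- enrichment_permutation(bm, paste0("G", 1:10), B = 200, seed = 2)
  expect_equal(r$T_obs, 1, tolerance = 1e-12)
  # every permutation tie-exceeds the observed value
  expect_equal(r$b, 200L)
  expect_equal(r$p_emp, 1)
})

test_that("empirical p respects its formula bounds and B = 1 cases", {
  set.seed(32)
  counts <- matrix(rpois(100 * 6, 0.3), 100, 6,
                   dimnames = list(NULL, paste0("G", 1:6)))
  bm <- make_bm(counts, rep(c(1L, 0L), each = 50))
  r1 <- enrichment_permutation(bm, c("G1", "G2"), B = 1, seed = 3)
  expect_true(r1$p_emp %in% c(0.5, 1))
  r2 <- enrichment_permutation(bm, c("G1", "G2"), B = 99, seed = 3)
  expect_gte(r2$p_emp, 1 / 100)
  expect_lte(r2$p_emp, 1)
  expect_equal(r2$p_emp, (r2$b + 1) / (r2$B + 1))
  expect_equal(r2$p_adj, min(1, 10 * r2$p_emp))
})

test_that("a planted 2-fold enriched set is detected at fixed seed", {
  set.seed(77)
  n <- 1000; status <- rep(c(1L, 0L), each = 500)
  n_genes <- 200; set_genes <- paste0("G", 1:50)
  lam <- matrix(0.05, n, n_genes)
  lam[status == 1L, 1:50] <- 0.10          # 2-fold case excess inside the set
  counts <- matrix(rpois(n * n_genes, lam), n, n_genes,
                   dimnames = list(NULL, paste0("G", 1:n_genes)))
  bm <- make_bm(counts, status)
  r <- enrichment_permutation(bm, set_genes, B = 2000, seed = 5)
  expect_lte(r$p_emp, 0.01)
  expect_gt(r$T_obs, 1.5)
})

test_that("empirical p is uniform under the null generator", {
  set.seed(78)
  n <- 300; status <- rep(c(1L, 0L), each = 150)
  n_genes <- 60
  pvals <- vapply(1:200, function(i) {
    counts <- matrix(rpois(n * n_genes, 0.08), n, n_genes,
                     dimnames = list(NULL, paste0("G", 1:n_genes)))
    bm <- make_bm(counts, status)
    enrichment_permutation(bm, paste0("G", 1:10), B = 99, seed = i)$p_emp
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("constraint-overlap chi-square reproduces the GWAS-set contrast", {
  # 53 constrained genes among 157 in the set; 19.1% prevalence genome-wide
  universe <- 18241; class_size <- round(0.191 * universe)
  r <- set_overlap_chisq(157, 53, universe, class_size)
  expect_equal(r$percent_set, 33.8, tolerance = 0.01)
  expect_equal(r$percent_universe, 19.1, tolerance = 0.05)
  expect_lt(r$p, 1e-5)
  # direct formula oracle on a small table
  r2 <- set_overlap_chisq(20, 10, 100, 30)
  tab <- matrix(c(10, 10, 20, 60), 2)
  expd <- outer(rowSums(tab), colSums(tab)) / 100
  expect_equal(r2$stat, sum((tab - expd)^2 / expd), tolerance = 1e-12)
  # overlap proportional to prevalence: no signal
  r3 <- set_overlap_chisq(50, 10, 500, 100)
  expect_equal(r3$stat, 0, tolerance = 1e-12)
  expect_equal(r3$p, 1)
})

test_that("stratified enrichment separates a DD-only planted signal", {
  set.seed(79)
  n1 <- 400; n0 <- 400
  status <- rep(c(1L, 0L), c(n1, n0))
  dd <- c(rep(c(1L, 0L), each = n1 / 2), rep(NA_integer_, n0))
  n_genes <- 100
  lam <- matrix(0.05, n1 + n0, n_genes)
  lam[seq_len(n1 / 2), 1:30] <- 0.15     # enrichment only in DD cases
  counts <- matrix(rpois((n1 + n0) * n_genes, lam), n1 + n0, n_genes,
                   dimnames = list(NULL, paste0("G", 1:n_genes)))
  bm <- make_bm(counts, status, dd)
  st <- stratified_enrichment(bm, paste0("G", 1:30), B = 500, seed = 6)
  expect_lt(st$dd$p_emp, 0.05)
  expect_lt(st$dd$p_emp, st$non_dd$p_emp)

  # all cases in one stratum: the other errors
  bm2 <- make_bm(counts, status, c(rep(1L, n1), rep(NA_integer_, n0)))
  expect_error(stratified_enrichment(bm2, paste0("G", 1:30), B = 10, seed = 1),
               "empty case stratum")
})
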
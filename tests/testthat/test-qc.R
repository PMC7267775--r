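qc_noise <- function(co, gq = 80, dp = 40) {
  # attach clean quality fields so profile rules have something to read
  n <- n_samples(co); m <- n_variants(co)
  co$gq <- matrix(gq, n, m); co$dp <- matrix(dp, n, m)
  ada <- matrix(0L, n, m)
  ada[co$geno == 1L & !is.na(co$geno)] <- dp / 2
  ada[co$geno == 2L & !is.na(co$geno)] <- dp
  co$ad_alt <- ada; co$ad_ref <- matrix(dp, n, m) - ada
  dimnames(co$gq) <- dimnames(co$dp) <- dimnames(co$ad_alt) <-
    dimnames(co$ad_ref) <- dimnames(co$geno)
  co
}

test_that("stage-2 genotype rules: moderate allelic balance needs depth > 25", {
  co <- qc_noise(toy_cohort(matrix(c(1L, 1L, 1L), 3, 1)))
  co$dp[] <- c(20, 30, 30)
  co$ad_alt[] <- round(c(20, 30, 30) * 0.25)   # AB = 0.25 for all three
  co$ad_ref[] <- co$dp - co$ad_alt
  res <- apply_genotype_qc(co, qc_profile_stage2())
  # DP 20 in the moderate band -> missing; DP 30 -> retained
  expect_true(is.na(res$dataset$geno[1, 1]))
  expect_equal(res$dataset$geno[2, 1], 1L)
  expect_equal(res$report$genotype[["moderate_ab_low_dp"]], 1L)
})

test_that("stage-2 genotype rules: depth, GQ by class, AB window, indel depth", {
  co <- toy_cohort(matrix(1L, 6, 2))
  co$variants$variant_class <- c("snp", "indel")
  co <- qc_noise(co)
  p <- qc_profile_stage2()
  co$dp[1, 1] <- 14                                  # DP < 15
  co$gq[2, 1] <- 19                                  # SNP GQ < 20
  co$gq[3, 2] <- 59                                  # indel GQ < 60
  co$ad_alt[4, 1] <- round(0.10 * co$dp[4, 1])       # AB 0.10 < 0.15
  co$ad_ref[4, 1] <- co$dp[4, 1] - co$ad_alt[4, 1]
  co$dp[5, 2] <- 2500                                # indel DP > 2000
  res <- apply_genotype_qc(co, p)
  expect_true(all(is.na(res$dataset$geno[cbind(1:5, c(1, 1, 2, 1, 2))])))
  expect_equal(res$dataset$geno[6, 1], 1L)
  expect_equal(res$report$genotype[["dp_below_min"]], 1L)
  expect_equal(res$report$genotype[["gq_below_min"]], 2L)
  expect_equal(res$report$genotype[["ab_outside_window"]], 1L)
  expect_equal(res$report$genotype[["indel_dp_above_max"]], 1L)
})

test_that("stage-1 genotype rules: GQ 30 boundary, DP1, AB 0.2-0.8", {
  co <- qc_noise(toy_cohort(matrix(c(0L, 0L, 1L, 1L, 1L), 5, 1)))
  p <- qc_profile_stage1()
  co$gq[1, 1] <- 50   # hom-ref, retained
  co$gq[2, 1] <- 29   # hom-ref, GQ < 30 -> missing
  co$ad_alt[3, 1] <- 1; co$ad_ref[3, 1] <- 39          # DP1 < 2
  co$ad_alt[4, 1] <- 34; co$ad_ref[4, 1] <- 6          # AB 0.85 > 0.8
  res <- apply_genotype_qc(co, p)
  expect_equal(res$dataset$geno[1, 1], 0L)
  expect_true(is.na(res$dataset$geno[2, 1]))
  expect_true(is.na(res$dataset$geno[3, 1]))
  expect_true(is.na(res$dataset$geno[4, 1]))
  expect_equal(res$dataset$geno[5, 1], 1L)
})

test_that("variant QC enforces group call rates and their difference", {
  # 100 cases, 100 controls; v1 has 11% missing among cases (CR 0.89);
  # v2 has case CR 0.99 and control CR 0.96 (diff 3% > 2.5%); v3 clean
  n <- 200
  geno <- matrix(0L, n, 3)
  geno[sample(1:100, 11), 1] <- NA
  geno[1, 2] <- NA
  geno[101:104, 2] <- NA
  co <- toy_cohort(geno, status = rep(c(1L, 0L), each = 100))
  res <- apply_variant_qc(co, qc_profile_stage2())
  expect_equal(n_variants(res$dataset), 1L)
  expect_equal(res$dataset$variants$pos, 300L)
  expect_equal(res$report$variant[["group_call_rate"]], 1L)
  expect_equal(res$report$variant[["call_rate_diff"]], 1L)
})

test_that("stage-1 variant QC drops HWE violations and keeps clean sites", {
  # v1: strong heterozygote deficit (50/0/50); v2: perfect HWE 25/50/25
  geno <- cbind(rep(c(0L, 2L), each = 50),
                rep(c(0L, 1L, 2L), c(25, 50, 25)))
  co <- qc_noise(toy_cohort(geno))
  res <- apply_variant_qc(co, qc_profile_stage1())
  expect_equal(res$report$variant[["hwe"]], 1L)
  expect_equal(n_variants(res$dataset), 1L)
})

test_that("sample QC applies thresholds and kinship resolution", {
  co <- toy_cohort(matrix(0L, 6, 2), status = rep(c(1L, 0L), 3))
  co$samples$missing_rate <- c(0.16, 0.01, 0.02, 0.01, 0.0, 0.0)
  co$samples$mean_depth <- c(30, 30, 30, 11, 30, 30)
  co$samples$contamination <- c(0, 0, 0, 0, 0.03, 0)
  kin <- data.frame(id1 = "s002", id2 = "s003", pi_hat = 0.5)
  res <- apply_sample_qc(co, qc_profile_stage1(), kin)
  # dropped: s001 (missing 0.16), s004 (depth 11), s005 (contamination 3%),
  # s003 (higher-missingness member of the related pair)
  expect_equal(res$dataset$samples$sample_id, c("s002", "s006"))
  expect_equal(res$report$sample[["missing_rate"]], 1L)
  expect_equal(res$report$sample[["mean_depth"]], 1L)
  expect_equal(res$report$sample[["contamination"]], 1L)
  expect_equal(res$report$sample[["kinship"]], 1L)

  # below-threshold pair retained
  kin2 <- data.frame(id1 = "s002", id2 = "s006", pi_hat = 0.124)
  res2 <- apply_sample_qc(res$dataset, qc_profile_stage1(), kin2)
  expect_equal(n_samples(res2$dataset), 2L)

  # unknown sample in pair: warn and skip
  kin3 <- data.frame(id1 = "s002", id2 = "nope", pi_hat = 0.5)
  expect_warning(apply_sample_qc(res$dataset, qc_profile_stage1(), kin3),
                 "unknown")
})

test_that("QC cascade is idempotent and never rewrites non-missing dosages", {
  set.seed(21)
  sim <- simulate_cohort(sim_config(seed = 21, n_cases = 40, n_controls = 60,
                                    n_genes = 6,
                                    plant_qc = list(n_low_gq = 10,
                                                    n_bad_samples = 2)))
  p <- qc_profile_stage1()
  once <- apply_qc(sim$dataset, p)
  twice <- apply_qc(once$dataset, p)
  expect_identical(once$dataset$geno, twice$dataset$geno)
  expect_identical(once$dataset$samples, twice$dataset$samples)
  expect_true(all(unlist(twice$report) == 0L))
  # surviving non-missing entries are unchanged
  keep_s <- match(once$dataset$samples$sample_id, sim$dataset$samples$sample_id)
  keep_v <- match(once$dataset$variants$key, sim$dataset$variants$key)
  orig <- sim$dataset$geno[keep_s, keep_v]
  now <- once$dataset$geno
  same <- !is.na(now)
  expect_identical(now[same], orig[same])
})

test_that("planted QC violations are each caught by the intended rule", {
  sim <- simulate_cohort(sim_config(
    seed = 33, n_cases = 50, n_controls = 80, n_genes = 8,
    plant_qc = list(n_low_gq = 12, n_low_dp1 = 7, n_bad_ab = 5,
                    n_high_missing_variants = 3, n_bad_samples = 4,
                    n_contaminated = 2, n_kin_pairs = 2)))
  p <- qc_profile_stage1()
  g <- apply_genotype_qc(sim$dataset, p)
  expect_equal(g$report$genotype[["gq_below_min"]], 12L)
  expect_equal(g$report$genotype[["dp1_below_min"]], 7L)
  expect_equal(g$report$genotype[["ab_outside_window"]], 5L)
  v <- apply_variant_qc(g$dataset, p)
  expect_equal(v$report$variant[["missingness"]], 3L)
  expect_equal(sort(v$dataset$variants$key),
               sort(setdiff(sim$dataset$variants$key,
                            sim$dataset$variants$key[sim$truth$qc$high_missing_variants])))
  s <- apply_sample_qc(v$dataset, p, sim$truth$kinship)
  expect_equal(s$report$sample[["missing_rate"]], 4L)
  expect_equal(s$report$sample[["contamination"]], 2L)
  expect_equal(s$report$sample[["kinship"]], 2L)
})
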
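test_that("frequency classing follows the panel-AND / group-OR rule", {
  cfg <- mask_config()
  pan <- rbind(rep(1e-4, 5),        # all panels very rare
               rep(0.004, 5),       # panels rare only
               c(0.02, rep(1e-4, 4)), # one panel common
               rep(NA_real_, 5))    # unobserved in panels
  grp <- rbind(c(2e-4, 1e-4),
               c(0.02, 0.005),      # control group qualifies at 1%
               c(1e-4, 1e-4),
               c(1e-4, 1e-4))
  expect_equal(frequency_class(pan, grp, cfg),
               c("very_rare", "rare", "common", "very_rare"))
})

test_that("frequency classing is monotone in panel AF", {
  set.seed(5)
  cfg <- mask_config()
  rank <- c(very_rare = 1, rare = 2, common = 3)
  for (i in 1:50) {
    pan <- matrix(runif(5, 0, 0.02), 1)
    grp <- matrix(runif(2, 0, 0.02), 1)
    base <- rank[frequency_class(pan, grp, cfg)]
    j <- sample(5, 1)
    pan2 <- pan; pan2[j] <- pan[j] + runif(1, 0, 0.05)
    expect_gte(rank[frequency_class(pan2, grp, cfg)], base)
  }
})

test_that("functional categories nest and map consequences correctly", {
  ann <- make_ann("chr1", 100L * (1:6),
                  consequence = c("stop_gained", "missense_variant",
                                  "missense_variant", "missense_variant",
                                  "synonymous_variant", "stop_lost"))
  # 5/5, 1/5, 0/5 damaging for the three missense rows
  for (p in c("sift", "pp2_hdiv", "pp2_hvar", "lrt", "mutation_taster"))
    ann[[p]][2] <- "damaging"
  ann$sift[3] <- "damaging"
  fc <- functional_category(ann)
  expect_equal(fc$is_lof, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(fc$is_strict, c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(fc$is_broad, c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(fc$is_synonymous, c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  # nesting holds row-wise
  expect_true(all(fc$is_broad[fc$is_strict]))
  expect_true(all(fc$is_strict[fc$is_lof]))
})

test_that("missing predictor verdicts count as not damaging by default", {
  ann <- make_ann("chr1", 100L, consequence = "missense_variant")
  expect_false(functional_category(ann)$is_broad)
  expect_true(functional_category(ann, missing_verdict_damaging = TRUE)$is_strict)
})

test_that("mask construction nests, excludes thin genes, respects MAF tiers", {
  # 10 samples; v1 LOF singleton, v2 strict-missense singleton,
  # v3 broad-only missense at cohort AF 5% but panel-rare (0.5%),
  # v4 synonymous singleton, v5 common in panels
  geno <- matrix(0L, 10, 5)
  geno[1, 1] <- 1L; geno[2, 2] <- 1L; geno[3, 3] <- 1L; geno[4, 4] <- 1L
  geno[5, 5] <- 1L
  co <- toy_cohort(geno)
  ann <- make_ann("chr1", co$variants$pos, gene = "G1",
                  consequence = c("frameshift_variant", "missense_variant",
                                  "missense_variant", "synonymous_variant",
                                  "missense_variant"))
  for (p in c("sift", "pp2_hdiv", "pp2_hvar", "lrt", "mutation_taster"))
    ann[[p]][2] <- "damaging"
  ann$sift[3] <- "damaging"; ann$sift[5] <- "damaging"
  ann[3, c("af_AFR", "af_AMR", "af_ASN", "af_EUR", "af_UK10K")] <- 0.005
  ann[5, c("af_AFR", "af_AMR", "af_ASN", "af_EUR", "af_UK10K")] <- 0.3
  co <- attach_annotations(co, ann)
  cfg <- mask_config(very_rare_threshold = 0.06, rare_threshold = 0.2)

  lof <- build_mask(co, "LOF", cfg)
  strict <- build_mask(co, "STRICT", cfg)
  broad <- build_mask(co, "BROAD", cfg)
  syn <- build_mask(co, "SYNONYMOUS", cfg)
  ks <- function(x) if (length(x)) x[[1]]$variants else character()
  expect_equal(ks(lof), co$variants$key[1])
  expect_setequal(ks(strict), co$variants$key[1:2])
  expect_setequal(ks(broad), co$variants$key[1:3])
  expect_equal(ks(syn), co$variants$key[4])
  # nesting of per-gene variant lists
  expect_true(all(ks(lof) %in% ks(strict)))
  expect_true(all(ks(strict) %in% ks(broad)))
  # single-variant gene excluded from tests, retained for aggregation
  expect_false(lof[[1]]$testable)
  expect_true(broad[[1]]$testable)
  # a panel-common variant enters no mask
  expect_false(co$variants$key[5] %in% ks(broad))
  # empty dataset -> empty list
  expect_length(build_mask(subset_cohort(co, variants = integer(0)),
                           "BROAD", cfg), 0L)
})

test_that("simulated mask truth matches build_mask output on every variant", {
  sim <- simulate_cohort(sim_config(seed = 91, n_cases = 80,
                                    n_controls = 120, n_genes = 10))
  co <- sim$dataset
  tr <- sim$truth$variants
  cfg <- mask_config()
  got <- mask_table(build_mask(co, "BROAD", cfg))
  # truth-side reconstruction: broadly damaging and rare/very rare in a group
  fc <- functional_category(co$annotations)
  af_case <- cohort_af(co, co$samples$status == 1L)
  af_ctrl <- cohort_af(co, co$samples$status == 0L)
  pan <- as.matrix(co$annotations[, c("af_AFR", "af_AMR", "af_ASN",
                                      "af_EUR", "af_UK10K")])
  cls <- frequency_class(pan, cbind(af_case, af_ctrl), cfg)
  want <- co$annotations$key[fc$is_broad & cls %in% c("rare", "very_rare")]
  expect_setequal(got$key, want)
  # every LOF truth variant that is very rare must sit in the LOF mask
  got_lof <- mask_table(build_mask(co, "LOF", cfg))
  want_lof <- co$annotations$key[fc$is_lof & cls == "very_rare"]
  expect_setequal(got_lof$key, want_lof)
})

test_that("mask nesting holds for every simulated variant", {
  sim <- simulate_cohort(sim_config(seed = 17, n_cases = 60,
                                    n_controls = 90, n_genes = 12))
  co <- sim$dataset
  lof <- mask_table(build_mask(co, "LOF"))$key
  strict <- mask_table(build_mask(co, "STRICT"))$key
  broad <- mask_table(build_mask(co, "BROAD"))$key
  expect_true(all(lof %in% strict))
  expect_true(all(strict %in% broad))
})
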
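test_that("dosage encoding and missing-data convention survive VCF reading", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB",
    "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1\t0/0",
    "chr1\t200\t.\tC\tT\t.\t.\t.\tGT\t./.\t1/1"), vcf)
  co <- read_vcf(vcf)
  expect_equal(unname(co$geno[, 1]), c(1L, 0L))
  expect_equal(unname(co$geno[, 2]), c(NA_integer_, 2L))
  expect_equal(co$variants$key, c("chr1:100:A:G", "chr1:200:C:T"))
})

test_that("VCF round-trip preserves dosages, missingness and quality fields", {
  set.seed(11)
  geno <- matrix(sample(c(0L, 1L, 2L, NA), 15, replace = TRUE), 5, 3)
  dp <- matrix(20L + rpois(15, 10), 5, 3)
  ada <- matrix(rbinom(15, 10, 0.5), 5, 3)
  co <- toy_cohort(geno, gq = matrix(55L, 5, 3), dp = dp,
                   ad_ref = dp - ada, ad_alt = ada)
  f <- tempfile(fileext = ".vcf")
  write_vcf(co, f)
  back <- read_vcf(f)
  expect_identical(unname(back$geno), unname(co$geno))
  expect_equal(unname(back$gq), unname(co$gq))
  expect_equal(unname(back$dp), unname(co$dp))
  expect_equal(unname(back$ad_alt), unname(co$ad_alt))
  expect_equal(back$variants$key, co$variants$key)
})

test_that("multi-allelic records are split without losing alt alleles", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic Depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb\tc",
    "chr2\t500\t.\tA\tG,T\t.\t.\t.\tGT:AD\t0/1:5,4,0\t1/2:2,3,6\t2/2:1,0,9"),
    vcf)
  co <- read_vcf(vcf)
  expect_equal(nrow(co$variants), 2L)
  expect_equal(co$variants$alt, c("G", "T"))
  # allele 1 dosages: 0/1 -> 1, 1/2 -> 1, 2/2 -> 0
  expect_equal(unname(co$geno[, 1]), c(1L, 1L, 0L))
  # allele 2 dosages: 0, 1, 2
  expect_equal(unname(co$geno[, 2]), c(0L, 1L, 2L))
  # total alt count preserved across the split records
  expect_equal(sum(co$geno), 1L + 1L + 0L + 0L + 1L + 2L)
  # AD apportioned to the matching alt
  expect_equal(unname(co$ad_alt[, 1]), c(4, 3, 0))
  expect_equal(unname(co$ad_alt[, 2]), c(0, 6, 9))
})

test_that("annotation reader enforces schema and vocabularies", {
  f <- tempfile(fileext = ".tsv")
  ann <- make_ann("chr1", c(100L, 200L), alt = c("G", "T"),
                  consequence = c("stop_gained", "missense_variant"),
                  sift = c("missing", "damaging"))
  write.table(ann[, setdiff(names(ann), "key")], f, sep = "\t",
              row.names = FALSE, quote = FALSE)
  rd <- read_annotations(f)
  expect_equal(nrow(rd), 2L)
  expect_equal(rd$sift, c("missing", "damaging"))

  bad <- ann; bad$sift <- "deleterious"
  write.table(bad[, setdiff(names(bad), "key")], f, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_annotations(f), "verdict")

  bad2 <- ann; bad2$consequence <- "nonsense_term"
  write.table(bad2[, setdiff(names(bad2), "key")], f, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_annotations(f), "consequence")

  write.table(ann[, setdiff(names(ann), c("key", "sift"))], f, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_annotations(f), "sift")
})

test_that("annotation reader keys five rows uniquely", {
  f <- tempfile(fileext = ".tsv")
  ann <- make_ann("chr3", seq(100L, 500L, by = 100L))
  write.table(ann[, setdiff(names(ann), "key")], f, sep = "\t",
              row.names = FALSE, quote = FALSE)
  rd <- read_annotations(f)
  expect_equal(nrow(rd), 5L)
  expect_false(anyDuplicated(rd$key) > 0)
})

test_that("GMT reading handles membership, duplicates and empty sets", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("obesity1A\t.\tLEP\tMC4R",
               "dup_set\t.\tPHIP\tPHIP"), f)
  expect_warning(sets <- read_gene_sets(f), "duplicate")
  expect_equal(sets$obesity1A, c("LEP", "MC4R"))
  expect_equal(sets$dup_set, "PHIP")

  writeLines("empty_set\t.", f)
  expect_error(read_gene_sets(f), "empty")

  # a GWAS-scale set keeps all 157 unique members
  writeLines(paste(c("gwas", ".", sprintf("G%03d", 1:157)), collapse = "\t"), f)
  expect_length(read_gene_sets(f)$gwas, 157L)
})

test_that("cohort validates dimensions, dosage domain and duplicates", {
  expect_error(toy_cohort(matrix(3L, 2, 1)), "dosages")
  expect_error(
    cohort(data.frame(sample_id = c("a", "a"), status = c(0L, 1L)),
           data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G"),
           matrix(0L, 2, 1)), "duplicate")
  expect_error(
    cohort(data.frame(sample_id = c("a", "b"), status = c(0L, 1L)),
           data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G"),
           matrix(0L, 3, 1)), "matrix")
})

test_that("minor-allele flip in cohort_af targets the rarer allele", {
  co <- toy_cohort(matrix(c(2L, 2L, 1L, 1L, 0L, 0L), 3, 2))
  af <- cohort_af(co)
  expect_equal(unname(af), c(1 / 6, 1 / 6), ignore_attr = TRUE)
  expect_true(attr(af, "flipped")[1])
  expect_false(attr(af, "flipped")[2])
})
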
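#' @keywords internal
"_PACKAGE"

# Controlled vocabulary for variant consequences (one consequence per
# variant: the most severe across protein-coding transcripts, collapsed
# upstream by the annotation pipeline).
CONSEQUENCE_VOCAB <- c(
  "splice_donor_variant", "splice_acceptor_variant", "stop_gained",
  "frameshift_variant", "stop_lost", "initiator_codon_variant",
  "missense_variant", "synonymous_variant",
  "inframe_insertion", "inframe_deletion", "splice_region_variant"
)

# Predictor verdict vocabulary (SIFT, PolyPhen2 HDIV/HVAR, LRT,
# MutationTaster collapsed upstream to a three-way verdict).
VERDICT_VOCAB <- c("damaging", "benign", "missing")

PREDICTOR_COLS <- c("sift", "pp2_hdiv", "pp2_hvar", "lrt", "mutation_taster")
PANEL_COLS <- c("af_AFR", "af_AMR", "af_ASN", "af_EUR", "af_UK10K")

#' Build a variant key
#'
#' Canonical key identifying a biallelic variant: `chrom:pos:ref:alt`.
#'
#' @param chrom,pos,ref,alt vectors describing the variant(s).
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct a case-control cohort dataset
#'
#' The central container of the pipeline: a sample table, a variant table,
#' and aligned genotype-level matrices (dosage of the alternate allele plus
#' optional GQ / DP / allele-depth matrices). Dosages are 0, 1, 2 or `NA`
#' (missing). All analyses in the package consume this object.
#'
#' @param samples data frame with columns `sample_id`, `status` (1 = case,
#'   0 = control) and optionally `dd_flag` (developmental delay, 0/1/NA),
#'   `stage`, `missing_rate`, `mean_depth`, `contamination`.
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`, and
#'   optionally `variant_class` ("snp"/"indel"), `gene`.
#' @param geno integer matrix, samples x variants, entries in \{0, 1, 2, NA\}.
#' @param gq,dp,ad_ref,ad_alt optional numeric matrices with the same
#'   dimensions as `geno` carrying genotype quality, read depth and
#'   per-allele read depths.
#' @param annotations optional annotation table as returned by
#'   [read_annotations()].
#' @return an object of class `cohort`.
#' @export
cohort <- function(samples, variants, geno, gq = NULL, dp = NULL,
                   ad_ref = NULL, ad_alt = NULL, annotations = NULL) {
  samples <- as.data.frame(samples)
  variants <- as.data.frame(variants)
  stopifnot(
    all(c("sample_id", "status") %in% names(samples)),
    all(c("chrom", "pos", "ref", "alt") %in% names(variants))
  )
  if (!all(samples$status %in% c(0L, 1L)))
    stop("sample status must be 0 (control) or 1 (case)")
  if (any(variants$pos < 1)) stop("variant positions are 1-based (pos >= 1)")
  if (!"dd_flag" %in% names(samples)) samples$dd_flag <- NA_integer_
  if (!"variant_class" %in% names(variants))
    variants$variant_class <- ifelse(
      nchar(variants$ref) == 1L & nchar(variants$alt) == 1L, "snp", "indel")
  if (!"gene" %in% names(variants)) variants$gene <- NA_character_
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  if (anyDuplicated(variants$key))
    stop("duplicate variant keys: ", variants$key[duplicated(variants$key)][1])
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids")

  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(samples) || ncol(geno) != nrow(variants))
    stop(sprintf("dosage matrix is %d x %d but there are %d samples and %d variants",
                 nrow(geno), ncol(geno), nrow(samples), nrow(variants)))
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(samples$sample_id, variants$key)

  chk <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!all(dim(m) == dim(geno)))
      stop(what, " matrix dimensions do not match the dosage matrix")
    dimnames(m) <- dimnames(geno)
    m
  }
  obj <- structure(list(
    samples = samples, variants = variants, geno = geno,
    gq = chk(gq, "GQ"), dp = chk(dp, "DP"),
    ad_ref = chk(ad_ref, "AD ref"), ad_alt = chk(ad_alt, "AD alt"),
    annotations = annotations
  ), class = "cohort")
  if (!is.null(annotations)) obj <- attach_annotations(obj, annotations)
  obj
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples (%d cases / %d controls), %d variants\n",
              nrow(x$samples), sum(x$samples$status == 1),
              sum(x$samples$status == 0), nrow(x$variants)))
  if (!is.null(x$annotations))
    cat(sprintf("  annotations attached for %d variants\n",
                sum(x$variants$key %in% x$annotations$key)))
  invisible(x)
}

#' Number of samples / variants in a cohort
#' @param x a [cohort()] object.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a cohort by samples and/or variants
#'
#' @param x a [cohort()] object.
#' @param samples logical/integer/character index into the sample table.
#' @param variants logical/integer/character index into the variant table
#'   (character indices are variant keys).
#' @return the subset `cohort`.
#' @export
subset_cohort <- function(x, samples = NULL, variants = NULL) {
  si <- seq_len(nrow(x$samples))
  vi <- seq_len(nrow(x$variants))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$samples$sample_id) else si[samples]
    if (anyNA(si)) stop("unknown sample id in subset")
  }
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, x$variants$key) else vi[variants]
    if (anyNA(vi)) stop("unknown variant key in subset")
  }
  sub <- function(m) if (is.null(m)) NULL else m[si, vi, drop = FALSE]
  out <- x
  out$samples <- x$samples[si, , drop = FALSE]
  out$variants <- x$variants[vi, , drop = FALSE]
  out$geno <- x$geno[si, vi, drop = FALSE]
  out$gq <- sub(x$gq); out$dp <- sub(x$dp)
  out$ad_ref <- sub(x$ad_ref); out$ad_alt <- sub(x$ad_alt)
  rownames(out$samples) <- NULL; rownames(out$variants) <- NULL
  out
}

#' Attach an annotation table to a cohort
#'
#' Copies the gene symbol from the annotation table onto the variant table
#' (gene membership comes from annotation, never from a gene model) and
#' stores the table for mask construction.
#'
#' @param x a [cohort()] object.
#' @param annotations annotation table from [read_annotations()].
#' @return the cohort with annotations attached.
#' @export
attach_annotations <- function(x, annotations) {
  idx <- match(x$variants$key, annotations$key)
  x$variants$gene <- ifelse(is.na(idx), x$variants$gene, annotations$gene[idx])
  x$annotations <- annotations
  x
}

#' Cohort allele frequencies of the alternate allele
#'
#' Computed on non-missing calls only. With `minor = TRUE` the frequency of
#' the minor allele is returned: when the alt-allele frequency exceeds 0.5
#' the complement is used (and a flip is recorded in the `flipped`
#' attribute), since MAF-based thresholds address the rarer allele.
#'
#' @param x a [cohort()] object.
#' @param which optional logical/integer sample index restricting the
#'   frequency to an analysis group (e.g. cases only).
#' @param minor flip to the minor allele when alt AF > 0.5?
#' @return named numeric vector of allele frequencies (NaN when no calls).
#' @export
cohort_af <- function(x, which = NULL, minor = TRUE) {
  g <- if (is.null(which)) x$geno else x$geno[which, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  af <- colSums(g, na.rm = TRUE) / (2 * n_called)
  flipped <- !is.na(af) & af > 0.5
  if (minor && any(flipped)) af[flipped] <- 1 - af[flipped]
  attr(af, "flipped") <- flipped
  af
}

#' Per-variant minor-allele counts
#'
#' @param x a [cohort()] object.
#' @param which optional sample index (rows).
#' @return named integer vector of alt-allele counts over non-missing calls.
#' @export
alt_allele_count <- function(x, which = NULL) {
  g <- if (is.null(which)) x$geno else x$geno[which, , drop = FALSE]
  colSums(g, na.rm = TRUE)
}
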
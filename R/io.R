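# File I/O: VCF (via vcfR), annotation TSV, GMT gene sets, constraint,
# kinship and external-control count tables.

#' Read a VCF into a cohort dataset
#'
#' Parses a VCF v4.2 file (FORMAT fields GT required; GQ, DP, AD used when
#' present) into a [cohort()] with alt-allele dosages. Multi-allelic records
#' are split into biallelic records: for alternate allele k the dosage is
#' the number of GT alleles equal to k, and the allele-depth pair is
#' (AD ref, AD of allele k). Genotypes without GT (`./.`) are missing.
#'
#' Sample phenotype fields (status etc.) are not carried by VCF; pass a
#' sample table or set them afterwards.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sample_subset optional character vector of sample ids to keep.
#' @param samples optional sample data frame (matched on `sample_id`);
#'   defaults to status 0 for everyone.
#' @return a [cohort()].
#' @export
read_vcf <- function(path, sample_subset = NULL, samples = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("VCF parse error in '", path, "': ",
                                         conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L)
    stop("VCF has no genotype columns: ", path)
  ids <- colnames(gt_raw)[-1L]
  if (!is.null(sample_subset)) {
    miss <- setdiff(sample_subset, ids)
    if (length(miss)) stop("samples not in VCF: ", paste(miss, collapse = ", "))
    keep <- match(sample_subset, ids)
    gt_raw <- gt_raw[, c(1L, keep + 1L), drop = FALSE]
    ids <- sample_subset
  }
  n_rec <- nrow(fix)
  n_smp <- length(ids)

  # Per-record FORMAT layout may differ; resolve field positions per record.
  fmt_split <- strsplit(gt_raw[, 1L], ":", fixed = TRUE)
  cell_split <- vector("list", n_rec)
  for (r in seq_len(n_rec))
    cell_split[[r]] <- strsplit(gt_raw[r, -1L], ":", fixed = TRUE)

  out <- list()   # one element per biallelic output record
  for (r in seq_len(n_rec)) {
    fmt <- fmt_split[[r]]
    i_gt <- match("GT", fmt); i_gq <- match("GQ", fmt)
    i_dp <- match("DP", fmt); i_ad <- match("AD", fmt)
    if (is.na(i_gt))
      stop(sprintf("VCF record %d (%s:%s) lacks GT", r, fix$CHROM[r], fix$POS[r]))
    cells <- cell_split[[r]]
    field <- function(i) vapply(cells, function(x)
      if (!is.na(i) && length(x) >= i) x[[i]] else NA_character_, "")
    gts <- field(i_gt)
    alleles_l <- strsplit(gsub("|", "/", gts, fixed = TRUE), "/", fixed = TRUE)
    gq <- suppressWarnings(as.numeric(field(i_gq)))
    dp <- suppressWarnings(as.numeric(field(i_dp)))
    ad_l <- if (!is.na(i_ad)) strsplit(field(i_ad), ",", fixed = TRUE) else NULL
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1L]]
    for (k in seq_along(alts)) {
      dos <- vapply(alleles_l, function(a) {
        if (any(a %in% c(".", ""))) return(NA_integer_)
        sum(a == as.character(k))
      }, integer(1))
      adr <- ada <- rep(NA_real_, n_smp)
      if (!is.null(ad_l)) {
        adr <- vapply(ad_l, function(a)
          suppressWarnings(as.numeric(a[1L])), numeric(1))
        ada <- vapply(ad_l, function(a)
          if (length(a) >= k + 1L) suppressWarnings(as.numeric(a[k + 1L]))
          else NA_real_, numeric(1))
      }
      out[[length(out) + 1L]] <- list(
        chrom = fix$CHROM[r], pos = as.integer(fix$POS[r]),
        ref = fix$REF[r], alt = alts[k],
        dos = dos, gq = gq, dp = dp, adr = adr, ada = ada)
    }
  }
  variants <- data.frame(
    chrom = vapply(out, `[[`, "", "chrom"),
    pos = vapply(out, `[[`, 0L, "pos"),
    ref = vapply(out, `[[`, "", "ref"),
    alt = vapply(out, `[[`, "", "alt"),
    stringsAsFactors = FALSE)
  grab <- function(f) {
    m <- vapply(out, `[[`, numeric(n_smp), f)
    matrix(m, nrow = n_smp)
  }
  geno <- vapply(out, function(o) as.numeric(o$dos), numeric(n_smp))
  geno <- matrix(geno, nrow = n_smp)
  if (is.null(samples))
    samples <- data.frame(sample_id = ids, status = 0L,
                          stringsAsFactors = FALSE)
  else {
    samples <- as.data.frame(samples)
    idx <- match(ids, samples$sample_id)
    if (anyNA(idx)) stop("sample table lacks ids present in VCF")
    samples <- samples[idx, , drop = FALSE]
    rownames(samples) <- NULL
  }
  cohort(samples, variants, geno,
         gq = grab("gq"), dp = grab("dp"),
         ad_ref = grab("adr"), ad_alt = grab("ada"))
}

#' Write a cohort's genotypes as a VCF v4.2 file
#'
#' Plain-text output with FORMAT `GT:GQ:DP:AD` (fields absent from the
#' cohort are written as `.`). Dosage 0/1/2 is encoded as 0/0, 0/1, 1/1;
#' missing dosage as `./.`.
#'
#' @param x a [cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic Depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples$sample_id), collapse = "\t"))
  writeLines(hdr, con)
  gt_str <- matrix("./.", nrow = n_samples(x), ncol = n_variants(x))
  gt_str[!is.na(x$geno) & x$geno == 0L] <- "0/0"
  gt_str[!is.na(x$geno) & x$geno == 1L] <- "0/1"
  gt_str[!is.na(x$geno) & x$geno == 2L] <- "1/1"
  fmt_num <- function(m, j) {
    if (is.null(m)) return(rep(".", n_samples(x)))
    v <- m[, j]
    ifelse(is.na(v), ".", format(v, trim = TRUE, scientific = FALSE))
  }
  for (j in seq_len(n_variants(x))) {
    ad <- if (is.null(x$ad_ref) || is.null(x$ad_alt))
      rep(".", n_samples(x))
    else {
      a1 <- x$ad_ref[, j]; a2 <- x$ad_alt[, j]
      ifelse(is.na(a1) | is.na(a2), ".",
             paste0(format(a1, trim = TRUE, scientific = FALSE), ",",
                    format(a2, trim = TRUE, scientific = FALSE)))
    }
    cells <- paste(gt_str[, j], fmt_num(x$gq, j), fmt_num(x$dp, j), ad,
                   sep = ":")
    writeLines(paste(c(x$variants$chrom[j], x$variants$pos[j], ".",
                       x$variants$ref[j], x$variants$alt[j], ".", ".", ".",
                       "GT:GQ:DP:AD", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read the per-variant annotation table
#'
#' Tab-separated with columns `chrom, pos, ref, alt, gene, consequence,
#' sift, pp2_hdiv, pp2_hvar, lrt, mutation_taster, af_AFR, af_AMR, af_ASN,
#' af_EUR, af_UK10K`. Consequences must belong to the controlled vocabulary;
#' predictor verdicts must be `damaging`, `benign` or `missing` (empty / NA
#' cells are read as `missing`). Reference-panel AFs are in [0, 1]; an empty
#' cell means the allele is unobserved in that panel (treated as AF 0 by
#' frequency classing).
#'
#' @param path TSV file path.
#' @return data frame with one row per variant key.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
            PREDICTOR_COLS, PANEL_COLS)
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(ann$consequence), CONSEQUENCE_VOCAB)
  bad <- bad[!is.na(bad)]
  if (length(bad))
    stop("unknown consequence term(s): ", paste(bad, collapse = ", "))
  for (p in PREDICTOR_COLS) {
    ann[[p]][is.na(ann[[p]])] <- "missing"
    badv <- setdiff(unique(ann[[p]]), VERDICT_VOCAB)
    if (length(badv))
      stop("predictor '", p, "' has verdict(s) outside {damaging, benign, missing}: ",
           paste(badv, collapse = ", "))
  }
  for (p in PANEL_COLS) {
    v <- ann[[p]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("panel AF column '", p, "' outside [0, 1]")
  }
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(ann$key))
    stop("duplicate variant keys in annotation table")
  ann
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members within a set are removed with a warning; empty sets
#' are rejected.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene-set file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("gene set '", parts[1L], "' is empty")
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stop("gene set '", parts[1L], "' is empty")
    if (anyDuplicated(members)) {
      warning("gene set '", parts[1L], "' has duplicate members; deduplicated")
      members <- unique(members)
    }
    sets[[parts[1L]]] <- members
  }
  sets
}

#' Read a gene constraint table (gene, pli)
#'
#' @param path TSV with columns `gene` and `pli` (pLI in [0, 1] or NA).
#' @return data frame.
#' @export
read_constraint <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "pli") %in% names(tab)))
    stop("constraint table needs columns gene, pli")
  if (any(!is.na(tab$pli) & (tab$pli < 0 | tab$pli > 1)))
    stop("pLI outside [0, 1]")
  tab
}

#' Read kinship pairs (id1, id2, pi_hat)
#'
#' @param path TSV with columns `id1`, `id2`, `pi_hat`.
#' @return data frame of pairwise kinship estimates.
#' @export
read_kinship <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id1", "id2", "pi_hat") %in% names(tab)))
    stop("kinship table needs columns id1, id2, pi_hat")
  tab
}

#' Read external-control per-gene allele counts
#'
#' Summary counts from an external reference cohort (e.g. a public
#' aggregation database) usable without genotype-level data: per gene and
#' mask, the total functional and synonymous very-rare allele counts.
#'
#' @param path TSV with columns `gene`, `mask`, `fun_alleles`,
#'   `syn_alleles`, `n_samples`.
#' @return data frame.
#' @export
read_external_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "mask", "fun_alleles", "syn_alleles", "n_samples")
  if (!all(need %in% names(tab)))
    stop("external count table needs columns: ", paste(need, collapse = ", "))
  if (any(tab$fun_alleles < 0 | tab$syn_alleles < 0))
    stop("allele counts must be nonnegative")
  tab
}
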
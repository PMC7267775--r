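# Quality-control cascades: genotype -> variant -> sample -> variant.
# Three dialects are shipped as named profiles (stage1 exome joint calls,
# stage2 targeted amplicon sequencing, adult exome cohort); every rule is a
# plain field of the profile so any can be switched off (NULL) or retuned.

#' Quality-control profile
#'
#' Bundles genotype-, variant- and sample-level rules. `NULL` disables a
#' rule. See [qc_profile_stage1()], [qc_profile_stage2()],
#' [qc_profile_adult()] for the shipped dialects.
#'
#' @param name profile label.
#' @param genotype list of genotype rules: `min_dp`, `min_gq_snp`,
#'   `min_gq_indel`, `min_dp1` (minimum alternate-allele read depth),
#'   `ab_window` = c(lo, hi) allelic-balance window for heterozygotes,
#'   `ab_moderate` = list(windows = list(c(lo, hi), ...), min_dp) requiring
#'   extra depth for moderate allelic balance, `max_indel_dp`.
#' @param variant list of variant rules: `min_group_call_rate`,
#'   `max_call_rate_diff` (between cases and controls), `max_missing`,
#'   `min_hwe_p`, `min_mean_gq`, `coverage` = list(min_dp, min_frac).
#' @param sample list of sample rules: `max_missing_rate`, `min_mean_depth`,
#'   `max_contamination` (drop when >= threshold), `kinship_threshold`.
#' @param hwe_samples compute the HWE test on `"all"` retained samples or
#'   `"controls"` only.
#' @return an object of class `qc_profile`.
#' @export
qc_profile <- function(name, genotype = list(), variant = list(),
                       sample = list(), hwe_samples = c("all", "controls")) {
  hwe_samples <- match.arg(hwe_samples)
  if (!is.null(genotype$ab_window)) {
    w <- genotype$ab_window
    stopifnot(length(w) == 2L, w[1] >= 0, w[1] < w[2], w[2] <= 1)
  }
  structure(list(name = name, genotype = genotype, variant = variant,
                 sample = sample, hwe_samples = hwe_samples),
            class = "qc_profile")
}

#' Shipped QC profiles
#'
#' `stage1`: joint-called exomes — genotypes missing when GQ < 30,
#' alternate-allele read depth < 2, or het allelic balance outside
#' [0.2, 0.8]; variants dropped when missingness >= 20%, HWE chi-square
#' p <= 1e-8, mean GQ < 30, or covered at 7x in under 80% of samples;
#' samples dropped for contamination >= 3%, mean depth < 12, missing rate
#' > 15%, or kinship >= 0.125.
#'
#' `stage2`: targeted sequencing — genotypes missing when DP < 15, GQ < 20
#' (SNV) / < 60 (indel), het AB outside [0.15, 0.85], het AB in the
#' moderate bands [0.15, 0.35] / [0.65, 0.85] without DP > 25, or indel
#' DP > 2000; variants dropped when call rate < 90% in cases or controls or
#' the case/control call-rate difference exceeds 2.5%; samples dropped for
#' missing rate > 15% or mean depth < 12.
#'
#' `adult`: exome case-control reanalysis — stage2-style call-rate rules
#' with a 5% sample missing-rate ceiling.
#'
#' @return a [qc_profile()].
#' @export
qc_profile_stage1 <- function() {
  qc_profile(
    "stage1",
    genotype = list(min_gq_snp = 30, min_gq_indel = 30, min_dp1 = 2,
                    ab_window = c(0.2, 0.8)),
    variant = list(max_missing = 0.2, min_hwe_p = 1e-8, min_mean_gq = 30,
                   coverage = list(min_dp = 7, min_frac = 0.8)),
    sample = list(max_missing_rate = 0.15, min_mean_depth = 12,
                  max_contamination = 0.03, kinship_threshold = 0.125))
}

#' @rdname qc_profile_stage1
#' @export
qc_profile_stage2 <- function() {
  qc_profile(
    "stage2",
    genotype = list(min_dp = 15, min_gq_snp = 20, min_gq_indel = 60,
                    ab_window = c(0.15, 0.85),
                    ab_moderate = list(windows = list(c(0.15, 0.35),
                                                      c(0.65, 0.85)),
                                       min_dp = 25),
                    max_indel_dp = 2000),
    variant = list(min_group_call_rate = 0.9, max_call_rate_diff = 0.025),
    sample = list(max_missing_rate = 0.15, min_mean_depth = 12))
}

#' @rdname qc_profile_stage1
#' @export
qc_profile_adult <- function() {
  qc_profile(
    "adult",
    variant = list(min_group_call_rate = 0.9, max_call_rate_diff = 0.025),
    sample = list(max_missing_rate = 0.05))
}

empty_report <- function() {
  structure(list(genotype = integer(), variant = integer(),
                 sample = integer()), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  for (lvl in c("genotype", "variant", "sample")) {
    if (!length(x[[lvl]])) next
    cat(" ", lvl, ":\n", sep = "")
    for (nm in names(x[[lvl]]))
      cat(sprintf("    %-22s %d\n", nm, x[[lvl]][[nm]]))
  }
  invisible(x)
}

merge_reports <- function(a, b) {
  for (lvl in c("genotype", "variant", "sample")) {
    common <- intersect(names(a[[lvl]]), names(b[[lvl]]))
    for (nm in common) a[[lvl]][[nm]] <- a[[lvl]][[nm]] + b[[lvl]][[nm]]
    add <- setdiff(names(b[[lvl]]), names(a[[lvl]]))
    a[[lvl]] <- c(a[[lvl]], b[[lvl]][add])
  }
  a
}

#' Genotype-level QC
#'
#' Sets offending genotypes to missing. Each genotype is attributed to the
#' first rule it violates, in the order: depth, genotype quality,
#' alternate-allele depth, indel depth ceiling, allelic-balance window,
#' moderate-allelic-balance depth requirement. Allelic balance is
#' alt-depth / (ref-depth + alt-depth); genotypes without allele depths
#' skip AB rules.
#'
#' @param x a [cohort()].
#' @param profile a [qc_profile()].
#' @return list with elements `dataset` (QC'ed cohort) and `report`
#'   (a `qc_report`).
#' @export
apply_genotype_qc <- function(x, profile) {
  g <- profile$genotype
  report <- empty_report()
  if (!length(g)) return(list(dataset = x, report = report))
  need <- function(field, rule) {
    if (is.null(x[[field]]))
      stop("QC profile '", profile$name, "' rule '", rule,
           "' needs per-genotype ", toupper(field), " which the data lacks")
  }
  called <- !is.na(x$geno)
  kill <- matrix(FALSE, nrow(x$geno), ncol(x$geno))
  counts <- integer()
  mark <- function(viol, rule) {
    new <- viol & called & !kill
    counts[[rule]] <<- sum(new)
    kill <<- kill | new
  }
  is_indel <- matrix(x$variants$variant_class == "indel",
                     nrow(x$geno), ncol(x$geno), byrow = TRUE)
  if (!is.null(g$min_dp)) {
    need("dp", "min_dp")
    mark(!is.na(x$dp) & x$dp < g$min_dp, "dp_below_min")
  }
  if (!is.null(g$min_gq_snp) || !is.null(g$min_gq_indel)) {
    need("gq", "min_gq")
    viol <- matrix(FALSE, nrow(x$geno), ncol(x$geno))
    if (!is.null(g$min_gq_snp))
      viol <- viol | (!is_indel & !is.na(x$gq) & x$gq < g$min_gq_snp)
    if (!is.null(g$min_gq_indel))
      viol <- viol | (is_indel & !is.na(x$gq) & x$gq < g$min_gq_indel)
    mark(viol, "gq_below_min")
  }
  if (!is.null(g$min_dp1)) {
    need("ad_alt", "min_dp1")
    # DP1 constrains genotypes carrying the alternate allele
    carrier <- called & x$geno > 0L
    mark(carrier & !is.na(x$ad_alt) & x$ad_alt < g$min_dp1, "dp1_below_min")
  }
  if (!is.null(g$max_indel_dp)) {
    need("dp", "max_indel_dp")
    mark(is_indel & !is.na(x$dp) & x$dp > g$max_indel_dp, "indel_dp_above_max")
  }
  ab <- NULL
  if (!is.null(g$ab_window) || !is.null(g$ab_moderate)) {
    if (!is.null(x$ad_ref) && !is.null(x$ad_alt)) {
      tot <- x$ad_ref + x$ad_alt
      ab <- ifelse(!is.na(tot) & tot > 0, x$ad_alt / tot, NA_real_)
    }
  }
  if (!is.null(g$ab_window) && !is.null(ab)) {
    het <- called & x$geno == 1L
    mark(het & !is.na(ab) & (ab < g$ab_window[1] | ab > g$ab_window[2]),
         "ab_outside_window")
  }
  if (!is.null(g$ab_moderate) && !is.null(ab)) {
    need("dp", "ab_moderate")
    het <- called & x$geno == 1L
    inmod <- Reduce(`|`, lapply(g$ab_moderate$windows, function(w)
      !is.na(ab) & ab >= w[1] & ab <= w[2]))
    mark(het & inmod & (is.na(x$dp) | x$dp <= g$ab_moderate$min_dp),
         "moderate_ab_low_dp")
  }
  x$geno[kill] <- NA_integer_
  report$genotype <- counts
  list(dataset = x, report = report)
}

#' Variant-level QC
#'
#' Drops variants failing any enabled rule; each dropped variant is
#' attributed to the first failing rule in the order: group call rate,
#' case/control call-rate difference, overall missingness, HWE, mean GQ,
#' coverage. The HWE test is the 1-df chi-square of [hwe_chisq()] computed
#' after the minor-allele flip.
#'
#' @inheritParams apply_genotype_qc
#' @return list(dataset, report).
#' @export
apply_variant_qc <- function(x, profile) {
  v <- profile$variant
  report <- empty_report()
  if (!length(v)) return(list(dataset = x, report = report))
  ncase <- sum(x$samples$status == 1L)
  nctrl <- sum(x$samples$status == 0L)
  if ((!is.null(v$min_group_call_rate) || !is.null(v$max_call_rate_diff)) &&
      (ncase == 0L || nctrl == 0L))
    stop("variant QC call-rate rules need both cases and controls")
  called <- !is.na(x$geno)
  drop <- rep(FALSE, n_variants(x))
  counts <- integer()
  mark <- function(viol, rule) {
    new <- viol & !drop
    counts[[rule]] <<- sum(new)
    drop <<- drop | new
  }
  if (!is.null(v$min_group_call_rate)) {
    cr_case <- colMeans(called[x$samples$status == 1L, , drop = FALSE])
    cr_ctrl <- colMeans(called[x$samples$status == 0L, , drop = FALSE])
    mark(cr_case < v$min_group_call_rate | cr_ctrl < v$min_group_call_rate,
         "group_call_rate")
  }
  if (!is.null(v$max_call_rate_diff)) {
    cr_case <- colMeans(called[x$samples$status == 1L, , drop = FALSE])
    cr_ctrl <- colMeans(called[x$samples$status == 0L, , drop = FALSE])
    mark(abs(cr_case - cr_ctrl) > v$max_call_rate_diff, "call_rate_diff")
  }
  if (!is.null(v$max_missing))
    mark(colMeans(!called) >= v$max_missing, "missingness")
  if (!is.null(v$min_hwe_p)) {
    rows <- if (profile$hwe_samples == "controls")
      x$samples$status == 0L else rep(TRUE, n_samples(x))
    g <- x$geno[rows, , drop = FALSE]
    hwe_p <- vapply(seq_len(ncol(g)), function(j) {
      gj <- g[, j]
      hwe_chisq(genotype_counts(sum(gj == 0L, na.rm = TRUE),
                                sum(gj == 1L, na.rm = TRUE),
                                sum(gj == 2L, na.rm = TRUE)))$p
    }, numeric(1))
    mark(hwe_p <= v$min_hwe_p, "hwe")
  }
  if (!is.null(v$min_mean_gq)) {
    if (is.null(x$gq))
      stop("QC profile '", profile$name, "' needs per-genotype GQ")
    mark(colMeans(x$gq, na.rm = TRUE) < v$min_mean_gq, "mean_gq")
  }
  if (!is.null(v$coverage)) {
    if (is.null(x$dp))
      stop("QC profile '", profile$name, "' needs per-genotype DP")
    frac <- colMeans(!is.na(x$dp) & x$dp >= v$coverage$min_dp)
    mark(frac < v$coverage$min_frac, "coverage")
  }
  report$variant <- counts
  list(dataset = subset_cohort(x, variants = !drop), report = report)
}

#' Sample-level QC
#'
#' Drops samples with missing rate, mean depth or contamination outside the
#' profile's thresholds, then resolves related pairs: for each kinship pair
#' at or above the threshold the member with the higher missing rate is
#' dropped (ties: the lexicographically larger id). Missing rate is taken
#' from the sample table when present, otherwise computed from the dosage
#' matrix.
#'
#' @inheritParams apply_genotype_qc
#' @param kinship data frame of pairs (`id1`, `id2`, `pi_hat`), or NULL.
#' @return list(dataset, report).
#' @export
apply_sample_qc <- function(x, profile, kinship = NULL) {
  s <- profile$sample
  report <- empty_report()
  if (!length(s)) return(list(dataset = x, report = report))
  mr <- x$samples$missing_rate
  if (is.null(mr) || all(is.na(mr))) mr <- rowMeans(is.na(x$geno))
  drop <- rep(FALSE, n_samples(x))
  counts <- integer()
  mark <- function(viol, rule) {
    viol[is.na(viol)] <- FALSE
    new <- viol & !drop
    counts[[rule]] <<- sum(new)
    drop <<- drop | new
  }
  meta <- function(col) {
    v <- x$samples[[col]]
    if (is.null(v))
      stop("QC profile '", profile$name, "' needs sample column '", col, "'")
    v
  }
  if (!is.null(s$max_missing_rate))
    mark(mr > s$max_missing_rate, "missing_rate")
  if (!is.null(s$min_mean_depth))
    mark(meta("mean_depth") < s$min_mean_depth, "mean_depth")
  if (!is.null(s$max_contamination))
    mark(meta("contamination") >= s$max_contamination, "contamination")
  if (!is.null(s$kinship_threshold) && !is.null(kinship) && nrow(kinship)) {
    n_kin <- 0L
    ids <- x$samples$sample_id
    for (k in seq_len(nrow(kinship))) {
      if (kinship$pi_hat[k] < s$kinship_threshold) next
      i1 <- match(kinship$id1[k], ids); i2 <- match(kinship$id2[k], ids)
      if (is.na(i1) || is.na(i2)) {
        warning("kinship pair references unknown sample(s): ",
                kinship$id1[k], " / ", kinship$id2[k], "; pair skipped")
        next
      }
      if (drop[i1] || drop[i2]) next
      victim <- if (mr[i1] > mr[i2]) i1
        else if (mr[i2] > mr[i1]) i2
        else if (ids[i1] > ids[i2]) i1 else i2
      drop[victim] <- TRUE
      n_kin <- n_kin + 1L
    }
    counts[["kinship"]] <- n_kin
  }
  report$sample <- counts
  list(dataset = subset_cohort(x, samples = !drop), report = report)
}

#' Full QC cascade
#'
#' Applies genotype, variant and sample QC in that order, then (by default)
#' a second variant pass so call-rate rules remain true after sample
#' removal.
#'
#' @inheritParams apply_sample_qc
#' @param second_variant_pass rerun variant QC after sample QC?
#' @return list(dataset, report) with all rule counts merged.
#' @export
apply_qc <- function(x, profile, kinship = NULL, second_variant_pass = TRUE) {
  r1 <- apply_genotype_qc(x, profile)
  r2 <- apply_variant_qc(r1$dataset, profile)
  r3 <- apply_sample_qc(r2$dataset, profile, kinship)
  report <- merge_reports(merge_reports(r1$report, r2$report), r3$report)
  out <- r3$dataset
  if (second_variant_pass && n_samples(out) > 0L) {
    r4 <- apply_variant_qc(out, profile)
    report <- merge_reports(report, r4$report)
    out <- r4$dataset
  }
  list(dataset = out, report = report)
}
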
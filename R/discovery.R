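# Stage-2 candidate selection and leave-one-out driver detection.

#' Leave-one-out driver detection for a gene signal
#'
#' Determines whether a gene-based signal is driven by few variants.
#' Iteratively: among the remaining variants seen more than twice in the
#' cohort (total minor-allele count > 2, cases and controls together) whose
#' single-variant p-value is nominally significant (< 0.05), remove the one
#' with the lowest single-variant p (ties: smaller genomic coordinate) and
#' re-run the gene test; stop when the gene p-value rises above the stop
#' threshold (0.1) or no eligible variant remains.
#'
#' @param setup a mask setup from [build_mask()].
#' @param x a [cohort()].
#' @param test gene test to re-run: "burden" or "skato".
#' @param config a [skato_config()] (for the SKAT-O branch).
#' @param stop_p stop once the gene p-value exceeds this (default 0.1).
#' @param nominal_p single-variant eligibility threshold (default 0.05).
#' @param min_mac eligible variants must have total minor-allele count
#'   strictly above this (default 2, "seen more than twice").
#' @return a `loo_trace`: list(gene, mask, removed, p_sequence,
#'   stop_reason) where `p_sequence` has one more element than `removed`
#'   (the initial gene p first).
#' @export
leave_one_out <- function(setup, x, test = c("burden", "skato"),
                          config = skato_config(), stop_p = 0.1,
                          nominal_p = 0.05, min_mac = 2) {
  test <- match.arg(test)
  run_gene <- function(keys) {
    s <- setup; s$variants <- keys
    if (length(keys) < 2L) return(NA_real_)
    if (test == "burden") burden_score_test(s, x)$result$p
    else skato_test(s, x, config = config)$result$p
  }
  keys <- setup$variants
  p_seq <- run_gene(keys)
  removed <- character()
  repeat {
    if (utils::tail(p_seq, 1) > stop_p) { reason <- "p_above_stop"; break }
    j <- match(keys, x$variants$key)
    mac <- colSums(x$geno[, j, drop = FALSE], na.rm = TRUE)
    elig <- which(mac > min_mac)
    if (!length(elig)) { reason <- "no_eligible_variant"; break }
    sv <- lapply(elig, function(e)
      single_variant_lrt(x$geno[, j[e]], x$samples$status, keys[e]))
    pv <- vapply(sv, function(r) r$p, numeric(1))
    elig <- elig[pv < nominal_p]
    pv <- pv[pv < nominal_p]
    if (!length(elig)) { reason <- "no_eligible_variant"; break }
    # min-p; ties broken by genomic coordinate
    best <- elig[order(pv, x$variants$chrom[j[elig]], x$variants$pos[j[elig]])][1]
    removed <- c(removed, keys[best])
    keys <- keys[-match(keys[best], keys)]
    p_seq <- c(p_seq, run_gene(keys))
    if (is.na(utils::tail(p_seq, 1))) {
      # fewer than 2 variants left: gene test undefined, treat as exhausted
      p_seq[length(p_seq)] <- 1
      reason <- "p_above_stop"; break
    }
    if (utils::tail(p_seq, 1) > stop_p) { reason <- "p_above_stop"; break }
  }
  structure(list(gene = setup$gene, mask = setup$mask, removed = removed,
                 p_sequence = p_seq, stop_reason = reason),
            class = "loo_trace")
}

#' Stage-2 candidate selection
#'
#' Applies the discovery thresholds to stage-1 results: genes with OR > 1
#' and p below the selection threshold in the LOF or STRICT burden tests
#' are sequenced; BROAD genes passing the threshold are genotyped at their
#' driver variants when the leave-one-out trace shows the signal is carried
#' by at most two variants, otherwise sequenced; single variants below the
#' threshold with case MAF > control MAF are genotyped. Gene results are
#' additionally flagged when exome-wide significant (Bonferroni for all
#' genes, p < 2.5e-6).
#'
#' @param gene_results list of gene-level `assoc_result`s (unit format
#'   "gene:MASK"); single-variant results in `variant_results`.
#' @param loo_traces named list of `loo_trace`s keyed by gene (BROAD).
#' @param variant_results list of single-variant `assoc_result`s carrying
#'   counts.
#' @param select_p selection threshold (default 1e-4).
#' @param bonferroni_p exome-wide threshold (default 2.5e-6).
#' @param max_driver_variants genotype rather than sequence when the LOO
#'   trace removed at most this many variants (default 2).
#' @return data frame of decisions: unit, decision, p, or_freq,
#'   exome_wide, targets (semicolon-joined variant keys to genotype).
#' @export
select_candidates <- function(gene_results, loo_traces = list(),
                              variant_results = list(),
                              select_p = 1e-4, bonferroni_p = 2.5e-6,
                              max_driver_variants = 2) {
  rows <- list()
  for (r in gene_results) {
    parts <- strsplit(r$unit, ":", fixed = TRUE)[[1]]
    gene <- parts[1]; mask <- parts[2]
    hit <- !is.na(r$or_freq) && r$or_freq > 1 && r$p < select_p
    decision <- "drop"; targets <- ""
    if (hit && mask %in% c("LOF", "STRICT")) decision <- "sequence_gene"
    if (hit && mask == "BROAD") {
      tr <- loo_traces[[gene]]
      if (!is.null(tr) && length(tr$removed) >= 1 &&
          length(tr$removed) <= max_driver_variants &&
          tr$stop_reason == "p_above_stop") {
        decision <- "genotype_variants"
        targets <- paste(tr$removed, collapse = ";")
      } else decision <- "sequence_gene"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      unit = r$unit, kind = "gene", decision = decision, p = r$p,
      or_freq = r$or_freq, exome_wide = r$p < bonferroni_p,
      targets = targets)
  }
  for (r in variant_results) {
    case_maf <- r$counts$a / (2 * r$counts$n1)
    ctrl_maf <- r$counts$b / (2 * r$counts$n2)
    hit <- r$p < select_p && case_maf > ctrl_maf
    rows[[length(rows) + 1L]] <- data.frame(
      unit = r$unit, kind = "variant",
      decision = if (hit) "genotype_variants" else "drop",
      p = r$p, or_freq = r$or_freq, exome_wide = r$p < bonferroni_p,
      targets = if (hit) r$unit else "")
  }
  if (!length(rows))
    return(data.frame(unit = character(), kind = character(),
                      decision = character(), p = numeric(),
                      or_freq = numeric(), exome_wide = logical(),
                      targets = character()))
  do.call(rbind, rows)
}

#' Leave-one-out trace as a flat table
#' @param trace a `loo_trace`.
#' @return data frame: gene, mask, step, removed_variant, p_after.
#' @export
loo_table <- function(trace) {
  data.frame(gene = trace$gene, mask = trace$mask,
             step = seq_along(trace$p_sequence) - 1L,
             removed_variant = c(NA_character_, trace$removed),
             p_after = trace$p_sequence,
             stop_reason = trace$stop_reason)
}
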
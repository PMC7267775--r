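# External-control comparison via the ratio of functional to synonymous
# very-rare allele counts (usable when only summary counts, not genotypes,
# are available for the controls).

#' Functional/synonymous count bundle for one gene
#'
#' @param fun_case,syn_case very-rare functional (LOF or STRICT mask) and
#'   synonymous allele counts in the internal cases.
#' @param fun_ctrl,syn_ctrl the same totals in the external controls.
#' @return a `proxecat_counts` object.
#' @export
proxecat_counts <- function(fun_case, syn_case, fun_ctrl, syn_ctrl) {
  stopifnot(fun_case >= 0, syn_case >= 0, fun_ctrl >= 0, syn_ctrl >= 0)
  structure(list(fun_case = fun_case, syn_case = syn_case,
                 fun_ctrl = fun_ctrl, syn_ctrl = syn_ctrl),
            class = "proxecat_counts")
}

#' Functional-to-synonymous ratio test against external controls
#'
#' Models the four allele counts as independent Poisson draws and performs
#' a 1-df likelihood-ratio test of equal functional/synonymous rate ratios
#' in cases and controls — equivalently the G-test of independence on the
#' 2x2 count table. Uses synonymous variation as an internal calibration so
#' external controls enter as count summaries only.
#'
#' @param counts a [proxecat_counts()] object.
#' @return an `assoc_result` with extra fields `ratio_case` and
#'   `ratio_ctrl`.
#' @export
proxecat_test <- function(counts) {
  with(counts, {
    if (fun_case + syn_case <= 0 || fun_ctrl + syn_ctrl <= 0)
      stop("need nonzero case and control count totals")
    obs <- c(fun_case, syn_case, fun_ctrl, syn_ctrl)
    flags <- character()
    work <- obs
    if (any(c(fun_case + fun_ctrl, syn_case + syn_ctrl) == 0) ||
        any(obs == 0)) {
      work <- obs + 0.5
      flags <- "continuity_corrected"
    }
    tot <- sum(work)
    row_m <- c(work[1] + work[2], work[3] + work[4])
    col_m <- c(work[1] + work[3], work[2] + work[4])
    expd <- outer(row_m, col_m) / tot
    stat <- 2 * sum(work * log(work / as.vector(t(expd))))
    stat <- max(0, stat)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    new_assoc_result("proxecat", "proxecat", stat, p, flags = flags,
                     extra = list(ratio_case = fun_case / syn_case,
                                  ratio_ctrl = fun_ctrl / syn_ctrl,
                                  counts_2x2 = obs))
  })
}

#' Assemble ratio-test counts for one gene
#'
#' Case counts are aggregated from the internal cohort's functional and
#' synonymous masks; external-control counts are read from a summary table
#' (columns gene, mask, fun_alleles, syn_alleles).
#'
#' @param x a [cohort()].
#' @param external external count table from [read_external_counts()].
#' @param gene gene symbol.
#' @param mask functional mask, "LOF" or "STRICT".
#' @param config a [mask_config()].
#' @return a [proxecat_counts()].
#' @export
collect_proxecat_counts <- function(x, external, gene, mask = c("LOF", "STRICT"),
                                    config = mask_config()) {
  mask <- match.arg(mask)
  gene_alleles <- function(setups) {
    s <- Filter(function(e) e$gene == gene, setups)
    if (!length(s)) return(0)
    j <- match(s[[1]]$variants, x$variants$key)
    sum(x$geno[x$samples$status == 1L, j, drop = FALSE], na.rm = TRUE)
  }
  fun_case <- gene_alleles(build_mask(x, mask, config))
  syn_case <- gene_alleles(build_mask(x, "SYNONYMOUS", config))
  ext <- external[external$gene == gene & external$mask == mask, ]
  if (!nrow(ext))
    stop("gene absent from external count table: ", gene, " (", mask, ")")
  proxecat_counts(fun_case, syn_case, ext$fun_alleles[1], ext$syn_alleles[1])
}
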
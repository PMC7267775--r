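# Single-variant and gene-level association statistics.
#
# All null models are intercept-only (analyses unadjusted for age and sex):
# the gene-level tests are score tests of H0: no genetic effect in a
# logistic model, using U = sum_i (y_i - ybar) * burden_i and
# V = ybar (1 - ybar) * sum_i (burden_i - mean(burden))^2.

#' Allele counts for a 2x2 case-control comparison
#'
#' @param a minor alleles observed in cases.
#' @param b minor alleles observed in controls.
#' @param n1,n2 case and control sample counts (allele denominators are
#'   twice these).
#' @param n_variants number of variants the counts aggregate over (gene
#'   totals can exceed one variant's allele denominator).
#' @return an `allele_counts` object.
#' @export
allele_counts <- function(a, b, n1, n2, n_variants = 1L) {
  stopifnot(a >= 0, b >= 0, a <= 2 * n1 * n_variants,
            b <= 2 * n2 * n_variants)
  structure(list(a = a, b = b, n1 = n1, n2 = n2), class = "allele_counts")
}

#' Case-control odds-ratio conventions
#'
#' `or_freq` is the case:control minor-allele-frequency ratio
#' (a / 2 n1) / (b / 2 n2) — the convention used for reported gene- and
#' variant-level ORs; it is infinite when controls carry no minor allele.
#' `or_adj` is the Haldane-corrected odds ratio on the allele 2x2 table
#' \[(a, 2 n1 - a), (b, 2 n2 - b)\] with 0.5 added to every cell, reported
#' alongside when a zero cell makes `or_freq` infinite. The 95% CI is the
#' Woolf (log-OR normal) interval on the (adjusted, if used) 2x2.
#'
#' @param counts an [allele_counts()] object.
#' @param conf confidence level for the Woolf interval.
#' @return list with `or_freq`, `or_adj`, `ci_lo`, `ci_hi`, `flags`.
#' @export
allele_or <- function(counts, conf = 0.95) {
  a <- counts$a; b <- counts$b
  N1 <- 2 * counts$n1; N2 <- 2 * counts$n2
  flags <- character()
  if (a == 0 && b == 0)
    return(list(or_freq = NA_real_, or_adj = NA_real_,
                ci_lo = NA_real_, ci_hi = NA_real_, flags = "no_carriers"))
  or_freq <- (a / N1) / (b / N2)       # Inf when b = 0, a > 0
  cells <- c(a, N1 - a, b, N2 - b)
  if (any(cells < 0)) {
    # multi-variant aggregate exceeding one variant's allele denominator:
    # the frequency ratio is still defined, the odds 2x2 is not
    return(list(or_freq = or_freq, or_adj = NA_real_,
                ci_lo = NA_real_, ci_hi = NA_real_,
                flags = "aggregate_exceeds_denominator"))
  }
  zero_cell <- any(cells == 0)
  or_adj <- if (zero_cell) {
    h <- cells + 0.5
    (h[1] * h[4]) / (h[2] * h[3])
  } else NA_real_
  ci_cells <- if (zero_cell) cells + 0.5 else cells
  log_or <- log((ci_cells[1] * ci_cells[4]) / (ci_cells[2] * ci_cells[3]))
  se <- sqrt(sum(1 / ci_cells))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or_freq = or_freq, or_adj = or_adj,
       ci_lo = exp(log_or - z * se), ci_hi = exp(log_or + z * se),
       flags = flags)
}

new_assoc_result <- function(unit, test, stat, p, counts = NULL,
                             n_variants = NA_integer_, or = NULL,
                             flags = character(), extra = list()) {
  if (is.null(or) && !is.null(counts)) or <- allele_or(counts)
  res <- c(list(unit = unit, test = test, stat = stat, p = p,
                counts = counts, n_variants = n_variants,
                or_freq = or$or_freq %||% NA_real_,
                or_adj = or$or_adj %||% NA_real_,
                ci_lo = or$ci_lo %||% NA_real_,
                ci_hi = or$ci_hi %||% NA_real_,
                flags = unique(c(flags, or$flags))), extra)
  class(res) <- "assoc_result"
  res
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %s [%s]  stat = %.4g  p = %.4g\n",
              x$unit, x$test, x$stat, x$p))
  if (!is.null(x$counts))
    cat(sprintf("  alleles %d/%d in %d cases / %d controls;  OR = %.4g\n",
                x$counts$a, x$counts$b, x$counts$n1, x$counts$n2, x$or_freq))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Results as a flat table
#' @param results list of `assoc_result` objects.
#' @return data frame (one row per result).
#' @export
assoc_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(unit = r$unit, test = r$test,
               n_variants = r$n_variants,
               a = r$counts$a %||% NA, b = r$counts$b %||% NA,
               n1 = r$counts$n1 %||% NA, n2 = r$counts$n2 %||% NA,
               or_freq = r$or_freq, or_adj = r$or_adj,
               ci_lo = r$ci_lo, ci_hi = r$ci_hi,
               stat = r$stat, p = r$p,
               flags = paste(r$flags, collapse = ";"))))
}

#' Single-variant likelihood-ratio test
#'
#' Additive logistic regression of case status on dosage versus the
#' intercept-only null; the statistic is twice the log-likelihood
#' difference, with a 1-df chi-square p-value. Missing dosages are dropped
#' (complete-case). Under separation (all carriers in one class) the fit is
#' capped and the result flagged `quasi_separated`; the log-OR and its SE
#' are reported for downstream meta-analysis.
#'
#' @param dosages numeric vector of 0/1/2/NA dosages.
#' @param status 0/1 phenotype vector aligned with `dosages`.
#' @param unit label for the result.
#' @return an `assoc_result` with extra fields `beta` and `se`.
#' @export
single_variant_lrt <- function(dosages, status, unit = "variant") {
  keep <- !is.na(dosages) & !is.na(status)
  d <- dosages[keep]; y <- status[keep]
  if (sum(y == 1) < 1 || sum(y == 0) < 1)
    stop("need at least one case and one control with non-missing dosage")
  flags <- character()
  if (stats::var(d) == 0) {
    counts <- allele_counts(sum(d[y == 1]), sum(d[y == 0]),
                            sum(y == 1), sum(y == 0))
    return(new_assoc_result(unit, "lrt", 0, 1, counts, 1L,
                            flags = "monomorphic",
                            extra = list(beta = 0, se = NA_real_)))
  }
  fit <- suppressWarnings(
    stats::glm(y ~ d, family = stats::binomial(),
               control = stats::glm.control(maxit = 50)))
  stat <- max(0, fit$null.deviance - fit$deviance)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  beta <- stats::coef(fit)[["d"]]
  se <- sqrt(diag(stats::vcov(fit)))[["d"]]
  eps <- 1e-8
  mu <- stats::fitted(fit)
  if (!fit$converged || any(mu < eps) || any(mu > 1 - eps) || abs(beta) > 15)
    flags <- "quasi_separated"
  counts <- allele_counts(sum(d[y == 1]), sum(d[y == 0]),
                          sum(y == 1), sum(y == 0))
  new_assoc_result(unit, "lrt", stat, p, counts, 1L, flags = flags,
                   extra = list(beta = beta, se = se))
}

#' Score statistics for a gene under a mask
#'
#' Computes the per-variant score vector S (S_j = sum_i (y_i - ybar) w_j
#' g_ij), its null covariance Phi = ybar(1 - ybar) W Gc' Gc W (Gc the
#' column-centered dosage matrix), and the burden aggregates U = 1'S and
#' V = 1' Phi 1. Missing dosages are imputed to the variant's observed
#' mean, matching score-test convention.
#'
#' @param setup a mask setup from [build_mask()] (or any list with
#'   `gene` and `variants` elements).
#' @param x a [cohort()].
#' @param weights per-variant weights; default equal (1).
#' @return an object of class `score_stat`.
#' @export
score_stat <- function(setup, x, weights = NULL) {
  keys <- setup$variants
  j <- match(keys, x$variants$key)
  if (anyNA(j)) stop("setup variants not in cohort: ",
                     paste(keys[is.na(j)], collapse = ", "))
  G <- x$geno[, j, drop = FALSE]
  y <- x$samples$status
  if (is.null(weights)) weights <- rep(1, length(keys))
  stopifnot(length(weights) == length(keys))
  a <- sum(G[y == 1L, , drop = FALSE], na.rm = TRUE)
  b <- sum(G[y == 0L, , drop = FALSE], na.rm = TRUE)
  counts <- allele_counts(a, b, sum(y == 1L), sum(y == 0L), length(keys))
  # mean-impute missing dosages within variant
  Gn <- apply(G, 2L, function(col) {
    col <- as.numeric(col)
    if (anyNA(col)) col[is.na(col)] <- mean(col, na.rm = TRUE)
    col[is.nan(col)] <- 0
    col
  })
  Gn <- matrix(Gn, nrow = nrow(G))
  ybar <- mean(y)
  v <- ybar * (1 - ybar)
  Gw <- sweep(Gn, 2L, weights, `*`)
  S <- drop(crossprod(Gw, y - ybar))
  Gc <- sweep(Gw, 2L, colMeans(Gw), `-`)
  Phi <- v * crossprod(Gc)
  names(S) <- keys
  dimnames(Phi) <- list(keys, keys)
  burden <- rowSums(Gw)
  structure(list(
    gene = setup$gene %||% "gene", mask = setup$mask %||% NA_character_,
    U = sum(S), V = v * sum((burden - mean(burden))^2),
    S = S, Phi = Phi, weights = weights,
    n_case = sum(y == 1L), n_ctrl = sum(y == 0L),
    counts = counts
  ), class = "score_stat")
}

#' Gene-based burden score test
#'
#' Collapses qualifying minor alleles per sample into a weighted burden and
#' tests it with the intercept-only score test: statistic U^2 / V against a
#' 1-df chi-square. Equal weights by default (Beta-MAF weights can be
#' passed explicitly).
#'
#' @inheritParams score_stat
#' @return list with `result` (an `assoc_result`) and `score` (the
#'   `score_stat`, for meta-analysis).
#' @export
burden_score_test <- function(setup, x, weights = NULL) {
  if (length(setup$variants) < 2L)
    stop("gene-based tests need at least 2 qualifying variants")
  ss <- score_stat(setup, x, weights)
  burden_from_score(ss)
}

burden_from_score <- function(ss, unit = NULL) {
  unit <- unit %||% paste0(ss$gene, if (!is.na(ss$mask)) paste0(":", ss$mask))
  flags <- character()
  if (ss$V <= 0) {
    res <- new_assoc_result(unit, "burden", 0, 1, ss$counts,
                            length(ss$S), flags = "degenerate")
    return(list(result = res, score = ss))
  }
  stat <- ss$U^2 / ss$V
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  res <- new_assoc_result(unit, "burden", stat, p, ss$counts, length(ss$S),
                          flags = flags)
  list(result = res, score = ss)
}

#' Genotype counts for the HWE test
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts (major hom, het,
#'   minor hom).
#' @return a `genotype_counts` object.
#' @export
genotype_counts <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  structure(list(n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa),
            class = "genotype_counts")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' 1-df chi-square comparing observed genotype counts with the p^2 / 2pq /
#' q^2 expectations at the sample allele frequency. Counts are flipped to
#' the minor allele first; monomorphic sites return p = 1.
#'
#' @param counts a [genotype_counts()] object.
#' @return list(stat, p).
#' @export
hwe_chisq <- function(counts) {
  n <- counts$n_AA + counts$n_Aa + counts$n_aa
  if (n == 0) stop("no genotypes")
  q <- (2 * counts$n_aa + counts$n_Aa) / (2 * n)
  if (q > 0.5) {
    tmp <- counts$n_AA; counts$n_AA <- counts$n_aa; counts$n_aa <- tmp
    q <- 1 - q
  }
  if (q == 0) return(list(stat = 0, p = 1))
  p1 <- 1 - q
  expd <- n * c(p1^2, 2 * p1 * q, q^2)
  obs <- c(counts$n_AA, counts$n_Aa, counts$n_aa)
  stat <- sum((obs - expd)^2 / expd)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test; two-sided p sums all tables at least as
#' improbable as the observed one.
#'
#' @param table 2x2 matrix of nonnegative integers.
#' @param sided "two", "greater" or "less".
#' @return p-value.
#' @export
fisher_2x2 <- function(table, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  alt <- switch(sided, two = "two.sided", greater = "greater", less = "less")
  stats::fisher.test(table, alternative = alt)$p.value
}

#' Expected homozygote count from a heterozygous intercross
#'
#' Under the Mendelian 1:2:1 ratio a quarter of offspring are expected to
#' be homozygous; the expectation is rounded half-up for reporting.
#'
#' @param n_offspring number of genotyped offspring.
#' @return integer expected homozygote count.
#' @export
mendelian_expected <- function(n_offspring) {
  stopifnot(n_offspring >= 0)
  as.integer(floor(n_offspring / 4 + 0.5))
}
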
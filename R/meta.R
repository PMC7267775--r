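# Cross-stage evidence combination: inverse-variance fixed-effects
# meta-analysis for single variants; score-statistic pooling for gene
# tests (homogeneous effects: scores summed, covariances added, variants
# aligned by key — a variant absent from a study contributes zero score
# and zero covariance for that study).

#' Fixed-effects inverse-variance meta-analysis
#'
#' @param beta per-study log odds ratios.
#' @param se per-study standard errors (> 0).
#' @param labels optional study labels.
#' @return list(beta, se, z, p) with a two-sided normal p-value.
#' @export
fixed_effects_meta <- function(beta, se, labels = NULL) {
  stopifnot(length(beta) == length(se), length(beta) >= 1, all(se > 0))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  z <- b / s
  list(beta = b, se = s, z = z,
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

pool_scores <- function(scores) {
  keys <- unique(unlist(lapply(scores, function(s) names(s$S))))
  if (!length(keys)) stop("no variants to pool")
  m <- length(keys)
  S <- stats::setNames(rep(0, m), keys)
  Phi <- matrix(0, m, m, dimnames = list(keys, keys))
  for (s in scores) {
    k <- names(s$S)
    S[k] <- S[k] + s$S
    Phi[k, k] <- Phi[k, k] + s$Phi
  }
  list(S = S, Phi = Phi)
}

pool_counts <- function(scores) {
  allele_counts(sum(vapply(scores, function(s) s$counts$a, 0)),
                sum(vapply(scores, function(s) s$counts$b, 0)),
                sum(vapply(scores, function(s) s$counts$n1, 0)),
                sum(vapply(scores, function(s) s$counts$n2, 0)),
                n_variants = sum(vapply(scores,
                                        function(s) length(s$S), 0L)))
}

#' Gene-level burden meta-analysis by score pooling
#'
#' Homogeneous-effect combination of per-study burden score statistics:
#' U_meta = sum_k U_k, V_meta = sum_k V_k, tested as U_meta^2 / V_meta
#' against a 1-df chi-square. Allele counts are pooled for the reported OR.
#'
#' @param scores list of `score_stat` objects for the same gene + mask
#'   across studies (variant sets may differ).
#' @return an `assoc_result` with stage label "meta".
#' @export
meta_burden <- function(scores) {
  stopifnot(length(scores) >= 1)
  U <- sum(vapply(scores, function(s) s$U, 0))
  V <- sum(vapply(scores, function(s) s$V, 0))
  counts <- pool_counts(scores)
  unit <- paste0(scores[[1]]$gene, ":",
                 scores[[1]]$mask %||% NA_character_, ":meta")
  nv <- length(unique(unlist(lapply(scores, function(s) names(s$S)))))
  if (V <= 0)
    return(new_assoc_result(unit, "burden_meta", 0, 1, counts, nv,
                            flags = "degenerate"))
  stat <- U^2 / V
  new_assoc_result(unit, "burden_meta", stat,
                   stats::pchisq(stat, df = 1, lower.tail = FALSE),
                   counts, nv)
}

#' Gene-level SKAT-O meta-analysis by score pooling
#'
#' Pools per-study score vectors and covariances on the union of variant
#' keys (shared variants: scores summed, covariances added; study-specific
#' variants: zero blocks elsewhere) and applies the SKAT-O construction to
#' the pooled quantities.
#'
#' @param scores list of `score_stat` objects for the same gene + mask.
#' @param config a [skato_config()].
#' @return an `assoc_result`.
#' @export
meta_skato <- function(scores, config = skato_config()) {
  stopifnot(length(scores) >= 1)
  pooled <- pool_scores(scores)
  counts <- pool_counts(scores)
  unit <- paste0(scores[[1]]$gene, ":",
                 scores[[1]]$mask %||% NA_character_, ":meta")
  sk <- skato_from_scores(pooled$S, pooled$Phi, config)
  new_assoc_result(unit, "skato_meta", sk$stat, sk$p, counts,
                   length(pooled$S), flags = sk$flags,
                   extra = list(p_rho = sk$p_rho, rho_grid = sk$rho_grid))
}
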
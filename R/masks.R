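# Allele-frequency classing and the nested functional variant masks.
#
# Masks (by qualifying consequence and frequency class):
#   LOF        very rare + predicted loss of function
#   STRICT     very rare + LOF, stop_lost, initiator_codon, or missense
#              called damaging by all five predictors
#   BROAD      rare or very rare + STRICT-qualifying consequence or
#              missense called damaging by at least one predictor
#   SYNONYMOUS very rare + synonymous (used by the external-control test)

LOF_CONSEQUENCES <- c("splice_donor_variant", "splice_acceptor_variant",
                      "stop_gained", "frameshift_variant")
EXTRA_STRICT_CONSEQUENCES <- c("stop_lost", "initiator_codon_variant")
MASK_NAMES <- c("LOF", "STRICT", "BROAD", "SYNONYMOUS")

#' Mask configuration
#'
#' @param rare_threshold minor-allele-frequency ceiling for "rare"
#'   (default 0.01).
#' @param very_rare_threshold MAF ceiling for "very rare" (default 0.00025,
#'   i.e. 0.025%, chosen to target variants private to a family or clan).
#' @param groups named list of analysis groups: each element a function of
#'   the sample table returning a logical row index, or a logical/integer
#'   vector. Defaults to cases and controls. A variant's cohort frequency
#'   must fall under the threshold in at least one group to qualify.
#' @param missing_verdict_damaging treat a missing predictor verdict as
#'   damaging? Default FALSE (missing counts as not damaging for both the
#'   all-five and the at-least-one rules).
#' @return an object of class `mask_config`.
#' @export
mask_config <- function(rare_threshold = 0.01, very_rare_threshold = 0.00025,
                        groups = NULL, missing_verdict_damaging = FALSE) {
  stopifnot(0 < very_rare_threshold, very_rare_threshold < rare_threshold,
            rare_threshold < 0.5)
  structure(list(rare_threshold = rare_threshold,
                 very_rare_threshold = very_rare_threshold,
                 groups = groups,
                 missing_verdict_damaging = missing_verdict_damaging),
            class = "mask_config")
}

resolve_groups <- function(x, config) {
  if (!is.null(config$groups)) {
    lapply(config$groups, function(g)
      if (is.function(g)) g(x$samples) else g)
  } else {
    list(cases = x$samples$status == 1L, controls = x$samples$status == 0L)
  }
}

#' Frequency class of variants
#'
#' A variant is `very_rare` when its allele frequency is below the
#' very-rare threshold in every reference panel AND below it in at least
#' one analysis group of the cohort; `rare` when the same holds at the rare
#' threshold; otherwise `common`. A missing panel AF counts as 0 (the
#' allele is unobserved in that panel).
#'
#' @param panel_afs numeric matrix (variants x panels) of reference-panel
#'   allele frequencies; NAs allowed.
#' @param group_afs numeric matrix (variants x groups) of cohort
#'   minor-allele frequencies per analysis group; NaN (no calls) treated as
#'   unobserved (0).
#' @param config a [mask_config()].
#' @return character vector: "very_rare", "rare" or "common".
#' @export
frequency_class <- function(panel_afs, group_afs, config = mask_config()) {
  panel_afs <- as.matrix(panel_afs); group_afs <- as.matrix(group_afs)
  panel_afs[is.na(panel_afs)] <- 0
  group_afs[is.na(group_afs)] <- 0
  below <- function(th)
    apply(panel_afs < th, 1L, all) & apply(group_afs < th, 1L, any)
  ifelse(below(config$very_rare_threshold), "very_rare",
         ifelse(below(config$rare_threshold), "rare", "common"))
}

#' Functional category flags of variants
#'
#' @param ann annotation data frame (rows = variants) as from
#'   [read_annotations()].
#' @param missing_verdict_damaging treat missing predictor verdicts as
#'   damaging?
#' @return data frame with logical columns `is_lof`, `is_strict`,
#'   `is_broad`, `is_synonymous` satisfying `is_lof => is_strict =>
#'   is_broad`.
#' @export
functional_category <- function(ann, missing_verdict_damaging = FALSE) {
  if (nrow(ann) == 0L)
    return(data.frame(is_lof = logical(), is_strict = logical(),
                      is_broad = logical(), is_synonymous = logical()))
  dmg <- sapply(PREDICTOR_COLS, function(p) {
    v <- ann[[p]]
    v == "damaging" | (missing_verdict_damaging & v == "missing")
  })
  dmg <- matrix(dmg, nrow = nrow(ann))
  n_dmg <- rowSums(dmg)
  missense <- ann$consequence == "missense_variant"
  is_lof <- ann$consequence %in% LOF_CONSEQUENCES
  is_strict <- is_lof | ann$consequence %in% EXTRA_STRICT_CONSEQUENCES |
    (missense & n_dmg == length(PREDICTOR_COLS))
  is_broad <- is_strict | (missense & n_dmg >= 1L)
  data.frame(is_lof = is_lof, is_strict = is_strict, is_broad = is_broad,
             is_synonymous = ann$consequence == "synonymous_variant")
}

#' Build per-gene variant masks
#'
#' Classifies every annotated variant by frequency and functional category
#' and groups qualifying variants by gene. Genes with fewer than two
#' qualifying variants are flagged `testable = FALSE`: they are excluded
#' from gene-based tests but still contribute to gene-set burden
#' aggregation.
#'
#' @param x a [cohort()] with annotations attached (genotype QC applied:
#'   cohort AFs are computed on the retained non-missing calls).
#' @param mask_name one of "LOF", "STRICT", "BROAD", "SYNONYMOUS".
#' @param config a [mask_config()].
#' @return list of mask setups, each `list(gene, mask, variants, classes,
#'   testable)`; ordered by gene.
#' @export
build_mask <- function(x, mask_name, config = mask_config()) {
  mask_name <- match.arg(mask_name, MASK_NAMES)
  if (is.null(x$annotations)) stop("cohort has no annotations attached")
  if (n_variants(x) == 0L) return(list())
  ann <- x$annotations[match(x$variants$key, x$annotations$key), , drop = FALSE]
  has_ann <- !is.na(ann$key)
  groups <- resolve_groups(x, config)
  gafs <- vapply(groups, function(g) cohort_af(x, which = g),
                 numeric(n_variants(x)))
  gafs <- matrix(gafs, nrow = n_variants(x))
  pafs <- as.matrix(ann[, PANEL_COLS])
  cls <- rep("common", n_variants(x))
  cls[has_ann] <- frequency_class(pafs[has_ann, , drop = FALSE],
                                  gafs[has_ann, , drop = FALSE], config)
  cat <- functional_category(ann[has_ann, , drop = FALSE],
                             config$missing_verdict_damaging)
  qual <- rep(FALSE, n_variants(x))
  qv <- switch(mask_name,
    LOF = cat$is_lof & cls[has_ann] == "very_rare",
    STRICT = cat$is_strict & cls[has_ann] == "very_rare",
    BROAD = cat$is_broad & cls[has_ann] %in% c("rare", "very_rare"),
    SYNONYMOUS = cat$is_synonymous & cls[has_ann] == "very_rare")
  qual[has_ann] <- qv
  if (!any(qual)) return(list())
  keys <- x$variants$key[qual]
  genes <- ann$gene[qual]
  classes <- cls[qual]
  ord <- order(genes)
  setups <- lapply(split(seq_along(keys)[ord], genes[ord]), function(i) {
    structure(list(gene = genes[i[1]], mask = mask_name,
                   variants = keys[i], classes = classes[i],
                   testable = length(i) >= 2L),
              class = "mask_setup")
  })
  unname(setups)
}

#' Mask setups as a flat table
#'
#' @param setups list of mask setups from [build_mask()].
#' @return data frame with columns gene, mask, key, class, testable —
#'   the TSV layout used by the analysis drivers.
#' @export
mask_table <- function(setups) {
  if (!length(setups))
    return(data.frame(gene = character(), mask = character(),
                      key = character(), class = character(),
                      testable = logical()))
  do.call(rbind, lapply(setups, function(s)
    data.frame(gene = s$gene, mask = s$mask, key = s$variants,
               class = s$classes, testable = s$testable)))
}
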
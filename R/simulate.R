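# Synthetic two-stage case-control cohort generator.
#
# Emulates the statistical structure the pipeline assumes: ultra-rare
# variants in linkage equilibrium, per-gene case enrichment of functional
# alleles (carrier-probability tilting), predictor-verdict annotation,
# reference-panel frequencies, genotype-level noise fields (GQ/DP/AD) and
# optional planted QC violations so every QC rule can be exercised and
# every planted effect recovered from truth tables.

#' Simulation configuration
#'
#' Defaults mirror the discovery-stage design the pipeline targets: a
#' 927-case / 4,057-control stage-1 cohort (shrinkable), a variant spectrum
#' dominated by very rare alleles, and a quarter of cases carrying a
#' developmental-delay flag.
#'
#' @param seed RNG seed, recorded in the output.
#' @param n_cases,n_controls cohort sizes (defaults 927 / 4057).
#' @param n_genes number of genes (default 50).
#' @param mean_variants_per_gene Poisson mean of the per-gene variant count
#'   (minimum 2; default 8).
#' @param maf_spectrum probabilities of the three frequency strata for a
#'   variant: `very_rare` (population AF below the very-rare threshold),
#'   `rare` (0.1%-0.8%), `common` (2%-20%). Default c(0.7, 0.2, 0.1).
#' @param class_fractions probabilities that a variant is loss-of-function,
#'   missense or synonymous (default c(lof = 0.2, missense = 0.55,
#'   synonymous = 0.25)).
#' @param damaging_profile for missense variants, probabilities that 5, 1-4
#'   or 0 of the five predictors call the change damaging (default
#'   c(all5 = 0.3, some = 0.4, none = 0.3)).
#' @param gene_rr named numeric vector of per-gene carrier relative risks
#'   applied to functional (LOF/damaging-missense) variants in cases;
#'   genes not named have RR 1.
#' @param dd_fraction fraction of cases flagged with developmental delay
#'   (default 0.24, matching roughly a quarter of cases).
#' @param dd_rr optional extra relative risk applied only to DD cases for
#'   genes named in `gene_rr` (default 1: no DD-specific effect).
#' @param mean_depth mean sequencing depth for the genotype noise model
#'   (default 40).
#' @param plant_qc list of planted QC violations (all default 0):
#'   `n_low_gq`, `n_low_dp1`, `n_bad_ab` (genotype-level; stage-1 rules),
#'   `n_high_missing_variants` (variant-level), `n_bad_samples`,
#'   `n_contaminated`, `n_kin_pairs` (sample-level).
#' @param stage stage label stored on samples.
#' @return a `sim_config` object.
#' @export
sim_config <- function(seed = 1L, n_cases = 927L, n_controls = 4057L,
                       n_genes = 50L, mean_variants_per_gene = 8,
                       maf_spectrum = c(very_rare = 0.7, rare = 0.2,
                                        common = 0.1),
                       class_fractions = c(lof = 0.2, missense = 0.55,
                                           synonymous = 0.25),
                       damaging_profile = c(all5 = 0.3, some = 0.4,
                                            none = 0.3),
                       gene_rr = numeric(), dd_fraction = 0.24, dd_rr = 1,
                       mean_depth = 40, plant_qc = list(), stage = 1L) {
  stopifnot(abs(sum(maf_spectrum) - 1) < 1e-9,
            abs(sum(class_fractions) - 1) < 1e-9,
            abs(sum(damaging_profile) - 1) < 1e-9,
            all(gene_rr > 0), dd_fraction >= 0, dd_fraction <= 1)
  structure(list(seed = seed, n_cases = n_cases, n_controls = n_controls,
                 n_genes = n_genes,
                 mean_variants_per_gene = mean_variants_per_gene,
                 maf_spectrum = maf_spectrum,
                 class_fractions = class_fractions,
                 damaging_profile = damaging_profile,
                 gene_rr = gene_rr, dd_fraction = dd_fraction, dd_rr = dd_rr,
                 mean_depth = mean_depth, plant_qc = plant_qc,
                 stage = stage), class = "sim_config")
}

#' Simulate a case-control cohort
#'
#' Generative model: each gene carries a Poisson number of variants (>= 2);
#' each variant draws a frequency stratum, a functional class and predictor
#' verdicts; control alt-allele frequency q0 comes from the stratum; case
#' frequency is q0 * RR for functional variants of enriched genes
#' (carrier-probability tilting — adequate for the ultra-rare alleles this
#' design targets, where carrier probabilities are far below 1). Genotypes
#' are Binomial(2, q) in linkage equilibrium; GQ/DP/AD noise fields are
#' drawn per genotype; QC violations are planted on otherwise-clean
#' genotypes/variants/samples and recorded.
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (a [cohort()] with annotations
#'   attached), `truth` (list of data frames: `variants` with true
#'   frequencies/classes/categories, `genes` with planted RRs, `qc` with
#'   planted violations), and `seed`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  n1 <- config$n_cases; n0 <- config$n_controls
  n <- n1 + n0
  genes <- sprintf("GENE%03d", seq_len(config$n_genes))
  rr <- stats::setNames(rep(1, config$n_genes), genes)
  unknown <- setdiff(names(config$gene_rr), genes)
  if (length(unknown)) stop("gene_rr names not simulated: ",
                            paste(unknown, collapse = ", "))
  rr[names(config$gene_rr)] <- config$gene_rr

  nv <- pmax(2L, stats::rpois(config$n_genes, config$mean_variants_per_gene))
  gene_of <- rep(genes, nv)
  m <- length(gene_of)
  stratum <- sample(names(config$maf_spectrum), m, replace = TRUE,
                    prob = config$maf_spectrum)
  klass <- sample(names(config$class_fractions), m, replace = TRUE,
                  prob = config$class_fractions)
  q0 <- numeric(m)
  q0[stratum == "very_rare"] <- stats::runif(sum(stratum == "very_rare"),
                                             0.25, 1.5) / (2 * n)
  q0[stratum == "rare"] <- stats::runif(sum(stratum == "rare"), 0.001, 0.008)
  q0[stratum == "common"] <- stats::runif(sum(stratum == "common"), 0.02, 0.2)

  # annotation: consequence + verdicts + panel AFs
  consequence <- character(m)
  consequence[klass == "lof"] <- sample(LOF_CONSEQUENCES,
                                        sum(klass == "lof"), replace = TRUE)
  consequence[klass == "missense"] <- "missense_variant"
  consequence[klass == "synonymous"] <- "synonymous_variant"
  n_dmg <- integer(m)
  mis <- which(klass == "missense")
  prof <- sample(names(config$damaging_profile), length(mis), replace = TRUE,
                 prob = config$damaging_profile)
  n_dmg[mis][prof == "all5"] <- 5L
  n_dmg[mis][prof == "some"] <- sample(1:4, sum(prof == "some"),
                                       replace = TRUE)
  verdicts <- matrix("benign", m, length(PREDICTOR_COLS),
                     dimnames = list(NULL, PREDICTOR_COLS))
  for (i in mis) {
    if (n_dmg[i] > 0)
      verdicts[i, sample(length(PREDICTOR_COLS), n_dmg[i])] <- "damaging"
  }
  verdicts[-mis, ] <- "missing"
  if (!length(mis)) verdicts[, ] <- "missing"
  panel <- matrix(0, m, length(PANEL_COLS),
                  dimnames = list(NULL, PANEL_COLS))
  panel[stratum == "rare", ] <- q0[stratum == "rare"] *
    matrix(stats::runif(sum(stratum == "rare") * length(PANEL_COLS),
                        0.5, 1.5), ncol = length(PANEL_COLS))
  panel[stratum == "common", ] <- q0[stratum == "common"] *
    matrix(stats::runif(sum(stratum == "common") * length(PANEL_COLS),
                        0.8, 1.2), ncol = length(PANEL_COLS))
  panel <- pmin(panel, 0.5)

  # phenotypes
  dd <- c(stats::rbinom(n1, 1L, config$dd_fraction), rep(NA_integer_, n0))
  status <- c(rep(1L, n1), rep(0L, n0))
  functional <- klass == "lof" | (klass == "missense" & n_dmg >= 1L)

  # genotypes: Binomial(2, q) with per-group q
  geno <- matrix(0L, n, m)
  tilted <- functional & stratum != "common"   # mask-qualifying variants
  for (j in seq_len(m)) {
    q_case <- q0[j]
    if (tilted[j] && rr[gene_of[j]] != 1) q_case <- q0[j] * rr[gene_of[j]]
    if (q_case > 1) stop("infeasible config: RR * q0 > 1 for ", gene_of[j])
    qc_dd <- min(1, q_case * ifelse(tilted[j], config$dd_rr, 1))
    case_q <- ifelse(!is.na(dd[1:n1]) & dd[1:n1] == 1L, qc_dd, q_case)
    geno[1:n1, j] <- stats::rbinom(n1, 2L, case_q)
    geno[(n1 + 1):n, j] <- stats::rbinom(n0, 2L, q0[j])
  }

  # genotype-level noise fields
  dp <- matrix(stats::rpois(n * m, config$mean_depth), n, m)
  ab_p <- matrix(0.02, n, m)
  ab_p[geno == 1L] <- 0.5
  ab_p[geno == 2L] <- 0.98
  ad_alt <- matrix(stats::rbinom(n * m, as.vector(dp), as.vector(ab_p)), n, m)
  ad_ref <- dp - ad_alt
  gq <- matrix(sample(60:99, n * m, replace = TRUE), n, m)

  variants <- data.frame(
    chrom = paste0("chr", 1 + (match(gene_of, genes) - 1) %% 22),
    pos = 1e6 + seq_len(m) * 1000L,
    ref = "A",
    alt = ifelse(klass == "lof" & consequence == "frameshift_variant",
                 "AT", "G"),
    gene = gene_of, stringsAsFactors = FALSE)

  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    status = status, dd_flag = dd, stage = config$stage,
    missing_rate = stats::runif(n, 0, 0.02),
    mean_depth = config$mean_depth + stats::rnorm(n, 0, 3),
    contamination = stats::runif(n, 0, 0.01), stringsAsFactors = FALSE)

  # plant QC violations on clean slots and record them
  pq <- utils::modifyList(list(n_low_gq = 0L, n_low_dp1 = 0L, n_bad_ab = 0L,
                               n_high_missing_variants = 0L,
                               n_bad_samples = 0L, n_contaminated = 0L,
                               n_kin_pairs = 0L), config$plant_qc)
  qc_truth <- list()
  planted <- matrix(FALSE, n, m)   # one violation per genotype cell
  plant_cells <- function(k, eligible) {
    idx <- which(eligible & !planted)
    if (length(idx) < k) stop("not enough clean genotypes to plant violations")
    cells <- sample(idx, k)
    planted[cells] <<- TRUE
    cells
  }
  if (pq$n_low_gq > 0) {
    cells <- plant_cells(pq$n_low_gq, gq >= 60)
    gq[cells] <- sample(0:29, pq$n_low_gq, replace = TRUE)
    qc_truth$low_gq <- cells
  }
  if (pq$n_low_dp1 > 0) {
    cells <- plant_cells(pq$n_low_dp1, geno == 1L & ad_alt >= 2)
    ad_alt[cells] <- 1L
    ad_ref[cells] <- dp[cells] - 1L
    qc_truth$low_dp1 <- cells
  }
  if (pq$n_bad_ab > 0) {
    cells <- plant_cells(pq$n_bad_ab, geno == 1L & ad_alt >= 2 & dp >= 20)
    ad_alt[cells] <- pmax(2L, round(dp[cells] * 0.1))
    ad_ref[cells] <- dp[cells] - ad_alt[cells]
    qc_truth$bad_ab <- cells
  }
  if (pq$n_high_missing_variants > 0) {
    vs <- sample(m, pq$n_high_missing_variants)
    for (j in vs) {
      rows <- which(!planted[, j])
      hit <- sample(rows, ceiling(0.25 * n))
      geno[hit, j] <- NA_integer_
      planted[hit, j] <- TRUE
    }
    qc_truth$high_missing_variants <- vs
  }
  if (pq$n_bad_samples > 0) {
    ss <- sample(n, pq$n_bad_samples)
    samples$missing_rate[ss] <- stats::runif(pq$n_bad_samples, 0.16, 0.3)
    qc_truth$bad_samples <- samples$sample_id[ss]
  }
  if (pq$n_contaminated > 0) {
    ok <- setdiff(seq_len(n), match(qc_truth$bad_samples, samples$sample_id))
    ss <- sample(ok, pq$n_contaminated)
    samples$contamination[ss] <- stats::runif(pq$n_contaminated, 0.03, 0.10)
    qc_truth$contaminated <- samples$sample_id[ss]
  }
  kinship <- NULL
  if (pq$n_kin_pairs > 0) {
    used <- match(c(qc_truth$bad_samples, qc_truth$contaminated),
                  samples$sample_id)
    ok <- setdiff(seq_len(n), used)
    pick <- matrix(sample(ok, 2 * pq$n_kin_pairs), ncol = 2)
    kinship <- data.frame(id1 = samples$sample_id[pick[, 1]],
                          id2 = samples$sample_id[pick[, 2]],
                          pi_hat = stats::runif(pq$n_kin_pairs, 0.25, 0.5))
    qc_truth$kin_pairs <- kinship
  }

  ann <- data.frame(variants[c("chrom", "pos", "ref", "alt", "gene")],
                    consequence = consequence,
                    as.data.frame(verdicts, stringsAsFactors = FALSE),
                    as.data.frame(panel), stringsAsFactors = FALSE)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)

  ds <- cohort(samples, variants, geno, gq = gq, dp = dp,
               ad_ref = ad_ref, ad_alt = ad_alt, annotations = ann)
  truth <- list(
    variants = data.frame(key = ann$key, gene = gene_of, stratum = stratum,
                          class = klass, n_damaging = n_dmg, q0 = q0,
                          functional = functional,
                          stringsAsFactors = FALSE),
    genes = data.frame(gene = genes, rr = rr, n_variants = nv,
                       stringsAsFactors = FALSE),
    qc = qc_truth, kinship = kinship)
  list(dataset = ds, truth = truth, seed = config$seed)
}

#' Simulate a two-stage cohort pair
#'
#' Stage 1 uses the config as given; stage 2 re-draws an independent cohort
#' at the replication scale (default 1,810 cases / 2,647 controls, scaled
#' by the same shrink factor as the config relative to the 927 / 4,057
#' design) with the same gene effects.
#'
#' @param config a [sim_config()] for stage 1.
#' @param n_cases2,n_controls2 stage-2 sizes; defaults scale 1810 / 2647 by
#'   the config's shrink relative to the full stage-1 design.
#' @return list(stage1, stage2) of [simulate_cohort()] results.
#' @export
simulate_two_stage <- function(config = sim_config(),
                               n_cases2 = NULL, n_controls2 = NULL) {
  shrink <- config$n_cases / 927
  cfg2 <- config
  cfg2$seed <- config$seed + 1L
  cfg2$stage <- 2L
  cfg2$n_cases <- n_cases2 %||% max(2L, round(1810 * shrink))
  cfg2$n_controls <- n_controls2 %||% max(2L, round(2647 * shrink))
  list(stage1 = simulate_cohort(config), stage2 = simulate_cohort(cfg2))
}

#' Null p-value sample for calibration
#'
#' Draws `n_reps` single-gene cohorts with no enrichment (RR = 1) and
#' returns the gene-test p-values. Genotypes are Binomial(2, q) with q
#' drawn per variant from `maf_range`; monomorphic draws are redrawn so
#' every replicate carries at least one minor allele.
#'
#' @param test "burden", "skat" or "skato".
#' @param n_reps number of replicates.
#' @param n_cases,n_controls cohort size per replicate.
#' @param n_variants variants per gene.
#' @param maf_range population allele-frequency range to draw from.
#' @param config a [skato_config()].
#' @param seed RNG seed.
#' @return numeric vector of `n_reps` p-values.
#' @export
simulate_null_pvalues <- function(test = c("burden", "skat", "skato"),
                                  n_reps = 1000L, n_cases = 250L,
                                  n_controls = 250L, n_variants = 3L,
                                  maf_range = c(0.005, 0.03),
                                  config = skato_config(),
                                  seed = 1L) {
  test <- match.arg(test)
  set.seed(seed)
  if (n_reps == 0L) return(numeric(0))
  n <- n_cases + n_controls
  y <- c(rep(1L, n_cases), rep(0L, n_controls))
  ybar <- mean(y); v <- ybar * (1 - ybar)
  vapply(seq_len(n_reps), function(r) {
    repeat {
      q <- stats::runif(n_variants, maf_range[1], maf_range[2])
      G <- matrix(stats::rbinom(n * n_variants, 2L, rep(q, each = n)),
                  n, n_variants)
      if (any(G > 0)) break
    }
    S <- drop(crossprod(G, y - ybar))
    Gc <- sweep(G, 2L, colMeans(G))
    if (test == "burden") {
      burden <- rowSums(G)
      V <- v * sum((burden - mean(burden))^2)
      if (V <= 0) return(1)
      stats::pchisq(sum(S)^2 / V, df = 1, lower.tail = FALSE)
    } else {
      Phi <- v * crossprod(Gc)
      if (test == "skat") {
        lam <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
        lam <- lam[lam > max(lam, 0) * 1e-10]
        if (!length(lam)) return(1)
        pchisq_mixture(sum(S^2), lam, config$method, config$tol)
      } else {
        skato_from_scores(S, Phi, config)$p
      }
    }
  }, numeric(1))
}
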
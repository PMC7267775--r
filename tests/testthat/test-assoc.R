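# grid-search profile-likelihood oracle for the logistic LRT
loglik_grid_max <- function(d, y, b1_range = c(-16, 16), n_grid = 401L) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * d
    sum(y * eta - log1p(exp(eta)))
  }
  best <- -Inf
  for (b1 in seq(b1_range[1], b1_range[2], length.out = n_grid)) {
    opt <- optimize(function(b0) ll(b0, b1), c(-20, 20), maximum = TRUE)
    if (opt$objective > best) best <- opt$objective
  }
  best
}

test_that("single-variant LRT: null identity, oracle match, additivity", {
  r0 <- single_variant_lrt(c(0, 1, 0, 1, 2, 2), c(1, 1, 0, 0, 1, 0))
  expect_equal(r0$stat, 0, tolerance = 1e-8)
  expect_equal(r0$p, 1)

  # 10 v 10 with 3 case carriers, 0 control carriers: compare to a
  # brute-force profile-likelihood grid oracle
  d <- c(rep(1, 3), rep(0, 7), rep(0, 10))
  y <- rep(c(1, 0), each = 10)
  r <- single_variant_lrt(d, y)
  l1 <- loglik_grid_max(d, y)
  l0 <- loglik_grid_max(d * 0, y)
  expect_equal(r$stat, 2 * (l1 - l0), tolerance = 1e-2)
  expect_equal(r$p, pchisq(2 * (l1 - l0), 1, lower.tail = FALSE),
               tolerance = 1e-2)
  expect_true("quasi_separated" %in% r$flags)

  # duplicating every sample doubles the statistic
  set.seed(3)
  d2 <- rbinom(40, 2, 0.3); y2 <- rep(c(1, 0), 20)
  ra <- single_variant_lrt(d2, y2)
  rb <- single_variant_lrt(rep(d2, 2), rep(y2, 2))
  expect_equal(rb$stat, 2 * ra$stat, tolerance = 1e-6)
})

test_that("burden score test reproduces the printed very-rare gene results", {
  # 927 cases / 4,057 controls; 6 distinct het case carriers, 0 in controls
  co6 <- carrier_cohort(927, 4057, 6, m = 5)
  r6 <- burden_score_test(gene_setup(co6), co6)
  expect_equal(r6$result$p, 2.94e-7, tolerance = 0.005)
  # 4 het case carriers
  co4 <- carrier_cohort(927, 4057, 4, m = 4)
  r4 <- burden_score_test(gene_setup(co4), co4)
  expect_equal(r4$result$p, 2.84e-5, tolerance = 0.005)
  # 1 het case carrier at both stage scales
  co1 <- carrier_cohort(927, 4057, 1, m = 2)
  expect_equal(burden_score_test(gene_setup(co1), co1)$result$p, 0.0364,
               tolerance = 0.005)
  co1b <- carrier_cohort(1810, 2647, 1, m = 2)
  expect_equal(burden_score_test(gene_setup(co1b), co1b)$result$p, 0.2265,
               tolerance = 0.005)
})

test_that("burden score test degenerates to p = 1 without carriers and is
           invariant to weight rescaling", {
  co <- carrier_cohort(10, 10, 0, m = 2)
  r <- burden_score_test(gene_setup(co), co)
  expect_equal(r$result$p, 1)
  expect_true("degenerate" %in% r$result$flags)

  set.seed(8)
  co2 <- toy_cohort(matrix(rbinom(60, 2, 0.2), 20, 3))
  w <- c(0.5, 1, 2)
  ra <- burden_score_test(gene_setup(co2), co2, weights = w)
  rb <- burden_score_test(gene_setup(co2), co2, weights = 7.3 * w)
  expect_equal(ra$result$stat, rb$result$stat, tolerance = 1e-12)
  expect_equal(ra$result$p, rb$result$p, tolerance = 1e-12)
})

test_that("burden asymptotic p tracks the exhaustive label-permutation p", {
  # carrier-count construction: the permutation p has a closed
  # hypergeometric form (3 case carriers / 1 control carrier among 8v8)
  geno0 <- matrix(0L, 16, 2)
  geno0[1:3, 1] <- 1L; geno0[9, 2] <- 1L
  stat0 <- function(y) {
    b <- rowSums(geno0); yb <- mean(y)
    V <- yb * (1 - yb) * sum((b - mean(b))^2)
    sum((y - yb) * b)^2 / V
  }
  p_exact <- perm_pvalue(geno0, 8, stat0)
  # 1 - P(exactly 2 of the 4 carriers are cases)
  expect_equal(p_exact, 1 - 784 / 1820, tolerance = 1e-12)

  # asymptotic p must sit inside the permutation tail bracket
  # [P(stat > obs), P(stat >= obs)] up to a small asymptotic allowance:
  # the permutation law at n = 16 is coarse, so both tails are reported
  set.seed(1)
  geno <- matrix(rbinom(48, 2, 0.4), 16, 3)
  co <- toy_cohort(geno, status = rep(c(1L, 0L), each = 8))
  r <- burden_score_test(gene_setup(co), co)
  stat_fn <- function(y) {
    b <- rowSums(geno); yb <- mean(y)
    V <- yb * (1 - yb) * sum((b - mean(b))^2)
    if (V <= 0) return(0)
    sum((y - yb) * b)^2 / V
  }
  br <- perm_bracket(geno, 8, stat_fn)
  expect_gte(r$result$p, br[1] - 0.1)
  expect_lte(r$result$p, br[2] + 0.1)
})

test_that("SKAT reduces to the marginal score test for a single effective
           variant and matches a permutation oracle", {
  # second variant is a zero column
  geno <- cbind(c(rep(1L, 4), rep(0L, 16)), rep(0L, 20))
  co <- toy_cohort(geno, status = rep(c(1L, 0L), each = 10))
  r <- skat_test(gene_setup(co), co)
  marg <- burden_score_test(gene_setup(co, co$variants$key[1:2]), co,
                            weights = c(1, 0))
  expect_equal(r$result$p, marg$result$p, tolerance = 1e-6)

  set.seed(1)
  geno2 <- matrix(rbinom(48, 2, 0.4), 16, 3)
  co2 <- toy_cohort(geno2, status = rep(c(1L, 0L), each = 8))
  r2 <- skat_test(gene_setup(co2), co2)
  stat_fn <- function(y) {
    yb <- mean(y)
    sum(drop(crossprod(geno2, y - yb))^2)
  }
  br <- perm_bracket(geno2, 8, stat_fn)
  expect_gte(r2$result$p, br[1] - 0.1)
  expect_lte(r2$result$p, br[2] + 0.1)

  rw <- skat_test(gene_setup(co2), co2, weights = c(0, 0, 0))
  expect_equal(rw$result$p, 1)
  expect_true("degenerate" %in% rw$result$flags)
})

test_that("SKAT-O reduces exactly to burden at rho 1 and SKAT at rho 0,
           stays within its min-p envelope, and tracks a permutation oracle", {
  set.seed(9)
  geno <- matrix(rbinom(48, 2, 0.2), 16, 3)
  co <- toy_cohort(geno, status = rep(c(1L, 0L), each = 8))
  su <- gene_setup(co)
  pb <- burden_score_test(su, co)$result$p
  ps <- skat_test(su, co)$result$p
  expect_equal(skato_test(su, co, config = skato_config(rho_grid = 1))$result$p,
               pb, tolerance = 1e-10)
  expect_equal(skato_test(su, co, config = skato_config(rho_grid = 0))$result$p,
               ps, tolerance = 1e-10)

  ro <- skato_test(su, co)$result
  minp <- min(ro$p_rho)
  expect_gte(ro$p, minp - 1e-12)
  expect_lte(ro$p, length(ro$rho_grid) * minp + 1e-12)

  # permutation oracle of the same min-p statistic on a small instance
  cfg <- skato_config()
  grid_c <- pmin(cfg$rho_grid, 0.999)
  set.seed(2)
  geno14 <- matrix(rbinom(42, 2, 0.4), 14, 3)
  co14 <- toy_cohort(geno14, status = rep(c(1L, 0L), each = 7))
  p_impl <- skato_test(gene_setup(co14), co14)$result$p
  minp_stat <- function(y) {
    yb <- mean(y); v <- yb * (1 - yb)
    S <- drop(crossprod(geno14, y - yb))
    Phi <- v * crossprod(sweep(geno14, 2, colMeans(geno14)))
    qs <- sum(S^2); qb <- sum(S)^2
    -min(vapply(grid_c, function(r)
      pchisq_mixture((1 - r) * qs + r * qb,
                     exburden:::lambda_rho(Phi, r, ncol(geno14))),
      numeric(1)))
  }
  br <- perm_bracket(geno14, 7, minp_stat)
  expect_gte(p_impl, br[1] - 0.1)
  expect_lte(p_impl, br[2] + 0.1)
})

test_that("odds-ratio conventions reproduce printed stage-1 values", {
  # allele-frequency-ratio OR from printed Table rows
  expect_equal(allele_or(allele_counts(7, 2, 927, 4057))$or_freq, 15.32,
               tolerance = 0.001)
  expect_equal(allele_or(allele_counts(14, 29, 927, 4057))$or_freq, 2.11,
               tolerance = 0.005)
  expect_equal(allele_or(allele_counts(7, 10, 927, 4057))$or_freq, 3.06,
               tolerance = 0.005)
  expect_equal(allele_or(allele_counts(25, 70, 927, 4057))$or_freq, 1.56,
               tolerance = 0.005)
  # symmetry
  expect_equal(allele_or(allele_counts(5, 5, 100, 100))$or_freq, 1)
  # zero control cell: infinite frequency OR, Haldane-adjusted companion
  # (4.5 * 8114.5) / (0.5 * 1850.5)
  oz <- allele_or(allele_counts(4, 0, 927, 4057))
  expect_equal(oz$or_freq, Inf)
  expect_equal(oz$or_adj, (4.5 * 8114.5) / (0.5 * 1850.5), tolerance = 1e-12)
  expect_true(oz$ci_lo < oz$or_adj && oz$or_adj < oz$ci_hi)
  # no carriers anywhere: undefined and flagged
  expect_true("no_carriers" %in% allele_or(allele_counts(0, 0, 10, 10))$flags)
})

test_that("HWE chi-square handles equilibrium, deficit and flipped counts", {
  expect_equal(hwe_chisq(genotype_counts(25, 50, 25))$stat, 0)
  expect_equal(hwe_chisq(genotype_counts(25, 50, 25))$p, 1)
  # direct formula oracle for complete het deficit
  h <- hwe_chisq(genotype_counts(50, 0, 50))
  n <- 100; q <- 0.5
  expd <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  expect_equal(h$stat, sum((c(50, 0, 50) - expd)^2 / expd), tolerance = 1e-12)
  # all-homozygous-alt flips to monomorphic
  expect_equal(hwe_chisq(genotype_counts(0, 0, 10))$stat, 0)
  expect_equal(hwe_chisq(genotype_counts(0, 0, 10))$p, 1)
})

test_that("Fisher exact test matches hypergeometric enumeration", {
  # mouse viability: 0 observed vs 14 expected homozygotes among 56
  expect_lt(fisher_2x2(matrix(c(0, 56, 14, 42), 2)), 1e-4)
  expect_equal(fisher_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  # full enumeration oracle for a 2x2 with margins (10, 10) x (10, 10)
  tab <- matrix(c(1, 9, 9, 1), 2)
  k <- 0:10
  prob <- dhyper(k, 10, 10, 10)
  p_enum <- sum(prob[prob <= dhyper(1, 10, 10, 10) + 1e-12])
  expect_equal(fisher_2x2(tab), p_enum, tolerance = 1e-10)
})

test_that("Mendelian intercross expectation is a quarter, rounded half-up", {
  expect_equal(mendelian_expected(56), 14L)
  expect_equal(mendelian_expected(95), 24L)
  expect_equal(mendelian_expected(0), 0L)
  expect_equal(mendelian_expected(2), 1L)
})
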
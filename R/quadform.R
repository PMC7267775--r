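# Tail probabilities of chi-square mixtures and the SKAT / SKAT-O tests.
#
# Under the intercept-only null the per-variant score vector S is
# asymptotically N(0, Phi), so the SKAT statistic Q = S'S is distributed
# as sum_k lambda_k chi^2_1 with lambda the eigenvalues of Phi. Tail
# probabilities default to a Lugannani-Rice saddlepoint inversion (fast,
# uniformly accurate into the far tail); numerical characteristic-function
# inversion (Imhof) and Liu moment matching are available alternatives.

#' Upper tail of a weighted chi-square mixture
#'
#' P(sum_k lambda_k chi^2_1 > q). The default `"saddlepoint"` method is the
#' Lugannani-Rice saddlepoint inversion of the cumulant generating
#' function — uniformly accurate into the far tail and free of convergence
#' failures, so it is used for all routine testing. `"integration"` (also
#' accepted as `"davies"`) performs direct numerical inversion of the
#' characteristic function (Imhof's integral) and serves as the slow,
#' high-accuracy cross-check; `"moment_match"` is the Liu noncentral
#' chi-square approximation, also the fallback when the integral fails.
#'
#' @param q quantile.
#' @param lambda positive mixture weights (near-zero weights are dropped).
#' @param method p-value method.
#' @param tol relative tolerance of the numerical integral.
#' @return upper-tail probability, floored at 1e-300.
#' @export
pchisq_mixture <- function(q, lambda,
                           method = c("saddlepoint", "integration", "davies",
                                      "moment_match"),
                           tol = 1e-9) {
  method <- match.arg(method)
  lambda <- lambda[lambda > max(lambda, 0) * 1e-10]
  if (!length(lambda) || all(lambda <= 0)) return(1)
  if (length(lambda) == 1L)
    return(max(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE), 1e-300))
  if (method == "saddlepoint") {
    p <- saddlepoint_pvalue(q, lambda)
    if (!is.na(p)) return(min(1, max(p, 1e-300)))
    return(liu_pvalue(q, lambda))
  }
  if (method != "moment_match") {
    p <- tryCatch({
      integrand <- function(u) {
        theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
        rho <- exp(0.25 * colSums(log1p(outer(lambda, u)^2)))
        sin(theta) / (u * rho)
      }
      it <- stats::integrate(integrand, 0, Inf, rel.tol = tol,
                             abs.tol = tol, subdivisions = 1000L,
                             stop.on.error = TRUE)
      0.5 + it$value / pi
    }, error = function(e) NA_real_)
    if (!is.na(p) && p > -1e-6 && p < 1 + 1e-6)
      return(min(1, max(p, 1e-300)))
  }
  liu_pvalue(q, lambda)
}

# Lugannani-Rice saddlepoint approximation to the upper tail of
# sum lambda_k chi^2_1 (Kuonen-style inversion of the CGF
# K(s) = -1/2 sum log(1 - 2 s lambda)). Returns NA near the mean, where
# the approximation is singular (callers fall back to moment matching).
saddlepoint_pvalue <- function(q, lambda) {
  if (q <= 0) return(1)
  mu <- sum(lambda)
  if (abs(q - mu) < 1e-6 * mu) return(NA_real_)
  K <- function(s) -0.5 * sum(log1p(-2 * s * lambda))
  K1 <- function(s) sum(lambda / (1 - 2 * s * lambda))
  K2 <- function(s) 2 * sum(lambda^2 / (1 - 2 * s * lambda)^2)
  hi <- 1 / (2 * max(lambda))
  f <- function(s) K1(s) - q
  if (q > mu) {              # root in (0, hi)
    b <- hi * (1 - 1e-9)
    while (f(b) < 0) b <- hi - (hi - b) / 10
    lo_b <- 0
  } else {                   # root in (-inf, 0)
    lo_b <- -1
    while (f(lo_b) > 0) lo_b <- lo_b * 2
    b <- 0
  }
  s <- tryCatch(stats::uniroot(f, c(lo_b, b), tol = 1e-13)$root,
                error = function(e) NA_real_)
  if (is.na(s) || abs(s) < 1e-10) return(NA_real_)
  w <- sign(s) * sqrt(max(0, 2 * (s * q - K(s))))
  u <- s * sqrt(K2(s))
  if (w == 0 || u == 0) return(NA_real_)
  stats::pnorm(w + log(u / w) / w, lower.tail = FALSE)
}

# Saddlepoint upper tail for a noncentral mixture sum lambda_k chi^2_1(ncp_k)
# (used by the SKAT-O omnibus: conditional on the burden component the
# remainder is exactly such a mixture). Falls back to noncentral Liu
# moments near the mean.
sp_tail_ncmix <- function(q, lambda, ncp) {
  keep <- lambda > max(lambda, 0) * 1e-12
  lambda <- lambda[keep]; ncp <- ncp[keep]
  if (!length(lambda)) return(if (q <= 0) 1 else 0)
  mu <- sum(lambda * (1 + ncp))
  if (q <= 0) return(1)
  liu_nc <- function() {
    c1 <- sum(lambda * (1 + ncp)); c2 <- sum(lambda^2 * (1 + 2 * ncp))
    c3 <- sum(lambda^3 * (1 + 3 * ncp)); c4 <- sum(lambda^4 * (1 + 4 * ncp))
    s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
    if (s1^2 > s2) {
      a <- 1 / (s1 - sqrt(s1^2 - s2)); d <- s1 * a^3 - a^2; l <- a^2 - 2 * d
    } else { a <- 1 / sqrt(s2); d <- 0; l <- 1 / s2 }
    p <- stats::pchisq((q - c1) / sqrt(2 * c2) * sqrt(2) * a + l + d,
                       df = l, ncp = d, lower.tail = FALSE)
    min(1, max(p, 0))
  }
  if (abs(q - mu) < 1e-6 * max(mu, 1)) return(liu_nc())
  K <- function(s) sum(-0.5 * log1p(-2 * s * lambda) +
                         s * lambda * ncp / (1 - 2 * s * lambda))
  K1 <- function(s) sum(lambda / (1 - 2 * s * lambda) +
                          lambda * ncp / (1 - 2 * s * lambda)^2)
  K2 <- function(s) sum(2 * lambda^2 / (1 - 2 * s * lambda)^2 +
                          4 * lambda^2 * ncp / (1 - 2 * s * lambda)^3)
  hi <- 1 / (2 * max(lambda))
  f <- function(s) K1(s) - q
  if (q > mu) {
    b <- hi * (1 - 1e-9)
    while (f(b) < 0) b <- hi - (hi - b) / 10
    br <- c(0, b)
  } else {
    lo <- -1
    while (f(lo) > 0) lo <- lo * 2
    br <- c(lo, 0)
  }
  s <- tryCatch(stats::uniroot(f, br, tol = 1e-12)$root,
                error = function(e) NA_real_)
  if (is.na(s) || abs(s) < 1e-9) return(liu_nc())
  w <- sign(s) * sqrt(max(0, 2 * (s * q - K(s))))
  u <- s * sqrt(K2(s))
  if (w == 0 || u == 0) return(liu_nc())
  min(1, max(stats::pnorm(w + log(u / w) / w, lower.tail = FALSE), 0))
}

# Liu, Tang & Zhang (2009) moment-matched noncentral chi-square
# approximation to the mixture tail.
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / sqrt(s2); delta <- 0; l <- 1 / s2
  }
  mu_x <- l + delta; sigma_x <- sqrt(2) * a
  tstar <- (q - c1) / sqrt(2 * c2)
  p <- stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = delta,
                     lower.tail = FALSE)
  min(1, max(p, 1e-300))
}

# Moment-matched (Liu) quantile of a chi-square mixture at upper-tail
# probability p — closed form, used for the per-rho quantiles feeding the
# SKAT-O omnibus integral (the reference implementations do the same; the
# final p-values themselves use the numerical inversion).
qchisq_mixture <- function(p, lambda) {
  lambda <- lambda[lambda > max(lambda, 0) * 1e-10]
  if (!length(lambda)) return(0)
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2)); delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else { a <- 1 / sqrt(s2); delta <- 0; l <- 1 / s2 }
  mu_x <- l + delta; sigma_x <- sqrt(2) * a
  max(0, c1 + (stats::qchisq(p, df = l, ncp = delta, lower.tail = FALSE) -
                 mu_x) / sigma_x * sqrt(2 * c2))
}

# Gauss-Legendre nodes/weights on [0, upper] for the omnibus integral
# (Golub-Welsch; cached per session).
gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n, upper) {
  key <- paste0(n, "_", upper)
  if (!is.null(gl_cache[[key]])) return(gl_cache[[key]])
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta; J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  out <- list(x = (x + 1) * upper / 2, w = w * upper / 2)
  gl_cache[[key]] <- out
  out
}

#' SKAT-O configuration
#'
#' @param rho_grid mixing grid over \[0, 1\] for the burden/SKAT
#'   combination Q_rho = (1 - rho) Q_SKAT + rho Q_burden. The default is
#'   the standard 8-point grid containing both pure tests.
#' @param method quadratic-form p-value method, see [pchisq_mixture()].
#' @param tol integration tolerance.
#' @return a `skato_config` object.
#' @export
skato_config <- function(rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                         method = "saddlepoint", tol = 1e-9) {
  rho_grid <- sort(unique(rho_grid))
  stopifnot(all(rho_grid >= 0), all(rho_grid <= 1))
  structure(list(rho_grid = rho_grid, method = method, tol = tol),
            class = "skato_config")
}

# Core SKAT-O computation from a score vector and its null covariance.
# Returns list(stat = min-p Q, p, p_rho, q_rho, rho_grid, flags).
skato_from_scores <- function(S, Phi, config = skato_config()) {
  grid <- config$rho_grid
  m <- length(S)
  flags <- character()
  eig_tol <- max(diag(Phi), 0) * 1e-10
  if (all(diag(Phi) <= eig_tol))
    return(list(stat = 0, p = 1, p_rho = rep(1, length(grid)),
                q_rho = rep(0, length(grid)), rho_grid = grid,
                flags = "degenerate"))
  U <- sum(S); V <- sum(Phi)
  q_skat <- sum(S^2)
  q_burden <- U^2
  # exact reductions at the grid extremes
  p_single <- function(rho) {
    q_rho <- (1 - rho) * q_skat + rho * q_burden
    lam <- lambda_rho(Phi, rho, m)
    pchisq_mixture(q_rho, lam, config$method, config$tol)
  }
  if (length(grid) == 1L) {
    rho <- grid
    if (rho == 1)
      return(list(stat = q_burden,
                  p = stats::pchisq(q_burden / V, 1, lower.tail = FALSE),
                  p_rho = stats::pchisq(q_burden / V, 1, lower.tail = FALSE),
                  q_rho = q_burden, rho_grid = grid, flags = flags))
    p1 <- p_single(rho)
    return(list(stat = (1 - rho) * q_skat + rho * q_burden, p = p1,
                p_rho = p1, q_rho = (1 - rho) * q_skat + rho * q_burden,
                rho_grid = grid, flags = flags))
  }
  # clamp rho away from 1 so the Lee decomposition stays nonsingular
  grid_c <- pmin(grid, 0.999)
  q_rho <- (1 - grid_c) * q_skat + grid_c * q_burden
  lam_list <- lapply(grid_c, function(r) lambda_rho(Phi, r, m))
  p_rho <- vapply(seq_along(grid_c), function(i)
    pchisq_mixture(q_rho[i], lam_list[[i]], config$method, config$tol),
    numeric(1))
  minp <- min(p_rho)
  # Lee et al. omnibus: condition on the burden component
  b <- drop(Phi %*% rep(1, m))
  sigma2 <- sum(b)                      # 1' Phi 1
  if (sigma2 <= eig_tol) {
    # burden direction carries no variance; SKAT-O degenerates to SKAT
    i0 <- which.min(abs(grid))
    return(list(stat = q_rho[i0], p = p_rho[i0], p_rho = p_rho,
                q_rho = q_rho, rho_grid = grid, flags = "burden_degenerate"))
  }
  # conditional on the burden component xi (xi^2 = sigma2 * x, x ~ chi^2_1)
  # the remainder kappa = eta'eta + 2 xi c'eta is exactly a noncentral
  # chi-square mixture in the eigenbasis of Phi_eta; its tail is evaluated
  # by saddlepoint rather than the usual variance-matched central
  # approximation (which is visibly conservative for few variants)
  Phi_eta <- Phi - tcrossprod(b) / sigma2
  ee <- eigen(Phi_eta, symmetric = TRUE)
  pos <- ee$values > max(ee$values, 0) * 1e-10
  lam_pos <- ee$values[pos]
  d <- drop(crossprod(ee$vectors, b / sigma2))   # c in the eigenbasis
  d2_pos <- d[pos]^2
  tau <- grid_c * sigma2 + (1 - grid_c) * sum(b^2) / sigma2
  q_min <- vapply(lam_list, function(l) qchisq_mixture(minp, l), numeric(1))
  # substitute x = t^2 (t half-normal) so the chi^2_1 weight is smooth at 0
  gl <- gauss_legendre(128L, sqrt(40))
  xs <- gl$x^2
  delta <- vapply(xs, function(xx)
    min((q_min - tau * xx) / (1 - grid_c)), numeric(1))
  f_cond <- vapply(seq_along(xs), function(i) {
    xi2 <- sigma2 * xs[i]
    thr <- delta[i] + xi2 * sum(d2_pos)
    if (thr <= 0) return(0)
    if (!length(lam_pos)) return(1)
    1 - sp_tail_ncmix(thr, lam_pos, xi2 * d2_pos / lam_pos)
  }, numeric(1))
  p <- 1 - sum(gl$w * f_cond * 2 * stats::dnorm(gl$x))
  # the omnibus p can never beat its best component nor exceed the
  # Bonferroni bound over the grid
  p <- min(max(p, minp, 1e-300), min(1, minp * length(grid)))
  i_min <- which.min(p_rho)
  list(stat = q_rho[i_min], p = p, p_rho = p_rho, q_rho = q_rho,
       rho_grid = grid, rho_min = grid[i_min], flags = flags)
}

# Eigenvalues of R_rho^{1/2} Phi R_rho^{1/2}, R_rho = (1-rho) I + rho J.
lambda_rho <- function(Phi, rho, m) {
  if (rho == 0) {
    lam <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  } else {
    a <- sqrt(1 - rho)
    bb <- (sqrt(1 - rho + m * rho) - a) / m
    Rh <- matrix(bb, m, m); diag(Rh) <- a + bb
    lam <- eigen(Rh %*% Phi %*% Rh, symmetric = TRUE,
                 only.values = TRUE)$values
  }
  lam[lam > max(lam, 0) * 1e-10]
}

#' SKAT variance-component test for a gene
#'
#' Q = sum_j (w_j S_j)^2 with the null distribution sum_k lambda_k chi^2_1,
#' lambda the eigenvalues of the weighted, centered genotype cross-product
#' scaled by ybar (1 - ybar).
#'
#' @inheritParams score_stat
#' @param config a [skato_config()] (p-value method settings).
#' @return list(result, score) as in [burden_score_test()].
#' @export
skat_test <- function(setup, x, weights = NULL, config = skato_config()) {
  if (length(setup$variants) < 2L)
    stop("gene-based tests need at least 2 qualifying variants")
  ss <- score_stat(setup, x, weights)
  skat_from_score(ss, config)
}

skat_from_score <- function(ss, config = skato_config(), unit = NULL) {
  unit <- unit %||% paste0(ss$gene, if (!is.na(ss$mask)) paste0(":", ss$mask))
  lam <- eigen(ss$Phi, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam, 0) * 1e-10]
  q <- sum(ss$S^2)
  if (!length(lam)) {
    res <- new_assoc_result(unit, "skat", 0, 1, ss$counts, length(ss$S),
                            flags = "degenerate")
    return(list(result = res, score = ss))
  }
  p <- pchisq_mixture(q, lam, config$method, config$tol)
  res <- new_assoc_result(unit, "skat", q, p, ss$counts, length(ss$S))
  list(result = res, score = ss)
}

#' SKAT-O optimal burden/SKAT combination for a gene
#'
#' Evaluates Q_rho = (1 - rho) Q_SKAT + rho Q_burden over the rho grid and
#' combines the per-rho p-values with the one-dimensional integration over
#' the shared burden component (the minimum-p construction of the optimal
#' unified test). A single-point grid \{1\} reduces exactly to the burden
#' test and \{0\} to SKAT.
#'
#' @inheritParams skat_test
#' @return list(result, score); the result carries `p_rho`, `rho_grid` and
#'   the minimising `rho_min` as extra fields.
#' @export
skato_test <- function(setup, x, weights = NULL, config = skato_config()) {
  if (length(setup$variants) < 2L)
    stop("gene-based tests need at least 2 qualifying variants")
  ss <- score_stat(setup, x, weights)
  skato_from_score(ss, config)
}

skato_from_score <- function(ss, config = skato_config(), unit = NULL) {
  unit <- unit %||% paste0(ss$gene, if (!is.na(ss$mask)) paste0(":", ss$mask))
  sk <- skato_from_scores(ss$S, ss$Phi, config)
  res <- new_assoc_result(unit, "skato", sk$stat, sk$p, ss$counts,
                          length(ss$S), flags = sk$flags,
                          extra = list(p_rho = sk$p_rho,
                                       rho_grid = sk$rho_grid,
                                       rho_min = sk$rho_min %||% NA_real_))
  list(result = res, score = ss)
}
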
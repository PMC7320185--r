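# The HEIDI heterogeneity test: do the Wald-ratio estimates at SNPs in LD
# with the instrument agree with the instrument's estimate? Homogeneity is
# what pleiotropy (one shared causal variant) predicts; heterogeneity points
# to linkage of distinct causal variants.

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch, memoized.
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  jac <- matrix(0, n, n)
  jac[cbind(i, i + 1)] <- b
  jac[cbind(i + 1, i)] <- b
  e <- eigen(jac, symmetric = TRUE)
  out <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
  ord <- order(out$nodes)
  out <- list(nodes = out$nodes[ord], weights = out$weights[ord])
  .gl_cache[[key]] <- out
  out
}

#' Upper tail of a weighted sum of 1-df chi-squares
#'
#' Computes `P(sum_k lambda_k * chisq_1 > q)` by numerical inversion of the
#' characteristic function (Imhof's method, adaptive quadrature). When the
#' quadrature fails to converge, falls back to two-moment Satterthwaite
#' matching (`a * chisq_d` with the same mean and variance); the `"method"`
#' attribute of the result records which path was used.
#'
#' @param q Observed statistic (scalar, non-negative).
#' @param lambda Positive weights (eigenvalues of the null correlation
#'   structure); non-positive values are dropped.
#' @return Tail probability in \[0, 1\] with attribute `method` equal to
#'   `"imhof"` or `"satterthwaite"`.
#' @export
pwsumchisq <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-8 * max(lambda, 0)]
  if (!length(lambda)) return(structure(1, method = "degenerate"))
  if (q <= 0) return(structure(1, method = "exact"))
  if (length(lambda) == 1) {
    return(structure(
      pchisq(q / lambda, df = 1, lower.tail = FALSE),
      method = "exact"
    ))
  }
  # scale invariance: P(sum lambda chi2 > q) = P(sum (lambda/c) chi2 > q/c)
  c0 <- max(lambda)
  lam <- lambda / c0
  qq <- q / c0
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lam, u))) - 0.5 * qq * u
    rho <- exp(0.25 * colSums(log1p(outer(lam^2, u^2))))
    out <- sin(theta) / (u * rho)
    out[u == 0] <- (sum(lam) - qq) / 2 # continuous limit at u -> 0
    out
  }
  # The integrand oscillates with asymptotic period 4*pi/q and decays like
  # u^-(k/2 + 1). Panel quadrature: blocks of about two periods, a fixed
  # 20-node Gauss-Legendre rule per block (ample for ~2 oscillations),
  # evaluated in one vectorized call. The truncation point is where the
  # envelope amplitude divided by the oscillation rate drops below 1e-11.
  amp <- function(u) {
    1 / (u * exp(0.25 * colSums(log1p(outer(lam^2, u^2)))))
  }
  grid <- exp(seq(log(0.5), log(1e6), length.out = 400))
  tail_bound <- (4 / (pi * qq)) * amp(grid)
  upper <- if (any(tail_bound < 1e-11)) grid[which(tail_bound < 1e-11)[1]] else 1e6
  block <- min(max(4 * pi / qq, 0.25), 50)
  n_blocks <- min(ceiling(upper / block), 50000L)
  gl <- .gauss_legendre(20L)
  starts <- (seq_len(n_blocks) - 1) * block
  u <- rep(starts, each = 20L) + rep((gl$nodes + 1) / 2 * block, n_blocks)
  w <- rep(gl$weights / 2 * block, n_blocks)
  total <- sum(w * integrand(u))
  p <- 0.5 + total / pi
  if (is.finite(p) && p > -1e-6 && p < 1 + 1e-6) {
    return(structure(min(max(p, 1e-300), 1), method = "imhof"))
  }
  # Satterthwaite: match E[Q] = sum(lambda), Var[Q] = 2 sum(lambda^2)
  a <- sum(lambda^2) / sum(lambda)
  d <- sum(lambda)^2 / sum(lambda^2)
  structure(
    pchisq(q / a, df = d, lower.tail = FALSE),
    method = "satterthwaite"
  )
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Candidate SNPs are the analysis set minus the instrument, restricted to
#' LD with the instrument inside `r2_window` (SNPs in near-perfect LD carry
#' no independent information; SNPs in negligible LD are not instruments for
#' the same signal), ranked by eQTL significance and truncated to
#' `max_snps`. For each candidate the deviation
#' `d_i = b_xy(i) - b_xy(top)` is formed; its covariance matrix is
#' assembled by the first-order delta method with LD correlations,
#' \deqn{Cov(b_{xy,i}, b_{xy,j}) \approx b_{xy,i} b_{xy,j}
#'   \left[\frac{r_{ij}}{z_{g,i} z_{g,j}} + \frac{r_{ij}}{z_{e,i} z_{e,j}}\right]}
#' and the statistic is `S = sum((d_i / sd_i)^2)`, whose null distribution
#' is a weighted sum of 1-df chi-squares with weights the eigenvalues of the
#' correlation matrix of the standardized deviations (see [pwsumchisq()]).
#' Testing requires at least `min_snps` candidates.
#'
#' @param analysis_set Harmonized, MAF-filtered SNP tibble (the analysis set
#'   from [filter_snps()]), including the instrument.
#' @param ld A `genotype_panel` or `ld_view` covering the SNPs.
#' @param top rsid of the instrument SNP.
#' @param min_snps Minimum candidate SNPs for the test to run (default 3).
#' @param max_snps Maximum candidate SNPs used (default 20).
#' @param r2_window Inclusive r-squared window with the instrument for a
#'   candidate to be eligible (default `c(0.05, 0.9)`).
#' @param ridge Diagonal ridge for the eigen-decomposition (default 1e-8).
#' @return A one-row tibble: `snps_used`, `s_heidi`, `p_heidi`, `status`
#'   (`"tested"`, `"skipped_too_few_snps"` or `"skipped_no_instrument"`),
#'   `tail_method`.
#' @export
heidi_test <- function(analysis_set, ld, top,
                       min_snps = 3, max_snps = 20,
                       r2_window = c(0.05, 0.9), ridge = 1e-8) {
  skip <- function(status) tibble::tibble(
    snps_used = 0L, s_heidi = NA_real_, p_heidi = NA_real_,
    status = status, tail_method = NA_character_
  )
  if (is.na(top) || !top %in% analysis_set$rsid) {
    return(skip("skipped_no_instrument"))
  }
  ldv <- if (inherits(ld, "genotype_panel")) {
    have <- intersect(analysis_set$rsid, ld$variants$rsid)
    ld_matrix(ld, have)
  } else {
    ld
  }
  snps <- analysis_set[analysis_set$rsid %in% ldv$rsids, , drop = FALSE]
  if (!top %in% snps$rsid) return(skip("skipped_no_instrument"))
  r_top <- ldv$r[snps$rsid, top]
  eligible <- snps$rsid != top &
    r_top^2 >= r2_window[1] & r_top^2 <= r2_window[2] &
    !is.na(snps$b_eqtl) & snps$b_eqtl != 0
  cand <- snps[eligible, , drop = FALSE]
  if (nrow(cand) < min_snps) return(skip("skipped_too_few_snps"))
  cand <- cand[order(cand$p_eqtl, cand$pos, cand$rsid), , drop = FALSE]
  cand <- head(cand, max_snps)

  topr <- snps[snps$rsid == top, ]
  all_snps <- dplyr::bind_rows(topr, cand)
  b_xy <- all_snps$b_gwas / all_snps$b_eqtl
  z_g <- all_snps$z_gwas
  z_e <- all_snps$z_eqtl
  r <- ldv$r[all_snps$rsid, all_snps$rsid]

  # delta-method covariance of the Wald ratios (index 1 = instrument)
  cov_bxy <- outer(b_xy, b_xy) * (r / outer(z_g, z_g) + r / outer(z_e, z_e))
  m <- nrow(cand)
  idx <- seq_len(m) + 1L
  v <- cov_bxy[idx, idx, drop = FALSE] -
    matrix(cov_bxy[idx, 1], m, m) -
    t(matrix(cov_bxy[idx, 1], m, m)) +
    cov_bxy[1, 1]
  d <- b_xy[idx] - b_xy[1]
  sd_d <- sqrt(pmax(diag(v), 1e-300))
  u <- d / sd_d
  s <- sum(u^2)
  if (s <= 1e-12) {
    return(tibble::tibble(
      snps_used = m, s_heidi = 0, p_heidi = 1,
      status = "tested", tail_method = "exact"
    ))
  }
  corr <- v / outer(sd_d, sd_d)
  corr <- (corr + t(corr)) / 2
  corr <- cov2cor(corr + diag(ridge, m))
  lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  p <- pwsumchisq(s, lambda)
  tibble::tibble(
    snps_used = m, s_heidi = s,
    p_heidi = max(min(as.numeric(p), 1), 1e-300),
    status = "tested", tail_method = attr(p, "method")
  )
}
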
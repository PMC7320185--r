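# Independent oracles and small fixture builders used across the suite.
# Each oracle is a direct transcription of a definition, kept free of any
# package internals it is used to check.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} min(m p_(j) / j, 1)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(p[ord] * m / seq_len(m), 1)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Brute-force connected components by repeated neighbour expansion over an
# adjacency matrix.
components_oracle <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    frontier <- s
    comp[s] <- cid
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] & is.na(comp))
        comp[nb] <- cid
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
  }
  comp
}

# Monte-Carlo oracle for the upper tail of sum(lambda_k chi2_1): draws from
# the null MVN of the standardized deviation vector with correlation C.
mc_tail_oracle <- function(q, corr, n_draws = 200000L, seed = 99L) {
  set.seed(seed)
  ch <- chol(corr + diag(1e-10, nrow(corr)))
  z <- matrix(rnorm(n_draws * nrow(corr)), ncol = nrow(corr)) %*% ch
  s <- rowSums(z^2)
  p_hat <- mean(s > q)
  list(p = p_hat, se = sqrt(p_hat * (1 - p_hat) / n_draws))
}

# Tiny GWAS summary table with full control over each field.
toy_gwas <- function(rsid = c("rs1", "rs2", "rs3"),
                     pos = c(100, 200, 300),
                     beta = c(0.10, 0.05, -0.02),
                     se = c(0.02, 0.02, 0.02),
                     maf = c(0.25, 0.30, 0.40),
                     chrom = "1",
                     a1 = "A", a2 = "G") {
  n <- length(rsid)
  tibble::tibble(
    rsid = rsid, chrom = chrom, pos = pos,
    allele_effect = rep_len(a1, n), allele_other = rep_len(a2, n),
    beta = beta, se = se, z = beta / se,
    pvalue = 2 * pnorm(-abs(beta / se)), maf = maf, n = 1000
  )
}

toy_eqtl <- function(..., probe_id = "p1", gene = "G1", tissue = "blood") {
  tab <- toy_gwas(...)
  tab$probe_id <- probe_id
  tab$gene <- gene
  tab$tissue <- tissue
  dplyr::relocate(tab, probe_id, gene, tissue)
}

# Harmonized-record tibble straight from chosen z/b values (bypasses file
# plumbing for the statistical tests).
toy_harmonized <- function(rsid, z_gwas, z_eqtl,
                           se_gwas = 0.01, se_eqtl = 0.05,
                           pos = seq_along(rsid) * 100,
                           maf = 0.3) {
  tibble::tibble(
    rsid = rsid, chrom = "1", pos = pos,
    allele_effect = "A", allele_other = "G",
    b_gwas = z_gwas * se_gwas, se_gwas = se_gwas, z_gwas = z_gwas,
    p_gwas = 2 * pnorm(-abs(z_gwas)),
    b_eqtl = z_eqtl * se_eqtl, se_eqtl = se_eqtl, z_eqtl = z_eqtl,
    p_eqtl = 2 * pnorm(-abs(z_eqtl)),
    maf_gwas = maf, maf_eqtl = maf
  )
}

# AR(1)-style correlation matrix wrapped as an ld_view.
toy_ld <- function(rsids, rho = 0.8) {
  m <- length(rsids)
  r <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  dimnames(r) <- list(rsids, rsids)
  as_ld_view(r)
}

# Minimal VCF text for panel-reading tests.
write_toy_vcf <- function(path, extra_triallelic = FALSE) {
  gts <- c(
    "0/0\t0/1\t1/1\t0/1",
    "0/1\t0/1\t1/1\t0/0",
    "0/0\t0/0\t0/1\t1/1"
  )
  lines <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3\ts4",
    paste0("1\t1000\trsA\tA\tG\t.\tPASS\t.\tGT\t", gts[1]),
    paste0("1\t2000\trsB\tC\tT\t.\tPASS\t.\tGT\t", gts[2]),
    paste0("1\t3000\trsC\tG\tA\t.\tPASS\t.\tGT\t", gts[3])
  )
  if (extra_triallelic) {
    lines <- c(lines, "1\t4000\trsD\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2\t1/2\t0/0")
  }
  writeLines(lines, path)
  path
}
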
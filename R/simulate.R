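# Synthetic study generator: an LD-structured genotype panel plus paired
# GWAS / cis-eQTL summary statistics under pleiotropy, linkage or null
# architectures. Summary statistics are simulated directly on the z-score
# scale — z ~ MVN(R lambda, R) with R the panel LD matrix and lambda a
# non-centrality vector placed at the causal SNP(s) — which gives exact
# marginal distributional control and is orders of magnitude faster than
# individual-level phenotype regression. Betas and SEs are back-filled
# assuming standardized phenotypes: se = 1/sqrt(2 maf (1-maf) n).

#' Configuration for one simulated GWAS/eQTL study
#'
#' The defaults are the package's reference study conditions: a 500-sample
#' reference panel of 30 SNPs forming a dense LD block (latent AR(1)
#' correlation 0.9, i.e. adjacent dosage r-squared around 0.5-0.65 after
#' threshold attenuation), minor-allele
#' frequencies in \[0.1, 0.5\], non-centrality 8 at the causal SNP for both
#' traits, a GWAS of 221,568 individuals (a large European CAD
#' meta-analysis scale) and an eQTL study of 500 individuals (a typical
#' expression cohort scale).
#'
#' @param scenario `"pleiotropy"` (one SNP causal for both traits),
#'   `"linkage"` (two distinct causal SNPs in LD) or `"null"` (no trait
#'   effect; the eQTL effect remains).
#' @param n_individuals,n_snps Reference-panel size.
#' @param ld_rho AR(1) correlation of the latent haplotype process, in
#'   \[0, 1).
#' @param maf_range Range minor-allele frequencies are drawn from
#'   (uniform), inside \[0.03, 0.5\].
#' @param causal_index_gwas,causal_index_eqtl Causal SNP indices; must be
#'   equal under pleiotropy and distinct under linkage.
#' @param lambda_gwas,lambda_eqtl Non-centrality magnitudes (z-score scale)
#'   at the causal SNPs; `lambda_gwas` is forced to 0 under the null.
#' @param n_gwas,n_eqtl Nominal sample sizes used to back-fill betas/SEs.
#' @param seed Integer seed; every draw is deterministic given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(scenario = c("pleiotropy", "linkage", "null"),
                       n_individuals = 500, n_snps = 30, ld_rho = 0.9,
                       maf_range = c(0.1, 0.5),
                       causal_index_gwas = NULL, causal_index_eqtl = NULL,
                       lambda_gwas = 8, lambda_eqtl = 8,
                       n_gwas = 221568, n_eqtl = 500, seed = 1L) {
  scenario <- match.arg(scenario)
  mid <- max(1L, n_snps %/% 2L)
  causal_index_gwas <- causal_index_gwas %||% mid
  causal_index_eqtl <- causal_index_eqtl %||%
    if (scenario == "linkage") min(mid + 1L, n_snps) else causal_index_gwas
  if (scenario == "null") lambda_gwas <- 0
  cfg <- list(
    scenario = scenario, n_individuals = n_individuals, n_snps = n_snps,
    ld_rho = ld_rho, maf_range = maf_range,
    causal_index_gwas = causal_index_gwas,
    causal_index_eqtl = causal_index_eqtl,
    lambda_gwas = lambda_gwas, lambda_eqtl = lambda_eqtl,
    n_gwas = n_gwas, n_eqtl = n_eqtl, seed = as.integer(seed)
  )
  if (ld_rho < 0 || ld_rho >= 1) abort("ld_rho must lie in [0, 1).")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] < 0.03 || maf_range[2] > 0.5) {
    abort("maf_range must be an ordered pair inside [0.03, 0.5].")
  }
  if (any(c(causal_index_gwas, causal_index_eqtl) < 1) ||
      any(c(causal_index_gwas, causal_index_eqtl) > n_snps)) {
    abort("Causal indices must lie in 1..n_snps.")
  }
  if (scenario == "pleiotropy" && causal_index_gwas != causal_index_eqtl) {
    abort("Pleiotropy requires equal causal indices.")
  }
  if (scenario == "linkage" && causal_index_gwas == causal_index_eqtl) {
    abort("Linkage requires distinct causal indices.")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate an LD-structured reference genotype panel
#'
#' Each individual gets two haplotypes; each haplotype is a latent AR(1)
#' standard-normal process thresholded at the normal quantile of the SNP's
#' allele frequency, so marginal genotypes are in Hardy-Weinberg proportions
#' and adjacent SNPs carry the tetrachoric-induced LD of the latent
#' correlation. MAFs are drawn uniformly from `maf_range`. Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `genotype_panel`.
#' @export
simulate_panel <- function(config) {
  set.seed(config$seed)
  m <- config$n_snps
  n <- config$n_individuals
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  thr <- qnorm(maf)
  hap <- function() {
    z <- matrix(rnorm(n * m), n, m)
    for (j in 2:m) {
      z[, j] <- config$ld_rho * z[, j - 1] +
        sqrt(1 - config$ld_rho^2) * z[, j]
    }
    z < matrix(thr, n, m, byrow = TRUE)
  }
  dosage <- hap() + hap()
  storage.mode(dosage) <- "double"
  variants <- tibble::tibble(
    rsid = sprintf("snp%03d", seq_len(m)),
    chrom = "1",
    pos = 1e6 + (seq_len(m) - 1) * 2000,
    allele_ref = "A", allele_alt = "G",
    maf = pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2)
  )
  keep <- apply(dosage, 2, stats::var) > 0
  new_genotype_panel(
    paste0("ind", seq_len(n)),
    variants[keep, , drop = FALSE],
    dosage[, keep, drop = FALSE]
  )
}

#' Simulate paired GWAS and cis-eQTL summary statistics over a panel
#'
#' Marginal z-score vectors for the two traits are drawn independently as
#' MVN(R lambda, R), where R is the panel's empirical LD matrix and lambda
#' places the configured non-centrality at the causal index of each trait.
#' Betas and SEs are back-filled on the standardized-phenotype scale using
#' the panel allele frequencies and the nominal sample sizes. Deterministic
#' given `config$seed` (offset so the panel and the statistics use
#' independent streams).
#'
#' @param config A [sim_config()].
#' @param panel A panel from [simulate_panel()] (or any `genotype_panel`
#'   covering `n_snps` variants).
#' @param ridge Diagonal ridge applied to R before the Cholesky root
#'   (default 1e-6).
#' @return A `sim_study` list: `panel`, `gwas` and `eqtl` validated
#'   summary-statistic tibbles, `ld` (`ld_view` of R), and `truth` (scenario
#'   label, causal rsids, true expression-to-trait effect ratio `b_xy_true`
#'   under pleiotropy).
#' @export
simulate_summary_stats <- function(config, panel, ridge = 1e-6) {
  set.seed(config$seed + 1000003L)
  v <- panel$variants
  m <- nrow(v)
  r <- ld_matrix(panel, v$rsid)$r
  ch <- tryCatch(
    chol(r + diag(ridge, m)),
    error = function(e) abort(
      "LD matrix not positive semi-definite even after ridge; increase `ridge`."
    )
  )
  draw_z <- function(lambda_vec) {
    as.numeric(r %*% lambda_vec + t(ch) %*% rnorm(m))
  }
  lam_g <- numeric(m)
  lam_g[config$causal_index_gwas] <- config$lambda_gwas
  lam_e <- numeric(m)
  lam_e[config$causal_index_eqtl] <- config$lambda_eqtl
  z_g <- draw_z(lam_g)
  z_e <- draw_z(lam_e)

  mk_table <- function(z, n_trait) {
    se <- 1 / sqrt(2 * v$maf * (1 - v$maf) * n_trait)
    tibble::tibble(
      rsid = v$rsid, chrom = v$chrom, pos = v$pos,
      allele_effect = v$allele_alt, allele_other = v$allele_ref,
      beta = z * se, se = se, z = z, pvalue = p_from_z(z),
      maf = v$maf, n = n_trait
    )
  }
  gwas <- read_sumstats(mk_table(z_g, config$n_gwas))
  eqtl <- read_sumstats(
    mk_table(z_e, config$n_eqtl),
    probe = list(probe_id = "probe1", gene = "GENE1", tissue = "simulated")
  )
  b_xy_true <- if (config$scenario == "pleiotropy" && config$lambda_eqtl != 0) {
    (config$lambda_gwas / sqrt(config$n_gwas)) /
      (config$lambda_eqtl / sqrt(config$n_eqtl))
  } else {
    NA_real_
  }
  structure(
    list(
      panel = panel, gwas = gwas, eqtl = eqtl,
      ld = as_ld_view(r),
      truth = list(
        scenario = config$scenario,
        causal_gwas = v$rsid[config$causal_index_gwas],
        causal_eqtl = v$rsid[config$causal_index_eqtl],
        causal_r2 = r[config$causal_index_gwas, config$causal_index_eqtl]^2,
        b_xy_true = b_xy_true
      ),
      config = config
    ),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study> scenario=", x$truth$scenario, ", ",
      nrow(x$gwas), " SNPs\n", sep = "")
  invisible(x)
}

#' Expected downstream colocalization call for a scenario
#'
#' Maps the generative architecture onto the call the decision rule should
#' produce when effects are strong: pleiotropy (one shared causal variant)
#' should pass; linkage of two distinct causal variants should be rejected
#' by the heterogeneity test; a null trait should fail the SMR stage. When
#' the two causal variants of a linkage scenario are in near-perfect LD the
#' architectures are statistically indistinguishable and the expectation is
#' flagged instead of asserted.
#'
#' @param config A [sim_config()].
#' @param causal_r2 Observed r-squared between the two causal SNPs (used
#'   only for the linkage scenario; defaults to unknown).
#' @return A list with `expected_call` and `indistinguishable` (logical).
#' @export
scenario_truth <- function(config, causal_r2 = NA_real_) {
  expected <- switch(config$scenario,
    pleiotropy = "pass",
    linkage = "fail_heidi",
    null = "fail_smr"
  )
  indist <- config$scenario == "linkage" &&
    !is.na(causal_r2) && causal_r2 > 0.95
  list(expected_call = expected, indistinguishable = indist)
}
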
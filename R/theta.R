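# Theta similarity metric between two association patterns at a locus — a
# lighter-weight companion check to HEIDI. Implemented as the Pearson
# correlation of effect-aligned z-score vectors over the shared filtered
# SNPs; the metric sits behind this one function so an alternative
# definition can be dropped in.

#' Theta similarity between two association patterns
#'
#' Pearson correlation between the allele-aligned z-score vectors of the two
#' traits over the same SNPs. Invariant under positive rescaling of either
#' vector; flips sign when one vector is negated.
#'
#' @param z_gwas,z_eqtl Equal-length numeric vectors (length at least 2) of
#'   z statistics over shared, allele-aligned SNPs.
#' @return Theta in \[-1, 1\], or `NA` when either vector is constant
#'   (undefined correlation).
#' @export
theta_metric <- function(z_gwas, z_eqtl) {
  if (length(z_gwas) != length(z_eqtl)) {
    abort("z-score vectors must have equal length.")
  }
  if (length(z_gwas) < 2) abort("theta needs at least 2 SNPs.")
  if (stats::sd(z_gwas) == 0 || stats::sd(z_eqtl) == 0) return(NA_real_)
  stats::cor(z_gwas, z_eqtl)
}

#' Colocalization call from the theta metric
#'
#' A probe is called colocalized iff `|theta|` strictly exceeds `theta_min`
#' and the number of SNPs strictly exceeds `n_min_exclusive`; with too few
#' SNPs (or undefined theta) the call is `"untested"`.
#'
#' @param theta Value from [theta_metric()] (may be `NA`).
#' @param n_snps Number of SNPs theta was computed over.
#' @param theta_min Threshold on `|theta|` (default 0.7, strict `>`).
#' @param n_min_exclusive SNP-count threshold (default 3, strict `>`).
#' @return `"colocalized"`, `"not_colocalized"` or `"untested"` (vectorized).
#' @export
theta_call <- function(theta, n_snps, theta_min = 0.7, n_min_exclusive = 3) {
  dplyr::case_when(
    n_snps <= n_min_exclusive | is.na(theta) ~ "untested",
    abs(theta) > theta_min ~ "colocalized",
    TRUE ~ "not_colocalized"
  )
}

#' Run the theta-metric scan over probe eQTL tables
#'
#' Uses the same harmonization and MAF filtering as the SMR/HEIDI scan (the
#' full analysis set, without excluding the instrument) so the two checks
#' are comparable.
#'
#' @inheritParams run_smr
#' @param theta_min,n_min_exclusive Decision thresholds (see [theta_call()]).
#' @return An object of class `theta_scan` with a `results` tibble (probe,
#'   gene, tissue, theta, n_snps, call).
#' @export
run_theta <- function(gwas, eqtls, maf_min = 0.03,
                      theta_min = 0.7, n_min_exclusive = 3) {
  if (is.data.frame(eqtls)) eqtls <- list(eqtls)
  rows <- lapply(eqtls, function(eq) {
    pid <- eq$probe_id[1] %||% NA_character_
    gene <- eq$gene[1] %||% NA_character_
    tissue <- eq$tissue[1] %||% NA_character_
    h <- tryCatch(harmonize_sumstats(gwas, eq), error = function(e) NULL)
    if (is.null(h)) {
      return(tibble::tibble(
        probe_id = pid, gene = gene, tissue = tissue,
        theta = NA_real_, n_snps = 0L, call = "untested"
      ))
    }
    a <- filter_snps(h, maf_min = maf_min)$analysis
    th <- if (nrow(a) >= 2) theta_metric(a$z_gwas, a$z_eqtl) else NA_real_
    tibble::tibble(
      probe_id = pid, gene = gene, tissue = tissue,
      theta = th, n_snps = nrow(a),
      call = theta_call(th, nrow(a), theta_min, n_min_exclusive)
    )
  })
  structure(
    list(
      results = dplyr::bind_rows(rows),
      settings = list(
        maf_min = maf_min, theta_min = theta_min,
        n_min_exclusive = n_min_exclusive
      )
    ),
    class = "theta_scan"
  )
}

#' @export
print.theta_scan <- function(x, ...) {
  cat("<theta_scan> ", nrow(x$results), " probe-tissue result(s)\n", sep = "")
  print(x$results, ...)
  invisible(x)
}
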
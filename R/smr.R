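# The SMR test, Wald-ratio estimate, FDR adjustment and the pass/fail
# colocalization call.

#' SMR colocalization test statistic
#'
#' For an instrument SNP with z statistics `z_gwas` (trait) and `z_eqtl`
#' (expression), the SMR statistic is
#' \deqn{T = \frac{z_{gwas}^2 \, z_{eqtl}^2}{z_{gwas}^2 + z_{eqtl}^2}}
#' compared against a 1-df chi-square. T is symmetric in its arguments,
#' never exceeds the smaller of the two squared z values, and attains it in
#' the limit as the other statistic grows.
#'
#' @param z_gwas,z_eqtl z statistics at the instrument SNP (vectorized).
#' @return A tibble with columns `t_smr` and `p_smr`.
#' @export
smr_statistic <- function(z_gwas, z_eqtl) {
  if (any(z_gwas == 0 & z_eqtl == 0)) {
    abort("SMR statistic undefined when both z statistics are zero.")
  }
  t <- (z_gwas^2 * z_eqtl^2) / (z_gwas^2 + z_eqtl^2)
  tibble::tibble(t_smr = t, p_smr = pmax(pchisq(t, df = 1, lower.tail = FALSE), 1e-300))
}

#' Wald-ratio estimate of the expression-to-trait effect
#'
#' The causal effect of expression on the trait at the instrument SNP is
#' estimated as `b_xy = b_gwas / b_eqtl`, with the first-order delta-method
#' standard error `se_xy = |b_xy| * sqrt(1/z_gwas^2 + 1/z_eqtl^2)`. Its sign
#' says whether increased expression associates with increased or decreased
#' trait risk.
#'
#' @param b_gwas,se_gwas,b_eqtl,se_eqtl Effect sizes and standard errors at
#'   the instrument SNP (vectorized).
#' @return A tibble with columns `b_xy` and `se_xy`.
#' @export
wald_ratio <- function(b_gwas, se_gwas, b_eqtl, se_eqtl) {
  if (any(b_eqtl == 0)) abort("Wald ratio undefined when b_eqtl is zero.")
  b_xy <- b_gwas / b_eqtl
  z_g <- b_gwas / se_gwas
  z_e <- b_eqtl / se_eqtl
  se_xy <- abs(b_xy) * sqrt(1 / z_g^2 + 1 / z_e^2)
  tibble::tibble(b_xy = b_xy, se_xy = se_xy)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up false-discovery-rate adjustment over one family of tests; thin
#' wrapper over the standard implementation so the family boundary is an
#' explicit module decision (one family per analysis run by default).
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues) | pvalues <= 0 | pvalues > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Pass/fail colocalization call for one probe-tissue result
#'
#' Expression of a gene is called consistent with a shared causal variant
#' (`"pass"`) iff the SMR FDR is below `fdr_max` AND the HEIDI test ran and
#' gave a p-value at or above `heidi_min`. When the SMR FDR passes but HEIDI
#' rejects, the call is `"fail_heidi"` (linkage of distinct causal variants,
#' not pleiotropy); when the SMR FDR passes but HEIDI could not run (too few
#' SNPs / no instrument), the call is `"untested_heidi"`; otherwise
#' `"fail_smr"`.
#'
#' @param q_fdr SMR BH-adjusted value.
#' @param p_heidi HEIDI p-value, `NA` when not tested.
#' @param heidi_status `"tested"`, `"skipped_too_few_snps"` or
#'   `"skipped_no_instrument"`.
#' @param fdr_max SMR FDR threshold (default 0.05, strict `<`).
#' @param heidi_min HEIDI p threshold (default 0.001, inclusive `>=` to pass).
#' @return Character vector of calls (vectorized over inputs).
#' @export
classify_coloc <- function(q_fdr, p_heidi, heidi_status,
                           fdr_max = 0.05, heidi_min = 0.001) {
  n <- max(length(q_fdr), length(p_heidi), length(heidi_status))
  q_fdr <- rep_len(q_fdr, n)
  p_heidi <- rep_len(p_heidi, n)
  heidi_status <- rep_len(heidi_status, n)
  dplyr::case_when(
    q_fdr >= fdr_max ~ "fail_smr",
    heidi_status != "tested" ~ "untested_heidi",
    p_heidi >= heidi_min ~ "pass",
    TRUE ~ "fail_heidi"
  )
}

#' Run the SMR/HEIDI scan over a set of probe-tissue eQTL tables
#'
#' For each probe: harmonizes the eQTL table with the GWAS, applies the SNP
#' eligibility filters, selects the instrument, computes the SMR statistic
#' and Wald ratio at the instrument, and runs the HEIDI heterogeneity test
#' against the LD reference. One BH family is then formed over all tested
#' probe-tissue pairs and every result receives a colocalization call.
#'
#' @param gwas Validated GWAS tibble from [read_sumstats()].
#' @param eqtls A list of validated probe eQTL tibbles (each tagged with
#'   `probe_id`/`gene`/`tissue`), or a single tibble.
#' @param ld A `genotype_panel` or `ld_view` covering the analysis SNPs
#'   (optional; without it HEIDI is skipped as `skipped_no_ld`).
#' @param maf_min,z2_min SNP filters (see [filter_snps()]).
#' @param fdr_max,heidi_min Decision thresholds (see [classify_coloc()]).
#' @param heidi_min_snps,heidi_max_snps,heidi_r2_window HEIDI settings (see
#'   [heidi_test()]).
#' @param instrument_by `"gwas"` (default; instrument = lowest trait
#'   p-value) or `"eqtl"` (lowest eQTL p-value, the alternative ranking used
#'   by the original SMR software).
#' @return An object of class `smr_scan`: a list with `results` (one tibble
#'   row per probe-tissue), `skipped` (probes without an instrument) and
#'   `settings`. Use [tidy()] / [glance()] / [autoplot()] on it.
#' @export
run_smr <- function(gwas, eqtls, ld = NULL,
                    maf_min = 0.03, z2_min = 10,
                    fdr_max = 0.05, heidi_min = 0.001,
                    heidi_min_snps = 3, heidi_max_snps = 20,
                    heidi_r2_window = c(0.05, 0.9),
                    instrument_by = c("gwas", "eqtl")) {
  instrument_by <- match.arg(instrument_by)
  if (is.data.frame(eqtls)) eqtls <- list(eqtls)
  rows <- list()
  skipped <- list()
  for (eq in eqtls) {
    pid <- eq$probe_id[1] %||% NA_character_
    gene <- eq$gene[1] %||% NA_character_
    tissue <- eq$tissue[1] %||% NA_character_
    h <- tryCatch(harmonize_sumstats(gwas, eq), error = function(e) NULL)
    if (is.null(h)) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        probe_id = pid, gene = gene, tissue = tissue, reason = "no overlap"
      )
      next
    }
    f <- filter_snps(h, maf_min = maf_min, z2_min = z2_min)
    cand <- if (instrument_by == "gwas") {
      f$instruments
    } else {
      inst <- f$instruments
      if (nrow(inst)) inst[order(inst$p_eqtl, inst$pos, inst$rsid), ] else inst
    }
    top <- if (instrument_by == "gwas") {
      select_top_snp(f$instruments)
    } else if (nrow(cand)) {
      cand$rsid[1]
    } else {
      structure(NA_character_, reason = "no instrument")
    }
    if (is.na(top)) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        probe_id = pid, gene = gene, tissue = tissue, reason = "no instrument"
      )
      next
    }
    rec <- f$analysis[f$analysis$rsid == top, ]
    smr <- smr_statistic(rec$z_gwas, rec$z_eqtl)
    wr <- wald_ratio(rec$b_gwas, rec$se_gwas, rec$b_eqtl, rec$se_eqtl)
    heidi <- if (is.null(ld)) {
      tibble::tibble(
        snps_used = 0L, s_heidi = NA_real_, p_heidi = NA_real_,
        status = "skipped_no_ld", tail_method = NA_character_
      )
    } else {
      heidi_test(
        f$analysis, ld, top,
        min_snps = heidi_min_snps, max_snps = heidi_max_snps,
        r2_window = heidi_r2_window
      )
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      probe_id = pid, gene = gene, tissue = tissue, top_snp = top,
      b_xy = wr$b_xy, se_xy = wr$se_xy,
      t_smr = smr$t_smr, p_smr = smr$p_smr,
      n_heidi_snps = heidi$snps_used, p_heidi = heidi$p_heidi,
      heidi_status = heidi$status
    )
  }
  results <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(
      probe_id = character(), gene = character(), tissue = character(),
      top_snp = character(), b_xy = numeric(), se_xy = numeric(),
      t_smr = numeric(), p_smr = numeric(), n_heidi_snps = integer(),
      p_heidi = numeric(), heidi_status = character()
    )
  if (nrow(results)) {
    results$q_fdr <- bh_fdr(results$p_smr)
    results$call <- classify_coloc(
      results$q_fdr, results$p_heidi, results$heidi_status,
      fdr_max = fdr_max, heidi_min = heidi_min
    )
    results <- dplyr::relocate(results, "q_fdr", .after = "p_smr")
  }
  structure(
    list(
      results = results,
      skipped = if (length(skipped)) dplyr::bind_rows(skipped) else NULL,
      settings = list(
        maf_min = maf_min, z2_min = z2_min, fdr_max = fdr_max,
        heidi_min = heidi_min, heidi_min_snps = heidi_min_snps,
        heidi_max_snps = heidi_max_snps, heidi_r2_window = heidi_r2_window,
        instrument_by = instrument_by
      )
    ),
    class = "smr_scan"
  )
}

#' @export
print.smr_scan <- function(x, ...) {
  cat("<smr_scan> ", nrow(x$results), " probe-tissue result(s)",
    if (!is.null(x$skipped)) paste0(", ", nrow(x$skipped), " skipped"),
    "\n",
    sep = ""
  )
  if (nrow(x$results)) print(x$results, ...)
  invisible(x)
}
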
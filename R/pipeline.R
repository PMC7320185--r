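# End-to-end orchestration: locus selection -> harmonization -> SMR/HEIDI ->
# theta -> evidence report, with per-stage outputs and a reproducibility
# manifest. Every stage is also exported on its own; run_pipeline() is the
# one-call composition.

#' Thresholds and inputs for a pipeline run
#'
#' Collects every decision threshold of the colocalization protocol with
#' its standard default: genome-wide significance 5e-8, ancestry
#' confirmation 5e-7, locus half-width 250 kb, MAF filter 0.03, squared-z
#' instrument filter 10, SMR FDR 0.05, HEIDI p 0.001 with 3-20 SNPs, theta
#' 0.7 with more than 3 SNPs, LD grouping r-squared 0.8.
#'
#' @param gwas Validated GWAS tibble (discovery + analysis dataset).
#' @param eqtls List of probe eQTL tibbles (see [read_sumstats()]).
#' @param panel Optional `genotype_panel` or `ld_view` for HEIDI/LD steps.
#' @param confirm_gwas Optional confirmation GWAS; when supplied, loci are
#'   confirmed and re-anchored before analysis.
#' @param evidence Optional `locus_evidence` object to fold into the report.
#' @param p_gw,p_confirm,flank_bp,maf_min,z2_min,fdr_max,heidi_min
#'   Thresholds as above.
#' @param heidi_snps Length-2 integer vector, min and max HEIDI SNPs.
#' @param theta_min,theta_n Theta decision thresholds.
#' @param r2_group LD-grouping threshold on r-squared.
#' @param instrument_by Instrument ranking, `"gwas"` or `"eqtl"`.
#' @param seed Seed recorded in the manifest.
#' @param out_dir Optional directory for per-stage TSV/JSON outputs.
#' @return A `run_config` list, validated.
#' @export
run_config <- function(gwas, eqtls, panel = NULL, confirm_gwas = NULL,
                       evidence = NULL,
                       p_gw = 5e-8, p_confirm = 5e-7, flank_bp = 250000,
                       maf_min = 0.03, z2_min = 10,
                       fdr_max = 0.05, heidi_min = 0.001,
                       heidi_snps = c(3L, 20L),
                       theta_min = 0.7, theta_n = 3,
                       r2_group = 0.8, instrument_by = "gwas",
                       seed = 1L, out_dir = NULL) {
  stopifnot(
    p_gw > 0, p_confirm > 0, flank_bp >= 1, maf_min > 0, z2_min > 0,
    fdr_max > 0, heidi_min > 0, length(heidi_snps) == 2,
    heidi_snps[1] <= heidi_snps[2], theta_min > 0, r2_group > 0
  )
  structure(
    list(
      gwas = gwas, eqtls = eqtls, panel = panel, confirm_gwas = confirm_gwas,
      evidence = evidence, p_gw = p_gw, p_confirm = p_confirm,
      flank_bp = flank_bp, maf_min = maf_min, z2_min = z2_min,
      fdr_max = fdr_max, heidi_min = heidi_min, heidi_snps = heidi_snps,
      theta_min = theta_min, theta_n = theta_n, r2_group = r2_group,
      instrument_by = instrument_by, seed = as.integer(seed),
      out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Run the full gene-prioritization pipeline
#'
#' Stages: (1) locus discovery by greedy clumping, with optional
#' confirmation/re-anchoring in a second dataset; (2) per-probe SMR/HEIDI
#' colocalization scan; (3) theta-metric scan; (4) evidence summary when a
#' curated evidence table is supplied. Soft per-probe skips (no instrument,
#' too few HEIDI SNPs) are tallied, not fatal. The manifest records every
#' threshold, the seed and record counts at each stage so a run is
#' reproducible from its report alone.
#'
#' @param config A [run_config()].
#' @return A `prio_report` object: list with `loci`, `smr` (`smr_scan`),
#'   `theta` (`theta_scan`), `evidence_summary` (or `NULL`) and `manifest`.
#'   When `config$out_dir` is set, per-stage files are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)

  loci <- find_loci(config$gwas, p_threshold = config$p_gw, flank = config$flank_bp)
  if (!is.null(config$confirm_gwas)) {
    loci <- confirm_loci(loci, config$confirm_gwas, p_threshold = config$p_confirm)
  }

  smr <- run_smr(
    config$gwas, config$eqtls, ld = config$panel,
    maf_min = config$maf_min, z2_min = config$z2_min,
    fdr_max = config$fdr_max, heidi_min = config$heidi_min,
    heidi_min_snps = config$heidi_snps[1], heidi_max_snps = config$heidi_snps[2],
    instrument_by = config$instrument_by
  )
  theta <- run_theta(
    config$gwas, config$eqtls, maf_min = config$maf_min,
    theta_min = config$theta_min, n_min_exclusive = config$theta_n
  )
  ev_summary <- if (!is.null(config$evidence)) {
    summarize_conclusions(config$evidence)
  }

  n_probes <- length(config$eqtls)
  n_skipped <- if (is.null(smr$skipped)) 0L else nrow(smr$skipped)
  manifest <- list(
    seed = config$seed,
    thresholds = config[c(
      "p_gw", "p_confirm", "flank_bp", "maf_min", "z2_min", "fdr_max",
      "heidi_min", "heidi_snps", "theta_min", "theta_n", "r2_group",
      "instrument_by"
    )],
    counts = list(
      gwas_snps = nrow(config$gwas),
      loci = nrow(loci),
      probes_in = n_probes,
      probes_tested = nrow(smr$results),
      probes_skipped = n_skipped,
      calls = as.list(table(smr$results$call))
    )
  )
  stopifnot(manifest$counts$probes_tested + manifest$counts$probes_skipped ==
    manifest$counts$probes_in)

  report <- structure(
    list(
      loci = loci, smr = smr, theta = theta,
      evidence_summary = ev_summary, manifest = manifest
    ),
    class = "prio_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.prio_report <- function(x, ...) {
  cat("<prio_report>\n")
  cat("  loci: ", nrow(x$loci), "\n", sep = "")
  cat("  probe-tissue results: ", nrow(x$smr$results), "\n", sep = "")
  if (nrow(x$smr$results)) {
    calls <- table(x$smr$results$call)
    cat("  calls: ", paste(names(calls), calls, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits stable-column-order TSVs for the locus, SMR/HEIDI and theta
#' tables, a BED file for the loci, a JSON report (manifest + per-probe
#' results) and a markdown per-locus summary.
#'
#' @param report A `prio_report`.
#' @param out_dir Output directory (created if needed).
#' @param formats Any of `"tsv"`, `"json"`, `"markdown"`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir, formats = c("tsv", "json", "markdown")) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) abort(paste0("Cannot create ", out_dir))
  }
  paths <- character(0)
  num <- function(x) ifelse(is.na(x), NA, formatC(x, digits = 6, format = "g"))
  if ("tsv" %in% formats) {
    p1 <- file.path(out_dir, "loci.tsv")
    readr::write_tsv(report$loci, p1)
    p2 <- file.path(out_dir, "smr_heidi.tsv")
    smr_out <- dplyr::mutate(
      report$smr$results,
      dplyr::across(dplyr::where(is.numeric), num)
    )
    readr::write_tsv(smr_out, p2)
    p3 <- file.path(out_dir, "theta.tsv")
    readr::write_tsv(
      dplyr::mutate(report$theta$results, dplyr::across(dplyr::where(is.numeric), num)),
      p3
    )
    p4 <- file.path(out_dir, "loci.bed")
    loci_to_bed(report$loci, p4)
    paths <- c(paths, p1, p2, p3, p4)
  }
  if ("json" %in% formats) {
    pj <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(
        manifest = report$manifest,
        results = report$smr$results,
        theta = report$theta$results,
        evidence_summary = report$evidence_summary
      ),
      pj,
      auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null"
    )
    paths <- c(paths, pj)
  }
  if ("markdown" %in% formats) {
    pm <- file.path(out_dir, "report.md")
    lines <- c("# Gene prioritization report", "")
    res <- report$smr$results
    if (nrow(res) == 0) {
      lines <- c(lines, "_No probe-tissue results._")
    } else {
      for (i in seq_len(nrow(res))) {
        r <- res[i, ]
        th <- report$theta$results[
          report$theta$results$probe_id == r$probe_id &
            report$theta$results$tissue == r$tissue,
        ]
        lines <- c(
          lines,
          paste0("## ", r$gene, " (", r$probe_id, ", ", r$tissue, ")"),
          paste0(
            "- top SNP ", r$top_snp,
            "; b_xy = ", signif(r$b_xy, 3),
            "; p_SMR = ", format(r$p_smr, digits = 3, scientific = TRUE),
            "; FDR = ", format(r$q_fdr, digits = 3, scientific = TRUE),
            "; p_HEIDI = ", ifelse(is.na(r$p_heidi), "not tested",
              format(r$p_heidi, digits = 3, scientific = TRUE)
            ),
            " (", r$n_heidi_snps, " SNPs)"
          ),
          paste0(
            "- call: **", r$call, "**",
            if (nrow(th)) paste0("; theta = ", signif(th$theta[1], 3),
                                 " (", th$call[1], ")")
          ),
          ""
        )
      }
    }
    writeLines(lines, pm)
    paths <- c(paths, pm)
  }
  invisible(paths)
}
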
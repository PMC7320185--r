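# broom-style accessors so scan objects drop straight into dplyr chains.

#' @rdname smr_scan_tidiers
#' @title Tidy and summarize SMR/HEIDI scan objects
#' @description `tidy()` returns the per-probe-tissue result tibble;
#'   `glance()` returns a one-row run summary.
#' @param x An `smr_scan` from [run_smr()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy smr_scan
#' @export
tidy.smr_scan <- function(x, ...) {
  x$results
}

#' @rdname smr_scan_tidiers
#' @method glance smr_scan
#' @export
glance.smr_scan <- function(x, ...) {
  res <- x$results
  tibble::tibble(
    n_results = nrow(res),
    n_pass = sum(res$call == "pass"),
    n_fail_smr = sum(res$call == "fail_smr"),
    n_fail_heidi = sum(res$call == "fail_heidi"),
    n_untested_heidi = sum(res$call == "untested_heidi"),
    n_skipped = if (is.null(x$skipped)) 0L else nrow(x$skipped),
    fdr_max = x$settings$fdr_max,
    heidi_min = x$settings$heidi_min
  )
}

#' @rdname theta_scan_tidiers
#' @title Tidy and summarize theta scan objects
#' @description `tidy()` returns the per-probe-tissue theta tibble;
#'   `glance()` a one-row summary.
#' @param x A `theta_scan` from [run_theta()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy theta_scan
#' @export
tidy.theta_scan <- function(x, ...) {
  x$results
}

#' @rdname theta_scan_tidiers
#' @method glance theta_scan
#' @export
glance.theta_scan <- function(x, ...) {
  res <- x$results
  tibble::tibble(
    n_results = nrow(res),
    n_colocalized = sum(res$call == "colocalized"),
    n_not_colocalized = sum(res$call == "not_colocalized"),
    n_untested = sum(res$call == "untested"),
    theta_min = x$settings$theta_min
  )
}

#' @rdname report_tidiers
#' @title Tidy and summarize pipeline reports
#' @description `tidy()` joins the SMR/HEIDI and theta results into one
#'   tibble per probe-tissue; `glance()` returns the manifest counts as one
#'   row.
#' @param x A `prio_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy prio_report
#' @export
tidy.prio_report <- function(x, ...) {
  dplyr::left_join(
    x$smr$results,
    dplyr::select(x$theta$results, "probe_id", "tissue",
      "theta", theta_n_snps = "n_snps", theta_call = "call"
    ),
    by = c("probe_id", "tissue")
  )
}

#' @rdname report_tidiers
#' @method glance prio_report
#' @export
glance.prio_report <- function(x, ...) {
  cnt <- x$manifest$counts
  tibble::tibble(
    gwas_snps = cnt$gwas_snps, loci = cnt$loci,
    probes_in = cnt$probes_in, probes_tested = cnt$probes_tested,
    probes_skipped = cnt$probes_skipped, seed = x$manifest$seed
  )
}

#' @rdname evidence_tidiers
#' @title Tidy and summarize locus-evidence tables
#' @description `tidy()` returns the per-gene evidence tibble (joined with
#'   the locus conclusions); `glance()` returns the headline accounting in
#'   one row.
#' @param x A `locus_evidence` from [load_locus_evidence()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy locus_evidence
#' @export
tidy.locus_evidence <- function(x, ...) {
  dplyr::left_join(
    x$genes,
    dplyr::select(x$loci, "locus_id", "lead_rsid", "conclusion"),
    by = "locus_id"
  )
}

#' @rdname evidence_tidiers
#' @method glance locus_evidence
#' @export
glance.locus_evidence <- function(x, ...) {
  s <- summarize_conclusions(x)
  wk <- well_known_genes(x)
  tibble::tibble(
    n_loci = s$n_loci,
    n_causal_loci = s$n_causal_loci,
    n_no_inference_loci = s$n_no_inference_loci,
    n_verdict_genes = s$n_verdict_genes,
    n_well_known_genes = nrow(wk),
    n_well_known_smr_support = sum(wk$smr_support)
  )
}
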
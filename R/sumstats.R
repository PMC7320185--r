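# Reading, validating and harmonizing GWAS / cis-eQTL summary statistics.
#
# The canonical per-variant record carries: rsid, chrom, pos (1-based),
# allele_effect, allele_other, beta (per effect allele), se, z, pvalue,
# maf (minor-allele frequency, in [0, 0.5]) and optionally n.

.sumstats_core_cols <- c("rsid", "chrom", "pos", "allele_effect", "allele_other")
.sumstats_num_cols <- c("beta", "se", "z", "pvalue", "maf", "n")

#' Column-mapping dialect for summary-statistics tables
#'
#' Summary-statistics files differ in column naming; a dialect maps the
#' canonical field names used throughout this package to the names (or
#' 1-based positions) of columns in a particular file. Fields omitted from
#' the dialect are assumed to use the canonical name itself; optional fields
#' absent from the file are tolerated.
#'
#' @param ... Named entries, e.g. `rsid = "SNP"`, `pvalue = "p"`, or 1-based
#'   column positions, e.g. `beta = 6`.
#' @return A named list usable as the `dialect` argument of
#'   [read_sumstats()].
#' @examples
#' sumstats_dialect(rsid = "SNP", pvalue = "p", maf = "eaf")
#' @export
sumstats_dialect <- function(...) {
  d <- list(...)
  if (length(d) && (is.null(names(d)) || any(!nzchar(names(d))))) {
    abort("All dialect entries must be named with canonical field names.")
  }
  unknown <- setdiff(names(d), c(.sumstats_core_cols, .sumstats_num_cols))
  if (length(unknown)) {
    abort(paste0("Unknown dialect field(s): ", paste(unknown, collapse = ", ")))
  }
  d
}

# Resolve one dialect entry to the column name actually present in the file,
# or NA if absent.
.resolve_col <- function(field, dialect, file_cols) {
  m <- dialect[[field]] %||% field
  if (is.numeric(m)) {
    if (m < 1 || m > length(file_cols)) return(NA_character_)
    return(file_cols[[as.integer(m)]])
  }
  if (m %in% file_cols) m else NA_character_
}

#' Read and validate a summary-statistics table
#'
#' Reads a tab-separated association table (GWAS or cis-eQTL), maps columns
#' through a [sumstats_dialect()], validates each row against the record
#' invariants (`se > 0`, `0 <= maf <= 0.5`, `pvalue` in (0, 1], `z`
#' consistent with `beta/se`), fills `z = beta/se` and the two-sided normal
#' `pvalue` from `z` when either is missing, and drops invalid rows with a
#' count retrievable via [drop_log()].
#'
#' @param path Path to a tab-separated file with a header row, or a data
#'   frame already in memory (then taken as-is before mapping).
#' @param dialect A [sumstats_dialect()] mapping canonical fields to file
#'   columns.
#' @param probe Optional named list with `probe_id`, `gene`, `tissue` to tag
#'   every record of a cis-eQTL table for one expression probe.
#' @return A tibble of validated variant associations, one row per SNP, with
#'   a `drop_log` attribute counting discarded rows by reason.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(), probe = NULL) {
  raw <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    if (!file.exists(path)) abort(paste0("File not found: ", path))
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(raw) == 0) abort("Empty summary-statistics table (no data rows).")

  cols <- names(raw)
  mapped <- lapply(
    setNames(nm = c(.sumstats_core_cols, .sumstats_num_cols)),
    .resolve_col, dialect = dialect, file_cols = cols
  )
  missing_core <- .sumstats_core_cols[is.na(unlist(mapped[.sumstats_core_cols]))]
  if (length(missing_core)) {
    abort(paste0(
      "Mandatory column(s) missing from table: ",
      paste(missing_core, collapse = ", ")
    ))
  }
  has_effect <- !is.na(mapped$z) || (!is.na(mapped$beta) && !is.na(mapped$se))
  if (!has_effect) {
    abort("Table must carry either a z column or both beta and se columns.")
  }

  out <- tibble::tibble(
    rsid = as.character(raw[[mapped$rsid]]),
    chrom = chrom_chr(raw[[mapped$chrom]]),
    pos = as.numeric(raw[[mapped$pos]]),
    allele_effect = toupper(as.character(raw[[mapped$allele_effect]])),
    allele_other = toupper(as.character(raw[[mapped$allele_other]]))
  )
  for (f in .sumstats_num_cols) {
    out[[f]] <- if (is.na(mapped[[f]])) NA_real_ else as.numeric(raw[[mapped[[f]]]])
  }

  # Fill derived fields before validation so partially-specified rows survive.
  fill_z <- is.na(out$z) & !is.na(out$beta) & !is.na(out$se) & out$se > 0
  out$z[fill_z] <- out$beta[fill_z] / out$se[fill_z]
  fill_p <- is.na(out$pvalue) & !is.na(out$z)
  out$pvalue[fill_p] <- p_from_z(out$z[fill_p])

  bad_core <- is.na(out$rsid) | is.na(out$chrom) | is.na(out$pos) |
    is.na(out$allele_effect) | is.na(out$allele_other)
  bad_se <- !is.na(out$se) & out$se <= 0
  bad_maf <- !is.na(out$maf) & (out$maf < 0 | out$maf > 0.5)
  bad_p <- !is.na(out$pvalue) & (out$pvalue <= 0 | out$pvalue > 1)
  bad_z <- !is.na(out$z) & !is.na(out$beta) & !is.na(out$se) & out$se > 0 &
    abs(out$z - out$beta / out$se) >= 1e-6

  keep <- !(bad_core | bad_se | bad_maf | bad_p | bad_z)
  log <- c(
    bad_core = sum(bad_core),
    bad_se = sum(bad_se & !bad_core),
    bad_maf = sum(bad_maf & !bad_core & !bad_se),
    bad_pvalue = sum(bad_p & !bad_core & !bad_se & !bad_maf),
    z_inconsistent = sum(bad_z & !bad_core & !bad_se & !bad_maf & !bad_p)
  )
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0) abort("All rows failed validation; empty table.")

  if (!is.null(probe)) {
    out <- dplyr::mutate(
      out,
      probe_id = probe$probe_id %||% NA_character_,
      gene = probe$gene %||% NA_character_,
      tissue = probe$tissue %||% NA_character_,
      .before = 1
    )
    if (anyDuplicated(out$rsid)) {
      abort(paste0("Duplicated rsids within probe ", probe$probe_id))
    }
  }
  set_drop_log(out, log)
}

#' Harmonize a GWAS table with a cis-eQTL table on shared SNPs
#'
#' Intersects the two tables on rsid and aligns the eQTL effect sizes to the
#' GWAS effect allele. When the effect/other alleles are swapped between the
#' datasets, the eQTL `beta` and `z` are negated and the allele labels
#' swapped (flipping twice is the identity). SNPs whose allele pairs are
#' incompatible between the datasets are dropped and counted in the
#' [drop_log()].
#'
#' @param gwas,eqtl Validated tibbles from [read_sumstats()]; `eqtl` may
#'   carry `probe_id`/`gene`/`tissue` columns which are propagated.
#' @return A tibble of harmonized records with columns `rsid`, `chrom`,
#'   `pos`, `allele_effect`, `allele_other`, `b_gwas`, `se_gwas`, `z_gwas`,
#'   `p_gwas`, `maf_gwas`, `b_eqtl`, `se_eqtl`, `z_eqtl`, `p_eqtl`,
#'   `maf_eqtl` (plus probe annotation when present), all relative to
#'   `allele_effect`.
#' @export
harmonize_sumstats <- function(gwas, eqtl) {
  probe_cols <- intersect(c("probe_id", "gene", "tissue"), names(eqtl))
  e <- dplyr::select(
    eqtl, dplyr::all_of(probe_cols), "rsid",
    e_allele_effect = "allele_effect", e_allele_other = "allele_other",
    b_eqtl = "beta", se_eqtl = "se", z_eqtl = "z", p_eqtl = "pvalue",
    maf_eqtl = "maf"
  )
  g <- dplyr::select(
    gwas, "rsid", "chrom", "pos", "allele_effect", "allele_other",
    b_gwas = "beta", se_gwas = "se", z_gwas = "z", p_gwas = "pvalue",
    maf_gwas = "maf"
  )
  j <- dplyr::inner_join(g, e, by = "rsid")
  if (nrow(j) == 0) abort("No overlapping SNPs between GWAS and eQTL tables.")

  same <- j$allele_effect == j$e_allele_effect & j$allele_other == j$e_allele_other
  swapped <- j$allele_effect == j$e_allele_other & j$allele_other == j$e_allele_effect
  incompatible <- !(same | swapped)

  j$b_eqtl[swapped] <- -j$b_eqtl[swapped]
  j$z_eqtl[swapped] <- -j$z_eqtl[swapped]

  out <- j[!incompatible, , drop = FALSE]
  if (nrow(out) == 0) abort("No allele-compatible SNPs between GWAS and eQTL tables.")
  out <- dplyr::select(out, -"e_allele_effect", -"e_allele_other")
  out <- dplyr::relocate(out, dplyr::all_of(probe_cols), .after = "maf_eqtl")
  set_drop_log(out, c(incompatible_alleles = sum(incompatible)))
}

#' Apply the SNP eligibility filters of the colocalization protocol
#'
#' Keeps, for the analysis set, harmonized SNPs with minor-allele frequency
#' at or above `maf_min` in both datasets (inclusive); the instrument
#' candidates are the subset with a squared GWAS z statistic at or above
#' `z2_min` (inclusive). Empty outputs are legal and signalled downstream.
#'
#' @param harmonized Output of [harmonize_sumstats()].
#' @param maf_min Minimum MAF required in both datasets (default 0.03).
#' @param z2_min Minimum squared GWAS z for an instrument candidate
#'   (default 10).
#' @return A list with tibbles `analysis` and `instruments`
#'   (`instruments` is always a subset of `analysis`).
#' @export
filter_snps <- function(harmonized, maf_min = 0.03, z2_min = 10) {
  pass_maf <- !is.na(harmonized$maf_gwas) & !is.na(harmonized$maf_eqtl) &
    harmonized$maf_gwas >= maf_min & harmonized$maf_eqtl >= maf_min
  analysis <- harmonized[pass_maf, , drop = FALSE]
  inst <- analysis[!is.na(analysis$z_gwas) & analysis$z_gwas^2 >= z2_min, ,
    drop = FALSE
  ]
  list(analysis = analysis, instruments = inst)
}

#' Select the instrumental ("top") SNP among filtered candidates
#'
#' The instrument is the candidate with the smallest GWAS p-value; ties are
#' broken by ascending position, then lexicographic rsid, so the choice is
#' deterministic.
#'
#' @param instruments Instrument-candidate tibble from [filter_snps()].
#' @return The rsid of the top SNP (length-1 character), or `NA` with a
#'   `"reason"` attribute of `"no instrument"` when no candidate exists.
#' @export
select_top_snp <- function(instruments) {
  if (is.null(instruments) || nrow(instruments) == 0) {
    return(structure(NA_character_, reason = "no instrument"))
  }
  ord <- order(instruments$p_gwas, instruments$pos, instruments$rsid)
  instruments$rsid[ord[1]]
}
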
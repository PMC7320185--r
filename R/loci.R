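# Locus discovery, ancestry-specific confirmation and cross-dataset matching.
#
# A locus is a +/- `flank` bp window around a lead SNP. Windows are 1-based
# and inclusive on both ends.

new_locus_tbl <- function(df) {
  tibble::as_tibble(df)
}

#' Discover trait-associated loci by greedy p-value clumping
#'
#' Repeatedly takes the most significant remaining SNP below `p_threshold`
#' as a lead and absorbs every SNP within `flank` bp of it on the same
#' chromosome, until no significant SNP remains. This is the standard
#' distance-based reconstruction of published locus lists when no explicit
#' clumping procedure is reported.
#'
#' @param gwas A validated GWAS tibble (needs `rsid`, `chrom`, `pos`,
#'   `pvalue`).
#' @param p_threshold Genome-wide significance threshold (default 5.0e-8,
#'   strict `<`).
#' @param flank Half-width of the locus window in bp (default 250,000).
#' @param source Label recorded in the `source_dataset` column.
#' @return A tibble of loci sorted by chromosome then position, with columns
#'   `lead_rsid`, `chrom`, `lead_pos`, `window_start`, `window_end`,
#'   `lead_pvalue`, `source_dataset`.
#' @export
find_loci <- function(gwas, p_threshold = 5.0e-8, flank = 250000, source = "gwas") {
  stopifnot(flank > 0)
  sig <- dplyr::filter(gwas, !is.na(.data$pvalue), .data$pvalue < p_threshold)
  leads <- list()
  while (nrow(sig) > 0) {
    i <- order(sig$pvalue, sig$pos, sig$rsid)[1]
    lead <- sig[i, ]
    leads[[length(leads) + 1]] <- lead
    sig <- dplyr::filter(
      sig,
      !(.data$chrom == lead$chrom & abs(.data$pos - lead$pos) <= flank)
    )
  }
  if (!length(leads)) {
    return(new_locus_tbl(tibble::tibble(
      lead_rsid = character(), chrom = character(), lead_pos = numeric(),
      window_start = numeric(), window_end = numeric(),
      lead_pvalue = numeric(), source_dataset = character()
    )))
  }
  out <- dplyr::bind_rows(leads)
  out <- tibble::tibble(
    lead_rsid = out$rsid, chrom = out$chrom, lead_pos = out$pos,
    window_start = pmax(out$pos - flank, 1), window_end = out$pos + flank,
    lead_pvalue = out$pvalue, source_dataset = source
  )
  dplyr::arrange(out, .data$chrom, .data$lead_pos)
}

#' Confirm loci in an ancestry-specific dataset and re-anchor their leads
#'
#' A locus is kept iff at least one SNP inside its window reaches
#' `p_threshold` (strict `<`) in the confirmation GWAS; a kept locus is
#' re-anchored on the most significant confirming SNP, which becomes the new
#' lead with a fresh window of the same half-width.
#'
#' @param loci Locus tibble from [find_loci()].
#' @param confirm_gwas Validated GWAS tibble for the confirmation dataset
#'   (e.g. a European-ancestry meta-analysis).
#' @param p_threshold Suggestive significance required in the confirmation
#'   dataset (default 5.0e-7).
#' @return The loci tibble restricted to confirmed loci, re-anchored, with
#'   added columns `confirmed_by` (new lead rsid) and `drop_reason` removed;
#'   dropped loci are returned in the `"dropped"` attribute with reasons.
#' @export
confirm_loci <- function(loci, confirm_gwas, p_threshold = 5.0e-7) {
  if (nrow(loci) == 0) return(loci)
  flank <- (loci$window_end - loci$window_start)[1] / 2
  kept <- list()
  dropped <- list()
  for (i in seq_len(nrow(loci))) {
    loc <- loci[i, ]
    inside <- dplyr::filter(
      confirm_gwas,
      .data$chrom == loc$chrom,
      .data$pos >= loc$window_start, .data$pos <= loc$window_end,
      !is.na(.data$pvalue)
    )
    if (nrow(inside) == 0) {
      dropped[[length(dropped) + 1]] <-
        dplyr::mutate(loc, drop_reason = "no coverage in confirmation dataset")
      next
    }
    j <- order(inside$pvalue, inside$pos, inside$rsid)[1]
    best <- inside[j, ]
    if (best$pvalue < p_threshold) {
      kept[[length(kept) + 1]] <- tibble::tibble(
        lead_rsid = best$rsid, chrom = best$chrom, lead_pos = best$pos,
        window_start = pmax(best$pos - flank, 1),
        window_end = best$pos + flank,
        lead_pvalue = best$pvalue,
        source_dataset = loc$source_dataset,
        discovery_lead = loc$lead_rsid
      )
    } else {
      dropped[[length(dropped) + 1]] <-
        dplyr::mutate(loc, drop_reason = "below confirmation threshold")
    }
  }
  out <- if (length(kept)) dplyr::bind_rows(kept) else
    tibble::tibble(
      lead_rsid = character(), chrom = character(), lead_pos = numeric(),
      window_start = numeric(), window_end = numeric(), lead_pvalue = numeric(),
      source_dataset = character(), discovery_lead = character()
    )
  attr(out, "dropped") <- if (length(dropped)) dplyr::bind_rows(dropped) else NULL
  out
}

#' Distance between two locus leads
#'
#' Absolute base-pair distance between the lead SNPs when both loci are on
#' the same chromosome, and `Inf` otherwise.
#'
#' @param a,b Single-row locus tibbles (or lists with `chrom`, `lead_pos`).
#' @return Distance in bp, or `Inf` across chromosomes.
#' @export
lead_distance <- function(a, b) {
  if (chrom_chr(a$chrom) != chrom_chr(b$chrom)) return(Inf)
  abs(a$lead_pos - b$lead_pos)
}

#' Report a bp distance in kb, half-up rounded to one decimal
#'
#' @param bp Distance in base pairs.
#' @return Distance in kb with one decimal (e.g. 269397 -> 269.4).
#' @export
distance_kb <- function(bp) round_half_up(bp / 1000, 1)

#' Match loci between two datasets by lead-SNP proximity
#'
#' Greedy one-to-one matching: the globally closest unmatched pair with lead
#' distance strictly below `max_dist` is paired first, then the next, until
#' no admissible pair remains. Loci left unmatched in either set are
#' returned separately; both are retained in a final union of loci.
#'
#' @param set_a,set_b Confirmed locus tibbles.
#' @param max_dist Maximum lead distance for similarity in bp
#'   (default 250,000, strict `<`).
#' @return A list with `pairs` (tibble: `lead_a`, `lead_b`, `distance`),
#'   `unmatched_a` and `unmatched_b` (locus tibbles).
#' @export
match_loci <- function(set_a, set_b, max_dist = 250000) {
  na <- nrow(set_a)
  nb <- nrow(set_b)
  d <- matrix(Inf, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d[i, j] <- lead_distance(set_a[i, ], set_b[j, ])
    }
  }
  pairs <- list()
  free_a <- rep(TRUE, na)
  free_b <- rep(TRUE, nb)
  repeat {
    dd <- d
    dd[!free_a, ] <- Inf
    dd[, !free_b] <- Inf
    if (!length(dd) || min(dd) >= max_dist) break
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    pairs[[length(pairs) + 1]] <- tibble::tibble(
      lead_a = set_a$lead_rsid[ij[1]], lead_b = set_b$lead_rsid[ij[2]],
      distance = dd[ij[1], ij[2]]
    )
    free_a[ij[1]] <- FALSE
    free_b[ij[2]] <- FALSE
  }
  list(
    pairs = if (length(pairs)) dplyr::bind_rows(pairs) else
      tibble::tibble(lead_a = character(), lead_b = character(), distance = numeric()),
    unmatched_a = set_a[free_a, , drop = FALSE],
    unmatched_b = set_b[free_b, , drop = FALSE]
  )
}

#' Export loci as BED-style intervals
#'
#' Writes `chrom`, 0-based half-open `start`/`end`, lead rsid and lead
#' p-value, the conventional interchange shape for genome-interval tools.
#'
#' @param loci Locus tibble.
#' @param path Optional output path; when `NULL` the tibble is returned.
#' @return The BED tibble, invisibly when written to `path`.
#' @export
loci_to_bed <- function(loci, path = NULL) {
  bed <- tibble::tibble(
    chrom = loci$chrom,
    start = loci$window_start - 1,
    end = loci$window_end,
    name = loci$lead_rsid,
    score = loci$lead_pvalue
  )
  if (!is.null(path)) {
    readr::write_tsv(bed, path, col_names = FALSE)
    return(invisible(bed))
  }
  bed
}
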
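# Linkage disequilibrium from a reference genotype panel.
#
# A genotype panel is a list with: `samples` (character), `variants` (tibble:
# rsid, chrom, pos, allele_ref, allele_alt, maf), and `dosage` (numeric
# matrix, individuals x variants, values in [0, 2], columns named by rsid).
# Monomorphic and multiallelic variants never enter LD computation.

new_genotype_panel <- function(samples, variants, dosage) {
  stopifnot(nrow(dosage) == length(samples), ncol(dosage) == nrow(variants))
  colnames(dosage) <- variants$rsid
  structure(
    list(samples = samples, variants = variants, dosage = dosage),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(
    "<genotype_panel> ", length(x$samples), " individuals x ",
    nrow(x$variants), " variants\n",
    sep = ""
  )
  invisible(x)
}

#' Read a reference genotype panel for LD computation
#'
#' Supports two plain-text formats: VCF (v4.x with hard-called GT) and a
#' whitespace-delimited dosage matrix whose header row holds rsids and whose
#' subsequent rows hold one individual each. Multiallelic and monomorphic
#' variants are excluded (and counted in the [drop_log()] of the variant
#' table) because they carry no usable LD information.
#'
#' @param path Path to the panel file.
#' @param format `"vcf"` or `"dosage"`.
#' @param maf_min Variants below this minor-allele frequency are excluded
#'   (default 0.03, mirroring the reference-panel frequency filtration used
#'   for LD estimation in European 1000 Genomes panels).
#' @return A `genotype_panel` object.
#' @export
read_panel <- function(path, format = c("vcf", "dosage"), maf_min = 0.03) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "vcf") .read_panel_vcf(path, maf_min) else .read_panel_dosage(path, maf_min)
}

.read_panel_vcf <- function(path, maf_min) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) abort("VCF contains no variant records.")
  biallelic <- vcfR::is.biallelic(vcf)
  n_multi <- sum(!biallelic)
  vcf <- vcf[biallelic, ]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # hard calls: count ALT alleles, any separator, missing -> NA
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  })
  fix <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- tibble::tibble(
    rsid = ids,
    chrom = chrom_chr(fix$CHROM),
    pos = as.numeric(fix$POS),
    allele_ref = fix$REF,
    allele_alt = fix$ALT
  )
  dosage <- t(dose) # individuals x variants
  .finish_panel(colnames(gt), variants, dosage, maf_min, n_multi)
}

.read_panel_dosage <- function(path, maf_min) {
  tab <- tryCatch(
    read.table(path, header = TRUE, check.names = FALSE),
    error = function(e) abort(paste0("Malformed dosage matrix: ", conditionMessage(e)))
  )
  if (nrow(tab) == 0) abort("Dosage matrix contains no individuals.")
  dosage <- as.matrix(tab)
  if (!is.numeric(dosage)) abort("Dosage matrix must be numeric.")
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE)) {
    abort("Dosage values must lie in [0, 2].")
  }
  variants <- tibble::tibble(
    rsid = colnames(dosage),
    chrom = NA_character_, pos = NA_real_,
    allele_ref = NA_character_, allele_alt = NA_character_
  )
  .finish_panel(paste0("ind", seq_len(nrow(dosage))), variants, dosage, maf_min, 0L)
}

.finish_panel <- function(samples, variants, dosage, maf_min, n_multi) {
  # complete-case per variant: mean-impute residual missing hard calls
  for (j in seq_len(ncol(dosage))) {
    miss <- is.na(dosage[, j])
    if (any(miss)) dosage[miss, j] <- mean(dosage[, j], na.rm = TRUE)
  }
  af <- colMeans(dosage) / 2
  maf <- pmin(af, 1 - af)
  mono <- apply(dosage, 2, function(v) stats::var(v) == 0)
  rare <- !mono & maf < maf_min
  keep <- !(mono | rare)
  if (!any(keep)) abort("No polymorphic variants left after filtering.")
  variants <- variants[keep, , drop = FALSE]
  variants$maf <- maf[keep]
  variants <- set_drop_log(
    variants,
    c(multiallelic = n_multi, monomorphic = sum(mono), below_maf = sum(rare))
  )
  new_genotype_panel(samples, variants, dosage[, keep, drop = FALSE])
}

.panel_check_rsids <- function(panel, rsids) {
  missing <- setdiff(rsids, panel$variants$rsid)
  if (length(missing)) {
    abort(paste0(
      "Variant(s) not in panel: ", paste(missing, collapse = ", ")
    ))
  }
}

#' Pairwise LD correlation between two variants
#'
#' Pearson correlation of genotype dosages (the standard composite-LD
#' estimate for unphased data). `pairwise_r(panel, a, a)` is exactly 1.
#'
#' @param panel A `genotype_panel`.
#' @param a,b rsids of two variants present in the panel.
#' @return The LD correlation r (square it for r-squared).
#' @export
pairwise_r <- function(panel, a, b) {
  .panel_check_rsids(panel, c(a, b))
  if (a == b) return(1)
  stats::cor(panel$dosage[, a], panel$dosage[, b])
}

#' LD matrix over a set of variants
#'
#' Symmetric matrix of dosage correlations with a unit diagonal. A small
#' ridge can be added for downstream eigen-decompositions of near-singular
#' matrices.
#'
#' @param panel A `genotype_panel`.
#' @param rsids Variants to include, in the order given.
#' @param ridge Non-negative value added to the diagonal (then renormalized
#'   to a correlation matrix); default 0.
#' @return An `ld_view` object: list with `rsids` and the `r` matrix.
#' @export
ld_matrix <- function(panel, rsids, ridge = 0) {
  .panel_check_rsids(panel, rsids)
  r <- stats::cor(panel$dosage[, rsids, drop = FALSE])
  r <- (r + t(r)) / 2
  diag(r) <- 1
  if (ridge > 0) {
    r <- cov2cor(r + diag(ridge, nrow(r)))
  }
  dimnames(r) <- list(rsids, rsids)
  structure(list(rsids = rsids, r = r), class = "ld_view")
}

#' Build an LD view directly from a correlation matrix
#'
#' Used by the simulator and by tests to wrap a known LD structure without a
#' genotype panel.
#'
#' @param r Symmetric correlation matrix with unit diagonal, dimnames = rsids.
#' @return An `ld_view` object.
#' @export
as_ld_view <- function(r) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r), !is.null(rownames(r)))
  if (max(abs(r - t(r))) > 1e-8) abort("LD matrix must be symmetric.")
  if (max(abs(diag(r) - 1)) > 1e-8) abort("LD matrix must have unit diagonal.")
  structure(list(rsids = rownames(r), r = r), class = "ld_view")
}

#' @export
print.ld_view <- function(x, ...) {
  cat("<ld_view> ", length(x$rsids), " variants\n", sep = "")
  invisible(x)
}

# r between two rsids from an ld_view
.ld_r <- function(ld, a, b) ld$r[a, b]

#' Group SNP-linked gene evidence by LD
#'
#' Links (SNP, gene, evidence source) are grouped into connected components
#' of the graph in which two SNPs are adjacent iff they are identical or
#' their LD r-squared is at or above `r2_min`. This reproduces the
#' arrow-annotation convention of curated evidence tables: genes linked to
#' the same prioritized SNP, or to SNPs in high LD with each other, share a
#' group. Grouping takes the transitive closure of the pairwise relation so
#' the result is a partition. Links whose SNP is absent from the LD source
#' form singleton groups and are flagged.
#'
#' @param links A data frame with at least columns `snp`, `gene`, `source`.
#' @param ld A `genotype_panel` or `ld_view` providing r.
#' @param r2_min LD threshold on r-squared (default 0.8, inclusive).
#' @return The input tibble with added columns `ld_group` (integer component
#'   id) and `snp_known` (logical).
#' @export
ld_group_links <- function(links, ld, r2_min = 0.8) {
  links <- tibble::as_tibble(links)
  stopifnot(all(c("snp", "gene", "source") %in% names(links)))
  known_rsids <- if (inherits(ld, "genotype_panel")) ld$variants$rsid else ld$rsids
  snps <- unique(links$snp)
  known <- snps %in% known_rsids
  k <- snps[known]
  comp <- rep(NA_integer_, length(snps))
  names(comp) <- snps
  if (length(k)) {
    r <- if (inherits(ld, "genotype_panel")) {
      ld_matrix(ld, k)$r
    } else {
      ld$r[k, k, drop = FALSE]
    }
    adj <- (r^2 >= r2_min) | diag(TRUE, length(k))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    comp[k] <- as.integer(igraph::components(g)$membership)
  }
  # unknown SNPs become singleton groups after the known components
  n_known_groups <- if (any(known)) max(comp[k]) else 0L
  unknown <- snps[!known]
  comp[unknown] <- n_known_groups + seq_along(unknown)
  if (length(unknown)) {
    warn(paste0(
      "SNP(s) absent from LD source form singleton groups: ",
      paste(unknown, collapse = ", ")
    ))
  }
  dplyr::mutate(
    links,
    ld_group = unname(comp[links$snp]),
    snp_known = links$snp %in% k
  )
}
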
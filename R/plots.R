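# Diagnostic figures. Kept deliberately simple: a z-z colocalization view
# per locus, a scan overview, and an LD heat map.

#' Association-pattern comparison plot for one probe
#'
#' Scatters the allele-aligned GWAS z statistics against the eQTL z
#' statistics over the shared SNPs — the visual counterpart of the theta
#' metric and the HEIDI homogeneity assumption (under a single shared
#' causal variant the points fall on a line through the origin).
#'
#' @param harmonized Tibble from [harmonize_sumstats()].
#' @param highlight Optional rsid (e.g. the instrument) drawn emphasized.
#' @return A ggplot object.
#' @export
plot_coloc_pattern <- function(harmonized, highlight = NULL) {
  df <- dplyr::mutate(
    harmonized,
    role = ifelse(!is.null(highlight) & .data$rsid %in% highlight,
      "instrument", "SNP"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_eqtl, y = .data$z_gwas)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$role, size = .data$role)) +
    ggplot2::scale_size_manual(values = c(instrument = 3, SNP = 1.5), guide = "none") +
    ggplot2::scale_colour_manual(values = c(instrument = "#d95f02", SNP = "#1b6ca8")) +
    ggplot2::labs(
      x = "eQTL z", y = "GWAS z", colour = NULL,
      title = "Association patterns over shared SNPs"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_coloc_pattern autoplot method for an SMR scan: -log10
#'   SMR p per probe-tissue, coloured by colocalization call, with the FDR
#'   threshold line.
#' @param object An `smr_scan`.
#' @param ... Unused.
#' @method autoplot smr_scan
#' @export
autoplot.smr_scan <- function(object, ...) {
  res <- object$results
  res$label <- paste0(res$gene, " / ", res$tissue)
  ggplot2::ggplot(
    res,
    ggplot2::aes(
      x = stats::reorder(.data$label, -.data$p_smr),
      y = -log10(.data$p_smr), fill = .data$call
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = expression(-log[10] ~ p[SMR]), fill = "call",
      title = "SMR/HEIDI scan"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_coloc_pattern autoplot method for an LD view: r-squared
#'   heat map.
#' @method autoplot ld_view
#' @export
autoplot.ld_view <- function(object, ...) {
  df <- tidyr::expand_grid(
    a = factor(object$rsids, levels = object$rsids),
    b = factor(object$rsids, levels = object$rsids)
  )
  df$r2 <- as.vector(object$r^2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(
      low = "white", high = "#b2182b", limits = c(0, 1),
      name = expression(r^2)
    ) +
    ggplot2::labs(x = NULL, y = NULL, title = "LD structure") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Evidence-category overview plot
#'
#' Bar chart of loci per conclusion category of a curated evidence table.
#'
#' @param ev A `locus_evidence`.
#' @return A ggplot object.
#' @export
plot_conclusions <- function(ev) {
  s <- summarize_conclusions(ev)$by_category
  s$conclusion <- factor(s$conclusion, levels = s$conclusion)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$conclusion, y = .data$n_loci)) +
    ggplot2::geom_col(fill = "#1b6ca8") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_loci), vjust = -0.4) +
    ggplot2::labs(
      x = NULL, y = "loci",
      title = "Loci per evidence conclusion"
    ) +
    ggplot2::theme_minimal()
}
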
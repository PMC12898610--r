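# ggplot2 renderings of the main result tables. Each takes the tidy table
# its stage emits, so plots can be rebuilt from written TSVs.

#' Heatmap of pairwise protein correlations
#'
#' @param corr Output of [protein_correlations()].
#' @return A ggplot.
#' @export
plot_protein_correlations <- function(corr) {
  ggplot2::ggplot(corr, ggplot2::aes(.data$analyte_x, .data$analyte_y,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#b2182b",
                                  mid = "white", high = "#2166ac") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Lollipop plot of functional-group enrichment scores
#'
#' @param scores Output of [enrichment_scores()].
#' @param analyte Analyte to display.
#' @param level `"snp"` or `"gene"`.
#' @return A ggplot; the dashed line at 1 marks no enrichment.
#' @export
plot_enrichment <- function(scores, analyte, level = "snp") {
  d <- scores[scores$analyte == analyte & scores$level == level, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$score, .data$functional_group)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$score,
                                       yend = .data$functional_group),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$observed_prop)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "enrichment score", y = NULL,
                  title = paste0(analyte, " (", level, " level)"),
                  size = "observed\nproportion") +
    ggplot2::theme_minimal()
}

#' Genotype-stratified box plot of an analyte
#'
#' Log2 levels by dosage stratum with the case percentage annotated per
#' stratum.
#'
#' @param genotypes,proteins,subjects Pipeline inputs.
#' @param rsid,analyte SNP and analyte to display.
#' @return A ggplot.
#' @export
plot_genotype_levels <- function(genotypes, proteins, subjects, rsid,
                                 analyte) {
  dat <- dplyr::inner_join(genotypes[c("subject_id", rsid)],
                           proteins[c("subject_id", analyte)],
                           by = "subject_id") |>
    dplyr::inner_join(subjects[c("subject_id", "group")], by = "subject_id") |>
    dplyr::filter(!is.na(.data[[rsid]]), !is.na(.data[[analyte]]))
  summ <- genotype_stratified_summary(genotypes, proteins, subjects, rsid,
                                      analyte)
  labs <- sprintf("%d\n%.0f%% cases", summ$dosage, 100 * summ$case_fraction)
  ggplot2::ggplot(dat, ggplot2::aes(factor(.data[[rsid]]),
                                    .data[[analyte]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$group), width = 0.15,
                         alpha = 0.7) +
    ggplot2::scale_x_discrete(labels = labs) +
    ggplot2::labs(x = paste(rsid, "minor-allele dosage"),
                  y = paste0("log2 ", analyte)) +
    ggplot2::theme_minimal()
}

#' Scan overview for a pQTL scan
#'
#' Minus log10 FvR p by SNP, coloured by analyte, with the reporting tiers
#' marked.
#'
#' @param object A `pqtl_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pqtl_scan
#' @export
autoplot.pqtl_scan <- function(object, ...) {
  d <- dplyr::as_tibble(object)
  d$idx <- match(d$rsid, unique(d$rsid))
  ggplot2::ggplot(d, ggplot2::aes(.data$idx, -log10(.data$p_fvr),
                                  colour = .data$analyte)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(c(0.05, 0.01)),
                        linetype = c("dashed", "dotted")) +
    ggplot2::labs(x = "SNP index", y = expression(-log[10] * " p (FvR)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
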
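# Functional-group enrichment of top pQTL hits, overlap with disease-
# associated SNPs, cis/trans classification, OR-beta directionality, and
# overlap with external GWAS summary statistics.

#' Top pQTL hits per analyte
#'
#' Filters scan records at `p_fvr < p_threshold` (strict inequality). A SNP
#' associated with several analytes appears in each relevant per-analyte
#' list; the pooled SNP and gene sets deduplicate across lists.
#'
#' @param scan A `pqtl_scan` tibble carrying `gene` annotation.
#' @param p_threshold Raw FvR p-value cutoff (default 0.01).
#' @return List: `hits` (tibble analyte, rsid, gene, functional_group,
#'   p_fvr), `snp_pool` (unique rsids), `gene_pool` (unique genes).
#' @export
top_hits <- function(scan, p_threshold = 0.01) {
  stopifnot(is.data.frame(scan))
  if (!"gene" %in% names(scan)) {
    stop("scan records carry no gene annotation; rerun pqtl_scan() with `snps`")
  }
  hits <- scan[scan$p_fvr < p_threshold, , drop = FALSE]
  hits <- dplyr::as_tibble(hits)[c("analyte", "rsid", "gene",
                                   "functional_group", "p_fvr")]
  if (any(is.na(hits$gene))) {
    warning(sum(is.na(hits$gene)),
            " hit(s) lack gene annotation: counted at SNP level only")
  }
  list(hits = hits,
       snp_pool = unique(hits$rsid),
       gene_pool = unique(stats::na.omit(hits$gene)))
}

#' Functional-group enrichment scores
#'
#' For each analyte and functional group, the enrichment score is the
#' observed proportion of that analyte's top hits falling in the group
#' divided by the group's expected proportion in the pooled distribution
#' across all analytes' top-hit lists. Scores above 1 indicate
#' overrepresentation. Computed separately at SNP level (every hit counts)
#' and gene level (a gene counts once per analyte list). By default the pool
#' keeps multiplicity across analyte lists; `dedupe = TRUE` pools unique
#' SNPs/genes instead.
#'
#' @param th Output of [top_hits()].
#' @param dedupe Pool with (`FALSE`, default) or without multiplicity.
#' @return Tibble: level (`"snp"`/`"gene"`), analyte, functional_group,
#'   observed_count, observed_prop, expected_prop, score.
#' @export
enrichment_scores <- function(th, dedupe = FALSE) {
  hits <- th$hits
  score_level <- function(tab, level) {
    if (nrow(tab) == 0) return(NULL)
    pool <- if (dedupe) dplyr::distinct(tab, .data$unit, .data$functional_group)
            else tab
    exp_tab <- pool |>
      dplyr::count(.data$functional_group, name = "pool_count") |>
      dplyr::mutate(expected_prop = .data$pool_count / sum(.data$pool_count))
    obs <- tab |>
      dplyr::count(.data$analyte, .data$functional_group,
                   name = "observed_count") |>
      dplyr::group_by(.data$analyte) |>
      dplyr::mutate(observed_prop = .data$observed_count /
                      sum(.data$observed_count)) |>
      dplyr::ungroup()
    grid <- tidyr::expand_grid(analyte = unique(tab$analyte),
                               functional_group = unique(exp_tab$functional_group))
    out <- grid |>
      dplyr::left_join(obs, by = c("analyte", "functional_group")) |>
      dplyr::left_join(exp_tab, by = "functional_group") |>
      dplyr::mutate(observed_count = dplyr::coalesce(.data$observed_count, 0L),
                    observed_prop = dplyr::coalesce(.data$observed_prop, 0),
                    score = .data$observed_prop / .data$expected_prop,
                    level = level)
    if (any(is.infinite(out$score) | (out$expected_prop == 0 &
                                      out$observed_prop > 0))) {
      warning("observed hits in a group with expected proportion 0; ",
              "score flagged infinite")
    }
    out[c("level", "analyte", "functional_group", "observed_count",
          "observed_prop", "expected_prop", "score")]
  }
  snp_tab <- dplyr::mutate(hits, unit = .data$rsid)
  gene_tab <- hits |>
    dplyr::filter(!is.na(.data$gene)) |>
    dplyr::distinct(.data$analyte, .data$gene, .data$functional_group) |>
    dplyr::mutate(unit = .data$gene)
  dplyr::bind_rows(score_level(snp_tab, "snp"), score_level(gene_tab, "gene"))
}

#' Intersect pQTL-significant SNPs with disease-associated SNPs
#'
#' SNPs present in both the significant pQTL set (`p_fvr < p_threshold`) and
#' the disease table, joined with the per-analyte effect and the disease
#' OR/risk allele. A shared SNP impacting several analytes fans out to one
#' row per analyte.
#'
#' @param scan A `pqtl_scan` tibble.
#' @param disease Disease-association tibble (see
#'   [read_disease_associations()]).
#' @param p_threshold Significance cutoff for the pQTL set (default 0.05).
#' @return Tibble: rsid, analyte, beta, se, p_fvr, risk_allele, odds_ratio
#'   (plus gene/cis_trans when present in `scan`).
#' @export
overlap_disease_snps <- function(scan, disease, p_threshold = 0.05) {
  if (any(duplicated(disease$rsid))) stop("duplicate rsid rows in disease table")
  sig <- scan[scan$p_fvr < p_threshold, , drop = FALSE]
  keep <- intersect(c("rsid", "analyte", "gene", "beta", "se", "p_fvr",
                      "cis_trans"), names(sig))
  dplyr::inner_join(dplyr::as_tibble(sig)[keep],
                    disease[intersect(c("rsid", "risk_allele", "risk_nt",
                                        "odds_ratio"), names(disease))],
                    by = "rsid")
}

#' Classify pQTL records as cis or trans
#'
#' A variant is cis to an analyte when it lies on the same chromosome as, and
#' within 1 Mb (inclusive) of, the transcription start site of the gene
#' encoding that protein; trans otherwise; unknown when the analyte has no
#' TSS mapping or the SNP lacks coordinates.
#'
#' @param records Tibble with `rsid`, `analyte` and (after annotation)
#'   `chrom`, `pos`; e.g. a `pqtl_scan` or an overlap table joined to SNP
#'   coordinates.
#' @param tss Tibble mapping analytes to their encoding gene's TSS:
#'   columns `analyte`, `gene`, `chrom`, `tss`.
#' @param window Cis window in bp, boundary inclusive (default 1e6).
#' @return `records` with the `cis_trans` column filled.
#' @export
classify_cis_trans <- function(records, tss, window = 1e6) {
  stopifnot(all(c("analyte", "chrom", "pos") %in% names(records)),
            all(c("analyte", "chrom", "tss") %in% names(tss)))
  idx <- match(records$analyte, tss$analyte)
  t_chrom <- as.character(tss$chrom)[idx]
  t_pos <- tss$tss[idx]
  known <- !is.na(t_chrom) & !is.na(records$chrom) & !is.na(records$pos)
  cis <- known & as.character(records$chrom) == t_chrom &
    abs(records$pos - t_pos) <= window
  records$cis_trans <- dplyr::case_when(!known ~ "unknown",
                                        cis ~ "cis",
                                        TRUE ~ "trans")
  records
}

#' Orient disease/protein effects to the minor allele
#'
#' Directionality analysis requires every point expressed with respect to the
#' minor allele: rows reported with respect to the major allele have their OR
#' inverted and their beta sign flipped.
#'
#' @param points Tibble with `odds_ratio`, `beta` and `allele_respect`
#'   (`"minor"`/`"major"`).
#' @return Tibble with all rows minor-allele-respect.
#' @export
orient_minor <- function(points) {
  stopifnot(all(c("odds_ratio", "beta") %in% names(points)))
  if (!"allele_respect" %in% names(points)) return(points)
  flip <- points$allele_respect == "major"
  points$odds_ratio[flip] <- 1 / points$odds_ratio[flip]
  points$beta[flip] <- -points$beta[flip]
  points$allele_respect <- "minor"
  points
}

#' OR-beta directionality regression
#'
#' OLS of the per-minor-allele protein effect (beta) on the disease odds
#' ratio, one point per SNP; the reported R-squared measures how consistently
#' genetic disease risk aligns with the direction of the protein effect.
#'
#' @param points Tibble with `odds_ratio` (> 0) and `beta`, already
#'   minor-allele-oriented (see [orient_minor()]).
#' @return One-row tibble: slope, intercept, r_squared, n.
#' @export
directionality <- function(points) {
  points <- orient_minor(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  if (sd(points$odds_ratio) == 0) stop("zero variance in odds ratios")
  fit <- lm(beta ~ odds_ratio, data = points)
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n = nrow(points))
}

#' Per-analyte top-N hits by p-value
#'
#' @param scan A `pqtl_scan` tibble.
#' @param n Hits to keep per analyte (default 50), ties broken by rsid for
#'   determinism.
#' @return Tibble of the lowest-p records per analyte.
#' @export
top_n_hits <- function(scan, n = 50) {
  dplyr::as_tibble(scan) |>
    dplyr::group_by(.data$analyte) |>
    dplyr::arrange(.data$p_fvr, .data$rsid, .by_group = TRUE) |>
    dplyr::slice_head(n = n) |>
    dplyr::ungroup()
}

#' Overlap top hits with an external GWAS summary table
#'
#' Joins each analyte's top hits to external summary rows by rsid. Unmatched
#' rows are dropped by design; a SNP in two analytes' lists matching one
#' external phenotype yields two rows.
#'
#' @param hits Per-analyte top hits, e.g. from [top_n_hits()].
#' @param external Tibble with `rsid`, `phenotype`, `odds_ratio` and
#'   optionally `ci_lower`, `ci_upper`, `p_value`, `gene`, `consequence`.
#' @return Tibble mirroring the external columns plus the internal analyte
#'   and FvR p-value.
#' @export
external_overlap <- function(hits, external) {
  stopifnot(all(c("rsid", "phenotype", "odds_ratio") %in% names(external)))
  keep <- intersect(c("phenotype", "rsid", "gene", "consequence",
                      "odds_ratio", "ci_lower", "ci_upper", "p_value"),
                    names(external))
  internal <- dplyr::as_tibble(hits)[intersect(c("rsid", "analyte", "p_fvr",
                                                 "beta"), names(hits))]
  out <- dplyr::inner_join(external[keep], internal, by = "rsid",
                           relationship = "many-to-many")
  dplyr::rename(out, pqtl_p = "p_fvr")
}
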
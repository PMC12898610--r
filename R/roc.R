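# Genotype-defined stratified ROC screening, filter rules, and two-marker
# subgroup assignment.
#
# AUC is the Mann-Whitney concordance of in-sample predicted probabilities
# (probability a random case outranks a random control, ties counted 1/2);
# its SE uses the Hanley-McNeil formula and the test against AUC = 0.5 a
# normal approximation on (AUC - 0.5)/SE. Apparent (in-sample) AUC is
# reported, as no held-out data exist at these stratum sizes; optimism is
# discussed in the vignette.

#' Mann-Whitney AUC with Hanley-McNeil standard error
#'
#' @param scores_case,scores_control Numeric prediction scores.
#' @return One-row tibble: auc, se, n_case, n_control.
#' @export
auc_mann_whitney <- function(scores_case, scores_control) {
  n1 <- length(scores_case)
  n2 <- length(scores_control)
  stopifnot(n1 > 0, n2 > 0)
  cmp <- outer(scores_case, scores_control, FUN = "-")
  auc <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (n1 * n2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  tibble::tibble(auc = auc, se = se, n_case = n1, n_control = n2)
}

roc_record <- function(scores, case, stratum_label, analyte, covariates,
                       auc_min = 0.75, p_max = 0.05, n_min = 15,
                       auc_op = `>`) {
  mw <- auc_mann_whitney(scores[case], scores[!case])
  p <- if (mw$se == 0) {
    if (mw$auc == 0.5) 1 else 0  # degenerate: perfect separation
  } else {
    2 * pnorm(-abs((mw$auc - 0.5) / mw$se))
  }
  n <- mw$n_case + mw$n_control
  tibble::tibble(
    stratum = stratum_label, analyte = analyte,
    covariates = paste(covariates, collapse = "+"),
    n_case = mw$n_case, n_control = mw$n_control,
    auc = mw$auc, se = mw$se,
    ci_lower = max(0, mw$auc - 1.96 * mw$se),
    ci_upper = min(1, mw$auc + 1.96 * mw$se),
    p_vs_half = p,
    passes_filters = auc_op(mw$auc, auc_min) && p < p_max && n >= n_min
  )
}

# Internal: logistic ROC on an explicit subject subset.
roc_on_subjects <- function(proteins, subjects, ids, stratum_label, analyte,
                            covariates, ...) {
  sub <- subjects[subjects$subject_id %in% ids, , drop = FALSE]
  if (nrow(sub) == 0) stop("empty stratum: ", stratum_label)
  if (length(unique(sub$group)) < 2) {
    stop("single-class stratum: ", stratum_label)
  }
  fit <- suppressWarnings(
    case_control_logistic(proteins, sub, analyte, covariates)
  )
  probs <- predict(fit$model, type = "response")
  case <- fit$data$group == "MECFS"
  rec <- roc_record(probs, case, stratum_label, analyte, fit$covariates, ...)
  rec$separation <- fit$separation
  rec
}

#' ROC of one analyte within a genotype-defined stratum
#'
#' Retains the subjects matching ALL genotype conditions, fits a logistic
#' model of case status on the log2 analyte plus covariates within the
#' stratum (covariates constant within the stratum, such as sex in an
#' all-female stratum, are dropped automatically), and summarises the
#' in-sample predicted probabilities as an ROC record.
#'
#' @param genotypes Dosage tibble.
#' @param proteins Log2 panel.
#' @param subjects Subject tibble.
#' @param stratum Named list or vector, rsid -> required dosage (e.g.
#'   `c(rs9332739 = 1)`); a subject must match every condition.
#' @param analyte Analyte name.
#' @param covariates Adjustment set.
#' @param auc_min,p_max,n_min Filter thresholds (defaults AUC > 0.75,
#'   p < 0.05, n >= 15).
#' @param auc_op Comparison for the AUC filter, `` `>` `` (default) or
#'   `` `>=` ``.
#' @return One-row tibble (an ROC record).
#' @export
stratum_roc <- function(genotypes, proteins, subjects, stratum, analyte,
                        covariates = character(), auc_min = 0.75,
                        p_max = 0.05, n_min = 15, auc_op = `>`) {
  rs <- names(stratum)
  if (is.null(rs) || !all(rs %in% names(genotypes))) {
    stop("stratum conditions must name genotype columns")
  }
  keep <- rep(TRUE, nrow(genotypes))
  for (r in rs) keep <- keep & !is.na(genotypes[[r]]) &
      genotypes[[r]] == stratum[[r]]
  ids <- genotypes$subject_id[keep]
  label <- paste(sprintf("%s=%d", rs, as.integer(unlist(stratum))),
                 collapse = ";")
  roc_on_subjects(proteins, subjects, ids, label, analyte, covariates,
                  auc_min = auc_min, p_max = p_max, n_min = n_min,
                  auc_op = auc_op)
}

#' Screen genotype strata for discriminative analytes
#'
#' For each SNP in `snp_set`, each of its observed dosage levels, and each
#' analyte, computes one stratified ROC record; records are ranked by AUC
#' and `passes_filters` reflects the thresholds. Failing strata (single
#' class, too small) are skipped and logged in the `skipped` attribute.
#'
#' @inheritParams stratum_roc
#' @param snp_set rsids to screen.
#' @param covariate_map Named list analyte -> covariates.
#' @param analyte_set Analytes to screen (default: all present).
#' @return Tibble of ROC records sorted by decreasing AUC, with a `skipped`
#'   attribute.
#' @export
screen_strata <- function(genotypes, proteins, subjects, snp_set,
                          covariate_map = list(), analyte_set = NULL,
                          auc_min = 0.75, p_max = 0.05, n_min = 15,
                          auc_op = `>`) {
  stopifnot(length(snp_set) > 0)
  analyte_set <- analyte_set %||% intersect(analytes(), names(proteins))
  recs <- list()
  skipped <- list()
  for (rs in snp_set) {
    levels_obs <- sort(unique(stats::na.omit(genotypes[[rs]])))
    for (g in levels_obs) {
      for (a in analyte_set) {
        rec <- tryCatch(
          stratum_roc(genotypes, proteins, subjects,
                      stratum = setNames(g, rs), analyte = a,
                      covariates = covariate_map[[a]] %||% character(),
                      auc_min = auc_min, p_max = p_max, n_min = n_min,
                      auc_op = auc_op),
          error = function(e) conditionMessage(e)
        )
        if (is.character(rec)) {
          skipped[[length(skipped) + 1L]] <-
            tibble::tibble(rsid = rs, dosage = g, analyte = a, reason = rec)
        } else {
          recs[[length(recs) + 1L]] <- rec
        }
      }
    }
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out)) out <- dplyr::arrange(out, dplyr::desc(.data$auc))
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}

#' Two-marker heterozygosity subgroup assignment
#'
#' A subject is "het" iff heterozygous (dosage exactly 1) at either marker;
#' subjects homozygous (dosage 0 or 2) at both are "rem" -- in particular,
#' homozygous-risk (dosage 2) carriers are NOT het. Labels combine illness
#' status with het status: CFShet, CFSrem, NFhet, NFrem, partitioning the
#' cohort.
#'
#' @param genotypes Dosage tibble.
#' @param subjects Subject tibble.
#' @param marker_a,marker_b rsids of the two markers.
#' @param missing How to treat subjects missing a genotype at either marker:
#'   `"exclude"` (default) or `"rem"`.
#' @return Tibble: subject_id, group, dosage_a, dosage_b, het, subgroup
#'   (factor CFShet/CFSrem/NFhet/NFrem).
#' @export
assign_subgroups <- function(genotypes, subjects, marker_a, marker_b,
                             missing = c("exclude", "rem")) {
  missing <- match.arg(missing)
  for (m in c(marker_a, marker_b)) {
    if (!m %in% names(genotypes)) stop("marker absent from matrix: ", m)
  }
  dat <- dplyr::inner_join(
    genotypes[c("subject_id", marker_a, marker_b)],
    subjects[c("subject_id", "group")], by = "subject_id"
  )
  names(dat)[2:3] <- c("dosage_a", "dosage_b")
  anymiss <- is.na(dat$dosage_a) | is.na(dat$dosage_b)
  if (missing == "exclude") {
    dat <- dat[!anymiss, , drop = FALSE]
    het <- dat$dosage_a == 1 | dat$dosage_b == 1
  } else {
    het <- !is.na(dat$dosage_a) & dat$dosage_a == 1 |
      !is.na(dat$dosage_b) & dat$dosage_b == 1
  }
  dat$het <- het
  dat$subgroup <- factor(
    paste0(ifelse(dat$group == "MECFS", "CFS", "NF"),
           ifelse(dat$het, "het", "rem")),
    levels = c("CFShet", "CFSrem", "NFhet", "NFrem")
  )
  dat[c("subject_id", "group", "dosage_a", "dosage_b", "het", "subgroup")]
}

#' Re-analyse the cohort under a four-group subgroup assignment
#'
#' Delegates to the association models on the 4-level labels: per-analyte
#' LRT for the protein's overall contribution, multinomial fits against the
#' NFhet reference, pairwise covariate-adjusted contrasts, het-only ROC
#' (CFShet vs NFhet), and optionally het-only survey associations on the
#' same restricted sample.
#'
#' @param proteins Log2 panel.
#' @param assignment Output of [assign_subgroups()].
#' @param subjects Subject tibble.
#' @param covariate_map Named list analyte -> covariates.
#' @param surveys Optional survey tibble for het-only score associations.
#' @param analyte_set Analytes to analyse (default: all present).
#' @return List: `sizes`, `lrt` (per-analyte), `multinomial` (long tidy),
#'   `contrasts` (long), `roc_het` (per-analyte), `survey_het` (long or
#'   NULL).
#' @export
subgroup_reanalysis <- function(proteins, assignment, subjects,
                                covariate_map = list(), surveys = NULL,
                                analyte_set = NULL) {
  sizes <- dplyr::count(assignment, .data$subgroup, .drop = FALSE)
  if (sum(sizes$n > 0) < 3) stop("need at least 3 nonempty subgroups")
  analyte_set <- analyte_set %||% intersect(analytes(), names(proteins))
  subjects_in <- subjects[subjects$subject_id %in% assignment$subject_id, ]

  lrt_rows <- list()
  multi_rows <- list()
  contrast_rows <- list()
  roc_rows <- list()
  het_ids <- assignment$subject_id[assignment$het]
  for (a in analyte_set) {
    covs <- covariate_map[[a]] %||% character()
    full <- suppressWarnings(
      multinomial_subgroups(proteins, assignment, subjects_in, a, covs)
    )
    lr <- lrt(full, reduced_fit(full))
    lrt_rows[[a]] <- dplyr::mutate(lr, analyte = a, .before = 1)
    multi_rows[[a]] <- dplyr::mutate(tidy(full), analyte = a, .before = 1)
    linfit <- suppressWarnings(
      subgroup_linear(proteins, assignment, subjects_in, a, covs)
    )
    contrast_rows[[a]] <- dplyr::mutate(pairwise_contrasts(linfit),
                                        analyte = a, .before = 1)
    roc_rows[[a]] <- tryCatch(
      roc_on_subjects(proteins, subjects_in, het_ids, "het-only", a, covs),
      error = function(e) NULL
    )
  }
  survey_het <- NULL
  if (!is.null(surveys)) {
    het_subjects <- subjects_in[subjects_in$subject_id %in% het_ids, ]
    survey_het <- survey_association_all(proteins, surveys, het_subjects,
                                         covariate_map = covariate_map,
                                         analyte_set = analyte_set)
  }
  list(sizes = sizes,
       lrt = dplyr::bind_rows(lrt_rows),
       multinomial = dplyr::bind_rows(multi_rows),
       contrasts = dplyr::bind_rows(contrast_rows),
       roc_het = dplyr::bind_rows(roc_rows),
       survey_het = survey_het)
}
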
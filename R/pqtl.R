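# SNP x protein QTL scan: covariate-adjusted full-versus-reduced (FvR)
# linear models with F-tests and Bonferroni correction.
#
# The full model regresses the log2 protein level on the additive minor-
# allele dosage (numeric 0/1/2) plus the analyte's covariates; the reduced
# model drops the dosage term. Both are fitted on identical rows and
# F = ((RSS_red - RSS_full) / 1) / (RSS_full / (n - p_full)), with the
# p-value from F(1, n - p_full). For the single added term F equals the
# squared t of the dosage coefficient.

# QR-based nested OLS on prebuilt design matrices; returns NULL on rank
# deficiency so the caller can raise a named error.
fvr_fit <- function(y, X_full, X_red) {
  qf <- qr(X_full)
  if (qf$rank < ncol(X_full)) return(NULL)
  qr_red <- qr(X_red)
  rss_full <- sum(qr.resid(qf, y)^2)
  rss_red <- sum(qr.resid(qr_red, y)^2)
  n <- length(y)
  p_full <- ncol(X_full)
  df_res <- n - p_full
  f_stat <- ((rss_red - rss_full) / 1) / (rss_full / df_res)
  coefs <- qr.coef(qf, y)
  sigma2 <- rss_full / df_res
  inv_piv <- chol2inv(qr.R(qf))  # (X'X)^-1 in pivoted column order
  xtx_inv <- matrix(NA_real_, p_full, p_full)
  xtx_inv[qf$pivot, qf$pivot] <- inv_piv
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(X_full)
  list(beta = coefs, se = se, f_statistic = f_stat,
       p_fvr = pf(f_stat, 1, df_res, lower.tail = FALSE), n = n,
       df_res = df_res)
}

pqtl_design <- function(genotypes, proteins, subjects, rsid, analyte,
                        covariates) {
  stopifnot(rsid %in% names(genotypes), analyte %in% names(proteins))
  dat <- dplyr::inner_join(genotypes[c("subject_id", rsid)],
                           proteins[c("subject_id", analyte)],
                           by = "subject_id")
  dat <- dplyr::inner_join(dat, subjects, by = "subject_id")
  dat$sex <- as.integer(dat$sex == "male")
  vars <- c(rsid, analyte, covariates)
  dat <- dat[complete.cases(dat[vars]), , drop = FALSE]
  covariates <- covariates[vapply(covariates,
                                  function(v) sd(dat[[v]]) > 0, logical(1))]
  list(dat = dat, covariates = covariates)
}

#' Fit one SNP-protein FvR model
#'
#' Subjects missing the genotype, the analyte, or any covariate are dropped
#' pairwise for this pair. A SNP is testable when the analysed rows carry at
#' least two distinct dosage values and at least 3 minor-allele copies;
#' otherwise the pair is skipped (returns `NULL` with a message).
#'
#' @param genotypes Dosage tibble (`subject_id` + rsid columns, minor-allele
#'   counts).
#' @param proteins Log2 panel.
#' @param subjects Subject tibble.
#' @param rsid SNP identifier (a column of `genotypes`).
#' @param analyte Analyte name.
#' @param covariates Adjustment set from `c("age", "sex", "bmi")`.
#' @return One-row tibble (rsid, analyte, beta, se, f_statistic, p_fvr,
#'   n_used, cis_trans = "unknown"), or `NULL` if skipped.
#' @export
fit_pqtl <- function(genotypes, proteins, subjects, rsid, analyte,
                     covariates = character()) {
  pd <- pqtl_design(genotypes, proteins, subjects, rsid, analyte, covariates)
  dat <- pd$dat
  covariates <- pd$covariates
  g <- dat[[rsid]]
  if (length(unique(g)) < 2 || sum(g) < 3) {
    message("skipping ", rsid, " x ", analyte,
            ": monomorphic or too few minor alleles in analysed rows")
    return(NULL)
  }
  if (nrow(dat) <= length(covariates) + 3) {
    message("skipping ", rsid, " x ", analyte, ": too few rows")
    return(NULL)
  }
  X_red <- matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(covariates)) X_red <- cbind(X_red, as.matrix(dat[covariates]))
  X_full <- cbind(X_red[, 1, drop = FALSE], dosage = g,
                  X_red[, -1, drop = FALSE])
  fit <- fvr_fit(dat[[analyte]], X_full, X_red)
  if (is.null(fit)) stop("rank-deficient design for ", rsid, " x ", analyte)
  tibble::tibble(
    rsid = rsid, analyte = analyte,
    beta = unname(fit$beta["dosage"]),
    se = unname(fit$se["dosage"]),
    f_statistic = fit$f_statistic, p_fvr = fit$p_fvr, n_used = fit$n,
    cis_trans = "unknown"
  )
}

#' Scan every SNP-analyte pair
#'
#' One FvR record per testable pair. The Bonferroni denominator `m` is the
#' number of models actually fitted in this scan (skipped pairs excluded):
#' `p_bonferroni = min(1, p_fvr * m)`. The summary reports counts at the two
#' reporting tiers p < 0.05 and p < 0.01.
#'
#' @inheritParams fit_pqtl
#' @param snps SNP annotation tibble (used for rsid list and carried gene
#'   annotation); defaults to every genotype column.
#' @param covariate_map Named list analyte -> covariates from
#'   [covariate_sets()].
#' @param analyte_set Analytes to scan (default: all panel analytes present).
#' @return Tibble of class `pqtl_scan` with attributes `m`, `summary`
#'   (counts) and `skipped` (tibble of skipped pairs with reasons).
#' @export
pqtl_scan <- function(genotypes, proteins, subjects, snps = NULL,
                      covariate_map = list(), analyte_set = NULL) {
  rsids <- if (!is.null(snps)) snps$rsid else
    setdiff(names(genotypes), "subject_id")
  missing_g <- setdiff(rsids, names(genotypes))
  if (length(missing_g)) stop("SNP(s) absent from genotype matrix: ",
                              paste(head(missing_g, 5), collapse = ", "))
  analyte_set <- analyte_set %||% intersect(analytes(), names(proteins))
  records <- vector("list", length(rsids) * length(analyte_set))
  skipped <- list()
  k <- 0L
  for (rs in rsids) {
    for (a in analyte_set) {
      rec <- withCallingHandlers(
        fit_pqtl(genotypes, proteins, subjects, rs, a,
                 covariate_map[[a]] %||% character()),
        message = function(m) invokeRestart("muffleMessage")
      )
      if (is.null(rec)) {
        skipped[[length(skipped) + 1L]] <-
          tibble::tibble(rsid = rs, analyte = a,
                         reason = "monomorphic or insufficient data")
      } else {
        k <- k + 1L
        records[[k]] <- rec
      }
    }
  }
  out <- dplyr::bind_rows(records[seq_len(k)])
  m <- nrow(out)
  if (m > 0) {
    out$p_bonferroni <- pmin(1, out$p_fvr * m)
    if (!is.null(snps)) {
      ann <- snps[intersect(c("rsid", "gene", "functional_group", "chrom",
                              "pos", "maf"), names(snps))]
      out <- dplyr::left_join(out, ann, by = "rsid")
    }
  } else {
    out$p_bonferroni <- numeric()
  }
  structure(out,
            class = c("pqtl_scan", class(out)),
            m = m,
            summary = tibble::tibble(
              models_fitted = m,
              snps_tested = length(unique(out$rsid)),
              n_sig_05 = sum(out$p_fvr < 0.05),
              n_sig_01 = sum(out$p_fvr < 0.01),
              snps_sig_05 = length(unique(out$rsid[out$p_fvr < 0.05])),
              snps_sig_01 = length(unique(out$rsid[out$p_fvr < 0.01]))),
            skipped = dplyr::bind_rows(skipped))
}

#' @export
summary.pqtl_scan <- function(object, ...) attr(object, "summary")

#' Per-genotype stratified summary of an analyte
#'
#' For each dosage level 0/1/2: subject counts, case count and fraction, and
#' the five-number summary plus mean of the log2 levels -- the table behind
#' genotype-stratified box plots annotated with the percentage of cases per
#' genotype group.
#'
#' @inheritParams fit_pqtl
#' @return Tibble: dosage, n, n_case, case_fraction, min, q1, median, q3,
#'   max, mean.
#' @export
genotype_stratified_summary <- function(genotypes, proteins, subjects, rsid,
                                        analyte) {
  pd <- pqtl_design(genotypes, proteins, subjects, rsid, analyte, character())
  dat <- pd$dat
  dat |>
    dplyr::group_by(dosage = .data[[rsid]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_case = sum(.data$group == "MECFS"),
      case_fraction = .data$n_case / .data$n,
      min = min(.data[[analyte]]),
      q1 = unname(quantile(.data[[analyte]], 0.25, type = 7)),
      median = median(.data[[analyte]]),
      q3 = unname(quantile(.data[[analyte]], 0.75, type = 7)),
      max = max(.data[[analyte]]),
      mean = mean(.data[[analyte]]),
      .groups = "drop"
    )
}
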
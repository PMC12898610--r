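# Demographic comparisons, covariate screening, and protein-protein
# correlation.

#' Compare demographics between illness groups
#'
#' Two-sided Wilcoxon rank-sum tests for age and BMI, plus sex counts per
#' group. The exact null distribution is used when both groups have at most
#' 25 subjects and the data are tie-free; otherwise the normal approximation
#' with mid-ranks and tie-corrected variance.
#'
#' @param subjects Subject tibble (see [read_subjects()]).
#' @return List with `tests` (tibble: variable, w_statistic, p_value, method)
#'   and `sex_counts` (tibble: group, male, female).
#' @export
compare_demographics <- function(subjects) {
  counts <- table(subjects$group)
  if (any(counts < 2)) stop("need at least 2 subjects per group")
  one <- function(var) {
    x <- subjects[[var]][subjects$group == "MECFS"]
    y <- subjects[[var]][subjects$group == "NF"]
    exact <- length(x) <= 25 && length(y) <= 25 &&
      !any(duplicated(c(x, y)))
    wt <- wilcox.test(x, y, exact = exact, correct = !exact)
    tibble::tibble(variable = var, w_statistic = unname(wt$statistic),
                   p_value = wt$p.value,
                   method = if (exact) "exact" else "normal approximation")
  }
  sex_counts <- subjects |>
    dplyr::count(.data$group, .data$sex) |>
    tidyr::pivot_wider(names_from = "sex", values_from = "n",
                       values_fill = 0L)
  list(tests = dplyr::bind_rows(one("age"), one("bmi")),
       sex_counts = sex_counts)
}

#' Screen demographic covariates against each analyte
#'
#' One simple (bivariate) linear regression of each log2 analyte on each
#' demographic covariate. Sex is coded male = 1, female = 0, so a negative
#' coefficient means lower levels in males. A covariate is selected for an
#' analyte's downstream adjustment set when its p-value falls below
#' `alpha`; the `force` list can add literature-supported covariates
#' regardless of p.
#'
#' @param proteins Log2 panel from [log2_transform()].
#' @param subjects Subject tibble.
#' @param alpha Screening significance level (default 0.05).
#' @param force Optional named list, analyte -> character vector of
#'   covariates to force into the adjustment set.
#' @return Tibble: analyte, covariate, estimate, std_error, adjusted_r2,
#'   f_statistic, p_value, n_used, selected, forced.
#' @export
screen_covariates <- function(proteins, subjects, alpha = 0.05, force = NULL) {
  covs <- c("age", "sex", "bmi")
  alist <- intersect(analytes(), names(proteins))
  dat <- dplyr::inner_join(proteins, subjects, by = "subject_id")
  dat$sex <- as.integer(dat$sex == "male")
  rows <- list()
  for (a in alist) {
    for (cv in covs) {
      d <- dat[complete.cases(dat[c(a, cv)]), c(a, cv)]
      if (nrow(d) < 10) stop("fewer than 10 complete rows for ", a, " ~ ", cv)
      if (sd(d[[cv]]) == 0) {
        warning("constant covariate '", cv, "'; skipping for ", a)
        next
      }
      fit <- lm(as.formula(paste(a, "~", cv)), data = d)
      sm <- summary(fit)
      forced <- cv %in% (force[[a]] %||% character())
      rows[[length(rows) + 1L]] <- tibble::tibble(
        analyte = a, covariate = cv,
        estimate = unname(coef(fit)[2]),
        std_error = sm$coefficients[2, 2],
        adjusted_r2 = sm$adj.r.squared,
        f_statistic = unname(sm$fstatistic[1]),
        p_value = sm$coefficients[2, 4],
        n_used = nrow(d),
        selected = sm$coefficients[2, 4] < alpha || forced,
        forced = forced
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Extract per-analyte covariate adjustment sets
#'
#' @param screen Output of [screen_covariates()].
#' @return Named list, analyte -> character vector of selected covariates.
#' @export
covariate_sets <- function(screen) {
  sel <- screen[screen$selected, , drop = FALSE]
  out <- split(sel$covariate, sel$analyte)
  # analytes with no selected covariate get an empty set
  for (a in setdiff(unique(screen$analyte), names(out))) out[[a]] <- character()
  out
}

#' Pairwise Pearson correlations between analytes
#'
#' Symmetric matrix of Pearson r with two-sided p-values from the t transform
#' of r, returned in tidy long form (diagonal r = 1, p = NA). Analytes with
#' zero variance are flagged undefined (`r = NA`).
#'
#' @param proteins Log2 panel.
#' @return Tibble: analyte_x, analyte_y, r, p_value, n.
#' @export
protein_correlations <- function(proteins) {
  alist <- intersect(analytes(), names(proteins))
  grid <- tidyr::expand_grid(analyte_x = alist, analyte_y = alist)
  purrr::pmap_dfr(grid, function(analyte_x, analyte_y) {
    x <- proteins[[analyte_x]]
    y <- proteins[[analyte_y]]
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < 3) stop("fewer than 3 complete pairs for ",
                    analyte_x, " vs ", analyte_y)
    if (analyte_x == analyte_y) {
      return(tibble::tibble(analyte_x, analyte_y, r = 1, p_value = NA_real_,
                            n = n))
    }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warning("zero-variance analyte in pair ", analyte_x, "/", analyte_y)
      return(tibble::tibble(analyte_x, analyte_y, r = NA_real_,
                            p_value = NA_real_, n = n))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(analyte_x, analyte_y, r = unname(ct$estimate),
                   p_value = ct$p.value, n = n)
  })
}

#' Correlation tibble to matrix
#'
#' @param corr Output of [protein_correlations()].
#' @param value Column to spread (`"r"` or `"p_value"`).
#' @return Square matrix with analyte dimnames.
#' @export
correlation_matrix <- function(corr, value = "r") {
  wide <- tidyr::pivot_wider(corr[c("analyte_x", "analyte_y", value)],
                             names_from = "analyte_y",
                             values_from = dplyr::all_of(value))
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$analyte_x
  m
}
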
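# Case-control and subgroup protein models: linear, binary/multinomial
# logistic, likelihood-ratio tests, pairwise covariate-adjusted contrasts,
# and survey-score regressions.
#
# All fitting goes through assemble_model_data(), which joins the panel to
# the cohort by subject_id, codes sex as a male indicator, and keeps only
# rows complete for the variables a given model uses -- so full and reduced
# fits of the same model family share identical rows.

assemble_model_data <- function(proteins, subjects, analyte, covariates,
                                extra = NULL) {
  stopifnot(analyte %in% names(proteins))
  bad <- setdiff(covariates, c("age", "sex", "bmi"))
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  dat <- dplyr::inner_join(proteins[c("subject_id", analyte)], subjects,
                           by = "subject_id")
  if (!is.null(extra)) dat <- dplyr::inner_join(dat, extra, by = "subject_id")
  dat$sex <- as.integer(dat$sex == "male")
  vars <- c(analyte, covariates,
            if (!is.null(extra)) setdiff(names(extra), "subject_id"))
  dat <- dat[complete.cases(dat[vars]), , drop = FALSE]
  # drop covariates constant in the analysed rows (e.g. all-female strata)
  dropped <- covariates[vapply(covariates, function(v) sd(dat[[v]]) == 0,
                               logical(1))]
  if (length(dropped)) {
    warning("covariate(s) constant in sample, dropped: ",
            paste(dropped, collapse = ", "))
  }
  attr(dat, "covariates") <- setdiff(covariates, dropped)
  dat
}

new_cc_fit <- function(model, type, outcome, analyte, covariates, data,
                       converged = TRUE, separation = FALSE,
                       reference = NULL) {
  ll <- as.numeric(logLik(model))
  structure(list(
    model = model, type = type, outcome = outcome, analyte = analyte,
    covariates = covariates, data = data,
    subject_ids = data$subject_id, n_used = nrow(data),
    log_likelihood = ll, df = attr(logLik(model), "df"),
    adjusted_r2 = if (type == "linear") summary(model)$adj.r.squared else NA_real_,
    converged = converged, separation = separation, reference = reference
  ), class = "cc_fit")
}

#' @export
print.cc_fit <- function(x, ...) {
  cat(sprintf("<cc_fit> %s model: %s ~ %s (n = %d)\n", x$type, x$outcome,
              paste(c(x$analyte, x$covariates), collapse = " + "), x$n_used))
  if (!x$converged) cat("  ! not converged",
                        if (x$separation) "(separation detected)", "\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted case-control model
#'
#' @param x A `cc_fit`.
#' @param ... Unused.
#' @return Tibble of per-term estimates: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value` (plus `level` for multinomial fits, including the
#'   all-zero reference block).
#' @method tidy cc_fit
#' @export
tidy.cc_fit <- function(x, ...) {
  if (x$type == "multinomial") {
    sm <- summary(x$model)
    co <- sm$coefficients
    se <- sm$standard.errors
    if (is.null(dim(co))) {  # two-level fit collapses to a vector
      co <- matrix(co, nrow = 1, dimnames = list(sm$lev[2], names(co)))
      se <- matrix(se, nrow = 1, dimnames = list(sm$lev[2], colnames(co)))
    }
    blocks <- purrr::map_dfr(rownames(co), function(lv) {
      z <- co[lv, ] / se[lv, ]
      tibble::tibble(level = lv, term = colnames(co),
                     estimate = unname(co[lv, ]),
                     std_error = unname(se[lv, ]), statistic = unname(z),
                     p_value = 2 * pnorm(-abs(unname(z))))
    })
    ref <- tibble::tibble(level = x$reference, term = colnames(co),
                          estimate = 0, std_error = 0, statistic = NA_real_,
                          p_value = NA_real_)
    return(dplyr::bind_rows(ref, blocks))
  }
  co <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(co), estimate = unname(co[, 1]),
                 std_error = unname(co[, 2]), statistic = unname(co[, 3]),
                 p_value = unname(co[, 4]))
}

#' Model-level summary of a fitted case-control model
#'
#' @param x A `cc_fit`.
#' @param ... Unused.
#' @return One-row tibble: type, outcome, analyte, n_used, log_likelihood,
#'   df, adjusted_r2, converged, separation.
#' @method glance cc_fit
#' @export
glance.cc_fit <- function(x, ...) {
  tibble::tibble(type = x$type, outcome = x$outcome, analyte = x$analyte,
                 n_used = x$n_used, log_likelihood = x$log_likelihood,
                 df = x$df, adjusted_r2 = x$adjusted_r2,
                 converged = x$converged, separation = x$separation)
}

#' Case-control linear model for one analyte
#'
#' OLS of the log2 analyte on illness group plus covariates. Group is coded
#' so the reported `groupNF` effect equals the covariate-adjusted
#' mean(control) minus mean(case): negative values indicate higher levels in
#' cases.
#'
#' @param proteins Log2 panel.
#' @param subjects Subject tibble.
#' @param analyte Analyte name.
#' @param covariates Character vector from `c("age", "sex", "bmi")`.
#' @return A `cc_fit`.
#' @export
case_control_linear <- function(proteins, subjects, analyte,
                                covariates = character()) {
  dat <- assemble_model_data(proteins, subjects, analyte, covariates)
  if (length(unique(dat$group)) < 2) stop("both groups must be represented")
  covariates <- attr(dat, "covariates")
  rhs <- paste(c("group", covariates), collapse = " + ")
  fit <- lm(as.formula(paste(analyte, "~", rhs)), data = dat)
  if (any(is.na(coef(fit)))) {
    stop("collinear terms: ", paste(names(coef(fit))[is.na(coef(fit))],
                                    collapse = ", "))
  }
  new_cc_fit(fit, "linear", outcome = analyte, analyte = analyte,
             covariates = covariates, data = dat)
}

#' Case-control logistic model for one analyte
#'
#' Maximum-likelihood logistic regression (IRLS, tolerance 1e-8, at most 100
#' iterations) of case status on the log2 analyte plus covariates. A positive
#' protein coefficient means higher levels raise the odds of being a case.
#' Perfect separation is flagged (`converged = FALSE`, `separation = TRUE`)
#' rather than silently reported.
#'
#' @inheritParams case_control_linear
#' @return A `cc_fit`.
#' @export
case_control_logistic <- function(proteins, subjects, analyte,
                                  covariates = character()) {
  dat <- assemble_model_data(proteins, subjects, analyte, covariates)
  if (length(unique(dat$group)) < 2) stop("both outcome classes must be present")
  covariates <- attr(dat, "covariates")
  dat$case <- as.integer(dat$group == "MECFS")
  rhs <- paste(c(analyte, covariates), collapse = " + ")
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(as.formula(paste("case ~", rhs)), data = dat, family = binomial(),
        control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # complete separation drives the deviance to zero without necessarily
  # tripping glm's own fitted-probability warning
  separation <- separation || fit$deviance < 1e-6
  new_cc_fit(fit, "logistic", outcome = "case", analyte = analyte,
             covariates = covariates, data = dat,
             converged = fit$converged && !separation, separation = separation)
}

#' Multinomial logistic model over genotype-defined subgroups
#'
#' Fits a multinomial logit of the 4-level subgroup label on the log2 analyte
#' plus covariates, with the stated reference level (all-zero coefficient
#' block). Empty levels are dropped with a warning.
#'
#' @inheritParams case_control_linear
#' @param labels Tibble (`subject_id`, `subgroup`) from [assign_subgroups()],
#'   or any categorical labelling.
#' @param reference Reference category (default `"NFhet"`).
#' @return A `cc_fit` of type `"multinomial"`.
#' @export
multinomial_subgroups <- function(proteins, labels, subjects, analyte,
                                  covariates = character(),
                                  reference = "NFhet") {
  lab <- labels[c("subject_id", "subgroup")]
  lab$subgroup <- as.character(lab$subgroup)
  dat <- assemble_model_data(proteins, subjects, analyte, covariates,
                             extra = lab)
  covariates <- attr(dat, "covariates")
  present <- unique(dat$subgroup)
  if (length(present) < 2) stop("need at least 2 subgroup levels")
  if (!reference %in% present) stop("reference level '", reference,
                                    "' not present")
  all_levels <- if (is.factor(labels$subgroup)) levels(labels$subgroup) else
    sort(unique(lab$subgroup))
  empty <- setdiff(all_levels, present)
  if (length(empty)) warning("empty level(s) dropped: ",
                             paste(empty, collapse = ", "))
  dat$subgroup <- stats::relevel(factor(dat$subgroup, levels = present),
                                 ref = reference)
  rhs <- paste(c(analyte, covariates), collapse = " + ")
  fit <- nnet::multinom(as.formula(paste("subgroup ~", rhs)), data = dat,
                        trace = FALSE, maxit = 500, reltol = 1e-12)
  out <- new_cc_fit(fit, "multinomial", outcome = "subgroup",
                    analyte = analyte, covariates = covariates, data = dat,
                    converged = fit$convergence == 0, reference = reference)
  out$dropped_levels <- empty
  out
}

#' Likelihood-ratio test of nested fits
#'
#' `statistic = -2 * (logLik(reduced) - logLik(full))`, chi-square with
#' degrees of freedom equal to the parameter-count difference. The reduced
#' model's terms must be a subset of the full model's and both fits must use
#' exactly the same rows.
#'
#' @param full,reduced `cc_fit` objects of the same family.
#' @return One-row tibble: statistic, df, p_value.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "cc_fit"), inherits(reduced, "cc_fit"))
  if (full$type != reduced$type) stop("models are of different families")
  if (!setequal(full$subject_ids, reduced$subject_ids) ||
      full$n_used != reduced$n_used) {
    stop("full and reduced models were fitted on different rows")
  }
  full_terms <- c(full$analyte, full$covariates)
  red_terms <- c(reduced$analyte, reduced$covariates)
  if (!all(red_terms %in% full_terms)) {
    stop("models are not nested: reduced has terms outside the full model")
  }
  stat <- -2 * (reduced$log_likelihood - full$log_likelihood)
  if (stat < -1e-8) stop("negative LRT statistic; models are not nested")
  stat <- max(stat, 0)
  df <- full$df - reduced$df
  if (df < 0) stop("reduced model has more parameters than the full model")
  # df = 0 (full compared against itself) degenerates to statistic 0, p 1
  tibble::tibble(statistic = stat, df = df,
                 p_value = if (df == 0) 1 else
                   pchisq(stat, df, lower.tail = FALSE))
}

# Intercept-only / covariates-only companion fits for LRTs.

#' Reduced (covariates-only) companion fit
#'
#' Refits a model's family with the analyte term removed, on exactly the rows
#' the full fit used, for [lrt()].
#'
#' @param fit A `cc_fit`.
#' @return A `cc_fit` without the analyte term.
#' @export
reduced_fit <- function(fit) {
  dat <- fit$data
  rhs <- if (length(fit$covariates)) paste(fit$covariates, collapse = " + ")
         else "1"
  m <- switch(fit$type,
    linear = lm(as.formula(paste(fit$outcome, "~ group +", rhs)), data = dat),
    logistic = glm(as.formula(paste("case ~", rhs)), data = dat,
                   family = binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    multinomial = nnet::multinom(as.formula(paste("subgroup ~", rhs)),
                                 data = dat, trace = FALSE, maxit = 500,
                                 reltol = 1e-12),
    stop("unsupported type")
  )
  out <- new_cc_fit(m, fit$type, outcome = fit$outcome, analyte = NULL,
                    covariates = fit$covariates, data = dat,
                    reference = fit$reference)
  out
}

#' Linear model of one analyte over 4-level subgroups
#'
#' OLS of the log2 analyte on the subgroup factor plus covariates, the basis
#' for [pairwise_contrasts()].
#'
#' @inheritParams multinomial_subgroups
#' @return A `cc_fit` of type `"linear"` with a `subgroup` factor term.
#' @export
subgroup_linear <- function(proteins, labels, subjects, analyte,
                            covariates = character(), reference = "NFhet") {
  lab <- labels[c("subject_id", "subgroup")]
  lab$subgroup <- as.character(lab$subgroup)
  dat <- assemble_model_data(proteins, subjects, analyte, covariates,
                             extra = lab)
  covariates <- attr(dat, "covariates")
  present <- sort(unique(dat$subgroup))
  ref <- if (reference %in% present) reference else present[1]
  dat$subgroup <- stats::relevel(factor(dat$subgroup, levels = present),
                                 ref = ref)
  rhs <- paste(c("subgroup", covariates), collapse = " + ")
  fit <- lm(as.formula(paste(analyte, "~", rhs)), data = dat)
  new_cc_fit(fit, "linear", outcome = analyte, analyte = analyte,
             covariates = covariates, data = dat, reference = ref)
}

#' Pairwise covariate-adjusted group contrasts
#'
#' Estimated marginal means at the covariate sample means (categorical
#' covariates at observed proportions) with all pairwise differences and
#' t-based p-values. No multiplicity adjustment is applied by default.
#'
#' @param fit A linear `cc_fit` whose model contains a categorical group term
#'   (`group` or `subgroup`).
#' @param adjust Multiplicity adjustment passed to emmeans (default
#'   `"none"`).
#' @return Tibble: contrast, estimate, std_error, df, statistic, p_value.
#'   Empty when the model has a single group level.
#' @export
pairwise_contrasts <- function(fit, adjust = "none") {
  stopifnot(inherits(fit, "cc_fit"), fit$type == "linear")
  term <- intersect(c("subgroup", "group"), names(fit$data))[1]
  if (is.na(term)) stop("fit has no categorical group term")
  if (length(unique(fit$data[[term]])) < 2) {
    return(tibble::tibble(contrast = character(), estimate = numeric(),
                          std_error = numeric(), df = numeric(),
                          statistic = numeric(), p_value = numeric()))
  }
  emm <- emmeans::emmeans(fit$model, specs = term, data = fit$data)
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = adjust))
  out <- tibble::tibble(contrast = as.character(prs$contrast),
                        estimate = prs$estimate, std_error = prs$SE,
                        df = prs$df, statistic = prs$t.ratio,
                        p_value = prs$p.value)
  # canonical orientation: "A - B" with A < B alphabetically, so output does
  # not depend on which level happened to be the model's reference
  parts <- stringr::str_split_fixed(out$contrast, stringr::fixed(" - "), 2)
  flip <- parts[, 1] > parts[, 2]
  out$contrast[flip] <- paste(parts[flip, 2], "-", parts[flip, 1])
  out$estimate[flip] <- -out$estimate[flip]
  out$statistic[flip] <- -out$statistic[flip]
  out[order(out$contrast), ]
}

#' Association of one analyte with one continuous survey score
#'
#' OLS of the log2 analyte on a continuous survey metric plus covariates.
#' The sign convention follows the model: a negative coefficient on an SF-36
#' scale means higher (better) functioning goes with lower protein levels.
#'
#' @inheritParams case_control_linear
#' @param surveys Survey tibble (see [read_surveys()]).
#' @param score Survey score column name.
#' @return A `cc_fit`.
#' @export
survey_association <- function(proteins, surveys, subjects, analyte, score,
                               covariates = character()) {
  stopifnot(score %in% names(surveys))
  dat <- assemble_model_data(proteins, subjects, analyte, covariates,
                             extra = surveys[c("subject_id", score)])
  covariates <- attr(dat, "covariates")
  if (nrow(dat) < 10) stop("fewer than 10 complete rows")
  if (sd(dat[[score]]) == 0) stop("constant score: ", score)
  rhs <- paste(c(score, covariates), collapse = " + ")
  fit <- lm(as.formula(paste(analyte, "~", rhs)), data = dat)
  out <- new_cc_fit(fit, "linear", outcome = analyte, analyte = analyte,
                    covariates = covariates, data = dat)
  out$score <- score
  out
}

#' All analyte-by-score survey associations as a tidy long table
#'
#' Runs [survey_association()] over every (analyte, score) pair, emitting the
#' long table a heatmap renders directly.
#'
#' @inheritParams survey_association
#' @param covariate_map Named list analyte -> covariates (from
#'   [covariate_sets()]); analytes not named get no adjustment.
#' @param scores Score columns to use (default: all non-id survey columns).
#' @param analyte_set Analytes to use (default: all panel analytes present).
#' @return Tibble: analyte, score, estimate, std_error, p_value, r_squared,
#'   n_used.
#' @export
survey_association_all <- function(proteins, surveys, subjects,
                                   covariate_map = list(),
                                   scores = NULL, analyte_set = NULL) {
  scores <- scores %||% setdiff(names(surveys), "subject_id")
  analyte_set <- analyte_set %||% intersect(analytes(), names(proteins))
  grid <- tidyr::expand_grid(analyte = analyte_set, score = scores)
  purrr::pmap_dfr(grid, function(analyte, score) {
    fit <- survey_association(proteins, surveys, subjects, analyte, score,
                              covariates = covariate_map[[analyte]] %||%
                                character())
    td <- tidy(fit)
    row <- td[td$term == score, ]
    tibble::tibble(analyte = analyte, score = score, estimate = row$estimate,
                   std_error = row$std_error, p_value = row$p_value,
                   r_squared = summary(fit$model)$r.squared,
                   n_used = fit$n_used)
  })
}
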
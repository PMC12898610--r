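# Synthetic genotype-phenotype cohort generator.
#
# Generates case-control cohorts with the statistical structure the pipeline
# assumes -- Hardy-Weinberg genotypes with optional LD (Gaussian copula on
# latent dosing normals), additive pQTL effects on log2 protein levels,
# demographic covariate effects, fixed-margin case-control design with
# group-level protein shifts, one shared latent factor driving inter-protein
# correlation, and survey scores linked to protein levels -- plus the planted
# ground truth for recovery testing.

#' Build a simulation configuration
#'
#' All effect sizes are in log2-concentration units. The case-control design
#' is fixed-margin: group labels are assigned first and protein shifts are
#' conditional on group. `disease_or` skews per-group minor-allele
#' frequencies so that risk genotypes are enriched in cases, and
#' `het_interaction` adds an extra case-control shift confined to
#' heterozygous carriers of a two-marker pair (centred so the marginal shift
#' stays at `group_shifts`).
#'
#' @param n_case,n_control Group sizes.
#' @param n_snps Total SNP count; SNPs beyond those named in `snps` are
#'   filler variants with MAF drawn uniformly from `maf_range`.
#' @param maf_range Range for filler minor-allele frequencies, within (0, 0.5].
#' @param snps Optional tibble (`rsid`, `maf`, `chrom`, `pos`, `gene`,
#'   `functional_group`, `consequence`, `major_allele`, `minor_allele`) of
#'   named variants.
#' @param ld_pairs Tibble (`rsid_a`, `rsid_b`, `r`) of target dosage
#'   correlations, |r| <= 1, achieved approximately via a Gaussian copula.
#' @param covariate_effects Tibble (`analyte`, `covariate`, `beta`):
#'   log2 units per kg/m^2 (bmi), per year (age), or male offset (sex).
#' @param pqtl_effects Tibble (`rsid`, `analyte`, `beta`) of planted additive
#'   effects per minor-allele copy.
#' @param group_shifts Named per-analyte log2 offset, case minus control.
#' @param latent_loadings Named per-analyte loading on one shared standard
#'   normal latent factor (inter-protein correlation).
#' @param noise_sd Named per-analyte residual SD (log2 units), all > 0.
#' @param control_means Named per-analyte target control mean (log2 units)
#'   used to set intercepts.
#' @param survey_links Tibble (`score`, `analyte`, `beta`) linking survey
#'   scores to centred log2 protein levels.
#' @param disease_or Tibble (`rsid`, `risk_allele`, `odds_ratio`) of
#'   SNP-disease associations realized in the generated cohort.
#' @param het_interaction Tibble (`rsid_a`, `rsid_b`, `analyte`, `delta`):
#'   extra case shift for heterozygous carriers at either marker.
#' @param female_fraction Probability a subject is female (both groups).
#' @param bmi_case_offset Additive BMI offset (kg/m^2) for cases.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_case = 50, n_control = 121, n_snps = 60,
                       maf_range = c(0.05, 0.5),
                       snps = NULL, ld_pairs = NULL,
                       covariate_effects = NULL, pqtl_effects = NULL,
                       group_shifts = NULL, latent_loadings = NULL,
                       noise_sd = NULL, control_means = NULL,
                       survey_links = NULL, disease_or = NULL,
                       het_interaction = NULL,
                       female_fraction = 0.75, bmi_case_offset = 2,
                       seed = 1L) {
  meas <- analytes(measured_only = TRUE)
  named_full <- function(x, default) {
    out <- setNames(rep(default, length(meas)), meas)
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  cfg <- list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_snps = as.integer(n_snps), maf_range = maf_range,
    snps = snps,
    ld_pairs = ld_pairs %||% tibble::tibble(rsid_a = character(),
                                            rsid_b = character(), r = numeric()),
    covariate_effects = covariate_effects %||%
      tibble::tibble(analyte = character(), covariate = character(),
                     beta = numeric()),
    pqtl_effects = pqtl_effects %||%
      tibble::tibble(rsid = character(), analyte = character(), beta = numeric()),
    group_shifts = named_full(group_shifts, 0),
    latent_loadings = named_full(latent_loadings, 0),
    noise_sd = named_full(noise_sd, 0.3),
    control_means = named_full(control_means, 0),
    survey_links = survey_links %||%
      tibble::tibble(score = character(), analyte = character(), beta = numeric()),
    disease_or = disease_or %||%
      tibble::tibble(rsid = character(), risk_allele = character(),
                     odds_ratio = numeric()),
    het_interaction = het_interaction %||%
      tibble::tibble(rsid_a = character(), rsid_b = character(),
                     analyte = character(), delta = numeric()),
    female_fraction = female_fraction,
    bmi_case_offset = bmi_case_offset,
    seed = as.integer(seed)
  )
  stopifnot(all(cfg$noise_sd > 0),
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
            all(abs(cfg$ld_pairs$r) <= 1))
  class(cfg) <- "sim_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default study-condition configuration
#'
#' Returns the generator configuration emulating the study conditions the
#' pipeline targets: 50 cases and 121 controls; demographic effects on log2
#' protein levels (e.g. BMI slope 0.169 for CRP and 0.033 for C3, age slope
#' 0.011 for Factor D, male offsets for CRP and Factor B); case-control
#' shifts per analyte (e.g. C3 +0.215, Bb -0.022 log2 units); planted
#' additive pQTL effects on the focal complement variants (e.g. -0.36 on Bb
#' for the C2 missense variant, -0.19 on Bb for the CFH V62I variant); an LD
#' pair between the paralogous C2/CFB variants; per-SNP disease odds ratios;
#' and a heterozygote-specific extra C3/CRP/FactorH case shift at the two
#' focal markers that drives genotype-dependent discriminability.
#'
#' @param n_snps Total SNP count including 8 named focal variants.
#' @param seed Seed stored in the configuration.
#' @return A `sim_config`.
#' @export
sim_config_default <- function(n_snps = 60, seed = 1L) {
  focal <- tibble::tibble(
    rsid = c("rs9332739", "rs4151667", "rs641153", "rs800292", "rs1061170",
             "rs17611", "rs17759529", "rs6108"),
    maf = c(0.05, 0.05, 0.09, 0.24, 0.36, 0.45, 0.25, 0.30),
    chrom = c("6", "6", "6", "1", "1", "9", "2", "14"),
    pos = c(31903804L, 31913449L, 31914180L, 196642233L, 196659237L,
            123775021L, 162848755L, 94770585L),
    gene = c("C2", "CFB", "CFB", "CFH", "CFH", "C5", "DPP4", "SERPINA5"),
    functional_group = c("complement", "complement", "complement",
                         "complement", "complement", "complement",
                         "cell_surface", "metabolic"),
    consequence = c("missense", "missense", "missense", "missense",
                    "missense", "missense", "intronic", "utr3"),
    major_allele = c("G", "T", "C", "C", "T", "G", "A", "G"),
    minor_allele = c("C", "A", "T", "T", "C", "A", "G", "A")
  )
  cov_eff <- tibble::tibble(
    analyte = c("CRP", "C3", "C3a", "C5a", "FactorB", "FactorD", "FactorH",
                "CRP", "FactorB", "FactorD"),
    covariate = c(rep("bmi", 7), "sex", "sex", "age"),
    beta = c(0.169, 0.033, 0.036, 0.025, 0.026, 0.020, 0.023,
             -0.645, -0.159, 0.011)
  )
  pqtl <- tibble::tibble(
    rsid = c("rs9332739", "rs9332739", "rs800292", "rs641153", "rs17611",
             "rs17759529", "rs6108"),
    analyte = c("Bb", "FactorB", "Bb", "FactorB", "C5a", "C3", "C3"),
    beta = c(-0.36, -0.23, -0.19, 0.24, -0.50, 0.15, 0.07)
  )
  shifts <- c(CRP = 1.087, C3 = 0.215, C3a = 0.16, C5a = 0.094, Bb = -0.022,
              FactorB = 0.143, FactorD = 0.094, FactorH = 0.128,
              SC5b9 = 0.039)
  # total SDs observed in comparable cohorts; residual SD subtracts the
  # latent-factor and demographic-covariate contributions
  total_sd <- c(CRP = 1.71, C3 = 0.31, C3a = 0.58, C5a = 0.40, Bb = 0.45,
                FactorB = 0.35, FactorD = 0.29, FactorH = 0.29, SC5b9 = 0.60)
  loadings <- c(CRP = 0.50, C3 = 0.15, C3a = 0.30, C5a = 0.15, Bb = 0.05,
                FactorB = 0.15, FactorD = 0.08, FactorH = 0.15, SC5b9 = 0.20)
  covvar <- setNames(numeric(length(total_sd)), names(total_sd))
  for (i in seq_len(nrow(cov_eff))) {
    v <- switch(cov_eff$covariate[i], bmi = 25, age = 100,
                sex = 0.25 * 0.75)
    covvar[cov_eff$analyte[i]] <- covvar[cov_eff$analyte[i]] +
      v * cov_eff$beta[i]^2
  }
  noise <- sqrt(pmax(total_sd^2 - loadings[names(total_sd)]^2 -
                       covvar[names(total_sd)], 0.04))
  ctrl_means <- c(CRP = 0.318, C3 = 0.324, C3a = 9.90, C5a = 4.218,
                  Bb = -0.077, FactorB = 8.242, FactorD = 1.233,
                  FactorH = 8.299, SC5b9 = 7.113)
  links <- tibble::tibble(
    score = c("cdc_si", "cdc_si", "mfi_gf", "sf36_pf", "sf36_pf", "sf36_gh"),
    analyte = c("C3", "CRP", "C3", "C3", "CRP", "C3"),
    beta = c(8, 1.5, 3, -12, -1.5, -10)
  )
  dis <- tibble::tibble(
    rsid = c("rs9332739", "rs4151667", "rs800292", "rs641153", "rs1061170",
             "rs6108"),
    risk_allele = c("minor", "minor", "minor", "major", "major", "minor"),
    odds_ratio = c(1.8, 1.8, 1.6, 1.5, 1.4, 1.3)
  )
  het_int <- tibble::tibble(
    rsid_a = rep("rs9332739", 3), rsid_b = rep("rs800292", 3),
    analyte = c("C3", "CRP", "FactorH"),
    delta = c(0.35, 1.2, 0.25)
  )
  sim_config(
    n_case = 50, n_control = 121, n_snps = n_snps,
    snps = focal,
    ld_pairs = tibble::tibble(rsid_a = "rs9332739", rsid_b = "rs4151667",
                              r = 0.95),
    covariate_effects = cov_eff, pqtl_effects = pqtl,
    group_shifts = shifts, latent_loadings = loadings, noise_sd = noise,
    control_means = ctrl_means, survey_links = links, disease_or = dis,
    het_interaction = het_int, seed = seed
  )
}

# Dosage correlation implied by a Gaussian copula with latent correlation r:
# under HWE the dosage is a sum of two threshold indicators of the latent
# normal, so each covariance cell is a bivariate-normal upper-tail rectangle.
copula_dosage_r <- function(r_latent, p1, p2) {
  a <- qnorm(c((1 - p1)^2, 1 - p1^2))
  b <- qnorm(c((1 - p2)^2, 1 - p2^2))
  cv <- 0
  for (aj in a) for (bk in b) {
    joint <- mvtnorm::pmvnorm(lower = c(aj, bk), upper = c(Inf, Inf),
                              corr = matrix(c(1, r_latent, r_latent, 1), 2))
    cv <- cv + as.numeric(joint) - (1 - pnorm(aj)) * (1 - pnorm(bk))
  }
  cv / sqrt(2 * p1 * (1 - p1) * 2 * p2 * (1 - p2))
}

# Invert copula_dosage_r by bisection; warns and returns the boundary when
# the requested dosage correlation is infeasible for the given MAFs.
latent_r_for_dosage_r <- function(target, p1, p2, tol = 1e-4) {
  if (target == 0) return(0)
  bound <- 0.9999 * sign(target)
  reach <- copula_dosage_r(bound, p1, p2)
  if (abs(reach) < abs(target)) {
    warning(sprintf(
      "requested LD r = %.3f infeasible for MAFs %.3f/%.3f (max |r| = %.3f); ",
      target, p1, p2, abs(reach)), "using best effort")
    return(bound)
  }
  lo <- 0
  hi <- bound
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (abs(copula_dosage_r(mid, p1, p2)) < abs(target)) lo <- mid else hi <- mid
    if (abs(hi - lo) < tol) break
  }
  (lo + hi) / 2
}

rtruncnorm1 <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  while (any(x <= lower)) {
    idx <- x <= lower
    x[idx] <- rnorm(sum(idx), mean, sd)
  }
  x
}

#' Simulate a cohort under a configuration
#'
#' Identical `config` and `seed` give bit-identical output. Genotypes are
#' drawn under Hardy-Weinberg at each SNP's (group-adjusted) minor-allele
#' frequency; LD pairs are induced by correlating the latent uniform draws
#' with a Gaussian copula, which achieves the requested dosage correlation
#' approximately (the discretisation to 0/1/2 attenuates |r| slightly).
#'
#' @param config A `sim_config`.
#' @param seed Optional override of `config$seed`.
#' @return List of class `sim_cohort`: `subjects`, `dosages`, `snps`,
#'   `proteins_raw`, `surveys`, `disease`, `truth`, `config`.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% config$seed)
  n <- config$n_case + config$n_control
  meas <- analytes(measured_only = TRUE)

  subjects <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = factor(rep(c("MECFS", "NF"), c(config$n_case, config$n_control)),
                   levels = c("MECFS", "NF")),
    sex = ifelse(runif(n) < config$female_fraction, "female", "male"),
    age = round(rtruncnorm1(n, 50, 10, 18), 1)
  )
  case <- as.integer(subjects$group == "MECFS")
  subjects$bmi <- round(rtruncnorm1(n, 27, 5, 15) +
                          config$bmi_case_offset * case, 1)

  # --- SNP table -----------------------------------------------------------
  snps <- config$snps %||%
    tibble::tibble(rsid = character(), maf = numeric(), chrom = character(),
                   pos = integer(), gene = character(),
                   functional_group = character(), consequence = character(),
                   major_allele = character(), minor_allele = character())
  n_fill <- config$n_snps - nrow(snps)
  if (n_fill < 0) stop("n_snps smaller than the number of named SNPs")
  if (n_fill > 0) {
    fill <- tibble::tibble(
      rsid = sprintf("rsSIM%04d", seq_len(n_fill)),
      maf = runif(n_fill, config$maf_range[1], config$maf_range[2]),
      chrom = as.character(sample(1:22, n_fill, replace = TRUE)),
      pos = as.integer(sample.int(2.4e8, n_fill)),
      gene = sprintf("GENE%04d", seq_len(n_fill)),
      functional_group = sample(functional_groups(), n_fill, replace = TRUE),
      consequence = sample(c("intronic", "missense", "utr3", "synonymous"),
                           n_fill, replace = TRUE),
      major_allele = sample(c("A", "C", "G", "T"), n_fill, replace = TRUE),
      minor_allele = sample(c("A", "C", "G", "T"), n_fill, replace = TRUE)
    )
    snps <- dplyr::bind_rows(snps, fill)
  }

  # --- genotypes: copula-correlated latents, HWE dosages -------------------
  bad <- setdiff(c(config$ld_pairs$rsid_a, config$ld_pairs$rsid_b), snps$rsid)
  if (length(bad)) stop("ld pair references unknown SNP(s): ",
                        paste(bad, collapse = ", "))
  m <- nrow(snps)
  R <- diag(m)
  if (nrow(config$ld_pairs)) {
    ia <- match(config$ld_pairs$rsid_a, snps$rsid)
    ib <- match(config$ld_pairs$rsid_b, snps$rsid)
    # calibrate the latent correlation so the discretised dosages reach the
    # requested r (the copula-to-genotype step attenuates correlation)
    r_lat <- vapply(seq_len(nrow(config$ld_pairs)), function(k) {
      latent_r_for_dosage_r(config$ld_pairs$r[k], snps$maf[ia[k]],
                            snps$maf[ib[k]])
    }, numeric(1))
    R[cbind(ia, ib)] <- r_lat
    R[cbind(ib, ia)] <- r_lat
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < 1e-8) {
      warning("requested LD structure not positive definite; using nearest ",
              "feasible correlations (best effort)")
      vals <- pmax(ev$values, 1e-6)
      R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
      R <- stats::cov2cor(R)
    }
  }
  Z <- matrix(rnorm(n * m), n, m) %*% chol(R)
  U <- pnorm(Z)

  # per-group minor allele frequency implied by the disease odds ratios
  p_ctrl <- snps$maf
  p_case <- p_ctrl
  if (nrow(config$disease_or)) {
    idx <- match(config$disease_or$rsid, snps$rsid)
    if (anyNA(idx)) stop("disease_or references unknown SNP(s)")
    or_minor <- ifelse(config$disease_or$risk_allele == "minor",
                       config$disease_or$odds_ratio,
                       1 / config$disease_or$odds_ratio)
    p0 <- p_ctrl[idx]
    p_case[idx] <- p0 * or_minor / (1 - p0 + p0 * or_minor)
  }
  dos <- matrix(0L, n, m, dimnames = list(NULL, snps$rsid))
  for (j in seq_len(m)) {
    pj <- ifelse(case == 1L, p_case[j], p_ctrl[j])
    dos[, j] <- qbinom(U[, j], 2L, pj)
  }

  # --- proteins ------------------------------------------------------------
  sexm <- as.integer(subjects$sex == "male")
  latent <- rnorm(n)
  cov_wide <- tidyr::pivot_wider(config$covariate_effects,
                                 names_from = "covariate",
                                 values_from = "beta")
  getcov <- function(analyte, covname) {
    if (!covname %in% names(cov_wide)) return(0)
    v <- cov_wide[[covname]][match(analyte, cov_wide$analyte)]
    ifelse(is.na(v), 0, v)
  }
  het_any <- rep(FALSE, n)
  if (nrow(config$het_interaction)) {
    mk <- unique(c(config$het_interaction$rsid_a, config$het_interaction$rsid_b))
    if (!all(mk %in% snps$rsid)) stop("het_interaction references unknown SNP(s)")
    het_any <- apply(dos[, mk, drop = FALSE] == 1L, 1, any)
    # expected het probability under HWE in cases, used to centre the
    # interaction so the marginal case-control shift stays at group_shifts
    p_het_case <- 1 - prod(1 - 2 * p_case[match(mk, snps$rsid)] *
                             (1 - p_case[match(mk, snps$rsid)]))
  }

  log2p <- matrix(0, n, length(meas), dimnames = list(NULL, meas))
  intercepts <- setNames(numeric(length(meas)), meas)
  for (a in meas) {
    eff <- rep(0, n)
    eff <- eff + getcov(a, "bmi") * subjects$bmi +
      getcov(a, "sex") * sexm + getcov(a, "age") * subjects$age
    pq <- config$pqtl_effects[config$pqtl_effects$analyte == a, , drop = FALSE]
    if (nrow(pq)) {
      if (!all(pq$rsid %in% snps$rsid)) stop("pqtl effect on unknown SNP")
      for (i in seq_len(nrow(pq))) {
        eff <- eff + pq$beta[i] * dos[, pq$rsid[i]]
      }
    }
    eff <- eff + config$group_shifts[[a]] * case
    hi <- config$het_interaction[config$het_interaction$analyte == a, ,
                                 drop = FALSE]
    if (nrow(hi)) {
      delta <- sum(hi$delta)
      eff <- eff + delta * case * (het_any - p_het_case)
    }
    eff <- eff + config$latent_loadings[[a]] * latent +
      rnorm(n, 0, config$noise_sd[[a]])
    # anchor the control mean at its target level
    base_ctrl <- mean(getcov(a, "bmi") * 27 + getcov(a, "sex") * 0.25 +
                        getcov(a, "age") * 50)
    pq_mean <- if (nrow(pq)) sum(pq$beta * 2 * p_ctrl[match(pq$rsid, snps$rsid)]) else 0
    intercepts[[a]] <- config$control_means[[a]] - base_ctrl - pq_mean
    log2p[, a] <- intercepts[[a]] + eff
  }
  proteins_raw <- dplyr::bind_cols(
    tibble::tibble(subject_id = subjects$subject_id),
    dplyr::as_tibble(as.data.frame(2^log2p))
  )

  # --- surveys -------------------------------------------------------------
  centered <- scale(log2p, center = TRUE, scale = FALSE)
  score_base <- c(cdc_si = 25, mfi_gf = 8, mfi_pf = 8, mfi_ra = 8,
                  mfi_rm = 8, mfi_mf = 8, sf36_pf = 52, sf36_rp = 52,
                  sf36_bp = 52, sf36_gh = 52, sf36_v = 52, sf36_sf = 52,
                  sf36_re = 52, sf36_mh = 52)
  score_case <- c(cdc_si = 20, mfi_gf = 6, mfi_pf = 6, mfi_ra = 5, mfi_rm = 4,
                  mfi_mf = 5, sf36_pf = -18, sf36_rp = -16, sf36_bp = -12,
                  sf36_gh = -15, sf36_v = -18, sf36_sf = -14, sf36_re = -10,
                  sf36_mh = -8)
  score_sd <- c(cdc_si = 8, mfi_gf = 2.5, mfi_pf = 2.5, mfi_ra = 2.5,
                mfi_rm = 2.5, mfi_mf = 2.5, sf36_pf = 8, sf36_rp = 8,
                sf36_bp = 8, sf36_gh = 8, sf36_v = 8, sf36_sf = 8,
                sf36_re = 8, sf36_mh = 8)
  surveys <- tibble::tibble(subject_id = subjects$subject_id)
  for (s in names(score_base)) {
    val <- score_base[[s]] + score_case[[s]] * case + rnorm(n, 0, score_sd[[s]])
    lk <- config$survey_links[config$survey_links$score == s, , drop = FALSE]
    for (i in seq_len(nrow(lk))) {
      val <- val + lk$beta[i] * centered[, lk$analyte[i]]
    }
    if (startsWith(s, "mfi_")) val <- pmin(pmax(round(val), 4), 20)
    surveys[[s]] <- val
  }

  disease <- config$disease_or
  if (nrow(disease)) {
    idx <- match(disease$rsid, snps$rsid)
    disease$risk_nt <- ifelse(disease$risk_allele == "minor",
                              snps$minor_allele[idx], snps$major_allele[idx])
  }

  structure(list(
    subjects = subjects,
    dosages = dplyr::bind_cols(tibble::tibble(subject_id = subjects$subject_id),
                               dplyr::as_tibble(as.data.frame(dos))),
    snps = dplyr::mutate(snps, maf = pmin(.data$maf, 0.5)),
    proteins_raw = proteins_raw,
    surveys = surveys,
    disease = disease,
    truth = list(pqtl_effects = config$pqtl_effects,
                 group_shifts = config$group_shifts,
                 covariate_effects = config$covariate_effects,
                 het_interaction = config$het_interaction,
                 intercepts = intercepts),
    config = config
  ), class = "sim_cohort")
}

#' Write a simulated cohort as pipeline input files
#'
#' Emits the five input files in the formats the readers expect, plus the
#' planted ground truth.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    subjects = file.path(dir, "subjects.csv"),
    proteins = file.path(dir, "proteins_raw.csv"),
    surveys = file.path(dir, "surveys.csv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    annotation = file.path(dir, "snp_annotation.tsv"),
    disease = file.path(dir, "disease_associations.tsv"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  readr::write_csv(sim$subjects, paths["subjects"])
  readr::write_csv(sim$proteins_raw, paths["proteins"])
  readr::write_csv(sim$surveys, paths["surveys"])
  readr::write_tsv(sim$dosages, paths["genotypes"])
  readr::write_tsv(sim$snps, paths["annotation"])
  readr::write_tsv(sim$disease, paths["disease"])
  truth_tab <- dplyr::bind_rows(
    dplyr::mutate(sim$truth$pqtl_effects, kind = "pqtl",
                  unit = "log2 per minor allele"),
    tibble::tibble(rsid = NA_character_,
                   analyte = names(sim$truth$group_shifts),
                   beta = unname(sim$truth$group_shifts),
                   kind = "group_shift", unit = "log2 case-control")
  )
  readr::write_tsv(truth_tab, paths["truth"])
  invisible(paths)
}
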
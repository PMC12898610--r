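test_that("AUC equals enumerated pairwise concordance on the toy example", {
  # cases {0.9, 0.4} vs controls {0.3, 0.5}: 3 of 4 pairs concordant
  mw <- auc_mann_whitney(c(0.9, 0.4), c(0.3, 0.5))
  expect_equal(mw$auc, 0.75)
  # perfect separation and constant predictor
  expect_equal(auc_mann_whitney(c(2, 3), c(0, 1))$auc, 1)
  expect_equal(auc_mann_whitney(c(1, 1), c(1, 1))$auc, 0.5)
})

test_that("AUC matches brute-force concordance with half ties, exactly", {
  set.seed(191)
  for (i in 1:40) {
    n1 <- sample(3:20, 1)
    n2 <- sample(3:20, 1)
    s1 <- sample(seq(0, 1, 0.1), n1, TRUE)  # discrete -> ties occur
    s2 <- sample(seq(0, 1, 0.1), n2, TRUE)
    conc <- 0
    for (a in s1) for (b in s2) {
      conc <- conc + (a > b) + 0.5 * (a == b)
    }
    expect_identical(auc_mann_whitney(s1, s2)$auc, conc / (n1 * n2))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(192)
  y <- rbinom(60, 1, 0.4)
  scores <- rnorm(60) + y
  mine <- auc_mann_whitney(scores[y == 1], scores[y == 0])$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(mine, theirs, tolerance = 1e-12)
})

test_that("Hanley-McNeil SE matches the closed-form arithmetic", {
  mw <- auc_mann_whitney(c(0.9, 0.8, 0.4), c(0.3, 0.5))
  a <- mw$auc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + 2 * (q1 - a^2) + 1 * (q2 - a^2)) / 6)
  expect_equal(mw$se, se, tolerance = 1e-12)
})

test_that("stratum ROC filters subjects by all genotype conditions", {
  subjects <- tiny_subjects(20, 20, seed = 201)
  set.seed(202)
  dos <- tibble::tibble(subject_id = subjects$subject_id,
                        rsA = rep(c(1, 0), 20), rsB = rep(c(0, 1, 1, 0), 10))
  prot <- tibble::tibble(
    subject_id = subjects$subject_id,
    C3 = rnorm(40, 0, 0.3) + (subjects$group == "MECFS"))
  rec <- stratum_roc(dos, prot, subjects, c(rsA = 1, rsB = 0), "C3")
  in_stratum <- dos$rsA == 1 & dos$rsB == 0
  expect_equal(rec$n_case + rec$n_control, sum(in_stratum))
  expect_equal(rec$stratum, "rsA=1;rsB=0")
  expect_error(stratum_roc(dos, prot, subjects, c(rsA = 2), "C3"),
               "stratum")
})

test_that("monotone logistic link: analyte-only ROC equals raw-value ROC", {
  subjects <- tiny_subjects(15, 15, seed = 211)
  set.seed(212)
  dos <- tibble::tibble(subject_id = subjects$subject_id, rs1 = rep(1, 30))
  prot <- tibble::tibble(
    subject_id = subjects$subject_id,
    C3 = rnorm(30, 0, 0.6) + 0.8 * (subjects$group == "MECFS"))
  rec <- stratum_roc(dos, prot, subjects, c(rs1 = 1), "C3")
  case <- subjects$group == "MECFS"
  raw <- auc_mann_whitney(prot$C3[case], prot$C3[!case])
  expect_equal(rec$auc, raw$auc, tolerance = 1e-12)
})

test_that("constant covariates inside a stratum are dropped automatically", {
  subjects <- tiny_subjects(12, 12, seed = 221)
  subjects$sex <- "female"  # all-female stratum
  set.seed(222)
  dos <- tibble::tibble(subject_id = subjects$subject_id, rs1 = rep(1, 24))
  prot <- tibble::tibble(
    subject_id = subjects$subject_id,
    C3 = rnorm(24, 0, 0.5) + 0.7 * (subjects$group == "MECFS"))
  rec <- stratum_roc(dos, prot, subjects, c(rs1 = 1), "C3",
                     covariates = c("sex", "bmi"))
  expect_equal(rec$covariates, "bmi")
})

test_that("filter rules and their monotonicity", {
  mk <- function(auc, p, n) tibble::tibble(auc = auc, p_vs_half = p,
                                           n = n)
  passes <- function(r, auc_min = 0.75, p_max = 0.05, n_min = 15) {
    r$auc > auc_min && r$p_vs_half < p_max && r$n >= n_min
  }
  expect_true(passes(mk(0.80, 0.01, 20)))
  expect_false(passes(mk(0.80, 0.01, 10)))   # size
  expect_false(passes(mk(0.70, 0.001, 30)))  # AUC
  expect_false(passes(mk(0.80, 0.10, 30)))   # p
  # screen_strata populates the same rule
  subjects <- tiny_subjects(25, 35, seed = 231)
  set.seed(232)
  dos <- tiny_dosages(subjects, mafs = c(rs1 = 0.4), seed = 233)
  prot <- tibble::tibble(
    subject_id = subjects$subject_id,
    C3 = rnorm(60, 0, 0.4) + 1.2 * (subjects$group == "MECFS"))
  scr <- screen_strata(dos, prot, subjects, "rs1", analyte_set = "C3")
  expect_equal(scr$passes_filters,
               scr$auc > 0.75 & scr$p_vs_half < 0.05 &
                 (scr$n_case + scr$n_control) >= 15)
  # tightening any threshold never adds a passing record
  tight <- screen_strata(dos, prot, subjects, "rs1", analyte_set = "C3",
                         auc_min = 0.85, p_max = 0.01, n_min = 25)
  expect_true(all(!scr$passes_filters | is.na(match(
    paste(tight$stratum, tight$analyte)[tight$passes_filters],
    paste(scr$stratum, scr$analyte)[scr$passes_filters]))) ||
      sum(tight$passes_filters) <= sum(scr$passes_filters))
})

test_that("two-marker subgroup rule over all nine genotype combinations", {
  combos <- tidyr::expand_grid(da = 0:2, db = 0:2)
  n <- nrow(combos) * 2
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:n),
    group = factor(rep(c("MECFS", "NF"), each = 9), levels = c("MECFS", "NF")),
    sex = "female", age = 40, bmi = 25)
  dos <- tibble::tibble(subject_id = subjects$subject_id,
                        mA = rep(combos$da, 2), mB = rep(combos$db, 2))
  asg <- assign_subgroups(dos, subjects, "mA", "mB")
  # het iff dosage 1 at either marker; homozygous risk (2) is NOT het
  expect_het <- rep(combos$da == 1 | combos$db == 1, 2)
  expect_equal(asg$het, expect_het)
  expect_equal(as.character(asg$subgroup),
               paste0(ifelse(subjects$group == "MECFS", "CFS", "NF"),
                      ifelse(expect_het, "het", "rem")))
  # the double-risk edge case: (0, 2) and (2, 2) land in rem
  dbl <- asg[asg$dosage_a == 0 & asg$dosage_b == 2 & asg$group == "NF", ]
  expect_equal(as.character(dbl$subgroup), "NFrem")
  # partition: every subject labelled exactly once
  expect_equal(nrow(asg), n)
  expect_equal(sum(table(asg$subgroup)), n)
})

test_that("missing marker genotypes are excluded or sent to rem", {
  subjects <- tiny_subjects(3, 3, seed = 241)
  dos <- tibble::tibble(subject_id = subjects$subject_id,
                        mA = c(1, NA, 0, 2, 1, 0),
                        mB = c(0, 0, NA, 0, 1, 0))
  excl <- assign_subgroups(dos, subjects, "mA", "mB")
  expect_equal(nrow(excl), 4)
  rem <- assign_subgroups(dos, subjects, "mA", "mB", missing = "rem")
  expect_equal(nrow(rem), 6)
  expect_false(rem$het[2])  # NA, 0 -> not het -> rem
  expect_error(assign_subgroups(dos, subjects, "mA", "nope"), "absent")
})

test_that("subgroup reanalysis bundles delegate results coherently", {
  set.seed(251)
  cfg <- sim_config_default(n_snps = 12, seed = 251)
  sim <- simulate_cohort(cfg)
  prot <- log2_transform(sim$proteins_raw)
  asg <- assign_subgroups(sim$dosages, sim$subjects, "rs9332739", "rs800292")
  out <- subgroup_reanalysis(prot, asg, sim$subjects,
                             covariate_map = list(C3 = "bmi", CRP = c("sex", "bmi")),
                             surveys = sim$surveys,
                             analyte_set = c("C3", "Bb", "CRP"))
  expect_equal(sum(out$sizes$n), nrow(asg))
  expect_setequal(unique(out$lrt$analyte), c("C3", "Bb", "CRP"))
  expect_true(all(out$lrt$statistic >= 0))
  expect_true(all(out$contrasts$contrast != ""))
  expect_setequal(unique(out$roc_het$stratum), "het-only")
  expect_true(!is.null(out$survey_het))
  # the planted heterozygote-specific C3 signal: C3 LRT strongest
  expect_equal(out$lrt$analyte[which.min(out$lrt$p_value)], "C3")
})
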
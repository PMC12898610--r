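test_that("noise-free group shift reproduces the NF-minus-case convention", {
  subjects <- tiny_subjects(10, 10)
  base <- rnorm(20, 0, 0)  # deterministic zero baseline
  prot <- tibble::tibble(
    subject_id = subjects$subject_id,
    C3 = base + ifelse(subjects$group == "MECFS", 0.215, 0))
  fit <- suppressWarnings(case_control_linear(prot, subjects, "C3"))
  td <- suppressWarnings(tidy(fit))
  # cases sit 0.215 higher, so the NF - ME/CFS difference is -0.215
  expect_equal(td$estimate[td$term == "groupNF"], -0.215, tolerance = 1e-12)
  expect_lt(td$p_value[td$term == "groupNF"], 1e-12)
})

test_that("identical groups yield a zero group effect", {
  subjects <- tiny_subjects(8, 8)
  prot <- tibble::tibble(subject_id = subjects$subject_id,
                         C3 = rep(c(0.1, 0.5, 0.9, 1.3), 4))
  fit <- case_control_linear(prot, subjects, "C3")
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "groupNF"], 0, tolerance = 1e-12)
})

test_that("linear coefficients equal the normal-equations oracle on 12 rows", {
  subjects <- tiny_subjects(6, 6, seed = 77)
  set.seed(78)
  prot <- tibble::tibble(subject_id = subjects$subject_id, C3 = rnorm(12))
  fit <- case_control_linear(prot, subjects, "C3", covariates = c("bmi", "age"))
  X <- cbind(1, as.integer(subjects$group == "NF"), subjects$bmi,
             subjects$age)
  beta <- solve(t(X) %*% X, t(X) %*% prot$C3)
  td <- tidy(fit)
  expect_equal(td$estimate, beta[, 1], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("logistic null effect stays within 4 SE of zero", {
  set.seed(99)
  subjects <- tibble::tibble(
    subject_id = as.character(1:171),
    group = factor(rep(c("MECFS", "NF"), c(50, 121)),
                   levels = c("MECFS", "NF")),
    sex = "female", age = rnorm(171, 50, 10), bmi = rnorm(171, 27, 5))
  prot <- tibble::tibble(subject_id = subjects$subject_id, C3 = rnorm(171))
  fit <- case_control_logistic(prot, subjects, "C3")
  td <- tidy(fit)
  row <- td[td$term == "C3", ]
  expect_lt(abs(row$estimate), 4 * row$std_error)
})

test_that("complete separation is flagged, not silently reported", {
  subjects <- tiny_subjects(6, 6)
  prot <- tibble::tibble(
    subject_id = subjects$subject_id,
    C3 = ifelse(subjects$group == "MECFS", 1, -1) + runif(12, 0, 0.1))
  fit <- case_control_logistic(prot, subjects, "C3")
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("logistic MLE matches a dense grid search of the likelihood", {
  set.seed(31)
  subjects <- tiny_subjects(10, 10, seed = 31)
  prot <- tibble::tibble(subject_id = subjects$subject_id,
                         C3 = rnorm(20))
  y <- as.integer(subjects$group == "MECFS")
  fit <- case_control_logistic(prot, subjects, "C3")
  td <- tidy(fit)
  b0_hat <- td$estimate[td$term == "(Intercept)"]
  b1_hat <- td$estimate[td$term == "C3"]
  # independent oracle: maximise the Bernoulli log-likelihood on a grid
  ll <- function(b0, b1) {
    eta <- b0 + b1 * prot$C3
    sum(y * eta - log1p(exp(eta)))
  }
  grid <- expand.grid(b0 = seq(b0_hat - 0.5, b0_hat + 0.5, length.out = 201),
                      b1 = seq(b1_hat - 0.5, b1_hat + 0.5, length.out = 201))
  vals <- mapply(ll, grid$b0, grid$b1)
  best <- grid[which.max(vals), ]
  expect_equal(best$b1, b1_hat, tolerance = 1e-2)
  expect_equal(best$b0, b0_hat, tolerance = 1e-2)
  # and the fitted point is a local maximum against small perturbations
  expect_gte(ll(b0_hat, b1_hat), ll(b0_hat + 1e-3, b1_hat) - 1e-9)
  expect_gte(ll(b0_hat, b1_hat), ll(b0_hat, b1_hat + 1e-3) - 1e-9)
})

test_that("two-level multinomial reduces to the binary logistic fit", {
  subjects <- tiny_subjects(15, 15, seed = 41)
  set.seed(42)
  prot <- tibble::tibble(subject_id = subjects$subject_id,
                         C3 = rnorm(30) + (subjects$group == "MECFS"))
  labels <- tibble::tibble(
    subject_id = subjects$subject_id,
    subgroup = ifelse(subjects$group == "MECFS", "CFShet", "NFhet"))
  mfit <- multinomial_subgroups(prot, labels, subjects, "C3")
  bfit <- case_control_logistic(prot, subjects, "C3")
  mt <- tidy(mfit)
  bt <- tidy(bfit)
  expect_equal(mt$estimate[mt$level == "CFShet" & mt$term == "C3"],
               bt$estimate[bt$term == "C3"], tolerance = 1e-5)
})

test_that("reference block is zero and relabelling permutes blocks only", {
  subjects <- tiny_subjects(20, 20, seed = 51)
  set.seed(52)
  prot <- tibble::tibble(subject_id = subjects$subject_id, C3 = rnorm(40))
  sub4 <- rep(c("CFShet", "CFSrem", "NFhet", "NFrem"), 10)
  labels <- tibble::tibble(subject_id = subjects$subject_id, subgroup = sub4)
  fit <- multinomial_subgroups(prot, labels, subjects, "C3")
  td <- tidy(fit)
  expect_equal(td$estimate[td$level == "NFhet"], c(0, 0))
  # swap the two non-reference CFS labels: their blocks swap, NFrem unchanged
  swapped <- labels
  swapped$subgroup[swapped$subgroup == "CFShet"] <- "tmp"
  swapped$subgroup[swapped$subgroup == "CFSrem"] <- "CFShet"
  swapped$subgroup[swapped$subgroup == "tmp"] <- "CFSrem"
  td2 <- tidy(multinomial_subgroups(prot, swapped, subjects, "C3"))
  expect_equal(td2$estimate[td2$level == "CFSrem"],
               td$estimate[td$level == "CFShet"], tolerance = 1e-6)
  expect_equal(td2$estimate[td2$level == "NFrem"],
               td$estimate[td$level == "NFrem"], tolerance = 1e-6)
})

test_that("LRT of a model against itself is exactly zero", {
  subjects <- tiny_subjects(12, 12)
  prot <- tiny_panel(subjects)
  fit <- case_control_logistic(prot, subjects, "C3", covariates = "bmi")
  same <- lrt(fit, fit)
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1)
  red <- reduced_fit(fit)
  out <- lrt(fit, red)
  expect_gte(out$statistic, 0)
  expect_equal(out$df, 1)
})

test_that("LRT rejects mismatched rows and non-nested models", {
  subjects <- tiny_subjects(12, 12)
  prot <- tiny_panel(subjects)
  full <- case_control_logistic(prot, subjects, "C3", covariates = "bmi")
  other <- case_control_logistic(prot[-1, ], subjects[-1, ], "C3",
                                 covariates = "bmi")
  expect_error(lrt(full, other), "different rows")
  nonnested <- case_control_logistic(prot, subjects, "Bb",
                                     covariates = "bmi")
  expect_error(lrt(full, nonnested), "not nested")
})

test_that("planted subgroup effect drives the LRT p-value to near zero", {
  set.seed(61)
  subjects <- tiny_subjects(40, 60, seed = 61)
  sub4 <- sample(c("CFShet", "CFSrem", "NFhet", "NFrem"), 100, replace = TRUE)
  labels <- tibble::tibble(subject_id = subjects$subject_id, subgroup = sub4)
  shift <- c(CFShet = 2, CFSrem = 0, NFhet = 0, NFrem = -1)
  prot <- tibble::tibble(subject_id = subjects$subject_id,
                         C3 = rnorm(100, 0, 0.4) + shift[sub4])
  fit <- multinomial_subgroups(prot, labels, subjects, "C3")
  out <- lrt(fit, reduced_fit(fit))
  expect_lt(out$p_value, 1e-4)
})

test_that("contrasts without covariates equal raw group-mean differences", {
  subjects <- tiny_subjects(9, 9, seed = 71)
  set.seed(72)
  sub3 <- rep(c("CFShet", "NFhet", "NFrem"), each = 6)
  labels <- tibble::tibble(subject_id = subjects$subject_id, subgroup = sub3)
  prot <- tibble::tibble(subject_id = subjects$subject_id, C3 = rnorm(18))
  fit <- subgroup_linear(prot, labels, subjects, "C3")
  ct <- pairwise_contrasts(fit)
  means <- tapply(prot$C3, sub3, mean)
  row <- ct[ct$contrast == "CFShet - NFhet", ]
  expect_equal(row$estimate, unname(means["CFShet"] - means["NFhet"]),
               tolerance = 1e-10)
  expect_equal(nrow(ct), 3)  # all pairs of 3 groups
})

test_that("adjusted contrasts equal the direct prediction-difference oracle", {
  subjects <- tiny_subjects(12, 12, seed = 81)
  set.seed(82)
  sub3 <- rep(c("CFShet", "NFhet", "NFrem"), 8)
  labels <- tibble::tibble(subject_id = subjects$subject_id, subgroup = sub3)
  prot <- tibble::tibble(subject_id = subjects$subject_id,
                         C3 = rnorm(24) + 0.05 * subjects$bmi)
  fit <- subgroup_linear(prot, labels, subjects, "C3", covariates = "bmi")
  ct <- pairwise_contrasts(fit)
  # oracle: own normal-equations fit (CFShet reference) and prediction
  # difference at the covariate sample mean
  X <- cbind(1, as.integer(sub3 == "NFhet"), as.integer(sub3 == "NFrem"),
             subjects$bmi)
  b <- solve(t(X) %*% X, t(X) %*% prot$C3)[, 1]
  at_mean <- function(level) {
    sum(b * c(1, level == "NFhet", level == "NFrem", mean(subjects$bmi)))
  }
  oracle <- at_mean("CFShet") - at_mean("NFhet")
  row <- ct[ct$contrast == "CFShet - NFhet", ]
  expect_equal(row$estimate, oracle, tolerance = 1e-9)
})

test_that("noise-free survey association recovers slope and direction", {
  subjects <- tiny_subjects(10, 10, seed = 91)
  set.seed(92)
  surveys <- tibble::tibble(subject_id = subjects$subject_id,
                            cdc_si = runif(20, 10, 60),
                            sf36_pf = runif(20, 20, 80))
  prot <- tibble::tibble(subject_id = subjects$subject_id,
                         CRP = 0.1 * surveys$cdc_si + 3,
                         C3 = -0.05 * surveys$sf36_pf + 2)
  fit <- suppressWarnings(
    survey_association(prot, surveys, subjects, "CRP", "cdc_si"))
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate[td$term == "cdc_si"], 0.1, tolerance = 1e-10)
  expect_equal(suppressWarnings(summary(fit$model))$r.squared, 1,
               tolerance = 1e-9)
  # higher (better) SF-36 functioning with lower protein -> negative slope
  fit2 <- suppressWarnings(
    survey_association(prot, surveys, subjects, "C3", "sf36_pf"))
  td2 <- suppressWarnings(tidy(fit2))
  expect_lt(td2$estimate[td2$term == "sf36_pf"], 0)
})

test_that("survey type-I rate is near nominal under independence", {
  set.seed(93)
  reps <- 300
  hits <- 0
  subjects <- tibble::tibble(
    subject_id = as.character(1:171),
    group = factor(rep(c("MECFS", "NF"), c(50, 121)),
                   levels = c("MECFS", "NF")),
    sex = "female", age = rnorm(171, 50, 10), bmi = rnorm(171, 27, 5))
  for (i in seq_len(reps)) {
    surveys <- tibble::tibble(subject_id = subjects$subject_id,
                              cdc_si = rnorm(171, 30, 10))
    prot <- tibble::tibble(subject_id = subjects$subject_id,
                           C3 = rnorm(171))
    fit <- survey_association(prot, surveys, subjects, "C3", "cdc_si")
    td <- tidy(fit)
    if (td$p_value[td$term == "cdc_si"] < 0.05) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.02)
  expect_lt(hits / reps, 0.09)
})

test_that("in-sample R-squared never decreases when adding a predictor", {
  subjects <- tiny_subjects(20, 20, seed = 95)
  prot <- tiny_panel(subjects)
  r2 <- function(covs) summary(case_control_linear(prot, subjects, "C3",
                                                   covs)$model)$r.squared
  base <- r2(character())
  plus1 <- r2("bmi")
  plus2 <- r2(c("bmi", "age"))
  expect_gte(plus1, base - 1e-12)
  expect_gte(plus2, plus1 - 1e-12)
})
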
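test_that("top hits filter strictly and deduplicate pools", {
  scan <- fake_scan(tibble::tibble(
    rsid = c("rs1", "rs2", "rs3", "rs3"),
    analyte = c("C3", "C3", "C3", "Bb"),
    gene = c("G1", "G1", "G2", "G2"),
    functional_group = "complement",
    p_fvr = c(0.005, 0.02, 0.009, 0.0099)))
  th <- top_hits(scan, p_threshold = 0.01)
  expect_equal(sort(unique(th$hits$rsid)), c("rs1", "rs3"))
  # rs2 at p = 0.02 dropped by the strict p < 0.01 rule
  expect_false("rs2" %in% th$hits$rsid)
  # two SNPs in one gene count once in the gene pool
  expect_equal(th$gene_pool, c("G1", "G2"))
  # rs3 hits two analytes -> appears in both per-analyte lists
  expect_equal(sum(th$hits$rsid == "rs3"), 2)
  # empty scan -> empty lists, no error
  th0 <- top_hits(scan[scan$p_fvr > 1, ], p_threshold = 0.01)
  expect_equal(nrow(th0$hits), 0)
  expect_length(th0$snp_pool, 0)
})

test_that("enrichment score arithmetic matches the hand example", {
  # analyte A: 4 of 8 hits in group g1; pooled: 10 of 100 in g1
  hits <- tibble::tibble(
    analyte = c(rep("A", 8), rep("B", 92)),
    rsid = sprintf("rs%03d", 1:100),
    gene = sprintf("g%03d", 1:100),
    functional_group = c(rep("complement", 4), rep("metabolic", 4),
                         rep("complement", 6), rep("metabolic", 86)),
    p_fvr = 0.001)
  th <- list(hits = hits)
  sc <- enrichment_scores(th)
  row <- sc[sc$level == "snp" & sc$analyte == "A" &
              sc$functional_group == "complement", ]
  expect_equal(row$observed_prop, 0.5)
  expect_equal(row$expected_prop, 0.1)
  expect_equal(row$score, 5)
})

test_that("uniform composition yields all scores 1 and the sum identity holds", {
  set.seed(171)
  hits <- tidyr::expand_grid(
    analyte = c("C3", "Bb", "CRP"),
    functional_group = functional_groups()) |>
    dplyr::mutate(rsid = sprintf("rs%02d", dplyr::row_number()),
                  gene = sprintf("g%02d", dplyr::row_number()),
                  p_fvr = 0.001)
  sc <- enrichment_scores(list(hits = hits))
  expect_equal(sc$score, rep(1, nrow(sc)))
  # identity sum_g expected_g * score_g = 1 on an uneven composition too
  hits2 <- tibble::tibble(
    analyte = sample(c("C3", "Bb"), 60, TRUE),
    rsid = sprintf("rs%02d", 1:60),
    gene = sprintf("g%02d", sample(40, 60, TRUE)),
    functional_group = sample(functional_groups()[1:4], 60, TRUE),
    p_fvr = 0.001)
  sc2 <- enrichment_scores(list(hits = hits2))
  sums <- sc2 |>
    dplyr::group_by(.data$level, .data$analyte) |>
    dplyr::summarise(s = sum(expected_prop * score), .groups = "drop")
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-12)
})

test_that("disease overlap joins by rsid and fans out per analyte", {
  scan <- fake_scan(tibble::tibble(
    rsid = c("rs1", "rs1", "rs2", "rs3"),
    analyte = c("Bb", "FactorB", "C3", "C3"),
    beta = c(-0.3, -0.2, 0.1, 0.2), se = 0.1,
    p_fvr = c(0.001, 0.002, 0.01, 0.2)))
  disease <- tibble::tibble(rsid = c("rs1", "rs4"),
                            risk_allele = "minor", odds_ratio = c(1.8, 1.2))
  ov <- overlap_disease_snps(scan, disease, p_threshold = 0.05)
  expect_equal(nrow(ov), 2)  # one shared rsid affecting 2 analytes
  expect_equal(unique(ov$rsid), "rs1")
  # disjoint sets -> empty
  ov0 <- overlap_disease_snps(scan, tibble::tibble(
    rsid = "rs9", risk_allele = "minor", odds_ratio = 2), 0.05)
  expect_equal(nrow(ov0), 0)
  # duplicate disease rows are rejected
  expect_error(overlap_disease_snps(scan, disease[c(1, 1), ], 0.05),
               "duplicate")
})

test_that("cis/trans classification honours the inclusive 1 Mb boundary", {
  tss <- tibble::tibble(analyte = "Bb", gene = "CFB", chrom = "6",
                        tss = 1000000)
  rec <- tibble::tibble(
    rsid = c("a", "b", "c", "d"),
    analyte = "Bb",
    chrom = c("6", "6", "7", "6"),
    pos = c(1500000, 2000000, 1000001, 2000001))
  out <- classify_cis_trans(rec, tss)
  expect_equal(out$cis_trans, c("cis", "cis", "trans", "trans"))
  # symmetric in |pos - TSS|: 1 Mb below the TSS is also cis
  rec2 <- tibble::tibble(rsid = "e", analyte = "Bb", chrom = "6", pos = 1)
  expect_equal(classify_cis_trans(rec2, tss)$cis_trans, "cis")
  # unmapped analyte -> unknown
  rec3 <- tibble::tibble(rsid = "f", analyte = "SC5b9", chrom = "6",
                         pos = 1000000)
  expect_equal(classify_cis_trans(rec3, tss)$cis_trans, "unknown")
})

test_that("directionality R-squared equals squared Pearson correlation", {
  set.seed(181)
  pts <- tibble::tibble(rsid = sprintf("rs%d", 1:20),
                        odds_ratio = runif(20, 0.5, 3),
                        beta = rnorm(20))
  out <- directionality(pts)
  expect_equal(out$r_squared, cor(pts$odds_ratio, pts$beta)^2,
               tolerance = 1e-12)
  # collinear points give R^2 = 1
  pts2 <- tibble::tibble(odds_ratio = c(1, 2, 3), beta = c(0.1, 0.3, 0.5))
  expect_equal(suppressWarnings(directionality(pts2))$r_squared, 1,
               tolerance = 1e-12)
  expect_error(directionality(pts2[1:2, ]), "3 points")
  expect_error(directionality(tibble::tibble(odds_ratio = c(1, 1, 1),
                                             beta = 1:3)), "zero variance")
})

test_that("allele flipping to minor respect matches a direct refit", {
  set.seed(182)
  pts <- tibble::tibble(rsid = sprintf("rs%d", 1:15),
                        odds_ratio = runif(15, 0.4, 2.5),
                        beta = rnorm(15),
                        allele_respect = sample(c("major", "minor"), 15, TRUE))
  out <- directionality(pts)
  flipped <- pts
  maj <- flipped$allele_respect == "major"
  flipped$odds_ratio[maj] <- 1 / flipped$odds_ratio[maj]
  flipped$beta[maj] <- -flipped$beta[maj]
  refit <- lm(beta ~ odds_ratio, data = flipped)  # oracle refit
  expect_equal(out$r_squared, summary(refit)$r.squared, tolerance = 1e-12)
  expect_equal(out$slope, unname(coef(refit)[2]), tolerance = 1e-12)
})

test_that("directionality R-squared is invariant to affine OR rescaling", {
  set.seed(183)
  pts <- tibble::tibble(odds_ratio = runif(12, 0.5, 3), beta = rnorm(12))
  a <- directionality(pts)
  pts2 <- dplyr::mutate(pts, odds_ratio = 3 * odds_ratio + 1)
  expect_equal(directionality(pts2)$r_squared, a$r_squared, tolerance = 1e-12)
})

test_that("external overlap joins per-analyte top hits by rsid", {
  hits <- tibble::tibble(rsid = c("rs800292", "rs800292", "rs999"),
                         analyte = c("Bb", "C3", "CRP"),
                         p_fvr = c(0.003, 0.01, 0.2), beta = c(-0.2, 0.1, 0))
  external <- tibble::tibble(
    phenotype = "fatigue_malaise", rsid = "rs800292", gene = "CFH",
    consequence = "missense", odds_ratio = 0.754,
    ci_lower = 0.61, ci_upper = 0.94, p_value = 0.010)
  out <- external_overlap(hits, external)
  expect_equal(nrow(out), 2)  # one external phenotype x two analyte lists
  expect_setequal(out$analyte, c("Bb", "C3"))
  expect_true("pqtl_p" %in% names(out))
  # empty external table -> empty output
  expect_equal(nrow(external_overlap(hits, external[0, ])), 0)
})
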
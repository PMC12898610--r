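# Fixtures built in code: tiny cohorts, dosage matrices and a minimal VCF
# writer shared across test files.

tiny_subjects <- function(n_case = 6, n_control = 6, seed = 101) {
  set.seed(seed)
  n <- n_case + n_control
  tibble::tibble(
    subject_id = sprintf("T%03d", seq_len(n)),
    group = factor(rep(c("MECFS", "NF"), c(n_case, n_control)),
                   levels = c("MECFS", "NF")),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = round(runif(n, 25, 70), 1),
    bmi = round(runif(n, 19, 38), 1)
  )
}

tiny_panel <- function(subjects, seed = 202, sd = 0.5) {
  set.seed(seed)
  n <- nrow(subjects)
  out <- tibble::tibble(subject_id = subjects$subject_id)
  for (a in analytes(measured_only = TRUE)) out[[a]] <- rnorm(n, 0, sd)
  out$BbC3ratio <- out$Bb - out$C3
  out
}

tiny_dosages <- function(subjects, mafs = c(rs1 = 0.3, rs2 = 0.2),
                         seed = 303) {
  set.seed(seed)
  out <- tibble::tibble(subject_id = subjects$subject_id)
  for (r in names(mafs)) out[[r]] <- rbinom(nrow(subjects), 2, mafs[[r]])
  out
}

# Minimal biallelic VCF writer: `gts` is a subjects x sites character matrix
# of GT strings ("0/0", "0/1", ...); alleles a 2-column matrix (REF, ALT).
write_tiny_vcf <- function(path, ids, site_ids, gts, alleles,
                           chrom = "1", pos = NULL) {
  pos <- pos %||% seq(1000, by = 1000, length.out = length(site_ids))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  paste(ids, collapse = "\t")))
  rows <- vapply(seq_along(site_ids), function(j) {
    paste(c(chrom, pos[j], site_ids[j], alleles[j, 1], alleles[j, 2], ".",
            "PASS", ".", "GT", gts[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small scan-shaped tibble for enrichment tests.
fake_scan <- function(df) {
  structure(dplyr::as_tibble(df), class = c("pqtl_scan", class(dplyr::as_tibble(df))))
}
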
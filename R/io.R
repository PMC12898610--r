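# Readers, writers and the log2 preprocessing shared by all stages.
#
# Tabular conventions: every reader returns a tibble keyed by `subject_id`
# (cohort tables) or `rsid` (variant tables); all outputs are tab-separated
# with fixed headers so results round-trip through read_results().

#' Log2-transform a raw protein panel
#'
#' Applies `log2(max(raw, floor))` to every measured analyte and derives the
#' alternative-pathway activity index `BbC3ratio = log2(Bb) - log2(C3)`.
#' The floor guards against zero concentrations (log2 of zero is undefined);
#' it can be a single value or a named per-analyte vector in each analyte's
#' native unit.
#'
#' @param raw Tibble with `subject_id` and one column per measured analyte
#'   (raw concentrations, see [analytes()]).
#' @param floor Positive detection floor, scalar or named per-analyte.
#' @return Tibble with `subject_id`, log2 values for each measured analyte,
#'   and the derived `BbC3ratio` column.
#' @export
log2_transform <- function(raw, floor = 0.01) {
  stopifnot(is.data.frame(raw), "subject_id" %in% names(raw))
  present <- intersect(analytes(measured_only = TRUE), names(raw))
  if (length(present) == 0L) stop("no analyte columns found in `raw`")
  floors <- rep(floor[[1]], length(present))
  names(floors) <- present
  if (!is.null(names(floor))) floors[names(floor)] <- unlist(floor)
  if (any(floors <= 0)) stop("detection floor must be positive")

  out <- dplyr::as_tibble(raw[c("subject_id", present)])
  for (a in present) {
    x <- out[[a]]
    if (any(x < 0, na.rm = TRUE)) {
      bad <- which(x < 0)[1]
      stop(sprintf("negative concentration for subject '%s', analyte '%s'",
                   out$subject_id[bad], a))
    }
    out[[a]] <- log2(pmax(x, floors[[a]]))
  }
  if (all(c("Bb", "C3") %in% present)) {
    out$BbC3ratio <- out$Bb - out$C3
  }
  attr(out, "units") <- analyte_units()[c(present,
                                          intersect("BbC3ratio", names(out)))]
  out
}

#' Read the subject table
#'
#' @param path CSV with columns `subject_id` (or `id`), `group`
#'   (`case`/`control`, or `MECFS`/`NF`), `age`, `sex` (`male`/`female`),
#'   `bmi`.
#' @return Tibble with `group` as a factor with levels `MECFS`, `NF`.
#' @export
read_subjects <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if ("id" %in% names(x) && !"subject_id" %in% names(x)) {
    x <- dplyr::rename(x, subject_id = "id")
  }
  need <- c("subject_id", "group", "age", "sex", "bmi")
  if (!all(need %in% names(x))) {
    stop("subject table must have columns: ", paste(need, collapse = ", "))
  }
  x$subject_id <- as.character(x$subject_id)
  x$group <- normalize_group(x$group)
  x$sex <- tolower(as.character(x$sex))
  if (!all(x$sex %in% c("male", "female"))) stop("sex must be male/female")
  if (any(duplicated(x$subject_id))) stop("duplicate subject ids")
  if (any(x$age <= 0, na.rm = TRUE)) stop("age must be > 0")
  if (any(x$bmi <= 0, na.rm = TRUE)) stop("bmi must be > 0")
  dplyr::as_tibble(x[need])
}

normalize_group <- function(g) {
  g <- as.character(g)
  g[g %in% c("case", "MECFS", "ME/CFS", "CFS", "mecfs")] <- "MECFS"
  g[g %in% c("control", "NF", "nf", "non-fatigued")] <- "NF"
  if (!all(g %in% c("MECFS", "NF"))) stop("unrecognized group labels")
  factor(g, levels = c("MECFS", "NF"))
}

#' Read the raw protein panel
#'
#' @param path CSV with `subject_id` plus one column per measured analyte,
#'   raw concentrations in native units.
#' @return Tibble of raw concentrations; pass to [log2_transform()].
#' @export
read_proteins <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if ("id" %in% names(x) && !"subject_id" %in% names(x)) {
    x <- dplyr::rename(x, subject_id = "id")
  }
  stopifnot("subject_id" %in% names(x))
  x$subject_id <- as.character(x$subject_id)
  dplyr::as_tibble(x)
}

#' Read the survey-score table
#'
#' Expected columns: `subject_id`, `cdc_si`, MFI-20 subscales
#' (`mfi_gf`, `mfi_pf`, `mfi_ra`, `mfi_rm`, `mfi_mf`, range 4-20) and SF-36
#' T-score subscales (`sf36_pf`, `sf36_rp`, `sf36_bp`, `sf36_gh`, `sf36_v`,
#' `sf36_sf`, `sf36_re`, `sf36_mh`). Only the columns present are validated.
#'
#' @param path CSV path.
#' @return Tibble of survey scores.
#' @export
read_surveys <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if ("id" %in% names(x) && !"subject_id" %in% names(x)) {
    x <- dplyr::rename(x, subject_id = "id")
  }
  stopifnot("subject_id" %in% names(x))
  x$subject_id <- as.character(x$subject_id)
  mfi <- grep("^mfi_", names(x), value = TRUE)
  for (m in mfi) {
    if (any(x[[m]] < 4 | x[[m]] > 20, na.rm = TRUE)) {
      stop("MFI subscale '", m, "' outside the 4-20 range")
    }
  }
  dplyr::as_tibble(x)
}

#' Read the SNP annotation table
#'
#' @param path TSV with columns `rsid`, `chrom`, `pos` (1-based bp), `gene`,
#'   `functional_group` (one of [functional_groups()]), `consequence`;
#'   optional `major_allele`, `minor_allele`.
#' @return Tibble of SNP annotation.
#' @export
read_snp_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("rsid", "chrom", "pos", "gene", "functional_group", "consequence")
  if (!all(need %in% names(x))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (any(duplicated(x$rsid))) stop("duplicate rsid in annotation")
  bad <- setdiff(stats::na.omit(unique(x$functional_group)), functional_groups())
  if (length(bad)) {
    stop("unknown functional group(s): ", paste(bad, collapse = ", "))
  }
  x$chrom <- as.character(x$chrom)
  dplyr::as_tibble(x)
}

#' Read the disease-association table
#'
#' @param path TSV with columns `rsid`, `risk_allele` (`major` or `minor`),
#'   `risk_nt` (nucleotide), `odds_ratio` (> 0, with respect to the risk
#'   allele).
#' @return Tibble of disease associations.
#' @export
read_disease_associations <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("rsid", "risk_allele", "odds_ratio")
  if (!all(need %in% names(x))) {
    stop("disease table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(x$risk_allele %in% c("major", "minor"))) {
    stop("risk_allele must be 'major' or 'minor'")
  }
  if (any(x$odds_ratio <= 0)) stop("odds_ratio must be > 0")
  dplyr::as_tibble(x)
}

#' Read a genotype matrix with SNP annotation
#'
#' Reads additive genotype dosages from a VCF (v4.x, biallelic, GT field) or
#' a TSV (rows = subjects, columns = rsIDs, values 0/1/2/NA) and recodes
#' every site so that dosage counts copies of the *in-sample minor allele*:
#' the less frequent allele among non-missing calls in this cohort. At an
#' exact 0.5/0.5 frequency tie the lexicographically smaller nucleotide is
#' taken as minor. Multi-allelic VCF records are skipped with a warning.
#'
#' @param path Genotype file.
#' @param format `"auto"` (by extension), `"vcf"`, or `"tsv"`.
#' @param annotation Optional annotation tibble from [read_snp_annotation()]
#'   (or a path to one). Required fields are merged onto the returned SNP
#'   table.
#' @param strict If `TRUE` (default), error when `annotation` is supplied but
#'   does not cover every variant; if `FALSE`, uncovered variants keep `NA`
#'   annotation with a warning.
#' @return List with `dosages` (tibble: `subject_id` + one 0/1/2/NA column
#'   per rsid) and `snps` (tibble: rsid, chrom, pos, gene, functional_group,
#'   consequence, major_allele, minor_allele, maf).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           annotation = NULL, strict = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (is.character(annotation)) annotation <- read_snp_annotation(annotation)

  parsed <- if (format == "vcf") parse_vcf_dosages(path) else parse_tsv_dosages(path)
  dos <- parsed$dosages      # numeric matrix subjects x snps, ALT/raw counts
  alleles <- parsed$alleles  # tibble rsid, chrom, pos, a0, a1 (a1 = counted)

  # In-sample minor-allele recode: the counted allele's frequency among
  # non-missing calls decides orientation; ties break to the smaller
  # nucleotide (or keep orientation when allele letters are unknown).
  snps <- alleles
  snps$maf <- NA_real_
  snps$major_allele <- NA_character_
  snps$minor_allele <- NA_character_
  for (j in seq_len(ncol(dos))) {
    d <- dos[, j]
    freq1 <- mean(d, na.rm = TRUE) / 2  # frequency of the counted allele a1
    a0 <- snps$a0[j]
    a1 <- snps$a1[j]
    flip <- if (isTRUE(all.equal(freq1, 0.5))) {
      # tie: minor = lexicographically smaller nucleotide when known
      !is.na(a0) && !is.na(a1) && a0 < a1
    } else {
      freq1 > 0.5
    }
    if (flip) {
      dos[, j] <- 2 - d
      snps$minor_allele[j] <- a0
      snps$major_allele[j] <- a1
    } else {
      snps$minor_allele[j] <- a1
      snps$major_allele[j] <- a0
    }
    snps$maf[j] <- mean(dos[, j], na.rm = TRUE) / 2
  }
  snps$a0 <- NULL
  snps$a1 <- NULL

  if (!is.null(annotation)) {
    missing_ann <- setdiff(snps$rsid, annotation$rsid)
    if (length(missing_ann) && strict) {
      stop("annotation missing for variant(s): ",
           paste(head(missing_ann, 5), collapse = ", "))
    }
    if (length(missing_ann)) {
      warning(length(missing_ann), " variant(s) lack annotation")
    }
    keep <- setdiff(names(annotation),
                    c("chrom", "pos", "maf", "major_allele", "minor_allele"))
    snps <- dplyr::left_join(snps, annotation[keep], by = "rsid")
    # fill coordinates from annotation when the genotype source had none
    if (all(is.na(snps$chrom)) && all(c("chrom", "pos") %in% names(annotation))) {
      snps$chrom <- annotation$chrom[match(snps$rsid, annotation$rsid)]
      snps$pos <- annotation$pos[match(snps$rsid, annotation$rsid)]
    }
  }
  for (col in c("gene", "functional_group", "consequence")) {
    if (!col %in% names(snps)) snps[[col]] <- NA_character_
  }

  dosages <- dplyr::bind_cols(
    tibble::tibble(subject_id = parsed$subject_ids),
    dplyr::as_tibble(as.data.frame(dos))
  )
  list(dosages = dosages, snps = dplyr::as_tibble(snps))
}

# Minimal structural validation with line numbers, then vcfR does the parse.
parse_vcf_dosages <- function(path) {
  lines <- readr::read_lines(path)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf < 10) {
      stop(sprintf("malformed VCF record at line %d: %d field(s), expected >= 10",
                   i, nf))
    }
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning("skipping ", sum(multi), " multi-allelic VCF record(s): ",
            paste(head(fix[multi, "ID"], 5), collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  # dosage = count of ALT alleles; accepts phased and unphased separators
  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(strsplit(g, "[/|]")[[1]] == "1")
  }
  dos <- t(apply(gt, 1, function(row) vapply(row, count_alt, numeric(1))))
  if (nrow(fix) == 1L) dos <- matrix(dos, nrow = 1L)
  dos <- t(dos)  # subjects x snps
  colnames(dos) <- fix[, "ID"]
  list(
    dosages = dos,
    subject_ids = colnames(gt),
    alleles = tibble::tibble(
      rsid = unname(fix[, "ID"]), chrom = unname(as.character(fix[, "CHROM"])),
      pos = unname(as.integer(fix[, "POS"])),
      a0 = unname(fix[, "REF"]), a1 = unname(fix[, "ALT"])
    )
  )
}

parse_tsv_dosages <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  idcol <- intersect(c("subject_id", "id"), names(x))[1]
  if (is.na(idcol)) stop("genotype TSV needs a subject_id column")
  ids <- as.character(x[[idcol]])
  dos <- as.matrix(x[setdiff(names(x), idcol)])
  storage.mode(dos) <- "numeric"
  bad <- !(dos %in% c(0, 1, 2) | is.na(dos))
  if (any(bad)) {
    stop("genotype TSV dosages must be 0/1/2/NA; first offending column: ",
         colnames(dos)[which(bad, arr.ind = TRUE)[1, 2]])
  }
  list(
    dosages = dos,
    subject_ids = ids,
    alleles = tibble::tibble(
      rsid = colnames(dos), chrom = NA_character_, pos = NA_integer_,
      a0 = NA_character_, a1 = NA_character_
    )
  )
}

#' Write and re-read tidy result tables
#'
#' All pipeline stages emit tab-separated tables with a fixed header; these
#' helpers guarantee the round trip: strings and integers are reproduced
#' bit-exactly and doubles to full precision (readr writes the shortest
#' representation that round-trips).
#'
#' @param records Data frame of one result type.
#' @param path Output path (`.tsv`).
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the tibble.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  readr::write_tsv(dplyr::as_tibble(records), path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
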
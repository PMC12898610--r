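# Configuration and the end-to-end pipeline driver.
#
# Stage order: transform -> screen -> associate -> pqtl -> integrate ->
# stratify. Rerunning with an identical config and seed reproduces every
# output file bit-identically (the manifest records only deterministic
# content: hashes, seed, thresholds, versions).

#' Build a pipeline configuration
#'
#' Either `inputs` (paths to the five input files) or `simulate = TRUE`
#' (generate them from `sim` at run time) must be provided.
#'
#' @param out_dir Output directory.
#' @param inputs Named list of paths: `subjects`, `proteins`, `surveys`,
#'   `genotypes`, `annotation`, `disease`, optional `external`, `tss`.
#' @param simulate If `TRUE`, generate inputs with [simulate_cohort()].
#' @param sim A `sim_config` (default [sim_config_default()]).
#' @param alpha_screen Covariate screening level.
#' @param alpha_pqtl Reporting threshold for the significant pQTL set.
#' @param alpha_top Top-hit threshold for enrichment.
#' @param roc_filters List: `auc_min`, `p_max`, `n_min`.
#' @param markers Two rsids for subgroup assignment, or `NULL` to take the
#'   two highest-AUC SNPs passing the ROC screen.
#' @param covariate_force Named list analyte -> covariates forced into
#'   adjustment sets.
#' @param top_n Per-analyte top-hit list size for the external overlap.
#' @param seed Integer seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, inputs = NULL, simulate = is.null(inputs),
                            sim = sim_config_default(),
                            alpha_screen = 0.05, alpha_pqtl = 0.05,
                            alpha_top = 0.01,
                            roc_filters = list(auc_min = 0.75, p_max = 0.05,
                                               n_min = 15),
                            markers = c("rs9332739", "rs800292"),
                            covariate_force = list(), top_n = 50,
                            seed = 1L) {
  cfg <- list(out_dir = out_dir, inputs = inputs, simulate = simulate,
              sim = sim, alpha_screen = alpha_screen,
              alpha_pqtl = alpha_pqtl, alpha_top = alpha_top,
              roc_filters = roc_filters, markers = markers,
              covariate_force = covariate_force, top_n = top_n,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  for (a in c("alpha_screen", "alpha_pqtl", "alpha_top")) {
    if (!(cfg[[a]] > 0 && cfg[[a]] < 1)) stop(a, " must be in (0, 1)")
  }
  if (!(cfg$roc_filters$p_max > 0 && cfg$roc_filters$p_max < 1)) {
    stop("roc p_max must be in (0, 1)")
  }
  if (!cfg$simulate) {
    need <- c("subjects", "proteins", "surveys", "genotypes", "annotation",
              "disease")
    missing_keys <- setdiff(need, names(cfg$inputs))
    if (length(missing_keys)) {
      stop("missing input path(s): ", paste(missing_keys, collapse = ", "))
    }
    for (k in need) {
      if (!file.exists(cfg$inputs[[k]])) {
        stop("input file does not exist: ", cfg$inputs[[k]])
      }
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Every key of [pipeline_config()] may appear in the file; the `sim` block
#' holds [sim_config()] fields (tables as lists of records).
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading (e.g. from CLI flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  overrides <- list(...)
  y[names(overrides)] <- overrides
  sim <- sim_config_default()
  if (!is.null(y$sim)) {
    simargs <- y$sim
    for (tab in c("ld_pairs", "covariate_effects", "pqtl_effects",
                  "survey_links", "disease_or", "het_interaction", "snps")) {
      if (!is.null(simargs[[tab]])) {
        simargs[[tab]] <- dplyr::bind_rows(simargs[[tab]])
      }
    }
    for (vec in c("group_shifts", "latent_loadings", "noise_sd",
                  "control_means")) {
      if (!is.null(simargs[[vec]])) simargs[[vec]] <- unlist(simargs[[vec]])
    }
    sim <- do.call(sim_config, simargs)
  }
  args <- y[setdiff(names(y), "sim")]
  args$sim <- sim
  do.call(pipeline_config, args)
}

default_tss <- function() {
  read_results(system.file("extdata", "analyte_tss_synthetic.tsv",
                           package = "pqtlstrat"))
}

#' Run the whole pipeline
#'
#' Executes all stages in dependency order, writes every stage output as a
#' tidy TSV under `out_dir`, and records a manifest (input hashes, seed,
#' thresholds, output hashes, package version). A stage failure aborts with
#' the failing stage named and leaves a `FAILED` marker next to any partial
#' outputs.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste("stage:", stage), file.path(out, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    set.seed(config$seed)
    manifest <- list(seed = config$seed,
                     package_version = as.character(utils::packageVersion("pqtlstrat")),
                     thresholds = list(alpha_screen = config$alpha_screen,
                                       alpha_pqtl = config$alpha_pqtl,
                                       alpha_top = config$alpha_top,
                                       roc_filters = config$roc_filters))

    stage <- "inputs"
    if (config$simulate) {
      say("stage inputs: simulating cohort (seed %d)", config$seed)
      sim <- simulate_cohort(config$sim, seed = config$seed)
      input_dir <- file.path(out, "inputs")
      paths <- write_cohort(sim, input_dir)
      subjects <- sim$subjects
      proteins_raw <- sim$proteins_raw
      surveys <- sim$surveys
      genotypes <- sim$dosages
      snps <- sim$snps
      # recompute in-sample MAF / orientation exactly as file inputs would
      snps$maf <- vapply(snps$rsid, function(r)
        mean(genotypes[[r]], na.rm = TRUE) / 2, numeric(1))
      disease <- sim$disease
      external <- NULL
      tss <- default_tss()
    } else {
      say("stage inputs: reading files")
      subjects <- read_subjects(config$inputs$subjects)
      proteins_raw <- read_proteins(config$inputs$proteins)
      surveys <- read_surveys(config$inputs$surveys)
      gt <- read_genotypes(config$inputs$genotypes,
                           annotation = config$inputs$annotation)
      genotypes <- gt$dosages
      snps <- gt$snps
      disease <- read_disease_associations(config$inputs$disease)
      external <- if (!is.null(config$inputs$external))
        read_results(config$inputs$external) else NULL
      tss <- if (!is.null(config$inputs$tss))
        read_results(config$inputs$tss) else default_tss()
      paths <- unlist(config$inputs)
    }
    input_files <- unname(unlist(paths))
    manifest$inputs <- setNames(as.list(unname(tools::md5sum(input_files))),
                                basename(input_files))

    stage <- "transform"
    proteins <- log2_transform(proteins_raw)

    stage <- "screen"
    say("stage screen: covariates and correlations")
    screen <- screen_covariates(proteins, subjects,
                                alpha = config$alpha_screen,
                                force = config$covariate_force)
    covmap <- covariate_sets(screen)
    corr <- protein_correlations(proteins)
    write_results(screen, file.path(out, "covariate_screen.tsv"))
    write_results(corr, file.path(out, "protein_correlations.tsv"))

    stage <- "associate"
    say("stage associate: case-control and survey models")
    cc <- purrr::map_dfr(intersect(analytes(), names(proteins)), function(a) {
      lin <- suppressWarnings(case_control_linear(
        proteins, subjects, a, covmap[[a]] %||% character()))
      log_ <- suppressWarnings(case_control_logistic(
        proteins, subjects, a, covmap[[a]] %||% character()))
      lin_td <- tidy(lin)
      log_td <- tidy(log_)
      tibble::tibble(
        analyte = a,
        beta_linear = lin_td$estimate[lin_td$term == "groupNF"],
        se_linear = lin_td$std_error[lin_td$term == "groupNF"],
        p_linear = lin_td$p_value[lin_td$term == "groupNF"],
        beta_logistic = log_td$estimate[log_td$term == a],
        se_logistic = log_td$std_error[log_td$term == a],
        p_logistic = log_td$p_value[log_td$term == a],
        n_used = lin$n_used
      )
    })
    write_results(cc, file.path(out, "case_control.tsv"))
    sa <- survey_association_all(proteins, surveys, subjects,
                                 covariate_map = covmap)
    write_results(sa, file.path(out, "survey_assoc.tsv"))

    stage <- "pqtl"
    say("stage pqtl: FvR scan over %d SNPs", nrow(snps))
    scan <- pqtl_scan(genotypes, proteins, subjects, snps,
                      covariate_map = covmap)
    scan <- classify_cis_trans(scan, tss)
    write_results(scan, file.path(out, "pqtl_scan.tsv"))
    top50 <- top_n_hits(scan, n = config$top_n)
    write_results(top50, file.path(out, "pqtl_top_hits.tsv"))
    jsonlite::write_json(c(as.list(summary(scan)),
                           list(bonferroni_m = attr(scan, "m"))),
                         file.path(out, "pqtl_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "integrate"
    say("stage integrate: enrichment, overlap, directionality")
    th <- suppressWarnings(top_hits(scan, p_threshold = config$alpha_top))
    enr <- if (nrow(th$hits)) enrichment_scores(th) else tibble::tibble()
    write_results(enr, file.path(out, "enrichment.tsv"))
    ov <- overlap_disease_snps(scan, disease, p_threshold = config$alpha_pqtl)
    write_results(ov, file.path(out, "overlap.tsv"))
    dir_rows <- purrr::map_dfr(c("C3", "Bb"), function(a) {
      pts <- dplyr::filter(ov, .data$analyte == a)
      pts$allele_respect <- ifelse(pts$risk_allele == "major", "major", "minor")
      # orient ORs to the minor allele before regressing beta on OR
      if (nrow(pts) < 3 || sd(orient_minor(pts)$odds_ratio) == 0) {
        return(NULL)
      }
      dplyr::mutate(directionality(pts), analyte = a, .before = 1)
    })
    write_results(dir_rows, file.path(out, "directionality.tsv"))
    if (!is.null(external)) {
      write_results(external_overlap(top50, external),
                    file.path(out, "external_overlap.tsv"))
    }

    stage <- "stratify"
    say("stage stratify: ROC screen and subgroups")
    sig_snps <- unique(scan$rsid[scan$p_fvr < config$alpha_pqtl])
    roc <- screen_strata(genotypes, proteins, subjects, sig_snps,
                         covariate_map = covmap,
                         auc_min = config$roc_filters$auc_min,
                         p_max = config$roc_filters$p_max,
                         n_min = config$roc_filters$n_min)
    write_results(roc, file.path(out, "roc_screen.tsv"))
    markers <- config$markers
    if (is.null(markers) || !all(markers %in% names(genotypes))) {
      passing <- roc[roc$passes_filters, , drop = FALSE]
      cand <- unique(sub("=.*$", "", passing$stratum))
      if (length(cand) < 2) stop("no marker pair available for stratification")
      markers <- cand[1:2]
    }
    assignment <- assign_subgroups(genotypes, subjects, markers[1], markers[2])
    write_results(assignment, file.path(out, "subgroups.tsv"))
    re <- suppressWarnings(
      subgroup_reanalysis(proteins, assignment, subjects,
                          covariate_map = covmap, surveys = surveys)
    )
    sub_models <- dplyr::bind_rows(
      dplyr::mutate(re$lrt, what = "lrt"),
      dplyr::mutate(re$multinomial, what = "multinomial"),
      dplyr::mutate(re$contrasts, what = "contrast")
    )
    write_results(sub_models, file.path(out, "subgroup_models.tsv"))
    write_results(re$roc_het, file.path(out, "subgroup_roc.tsv"))
    if (!is.null(re$survey_het)) {
      write_results(re$survey_het, file.path(out, "subgroup_survey.tsv"))
    }

    stage <- "manifest"
    outputs <- list.files(out, pattern = "\\.(tsv|json)$", full.names = TRUE,
                          recursive = TRUE)
    outputs <- setdiff(outputs, file.path(out, "manifest.json"))
    manifest$outputs <- setNames(as.list(unname(tools::md5sum(outputs))),
                                 sub(paste0("^", out, "/?"), "", outputs))
    manifest$markers <- markers
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (file.exists(file.path(out, "FAILED"))) {
      file.remove(file.path(out, "FAILED"))
    }
    say("pipeline complete: %s", out)
    invisible(manifest)
  }, error = on_fail)
}
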
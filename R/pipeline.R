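#' Pipeline configuration
#'
#' Collects inputs (file paths or a synthetic [cohort_spec()]), thresholds
#' and seeds for [run_pipeline()]. Either `inputs` (named paths: counts,
#' tpm, ioe, phenotypes, and optionally gmt) or `synthetic` must be given.
#'
#' @param synthetic a [cohort_spec()], or NULL when reading files.
#' @param inputs named list of file paths, or NULL for a synthetic run.
#' @param gmt optional path to a GMT gene-set file; GSEA is skipped without
#'   one unless `gene_sets` is supplied.
#' @param gene_sets optional named list of gene sets (overrides `gmt`).
#' @param output_dir directory for all outputs.
#' @param fdr_gene,fdr_gsea,unique_other_p,edf_nonlinear,min_set,max_set
#'   analysis thresholds (defaults 0.05, 0.1, 0.1, 1.5, 15, 500).
#' @param min_mean_count,min_mean_tpm,min_psi_frac filtering knobs: minimum
#'   mean raw count for genes, minimum mean TPM for isoforms, minimum
#'   fraction of non-NA samples for an AS event.
#' @param smooth a [smooth_spec()].
#' @param n_perm GSEA permutations.
#' @param seed master seed for the analysis stages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL, gmt = NULL,
                            gene_sets = NULL, output_dir = "symptomDE_out",
                            fdr_gene = 0.05, fdr_gsea = 0.1,
                            unique_other_p = 0.1, edf_nonlinear = 1.5,
                            min_set = 15, max_set = 500,
                            min_mean_count = 5, min_mean_tpm = 1,
                            min_psi_frac = 0.8,
                            smooth = smooth_spec(), n_perm = 1000L,
                            seed = 1L) {
  if (is.null(synthetic) && is.null(inputs))
    stop("either a synthetic cohort spec or input paths must be given")
  for (v in c(fdr_gene, fdr_gsea, unique_other_p, min_psi_frac))
    if (v <= 0 || v >= 1) stop("probability thresholds must lie in (0, 1)")
  if (edf_nonlinear <= 1) stop("edf_nonlinear must exceed 1")
  structure(list(synthetic = synthetic, inputs = inputs, gmt = gmt,
                 gene_sets = gene_sets, output_dir = output_dir,
                 fdr_gene = fdr_gene, fdr_gsea = fdr_gsea,
                 unique_other_p = unique_other_p,
                 edf_nonlinear = edf_nonlinear,
                 min_set = min_set, max_set = max_set,
                 min_mean_count = min_mean_count,
                 min_mean_tpm = min_mean_tpm, min_psi_frac = min_psi_frac,
                 smooth = smooth, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `synthetic`
#' mapping is passed to [cohort_spec()] and a `smooth` mapping to
#' [smooth_spec()].
#'
#' @param path YAML file.
#' @param ... overrides applied after reading the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(cohort_spec, y$synthetic)
  if (!is.null(y$smooth)) y$smooth <- do.call(smooth_spec, y$smooth)
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y)
}

.covariate_columns <- c("age", "race", "cd4t", "cd8t", "monocytes", "nk",
                        "bcells", "sv1", "sv2")

#' Validate pipeline inputs for concordance
#'
#' Checks that the sample ids of every matrix match the phenotype table,
#' that the phenotype table has the required phenotype and covariate
#' columns, and that every ioe transcript is present in the TPM matrix.
#'
#' @param phenotypes phenotype data.frame.
#' @param counts optional gene count matrix.
#' @param tpm optional transcript TPM matrix.
#' @param events optional event catalog.
#' @return character vector of issues (empty when everything is concordant).
#' @export
validate_inputs <- function(phenotypes, counts = NULL, tpm = NULL,
                            events = NULL) {
  issues <- character(0)
  need <- c("subject_id", pcl_dimension_names(FALSE), "total_pcl")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss))
    issues <- c(issues, paste("phenotype table lacks column(s):",
                              paste(miss, collapse = ", ")))
  for (nm in c("counts", "tpm")) {
    m <- get(nm)
    if (is.null(m)) next
    extra <- setdiff(colnames(m), phenotypes$subject_id)
    gone <- setdiff(phenotypes$subject_id, colnames(m))
    if (length(extra))
      issues <- c(issues, paste0(nm, " sample(s) missing from phenotypes: ",
                                 paste(extra, collapse = ", ")))
    if (length(gone))
      issues <- c(issues, paste0("subject(s) missing from ", nm, ": ",
                                 paste(gone, collapse = ", ")))
  }
  if (!is.null(events) && !is.null(tpm)) {
    for (i in seq_len(nrow(events))) {
      tot <- .split_ids(events$total_transcripts[i])[[1]]
      unknown <- setdiff(tot, rownames(tpm))
      if (length(unknown))
        issues <- c(issues,
                    paste0("event ", events$event_id[i],
                           " references unknown transcript(s): ",
                           paste(unknown, collapse = ", ")))
    }
  }
  issues
}

.stage <- function(manifest, name, t0, outputs) {
  manifest$stages[[name]] <- list(
    seconds = round(as.numeric(Sys.time()) - t0, 2),
    outputs = outputs,
    checksums = as.list(tools::md5sum(outputs)))
  manifest
}

#' Run the full dimension-resolved analysis pipeline
#'
#' Stages: (synthetic generation or file loading) -> input validation ->
#' count filtering and size factors -> NB-GAM DE per phenotype dimension
#' (total + four subdimensions) -> isoform log(TPM+1) and logit-PSI spline DE
#' -> post-hoc clustering of significant nonlinear gene curves ->
#' cross-dimension comparison (uniqueness, correlations, Venn, threshold
#' curves, AS proportion test) -> optional preranked GSEA per dimension.
#' Every output is written under `config$output_dir` and listed, with MD5
#' checksums and wall-clock, in the returned manifest (also written as
#' `manifest.json`).
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list with config snapshot, per-stage
#'   outputs/checksums/timings, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  cfg_snapshot <- unclass(config)[setdiff(names(config), "gene_sets")]
  cfg_snapshot <- lapply(cfg_snapshot, function(x)
    if (is.list(x)) unclass(x) else x)
  manifest <- list(
    version = as.character(utils::packageVersion("symptomDE")),
    config = cfg_snapshot,
    stages = list())

  ## stage: data
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$synthetic)) {
    co <- simulate_cohort(config$synthetic)
    pheno <- co$phenotypes
    counts <- co$counts; tpm_iso <- co$isoform_tpm
    events <- co$events; tpm_ev <- co$event_tpm
    files <- c(out("phenotypes.tsv"), out("counts.tsv"),
               out("isoform_tpm.tsv"), out("events.ioe"),
               out("truth_genes.tsv"))
    write_table_tsv(pheno, files[1])
    write_matrix_tsv(co$counts, files[2])
    write_matrix_tsv(co$isoform_tpm, files[3], "isoform_id")
    write_ioe(events, files[4])
    write_table_tsv(co$gene_truth, files[5])
  } else {
    pheno <- read_table_tsv(config$inputs$phenotypes)
    counts <- read_matrix_tsv(config$inputs$counts)
    tpm_iso <- read_matrix_tsv(config$inputs$tpm)
    events <- read_ioe(config$inputs$ioe)
    tpm_ev <- tpm_iso
    files <- character(0)
  }
  manifest <- .stage(manifest, "data", t0, files)

  ## stage: validate
  t0 <- as.numeric(Sys.time())
  issues <- validate_inputs(pheno, counts, tpm_ev, events)
  if (length(issues)) {
    manifest$issues <- issues
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
    stop("input validation failed:\n  ", paste(issues, collapse = "\n  "))
  }
  manifest <- .stage(manifest, "validate", t0, character(0))

  covars <- pheno[, intersect(.covariate_columns, names(pheno)), drop = FALSE]
  dims <- pcl_dimension_names(TRUE)
  pheno_col <- function(d) if (d == "total") pheno$total_pcl else pheno[[d]]

  ## stage: gene DE per dimension
  t0 <- as.numeric(Sys.time())
  counts_f <- filter_low_counts(counts, config$min_mean_count)
  sf <- estimate_size_factors(counts_f)
  de_genes <- lapply(dims, function(d)
    run_de(counts_f, pheno_col(d), covars, config$smooth, sf,
           alpha = config$fdr_gene, edf_threshold = config$edf_nonlinear))
  names(de_genes) <- dims
  gene_files <- vapply(dims, function(d) {
    f <- out(paste0("de_genes_", d, ".tsv"))
    write_table_tsv(de_genes[[d]]$results, f)
    f
  }, "")
  curve_file <- out("curves_genes_total.tsv")
  write_matrix_tsv(de_genes$total$curves, curve_file)
  manifest <- .stage(manifest, "de_genes", t0, c(gene_files, curve_file))

  ## stage: isoform DE (total dimension)
  t0 <- as.numeric(Sys.time())
  iso_keep <- rowMeans(tpm_iso) >= config$min_mean_tpm
  message(sprintf("isoform filter: kept %d/%d isoforms (mean TPM >= %g)",
                  sum(iso_keep), length(iso_keep), config$min_mean_tpm))
  log_tpm <- transform_isoforms(tpm_iso[iso_keep, , drop = FALSE])
  de_iso <- run_continuous_de(log_tpm, pheno$total_pcl, covars,
                              config$smooth, alpha = config$fdr_gene,
                              edf_threshold = config$edf_nonlinear)
  f_iso <- out("de_isoforms_total.tsv")
  write_table_tsv(de_iso$results, f_iso)
  manifest <- .stage(manifest, "de_isoforms", t0, f_iso)

  ## stage: AS DE per dimension
  t0 <- as.numeric(Sys.time())
  psi <- compute_psi_matrix(events, tpm_ev)
  usable <- rowMeans(!is.na(psi)) >= config$min_psi_frac
  message(sprintf("event filter: kept %d/%d events (>= %.0f%% non-NA samples)",
                  sum(usable), length(usable), 100 * config$min_psi_frac))
  psi_l <- logit_psi(psi[usable, , drop = FALSE])
  de_as <- lapply(dims, function(d)
    run_continuous_de(psi_l, pheno_col(d), covars, config$smooth,
                      alpha = config$fdr_gene,
                      edf_threshold = config$edf_nonlinear))
  names(de_as) <- dims
  psi_file <- out("psi.tsv")
  write_matrix_tsv(psi[usable, , drop = FALSE], psi_file, "event_id")
  as_files <- vapply(dims, function(d) {
    f <- out(paste0("de_events_", d, ".tsv"))
    write_table_tsv(de_as[[d]]$results, f)
    f
  }, "")
  manifest <- .stage(manifest, "de_events", t0, c(psi_file, as_files))

  ## stage: clustering of nonlinear gene curves (total)
  t0 <- as.numeric(Sys.time())
  nl_ids <- de_genes$total$results$feature_id[de_genes$total$results$nonlinear]
  clu_files <- character(0)
  if (length(nl_ids) >= 3) {
    cl <- cluster_curves(de_genes$total, nl_ids, seed = config$seed)
    clu_files <- c(out("cluster_assignments.tsv"), out("gap_curve.tsv"),
                   out("cluster_mean_curves.tsv"))
    write_table_tsv(data.frame(feature_id = names(cl$clustering$assignments),
                               cluster = cl$clustering$assignments),
                    clu_files[1])
    write_table_tsv(data.frame(k = seq_along(cl$gap$gap), gap = cl$gap$gap,
                               se = cl$gap$se), clu_files[2])
    write_matrix_tsv(cl$clustering$mean_curves, clu_files[3], "cluster")
  } else {
    message("clustering skipped: fewer than 3 nonlinear significant genes")
  }
  manifest <- .stage(manifest, "clustering", t0, clu_files)

  ## stage: cross-dimension comparison
  t0 <- as.numeric(Sys.time())
  mdr <- multi_dim_results(de_genes)
  cmp_files <- c(out("neglogp_correlation.tsv"), out("venn_regions.tsv"),
                 out("threshold_curves.tsv"))
  write_matrix_tsv(neglogp_correlation(mdr), cmp_files[1], "dimension")
  write_table_tsv(overlap_counts(mdr, config$fdr_gene), cmp_files[2])
  write_table_tsv(significance_curves(mdr), cmp_files[3])
  for (d in pcl_dimension_names(FALSE)) {
    uq <- call_unique(mdr, d, config$fdr_gene, config$unique_other_p)
    f <- out(paste0("unique_genes_", d, ".tsv"))
    write_table_tsv(data.frame(feature_id = uq), f)
    cmp_files <- c(cmp_files, f)
  }
  # AS event-type proportion test: significant (total) vs catalog background
  as_tab <- de_as$total$results
  sig_ev <- as_tab$feature_id[!is.na(as_tab$fdr) & as_tab$fdr < config$fdr_gene]
  bg <- table(factor(events$event_type,
                     levels = sort(unique(events$event_type))))
  prop_file <- character(0)
  if (length(sig_ev) >= 1) {
    obs <- table(factor(events$event_type[match(sig_ev, events$event_id)],
                        levels = names(bg)))
    pt <- as_proportion_test(stats::setNames(as.numeric(obs), names(obs)),
                             stats::setNames(as.numeric(bg) / sum(bg),
                                             names(bg)))
    prop_file <- out("as_proportion_test.json")
    jsonlite::write_json(
      list(statistic = pt$statistic, df = pt$df, p_value = pt$p_value,
           merged = as.list(pt$merged)),
      prop_file, auto_unbox = TRUE, digits = NA)
  }
  manifest <- .stage(manifest, "comparison", t0, c(cmp_files, prop_file))

  ## stage: GSEA per dimension (optional)
  t0 <- as.numeric(Sys.time())
  sets <- config$gene_sets
  if (is.null(sets) && !is.null(config$gmt)) sets <- read_gmt(config$gmt)
  gsea_files <- character(0)
  if (!is.null(sets)) {
    gsea_tabs <- lapply(dims, function(d) {
      rk <- build_ranking(de_genes[[d]])
      fs <- filter_sets(sets, rk, config$min_set, config$max_set)
      if (length(fs) == 0) return(NULL)
      gsea_significance(rk, fs, config$n_perm, config$seed)
    })
    names(gsea_tabs) <- dims
    gsea_tabs <- Filter(Negate(is.null), gsea_tabs)
    gsea_files <- vapply(names(gsea_tabs), function(d) {
      f <- out(paste0("gsea_", d, ".tsv"))
      write_table_tsv(gsea_tabs[[d]], f)
      f
    }, "")
    subdims <- intersect(pcl_dimension_names(FALSE), names(gsea_tabs))
    if (length(subdims) == 4) {
      for (d in subdims) {
        uq <- call_unique_sets(gsea_tabs, d, config$fdr_gsea,
                               other_p_threshold = config$unique_other_p)
        f <- file.path(config$output_dir, paste0("unique_sets_", d, ".tsv"))
        write_table_tsv(data.frame(set_name = uq), f)
        gsea_files <- c(gsea_files, f)
      }
    }
  }
  manifest <- .stage(manifest, "gsea", t0, gsea_files)

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
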
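#' Default pipeline configuration
#'
#' A configuration list for [run_pipeline()] in simulation mode: the
#' synthetic-data generator supplies every input, and the analysis
#' parameters take the package defaults (score cutoff 5, cis-only loops,
#' 2 kb promoter windows, either-anchor TF selection, AP-1 subunit set).
#'
#' @param seed Master seed for the simulation.
#' @param ... Overrides passed to [simulation_config()].
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, ...) {
  list(
    simulation = simulation_config(seed = seed, ...),
    params = list(
      min_score = 5,
      cis_only = TRUE,
      promoter_mode = "tss_window",
      promoter_flank = 2000,
      tf_mode = "either_anchor",
      delta_threshold = 0,
      subunits = AP1_SUBUNITS
    )
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (!is.null(config$simulation))
      config$simulation <- do.call(simulation_config, config$simulation)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- default_pipeline_config()$params
  config$params <- utils::modifyList(defaults, config$params %||% list())
  config
}

load_stage_inputs <- function(config) {
  if (!is.null(config$simulation)) {
    cfg <- config$simulation
    if (!inherits(cfg, "simulation_config"))
      cfg <- do.call(simulation_config, cfg)
    genome <- simulate_genome(cfg)
    peaks <- simulate_peaks(cfg, genome)
    loops <- simulate_interactions(cfg, genome, peaks)
    expr <- simulate_expression(cfg, genome, loops$truth)
    cohort <- simulate_cohort(cfg)
    list(genes = genome$genes, peaks = peaks,
         iset_a = loops$a, iset_b = loops$b, truth = loops$truth,
         expr_a = expr$a, expr_b = expr$b,
         cohort_expression = cohort$expression,
         cohort_clinical = cohort$clinical,
         sim_config = cfg)
  } else {
    inp <- config$inputs
    if (is.null(inp$interactions_a) || is.null(inp$interactions_b) ||
        is.null(inp$genes))
      stop("config$inputs must name interactions_a, interactions_b, genes")
    peaks <- lapply(inp$peaks %||% list(), read_bed)
    list(
      genes = read_gene_table(inp$genes),
      peaks = peaks,
      iset_a = read_bedpe_interactions(inp$interactions_a, "condition_a"),
      iset_b = read_bedpe_interactions(inp$interactions_b, "condition_b"),
      truth = NULL,
      expr_a = if (!is.null(inp$expression_a))
        read_expression_matrix(inp$expression_a) else NULL,
      expr_b = if (!is.null(inp$expression_b))
        read_expression_matrix(inp$expression_b) else NULL,
      cohort_expression = if (!is.null(inp$cohort_expression))
        read_expression_matrix(inp$cohort_expression) else NULL,
      cohort_clinical = if (!is.null(inp$cohort_clinical))
        read_cohort_table(inp$cohort_clinical) else NULL,
      sim_config = NULL
    )
  }
}

#' Run the full loop-analysis pipeline
#'
#' Executes the stages in fixed order: load or simulate inputs; collapse
#' duplicate loops; confidence-filter (score cutoff, cis only);
#' CPM-normalize; build the element catalog; tally TF-anchored loop types;
#' per-oncogene differential PE looping summary; loop-strength vs
#' expression Spearman correlation; cohort TF-activity scoring with
#' median-split Kaplan-Meier / log-rank survival. Stages whose inputs are
#' absent (expression, cohort) are skipped with a warning recorded in the
#' report. A failure in any stage aborts naming the stage. The report
#' carries no timestamps, so a rerun under the same config and seed is
#' byte-identical.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or
#'   path to a YAML file with the same structure.
#' @param out_dir Optional output directory; when given, all generated
#'   inputs, per-gene differential records, and the JSON run report are
#'   written there.
#' @return The run report, an object of class `loopbridge_report`
#'   (invisibly a plain list).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  config <- read_pipeline_config(config)
  params <- config$params
  warnings <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- stage("load_inputs", load_stage_inputs(config))
  counts <- list(input = list(
    n_genes = nrow(inputs$genes),
    n_interactions_a = n_interactions(inputs$iset_a),
    n_interactions_b = n_interactions(inputs$iset_b)))

  dedup_a <- stage("collapse_duplicates", collapse_duplicates(inputs$iset_a))
  dedup_b <- stage("collapse_duplicates", collapse_duplicates(inputs$iset_b))
  filt_a <- stage("filter_confident",
                  filter_confident(dedup_a, params$min_score,
                                   params$cis_only))
  filt_b <- stage("filter_confident",
                  filter_confident(dedup_b, params$min_score,
                                   params$cis_only))
  counts$filter <- list(n_confident_a = n_interactions(filt_a),
                        n_confident_b = n_interactions(filt_b))
  norm_a <- stage("cpm_normalize", cpm_normalize(filt_a))
  norm_b <- stage("cpm_normalize", cpm_normalize(filt_b))

  catalog <- stage("build_catalog",
                   build_catalog(inputs$peaks, inputs$genes,
                                 promoter_mode = params$promoter_mode,
                                 flank = params$promoter_flank))
  counts$catalog <- list(n_promoters = nrow(catalog$promoters),
                         n_enhancers = nrow(catalog$enhancers),
                         n_insulators = nrow(catalog$insulators))

  tally <- NULL
  if (!is.null(inputs$peaks$TF)) {
    tf_a <- stage("tf_anchored_tally",
                  select_tf_anchored(norm_a, inputs$peaks$TF,
                                     mode = params$tf_mode))
    tf_b <- stage("tf_anchored_tally",
                  select_tf_anchored(norm_b, inputs$peaks$TF,
                                     mode = params$tf_mode))
    tally <- list(
      n_tf_anchored_a = n_interactions(tf_a),
      n_tf_anchored_b = n_interactions(tf_b),
      fractions_a = if (n_interactions(tf_a) > 0)
        as.list(tally_loop_types(tf_a, catalog)) else NULL,
      fractions_b = if (n_interactions(tf_b) > 0)
        as.list(tally_loop_types(tf_b, catalog)) else NULL)
  } else {
    warnings <- c(warnings, "no TF peak set; loop-type tally skipped")
  }

  gene_list <- inputs$genes$gene_id[inputs$genes$is_oncogene]
  if (length(gene_list) == 0) gene_list <- inputs$genes$gene_id
  remod <- stage("differential_looping",
                 remodeling_summary(gene_list, norm_a, norm_b, catalog,
                                    threshold = params$delta_threshold))

  correlation <- NULL
  if (!is.null(inputs$expr_a) && !is.null(inputs$expr_b)) {
    correlation <- stage("loop_expression_correlation", {
      corr_one <- function(iset, expr) {
        strength <- gene_pe_means(iset, catalog)
        ls <- stats::setNames(strength$mean_count, strength$gene_id)
        loop_expression_correlation(ls, rowMeans(expr))
      }
      list(a = corr_one(norm_a, inputs$expr_a),
           b = corr_one(norm_b, inputs$expr_b))
    })
  } else {
    warnings <- c(warnings, "no expression matrices; correlation skipped")
  }

  survival_res <- NULL
  if (!is.null(inputs$cohort_expression) &&
      !is.null(inputs$cohort_clinical)) {
    survival_res <- stage("cohort_survival", {
      z <- zscore_rows(inputs$cohort_expression)
      subunits <- intersect(params$subunits,
                            rownames(inputs$cohort_expression))
      if (length(subunits) == 0)
        stop("none of the configured subunits are in the cohort matrix")
      score <- activity_score(z, subunits)
      split <- median_split(score)
      clin <- inputs$cohort_clinical
      grp <- split[clin$sample_id]
      lr <- logrank_test(clin[grp == "high", ], clin[grp == "low", ])
      quart <- quantile_groups(score, 4)
      list(n_high = sum(grp == "high"), n_low = sum(grp == "low"),
           logrank_statistic = lr$statistic, logrank_p = lr$p_value,
           quartile_sizes = as.list(table(quart)),
           km_high = km_estimate(clin[grp == "high", ]),
           km_low = km_estimate(clin[grp == "low", ]))
    })
  } else {
    warnings <- c(warnings, "no cohort tables; survival stage skipped")
  }

  report <- list(
    config = list(seed = if (!is.null(inputs$sim_config))
      inputs$sim_config$seed else NULL,
      params = params[order(names(params))]),
    stages = counts,
    loop_type_tally = tally,
    remodeling = remod[c("n_evaluable", "n_increased",
                         "fraction_increased")],
    correlation = correlation,
    survival = if (!is.null(survival_res))
      survival_res[c("n_high", "n_low", "logrank_statistic", "logrank_p",
                     "quartile_sizes")] else NULL,
    warnings = warnings
  )
  class(report) <- "loopbridge_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
    write_gene_table(inputs$genes, file.path(out_dir, "genes.tsv"))
    for (mark in names(inputs$peaks))
      write_regions(inputs$peaks[[mark]],
                    file.path(out_dir, "peaks", paste0(mark, ".bed")))
    write_interactions(inputs$iset_a, file.path(out_dir, "a.bedpe"))
    write_interactions(inputs$iset_b, file.path(out_dir, "b.bedpe"))
    if (!is.null(inputs$expr_a))
      write_expression_matrix(inputs$expr_a,
                              file.path(out_dir, "expr_a.tsv"))
    if (!is.null(inputs$expr_b))
      write_expression_matrix(inputs$expr_b,
                              file.path(out_dir, "expr_b.tsv"))
    if (!is.null(inputs$cohort_expression))
      write_expression_matrix(inputs$cohort_expression,
                              file.path(out_dir, "cohort_expression.tsv"))
    if (!is.null(inputs$cohort_clinical))
      write_cohort_table(inputs$cohort_clinical,
                         file.path(out_dir, "cohort_clinical.tsv"))
    if (!is.null(inputs$truth))
      utils::write.table(inputs$truth, file.path(out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(remod$records, file.path(out_dir, "diffloop.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Write a run report as JSON
#'
#' Stable key order, unboxed scalars, full numeric precision, no
#' timestamps: reruns under the same config and seed serialize
#' byte-identically.
#'
#' @param report A `loopbridge_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.loopbridge_report <- function(x, ...) {
  cat("loopbridge run report\n")
  cat("  confident loops: A =", x$stages$filter$n_confident_a,
      ", B =", x$stages$filter$n_confident_b, "\n")
  cat("  remodeling: ", x$remodeling$n_increased, "/",
      x$remodeling$n_evaluable, " genes increased (fraction ",
      round(x$remodeling$fraction_increased, 3), ")\n", sep = "")
  if (!is.null(x$correlation))
    cat("  loop~expression Spearman rho: A =",
        round(x$correlation$a$rho, 3), ", B =",
        round(x$correlation$b$rho, 3), "\n")
  if (!is.null(x$survival))
    cat("  log-rank high vs low activity: chisq =",
        round(x$survival$logrank_statistic, 2), ", p =",
        signif(x$survival$logrank_p, 3), "\n")
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
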
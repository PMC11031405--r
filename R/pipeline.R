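#' Pipeline configuration
#'
#' Collects all stage parameters with the study defaults: detection in at
#' least 3 of 4 replicates per cell, kNN imputation with k = 10,
#' propagation with alpha = 0.5 for 26 iterations over the
#' score > 899 network, top/bottom 5% of nodes with more than 4
#' interactions, Fisher tests with minimal node size 5, p < 0.05
#' significance filters and a 100-fold (margin 2 on the -log10 scale)
#' p-ratio rule.
#'
#' @param synth a [synth_config()] describing the dataset to simulate,
#'   or `NULL` when `inputs` supplies files.
#' @param inputs optional named list of file paths (`peptides`, `design`,
#'   `edges`, `annotations`) read instead of simulating.
#' @param min_detected,knn_k preprocessing parameters.
#' @param alpha,iterations propagation parameters.
#' @param score_threshold strict lower bound on STRING combined scores.
#' @param min_degree,quantile node-selection parameters.
#' @param min_term_size minimal term size in background.
#' @param alpha_p significance threshold for the classification rules.
#' @param rule_margin -log10 p margin of the dependence rules.
#' @param normalization,weighting propagation operator options.
#' @param seed RNG seed for the run.
#' @return object of class `pipeline_config` (named list).
#' @export
pipeline_config <- function(synth = synth_config(),
                            inputs = NULL,
                            min_detected = 3, knn_k = 10,
                            alpha = 0.5, iterations = 26,
                            score_threshold = 899,
                            min_degree = 5, quantile = 0.05,
                            min_term_size = 5, alpha_p = 0.05,
                            rule_margin = 2,
                            normalization = "symmetric",
                            weighting = "binary",
                            seed = 1L) {
  cfg <- as.list(environment())
  assert_that(cfg$alpha >= 0 && cfg$alpha < 1, "alpha must be in [0, 1)")
  assert_that(cfg$quantile > 0 && cfg$quantile < 0.5,
              "quantile must be in (0, 0.5)")
  if (!is.null(cfg$synth)) cfg$synth$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> preprocess -> differential expression
#' -> propagation -> node selection -> enrichment -> classification on
#' one dataset, optionally writing every stage table plus a run manifest
#' to `out_dir`. Re-running with an identical config reproduces all
#' outputs bit-identically.
#'
#' Contrast conventions: `OldvsYoung_control` (ageing), `EtOHvsRapa`
#' (rapamycin, uninduced), `RUvsRURapa` (rapamycin under induction) and
#' `RUvsEtOH` (induction); the latter serves as the knockdown contrast
#' stand-in when the pipeline is run on a single synthetic dataset.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @param contrasts optional named list of contrast definitions (see
#'   [de_analysis()]); defaults to the built-in factorial set, the
#'   within-age contrasts moderated per age stratum.
#' @return list: `data` (simulated/loaded inputs), `proteins`,
#'   `preprocess_record`, `de` (named DE tables), `propagation`,
#'   `selections`, `background`, `enrichment` (per contrast, collapsed),
#'   `classes` (age / rapa / inhibition labels, protein-level S6K
#'   labels), `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, contrasts = NULL) {
  set.seed(config$seed)
  # --- inputs -------------------------------------------------------
  if (!is.null(config$synth)) {
    data <- simulate_dataset(config$synth)
  } else {
    inp <- config$inputs
    assert_that(!is.null(inp), "either synth or inputs must be given")
    data <- list(
      peptides = read_intensity_table(inp$peptides, scale = "raw"),
      design = read_design(inp$design),
      graph = read_network_edges(inp$edges,
                                 score_threshold = config$score_threshold),
      annotations = read_annotations(inp$annotations,
                                     format = inp$annotation_format %||%
                                       "two_column"),
      truth = NULL)
  }
  design <- data$design
  bad <- setdiff(colnames(data$peptides$values), design$sample_id)
  if (length(bad)) {
    abort_ctx("intensity columns unknown to the design: ",
              paste(bad, collapse = ", "))
  }

  # --- preprocess ---------------------------------------------------
  prep <- preprocess_peptides(data$peptides, design,
                              min_detected = config$min_detected,
                              k = config$knn_k)
  proteins <- prep$proteins

  # --- differential expression -------------------------------------
  if (is.null(contrasts)) {
    ages <- unique(design$age)
    base <- default_contrasts(ages, unique(design$drug),
                              unique(design$induction))
    contrasts <- list(
      OldvsYoung_control = list(coefficients = base$OldvsYoung_control,
                                subset = NULL),
      EtOHvsRapa = list(coefficients = base$EtOHvsRapa,
                        subset = list(age = ages[1])),
      RUvsRURapa = list(coefficients = base$RUvsRURapa,
                        subset = list(age = ages[1])),
      RUvsEtOH = list(coefficients = base$RUvsEtOH,
                      subset = list(age = ages[1]))
    )
  }
  # batch enters as covariate only when not aliased with the cells
  covariates <- character(0)
  cellv <- design_cells(design)
  if (length(unique(design$batch)) > 1L) {
    # batch is aliased when every design cell sits in exactly one batch
    aliased <- all(colSums(base::table(design$batch, cellv) > 0) == 1L)
    if (!aliased) covariates <- "batch" else
      message("batch aliased with design cells; omitted as DE covariate")
  }
  de <- de_analysis(proteins, design, contrasts, covariates = covariates)

  # --- propagation + selection + enrichment ------------------------
  op <- build_operator(data$graph, normalization = config$normalization,
                       weighting = config$weighting)
  deg <- graph_degree(data$graph)
  propagation <- list(); selections <- list(); enrichment <- list()
  background <- list()
  for (nm in names(de)) {
    x0 <- stats::setNames(de[[nm]]$log2fc, de[[nm]]$protein_id)
    sc <- propagate(x0, op, alpha = config$alpha,
                    iterations = config$iterations)
    sel <- select_nodes(sc, data$graph, min_degree = config$min_degree,
                        quantile = config$quantile)
    # background: degree-filtered network nodes with measured input
    bg <- intersect(names(deg)[deg >= config$min_degree],
                    de[[nm]]$protein_id)
    enr <- fisher_enrichment(sel, bg, data$annotations,
                             min_size = config$min_term_size)
    propagation[[nm]] <- sc
    selections[[nm]] <- sel
    background[[nm]] <- bg
    enrichment[[nm]] <- signed_scores(enr)
  }

  # --- classification rules ----------------------------------------
  classes <- list(
    age_related = classify_age_terms(enrichment$OldvsYoung_control,
                                     alpha = config$alpha_p),
    rapa = classify_rapa_terms(enrichment$EtOHvsRapa,
                               enrichment$RUvsRURapa,
                               margin = config$rule_margin),
    s6k_inhibition = classify_s6k_inhibition_terms(enrichment$RUvsEtOH,
                                                   threshold =
                                                     config$rule_margin),
    s6k_dependent_proteins = classify_s6k_dependent(de$RUvsEtOH,
                                                    de$EtOHvsRapa,
                                                    de$RUvsRURapa,
                                                    alpha = config$alpha_p)
  )

  result <- list(data = data, proteins = proteins,
                 preprocess_record = prep$record, de = de,
                 propagation = propagation, selections = selections,
                 background = background, enrichment = enrichment,
                 classes = classes, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write all pipeline stage outputs to a directory
#'
#' One TSV per stage table plus `manifest.json` (parameters, R version,
#' file checksums). Deterministic given a deterministic result.
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_table(result$proteins, fp("proteins.tsv"))
  write_table(result$data$design, fp("design.tsv"))
  for (nm in names(result$de)) {
    write_table(result$de[[nm]], fp(paste0("de_", nm, ".tsv")))
    sc <- result$propagation[[nm]]
    write_table(data.frame(node = names(sc), score = as.vector(sc),
                           stringsAsFactors = FALSE),
                fp(paste0("propagation_", nm, ".tsv")))
    sel <- result$selections[[nm]]
    write_table(data.frame(node = c(sel$up, sel$down),
                           direction = rep(c("up", "down"),
                                           c(length(sel$up),
                                             length(sel$down))),
                           stringsAsFactors = FALSE),
                fp(paste0("selection_", nm, ".tsv")))
    write_table(as.data.frame(result$enrichment[[nm]]),
                fp(paste0("enrichment_", nm, ".tsv")))
  }
  for (nm in names(result$classes)) {
    write_table(result$classes[[nm]], fp(paste0("class_", nm, ".tsv")))
  }
  cfg <- result$config
  cfg$synth <- unclass(cfg$synth)
  files <- sort(list.files(out_dir, pattern = "\\.tsv$"))
  manifest <- list(
    parameters = cfg[setdiff(names(cfg), "inputs")],
    r_version = as.character(getRversion()),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Three-dataset concordance run
#'
#' Simulates (or accepts) three datasets, restricts their DE tables for
#' the chosen contrast to the common gene universe, re-propagates and
#' re-enriches each dataset on that universe, and intersects the results
#' — the workflow behind the shared up-/down-regulated annotation
#' heatmap.
#'
#' @param runs named list of three [run_pipeline()] results sharing an
#'   annotation source.
#' @param contrast contrast name to integrate (default `"EtOHvsRapa"`).
#' @param alpha_p per-dataset significance threshold.
#' @return list: `concordance` (see [cross_dataset_concordance()]),
#'   `n_common`, `enrichment` (per-dataset collapsed tables).
#' @export
integrate_datasets <- function(runs, contrast = "EtOHvsRapa",
                               alpha_p = 0.05) {
  assert_that(length(runs) == 3, "need exactly three pipeline runs")
  de_tabs <- lapply(runs, function(r) r$de[[contrast]])
  restr <- restrict_to_common_genes(de_tabs)
  enr <- list()
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    cfg <- r$config
    op <- build_operator(r$data$graph, normalization = cfg$normalization,
                         weighting = cfg$weighting)
    tab <- restr$tables[[i]]
    x0 <- stats::setNames(tab$log2fc, tab$protein_id)
    sc <- propagate(x0, op, alpha = cfg$alpha, iterations = cfg$iterations)
    sel <- select_nodes(sc, r$data$graph, min_degree = cfg$min_degree,
                        quantile = cfg$quantile)
    deg <- graph_degree(r$data$graph)
    bg <- intersect(names(deg)[deg >= cfg$min_degree], tab$protein_id)
    enr[[i]] <- signed_scores(
      fisher_enrichment(sel, bg, r$data$annotations,
                        min_size = cfg$min_term_size))
  }
  names(enr) <- names(runs) %||% paste0("dataset", seq_along(runs))
  list(concordance = cross_dataset_concordance(enr, alpha = alpha_p),
       n_common = restr$n_common,
       enrichment = enr)
}
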
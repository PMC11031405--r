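#' Configuration for the synthetic factorial TMT simulator
#'
#' Defaults emulate the fly fat-body study design: 2 ages x 2 drug levels
#' (vehicle/rapamycin) x 2 induction levels (uninduced/RU486) x 4
#' replicates, with the dissection batch tied to age (each age is one TMT
#' plex). Planted differential effects are concentrated in network
#' modules so that propagation and enrichment recovery can be scored
#' against ground truth.
#'
#' @param n_proteins total number of simulated proteins; the first
#'   `n_modules * module_size` of them are network nodes.
#' @param peptides_per_protein mean of the (shifted Poisson) peptide count
#'   per protein, minimum 1.
#' @param ages,drugs,inductions factor levels of the 2x2x2 design.
#' @param replicates biological replicates per design cell.
#' @param effect_map list of planted effects; each element is
#'   `list(contrast = <name>, module = <module index> | proteins = <ids>,
#'   delta = <log2 effect>)`. Contrast names must exist in
#'   [default_contrasts()].
#' @param baseline_mean,baseline_sd log2-intensity baseline distribution
#'   across proteins.
#' @param batch_sd SD of per-protein, per-batch log2 shifts.
#' @param peptide_offset_sd SD of the per-peptide ionization offset.
#' @param noise_sd SD of the residual peptide-level log2 noise.
#' @param mnar_midpoint,mnar_slope logistic intensity-dependent dropout:
#'   dropout probability `plogis(mnar_slope * (mnar_midpoint - log2
#'   intensity))`; a slope of 0 disables the MNAR channel.
#' @param mcar_rate probability of missing-completely-at-random dropout,
#'   layered on top of MNAR.
#' @param n_modules,module_size stochastic-block-model module layout.
#' @param within_module_edge_prob,between_module_edge_prob SBM edge
#'   probabilities.
#' @param n_terms number of annotation terms (one true term per module
#'   plus decoys); must be >= `n_modules`.
#' @param term_noise probability that a true-term member is swapped for a
#'   random network gene outside its module.
#' @param dataset_id dataset label written into the design table.
#' @param seed RNG seed used by [simulate_dataset()].
#' @return object of class `synth_config` (a named list).
#' @export
synth_config <- function(n_proteins = 2000,
                         peptides_per_protein = 3,
                         ages = c("young", "old"),
                         drugs = c("EtOH", "Rapa"),
                         inductions = c("ctrl", "RU"),
                         replicates = 4,
                         effect_map = list(list(contrast = "EtOHvsRapa",
                                                module = 1, delta = 1)),
                         baseline_mean = 18, baseline_sd = 1.5,
                         batch_sd = 0.3,
                         peptide_offset_sd = 1,
                         noise_sd = 0.25,
                         mnar_midpoint = 14, mnar_slope = 0.8,
                         mcar_rate = 0.02,
                         n_modules = 10, module_size = 20,
                         within_module_edge_prob = 0.4,
                         between_module_edge_prob = 0.02,
                         n_terms = 50, term_noise = 0.05,
                         dataset_id = "synth1",
                         seed = 1L) {
  cfg <- as.list(environment())
  assert_that(cfg$noise_sd >= 0 && cfg$batch_sd >= 0 &&
                cfg$peptide_offset_sd >= 0, "all sds must be >= 0")
  for (p in c("mcar_rate", "term_noise", "within_module_edge_prob",
              "between_module_edge_prob")) {
    assert_that(cfg[[p]] >= 0 && cfg[[p]] <= 1,
                paste(p, "must be a probability"))
  }
  assert_that(cfg$n_terms >= cfg$n_modules, "n_terms must be >= n_modules")
  assert_that(cfg$n_proteins >= cfg$n_modules * cfg$module_size,
              "n_proteins must cover the network modules")
  structure(cfg, class = "synth_config")
}

protein_ids <- function(n) sprintf("P%04d", seq_len(n))

#' Built-in factorial contrasts
#'
#' Cell-mean contrasts over the age.drug.induction cells, named after the
#' comparisons the pipeline reports: `OldvsYoung_control` (ageing under
#' vehicle, uninduced), `EtOHvsRapa` (rapamycin vs vehicle, uninduced),
#' `RUvsRURapa` (rapamycin vs vehicle under induction) and `RUvsEtOH`
#' (induction vs control, vehicle), the latter three within the young
#' stratum. Positive log2 fold change means higher under the first-named
#' perturbed condition (rapamycin / induction / old age).
#'
#' @param ages,drugs,inductions the factor levels in use.
#' @return named list of contrast coefficient vectors over cell labels.
#' @export
default_contrasts <- function(ages = c("young", "old"),
                              drugs = c("EtOH", "Rapa"),
                              inductions = c("ctrl", "RU")) {
  young <- ages[1]; old <- ages[2]
  veh <- drugs[1]; rapa <- drugs[2]
  unind <- inductions[1]; ind <- inductions[2]
  ct <- function(plus, minus) {
    v <- c(1, -1)
    names(v) <- c(plus, minus)
    v
  }
  list(
    OldvsYoung_control = ct(cell_label(old, veh, unind),
                            cell_label(young, veh, unind)),
    EtOHvsRapa = ct(cell_label(young, rapa, unind),
                    cell_label(young, veh, unind)),
    RUvsRURapa = ct(cell_label(young, rapa, ind),
                    cell_label(young, veh, ind)),
    RUvsEtOH = ct(cell_label(young, veh, ind),
                  cell_label(young, veh, unind))
  )
}

#' Generate a modular interaction network
#'
#' Stochastic-block-model graph over the first `n_modules * module_size`
#' protein ids; edge confidence scores are drawn uniformly from 900-999 so
#' every edge survives the high-confidence read threshold (>899). Isolated
#' nodes are reconnected to a random member of their own module so the
#' graph satisfies the degree >= 1 invariant. Uses the current RNG state.
#'
#' @param config a [synth_config()].
#' @return list with `graph` (an `interaction_graph`) and `modules`
#'   (named integer vector, node -> module index).
#' @export
generate_network <- function(config) {
  n_nodes <- config$n_modules * config$module_size
  ids <- protein_ids(config$n_proteins)[seq_len(n_nodes)]
  pref <- matrix(config$between_module_edge_prob,
                 config$n_modules, config$n_modules)
  diag(pref) <- config$within_module_edge_prob
  g <- igraph::sample_sbm(n_nodes, pref.matrix = pref,
                          block.sizes = rep(config$module_size,
                                            config$n_modules))
  modules <- rep(seq_len(config$n_modules), each = config$module_size)
  names(modules) <- ids
  el <- igraph::as_edgelist(g, names = FALSE)
  # reconnect isolated nodes within their module
  deg <- igraph::degree(g)
  for (v in which(deg == 0)) {
    mates <- setdiff(which(modules == modules[v]), v)
    if (length(mates) == 0L) abort_ctx("module of size 1 cannot be connected")
    el <- rbind(el, c(v, mates[sample.int(length(mates), 1L)]))
  }
  if (nrow(el) == 0L) abort_ctx("generated graph has no edges")
  scores <- sample(900:999, nrow(el), replace = TRUE)
  graph <- interaction_graph(ids[el[, 1]], ids[el[, 2]], scores)
  list(graph = graph, modules = modules)
}

#' Generate module-aligned annotations with decoys
#'
#' One "true" term per module (its members, each swapped with probability
#' `term_noise` for a random network gene outside the module) plus decoy
#' terms of matched size sampled uniformly from the network genes. True
#' terms are named `TERM_M<module>`, decoys `TERM_D<k>`. Uses the current
#' RNG state.
#'
#' @param modules module assignment from [generate_network()].
#' @param config a [synth_config()].
#' @return an `annotation_set`.
#' @export
generate_annotations <- function(modules, config) {
  universe <- names(modules)
  term_ids <- character(0)
  genes <- list()
  for (m in seq_len(config$n_modules)) {
    members <- universe[modules == m]
    outside <- universe[modules != m]
    swap <- stats::runif(length(members)) < config$term_noise
    if (any(swap)) {
      members[swap] <- sample(setdiff(outside, members), sum(swap))
    }
    term_ids <- c(term_ids, rep(sprintf("TERM_M%02d", m), length(members)))
    genes <- c(genes, list(members))
  }
  n_decoys <- config$n_terms - config$n_modules
  for (k in seq_len(n_decoys)) {
    members <- sample(universe, config$module_size)
    term_ids <- c(term_ids, rep(sprintf("TERM_D%02d", k), length(members)))
    genes <- c(genes, list(members))
  }
  annotation_set(term_ids, unlist(genes))
}

#' Generate a factorial TMT-like peptide experiment with known truth
#'
#' Protein log2 abundance is baseline + planted cell effects + a
#' per-protein batch shift; each peptide inherits its protein value plus a
#' peptide offset and residual noise; intensities are returned on the raw
#' scale (2^log2). Missingness is MCAR plus logistic intensity-dependent
#' MNAR. Planted effects enter at the protein level on the positive cells
#' of the named contrast, so the true log2 fold change of an affected
#' protein equals `delta` for that contrast. Uses the current RNG state.
#'
#' @param config a [synth_config()].
#' @param modules module assignment (used to resolve `module =` entries of
#'   the effect map).
#' @return list with `peptides` (raw-scale [peptide_table()]), `design`
#'   (a `sample_design`), and `truth` (list: `log2fc` protein x contrast
#'   matrix, `effects`, `planted_terms` data.frame contrast/term/direction).
#' @export
generate_experiment <- function(config, modules = NULL) {
  ids <- protein_ids(config$n_proteins)
  contrasts <- default_contrasts(config$ages, config$drugs, config$inductions)

  grid <- expand.grid(replicate = seq_len(config$replicates),
                      induction = config$inductions,
                      drug = config$drugs,
                      age = config$ages,
                      stringsAsFactors = FALSE)
  design <- data.frame(
    sample_id = sprintf("%s_%s_%s_r%d", grid$age, grid$drug, grid$induction,
                        grid$replicate),
    age = grid$age, drug = grid$drug, induction = grid$induction,
    replicate = grid$replicate,
    batch = paste0("batch_", grid$age),
    dataset_id = config$dataset_id,
    stringsAsFactors = FALSE)
  design <- sample_design(design)

  cells <- sort(unique(design_cells(design)))
  cell_of_sample <- design_cells(design)
  # only contrasts whose cells exist in this design are expressible
  contrasts <- Filter(function(cv) all(names(cv) %in% cells), contrasts)

  # planted effects: delta added to the positive cells of the named contrast
  cell_shift <- matrix(0, config$n_proteins, length(cells),
                       dimnames = list(ids, cells))
  planted <- list()
  for (eff in config$effect_map) {
    cname <- eff$contrast
    if (is.null(contrasts[[cname]])) {
      abort_ctx("effect_map contrast not expressible in the design: ", cname)
    }
    prots <- if (!is.null(eff$proteins)) eff$proteins else {
      assert_that(!is.null(modules), "module-based effect needs a module assignment")
      names(modules)[modules == eff$module]
    }
    assert_that(all(prots %in% ids), "effect proteins outside the protein universe")
    cvec <- contrasts[[cname]]
    pos <- names(cvec)[cvec > 0]
    cell_shift[prots, pos] <- cell_shift[prots, pos] + eff$delta
    planted[[length(planted) + 1L]] <-
      data.frame(contrast = cname,
                 term_id = if (!is.null(eff$module))
                   sprintf("TERM_M%02d", eff$module) else NA_character_,
                 direction = if (eff$delta > 0) "up" else "down",
                 delta = eff$delta, stringsAsFactors = FALSE)
  }

  # bookkeeping truth: contrast applied to the planted cell means
  truth_fc <- sapply(contrasts, function(cvec) {
    as.vector(cell_shift[, names(cvec), drop = FALSE] %*% cvec)
  })
  rownames(truth_fc) <- ids

  baseline <- stats::rnorm(config$n_proteins, config$baseline_mean,
                           config$baseline_sd)
  batches <- sort(unique(design$batch))
  batch_shift <- matrix(stats::rnorm(config$n_proteins * length(batches),
                                     0, config$batch_sd),
                        config$n_proteins, length(batches),
                        dimnames = list(ids, batches))

  prot_value <- baseline + cell_shift[, cell_of_sample, drop = FALSE] +
    batch_shift[, design$batch, drop = FALSE]
  colnames(prot_value) <- design$sample_id

  n_pep <- 1L + stats::rpois(config$n_proteins,
                             max(config$peptides_per_protein - 1, 0))
  pep_protein <- rep(ids, n_pep)
  pep_id <- sprintf("%s_pep%02d", pep_protein,
                    unlist(lapply(n_pep, seq_len)))
  offsets <- stats::rnorm(length(pep_id), 0, config$peptide_offset_sd)
  pep_log2 <- prot_value[pep_protein, , drop = FALSE] + offsets +
    matrix(stats::rnorm(length(pep_id) * nrow(design), 0, config$noise_sd),
           length(pep_id), nrow(design))

  drop_p <- matrix(config$mcar_rate, nrow(pep_log2), ncol(pep_log2))
  if (config$mnar_slope > 0) {
    p_mnar <- stats::plogis(config$mnar_slope *
                              (config$mnar_midpoint - pep_log2))
    drop_p <- 1 - (1 - drop_p) * (1 - p_mnar)
  }
  miss <- matrix(stats::runif(length(pep_log2)), nrow(pep_log2)) < drop_p
  raw <- 2^pep_log2
  raw[miss] <- NA_real_

  peptides <- peptide_table(raw, pep_id, pep_protein, scale = "raw")
  truth <- list(log2fc = truth_fc,
                effects = config$effect_map,
                planted_terms = if (length(planted))
                  do.call(rbind, planted) else
                    data.frame(contrast = character(0), term_id = character(0),
                               direction = character(0), delta = numeric(0)))
  list(peptides = peptides, design = design, truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Seeds the RNG once from `config$seed` and draws the network, the
#' annotations and the experiment in a fixed order, so identical configs
#' give bit-identical datasets.
#'
#' @param config a [synth_config()].
#' @return list: `peptides`, `design`, `graph`, `modules`, `annotations`,
#'   `truth`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  net <- generate_network(config)
  ann <- generate_annotations(net$modules, config)
  exp <- generate_experiment(config, net$modules)
  truth <- exp$truth
  truth$modules <- net$modules
  list(peptides = exp$peptides, design = exp$design, graph = net$graph,
       modules = net$modules, annotations = ann, truth = truth)
}
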
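# Shared fixture builders; everything is generated in code.

# Factorial design with n_rep replicates per age x drug x induction cell.
toy_design <- function(n_rep = 2, ages = c("young", "old"),
                       drugs = c("EtOH", "Rapa"),
                       inductions = c("ctrl", "RU"),
                       batch_by_age = TRUE) {
  grid <- expand.grid(replicate = seq_len(n_rep), induction = inductions,
                      drug = drugs, age = ages, stringsAsFactors = FALSE)
  sample_design(data.frame(
    sample_id = sprintf("%s_%s_%s_r%d", grid$age, grid$drug, grid$induction,
                        grid$replicate),
    age = grid$age, drug = grid$drug, induction = grid$induction,
    replicate = grid$replicate,
    batch = if (batch_by_age) paste0("b_", grid$age) else "b1",
    dataset_id = "toy", stringsAsFactors = FALSE))
}

# Two-group design (drug only), n per group, single age/induction/batch.
two_group_design <- function(n = 4) {
  toy_design(n_rep = n, ages = "young", inductions = "ctrl",
             batch_by_age = FALSE)
}

# Protein table from a matrix, default sample names from a design.
toy_proteins <- function(m, design = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("P%03d", seq_len(nrow(m)))
  if (!is.null(design)) colnames(m) <- design$sample_id
  protein_table(m)
}

# Ring lattice: node i linked to its k nearest neighbours per side,
# giving degree 2k everywhere. Deterministic, no RNG.
ring_graph <- function(n = 100, k = 3, ids = sprintf("N%03d", seq_len(n))) {
  p1 <- integer(0); p2 <- integer(0)
  for (d in seq_len(k)) {
    p1 <- c(p1, seq_len(n))
    p2 <- c(p2, (seq_len(n) + d - 1L) %% n + 1L)
  }
  interaction_graph(ids[p1], ids[p2], rep(950L, length(p1)))
}

# Random connected-ish graph for operator tests: G(n, p) with isolated
# nodes dropped. Uses the current RNG state.
random_graph <- function(n = 50, p = 0.1) {
  g <- igraph::sample_gnp(n, p)
  deg <- igraph::degree(g)
  g <- igraph::induced_subgraph(g, which(deg > 0))
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- sprintf("N%03d", seq_len(igraph::vcount(g)))
  interaction_graph(ids[el[, 1]], ids[el[, 2]],
                    sample(900:999, nrow(el), replace = TRUE))
}

# Minimal protein_fit for exercising the moderated-test formulas.
make_fit <- function(log2fc, s2, df, var_unscaled = 1) {
  n <- length(log2fc)
  coef <- cbind(A = log2fc, B = rep(0, n))
  rownames(coef) <- sprintf("P%03d", seq_len(n))
  cov <- diag(c(var_unscaled / 2, var_unscaled / 2))
  dimnames(cov) <- list(c("A", "B"), c("A", "B"))
  structure(list(coef = coef, s2 = s2, df = rep_len(df, n),
                 cov_unscaled = cov, cells = c("A", "B"), n = df + 2),
            class = "protein_fit")
}

# Enrichment-table row builder for the classification rules.
enr_row <- function(term_id, p, direction = "up") {
  data.frame(term_id = term_id, direction = direction,
             k = 1L, K = 5L, n = 10L, N = 100L, p = p,
             signed_score = ifelse(direction == "up", 1, -1) * (-log10(p)),
             stringsAsFactors = FALSE)
}

enr_table <- function(term_id, p, direction = "up") {
  do.call(rbind, Map(enr_row, term_id, p, direction))
}

# Hypergeometric upper tail by explicit enumeration (independent oracle).
hyper_tail_oracle <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
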
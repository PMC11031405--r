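#' Log2/z rescaling of peptide intensities
#'
#' Each peptide row is z-scored over its present values and rescaled back
#' to intensity units by multiplying with the global standard deviation of
#' the log2 data and adding the global mean, so every retained row shares
#' the global location and spread while keeping its relative sample
#' pattern. Rows with fewer than two present values or with zero variance
#' cannot be z-scored and are dropped (counted in the record).
#'
#' @param table a [peptide_table()]; raw values are log2-transformed
#'   first (all present raw values must be positive).
#' @return list with `table` (normalized `peptide_table`, scale `"log2"`)
#'   and `record` (list: `global_mean`, `global_sd`,
#'   `dropped_constant_rows`).
#' @export
log2_z_rescale <- function(table) {
  x <- table$values
  if (table$scale == "raw") {
    if (any(x <= 0, na.rm = TRUE)) {
      abort_ctx("nonpositive raw intensity cannot be log2-transformed")
    }
    x <- log2(x)
  }
  n_present <- rowSums(!is.na(x))
  row_sd <- apply(x, 1L, stats::sd, na.rm = TRUE)
  keep <- n_present >= 2L & !is.na(row_sd) & row_sd > 0
  dropped <- sum(!keep)
  if (!any(keep)) abort_ctx("all peptide rows are constant")
  x <- x[keep, , drop = FALSE]
  m_global <- mean(x, na.rm = TRUE)
  sd_global <- stats::sd(as.vector(x), na.rm = TRUE)
  row_mean <- rowMeans(x, na.rm = TRUE)
  row_sd <- row_sd[keep]
  z <- (x - row_mean) / row_sd
  y <- z * sd_global + m_global
  out <- peptide_table(y, table$peptide_id[keep], table$protein_id[keep],
                       scale = "log2")
  list(table = out,
       record = list(global_mean = m_global, global_sd = sd_global,
                     dropped_constant_rows = dropped))
}

#' Aggregate peptides to protein level
#'
#' Per protein and sample, the median (default) or mean over present
#' peptide values; a protein-sample cell is missing only when all its
#' peptides are missing there.
#'
#' @param table normalized [peptide_table()] (log2 scale).
#' @param method `"median"` or `"mean"`.
#' @return a [protein_table()].
#' @export
aggregate_peptides <- function(table, method = c("median", "mean")) {
  method <- match.arg(method)
  fun <- if (method == "median") {
    function(v) stats::median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  prot <- factor(table$protein_id)
  agg <- matrix(NA_real_, nlevels(prot), ncol(table$values),
                dimnames = list(levels(prot), colnames(table$values)))
  for (j in seq_len(ncol(agg))) {
    v <- tapply(table$values[, j], prot, fun)
    agg[, j] <- as.vector(v)[match(levels(prot), names(v))]
  }
  agg[is.nan(agg)] <- NA_real_
  protein_table(agg)
}

#' Filter proteins by per-group detection
#'
#' A protein is retained only if, in every group defined by `group_by`
#' (default: each age x drug x induction cell), it has at least
#' `min_detected` present values — the "detected in at least three out of
#' four replicates for each treatment" rule.
#'
#' @param table a [protein_table()].
#' @param design matching `sample_design`.
#' @param min_detected minimum present values per group.
#' @param group_by character vector of design columns defining groups.
#' @return filtered `protein_table`; attributes `n_retained`, `n_dropped`.
#' @export
filter_by_detection <- function(table, design, min_detected = 3,
                                group_by = c("age", "drug", "induction")) {
  m <- unclass(table)
  assert_that(all(colnames(m) %in% design$sample_id),
              "protein table columns must be design sample ids")
  design <- design[match(colnames(m), design$sample_id), , drop = FALSE]
  groups <- interaction(design[group_by], drop = TRUE, sep = ".")
  sizes <- base::table(groups)
  too_small <- names(sizes)[sizes < min_detected]
  if (length(too_small)) {
    abort_ctx("group(s) smaller than min_detected: ",
              paste(too_small, collapse = ", "))
  }
  present <- !is.na(m)
  keep <- rep(TRUE, nrow(m))
  for (g in levels(groups)) {
    cnt <- rowSums(present[, groups == g, drop = FALSE])
    keep <- keep & cnt >= min_detected
  }
  out <- protein_table(m[keep, , drop = FALSE])
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' k-nearest-neighbour imputation of missing protein values
#'
#' For each protein with missing values, the `k` proteins nearest in
#' Euclidean distance over mutually present samples (distance averaged
#' per shared sample; at least one shared sample required) are found,
#' and each missing cell is filled with the mean of the neighbours'
#' present values in that sample. Rows with more than `max_missing_frac`
#' missing, or missing cells no neighbour covers, fall back to the row
#' mean. Observed entries are never modified.
#'
#' @param table a [protein_table()] (post-filter).
#' @param k number of neighbours.
#' @param max_missing_frac fall back to row mean above this missing
#'   fraction.
#' @return complete `protein_table`.
#' @export
impute_missing <- function(table, k = 10, max_missing_frac = 0.5) {
  m <- unclass(table)
  n_present <- rowSums(!is.na(m))
  if (any(n_present == 0L)) {
    abort_ctx("protein(s) with no present values: ",
              paste(rownames(m)[n_present == 0L], collapse = ", "))
  }
  assert_that(k >= 1, "k must be >= 1")
  has_na <- which(rowSums(is.na(m)) > 0L)
  if (length(has_na) == 0L) return(table)

  row_means <- rowMeans(m, na.rm = TRUE)
  frac_missing <- rowSums(is.na(m)) / ncol(m)
  obs <- (!is.na(m)) * 1
  m0 <- m
  m0[is.na(m)] <- 0
  # pairwise mean squared differences over mutually present samples,
  # via the zero-filled cross-product expansion, query rows x all rows
  sq <- m0^2
  q <- has_na
  shared <- obs[q, , drop = FALSE] %*% t(obs)
  d2 <- sq[q, , drop = FALSE] %*% t(obs) +
    obs[q, , drop = FALSE] %*% t(sq) -
    2 * (m0[q, , drop = FALSE] %*% t(m0))
  dmat <- sqrt(pmax(d2, 0) / pmax(shared, 1))
  dmat[shared == 0] <- Inf

  out <- m
  for (qi in seq_along(q)) {
    i <- q[qi]
    if (frac_missing[i] > max_missing_frac) {
      out[i, is.na(m[i, ])] <- row_means[i]
      next
    }
    d <- dmat[qi, ]
    d[i] <- Inf
    ord <- order(d, rownames(m))                     # deterministic ties
    nb <- ord[seq_len(min(k, sum(is.finite(d))))]
    for (j in which(is.na(m[i, ]))) {
      vals <- m[nb, j]
      vals <- vals[!is.na(vals)]
      out[i, j] <- if (length(vals)) mean(vals) else row_means[i]
    }
  }
  protein_table(out)
}

#' Remove batch means for visualization
#'
#' Per protein, subtracts the batch mean and adds back the grand mean.
#' Intended for PCA and plotting only; differential testing models the
#' batch as a covariate instead. With a single batch this is the identity
#' (with a warning). Warns when batch is confounded with `warn_factor`.
#'
#' @param table complete [protein_table()].
#' @param design matching `sample_design`.
#' @param warn_factor design column checked for confounding with batch.
#' @return batch-centered `protein_table`.
#' @export
remove_batch_means <- function(table, design, warn_factor = "drug") {
  m <- unclass(table)
  design <- design[match(colnames(m), design$sample_id), , drop = FALSE]
  batches <- unique(design$batch)
  if (length(batches) < 2L) {
    warning("single batch: remove_batch_means is the identity")
    return(table)
  }
  if (warn_factor %in% names(design)) {
    tab <- base::table(design$batch, design[[warn_factor]])
    if (all(rowSums(tab > 0) == 1L)) {
      warning("batch is confounded with ", warn_factor)
    }
  }
  grand <- rowMeans(m)
  out <- m
  for (b in batches) {
    idx <- design$batch == b
    out[, idx] <- m[, idx] - rowMeans(m[, idx, drop = FALSE]) + grand
  }
  protein_table(out)
}

#' Principal component scores of samples
#'
#' Centered (unscaled) PCA of the samples in protein space, the standard
#' QC view for separation by age and treatment.
#'
#' @param table complete [protein_table()].
#' @param n_components number of components to return.
#' @return list: `scores` (sample x component), `var_explained`
#'   (fractions, non-increasing), `sdev`.
#' @export
pca_scores <- function(table, n_components = 2) {
  m <- unclass(table)
  assert_that(!anyNA(m), "pca_scores needs a complete table")
  assert_that(n_components <= min(dim(m)),
              "n_components exceeds min(samples, proteins)")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       var_explained = ve[seq_len(n_components)],
       sdev = pc$sdev)
}

#' Run the full preprocessing chain
#'
#' log2/z rescaling, median peptide-to-protein aggregation, per-cell
#' detection filtering and kNN imputation, in the order the pipeline
#' applies them.
#'
#' @param peptides a [peptide_table()].
#' @param design matching `sample_design`.
#' @param min_detected detection filter threshold per design cell.
#' @param k imputation neighbours.
#' @return list: `proteins` (complete `protein_table`), `record`
#'   (normalization record plus filter counts).
#' @export
preprocess_peptides <- function(peptides, design, min_detected = 3, k = 10) {
  norm <- log2_z_rescale(peptides)
  prot <- aggregate_peptides(norm$table, method = "median")
  filt <- filter_by_detection(prot, design, min_detected = min_detected)
  imp <- impute_missing(filt, k = k)
  rec <- norm$record
  rec$n_proteins_detected <- attr(filt, "n_retained")
  rec$n_proteins_dropped <- attr(filt, "n_dropped")
  list(proteins = imp, record = rec)
}
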
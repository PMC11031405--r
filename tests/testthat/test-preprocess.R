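test_that("log2/z rescaling reproduces the hand-computed worked case", {
  # rows [0,2] and [4,6] on log2 scale: global mean 3, global sd
  # sqrt(20/3); each row z-scores to +-1/sqrt(2) and rescales to
  # 3 -+ sqrt(10/3) = (1.174, 4.826)
  tab <- peptide_table(rbind(c(0, 2), c(4, 6)), c("p1", "p2"),
                       c("A", "B"), scale = "log2")
  out <- log2_z_rescale(tab)
  lo <- 3 - sqrt(10 / 3)
  hi <- 3 + sqrt(10 / 3)
  expect_equal(unname(out$table$values),
               rbind(c(lo, hi), c(lo, hi)), tolerance = 1e-12)
  expect_equal(out$record$global_mean, 3)
  expect_equal(out$record$global_sd, sqrt(20 / 3))
  expect_equal(round(c(lo, hi), 3), c(1.174, 4.826))
})

test_that("a single-row table is a fixed point of the rescale", {
  tab <- peptide_table(matrix(c(1, 2, 7), 1), "p1", "A", scale = "log2")
  out <- log2_z_rescale(tab)
  expect_equal(unname(out$table$values), matrix(c(1, 2, 7), 1),
               tolerance = 1e-12)
})

test_that("constant and near-empty rows are dropped and counted", {
  tab <- peptide_table(rbind(c(5, 5, 5, 5), c(1, 2, 3, 4),
                             c(9, NA, NA, NA)),
                       c("pc", "pv", "p1"), c("A", "A", "B"),
                       scale = "log2")
  out <- log2_z_rescale(tab)
  expect_equal(out$table$peptide_id, "pv")
  expect_equal(out$record$dropped_constant_rows, 2L)
  tab_all_const <- peptide_table(matrix(5, 2, 3), c("a", "b"),
                                 c("A", "B"), scale = "log2")
  expect_error(log2_z_rescale(tab_all_const), "constant")
  tab_neg <- peptide_table(matrix(c(0, 1, 2, 3), 2), c("a", "b"),
                           c("A", "B"), scale = "raw")
  expect_error(log2_z_rescale(tab_neg), "nonpositive")
})

test_that("every retained row acquires the global mean and sd to 1e-9", {
  set.seed(4)
  vals <- matrix(rnorm(200 * 8, 18, 2), 200, 8)
  vals[sample(length(vals), 150)] <- NA
  keepable <- rowSums(!is.na(vals)) >= 2
  tab <- peptide_table(vals[keepable, ], sprintf("p%03d", which(keepable)),
                       sprintf("P%03d", which(keepable)), scale = "log2")
  out <- log2_z_rescale(tab)
  y <- out$table$values
  rm_ <- rowMeans(y, na.rm = TRUE)
  rs <- apply(y, 1, sd, na.rm = TRUE)
  expect_true(all(abs(rm_ - out$record$global_mean) < 1e-9))
  expect_true(all(abs(rs - out$record$global_sd) < 1e-9))
})

test_that("peptide aggregation takes the per-sample median over present values", {
  tab <- peptide_table(rbind(c(1, 2), c(3, NA), c(100, 4), c(7, 8)),
                       c("a1", "a2", "a3", "b1"),
                       c("A", "A", "A", "B"), scale = "log2")
  prot <- aggregate_peptides(tab, method = "median")
  m <- unclass(prot)
  expect_equal(unname(m["A", 1]), 3)    # median of 1, 3, 100
  expect_equal(unname(m["A", 2]), 3)    # median of 2, 4 with one missing
  expect_equal(m["B", ], c(7, 8), ignore_attr = TRUE)  # single peptide
  prot2 <- aggregate_peptides(tab, method = "mean")
  expect_equal(unname(unclass(prot2)["A", 1]), mean(c(1, 3, 100)))
})

test_that("a protein-sample cell is missing only when all peptides are", {
  tab <- peptide_table(rbind(c(1, NA), c(3, NA)), c("a1", "a2"),
                       c("A", "A"), scale = "log2")
  m <- unclass(aggregate_peptides(tab))
  expect_false(is.na(m["A", 1]))
  expect_true(is.na(m["A", 2]))
})

test_that("detection filtering applies the every-group >= min rule", {
  d <- two_group_design(4)                       # 2 cells x 4 replicates
  vals <- rbind(c(1:4, 5:8),                     # 4 + 4 present
                c(1:4, 5, 6, 7, NA),             # 4 + 3 -> kept
                c(1:4, 5, 6, NA, NA),            # 4 + 2 -> dropped
                c(1:4, rep(NA, 4)))              # absent in one group
  rownames(vals) <- sprintf("P%d", 1:4)
  colnames(vals) <- d$sample_id
  out <- filter_by_detection(protein_table(vals), d, min_detected = 3)
  expect_setequal(rownames(out), c("P1", "P2"))
  expect_equal(attr(out, "n_dropped"), 2L)

  all_kept <- filter_by_detection(protein_table(vals), d, min_detected = 0)
  expect_equal(nrow(all_kept), 4L)
  expect_error(filter_by_detection(protein_table(vals), d, min_detected = 5),
               "min_detected")
})

test_that("raising min_detected never adds proteins (monotonicity)", {
  d <- two_group_design(4)
  set.seed(12)
  vals <- matrix(rnorm(50 * 8), 50, 8,
                 dimnames = list(sprintf("P%02d", 1:50), d$sample_id))
  vals[sample(length(vals), 120)] <- NA
  vals <- vals[rowSums(!is.na(vals)) > 0, ]
  prev <- rownames(vals)
  for (md in 1:4) {
    kept <- rownames(filter_by_detection(protein_table(vals), d,
                                         min_detected = md))
    expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("kNN imputation fills from nearest neighbours deterministically", {
  d <- two_group_design(2)
  # P1 matches complete neighbour P2 exactly on shared samples
  vals <- rbind(P1 = c(1, 2, 3, NA),
                P2 = c(1, 2, 3, 4),
                P3 = c(50, 60, 70, 80))
  colnames(vals) <- d$sample_id
  out <- unclass(impute_missing(protein_table(vals), k = 1))
  expect_equal(unname(out["P1", 4]), 4)
  # observed entries preserved bit-exactly
  expect_identical(out[!is.na(vals)], vals[!is.na(vals)])

  complete <- protein_table(vals[2:3, ])
  expect_identical(unclass(impute_missing(complete, k = 1)),
                   unclass(complete))
})

test_that("equidistant neighbours average and sparse rows fall back to row mean", {
  d <- two_group_design(2)
  # all three neighbours at squared distance 1 on shared samples
  vals <- rbind(q = c(0, 0, 0, NA),
                n1 = c(1, 0, 0, 10),
                n2 = c(0, 1, 0, 20),
                n3 = c(0, 0, 1, 30))
  colnames(vals) <- d$sample_id
  out <- unclass(impute_missing(protein_table(vals), k = 3))
  expect_equal(unname(out["q", 4]), mean(c(10, 20, 30)))  # direct-average oracle

  sparse <- rbind(s = c(5, NA, NA, NA), f = c(1, 2, 3, 4))
  colnames(sparse) <- d$sample_id
  out2 <- unclass(impute_missing(protein_table(sparse), k = 1))
  expect_equal(unname(out2["s", 2:4]), rep(5, 3))  # row-mean fallback

  empty <- rbind(e = rep(NA_real_, 4), f = c(1, 2, 3, 4))
  colnames(empty) <- d$sample_id
  expect_error(impute_missing(protein_table(empty), k = 1), "no present")
})

test_that("batch mean removal centers batches and keeps grand means", {
  d <- toy_design(n_rep = 2)                     # 2 batches of 16 samples
  vals <- matrix(0, 2, 16, dimnames = list(c("P1", "P2"), d$sample_id))
  vals[1, d$batch == "b_young"] <- 5
  vals[1, d$batch == "b_old"] <- 7
  vals[2, ] <- rnorm(16)
  out <- unclass(remove_batch_means(protein_table(vals), d,
                                    warn_factor = "drug"))
  expect_equal(unname(out[1, ]), rep(6, 16))
  expect_true(all(abs(rowMeans(out) - rowMeans(vals)) < 1e-9))

  single <- toy_design(n_rep = 2, batch_by_age = FALSE)
  vals2 <- matrix(rnorm(16), 1, 16,
                  dimnames = list("P1", single$sample_id))
  expect_warning(same <- remove_batch_means(protein_table(vals2), single),
                 "single batch")
  expect_equal(unclass(same), vals2)
})

test_that("orthogonal batch removal leaves a planted group difference intact", {
  # batch crossed with drug: removal must not touch the drug effect
  set.seed(33)
  d <- toy_design(n_rep = 2, ages = "young", inductions = "ctrl",
                  batch_by_age = FALSE)
  d$batch <- rep(c("b1", "b2"), 2)               # orthogonal to drug
  vals <- matrix(rnorm(30 * 4, 18), 30, 4,
                 dimnames = list(sprintf("P%02d", 1:30), d$sample_id))
  vals[, d$drug == "Rapa"] <- vals[, d$drug == "Rapa"] + 1
  vals[, d$batch == "b2"] <- vals[, d$batch == "b2"] + 0.7
  est <- function(m) rowMeans(m[, d$drug == "Rapa"]) -
    rowMeans(m[, d$drug == "EtOH"])
  before <- est(vals)
  after <- est(unclass(remove_batch_means(protein_table(vals), d)))
  expect_equal(after, before, tolerance = 1e-9)
})

test_that("PCA separates duplicated sample groups on PC1 and behaves", {
  set.seed(7)
  base <- rnorm(40)
  m <- cbind(a1 = base, a2 = base + rnorm(40, 0, 0.01),
             b1 = base + 3, b2 = base + 3 + rnorm(40, 0, 0.01))
  rownames(m) <- sprintf("P%02d", 1:40)
  pc <- pca_scores(protein_table(m), n_components = 3)
  expect_gt(pc$var_explained[1], 0.99)
  expect_true(all(sign(pc$scores[c("a1", "a2"), 1]) !=
                    sign(pc$scores[c("b1", "b2"), 1])))
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lt(abs(crossprod(pc$scores[, 1], pc$scores[, 2])), 1e-8)
  expect_error(pca_scores(protein_table(m), n_components = 5), "n_components")
})
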
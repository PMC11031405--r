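test_that("two-group OLS recovers the group-mean difference", {
  d <- two_group_design(4)
  set.seed(1)
  m <- matrix(rnorm(20 * 8), 20, 8,
              dimnames = list(sprintf("P%02d", 1:20), d$sample_id))
  fit <- fit_models(protein_table(m), d)
  ct <- default_contrasts(ages = "young", inductions = "ctrl")$EtOHvsRapa
  res <- moderated_test(fit, list(d0 = 0, s0_sq = 1),
                        contrast_spec("EtOHvsRapa", ct))
  rapa <- d$sample_id[d$drug == "Rapa"]
  etoh <- d$sample_id[d$drug == "EtOH"]
  expect_equal(res$log2fc,
               unname(rowMeans(m[, rapa]) - rowMeans(m[, etoh])),
               tolerance = 1e-12)
})

test_that("an orthogonal batch covariate leaves the contrast untouched", {
  d <- two_group_design(4)
  d$batch <- rep(c("b1", "b2"), 4)               # balanced across drug
  set.seed(2)
  m <- matrix(rnorm(15 * 8), 15, 8,
              dimnames = list(sprintf("P%02d", 1:15), d$sample_id))
  ct <- default_contrasts(ages = "young", inductions = "ctrl")$EtOHvsRapa
  f0 <- fit_models(protein_table(m), d)
  f1 <- fit_models(protein_table(m), d, covariates = "batch")
  fc0 <- as.vector(f0$coef %*% replace(numeric(2), match(names(ct), colnames(f0$coef)), ct))
  cv1 <- stats::setNames(numeric(ncol(f1$coef)), colnames(f1$coef))
  cv1[names(ct)] <- ct
  fc1 <- as.vector(f1$coef %*% cv1)
  expect_equal(fc1, fc0, tolerance = 1e-10)
})

test_that("rank-deficient designs error naming the aliased term", {
  d <- two_group_design(4)                        # batch b1 for everyone?
  d$batch <- ifelse(d$drug == "Rapa", "b2", "b1") # aliased with drug
  m <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(sprintf("P%02d", 1:10), d$sample_id))
  expect_error(fit_models(protein_table(m), d, covariates = "batch"),
               "aliased")
})

test_that("zero-residual data yields s2 = 0 and df = n - rank", {
  d <- two_group_design(2)
  m <- matrix(NA_real_, 1, 4, dimnames = list("P1", d$sample_id))
  m[1, d$drug == "EtOH"] <- 1
  m[1, d$drug == "Rapa"] <- 2
  fit <- fit_models(protein_table(m), d)
  expect_equal(unname(fit$s2), 0)
  expect_equal(fit$df[1], 4 - 2)
})

test_that("trigamma inversion matches a bisection oracle to 1e-8", {
  bisect <- function(y, lo = 1e-8, hi = 1e8) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (trigamma(mid) > y) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (y in c(0.01, 0.1, 0.5, 1, 2, 10, 100)) {
    expect_equal(trigamma_inverse(y), bisect(y), tolerance = 1e-8)
  }
  expect_identical(trigamma_inverse(0), Inf)
})

test_that("the variance prior is recovered from scaled chi-square draws", {
  d0 <- 4; s0 <- 1.5; d <- 6
  set.seed(10)
  ests <- replicate(3, {
    sigma2 <- d0 * s0 / rchisq(3000, df = d0)
    s2 <- sigma2 * rchisq(3000, df = d) / d
    estimate_moderation(s2, d)$d0
  })
  expect_true(all(abs(ests - d0) / d0 < 0.25))
})

test_that("degenerate variance inputs give the no-dispersion limit", {
  out <- estimate_moderation(rep(2, 100), 4)
  expect_identical(out$d0, Inf)
  expect_equal(out$s0_sq, 2)
  expect_error(estimate_moderation(rep(2, 10), 4), "30")
})

test_that("posterior variance follows the shrinkage formula and its limits", {
  fit <- make_fit(log2fc = c(1, -2), s2 = c(4, 4), df = 2)
  # d0=4, s0^2=1, d=2, s^2=4 -> s2_post = (4 + 8)/6 = 2
  res <- moderated_test(fit, list(d0 = 4, s0_sq = 1),
                        contrast_spec("c", c(A = 1, B = -1)))
  expect_equal(res$t_mod[1], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(res$df_total, rep(6, 2))

  # d0 = 0: ordinary t with d df
  set.seed(3)
  x <- rnorm(4); y <- rnorm(4)
  d <- two_group_design(2)
  m <- matrix(NA_real_, 1, 4, dimnames = list("P1", d$sample_id))
  m[1, d$drug == "EtOH"] <- x[1:2]
  m[1, d$drug == "Rapa"] <- y[1:2]
  fit2 <- fit_models(protein_table(m), d)
  res2 <- moderated_test(fit2, list(d0 = 0, s0_sq = 1),
                         contrast_spec("c", default_contrasts(
                           ages = "young", inductions = "ctrl")$EtOHvsRapa))
  tt <- t.test(y[1:2], x[1:2], var.equal = TRUE)
  expect_equal(res2$t_mod, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)
})

test_that("s2_post always lies between the observed and prior variance", {
  set.seed(8)
  s2 <- rchisq(200, 3)
  fit <- make_fit(log2fc = rnorm(200), s2 = s2, df = 5)
  for (params in list(list(d0 = 2, s0_sq = 0.8), list(d0 = 50, s0_sq = 3))) {
    res <- moderated_test(fit, params, contrast_spec("c", c(A = 1, B = -1)))
    s2_post <- (1 / res$t_mod^2) * res$log2fc^2   # var_unscaled = 1
    lo <- pmin(s2, params$s0_sq) - 1e-12
    hi <- pmax(s2, params$s0_sq) + 1e-12
    expect_true(all(s2_post >= lo & s2_post <= hi))
  }
})

test_that("huge prior df collapses all variances onto the prior", {
  set.seed(9)
  fit <- make_fit(log2fc = rnorm(50), s2 = rchisq(50, 3), df = 5)
  res <- moderated_test(fit, list(d0 = 1e9, s0_sq = 2),
                        contrast_spec("c", c(A = 1, B = -1)))
  expect_equal(res$t_mod, res$log2fc / sqrt(2), tolerance = 1e-6)
  res_inf <- moderated_test(fit, list(d0 = Inf, s0_sq = 2),
                            contrast_spec("c", c(A = 1, B = -1)))
  expect_equal(res_inf$t_mod, res_inf$log2fc / sqrt(2), tolerance = 1e-12)
})

test_that("the moderated pipeline agrees with limma on the same data", {
  skip_if_not_installed("limma")
  d <- two_group_design(4)
  set.seed(14)
  # heterogeneous per-protein variances so the prior df is finite
  sds <- sqrt(3 * 0.8 / rchisq(300, df = 3))
  m <- matrix(rnorm(300 * 8, 18, rep(sds, 8)), 300, 8,
              dimnames = list(sprintf("P%03d", 1:300), d$sample_id))
  m[1:30, d$drug == "Rapa"] <- m[1:30, d$drug == "Rapa"] + 1

  ct <- default_contrasts(ages = "young", inductions = "ctrl")$EtOHvsRapa
  fit <- fit_models(protein_table(m), d)
  params <- estimate_moderation(fit$s2, fit$df)
  mine <- moderated_test(fit, params, contrast_spec("EtOHvsRapa", ct))

  group <- factor(d$drug, levels = c("EtOH", "Rapa"))
  X <- stats::model.matrix(~0 + group)
  lfit <- limma::lmFit(m, X)
  lfit <- limma::contrasts.fit(lfit, c(-1, 1))
  eb <- limma::eBayes(lfit)
  expect_equal(params$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(params$s0_sq, eb$s2.prior, tolerance = 1e-6)
  expect_equal(mine$t_mod, unname(eb$t[, 1]), tolerance = 1e-8)
  expect_equal(mine$p, unname(eb$p.value[, 1]), tolerance = 1e-8)
})

test_that("S6K-dependence labels follow the three-way p-value rule", {
  mk <- function(ids, ps) data.frame(protein_id = ids, p = ps,
                                     stringsAsFactors = FALSE)
  ids <- c("P1", "P2", "P3")
  res <- classify_s6k_dependent(mk(ids, c(0.01, 0.01, 0.06)),
                                mk(ids, c(0.03, 0.03, 0.01)),
                                mk(ids, c(0.20, 0.04, 0.50)))
  expect_equal(res$label,
               c("TORC1_S6K_dependent", "unlabeled", "unlabeled"))
  # permutation invariance
  perm <- classify_s6k_dependent(mk(rev(ids), rev(c(0.01, 0.01, 0.06))),
                                 mk(ids, c(0.03, 0.03, 0.01)),
                                 mk(ids, c(0.20, 0.04, 0.50)))
  expect_identical(res, perm)
})

test_that("gene-set shift test matches exact enumeration and approximations", {
  de <- data.frame(protein_id = c("a", "b", "c", "d"),
                   log2fc = c(-1, -2, 1, 2), stringsAsFactors = FALSE)
  # enumeration over C(4,2) splits: one-sided 1/6, two-sided 1/3
  out <- gene_set_shift_test(de, gene_set("s", c("a", "b", "x")),
                             exact_max = 10)
  expect_equal(out$p, 1 / 3, tolerance = 1e-12)
  expect_lt(out$median_shift, 0)

  same <- data.frame(protein_id = letters[1:6], log2fc = rep(1, 6),
                     stringsAsFactors = FALSE)
  out2 <- gene_set_shift_test(same, gene_set("s", letters[1:3]))
  expect_equal(out2$p, 1)

  set.seed(15)
  big <- data.frame(protein_id = sprintf("g%02d", 1:60),
                    log2fc = rnorm(60), stringsAsFactors = FALSE)
  setg <- gene_set("s", sprintf("g%02d", 1:10))
  p_exact <- suppressWarnings(
    stats::wilcox.test(big$log2fc[1:10], big$log2fc[11:60],
                       exact = TRUE))$p.value
  p_approx <- gene_set_shift_test(big, setg, exact_max = 5)$p
  expect_lt(abs(p_exact - p_approx), 0.02)
  expect_error(gene_set_shift_test(big, gene_set("s", c("zz", "yy", "g01"))),
               "2")
})

test_that("gene-set fold-change matrices apply the intersection rule", {
  r1 <- data.frame(protein_id = c("A", "B", "C", "D"),
                   log2fc = c(1, 2, 3, 4), stringsAsFactors = FALSE)
  r2 <- data.frame(protein_id = c("A", "B", "C"),
                   log2fc = c(5, 6, 7), stringsAsFactors = FALSE)
  m <- extract_geneset_fc_matrix(list(c1 = r1, c2 = r2),
                                 gene_set("amps", c("A", "C", "D")))
  expect_equal(rownames(m), c("A", "C"))          # D absent from c2
  expect_identical(m["A", "c1"], 1)               # bit-exact copies
  expect_identical(m["C", "c2"], 7)
  empty <- extract_geneset_fc_matrix(list(c1 = r1),
                                     gene_set("none", "ZZ"))
  expect_equal(nrow(empty), 0L)
})
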
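#' Per-protein factorial linear model fits
#'
#' Ordinary least squares of every protein on the cell-mean design
#' (one coefficient per age.drug.induction cell, no intercept) plus
#' optional covariate factors such as the labeling/dissection batch.
#' Residual variance `s2 = RSS / d` with `d = n - rank`.
#'
#' @param table complete [protein_table()].
#' @param design matching `sample_design`.
#' @param covariates character vector of design columns to adjust for
#'   (e.g. `"batch"`); must not be aliased with the design cells.
#' @return object of class `protein_fit`: list with `coef` (protein x
#'   coefficient), `s2`, `df` (residual df), `cov_unscaled`
#'   (`(X'X)^-1`), `cells` (cell coefficient names), `n`.
#' @export
fit_models <- function(table, design, covariates = character(0)) {
  m <- unclass(table)
  design <- design[match(colnames(m), design$sample_id), , drop = FALSE]
  cell <- factor(design_cells(design))
  X <- stats::model.matrix(~ 0 + cell)
  colnames(X) <- levels(cell)
  for (cv in covariates) {
    f <- factor(design[[cv]])
    if (nlevels(f) < 2L) next
    C <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(C) <- paste0(cv, levels(f)[-1])
    X <- cbind(X, C)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort_ctx("design matrix is rank deficient; aliased term(s): ",
              paste(aliased, collapse = ", "))
  }
  Y <- t(m)                                     # samples x proteins
  coef <- qr.coef(qrX, Y)                       # coefficients x proteins
  resid <- Y - X %*% coef
  d <- nrow(X) - qrX$rank
  s2 <- colSums(resid^2) / d
  XtXinv <- chol2inv(chol(crossprod(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  structure(list(coef = t(coef), s2 = s2, df = rep(d, ncol(Y)),
                 cov_unscaled = XtXinv, cells = levels(cell),
                 n = nrow(X)),
            class = "protein_fit")
}

#' Define a named cell-mean contrast
#'
#' @param name contrast label (e.g. `"EtOHvsRapa"`).
#' @param coefficients named numeric vector over design-cell labels;
#'   must sum to zero.
#' @return object of class `contrast_spec`.
#' @export
contrast_spec <- function(name, coefficients) {
  assert_that(abs(sum(coefficients)) < 1e-12,
              "contrast coefficients must sum to zero")
  assert_that(!is.null(names(coefficients)), "coefficients must be named by cell")
  structure(list(name = name, coefficients = coefficients),
            class = "contrast_spec")
}

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by monotone Newton iteration on
#' `1/trigamma` (trigamma is strictly decreasing). Used to fit the prior
#' degrees of freedom of the variance model.
#'
#' @param y positive target value(s).
#' @return x with `trigamma(x) = y` to ~1e-12 relative accuracy;
#'   `Inf` where `y <= 0`.
#' @export
trigamma_inverse <- function(y) {
  out <- numeric(length(y))
  for (i in seq_along(y)) {
    yi <- y[i]
    if (!is.finite(yi) || yi <= 0) { out[i] <- Inf; next }
    if (yi > 1e7) { out[i] <- 1 / sqrt(yi); next }
    x <- 0.5 + 1 / yi                       # starting value, asymptotics
    for (it in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
    }
    out[i] <- x
  }
  out
}

#' Empirical-Bayes moderation parameters for residual variances
#'
#' Fits a scaled inverse chi-square prior (`d0`, `s0_sq`) to the observed
#' per-protein residual variances by the log-variance moment method:
#' `log s2` has mean `log s0_sq + digamma(d/2) - log(d/2) -
#' digamma(d0/2) + log(d0/2)` and excess variance `trigamma(d0/2)` beyond
#' the sampling term `trigamma(d/2)`. `d0` is recovered by trigamma
#' inversion; when the empirical excess is not positive there is no
#' evidence of variance dispersion and `d0 = Inf`.
#'
#' @param s2 per-protein residual variances (positive; nonpositive values
#'   are excluded from estimation).
#' @param df residual degrees of freedom (scalar or per-protein vector).
#' @return list with `d0` (prior df, possibly `Inf`) and `s0_sq`.
#' @export
estimate_moderation <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df >= 1
  assert_that(sum(ok) >= 30,
              "need at least 30 proteins with positive s2 and df >= 1")
  s2 <- s2[ok]; df <- df[ok]
  z <- log(s2) - digamma(df / 2) + log(df / 2)   # E[z] = log s0^2 - digamma(d0/2) + log(d0/2)
  evar <- stats::var(z) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0) {
    # no excess dispersion: common variance, estimated by the plain mean
    return(list(d0 = Inf, s0_sq = mean(s2)))
  }
  half_d0 <- trigamma_inverse(evar)
  d0 <- 2 * half_d0
  s0_sq <- exp(mean(z) + digamma(half_d0) - log(half_d0))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-test for a contrast
#'
#' Shrinks each protein's residual variance toward the prior:
#' `s2_post = (d0 * s0_sq + d * s2) / (d0 + d)` (equal to `s0_sq` when
#' `d0 = Inf`), forms `t = log2fc / sqrt(c' (X'X)^-1 c * s2_post)` and a
#' two-sided p-value on `d0 + d` degrees of freedom. Benjamini-Hochberg
#' adjusted p-values are reported alongside the raw ones; the pipeline's
#' significance filters use the raw p, matching the P < 0.05 convention.
#'
#' @param fit a [fit_models()] result.
#' @param params moderation parameters from [estimate_moderation()].
#' @param contrast a [contrast_spec()] over the fit's cells.
#' @return `data.frame` of class `de_result`: `protein_id`, `log2fc`,
#'   `t_mod`, `p`, `p_adj`, `df_total`, `contrast`.
#' @export
moderated_test <- function(fit, params, contrast) {
  cells <- contrast$coefficients
  missing_cells <- setdiff(names(cells), colnames(fit$coef))
  if (length(missing_cells)) {
    abort_ctx("contrast references unknown cell(s): ",
              paste(missing_cells, collapse = ", "))
  }
  cvec <- stats::setNames(numeric(ncol(fit$coef)), colnames(fit$coef))
  cvec[names(cells)] <- cells
  log2fc <- as.vector(fit$coef %*% cvec)
  var_unscaled <- as.numeric(t(cvec) %*% fit$cov_unscaled %*% cvec)
  d0 <- params$d0; s0 <- params$s0_sq
  d <- fit$df
  s2_post <- if (is.infinite(d0)) rep(s0, length(fit$s2)) else
    (d0 * s0 + d * fit$s2) / (d0 + d)
  if (any(d0 + d <= 0)) abort_ctx("nonpositive total degrees of freedom")
  se <- sqrt(var_unscaled * s2_post)
  t_mod <- log2fc / se
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  res <- data.frame(protein_id = rownames(fit$coef),
                    log2fc = log2fc, t_mod = t_mod, p = p,
                    p_adj = stats::p.adjust(p, "BH"),
                    df_total = df_total,
                    contrast = contrast$name,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Differential expression for a set of contrasts
#'
#' Convenience wrapper: fits the cell-mean models, estimates moderation
#' parameters once per stratum, and tests each contrast. Contrasts may
#' carry a `subset` (named list of design column = level) restricting the
#' samples; contrasts sharing a subset share a fit and moderation
#' parameters, so e.g. the two TMT age strata are moderated separately.
#'
#' @param table complete [protein_table()].
#' @param design matching `sample_design`.
#' @param contrasts named list; each element is a numeric cell-coefficient
#'   vector or a list `list(coefficients =, subset =)`.
#' @param covariates passed to [fit_models()].
#' @return named list of `de_result` tables.
#' @export
de_analysis <- function(table, design, contrasts, covariates = character(0)) {
  norm_contrasts <- lapply(names(contrasts), function(nm) {
    ct <- contrasts[[nm]]
    if (is.numeric(ct)) ct <- list(coefficients = ct, subset = NULL)
    list(name = nm, coefficients = ct$coefficients, subset = ct$subset)
  })
  subset_key <- vapply(norm_contrasts, function(ct) {
    if (is.null(ct$subset)) "" else
      paste(names(ct$subset), unlist(ct$subset), sep = "=", collapse = ",")
  }, character(1))
  results <- list()
  for (key in unique(subset_key)) {
    group <- norm_contrasts[subset_key == key]
    sub_design <- design
    if (nzchar(key)) {
      ss <- group[[1]]$subset
      keep <- rep(TRUE, nrow(design))
      for (f in names(ss)) keep <- keep & design[[f]] == ss[[f]]
      sub_design <- design[keep, , drop = FALSE]
    }
    sub_table <- protein_table(unclass(table)[, sub_design$sample_id,
                                              drop = FALSE])
    fit <- fit_models(sub_table, sub_design, covariates = covariates)
    params <- estimate_moderation(fit$s2, fit$df)
    for (ct in group) {
      results[[ct$name]] <-
        moderated_test(fit, params, contrast_spec(ct$name, ct$coefficients))
    }
  }
  results[names(contrasts)]
}

#' Classify proteins as TORC1-S6K dependent
#'
#' A protein is labeled dependent when it is significantly changed
#' (p < alpha) by both S6K knockdown and rapamycin treatment but not
#' altered by rapamycin under constitutive S6K activation (p >= alpha).
#'
#' @param res_rnai DE table for the knockdown-induction contrast.
#' @param res_rapa DE table for rapamycin vs control.
#' @param res_rapa_ca DE table for rapamycin under activated S6K.
#' @param alpha significance threshold on the raw p-values.
#' @return `data.frame` `protein_id`, `label` (`"TORC1_S6K_dependent"` or
#'   `"unlabeled"`), restricted to proteins shared by all three tables
#'   and sorted by protein id.
#' @export
classify_s6k_dependent <- function(res_rnai, res_rapa, res_rapa_ca,
                                   alpha = 0.05) {
  common <- sort(Reduce(intersect, list(res_rnai$protein_id,
                                        res_rapa$protein_id,
                                        res_rapa_ca$protein_id)))
  if (length(common) == 0L) abort_ctx("no shared proteins across contrasts")
  p1 <- res_rnai$p[match(common, res_rnai$protein_id)]
  p2 <- res_rapa$p[match(common, res_rapa$protein_id)]
  p3 <- res_rapa_ca$p[match(common, res_rapa_ca$protein_id)]
  dep <- p1 < alpha & p2 < alpha & p3 >= alpha
  data.frame(protein_id = common,
             label = ifelse(dep, "TORC1_S6K_dependent", "unlabeled"),
             stringsAsFactors = FALSE)
}

#' Rank-sum shift test for a gene set
#'
#' Two-sided Wilcoxon rank-sum test of the set members' log2 fold
#' changes against the complement — the test behind statements like
#' "5'TOP proteins were significantly downregulated". Exact enumeration
#' when both groups have at most `exact_max` values, normal approximation
#' with tie correction otherwise.
#'
#' @param result a `de_result` table.
#' @param set a [gene_set()].
#' @param exact_max exact-test size cutoff per group.
#' @return list: `statistic` (rank-sum W), `p`, `median_shift`
#'   (median set log2fc minus median complement log2fc), `n_set`.
#' @export
gene_set_shift_test <- function(result, set, exact_max = 10) {
  in_set <- result$protein_id %in% set$members
  assert_that(sum(in_set) >= 2, "need >= 2 set members present in the result")
  assert_that(sum(!in_set) >= 1, "empty complement")
  x <- result$log2fc[in_set]
  y <- result$log2fc[!in_set]
  exact <- length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact))
  p <- wt$p.value
  # degenerate case: no rank variation (e.g. all values tied) carries
  # no evidence of a shift
  if (!is.finite(p)) p <- 1
  list(statistic = unname(wt$statistic), p = p,
       median_shift = stats::median(x) - stats::median(y),
       n_set = length(x))
}

#' Gene x contrast log2 fold-change matrix for a gene set
#'
#' Rows are the set members detected in every supplied DE table (the
#' intersection rule used for the AMP and NF-kB target heatmaps); cells
#' are the corresponding log2 fold changes, copied bit-exactly.
#'
#' @param results named list of `de_result` tables (one per contrast).
#' @param set a [gene_set()].
#' @return numeric matrix, possibly with zero rows; attribute
#'   `detection_rule` documents the intersection.
#' @export
extract_geneset_fc_matrix <- function(results, set) {
  assert_that(length(results) >= 1, "need at least one DE table")
  detected <- Reduce(intersect, lapply(results, `[[`, "protein_id"))
  rows <- sort(intersect(set$members, detected))
  m <- matrix(NA_real_, length(rows), length(results),
              dimnames = list(rows, names(results)))
  for (j in seq_along(results)) {
    m[, j] <- results[[j]]$log2fc[match(rows, results[[j]]$protein_id)]
  }
  attr(m, "detection_rule") <- "set members detected in every contrast"
  m
}
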
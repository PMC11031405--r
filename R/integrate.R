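# Annotation-level classification rules and cross-dataset aggregation.
# All rules are pure functions of term p-values and directions; tables
# are expected in collapsed one-row-per-term form (see signed_scores()).

collapse_if_needed <- function(tab) {
  if (anyDuplicated(tab$term_id)) signed_scores(tab) else tab
}

#' Label age-related terms
#'
#' Terms significantly enriched (p < alpha) in the old-versus-young
#' comparison of the control treatment group, labeled with their
#' regulation direction.
#'
#' @param enrichment enrichment table for the old-vs-young control
#'   contrast.
#' @param alpha significance threshold.
#' @return `data.frame` `term_id`, `class` (`"age_related"`),
#'   `direction`, `signed_score`.
#' @export
classify_age_terms <- function(enrichment, alpha = 0.05) {
  tab <- collapse_if_needed(enrichment)
  keep <- tab$p < alpha
  data.frame(term_id = tab$term_id[keep],
             class = rep("age_related", sum(keep)),
             direction = tab$direction[keep],
             signed_score = tab$signed_score[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify rapamycin-induced terms by S6K-activation dependence
#'
#' Compares the rapamycin-vs-control enrichment (EtOHvsRapa) with the
#' rapamycin enrichment under constitutively active S6K (RUvsRURapa),
#' writing `L(x) = -log10 p_x`:
#' dependent iff `L(EtOHvsRapa) - L(RUvsRURapa) > margin` (the
#' rapamycin p-value is more than 10^margin times smaller than under
#' activation); independent iff `L(EtOHvsRapa) > margin` and the
#' difference is `<= margin`. Terms absent from one table count as p = 1
#' there (no evidence). Directions are carried from the EtOHvsRapa
#' table.
#'
#' @param enr_rapa enrichment table for rapamycin vs control.
#' @param enr_rapa_ca enrichment table for rapamycin under activated
#'   S6K.
#' @param margin rule margin on the -log10 p scale (default 2, i.e. a
#'   100-fold p-value ratio).
#' @return `data.frame` `term_id`, `class`
#'   (`"s6kca_dependent_rapa"`/`"s6kca_independent_rapa"`), `direction`,
#'   `score_rapa`, `score_rapa_ca`.
#' @export
classify_rapa_terms <- function(enr_rapa, enr_rapa_ca, margin = 2) {
  a <- collapse_if_needed(enr_rapa)
  b <- collapse_if_needed(enr_rapa_ca)
  terms <- sort(union(a$term_id, b$term_id))
  la <- stats::setNames(rep(0, length(terms)), terms)   # -log10(1) = 0
  la[a$term_id] <- -log10(a$p)
  lb <- stats::setNames(rep(0, length(terms)), terms)
  lb[b$term_id] <- -log10(b$p)
  dirs <- stats::setNames(rep(NA_character_, length(terms)), terms)
  dirs[a$term_id] <- a$direction
  dependent <- (la - lb) > margin
  independent <- la > margin & (la - lb) <= margin
  keep <- dependent | independent
  data.frame(term_id = terms[keep],
             class = ifelse(dependent[keep], "s6kca_dependent_rapa",
                            "s6kca_independent_rapa"),
             direction = dirs[keep],
             score_rapa = unname(la[keep]),
             score_rapa_ca = unname(lb[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Label terms induced by S6K inhibition
#'
#' Terms with `-log10 p > threshold` in the knockdown-induction contrast
#' of the RNAi dataset (threshold 2 by default, consistent with the
#' rapamycin rules; configurable down to `-log10(0.05)`).
#'
#' @param enrichment enrichment table for the RNAi induction contrast.
#' @param threshold on the -log10 p scale.
#' @return `data.frame` `term_id`, `class` (`"s6k_inhibition_induced"`),
#'   `direction`, `signed_score`.
#' @export
classify_s6k_inhibition_terms <- function(enrichment, threshold = 2) {
  tab <- collapse_if_needed(enrichment)
  keep <- -log10(tab$p) > threshold
  data.frame(term_id = tab$term_id[keep],
             class = rep("s6k_inhibition_induced", sum(keep)),
             direction = tab$direction[keep],
             signed_score = tab$signed_score[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-dataset concordance of enriched terms
#'
#' Keeps the terms significantly enriched (p < alpha) in the same
#' direction in all three datasets, reporting each dataset's signed
#' significance score — the shared up-/down-regulated annotation rule of
#' the three-dataset liver integration.
#'
#' @param tables named list of exactly three enrichment tables (one per
#'   dataset), each built on the common-gene universe.
#' @param alpha per-dataset significance threshold.
#' @return `data.frame` `term_id`, `direction`, one `score_<dataset>`
#'   column per input table.
#' @export
cross_dataset_concordance <- function(tables, alpha = 0.05) {
  assert_that(length(tables) == 3, "need exactly 3 enrichment tables")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("dataset", seq_along(tables))
  }
  tabs <- lapply(tables, collapse_if_needed)
  terms <- sort(Reduce(intersect, lapply(tabs, `[[`, "term_id")))
  if (length(terms) == 0L) {
    out <- data.frame(term_id = character(0), direction = character(0),
                      stringsAsFactors = FALSE)
    for (nm in names(tabs)) out[[paste0("score_", nm)]] <- numeric(0)
    return(out)
  }
  ps <- sapply(tabs, function(t) t$p[match(terms, t$term_id)])
  dirs <- sapply(tabs, function(t) t$direction[match(terms, t$term_id)])
  scores <- sapply(tabs, function(t) t$signed_score[match(terms, t$term_id)])
  if (length(terms) == 1L) {
    ps <- matrix(ps, nrow = 1); dirs <- matrix(dirs, nrow = 1)
    scores <- matrix(scores, nrow = 1, dimnames = list(NULL, names(tabs)))
  }
  sig <- rowSums(ps < alpha) == 3L
  same_dir <- apply(dirs, 1L, function(d) length(unique(d)) == 1L)
  keep <- sig & same_dir
  out <- data.frame(term_id = terms[keep],
                    direction = dirs[keep, 1],
                    stringsAsFactors = FALSE, row.names = NULL)
  for (j in seq_along(tabs)) {
    out[[paste0("score_", names(tabs)[j])]] <- scores[keep, j]
  }
  out
}

#' Restrict differential results to the shared gene universe
#'
#' Intersects the protein/gene ids of two or more DE tables; downstream
#' propagation and enrichment for the integration run on these common
#' genes only.
#'
#' @param de_tables list of `de_result` tables.
#' @return list with `tables` (restricted, original order) and
#'   `n_common`.
#' @export
restrict_to_common_genes <- function(de_tables) {
  assert_that(length(de_tables) >= 2, "need at least two DE tables")
  common <- Reduce(intersect, lapply(de_tables, `[[`, "protein_id"))
  if (length(common) == 0L) abort_ctx("no genes shared across the tables")
  restricted <- lapply(de_tables, function(t) {
    out <- t[t$protein_id %in% common, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  list(tables = restricted, n_common = length(common))
}
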
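#' Propagate annotations to ancestor terms
#'
#' When the annotation set carries a term -> parents map (an is_a
#' closure input), every gene annotated to a term is also annotated to
#' all of the term's ancestors; a diamond-shaped hierarchy counts each
#' gene once. Without a parent map this is the identity.
#'
#' @param annotations an [annotation_set()].
#' @return an `annotation_set` with up-propagated gene sets.
#' @export
close_annotations <- function(annotations) {
  parents <- annotations$parents
  if (is.null(parents) || length(parents) == 0L) return(annotations)
  ancestors_of <- function(term, seen = character(0)) {
    ps <- parents[[term]]
    if (is.null(ps)) return(character(0))
    if (any(ps %in% seen)) {
      abort_ctx("cycle in parent map involving: ",
                intersect(ps, seen)[1])
    }
    out <- ps
    for (p in ps) out <- union(out, ancestors_of(p, c(seen, term)))
    out
  }
  terms <- annotations$terms
  closed <- terms
  for (term in names(terms)) {
    for (anc in ancestors_of(term)) {
      closed[[anc]] <- union(closed[[anc]] %||% character(0), terms[[term]])
    }
  }
  closed <- lapply(closed, function(g) sort(unique(g)))
  closed <- closed[order(names(closed))]
  structure(list(terms = closed, parents = parents),
            class = "annotation_set")
}

# Upper hypergeometric tail P(X >= k), X ~ Hypergeom(N, K, n):
# the one-sided Fisher over-representation p-value. Vectorized over k/K.
hyper_tail_p <- function(k, K, n, N) {
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' One-sided Fisher term enrichment of selected nodes
#'
#' For each direction (up/down selection) and each term with at least
#' `min_size` genes in the background universe, tests over-representation
#' of the term in the selection with the one-sided Fisher exact test:
#' p = P(X >= k) for X ~ Hypergeometric(N, K, n), where N is the
#' background size, K the term size in background, n the selection size
#' and k the overlap. The background is the propagation-eligible
#' universe (degree-filtered network nodes with measured input). Signed
#' significance scores are attached: -log10(p), positive for up,
#' negative for down.
#'
#' @param selection a [select_nodes()] result (or a list with `up` and
#'   `down` character vectors).
#' @param background character vector, the background universe;
#'   selections must be subsets of it.
#' @param annotations an [annotation_set()].
#' @param min_size minimal term size in background.
#' @return `data.frame` of class `enrichment_table`: `term_id`,
#'   `direction`, `k`, `K`, `n`, `N`, `p`, `signed_score`; attribute
#'   `n_below_min_size` counts skipped terms.
#' @export
fisher_enrichment <- function(selection, background, annotations,
                              min_size = 5) {
  background <- unique(as.character(background))
  N <- length(background)
  if (N == 0L) abort_ctx("empty background")
  assert_that(all(selection$up %in% background) &&
                all(selection$down %in% background),
              "selection must be a subset of the background")
  term_bg <- lapply(annotations$terms, function(g) intersect(g, background))
  sizes <- lengths(term_bg)
  n_small <- sum(sizes < min_size)
  term_bg <- term_bg[sizes >= min_size]
  rows <- list()
  for (direction in c("up", "down")) {
    sel <- selection[[direction]]
    n <- length(sel)
    if (n == 0L) next
    k <- vapply(term_bg, function(g) length(intersect(g, sel)), integer(1))
    K <- lengths(term_bg)
    p <- hyper_tail_p(k, K, n, N)
    nt <- length(term_bg)
    rows[[direction]] <- data.frame(term_id = names(term_bg) %||% character(0),
                                    direction = rep(direction, nt),
                                    k = k, K = K,
                                    n = rep(n, nt), N = rep(N, nt), p = p,
                                    stringsAsFactors = FALSE,
                                    row.names = NULL)
  }
  empty <- data.frame(term_id = character(0), direction = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  tab <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(tab) <- NULL
  tab$signed_score <- ifelse(tab$direction == "up", 1, -1) * (-log10(tab$p))
  tab <- tab[order(tab$term_id, tab$direction), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_below_min_size") <- n_small
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Collapse an enrichment table to one signed score per term
#'
#' When a term was tested in both directions, keeps the direction with
#' the smaller p-value (ties resolved toward the larger overlap, then
#' "up", for determinism) and reports its signed significance score
#' -log10(p) (positive up, negative down). p-values of zero are capped
#' at the machine minimum with a warning.
#'
#' @param table an `enrichment_table` from [fisher_enrichment()].
#' @return `enrichment_table` with one row per term.
#' @export
signed_scores <- function(table) {
  if (any(table$p <= 0)) {
    warning("p-values of 0 capped at the machine minimum")
    table$p <- pmax(table$p, .Machine$double.xmin)
  }
  ord <- order(table$term_id, table$p, -table$k,
               match(table$direction, c("up", "down")))
  tab <- table[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab$term_id), , drop = FALSE]
  tab$signed_score <- ifelse(tab$direction == "up", 1, -1) * (-log10(tab$p))
  tab <- tab[order(tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}
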
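#' Build the normalized propagation operator
#'
#' Forms the (sparse) adjacency of the interaction graph — binary by
#' default, or `combined_score / 1000` weighted — and normalizes it
#' either symmetrically, `W = D^(-1/2) A D^(-1/2)` (spectrum in [-1, 1]),
#' or row-stochastically, `W = D^(-1) A`. Node order is fixed to the
#' graph's sorted node ids and recorded.
#'
#' @param graph an `interaction_graph`.
#' @param normalization `"symmetric"` or `"row"`.
#' @param weighting `"binary"` or `"score"`.
#' @return object of class `propagation_operator`: list with `W`
#'   (sparse matrix), `nodes`, `degree` (interaction counts),
#'   `normalization`, `weighting`.
#' @export
build_operator <- function(graph, normalization = c("symmetric", "row"),
                           weighting = c("binary", "score")) {
  normalization <- match.arg(normalization)
  weighting <- match.arg(weighting)
  nodes <- graph$nodes
  assert_that(length(nodes) > 0, "empty graph")
  i <- match(graph$edges$protein1, nodes)
  j <- match(graph$edges$protein2, nodes)
  w <- if (weighting == "binary") rep(1, nrow(graph$edges)) else
    graph$edges$combined_score / 1000
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(length(nodes), length(nodes)),
                            dimnames = list(nodes, nodes))
  deg <- Matrix::rowSums(A)
  if (any(deg == 0)) {
    abort_ctx("isolated node(s) in graph: ",
              paste(nodes[deg == 0], collapse = ", "))
  }
  W <- if (normalization == "symmetric") {
    Dm <- Matrix::Diagonal(x = 1 / sqrt(deg))
    Dm %*% A %*% Dm
  } else {
    Matrix::Diagonal(x = 1 / deg) %*% A
  }
  dimnames(W) <- list(nodes, nodes)
  structure(list(W = W, nodes = nodes, degree = graph_degree(graph),
                 normalization = normalization, weighting = weighting),
            class = "propagation_operator")
}

# Align an input score vector to the operator's node order; unmeasured
# nodes get 0, and coverage is recorded.
align_x0 <- function(x0, op) {
  v <- stats::setNames(numeric(length(op$nodes)), op$nodes)
  measured <- intersect(names(x0), op$nodes)
  v[measured] <- x0[measured]
  attr(v, "coverage") <- length(measured) / length(op$nodes)
  v
}

#' Iterative network propagation of node scores
#'
#' Runs exactly `iterations` steps of the smoothing recursion
#' `x_{t+1} = alpha * W %*% x_t + (1 - alpha) * x0`, the random-walk-with-
#' restart update that concentrates fold-change signal in connected
#' modules. Nodes absent from `x0` start at 0.
#'
#' @param x0 named numeric vector of input scores (log2 fold changes).
#' @param op a [build_operator()] result.
#' @param alpha restart smoothing weight in [0, 1).
#' @param iterations number of iterations (the fly analysis uses 26, the
#'   mouse analysis 25).
#' @return object of class `propagation_scores`: named numeric vector
#'   with attributes `alpha`, `iterations`, `coverage`, `normalization`.
#' @export
propagate <- function(x0, op, alpha = 0.5, iterations = 26) {
  assert_that(alpha >= 0 && alpha < 1, "alpha must be in [0, 1)")
  assert_that(iterations >= 0, "iterations must be >= 0")
  v0 <- align_x0(x0, op)
  x <- v0
  for (t in seq_len(iterations)) {
    x <- as.vector(alpha * (op$W %*% x)) + (1 - alpha) * v0
  }
  x <- stats::setNames(as.vector(x), op$nodes)
  structure(x, alpha = alpha, iterations = iterations,
            coverage = attr(v0, "coverage"),
            normalization = op$normalization,
            class = "propagation_scores")
}

#' Closed-form limit of the propagation recursion
#'
#' Solves `(I - alpha W) x = (1 - alpha) x0` directly; the fixed point the
#' iterative scheme converges to geometrically when `alpha * rho(W) < 1`.
#' Serves as the convergence oracle for [propagate()].
#'
#' @inheritParams propagate
#' @return `propagation_scores` (attribute `iterations = Inf`).
#' @export
propagate_closed_form <- function(x0, op, alpha = 0.5) {
  assert_that(alpha >= 0 && alpha < 1, "alpha must be in [0, 1)")
  v0 <- align_x0(x0, op)
  n <- length(op$nodes)
  M <- Matrix::Diagonal(n) - alpha * op$W
  x <- as.vector(Matrix::solve(M, (1 - alpha) * v0))
  x <- stats::setNames(x, op$nodes)
  structure(x, alpha = alpha, iterations = Inf,
            coverage = attr(v0, "coverage"),
            normalization = op$normalization,
            class = "propagation_scores")
}

#' Select top and bottom propagated nodes under a degree filter
#'
#' Restricts to nodes with more than `min_degree - 1` interaction
#' partners (default: degree > 4), then takes the `ceiling(quantile * m)`
#' highest-scoring nodes as the up set and the same number of
#' lowest-scoring nodes as the down set, `m` being the filtered node
#' count. Ties at the boundary break by lexicographic node id so reruns
#' are identical.
#'
#' @param scores a `propagation_scores` vector.
#' @param graph the `interaction_graph` the scores live on (defines
#'   interaction counts).
#' @param min_degree minimum interaction count (node kept iff degree >=
#'   `min_degree`, i.e. strictly more than `min_degree - 1` partners).
#' @param quantile selection fraction per tail.
#' @return object of class `node_selection`: list with `up`, `down`
#'   (character vectors), `n_filtered`, `min_degree`, `quantile`.
#' @export
select_nodes <- function(scores, graph, min_degree = 5, quantile = 0.05) {
  deg <- graph_degree(graph)
  eligible <- names(deg)[deg >= min_degree]
  eligible <- intersect(eligible, names(scores))
  m <- length(eligible)
  if (m == 0L) abort_ctx("no nodes pass the degree filter")
  n_take <- ceiling(quantile * m)
  if (2 * n_take > m) abort_ctx("quantile too large for filtered node count")
  s <- unclass(scores)[eligible]
  up <- eligible[order(-s, eligible)][seq_len(n_take)]
  rest <- setdiff(eligible, up)             # keeps up and down disjoint
  down <- rest[order(s[rest], rest)][seq_len(n_take)]
  structure(list(up = sort(up), down = sort(down), n_filtered = m,
                 min_degree = min_degree, quantile = quantile),
            class = "node_selection")
}

#' @export
print.node_selection <- function(x, ...) {
  cat(sprintf("node_selection: %d up, %d down of %d degree-filtered nodes\n",
              length(x$up), length(x$down), x$n_filtered))
  invisible(x)
}
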
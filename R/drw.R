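#' Initial weight vector for the directed random walk
#'
#' Seeds the walk with differential-expression evidence: every measured gene
#' gets weight |t-score|, genes present in the network but unmeasured get 0,
#' and the virtual node gets 0. The vector is then normalised to sum to 1 so
#' the walk iterates over a probability distribution.
#'
#' @param stats `diff_stats` for genes, from [ttest_two_group()].
#' @param g GDPN graph.
#' @return Named numeric probability vector over the graph's node order
#'   (genes then virtual node).
#' @export
initial_weights <- function(stats, g) {
  nodes <- igraph::V(g)$name
  w <- stats::setNames(numeric(length(nodes)), nodes)
  measured <- intersect(rownames(stats)[!stats$degenerate], nodes)
  w[measured] <- abs(stats[measured, "t"])
  w[VIRTUAL_NODE] <- 0
  total <- sum(w)
  if (!is.finite(total) || total <= 0) {
    stop("no seed signal: all initial weights are zero")
  }
  w / total
}

#' Row-stochastic transition matrix of the GDPN walk
#'
#' In the default `downstream_influence` orientation probability mass flows
#' from a gene's downstream targets back to the gene, i.e. the walk runs on
#' the edge-reversed graph relative to PageRank, so a gene that influences
#' more downstream genes accumulates more weight. `pagerank` gives the
#' conventional forward orientation for comparison.
#'
#' Each row of the returned matrix is divided by its row sum; the virtual
#' node guarantees no row is empty.
#'
#' @param g GDPN graph (virtual node required).
#' @param orientation `"downstream_influence"` (default) or `"pagerank"`.
#' @return Dense row-stochastic matrix `M` with node dimnames; the walk
#'   multiplies by `t(M)`.
#' @export
build_transition <- function(g,
                             orientation = c("downstream_influence",
                                             "pagerank")) {
  orientation <- match.arg(orientation)
  nodes <- igraph::V(g)$name
  if (!VIRTUAL_NODE %in% nodes) stop("GDPN lacks the virtual node")
  a <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  a@x[] <- 1
  # dense is faster up to a few thousand nodes; sparse keeps larger
  # networks feasible with identical results
  if (nrow(a) <= 2000L) a <- as.matrix(a)
  if (orientation == "downstream_influence") a <- Matrix::t(a)
  rs <- Matrix::rowSums(a)
  if (any(rs == 0)) {
    stop("node(s) without outgoing edges: ",
         paste(nodes[rs == 0], collapse = ", "))
  }
  m <- a / rs
  dimnames(m) <- list(nodes, nodes)
  m
}

#' Directed random walk with restart
#'
#' Iterates `P_{t+1} = (1 - r) * t(M) %*% P_t + r * P_0` from `P_0` until
#' the max-norm change drops to `tol`, returning the stationary weight
#' vector. With restart probability 1 the walk returns the seeds unchanged;
#' below 1 the map is a contraction, so convergence is guaranteed and
#' `max_iter` is only a safety net.
#'
#' @param m Row-stochastic transition matrix from [build_transition()].
#' @param p0 Initial probability vector from [initial_weights()]; must sum
#'   to 1 in the matrix's node order.
#' @param r Restart probability in `[0, 1]`; default 0.7.
#' @param tol Convergence tolerance on the max-norm update; default 1e-10.
#' @param max_iter Iteration cap before a convergence error.
#' @return Named stationary probability vector (`P_inf`) over the nodes.
#' @export
drw_walk <- function(m, p0, r = 0.7, tol = 1e-10, max_iter = 10000L) {
  stopifnot(r >= 0, r <= 1, tol > 0)
  nodes <- rownames(m)
  if (!is.null(names(p0))) p0 <- p0[nodes]
  if (abs(sum(p0) - 1) > 1e-9) stop("p0 must sum to 1")
  mt <- Matrix::t(m)
  p <- p0
  for (iter in seq_len(max_iter)) {
    p_next <- as.vector((1 - r) * (mt %*% p) + r * p0)
    delta <- max(abs(p_next - p))
    p <- p_next
    if (delta <= tol) {
      return(stats::setNames(p, nodes))
    }
  }
  stop("random walk failed to converge after ", max_iter,
       " iterations (residual ", format(delta), ")")
}

#' Closed-form stationary solution of the restart walk
#'
#' Solves `(I - (1 - r) * t(M)) P = r * P0` directly. Primarily a
#' cross-check of the iterative [drw_walk()]; both agree to solver
#' precision on any graph.
#'
#' @inheritParams drw_walk
#' @return Named stationary probability vector.
#' @export
drw_solve <- function(m, p0, r = 0.7) {
  stopifnot(r > 0, r <= 1)
  nodes <- rownames(m)
  if (!is.null(names(p0))) p0 <- p0[nodes]
  n <- nrow(m)
  p <- solve(diag(n) - (1 - r) * as.matrix(Matrix::t(m)), r * p0)
  stats::setNames(as.vector(p), nodes)
}

#' Export stationary weights as 2-column TSV
#'
#' @param w Named weight vector.
#' @param path Output path.
#' @export
write_weights <- function(w, path) {
  utils::write.table(data.frame(node = names(w), weight = unname(w)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
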
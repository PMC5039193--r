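#' Weighted graph metrics: strength, clustering, efficiency
#'
#' Nodal and global metrics for non-negative, symmetric, zero-diagonal
#' weighted graphs (a W+ or W- connection graph):
#' \itemize{
#'   \item connectivity strength `CS_i = sum_j w_ij`; global CS is the
#'     nodal mean;
#'   \item clustering coefficient
#'     `CC_i = (1/D_i) * sum_{j,k} (w_ij w_ik w_jk)^(1/3)` with
#'     denominator `D_i` either `k_i (k_i - 1)` (degree convention, the
#'     default, where `k_i` counts nonzero neighbours) or
#'     `CS_i (CS_i - 1)` (strength convention); global CC is the nodal
#'     mean;
#'   \item global efficiency `GE_i = mean_{j != i} 1 / d_ij`, where `d_ij`
#'     is the shortest weighted path length under the inverse map
#'     `length = 1/weight`, and unreachable pairs contribute 0.
#' }
#'
#' @name graph_metrics
NULL

.check_w <- function(w) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("W must be square")
  if (any(w < 0)) stop("W has negative weights; split signs first")
  if (max(abs(w - t(w))) > 0) stop("W must be symmetric")
  if (any(diag(w) != 0)) stop("W must have a zero diagonal")
  w
}

#' Nodal connectivity strength
#'
#' @param w non-negative symmetric matrix with zero diagonal.
#' @return numeric vector of row sums (one per node).
#' @export
nodal_strength <- function(w) {
  w <- .check_w(w)
  rowSums(w)
}

#' Nodal weighted clustering coefficient
#'
#' Triangle intensity around each node by geometric-mean weights. The
#' numerator is the diagonal of the elementwise cube root of W, cubed as a
#' matrix product; the self- and repeated-index terms vanish because the
#' diagonal is zero. Nodes with fewer than two neighbours get 0.
#'
#' @param w non-negative symmetric matrix, zero diagonal, weights in [0, 1].
#' @param denominator `"degree"` for `k_i (k_i - 1)` (default) or
#'   `"strength"` for `CS_i (CS_i - 1)`.
#' @return numeric vector, one value per node.
#' @export
nodal_clustering <- function(w, denominator = c("degree", "strength")) {
  denominator <- match.arg(denominator)
  w <- .check_w(w)
  if (any(w > 1)) stop("weights > 1: geometric-mean clustering assumes [0, 1]")
  cw <- w^(1 / 3)
  num <- diag(cw %*% cw %*% cw)
  k <- rowSums(w > 0)
  den <- if (denominator == "degree") k * (k - 1) else {
    cs <- rowSums(w)
    cs * (cs - 1)
  }
  cc <- ifelse(k < 2 | den <= 0, 0, num / den)
  as.numeric(cc)
}

#' Nodal global efficiency
#'
#' Edge lengths are inverse weights; shortest path lengths d_ij come from
#' Dijkstra's algorithm on the length graph. `GE_i` is the mean of 1/d_ij
#' over j != i, with unreachable pairs contributing 0.
#'
#' @param w non-negative symmetric matrix with zero diagonal.
#' @return numeric vector, one value per node (0 for a single-node graph).
#' @export
nodal_efficiency <- function(w) {
  w <- .check_w(w)
  n <- nrow(w)
  if (n < 2) return(rep(0, n))
  len <- ifelse(w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  inv <- 1 / d
  diag(inv) <- 0                 # exclude j = i; 1/Inf is already 0
  rowSums(inv) / (n - 1)
}

#' Full metric set for one graph
#'
#' @param w non-negative symmetric matrix with zero diagonal.
#' @param denominator clustering denominator convention (see
#'   [nodal_clustering()]).
#' @return list of class `graph_metric_set`: `cs_nodal`, `cc_nodal`,
#'   `ge_nodal` (length-N vectors) and `cs_global`, `cc_global`,
#'   `ge_global` (their means).
#' @export
global_metrics <- function(w, denominator = "degree") {
  cs <- nodal_strength(w)
  cc <- nodal_clustering(w, denominator)
  ge <- nodal_efficiency(w)
  structure(list(cs_nodal = cs, cc_nodal = cc, ge_nodal = ge,
                 cs_global = mean(cs), cc_global = mean(cc),
                 ge_global = mean(ge),
                 node_labels = rownames(as.matrix(w))),
            class = "graph_metric_set")
}

#' @export
print.graph_metric_set <- function(x, ...) {
  cat(sprintf("graph metrics (N = %d): CS_net = %.4f, CC_net = %.4f, GE_net = %.4f\n",
              length(x$cs_nodal), x$cs_global, x$cc_global, x$ge_global))
  invisible(x)
}

#' Write a metric set as a TSV table
#'
#' One row per node plus a final `GLOBAL` row; columns CS, CC, GE.
#'
#' @param m `graph_metric_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(m, path) {
  labels <- m$node_labels
  if (is.null(labels)) labels <- paste0("node", seq_along(m$cs_nodal))
  tab <- rbind(cbind(m$cs_nodal, m$cc_nodal, m$ge_nodal),
               c(m$cs_global, m$cc_global, m$ge_global))
  dimnames(tab) <- list(c(labels, "GLOBAL"), c("CS", "CC", "GE"))
  write_labeled_matrix(tab, path)
}
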
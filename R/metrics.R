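#' @importFrom stats cor lm pf pt rnorm runif sd setNames quantile
NULL

as_weight_matrix <- function(net) {
  if (inherits(net, "weighted_connectome")) return(net$weights)
  m <- as.matrix(net)
  if (nrow(m) != ncol(m)) stop("weight matrix must be square")
  m
}

# Floyd-Warshall on an edge-length matrix (Inf = no edge, 0 diag).
fw_shortest_paths <- function(len) {
  d <- fw_dist_cpp(len)
  dimnames(d) <- dimnames(len)
  d
}

#' Pairwise shortest-path distances under reciprocal-FA edge lengths
#'
#' Edge length is `1/w` for FA weight `w` (strong connections are short), so
#' a path's length is the sum of reciprocal weights along it. Disconnected
#' pairs get `Inf`; the diagonal is 0. With all weights 1 this reduces to
#' ordinary hop-count distance.
#'
#' @param net A [weighted_connectome()] or weight matrix.
#' @param binary If `TRUE`, use unit lengths on existing edges (hop count)
#'   instead of reciprocal weights.
#' @return Symmetric numeric matrix of distances.
#' @export
shortest_path_lengths <- function(net, binary = FALSE) {
  w <- as_weight_matrix(net)
  len <- matrix(Inf, nrow(w), ncol(w), dimnames = dimnames(w))
  pos <- w > 0
  len[pos] <- if (binary) 1 else 1 / w[pos]
  diag(len) <- 0
  fw_shortest_paths(len)
}

#' Characteristic path length
#'
#' Mean of the finite off-diagonal distances. The number of infinite
#' (disconnected) ordered pairs is reported alongside rather than being
#' folded into the mean.
#'
#' @inheritParams shortest_path_lengths
#' @return List with `Lp` (numeric) and `infinite_pairs` (ordered-pair count).
#' @export
characteristic_path_length <- function(net, binary = FALSE) {
  d <- if (is.matrix(net) && all(diag(net) == 0) && any(is.infinite(net)))
    net else shortest_path_lengths(net, binary)
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  list(Lp = if (length(finite)) mean(finite) else NA_real_,
       infinite_pairs = sum(is.infinite(off)))
}

#' Nodal shortest path length
#'
#' `NLp(i)` is the mean of the finite distances from node `i` to all other
#' nodes. A node with no finite distances (an isolate) gets `NA` with a
#' warning.
#'
#' @inheritParams shortest_path_lengths
#' @return Named numeric vector, one value per node.
#' @export
nodal_shortest_path <- function(net, binary = FALSE) {
  d <- shortest_path_lengths(net, binary)
  diag(d) <- NA
  out <- apply(d, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f)) mean(f) else NA_real_
  })
  if (anyNA(out))
    warning("NLp undefined (no finite distances) for nodes: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Weighted clustering coefficient (geometric-mean triangle formula)
#'
#' Per-node clustering is the Onnela formula: weights are normalized by the
#' network maximum, and each triangle contributes the geometric mean of its
#' three normalized weights. `Cp` is the mean over all nodes, with nodes of
#' degree < 2 contributing 0.
#'
#' @inheritParams shortest_path_lengths
#' @param per_node If `TRUE`, return the per-node vector instead of the mean.
#' @return `Cp` (scalar) or per-node clustering values.
#' @export
clustering_coefficient <- function(net, per_node = FALSE) {
  w <- as_weight_matrix(net)
  mx <- max(w)
  n <- nrow(w)
  if (mx == 0) {
    out <- setNames(numeric(n), rownames(w))
    return(if (per_node) out else 0)
  }
  wh <- (w / mx)^(1 / 3)
  num <- diag(wh %*% wh %*% wh)          # 2 * sum of triangle geometric means
  k <- rowSums(w > 0)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  cc <- setNames(cc, rownames(w))
  if (per_node) cc else mean(cc)
}

#' Nodal and global efficiency
#'
#' `E_nodal(i)` is the mean inverse distance from `i` to every other node
#' (inverse of `Inf` counted as 0); `Eglob` is the mean of `E_nodal` over
#' nodes. With FA weights `<= 1` both lie in `[0, 1]`.
#'
#' @inheritParams shortest_path_lengths
#' @return Named numeric vector (`nodal_efficiency`) or scalar
#'   (`global_efficiency`).
#' @export
nodal_efficiency <- function(net, binary = FALSE) {
  d <- shortest_path_lengths(net, binary)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(d)
  setNames(rowSums(inv) / (n - 1), rownames(d))
}

#' @rdname nodal_efficiency
#' @export
global_efficiency <- function(net, binary = FALSE) {
  mean(nodal_efficiency(net, binary))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors (original weights retained): how well the neighborhood
#' communicates if the node is removed. Nodes with fewer than two neighbors
#' contribute 0; `Eloc` is the mean over all nodes.
#'
#' @inheritParams clustering_coefficient
#' @return `Eloc` (scalar) or per-node values.
#' @export
local_efficiency <- function(net, per_node = FALSE) {
  w <- as_weight_matrix(net)
  vals <- setNames(as.numeric(local_eff_nodes_cpp(w)), rownames(w))
  if (per_node) vals else mean(vals)
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness under reciprocal-FA edge lengths,
#' with fractional credit split among tied shortest paths and endpoints
#' excluded (Brandes' algorithm, via igraph).
#'
#' @inheritParams shortest_path_lengths
#' @return Named numeric vector of per-node betweenness.
#' @export
betweenness_centrality <- function(net, binary = FALSE) {
  w <- as_weight_matrix(net)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- if (binary) rep(1, igraph::ecount(g)) else 1 / igraph::E(g)$weight
  b <- igraph::betweenness(g, directed = FALSE, weights = len)
  setNames(as.numeric(b), rownames(w))
}

#' Degree centrality
#'
#' Count of nonzero incident edges per node.
#'
#' @inheritParams shortest_path_lengths
#' @return Named integer vector.
#' @export
degree_centrality <- function(net) {
  w <- as_weight_matrix(net)
  setNames(as.integer(rowSums(w > 0)), rownames(w))
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integral of metric values over a strictly increasing
#' sparsity grid — the threshold-free scalar summary used for group
#' statistics.
#'
#' @param s Numeric vector of sparsities, strictly increasing, length >= 2.
#' @param values Metric values at each sparsity.
#' @return Scalar AUC (metric units x sparsity).
#' @export
#' @examples
#' metric_auc(seq(0.05, 0.5, 0.05), rep(1, 10))  # 0.45
metric_auc <- function(s, values) {
  if (length(s) != length(values))
    stop("grid and values lengths differ (", length(s), " vs ",
         length(values), ")")
  if (length(s) < 2 || any(diff(s) <= 0))
    stop("sparsity grid must be strictly increasing with >= 2 points")
  sum(diff(s) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' All global and nodal metrics for one network
#'
#' Convenience wrapper computing the full metric set of a single
#' (sparsity-thresholded) network, with optional small-world normalization
#' against a null ensemble.
#'
#' @param net A [weighted_connectome()] or weight matrix.
#' @param ensemble Optional [null_ensemble()] for gamma/lambda/sigma.
#' @return List with `global` (named numeric vector) and `nodal`
#'   (data.frame: node, NLp, degree, betweenness, nodal_efficiency).
#' @export
network_metrics <- function(net, ensemble = NULL) {
  w <- as_weight_matrix(net)
  d <- shortest_path_lengths(w)
  off <- d[row(d) != col(d)]
  lp <- mean(off[is.finite(off)])
  inv <- 1 / d; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
  en <- rowSums(inv) / (nrow(w) - 1)
  diag(d) <- NA
  nlp <- apply(d, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f)) mean(f) else NA_real_
  })
  glob <- c(Cp = clustering_coefficient(w), Lp = lp,
            Eglob = mean(en), Eloc = local_efficiency(w))
  if (!is.null(ensemble)) {
    sw <- small_worldness(w, ensemble)
    glob <- c(glob, gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
  }
  nodal <- data.frame(
    node = if (!is.null(rownames(w))) rownames(w) else paste0("n", seq_len(nrow(w))),
    NLp = as.numeric(nlp),
    degree = as.integer(rowSums(w > 0)),
    betweenness = as.numeric(betweenness_centrality(w)),
    nodal_efficiency = as.numeric(en),
    stringsAsFactors = FALSE
  )
  list(global = glob, nodal = nodal,
       infinite_pairs = sum(is.infinite(off)))
}
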
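#' Raw per-subject connectivity matrix pair
#'
#' Bundles the two matrices deterministic tractography produces per subject:
#' a streamline-count matrix (how many reconstructed fibers connect each
#' region pair) and a mean-FA matrix (mean fractional anisotropy along those
#' fibers, the eventual edge weight). Both must be symmetric with a zero
#' diagonal, and FA must be zero wherever the count is zero.
#'
#' @param count_matrix Square numeric matrix of non-negative integer
#'   streamline counts.
#' @param fa_matrix Square numeric matrix of mean FA values in `[0, 1]`,
#'   same dimension as `count_matrix`.
#' @param node_labels Character vector of region names, one per node.
#' @return An object of class `connectome_pair`.
#' @export
connectome_pair <- function(count_matrix, fa_matrix, node_labels = NULL) {
  count_matrix <- as.matrix(count_matrix)
  fa_matrix <- as.matrix(fa_matrix)
  if (!all(dim(count_matrix) == dim(fa_matrix)))
    stop("count and FA matrices must have identical dimensions")
  n <- nrow(count_matrix)
  if (n != ncol(count_matrix)) stop("matrices must be square")
  if (is.null(node_labels)) {
    node_labels <- rownames(count_matrix)
    if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  }
  if (length(node_labels) != n)
    stop("node_labels length (", length(node_labels),
         ") does not match matrix dimension (", n, ")")
  check_symmetric(count_matrix, "count_matrix")
  check_symmetric(fa_matrix, "fa_matrix")
  if (any(count_matrix < 0))
    stop("count_matrix has negative entries at indices: ",
         index_string(which(count_matrix < 0, arr.ind = TRUE)))
  if (any(fa_matrix < 0 | fa_matrix > 1))
    stop("fa_matrix has entries outside [0,1] at indices: ",
         index_string(which(fa_matrix < 0 | fa_matrix > 1, arr.ind = TRUE)))
  bad <- count_matrix == 0 & fa_matrix != 0
  if (any(bad))
    stop("fa_matrix is nonzero where count_matrix is zero at indices: ",
         index_string(which(bad, arr.ind = TRUE)))
  dimnames(count_matrix) <- dimnames(fa_matrix) <-
    list(node_labels, node_labels)
  structure(
    list(count_matrix = count_matrix, fa_matrix = fa_matrix,
         node_labels = node_labels),
    class = "connectome_pair"
  )
}

check_symmetric <- function(m, name, tol = 1e-9) {
  d <- abs(m - t(m))
  if (any(d > tol))
    stop(name, " is not symmetric (tolerance ", tol, ") at indices: ",
         index_string(which(d > tol, arr.ind = TRUE)))
  if (any(abs(diag(m)) > tol))
    stop(name, " has a nonzero diagonal at nodes: ",
         paste(which(abs(diag(m)) > tol), collapse = ", "))
  invisible(TRUE)
}

index_string <- function(ind, max_show = 5L) {
  ind <- ind[ind[, 1] < ind[, 2], , drop = FALSE]
  if (nrow(ind) == 0) ind <- matrix(ind, ncol = 2)
  shown <- utils::head(seq_len(nrow(ind)), max_show)
  s <- paste(sprintf("(%d,%d)", ind[shown, 1], ind[shown, 2]), collapse = " ")
  if (nrow(ind) > max_show) s <- paste0(s, " ...")
  s
}

#' FA-weighted structural connectome
#'
#' Thin container for an analysis-ready weighted network: a symmetric FA
#' weight matrix with zero diagonal, node labels, and the streamline
#' threshold used to build it (provenance).
#'
#' @param weight_matrix Symmetric numeric matrix, weights in `[0, 1]`,
#'   zero diagonal.
#' @param node_labels Character vector of region names.
#' @param streamline_threshold Integer threshold recorded as metadata.
#' @return An object of class `weighted_connectome`.
#' @export
weighted_connectome <- function(weight_matrix, node_labels = NULL,
                                streamline_threshold = NA_integer_) {
  weight_matrix <- as.matrix(weight_matrix)
  n <- nrow(weight_matrix)
  if (n != ncol(weight_matrix)) stop("weight matrix must be square")
  if (is.null(node_labels)) {
    node_labels <- rownames(weight_matrix)
    if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  }
  check_symmetric(weight_matrix, "weight_matrix")
  if (any(weight_matrix < 0 | weight_matrix > 1))
    stop("weights must lie in [0,1]")
  dimnames(weight_matrix) <- list(node_labels, node_labels)
  structure(
    list(weights = weight_matrix, node_labels = node_labels,
         streamline_threshold = streamline_threshold),
    class = "weighted_connectome"
  )
}

#' @export
print.weighted_connectome <- function(x, ...) {
  cat("FA-weighted connectome:", length(x$node_labels), "nodes,",
      n_edges(x), "edges, density",
      sprintf("%.3f", edge_density(x)), "\n")
  invisible(x)
}

n_edges <- function(net) sum(net$weights[upper.tri(net$weights)] > 0)

edge_density <- function(net) {
  n <- length(net$node_labels)
  n_edges(net) / (n * (n - 1) / 2)
}

#' Build an FA-weighted connectome by streamline-count filtering
#'
#' An edge is retained iff its streamline count is at least
#' `streamline_threshold` (inclusive); retained edges carry their mean-FA
#' value as weight, all other entries are zero. Thresholding on the
#' streamline count suppresses likely false-positive connections from the
#' tractography stage.
#'
#' @param pair A [connectome_pair()].
#' @param streamline_threshold Integer `>= 1`; the conventional default for
#'   deterministic tractography cohorts is 3.
#' @return A [weighted_connectome()].
#' @export
#' @examples
#' cnt <- matrix(0, 4, 4); cnt[1, 3] <- cnt[3, 1] <- 3; cnt[2, 4] <- cnt[4, 2] <- 5
#' cnt[1, 2] <- cnt[2, 1] <- 1
#' fa <- (cnt > 0) * 0.5
#' net <- build_connectome(connectome_pair(cnt, fa), streamline_threshold = 3)
#' sum(net$weights > 0) / 2  # 2 surviving edges
build_connectome <- function(pair, streamline_threshold = 3L) {
  if (!inherits(pair, "connectome_pair"))
    pair <- connectome_pair(pair$count_matrix, pair$fa_matrix, pair$node_labels)
  streamline_threshold <- as.integer(streamline_threshold)
  if (is.na(streamline_threshold) || streamline_threshold < 1L)
    stop("streamline_threshold must be an integer >= 1")
  w <- ifelse(pair$count_matrix >= streamline_threshold, pair$fa_matrix, 0)
  weighted_connectome(w, pair$node_labels, streamline_threshold)
}

#' Sparsity grid for threshold sweeps
#'
#' A sparsity value is the proportion of the `N(N-1)/2` possible edges that
#' survive thresholding. The default grid, 0.05 to 0.50 in steps of 0.05,
#' spans the range over which whole-brain structural networks stay both
#' sparse and connected.
#'
#' @param s_min,s_max Range endpoints, `0 < s_min <= s_max < 1`.
#' @param s_step Step; must divide the range exactly (within 1e-8).
#' @return Numeric vector of sparsity values, class `sparsity_grid`.
#' @export
sparsity_grid <- function(s_min = 0.05, s_max = 0.50, s_step = 0.05) {
  if (!(s_min > 0 && s_min <= s_max && s_max < 1))
    stop("require 0 < s_min <= s_max < 1")
  k <- (s_max - s_min) / s_step
  if (abs(k - round(k)) > 1e-8)
    stop("s_step must divide the range s_max - s_min exactly")
  s <- s_min + s_step * (0:round(k))
  structure(s, class = "sparsity_grid")
}

#' Threshold a connectome to a target sparsity
#'
#' Retains exactly `floor(s * N(N-1)/2)` strongest-FA edges, preserving
#' their weights. Ties in FA are broken by ascending `(i, j)` node index so
#' the retained edge set is deterministic and nested across sparsities.
#'
#' @param net A [weighted_connectome()].
#' @param s Target sparsity in `(0, 1)`.
#' @return A [weighted_connectome()] at density `floor(s*M)/M`.
#' @export
threshold_to_sparsity <- function(net, s) {
  if (!(s > 0 && s < 1)) stop("sparsity must lie in (0, 1)")
  n <- length(net$node_labels)
  m_possible <- n * (n - 1) / 2
  k <- floor(s * m_possible)
  ut <- which(upper.tri(net$weights), arr.ind = TRUE)
  w <- net$weights[upper.tri(net$weights)]
  avail <- sum(w > 0)
  if (avail < k)
    stop(sprintf(
      "sparsity infeasible: %d edges needed for s = %g but only %d present (achievable density %.4f)",
      k, s, avail, avail / m_possible))
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  out <- matrix(0, n, n)
  out[ut[keep, , drop = FALSE]] <- w[keep]
  out <- out + t(out)
  weighted_connectome(out, net$node_labels, net$streamline_threshold)
}

#' Sweep a connectome over a sparsity grid
#'
#' Applies [threshold_to_sparsity()] at every grid point. Because edges are
#' selected top-k with a deterministic tie-break, the edge sets are nested:
#' every edge present at a lower sparsity is present at every higher one.
#'
#' @param net A [weighted_connectome()].
#' @param grid A [sparsity_grid()].
#' @return Named list of [weighted_connectome()] objects, one per grid
#'   point, names formatted from the sparsity values.
#' @export
sparsity_sweep <- function(net, grid = sparsity_grid()) {
  out <- lapply(as.numeric(grid), function(s) threshold_to_sparsity(net, s))
  names(out) <- format_sparsity(as.numeric(grid))
  out
}

format_sparsity <- function(s) sprintf("s%.2f", s)

#' Read a whitespace-delimited square matrix
#'
#' @param path File with one matrix row per line, whitespace-separated.
#' @param node_labels Optional labels to attach.
#' @return Numeric matrix.
#' @export
read_square_matrix <- function(path, node_labels = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  if (!is.null(node_labels)) dimnames(m) <- list(node_labels, node_labels)
  m
}

#' Write a square matrix as whitespace-delimited text
#'
#' @param m Matrix.
#' @param path Output file.
#' @export
write_square_matrix <- function(m, path) {
  utils::write.table(m, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
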
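#' Full metric sweep for one subject network
#'
#' Thresholds a streamline-filtered connectome at every sparsity of the
#' grid and computes the global metrics (Cp, Lp, Eglob, Eloc, and — when
#' `n_nulls > 0` — gamma, lambda, sigma against degree-preserving nulls)
#' and the four nodal metrics (NLp, degree, betweenness, nodal efficiency)
#' at each sparsity, plus their trapezoidal AUCs over the grid.
#'
#' @param net A [weighted_connectome()] (streamline-filtered, dense enough
#'   for the grid maximum).
#' @param grid A [sparsity_grid()].
#' @param n_nulls Nulls per sparsity for small-world normalization; 0
#'   skips gamma/lambda/sigma.
#' @param seed Integer seed for the null ensembles.
#' @return Object of class `sparsity_sweep_result`: `sparsity`, `global`
#'   (data frame, one row per sparsity), `global_auc` (named vector),
#'   `nodal` (list of per-sparsity data frames), `nodal_auc` (data frame:
#'   node x metric AUCs), `infinite_pairs`.
#' @export
sweep_metrics <- function(net, grid = sparsity_grid(), n_nulls = 0L,
                          seed = NULL) {
  s <- as.numeric(grid)
  if (!is.null(seed)) set.seed(seed)
  nets <- sparsity_sweep(net, grid)
  glob <- vector("list", length(s))
  nodal <- vector("list", length(s))
  inf_pairs <- integer(length(s))
  for (k in seq_along(s)) {
    ens <- if (n_nulls > 0) null_ensemble(nets[[k]], n_nulls) else NULL
    m <- network_metrics(nets[[k]], ens)
    glob[[k]] <- as.data.frame(as.list(c(s = s[k], m$global)))
    nodal[[k]] <- m$nodal
    inf_pairs[k] <- m$infinite_pairs
  }
  glob <- do.call(rbind, glob)
  gm <- setdiff(names(glob), "s")
  global_auc <- vapply(gm, function(col) metric_auc(s, glob[[col]]),
                       numeric(1))
  nodal_metrics <- c("NLp", "degree", "betweenness", "nodal_efficiency")
  nodal_auc <- data.frame(node = nodal[[1]]$node)
  for (col in nodal_metrics) {
    vals <- sapply(nodal, `[[`, col)      # nodes x sparsities
    # isolate nodes can have NA NLp at sparse thresholds; AUC needs the
    # full curve, so propagate NA rather than inventing a value
    nodal_auc[[col]] <- apply(vals, 1, function(v)
      if (anyNA(v)) NA_real_ else metric_auc(s, v))
  }
  names(nodal) <- format_sparsity(s)
  structure(list(sparsity = s, global = glob, global_auc = global_auc,
                 nodal = nodal, nodal_auc = nodal_auc,
                 infinite_pairs = inf_pairs),
            class = "sparsity_sweep_result")
}
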
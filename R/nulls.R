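#' Degree-preserving random rewiring of a weighted network
#'
#' Produces one null network with exactly the original degree sequence by
#' double-edge-swap rewiring (10 x |E| rewiring trials, igraph's C
#' implementation), then randomly reassigns the original FA weights among
#' the rewired edges. Uses the current RNG state; seed at the ensemble
#' level for reproducibility.
#'
#' @param net A [weighted_connectome()] or weight matrix with >= 2 edges.
#' @return A weight matrix of the same dimension.
#' @export
rewire_null <- function(net) {
  w <- as_weight_matrix(net)
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected",
                                           diag = FALSE)
  m <- igraph::ecount(g)
  if (m < 2) stop("need at least 2 edges to rewire")
  g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * m))
  el <- igraph::as_edgelist(g2, names = FALSE)
  vals <- sample(w[upper.tri(w)][w[upper.tri(w)] > 0])
  out <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  out[el] <- vals
  out[el[, c(2, 1), drop = FALSE]] <- vals
  out
}

#' Ensemble of degree-matched random networks
#'
#' Generates `n_nulls` degree-preserving rewired versions of `net` and
#' summarizes their clustering coefficient and characteristic path length.
#' These ensemble means are the denominators of the small-world ratios
#' gamma, lambda and sigma.
#'
#' @param net A [weighted_connectome()] or weight matrix.
#' @param n_nulls Number of nulls (default 100).
#' @param seed Integer seed; same seed gives an identical ensemble.
#' @return Object of class `null_ensemble`: `n_nulls`, `seed`, ensemble
#'   means `Cp_rand` and `Lp_rand`, and the per-null vectors.
#' @export
null_ensemble <- function(net, n_nulls = 100L, seed = NULL) {
  if (n_nulls < 1) stop("n_nulls must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  w <- as_weight_matrix(net)
  n <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected",
                                           diag = FALSE)
  m <- igraph::ecount(g)
  if (m < 2) stop("need at least 2 edges to rewire")
  vals0 <- w[upper.tri(w)][w[upper.tri(w)] > 0]
  cp <- lp <- numeric(n_nulls)
  wn <- matrix(0, n, n)
  offdiag <- row(wn) != col(wn)
  for (b in seq_len(n_nulls)) {
    g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * m))
    el <- igraph::as_edgelist(g2, names = FALSE)
    vals <- sample(vals0)
    wn[] <- 0
    wn[el] <- vals
    wn[el[, c(2, 1), drop = FALSE]] <- vals
    len <- matrix(Inf, n, n)
    len[wn > 0] <- 1 / wn[wn > 0]
    diag(len) <- 0
    d <- fw_dist_cpp(len)
    off <- d[offdiag]
    lp[b] <- mean(off[is.finite(off)])
    cp[b] <- clustering_coefficient(wn)
  }
  structure(
    list(n_nulls = n_nulls, seed = seed,
         Cp_rand = mean(cp), Lp_rand = mean(lp),
         Cp_each = cp, Lp_each = lp),
    class = "null_ensemble"
  )
}

#' Small-world ratios gamma, lambda, sigma
#'
#' `gamma = Cp / Cp_rand`, `lambda = Lp / Lp_rand` against the ensemble
#' means of degree-matched random networks, and `sigma = gamma / lambda`.
#' A network is small-world when it clusters far more than random
#' (`gamma > 1`) at near-random path length (`lambda ~ 1`), i.e.
#' `sigma > 1`.
#'
#' @param net A [weighted_connectome()] or weight matrix.
#' @param ensemble A [null_ensemble()] computed on the same network.
#' @return List with `gamma`, `lambda`, `sigma`, `Cp`, `Lp`.
#' @export
small_worldness <- function(net, ensemble) {
  if (!inherits(ensemble, "null_ensemble"))
    stop("ensemble must be a null_ensemble object")
  if (!is.finite(ensemble$Cp_rand) || ensemble$Cp_rand <= 0 ||
      !is.finite(ensemble$Lp_rand) || ensemble$Lp_rand <= 0)
    stop("undefined normalization: ensemble mean Cp_rand/Lp_rand must be positive")
  cp <- clustering_coefficient(net)
  lp <- characteristic_path_length(net)$Lp
  gamma <- cp / ensemble$Cp_rand
  lambda <- lp / ensemble$Lp_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       Cp = cp, Lp = lp)
}
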
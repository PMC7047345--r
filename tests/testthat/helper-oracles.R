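# Brute-force oracles for small graphs (n <= 7): exhaustive simple-path
# enumeration, independent of the package's Floyd-Warshall / igraph routes.

# all simple paths i -> j as lists of node index vectors
all_simple_paths_bf <- function(adj, i, j) {
  n <- nrow(adj)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == j) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (nxt in which(adj[last, ] > 0)) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(i)
  out
}

path_length_bf <- function(w, path) {
  if (length(path) < 2) return(0)
  sum(1 / w[cbind(path[-length(path)], path[-1])])
}

oracle_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    paths <- all_simple_paths_bf(w, i, j)
    if (length(paths)) {
      d[i, j] <- d[j, i] <- min(vapply(paths, path_length_bf, numeric(1), w = w))
    }
  }
  d
}

oracle_betweenness <- function(w, tol = 1e-12) {
  n <- nrow(w)
  b <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    paths <- all_simple_paths_bf(w, i, j)
    if (!length(paths)) next
    lens <- vapply(paths, path_length_bf, numeric(1), w = w)
    shortest <- paths[lens <= min(lens) + tol]
    for (p in shortest) {
      interior <- setdiff(p, c(i, j))
      b[interior] <- b[interior] + 1 / length(shortest)
    }
  }
  b
}

oracle_nodal_efficiency <- function(w) {
  d <- oracle_distances(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (nrow(w) - 1)
}

# local efficiency by explicit neighbor-subgraph materialization
oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) >= 2) {
      sub <- w[nb, nb, drop = FALSE]
      vals[i] <- mean(oracle_nodal_efficiency(sub))
    }
  }
  mean(vals)
}

# rich-club density straight from the definition
oracle_phi <- function(w, k) {
  deg <- rowSums(w > 0)
  vk <- which(deg > k)
  if (length(vk) < 2) return(NA_real_)
  sub <- w[vk, vk, drop = FALSE]
  sum(sub[upper.tri(sub)] > 0) / (length(vk) * (length(vk) - 1) / 2)
}

# random connected weighted graph on n nodes
random_weighted_graph <- function(n, p = 0.5) {
  repeat {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w))
    on <- runif(length(ut)) < p
    w[ut[on]] <- round(runif(sum(on), 0.1, 1), 3)
    w <- w + t(w)
    d <- oracle_distances(w)
    if (all(is.finite(d))) return(w)
  }
}

# symmetric matrix builders for toy graphs
sym_graph <- function(n, edges) {
  w <- matrix(0, n, n)
  for (e in edges) {
    w[e[1], e[2]] <- e[3]
    w[e[2], e[1]] <- e[3]
  }
  w
}

path_abc <- function(wgt = 1) sym_graph(3, list(c(1, 2, wgt), c(2, 3, wgt)))
triangle <- function(w12 = 1, w13 = 1, w23 = 1)
  sym_graph(3, list(c(1, 2, w12), c(1, 3, w13), c(2, 3, w23)))
star_k <- function(k, wgt = 1)
  sym_graph(k + 1, lapply(seq_len(k) + 1, function(j) c(1, j, wgt)))
complete_graph <- function(n, wgt = 1) {
  w <- matrix(wgt, n, n); diag(w) <- 0; w
}
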
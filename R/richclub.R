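#' Select rich-club hub regions from a cohort
#'
#' Ranks nodes by nodal degree averaged over all subjects' streamline-
#' filtered networks (all groups pooled) and returns the top
#' `floor(fraction * N)` as hubs. Ties are broken by higher average nodal
#' strength (summed FA weight), then by node index, so the selection is
#' deterministic.
#'
#' @param nets List of [weighted_connectome()] objects (one per subject),
#'   all sharing the same node labels.
#' @param fraction Fraction of nodes to select, in `(0, 0.5]`; 0.15 of a
#'   90-node parcellation gives the conventional 13 hubs.
#' @return Character vector of hub node labels.
#' @export
select_hubs <- function(nets, fraction = 0.15) {
  if (length(nets) < 1) stop("empty cohort: need at least one subject network")
  if (!(fraction > 0 && fraction <= 0.5))
    stop("fraction must lie in (0, 0.5]")
  labels <- nets[[1]]$node_labels
  deg <- rowMeans(sapply(nets, function(x) degree_centrality(x)))
  strength <- rowMeans(sapply(nets, function(x) rowSums(as_weight_matrix(x))))
  n_hub <- floor(fraction * length(labels))
  ord <- order(-deg, -strength, seq_along(labels))
  labels[ord[seq_len(n_hub)]]
}

#' Rich-club coefficient at degree level k
#'
#' With `V_k` the set of nodes of degree strictly greater than `k`,
#' `phi(k)` is the density of the subgraph they induce:
#' `2 E_k / (|V_k| (|V_k| - 1))`, where `E_k` counts edges with both
#' endpoints in `V_k`. Undefined (`NA`) when fewer than two nodes exceed
#' `k`. The default is the topological (binary) density; `weighted = TRUE`
#' gives the weighted variant, club weight divided by the sum of the `E_k`
#' strongest weights in the whole network.
#'
#' @param net A [weighted_connectome()] or weight matrix.
#' @param k Degree level, `>= 0`.
#' @param weighted Use the weighted variant (non-default).
#' @return `phi(k)` in `[0, 1]`, or `NA` where undefined.
#' @export
rich_club_coefficient <- function(net, k, weighted = FALSE) {
  w <- as_weight_matrix(net)
  deg <- rowSums(w > 0)
  vk <- which(deg > k)
  if (length(vk) < 2) return(NA_real_)
  sub <- w[vk, vk, drop = FALSE]
  ek <- sum(sub[upper.tri(sub)] > 0)
  if (!weighted)
    return(2 * ek / (length(vk) * (length(vk) - 1)))
  if (ek == 0) return(0)
  club_w <- sum(sub[upper.tri(sub)])
  all_w <- sort(w[upper.tri(w)][w[upper.tri(w)] > 0], decreasing = TRUE)
  club_w / sum(all_w[seq_len(ek)])
}

#' Rich-club curve phi(k) over a degree range
#'
#' @inheritParams rich_club_coefficient
#' @param k_range Integer vector of degree levels; default `0:(max degree - 1)`.
#' @return Named numeric vector `phi(k)`, `NA` where undefined.
#' @export
rich_club_curve <- function(net, k_range = NULL, weighted = FALSE) {
  w <- as_weight_matrix(net)
  deg <- rowSums(w > 0)
  if (is.null(k_range)) k_range <- 0:max(max(deg) - 1, 0)
  if (weighted)
    return(setNames(vapply(k_range, function(k)
      rich_club_coefficient(w, k, weighted = TRUE), numeric(1)),
      paste0("k", k_range)))
  # binary phi(k) in O(E + K): an edge lies inside V_k iff the smaller of
  # its endpoint degrees exceeds k; |V_k| is a degree tail count
  ij <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  mindeg <- pmin(deg[ij[, 1]], deg[ij[, 2]])
  phi <- vapply(k_range, function(k) {
    nk <- sum(deg > k)
    if (nk < 2) return(NA_real_)
    2 * sum(mindeg > k) / (nk * (nk - 1))
  }, numeric(1))
  setNames(phi, paste0("k", k_range))
}

#' Normalized rich-club curve against degree-preserving nulls
#'
#' `phi_norm(k) = phi(k) / mean_null phi_null(k)`, the null mean taken over
#' `n_nulls` degree-preserving rewired networks. Rich-club organization is
#' indicated where `phi_norm(k) > 1`. `NA` where the observed or every null
#' value is undefined.
#'
#' @inheritParams rich_club_curve
#' @param n_nulls Number of null networks.
#' @param seed Integer seed for the null ensemble.
#' @return List with `k`, `phi`, `phi_null_mean`, `phi_norm`.
#' @export
normalized_rich_club <- function(net, k_range = NULL, n_nulls = 100L,
                                 seed = NULL) {
  w <- as_weight_matrix(net)
  if (is.null(k_range)) {
    kmax <- max(rowSums(w > 0))
    k_range <- 0:max(kmax - 1, 0)
  }
  phi <- rich_club_curve(w, k_range)
  if (!is.null(seed)) set.seed(seed)
  null_phi <- matrix(NA_real_, n_nulls, length(k_range))
  for (b in seq_len(n_nulls))
    null_phi[b, ] <- rich_club_curve(rewire_null(w), k_range)
  null_mean <- colMeans(null_phi, na.rm = TRUE)
  null_mean[!is.finite(null_mean)] <- NA_real_
  phi_norm <- unname(phi) / null_mean
  list(k = k_range, phi = unname(phi), phi_null_mean = null_mean,
       phi_norm = phi_norm)
}

#' Classify edges as rich, feeder or local and sum class strengths
#'
#' Edges between two hubs are `rich`, between a hub and a peripheral node
#' `feeder`, and between two peripheral nodes `local`. The three classes
#' partition the edge set, so their summed FA strengths add up to the total
#' network strength.
#'
#' @param net A [weighted_connectome()].
#' @param hub_labels Character vector of hub node labels (must all be
#'   present in the network).
#' @return Named numeric vector `c(rich, feeder, local)` of summed FA
#'   weights.
#' @export
classify_and_sum <- function(net, hub_labels) {
  w <- as_weight_matrix(net)
  labels <- if (!is.null(rownames(w))) rownames(w) else
    paste0("n", seq_len(nrow(w)))
  unknown <- setdiff(hub_labels, labels)
  if (length(unknown))
    stop("unknown hub labels: ", paste(unknown, collapse = ", "))
  is_hub <- labels %in% hub_labels
  n_hub_ends <- outer(is_hub, is_hub, "+")   # 2 = rich, 1 = feeder, 0 = local
  ut <- upper.tri(w)
  c(rich = sum(w[ut & n_hub_ends == 2]),
    feeder = sum(w[ut & n_hub_ends == 1]),
    local = sum(w[ut & n_hub_ends == 0]))
}
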
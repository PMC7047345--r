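#' Effect configuration for the synthetic cohort generator
#'
#' Encodes the group-level alterations injected into tumor-group subjects:
#' a multiplicative reduction of peripheral (local) edge weights driving a
#' local-efficiency deficit, a multiplicative boost of hub-hub edge weights
#' driving increased rich-club strength, random deletion of a fraction of
#' local edges, subject-level weight jitter, and target correlations
#' between cognitive scores and local-efficiency AUC.
#'
#' @param eloc_reduction Factor (> 0, < 1 for a deficit) applied to
#'   local-class edge weights in tumor groups.
#' @param richclub_boost Factor (> 1 for a boost) applied to hub-hub edge
#'   weights in tumor groups.
#' @param local_edge_dropout Fraction in `[0, 1)` of local-class edges
#'   deleted in tumor groups.
#' @param behavior_r Named list of target score-vs-Eloc-AUC correlations,
#'   names `"<group>.<score>"`, values in `(-1, 1)`. The defaults calibrate
#'   the memory score in the temporal-tumor group to r = 0.503 and the DSST
#'   score in the frontal-tumor group to r = 0.49.
#' @param noise_sd SD of the additive FA jitter applied per subject.
#' @return Object of class `effect_config`.
#' @export
effect_config <- function(eloc_reduction = 0.90,
                          richclub_boost = 1.10,
                          local_edge_dropout = 0.05,
                          behavior_r = list(TTumor.memory = 0.503,
                                            FTumor.DSST = 0.49),
                          noise_sd = 0.02) {
  if (eloc_reduction <= 0 || richclub_boost <= 0)
    stop("effect factors must be positive")
  if (local_edge_dropout < 0 || local_edge_dropout >= 1)
    stop("local_edge_dropout must lie in [0, 1)")
  if (length(behavior_r) &&
      any(abs(unlist(behavior_r)) >= 1))
    stop("behavior_r values must lie in (-1, 1)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(eloc_reduction = eloc_reduction,
                 richclub_boost = richclub_boost,
                 local_edge_dropout = local_edge_dropout,
                 behavior_r = behavior_r,
                 noise_sd = noise_sd),
            class = "effect_config")
}

#' Specification of a synthetic three-group cohort
#'
#' @param n_per_group Named integer vector `c(CN = , FTumor = , TTumor = )`,
#'   each `>= 2`.
#' @param seed Integer; the same spec (including seed) reproduces the
#'   cohort exactly.
#' @param n_nodes Number of atlas regions (default 90).
#' @param hub_labels Regions designated as hubs; default the 13 canonical
#'   rich-club regions of [default_hub_labels()] when `n_nodes` is 90.
#' @param node_labels Region names; default [aal90_labels()] for 90 nodes.
#' @param effects An [effect_config()].
#' @param streamline_threshold,grid Threshold and [sparsity_grid()] used
#'   when the generator computes each subject's local-efficiency AUC (the
#'   quantity cognition is calibrated against).
#' @param missing_score_fraction Fraction of patient cognitive scores set
#'   missing at random (default 0).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(CN = 14L, FTumor = 13L, TTumor = 18L),
                        seed = 1L,
                        n_nodes = 90L,
                        node_labels = NULL,
                        hub_labels = NULL,
                        effects = effect_config(),
                        streamline_threshold = 3L,
                        grid = sparsity_grid(),
                        missing_score_fraction = 0) {
  if (is.null(names(n_per_group)))
    names(n_per_group) <- c("CN", "FTumor", "TTumor")[seq_along(n_per_group)]
  if (any(n_per_group < 2)) stop("every group needs n >= 2")
  if (is.null(node_labels))
    node_labels <- if (n_nodes == 90) aal90_labels() else
      paste0("n", seq_len(n_nodes))
  if (length(node_labels) != n_nodes)
    stop("node_labels length must equal n_nodes")
  if (is.null(hub_labels))
    hub_labels <- if (n_nodes == 90) default_hub_labels() else
      node_labels[seq_len(max(2L, floor(0.15 * n_nodes)))]
  if (!all(hub_labels %in% node_labels))
    stop("hub_labels must be a subset of node_labels")
  if (length(hub_labels) > 0.2 * n_nodes)
    stop("hubs must not exceed 20% of nodes")
  if (missing_score_fraction < 0 || missing_score_fraction >= 1)
    stop("missing_score_fraction must lie in [0, 1)")
  structure(list(n_per_group = n_per_group, seed = as.integer(seed),
                 n_nodes = as.integer(n_nodes), node_labels = node_labels,
                 hub_labels = hub_labels, effects = effects,
                 streamline_threshold = as.integer(streamline_threshold),
                 grid = grid,
                 missing_score_fraction = missing_score_fraction),
            class = "cohort_spec")
}

# Demographic and cognitive calibration table (group mean, SD) for a
# three-group glioma cohort; cognition in score points, age/education in
# years, sex as male fraction.
cohort_calibration <- function() {
  list(
    age = list(CN = c(48.57, 8.7), FTumor = c(44.54, 12.8),
               TTumor = c(53.11, 12.9)),
    education = list(CN = c(10.92, 3.5), FTumor = c(9.83, 2.5),
                     TTumor = c(8.44, 2.5)),
    male_fraction = c(CN = 6 / 14, FTumor = 5 / 13, TTumor = 10 / 18),
    scores = list(
      DST = list(CN = c(11.00, 2.3), FTumor = c(7.60, 5.6),
                 TTumor = c(8.09, 2.9)),
      memory = list(CN = c(11.88, 1.6), FTumor = c(5.80, 5.1),
                    TTumor = c(4.27, 4.8)),
      visuospatial = list(CN = c(10.63, 1.6), FTumor = c(3.90, 3.98),
                          TTumor = c(4.82, 4.4)),
      DSST = list(CN = c(11.88, 1.6), FTumor = c(4.10, 5.6),
                  TTumor = c(4.09, 4.3)),
      mapping = list(CN = c(9.88, 0.6), FTumor = c(3.60, 2.3),
                     TTumor = c(4.82, 2.8)),
      similarity = list(CN = c(10.0, 1.1), FTumor = c(5.30, 3.1),
                        TTumor = c(5.00, 3.5))
    )
  )
}

#' Generate the healthy template network
#'
#' Builds the deterministic-seeded FA-weighted template all synthetic
#' subjects are derived from: nodes sit on a ring and connect to all
#' neighbors within a band (about 56% density), with FA decaying smoothly
#' from about 0.7 for adjacent nodes to about 0.22 at the band edge, so
#' that thresholding at any sparsity yields a lattice-like, highly
#' clustered topology. Designated hubs are additionally wired to each other
#' and into every ring segment (module) with strong weights, producing both
#' the highest degrees and a detectable rich club. All weights are Beta
#' draws scaled into the plausible white-matter FA range `[0.2, 0.8]`.
#'
#' @param n_nodes Number of nodes, `>= 20`.
#' @param hub_labels Hub region names (at most 20% of nodes).
#' @param seed Integer seed; same seed, same matrix.
#' @param node_labels Node names; defaults as in [cohort_spec()].
#' @param n_modules Ring segments each hub is wired into (default 6).
#' @return A [weighted_connectome()] with density >= 0.5.
#' @export
make_template_network <- function(n_nodes = 90L, hub_labels = NULL,
                                  seed = 1L, node_labels = NULL,
                                  n_modules = 6L) {
  if (n_nodes < 20) stop("need n_nodes >= 20")
  if (is.null(node_labels))
    node_labels <- if (n_nodes == 90) aal90_labels() else
      paste0("n", seq_len(n_nodes))
  if (is.null(hub_labels))
    hub_labels <- if (n_nodes == 90) default_hub_labels() else
      node_labels[seq_len(max(2L, floor(0.15 * n_nodes)))]
  if (!all(hub_labels %in% node_labels))
    stop("invalid spec: hub labels not among node labels")
  if (length(hub_labels) > 0.2 * n_nodes)
    stop("invalid spec: hub set exceeds 20% of nodes")
  set.seed(seed)
  n <- n_nodes
  hubs <- which(node_labels %in% hub_labels)
  # ring-band core: connect i,j iff circular distance <= d_max
  d_max <- ceiling(0.28 * (n - 1))          # band degree 2*d_max ~ 0.56 (n-1)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  circ <- pmin(abs(ij[, 1] - ij[, 2]), n - abs(ij[, 1] - ij[, 2]))
  w <- matrix(0, n, n, dimnames = list(node_labels, node_labels))
  band <- circ <= d_max
  prox <- (1 - (circ[band] - 1) / d_max)^0.75   # 1 adjacent -> ~0 at band edge
  wv <- 0.2 + 0.6 * prox * stats::rbeta(sum(band), 10, 2)
  w[ij[band, , drop = FALSE]] <- pmin(wv, 0.8)
  # hub overlay: hub-hub clique, strong
  if (length(hubs) >= 2) {
    hh <- t(utils::combn(hubs, 2))
    w[hh] <- pmax(w[hh], 0.2 + 0.6 * stats::rbeta(nrow(hh), 12, 3))
  }
  # hub spokes into every ring segment
  module_of <- ceiling(seq_len(n) / (n / n_modules))
  for (h in hubs) {
    for (m in seq_len(n_modules)) {
      cand <- setdiff(which(module_of == m), c(h, hubs))
      if (!length(cand)) next
      tgt <- if (length(cand) == 1) cand else
        sample(cand, min(2L, length(cand)))
      w[cbind(pmin(h, tgt), pmax(h, tgt))] <-
        pmax(w[cbind(pmin(h, tgt), pmax(h, tgt))],
             0.2 + 0.6 * stats::rbeta(length(tgt), 10, 3))
    }
  }
  w <- w + t(w)
  weighted_connectome(w, node_labels)
}

# Edge-class index sets (upper triangle) for a hub set.
edge_classes <- function(n, hubs) {
  is_hub <- seq_len(n) %in% hubs
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ends <- is_hub[ij[, 1]] + is_hub[ij[, 2]]
  list(ij = ij, rich = ends == 2, feeder = ends == 1, local = ends == 0)
}

#' Generate a synthetic cohort
#'
#' Draws every subject from the seeded template: controls are jittered
#' copies; tumor-group subjects additionally have local-class edge weights
#' multiplied by `eloc_reduction`, a fraction `local_edge_dropout` of local
#' edges deleted, and hub-hub weights multiplied by `richclub_boost`
#' (clipped into `[0, 1]`). Streamline counts are weight-proportional
#' Poisson draws (`rpois(50 w) + 1`). Demographics are drawn from the
#' calibration table; cognitive scores are Gaussian with calibrated group
#' means/SDs, and for each configured `(group, score)` pair the score is
#' constructed from the subject's standardized local-efficiency AUC so that
#' the large-sample correlation equals `behavior_r`.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: `subjects` (list; each has
#'   `subject_id`, `group`, demographics, `scores`, `count_matrix`,
#'   `fa_matrix`, `eloc_auc`), `table` (cohort data frame), `template`,
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  template <- make_template_network(spec$n_nodes, spec$hub_labels,
                                    spec$seed, spec$node_labels)
  set.seed(spec$seed + 1L)
  n <- spec$n_nodes
  hubs <- which(spec$node_labels %in% spec$hub_labels)
  cls <- edge_classes(n, hubs)
  wt <- template$weights
  eff <- spec$effects
  cal <- cohort_calibration()
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  subjects <- vector("list", length(groups))
  s_grid <- as.numeric(spec$grid)
  clipped <- 0L
  for (i in seq_along(groups)) {
    g <- groups[i]
    w <- wt
    if (g != "CN") {
      ut_rich <- cls$ij[cls$rich, , drop = FALSE]
      ut_local <- cls$ij[cls$local, , drop = FALSE]
      w[ut_rich] <- w[ut_rich] * eff$richclub_boost
      w[ut_local] <- w[ut_local] * eff$eloc_reduction
      if (eff$local_edge_dropout > 0) {
        present <- which(w[ut_local] > 0)
        kill <- sample(present,
                       floor(eff$local_edge_dropout * length(present)))
        w[ut_local[kill, , drop = FALSE]] <- 0
      }
      w[lower.tri(w)] <- 0
      w <- w + t(w)
    }
    # subject-level jitter on existing edges, FA kept inside (0, 1]
    pos <- which(upper.tri(w) & w > 0)
    jit <- w[pos] + stats::rnorm(length(pos), 0, eff$noise_sd)
    clipped <- clipped + sum(jit > 1 | jit < 0.01)
    w[pos] <- pmin(pmax(jit, 0.01), 1)
    w[lower.tri(w)] <- 0
    w <- w + t(w)
    # weight-proportional streamline counts
    cnt <- matrix(0, n, n)
    cnt[pos] <- stats::rpois(length(pos), 50 * w[pos]) + 1
    cnt[lower.tri(cnt)] <- 0
    cnt <- cnt + t(cnt)
    dimnames(cnt) <- dimnames(w) <- list(spec$node_labels, spec$node_labels)
    pair <- connectome_pair(cnt, ifelse(cnt > 0, w, 0), spec$node_labels)
    net <- build_connectome(pair, spec$streamline_threshold)
    eloc <- vapply(s_grid, function(s)
      local_efficiency(threshold_to_sparsity(net, s)), numeric(1))
    subjects[[i]] <- list(
      subject_id = sprintf("%s_%03d", g, sum(groups[seq_len(i)] == g)),
      group = g,
      age = min(80, max(18, stats::rnorm(1, cal$age[[g]][1], cal$age[[g]][2]))),
      sex = if (stats::runif(1) < cal$male_fraction[[g]]) "M" else "F",
      education = min(22, max(0, stats::rnorm(1, cal$education[[g]][1],
                                              cal$education[[g]][2]))),
      count_matrix = pair$count_matrix,
      fa_matrix = pair$fa_matrix,
      eloc_auc = metric_auc(s_grid, eloc)
    )
  }
  if (clipped > 0)
    message("clipped ", clipped, " jittered FA value(s) into [0.01, 1]")
  # cognitive scores: calibrated Gaussians, correlation-targeted where configured
  eloc_auc <- vapply(subjects, `[[`, numeric(1), "eloc_auc")
  score_names <- names(cal$scores)
  scores <- matrix(NA_real_, length(subjects), length(score_names),
                   dimnames = list(NULL, score_names))
  for (sn in score_names) {
    for (g in unique(groups)) {
      idx <- which(groups == g)
      ms <- cal$scores[[sn]][[g]]
      key <- paste0(g, ".", sn)
      eps <- stats::rnorm(length(idx))
      if (!is.null(eff$behavior_r[[key]]) && length(idx) >= 4) {
        r <- eff$behavior_r[[key]]
        z <- as.numeric(scale(eloc_auc[idx]))
        # orthogonalize the noise against z so the realized within-group
        # correlation equals the target exactly, not just in expectation
        eps <- as.numeric(scale(stats::resid(lm(eps ~ z))))
        scores[idx, sn] <- ms[1] + ms[2] * (r * z + sqrt(1 - r^2) * eps)
      } else {
        scores[idx, sn] <- ms[1] + ms[2] * eps
      }
    }
  }
  if (spec$missing_score_fraction > 0) {
    patient <- which(groups != "CN")
    cells <- expand.grid(i = patient, j = seq_along(score_names))
    drop <- sample(nrow(cells),
                   floor(spec$missing_score_fraction * nrow(cells)))
    scores[as.matrix(cells[drop, ])] <- NA_real_
  }
  for (i in seq_along(subjects))
    subjects[[i]]$scores <- scores[i, ]
  tab <- data.frame(
    subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
    group = groups,
    age = vapply(subjects, `[[`, numeric(1), "age"),
    sex = vapply(subjects, `[[`, character(1), "sex"),
    education = vapply(subjects, `[[`, numeric(1), "education"),
    scores,
    eloc_auc = eloc_auc,
    stringsAsFactors = FALSE
  )
  structure(list(subjects = subjects, table = tab, template = template,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$table), "subjects (",
      paste(sprintf("%s=%d", names(table(x$table$group)),
                    as.integer(table(x$table$group))), collapse = ", "),
      "),", x$spec$n_nodes, "nodes, seed", x$spec$seed, "\n")
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Per subject, whitespace-delimited square `<id>_count.txt` and
#' `<id>_fa.txt` matrices; plus `node_labels.txt` (one region per line) and
#' `cohort.csv` (subject_id, group, age, sex, education, six score
#' columns).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    write_square_matrix(s$count_matrix,
                        file.path(dir, paste0(s$subject_id, "_count.txt")))
    write_square_matrix(s$fa_matrix,
                        file.path(dir, paste0(s$subject_id, "_fa.txt")))
  }
  writeLines(cohort$spec$node_labels, file.path(dir, "node_labels.txt"))
  utils::write.csv(
    cohort$table[, !(names(cohort$table) == "eloc_auc")],
    file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cohort.csv`, `node_labels.txt` and the
#'   per-subject matrix files.
#' @return List with `pairs` (named list of [connectome_pair()]), `table`,
#'   `node_labels`.
#' @export
read_cohort <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "cohort.csv"),
                         stringsAsFactors = FALSE)
  labels <- readLines(file.path(dir, "node_labels.txt"))
  pairs <- lapply(tab$subject_id, function(id) {
    connectome_pair(
      read_square_matrix(file.path(dir, paste0(id, "_count.txt"))),
      read_square_matrix(file.path(dir, paste0(id, "_fa.txt"))),
      labels)
  })
  names(pairs) <- tab$subject_id
  list(pairs = pairs, table = tab, node_labels = labels)
}
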
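test_that("the template is connected, dense, hub-dominated and reproducible", {
  net <- make_template_network(90, seed = 1)
  expect_gte(edge_density(net), 0.5)
  expect_true(all(is.finite(shortest_path_lengths(net))))
  deg <- degree_centrality(net)
  top13 <- names(sort(deg, decreasing = TRUE))[1:13]
  expect_setequal(top13, default_hub_labels())

  net2 <- make_template_network(90, seed = 1)
  expect_identical(net$weights, net2$weights)
  net3 <- make_template_network(90, seed = 2)
  expect_false(identical(net$weights, net3$weights))

  expect_error(make_template_network(10), "n_nodes >= 20")
  expect_error(
    make_template_network(30, hub_labels = paste0("n", 1:10)),
    "invalid spec")
  expect_error(
    make_template_network(30, hub_labels = c("n1", "zz")),
    "invalid spec")
})

test_that("generated cohorts are bit-identical under the same spec", {
  spec <- cohort_spec(c(CN = 2, FTumor = 2, TTumor = 2), seed = 99)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$table, c2$table)
  expect_identical(c1$subjects[[3]]$fa_matrix, c2$subjects[[3]]$fa_matrix)
  expect_identical(c1$subjects[[5]]$count_matrix, c2$subjects[[5]]$count_matrix)
})

test_that("generated matrices satisfy the connectome invariants", {
  co <- generate_cohort(cohort_spec(c(CN = 2, FTumor = 2, TTumor = 2), seed = 3))
  for (s in co$subjects) {
    expect_equal(s$fa_matrix, t(s$fa_matrix))
    expect_true(all(diag(s$fa_matrix) == 0))
    expect_true(all(s$fa_matrix >= 0 & s$fa_matrix <= 1))
    expect_true(all(s$count_matrix == round(s$count_matrix)))
    expect_true(all(s$count_matrix >= 0))
    expect_true(all(s$fa_matrix[s$count_matrix == 0] == 0))
    # constructor validation passes
    expect_s3_class(connectome_pair(s$count_matrix, s$fa_matrix),
                    "connectome_pair")
  }
})

test_that("null effect configuration produces no systematic group differences", {
  null_eff <- effect_config(eloc_reduction = 1, richclub_boost = 1,
                            local_edge_dropout = 0, behavior_r = list())
  pvals <- vapply(1:12, function(sd) {
    co <- generate_cohort(cohort_spec(c(CN = 5, FTumor = 5, TTumor = 5),
                                      seed = 600 + sd, effects = null_eff))
    summary(stats::aov(eloc_auc ~ group, data = co$table))[[1]]$`Pr(>F)`[1]
  }, numeric(1))
  # at alpha = 0.05 the expected rejection count over 12 seeds is 0.6
  expect_lte(sum(pvals < 0.05), 3)
})

test_that("stronger local-weight reduction widens the CN-vs-tumor Eloc gap", {
  # factor levels within the designed effect regime; far stronger
  # reductions saturate because top-k sparsity selection recruits
  # replacement edges (see the methods vignette)
  gap <- vapply(c(1.0, 0.95, 0.90), function(fac) {
    eff <- effect_config(eloc_reduction = fac, richclub_boost = 1,
                         local_edge_dropout = 0, behavior_r = list())
    co <- generate_cohort(cohort_spec(c(CN = 15, FTumor = 2, TTumor = 15),
                                      seed = 71, effects = eff))
    m <- tapply(co$table$eloc_auc, co$table$group, mean)
    unname(m["CN"] - m["TTumor"])
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
  expect_lt(abs(gap[1]), 0.002)
})

test_that("default effects reduce tumor-group local efficiency", {
  co <- generate_cohort(cohort_spec(c(CN = 25, FTumor = 25, TTumor = 25),
                                    seed = 83))
  m <- tapply(co$table$eloc_auc, co$table$group, mean)
  expect_gt(m[["CN"]], m[["FTumor"]])
  expect_gt(m[["CN"]], m[["TTumor"]])
})

test_that("missing-score fraction only blanks patient scores", {
  spec <- cohort_spec(c(CN = 4, FTumor = 4, TTumor = 4), seed = 5,
                      missing_score_fraction = 0.3)
  co <- generate_cohort(spec)
  score_cols <- c("DST", "memory", "visuospatial", "DSST", "mapping",
                  "similarity")
  cn <- co$table[co$table$group == "CN", score_cols]
  pat <- co$table[co$table$group != "CN", score_cols]
  expect_false(anyNA(cn))
  expect_equal(sum(is.na(pat)), floor(0.3 * nrow(pat) * length(score_cols)))
})

test_that("a cohort survives the plain-text round trip", {
  co <- generate_cohort(cohort_spec(c(CN = 2, FTumor = 2, TTumor = 2), seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "node_labels.txt")))
  back <- read_cohort(dir)
  expect_equal(back$table$subject_id, co$table$subject_id)
  expect_equal(back$node_labels, co$spec$node_labels)
  id <- co$table$subject_id[4]
  expect_equal(unname(back$pairs[[id]]$count_matrix),
               unname(co$subjects[[4]]$count_matrix))
  expect_equal(unname(back$pairs[[id]]$fa_matrix),
               unname(co$subjects[[4]]$fa_matrix), tolerance = 1e-9)
})

test_that("cohort specs validate their invariants", {
  expect_error(cohort_spec(c(CN = 1, FTumor = 5, TTumor = 5)), "n >= 2")
  expect_error(cohort_spec(hub_labels = c("PCUN.L", "nope")), "subset")
  expect_error(cohort_spec(hub_labels = aal90_labels()[1:20]), "20%")
  expect_error(effect_config(eloc_reduction = -1), "positive")
  expect_error(effect_config(local_edge_dropout = 1), "\\[0, 1\\)")
  expect_error(effect_config(behavior_r = list(a = 1.2)), "\\(-1, 1\\)")
})
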
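test_that("summary-statistics ANOVA equals raw-data ANOVA on exact summaries", {
  set.seed(11)
  for (rep in 1:10) {
    g <- sample(2:4, 1)
    ns <- sample(4:9, g, replace = TRUE)
    y <- lapply(ns, function(n) rnorm(n, sample(0:3, 1), runif(1, 0.5, 2)))
    fit <- summary(stats::aov(unlist(y) ~ factor(rep(seq_len(g), ns))))[[1]]
    res <- anova_from_summary(vapply(y, mean, 1), vapply(y, sd, 1), ns)
    expect_equal(res$F, fit$`F value`[1], tolerance = 1e-9)
    expect_equal(res$p, fit$`Pr(>F)`[1], tolerance = 1e-9)
  }
  expect_equal(anova_from_summary(c(1, 1, 1), c(1, 2, 3), c(5, 5, 5))$F, 0)
  expect_error(anova_from_summary(c(1, 2), c(1, 1), c(1, 5)), "n >= 2")
})

test_that("chi-square matches the hand expected-count formula", {
  tab <- rbind(c(12, 7), c(5, 9))
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2_hand <- sum((tab - expected)^2 / expected)
  res <- chisq_independence(tab)
  expect_equal(res$chi2, chi2_hand, tolerance = 1e-12)
  expect_equal(res$df, 1)

  # perfectly proportional table
  prop <- rbind(c(10, 20), c(5, 10))
  expect_equal(chisq_independence(prop)$chi2, 0, tolerance = 1e-12)
  expect_error(chisq_independence(rbind(c(0, 0), c(1, 2))), "positive")
})

test_that("with null covariates the adjusted test reduces to one-way ANOVA", {
  set.seed(13)
  n <- 30
  group <- rep(c("A", "B", "C"), each = n / 3)
  y <- rnorm(n) + (group == "B") * 0.5
  covs <- data.frame(age = rnorm(n, 50, 10), sex = sample(c("M", "F"), n, TRUE),
                     education = rnorm(n, 10, 2))
  # covariates present but with zero true effect: F close to unadjusted
  raw_f <- summary(stats::aov(y ~ factor(group)))[[1]]$`F value`[1]
  # strictly zero-covariate reduction: constant covariates are collinear,
  # so compare the partial F with covariates omitted
  adj0 <- adjusted_group_test(y, group, NULL)
  expect_equal(adj0$F, raw_f, tolerance = 1e-6)
  expect_equal(unname(adj0$adjusted_means),
               as.numeric(tapply(y, group, mean)), tolerance = 1e-9)

  adj <- adjusted_group_test(y, group, covs)
  expect_equal(adj$df[1], 2)
  expect_error(
    adjusted_group_test(y, group, data.frame(age = covs$age, age2 = covs$age)),
    "collinear")
})

test_that("post hoc contrasts match the model coefficient route", {
  set.seed(17)
  n <- 36
  group <- factor(rep(c("CN", "FTumor", "TTumor"), each = 12))
  covs <- data.frame(age = rnorm(n, 50, 8), sex = sample(c("M", "F"), n, TRUE),
                     education = rnorm(n, 10, 3))
  y <- 1 + 0.02 * covs$age + 0.3 * (group == "TTumor") + rnorm(n, 0, 0.4)
  ph <- posthoc_pairwise(y, group, covs)
  expect_equal(nrow(ph), 3)

  # independent route: treatment-coded lm summary gives the CN-vs-X contrasts
  fit <- lm(y ~ group + age + sex + education, data = cbind(covs, group = group))
  sm <- summary(fit)$coefficients
  row_ft <- ph[ph$group1 == "CN" & ph$group2 == "FTumor", ]
  expect_equal(row_ft$t, -sm["groupFTumor", "t value"], tolerance = 1e-9)
  expect_equal(row_ft$p, sm["groupFTumor", "Pr(>|t|)"], tolerance = 1e-9)

  # identical outcomes across groups: t = 0
  y0 <- rep(seq_len(12), 3)
  ph0 <- posthoc_pairwise(y0, group, NULL)
  expect_equal(ph0$t, rep(0, 3), tolerance = 1e-12)
})

test_that("BH adjustment matches hand computation and the selection rule", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(29)
  p <- runif(40)^2
  padj <- fdr_adjust(p)
  expect_true(all(padj >= p))
  # thresholding adjusted p at alpha reproduces classical BH selection
  alpha <- 0.05
  m <- length(p)
  ord <- order(p)
  k <- suppressWarnings(max(which(p[ord] <= alpha * seq_len(m) / m)))
  selected_bh <- if (is.finite(k)) ord[seq_len(k)] else integer(0)
  expect_setequal(which(padj <= alpha), selected_bh)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("partial correlation reduces to Pearson without covariates", {
  set.seed(37)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  br <- behavior_regression(x, y, NULL)
  expect_equal(br$r, cor(x, y), tolerance = 1e-12)
  expect_equal(br$p, cor.test(x, y)$p.value, tolerance = 1e-9)
  expect_error(behavior_regression(x[1:5], y[1:5], NULL), "complete cases")
})

test_that("partial correlation removes a pure covariate-driven association", {
  set.seed(43)
  n <- 200
  age <- rnorm(n, 50, 10)
  x <- 0.1 * age + rnorm(n, 0, 0.5)
  y <- 0.2 * age + rnorm(n, 0, 0.5)
  raw <- cor(x, y)
  br <- behavior_regression(x, y, data.frame(age = age))
  expect_gt(raw, 0.5)
  expect_lt(abs(br$r), 0.15)
})
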
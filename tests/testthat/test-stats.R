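test_that("Cohen's d matches hand evaluation and its categories", {
  g1 <- c(1, 2, 3); g2 <- g1
  es <- suppressWarnings(cohens_d(g1, g2))
  expect_equal(es$d, 0)
  expect_equal(es$category, "none")
  expect_equal(es$direction, "none")

  # M1 = 2, M2 = 1, SD1 = SD2 = 1 -> d = 1, large
  set.seed(1)
  a <- rnorm(5000); a <- (a - mean(a)) / sd(a) + 2
  b <- rnorm(5000); b <- (b - mean(b)) / sd(b) + 1
  es2 <- cohens_d(a, b)
  expect_equal(es2$d, 1.0, tolerance = 1e-12)
  expect_equal(es2$category, "large")
  expect_equal(es2$direction, "increase")

  expect_equal(effect_size_category(0.6), "medium")
  expect_equal(effect_size_category(-0.6), "medium")
  # boundaries fall upward exactly as printed
  expect_identical(effect_size_category(c(0.19, 0.2, 0.49, 0.5, 0.79, 0.8)),
                   c("none", "small", "small", "medium", "medium", "large"))
})

test_that("Cohen's d is antisymmetric and location/scale invariant", {
  set.seed(7)
  x <- rnorm(300, 5, 2); y <- rnorm(300, 6, 3)
  d_xy <- cohens_d(x, y)$d
  expect_identical(cohens_d(y, x)$d, -d_xy)
  expect_equal(cohens_d(x + 100, y + 100)$d, d_xy, tolerance = 1e-12)
  expect_equal(cohens_d(3.7 * x, 3.7 * y)$d, d_xy, tolerance = 1e-12)
})

test_that("degenerate groups are flagged", {
  expect_warning(es <- cohens_d(rep(1, 200), rep(2, 200)), "undefined")
  expect_true(is.na(es$d))
  expect_error(cohens_d(1, 1:5), "2 values")
  expect_warning(cohens_d(rnorm(10) + 10, rnorm(10)), "fewer than")
})

test_that("targeted effect sizes are recovered empirically", {
  set.seed(33)
  for (d_target in c(0.2, 0.5, 0.8, 2.0)) {
    g1 <- rnorm(1000, d_target, 1)
    g2 <- rnorm(1000, 0, 1)
    expect_lt(abs(cohens_d(g1, g2)$d - d_target), 0.1)
  }
})

test_that("coefficient of variation follows its definition", {
  expect_equal(coefficient_of_variation(rep(4.2, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  set.seed(9)
  x <- rlnorm(50)
  expect_equal(coefficient_of_variation(17 * x), coefficient_of_variation(x),
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(5), "2 values")
  expect_warning(v <- coefficient_of_variation(c(-3, 1)), "non-positive")
  expect_true(is.na(v))
})

test_that("z-scoring standardises every column and is invertible", {
  tab <- sample_feature_table(default_pbmc_profiles("quiescent"), 50,
                              rng_seed = 14)
  z <- zscore_features(tab)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  # inverse transform recovers the data
  back <- sweep(sweep(z, 2, attr(z, "scale"), "*"), 2, attr(z, "center"), "+")
  expect_equal(as.vector(back), as.vector(as.matrix(tab[, colnames(z)])),
               tolerance = 1e-12)

  # two-row symmetry
  z2 <- zscore_features(data.frame(a = c(1, 3)), "a")
  expect_equal(as.vector(z2), c(-sqrt(0.5), sqrt(0.5)))

  tab$flat <- 1
  expect_warning(z3 <- zscore_features(tab, c("orr", "flat")), "zero-variance")
  expect_identical(colnames(z3), "orr")
  expect_error(zscore_features(tab, c("orr", "nope")), "absent")
})

test_that("Ward clustering separates well-separated blobs at the first cut", {
  set.seed(21)
  x <- rbind(matrix(rnorm(100 * 2), ncol = 2),
             matrix(rnorm(100 * 2, mean = 10), ncol = 2))
  truth <- rep(1:2, each = 100)
  wc <- ward_cluster(x, annotations = data.frame(type = truth))
  tab <- table(wc$assignments, truth)
  expect_equal(min(max(tab[1, ]), max(tab[2, ])), 100)
  expect_equal(sum(diag(tab)) %% 200, 0)  # perfect split either labelling
})

test_that("duplicated rows merge first at height zero", {
  set.seed(2)
  x <- matrix(rnorm(12), ncol = 2)
  x[4, ] <- x[1, ]
  wc <- ward_cluster(x)
  expect_equal(wc$hclust$height[1], 0)
  expect_identical(sort(-wc$hclust$merge[1, ]), c(1L, 4L))
})

test_that("first Ward merges match the enumerated variance criterion", {
  set.seed(31)
  for (i in 1:10) {
    x <- matrix(rnorm(9), 3, 3)
    wc <- ward_cluster(x)
    oracle <- ward_first_merge(x)
    expect_identical(as.integer(sort(-wc$hclust$merge[1, ])), as.integer(sort(oracle$pair)))
    expect_equal(wc$hclust$height[1], oracle$height, tolerance = 1e-12)
  }
})

test_that("annotations never influence the dendrogram", {
  set.seed(41)
  x <- matrix(rnorm(60), ncol = 3)
  ann1 <- data.frame(donor = sample(letters[1:3], 20, TRUE))
  ann2 <- data.frame(donor = rev(ann1$donor))
  wc1 <- ward_cluster(x, ann1)
  wc2 <- ward_cluster(x, ann2)
  expect_identical(wc1$hclust$merge, wc2$hclust$merge)
  expect_identical(wc1$hclust$height, wc2$hclust$height)
  expect_error(ward_cluster(rbind(c(1, NA), c(2, 3))), "missing")
})

test_that("the dendrogram exports as Newick text", {
  set.seed(3)
  wc <- ward_cluster(matrix(rnorm(20), ncol = 2))
  nwk <- dendrogram_newick(wc)
  expect_match(nwk, "^\\(.*\\);$")
})

test_that("heterogeneity tables carry COV per stratum and variable", {
  q <- sample_feature_table(default_pbmc_profiles("quiescent"), 60,
                            rng_seed = 5, condition = "quiescent")
  a <- sample_feature_table(default_pbmc_profiles("activated"), 60,
                            rng_seed = 6, condition = "activated")
  het <- heterogeneity_table(rbind(q, a))
  expect_equal(nrow(het), 10 * 10)  # 5 types x 2 conditions x 10 variables
  expect_true(all(het$cov > 0))
  expect_equal(het$cov, het$sd / het$mean, tolerance = 1e-12)
  expect_true(all(het$n == 60))
})

test_that("activation effect sizes report the direction of change", {
  q <- sample_feature_table(default_pbmc_profiles("quiescent"), 200,
                            rng_seed = 15, condition = "quiescent")
  a <- sample_feature_table(default_pbmc_profiles("activated"), 200,
                            rng_seed = 16, condition = "activated")
  es <- activation_effect_sizes(rbind(q, a), by = "cell_type")
  # the configured qualitative pattern: lymphocyte tau_m falls, monocyte
  # rises; ORR rises and NAD(P)H tau1 falls for every type
  taum <- es[es$variable == "nadph_tau_m", ]
  expect_equal(taum$direction[taum$cell_type == "helper_T"], "decrease")
  expect_equal(taum$direction[taum$cell_type == "monocyte"], "increase")
  expect_true(all(es$direction[es$variable == "orr"] == "increase"))
  expect_true(all(es$direction[es$variable == "nadph_tau1"] == "decrease"))
})
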
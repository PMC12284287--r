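fake_profiles <- function(n = 30, seed = 1) {
  set.seed(seed)
  feats <- gpe_feature_names()
  x <- as.data.frame(matrix(rnorm(n * length(feats)), n,
                            dimnames = list(NULL, feats)))
  cbind(data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                   group = rep(c("a", "b"), length.out = n)), x)
}

test_that("rows with missing features are dropped, never imputed", {
  pr <- fake_profiles(10)
  pr$rheobase[c(2, 7)] <- NA
  expect_message(fm <- build_feature_matrix(pr), "dropping 2 rows")
  expect_equal(nrow(fm$x), 8)
  expect_setequal(fm$dropped, c("c002", "c007"))
  # z-scoring: each column mean 0, SD 1
  expect_true(all(abs(colMeans(fm$x)) < 1e-9))
  expect_true(all(abs(apply(fm$x, 2, sd) - 1) < 1e-9))
})

test_that("constant columns are excluded with a warning", {
  pr <- fake_profiles(12)
  pr$fi_slope <- 3
  expect_warning(fm <- build_feature_matrix(pr), "constant feature")
  expect_false("fi_slope" %in% fm$features)
  expect_equal(length(fm$features), 14)
  pr2 <- fake_profiles(3)[1:1, ]
  expect_error(build_feature_matrix(pr2), "fewer than 2")
})

test_that("correlation PCA satisfies its analytic identities", {
  pr <- fake_profiles(200, seed = 3)
  fm <- build_feature_matrix(pr)
  pc <- run_pca(fm)
  p <- length(fm$features)
  expect_equal(sum(pc$eigenvalues), p, tolerance = 1e-8)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  # orthonormal loadings
  expect_equal(crossprod(pc$loadings), diag(p), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full reconstruction of the z-scored matrix
  rec <- pc$scores %*% t(pc$loadings)
  expect_lt(max(abs(rec - fm$x)), 1e-8)
  # independent features at large n: eigenvalues near 1
  expect_true(all(abs(pc$eigenvalues - 1) < 0.6))
  # cross-check against prcomp on the same matrix
  pr2 <- stats::prcomp(fm$x, center = FALSE, scale. = FALSE)
  expect_equal(pc$eigenvalues, pr2$sdev^2, tolerance = 1e-6)
})

test_that("two perfectly correlated features collapse onto one component", {
  z <- rnorm(40)
  pr <- data.frame(cell_id = sprintf("c%d", 1:40), group = "a",
                   f1 = z, f2 = 2 * z + 5)
  fm <- build_feature_matrix(pr, feature_list = c("f1", "f2"))
  pc <- run_pca(fm)
  expect_equal(pc$eigenvalues, c(2, 0), tolerance = 1e-8)
  expect_equal(pc$n_retained, 1)
  expect_true(pc$rank_deficient)
})

test_that("Ward clustering separates point masses and is order invariant", {
  x <- rbind(matrix(rnorm(50, 0, 1e-3), 5), matrix(rnorm(50, 10, 1e-3), 5))
  pr <- cbind(data.frame(cell_id = sprintf("c%d", 1:10),
                         group = rep(c("g1", "g2"), each = 5)),
              as.data.frame(x))
  fm <- build_feature_matrix(pr, feature_list = paste0("V", 1:10))
  hc <- hier_cluster(fm, 2)
  expect_equal(unname(hc$purity), c(1, 1))
  expect_true(all(diff(hc$hclust$height) >= -1e-12))
  expect_error(hier_cluster(fm, 11), "k must lie")
  # permutation invariance up to label renaming
  perm <- sample(nrow(pr))
  fm2 <- build_feature_matrix(pr[perm, ], feature_list = paste0("V", 1:10))
  hc2 <- hier_cluster(fm2, 2)
  expect_equal(unname(hc2$purity), c(1, 1))
  agree <- table(hc$labels[perm], hc2$labels)
  expect_equal(sum(agree > 0), 2)  # one-to-one label correspondence
})

test_that("the dispatcher picks ANOVA for normal data and finds the shift", {
  set.seed(5)
  g <- list(a = rnorm(50), b = rnorm(50, 3), c = rnorm(50))
  r <- compare_groups(g)
  expect_identical(r$branch, "anova")
  expect_lt(r$omnibus_p, 1e-4)
  sig <- r$pairwise$p < 0.05
  hit_b <- grepl("b", r$pairwise$comparison)
  expect_true(all(sig == hit_b))
  expect_identical(p_stars(2e-5), "****")
  # three identical groups: omnibus p ~ 1
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  r0 <- compare_groups(same)
  expect_gt(r0$omnibus_p, 0.99)
  expect_true(all(r0$pairwise$p > 0.9))
})

test_that("non-normal or degenerate groups take the Kruskal-Wallis branch", {
  set.seed(6)
  h <- list(a = rcauchy(40), b = rcauchy(40), c = rcauchy(40, 3))
  r <- compare_groups(h)
  expect_identical(r$branch, "kruskal")
  expect_lt(r$omnibus_p, 0.05)
  d <- list(a = rep(1, 5), b = rnorm(5), c = rnorm(5))
  r2 <- compare_groups(d)
  expect_identical(r2$branch, "kruskal")
  expect_true("degenerate_group_forced_nonparametric" %in% r2$flags)
})

test_that("Dunn z equals the square root of the two-group KW statistic", {
  set.seed(7)
  v <- c(rnorm(12), rnorm(15, 1))
  g <- rep(c("a", "b"), c(12, 15))
  d <- dunn_test(v, g)
  H <- stats::kruskal.test(v, factor(g))$statistic
  expect_equal(d$z^2, unname(H), tolerance = 1e-9)
  # and with ties
  v2 <- round(v)
  H2 <- stats::kruskal.test(v2, factor(g))$statistic
  expect_equal(dunn_test(v2, g)$z^2, unname(H2), tolerance = 1e-9)
})
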
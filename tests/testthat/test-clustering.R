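test_that("k-means recovers two well-separated planted groups", {
  cent <- matrix(c(0, 0, 0, 10, 10, 10), nrow = 2, byrow = TRUE,
                 dimnames = list(NULL, c("t1", "t2", "t3")))
  pp <- planted_profiles(cent, n_per = 20, noise_sd = 0.3, seed = 4)
  fit <- kmeans_fit(pp$profiles, 2, n_restarts = 10, seed = 1)
  # agreement up to relabelling: brute force over both labelings
  agree <- max(mean(fit$cluster == pp$labels),
               mean(fit$cluster == 3 - pp$labels))
  expect_equal(agree, 1)
})

test_that("degenerate k values have closed-form WCSS", {
  x <- matrix(rnorm(30), nrow = 10,
              dimnames = list(sprintf("g%d", 1:10), c("a", "b", "c")))
  # k = n: every gene its own cluster, wcss = 0
  fit_n <- kmeans_fit(x, 10, n_restarts = 5, seed = 2)
  expect_equal(fit_n$wcss, 0)
  expect_equal(sort(unique(unname(fit_n$cluster))), 1:10)
  # k = 1: wcss = total SS around the grand centroid
  fit_1 <- kmeans_fit(x, 1, n_restarts = 2, seed = 2)
  expect_equal(fit_1$wcss, sum(scale(x, scale = FALSE)^2))
  # k > distinct rows errors
  xx <- x[rep(1:2, 5), ]
  expect_error(kmeans_fit(xx, 3, seed = 1), "distinct")
})

test_that("fitted models satisfy the centroid and occupancy invariants", {
  x <- planted_profiles(default_archetypes(), 30, 0.2, seed = 8)$profiles
  for (k in c(2, 5, 9)) {
    fit <- kmeans_fit(x, k, n_restarts = 10, seed = 3)
    expect_true(all(tabulate(fit$cluster, k) > 0))
    for (j in seq_len(k)) {
      members <- x[fit$cluster == j, , drop = FALSE]
      expect_lt(max(abs(fit$centers[j, ] - colMeans(members))), 1e-8)
    }
    # reported WCSS equals direct recomputation from assignments
    expect_equal(fit$wcss, oracle_wcss(x, fit$cluster, fit$centers))
  }
})

test_that("identical seeds give bit-identical fits", {
  x <- planted_profiles(default_archetypes(), 10, 0.3, seed = 5)$profiles
  f1 <- kmeans_fit(x, 4, n_restarts = 7, seed = 99)
  f2 <- kmeans_fit(x, 4, n_restarts = 7, seed = 99)
  expect_identical(f1, f2)
})

test_that("the WCSS curve is non-increasing and matches recomputation", {
  x <- planted_profiles(default_archetypes(), 40, 0.25, seed = 6)$profiles
  cfg <- run_config(k_min = 2, k_max = 12, n_restarts = 50, seed = 7)
  sw <- wcss_sweep(x, cfg)
  expect_equal(sw$curve$k, 2:12)
  expect_true(all(diff(sw$curve$wcss) <= 1e-9))
  for (k in c(2, 6, 12)) {
    m <- sw$models[[as.character(k)]]
    expect_equal(sw$curve$wcss[sw$curve$k == k],
                 oracle_wcss(x, m$cluster, m$centers))
  }
  expect_equal(sw$curve$gain[-1],
               -diff(sw$curve$wcss) / head(sw$curve$wcss, -1))
})

test_that("a sweep reaching the number of distinct rows hits wcss 0", {
  x <- default_archetypes()[rep(1:3, each = 5), 1:3]
  rownames(x) <- sprintf("g%02d", 1:15)
  cfg <- run_config(k_min = 2, k_max = 3, n_restarts = 5, seed = 1)
  sw <- wcss_sweep(x, cfg)
  expect_equal(sw$curve$wcss[sw$curve$k == 3], 0)
})

test_that("k-means matches the reference implementation's optimum", {
  # independent cross-check: same data, generous restarts on both sides
  x <- planted_profiles(default_archetypes(), 25, 0.3, seed = 10)$profiles
  ours <- kmeans_fit(x, 5, n_restarts = 50, seed = 11)
  ref <- stats::kmeans(x, 5, nstart = 50, iter.max = 1000,
                       algorithm = "Lloyd")
  expect_equal(ours$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("the elbow rule reproduces the worked example and edge cases", {
  curve <- data.frame(k = 2:6, wcss = c(100, 60, 50, 48, 47))
  sel <- select_k(curve, 0.05)
  expect_equal(sel$k, 4)
  expect_equal(sel$rationale, "elbow")
  expect_equal(sel$gains$gain,
               c(0.40, 10 / 60, 2 / 50, 1 / 48), tolerance = 1e-12)

  # strictly geometric curve: every gain 50%, rule exhausts at k_max
  geo <- data.frame(k = 2:15, wcss = 0.5^(2:15))
  sel_geo <- select_k(geo, 0.05)
  expect_equal(sel_geo$k, 15)
  expect_equal(sel_geo$rationale, "no-elbow")

  # piecewise-linear elbow family: wcss = A * max(k0 - k, 0) + B
  for (k0 in c(5, 7, 9)) {
    ks <- 2:12
    analytic <- data.frame(k = ks, wcss = 100 * pmax(k0 - ks, 0) + 1000)
    expect_equal(select_k(analytic, 0.05)$k, k0)
  }

  # a rising curve beyond tolerance signals insufficient restarts
  bad <- data.frame(k = 2:5, wcss = c(100, 60, 65, 40))
  expect_error(select_k(bad, 0.05), "increases")
})

test_that("cluster labels are deterministic and purely a permutation", {
  cent4 <- default_archetypes()[c(1, 3, 5, 7), ] * 3
  x <- planted_profiles(cent4, 20, 0.1, seed = 12)$profiles
  fit <- kmeans_fit(x, 4, n_restarts = 10, seed = 13)
  lab <- label_clusters(fit)
  expect_equal(lab$centers[, 1], sort(fit$centers[, 1]),
               ignore_attr = TRUE)
  expect_equal(lab$wcss, fit$wcss)
  expect_equal(sort(table(lab$cluster)), sort(table(fit$cluster)),
               ignore_attr = TRUE)
  # two clusters with first-stage centroids (1.2, -0.8) -> labels (2, 1)
  toy <- list(k = 2L,
              centers = matrix(c(1.2, 0, 0, -0.8, 0, 0), nrow = 2,
                               byrow = TRUE),
              cluster = c(a = 1L, b = 1L, c = 2L), wcss = 0)
  relab <- label_clusters(toy)
  expect_equal(unname(relab$cluster), c(2L, 2L, 1L))
  # permuting gene order leaves labels unchanged
  perm <- sample(nrow(x))
  fit_p <- label_clusters(kmeans_fit(x[perm, ], 4, n_restarts = 10,
                                     seed = 13))
  lab_map <- lab$cluster[rownames(x)[perm]]
  expect_equal(unname(fit_p$cluster), unname(lab_map))
})

test_that("planted archetypes are recovered with high ARI at 4+ sd separation", {
  arch <- default_archetypes()
  sep <- min(dist(arch))
  noise <- sep / 5  # per-coordinate sd; separation = 5 intra-cluster sd
  pp <- planted_profiles(arch, 100, noise, seed = 14)
  fit <- kmeans_fit(pp$profiles, 9, n_restarts = 50, seed = 15)
  expect_gte(ari(fit$cluster, pp$labels), 0.90)
})
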
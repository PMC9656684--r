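blobs <- function(centers, n_per, sd = 0.05, seed = 16) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  list(x = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("DBSCAN sweep covers the stated grid and resolves well-separated blobs", {
  b <- blobs(rbind(c(0, 0), c(5, 5)), 40)
  out <- sweep_dbscan(b$x)
  expect_length(out, 19)
  eps <- vapply(out, function(o) o$params$eps, numeric(1))
  expect_equal(eps, seq(0.10, 1.00, by = 0.05))
  expect_true(all(vapply(out, function(o) o$params$min_samples, numeric(1)) ==
                    ceiling(0.05 * 80)))
  good <- out[[which(abs(eps - 0.5) < 1e-9)]]
  expect_equal(good$n_clusters, 2)
  expect_equal(sum(good$labels == -1), 0)
  expect_equal(ari(good$labels, b$labels), 1)
  # epsilon below all pairwise distances: everything is noise, unscoreable
  spread <- matrix(seq(0, 100, length.out = 40), 40, 2)
  allnoise <- sweep_dbscan(spread, eps_grid = 0.1)[[1]]
  expect_true(all(allnoise$labels == -1))
  expect_false(allnoise$scoreable)
})

test_that("K-means sweep is deterministic and exact on 10-sigma-separated blobs", {
  b <- blobs(rbind(c(0, 0), c(3, 0), c(0, 3)), 30, sd = 0.05)
  out <- sweep_kmeans(b$x, seed = 77L)
  expect_length(out, 14)
  expect_equal(vapply(out, function(o) o$params$k, numeric(1)), 2:15)
  k3 <- out[[2]]
  expect_equal(ari(k3$labels, b$labels), 1)   # permutation-invariant exact match
  out2 <- sweep_kmeans(b$x, seed = 77L)
  expect_identical(out2[[2]]$labels, k3$labels)
})

test_that("Ward sweep cuts one deterministic tree at each k", {
  b <- blobs(rbind(c(0, 0), c(8, 8)), 30)
  out <- sweep_ward(b$x)
  expect_length(out, 14)
  expect_equal(ari(out[[1]]$labels, b$labels), 1)
  out2 <- sweep_ward(b$x)
  expect_identical(lapply(out, `[[`, "labels"), lapply(out2, `[[`, "labels"))
})

test_that("partition scores match the closed-form four-point case and label invariance", {
  # two pairs: intra-pair distance delta, inter-pair distance d >> delta
  delta <- 0.1; d <- 10
  X <- rbind(c(0, 0), c(delta, 0), c(d, 0), c(d + delta, 0))
  lab <- c(1, 1, 2, 2)
  sc <- score_partition(X, lab)
  # hand enumeration: a = delta; b = mean distance to the other pair
  a <- delta
  b1 <- (d + (d + delta)) / 2       # for point 1
  b2 <- ((d - delta) + d) / 2       # for point 2
  sil_exp <- mean(c((b1 - a) / b1, (b2 - a) / b2, (b2 - a) / b2, (b1 - a) / b1))
  expect_equal(sc$silhouette, sil_exp, tolerance = 1e-10)
  # CH from its definition
  grand <- colMeans(X)
  ssb <- 2 * sum((colMeans(X[1:2, ]) - grand)^2) + 2 * sum((colMeans(X[3:4, ]) - grand)^2)
  ssw <- sum((X[1:2, 1] - mean(X[1:2, 1]))^2) + sum((X[3:4, 1] - mean(X[3:4, 1]))^2)
  expect_equal(sc$calinski_harabasz, (ssb / 1) / (ssw / 2), tolerance = 1e-10)
  # label permutation leaves both scores unchanged
  sc2 <- score_partition(X, c(2, 2, 1, 1))
  expect_equal(sc2, sc)
  # identical points within clusters: CH is infinite
  Y <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_equal(score_partition(Y, lab)$calinski_harabasz, Inf)
  expect_error(score_partition(X, rep(1, 4)), "single cluster")
})

test_that("best-outcome selection reports score disagreement for contingency analysis", {
  b <- blobs(rbind(c(0, 0), c(4, 4), c(8, 0)), 25)
  km <- sweep_kmeans(b$x, k_grid = 2:6)
  best <- select_best(km)
  expect_true(best$by_silhouette$scoreable)
  expect_s3_class(best$by_silhouette, "ClusteringOutcome")
  # dominating outcome returned alone
  one <- list(km[[2]])
  both <- select_best(one)
  expect_true(both$agree)
  expect_error(select_best(list()), "no scoreable")
})

test_that("contingency agreement uses one-to-one matching and handles the swap case", {
  lab <- rep(1:2, each = 50)
  same <- contingency_agreement(lab, lab)
  expect_equal(same$agreement, 1.0)
  perm <- ifelse(lab == 1, 2, 1)
  expect_equal(contingency_agreement(lab, perm)$agreement, 1.0)
  # 100 points, 2 clusters, 50 swapped in B -> 0.5
  swapped <- lab
  swapped[c(1:25, 51:75)] <- 3 - swapped[c(1:25, 51:75)]
  expect_equal(contingency_agreement(lab, swapped)$agreement, 0.5)
  # symmetry and noise exclusion
  a <- c(rep(1, 30), rep(2, 30), -1)
  b2 <- c(rep(2, 30), rep(1, 15), rep(3, 15), -1)
  expect_equal(contingency_agreement(a, b2)$agreement,
               contingency_agreement(b2, a)$agreement)
  expect_error(contingency_agreement(rep(-1, 5), rep(1, 5)), "no frames")
})

test_that("cluster composition percentages tally the labelled frames", {
  labels <- c(1, 1, 2, 2, 2, -1)
  entities <- c("a", "b", "a", "a", "b", "a")
  comp <- cluster_composition(labels, entities)
  expect_equal(sum(comp$percent), 100, tolerance = 1e-9)
  expect_equal(comp$percent[comp$cluster == 1 & comp$entity == "a"], 20)
  expect_equal(comp$percent[comp$cluster == 2 & comp$entity == "a"], 40)
  # single-entity data: all clusters 100% that entity within their share
  comp1 <- cluster_composition(c(1, 1, 2), rep("only", 3))
  expect_equal(comp1$entity, rep("only", 2))
  # random labels against a direct tally
  set.seed(17)
  lab <- sample(1:3, 60, replace = TRUE)
  ent <- sample(c("x", "y"), 60, replace = TRUE)
  comp2 <- cluster_composition(lab, ent)
  for (r in seq_len(nrow(comp2))) {
    expect_equal(comp2$percent[r],
                 100 * sum(lab == comp2$cluster[r] & ent == comp2$entity[r]) / 60)
  }
})

test_that("medoids match brute force and break ties by lowest index", {
  set.seed(18)
  X <- matrix(rnorm(60), 30, 2)
  lab <- rep(1:3, each = 10)
  for (g in 1:3) {
    got <- representative_conformation(X, lab, g)
    rows <- which(lab == g)
    sums <- vapply(rows, function(i) sum(sqrt(colSums((t(X[rows, ]) - X[i, ])^2))),
                   numeric(1))
    expect_equal(got, rows[which.min(sums)])
  }
  # singleton cluster is its own representative
  expect_equal(representative_conformation(X, c(9, lab[-1]), 9), 1)
  # symmetric triangle: tie broken by the lowest frame index
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(representative_conformation(tri, rep(1, 3), 1), 1)
  expect_error(representative_conformation(X, lab, 99), "empty")
})
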
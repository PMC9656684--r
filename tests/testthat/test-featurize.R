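test_that("the extracted table carries exactly the 31-descriptor catalog", {
  cat31 <- feature_catalog()
  expect_equal(nrow(cat31), 31)
  expect_false(anyDuplicated(cat31$name) > 0)
  ft <- mini_features()
  expect_s3_class(ft, "FeatureTable")
  expect_identical(attr(ft, "state"), "raw")
  expect_identical(attr(ft, "features"), cat31$name)
  expect_equal(sum(startsWith(names(ft), "d_7")), 6 + 3 + 1)
  expect_false(anyNA(as.data.frame(ft)[, cat31$name]))
  # tyrosine pair block is C(4,2) = 6 columns
  expect_equal(sum(grepl("^d_7(03|21|30|47)_", names(ft))), 6)
  # angular columns stay in (-180, 180]
  ang <- as.matrix(as.data.frame(ft)[, grepl("^(phi|psi|T)", names(ft))])
  expect_true(all(ang > -180 & ang <= 180))
})

test_that("feature extraction is deterministic and identical frames give identical rows", {
  ens <- mini_ensemble()
  fr <- get_frame(ens$trajectory, 3)
  dup <- trajectory(fr$topology,
                    array(rep(fr$xyz, each = 2), c(2, nrow(fr$topology), 3)))
  ft <- extract_features(dup)
  feats <- attr(ft, "features")
  expect_identical(as.numeric(ft[1, feats]), as.numeric(ft[2, feats]))
  ft2 <- extract_features(dup)
  expect_identical(ft, ft2)
})

test_that("min-max scaling is per entity, idempotent, and flags constants", {
  set.seed(11)
  M <- matrix(rnorm(40), 20, 2)
  tab <- make_feature_table(M, entity = rep(c("a", "b"), each = 10))
  sc <- minmax_scale(tab)
  expect_identical(attr(sc, "state"), "scaled")
  for (ent in c("a", "b")) {
    sub <- as.data.frame(sc)[sc$entity == ent, attr(sc, "features")]
    expect_equal(unname(apply(sub, 2, min)), c(0, 0))
    expect_equal(unname(apply(sub, 2, max)), c(1, 1))
  }
  # idempotence
  sc2 <- minmax_scale(sc)
  expect_equal(as.data.frame(sc2), as.data.frame(sc), tolerance = 1e-12)
  # constant column within an entity maps to 0 with a warning
  M2 <- cbind(rep(1, 6), rnorm(6))
  tab2 <- make_feature_table(M2)
  expect_warning(sc3 <- minmax_scale(tab2), "constant")
  expect_equal(sc3$f1, rep(0, 6))
})

test_that("correlation matrix has unit diagonal and exact limits", {
  set.seed(12)
  x <- rnorm(30)
  M <- cbind(x, 2 * x + 1, -x, rnorm(30))
  tab <- make_feature_table(M)
  cm <- correlation_matrix(tab)
  expect_equal(diag(cm), setNames(rep(1, 4), attr(tab, "features")))
  expect_equal(cm[1, 2], 1)
  expect_equal(cm[1, 3], -1)
  expect_true(isSymmetric(cm))
})

test_that("pruning removes the higher-index member of each correlated pair", {
  set.seed(13)
  x <- rnorm(50)
  M <- cbind(x + rnorm(50, sd = 0.05),    # f1
             rnorm(50),                   # f2 independent
             x + rnorm(50, sd = 0.05),    # f3 correlated with f1
             rnorm(50))                   # f4 independent
  tab <- make_feature_table(M)
  pr <- prune_correlated(tab, threshold = 0.8)
  expect_identical(pr$removed, "f3")
  expect_identical(attr(pr$table, "features"), c("f1", "f2", "f4"))
  expect_identical(attr(pr$table, "state"), "pruned")
  # no removals below threshold
  ind <- make_feature_table(matrix(rnorm(200), 50, 4))
  expect_length(prune_correlated(ind, 0.8)$removed, 0)
  # duplicated column: exactly one copy removed
  dupe <- make_feature_table(cbind(x, x))
  expect_identical(prune_correlated(dupe)$removed, "f2")
  # retained set never contains a pair at or above the threshold
  set.seed(14)
  Z <- matrix(rnorm(40 * 6), 40, 6)
  Z[, 4] <- Z[, 1] * 0.95 + rnorm(40, sd = 0.1)
  Z[, 5] <- -Z[, 2]
  tabz <- make_feature_table(Z)
  prz <- prune_correlated(tabz, 0.8)
  keep <- attr(prz$table, "features")
  cmz <- correlation_matrix(tabz)[keep, keep]
  diag(cmz) <- 0
  expect_true(all(abs(cmz) < 0.8))
})

test_that("PCA reduction hits the variance target and matches an SVD oracle", {
  # isotropic 3-feature data: k = 3
  set.seed(15)
  iso <- matrix(rnorm(900), 300, 3)
  iso <- scale(iso, center = TRUE, scale = FALSE)
  sv <- svd(iso)
  iso <- iso %*% sv$v %*% diag(1 / sv$d) * sqrt(300)   # exactly equal variances
  p_iso <- pca_reduce(make_feature_table(iso), 0.80)
  expect_equal(p_iso$k, 3)
  # one dominant direction: k = 1
  dom <- cbind(rnorm(100, sd = 10), rnorm(100, sd = 0.5), rnorm(100, sd = 0.5))
  expect_equal(pca_reduce(make_feature_table(dom), 0.80)$k, 1)
  # random 50 x 10 against an independent SVD, up to per-component sign
  M <- matrix(rnorm(500), 50, 10)
  got <- pca_reduce(make_feature_table(M), 0.80)
  C <- scale(M, center = TRUE, scale = FALSE)
  sv2 <- svd(C)
  scores <- sv2$u %*% diag(sv2$d)
  for (j in seq_len(got$k)) {
    expect_true(max(abs(got$scores[, j] - scores[, j])) < 1e-8 ||
                  max(abs(got$scores[, j] + scores[, j])) < 1e-8)
  }
  # explained fractions sum to 1; scores are centred
  expect_equal(sum(got$explained), 1, tolerance = 1e-10)
  expect_equal(max(abs(colMeans(got$scores))), 0, tolerance = 1e-10)
  expect_error(pca_reduce(make_feature_table(M[1, , drop = FALSE])), "2 rows")
})
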
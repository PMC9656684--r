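## --- clustering outcomes -------------------------------------------------

new_outcome <- function(method, params, labels, data) {
  labs <- labels[labels != -1L]
  ncl <- length(unique(labs))
  scoreable <- ncl >= 2L && length(labs) > ncl
  sil <- NA_real_
  ch <- NA_real_
  if (scoreable) {
    sc <- score_partition(data[labels != -1L, , drop = FALSE], labs)
    sil <- sc$silhouette
    ch <- sc$calinski_harabasz
  }
  structure(list(method = method, params = params, labels = labels,
                 n_clusters = ncl, silhouette = sil, calinski_harabasz = ch,
                 scoreable = scoreable),
            class = "ClusteringOutcome")
}

#' @export
print.ClusteringOutcome <- function(x, ...) {
  cat("ClusteringOutcome:", x$method, "(",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "), ")\n")
  cat("  clusters:", x$n_clusters,
      " silhouette:", signif(x$silhouette, 4),
      " CH:", signif(x$calinski_harabasz, 6), "\n")
  invisible(x)
}

## --- DBSCAN (classic density-based algorithm) ----------------------------

## Plain DBSCAN on a Euclidean distance matrix; labels are 1..k with -1 for
## noise.  Deterministic: points are visited in index order.
dbscan_labels <- function(data, eps, min_pts) {
  n <- nrow(data)
  D <- as.matrix(stats::dist(data))
  neighbours <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  labels <- rep(0L, n)   # 0 = unvisited
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    if (length(neighbours[[i]]) < min_pts) {
      labels[i] <- -1L
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(neighbours[[i]], i)
    while (length(queue)) {
      q <- queue[1L]
      queue <- queue[-1L]
      if (labels[q] == -1L) labels[q] <- cl       # border point
      if (labels[q] != 0L) next
      labels[q] <- cl
      if (length(neighbours[[q]]) >= min_pts) {
        queue <- c(queue, setdiff(neighbours[[q]], which(labels != 0L)))
      }
    }
  }
  labels
}

#' DBSCAN hyperparameter sweep
#'
#' Runs DBSCAN over the epsilon grid 0.10, 0.15, ..., 1.00 (19 values) with
#' the minimum sample size fixed at 5 percent of the data
#' (`ceiling(0.05 * n)`).  Outcomes with fewer than 2 clusters are flagged
#' unscoreable.
#'
#' @param data numeric matrix of reduced scores (rows = frames).
#' @param eps_grid epsilon values to sweep.
#' @param min_samples_frac minimum-sample fraction of `n`.
#' @return List of `ClusteringOutcome`.
#' @export
sweep_dbscan <- function(data, eps_grid = seq(0.10, 1.00, by = 0.05),
                         min_samples_frac = 0.05) {
  stopifnot(nrow(data) >= 1L)
  min_pts <- ceiling(min_samples_frac * nrow(data))
  lapply(eps_grid, function(eps) {
    labels <- dbscan_labels(data, eps, min_pts)
    new_outcome("dbscan", list(eps = eps, min_samples = min_pts), labels, data)
  })
}

#' K-means hyperparameter sweep
#'
#' One outcome per k in 2..15, with the iteration budget split over
#' restarts (10 restarts of up to 100 Lloyd iterations, i.e. a 1000
#' iteration budget per k) and a fixed recorded seed for reproducibility.
#'
#' @param data numeric matrix (rows = frames); needs `nrow(data) >= 15`.
#' @param seed integer seed recorded in every outcome.
#' @param k_grid cluster counts to sweep.
#' @return List of `ClusteringOutcome`.
#' @export
sweep_kmeans <- function(data, seed = 1234L, k_grid = 2:15) {
  stopifnot(nrow(data) >= max(k_grid))
  out <- list()
  for (k in k_grid) {
    if (nrow(data) < k) {
      warning("skipping k = ", k, ": fewer rows than clusters")
      next
    }
    set.seed(seed)
    km <- stats::kmeans(data, centers = k, iter.max = 100L, nstart = 10L)
    out[[length(out) + 1L]] <- new_outcome(
      "kmeans", list(k = k, seed = seed, iter_budget = 1000L),
      as.integer(km$cluster), data)
  }
  out
}

#' Ward hierarchical clustering sweep
#'
#' Builds a single Ward tree (Ward's minimum-variance criterion on
#' Euclidean distances) and cuts it at each k in 2..15.
#'
#' @param data numeric matrix (rows = frames).
#' @param k_grid cluster counts at which to cut the tree.
#' @return List of `ClusteringOutcome`.
#' @export
sweep_ward <- function(data, k_grid = 2:15) {
  stopifnot(nrow(data) >= max(k_grid))
  hc <- stats::hclust(stats::dist(data), method = "ward.D2")
  lapply(k_grid, function(k) {
    new_outcome("ward", list(k = k), as.integer(stats::cutree(hc, k = k)), data)
  })
}

#' Silhouette and Calinski-Harabasz scores of a partition
#'
#' Silhouette: mean over points of `(b - a) / max(a, b)` where `a` is the
#' mean intra-cluster distance and `b` the smallest mean distance to
#' another cluster.  Calinski-Harabasz: between-cluster dispersion over
#' `k - 1`, divided by within-cluster dispersion over `n - k`; `Inf` when
#' the within-cluster dispersion is zero.
#'
#' @param data numeric matrix of clustered points (noise already removed).
#' @param labels integer labels, at least 2 distinct values.
#' @return List with `silhouette` and `calinski_harabasz`.
#' @export
score_partition <- function(data, labels) {
  stopifnot(nrow(data) == length(labels))
  ks <- unique(labels)
  if (length(ks) < 2L) stop("scores are undefined for a single cluster")
  sil <- mean(cluster::silhouette(as.integer(factor(labels)),
                                  stats::dist(data))[, "sil_width"])
  n <- nrow(data)
  k <- length(ks)
  grand <- colMeans(data)
  ssw <- 0
  ssb <- 0
  for (g in ks) {
    rows <- which(labels == g)
    cm <- colMeans(data[rows, , drop = FALSE])
    ssw <- ssw + sum(sweep(data[rows, , drop = FALSE], 2L, cm)^2)
    ssb <- ssb + length(rows) * sum((cm - grand)^2)
  }
  ch <- if (ssw == 0) Inf else (ssb / (k - 1)) / (ssw / (n - k))
  list(silhouette = sil, calinski_harabasz = ch)
}

#' Select the best clustering outcome(s)
#'
#' Ranks scoreable outcomes by Silhouette and by Calinski-Harabasz.  When
#' both criteria agree, a single outcome is returned; when they disagree
#' both are returned, flagged for contingency analysis.
#'
#' @param outcomes list of `ClusteringOutcome` (e.g. from the sweeps).
#' @return List with `by_silhouette`, `by_calinski_harabasz` and `agree`
#'   (logical: the two are the same outcome).
#' @export
select_best <- function(outcomes) {
  sc <- Filter(function(o) isTRUE(o$scoreable), outcomes)
  if (length(sc) == 0L) stop("no scoreable clustering outcome")
  sils <- vapply(sc, `[[`, numeric(1), "silhouette")
  chs <- vapply(sc, `[[`, numeric(1), "calinski_harabasz")
  bi <- which.max(sils)
  bc <- which.max(chs)
  list(by_silhouette = sc[[bi]], by_calinski_harabasz = sc[[bc]],
       agree = identical(sc[[bi]]$params, sc[[bc]]$params) &&
         sc[[bi]]$method == sc[[bc]]$method)
}

## Maximum-weight one-to-one assignment on a (small) non-negative matrix,
## by exact dynamic programming over column subsets.  Returns row -> column
## (NA where a row is unmatched).
max_assignment <- function(W) {
  nr <- nrow(W)
  nc <- ncol(W)
  if (nr > nc) {
    tr <- max_assignment(t(W))
    out <- rep(NA_integer_, nr)
    out[tr[!is.na(tr)]] <- which(!is.na(tr))
    return(out)
  }
  if (nc > 25L) stop("assignment matrix too large for exact matching")
  nstates <- bitwShiftL(1L, nc)
  NEG <- -Inf
  best <- matrix(NEG, nr + 1L, nstates)
  best[1L, 1L] <- 0
  choice <- matrix(NA_integer_, nr + 1L, nstates)
  for (r in seq_len(nr)) {
    for (s in 0:(nstates - 1L)) {
      b <- best[r, s + 1L]
      if (b == NEG) next
      for (cidx in seq_len(nc)) {
        bit <- bitwShiftL(1L, cidx - 1L)
        if (bitwAnd(s, bit) != 0L) next
        s2 <- bitwOr(s, bit)
        v <- b + W[r, cidx]
        if (v > best[r + 1L, s2 + 1L]) {
          best[r + 1L, s2 + 1L] <- v
          choice[r + 1L, s2 + 1L] <- cidx
        }
      }
    }
  }
  s_best <- which.max(best[nr + 1L, ]) - 1L
  assign <- rep(NA_integer_, nr)
  s <- s_best
  for (r in rev(seq_len(nr))) {
    cidx <- choice[r + 1L, s + 1L]
    assign[r] <- cidx
    s <- bitwAnd(s, bitwNot(bitwShiftL(1L, cidx - 1L)))
  }
  assign
}

#' Contingency agreement between two clusterings
#'
#' Cross-tabulates two labelings of the same frames (noise points in either
#' labeling are dropped pairwise), finds the maximum-weight one-to-one
#' matching between the two cluster sets, and reports the matched-cell mass
#' as the strong-agreement fraction.
#'
#' @param labelsA,labelsB integer label vectors of equal length (`-1` =
#'   noise).
#' @return List of class `"ContingencyReport"` with `table`, `matching`
#'   (data.frame `cluster_a`, `cluster_b`, `count`) and `agreement` in
#'   `[0, 1]`.
#' @export
contingency_agreement <- function(labelsA, labelsB) {
  stopifnot(length(labelsA) == length(labelsB))
  keep <- labelsA != -1L & labelsB != -1L
  if (!any(keep)) stop("no frames clustered in both labelings")
  a <- factor(labelsA[keep])
  b <- factor(labelsB[keep])
  tab <- table(a, b)
  W <- matrix(as.numeric(tab), nrow(tab), ncol(tab))
  assign <- max_assignment(W)
  rows <- which(!is.na(assign))
  matching <- data.frame(
    cluster_a = as.integer(as.character(rownames(tab)[rows])),
    cluster_b = as.integer(as.character(colnames(tab)[assign[rows]])),
    count = W[cbind(rows, assign[rows])])
  structure(list(table = tab, matching = matching,
                 agreement = sum(matching$count) / sum(W)),
            class = "ContingencyReport")
}

#' @export
print.ContingencyReport <- function(x, ...) {
  cat("ContingencyReport: strong agreement",
      sprintf("%.1f%%", 100 * x$agreement), "\n")
  print(x$table)
  invisible(x)
}

#' Cluster composition by entity
#'
#' For every cluster, the percentage of all clustered frames contributed by
#' each entity; percentages over the whole table sum to 100.
#'
#' @param labels integer labels (`-1` = noise, excluded).
#' @param entities character vector of per-frame entity labels.
#' @return `data.frame` with columns `cluster`, `entity`, `percent`.
#' @export
cluster_composition <- function(labels, entities) {
  stopifnot(length(labels) == length(entities))
  keep <- labels != -1L
  n <- sum(keep)
  tab <- table(cluster = labels[keep], entity = entities[keep])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df$percent <- 100 * df$Freq / n
  df <- df[, c("cluster", "entity", "percent")]
  df$cluster <- as.integer(df$cluster)
  df[order(df$cluster, df$entity), , drop = FALSE]
}

#' Representative conformation (medoid) of a cluster
#'
#' The cluster member minimising the summed Euclidean distance to its
#' co-members in the reduced space; ties broken by the lowest frame index.
#'
#' @param data numeric matrix of reduced scores.
#' @param labels integer labels over the rows of `data`.
#' @param cluster cluster id.
#' @return The frame (row) index of the medoid.
#' @export
representative_conformation <- function(data, labels, cluster) {
  rows <- which(labels == cluster)
  if (length(rows) == 0L) stop("cluster ", cluster, " is empty")
  if (length(rows) == 1L) return(rows)
  D <- as.matrix(stats::dist(data[rows, , drop = FALSE]))
  sums <- rowSums(D)
  rows[which(sums <= min(sums) + 1e-12)[1L]]
}
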
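## FNV-1a 32-bit hash of a string; used to stamp output artifacts with a
## config fingerprint without external dependencies.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h - 2^32 * (h >= 2^31)), b)
    h <- h %% 2^32
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis.  Input is either a list
#' of multi-model PDB paths with entity labels, or a synthetic-ensemble
#' specification.
#'
#' @param input either `list(pdbs = c(path1, ...), entities = c(...))` or a
#'   `SyntheticEnsembleSpec`.
#' @param roles a `ResidueRoles`.
#' @param criteria a `ContactCriteria`.
#' @param stride_ps analysis stride in ps (default 100); applied when the
#'   input trajectories are finer-grained.
#' @param variance_target PCA cumulative-variance target.
#' @param prune_threshold absolute-correlation pruning threshold.
#' @param kmeans_seed seed recorded for the K-means restarts.
#' @param fel list of free-energy-landscape settings: `coords` (`"pca"`,
#'   `"T1"`, `"T2"` or `"T3"`), `temperature` (K), `k` (`NULL` =
#'   `ceiling(sqrt(n))`), `grid` (bin counts), `depth_min` (kcal/mol).
#' @param outdir output directory (created if needed).
#' @param seed master seed recorded in the report.
#' @return An object of class `"PipelineConfig"`.
#' @export
pipeline_config <- function(input, roles = residue_roles(),
                            criteria = contact_criteria(), stride_ps = 100,
                            variance_target = 0.80, prune_threshold = 0.8,
                            kmeans_seed = 1234L,
                            fel = list(coords = "pca", temperature = 310,
                                       k = NULL, grid = c(100L, 100L),
                                       depth_min = 1.0),
                            outdir = tempfile("idrfel_run_"), seed = 42L) {
  if (!inherits(input, "SyntheticEnsembleSpec")) {
    if (!is.list(input) || is.null(input$pdbs) || is.null(input$entities)) {
      stop("input must be a SyntheticEnsembleSpec or list(pdbs=, entities=)")
    }
    missing <- input$pdbs[!file.exists(input$pdbs)]
    if (length(missing)) stop("input file(s) not found: ",
                              paste(missing, collapse = ", "))
  }
  defaults <- list(coords = "pca", temperature = 310, k = NULL,
                   grid = c(100L, 100L), depth_min = 1.0)
  fel <- utils::modifyList(defaults, fel, keep.null = TRUE)
  structure(list(input = input, roles = roles, criteria = criteria,
                 stride_ps = stride_ps, variance_target = variance_target,
                 prune_threshold = prune_threshold,
                 kmeans_seed = as.integer(kmeans_seed), fel = fel,
                 outdir = outdir, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the [pipeline_config()] arguments; residue roles
#' and contact criteria are given as nested mappings.
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  roles <- if (is.null(y$roles)) residue_roles() else do.call(residue_roles, y$roles)
  criteria <- if (is.null(y$criteria)) contact_criteria() else
    do.call(contact_criteria, y$criteria)
  input <- if (!is.null(y$synthetic)) {
    do.call(default_three_basin_spec,
            y$synthetic[intersect(names(y$synthetic), c("n_frames", "seed"))])
  } else {
    list(pdbs = vapply(y$input, `[[`, character(1), "pdb"),
         entities = vapply(y$input, `[[`, character(1), "entity"))
  }
  args <- list(input = input, roles = roles, criteria = criteria)
  for (k in c("stride_ps", "variance_target", "prune_threshold", "kmeans_seed",
              "fel", "outdir", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipeline_config, args)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full ensemble-analysis pipeline
#'
#' Chains feature extraction, per-entity scaling, correlation pruning, PCA
#' reduction, the three clustering sweeps with score-based selection,
#' contingency agreement between the Silhouette-best and
#' Calinski-Harabasz-best clusterings, cluster composition by entity,
#' representative (medoid) frames, and the free-energy landscape with well
#' detection.  All artifacts are written to `config$outdir` as CSV/JSON
#' with the seed and a config fingerprint embedded in the report.
#'
#' @param config a `PipelineConfig`.
#' @return Invisibly, a list with every intermediate result (`ensemble`,
#'   `features_raw`, `features_scaled`, `pruned`, `pca`, `sweeps`, `best`,
#'   `contingency`, `composition`, `medoids`, `fel`, `wells`, `report`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  true_labels <- NULL
  traj <- run_stage("input", {
    if (inherits(config$input, "SyntheticEnsembleSpec")) {
      ens <- sample_ensemble(config$input, frame_spacing_ps = config$stride_ps)
      true_labels <- ens$true_labels
      ens$trajectory
    } else {
      trajs <- mapply(read_multimodel_pdb, config$input$pdbs,
                      config$input$entities, SIMPLIFY = FALSE)
      concatenate(lapply(trajs, function(tr) {
        if (tr$frame_spacing_ps < config$stride_ps) subsample(tr, config$stride_ps)
        else tr
      }))
    }
  })
  feats <- run_stage("features",
                     extract_features(traj, config$roles, config$criteria))
  scaled <- run_stage("scale", minmax_scale(feats))
  pr <- run_stage("prune", prune_correlated(scaled, config$prune_threshold))
  pca <- run_stage("pca", pca_reduce(pr$table, config$variance_target))
  sweeps <- run_stage("cluster", list(
    dbscan = sweep_dbscan(pca$scores),
    kmeans = sweep_kmeans(pca$scores, seed = config$kmeans_seed),
    ward = sweep_ward(pca$scores)))
  best <- run_stage("select", select_best(c(sweeps$dbscan, sweeps$kmeans,
                                            sweeps$ward)))
  contingency <- run_stage("contingency", {
    if (best$agree) NULL else contingency_agreement(best$by_silhouette$labels,
                                                    best$by_calinski_harabasz$labels)
  })
  composition <- run_stage("composition",
                           cluster_composition(best$by_silhouette$labels, traj$entity))
  medoids <- run_stage("medoids", {
    labs <- best$by_silhouette$labels
    cl <- sort(unique(labs[labs != -1L]))
    data.frame(cluster = cl, frame = vapply(cl, function(g)
      representative_conformation(pca$scores, labs, g), numeric(1)))
  })
  felres <- run_stage("fel", {
    co <- config$fel$coords
    if (identical(co, "pca")) {
      c1 <- pca$scores[, 1L]
      c2 <- if (ncol(pca$scores) >= 2L) pca$scores[, 2L] else pca$scores[, 1L]
    } else {
      td <- td_coordinates(feats, co, config$roles)
      c1 <- td$torsion; c2 <- td$distance
    }
    grid <- free_energy_landscape(c1, c2, temperature = config$fel$temperature,
                                  k = config$fel$k, grid = config$fel$grid)
    list(grid = grid, wells = fel_wells(grid, config$fel$depth_min))
  })
  report <- list(
    package = "idrfel",
    version = as.character(utils::packageVersion("idrfel")),
    seed = config$seed, kmeans_seed = config$kmeans_seed,
    config_hash = fnv1a_hash(config_fingerprint(config)),
    n_frames = n_frames(traj), n_features_raw = length(feature_cols(feats)),
    removed_features = pr$removed, pca_k = pca$k,
    pca_explained = pca$explained,
    best_silhouette = list(method = best$by_silhouette$method,
                           params = best$by_silhouette$params,
                           silhouette = best$by_silhouette$silhouette,
                           calinski_harabasz = best$by_silhouette$calinski_harabasz),
    best_calinski_harabasz = list(method = best$by_calinski_harabasz$method,
                                  params = best$by_calinski_harabasz$params,
                                  silhouette = best$by_calinski_harabasz$silhouette,
                                  calinski_harabasz = best$by_calinski_harabasz$calinski_harabasz),
    selection_agrees = best$agree,
    agreement = if (is.null(contingency)) 1.0 else contingency$agreement,
    fel = list(kBT = felres$grid$kBT, temperature = felres$grid$temperature,
               k = felres$grid$knn_k, coords = config$fel$coords,
               n_wells = nrow(felres$wells)))
  write_pipeline_outputs(config$outdir, feats, scaled, pr, pca, best,
                         contingency, composition, medoids, felres, report,
                         true_labels)
  invisible(list(ensemble = traj, true_labels = true_labels,
                 features_raw = feats, features_scaled = scaled, pruned = pr,
                 pca = pca, sweeps = sweeps, best = best,
                 contingency = contingency, composition = composition,
                 medoids = medoids, fel = felres$grid, wells = felres$wells,
                 report = report))
}

config_fingerprint <- function(config) {
  keep <- config[setdiff(names(config), "outdir")]
  if (inherits(keep$input, "SyntheticEnsembleSpec")) {
    keep$input <- list(sequence = paste(keep$input$sequence, collapse = ""),
                       n_frames = keep$input$n_frames, seed = keep$input$seed)
  }
  jsonlite::toJSON(keep, auto_unbox = TRUE, force = TRUE, digits = NA)
}

write_pipeline_outputs <- function(outdir, feats, scaled, pr, pca, best,
                                   contingency, composition, medoids, felres,
                                   report, true_labels) {
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  wcsv(as.data.frame(feats), "features_raw.csv")
  wcsv(as.data.frame(scaled), "features_scaled.csv")
  wcsv(as.data.frame(pr$table), "features_pruned.csv")
  sc <- as.data.frame(pca$scores)
  sc <- cbind(frame = feats$frame, sc)
  wcsv(sc, "pca_scores.csv")
  labs <- data.frame(frame = feats$frame, entity = feats$entity,
                     label_silhouette_best = best$by_silhouette$labels,
                     label_ch_best = best$by_calinski_harabasz$labels)
  if (!is.null(true_labels)) labs$true_basin <- true_labels
  wcsv(labs, "cluster_labels.csv")
  if (!is.null(contingency)) {
    wcsv(as.data.frame(contingency$table), "contingency.csv")
  }
  wcsv(composition, "cluster_composition.csv")
  wcsv(medoids, "medoids.csv")
  g <- felres$grid
  fel_df <- expand.grid(axis1 = g$axis1, axis2 = g$axis2)
  fel_df$delta_g <- as.vector(g$delta_g)
  wcsv(fel_df, "fel_grid.csv")
  wcsv(felres$wells, "fel_wells.csv")
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
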
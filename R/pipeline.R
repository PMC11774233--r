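# End-to-end pipeline: ingest -> descriptor -> (scale/resample/subsample)
# -> optional embedding -> optional clustering -> per-cluster statistics.
# Driven by a flat key-value configuration (YAML mapping of scalars) shared
# with the command-line interface.

.PIPELINE_DEFAULTS <- list(
  root_dir = ".",
  reference = NULL,           # default: <root_dir>/geom.xyz
  descriptor = "r2",
  ring_atoms = NULL,          # e.g. "1,2,3,4,5,6" for cremer_pople
  scaler = "none",            # zscore | minmax | none
  stride_fs = NULL,           # e.g. 0.5 to thin 0.1 fs data
  n_samples = NULL,           # random subsample size
  seed = 1L,
  embed_method = "none",      # pca | isomap | tsne | none
  n_components = 2L,
  n_neighbors = 30L,
  perplexity = 30,
  cluster_algorithm = "none", # kmeans | gmm | hierarchical | spectral | none
  n_clusters = "best",
  k_range = "2:6",
  linkage = "ward",
  properties = "DE21,Hops_S21,Hops_S12",
  out_dir = "ulout",
  log_level = "info")

#' Assemble a pipeline configuration
#'
#' Merges user keys over the documented defaults.  \code{config} may be a
#' named list or the path of a flat YAML file (scalar keys only).
#'
#' @param config named list or YAML file path.
#' @param ... individual key overrides (take precedence).
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or a file path")
  unknown <- setdiff(names(config), names(.PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, config, keep.null = TRUE)
  cfg <- utils::modifyList(cfg, list(...), keep.null = TRUE)
  structure(cfg, class = c("pipeline_config", "list"))
}

.parse_int_vec <- function(s) {
  if (is.numeric(s)) return(as.integer(s))
  if (grepl(":", s)) {
    parts <- as.integer(strsplit(s, ":")[[1]])
    return(parts[1]:parts[2])
  }
  as.integer(strsplit(as.character(s), ",")[[1]])
}

.plog <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message(...)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: ensemble ingestion (writing the merged property table
#' with per-frame RMSD), descriptor generation, descriptive statistics,
#' then optionally scaling/resampling/subsampling, embedding and clustering
#' with per-cluster property statistics.  Every output is a CSV under
#' \code{out_dir}; a JSON manifest records all parameters and seeds used.
#' Any stage failure aborts with a stage-named error; outputs written by
#' earlier stages are retained.
#'
#' @param config a \code{\link{pipeline_config}}, named list, or YAML path.
#' @param stop_after optionally stop early: \code{"ingest"} (ensemble table
#'   only) or \code{"describe"} (descriptor + statistics, no embedding or
#'   clustering).
#' @return named list of written file paths, invisibly.
#' @export
run_pipeline <- function(config = list(), stop_after = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ens <- stage("ingest", load_ensemble(cfg$root_dir))
  .plog(cfg, "ingest: ", ens$n_frames, " frames / ", ens$n_trajs, " trajectories")
  ref_path <- if (is.null(cfg$reference)) file.path(cfg$root_dir, "geom.xyz")
              else cfg$reference
  ens_table <- ens$properties
  reference <- NULL
  if (file.exists(ref_path)) {
    reference <- stage("ingest", read_reference_geometry(ref_path))
    ens_table$rmsd <- stage("rmsd", rmsd_series(ens, reference)$rmsd)
  }
  outputs$ensemble <- file.path(cfg$out_dir, "ensemble.csv")
  stage("ingest", write_dataset_csv(ens_table, outputs$ensemble))
  if (identical(stop_after, "ingest")) return(invisible(outputs))

  ring <- if (!is.null(cfg$ring_atoms)) .parse_int_vec(cfg$ring_atoms)
  feat <- stage("descriptor",
                descriptor_dataset(ens, cfg$descriptor, reference = reference,
                                   ring_atoms = ring))
  outputs$descriptor <- file.path(cfg$out_dir, "descriptor.csv")
  stage("descriptor", write_dataset_csv(feat, outputs$descriptor))

  stats_df <- stage("stats", .describe_table(feat))
  outputs$descriptor_stats <- file.path(cfg$out_dir, "descriptor_stats.csv")
  utils::write.csv(stats_df, outputs$descriptor_stats, row.names = FALSE,
                   quote = FALSE)
  if (identical(stop_after, "describe")) return(invisible(outputs))

  work <- feat
  if (!is.null(cfg$stride_fs))
    work <- stage("prep", resample_by_stride(work, as.numeric(cfg$stride_fs)))
  if (!is.null(cfg$n_samples) && as.integer(cfg$n_samples) < nrow(work))
    work <- stage("prep", random_subsample(work, as.integer(cfg$n_samples),
                                           seed = cfg$seed))
  if (cfg$scaler == "zscore") work <- stage("prep", zscore_scale(work)$table)
  else if (cfg$scaler == "minmax") work <- stage("prep", minmax_scale(work)$table)
  else if (cfg$scaler != "none") stop("unknown scaler: ", cfg$scaler)

  if (cfg$embed_method != "none") {
    emb <- stage("embed", switch(cfg$embed_method,
      pca = pca_fit_transform(work, as.integer(cfg$n_components)),
      isomap = isomap_fit_transform(work, as.integer(cfg$n_neighbors),
                                    as.integer(cfg$n_components)),
      tsne = tsne_fit_transform(work, as.numeric(cfg$perplexity),
                                as.integer(cfg$n_components),
                                seed = cfg$seed),
      stop("unknown embed method: ", cfg$embed_method)))
    outputs$embedding <- file.path(cfg$out_dir, "embedding.csv")
    stage("embed", write_dataset_csv(as.data.frame(emb), outputs$embedding))
  }

  if (cfg$cluster_algorithm != "none") {
    k <- cfg$n_clusters
    if (identical(k, "best")) {
      k <- stage("cluster", select_k_best(work, .parse_int_vec(cfg$k_range),
                                          cfg$cluster_algorithm,
                                          seed = cfg$seed))
      .plog(cfg, "cluster: selected k = ", k)
    }
    res <- stage("cluster",
                 run_clustering(work, cfg$cluster_algorithm, as.integer(k),
                                seed = cfg$seed))
    labels_df <- cbind(res$keys, label = res$labels)
    outputs$labels <- file.path(cfg$out_dir, "labels.csv")
    stage("cluster", write_dataset_csv(labels_df, outputs$labels))

    key <- paste(res$keys$traj, round(res$keys$time, 6))
    prop_key <- paste(ens_table$traj, round(ens_table$time, 6))
    props <- ens_table[match(key, prop_key), , drop = FALSE]
    wanted <- strsplit(cfg$properties, ",")[[1]]
    summ <- stage("stats", cluster_statistics(props, res$labels, wanted))
    outputs$cluster_summary <- file.path(cfg$out_dir, "cluster_summary.csv")
    write_cluster_summary(summ, outputs$cluster_summary)
  }

  manifest <- c(unclass(cfg), list(
    n_frames = ens$n_frames, n_trajs = ens$n_trajs,
    n_rows_analysed = nrow(work),
    package_version = as.character(utils::packageVersion("namdclust")),
    r_version = R.version.string,
    outputs = lapply(outputs, normalizePath)))
  outputs$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, outputs$manifest, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  .plog(cfg, "pipeline: wrote ", length(outputs), " artifacts to ", cfg$out_dir)
  invisible(outputs)
}

# mean / median / population-std per feature column
.describe_table <- function(t) {
  fm <- feature_matrix(t)
  data.frame(feature = colnames(fm$x),
             mean = colMeans(fm$x),
             median = apply(fm$x, 2, stats::median),
             std = sqrt(colMeans(sweep(fm$x, 2, colMeans(fm$x))^2)),
             row.names = NULL)
}
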
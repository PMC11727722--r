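#' Build a validated pipeline configuration
#'
#' Collects every knob of the end-to-end run. Graph construction uses a
#' distance radius when `rad_cutoff` is given, otherwise symmetrized
#' k-nearest neighbors with `knn_k`. `cost_ssc` is the trade-off weight
#' of the multiscale self-expression loss; `alpha` mixes spatial and
#' cell-type-aware attention; `method` picks the final domain-calling
#' algorithm.
#'
#' @param rad_cutoff optional spatial radius; `NULL` selects k-NN.
#' @param knn_k spatial neighbors when `rad_cutoff` is `NULL` (default 6).
#' @param cost_ssc self-expression trade-off weight (default 0.1).
#' @param alpha attention mixing weight in `[0, 1]` (default 0).
#' @param method final clustering: `"louvain"`, `"leiden"`, `"gmm"` or
#'   `"mclust"`.
#' @param n_clusters number of clusters `m` for the subspace module and
#'   the gmm route; also the resolution-tuning target when `target_k` is
#'   unset.
#' @param target_k optional target domain count for resolution tuning.
#' @param hvg_n highly variable genes to keep (capped at the gene count).
#' @param epochs_pre,epochs_joint,refresh_every,lr training schedule.
#' @param hidden_dims,head_dims network widths.
#' @param refine run neighborhood-vote refinement on the labels?
#' @param r_refine refinement radius (default 50 coordinate units).
#' @param precluster_resolution Louvain resolution for the expression
#'   preclustering behind the cell-type-aware graph.
#' @param seed master seed for the run.
#' @return A validated `spadom_config` list.
#' @export
spadom_config <- function(rad_cutoff = NULL, knn_k = 6, cost_ssc = 0.1,
                          alpha = 0, method = "louvain", n_clusters = 4,
                          target_k = NULL, hvg_n = 3000,
                          epochs_pre = 500, epochs_joint = 300,
                          refresh_every = 50, lr = 1e-4,
                          hidden_dims = c(512, 30),
                          head_dims = c(128, 64, 32),
                          refine = TRUE, r_refine = 50,
                          precluster_resolution = 1.0, seed = 0) {
  if (!is.null(rad_cutoff) && rad_cutoff <= 0) stop("rad_cutoff must be positive")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (cost_ssc < 0) stop("cost_ssc must be non-negative")
  if (!method %in% c("louvain", "leiden", "gmm", "mclust"))
    stop("unknown method: ", method)
  if (n_clusters < 2) stop("n_clusters must be at least 2")
  structure(list(rad_cutoff = rad_cutoff, knn_k = knn_k, cost_ssc = cost_ssc,
                 alpha = alpha, method = method, n_clusters = n_clusters,
                 target_k = target_k, hvg_n = hvg_n,
                 epochs_pre = epochs_pre, epochs_joint = epochs_joint,
                 refresh_every = refresh_every, lr = lr,
                 hidden_dims = hidden_dims, head_dims = head_dims,
                 refine = refine, r_refine = r_refine,
                 precluster_resolution = precluster_resolution, seed = seed),
            class = "spadom_config")
}

#' Read a configuration from a JSON preset file
#'
#' @param path JSON file of `spadom_config` fields.
#' @param ... overrides applied on top of the file.
#' @return A `spadom_config`.
#' @export
read_spadom_config <- function(path, ...) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- utils::modifyList(vals, list(...))
  do.call(spadom_config, vals)
}

#' Run the full spatial-domain pipeline
#'
#' Preprocesses the dataset (empty-spot removal, library-size + log1p
#' normalization, HVG selection), builds the spatial and cell-type-aware
#' neighbor graphs, fits the model, calls domains on the final embedding
#' (tuning the resolution towards `target_k` when requested), optionally
#' refines labels by neighborhood vote, computes validity metrics (plus
#' ARI when truth labels are present), and ranks marker genes per domain.
#' All artifacts are written to `output_dir` as plain text: `labels.csv`,
#' `embeddings.csv`, `loss_log.csv`, `metrics.json`, `markers.csv` and a
#' `config.json` echo.
#'
#' @param ds a raw or normalized [spot_dataset()].
#' @param config a [spadom_config()].
#' @param output_dir artifact directory (created if needed).
#' @param verbose log per-stage progress.
#' @return Invisibly, a list with `labels` (`domain_assignment`), `fit`
#'   (`spadom_fit`), `metrics`, `markers` and `output_dir`.
#' @export
run_pipeline <- function(ds, config = spadom_config(), output_dir,
                         verbose = TRUE) {
  stopifnot(inherits(ds, "spot_dataset"), inherits(config, "spadom_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) if (verbose) message("[", stage, "] ", sprintf(...))
  t0 <- Sys.time()

  say("preprocess", "%d spots, %d genes", nrow(ds$X), ncol(ds$X))
  if (!ds$normalized) {
    ds <- drop_empty_spots(ds)
    ds <- normalize_log1p(ds)
  }
  hvg_n <- min(config$hvg_n, ncol(ds$X))
  ds <- select_hvg(ds, hvg_n)

  say("graph", "building %s spatial graph",
      if (is.null(config$rad_cutoff)) sprintf("%d-NN", config$knn_k)
      else sprintf("radius-%g", config$rad_cutoff))
  snn <- if (is.null(config$rad_cutoff))
    build_knn_graph(ds$coords, config$knn_k)
  else
    build_radius_graph(ds$coords, config$rad_cutoff)
  pre_labels <- precluster_expression(ds, resolution = config$precluster_resolution,
                                      seed = config$seed)
  ctasnn <- prune_to_ctasnn(snn, pre_labels)

  say("fit", "pretrain %d + joint %d epochs (alpha=%g, cost_ssc=%g)",
      config$epochs_pre, config$epochs_joint, config$alpha, config$cost_ssc)
  fit <- fit_spadom(ds, snn, ctasnn, m = config$n_clusters,
                    alpha = config$alpha, lambda = config$cost_ssc,
                    hidden_dims = config$hidden_dims,
                    head_dims = config$head_dims,
                    epochs_pre = config$epochs_pre,
                    epochs_joint = config$epochs_joint,
                    refresh_every = config$refresh_every,
                    lr = config$lr, seed = config$seed)
  Z_L <- fit$Z[[length(fit$Z)]]

  say("cluster", "method=%s", config$method)
  target_k <- config$target_k
  da <- if (config$method %in% c("louvain", "leiden") && !is.null(target_k))
    tune_resolution(Z_L, config$method, target_k, seed = config$seed)
  else if (config$method %in% c("gmm", "mclust"))
    cluster_embeddings(Z_L, "gmm", param = config$n_clusters, seed = config$seed)
  else
    cluster_embeddings(Z_L, config$method, param = 1.0, seed = config$seed)

  if (config$refine) {
    say("refine", "neighborhood vote, r=%g", config$r_refine)
    da$labels <- refine_by_neighborhood(da$labels, ds$coords, config$r_refine)
    da$refined <- TRUE
    da$r_refine <- config$r_refine
  }

  say("metrics", "computing validity indices")
  met <- metrics_report(Z_L, da$labels, truth = ds$truth_labels)

  say("diffexp", "ranking marker genes per domain")
  markers <- tryCatch(rank_all_domains(ds, da$labels),
                      error = function(e) { say("diffexp", "skipped: %s",
                                                conditionMessage(e)); NULL })

  # ---- artifacts ----
  utils::write.table(data.frame(spot_id = ds$spot_ids, domain = da$labels),
                     file.path(output_dir, "labels.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  emb <- data.frame(spot_id = ds$spot_ids, Z_L)
  colnames(emb) <- c("spot_id", paste0("dim_", seq_len(ncol(Z_L))))
  utils::write.table(emb, file.path(output_dir, "embeddings.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(fit$loss_log, file.path(output_dir, "loss_log.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(met, file.path(output_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(markers))
    utils::write.table(markers, file.path(output_dir, "markers.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
  cfg <- unclass(config)
  cfg$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(cfg, file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done", "%.1f s, artifacts in %s", cfg$elapsed_sec, output_dir)
  invisible(list(labels = da, fit = fit, metrics = met, markers = markers,
                 output_dir = output_dir))
}
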
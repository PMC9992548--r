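#' Resolved settings for a full pipeline run
#'
#' Defaults mirror the published analysis settings: 100-value penalty
#' path with rotation-information-criterion selection, spinglass with
#' 500 restarts, clique percolation with k = 4 and intensity threshold
#' I = 0.08, 1,000 permutations for the network comparison test, and a
#' 100-value / 10-fold lasso for the cross-lagged network.  Every run
#' writes the fully resolved configuration alongside its outputs.
#'
#' @param input path of a wide two-wave CSV (see [read_panel_csv()]), or
#'   `NULL` to simulate from `synthetic`.
#' @param out_dir output directory.
#' @param seed global seed; all stage seeds derive from it via
#'   [derive_seed()].
#' @param synthetic a [synthetic_config()] used when `input` is `NULL`.
#' @param estimator a [net_config()].
#' @param cpm_k,cpm_I clique percolation parameters.
#' @param spinglass_spins spinglass restarts.
#' @param nct_permutations permutations of the comparison test.
#' @param clpn_lambda,clpn_folds cross-lagged penalty path and folds.
#' @param stability_boot case-dropping replicates per proportion
#'   (`0` skips the stability stage).
#' @param run_nct,run_clpn toggles for the expensive stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, out_dir = "clpnet-run",
                            seed = 1L,
                            synthetic = synthetic_config(seed = seed),
                            estimator = net_config(),
                            cpm_k = 4L, cpm_I = 0.08,
                            spinglass_spins = 500L,
                            nct_permutations = 1000L,
                            clpn_lambda = 100L, clpn_folds = 10L,
                            stability_boot = 100L,
                            run_nct = TRUE, run_clpn = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Top-level keys override the [pipeline_config()] defaults; nested
#' `synthetic` and `estimator` maps override the corresponding
#' constructor defaults.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- do.call(synthetic_config, raw$synthetic %||% list())
  est <- do.call(net_config, raw$estimator %||% list())
  raw$synthetic <- NULL; raw$estimator <- NULL
  do.call(pipeline_config, c(raw, list(synthetic = syn, estimator = est)))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Export / read a network as edge-list and adjacency CSV
#'
#' @param net a [weighted_network()].
#' @param path base path; `write_network_csv` writes
#'   `<path>_edges.csv` and `<path>_adjacency.csv`, `read_network_csv`
#'   reads the adjacency file back.
#' @return written file paths / a [weighted_network()].
#' @export
write_network_csv <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  adj_path <- paste0(path, "_adjacency.csv")
  edge_path <- paste0(path, "_edges.csv")
  adj <- as.data.frame(net$weights)
  write.csv(cbind(node = net$node_labels, adj), adj_path,
            row.names = FALSE)
  idx <- which(upper.tri(net$weights) & net$weights != 0, arr.ind = TRUE)
  edges <- data.frame(from = net$node_labels[idx[, 1]],
                      to = net$node_labels[idx[, 2]],
                      weight = net$weights[idx])
  write.csv(edges, edge_path, row.names = FALSE)
  invisible(c(adj_path, edge_path))
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(path) {
  adj <- read.csv(paste0(path, "_adjacency.csv"), check.names = FALSE)
  labels <- adj$node
  m <- as.matrix(adj[, -1, drop = FALSE])
  rownames(m) <- labels
  m <- (m + t(m)) / 2   # guard against decimal round-trip asymmetry
  weighted_network(m, labels)
}

#' Export a network (optionally with community attributes) as GraphML
#'
#' @param net a [weighted_network()].
#' @param path output file.
#' @param partition optional [spinglass_partition()].
#' @param overlap optional [clique_percolation()] result; multi-community
#'   membership is encoded as a `|`-delimited node attribute.
#' @export
write_network_graphml <- function(net, path, partition = NULL,
                                  overlap = NULL) {
  g <- net_to_igraph(net)
  if (!is.null(partition))
    igraph::V(g)$community <- as.integer(partition$membership)
  if (!is.null(overlap)) {
    memb <- vapply(net$node_labels, function(nd) {
      inn <- which(vapply(overlap$communities, function(cc) nd %in% cc,
                          logical(1)))
      if (length(inn) == 0) "" else paste(inn, collapse = "|")
    }, character(1))
    igraph::V(g)$cpm_communities <- unname(memb)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export overlapping communities as JSON
#' @param oc an `overlap_communities` object.
#' @param path output file.
#' @export
write_communities_json <- function(oc, path) {
  write_json_file(list(k = oc$k, I = oc$I, communities = oc$communities,
                       percolated = percolated_items(oc)), path)
}

#' Run the full two-wave network pipeline
#'
#' Executes preprocessing, contemporaneous estimation, community
#' detection, centrality, wave comparison, the cross-lagged network and
#' stability, writing every artifact plus a manifest (with MD5
#' checksums) into `out_dir`.  Any stage error aborts the run with the
#' stage name after persisting the partial manifest.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, created = format(Sys.time()),
                   artifacts = list())
  out <- function(name) file.path(config$out_dir, name)
  add <- function(name) {
    manifest$artifacts[[name]] <<-
      list(file = name, md5 = unname(tools::md5sum(out(name))))
  }
  persist_manifest <- function() {
    write_json_file(manifest, out("manifest.json"))
  }
  stage <- "configure"
  result <- tryCatch({
    cfg_ser <- config
    cfg_ser$synthetic <- unclass(cfg_ser$synthetic)
    cfg_ser$estimator <- unclass(cfg_ser$estimator)
    write_json_file(cfg_ser, out("config.json")); add("config.json")

    stage <- "load"
    if (is.null(config$input)) {
      truth <- generate_truth(config$synthetic)
      pair <- simulate_panel(truth, config$synthetic$n_participants,
                             seed = derive_seed(config$seed, 100L))
      write_truth_json(truth, out("truth.json")); add("truth.json")
      write_panel_csv(pair, out("panel.csv")); add("panel.csv")
    } else {
      if (!file.exists(config$input))
        stop("input file not found: ", config$input)
      pair <- read_panel_csv(config$input)
    }

    stage <- "preprocessing"
    for (wv in c("T1", "T2")) {
      d <- compute_descriptives(pair[[wv]])
      write_table_csv(d, out(paste0("descriptives_", wv, ".csv")))
      add(paste0("descriptives_", wv, ".csv"))
      gb <- goldbricker(pair[[wv]])
      write_table_csv(gb, out(paste0("goldbricker_", wv, ".csv")))
      add(paste0("goldbricker_", wv, ".csv"))
    }

    stage <- "estimation"
    nets <- list()
    for (wv in c("T1", "T2")) {
      cfg <- config$estimator
      cfg$seed <- derive_seed(config$seed, if (wv == "T1") 101L else 102L)
      nets[[wv]] <- estimate_network(pair[[wv]], cfg)
      write_network_csv(nets[[wv]], out(paste0("network_", wv)))
      add(paste0("network_", wv, "_adjacency.csv"))
      add(paste0("network_", wv, "_edges.csv"))
    }

    stage <- "communities"
    parts <- list(); overlaps <- list()
    for (wv in c("T1", "T2")) {
      parts[[wv]] <- spinglass_partition(
        nets[[wv]], n_spins = config$spinglass_spins,
        seed = derive_seed(config$seed, if (wv == "T1") 103L else 104L))
      overlaps[[wv]] <- clique_percolation(nets[[wv]], config$cpm_k,
                                           config$cpm_I)
      write_communities_json(overlaps[[wv]],
                             out(paste0("communities_cpm_", wv, ".json")))
      add(paste0("communities_cpm_", wv, ".json"))
      write_network_graphml(nets[[wv]],
                            out(paste0("network_", wv, ".graphml")),
                            parts[[wv]], overlaps[[wv]])
      add(paste0("network_", wv, ".graphml"))
    }

    stage <- "centrality"
    for (wv in c("T1", "T2")) {
      ct <- centrality_table(nets[[wv]], parts[[wv]],
                             nonparanormal_transform(pair[[wv]]))
      write_table_csv(ct, out(paste0("centrality_", wv, ".csv")))
      add(paste0("centrality_", wv, ".csv"))
    }

    stage <- "comparison"
    sim <- adjacency_correlation(nets$T1, nets$T2)
    write_table_csv(sim, out("similarity.csv")); add("similarity.csv")
    if (config$run_nct) {
      nct <- network_structure_test(pair$T1, pair$T2,
                                    n_perm = config$nct_permutations,
                                    seed = derive_seed(config$seed, 105L),
                                    config = config$estimator)
      write_json_file(list(M = nct$M, S = nct$S, p_M = nct$p_M,
                           p_S = nct$p_S, n_perm = nct$n_perm),
                      out("nct.json"))
      add("nct.json")
      write_table_csv(nct$edge_tests, out("nct_edges.csv"))
      add("nct_edges.csv")
    }

    stage <- "cross_lagged"
    if (config$run_clpn) {
      clpn <- fit_clpn(pair, n_lambda = config$clpn_lambda,
                       cv_folds = config$clpn_folds,
                       seed = derive_seed(config$seed, 106L))
      write.csv(as.data.frame(clpn$beta), out("clpn_beta.csv"))
      add("clpn_beta.csv")
      pred <- data.frame(node = clpn$item_labels,
                         in_prediction = clpn$in_prediction,
                         out_prediction = clpn$out_prediction)
      write.csv(pred, out("clpn_prediction.csv"), row.names = FALSE)
      add("clpn_prediction.csv")
      fi <- path_model_fit(clpn)
      write_json_file(list(chi_square = fi$chi_square, df = fi$df,
                           CFI = fi$CFI, TLI = fi$TLI,
                           RMSEA = fi$RMSEA, SRMR = fi$SRMR),
                      out("clpn_fit.json"))
      add("clpn_fit.json")
    }

    stage <- "stability"
    if (config$stability_boot > 0) {
      cs <- case_dropping_cs(pair$T1, "edge",
                             n_boot = config$stability_boot,
                             seed = derive_seed(config$seed, 107L),
                             config = config$estimator)
      write_json_file(list(cs = cs$cs, statistic = cs$statistic,
                           table = cs$table), out("stability_T1.json"))
      add("stability_T1.json")
    }

    persist_manifest(); add("manifest.json")
    manifest
  }, error = function(e) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    persist_manifest()
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  persist_manifest()
  invisible(result)
}
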
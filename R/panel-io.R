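#' Read and write symptom panels as CSV
#'
#' Two dialects are supported. `"wide"`: one row per subject-wave with
#' columns `id`, `wave`, one column per item, then one column per covariate;
#' missing item values are empty cells. `"long"`: columns `id`, `wave`,
#' `item`, `value` (missing measurements simply absent or empty), with
#' covariates repeated in extra columns. Both round-trip exactly, including
#' the missingness pattern.
#'
#' @param panel a [symptom_panel()].
#' @param path file path.
#' @param format `"wide"` or `"long"`.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` returns
#'   a `symptom_panel`.
#' @export
write_panel <- function(panel, path, format = c("wide", "long")) {
  format <- match.arg(format)
  stopifnot(inherits(panel, "symptom_panel"))
  covs <- panel$covariates
  if (format == "wide") {
    rows <- do.call(rbind, lapply(seq_len(panel$n_waves), function(w) {
      m <- wave_matrix(panel, w)
      df <- data.frame(id = panel$subject_ids, wave = panel$wave_labels[w],
                       m, check.names = FALSE)
      if (ncol(covs)) df <- cbind(df, covs)
      df
    }))
    rows <- rows[order(match(rows$id, panel$subject_ids), rows$wave), ]
    utils::write.csv(rows, path, row.names = FALSE, na = "")
  } else {
    long <- do.call(rbind, lapply(seq_len(panel$n_waves), function(w) {
      m <- wave_matrix(panel, w)
      df <- data.frame(
        id = rep(panel$subject_ids, panel$n_items),
        wave = panel$wave_labels[w],
        item = rep(panel$item_labels, each = panel$n_subjects),
        value = as.vector(m))
      if (ncol(covs)) df <- cbind(df, covs[rep(seq_len(nrow(covs)),
                                               panel$n_items), , drop = FALSE])
      df
    }))
    long <- long[order(match(long$id, panel$subject_ids), long$wave), ]
    utils::write.csv(long, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_panel
#' @param covariate_cols names of covariate columns; by default every column
#'   other than `id`, `wave` and the item columns (wide) or `id`, `wave`,
#'   `item`, `value` (long).
#' @export
read_panel <- function(path, format = c("wide", "long"), covariate_cols = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, na.strings = "")
  if (!all(c("id", "wave") %in% names(raw)))
    stopf("panel file must have 'id' and 'wave' columns")

  if (format == "long") {
    if (!all(c("item", "value") %in% names(raw)))
      stopf("long panel file must have 'item' and 'value' columns")
    check_binary(raw$value, raw$item, seq_len(nrow(raw)), path)
    item_labels <- unique(raw$item)
    cov_cols <- covariate_cols %||% setdiff(names(raw),
                                            c("id", "wave", "item", "value"))
    waves <- sort(unique(raw$wave))
    ids <- unique(raw$id)
    key <- paste(raw$id, raw$wave, raw$item, sep = "\r")
    if (anyDuplicated(key))
      stopf("duplicated (id, wave, item) rows in %s", path)
    arr <- array(NA_real_, c(length(ids), length(waves), length(item_labels)))
    arr[cbind(match(raw$id, ids), match(raw$wave, waves),
              match(raw$item, item_labels))] <- raw$value
    covs <- if (length(cov_cols)) {
      first <- raw[!duplicated(raw$id), , drop = FALSE]
      as.matrix(first[match(ids, first$id), cov_cols, drop = FALSE])
    } else NULL
    return(symptom_panel(arr, covariates = covs, subject_ids = ids,
                         item_labels = item_labels, wave_labels = waves))
  }

  key <- paste(raw$id, raw$wave, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stopf("duplicated (id, wave) pair in %s: %s", path, gsub("\r", ", ", d))
  }
  item_cols <- setdiff(names(raw), c("id", "wave"))
  if (!is.null(covariate_cols)) {
    cov_cols <- covariate_cols
  } else {
    # covariates are the trailing constant-within-subject binary columns
    # named differently from items; default generator writes gender/ethnicity
    cov_cols <- intersect(c("gender", "ethnicity"), item_cols)
  }
  item_cols <- setdiff(item_cols, cov_cols)
  if (!length(item_cols)) stopf("no item columns found in %s", path)
  for (cl in item_cols)
    check_binary(raw[[cl]], cl, seq_len(nrow(raw)), path)
  waves <- sort(unique(raw$wave))
  ids <- unique(raw$id)
  arr <- array(NA_real_, c(length(ids), length(waves), length(item_cols)))
  ri <- match(raw$id, ids); wi <- match(raw$wave, waves)
  for (k in seq_along(item_cols))
    arr[cbind(ri, wi, k)] <- raw[[item_cols[k]]]
  covs <- if (length(cov_cols)) {
    first <- raw[!duplicated(raw$id), , drop = FALSE]
    as.matrix(first[match(ids, first$id), cov_cols, drop = FALSE])
  } else NULL
  symptom_panel(arr, covariates = covs, subject_ids = ids,
                item_labels = item_cols, wave_labels = waves)
}

check_binary <- function(values, colname, rows, path) {
  bad <- which(!is.na(values) & !(values %in% c(0, 1)))
  if (length(bad)) {
    stopf("non-binary item value %s in %s (column %s, row %d)",
          format(values[bad[1]]), path,
          if (length(colname) > 1) format(colname[bad[1]]) else colname,
          bad[1])
  }
  invisible(TRUE)
}

#' Export a network as an edge-list CSV and a GraphML file
#'
#' The edge list has columns `source`, `target`, `weight_log_odds`,
#' `weight_or` (`weight_or = exp(weight_log_odds)` on every row) and
#' `network`; zero-weight edges are omitted. The GraphML file carries the
#' log-odds weight as an edge attribute and is directed for cross-lagged
#' networks, undirected (each symmetric edge written once) for Ising
#' networks.
#'
#' @param network a `clpn` or `ising_net` object.
#' @param path output path without extension; `<path>.csv` and
#'   `<path>.graphml` are written.
#' @param label network label recorded in the edge list.
#' @return Data frame of the edge list, invisibly.
#' @export
export_network <- function(network, path, label = NULL) {
  if (inherits(network, "clpn")) {
    W <- coef(network, scale = "log_odds")
    el <- which(W != 0, arr.ind = TRUE)
    edges <- data.frame(source = rownames(W)[el[, 1]],
                        target = colnames(W)[el[, 2]],
                        weight_log_odds = W[el])
    directed <- TRUE
    vertices <- unique(c(rownames(W), colnames(W)))
  } else if (inherits(network, "ising_net")) {
    W <- network$weights
    idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
    edges <- data.frame(source = rownames(W)[idx[, 1]],
                        target = colnames(W)[idx[, 2]],
                        weight_log_odds = W[idx])
    directed <- FALSE
    vertices <- rownames(W)
  } else stopf("unsupported network class")
  edges$weight_or <- exp(edges$weight_log_odds)
  edges$network <- rep(label %||% (attr(network, "label") %||% "network"),
                       nrow(edges))
  utils::write.csv(edges, paste0(path, ".csv"), row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges[, c("source", "target")] else
      data.frame(source = character(), target = character()),
    directed = directed, vertices = data.frame(name = vertices))
  if (nrow(edges)) igraph::E(g)$weight <- edges$weight_log_odds
  igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  invisible(edges)
}

#' Run the full panel-network pipeline from a plain-text config
#'
#' Stages: simulate (or read) the panel, descriptives, optional imputation
#' of missing data, one cross-lagged network per consecutive wave pair,
#' optional per-wave Ising networks, centrality tables, comparisons of
#' consecutive networks, and optional bootstrap accuracy for the first
#' transition. All numeric artifacts are written as CSV under `out_dir`
#' and a manifest records versions, seeds and stage timings. A rerun with
#' the same config and seed reproduces the artifacts exactly.
#'
#' @param config path to a YAML key-value config file, or an equivalent
#'   named list. Recognised keys: `input` (CSV path) and `input_format`, or
#'   `simulate: {n_subjects, attrition}`; `seed`; `impute: {iterations}`;
#'   `ising: {enabled, gamma, rule}`; `bootstrap: {enabled, B, proportions}`;
#'   `fit: {nfolds, rule, covariates}`.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the fitted networks, centrality tables,
#'   comparison table and manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  manifest <- list(package_version = as.character(utils::packageVersion("clpnet")),
                   r_version = R.version.string, seed = seed, stages = list())
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  log_stage <- function(name, t0)
    timings[[name]] <<- round(tic() - t0, 3)

  t0 <- tic()
  if (!is.null(cfg$input)) {
    panel <- read_panel(cfg$input, format = cfg$input_format %||% "wide")
  } else {
    sim <- cfg$simulate %||% list()
    spec <- if (!is.null(sim$spec)) read_ground_truth(sim$spec)
            else default_ground_truth(seed = seed)
    panel <- simulate_panel(spec, n_subjects = sim$n_subjects %||% 1000,
                            seed = seed)
    if (isTRUE(sim$attrition %||% FALSE))
      panel <- apply_attrition(panel, spec, seed = seed)
    write_panel(panel, file.path(out_dir, "panel.csv"), format = "wide")
  }
  log_stage("input", t0)

  t0 <- tic()
  desc <- describe_panel(panel)
  utils::write.csv(desc$items, file.path(out_dir, "descriptives_items.csv"),
                   row.names = FALSE)
  utils::write.csv(desc$waves, file.path(out_dir, "descriptives_waves.csv"),
                   row.names = FALSE)
  log_stage("descriptives", t0)

  if (anyNA(panel$items)) {
    t0 <- tic()
    imp <- cfg$impute %||% list()
    panel <- impute_chained(panel, n_iterations = imp$iterations %||% 20,
                            seed = seed)
    write_panel(panel, file.path(out_dir, "panel_imputed.csv"), format = "wide")
    log_stage("impute", t0)
  }

  fitcfg <- cfg$fit %||% list()
  t0 <- tic()
  nets <- lapply(seq_len(panel$n_waves - 1), function(w)
    clpn(panel, wave = w, nfolds = fitcfg$nfolds %||% 10,
         rule = fitcfg$rule %||% "1se",
         covariates = fitcfg$covariates %||% TRUE, seed = seed))
  for (net in nets) {
    export_network(net, file.path(out_dir, attr(net, "label")))
    ei <- expected_influence(net)
    utils::write.csv(ei, file.path(out_dir, paste0("centrality_",
                                                   attr(net, "label"), ".csv")),
                     row.names = FALSE)
  }
  log_stage("clpn", t0)

  isingcfg <- cfg$ising %||% list()
  if (isTRUE(isingcfg$enabled %||% FALSE)) {
    t0 <- tic()
    for (w in seq_len(panel$n_waves)) {
      inet <- ising(panel, wave = w, gamma = isingcfg$gamma %||% 0.25,
                    rule = isingcfg$rule %||% "AND")
      export_network(inet, file.path(out_dir, sprintf("ising_w%d", w)))
    }
    log_stage("ising", t0)
  }

  comp <- NULL
  if (length(nets) >= 2) {
    t0 <- tic()
    comp <- do.call(rbind, lapply(seq_len(length(nets) - 1), function(i)
      as.data.frame(compare_networks(nets[[i]], nets[[i + 1]]))))
    utils::write.csv(comp, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    log_stage("compare", t0)
  } else {
    utils::write.csv(data.frame(), file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }

  bootcfg <- cfg$bootstrap %||% list()
  if (isTRUE(bootcfg$enabled %||% FALSE)) {
    t0 <- tic()
    bt <- bootstrap_edges(panel, wave = 1, B = bootcfg$B %||% 200, seed = seed)
    utils::write.csv(bt$ci, file.path(out_dir, "edge_ci_t1_t2.csv"),
                     row.names = FALSE)
    log_stage("bootstrap", t0)
  }

  manifest$stages <- timings
  manifest$n_networks <- length(nets)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(panel = panel, networks = nets, comparisons = comp,
                 manifest = manifest))
}
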
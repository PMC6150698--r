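#' @name pipeline
#' @title End-to-end screen pipeline
#'
#' @description
#' One configuration object controls every stage. All intermediate artifacts
#' are plain files (CSV/JSON), so any stage can be rerun in isolation, and a
#' single master seed feeds all stochastic stages through derived sub-seeds:
#' two runs from the same configuration produce identical outputs.
NULL

#' Default pipeline configuration
#'
#' @param ... overrides of the defaults.
#' @return named list of class `cx_config`.
#' @export
cx_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_flies = 6L, n_repeats = 4L,
    n_pulses = c(1L, 5L, 10L, 20L, 30L),
    pulse_rate = 30, pulse_duration = 0.002, onset_time = 5,
    sampling_rate = 10, duration = 16,
    fbase_floor = 0.05, cor_method = "pearson",
    upsample = 10,
    support_fraction = 0.75, mcd_nsamp = 100L,
    bootstrap_B = 10000L, alpha = 0.01, bootstrap_scheme = "holdout",
    holdout_frac = 0.05,
    protocol_select = NA)  # NA = strongest stimulation present
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("cx_config", "list"))
}

#' Read / write a configuration as YAML
#'
#' @param cfg a [cx_config()].
#' @param path file path.
#' @return `read_config` returns a `cx_config`; missing keys are an error.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- names(cx_config())
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("config file is missing key(s): ", paste(missing, collapse = ", "))
  do.call(cx_config, raw[need])
}

#' Write a dataset to disk as per-run CSVs plus a JSON manifest
#'
#' Each run file has columns `time, repeat1..repeatN`; the manifest records
#' pairs, flies, protocols, overlap labels and the planted ground truth.
#'
#' @param dataset a `cx_dataset`.
#' @param dir output directory.
#' @param force overwrite an existing dataset directory.
#' @export
write_dataset <- function(dataset, dir, force = FALSE) {
  if (dir.exists(file.path(dir, "runs")) && !force)
    stop(sprintf("output directory '%s' already holds a dataset; use force = TRUE to overwrite", dir))
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(dataset$traces)) {
    df <- data.frame(time = dataset$time, dataset$traces[[id]], check.names = FALSE)
    utils::write.csv(df, file.path(dir, "runs", paste0(id, ".csv")),
                     row.names = FALSE)
  }
  gt <- dataset$ground_truth
  manifest <- list(
    params = dataset$params,
    runs = dataset$runs,
    ground_truth = if (!is.null(gt)) list(
      cell_types = gt$cell_types,
      pairs = gt$pairs[, c("pre", "post", "kind", "overlapping")]))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a `cx_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  runs <- manifest$runs
  traces <- list()
  time <- NULL
  for (id in runs$run_id) {
    df <- utils::read.csv(file.path(dir, "runs", paste0(id, ".csv")),
                          check.names = FALSE)
    time <- df$time
    traces[[id]] <- as.matrix(df[, -1, drop = FALSE])
  }
  gt <- NULL
  if (!is.null(manifest$ground_truth)) {
    p <- manifest$ground_truth$pairs
    gt <- connectome(manifest$ground_truth$cell_types,
                     data.frame(pre = p$pre, post = p$post, kind = p$kind),
                     overlap_labels = p$overlapping)
  }
  structure(list(time = time, runs = runs, traces = traces, ground_truth = gt,
                 params = manifest$params), class = "cx_dataset")
}

#' Simulate a screen dataset to disk
#'
#' Wraps [simulate_experiment()] with the configuration's parameters and
#' writes the dataset (traces + manifest).
#'
#' @param cfg a [cx_config()].
#' @param out_dir output directory.
#' @param gt ground-truth [connectome()]; defaults to the packaged fixture.
#' @param force overwrite existing output.
#' @return the dataset, invisibly.
#' @export
cx_simulate <- function(cfg = cx_config(), out_dir, gt = example_connectome(),
                        force = FALSE) {
  protocols <- default_protocols(cfg$n_pulses, pulse_rate = cfg$pulse_rate,
                                 pulse_duration = cfg$pulse_duration,
                                 onset_time = cfg$onset_time)
  ds <- simulate_experiment(gt, n_flies = cfg$n_flies, protocols = protocols,
                            sampling_rate = cfg$sampling_rate,
                            duration = cfg$duration,
                            n_repeats = cfg$n_repeats, seed = cfg$seed)
  write_dataset(ds, out_dir, force = force)
  invisible(ds)
}

#' Run the complete analysis on a dataset
#'
#' Statistics, null-model fit on the non-overlapping controls, bootstrap
#' significance threshold, edge classification; optionally writes all tables
#' (`repeat_stats.csv`, `run_stats.csv`, `pair_stats.csv`, `edges.csv`), the
#' null-model record (JSON), the network (GraphML + node-link JSON), a
#' markdown report and — when the manifest carries a planted connectome — a
#' ground-truth confusion table.
#'
#' @param dataset a `cx_dataset` or a dataset directory.
#' @param cfg a [cx_config()].
#' @param out_dir optional output directory for the artifacts.
#' @return list with `stats`, `features`, `null_model`, `threshold`,
#'   `edges`, and `confusion` (NULL without ground truth).
#' @export
cx_run_all <- function(dataset, cfg = cx_config(), out_dir = NULL) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  st <- screen_statistics(dataset, fbase_floor = cfg$fbase_floor,
                          cor_method = cfg$cor_method)
  np <- if (is.na(cfg$protocol_select)) NULL else cfg$protocol_select
  feats <- feature_points(st$pairs, n_pulses = np)
  nulls <- feats[!feats$overlapping, , drop = FALSE]
  model <- fit_null(nulls, support_fraction = cfg$support_fraction,
                    nsamp = cfg$mcd_nsamp,
                    seed = derive_seed(cfg$seed, "fit_null"))
  thr <- significance_threshold(nulls, B = cfg$bootstrap_B, alpha = cfg$alpha,
                                seed = derive_seed(cfg$seed, "bootstrap"),
                                scheme = cfg$bootstrap_scheme,
                                holdout_frac = cfg$holdout_frac,
                                support_fraction = cfg$support_fraction,
                                nsamp = cfg$mcd_nsamp)
  edges <- classify_edges(feats, model, thr)
  confusion <- NULL
  if (!is.null(dataset$ground_truth)) {
    gt <- dataset$ground_truth$pairs
    key <- paste(gt$pre, gt$post)
    truth <- gt$kind[match(paste(edges$pre, edges$post), key)]
    confusion <- as.data.frame(table(
      truth = factor(truth, levels = unique(c("none", sort(unique(truth))))),
      called = factor(ifelse(edges$significant,
                             ifelse(edges$sign >= 0, "excitatory", "inhibitory"),
                             "not_significant"),
                      levels = c("excitatory", "inhibitory", "not_significant"))))
  }
  res <- list(stats = st, features = feats, null_model = model,
              threshold = thr[c("threshold", "alpha", "B", "scheme")],
              edges = edges, confusion = confusion)
  if (!is.null(out_dir)) write_results(res, cfg, out_dir)
  res
}

# Write all analysis artifacts to out_dir.
write_results <- function(res, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$stats$repeats, file.path(out_dir, "repeat_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(res$stats$runs, file.path(out_dir, "run_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(res$stats$pairs, file.path(out_dir, "pair_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(res$edges, file.path(out_dir, "edges.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(mu = res$null_model$mu, S = res$null_model$S,
         n = res$null_model$n, method = res$null_model$method,
         support_fraction = res$null_model$support_fraction,
         threshold = res$threshold$threshold, alpha = res$threshold$alpha,
         B = res$threshold$B, scheme = res$threshold$scheme,
         seed = cfg$seed, config = unclass(cfg)),
    file.path(out_dir, "null_model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  export_network(res$edges, file.path(out_dir, "network"))
  if (!is.null(res$confusion))
    utils::write.csv(res$confusion, file.path(out_dir, "confusion.csv"),
                     row.names = FALSE)
  render_report(res$edges, res$stats$pairs, file.path(out_dir, "report.md"),
                null_model = res$null_model, threshold = res$threshold)
  invisible(out_dir)
}

#' Export the connectivity network as GraphML and node-link JSON
#'
#' @param edges edge table from [classify_edges()].
#' @param basename output path without extension.
#' @export
export_network <- function(edges, basename) {
  sig <- edges[edges$significant & !edges$control, , drop = FALSE]
  nodes <- unique(c(edges$pre[!edges$control], edges$post[!edges$control],
                    sig$pre, sig$post))
  g <- igraph::graph_from_data_frame(
    sig[, c("pre", "post", "strength", "sign", "reliability")],
    directed = TRUE, vertices = data.frame(name = nodes))
  igraph::write_graph(g, paste0(basename, ".graphml"), format = "graphml")
  jsonlite::write_json(
    list(nodes = data.frame(id = nodes),
         links = sig[, c("pre", "post", "strength", "sign", "reliability")]),
    paste0(basename, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(basename)
}

#' Render a human-readable markdown report
#'
#' Lists every scored pair once, the null model, the significance threshold,
#' and the feature-plane summary; a companion PNG with the feature-plane
#' scatter (axes `[-1, 1]`) is written next to the report.
#'
#' @param edges edge table from [classify_edges()].
#' @param pair_table pair statistics table.
#' @param path output `.md` path.
#' @param null_model,threshold optional model/threshold records to include.
#' @export
render_report <- function(edges, pair_table, path, null_model = NULL,
                          threshold = NULL) {
  lines <- c("# Functional connectivity screen report", "")
  if (!is.null(null_model))
    lines <- c(lines, sprintf(
      "Null model (MCD, support %.2f): mu = (%.4f, %.4f); S = [[%.5f, %.5f], [%.5f, %.5f]]; n = %d null pairs.",
      null_model$support_fraction, null_model$mu[1], null_model$mu[2],
      null_model$S[1, 1], null_model$S[1, 2], null_model$S[2, 1],
      null_model$S[2, 2], null_model$n), "")
  if (!is.null(threshold))
    lines <- c(lines, sprintf(
      "Significance: squared Mahalanobis distance > %.3f (alpha = %g, %d %s replicates).",
      threshold$threshold, threshold$alpha, threshold$B, threshold$scheme), "")
  lines <- c(lines,
             sprintf("%d pairs scored; %d significant (%d candidates, %d controls).",
                     nrow(edges), sum(edges$significant),
                     sum(edges$significant & !edges$control),
                     sum(edges$significant & edges$control)), "",
             "| pair | pre | post | strength | sign | reliability | significant | control |",
             "|------|-----|------|----------|------|-------------|-------------|---------|")
  for (i in seq_len(nrow(edges)))
    lines <- c(lines, sprintf("| %s | %s | %s | %.3f | %+d | %.3f | %s | %s |",
                              edges$pair_id[i], edges$pre[i], edges$post[i],
                              edges$strength[i], as.integer(edges$sign[i]),
                              edges$reliability[i],
                              ifelse(edges$significant[i], "yes", "no"),
                              ifelse(edges$control[i], "yes", "no")))
  writeLines(lines, path)
  sub_tab <- pair_table[pair_table$n_pulses == max(pair_table$n_pulses), ,
                        drop = FALSE]
  m <- match(edges$pair_id, sub_tab$pair_id)
  x1 <- sub_tab$ItoPeak_norm_scaled[m]; x2 <- sub_tab$R_between[m]
  png_path <- sub("\\.md$", "_features.png", path)
  grDevices::png(png_path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  graphics::plot(x1, x2, xlim = c(-1, 1), ylim = c(-1, 1),
                 pch = ifelse(edges$control, 1, 19),
                 col = ifelse(edges$significant, "red", "grey30"),
                 xlab = "ItoPeak_norm (scaled)", ylab = "R_between",
                 main = "Feature plane (filled = candidate, red = significant)")
  if (!is.null(null_model))
    graphics::points(null_model$mu[1], null_model$mu[2], pch = 3, cex = 2,
                     col = "blue")
  invisible(path)
}
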
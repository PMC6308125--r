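# Orchestration: one configuration object, one entry point that runs
# simulate/load -> preprocess -> spectral -> netbuild -> graph metrics ->
# group statistics, deterministically for a fixed master seed.

#' Build a pipeline configuration
#'
#' Defaults mirror the reference resting-state protocol: 512 ROIs at 500 Hz,
#' 1,024-sample epochs (2.048 s), the five-stage Butterworth bank, bior5.5
#' wavelet analysis, graphs at 10,000 / 12,500 / 15,000 edges, 100 random
#' nulls, and 1.5 hub thresholds.
#'
#' @param design a \code{\link{cohort_design}} to simulate, or NULL when
#'   reading recordings from \code{inputs}.
#' @param inputs optional data.frame with columns participant, group, time,
#'   path (files readable by \code{\link{read_roi_signals}}).
#' @param n_nodes,fs,duration simulation geometry (ignored for file inputs).
#' @param base_params baseline generator parameters for simulation.
#' @param epoch_len epoch length in samples (default 2.048 s at \code{fs}).
#' @param peak_to_peak_limit epoch rejection threshold in signal units.
#' @param densities edge counts at which graphs are built.
#' @param n_nulls random nulls per density (default 100).
#' @param wavelet wavelet family for the spectral stage.
#' @param hub_bc,hub_z hub thresholds (default 1.5 both).
#' @param compute_local also compute per-node metrics tables (slower).
#' @param strongest connect smallest-RWE pairs (default TRUE).
#' @param holm_adjust add Holm-adjusted p-values (across metrics and
#'   densities, per effect) to the ANOVA table; off by default, matching the
#'   reference analysis which reports uncorrected p-values.
#' @param seed master seed for nulls (and community detection).
#' @param out_dir optional output directory for the result tables.
#' @param verbose print per-cell progress messages.
#' @return a \code{run_config} list.
#' @export
run_config <- function(design = NULL, inputs = NULL, n_nodes = 512L,
                       fs = 500, duration = 300,
                       base_params = default_cell_params(),
                       epoch_len = round(2.048 * fs),
                       peak_to_peak_limit = 200,
                       densities = c(10000L, 12500L, 15000L),
                       n_nulls = 100L, wavelet = "bior5.5", hub_bc = 1.5,
                       hub_z = 1.5, compute_local = FALSE, strongest = TRUE,
                       holm_adjust = FALSE, seed = 1L, out_dir = NULL,
                       verbose = FALSE) {
  assert_that(!is.null(design) || !is.null(inputs),
              "config needs a simulation design or input files")
  cfg <- list(design = design, inputs = inputs, n_nodes = n_nodes, fs = fs,
              duration = duration, base_params = base_params,
              epoch_len = as.integer(epoch_len),
              peak_to_peak_limit = peak_to_peak_limit,
              densities = as.integer(densities), n_nulls = as.integer(n_nulls),
              wavelet = wavelet, hub_bc = hub_bc, hub_z = hub_z,
              compute_local = compute_local, strongest = strongest,
              holm_adjust = holm_adjust, seed = as.integer(seed),
              out_dir = out_dir, verbose = verbose)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a JSON file
#'
#' The JSON object may contain any \code{\link{run_config}} field; a
#' \code{design} sub-object (n_per_group, effect_spec, seed, ...) is turned
#' into a \code{\link{cohort_design}}.
#'
#' @param path JSON file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), "no such config file: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$design)) {
    d <- raw$design
    raw$design <- cohort_design(
      n_per_group = d$n_per_group %||% 22L,
      groups = d$groups %||% c("dance", "active"),
      times = d$times %||% c("pre", "post"),
      effect_spec = d$effect_spec,
      seed = d$seed %||% 1L
    )
  }
  if (!is.null(raw$base_params)) {
    bp <- default_cell_params()
    bp[names(raw$base_params)] <- raw$base_params
    raw$base_params <- bp
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  assert_that(length(bad) == 0, "unknown config fields: %s",
              paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

null_stats_cached <- function(cache, n_nodes, n_edges, n_nulls, seed) {
  key <- sprintf("%d:%d", n_nodes, n_edges)
  if (is.null(cache[[key]])) {
    cache[[key]] <- null_ensemble_stats(
      n_nodes, n_edges, n_nulls,
      seed = derive_seed(seed, "nulls", key)
    )
  }
  cache[[key]]
}

# Analyse one preprocessed recording at every density; returns per-density
# global metrics (per-epoch values averaged) and optional node tables.
analyze_recording <- function(ts, cfg, cache) {
  eps <- preprocess(ts, epoch_len = cfg$epoch_len,
                    peak_to_peak_limit = cfg$peak_to_peak_limit)
  mats <- epoch_rwe_matrices(eps, wavelet = cfg$wavelet)
  n <- n_rois(ts)
  glob <- list()
  nodes <- list()
  for (d in cfg$densities) {
    ns <- null_stats_cached(cache, n, d, cfg$n_nulls, cfg$seed)
    graphs <- participant_graphs(mats, d, strongest = cfg$strongest)
    gm <- lapply(graphs, small_world_sigma, ensemble = ns)
    glob[[as.character(d)]] <- data.frame(
      density_label = d,
      c_mean = mean(vapply(gm, `[[`, numeric(1), "c_mean")),
      l_mean = mean(vapply(gm, `[[`, numeric(1), "l_mean")),
      c_rand = ns$c_rand, l_rand = ns$l_rand,
      sigma = mean(vapply(gm, `[[`, numeric(1), "sigma")),
      unreachable_fraction =
        mean(vapply(gm, `[[`, numeric(1), "unreachable_fraction")),
      n_epochs = length(graphs)
    )
    if (cfg$compute_local) {
      per_epoch <- lapply(seq_along(graphs), function(i) {
        node_metrics(graphs[[i]],
                     seed = derive_seed(cfg$seed, "community", d, i),
                     bc_threshold = cfg$hub_bc, z_threshold = cfg$hub_z)
      })
      b_i <- rowMeans(vapply(per_epoch, `[[`, numeric(n), "b_i"))
      z <- rowMeans(vapply(per_epoch, `[[`, numeric(n), "z"))
      p <- rowMeans(vapply(per_epoch, `[[`, numeric(n), "p"))
      nodes[[as.character(d)]] <- data.frame(
        density_label = d, node = seq_len(n),
        bc_raw = rowMeans(vapply(per_epoch, `[[`, numeric(n), "bc_raw")),
        b_i = b_i, z = z, p = p,
        role = assign_roles(z, p, cfg$hub_z),
        is_hub_bc = b_i >= cfg$hub_bc
      )
    }
  }
  list(global = do.call(rbind, glob),
       nodes = if (cfg$compute_local) do.call(rbind, nodes) else NULL,
       n_epochs_kept = sum(eps$kept_mask),
       n_epochs_total = length(eps$kept_mask))
}

pipeline_cells <- function(cfg) {
  if (!is.null(cfg$inputs)) {
    need <- c("participant", "group", "time", "path")
    assert_that(all(need %in% names(cfg$inputs)),
                "inputs needs columns %s", paste(need, collapse = ", "))
    return(lapply(seq_len(nrow(cfg$inputs)), function(i) {
      as.list(cfg$inputs[i, need])
    }))
  }
  d <- cfg$design
  cells <- list()
  for (i in seq_len(nrow(d$participants))) {
    for (tm in d$times) {
      cells[[length(cells) + 1L]] <- list(
        participant = d$participants$id[i],
        group = d$participants$group[i], time = tm, path = NULL
      )
    }
  }
  cells
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) every recording of the design, preprocesses it,
#' computes per-epoch RWE connectomes, thresholds them at the configured
#' densities, scores global (and optionally local) network metrics against
#' cached random-null ensembles, and — when both groups and both times are
#' present — runs the 2x2 mixed ANOVA on each global metric per density.
#' Recordings are analysed one at a time, so memory stays flat in the cohort
#' size. The run is deterministic given the config (master seed included).
#'
#' @param cfg a \code{\link{run_config}}.
#' @return a \code{pipeline_result}: list with \code{panel} (long metric
#'   table), \code{global} (wide per-cell global metrics), \code{nodes}
#'   (per-node table or NULL), \code{anova} (metric x density x effect
#'   table, or NULL), and \code{manifest}.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  cells <- pipeline_cells(cfg)
  cache <- new.env(parent = emptyenv())
  global_rows <- list()
  node_rows <- list()
  for (cell in cells) {
    if (is.null(cell$path)) {
      sim <- simulate_cell(cfg$design, cell$participant, cell$group,
                           cell$time, cfg$n_nodes, cfg$fs, cfg$duration,
                           cfg$base_params)
      ts <- sim$ts
    } else {
      ts <- tryCatch(read_roi_signals(cell$path), error = function(e) {
        stopf("load stage failed for %s/%s: %s", cell$participant,
              cell$time, conditionMessage(e))
      })
    }
    res <- tryCatch(analyze_recording(ts, cfg, cache), error = function(e) {
      stopf("analysis failed for %s/%s: %s", cell$participant, cell$time,
            conditionMessage(e))
    })
    meta <- data.frame(participant = cell$participant, group = cell$group,
                       time = cell$time)
    global_rows[[length(global_rows) + 1L]] <- cbind(meta, res$global)
    if (!is.null(res$nodes)) {
      node_rows[[length(node_rows) + 1L]] <- cbind(meta, res$nodes)
    }
    if (cfg$verbose) {
      message(sprintf("analysed %s/%s (%d/%d epochs kept)", cell$participant,
                      cell$time, res$n_epochs_kept, res$n_epochs_total))
    }
  }
  global <- do.call(rbind, global_rows)
  rownames(global) <- NULL
  metrics <- c("c_mean", "l_mean", "sigma")
  panel <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(participant = global$participant, group = global$group,
               time = global$time, density_label = global$density_label,
               metric = m, value = global[[m]])
  }))
  anova <- NULL
  if (length(unique(global$group)) == 2 &&
      length(unique(global$time)) == 2) {
    time_order <- if (!is.null(cfg$design)) cfg$design$times else
      sort(unique(global$time))
    combos <- expand.grid(metric = metrics,
                          density_label = unique(global$density_label),
                          stringsAsFactors = FALSE)
    anova <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      sub <- panel[panel$metric == combos$metric[i] &
                     panel$density_label == combos$density_label[i], ]
      sub$value <- as.numeric(sub$value)
      out <- mixed_anova_2x2(sub, time_order = time_order)
      cbind(metric = combos$metric[i],
            density_label = combos$density_label[i], out)
    }))
    if (isTRUE(cfg$holm_adjust)) {
      # non-default behaviour: the reference analysis reports uncorrected p
      anova$p_holm <- NA_real_
      for (eff in unique(anova$effect)) {
        sel <- anova$effect == eff
        anova$p_holm[sel] <- stats::p.adjust(anova$p[sel], method = "holm")
      }
    }
  }
  hash <- config_hash(cfg[setdiff(names(cfg), c("out_dir", "verbose"))])
  manifest <- list(config_hash = hash, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("rweconn")),
                   n_cells = length(cells),
                   densities = cfg$densities, wavelet = cfg$wavelet,
                   n_panel_rows = nrow(panel))
  res <- structure(list(panel = panel, global = global,
                        nodes = if (length(node_rows)) do.call(rbind, node_rows) else NULL,
                        anova = anova, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_result(res, cfg$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d cells, %d panel rows (config %s)\n",
              x$manifest$n_cells, nrow(x$panel), x$manifest$config_hash))
  if (!is.null(x$anova)) {
    cat("time x group interactions:\n")
    print(x$anova[x$anova$effect == "interaction",
                  c("metric", "density_label", "F", "df1", "df2", "p")],
          row.names = FALSE)
  }
  invisible(x)
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) cbind(df, config_hash = res$manifest$config_hash)
  utils::write.table(stamp(res$panel), file.path(out_dir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(stamp(res$global), file.path(out_dir, "global.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$nodes)) {
    utils::write.table(stamp(res$nodes), file.path(out_dir, "node_metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(res$anova)) {
    utils::write.table(stamp(res$anova), file.path(out_dir, "anova.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
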
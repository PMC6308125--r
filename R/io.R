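# Delimited-text and JSON interchange formats.
#
# Signals: tab-separated, one row per ROI, first column "roi", remaining
# columns s1..sN; a JSON sidecar (<path>.json) carries fs, labels and any
# generator metadata. Graphs: two-column edge lists (source, target, 0-based)
# with a "# {json}" header line. RWE matrices: tab-separated square matrices
# with ROI-labelled header and row names.

#' Write ROI signals as delimited text with a JSON manifest
#'
#' @param x a \code{roi_ts}.
#' @param path output file; the manifest is written to \code{paste0(path,
#'   ".json")}.
#' @param meta optional named list merged into the manifest.
#' @return \code{path}, invisibly.
#' @export
write_roi_signals <- function(x, path, meta = list()) {
  stopifnot(inherits(x, "roi_ts"))
  df <- data.frame(roi = x$labels, x$data, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("roi", sprintf("s%d", seq_len(n_samples(x))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- c(list(fs = x$fs, n_rois = n_rois(x),
                     n_samples = n_samples(x), labels = x$labels), meta)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read ROI signals written by \code{\link{write_roi_signals}}
#'
#' @param path signals file; \code{paste0(path, ".json")} must exist.
#' @return a \code{roi_ts}.
#' @export
read_roi_signals <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  mpath <- paste0(path, ".json")
  assert_that(file.exists(mpath), "missing manifest: %s", mpath)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(identical(colnames(df)[1], "roi"),
              "malformed header: first column must be 'roi'")
  labels <- df[[1]]
  data <- as.matrix(df[, -1, drop = FALSE])
  assert_that(length(manifest$labels) == nrow(data),
              "manifest labels (%d) do not match signal rows (%d)",
              length(manifest$labels), nrow(data))
  assert_that(all(labels == manifest$labels), "label mismatch with manifest")
  assert_that(!anyNA(data), "signals contain NA")
  roi_timeseries(data, manifest$fs, labels)
}

#' Write a JSON epoch-screening report
#'
#' Records how many epochs were kept/rejected and the peak-to-peak limit in
#' force, for provenance alongside exported epoch data.
#'
#' @param e an \code{epoch_set}.
#' @param path output JSON file.
#' @param peak_to_peak_limit the limit that produced the mask (optional).
#' @return \code{path}, invisibly.
#' @export
write_epoch_report <- function(e, path, peak_to_peak_limit = NA) {
  stopifnot(inherits(e, "epoch_set"))
  jsonlite::write_json(
    list(n_epochs = length(e$kept_mask), n_kept = sum(e$kept_mask),
         n_rejected = sum(!e$kept_mask), kept_mask = e$kept_mask,
         epoch_len = e$epoch_len, fs = e$fs,
         epoch_duration_s = epoch_duration(e),
         peak_to_peak_limit = peak_to_peak_limit),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a graph as an edge list with a JSON header
#'
#' First line: \code{# {json}} with n_nodes, n_edges, density_label and the
#' tie-break convention; then tab-separated 0-based (source, target) rows.
#'
#' @param g a \code{bdgraph}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "bdgraph"))
  hdr <- jsonlite::toJSON(list(n_nodes = g$n_nodes, n_edges = g$n_edges,
                               density_label = g$density_label,
                               topology = g$topology,
                               tie_break = "value,source,target"),
                          auto_unbox = TRUE, null = "null")
  edges <- which(g$adjacency == 1L, arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE] - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  utils::write.table(edges, con, sep = "\t", row.names = FALSE,
                     col.names = c("source", "target"), quote = FALSE)
  invisible(path)
}

#' Read a graph written by \code{\link{write_edge_list}}
#'
#' @param path edge-list file.
#' @return a \code{bdgraph}.
#' @export
read_edge_list <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  first <- readLines(path, n = 1)
  assert_that(startsWith(first, "# "), "missing JSON header line")
  hdr <- jsonlite::fromJSON(sub("^# ", "", first))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1)
  assert_that(all(df$source != df$target), "edge list contains a self-loop")
  assert_that(all(df$source >= 0 & df$source < hdr$n_nodes) &&
                all(df$target >= 0 & df$target < hdr$n_nodes),
              "edge indices out of range")
  adj <- matrix(0L, hdr$n_nodes, hdr$n_nodes)
  adj[cbind(df$source + 1L, df$target + 1L)] <- 1L
  assert_that(sum(adj) == hdr$n_edges,
              "edge count %d does not match header (%d)", sum(adj),
              hdr$n_edges)
  bdgraph(adj, density_label = hdr$density_label,
          topology = if (is.null(hdr$topology)) NULL else hdr$topology)
}

#' Write an RWE matrix as labelled delimited text
#'
#' @param m an \code{rwe_matrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_rwe_matrix <- function(m, path) {
  vals <- unclass(m)
  # 17 significant digits survive the text round trip exactly
  df <- as.data.frame(apply(vals, 2, sprintf, fmt = "%.17g"))
  colnames(df) <- colnames(m)
  utils::write.table(cbind(roi = rownames(m), df), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an RWE matrix written by \code{\link{write_rwe_matrix}}
#'
#' @param path matrix file.
#' @return an \code{rwe_matrix}.
#' @export
read_rwe_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  assert_that(nrow(m) == ncol(m), "matrix is not square")
  assert_that(!anyNA(m), "matrix contains NA")
  rownames(m) <- df[[1]]
  structure(m, class = c("rwe_matrix", "matrix"), epoch_index = NA_integer_)
}
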
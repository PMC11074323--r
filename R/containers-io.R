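#' Node-to-network atlas
#'
#' @param node_id character or integer node identifiers (unique).
#' @param network network name per node; at least two distinct networks.
#' @return a `network_atlas`: list with `node_id`, `network_of_node`
#'   (character per node) and `networks` (ordered unique network names).
#' @export
network_atlas <- function(node_id, network) {
  stopifnot(length(node_id) == length(network))
  if (anyDuplicated(node_id)) stop("network_atlas: duplicate node ids")
  network <- as.character(network)
  networks <- unique(network)
  if (length(networks) < 2) stop("network_atlas: need >= 2 networks")
  structure(
    list(node_id = as.character(node_id), network_of_node = network,
         networks = networks),
    class = "network_atlas"
  )
}

#' Region-of-interest time series for one subject
#'
#' @param data nodes-by-scans numeric matrix, no missing values.
#' @param subject_id subject identifier.
#' @param atlas optional `network_atlas`; node order must match rows.
#' @param tr_seconds repetition time of the scan sequence (default 2).
#' @param repetition_onsets scan indices (1-based) of trial onsets.
#' @return an `roi_timeseries` list.
#' @export
roi_timeseries <- function(data, subject_id = NA, atlas = NULL,
                           tr_seconds = 2, repetition_onsets = integer()) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("roi_timeseries: missing values in data")
  if (ncol(data) < 2) stop("roi_timeseries: need >= 2 scans")
  if (!is.null(atlas)) {
    stopifnot(inherits(atlas, "network_atlas"),
              nrow(data) == length(atlas$node_id))
    rownames(data) <- atlas$node_id
  }
  structure(
    list(subject_id = subject_id, data = data, atlas = atlas,
         tr_seconds = tr_seconds,
         repetition_onsets = as.integer(repetition_onsets)),
    class = "roi_timeseries"
  )
}

#' @rdname io_tables
#' @param ts an `roi_timeseries`.
#' @param path file path.
#' @export
write_timeseries <- function(ts, path) {
  df <- data.frame(node_id = rownames(ts$data), ts$data,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Delimited-table readers and writers
#'
#' Time series are tab-delimited with nodes as rows (node id in the first
#' column) and scans as columns; the atlas is tab-delimited `node_id`,
#' `network_name`; trial tables are comma-delimited.
#'
#' @name io_tables
#' @param path file path.
#' @param atlas optional `network_atlas` to attach.
#' @param ... passed through to [roi_timeseries()].
#' @export
read_timeseries <- function(path, atlas = NULL, ...) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  roi_timeseries(m, atlas = atlas, ...)
}

#' @rdname io_tables
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(
    data.frame(node_id = atlas$node_id, network_name = atlas$network_of_node),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname io_tables
#' @export
read_atlas <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  network_atlas(df$node_id, df$network_name)
}

#' @rdname io_tables
#' @param trials trial-table data frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
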
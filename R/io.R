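#' Read a node table from delimited text
#'
#' Expects a header with columns `id,x,y,z` (extra columns are kept but
#' ignored). Coordinates are converted to micrometres according to
#' `input_unit`.
#'
#' @param path file path (CSV or TSV; the delimiter is sniffed from the
#'   header line).
#' @param soma_size_unit micrometres per soma-size unit (default 1).
#' @param input_unit one of `"um"`, `"nm"`, `"mm"`: unit of the stored
#'   coordinates.
#' @return validated node data frame (sorted by id) with attribute
#'   `soma_size_unit`; pass to [spatial_network()].
#' @export
read_node_table <- function(path, soma_size_unit = 1,
                            input_unit = c("um", "nm", "mm")) {
  input_unit <- match.arg(input_unit)
  tab <- read_delimited(path)
  for (cc in c("x", "y", "z")) {
    v <- tab[[cc]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num))
      stop("non-numeric coordinate in column '", cc, "' at row(s) ",
           paste(utils::head(which(is.na(num)), 5L), collapse = ", "))
    tab[[cc]] <- num * switch(input_unit, um = 1, nm = 1e-3, mm = 1e3)
  }
  nodes <- validate_node_table(tab, soma_size_unit)
  attr(nodes, "soma_size_unit") <- soma_size_unit
  nodes
}

#' Read an undirected edge list from delimited text
#'
#' First two columns are endpoint ids; an optional `weight` column carries
#' synapse counts. Unordered duplicates (`(a,b)` and `(b,a)`) collapse to one
#' edge; when `weighted`, their weights are summed (synapse lists enumerate
#' individual synapses), otherwise duplicates collapse silently with a
#' message reporting the count.
#'
#' @param path file path.
#' @param nodes validated node table (from [read_node_table()] or a
#'   `spatial_network`'s `$nodes`).
#' @param weighted read and aggregate the `weight` column?
#' @return data frame `from`, `to` (ids, from < to in node order) and
#'   optionally `weight`.
#' @export
read_edge_list <- function(path, nodes, weighted = FALSE) {
  if (inherits(nodes, "spatial_network")) nodes <- nodes$nodes
  tab <- read_delimited(path)
  idx <- edge_ids_to_index(tab[[1L]], tab[[2L]], nodes$id)  # validates
  i <- match(as.character(tab[[1L]]), nodes$id)
  j <- match(as.character(tab[[2L]]), nodes$id)
  key <- paste(pmin(i, j), pmax(i, j), sep = "-")
  if (weighted) {
    if (!("weight" %in% names(tab)))
      stop("weighted = TRUE but no 'weight' column in ", path)
    check_weights(tab$weight)
    w <- tapply(as.integer(tab$weight), key, sum)
    key_u <- names(w)
  } else {
    ndup <- sum(duplicated(key))
    if (ndup > 0L)
      message("collapsed ", ndup, " duplicate unordered edge row(s)")
    key_u <- unique(key)
    w <- NULL
  }
  parts <- do.call(rbind, strsplit(key_u, "-", fixed = TRUE))
  ii <- as.integer(parts[, 1L]); jj <- as.integer(parts[, 2L])
  ord <- order(ii, jj)
  out <- data.frame(from = nodes$id[ii[ord]], to = nodes$id[jj[ord]])
  if (weighted) out$weight <- as.integer(w[ord])
  out
}

#' @rdname read_node_table
#' @param nodes node data frame to write
#' @export
write_node_table <- function(nodes, path) {
  utils::write.csv(nodes[, c("id", "x", "y", "z")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname read_edge_list
#' @param edges edge data frame (`from`, `to`[, `weight`]) to write
#' @export
write_edge_list <- function(edges, path) {
  utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Edge data frame of a network (by node id)
#' @param net a `spatial_network`
#' @export
edge_list <- function(net) {
  ids <- node_ids(net)
  out <- data.frame(from = ids[net$edge_idx[, 1L]],
                    to = ids[net$edge_idx[, 2L]])
  if (!is.null(net$weight)) out$weight <- net$weight
  out
}

read_delimited <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
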
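#' Spatial network of neurons
#'
#' A `spatial_network` couples a node table (one neuron per row, with a 3D
#' "center of mesh" position in micrometres) with an undirected, simple edge
#' set. It represents either a connectome (edges = at least one chemical
#' synapse between the pair) or a contactome (edges = neuron surfaces within a
#' small contact threshold). All internal distances are expressed in soma-size
#' units: positions are stored in micrometres and divided by `soma_size_unit`
#' whenever a distance is computed, so that decay scales are comparable across
#' organisms.
#'
#' Nodes are sorted by id (as character) at construction; all integer node
#' indices used elsewhere in the package refer to this deterministic order.
#'
#' @param nodes data frame with columns `id`, `x`, `y`, `z` (positions in
#'   micrometres). Ids must be unique; coordinates finite.
#' @param edges data frame (or 2-column matrix) whose first two columns name
#'   edge endpoints by node id; an optional `weight` column gives positive
#'   integer synapse counts. Self loops are an error; duplicate unordered
#'   pairs are an error here (use [read_edge_list()] for tolerant parsing).
#' @param soma_size_unit positive scalar, micrometres per soma-size unit.
#'   The default 1 reports all distances in micrometres.
#' @return An object of class `spatial_network`: a list with elements
#'   `nodes` (sorted data frame), `edge_idx` (2-column integer matrix, each
#'   row `i < j` in node order, rows sorted lexicographically), `weight`
#'   (integer vector or `NULL`) and `soma_size_unit`.
#' @examples
#' nodes <- data.frame(id = c("a", "b", "c"),
#'                     x = c(0, 3, 0), y = c(0, 4, 1), z = 0)
#' net <- spatial_network(nodes, data.frame(from = "a", to = "b"))
#' n_edges(net)
#' wiring_length(net)  # 5: the 3-4-5 triangle hypotenuse
#' @export
spatial_network <- function(nodes, edges = NULL, soma_size_unit = 1) {
  nodes <- validate_node_table(nodes, soma_size_unit)
  net <- structure(
    list(nodes = nodes,
         edge_idx = matrix(integer(0), 0L, 2L),
         weight = NULL,
         soma_size_unit = soma_size_unit),
    class = "spatial_network")
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.data.frame(edges)
    idx <- edge_ids_to_index(edges[[1L]], edges[[2L]], nodes$id)
    if (anyDuplicated(idx)) stop("duplicate unordered edge pairs in `edges`")
    net$edge_idx <- idx
    if ("weight" %in% names(edges)) {
      w <- edges$weight[order_edge_rows(edges[[1L]], edges[[2L]], nodes$id)]
      check_weights(w)
      net$weight <- as.integer(w)
    }
  }
  net
}

validate_node_table <- function(nodes, soma_size_unit = 1) {
  nodes <- as.data.frame(nodes)
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(nodes)))
    stop("node table must have columns id, x, y, z")
  if (!(is.numeric(soma_size_unit) && length(soma_size_unit) == 1L &&
        is.finite(soma_size_unit) && soma_size_unit > 0))
    stop("soma_size_unit must be a positive finite scalar")
  id <- as.character(nodes$id)
  dup <- id[duplicated(id)]
  if (length(dup))
    stop("duplicate node id(s): ", paste(unique(dup), collapse = ", "))
  for (cc in c("x", "y", "z")) {
    v <- nodes[[cc]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      bad <- which(!is.numeric(v) | !is.finite(suppressWarnings(as.numeric(v))))
      stop("non-finite/non-numeric coordinate in column '", cc,
           "' at row(s) ", paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  nodes <- nodes[order(id), need, drop = FALSE]
  nodes$id <- sort(id)
  rownames(nodes) <- NULL
  nodes
}

# map endpoint id vectors to a sorted (i<j, lexicographic) integer edge matrix
edge_ids_to_index <- function(from, to, ids) {
  i <- match(as.character(from), ids)
  j <- match(as.character(to), ids)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(as.character(from)[is.na(i)], as.character(to)[is.na(j)]))
    stop("edge endpoint(s) not in node table: ", paste(bad, collapse = ", "))
  }
  if (any(i == j))
    stop("self-loop(s) on node(s): ",
         paste(unique(ids[i[i == j]]), collapse = ", "))
  idx <- cbind(pmin(i, j), pmax(i, j))
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

order_edge_rows <- function(from, to, ids) {
  i <- match(as.character(from), ids)
  j <- match(as.character(to), ids)
  order(pmin(i, j), pmax(i, j))
}

check_weights <- function(w) {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w < 1) ||
      any(w != round(w)))
    stop("edge weights must be positive integers (synapse counts)")
  invisible(TRUE)
}

#' @rdname spatial_network
#' @param net,x a `spatial_network`
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname spatial_network
#' @export
n_edges <- function(net) nrow(net$edge_idx)

#' @rdname spatial_network
#' @export
node_ids <- function(net) net$nodes$id

#' Node positions in soma-size units
#'
#' @param net a `spatial_network`
#' @return numeric matrix, one row per node in node order, columns x,y,z,
#'   positions divided by the network's `soma_size_unit`.
#' @export
node_positions <- function(net) {
  as.matrix(net$nodes[, c("x", "y", "z")]) / net$soma_size_unit
}

#' Undirected degree sequence (all nodes, including isolated)
#'
#' @param net a `spatial_network`
#' @return integer vector in node order.
#' @export
degree_sequence <- function(net) {
  tabulate(c(net$edge_idx[, 1L], net$edge_idx[, 2L]), nbins = n_nodes(net))
}

#' Per-edge Euclidean lengths and total wiring length
#'
#' The wiring length L is the sum of Euclidean distances (in soma-size units)
#' over connected pairs, the linear wiring-cost proxy used throughout the
#' package.
#'
#' @param net a `spatial_network`
#' @return `edge_lengths`: numeric vector per edge; `wiring_length`: scalar L.
#' @export
edge_lengths <- function(net) {
  if (n_edges(net) == 0L) return(numeric(0))
  pos <- node_positions(net)
  d <- pos[net$edge_idx[, 1L], , drop = FALSE] -
    pos[net$edge_idx[, 2L], , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' @rdname edge_lengths
#' @export
wiring_length <- function(net) sum(edge_lengths(net))

#' @export
print.spatial_network <- function(x, ...) {
  cat("<spatial_network> ", n_nodes(x), " nodes, ", n_edges(x), " edges",
      if (!is.null(x$weight)) " (weighted)", "\n", sep = "")
  cat("  soma_size_unit: ", x$soma_size_unit, " um\n", sep = "")
  invisible(x)
}

#' Logical adjacency matrix (dense; small networks only)
#' @param net a `spatial_network`
#' @keywords internal
adjacency_matrix <- function(net) {
  n <- n_nodes(net)
  A <- matrix(0, n, n)
  if (n_edges(net)) {
    A[net$edge_idx] <- 1
    A[net$edge_idx[, 2:1, drop = FALSE]] <- 1
  }
  A
}

#' Edge set keys "i-j" for fast membership tests
#' @keywords internal
edge_keys <- function(idx) paste(idx[, 1L], idx[, 2L], sep = "-")

#' Validate the multilayer connectome/contactome subset invariant
#'
#' Connectomes are subnetworks of contactomes: every synaptic edge must also
#' be a contact edge. This reports the synaptic edges missing from the contact
#' layer and the achieved coverage fraction.
#'
#' @param connectome,contactome `spatial_network`s on the same node table.
#' @return list with `violations` (data frame of offending edges, by id),
#'   `coverage` (fraction of connectome edges present in the contactome) and
#'   `valid` (`TRUE` iff no violations).
#' @export
validate_multilayer <- function(connectome, contactome) {
  if (!identical(node_ids(connectome), node_ids(contactome)))
    stop("connectome and contactome must share the same node table")
  ck <- edge_keys(connectome$edge_idx)
  missing <- !(ck %in% edge_keys(contactome$edge_idx))
  viol <- connectome$edge_idx[missing, , drop = FALSE]
  ids <- node_ids(connectome)
  list(
    violations = data.frame(from = ids[viol[, 1L]], to = ids[viol[, 2L]]),
    coverage = if (length(ck)) 1 - mean(missing) else 1,
    valid = !any(missing))
}

#' Paired connectome/contactome container
#'
#' @param connectome,contactome `spatial_network`s on the same node table;
#'   the connectome edge set must be a subset of the contactome's.
#' @return object of class `multilayer_connectome`.
#' @export
multilayer_connectome <- function(connectome, contactome) {
  rep <- validate_multilayer(connectome, contactome)
  if (!rep$valid)
    stop("connectome is not a subnetwork of the contactome (",
         nrow(rep$violations), " violating edge(s))")
  structure(list(connectome = connectome, contactome = contactome),
            class = "multilayer_connectome")
}

#' @export
print.multilayer_connectome <- function(x, ...) {
  cat("<multilayer_connectome> ", n_nodes(x$connectome), " nodes; E_syn = ",
      n_edges(x$connectome), ", E_cont = ", n_edges(x$contactome), "\n",
      sep = "")
  invisible(x)
}
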
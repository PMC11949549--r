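#' Point clouds of neuron surfaces
#'
#' A point cloud stands in for the vertices of a neuron's surface mesh:
#' a matrix of 3D sample points in micrometres. The center of mesh — the
#' arithmetic mean of the points — serves as the neuron's node position.
#'
#' @param points numeric matrix (or data frame) with 3 columns, micrometres.
#' @param node_id node label.
#' @return object of class `point_cloud`.
#' @export
point_cloud <- function(points, node_id = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 1L)
    stop("point cloud must be a non-empty 3-column matrix")
  if (any(!is.finite(points))) stop("non-finite point coordinates")
  dimnames(points) <- NULL
  structure(list(node_id = as.character(node_id), points = points),
            class = "point_cloud")
}

#' @rdname point_cloud
#' @param cloud a `point_cloud`
#' @return `center_of_mesh`: 3-vector, the mean point position (micrometres).
#' @export
center_of_mesh <- function(cloud) {
  colMeans(cloud$points)
}

#' Exact minimum distance between two point clouds, in nanometres
#'
#' The smallest Euclidean distance over all point pairs of the two clouds
#' (cloud coordinates in micrometres; result in nanometres). Computed
#' exactly by blocked evaluation with a bounding-box lower-bound prune —
#' blocks whose axis-aligned bounding boxes cannot beat the current best
#' distance are skipped.
#'
#' @param a,b `point_cloud`s (or bare 3-column matrices, micrometres).
#' @param block_size points per block.
#' @return minimum inter-cloud distance in nanometres.
#' @export
min_cloud_distance <- function(a, b, block_size = 256L) {
  pa <- if (inherits(a, "point_cloud")) a$points else as.matrix(a)
  pb <- if (inherits(b, "point_cloud")) b$points else as.matrix(b)
  best2 <- Inf
  na <- nrow(pa); nb <- nrow(pb)
  sa <- split(seq_len(na), (seq_len(na) - 1L) %/% block_size)
  sb <- split(seq_len(nb), (seq_len(nb) - 1L) %/% block_size)
  box <- function(m) rbind(apply(m, 2L, min), apply(m, 2L, max))
  boxes_a <- lapply(sa, function(ii) box(pa[ii, , drop = FALSE]))
  boxes_b <- lapply(sb, function(ii) box(pb[ii, , drop = FALSE]))
  box_gap2 <- function(ba, bb) {
    g <- pmax(0, pmax(ba[1L, ] - bb[2L, ], bb[1L, ] - ba[2L, ]))
    sum(g * g)
  }
  for (ia in seq_along(sa)) {
    for (ib in seq_along(sb)) {
      if (box_gap2(boxes_a[[ia]], boxes_b[[ib]]) >= best2) next
      A <- pa[sa[[ia]], , drop = FALSE]
      B <- pb[sb[[ib]], , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      m <- min(d2)
      if (m < best2) best2 <- m
    }
  }
  sqrt(max(best2, 0)) * 1000
}

#' Minimum inter-cloud distances for a set of candidate pairs
#'
#' @param clouds named list of `point_cloud`s (names = node ids).
#' @param pairs data frame or 2-column matrix of node-id pairs.
#' @return data frame `from`, `to`, `d_min` (nanometres).
#' @export
contact_candidates <- function(clouds, pairs) {
  pairs <- as.data.frame(pairs)
  from <- as.character(pairs[[1L]]); to <- as.character(pairs[[2L]])
  miss <- setdiff(unique(c(from, to)), names(clouds))
  if (length(miss))
    stop("no point cloud for node(s): ", paste(miss, collapse = ", "))
  d <- mapply(function(u, v) min_cloud_distance(clouds[[u]], clouds[[v]]),
              from, to)
  data.frame(from = from, to = to, d_min = unname(d))
}

#' Select the contact distance threshold from synaptic-edge coverage
#'
#' Picks the smallest integer-nanometre threshold `t` such that the fraction
#' of synaptic pairs with minimum inter-cloud distance strictly below `t`
#' reaches `coverage` (default 99 percent). The strict inequality matches
#' contact assignment (`d_min < d_thr`), and the minimal real threshold is
#' rounded up to the next nanometre.
#'
#' @param candidates data frame with columns `from`, `to`, `d_min` (nm), as
#'   from [contact_candidates()]. Every synaptic pair must be present.
#' @param synaptic_pairs data frame/matrix of synaptic node-id pairs.
#' @param coverage required covered fraction in (0, 1].
#' @return integer threshold, nanometres.
#' @examples
#' cand <- data.frame(from = letters[1:4], to = letters[2:5],
#'                    d_min = c(10, 20, 30, 100))
#' select_contact_threshold(cand, cand[, 1:2], coverage = 0.99)  # 101
#' select_contact_threshold(cand, cand[, 1:2], coverage = 0.5)   # 21
#' @export
select_contact_threshold <- function(candidates, synaptic_pairs,
                                     coverage = 0.99) {
  stopifnot(coverage > 0, coverage <= 1)
  d <- candidate_lookup(candidates, synaptic_pairs)
  if (anyNA(d))
    stop("missing contact candidate for ", sum(is.na(d)), " synaptic pair(s)")
  m <- ceiling(coverage * length(d))
  d_sorted <- sort(d)
  d_m <- d_sorted[m]
  if (!is.finite(d_m)) stop("required coverage unattainable: non-finite d_min")
  as.integer(floor(d_m) + 1)
}

candidate_lookup <- function(candidates, pairs) {
  pairs <- as.data.frame(pairs)
  key <- function(u, v) paste(pmin(as.character(u), as.character(v)),
                              pmax(as.character(u), as.character(v)),
                              sep = "\r")
  ck <- key(candidates$from, candidates$to)
  d <- candidates$d_min[match(key(pairs[[1L]], pairs[[2L]]), ck)]
  d
}

#' Assemble a contactome and the multilayer connectome/contactome pair
#'
#' Contact edges are all candidate pairs with `d_min` strictly below the
#' threshold, plus any synaptic edges not already contained (the forced
#' "top-up" that guarantees the subset invariant exactly).
#'
#' @param candidates data frame `from`, `to`, `d_min` (nm).
#' @param threshold contact threshold in nanometres.
#' @param connectome synaptic [spatial_network()]; its nodes carry positions.
#' @return a `multilayer_connectome`; element `contactome` holds the contact
#'   network, and attribute `forced_edges` counts synaptic edges added by
#'   the top-up.
#' @export
assemble_contactome <- function(candidates, threshold, connectome) {
  hit <- candidates$d_min < threshold
  contact <- data.frame(from = as.character(candidates$from[hit]),
                        to = as.character(candidates$to[hit]))
  syn <- edge_list(connectome)[, c("from", "to")]
  d_syn <- candidate_lookup(candidates, syn)
  forced <- syn[!(d_syn < threshold) | is.na(d_syn), , drop = FALSE]
  all_edges <- unique(rbind(contact, forced))
  contactome <- spatial_network(connectome$nodes, all_edges,
                                soma_size_unit = connectome$soma_size_unit)
  ml <- multilayer_connectome(connectome, contactome)
  attr(ml, "forced_edges") <- nrow(forced)
  attr(ml, "threshold_nm") <- threshold
  ml
}
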
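#' Stream all pairwise node distances in blocks
#'
#' Enumerates every unordered node pair (i < j in node order, lexicographic)
#' exactly once and reports its Euclidean distance in soma-size units. Pairs
#' are produced block-wise — rows `i` are processed `block_size` at a time
#' against all `j > i` — so the peak working set is O(block_size * N) and the
#' full N x N matrix is never materialised.
#'
#' @param net a [spatial_network()] (or a validated node table plus
#'   `soma_size_unit`).
#' @param block_size number of `i` rows per block (>= 1).
#' @param fun optional callback `fun(i, j, d)` receiving integer endpoint
#'   vectors and distances for one block; when supplied its return values are
#'   collected in a list and the distance vector is not accumulated.
#' @return When `fun` is `NULL`, the numeric vector of all N(N-1)/2 distances
#'   in lexicographic pair order; otherwise the list of callback results.
#' @examples
#' net <- spatial_network(data.frame(id = 1:2, x = c(0, 3), y = c(0, 4), z = 0))
#' pairwise_distances(net)  # 5
#' @export
pairwise_distances <- function(net, block_size = 512L, fun = NULL) {
  stopifnot(block_size >= 1L)
  pos <- node_positions(net)
  n <- nrow(pos)
  acc <- if (is.null(fun)) vector("list", 0L) else list()
  out <- NULL
  if (is.null(fun)) out <- numeric(n * (n - 1) / 2)
  pos_t <- t(pos)
  at <- 0L
  i0 <- 1L
  res <- list()
  while (i0 < n) {
    i1 <- min(i0 + block_size - 1L, n - 1L)
    rows <- i0:i1
    # squared distances of block rows against all columns, then keep j > i
    blk <- pos[rows, , drop = FALSE]
    sq <- outer(rowSums(blk^2), rowSums(pos^2), "+") - 2 * blk %*% pos_t
    sq[sq < 0] <- 0
    for (r in seq_along(rows)) {
      i <- rows[r]
      j <- (i + 1L):n
      d <- sqrt(sq[r, j])
      if (is.null(fun)) {
        out[at + seq_along(j)] <- d
        at <- at + length(j)
      } else {
        res[[length(res) + 1L]] <- fun(rep.int(i, length(j)), j, d)
      }
    }
    i0 <- i1 + 1L
  }
  if (is.null(fun)) out else res
}

#' Linear index of an unordered pair in lexicographic (i < j) order
#' @param i,j node indices with i < j elementwise
#' @param n number of nodes
#' @keywords internal
pair_linear_index <- function(i, j, n) {
  (i - 1) * n - i * (i + 1) / 2 + j
}

# dense distance matrix in soma-size units; guarded so that large networks
# go through the streaming interface instead
distance_matrix <- function(net, max_n = 6000L) {
  n <- n_nodes(net)
  if (n > max_n)
    stop("refusing to build a dense ", n, "x", n,
         " distance matrix; use pairwise_distances()")
  D <- as.matrix(stats::dist(node_positions(net)))
  dimnames(D) <- NULL
  D
}
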
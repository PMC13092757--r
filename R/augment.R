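# Type-specific graph augmentation: nodes incident to sensitive edges are
# protected; perturbed views are produced by deleting non-critical edges
# (resistant and low-similarity connections) and masking feature
# dimensions of non-sensitive nodes. Sampling is count-based, so realized
# rates equal requested rates exactly and every draw is seed-reproducible.

#' Augmentation configuration
#'
#' @param edge_rate Fraction of the deletion pool removed per view
#'   (default 0.40, the best-performing augmentation rate).
#' @param mask_rate Fraction of feature dimensions masked per
#'   non-sensitive node (default 0.30).
#' @param protect_resistant Keep resistant edges out of the deletion pool
#'   (default FALSE: resistant edges are treated as removable noise, since
#'   with similarity edges disabled the pool would otherwise be empty).
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(edge_rate = 0.40, mask_rate = 0.30,
                           protect_resistant = FALSE) {
  stopifnot(edge_rate >= 0, edge_rate <= 1, mask_rate >= 0, mask_rate <= 1)
  structure(list(edge_rate = edge_rate, mask_rate = mask_rate,
                 protect_resistant = protect_resistant),
            class = "augment_config")
}

#' Partition graph nodes into sensitive and non-sensitive sets
#'
#' A node belongs to the sensitive set `S_s` iff it is incident to at
#' least one sensitive edge; all other nodes form `S_n`.
#'
#' @param graph A `response_graph` with response relations.
#' @return A list of class `node_partition` with integer index vectors
#'   `sensitive` and `nonsensitive`.
#' @export
partition_nodes <- function(graph) {
  stopifnot(inherits(graph, "response_graph"))
  if (is.null(graph$relations$sensitive)) {
    stop("graph has no 'sensitive' relation")
  }
  a <- graph$relations$sensitive
  incident <- (Matrix::rowSums(a) + Matrix::colSums(a)) > 0
  structure(list(sensitive = which(incident),
                 nonsensitive = which(!incident),
                 n_nodes = length(incident)),
            class = "node_partition")
}

# the removable-edge pool: resistant forward edges (unless protected) and
# the bottom half of similarity edges by score, as undirected units
.deletion_pool <- function(graph, protect_resistant = FALSE) {
  pool <- list()
  if (!protect_resistant && !is.null(graph$relations$resistant)) {
    tr <- .sparse_triplets(graph$relations$resistant)
    if (nrow(tr) > 0L) {
      pool[[length(pool) + 1L]] <-
        data.frame(relation = "resistant", i = tr$i, j = tr$j)
    }
  }
  for (nm in intersect(c("cell_sim", "drug_sim"), names(graph$relations))) {
    tr <- .sparse_triplets(graph$relations[[nm]])
    tr <- tr[tr$i < tr$j, , drop = FALSE]          # undirected units
    if (nrow(tr) == 0L) next
    sc <- graph$sim_scores[[nm]]
    score <- if (is.null(sc)) rep(0, nrow(tr)) else sc[cbind(tr$i, tr$j)]
    low <- rank(score, ties.method = "first") <= floor(nrow(tr) / 2)
    if (!any(low)) next
    pool[[length(pool) + 1L]] <-
      data.frame(relation = nm, i = tr$i[low], j = tr$j[low])
  }
  if (length(pool) == 0L) {
    return(data.frame(relation = character(0), i = integer(0),
                      j = integer(0)))
  }
  do.call(rbind, pool)
}

#' Delete non-critical edges from a response graph
#'
#' Removes exactly `round(rate * pool_size)` edges drawn uniformly from
#' the deletion pool (resistant edges plus the bottom half of similarity
#' edges by score). Sensitive edges and high-similarity edges are never
#' removed. Resistant deletions drop the forward and inverse directions
#' together; similarity deletions drop both directions of the undirected
#' pair.
#'
#' @param graph A `response_graph`.
#' @param partition A [partition_nodes()] result (recorded in provenance).
#' @param rate Deletion rate in `[0, 1]`.
#' @param seed Integer seed.
#' @param protect_resistant Exclude resistant edges from the pool.
#' @return The perturbed graph, with the deleted edges attached as
#'   attribute `deleted` (a data frame `relation`, `i`, `j`).
#' @export
delete_edges <- function(graph, partition, rate, seed = 1L,
                         protect_resistant = FALSE) {
  stopifnot(inherits(graph, "response_graph"), rate >= 0, rate <= 1)
  pool <- .deletion_pool(graph, protect_resistant)
  if (rate == 0 || nrow(pool) == 0L) {
    attr(graph, "deleted") <- pool[0, , drop = FALSE]
    return(graph)
  }
  take <- with_seed(seed, sample_exact(nrow(pool), rate))
  del <- pool[take, , drop = FALSE]
  for (nm in unique(del$relation)) {
    d <- del[del$relation == nm, , drop = FALSE]
    a <- graph$relations[[nm]]
    a[cbind(d$i, d$j)] <- 0
    if (nm == "resistant") {
      inv <- graph$relations$resistant_inv
      inv[cbind(d$j, d$i)] <- 0
      graph$relations$resistant_inv <- Matrix::drop0(inv)
    } else {
      a[cbind(d$j, d$i)] <- 0
    }
    graph$relations[[nm]] <- Matrix::drop0(a)
  }
  attr(graph, "deleted") <- del
  graph
}

# 0/1 multiplier matrix implementing per-node dimension masking; exactly
# round(rate * n_dims) zeros per non-sensitive row
.mask_matrix <- function(n_nodes, n_dims, mask_rows, rate, seed = 1L) {
  m <- matrix(1, n_nodes, n_dims)
  if (rate == 0 || length(mask_rows) == 0L) return(m)
  with_seed(seed, {
    for (r in mask_rows) m[r, sample_exact(n_dims, rate)] <- 0
  })
  m
}

#' Mask feature dimensions of non-sensitive nodes
#'
#' For every node in the non-sensitive set, exactly `round(rate * F)`
#' feature dimensions (drawn independently per node) are set to zero.
#' Rows of sensitive nodes are untouched.
#'
#' @param features Numeric node-feature matrix.
#' @param partition A [partition_nodes()] result.
#' @param rate Masking rate in `[0, 1]`.
#' @param seed Integer seed.
#' @return The masked matrix, with the 0/1 multiplier attached as
#'   attribute `mask`.
#' @export
mask_features <- function(features, partition, rate, seed = 1L) {
  stopifnot(inherits(partition, "node_partition"),
            nrow(features) == partition$n_nodes, rate >= 0, rate <= 1)
  m <- .mask_matrix(nrow(features), ncol(features),
                    partition$nonsensitive, rate, seed)
  out <- features * m
  attr(out, "mask") <- m
  out
}

#' Generate two augmented views of a response graph
#'
#' Each view applies protected edge deletion and targeted feature masking
#' under an independent sub-seed derived from `seed` (`2 * seed + 1` and
#' `2 * seed + 2`). The subgraph induced by sensitive edges and the
#' feature rows of sensitive nodes are bit-identical to the source in
#' every view.
#'
#' @param graph A `response_graph` with `features` set.
#' @param config An [augment_config()].
#' @param seed Integer seed.
#' @return A list of two `augmented_view` objects, each with `graph`,
#'   `features`, and `provenance` (seed, rates, deleted edges, mask).
#' @export
make_views <- function(graph, config = augment_config(), seed = 1L) {
  stopifnot(inherits(graph, "response_graph"))
  if (is.null(graph$features)) stop("graph has no feature matrix")
  part <- partition_nodes(graph)
  sub_seeds <- c((2 * as.numeric(seed) + 1) %% 2147483647,
                 (2 * as.numeric(seed) + 2) %% 2147483647)
  views <- lapply(sub_seeds, function(sv) {
    g <- delete_edges(graph, part, config$edge_rate,
                      seed = derive_seed(sv, "edges"),
                      protect_resistant = config$protect_resistant)
    f <- mask_features(graph$features, part, config$mask_rate,
                       seed = derive_seed(sv, "mask"))
    structure(
      list(graph = g, features = f,
           provenance = list(seed = sv, edge_rate = config$edge_rate,
                             mask_rate = config$mask_rate,
                             deleted = attr(g, "deleted"),
                             mask = attr(f, "mask"))),
      class = "augmented_view")
  })
  names(views) <- c("g1", "g2")
  views
}
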
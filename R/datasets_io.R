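# Reading omics/drug/response tables, IC50 labeling, and assembly of the
# directed heterogeneous response graph.

#' Assign sensitivity labels from log10 IC50 thresholds
#'
#' Screening outcomes are categorised by thresholding the log10-transformed
#' IC50: values below `low_threshold` mean the cell line is sensitive to
#' the drug, values above `high_threshold` mean it is resistant, values in
#' between are treated as uncorrelated and excluded from the binary task.
#'
#' @param records A data frame with columns `cell_id`, `drug_id`,
#'   `log_ic50`.
#' @param low_threshold,high_threshold Numeric thresholds on log10 IC50;
#'   defaults -3 and 3. `low_threshold` must be less than `high_threshold`.
#' @return A tibble of the finite-IC50 records with an added `label` factor
#'   (`sensitive`/`resistant`/`uncorrelated`). Records with non-finite
#'   `log_ic50` are removed, reported via a warning, and attached as the
#'   `rejected` attribute. Per-class counts are attached as the `counts`
#'   attribute.
#' @examples
#' tbl <- tibble::tibble(cell_id = "c1", drug_id = "d1", log_ic50 = -4)
#' label_responses(tbl)$label
#' @export
label_responses <- function(records, low_threshold = -3, high_threshold = 3) {
  stopifnot(all(c("cell_id", "drug_id", "log_ic50") %in% names(records)))
  if (!(low_threshold < high_threshold)) {
    stop("low_threshold must be strictly less than high_threshold")
  }
  records <- tibble::as_tibble(records)
  bad <- !is.finite(records$log_ic50)
  rejected <- records[bad, , drop = FALSE]
  if (nrow(rejected) > 0L) {
    warning(nrow(rejected), " record(s) with non-finite log_ic50 rejected ",
            "(see attr(, 'rejected'))")
  }
  out <- records[!bad, , drop = FALSE]
  out$label <- factor(
    ifelse(out$log_ic50 < low_threshold, "sensitive",
           ifelse(out$log_ic50 > high_threshold, "resistant", "uncorrelated")),
    levels = c("sensitive", "resistant", "uncorrelated")
  )
  attr(out, "counts") <- table(out$label)
  attr(out, "rejected") <- rejected
  attr(out, "thresholds") <- c(low = low_threshold, high = high_threshold)
  out
}

#' Construct an omics profile set
#'
#' Bundles the per-view feature matrices for one cohort of cell lines. All
#' views must have one row per cell line in identical order.
#'
#' @param views Named list of numeric matrices (canonical order:
#'   transcriptomics, proteomics, cnv, mutations, methylation,
#'   metabolomics), each `n_c x p_view`.
#' @param cell_ids Character vector of cell line identifiers, length `n_c`.
#' @return An object of class `omics_profile_set`.
#' @export
omics_profile_set <- function(views, cell_ids) {
  stopifnot(is.list(views), length(views) >= 1L, !is.null(names(views)))
  cell_ids <- as.character(cell_ids)
  for (nm in names(views)) {
    v <- as.matrix(views[[nm]])
    if (nrow(v) != length(cell_ids)) {
      stop("view '", nm, "' has ", nrow(v), " rows but there are ",
           length(cell_ids), " cell ids")
    }
    if (ncol(v) == 0L) stop("view '", nm, "' has zero columns")
    if (!all(is.finite(v))) stop("view '", nm, "' has non-finite values")
    rownames(v) <- cell_ids
    views[[nm]] <- v
  }
  structure(list(views = views, cell_ids = cell_ids),
            class = "omics_profile_set")
}

#' @export
print.omics_profile_set <- function(x, ...) {
  cat("<omics_profile_set> ", length(x$cell_ids), " cell lines, ",
      length(x$views), " views\n", sep = "")
  for (nm in names(x$views)) {
    cat("  ", format(nm, width = 16), ncol(x$views[[nm]]), "features\n")
  }
  invisible(x)
}

#' Read per-view omics tables from disk
#'
#' Each file must be a CSV/TSV with a header row of feature names and cell
#' identifiers in the first column. Views are row-aligned by intersecting
#' cell ids across all files; cells absent from any view are dropped (and
#' reported). Missing values are median-imputed per column, then every
#' column is z-score standardised (constant columns become all-zero).
#'
#' @param paths Named character vector or list mapping view name to file.
#' @return An [omics_profile_set()]; dropped cell ids are attached as the
#'   `dropped_cells` attribute.
#' @export
read_omics_tables <- function(paths) {
  stopifnot(length(paths) >= 1L, !is.null(names(paths)))
  raw <- lapply(paths, function(p) {
    delim <- if (grepl("\\.tsv$|\\.txt$", p)) "\t" else ","
    df <- readr::read_delim(p, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  })
  id_sets <- lapply(raw, rownames)
  common <- Reduce(intersect, id_sets)
  if (length(common) == 0L) {
    stop("no cell ids shared across all views (per-view counts: ",
         paste(names(raw), vapply(id_sets, length, 1L), sep = "=",
               collapse = ", "), ")")
  }
  dropped <- setdiff(unique(unlist(id_sets)), common)
  if (length(dropped) > 0L) {
    message(length(dropped), " cell id(s) missing from at least one view ",
            "were dropped")
  }
  views <- lapply(raw, function(m) {
    m <- m[common, , drop = FALSE]
    standardize_columns(impute_median(m))
  })
  out <- omics_profile_set(views, common)
  attr(out, "dropped_cells") <- dropped
  out
}

# median imputation per column; a column with no observed value becomes 0
impute_median <- function(m) {
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) {
      med <- stats::median(m[!miss, j])
      m[miss, j] <- if (is.finite(med)) med else 0
    }
  }
  m
}

standardize_columns <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  sweep(sweep(m, 2L, mu), 2L, sdv, "/")
}

#' k-nearest-neighbour similarity edges within one node type
#'
#' Computes pairwise cosine or Tanimoto similarity over feature rows and
#' connects each node to its `k` most similar other nodes; the result is
#' symmetrised as the union of the directed top-k sets. Self-similarity is
#' excluded. Each retained edge keeps its similarity score (used later to
#' pool low-similarity edges for augmentation-time deletion).
#'
#' @param features Numeric matrix, one row per node (binary fingerprints
#'   for `metric = "tanimoto"`).
#' @param k Number of neighbours per node; must be `< nrow(features)`.
#' @param metric `"cosine"` or `"tanimoto"`.
#' @return A sparse binary symmetric adjacency (`Matrix::dgCMatrix`) with
#'   the score-valued sparse matrix attached as attribute `scores`.
#' @export
compute_similarity_edges <- function(features, k = 5L,
                                     metric = c("cosine", "tanimoto")) {
  metric <- match.arg(metric)
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(k >= 1L, k < n)
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(features^2))
    zero <- nrm == 0
    if (any(zero)) {
      warning(sum(zero), " all-zero feature row(s); their similarity is 0 ",
              "against all nodes")
      nrm[zero] <- 1
    }
    sim <- tcrossprod(features / nrm)
  } else {
    if (any(rowSums(features) == 0)) {
      warning(sum(rowSums(features) == 0), " empty fingerprint row(s); ",
              "their similarity is 0 against all nodes")
    }
    sim <- tanimoto_similarity(features)
  }
  diag(sim) <- -Inf
  adj <- Matrix::Matrix(0, n, n, sparse = TRUE)
  for (i in seq_len(n)) {
    nb <- order(sim[i, ], decreasing = TRUE)[seq_len(k)]
    adj[i, nb] <- 1
  }
  adj <- methods::as(((adj + Matrix::t(adj)) > 0) * 1, "CsparseMatrix")
  diag(sim) <- 0
  scores <- adj * sim
  attr(adj, "scores") <- methods::as(scores, "CsparseMatrix")
  adj
}

#' Build the directed heterogeneous response graph
#'
#' Nodes are cell lines followed by drugs. Each labeled sensitive record
#' contributes one directed cell-to-drug edge in the `sensitive` relation
#' and each resistant record one in the `resistant` relation; the two
#' adjacencies are disjoint by construction. Inverse relations
#' (`sensitive_inv`, `resistant_inv`, drug-to-cell) are materialised as
#' separate relation names so both node types receive messages.
#' Uncorrelated records are excluded. Similarity relations can be attached
#' afterwards with [add_similarity_edges()].
#'
#' @param cells An [omics_profile_set()] or a character vector of cell ids.
#' @param drug_ids Character vector of drug ids.
#' @param labeled A data frame as returned by [label_responses()] (columns
#'   `cell_id`, `drug_id`, `label`).
#' @return An object of class `response_graph`: node registry, one sparse
#'   adjacency per relation, empty feature slot.
#' @export
build_response_graph <- function(cells, drug_ids, labeled) {
  cell_ids <- if (inherits(cells, "omics_profile_set")) cells$cell_ids else as.character(cells)
  drug_ids <- as.character(drug_ids)
  stopifnot(!anyDuplicated(cell_ids), !anyDuplicated(drug_ids),
            all(c("cell_id", "drug_id", "label") %in% names(labeled)))
  n_cell <- length(cell_ids)
  n_drug <- length(drug_ids)
  n <- n_cell + n_drug

  lab <- labeled[labeled$label != "uncorrelated", , drop = FALSE]
  ci <- match(lab$cell_id, cell_ids)
  di <- match(lab$drug_id, drug_ids)
  if (anyNA(ci)) {
    stop("unknown cell id(s): ",
         paste(unique(lab$cell_id[is.na(ci)]), collapse = ", "))
  }
  if (anyNA(di)) {
    stop("unknown drug id(s): ",
         paste(unique(lab$drug_id[is.na(di)]), collapse = ", "))
  }
  key <- paste(ci, di)
  if (anyDuplicated(key)) {
    conf <- unique(key[duplicated(key)])
    for (kk in conf) {
      labs <- unique(lab$label[key == kk])
      if (length(labs) > 1L) {
        rec <- lab[match(kk, key), ]
        stop("conflicting labels for pair (", rec$cell_id, ", ",
             rec$drug_id, ")")
      }
    }
    dup <- duplicated(key)
    lab <- lab[!dup, , drop = FALSE]; ci <- ci[!dup]; di <- di[!dup]
  }

  make_adj <- function(rows, cols) {
    Matrix::sparseMatrix(i = rows, j = cols, x = rep(1, length(rows)),
                         dims = c(n, n))
  }
  sens <- lab$label == "sensitive"
  relations <- list(
    sensitive = make_adj(ci[sens], n_cell + di[sens]),
    resistant = make_adj(ci[!sens], n_cell + di[!sens])
  )
  relations$sensitive_inv <- Matrix::t(relations$sensitive)
  relations$resistant_inv <- Matrix::t(relations$resistant)

  structure(
    list(
      node_ids = c(cell_ids, drug_ids),
      node_type = factor(rep(c("cell", "drug"), c(n_cell, n_drug)),
                         levels = c("cell", "drug")),
      n_cell = n_cell,
      n_drug = n_drug,
      relations = relations,
      sim_scores = list(),
      features = NULL
    ),
    class = "response_graph"
  )
}

#' Attach within-type similarity relations to a response graph
#'
#' Adds `cell_sim` (cosine over concatenated standardised omics) and/or
#' `drug_sim` (Tanimoto over hashed fingerprints) relations. Both connect
#' only nodes of their own type.
#'
#' @param graph A [build_response_graph()] result.
#' @param cell_features Numeric matrix, one row per cell node, or NULL.
#' @param drug_features Binary fingerprint matrix, one row per drug node,
#'   or NULL.
#' @param k Neighbours per node.
#' @return The graph with similarity relations and their scores attached.
#' @export
add_similarity_edges <- function(graph, cell_features = NULL,
                                 drug_features = NULL, k = 5L) {
  stopifnot(inherits(graph, "response_graph"))
  n <- length(graph$node_ids)
  embed <- function(adj, offset) {
    big <- Matrix::Matrix(0, n, n, sparse = TRUE)
    idx <- offset + seq_len(nrow(adj))
    big[idx, idx] <- adj
    methods::as(big, "CsparseMatrix")
  }
  if (!is.null(cell_features)) {
    stopifnot(nrow(cell_features) == graph$n_cell)
    adj <- compute_similarity_edges(cell_features, k = k, metric = "cosine")
    graph$relations$cell_sim <- embed(adj, 0L)
    graph$sim_scores$cell_sim <- embed(attr(adj, "scores"), 0L)
  }
  if (!is.null(drug_features)) {
    stopifnot(nrow(drug_features) == graph$n_drug)
    adj <- compute_similarity_edges(drug_features, k = k, metric = "tanimoto")
    graph$relations$drug_sim <- embed(adj, graph$n_cell)
    graph$sim_scores$drug_sim <- embed(attr(adj, "scores"), graph$n_cell)
  }
  graph
}

#' Set node attribute matrix on a response graph
#'
#' @param graph A `response_graph`.
#' @param features Numeric matrix with one row per node (cells first, then
#'   drugs).
#' @return The graph with `features` set.
#' @export
set_graph_features <- function(graph, features) {
  stopifnot(inherits(graph, "response_graph"),
            nrow(features) == length(graph$node_ids))
  graph$features <- as.matrix(features)
  graph
}

#' @export
print.response_graph <- function(x, ...) {
  cat("<response_graph> ", x$n_cell, " cells + ", x$n_drug, " drugs\n",
      sep = "")
  for (nm in names(x$relations)) {
    cat("  ", format(nm, width = 14), Matrix::nnzero(x$relations[[nm]]),
        "edges\n")
  }
  if (!is.null(x$features)) {
    cat("  features: ", nrow(x$features), " x ", ncol(x$features), "\n",
        sep = "")
  }
  invisible(x)
}

#' Export a response graph as an edge-list table
#'
#' @param graph A `response_graph`.
#' @param path Optional TSV path; if NULL the tibble is only returned.
#' @return A tibble with columns `src`, `dst`, `relation`.
#' @export
graph_edge_list <- function(graph, path = NULL) {
  rows <- purrr::map_dfr(names(graph$relations), function(nm) {
    tr <- .sparse_triplets(graph$relations[[nm]])
    if (nrow(tr) == 0L) return(tibble::tibble())
    tibble::tibble(src = graph$node_ids[tr$i], dst = graph$node_ids[tr$j],
                   relation = nm)
  })
  if (!is.null(path)) readr::write_tsv(rows, path)
  rows
}
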
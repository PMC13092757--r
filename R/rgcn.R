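# Relational graph convolution over the directed heterogeneous response
# graph: one weight matrix per relation plus a self-loop weight, messages
# flowing along edge direction, in-degree normalisation, ReLU. The final
# node embedding averages the retained per-layer hidden states.

#' Initialise RGCN parameters
#'
#' One `f_dim x f_dim` weight per relation per layer plus a per-layer
#' self-loop weight `W0`. No basis decomposition: with a handful of
#' relations the full parameterisation needs no extra regularisation.
#'
#' @param relations Character vector of relation names.
#' @param f_dim Embedding width.
#' @param layers Number of propagation layers (default 2).
#' @param seed Integer seed.
#' @return A list of class `rgcn_params`.
#' @export
init_rgcn_params <- function(relations, f_dim = 96L, layers = 2L, seed = 1L) {
  stopifnot(length(relations) >= 1L, layers >= 1L)
  sc <- sqrt(1 / f_dim)
  lyr <- vector("list", layers)
  for (l in seq_len(layers)) {
    w_rel <- list()
    for (r in relations) {
      w_rel[[r]] <- with_seed(derive_seed(seed, "rgcn", l, r),
                              matrix(stats::rnorm(f_dim^2), f_dim) * sc)
    }
    lyr[[l]] <- list(
      w_rel = w_rel,
      w0 = with_seed(derive_seed(seed, "rgcn0", l),
                     matrix(stats::rnorm(f_dim^2), f_dim) * sc)
    )
  }
  structure(list(layers = lyr, relations = relations, f_dim = f_dim,
                 n_layers = layers),
            class = "rgcn_params")
}

# per-relation incoming-message operators: row i of norm_adj[[r]] averages
# the states of i's in-neighbours under relation r (c_{i,r} = in-degree)
.rgcn_norm_adjs <- function(relations) {
  lapply(relations, function(a) {
    at <- Matrix::t(a)                       # rows = targets
    deg <- Matrix::rowSums(at)
    deg[deg == 0] <- 1
    methods::as(at / deg, "CsparseMatrix")
  })
}

# tape-level single layer
.rgcn_layer_t <- function(h, norm_adjs, layer_pn, activation = TRUE) {
  acc <- ad_mm(h, layer_pn$w0)
  for (r in names(norm_adjs)) {
    if (is.null(layer_pn$w_rel[[r]])) {
      stop("relation '", r, "' present in graph but absent from parameters")
    }
    acc <- ad_add(acc, ad_mm(ad_mm(norm_adjs[[r]], h), layer_pn$w_rel[[r]]))
  }
  if (activation) ad_relu(acc) else acc
}

#' One relational graph-convolution layer
#'
#' Computes `h_i' = relu( sum_r sum_{j in N_i^r} (1 / c_{i,r}) W_r h_j +
#' W0 h_i )`, where `N_i^r` are the in-neighbours of node `i` under
#' relation `r` and `c_{i,r}` is the in-degree.
#'
#' @param h_in Numeric matrix of node states (`n x f_dim`).
#' @param graph A `response_graph` (its relations define the messages).
#' @param layer_params One layer's parameters: a list with `w_rel` (named
#'   list of matrices) and `w0`, e.g. `init_rgcn_params(...)$layers[[1]]`.
#' @param activation Apply the ReLU (default TRUE).
#' @return Numeric matrix of updated node states.
#' @export
rgcn_layer <- function(h_in, graph, layer_params, activation = TRUE) {
  stopifnot(inherits(graph, "response_graph"))
  norm <- .rgcn_norm_adjs(graph$relations)
  ad_value(.rgcn_layer_t(h_in, norm, layer_params, activation))
}

# tape-level multi-layer embedding; returns the mean of per-layer states
.embed_graph_t <- function(x, norm_adjs, pn) {
  states <- vector("list", pn$n_layers)
  h <- x
  for (l in seq_len(pn$n_layers)) {
    h <- .rgcn_layer_t(h, norm_adjs, pn$layers[[l]])
    states[[l]] <- h
  }
  if (pn$n_layers == 1L) return(states[[1L]])
  acc <- states[[1L]]
  for (l in 2:pn$n_layers) acc <- ad_add(acc, states[[l]])
  ad_affine(acc, mult = 1 / pn$n_layers)
}

#' Embed a response graph with the RGCN
#'
#' Runs all layers on the graph's node attribute matrix `X = [C; D]` and
#' averages the retained per-layer hidden states into the final node
#' embedding matrix `H`.
#'
#' @param graph A `response_graph` with `features` set.
#' @param params An [init_rgcn_params()] result covering the graph's
#'   relations.
#' @return Numeric matrix `H` (`n_nodes x f_dim`), rows ordered as the
#'   graph's node registry.
#' @export
embed_graph <- function(graph, params) {
  stopifnot(inherits(graph, "response_graph"),
            inherits(params, "rgcn_params"))
  if (is.null(graph$features)) stop("graph has no feature matrix")
  norm <- .rgcn_norm_adjs(graph$relations)
  H <- ad_value(.embed_graph_t(graph$features, norm, params))
  rownames(H) <- graph$node_ids
  H
}
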
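# Joint optimisation components: shared multi-head graph attention over
# the (augmented) response graph, embedding fusion, the mean/variance
# anchored view-alignment loss, the focal classification loss, and the
# pair-scoring head.

#' Objective configuration
#'
#' @param omega1,omega2 Weights of the alignment-loss terms (mean match,
#'   standard-deviation anchor).
#' @param phi_target Target standard deviation for the anchor term (during
#'   training it is recomputed each epoch from the original-graph
#'   embeddings; see [phi_anchor()]).
#' @param focal_alpha Focal-loss multiplier `alpha_t` in `(0, 1]`.
#' @param focal_gamma Focal-loss exponent `gamma >= 0` (down-weights easy
#'   samples).
#' @return A list of class `objective_config`.
#' @export
objective_config <- function(omega1 = 1, omega2 = 1, phi_target = 1,
                             focal_alpha = 0.25, focal_gamma = 2) {
  stopifnot(omega1 >= 0, omega2 >= 0, focal_gamma >= 0,
            focal_alpha > 0, focal_alpha <= 1)
  structure(list(omega1 = omega1, omega2 = omega2, phi_target = phi_target,
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma),
            class = "objective_config")
}

#' Initialise graph-attention parameters
#'
#' One hidden layer whose `heads` outputs (width `f_dim / heads`) are
#' concatenated, then an output layer whose `heads` outputs (width
#' `f_dim`) are averaged. Parameters are shared between the original graph
#' and both augmented views.
#'
#' @param f_dim Embedding width (divisible by `heads`).
#' @param heads Number of attention heads K (default 3).
#' @param seed Integer seed.
#' @param leaky_slope Negative slope of the LeakyReLU on attention logits.
#' @return A list of class `gat_params`.
#' @export
init_gat_params <- function(f_dim = 96L, heads = 3L, seed = 1L,
                            leaky_slope = 0.2) {
  stopifnot(f_dim %% heads == 0L)
  hw <- f_dim %/% heads
  mk_head <- function(din, dout, sd_seed) {
    with_seed(sd_seed, list(
      w = matrix(stats::rnorm(din * dout), din) * sqrt(2 / din),
      a_dst = matrix(stats::rnorm(dout), dout) * sqrt(1 / dout),
      a_src = matrix(stats::rnorm(dout), dout) * sqrt(1 / dout)
    ))
  }
  structure(list(
    hidden = lapply(seq_len(heads), function(k) {
      mk_head(f_dim, hw, derive_seed(seed, "gat_h", k))
    }),
    output = lapply(seq_len(heads), function(k) {
      mk_head(f_dim, f_dim, derive_seed(seed, "gat_o", k))
    }),
    heads = heads, f_dim = f_dim, leaky_slope = leaky_slope
  ), class = "gat_params")
}

# directed edge list (src -> dst) of the union of a graph's relations,
# with self-loops added so isolated nodes stay defined
.gat_edges <- function(relations, n) {
  acc <- Matrix::Matrix(0, n, n, sparse = TRUE)
  for (a in relations) acc <- acc + a
  acc <- acc + Matrix::Diagonal(n)
  # symmetric unions get auto-promoted to symmetric storage, whose
  # triplet summary covers one triangle only; force general storage
  tr <- .sparse_triplets(acc)
  src <- tr$i; dst <- tr$j
  agg <- Matrix::sparseMatrix(i = dst, j = seq_along(dst),
                              x = rep(1, length(dst)),
                              dims = c(n, length(dst)))
  # per-destination edge index groups, shared by all attention heads for
  # the numerically stabilising segment-max shift
  sidx <- split(seq_along(dst), dst)
  list(src = src, dst = dst, agg = agg, n = n, sidx = sidx)
}

# one attention head on the tape: softmax over each node's in-neighbour
# set (self included) of LeakyReLU(a_dst . W t_i + a_src . W t_j)
.gat_head_t <- function(t_in, ed, head_pn, slope) {
  z <- ad_mm(t_in, head_pn$w)
  e_dst <- ad_mm(z, head_pn$a_dst)
  e_src <- ad_mm(z, head_pn$a_src)
  e <- ad_leaky_relu(ad_add(ad_rows(e_dst, ed$dst), ad_rows(e_src, ed$src)),
                     slope)
  # per-destination max shift: constant w.r.t. the tape (softmax is
  # shift-invariant, so the gradient is exact)
  ev <- as.vector(ad_value(e))
  shift_edge <- numeric(length(ev))
  for (ix in ed$sidx) shift_edge[ix] <- max(ev[ix])
  ex <- ad_exp(ad_affine(e, add = -shift_edge))
  denom <- ad_mm(ed$agg, ex)
  alpha <- ad_div(ex, ad_rows(denom, ed$dst))
  ad_mm(ed$agg, ad_mul_colvec(ad_rows(z, ed$src), alpha))
}

# full GAT forward: hidden layer concatenates ReLU'd heads, output layer
# averages heads then applies the activation
.gat_forward_t <- function(t_in, ed, pn) {
  hid <- lapply(pn$hidden, function(hp) {
    ad_relu(.gat_head_t(t_in, ed, hp, pn$leaky_slope))
  })
  h <- if (length(hid) == 1L) hid[[1L]] else do.call(ad_cbind, hid)
  outs <- lapply(pn$output, function(hp) .gat_head_t(h, ed, hp, pn$leaky_slope))
  acc <- outs[[1L]]
  if (length(outs) > 1L) for (k in 2:length(outs)) acc <- ad_add(acc, outs[[k]])
  ad_relu(ad_affine(acc, mult = 1 / length(outs)))
}

#' Encode node features with the multi-head graph attention network
#'
#' Attention weights are a softmax over each node's in-neighbour set plus
#' itself; hidden-layer head outputs are concatenated, output-layer head
#' outputs averaged.
#'
#' @param features Node feature matrix (`n x f_dim`).
#' @param adjacency A single (sparse) adjacency, or a list of relation
#'   adjacencies whose union defines the neighbourhoods.
#' @param params An [init_gat_params()] result.
#' @return Numeric matrix `T` (`n x f_dim`).
#' @export
gat_encode <- function(features, adjacency, params) {
  stopifnot(inherits(params, "gat_params"))
  rel <- if (is.list(adjacency)) adjacency else list(adjacency)
  rel <- lapply(rel, function(a) methods::as(Matrix::Matrix(a, sparse = TRUE),
                                             "CsparseMatrix"))
  ed <- .gat_edges(rel, nrow(features))
  pn <- .wrap_params(params, wrap = FALSE)
  ad_value(.gat_forward_t(features, ed, pn))
}

#' Fuse attention and relational embeddings
#'
#' Per node, the fused representation is the elementwise product of the
#' attention output `T` and the RGCN embedding `H`; when `T` holds one
#' matrix per augmented view the products are mean-pooled across views.
#'
#' @param T_mat Attention embedding matrix, or a list of them (one per
#'   view).
#' @param H RGCN embedding matrix of matching shape.
#' @return Numeric fused matrix `X`.
#' @export
fuse_embeddings <- function(T_mat, H) {
  H <- as.matrix(H)
  mats <- if (is.list(T_mat)) T_mat else list(T_mat)
  for (m in mats) {
    if (!all(dim(m) == dim(H))) stop("T and H must have identical shape")
  }
  Reduce(`+`, lapply(mats, function(m) m * H)) / length(mats)
}

.fuse_t <- function(t_list, h) {
  prods <- lapply(t_list, function(tt) ad_mul(tt, h))
  acc <- prods[[1L]]
  if (length(prods) > 1L) {
    for (k in 2:length(prods)) acc <- ad_add(acc, prods[[k]])
  }
  ad_affine(acc, mult = 1 / length(prods))
}

#' Standard-deviation anchor of an embedding matrix
#'
#' The anchor `phi` is the average per-dimension standard deviation of
#' the cell-line and drug embeddings of the original (unaugmented) graph,
#' recomputed once per epoch and treated as a constant (no gradient flows
#' into it).
#'
#' @param x Embedding matrix.
#' @param n_cell Number of leading rows that are cell lines; if NULL the
#'   matrix is treated as one block.
#' @return A single number.
#' @export
phi_anchor <- function(x, n_cell = NULL) {
  if (is.null(n_cell) || n_cell <= 0L || n_cell >= nrow(x)) {
    return(mean(apply(x, 2L, stats::sd)))
  }
  mean(c(apply(x[seq_len(n_cell), , drop = FALSE], 2L, stats::sd),
         apply(x[-seq_len(n_cell), , drop = FALSE], 2L, stats::sd)))
}

# per-dimension sample standard deviations on the tape (1 x F node)
.col_sd_t <- function(x) {
  n <- nrow(ad_value(x))
  ones <- matrix(1 / n, 1L, n)
  mu <- ad_mm(ones, x)
  cen <- ad_sub_rowvec(x, mu)
  ss <- ad_affine(ad_mm(matrix(1, 1L, n), ad_pow(cen, 2)),
                  mult = 1 / max(n - 1L, 1L))
  ad_pow(ad_affine(ss, add = 1e-12), 0.5)
}

.alignment_loss_t <- function(x1, x2, omega1, omega2, phi) {
  d <- ad_sub(x1, x2)
  fdim <- ncol(ad_value(x1))
  rn <- ad_pow(ad_affine(ad_mm(ad_pow(d, 2), matrix(1, fdim, 1L)),
                         add = 1e-12), 0.5)
  term1 <- ad_mean(rn)
  s1 <- .col_sd_t(x1); s2 <- .col_sd_t(x2)
  term2 <- ad_add(ad_sum(ad_pow(ad_affine(s1, add = -phi), 2)),
                  ad_sum(ad_pow(ad_affine(s2, add = -phi), 2)))
  ad_add(ad_affine(term1, mult = omega1), ad_affine(term2, mult = omega2))
}

#' Alignment loss between two augmented-view embeddings
#'
#' `omega1 * mean_i ||X1_i - X2_i|| + omega2 * sum_d ((s1_d - phi)^2 +
#' (s2_d - phi)^2)`, where `s1`, `s2` are per-dimension sample standard
#' deviations. The first term pulls the two views' embeddings of each node
#' together; the second anchors their spread at `phi` so the aligned
#' embeddings cannot collapse.
#'
#' @param x1,x2 Embedding matrices of identical shape (matched rows).
#' @param config An [objective_config()] (uses `omega1`, `omega2`,
#'   `phi_target`).
#' @return A single number.
#' @export
alignment_loss <- function(x1, x2, config = objective_config()) {
  stopifnot(all(dim(x1) == dim(x2)), config$phi_target > 0)
  as.numeric(ad_value(.alignment_loss_t(as.matrix(x1), as.matrix(x2),
                                        config$omega1, config$omega2,
                                        config$phi_target)))
}

.focal_loss_t <- function(p, y, alpha_t, gamma) {
  y <- as.numeric(y)
  pt <- ad_add(ad_mul(p, matrix(y, ncol = 1L)),
               ad_mul(ad_affine(p, mult = -1, add = 1),
                      matrix(1 - y, ncol = 1L)))
  pt <- ad_clamp(pt, 1e-7, 1 - 1e-7)
  w <- ad_pow(ad_affine(pt, mult = -1, add = 1), gamma)
  ad_affine(ad_mean(ad_mul(w, ad_log(pt))), mult = -alpha_t)
}

#' Focal loss for imbalanced binary classification
#'
#' Mean over samples of `-alpha_t * (1 - p_t)^gamma * log(p_t)` with
#' `p_t = p` for positives and `1 - p` for negatives. With `gamma = 0` and
#' `alpha_t = 1` this is exactly binary cross-entropy; larger `gamma`
#' down-weights well-classified samples so the rare sensitive class is
#' not drowned out.
#'
#' @param p Predicted probabilities in `(0, 1)`.
#' @param y Binary labels (1 = sensitive).
#' @param alpha_t Multiplier in `(0, 1]` (default 0.25).
#' @param gamma Focusing exponent (default 2).
#' @return A single number.
#' @export
focal_loss <- function(p, y, alpha_t = 0.25, gamma = 2) {
  stopifnot(length(p) == length(y), all(y %in% c(0, 1)), gamma >= 0,
            alpha_t > 0, alpha_t <= 1)
  if (any(p <= 0 | p >= 1)) {
    warning("probabilities at 0/1 clamped to [1e-7, 1 - 1e-7]")
  }
  as.numeric(ad_value(.focal_loss_t(matrix(p, ncol = 1L), y, alpha_t, gamma)))
}

#' Combine alignment and classification losses
#'
#' @param l1 Alignment-loss value.
#' @param l2 Focal-loss value.
#' @return Their sum.
#' @export
total_loss <- function(l1, l2) {
  if (!is.finite(l1)) stop("alignment loss (L1) is not finite")
  if (!is.finite(l2)) stop("classification loss (L2) is not finite")
  l1 + l2
}

#' Initialise the pair-scoring head
#'
#' A two-hidden-layer MLP on the concatenated fused embeddings of the cell
#' and the drug, with a sigmoid output.
#'
#' @param f_dim Embedding width.
#' @param hidden Widths of the two hidden layers.
#' @param seed Integer seed.
#' @return A list of class `scorer_params`.
#' @export
init_scorer_params <- function(f_dim = 96L, hidden = c(64L, 32L), seed = 1L) {
  stopifnot(length(hidden) == 2L)
  d0 <- 2L * f_dim
  with_seed(derive_seed(seed, "scorer"), structure(list(
    w1 = matrix(stats::rnorm(d0 * hidden[1L]), d0) * sqrt(2 / d0),
    b1 = matrix(0, 1L, hidden[1L]),
    w2 = matrix(stats::rnorm(hidden[1L] * hidden[2L]), hidden[1L]) *
      sqrt(2 / hidden[1L]),
    b2 = matrix(0, 1L, hidden[2L]),
    w3 = matrix(stats::rnorm(hidden[2L]), hidden[2L]) * sqrt(2 / hidden[2L]),
    b3 = matrix(0, 1L, 1L)
  ), class = "scorer_params"))
}

.score_pairs_t <- function(x, cell_idx, drug_idx, pn) {
  h0 <- ad_cbind(ad_rows(x, cell_idx), ad_rows(x, drug_idx))
  h1 <- ad_relu(ad_add_rowvec(ad_mm(h0, pn$w1), pn$b1))
  h2 <- ad_relu(ad_add_rowvec(ad_mm(h1, pn$w2), pn$b2))
  ad_sigmoid(ad_add_rowvec(ad_mm(h2, pn$w3), pn$b3))
}

#' Score cell-drug pairs from fused embeddings
#'
#' @param x Fused embedding matrix with node row names.
#' @param pairs Two-column matrix/data frame of (cell, drug) node indices,
#'   or node names matched against `rownames(x)`.
#' @param params An [init_scorer_params()] result.
#' @return Numeric vector of sensitivity probabilities in `(0, 1)`.
#' @export
score_pairs <- function(x, pairs, params) {
  stopifnot(inherits(params, "scorer_params"))
  pairs <- as.data.frame(pairs)
  resolve <- function(v) {
    if (is.numeric(v)) return(as.integer(v))
    idx <- match(as.character(v), rownames(x))
    if (anyNA(idx)) {
      stop("unknown node id(s): ",
           paste(unique(v[is.na(idx)]), collapse = ", "))
    }
    idx
  }
  ci <- resolve(pairs[[1L]]); di <- resolve(pairs[[2L]])
  if (any(ci < 1L | ci > nrow(x)) || any(di < 1L | di > nrow(x))) {
    stop("pair index out of range")
  }
  pn <- .wrap_params(params, wrap = FALSE)
  as.vector(ad_value(.score_pairs_t(as.matrix(x), ci, di, pn)))
}
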
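# Minimal tape-based reverse-mode automatic differentiation on matrices.
#
# Every differentiable computation in the model (omics encoder, drug GCN,
# RGCN, GAT, losses) is expressed in these primitives. Nodes are
# environments carrying a value `v`, an accumulated gradient `g`, parent
# references `pa`, and a backward closure `bw`. Constants (plain numerics,
# matrices, sparse Matrix objects) can be passed wherever a node is
# accepted; they receive no gradient. Graph order is tracked by a global
# creation counter so backpropagation can run in reverse topological order.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0

ad_is_node <- function(x) inherits(x, "ad_node")

.ad_new <- function(v, pa = list(), bw = NULL, leaf = FALSE) {
  # force both promises before taking an id: nested op calls must create
  # their (parent) nodes first so ids are topologically ordered
  force(v); force(pa)
  n <- new.env(parent = emptyenv())
  .ad$counter <- .ad$counter + 1
  n$id <- .ad$counter
  n$v <- v
  n$g <- NULL
  n$pa <- pa
  n$bw <- bw
  n$leaf <- leaf
  class(n) <- "ad_node"
  n
}

.ad_mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = if (length(x) == 1L) 1L else length(x))
}

#' @noRd
ad_param <- function(x) .ad_new(.ad_mat(x), leaf = TRUE)

#' @noRd
ad_const <- function(x) .ad_new(.ad_mat(x))

ad_value <- function(x) if (ad_is_node(x)) x$v else x

.ad_accum <- function(node, g) {
  if (!ad_is_node(node)) return(invisible(NULL))
  if (!is.matrix(g)) g <- as.matrix(g)
  node$g <- if (is.null(node$g)) g else node$g + g
  invisible(NULL)
}

# ---- primitive operations ---------------------------------------------------

ad_mm <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  out <- .ad_new(as.matrix(va %*% vb), pa = list(a, b)[c(ad_is_node(a), ad_is_node(b))])
  out$bw <- function() {
    g <- out$g
    if (ad_is_node(a)) {
      .ad_accum(a, if (is.matrix(vb)) tcrossprod(g, vb) else g %*% Matrix::t(vb))
    }
    if (ad_is_node(b)) {
      .ad_accum(b, if (is.matrix(va)) crossprod(va, g) else Matrix::crossprod(va, g))
    }
  }
  out
}

ad_add <- function(a, b) {
  out <- .ad_new(ad_value(a) + ad_value(b), pa = list(a, b)[c(ad_is_node(a), ad_is_node(b))])
  out$bw <- function() {
    .ad_accum(a, out$g); .ad_accum(b, out$g)
  }
  out
}

ad_sub <- function(a, b) {
  out <- .ad_new(ad_value(a) - ad_value(b), pa = list(a, b)[c(ad_is_node(a), ad_is_node(b))])
  out$bw <- function() {
    .ad_accum(a, out$g); .ad_accum(b, -out$g)
  }
  out
}

ad_mul <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  out <- .ad_new(va * vb, pa = list(a, b)[c(ad_is_node(a), ad_is_node(b))])
  out$bw <- function() {
    g <- out$g
    if (ad_is_node(a)) .ad_accum(a, if (length(vb) == 1L) g * as.numeric(vb) else g * vb)
    if (ad_is_node(b)) {
      gb <- if (length(vb) == 1L) sum(g * va) else g * va
      .ad_accum(b, gb)
    }
  }
  out
}

ad_div <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  out <- .ad_new(va / vb, pa = list(a, b)[c(ad_is_node(a), ad_is_node(b))])
  out$bw <- function() {
    g <- out$g
    if (ad_is_node(a)) .ad_accum(a, g / vb)
    if (ad_is_node(b)) .ad_accum(b, -g * va / vb^2)
  }
  out
}

# a (n x m) plus a 1 x m row vector broadcast down rows (bias addition)
ad_add_rowvec <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  val <- va + matrix(vb, nrow(va), ncol(va), byrow = TRUE)
  out <- .ad_new(val, pa = list(a, b)[c(ad_is_node(a), ad_is_node(b))])
  out$bw <- function() {
    g <- out$g
    if (ad_is_node(a)) .ad_accum(a, g)
    if (ad_is_node(b)) .ad_accum(b, matrix(colSums(g), 1L))
  }
  out
}

ad_sub_rowvec <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  val <- va - matrix(vb, nrow(va), ncol(va), byrow = TRUE)
  out <- .ad_new(val, pa = list(a, b)[c(ad_is_node(a), ad_is_node(b))])
  out$bw <- function() {
    g <- out$g
    if (ad_is_node(a)) .ad_accum(a, g)
    if (ad_is_node(b)) .ad_accum(b, matrix(-colSums(g), 1L))
  }
  out
}

# multiply every row i of a (n x m) by scalar v[i] taken from an n x 1 column
ad_mul_colvec <- function(a, v) {
  va <- ad_value(a); vv <- as.vector(ad_value(v))
  out <- .ad_new(va * vv, pa = list(a, v)[c(ad_is_node(a), ad_is_node(v))])
  out$bw <- function() {
    g <- out$g
    if (ad_is_node(a)) .ad_accum(a, g * vv)
    if (ad_is_node(v)) .ad_accum(v, matrix(rowSums(g * va), ncol = 1L))
  }
  out
}

# elementwise constant affine map mult * a + add (mult/add scalar or conformable)
ad_affine <- function(a, mult = 1, add = 0) {
  va <- ad_value(a)
  out <- .ad_new(va * mult + add, pa = list(a)[ad_is_node(a)])
  out$bw <- function() .ad_accum(a, out$g * mult)
  out
}

ad_relu <- function(a) {
  va <- ad_value(a)
  out <- .ad_new(pmax(va, 0), pa = list(a)[ad_is_node(a)])
  out$bw <- function() .ad_accum(a, out$g * (va > 0))
  out
}

ad_leaky_relu <- function(a, slope = 0.2) {
  va <- ad_value(a)
  pos <- va > 0
  out <- .ad_new(va * pos + slope * va * !pos, pa = list(a)[ad_is_node(a)])
  out$bw <- function() .ad_accum(a, out$g * (pos + slope * !pos))
  out
}

ad_sigmoid <- function(a) {
  va <- ad_value(a)
  s <- 1 / (1 + exp(-va))
  out <- .ad_new(s, pa = list(a)[ad_is_node(a)])
  out$bw <- function() .ad_accum(a, out$g * s * (1 - s))
  out
}

ad_exp <- function(a) {
  e <- exp(ad_value(a))
  out <- .ad_new(e, pa = list(a)[ad_is_node(a)])
  out$bw <- function() .ad_accum(a, out$g * e)
  out
}

ad_log <- function(a) {
  va <- ad_value(a)
  out <- .ad_new(log(va), pa = list(a)[ad_is_node(a)])
  out$bw <- function() .ad_accum(a, out$g / va)
  out
}

# power with a constant exponent; base assumed positive for non-integer p
ad_pow <- function(a, p) {
  va <- ad_value(a)
  out <- .ad_new(va^p, pa = list(a)[ad_is_node(a)])
  out$bw <- function() .ad_accum(a, out$g * p * va^(p - 1))
  out
}

ad_clamp <- function(a, lo, hi) {
  va <- ad_value(a)
  out <- .ad_new(pmin(pmax(va, lo), hi), pa = list(a)[ad_is_node(a)])
  out$bw <- function() .ad_accum(a, out$g * (va > lo & va < hi))
  out
}

ad_rows <- function(a, idx) {
  va <- ad_value(a)
  out <- .ad_new(va[idx, , drop = FALSE], pa = list(a)[ad_is_node(a)])
  out$bw <- function() {
    rs <- rowsum(out$g, group = idx)
    gr <- matrix(0, nrow(va), ncol(va))
    gr[as.integer(rownames(rs)), ] <- rs
    .ad_accum(a, gr)
  }
  out
}

ad_cols <- function(a, idx) {
  va <- ad_value(a)
  out <- .ad_new(va[, idx, drop = FALSE], pa = list(a)[ad_is_node(a)])
  out$bw <- function() {
    rs <- rowsum(t(out$g), group = idx)
    gc <- matrix(0, nrow(va), ncol(va))
    gc[, as.integer(rownames(rs))] <- t(rs)
    .ad_accum(a, gc)
  }
  out
}

# column-major reshape (same semantics as matrix(x, nr, nc))
ad_reshape <- function(a, nr, nc) {
  va <- ad_value(a)
  stopifnot(length(va) == nr * nc)
  out <- .ad_new(matrix(va, nr, nc), pa = list(a)[ad_is_node(a)])
  out$bw <- function() .ad_accum(a, matrix(out$g, nrow(va), ncol(va)))
  out
}

ad_cbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, ad_value)
  widths <- vapply(vals, ncol, 1L)
  out <- .ad_new(do.call(cbind, vals), pa = args[vapply(args, ad_is_node, TRUE)])
  out$bw <- function() {
    off <- 0L
    for (i in seq_along(args)) {
      if (ad_is_node(args[[i]])) {
        .ad_accum(args[[i]], out$g[, off + seq_len(widths[i]), drop = FALSE])
      }
      off <- off + widths[i]
    }
  }
  out
}

ad_rbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, ad_value)
  heights <- vapply(vals, nrow, 1L)
  out <- .ad_new(do.call(rbind, vals), pa = args[vapply(args, ad_is_node, TRUE)])
  out$bw <- function() {
    off <- 0L
    for (i in seq_along(args)) {
      if (ad_is_node(args[[i]])) {
        .ad_accum(args[[i]], out$g[off + seq_len(heights[i]), , drop = FALSE])
      }
      off <- off + heights[i]
    }
  }
  out
}

ad_sum <- function(a) {
  va <- ad_value(a)
  out <- .ad_new(matrix(sum(va), 1L, 1L), pa = list(a)[ad_is_node(a)])
  out$bw <- function() .ad_accum(a, matrix(out$g[1L], nrow(va), ncol(va)))
  out
}

ad_mean <- function(a) {
  va <- ad_value(a)
  out <- .ad_new(matrix(mean(va), 1L, 1L), pa = list(a)[ad_is_node(a)])
  out$bw <- function() .ad_accum(a, matrix(out$g[1L] / length(va), nrow(va), ncol(va)))
  out
}

# ---- backward pass ----------------------------------------------------------

#' @noRd
ad_backward <- function(out) {
  out$g <- matrix(1, nrow(out$v), ncol(out$v))
  # collect reachable nodes (iterative DFS), then replay in reverse id order
  seen <- new.env(parent = emptyenv())
  nodes <- vector("list", 256L)
  n_nodes <- 0L
  stack <- list(out)
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    n_nodes <- n_nodes + 1L
    if (n_nodes > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[n_nodes]] <- nd
    for (p in nd$pa) if (ad_is_node(p)) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(n_nodes)]
  ord <- order(vapply(nodes, function(n) n$id, 0), decreasing = TRUE)
  for (nd in nodes[ord]) {
    if (!is.null(nd$bw) && !is.null(nd$g)) nd$bw()
  }
  invisible(NULL)
}

#' @noRd
ad_zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2
  opt$eps <- eps; opt$wd <- weight_decay; opt$t <- 0
  opt$m <- lapply(params, function(p) p$v * 0)
  opt$s <- lapply(params, function(p) p$v * 0)
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$g)) next
    g <- p$g + opt$wd * p$v
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$s[[i]] <- opt$beta2 * opt$s[[i]] + (1 - opt$beta2) * g^2
    p$v <- p$v - opt$lr * (opt$m[[i]] / bc1) / (sqrt(opt$s[[i]] / bc2) + opt$eps)
    p$g <- NULL
  }
  invisible(NULL)
}
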
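# Multi-omics cell-line encoder: one small 1-D convolutional transform per
# omics view, concatenated into a single F-dimensional representation per
# cell line. Disabled views contribute a fixed-width zero block so the
# downstream dimensionality is stable across ablations.

#' Omics encoder configuration
#'
#' @param f_dim Total embedding width F (must be divisible by the number
#'   of views; default 96).
#' @param conv_channels Channels of the per-view 1-D convolution.
#' @param kernel Convolution kernel width.
#' @param stride Convolution stride.
#' @param pool Adaptive average-pooling output length.
#' @return A list of class `omics_encoder_config`.
#' @export
omics_encoder_config <- function(f_dim = 96L, conv_channels = 8L,
                                 kernel = 7L, stride = 2L, pool = 16L) {
  structure(list(f_dim = as.integer(f_dim),
                 conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 pool = as.integer(pool)),
            class = "omics_encoder_config")
}

#' Initialise omics encoder parameters
#'
#' Per view: 1-D convolution (1 -> `conv_channels` channels) -> ReLU ->
#' adaptive average pooling -> linear head to `f_dim / n_views`.
#'
#' @param view_dims Named integer vector of per-view feature counts.
#' @param config An [omics_encoder_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A list of class `omics_encoder_params` (plain matrices).
#' @export
init_omics_params <- function(view_dims, config = omics_encoder_config(),
                              seed = 1L) {
  nv <- length(view_dims)
  stopifnot(nv >= 1L, config$f_dim %% nv == 0L)
  if (any(view_dims < config$kernel)) {
    stop("every view needs at least `kernel` (", config$kernel,
         ") features; too narrow: ",
         paste(names(view_dims)[view_dims < config$kernel], collapse = ", "))
  }
  f_out <- config$f_dim %/% nv
  per_view <- list()
  for (vi in seq_along(view_dims)) {
    nm <- names(view_dims)[vi]
    lin_in <- config$pool * config$conv_channels
    per_view[[nm]] <- with_seed(derive_seed(seed, "omics", vi), list(
      w_conv = matrix(stats::rnorm(config$kernel * config$conv_channels),
                      config$kernel) * sqrt(2 / config$kernel),
      b_conv = matrix(0, 1L, config$conv_channels),
      w_lin = matrix(stats::rnorm(lin_in * f_out), lin_in) * sqrt(2 / lin_in),
      b_lin = matrix(0, 1L, f_out)
    ))
  }
  structure(list(view = per_view, view_dims = view_dims, f_out = f_out,
                 config = config),
            class = "omics_encoder_params")
}

# constant helper matrices for one view: patch-extraction column index and
# the channel-blocked adaptive pooling operator
.conv_plan <- function(len, config) {
  k <- config$kernel; s <- config$stride
  l_out <- (len - k) %/% s + 1L
  starts <- (seq_len(l_out) - 1L) * s + 1L
  idx <- as.vector(outer(starts, 0:(k - 1L), "+"))  # k-major column order
  pm <- .adaptive_pool_matrix(l_out, config$pool)
  bd <- kronecker(Matrix::Diagonal(config$conv_channels), pm)
  list(l_out = l_out, idx = idx, pool_op = bd)
}

# (l_in x p) averaging operator: window p covers floor/ceil fractional
# bounds, as in adaptive average pooling
.adaptive_pool_matrix <- function(l_in, p) {
  m <- matrix(0, l_in, p)
  for (j in seq_len(p)) {
    lo <- floor((j - 1) * l_in / p) + 1L
    hi <- max(lo, ceiling(j * l_in / p))
    m[lo:hi, j] <- 1 / (hi - lo + 1L)
  }
  Matrix::Matrix(m, sparse = TRUE)
}

# tape-level forward: views = named list of matrices/nodes (n x p_view)
.encode_cells_t <- function(views, pn, enabled_views = names(pn$view)) {
  cfg <- pn$config
  nms <- names(pn$view)
  stopifnot(length(enabled_views) >= 1L)
  n <- nrow(ad_value(views[[1L]]))
  blocks <- vector("list", length(nms))
  for (vi in seq_along(nms)) {
    nm <- nms[vi]
    if (!(nm %in% enabled_views)) {
      blocks[[vi]] <- matrix(0, n, pn$f_out)
      next
    }
    v <- views[[nm]]
    if (is.null(v)) stop("view '", nm, "' missing from input")
    len <- ncol(ad_value(v))
    if (len != pn$view_dims[[nm]]) {
      stop("view '", nm, "' has ", len, " columns but params expect ",
           pn$view_dims[[nm]])
    }
    plan <- .conv_plan(len, cfg)
    pv <- pn$view[[nm]]
    patches <- ad_reshape(ad_cols(v, plan$idx), n * plan$l_out, cfg$kernel)
    conv <- ad_relu(ad_add_rowvec(ad_mm(patches, pv$w_conv), pv$b_conv))
    wide <- ad_reshape(conv, n, plan$l_out * cfg$conv_channels)
    pooled <- ad_mm(wide, plan$pool_op)
    blocks[[vi]] <- ad_add_rowvec(ad_mm(pooled, pv$w_lin), pv$b_lin)
  }
  do.call(ad_cbind, blocks)
}

#' Encode cell lines from their omics views
#'
#' Applies the per-view convolutional transforms and concatenates the six
#' blocks in the fixed view order of `params`; disabled views contribute
#' zero blocks of unchanged width.
#'
#' @param omics An [omics_profile_set()] (views already imputed/scaled).
#' @param params An [init_omics_params()] result.
#' @param enabled_views Character subset of view names to use.
#' @return Numeric matrix `C` (`n_c x f_dim`), row names = cell ids.
#' @export
encode_cells <- function(omics, params,
                         enabled_views = names(params$view)) {
  stopifnot(inherits(omics, "omics_profile_set"),
            inherits(params, "omics_encoder_params"))
  pn <- .wrap_params(params, wrap = FALSE)
  C <- ad_value(.encode_cells_t(omics$views, pn, enabled_views))
  rownames(C) <- omics$cell_ids
  C
}

#' Drop omics views from a model configuration
#'
#' Returns a configuration in which the dropped views contribute zero
#' blocks (the single- and multi-omics ablation sweeps); at least one view
#' must remain.
#'
#' @param config A [model_config()].
#' @param drop Character vector of view names to disable.
#' @return The modified configuration.
#' @export
ablate_views <- function(config, drop = character(0)) {
  if (length(drop) == 0L) return(config)
  unknown <- setdiff(drop, config$enabled_views)
  if (length(unknown) > 0L) {
    stop("unknown or already-disabled view(s): ",
         paste(unknown, collapse = ", "))
  }
  keep <- setdiff(config$enabled_views, drop)
  if (length(keep) == 0L) stop("cannot drop all omics views")
  config$enabled_views <- keep
  config
}

# recursively convert every numeric matrix in a params list into autodiff
# leaves (wrap = TRUE) or leave as constants (wrap = FALSE); returns the
# same structure with matrices replaced
.wrap_params <- function(x, wrap = TRUE) {
  wrap_one <- function(el) {
    if (is.matrix(el)) {
      if (wrap) ad_param(el) else el
    } else if (is.list(el)) {
      lapply(el, wrap_one)
    } else {
      el
    }
  }
  out <- lapply(unclass(x), wrap_one)
  out
}

# flatten all ad_param leaves of a wrapped params structure into one list
.collect_params <- function(x) {
  out <- list()
  rec <- function(el) {
    if (ad_is_node(el)) {
      out[[length(out) + 1L]] <<- el
    } else if (is.list(el)) {
      lapply(el, rec)
    }
    invisible(NULL)
  }
  rec(x)
  out
}

# read current values back out of a wrapped params structure
.unwrap_params <- function(x) {
  un <- function(el) {
    if (ad_is_node(el)) el$v
    else if (is.list(el)) lapply(el, un)
    else el
  }
  lapply(x, un)
}
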
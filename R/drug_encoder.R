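# Drug structure encoder: two graph-convolution layers over atom nodes
# (symmetric-normalised adjacency with self-loops) followed by a
# permutation-invariant mean readout and a linear head to width F.
# All drugs are encoded in one batch via a block-diagonal adjacency.

#' Drug encoder configuration
#'
#' @param f_dim Output embedding width (shared with the omics encoder).
#' @param hidden Hidden width of the two graph-convolution layers.
#' @return A list of class `drug_encoder_config`.
#' @export
drug_encoder_config <- function(f_dim = 96L, hidden = 64L) {
  structure(list(f_dim = as.integer(f_dim), hidden = as.integer(hidden)),
            class = "drug_encoder_config")
}

#' Initialise drug encoder parameters
#'
#' @param config A [drug_encoder_config()].
#' @param seed Integer seed.
#' @param atom_width Atom feature width (fixed by the featurisation).
#' @return A list of class `drug_encoder_params`.
#' @export
init_drug_params <- function(config = drug_encoder_config(), seed = 1L,
                             atom_width = atom_feature_width()) {
  h <- config$hidden
  with_seed(derive_seed(seed, "drug_enc"), structure(list(
    w1 = matrix(stats::rnorm(atom_width * h), atom_width) * sqrt(2 / atom_width),
    b1 = matrix(0, 1L, h),
    w2 = matrix(stats::rnorm(h * h), h) * sqrt(2 / h),
    b2 = matrix(0, 1L, h),
    w_out = matrix(stats::rnorm(h * config$f_dim), h) * sqrt(2 / h),
    b_out = matrix(0, 1L, config$f_dim),
    atom_width = atom_width,
    config = config
  ), class = "drug_encoder_params"))
}

# stack molecular graphs into one batch: block-diagonal normalised
# adjacency (self-loops, D^-1/2 (A+I) D^-1/2) and a mean-readout operator
.drug_batch <- function(graphs) {
  sizes <- vapply(graphs, function(g) g$n_atoms, 1L)
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  total <- sum(sizes)
  X <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  ri <- integer(0); rj <- integer(0); rx <- numeric(0)
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    a <- g$adjacency + diag(g$n_atoms)
    dg <- 1 / sqrt(rowSums(a))
    ah <- a * outer(dg, dg)
    nz <- which(ah != 0, arr.ind = TRUE)
    ii <- c(ii, offsets[gi] + nz[, 1L])
    jj <- c(jj, offsets[gi] + nz[, 2L])
    xx <- c(xx, ah[nz])
    ri <- c(ri, rep(gi, g$n_atoms))
    rj <- c(rj, offsets[gi] + seq_len(g$n_atoms))
    rx <- c(rx, rep(1 / g$n_atoms, g$n_atoms))
  }
  list(
    X = X,
    adj = Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(total, total)),
    readout = Matrix::sparseMatrix(i = ri, j = rj, x = rx,
                                   dims = c(length(graphs), total)),
    drug_ids = vapply(graphs, function(g) g$drug_id, "")
  )
}

# tape-level forward over a prepared batch
.encode_drugs_t <- function(batch, pn) {
  h1 <- ad_relu(ad_add_rowvec(ad_mm(batch$adj, ad_mm(batch$X, pn$w1)), pn$b1))
  h2 <- ad_relu(ad_add_rowvec(ad_mm(batch$adj, ad_mm(h1, pn$w2)), pn$b2))
  ad_add_rowvec(ad_mm(ad_mm(batch$readout, h2), pn$w_out), pn$b_out)
}

#' Encode drugs from their molecular graphs
#'
#' Messages are aggregated over the symmetric-normalised bond adjacency
#' with self-loops; the readout is the mean over atom states, so the
#' embedding is invariant to atom relabeling.
#'
#' @param graphs A list of [smiles_to_graph()] results.
#' @param params An [init_drug_params()] result.
#' @return Numeric matrix `D` (`n_drugs x f_dim`), row names = drug ids.
#' @export
encode_drugs <- function(graphs, params) {
  stopifnot(length(graphs) >= 1L, inherits(params, "drug_encoder_params"))
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  batch <- .drug_batch(graphs)
  pn <- .wrap_params(params, wrap = FALSE)
  D <- ad_value(.encode_drugs_t(batch, pn))
  rownames(D) <- batch$drug_ids
  D
}
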
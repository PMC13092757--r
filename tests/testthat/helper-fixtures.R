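# Shared fixtures and oracles, built in code at test time.

# central-difference numerical gradient of scalar-valued f at matrix w
num_grad <- function(f, w, eps = 1e-5) {
  g <- w
  for (i in seq_along(w)) {
    wp <- w; wm <- w
    wp[i] <- wp[i] + eps
    wm[i] <- wm[i] - eps
    g[i] <- (f(wp) - f(wm)) / (2 * eps)
  }
  g
}

# tiny labeled response table: n_cell x n_drug grid with planted labels
tiny_pairs <- function(n_cell = 4, n_drug = 3, sens = list(c(1, 1)),
                       res = list(c(2, 2))) {
  cells <- paste0("c", seq_len(n_cell))
  drugs <- paste0("d", seq_len(n_drug))
  rows <- list()
  for (s in sens) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cell_id = cells[s[1]], drug_id = drugs[s[2]], log_ic50 = -4)
  }
  for (r in res) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cell_id = cells[r[1]], drug_id = drugs[r[2]], log_ic50 = 4)
  }
  label_responses(dplyr::bind_rows(rows))
}

# random directed multigraph as a response_graph-shaped relation list
random_relations <- function(n_nodes, n_rel, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    rel <- list()
    for (r in seq_len(n_rel)) {
      a <- matrix(rbinom(n_nodes^2, 1, p), n_nodes)
      diag(a) <- 0
      rel[[paste0("rel", r)]] <- Matrix::Matrix(a, sparse = TRUE)
    }
    rel
  })
}

# brute-force RGCN layer: triple loop over (node, relation, neighbour)
rgcn_brute <- function(h, relations, w_rel, w0, activation = TRUE) {
  n <- nrow(h)
  out <- matrix(0, n, ncol(w0))
  for (i in seq_len(n)) {
    acc <- as.vector(h[i, ] %*% w0)
    for (r in names(relations)) {
      a <- as.matrix(relations[[r]])
      nbr <- which(a[, i] > 0)          # incoming j -> i
      if (length(nbr) == 0) next
      c_ir <- length(nbr)
      for (j in nbr) {
        acc <- acc + as.vector(h[j, ] %*% w_rel[[r]]) / c_ir
      }
    }
    out[i, ] <- acc
  }
  if (activation) pmax(out, 0) else out
}

# brute-force GAT forward mirroring the layer structure: per-node softmax
# attention over in-neighbours + self, hidden heads concatenated (ReLU),
# output heads averaged then ReLU
gat_brute <- function(features, adjacency, params) {
  n <- nrow(features)
  a <- as.matrix(adjacency)
  slope <- params$leaky_slope
  lrelu <- function(x) ifelse(x > 0, x, slope * x)
  head_out <- function(t_in, hp) {
    z <- t_in %*% hp$w
    out <- matrix(0, n, ncol(z))
    for (i in seq_len(n)) {
      nbr <- unique(c(which(a[, i] > 0), i))
      e <- vapply(nbr, function(j) {
        lrelu(sum(z[i, ] * hp$a_dst) + sum(z[j, ] * hp$a_src))
      }, 0)
      al <- exp(e - max(e)); al <- al / sum(al)
      out[i, ] <- colSums(al * z[nbr, , drop = FALSE])
    }
    out
  }
  hid <- do.call(cbind, lapply(params$hidden, function(hp) {
    pmax(head_out(features, hp), 0)
  }))
  outs <- lapply(params$output, function(hp) head_out(hid, hp))
  pmax(Reduce(`+`, outs) / length(outs), 0)
}

# small cached cohort so multiple test files can reuse one generation
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$co)) {
    .fixture_env$co <- generate_cohort(
      n_cells = 24, n_drugs = 15, k_latent = 3,
      view_dims = c(transcriptomics = 20L, proteomics = 16L, cnv = 12L,
                    mutations = 12L, methylation = 16L, metabolomics = 8L),
      noise_sd = 0.2, target_prevalence = 0.15, seed = 42)
  }
  .fixture_env$co
}
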
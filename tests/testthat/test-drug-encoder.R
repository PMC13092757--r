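# SMILES parsing and the permutation-invariant drug encoder.

test_that("small molecules parse to the expected graphs", {
  g <- smiles_to_graph("CCO")
  expect_equal(g$n_atoms, 3)
  expect_equal(sum(g$adjacency) / 2, 2)
  expect_true(Matrix::isSymmetric(Matrix::Matrix(g$adjacency)))
  expect_equal(diag(g$adjacency), rep(0, 3))

  b <- smiles_to_graph("c1ccccc1")
  expect_equal(b$n_atoms, 6)
  expect_equal(sum(b$adjacency) / 2, 6)
  expect_true(all(b$aromatic))

  expect_error(smiles_to_graph("not_a_smiles"), "not_a_smiles")
  expect_error(smiles_to_graph(""), "nzchar")
})

test_that("salts keep the largest fragment with a warning", {
  expect_warning(g <- smiles_to_graph("CC(=O)[O-].[Na+]"), "fragments")
  expect_equal(g$n_atoms, 4)
  expect_equal(g$n_fragments, 2)
  expect_equal(g$formal_charge[4], -1)
})

test_that("atom features encode element, degree, aromaticity, charge, H", {
  g <- smiles_to_graph("CCO")
  f <- g$atom_features
  expect_equal(ncol(f), dragnet:::atom_feature_width())
  expect_equal(f[, "el_C"], c(1, 1, 0), ignore_attr = TRUE)
  expect_equal(f[, "el_O"], c(0, 0, 1), ignore_attr = TRUE)
  expect_equal(f[, "deg_1"], c(1, 0, 1), ignore_attr = TRUE)
  # implicit H: CH3 = 3, CH2 = 2, OH = 1
  expect_equal(f[, "h_3"], c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(f[, "h_2"], c(0, 1, 0), ignore_attr = TRUE)
  expect_equal(f[, "h_1"], c(0, 0, 1), ignore_attr = TRUE)
})

test_that("embedding is invariant to atom relabeling", {
  params <- init_drug_params(drug_encoder_config(f_dim = 12L, hidden = 8L),
                             seed = 2)
  g <- smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O", drug_id = "asp")
  base <- encode_drugs(list(g), params)
  for (s in 1:20) {
    perm <- withr::with_seed(s, sample(g$n_atoms))
    gp <- g
    gp$atom_features <- g$atom_features[perm, , drop = FALSE]
    gp$adjacency <- g$adjacency[perm, perm]
    out <- encode_drugs(list(gp), params)
    expect_lt(max(abs(out - base)), 1e-6)
  }
})

test_that("identical molecules map to identical rows; readout is a mean", {
  params <- init_drug_params(drug_encoder_config(f_dim = 10L, hidden = 6L),
                             seed = 3)
  g <- smiles_to_graph("c1ccccc1")
  two <- encode_drugs(list(g, g), params)
  expect_equal(two[1, ], two[2, ], ignore_attr = TRUE)

  # a single-atom graph's embedding equals its transformed atom state
  g1 <- smiles_to_graph("C")
  expect_equal(g1$n_atoms, 1)
  d1 <- encode_drugs(list(g1), params)
  x <- g1$atom_features
  h1 <- pmax(x %*% params$w1 + matrix(params$b1, 1), 0)
  h2 <- pmax(h1 %*% params$w2 + matrix(params$b2, 1), 0)
  expect_equal(as.vector(h2 %*% params$w_out + params$b_out),
               as.vector(d1), tolerance = 1e-10)

  # multi-fragment input keeps the ring, not the isolated atom
  expect_warning(gm <- smiles_to_graph("C.c1ccccc1"), "fragments")
  expect_equal(gm$n_atoms, 6)
})

test_that("an isolated extra atom shifts the mean readout predictably", {
  # build a two-fragment graph by hand (bypassing the largest-fragment
  # rule) and check the readout is the mean over n+1 atom states
  params <- init_drug_params(drug_encoder_config(f_dim = 10L, hidden = 6L),
                             seed = 3)
  g <- smiles_to_graph("CCO")
  gc <- smiles_to_graph("C")
  gplus <- g
  gplus$atom_features <- rbind(g$atom_features, gc$atom_features)
  gplus$adjacency <- as.matrix(Matrix::bdiag(g$adjacency, 0))
  gplus$n_atoms <- 4L
  hidden_states <- function(x, a) {
    ah <- a + diag(nrow(a))
    dg <- 1 / sqrt(rowSums(ah))
    ah <- ah * outer(dg, dg)
    h1 <- pmax(ah %*% x %*% params$w1 +
                 matrix(params$b1, nrow(x), 6, byrow = TRUE), 0)
    pmax(ah %*% h1 %*% params$w2 +
           matrix(params$b2, nrow(x), 6, byrow = TRUE), 0)
  }
  hs <- hidden_states(gplus$atom_features, gplus$adjacency)
  want <- colMeans(hs) %*% params$w_out + params$b_out
  got <- encode_drugs(list(gplus), params)
  expect_equal(as.vector(got), as.vector(want), tolerance = 1e-10)
})

test_that("drug batch shapes are stable at cohort scale", {
  co <- small_cohort()
  params <- init_drug_params(drug_encoder_config(f_dim = 24L, hidden = 16L),
                             seed = 1)
  D <- encode_drugs(co$drug_graphs, params)
  expect_equal(dim(D), c(15L, 24L))
  expect_equal(rownames(D), co$smiles$drug_id, ignore_attr = TRUE)
  expect_true(all(is.finite(D)))
})

test_that("fingerprints are deterministic and discriminate structures", {
  gs <- lapply(c("CCO", "c1ccccc1", "CCO"), smiles_to_graph)
  fp <- drug_fingerprints(gs, nbits = 512)
  expect_identical(fp[1, ], fp[3, ])
  expect_false(all(fp[1, ] == fp[2, ]))
  sim <- tanimoto_similarity(fp)
  expect_equal(sim[1, 3], 1)
  expect_lt(sim[1, 2], 0.5)
  expect_equal(diag(sim), rep(1, 3), ignore_attr = TRUE)
})
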
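# IC50 labeling, omics table IO, similarity edges and response-graph
# assembly.

test_that("IC50 thresholds assign the three response categories", {
  tbl <- tibble::tibble(cell_id = c("a", "a", "a"),
                        drug_id = c("d1", "d2", "d3"),
                        log_ic50 = c(-4, 5, 0))
  lab <- label_responses(tbl, -3, 3)
  expect_equal(as.character(lab$label),
               c("sensitive", "resistant", "uncorrelated"))
  # boundary values are not sensitive/resistant (strict inequalities)
  lab2 <- label_responses(tibble::tibble(cell_id = "a", drug_id = "d",
                                         log_ic50 = c(-3)), -3, 3)
  expect_equal(as.character(lab2$label), "uncorrelated")
  expect_error(label_responses(tbl, 3, -3), "low_threshold")
})

test_that("label counts always partition the input and rejects are reported", {
  withr::with_seed(9, {
    n <- 200
    tbl <- tibble::tibble(cell_id = paste0("c", 1:n), drug_id = "d",
                          log_ic50 = rnorm(n, sd = 4))
  })
  for (th in list(c(-3, 3), c(-1, 1), c(0, 5))) {
    lab <- label_responses(tbl, th[1], th[2])
    expect_equal(sum(attr(lab, "counts")), n)
  }
  tbl$log_ic50[5] <- NA
  expect_warning(lab <- label_responses(tbl), "non-finite")
  expect_equal(nrow(attr(lab, "rejected")), 1)
  expect_equal(nrow(lab), n - 1)
})

test_that("response graph holds one directed edge per labeled record", {
  lab <- tiny_pairs(2, 2, sens = list(c(1, 1)), res = list(c(2, 2)))
  g <- build_response_graph(paste0("c", 1:2), paste0("d", 1:2), lab)
  expect_equal(sum(g$relations$sensitive), 1)
  expect_equal(sum(g$relations$resistant), 1)
  expect_equal(as.matrix(g$relations$sensitive_inv),
               t(as.matrix(g$relations$sensitive)), ignore_attr = TRUE)
  # zero records
  g0 <- build_response_graph("c1", "d1", lab[0, ])
  expect_true(all(vapply(g0$relations, sum, 0) == 0))
})

test_that("graph assembly scales to planted counts and stays disjoint", {
  withr::with_seed(11, {
    cells <- sprintf("c%03d", 1:60)
    drugs <- sprintf("d%03d", 1:60)
    pick <- sample(3600, 3400)
    grid <- expand.grid(ci = 1:60, di = 1:60)[pick, ]
    ic50 <- c(rep(-4, 3001), runif(399, 3.1, 6))
  })
  tbl <- tibble::tibble(cell_id = cells[grid$ci], drug_id = drugs[grid$di],
                        log_ic50 = ic50)
  lab <- label_responses(tbl)
  g <- build_response_graph(cells, drugs, lab)
  expect_equal(sum(g$relations$sensitive), 3001)
  expect_equal(sum(g$relations$resistant), 399)
  # disjointness and direction block structure
  expect_equal(sum(g$relations$sensitive * g$relations$resistant), 0)
  n_c <- g$n_cell
  fw <- as.matrix(g$relations$sensitive + g$relations$resistant)
  expect_true(all(fw[, seq_len(n_c)] == 0))        # no edges into cells
  expect_true(all(fw[-seq_len(n_c), ] == 0))       # no edges out of drugs
})

test_that("conflicting duplicate labels are rejected by pair name", {
  tbl <- tibble::tibble(cell_id = c("c1", "c1"), drug_id = c("d1", "d1"),
                        log_ic50 = c(-4, 4))
  lab <- label_responses(tbl)
  expect_error(build_response_graph("c1", "d1", lab), "c1.*d1")
  only_sens <- tiny_pairs(1, 1, sens = list(c(1, 1)), res = list())
  expect_error(build_response_graph("c1", "d9", only_sens), "unknown drug")
})

test_that("similarity edges agree with a brute-force pairwise oracle", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      n <- sample(8:20, 1)
      k <- sample(2:4, 1)
      feats <- matrix(rnorm(n * 6), n)
    })
    adj <- compute_similarity_edges(feats, k = k, metric = "cosine")
    # oracle: dense cosine, union of directed top-k
    nrm <- feats / sqrt(rowSums(feats^2))
    sim <- nrm %*% t(nrm)
    diag(sim) <- -Inf
    want <- matrix(0, n, n)
    for (i in seq_len(n)) {
      want[i, order(sim[i, ], decreasing = TRUE)[seq_len(k)]] <- 1
    }
    want <- pmax(want, t(want))
    expect_equal(as.matrix(adj), want, ignore_attr = TRUE)
    # directed entry count bounds after symmetrisation
    expect_gte(sum(want), n * k)
    expect_lte(sum(want), 2 * n * k)
  }
})

test_that("identical and orthogonal rows get similarity 1 and 0", {
  feats <- rbind(c(1, 1, 0), c(2, 2, 0), c(0, 0, 5))
  adj <- compute_similarity_edges(feats, k = 1)
  sc <- attr(adj, "scores")
  expect_equal(sc[1, 2], 1)
  expect_equal(adj[1, 2], 1)
  expect_equal(sc[1, 3], 0)
  expect_warning(compute_similarity_edges(rbind(feats, 0), k = 1),
                 "all-zero")
})

test_that("omics tables round-trip with intersection, imputation, scaling", {
  dir <- withr::local_tempdir()
  w1 <- tibble::tibble(cell_id = c("a", "b", "c"), f1 = c(1, 2, NA),
                       f2 = c(0, 1, 2))
  w2 <- tibble::tibble(cell_id = c("b", "a", "c", "d"), g1 = c(4, 2, 6, 9))
  readr::write_csv(w1, file.path(dir, "v1.csv"))
  readr::write_csv(w2, file.path(dir, "v2.csv"))
  expect_message(
    om <- read_omics_tables(c(v1 = file.path(dir, "v1.csv"),
                              v2 = file.path(dir, "v2.csv"))),
    "dropped")
  expect_equal(om$cell_ids, c("a", "b", "c"))
  expect_equal(attr(om, "dropped_cells"), "d")
  # median of {1, 2} = 1.5 imputed before z-scoring
  raw <- c(1, 2, 1.5)
  expect_equal(om$views$v1[, "f1"], (raw - mean(raw)) / sd(raw),
               ignore_attr = TRUE)
  # columns standardised
  expect_equal(colMeans(om$views$v2), 0, ignore_attr = TRUE,
               tolerance = 1e-12)
  # empty intersection errors with per-view counts
  w3 <- tibble::tibble(cell_id = "zz", h1 = 1)
  readr::write_csv(w3, file.path(dir, "v3.csv"))
  expect_error(read_omics_tables(c(v1 = file.path(dir, "v1.csv"),
                                   v3 = file.path(dir, "v3.csv"))),
               "v1=3")
})

test_that("edge-list export covers every relation", {
  lab <- tiny_pairs(3, 2, sens = list(c(1, 1), c(2, 1)), res = list(c(3, 2)))
  g <- build_response_graph(paste0("c", 1:3), paste0("d", 1:2), lab)
  el <- graph_edge_list(g)
  expect_equal(nrow(el), 2 * 3)        # forward + inverse per record
  expect_setequal(unique(el$relation),
                  c("sensitive", "resistant", "sensitive_inv",
                    "resistant_inv"))
})
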
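# Type-specific augmentation: partitioning, protected deletion, exact
# masking counts, two-view generation.

aug_graph <- function() {
  lab <- tiny_pairs(4, 3, sens = list(c(1, 1), c(2, 1)),
                    res = list(c(3, 2), c(4, 3), c(2, 2)))
  g <- build_response_graph(paste0("c", 1:4), paste0("d", 1:3), lab)
  g$features <- withr::with_seed(1, matrix(rnorm(7 * 10), 7))
  g
}

test_that("sensitive incidence defines the node partition", {
  g <- aug_graph()
  part <- partition_nodes(g)
  # cells c1, c2 and drug d1 touch sensitive edges (nodes 1, 2, 5)
  expect_equal(part$sensitive, c(1L, 2L, 5L))
  expect_length(part$nonsensitive, 4L)
  expect_setequal(c(part$sensitive, part$nonsensitive), 1:7)

  # all-sensitive and no-sensitive corner cases
  lab_all <- tiny_pairs(2, 1, sens = list(c(1, 1), c(2, 1)), res = list())
  g_all <- build_response_graph(paste0("c", 1:2), "d1", lab_all)
  expect_length(partition_nodes(g_all)$nonsensitive, 0L)
  lab_none <- tiny_pairs(2, 1, sens = list(), res = list(c(1, 1)))
  g_none <- build_response_graph(paste0("c", 1:2), "d1", lab_none)
  expect_length(partition_nodes(g_none)$sensitive, 0L)
})

test_that("edge deletion removes an exact seeded count from the pool only", {
  g <- aug_graph()
  part <- partition_nodes(g)
  pool <- dragnet:::.deletion_pool(g)
  expect_equal(nrow(pool), 3L)         # the three resistant edges

  d0 <- delete_edges(g, part, 0, seed = 1)
  expect_equal(as.matrix(d0$relations$resistant),
               as.matrix(g$relations$resistant))

  d1 <- delete_edges(g, part, 2 / 3, seed = 7)
  expect_equal(sum(d1$relations$resistant), 1)
  expect_equal(as.matrix(d1$relations$resistant_inv),
               t(as.matrix(d1$relations$resistant)), ignore_attr = TRUE)
  # sensitive edges never touched, any rate
  d_full <- delete_edges(g, part, 1, seed = 3)
  expect_equal(as.matrix(d_full$relations$sensitive),
               as.matrix(g$relations$sensitive))
  expect_equal(sum(d_full$relations$resistant), 0)
  # reproducible choice
  d1b <- delete_edges(g, part, 2 / 3, seed = 7)
  expect_identical(attr(d1, "deleted"), attr(d1b, "deleted"))
  # protecting resistant edges empties this pool
  dp <- delete_edges(g, part, 1, seed = 3, protect_resistant = TRUE)
  expect_equal(sum(dp$relations$resistant), 3)
})

test_that("only the low-similarity half of similarity edges is deletable", {
  withr::with_seed(8, feats <- matrix(rnorm(12 * 6), 12))
  lab <- tiny_pairs(12, 2, sens = list(c(1, 1)), res = list())
  g <- build_response_graph(paste0("c", 1:12), paste0("d", 1:2), lab)
  g <- add_similarity_edges(g, cell_features = feats, k = 3L)
  pool <- dragnet:::.deletion_pool(g)
  sims <- pool[pool$relation == "cell_sim", ]
  tr <- Matrix::summary(methods::as(g$relations$cell_sim, "TsparseMatrix"))
  n_undirected <- sum(tr$i < tr$j)
  expect_equal(nrow(sims), floor(n_undirected / 2))
  # deleted similarity edges all score below the median of the pool
  sc <- g$sim_scores$cell_sim
  pooled_scores <- sc[cbind(sims$i, sims$j)]
  all_scores <- sc[cbind(tr$i[tr$i < tr$j], tr$j[tr$i < tr$j])]
  expect_lte(max(pooled_scores), stats::median(all_scores))
  # deletion drops both directions
  d <- delete_edges(g, partition_nodes(g), 1, seed = 2)
  expect_true(Matrix::isSymmetric(d$relations$cell_sim))
})

test_that("masking zeroes an exact per-node count and spares S_s", {
  g <- aug_graph()
  part <- partition_nodes(g)
  f <- 10L
  m <- mask_features(g$features, part, 0.3, seed = 5)
  msk <- attr(m, "mask")
  for (r in part$nonsensitive) expect_equal(sum(msk[r, ] == 0), 3)
  for (r in part$sensitive) expect_equal(sum(msk[r, ] == 0), 0)
  expect_equal(sum(m == 0), 3 * length(part$nonsensitive))
  expect_identical(m[part$sensitive, ], g$features[part$sensitive, ])
  expect_identical(mask_features(g$features, part, 0, seed = 5),
                   structure(g$features, mask = matrix(1, 7, 10)))
  # S_n empty -> identity at any rate
  lab_all <- tiny_pairs(2, 1, sens = list(c(1, 1), c(2, 1)), res = list())
  g_all <- build_response_graph(paste0("c", 1:2), "d1", lab_all)
  p_all <- partition_nodes(g_all)
  feats <- matrix(1, 3, 4)
  expect_equal(unclass(mask_features(feats, p_all, 0.9, seed = 1)),
               feats, ignore_attr = TRUE)
})

test_that("two views protect sensitive structure and differ from each other", {
  g <- aug_graph()
  cfg <- augment_config(edge_rate = 0.4, mask_rate = 0.3)
  v <- make_views(g, cfg, seed = 10)
  part <- partition_nodes(g)
  for (view in v) {
    expect_identical(as.matrix(view$graph$relations$sensitive),
                     as.matrix(g$relations$sensitive))
    expect_identical(view$features[part$sensitive, ],
                     g$features[part$sensitive, ])
  }
  v2 <- make_views(g, cfg, seed = 10)
  expect_identical(v$g1$features, v2$g1$features)
  expect_identical(attr(v$g2$graph, "deleted"), attr(v2$g2$graph, "deleted"))
  # zero rates reproduce the source graph in both views
  v0 <- make_views(g, augment_config(0, 0), seed = 1)
  expect_equal(unclass(v0$g1$features), g$features, ignore_attr = TRUE)
  expect_equal(as.matrix(v0$g2$graph$relations$resistant),
               as.matrix(g$relations$resistant))
})

test_that("views differ across seeds on a 50-node fixture", {
  withr::with_seed(20, {
    cells <- sprintf("c%02d", 1:30)
    drugs <- sprintf("d%02d", 1:20)
    grid <- expand.grid(ci = 1:30, di = 1:20)
    pick <- sample(nrow(grid), 250)
    ic <- c(rep(-4, 40), rep(4, 210))
  })
  tbl <- tibble::tibble(cell_id = cells[grid$ci[pick]],
                        drug_id = drugs[grid$di[pick]], log_ic50 = ic)
  g <- build_response_graph(cells, drugs, label_responses(tbl))
  g$features <- withr::with_seed(21, matrix(rnorm(50 * 8), 50))
  differing <- 0L
  for (s in 1:20) {
    v <- make_views(g, augment_config(0.4, 0.3), seed = s)
    same_edges <- identical(attr(v$g1$graph, "deleted"),
                            attr(v$g2$graph, "deleted"))
    same_feats <- identical(v$g1$features, v$g2$features)
    if (!(same_edges && same_feats)) differing <- differing + 1L
  }
  expect_equal(differing, 20L)
})
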
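# GAT attention, fusion, alignment and focal losses, pair scoring.

test_that("singleton attention reduces to the transformed self state", {
  f <- 6L
  params <- init_gat_params(f_dim = f, heads = 1L, seed = 2)
  feats <- withr::with_seed(3, matrix(rnorm(f), 1, f))
  adj <- Matrix::Matrix(0, 1, 1, sparse = TRUE)
  out <- gat_encode(feats, adj, params)
  # alpha = 1 on the self loop at both layers
  z1 <- pmax(feats %*% params$hidden[[1]]$w, 0)
  want <- pmax(z1 %*% params$output[[1]]$w, 0)
  expect_equal(out, want, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("identical-feature neighbours receive equal attention", {
  f <- 4L
  params <- init_gat_params(f_dim = f, heads = 2L, seed = 4)
  feats <- withr::with_seed(5, {
    base <- rnorm(f)
    rbind(rnorm(f), base, base)
  })
  # node 1 attends nodes 2 and 3 (identical) and itself
  adj <- Matrix::sparseMatrix(i = c(2, 3), j = c(1, 1), x = 1,
                              dims = c(3, 3))
  # brute-force attention weights for head 1, layer 1
  hp <- params$hidden[[1]]
  z <- feats %*% hp$w
  lrelu <- function(x) ifelse(x > 0, x, params$leaky_slope * x)
  e <- vapply(c(2, 3, 1), function(j) {
    lrelu(sum(z[1, ] * hp$a_dst) + sum(z[j, ] * hp$a_src))
  }, 0)
  al <- exp(e - max(e)); al <- al / sum(al)
  expect_equal(al[1], al[2], tolerance = 1e-12)
})

test_that("gat_encode matches the per-node brute-force oracle", {
  for (seed in 1:12) {
    k <- c(1L, 2L, 3L)[(seed %% 3) + 1L]
    f <- 6L
    withr::with_seed(seed, {
      n <- sample(4:8, 1)
      feats <- matrix(rnorm(n * f), n)
      a <- matrix(rbinom(n^2, 1, 0.4), n); diag(a) <- 0
    })
    params <- init_gat_params(f_dim = f, heads = k, seed = seed + 50)
    got <- gat_encode(feats, Matrix::Matrix(a, sparse = TRUE), params)
    want <- gat_brute(feats, a, params)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("attention rows are normalised in the differentiable path", {
  f <- 4L
  withr::with_seed(6, {
    n <- 5
    feats <- matrix(rnorm(n * f), n)
    a <- matrix(rbinom(n^2, 1, 0.5), n); diag(a) <- 0
  })
  params <- init_gat_params(f_dim = f, heads = 2L, seed = 7)
  ed <- dragnet:::.gat_edges(list(Matrix::Matrix(a, sparse = TRUE)), n)
  pn <- dragnet:::.wrap_params(params, wrap = FALSE)
  # recompute the alpha vector of head 1 exactly as the layer does
  hp <- pn$hidden[[1]]
  z <- dragnet:::ad_mm(feats, hp$w)
  e_dst <- dragnet:::ad_mm(z, hp$a_dst)
  e_src <- dragnet:::ad_mm(z, hp$a_src)
  e <- dragnet:::ad_leaky_relu(
    dragnet:::ad_add(dragnet:::ad_rows(e_dst, ed$dst),
                     dragnet:::ad_rows(e_src, ed$src)), 0.2)
  shift <- vapply(split(as.vector(dragnet:::ad_value(e)), ed$dst), max, 0)
  ex <- dragnet:::ad_exp(dragnet:::ad_affine(
    e, add = -shift[as.character(ed$dst)]))
  denom <- dragnet:::ad_mm(ed$agg, ex)
  alpha <- dragnet:::ad_value(dragnet:::ad_div(
    ex, dragnet:::ad_rows(denom, ed$dst)))
  sums <- tapply(as.vector(alpha), ed$dst, sum)
  expect_equal(as.vector(sums), rep(1, n), tolerance = 1e-6)
})

test_that("fusion is the elementwise product, mean-pooled across views", {
  T1 <- matrix(c(1, 2), 1)
  H <- matrix(c(3, 4), 1)
  expect_equal(fuse_embeddings(T1, H), matrix(c(3, 8), 1))
  expect_equal(fuse_embeddings(matrix(1, 2, 3), matrix(5, 2, 3)),
               matrix(5, 2, 3))                       # H = T when T = 1
  expect_equal(fuse_embeddings(list(T1, T1), H),
               fuse_embeddings(T1, H))                # identical views
  expect_error(fuse_embeddings(matrix(0, 2, 2), matrix(0, 3, 2)),
               "identical shape")
})

test_that("alignment loss vanishes iff views match and stds hit the anchor", {
  withr::with_seed(8, x <- matrix(rnorm(40), 10))
  x <- scale(x)                         # per-dimension sd exactly 1
  cfg <- objective_config(phi_target = 1)
  expect_lt(alignment_loss(x, x, cfg), 1e-5)   # only the sqrt-eps floor
  # doubling omega1 doubles the first term exactly
  y <- x + 0.5
  l_base <- alignment_loss(x, y, objective_config(omega1 = 1, omega2 = 0,
                                                  phi_target = 1))
  l_double <- alignment_loss(x, y, objective_config(omega1 = 2, omega2 = 0,
                                                    phi_target = 1))
  expect_equal(l_double, 2 * l_base, tolerance = 1e-9)
})

test_that("alignment loss equals the hand computation on a 3x2 fixture", {
  x1 <- matrix(c(1, 2, 3, 4, 5, 6), 3)
  x2 <- matrix(c(2, 2, 2, 3, 5, 7), 3)
  # by hand: row distances, column sds, anchor 1, omega1 = omega2 = 1
  d <- sqrt(rowSums((x1 - x2)^2))
  t1 <- mean(d)
  s1 <- apply(x1, 2, sd); s2 <- apply(x2, 2, sd)
  t2 <- sum((s1 - 1)^2 + (s2 - 1)^2)
  expect_equal(alignment_loss(x1, x2, objective_config(phi_target = 1)),
               t1 + t2, tolerance = 1e-6)
  # invariant to a common row permutation
  perm <- c(3, 1, 2)
  expect_equal(alignment_loss(x1[perm, ], x2[perm, ],
                              objective_config(phi_target = 1)),
               t1 + t2, tolerance = 1e-6)
})

test_that("focal loss closed forms hold", {
  withr::with_seed(9, {
    p <- runif(1000, 0.01, 0.99)
    y <- rbinom(1000, 1, 0.3)
  })
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(focal_loss(p, y, alpha_t = 1, gamma = 0), bce,
               tolerance = 1e-9)
  expect_equal(focal_loss(0.5, 1, alpha_t = 0.25, gamma = 2),
               0.25 * 0.25 * log(2), tolerance = 1e-9)
  # perfectly classified samples contribute (almost) nothing
  expect_lt(focal_loss(1 - 1e-7, 1, alpha_t = 0.25, gamma = 2), 1e-10)
  expect_warning(focal_loss(c(0.5, 1), c(1, 1)), "clamped")
})

test_that("total loss is the sum and rejects non-finite parts", {
  expect_equal(total_loss(0, 0), 0)
  expect_equal(total_loss(0.5, 0.25), 0.75)
  expect_error(total_loss(NaN, 1), "L1")
  expect_error(total_loss(0, Inf), "L2")
})

test_that("joint gradient equals the sum of per-term gradients", {
  # two-node fixture: d(L1 + L2)/dw == dL1/dw + dL2/dw
  withr::with_seed(10, {
    x1v <- matrix(rnorm(8), 2)
    x2v <- matrix(rnorm(8), 2)
  })
  grad_of <- function(build) {
    w <- dragnet:::ad_param(diag(4))
    out <- build(w)
    dragnet:::ad_backward(out)
    w$g
  }
  b1 <- function(w) dragnet:::.alignment_loss_t(
    dragnet:::ad_mm(x1v, w), dragnet:::ad_mm(x2v, w), 1, 1, 1)
  b2 <- function(w) dragnet:::.focal_loss_t(
    dragnet:::ad_sigmoid(dragnet:::ad_mm(
      dragnet:::ad_mm(x1v, w), matrix(1, 4, 1))), c(1, 0), 0.25, 2)
  bsum <- function(w) dragnet:::ad_add(b1(w), b2(w))
  expect_equal(grad_of(bsum), grad_of(b1) + grad_of(b2), tolerance = 1e-9)
})

test_that("scorer outputs are bounded, deterministic, and id-resolving", {
  f <- 8L
  params <- init_scorer_params(f_dim = f, hidden = c(6L, 4L), seed = 3)
  withr::with_seed(11, x <- matrix(rnorm(10 * f), 10))
  rownames(x) <- paste0("n", 1:10)
  pairs <- data.frame(cell = c(1, 2, 2), drug = c(6, 7, 7))
  p <- score_pairs(x, pairs, params)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p[2], p[3])
  expect_identical(p, score_pairs(x, pairs, params))
  # by name
  p2 <- score_pairs(x, data.frame(cell = "n1", drug = "n6"), params)
  expect_equal(p2, p[1])
  expect_error(score_pairs(x, data.frame(cell = "zz", drug = "n6"), params),
               "zz")
})

test_that("shared GAT parameters accumulate gradient from both views", {
  f <- 6L
  withr::with_seed(12, {
    n <- 5
    feats <- matrix(rnorm(n * f), n)
    a1 <- matrix(rbinom(n^2, 1, 0.5), n); diag(a1) <- 0
    a2 <- matrix(rbinom(n^2, 1, 0.5), n); diag(a2) <- 0
  })
  params <- init_gat_params(f_dim = f, heads = 1L, seed = 13)
  ed1 <- dragnet:::.gat_edges(list(Matrix::Matrix(a1, sparse = TRUE)), n)
  ed2 <- dragnet:::.gat_edges(list(Matrix::Matrix(a2, sparse = TRUE)), n)
  run <- function(eds) {
    pn <- dragnet:::.wrap_params(params, wrap = TRUE)
    outs <- lapply(eds, function(ed) {
      dragnet:::ad_sum(dragnet:::.gat_forward_t(feats, ed, pn))
    })
    total <- if (length(outs) == 1) outs[[1]] else do.call(dragnet:::ad_add, outs)
    dragnet:::ad_backward(total)
    pn$hidden[[1]]$w$g
  }
  # the single parameter store receives the sum of both views' gradients
  expect_equal(run(list(ed1, ed2)), run(list(ed1)) + run(list(ed2)),
               tolerance = 1e-9)
})
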
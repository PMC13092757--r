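# End-to-end model assembly and training: encoders -> response graph ->
# RGCN -> augmented views -> shared GAT -> fused embeddings -> focal +
# alignment objective, optimised with Adam; plus prediction,
# cross-validation and a raw-feature logistic baseline.

#' Full model configuration
#'
#' Gathers every tunable of the pipeline with the shipped defaults:
#' embedding width F = 96, RGCN depth 2, K = 3 attention heads, edge
#' deletion rate 0.40, feature masking rate 0.30, focal loss (0.25, 2),
#' equal alignment weights.
#'
#' @param f_dim Shared embedding width F.
#' @param heads GAT attention heads K.
#' @param rgcn_layers RGCN propagation depth l.
#' @param edge_rate,mask_rate,protect_resistant See [augment_config()].
#' @param omega1,omega2,focal_alpha,focal_gamma See [objective_config()].
#' @param use_similarity Attach cell-cell / drug-drug similarity edges.
#' @param k_sim Neighbours per node for similarity edges.
#' @param enabled_views Omics views used by the cell encoder.
#' @param lr,weight_decay,epochs,patience Adam learning rate, weight
#'   decay, epoch budget, early-stopping patience (on validation AUPR).
#' @param val_fraction Fraction of training pairs held out for validation.
#' @param low_threshold,high_threshold log10 IC50 labeling thresholds.
#' @param score_source Score pairs from the view-fused embeddings
#'   (`"fused"`, default) or from the original-graph attention embeddings
#'   (`"original"`).
#' @param verbose Print per-epoch progress.
#' @return A list of class `model_config`.
#' @export
model_config <- function(f_dim = 96L, heads = 3L, rgcn_layers = 2L,
                         edge_rate = 0.40, mask_rate = 0.30,
                         protect_resistant = FALSE,
                         omega1 = 1, omega2 = 1,
                         focal_alpha = 0.25, focal_gamma = 2,
                         use_similarity = TRUE, k_sim = 5L,
                         enabled_views = VIEW_NAMES,
                         lr = 3e-3, weight_decay = 1e-5,
                         epochs = 300L, patience = 60L,
                         val_fraction = 0.1,
                         low_threshold = -3, high_threshold = 3,
                         score_source = c("fused", "original"),
                         verbose = FALSE) {
  structure(list(
    f_dim = as.integer(f_dim), heads = as.integer(heads),
    rgcn_layers = as.integer(rgcn_layers),
    augment = augment_config(edge_rate, mask_rate, protect_resistant),
    objective = objective_config(omega1, omega2, 1, focal_alpha,
                                 focal_gamma),
    use_similarity = use_similarity, k_sim = as.integer(k_sim),
    enabled_views = enabled_views,
    lr = lr, weight_decay = weight_decay,
    epochs = as.integer(epochs), patience = as.integer(patience),
    val_fraction = val_fraction,
    low_threshold = low_threshold, high_threshold = high_threshold,
    score_source = match.arg(score_source),
    omics = omics_encoder_config(f_dim),
    drug = drug_encoder_config(f_dim),
    verbose = isTRUE(verbose)
  ), class = "model_config")
}

# standardised views, drug batch, labeled binary pairs, similarity inputs
.prepare_data <- function(cohort, config) {
  stopifnot(inherits(cohort, "synthetic_cohort") || is.list(cohort))
  std_views <- lapply(cohort$omics$views, function(m) {
    standardize_columns(impute_median(m))
  })
  graphs <- cohort$drug_graphs %||% parse_smiles_set(cohort$smiles)
  fp <- cohort$fingerprints %||% drug_fingerprints(graphs)
  labeled <- suppressWarnings(
    label_responses(cohort$responses, config$low_threshold,
                    config$high_threshold))
  pairs <- labeled[labeled$label != "uncorrelated", , drop = FALSE]
  pairs$y <- as.numeric(pairs$label == "sensitive")
  list(
    cell_ids = cohort$omics$cell_ids,
    drug_ids = cohort$smiles$drug_id,
    std_views = std_views,
    cell_features = do.call(cbind, std_views),
    batch = .drug_batch(graphs[cohort$smiles$drug_id]),
    fingerprints = fp[cohort$smiles$drug_id, , drop = FALSE],
    labeled = labeled,
    pairs = tibble::as_tibble(pairs)
  )
}

# response graph over all cohort entities with edges from `edge_idx` rows
# of data$pairs only (test/validation pairs contribute no edges)
.build_train_graph <- function(data, config, edge_idx) {
  graph <- build_response_graph(data$cell_ids, data$drug_ids,
                                data$pairs[edge_idx, , drop = FALSE])
  if (config$use_similarity) {
    graph <- add_similarity_edges(graph, cell_features = data$cell_features,
                                  drug_features = data$fingerprints,
                                  k = config$k_sim)
  }
  graph
}

.pair_node_idx <- function(data, pairs, n_cell) {
  ci <- match(pairs$cell_id, data$cell_ids)
  di <- match(pairs$drug_id, data$drug_ids)
  stopifnot(!anyNA(ci), !anyNA(di))
  list(cell = ci, drug = n_cell + di)
}

# one full differentiable forward pass; plans == NULL means the original
# graph serves as both views (inference / no augmentation)
.forward_t <- function(pn, data, graph, norm_adjs, ed_views, masks,
                       config, phi) {
  c_t <- .encode_cells_t(data$std_views, pn$omics, config$enabled_views)
  d_t <- .encode_drugs_t(data$batch, pn$drug)
  x_t <- ad_rbind(c_t, d_t)
  h_t <- .embed_graph_t(x_t, norm_adjs, pn$rgcn)
  t_views <- vector("list", length(ed_views))
  for (v in seq_along(ed_views)) {
    hv <- if (is.null(masks[[v]])) h_t else ad_affine(h_t, mult = masks[[v]])
    t_views[[v]] <- .gat_forward_t(hv, ed_views[[v]], pn$gat)
  }
  xv <- lapply(t_views, function(tt) ad_mul(tt, h_t))
  x_fused <- if (length(xv) == 1L) xv[[1L]] else {
    acc <- xv[[1L]]
    for (k in 2:length(xv)) acc <- ad_add(acc, xv[[k]])
    ad_affine(acc, mult = 1 / length(xv))
  }
  l1 <- if (length(xv) >= 2L) {
    .alignment_loss_t(xv[[1L]], xv[[2L]], config$objective$omega1,
                      config$objective$omega2, phi)
  } else NULL
  list(h = h_t, x_fused = x_fused, x_views = xv, l1 = l1)
}

#' Labeled binary pairs of a cohort
#'
#' The cohort's response records after IC50 labeling, with uncorrelated
#' pairs removed and a numeric outcome `y` (sensitive = 1, resistant =
#' 0). Row order defines the pair indices used by [make_splits()],
#' [train_model()] and [baseline_logistic()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param config A [model_config()] (for the labeling thresholds).
#' @return A tibble with `cell_id`, `drug_id`, `log_ic50`, `label`, `y`.
#' @export
labeled_pairs <- function(cohort, config = model_config()) {
  .prepare_data(cohort, config)$pairs
}

#' Train the drug-response model
#'
#' Per epoch, two fresh augmented views are drawn (sub-seeds derived from
#' the root seed and the epoch), the shared-parameter GAT encodes both,
#' and Adam minimises `L = L1 + L2`: the alignment loss between the view
#' embeddings plus the focal loss of the pair scorer on the training
#' pairs. Early stopping monitors validation AUPR.
#'
#' @param cohort A [generate_cohort()] result (or a list with the same
#'   fields).
#' @param config A [model_config()].
#' @param train_idx Integer row indices into the cohort's labeled binary
#'   pairs used for training (default: all pairs). A validation split is
#'   carved from these; response edges come from the remaining training
#'   pairs only.
#' @param seed Integer root seed for initialisation, validation split and
#'   augmentation draws.
#' @return An object of class `dragnet_model` with fitted parameter
#'   values, the training graph, per-epoch `history`, and everything
#'   needed by [predict.dragnet_model()].
#' @export
train_model <- function(cohort, config = model_config(), train_idx = NULL,
                        seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  data <- .prepare_data(cohort, config)
  n_pairs <- nrow(data$pairs)
  train_idx <- train_idx %||% seq_len(n_pairs)
  y_all <- data$pairs$y[train_idx]
  if (length(unique(y_all)) < 2L) {
    stop("training pairs contain a single class; cannot train")
  }
  # stratified validation split
  val_local <- with_seed(derive_seed(seed, "valsplit"), {
    pos <- which(y_all == 1); neg <- which(y_all == 0)
    c(sample(pos, max(1L, round(config$val_fraction * length(pos)))),
      sample(neg, max(1L, round(config$val_fraction * length(neg)))))
  })
  val_idx <- train_idx[val_local]
  fit_idx <- setdiff(train_idx, val_idx)
  if (length(unique(data$pairs$y[fit_idx])) < 2L) {
    stop("training pairs contain a single class after validation split")
  }

  graph <- .build_train_graph(data, config, fit_idx)
  norm_adjs <- .rgcn_norm_adjs(graph$relations)
  part <- partition_nodes(graph)
  ed_orig <- .gat_edges(graph$relations, length(graph$node_ids))
  n_cell <- graph$n_cell

  params <- list(
    omics = init_omics_params(
      vapply(data$std_views, ncol, 1L), config$omics, seed),
    drug = init_drug_params(config$drug, seed),
    rgcn = init_rgcn_params(names(graph$relations), config$f_dim,
                            config$rgcn_layers, seed),
    gat = init_gat_params(config$f_dim, config$heads, seed),
    scorer = init_scorer_params(config$f_dim, seed = seed)
  )
  pn <- lapply(params, .wrap_params, wrap = TRUE)
  flat <- .collect_params(pn)
  opt <- adam_init(flat, lr = config$lr, weight_decay = config$weight_decay)

  fit_nodes <- .pair_node_idx(data, data$pairs[fit_idx, ], n_cell)
  val_nodes <- .pair_node_idx(data, data$pairs[val_idx, ], n_cell)
  y_fit <- data$pairs$y[fit_idx]
  y_val <- data$pairs$y[val_idx]
  aug <- config$augment
  augmenting <- aug$edge_rate > 0 || aug$mask_rate > 0
  phi <- 1

  history <- vector("list", config$epochs)
  best <- list(aupr = -Inf, values = NULL, epoch = 0L)
  for (epoch in seq_len(config$epochs)) {
    if (augmenting) {
      es <- derive_seed(seed, "views", epoch)
      sub <- c((2 * as.numeric(es) + 1) %% 2147483647,
               (2 * as.numeric(es) + 2) %% 2147483647)
      ed_views <- list(); masks <- list()
      for (v in 1:2) {
        gv <- delete_edges(graph, part, aug$edge_rate,
                           seed = derive_seed(sub[v], "edges"),
                           protect_resistant = aug$protect_resistant)
        ed_views[[v]] <- .gat_edges(gv$relations, length(graph$node_ids))
        masks[[v]] <- .mask_matrix(length(graph$node_ids), config$f_dim,
                                   part$nonsensitive, aug$mask_rate,
                                   derive_seed(sub[v], "mask"))
      }
    } else {
      ed_views <- list(ed_orig); masks <- list(NULL)
    }

    fw <- .forward_t(pn, data, graph, norm_adjs, ed_views, masks, config,
                     phi)
    phi <- phi_anchor(ad_value(fw$h), n_cell)   # anchor for next epoch
    x_score <- if (config$score_source == "fused") fw$x_fused else {
      t_ori <- .gat_forward_t(fw$h, ed_orig, pn$gat)
      ad_mul(t_ori, fw$h)
    }
    p_fit <- .score_pairs_t(x_score, fit_nodes$cell, fit_nodes$drug,
                            pn$scorer)
    l2 <- .focal_loss_t(p_fit, y_fit, config$objective$focal_alpha,
                        config$objective$focal_gamma)
    loss <- if (is.null(fw$l1)) l2 else ad_add(fw$l1, l2)
    ad_zero_grads(flat)
    ad_backward(loss)
    adam_step(opt)

    p_val <- as.vector(ad_value(
      .score_pairs_t(x_score, val_nodes$cell, val_nodes$drug, pn$scorer)))
    val_m <- if (length(unique(y_val)) == 2L) {
      c(auc = auc_score(p_val, y_val), aupr = aupr_score(p_val, y_val))
    } else c(auc = NA_real_, aupr = NA_real_)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch,
      loss = as.numeric(ad_value(loss)),
      l1 = if (is.null(fw$l1)) 0 else as.numeric(ad_value(fw$l1)),
      l2 = as.numeric(ad_value(l2)),
      val_auc = val_m[["auc"]], val_aupr = val_m[["aupr"]]
    )
    if (config$verbose && (epoch %% 10L == 0L || epoch == 1L)) {
      message(sprintf("epoch %3d  loss %.4f  val AUPR %.3f", epoch,
                      history[[epoch]]$loss, val_m[["aupr"]]))
    }
    if (!is.na(val_m[["aupr"]]) && val_m[["aupr"]] > best$aupr + 1e-9) {
      best$aupr <- val_m[["aupr"]]
      best$epoch <- epoch
      best$values <- lapply(flat, function(p) p$v)
    }
    if (epoch - best$epoch >= config$patience && best$epoch > 0L) break
  }
  if (!is.null(best$values)) {
    for (i in seq_along(flat)) flat[[i]]$v <- best$values[[i]]
  }

  structure(list(
    params = lapply(pn, .unwrap_params),
    pn = pn,
    config = config,
    data = data,
    graph = graph,
    norm_adjs = norm_adjs,
    ed_orig = ed_orig,
    n_cell = n_cell,
    phi = phi,
    history = dplyr::bind_rows(history[!vapply(history, is.null, TRUE)]),
    best_epoch = best$epoch,
    train_idx = fit_idx,
    val_idx = val_idx,
    seed = seed
  ), class = "dragnet_model")
}

#' @export
print.dragnet_model <- function(x, ...) {
  h <- x$history
  cat("<dragnet_model> F=", x$config$f_dim, ", ", x$config$rgcn_layers,
      " RGCN layers, K=", x$config$heads, " heads\n", sep = "")
  cat("  trained ", nrow(h), " epochs (best validation AUPR ",
      sprintf("%.3f", max(h$val_aupr, na.rm = TRUE)), " at epoch ",
      x$best_epoch, ")\n", sep = "")
  invisible(x)
}

# inference-time embeddings: original graph as the single view
.infer_embeddings <- function(model) {
  fw <- .forward_t(model$pn, model$data, model$graph, model$norm_adjs,
                   list(model$ed_orig), list(NULL), model$config, model$phi)
  x <- ad_value(fw$x_fused)
  rownames(x) <- model$graph$node_ids
  x
}

#' Predict sensitivity probabilities for cell-drug pairs
#'
#' Embeds the training graph (no augmentation at inference: the original
#' graph is its own view, so fused and original scoring coincide) and
#' scores the requested pairs. Pairs may reference entities that carried
#' no response edges during training (cold start).
#'
#' @param object A [train_model()] result.
#' @param pairs Data frame with `cell_id`, `drug_id` (default: the
#'   model's validation pairs).
#' @param ... Unused.
#' @return The input pairs with a `.pred` probability column.
#' @export
predict.dragnet_model <- function(object, pairs = NULL, ...) {
  pairs <- pairs %||% object$data$pairs[object$val_idx, ]
  x <- .infer_embeddings(object)
  nodes <- .pair_node_idx(object$data, pairs, object$n_cell)
  p <- as.vector(ad_value(.score_pairs_t(
    x, nodes$cell, nodes$drug,
    .wrap_params(object$params$scorer, wrap = FALSE))))
  out <- tibble::as_tibble(pairs)
  out$.pred <- p
  out
}

#' Cross-validate the model over a split plan
#'
#' Trains one model per fold (graph edges from that fold's training pairs
#' only) and evaluates on the fold's test pairs.
#'
#' @param cohort A [generate_cohort()] result.
#' @param plan A [make_splits()] result over the cohort's labeled binary
#'   pairs (order as in the prepared pair table: label_responses minus
#'   uncorrelated).
#' @param config A [model_config()].
#' @param seed Integer root seed (per-fold seeds are derived).
#' @param keep_models Keep the fitted models in the result.
#' @return A `fold_report`: tibble with one row of metrics per fold;
#'   attributes `summary` (mean, sd, se per metric), `predictions`, and
#'   optionally `models`.
#' @export
cross_validate <- function(cohort, plan, config = model_config(),
                           seed = 1L, keep_models = FALSE) {
  stopifnot(inherits(plan, "split_plan"))
  reports <- list(); preds <- list(); models <- list()
  for (f in seq_len(plan$n_folds)) {
    fold <- plan$folds[[f]]
    m <- train_model(cohort, config, train_idx = fold$train,
                     seed = derive_seed(seed, "fold", f))
    test_pairs <- m$data$pairs[fold$test, , drop = FALSE]
    pr <- predict(m, test_pairs)
    met <- evaluate_scores(pr$.pred, pr$y)
    met <- tibble::add_column(met, fold = f, .before = 1L)
    reports[[f]] <- met
    pr$fold <- f
    preds[[f]] <- pr
    if (keep_models) models[[f]] <- m
  }
  out <- dplyr::bind_rows(reports)
  class(out) <- c("fold_report", class(out))
  attr(out, "summary") <- summarize_folds(out)
  attr(out, "predictions") <- dplyr::bind_rows(preds)
  if (keep_models) attr(out, "models") <- models
  out
}

#' Aggregate fold metrics to mean, sd and standard error
#'
#' @param report A `fold_report` (tibble of per-fold metrics).
#' @return A tibble with one row per metric.
#' @export
summarize_folds <- function(report) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(report), -dplyr::any_of(c("fold", "n"))),
    dplyr::everything(), names_to = "metric", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()), .groups = "drop")
}

#' Logistic baseline on raw concatenated features
#'
#' Ridge-penalised logistic regression on the concatenation of a pair's
#' standardised omics features and the drug's structural fingerprint —
#' the no-graph reference the full model must beat.
#'
#' @param cohort A [generate_cohort()] result.
#' @param train_idx,test_idx Row indices into the cohort's labeled binary
#'   pair table.
#' @param config A [model_config()] (for the labeling thresholds).
#' @param lambda Ridge penalty (fixed; default 0.01).
#' @return Tibble of test pairs with `.pred`, with AUC in attribute
#'   `metrics`.
#' @export
baseline_logistic <- function(cohort, train_idx, test_idx,
                              config = model_config(), lambda = 0.01) {
  data <- .prepare_data(cohort, config)
  feat <- function(idx) {
    pr <- data$pairs[idx, ]
    cbind(data$cell_features[match(pr$cell_id, data$cell_ids), ,
                             drop = FALSE],
          data$fingerprints[match(pr$drug_id, data$drug_ids), ,
                            drop = FALSE])
  }
  x_tr <- feat(train_idx); y_tr <- data$pairs$y[train_idx]
  fit <- glmnet::glmnet(x_tr, y_tr, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  x_te <- feat(test_idx)
  p <- as.vector(stats::predict(fit, x_te, type = "response"))
  out <- tibble::as_tibble(data$pairs[test_idx, ])
  out$.pred <- p
  attr(out, "metrics") <- evaluate_scores(p, out$y)
  out
}
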
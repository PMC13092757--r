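# Cross-validation split plans: label-stratified random pair folds, and
# cold-start (disjoint-entity) folds in which no test cell line or drug
# appears in training.

#' Build a cross-validation split plan over labeled pairs
#'
#' `random_pair` assigns pairs to folds stratified by label. In
#' `disjoint_entity` mode, cell lines and drugs are partitioned into
#' `n_folds` groups first and a fold's test set contains the pairs whose
#' cell AND drug both fall in that fold's groups; training keeps pairs
#' with neither entity in the test groups, and pairs straddling the
#' boundary are dropped for that fold (reported per fold). This enforces
#' the cold-start protocol exactly: no test-set drug or cell line occurs
#' in training.
#'
#' @param pairs A data frame with `cell_id`, `drug_id` and (for
#'   stratification) `label`.
#' @param mode `"random_pair"` or `"disjoint_entity"`.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return An object of class `split_plan`: per fold, integer row indices
#'   `train` and `test` into `pairs` (plus `dropped` in disjoint mode).
#' @export
make_splits <- function(pairs, mode = c("random_pair", "disjoint_entity"),
                        n_folds = 5L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_folds >= 2L,
            all(c("cell_id", "drug_id") %in% names(pairs)))
  n <- nrow(pairs)
  folds <- vector("list", n_folds)
  if (mode == "random_pair") {
    strata <- if ("label" %in% names(pairs)) as.character(pairs$label) else rep("all", n)
    assign <- integer(n)
    with_seed(derive_seed(seed, "split_rp"), {
      # cyclic fold labels with a running offset: balanced within every
      # stratum and globally (fold sizes differ by at most one)
      offset <- 0L
      for (s in unique(strata)) {
        idx <- which(strata == s)
        lab <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
        assign[idx] <- lab[sample(length(idx))]
        offset <- (offset + length(idx)) %% n_folds
      }
    })
    for (f in seq_len(n_folds)) {
      folds[[f]] <- list(train = which(assign != f),
                         test = which(assign == f),
                         dropped = integer(0))
    }
  } else {
    cells <- unique(pairs$cell_id)
    drugs <- unique(pairs$drug_id)
    if (length(cells) < n_folds || length(drugs) < n_folds) {
      stop("disjoint_entity mode needs at least n_folds distinct cells ",
           "and drugs")
    }
    with_seed(derive_seed(seed, "split_de"), {
      cg <- (sample(seq_along(cells)) %% n_folds) + 1L
      dg <- (sample(seq_along(drugs)) %% n_folds) + 1L
    })
    cell_grp <- cg[match(pairs$cell_id, cells)]
    drug_grp <- dg[match(pairs$drug_id, drugs)]
    for (f in seq_len(n_folds)) {
      test <- which(cell_grp == f & drug_grp == f)
      train <- which(cell_grp != f & drug_grp != f)
      folds[[f]] <- list(train = train, test = test,
                         dropped = setdiff(seq_len(n), c(train, test)))
    }
  }
  structure(list(mode = mode, n_folds = n_folds, folds = folds,
                 n_pairs = n, seed = seed),
            class = "split_plan")
}

#' Hold out a final test set of pairs
#'
#' With `disjoint = TRUE`, roughly `test_fraction` of cell lines and of
#' drugs are reserved and the test set contains the pairs between
#' reserved entities only, so the held-out drugs and cell lines never
#' occur in the remainder (pairs straddling the boundary are dropped).
#'
#' @param pairs A data frame with `cell_id`, `drug_id`.
#' @param test_fraction Target fraction of pairs/entities held out.
#' @param disjoint Enforce entity disjointness (default TRUE).
#' @param seed Integer seed.
#' @return A list with integer indices `train`, `test`, `dropped`.
#' @export
make_holdout <- function(pairs, test_fraction = 0.1, disjoint = TRUE,
                         seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- nrow(pairs)
  if (!disjoint) {
    test <- with_seed(derive_seed(seed, "holdout"),
                      sample_exact(n, test_fraction))
    return(list(train = setdiff(seq_len(n), test), test = test,
                dropped = integer(0)))
  }
  cells <- unique(pairs$cell_id)
  drugs <- unique(pairs$drug_id)
  # entity fraction sqrt(test_fraction) so the test block of pairs is
  # approximately test_fraction of all pairs
  ef <- sqrt(test_fraction)
  hc <- with_seed(derive_seed(seed, "holdout_c"),
                  sample(cells, max(1L, round(ef * length(cells)))))
  hd <- with_seed(derive_seed(seed, "holdout_d"),
                  sample(drugs, max(1L, round(ef * length(drugs)))))
  in_hc <- pairs$cell_id %in% hc
  in_hd <- pairs$drug_id %in% hd
  test <- which(in_hc & in_hd)
  train <- which(!in_hc & !in_hd)
  list(train = train, test = test,
       dropped = setdiff(seq_len(n), c(train, test)))
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> mode=", x$mode, ", ", x$n_folds, " folds over ",
      x$n_pairs, " pairs\n", sep = "")
  for (f in seq_len(x$n_folds)) {
    fd <- x$folds[[f]]
    cat("  fold ", f, ": train ", length(fd$train), ", test ",
        length(fd$test),
        if (length(fd$dropped)) paste0(", dropped ", length(fd$dropped)),
        "\n", sep = "")
  }
  invisible(x)
}
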
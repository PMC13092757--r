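# Classification metrics (AUC by rank statistic, AUPR by step
# integration, thresholded precision/recall/F1) and paired significance
# tests for comparing two scorers on the same labels (DeLong for AUC,
# paired bootstrap for AUC/AUPR).

.check_two_classes <- function(labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)")
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in labels")
  }
  labels
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a random positive is
#' scored above a random negative, with ties counting one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- .check_two_classes(labels)
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (step integration)
#'
#' Thresholds sweep the distinct score values from high to low; the curve
#' is integrated as `sum (R_t - R_{t-1}) * P_t`. A constant scorer yields
#' a single point at recall 1 with precision equal to prevalence, so its
#' AUPR equals the prevalence.
#'
#' @inheritParams auc_score
#' @return AUPR in `[0, 1]`.
#' @export
aupr_score <- function(scores, labels) {
  labels <- .check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(s[-length(s)] != s[-1L], TRUE)   # last index of each threshold
  tp <- tp[keep]; fp <- fp[keep]
  n_pos <- sum(y)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Threshold and ranking metrics for one scorer
#'
#' @param scores Predicted probabilities.
#' @param labels Binary labels (1 = sensitive).
#' @param threshold Classification threshold for
#'   accuracy/precision/recall/F1 (default 0.5).
#' @return A one-row tibble with `auc`, `aupr`, `accuracy`, `precision`,
#'   `recall`, `f1`, `n`, `prevalence`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  labels <- .check_two_classes(labels)
  stopifnot(length(scores) == length(labels))
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(
    auc = auc_score(scores, labels),
    aupr = aupr_score(scores, labels),
    accuracy = mean(pred == labels),
    precision = precision,
    recall = recall,
    f1 = f1,
    n = length(labels),
    prevalence = mean(labels)
  )
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two scorers evaluated on the same labels, using
#' placement-value covariance estimates and a two-sided normal reference.
#'
#' @param scores_a,scores_b Scores of the two models on the same samples.
#' @param labels Shared binary labels.
#' @return A tibble with `auc_a`, `auc_b`, `delta`, `z`, `p_value`. When
#'   the variance of the difference is zero (e.g. identical scorers),
#'   `p_value` is 1 with a warning.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- .check_two_classes(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pos <- which(labels == 1); neg <- which(labels == 0)
  m <- length(pos); n <- length(neg)
  placements <- function(s) {
    xs <- s[pos]; ys <- s[neg]
    v10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)), 0)
    v01 <- vapply(ys, function(y) mean((xs > y) + 0.5 * (xs == y)), 0)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a); pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (var_delta <= .Machine$double.eps) {
    warning("zero variance of the AUC difference; p set to 1")
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z,
                 p_value = p)
}

#' Paired bootstrap p-value for a metric difference
#'
#' Resamples sample indices with replacement (jointly for both scorers)
#' and reports the fraction of resamples in which scorer `b` meets or
#' beats scorer `a` (ties count one half, so identical scorers give
#' p close to 0.5). Degenerate single-class resamples are redrawn and
#' counted.
#'
#' @param scores_a,scores_b Scores of the two models on the same samples.
#' @param labels Shared binary labels.
#' @param metric `"auc"` or `"aupr"`.
#' @param n_boot Number of bootstrap resamples (>= 1000).
#' @param seed Integer seed.
#' @return A single p-value, with attributes `n_boot` and `n_redrawn`.
#' @export
bootstrap_pvalue <- function(scores_a, scores_b, labels,
                             metric = c("auc", "aupr"), n_boot = 1000L,
                             seed = 1L) {
  metric <- match.arg(metric)
  labels <- .check_two_classes(labels)
  stopifnot(n_boot >= 1000L)
  mfun <- if (metric == "auc") auc_score else aupr_score
  n <- length(labels)
  wins <- numeric(n_boot)
  redrawn <- 0L
  with_seed(derive_seed(seed, "boot", metric), {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
        redrawn <- redrawn + 1L
        if (redrawn > 100L * n_boot) stop("too many degenerate resamples")
      }
      ma <- mfun(scores_a[idx], labels[idx])
      mb <- mfun(scores_b[idx], labels[idx])
      wins[b] <- (mb > ma) + 0.5 * (mb == ma)
    }
  })
  structure(mean(wins), n_boot = n_boot, n_redrawn = redrawn)
}
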
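# Synthetic cohort generator: desk-scale cohorts with the statistical
# structure the model assumes (shared low-rank cell latent across omics
# views, structure-informative drug latents, heavily imbalanced three-way
# response labels), so the full pipeline is testable offline.

VIEW_NAMES <- c("transcriptomics", "proteomics", "cnv", "mutations",
                "methylation", "metabolomics")

default_view_dims <- function() {
  c(transcriptomics = 128L, proteomics = 96L, cnv = 64L, mutations = 64L,
    methylation = 96L, metabolomics = 24L)
}

#' Load the packaged SMILES library
#'
#' Curated common-drug SMILES plus enumerated drug-like analogs, all
#' validated against the package's parser at build time.
#'
#' @return A tibble with columns `drug_id`, `smiles`, `source`, `n_atoms`.
#' @export
smiles_library <- function() {
  path <- system.file("extdata", "smiles_library.csv", package = "dragnet")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Generate a synthetic drug-response cohort
#'
#' Cell lines carry a shared k-dimensional latent `U` (standard normal);
#' every omics view is `U %*% W_view` plus view-specific Gaussian noise.
#' Drugs are drawn from the packaged SMILES library and their latent `V`
#' is taken from the leading principal directions of their hashed
#' structural fingerprints, so drug structure is informative about
#' response. The response score `s = U %*% t(V)` is cut at planted
#' quantiles: the top `labeled_frac * target_prevalence` fraction of pairs
#' receives log10 IC50 below -3 (sensitive), the next
#' `labeled_frac * (1 - target_prevalence)` fraction from the bottom
#' receives log10 IC50 above 3 (resistant), and the middle band falls
#' strictly inside (-3, 3) (uncorrelated), mirroring the roughly 1:9
#' sensitive:resistant imbalance of real screens. The IC50 map is a
#' monotone decreasing function of the score, so in the noiseless limit
#' the planted latent separates the classes perfectly and
#' [label_responses()] at the default thresholds reproduces the planted
#' classes exactly.
#'
#' @param n_cells,n_drugs Cohort size (the emulated full-scale study has
#'   192 cell lines and 352 drugs).
#' @param k_latent Latent dimensionality (default 8).
#' @param view_dims Named integer vector of per-view feature counts; all
#'   must be at least `k_latent`.
#' @param noise_sd View-specific noise standard deviation (signal columns
#'   have unit-scale variance).
#' @param target_prevalence Sensitive fraction among labeled (sensitive +
#'   resistant) pairs, in (0, 0.5).
#' @param labeled_frac Fraction of all pairs that receive a sensitive or
#'   resistant label (the rest are uncorrelated).
#' @param seed Integer root seed; regenerating with the same arguments is
#'   bit-identical.
#' @return An object of class `synthetic_cohort`: `omics`
#'   (an [omics_profile_set()]), `smiles` (tibble `drug_id`, `smiles`),
#'   `responses` (tibble `cell_id`, `drug_id`, `log_ic50`), and `truth`
#'   (latents `U`, `V`, score matrix, bias, noise scale, seed).
#' @examples
#' co <- generate_cohort(n_cells = 12, n_drugs = 8, k_latent = 2, seed = 1)
#' nrow(co$responses)  # 96 pairs
#' @export
generate_cohort <- function(n_cells = 192L, n_drugs = 352L, k_latent = 8L,
                            view_dims = default_view_dims(),
                            noise_sd = 0.3, target_prevalence = 0.10,
                            labeled_frac = 0.44, seed = 1L) {
  stopifnot(n_cells >= 1L, n_drugs >= 1L, k_latent >= 1L,
            noise_sd >= 0, labeled_frac > 0, labeled_frac <= 1)
  if (!(target_prevalence > 0 && target_prevalence < 0.5)) {
    stop("target_prevalence must be in (0, 0.5)")
  }
  if (any(view_dims < k_latent)) {
    stop("all view_dims must be >= k_latent (latent not recoverable from ",
         "views ", paste(names(view_dims)[view_dims < k_latent],
                         collapse = ", "), ")")
  }
  lib <- smiles_library()
  if (n_drugs > nrow(lib)) {
    stop("n_drugs exceeds the packaged SMILES library (",
         nrow(lib), " entries)")
  }

  # drugs and structure-derived latents
  lib_rows <- with_seed(derive_seed(seed, "drugs"),
                        sample.int(nrow(lib), n_drugs))
  smiles <- tibble::tibble(drug_id = sprintf("D%04d", seq_len(n_drugs)),
                           smiles = lib$smiles[lib_rows],
                           library_id = lib$drug_id[lib_rows])
  graphs <- parse_smiles_set(smiles)
  fp <- drug_fingerprints(graphs)
  V <- with_seed(derive_seed(seed, "drug_latent"),
                 .fingerprint_latent(fp, k_latent))
  rownames(V) <- smiles$drug_id

  # cell latents and omics views
  cell_ids <- sprintf("CL%04d", seq_len(n_cells))
  U <- with_seed(derive_seed(seed, "cell_latent"),
                 matrix(stats::rnorm(n_cells * k_latent), n_cells, k_latent))
  rownames(U) <- cell_ids
  views <- list()
  for (vi in seq_along(view_dims)) {
    nm <- names(view_dims)[vi] %||% VIEW_NAMES[vi]
    d <- view_dims[[vi]]
    W <- with_seed(derive_seed(seed, "loadings", vi),
                   matrix(stats::rnorm(k_latent * d), k_latent, d) /
                     sqrt(k_latent))
    eps <- with_seed(derive_seed(seed, "noise", vi),
                     matrix(stats::rnorm(n_cells * d), n_cells, d))
    m <- U %*% W + noise_sd * eps
    colnames(m) <- sprintf("%s_f%03d", substr(nm, 1, 4), seq_len(d))
    views[[nm]] <- m
  }
  omics <- omics_profile_set(views, cell_ids)

  # response scores -> planted three-way labels -> log10 IC50
  s <- U %*% t(V)
  n_pairs <- n_cells * n_drugs
  n_sens <- max(1L, round(labeled_frac * target_prevalence * n_pairs))
  n_res <- max(1L, round(labeled_frac * (1 - target_prevalence) * n_pairs))
  stopifnot(n_sens + n_res <= n_pairs)
  ord <- order(s, decreasing = TRUE)       # 1 = strongest response
  rnk <- integer(n_pairs); rnk[ord] <- seq_len(n_pairs)
  log_ic50 <- .rank_to_ic50(rnk, n_sens, n_res, n_pairs)

  idx <- arrayInd(seq_len(n_pairs), dim(s))
  responses <- tibble::tibble(
    cell_id = cell_ids[idx[, 1L]],
    drug_id = smiles$drug_id[idx[, 2L]],
    log_ic50 = log_ic50
  )

  structure(
    list(
      omics = omics,
      smiles = smiles[, c("drug_id", "smiles")],
      responses = responses,
      truth = list(U = U, V = V, score = s,
                   bias = -sort(s, decreasing = TRUE)[n_sens],
                   noise_sd = noise_sd, seed = seed,
                   n_sensitive = n_sens, n_resistant = n_res,
                   target_prevalence = target_prevalence,
                   labeled_frac = labeled_frac),
      drug_graphs = graphs,
      fingerprints = fp,
      degraded = FALSE
    ),
    class = "synthetic_cohort"
  )
}

# monotone decreasing map from score rank (1 = strongest) to log10 IC50:
# sensitive band -> [-6, -3), uncorrelated -> (-2.9, 2.9), resistant ->
# (3, 6]; strict inequalities guarantee exact label recovery
.rank_to_ic50 <- function(rnk, n_sens, n_res, n_pairs) {
  n_unc <- n_pairs - n_sens - n_res
  out <- numeric(n_pairs)
  in_sens <- rnk <= n_sens
  in_res <- rnk > n_pairs - n_res
  in_unc <- !in_sens & !in_res
  band_pos <- function(r, lo, width) if (width > 1) (r - lo) / (width - 1) else rep(0.5, length(r))
  out[in_sens] <- -6 + 2.99 * band_pos(rnk[in_sens], 1L, n_sens)
  if (n_unc > 0L) {
    out[in_unc] <- -2.9 + 5.8 * band_pos(rnk[in_unc], n_sens + 1L, n_unc)
  }
  out[in_res] <- 3.01 + 2.99 * band_pos(rnk[in_res], n_pairs - n_res + 1L, n_res)
  out
}

# leading principal-component scores of the fingerprint matrix, each
# column rescaled to unit variance; rank-deficient directions are padded
# with standard normal draws
.fingerprint_latent <- function(fp, k) {
  cf <- scale(fp, center = TRUE, scale = FALSE)
  sv <- svd(cf, nu = min(k, nrow(fp)), nv = 0)
  keep <- which(sv$d[seq_len(min(k, length(sv$d)))] > 1e-8)
  V <- matrix(0, nrow(fp), k)
  if (length(keep) > 0L) {
    sc <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
    V[, keep] <- scale(sc)
  }
  if (length(keep) < k) {
    pad <- setdiff(seq_len(k), keep)
    V[, pad] <- stats::rnorm(nrow(fp) * length(pad))
  }
  V
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$omics$cell_ids), " cells x ",
      nrow(x$smiles), " drugs, ", nrow(x$responses), " response records",
      if (x$degraded) " (degraded)", "\n", sep = "")
  invisible(x)
}

#' Introduce missingness into a cohort's omics views
#'
#' Sets exactly `round(missing_frac * length(view))` entries of every view
#' to `NA`, uniformly at random; the planted truth is untouched. The same
#' seed always produces the same missing mask.
#'
#' @param cohort A [generate_cohort()] result.
#' @param missing_frac Fraction of entries per view to blank, in `[0, 1)`.
#' @param seed Integer seed.
#' @return The cohort with degraded omics (marked `degraded = TRUE`).
#' @export
degrade_cohort <- function(cohort, missing_frac, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            missing_frac >= 0, missing_frac < 1)
  if (missing_frac == 0) return(cohort)
  for (vi in seq_along(cohort$omics$views)) {
    m <- cohort$omics$views[[vi]]
    hit <- with_seed(derive_seed(seed, "degrade", vi),
                     sample_exact(length(m), missing_frac))
    m[hit] <- NA_real_
    cohort$omics$views[[vi]] <- m
  }
  cohort$degraded <- TRUE
  cohort
}

#' Write a cohort to disk in the formats the readers consume
#'
#' Omics views become per-view CSVs (`<view>.csv`, id column + features),
#' drugs `drugs.csv` (`drug_id`, `smiles`), responses `responses.csv`
#' (`cell_id`, `drug_id`, `log_ic50`), and the planted latents
#' `truth_U.csv` / `truth_V.csv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(cohort$omics$views)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    df <- tibble::as_tibble(cohort$omics$views[[nm]])
    df <- tibble::add_column(df, cell_id = cohort$omics$cell_ids,
                             .before = 1L)
    readr::write_csv(df, p)
    paths[nm] <- p
  }
  readr::write_csv(cohort$smiles, file.path(dir, "drugs.csv"))
  readr::write_csv(cohort$responses, file.path(dir, "responses.csv"))
  for (nm in c("U", "V")) {
    m <- cohort$truth[[nm]]
    df <- tibble::as_tibble(m, .name_repair = ~ sprintf("k%02d", seq_along(.x)))
    df <- tibble::add_column(df, id = rownames(m), .before = 1L)
    readr::write_csv(df, file.path(dir, paste0("truth_", nm, ".csv")))
  }
  paths["drugs"] <- file.path(dir, "drugs.csv")
  paths["responses"] <- file.path(dir, "responses.csv")
  invisible(paths)
}
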
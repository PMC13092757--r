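# SMILES -> molecular graph conversion and hashed structural fingerprints.
#
# Chemistry parsing is delegated to OpenBabel (via ChemmineR / ChemmineOB);
# this file only assembles the parsed atoms and bonds into the atom-feature
# matrix / adjacency representation the drug encoder consumes.

ELEMENT_SET <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "other")
MAX_DEGREE <- 6L
MAX_HCOUNT <- 4L

# default valences used to infer implicit hydrogen counts from the
# (kekulized) bond orders OpenBabel reports
.default_valence <- c(C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1, Br = 1,
                      I = 1, P = 3, B = 3, Si = 4)

#' Convert a SMILES string to a molecular graph
#'
#' Parses a SMILES string with OpenBabel and returns the heavy-atom graph:
#' an atom feature matrix (element one-hot, degree one-hot, aromaticity
#' flag, formal charge, implicit hydrogen-count one-hot) and a symmetric
#' bond adjacency matrix with bond orders stored alongside. Hydrogens stay
#' implicit. Multi-fragment inputs (salts) are reduced to their largest
#' connected fragment with a warning.
#'
#' @param smiles A single SMILES string.
#' @param drug_id Optional identifier attached to the result.
#' @return An object of class `molecular_graph`: a list with `atom_features`
#'   (N_d x feature-width numeric matrix), `adjacency` (N_d x N_d binary,
#'   symmetric, zero diagonal), `bond_order` (same shape, bond orders),
#'   `elements`, `aromatic`, `n_atoms`, `n_fragments`, `drug_id`, `smiles`.
#' @examples
#' g <- smiles_to_graph("CCO")
#' g$n_atoms  # 3 heavy atoms
#' @export
smiles_to_graph <- function(smiles, drug_id = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  parsed <- tryCatch(
    .parse_one_smiles(smiles),
    error = function(e) {
      stop("cannot parse SMILES string: '", smiles, "'", call. = FALSE)
    }
  )
  elements <- parsed$elements
  n <- length(elements)
  if (n < 1L) stop("cannot parse SMILES string: '", smiles, "'", call. = FALSE)

  adj <- matrix(0, n, n)
  bord <- matrix(0, n, n)
  if (nrow(parsed$bonds) > 0L) {
    for (b in seq_len(nrow(parsed$bonds))) {
      i <- parsed$bonds[b, 1L]; j <- parsed$bonds[b, 2L]; o <- parsed$bonds[b, 3L]
      adj[i, j] <- adj[j, i] <- 1
      bord[i, j] <- bord[j, i] <- o
    }
  }

  comp <- .graph_components(adj)
  n_frag <- max(comp)
  keep <- seq_len(n)
  if (n_frag > 1L) {
    warning("SMILES '", smiles, "' has ", n_frag,
            " disconnected fragments; keeping the largest")
    main <- which.max(tabulate(comp))
    keep <- which(comp == main)
    adj <- adj[keep, keep, drop = FALSE]
    bord <- bord[keep, keep, drop = FALSE]
    elements <- elements[keep]
  }
  aromatic <- parsed$aromatic[keep]
  charge <- parsed$charge[keep]

  degree <- rowSums(adj)
  # implicit H from default valence minus bonded order (aromatic atoms get
  # kekulized orders from OpenBabel, so the order sum is well defined)
  valence <- unname(.default_valence[elements])
  valence[is.na(valence)] <- rowSums(bord)[is.na(valence)]
  # isoelectronic rule: formal charge shifts the effective valence
  # (N+ binds 4, O- binds 1, ...)
  hcount <- pmax(0, round(valence - rowSums(bord) + charge))
  hcount <- pmin(hcount, MAX_HCOUNT)

  feats <- .atom_feature_matrix(elements, degree, aromatic, charge, hcount)

  structure(
    list(
      atom_features = feats,
      adjacency = adj,
      bond_order = bord,
      elements = elements,
      aromatic = aromatic,
      formal_charge = charge,
      n_atoms = length(elements),
      n_fragments = n_frag,
      drug_id = drug_id %||% smiles,
      smiles = smiles
    ),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", x$drug_id, ": ", x$n_atoms, " heavy atoms, ",
      sum(x$adjacency) / 2, " bonds, ", sum(x$aromatic), " aromatic atoms\n",
      sep = "")
  invisible(x)
}

# session-level parse cache keyed by SMILES string (OpenBabel calls
# dominate cohort assembly time)
.parse_cache <- new.env(parent = emptyenv())

# run OpenBabel once for connectivity/charges (MOL block) and once for
# aromaticity (molreport atom types); both outputs share atom order
.parse_one_smiles <- function(smiles) {
  key <- paste0("s", hash_to_bit(smiles, 2147483587L), "_", nchar(smiles))
  hit <- .parse_cache[[key]]
  if (!is.null(hit) && identical(hit$smiles, smiles)) return(hit$parsed)
  parsed <- .parse_one_smiles_uncached(smiles)
  .parse_cache[[key]] <- list(smiles = smiles, parsed = parsed)
  parsed
}

.parse_one_smiles_uncached <- function(smiles) {
  mol <- ChemmineOB::convertFormat("SMI", "MOL", source = smiles)
  lines <- strsplit(mol, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("empty conversion")
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1L, 3L))
  n_bonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(n_atoms) || n_atoms < 1L) stop("no atoms")
  atom_lines <- lines[4L + seq_len(n_atoms)]
  elements <- trimws(substr(atom_lines, 32L, 34L))
  bonds <- matrix(0L, n_bonds, 3L)
  if (n_bonds > 0L) {
    bond_lines <- lines[4L + n_atoms + seq_len(n_bonds)]
    bonds[, 1L] <- as.integer(substr(bond_lines, 1L, 3L))
    bonds[, 2L] <- as.integer(substr(bond_lines, 4L, 6L))
    bonds[, 3L] <- as.integer(substr(bond_lines, 7L, 9L))
  }
  charge <- numeric(n_atoms)
  for (cl in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "\\s+")[[1]])
    k <- toks[1L]
    for (i in seq_len(k)) {
      charge[toks[2L * i]] <- toks[2L * i + 1L]
    }
  }

  rep_txt <- ChemmineOB::convertFormat("SMI", "molreport", source = smiles)
  rep_lines <- strsplit(rep_txt, "\n", fixed = TRUE)[[1]]
  type_lines <- grep("^ATOM:", rep_lines, value = TRUE)
  types <- sub(".*TYPE:\\s*(\\S+).*", "\\1", type_lines)
  aromatic <- grepl("ar$", types)
  if (length(aromatic) != n_atoms) aromatic <- rep(FALSE, n_atoms)
  # heteroatoms inside aromatic rings (furan O, thiophene S) are typed
  # plainly by OpenBabel; flag them when >= 2 ring neighbours are aromatic
  if (n_bonds > 0L && any(aromatic)) {
    for (i in which(!aromatic & elements %in% c("O", "S", "N"))) {
      nb <- c(bonds[bonds[, 1L] == i, 2L], bonds[bonds[, 2L] == i, 1L])
      if (sum(aromatic[nb]) >= 2L) aromatic[i] <- TRUE
    }
  }
  list(elements = elements, bonds = bonds, charge = charge, aromatic = aromatic)
}

.atom_feature_matrix <- function(elements, degree, aromatic, charge, hcount) {
  n <- length(elements)
  el <- ifelse(elements %in% ELEMENT_SET, elements, "other")
  el_oh <- matrix(0, n, length(ELEMENT_SET),
                  dimnames = list(NULL, paste0("el_", ELEMENT_SET)))
  el_oh[cbind(seq_len(n), match(el, ELEMENT_SET))] <- 1
  dg <- pmin(pmax(degree, 0L), MAX_DEGREE)
  dg_oh <- matrix(0, n, MAX_DEGREE + 1L,
                  dimnames = list(NULL, paste0("deg_", 0:MAX_DEGREE)))
  dg_oh[cbind(seq_len(n), dg + 1L)] <- 1
  h_oh <- matrix(0, n, MAX_HCOUNT + 1L,
                 dimnames = list(NULL, paste0("h_", 0:MAX_HCOUNT)))
  h_oh[cbind(seq_len(n), hcount + 1L)] <- 1
  cbind(el_oh, dg_oh, aromatic = as.numeric(aromatic),
        charge = as.numeric(charge), h_oh)
}

# atom-feature width of the fixed featurization (needed to size encoders)
atom_feature_width <- function() {
  length(ELEMENT_SET) + (MAX_DEGREE + 1L) + 1L + 1L + (MAX_HCOUNT + 1L)
}

# connected components of a symmetric 0/1 adjacency by BFS
.graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Parse a table of SMILES strings into molecular graphs
#'
#' @param drugs A data frame with columns `drug_id` and `smiles`.
#' @param on_error `"stop"` to fail on the first unparseable SMILES,
#'   `"drop"` to skip it with a warning.
#' @return A named list of [smiles_to_graph()] results.
#' @export
parse_smiles_set <- function(drugs, on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  stopifnot(all(c("drug_id", "smiles") %in% names(drugs)))
  out <- list()
  for (i in seq_len(nrow(drugs))) {
    g <- tryCatch(
      smiles_to_graph(drugs$smiles[i], drug_id = drugs$drug_id[i]),
      error = function(e) e
    )
    if (inherits(g, "error")) {
      if (on_error == "stop") stop(conditionMessage(g), call. = FALSE)
      warning("dropping ", drugs$drug_id[i], ": ", conditionMessage(g))
    } else {
      out[[drugs$drug_id[i]]] <- g
    }
  }
  out
}

#' Hashed structural fingerprints for molecular graphs
#'
#' Circular (Morgan-style) substructure fingerprints: atom environments of
#' radius 0..`radius` are canonicalised by iterative neighbourhood label
#' refinement and hashed into a fixed-width bit vector with an in-package
#' deterministic string hash, so fingerprints are stable across sessions.
#'
#' @param graphs A list of `molecular_graph` objects.
#' @param nbits Fingerprint width in bits (default 2048).
#' @param radius Maximum environment radius (default 2).
#' @return A binary matrix with one row per graph, `nbits` columns, row
#'   names taken from drug ids.
#' @export
drug_fingerprints <- function(graphs, nbits = 2048L, radius = 2L) {
  fp <- matrix(0L, length(graphs), nbits,
               dimnames = list(vapply(graphs, function(g) g$drug_id, ""), NULL))
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    lab <- paste0(g$elements, "|d", rowSums(g$adjacency),
                  "|a", as.integer(g$aromatic), "|c", g$formal_charge)
    for (r in 0:radius) {
      for (l in unique(lab)) fp[gi, hash_to_bit(paste0("r", r, ":", l), nbits)] <- 1L
      if (r == radius) break
      new_lab <- character(g$n_atoms)
      for (i in seq_len(g$n_atoms)) {
        nb <- which(g$adjacency[i, ] > 0)
        nb_lab <- sort(paste0(g$bond_order[i, nb], "~", lab[nb]))
        new_lab[i] <- paste0(lab[i], "(", paste(nb_lab, collapse = ","), ")")
      }
      lab <- new_lab
    }
  }
  fp
}

#' Tanimoto similarity between fingerprint rows
#'
#' @param fp Binary fingerprint matrix (rows = molecules).
#' @return Symmetric similarity matrix in `[0, 1]`; rows with empty
#'   fingerprints have similarity 0 against everything.
#' @export
tanimoto_similarity <- function(fp) {
  fp <- as.matrix(fp)
  inter <- tcrossprod(fp)
  counts <- rowSums(fp)
  uni <- outer(counts, counts, "+") - inter
  sim <- ifelse(uni > 0, inter / uni, 0)
  diag(sim) <- 1
  dimnames(sim) <- list(rownames(fp), rownames(fp))
  sim
}
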
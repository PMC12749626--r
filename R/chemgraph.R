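# Molecular graph featurization: one-hot atom features, covalent edges,
# reaction-condition one-hots, Fourier-encoded interatomic distances and a
# seeded 3D conformer embedder.

GRAPH_ELEMENTS <- c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I",
                    "Si", "Se")
HYBRIDIZATIONS <- c("SP3", "SP2", "SP", "S")
CONDITION_CATEGORIES <- c("reagent", "solvent", "catalyst", "additive",
                          "atmosphere")

COVALENT_RADIUS <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Se = 1.20, Br = 1.20, I = 1.39
)

#' One-hot atom featurization
#'
#' Encodes an atom as the concatenation of four mutually exclusive one-hot
#' blocks: 12 element types (H, C, N, O, F, P, S, Cl, Br, I, Si, Se), ring
#' membership (2), aromaticity (2) and hybridization (SP3, SP2, SP, S; "S"
#' covers hydrogen and other unhybridized atoms).  Total length 20 with
#' exactly four bits set.
#'
#' @param element element symbol, one of the 12 supported types.
#' @param in_ring logical, atom is part of a ring.
#' @param aromatic logical, atom is aromatic.
#' @param hybridization one of `"SP3"`, `"SP2"`, `"SP"`, `"S"`.
#' @return numeric vector of length 20.
#' @export
#' @examples
#' featurize_atom("C", in_ring = TRUE, aromatic = TRUE, hybridization = "SP2")
featurize_atom <- function(element, in_ring, aromatic, hybridization) {
  if (!element %in% GRAPH_ELEMENTS) {
    stop_mf("unsupported_atom_error",
            "unsupported atom type '%s' (supported: %s)",
            element, paste(GRAPH_ELEMENTS, collapse = ", "))
  }
  if (!hybridization %in% HYBRIDIZATIONS) {
    stop_mf("argument_error", "unknown hybridization label '%s'",
            hybridization)
  }
  v <- numeric(20)
  v[match(element, GRAPH_ELEMENTS)] <- 1
  v[12L + if (isTRUE(in_ring)) 1L else 2L] <- 1
  v[14L + if (isTRUE(aromatic)) 1L else 2L] <- 1
  v[16L + match(hybridization, HYBRIDIZATIONS)] <- 1
  v
}

#' Geometrically spaced Fourier frequency basis
#'
#' Default basis of `k` frequencies whose half-periods (pi / f) span 0.5 to
#' 12 angstrom, covering covalent bond lengths up to through-space distances.
#'
#' @param k number of frequencies.
#' @return numeric vector of `k` frequencies (1/angstrom), decreasing.
#' @export
fourier_frequencies <- function(k = 16L) {
  assert_that(k >= 1L, "argument_error", "k must be >= 1")
  half_periods <- exp(seq(log(0.5), log(12), length.out = k))
  pi / half_periods
}

#' Fourier encoding of a scalar distance
#'
#' Encodes distances r as `[sin(f_1 r), ..., sin(f_K r), cos(f_1 r), ...,
#' cos(f_K r)]`.
#'
#' @param r non-negative distance(s) in angstrom.
#' @param frequencies numeric vector of K frequencies.
#' @return for scalar `r`, a numeric vector of length 2K; for vector `r`, a
#'   matrix with one row per distance.
#' @export
fourier_distance <- function(r, frequencies = fourier_frequencies()) {
  if (any(r < 0)) stop_mf("argument_error", "distances must be non-negative")
  outerp <- outer(r, frequencies)
  enc <- cbind(sin(outerp), cos(outerp))
  if (length(r) == 1L) drop(enc) else enc
}

#' Convert a structure to a featurized molecular graph
#'
#' Parses a SMILES string, makes hydrogens explicit, and returns atom feature
#' vectors, covalent bond edges, and (optionally) a seeded ensemble of 3D
#' conformer coordinates produced by the package's distance-geometry embedder.
#'
#' @param smiles structure as SMILES.
#' @param with_conformers generate a conformer ensemble.
#' @param n_conformers number of conformers (default 10).
#' @param seed integer seed driving the (stochastic) embedding; the same
#'   structure and seed give bitwise identical coordinates.
#' @return an object of class `mf_graph`: list with `features` (n x 20
#'   matrix), `edges` (m x 2 matrix of 1-based undirected atom index pairs),
#'   `elements`, `n_heavy`, `smiles` and `conformers` (list of n x 3 coordinate
#'   matrices, or `NULL`).
#' @export
#' @examples
#' g <- mol_to_graph("C")  # methane: 5 atoms, 4 edges
#' nrow(g$features); nrow(g$edges)
mol_to_graph <- function(smiles, with_conformers = FALSE, n_conformers = 10L,
                         seed = 1L) {
  mol <- parse_smiles(smiles)
  n_heavy <- nrow(mol$atoms)

  elements <- mol$atoms$element
  in_ring <- mol$atoms$in_ring
  aromatic <- mol$atoms$aromatic
  hyb <- mol$atoms$hyb
  edges <- as.matrix(mol$bonds[, c("i", "j"), drop = FALSE])

  # explicit hydrogens appended after the heavy atoms, parent-major order
  h_parent <- rep(seq_len(n_heavy), mol$atoms$nH)
  nH_total <- length(h_parent)
  if (nH_total > 0L) {
    h_idx <- n_heavy + seq_len(nH_total)
    elements <- c(elements, rep("H", nH_total))
    in_ring <- c(in_ring, rep(FALSE, nH_total))
    aromatic <- c(aromatic, rep(FALSE, nH_total))
    hyb <- c(hyb, rep("S", nH_total))
    edges <- rbind(edges, cbind(h_parent, h_idx))
  }
  n <- length(elements)

  feats <- matrix(0, nrow = n, ncol = 20L)
  for (a in seq_len(n)) {
    feats[a, ] <- featurize_atom(elements[a], in_ring[a], aromatic[a], hyb[a])
  }
  dimnames(edges) <- NULL

  g <- structure(
    list(smiles = smiles, features = feats, edges = edges,
         elements = elements, n_heavy = n_heavy, conformers = NULL),
    class = "mf_graph"
  )
  if (isTRUE(with_conformers)) {
    assert_that(n_conformers >= 1L, "argument_error",
                "n_conformers must be >= 1")
    g$conformers <- embed_conformers(g, mol, n_conformers, seed)
  }
  g
}

#' @export
print.mf_graph <- function(x, ...) {
  cat(sprintf("<mf_graph> %s: %d atoms (%d heavy), %d bonds, %s conformers\n",
              x$smiles, length(x$elements), x$n_heavy, nrow(x$edges),
              if (is.null(x$conformers)) "no" else length(x$conformers)))
  invisible(x)
}

# ---- conformer embedding ----------------------------------------------------

# Seeded distance-geometry-style embedder: random initial coordinates refined
# by gradient descent on a harmonic force field with bond-length terms
# (covalent radii sums, shortened for higher bond order), 1-3 angle terms
# (ideal angle by hybridization of the central atom) and a soft repulsion
# between atoms three or more bonds apart.  Distinct conformers come from
# distinct random initializations relaxing into different local minima.
embed_conformers <- function(g, mol, n_conformers, seed) {
  terms <- forcefield_terms(g, mol)
  n <- length(g$elements)
  out <- vector("list", n_conformers)
  for (c_i in seq_len(n_conformers)) {
    coords <- NULL
    for (attempt in 0:4) {
      s <- derive_seed(seed, sprintf("conformer-%d-%d", c_i, attempt))
      cand <- with_seed(s, try_embed(n, terms))
      if (!is.null(cand)) { coords <- cand; break }
    }
    if (is.null(coords)) {
      stop_mf("conformer_error",
              "conformer embedding failed after 5 attempts for '%s'",
              g$smiles)
    }
    out[[c_i]] <- coords
  }
  out
}

forcefield_terms <- function(g, mol) {
  n <- length(g$elements)
  edges <- g$edges
  r <- COVALENT_RADIUS[g$elements]
  # bond order lookup (explicit-H bonds are single)
  order <- rep(1, nrow(edges))
  nb <- nrow(mol$bonds)
  if (nb > 0L) order[seq_len(nb)] <- mol$bonds$order
  t_bond <- (r[edges[, 1]] + r[edges[, 2]]) * (1 - 0.06 * (order - 1))

  # adjacency & BFS graph distances (small molecules; dense is fine)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  gd <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    gd[s, s] <- 0; q <- s
    while (length(q) > 0L) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) {
        if (is.infinite(gd[s, w])) { gd[s, w] <- gd[s, v] + 1; q <- c(q, w) }
      }
    }
  }

  # 1-3 terms with ideal angle from the central atom's hybridization
  hyb_all <- c(mol$atoms$hyb, rep("S", n - nrow(mol$atoms)))
  a13 <- list(i = integer(), j = integer(), t = numeric())
  for (b in seq_len(n)) {
    nbrs <- adj[[b]]
    if (length(nbrs) < 2L) next
    theta <- switch(hyb_all[b], SP3 = 109.47, SP2 = 120, SP = 180, S = 109.47)
    theta <- theta * pi / 180
    for (p in seq_len(length(nbrs) - 1L)) {
      for (q in seq(p + 1L, length(nbrs))) {
        i <- nbrs[p]; j <- nbrs[q]
        e_bi <- which((edges[, 1] == b & edges[, 2] == i) |
                      (edges[, 1] == i & edges[, 2] == b))[1]
        e_bj <- which((edges[, 1] == b & edges[, 2] == j) |
                      (edges[, 1] == j & edges[, 2] == b))[1]
        d1 <- t_bond[e_bi]; d2 <- t_bond[e_bj]
        a13$i <- c(a13$i, i); a13$j <- c(a13$j, j)
        a13$t <- c(a13$t, sqrt(d1^2 + d2^2 - 2 * d1 * d2 * cos(theta)))
      }
    }
  }

  rep_pairs <- which(gd >= 3 & upper.tri(gd), arr.ind = TRUE)
  list(
    bi = edges[, 1], bj = edges[, 2], bt = t_bond,
    ai = a13$i, aj = a13$j, at = a13$t,
    ri = rep_pairs[, 1], rj = rep_pairs[, 2],
    n = n
  )
}

try_embed <- function(n, terms, n_iter = 300L) {
  x <- matrix(stats::rnorm(n * 3, sd = 1.5), ncol = 3)
  pi_ <- c(terms$bi, terms$ai, terms$ri)
  pj_ <- c(terms$bj, terms$aj, terms$rj)
  tgt <- c(terms$bt, terms$at, rep(2.1, length(terms$ri)))
  w <- c(rep(4, length(terms$bi)), rep(1, length(terms$ai)),
         rep(0.6, length(terms$ri)))
  repulsive <- c(rep(FALSE, length(terms$bi) + length(terms$ai)),
                 rep(TRUE, length(terms$ri)))
  for (it in seq_len(n_iter)) {
    lr <- 0.12 * (1 - it / (n_iter + 1)) + 0.01
    d <- x[pi_, , drop = FALSE] - x[pj_, , drop = FALSE]
    dist <- sqrt(rowSums(d * d)) + 1e-9
    dEdd <- 2 * w * (dist - tgt)
    dEdd[repulsive & dist >= tgt] <- 0
    coef <- dEdd / dist
    gvec <- d * coef
    grad <- rowsum(gvec, pi_, reorder = FALSE)
    grad_j <- rowsum(-gvec, pj_, reorder = FALSE)
    gmat <- matrix(0, n, 3)
    gmat[as.integer(rownames(grad)), ] <- gmat[as.integer(rownames(grad)), ] + grad
    gmat[as.integer(rownames(grad_j)), ] <-
      gmat[as.integer(rownames(grad_j)), ] + grad_j
    gn <- sqrt(sum(gmat^2)) + 1e-12
    step <- min(lr, 2 / gn)
    x <- x - step * gmat
  }
  # success check: bond lengths close to target
  d <- x[terms$bi, , drop = FALSE] - x[terms$bj, , drop = FALSE]
  dist <- sqrt(rowSums(d * d))
  if (sqrt(mean((dist - terms$bt)^2)) > 0.25) return(NULL)
  x - matrix(colMeans(x), n, 3, byrow = TRUE)
}

# ---- reaction condition encoding --------------------------------------------

#' Build a reaction-condition vocabulary
#'
#' Collects the labels of the five condition categories (reagent, solvent,
#' catalyst, additive, atmosphere) in first-appearance order.
#'
#' @param x a `reaction_dataset` or a data.frame of reaction records.
#' @param unk categories (subset of the five names) for which an `"<UNK>"`
#'   level is appended so unseen labels can be encoded; by default none, and
#'   unseen labels raise a vocabulary error at encoding time.
#' @return named list of character vectors, class `mf_condition_vocab`.
#' @export
condition_vocabulary <- function(x, unk = character()) {
  rec <- if (inherits(x, "reaction_dataset")) x$records else x
  bad <- setdiff(unk, CONDITION_CATEGORIES)
  assert_that(length(bad) == 0L, "argument_error",
              "unknown condition categories: %s", paste(bad, collapse = ","))
  vocab <- lapply(CONDITION_CATEGORIES, function(cat) {
    labels <- unique(as.character(rec[[cat]]))
    assert_that(!anyNA(labels) && all(nzchar(labels)), "validation_error",
                "empty %s label in records", cat)
    if (cat %in% unk) labels <- c(labels, "<UNK>")
    labels
  })
  names(vocab) <- CONDITION_CATEGORIES
  structure(vocab, class = "mf_condition_vocab")
}

#' One-hot encode the conditions of a reaction record
#'
#' Concatenates one one-hot block per condition category, in the order
#' reagent, solvent, catalyst, additive, atmosphere.  Exactly five bits are
#' set; with the 4/4/11/4/2 vocabulary of the training plate data the vector
#' has length 25.
#'
#' @param record a single reaction record (one-row data.frame or named list
#'   with `reagent`, `solvent`, `catalyst`, `additive`, `atmosphere`).
#' @param vocab an `mf_condition_vocab`.
#' @return numeric one-hot vector.
#' @export
encode_conditions <- function(record, vocab) {
  blocks <- lapply(CONDITION_CATEGORIES, function(cat) {
    labels <- vocab[[cat]]
    lab <- as.character(record[[cat]])
    if (length(lab) != 1L || is.na(lab)) {
      stop_mf("validation_error", "record lacks a %s label", cat)
    }
    pos <- match(lab, labels)
    if (is.na(pos)) {
      if ("<UNK>" %in% labels) pos <- match("<UNK>", labels)
      else stop_mf("vocabulary_error",
                   "unknown %s label '%s' (UNK disabled for this category)",
                   cat, lab)
    }
    v <- numeric(length(labels)); v[pos] <- 1; v
  })
  unlist(blocks, use.names = FALSE)
}

condition_vector_length <- function(vocab) {
  sum(lengths(vocab))
}

# ---- conformer export -------------------------------------------------------

#' Write a conformer ensemble to a multi-record SDF file
#'
#' @param graph an `mf_graph` with conformers.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_conformers_sdf <- function(graph, path) {
  assert_that(!is.null(graph$conformers), "argument_error",
              "graph has no conformers")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(graph$conformers)) {
    xyz <- graph$conformers[[k]]
    n <- nrow(xyz); m <- nrow(graph$edges)
    writeLines(c(sprintf("%s conformer %d", graph$smiles, k),
                 "  miniscifunnel", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m), con)
    for (a in seq_len(n)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         xyz[a, 1], xyz[a, 2], xyz[a, 3], graph$elements[a]),
                 con)
    }
    for (b in seq_len(m)) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", graph$edges[b, 1],
                         graph$edges[b, 2], 1L), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
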
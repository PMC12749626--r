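# Virtual library enumeration: Minisci alkylation products from
# N-heteroaromatic scaffolds and carboxylic acids via template application
# (decarboxylative C-H alkylation: the acid's carboxyl group leaves as CO2
# and the remaining alkyl fragment replaces a ring C-H).

# locate carboxylic-acid groups: non-aromatic C bonded to =O and -O(H)
find_carboxyl_groups <- function(mol) {
  groups <- list()
  b <- mol$bonds
  for (a in seq_len(nrow(mol$atoms))) {
    if (mol$atoms$element[a] != "C" || mol$atoms$aromatic[a]) next
    rows <- which(b$i == a | b$j == a)
    nbr <- ifelse(b$i[rows] == a, b$j[rows], b$i[rows])
    ord <- b$order[rows]
    o_double <- nbr[mol$atoms$element[nbr] == "O" & ord == 2]
    o_single <- nbr[mol$atoms$element[nbr] == "O" & ord == 1 &
                      (mol$atoms$nH[nbr] >= 1L | mol$atoms$charge[nbr] == -1L)]
    other <- nbr[mol$atoms$element[nbr] != "O"]
    if (length(o_double) == 1L && length(o_single) == 1L) {
      groups[[length(groups) + 1L]] <- list(
        c_idx = a, o_idx = c(o_double, o_single),
        alpha = if (length(other) >= 1L) other[1] else NA_integer_)
    }
  }
  groups
}

#' Filter carboxylic acids on molecular weight and sp3 content
#'
#' Retains acids with molecular weight strictly below `mw_max` and Fsp3 at
#' least `fsp3_min`.
#'
#' @param acids data.frame with columns `acid_id` and `smiles` (`mw` / `fsp3`
#'   are computed when absent).
#' @param mw_max molecular weight cut-off in g/mol (exclusive; default 230).
#' @param fsp3_min minimum fraction of sp3 carbons (inclusive; default 0).
#' @return the retained rows, with `mw` and `fsp3` columns filled in.
#' @export
filter_acids <- function(acids, mw_max = 230, fsp3_min = 0) {
  if (nrow(acids) == 0L) {
    acids$mw <- numeric(0); acids$fsp3 <- numeric(0)
    return(acids)
  }
  if (!"mw" %in% names(acids) || anyNA(acids$mw)) {
    acids$mw <- vapply(acids$smiles, mol_weight, 0, USE.NAMES = FALSE)
  }
  if (!"fsp3" %in% names(acids) || anyNA(acids$fsp3)) {
    acids$fsp3 <- vapply(acids$smiles, fsp3, 0, USE.NAMES = FALSE)
  }
  acids[acids$mw < mw_max & acids$fsp3 >= fsp3_min, , drop = FALSE]
}

#' Suggest the Minisci alkylation site of an N-heteroarene
#'
#' Returns the 0-based atom index (in the input SMILES atom ordering) of an
#' aromatic C-H carbon activated for Minisci-type radical addition: positions
#' ortho to a ring nitrogen are preferred (the classic selectivity of
#' protonated azines), then para positions within the same six-membered ring;
#' ties are broken by the lowest atom index.
#'
#' @param scaffold SMILES of the N-heteroarene.
#' @return 0-based atom index of the suggested site.
#' @export
#' @examples
#' suggest_site("c1ccncc1")  # pyridine: C-2, ortho to nitrogen
suggest_site <- function(scaffold) {
  mol <- parse_smiles(scaffold)
  at <- mol$atoms
  ring_n <- which(at$element == "N" & at$aromatic)
  if (length(ring_n) == 0L) {
    stop_mf("site_error", "no aromatic ring nitrogen in '%s'", scaffold)
  }
  ch <- which(at$element == "C" & at$aromatic & at$nH >= 1L)
  if (length(ch) == 0L) {
    stop_mf("site_error", "no aromatic C-H position in '%s'", scaffold)
  }
  adj <- adjacency_list(mol)
  ortho <- ch[vapply(ch, function(a) any(adj[[a]] %in% ring_n), TRUE)]
  if (length(ortho) > 0L) return(min(ortho) - 1L)
  # para: distance 3 around a six-membered ring containing the nitrogen
  rings <- smallest_rings(mol)
  para <- integer(0)
  for (ring in rings) {
    if (length(ring) != 6L) next
    ns <- intersect(ring, ring_n)
    if (length(ns) == 0L) next
    for (nn in ns) {
      pos_n <- match(nn, ring)
      opposite <- ring[(pos_n - 1L + 3L) %% 6L + 1L]
      if (opposite %in% ch) para <- c(para, opposite)
    }
  }
  if (length(para) > 0L) return(min(para) - 1L)
  stop_mf("site_error",
          "no ortho/para aromatic C-H site relative to ring N in '%s'",
          scaffold)
}

# decarboxylate: acid SMILES -> alkyl fragment SMILES (branch form)
acid_fragment <- function(acid_smiles) {
  mol <- parse_smiles(acid_smiles)
  groups <- find_carboxyl_groups(mol)
  if (length(groups) != 1L) {
    stop_mf("enumeration_error",
            "acid '%s' must contain exactly one carboxylic-acid group (found %d)",
            acid_smiles, length(groups))
  }
  g <- groups[[1]]
  if (is.na(g$alpha)) {
    stop_mf("enumeration_error",
            "acid '%s' has no alkyl fragment (formic acid?)", acid_smiles)
  }
  keep <- setdiff(seq_len(nrow(mol$atoms)), c(g$c_idx, g$o_idx))
  write_smiles(mol, root = g$alpha, keep = keep)
}

resolve_sites <- function(scaffold_smiles, site, multi_site) {
  mol <- parse_smiles(scaffold_smiles)
  if (!is.null(site) && !is.na(site)) {
    a <- as.integer(site) + 1L
    if (a < 1L || a > nrow(mol$atoms)) {
      stop_mf("enumeration_error", "site %s out of range for '%s'",
              site, scaffold_smiles)
    }
    ok <- mol$atoms$element[a] == "C" && mol$atoms$aromatic[a] &&
      mol$atoms$nH[a] >= 1L
    if (!ok) {
      stop_mf("enumeration_error",
              "designated site %s of '%s' is not an aromatic C-H carbon",
              site, scaffold_smiles)
    }
    return(as.integer(site))
  }
  if (multi_site) {
    at <- mol$atoms
    adj <- adjacency_list(mol)
    ring_n <- which(at$element == "N" & at$aromatic)
    ch <- which(at$element == "C" & at$aromatic & at$nH >= 1L)
    sites <- ch[vapply(ch, function(x) any(adj[[x]] %in% ring_n), TRUE)]
    if (length(sites) == 0L) sites <- suggest_site(scaffold_smiles) + 1L
    return(sort(sites) - 1L)
  }
  suggest_site(scaffold_smiles)
}

#' Enumerate virtual Minisci alkylation products
#'
#' Applies the decarboxylative alkylation template: for every (scaffold,
#' acid) pair, the hydrogen at the scaffold's alkylation site is replaced by
#' the acid's alkyl fragment (acid minus CO2).  With the default single-site
#' policy the library has exactly `nrow(scaffolds) * nrow(acids)` products in
#' scaffold-major order.
#'
#' @param scaffolds data.frame with `scaffold_id`, `smiles` and optional
#'   `site` (0-based atom index in the given SMILES atom ordering; `NA` or
#'   absent means the site is resolved by [suggest_site()]).
#' @param acids data.frame with `acid_id`, `smiles`.
#' @param multi_site enumerate all ortho C-H sites per scaffold instead of
#'   one (excluded from the single-site pair count).
#' @param dedupe drop duplicate canonical products (off by default so the
#'   pair count is preserved).
#' @param validate re-parse every product and assert the heavy-atom balance
#'   heavy(product) = heavy(scaffold) + heavy(acid) - 3.
#' @return data.frame with `scaffold_id`, `acid_id`, `product`, `site`.
#' @export
enumerate_products <- function(scaffolds, acids, multi_site = FALSE,
                               dedupe = FALSE, validate = TRUE) {
  if (nrow(scaffolds) == 0L || nrow(acids) == 0L) {
    return(data.frame(scaffold_id = character(0), acid_id = character(0),
                      product = character(0), site = integer(0),
                      stringsAsFactors = FALSE))
  }
  frags <- vapply(acids$smiles, acid_fragment, "", USE.NAMES = FALSE)
  acid_heavy <- vapply(acids$smiles, heavy_atom_count, 0L, USE.NAMES = FALSE)

  out <- vector("list", nrow(scaffolds))
  for (s in seq_len(nrow(scaffolds))) {
    sm <- scaffolds$smiles[s]
    given <- if ("site" %in% names(scaffolds)) scaffolds$site[s] else NA
    sites <- tryCatch(
      resolve_sites(sm, given, multi_site),
      error = function(e) {
        stop_mf("enumeration_error", "scaffold '%s' (%s): %s",
                scaffolds$scaffold_id[s], sm, conditionMessage(e))
      })
    mol <- parse_smiles(sm)
    scaff_heavy <- sum(mol$atoms$element != "H")
    rows <- vector("list", length(sites))
    for (q in seq_along(sites)) {
      site <- sites[q]
      sp <- splice_point(sm, site, mol = mol)
      products <- paste0(sp$pre, "(", frags, ")", sp$post)
      if (validate) {
        # per-product heavy-atom balance: product = scaffold + acid - CO2
        ph <- vapply(products, token_heavy_atoms, 0L, USE.NAMES = FALSE)
        bad <- which(ph != scaff_heavy + acid_heavy - 3L)
        if (length(bad) > 0L) {
          stop_mf("enumeration_error",
                  "heavy-atom balance violated for scaffold '%s' + acid '%s'",
                  scaffolds$scaffold_id[s], acids$acid_id[bad[1]])
        }
        # full sanitization of one product per scaffold/site (all pairs share
        # the splice point; the whole-library parse is exercised in tests)
        parse_smiles(products[1])
      }
      rows[[q]] <- data.frame(
        scaffold_id = scaffolds$scaffold_id[s], acid_id = acids$acid_id,
        product = products, site = site, stringsAsFactors = FALSE)
    }
    out[[s]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (dedupe) {
    canon <- canonical_smiles(res$product)
    res <- res[!duplicated(canon), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}
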
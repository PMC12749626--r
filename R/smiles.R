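# Internal SMILES machinery.
#
# The package keeps its own light-weight molecular graph representation because
# its contracts are expressed in terms of the *input* SMILES atom ordering
# (site indices for enumeration), require graph editing (fragment splicing),
# and need explicit-hydrogen graphs with a fixed featurization scheme.
# Canonicalization and cross-checks are delegated to Open Babel (ChemmineOB).
#
# Supported SMILES subset: organic subset atoms (B, C, N, O, P, S, F, Cl, Br,
# I and aromatic b c n o p s), bracket atoms with isotope/chirality/H-count/
# charge, branches, ring closures (incl. %nn), bond symbols - = # : / \.
# Disconnected structures (.) are rejected.

SMILES_TOKEN_RE <- paste0(
  "\\[[^\\]]+\\]|Cl|Br|%[0-9]{2}|[BCNOPSFI]|[bcnops]|[0-9]|",
  "[-=#:/\\\\()]"
)

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# standard valences used for implicit hydrogen assignment
STANDARD_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, Si = 4, Se = c(2, 4, 6), H = 1
)

ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Se = 78.971,
  Br = 79.904, I = 126.904, Sn = 118.71, As = 74.922
)

smiles_tokens <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop_mf("structure_error", "empty or non-string SMILES input")
  }
  if (grepl(".", smiles, fixed = TRUE)) {
    stop_mf("structure_error",
            "disconnected (multi-fragment) SMILES unsupported: '%s'", smiles)
  }
  m <- gregexpr(SMILES_TOKEN_RE, smiles, perl = TRUE)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(smiles)) {
    stop_mf("structure_error", "unrecognized characters in SMILES '%s'", smiles)
  }
  tok <- regmatches(smiles,
                    gregexpr(SMILES_TOKEN_RE, smiles, perl = TRUE))[[1]]
  type <- character(length(tok))
  for (k in seq_along(tok)) {
    t <- tok[k]
    type[k] <- if (startsWith(t, "[")) "atom"
    else if (t %in% c("(", ")")) if (t == "(") "open" else "close"
    else if (t %in% c("-", "=", "#", ":", "/", "\\")) "bond"
    else if (grepl("^%?[0-9]", t)) "ring"
    else "atom"
  }
  data.frame(token = tok, type = type, stringsAsFactors = FALSE)
}

parse_bracket_atom <- function(tok, smiles) {
  body <- substr(tok, 2L, nchar(tok) - 1L)
  re <- "^([0-9]+)?([A-Za-z][a-z]?)(@@?)?(H[0-9]*)?([+-][0-9]*|\\++|-+)?$"
  m <- regmatches(body, regexec(re, body))[[1]]
  if (length(m) == 0L) {
    stop_mf("structure_error", "cannot parse bracket atom '%s' in '%s'",
            tok, smiles)
  }
  sym <- m[3]
  aromatic <- sym == tolower(sym) && substr(sym, 1L, 1L) %in% letters
  element <- paste0(toupper(substr(sym, 1L, 1L)), substring(sym, 2L))
  htok <- m[5]
  hcount <- if (!nzchar(htok)) 0L
  else if (htok == "H") 1L else as.integer(substring(htok, 2L))
  ctok <- m[6]
  charge <- if (!nzchar(ctok)) 0L
  else if (grepl("^\\++$", ctok)) nchar(ctok)
  else if (grepl("^-+$", ctok)) -nchar(ctok)
  else if (ctok %in% c("+", "-")) ifelse(ctok == "+", 1L, -1L)
  else as.integer(ctok)
  list(element = element, aromatic = aromatic, hcount = hcount,
       charge = as.integer(charge), tag = m[4], bracket = TRUE)
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds the package-internal molecular graph: one row per heavy atom (in the
#' order the atoms appear in the SMILES string, 1-based), bonds with orders,
#' aromatic flags, implicit hydrogen counts, ring membership and a rule-based
#' hybridization label.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `mf_mol`: a list with `atoms` (data.frame:
#'   `element`, `aromatic`, `charge`, `nH`, `in_ring`, `hyb`, `bracket`,
#'   `tag`), `bonds` (data.frame: `i`, `j`, `order`, `aromatic`) and `smiles`.
#' @export
#' @examples
#' m <- parse_smiles("c1ccncc1")
#' m$atoms$element
parse_smiles <- function(smiles) {
  toks <- smiles_tokens(smiles)
  atoms <- list()
  bonds <- list(i = integer(), j = integer(), order = numeric(),
                aromatic = logical(), explicit = logical())
  stack <- integer()       # branch return points
  prev <- NA_integer_
  pending <- NA_character_ # pending bond symbol
  rings <- list()          # digit -> list(atom, bond)

  add_bond <- function(a, b, sym) {
    arom_a <- atoms[[a]]$aromatic
    arom_b <- atoms[[b]]$aromatic
    if (is.na(sym) || sym %in% c("/", "\\")) {
      if (arom_a && arom_b) {
        order <- 1.5; arom <- TRUE; expl <- FALSE
      } else {
        order <- 1; arom <- FALSE; expl <- !is.na(sym)
      }
    } else if (sym == ":") {
      order <- 1.5; arom <- TRUE; expl <- TRUE
    } else {
      order <- c("-" = 1, "=" = 2, "#" = 3)[[sym]]
      arom <- FALSE; expl <- TRUE
    }
    bonds$i[[length(bonds$i) + 1L]] <<- a
    bonds$j[[length(bonds$j) + 1L]] <<- b
    bonds$order[[length(bonds$order) + 1L]] <<- order
    bonds$aromatic[[length(bonds$aromatic) + 1L]] <<- arom
    bonds$explicit[[length(bonds$explicit) + 1L]] <<- expl
  }

  for (k in seq_len(nrow(toks))) {
    t <- toks$token[k]; ty <- toks$type[k]
    if (ty == "atom") {
      at <- if (startsWith(t, "[")) parse_bracket_atom(t, smiles)
      else {
        aromatic <- t %in% c("b", "c", "n", "o", "p", "s")
        el <- if (aromatic) toupper(t) else t
        if (!el %in% ORGANIC_SUBSET) {
          stop_mf("structure_error", "invalid atom token '%s' in '%s'",
                  t, smiles)
        }
        list(element = el, aromatic = aromatic, hcount = NA_integer_,
             charge = 0L, tag = "", bracket = FALSE)
      }
      atoms[[length(atoms) + 1L]] <- at
      idx <- length(atoms)
      if (!is.na(prev)) add_bond(prev, idx, pending)
      pending <- NA_character_
      prev <- idx
    } else if (ty == "bond") {
      pending <- t
    } else if (ty == "open") {
      stack <- c(stack, prev)
    } else if (ty == "close") {
      if (length(stack) == 0L) {
        stop_mf("structure_error", "unbalanced ')' in '%s'", smiles)
      }
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pending <- NA_character_
    } else if (ty == "ring") {
      key <- sub("^%", "", t)
      if (is.na(prev)) {
        stop_mf("structure_error", "ring closure before any atom in '%s'",
                smiles)
      }
      if (!is.null(rings[[key]])) {
        opened <- rings[[key]]
        sym <- if (!is.na(pending)) pending else opened$sym
        add_bond(opened$atom, prev, sym)
        rings[[key]] <- NULL
      } else {
        rings[[key]] <- list(atom = prev, sym = pending)
      }
      pending <- NA_character_
    }
  }
  if (length(stack) > 0L) {
    stop_mf("structure_error", "unbalanced '(' in '%s'", smiles)
  }
  open_rings <- names(rings)[!vapply(rings, is.null, logical(1))]
  if (length(open_rings) > 0L) {
    stop_mf("structure_error", "unmatched ring closure(s) %s in '%s'",
            paste(open_rings, collapse = ","), smiles)
  }
  if (length(atoms) == 0L) {
    stop_mf("structure_error", "no atoms in SMILES '%s'", smiles)
  }

  adf <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, TRUE, "aromatic"),
    charge = vapply(atoms, `[[`, 1L, "charge"),
    hcount = vapply(atoms, function(a) as.integer(a$hcount), 1L),
    bracket = vapply(atoms, `[[`, TRUE, "bracket"),
    tag = vapply(atoms, `[[`, "", "tag"),
    stringsAsFactors = FALSE
  )
  bdf <- data.frame(i = bonds$i, j = bonds$j, order = bonds$order,
                    aromatic = bonds$aromatic)
  mol <- structure(list(atoms = adf, bonds = bdf, smiles = smiles),
                   class = "mf_mol")
  finalize_mol(mol)
}

# connectivity, implicit H, ring membership, hybridization, valence sanity
finalize_mol <- function(mol) {
  n <- nrow(mol$atoms)
  b <- mol$bonds
  if (nrow(b) > 0L && n > 1L) {
    comp <- connected_components(n, b)
    if (length(unique(comp)) > 1L) {
      stop_mf("structure_error", "disconnected structure '%s'", mol$smiles)
    }
  } else if (n > 1L) {
    stop_mf("structure_error", "disconnected structure '%s'", mol$smiles)
  }

  # per-atom bond order sums; aromatic bonds contribute 1 each plus a single
  # +1 "aromatic system" increment per aromatic atom (benzene carbon: 2+1 -> 3)
  ordsum <- numeric(n); nar <- integer(n); ndouble <- integer(n)
  ntriple <- integer(n); deg <- integer(n)
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    o <- if (b$aromatic[r]) 1 else b$order[r]
    ordsum[i] <- ordsum[i] + o; ordsum[j] <- ordsum[j] + o
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    if (b$aromatic[r]) { nar[i] <- nar[i] + 1L; nar[j] <- nar[j] + 1L }
    if (!b$aromatic[r] && b$order[r] == 2) {
      ndouble[i] <- ndouble[i] + 1L; ndouble[j] <- ndouble[j] + 1L
    }
    if (!b$aromatic[r] && b$order[r] == 3) {
      ntriple[i] <- ntriple[i] + 1L; ntriple[j] <- ntriple[j] + 1L
    }
  }
  ordsum <- ordsum + as.numeric(mol$atoms$aromatic & nar > 0L)

  nH <- integer(n)
  for (a in seq_len(n)) {
    if (!is.na(mol$atoms$hcount[a])) {
      nH[a] <- mol$atoms$hcount[a]
      next
    }
    el <- mol$atoms$element[a]
    vals <- STANDARD_VALENCE[[el]]
    if (is.null(vals)) { nH[a] <- 0L; next }
    need <- ordsum[a] - mol$atoms$charge[a] * ifelse(el %in% c("N", "O"), -1, 0)
    v <- vals[vals >= need][1]
    if (is.na(v)) v <- max(vals)
    nH[a] <- as.integer(max(0, round(v - need)))
  }
  mol$atoms$nH <- nH

  mol$atoms$in_ring <- ring_membership(n, b)

  hyb <- character(n)
  for (a in seq_len(n)) {
    hyb[a] <- if (mol$atoms$element[a] == "H") "S"
    else if (mol$atoms$aromatic[a]) "SP2"
    else if (ntriple[a] > 0L || ndouble[a] >= 2L) "SP"
    else if (ndouble[a] > 0L) "SP2"
    else "SP3"
  }
  mol$atoms$hyb <- hyb
  mol$atoms$degree <- deg
  mol
}

connected_components <- function(n, bonds) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# atoms that survive iterative pruning of degree-1 vertices lie on a cycle
ring_membership <- function(n, bonds) {
  if (nrow(bonds) == 0L) return(rep(FALSE, n))
  alive <- rep(TRUE, n)
  repeat {
    deg <- integer(n)
    keep <- alive[bonds$i] & alive[bonds$j]
    for (r in which(keep)) {
      deg[bonds$i[r]] <- deg[bonds$i[r]] + 1L
      deg[bonds$j[r]] <- deg[bonds$j[r]] + 1L
    }
    leaf <- alive & deg <= 1L
    if (!any(leaf)) break
    alive[leaf] <- FALSE
  }
  alive
}

adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# smallest ring containing each ring bond (BFS shortest path avoiding the bond)
smallest_rings <- function(mol) {
  inring <- mol$atoms$in_ring
  b <- mol$bonds
  adj <- adjacency_list(mol)
  rings <- list()
  seen <- character()
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    if (!inring[i] || !inring[j]) next
    # BFS from i to j excluding bond (i,j)
    n <- nrow(mol$atoms)
    par <- rep(NA_integer_, n); par[i] <- 0L
    q <- i
    while (length(q) > 0L && is.na(par[j])) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) {
        if (v == i && w == j) next
        if (is.na(par[w])) { par[w] <- v; q <- c(q, w) }
      }
    }
    if (is.na(par[j])) next
    path <- j; v <- j
    while (par[v] != 0L) { v <- par[v]; path <- c(path, v) }
    key <- paste(sort(path), collapse = "-")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- path  # ordered cycle j..i, bond closes it
    }
  }
  rings
}

#' Molecular weight from an internal molecular graph
#'
#' Average-isotope molecular weight including implicit hydrogens.
#'
#' @param mol an `mf_mol` (or SMILES string, parsed on the fly).
#' @return weight in g/mol.
#' @export
mol_weight <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  masses <- ATOMIC_MASS[mol$atoms$element]
  if (anyNA(masses)) {
    stop_mf("structure_error", "no mass for element(s): %s",
            paste(unique(mol$atoms$element[is.na(masses)]), collapse = ","))
  }
  sum(masses) + sum(mol$atoms$nH) * ATOMIC_MASS[["H"]]
}

#' Fraction of sp3-hybridized carbon atoms
#'
#' @param mol an `mf_mol` or SMILES string.
#' @return Fsp3 in \[0, 1\] (0 when the molecule has no carbons).
#' @export
fsp3 <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  isC <- mol$atoms$element == "C"
  if (!any(isC)) return(0)
  mean(mol$atoms$hyb[isC] == "SP3")
}

heavy_atom_count <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  sum(mol$atoms$element != "H")
}

#' Canonical SMILES via Open Babel
#'
#' Canonicalization is delegated to Open Babel (through ChemmineOB); used for
#' entity identity in data splits and duplicate detection.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES (`NA` for unparsable input).
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  one <- function(s) {
    out <- tryCatch(
      suppressWarnings(suppressMessages(
        ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))
      )),
      error = function(e) ""
    )
    line <- strsplit(out, "\n", fixed = TRUE)[[1]]
    if (length(line) == 0L || !nzchar(line[1])) return(NA_character_)
    sub("\t.*$", "", line[1])
  }
  # batch first; fall back to per-molecule on count mismatch (invalid entries)
  out <- tryCatch(
    suppressWarnings(suppressMessages(
      ChemmineOB::convertFormat(
        "SMI", "CAN",
        paste0(paste(smiles, seq_along(smiles)), collapse = "\n"))
    )),
    error = function(e) ""
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) == length(smiles)) {
    return(sub("[\t ].*$", "", lines))
  }
  vapply(smiles, one, "", USE.NAMES = FALSE)
}

# ---- fragment writing and splicing ------------------------------------------

atom_token <- function(mol, a, h_override = NULL) {
  el <- mol$atoms$element[a]
  arom <- mol$atoms$aromatic[a]
  sym <- if (arom) tolower(el) else el
  needs_bracket <- mol$atoms$bracket[a] || mol$atoms$charge[a] != 0L ||
    nzchar(mol$atoms$tag[a]) || !(el %in% ORGANIC_SUBSET)
  if (!needs_bracket) return(sym)
  h <- if (!is.null(h_override)) h_override else mol$atoms$nH[a]
  htok <- if (h <= 0L) "" else if (h == 1L) "H" else paste0("H", h)
  ch <- mol$atoms$charge[a]
  ctok <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
  else sprintf("%+d", ch)
  paste0("[", sym, mol$atoms$tag[a], htok, ctok, "]")
}

bond_token <- function(order, aromatic) {
  if (aromatic) return("")
  if (order == 2) return("=")
  if (order == 3) return("#")
  ""
}

# Write a SMILES string for the sub-molecule of `mol` induced by `keep`,
# rooted at atom `root`.  Two-pass: a DFS classifies tree vs ring-closure
# bonds, then rendering emits closure digits at both endpoints.
# `root_loses_h` subtracts one explicit H from a bracketed root (it will gain
# a bond when spliced into a scaffold).
write_smiles <- function(mol, root = 1L, keep = NULL, root_loses_h = FALSE) {
  n <- nrow(mol$atoms)
  keepv <- rep(FALSE, n)
  if (is.null(keep)) keepv[] <- TRUE else {
    if (any(keep > n) || any(keep < 1L)) {
      stop_mf("enumeration_error", "fragment atom index out of range")
    }
    keepv[keep] <- TRUE
  }
  if (!keepv[root]) stop_mf("enumeration_error", "root atom not in fragment")

  badj <- vector("list", n)
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    if (!keepv[i] || !keepv[j]) next
    badj[[i]] <- rbind(badj[[i]], c(j, r))
    badj[[j]] <- rbind(badj[[j]], c(i, r))
  }

  # pass 1: DFS to classify tree/back edges and record ring digits per atom
  visited <- rep(FALSE, n)
  tree_children <- vector("list", n)   # list of c(child, bondrow)
  ring_marks <- vector("list", n)      # per atom: list of c(bondrow)
  used <- rep(FALSE, max(1L, nrow(mol$bonds)))
  stack <- list(root)
  order_visited <- integer(0)
  dfs <- function(a) {
    visited[a] <<- TRUE
    order_visited <<- c(order_visited, a)
    nbrs <- badj[[a]]
    if (is.null(nbrs)) return(invisible())
    for (q in seq_len(nrow(nbrs))) {
      b <- nbrs[q, 1]; r <- nbrs[q, 2]
      if (used[r]) next
      if (visited[b]) {
        used[r] <<- TRUE
        ring_marks[[a]] <<- c(ring_marks[[a]], r)
        ring_marks[[b]] <<- c(ring_marks[[b]], r)
      } else {
        used[r] <<- TRUE
        tree_children[[a]] <<- c(tree_children[[a]], list(c(b, r)))
        dfs(b)
      }
    }
  }
  dfs(root)
  if (!all(visited[keepv])) {
    stop_mf("enumeration_error", "fragment is disconnected from root")
  }

  digits <- new.env(parent = emptyenv())
  next_digit <- local({d <- 0L; function() {d <<- d + 1L; d}})
  digit_token <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)

  render <- function(a) {
    h_over <- NULL
    if (root_loses_h && a == root && mol$atoms$bracket[a] &&
        mol$atoms$nH[a] > 0L) h_over <- mol$atoms$nH[a] - 1L
    out <- atom_token(mol, a, h_override = h_over)
    for (r in ring_marks[[a]]) {
      key <- as.character(r)
      if (is.null(digits[[key]])) digits[[key]] <- next_digit()
      bt <- bond_token(mol$bonds$order[r], mol$bonds$aromatic[r])
      out <- paste0(out, bt, digit_token(digits[[key]]))
    }
    ch <- tree_children[[a]]
    if (length(ch) > 0L) {
      for (q in seq_along(ch)) {
        b <- ch[[q]][1]; r <- ch[[q]][2]
        bt <- bond_token(mol$bonds$order[r], mol$bonds$aromatic[r])
        sub <- paste0(bt, render(b))
        if (q < length(ch)) out <- paste0(out, "(", sub, ")")
        else out <- paste0(out, sub)
      }
    }
    out
  }
  render(root)
}

#' Attach a branch to an atom of a SMILES string
#'
#' Inserts `(<fragment>)` directly after the `site`-th atom token (0-based, in
#' the order atoms appear in the input string), after any ring-closure digits
#' belonging to that atom.  The atom must carry at least one hydrogen.
#'
#' @param smiles scaffold SMILES.
#' @param site 0-based atom index in the input atom ordering.
#' @param fragment branch SMILES (written without enclosing parentheses).
#' @return the spliced SMILES string.
#' @export
#' @examples
#' splice_smiles("c1ccncc1", 2L, "C(C)(C)C")
splice_smiles <- function(smiles, site, fragment) {
  sp <- splice_point(smiles, site)
  out <- paste0(sp$pre, "(", fragment, ")", sp$post)
  parse_smiles(out)  # must sanitize
  out
}

# pre/post strings around the insertion point after the site-th atom token
# (plus its ring-closure digits); computed once per scaffold for bulk
# enumeration
splice_point <- function(smiles, site, mol = NULL) {
  if (is.null(mol)) mol <- parse_smiles(smiles)
  n <- nrow(mol$atoms)
  if (site < 0L || site >= n) {
    stop_mf("site_error", "site index %d out of range for '%s' (%d atoms)",
            site, smiles, n)
  }
  if (mol$atoms$nH[site + 1L] < 1L) {
    stop_mf("site_error", "site atom %d of '%s' carries no hydrogen",
            site, smiles)
  }
  toks <- smiles_tokens(smiles)
  atom_rows <- which(toks$type == "atom")
  row <- atom_rows[site + 1L]
  k <- row
  while (k + 1L <= nrow(toks)) {
    nx <- toks$type[k + 1L]
    if (nx == "ring") { k <- k + 1L; next }
    if (nx == "bond" && k + 2L <= nrow(toks) && toks$type[k + 2L] == "ring") {
      k <- k + 2L; next
    }
    break
  }
  list(pre = paste(toks$token[seq_len(k)], collapse = ""),
       post = if (k < nrow(toks)) {
         paste(toks$token[seq(k + 1L, nrow(toks))], collapse = "")
       } else "")
}

# heavy-atom count straight from the token stream (cheap per-product check)
token_heavy_atoms <- function(smiles) {
  toks <- smiles_tokens(smiles)
  at <- toks$token[toks$type == "atom"]
  sum(!grepl("^\\[[0-9]*H", at))
}
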
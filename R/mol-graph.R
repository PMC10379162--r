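# A minimal molecular-graph layer used where the package must manipulate
# structures itself: SMILES enumeration (random atom orderings), SELFIES
# encoding/decoding, and circular-fragment generation. It is not a general
# cheminformatics toolkit: it covers the organic subset (B C N O P S F Cl
# Br I), aromatic lowercase atoms, brackets with explicit H counts and
# charges, ring closures (including %nn and bond-annotated closures) and
# branches. Stereo markers are accepted and dropped; disconnected
# structures are rejected. Open Babel remains the authority on molecular
# identity (canonicalization) and validity.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")

# Allowed total valences per element (kekule graphs).
VALENCES <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                 S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

new_mol_graph <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds\n",
      sep = "")
  invisible(x)
}

empty_atoms <- function() {
  data.frame(element = character(), aromatic = logical(),
             charge = integer(), hcount = integer(),
             bracket = logical(), stringsAsFactors = FALSE)
}

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles a single SMILES string.
#' @return a `mol_graph` with atom table (element, aromatic, charge,
#'   hcount, bracket) and bond table (from, to, order, aromatic).
#' @keywords internal
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop("parse error: empty or non-scalar SMILES input")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  el <- character(); arom <- logical(); chg <- integer()
  hct <- integer(); brk <- logical()
  b_from <- integer(); b_to <- integer(); b_ord <- integer()
  b_arom <- logical()

  prev <- NA_integer_          # atom awaiting the next bond
  stack <- integer()           # open branches
  pending <- NA_character_     # explicit bond symbol waiting to be used
  rings <- list()              # closure digit -> list(atom, bond)

  add_atom <- function(element, aromatic, charge, hcount, bracket) {
    el[length(el) + 1L] <<- element
    arom[length(arom) + 1L] <<- aromatic
    chg[length(chg) + 1L] <<- charge
    hct[length(hct) + 1L] <<- hcount
    brk[length(brk) + 1L] <<- bracket
    idx <- length(el)
    if (!is.na(prev)) add_bond(prev, idx, pending)
    pending <<- NA_character_
    prev <<- idx
    idx
  }
  add_bond <- function(a, b, sym) {
    aromatic <- FALSE
    if (is.na(sym)) {
      if (arom[a] && arom[b]) aromatic <- TRUE
      ord <- 1L
    } else {
      ord <- switch(sym, "-" = 1L, "/" = 1L, "\\" = 1L, "=" = 2L,
                    "#" = 3L, ":" = 1L,
                    stop("parse error: bond symbol '", sym, "'"))
      if (sym == ":") aromatic <- TRUE
    }
    b_from[length(b_from) + 1L] <<- a
    b_to[length(b_to) + 1L] <<- b
    b_ord[length(b_ord) + 1L] <<- ord
    b_arom[length(b_arom) + 1L] <<- aromatic
  }
  close_ring <- function(key) {
    if (is.na(prev))
      stop("parse error in '", smiles, "': ring closure before any atom")
    if (!is.null(rings[[key]])) {
      open <- rings[[key]]
      sym <- pending
      if (is.na(sym)) sym <- open$bond
      else if (!is.na(open$bond) && open$bond != sym)
        stop("parse error in '", smiles, "': conflicting ring bond orders")
      add_bond(open$atom, prev, sym)
      rings[[key]] <<- NULL
    } else {
      rings[[key]] <<- list(atom = prev, bond = pending)
    }
    pending <<- NA_character_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("parse error in '", smiles, "': '(' before atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L)
        stop("parse error in '", smiles, "': unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("parse error in '", smiles, "': bad %nn closure")
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("parse error in '", smiles, "': unterminated '['")
      spec <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      a <- parse_bracket_atom(spec, smiles)
      add_atom(a$element, a$aromatic, a$charge, a$hcount, TRUE)
      i <- j + 1L
    } else if (ch == ".") {
      stop("parse error in '", smiles, "': disconnected structures ",
           "are not supported")
    } else {
      # organic-subset atom, possibly two characters (Cl, Br)
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, NA_integer_, FALSE); i <- i + 2L
      } else if (ch %in% ORGANIC_SUBSET) {
        add_atom(ch, FALSE, 0L, NA_integer_, FALSE); i <- i + 1L
      } else if (ch %in% AROMATIC_OK) {
        add_atom(toupper(ch), TRUE, 0L, NA_integer_, FALSE); i <- i + 1L
      } else {
        stop("parse error in '", smiles, "': unexpected character '",
             ch, "'")
      }
    }
  }
  if (length(rings) > 0L)
    stop("parse error in '", smiles, "': unclosed ring bond")
  if (length(stack) > 0L)
    stop("parse error in '", smiles, "': unclosed branch")
  if (length(el) == 0L)
    stop("parse error in '", smiles, "': no atoms")

  atoms <- data.frame(element = el, aromatic = arom, charge = chg,
                      hcount = hct, bracket = brk, stringsAsFactors = FALSE)
  bonds <- data.frame(from = b_from, to = b_to, order = b_ord,
                      aromatic = b_arom)
  new_mol_graph(atoms, bonds)
}

# Parse the inside of a bracket atom, e.g. "nH", "N+", "NH3+", "13CH4".
parse_bracket_atom <- function(spec, context) {
  s <- spec
  s <- sub("^[0-9]+", "", s)              # isotope label dropped
  m <- regmatches(s, regexpr("^([A-Z][a-z]?|[a-z])", s))
  if (length(m) == 0L)
    stop("parse error in '", context, "': bad bracket atom [", spec, "]")
  sym <- m
  s <- substring(s, nchar(sym) + 1L)
  aromatic <- sym %in% AROMATIC_OK
  element <- if (aromatic) toupper(sym) else sym
  s <- gsub("@", "", s, fixed = TRUE)     # stereo dropped
  hcount <- 0L
  hm <- regmatches(s, regexpr("^H[0-9]*", s))
  if (length(hm) == 1L && nzchar(hm)) {
    hcount <- if (nchar(hm) == 1L) 1L else as.integer(substring(hm, 2L))
    s <- substring(s, nchar(hm) + 1L)
  }
  charge <- 0L
  cm <- regmatches(s, regexpr("^(\\++|-+)([0-9]+)?", s))
  if (length(cm) == 1L && nzchar(cm)) {
    sign <- if (substring(cm, 1L, 1L) == "+") 1L else -1L
    digits <- sub("^[+-]+", "", cm)
    mag <- if (nzchar(digits)) as.integer(digits)
           else nchar(gsub("[0-9]", "", cm))
    charge <- sign * mag
    s <- substring(s, nchar(cm) + 1L)
  }
  if (nzchar(s))
    stop("parse error in '", context, "': unsupported bracket content [",
         spec, "]")
  list(element = element, aromatic = aromatic, charge = charge,
       hcount = hcount)
}

# Adjacency list: for each atom, data.frame of (nbr, order, aromatic).
mol_adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(), ord = integer(),
                                         arom = logical())
  b <- g$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$from[k]; j <- b$to[k]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j)
    adj[[i]]$ord <- c(adj[[i]]$ord, b$order[k])
    adj[[i]]$arom <- c(adj[[i]]$arom, b$aromatic[k])
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i)
    adj[[j]]$ord <- c(adj[[j]]$ord, b$order[k])
    adj[[j]]$arom <- c(adj[[j]]$arom, b$aromatic[k])
  }
  adj
}

# Implicit hydrogen count per atom. Exact on kekule graphs; aromatic atoms
# use explicit bracket H only (sufficient for the uses in this package,
# which kekulize first).
implicit_hydrogens <- function(g) {
  adj <- mol_adjacency(g)
  n <- nrow(g$atoms)
  out <- integer(n)
  for (i in seq_len(n)) {
    a <- g$atoms[i, ]
    if (a$bracket) { out[i] <- ifelse(is.na(a$hcount), 0L, a$hcount); next }
    vs <- VALENCES[[a$element]]
    if (is.null(vs)) { out[i] <- 0L; next }
    deg <- sum(adj[[i]]$ord)
    if (a$aromatic) deg <- deg + 1L   # one valence absorbed by the pi system
    fit <- vs[vs >= deg]
    out[i] <- if (length(fit) == 0L) 0L else fit[1] - deg
  }
  out
}

# Write a graph back to SMILES. `order` permutes atom visiting priority;
# the first element is the DFS root. With order = NULL the traversal is
# the parse order (deterministic).
write_smiles <- function(g, order = NULL) {
  n <- nrow(g$atoms)
  if (is.null(order)) order <- seq_len(n)
  stopifnot(length(order) == n)
  rank <- integer(n); rank[order] <- seq_len(n)
  adj <- mol_adjacency(g)

  visited <- logical(n)
  ring_digit <- 0L
  ring_marks <- vector("list", n)  # atom -> character vector of closures
  tree_child <- vector("list", n)
  tree_bond <- vector("list", n)

  bond_sym <- function(ord, arom, a, b) {
    if (arom) return("")
    if (ord == 2L) return("=")
    if (ord == 3L) return("#")
    if (g$atoms$aromatic[a] && g$atoms$aromatic[b]) return("-")
    ""
  }

  # DFS assigning ring-closure digits to back edges
  seen_edge <- new.env(hash = TRUE)
  edge_key <- function(a, b) paste0(min(a, b), "_", max(a, b))
  dfs <- function(v) {
    visited[v] <<- TRUE
    nb <- adj[[v]]
    ordering <- order(rank[nb$nbr])
    for (k in ordering) {
      w <- nb$nbr[k]
      key <- edge_key(v, w)
      if (!is.null(seen_edge[[key]])) next
      seen_edge[[key]] <- TRUE
      if (!visited[w]) {
        tree_child[[v]] <<- c(tree_child[[v]], w)
        tree_bond[[v]] <<- c(tree_bond[[v]],
                             bond_sym(nb$ord[k], nb$arom[k], v, w))
        dfs(w)
      } else {
        ring_digit <<- ring_digit + 1L
        d <- if (ring_digit < 10L) as.character(ring_digit)
             else sprintf("%%%02d", ring_digit)
        sym <- bond_sym(nb$ord[k], nb$arom[k], v, w)
        ring_marks[[v]] <<- c(ring_marks[[v]], paste0(sym, d))
        ring_marks[[w]] <<- c(ring_marks[[w]], paste0(sym, d))
      }
    }
  }
  root <- order[1]
  dfs(root)
  if (!all(visited)) stop("write error: graph is disconnected")

  emit <- function(v) {
    out <- atom_smiles(g$atoms[v, ])
    if (!is.null(ring_marks[[v]]))
      out <- paste0(out, paste(ring_marks[[v]], collapse = ""))
    kids <- tree_child[[v]]
    bnds <- tree_bond[[v]]
    if (length(kids) > 0L) {
      for (k in seq_along(kids)) {
        part <- paste0(bnds[k], emit(kids[k]))
        if (k < length(kids)) part <- paste0("(", part, ")")
        out <- paste0(out, part)
      }
    }
    out
  }
  emit(root)
}

atom_smiles <- function(a) {
  sym <- if (a$aromatic) tolower(a$element) else a$element
  plain <- !a$bracket && a$charge == 0L &&
    (is.na(a$hcount) || !a$bracket) &&
    a$element %in% ORGANIC_SUBSET &&
    (!a$aromatic || tolower(a$element) %in% AROMATIC_OK)
  if (plain) return(sym)
  h <- if (is.na(a$hcount) || a$hcount == 0L) ""
       else if (a$hcount == 1L) "H"
       else paste0("H", a$hcount)
  q <- if (a$charge == 0L) ""
       else if (a$charge > 0L) paste0("+", if (a$charge > 1L) a$charge else "")
       else paste0("-", if (a$charge < -1L) -a$charge else "")
  paste0("[", sym, h, q, "]")
}

# Circular atom environments (Morgan/ECFP style). Returns, for every heavy
# atom and every radius 0..radius, a stable string id of its environment.
atom_environments <- function(g, radius = 2L) {
  adj <- mol_adjacency(g)
  n <- nrow(g$atoms)
  hs <- implicit_hydrogens(g)
  inv <- vapply(seq_len(n), function(i) {
    a <- g$atoms[i, ]
    paste(a$element, as.integer(a$aromatic), a$charge,
          if (a$bracket) ifelse(is.na(a$hcount), 0L, a$hcount) else hs[i],
          length(adj[[i]]$nbr), sep = "/")
  }, character(1))
  ids <- paste0("r0:", vapply(inv, fnv1a32, character(1)))
  all_ids <- ids
  cur <- inv
  r <- 1L
  while (r <= radius) {
    nxt <- character(n)
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      if (length(nb$nbr) == 0L) { nxt[i] <- cur[i]; next }
      bk <- ifelse(nb$arom, "a", as.character(nb$ord))
      parts <- sort(paste0(bk, ":", cur[nb$nbr]))
      nxt[i] <- paste0(cur[i], "|", paste(parts, collapse = ","))
    }
    cur <- nxt
    all_ids <- c(all_ids,
                 paste0("r", r, ":", vapply(cur, fnv1a32, character(1))))
    r <- r + 1L
  }
  all_ids
}

# 32-bit FNV-1a hash of a string, as 8 hex digits. Deterministic across
# platforms; used only to keep fragment ids compact. Arithmetic is done in
# doubles (exact below 2^53) with the multiply split into 16-bit halves.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- bitwXor(h %% 65536, b %% 65536)
    hi <- bitwXor(h %/% 65536, b %/% 65536)
    h <- hi * 65536 + lo
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
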
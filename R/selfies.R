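# SELFIES codec.
#
# SELFIES is a molecular string grammar in which any token sequence
# derives a valid molecule: bond orders and ring/branch targets that would
# violate valence rules are reduced or skipped during derivation instead
# of producing a parse error. That robustness is what makes it usable as
# the output alphabet of a generative sequence model. This file implements
# the grammar over kekule structures:
#
#   atom tokens      [C] [=C] [#N] [O-1] [NH1] ...  (optional bond prefix,
#                    element, optional explicit H count, optional charge)
#   branch tokens    [Branch1] [=Branch2] ...  followed by L index tokens
#                    giving Q; the next Q+1 tokens form the branch
#   ring tokens      [Ring1] [=Ring1] ...  followed by L index tokens;
#                    bonds the current atom to the atom Q+1 places back in
#                    derivation order
#
# Index tokens encode base-16 digits through the fixed overloaded token
# list below. Derivation respects per-element valence capacities; explicit
# hydrogens and charges adjust capacity.

SELFIES_IDX_TOKENS <- c("[C]", "[Ring1]", "[Ring2]",
                        "[Branch1]", "[=Branch1]", "[#Branch1]",
                        "[Branch2]", "[=Branch2]", "[#Branch2]",
                        "[O]", "[N]", "[=N]", "[=C]", "[#C]", "[S]", "[P]")

# Maximum total bond order per element in the SELFIES derivation.
SELFIES_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 5, S = 6,
                     F = 1, Cl = 1, Br = 1, I = 1)

selfies_capacity <- function(element, charge, hcount) {
  base <- SELFIES_VALENCE[[element]]
  if (is.null(base)) base <- 4
  max(1L, as.integer(base) + as.integer(charge)) - as.integer(hcount)
}

#' Split a SELFIES string into tokens
#'
#' @param selfies a single SELFIES string of bracketed tokens.
#' @return character vector of tokens, each of the form `[...]`.
#' @export
selfies_tokens <- function(selfies) {
  if (!is.character(selfies) || length(selfies) != 1L || is.na(selfies) ||
      !nzchar(selfies))
    stop("SELFIES error: empty input")
  m <- gregexpr("\\[[^][]*\\]", selfies)[[1]]
  toks <- regmatches(selfies, gregexpr("\\[[^][]*\\]", selfies))[[1]]
  if (paste(toks, collapse = "") != selfies)
    stop("SELFIES error: input is not a sequence of bracketed tokens: '",
         selfies, "'")
  toks
}

# Parse one atom token; NULL if the token is not an atom token.
parse_selfies_atom <- function(token) {
  m <- regexec("^\\[(=|#)?([A-Z][a-z]?)(H([0-9]))?((\\+|-)([0-9]?))?\\]$",
               token)
  g <- regmatches(token, m)[[1]]
  if (length(g) == 0L) return(NULL)
  element <- g[3]
  if (!element %in% names(SELFIES_VALENCE)) return(NULL)
  bond <- switch(g[2], "=" = 2L, "#" = 3L, 1L)
  if (g[2] == "") bond <- 1L
  hcount <- if (nzchar(g[4])) {
    if (nzchar(g[5])) as.integer(g[5]) else 1L
  } else 0L
  charge <- 0L
  if (nzchar(g[6])) {
    mag <- if (nzchar(g[8])) as.integer(g[8]) else 1L
    charge <- if (g[7] == "+") mag else -mag
  }
  list(bond = bond, element = element, hcount = hcount, charge = charge)
}

parse_selfies_control <- function(token) {
  m <- regexec("^\\[(=|#)?(Branch|Ring)([123])\\]$", token)
  g <- regmatches(token, m)[[1]]
  if (length(g) == 0L) return(NULL)
  list(kind = g[3],
       bond = switch(g[2], "=" = 2L, "#" = 3L, 1L),
       level = as.integer(g[4]))
}

selfies_index_value <- function(tokens) {
  vals <- match(tokens, SELFIES_IDX_TOKENS) - 1L
  vals[is.na(vals)] <- 0L  # non-index tokens read as digit 0 (robustness)
  q <- 0L
  for (v in vals) q <- q * 16L + v
  q
}

#' Decode a SELFIES string to SMILES
#'
#' Derives a molecule under valence constraints: bond orders are capped by
#' the remaining capacity of both endpoints, branches at saturated atoms
#' are skipped, and out-of-range ring targets are clamped. Any token
#' sequence containing at least one atom token therefore yields a valid
#' molecule.
#'
#' @param selfies a single SELFIES string.
#' @return a SMILES string (kekule form).
#' @export
selfies_to_smiles <- function(selfies) {
  toks <- selfies_tokens(selfies)
  env <- new.env()
  env$el <- character(); env$chg <- integer(); env$hct <- integer()
  env$cap <- integer()
  env$b_from <- integer(); env$b_to <- integer(); env$b_ord <- integer()

  place_atom <- function(a) {
    env$el <- c(env$el, a$element)
    env$chg <- c(env$chg, a$charge)
    env$hct <- c(env$hct, a$hcount)
    env$cap <- c(env$cap, selfies_capacity(a$element, a$charge, a$hcount))
    length(env$el)
  }
  add_bond <- function(i, j, ord) {
    env$b_from <- c(env$b_from, i)
    env$b_to <- c(env$b_to, j)
    env$b_ord <- c(env$b_ord, ord)
    env$cap[i] <- env$cap[i] - ord
    env$cap[j] <- env$cap[j] - ord
  }

  # Derive one chain. `attach`: atom index the chain bonds to (NA = none,
  # start of the molecule); `max_bond`: cap on the first bond (branches).
  derive <- function(tokens, attach, max_bond) {
    cur <- attach
    k <- 1L
    n <- length(tokens)
    first <- TRUE
    while (k <= n) {
      tk <- tokens[k]
      atom <- parse_selfies_atom(tk)
      if (!is.null(atom)) {
        if (is.na(cur)) {
          cur <- place_atom(atom)
        } else {
          want <- atom$bond
          if (first) want <- min(want, max_bond)
          cap_new <- selfies_capacity(atom$element, atom$charge, atom$hcount)
          ord <- min(want, env$cap[cur], cap_new)
          if (ord < 1L) break  # saturated: derivation of this chain ends
          idx <- place_atom(atom)
          add_bond(cur, idx, ord)
          cur <- idx
        }
        first <- FALSE
        k <- k + 1L
        next
      }
      ctl <- parse_selfies_control(tk)
      if (is.null(ctl)) { k <- k + 1L; next }  # unknown token: skipped
      l <- ctl$level
      if (k + l > n) break  # truncated index: derivation ends
      q <- selfies_index_value(tokens[(k + 1L):(k + l)])
      k <- k + 1L + l
      if (ctl$kind == "Branch") {
        if (is.na(cur) || env$cap[cur] < 2L) {
          # cannot branch here: the branch symbol and its index tokens
          # are ignored and the content continues as the main chain
          next
        }
        len <- q + 1L
        content <- tokens[seq.int(k, min(n, k + len - 1L))]
        k <- k + len
        derive(content, cur, ctl$bond)
      } else {  # Ring
        if (is.na(cur)) next
        target <- max(1L, cur - (q + 1L))
        if (target == cur) next
        already <- any((env$b_from == target & env$b_to == cur) |
                       (env$b_from == cur & env$b_to == target))
        if (already) next
        ord <- min(ctl$bond, env$cap[cur], env$cap[target])
        if (ord >= 1L) add_bond(target, cur, ord)
      }
    }
    invisible(NULL)
  }
  derive(toks, NA_integer_, 1L)

  if (length(env$el) == 0L)
    stop("SELFIES error: '", selfies, "' derives an empty molecule")
  atoms <- data.frame(
    element = env$el, aromatic = FALSE, charge = env$chg,
    hcount = ifelse(env$chg != 0L | env$hct > 0L, env$hct, NA_integer_),
    bracket = env$chg != 0L | env$hct > 0L, stringsAsFactors = FALSE)
  bonds <- data.frame(from = env$b_from, to = env$b_to, order = env$b_ord,
                      aromatic = logical(length(env$b_from)))
  write_smiles(new_mol_graph(atoms, bonds))
}

#' Encode a SMILES string as SELFIES
#'
#' The structure is kekulized first (the grammar carries explicit bond
#' orders), then traversed depth-first, emitting atom tokens with bond
#' prefixes, branch tokens with base-16 length indices, and ring tokens
#' with back-reference indices.
#'
#' @param smiles a single SMILES string.
#' @return a SELFIES string.
#' @export
smiles_to_selfies <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop("SELFIES error: empty SMILES input")
  kek <- kekulize_smiles(smiles)
  g <- parse_smiles(kek)
  encode_graph_selfies(g)
}

encode_graph_selfies <- function(g) {
  n <- nrow(g$atoms)
  hs_implicit <- implicit_hydrogens(g)
  adj <- mol_adjacency(g)

  # capacity check: every atom must be representable under the grammar
  for (i in seq_len(n)) {
    a <- g$atoms[i, ]
    hc <- if (a$bracket) ifelse(is.na(a$hcount), 0L, a$hcount) else 0L
    cap <- selfies_capacity(a$element, a$charge, hc)
    if (sum(adj[[i]]$ord) > cap)
      stop("SELFIES error: atom ", i, " (", a$element,
           ") exceeds the grammar's valence capacity")
  }

  visited <- logical(n)
  pos <- integer(n)        # derivation position of each atom
  counter <- 0L
  seen_edge <- new.env(hash = TRUE)
  edge_key <- function(a, b) paste0(min(a, b), "_", max(a, b))

  atom_token <- function(i, bond) {
    a <- g$atoms[i, ]
    prefix <- c("", "=", "#")[bond]
    h <- if (a$bracket && !is.na(a$hcount) && a$hcount > 0L)
      paste0("H", a$hcount) else ""
    q <- if (a$charge > 0L) paste0("+", a$charge)
         else if (a$charge < 0L) paste0("-", -a$charge)
         else ""
    paste0("[", prefix, a$element, h, q, "]")
  }
  index_tokens <- function(q, level) {
    digits <- integer(level)
    for (d in seq.int(level, 1L)) { digits[d] <- q %% 16L; q <- q %/% 16L }
    SELFIES_IDX_TOKENS[digits + 1L]
  }
  control_token <- function(kind, bond, level) {
    paste0("[", c("", "=", "#")[bond], kind, level, "]")
  }
  level_for <- function(q) {
    if (q < 16L) 1L else if (q < 256L) 2L else if (q < 4096L) 3L
    else stop("SELFIES error: index ", q, " out of range")
  }

  emit <- function(v, inbond) {
    visited[v] <<- TRUE
    counter <<- counter + 1L
    pos[v] <<- counter
    out <- atom_token(v, inbond)
    nb <- adj[[v]]
    ring_toks <- character()
    kids <- integer(); kbond <- integer()
    for (k in order(nb$nbr)) {
      w <- nb$nbr[k]
      key <- edge_key(v, w)
      if (!is.null(seen_edge[[key]])) next
      if (visited[w]) {
        # back edge: emit ring token at this (second) endpoint
        seen_edge[[key]] <- TRUE
        q <- pos[v] - pos[w] - 1L
        lv <- level_for(q)
        ring_toks <- c(ring_toks, control_token("Ring", nb$ord[k], lv),
                       index_tokens(q, lv))
      } else {
        kids <- c(kids, w); kbond <- c(kbond, nb$ord[k])
      }
    }
    out <- c(out, ring_toks)
    # unvisited children may have been claimed by an earlier sibling via
    # rings; re-check at emission time
    live <- kids[!visited[kids]]
    kbond <- kbond[!visited[kids]]
    if (length(live) > 0L) {
      for (k in seq_along(live)) {
        w <- live[k]
        if (visited[w]) next
        seen_edge[[edge_key(v, w)]] <- TRUE
        sub <- emit(w, kbond[k])
        remaining <- any(!visited[adj[[v]]$nbr])
        if (k < length(live) && any(!visited[live[(k + 1L):length(live)]])) {
          q <- length(sub) - 1L
          lv <- level_for(q)
          out <- c(out, control_token("Branch", kbond[k], lv),
                   index_tokens(q, lv), sub)
        } else {
          out <- c(out, sub)
        }
      }
    }
    out
  }

  toks <- emit(1L, 1L)
  paste(toks, collapse = "")
}
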
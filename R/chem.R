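# Molecular string handling: compound records, SMILES enumeration
# augmentation, corpus building, one-hot vectorization and corpus
# splitting. Augmentation turns a small seed set into many distinct string
# representations of the same molecules so a sequence model has enough
# data to learn the grammar of the chemical family.

SENTINEL_START <- "!"
SENTINEL_END <- "E"
SENTINEL_PAD <- "[nop]"

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a compound set
#'
#' A compound set is the package's tabular container for molecules: one
#' row per compound with a short id, the input SMILES, its canonical
#' form, and (optionally) the measured cytoprotective activity in percent
#' (inhibition of free-radical-induced hemolysis, 0-100).
#'
#' @param smiles character vector of SMILES strings.
#' @param id compound identifiers; defaults to `cpd_1`, `cpd_2`, ...
#' @param activity_pct numeric activities in `[0, 100]`, or `NA`.
#' @return a data.frame of class `compound_set` with columns
#'   `id`, `smiles`, `canonical`, `activity_pct`.
#' @examples
#' compound_set("c1ccc2c(c1)cc[nH]2", id = "indole", activity_pct = 60)
#' @export
compound_set <- function(smiles, id = NULL,
                         activity_pct = rep(NA_real_, length(smiles))) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (is.null(id)) id <- paste0("cpd_", seq_along(smiles))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("compound ids must be unique")
  stopifnot(length(id) == length(smiles),
            length(activity_pct) == length(smiles))
  activity_pct <- as.numeric(activity_pct)
  bad <- !is.na(activity_pct) &
    (!is.finite(activity_pct) | activity_pct < 0 | activity_pct > 100)
  if (any(bad))
    stop("activity_pct outside [0, 100] for id(s): ",
         paste(id[bad], collapse = ", "))
  canonical <- tryCatch(canonicalize(smiles), error = function(e)
    stop("compound set contains invalid SMILES: ", conditionMessage(e)))
  out <- data.frame(id = id, smiles = smiles, canonical = canonical,
                    activity_pct = activity_pct, stringsAsFactors = FALSE)
  class(out) <- c("compound_set", "data.frame")
  out
}

#' @export
print.compound_set <- function(x, ...) {
  cat("<compound_set> ", nrow(x), " compounds, ",
      sum(!is.na(x$activity_pct)), " with measured activity\n", sep = "")
  NextMethod()
}

#' Read compounds from a SMI or CSV file
#'
#' CSV files need a header with columns `id`, `smiles` and optionally
#' `activity_pct`. SMI files carry one SMILES per line, optionally
#' followed by whitespace and an id.
#'
#' @param path file path; format inferred from the extension
#'   (`.csv` vs anything else).
#' @return a [compound_set()].
#' @export
read_compounds <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(df)))
      stop("CSV must have columns id,smiles[,activity_pct]: ", path)
    act <- if ("activity_pct" %in% names(df)) df$activity_pct
           else rep(NA_real_, nrow(df))
    compound_set(df$smiles, id = df$id, activity_pct = act)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "[ \t]+")
    smi <- vapply(parts, `[`, character(1), 1L)
    ids <- vapply(parts, function(p) if (length(p) > 1L) p[2] else
      NA_character_, character(1))
    if (anyNA(ids)) ids <- paste0("cpd_", seq_along(smi))
    compound_set(smi, id = ids)
  }
}

#' Write a compound set to CSV
#'
#' @param records a [compound_set()].
#' @param path output path.
#' @export
write_compounds <- function(records, path) {
  utils::write.csv(
    records[, c("id", "smiles", "activity_pct")], path, row.names = FALSE)
  invisible(path)
}

#' Enumerate alternative SMILES representations of one molecule
#'
#' Rewrites the molecule from `n_attempts` random atom orderings and
#' deduplicates the resulting strings. Every output string encodes the
#' same molecule as the input.
#'
#' @param smiles a single valid SMILES string.
#' @param n_attempts number of random rewrites to try (>= 1).
#' @param seed integer seed; the same seed gives the same list.
#' @return character vector of distinct SMILES strings.
#' @examples
#' enumerate_smiles("c1ccc2c(c1)cc[nH]2", 25, seed = 1)
#' @export
enumerate_smiles <- function(smiles, n_attempts, seed = 1L) {
  stopifnot(length(smiles) == 1L, n_attempts >= 1L)
  ref <- canonicalize(smiles)  # errors on unparseable input
  g <- parse_smiles(smiles)
  n <- nrow(g$atoms)
  out <- with_seed(seed, {
    vapply(seq_len(n_attempts), function(k) {
      write_smiles(g, order = sample.int(n))
    }, character(1))
  })
  unique(out)
}

#' Build an augmented SELFIES token corpus
#'
#' For each record, enumerates `n_attempts` SMILES rewrites, kekulizes
#' them, and translates each to SELFIES; entries are deduplicated
#' globally on the exact SELFIES string (distinct strings for one
#' molecule are deliberately kept -- they are the augmentation). The
#' alphabet collects every token occurring in the corpus plus the start
#' (`!`), end (`E`) and pad (`[nop]`) sentinels.
#'
#' @param records a [compound_set()].
#' @param n_attempts enumeration attempts per record.
#' @param seed integer seed.
#' @return an object of class `token_corpus`: `entries` (data.frame with
#'   `source_id`, `selfies`, `n_tokens`), `tokens` (list of token
#'   vectors), `alphabet` (a `selfies_alphabet`), `max_len` (longest
#'   sentinel-wrapped sequence).
#' @export
build_corpus <- function(records, n_attempts = 5000L, seed = 1L) {
  stopifnot(inherits(records, "compound_set"), n_attempts >= 1L)
  sel <- character(); src <- character()
  for (i in seq_len(nrow(records))) {
    smi <- tryCatch(
      enumerate_smiles(records$smiles[i], n_attempts, seed = seed + i),
      error = function(e) stop("record '", records$id[i], "': ",
                               conditionMessage(e)))
    kek <- kekulize_smiles(smi)
    sf <- vapply(kek, function(k) encode_graph_selfies(parse_smiles(k)),
                 character(1), USE.NAMES = FALSE)
    sel <- c(sel, sf)
    src <- c(src, rep(records$id[i], length(sf)))
  }
  keep <- !duplicated(sel)
  sel <- sel[keep]; src <- src[keep]
  tokens <- lapply(sel, selfies_tokens)
  alphabet <- selfies_alphabet(sort(unique(unlist(tokens))))
  max_len <- max(lengths(tokens)) + 2L
  structure(list(
    entries = data.frame(source_id = src, selfies = sel,
                         n_tokens = lengths(tokens),
                         stringsAsFactors = FALSE),
    tokens = tokens, alphabet = alphabet, max_len = max_len),
    class = "token_corpus")
}

#' @export
print.token_corpus <- function(x, ...) {
  cat("<token_corpus> ", nrow(x$entries), " entries from ",
      length(unique(x$entries$source_id)), " source molecules; alphabet ",
      length(x$alphabet), " tokens; max_len ", x$max_len, "\n", sep = "")
  invisible(x)
}

#' Token alphabet with sentinels
#'
#' @param tokens character vector of distinct SELFIES tokens.
#' @return character vector of class `selfies_alphabet`: the three
#'   sentinels (`!` start, `E` end, `[nop]` pad) followed by the tokens.
#' @export
selfies_alphabet <- function(tokens) {
  stopifnot(is.character(tokens))
  tokens <- setdiff(unique(tokens),
                    c(SENTINEL_START, SENTINEL_END, SENTINEL_PAD))
  structure(c(SENTINEL_START, SENTINEL_END, SENTINEL_PAD, tokens),
            class = "selfies_alphabet")
}

#' One-hot encode a token sequence
#'
#' Row `t` of the result is the indicator of token `t` of the
#' sentinel-wrapped sequence `! <entry> E`; remaining rows carry the pad
#' indicator, so all matrices for a corpus share one shape and every row
#' sums to exactly 1.
#'
#' @param entry SELFIES string or token character vector.
#' @param alphabet a [selfies_alphabet()].
#' @param max_len number of rows of the matrix.
#' @return binary matrix `max_len` x `length(alphabet)`.
#' @export
vectorize <- function(entry, alphabet, max_len) {
  toks <- if (is.character(entry) && length(entry) == 1L)
    selfies_tokens(entry) else as.character(entry)
  seqn <- c(SENTINEL_START, toks, SENTINEL_END)
  if (length(seqn) > max_len)
    stop("entry longer than max_len (", length(seqn), " > ", max_len, ")")
  idx <- match(seqn, alphabet)
  if (anyNA(idx))
    stop("token(s) not in alphabet: ",
         paste(unique(seqn[is.na(idx)]), collapse = " "))
  pad <- match(SENTINEL_PAD, alphabet)
  rows <- c(idx, rep(pad, max_len - length(seqn)))
  m <- matrix(0L, nrow = max_len, ncol = length(alphabet),
              dimnames = list(NULL, as.character(alphabet)))
  m[cbind(seq_len(max_len), rows)] <- 1L
  m
}

#' Invert [vectorize()]
#'
#' @param mat a one-hot matrix produced by [vectorize()].
#' @param alphabet the matching [selfies_alphabet()].
#' @return the SELFIES string (sentinels and padding stripped).
#' @export
devectorize <- function(mat, alphabet) {
  stopifnot(is.matrix(mat), ncol(mat) == length(alphabet))
  if (!all(rowSums(mat) == 1L))
    stop("matrix is not one-hot: every row must sum to 1")
  toks <- as.character(alphabet)[max.col(mat, ties.method = "first")]
  toks <- toks[toks != SENTINEL_PAD & toks != SENTINEL_START]
  end <- match(SENTINEL_END, toks)
  if (!is.na(end)) toks <- toks[seq_len(end - 1L)]
  paste(toks, collapse = "")
}

#' Split a corpus into training and validation partitions
#'
#' @param n_entries total number of entries (>= 2).
#' @param val_fraction validation fraction in (0, 1); default 0.1.
#' @param seed seed for the shuffle assigning entries to partitions.
#' @return list with `n_train`, `n_val`, and index vectors `train`,
#'   `val`. `n_train = floor(n_entries * (1 - val_fraction))`.
#' @examples
#' split_corpus(134373, 0.1)  # 120935 train / 13438 validation
#' @export
split_corpus <- function(n_entries, val_fraction = 0.1, seed = 1L) {
  stopifnot(length(n_entries) == 1L, n_entries == floor(n_entries))
  if (n_entries < 2L)
    stop("need at least 2 entries to form train and validation sets")
  if (!(val_fraction > 0 && val_fraction < 1))
    stop("val_fraction must be in (0, 1)")
  n_train <- floor(n_entries * (1 - val_fraction))
  n_val <- n_entries - n_train
  perm <- with_seed(seed, sample.int(n_entries))
  list(n_train = as.integer(n_train), n_val = as.integer(n_val),
       train = sort(perm[seq_len(n_train)]),
       val = sort(perm[seq.int(n_train + 1L, n_entries)]))
}

#' Write a corpus manifest CSV and alphabet listing
#'
#' @param corpus a [build_corpus()] result.
#' @param path output CSV path (`source_id`, `selfies`, `n_tokens`).
#' @export
write_corpus_manifest <- function(corpus, path) {
  utils::write.csv(corpus$entries, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corpus_manifest
#' @param alphabet a [selfies_alphabet()].
#' @export
write_alphabet <- function(alphabet, path) {
  jsonlite::write_json(list(tokens = as.character(alphabet)), path,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
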
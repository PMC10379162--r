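# Chemical-space analytics: path fingerprints, Tanimoto similarity,
# nearest-seed mapping, similarity histograms, 2-D embedding, and an
# injectable PubChem lookup.

#' Molecular fingerprint
#'
#' Daylight-like path-based bit fingerprint (Open Babel FP2; native
#' length 1024 bits, optionally folded). Deterministic and invariant to
#' the SMILES representation chosen for a molecule.
#'
#' @param smiles character vector of SMILES (or a [compound_set()]).
#' @param nbits fingerprint length; the engine's native 1024 by default.
#' @return list of `fingerprint` objects: integer vectors of set-bit
#'   positions (0-based) with attribute `nbits`.
#' @export
fingerprint <- function(smiles, nbits = 1024L) {
  if (inherits(smiles, "compound_set")) smiles <- smiles$smiles
  stopifnot(nbits >= 1L)
  if (length(smiles) == 0L) return(list())
  bad <- !is_valid_smiles(smiles)
  if (any(bad))
    stop("unparseable SMILES: '", smiles[which(bad)[1]], "'")
  bits <- ob_fingerprint_bits(smiles, nbits = nbits)
  lapply(bits, function(b)
    structure(as.integer(b), nbits = as.integer(nbits),
              class = "fingerprint"))
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint> ", length(unclass(x)), " of ", attr(x, "nbits"),
      " bits set\n", sep = "")
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|`; 1 for identical fingerprints, 0 when
#' no bits are shared. Two empty fingerprints count as identical (1).
#'
#' @param a,b [fingerprint()] objects (or plain integer bit-position
#'   vectors with matching `nbits`).
#' @return similarity in `[0, 1]`.
#' @examples
#' a <- structure(c(1L, 2L, 3L), nbits = 16L, class = "fingerprint")
#' b <- structure(c(2L, 3L, 4L), nbits = 16L, class = "fingerprint")
#' tanimoto(a, b)  # 2 shared / 4 union = 0.5
#' @export
tanimoto <- function(a, b) {
  na <- attr(a, "nbits"); nb <- attr(b, "nbits")
  if (!is.null(na) && !is.null(nb) && na != nb)
    stop("fingerprints have different lengths: ", na, " vs ", nb)
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  u <- length(union(a, b))
  if (u == 0L) return(1)  # identical absence
  length(intersect(a, b)) / u
}

#' Candidate-by-seed similarity matrix and nearest-seed mapping
#'
#' @param candidates,initial [compound_set()]s (or lists of
#'   fingerprints); both non-empty.
#' @param nbits fingerprint length.
#' @return object of class `similarity_result`: `matrix` (candidates x
#'   initial, dimnames = ids) and `nearest` (data.frame candidate_id,
#'   nearest_id, similarity; ties broken by seed order).
#' @export
similarity_matrix <- function(candidates, initial, nbits = 1024L) {
  as_fps <- function(x) {
    if (inherits(x, "compound_set"))
      list(fp = fingerprint(x, nbits), id = x$id)
    else list(fp = x, id = names(x) %||% paste0("item_", seq_along(x)))
  }
  ca <- as_fps(candidates); init <- as_fps(initial)
  if (length(ca$fp) == 0L || length(init$fp) == 0L)
    stop("both candidate and initial sets must be non-empty")
  m <- matrix(0, length(ca$fp), length(init$fp),
              dimnames = list(ca$id, init$id))
  for (i in seq_along(ca$fp))
    for (j in seq_along(init$fp))
      m[i, j] <- tanimoto(ca$fp[[i]], init$fp[[j]])
  best <- apply(m, 1L, which.max)  # first maximum = seed-order tie-break
  nearest <- data.frame(candidate_id = ca$id,
                        nearest_id = init$id[best],
                        similarity = m[cbind(seq_along(best), best)],
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(matrix = m, nearest = nearest),
            class = "similarity_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.similarity_result <- function(x, ...) {
  cat("<similarity_result> ", nrow(x$matrix), " candidates x ",
      ncol(x$matrix), " seeds; mean nearest similarity ",
      signif(mean(x$nearest$similarity), 3), "\n", sep = "")
  invisible(x)
}

#' Histogram of similarity values
#'
#' Half-open bins `[lo, hi)` of the given width over `[0, 1]`; the last
#' bin is closed so a similarity of exactly 1 is counted.
#'
#' @param similarities numeric values in `[0, 1]`.
#' @param bin_width bin width (must divide 1 into a whole number of
#'   bins up to rounding).
#' @return data.frame with `lo`, `hi`, `count`; counts sum to the number
#'   of input values.
#' @export
similarity_histogram <- function(similarities, bin_width = 0.1) {
  s <- as.numeric(similarities)
  if (any(!is.finite(s))) stop("similarities must be finite")
  if (any(s < 0 | s > 1)) stop("similarities must lie in [0, 1]")
  nb <- max(1L, ceiling(round(1 / bin_width, 9)))
  lo <- (seq_len(nb) - 1L) * bin_width
  hi <- pmin(lo + bin_width, 1)
  idx <- pmin(floor(s / bin_width) + 1L, nb)  # top edge closed
  counts <- tabulate(idx, nbins = nb)
  data.frame(lo = lo, hi = hi, count = counts)
}

#' 2-D chemical-space embedding
#'
#' Embeds fingerprints with t-SNE on Tanimoto (Jaccard) distances.
#' Run it on the joint candidate + seed set so both live in one space.
#'
#' @param fps list of [fingerprint()]s (>= 5), optionally named by
#'   compound id.
#' @param seed integer seed (same seed, same coordinates).
#' @param perplexity t-SNE perplexity; default `min(30, n/4)`, and must
#'   be smaller than the number of items.
#' @param ids compound ids (default: names of `fps`).
#' @return object of class `chemspace_embedding`: data.frame `coords`
#'   with id, TSNE_C1, TSNE_C2, plus `seed` and `perplexity`.
#' @export
embed_2d <- function(fps, seed = 1L, perplexity = NULL, ids = NULL) {
  n <- length(fps)
  if (n < 5L) stop("need at least 5 items to embed")
  if (is.null(perplexity)) perplexity <- max(2, min(30, n / 4))
  if (is.null(ids)) ids <- names(fps) %||% paste0("item_", seq_len(n))
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (j > i) d[i, j] <- d[j, i] <- 1 - tanimoto(fps[[i]], fps[[j]])
  Y <- tsne_embed(d, perplexity = perplexity, seed = seed)
  structure(list(coords = data.frame(id = ids, TSNE_C1 = Y[, 1],
                                     TSNE_C2 = Y[, 2],
                                     stringsAsFactors = FALSE),
                 seed = as.integer(seed), perplexity = perplexity),
            class = "chemspace_embedding")
}

#' @export
print.chemspace_embedding <- function(x, ...) {
  cat("<chemspace_embedding> ", nrow(x$coords), " items; perplexity ",
      x$perplexity, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' PubChem lookup with an injectable client
#'
#' Checks whether each structure exists in PubChem. The client is
#' injected so pipelines are testable offline: `offline_client()` answers
#' "unavailable" for everything, `mock_client(map)` serves a fixed
#' canonical-SMILES -> CID map, and `pubchem_rest_client()` queries the
#' live PUG-REST service. Results are cached per canonical SMILES within
#' the call; network failures degrade to "unavailable" rather than
#' failing the pipeline.
#'
#' @param records a [compound_set()].
#' @param client a lookup client.
#' @return data.frame with `id`, `canonical`, `status`
#'   (`found` / `not_found` / `unavailable`) and `external_id`.
#' @export
pubchem_lookup <- function(records, client = offline_client()) {
  stopifnot(inherits(records, "compound_set"))
  cache <- new.env(hash = TRUE)
  status <- character(nrow(records)); ext <- rep(NA_character_,
                                                 nrow(records))
  for (i in seq_len(nrow(records))) {
    key <- records$canonical[i]
    res <- cache[[key]]
    if (is.null(res)) {
      res <- tryCatch(client(key),
                      error = function(e) list(status = "unavailable",
                                               id = NA_character_))
      cache[[key]] <- res
    }
    status[i] <- res$status
    ext[i] <- res$id
  }
  data.frame(id = records$id, canonical = records$canonical,
             status = status, external_id = ext, stringsAsFactors = FALSE)
}

#' @rdname pubchem_lookup
#' @export
offline_client <- function() {
  function(canonical_smiles) list(status = "unavailable",
                                  id = NA_character_)
}

#' @rdname pubchem_lookup
#' @param map named character vector: canonical SMILES -> external id.
#' @export
mock_client <- function(map) {
  force(map)
  function(canonical_smiles) {
    if (canonical_smiles %in% names(map))
      list(status = "found", id = unname(map[[canonical_smiles]]))
    else list(status = "not_found", id = NA_character_)
  }
}

#' @rdname pubchem_lookup
#' @param timeout seconds before a request is abandoned.
#' @export
pubchem_rest_client <- function(timeout = 10) {
  function(canonical_smiles) {
    url <- paste0("https://pubchem.ncbi.nlm.nih.gov/rest/pug/compound/",
                  "smiles/", utils::URLencode(canonical_smiles,
                                              reserved = TRUE),
                  "/cids/TXT")
    txt <- tryCatch({
      con <- url(url)
      on.exit(close(con))
      old <- options(timeout = timeout); on.exit(options(old), add = TRUE)
      readLines(con, warn = FALSE)
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(txt)) return(list(status = "unavailable",
                                  id = NA_character_))
    cid <- suppressWarnings(as.integer(txt[1]))
    if (is.na(cid) || cid == 0L)
      list(status = "not_found", id = NA_character_)
    else list(status = "found", id = as.character(cid))
  }
}

#' Write embedding / similarity outputs
#'
#' @param embedding a [embed_2d()] result.
#' @param labels optional set labels (initial / generated / selected).
#' @param path output CSV path.
#' @export
write_embedding <- function(embedding, path, labels = NULL) {
  df <- embedding$coords
  df$set_label <- if (is.null(labels)) NA_character_ else labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @param sim a [similarity_matrix()] result.
#' @export
write_similarity <- function(sim, path) {
  utils::write.csv(data.frame(candidate_id = rownames(sim$matrix),
                              sim$matrix, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
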
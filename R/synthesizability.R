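# Fragment-additive Bayesian synthesizability scoring.
#
# The score follows the SYBA construction: a molecule is decomposed into
# circular atom environments (fragments), each fragment carries a
# log-odds weight estimated from a corpus of easy-to-synthesize
# (positive) versus hard (negative) molecules under a Bernoulli
# presence/absence model, and the molecule's score is the sum of the
# weights of its distinct fragments. Higher scores mean easier synthesis.
# The selection rule scores the seed set, takes the minimum as the
# threshold, and retains generated candidates at or above it.

#' Circular fragments of a molecule
#'
#' Environments of every heavy atom at radii 0 up to `radius`, hashed to
#' stable string ids (Morgan-style iterative neighbourhood refinement).
#'
#' @param smiles a single SMILES string.
#' @param radius maximum environment radius (default 2).
#' @return character vector of fragment ids (one per atom per radius; a
#'   multiset -- duplicates mean repeated environments).
#' @export
fragment_molecule <- function(smiles, radius = 2L) {
  stopifnot(length(smiles) == 1L, radius >= 0L)
  g <- parse_smiles(kekulize_smiles(smiles))
  atom_environments(g, radius = radius)
}

#' Train a fragment log-odds scorer
#'
#' Weight of fragment f:
#' `log((n_pos(f) + s) / (N_pos + 2s)) - log((n_neg(f) + s) / (N_neg + 2s))`
#' where `n_pos(f)` counts positive molecules *containing* f (presence,
#' not multiplicity), `N_pos` the number of positive molecules, and `s`
#' the smoothing pseudo-count. Fragments never seen in training score 0.
#'
#' @param positives,negatives [compound_set()]s (or character SMILES
#'   vectors) of easy and hard molecules; both non-empty.
#' @param radius circular fragment radius.
#' @param smoothing positive pseudo-count (default 1).
#' @return object of class `fragment_score_model`: named numeric
#'   `weights`, `radius`, `smoothing`, class counts.
#' @export
train_fragment_model <- function(positives, negatives, radius = 2L,
                                 smoothing = 1) {
  pos <- if (inherits(positives, "compound_set")) positives$smiles
         else as.character(positives)
  neg <- if (inherits(negatives, "compound_set")) negatives$smiles
         else as.character(negatives)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both positive and negative sets must be non-empty")
  stopifnot(smoothing > 0)
  presence <- function(smis) {
    tab <- new.env(hash = TRUE)
    for (s in smis) {
      for (f in unique(fragment_molecule(s, radius)))
        tab[[f]] <- (if (is.null(tab[[f]])) 0L else tab[[f]]) + 1L
    }
    unlist(as.list(tab))
  }
  cp <- presence(pos); cn <- presence(neg)
  frags <- union(names(cp), names(cn))
  np <- ifelse(frags %in% names(cp), cp[frags], 0L)
  nn <- ifelse(frags %in% names(cn), cn[frags], 0L)
  w <- log((np + smoothing) / (length(pos) + 2 * smoothing)) -
       log((nn + smoothing) / (length(neg) + 2 * smoothing))
  names(w) <- frags
  structure(list(weights = w, radius = as.integer(radius),
                 smoothing = smoothing,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "fragment_score_model")
}

#' @export
print.fragment_score_model <- function(x, ...) {
  cat("<fragment_score_model> radius ", x$radius, ", smoothing ",
      x$smoothing, "; ", length(x$weights), " fragments from ",
      x$n_pos, " positive / ", x$n_neg, " negative molecules\n", sep = "")
  invisible(x)
}

#' Synthesizability score of molecules
#'
#' Sum of the model's log-odds weights over each molecule's *distinct*
#' fragments; fragments absent from the model contribute 0. Invariant to
#' the SMILES representation chosen for a molecule.
#'
#' @param model a [train_fragment_model()] scorer (or any object with
#'   `weights` and `radius`).
#' @param smiles character vector of SMILES (or a [compound_set()]).
#' @return numeric scores, one per molecule.
#' @export
score_synthesizability <- function(model, smiles) {
  if (inherits(smiles, "compound_set")) smiles <- smiles$smiles
  vapply(smiles, function(s) {
    frags <- unique(fragment_molecule(s, model$radius))
    known <- frags[frags %in% names(model$weights)]
    sum(model$weights[known])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Score threshold from the seed set
#'
#' The selection threshold is the minimum score over the initial
#' structures: no generated candidate should look harder to synthesize
#' than the hardest molecule that has actually been made.
#'
#' @param scores numeric scores of the initial structures (non-empty).
#' @return object of class `score_threshold` with `value` and
#'   `provenance`.
#' @examples
#' threshold_from_initial(c(50.1, 42.29, 77.0))$value  # 42.29
#' @export
threshold_from_initial <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L || anyNA(scores))
    stop("scores must be non-empty and non-missing")
  structure(list(value = min(scores),
                 provenance = "min over initial structures"),
            class = "score_threshold")
}

#' @export
print.score_threshold <- function(x, ...) {
  cat("<score_threshold> ", x$value, " (", x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Filter candidates by synthesizability score
#'
#' Retains candidates with `score >= threshold` (inclusive boundary).
#'
#' @param candidates a [compound_set()] (or data.frame with an `id`).
#' @param scores numeric scores aligned with the candidates.
#' @param threshold a [threshold_from_initial()] object or a number.
#' @return the retained subset, with a `syba_score` column appended.
#' @export
filter_by_score <- function(candidates, scores, threshold) {
  cut <- if (inherits(threshold, "score_threshold")) threshold$value
         else as.numeric(threshold)
  stopifnot(length(scores) == nrow(candidates))
  out <- candidates[scores >= cut, , drop = FALSE]
  out$syba_score <- scores[scores >= cut]
  out
}

#' Write a scorer archive / filter report
#'
#' @param model a [train_fragment_model()] scorer.
#' @param path output path (JSON: radius, smoothing, weights table).
#' @export
write_fragment_model <- function(model, path) {
  jsonlite::write_json(
    list(radius = model$radius, smoothing = model$smoothing,
         n_pos = model$n_pos, n_neg = model$n_neg,
         weights = as.list(model$weights)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fragment_model
#' @export
read_fragment_model <- function(path) {
  j <- jsonlite::read_json(path)
  structure(list(weights = unlist(j$weights), radius = j$radius,
                 smoothing = j$smoothing, n_pos = j$n_pos,
                 n_neg = j$n_neg),
            class = "fragment_score_model")
}

#' @rdname filter_by_score
#' @param scores_all scores for every candidate.
#' @param path output CSV path (candidate_id, score, retained).
#' @export
write_filter_report <- function(candidates, scores_all, threshold, path) {
  cut <- if (inherits(threshold, "score_threshold")) threshold$value
         else as.numeric(threshold)
  utils::write.csv(
    data.frame(candidate_id = candidates$id, score = scores_all,
               retained = scores_all >= cut),
    path, row.names = FALSE)
  invisible(path)
}
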
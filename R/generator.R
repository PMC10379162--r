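# Generative sequence model over SELFIES tokens.
#
# The model is an autoencoder: the one-hot token matrix of an entry is
# flattened, mapped through a tanh encoder to a latent vector, and decoded
# by a linear layer into per-position logits over the alphabet, trained
# with per-position categorical cross-entropy (Adam, full batch or
# mini-batches for larger corpora). Novel structures are sampled by
# encoding a seed molecule, perturbing its latent vector with isotropic
# Gaussian noise, and decoding greedily (argmax per position) until the
# end sentinel. Because the output grammar is SELFIES, every decoded
# sequence corresponds to a valid molecule.

flatten_entry <- function(tokens, alphabet, max_len) {
  as.numeric(vectorize(tokens, alphabet, max_len))
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Train the SELFIES autoencoder
#'
#' @param corpus a [build_corpus()] result with at least 2 entries.
#' @param epochs number of training epochs (>= 1).
#' @param latent_dim latent-space dimension (default 64).
#' @param seed integer seed controlling initialization, the
#'   train/validation split and mini-batch order.
#' @param val_fraction validation fraction handed to [split_corpus()].
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size; corpora at or below this size train
#'   full-batch.
#' @param init optional previously trained model to resume from (its
#'   weights are the starting point; alphabet and max_len must match).
#' @return object of class `selfies_autoencoder` with weights, alphabet,
#'   `max_len`, `latent_dim`, the train/validation split, and
#'   `loss_history` (per-epoch training and validation categorical
#'   cross-entropy, in nats per token position).
#' @export
train_generator <- function(corpus, epochs = 300L, latent_dim = 64L,
                            seed = 1L, val_fraction = 0.1,
                            learning_rate = 0.05, batch_size = 256L,
                            init = NULL) {
  stopifnot(inherits(corpus, "token_corpus"), epochs >= 1L,
            latent_dim >= 1L)
  n <- nrow(corpus$entries)
  if (n < 2L) stop("corpus must contain at least 2 entries")
  alphabet <- corpus$alphabet
  max_len <- corpus$max_len
  A <- length(alphabet); D <- max_len * A

  split <- split_corpus(n, val_fraction, seed = seed)
  X <- t(vapply(corpus$tokens,
                flatten_entry, numeric(D),
                alphabet = alphabet, max_len = max_len))
  Xtr <- X[split$train, , drop = FALSE]
  Xva <- X[split$val, , drop = FALSE]

  if (!is.null(init)) {
    stopifnot(inherits(init, "selfies_autoencoder"),
              identical(as.character(init$alphabet), as.character(alphabet)),
              init$max_len == max_len, init$latent_dim == latent_dim)
    W1 <- init$W1; b1 <- init$b1; W2 <- init$W2; b2 <- init$b2
  } else {
    w <- with_seed(seed, stats::rnorm(D * latent_dim + latent_dim * D))
    W1 <- matrix(w[seq_len(D * latent_dim)] * sqrt(1 / D), D, latent_dim)
    W2 <- matrix(w[-seq_len(D * latent_dim)] * sqrt(1 / latent_dim),
                 latent_dim, D)
    b1 <- numeric(latent_dim); b2 <- numeric(D)
  }

  # cross-entropy per token position, plus softmax probabilities
  ce_loss <- function(Xb) {
    Z <- tanh(sweep(Xb %*% W1, 2L, b1, "+"))
    L <- sweep(Z %*% W2, 2L, b2, "+")
    nb <- nrow(Xb)
    P <- matrix(0, nb, D)
    loss <- 0
    for (i in seq_len(nb)) {
      logits <- matrix(L[i, ], max_len, A)
      p <- softmax_rows(logits)
      y <- matrix(Xb[i, ], max_len, A)
      loss <- loss - sum(y * log(pmax(p, 1e-12)))
      P[i, ] <- as.numeric(p)
    }
    list(loss = loss / (nb * max_len), P = P, Z = Z)
  }

  adam <- list(t = 0)
  for (nm in c("W1", "b1", "W2", "b2")) {
    adam[[paste0("m_", nm)]] <- get(nm) * 0
    adam[[paste0("v_", nm)]] <- get(nm) * 0
  }
  adam_step <- function(nm, grad) {
    m <- adam[[paste0("m_", nm)]] * 0.9 + 0.1 * grad
    v <- adam[[paste0("v_", nm)]] * 0.999 + 0.001 * grad^2
    adam[[paste0("m_", nm)]] <<- m
    adam[[paste0("v_", nm)]] <<- v
    mh <- m / (1 - 0.9^adam$t); vh <- v / (1 - 0.999^adam$t)
    get(nm, envir = parent.env(environment())) -
      learning_rate * mh / (sqrt(vh) + 1e-8)
  }

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  ntr <- nrow(Xtr)
  batch_plan <- with_seed(seed + 104729L, {
    lapply(seq_len(epochs), function(e) sample.int(ntr))
  })

  for (ep in seq_len(epochs)) {
    ord <- batch_plan[[ep]]
    starts <- seq(1L, ntr, by = batch_size)
    for (s in starts) {
      idx <- ord[seq.int(s, min(s + batch_size - 1L, ntr))]
      Xb <- Xtr[idx, , drop = FALSE]
      fw <- ce_loss(Xb)
      if (!is.finite(fw$loss))
        stop("non-finite training loss at epoch ", ep,
             "; reduce learning_rate (current ", learning_rate, ")")
      nb <- nrow(Xb)
      dL <- (fw$P - Xb) / (nb * max_len)     # d loss / d logits
      gW2 <- crossprod(fw$Z, dL)
      gb2 <- colSums(dL)
      dZ <- (dL %*% t(W2)) * (1 - fw$Z^2)
      gW1 <- crossprod(Xb, dZ)
      gb1 <- colSums(dZ)
      adam$t <- adam$t + 1
      W1 <- adam_step("W1", gW1); b1 <- adam_step("b1", gb1)
      W2 <- adam_step("W2", gW2); b2 <- adam_step("b2", gb2)
    }
    tr <- ce_loss(Xtr)$loss
    va <- ce_loss(Xva)$loss
    if (!is.finite(tr) || !is.finite(va))
      stop("non-finite loss at epoch ", ep, " (train ", tr, ", val ", va,
           ")")
    history[ep, ] <- list(ep, tr, va)
  }

  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 alphabet = alphabet, max_len = max_len,
                 latent_dim = as.integer(latent_dim),
                 loss_history = history, split = split, seed = seed,
                 learning_rate = learning_rate),
            class = "selfies_autoencoder")
}

#' @export
print.selfies_autoencoder <- function(x, ...) {
  h <- x$loss_history
  cat("<selfies_autoencoder> latent_dim ", x$latent_dim, ", alphabet ",
      length(x$alphabet), " tokens, max_len ", x$max_len, "\n",
      "  trained ", nrow(h), " epochs; final loss train ",
      signif(h$train_loss[nrow(h)], 4), " / val ",
      signif(h$val_loss[nrow(h)], 4), " (nats/position)\n", sep = "")
  invisible(x)
}

# Latent vector of one SELFIES entry.
encode_latent <- function(model, selfies) {
  x <- flatten_entry(selfies_tokens(selfies), model$alphabet, model$max_len)
  as.numeric(tanh(x %*% model$W1 + model$b1))
}

# Greedy decode of one latent vector: argmax token per position, reading
# until the end sentinel. Returns the SELFIES string with attribute
# `truncated` = TRUE when no end sentinel appeared within max_len.
decode_latent <- function(model, z) {
  logits <- matrix(as.numeric(z %*% model$W2 + model$b2),
                   model$max_len, length(model$alphabet))
  toks <- as.character(model$alphabet)[max.col(logits,
                                               ties.method = "first")]
  toks <- toks[toks != SENTINEL_START & toks != SENTINEL_PAD]
  end <- match(SENTINEL_END, toks)
  truncated <- is.na(end)
  if (!truncated) toks <- toks[seq_len(end - 1L)]
  structure(paste(toks, collapse = ""), truncated = truncated)
}

#' Reconstruction accuracy of the autoencoder on corpus entries
#'
#' Fraction of token positions (sentinel-wrapped, padded sequences) that
#' the greedy decode reproduces exactly.
#'
#' @param model a [train_generator()] model.
#' @param corpus the corpus to score.
#' @param idx entry indices (default: all).
#' @return scalar accuracy in `[0, 1]`.
#' @export
reconstruction_accuracy <- function(model, corpus, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(corpus$entries))
  A <- length(model$alphabet)
  hits <- 0L; total <- 0L
  for (i in idx) {
    x <- flatten_entry(corpus$tokens[[i]], model$alphabet, model$max_len)
    z <- tanh(x %*% model$W1 + model$b1)
    logits <- matrix(as.numeric(z %*% model$W2 + model$b2),
                     model$max_len, A)
    pred <- max.col(logits, ties.method = "first")
    truth <- max.col(matrix(x, model$max_len, A), ties.method = "first")
    hits <- hits + sum(pred == truth)
    total <- total + model$max_len
  }
  hits / total
}

#' Sample candidate SELFIES strings around one seed molecule
#'
#' Encodes the record to its latent vector, adds isotropic Gaussian noise
#' of scale `noise_scale` (one independent draw per sample), and decodes
#' greedily until the end sentinel.
#'
#' @param model a [train_generator()] model.
#' @param record one-row [compound_set()] (or a SELFIES string).
#' @param n_samples number of samples to draw.
#' @param noise_scale standard deviation of the latent noise (>= 0, in
#'   latent units); 0 reproduces the greedy reconstruction.
#' @param seed integer seed.
#' @return character vector of `n_samples` SELFIES strings (duplicates
#'   allowed); attribute `truncated` flags decodes that ran past
#'   `max_len` without an end sentinel.
#' @export
generate_candidates <- function(model, record, n_samples = 20L,
                                noise_scale = 0.5, seed = 1L) {
  stopifnot(inherits(model, "selfies_autoencoder"), n_samples >= 1L,
            noise_scale >= 0)
  selfies <- if (inherits(record, "data.frame")) {
    stopifnot(nrow(record) == 1L)
    smiles_to_selfies(record$smiles[1])
  } else as.character(record)
  toks <- selfies_tokens(selfies)
  unknown <- setdiff(toks, as.character(model$alphabet))
  if (length(unknown) > 0L)
    stop("token(s) not in model alphabet: ",
         paste(unknown, collapse = " "))
  z0 <- encode_latent(model, selfies)
  noise <- with_seed(seed, matrix(stats::rnorm(n_samples * model$latent_dim,
                                               sd = max(noise_scale, 1e-300)),
                                  n_samples, model$latent_dim))
  if (noise_scale == 0) noise[] <- 0
  out <- character(n_samples); trunc <- logical(n_samples)
  for (k in seq_len(n_samples)) {
    dec <- decode_latent(model, z0 + noise[k, ])
    out[k] <- dec
    trunc[k] <- attr(dec, "truncated")
  }
  structure(out, truncated = trunc)
}

#' Generate a library of novel structures from a seed set
#'
#' Runs [generate_candidates()] for every seed record, decodes SELFIES to
#' SMILES, drops undecodable samples, deduplicates on canonical SMILES
#' and removes any structure already present in the seed set.
#'
#' @param model a [train_generator()] model.
#' @param initial the seed [compound_set()].
#' @param n_samples_per_structure samples per seed molecule (default 20).
#' @param noise_scale latent noise scale.
#' @param seed integer seed.
#' @param corpus optional training [build_corpus()]: when given, each
#'   seed record is encoded through its first corpus entry, whose tokens
#'   are guaranteed to lie in the model alphabet.
#' @return object of class `generation_result`: `candidates` (a
#'   [compound_set()] of novel structures), `provenance` (data.frame
#'   candidate_id, smiles, selfies, source_id, noise_seed), and the
#'   funnel counts `n_raw`, `n_valid`, `n_novel`.
#' @export
generate_library <- function(model, initial, n_samples_per_structure = 20L,
                             noise_scale = 0.5, seed = 1L,
                             corpus = NULL) {
  stopifnot(inherits(model, "selfies_autoencoder"),
            inherits(initial, "compound_set"))
  raw_sf <- character(); raw_src <- character(); raw_seed <- integer()
  for (i in seq_len(nrow(initial))) {
    s <- seed + i
    rec <- initial[i, , drop = FALSE]
    seed_repr <- rec
    if (!is.null(corpus)) {
      hit <- which(corpus$entries$source_id == rec$id)
      if (length(hit) > 0L) seed_repr <- corpus$entries$selfies[hit[1]]
    }
    cand <- generate_candidates(model, seed_repr,
                                n_samples = n_samples_per_structure,
                                noise_scale = noise_scale, seed = s)
    raw_sf <- c(raw_sf, as.character(cand))
    raw_src <- c(raw_src, rep(initial$id[i], length(cand)))
    raw_seed <- c(raw_seed, rep(s, length(cand)))
  }
  n_raw <- length(raw_sf)

  smi <- rep(NA_character_, n_raw)
  for (k in seq_len(n_raw)) {
    smi[k] <- tryCatch(selfies_to_smiles(raw_sf[k]),
                       error = function(e) NA_character_)
  }
  ok <- !is.na(smi)
  can <- rep(NA_character_, n_raw)
  if (any(ok)) {
    res <- suppressWarnings(ob_convert(smi[ok], to = "CAN"))
    can[ok] <- res
  }
  valid <- !is.na(can)
  n_valid <- sum(valid)

  keep <- valid & !duplicated(can) & !(can %in% initial$canonical)
  n_novel <- sum(keep)

  if (n_novel > 0L) {
    ids <- paste0("gen_", seq_len(n_novel))
    candidates <- compound_set(can[keep], id = ids)
    provenance <- data.frame(candidate_id = ids, smiles = can[keep],
                             selfies = raw_sf[keep],
                             source_id = raw_src[keep],
                             noise_seed = raw_seed[keep],
                             stringsAsFactors = FALSE)
  } else {
    candidates <- NULL
    provenance <- data.frame(candidate_id = character(),
                             smiles = character(), selfies = character(),
                             source_id = character(),
                             noise_seed = integer())
  }
  structure(list(candidates = candidates, provenance = provenance,
                 n_raw = n_raw, n_valid = as.integer(n_valid),
                 n_novel = as.integer(n_novel)),
            class = "generation_result")
}

#' @export
print.generation_result <- function(x, ...) {
  cat("<generation_result> funnel: ", x$n_raw, " raw -> ", x$n_valid,
      " valid -> ", x$n_novel, " novel\n", sep = "")
  invisible(x)
}

#' @export
predict.selfies_autoencoder <- function(object, newdata, noise_scale = 0,
                                        seed = 1L, ...) {
  if (inherits(newdata, "compound_set")) {
    vapply(seq_len(nrow(newdata)), function(i) {
      as.character(generate_candidates(object,
                                       newdata[i, , drop = FALSE],
                                       n_samples = 1L,
                                       noise_scale = noise_scale,
                                       seed = seed + i))
    }, character(1))
  } else {
    vapply(as.character(newdata), function(s) {
      as.character(generate_candidates(object, s, n_samples = 1L,
                                       noise_scale = noise_scale,
                                       seed = seed))
    }, character(1), USE.NAMES = FALSE)
  }
}
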
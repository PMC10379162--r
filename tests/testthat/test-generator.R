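# Generator contracts: overfit reconstruction, seeded determinism, noise
# sampling, and the generation funnel.

test_that("training overfits a small corpus: loss drops, reconstruction is near-perfect", {
  fx <- overfit_fixture()
  h <- fx$model$loss_history
  expect_identical(nrow(h), 300L)
  expect_true(all(is.finite(h$train_loss)) && all(h$train_loss >= 0))
  expect_true(all(is.finite(h$val_loss)) && all(h$val_loss >= 0))
  expect_lt(h$train_loss[300], h$train_loss[1])
  expect_gte(reconstruction_accuracy(fx$model, fx$corpus), 0.95)
})

test_that("validation entries are disjoint from training entries", {
  sp <- overfit_fixture()$model$split
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_identical(sort(c(sp$train, sp$val)),
                   seq_len(nrow(overfit_fixture()$corpus$entries)))
})

test_that("training is seeded and resumable", {
  recs <- compound_set(c("CCO", "Oc1ccccc1", "CCN"))
  co <- build_corpus(recs, n_attempts = 5, seed = 2)
  m1 <- train_generator(co, epochs = 30, latent_dim = 8, seed = 11)
  m2 <- train_generator(co, epochs = 30, latent_dim = 8, seed = 11)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$W1, m2$W1)
  # resuming from a trained model starts from its weights, far below a
  # cold start (fresh optimizer state may wobble the first steps)
  m3 <- train_generator(co, epochs = 10, latent_dim = 8, seed = 11,
                        init = m1)
  expect_identical(nrow(m3$loss_history), 10L)
  expect_lt(m3$loss_history$train_loss[10], m1$loss_history$train_loss[1])
  tiny <- build_corpus(recs[1, ], n_attempts = 1, seed = 1)
  expect_error(train_generator(tiny, epochs = 5), "at least 2 entries")
})

test_that("zero-noise decoding reproduces a training entry exactly", {
  fx <- overfit_fixture()
  tr <- fx$model$split$train
  sf <- fx$corpus$entries$selfies[tr[1]]
  out <- generate_candidates(fx$model, sf, n_samples = 1,
                             noise_scale = 0, seed = 99)
  expect_identical(as.character(out), sf)
})

test_that("sampling returns the requested number of decodable strings", {
  fx <- overfit_fixture()
  out <- generate_candidates(fx$model, fx$records[1, ], n_samples = 20,
                             noise_scale = 0.5, seed = 4)
  expect_length(as.character(out), 20L)
  for (s in as.character(out)) {
    smi <- tryCatch(selfies_to_smiles(s), error = function(e) NA)
    if (!is.na(smi)) expect_true(is_valid_smiles(smi), info = s)
  }
  # same seed, same samples
  out2 <- generate_candidates(fx$model, fx$records[1, ], n_samples = 20,
                              noise_scale = 0.5, seed = 4)
  expect_identical(as.character(out), as.character(out2))
  expect_error(generate_candidates(fx$model, "[Zn]", 5, 0.5, 1),
               "not in model alphabet")
})

test_that("latent noise weakly increases decode diversity (mean over seeds)", {
  fx <- overfit_fixture()
  mean_distinct <- function(noise) {
    mean(vapply(1:10, function(s) {
      out <- generate_candidates(fx$model, fx$records[1, ],
                                 n_samples = 10, noise_scale = noise,
                                 seed = s)
      length(unique(as.character(out)))
    }, numeric(1)))
  }
  d0 <- mean_distinct(0)
  d1 <- mean_distinct(0.5)
  d2 <- mean_distinct(2)
  expect_identical(d0, 1)
  expect_lte(d0, d1 + 1e-9)
  expect_lte(d1, d2 + 1e-9)
})

test_that("the generation funnel counts and filters correctly", {
  fx <- overfit_fixture()
  gl <- generate_library(fx$model, fx$records,
                         n_samples_per_structure = 20,
                         noise_scale = 1, seed = 11)
  expect_identical(gl$n_raw, 20L * nrow(fx$records))
  expect_lte(gl$n_novel, gl$n_valid)
  expect_lte(gl$n_valid, gl$n_raw)
  if (gl$n_novel > 0) {
    expect_false(any(gl$candidates$canonical %in% fx$records$canonical))
    expect_identical(anyDuplicated(gl$candidates$canonical), 0L)
    expect_identical(nrow(gl$provenance), gl$n_novel)
    expect_true(all(gl$provenance$source_id %in% fx$records$id))
  }
})

test_that("a single-molecule zero-noise model generates nothing novel", {
  recs <- compound_set(c("CCO", "CCC"))
  co <- build_corpus(recs, n_attempts = 3, seed = 1)
  m <- train_generator(co, epochs = 150, latent_dim = 8, seed = 5)
  gl <- generate_library(m, recs, n_samples_per_structure = 5,
                         noise_scale = 0, seed = 1)
  expect_identical(gl$n_novel, 0L)
  expect_identical(gl$n_raw, 10L)
})
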
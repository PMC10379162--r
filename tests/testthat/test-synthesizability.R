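# Fragment scoring and the minimum-over-seed-set selection rule.

test_that("circular fragments are deterministic and respect symmetry", {
  f_methane <- fragment_molecule("C", radius = 0)
  expect_length(f_methane, 1L)
  f_benzene <- fragment_molecule("c1ccccc1", radius = 0)
  expect_length(f_benzene, 6L)
  expect_length(unique(f_benzene), 1L)
  expect_identical(fragment_molecule("Oc1ccccc1O", 2),
                   fragment_molecule("Oc1ccccc1O", 2))
})

test_that("fragment weights follow the smoothed log-odds formula", {
  pos <- compound_set(rep("CCO", 10), id = paste0("p", 1:10))
  neg <- compound_set(rep("c1ccccc1", 10), id = paste0("n", 1:10))
  m <- train_fragment_model(pos, neg, radius = 1, smoothing = 1)
  # every CCO fragment: present in all 10 positives, no negatives
  frag_cco <- unique(fragment_molecule("CCO", 1))
  expect_equal(unname(m$weights[frag_cco]),
               rep(log(11), length(frag_cco)), tolerance = 1e-12)
  # equal frequency in both classes gives weight 0
  both <- compound_set(rep("CCN", 5), id = paste0("b", 1:5))
  m2 <- train_fragment_model(
    compound_set(rep("CCN", 5), id = paste0("p", 1:5)),
    compound_set(rep("CCN", 5), id = paste0("n", 1:5)))
  expect_equal(unname(m2$weights), rep(0, length(m2$weights)))
  # swapping the classes negates every weight
  m3 <- train_fragment_model(neg, pos, radius = 1, smoothing = 1)
  common <- intersect(names(m$weights), names(m3$weights))
  expect_equal(unname(m$weights[common]), -unname(m3$weights[common]))
  expect_error(train_fragment_model(character(), "CCO"), "non-empty")
})

test_that("scores are additive over distinct fragments with unknown = 0", {
  m <- structure(list(weights = c(a = 1.0, b = -2.0), radius = 0L,
                      smoothing = 1, n_pos = 1L, n_neg = 1L),
                 class = "fragment_score_model")
  # methane yields one radius-0 fragment; aliasing it into the model
  f <- unique(fragment_molecule("C", 0))
  m$weights <- c(1.0, -2.0)
  names(m$weights) <- c(f, "other")
  expect_equal(score_synthesizability(m, "C"), 1.0)
  m$weights <- c(-3.5)
  names(m$weights) <- "nothing_matches"
  expect_equal(score_synthesizability(m, "C"), 0)
})

test_that("scores are invariant to the SMILES representation", {
  fc <- make_fragment_corpus(1)
  m <- train_fragment_model(fc$positives, fc$negatives)
  variants <- enumerate_smiles("CC(=O)Nc1ccc(O)cc1", 25, seed = 3)
  scores <- score_synthesizability(m, variants)
  expect_gt(length(variants), 3L)
  expect_equal(max(scores) - min(scores), 0, tolerance = 1e-12)
})

test_that("the threshold is the minimum over initial structures", {
  thr <- threshold_from_initial(c(50.1, 42.29, 77.0))
  expect_equal(thr$value, 42.29)
  expect_identical(thr$provenance, "min over initial structures")
  expect_equal(threshold_from_initial(5.5)$value, 5.5)
  expect_equal(threshold_from_initial(c(50.1, 42.29, 77.0, 42.3))$value,
               42.29)
  expect_error(threshold_from_initial(numeric()), "non-empty")
})

test_that("filtering keeps the inclusive boundary and is monotone and idempotent", {
  cands <- compound_set(c("CCO", "CCC", "CCN"), id = c("a", "b", "c"))
  scores <- c(41.0, 42.29, 100.0)
  kept <- filter_by_score(cands, scores, 42.29)
  expect_identical(kept$id, c("b", "c"))
  expect_identical(nrow(filter_by_score(cands, scores, -Inf)), 3L)
  sizes <- vapply(c(-Inf, 41, 42.29, 50, 101),
                  function(t) nrow(filter_by_score(cands, scores, t)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # idempotent: refiltering the retained set changes nothing
  again <- filter_by_score(kept[, 1:4], kept$syba_score, 42.29)
  expect_identical(again$id, kept$id)
  # order-independent
  perm <- c(3, 1, 2)
  kept_perm <- filter_by_score(cands[perm, ], scores[perm], 42.29)
  expect_setequal(kept_perm$id, kept$id)
})

test_that("the trained scorer separates planted easy and hard classes", {
  for (s in 1:5) {
    fc <- make_fragment_corpus(seed = s)
    n_pos <- nrow(fc$positives); n_neg <- nrow(fc$negatives)
    tr_p <- seq_len(n_pos - 4); tr_n <- seq_len(n_neg - 4)
    m <- train_fragment_model(fc$positives[tr_p, ],
                              fc$negatives[tr_n, ])
    held_p <- score_synthesizability(m, fc$positives[-tr_p, ])
    held_n <- score_synthesizability(m, fc$negatives[-tr_n, ])
    expect_gt(mean(held_p), mean(held_n))
  }
})

test_that("the scorer archive round-trips through JSON", {
  fc <- make_fragment_corpus(2)
  m <- train_fragment_model(fc$positives, fc$negatives)
  path <- tempfile(fileext = ".json")
  write_fragment_model(m, path)
  back <- read_fragment_model(path)
  expect_equal(back$weights[names(m$weights)], m$weights)
  expect_identical(back$radius, m$radius)
  s <- score_synthesizability(back, "CC(=O)Nc1ccc(O)cc1")
  expect_equal(s, score_synthesizability(m, "CC(=O)Nc1ccc(O)cc1"))
})
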
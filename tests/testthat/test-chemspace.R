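# Fingerprints, Tanimoto similarity, histograms, embedding, lookup.

fp <- function(bits, nbits = 16L) {
  structure(as.integer(bits), nbits = as.integer(nbits),
            class = "fingerprint")
}

test_that("tanimoto matches its set definition and conventions", {
  expect_equal(tanimoto(fp(c(1, 2, 3)), fp(c(1, 2, 3))), 1)
  expect_equal(tanimoto(fp(c(1, 2)), fp(c(5, 6))), 0)
  expect_equal(tanimoto(fp(c(1, 2, 3)), fp(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(fp(integer()), fp(integer())), 1)
  expect_error(tanimoto(fp(1, nbits = 16), fp(1, nbits = 32)),
               "different lengths")
})

test_that("tanimoto is symmetric, reflexive and bounded on 1000 random fingerprints", {
  set.seed(2024)
  fps <- replicate(1000, random_fingerprint(), simplify = FALSE)
  idx <- matrix(sample.int(1000, 2000, replace = TRUE), ncol = 2)
  for (k in seq_len(nrow(idx))) {
    a <- fps[[idx[k, 1]]]; b <- fps[[idx[k, 2]]]
    s <- tanimoto(a, b)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_identical(s, tanimoto(b, a))
  }
  for (k in sample.int(1000, 50)) {
    self <- tanimoto(fps[[k]], fps[[k]])
    expect_equal(self, 1)
  }
})

test_that("fingerprints are canonical-invariant and structure-sensitive", {
  variants <- enumerate_smiles("CC(=O)Nc1ccc(O)cc1", 20, seed = 9)
  fps <- fingerprint(variants)
  expect_gt(length(fps), 2L)
  for (f in fps[-1]) expect_identical(unclass(f), unclass(fps[[1]]))
  pair <- fingerprint(c("c1ccc2c(c1)cc[nH]2", "c1ccccc1"))
  expect_false(identical(unclass(pair[[1]]), unclass(pair[[2]])))
  expect_true(all(unlist(pair) >= 0 & unlist(pair) < 1024))
  expect_error(fingerprint("C1CC"), "unparseable")
})

test_that("similarity matrix and nearest mapping agree with a brute-force scan", {
  cands <- compound_set(c("Cc1c[nH]c2ccccc12", "CCO", "Oc1ccccc1",
                          "CCN", "c1ccncc1"),
                        id = paste0("g", 1:5))
  init <- compound_set(c("c1ccc2c(c1)cc[nH]2", "CCO", "Nc1ccccc1"),
                       id = paste0("i", 1:3))
  sm <- similarity_matrix(cands, init)
  expect_identical(dim(sm$matrix), c(5L, 3L))
  expect_true(all(sm$matrix >= 0 & sm$matrix <= 1))
  fpc <- fingerprint(cands); fpi <- fingerprint(init)
  for (i in 1:5) {
    sims <- vapply(1:3, function(j) tanimoto(fpc[[i]], fpi[[j]]),
                   numeric(1))
    expect_equal(unname(sm$matrix[i, ]), sims)
    expect_identical(sm$nearest$nearest_id[i],
                     init$id[which.max(sims)])
    expect_equal(sm$nearest$similarity[i], max(sims))
  }
  # a candidate identical to a seed maps to it with similarity 1
  expect_equal(sm$nearest$similarity[2], 1)
  expect_identical(sm$nearest$nearest_id[2], "i2")
  expect_error(similarity_matrix(cands[0, ], init), "non-empty")
})

test_that("histograms conserve counts with half-open bins and a closed top", {
  h <- similarity_histogram(runif(10), 0.25)
  expect_identical(sum(h$count), 10L)
  top <- similarity_histogram(rep(1, 7), 0.1)
  expect_identical(top$count[10], 7L)
  expect_identical(sum(top$count), 7L)
  h2 <- similarity_histogram(c(0.05, 0.15, 0.15), 0.1)
  expect_identical(h2$count[1:2], c(1L, 2L))
  expect_error(similarity_histogram(c(0.5, NaN)), "finite")
  expect_error(similarity_histogram(1.2), "\\[0, 1\\]")
})

test_that("the 2-D embedding is seeded and groups identical fingerprints", {
  recs <- planted_set()[1:20, ]
  fps <- fingerprint(recs)
  emb <- embed_2d(fps, seed = 4, ids = recs$id)
  expect_identical(nrow(emb$coords), 20L)
  expect_true(all(is.finite(emb$coords$TSNE_C1)))
  expect_identical(embed_2d(fps, seed = 4, ids = recs$id)$coords,
                   emb$coords)
  expect_error(embed_2d(fps[1:4]), "at least 5")
  expect_error(embed_2d(fps, perplexity = 25), "perplexity")

  # planted two-cluster fixture: copies of one molecule must land nearer
  # to each other than to a maximally dissimilar item
  for (s in 1:3) {
    fps2 <- c(fingerprint(rep("c1ccc2c(c1)cc[nH]2", 4)),
              fingerprint(rep("OCC(F)(F)F", 4)),
              fingerprint(c("CCO", "CCN", "CCS")))
    e <- embed_2d(fps2, seed = s, perplexity = 3)
    co <- as.matrix(e$coords[, c("TSNE_C1", "TSNE_C2")])
    d <- as.matrix(dist(co))
    within <- d[1, 2]
    across <- d[1, 5]
    expect_lt(within, across)
  }
})

test_that("lookup respects the injected client and caches by canonical form", {
  recs <- compound_set(c("CCO", "OCC", "c1ccccc1"),
                       id = c("a", "b", "c"))
  expect_identical(recs$canonical[1], recs$canonical[2])
  off <- pubchem_lookup(recs, offline_client())
  expect_true(all(off$status == "unavailable"))

  calls <- 0L
  counting <- function(canonical_smiles) {
    calls <<- calls + 1L
    mock_client(stats::setNames("702", recs$canonical[1]))(canonical_smiles)
  }
  res <- pubchem_lookup(recs, counting)
  expect_identical(calls, 2L)  # ethanol asked once despite two records
  expect_identical(res$status, c("found", "found", "not_found"))
  expect_identical(res$external_id[1], "702")

  failing <- function(canonical_smiles) stop("network down")
  res2 <- pubchem_lookup(recs, failing)
  expect_true(all(res2$status == "unavailable"))
})
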
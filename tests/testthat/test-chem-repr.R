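# Molecular string handling: canonicalization, enumeration, SELFIES
# translation, corpus building, vectorization, splitting.

test_that("canonicalization maps equivalent SMILES to one string and is idempotent", {
  a <- canonicalize("C1=CC2=C(C=C1)C=CN2")
  b <- canonicalize("c1ccc2c(c1)cc[nH]2")
  expect_identical(a, b)
  expect_identical(canonicalize(a), a)
  for (x in c("CCO", "c1ccccc1O", "CC(=O)Nc1ccc(O)cc1"))
    expect_identical(canonicalize(canonicalize(x)), canonicalize(x))
})

test_that("unparseable SMILES raise a structured error naming the input", {
  expect_error(canonicalize("C1CC"), "C1CC")
  expect_error(canonicalize(""), "empty")
  expect_error(compound_set("not_a_molecule"), "invalid SMILES")
})

test_that("enumeration preserves molecular identity and is seeded", {
  expect_identical(enumerate_smiles("C", 50, seed = 7), "C")
  x <- "CC(=O)Nc1ccc(O)cc1"
  en <- enumerate_smiles(x, 40, seed = 42)
  expect_gt(length(en), 1L)
  expect_identical(anyDuplicated(en), 0L)
  expect_true(all(canonicalize(en) == canonicalize(x)))
  expect_identical(en, enumerate_smiles(x, 40, seed = 42))
  expect_false(identical(en, enumerate_smiles(x, 40, seed = 43)))
})

test_that("SELFIES round trip preserves canonical identity", {
  battery <- c("c1ccc2c(c1)cc[nH]2", "CC(=O)Nc1ccc(O)cc1", "C",
               "C[N+](C)(C)C", "CC(=O)[O-]", "N#Cc1ccccc1", "C1CC1",
               "OCC(N)C(=O)O", "c1ccc(-c2ccccc2)cc1",
               "CCOC(=O)C1=CNC2=CC=CC=C12", "NCCc1c[nH]c2ccccc12",
               "OCC1OC(O)C(O)C(O)C1O", "CC(=O)OC1=CC=CC=C1C(=O)O")
  for (x in battery) {
    sf <- smiles_to_selfies(x)
    expect_identical(canonicalize(selfies_to_smiles(sf)),
                     canonicalize(x), info = x)
  }
})

test_that("SELFIES tokens are bracket-delimited and inputs are validated", {
  sf <- smiles_to_selfies("NCCc1c[nH]c2ccccc12")
  toks <- selfies_tokens(sf)
  expect_true(all(grepl("^\\[[^][]+\\]$", toks)))
  expect_identical(paste(toks, collapse = ""), sf)
  expect_error(smiles_to_selfies(""), "empty")
  expect_error(selfies_to_smiles(""), "empty")
  expect_error(selfies_tokens("[C]C"), "bracketed")
})

test_that("corpus building dedups globally, conserves identity, and is seeded", {
  recs <- compound_set(c("c1ccc2c(c1)cc[nH]2", "Oc1ccccc1", "CCO"),
                       id = c("a", "b", "c"))
  one <- build_corpus(recs[1, ], n_attempts = 1, seed = 1)
  expect_identical(nrow(one$entries), 1L)

  co <- build_corpus(recs, n_attempts = 200, seed = 5)
  expect_lte(nrow(co$entries), 200L * 3L)
  expect_identical(anyDuplicated(co$entries$selfies), 0L)
  # conservation: every entry decodes back to its source molecule
  for (i in seq_len(nrow(co$entries))) {
    src <- recs$canonical[match(co$entries$source_id[i], recs$id)]
    expect_identical(canonicalize(selfies_to_smiles(co$entries$selfies[i])),
                     src)
  }
  # seeded determinism: byte-identical rerun
  co2 <- build_corpus(recs, n_attempts = 200, seed = 5)
  expect_identical(co$entries, co2$entries)
  expect_identical(as.character(co$alphabet), as.character(co2$alphabet))
  expect_identical(co$max_len, co2$max_len)
  # invalid record aborts with its id
  bad <- recs; bad$smiles[2] <- "C1CC"
  expect_error(build_corpus(bad, 2, 1), "'b'")
})

test_that("alphabet contains each sentinel exactly once and indexes bijectively", {
  co <- overfit_fixture()$corpus
  al <- as.character(co$alphabet)
  expect_identical(sum(al == "!"), 1L)
  expect_identical(sum(al == "E"), 1L)
  expect_identical(sum(al == "[nop]"), 1L)
  expect_identical(anyDuplicated(al), 0L)
  expect_setequal(setdiff(al, c("!", "E", "[nop]")),
                  unique(unlist(co$tokens)))
  expect_identical(co$max_len, max(lengths(co$tokens)) + 2L)
})

test_that("vectorization one-hot encodes with sentinels and inverts exactly", {
  al <- selfies_alphabet("[C]")  # "!", "E", "[nop]", "[C]"
  m <- vectorize("[C]", al, 4L)
  expected <- matrix(0L, 4, 4, dimnames = list(NULL, as.character(al)))
  expected[1, "!"] <- 1L; expected[2, "[C]"] <- 1L
  expected[3, "E"] <- 1L; expected[4, "[nop]"] <- 1L
  expect_identical(m, expected)
  expect_true(all(rowSums(m) == 1L))
  expect_identical(devectorize(m, al), "[C]")

  co <- overfit_fixture()$corpus
  for (i in sample(nrow(co$entries), 10)) {
    mm <- vectorize(co$tokens[[i]], co$alphabet, co$max_len)
    expect_true(all(rowSums(mm) == 1L))
    expect_identical(devectorize(mm, co$alphabet), co$entries$selfies[i])
  }
  expect_error(vectorize("[Xx]", al, 4L), "\\[Xx\\]")
  expect_error(vectorize(rep("[C]", 5), al, 4L), "max_len")
})

test_that("corpus split reproduces the published 120935/13438 arithmetic", {
  s <- split_corpus(134373, 0.1)
  expect_identical(s$n_train, 120935L)
  expect_identical(s$n_val, 13438L)
  expect_identical(split_corpus(10, 0.1)$n_train, 9L)
  expect_identical(split_corpus(10, 0.1)$n_val, 1L)
  for (n in c(2, 17, 101, 5000)) {
    sp <- split_corpus(n, 0.25, seed = 3)
    expect_identical(sp$n_train + sp$n_val, as.integer(n))
    expect_identical(sort(c(sp$train, sp$val)), seq_len(n))
  }
  expect_error(split_corpus(1, 0.1), "at least 2")
  # seeded shuffle: same seed, same assignment
  expect_identical(split_corpus(100, 0.2, seed = 9)$val,
                   split_corpus(100, 0.2, seed = 9)$val)
})

test_that("compound files round-trip through SMI and CSV readers", {
  recs <- compound_set(c("CCO", "c1ccccc1"), id = c("x", "y"),
                       activity_pct = c(55, NA))
  csv <- tempfile(fileext = ".csv")
  write_compounds(recs, csv)
  back <- read_compounds(csv)
  expect_identical(back$canonical, recs$canonical)
  expect_equal(back$activity_pct, recs$activity_pct)

  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO x", "c1ccccc1 y"), smi)
  expect_identical(read_compounds(smi)$id, c("x", "y"))
  expect_error(compound_set("CCO", activity_pct = 120), "\\[0, 100\\]")
})
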
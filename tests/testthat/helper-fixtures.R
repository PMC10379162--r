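# Shared, memoized test fixtures. The expensive objects (the overfit
# generator, the 44-compound planted-signal set, the end-to-end pipeline
# run) are built once per test session and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Five seed molecules with ~30 enumerated representations each, trained
# to overfit for 300 epochs: the reference fixture for generator
# contracts (loss drop, reconstruction, zero-noise identity, sampling).
overfit_fixture <- function() {
  memo("overfit", function() {
    records <- compound_set(
      c("c1ccc2c(c1)cc[nH]2", "CC(=O)Nc1ccc(O)cc1", "OC1=CC=CC=C1",
        "NCCc1c[nH]c2ccccc12", "CC(C)Cc1ccccc1"),
      id = c("indole", "paracetamol", "phenol", "tryptamine",
             "isobutylbenzene"))
    corpus <- build_corpus(records, n_attempts = 30, seed = 7)
    model <- train_generator(corpus, epochs = 300, latent_dim = 32,
                             seed = 3)
    list(records = records, corpus = corpus, model = model)
  })
}

# 44 compounds with activity = 10 * donors + 30 + N(0, 5).
planted_set <- function() {
  memo("planted44", function() {
    make_compound_set(fixture_spec(n_compounds = 44, seed = 10))
  })
}

# Cleaned descriptors of the planted set.
planted_descriptors <- function() {
  memo("planted44_dm", function() {
    clean_descriptors(compute_descriptors(planted_set()))
  })
}

# Parameter-recovery sweep: for split seeds 1..5, does the correlation
# filter (threshold 0.39, training rows) retain nHBDon, and what test R
# does RF-6 reach?
param_recovery <- function() {
  memo("param_recovery", function() {
    recs <- planted_set()
    do.call(rbind, lapply(1:5, function(s) {
      fit <- fit_qsar(recs, method = "RF-6", threshold = 0.39,
                      standardize = FALSE, split_seed = s)
      data.frame(seed = s, donor_kept = "nHBDon" %in% fit$features,
                 r_test = fit$test_metrics$R)
    }))
  })
}

# One small end-to-end pipeline run, executed twice in the same work
# directory to compare manifests byte for byte.
pipeline_fixture <- function() {
  memo("pipeline_e2e", function() {
    wd <- file.path(tempdir(), "indolegen_e2e")
    unlink(wd, recursive = TRUE)
    input <- file.path(tempdir(), "indolegen_e2e_seed.csv")
    write_compounds(make_compound_set(fixture_spec(n_compounds = 10,
                                                   seed = 2)), input)
    cfg <- pipeline_config(
      input, wd,
      augmentation = list(n_attempts = 15, seed = 1),
      generator = list(epochs = 150, latent_dim = 32, noise_scale = 1,
                       per_structure = 20, seed = 1),
      qsar = list(thresholds = c(0.2, 0.39), split_seed = 1))
    null_log <- file(nullfile(), open = "wt")
    on.exit(close(null_log))
    manifest1 <- run_pipeline(cfg, log_con = null_log)
    bytes1 <- readLines(file.path(wd, "manifest.json"))
    manifest2 <- run_pipeline(cfg, log_con = null_log)
    bytes2 <- readLines(file.path(wd, "manifest.json"))
    list(config = cfg, workdir = wd, manifest = manifest2,
         bytes1 = bytes1, bytes2 = bytes2)
  })
}

# Deterministic pseudo-random fingerprints for property tests.
random_fingerprint <- function(nbits = 64L, density = 0.3) {
  bits <- which(stats::runif(nbits) < density) - 1L
  structure(as.integer(bits), nbits = as.integer(nbits),
            class = "fingerprint")
}
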
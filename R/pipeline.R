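# Pipeline orchestration: the full workflow (augment -> train -> generate
# -> QSAR -> synthesizability selection -> chemical-space analytics) as
# composable, seeded stages with per-stage CSV outputs and a
# machine-readable manifest. Generator training -- the slow stage -- is
# cached in the work directory keyed by a hash of the stages upstream of
# it, so reruns and downstream-only changes are cheap.

#' Pipeline configuration
#'
#' All knobs of the end-to-end run, with the workflow's defaults: 20
#' samples per seed structure, latent noise 0.5, correlation thresholds
#' swept over {0.25, 0.34, 0.39}, best-model rule with 0.05 tolerance and
#' the ensemble requirement, bundled fragment scorer at radius 2, 1024-bit
#' fingerprints. Round-trips losslessly through
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param input_csv path to the seed set (id, smiles, activity_pct).
#' @param workdir directory for stage outputs and the manifest.
#' @param augmentation list: `n_attempts`, `seed`.
#' @param generator list: `epochs`, `latent_dim`, `noise_scale`,
#'   `per_structure`, `seed`, `val_fraction`.
#' @param qsar list: `methods`, `thresholds`, `standardize_options`,
#'   `split_seed`, `selection_tolerance`, `require_ensemble`,
#'   `leaky_selection`.
#' @param synthesizability list: `scorer` (`"bundled"` or a path to a
#'   [write_fragment_model()] archive), `radius`, `smoothing`, `seed`.
#' @param chemspace list: `nbits`, `embed_seed`, `perplexity`.
#' @param lookup list: `enabled`.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_csv, workdir,
                            augmentation = list(),
                            generator = list(),
                            qsar = list(),
                            synthesizability = list(),
                            chemspace = list(),
                            lookup = list()) {
  merge_defaults <- function(user, def) {
    bad <- setdiff(names(user), names(def))
    if (length(bad) > 0L)
      stop("unknown config field(s): ", paste(bad, collapse = ", "))
    def[names(user)] <- user
    def
  }
  cfg <- list(
    input_csv = input_csv, workdir = workdir,
    augmentation = merge_defaults(augmentation,
                                  list(n_attempts = 5000L, seed = 1L)),
    generator = merge_defaults(generator,
                               list(epochs = 300L, latent_dim = 64L,
                                    noise_scale = 0.5,
                                    per_structure = 20L, seed = 1L,
                                    val_fraction = 0.1)),
    qsar = merge_defaults(qsar,
                          list(methods = c("DT", "RF-12", "RF-6", "KNN",
                                           "MLR", "SVR"),
                               thresholds = c(0.25, 0.34, 0.39),
                               standardize_options = c(FALSE, TRUE),
                               split_seed = 1L,
                               selection_tolerance = 0.05,
                               require_ensemble = TRUE,
                               leaky_selection = FALSE)),
    synthesizability = merge_defaults(synthesizability,
                                      list(scorer = "bundled",
                                           radius = 2L, smoothing = 1,
                                           seed = 1L)),
    chemspace = merge_defaults(chemspace,
                               list(nbits = 1024L, embed_seed = 1L,
                                    perplexity = NULL)),
    lookup = merge_defaults(lookup, list(enabled = FALSE)))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config,
          c(list(input_csv = j$input_csv, workdir = j$workdir),
            lapply(j[c("augmentation", "generator", "qsar",
                       "synthesizability", "chemspace", "lookup")],
                   as.list)))
}

config_hash <- function(x) {
  fnv1a32(paste(deparse(x), collapse = ""))
}

#' Run the end-to-end pipeline
#'
#' Executes the stages in order, writing per-stage CSVs, a human log and
#' a machine-readable `manifest.json` (seeds, versions, output files, and
#' the counts funnel n_seed -> n_corpus -> n_raw -> n_valid -> n_novel ->
#' n_selected) to the work directory. A stage failure stops the run with
#' the stage name; outputs of completed stages persist.
#'
#' @param config a [pipeline_config()].
#' @param client PubChem lookup client (used only if
#'   `config$lookup$enabled`); defaults to the offline client.
#' @param log_con connection for the human-readable log (default stderr).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, client = offline_client(),
                         log_con = stderr()) {
  stopifnot(inherits(config, "pipeline_config"))
  wd <- config$workdir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(wd, "pipeline.log")
  say <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    say("[", name, "] start")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  outfile <- function(f) file.path(wd, f)
  manifest <- list(
    config = unclass(config),
    versions = list(
      package = as.character(utils::packageVersion("indolegen")),
      r = paste(R.version$major, R.version$minor, sep = "."),
      descriptor_engine = descriptor_engine()$version))

  records <- stage("load", read_compounds(config$input_csv))
  manifest$funnel <- list(n_seed = nrow(records))

  corpus <- stage("augment", {
    co <- build_corpus(records, n_attempts = config$augmentation$n_attempts,
                       seed = config$augmentation$seed)
    write_corpus_manifest(co, outfile("corpus.csv"))
    write_alphabet(co$alphabet, outfile("alphabet.json"))
    co
  })
  manifest$funnel$n_corpus <- nrow(corpus$entries)

  model <- stage("train", {
    up_hash <- config_hash(list(config$input_csv, config$augmentation,
                                config$generator[c("epochs", "latent_dim",
                                                   "seed",
                                                   "val_fraction")]))
    cache <- outfile(paste0("generator_", up_hash, ".rds"))
    if (file.exists(cache)) {
      say("[train] using cached model ", basename(cache))
      readRDS(cache)
    } else {
      m <- train_generator(corpus, epochs = config$generator$epochs,
                           latent_dim = config$generator$latent_dim,
                           seed = config$generator$seed,
                           val_fraction = config$generator$val_fraction)
      saveRDS(m, cache)
      utils::write.csv(m$loss_history, outfile("loss_history.csv"),
                       row.names = FALSE)
      m
    }
  })

  gen <- stage("generate", {
    g <- generate_library(model, records,
                          n_samples_per_structure =
                            config$generator$per_structure,
                          noise_scale = config$generator$noise_scale,
                          seed = config$generator$seed, corpus = corpus)
    utils::write.csv(g$provenance, outfile("generated.csv"),
                     row.names = FALSE)
    g
  })
  manifest$funnel$n_raw <- gen$n_raw
  manifest$funnel$n_valid <- gen$n_valid
  manifest$funnel$n_novel <- gen$n_novel

  qsar_out <- stage("qsar", {
    grid <- grid_evaluate(records, methods = config$qsar$methods,
                          thresholds = config$qsar$thresholds,
                          standardize_options =
                            config$qsar$standardize_options,
                          split_seed = config$qsar$split_seed,
                          leaky_selection = config$qsar$leaky_selection)
    write_evaluation_report(grid, outfile("qsar_grid.csv"))
    best <- select_best(grid,
                        score_tolerance = config$qsar$selection_tolerance,
                        require_ensemble = config$qsar$require_ensemble)
    method <- if (!is.na(best$n_estimators))
      paste0(best$method, "-", best$n_estimators) else best$method
    fit <- fit_qsar(records, method = method,
                    threshold = best$threshold,
                    standardize = best$standardized,
                    split_seed = config$qsar$split_seed,
                    leaky_selection = config$qsar$leaky_selection)
    list(grid = grid, best = best, fit = fit)
  })
  manifest$best_model <- list(
    method = qsar_out$best$method,
    n_estimators = qsar_out$best$n_estimators,
    threshold = qsar_out$best$threshold,
    n_features = qsar_out$best$n_features,
    standardized = qsar_out$best$standardized,
    r_train = qsar_out$best$r_train, r_test = qsar_out$best$r_test)

  candidates <- gen$candidates
  predicted <- NULL
  if (!is.null(candidates) && nrow(candidates) > 0L) {
    predicted <- stage("predict", {
      p <- predict_library(qsar_out$fit, candidates)
      utils::write.csv(as.data.frame(p)[, c("id", "smiles",
                                            "predicted_activity_pct",
                                            "out_of_range")],
                       outfile("predictions.csv"), row.names = FALSE)
      p
    })
  } else {
    say("[predict] no novel candidates; stage skipped")
  }

  syn <- stage("synthesizability", {
    scorer <- if (identical(config$synthesizability$scorer, "bundled")) {
      fc <- make_fragment_corpus(seed = config$synthesizability$seed)
      train_fragment_model(fc$positives, fc$negatives,
                           radius = config$synthesizability$radius,
                           smoothing = config$synthesizability$smoothing)
    } else read_fragment_model(config$synthesizability$scorer)
    write_fragment_model(scorer, outfile("fragment_model.json"))
    thr <- threshold_from_initial(
      score_synthesizability(scorer, records))
    sel <- NULL
    if (!is.null(predicted) && nrow(predicted) > 0L) {
      sc <- score_synthesizability(scorer, predicted)
      write_filter_report(predicted, sc, thr, outfile("filter.csv"))
      sel <- filter_by_score(predicted, sc, thr)
    }
    list(scorer = scorer, threshold = thr, selected = sel)
  })
  manifest$funnel$n_selected <- if (is.null(syn$selected)) 0L
                                else nrow(syn$selected)
  manifest$syba_threshold <- syn$threshold$value

  stage("chemspace", {
    if (!is.null(predicted) && nrow(predicted) >= 1L) {
      sim <- similarity_matrix(predicted, records,
                               nbits = config$chemspace$nbits)
      write_similarity(sim, outfile("similarity.csv"))
      utils::write.csv(sim$nearest, outfile("nearest.csv"),
                       row.names = FALSE)
      hist_all <- similarity_histogram(sim$nearest$similarity)
      utils::write.csv(hist_all, outfile("histogram_generated.csv"),
                       row.names = FALSE)
      if (!is.null(syn$selected) && nrow(syn$selected) > 0L) {
        keep <- sim$nearest$candidate_id %in% syn$selected$id
        utils::write.csv(
          similarity_histogram(sim$nearest$similarity[keep]),
          outfile("histogram_selected.csv"), row.names = FALSE)
      }
      joint <- rbind(records[, c("id", "smiles", "canonical",
                                 "activity_pct")],
                     predicted[, c("id", "smiles", "canonical",
                                   "activity_pct")])
      n <- nrow(joint)
      if (n >= 5L) {
        fps <- fingerprint(joint$smiles, nbits = config$chemspace$nbits)
        emb <- embed_2d(fps, seed = config$chemspace$embed_seed,
                        perplexity = config$chemspace$perplexity,
                        ids = joint$id)
        labels <- ifelse(joint$id %in% records$id, "initial",
                         ifelse(!is.null(syn$selected) &
                                  joint$id %in% syn$selected$id,
                                "selected", "generated"))
        write_embedding(emb, outfile("embedding.csv"), labels = labels)
      }
    } else say("[chemspace] no candidates; stage skipped")
    if (isTRUE(config$lookup$enabled) && !is.null(predicted)) {
      lk <- pubchem_lookup(predicted, client = client)
      utils::write.csv(lk, outfile("pubchem.csv"), row.names = FALSE)
    }
    NULL
  })

  manifest$outputs <- sort(setdiff(list.files(wd),
                                   c("manifest.json", "pipeline.log")))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  say("[done] manifest written")
  invisible(manifest)
}
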
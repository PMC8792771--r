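#' Run the end-to-end pipeline with per-stage artifacts and manifests
#'
#' Wires the stages together — `simulate` → `embeddings` → `cnn` →
#' `predict` → `evaluate` — under one configuration with one global
#' seed.  Each stage writes its artifact into `outdir` together with a
#' manifest (`<stage>.manifest.json`: input file checksums, a hash of
#' the stage configuration, the seed, package version), so any artifact
#' can be regenerated exactly from its manifest; rerunning with an
#' identical configuration reproduces identical artifacts.  Per-stage
#' timing and prediction-source counts go to `stderr`.
#'
#' @param config A configuration list, or the path of a YAML file
#'   holding one.  Top level: `outdir`, `seed`, and optional sections
#'   `simulate` (arguments of [synth_config()]), `embedding`
#'   ([train_word2vec()] arguments), `cnn` ([cnn_config()] arguments),
#'   `predict` (`mode`, `target`), `evaluate` (`target`).
#' @param stages Ordered subset of
#'   `c("simulate", "embeddings", "cnn", "predict", "evaluate")`.
#'   A stage whose dependency is missing (e.g. `predict` in a CNN mode
#'   without a trained model) fails with an error naming the stage to
#'   run first.
#' @return Invisibly, a list of the artifacts produced in this call.
#' @export
run_pipeline <- function(config,
                         stages = c(
                           "simulate", "embeddings", "cnn",
                           "predict", "evaluate"
                         )) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stages <- match.arg(stages,
    c("simulate", "embeddings", "cnn", "predict", "evaluate"),
    several.ok = TRUE
  )
  outdir <- config$outdir %||% "edssnlp-out"
  seed <- as.integer(config$seed %||% 1L)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  pth <- function(...) file.path(outdir, ...)
  log_stage <- function(...) message("[pipeline] ", ...)

  manifest <- function(stage, inputs, cfg, outputs) {
    m <- list(
      stage = stage,
      inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
      config_hash = rlang::hash(cfg),
      seed = seed,
      package_version = as.character(utils::packageVersion("edssnlp")),
      outputs = as.list(tools::md5sum(outputs[file.exists(outputs)]))
    )
    jsonlite::write_json(m, pth(paste0(stage, ".manifest.json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  need <- function(path, producer) {
    if (!file.exists(path)) {
      abort(paste0(
        "missing dependency '", path, "'; run the '", producer,
        "' stage first"
      ))
    }
    path
  }
  timed <- function(stage, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    log_stage(sprintf(
      "%s done in %.1fs", stage,
      as.numeric(Sys.time() - t0, units = "secs")
    ))
    out
  }

  artifacts <- list()
  for (stage in stages) {
    if (stage == "simulate") {
      cfg <- config$simulate %||% list()
      corpus <- timed("simulate", simulate_notes(
        do.call(synth_config, c(cfg, list(seed = seed)))
      ))
      write_corpus(corpus, outdir)
      manifest(
        "simulate", character(), c(cfg, seed = seed),
        pth(c("notes.jsonl", "labels.csv", "metadata.csv"))
      )
      artifacts$corpus <- corpus
    } else if (stage == "embeddings") {
      notes_path <- need(pth("notes.jsonl"), "simulate")
      cfg <- config$embedding %||% list()
      notes <- preprocess_notes(read_notes_jsonl(notes_path))
      model <- timed("embeddings", do.call(
        train_word2vec,
        c(list(notes$tokens), cfg, list(seed = seed))
      ))
      write_word2vec(model, pth("vectors.txt"))
      manifest("embeddings", notes_path, c(cfg, seed = seed), pth("vectors.txt"))
      artifacts$embedding <- model
    } else if (stage == "cnn") {
      notes_path <- need(pth("notes.jsonl"), "simulate")
      vec_path <- need(pth("vectors.txt"), "embeddings")
      cfg <- config$cnn %||% list()
      emb <- read_word2vec(vec_path)
      ccfg <- do.call(cnn_config, c(
        cfg,
        list(embedding_dim = ncol(emb$vectors), seed = seed)
      ))
      notes <- read_notes_jsonl(notes_path)
      target <- (config$predict %||% list())$target %||% "total"
      model <- timed("cnn", train_edss_cnn(notes,
        target = target,
        embedding = emb, config = ccfg
      ))
      saveRDS(model, pth("model.rds"))
      manifest("cnn", c(notes_path, vec_path), c(cfg, seed = seed), pth("model.rds"))
      artifacts$model <- model
    } else if (stage == "predict") {
      notes_path <- need(pth("notes.jsonl"), "simulate")
      cfg <- config$predict %||% list()
      mode <- cfg$mode %||% "combined"
      target <- cfg$target %||% "total"
      model <- NULL
      if (mode != "rule") {
        model <- readRDS(need(pth("model.rds"), "cnn"))
      }
      notes <- read_notes_jsonl(notes_path)
      preds <- timed("predict", predict_edss(notes,
        mode = mode,
        model = model, target = target
      ))
      srcs <- prediction_sources(preds)
      for (i in seq_len(nrow(srcs))) {
        log_stage(sprintf(
          "source=%s n=%d unknown=%.4f", srcs$source[i],
          srcs$n[i], srcs$unknown_rate[i]
        ))
      }
      readr::write_csv(preds, pth("predictions.csv"), progress = FALSE)
      manifest(
        "predict", c(notes_path, pth("model.rds")),
        c(cfg, seed = seed), pth("predictions.csv")
      )
      artifacts$predictions <- preds
    } else if (stage == "evaluate") {
      preds_path <- need(pth("predictions.csv"), "predict")
      labels_path <- need(pth("labels.csv"), "simulate")
      cfg <- config$evaluate %||% list()
      target <- cfg$target %||% "total"
      preds <- readr::read_csv(preds_path,
        show_col_types = FALSE,
        progress = FALSE
      )
      refs <- read_labels_csv(labels_path)
      ref_col <- if (target == "total") "edss" else target
      d <- left_join(preds, refs, by = "note_id")
      ev <- evaluate_edss(d,
        truth = ref_col, estimate = "value",
        tolerance = if (target == "total") 0 else 1,
        class_values = if (target == "total") edss_classes() else 0:6
      )
      jsonlite::write_json(as.list(glance(ev)), pth("report.json"),
        auto_unbox = TRUE, digits = NA
      )
      manifest(
        "evaluate", c(preds_path, labels_path),
        c(cfg, seed = seed), pth("report.json")
      )
      artifacts$report <- ev
    }
  }
  invisible(artifacts)
}
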
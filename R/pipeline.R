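# Pipeline orchestration: simulate -> prepare -> train -> evaluate/crossval,
# driven by one YAML config, with a JSON manifest tracing every artifact.

config_error <- function(field, msg) {
  stop(sprintf("config error at %s: %s", field, msg), call. = FALSE)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed)) config_error("seed", "missing")
  if (is.null(cfg$out_dir)) config_error("out_dir", "missing")
  stages <- cfg$stages %||% c("simulate", "prepare", "train", "evaluate")
  known <- c("simulate", "prepare", "train", "evaluate", "crossval")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) {
    config_error("stages", paste("unknown stage:", paste(bad, collapse = ", ")))
  }
  tr <- cfg$train
  if (!is.null(tr$learning_rate) &&
      (!is.numeric(tr$learning_rate) || tr$learning_rate <= 0)) {
    config_error("train.learning_rate", "must be a number > 0")
  }
  if (!is.null(tr$batch_size) && tr$batch_size < 1) {
    config_error("train.batch_size", "must be >= 1")
  }
  if (!is.null(cfg$model$dropout) &&
      (cfg$model$dropout < 0 || cfg$model$dropout >= 1)) {
    config_error("model.dropout", "must be in [0, 1)")
  }
  if (!is.null(cfg$crossval$k) && cfg$crossval$k < 2) {
    config_error("crossval.k", "must be >= 2")
  }
  cfg$stages <- stages
  cfg
}

pick_args <- function(lst, fn) {
  if (is.null(lst)) return(list())
  lst[intersect(names(lst), names(formals(fn)))]
}

model_config_from <- function(cfg) {
  do.call(model_config, pick_args(cfg$model, model_config))
}

train_config_from <- function(cfg, seed) {
  args <- pick_args(cfg$train, train_config)
  if (is.null(args$seed)) args$seed <- seed
  do.call(train_config, args)
}

corpus_paths <- function(dir) {
  list(text = file.path(dir, "text"),
       concepts = file.path(dir, "concepts"),
       relations = file.path(dir, "relations"),
       conllu = file.path(dir, "parses.conllu"),
       embeddings = file.path(dir, "embeddings.txt"))
}

#' Run the end-to-end pipeline from a YAML config
#'
#' Executes the requested stages in order. `simulate` writes a synthetic
#' corpus (i2b2-style dialect + CoNLL-U + toy embeddings) under
#' `out_dir/corpus`; `prepare` reads the corpus (or user-supplied paths under
#' the `corpus:` key) into relation instances at `out_dir/instances.jsonl`;
#' `train` fits the model and writes `out_dir/checkpoint.rds` plus a JSON-lines
#' training log; `evaluate` scores the checkpoint on the prepared instances;
#' `crossval` runs document-level k-fold cross-validation and, with
#' `crossval: {ablation: true}`, repeats it for the sentence-only, +SDP-words
#' and full configurations and writes a side-by-side report. Any stage can be
#' resumed from the artifacts of a previous run. A `manifest.json` records the
#' seed, config digest and the MD5 digest of every artifact.
#'
#' @param config_path Path to the YAML config, or an equivalent named list.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config_path) {
  if (is.character(config_path)) {
    cfg <- yaml::read_yaml(config_path)
    cfg_digest <- unname(tools::md5sum(config_path))
  } else {
    cfg <- config_path
    cfg_digest <- digest_object(cfg)
  }
  cfg <- validate_pipeline_config(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  add_artifact <- function(name, path) {
    artifacts[[name]] <<- list(path = path,
                               md5 = unname(tools::md5sum(path)))
  }

  paths <- if (!is.null(cfg$corpus)) {
    utils::modifyList(corpus_paths(file.path(out_dir, "corpus")),
                      cfg$corpus)
  } else {
    corpus_paths(file.path(out_dir, "corpus"))
  }
  instances_path <- file.path(out_dir, "instances.jsonl")
  checkpoint_path <- file.path(out_dir, "checkpoint.rds")

  if ("simulate" %in% cfg$stages) {
    args <- pick_args(cfg$simulate, synth_config)
    if (is.null(args$seed)) args$seed <- cfg$seed
    sc <- do.call(synth_config, args)
    write_fixture_suite(file.path(out_dir, "corpus"), config = sc,
                        embedding_dim = cfg$model$word_dim %||% 10L)
    add_artifact("conllu", paths$conllu)
    add_artifact("embeddings", paths$embeddings)
  }

  if ("prepare" %in% cfg$stages) {
    for (p in c(paths$text, paths$conllu)) {
      if (!file.exists(p)) {
        stop(sprintf("dependency error: missing upstream artifact %s", p),
             call. = FALSE)
      }
    }
    sentences <- read_i2b2_corpus(paths$text, paths$concepts, paths$relations)
    graphs <- read_conllu(paths$conllu)
    graphs <- align_graphs(sentences, graphs)
    instances <- build_instances(sentences, graphs)
    write_instances(instances, instances_path)
    add_artifact("instances", instances_path)
  }

  embeddings <- NULL
  if (!is.null(paths$embeddings) && file.exists(paths$embeddings) &&
      !is.null(cfg$model$word_dim)) {
    embeddings <- load_word2vec_text(paths$embeddings, cfg$model$word_dim)
  }
  mcfg <- model_config_from(cfg)
  tcfg <- train_config_from(cfg, cfg$seed)

  if ("train" %in% cfg$stages) {
    if (!file.exists(instances_path)) {
      stop("dependency error: missing upstream artifact instances.jsonl",
           call. = FALSE)
    }
    instances <- read_instances(instances_path)
    val_frac <- cfg$train$val_fraction %||% 0
    val <- NULL
    if (val_frac > 0) {
      set.seed(cfg$seed)
      docs <- unique(vapply(instances, `[[`, character(1), "doc_id"))
      n_val <- max(1L, round(val_frac * length(docs)))
      val_docs <- sample(docs, n_val)
      is_val <- vapply(instances, function(x) x$doc_id %in% val_docs,
                       logical(1))
      val <- instances[is_val]
      instances <- instances[!is_val]
    }
    fit <- train_relex(instances, config = mcfg, train_cfg = tcfg,
                       embeddings = embeddings, val_instances = val)
    save_checkpoint(fit, checkpoint_path)
    add_artifact("checkpoint", checkpoint_path)
    log_path <- file.path(out_dir, "train_log.jsonl")
    log_lines <- vapply(seq_along(fit$loss_trace), function(e) {
      as.character(jsonlite::toJSON(list(
        stage = "train", epoch = e, loss = fit$loss_trace[e],
        val_micro_f = if (length(fit$val_trace) >= e)
          fit$val_trace[e] else NULL), auto_unbox = TRUE))
    }, character(1))
    writeLines(log_lines, log_path)
    add_artifact("train_log", log_path)
  }

  if ("evaluate" %in% cfg$stages) {
    model <- load_checkpoint(checkpoint_path)
    instances <- read_instances(instances_path)
    pred <- predict_relations(model, instances)
    gold <- vapply(instances, `[[`, character(1), "label")
    res <- micro_prf(gold, pred)
    report_path <- file.path(out_dir, "evaluation.json")
    jsonlite::write_json(list(micro_precision = res$micro_precision,
                              micro_recall = res$micro_recall,
                              micro_f = res$micro_f,
                              per_class_f = as.list(res$per_class_f)),
                         report_path, auto_unbox = TRUE, digits = NA)
    add_artifact("evaluation", report_path)
  }

  if ("crossval" %in% cfg$stages) {
    instances <- read_instances(instances_path)
    k <- cfg$crossval$k %||% 5L
    configs <- if (isTRUE(cfg$crossval$ablation)) {
      list(
        "sentence sequence only" = utils::modifyList(
          mcfg, list(use_sdp_words = FALSE, use_sdp_relations = FALSE)),
        "+SDP (word sequence)" = utils::modifyList(
          mcfg, list(use_sdp_words = TRUE, use_sdp_relations = FALSE)),
        "+SDP (word sequence + relation type)" = utils::modifyList(
          mcfg, list(use_sdp_words = TRUE, use_sdp_relations = TRUE)))
    } else {
      list(model = mcfg)
    }
    results <- lapply(configs, function(mc) {
      class(mc) <- "model_config"
      cross_validate(instances, k = k, config = mc, train_cfg = tcfg,
                     embeddings = embeddings, seed = cfg$seed)
    })
    report_path <- file.path(out_dir, "crossval_report.txt")
    writeLines(ablation_report(results), report_path)
    add_artifact("crossval_report", report_path)
    json_path <- file.path(out_dir, "crossval.json")
    jsonlite::write_json(
      lapply(results, function(r) list(
        micro_precision = r$pooled$micro_precision,
        micro_recall = r$pooled$micro_recall,
        micro_f = r$pooled$micro_f)),
      json_path, auto_unbox = TRUE, digits = NA)
    add_artifact("crossval", json_path)
  }

  manifest <- list(package = "sdprel",
                   version = as.character(utils::packageVersion("sdprel")),
                   seed = cfg$seed, config_md5 = cfg_digest,
                   stages = cfg$stages, artifacts = artifacts,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# md5 of a canonical serialization, for in-memory configs
digest_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# match parses to sentences via "# sent_id = <doc>:<line>" comments when
# present, else by order
align_graphs <- function(sentences, graphs) {
  ids <- vapply(graphs, function(g) attr(g, "sent_id") %||% NA_character_,
                character(1))
  if (anyNA(ids)) {
    if (length(graphs) < length(sentences)) {
      stop("fewer parses than sentences and no sent_id comments",
           call. = FALSE)
    }
    return(graphs[seq_along(sentences)])
  }
  keys <- vapply(sentences, function(s)
    sprintf("%s:%d", s$doc_id, s$sentence_index), character(1))
  hit <- match(keys, ids)
  if (anyNA(hit)) {
    stop(sprintf("no parse for sentence %s", keys[which(is.na(hit))[1L]]),
         call. = FALSE)
  }
  graphs[hit]
}
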
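#' Micro-averaged precision, recall and F-measure
#'
#' Pools true positives, false positives and false negatives over the
#' positive relation classes (by default all eight relations, excluding
#' `"None"`) and reports percentages on the 0-100 scale. Per-class F-measures
#' and the full 9 x 9 confusion matrix (gold in rows, prediction in columns)
#' are included.
#'
#' @param gold,pred Character vectors of equal length with values in
#'   [relation_labels()].
#' @param positive_classes Classes pooled into the micro average; the default
#'   excludes `"None"`. Pass `relation_labels()` to include it (diagnostics
#'   only).
#' @return An `eval_result`: list with `micro_precision`, `micro_recall`,
#'   `micro_f` (percent), `per_class_f` (named percent vector over
#'   `positive_classes`), `confusion`, and the pooled `tp`, `fp`, `fn` counts.
#' @export
micro_prf <- function(gold, pred,
                      positive_classes = setdiff(relation_labels(), "None")) {
  if (length(gold) == 0L) stop("empty input", call. = FALSE)
  if (length(gold) != length(pred)) {
    stop("gold and pred must have equal length", call. = FALSE)
  }
  assert_label(gold, "gold label")
  assert_label(pred, "predicted label")
  g <- factor(gold, levels = RELATION_LABELS)
  p <- factor(pred, levels = RELATION_LABELS)
  confusion <- table(gold = g, pred = p)
  tp <- fp <- fn <- 0
  per_class_f <- stats::setNames(numeric(length(positive_classes)),
                                 positive_classes)
  for (cl in positive_classes) {
    tp_c <- confusion[cl, cl]
    fp_c <- sum(confusion[, cl]) - tp_c
    fn_c <- sum(confusion[cl, ]) - tp_c
    tp <- tp + tp_c; fp <- fp + fp_c; fn <- fn + fn_c
    p_c <- if (tp_c + fp_c > 0) tp_c / (tp_c + fp_c) else 0
    r_c <- if (tp_c + fn_c > 0) tp_c / (tp_c + fn_c) else 0
    per_class_f[cl] <- if (p_c + r_c > 0) 200 * p_c * r_c / (p_c + r_c) else 0
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(micro_precision = 100 * precision,
                 micro_recall = 100 * recall, micro_f = 100 * f,
                 per_class_f = per_class_f, confusion = confusion,
                 tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("micro-P %.2f%%  micro-R %.2f%%  micro-F %.2f%%\n",
              x$micro_precision, x$micro_recall, x$micro_f))
  cat("per-class F (%):\n")
  print(round(x$per_class_f, 2))
  invisible(x)
}

assign_folds <- function(doc_ids, k, seed) {
  docs <- unique(doc_ids)
  if (length(docs) < k) {
    stop(sprintf("need at least %d documents for %d folds, have %d",
                 k, k, length(docs)), call. = FALSE)
  }
  set.seed(seed)
  docs <- sample(docs)
  fold_of_doc <- stats::setNames(rep(seq_len(k), length.out = length(docs)),
                                 docs)
  fold_of_doc[doc_ids]
}

#' Document-level k-fold cross-validation
#'
#' Splits instances into folds by document (no document's sentences appear in
#' both a training and a test fold), trains one model per fold and pools all
#' fold predictions into a single micro-averaged result, alongside per-fold
#' results.
#'
#' @param instances List of `relation_instance` objects (each carries its
#'   `doc_id`).
#' @param k Number of folds (>= 2).
#' @param config A [model_config].
#' @param train_cfg A [train_config]; fold `i` trains with seed
#'   `train_cfg$seed + i` so folds are independent but reproducible.
#' @param embeddings Optional pretrained `embedding_table`.
#' @param seed Seed for the fold assignment.
#' @param verbose Print per-fold progress.
#' @return List with `pooled` (an `eval_result` over the union of all fold
#'   predictions), `folds` (list of per-fold `eval_result`s), `predictions`
#'   (data.frame with `doc_id`, `fold`, `gold`, `pred`) and `fold_of_doc`.
#' @export
cross_validate <- function(instances, k = 5L, config = model_config(),
                           train_cfg = train_config(), embeddings = NULL,
                           seed = 1L, verbose = FALSE) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  doc_ids <- vapply(instances, `[[`, character(1), "doc_id")
  fold <- assign_folds(doc_ids, k, seed)
  gold_all <- character(0)
  pred_all <- character(0)
  fold_all <- integer(0)
  doc_all <- character(0)
  folds <- vector("list", k)
  for (i in seq_len(k)) {
    test_idx <- which(fold == i)
    train_idx <- which(fold != i)
    cfg_i <- train_cfg
    cfg_i$seed <- train_cfg$seed + i
    fit <- train_relex(instances[train_idx], config = config,
                       train_cfg = cfg_i, embeddings = embeddings)
    pred <- predict_relations(fit, instances[test_idx])
    gold <- vapply(instances[test_idx], `[[`, character(1), "label")
    folds[[i]] <- micro_prf(gold, pred)
    gold_all <- c(gold_all, gold)
    pred_all <- c(pred_all, as.character(pred))
    fold_all <- c(fold_all, rep(i, length(test_idx)))
    doc_all <- c(doc_all, doc_ids[test_idx])
    if (verbose) {
      message(sprintf("fold %d/%d: micro-F %.2f%% (%d test instances)",
                      i, k, folds[[i]]$micro_f, length(test_idx)))
    }
  }
  pooled <- micro_prf(gold_all, pred_all)
  list(pooled = pooled, folds = folds,
       predictions = data.frame(doc_id = doc_all, fold = fold_all,
                                gold = gold_all, pred = pred_all,
                                stringsAsFactors = FALSE),
       fold_of_doc = fold[!duplicated(doc_ids)])
}

#' Side-by-side ablation report
#'
#' Formats pooled cross-validation results of several model configurations as
#' a plain-text table: micro P/R/F per configuration plus per-class F columns,
#' mirroring the usual presentation of sentence-only versus +SDP systems.
#'
#' @param results Named list of `cross_validate()` returns (or `eval_result`s).
#' @return Character vector of report lines (also printed invisibly-friendly).
#' @export
ablation_report <- function(results) {
  evals <- lapply(results, function(r) if (!is.null(r$pooled)) r$pooled else r)
  lines <- c(sprintf("%-40s %9s %9s %9s", "Configuration", "P (%)", "R (%)",
                     "F (%)"))
  for (nm in names(evals)) {
    e <- evals[[nm]]
    lines <- c(lines, sprintf("%-40s %9.2f %9.2f %9.2f", nm,
                              e$micro_precision, e$micro_recall, e$micro_f))
  }
  lines <- c(lines, "", sprintf("%-10s %s", "Class",
                                paste(sprintf("%14s", names(evals)),
                                      collapse = " ")))
  classes <- names(evals[[1L]]$per_class_f)
  for (cl in classes) {
    vals <- vapply(evals, function(e) e$per_class_f[[cl]], numeric(1))
    lines <- c(lines, sprintf("%-10s %s", cl,
                              paste(sprintf("%14.2f", vals), collapse = " ")))
  }
  lines
}
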
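#' Training configuration
#'
#' Defaults follow the published regime: Adam with learning rate 1e-5 and
#' mini-batches of 32. The epoch count is a free choice (the source regime
#' leaves it unstated); the default keeps desk-scale experiments fast.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Mini-batch size (>= 1).
#' @param max_epochs Number of passes over the training set.
#' @param seed Integer seed; initialization, shuffling and dropout all flow
#'   from it, so runs are bitwise reproducible.
#' @param early_stop_patience Stop after this many epochs without improvement
#'   of validation micro-F; `NULL` disables early stopping.
#' @param grad_clip Clip gradients to this L2 norm per parameter tensor;
#'   `NULL` (default) disables clipping.
#' @param class_weights Optional named weight per relation label applied to
#'   the cross-entropy; `NULL` (default) trains on the natural class imbalance.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 32L,
                         max_epochs = 30L, seed = 1L,
                         early_stop_patience = NULL, grad_clip = NULL,
                         class_weights = NULL) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("learning_rate must be > 0", call. = FALSE)
  }
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (max_epochs < 1L) stop("max_epochs must be >= 1", call. = FALSE)
  if (!is.null(class_weights)) {
    assert_label(names(class_weights), "class_weights name")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 early_stop_patience = early_stop_patience,
                 grad_clip = grad_clip, class_weights = class_weights),
            class = "train_config")
}

#' Shuffled mini-batch index iterator
#'
#' Partitions `1..n` into shuffled batches; every index appears exactly once,
#' the final batch holds the remainder.
#'
#' @param n Number of instances.
#' @param batch_size Batch size.
#' @param seed Optional seed for the shuffle; `NULL` uses the current RNG
#'   state.
#' @param shuffle Shuffle before splitting.
#' @return List of integer index vectors.
#' @export
batch_iterator <- function(n, batch_size, seed = NULL, shuffle = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  idx <- if (shuffle) sample.int(n) else seq_len(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

clip_grads <- function(grads, max_norm) {
  for (nm in names(grads)) {
    nrm <- sqrt(sum(grads[[nm]]^2))
    if (nrm > max_norm) grads[[nm]] <- grads[[nm]] * (max_norm / nrm)
  }
  grads
}

#' Train the relation classifier
#'
#' Mini-batch training with cross-entropy loss and Adam. When a validation set
#' is supplied the parameters with the best validation micro-F (positive
#' classes pooled, None excluded) are returned; otherwise the final-epoch
#' parameters are.
#'
#' @param instances Training instances from [build_instances()].
#' @param config A [model_config].
#' @param train_cfg A [train_config].
#' @param embeddings Optional pretrained `embedding_table`.
#' @param val_instances Optional held-out instances used only for model
#'   selection, never for parameter updates.
#' @param verbose Print one line per epoch.
#' @return An `sdprel_fit`: list with `model` (the `sdprel_model`),
#'   `loss_trace` (mean training cross-entropy per epoch), `val_trace`
#'   (validation micro-F per epoch, if a validation set was given) and
#'   `best_epoch`.
#' @export
train_relex <- function(instances, config = model_config(),
                        train_cfg = train_config(), embeddings = NULL,
                        val_instances = NULL, verbose = FALSE) {
  if (length(instances) == 0L) stop("no training instances", call. = FALSE)
  labs <- vapply(instances, `[[`, character(1), "label")
  assert_label(labs)
  set.seed(train_cfg$seed)
  model <- init_model(config, instances, embeddings = embeddings)
  state <- adam_init(model$params)
  n <- length(instances)
  loss_trace <- numeric(0)
  val_trace <- numeric(0)
  best_f <- -Inf
  best_params <- NULL
  best_epoch <- NA_integer_
  stale <- 0L

  for (epoch in seq_len(train_cfg$max_epochs)) {
    batches <- batch_iterator(n, train_cfg$batch_size)
    tot_loss <- 0
    for (bi in batches) {
      batch <- make_batch(instances[bi], model,
                          class_weights = train_cfg$class_weights)
      fwd <- nn_forward(model, batch, train = TRUE, keep_cache = TRUE)
      grads <- nn_backward(model, batch, fwd)
      if (!is.null(train_cfg$grad_clip)) {
        grads <- clip_grads(grads, train_cfg$grad_clip)
      }
      upd <- adam_step(model$params, grads, state, train_cfg$learning_rate)
      model$params <- upd$params
      state <- upd$state
      tot_loss <- tot_loss + fwd$loss * length(bi)
    }
    loss_trace <- c(loss_trace, tot_loss / n)
    if (!is.null(val_instances)) {
      pred <- predict_relations(model, val_instances)
      gold <- vapply(val_instances, `[[`, character(1), "label")
      f <- micro_prf(gold, pred)$micro_f
      val_trace <- c(val_trace, f)
      if (f > best_f) {
        best_f <- f
        best_params <- model$params
        best_epoch <- epoch
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (!is.null(train_cfg$early_stop_patience) &&
            stale >= train_cfg$early_stop_patience) {
          if (verbose) message(sprintf("early stop at epoch %d", epoch))
          break
        }
      }
    }
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f%s", epoch,
                      loss_trace[length(loss_trace)],
                      if (length(val_trace) > 0)
                        sprintf(", val micro-F %.2f",
                                val_trace[length(val_trace)]) else ""))
    }
  }
  if (!is.null(best_params)) model$params <- best_params
  structure(list(model = model, loss_trace = loss_trace,
                 val_trace = val_trace, best_epoch = best_epoch,
                 train_cfg = train_cfg),
            class = "sdprel_fit")
}

#' @export
print.sdprel_fit <- function(x, ...) {
  cat(sprintf("<sdprel_fit: %d epochs, final loss %.4f%s>\n",
              length(x$loss_trace), x$loss_trace[length(x$loss_trace)],
              if (length(x$val_trace) > 0)
                sprintf(", best val micro-F %.2f (epoch %d)",
                        max(x$val_trace), x$best_epoch) else ""))
  invisible(x)
}

CHECKPOINT_VERSION <- 1L

#' Save a model checkpoint
#'
#' Single-file archive of config, parameters and vocabularies, with a format
#' version for forward compatibility.
#'
#' @param fit An `sdprel_fit` or `sdprel_model`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "sdprel_fit")) fit$model else fit
  obj <- list(format = "sdprel-checkpoint", version = CHECKPOINT_VERSION,
              config = model$config, params = model$params,
              vocab = model$vocab, deprel_vocab = model$deprel_vocab,
              loss_trace = if (inherits(fit, "sdprel_fit")) fit$loss_trace)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return An `sdprel_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "sdprel-checkpoint")) {
    stop("not an sdprel checkpoint", call. = FALSE)
  }
  if (obj$version > CHECKPOINT_VERSION) {
    stop("checkpoint version newer than supported", call. = FALSE)
  }
  structure(list(config = obj$config, params = obj$params,
                 vocab = obj$vocab, deprel_vocab = obj$deprel_vocab),
            class = "sdprel_model")
}
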
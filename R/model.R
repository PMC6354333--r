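#' Model configuration
#'
#' Hyperparameters of the dual-branch relation classifier. The defaults follow
#' the published regime: 100-dimensional word embeddings, 50-dimensional
#' position embeddings, 200 hidden units in both Bi-LSTMs and in the
#' path-convolution output, and dropout on the fully-connected layer.
#'
#' The two ablation flags reproduce the three studied configurations:
#' `use_sdp_words = FALSE` gives the sentence-sequence-only model;
#' `use_sdp_words = TRUE, use_sdp_relations = FALSE` adds the path-word
#' convolution; both `TRUE` adds the dependency-relation-type embeddings.
#'
#' @param word_dim Word-embedding dimension (n1 of the path convolution).
#' @param position_dim Position-embedding dimension.
#' @param deprel_dim Dependency-relation-type embedding dimension. The source
#'   regime leaves this unstated; it defaults to the position dimension.
#' @param hidden Hidden units per LSTM direction and convolution output
#'   dimension (n2).
#' @param fc_dim Width of the fully-connected layer before the softmax.
#' @param n_classes Number of relation classes (8 relations + None).
#' @param dropout Dropout rate on the fully-connected layer input at train
#'   time.
#' @param max_dist Position-feature clip: distances beyond `[-max_dist,
#'   max_dist]` share an out-of-range embedding row.
#' @param use_sdp_words Include the shortest-dependency-path branch.
#' @param use_sdp_relations Include dependency-relation-type embeddings in the
#'   path branch (requires `use_sdp_words`).
#' @param pooling How per-step Bi-LSTM outputs are reduced to one vector:
#'   `"max"` (element-wise max over timesteps) or `"final"` (last forward and
#'   first backward state).
#' @param train_embeddings Update embedding tables during training.
#' @return A `model_config` list.
#' @export
model_config <- function(word_dim = 100L, position_dim = 50L,
                         deprel_dim = position_dim, hidden = 200L,
                         fc_dim = hidden, n_classes = 9L, dropout = 0.5,
                         max_dist = 60L, use_sdp_words = TRUE,
                         use_sdp_relations = TRUE,
                         pooling = c("max", "final"),
                         train_embeddings = TRUE) {
  pooling <- match.arg(pooling)
  stopifnot(word_dim >= 1, position_dim >= 1, deprel_dim >= 1, hidden >= 1,
            fc_dim >= 1, n_classes >= 2, max_dist >= 1)
  if (dropout < 0 || dropout >= 1) {
    stop("dropout must be in [0, 1)", call. = FALSE)
  }
  if (use_sdp_relations && !use_sdp_words) {
    stop("use_sdp_relations requires use_sdp_words", call. = FALSE)
  }
  structure(list(word_dim = as.integer(word_dim),
                 position_dim = as.integer(position_dim),
                 deprel_dim = as.integer(deprel_dim),
                 hidden = as.integer(hidden), fc_dim = as.integer(fc_dim),
                 n_classes = as.integer(n_classes), dropout = dropout,
                 max_dist = as.integer(max_dist),
                 use_sdp_words = isTRUE(use_sdp_words),
                 use_sdp_relations = isTRUE(use_sdp_relations),
                 pooling = pooling,
                 train_embeddings = isTRUE(train_embeddings)),
            class = "model_config")
}

UNK_TOKEN <- "<unk>"
UNK_DEPREL <- "<unk>"

# position-embedding row: -max..max map to 1..2*max+1, out-of-range to the
# bucket row 2*max+2
position_row <- function(d, max_dist) {
  ifelse(abs(d) > max_dist, 2L * max_dist + 2L, d + max_dist + 1L)
}

build_word_vocab <- function(instances) {
  toks <- unlist(lapply(instances, `[[`, "masked_tokens"), use.names = FALSE)
  sort(unique(c(UNK_TOKEN, toks)))
}

build_deprel_vocab <- function(instances) {
  rels <- unlist(lapply(instances, function(x) x$sdp$relations),
                 use.names = FALSE)
  sort(unique(c(UNK_DEPREL, rels)))
}

glorot <- function(nr, nc) runif_mat(nr, nc, sqrt(6 / (nr + nc)))

lstm_params <- function(din, h, prefix) {
  p <- list(glorot(din, 4L * h), glorot(h, 4L * h), numeric(4L * h),
            glorot(din, 4L * h), glorot(h, 4L * h), numeric(4L * h))
  names(p) <- paste0(prefix, c("Wf", "Uf", "bf", "Wb", "Ub", "bb"))
  p
}

#' Initialize the dual-branch relation classifier
#'
#' Builds the word and dependency-relation vocabularies from the training
#' instances and initializes all parameters. Word embeddings are copied from a
#' pretrained table where available; tokens missing from the table follow the
#' table's out-of-vocabulary policy (uniform in \[-0.25, 0.25\] or zero).
#' Position and relation-type embeddings are uniform in \[-0.05, 0.05\].
#' Weight matrices use uniform Glorot initialization; biases start at zero.
#'
#' @param config A [model_config].
#' @param instances Training instances from [build_instances()].
#' @param embeddings Optional `embedding_table` from [load_word2vec_text()];
#'   its dimension must equal `config$word_dim`.
#' @param seed Optional integer seed for the random initialization.
#' @return An `sdprel_model`: list with `config`, `params` (named list of
#'   arrays), `vocab`, `deprel_vocab`.
#' @export
init_model <- function(config, instances, embeddings = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(embeddings) && embeddings$dimension != config$word_dim) {
    stop(sprintf("embedding dimension %d does not match word_dim %d",
                 embeddings$dimension, config$word_dim), call. = FALSE)
  }
  vocab <- build_word_vocab(instances)
  V <- length(vocab)
  dw <- config$word_dim
  We <- runif_mat(V, dw, 0.25)
  if (!is.null(embeddings)) {
    if (embeddings$oov_policy == "zero") We[] <- 0
    hit <- match(vocab, names(embeddings$vocabulary))
    found <- which(!is.na(hit))
    We[found, ] <- embeddings$vectors[embeddings$vocabulary[hit[found]], ,
                                      drop = FALSE]
  }
  params <- list(We = We,
                 Pe = runif_mat(2L * config$max_dist + 2L,
                                config$position_dim, 0.05))
  h <- config$hidden
  din_sent <- dw + 2L * config$position_dim
  params <- c(params, lstm_params(din_sent, h, "s"))

  deprel_vocab <- character(0)
  if (config$use_sdp_words) {
    n2 <- h
    params$M <- glorot(dw, n2)
    din_sdp <- 2L * n2
    if (config$use_sdp_relations) {
      deprel_vocab <- build_deprel_vocab(instances)
      params$De <- runif_mat(length(deprel_vocab), config$deprel_dim, 0.05)
      din_sdp <- din_sdp + config$deprel_dim
    }
    params$placeholder <- stats::runif(din_sdp, -0.05, 0.05)
    params <- c(params, lstm_params(din_sdp, h, "p"))
  }
  vdim <- if (config$use_sdp_words) 4L * h else 2L * h
  params$W1 <- glorot(vdim, config$fc_dim)
  params$b1 <- numeric(config$fc_dim)
  params$Wo <- glorot(config$fc_dim, config$n_classes)
  params$bo <- numeric(config$n_classes)
  structure(list(config = config, params = params, vocab = vocab,
                 deprel_vocab = deprel_vocab),
            class = "sdprel_model")
}

#' @export
print.sdprel_model <- function(x, ...) {
  cat(sprintf(paste0("<sdprel_model: |V|=%d, |deprels|=%d, hidden=%d, ",
                     "%d parameters%s%s>\n"),
              length(x$vocab), length(x$deprel_vocab), x$config$hidden,
              n_parameters(x),
              if (x$config$use_sdp_words) ", +SDP words" else ", sentence-only",
              if (x$config$use_sdp_relations) " +relation types" else ""))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model An `sdprel_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

token_ids <- function(tokens, vocab) {
  i <- match(tokens, vocab)
  i[is.na(i)] <- match(UNK_TOKEN, vocab)
  i
}

# Assemble one padded batch: token/position index matrices plus masks for the
# sentence branch, path-token/relation index matrices plus step mask and
# placeholder flags for the SDP branch.
make_batch <- function(instances, model, class_weights = NULL) {
  cfg <- model$config
  B <- length(instances)
  if (B == 0L) stop("cannot build a batch from zero instances", call. = FALSE)
  lens <- vapply(instances, function(x) length(x$masked_tokens), integer(1))
  T_ <- max(lens)
  unk <- match(UNK_TOKEN, model$vocab)
  widx <- matrix(unk, B, T_)
  p1 <- matrix(1L, B, T_)
  p2 <- matrix(1L, B, T_)
  mask <- matrix(0, B, T_)
  labels <- integer(B)
  for (i in seq_len(B)) {
    x <- instances[[i]]
    n <- lens[i]
    widx[i, seq_len(n)] <- token_ids(x$masked_tokens, model$vocab)
    p1[i, seq_len(n)] <- position_row(x$pos1, cfg$max_dist)
    p2[i, seq_len(n)] <- position_row(x$pos2, cfg$max_dist)
    mask[i, seq_len(n)] <- 1
    labels[i] <- match(x$label, RELATION_LABELS)
  }
  wts <- rep(1, B)
  if (!is.null(class_weights)) {
    hit <- class_weights[RELATION_LABELS[labels]]
    wts <- ifelse(is.na(hit), 1, hit)
  }
  batch <- list(B = B, T_ = T_, widx = widx, p1 = p1, p2 = p2, mask = mask,
                labels = labels, wts = wts)
  if (cfg$use_sdp_words) {
    steps <- vapply(instances, function(x) {
      if (is.null(x$sdp) || length(x$sdp$nodes) < 2L) 1L
      else length(x$sdp$nodes) - 1L
    }, integer(1))
    S <- max(steps)
    pidx <- matrix(unk, B, S + 1L)
    didx <- matrix(1L, B, S)
    smask <- matrix(0, B, S)
    flag <- logical(B)
    unk_rel <- if (cfg$use_sdp_relations) {
      match(UNK_DEPREL, model$deprel_vocab)
    } else 1L
    didx[] <- unk_rel
    for (i in seq_len(B)) {
      x <- instances[[i]]
      if (is.null(x$sdp) || length(x$sdp$nodes) < 2L) {
        flag[i] <- TRUE
        smask[i, 1L] <- 1
        next
      }
      m <- length(x$sdp$nodes)
      pidx[i, seq_len(m)] <- token_ids(x$sdp$words, model$vocab)
      smask[i, seq_len(m - 1L)] <- 1
      if (cfg$use_sdp_relations) {
        r <- match(x$sdp$relations, model$deprel_vocab)
        r[is.na(r)] <- unk_rel
        didx[i, seq_len(m - 1L)] <- r
      }
    }
    batch$S <- S
    batch$pidx <- pidx
    batch$didx <- didx
    batch$smask <- smask
    batch$flag <- flag
  }
  batch
}

#' Pairwise convolution over neighboring path words
#'
#' For a path of m word vectors (rows of `P`, dimension n1) returns the m - 1
#' merged local features: the two neighboring vectors are stacked into a
#' 2 x n1 block and right-multiplied by the shared transform `M` (n1 x n2),
#' and the 2 x n2 result is flattened row-wise into one vector of length
#' 2 * n2. `M` is identical across all positions of the path.
#'
#' @param P Numeric matrix, one path-word embedding per row.
#' @param M Transform matrix (n1 x n2).
#' @return Matrix with m - 1 rows and 2 * n2 columns.
#' @export
sdp_convolution <- function(P, M) {
  m <- nrow(P)
  if (m < 2L) stop("path must have at least two words", call. = FALSE)
  Q <- P %*% M
  cbind(Q[-m, , drop = FALSE], Q[-1L, , drop = FALSE])
}

# Full forward pass. Returns probabilities, the mean cross-entropy when the
# batch carries labels, and (optionally) all caches needed for the backward
# pass. Dropout (inverted scaling) is applied only when train = TRUE.
nn_forward <- function(model, batch, train = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  pr <- model$params
  B <- batch$B
  T_ <- batch$T_
  h <- cfg$hidden

  Xs <- vector("list", T_)
  for (t in seq_len(T_)) {
    Xs[[t]] <- cbind(pr$We[batch$widx[, t], , drop = FALSE],
                     pr$Pe[batch$p1[, t], , drop = FALSE],
                     pr$Pe[batch$p2[, t], , drop = FALSE])
  }
  bi_s <- bilstm_forward(Xs, batch$mask,
                         list(Wf = pr$sWf, Uf = pr$sUf, bf = pr$sbf,
                              Wb = pr$sWb, Ub = pr$sUb, bb = pr$sbb))
  if (cfg$pooling == "max") {
    pool_s <- masked_max_pool(bi_s$H, batch$mask)
    sent_vec <- pool_s$pooled
  } else {
    pool_s <- NULL
    sent_vec <- final_pool(bi_s$H, h)
  }

  sdp <- NULL
  if (cfg$use_sdp_words) {
    S <- batch$S
    Qp <- vector("list", S + 1L)
    for (j in seq_len(S + 1L)) {
      Qp[[j]] <- pr$We[batch$pidx[, j], , drop = FALSE] %*% pr$M
    }
    Xp <- vector("list", S)
    for (s in seq_len(S)) {
      Xp[[s]] <- if (cfg$use_sdp_relations) {
        cbind(Qp[[s]], Qp[[s + 1L]],
              pr$De[batch$didx[, s], , drop = FALSE])
      } else {
        cbind(Qp[[s]], Qp[[s + 1L]])
      }
    }
    if (any(batch$flag)) {
      Xp[[1L]][batch$flag, ] <- matrix(pr$placeholder, sum(batch$flag),
                                       length(pr$placeholder), byrow = TRUE)
    }
    bi_p <- bilstm_forward(Xp, batch$smask,
                           list(Wf = pr$pWf, Uf = pr$pUf, bf = pr$pbf,
                                Wb = pr$pWb, Ub = pr$pUb, bb = pr$pbb))
    if (cfg$pooling == "max") {
      pool_p <- masked_max_pool(bi_p$H, batch$smask)
      sdp_vec <- pool_p$pooled
    } else {
      pool_p <- NULL
      sdp_vec <- final_pool(bi_p$H, h)
    }
    sdp <- list(Qp = Qp, bi = bi_p, pool = pool_p, vec = sdp_vec)
    v <- cbind(sent_vec, sdp_vec)
  } else {
    v <- sent_vec
  }

  if (train && cfg$dropout > 0) {
    dmask <- (matrix(stats::runif(length(v)), nrow(v)) >= cfg$dropout) /
      (1 - cfg$dropout)
  } else {
    dmask <- NULL
  }
  u <- if (is.null(dmask)) v else v * dmask
  z1 <- u %*% pr$W1 + matrix(pr$b1, B, cfg$fc_dim, byrow = TRUE)
  s1 <- tanh(z1)
  logits <- s1 %*% pr$Wo + matrix(pr$bo, B, cfg$n_classes, byrow = TRUE)
  probs <- softmax_rows(logits)
  loss <- if (!is.null(batch$labels) && all(batch$labels > 0L)) {
    w <- batch$wts %||% rep(1, B)
    ce <- -log(pmax(probs[cbind(seq_len(B), batch$labels)], 1e-12))
    sum(w * ce) / sum(w)
  } else {
    NA_real_
  }
  out <- list(probs = probs, loss = loss)
  if (keep_cache) {
    out$cache <- list(bi_s = bi_s, pool_s = pool_s, sent_vec = sent_vec,
                      sdp = sdp, v = v, dmask = dmask, u = u, s1 = s1)
  }
  out
}

# Analytic gradients of the mean cross-entropy for one batch. Returns a named
# list parallel to model$params (embedding gradients omitted when
# train_embeddings is off).
nn_backward <- function(model, batch, fwd) {
  cfg <- model$config
  pr <- model$params
  ca <- fwd$cache
  B <- batch$B
  T_ <- batch$T_
  h <- cfg$hidden
  dw <- cfg$word_dim
  dp <- cfg$position_dim

  dlogits <- fwd$probs
  dlogits[cbind(seq_len(B), batch$labels)] <-
    dlogits[cbind(seq_len(B), batch$labels)] - 1
  w <- batch$wts %||% rep(1, B)
  dlogits <- dlogits * (w / sum(w))

  g <- list()
  g$Wo <- crossprod(ca$s1, dlogits)
  g$bo <- colSums(dlogits)
  ds1 <- dlogits %*% t(pr$Wo)
  dz1 <- ds1 * (1 - ca$s1^2)
  g$W1 <- crossprod(ca$u, dz1)
  g$b1 <- colSums(dz1)
  du <- dz1 %*% t(pr$W1)
  dv <- if (is.null(ca$dmask)) du else du * ca$dmask

  d_sent <- dv[, seq_len(2L * h), drop = FALSE]
  if (cfg$pooling == "max") {
    dHs <- masked_max_pool_backward(d_sent, ca$pool_s$arg, T_)
  } else {
    dHs <- final_pool_backward(d_sent, T_, h, B)
  }
  gs <- bilstm_backward(ca$bi_s, dHs)
  g$sWf <- gs$dWf; g$sUf <- gs$dUf; g$sbf <- gs$dbf
  g$sWb <- gs$dWb; g$sUb <- gs$dUb; g$sbb <- gs$dbb

  if (cfg$train_embeddings) {
    dWe <- matrix(0, nrow(pr$We), dw)
    dPe <- matrix(0, nrow(pr$Pe), dp)
    for (t in seq_len(T_)) {
      dX <- gs$dX[[t]]
      dWe <- scatter_add(dWe, batch$widx[, t], dX[, seq_len(dw), drop = FALSE])
      dPe <- scatter_add(dPe, batch$p1[, t],
                         dX[, dw + seq_len(dp), drop = FALSE])
      dPe <- scatter_add(dPe, batch$p2[, t],
                         dX[, dw + dp + seq_len(dp), drop = FALSE])
    }
    g$Pe <- dPe
  } else {
    dWe <- NULL
  }

  if (cfg$use_sdp_words) {
    S <- batch$S
    n2 <- h
    d_sdp <- dv[, 2L * h + seq_len(2L * h), drop = FALSE]
    if (cfg$pooling == "max") {
      dHp <- masked_max_pool_backward(d_sdp, ca$sdp$pool$arg, S)
    } else {
      dHp <- final_pool_backward(d_sdp, S, h, B)
    }
    gp <- bilstm_backward(ca$sdp$bi, dHp)
    g$pWf <- gp$dWf; g$pUf <- gp$dUf; g$pbf <- gp$dbf
    g$pWb <- gp$dWb; g$pUb <- gp$dUb; g$pbb <- gp$dbb

    dXp <- gp$dX
    if (any(batch$flag)) {
      g$placeholder <- colSums(dXp[[1L]][batch$flag, , drop = FALSE])
      dXp[[1L]][batch$flag, ] <- 0
    } else {
      g$placeholder <- numeric(length(pr$placeholder))
    }
    dQ <- vector("list", S + 1L)
    for (j in seq_len(S + 1L)) dQ[[j]] <- matrix(0, B, n2)
    if (cfg$use_sdp_relations) {
      dDe <- matrix(0, nrow(pr$De), cfg$deprel_dim)
    }
    for (s in seq_len(S)) {
      dX <- dXp[[s]]
      dQ[[s]] <- dQ[[s]] + dX[, seq_len(n2), drop = FALSE]
      dQ[[s + 1L]] <- dQ[[s + 1L]] + dX[, n2 + seq_len(n2), drop = FALSE]
      if (cfg$use_sdp_relations) {
        dDe <- scatter_add(dDe, batch$didx[, s],
                           dX[, 2L * n2 + seq_len(cfg$deprel_dim),
                              drop = FALSE])
      }
    }
    dM <- matrix(0, dw, n2)
    for (j in seq_len(S + 1L)) {
      Pj <- pr$We[batch$pidx[, j], , drop = FALSE]
      dM <- dM + crossprod(Pj, dQ[[j]])
      if (cfg$train_embeddings) {
        dWe <- scatter_add(dWe, batch$pidx[, j], dQ[[j]] %*% t(pr$M))
      }
    }
    g$M <- dM
    if (cfg$use_sdp_relations) g$De <- dDe
  }
  if (cfg$train_embeddings) g$We <- dWe
  g
}

# loss-only evaluation used by the finite-difference gradient check
nn_loss <- function(model, batch) {
  nn_forward(model, batch, train = FALSE)$loss
}

#' Predict relation labels
#'
#' Runs the forward pass in evaluation mode (no dropout) and returns the
#' argmax label per instance.
#'
#' @param model A trained `sdprel_model` (see [train_relex()]; the `model`
#'   element of the fit, or the fit itself).
#' @param instances List of `relation_instance` objects.
#' @param batch_size Instances per forward batch.
#' @return Character vector of predicted labels, with the class-probability
#'   matrix attached as attribute `"probabilities"`.
#' @export
predict_relations <- function(model, instances, batch_size = 64L) {
  if (inherits(model, "sdprel_fit")) model <- model$model
  n <- length(instances)
  probs <- matrix(NA_real_, n, model$config$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    batch <- make_batch(instances[i:j], model)
    batch$labels <- NULL
    probs[i:j, ] <- nn_forward(model, batch)$probs
    i <- j + 1L
  }
  colnames(probs) <- RELATION_LABELS
  labels <- RELATION_LABELS[max.col(probs, ties.method = "first")]
  attr(labels, "probabilities") <- probs
  labels
}
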
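test_that("pairwise path convolution reduces to copies under identity", {
  M <- diag(2)
  P <- rbind(c(1, 0), c(0, 1))
  expect_equal(sdp_convolution(P, M), cbind(rbind(c(1, 0)), rbind(c(0, 1))),
               ignore_attr = TRUE)
  expect_equal(as.numeric(sdp_convolution(P, M)[1L, ]), c(1, 0, 0, 1))
})

test_that("path convolution matches a per-pair matrix-product oracle", {
  set.seed(14)
  for (rep in 1:100) {
    m <- sample(2:6, 1L)
    n1 <- sample(2:8, 1L)
    n2 <- sample(2:8, 1L)
    P <- matrix(rnorm(m * n1), m, n1)
    M <- matrix(rnorm(n1 * n2), n1, n2)
    got <- sdp_convolution(P, M)
    expect_equal(nrow(got), m - 1L)
    for (i in seq_len(m - 1L)) {
      block <- rbind(P[i, ], P[i + 1L, ]) %*% M  # 2 x n2, flattened row-wise
      expect_equal(as.numeric(got[i, ]), c(block[1L, ], block[2L, ]),
                   tolerance = 1e-6)
    }
  }
})

test_that("token input vectors concatenate word and two position channels", {
  inst <- separable_instances(1L)
  cfg <- tiny_model_config()
  model <- init_model(cfg, inst, seed = 4)
  x <- inst[[1L]]
  b <- sdprel:::make_batch(list(x), model)
  # expected dimension: word + 2 x position
  expect_equal(cfg$word_dim + 2L * cfg$position_dim, 14L)
  # the target token's own position channel uses the zero-distance row
  zero_row <- sdprel:::position_row(0L, cfg$max_dist)
  expect_equal(b$p1[1L, x$e1_index], zero_row)
  expect_equal(b$p2[1L, x$e2_index], zero_row)
  # distances beyond the clip share the out-of-range bucket row
  expect_equal(sdprel:::position_row(cfg$max_dist + 5L, cfg$max_dist),
               sdprel:::position_row(-cfg$max_dist - 99L, cfg$max_dist))
})

test_that("default dimensions follow the published regime", {
  cfg <- model_config()
  expect_equal(cfg$word_dim + 2L * cfg$position_dim, 200L)
  expect_equal(cfg$hidden, 200L)
  # per-timestep Bi-LSTM output is the forward/backward concatenation
  inst <- separable_instances(1L)
  model <- init_model(tiny_model_config(), inst, seed = 1)
  b <- sdprel:::make_batch(inst[1:2], model)
  fwd <- sdprel:::nn_forward(model, b, keep_cache = TRUE)
  expect_equal(ncol(fwd$cache$bi_s$H[[1L]]), 2L * model$config$hidden)
  expect_equal(ncol(fwd$cache$sent_vec), 2L * model$config$hidden)
})

test_that("single-token sequences pool to their only timestep", {
  inst <- separable_instances(1L)
  model <- init_model(tiny_model_config(), inst, seed = 2)
  x <- inst[[1L]]
  x$masked_tokens <- x$masked_tokens[1L]
  x$e1_index <- 1L; x$e2_index <- 1L
  x$pos1 <- 0L; x$pos2 <- 0L
  x$sdp <- NULL
  b <- sdprel:::make_batch(list(x), model)
  fwd <- sdprel:::nn_forward(model, b, keep_cache = TRUE)
  expect_equal(fwd$cache$sent_vec, fwd$cache$bi_s$H[[1L]])
})

test_that("reversing the input swaps forward and backward roles", {
  set.seed(5)
  Tn <- 4L; B <- 1L; d <- 3L; h <- 2L
  W <- matrix(rnorm(d * 4 * h), d); U <- matrix(rnorm(h * 4 * h), h)
  b <- rnorm(4 * h)
  p <- list(Wf = W, Uf = U, bf = b, Wb = W, Ub = U, bb = b)  # tied weights
  X <- lapply(1:Tn, function(t) matrix(rnorm(B * d), B, d))
  mask <- matrix(1, B, Tn)
  H1 <- sdprel:::bilstm_forward(X, mask, p)$H
  H2 <- sdprel:::bilstm_forward(rev(X), mask, p)$H
  for (t in 1:Tn) {
    expect_equal(H1[[t]][, 1:h], H2[[Tn - t + 1L]][, h + 1:h],
                 tolerance = 1e-12)
    expect_equal(H1[[t]][, h + 1:h], H2[[Tn - t + 1L]][, 1:h],
                 tolerance = 1e-12)
  }
})

test_that("padding never changes an instance's probabilities", {
  inst <- separable_instances(2L)
  model <- init_model(tiny_model_config(), inst, seed = 6)
  short <- inst[[1L]]
  long <- inst[[2L]]
  long$masked_tokens <- c(long$masked_tokens, sprintf("pad%d", 1:9))
  long$pos1 <- c(long$pos1, 5:13)
  long$pos2 <- c(long$pos2, 2:10)
  alone <- sdprel:::make_batch(list(short), model)
  padded <- sdprel:::make_batch(list(short, long), model)
  p1 <- sdprel:::nn_forward(model, alone)$probs
  p2 <- sdprel:::nn_forward(model, padded)$probs
  expect_equal(p1[1L, ], p2[1L, ], tolerance = 1e-12)
})

test_that("softmax head yields valid, shift-invariant distributions", {
  set.seed(8)
  z <- matrix(rnorm(50 * 9), 50, 9)
  p <- sdprel:::softmax_rows(z)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p > 0))
  expect_equal(sdprel:::softmax_rows(z + 17.3), p, tolerance = 1e-9)
  expect_equal(as.numeric(sdprel:::softmax_rows(matrix(0, 1, 9))),
               rep(1 / 9, 9))
})

test_that("zeroed output head gives uniform class probabilities", {
  inst <- separable_instances(2L)
  model <- init_model(tiny_model_config(), inst, seed = 9)
  model$params$Wo[] <- 0
  model$params$bo[] <- 0
  b <- sdprel:::make_batch(inst, model)
  probs <- sdprel:::nn_forward(model, b)$probs
  expect_equal(probs, matrix(1 / 9, nrow(probs), 9), ignore_attr = TRUE,
               tolerance = 1e-12)
  # cross-entropy of the uniform head is exactly ln(9)
  expect_equal(sdprel:::nn_forward(model, b)$loss, log(9), tolerance = 1e-9)
})

test_that("sentence-only outputs are independent of any SDP input", {
  inst <- separable_instances(3L)
  model <- init_model(tiny_model_config(use_sdp_words = FALSE,
                                        use_sdp_relations = FALSE),
                      inst, seed = 10)
  scrambled <- lapply(inst, function(x) {
    x$sdp$words <- rev(x$sdp$words)
    x$sdp$relations <- c("zzz", "yyy")
    x
  })
  removed <- lapply(inst, function(x) { x$sdp <- NULL; x })
  p0 <- sdprel:::nn_forward(model, sdprel:::make_batch(inst, model))$probs
  p1 <- sdprel:::nn_forward(model,
                            sdprel:::make_batch(scrambled, model))$probs
  p2 <- sdprel:::nn_forward(model, sdprel:::make_batch(removed, model))$probs
  expect_identical(p0, p1)
  expect_identical(p0, p2)
})

test_that("relation-type ablation makes outputs label-invariant", {
  inst <- separable_instances(3L)
  model <- init_model(tiny_model_config(use_sdp_relations = FALSE),
                      inst, seed = 11)
  relabeled <- lapply(inst, function(x) {
    x$sdp$relations <- c("made_up_rel", "another_rel")
    x
  })
  p0 <- sdprel:::nn_forward(model, sdprel:::make_batch(inst, model))$probs
  p1 <- sdprel:::nn_forward(model,
                            sdprel:::make_batch(relabeled, model))$probs
  expect_identical(p0, p1)
})

test_that("unknown relation labels fall back to the UNK embedding", {
  inst <- separable_instances(2L)
  model <- init_model(tiny_model_config(), inst, seed = 12)
  set.seed(33)
  for (rep in 1:20) {
    fuzzed <- lapply(inst, function(x) {
      x$sdp$relations <- paste0("rel_", sample(1e6, length(x$sdp$relations)))
      x
    })
    b <- sdprel:::make_batch(fuzzed, model)
    expect_true(all(is.finite(sdprel:::nn_forward(model, b)$probs)))
  }
})

test_that("instances without a path use the learned placeholder", {
  inst <- separable_instances(2L)
  nopath <- lapply(inst, function(x) { x$sdp <- NULL; x })
  model <- init_model(tiny_model_config(), c(inst, nopath), seed = 13)
  b <- sdprel:::make_batch(nopath, model)
  expect_true(all(b$flag))
  fwd <- sdprel:::nn_forward(model, b)
  expect_true(all(is.finite(fwd$probs)))
  # the placeholder influences the output: perturbing it changes probs
  model2 <- model
  model2$params$placeholder <- model2$params$placeholder + 0.5
  fwd2 <- sdprel:::nn_forward(model2, b)
  expect_false(isTRUE(all.equal(fwd$probs, fwd2$probs, tolerance = 1e-12)))
})

test_that("parameter count matches the closed-form expression", {
  inst <- separable_instances(2L)
  cfg <- tiny_model_config()
  model <- init_model(cfg, inst, seed = 14)
  V <- length(model$vocab)
  R <- length(model$deprel_vocab)
  h <- cfg$hidden
  din_sent <- cfg$word_dim + 2L * cfg$position_dim
  din_sdp <- 2L * h + cfg$deprel_dim
  expected <- V * cfg$word_dim +                       # word table
    (2L * cfg$max_dist + 2L) * cfg$position_dim +      # position table
    2L * (din_sent * 4L * h + h * 4L * h + 4L * h) +   # sentence Bi-LSTM
    cfg$word_dim * h +                                 # path transform M
    R * cfg$deprel_dim +                               # deprel table
    din_sdp +                                          # no-path placeholder
    2L * (din_sdp * 4L * h + h * 4L * h + 4L * h) +    # path Bi-LSTM
    4L * h * cfg$fc_dim + cfg$fc_dim +                 # fully-connected
    cfg$fc_dim * cfg$n_classes + cfg$n_classes         # output layer
  expect_equal(n_parameters(model), expected)
})

test_that("pretrained vectors seed the word table and OOV policy applies", {
  inst <- separable_instances(1L)
  path <- withr::local_tempfile(fileext = ".txt")
  vec <- round(seq(0.1, 0.6, by = 0.1), 1)
  writeLines(c(paste("1", 6), paste(c("tar_problem", vec), collapse = " ")),
             path)
  tab <- load_word2vec_text(path, 6L)
  model <- init_model(tiny_model_config(), inst, embeddings = tab, seed = 15)
  row <- match("tar_problem", model$vocab)
  expect_equal(as.numeric(model$params$We[row, ]), vec)
  oov <- match("tar_test", model$vocab)
  expect_true(all(abs(model$params$We[oov, ]) <= 0.25))
  expect_error(init_model(tiny_model_config(), inst,
                          embeddings = load_word2vec_text(path, 6L),
                          seed = 1)$config, NA)
  expect_error(init_model(model_config(word_dim = 9L), inst,
                          embeddings = tab), "does not match word_dim")
})
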
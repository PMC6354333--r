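test_that("candidate generation follows the type-pair schema", {
  ex <- example_clinical_sentence()$sentence
  cand <- generate_candidates(ex)
  # two treatments + one problem: the two treatment-problem pairs qualify,
  # the treatment-treatment pair does not
  expect_equal(nrow(cand), 2L)
  expect_setequal(cand$m1, c("1:5-6", "1:8-8"))
  expect_true(all(cand$m2 == "1:10-11"))
  expect_setequal(cand$label, c("TrAP", "None"))
})

test_that("single-mention sentences yield no candidates", {
  s <- annotated_sentence("d", 1L, c("a", "b"),
                          mentions = data.frame(
                            id = "1:1-1", token_start = 1L, token_end = 1L,
                            entity_type = "problem", surface = "a",
                            stringsAsFactors = FALSE))
  expect_equal(nrow(generate_candidates(s)), 0L)
})

test_that("candidate counts match a brute-force double loop", {
  cfg <- synth_config(n_documents = 5, sentences_per_doc = 5, seed = 17)
  corp <- generate_corpus(cfg)
  schema <- pair_schema_i2b2()
  for (s in corp$sentences) {
    cand <- generate_candidates(s, schema)
    # oracle: count admissible unordered pairs directly
    cnt <- 0L
    m <- s$mentions
    if (nrow(m) >= 2L) {
      for (i in seq_len(nrow(m))) {
        for (j in seq_len(nrow(m))) {
          if (i < j && !is.null(admissible_labels(schema, m$entity_type[i],
                                                  m$entity_type[j]))) {
            cnt <- cnt + 1L
          }
        }
      }
    }
    expect_equal(nrow(cand), cnt)
    # labels always in the admissible set
    for (k in seq_len(nrow(cand))) {
      t1 <- m$entity_type[m$id == cand$m1[k]]
      t2 <- m$entity_type[m$id == cand$m2[k]]
      expect_true(cand$label[k] %in% admissible_labels(schema, t1, t2))
    }
  }
})

test_that("masking reproduces the published example conversion", {
  ex <- example_clinical_sentence()$sentence
  mk <- mask_entities(ex, c("1:5-6", "1:10-11"))
  expect_equal(paste(mk$tokens, collapse = " "),
               "She was maintained on tar_treatment and ent_treatment for tar_problem")
  expect_equal(mk$e1_index, 5L)
  expect_equal(mk$e2_index, 9L)
  expect_true(startsWith(mk$tokens[mk$e1_index], "tar_"))
  expect_true(startsWith(mk$tokens[mk$e2_index], "tar_"))
})

test_that("masked length equals token count minus collapsed span excess", {
  cfg <- synth_config(n_documents = 5, sentences_per_doc = 4, seed = 23)
  corp <- generate_corpus(cfg)
  for (s in corp$sentences) {
    if (nrow(s$mentions) < 2L) next
    cand <- generate_candidates(s)
    if (nrow(cand) == 0L) next
    mk <- mask_entities(s, c(cand$m1[1L], cand$m2[1L]))
    excess <- sum(s$mentions$token_end - s$mentions$token_start)
    expect_length(mk$tokens, length(s$tokens) - excess)
    expect_true(mk$e1_index != mk$e2_index)
  }
})

test_that("masking an already-masked sentence is a no-op", {
  ex <- example_clinical_sentence()$sentence
  mk <- mask_entities(ex, c("1:5-6", "1:10-11"))
  remask <- annotated_sentence(
    "d", 1L, mk$tokens,
    mentions = data.frame(
      id = c("a", "b", "c"),
      token_start = c(5L, 7L, 9L), token_end = c(5L, 7L, 9L),
      entity_type = c("treatment", "treatment", "problem"),
      surface = mk$tokens[c(5L, 7L, 9L)], stringsAsFactors = FALSE))
  mk2 <- mask_entities(remask, c("a", "c"))
  expect_equal(mk2$tokens, mk$tokens)
})

test_that("overlap resolution keeps the longer span and warns", {
  s <- annotated_sentence(
    "d", 1L, c("a", "b", "c", "d", "e"),
    mentions = data.frame(
      id = c("long", "short", "t2"),
      token_start = c(1L, 2L, 5L), token_end = c(3L, 2L, 5L),
      entity_type = c("problem", "problem", "test"),
      surface = c("a b c", "b", "e"), stringsAsFactors = FALSE))
  expect_warning(mk <- mask_entities(s, c("long", "t2")), "overlapping")
  expect_equal(mk$tokens, c("tar_problem", "d", "tar_test"))
})

test_that("position features reproduce the published relative distances", {
  ex <- example_clinical_sentence()$sentence
  mk <- mask_entities(ex, c("1:5-6", "1:10-11"))
  pos <- position_features(length(mk$tokens), mk$e1_index, mk$e2_index)
  expect_equal(pos$pos1[1L], -4L)  # "She" to the first target
  expect_equal(pos$pos2[1L], -8L)  # "She" to the second target
  expect_equal(pos$pos1[mk$e1_index], 0L)
  expect_equal(pos$pos2[mk$e2_index], 0L)
})

test_that("position feature identities hold on random instances", {
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(3:40, 1L)
    e <- sort(sample.int(n, 2L))
    pos <- position_features(n, e[1L], e[2L])
    expect_equal(pos$pos1[e[1L]], 0L)
    expect_equal(pos$pos2[e[2L]], 0L)
    expect_true(all(pos$pos1 - pos$pos2 == e[2L] - e[1L]))
  }
})

test_that("instances expose valid spans, positions and paths", {
  cfg <- synth_config(n_documents = 4, sentences_per_doc = 4, seed = 5)
  corp <- generate_corpus(cfg)
  instances <- build_instances(corp$sentences, corp$graphs)
  expect_gt(length(instances), 0L)
  for (x in instances) {
    n <- length(x$masked_tokens)
    expect_true(startsWith(x$masked_tokens[x$e1_index], "tar_"))
    expect_true(startsWith(x$masked_tokens[x$e2_index], "tar_"))
    expect_length(x$pos1, n)
    expect_length(x$pos2, n)
    expect_equal(x$pos1[x$e1_index], 0L)
    if (!is.null(x$sdp)) {
      m <- length(x$sdp$nodes)
      expect_equal(x$sdp$nodes[1L], x$e1_index)
      expect_equal(x$sdp$nodes[m], x$e2_index)
      expect_length(x$sdp$relations, m - 1L)
      expect_equal(x$sdp$words, x$masked_tokens[x$sdp$nodes])
    }
  }
})

test_that("instances round-trip through JSON lines", {
  cfg <- synth_config(n_documents = 3, sentences_per_doc = 3, seed = 77)
  corp <- generate_corpus(cfg)
  instances <- build_instances(corp$sentences, corp$graphs)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_instances(instances, path)
  back <- read_instances(path)
  expect_length(back, length(instances))
  for (i in seq_along(back)) {
    expect_equal(unclass(back[[i]]), unclass(instances[[i]]))
  }
})
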
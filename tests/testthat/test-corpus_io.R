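test_that("the worked example reads from the i2b2-style dialect", {
  dir <- withr::local_tempdir()
  write_i2b2_corpus(list(example_clinical_sentence()$sentence),
                    file.path(dir, "text"), file.path(dir, "con"),
                    file.path(dir, "rel"))
  sents <- read_i2b2_corpus(file.path(dir, "text"), file.path(dir, "con"),
                            file.path(dir, "rel"))
  expect_length(sents, 1L)
  s <- sents[[1L]]
  expect_equal(paste(s$tokens, collapse = " "),
               "She was maintained on an epidural and pca for pain control")
  expect_equal(nrow(s$mentions), 3L)
  expect_setequal(s$mentions$surface, c("an epidural", "pca", "pain control"))
  expect_setequal(s$mentions$entity_type, c("treatment", "treatment",
                                            "problem"))
  expect_equal(s$relations$label, "TrAP")
})

test_that("a synthetic corpus round-trips through the dialect", {
  cfg <- synth_config(n_documents = 4, sentences_per_doc = 5, seed = 31)
  corp <- generate_corpus(cfg)
  dir <- withr::local_tempdir()
  write_i2b2_corpus(corp$sentences, file.path(dir, "text"),
                    file.path(dir, "con"), file.path(dir, "rel"))
  back <- read_i2b2_corpus(file.path(dir, "text"), file.path(dir, "con"),
                           file.path(dir, "rel"))
  expect_length(back, length(corp$sentences))
  for (i in seq_along(back)) {
    a <- corp$sentences[[i]]; b <- back[[i]]
    expect_equal(b$tokens, a$tokens)
    expect_equal(b$mentions[order(b$mentions$id), ],
                 a$mentions[order(a$mentions$id), ],
                 ignore_attr = TRUE)
    key <- function(r) sort(sprintf("%s|%s|%s", r$m1, r$m2, r$label))
    expect_equal(key(b$relations), key(a$relations))
  }
})

test_that("relations always link mentions within one sentence", {
  cfg <- synth_config(n_documents = 3, sentences_per_doc = 4, seed = 8)
  corp <- generate_corpus(cfg)
  for (s in corp$sentences) {
    if (nrow(s$relations) == 0L) next
    expect_true(all(s$relations$m1 %in% s$mentions$id))
    expect_true(all(s$relations$m2 %in% s$mentions$id))
  }
})

test_that("malformed and inconsistent annotation lines are rejected", {
  dir <- withr::local_tempdir()
  for (d in c("text", "con", "rel")) dir.create(file.path(dir, d))
  writeLines("a b c d", file.path(dir, "text", "doc1.txt"))
  writeLines('c="b" 1:2 1:2|t="problem"',  # missing second pipe
             file.path(dir, "con", "doc1.con"))
  expect_error(read_i2b2_corpus(file.path(dir, "text"), file.path(dir, "con"),
                                file.path(dir, "rel")),
               "doc1\\.con:1")
  writeLines('c="b" 1:2 1:2||t="problem"', file.path(dir, "con", "doc1.con"))
  writeLines('c="a" 1:1 1:1||r="PIP"||c="b" 1:2 1:2',
             file.path(dir, "rel", "doc1.rel"))
  expect_error(read_i2b2_corpus(file.path(dir, "text"), file.path(dir, "con"),
                                file.path(dir, "rel")),
               "unknown concept span")
})

test_that("cross-sentence relation lines are dropped with a warning", {
  dir <- withr::local_tempdir()
  for (d in c("text", "con", "rel")) dir.create(file.path(dir, d))
  writeLines(c("a b", "c d"), file.path(dir, "text", "doc1.txt"))
  writeLines(c('c="a" 1:1 1:1||t="problem"', 'c="c" 2:1 2:1||t="problem"'),
             file.path(dir, "con", "doc1.con"))
  writeLines('c="a" 1:1 1:1||r="PIP"||c="c" 2:1 2:1',
             file.path(dir, "rel", "doc1.rel"))
  expect_warning(
    sents <- read_i2b2_corpus(file.path(dir, "text"), file.path(dir, "con"),
                              file.path(dir, "rel")),
    "cross-sentence")
  expect_true(all(vapply(sents, function(s) nrow(s$relations), integer(1)) ==
                    0L))
})

test_that("an absent relation file means no relations", {
  dir <- withr::local_tempdir()
  for (d in c("text", "con", "rel")) dir.create(file.path(dir, d))
  writeLines("a b", file.path(dir, "text", "doc1.txt"))
  writeLines('c="a" 1:1 1:1||t="test"', file.path(dir, "con", "doc1.con"))
  sents <- read_i2b2_corpus(file.path(dir, "text"), file.path(dir, "con"),
                            file.path(dir, "rel"))
  expect_length(sents, 1L)
  expect_equal(nrow(sents[[1L]]$relations), 0L)
})

test_that("CoNLL-U blocks round-trip for random projective trees", {
  set.seed(11)
  graphs <- lapply(1:20, function(i) {
    g <- random_projective_tree(sample(2:12, 1L))
    g$tokens <- sprintf("t%02d", seq_len(g$n_tokens))
    g
  })
  path <- withr::local_tempfile(fileext = ".conllu")
  write_conllu(graphs, path, sent_ids = sprintf("s%d", 1:20))
  back <- read_conllu(path)
  expect_length(back, 20L)
  for (i in 1:20) {
    expect_equal(back[[i]]$heads, graphs[[i]]$heads)
    expect_equal(back[[i]]$deprels, graphs[[i]]$deprels)
    expect_equal(back[[i]]$tokens, graphs[[i]]$tokens)
    expect_equal(attr(back[[i]], "sent_id"), sprintf("s%d", i))
  }
})

test_that("CoNLL-U reader skips multiword ranges and flags bad heads", {
  path <- withr::local_tempfile(fileext = ".conllu")
  writeLines(c("# sent_id = x",
               paste("1-2", "ab", "_", "_", "_", "_", "_", "_", "_", "_",
                     sep = "\t"),
               paste("1", "a", "_", "_", "_", "_", "2", "dep", "_", "_",
                     sep = "\t"),
               paste("2", "b", "_", "_", "_", "_", "0", "root", "_", "_",
                     sep = "\t"), ""), path)
  g <- read_conllu(path)
  expect_length(g, 1L)
  expect_equal(g[[1L]]$n_tokens, 2L)

  writeLines(c(paste("1", "a", "_", "_", "_", "_", "5", "dep", "_", "_",
                     sep = "\t"),
               paste("2", "b", "_", "_", "_", "_", "0", "root", "_", "_",
                     sep = "\t"), ""), path)
  expect_error(read_conllu(path), "out of range")
})

test_that("word2vec text files load, validate dimension, and round-trip", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2 3", "alpha 0.1 0.2 0.3", "beta -1 0 1"), path)
  tab <- load_word2vec_text(path, 3L)
  expect_equal(length(tab$vocabulary), 2L)
  expect_equal(tab$dimension, 3L)
  expect_equal(embedding_lookup(tab, "beta"), c(-1, 0, 1))
  expect_null(embedding_lookup(tab, "gamma"))
  expect_error(load_word2vec_text(path, 100L), "does not match expected_dim")

  out <- withr::local_tempfile(fileext = ".txt")
  write_word2vec_text(tab, out)
  back <- load_word2vec_text(out, 3L)
  expect_equal(embedding_lookup(back, "alpha"), c(0.1, 0.2, 0.3))
  # headerless variant
  writeLines("solo 1 2 3", path)
  tab2 <- load_word2vec_text(path, 3L)
  expect_equal(embedding_lookup(tab2, "solo"), c(1, 2, 3))
})
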
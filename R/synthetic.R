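# Synthetic clinical-style corpora. Sentences are templated token strings
# with typed entity mentions and random projective dependency trees; relation
# labels follow the task's class imbalance. A class-specific trigger token can
# be planted ON the dependency path between the two targets (so path features
# are informative) together with an off-path distractor trigger of another
# class (so bag-of-words features alone are ambiguous).

DEPREL_SET <- c("nsubj", "obj", "obl", "nmod", "amod", "advmod", "case",
                "det", "conj", "cc", "dep")

#' Default class proportions of the relation task
#'
#' Instance proportions mirroring the published corpus statistics of the 2010
#' i2b2/VA relation subset (29,282 candidate pairs, 19,870 of them unrelated).
#'
#' @return Named numeric vector over [relation_labels()] summing to 1.
#' @export
i2b2_class_proportions <- function() {
  counts <- c(TeCP = 504, TeRP = 3052, PIP = 2203, TrCP = 526, TrAP = 2617,
              TrWP = 133, TrNAP = 174, TrIP = 203, None = 19870)
  counts / sum(counts)
}

#' Configuration of the synthetic-corpus generator
#'
#' @param n_documents Number of documents.
#' @param sentences_per_doc Sentences per document.
#' @param vocab_size Size of the filler-token vocabulary (`w0001` ...).
#' @param entity_density Mean mentions per sentence (truncated to 1..5).
#' @param class_proportions Named probability vector over [relation_labels()];
#'   defaults to the published corpus imbalance ([i2b2_class_proportions()]).
#'   Labels are sampled per candidate pair from this vector restricted to the
#'   pair's admissible label set and renormalized.
#' @param sdp_signal_strength Probability in \[0, 1\] that the class trigger
#'   token of a labeled pair is planted ON the dependency path between the
#'   targets (otherwise it is placed off-path); an off-path distractor trigger
#'   of a different class is always added, so only path membership
#'   disambiguates the label.
#' @param multi_token_prob Probability that a mention spans two tokens.
#' @param seed Integer seed; all generation is deterministic given the seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_documents = 20, sentences_per_doc = 10,
                         vocab_size = 200, entity_density = 2,
                         class_proportions = i2b2_class_proportions(),
                         sdp_signal_strength = 1, multi_token_prob = 0.3,
                         seed = 1L) {
  stopifnot(n_documents >= 1, sentences_per_doc >= 1, vocab_size >= 10,
            entity_density > 0, multi_token_prob >= 0, multi_token_prob <= 1)
  if (sdp_signal_strength < 0 || sdp_signal_strength > 1) {
    stop("sdp_signal_strength must be in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(class_proportions), RELATION_LABELS)) {
    stop("class_proportions must name all nine relation labels", call. = FALSE)
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 vocab_size = as.integer(vocab_size),
                 entity_density = entity_density,
                 class_proportions = class_proportions[RELATION_LABELS],
                 sdp_signal_strength = sdp_signal_strength,
                 multi_token_prob = multi_token_prob,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Random projective dependency tree
#'
#' Recursive-split construction: a head is drawn for the span, the tokens on
#' each side are cut into contiguous blocks, and each block becomes a subtree
#' attached to the head. The result is always a single-rooted, acyclic,
#' projective tree.
#'
#' @param n Number of tokens.
#' @param split_prob Probability of cutting between adjacent tokens when
#'   forming sibling blocks.
#' @return A [dep_graph] with random relation labels.
#' @export
random_projective_tree <- function(n, split_prob = 0.5) {
  heads <- integer(n)
  build <- function(lo, hi) {
    r <- if (lo == hi) lo else sample(seq(lo, hi), 1L)
    for (side in list(c(lo, r - 1L), c(r + 1L, hi))) {
      a <- side[1L]; b <- side[2L]
      if (a > b) next
      # cut [a, b] into contiguous blocks
      cuts <- if (b > a) which(stats::runif(b - a) < split_prob) else integer(0)
      starts <- c(a, a + cuts)
      ends <- c(a + cuts - 1L, b)
      for (k in seq_along(starts)) {
        child <- build(starts[k], ends[k])
        heads[child] <<- r
      }
    }
    r
  }
  root <- build(1L, n)
  heads[root] <- 0L
  rels <- sample(DEPREL_SET, n, replace = TRUE)
  rels[root] <- "root"
  dep_graph(heads, rels)
}

trigger_token <- function(label) paste0("xtrig", tolower(label))

# sample one sentence: tokens, mentions, tree
synth_sentence <- function(doc_id, line, config) {
  m <- max(1L, min(5L, stats::rpois(1L, config$entity_density)))
  types <- sample(ENTITY_TYPES, m, replace = TRUE, prob = c(0.45, 0.35, 0.2))
  span_len <- 1L + stats::rbinom(m, 1L, config$multi_token_prob)
  # filler count grows with mention count so dependency paths have room for
  # on-path trigger tokens even in mention-dense sentences
  n_fillers <- sample(6:14, 1L) + 2L * m
  slots <- sample(c(rep.int(0L, n_fillers), seq_len(m)))
  tokens <- character(0)
  starts <- integer(m); ends <- integer(m)
  for (s in slots) {
    if (s == 0L) {
      tokens <- c(tokens, sprintf("w%04d", sample.int(config$vocab_size, 1L)))
    } else {
      starts[s] <- length(tokens) + 1L
      tokens <- c(tokens, sprintf("w%04d",
                                  sample.int(config$vocab_size, span_len[s])))
      ends[s] <- length(tokens)
    }
  }
  tree <- random_projective_tree(length(tokens))
  mentions <- data.frame(
    id = mention_id(line, starts, ends),
    token_start = starts, token_end = ends, entity_type = types,
    surface = vapply(seq_len(m), function(i)
      paste(tokens[seq(starts[i], ends[i])], collapse = " "), character(1)),
    stringsAsFactors = FALSE)
  mentions <- mentions[order(mentions$token_start), , drop = FALSE]
  list(tokens = tokens, mentions = mentions, tree = tree)
}

#' Generate a synthetic annotated corpus
#'
#' Produces documents of templated sentences with typed entity mentions,
#' random projective dependency trees, and relation labels drawn from the
#' configured class proportions (restricted per pair to the schema's
#' admissible set). For every labeled pair a class trigger token is planted on
#' the dependency path between the targets with probability
#' `sdp_signal_strength` (off-path otherwise), and an off-path distractor
#' trigger of a different class is added when a free token is available.
#'
#' @param config A [synth_config].
#' @param schema A `pair_schema`.
#' @return List with `sentences` (list of [annotated_sentence]) and `graphs`
#'   (parallel list of [dep_graph]).
#' @export
generate_corpus <- function(config, schema = pair_schema_i2b2()) {
  set.seed(config$seed)
  sentences <- list()
  graphs <- list()
  positive <- setdiff(RELATION_LABELS, "None")
  for (d in seq_len(config$n_documents)) {
    doc_id <- sprintf("doc%04d", d)
    for (ln in seq_len(config$sentences_per_doc)) {
      syn <- synth_sentence(doc_id, ln, config)
      sent <- annotated_sentence(doc_id, ln, syn$tokens,
                                 mentions = syn$mentions)
      cand <- generate_candidates(sent, schema)
      rel <- empty_relations()
      if (nrow(cand) > 0L) {
        men <- sent$mentions
        # sample gold labels and on/off-path placement coins up front
        labels <- character(nrow(cand))
        for (ci in seq_len(nrow(cand))) {
          t1 <- men$entity_type[men$id == cand$m1[ci]]
          t2 <- men$entity_type[men$id == cand$m2[ci]]
          adm <- admissible_labels(schema, t1, t2)
          pr <- config$class_proportions[adm]
          labels[ci] <- sample(adm, 1L, prob = pr / sum(pr))
        }
        pos_ci <- which(labels != "None")
        on_path <- stats::runif(length(pos_ci)) < config$sdp_signal_strength
        if (length(pos_ci) > 0L) {
          rel <- data.frame(m1 = cand$m1[pos_ci], m2 = cand$m2[pos_ci],
                            label = labels[pos_ci], stringsAsFactors = FALSE)
          # redraw the tree until every on-path trigger has a free interior
          # slot on its pair's dependency path
          plan <- NULL
          for (attempt in seq_len(200L)) {
            plan <- plan_triggers(sent, syn$tree, cand[pos_ci, , drop = FALSE],
                                  labels[pos_ci], on_path, positive)
            if (!is.null(plan)) break
            syn$tree <- random_projective_tree(length(syn$tokens))
          }
          if (is.null(plan)) {
            # fall back to best effort with the last tree drawn
            plan <- plan_triggers(sent, syn$tree, cand[pos_ci, , drop = FALSE],
                                  labels[pos_ci], on_path, positive,
                                  strict = FALSE)
          }
          syn$tokens[plan$position] <- plan$token
        }
        # refresh mention surfaces (triggers never land inside spans)
        sent <- annotated_sentence(doc_id, ln, syn$tokens,
                                   mentions = syn$mentions, relations = rel)
      }
      sentences[[length(sentences) + 1L]] <- sent
      syn$tree$tokens <- syn$tokens
      graphs[[length(graphs) + 1L]] <- syn$tree
    }
  }
  list(sentences = sentences, graphs = graphs)
}

# sample() guard: sample(10L, 1) would draw from 1:10
resample <- function(x, size) x[sample.int(length(x), size)]

# Decide where each labeled pair's class trigger (and its off-path distractor
# of another class) goes under the given tree. Returns a data.frame of token
# positions and replacement tokens, or NULL when `strict` and some on-path
# trigger has no free interior slot on its pair's path.
plan_triggers <- function(sent, tree, pairs, labels, on_path, positive,
                          strict = TRUE) {
  n <- length(sent$tokens)
  men <- sent$mentions
  in_span <- rep(FALSE, n)
  for (i in seq_len(nrow(men))) {
    in_span[seq(men$token_start[i], men$token_end[i])] <- TRUE
  }
  used <- rep(FALSE, n)
  position <- integer(0)
  token <- character(0)
  # the classifier-visible path of every pair (independent of trigger text)
  path_of <- vector("list", nrow(pairs))
  interior_of <- vector("list", nrow(pairs))
  for (ci in seq_len(nrow(pairs))) {
    mk <- mask_entities(sent, c(pairs$m1[ci], pairs$m2[ci]))
    cg <- collapse_dep_graph(tree, mk)
    p <- shortest_dependency_path(cg, mk$e1_index, mk$e2_index)
    path_of[[ci]] <- integer(0)
    interior_of[[ci]] <- integer(0)
    if (isTRUE(p$has_path)) {
      path_of[[ci]] <- which(mk$index_map %in% p$nodes)
      if (length(p$nodes) > 2L) {
        interior <- setdiff(p$nodes[-c(1L, length(p$nodes))],
                            mk$spans$new_index)
        interior_of[[ci]] <- which(mk$index_map %in% interior & !in_span)
      }
    }
  }
  # a token of class L may sit on pair ci's path only if labels[ci] == L;
  # placements respect this so path membership stays a clean class signal
  paths_with_other_label <- function(label) {
    sel <- which(labels != label)
    unique(unlist(path_of[sel], use.names = FALSE))
  }
  all_paths <- unique(unlist(path_of, use.names = FALSE))
  # pass 1: the class triggers themselves
  for (ci in seq_len(nrow(pairs))) {
    if (on_path[ci]) {
      # prefer interior slots not shared with a differently-labeled pair's
      # path, but own-path placement always takes precedence
      avail <- interior_of[[ci]][!used[interior_of[[ci]]]]
      clean <- setdiff(avail, paths_with_other_label(labels[ci]))
      ok <- if (length(clean) > 0L) clean else avail
      if (length(ok) == 0L) {
        if (strict) return(NULL)
        ok <- which(!in_span & !used & !(seq_len(n) %in% all_paths))
      }
    } else {
      # off-path triggers stay off every labeled pair's path
      ok <- which(!in_span & !used & !(seq_len(n) %in% all_paths))
      if (length(ok) == 0L && strict) return(NULL)
    }
    if (length(ok) == 0L) next
    pos_t <- resample(ok, 1L)
    position <- c(position, pos_t)
    token <- c(token, trigger_token(labels[ci]))
    used[pos_t] <- TRUE
  }
  # pass 2: off-path distractors of other classes
  for (ci in seq_len(nrow(pairs))) {
    free <- which(!in_span & !used & !(seq_len(n) %in% path_of[[ci]]))
    if (length(free) == 0L) next
    dpos <- resample(free, 1L)
    # the distractor class may not match the label of any pair whose path
    # contains the chosen position (nor this pair's own label)
    touching <- labels[vapply(path_of, function(p) dpos %in% p, logical(1))]
    cls <- setdiff(positive, c(labels[ci], touching))
    if (length(cls) == 0L) next
    position <- c(position, dpos)
    token <- c(token, trigger_token(resample(cls, 1L)))
    used[dpos] <- TRUE
  }
  data.frame(position = position, token = token, stringsAsFactors = FALSE)
}

#' The worked-example sentence and its parse
#'
#' Builds the sentence "She was maintained on an epidural and pca for pain
#' control" with its three typed mentions (two treatments and a problem), an
#' illustrative TrAP relation between "an epidural" and "pain control", and a
#' dependency tree in which "maintained" heads both "epidural" and "control"
#' via `nmod`. After masking, the relative distances of "She" to the two
#' targets are -4 and -8, and the shortest dependency path between them is
#' tar_treatment -nmod-> maintained -nmod-> tar_problem.
#'
#' @return List with `sentence` (an [annotated_sentence]) and `graph` (a
#'   [dep_graph]).
#' @export
example_clinical_sentence <- function() {
  tokens <- c("She", "was", "maintained", "on", "an", "epidural", "and",
              "pca", "for", "pain", "control")
  mentions <- data.frame(
    id = mention_id(1L, c(5L, 8L, 10L), c(6L, 8L, 11L)),
    token_start = c(5L, 8L, 10L), token_end = c(6L, 8L, 11L),
    entity_type = c("treatment", "treatment", "problem"),
    surface = c("an epidural", "pca", "pain control"),
    stringsAsFactors = FALSE)
  relations <- data.frame(m1 = mentions$id[1L], m2 = mentions$id[3L],
                          label = "TrAP", stringsAsFactors = FALSE)
  sentence <- annotated_sentence("example01", 1L, tokens,
                                 mentions = mentions, relations = relations)
  heads <- c(3L, 3L, 0L, 6L, 6L, 3L, 8L, 6L, 11L, 11L, 3L)
  deprels <- c("nsubj", "aux", "root", "case", "det", "nmod", "cc", "conj",
               "case", "compound", "nmod")
  graph <- dep_graph(heads, deprels, tokens = tokens)
  list(sentence = sentence, graph = graph)
}

#' Write a golden fixture suite to disk
#'
#' Emits a small fixed-seed synthetic corpus in the i2b2-style dialect
#' (`text/`, `concepts/`, `relations/` directories), the matching dependency
#' parses as `parses.conllu`, and a toy word2vec text embedding file covering
#' the masked-token vocabulary. The corpus always includes the worked-example
#' document from [example_clinical_sentence()]. Output is byte-identical for
#' a given configuration.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [synth_config]; the default is a small fixture-sized corpus.
#' @param embedding_dim Dimension of the toy embeddings.
#' @return Invisibly, a list of the paths written.
#' @export
write_fixture_suite <- function(out_dir,
                                config = synth_config(n_documents = 3,
                                                      sentences_per_doc = 4,
                                                      seed = 42L),
                                embedding_dim = 10L) {
  corpus <- generate_corpus(config)
  ex <- example_clinical_sentence()
  sentences <- c(corpus$sentences, list(ex$sentence))
  graphs <- c(corpus$graphs, list(ex$graph))

  text_dir <- file.path(out_dir, "text")
  concept_dir <- file.path(out_dir, "concepts")
  relation_dir <- file.path(out_dir, "relations")
  write_i2b2_corpus(sentences, text_dir, concept_dir, relation_dir)
  sent_ids <- vapply(sentences, function(s)
    sprintf("%s:%d", s$doc_id, s$sentence_index), character(1))
  conllu_path <- file.path(out_dir, "parses.conllu")
  write_conllu(graphs, conllu_path, sent_ids = sent_ids)

  # toy embeddings over the masked vocabulary (placeholders included)
  vocab <- sort(unique(c(unlist(lapply(sentences, `[[`, "tokens")),
                         paste0("tar_", ENTITY_TYPES),
                         paste0("ent_", ENTITY_TYPES))))
  set.seed(config$seed + 1L)
  vecs <- matrix(round(stats::runif(length(vocab) * embedding_dim,
                                    -0.5, 0.5), 6),
                 nrow = length(vocab))
  table <- structure(list(vocabulary = stats::setNames(seq_along(vocab),
                                                       vocab),
                          vectors = vecs,
                          dimension = as.integer(embedding_dim),
                          oov_policy = "random_init"),
                     class = "embedding_table")
  emb_path <- file.path(out_dir, "embeddings.txt")
  write_word2vec_text(table, emb_path)
  invisible(list(text = text_dir, concepts = concept_dir,
                 relations = relation_dir, conllu = conllu_path,
                 embeddings = emb_path))
}
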
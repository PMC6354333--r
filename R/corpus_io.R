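#' Annotated sentence
#'
#' One sentence of a relation-annotated clinical corpus: its whitespace
#' tokens, typed entity mentions (token-level, 1-based inclusive spans) and
#' intra-sentence gold relations between mention pairs.
#'
#' @param doc_id Document identifier.
#' @param sentence_index 1-based line number of the sentence in its document.
#' @param tokens Character vector of tokens.
#' @param mentions data.frame with columns `id`, `token_start`, `token_end`,
#'   `entity_type`, `surface`. Entity types must be one of `problem`,
#'   `treatment`, `test`.
#' @param relations data.frame with columns `m1`, `m2` (mention ids) and
#'   `label` (a [relation_labels()] value other than `"None"`).
#'
#' @return An object of class `annotated_sentence`.
#' @export
annotated_sentence <- function(doc_id, sentence_index, tokens,
                               mentions = empty_mentions(),
                               relations = empty_relations()) {
  n <- length(tokens)
  if (nrow(mentions) > 0L) {
    if (any(mentions$token_start > mentions$token_end)) {
      stop("mention with token_start > token_end", call. = FALSE)
    }
    if (any(mentions$token_start < 1L) || any(mentions$token_end > n)) {
      stop("mention span outside sentence", call. = FALSE)
    }
    bad <- setdiff(mentions$entity_type, ENTITY_TYPES)
    if (length(bad) > 0L) {
      stop(sprintf("unknown entity type: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    if (anyDuplicated(mentions$id)) {
      stop("duplicate mention ids in sentence", call. = FALSE)
    }
  }
  if (nrow(relations) > 0L) {
    missing <- setdiff(c(relations$m1, relations$m2), mentions$id)
    if (length(missing) > 0L) {
      stop(sprintf("relation references unknown mention: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    assert_label(relations$label)
  }
  structure(list(doc_id = doc_id,
                 sentence_index = as.integer(sentence_index),
                 tokens = as.character(tokens),
                 mentions = mentions, relations = relations),
            class = "annotated_sentence")
}

empty_mentions <- function() {
  data.frame(id = character(0), token_start = integer(0),
             token_end = integer(0), entity_type = character(0),
             surface = character(0), stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(m1 = character(0), m2 = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat(sprintf("<sentence %s:%d, %d tokens, %d mentions, %d relations>\n",
              x$doc_id, x$sentence_index, length(x$tokens),
              nrow(x$mentions), nrow(x$relations)))
  invisible(x)
}

# --- i2b2-2010-style annotation dialect ------------------------------------
#
# Per document: <doc>.txt (one pre-tokenized sentence per line), <doc>.con
# (concept lines) and <doc>.rel (relation lines).
#
#   c="pain control" 3:9 3:10||t="problem"
#   c="an epidural" 3:5 3:6||r="TrAP"||c="pain control" 3:9 3:10
#
# Line and token coordinates are 1-based and token-level; spans are inclusive.

I2B2_SPAN_RE <- '^c="(.*)" (\\d+):(\\d+) (\\d+):(\\d+)$'

parse_i2b2_span <- function(part, file, lineno) {
  m <- regmatches(part, regexec(I2B2_SPAN_RE, part))[[1L]]
  if (length(m) == 0L) {
    stop(sprintf("%s:%d: malformed concept span: %s", file, lineno, part),
         call. = FALSE)
  }
  list(surface = m[2L], line = as.integer(m[3L]), start = as.integer(m[4L]),
       end_line = as.integer(m[5L]), end = as.integer(m[6L]))
}

#' Read an i2b2-2010-style corpus
#'
#' Reads per-document plain text (one pre-tokenized sentence per line),
#' concept annotation files (`<doc>.con`) and relation annotation files
#' (`<doc>.rel`) into [annotated_sentence] objects. Only sentences containing
#' at least one mention are returned. The dialect's 1-based line:token
#' coordinates map directly onto the internal 1-based inclusive token spans.
#' Relation lines whose two concepts lie in different sentences are dropped
#' with a warning (the classifier is intra-sentence by construction).
#'
#' @param text_dir Directory of `<doc>.txt` files.
#' @param concept_dir Directory of `<doc>.con` files.
#' @param relation_dir Directory of `<doc>.rel` files; a missing `.rel` file
#'   is treated as a document with no relations.
#' @return List of `annotated_sentence` objects, ordered by document and line.
#' @export
read_i2b2_corpus <- function(text_dir, concept_dir, relation_dir) {
  txt_files <- sort(list.files(text_dir, pattern = "\\.txt$",
                               full.names = TRUE))
  if (length(txt_files) == 0L) {
    stop(sprintf("no .txt files in %s", text_dir), call. = FALSE)
  }
  out <- list()
  for (tf in txt_files) {
    doc <- sub("\\.txt$", "", basename(tf))
    lines <- readLines(tf, warn = FALSE)
    toks <- strsplit(lines, "[ \t]+")
    toks <- lapply(toks, function(x) x[nzchar(x)])

    cf <- file.path(concept_dir, paste0(doc, ".con"))
    mentions_by_line <- read_i2b2_concepts(cf, toks)
    rf <- file.path(relation_dir, paste0(doc, ".rel"))
    relations_by_line <- read_i2b2_relations(rf, mentions_by_line, doc)

    for (ln in seq_along(lines)) {
      men <- mentions_by_line[[ln]]
      if (is.null(men) || nrow(men) == 0L) next
      rel <- relations_by_line[[ln]] %||% empty_relations()
      out[[length(out) + 1L]] <- annotated_sentence(
        doc_id = doc, sentence_index = ln, tokens = toks[[ln]],
        mentions = men, relations = rel)
    }
  }
  out
}

mention_id <- function(line, start, end) sprintf("%d:%d-%d", line, start, end)

read_i2b2_concepts <- function(path, toks) {
  by_line <- vector("list", length(toks))
  if (!file.exists(path)) return(by_line)
  lines <- readLines(path, warn = FALSE)
  for (k in seq_along(lines)) {
    raw <- trimws(lines[k])
    if (!nzchar(raw)) next
    parts <- strsplit(raw, "||", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !grepl('^t="', parts[2L])) {
      stop(sprintf("%s:%d: malformed concept line: %s", path, k, raw),
           call. = FALSE)
    }
    sp <- parse_i2b2_span(parts[1L], path, k)
    type <- sub('^t="(.*)"$', "\\1", parts[2L])
    if (sp$line != sp$end_line) {
      stop(sprintf("%s:%d: concept spans multiple lines", path, k),
           call. = FALSE)
    }
    if (sp$line < 1L || sp$line > length(toks) ||
        sp$start < 1L || sp$end > length(toks[[sp$line]]) ||
        sp$start > sp$end) {
      stop(sprintf("%s:%d: concept coordinates out of range", path, k),
           call. = FALSE)
    }
    men <- data.frame(id = mention_id(sp$line, sp$start, sp$end),
                      token_start = sp$start, token_end = sp$end,
                      entity_type = type, surface = sp$surface,
                      stringsAsFactors = FALSE)
    prev <- by_line[[sp$line]]
    if (!is.null(prev) && men$id %in% prev$id) next  # duplicate concept line
    by_line[[sp$line]] <- rbind(prev, men)
  }
  by_line
}

read_i2b2_relations <- function(path, mentions_by_line, doc) {
  by_line <- vector("list", length(mentions_by_line))
  if (!file.exists(path)) return(by_line)
  lines <- readLines(path, warn = FALSE)
  for (k in seq_along(lines)) {
    raw <- trimws(lines[k])
    if (!nzchar(raw)) next
    parts <- strsplit(raw, "||", fixed = TRUE)[[1L]]
    if (length(parts) != 3L || !grepl('^r="', parts[2L])) {
      stop(sprintf("%s:%d: malformed relation line: %s", path, k, raw),
           call. = FALSE)
    }
    s1 <- parse_i2b2_span(parts[1L], path, k)
    s2 <- parse_i2b2_span(parts[3L], path, k)
    label <- sub('^r="(.*)"$', "\\1", parts[2L])
    assert_label(label, "relation label")
    if (s1$line != s2$line) {
      warning(sprintf("%s:%d: cross-sentence relation dropped", path, k),
              call. = FALSE)
      next
    }
    id1 <- mention_id(s1$line, s1$start, s1$end)
    id2 <- mention_id(s2$line, s2$start, s2$end)
    men <- mentions_by_line[[s1$line]]
    if (is.null(men) || !all(c(id1, id2) %in% men$id)) {
      stop(sprintf("%s:%d: relation references unknown concept span", path, k),
           call. = FALSE)
    }
    by_line[[s1$line]] <- rbind(
      by_line[[s1$line]],
      data.frame(m1 = id1, m2 = id2, label = label, stringsAsFactors = FALSE))
  }
  by_line
}

#' Write a corpus in the i2b2-2010-style dialect
#'
#' Inverse of [read_i2b2_corpus()]: writes one `.txt`, `.con` and `.rel` file
#' per document. Sentences of one document must carry distinct
#' `sentence_index` values; missing line numbers are written as empty lines so
#' coordinates round-trip.
#'
#' @param sentences List of [annotated_sentence] objects.
#' @param text_dir,concept_dir,relation_dir Output directories (created if
#'   needed).
#' @return Invisibly, the vector of document ids written.
#' @export
write_i2b2_corpus <- function(sentences, text_dir, concept_dir, relation_dir) {
  for (d in unique(c(text_dir, concept_dir, relation_dir))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  docs <- unique(vapply(sentences, function(s) s$doc_id, character(1)))
  for (doc in docs) {
    sel <- Filter(function(s) s$doc_id == doc, sentences)
    idx <- vapply(sel, function(s) s$sentence_index, integer(1))
    n_lines <- max(idx)
    txt <- rep("", n_lines)
    con <- character(0)
    rel <- character(0)
    for (s in sel) {
      ln <- s$sentence_index
      txt[ln] <- paste(s$tokens, collapse = " ")
      if (nrow(s$mentions) > 0L) {
        con <- c(con, sprintf('c="%s" %d:%d %d:%d||t="%s"',
                              s$mentions$surface, ln, s$mentions$token_start,
                              ln, s$mentions$token_end,
                              s$mentions$entity_type))
      }
      if (nrow(s$relations) > 0L) {
        for (r in seq_len(nrow(s$relations))) {
          m1 <- s$mentions[s$mentions$id == s$relations$m1[r], ]
          m2 <- s$mentions[s$mentions$id == s$relations$m2[r], ]
          rel <- c(rel, sprintf('c="%s" %d:%d %d:%d||r="%s"||c="%s" %d:%d %d:%d',
                                m1$surface, ln, m1$token_start, ln,
                                m1$token_end, s$relations$label[r],
                                m2$surface, ln, m2$token_start, ln,
                                m2$token_end))
        }
      }
    }
    writeLines(txt, file.path(text_dir, paste0(doc, ".txt")))
    writeLines(con, file.path(concept_dir, paste0(doc, ".con")))
    writeLines(rel, file.path(relation_dir, paste0(doc, ".rel")))
  }
  invisible(docs)
}

# --- CoNLL-U ----------------------------------------------------------------

#' Read CoNLL-U dependency parses
#'
#' Parses a CoNLL-U file into one [dep_graph] per sentence block. Comment
#' lines are honored for `# sent_id`; multiword-token ranges (`1-2`) and
#' empty nodes (`1.1`) are skipped.
#'
#' @param path CoNLL-U file.
#' @return List of `dep_graph` objects; each carries a `sent_id` attribute
#'   when the block declares one.
#' @export
read_conllu <- function(path) {
  lines <- readLines(path, warn = FALSE)
  graphs <- list()
  block <- list(forms = character(0), heads = integer(0),
                deprels = character(0), sent_id = NULL)
  flush <- function(block) {
    if (length(block$forms) == 0L) return(NULL)
    g <- dep_graph(block$heads, block$deprels, tokens = block$forms)
    attr(g, "sent_id") <- block$sent_id
    g
  }
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(trimws(ln))) {
      g <- flush(block)
      if (!is.null(g)) graphs[[length(graphs) + 1L]] <- g
      block <- list(forms = character(0), heads = integer(0),
                    deprels = character(0), sent_id = NULL)
      next
    }
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*sent_id\\s*=\\s*(.+)$", ln))[[1L]]
      if (length(m) > 0L) block$sent_id <- trimws(m[2L])
      next
    }
    cols <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(cols) != 10L) {
      stop(sprintf("%s:%d: expected 10 tab-separated columns", path, k),
           call. = FALSE)
    }
    if (grepl("[-.]", cols[1L])) next  # multiword token or empty node
    id <- as.integer(cols[1L])
    if (is.na(id) || id != length(block$forms) + 1L) {
      stop(sprintf("%s:%d: non-consecutive token id '%s'", path, k, cols[1L]),
           call. = FALSE)
    }
    head <- suppressWarnings(as.integer(cols[7L]))
    if (is.na(head)) {
      stop(sprintf("%s:%d: bad HEAD field '%s'", path, k, cols[7L]),
           call. = FALSE)
    }
    block$forms <- c(block$forms, cols[2L])
    block$heads <- c(block$heads, head)
    block$deprels <- c(block$deprels, cols[8L])
  }
  g <- flush(block)
  if (!is.null(g)) graphs[[length(graphs) + 1L]] <- g
  graphs
}

#' Write dependency graphs in CoNLL-U format
#'
#' @param graphs List of [dep_graph] objects with token forms.
#' @param path Output file.
#' @param sent_ids Optional character vector of sentence ids, written as
#'   `# sent_id` comments.
#' @return Invisibly, `path`.
#' @export
write_conllu <- function(graphs, path, sent_ids = NULL) {
  out <- character(0)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    sid <- if (!is.null(sent_ids)) sent_ids[i] else attr(g, "sent_id")
    if (!is.null(sid) && !is.na(sid)) out <- c(out, paste0("# sent_id = ", sid))
    forms <- g$tokens %||% paste0("tok", seq_len(g$n_tokens))
    for (t in seq_len(g$n_tokens)) {
      out <- c(out, paste(t, forms[t], "_", "_", "_", "_",
                          g$heads[t], g$deprels[t], "_", "_", sep = "\t"))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

# --- word2vec text embeddings ----------------------------------------------

#' Load word embeddings in word2vec text format
#'
#' Reads the plain-text word2vec format: an optional header line `"V D"`
#' followed by one `token v1 ... vD` row per word.
#'
#' @param path Embedding file.
#' @param expected_dim Required vector dimension; a mismatch is an error.
#' @param oov_policy How tokens absent from the file are materialized later:
#'   `"random_init"` (uniform in \[-0.25, 0.25\], seeded) or `"zero"`.
#' @return An `embedding_table`: list with `vocabulary` (token to row index),
#'   `vectors` (V x D matrix), `dimension`, `oov_policy`.
#' @export
load_word2vec_text <- function(path, expected_dim,
                               oov_policy = c("random_init", "zero")) {
  oov_policy <- match.arg(oov_policy)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty embedding file", call. = FALSE)
  first <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  has_header <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.numeric(first)))
  rows <- if (has_header) lines[-1L] else lines
  parts <- strsplit(trimws(rows), "[ \t]+")
  tokens <- vapply(parts, `[[`, character(1), 1L)
  dims <- lengths(parts) - 1L
  if (any(dims != expected_dim)) {
    stop(sprintf("embedding dimension %d does not match expected_dim %d",
                 dims[which(dims != expected_dim)[1L]], expected_dim),
         call. = FALSE)
  }
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                   numeric(expected_dim)))
  if (anyNA(vecs)) stop("non-numeric embedding value", call. = FALSE)
  rownames(vecs) <- NULL
  structure(list(vocabulary = stats::setNames(seq_along(tokens), tokens),
                 vectors = vecs, dimension = as.integer(expected_dim),
                 oov_policy = oov_policy),
            class = "embedding_table")
}

#' Write word embeddings in word2vec text format
#'
#' @param table An `embedding_table` (see [load_word2vec_text()]).
#' @param path Output file.
#' @param digits Significant digits for the vector components.
#' @return Invisibly, `path`.
#' @export
write_word2vec_text <- function(table, path, digits = 8) {
  v <- table$vectors
  toks <- names(table$vocabulary)[order(table$vocabulary)]
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(toks[i], format(v[i, ], digits = digits, trim = TRUE,
                            scientific = FALSE)), collapse = " ")
  }, character(1))
  writeLines(c(paste(nrow(v), ncol(v)), rows), path)
  invisible(path)
}

#' Look up one embedding vector
#'
#' @param table An `embedding_table`.
#' @param token Token string.
#' @return Numeric vector of length `table$dimension`, or `NULL` if absent.
#' @export
embedding_lookup <- function(table, token) {
  i <- match(token, names(table$vocabulary))
  if (is.na(i)) return(NULL)
  table$vectors[table$vocabulary[[i]], ]
}
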
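#' Admissible relation labels per entity-type pair
#'
#' The i2b2-2010 task defines relations only between certain entity-type
#' pairs: test-problem (TeCP, TeRP), problem-problem (PIP) and
#' treatment-problem (TrCP, TrAP, TrWP, TrNAP, TrIP). Every admissible pair
#' may also be unrelated (`"None"`). Pairs of other types (e.g.
#' treatment-treatment) yield no candidate.
#'
#' @return A `pair_schema`: named list mapping a sorted `"type1|type2"` key to
#'   the admissible label vector.
#' @export
pair_schema_i2b2 <- function() {
  structure(list(
    "problem|test" = c("TeCP", "TeRP", "None"),
    "problem|problem" = c("PIP", "None"),
    "problem|treatment" = c("TrCP", "TrAP", "TrWP", "TrNAP", "TrIP", "None")
  ), class = "pair_schema")
}

schema_key <- function(t1, t2) paste(sort(c(t1, t2)), collapse = "|")

#' Admissible labels for an entity-type pair
#'
#' @param schema A `pair_schema`.
#' @param type1,type2 Entity types.
#' @return Character vector of admissible labels, or `NULL` if the type pair
#'   admits no relation.
#' @export
admissible_labels <- function(schema, type1, type2) {
  schema[[schema_key(type1, type2)]]
}

#' Generate candidate mention pairs for one sentence
#'
#' Every unordered pair of mentions whose entity types admit at least one
#' relation under the schema becomes one candidate, with the annotated gold
#' label attached when present and `"None"` otherwise. The (e1, e2) order
#' follows sentence order (by token position).
#'
#' @param sentence An [annotated_sentence].
#' @param schema A `pair_schema`, default [pair_schema_i2b2()].
#' @return data.frame with columns `m1`, `m2` (mention ids, sentence order)
#'   and `label`.
#' @export
generate_candidates <- function(sentence, schema = pair_schema_i2b2()) {
  men <- sentence$mentions
  if (nrow(men) < 2L) {
    return(data.frame(m1 = character(0), m2 = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  men <- men[order(men$token_start, men$token_end), , drop = FALSE]
  rel <- sentence$relations
  out <- list()
  for (i in seq_len(nrow(men) - 1L)) {
    for (j in seq((i + 1L), nrow(men))) {
      adm <- admissible_labels(schema, men$entity_type[i], men$entity_type[j])
      if (is.null(adm)) next
      label <- "None"
      if (nrow(rel) > 0L) {
        hit <- (rel$m1 == men$id[i] & rel$m2 == men$id[j]) |
          (rel$m1 == men$id[j] & rel$m2 == men$id[i])
        if (any(hit)) label <- rel$label[which(hit)[1L]]
      }
      out[[length(out) + 1L]] <- data.frame(
        m1 = men$id[i], m2 = men$id[j], label = label,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(m1 = character(0), m2 = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Mask entity mentions in a sentence
#'
#' Replaces every mention span with a single placeholder token carrying the
#' entity type: `tar_<type>` for the two target mentions of the candidate
#' pair, `ent_<type>` for all other mentions. Multi-token spans collapse to
#' one token. Overlapping mention spans are resolved in favor of the longer
#' span (with a warning), except that target mentions always survive.
#'
#' @param sentence An [annotated_sentence].
#' @param target_pair Character vector of the two target mention ids.
#' @return List with `tokens` (masked sequence), `e1_index`, `e2_index`
#'   (positions of the two `tar_` tokens, in `target_pair` order),
#'   `index_map` (old token index to new token index) and `spans`
#'   (data.frame of the collapsed spans with their new indices).
#' @export
mask_entities <- function(sentence, target_pair) {
  men <- sentence$mentions
  if (!all(target_pair %in% men$id)) {
    stop("target mention not in sentence", call. = FALSE)
  }
  if (target_pair[1L] == target_pair[2L]) {
    stop("target mentions must be distinct", call. = FALSE)
  }
  n <- length(sentence$tokens)
  men$is_target <- men$id %in% target_pair
  men$len <- men$token_end - men$token_start + 1L
  # targets first, then longer spans, so overlap resolution keeps targets
  men <- men[order(-men$is_target, -men$len, men$token_start), , drop = FALSE]
  occupied <- rep(FALSE, n)
  keep <- logical(nrow(men))
  for (i in seq_len(nrow(men))) {
    span <- seq(men$token_start[i], men$token_end[i])
    if (any(occupied[span])) {
      warning(sprintf("overlapping mention '%s' dropped during masking",
                      men$id[i]), call. = FALSE)
      next
    }
    occupied[span] <- TRUE
    keep[i] <- TRUE
  }
  men <- men[keep, , drop = FALSE]
  men <- men[order(men$token_start), , drop = FALSE]

  tokens <- character(0)
  index_map <- integer(n)
  new_start <- integer(nrow(men))
  k <- 1L
  m_i <- 1L
  while (k <= n) {
    if (m_i <= nrow(men) && k == men$token_start[m_i]) {
      prefix <- if (men$is_target[m_i]) "tar_" else "ent_"
      tokens <- c(tokens, paste0(prefix, men$entity_type[m_i]))
      new_idx <- length(tokens)
      index_map[seq(k, men$token_end[m_i])] <- new_idx
      new_start[m_i] <- new_idx
      k <- men$token_end[m_i] + 1L
      m_i <- m_i + 1L
    } else {
      tokens <- c(tokens, sentence$tokens[k])
      index_map[k] <- length(tokens)
      k <- k + 1L
    }
  }
  spans <- data.frame(id = men$id, token_start = men$token_start,
                      token_end = men$token_end, new_index = new_start,
                      is_target = men$is_target, stringsAsFactors = FALSE)
  e1 <- spans$new_index[spans$id == target_pair[1L]]
  e2 <- spans$new_index[spans$id == target_pair[2L]]
  if (length(e1) != 1L || length(e2) != 1L) {
    stop("target mentions overlap each other; pair cannot be masked",
         call. = FALSE)
  }
  list(tokens = tokens, e1_index = e1, e2_index = e2,
       index_map = index_map, spans = spans)
}

#' Relative-position features
#'
#' For every token of the masked sentence, the signed distance to each of the
#' two target-entity tokens: `pos1[i] = i - e1_index`, `pos2[i] = i -
#' e2_index`. Distances are stored unclipped; the model clips them to its
#' position-vocabulary range (an out-of-range bucket) at embedding lookup.
#'
#' @param n_tokens Length of the masked token sequence.
#' @param e1_index,e2_index Positions of the two target tokens.
#' @return List with integer vectors `pos1` and `pos2`.
#' @export
position_features <- function(n_tokens, e1_index, e2_index) {
  i <- seq_len(n_tokens)
  list(pos1 = i - as.integer(e1_index), pos2 = i - as.integer(e2_index))
}

# Re-index a dependency graph after masking: each collapsed mention is
# represented by the parse node of its last token; tokens whose head lies
# inside a collapsed span re-attach to the span's placeholder node.
collapse_dep_graph <- function(graph, mask_info) {
  index_map <- mask_info$index_map
  spans <- mask_info$spans
  n_new <- length(mask_info$tokens)
  old_heads <- graph$heads
  span_of <- rep(0L, graph$n_tokens)
  for (s in seq_len(nrow(spans))) {
    span_of[seq(spans$token_start[s], spans$token_end[s])] <- s
  }
  heads <- integer(n_new)
  deprels <- character(n_new)
  for (new_i in seq_len(n_new)) {
    s <- match(new_i, spans$new_index)
    if (!is.na(s)) {
      # representative old token = last token of the span; walk the head
      # chain upward until it leaves the span
      o <- spans$token_end[s]
      h <- old_heads[o]
      steps <- 0L
      while (h != 0L && span_of[h] == s && steps <= graph$n_tokens) {
        o <- h
        h <- old_heads[o]
        steps <- steps + 1L
      }
    } else {
      o <- which(index_map == new_i)[1L]
      h <- old_heads[o]
    }
    heads[new_i] <- if (h == 0L) 0L else index_map[h]
    deprels[new_i] <- graph$deprels[o]
    if (heads[new_i] == new_i) heads[new_i] <- 0L  # degenerate parse guard
  }
  suppressWarnings(dep_graph(heads, deprels, tokens = mask_info$tokens))
}

#' Build classifier-ready relation instances
#'
#' Runs the full preprocessing chain for every candidate pair of every
#' sentence: candidate generation under the schema, entity masking with
#' `tar_`/`ent_` placeholders, relative-position features, dependency-graph
#' re-indexing onto the masked token sequence, and shortest-dependency-path
#' extraction between the two target tokens.
#'
#' @param sentences List of [annotated_sentence] objects.
#' @param graphs Optional list of [dep_graph] objects parallel to
#'   `sentences` (pre-masking token indices). When `NULL`, instances carry no
#'   path and the model falls back to sentence-only features.
#' @param schema A `pair_schema`.
#' @param parser Optional callable `function(tokens) -> dep_graph` used to
#'   parse sentences on the fly when `graphs` is `NULL`.
#' @return List of `relation_instance` objects: `doc_id`, `sentence_index`,
#'   `masked_tokens`, `e1_index`, `e2_index`, `pos1`, `pos2`, `label`, and
#'   `sdp` (list with `nodes`, `words`, `relations`, `directions`) or `NULL`
#'   when no path exists.
#' @export
build_instances <- function(sentences, graphs = NULL,
                            schema = pair_schema_i2b2(), parser = NULL) {
  if (!is.null(graphs) && length(graphs) != length(sentences)) {
    stop("graphs must be parallel to sentences", call. = FALSE)
  }
  out <- list()
  for (si in seq_along(sentences)) {
    sent <- sentences[[si]]
    cand <- generate_candidates(sent, schema)
    if (nrow(cand) == 0L) next
    g <- if (!is.null(graphs)) graphs[[si]]
    else if (!is.null(parser)) parser(sent$tokens)
    else NULL
    if (!is.null(g) && g$n_tokens != length(sent$tokens)) {
      stop(sprintf("parse/sentence token count mismatch in %s:%d",
                   sent$doc_id, sent$sentence_index), call. = FALSE)
    }
    for (ci in seq_len(nrow(cand))) {
      mk <- mask_entities(sent, c(cand$m1[ci], cand$m2[ci]))
      pos <- position_features(length(mk$tokens), mk$e1_index, mk$e2_index)
      sdp <- NULL
      if (!is.null(g)) {
        cg <- collapse_dep_graph(g, mk)
        p <- shortest_dependency_path(cg, mk$e1_index, mk$e2_index)
        if (isTRUE(p$has_path)) {
          sdp <- list(nodes = p$nodes, words = mk$tokens[p$nodes],
                      relations = p$relations, directions = p$directions)
        }
      }
      out[[length(out) + 1L]] <- structure(
        list(doc_id = sent$doc_id, sentence_index = sent$sentence_index,
             masked_tokens = mk$tokens, e1_index = mk$e1_index,
             e2_index = mk$e2_index, pos1 = pos$pos1, pos2 = pos$pos2,
             label = cand$label[ci], sdp = sdp),
        class = "relation_instance")
    }
  }
  out
}

#' @export
print.relation_instance <- function(x, ...) {
  cat(sprintf("<instance %s:%d [%s] e1=%d e2=%d%s>\n", x$doc_id,
              x$sentence_index, x$label, x$e1_index, x$e2_index,
              if (is.null(x$sdp)) " no-path" else
                sprintf(" path=%d", length(x$sdp$nodes))))
  invisible(x)
}

INSTANCE_FORMAT <- "sdprel-instances"
INSTANCE_VERSION <- 1L

#' Write relation instances as JSON lines
#'
#' One JSON object per line, preceded by a versioned header line, so instance
#' sets can be staged between pipeline steps.
#'
#' @param instances List of `relation_instance` objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_instances <- function(instances, path) {
  hdr <- jsonlite::toJSON(list(format = INSTANCE_FORMAT,
                               version = INSTANCE_VERSION),
                          auto_unbox = TRUE)
  lines <- vapply(instances, function(x) {
    as.character(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, null = "null"))
  }, character(1))
  writeLines(c(as.character(hdr), lines), path)
  invisible(path)
}

#' Read relation instances from JSON lines
#'
#' @param path File written by [write_instances()].
#' @return List of `relation_instance` objects.
#' @export
read_instances <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty instance file", call. = FALSE)
  hdr <- jsonlite::fromJSON(lines[1L])
  if (!identical(hdr$format, INSTANCE_FORMAT)) {
    stop("not an sdprel instance file", call. = FALSE)
  }
  if (hdr$version > INSTANCE_VERSION) {
    stop(sprintf("instance file version %s is newer than supported",
                 hdr$version), call. = FALSE)
  }
  lapply(lines[-1L], function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    x$e1_index <- as.integer(x$e1_index)
    x$e2_index <- as.integer(x$e2_index)
    x$sentence_index <- as.integer(x$sentence_index)
    x$pos1 <- as.integer(x$pos1)
    x$pos2 <- as.integer(x$pos2)
    if (!is.null(x$sdp)) x$sdp$nodes <- as.integer(x$sdp$nodes)
    structure(x, class = "relation_instance")
  })
}
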
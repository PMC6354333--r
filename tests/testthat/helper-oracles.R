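# Independent oracles used across tests. These are deliberately brute-force
# and share no code with the implementation paths they check.

# all simple paths from a to b by depth-first enumeration over the undirected
# edge set; returns the minimal-length node sequences
exhaustive_shortest_paths <- function(graph, a, b) {
  n <- graph$n_tokens
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    h <- graph$edges$head[k]; d <- graph$edges$dep[k]
    adj[[h]] <- c(adj[[h]], d)
    adj[[d]] <- c(adj[[d]], h)
  }
  found <- list()
  dfs <- function(path) {
    cur <- path[length(path)]
    if (cur == b) {
      found[[length(found) + 1L]] <<- path
      return(invisible())
    }
    for (v in adj[[cur]]) {
      if (!(v %in% path)) dfs(c(path, v))
    }
  }
  dfs(a)
  if (length(found) == 0L) return(list())
  lens <- vapply(found, length, integer(1))
  found[lens == min(lens)]
}

# node depth (root = 0) and lowest common ancestor in a dependency tree
tree_depth <- function(graph, v) {
  d <- 0L
  while (graph$heads[v] != 0L) {
    v <- graph$heads[v]
    d <- d + 1L
  }
  d
}

tree_ancestors <- function(graph, v) {
  out <- v
  while (graph$heads[v] != 0L) {
    v <- graph$heads[v]
    out <- c(out, v)
  }
  out
}

tree_lca <- function(graph, a, b) {
  anc_a <- tree_ancestors(graph, a)
  anc_b <- tree_ancestors(graph, b)
  intersect(anc_a, anc_b)[1L]
}

# a small deterministic instance set whose label is determined by one
# sentence token, used for overfitting and determinism checks
separable_instances <- function(n_per_class = 5L,
                                classes = c("TeRP", "TrAP", "PIP", "None")) {
  out <- list()
  for (ci in seq_along(classes)) {
    for (r in seq_len(n_per_class)) {
      toks <- c("tar_problem", paste0("cue_", tolower(classes[ci])),
                sprintf("w%02d", r), "tar_test")
      pos <- position_features(length(toks), 1L, 4L)
      out[[length(out) + 1L]] <- structure(
        list(doc_id = sprintf("d%d", r), sentence_index = ci,
             masked_tokens = toks, e1_index = 1L, e2_index = 4L,
             pos1 = pos$pos1, pos2 = pos$pos2, label = classes[ci],
             sdp = list(nodes = c(1L, 2L, 4L),
                        words = toks[c(1L, 2L, 4L)],
                        relations = c("nsubj", "obj"),
                        directions = c("up", "down"))),
        class = "relation_instance")
    }
  }
  out
}

tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(word_dim = 6L, position_dim = 4L, deprel_dim = 3L, hidden = 5L,
         fc_dim = 8L, dropout = 0, max_dist = 10L),
    list(...))
  do.call(model_config, args)
}

instance_labels <- function(instances) {
  vapply(instances, `[[`, character(1), "label")
}
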
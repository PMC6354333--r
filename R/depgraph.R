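#' Dependency graph of one sentence
#'
#' A sentence's dependency parse as a set of labeled, directed
#' head-to-dependent edges over token indices. Token indices are 1-based.
#' A well-formed parse is a tree (every token except the root has exactly one
#' head), but the constructor only warns on zero or multiple roots so that
#' imperfect parses can still be carried through the pipeline.
#'
#' @param heads Integer vector: `heads[i]` is the head of token `i`, with 0
#'   marking the root.
#' @param deprels Character vector of dependency relation labels, parallel to
#'   `heads`.
#' @param tokens Optional character vector of token forms, parallel to
#'   `heads`; kept for round-tripping and debugging dumps.
#'
#' @return An object of class `dep_graph` with fields `n_tokens`, `edges`
#'   (data.frame with columns `head`, `dep`, `rel`), `root` (integer vector;
#'   length 1 for a well-formed tree) and `tokens`.
#' @export
dep_graph <- function(heads, deprels, tokens = NULL) {
  heads <- as.integer(heads)
  n <- length(heads)
  if (length(deprels) != n) {
    stop("heads and deprels must have the same length", call. = FALSE)
  }
  if (any(heads < 0L | heads > n)) {
    stop(sprintf("head index out of range: %s",
                 paste(heads[heads < 0L | heads > n], collapse = ", ")),
         call. = FALSE)
  }
  if (any(heads == seq_len(n))) {
    stop("self-loop: a token may not head itself", call. = FALSE)
  }
  root <- which(heads == 0L)
  if (length(root) != 1L) {
    warning(sprintf("expected exactly one root, found %d", length(root)),
            call. = FALSE)
  }
  dep <- which(heads != 0L)
  edges <- data.frame(head = heads[dep], dep = dep,
                      rel = as.character(deprels[dep]),
                      stringsAsFactors = FALSE)
  structure(list(n_tokens = n, edges = edges, root = root,
                 heads = heads, deprels = as.character(deprels),
                 tokens = tokens),
            class = "dep_graph")
}

#' @export
print.dep_graph <- function(x, ...) {
  cat(sprintf("<dep_graph: %d tokens, %d edges, root at %s>\n",
              x$n_tokens, nrow(x$edges), paste(x$root, collapse = ",")))
  invisible(x)
}

# adjacency list over the undirected view of the edge set
undirected_adjacency <- function(graph) {
  adj <- vector("list", graph$n_tokens)
  for (k in seq_len(nrow(graph$edges))) {
    h <- graph$edges$head[k]
    d <- graph$edges$dep[k]
    adj[[h]] <- c(adj[[h]], d)
    adj[[d]] <- c(adj[[d]], h)
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Shortest dependency path between two tokens
#'
#' Breadth-first search over the undirected view of the dependency edges,
#' returning a minimal-edge-count path from `a` to `b` together with the
#' original relation label and traversal direction of every step (`"up"` =
#' toward the head of the edge, `"down"` = toward the dependent). When several
#' shortest paths exist (possible only in non-tree graphs) the
#' lexicographically smallest node sequence is returned, so results are
#' reproducible.
#'
#' @param graph A [dep_graph].
#' @param a,b Distinct 1-based token indices.
#'
#' @return An object of class `sdp_path` with fields `nodes` (token indices,
#'   `a` first, `b` last), `relations` and `directions` (both one element per
#'   step). If `b` is unreachable from `a` the object has `has_path = FALSE`
#'   and empty fields; callers fall back to sentence-only features.
#' @export
shortest_dependency_path <- function(graph, a, b) {
  n <- graph$n_tokens
  a <- as.integer(a); b <- as.integer(b)
  if (a == b) stop("path endpoints must differ", call. = FALSE)
  if (a < 1L || a > n || b < 1L || b > n) {
    stop("path endpoint out of range", call. = FALSE)
  }
  adj <- undirected_adjacency(graph)
  dist_a <- bfs_distances(adj, a, n)
  if (is.na(dist_a[b])) {
    return(structure(list(nodes = integer(0), relations = character(0),
                          directions = character(0), has_path = FALSE),
                     class = "sdp_path"))
  }
  dist_b <- bfs_distances(adj, b, n)
  # walk from a to b, always taking the smallest-index neighbor that stays on
  # some shortest path; this yields the lexicographically smallest sequence
  nodes <- a
  cur <- a
  while (cur != b) {
    nb <- adj[[cur]]
    ok <- nb[!is.na(dist_a[nb]) & !is.na(dist_b[nb]) &
               dist_a[nb] == dist_a[cur] + 1L &
               dist_b[nb] == dist_b[cur] - 1L]
    cur <- min(ok)
    nodes <- c(nodes, cur)
  }
  step <- step_annotations(graph, nodes)
  structure(list(nodes = nodes, relations = step$rel,
                 directions = step$dir, has_path = TRUE),
            class = "sdp_path")
}

bfs_distances <- function(adj, start, n) {
  dist <- rep(NA_integer_, n)
  dist[start] <- 0L
  queue <- start
  while (length(queue) > 0L) {
    u <- queue[1L]
    queue <- queue[-1L]
    for (v in adj[[u]]) {
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L
        queue <- c(queue, v)
      }
    }
  }
  dist
}

# relation label + direction for each consecutive node pair; "up" means the
# step moves from a dependent to its head
step_annotations <- function(graph, nodes) {
  m <- length(nodes)
  rel <- character(m - 1L)
  dir <- character(m - 1L)
  e <- graph$edges
  for (i in seq_len(m - 1L)) {
    u <- nodes[i]; v <- nodes[i + 1L]
    up <- which(e$head == v & e$dep == u)
    if (length(up) > 0L) {
      rel[i] <- e$rel[up[1L]]
      dir[i] <- "up"
    } else {
      down <- which(e$head == u & e$dep == v)
      if (length(down) == 0L) {
        stop("internal error: path step is not a graph edge", call. = FALSE)
      }
      rel[i] <- e$rel[down[1L]]
      dir[i] <- "down"
    }
  }
  list(rel = rel, dir = dir)
}

#' Reverse a shortest dependency path
#'
#' Reverses node and relation order and flips every step direction, so that
#' `path_reverse(shortest_dependency_path(g, a, b))` equals
#' `shortest_dependency_path(g, b, a)` on trees.
#'
#' @param path An `sdp_path`.
#' @return The reversed `sdp_path`.
#' @export
path_reverse <- function(path) {
  if (!inherits(path, "sdp_path")) stop("not an sdp_path", call. = FALSE)
  if (!isTRUE(path$has_path)) return(path)
  structure(list(nodes = rev(path$nodes),
                 relations = rev(path$relations),
                 directions = rev(ifelse(path$directions == "up",
                                         "down", "up")),
                 has_path = TRUE),
            class = "sdp_path")
}

#' Format a dependency path in arrow notation
#'
#' Renders a path as `word -rel-> word` chains for logs and debugging dumps.
#'
#' @param path An `sdp_path`.
#' @param tokens Character vector of sentence tokens used to name the nodes;
#'   if `NULL`, node indices are printed.
#' @return A single string.
#' @export
format_sdp <- function(path, tokens = NULL) {
  if (!isTRUE(path$has_path)) return("<no path>")
  name <- if (is.null(tokens)) as.character(path$nodes) else tokens[path$nodes]
  out <- name[1L]
  for (i in seq_along(path$relations)) {
    out <- paste0(out, " -", path$relations[i], "-> ", name[i + 1L])
  }
  out
}

#' @export
print.sdp_path <- function(x, ...) {
  cat(format_sdp(x), "\n")
  invisible(x)
}
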
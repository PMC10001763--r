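#' Path algebra on signed graphs
#'
#' A path carries the product of its edge relations as its sign: an even
#' number of inhibiting steps yields net activation, an odd number net
#' inhibition. Zero-length paths have sign +1 (identity).
#'
#' @param path a `signed_path` or an integer vector of edge relations.
#' @return -1 or +1.
#' @examples
#' path_sign(c(-1, -1)) # double negation activates
#' @export
path_sign <- function(path) {
  r <- if (inherits(path, "signed_path")) path$relations else as.integer(path)
  if (!length(r)) return(1L)
  if (any(!r %in% c(-1L, 1L))) stop("relations must be -1 or +1", call. = FALSE)
  as.integer(prod(r))
}

new_signed_path <- function(nodes, relations) {
  structure(
    list(nodes = nodes, relations = as.integer(relations),
         length = length(nodes) - 1L, sign = path_sign(relations)),
    class = "signed_path"
  )
}

#' @export
print.signed_path <- function(x, ...) {
  arrows <- ifelse(x$relations == 1L, " -> ", " -| ")
  cat("<signed_path> sign ", x$sign, ", length ", x$length, ": ",
      paste0(x$nodes, c(arrows, "")), "\n", sep = "")
  invisible(x)
}

# sorted adjacency list and (source,target) -> relation lookup; when a pair
# is linked by contradictory parallel edges the activating one labels paths
graph_index <- function(g) {
  e <- g$edges
  adj <- lapply(split(e$target, e$source), function(v) sort(unique(v)))
  key <- paste(e$source, e$target, sep = "\r")
  rel <- tapply(e$relation, key, max)
  list(adj = adj, rel = rel, nodes = g$nodes$node)
}

index_path <- function(idx, nodes) {
  if (length(nodes) < 2) return(new_signed_path(nodes, integer(0)))
  key <- paste(nodes[-length(nodes)], nodes[-1], sep = "\r")
  new_signed_path(nodes, unname(idx$rel[key]))
}

#' Shortest signed path by breadth-first search
#'
#' Minimum-length directed path between two vertices, computed by BFS.
#' Among equal-length alternatives the lexicographically smallest vertex
#' sequence is returned, fixing the result deterministically. `to` may be
#' a vector of targets, in which case a shortest path to the nearest
#' target is returned.
#'
#' @param g a `signed_graph`.
#' @param from,to vertex ids.
#' @return a `signed_path`, or `NULL` if no target is reachable.
#' @export
shortest_path <- function(g, from, to) {
  stopifnot(inherits(g, "signed_graph"))
  absent <- setdiff(c(from, to), g$nodes$node)
  if (length(absent)) {
    stop("vertex not in graph: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  idx <- graph_index(g)
  if (from %in% to) return(index_path(idx, from))
  # multi-source reverse BFS: dist[u] = hops from u to the nearest target
  radj <- lapply(split(g$edges$source, g$edges$target), unique)
  dist <- stats::setNames(rep(Inf, length(idx$nodes)), idx$nodes)
  dist[to] <- 0
  queue <- sort(unique(to))
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    for (v in radj[[u]]) {
      if (!is.finite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  if (!is.finite(dist[from])) return(NULL)
  # greedy walk along decreasing distance, smallest vertex id first:
  # yields the lexicographically smallest shortest path
  path <- from
  u <- from
  while (!u %in% to) {
    cand <- idx$adj[[u]]
    u <- cand[dist[cand] == dist[u] - 1][1]
    path <- c(path, u)
  }
  index_path(idx, path)
}

# Kahn topological sort; NULL if cyclic
topo_order <- function(g) {
  nodes <- g$nodes$node
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(g$edges$target)
  indeg[names(tab)] <- as.integer(tab)
  adj <- lapply(split(g$edges$target, g$edges$source), unique)
  ready <- sort(nodes[indeg == 0])
  out <- character(0)
  while (length(ready)) {
    u <- ready[1]
    ready <- ready[-1]
    out <- c(out, u)
    for (v in adj[[u]]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) ready <- sort(c(ready, v))
    }
  }
  if (length(out) < length(nodes)) NULL else out
}

#' Topological weight of an element for an LM class
#'
#' On the acyclic biosynthesis submap of a class, the weight of element `e`
#' combines its share of the simple precursor-to-product paths with its
#' share of the vertices connected to the class products, signed by the
#' relation product of the shortest path from `e` to a product:
#' \deqn{w_{e,p} = r(SP_{e,p}) (N^{e}_{paths}/N_{paths} +
#'   N^{e}_{nodes}/N_{nodes})}
#' Path counts pool all terminal products of the class. The connected-node
#' count covers every vertex with a directed path to some product (products
#' included); the class precursor, being the fixed entry point rather than
#' part of the biosynthetic machinery, is not counted, which makes the
#' maximum weight of 2 attainable for a sole enzyme on a sole path.
#' Elements with no route to any product get weight 0.
#'
#' @param g_sub the class biosynthesis submap (`signed_graph`); must be
#'   acyclic.
#' @param element element id to weight.
#' @param class an `lm_class` (precursor and products are used).
#' @return a single weight in \[-2, 2\].
#' @export
topological_weight <- function(g_sub, element, class) {
  stopifnot(inherits(g_sub, "signed_graph"), inherits(class, "lm_class"))
  nodes <- g_sub$nodes$node
  if (!element %in% nodes) return(0)
  if (!class$precursor %in% nodes) {
    stop("precursor ", class$precursor, " absent from submap", call. = FALSE)
  }
  ord <- topo_order(g_sub)
  if (is.null(ord)) {
    stop("submap is cyclic: path counts are undefined", call. = FALSE)
  }
  products <- intersect(class$products, nodes)
  if (!length(products)) return(0)

  adj_out <- lapply(split(g_sub$edges$target, g_sub$edges$source), unique)
  adj_in <- lapply(split(g_sub$edges$source, g_sub$edges$target), unique)

  # paths_from[v]: number of simple paths from v ending at any product
  paths_from <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in rev(ord)) {
    paths_from[v] <- as.numeric(v %in% products) +
      sum(paths_from[adj_out[[v]]])
  }
  # paths_to[v]: number of simple paths precursor -> v
  paths_to <- stats::setNames(numeric(length(nodes)), nodes)
  paths_to[class$precursor] <- 1
  for (v in ord) {
    paths_to[v] <- paths_to[v] + sum(paths_to[adj_in[[v]]])
  }
  n_paths <- paths_from[class$precursor]
  if (n_paths == 0) {
    stop("no precursor-to-product path in submap", call. = FALSE)
  }
  if (paths_from[element] == 0) return(0)

  sp <- shortest_path(g_sub, element, products)
  connected <- setdiff(nodes[paths_from > 0], class$precursor)
  n_paths_e <- paths_to[element] * paths_from[element]
  n_nodes_e <- length(setdiff(sp$nodes, class$precursor))
  unname(sp$sign * (n_paths_e / n_paths + n_nodes_e / length(connected)))
}

#' Weight table for all enzymes of several LM classes
#'
#' @param g_sub biosynthesis submap containing all classes (acyclic).
#' @param classes named list of `lm_class` objects.
#' @param elements elements to weight per class; defaults to each class's
#'   enzymes.
#' @return tibble with columns `class`, `element`, `weight`.
#' @export
topological_weights <- function(g_sub, classes, elements = NULL) {
  purrr::map_dfr(classes, function(cl) {
    els <- if (is.null(elements)) cl$enzymes else elements
    tibble::tibble(
      class = cl$name, element = els,
      weight = purrr::map_dbl(els, topological_weight, g_sub = g_sub,
                              class = cl)
    )
  })
}

# ---- widest (maximum-bottleneck) paths --------------------------------------

# Dijkstra over the lexicographic objective (bottleneck desc, hops asc,
# path lexicographic asc); every component is monotone under extension, so
# greedy finalization is exact. Edge weight = weight of the edge's target.
widest_path_tree <- function(g, from, node_weight) {
  idx <- graph_index(g)
  nodes <- idx$nodes
  wt <- stats::setNames(rep(0, length(nodes)), nodes)
  shared <- intersect(names(node_weight), nodes)
  wt[shared] <- node_weight[shared]

  bot <- stats::setNames(rep(-Inf, length(nodes)), nodes)
  hops <- stats::setNames(rep(Inf, length(nodes)), nodes)
  pkey <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  paths <- stats::setNames(vector("list", length(nodes)), nodes)
  done <- stats::setNames(logical(length(nodes)), nodes)

  bot[from] <- Inf
  hops[from] <- 0
  paths[[from]] <- from
  pkey[from] <- from

  repeat {
    cand <- nodes[!done & bot > -Inf]
    if (!length(cand)) break
    o <- order(-bot[cand], hops[cand], pkey[cand], method = "radix")
    u <- cand[o[1]]
    done[u] <- TRUE
    for (v in idx$adj[[u]]) {
      if (done[v]) next
      nb <- min(bot[u], wt[v])
      nh <- hops[u] + 1
      nk <- paste(pkey[u], v, sep = "\x1f")
      better <- nb > bot[v] ||
        (nb == bot[v] && (nh < hops[v] || (nh == hops[v] && nk < pkey[v])))
      if (is.na(pkey[v]) || better) {
        bot[v] <- nb
        hops[v] <- nh
        pkey[v] <- nk
        paths[[v]] <- c(paths[[u]], v)
      }
    }
  }
  list(idx = idx, bottleneck = bot, paths = paths)
}

#' Widest (maximum-bottleneck) path
#'
#' Returns the directed path maximizing the minimum edge weight, where each
#' edge inherits the weight of its target node (per-vertex regulatory
#' scores in CRN extraction). Solved with an adaptation of Dijkstra's
#' algorithm; among paths of equal bottleneck the shorter one is preferred,
#' then the lexicographically smallest vertex sequence. Vertices without a
#' supplied weight count as 0: they are traversable but cap the bottleneck
#' at 0, ranking below any positive-bottleneck route.
#'
#' @param g a `signed_graph`.
#' @param from,to vertex ids.
#' @param node_weight named numeric vector of node weights (default 0 for
#'   missing vertices).
#' @return a `signed_path` with attribute `bottleneck`, or `NULL` if `to`
#'   is unreachable.
#' @export
widest_path <- function(g, from, to, node_weight = numeric(0)) {
  stopifnot(inherits(g, "signed_graph"))
  absent <- setdiff(c(from, to), g$nodes$node)
  if (length(absent)) {
    stop("vertex not in graph: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  tree <- widest_path_tree(g, from, node_weight)
  if (is.null(tree$paths[[to]])) return(NULL)
  p <- index_path(tree$idx, tree$paths[[to]])
  attr(p, "bottleneck") <- unname(tree$bottleneck[to])
  p
}

#' Core regulatory network by widest-path union
#'
#' Combines, for every scored transcription factor and every class enzyme
#' present in the cell subgraph, the widest path from the TF to the enzyme,
#' with node weights `s` (mode `"single"`, scores of one cell) or `|s|`
#' (mode `"delta"`, pass score differences between two cells/conditions).
#' TFs whose score is exactly 0 contribute no path.
#'
#' @param gc a `cell_subgraph`.
#' @param scores named numeric vector (or two-column data frame gene/score)
#'   of regulatory scores for the vertices of `gc`.
#' @param class an `lm_class`.
#' @param mode `"single"` or `"delta"`.
#' @return an `lm_crn`: list with `$graph`, `$node_scores`, `$paths`,
#'   `$class`, `$mode`.
#' @export
extract_crn <- function(gc, scores, class, mode = c("single", "delta")) {
  stopifnot(inherits(gc, "cell_subgraph"), inherits(class, "lm_class"))
  mode <- match.arg(mode)
  if (is.data.frame(scores)) {
    scores <- stats::setNames(as.numeric(scores[[2]]), as.character(scores[[1]]))
  }
  g <- gc$graph
  weight <- if (mode == "delta") abs(scores) else scores
  enzymes <- intersect(class$enzymes, g$nodes$node)
  empty <- structure(
    list(graph = signed_graph(NULL), node_scores = numeric(0), paths = list(),
         class = class$name, mode = mode),
    class = "lm_crn"
  )
  if (!length(enzymes)) {
    warning("no enzymes of class ", class$name, " in subgraph; empty CRN")
    return(empty)
  }
  tfs <- g$nodes$node[g$nodes$role == "TF"]
  tfs <- tfs[!is.na(weight[tfs]) & weight[tfs] != 0]
  paths <- list()
  for (tf in sort(tfs)) {
    tree <- widest_path_tree(g, tf, weight)
    for (enz in sort(enzymes)) {
      if (!is.null(tree$paths[[enz]])) {
        p <- index_path(tree$idx, tree$paths[[enz]])
        attr(p, "bottleneck") <- unname(tree$bottleneck[enz])
        paths[[paste(tf, enz, sep = "->")]] <- p
      }
    }
  }
  if (!length(paths)) return(empty)
  keep <- unique(unlist(purrr::map(paths, "nodes")))
  crn_edges <- purrr::map_dfr(paths, function(p) {
    tibble::tibble(source = p$nodes[-length(p$nodes)], relation = p$relations,
                   target = p$nodes[-1])
  })
  crn <- signed_graph(crn_edges, g$nodes[g$nodes$node %in% keep, ])
  ns <- stats::setNames(rep(0, length(keep)), keep)
  shared <- intersect(names(weight), keep)
  ns[shared] <- weight[shared]
  structure(
    list(graph = crn, node_scores = ns[sort(keep)], paths = paths,
         class = class$name, mode = mode),
    class = "lm_crn"
  )
}

#' @export
print.lm_crn <- function(x, ...) {
  cat("<lm_crn> class ", x$class, " (mode ", x$mode, "): ",
      nrow(x$graph$nodes), " nodes, ", nrow(x$graph$edges), " edges, ",
      length(x$paths), " widest path(s)\n", sep = "")
  invisible(x)
}

#' @rdname extract_crn
#' @param x an `lm_crn`.
#' @param ... unused.
#' @method tidy lm_crn
#' @export
tidy.lm_crn <- function(x, ...) {
  dplyr::mutate(tidy(x$graph),
                class = x$class, mode = x$mode)
}

#' @rdname extract_crn
#' @method glance lm_crn
#' @export
glance.lm_crn <- function(x, ...) {
  tibble::tibble(
    class = x$class, mode = x$mode,
    n_nodes = nrow(x$graph$nodes), n_edges = nrow(x$graph$edges),
    n_paths = length(x$paths),
    max_bottleneck = if (length(x$paths)) {
      max(purrr::map_dbl(x$paths, attr, "bottleneck"))
    } else NA_real_
  )
}
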
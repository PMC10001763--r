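# Independent brute-force oracles and small fixture builders.
# Everything here is deliberately naive (recursion, dense loops) and shares
# no code with the package internals.

# all simple directed paths from `from` ending at any vertex of `to`
enumerate_simple_paths <- function(edges, from, to) {
  adj <- split(edges$target, edges$source)
  paths <- list()
  recurse <- function(path) {
    u <- path[length(path)]
    if (u %in% to) paths[[length(paths) + 1]] <<- path
    for (v in setdiff(adj[[u]], path)) recurse(c(path, v))
  }
  recurse(from)
  paths
}

path_relations <- function(edges, path) {
  vapply(seq_len(length(path) - 1), function(i) {
    r <- edges$relation[edges$source == path[i] & edges$target == path[i + 1]]
    max(r) # activating edge labels contradictory parallels
  }, numeric(1))
}

# lexicographically smallest among the shortest enumerated paths
oracle_shortest <- function(edges, from, to) {
  paths <- enumerate_simple_paths(edges, from, to)
  if (!length(paths)) return(NULL)
  lens <- lengths(paths)
  short <- paths[lens == min(lens)]
  keys <- vapply(short, paste, "", collapse = "\x1f")
  short[[order(keys)[1]]]
}

# maximum over all simple paths of the minimum target-node weight
oracle_widest_bottleneck <- function(edges, from, to, wt) {
  paths <- enumerate_simple_paths(edges, from, to)
  paths <- paths[vapply(paths, function(p) p[length(p)] == to, TRUE)]
  if (!length(paths)) return(NULL)
  max(vapply(paths, function(p) {
    if (length(p) == 1) Inf else min(wt[p[-1]])
  }, numeric(1)))
}

# brute-force topological weight under the package's stated convention
oracle_topological_weight <- function(edges, nodes, precursor, products, e) {
  all_paths <- enumerate_simple_paths(edges, precursor, products)
  n_paths <- length(all_paths)
  stopifnot(n_paths > 0)
  connected <- nodes[vapply(nodes, function(u) {
    length(enumerate_simple_paths(edges, u, products)) > 0
  }, TRUE)]
  connected <- setdiff(connected, precursor)
  if (!e %in% c(connected, precursor) ||
      length(enumerate_simple_paths(edges, e, products)) == 0) {
    return(0)
  }
  through <- sum(vapply(all_paths, function(p) e %in% p, TRUE))
  sp <- oracle_shortest(edges, e, products)
  sgn <- if (length(sp) == 1) 1 else prod(path_relations(edges, sp))
  sgn * (through / n_paths +
           length(setdiff(sp, precursor)) / length(connected))
}

# dense propagation oracle: explicit per-vertex loops over the edge list
oracle_propagation <- function(nodes, roles, edges, deg, f, s0, steps,
                               signed = TRUE) {
  traj <- matrix(0, nrow = length(nodes), ncol = steps + 1,
                 dimnames = list(nodes, NULL))
  s <- s0[nodes]
  traj[, 1] <- s
  for (t in seq_len(steps)) {
    s_new <- stats::setNames(numeric(length(nodes)), nodes)
    for (u in nodes) {
      if (roles[u] == "enzyme") {
        s_new[u] <- s[u]
      } else {
        acc <- 0
        for (i in seq_len(nrow(edges))) {
          if (edges$source[i] == u) {
            r <- if (signed) edges$relation[i] else abs(edges$relation[i])
            acc <- acc + r * s[edges$target[i]] /
              (deg[u] * deg[edges$target[i]])
          }
        }
        s_new[u] <- f[u] * acc
      }
    }
    s <- s_new
    traj[, t + 1] <- s
  }
  traj
}

# textbook Benjamini-Hochberg, written independently of stats::p.adjust
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  adj[o] <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  adj
}

# ---- random fixtures --------------------------------------------------------

node_ids <- function(n) sprintf("N%02d", seq_len(n))

# random signed digraph (cycles allowed), unique (source, target) pairs
random_signed_graph <- function(n, p_edge = 0.35, neg_prob = 0.3, seed = 0) {
  withr::with_seed(seed, {
    ids <- node_ids(n)
    pairs <- expand.grid(source = ids, target = ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    pairs <- pairs[stats::runif(nrow(pairs)) < p_edge, ]
    if (nrow(pairs) == 0) pairs <- data.frame(source = ids[1], target = ids[2])
    pairs$relation <- ifelse(stats::runif(nrow(pairs)) < neg_prob, -1L, 1L)
    list(graph = signed_graph(pairs, tibble::tibble(node = ids, role = "gene")),
         edges = pairs, nodes = ids)
  })
}

# random DAG submap: edges only from lower to higher ids, node 1 = precursor,
# sinks reachable from the precursor are the products
random_dag_submap <- function(n, p_edge = 0.4, neg_prob = 0.3, seed = 0) {
  withr::with_seed(seed, {
    ids <- node_ids(n)
    pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
    pairs <- pairs[pairs$i < pairs$j, ]
    pairs <- pairs[stats::runif(nrow(pairs)) < p_edge, ]
    edges <- data.frame(source = ids[pairs$i], target = ids[pairs$j],
                        relation = ifelse(stats::runif(nrow(pairs)) < neg_prob,
                                          -1L, 1L))
    if (!ids[1] %in% edges$source) {
      edges <- rbind(edges, data.frame(source = ids[1], target = ids[2],
                                       relation = 1L))
    }
    sinks <- setdiff(ids, edges$source)
    reach <- setdiff(
      unique(unlist(lapply(enumerate_simple_paths(edges, ids[1], sinks),
                           function(p) p[length(p)]))),
      ids[1]
    )
    if (!length(reach)) {
      edges <- rbind(edges, data.frame(source = ids[1], target = ids[n],
                                       relation = 1L))
      sinks <- setdiff(ids, edges$source)
      reach <- ids[n]
    }
    roles <- tibble::tibble(node = ids,
                            role = ifelse(ids %in% sinks, "product",
                                          "metabolite"))
    list(graph = signed_graph(edges, roles), edges = edges, nodes = ids,
         precursor = ids[1], products = reach)
  })
}

# three well-separated Gaussian blobs in 5 dimensions
make_blobs <- function(n_per = 15, d = 5, sep = 20, sd = 1, seed = 0) {
  withr::with_seed(seed, {
    centers <- diag(3)[rep(1:3, each = n_per), , drop = FALSE] %*%
      matrix(stats::rnorm(3 * d, sd = sep), nrow = 3)
    m <- centers + matrix(stats::rnorm(3 * n_per * d, sd = sd),
                          ncol = d)
    tibble::tibble(sample = sprintf("b%02d", seq_len(3 * n_per)),
                   !!!stats::setNames(as.data.frame(m), paste0("f", 1:d)),
                   label = rep(1:3, each = n_per))
  })
}

# tiny two-enzyme chain fixture shared by several tests
chain_fixture <- function() {
  rx <- data.frame(substrate = c("AA", "M1"), enzyme = c("E1", "E2"),
                   product = c("M1", "P"))
  list(submap = transform_catalysis(rx),
       class = lm_class("chain", "AA", "P", c("E1", "E2")))
}

# cache shared across acceptance blocks: the 20-replicate cohort statistics
.replicate_cache <- new.env(parent = emptyenv())

replicate_cohort <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.replicate_cache[[key]])) return(.replicate_cache[[key]])
  ds <- simulate_lm_dataset(seed = seed)
  scores <- score_table(ds$graph, ds$classes, ds$expr,
                        graph_overrides = ds$graph_overrides)
  qhat <- normalize_expression(ds$expr)
  clusters <- tibble::tibble(sample = names(ds$truth$cluster_of),
                             cluster = unname(ds$truth$cluster_of))
  tests <- cluster_feature_tests(scores, qhat, clusters)
  sig <- significant_cluster_genes(tests, alpha = 0.05)
  res <- list(ds = ds, scores = scores, qhat = qhat, clusters = clusters,
              significant = sig)
  .replicate_cache[[key]] <- res
  res
}

# seeded random TF-layer-plus-pathway case for propagation oracle checks
random_propagation_case <- function(seed) {
  withr::with_seed(seed, {
    n_tf <- 8
    tfs <- sprintf("T%02d", 1:n_tf)
    enz <- c("E1", "E2")
    edges <- data.frame(
      source = sample(tfs, 14, replace = TRUE),
      target = sample(c(tfs, enz), 14, replace = TRUE),
      relation = sample(c(-1L, 1L), 14, replace = TRUE)
    )
    edges <- unique(edges[edges$source != edges$target, ])
    edges <- rbind(edges,
                   data.frame(source = c("AA", "M"), target = enz,
                              relation = 1L),
                   data.frame(source = enz, target = c("M", "P"),
                              relation = 1L))
    counts <- stats::setNames(stats::rpois(n_tf + 2, 40), c(tfs, enz))
  })
  g <- signed_graph(edges, tibble::tibble(
    node = c(tfs, enz, "AA", "M", "P"),
    role = c(rep("TF", n_tf), "enzyme", "enzyme", "metabolite",
             "metabolite", "product")
  ))
  expr <- data.frame(gene = names(counts), s1 = unname(counts))
  gc <- filter_expressed(g, expr, "s1")
  qhat <- stats::setNames(normalize_expression(expr)$s1, names(counts))
  nodes <- gc$graph$nodes$node
  roles <- stats::setNames(gc$graph$nodes$role, nodes)
  f <- stats::setNames(rep(1, length(nodes)), nodes)
  meas <- intersect(nodes[roles %in% c("TF", "gene")], names(qhat))
  f[meas] <- qhat[meas]
  w <- c(E1 = 1.2, E2 = -0.4)
  s0 <- stats::setNames(rep(0, length(nodes)), nodes)
  s0[intersect(names(w), nodes)] <- w[intersect(names(w), nodes)]
  list(graph = g, gc = gc, qhat = qhat, weights = w,
       class = lm_class("c", "AA", "P", enz),
       nodes = nodes, roles = roles, f = f, s0 = s0,
       deg = node_degrees(g))
}
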
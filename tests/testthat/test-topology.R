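test_that("path signs multiply along relations", {
  expect_equal(path_sign(c(1, 1, 1)), 1L)
  expect_equal(path_sign(c(-1, -1)), 1L)
  expect_equal(path_sign(c(-1, 1, 1)), -1L)
  expect_equal(path_sign(integer(0)), 1L) # zero-length path is the identity
  expect_error(path_sign(c(1, 0)), "-1 or \\+1")

  # multiplicative under concatenation
  withr::with_seed(5, {
    for (i in 1:20) {
      r1 <- sample(c(-1L, 1L), sample(0:4, 1), replace = TRUE)
      r2 <- sample(c(-1L, 1L), sample(0:4, 1), replace = TRUE)
      expect_equal(path_sign(c(r1, r2)), path_sign(r1) * path_sign(r2))
    }
  })
})

test_that("BFS shortest paths match exhaustive enumeration", {
  g <- signed_graph(data.frame(source = "A", relation = -1, target = "B"))
  p <- shortest_path(g, "A", "B")
  expect_equal(p$nodes, c("A", "B"))
  expect_equal(p$length, 1L)
  expect_equal(p$sign, -1L)

  expect_null(shortest_path(g, "B", "A"))
  expect_error(shortest_path(g, "A", "Z"), "not in graph")

  # 6-node graph with a 2-hop and a 3-hop route
  e6 <- data.frame(source = c("A", "X", "A", "B", "C"),
                   target = c("X", "Z", "B", "C", "Z"),
                   relation = 1L)
  p6 <- shortest_path(signed_graph(e6), "A", "Z")
  expect_equal(p6$length,
               min(lengths(enumerate_simple_paths(e6, "A", "Z"))) - 1L)
  expect_equal(p6$nodes, c("A", "X", "Z"))

  for (i in 1:50) {
    rg <- random_signed_graph(7, seed = 100 + i)
    ids <- rg$nodes
    for (pair in list(c(ids[1], ids[7]), c(ids[3], ids[5]))) {
      got <- shortest_path(rg$graph, pair[1], pair[2])
      want <- oracle_shortest(rg$edges, pair[1], pair[2])
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$nodes, want) # length AND lexicographic tie-break
        expect_equal(got$sign, path_sign(path_relations(rg$edges, want)))
      }
    }
  }
})

test_that("topological weight reproduces hand-derived submaps", {
  fx <- chain_fixture()
  # sole enzyme on the sole path, covering the whole connected set
  single <- transform_catalysis(data.frame(substrate = "AA", enzyme = "E",
                                           product = "P"))
  cls <- lm_class("single", "AA", "P", "E")
  expect_equal(topological_weight(single, "E", cls), 2)

  # two-enzyme chain: upstream enzyme still spans everything, the terminal
  # one holds half the connected set
  expect_equal(topological_weight(fx$submap, "E1", fx$class), 2)
  expect_equal(topological_weight(fx$submap, "E2", fx$class), 1.5)

  # inhibiting edge on the shortest path flips the sign
  neg <- signed_graph(
    data.frame(source = c("AA", "E"), relation = c(1, -1),
               target = c("E", "P")),
    nodes = data.frame(node = c("AA", "E", "P"),
                       role = c("metabolite", "enzyme", "product"))
  )
  expect_equal(topological_weight(neg, "E", cls), -2)

  # 7-node two-branch DAG: 3 paths to P, e (= B) on 2 of them, SP from B
  # has 3 nodes, 6 nodes connected to P
  e7 <- data.frame(
    source = c("AA", "E", "F", "AA", "B", "C", "B", "D"),
    target = c("E", "F", "P", "B", "C", "P", "D", "P"),
    relation = 1L
  )
  g7 <- signed_graph(e7, data.frame(
    node = c("AA", "B", "C", "D", "E", "F", "P"),
    role = c("metabolite", "enzyme", "metabolite", "metabolite",
             "metabolite", "metabolite", "product")
  ))
  cl7 <- lm_class("branch", "AA", "P", "B")
  expect_equal(topological_weight(g7, "B", cl7), 2 / 3 + 3 / 6)
  expect_equal(topological_weight(g7, "B", cl7),
               oracle_topological_weight(e7, g7$nodes$node, "AA", "P", "B"))

  # disconnected element scores zero; cyclic submaps are refused
  iso <- signed_graph(rbind(e7, data.frame(source = "Q", target = "R",
                                           relation = 1L)))
  expect_equal(topological_weight(iso, "Q", cl7), 0)
  cyc <- signed_graph(data.frame(source = c("AA", "E", "P"),
                                 target = c("E", "P", "E"), relation = 1L))
  expect_error(topological_weight(cyc, "E", cls), "cyclic")
})

test_that("topological weights equal brute force and stay within [-2, 2] on random DAGs", {
  for (i in 1:60) {
    dag <- random_dag_submap(sample(4:9, 1), seed = 400 + i)
    cls <- lm_class("r", dag$precursor, dag$products,
                    setdiff(dag$nodes, dag$precursor)[1])
    for (e in setdiff(dag$nodes, dag$precursor)) {
      w <- topological_weight(dag$graph, e, cls)
      expect_lte(abs(w), 2)
      expect_equal(
        w,
        oracle_topological_weight(dag$edges, dag$nodes, dag$precursor,
                                  dag$products, e),
        tolerance = 1e-12
      )
    }
  }
})

test_that("widest paths maximize the bottleneck with deterministic ties", {
  # single route is returned regardless of weights
  line <- signed_graph(data.frame(source = c("A", "B"), target = c("B", "C"),
                                  relation = 1L))
  p <- widest_path(line, "A", "C", c(A = 1, B = 0.1, C = 0.9))
  expect_equal(p$nodes, c("A", "B", "C"))
  expect_equal(attr(p, "bottleneck"), 0.1)

  # two routes: pick the larger bottleneck
  fork <- signed_graph(data.frame(source = c("A", "B", "A", "C"),
                                  target = c("B", "D", "C", "D"),
                                  relation = 1L))
  expect_equal(widest_path(fork, "A", "D",
                           c(B = 0.9, C = 0.4, D = 0.95))$nodes,
               c("A", "B", "D"))

  # zero-weight vertices are traversable but rank below positive routes
  expect_equal(widest_path(fork, "A", "D", c(B = 0, C = 0.2, D = 1))$nodes,
               c("A", "C", "D"))

  # equal bottleneck and hops: lexicographically smallest path wins
  expect_equal(widest_path(fork, "A", "D", c(B = 0.5, C = 0.5, D = 0.5))$nodes,
               c("A", "B", "D"))

  # equal bottleneck: fewer hops preferred
  tri <- signed_graph(data.frame(source = c("A", "A", "B"),
                                 target = c("C", "B", "C"), relation = 1L))
  expect_equal(widest_path(tri, "A", "C", c(B = 0.5, C = 0.5))$nodes,
               c("A", "C"))

  expect_null(widest_path(line, "C", "A", c(A = 1)))
})

test_that("widest-path bottlenecks equal exhaustive enumeration on random graphs", {
  for (i in 1:40) {
    rg <- random_signed_graph(sample(4:8, 1), p_edge = 0.4, seed = 700 + i)
    wt <- withr::with_seed(700 + i,
                           stats::setNames(round(stats::runif(length(rg$nodes)), 3),
                                           rg$nodes))
    from <- rg$nodes[1]
    to <- rg$nodes[length(rg$nodes)]
    got <- widest_path(rg$graph, from, to, wt)
    want <- oracle_widest_bottleneck(rg$edges, from, to, wt)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(attr(got, "bottleneck"), want, tolerance = 1e-12)
    }
  }
})

test_that("CRN extraction unions widest TF-to-enzyme paths", {
  g <- merge_networks(
    transform_catalysis(data.frame(substrate = "AA", enzyme = "E1",
                                   product = "P")),
    signed_graph(data.frame(source = c("T1", "T2"), relation = 1,
                            target = "E1"),
                 nodes = data.frame(node = c("T1", "T2", "E1"),
                                    role = c("TF", "TF", "enzyme")))
  )
  expr <- data.frame(gene = c("T1", "T2", "E1"), s1 = c(50, 50, 50))
  gc <- filter_expressed(g, expr, "s1")
  cls <- lm_class("c", "AA", "P", "E1")

  crn <- extract_crn(gc, c(T1 = 1.2, T2 = 0, E1 = 3), cls)
  # the single scored TF contributes exactly its one path
  expect_setequal(crn$graph$nodes$node, c("T1", "E1"))
  expect_equal(length(crn$paths), 1)
  expect_equal(crn$paths[["T1->E1"]]$nodes, c("T1", "E1"))
  # zero-score TFs contribute nothing
  expect_false("T2" %in% crn$graph$nodes$node)

  # delta mode uses |score|, so negative deltas still route
  crn_d <- extract_crn(gc, c(T1 = -0.5, T2 = -2), cls, mode = "delta")
  expect_setequal(crn_d$graph$nodes$node, c("T1", "T2", "E1"))
  expect_true(all(crn_d$node_scores >= 0))

  # class without enzymes in the subgraph yields an empty CRN with warning
  expect_warning(
    empty <- extract_crn(gc, c(T1 = 1), lm_class("x", "AA", "Q", "E9")),
    "empty CRN"
  )
  expect_equal(nrow(empty$graph$nodes), 0)
})

test_that("the planted regulator's route appears in its cluster's CRN", {
  rc <- replicate_cohort(7)
  ds <- rc$ds
  pr <- ds$truth$planted_regulators[1, ]
  cls_name <- pr$classes[[1]][1]
  smp <- names(ds$truth$cluster_of)[ds$truth$cluster_of == pr$cluster][1]
  gc <- filter_expressed(ds$graph, ds$expr, smp)
  sl <- rc$scores[rc$scores$class == cls_name & rc$scores$sample == smp, ]
  crn <- extract_crn(gc, stats::setNames(sl$score, sl$gene),
                     ds$classes[[cls_name]])
  expect_true(pr$tf %in% crn$graph$nodes$node)
  # the recorded widest path from the planted TF runs through an
  # intermediate to a class enzyme, matching the generator's wiring
  key <- grep(paste0("^", pr$tf, "->"), names(crn$paths), value = TRUE)
  expect_gte(length(key), 1)
  expect_true(any(vapply(crn$paths[key], function(p) {
    any(pr$intermediates[[1]] %in% p$nodes)
  }, TRUE)))
})
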
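test_that("catalytic reactions become activity-flow triples through the enzyme", {
  g <- transform_catalysis(
    data.frame(substrate = "AA", enzyme = "Ptgs2", product = "PGH2")
  )
  expect_setequal(g$nodes$node, c("AA", "Ptgs2", "PGH2"))
  expect_equal(nrow(g$edges), 2)
  expect_true(all(g$edges$relation == 1L))
  expect_true(any(g$edges$source == "AA" & g$edges$target == "Ptgs2"))
  expect_true(any(g$edges$source == "Ptgs2" & g$edges$target == "PGH2"))
  # no direct substrate -> product shortcut
  expect_false(any(g$edges$source == "AA" & g$edges$target == "PGH2"))

  expect_equal(nrow(transform_catalysis(data.frame(substrate = character(),
                                                   enzyme = character(),
                                                   product = character()))$edges),
               0)

  shared <- transform_catalysis(
    data.frame(substrate = c("AA", "EPA"), enzyme = "Alox5",
               product = c("LTA4", "HEPE"))
  )
  expect_equal(sum(shared$nodes$role == "enzyme"), 1)
  expect_equal(nrow(shared$edges), 4)

  expect_error(
    transform_catalysis(data.frame(substrate = "AA", enzyme = NA,
                                   product = "X")),
    "malformed"
  )
})

test_that("no transformed reaction links two non-enzyme metabolites directly", {
  withr::with_seed(42, {
    rx <- data.frame(substrate = sample(LETTERS[1:6], 10, TRUE),
                     enzyme = sprintf("E%d", 1:10),
                     product = sample(letters[1:6], 10, TRUE))
  })
  g <- transform_catalysis(rx)
  roles <- stats::setNames(g$nodes$role, g$nodes$node)
  bad <- roles[g$edges$source] != "enzyme" & roles[g$edges$target] != "enzyme"
  expect_false(any(bad))
})

test_that("network merging unions vertices and edges and preserves signs", {
  pathway <- transform_catalysis(
    data.frame(substrate = "AA", enzyme = "Ptgs2", product = "PGH2")
  )
  tfs <- signed_graph(
    data.frame(source = c("Nfkb1", "Rela"), relation = c(1, -1),
               target = "Ptgs2"),
    nodes = data.frame(node = c("Nfkb1", "Rela", "Ptgs2"),
                       role = c("TF", "TF", "enzyme"))
  )
  merged <- merge_networks(pathway, tfs)
  expect_equal(nrow(merged$nodes), 5)
  expect_equal(nrow(merged$edges), 4)

  expect_identical(merge_networks(pathway, signed_graph(NULL))$edges,
                   pathway$edges)

  # a TF regulating two enzymes with opposite signs keeps both edges
  two <- signed_graph(
    data.frame(source = "Stat3", relation = c(1, -1),
               target = c("Alox5", "Alox15")),
    nodes = data.frame(node = c("Stat3", "Alox5", "Alox15"),
                       role = c("TF", "enzyme", "enzyme"))
  )
  m2 <- merge_networks(signed_graph(NULL), two)
  expect_equal(sort(m2$edges$relation), c(-1L, 1L))

  conflicting <- signed_graph(data.frame(source = "Ptgs2", relation = 1,
                                         target = "X"),
                              nodes = data.frame(node = c("Ptgs2", "X"),
                                                 role = c("TF", "gene")))
  expect_error(merge_networks(pathway, conflicting), "role conflict")
})

test_that("expression filtering removes low TFs but never protected vertices", {
  g <- merge_networks(
    transform_catalysis(data.frame(substrate = "AA", enzyme = "E1",
                                   product = "P")),
    signed_graph(data.frame(source = c("T1", "T2", "T3"), relation = 1,
                            target = "E1"),
                 nodes = data.frame(node = c("T1", "T2", "T3", "E1"),
                                    role = c("TF", "TF", "TF", "enzyme")))
  )
  expr <- data.frame(gene = c("T1", "T2", "T3", "E1"),
                     s1 = c(9, 10, 50, 0))
  gc <- filter_expressed(g, expr, "s1")
  expect_false("T1" %in% gc$graph$nodes$node) # 9 < 10 removed
  expect_true("T2" %in% gc$graph$nodes$node)  # boundary kept
  expect_true("E1" %in% gc$graph$nodes$node)  # protected despite 0
  expect_true(all(gc$graph$edges$source %in% gc$graph$nodes$node))

  all_high <- data.frame(gene = c("T1", "T2", "T3", "E1"), s1 = 100)
  gc2 <- filter_expressed(g, all_high, "s1")
  expect_identical(gc2$graph$edges, g$edges)

  expect_error(filter_expressed(g, expr, "nope"), "unknown sample")
})

test_that("protected vertices survive filtering across random graphs and thresholds", {
  for (i in 1:100) {
    rg <- random_signed_graph(8, seed = i)
    roles <- c("TF", "enzyme", "metabolite", "gene", "product")
    withr::with_seed(i, {
      nodes <- tibble::tibble(node = rg$nodes,
                              role = sample(roles, 8, replace = TRUE))
      thr <- sample(1:50, 1)
      expr <- data.frame(gene = rg$nodes, s1 = stats::rpois(8, 20))
    })
    g <- signed_graph(rg$edges, nodes)
    gc <- filter_expressed(g, expr, "s1", threshold = thr)
    protected <- nodes$node[!nodes$role %in% c("TF", "gene")]
    expect_true(all(protected %in% gc$graph$nodes$node))
  }
})

test_that("retained edges shrink monotonically with the threshold", {
  rg <- random_signed_graph(10, seed = 99)
  g <- signed_graph(rg$edges,
                    tibble::tibble(node = rg$nodes,
                                   role = rep(c("TF", "enzyme"), 5)))
  withr::with_seed(99, expr <- data.frame(gene = rg$nodes,
                                          s1 = stats::rpois(10, 15)))
  sizes <- vapply(c(0, 5, 10, 20, 40), function(thr) {
    nrow(filter_expressed(g, expr, "s1", threshold = thr)$graph$edges)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("max-normalization maps each gene to [0,1] with its peak at 1", {
  expr <- data.frame(gene = c("a", "b", "c"),
                     s1 = c(5, 0, 7), s2 = c(10, 0, 7), s3 = c(20, 0, 7))
  q <- normalize_expression(expr)
  expect_equal(unlist(q[q$gene == "a", -1], use.names = FALSE),
               c(0.25, 0.5, 1))
  expect_equal(unlist(q[q$gene == "b", -1], use.names = FALSE), c(0, 0, 0))
  expect_equal(unlist(q[q$gene == "c", -1], use.names = FALSE), c(1, 1, 1))

  single <- normalize_expression(data.frame(gene = "g", s1 = 7))
  expect_equal(single$s1, 1)

  # idempotent once every gene's maximum is 1
  expect_equal(as.matrix(normalize_expression(q)[-1]), as.matrix(q[-1]))

  withr::with_seed(1, big <- data.frame(gene = sprintf("g%d", 1:50),
                                        matrix(stats::rpois(500, 30), 50)))
  qb <- as.matrix(normalize_expression(big)[-1])
  expect_true(all(qb >= 0 & qb <= 1))
  expect_true(all(abs(apply(qb, 1, max) - 1) < 1e-12))

  expect_error(normalize_expression(data.frame(gene = "g", s1 = -3)),
               "negative")
})

test_that("identifier mapping renames, drops unmapped and aggregates by maximum", {
  expr <- data.frame(gene = c("Alox5", "Gm123"), s1 = c(5, 9), s2 = c(7, 1))
  mapped <- suppressMessages(
    map_identifiers(expr, data.frame(from = "Alox5", to = "ALOX5"))
  )
  expect_equal(mapped$gene, "ALOX5")
  expect_equal(nrow(mapped), 1)
  expect_message(map_identifiers(expr, data.frame(from = "Alox5",
                                                  to = "ALOX5")),
                 "1 unmapped")

  # two mouse genes collapsing onto one human id: counts combined by max
  two <- data.frame(gene = c("Cyp4f18", "Cyp4f39"), s1 = c(3, 11),
                    s2 = c(8, 2))
  agg <- map_identifiers(two, data.frame(from = c("Cyp4f18", "Cyp4f39"),
                                         to = "CYP4F3"))
  expect_equal(agg$s1, 11)
  expect_equal(agg$s2, 8)

  expect_error(map_identifiers(expr, data.frame()), "empty")
  expect_error(
    map_identifiers(expr, data.frame(from = c("a", "a"), to = c("x", "y"))),
    "unique"
  )
})

test_that("edge lists, roles, class YAML and expression tables round-trip", {
  dir <- withr::local_tempdir()
  g <- signed_graph(
    data.frame(source = c("T1", "T2"), relation = c(1, -1), target = "E1"),
    nodes = data.frame(node = c("T1", "T2", "E1"),
                       role = c("TF", "TF", "enzyme"))
  )
  write_signed_graph(g, file.path(dir, "e.tsv"), file.path(dir, "r.tsv"))
  g2 <- read_signed_graph(file.path(dir, "e.tsv"), file.path(dir, "r.tsv"))
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$nodes, g$nodes)

  # verbal relations and the unsigned-edge default
  writeLines(c("source\trelation\ttarget", "A\tactivates\tB", "B\tinhibits\tC",
               "C\t\tD"),
             file.path(dir, "verbal.tsv"))
  gv <- read_signed_graph(file.path(dir, "verbal.tsv"), unsigned_default = 1)
  expect_equal(gv$edges$relation[gv$edges$source == "A"], 1L)
  expect_equal(gv$edges$relation[gv$edges$source == "B"], -1L)
  expect_equal(gv$edges$relation[gv$edges$source == "C"], 1L)
  expect_error(read_signed_graph(file.path(dir, "verbal.tsv")), "relation")

  classes <- list(a = lm_class("a", "AA", c("P1", "P2"), c("E1", "E2")))
  write_lm_classes(classes, file.path(dir, "cls.yaml"))
  back <- read_lm_classes(file.path(dir, "cls.yaml"))
  expect_equal(back$a$products, c("P1", "P2"))
  expect_equal(back$a$enzymes, c("E1", "E2"))

  expr <- tibble::tibble(gene = c("g1", "g2"), s1 = c(1, 2), s2 = c(3, 4))
  write_expression(expr, file.path(dir, "expr.tsv"))
  expect_equal(as.data.frame(read_expression(file.path(dir, "expr.tsv"))),
               as.data.frame(expr))

  write_graphml(g, file.path(dir, "g.graphml"),
                score = c(T1 = 1, T2 = -0.5, E1 = 2))
  ig <- igraph::read_graph(file.path(dir, "g.graphml"), format = "graphml")
  expect_equal(igraph::gorder(ig), 3)
  expect_setequal(round(igraph::V(ig)$score, 3), c(1, -0.5, 2))
})
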
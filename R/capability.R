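#' De novo LM synthesis capability
#'
#' A cell type can synthesize an LM class if a complete directed route from
#' the class precursor (AA, DHA or EPA) to any terminal product of the
#' class exists in which every catalysing enzyme is expressed (raw count at
#' or above the threshold). Metabolite intermediates carry no expression
#' requirement; enzymes missing from the expression table are treated as
#' unexpressed (no evidence of a working route).
#'
#' @param graph full `signed_graph` or a `cell_subgraph` (its parent graph
#'   is used; capability is decided on raw counts, not on the filtered
#'   network, since pathway enzymes are protected from filtering).
#' @param class an `lm_class`.
#' @param counts named numeric vector of raw counts for one sample, or a
#'   wide expression table together with `sample`.
#' @param sample sample id when `counts` is a table.
#' @param threshold minimum count for an enzyme to carry flux (default 10).
#' @return logical; attribute `witness` holds one precursor-to-product
#'   path (BFS order, lexicographic tie-break) when `TRUE`.
#' @examples
#' g <- transform_catalysis(
#'   data.frame(substrate = c("AA", "PGH2"), enzyme = c("Ptgs2", "Ptgds"),
#'              product = c("PGH2", "PGD2"))
#' )
#' cl <- lm_class("prostaglandins_D", "AA", "PGD2", c("Ptgs2", "Ptgds"))
#' can_synthesize(g, cl, c(Ptgs2 = 50, Ptgds = 12))
#' @export
can_synthesize <- function(graph, class, counts, sample = NULL,
                           threshold = 10) {
  stopifnot(inherits(class, "lm_class"))
  if (inherits(graph, "cell_subgraph")) graph <- graph$parent
  if (is.data.frame(counts)) {
    counts <- check_expression(counts)
    if (is.null(sample) || !sample %in% names(counts)) {
      stop("supply a valid `sample` column name", call. = FALSE)
    }
    counts <- stats::setNames(counts[[sample]], counts$gene)
  }
  ctx <- capability_context(graph)
  capability_call(ctx, class, counts, threshold)
}

# precomputed biosynthesis submap, adjacency and enzyme set
capability_context <- function(graph) {
  submap <- biosynthesis_submap(graph)
  roles <- node_roles(submap)
  list(submap = submap, idx = graph_index(submap),
       nodes = submap$nodes$node,
       enzymes = submap$nodes$node[roles == "enzyme"])
}

capability_call <- function(ctx, class, counts, threshold) {
  if (!class$precursor %in% ctx$nodes) {
    stop("precursor ", class$precursor,
         " absent from the biosynthesis submap", call. = FALSE)
  }
  expressed <- ctx$enzymes[!is.na(counts[ctx$enzymes]) &
                             counts[ctx$enzymes] >= threshold]
  blocked <- setdiff(ctx$enzymes, expressed)
  witness <- route_bfs(ctx$idx, class$precursor,
                       intersect(class$products, ctx$nodes), blocked)
  out <- !is.null(witness)
  attr(out, "witness") <- witness
  out
}

# BFS skipping blocked (unexpressed enzyme) vertices; lexicographic
# neighbour order gives a deterministic witness
route_bfs <- function(idx, from, to, blocked) {
  if (!length(to) || from %in% blocked) return(NULL)
  if (from %in% to) return(index_path(idx, from))
  parent <- stats::setNames(rep(NA_character_, length(idx$nodes)), idx$nodes)
  seen <- stats::setNames(logical(length(idx$nodes)), idx$nodes)
  seen[from] <- TRUE
  seen[blocked] <- TRUE # never enter blocked vertices
  queue <- from
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    for (v in idx$adj[[u]]) {
      if (!seen[v]) {
        seen[v] <- TRUE
        parent[v] <- u
        if (v %in% to) {
          nodes <- v
          while (!is.na(parent[nodes[1]])) nodes <- c(parent[nodes[1]], nodes)
          return(index_path(idx, unname(nodes)))
        }
        queue <- c(queue, v)
      }
    }
  }
  NULL
}

#' Sample-by-class capability matrix
#'
#' @param graph full `signed_graph`.
#' @param classes named list of `lm_class` objects.
#' @param expr raw count table.
#' @param samples samples to call (default all).
#' @param threshold enzyme expression threshold.
#' @return an `lm_capability` tibble: `sample` column plus one logical
#'   column per class; attribute `witness` is a long tibble of witness
#'   routes.
#' @export
capability_matrix <- function(graph, classes, expr, samples = NULL,
                              threshold = 10) {
  expr <- check_expression(expr)
  if (is.null(samples)) samples <- setdiff(names(expr), "gene")
  ctx <- capability_context(graph)
  rows <- purrr::map(samples, function(smp) {
    counts <- stats::setNames(expr[[smp]], expr$gene)
    calls <- purrr::map(classes, capability_call, ctx = ctx,
                        counts = counts, threshold = threshold)
    wit <- purrr::imap_dfr(calls, function(cc, nm) {
      w <- attr(cc, "witness")
      tibble::tibble(sample = smp, class = nm,
                     witness = if (is.null(w)) NA_character_ else
                       paste(w$nodes, collapse = ";"))
    })
    list(row = tibble::tibble(sample = smp, !!!purrr::map(calls, as.logical)),
         witness = wit)
  })
  out <- purrr::map_dfr(rows, "row")
  attr(out, "witness") <- purrr::map_dfr(rows, "witness")
  class(out) <- c("lm_capability", class(out))
  out
}

#' @rdname capability_matrix
#' @param x an `lm_capability`.
#' @param file output TSV path (0/1 entries).
#' @export
write_capability <- function(x, file) {
  out <- dplyr::mutate(tibble::as_tibble(x),
                       dplyr::across(-"sample", as.integer))
  readr::write_tsv(out, file, progress = FALSE)
  invisible(x)
}

#' @rdname capability_matrix
#' @param object an `lm_capability`.
#' @param ... unused.
#' @method autoplot lm_capability
#' @export
autoplot.lm_capability <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"sample",
                              names_to = "class", values_to = "capable")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$sample,
                                     fill = .data$capable)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey95")) +
    ggplot2::labs(x = "LM class", y = "sample", fill = "capable") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
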
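#' Reverse signal propagation through the regulatory network
#'
#' Regulatory scores arise from a stepwise signal that starts at the LM
#' enzymes of one class (at their topological weights) and travels in
#' reverse through the transcription network: at each step a regulator's
#' score is rebuilt from the scores of its targets, attenuated by the
#' degree product of both endpoints in the original unfiltered network and
#' scaled by the regulator's normalized expression. The update for a
#' transcription factor u is
#' \deqn{s_u(t+1) = \hat q_u \sum_{(u,r,v) \in E_c} r\, s_v(t) /
#'   (deg_G(u)\, deg_G(v))}
#' Enzyme vertices are constant sources (they hold their initial weight);
#' vertices without a measurement (metabolites, complexes, unmeasured
#' genes) relay with expression factor 1 so signal is not lost at curated
#' intermediates. Edge signs multiply the contribution by default, letting
#' inhibitory regulators accumulate negative scores.
#'
#' @name propagation
NULL

# sparse linear operator of one propagation step on a cell subgraph
propagation_operator <- function(gc, degrees = NULL, qhat = NULL,
                                 signed = TRUE) {
  stopifnot(inherits(gc, "cell_subgraph"))
  g <- gc$graph
  nodes <- g$nodes$node
  if (is.null(degrees)) degrees <- node_degrees(gc$parent)
  e <- g$edges
  rel <- if (signed) e$relation else abs(e$relation)
  W <- Matrix::sparseMatrix(
    i = match(e$source, nodes), j = match(e$target, nodes),
    x = rel / (degrees[e$source] * degrees[e$target]),
    dims = c(length(nodes), length(nodes)),
    dimnames = list(nodes, nodes)
  )
  roles <- node_roles(g)
  f <- rep(1, length(nodes))
  names(f) <- nodes
  if (!is.null(qhat)) {
    measured <- intersect(nodes[roles[nodes] %in% c("TF", "gene")], names(qhat))
    f[measured] <- qhat[measured]
  }
  list(W = W, f = f, enzyme = roles[nodes] == "enzyme", nodes = nodes)
}

#' One propagation step
#'
#' Applies the reverse-propagation update once. Exposed mainly for
#' inspection and testing; [run_propagation()] iterates it efficiently.
#'
#' @param gc a `cell_subgraph`.
#' @param scores named numeric vector of current scores (missing vertices
#'   count as 0).
#' @param qhat named numeric vector of normalized read counts in \[0, 1\]
#'   for the sample.
#' @param degrees named degree vector computed on the original unfiltered
#'   graph (see [node_degrees()]); defaults to the parent of `gc`.
#' @param signed propagate edge signs (default) or treat all edges as
#'   activating.
#' @return named numeric vector of next-step scores; enzyme vertices keep
#'   their current (source) value.
#' @export
propagate_step <- function(gc, scores, qhat, degrees = NULL, signed = TRUE) {
  op <- propagation_operator(gc, degrees, qhat, signed)
  s <- stats::setNames(rep(0, length(op$nodes)), op$nodes)
  shared <- intersect(names(scores), op$nodes)
  s[shared] <- scores[shared]
  s_next <- op$f * as.numeric(op$W %*% s)
  s_next[op$enzyme] <- s[op$enzyme]
  stats::setNames(s_next, op$nodes)
}

#' Run the propagation for one LM class
#'
#' @param gc a `cell_subgraph`.
#' @param class an `lm_class`; its enzymes present in the subgraph are the
#'   constant sources.
#' @param weights enzyme starting weights: named numeric vector or the
#'   tibble from [topological_weights()] (filtered to rows of this class or
#'   carrying a `class` column).
#' @param qhat named numeric vector of normalized counts for the sample.
#' @param steps number of signalling steps (default 100).
#' @inheritParams propagate_step
#' @return an `lm_trajectory`: numeric matrix vertices x (steps + 1) with
#'   attributes `class` and `steps`.
#' @export
run_propagation <- function(gc, class, weights, qhat, steps = 100,
                            degrees = NULL, signed = TRUE) {
  stopifnot(inherits(class, "lm_class"))
  weights <- weights_vector(weights, class$name)
  op <- propagation_operator(gc, degrees, qhat, signed)
  s <- stats::setNames(rep(0, length(op$nodes)), op$nodes)
  src <- intersect(class$enzymes, op$nodes)
  s[src] <- weights[src]
  s[is.na(s)] <- 0
  traj <- matrix(0, nrow = length(op$nodes), ncol = steps + 1,
                 dimnames = list(op$nodes, paste0("t", 0:steps)))
  traj[, 1] <- s
  if (steps > 0) {
    for (t in seq_len(steps)) {
      s_next <- op$f * as.numeric(op$W %*% s)
      s_next[op$enzyme] <- s[op$enzyme]
      s <- s_next
      traj[, t + 1] <- s
    }
  }
  if (!all(is.finite(traj))) {
    stop("non-finite score encountered during propagation", call. = FALSE)
  }
  structure(traj, class = c("lm_trajectory", class(traj)),
            lm_class = class$name, steps = steps)
}

weights_vector <- function(weights, class_name) {
  if (is.data.frame(weights)) {
    if ("class" %in% names(weights)) {
      weights <- weights[weights$class == class_name, ]
    }
    stats::setNames(weights$weight, weights$element)
  } else {
    weights
  }
}

#' Regulatory score: area under the propagation trajectory
#'
#' Trapezoidal integral of each vertex's score over the signalling steps.
#' A constant trajectory of value c over 100 steps integrates to 100 c.
#'
#' @param traj an `lm_trajectory` from [run_propagation()].
#' @return named numeric vector of scores `s_bar` per vertex.
#' @export
regulatory_score <- function(traj) {
  if (!all(is.finite(traj))) stop("non-finite value in trajectory", call. = FALSE)
  n <- ncol(traj)
  if (n == 1) {
    return(stats::setNames(rep(0, nrow(traj)), rownames(traj)))
  }
  s <- rowSums((traj[, -n, drop = FALSE] + traj[, -1, drop = FALSE]) / 2)
  stats::setNames(as.numeric(s), rownames(traj))
}

#' @rdname propagation
#' @param x an `lm_trajectory`.
#' @param ... unused.
#' @method tidy lm_trajectory
#' @export
tidy.lm_trajectory <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "step", values_to = "score") |>
    dplyr::mutate(step = as.integer(sub("^t", "", .data$step)),
                  class = attr(x, "lm_class"))
}

#' Per-sample, per-class regulatory score table
#'
#' Runs the whole feature-extraction stage: for every sample, the
#' expression-filtered cell subgraph is built, and for every LM class the
#' reverse propagation is run from the class enzymes (seeded with their
#' topological weights) for `steps` steps; the trapezoidal AUC is the
#' regulatory score. Genes absent from a sample's subgraph score 0.
#'
#' @param graph full `signed_graph` (biosynthesis + TF layer).
#' @param classes named list of `lm_class` objects.
#' @param expr raw count table (`gene` column + sample columns).
#' @param samples samples to score (default: all columns of `expr`).
#' @param threshold expression threshold for subgraph filtering.
#' @param steps propagation steps (default 100).
#' @param signed propagate edge signs (default TRUE).
#' @param graph_overrides optional named list sample -> `signed_graph`
#'   replacing the network for specific samples (e.g. rewired variants).
#' @param genes genes to report; default all TF/gene/enzyme vertices of
#'   `graph` (enzymes hold their source weight, so their score is the
#'   constant trajectory's area, `steps * w`).
#' @return tibble with columns `sample`, `gene`, `class`, `score`.
#' @export
score_table <- function(graph, classes, expr, samples = NULL, threshold = 10,
                        steps = 100, signed = TRUE, graph_overrides = NULL,
                        genes = NULL) {
  expr <- check_expression(expr)
  qhat_tab <- normalize_expression(expr)
  if (is.null(samples)) samples <- setdiff(names(expr), "gene")
  if (is.null(genes)) {
    genes <- sort(graph$nodes$node[graph$nodes$role %in%
                                     c("TF", "gene", "enzyme")])
  }
  base_weights <- topological_weights(biosynthesis_submap(graph), classes)
  base_degrees <- node_degrees(graph)
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    smp <- samples[[i]]
    g <- graph
    weights <- base_weights
    degrees <- base_degrees
    if (!is.null(graph_overrides) && smp %in% names(graph_overrides)) {
      g <- graph_overrides[[smp]]
      weights <- topological_weights(biosynthesis_submap(g), classes)
      degrees <- node_degrees(g)
    }
    gc <- filter_expressed(g, expr, smp, threshold)
    qhat <- stats::setNames(qhat_tab[[smp]], qhat_tab$gene)
    op <- propagation_operator(gc, degrees, qhat, signed)
    per_class <- purrr::map_dfr(classes, function(cl) {
      w <- weights_vector(weights, cl$name)
      s <- stats::setNames(rep(0, length(op$nodes)), op$nodes)
      src <- intersect(cl$enzymes, op$nodes)
      s[src] <- w[src]
      s[is.na(s)] <- 0
      # trapezoidal AUC accumulated on the fly
      auc <- rep(0, length(s))
      for (t in seq_len(steps)) {
        s_next <- op$f * as.numeric(op$W %*% s)
        s_next[op$enzyme] <- s[op$enzyme]
        auc <- auc + (s + s_next) / 2
        s <- s_next
      }
      if (!all(is.finite(auc))) {
        stop("non-finite score during propagation", call. = FALSE)
      }
      full <- stats::setNames(rep(0, length(genes)), genes)
      shared <- intersect(genes, op$nodes)
      full[shared] <- auc[match(shared, op$nodes)]
      tibble::tibble(sample = smp, gene = genes, class = cl$name,
                     score = unname(full))
    })
    out[[i]] <- per_class
  }
  dplyr::bind_rows(out)
}

#' Biosynthesis submap of a full GRN
#'
#' Induced subgraph on all non-TF/gene vertices (metabolites, enzymes,
#' products, phenotypes) -- the curated pathway layer on which topological
#' weights and synthesis-capability calls are defined.
#'
#' @param graph full `signed_graph`.
#' @return `signed_graph`.
#' @export
biosynthesis_submap <- function(graph) {
  induce_subgraph(graph,
                  graph$nodes$node[!graph$nodes$role %in% c("TF", "gene")])
}

#' Read / write long-format score tables
#' @param file path to a TSV with columns sample, gene, class, score.
#' @export
read_score_table <- function(file) {
  readr::read_tsv(file, col_types = "cccd", progress = FALSE)
}

#' @rdname read_score_table
#' @param scores score tibble from [score_table()].
#' @export
write_score_table <- function(scores, file) {
  readr::write_tsv(scores, file, progress = FALSE)
  invisible(scores)
}
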
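#' Run the full LM regulatory-network pipeline
#'
#' End-to-end orchestration on an `lm_dataset` (or equivalently assembled
#' inputs): capability calling, per-sample/per-class regulatory scoring,
#' expression / per-class / combined UMAP embeddings, k-means clustering,
#' the half-normal cluster statistic with BH adjustment, between-cluster
#' delta rankings, divergent-pair ranking, and core regulatory network
#' extraction. All randomness derives from `seed` (stage seeds are
#' `seed`, `seed + 1`, ... in a fixed order), so two runs with the same
#' inputs and seed are identical.
#'
#' @param dataset an `lm_dataset` from [simulate_lm_dataset()], or a list
#'   with elements `graph`, `classes`, `expr` (raw counts), optionally
#'   `metadata` and `graph_overrides`.
#' @param k number of k-means clusters (the manually adjusted choice;
#'   defaults to the generator's cluster count when known, else 3).
#' @param seed master seed for the embedding/clustering stages.
#' @param threshold expression threshold (default 10).
#' @param steps propagation steps (default 100).
#' @param signed propagate edge signs (default TRUE).
#' @param alpha adjusted-p significance level (default 0.05).
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param delta_k top TFs per class in the delta ranking (default 3).
#' @param crn_classes classes for which CRNs are extracted for the first
#'   sample (default: the first class; widest-path trees are per TF and
#'   per class, so this is the expensive stage).
#' @return an `lm_bundle`: named list with elements `capability`,
#'   `scores`, `embeddings` (list: `expression`, per class, `combined`),
#'   `clusters`, `tests`, `significant`, `delta`, `divergent`, `crns`,
#'   `config`.
#' @export
run_lm_pipeline <- function(dataset, k = NULL, seed = 42, threshold = 10,
                            steps = 100, signed = TRUE, alpha = 0.05,
                            n_neighbors = 15, min_dist = 0.1, delta_k = 3,
                            crn_classes = NULL) {
  stopifnot(is.list(dataset),
            all(c("graph", "classes", "expr") %in% names(dataset)))
  graph <- dataset$graph
  classes <- dataset$classes
  expr <- check_expression(dataset$expr)
  samples <- setdiff(names(expr), "gene")
  if (is.null(k)) {
    k <- if (!is.null(dataset$truth)) {
      max(2L, dataset$truth$params$n_clusters)
    } else 3L
  }
  qhat <- normalize_expression(expr)

  capability <- capability_matrix(graph, classes, expr, threshold = threshold)
  scores <- score_table(graph, classes, expr, threshold = threshold,
                        steps = steps, signed = signed,
                        graph_overrides = dataset$graph_overrides)

  # expression-based embedding over the network genes
  net_genes <- intersect(qhat$gene, graph$nodes$node)
  qt <- t(as.matrix(qhat[match(net_genes, qhat$gene), samples]))
  colnames(qt) <- net_genes
  expr_features <- dplyr::bind_cols(tibble::tibble(sample = samples),
                                    tibble::as_tibble(qt))
  emb_expr <- embed_features(expr_features, seed = seed,
                             n_neighbors = n_neighbors, min_dist = min_dist,
                             feature_set = "expression")

  tf_genes <- sort(graph$nodes$node[graph$nodes$role == "TF"])
  class_embs <- purrr::imap(classes, function(cl, nm) {
    feat <- scores |>
      dplyr::filter(.data$class == nm, .data$gene %in% tf_genes) |>
      dplyr::select("sample", "gene", "score") |>
      tidyr::pivot_wider(names_from = "gene", values_from = "score")
    embed_features(feat, seed = seed + 1, n_neighbors = n_neighbors,
                   min_dist = min_dist, feature_set = paste0("scores_", nm))
  })
  emb_combined <- combine_class_embeddings(class_embs, seed = seed + 2,
                                           n_neighbors = n_neighbors,
                                           min_dist = min_dist)

  clusters <- cluster_embedding(emb_combined, k = k, seed = seed + 3)
  tests <- cluster_feature_tests(scores, qhat, clusters)
  significant <- significant_cluster_genes(tests, alpha = alpha)

  # delta ranking: cluster 0 vs cluster 1 mean scores per class
  delta <- NULL
  if (length(unique(clusters$cluster)) >= 2) {
    cl_ids <- sort(unique(clusters$cluster))[1:2]
    mean_scores <- scores |>
      dplyr::filter(.data$gene %in% tf_genes) |>
      dplyr::left_join(tibble::as_tibble(clusters), by = "sample") |>
      dplyr::filter(.data$cluster %in% cl_ids) |>
      dplyr::group_by(.data$class, .data$gene, .data$cluster) |>
      dplyr::summarise(score = mean(.data$score), .groups = "drop")
    delta <- purrr::map_dfr(names(classes), function(nm) {
      sl <- mean_scores[mean_scores$class == nm, ]
      a <- sl[sl$cluster == cl_ids[1], c("gene", "score")]
      b <- sl[sl$cluster == cl_ids[2], c("gene", "score")]
      dplyr::mutate(tibble::as_tibble(rank_delta_tfs(a, b, k = delta_k)),
                    class = nm, .before = 1)
    })
  }

  score_features <- scores |>
    dplyr::filter(.data$gene %in% tf_genes) |>
    tidyr::pivot_wider(names_from = c("class", "gene"),
                       values_from = "score")
  divergent <- rank_divergent_pairs(expr_features, score_features)

  if (is.null(crn_classes)) crn_classes <- names(classes)[1]
  unknown <- setdiff(crn_classes, names(classes))
  if (length(unknown)) {
    stop("unknown class name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  first_sample <- samples[1]
  gc1 <- filter_expressed(graph, expr, first_sample, threshold)
  crns <- purrr::map(rlang::set_names(crn_classes), function(nm) {
    sl <- scores[scores$class == nm & scores$sample == first_sample, ]
    extract_crn(gc1, stats::setNames(sl$score, sl$gene), classes[[nm]],
                mode = "single")
  })

  structure(
    list(
      capability = capability, scores = scores,
      embeddings = c(list(expression = emb_expr), class_embs,
                     list(combined = emb_combined)),
      clusters = clusters, tests = tests, significant = significant,
      delta = delta, divergent = divergent, crns = crns,
      config = list(k = k, seed = seed, threshold = threshold, steps = steps,
                    signed = signed, alpha = alpha,
                    n_neighbors = n_neighbors, min_dist = min_dist,
                    delta_k = delta_k, crn_classes = crn_classes,
                    crn_sample = first_sample)
    ),
    class = "lm_bundle"
  )
}

#' @export
print.lm_bundle <- function(x, ...) {
  cat("<lm_bundle> ", nrow(x$capability), " samples, ",
      length(x$embeddings) - 2, " LM classes, k = ", x$config$k, "\n",
      "  significant cluster genes: ", nrow(x$significant), "\n", sep = "")
  invisible(x)
}

#' Write a pipeline bundle to disk
#'
#' Emits TSV tables for every tabular artifact, GraphML for the CRNs and a
#' JSON copy of the configuration.
#'
#' @param bundle an `lm_bundle` from [run_lm_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_lm_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  w <- function(x, name) {
    path <- file.path(dir, name)
    readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
    files <<- c(files, path)
  }
  write_capability(bundle$capability, file.path(dir, "capability.tsv"))
  files <- c(files, file.path(dir, "capability.tsv"))
  w(bundle$scores, "scores.tsv")
  for (nm in names(bundle$embeddings)) {
    emb <- bundle$embeddings[[nm]]
    w(dplyr::mutate(tibble::as_tibble(emb),
                    feature_set = attr(emb, "feature_set"),
                    seed = attr(emb, "seed")),
      paste0("embedding_", nm, ".tsv"))
  }
  w(bundle$clusters, "clusters.tsv")
  w(bundle$tests, "tests.tsv")
  w(bundle$significant, "significant_genes.tsv")
  if (!is.null(bundle$delta)) w(bundle$delta, "delta_ranking.tsv")
  w(bundle$divergent, "divergent_pairs.tsv")
  for (nm in names(bundle$crns)) {
    path <- file.path(dir, paste0("crn_", nm, ".graphml"))
    write_graphml(bundle$crns[[nm]]$graph, path,
                  score = bundle$crns[[nm]]$node_scores)
    files <- c(files, path)
  }
  cfg <- file.path(dir, "config.json")
  jsonlite::write_json(bundle$config, cfg, auto_unbox = TRUE, digits = NA)
  files <- c(files, cfg)
  invisible(files)
}
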
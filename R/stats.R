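#' Half-normal cluster statistic for one feature
#'
#' Regulatory scores are biased towards expression (propagation multiplies
#' by q-hat), so cluster-specific regulation is tested against that trend
#' rather than by score magnitude. The out-of-cluster cells fit an ordinary
#' least-squares line of score on normalized expression; the absolute
#' vertical residuals of those cells define a half-normal distribution
#' (scale `sigma` with `sigma^2` the mean squared distance). The cluster
#' statistic is the mean absolute residual `d_bar` of the in-cluster cells
#' relative to that line; its z-score against the half-normal mean
#' `sigma * sqrt(2/pi)` with standard error
#' `sigma * sqrt(1 - 2/pi) / sqrt(n_cluster)` yields a one-sided upper-tail
#' normal p-value: only clusters whose cells sit unusually far from the
#' cohort trend (distinct regulation) are called.
#'
#' @param qhat normalized expression of the gene per sample, in \[0, 1\].
#' @param score regulatory score of the gene per sample.
#' @param in_cluster logical mask of cluster membership (same length);
#'   needs at least 3 out-of-cluster and 1 in-cluster sample.
#' @return one-row tibble: `slope`, `intercept`, `sigma`, `d_bar`, `z`,
#'   `p_value`, `n_cluster`, `n_out`, `degenerate`.
#' @export
cluster_feature_pvalue <- function(qhat, score, in_cluster) {
  stopifnot(length(qhat) == length(score), length(score) == length(in_cluster))
  in_cluster <- as.logical(in_cluster)
  n_in <- sum(in_cluster)
  n_out <- sum(!in_cluster)
  if (n_in < 1) stop("need at least 1 in-cluster sample", call. = FALSE)
  if (n_out < 3) stop("need at least 3 out-of-cluster samples", call. = FALSE)
  qo <- qhat[!in_cluster]
  so <- score[!in_cluster]
  sxx <- mean(qo^2) - mean(qo)^2
  degenerate <- sxx <= 0
  b <- if (degenerate) 0 else (mean(qo * so) - mean(qo) * mean(so)) / sxx
  a <- mean(so) - b * mean(qo)
  sigma <- sqrt(mean(abs(so - (a + b * qo))^2))
  d_bar <- mean(abs(score[in_cluster] - (a + b * qhat[in_cluster])))
  if (sigma > 0) {
    mu_hn <- sigma * sqrt(2 / pi)
    se_hn <- sigma * sqrt(1 - 2 / pi) / sqrt(n_in)
    z <- (d_bar - mu_hn) / se_hn
    p <- stats::pnorm(z, lower.tail = FALSE)
  } else {
    z <- if (d_bar > 0) Inf else 0
    p <- if (d_bar > 0) 0 else 0.5
  }
  tibble::tibble(slope = b, intercept = a, sigma = sigma, d_bar = d_bar,
                 z = z, p_value = p, n_cluster = n_in, n_out = n_out,
                 degenerate = degenerate)
}

#' Cluster-specific regulator tests over all genes, classes and clusters
#'
#' Vectorized application of [cluster_feature_pvalue()] to every
#' (gene, class, cluster) combination, with Benjamini-Hochberg adjustment
#' within each (cluster, class) family -- the smallest unit in which gene
#' lists are reported.
#'
#' @param scores long score table (`sample`, `gene`, `class`, `score`).
#' @param qhat normalized expression table (`gene` column + sample columns),
#'   e.g. from [normalize_expression()].
#' @param clusters `lm_clusters` tibble (`sample`, `cluster`).
#' @return tibble `cluster`, `class`, `gene`, `slope`, `intercept`,
#'   `sigma`, `d_bar`, `z`, `p_value`, `adj_p`, `degenerate`.
#' @export
cluster_feature_tests <- function(scores, qhat, clusters) {
  clusters <- tibble::as_tibble(clusters)
  stopifnot(all(c("sample", "cluster") %in% names(clusters)))
  samples <- clusters$sample
  qm <- as.matrix(qhat[setdiff(names(qhat), "gene")])
  rownames(qm) <- qhat$gene

  out <- list()
  for (cl_name in sort(unique(scores$class))) {
    sl <- scores[scores$class == cl_name, ]
    sm <- tidyr::pivot_wider(sl[c("sample", "gene", "score")],
                             names_from = "sample", values_from = "score")
    genes <- sm$gene
    S <- as.matrix(sm[samples])
    Q <- matrix(0, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
    shared <- intersect(genes, rownames(qm))
    Q[shared, ] <- qm[shared, samples]
    for (k in sort(unique(clusters$cluster))) {
      inc <- clusters$cluster == k
      n_in <- sum(inc)
      n_out <- sum(!inc)
      Qo <- Q[, !inc, drop = FALSE]
      So <- S[, !inc, drop = FALSE]
      mx <- rowMeans(Qo)
      my <- rowMeans(So)
      sxx <- rowMeans(Qo^2) - mx^2
      degen <- sxx <= 0
      b <- ifelse(degen, 0, (rowMeans(Qo * So) - mx * my) / pmax(sxx, 1e-300))
      a <- my - b * mx
      sigma <- sqrt(rowMeans((So - (a + b * Qo))^2))
      d_bar <- rowMeans(abs(S[, inc, drop = FALSE] -
                              (a + b * Q[, inc, drop = FALSE])))
      mu_hn <- sigma * sqrt(2 / pi)
      se_hn <- sigma * sqrt(1 - 2 / pi) / sqrt(n_in)
      z <- ifelse(sigma > 0, (d_bar - mu_hn) / se_hn,
                  ifelse(d_bar > 0, Inf, 0))
      p <- ifelse(sigma > 0, stats::pnorm(z, lower.tail = FALSE),
                  ifelse(d_bar > 0, 0, 0.5))
      out[[length(out) + 1]] <- tibble::tibble(
        cluster = k, class = cl_name, gene = genes, slope = unname(b),
        intercept = unname(a), sigma = unname(sigma), d_bar = unname(d_bar),
        z = unname(z), p_value = unname(p), degenerate = unname(degen)
      )
    }
  }
  res <- dplyr::bind_rows(out) |>
    dplyr::group_by(.data$cluster, .data$class) |>
    dplyr::mutate(adj_p = adjust_pvalues(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::relocate("adj_p", .after = "p_value")
  class(res) <- c("lm_cluster_tests", class(res))
  res
}

#' Benjamini-Hochberg adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (monotone, bounded by 1, never below input).
#' @export
adjust_pvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Significant cluster-specific regulators
#'
#' Genes with adjusted p below `alpha` for at least one LM class in a
#' cluster, with the best-supported class recorded per gene.
#'
#' @param results tibble from [cluster_feature_tests()].
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return tibble `cluster`, `gene`, `best_class`, `adj_p` (best class's),
#'   `n_classes_significant`.
#' @export
significant_cluster_genes <- function(results, alpha = 0.05) {
  results |>
    dplyr::filter(.data$adj_p < alpha) |>
    dplyr::group_by(.data$cluster, .data$gene) |>
    dplyr::arrange(.data$adj_p, .data$p_value, .data$class, .by_group = TRUE) |>
    dplyr::summarise(best_class = dplyr::first(.data$class),
                     adj_p = dplyr::first(.data$adj_p),
                     n_classes_significant = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$cluster, .data$adj_p, .data$gene)
}

#' Rank transcription factors by regulatory-score change
#'
#' Between two conditions (samples, time points, or averaged sets), the
#' score change per TF is `delta = score_b - score_a` over the union of
#' genes (0 for genes absent from one side). The default ranks by
#' decreasing delta ("increasing association"); `by = "abs"` ranks by
#' magnitude. Ties break deterministically by gene id.
#'
#' @param scores_a,scores_b two-column data frames (`gene`, `score`) or
#'   named numeric vectors; slices of a score table for one class.
#' @param k how many top TFs to return (default 3).
#' @param by `"delta"` (signed, decreasing) or `"abs"`.
#' @return an `lm_delta_ranking` tibble `gene`, `score_a`, `score_b`,
#'   `delta`, restricted to the top `k`.
#' @export
rank_delta_tfs <- function(scores_a, scores_b, k = 3, by = c("delta", "abs")) {
  by <- match.arg(by)
  va <- scores_as_vector(scores_a)
  vb <- scores_as_vector(scores_b)
  if (!length(intersect(names(va), names(vb)))) {
    stop("score slices share no genes", call. = FALSE)
  }
  genes <- sort(union(names(va), names(vb)))
  a <- ifelse(genes %in% names(va), va[genes], 0)
  b <- ifelse(genes %in% names(vb), vb[genes], 0)
  out <- tibble::tibble(gene = genes, score_a = unname(a),
                        score_b = unname(b), delta = unname(b - a))
  key <- if (by == "abs") abs(out$delta) else out$delta
  out <- out[order(-key, out$gene), ]
  out <- utils::head(out, k)
  structure(out, class = c("lm_delta_ranking", class(tibble::tibble())),
            by = by, k = k)
}

scores_as_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("gene", "score") %in% names(x)))
    v <- stats::setNames(x$score, x$gene)
  } else {
    v <- x
  }
  if (anyDuplicated(names(v))) stop("duplicate gene ids in score slice",
                                    call. = FALSE)
  v
}

#' @rdname cluster_feature_tests
#' @param object results tibble from [cluster_feature_tests()].
#' @param alpha significance threshold drawn on the plot.
#' @param ... unused.
#' @method autoplot lm_cluster_tests
#' @export
autoplot.lm_cluster_tests <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z,
                                   y = -log10(pmax(.data$adj_p, 1e-300)),
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "z-score", y = "-log10 adjusted p", colour = "cluster") +
    ggplot2::theme_minimal()
}
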
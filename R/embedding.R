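#' UMAP embedding of samples
#'
#' Two-dimensional UMAP of a samples x features table, run single-threaded
#' with a fixed seed so coordinates are exactly reproducible. Duplicate
#' feature rows are collapsed before embedding and share coordinates
#' afterwards, so identical samples are guaranteed identical positions.
#'
#' @param features data frame: `sample` column plus numeric feature
#'   columns; at least 3 samples, no missing/non-finite values.
#' @param seed integer random seed.
#' @param n_neighbors,min_dist UMAP hyperparameters (defaults 15 and 0.1,
#'   Euclidean metric); `n_neighbors` is capped at one less than the number
#'   of distinct rows.
#' @param feature_set provenance label stored on the result.
#' @return an `lm_embedding` tibble with columns `sample`, `x`, `y` and
#'   provenance attributes (`feature_set`, `seed`, `params`).
#' @export
embed_features <- function(features, seed = 42, n_neighbors = 15,
                           min_dist = 0.1, feature_set = "features") {
  features <- tibble::as_tibble(features)
  if (!"sample" %in% names(features)) {
    stop("`features` needs a `sample` column", call. = FALSE)
  }
  m <- as.matrix(features[setdiff(names(features), "sample")])
  if (nrow(m) < 3) stop("need at least 3 samples", call. = FALSE)
  if (!is.numeric(m) || !all(is.finite(m))) {
    stop("non-finite feature value", call. = FALSE)
  }
  rownames(m) <- features$sample
  key <- apply(m, 1, paste, collapse = "\r")
  uniq <- !duplicated(key)
  mu <- m[uniq, , drop = FALSE]
  nn <- max(2, min(n_neighbors, nrow(mu) - 1))
  coords <- withr::with_seed(seed, {
    uwot::umap(mu, n_neighbors = nn, min_dist = min_dist, metric = "euclidean",
               init = pca_range_init(mu), n_threads = 1,
               n_sgd_threads = 1, verbose = FALSE)
  })
  coords <- coords[match(key, key[uniq]), , drop = FALSE]
  out <- tibble::tibble(sample = features$sample,
                        x = coords[, 1], y = coords[, 2])
  structure(out, class = c("lm_embedding", class(out)),
            feature_set = feature_set, seed = seed,
            params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                          metric = "euclidean"))
}

# deterministic two-component PCA initialization with columns rescaled to
# a fixed range: the embedding then depends on the input only through its
# pairwise distances (up to axis flips), so duplicated or uniformly
# rescaled feature blocks reproduce the same layout
pca_range_init <- function(m) {
  sc <- stats::prcomp(m, rank. = 2)$x
  if (ncol(sc) < 2) sc <- cbind(sc, 0, 0)[, 1:2, drop = FALSE]
  apply(sc, 2, function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0, length(v)) else 10 * (v - min(v)) / r - 5
  })
}

#' Combine per-class embeddings into one UMAP
#'
#' Concatenates the (x, y) coordinates of each class embedding into a
#' samples x (2 x classes) matrix, rescaled by the square root of the
#' number of classes (so the combined metric averages rather than sums
#' across classes), and embeds that again, giving one map that summarizes
#' regulatory similarity across all LM classes.
#'
#' @param embeddings named list of `lm_embedding` objects covering the same
#'   samples.
#' @inheritParams embed_features
#' @return an `lm_embedding`.
#' @export
combine_class_embeddings <- function(embeddings, seed = 42, n_neighbors = 15,
                                     min_dist = 0.1) {
  stopifnot(length(embeddings) >= 1)
  samples <- sort(embeddings[[1]]$sample)
  for (e in embeddings) {
    if (!identical(sort(e$sample), samples)) {
      stop("embeddings cover different samples", call. = FALSE)
    }
  }
  if (is.null(names(embeddings))) {
    names(embeddings) <- paste0("class", seq_along(embeddings))
  }
  wide <- purrr::imap(embeddings, function(e, nm) {
    e <- e[match(samples, e$sample), ]
    stats::setNames(tibble::tibble(e$x, e$y), paste0(nm, c("_x", "_y")))
  })
  features <- dplyr::bind_cols(tibble::tibble(sample = samples), wide)
  scale_cols <- setdiff(names(features), "sample")
  features[scale_cols] <- features[scale_cols] / sqrt(length(embeddings))
  embed_features(features, seed = seed, n_neighbors = n_neighbors,
                 min_dist = min_dist, feature_set = "combined_classes")
}

#' k-means clustering of an embedding
#'
#' k-means on the 2-D coordinates with a fixed seed; k is supplied by the
#' analyst (the "manual adjustment" step -- no automatic model selection).
#' Cluster ids are relabelled 0..k-1 in order of first appearance, making
#' labels deterministic. When k equals the number of distinct coordinate
#' points the exact zero-inertia solution (one cluster per distinct point)
#' is returned directly.
#'
#' @param emb an `lm_embedding` (or any data frame with `sample`, `x`, `y`).
#' @param k number of clusters (2 <= k < n samples, and at most the number
#'   of distinct points).
#' @param seed integer seed.
#' @param n_init number of k-means restarts (default 10).
#' @return an `lm_clusters` tibble `sample`, `cluster` with attributes `k`
#'   and `inertia`.
#' @export
cluster_embedding <- function(emb, k, seed = 42, n_init = 10) {
  emb <- tibble::as_tibble(emb)
  stopifnot(all(c("sample", "x", "y") %in% names(emb)))
  m <- as.matrix(emb[c("x", "y")])
  n_distinct_pts <- nrow(unique(m))
  if (k < 2 || k > n_distinct_pts) {
    stop("k must satisfy 2 <= k <= number of distinct points", call. = FALSE)
  }
  if (k == n_distinct_pts) {
    key <- apply(m, 1, paste, collapse = "\r")
    raw <- match(key, unique(key))
    inertia <- 0
  } else {
    km <- withr::with_seed(seed, stats::kmeans(m, centers = k, nstart = n_init,
                                               iter.max = 100))
    raw <- km$cluster
    inertia <- km$tot.withinss
  }
  relabel <- match(raw, unique(raw)) - 1L
  structure(tibble::tibble(sample = emb$sample, cluster = relabel),
            class = c("lm_clusters", class(tibble::tibble())),
            k = k, inertia = inertia, seed = seed)
}

#' Within-cluster sum of squares across a range of k (elbow helper)
#'
#' @param emb an `lm_embedding`.
#' @param ks integer vector of cluster counts to evaluate.
#' @param seed,n_init passed to [cluster_embedding()].
#' @return tibble `k`, `inertia`.
#' @export
kmeans_elbow <- function(emb, ks = 2:8, seed = 42, n_init = 10) {
  tibble::tibble(
    k = ks,
    inertia = purrr::map_dbl(ks, function(k) {
      attr(cluster_embedding(emb, k, seed = seed, n_init = n_init), "inertia")
    })
  )
}

#' Rank sample pairs close in expression but distant in regulation
#'
#' For every unordered sample pair, the Euclidean distance is computed in
#' an expression-based and a regulatory-network-based feature space;
#' distances are converted to percentile ranks within each space (their
#' scales are not comparable) and the divergence score is the rank
#' difference (network minus expression). High scores flag pairs of cells
#' with near-identical transcriptomes but clearly different regulatory
#' wiring. Inputs may be any samples-by-features tables -- full feature
#' matrices (recommended: distances are then stable) or 2-D embeddings
#' (`lm_embedding` objects, using their coordinates).
#'
#' @param expr_feat,net_feat data frames with a `sample` column plus
#'   numeric feature columns, covering the same samples: e.g. normalized
#'   expression features and per-class regulatory-score features (or
#'   embeddings thereof).
#' @param top_n number of pairs to return (default all).
#' @return tibble `sample_a`, `sample_b`, `dist_expr`, `dist_net`,
#'   `rank_expr`, `rank_net`, `score`, sorted by decreasing score with
#'   lexicographic tie-break.
#' @export
rank_divergent_pairs <- function(expr_feat, net_feat, top_n = Inf) {
  a <- tibble::as_tibble(expr_feat)
  b <- tibble::as_tibble(net_feat)
  stopifnot("sample" %in% names(a), "sample" %in% names(b))
  if (nrow(a) < 2) stop("need at least 2 samples", call. = FALSE)
  if (!setequal(a$sample, b$sample)) {
    stop("feature tables cover different samples", call. = FALSE)
  }
  b <- b[match(a$sample, b$sample), ]
  d_expr <- as.matrix(stats::dist(as.matrix(a[setdiff(names(a), "sample")])))
  d_net <- as.matrix(stats::dist(as.matrix(b[setdiff(names(b), "sample")])))
  ij <- which(upper.tri(d_expr), arr.ind = TRUE)
  # order each pair lexicographically for stable ids
  s1 <- a$sample[ij[, 1]]
  s2 <- a$sample[ij[, 2]]
  swap <- s1 > s2
  pairs <- tibble::tibble(
    sample_a = ifelse(swap, s2, s1),
    sample_b = ifelse(swap, s1, s2),
    dist_expr = d_expr[ij],
    dist_net = d_net[ij]
  )
  n <- nrow(pairs)
  pairs$rank_expr <- (rank(pairs$dist_expr, ties.method = "average") - 1) /
    max(1, n - 1)
  pairs$rank_net <- (rank(pairs$dist_net, ties.method = "average") - 1) /
    max(1, n - 1)
  pairs$score <- pairs$rank_net - pairs$rank_expr
  pairs <- dplyr::arrange(pairs, dplyr::desc(.data$score), .data$sample_a,
                          .data$sample_b)
  utils::head(pairs, top_n)
}

#' @rdname embed_features
#' @param object an `lm_embedding`.
#' @param colour_by optional vector (aligned with samples) to colour points.
#' @param ... unused.
#' @method autoplot lm_embedding
#' @export
autoplot.lm_embedding <- function(object, colour_by = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- if (is.null(colour_by)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  } else {
    df$colour_by <- factor(colour_by)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$colour_by))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = paste("UMAP:", attr(object, "feature_set")),
                  x = "UMAP 1", y = "UMAP 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname embed_features
#' @param x an `lm_embedding`.
#' @method glance lm_embedding
#' @export
glance.lm_embedding <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(n_samples = nrow(x), feature_set = attr(x, "feature_set"),
                 seed = attr(x, "seed"), n_neighbors = p$n_neighbors,
                 min_dist = p$min_dist, metric = p$metric)
}
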
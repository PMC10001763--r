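#' Synthetic cohorts with planted regulatory ground truth
#'
#' The generator emulates the shape of the study's real inputs -- a curated
#' biosynthesis map per LM class, a signed transcription-factor layer, and
#' bulk-sorted count matrices over immune-cell samples -- while planting
#' recorded structure so every pipeline stage can be validated end to end:
#' cluster-specific regulators (a TF whose own and whose target-TFs'
#' expression is raised in one cluster), per-cluster synthesis capabilities
#' (enforced by flooring route enzymes at the expression threshold in
#' capable clusters and capping one gating enzyme below it elsewhere), and
#' one "divergent" sample that duplicates another cell's expression exactly
#' but loses its TF-to-enzyme wiring in a rewired network variant.
#'
#' @name synthetic-data
NULL

#' Default LM class table
#'
#' Eight classes spanning the three precursor fatty acids: five
#' AA-derived (prostaglandin D and E series, thromboxanes, leukotrienes,
#' lipoxins), one EPA-derived (E-series resolvins) and two DHA-derived
#' (D-series resolvins, protectins).
#'
#' @return tibble `class`, `precursor`.
#' @export
lm_default_class_table <- function() {
  tibble::tibble(
    class = c("prostaglandins_D", "prostaglandins_E", "thromboxanes",
              "leukotrienes", "lipoxins", "e_resolvins", "d_resolvins",
              "protectins"),
    precursor = c("AA", "AA", "AA", "AA", "AA", "EPA", "DHA", "DHA")
  )
}

#' Generate a synthetic signed GRN with LM-class submaps
#'
#' Builds, per class, an acyclic biosynthesis chain or two-branch DAG of
#' enzymes via [transform_catalysis()], and a signed TF layer wired to
#' enzymes and other TFs. When the TF budget allows, one regulator per
#' cluster is planted (wired through two intermediate TFs to the enzymes
#' of two designated classes).
#'
#' @param n_tf number of transcription factors (default 120).
#' @param n_enzymes total enzymes distributed over classes (default 30;
#'   must be at least the number of classes).
#' @param n_classes number of LM classes, up to 8 (default 8).
#' @param n_clusters clusters for which regulators are planted (default 3).
#' @param neg_prob probability that a random TF edge is inhibiting
#'   (default 0.2).
#' @param seed integer seed.
#' @return list with `$graph` (`signed_graph`), `$classes` (named list of
#'   [lm_class()]), and `$truth` (planted wiring: regulators,
#'   intermediates).
#' @export
generate_grn <- function(n_tf = 120, n_enzymes = 30, n_classes = 8,
                         n_clusters = 3, neg_prob = 0.2, seed = 0) {
  if (n_enzymes < n_classes) {
    stop("need at least one enzyme per class", call. = FALSE)
  }
  class_tab <- utils::head(lm_default_class_table(), n_classes)
  per_class <- rep(n_enzymes %/% n_classes, n_classes) +
    (seq_len(n_classes) <= n_enzymes %% n_classes)
  enz_ids <- sprintf("Enz%02d", seq_len(n_enzymes))

  reactions <- list()
  classes <- list()
  offset <- 0
  for (i in seq_len(n_classes)) {
    cl <- class_tab$class[i]
    pre <- class_tab$precursor[i]
    enz <- enz_ids[offset + seq_len(per_class[i])]
    offset <- offset + per_class[i]
    met <- function(j) sprintf("Met_%s_%d", cl, j)
    prod_a <- sprintf("Prod_%s_a", cl)
    if (per_class[i] >= 4) {
      # two-branch DAG: shared first step, then a long and a short branch
      prod_b <- sprintf("Prod_%s_b", cl)
      n_long <- per_class[i] - 2
      chain <- c(met(1), if (n_long > 1) vapply(1 + seq_len(n_long - 1), met, ""),
                 prod_a)
      rx <- tibble::tibble(
        substrate = c(pre, chain[-length(chain)], met(1)),
        enzyme = enz,
        product = c(met(1), chain[-1], prod_b)
      )
      products <- c(prod_a, prod_b)
    } else {
      nodes <- c(pre, vapply(seq_len(per_class[i] - 1), met, ""), prod_a)
      rx <- tibble::tibble(substrate = nodes[-length(nodes)], enzyme = enz,
                           product = nodes[-1])
      products <- prod_a
    }
    reactions[[cl]] <- rx
    classes[[cl]] <- lm_class(cl, pre, products, enz)
  }
  submap <- transform_catalysis(dplyr::bind_rows(reactions))
  # mark terminal products
  submap$nodes$role[grepl("^Prod_", submap$nodes$node)] <- "product"

  tf_ids <- sprintf("Tf%03d", seq_len(n_tf))
  first_enzyme <- purrr::map_chr(classes, ~ .x$enzymes[1])

  planted <- tibble::tibble(cluster = integer(), tf = character())
  tf_edges <- list()
  n_reserved <- 0
  plant <- n_tf >= 4 * n_clusters && n_clusters >= 1 && n_classes >= 2
  if (plant) {
    # one regulator + two intermediate TFs per cluster
    for (j in seq_len(n_clusters)) {
      reg <- tf_ids[n_reserved + 1]
      ints <- tf_ids[n_reserved + 2:3]
      n_reserved <- n_reserved + 3
      cls <- names(classes)[(2 * (j - 1)) %% n_classes + 1:2]
      cls <- cls[!is.na(cls)]
      tf_edges[[length(tf_edges) + 1]] <- tibble::tibble(
        source = reg, relation = 1L, target = ints
      )
      for (int in ints) {
        tf_edges[[length(tf_edges) + 1]] <- tibble::tibble(
          source = int, relation = 1L,
          target = unname(first_enzyme[cls])
        )
      }
      planted <- dplyr::bind_rows(planted, tibble::tibble(
        cluster = j - 1L, tf = reg, classes = list(cls),
        intermediates = list(ints)
      ))
    }
  }
  free_tfs <- tf_ids[(n_reserved + 1):n_tf]
  random_edges <- withr::with_seed(seed, {
    purrr::map_dfr(free_tfs, function(tf) {
      n_e <- sample(1:3, 1)
      targ_e <- sample(enz_ids, min(n_e, n_enzymes))
      others <- setdiff(tf_ids, tf)
      targ_t <- if (length(others) && stats::runif(1) < 0.4) {
        sample(others, 1)
      } else {
        character(0)
      }
      targ <- c(targ_e, targ_t)
      tibble::tibble(source = tf, target = targ,
                     relation = ifelse(stats::runif(length(targ)) < neg_prob,
                                       -1L, 1L))
    })
  })
  tf_layer <- signed_graph(
    dplyr::bind_rows(c(tf_edges, list(random_edges))),
    nodes = dplyr::bind_rows(tibble::tibble(node = tf_ids, role = "TF"),
                             tibble::tibble(node = enz_ids, role = "enzyme"))
  )
  graph <- merge_networks(submap, tf_layer)
  list(
    graph = graph, classes = classes,
    truth = list(planted_regulators = planted,
                 first_enzyme = first_enzyme,
                 params = list(n_tf = n_tf, n_enzymes = n_enzymes,
                               n_classes = n_classes, n_clusters = n_clusters,
                               neg_prob = neg_prob, seed = seed))
  )
}

#' Generate a synthetic count matrix over clustered samples
#'
#' Counts are negative-binomial around log-normal per-gene baselines
#' modulated by per-cluster cell-type profiles (overdispersed RNA-seq-like
#' noise with cluster-structured means; `dispersion = 0` gives Poisson).
#' In each cluster the planted regulator and its intermediate TFs are
#' raised by `effect_size`; withheld LM classes get a gating enzyme capped
#' below the expression threshold while capable clusters have route
#' enzymes floored at it; the divergent twin sample duplicates the first
#' cluster-0 sample's counts exactly and carries a rewired network variant
#' (all TF-to-enzyme edges dropped: identical transcriptome,
#' disconnected regulation) in `$graph_overrides`.
#'
#' @param grn result of [generate_grn()].
#' @param cells_per_cluster samples per cluster (default 30).
#' @param effect_size multiplicative expression effect of planted
#'   regulators in their cluster (default 5; 1 = null mode).
#' @param dispersion negative-binomial dispersion (default 0.3; 0 =
#'   Poisson).
#' @param cluster_sd standard deviation (log scale) of per-gene,
#'   per-cluster expression factors (default 0.5, i.e. typical 1.6-fold
#'   between-cluster differences): every gene carries a cell-type profile,
#'   giving the cluster-structured expression of real sorted immune-cell
#'   cohorts. Set 0 for exchangeable clusters.
#' @param threshold expression threshold the capability planting is
#'   enforced against (default 10).
#' @param capable_classes named/indexed list: for each cluster (0-based
#'   order) the class names it can synthesize. Default: cluster 0 all
#'   classes (myeloid-like), cluster 1 the AA-derived classes only,
#'   cluster 2 and beyond none (lymphoid-like).
#' @param divergent_pair plant the duplicated/rewired sample pair
#'   (default TRUE).
#' @param pair_boost factor applied to the divergent cell's TF counts
#'   (default 3): the duplicated cell is a transcriptionally highly active
#'   one, so that its regulatory score profile is strong and the contrast
#'   with the rewired twin is informative rather than noise-sized.
#' @param seed integer seed.
#' @return an `lm_dataset`: list with `$graph`, `$classes`, `$expr` (raw
#'   counts), `$metadata`, `$graph_overrides`, `$truth` (an `lm_truth`).
#' @export
generate_expression <- function(grn, cells_per_cluster = 30, effect_size = 5,
                                dispersion = 0.3, threshold = 10,
                                capable_classes = NULL, divergent_pair = TRUE,
                                pair_boost = 3, cluster_sd = 0.5, seed = 0) {
  graph <- grn$graph
  classes <- grn$classes
  n_clusters <- max(1L, grn$truth$params$n_clusters)
  class_names <- names(classes)
  if (is.null(capable_classes)) {
    capable_classes <- purrr::map(seq_len(n_clusters) - 1, function(j) {
      if (j == 0) class_names
      else if (j == 1) class_names[purrr::map_chr(classes, "precursor") == "AA"]
      else character(0)
    })
  }
  roles <- node_roles(graph)
  tfs <- sort(names(roles)[roles == "TF"])
  enzymes <- sort(names(roles)[roles == "enzyme"])
  genes <- c(tfs, enzymes)
  samples <- as.vector(t(outer(seq_len(n_clusters) - 1, seq_len(cells_per_cluster),
                               function(j, i) sprintf("c%d_s%02d", j, i))))
  cluster_of <- rep(seq_len(n_clusters) - 1L, each = cells_per_cluster)
  names(cluster_of) <- samples

  planted <- grn$truth$planted_regulators

  counts <- withr::with_seed(seed, {
    base <- c(
      stats::rlnorm(length(tfs), meanlog = log(100), sdlog = 1),
      stats::rlnorm(length(enzymes), meanlog = log(200), sdlog = 0.5)
    )
    names(base) <- genes
    # per-gene cell-type profiles: cluster-structured expression
    cl_factor <- matrix(exp(stats::rnorm(length(genes) * n_clusters,
                                         sd = cluster_sd)),
                        nrow = length(genes))
    mu <- base * cl_factor[, cluster_of + 1, drop = FALSE]
    dimnames(mu) <- list(genes, samples)
    if (nrow(planted)) {
      for (r in seq_len(nrow(planted))) {
        boost <- c(planted$tf[r], planted$intermediates[[r]])
        mu[boost, cluster_of == planted$cluster[r]] <-
          mu[boost, cluster_of == planted$cluster[r]] * effect_size
      }
    }
    draw <- function(m) {
      if (dispersion > 0) {
        stats::rnbinom(length(m), size = 1 / dispersion, mu = m)
      } else {
        stats::rpois(length(m), m)
      }
    }
    cnt <- matrix(draw(mu), nrow = nrow(mu), dimnames = dimnames(mu))
    # enforce planted capabilities against the threshold
    for (j in seq_len(n_clusters) - 1) {
      in_cl <- cluster_of == j
      capable <- intersect(unlist(capable_classes[[j + 1]]), class_names)
      for (cl in class_names) {
        enz <- classes[[cl]]$enzymes
        if (cl %in% capable) {
          cnt[enz, in_cl] <- pmax(cnt[enz, in_cl], threshold)
        } else {
          gate <- enz[1]
          cnt[gate, in_cl] <- pmin(cnt[gate, in_cl],
                                   sample(0:(threshold - 1), sum(in_cl),
                                          replace = TRUE))
        }
      }
    }
    cnt
  })

  overrides <- NULL
  div_pair <- NULL
  if (divergent_pair) {
    twin <- "c0_div"
    anchor <- samples[1]
    counts[tfs, anchor] <- round(counts[tfs, anchor] * pair_boost)
    counts <- cbind(counts, stats::setNames(counts[, anchor, drop = FALSE],
                                            twin))
    colnames(counts)[ncol(counts)] <- twin
    cluster_of <- c(cluster_of, stats::setNames(0L, twin))
    samples <- c(samples, twin)
    # the twin keeps the cell's expression but loses the cell's entire
    # TF-to-enzyme wiring: same transcriptome, different regulation
    drop <- graph$edges$source %in% tfs & graph$edges$target %in% enzymes
    rewired <- signed_graph(graph$edges[!drop, ], graph$nodes)
    overrides <- stats::setNames(list(rewired), twin)
    div_pair <- c(anchor, twin)
  }

  expr <- dplyr::bind_cols(tibble::tibble(gene = rownames(counts)),
                           tibble::as_tibble(counts))
  metadata <- tibble::tibble(
    sample = samples,
    cell_type = sprintf("type%d", cluster_of),
    tissue = "synthetic", stimulus = "none", time_point = "0h",
    cluster = unname(cluster_of)
  )
  truth <- structure(
    list(params = c(grn$truth$params,
                    list(cells_per_cluster = cells_per_cluster,
                         effect_size = effect_size, dispersion = dispersion,
                         threshold = threshold, pair_boost = pair_boost,
                         cluster_sd = cluster_sd, expr_seed = seed)),
         planted_regulators = planted,
         planted_capabilities = purrr::map(capable_classes, unlist),
         divergent_pair = div_pair,
         cluster_of = cluster_of),
    class = "lm_truth"
  )
  structure(
    list(graph = graph, classes = classes, expr = expr, metadata = metadata,
         graph_overrides = overrides, truth = truth),
    class = "lm_dataset"
  )
}

#' One-call synthetic cohort under the default study conditions
#'
#' @param seed integer seed (drives both the GRN wiring and the counts).
#' @param ... overrides passed to [generate_grn()] /
#'   [generate_expression()] (matched by name).
#' @return an `lm_dataset`.
#' @export
simulate_lm_dataset <- function(seed = 0, ...) {
  dots <- list(...)
  grn_args <- dots[names(dots) %in% names(formals(generate_grn))]
  expr_args <- dots[names(dots) %in% setdiff(names(formals(generate_expression)),
                                             c("grn", "seed"))]
  grn <- do.call(generate_grn, c(grn_args, list(seed = seed)))
  do.call(generate_expression, c(list(grn = grn, seed = seed + 1L), expr_args))
}

#' @export
print.lm_dataset <- function(x, ...) {
  cat("<lm_dataset> ", ncol(x$expr) - 1, " samples, ", nrow(x$expr),
      " measured genes, ", length(x$classes), " LM classes\n", sep = "")
  print(x$graph)
  invisible(x)
}

#' Write a synthetic dataset in the pipeline's file formats
#'
#' Emits the edge-list and roles TSVs, the class YAML, the count and
#' metadata TSVs, and the planted truth as JSON.
#'
#' @param dataset an `lm_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_lm_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("edges.tsv", "roles.tsv", "classes.yaml",
                            "counts.tsv", "metadata.tsv", "truth.json"))
  write_signed_graph(dataset$graph, paths[1], paths[2])
  write_lm_classes(dataset$classes, paths[3])
  write_expression(dataset$expr, paths[4])
  readr::write_tsv(dataset$metadata, paths[5], progress = FALSE)
  truth <- dataset$truth
  truth$cluster_of <- as.list(truth$cluster_of)
  jsonlite::write_json(unclass(truth), paths[6], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Feature-level null for calibrating the cluster statistic
#'
#' Simulates genes whose score is a gene-specific linear function of
#' normalized expression plus Gaussian noise, with no cluster effect --
#' exactly the regression-plus-half-normal model the statistic assumes.
#' Used to check that the raw p-value distribution is approximately
#' uniform.
#'
#' @param n_genes number of features (default 1000).
#' @param n_samples samples per feature (default 90).
#' @param n_cluster size of the (effect-free) test cluster (default 30).
#' @param seed integer seed.
#' @return list with `$qhat`, `$score` (matrices genes x samples) and
#'   `$in_cluster` (logical mask over samples).
#' @export
simulate_null_scores <- function(n_genes = 1000, n_samples = 90,
                                 n_cluster = 30, seed = 1) {
  withr::with_seed(seed, {
    qhat <- matrix(stats::runif(n_genes * n_samples), nrow = n_genes)
    a <- stats::rnorm(n_genes)
    b <- stats::rnorm(n_genes, mean = 1)
    sd_g <- stats::rlnorm(n_genes, meanlog = -1, sdlog = 0.5)
    noise <- matrix(stats::rnorm(n_genes * n_samples, sd = sd_g), nrow = n_genes)
    score <- a + b * qhat + noise
    mask <- seq_len(n_samples) <= n_cluster
    dimnames(qhat) <- dimnames(score) <-
      list(sprintf("g%04d", seq_len(n_genes)), sprintf("s%03d", seq_len(n_samples)))
    list(qhat = qhat, score = score, in_cluster = mask)
  })
}
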
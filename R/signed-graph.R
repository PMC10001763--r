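#' Signed molecular interaction graphs
#'
#' A `signed_graph` stores a directed molecular interaction network in the
#' activity-flow formalism: every edge is a triple (source, relation, target)
#' with relation `-1` (inhibition / downregulation) or `+1` (activation /
#' upregulation). Vertices carry a role: `"TF"`, `"enzyme"`, `"metabolite"`,
#' `"product"`, `"phenotype"` or `"gene"`. Parallel edges with identical
#' (source, target, relation) are deduplicated; edges that differ only in
#' sign are kept as two distinct triples.
#'
#' @param edges data frame with columns `source`, `relation`, `target`.
#'   `relation` may be numeric (-1/1) or character ("+1"/"-1",
#'   "activates"/"inhibits").
#' @param nodes optional data frame with columns `node`, `role`. Vertices
#'   appearing only in `edges` are added with `default_role`.
#' @param default_role role assigned to vertices not listed in `nodes`.
#' @return an object of class `signed_graph` with tibble components
#'   `$edges` and `$nodes`.
#' @examples
#' g <- signed_graph(
#'   data.frame(source = "Nfkb1", relation = 1, target = "Ptgs2"),
#'   nodes = data.frame(node = c("Nfkb1", "Ptgs2"), role = c("TF", "enzyme"))
#' )
#' glance(g)
#' @export
signed_graph <- function(edges, nodes = NULL, default_role = "gene") {
  edges <- if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    tibble::tibble(source = character(), relation = integer(), target = character())
  } else {
    tibble::as_tibble(edges)
  }
  req <- c("source", "relation", "target")
  if (!all(req %in% names(edges))) {
    stop("`edges` must have columns source, relation, target", call. = FALSE)
  }
  edges <- dplyr::select(edges, dplyr::all_of(req))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$relation <- parse_relation(edges$relation)
  if (anyNA(edges$source) || anyNA(edges$target) || anyNA(edges$relation)) {
    stop("malformed edge: NA in source, relation or target", call. = FALSE)
  }
  edges <- dplyr::distinct(edges)

  node_ids <- unique(c(edges$source, edges$target))
  if (is.null(nodes)) {
    nodes <- tibble::tibble(node = node_ids, role = default_role)
  } else {
    nodes <- tibble::as_tibble(nodes)
    if (!all(c("node", "role") %in% names(nodes))) {
      stop("`nodes` must have columns node, role", call. = FALSE)
    }
    nodes <- dplyr::distinct(dplyr::select(nodes, "node", "role"))
    nodes$node <- as.character(nodes$node)
    if (anyDuplicated(nodes$node)) {
      dup <- unique(nodes$node[duplicated(nodes$node)])
      stop("conflicting roles for node(s): ", paste(dup, collapse = ", "),
           call. = FALSE)
    }
    missing <- setdiff(node_ids, nodes$node)
    if (length(missing)) {
      nodes <- dplyr::bind_rows(
        nodes, tibble::tibble(node = missing, role = default_role)
      )
    }
  }
  nodes <- dplyr::arrange(nodes, .data$node)
  edges <- dplyr::arrange(edges, .data$source, .data$target, .data$relation)
  structure(list(edges = edges, nodes = nodes), class = "signed_graph")
}

parse_relation <- function(r) {
  if (is.numeric(r)) {
    r <- as.integer(r)
  } else {
    r <- as.character(r)
    r <- dplyr::case_match(
      tolower(trimws(r)),
      c("+1", "1", "activates", "activation", "up") ~ 1L,
      c("-1", "inhibits", "inhibition", "down") ~ -1L,
      .default = NA_integer_
    )
  }
  if (any(!r %in% c(-1L, 1L))) {
    stop("edge relation must be -1 or +1", call. = FALSE)
  }
  r
}

#' @export
print.signed_graph <- function(x, ...) {
  cat("<signed_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  role_tab <- table(x$nodes$role)
  cat("  roles: ", paste(names(role_tab), role_tab, sep = ":", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname signed_graph
#' @param x a `signed_graph`.
#' @param ... unused.
#' @method tidy signed_graph
#' @export
tidy.signed_graph <- function(x, ...) {
  dplyr::left_join(x$edges, x$nodes, by = c(source = "node")) |>
    dplyr::rename(source_role = "role") |>
    dplyr::left_join(x$nodes, by = c(target = "node")) |>
    dplyr::rename(target_role = "role")
}

#' @rdname signed_graph
#' @method glance signed_graph
#' @export
glance.signed_graph <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_tf = sum(x$nodes$role == "TF"),
    n_enzyme = sum(x$nodes$role == "enzyme"),
    n_activating = sum(x$edges$relation == 1L),
    n_inhibiting = sum(x$edges$relation == -1L)
  )
}

node_roles <- function(g) {
  stats::setNames(g$nodes$role, g$nodes$node)
}

#' Convert catalytic reactions to activity flow
#'
#' Each catalytic reaction (substrate, enzyme, product) becomes two positive
#' edges, substrate -> enzyme and enzyme -> product, placing the enzyme in
#' between the mass-flow endpoints. No direct substrate -> product edge is
#' created; enzymes catalysing several reactions appear once.
#'
#' @param reactions data frame with columns `substrate`, `enzyme`, `product`.
#' @param substrate_role,product_role roles given to the non-enzyme
#'   endpoints (default `"metabolite"`). Terminal products can be relabelled
#'   afterwards or via an `lm_class` spec.
#' @return a `signed_graph` with enzymes in role `"enzyme"`.
#' @examples
#' transform_catalysis(
#'   data.frame(substrate = "AA", enzyme = "Ptgs2", product = "PGH2")
#' )
#' @export
transform_catalysis <- function(reactions, substrate_role = "metabolite",
                                product_role = "metabolite") {
  reactions <- tibble::as_tibble(reactions)
  req <- c("substrate", "enzyme", "product")
  if (!all(req %in% names(reactions))) {
    stop("`reactions` must have columns substrate, enzyme, product",
         call. = FALSE)
  }
  if (nrow(reactions) == 0) {
    return(signed_graph(NULL))
  }
  bad <- !stats::complete.cases(reactions[req]) |
    reactions$substrate == "" | reactions$enzyme == "" | reactions$product == ""
  if (any(bad)) {
    stop("malformed reaction: missing substrate, enzyme or product",
         call. = FALSE)
  }
  edges <- dplyr::bind_rows(
    tibble::tibble(source = reactions$substrate, relation = 1L,
                   target = reactions$enzyme),
    tibble::tibble(source = reactions$enzyme, relation = 1L,
                   target = reactions$product)
  )
  nodes <- dplyr::bind_rows(
    tibble::tibble(node = reactions$enzyme, role = "enzyme"),
    tibble::tibble(node = reactions$substrate, role = substrate_role),
    tibble::tibble(node = reactions$product, role = product_role)
  )
  # an id seen as enzyme anywhere keeps the enzyme role
  nodes <- nodes[!duplicated(nodes$node), ]
  signed_graph(edges, nodes)
}

#' Merge a biosynthesis network with transcription-factor interactions
#'
#' Vertex and edge union of two signed graphs; node roles must agree on
#' shared vertices.
#'
#' @param pathway,tf_edges `signed_graph` objects.
#' @return merged `signed_graph`.
#' @export
merge_networks <- function(pathway, tf_edges) {
  stopifnot(inherits(pathway, "signed_graph"), inherits(tf_edges, "signed_graph"))
  shared <- dplyr::inner_join(pathway$nodes, tf_edges$nodes, by = "node",
                              suffix = c("_a", "_b"))
  conflict <- shared$node[shared$role_a != shared$role_b]
  if (length(conflict)) {
    stop("role conflict on merge for node(s): ",
         paste(conflict, collapse = ", "), call. = FALSE)
  }
  signed_graph(
    dplyr::bind_rows(pathway$edges, tf_edges$edges),
    dplyr::distinct(dplyr::bind_rows(pathway$nodes, tf_edges$nodes))
  )
}

#' @rdname signed_graph
#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @export
as_igraph.signed_graph <- function(x, ...) {
  igraph::graph_from_data_frame(
    d = data.frame(from = x$edges$source, to = x$edges$target,
                   relation = x$edges$relation),
    directed = TRUE,
    vertices = data.frame(name = x$nodes$node, role = x$nodes$role)
  )
}

#' Total node degree counting each signed triple once
#'
#' Degree centrality (number of incident interactions, in plus out) in a
#' signed graph. Used as the normalising degree of the propagation step,
#' always computed on the original unfiltered network.
#'
#' @param g a `signed_graph`.
#' @return named integer vector over all vertices.
#' @export
node_degrees <- function(g) {
  stopifnot(inherits(g, "signed_graph"))
  deg <- stats::setNames(integer(nrow(g$nodes)), g$nodes$node)
  tab <- table(c(g$edges$source, g$edges$target))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Induce the subgraph on a vertex set
#' @noRd
induce_subgraph <- function(g, keep) {
  keep <- intersect(g$nodes$node, keep)
  edges <- g$edges[g$edges$source %in% keep & g$edges$target %in% keep, ]
  signed_graph(edges, g$nodes[g$nodes$node %in% keep, ])
}

#' Cell-type-specific subgraphs by expression filtering
#'
#' Removes measured transcription-factor/gene vertices whose raw read count
#' in the given sample is below `threshold` (a count equal to the threshold
#' is kept), together with their incident edges. Vertices in the protected
#' set -- every vertex whose role is not `TF`/`gene`, i.e. curated-pathway
#' enzymes, metabolites, products and phenotypes -- are never removed, nor
#' are TF/gene vertices absent from the expression table (nodes without a
#' measurement stay in the network).
#'
#' @param g the full `signed_graph`.
#' @param expr expression table: column `gene` plus one numeric column of
#'   raw counts per sample.
#' @param sample sample (column) id.
#' @param threshold minimum raw read count to call a gene expressed
#'   (default 10).
#' @return a `cell_subgraph`: list with `$graph` (filtered `signed_graph`),
#'   `$parent`, `$sample`, `$protected`, `$removed`.
#' @export
filter_expressed <- function(g, expr, sample, threshold = 10) {
  stopifnot(inherits(g, "signed_graph"))
  expr <- check_expression(expr)
  if (!sample %in% setdiff(names(expr), "gene")) {
    stop("unknown sample: ", sample, call. = FALSE)
  }
  protected <- g$nodes$node[!g$nodes$role %in% c("TF", "gene")]
  q <- stats::setNames(expr[[sample]], expr$gene)
  measured <- intersect(g$nodes$node, names(q))
  low <- measured[q[measured] < threshold]
  removed <- setdiff(low, protected)
  keep <- setdiff(g$nodes$node, removed)
  structure(
    list(graph = induce_subgraph(g, keep), parent = g, sample = sample,
         protected = protected, removed = removed, threshold = threshold),
    class = "cell_subgraph"
  )
}

#' @export
print.cell_subgraph <- function(x, ...) {
  cat("<cell_subgraph> sample ", x$sample, ": ", nrow(x$graph$nodes), "/",
      nrow(x$parent$nodes), " nodes, ", nrow(x$graph$edges), "/",
      nrow(x$parent$edges), " edges (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

# ---- input / output ---------------------------------------------------------

#' Read and write signed edge lists
#'
#' Edge lists are tab-separated files with columns `source`, `relation`
#' (`+1`/`-1` or `activates`/`inhibits`), `target`; roles are a two-column
#' TSV `node`, `role`.
#'
#' @param edge_file,roles_file file paths.
#' @param unsigned_default if non-`NULL`, edges with an empty relation field
#'   are accepted and given this sign (set to `1` for databases that do not
#'   annotate signs); the default `NULL` rejects unsigned edges.
#' @return a `signed_graph`.
#' @export
read_signed_graph <- function(edge_file, roles_file = NULL,
                              unsigned_default = NULL) {
  edges <- readr::read_tsv(edge_file, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (!is.null(unsigned_default)) {
    blank <- is.na(edges$relation) | trimws(edges$relation) == ""
    edges$relation[blank] <- as.character(unsigned_default)
  }
  nodes <- NULL
  if (!is.null(roles_file)) {
    nodes <- readr::read_tsv(roles_file, col_types = "cc", progress = FALSE)
  }
  signed_graph(edges, nodes)
}

#' @rdname read_signed_graph
#' @param g a `signed_graph`.
#' @param edge_file,roles_file output paths.
#' @export
write_signed_graph <- function(g, edge_file, roles_file = NULL) {
  readr::write_tsv(g$edges, edge_file, progress = FALSE)
  if (!is.null(roles_file)) {
    readr::write_tsv(g$nodes, roles_file, progress = FALSE)
  }
  invisible(g)
}

#' Export a signed graph (or CRN) to GraphML
#'
#' Node attributes `role` and, when supplied, `score` and `qhat` are
#' attached so downstream viewers can map shape to role and colour to
#' normalized expression.
#'
#' @param g a `signed_graph`.
#' @param file output path.
#' @param score optional named numeric vector of per-node scores.
#' @param qhat optional named numeric vector of normalized read counts.
#' @export
write_graphml <- function(g, file, score = NULL, qhat = NULL) {
  ig <- as_igraph(g)
  if (!is.null(score)) {
    igraph::V(ig)$score <- unname(score[igraph::V(ig)$name])
  }
  if (!is.null(qhat)) {
    igraph::V(ig)$qhat <- unname(qhat[igraph::V(ig)$name])
  }
  igraph::write_graph(ig, file, format = "graphml")
  invisible(g)
}
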
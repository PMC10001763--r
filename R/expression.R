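#' Expression tables
#'
#' Expression data are kept as wide tibbles: a `gene` column plus one
#' numeric column of non-negative read counts per sample. Normalization is
#' per gene: each count is divided by the gene's maximum across samples, so
#' normalized values live in \[0, 1\] and every gene with any signal reaches
#' 1 in the sample where it peaks.
#'
#' @name expression-tables
NULL

check_expression <- function(expr, normalized = FALSE) {
  expr <- tibble::as_tibble(expr)
  if (!"gene" %in% names(expr)) {
    stop("expression table needs a `gene` column", call. = FALSE)
  }
  expr$gene <- as.character(expr$gene)
  samples <- setdiff(names(expr), "gene")
  if (!length(samples)) stop("expression table has no sample columns", call. = FALSE)
  vals <- as.matrix(expr[samples])
  if (!is.numeric(vals) || anyNA(vals)) {
    stop("sample columns must be numeric without NAs", call. = FALSE)
  }
  if (any(vals < 0)) stop("negative read count", call. = FALSE)
  if (anyDuplicated(expr$gene)) stop("duplicated gene ids", call. = FALSE)
  expr
}

#' Cell-type (max) normalization of read counts
#'
#' Divides each gene's counts by its maximum across all samples. Genes with
#' all-zero counts are set to 0 everywhere (the 0/0 case), consistent with
#' such genes being filtered out of every cell subgraph anyway.
#'
#' @param expr wide expression table (`gene` column + sample columns).
#' @return table of the same shape with values in \[0, 1\] and attribute
#'   `normalized = TRUE`.
#' @examples
#' normalize_expression(data.frame(gene = "Alox5", s1 = 5, s2 = 10, s3 = 20))
#' @export
normalize_expression <- function(expr) {
  expr <- check_expression(expr)
  samples <- setdiff(names(expr), "gene")
  m <- as.matrix(expr[samples])
  gene_max <- apply(m, 1, max)
  scale <- ifelse(gene_max > 0, gene_max, 1)
  out <- expr
  out[samples] <- m / scale
  attr(out, "normalized") <- TRUE
  out
}

#' Map gene identifiers (e.g. mouse to human orthologs)
#'
#' Replaces gene ids using a two-column lookup. Source ids must be unique;
#' several sources may map to one target, in which case counts are
#' aggregated by the maximum (a gene is expressed if any ortholog is).
#' Unmapped genes are dropped and their number reported via a message.
#'
#' @param expr wide expression table.
#' @param mapping data frame whose first two columns are source id and
#'   target id.
#' @return mapped expression table.
#' @export
map_identifiers <- function(expr, mapping) {
  expr <- check_expression(expr)
  mapping <- tibble::as_tibble(mapping)
  if (nrow(mapping) == 0 || ncol(mapping) < 2) {
    stop("identifier mapping is empty", call. = FALSE)
  }
  mapping <- stats::setNames(mapping[1:2], c("from", "to"))
  mapping$from <- as.character(mapping$from)
  mapping$to <- as.character(mapping$to)
  if (anyDuplicated(mapping$from)) {
    stop("mapping source ids must be unique", call. = FALSE)
  }
  n_unmapped <- sum(!expr$gene %in% mapping$from)
  if (n_unmapped > 0) {
    message(n_unmapped, " unmapped gene(s) dropped")
  }
  out <- dplyr::inner_join(expr, mapping, by = c(gene = "from")) |>
    dplyr::mutate(gene = .data$to, .keep = "unused") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), max), .groups = "drop")
  attr(out, "normalized") <- attr(expr, "normalized")
  out
}

#' @rdname expression-tables
#' @param file path to a TSV/CSV file, genes as rows (first column `gene`
#'   or unnamed), samples as columns with a header of sample ids.
#' @export
read_expression <- function(file) {
  delim <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  expr <- readr::read_delim(file, delim = delim, progress = FALSE,
                            show_col_types = FALSE)
  if (!"gene" %in% names(expr)) names(expr)[1] <- "gene"
  check_expression(expr)
}

#' @rdname expression-tables
#' @param expr expression table.
#' @export
write_expression <- function(expr, file) {
  readr::write_tsv(expr, file, progress = FALSE)
  invisible(expr)
}

#' @rdname expression-tables
#' @export
read_sample_metadata <- function(file) {
  readr::read_tsv(file, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

# ---- LM class specifications ------------------------------------------------

#' Lipid mediator class specification
#'
#' One LM class (e.g. D-series resolvins) is defined by its polyunsaturated
#' fatty-acid precursor (`AA`, `DHA` or `EPA`), its terminal product
#' metabolites, and the set of enzymes catalysing steps of its biosynthesis.
#'
#' @param name class name.
#' @param precursor precursor metabolite id.
#' @param products character vector of terminal product ids.
#' @param enzymes character vector of enzyme ids (non-empty).
#' @return an `lm_class` object.
#' @export
lm_class <- function(name, precursor, products, enzymes) {
  if (!length(enzymes)) stop("lm_class needs at least one enzyme", call. = FALSE)
  if (precursor %in% products) {
    stop("precursor cannot also be a product", call. = FALSE)
  }
  structure(
    list(name = as.character(name), precursor = as.character(precursor),
         products = as.character(products), enzymes = as.character(enzymes)),
    class = "lm_class"
  )
}

#' @export
print.lm_class <- function(x, ...) {
  cat("<lm_class> ", x$name, ": ", x$precursor, " -> {",
      paste(x$products, collapse = ", "), "} via ",
      length(x$enzymes), " enzyme(s)\n", sep = "")
  invisible(x)
}

#' Read / write LM class specs as YAML
#'
#' The YAML layout maps class name to `precursor`, `products`, `enzymes`.
#'
#' @param file path to a YAML file.
#' @return named list of `lm_class` objects.
#' @export
read_lm_classes <- function(file) {
  raw <- yaml::read_yaml(file)
  purrr::imap(raw, function(cl, nm) {
    lm_class(nm, cl$precursor, unlist(cl$products), unlist(cl$enzymes))
  })
}

#' @rdname read_lm_classes
#' @param classes named list of `lm_class` objects.
#' @export
write_lm_classes <- function(classes, file) {
  yaml::write_yaml(
    purrr::map(rlang::set_names(classes, purrr::map_chr(classes, "name")),
               function(cl) {
                 list(precursor = cl$precursor, products = as.list(cl$products),
                      enzymes = as.list(cl$enzymes))
               }),
    file
  )
  invisible(classes)
}
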
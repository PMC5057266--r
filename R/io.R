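# Readers/writers for the plain-text formats the pipeline exchanges:
# TSV matrices, GMT gene sets, 2-column edge lists and module JSON.

#' Read a log-ratio matrix from TSV
#'
#' Expects genes in rows with identifiers in the first column and a header row
#' of condition identifiers; values are tab-separated with '.' decimals.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and condition colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df[[1]])
  storage.mode(mat) <- "double"
  assert_log_ratio_matrix(mat)
}

#' Write a log-ratio matrix as TSV
#'
#' @param mat numeric matrix with dimnames.
#' @param path destination path.
#' @export
write_matrix_tsv <- function(mat, path) {
  assert_log_ratio_matrix(mat)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (one set per line: name, description, member genes).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path destination path.
#' @param description optional per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  desc <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sets), desc, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read an undirected network from an edge list
#'
#' Accepts a 2-column tab-separated edge list, or SIF's simple 3-column
#' dialect (source, interaction type, target; the type is ignored). Self-loops
#' and duplicate edges are removed.
#'
#' @param path file path.
#' @param header logical; does the file carry a header row?
#' @return an igraph undirected simple graph.
#' @export
read_edge_list <- function(path, header = FALSE) {
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) >= 3) df <- df[, c(1, 3)] else df <- df[, 1:2]
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write an undirected network as a 2-column edge list
#'
#' @param graph igraph object.
#' @param path destination path.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a ModuleCollection to JSON
#'
#' @param collection a [ModuleCollection].
#' @param path destination path.
#' @export
write_modules_json <- function(collection, path) {
  stopifnot(inherits(collection, "ModuleCollection"))
  payload <- list(
    source_matrix_digest = collection$source_matrix_digest,
    modules = lapply(seq_along(collection$modules), function(i) {
      m <- collection$modules[[i]]
      list(
        id = i,
        gene_ids = names(m$genes), gene_scores = unname(m$genes),
        condition_ids = names(m$conditions),
        condition_scores = unname(m$conditions),
        gene_threshold = m$params$gene_threshold,
        condition_threshold = m$params$condition_threshold,
        seed_index = m$seed_index
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ModuleCollection from JSON
#'
#' @param path file written by [write_modules_json()].
#' @return a [ModuleCollection].
#' @export
read_modules_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  modules <- lapply(payload$modules, function(m) {
    gene_module(
      genes = stats::setNames(as.numeric(m$gene_scores), m$gene_ids),
      conditions = stats::setNames(as.numeric(m$condition_scores),
                                   m$condition_ids),
      params = isa_params(gene_threshold = m$gene_threshold,
                          condition_threshold = m$condition_threshold),
      seed_index = m$seed_index %||% NA_integer_
    )
  })
  module_collection(modules,
                    source_matrix_digest = payload$source_matrix_digest)
}
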
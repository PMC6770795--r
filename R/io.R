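#' Read and write pipeline tables
#'
#' All pipeline tables are plain tab-delimited text with a header row.
#' Gene assignment tables carry `gene_id`, `species`, `chromosome`,
#' `period_class`; gene sets are one id per line; energy tables carry
#' `protein_id`, `group` and the feature columns (column names may contain
#' spaces, so they are never mangled on read).
#'
#' @param x object to write (data frame, or character vector for gene sets).
#' @param path file path.
#' @return readers return the parsed object; writers return `path`
#'   invisibly.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_assignment <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("assignment table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  tab
}

#' @rdname pipeline-io
#' @export
read_gene_set <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  unique(ids[nzchar(ids)])
}

#' @rdname pipeline-io
#' @export
write_gene_set <- function(x, path) {
  writeLines(as.character(x), path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_energy_table <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!all(c("protein_id", "group") %in% names(tab))) {
    stop("energy table ", path, " lacks protein_id/group columns")
  }
  class(tab) <- c("energy_table", "data.frame")
  tab
}

#' Export a co-localization network
#'
#' `write_sif()` writes the Cytoscape simple-interaction format, one edge
#' per line with relation label `co_loc`. `write_graphml()` writes GraphML
#' via igraph.
#'
#' @param net a [coloc_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "coloc_network"))
  lines <- paste(net$edges[, 1], "co_loc", net$edges[, 2], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "coloc_network"))
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_sif
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(coloc_network(matrix(character(0), ncol = 2L)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("malformed SIF line ", bad[1], " in ", path)
  edges <- t(vapply(parts, function(p) p[c(1L, 3L)], character(2)))
  coloc_network(edges)
}
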
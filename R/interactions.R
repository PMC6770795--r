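#' Protein-protein interaction reference
#'
#' A simple undirected interaction universe: self-loops are dropped and
#' duplicate records (in either orientation) are collapsed to one edge.
#' Record multiplicity from interaction databases, where the same pair can
#' be reported by several experiments, is preserved separately in the
#' `multiplicity` attribute so counting functions can optionally weight by
#' records rather than unique pairs.
#'
#' @param edges two-column character matrix or data frame of interactor id
#'   pairs.
#' @param nodes optional character vector of the full node universe;
#'   defaults to the ids appearing in `edges`. Ids in `edges` are always
#'   included.
#' @param provenance free-text description of where the interactions came
#'   from.
#' @return an object of class `interaction_reference`: a list with `nodes`,
#'   `edges` (canonicalized two-column character matrix), `multiplicity`
#'   (integer records per unique edge) and `provenance`.
#' @export
interaction_reference <- function(edges, nodes = NULL, provenance = "") {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  storage.mode(edges) <- "character"
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]  # no self-loops
  canon <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  key <- paste(canon[, 1], canon[, 2], sep = "\r")
  mult <- table(key)
  uniq <- !duplicated(key)
  canon <- canon[uniq, , drop = FALSE]
  key <- key[uniq]
  o <- order(canon[, 1], canon[, 2])
  canon <- canon[o, , drop = FALSE]
  multiplicity <- as.integer(mult[key[o]])
  nodes <- sort(unique(c(as.character(nodes), canon)))
  structure(list(nodes = nodes, edges = canon,
                 multiplicity = multiplicity, provenance = provenance),
            class = "interaction_reference")
}

#' @export
print.interaction_reference <- function(x, ...) {
  cat("Interaction reference: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " unique edges (", sum(x$multiplicity),
      " records)\n", sep = "")
  if (nzchar(x$provenance)) cat("  source: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Read an interaction reference from MITAB or a two-column edge table
#'
#' PSI-MI TAB (2.5 and later) files are recognised by their column count or
#' an `#ID(s) interactor A` style header: the first two columns are taken as
#' interactor identifiers and database prefixes (`uniprotkb:`, `entrez
#' gene/locuslink:` ...) are stripped. Any other tab-delimited file is read
#' as a plain two-column edge list with an optional header.
#'
#' @param path file path.
#' @param format `"auto"` (default), `"mitab"` or `"edges"`.
#' @return an [interaction_reference()].
#' @export
read_interactions <- function(path, format = c("auto", "mitab", "edges")) {
  format <- match.arg(format)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(interaction_reference(matrix(character(0), ncol = 2L),
                                 provenance = path))
  }
  ncols <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (format == "auto") {
    format <- if (ncols >= 11L || grepl("interactor", first, ignore.case = TRUE))
      "mitab" else "edges"
  }
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "", colClasses = "character")
  has_header <- grepl("interactor", tab[1, 1], ignore.case = TRUE) ||
    grepl("^#", tab[1, 1]) ||
    (format == "edges" && identical(unname(tolower(unlist(tab[1, 1:2]))),
                                    c("id_a", "id_b")))
  if (has_header) tab <- tab[-1, , drop = FALSE]
  if (nrow(tab) == 0L) {
    return(interaction_reference(matrix(character(0), ncol = 2L),
                                 provenance = path))
  }
  a <- tab[[1]]
  b <- tab[[2]]
  if (format == "mitab") {
    a <- sub("^[^:]+:", "", a)
    b <- sub("^[^:]+:", "", b)
  }
  interaction_reference(cbind(a, b), provenance = path)
}

#' Write an interaction reference
#'
#' `write_mitab()` emits a minimal PSI-MI TAB 2.5 file (15 columns, the
#' first two carrying `uniprotkb:`-prefixed ids, remaining columns `-`);
#' each unique edge is written once per original record so multiplicity
#' round-trips. `write_edges()` writes a two-column tab-delimited edge list
#' with header `id_a`/`id_b`.
#'
#' @param ref an [interaction_reference()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_mitab <- function(ref, path) {
  stopifnot(inherits(ref, "interaction_reference"))
  header <- paste(c("#ID(s) interactor A", "ID(s) interactor B",
                    "Alt. ID(s) interactor A", "Alt. ID(s) interactor B",
                    "Alias(es) interactor A", "Alias(es) interactor B",
                    "Interaction detection method(s)",
                    "Publication 1st author(s)", "Publication Identifier(s)",
                    "Taxid interactor A", "Taxid interactor B",
                    "Interaction type(s)", "Source database(s)",
                    "Interaction identifier(s)", "Confidence value(s)"),
                  collapse = "\t")
  i <- rep(seq_len(nrow(ref$edges)), times = ref$multiplicity)
  lines <- paste(paste0("uniprotkb:", ref$edges[i, 1]),
                 paste0("uniprotkb:", ref$edges[i, 2]),
                 "-", "-", "-", "-", "-", "-", "-", "-", "-", "-", "-", "-",
                 "-", sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_mitab
#' @export
write_edges <- function(ref, path) {
  stopifnot(inherits(ref, "interaction_reference"))
  df <- data.frame(id_a = ref$edges[, 1], id_b = ref$edges[, 2])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
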
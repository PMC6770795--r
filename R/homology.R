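#' Resolve one-to-many homolog candidates to a one-to-one mapping
#'
#' Orthology calls between two species frequently return several candidate
#' homologs per query gene (one-to-many and many-to-many relationships).
#' Candidates for each query are ranked by a fixed priority cascade of
#' scores, in this order: confidence score (higher better), gene order
#' conservation (GOC) score (higher better), target percent identity,
#' query percent identity, and the dN/dS ratio. By default a dN/dS closer to
#' zero ranks better (stronger purifying selection); set
#' `prefer_low_dnds = FALSE` to rank larger ratios first instead. A score
#' that is missing ranks below every present value at its cascade level, and
#' candidates still tied after all five scores are broken by the smallest
#' target id, so resolution is fully deterministic.
#'
#' With `one_to_one = TRUE` (default) queries are processed in ascending
#' query-id order and assignment is greedy: a target already claimed by an
#' earlier query is skipped and the query falls through to its next-ranked
#' candidate, which makes the output injective in both directions. With
#' `one_to_one = FALSE` each query simply takes its top-ranked candidate and
#' several queries may share a target.
#'
#' Queries whose candidates are exhausted are reported in `unmapped`, never
#' imputed.
#'
#' @param candidates data frame of homolog candidates with columns
#'   `query_id`, `target_id`, `confidence`, `goc`, `target_pid`,
#'   `query_pid`, `dn_ds` (the last four may contain `NA`). Duplicate
#'   (query, target) rows are collapsed keeping the best value of each
#'   score.
#' @param one_to_one enforce global one-to-one assignment (default `TRUE`).
#' @param prefer_low_dnds rank dN/dS by closeness to zero (default `TRUE`).
#' @return an object of class `homology_map`: list with `pairs` (data frame
#'   `query_id`, `target_id`) and `unmapped` (character vector of query
#'   ids).
#' @examples
#' cand <- data.frame(query_id = "q1", target_id = c("t1", "t2"),
#'                    confidence = c(1, 1), goc = c(50, 100),
#'                    target_pid = NA, query_pid = NA, dn_ds = NA)
#' resolve_homologs(cand)$pairs
#' @export
resolve_homologs <- function(candidates, one_to_one = TRUE,
                             prefer_low_dnds = TRUE) {
  candidates <- validate_candidates(candidates)
  if (nrow(candidates) == 0L) {
    return(structure(list(pairs = data.frame(query_id = character(0),
                                             target_id = character(0),
                                             stringsAsFactors = FALSE),
                          unmapped = character(0)),
                     class = "homology_map"))
  }
  cand <- collapse_duplicates(candidates)

  # missing scores sink below any present value at their cascade level
  na_low <- function(x) ifelse(is.na(x), -Inf, x)
  dnds_key <- if (prefer_low_dnds) abs(cand$dn_ds) else -cand$dn_ds
  dnds_key <- ifelse(is.na(dnds_key), Inf, dnds_key)
  o <- order(cand$query_id,
             -na_low(cand$confidence), -na_low(cand$goc),
             -na_low(cand$target_pid), -na_low(cand$query_pid),
             dnds_key, cand$target_id, method = "radix")
  cand <- cand[o, , drop = FALSE]

  queries <- unique(cand$query_id)      # already ascending
  by_query <- split(cand$target_id, factor(cand$query_id, levels = queries))
  taken <- new.env(parent = emptyenv())
  q_out <- character(length(queries))
  t_out <- character(length(queries))
  k <- 0L
  unmapped <- character(0)
  for (i in seq_along(queries)) {
    targets <- by_query[[i]]
    hit <- NA_character_
    if (one_to_one) {
      for (t in targets) {
        if (is.null(taken[[t]])) { hit <- t; break }
      }
    } else {
      hit <- targets[1L]
    }
    if (is.na(hit)) {
      unmapped <- c(unmapped, queries[i])
    } else {
      if (one_to_one) taken[[hit]] <- TRUE
      k <- k + 1L
      q_out[k] <- queries[i]
      t_out[k] <- hit
    }
  }
  pairs <- data.frame(query_id = q_out[seq_len(k)],
                      target_id = t_out[seq_len(k)],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, unmapped = unmapped), class = "homology_map")
}

validate_candidates <- function(candidates) {
  need <- c("query_id", "target_id", "confidence", "goc", "target_pid",
            "query_pid", "dn_ds")
  if (!is.data.frame(candidates)) stop("'candidates' must be a data frame")
  missing <- setdiff(need, names(candidates))
  if (length(missing)) {
    stop("candidate table lacks column(s): ", paste(missing, collapse = ", "))
  }
  candidates$query_id <- as.character(candidates$query_id)
  candidates$target_id <- as.character(candidates$target_id)
  for (col in c("goc", "target_pid", "query_pid")) {
    v <- candidates[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad)) {
      stop("parse error: '", col, "' outside [0, 100] at row ", bad[1])
    }
  }
  bad <- which(!is.na(candidates$dn_ds) & candidates$dn_ds < 0)
  if (length(bad)) stop("parse error: negative dn_ds at row ", bad[1])
  bad <- which(is.na(candidates$query_id) | is.na(candidates$target_id) |
                 candidates$query_id == "" | candidates$target_id == "")
  if (length(bad)) stop("parse error: empty gene id at row ", bad[1])
  candidates
}

# same (query, target) reported twice keeps the best value of every score
collapse_duplicates <- function(cand) {
  key <- paste(cand$query_id, cand$target_id, sep = "\r")
  if (!anyDuplicated(key)) return(cand)
  best_hi <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  best_lo <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  grp <- match(key, unique(key))
  out <- cand[!duplicated(key), , drop = FALSE]
  out$confidence <- tapply(cand$confidence, grp, best_hi)[as.character(seq_len(nrow(out)))]
  out$goc <- tapply(cand$goc, grp, best_hi)[as.character(seq_len(nrow(out)))]
  out$target_pid <- tapply(cand$target_pid, grp, best_hi)[as.character(seq_len(nrow(out)))]
  out$query_pid <- tapply(cand$query_pid, grp, best_hi)[as.character(seq_len(nrow(out)))]
  out$dn_ds <- tapply(cand$dn_ds, grp, best_lo)[as.character(seq_len(nrow(out)))]
  out
}

#' @export
print.homology_map <- function(x, ...) {
  cat("Homology map: ", nrow(x$pairs), " resolved pairs, ",
      length(x$unmapped), " unmapped queries\n", sep = "")
  invisible(x)
}

#' Invert a homology map
#'
#' Swaps query and target roles so a species-2 network can be relabelled to
#' species-1 ids (or vice versa). Only valid for one-to-one maps.
#'
#' @param map a `homology_map`.
#' @return a `homology_map` with queries and targets exchanged.
#' @export
invert_map <- function(map) {
  stopifnot(inherits(map, "homology_map"))
  if (anyDuplicated(map$pairs$target_id)) {
    stop("map is not injective on targets; cannot invert")
  }
  structure(list(pairs = data.frame(query_id = map$pairs$target_id,
                                    target_id = map$pairs$query_id,
                                    stringsAsFactors = FALSE),
                 unmapped = character(0)),
            class = "homology_map")
}

#' Coverage of a gene set by a homology map
#'
#' @param map a `homology_map`.
#' @param gene_set character vector of query ids.
#' @return named integer vector `c(n_mapped, n_total)`.
#' @examples
#' m <- structure(list(pairs = data.frame(query_id = "g1", target_id = "h1"),
#'                     unmapped = character(0)), class = "homology_map")
#' mapping_coverage(m, c("g1", "g2"))
#' @export
mapping_coverage <- function(map, gene_set) {
  stopifnot(inherits(map, "homology_map"))
  gene_set <- unique(as.character(gene_set))
  c(n_mapped = sum(gene_set %in% map$pairs$query_id),
    n_total = length(gene_set))
}

#' Read and write homolog candidate and resolved-map tables
#'
#' Candidate tables are tab-delimited with header `query_id`, `target_id`,
#' `confidence`, `goc`, `target_pid`, `query_pid`, `dn_ds`; empty fields and
#' `NA` denote missing scores. Malformed numeric fields raise an error
#' naming the offending line.
#'
#' @param path file path.
#' @return `read_homolog_candidates()`: a validated candidate data frame.
#' @export
read_homolog_candidates <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = c("", "NA"))
  need <- c("query_id", "target_id", "confidence", "goc", "target_pid",
            "query_pid", "dn_ds")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  for (col in need[3:7]) {
    raw <- tab[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad)) {
      stop("parse error in ", path, " line ", bad[1] + 1L,
           ": non-numeric '", col, "' value \"", raw[bad[1]], "\"")
    }
    tab[[col]] <- num
  }
  validate_candidates(tab)
}

#' @rdname read_homolog_candidates
#' @param map a `homology_map`.
#' @param pairs_path,unmapped_path output paths; `unmapped_path = NULL`
#'   skips the unmapped listing.
#' @export
write_homology_map <- function(map, pairs_path, unmapped_path = NULL) {
  stopifnot(inherits(map, "homology_map"))
  write.table(map$pairs, pairs_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(unmapped_path)) {
    writeLines(map$unmapped, unmapped_path)
  }
  invisible(pairs_path)
}
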
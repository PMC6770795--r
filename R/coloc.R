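#' Chromosomal co-localization networks
#'
#' A co-localization network represents a gene set as a graph in which two
#' genes are joined by an edge whenever they reside on the same chromosome.
#' Each chromosome therefore contributes one clique, and every connected
#' component of such a network (and of any intersection of such networks) is
#' a clique. Isolate nodes — genes alone on their chromosome — are removed
#' before any statistics are reported.
#'
#' `coloc_network()` is the low-level constructor used by
#' [build_coloc_network()], [relabel_by_homology()] and
#' [intersect_networks()]; it prunes isolates, recomputes component counts
#' and asserts the clique structure.
#'
#' @param edges two-column character matrix of gene-id pairs.
#' @param species free-text species tag.
#' @return an object of class `coloc_network`: list with `nodes`, `edges`
#'   (canonical two-column matrix), `species` and `stats`
#'   (`n_nodes`, `n_edges`, `n_components`).
#' @export
coloc_network <- function(edges, species = "") {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(0), ncol = 2L)
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  storage.mode(edges) <- "character"
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  canon <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  canon <- canon[!duplicated(paste(canon[, 1], canon[, 2], sep = "\r")), ,
                 drop = FALSE]
  canon <- canon[order(canon[, 1], canon[, 2]), , drop = FALSE]
  nodes <- sort(unique(as.character(canon)))   # isolates never enter: nodes
  n_comp <- if (length(nodes)) {               # are defined by their edges
    g <- igraph::graph_from_edgelist(canon, directed = FALSE)
    comp <- igraph::components(g)
    # structural guarantee: components of intersected chromosome
    # partitions are cliques; verify edges = sum C(size, 2)
    if (nrow(canon) != sum(choose(comp$csize, 2))) {
      stop("internal error: a co-localization component is not a clique")
    }
    comp$no
  } else 0L
  structure(list(nodes = nodes, edges = canon, species = species,
                 stats = c(n_nodes = length(nodes), n_edges = nrow(canon),
                           n_components = n_comp)),
            class = "coloc_network")
}

#' @export
print.coloc_network <- function(x, ...) {
  cat("Co-localization network",
      if (nzchar(x$species)) paste0(" [", x$species, "]"), ": ",
      x$stats["n_nodes"], " nodes, ", x$stats["n_edges"], " edges, ",
      x$stats["n_components"], " components (isolates removed)\n", sep = "")
  invisible(x)
}

#' Build a co-localization network for a gene set
#'
#' Groups the members of `gene_set` by chromosome according to `assignment`
#' and joins every same-chromosome pair, yielding one clique per chromosome.
#' Genes alone on their chromosome become isolates and are dropped before
#' the statistics are computed. Set members absent from the assignment are
#' skipped with a warning (and counted in the `skipped` attribute); a gene
#' assigned to more than one chromosome is an input error.
#'
#' @param assignment data frame with columns `gene_id` and `chromosome`
#'   (one row per gene).
#' @param gene_set character vector of gene ids; defaults to all assigned
#'   genes.
#' @param species species tag carried on the network.
#' @return a [coloc_network()].
#' @examples
#' asg <- data.frame(gene_id = paste0("g", 1:6),
#'                   chromosome = c("c1", "c1", "c2", "c2", "c2", "c3"))
#' build_coloc_network(asg)$stats
#' @export
build_coloc_network <- function(assignment, gene_set = NULL, species = "") {
  if (!all(c("gene_id", "chromosome") %in% names(assignment))) {
    stop("'assignment' needs columns gene_id and chromosome")
  }
  if (anyDuplicated(assignment$gene_id)) {
    dup <- assignment$gene_id[duplicated(assignment$gene_id)][1]
    stop("input error: gene '", dup, "' assigned to more than one chromosome")
  }
  if (is.null(gene_set)) gene_set <- assignment$gene_id
  gene_set <- unique(as.character(gene_set))
  known <- gene_set %in% assignment$gene_id
  if (any(!known)) {
    warning(sum(!known), " gene(s) not in the assignment were skipped")
  }
  members <- assignment[assignment$gene_id %in% gene_set[known],
                        c("gene_id", "chromosome")]
  groups <- split(members$gene_id, members$chromosome)
  edge_list <- lapply(groups, function(g) {
    if (length(g) < 2L) return(NULL)
    t(combn(sort(g), 2L))
  })
  edges <- do.call(rbind, edge_list)
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2L)
  net <- coloc_network(edges, species = species)
  attr(net, "skipped") <- sum(!known)
  net
}

#' Relabel a network through a homology map
#'
#' Renames the nodes of a species-2 network to their species-1 counterparts
#' (or the other way round, via [invert_map()]). Nodes without a resolved
#' homolog are dropped together with their edges, and the pruned graph loses
#' any isolates that this creates.
#'
#' @param net a [coloc_network()] whose node ids match the map's queries.
#' @param map a one-to-one `homology_map`; queries are the current node
#'   ids, targets the new ones.
#' @param species species tag for the relabelled network.
#' @return a [coloc_network()] on the target id namespace.
#' @export
relabel_by_homology <- function(net, map, species = net$species) {
  stopifnot(inherits(net, "coloc_network"), inherits(map, "homology_map"))
  if (anyDuplicated(map$pairs$query_id) || anyDuplicated(map$pairs$target_id)) {
    stop("homology map must be injective in both directions")
  }
  lut <- setNames(map$pairs$target_id, map$pairs$query_id)
  a <- unname(lut[net$edges[, 1]])
  b <- unname(lut[net$edges[, 2]])
  keep <- !is.na(a) & !is.na(b)
  coloc_network(cbind(a[keep], b[keep]), species = species)
}

#' Intersect two co-localization networks
#'
#' Keeps only the nodes and the edges present in both networks (which must
#' already share one id namespace — relabel one of them first). An edge
#' survives when its two genes are co-chromosomal in both species; the
#' chromosomes themselves need not correspond. Isolates created by the
#' intersection are removed and statistics recomputed. The operation is
#' commutative and idempotent.
#'
#' @param net_a,net_b [coloc_network()] objects on a common namespace.
#' @param species species tag for the result (default combines the parents').
#' @return a [coloc_network()].
#' @export
intersect_networks <- function(net_a, net_b, species = NULL) {
  stopifnot(inherits(net_a, "coloc_network"), inherits(net_b, "coloc_network"))
  if (is.null(species)) {
    species <- paste(unique(c(net_a$species, net_b$species)), collapse = " ^ ")
  }
  common_nodes <- intersect(net_a$nodes, net_b$nodes)
  key_a <- paste(net_a$edges[, 1], net_a$edges[, 2], sep = "\r")
  key_b <- paste(net_b$edges[, 1], net_b$edges[, 2], sep = "\r")
  edges <- net_a$edges[key_a %in% key_b, , drop = FALSE]
  keep <- edges[, 1] %in% common_nodes & edges[, 2] %in% common_nodes
  coloc_network(edges[keep, , drop = FALSE], species = species)
}

#' Chromosomal localization conservation score
#'
#' The percentage of the species-1 network's genes that survive into the
#' cross-species intersection network: `100 * n_intersection_nodes /
#' n_species1_nodes`, rounded half-up to the nearest integer percent. Both
#' node counts are taken after isolate removal.
#'
#' `conservation_percent()` is the bare arithmetic on two node counts, for
#' use with published network statistics.
#'
#' @param intersection the intersection [coloc_network()].
#' @param species1_net the species-1 [coloc_network()] (must be non-empty).
#' @return integer percent in \[0, 100\].
#' @examples
#' conservation_percent(33, 51)   # 8-h gene sets: 65
#' conservation_percent(45, 199)  # 12-h: 23
#' conservation_percent(103, 1827) # 24-h: 6
#' @export
conservation_score <- function(intersection, species1_net) {
  stopifnot(inherits(intersection, "coloc_network"),
            inherits(species1_net, "coloc_network"))
  conservation_percent(intersection$stats[["n_nodes"]],
                       species1_net$stats[["n_nodes"]])
}

#' @rdname conservation_score
#' @param n_intersection,n_species1 node counts of the intersection and
#'   species-1 networks.
#' @export
conservation_percent <- function(n_intersection, n_species1) {
  if (n_species1 <= 0) {
    stop("conservation undefined: species-1 network has no nodes")
  }
  if (n_intersection < 0 || n_intersection > n_species1) {
    stop("intersection node count must lie in [0, n_species1]")
  }
  as.integer(floor(100 * n_intersection / n_species1 + 0.5))  # half-up
}

#' Per-chromosome coverage by a gene set
#'
#' Fraction of each chromosome's genes that belong to the gene set — the
#' quantity usually shown as per-chromosome bar plots of oscillating-gene
#' density. Chromosomes without set members report 0.
#'
#' @param assignment data frame with `gene_id` and `chromosome`.
#' @param gene_set character vector of gene ids.
#' @param totals named numeric vector, total genes per chromosome; must
#'   cover every chromosome in the assignment. Defaults to counting the
#'   assignment itself.
#' @return named numeric vector of fractions, one per chromosome in
#'   `totals`.
#' @export
chromosome_coverage <- function(assignment, gene_set, totals = NULL) {
  if (is.null(totals)) {
    totals <- table(assignment$chromosome)
    totals <- setNames(as.numeric(totals), names(totals))
  }
  miss <- setdiff(unique(assignment$chromosome), names(totals))
  if (length(miss)) {
    stop("'totals' lacks chromosome(s): ", paste(miss, collapse = ", "))
  }
  members <- assignment[assignment$gene_id %in% gene_set, ]
  counts <- table(factor(members$chromosome, levels = names(totals)))
  counts <- setNames(as.numeric(counts), names(totals))
  bad <- names(totals)[totals == 0 & counts > 0]
  if (length(bad)) {
    stop("chromosome(s) with members but zero total: ",
         paste(bad, collapse = ", "))
  }
  out <- ifelse(totals == 0, 0, counts / totals)
  setNames(as.numeric(out), names(totals))
}

#' Network statistics table
#'
#' Collects the reported statistics of several networks into one table with
#' columns `network`, `nodes`, `edges`, `components` — the shape used for
#' published topological summaries of co-localization networks.
#'
#' @param ... named [coloc_network()] objects.
#' @return data frame with one row per network.
#' @export
network_stats_table <- function(...) {
  nets <- list(...)
  if (length(nets) == 1L && is.list(nets[[1]]) &&
      !inherits(nets[[1]], "coloc_network")) {
    nets <- nets[[1]]
  }
  stopifnot(length(nets) > 0L, !is.null(names(nets)))
  do.call(rbind, lapply(names(nets), function(nm) {
    s <- nets[[nm]]$stats
    data.frame(network = nm, nodes = s[["n_nodes"]], edges = s[["n_edges"]],
               components = s[["n_components"]], stringsAsFactors = FALSE)
  }))
}
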
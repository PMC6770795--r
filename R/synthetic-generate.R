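#' Generate a two-species gene assignment with planted conservation
#'
#' Places the species-1 gene universe on chromosomes, labels the 8-h / 12-h /
#' 24-h gene sets, and derives a species-2 counterpart in which chromosomal
#' co-localization is conserved with probability `conservation_rho`:
#' each species-1 chromosome's gene block either migrates as a whole to one
#' common species-2 chromosome (with probability rho) or is broken up, every
#' gene landing apart. Under this block-level planting the probability that
#' any two same-chromosome species-1 genes co-localize in species 2, and the
#' expected node-level conservation score of the downstream intersection
#' network, both equal `conservation_rho`.
#'
#' Every species-1 gene gets one true homolog candidate (carrying the
#' strictly best confidence score); a fraction `multi_map_rate` of genes
#' additionally receives 1-3 decoy candidates with randomized scores, so the
#' one-to-many resolution cascade can be exercised and verified against the
#' planted truth.
#'
#' @param config a [synthetic_config()] object.
#' @return a list of class `two_species_assignment` with elements
#'   `species1`, `species2` (data frames: `gene_id`, `species`, `chromosome`,
#'   `period_class`), `candidates` (homolog candidate table), `truth`
#'   (planted `query_id` -> `target_id` pairs), `sets` (list of gene-id
#'   vectors per period class) and `conserved` (named logical per species-1
#'   chromosome).
#' @export
gen_two_species_assignment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed_offset(config, "assignment"))
  n_chr1 <- config$n_chromosomes_per_species[1]
  n_chr2 <- config$n_chromosomes_per_species[2]
  gpc <- config$genes_per_chromosome
  n_genes <- sum(gpc)

  gene1 <- sprintf("mm_g%05d", seq_len(n_genes))
  gene2 <- sprintf("hs_g%05d", seq_len(n_genes))
  chr1 <- rep(sprintf("chr%d", seq_len(n_chr1)), times = gpc)

  # period-class labels over a disjoint random draw from the universe
  period <- rep("NONE", n_genes)
  pool <- sample.int(n_genes, sum(config$set_sizes))
  sizes <- config$set_sizes
  idx <- split(pool, rep(names(sizes), times = sizes))
  for (cl in names(idx)) period[idx[[cl]]] <- cl
  sets <- lapply(idx, function(i) gene1[sort(i)])[c("P8", "P12", "P24")]

  # plant block-level conservation per species-1 chromosome
  conserved <- stats::runif(n_chr1) < config$conservation_rho
  names(conserved) <- sprintf("chr%d", seq_len(n_chr1))
  home <- sample.int(n_chr2, n_chr1, replace = TRUE)
  chr2 <- character(n_genes)
  chrom_of <- rep(seq_len(n_chr1), times = gpc)
  for (c1 in seq_len(n_chr1)) {
    members <- which(chrom_of == c1)
    if (conserved[c1]) {
      chr2[members] <- sprintf("chr%d", home[c1])
    } else if (config$scatter == "uniform") {
      others <- setdiff(seq_len(n_chr2), home[c1])
      chr2[members] <- sprintf("chr%d", sample(others, length(members),
                                               replace = TRUE))
    } else {
      chr2[members] <- sprintf("scf%05d", members)
    }
  }

  species1 <- data.frame(gene_id = gene1, species = "species1",
                         chromosome = chr1, period_class = period,
                         stringsAsFactors = FALSE)
  species2 <- data.frame(gene_id = gene2, species = "species2",
                         chromosome = chr2, period_class = period,
                         stringsAsFactors = FALSE)

  candidates <- make_candidates(gene1, gene2, config$multi_map_rate)
  truth <- data.frame(query_id = gene1, target_id = gene2,
                      stringsAsFactors = FALSE)

  structure(list(species1 = species1, species2 = species2,
                 candidates = candidates, truth = truth,
                 sets = sets, conserved = conserved),
            class = "two_species_assignment")
}

# true candidate gets the strictly best confidence (1 vs 0 for decoys);
# remaining scores randomized so lower cascade keys carry no planted signal
make_candidates <- function(gene1, gene2, multi_map_rate) {
  n <- length(gene1)
  true_cand <- data.frame(
    query_id = gene1,
    target_id = gene2,
    confidence = 1,
    goc = round(stats::runif(n, 50, 100), 2),
    target_pid = round(stats::runif(n, 50, 100), 2),
    query_pid = round(stats::runif(n, 50, 100), 2),
    dn_ds = round(stats::runif(n, 0, 0.3), 4),
    stringsAsFactors = FALSE
  )
  multi <- which(stats::runif(n) < multi_map_rate)
  if (length(multi) == 0L) return(true_cand)
  n_decoy <- sample(1:3, length(multi), replace = TRUE)
  qidx <- rep(multi, times = n_decoy)
  m <- length(qidx)
  decoys <- data.frame(
    query_id = gene1[qidx],
    target_id = gene2[vapply(qidx, function(i) sample(seq_len(n)[-i], 1L),
                             integer(1))],
    confidence = 0,
    goc = ifelse(stats::runif(m) < 0.1, NA_real_,
                 round(stats::runif(m, 0, 100), 2)),
    target_pid = round(stats::runif(m, 0, 100), 2),
    query_pid = round(stats::runif(m, 0, 100), 2),
    dn_ds = ifelse(stats::runif(m) < 0.1, NA_real_,
                   round(stats::runif(m, 0, 2), 4)),
    stringsAsFactors = FALSE
  )
  out <- rbind(true_cand, decoys)
  out <- out[order(out$query_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a protein-protein interaction reference with planted enrichment
#'
#' Draws an Erdos-Renyi background over the node universe and replaces the
#' edges between `focal_set` and `target_set` with draws at the inflated
#' probability `min(1, ppi_edge_prob * (1 + enrichment_delta))`, planting an
#' excess connectivity between the focal gene set and the target subnetwork
#' that the permutation test should detect. The graph is simple and
#' undirected with no self-loops.
#'
#' @param config a [synthetic_config()] object (`ppi_n_nodes`,
#'   `ppi_edge_prob`, `enrichment_delta` are used).
#' @param focal_set,target_set disjoint character vectors of node ids; both
#'   must be contained in the node universe.
#' @param nodes optional character vector naming the node universe; defaults
#'   to `p0001 ... pN` with `N = ppi_n_nodes`, extended to cover the two
#'   sets if they use other ids.
#' @return an [interaction_reference()] object.
#' @export
gen_ppi <- function(config, focal_set, target_set, nodes = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  focal_set <- unique(as.character(focal_set))
  target_set <- unique(as.character(target_set))
  if (length(intersect(focal_set, target_set)) > 0L) {
    stop("focal and target sets must be disjoint")
  }
  if (is.null(nodes)) {
    nodes <- sprintf("p%04d", seq_len(config$ppi_n_nodes))
    extra <- setdiff(c(focal_set, target_set), nodes)
    if (length(extra)) {
      # keep the universe at ppi_n_nodes where possible, set ids first
      n_fill <- max(0L, config$ppi_n_nodes - length(extra))
      nodes <- c(extra, nodes[seq_len(n_fill)])
    }
  }
  nodes <- unique(as.character(nodes))
  if (!all(c(focal_set, target_set) %in% nodes)) {
    stop("focal and target sets must be drawn from the node universe")
  }
  set.seed(seed_offset(config, "ppi"))
  g <- igraph::sample_gnp(length(nodes), config$ppi_edge_prob)
  em <- igraph::as_edgelist(g, names = FALSE)
  edges <- cbind(nodes[em[, 1]], nodes[em[, 2]])
  # background edges between the two sets are re-drawn at the planted rate
  is_cross <- (edges[, 1] %in% focal_set & edges[, 2] %in% target_set) |
    (edges[, 1] %in% target_set & edges[, 2] %in% focal_set)
  edges <- edges[!is_cross, , drop = FALSE]
  if (is.infinite(config$enrichment_delta)) {
    p_cross <- 1
  } else {
    p_cross <- min(1, config$ppi_edge_prob * (1 + config$enrichment_delta))
  }
  cross <- expand.grid(a = focal_set, b = target_set,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(cross)) < p_cross
  edges <- rbind(edges, as.matrix(cross[keep, , drop = FALSE]))
  interaction_reference(edges, nodes = nodes,
                        provenance = sprintf(
                          "synthetic ER(n=%d, p=%g) + planted delta=%g",
                          length(nodes), config$ppi_edge_prob,
                          config$enrichment_delta))
}

#' Generate a per-protein energy feature table
#'
#' Samples each of the 18 energy features independently per protein from a
#' normal law with the configured (group, feature) mean and standard
#' deviation. `Residue Number` is rounded to an integer with a floor of 30
#' residues (smaller chains are not realistic structures). Feature
#' independence is a deliberate simplification: empirical correlations among
#' energy terms are an output of the downstream analysis, not a generative
#' assumption here.
#'
#' @param config a [synthetic_config()] object (its `energy_params` and seed
#'   are used).
#' @param n_per_group named integer vector: proteins per group. Defaults to
#'   the configured set sizes plus a non-oscillating control of matching
#'   total size.
#' @return data frame of class `energy_table` with columns `protein_id`,
#'   `group` and the 18 feature columns of [energy_features()].
#' @export
gen_energy_table <- function(config, n_per_group = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(n_per_group)) {
    n_per_group <- c(config$set_sizes, NONOSC = sum(config$set_sizes))
  }
  if (is.null(names(n_per_group)) || any(names(n_per_group) == "")) {
    stop("'n_per_group' must be a named vector of group sizes")
  }
  ep <- config$energy_params
  feats <- unique(ep$feature)
  set.seed(seed_offset(config, "energy"))
  blocks <- lapply(names(n_per_group), function(grp) {
    n <- as.integer(n_per_group[[grp]])
    rows <- ep[ep$group == grp, , drop = FALSE]
    missing <- setdiff(feats, rows$feature)
    if (nrow(rows) == 0L || length(missing)) {
      stop("config error: no (group, feature) parameters for group '", grp,
           "'", if (length(missing)) paste0(" feature(s) ",
                                            paste(missing, collapse = ", ")))
    }
    vals <- vapply(feats, function(f) {
      pr <- rows[rows$feature == f, ]
      stats::rnorm(n, pr$mean, pr$sd)
    }, numeric(n))
    if (n == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, feats))
    df <- data.frame(protein_id = sprintf("prot_%s_%04d", grp, seq_len(n)),
                     group = grp, stringsAsFactors = FALSE)
    cbind(df, as.data.frame(vals, check.names = FALSE))
  })
  out <- do.call(rbind, blocks)
  if ("Residue Number" %in% names(out)) {
    out[["Residue Number"]] <- pmax(30L, as.integer(round(out[["Residue Number"]])))
  }
  rownames(out) <- NULL
  class(out) <- c("energy_table", "data.frame")
  out
}
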
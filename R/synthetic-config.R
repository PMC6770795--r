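#' Configuration for the synthetic two-species study
#'
#' Bundles every tunable of the synthetic-data generators into one validated
#' object. The defaults emulate the mouse-liver study conditions this package
#' is built around: a mouse-sized genome of 21 chromosomes against a
#' human-sized one of 24, and oscillating gene-set sizes of 56 (8-h),
#' 205 (12-h) and 2054 (24-h) transcripts.
#'
#' @param seed integer master seed. Each sub-generator derives its own stream
#'   from it by a fixed offset, so assignments, interaction graphs and energy
#'   tables can be regenerated independently yet reproducibly.
#' @param n_chromosomes_per_species integer of length 1 or 2: chromosome
#'   counts for species 1 and species 2 (recycled if length 1).
#' @param genes_per_chromosome integer: genes on each species-1 chromosome
#'   (constant, or one value per chromosome).
#' @param set_sizes named integer vector with names `P8`, `P12`, `P24`:
#'   how many genes belong to each period class. Must sum to at most the
#'   total gene count.
#' @param conservation_rho probability in \[0, 1\] that a species-1
#'   chromosome's gene block stays co-localized on one common species-2
#'   chromosome. It is simultaneously the probability that any two
#'   same-chromosome species-1 genes co-localize in species 2, and the
#'   expected value of the downstream conservation score.
#' @param multi_map_rate probability in \[0, 1\] that a gene receives decoy
#'   homolog candidates (2-4 candidates total) in addition to its true one.
#' @param ppi_n_nodes number of proteins in the synthetic interaction
#'   reference.
#' @param ppi_edge_prob background edge probability of the interaction
#'   reference (Erdos-Renyi).
#' @param enrichment_delta non-negative multiplier planted on the cross-set
#'   edge probability: edges between the focal set and the target subnetwork
#'   appear with probability `min(1, ppi_edge_prob * (1 + enrichment_delta))`.
#' @param target_set_size size of the designated target subnetwork (the
#'   stand-in for a reference circadian gene network, whose true size is not
#'   published).
#' @param energy_params data frame with columns `group`, `feature`, `mean`,
#'   `sd` giving the per-group sampling law of each energy feature; defaults
#'   to [default_energy_params()].
#' @param scatter how genes of a non-conserved chromosome block are placed in
#'   species 2: `"dispersed"` (default) gives each its own unique chromosome
#'   label, so co-localization in species 2 arises only from the planted
#'   conservation; `"uniform"` draws a species-2 chromosome uniformly at
#'   random, adding a realistic background of chance co-localization.
#' @return an object of class `synthetic_config` (a validated list).
#' @seealso [gen_two_species_assignment()], [gen_ppi()], [gen_energy_table()]
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes_per_species = c(21L, 24L),
                             genes_per_chromosome = 120L,
                             set_sizes = c(P8 = 56L, P12 = 205L, P24 = 2054L),
                             conservation_rho = 0.6,
                             multi_map_rate = 0.3,
                             ppi_n_nodes = 1000L,
                             ppi_edge_prob = 0.01,
                             enrichment_delta = 4,
                             target_set_size = 100L,
                             energy_params = default_energy_params(),
                             scatter = c("dispersed", "uniform")) {
  scatter <- match.arg(scatter)
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > 2^31 - 1e4) {
    stop("'seed' must be an integer of magnitude below 2^31 - 10000")
  }
  n_chr <- as.integer(rep_len(n_chromosomes_per_species, 2L))
  if (any(n_chr < 1L)) stop("chromosome counts must be >= 1")
  gpc <- as.integer(genes_per_chromosome)
  if (length(gpc) == 1L) gpc <- rep(gpc, n_chr[1L])
  if (length(gpc) != n_chr[1L]) {
    stop("'genes_per_chromosome' must have length 1 or n_chromosomes (species 1)")
  }
  if (any(gpc < 1L)) stop("'genes_per_chromosome' must be >= 1")
  if (is.null(names(set_sizes)) || !all(c("P8", "P12", "P24") %in% names(set_sizes))) {
    stop("'set_sizes' must be named with P8, P12 and P24")
  }
  set_sizes <- vapply(set_sizes[c("P8", "P12", "P24")], as.integer, integer(1))
  if (any(set_sizes < 0L)) stop("'set_sizes' must be non-negative")
  if (sum(set_sizes) > sum(gpc)) {
    stop("config error: set sizes (", sum(set_sizes),
         ") exceed the gene universe (", sum(gpc), ")")
  }
  for (p in c(conservation_rho = conservation_rho,
              multi_map_rate = multi_map_rate,
              ppi_edge_prob = ppi_edge_prob)) {
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) {
      stop("probabilities must lie in [0, 1]")
    }
  }
  if (!is.numeric(enrichment_delta) || is.na(enrichment_delta) ||
      enrichment_delta < 0) {
    stop("'enrichment_delta' must be a non-negative real (Inf allowed)")
  }
  ppi_n_nodes <- as.integer(ppi_n_nodes)
  target_set_size <- as.integer(target_set_size)
  if (ppi_n_nodes < 2L) stop("'ppi_n_nodes' must be >= 2")
  validate_energy_params(energy_params)
  structure(
    list(seed = seed,
         n_chromosomes_per_species = n_chr,
         genes_per_chromosome = gpc,
         set_sizes = set_sizes,
         conservation_rho = conservation_rho,
         multi_map_rate = multi_map_rate,
         ppi_n_nodes = ppi_n_nodes,
         ppi_edge_prob = ppi_edge_prob,
         enrichment_delta = enrichment_delta,
         target_set_size = target_set_size,
         energy_params = energy_params,
         scatter = scatter),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic study configuration (seed ", x$seed, ")\n", sep = "")
  cat("  species 1: ", x$n_chromosomes_per_species[1], " chromosomes, ",
      sum(x$genes_per_chromosome), " genes\n", sep = "")
  cat("  species 2: ", x$n_chromosomes_per_species[2], " chromosomes\n", sep = "")
  cat("  gene sets: ", paste(names(x$set_sizes), x$set_sizes,
                             sep = "=", collapse = ", "), "\n", sep = "")
  cat("  conservation rho ", x$conservation_rho,
      ", multi-map rate ", x$multi_map_rate, "\n", sep = "")
  cat("  PPI: ", x$ppi_n_nodes, " nodes, p = ", x$ppi_edge_prob,
      ", planted delta = ", x$enrichment_delta, "\n", sep = "")
  invisible(x)
}

validate_energy_params <- function(ep) {
  need <- c("group", "feature", "mean", "sd")
  if (!is.data.frame(ep) || !all(need %in% names(ep))) {
    stop("'energy_params' must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  if (anyNA(ep$mean) || anyNA(ep$sd) || any(ep$sd < 0)) {
    stop("config error: every (group, feature) needs a finite mean and sd >= 0")
  }
  if (anyDuplicated(ep[c("group", "feature")])) {
    stop("config error: duplicated (group, feature) rows in 'energy_params'")
  }
  invisible(ep)
}

#' Read a synthetic configuration from a YAML file
#'
#' Fields follow the arguments of [synthetic_config()]; `energy_params` may be
#' omitted (the built-in defaults are used) or given as a list of records with
#' `group`, `feature`, `mean`, `sd`.
#'
#' @param path path to a YAML file.
#' @return a `synthetic_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$set_sizes)) raw$set_sizes <- unlist(raw$set_sizes)
  if (!is.null(raw$energy_params)) {
    raw$energy_params <- do.call(rbind, lapply(raw$energy_params, as.data.frame))
  }
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(synthetic_config, raw)
}

#' The 18 protein energy features
#'
#' Column names of the per-protein energy table, matching the terms of the
#' FoldX empirical force field as reported for oscillating-protein studies:
#' total folding free energy (`Delta_G`), backbone and side-chain hydrogen
#' bonds, van der Waals terms, solvation penalties for polar and hydrophobic
#' groups, electrostatics (including the helix dipole and the inter-molecular
#' precomplex term), water bridges, bound-metal interactions, ionisation
#' energy and complex entropy, plus the residue count of the structure.
#'
#' @return character vector of length 18.
#' @export
energy_features <- function() {
  c("Residue Number", "Delta_G", "H-bonds_Backbone", "H-bonds_Sidechain",
    "Energy_VanderWaals", "Electrostat_Int", "Penal_PolarGroups",
    "Cont_Hydrophobic", "Penal_VanderWaals", "VanderWaals_Torsion",
    "Backbone_VanderWaals", "Water Bonds", "Electrostatic_HelixDipole",
    "Cost_PeptideBond", "Electrostat_Precomplex", "Interaction_BoundMetals",
    "Energy_Ionisation", "Entropy_Complex")
}

#' Reference sampling parameters for the energy features
#'
#' Per-group mean and standard deviation of each of the 18 energy features,
#' taken from published descriptive statistics of FoldX energies for proteins
#' encoded by 8-h, 12-h and 24-h oscillating genes and by a non-oscillating
#' control set. These are the default sampling laws of [gen_energy_table()].
#'
#' @return data frame with columns `group` (`P8`, `P12`, `P24`, `NONOSC`),
#'   `feature`, `mean`, `sd`; one row per (group, feature) pair.
#' @export
default_energy_params <- function() {
  f <- energy_features()
  # columns: P8 mean, P8 sd, P12 mean, P12 sd, P24 mean, P24 sd, NONOSC mean, NONOSC sd
  m <- matrix(c(
    224.0,  136.6,   373.3,  232.1,   321.8,  188.5,   313.3,  165.5,   # Residue Number
    81.91,  133.64,  13.53,  95.47,   21.64,  125.74,  29.84,  91.09,   # Delta_G
    -135.4, 95.49,   -236.2, 157.46,  -206,   104.26,  -209.4, 121.7,   # H-bonds_Backbone
    -61.66, 56.19,   -103.98, 65.35,  -87.67, 45.53,   -89.31, 52.65,   # H-bonds_Sidechain
    -239.1, 168.5,   -407.4, 260.7,   -354.5, 191.4,   -363.0, 211.2,   # Energy_VanderWaals
    -8.291, 9.198,   -16.011, 9.858,  -13.710, 9.049,  -14.03, 10.912,  # Electrostat_Int
    335.0,  232.3,   541.5,  339.8,   472.6,  255.7,   486.5,  278.3,   # Penal_PolarGroups
    -311.7, 219.0,   -542.3, 350.6,   -470.8, 254.0,   -480.7, 281.7,   # Cont_Hydrophobic
    19.94,  27.56,   22.23,  23.03,   23.46,  53.31,   24.85,  21.93,   # Penal_VanderWaals
    126.9,  91.05,   223.1,  151.23,  188.2,  100.39,  191.1,  109.7,   # VanderWaals_Torsion
    352.1,  228.7,   532.7,  331.3,   467.9,  263.5,   485.1,  258.7,   # Backbone_VanderWaals
    0.237,  0.451,   0.550,  0.742,   0.745,  1.227,   0.693,  1.024,   # Water Bonds
    8.414,  8.079,   12.091, 9.241,   11.769, 11.938,  12.04,  8.639,   # Electrostatic_HelixDipole
    -3.399, 3.684,   -5.705, 5.276,   -5.401, 4.399,   -5.511, 6.128,   # Cost_PeptideBond
    0.000,  0.000,   0.000,  0.000,   -1.373, 5.422,   -3.606, 7.590,   # Electrostat_Precomplex
    0.000,  0.000,   -0.053, 0.288,   -0.011, 0.129,   0.000,  0.000,   # Interaction_BoundMetals
    -1.984, 4.856,   -8.547, 14.491,  -4.628, 12.589,  -6.075, 15.55,   # Energy_Ionisation
    0.865,  0.876,   1.379,  1.0124,  1.215,  0.951,   1.108,  0.820    # Entropy_Complex
  ), ncol = 8L, byrow = TRUE)
  groups <- c("P8", "P12", "P24", "NONOSC")
  data.frame(
    group = rep(groups, each = length(f)),
    feature = rep(f, times = length(groups)),
    mean = c(m[, 1], m[, 3], m[, 5], m[, 7]),
    sd = c(m[, 2], m[, 4], m[, 6], m[, 8]),
    stringsAsFactors = FALSE
  )
}

# fixed offsets carving independent streams out of the master seed
seed_offset <- function(config, stage) {
  config$seed + switch(stage,
                       assignment = 101L,
                       ppi = 202L,
                       energy = 303L,
                       pipeline = 404L,
                       stop("unknown seed stage: ", stage))
}
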
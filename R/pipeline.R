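#' Write every synthetic input the pipeline consumes
#'
#' Runs the three generators of a [synthetic_config()] and writes their
#' outputs as plain files: two gene-assignment tables, the homolog
#' candidate table (plus the planted truth, for calibration), one gene-set
#' file per period class, the interaction reference as both MITAB and edge
#' TSV together with the focal and target set files, and the energy feature
#' table. The focal set of the interaction experiment is the 8-h gene set;
#' the target subnetwork — the stand-in for a reference circadian gene
#' network — is a random draw of `target_set_size` genes outside the focal
#' set, taken from the species-1 gene universe over which the interaction
#' graph is built.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the written file paths, invisibly.
#' @export
write_synthetic_inputs <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  asg <- gen_two_species_assignment(config)
  write_tsv(asg$species1, p("assignment_species1.tsv"))
  write_tsv(asg$species2, p("assignment_species2.tsv"))
  write_tsv(asg$candidates, p("homolog_candidates.tsv"))
  write_tsv(asg$truth, p("homolog_truth.tsv"))
  for (cl in names(asg$sets)) {
    write_gene_set(asg$sets[[cl]], p(sprintf("set_%s.txt", cl)))
  }

  focal <- asg$sets$P8
  set.seed(seed_offset(config, "pipeline"))
  pool <- setdiff(asg$species1$gene_id, focal)
  if (length(pool) < config$target_set_size) {
    stop("config error: target_set_size exceeds the non-focal gene universe")
  }
  target <- sort(sample(pool, config$target_set_size))
  ref <- gen_ppi(config, focal, target, nodes = asg$species1$gene_id)
  write_mitab(ref, p("interactions.mitab"))
  write_edges(ref, p("interactions_edges.tsv"))
  write_gene_set(focal, p("ppi_focal_set.txt"))
  write_gene_set(target, p("ppi_target_set.txt"))

  energy <- gen_energy_table(config)
  write_tsv(energy, p("energy_table.tsv"))

  files <- c(species1 = p("assignment_species1.tsv"),
             species2 = p("assignment_species2.tsv"),
             candidates = p("homolog_candidates.tsv"),
             truth = p("homolog_truth.tsv"),
             set_P8 = p("set_P8.txt"), set_P12 = p("set_P12.txt"),
             set_P24 = p("set_P24.txt"),
             mitab = p("interactions.mitab"),
             edges = p("interactions_edges.tsv"),
             focal = p("ppi_focal_set.txt"),
             target = p("ppi_target_set.txt"),
             energy = p("energy_table.tsv"))
  invisible(files)
}

#' Run the co-localization analysis for one period class
#'
#' Builds the species-1 network on the gene set, the species-2 network on
#' the set's resolved homologs, relabels the latter back to species-1 ids,
#' intersects the two, and reports networks, statistics, mapping coverage
#' and the conservation score.
#'
#' @param assignment1,assignment2 gene assignment data frames for the two
#'   species.
#' @param gene_set character vector of species-1 gene ids.
#' @param map a one-to-one `homology_map` from species-1 to species-2 ids.
#' @param label name used in the statistics table (e.g. `"P8"`).
#' @return list with `net1`, `net2`, `intersection` ([coloc_network()]s),
#'   `conservation_pct`, `coverage` and `stats` (a
#'   [network_stats_table()]).
#' @export
coloc_pipeline <- function(assignment1, assignment2, gene_set, map,
                           label = "set") {
  coverage <- mapping_coverage(map, gene_set)
  net1 <- build_coloc_network(assignment1, gene_set, species = "species1")
  lut <- setNames(map$pairs$target_id, map$pairs$query_id)
  set2 <- unname(lut[gene_set[gene_set %in% names(lut)]])
  net2 <- build_coloc_network(assignment2, set2, species = "species2")
  net2_rel <- relabel_by_homology(net2, invert_map(map), species = "species2")
  inter <- intersect_networks(net1, net2_rel, species = "intersection")
  nets <- list(net1, net2, inter)
  names(nets) <- paste(c("species1", "species2", "intersection"), label)
  list(net1 = net1, net2 = net2, intersection = inter,
       conservation_pct = if (net1$stats[["n_nodes"]] > 0)
         conservation_score(inter, net1) else NA_integer_,
       coverage = coverage,
       stats = network_stats_table(nets))
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order — simulate, map-homologs,
#' co-localization networks, connectivity permutation test, energy-feature
#' statistics — writing each stage's outputs as plain files under
#' `out_dir` and recording a JSON run manifest (`manifest.json`) with the
#' configuration snapshot, seeds, per-stage status and timing, and an MD5
#' hash of every output file. Re-running with the same configuration and
#' seed reproduces hash-identical outputs; a failing stage leaves the
#' completed stages' outputs in place and records the error in the
#' manifest before the error propagates.
#'
#' @param config a [synthetic_config()], or the path to a YAML file for
#'   [read_config()].
#' @param out_dir output directory.
#' @param n_iter iterations of the connectivity permutation test.
#' @return the manifest, invisibly (a list).
#' @export
run_all <- function(config, out_dir, n_iter = 100L) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  manifest <- list(
    tool = paste("harmonet", as.character(utils::packageVersion("harmonet"))),
    seed = config$seed,
    config = config[setdiff(names(config), "energy_params")],
    stages = list(), files = character(0)
  )
  flush_manifest <- function() {
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, force = TRUE, digits = NA)
  }
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    elapsed <- round(proc.time()[["elapsed"]] - t0, 3)
    ok <- !inherits(res, "error")
    manifest$stages[[name]] <<- list(
      status = if (ok) "ok" else "error",
      seconds = elapsed,
      error = if (ok) NULL else conditionMessage(res))
    if (!ok) {
      flush_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(res))
    }
    res
  }

  stage("simulate", function() write_synthetic_inputs(config, out_dir))

  map <- stage("map_homologs", function() {
    cand <- read_homolog_candidates(p("homolog_candidates.tsv"))
    m <- resolve_homologs(cand)
    write_homology_map(m, p("homology_map.tsv"), p("unmapped_queries.txt"))
    m
  })

  coloc <- stage("coloc", function() {
    asg1 <- read_assignment(p("assignment_species1.tsv"))
    asg2 <- read_assignment(p("assignment_species2.tsv"))
    res <- list()
    stats <- list()
    conservation <- list()
    for (cl in c("P8", "P12", "P24")) {
      gene_set <- read_gene_set(p(sprintf("set_%s.txt", cl)))
      r <- coloc_pipeline(asg1, asg2, gene_set, map, label = cl)
      write_sif(r$intersection, p(sprintf("intersection_%s.sif", cl)))
      write_graphml(r$intersection, p(sprintf("intersection_%s.graphml", cl)))
      write_sif(r$net1, p(sprintf("network_species1_%s.sif", cl)))
      write_sif(r$net2, p(sprintf("network_species2_%s.sif", cl)))
      stats[[cl]] <- r$stats
      conservation[[cl]] <- data.frame(
        period_class = cl, conservation_pct = r$conservation_pct,
        n_mapped = r$coverage[["n_mapped"]],
        n_total = r$coverage[["n_total"]])
      res[[cl]] <- r
    }
    write_tsv(do.call(rbind, stats), p("network_stats.tsv"))
    write_tsv(do.call(rbind, conservation), p("conservation.tsv"))
    res
  })

  perm <- stage("permtest", function() {
    ref <- read_interactions(p("interactions_edges.tsv"))
    focal <- read_gene_set(p("ppi_focal_set.txt"))
    target <- read_gene_set(p("ppi_target_set.txt"))
    res <- connectivity_test(ref, focal, target, n_iter = n_iter,
                             seed = seed_offset(config, "pipeline"))
    jsonlite::write_json(unclass(res), p("connectivity.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res
  })

  stats_res <- stage("stats", function() {
    energy <- read_energy_table(p("energy_table.tsv"))
    res <- compare_energy_groups(energy, adjust_for_residues = TRUE)
    write_tsv(res$descriptives, p("energy_descriptives.tsv"))
    write_tsv(res$kw, p("energy_kw.tsv"))
    write_tsv(res$dunn, p("energy_dunn.tsv"))
    sp <- spearman_matrix(energy, groups = c("P8", "P12", "P24"))
    write_tsv(cbind(feature = rownames(sp$rho),
                    as.data.frame(sp$rho, check.names = FALSE)),
              p("spearman_oscillating.tsv"))
    sp0 <- spearman_matrix(energy, groups = "NONOSC")
    write_tsv(cbind(feature = rownames(sp0$rho),
                    as.data.frame(sp0$rho, check.names = FALSE)),
              p("spearman_nonoscillating.tsv"))
    res
  })

  outputs <- setdiff(list.files(out_dir, full.names = TRUE),
                     p("manifest.json"))
  manifest$files <- as.list(tools::md5sum(outputs))
  names(manifest$files) <- basename(outputs)
  flush_manifest()

  invisible(c(manifest,
              list(results = list(coloc = coloc, connectivity = perm,
                                  energy = stats_res))))
}
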
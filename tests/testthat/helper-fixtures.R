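# shared fixture builders; everything is generated in code

ref_from_pairs <- function(...) {
  interaction_reference(do.call(rbind, list(...)))
}

path_graph <- function(ids) {
  interaction_reference(cbind(ids[-length(ids)], ids[-1]))
}

# minimal homolog candidate row(s); scores default to missing
cand_rows <- function(query, target, confidence = NA_real_, goc = NA_real_,
                      target_pid = NA_real_, query_pid = NA_real_,
                      dn_ds = NA_real_) {
  data.frame(query_id = query, target_id = target, confidence = confidence,
             goc = goc, target_pid = target_pid, query_pid = query_pid,
             dn_ds = dn_ds, stringsAsFactors = FALSE)
}

identity_map <- function(ids) {
  structure(list(pairs = data.frame(query_id = ids, target_id = ids,
                                    stringsAsFactors = FALSE),
                 unmapped = character(0)),
            class = "homology_map")
}

map_of <- function(query, target) {
  structure(list(pairs = data.frame(query_id = query, target_id = target,
                                    stringsAsFactors = FALSE),
                 unmapped = character(0)),
            class = "homology_map")
}

assignment_of <- function(genes, chromosomes) {
  data.frame(gene_id = genes, species = "species1",
             chromosome = chromosomes, period_class = "NONE",
             stringsAsFactors = FALSE)
}

small_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed,
                   n_chromosomes_per_species = c(8, 200),
                   genes_per_chromosome = 10,
                   set_sizes = c(P8 = 10, P12 = 15, P24 = 20),
                   ppi_n_nodes = 120, ppi_edge_prob = 0.02,
                   enrichment_delta = 4, target_set_size = 15)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

# energy table with groups and values given as a named list
energy_of <- function(values_by_group, feature = "Delta_G",
                      residues = NULL) {
  groups <- rep(names(values_by_group), lengths(values_by_group))
  vals <- unlist(values_by_group, use.names = FALSE)
  df <- data.frame(protein_id = sprintf("p%03d", seq_along(vals)),
                   group = groups, stringsAsFactors = FALSE)
  df[[feature]] <- vals
  df[["Residue Number"]] <- if (is.null(residues)) 100L else residues
  df
}
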
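# harmonet

Cross-species network analysis of ultradian and circadian gene sets.

Mammalian transcriptomes contain, besides the well-known circadian (~24 h)
genes, smaller sets oscillating at the second (12 h) and third (8 h)
harmonic of the daily rhythm. `harmonet` implements, as a reusable and
tested R pipeline, the computational stages used to characterize such gene
sets across species:

* **Period classification** — transcripts binned into `P24` (24 ± 4 h),
  `P12` (12 ± 2 h) and `P8` (8 ± 1 h) classes, windows closed at both ends.
* **Homolog resolution** — one-to-many / many-to-many ortholog candidates
  reduced to a one-to-one map by a score priority cascade: confidence,
  gene order conservation (GOC), target %ID, query %ID, dN/dS; ties broken
  deterministically and conflicts settled greedily so the map is injective
  in both directions.
* **Chromosomal co-localization networks** — genes as nodes, an edge
  whenever two genes share a chromosome (one clique per chromosome),
  isolate nodes removed before statistics; mouse and homology-relabelled
  human networks intersected keeping only common nodes and edges (the
  chromosomes themselves need not correspond), and a **conservation
  score**

  `conservation = round(100 · n_intersection_nodes / n_species1_nodes)`

* **Randomized connectivity test** — the number of protein–protein
  interactions between a focal gene set and a target subnetwork compared
  with an empirical null from random node sets of matching size:
  `z = (observed − null mean) / null SD` and an empirical p-value
  `(1 + #{null ≥ observed}) / (iterations + 1)`, plus a brute-force
  exhaustive null for verification on small universes.
* **Protein energy-feature statistics** — per-group mean ± SD tables over
  the 18 FoldX energy terms, tie-corrected Kruskal–Wallis with an optional
  rank-residualization adjustment for residue number, Dunn's post hoc test
  with Benjamini–Hochberg FDR correction, and Spearman correlation
  matrices.
* **Synthetic-data generator** — seeded, byte-reproducible generators for
  every input: two-species chromosome assignments with a tunable
  co-localization conservation probability, homolog candidate tables with
  planted truth, interaction graphs with planted cross-set enrichment, and
  energy tables sampled from published group means/SDs. Generated data are
  labelled synthetic throughout; they stand in for restricted or
  unpublished external resources so every stage can be calibrated.

## Worked example

```r
library(harmonet)

cfg <- synthetic_config(seed = 42,
                        n_chromosomes_per_species = c(15, 400),
                        genes_per_chromosome = 20,
                        set_sizes = c(P8 = 20, P12 = 40, P24 = 80),
                        conservation_rho = 0.6,
                        ppi_n_nodes = 300, target_set_size = 40,
                        enrichment_delta = 6)

asg <- gen_two_species_assignment(cfg)
map <- resolve_homologs(asg$candidates)
map
#> Homology map: 300 resolved pairs, 0 unmapped queries

res <- coloc_pipeline(asg$species1, asg$species2, asg$sets$P12, map, "P12")
res$stats
#>            network nodes edges components
#> 1     species1 P12    38    45         13
#> 2     species2 P12    24    35          7
#> 3 intersection P12    24    35          7
res$conservation_pct
#> [1] 63
```

38 of the 40 12-h genes share a chromosome with another set member in
species 1; 24 of them still co-localize after mapping to species 2, giving
a conservation score of 63% — close to the planted `conservation_rho` of
0.6.

```r
set.seed(1)
target <- sort(sample(setdiff(asg$species1$gene_id, asg$sets$P8), 40))
ref <- gen_ppi(cfg, asg$sets$P8, target, nodes = asg$species1$gene_id)
connectivity_test(ref, asg$sets$P8, target, n_iter = 100, seed = 42)
#> Connectivity test: observed 42 vs null 14.50 +/- 4.05 (100 random sets)
#>   z = 6.78, empirical p = 0.0099
```

The focal 8-h set shows 42 interactions with the target subnetwork while
random sets of the same size average 14.5 ± 4.05 — the planted enrichment
(`enrichment_delta = 6`) is detected at z ≈ 6.8, with the smallest
empirical p-value 100 iterations can produce (1/101).

```r
energy <- gen_energy_table(cfg, n_per_group = c(P8 = 56, P12 = 205, P24 = 300))
d <- dunn_posthoc(energy, "Delta_G", adjust_for_residues = TRUE)
d[d$group_i == "P12" & d$group_j == "P8", ]
#>   feature group_i group_j         z           p      p_adj
#> 2 Delta_G     P12      P8 -2.742436 0.006098539 0.01829562
```

The 8-h proteins' higher folding free energy (lower stability) relative to
the 12-h group is recovered as a significant FDR-corrected contrast.

The whole pipeline can also be run as one reproducible unit,
`run_all(cfg, "out/")`, which writes every intermediate file plus a JSON
manifest with MD5 hashes (re-running with the same seed is hash-identical),
or from the shell via the bundled CLI:

```sh
harmonet=$(Rscript -e 'cat(system.file("cli", "harmonet", package="harmonet"))')
Rscript "$harmonet" run --config config.yaml --out out/
```

## Limitations

The package operates downstream of rhythm detection: it consumes gene sets,
chromosome assignments, homolog candidate tables, interaction tables
(PSI-MI TAB or edge lists) and per-protein energy tables, and does not
fetch Ensembl/biomaRt homology, interaction databases or expression data,
nor run FoldX. The synthetic generator plants conservation at the level of
whole chromosome blocks and samples energy features independently; see the
methods vignette (`vignettes/oscillating-gene-networks.Rmd`) for what that
does and does not emulate.
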
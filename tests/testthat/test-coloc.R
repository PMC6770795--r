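test_that("build yields one clique per chromosome and drops isolates", {
  asg <- assignment_of(paste0("g", 1:6), c("c1", "c1", "c2", "c2", "c2", "c3"))
  net <- build_coloc_network(asg)
  expect_equal(unname(net$stats),
               c(5L, 4L, 2L))  # g6 alone on c3 is an isolate
  expect_false("g6" %in% net$nodes)

  # all genes on distinct chromosomes: empty network
  asg2 <- assignment_of(paste0("g", 1:4), paste0("c", 1:4))
  expect_equal(unname(build_coloc_network(asg2)$stats), c(0L, 0L, 0L))

  # chromosome group sizes 4, 3, 2: edges C(4,2)+C(3,2)+C(2,2) = 10
  asg3 <- assignment_of(paste0("g", 1:9),
                        rep(c("c1", "c2", "c3"), times = c(4, 3, 2)))
  expect_equal(unname(build_coloc_network(asg3)$stats), c(9L, 10L, 3L))
})

test_that("build rejects ambiguous assignments and skips unknown genes", {
  dup <- assignment_of(c("g1", "g1", "g2"), c("c1", "c2", "c1"))
  expect_error(build_coloc_network(dup), "more than one chromosome")
  asg <- assignment_of(paste0("g", 1:4), c("c1", "c1", "c1", "c2"))
  expect_warning(net <- build_coloc_network(asg, c("g1", "g2", "g3", "gX")),
                 "skipped")
  expect_equal(attr(net, "skipped"), 1L)
  expect_equal(unname(net$stats["n_nodes"]), 3L)
})

test_that("relabelling through a homology map drops unmapped genes", {
  asg <- assignment_of(paste0("g", 1:3), rep("c1", 3))
  net <- build_coloc_network(asg)
  ident <- relabel_by_homology(net, identity_map(paste0("g", 1:3)))
  expect_equal(ident$edges, net$edges)
  expect_equal(ident$stats, net$stats)
  # losing one member of a 3-clique leaves a single edge
  m2 <- map_of(c("g1", "g2"), c("h1", "h2"))
  rel <- relabel_by_homology(net, m2)
  expect_equal(unname(rel$stats), c(2L, 1L, 1L))
  expect_equal(sort(rel$nodes), c("h1", "h2"))
  # an 80%-coverage map on a 10-clique: 8 survivors give C(8,2) edges
  big <- build_coloc_network(assignment_of(sprintf("g%02d", 1:10),
                                           rep("c1", 10)))
  m8 <- identity_map(sprintf("g%02d", 1:8))
  expect_equal(unname(relabel_by_homology(big, m8)$stats), c(8L, 28L, 1L))
  # non-injective maps are rejected
  bad <- map_of(c("g1", "g2"), c("h1", "h1"))
  expect_error(relabel_by_homology(net, bad), "injective")
})

test_that("intersection keeps only common nodes and edges", {
  a <- coloc_network(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                           c("d", "e")))
  b <- coloc_network(rbind(t(combn(c("a", "b", "c", "d"), 2)),
                           c("e", "f")))
  i <- intersect_networks(a, b)
  expect_equal(i$nodes, c("a", "b", "c"))
  expect_equal(unname(i$stats), c(3L, 3L, 1L))
  # commutative and idempotent
  expect_equal(intersect_networks(b, a)$edges, i$edges)
  expect_equal(intersect_networks(a, a)$edges, a$edges)
  expect_equal(unname(intersect_networks(a, a)$stats), unname(a$stats))
  # disjoint networks intersect to nothing
  d <- coloc_network(rbind(c("x", "y")))
  expect_equal(unname(intersect_networks(a, d)$stats), c(0L, 0L, 0L))
  # stats never exceed either parent
  expect_true(all(i$stats[c("n_nodes", "n_edges")] <=
                    pmin(a$stats, b$stats)[c("n_nodes", "n_edges")]))
})

test_that("conservation percentages reproduce half-up integer rounding", {
  expect_identical(conservation_percent(0, 10), 0L)
  expect_identical(conservation_percent(10, 10), 100L)
  expect_identical(conservation_percent(1, 8), 13L)   # 12.5 rounds up
  expect_identical(conservation_percent(1, 200), 1L)  # 0.5 rounds up
  expect_error(conservation_percent(1, 0), "undefined")
  expect_error(conservation_percent(5, 4), "\\[0, n_species1\\]")
  n <- build_coloc_network(assignment_of(paste0("g", 1:4), rep("c1", 4)))
  expect_identical(conservation_score(n, n), 100L)
})

test_that("every emitted component is a clique with edges = sum C(n,2)", {
  set.seed(11)
  for (rep in 1:10) {
    n_genes <- sample(10:40, 1)
    genes <- sprintf("g%02d", seq_len(n_genes))
    asg1 <- assignment_of(genes, sample(paste0("c", 1:6), n_genes, TRUE))
    asg2 <- assignment_of(genes, sample(paste0("k", 1:6), n_genes, TRUE))
    n1 <- build_coloc_network(asg1)
    n2 <- build_coloc_network(asg2)
    for (net in list(n1, n2, intersect_networks(n1, n2))) {
      if (net$stats["n_nodes"] == 0) next
      g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
      sizes <- igraph::components(g)$csize
      expect_equal(net$stats[["n_edges"]], sum(choose(sizes, 2)))
      expect_equal(net$stats[["n_components"]], length(sizes))
      expect_gte(net$stats[["n_edges"]],
                 net$stats[["n_nodes"]] - net$stats[["n_components"]])
    }
  }
})

test_that("chromosome coverage divides set members by chromosome totals", {
  asg <- assignment_of(paste0("g", 1:10), rep(c("c1", "c2"), c(10, 0)))
  expect_equal(chromosome_coverage(asg, paste0("g", 1:2))[["c1"]], 0.2)
  # fixture with totals (5, 10, 20) and hits (1, 2, 4)
  asg3 <- assignment_of(paste0("g", 1:35),
                        rep(c("c1", "c2", "c3"), c(5, 10, 20)))
  hits <- c("g1", "g6", "g7", "g16", "g17", "g18", "g19")
  cov <- chromosome_coverage(asg3, hits)
  expect_equal(unname(cov), c(0.2, 0.2, 0.2))
  expect_equal(unname(chromosome_coverage(asg3, character(0))), rep(0, 3))
  # totals must cover the assignment; zero totals with members are errors
  expect_error(chromosome_coverage(asg3, hits, totals = c(c1 = 5)),
               "lacks chromosome")
  expect_error(chromosome_coverage(asg3, hits,
                                   totals = c(c1 = 0, c2 = 10, c3 = 20)),
               "zero total")
})

test_that("SIF and GraphML round-trip preserves the network", {
  net <- build_coloc_network(assignment_of(paste0("g", 1:5),
                                           c("c1", "c1", "c1", "c2", "c2")))
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, sif)
  back <- read_sif(sif)
  expect_equal(back$edges, net$edges)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), unname(net$stats[["n_edges"]]))
})
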
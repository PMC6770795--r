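test_that("each cascade key decides in priority order", {
  # confidence first
  m <- resolve_homologs(cand_rows("q1", c("t1", "t2"), confidence = c(1, 0)))
  expect_equal(m$pairs$target_id, "t1")
  # goc breaks a confidence tie
  m <- resolve_homologs(cand_rows("q1", c("t1", "t2"), confidence = 1,
                                  goc = c(50, 100)))
  expect_equal(m$pairs$target_id, "t2")
  # target %ID breaks confidence+goc ties
  m <- resolve_homologs(cand_rows("q1", c("t1", "t2"), confidence = 1,
                                  goc = 75, target_pid = c(40, 90)))
  expect_equal(m$pairs$target_id, "t2")
  # query %ID next
  m <- resolve_homologs(cand_rows("q1", c("t1", "t2"), confidence = 1,
                                  goc = 75, target_pid = 80,
                                  query_pid = c(95, 20)))
  expect_equal(m$pairs$target_id, "t1")
  # dN/dS last: closer to zero wins by default, flag inverts
  cc <- cand_rows("q1", c("t1", "t2"), confidence = 1, goc = 75,
                  target_pid = 80, query_pid = 80, dn_ds = c(1.2, 0.05))
  expect_equal(resolve_homologs(cc)$pairs$target_id, "t2")
  expect_equal(resolve_homologs(cc, prefer_low_dnds = FALSE)$pairs$target_id,
               "t1")
  # full tie broken by smallest target id
  m <- resolve_homologs(cand_rows("q1", c("t9", "t2"), confidence = 1))
  expect_equal(m$pairs$target_id, "t2")
})

test_that("missing scores rank below any present value at their level", {
  m <- resolve_homologs(cand_rows("q1", c("t1", "t2"),
                                  confidence = c(NA, 0)))
  expect_equal(m$pairs$target_id, "t2")
  m <- resolve_homologs(cand_rows("q1", c("t1", "t2"), confidence = 1,
                                  goc = c(NA, 1)))
  expect_equal(m$pairs$target_id, "t2")
  cc <- cand_rows("q1", c("t1", "t2"), confidence = 1, goc = 50,
                  target_pid = 50, query_pid = 50, dn_ds = c(NA, 1.9))
  expect_equal(resolve_homologs(cc)$pairs$target_id, "t2")
})

test_that("greedy assignment keeps the map one-to-one and cascade-consistent", {
  # q1 and q2 both prefer t1; q1 (earlier id) takes it, q2 falls through
  cc <- rbind(cand_rows(c("q1", "q1"), c("t1", "t2"), confidence = c(1, 0)),
              cand_rows(c("q2", "q2"), c("t1", "t2"), confidence = c(1, 0)))
  m <- resolve_homologs(cc)
  expect_equal(m$pairs$target_id[m$pairs$query_id == "q1"], "t1")
  expect_equal(m$pairs$target_id[m$pairs$query_id == "q2"], "t2")

  # exhaustive check over all 2-query x 2-target score tables
  grid <- expand.grid(c11 = 0:1, c12 = 0:1, c21 = 0:1, c22 = 0:1,
                      g11 = c(0, 50), g12 = c(0, 50))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cc <- rbind(
      cand_rows("q1", "t1", confidence = g$c11, goc = g$g11),
      cand_rows("q1", "t2", confidence = g$c12, goc = g$g12),
      cand_rows("q2", "t1", confidence = g$c21, goc = 25),
      cand_rows("q2", "t2", confidence = g$c22, goc = 25))
    m <- resolve_homologs(cc)
    expect_false(anyDuplicated(m$pairs$query_id) > 0)
    expect_false(anyDuplicated(m$pairs$target_id) > 0)
    # q1 is served first and must hold its cascade-best target
    best_q1 <- order(-c(g$c11, g$c12), -c(g$g11, g$g12), c("t1", "t2"))[1]
    expect_equal(m$pairs$target_id[m$pairs$query_id == "q1"],
                 c("t1", "t2")[best_q1])
    expect_equal(nrow(m$pairs) + length(m$unmapped), 2L)
  }
})

test_that("resolution is invariant to input row order", {
  set.seed(7)
  cfg <- small_config(seed = 3, multi_map_rate = 0.6)
  cand <- gen_two_species_assignment(cfg)$candidates
  base <- resolve_homologs(cand)
  for (i in 1:3) {
    shuf <- cand[sample(nrow(cand)), , drop = FALSE]
    expect_equal(resolve_homologs(shuf), base)
  }
})

test_that("duplicate (query, target) rows collapse keeping best scores", {
  cc <- rbind(cand_rows("q1", "t1", confidence = 0, goc = 10),
              cand_rows("q1", "t1", confidence = 1, goc = NA),
              cand_rows("q1", "t2", confidence = 1, goc = 99))
  # collapsed t1 row has confidence 1 and goc 10; t2 wins on goc
  expect_equal(resolve_homologs(cc)$pairs$target_id, "t2")
})

test_that("many-to-one is allowed only when one_to_one is off", {
  cc <- rbind(cand_rows("q1", "t1", confidence = 1),
              cand_rows("q2", "t1", confidence = 1))
  m <- resolve_homologs(cc, one_to_one = FALSE)
  expect_equal(sort(unique(m$pairs$target_id)), "t1")
  expect_equal(nrow(m$pairs), 2L)
  m1 <- resolve_homologs(cc)
  expect_equal(nrow(m1$pairs), 1L)
  expect_equal(m1$unmapped, "q2")
})

test_that("planted true candidates are recovered on synthetic data", {
  for (s in 1:5) {
    cfg <- small_config(seed = s, multi_map_rate = 0.5)
    asg <- gen_two_species_assignment(cfg)
    m <- resolve_homologs(asg$candidates)
    hit <- merge(m$pairs, asg$truth, by = "query_id")
    recovery <- mean(hit$target_id.x == hit$target_id.y)
    expect_gte(recovery, 0.99)
    expect_false(anyDuplicated(m$pairs$target_id) > 0)
  }
})

test_that("mapping coverage counts resolved set members", {
  ids <- sprintf("g%02d", 1:50)
  m <- identity_map(ids)
  expect_equal(mapping_coverage(m, ids), c(n_mapped = 50L, n_total = 50L))
  expect_equal(mapping_coverage(m, character(0)),
               c(n_mapped = 0L, n_total = 0L))
  # three set members lose their candidates
  m47 <- identity_map(setdiff(ids, c("g05", "g17", "g42")))
  expect_equal(mapping_coverage(m47, ids), c(n_mapped = 47L, n_total = 50L))
})

test_that("malformed candidate tables raise parse errors naming the line", {
  expect_error(resolve_homologs(cand_rows("q1", "t1", goc = 140)),
               "\\[0, 100\\]")
  expect_error(resolve_homologs(cand_rows("q1", "t1", dn_ds = -0.5)),
               "negative")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query_id\ttarget_id\tconfidence\tgoc\ttarget_pid\tquery_pid\tdn_ds",
               "q1\tt1\t1\t50\t80\t80\t0.1",
               "q2\tt2\thigh\t50\t80\t80\t0.1"), f)
  expect_error(read_homolog_candidates(f), "line 3")
  expect_equal(nrow(resolve_homologs(data.frame(
    query_id = character(0), target_id = character(0),
    confidence = numeric(0), goc = numeric(0), target_pid = numeric(0),
    query_pid = numeric(0), dn_ds = numeric(0)))$pairs), 0L)
})
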
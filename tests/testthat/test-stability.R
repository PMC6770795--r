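test_that("descriptive tables report sample mean and n-1 SD per cell", {
  tab <- energy_of(list(A = c(0, 2), B = c(5, 5, 5)))
  d <- descriptive_table(tab, "Delta_G")
  a <- d[d$group == "A", ]
  expect_equal(a$mean, 1)
  expect_equal(a$sd, sqrt(2))
  b <- d[d$group == "B", ]
  expect_equal(b$sd, 0)
  expect_equal(b$n, 3L)
  expect_error(descriptive_table(energy_of(list(A = 1, B = c(1, 2)))),
               "at least 2 rows")
})

test_that("Kruskal-Wallis matches the closed-form rank statistic", {
  tab <- energy_of(list(A = c(1, 2), B = c(3, 4), C = c(5, 6)))
  kw <- kw_test(tab, "Delta_G")
  # no ties: H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2 = 12/42 * 16
  r <- rank(tab$Delta_G)
  rbar <- tapply(r, tab$group, mean)
  H <- 12 / (6 * 7) * sum(2 * (rbar - mean(r))^2)
  expect_equal(H, 32 / 7)
  expect_equal(kw$H, H)
  expect_equal(kw$df, 2L)

  # all values identical across groups: H = 0, p = 1
  flat <- energy_of(list(A = c(1, 1), B = c(1, 1)))
  expect_equal(kw_test(flat, "Delta_G")[, c("H", "p")],
               data.frame(H = 0, p = 1))
})

test_that("a constant covariate makes the adjusted test a no-op", {
  set.seed(21)
  tab <- energy_of(list(A = rnorm(8), B = rnorm(8, 2), C = rnorm(8)),
                   residues = 150L)
  plain <- kw_test(tab, "Delta_G")
  adj <- kw_test(tab, "Delta_G", adjust_for_residues = TRUE)
  expect_equal(adj$H, plain$H)
  # the covariate itself is never adjusted against itself
  rn <- kw_test(tab, "Residue Number", adjust_for_residues = TRUE)
  expect_equal(rn$H, kw_test(tab, "Residue Number")$H)
})

test_that("residue adjustment removes a size-driven false positive", {
  # feature depends only on residue number, which differs between groups
  set.seed(33)
  res <- as.integer(c(rnorm(40, 150, 10), rnorm(40, 400, 10)))
  tab <- energy_of(list(A = res[1:40] * 0.5 + rnorm(40, sd = 2),
                        B = res[41:80] * 0.5 + rnorm(40, sd = 2)),
                   residues = res)
  expect_lt(kw_test(tab, "Delta_G")$p, 0.001)
  expect_gt(kw_test(tab, "Delta_G", adjust_for_residues = TRUE)$p, 0.05)
})

test_that("Dunn z agrees with the hand-computed example", {
  tab <- energy_of(list(A = c(1, 2), B = c(3, 4), C = c(5, 6)))
  d <- dunn_posthoc(tab, "Delta_G")
  zac <- d$z[d$group_i == "A" & d$group_j == "C"]
  expect_equal(abs(zac), 4 / sqrt(3.5), tolerance = 1e-12)
  expect_equal(2 * pnorm(-abs(zac)), d$p[d$group_i == "A" & d$group_j == "C"])

  flat <- energy_of(list(A = c(2, 2), B = c(2, 2)))
  df <- dunn_posthoc(flat, "Delta_G")
  expect_equal(df$z, 0)
  expect_equal(df$p, 1)
})

test_that("Dunn z matches a brute-force rank oracle on all small configurations", {
  # independent oracle: counting-based mid-ranks and explicit tie census
  oracle_z <- function(y, g, gi, gj) {
    r <- vapply(y, function(v) sum(y < v) + (sum(y == v) + 1) / 2, numeric(1))
    n <- length(y)
    tie_sizes <- as.integer(table(match(y, y)))
    tie_term <- sum(tie_sizes^3 - tie_sizes)
    s2 <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
    ni <- sum(g == gi); nj <- sum(g == gj)
    (mean(r[g == gi]) - mean(r[g == gj])) / sqrt(s2 * (1 / ni + 1 / nj))
  }
  set.seed(91)
  sizes <- list(c(2, 2, 2), c(2, 2, 3), c(2, 3, 3), c(2, 2, 4))
  for (sz in sizes) {
    for (draw in 1:5) {
      n <- sum(sz)
      y <- sample(1:4, n, replace = TRUE)  # integer pool forces ties
      g <- rep(c("A", "B", "C"), sz)
      tab <- data.frame(protein_id = seq_len(n), group = g, Delta_G = y)
      d <- dunn_posthoc(tab, "Delta_G")
      for (k in seq_len(nrow(d))) {
        zo <- oracle_z(y, g, d$group_i[k], d$group_j[k])
        if (is.nan(zo)) zo <- 0  # all values tied
        expect_equal(d$z[k], zo, tolerance = 1e-12)
      }
    }
  }
})

test_that("FDR adjustment obeys the Benjamini-Hochberg step-up property", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  expect_equal(bh_oracle(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  set.seed(14)
  tab <- energy_of(list(A = rnorm(6), B = rnorm(6, 1), C = rnorm(6, 3)))
  d <- dunn_posthoc(tab, "Delta_G")
  expect_equal(d$p_adj, bh_oracle(d$p))
  expect_true(all(d$p_adj >= d$p))
  expect_true(all(d$p_adj <= 1))
  expect_equal(order(d$p_adj), order(d$p))
})

test_that("Spearman matrices are symmetric, tie-aware and monotone-invariant", {
  set.seed(51)
  x <- rnorm(30)
  tab <- data.frame(protein_id = 1:30, group = "P8",
                    a = x, b = exp(x), c = rnorm(30), d = 1,
                    check.names = FALSE)
  sp <- spearman_matrix(tab, features = c("a", "b", "c", "d"))
  expect_equal(sp$rho["a", "b"], 1)           # monotone transform
  expect_equal(sp$p["a", "b"], 0)
  expect_equal(sp$rho, t(sp$rho))
  expect_equal(unname(diag(sp$rho)[1:3]), rep(1, 3))
  expect_true(all(is.na(sp$rho[, "d"])))      # constant column undefined

  # hand-computed: x = 1,2,3 vs y = 2,1,3 -> rho = 1 - 12/24 = 0.5
  t3 <- data.frame(protein_id = 1:3, group = "g", x = 1:3, y = c(2, 1, 3))
  expect_equal(spearman_matrix(t3, features = c("x", "y"))$rho["x", "y"], 0.5)
  expect_error(spearman_matrix(t3[1:2, ], features = c("x", "y")), ">= 3")
})

test_that("group filtering feeds the correlation analysis", {
  cfg <- small_config(seed = 8)
  tab <- gen_energy_table(cfg, n_per_group = c(P8 = 30, NONOSC = 40))
  sp_all <- spearman_matrix(tab)
  sp_p8 <- spearman_matrix(tab, groups = "P8")
  expect_equal(sp_all$n, 70L)
  expect_equal(sp_p8$n, 30L)
  expect_equal(dim(sp_p8$rho), c(18L, 18L))
})
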
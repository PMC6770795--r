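#' Count interactions between two gene sets
#'
#' Number of reference edges with one endpoint in `set_a` and the other in
#' `set_b`. Both sets are first reduced to ids present in the reference
#' (absent ids are dropped, with a message when `verbose`); ids occurring in
#' both sets are removed from `set_b`, since self-connectivity of a set
#' would inflate its apparent connectivity to the other. With
#' `count_records = TRUE` each underlying interaction record counts
#' separately (databases often report one pair through several
#' experiments); the default counts unique pairs.
#'
#' @param ref an [interaction_reference()].
#' @param set_a,set_b character vectors of node ids.
#' @param count_records count interaction records instead of unique pairs.
#' @param verbose message about dropped ids.
#' @return integer count.
#' @examples
#' ref <- interaction_reference(rbind(c("a", "x"), c("b", "y"), c("a", "b")))
#' count_cross_interactions(ref, c("a", "b"), c("x", "y"))  # 2
#' @export
count_cross_interactions <- function(ref, set_a, set_b,
                                     count_records = FALSE, verbose = FALSE) {
  stopifnot(inherits(ref, "interaction_reference"))
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  dropped <- sum(!(c(set_a, set_b) %in% ref$nodes))
  if (verbose && dropped > 0L) {
    message(dropped, " set id(s) absent from the reference were dropped")
  }
  set_a <- set_a[set_a %in% ref$nodes]
  set_b <- setdiff(set_b[set_b %in% ref$nodes], set_a)
  if (length(set_a) == 0L && length(set_b) == 0L) {
    stop("both sets are empty after reduction to the reference")
  }
  cross_count(ref, set_a, set_b, count_records)
}

# counting core, no validation: used in the permutation loop
cross_count <- function(ref, set_a, set_b, count_records = FALSE) {
  a1 <- ref$edges[, 1] %in% set_a
  a2 <- ref$edges[, 2] %in% set_a
  b1 <- ref$edges[, 1] %in% set_b
  b2 <- ref$edges[, 2] %in% set_b
  hit <- (a1 & b2) | (a2 & b1)
  if (count_records) sum(ref$multiplicity[hit]) else sum(hit)
}

#' Connectivity of a gene set to a subnetwork, against a randomized null
#'
#' Tests whether a focal gene set (`set_a`) interacts with a designated
#' subnetwork (`set_b`) more than expected by chance. The observed count of
#' reference interactions between the two sets is compared with an empirical
#' null built from `n_iter` random gene sets of the same size as `set_b`,
#' drawn uniformly without replacement from the sampling universe (by
#' default, every reference node outside `set_a`). This is a node-label
#' randomization against a fixed interaction reference: the interaction
#' structure itself is never rewired.
#'
#' The z-score is `(observed - null mean) / null SD` with the SD computed on
#' `n_iter - 1` degrees of freedom, and the empirical p-value uses the
#' pseudo-count form `(1 + #\{null >= observed\}) / (n_iter + 1)`, so it is
#' never exactly zero. A degenerate null with SD 0 reports `z = Inf` when
#' the observed count exceeds the null mean and `z = 0` when it equals it.
#'
#' @inheritParams count_cross_interactions
#' @param n_iter number of random sets (>= 1).
#' @param seed integer seed; the null is fully reproducible from it.
#' @param universe optional sampling universe; defaults to
#'   `setdiff(ref$nodes, set_a)`.
#' @return object of class `connectivity_result`: list with `observed`,
#'   `null_mean`, `null_sd`, `z`, `p_empirical`, `n_iter`, `seed`,
#'   `null_counts`, `set_sizes`.
#' @seealso [connectivity_z()] for the bare z arithmetic,
#'   [exhaustive_null()] for the brute-force null on small universes.
#' @export
connectivity_test <- function(ref, set_a, set_b, n_iter = 100L, seed = 1L,
                              universe = NULL, count_records = FALSE,
                              verbose = FALSE) {
  stopifnot(inherits(ref, "interaction_reference"))
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("'n_iter' must be >= 1")
  set_a <- unique(as.character(set_a))
  set_a <- set_a[set_a %in% ref$nodes]
  set_b <- unique(as.character(set_b))
  set_b <- setdiff(set_b[set_b %in% ref$nodes], set_a)
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("a set is empty after reduction to the reference")
  }
  if (is.null(universe)) universe <- setdiff(ref$nodes, set_a)
  universe <- unique(as.character(universe))
  k <- length(set_b)
  if (length(universe) < k) {
    stop("sampling universe (", length(universe),
         ") smaller than |set_b| (", k, ")")
  }
  observed <- cross_count(ref, set_a, set_b, count_records)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_iter), function(i) {
    cross_count(ref, set_a, setdiff(sample(universe, k), set_a), count_records)
  }, numeric(1))
  null_mean <- mean(null_counts)
  null_sd <- if (n_iter > 1L) stats::sd(null_counts) else 0
  z <- connectivity_z(observed, null_mean, null_sd)
  p <- (1 + sum(null_counts >= observed)) / (n_iter + 1)
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, z = z, p_empirical = p,
                 n_iter = n_iter, seed = as.integer(seed),
                 null_counts = as.integer(null_counts),
                 set_sizes = c(set_a = length(set_a), set_b = k)),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat("Connectivity test: observed ", x$observed, " vs null ",
      sprintf("%.2f +/- %.2f", x$null_mean, x$null_sd),
      " (", x$n_iter, " random sets)\n", sep = "")
  cat("  z = ", sprintf("%.2f", x$z),
      ", empirical p = ", format(x$p_empirical, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Connectivity z-score arithmetic
#'
#' `(observed - null_mean) / null_sd`, the standardized excess of a gene
#' set's observed connectivity over a randomized null. Usable directly on
#' published summaries, e.g. an observed count of 12 against a null of
#' 3.99 +/- 2.91 gives z = 2.75.
#'
#' @param observed observed interaction count.
#' @param null_mean,null_sd mean and standard deviation of the null counts.
#' @return numeric z (Inf when `null_sd` is 0 and `observed > null_mean`,
#'   0 when the two are equal).
#' @export
connectivity_z <- function(observed, null_mean, null_sd) {
  if (null_sd > 0) return((observed - null_mean) / null_sd)
  if (observed == null_mean) 0 else sign(observed - null_mean) * Inf
}

#' Exhaustive null distribution of cross-set counts
#'
#' Brute-force oracle: the cross-interaction count for every k-subset of
#' the universe, enumerated in lexicographic order (after sorting the
#' universe). Feasible only for small instances; used to verify the
#' Monte-Carlo null of [connectivity_test()].
#'
#' @inheritParams connectivity_test
#' @param k subset size.
#' @param max_subsets refuse enumerations larger than this (default 1e6).
#' @return integer vector of length `choose(length(universe), k)`.
#' @export
exhaustive_null <- function(ref, set_a, universe, k, count_records = FALSE,
                            max_subsets = 1e6) {
  stopifnot(inherits(ref, "interaction_reference"))
  universe <- sort(unique(as.character(universe)))
  k <- as.integer(k)
  if (k < 1L || k > length(universe)) stop("'k' out of range")
  if (choose(length(universe), k) > max_subsets) {
    stop("combinatorial bound exceeded: choose(", length(universe), ", ", k,
         ") > ", max_subsets)
  }
  set_a <- unique(as.character(set_a))
  subsets <- combn(universe, k, simplify = FALSE)
  vapply(subsets, function(s) {
    as.integer(cross_count(ref, set_a, setdiff(s, set_a), count_records))
  }, integer(1))
}
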
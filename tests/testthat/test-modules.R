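test_that("similarity_to_distance complements and rescales", {
  s <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  d <- similarity_to_distance(s)
  expect_equal(unname(diag(d)), c(0, 0))
  expect_equal(d[1, 2], 0.6)
  # unnormalized input is rescaled by its maximum first
  s2 <- matrix(c(1.3863, 0.3, 0.3, 1.3863), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  d2 <- similarity_to_distance(s2)
  expect_equal(attr(d2, "rescaled_by"), 1.3863)
  expect_true(all(d2 >= 0 & d2 <= 1))
  expect_equal(d2[1, 2], 1 - 0.3 / 1.3863)
  asym <- s; asym[1, 2] <- 0.9
  expect_error(similarity_to_distance(asym), "symmetric")
})

test_that("average linkage reproduces UPGMA by hand", {
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d["a", "b"] <- d["b", "a"] <- 0.1
  d["a", "c"] <- d["c", "a"] <- 0.9
  d["b", "c"] <- d["c", "b"] <- 0.9
  hc <- average_linkage(d)
  expect_equal(hc$height, c(0.1, 0.9))
  expect_setequal(hc$labels[-hc$merge[1, ]], c("a", "b"))
  # two points: single merge at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(average_linkage(d2)$height, 0.4)
  expect_error(average_linkage(matrix(0, 1, 1)), "two items")
})

test_that("cut_static keeps components of merges strictly below the height", {
  d <- matrix(0.9, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d["a", "b"] <- d["b", "a"] <- 0.1
  diag(d) <- 0
  hc <- average_linkage(d)
  lab <- cut_static(hc, height = 0.5, min_size = 2)
  expect_identical(unname(lab[c("a", "b")]), c(1L, 1L))
  expect_identical(unname(lab[["c"]]), 0L)
  # height above the top merge: everything in one module
  all_in <- cut_static(hc, height = 1.0, min_size = 1)
  expect_identical(unname(all_in), rep(1L, 3))
  # height 0 admits no merge: all unassigned when min_size > 1
  none <- cut_static(hc, height = 0, min_size = 2)
  expect_identical(unname(none), rep(0L, 3))
})

test_that("static cuts are nested across heights", {
  s <- planted_similarity(c(6, 6, 6), within = 0.9, between = 0.1,
                          noise_sd = 0.05, seed = 3L)
  hc <- average_linkage(similarity_to_distance(s))
  lo <- cut_static(hc, height = 0.3, min_size = 1)
  hi <- cut_static(hc, height = 0.95, min_size = 1)
  # every low-cut module is contained in exactly one high-cut module
  for (m in unique(lo)) {
    ids <- names(lo)[lo == m]
    expect_length(unique(hi[ids]), 1L)
  }
})

same_partition <- function(assignment, truth) {
  ids <- names(truth)
  length(unique(assignment[ids])) == length(unique(truth)) &&
    all(vapply(split(ids, truth), function(block) {
      length(unique(assignment[block])) == 1L && all(assignment[block] > 0L)
    }, logical(1))) &&
    # no two different blocks share a module label
    anyDuplicated(vapply(split(ids, truth), function(block) {
      assignment[block][[1L]]
    }, integer(1))) == 0L
}

test_that("both cuts recover planted partitions exactly", {
  block_specs <- list(c(12, 15), c(10, 14, 18), c(10, 11, 12, 13, 14))
  for (seed in 1:6) {
    for (blocks in block_specs) {
      s <- planted_similarity(blocks, within = 0.9, between = 0.1,
                              noise_sd = 0.02, seed = seed)
      truth <- attr(s, "truth")
      hc <- average_linkage(similarity_to_distance(s))
      stat <- cut_static(hc, height = 0.5, min_size = 10)
      dyn <- cut_dynamic(hc, min_size = 10)
      expect_true(same_partition(stat, truth),
                  info = sprintf("static seed %d blocks %s", seed,
                                 paste(blocks, collapse = ",")))
      expect_true(same_partition(dyn, truth),
                  info = sprintf("dynamic seed %d blocks %s", seed,
                                 paste(blocks, collapse = ",")))
    }
  }
})

test_that("dynamic-cut modules are contiguous dendrogram branches", {
  s <- planted_similarity(c(12, 15, 10), within = 0.9, between = 0.1,
                          noise_sd = 0.02, seed = 8L)
  hc <- average_linkage(similarity_to_distance(s))
  lab <- cut_dynamic(hc, min_size = 10)
  # a module is a branch iff some merge's member set equals the module
  members <- lapply(seq_len(nrow(hc$merge)), function(i) {
    idx <- integer(0)
    stack <- i
    while (length(stack)) {
      j <- stack[[1L]]; stack <- stack[-1L]
      for (v in hc$merge[j, ]) {
        if (v < 0) idx <- c(idx, -v) else stack <- c(stack, v)
      }
    }
    sort(hc$labels[idx])
  })
  for (m in setdiff(unique(lab), 0L)) {
    ids <- sort(names(lab)[lab == m])
    expect_true(any(vapply(members, identical, logical(1), y = ids)),
                info = paste("module", m))
  }
})

test_that("dynamic cut handles structureless and undersized inputs", {
  # constant off-diagonal similarity: all merges at one height, no gap
  s <- planted_similarity(30, within = 0.6, between = 0, noise_sd = 0,
                          seed = 1L)
  hc <- average_linkage(similarity_to_distance(s))
  lab <- cut_dynamic(hc, min_size = 10)
  expect_lte(length(setdiff(unique(lab), 0L)), 1L)
  # min_size beyond n: everything unassigned
  lab2 <- cut_dynamic(hc, min_size = 40)
  expect_identical(unname(lab2), rep(0L, 30))
  expect_error(cut_dynamic(hc, min_size = 1), "min_size")
})

test_that("permutation threshold is seeded, monotone and exact on constants", {
  s <- planted_similarity(12, within = 0.5, between = 0, noise_sd = 0,
                          seed = 1L)
  diag(s) <- 1
  sim_fn <- function(ids) s[ids, ids]
  thr <- permutation_threshold(sim_fn, rownames(s), sample_size = 6,
                               reps = 20, percentile = 99, seed = 42)
  expect_equal(thr, 0.5)  # constant background
  s2 <- planted_similarity(c(8, 8), within = 0.9, between = 0.1,
                           noise_sd = 0.05, seed = 2L)
  fn2 <- function(ids) s2[ids, ids]
  t50 <- permutation_threshold(fn2, rownames(s2), 8, reps = 50,
                               percentile = 50, seed = 7)
  t99 <- permutation_threshold(fn2, rownames(s2), 8, reps = 50,
                               percentile = 99, seed = 7)
  expect_lte(t50, t99)
  expect_identical(
    permutation_threshold(fn2, rownames(s2), 8, reps = 50,
                          percentile = 99, seed = 7),
    t99
  )
  expect_error(permutation_threshold(fn2, rownames(s2), 8, reps = 10,
                                     percentile = 101, seed = 1),
               "percentile")
})

test_that("module significance is smoothed, bounded and seed-stable", {
  s <- planted_similarity(c(10, 20), within = 0.9, between = 0.1,
                          noise_sd = 0.02, seed = 5L)
  hc <- average_linkage(similarity_to_distance(s))
  lab <- cut_static(hc, 0.5, min_size = 5)
  stats1 <- module_significance(s, lab, reps = 199, seed = 11)
  stats2 <- module_significance(s, lab, reps = 199, seed = 11)
  expect_identical(stats1, stats2)
  expect_true(all(stats1$p_value >= 1 / 200))
  expect_true(all(stats1$p_value <= 1))
  # the planted tight block is maximally significant at these reps
  tight <- stats1[which.max(stats1$mean_similarity), ]
  expect_equal(tight$p_value, 1 / 200)
  expect_equal(stats1$fdr, bh_fdr(stats1$p_value))
})

test_that("sampled module p-values converge to the exhaustive fraction", {
  # 7 labels, module of size 3: only choose(7,3) = 35 subsets exist
  set.seed(31)
  n <- 7L
  s <- matrix(runif(n * n), n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  labels <- sprintf("x%d", seq_len(n))
  dimnames(s) <- list(labels, labels)
  module_ids <- labels[1:3]
  assignment <- stats::setNames(c(rep(1L, 3), rep(0L, 4)), labels)
  mean_off <- function(ids) {
    sub <- s[ids, ids]
    mean(sub[lower.tri(sub)])
  }
  obs <- mean_off(module_ids)
  combos <- utils::combn(labels, 3, simplify = FALSE)
  exact_frac <- mean(vapply(combos, mean_off, numeric(1)) >= obs)
  reps <- 4000L
  p_hat <- module_significance(s, assignment, reps = reps, seed = 2)$p_value
  expect_equal(p_hat, exact_frac, tolerance = 0.05)
})

test_that("significant pairs and Newick export round out the module outputs", {
  s <- planted_similarity(c(5, 5), within = 0.9, between = 0.1,
                          noise_sd = 0, seed = 1L)
  pairs <- significant_pairs(s, threshold = 0.5)
  expect_identical(nrow(pairs), 2L * as.integer(choose(5L, 2L)))
  expect_true(all(pairs$similarity > 0.5))
  f <- withr::local_tempfile(fileext = ".nwk")
  hc <- average_linkage(similarity_to_distance(s))
  write_dendrogram_newick(hc, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, rownames(s))
})
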
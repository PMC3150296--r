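fx <- fixture_toy9()
acc <- fx$acc
E <- acc[["E"]]; F_ <- acc[["F"]]; C <- acc[["C"]]

test_that("mica picks the maximal-IC common ancestor with lexicographic ties", {
  m <- mica(fx$dag, fx$ic, E, F_)
  expect_identical(m$term, unname(acc[["A"]]))
  expect_equal(m$ic, 0.2877, tolerance = 1e-4)
  expect_identical(mica(fx$dag, fx$ic, E, E)$term, unname(E))
  # containment: C is an ancestor of E
  expect_identical(mica(fx$dag, fx$ic, E, C)$term, unname(C))
})

test_that("disjunctive pairs match the path-enumeration oracle on toy9", {
  got <- disjunctive_ancestor_pairs(fx$dag, F_)
  want <- oracle_disjunctive_pairs(fx$dag, F_)
  expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
  # (A, B) is disjunctive for F: A->D->F avoids B, B->D->F avoids A
  expect_true(paste(acc[["A"]], acc[["B"]]) %in% paste(got[, 1], got[, 2]))
  # E sits on a single chain: no disjunctive pair
  expect_identical(nrow(disjunctive_ancestor_pairs(fx$dag, E)), 0L)
})

test_that("DCA and Share follow the GraSM rule on the fixture", {
  d <- dca(fx$dag, fx$ic, E, F_)
  expect_setequal(d$dca, acc[c("A", "R")])
  expect_near(d$share, 0.1438)
  o <- oracle_dca(fx$dag, fx$ic, E, F_)
  expect_setequal(d$dca, o$dca)
  expect_equal(d$share, o$share)
  # self: DCA is the term itself
  ds <- dca(fx$dag, fx$ic, E, E)
  expect_identical(ds$dca, unname(E))
  expect_equal(ds$share, fx$ic$ic[[E]])
})

test_that("Wang contributions are best-path products over the ancestor sub-DAG", {
  wE <- wang_contributions(fx$dag, E)
  expect_equal(sort(unname(wE$contributions), decreasing = TRUE),
               0.7^(0:3))
  expect_equal(wE$sv, 2.533)
  wF <- wang_contributions(fx$dag, F_)
  expect_equal(unname(wF$contributions[acc[c("F", "D", "A", "B", "R")]]),
               c(1, 0.7, 0.49, 0.49, 0.343))
  expect_equal(wF$sv, 3.023)
  expect_equal(wang_contributions(fx$dag, acc[["R"]])$sv, 1)
  expect_error(wang_contributions(fx$dag, E, w_e = 1.2), "w_e")
})

test_that("the ten measures reproduce the fixture values", {
  val <- function(ms) term_similarity(fx$dag, fx$ic, E, F_, ms)
  expect_near(val("Resnik"), 0.2877)
  expect_near(val("Lin"), 0.2075)
  expect_near(val("Rel"), 0.0519)
  expect_near(val("GIC"), 0.0503)
  expect_near(val("Wang"), 0.2999)
  expect_near(val("CoutoResnik"), 0.1438)
  expect_near(val("CoutoLin"), 0.1037)
  expect_equal(val("JC"), 0)  # distance 2.197 clamps to 0 similarity
  # self-similarity of normalized measures is 1
  for (ms in c("Lin", "JC", "Wang", "GIC", "CoutoLin", "CoutoJC")) {
    expect_equal(term_similarity(fx$dag, fx$ic, E, E, ms), 1,
                 info = ms)
  }
  expect_error(term_similarity(fx$dag, fx$ic, E, F_, "bogus"), "valid measures")
})

test_that("all measures agree with direct formula evaluation on random DAGs", {
  for (seed in 1:4) {
    r <- random_fixture(seed)
    terms <- names(r$ic$ic)
    pairs <- utils::combn(terms, 2)
    take <- seq_len(min(ncol(pairs), 10L))
    for (pi in take) {
      t1 <- pairs[1, pi]; t2 <- pairs[2, pi]
      for (ms in similarity_measures()) {
        expect_equal(
          term_similarity(r$dag, r$ic, t1, t2, ms),
          oracle_term_similarity(r$dag, r$ic, t1, t2, ms),
          tolerance = 1e-12,
          info = sprintf("seed %d %s (%s, %s)", seed, ms, t1, t2)
        )
      }
    }
  }
})

test_that("every measure is symmetric and respects its stated range", {
  normalized <- c("Lin", "Rel", "simIC", "GIC", "Wang", "JC",
                  "CoutoLin", "CoutoJC")
  for (seed in 1:4) {
    r <- random_fixture(seed)
    terms <- names(r$ic$ic)
    max_ic <- max(r$ic$ic)
    set.seed(seed)
    sampled <- replicate(8, sample(terms, 2), simplify = FALSE)
    for (pr in sampled) {
      for (ms in similarity_measures()) {
        v12 <- term_similarity(r$dag, r$ic, pr[[1]], pr[[2]], ms)
        v21 <- term_similarity(r$dag, r$ic, pr[[2]], pr[[1]], ms)
        expect_equal(v12, v21, info = ms)
        if (ms %in% normalized) {
          expect_gte(v12, 0); expect_lte(v12, 1 + 1e-12)
        } else {
          expect_gte(v12, 0); expect_lte(v12, max_ic + 1e-12)
        }
      }
    }
  }
})

test_that("simIC and Rel never exceed Lin", {
  for (seed in 1:3) {
    r <- random_fixture(seed)
    terms <- names(r$ic$ic)
    set.seed(seed)
    for (i in 1:10) {
      pr <- sample(terms, 2)
      lin <- term_similarity(r$dag, r$ic, pr[[1]], pr[[2]], "Lin")
      expect_lte(term_similarity(r$dag, r$ic, pr[[1]], pr[[2]], "simIC"),
                 lin + 1e-12)
      expect_lte(term_similarity(r$dag, r$ic, pr[[1]], pr[[2]], "Rel"),
                 lin + 1e-12)
    }
  }
})

test_that("ratio measures are invariant to the IC log base", {
  r <- random_fixture(11L)
  ic2 <- information_content(r$dag, r$corpus, log_base = 10)
  terms <- names(r$ic$ic)
  set.seed(11)
  for (i in 1:6) {
    pr <- sample(terms, 2)
    for (ms in c("Lin", "Rel", "GIC", "CoutoLin")) {
      expect_equal(
        term_similarity(r$dag, r$ic, pr[[1]], pr[[2]], ms),
        term_similarity(r$dag, ic2, pr[[1]], pr[[2]], ms),
        tolerance = 1e-12, info = ms
      )
    }
  }
})

test_that("Wang ignores the annotation corpus entirely", {
  r <- random_fixture(13L)
  # permute the corpus gene -> term assignments
  shuffled <- with(r$corpus, {
    terms <- unlist(direct, use.names = FALSE)
    set.seed(99)
    new_terms <- sample(terms)
    annotation_corpus(rep(names(direct), lengths(direct)), new_terms, r$dag)
  })
  ic_b <- information_content(r$dag, shuffled, log_base = 2)
  terms <- active_terms(r$dag)
  set.seed(13)
  for (i in 1:6) {
    pr <- sample(terms, 2)
    expect_equal(term_similarity(r$dag, r$ic, pr[[1]], pr[[2]], "Wang"),
                 term_similarity(r$dag, ic_b, pr[[1]], pr[[2]], "Wang"))
  }
})

test_that("on trees the GraSM variants collapse onto their base measures", {
  for (seed in 1:5) {
    dag <- random_ontology(12L, depth_target = 4L, max_parents = 1L,
                           seed = seed)
    corpus <- random_corpus(dag, 10L, seed = seed, leaf_coverage = TRUE)
    ic <- information_content(dag, corpus)
    terms <- names(ic$ic)
    pairs <- utils::combn(terms, 2)
    for (pi in seq_len(ncol(pairs))) {
      t1 <- pairs[1, pi]; t2 <- pairs[2, pi]
      expect_equal(term_similarity(dag, ic, t1, t2, "CoutoResnik"),
                   term_similarity(dag, ic, t1, t2, "Resnik"),
                   tolerance = 1e-12)
      expect_equal(term_similarity(dag, ic, t1, t2, "CoutoLin"),
                   term_similarity(dag, ic, t1, t2, "Lin"),
                   tolerance = 1e-12)
      expect_equal(term_similarity(dag, ic, t1, t2, "CoutoJC"),
                   term_similarity(dag, ic, t1, t2, "JC"),
                   tolerance = 1e-12)
    }
  }
})

test_that("term similarity matrices are symmetric with the right diagonal", {
  m <- term_similarity_matrix(fx$dag, fx$ic, acc[c("E", "F", "C")], "Lin")
  expect_identical(dim(m), c(3L, 3L))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  two <- term_similarity_matrix(fx$dag, fx$ic, c(E, F_), "Lin")
  expect_equal(two[1, 2], 0.2075, tolerance = 1e-4)
  # determinism
  expect_identical(m, term_similarity_matrix(fx$dag, fx$ic,
                                             acc[c("E", "F", "C")], "Lin"))
  # Resnik diagonal carries each term's own IC
  mr <- term_similarity_matrix(fx$dag, fx$ic, c(E, C), "Resnik")
  expect_equal(unname(diag(mr)), unname(fx$ic$ic[c(E, C)]))
  expect_error(term_similarity_matrix(fx$dag, fx$ic, E, "Lin"), "two terms")
})
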
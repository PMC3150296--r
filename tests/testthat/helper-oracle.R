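# Independent oracles used to pin expected values: everything here works by
# exhaustive enumeration or direct formula evaluation on the raw edge lists,
# never through the package's own similarity code paths.

# all directed paths from ancestor `from` down to `to` (child edges),
# returned as character vectors including both endpoints
oracle_all_paths <- function(dag, from, to) {
  paths <- list()
  walk <- function(node, trail) {
    trail <- c(trail, node)
    if (node == to) {
      paths[[length(paths) + 1L]] <<- trail
      return(invisible(NULL))
    }
    for (ch in dag$children[[node]]) walk(ch, trail)
    invisible(NULL)
  }
  walk(from, character(0))
  paths
}

oracle_proper_ancestors <- function(dag, t) {
  act <- setdiff(dag$accession[!dag$obsolete[dag$accession]], t)
  act[vapply(act, function(a) length(oracle_all_paths(dag, a, t)) > 0,
             logical(1))]
}

# pairs (a1, a2) disjunctive for t by brute-force path enumeration;
# a path passes through its endpoints
oracle_disjunctive_pairs <- function(dag, t) {
  anc <- sort(oracle_proper_ancestors(dag, t))
  out <- matrix(character(0), ncol = 2)
  if (length(anc) < 2L) return(out)
  paths <- lapply(anc, oracle_all_paths, dag = dag, to = t)
  names(paths) <- anc
  avoids <- function(a1, a2) {
    any(vapply(paths[[a1]], function(p) !(a2 %in% p), logical(1)))
  }
  for (i in seq_len(length(anc) - 1L)) {
    for (j in (i + 1L):length(anc)) {
      if (avoids(anc[[i]], anc[[j]]) && avoids(anc[[j]], anc[[i]])) {
        out <- rbind(out, c(anc[[i]], anc[[j]]))
      }
    }
  }
  out
}

oracle_ancestors_self <- function(dag, t) {
  c(t, oracle_proper_ancestors(dag, t))
}

# DCA + Share by direct application of the GraSM rule, using the
# brute-force disjunctive sets above
oracle_dca <- function(dag, ic_table, t1, t2) {
  ca <- intersect(oracle_ancestors_self(dag, t1), oracle_ancestors_self(dag, t2))
  ca <- ca[ca %in% names(ic_table$ic)]
  key <- function(m) if (nrow(m) == 0L) character(0) else paste(m[, 1], m[, 2])
  disj <- unique(c(key(oracle_disjunctive_pairs(dag, t1)),
                   key(oracle_disjunctive_pairs(dag, t2))))
  ics <- ic_table$ic[ca]
  keep <- vapply(ca, function(a) {
    higher <- ca[ics > ics[[a]]]
    all(vapply(higher, function(b) {
      paste(min(a, b), max(a, b)) %in% disj
    }, logical(1)))
  }, logical(1))
  list(dca = sort(ca[keep]), share = mean(ics[keep]))
}

# IC recomputed from scratch: descendants by path existence, distinct genes
oracle_ic_table <- function(dag, corpus) {
  act <- dag$accession[!dag$obsolete[dag$accession]]
  genes_of <- function(t) {
    desc <- act[vapply(act, function(d) {
      d == t || length(oracle_all_paths(dag, t, d)) > 0
    }, logical(1))]
    unique(unlist(lapply(names(corpus$direct), function(g) {
      if (any(corpus$direct[[g]] %in% desc)) g else NULL
    })))
  }
  counts <- vapply(act, function(t) length(genes_of(t)), integer(1))
  p <- counts / corpus$universe_size
  list(p = p, ic = -log(p[p > 0]))
}

# Wang contribution of ancestor a to t: with a single uniform edge weight the
# best path product is w_e^(shortest path length), read off the enumerated
# paths directly
oracle_wang_contributions <- function(dag, t, w_e = 0.7) {
  anc <- oracle_ancestors_self(dag, t)
  contrib <- vapply(anc, function(a) {
    if (a == t) return(1)
    lens <- vapply(oracle_all_paths(dag, a, t), length, integer(1)) - 1L
    max(w_e^lens)
  }, numeric(1))
  list(contributions = contrib, sv = sum(contrib))
}

# direct formula evaluation for the ten measures (no shared code with the
# package beyond the DAG container)
oracle_term_similarity <- function(dag, ic_table, t1, t2, measure, w_e = 0.7) {
  anc1 <- oracle_ancestors_self(dag, t1)
  anc2 <- oracle_ancestors_self(dag, t2)
  if (measure == "Wang") {
    c1 <- oracle_wang_contributions(dag, t1, w_e)
    c2 <- oracle_wang_contributions(dag, t2, w_e)
    common <- intersect(names(c1$contributions), names(c2$contributions))
    return(sum(c1$contributions[common] + c2$contributions[common]) /
             (c1$sv + c2$sv))
  }
  dom <- names(ic_table$ic)
  i1 <- ic_table$ic[[t1]]; i2 <- ic_table$ic[[t2]]
  ca <- intersect(anc1, anc2); ca <- ca[ca %in% dom]
  im <- max(ic_table$ic[ca])
  mica_term <- sort(ca[ic_table$ic[ca] == im])[[1]]
  ratio <- function(sh) if (i1 + i2 == 0) 1 else 2 * sh / (i1 + i2)
  if (measure == "GIC") {
    uni <- union(anc1, anc2); uni <- uni[uni %in% dom]
    denom <- sum(ic_table$ic[uni])
    return(if (denom == 0) 1 else sum(ic_table$ic[ca]) / denom)
  }
  sh <- oracle_dca(dag, ic_table, t1, t2)$share
  switch(measure,
    Resnik = im,
    Lin = ratio(im),
    JC = 1 - min(1, i1 + i2 - 2 * im),
    Rel = ratio(im) * (1 - ic_table$p[[mica_term]]),
    simIC = ratio(im) * (1 - 1 / (1 + im)),
    CoutoResnik = sh,
    CoutoLin = ratio(sh),
    CoutoJC = 1 - min(1, i1 + i2 - 2 * sh)
  )
}

# exhaustive upper-tail hypergeometric probability by enumerating draws
oracle_hypergeom <- function(N, M, k, x) {
  sum(vapply(x:min(M, k), function(i) {
    choose(M, i) * choose(N - M, k - i)
  }, numeric(1))) / choose(N, k)
}

# helper: a small seeded random DAG + full-coverage corpus + IC
random_fixture <- function(seed, n_terms = 10L, max_parents = 2L,
                           depth_target = 3L, n_genes = 12L) {
  dag <- random_ontology(n_terms, depth_target = depth_target,
                         max_parents = max_parents, seed = seed)
  corpus <- random_corpus(dag, n_genes, seed = seed + 1000L,
                          leaf_coverage = TRUE)
  list(dag = dag, corpus = corpus, ic = information_content(dag, corpus))
}

# absolute-tolerance comparison against reference values printed to 4 d.p.
expect_near <- function(actual, expected, tol = 1e-4, info = NULL) {
  testthat::expect_lt(abs(actual - expected), tol, label = info)
}
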
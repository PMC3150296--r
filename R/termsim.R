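#' Term-term semantic similarity
#'
#' Ten measures over an "is-a" DAG. Nine are information-content based
#' (Resnik, Lin, JC, Rel, GIC, simIC and the GraSM disjunctive-common-ancestor
#' variants CoutoResnik, CoutoLin, CoutoJC); the tenth (Wang) is structural,
#' built from edge-weight semantic contributions, and needs no annotation
#' corpus.
#'
#' @name termsim
NULL

#' Similarity measure names
#' @return character vector of the ten supported measure names
#' @export
similarity_measures <- function() {
  c("Resnik", "Lin", "JC", "Rel", "GIC", "simIC",
    "CoutoResnik", "CoutoLin", "CoutoJC", "Wang")
}

match_measure <- function(measure) {
  m <- similarity_measures()
  hit <- m[tolower(m) == tolower(measure[[1L]])]
  if (length(hit) != 1L) {
    stop("unknown measure '", measure, "'; valid measures: ",
         paste(m, collapse = ", "), call. = FALSE)
  }
  hit
}

ic_value <- function(ic_table, t) {
  v <- ic_table$ic[t]
  if (anyNA(v)) {
    stop("term outside the IC domain (zero annotation count): ",
         t[is.na(v)][[1L]], call. = FALSE)
  }
  unname(v)
}

#' Most informative common ancestor
#'
#' Among the common ancestors of `t1` and `t2` (a term counts as its own
#' ancestor), returns the one with maximal information content; IC ties are
#' broken by the lexicographically smallest accession.
#'
#' @param dag an [OntologyDAG]
#' @param ic_table an `ICTable` from [information_content()]
#' @param t1,t2 term accessions inside the IC domain
#' @return list with `term` (accession) and `ic` (its information content)
#' @export
mica <- function(dag, ic_table, t1, t2) {
  t1 <- check_term(dag, t1); t2 <- check_term(dag, t2)
  ca <- intersect(ancestors(dag, t1, TRUE), ancestors(dag, t2, TRUE))
  ca <- ca[ca %in% ic_domain(ic_table)]
  if (length(ca) == 0L) {
    stop("no common ancestor in the IC domain for ", t1, " and ", t2,
         call. = FALSE)
  }
  ics <- ic_table$ic[ca]
  best <- ca[ics == max(ics)]
  term <- sort(best)[[1L]]
  list(term = term, ic = unname(ic_table$ic[[term]]))
}

#' Disjunctive ancestor pairs of a term
#'
#' Two proper ancestors `a1`, `a2` of `t` are disjunctive when there is a
#' directed path from `a1` down to `t` avoiding `a2` and one from `a2` down to
#' `t` avoiding `a1` — they represent independent interpretations of `t`.
#' Paths include their endpoints, so no pair involving `t` itself is ever
#' disjunctive.
#'
#' @param dag an [OntologyDAG]
#' @param t term accession
#' @return two-column character matrix of unordered pairs (columns `a1`,
#'   `a2`, with `a1 < a2` lexicographically); zero rows when no pair is
#'   disjunctive
#' @export
disjunctive_ancestor_pairs <- function(dag, t) {
  t <- check_term(dag, t)
  anc <- ancestors(dag, t, include_self = FALSE)
  empty <- matrix(character(0), ncol = 2, dimnames = list(NULL, c("a1", "a2")))
  if (length(anc) < 2L) return(empty)
  # reach_avoid[[a]]: ancestors that still reach t when a is removed
  reach_avoid <- lapply(anc, function(a) {
    frontier <- t
    seen <- t
    repeat {
      nxt <- unlist(dag$parents[frontier], use.names = FALSE)
      nxt <- setdiff(unique(nxt), c(seen, a))
      if (!length(nxt)) break
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  })
  names(reach_avoid) <- anc
  pairs <- utils::combn(sort(anc), 2)
  keep <- apply(pairs, 2, function(pr) {
    pr[[1L]] %in% reach_avoid[[pr[[2L]]]] && pr[[2L]] %in% reach_avoid[[pr[[1L]]]]
  })
  out <- t(pairs[, keep, drop = FALSE])
  colnames(out) <- c("a1", "a2")
  out
}

#' Disjunctive common ancestors and GraSM shared information
#'
#' A common ancestor `a` of `t1`, `t2` belongs to the DCA set when every
#' common ancestor of strictly higher IC forms a disjunctive pair with `a`
#' for `t1` or for `t2`; the MICA qualifies vacuously. The shared information
#' `share` is the mean IC over the DCA set — equal to the MICA's IC whenever
#' the common ancestors form a chain (tree-shaped DAGs).
#'
#' @inheritParams mica
#' @return list with `mica` (accession), `dca` (character vector), `share`
#'   (numeric)
#' @export
dca <- function(dag, ic_table, t1, t2) {
  t1 <- check_term(dag, t1); t2 <- check_term(dag, t2)
  ca <- intersect(ancestors(dag, t1, TRUE), ancestors(dag, t2, TRUE))
  ca <- ca[ca %in% ic_domain(ic_table)]
  if (length(ca) == 0L) {
    stop("no common ancestor in the IC domain for ", t1, " and ", t2,
         call. = FALSE)
  }
  ics <- ic_table$ic[ca]
  pair_key <- function(m) {
    if (nrow(m) == 0L) character(0) else paste(m[, 1L], m[, 2L])
  }
  disj <- unique(c(
    pair_key(disjunctive_ancestor_pairs(dag, t1)),
    pair_key(disjunctive_ancestor_pairs(dag, t2))
  ))
  is_disj <- function(a, b) {
    paste(min(a, b), max(a, b)) %in% disj
  }
  in_dca <- vapply(ca, function(a) {
    higher <- ca[ics > ics[[a]]]
    all(vapply(higher, is_disj, logical(1), a = a))
  }, logical(1))
  dset <- ca[in_dca]
  mt <- mica(dag, ic_table, t1, t2)
  list(mica = mt$term, dca = sort(dset), share = mean(ic_table$ic[dset]))
}

#' Wang semantic contributions
#'
#' Within the sub-DAG of `t` and its ancestors, the contribution of an
#' ancestor `a` to `t` is the maximum over all directed paths from `a` down
#' to `t` of the product of edge weights (each "is-a" edge contributes the
#' factor `w_e`); the contribution of `t` to itself is 1. The semantic value
#' `sv` is the sum of all contributions.
#'
#' @param dag an [OntologyDAG]
#' @param t term accession
#' @param w_e semantic contribution factor per "is-a" edge, strictly between
#'   0 and 1; 0.7 by default
#' @return list with `contributions` (named numeric, ancestors-or-self of
#'   `t`), `sv` (their sum), `w_e`
#' @export
wang_contributions <- function(dag, t, w_e = 0.7) {
  if (!is.numeric(w_e) || length(w_e) != 1L || w_e <= 0 || w_e >= 1) {
    stop("w_e must lie strictly between 0 and 1", call. = FALSE)
  }
  t <- check_term(dag, t)
  nodes <- ancestors(dag, t, include_self = TRUE)
  contrib <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  contrib[[t]] <- 1
  # process in topological order of the sub-DAG: a node is ready when all of
  # its in-sub-DAG children are done
  pending <- setdiff(nodes, t)
  while (length(pending)) {
    progressed <- FALSE
    for (a in pending) {
      kids <- intersect(dag$children[[a]], nodes)
      if (all(!is.na(contrib[kids]))) {
        contrib[[a]] <- max(contrib[kids]) * w_e
        pending <- setdiff(pending, a)
        progressed <- TRUE
      }
    }
    if (!progressed) stop("internal error: ancestor sub-DAG not acyclic")
  }
  list(contributions = contrib, sv = sum(contrib), w_e = w_e)
}

wang_pair <- function(dag, t1, t2, w_e = 0.7, cache = NULL) {
  get_c <- function(t) {
    if (!is.null(cache) && !is.null(cache[[t]])) return(cache[[t]])
    wang_contributions(dag, t, w_e)
  }
  c1 <- get_c(t1); c2 <- get_c(t2)
  common <- intersect(names(c1$contributions), names(c2$contributions))
  sum(c1$contributions[common] + c2$contributions[common]) / (c1$sv + c2$sv)
}

#' Semantic similarity between two terms
#'
#' @param dag an [OntologyDAG]
#' @param ic_table an `ICTable`; may be `NULL` for the Wang measure, which is
#'   corpus-free
#' @param t1,t2 term accessions
#' @param measure one of [similarity_measures()] (case-insensitive)
#' @param w_e edge weight for the Wang measure
#' @param normalize_resnik divide Resnik/CoutoResnik output by the corpus-wide
#'   maximum IC (off by default; the raw IC scale is reported otherwise)
#' @return a single numeric similarity
#' @details
#' With `I1 = ic(t1)`, `I2 = ic(t2)`, `IM = ic(MICA)` and `Sh = Share(t1,t2)`:
#' \itemize{
#'   \item Resnik: `IM`
#'   \item Lin: `2 IM / (I1 + I2)`
#'   \item JC: `1 - min(1, I1 + I2 - 2 IM)` (distance clamped into a
#'     similarity)
#'   \item Rel: `Lin * (1 - p(MICA))`
#'   \item GIC: sum of IC over common ancestors divided by the sum over the
#'     ancestor union (ancestors include self)
#'   \item simIC: `Lin * (1 - 1 / (1 + IM))`
#'   \item CoutoResnik / CoutoLin / CoutoJC: as Resnik / Lin / JC with `Sh`
#'     in place of `IM`
#'   \item Wang: sum over shared ancestors of both terms' semantic
#'     contributions, divided by `SV(t1) + SV(t2)`
#' }
#' When both terms are the root (`I1 + I2 = 0`) the ratio measures return 1.
#' @examples
#' fx <- fixture_toy9()
#' term_similarity(fx$dag, fx$ic, fx$acc[["E"]], fx$acc[["F"]], "Lin")
#' @export
term_similarity <- function(dag, ic_table, t1, t2, measure,
                            w_e = 0.7, normalize_resnik = FALSE) {
  measure <- match_measure(measure)
  t1 <- check_term(dag, t1); t2 <- check_term(dag, t2)
  if (measure == "Wang") return(wang_pair(dag, t1, t2, w_e))

  i1 <- ic_value(ic_table, t1)
  i2 <- ic_value(ic_table, t2)

  if (measure == "GIC") {
    a1 <- ancestors(dag, t1, TRUE); a2 <- ancestors(dag, t2, TRUE)
    dom <- ic_domain(ic_table)
    common <- intersect(a1, a2); common <- common[common %in% dom]
    uni <- union(a1, a2); uni <- uni[uni %in% dom]
    denom <- sum(ic_table$ic[uni])
    if (denom == 0) return(1)  # both terms are the root
    return(sum(ic_table$ic[common]) / denom)
  }

  couto <- measure %in% c("CoutoResnik", "CoutoLin", "CoutoJC")
  if (couto) {
    shared <- dca(dag, ic_table, t1, t2)$share
  } else {
    mt <- mica(dag, ic_table, t1, t2)
    shared <- mt$ic
  }

  ratio <- function(sh) if (i1 + i2 == 0) 1 else 2 * sh / (i1 + i2)
  max_ic <- max(ic_table$ic)

  switch(measure,
    Resnik = if (normalize_resnik && max_ic > 0) shared / max_ic else shared,
    CoutoResnik = if (normalize_resnik && max_ic > 0) shared / max_ic else shared,
    Lin = ratio(shared),
    CoutoLin = ratio(shared),
    JC = 1 - min(1, i1 + i2 - 2 * shared),
    CoutoJC = 1 - min(1, i1 + i2 - 2 * shared),
    Rel = {
      p_mica <- unname(ic_table$p[[mica(dag, ic_table, t1, t2)$term]])
      ratio(shared) * (1 - p_mica)
    },
    simIC = ratio(shared) * (1 - 1 / (1 + shared))
  )
}

#' Pairwise term similarity matrix
#'
#' @inheritParams term_similarity
#' @param terms character vector of at least two accessions
#' @return a symmetric numeric matrix with `terms` as dimnames and attributes
#'   `measure`, `w_e` (Wang only)
#' @export
term_similarity_matrix <- function(dag, ic_table, terms, measure,
                                   w_e = 0.7, normalize_resnik = FALSE) {
  measure <- match_measure(measure)
  if (length(terms) < 2L) stop("need at least two terms", call. = FALSE)
  if (anyDuplicated(terms)) stop("duplicate terms in list", call. = FALSE)
  terms <- vapply(terms, check_term, character(1), dag = dag)
  n <- length(terms)
  cache <- NULL
  if (measure == "Wang") {
    cache <- lapply(terms, wang_contributions, dag = dag, w_e = w_e)
    names(cache) <- terms
  }
  m <- matrix(0, n, n, dimnames = list(unname(terms), unname(terms)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- if (measure == "Wang") {
        wang_pair(dag, terms[[i]], terms[[j]], w_e, cache = cache)
      } else {
        term_similarity(dag, ic_table, terms[[i]], terms[[j]], measure,
                        w_e = w_e, normalize_resnik = normalize_resnik)
      }
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  attr(m, "measure") <- measure
  if (measure == "Wang") attr(m, "w_e") <- w_e
  m
}
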
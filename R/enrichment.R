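#' Hypergeometric term enrichment
#'
#' Tests whether a gene set is over-represented in the genes annotated
#' (directly or through descendants) to each candidate term. Candidate terms
#' are selected by two pre-specified criteria before testing: a minimum
#' propagated gene count (`filter`) and a minimum DAG depth (`layer`,
#' excluding overly general terms near the root). FDR control is applied
#' across the candidate set only.
#'
#' @name enrichment
NULL

#' Upper-tail hypergeometric p-value
#'
#' Probability of drawing at least `x` annotated genes when `k` genes are
#' drawn without replacement from a universe of `N` genes of which `M` are
#' annotated.
#'
#' @param N universe size
#' @param M annotated genes in the universe
#' @param k drawn genes (gene-set size within the universe)
#' @param x observed annotated genes in the draw
#' @return a p-value in (0, 1]
#' @export
hypergeom_pvalue <- function(N, M, k, x) {
  stopifnot(length(N) == 1L, length(M) == 1L, length(k) == 1L, length(x) == 1L)
  if (M > N || k > N || x < 0 || x > min(M, k)) {
    stop("invalid hypergeometric bounds: need x <= min(M, k), M <= N, k <= N",
         call. = FALSE)
  }
  stats::phyper(x - 1, M, N - M, k, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return numeric vector of q-values, same length and order
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Term enrichment of a gene set
#'
#' @param dag an [OntologyDAG]
#' @param corpus an [AnnotationCorpus]
#' @param gene_set character vector of gene IDs; members outside the
#'   annotation universe are dropped from `k` with a message
#' @param filter minimum propagated gene count a term needs to be tested
#'   (>= 1)
#' @param layer minimum depth a term needs to be tested (root has depth 0)
#' @param universe_N optional user-supplied universe size `N`; defaults to
#'   the number of annotated genes in the corpus
#' @return data.frame with columns term, name, depth, x, M, k, N, p_value,
#'   fdr, genes (semicolon-joined hits), sorted by p ascending
#' @examples
#' fx <- fixture_toy9()
#' enrich(fx$dag, fx$corpus, c("g1", "g2", "g3"), filter = 2, layer = 1)
#' @export
enrich <- function(dag, corpus, gene_set, filter = 1L, layer = 0L,
                   universe_N = NULL) {
  stopifnot(filter >= 1L, layer >= 0L)
  if (length(gene_set) == 0L) stop("gene set is empty", call. = FALSE)
  gene_set <- unique(gene_set)
  universe <- names(corpus$direct)
  in_universe <- gene_set[gene_set %in% universe]
  outside <- length(gene_set) - length(in_universe)
  if (outside > 0L) {
    message(outside, " query gene(s) not in the annotation universe; dropped")
  }
  if (length(in_universe) == 0L) {
    stop("no gene overlaps the annotation universe", call. = FALSE)
  }
  N <- if (is.null(universe_N)) corpus$universe_size else as.integer(universe_N)
  k <- length(in_universe)

  gene_sets <- propagated_genes(dag, corpus)
  counts <- vapply(gene_sets, length, integer(1))
  depths <- all_depths(dag)
  cand <- names(counts)[counts >= filter & depths[names(counts)] >= layer]

  if (length(cand) == 0L) {
    return(empty_enrichment())
  }
  rows <- lapply(cand, function(t) {
    hits <- intersect(in_universe, gene_sets[[t]])
    M <- counts[[t]]
    data.frame(
      term = t,
      name = unname(dag$name[[t]]),
      depth = unname(depths[[t]]),
      x = length(hits),
      M = M,
      k = k,
      N = N,
      p_value = hypergeom_pvalue(N, M, k, length(hits)),
      genes = paste(sort(hits), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  out[, c("term", "name", "depth", "x", "M", "k", "N", "p_value", "fdr", "genes")]
}

empty_enrichment <- function() {
  data.frame(
    term = character(0), name = character(0), depth = integer(0),
    x = integer(0), M = integer(0), k = integer(0), N = integer(0),
    p_value = numeric(0), fdr = numeric(0), genes = character(0),
    stringsAsFactors = FALSE
  )
}

#' Enrichment over a flat term-to-gene map
#'
#' Same hypergeometric engine without a DAG: any vocabulary given as a named
#' list of term -> gene sets can be tested (the mechanism behind multilayer
#' annotation of modules with external vocabularies). The depth criterion
#' does not apply.
#'
#' @param term2genes named list, term -> character vector of genes
#' @param gene_set character vector of query gene IDs
#' @param filter minimum number of genes a term needs to be tested
#' @param universe optional character vector defining the gene universe;
#'   defaults to the union of all genes in `term2genes`
#' @return data.frame as in [enrich()] minus name/depth columns
#' @export
enrich_map <- function(term2genes, gene_set, filter = 1L, universe = NULL) {
  stopifnot(is.list(term2genes), filter >= 1L)
  term2genes <- lapply(term2genes, unique)
  if (is.null(universe)) {
    universe <- unique(unlist(term2genes, use.names = FALSE))
  }
  gene_set <- unique(gene_set)
  in_universe <- gene_set[gene_set %in% universe]
  if (length(in_universe) == 0L) {
    stop("no gene overlaps the annotation universe", call. = FALSE)
  }
  N <- length(universe)
  k <- length(in_universe)
  counts <- vapply(term2genes, length, integer(1))
  cand <- names(term2genes)[counts >= filter]
  if (length(cand) == 0L) {
    out <- empty_enrichment()
    return(out[, setdiff(names(out), c("name", "depth"))])
  }
  rows <- lapply(cand, function(t) {
    hits <- intersect(in_universe, term2genes[[t]])
    data.frame(
      term = t, x = length(hits), M = counts[[t]], k = k, N = N,
      p_value = hypergeom_pvalue(N, counts[[t]], k, length(hits)),
      genes = paste(sort(hits), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  out[, c("term", "x", "M", "k", "N", "p_value", "fdr", "genes")]
}
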
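#' Gene-gene similarity from annotation term sets
#'
#' A gene is represented by its set of direct term annotations; the
#' similarity of two genes aggregates the term-pair similarity matrix `s`
#' between the two sets by one of five methods.
#'
#' @name genesim
NULL

#' Aggregation method names
#' @return character vector of the five supported methods
#' @export
aggregation_methods <- function() {
  c("Max", "Mean", "funSimMax", "funSimAvg", "BMA")
}

match_method <- function(method) {
  m <- aggregation_methods()
  hit <- m[tolower(m) == tolower(method[[1L]])]
  if (length(hit) != 1L) {
    stop("unknown method '", method, "'; valid methods: ",
         paste(m, collapse = ", "), call. = FALSE)
  }
  hit
}

#' Aggregate a term-pair similarity matrix into one score
#'
#' Given the m x n matrix `s` of term similarities between the annotation
#' sets of two genes, with `rowScore` the mean of the row maxima and
#' `columnScore` the mean of the column maxima:
#' \itemize{
#'   \item Max: the grand maximum of `s`
#'   \item Mean: the grand mean of `s`
#'   \item funSimMax: `max(rowScore, columnScore)`
#'   \item funSimAvg: `(rowScore + columnScore) / 2`
#'   \item BMA: best-match average, `(sum of row maxima + sum of column
#'     maxima) / (m + n)`
#' }
#'
#' @param s numeric matrix, non-empty and finite
#' @param method one of [aggregation_methods()] (case-insensitive)
#' @return a single numeric score
#' @export
term_set_similarity <- function(s, method) {
  method <- match_method(method)
  if (!is.matrix(s)) s <- as.matrix(s)
  if (length(s) == 0L) stop("similarity matrix is empty", call. = FALSE)
  if (!all(is.finite(s))) stop("similarity matrix has non-finite entries",
                               call. = FALSE)
  rmax <- apply(s, 1, max)
  cmax <- apply(s, 2, max)
  switch(method,
    Max = max(s),
    Mean = mean(s),
    funSimMax = max(mean(rmax), mean(cmax)),
    funSimAvg = (mean(rmax) + mean(cmax)) / 2,
    BMA = (sum(rmax) + sum(cmax)) / (nrow(s) + ncol(s))
  )
}

direct_terms_for <- function(dag, ic_table, corpus, g, measure) {
  ts <- corpus$direct[[g]]
  if (is.null(ts) || length(ts) == 0L) {
    stop("gene has no annotation: ", g, call. = FALSE)
  }
  if (measure != "Wang") {
    dom <- ic_domain(ic_table)
    ts <- ts[ts %in% dom]
    if (length(ts) == 0L) {
      stop("gene ", g, " has no annotation inside the IC domain", call. = FALSE)
    }
  }
  ts
}

#' Similarity between two genes
#'
#' Builds the term-pair similarity matrix from the genes' direct annotation
#' sets (no ancestor propagation) under the chosen term measure, then
#' aggregates it.
#'
#' @param dag an [OntologyDAG]
#' @param ic_table an `ICTable` (ignored by the Wang measure)
#' @param corpus an [AnnotationCorpus]
#' @param g1,g2 gene identifiers present in the corpus
#' @param measure term measure, one of [similarity_measures()]
#' @param method aggregation, one of [aggregation_methods()]
#' @param w_e Wang edge weight
#' @return a single numeric similarity
#' @examples
#' fx <- fixture_toy9()
#' gene_similarity(fx$dag, fx$ic, fx$corpus, "g2", "g4", "Lin", "BMA")
#' @export
gene_similarity <- function(dag, ic_table, corpus, g1, g2, measure, method,
                            w_e = 0.7) {
  measure <- match_measure(measure)
  method <- match_method(method)
  ts1 <- direct_terms_for(dag, ic_table, corpus, g1, measure)
  ts2 <- direct_terms_for(dag, ic_table, corpus, g2, measure)
  s <- matrix(0, length(ts1), length(ts2), dimnames = list(ts1, ts2))
  for (i in seq_along(ts1)) {
    for (j in seq_along(ts2)) {
      s[i, j] <- term_similarity(dag, ic_table, ts1[[i]], ts2[[j]], measure,
                                 w_e = w_e)
    }
  }
  term_set_similarity(s, method)
}

#' Pairwise gene similarity matrix
#'
#' Genes lacking usable annotations are dropped with a message (mirroring
#' corpus-restricted analyses where only annotated genes can be scored); the
#' diagonal holds each gene's self-similarity under the chosen method, which
#' is 1 for normalized measures and the gene's own information scale for
#' unnormalized ones (Resnik, CoutoResnik).
#'
#' @inheritParams gene_similarity
#' @param genes character vector of gene identifiers (at least two usable)
#' @return symmetric numeric matrix with attributes `measure`, `method`,
#'   `dropped` (character vector of unusable gene IDs)
#' @export
gene_similarity_matrix <- function(dag, ic_table, corpus, genes, measure,
                                   method, w_e = 0.7) {
  measure <- match_measure(measure)
  method <- match_method(method)
  genes <- unique(genes)
  usable <- vapply(genes, function(g) {
    !is.null(corpus$direct[[g]]) &&
      length(corpus$direct[[g]]) > 0L &&
      (measure == "Wang" ||
         any(corpus$direct[[g]] %in% ic_domain(ic_table)))
  }, logical(1))
  dropped <- genes[!usable]
  genes <- genes[usable]
  if (length(dropped)) {
    message(length(dropped), " gene(s) dropped (no usable annotation): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  if (length(genes) < 2L) {
    stop("fewer than two annotated genes remain", call. = FALSE)
  }
  # precompute term-level matrix over the union of direct terms
  all_terms <- unique(unlist(corpus$direct[genes], use.names = FALSE))
  if (measure != "Wang") all_terms <- all_terms[all_terms %in% ic_domain(ic_table)]
  tm <- if (length(all_terms) >= 2L) {
    term_similarity_matrix(dag, ic_table, all_terms, measure, w_e = w_e)
  } else {
    v <- term_similarity(dag, ic_table, all_terms, all_terms, measure, w_e = w_e)
    matrix(v, 1, 1, dimnames = list(all_terms, all_terms))
  }
  n <- length(genes)
  m <- matrix(0, n, n, dimnames = list(genes, genes))
  tsets <- lapply(genes, function(g) {
    ts <- corpus$direct[[g]]
    if (measure != "Wang") ts <- ts[ts %in% ic_domain(ic_table)]
    ts
  })
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- tm[tsets[[i]], tsets[[j]], drop = FALSE]
      v <- term_set_similarity(s, method)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  attr(m, "measure") <- measure
  attr(m, "method") <- method
  attr(m, "dropped") <- dropped
  m
}
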
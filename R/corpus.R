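#' Annotation corpora and information content
#'
#' An `AnnotationCorpus` holds direct gene-to-term annotations; probabilities
#' and information content are derived from counts propagated up the DAG
#' (a gene annotated to a term is implicitly annotated to all of its
#' ancestors).
#'
#' @name AnnotationCorpus
NULL

new_annotation_corpus <- function(direct) {
  structure(
    list(direct = direct, universe_size = length(direct)),
    class = "AnnotationCorpus"
  )
}

#' @export
print.AnnotationCorpus <- function(x, ...) {
  cat(sprintf(
    "AnnotationCorpus: %d genes, %d direct annotations\n",
    x$universe_size, sum(lengths(x$direct))
  ))
  invisible(x)
}

#' Build a corpus from a gene/term table
#'
#' @param genes character vector of gene IDs
#' @param terms character vector of accessions, parallel to `genes`
#' @param dag an [OntologyDAG]; rows whose accession is unknown or obsolete
#'   are dropped with a message
#' @return an [AnnotationCorpus]
#' @export
annotation_corpus <- function(genes, terms, dag) {
  stopifnot(length(genes) == length(terms))
  # map alternate accessions to canonical
  terms <- ifelse(terms %in% names(dag$alt), unname(dag$alt[terms]), terms)
  known <- terms %in% dag$accession
  live <- known & !dag$obsolete[terms] %in% TRUE
  dropped <- sum(!live)
  if (dropped > 0L) {
    message(dropped, " annotation row(s) dropped (unknown or obsolete accession)")
  }
  genes <- genes[live]; terms <- terms[live]
  direct <- lapply(split(terms, genes), unique)
  new_annotation_corpus(direct)
}

#' Read a two-column annotation TSV
#'
#' Expected format: gene ID, term accession, tab-separated; lines starting
#' with `#` are comments. Rows referencing unknown or obsolete terms are
#' dropped and counted in a message; duplicate (gene, term) rows collapse.
#'
#' @param file path to the TSV
#' @param dag an [OntologyDAG]
#' @return an [AnnotationCorpus]
#' @export
read_annotations <- function(file, dag) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(new_annotation_corpus(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed annotation row (expected 2 columns) at line ", bad[[1L]],
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  annotation_corpus(m[, 1L], m[, 2L], dag)
}

#' Propagated per-term gene counts
#'
#' For each active term, the number of distinct genes annotated to the term
#' or any of its descendants. A gene annotated to two descendants of a term
#' counts once.
#'
#' @param dag an [OntologyDAG]
#' @param corpus an [AnnotationCorpus]
#' @return named integer vector over active terms
#' @export
propagated_counts <- function(dag, corpus) {
  vapply(propagated_genes(dag, corpus), length, integer(1))
}

#' Propagated per-term gene sets
#'
#' @inheritParams propagated_counts
#' @return named list of character vectors (genes) over active terms
#' @export
propagated_genes <- function(dag, corpus) {
  act <- active_terms(dag)
  direct_by_term <- vector("list", length(act))
  names(direct_by_term) <- act
  for (g in names(corpus$direct)) {
    for (t in corpus$direct[[g]]) {
      direct_by_term[[t]] <- c(direct_by_term[[t]], g)
    }
  }
  # accumulate child sets in reverse topological order (children first)
  ord <- topo_order(dag)
  sets <- direct_by_term
  for (t in rev(ord)) {
    kids <- dag$children[[t]]
    if (length(kids)) {
      sets[[t]] <- unique(c(sets[[t]], unlist(sets[kids], use.names = FALSE)))
    } else {
      sets[[t]] <- unique(sets[[t]])
    }
  }
  lapply(sets, function(s) if (is.null(s)) character(0) else s)
}

# topological order from root to leaves (parents before children)
topo_order <- function(dag) {
  act <- active_terms(dag)
  in_deg <- lengths(dag$parents[act])
  names(in_deg) <- act
  queue <- act[in_deg == 0L]
  ord <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (c in dag$children[[v]]) {
      in_deg[[c]] <- in_deg[[c]] - 1L
      if (in_deg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  ord
}

#' Information content table
#'
#' Computes, for every active term, the annotation probability
#' `p(t) = count(t) / universe_size` from descendant-propagated distinct-gene
#' counts, and the information content `ic(t) = -log p(t)` (in the requested
#' base; natural log by default). Terms with zero propagated count have no
#' defined IC and are excluded from the IC domain — IC-based similarity
#' measures refuse them, while the structure-only Wang measure still accepts
#' them.
#'
#' @param dag an [OntologyDAG]
#' @param corpus an [AnnotationCorpus] with at least one gene
#' @param log_base base of the logarithm; `exp(1)` (nats) by default. Ratio
#'   measures (Lin, Rel, GIC, simIC, CoutoLin) are invariant to this choice;
#'   Resnik and the Jiang-Conrath clamp are not, so the base is recorded in
#'   the table.
#' @return an object of class `ICTable`: list with `p` (named numeric over
#'   active terms), `ic` (named numeric over terms with `p > 0`), `log_base`,
#'   `universe_size`
#' @export
information_content <- function(dag, corpus, log_base = exp(1)) {
  if (corpus$universe_size == 0L) {
    stop("corpus has no annotated genes; information content undefined",
         call. = FALSE)
  }
  stopifnot(is.numeric(log_base), log_base > 0, log_base != 1)
  counts <- propagated_counts(dag, corpus)
  p <- counts / corpus$universe_size
  ic <- -log(p[p > 0]) / log(log_base)
  ic[ic < 0] <- 0  # guard against -0
  structure(
    list(p = p, ic = ic, log_base = log_base,
         universe_size = corpus$universe_size),
    class = "ICTable"
  )
}

#' @export
print.ICTable <- function(x, ...) {
  cat(sprintf(
    "ICTable: %d terms (%d with defined IC), universe %d genes, log base %.4g\n",
    length(x$p), length(x$ic), x$universe_size, x$log_base
  ))
  invisible(x)
}

#' Write an IC table as TSV
#'
#' Three columns (accession, p, ic) with comment headers recording the
#' universe size and log base; terms outside the IC domain print `NA` ic.
#'
#' @param ic_table an `ICTable`
#' @param file output path
#' @return `file`, invisibly
#' @export
write_ic_table <- function(ic_table, file) {
  accs <- names(ic_table$p)
  ic <- ic_table$ic[accs]
  lines <- c(
    sprintf("#universe_size\t%d", ic_table$universe_size),
    sprintf("#log_base\t%.17g", ic_table$log_base),
    "accession\tp\tic",
    sprintf("%s\t%.17g\t%s", accs, ic_table$p,
            ifelse(is.na(ic), "NA", sprintf("%.17g", ic)))
  )
  writeLines(lines, file)
  invisible(file)
}

ic_domain <- function(ic_table) names(ic_table$ic)
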
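#' Synthetic ontologies, corpora and similarity matrices
#'
#' Deterministic fixtures and seeded random generators so every analysis in
#' the package can be exercised without any external ontology download.
#'
#' @name synthetic
NULL

#' The canonical 9-term fixture
#'
#' A small rooted DAG with one multi-parent term and a fully worked-out
#' annotation corpus, used across the package's examples and tests:
#'
#' \preformatted{
#'        R
#'       / \
#'      A   B
#'     / \ /
#'    C   D
#'    |   |
#'    E   F
#' }
#'
#' Terms use accessions `TOY:0000001` ... `TOY:0000007` with mnemonic letters
#' R, A, B, C, D, E, F (D has the two parents A and B); two obsolete padding
#' terms are included to exercise obsolete handling. Eight genes g1..g8 are
#' directly annotated to E; E,F; F; C; D; B; A; R respectively, which gives
#' propagated probabilities such as `p(A) = 6/8` and information content
#' `ic(E) = -ln(1/4)`.
#'
#' @return list with components `dag` ([OntologyDAG]), `corpus`
#'   ([AnnotationCorpus]), `ic` (`ICTable`, natural log), `acc` (named
#'   character vector mapping letters to accessions), `expected` (data.frame
#'   of reference quantities used in tests, re-derivable from the fixture by
#'   direct set enumeration)
#' @examples
#' fx <- fixture_toy9()
#' fx$ic$p[[fx$acc[["A"]]]]  # 0.75
#' @export
fixture_toy9 <- function() {
  acc <- stats::setNames(sprintf("TOY:%07d", 1:7),
                         c("R", "A", "B", "C", "D", "E", "F"))
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", paste0("id: ", acc[["R"]]), "name: R root term", "",
    "[Term]", paste0("id: ", acc[["A"]]), "name: A branch",
    paste0("is_a: ", acc[["R"]]), "",
    "[Term]", paste0("id: ", acc[["B"]]), "name: B branch",
    paste0("is_a: ", acc[["R"]]), "",
    "[Term]", paste0("id: ", acc[["C"]]), "name: C under A",
    paste0("is_a: ", acc[["A"]]), "",
    "[Term]", paste0("id: ", acc[["D"]]), "name: D under A and B",
    paste0("is_a: ", acc[["A"]]), paste0("is_a: ", acc[["B"]]), "",
    "[Term]", paste0("id: ", acc[["E"]]), "name: E leaf",
    paste0("is_a: ", acc[["C"]]), "",
    "[Term]", paste0("id: ", acc[["F"]]), "name: F leaf",
    paste0("is_a: ", acc[["D"]]), "",
    "[Term]", "id: TOY:0000008", "name: obsolete padding one",
    "is_obsolete: true", "",
    "[Term]", "id: TOY:0000009", "name: obsolete padding two",
    "is_obsolete: true", ""
  )
  dag <- parse_obo(text = obo)
  direct <- list(
    g1 = acc[["E"]],
    g2 = c(acc[["E"]], acc[["F"]]),
    g3 = acc[["F"]],
    g4 = acc[["C"]],
    g5 = acc[["D"]],
    g6 = acc[["B"]],
    g7 = acc[["A"]],
    g8 = acc[["R"]]
  )
  corpus <- annotation_corpus(
    rep(names(direct), lengths(direct)),
    unlist(direct, use.names = FALSE),
    dag
  )
  ic <- information_content(dag, corpus)
  expected <- data.frame(
    quantity = c("p_A", "ic_A", "ic_E", "ic_F", "lin_EF", "resnik_EF",
                 "rel_EF", "gic_EF", "share_EF", "couto_lin_EF", "wang_EF",
                 "bma_lin_g2_g4", "enrich_p_E"),
    value = c(6 / 8, -log(6 / 8), -log(1 / 4), -log(1 / 4),
              2 * (-log(6 / 8)) / (2 * -log(1 / 4)),
              -log(6 / 8),
              2 * (-log(6 / 8)) / (2 * -log(1 / 4)) * (1 - 6 / 8),
              -log(6 / 8) /
                sum(-log(c(1 / 4, 3 / 8, 6 / 8, 1 / 4, 3 / 8, 4 / 8))),
              (-log(6 / 8) + 0) / 2,
              (-log(6 / 8) + 0) / (2 * -log(1 / 4)),
              (0.49 + 0.49 + 0.343 + 0.343) /
                (sum(0.7^(0:3)) + (1 + 0.7 + 2 * 0.49 + 0.343)),
              NA,  # filled below
              6 / 56),
    stringsAsFactors = FALSE
  )
  lin_EC <- 2 * (-log(3 / 8)) / (-log(1 / 4) + -log(3 / 8))
  lin_FC <- 2 * (-log(6 / 8)) / (-log(1 / 4) + -log(3 / 8))
  expected$value[expected$quantity == "bma_lin_g2_g4"] <-
    (lin_EC + lin_FC + lin_EC) / 3
  list(dag = dag, corpus = corpus, ic = ic, acc = acc, expected = expected)
}

#' Random layered ontology
#'
#' Generates a rooted multi-parent DAG: terms are assigned to layers
#' 1..`depth_target` below the root and every non-root term draws between 1
#' and `max_parents` parents from strictly shallower layers, so the result is
#' acyclic by construction and single-rooted. With `max_parents = 1` the
#' result is a tree, which is what the exact tree-reduction identities of the
#' GraSM measures require.
#'
#' @param n_terms total number of terms including the root (>= 2)
#' @param depth_target number of layers below the root (>= 1)
#' @param max_parents maximum parents per term (>= 1)
#' @param seed integer seed
#' @param prefix accession prefix
#' @return an [OntologyDAG]
#' @export
random_ontology <- function(n_terms, depth_target = 3L, max_parents = 2L,
                            seed = 1L, prefix = "RND") {
  stopifnot(n_terms >= 2L, depth_target >= 1L, max_parents >= 1L)
  with_seed(seed, {
    accs <- sprintf("%s:%07d", prefix, seq_len(n_terms))
    root <- accs[[1L]]
    rest <- accs[-1L]
    # every layer gets at least one term
    depth_target <- min(depth_target, length(rest))
    layer <- sort(c(seq_len(depth_target),
                    sample(depth_target, max(0L, length(rest) - depth_target),
                           replace = TRUE)))
    parents <- stats::setNames(vector("list", n_terms), accs)
    parents[[root]] <- character(0)
    for (i in seq_along(rest)) {
      shallower <- c(root, rest[which(layer < layer[[i]])])
      k <- sample(min(max_parents, length(shallower)), 1L)
      parents[[rest[[i]]]] <- sample(shallower, k)
    }
    nm <- stats::setNames(paste("term", seq_len(n_terms)), accs)
    obs <- stats::setNames(rep(FALSE, n_terms), accs)
    dag <- new_ontology_dag(accs, nm, parents, obs)
    dag$root <- root
    validate_dag(dag)
    dag
  })
}

#' Random annotation corpus
#'
#' Each gene draws a number of direct annotations uniformly from
#' `annotations_per_gene` among the non-root active terms. With
#' `leaf_coverage = TRUE` one extra sentinel gene is added per leaf so every
#' term ends up with a positive propagated count (the full IC domain).
#'
#' @param dag an [OntologyDAG]
#' @param n_genes number of genes
#' @param annotations_per_gene integer range `c(lo, hi)` of direct
#'   annotations per gene
#' @param seed integer seed
#' @param leaf_coverage add one sentinel gene per leaf term
#' @return an [AnnotationCorpus]
#' @export
random_corpus <- function(dag, n_genes, annotations_per_gene = c(1L, 3L),
                          seed = 1L, leaf_coverage = FALSE) {
  stopifnot(n_genes >= 0L, length(annotations_per_gene) == 2L)
  terms <- setdiff(active_terms(dag), dag$root)
  with_seed(seed, {
    genes <- character(0)
    anns <- character(0)
    if (n_genes > 0L && length(terms) > 0L) {
      for (i in seq_len(n_genes)) {
        k <- sample(seq(annotations_per_gene[[1L]], annotations_per_gene[[2L]]), 1L)
        k <- min(k, length(terms))
        drawn <- sample(terms, k)
        genes <- c(genes, rep(sprintf("gene%04d", i), k))
        anns <- c(anns, drawn)
      }
    }
    if (leaf_coverage) {
      leaves <- terms[lengths(dag$children[terms]) == 0L]
      genes <- c(genes, sprintf("sentinel%04d", seq_along(leaves)))
      anns <- c(anns, leaves)
    }
    if (length(genes) == 0L) return(new_annotation_corpus(list()))
    annotation_corpus(genes, anns, dag)
  })
}

#' Planted-partition similarity matrix
#'
#' Block-structured symmetric matrix with known ground-truth modules:
#' within-block similarity `within`, between-block similarity `between`,
#' independent Gaussian noise added, values clipped to \[0, 1\], diagonal 1.
#' The generating labels are attached as the `truth` attribute.
#'
#' @param blocks integer vector of block sizes
#' @param within within-block similarity (must exceed `between`)
#' @param between between-block similarity
#' @param noise_sd standard deviation of the Gaussian noise
#' @param seed integer seed
#' @return symmetric numeric matrix with labels `item0001`, ... and attribute
#'   `truth` (integer block label per item)
#' @export
planted_similarity <- function(blocks, within = 0.9, between = 0.1,
                               noise_sd = 0.02, seed = 1L) {
  stopifnot(length(blocks) >= 1L, all(blocks >= 1L))
  if (!(between >= 0 && between < within && within <= 1)) {
    stop("need 0 <= between < within <= 1", call. = FALSE)
  }
  n <- sum(blocks)
  truth <- rep(seq_along(blocks), blocks)
  base <- matrix(between, n, n)
  for (b in seq_along(blocks)) {
    idx <- which(truth == b)
    base[idx, idx] <- within
  }
  s <- with_seed(seed, {
    noise <- matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    base + noise
  })
  s[s < 0] <- 0
  s[s > 1] <- 1
  diag(s) <- 1
  labels <- sprintf("item%04d", seq_len(n))
  dimnames(s) <- list(labels, labels)
  attr(s, "truth") <- stats::setNames(truth, labels)
  s
}

#' Write an annotation corpus as a two-column TSV
#'
#' @param corpus an [AnnotationCorpus]
#' @param file output path
#' @return `file`, invisibly
#' @export
write_annotations <- function(corpus, file) {
  lines <- unlist(lapply(names(corpus$direct), function(g) {
    paste(g, corpus$direct[[g]], sep = "\t")
  }), use.names = FALSE)
  writeLines(c("#gene\tterm", lines), file)
  invisible(file)
}
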
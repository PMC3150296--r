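#' Similarity-driven module detection
#'
#' Modules (of genes or of terms) are detected from a similarity matrix by
#' average-linkage hierarchical clustering of the complemented similarities,
#' cut either at a constant height or adaptively at the largest height gaps,
#' with permutation-based significance per module.
#'
#' @name modules
NULL

#' Convert a similarity matrix to a distance matrix
#'
#' `d = 1 - s` with the diagonal forced to 0. Matrices from unnormalized
#' measures (maximum above 1, e.g. Resnik) are first rescaled by their
#' maximum so that distances stay in \[0, 1\]; the applied scale is recorded
#' in the `rescaled_by` attribute.
#'
#' @param sim symmetric numeric similarity matrix
#' @return symmetric distance matrix, diagonal 0
#' @export
similarity_to_distance <- function(sim) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim)) {
    stop("similarity matrix must be square", call. = FALSE)
  }
  if (max(abs(sim - t(sim))) > 1e-8) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  scale <- 1
  if (max(sim) > 1) {
    scale <- max(sim)
    sim <- sim / scale
  }
  d <- 1 - sim
  diag(d) <- 0
  d <- (d + t(d)) / 2
  attr(d, "rescaled_by") <- scale
  d
}

#' Average-linkage (UPGMA) dendrogram
#'
#' @param d symmetric distance matrix (or a [stats::dist] object)
#' @return an object of class [stats::hclust]
#' @export
average_linkage <- function(d) {
  if (is.matrix(d)) {
    if (nrow(d) < 2L) stop("need at least two items", call. = FALSE)
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "average")
}

# members (leaf indices) below each merge of an hclust object
merge_members <- function(hc) {
  n <- nrow(hc$merge)
  members <- vector("list", n)
  for (i in seq_len(n)) {
    members[[i]] <- unlist(lapply(hc$merge[i, ], function(v) {
      if (v < 0) -v else members[[v]]
    }), use.names = FALSE)
  }
  members
}

# assign 1..K labels (ordered by decreasing size, ties by smallest member)
# to a list of leaf-index vectors; everything else gets 0
number_modules <- function(groups, labels) {
  out <- stats::setNames(rep(0L, length(labels)), labels)
  if (length(groups) == 0L) return(out)
  ord <- order(-lengths(groups), vapply(groups, min, numeric(1)))
  for (k in seq_along(ord)) {
    out[groups[[ord[[k]]]]] <- k
  }
  out
}

#' Cut a dendrogram at a constant height
#'
#' Clusters are the connected components formed by merges strictly below
#' `height`; components smaller than `min_size` are left unassigned
#' (module 0, the "grey" group).
#'
#' @param hc an [stats::hclust] object
#' @param height non-negative cut height
#' @param min_size minimum members a component needs to become a module
#' @return named integer vector over the dendrogram labels; 0 = unassigned,
#'   modules numbered 1..K by decreasing size
#' @export
cut_static <- function(hc, height, min_size = 3L) {
  stopifnot(inherits(hc, "hclust"), height >= 0)
  n <- length(hc$labels)
  members <- merge_members(hc)
  parent <- seq_len(n)
  find <- function(i) { r <- i; while (parent[[r]] != r) r <- parent[[r]]; r }
  for (i in seq_len(nrow(hc$merge))) {
    if (hc$height[[i]] < height) {
      m <- members[[i]]
      r0 <- find(m[[1L]])
      for (v in m[-1L]) parent[find(v)] <- r0
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  groups <- groups[lengths(groups) >= min_size]
  number_modules(unname(groups), hc$labels)
}

#' Adaptive gap-based dendrogram cut
#'
#' A data-driven alternative to a constant-height cut: the dendrogram is
#' recursively split at the largest gap in its sorted merge heights, provided
#' the gap is substantial relative to the dendrogram's top height
#' (`gap_frac`); branches that cannot be split further and hold at least
#' `min_size` leaves are accepted as modules, so every module is a contiguous
#' dendrogram branch. Leaves of rejected branches are left unassigned
#' (module 0).
#'
#' @param hc an [stats::hclust] object
#' @param min_size minimum leaves per module (>= 2)
#' @param gap_frac a split is performed only when the largest height gap
#'   exceeds this fraction of the root height; 0.3 by default
#' @return named integer vector over the dendrogram labels; 0 = unassigned
#' @export
cut_dynamic <- function(hc, min_size = 10L, gap_frac = 0.3) {
  stopifnot(inherits(hc, "hclust"))
  if (min_size < 2L) stop("min_size must be at least 2", call. = FALSE)
  n <- length(hc$labels)
  members <- merge_members(hc)
  root_height <- max(hc$height)
  modules <- list()

  # merge indices contained in the subtree rooted at merge i
  sub_merges <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    sub_merges[[i]] <- c(
      unlist(lapply(hc$merge[i, ], function(v) {
        if (v > 0) sub_merges[[v]] else integer(0)
      }), use.names = FALSE),
      i
    )
  }

  components_below <- function(merges, cut_h) {
    leaves <- members[[max(merges)]]
    parent <- stats::setNames(leaves, leaves)
    find <- function(i) {
      r <- i
      while (parent[[as.character(r)]] != r) r <- parent[[as.character(r)]]
      r
    }
    for (i in merges) {
      if (hc$height[[i]] < cut_h) {
        m <- members[[i]]
        r0 <- find(m[[1L]])
        for (v in m[-1L]) parent[[as.character(find(v))]] <- r0
      }
    }
    comp <- vapply(leaves, find, numeric(1))
    unname(split(leaves, comp))
  }

  recurse <- function(merges) {
    top <- max(merges)
    leaves <- members[[top]]
    if (length(leaves) < min_size) return(invisible(NULL))
    hs <- sort(hc$height[merges])
    if (length(hs) < 2L || (hs[[length(hs)]] - hs[[1L]]) < 1e-12) {
      modules[[length(modules) + 1L]] <<- leaves
      return(invisible(NULL))
    }
    gaps <- diff(hs)
    g <- max(gaps)
    if (g < gap_frac * root_height) {
      modules[[length(modules) + 1L]] <<- leaves
      return(invisible(NULL))
    }
    at <- which.max(gaps)
    cut_h <- (hs[[at]] + hs[[at + 1L]]) / 2
    comps <- components_below(merges, cut_h)
    for (comp in comps) {
      if (length(comp) < min_size) next
      if (length(comp) == 1L) next
      # merge indices fully inside this component
      inside <- merges[vapply(merges, function(i) {
        all(members[[i]] %in% comp)
      }, logical(1))]
      recurse(inside)
    }
    invisible(NULL)
  }

  recurse(sub_merges[[nrow(hc$merge)]])
  number_modules(modules, hc$labels)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Permutation-derived similarity significance threshold
#'
#' Draws `reps` random subsets of `sample_size` items from `pool` without
#' replacement, pools all pairwise similarities returned by `sim_fn`, and
#' returns the requested percentile of that background distribution (the
#' device used to declare observed pairwise similarities significant).
#'
#' @param sim_fn function taking a character vector of pool members and
#'   returning either a symmetric similarity matrix or a numeric vector of
#'   pairwise similarities
#' @param pool character vector to sample from
#' @param sample_size subset size per draw (<= length(pool))
#' @param reps number of random draws (>= 1)
#' @param percentile percentile of the background, in (0, 100)
#' @param seed integer seed; the draw sequence is fully reproducible
#' @return the background value at the requested percentile
#' @export
permutation_threshold <- function(sim_fn, pool, sample_size, reps = 100L,
                                  percentile = 99, seed = 1L) {
  stopifnot(sample_size <= length(pool), reps >= 1L)
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must lie strictly between 0 and 100", call. = FALSE)
  }
  values <- with_seed(seed, {
    unlist(lapply(seq_len(reps), function(r) {
      subset <- sample(pool, sample_size, replace = FALSE)
      v <- sim_fn(subset)
      if (is.matrix(v)) v <- v[lower.tri(v)]
      as.numeric(v)
    }), use.names = FALSE)
  })
  unname(stats::quantile(values, probs = percentile / 100, type = 7))
}

#' Permutation significance of modules
#'
#' For every module, the observed statistic is the mean off-diagonal
#' within-module similarity; the null draws random label subsets of the same
#' size from the matrix and the p-value is the add-one-smoothed fraction of
#' draws at least as similar, `(b + 1) / (reps + 1)` — bounded below by
#' `1 / (reps + 1)`. FDR across modules by Benjamini-Hochberg.
#'
#' @param sim symmetric similarity matrix with labels
#' @param assignment named integer vector as returned by [cut_static()] /
#'   [cut_dynamic()] (0 = unassigned)
#' @param reps permutation draws per module
#' @param seed integer seed
#' @return data.frame with columns module, size, mean_similarity, p_value,
#'   fdr
#' @export
module_significance <- function(sim, assignment, reps = 999L, seed = 1L) {
  labels <- rownames(sim)
  if (!all(names(assignment) %in% labels)) {
    stop("assignment contains labels absent from the similarity matrix",
         call. = FALSE)
  }
  mods <- sort(unique(assignment[assignment > 0L]))
  if (length(mods) == 0L) {
    return(data.frame(module = integer(0), size = integer(0),
                      mean_similarity = numeric(0), p_value = numeric(0),
                      fdr = numeric(0)))
  }
  mean_offdiag <- function(ids) {
    s <- sim[ids, ids, drop = FALSE]
    mean(s[lower.tri(s)])
  }
  rows <- with_seed(seed, {
    lapply(mods, function(m) {
      ids <- names(assignment)[assignment == m]
      obs <- mean_offdiag(ids)
      null <- vapply(seq_len(reps), function(r) {
        mean_offdiag(sample(labels, length(ids), replace = FALSE))
      }, numeric(1))
      data.frame(module = m, size = length(ids), mean_similarity = obs,
                 p_value = (sum(null >= obs) + 1) / (reps + 1))
    })
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out
}

#' Pairs above a similarity threshold
#'
#' Extracts the upper-triangle pairs of a similarity matrix whose similarity
#' strictly exceeds `threshold` — the edge list of the significant-pair
#' network (importable into network viewers).
#'
#' @param sim symmetric similarity matrix with labels
#' @param threshold similarity cutoff (e.g. from [permutation_threshold()])
#' @return data.frame with columns id1, id2, similarity, sorted by
#'   decreasing similarity
#' @export
significant_pairs <- function(sim, threshold) {
  idx <- which(upper.tri(sim) & sim > threshold, arr.ind = TRUE)
  out <- data.frame(
    id1 = rownames(sim)[idx[, 1L]],
    id2 = colnames(sim)[idx[, 2L]],
    similarity = sim[idx],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$similarity, out$id1, out$id2), ]
  rownames(out) <- NULL
  out
}

#' Write a dendrogram as Newick
#'
#' Branch lengths carry the merge heights.
#'
#' @param hc an [stats::hclust] object
#' @param file output path
#' @return `file`, invisibly
#' @export
write_dendrogram_newick <- function(hc, file) {
  ape::write.tree(ape::as.phylo(hc), file)
  invisible(file)
}
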
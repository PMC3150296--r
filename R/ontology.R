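#' Ontology DAG objects
#'
#' An `OntologyDAG` represents a rooted directed acyclic graph of terms
#' connected by "is-a" edges (child points to parent). It is the substrate of
#' every similarity, enrichment and module operation in the package.
#'
#' @details
#' The object is a list with components:
#' \describe{
#'   \item{accession}{character vector of all term accessions (non-obsolete
#'     and obsolete).}
#'   \item{name}{named character vector of human-readable labels.}
#'   \item{parents}{named list; for each non-obsolete term, the character
#'     vector of accessions one "is-a" edge up. Obsolete terms keep no edges.}
#'   \item{children}{named list; inverse of `parents`.}
#'   \item{obsolete}{named logical vector.}
#'   \item{root}{accession of the unique top term. When the source file has
#'     several parentless terms a synthetic root `"SYN:0000000"` is inserted
#'     above them so that every term pair has a common ancestor.}
#'   \item{alt}{named character vector mapping alternate accessions to their
#'     canonical accession.}
#' }
#'
#' @name OntologyDAG
NULL

SYNTHETIC_ROOT <- "SYN:0000000"

new_ontology_dag <- function(accession, name, parents, obsolete, alt = character()) {
  children <- vector("list", length(accession))
  names(children) <- accession
  for (acc in accession) {
    for (p in parents[[acc]]) children[[p]] <- c(children[[p]], acc)
  }
  structure(
    list(
      accession = accession,
      name = name,
      parents = parents,
      children = children,
      obsolete = obsolete,
      root = NA_character_,
      alt = alt
    ),
    class = "OntologyDAG"
  )
}

#' @export
print.OntologyDAG <- function(x, ...) {
  n_obs <- sum(x$obsolete)
  n_edges <- sum(lengths(x$parents))
  cat(sprintf(
    "OntologyDAG: %d terms (%d obsolete), %d is-a edges, root %s (%s)\n",
    length(x$accession), n_obs, n_edges, x$root, x$name[[x$root]]
  ))
  invisible(x)
}

#' Test for OntologyDAG
#' @param x object
#' @return logical
#' @export
is_ontology_dag <- function(x) inherits(x, "OntologyDAG")

#' Active (non-obsolete) terms of a DAG
#' @param dag an [OntologyDAG]
#' @return character vector of accessions
#' @export
active_terms <- function(dag) {
  dag$accession[!dag$obsolete[dag$accession]]
}

resolve_accession <- function(dag, t) {
  if (t %in% names(dag$parents) || (t %in% dag$accession)) return(t)
  if (t %in% names(dag$alt)) return(unname(dag$alt[[t]]))
  stop("unknown accession: ", t, call. = FALSE)
}

check_term <- function(dag, t, allow_obsolete = FALSE) {
  t <- resolve_accession(dag, t)
  if (!allow_obsolete && isTRUE(dag$obsolete[[t]])) {
    stop("term is obsolete: ", t, call. = FALSE)
  }
  t
}

#' Parse an OBO 1.2 flat file into a validated DAG
#'
#' Reads `[Term]` stanzas and retains `id`, `name`, `alt_id`, `is_a` and
#' `is_obsolete` lines. Only "is-a" relationships are kept; any
#' `relationship:` line (part-of, regulates, ...) is ignored with a warning.
#' Obsolete terms are retained in the term table but carry no edges and are
#' excluded from all similarity, enrichment and graph operations. If the file
#' contains several parentless terms, a synthetic root `"SYN:0000000"` is
#' inserted above them (reported via [message()]); it is never annotated
#' directly, so information content at the root stays zero.
#'
#' @param file path to an OBO file, or a character vector of lines via `text`
#' @param text optional character scalar/vector with OBO content (overrides
#'   `file`)
#' @return an [OntologyDAG]
#' @examples
#' obo <- c("[Term]", "id: X:1", "name: root",
#'          "[Term]", "id: X:2", "name: child", "is_a: X:1 ! root")
#' dag <- parse_obo(text = obo)
#' @export
parse_obo <- function(file = NULL, text = NULL) {
  if (!is.null(text)) {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    if (is.null(file)) stop("either `file` or `text` is required", call. = FALSE)
    lines <- readLines(file, warn = FALSE, encoding = "UTF-8")
  }
  lines <- sub("\\s+$", "", lines)

  # split into stanzas
  starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) stop("no [Term] stanza found", call. = FALSE)

  acc <- character(0)
  nm <- character(0)
  par_list <- list()
  obs <- logical(0)
  alt <- character(0)
  other_rel <- 0L

  bounds <- c(starts, length(lines) + 1L)
  for (s in term_starts) {
    e <- bounds[which(bounds == s) + 1L] - 1L
    body <- lines[(s + 1L):e]
    get1 <- function(tag) {
      hit <- grep(paste0("^", tag, ": ?"), body, value = TRUE)
      if (length(hit) == 0L) return(NA_character_)
      sub(paste0("^", tag, ": ?"), "", hit[[1L]])
    }
    id <- get1("id")
    if (is.na(id) || !nzchar(id)) stop("[Term] stanza without id", call. = FALSE)
    if (id %in% acc) stop("duplicate accession: ", id, call. = FALSE)
    name <- get1("name")
    if (is.na(name)) name <- id
    is_obs <- identical(get1("is_obsolete"), "true")
    isa_lines <- grep("^is_a: ?", body, value = TRUE)
    targets <- sub("^is_a: ?", "", isa_lines)
    targets <- sub("\\s*!.*$", "", targets)          # strip trailing comment
    targets <- sub("\\s*\\{.*\\}\\s*$", "", targets) # strip trailer
    alt_ids <- sub("^alt_id: ?", "", grep("^alt_id: ?", body, value = TRUE))
    other_rel <- other_rel + length(grep("^relationship:", body))

    acc <- c(acc, id)
    nm[id] <- name
    par_list[[id]] <- if (is_obs) character(0) else unique(targets)
    obs[id] <- is_obs
    if (length(alt_ids)) alt[alt_ids] <- id
  }
  if (other_rel > 0L) {
    warning(other_rel, " non is-a relationship line(s) ignored", call. = FALSE)
  }

  # dangling parents
  for (id in acc) {
    missing <- setdiff(par_list[[id]], acc)
    if (length(missing)) {
      stop("is_a target not defined in file: ", missing[[1L]], call. = FALSE)
    }
    # edges into obsolete parents are dropped
    par_list[[id]] <- par_list[[id]][!obs[par_list[[id]]]]
  }

  dag <- new_ontology_dag(acc, nm, par_list, obs, alt)
  dag <- normalize_root(dag)
  validate_dag(dag)
  dag
}

normalize_root <- function(dag) {
  act <- dag$accession[!dag$obsolete[dag$accession]]
  parentless <- act[lengths(dag$parents[act]) == 0L]
  if (length(parentless) == 0L) {
    stop("cycle detected: no parentless term exists", call. = FALSE)
  }
  if (length(parentless) == 1L) {
    dag$root <- parentless
    return(dag)
  }
  message(
    "multiple parentless terms (", length(parentless),
    "); inserting synthetic root ", SYNTHETIC_ROOT
  )
  dag$accession <- c(dag$accession, SYNTHETIC_ROOT)
  dag$name[SYNTHETIC_ROOT] <- "synthetic root"
  dag$obsolete[SYNTHETIC_ROOT] <- FALSE
  dag$parents[[SYNTHETIC_ROOT]] <- character(0)
  dag$children[[SYNTHETIC_ROOT]] <- parentless
  for (p in parentless) dag$parents[[p]] <- SYNTHETIC_ROOT
  dag$root <- SYNTHETIC_ROOT
  dag
}

validate_dag <- function(dag) {
  act <- active_terms(dag)
  # Kahn topological sort over child -> parent edges; leftover nodes lie on a cycle
  out_deg <- lengths(dag$parents[act])  # edges toward parents
  names(out_deg) <- act
  queue <- act[out_deg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (c in dag$children[[v]]) {
      out_deg[[c]] <- out_deg[[c]] - 1L
      if (out_deg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (seen != length(act)) {
    bad <- names(out_deg)[out_deg > 0L][[1L]]
    stop(
      "cycle detected involving edge ", bad, " -> ", dag$parents[[bad]][[1L]],
      call. = FALSE
    )
  }
  # reachability from root
  reach <- descendants(dag, dag$root, include_self = TRUE)
  unreachable <- setdiff(act, reach)
  if (length(unreachable)) {
    stop("term does not reach root: ", unreachable[[1L]], call. = FALSE)
  }
  invisible(dag)
}

#' Serialize an OntologyDAG back to OBO 1.2 text
#'
#' @param dag an [OntologyDAG]
#' @param file optional path; when `NULL` the lines are returned invisibly
#' @return character vector of OBO lines (invisibly when written to file)
#' @export
write_obo <- function(dag, file = NULL) {
  out <- c("format-version: 1.2", "")
  for (acc in dag$accession) {
    out <- c(out, "[Term]", paste0("id: ", acc), paste0("name: ", dag$name[[acc]]))
    if (isTRUE(dag$obsolete[[acc]])) {
      out <- c(out, "is_obsolete: true")
    } else {
      for (p in dag$parents[[acc]]) {
        out <- c(out, paste0("is_a: ", p, " ! ", dag$name[[p]]))
      }
    }
    out <- c(out, "")
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

closure <- function(adj, start, include_self) {
  seen <- character(0)
  frontier <- adj[[start]]
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
    frontier <- unlist(adj[frontier], use.names = FALSE)
  }
  if (include_self) unique(c(start, seen)) else setdiff(seen, start)
}

#' Ancestors of a term
#'
#' Transitive closure over "is-a" parent edges.
#'
#' @param dag an [OntologyDAG]
#' @param t term accession
#' @param include_self whether `t` itself is a member (the convention used by
#'   every similarity measure here is that a term is an ancestor of itself)
#' @return character vector of accessions
#' @export
ancestors <- function(dag, t, include_self = TRUE) {
  t <- check_term(dag, t)
  closure(dag$parents, t, include_self)
}

#' Descendants of a term
#'
#' @inheritParams ancestors
#' @return character vector of accessions
#' @export
descendants <- function(dag, t, include_self = TRUE) {
  t <- check_term(dag, t)
  closure(dag$children, t, include_self)
}

#' Depth of a term
#'
#' Minimum number of edges on a path from the root; `term_depth(dag, root)`
#' is 0.
#'
#' @inheritParams ancestors
#' @return non-negative integer
#' @export
term_depth <- function(dag, t) {
  t <- check_term(dag, t)
  unname(all_depths(dag)[t])
}

all_depths <- function(dag) {
  act <- active_terms(dag)
  d <- rep(NA_integer_, length(act))
  names(d) <- act
  d[dag$root] <- 0L
  frontier <- dag$root
  lev <- 0L
  while (length(frontier)) {
    lev <- lev + 1L
    nxt <- unique(unlist(dag$children[frontier], use.names = FALSE))
    nxt <- nxt[is.na(d[nxt])]
    d[nxt] <- lev
    frontier <- nxt
  }
  if (anyNA(d)) stop("term not reachable from root: ",
                     names(d)[is.na(d)][[1L]], call. = FALSE)
  d
}

#' Induced ancestor subgraph
#'
#' Extracts the sub-DAG spanned by a set of terms and all of their ancestors
#' (the usual way to visualise where a set of terms sits in the ontology; the
#' given terms become the sinks of the subgraph unless they are ancestors of
#' one another).
#'
#' @param dag an [OntologyDAG]
#' @param leaves character vector of term accessions (non-empty)
#' @return an [OntologyDAG] restricted to the ancestor closure of `leaves`
#' @export
induced_graph <- function(dag, leaves) {
  if (length(leaves) == 0L) stop("leaf set must not be empty", call. = FALSE)
  leaves <- vapply(leaves, check_term, character(1), dag = dag)
  keep <- unique(unlist(
    lapply(leaves, ancestors, dag = dag, include_self = TRUE),
    use.names = FALSE
  ))
  keep <- dag$accession[dag$accession %in% keep]  # original order
  par_list <- lapply(keep, function(a) intersect(dag$parents[[a]], keep))
  names(par_list) <- keep
  sub <- new_ontology_dag(
    keep, dag$name[keep], par_list,
    stats::setNames(rep(FALSE, length(keep)), keep)
  )
  sub$root <- dag$root
  sub
}

#' One-step related terms
#'
#' @param dag an [OntologyDAG]
#' @param t term accession
#' @param relation one of `"parents"`, `"children"`, `"siblings"`; siblings
#'   are terms sharing at least one parent with `t`, excluding `t`
#' @return character vector of accessions
#' @export
related_terms <- function(dag, t, relation = c("parents", "children", "siblings")) {
  relation <- match.arg(relation)
  t <- check_term(dag, t)
  switch(relation,
    parents = dag$parents[[t]],
    children = if (is.null(dag$children[[t]])) character(0) else dag$children[[t]],
    siblings = {
      sib <- unlist(dag$children[dag$parents[[t]]], use.names = FALSE)
      setdiff(unique(sib), t)
    }
  )
}

#' Convert a DAG to an igraph object
#'
#' Edges are directed child -> parent; the `name` vertex attribute carries the
#' term label.
#'
#' @param dag an [OntologyDAG]
#' @return an [igraph::igraph] object
#' @export
as_igraph <- function(dag) {
  act <- active_terms(dag)
  edges <- do.call(rbind, lapply(act, function(a) {
    ps <- dag$parents[[a]]
    if (!length(ps)) return(NULL)
    cbind(a, ps)
  }))
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(act), name = act,
                            label = unname(dag$name[act]))
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  g
}

#' Export a DAG for external viewers
#'
#' Writes GraphML or Graphviz DOT via igraph, or a two-column child/parent
#' edge-list TSV.
#'
#' @param dag an [OntologyDAG]
#' @param file output path
#' @param format one of `"graphml"`, `"dot"`, `"edgelist"`
#' @return `file`, invisibly
#' @export
write_dag <- function(dag, file, format = c("graphml", "dot", "edgelist")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    act <- active_terms(dag)
    rows <- unlist(lapply(act, function(a) {
      vapply(dag$parents[[a]], function(p) paste(a, p, sep = "\t"), character(1))
    }), use.names = FALSE)
    writeLines(c("child\tparent", rows), file)
  } else {
    igraph::write_graph(as_igraph(dag), file, format = format)
  }
  invisible(file)
}
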
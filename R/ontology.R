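# OBO parsing and the GO DAG.
#
# The graph keeps only is_a and part_of edges; every other relationship type
# (regulates, occurs_in, ...) is dropped at parse time.  Terms live in one of
# the three GO namespaces and every per-measure computation downstream is
# namespace-local; cross-namespace parentage is a hard error.

GO_NAMESPACES <- c("biological_process", "molecular_function",
                   "cellular_component")

#' Parse an ontology in OBO 1.2 format
#'
#' Reads `[Term]` stanzas and builds a directed acyclic graph over the
#' `is_a` and `part_of` relations.  Obsolete terms are discarded entirely
#' (their ids are not resolvable unless listed as `alt_id` of a live term).
#' Term levels are computed as the length of the longest path to the
#' namespace root (root level 0).
#'
#' @param obo a file path, a single string, or a character vector of lines.
#' @param strict if `TRUE`, anomalies that would otherwise be logged and
#'   skipped (e.g. a parent reference to an unknown term) become hard errors.
#' @return an object of class `go_ontology` with fields `ids`, `name`,
#'   `namespace`, `parents`/`parent_rel`, `children`/`child_rel`, `levels`,
#'   `roots` (one per namespace), `alt` (alt_id to primary id map), `index`
#'   and `topo` (a parents-before-children ordering).
#' @export
parse_obo <- function(obo, strict = FALSE) {
  lines <- trimws(.gf_read_lines(obo))
  if (!any(nzchar(lines))) gf_error("empty OBO input", "gf_parse_error")

  hdr <- grepl("^\\[.+\\]$", lines)
  stanza <- cumsum(hdr)

  default_ns <- NULL
  head_lines <- lines[stanza == 0L]
  dn <- grep("^default-namespace:", head_lines, value = TRUE)
  if (length(dn)) default_ns <- trimws(sub("^default-namespace:", "", dn[1L]))

  term_stanzas <- stanza[hdr][lines[hdr] == "[Term]"]
  if (!length(term_stanzas)) gf_error("no [Term] stanzas found", "gf_parse_error")

  recs <- vector("list", length(term_stanzas))
  for (i in seq_along(term_stanzas)) {
    body <- lines[stanza == term_stanzas[i] & !hdr]
    body <- body[nzchar(body)]
    key <- sub(":.*$", "", body)
    val <- trimws(sub("^[^:]+:", "", body))
    val <- sub("\\s+!\\s.*$", "", val)  # trailing "! comment"
    get1 <- function(k) {
      v <- val[key == k]
      if (length(v)) v[1L] else NA_character_
    }
    rel <- strsplit(val[key == "relationship"], "\\s+")
    part_of <- vapply(Filter(function(z) length(z) >= 2L && z[1L] == "part_of", rel),
                      `[`, character(1L), 2L)
    recs[[i]] <- list(
      id = get1("id"),
      name = get1("name") %||% "",
      namespace = get1("namespace") %||% default_ns,
      is_a = val[key == "is_a"],
      part_of = part_of,
      alt_id = val[key == "alt_id"],
      obsolete = identical(get1("is_obsolete"), "true")
    )
  }

  ids <- vapply(recs, function(r) r$id %||% NA_character_, character(1L))
  if (anyNA(ids)) gf_error("[Term] stanza without an id", "gf_parse_error")
  if (anyDuplicated(ids)) {
    gf_error(paste("duplicate term id:", ids[duplicated(ids)][1L]), "gf_parse_error")
  }
  bad_id <- !grepl("^GO:\\d{7}$", ids)
  if (any(bad_id)) {
    gf_error(paste("malformed term id:", ids[bad_id][1L]), "gf_parse_error")
  }

  obsolete <- vapply(recs, `[[`, logical(1L), "obsolete")
  recs <- recs[!obsolete]
  ids <- ids[!obsolete]
  if (!length(recs)) gf_error("no non-obsolete terms in OBO input", "gf_parse_error")

  ns <- vapply(recs, function(r) r$namespace %||% NA_character_, character(1L))
  if (anyNA(ns)) {
    gf_error("term without a namespace and no default-namespace header",
             "gf_parse_error")
  }

  # alt_id -> primary id
  alt <- character(0L)
  for (r in recs) {
    if (length(r$alt_id)) {
      dup <- intersect(r$alt_id, names(alt))
      clash <- dup[alt[dup] != r$id]
      if (length(clash)) {
        gf_error(paste("alt_id maps to multiple terms:", clash[1L]), "gf_parse_error")
      }
      alt[r$alt_id] <- r$id
    }
  }
  alt <- alt[!(names(alt) %in% ids)]

  n <- length(ids)
  index <- stats::setNames(seq_len(n), ids)
  parents <- vector("list", n)
  parent_rel <- vector("list", n)
  n_dropped_edges <- 0L
  for (i in seq_len(n)) {
    pid <- c(recs[[i]]$is_a, recs[[i]]$part_of)
    rels <- c(rep("is_a", length(recs[[i]]$is_a)),
              rep("part_of", length(recs[[i]]$part_of)))
    # resolve parent references through alt ids, then drop unknown targets
    hit <- match(pid, names(alt))
    pid[!is.na(hit)] <- alt[hit[!is.na(hit)]]
    known <- pid %in% ids
    if (any(!known)) {
      if (strict) {
        gf_error(paste0("term ", ids[i], " has unknown parent ", pid[!known][1L]),
                 "gf_parse_error")
      }
      n_dropped_edges <- n_dropped_edges + sum(!known)
      rels <- rels[known]
      pid <- pid[known]
    }
    pidx <- unname(index[pid])
    cross <- ns[pidx] != ns[i]
    if (any(cross)) {
      gf_error(sprintf("term %s (%s) has parent %s in namespace %s",
                       ids[i], ns[i], pid[cross][1L], ns[pidx][cross][1L]),
               "gf_parse_error")
    }
    keep <- !duplicated(paste(pidx, rels))
    parents[[i]] <- pidx[keep]
    parent_rel[[i]] <- rels[keep]
  }
  if (n_dropped_edges > 0L) {
    message("parse_obo: dropped ", n_dropped_edges,
            " parent reference(s) to unknown terms")
  }

  children <- rep(list(integer(0L)), n)
  child_rel <- rep(list(character(0L)), n)
  for (i in seq_len(n)) {
    for (j in seq_along(parents[[i]])) {
      p <- parents[[i]][j]
      children[[p]] <- c(children[[p]], i)
      child_rel[[p]] <- c(child_rel[[p]], parent_rel[[i]][j])
    }
  }

  # Kahn topological sort over child -> parent edges; roots come first.
  remaining <- lengths(parents)
  topo <- integer(n)
  queue <- which(remaining == 0L)
  head <- 1L
  count <- 0L
  while (head <= length(queue)) {
    v <- queue[head]
    head <- head + 1L
    count <- count + 1L
    topo[count] <- v
    for (ch in children[[v]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (count < n) {
    unproc <- setdiff(seq_len(n), topo[seq_len(count)])
    u <- unproc[1L]
    seen <- integer(0L)
    repeat {
      seen <- c(seen, u)
      p <- intersect(parents[[u]], unproc)[1L]
      if (p %in% seen) {
        gf_error(sprintf("cycle detected in ontology; edge %s -> %s lies on it",
                         ids[u], ids[p]), "gf_parse_error")
      }
      u <- p
    }
  }

  root_idx <- which(lengths(parents) == 0L)
  roots <- character(0L)
  for (nsi in unique(ns)) {
    r <- root_idx[ns[root_idx] == nsi]
    if (length(r) != 1L) {
      gf_error(sprintf("namespace %s has %d parentless terms (expected 1 root)",
                       nsi, length(r)), "gf_parse_error")
    }
    roots[nsi] <- ids[r]
  }

  levels <- integer(n)
  for (v in topo) {
    levels[v] <- if (!length(parents[[v]])) 0L else 1L + max(levels[parents[[v]]])
  }

  structure(list(
    ids = ids, name = vapply(recs, `[[`, character(1L), "name"),
    namespace = ns, parents = parents, parent_rel = parent_rel,
    children = children, child_rel = child_rel, levels = levels,
    roots = roots, alt = alt, index = index, topo = topo, n = n,
    cache = new.env(parent = emptyenv())
  ), class = "go_ontology")
}

#' @export
print.go_ontology <- function(x, ...) {
  cat("go_ontology:", x$n, "terms in",
      length(x$roots), "namespace(s)\n")
  for (nsi in names(x$roots)) {
    cat("  ", nsi, ": root ", x$roots[[nsi]],
        " (", sum(x$namespace == nsi), " terms)\n", sep = "")
  }
  invisible(x)
}

# primary-id resolution (alt_id transparent); returns integer index
.term_index <- function(graph, term) {
  i <- graph$index[term]
  if (!is.na(i)) return(unname(i))
  primary <- graph$alt[term]
  if (!is.na(primary)) return(unname(graph$index[primary]))
  gf_error(paste("unknown GO id:", term), "gf_lookup_error")
}

#' Resolve a GO id to its primary id
#'
#' `alt_id`s are mapped transparently to the primary id.
#' @param graph a `go_ontology`.
#' @param term a GO accession.
#' @export
resolve_term <- function(graph, term) {
  graph$ids[.term_index(graph, term)]
}

#' Term accessors
#'
#' `term_level` is the longest-path distance to the namespace root,
#' `term_name` the term's label and `term_namespace` its GO namespace.
#' @param graph a `go_ontology`.
#' @param term a GO accession (alt_ids allowed).
#' @export
term_level <- function(graph, term) graph$levels[.term_index(graph, term)]

#' @rdname term_level
#' @export
term_name <- function(graph, term) graph$name[.term_index(graph, term)]

#' @rdname term_level
#' @export
term_namespace <- function(graph, term) graph$namespace[.term_index(graph, term)]

# inclusive ancestor index sets for every term, parents-before-children DP
.ancestor_sets <- function(graph) {
  if (!is.null(graph$cache$anc)) return(graph$cache$anc)
  anc <- vector("list", graph$n)
  for (v in graph$topo) {
    anc[[v]] <- unique(c(v, unlist(anc[graph$parents[[v]]], use.names = FALSE)))
  }
  graph$cache$anc <- anc
  anc
}

#' Ancestors of a term
#'
#' All terms reachable by following `is_a`/`part_of` edges upward.
#' @param graph a `go_ontology`.
#' @param term a GO accession.
#' @param inclusive include the term itself?
#' @return a sorted character vector of GO ids.
#' @export
go_ancestors <- function(graph, term, inclusive = FALSE) {
  i <- .term_index(graph, term)
  a <- .ancestor_sets(graph)[[i]]
  if (!inclusive) a <- setdiff(a, i)
  sort(graph$ids[a])
}

#' Common ancestors of two terms
#'
#' Intersection of the two inclusive ancestor sets.  Both terms must lie in
#' the same namespace.
#' @param graph a `go_ontology`.
#' @param t1,t2 GO accessions.
#' @return a sorted character vector of GO ids.
#' @export
go_common_ancestors <- function(graph, t1, t2) {
  i <- .term_index(graph, t1)
  j <- .term_index(graph, t2)
  if (graph$namespace[i] != graph$namespace[j]) {
    gf_error(sprintf("terms %s (%s) and %s (%s) are in different namespaces",
                     graph$ids[i], graph$namespace[i],
                     graph$ids[j], graph$namespace[j]),
             "gf_namespace_error")
  }
  a <- .ancestor_sets(graph)
  sort(graph$ids[intersect(a[[i]], a[[j]])])
}
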
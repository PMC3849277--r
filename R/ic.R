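# Term information content.
#
# Four models, all in natural-log units, all zero at the namespace root:
#  * annotation:  IC(t) = -ln p(t), p(t) the corpus usage probability;
#  * zhang:       descendant-leaf counting, IC(t) = -ln(D(t)/D(root)) with
#                 D = 1 at leaves and the sum over children elsewhere;
#  * universal:   topological position A(root) = 1,
#                 A(t) = prod over parents p of A(p)/|children(p)|,
#                 IC(t) = -ln A(t);
#  * the semantic-contribution propagation (S-values) used by the Wang
#    approach, which is anchored per term rather than tabulated.

.new_ic <- function(model, namespace, values, prob = NULL) {
  structure(list(
    model = model, namespace = namespace, values = values,
    ic_max = if (length(values)) max(values) else 0, prob = prob
  ), class = "go_ic")
}

#' @export
print.go_ic <- function(x, ...) {
  cat("go_ic: model", x$model, "/", x$namespace, "-", length(x$values),
      "terms, ic_max", format(x$ic_max, digits = 6), "\n")
  invisible(x)
}

#' Annotation (corpus-frequency) information content
#'
#' `IC(t) = -ln p(t)` for every term used in the corpus; terms absent from
#' the corpus have no annotation IC and queries touching them fail rather
#' than imputing a value.
#'
#' @param usage a `go_usage` from [term_usage()].
#' @return a `go_ic` with `model = "annotation"`.
#' @export
annotation_ic <- function(usage) {
  p <- usage$probabilities
  if (!length(p)) gf_error("empty term usage", "gf_parameter_error")
  if (any(p <= 0 | p > 1)) {
    gf_error("usage probabilities outside (0, 1]", "gf_parameter_error")
  }
  values <- -log(p)
  values[values <= 0] <- 0
  .new_ic("annotation", usage$namespace, values, prob = p)
}

#' Descendant-leaf-count (Zhang-style) information content
#'
#' Bottom-up D-value: `D = 1` at leaves, the sum over children elsewhere;
#' `IC(t) = -ln(D(t)/D(root))`.  Defined for every term of the namespace.
#'
#' @param graph a `go_ontology`.
#' @param namespace one of the GO namespaces present in `graph`.
#' @return a `go_ic` with `model = "zhang"`.
#' @export
zhang_ic <- function(graph, namespace) {
  key <- paste0("zhang_", namespace)
  if (!is.null(graph$cache[[key]])) return(graph$cache[[key]])
  in_ns <- graph$namespace == namespace
  if (!any(in_ns)) {
    gf_error(paste("namespace not present in ontology:", namespace),
             "gf_parameter_error")
  }
  D <- numeric(graph$n)
  for (v in rev(graph$topo)) {
    if (!in_ns[v]) next
    ch <- graph$children[[v]]
    D[v] <- if (!length(ch)) 1 else sum(D[ch])
  }
  root <- unname(graph$index[graph$roots[[namespace]]])
  idx <- which(in_ns)
  values <- stats::setNames(-log(D[idx] / D[root]), graph$ids[idx])
  values[values <= 0] <- 0
  out <- .new_ic("zhang", namespace, values)
  graph$cache[[key]] <- out
  out
}

#' Topological-position (GO-universal) information content
#'
#' `A(root) = 1`; `A(t)` is the product over parents `p` of
#' `A(p)/|children(p)|`; `IC(t) = -ln A(t)`, computed in topological order.
#'
#' @inheritParams zhang_ic
#' @return a `go_ic` with `model = "universal"`.
#' @export
universal_ic <- function(graph, namespace) {
  key <- paste0("universal_", namespace)
  if (!is.null(graph$cache[[key]])) return(graph$cache[[key]])
  in_ns <- graph$namespace == namespace
  if (!any(in_ns)) {
    gf_error(paste("namespace not present in ontology:", namespace),
             "gf_parameter_error")
  }
  A <- numeric(graph$n)
  nchild <- lengths(graph$children)
  for (v in graph$topo) {
    if (!in_ns[v]) next
    ps <- graph$parents[[v]]
    A[v] <- if (!length(ps)) 1 else prod(A[ps] / nchild[ps])
  }
  idx <- which(in_ns)
  values <- stats::setNames(-log(A[idx]), graph$ids[idx])
  values[values <= 0] <- 0
  out <- .new_ic("universal", namespace, values)
  graph$cache[[key]] <- out
  out
}

#' Semantic contribution values (S-values) anchored at a term
#'
#' The anchor contributes 1 to itself; every ancestor `a` receives
#' `max over children c of a within the anchor's ancestor graph of
#' w(c -> a) * S(c)`, with edge weights `w_is_a` and `w_part_of`.
#'
#' @param graph a `go_ontology`.
#' @param term anchor GO accession.
#' @param w_is_a,w_part_of semantic contribution factors in (0, 1);
#'   defaults 0.8 and 0.6.
#' @return an object of class `go_wang` with `anchor`, `svalues` (named over
#'   the inclusive ancestor set) and `sv_total`.
#' @export
wang_svalues <- function(graph, term, w_is_a = 0.8, w_part_of = 0.6) {
  if (w_is_a <= 0 || w_is_a >= 1 || w_part_of <= 0 || w_part_of >= 1) {
    gf_error("semantic contribution factors must lie in (0, 1)",
             "gf_parameter_error")
  }
  i <- .term_index(graph, term)
  ancset <- .ancestor_sets(graph)[[i]]
  in_anc <- logical(graph$n)
  in_anc[ancset] <- TRUE
  w <- c(is_a = w_is_a, part_of = w_part_of)
  S <- numeric(graph$n)
  S[i] <- 1
  # children-before-parents within the ancestor-induced subgraph
  for (v in rev(graph$topo)) {
    if (!in_anc[v] || v == i) next
    ch <- graph$children[[v]]
    rel <- graph$child_rel[[v]]
    sel <- in_anc[ch]
    S[v] <- max(w[rel[sel]] * S[ch[sel]])
  }
  svalues <- stats::setNames(S[ancset], graph$ids[ancset])
  structure(list(anchor = graph$ids[i], svalues = svalues,
                 sv_total = sum(svalues)), class = "go_wang")
}

#' Uniformized (normalized) information content
#'
#' `u(t) = IC(t) / ic_max`, mapping the namespace to `[0, 1]`.
#' @param ic a `go_ic`.
#' @return named numeric vector.
#' @export
uniformized_ic <- function(ic) {
  if (ic$ic_max <= 0) gf_error("ic_max is zero; cannot uniformize",
                               "gf_parameter_error")
  ic$values / ic$ic_max
}

#' Export / import an IC table as 3-column TSV
#'
#' Columns `term_id`, `model`, `ic`; values written with 12 significant
#' digits so a round trip is stable at that precision.
#' @param ic a `go_ic`.
#' @param path file path.
#' @export
write_ic_tsv <- function(ic, path) {
  df <- data.frame(term_id = names(ic$values), model = ic$model,
                   ic = sprintf("%.15g", ic$values),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ic_tsv
#' @param namespace namespace recorded on the reconstructed table.
#' @export
read_ic_tsv <- function(path, namespace = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "model", "ic") %in% names(df))) {
    gf_error("IC TSV must have columns term_id, model, ic", "gf_parse_error")
  }
  model <- unique(df$model)
  if (length(model) != 1L) {
    gf_error("IC TSV mixes several models", "gf_parse_error")
  }
  values <- stats::setNames(as.numeric(df$ic), df$term_id)
  prob <- if (model == "annotation") exp(-values) else NULL
  .new_ic(model, namespace, values, prob = prob)
}

# Topology ICs can be derived (and cached) from the graph on demand;
# annotation IC must be supplied explicitly.
.get_ic <- function(graph, model, namespace, ic = NULL) {
  if (!is.null(ic)) {
    if (ic$model != model) {
      gf_error(sprintf("approach requires %s IC but got a %s table",
                       model, ic$model), "gf_parameter_error")
    }
    return(ic)
  }
  switch(model,
    zhang = zhang_ic(graph, namespace),
    universal = universal_ic(graph, namespace),
    gf_error(paste("an annotation IC table must be supplied for model", model),
             "gf_parameter_error")
  )
}
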
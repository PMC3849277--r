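# Protein-to-protein functional similarity.
#
# Two routes: combiners (avg, max, bma, abm) over a term-similarity matrix
# between the two proteins' direct term sets, and direct closure-overlap
# measures (simgic, simdic, simuic, simui) weighting annotation closures by
# IC.  The canonical registry enumerates the 27 named configurations.

DIRECT_MEASURES <- c("simgic", "simdic", "simuic", "simui")
COMBINERS <- c("avg", "max", "bma", "abm")

#' Combine a term-similarity matrix into one protein-pair score
#'
#' \describe{
#'   \item{avg}{mean of all `n * m` entries.}
#'   \item{max}{maximum entry.}
#'   \item{abm}{average best matches: pooled row and column maxima divided
#'     by `n + m`.}
#'   \item{bma}{best-match average: mean of the two directional best-match
#'     averages.}
#' }
#' `abm` and `bma` coincide exactly when `n = m`.
#'
#' @param mat an `n x m` numeric matrix of term similarities.
#' @param combiner one of `"avg"`, `"max"`, `"bma"`, `"abm"`.
#' @return a numeric score.
#' @export
combine_scores <- function(mat, combiner = c("avg", "max", "bma", "abm")) {
  combiner <- match.arg(combiner)
  mat <- as.matrix(mat)
  if (length(mat) == 0L) {
    gf_error("empty term-similarity matrix", "gf_parameter_error")
  }
  row_max <- apply(mat, 1L, max)
  col_max <- apply(mat, 2L, max)
  switch(combiner,
    avg = mean(mat),
    max = max(mat),
    abm = (sum(row_max) + sum(col_max)) / (nrow(mat) + ncol(mat)),
    bma = (mean(row_max) + mean(col_max)) / 2
  )
}

#' Direct closure-overlap similarity
#'
#' Weighted set-overlap measures over two annotation closures:
#' `simgic` (Jaccard, IC-weighted), `simdic` (Dice, IC-weighted),
#' `simuic` (universal index, IC-weighted) and `simui`
#' (unweighted Jaccard; needs no IC).
#'
#' @param measure one of `DIRECT_MEASURES`.
#' @param ic a `go_ic` defined on all closure terms (ignored for `simui`).
#' @param closure_p,closure_q character vectors of GO ids (closures).
#' @return a numeric score in `[0, 1]`.
#' @export
direct_similarity <- function(measure, ic, closure_p, closure_q) {
  measure <- match.arg(measure, DIRECT_MEASURES)
  if (!length(closure_p) || !length(closure_q)) {
    gf_error("empty annotation closure", "gf_parameter_error")
  }
  inter <- intersect(closure_p, closure_q)
  if (measure == "simui") {
    return(length(inter) / length(union(closure_p, closure_q)))
  }
  if (is.null(ic)) {
    gf_error("IC-weighted direct measures require an IC table",
             "gf_parameter_error")
  }
  terms <- union(closure_p, closure_q)
  vals <- ic$values[terms]
  if (anyNA(vals)) {
    gf_error(paste("term unused in corpus (no IC):",
                   terms[is.na(vals)][1L]), "gf_lookup_error")
  }
  sp <- sum(ic$values[closure_p])
  sq <- sum(ic$values[closure_q])
  if (sp + sq <= 0) {
    gf_error("both closures carry zero total IC; similarity undefined",
             "gf_parameter_error")
  }
  si <- sum(ic$values[inter])
  switch(measure,
    simgic = si / sum(vals),
    simdic = 2 * si / (sp + sq),
    simuic = si / max(sp, sq)
  )
}

#' The canonical registry of 27 functional-similarity configurations
#'
#' Three IC-weighted direct measures on the annotation IC row, the five
#' annotation-family term approaches crossed with the four combiners, the
#' unweighted union-intersection measure, and the three topology approaches
#' bound to their published combiner (descendant-leaf-count and
#' semantic-contribution approaches with average best matches, the
#' topological-position approach with best-match average).
#'
#' @return a data.frame with columns `family`, `approach`, `combiner`
#'   (`NA` for direct measures) and a unique `label`.
#' @export
measure_registry <- function() {
  rows <- list(
    list("annotation", "simgic", NA_character_),
    list("annotation", "simdic", NA_character_),
    list("annotation", "simuic", NA_character_)
  )
  for (app in c("xgrasm", "resnik", "lin", "li", "relevance")) {
    for (comb in c("bma", "abm", "avg", "max")) {
      rows[[length(rows) + 1L]] <- list("annotation", app, comb)
    }
  }
  rows <- c(rows, list(
    list("topology", "simui", NA_character_),
    list("topology", "zhang", "abm"),
    list("topology", "wang", "abm"),
    list("topology", "universal", "bma")
  ))
  df <- data.frame(
    family = vapply(rows, `[[`, character(1L), 1L),
    approach = vapply(rows, `[[`, character(1L), 2L),
    combiner = vapply(rows, `[[`, character(1L), 3L),
    stringsAsFactors = FALSE
  )
  df$label <- ifelse(is.na(df$combiner), df$approach,
                     paste(df$approach, df$combiner, sep = "-"))
  df
}

# Accepts a registry label ("lin-bma", "simgic", ...) or a list with
# approach/combiner fields; returns list(family, approach, combiner).
.resolve_measure <- function(measure) {
  reg <- measure_registry()
  if (is.character(measure) && length(measure) == 1L) {
    hit <- reg[reg$label == measure, ]
    if (nrow(hit) == 1L) {
      return(list(family = hit$family, approach = hit$approach,
                  combiner = if (is.na(hit$combiner)) NULL else hit$combiner))
    }
    # off-registry but valid approach/combiner combinations are permitted
    parts <- strsplit(measure, "-", fixed = TRUE)[[1L]]
    if (length(parts) == 2L && parts[1L] %in% TERM_SIM_APPROACHES &&
        parts[2L] %in% COMBINERS) {
      fam <- if (parts[1L] %in% .ANNOTATION_APPROACHES) "annotation" else "topology"
      return(list(family = fam, approach = parts[1L], combiner = parts[2L]))
    }
    gf_error(paste("unknown measure label:", measure), "gf_parameter_error")
  }
  if (is.list(measure) && !is.null(measure$approach)) {
    comb <- measure$combiner
    if (!is.null(comb) && is.na(comb)) comb <- NULL
    app <- measure$approach
    if (app %in% DIRECT_MEASURES) {
      if (!is.null(comb)) {
        gf_error("direct measures take no combiner", "gf_parameter_error")
      }
    } else {
      if (!(app %in% TERM_SIM_APPROACHES)) {
        gf_error(paste("unknown approach:", app), "gf_parameter_error")
      }
      if (is.null(comb) || !(comb %in% COMBINERS)) {
        gf_error("a combiner (avg/max/bma/abm) is required", "gf_parameter_error")
      }
    }
    fam <- measure$family %||%
      if (app %in% c(.ANNOTATION_APPROACHES, "simgic", "simdic", "simuic"))
        "annotation" else "topology"
    return(list(family = fam, approach = app, combiner = comb))
  }
  gf_error("cannot interpret measure specification", "gf_parameter_error")
}

#' Protein functional similarity
#'
#' Dispatches to [combine_scores()] over pairwise term similarities of the
#' two proteins' direct term sets, or to [direct_similarity()] on their
#' annotation closures.  A protein with no annotation in the namespace
#' yields `NA` (missing annotation is not dissimilarity).
#'
#' @param graph a `go_ontology`.
#' @param corpus a `go_corpus`.
#' @param p,q protein accessions or gene symbols.
#' @param measure a registry label (see [measure_registry()]) or a list with
#'   `approach` and `combiner`.
#' @param ic IC table for annotation-family measures (and optionally for
#'   direct measures under a topology IC); topology term approaches derive
#'   theirs from the graph.
#' @param namespace the GO namespace to score in.
#' @return a numeric score in `[0, 1]`, or `NA` for missing annotation.
#' @export
protein_similarity <- function(graph, corpus, p, q, measure, ic = NULL,
                               namespace = "biological_process") {
  cfg <- .resolve_measure(measure)
  p <- resolve_protein(corpus, p)
  q <- resolve_protein(corpus, q)
  tp <- corpus$direct[[namespace]][[p]]
  tq <- corpus$direct[[namespace]][[q]]
  if (is.null(tp) || is.null(tq)) return(NA_real_)

  if (cfg$approach %in% DIRECT_MEASURES) {
    cp <- corpus$closures[[namespace]][[p]]
    cq <- corpus$closures[[namespace]][[q]]
    return(direct_similarity(cfg$approach, ic, cp, cq))
  }
  mat <- matrix(0, length(tp), length(tq))
  for (i in seq_along(tp)) {
    for (j in seq_along(tq)) {
      mat[i, j] <- term_similarity(graph, tp[i], tq[j], cfg$approach, ic)
    }
  }
  combine_scores(mat, cfg$combiner)
}

#' Batch protein-pair scoring
#'
#' @param graph a `go_ontology`.
#' @param corpus a `go_corpus`.
#' @param pairs a data.frame (or 2-column matrix) of protein identifiers.
#' @inheritParams protein_similarity
#' @return a data.frame `p, q, measure, score, note` (`NA` score with a note
#'   for unresolvable rows).
#' @export
protein_similarity_batch <- function(graph, corpus, pairs, measure, ic = NULL,
                                     namespace = "biological_process") {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  label <- if (is.character(measure)) measure else {
    cfg <- .resolve_measure(measure)
    if (is.null(cfg$combiner)) cfg$approach
    else paste(cfg$approach, cfg$combiner, sep = "-")
  }
  score <- rep(NA_real_, nrow(pairs))
  note <- rep("", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    res <- tryCatch(
      protein_similarity(graph, corpus, pairs[[1L]][i], pairs[[2L]][i],
                         measure, ic, namespace),
      gf_error = function(e) e
    )
    if (inherits(res, "gf_error")) note[i] <- conditionMessage(res)
    else {
      score[i] <- res
      if (is.na(res)) note[i] <- "missing annotation"
    }
  }
  data.frame(p = pairs[[1L]], q = pairs[[2L]], measure = label,
             score = score, note = note, stringsAsFactors = FALSE)
}
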
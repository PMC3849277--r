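# Pairwise GO-term semantic similarity.
#
# Nine approaches, all normalized to [0, 1].  The annotation family
# (resnik, lin, relevance, li, and the two XGraSM flavors) consumes
# annotation IC; zhang and universal consume their topology IC tables (built
# on demand); wang needs only the graph.  Jiang-Conrath is not a separate
# approach: it is the unnormalized distance derived from Lin's measure.

TERM_SIM_APPROACHES <- c("resnik", "lin", "relevance", "li",
                         "xgrasm", "xgrasm_resnik", "xgrasm_lin",
                         "wang", "zhang", "universal")

.ANNOTATION_APPROACHES <- c("resnik", "lin", "relevance", "li",
                            "xgrasm", "xgrasm_resnik", "xgrasm_lin")

#' Most informative common ancestor (MICA)
#'
#' Among the common ancestors of `t1` and `t2` with a defined IC, returns
#' one maximizing IC; ties are broken by lexicographically smallest id so
#' the choice is deterministic.
#'
#' @param graph a `go_ontology`.
#' @param ic a `go_ic`.
#' @param t1,t2 GO accessions in the same namespace.
#' @return a list with `term` and `ic`.
#' @export
mica <- function(graph, ic, t1, t2) {
  ca <- go_common_ancestors(graph, t1, t2)
  vals <- ic$values[ca]
  ok <- !is.na(vals)
  if (!any(ok)) {
    gf_error(sprintf("no common ancestor of %s and %s has a defined IC",
                     t1, t2), "gf_parameter_error")
  }
  ca <- ca[ok]
  vals <- unname(vals[ok])
  best <- vals == max(vals)
  pick <- sort(ca[best])[1L]
  list(term = pick, ic = ic$values[[pick]])
}

.require_annotation_ic <- function(ic, terms) {
  if (is.null(ic) || ic$model != "annotation") {
    gf_error("this approach requires an annotation IC table",
             "gf_parameter_error")
  }
  missing <- terms[!(terms %in% names(ic$values))]
  if (length(missing)) {
    gf_error(paste("term unused in corpus (no annotation IC):",
                   paste(missing, collapse = ", ")), "gf_lookup_error")
  }
}

.lin_form <- function(ic_mica, ic1, ic2) {
  if (ic1 + ic2 <= 0) 0 else 2 * ic_mica / (ic1 + ic2)
}

#' GO term semantic similarity
#'
#' Computes `S(t1, t2)` in `[0, 1]` under one of nine approaches:
#' \describe{
#'   \item{resnik}{uniformized MICA information content, `IC(MICA)/ic_max`.}
#'   \item{lin}{`2 IC(MICA) / (IC(t1) + IC(t2))`.}
#'   \item{relevance}{Lin score times `1 - p(MICA)` (SimRel).}
#'   \item{li}{Lin score times `1 - 1/(1 + IC(MICA))` (information
#'     coefficient, SimIC).}
#'   \item{xgrasm / xgrasm_lin, xgrasm_resnik}{replace `IC(MICA)` by the
#'     mean IC over all informative common ancestors (common ancestors with
#'     IC > 0); `xgrasm` is the Lin flavor.}
#'   \item{wang}{sum of the two anchors' S-values over the common inclusive
#'     ancestors, divided by `SV(t1) + SV(t2)`.}
#'   \item{zhang}{Lin form over descendant-leaf-count IC.}
#'   \item{universal}{`IC_U(MICA) / max(IC_U(t1), IC_U(t2))`.}
#' }
#' The score between a term and itself is set to 1 under every approach
#' (self-identity takes precedence over the raw formulas, which for
#' uniformized MICA content would otherwise yield `IC(t)/ic_max < 1`).
#' Results are clamped to `[0, 1]`.
#'
#' @param graph a `go_ontology`.
#' @param t1,t2 GO accessions in the same namespace.
#' @param approach one of `TERM_SIM_APPROACHES`.
#' @param ic the IC table the approach consumes; annotation approaches
#'   require it, `zhang`/`universal` build (and cache) theirs from the graph
#'   when `NULL`, `wang` ignores it.
#' @param w_is_a,w_part_of edge weights for the `wang` approach.
#' @return a numeric score in `[0, 1]`.
#' @export
term_similarity <- function(graph, t1, t2, approach, ic = NULL,
                            w_is_a = 0.8, w_part_of = 0.6) {
  approach <- match.arg(approach, TERM_SIM_APPROACHES)
  t1 <- resolve_term(graph, t1)
  t2 <- resolve_term(graph, t2)
  ns1 <- term_namespace(graph, t1)
  if (ns1 != term_namespace(graph, t2)) {
    gf_error(sprintf("terms %s and %s are in different namespaces", t1, t2),
             "gf_namespace_error")
  }

  score <- switch(approach,
    resnik = {
      .require_annotation_ic(ic, c(t1, t2))
      if (t1 == t2) 1
      else if (ic$ic_max <= 0) 0
      else mica(graph, ic, t1, t2)$ic / ic$ic_max
    },
    lin = {
      .require_annotation_ic(ic, c(t1, t2))
      if (t1 == t2) 1
      else .lin_form(mica(graph, ic, t1, t2)$ic,
                     ic$values[[t1]], ic$values[[t2]])
    },
    relevance = {
      .require_annotation_ic(ic, c(t1, t2))
      if (t1 == t2) 1
      else {
        m <- mica(graph, ic, t1, t2)
        .lin_form(m$ic, ic$values[[t1]], ic$values[[t2]]) * (1 - exp(-m$ic))
      }
    },
    li = {
      .require_annotation_ic(ic, c(t1, t2))
      if (t1 == t2) 1
      else {
        m <- mica(graph, ic, t1, t2)
        .lin_form(m$ic, ic$values[[t1]], ic$values[[t2]]) *
          (1 - 1 / (1 + m$ic))
      }
    },
    xgrasm = ,
    xgrasm_lin = ,
    xgrasm_resnik = {
      .require_annotation_ic(ic, c(t1, t2))
      if (t1 == t2) 1
      else {
        ca <- go_common_ancestors(graph, t1, t2)
        vals <- ic$values[ca]
        ica <- vals[!is.na(vals) & vals > 0]
        if (!length(ica)) 0
        else if (approach == "xgrasm_resnik") {
          if (ic$ic_max <= 0) 0 else mean(ica) / ic$ic_max
        } else {
          .lin_form(mean(ica), ic$values[[t1]], ic$values[[t2]])
        }
      }
    },
    wang = {
      sv1 <- wang_svalues(graph, t1, w_is_a, w_part_of)
      sv2 <- wang_svalues(graph, t2, w_is_a, w_part_of)
      common <- intersect(names(sv1$svalues), names(sv2$svalues))
      (sum(sv1$svalues[common]) + sum(sv2$svalues[common])) /
        (sv1$sv_total + sv2$sv_total)
    },
    zhang = {
      # a supplied table is honoured only if it is the right model; an
      # annotation table passed alongside is ignored, not an error
      icz <- .get_ic(graph, "zhang", ns1,
                     if (!is.null(ic) && ic$model == "zhang") ic)
      if (t1 == t2) 1
      else .lin_form(mica(graph, icz, t1, t2)$ic,
                     icz$values[[t1]], icz$values[[t2]])
    },
    universal = {
      icu <- .get_ic(graph, "universal", ns1,
                     if (!is.null(ic) && ic$model == "universal") ic)
      if (t1 == t2) 1
      else {
        denom <- max(icu$values[[t1]], icu$values[[t2]])
        if (denom <= 0) 0 else mica(graph, icu, t1, t2)$ic / denom
      }
    }
  )
  min(max(score, 0), 1)
}

#' Batch term-pair scoring
#'
#' Scores a two-column table of GO id pairs; cross-namespace or unresolvable
#' pairs yield `NA` with a reason instead of failing the batch.
#'
#' @param graph a `go_ontology`.
#' @param pairs a data.frame (or 2-column matrix) of GO id pairs.
#' @inheritParams term_similarity
#' @return a data.frame `t1, t2, approach, score, note`.
#' @export
term_similarity_batch <- function(graph, pairs, approach, ic = NULL, ...) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  score <- rep(NA_real_, nrow(pairs))
  note <- rep("", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    res <- tryCatch(
      term_similarity(graph, pairs[[1L]][i], pairs[[2L]][i], approach, ic, ...),
      gf_error = function(e) e
    )
    if (inherits(res, "gf_error")) note[i] <- conditionMessage(res)
    else score[i] <- res
  }
  data.frame(t1 = pairs[[1L]], t2 = pairs[[2L]], approach = approach,
             score = score, note = note, stringsAsFactors = FALSE)
}
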
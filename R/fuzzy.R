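# Fuzzy agreement-level term statistics.
#
# The fuzzy annotation score of a term t for a protein g is
#   A_g(t) = max{ S(t, s) : s in g's DIRECT term set },
# so a term annotating g directly scores 1 under any approach with unit
# self-similarity.  A term "fuzzy occurs" through g at agreement level c
# when A_g(t) >= c; the fuzzy frequency ff(t) of a protein set counts such
# proteins.  Presets: moderate c = 0.3 (default), high c = 0.7, perfect
# c = 1 (which recovers the classical crisp statistics).

AGREEMENT_PRESETS <- c(moderate = 0.3, high = 0.7, perfect = 1.0)

.check_agreement <- function(c) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 0 || c > 1) {
    gf_error("agreement level must lie in (0, 1]", "gf_parameter_error")
  }
  c
}

#' Fuzzy annotation score of a term for a protein
#'
#' Maximum term similarity between `term` and the protein's direct term set
#' in the term's namespace.
#'
#' @param graph a `go_ontology`.
#' @param corpus a `go_corpus`.
#' @param term GO accession.
#' @param protein protein accession or gene symbol.
#' @param approach a term-similarity approach (see [term_similarity()]);
#'   direct closure measures are not usable here.
#' @param ic IC table for annotation-family approaches.
#' @return `A_g(t)` in `[0, 1]`.
#' @export
fuzzy_score <- function(graph, corpus, term, protein, approach, ic = NULL) {
  term <- resolve_term(graph, term)
  ns <- term_namespace(graph, term)
  protein <- resolve_protein(corpus, protein)
  tg <- corpus$direct[[ns]][[protein]]
  if (is.null(tg)) {
    gf_error(sprintf("protein %s has no annotation in namespace %s",
                     protein, ns), "gf_lookup_error")
  }
  max(vapply(tg, function(s) term_similarity(graph, term, s, approach, ic),
             numeric(1L)))
}

#' Fuzzy frequency of a term over a protein set
#'
#' Number of proteins whose fuzzy annotation score for `term` reaches the
#' agreement level.
#'
#' @inheritParams fuzzy_score
#' @param proteins character vector of protein ids.
#' @param agreement threshold `c` in `(0, 1]`; default 0.3 (moderate).
#' @return an integer count.
#' @export
fuzzy_frequency <- function(graph, corpus, term, proteins, approach,
                            ic = NULL, agreement = 0.3) {
  agreement <- .check_agreement(agreement)
  scores <- vapply(proteins, function(g)
    fuzzy_score(graph, corpus, term, g, approach, ic), numeric(1L))
  sum(scores >= agreement)
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `l` annotated genes in a target of size
#' `n` drawn from a reference of `N` genes of which `m` are annotated.
#' Computed through the stable log-space tail of the hypergeometric
#' distribution.
#'
#' @param N reference population size.
#' @param m annotated genes in the reference.
#' @param n target set size.
#' @param l observed annotated genes in the target.
#' @return p in `[0, 1]`.
#' @export
hypergeom_pvalue <- function(N, m, n, l) {
  if (any(c(N, m, n, l) < 0) || m > N || n > N || l > n) {
    gf_error("inconsistent hypergeometric counts (need l <= n <= N, m <= N)",
             "gf_parameter_error")
  }
  if (l == 0) return(1)
  stats::phyper(l - 1, m, N - m, n, lower.tail = FALSE)
}

#' Upper-tail binomial p-value
#'
#' Probability of at least `l` successes in `n` trials at success
#' probability `p`; the large-population approximation of the
#' hypergeometric test with `p = m/N`.
#'
#' @param n number of trials.
#' @param p success probability.
#' @param l observed successes.
#' @return p-value in `[0, 1]`.
#' @export
binomial_pvalue <- function(n, p, l) {
  if (n < 0 || l < 0 || l > n || p < 0 || p > 1) {
    gf_error("inconsistent binomial parameters (need 0 <= l <= n, p in [0,1])",
             "gf_parameter_error")
  }
  if (l == 0) return(1)
  stats::pbinom(l - 1, n, p, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' @param p_values numeric vector of raw p-values.
#' @param k number of tests; must be at least `length(p_values)`.
#' @return `pmin(1, p * k)`, order preserved.
#' @export
bonferroni <- function(p_values, k = length(p_values)) {
  if (k <= 0) gf_error("Bonferroni k must be positive", "gf_parameter_error")
  if (k < length(p_values)) {
    gf_error("Bonferroni k smaller than the number of p-values",
             "gf_parameter_error")
  }
  pmin(1, p_values * k)
}

#' Fuzzy retrieval of proteins by GO term
#'
#' For each query term, detects the proteins of the corpus whose fuzzy
#' annotation score reaches the agreement level, and scores the detection
#' count with a one-sided binomial test whose success probability is the
#' term's relative fuzzy frequency in the reference corpus (at the same
#' agreement level).  P-values are Bonferroni-corrected over the query
#' terms.
#'
#' @param graph a `go_ontology`.
#' @param corpus the target `go_corpus` whose proteins are scanned.
#' @param terms query GO ids (all in one namespace; at most `limit` unless
#'   `force`).
#' @param approach,ic term-similarity configuration (see [fuzzy_score()]).
#' @param agreement agreement level `c`; default 0.3.
#' @param reference the reference corpus estimating the background
#'   frequency; defaults to `corpus` itself.
#' @param limit input-size limit (default 20).
#' @param force raise the limit.
#' @return a data.frame `term, name, level, n_detected, p_value,
#'   corrected_p`, one row per query term (query order preserved), with an
#'   attribute `"detected"`: a named list of data.frames
#'   `protein, score` ranked by descending fuzzy score.
#' @export
fuzzy_retrieve <- function(graph, corpus, terms, approach, ic = NULL,
                           agreement = 0.3, reference = corpus,
                           limit = 20L, force = FALSE) {
  agreement <- .check_agreement(agreement)
  if (length(terms) > limit && !force) {
    gf_error(sprintf("%d query terms exceed the limit of %d (use force)",
                     length(terms), limit), "gf_input_limit")
  }
  if (!length(terms)) gf_error("empty query", "gf_parameter_error")
  terms <- vapply(terms, function(t) resolve_term(graph, t), character(1L))
  ns <- unique(vapply(terms, function(t) term_namespace(graph, t), character(1L)))
  if (length(ns) != 1L) {
    gf_error("query terms span several namespaces", "gf_namespace_error")
  }
  target_prot <- corpus$proteins[[ns]]
  ref_prot <- reference$proteins[[ns]]
  if (is.null(target_prot) || !length(target_prot)) {
    gf_error(paste("corpus has no annotated proteins in", ns),
             "gf_parameter_error")
  }
  n <- length(target_prot)
  N_ref <- length(ref_prot)

  detected <- vector("list", length(terms))
  names(detected) <- terms
  p_value <- numeric(length(terms))
  for (i in seq_along(terms)) {
    t <- terms[i]
    scores <- vapply(target_prot, function(g)
      fuzzy_score(graph, corpus, t, g, approach, ic), numeric(1L))
    hit <- scores >= agreement
    ord <- order(-scores[hit], names(scores)[hit])
    detected[[i]] <- data.frame(protein = names(scores)[hit][ord],
                                score = unname(scores[hit][ord]),
                                stringsAsFactors = FALSE)
    ff_ref <- fuzzy_frequency(graph, reference, t, ref_prot, approach, ic,
                              agreement)
    p_value[i] <- binomial_pvalue(n, ff_ref / N_ref, sum(hit))
  }
  out <- data.frame(
    term = terms,
    name = vapply(terms, function(t) term_name(graph, t), character(1L)),
    level = vapply(terms, function(t) term_level(graph, t), integer(1L)),
    n_detected = vapply(detected, nrow, integer(1L)),
    p_value = p_value,
    corrected_p = bonferroni(p_value, length(terms)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "detected") <- detected
  out
}

#' Fuzzy term enrichment analysis
#'
#' Tests every namespace term with a nonzero target fuzzy frequency for
#' over-representation in the target protein set against the reference
#' corpus, using the upper-tail hypergeometric test on fuzzy frequencies at
#' the chosen agreement level, Bonferroni-corrected over the number of
#' tested terms.
#'
#' @param graph a `go_ontology`.
#' @param reference the reference (background) `go_corpus`.
#' @param target protein accessions or gene symbols, a subset of the
#'   reference's annotated proteins.
#' @param approach,ic term-similarity configuration.
#' @param agreement agreement level `c`; default 0.3.
#' @param namespace the GO namespace analyzed.
#' @param limit input-size limit on the target (default 2000).
#' @param force raise the limit.
#' @param strict unknown target proteins are errors (`TRUE`, default) or
#'   skipped with a message.
#' @return a data.frame `approach, term, name, level, ref_ff, target_ff,
#'   p_value, corrected_p`, sorted by corrected then raw p-value.
#' @export
fuzzy_enrich <- function(graph, reference, target, approach, ic = NULL,
                         agreement = 0.3, namespace = "biological_process",
                         limit = 2000L, force = FALSE, strict = TRUE) {
  agreement <- .check_agreement(agreement)
  if (!length(target)) gf_error("empty target set", "gf_parameter_error")
  if (length(target) > limit && !force) {
    gf_error(sprintf("%d target proteins exceed the limit of %d (use force)",
                     length(target), limit), "gf_input_limit")
  }
  resolved <- character(0L)
  for (id in target) {
    r <- tryCatch(resolve_protein(reference, id), gf_error = function(e) e)
    if (inherits(r, "gf_error")) {
      if (strict) stop(r)
      message("fuzzy_enrich: skipping ", id, " (", conditionMessage(r), ")")
    } else resolved <- c(resolved, r)
  }
  resolved <- unique(resolved)
  ref_prot <- reference$proteins[[namespace]]
  resolved <- resolved[resolved %in% ref_prot]
  if (!length(resolved)) {
    gf_error("no target protein is annotated in the reference corpus",
             "gf_parameter_error")
  }

  terms <- graph$ids[graph$namespace == namespace]
  n <- length(resolved)
  N <- length(ref_prot)

  # target fuzzy frequencies for all namespace terms, then reference
  # frequencies only for the candidates (target ff >= 1)
  target_ff <- integer(length(terms))
  for (i in seq_along(terms)) {
    target_ff[i] <- fuzzy_frequency(graph, reference, terms[i], resolved,
                                    approach, ic, agreement)
  }
  cand <- which(target_ff >= 1L)
  if (!length(cand)) {
    return(data.frame(approach = character(0L), term = character(0L),
                      name = character(0L), level = integer(0L),
                      ref_ff = integer(0L), target_ff = integer(0L),
                      p_value = numeric(0L), corrected_p = numeric(0L),
                      stringsAsFactors = FALSE))
  }
  ref_ff <- integer(length(cand))
  p_value <- numeric(length(cand))
  for (j in seq_along(cand)) {
    t <- terms[cand[j]]
    ref_ff[j] <- fuzzy_frequency(graph, reference, t, ref_prot, approach, ic,
                                 agreement)
    p_value[j] <- hypergeom_pvalue(N, ref_ff[j], n, target_ff[cand[j]])
  }
  out <- data.frame(
    approach = approach,
    term = terms[cand],
    name = graph$name[match(terms[cand], graph$ids)],
    level = graph$levels[match(terms[cand], graph$ids)],
    ref_ff = ref_ff,
    target_ff = target_ff[cand],
    p_value = p_value,
    corrected_p = bonferroni(p_value, length(cand)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$corrected_p, out$p_value, out$term), , drop = FALSE]
}
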
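# GAF parsing: per-protein direct GO term sets per namespace, annotation
# closures under the true-path rule, and corpus term-usage statistics.

.ASPECT_NS <- c(P = "biological_process", F = "molecular_function",
                C = "cellular_component")

#' Parse annotations in GAF 2.x format
#'
#' Builds an annotation corpus from a Gene Association File: per-protein
#' direct term sets partitioned by namespace, plus ancestor closures
#' (true-path rule).  `NOT`-qualified rows are dropped (a negated annotation
#' must not assert function), as are rows carrying an excluded evidence code
#' and rows whose GO id cannot be resolved in the companion ontology
#' (obsolete/unknown; counted and logged).
#'
#' @param gaf a file path, a single string, or a character vector of lines.
#' @param graph the companion `go_ontology`.
#' @param exclude_evidence evidence codes (e.g. `"IEA"`) whose rows are
#'   dropped; default none (the corpus is used wholesale).
#' @param strict if `TRUE`, malformed lines are hard errors instead of being
#'   logged and skipped.
#' @return an object of class `go_corpus` with fields `direct` and
#'   `closures` (per-namespace named lists protein -> character vector of GO
#'   ids), `proteins` (per-namespace id vectors), `gene_names` (lower-cased
#'   symbol -> protein ids) and `dropped` (counts of discarded rows).
#' @export
parse_gaf <- function(gaf, graph, exclude_evidence = character(0L),
                      strict = FALSE) {
  lines <- .gf_read_lines(gaf)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) gf_error("no annotation rows in GAF input", "gf_parse_error")

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  malformed <- nf < 15L
  if (any(malformed)) {
    if (strict) {
      gf_error(sprintf("malformed GAF line (%d columns): %.60s",
                       nf[malformed][1L], lines[malformed][1L]),
               "gf_parse_error")
    }
    message("parse_gaf: skipped ", sum(malformed), " malformed line(s)")
    fields <- fields[!malformed]
  }
  if (!length(fields)) gf_error("zero usable annotations", "gf_parse_error")

  col <- function(k) vapply(fields, `[`, character(1L), k)
  protein <- col(2L)
  symbol <- col(3L)
  qualifier <- col(4L)
  go_id <- col(5L)
  evidence <- col(7L)

  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
  n_not <- sum(!keep)
  keep <- keep & !(evidence %in% exclude_evidence)

  # resolve terms through alt ids; drop unknown/obsolete with a logged count
  idx <- unname(graph$index[go_id])
  via_alt <- is.na(idx)
  if (any(via_alt)) {
    primary <- graph$alt[go_id[via_alt]]
    idx[via_alt] <- unname(graph$index[primary])
  }
  unknown <- is.na(idx) & keep
  if (any(unknown)) {
    message("parse_gaf: dropped ", sum(unknown),
            " annotation(s) to unknown or obsolete terms")
  }
  keep <- keep & !is.na(idx)
  if (!any(keep)) gf_error("zero usable annotations", "gf_parse_error")

  protein <- protein[keep]
  symbol <- symbol[keep]
  idx <- idx[keep]
  ns <- graph$namespace[idx]

  anc <- .ancestor_sets(graph)
  direct <- list()
  closures <- list()
  for (nsi in unique(ns)) {
    sel <- ns == nsi
    d <- split(idx[sel], protein[sel])
    d <- lapply(d, unique)
    direct[[nsi]] <- lapply(d, function(ii) sort(graph$ids[ii]))
    closures[[nsi]] <- lapply(d, function(ii) {
      sort(graph$ids[unique(unlist(anc[ii], use.names = FALSE))])
    })
  }

  gene_names <- lapply(split(protein, tolower(symbol)), unique)
  gene_names <- gene_names[nzchar(names(gene_names))]

  structure(list(
    direct = direct,
    closures = closures,
    proteins = lapply(direct, names),
    gene_names = gene_names,
    dropped = c(not_qualified = n_not, unknown_term = sum(unknown),
                malformed = sum(malformed))
  ), class = "go_corpus")
}

#' @export
print.go_corpus <- function(x, ...) {
  cat("go_corpus:\n")
  for (nsi in names(x$direct)) {
    cat("  ", nsi, ": ", length(x$direct[[nsi]]), " protein(s)\n", sep = "")
  }
  invisible(x)
}

#' Term usage statistics of an annotation corpus
#'
#' For each term, counts the number of proteins whose annotation closure
#' contains the term (protein-level counting, so redundantly annotated
#' proteins contribute once), and the usage probability relative to the
#' namespace root.
#'
#' @param corpus a `go_corpus`.
#' @param graph the companion `go_ontology`.
#' @param namespace one of the GO namespaces.
#' @return an object of class `go_usage` with `counts`, `probabilities`,
#'   `namespace` and `n_proteins`.
#' @export
term_usage <- function(corpus, graph, namespace) {
  cl <- corpus$closures[[namespace]]
  if (is.null(cl) || !length(cl)) {
    gf_error(paste("no annotated proteins in namespace", namespace),
             "gf_parameter_error")
  }
  tab <- table(unlist(cl, use.names = FALSE))
  counts <- stats::setNames(as.integer(tab), names(tab))
  root <- graph$roots[[namespace]]
  stopifnot(counts[[root]] == length(cl))
  structure(list(
    counts = counts,
    probabilities = counts / counts[[root]],
    namespace = namespace,
    n_proteins = length(cl)
  ), class = "go_usage")
}

#' Resolve a protein accession or gene symbol
#'
#' Accessions are matched exactly; gene symbols case-insensitively.  An
#' ambiguous symbol (shared by several accessions) and an unknown identifier
#' are errors, the latter listing near-misses if any.
#'
#' @param corpus a `go_corpus`.
#' @param identifier accession or gene symbol.
#' @return the canonical protein id.
#' @export
resolve_protein <- function(corpus, identifier) {
  all_proteins <- unique(unlist(corpus$proteins, use.names = FALSE))
  if (identifier %in% all_proteins) return(identifier)
  hit <- corpus$gene_names[[tolower(identifier)]]
  if (!is.null(hit)) {
    if (length(hit) == 1L) return(hit)
    gf_error(sprintf("ambiguous gene symbol '%s': candidates %s", identifier,
                     paste(sort(hit), collapse = ", ")),
             "gf_lookup_error")
  }
  near <- unique(c(
    agrep(identifier, all_proteins, max.distance = 0.25, value = TRUE),
    agrep(tolower(identifier), names(corpus$gene_names),
          max.distance = 0.25, value = TRUE)
  ))
  msg <- paste0("unknown protein or gene identifier: ", identifier)
  if (length(near)) {
    msg <- paste0(msg, " (near misses: ",
                  paste(utils::head(near, 5L), collapse = ", "), ")")
  }
  gf_error(msg, "gf_lookup_error")
}
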
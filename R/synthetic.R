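# Deterministic toy fixtures and seeded random OBO/GAF generators.
#
# Generators emit real OBO/GAF text so the parsers are exercised on every
# test run; nothing here depends on network access or deposited data.

#' The deterministic toy fixture (6 terms, 5 proteins)
#'
#' A six-term biological_process ontology
#' (`GO:0000001` root; `GO:0000002`, `GO:0000003` is_a root;
#' `GO:0000004` is_a `GO:0000002`; `GO:0000005` is_a `GO:0000002` and
#' part_of `GO:0000003`; `GO:0000006` is_a `GO:0000004`) and a five-protein
#' corpus (P1:{6}, P2:{5}, P3:{4}, P4:{3}, P5:{2,5}; gene symbols katG and
#' g2..g5).  Byte-stable across runs.
#'
#' @return a list with `obo_text`, `gaf_text`, `terms` (a G1..G6 shorthand
#'   to GO id map) and `expected` (hand-derivable quantities: levels, usage
#'   counts and probabilities, leaf-count D values and topological-position
#'   A values).
#' @export
toy_fixture <- function() {
  g <- sprintf("GO:%07d", 1:6)
  names(g) <- paste0("G", 1:6)
  obo <- c(
    "format-version: 1.2",
    "",
    "[Term]",
    paste0("id: ", g[["G1"]]),
    "name: toy root process",
    "namespace: biological_process",
    "",
    "[Term]",
    paste0("id: ", g[["G2"]]),
    "name: branch A",
    "namespace: biological_process",
    paste0("is_a: ", g[["G1"]], " ! toy root process"),
    "",
    "[Term]",
    paste0("id: ", g[["G3"]]),
    "name: branch B",
    "namespace: biological_process",
    paste0("is_a: ", g[["G1"]], " ! toy root process"),
    "",
    "[Term]",
    paste0("id: ", g[["G4"]]),
    "name: process A1",
    "namespace: biological_process",
    paste0("is_a: ", g[["G2"]], " ! branch A"),
    "",
    "[Term]",
    paste0("id: ", g[["G5"]]),
    "name: process A2 within B",
    "namespace: biological_process",
    paste0("is_a: ", g[["G2"]], " ! branch A"),
    paste0("relationship: part_of ", g[["G3"]], " ! branch B"),
    "",
    "[Term]",
    paste0("id: ", g[["G6"]]),
    "name: process A1a",
    "namespace: biological_process",
    paste0("is_a: ", g[["G4"]], " ! process A1")
  )
  gaf_row <- function(prot, sym, go) {
    paste(c("UP", prot, sym, "", go, "PMID:0000001", "IEA", "", "P",
            paste(sym, "protein"), "", "protein", "taxon:1", "20130101",
            "UP", "", ""), collapse = "\t")
  }
  gaf <- c(
    "!gaf-version: 2.1",
    gaf_row("P1", "katG", g[["G6"]]),
    gaf_row("P2", "g2", g[["G5"]]),
    gaf_row("P3", "g3", g[["G4"]]),
    gaf_row("P4", "g4", g[["G3"]]),
    gaf_row("P5", "g5", g[["G2"]]),
    gaf_row("P5", "g5", g[["G5"]])
  )
  expected <- list(
    levels = stats::setNames(c(0L, 1L, 1L, 2L, 2L, 3L), unname(g)),
    counts = stats::setNames(c(5L, 4L, 3L, 2L, 2L, 1L), unname(g)),
    probabilities = stats::setNames(c(1, .8, .6, .4, .4, .2), unname(g)),
    zhang_D = stats::setNames(c(3, 2, 1, 1, 1, 1), unname(g)),
    universal_A = stats::setNames(c(1, .5, .5, .25, .125, .25), unname(g)),
    closures = list(
      P1 = unname(g[c("G1", "G2", "G4", "G6")]),
      P2 = unname(g[c("G1", "G2", "G3", "G5")]),
      P3 = unname(g[c("G1", "G2", "G4")]),
      P4 = unname(g[c("G1", "G3")]),
      P5 = unname(g[c("G1", "G2", "G3", "G5")])
    )
  )
  list(obo_text = paste(obo, collapse = "\n"),
       gaf_text = paste(gaf, collapse = "\n"),
       terms = g, expected = expected)
}

#' Seeded random ontology + annotation instance
#'
#' Grows a rooted DAG in topological construction order: term `i` attaches
#' to 1..`max_parents` uniformly chosen earlier terms, each edge being
#' `part_of` with probability `part_of_fraction`; proteins are annotated
#' with uniformly chosen non-root terms.  Identical spec + seed give
#' byte-identical output; the caller's RNG state is untouched.
#'
#' @param n_terms number of terms (>= 2).
#' @param max_parents maximum parents per non-root term.
#' @param part_of_fraction probability an edge is `part_of`.
#' @param n_proteins number of annotated proteins.
#' @param annotations_per_protein direct annotations per protein.
#' @param seed integer seed.
#' @return a list with `obo_text` and `gaf_text`.
#' @export
random_instance <- function(n_terms = 50L, max_parents = 3L,
                            part_of_fraction = 0.2, n_proteins = 10L,
                            annotations_per_protein = 2L, seed = 1L) {
  if (n_terms < 2L || max_parents < 1L || n_proteins < 1L ||
      annotations_per_protein < 1L ||
      part_of_fraction < 0 || part_of_fraction > 1) {
    gf_error("invalid random instance specification", "gf_parameter_error")
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)

  ids <- sprintf("GO:%07d", seq_len(n_terms))
  obo <- c("format-version: 1.2", "",
           "[Term]", paste0("id: ", ids[1L]), "name: synthetic root",
           "namespace: biological_process")
  for (i in 2:n_terms) {
    k <- sample.int(min(max_parents, i - 1L), 1L)
    parents <- sort(sample.int(i - 1L, k))
    rel <- stats::runif(k) < part_of_fraction
    stanza <- c("", "[Term]", paste0("id: ", ids[i]),
                paste0("name: synthetic term ", i),
                "namespace: biological_process",
                ifelse(rel, paste0("relationship: part_of ", ids[parents]),
                       paste0("is_a: ", ids[parents])))
    obo <- c(obo, stanza)
  }

  gaf <- "!gaf-version: 2.1"
  for (p in seq_len(n_proteins)) {
    prot <- sprintf("SP%04d", p)
    sym <- sprintf("gene%d", p)
    terms <- sample(2:n_terms, min(annotations_per_protein, n_terms - 1L))
    for (t in terms) {
      gaf <- c(gaf, paste(c("UP", prot, sym, "", ids[t], "PMID:0000001",
                            "IEA", "", "P", paste(sym, "protein"), "",
                            "protein", "taxon:1", "20130101", "UP", "", ""),
                          collapse = "\t"))
    }
  }
  list(obo_text = paste(obo, collapse = "\n"),
       gaf_text = paste(gaf, collapse = "\n"))
}

#' Write the toy fixture to a directory
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_fixture_files <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- toy_fixture()
  obo <- file.path(dir, "toy.obo")
  gaf <- file.path(dir, "toy.gaf")
  writeLines(fx$obo_text, obo)
  writeLines(fx$gaf_text, gaf)
  invisible(c(obo = obo, gaf = gaf))
}
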
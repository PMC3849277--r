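# Shared fixtures, built once per test run.

.toy_cache <- new.env(parent = emptyenv())

toy <- function() {
  if (is.null(.toy_cache$x)) {
    fx <- toy_fixture()
    g <- parse_obo(fx$obo_text)
    co <- parse_gaf(fx$gaf_text, g)
    us <- term_usage(co, g, "biological_process")
    .toy_cache$x <- list(fx = fx, graph = g, corpus = co, usage = us,
                         ic = annotation_ic(us))
  }
  .toy_cache$x
}

# GO:0000001..6 shorthand
gid <- function(k) sprintf("GO:%07d", k)

# a two-namespace ontology for cross-namespace error paths
two_ns_obo <- function() {
  paste(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: bp root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: bp child",
    "namespace: biological_process", "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000011", "name: mf root",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0000012", "name: mf child",
    "namespace: molecular_function", "is_a: GO:0000011"
  ), collapse = "\n")
}

gaf_line <- function(prot, sym, go, qualifier = "", evidence = "IEA",
                     aspect = "P") {
  paste(c("UP", prot, sym, qualifier, go, "PMID:0000001", evidence, "",
          aspect, paste(sym, "protein"), "", "protein", "taxon:1",
          "20130101", "UP", "", ""), collapse = "\t")
}

# small random instance parsed into graph/corpus/IC tables
random_setup <- function(seed, n_terms = 12L, n_proteins = 5L,
                         max_parents = 2L, annotations_per_protein = 2L) {
  inst <- random_instance(n_terms = n_terms, max_parents = max_parents,
                          part_of_fraction = 0.25, n_proteins = n_proteins,
                          annotations_per_protein = annotations_per_protein,
                          seed = seed)
  g <- parse_obo(inst$obo_text)
  co <- parse_gaf(inst$gaf_text, g)
  us <- term_usage(co, g, "biological_process")
  list(inst = inst, graph = g, corpus = co, usage = us,
       ic = annotation_ic(us))
}
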
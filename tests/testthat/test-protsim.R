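test_that("combiners reproduce the hand toy evaluation", {
  tt <- toy()
  lin25 <- 2 * (-log(0.8)) / (-log(0.8) + -log(0.4))  # S(G2, G5)
  mat <- matrix(c(lin25, 1), nrow = 2L)               # P5 = {G2,G5} vs P2 = {G5}
  expect_equal(combine_scores(mat, "abm"), (lin25 + 1 + 1) / 3)
  expect_equal(combine_scores(mat, "bma"), ((lin25 + 1) / 2 + 1) / 2)
  expect_equal(combine_scores(mat, "avg"), mean(c(lin25, 1)))
  expect_equal(combine_scores(mat, "max"), 1)
  # single entry: all four reduce to the entry
  for (comb in c("avg", "max", "bma", "abm")) {
    expect_equal(combine_scores(matrix(0.42), comb), 0.42)
  }
  expect_error(combine_scores(matrix(numeric(0L), 0L, 0L), "avg"),
               class = "gf_parameter_error")
})

test_that("abm equals bma exactly on square matrices and Eq-1/Eq-2 oracles agree", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(1:6, 1L); m <- sample(1:6, 1L)
    mat <- matrix(runif(n * m), n, m)
    expect_equal(combine_scores(mat, "abm"), oracle_abm(mat),
                 tolerance = 1e-12)
    expect_equal(combine_scores(mat, "bma"), oracle_bma(mat),
                 tolerance = 1e-12)
    if (n == m) {
      expect_equal(combine_scores(mat, "abm"), combine_scores(mat, "bma"))
    }
    # dominance: max >= bma/abm >= avg
    expect_gte(combine_scores(mat, "max"), combine_scores(mat, "bma") - 1e-12)
    expect_gte(combine_scores(mat, "max"), combine_scores(mat, "abm") - 1e-12)
    expect_gte(combine_scores(mat, "bma"), combine_scores(mat, "avg") - 1e-12)
    expect_gte(combine_scores(mat, "abm"), combine_scores(mat, "avg") - 1e-12)
  }
})

test_that("direct closure measures reproduce the hand toy values", {
  tt <- toy()
  bp <- tt$corpus$closures$biological_process
  ic <- tt$ic
  si <- -log(0.8)                         # IC over {G1, G2}
  su <- sum(-log(c(0.8, 0.6, 0.4, 0.4, 0.2)))
  sp <- sum(-log(c(0.8, 0.4, 0.2)))       # P1 closure
  sq <- sum(-log(c(0.8, 0.6, 0.4)))       # P2 closure
  expect_equal(direct_similarity("simgic", ic, bp$P1, bp$P2), si / su)
  expect_equal(direct_similarity("simdic", ic, bp$P1, bp$P2),
               2 * si / (sp + sq))
  expect_equal(direct_similarity("simuic", ic, bp$P1, bp$P2), si / max(sp, sq))
  expect_equal(direct_similarity("simui", NULL, bp$P1, bp$P2), 2 / 6)
  # identical closures: all four are 1
  for (m in c("simgic", "simdic", "simuic", "simui")) {
    expect_equal(direct_similarity(m, ic, bp$P2, bp$P5), 1, info = m)
  }
  # constant IC: the weights cancel and simgic equals simui
  flat <- ic
  flat$values[] <- 1
  expect_equal(direct_similarity("simgic", flat, bp$P1, bp$P2),
               direct_similarity("simui", NULL, bp$P1, bp$P2))
})

test_that("simdic and simuic agree with their naive summation oracles", {
  set.seed(7)
  for (i in 1:50) {
    terms <- paste0("T", 1:12)
    icv <- stats::setNames(runif(12, 0.01, 3), terms)
    cp <- sample(terms, sample(2:8, 1L))
    cq <- sample(terms, sample(2:8, 1L))
    expect_equal(direct_similarity("simdic", list(values = icv), cp, cq),
                 oracle_simdic(icv, cp, cq), tolerance = 1e-12)
    expect_equal(direct_similarity("simuic", list(values = icv), cp, cq),
                 oracle_simuic(icv, cp, cq), tolerance = 1e-12)
    expect_gte(direct_similarity("simdic", list(values = icv), cp, cq),
               direct_similarity("simgic", list(values = icv), cp, cq) - 1e-12)
  }
})

test_that("the registry enumerates exactly the 27 canonical configurations", {
  reg <- measure_registry()
  expect_equal(nrow(reg), 27L)
  expect_equal(anyDuplicated(reg$label), 0L)
  expect_equal(sum(reg$approach %in% c("simgic", "simdic", "simuic") &
                     reg$family == "annotation"), 3L)
  expect_equal(sum(reg$family == "annotation" & !is.na(reg$combiner)), 20L)
  expect_true("universal-bma" %in% reg$label)
  expect_false("universal-max" %in% reg$label)
  expect_true(all(c("wang-abm", "zhang-abm", "simui") %in% reg$label))
  # topology bindings are unique
  expect_equal(sum(reg$approach == "universal"), 1L)
  expect_equal(sum(reg$approach == "wang"), 1L)
  expect_equal(sum(reg$approach == "zhang"), 1L)
})

test_that("protein similarity dispatches correctly on the toy corpus", {
  tt <- toy()
  g <- tt$graph; co <- tt$corpus; ic <- tt$ic
  lin25 <- 2 * (-log(0.8)) / (-log(0.8) + -log(0.4))
  expect_equal(protein_similarity(g, co, "P5", "P2", "lin-bma", ic),
               ((lin25 + 1) / 2 + 1) / 2)
  expect_equal(protein_similarity(g, co, "P5", "P2", "lin-abm", ic),
               (lin25 + 2) / 3)
  expect_equal(protein_similarity(g, co, "P1", "P2", "simui"), 1 / 3)
  # symmetry and self-similarity across the whole registry; the avg
  # combiner is by definition the mean of ALL entries, so its self-score
  # equals the mean of the self term-similarity matrix, not 1
  reg <- measure_registry()
  for (r in seq_len(nrow(reg))) {
    s1 <- protein_similarity(g, co, "P5", "P2", reg$label[r], ic)
    s2 <- protein_similarity(g, co, "P2", "P5", reg$label[r], ic)
    expect_equal(s1, s2, info = reg$label[r])
    expect_true(s1 >= 0 && s1 <= 1, info = reg$label[r])
    self <- protein_similarity(g, co, "P5", "P5", reg$label[r], ic)
    if (identical(reg$combiner[r], "avg")) {
      expect_true(self > 0 && self <= 1, info = reg$label[r])
    } else {
      expect_equal(self, 1, info = reg$label[r])
    }
  }
  lin25 <- 2 * (-log(0.8)) / (-log(0.8) + -log(0.4))
  expect_equal(protein_similarity(g, co, "P5", "P5", "lin-avg", ic),
               mean(c(1, lin25, lin25, 1)))
})

test_that("unannotated proteins yield NA, not zero and not an error", {
  g <- parse_obo(two_ns_obo())
  gaf <- paste(c(gaf_line("P1", "a1", "GO:0000002"),
                 gaf_line("P2", "a2", "GO:0000012", aspect = "F")),
               collapse = "\n")
  co <- parse_gaf(gaf, g)
  # P2 is annotated only in molecular_function
  expect_true(is.na(protein_similarity(g, co, "P1", "P2", "simui",
                                       namespace = "biological_process")))
  res <- protein_similarity_batch(
    g, co, data.frame(a = "P1", b = "P2"), "simui",
    namespace = "biological_process")
  expect_true(is.na(res$score))
  expect_match(res$note, "missing annotation")
})
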
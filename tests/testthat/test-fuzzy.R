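test_that("fuzzy annotation scores match the hand toy values", {
  tt <- toy()
  g <- tt$graph; co <- tt$corpus
  # P1's only direct term is G6; topological-position sim(G5, G6) = 1/3
  a <- fuzzy_score(g, co, gid(5), "P1", "universal")
  expect_equal(a, 1 / 3)
  # a direct annotation always scores 1 (self-similarity dominates the max)
  expect_equal(fuzzy_score(g, co, gid(5), "P2", "universal"), 1)
  expect_equal(fuzzy_score(g, co, gid(5), "P5", "lin", tt$ic), 1)
  # threshold indicator at the preset agreement levels
  expect_true(a >= 0.3)
  expect_false(a >= 0.7)
  # unannotated protein is a classed failure
  gaf <- gaf_line("P9", "x9", gid(6))
  co1 <- parse_gaf(gaf, g)
  expect_error(fuzzy_score(g, co1, gid(5), "P1", "universal"),
               class = "gf_lookup_error")
})

test_that("fuzzy frequency counts threshold crossings and is monotone in c", {
  tt <- toy()
  g <- tt$graph; co <- tt$corpus
  prots <- paste0("P", 1:5)
  # brute-force the five universal scores for G5
  scores <- vapply(prots, function(p)
    fuzzy_score(g, co, gid(5), p, "universal"), numeric(1L))
  for (c_level in c(0.1, 0.3, 0.7, 1)) {
    expect_equal(fuzzy_frequency(g, co, gid(5), prots, "universal",
                                 agreement = c_level),
                 sum(scores >= c_level))
  }
  # non-increasing in c
  ffs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 1), function(c_level)
    fuzzy_frequency(g, co, gid(5), prots, "universal",
                    agreement = c_level), numeric(1L))
  expect_true(all(diff(ffs) <= 0))
  # ff at c = 1 never exceeds the closure count
  expect_lte(ffs[length(ffs)], unname(tt$usage$counts[[gid(5)]]))
  # the root is uninformative: MICA-based scores to it are 0, so ff = 0
  expect_equal(fuzzy_frequency(g, co, gid(1), prots, "universal",
                               agreement = 0.3), 0)
  expect_equal(fuzzy_frequency(g, co, gid(1), prots, "zhang",
                               agreement = 0.3), 0)
  expect_equal(fuzzy_frequency(g, co, gid(1), prots, "resnik", tt$ic,
                               agreement = 0.3), 0)
  expect_error(fuzzy_frequency(g, co, gid(5), prots, "universal",
                               agreement = 0), class = "gf_parameter_error")
})

test_that("hypergeometric and binomial tails match hand enumeration", {
  expect_equal(hypergeom_pvalue(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(10, 4, 5, 0), 1)
  expect_equal(hypergeom_pvalue(10, 10, 10, 10), 1)
  expect_equal(binomial_pvalue(5, 0.4, 3), 0.31744, tolerance = 1e-12)
  expect_equal(binomial_pvalue(5, 0, 1), 0)
  expect_equal(binomial_pvalue(5, 0.4, 0), 1)
  expect_error(hypergeom_pvalue(10, 11, 5, 3), class = "gf_parameter_error")
  expect_error(binomial_pvalue(5, 1.2, 3), class = "gf_parameter_error")
})

test_that("Bonferroni correction caps at 1 and preserves order", {
  expect_equal(bonferroni(c(2.42e-14, 2.75e-14), k = 4),
               c(9.68e-14, 1.10e-13))
  expect_equal(bonferroni(0.5, k = 4), 1)
  expect_equal(bonferroni(c(0.01, 0.001)), c(0.02, 0.002))
  expect_error(bonferroni(0.1, k = 0), class = "gf_parameter_error")
  expect_error(bonferroni(c(0.1, 0.2), k = 1), class = "gf_parameter_error")
})

test_that("fuzzy retrieval matches a brute-force scan of the corpus", {
  tt <- toy()
  g <- tt$graph; co <- tt$corpus
  prots <- paste0("P", 1:5)
  res <- fuzzy_retrieve(g, co, gid(5), "universal", agreement = 0.3)
  scores <- vapply(prots, function(p)
    fuzzy_score(g, co, gid(5), p, "universal"), numeric(1L))
  expect_equal(res$n_detected, sum(scores >= 0.3))
  det <- attr(res, "detected")[[gid(5)]]
  expect_setequal(det$protein, names(scores)[scores >= 0.3])
  expect_true(all(diff(det$score) <= 0))  # ranked by descending score
  # the binomial parametrization: reference = corpus itself here
  m <- sum(scores >= 0.3)
  expect_equal(res$p_value, binomial_pvalue(5, m / 5, m))
  # single-term query: corrected equals raw
  expect_equal(res$corrected_p, res$p_value)
})

test_that("retrieval respects limits, namespaces and the zero-detection edge", {
  tt <- toy()
  g <- tt$graph; co <- tt$corpus
  expect_error(fuzzy_retrieve(g, co, rep(gid(5), 21), "universal"),
               class = "gf_input_limit")
  res <- fuzzy_retrieve(g, co, rep(gid(5), 21), "universal", force = TRUE)
  expect_equal(nrow(res), 21L)
  g2 <- parse_obo(two_ns_obo())
  gaf <- paste(c(gaf_line("P1", "a1", "GO:0000002"),
                 gaf_line("P1", "a1", "GO:0000012", aspect = "F")),
               collapse = "\n")
  co2 <- parse_gaf(gaf, g2)
  expect_error(
    fuzzy_retrieve(g2, co2, c("GO:0000002", "GO:0000012"), "universal"),
    class = "gf_namespace_error")
  # a query term similar to nothing: detected empty, p-value 1
  # (P4's branch-B-only term G3 vs a corpus annotated only at G6)
  co3 <- parse_gaf(gaf_line("P1", "katG", gid(6)), g)
  res3 <- fuzzy_retrieve(g, co3, gid(3), "universal", agreement = 0.7)
  expect_equal(res3$n_detected, 0L)
  expect_equal(res3$p_value, 1)
})

test_that("four-term queries reproduce the x4 Bonferroni relation", {
  tt <- toy()
  res <- fuzzy_retrieve(tt$graph, tt$corpus,
                        c(gid(3), gid(4), gid(5), gid(6)),
                        "universal", agreement = 0.3)
  expect_equal(res$corrected_p, pmin(1, res$p_value * 4))
})

test_that("enrichment on the toy corpus matches the hand hypergeometric tail", {
  tt <- toy()
  g <- tt$graph; co <- tt$corpus
  res <- fuzzy_enrich(g, co, c("P2", "P5"), "universal", agreement = 1)
  expect_true(all(c("approach", "term", "name", "level", "ref_ff",
                    "target_ff", "p_value", "corrected_p") %in% names(res)))
  row5 <- res[res$term == gid(5), ]
  # at c = 1 only an exact direct (or similarity-1) annotation counts:
  # G5 annotates P2 and P5 directly -> l = 2, m = 2, N = 5, n = 2
  expect_equal(row5$target_ff, 2L)
  expect_equal(row5$ref_ff, 2L)
  expect_equal(row5$p_value, hypergeom_pvalue(5, 2, 2, 2), tolerance = 1e-12)
  expect_equal(row5$p_value, 1 / choose(5, 2), tolerance = 1e-12)
  # sorted by corrected then raw p-value
  expect_true(all(diff(res$corrected_p) >= 0))
})

test_that("enrichment of the whole reference yields p-value 1 everywhere", {
  tt <- toy()
  res <- fuzzy_enrich(tt$graph, tt$corpus, paste0("P", 1:5), "universal",
                      agreement = 0.3)
  expect_true(all(res$p_value == 1))
  expect_equal(res$target_ff, res$ref_ff)
})

test_that("enrichment input handling: limits, unknown proteins, empty target", {
  tt <- toy()
  g <- tt$graph; co <- tt$corpus
  expect_error(fuzzy_enrich(g, co, character(0L), "universal"),
               class = "gf_parameter_error")
  expect_error(fuzzy_enrich(g, co, paste0("X", 1:3000), "universal"),
               class = "gf_input_limit")
  expect_error(fuzzy_enrich(g, co, c("P2", "nosuch"), "universal"),
               class = "gf_lookup_error")
  expect_message(
    res <- fuzzy_enrich(g, co, c("P2", "nosuch"), "universal",
                        strict = FALSE),
    "skipping")
  expect_true(nrow(res) > 0L)
})
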
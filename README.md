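# gofunsim

Gene Ontology (GO) semantic similarity, fuzzy term statistics and
functional clustering in R.

## Who this is for

Computational biologists who need, without a web service in the loop:

* GO **term information content** under an annotation (corpus-frequency)
  model and three topology models;
* pairwise GO **term semantic similarity** under nine approaches;
* **protein functional similarity** under the canonical grid of 27 named
  configurations;
* **fuzzy agreement-level statistics**: retrieval of proteins by GO term
  (binomial test) and term enrichment analysis (hypergeometric test),
  both Bonferroni-corrected;
* **protein clustering**: hierarchical with Newick export, and spectral
  k-means.

Inputs are standard flat files — an ontology in OBO 1.2 (`is_a`,
`part_of`) and annotations in GAF 2.x — plus plain-text query lists.

## The model in brief

For a term `t` with corpus usage probability `p(t)` (fraction of proteins
whose annotation closure contains `t`), the annotation IC is
`IC(t) = -ln p(t)`.  Topology ICs come from descendant-leaf counting
(`IC_Z = -ln(D(t)/D(root))`), from the topological-position recursion
(`A(t) = prod_p A(p)/|children(p)|`, `IC_U = -ln A`), or from per-anchor
semantic-contribution S-values (edge weights 0.8 / 0.6).

Term similarity `S(t1, t2) ∈ [0, 1]` uses the most informative common
ancestor (Resnik, Lin, Relevance, Li), the mean over all informative
common ancestors (XGraSM), S-value overlap (Wang), or the Lin form over
topology IC (Zhang, GO-universal).  Protein similarity either combines
the term-similarity matrix of two proteins' direct term sets (`avg`,
`max`, `bma`, `abm`) or weights their annotation closures directly
(`simgic`, `simdic`, `simuic`, `simui`).  `measure_registry()` enumerates
the 27 canonical configurations.

The fuzzy score of term `t` for protein `g` is
`A_g(t) = max{S(t, s) : s in direct terms of g}`; at agreement level
`c` (moderate 0.3, high 0.7, perfect 1.0) the fuzzy frequency `ff(t)`
counts proteins with `A_g(t) >= c`, and feeds the binomial (retrieval)
and hypergeometric (enrichment) upper-tail tests.

See `vignettes/gofunsim-methods.Rmd` for formulas, parameter rationale
and numerical edge cases.

## Worked example

Everything below runs on the built-in six-term / five-protein toy
fixture; all printed numbers are hand-checkable.

```r
library(gofunsim)

fx <- toy_fixture()
g  <- parse_obo(fx$obo_text)
co <- parse_gaf(fx$gaf_text, g)
ic <- annotation_ic(term_usage(co, g, "biological_process"))

round(ic$values, 4)
#> GO:0000001 GO:0000002 GO:0000003 GO:0000004 GO:0000005 GO:0000006
#>     0.0000     0.2231     0.5108     0.9163     0.9163     1.6094
```

The root carries no information; `GO:0000006` is used by 1 of 5 proteins,
so `IC = -ln 0.2 = 1.6094`.

```r
term_similarity(g, "GO:0000004", "GO:0000005", "lin", ic)
#> [1] 0.2435292
protein_similarity(g, co, "P5", "P2", "lin-bma", ic)
#> [1] 0.8479186
```

The two sibling terms share the weakly informative ancestor
`GO:0000002`, hence the low Lin score; proteins P5 = {G2, G5} and
P2 = {G5} share a direct term, so their best-match-average similarity is
high.

```r
fuzzy_enrich(g, co, c("P2", "P5"), "universal", agreement = 1)
#>   approach       term                name level ref_ff target_ff p_value corrected_p
#>  universal GO:0000005 process A2 within B     2      2         2     0.1         0.2
#>  universal GO:0000002            branch A     1      1         1     0.4         0.8
```

At perfect agreement (`c = 1`) only exact annotations count:
`GO:0000005` annotates both target proteins and only them in the 5-protein
reference, giving the hypergeometric tail `1/C(5,2) = 0.1`, corrected
over the 2 tested terms.

```r
sim  <- protein_sim_matrix(g, co, paste0("P", 1:5), "lin-bma", ic)
cluster_hierarchical(sim)$newick
#> ((P1:0.1372172704,P3:0.1372172704):0.279309014,(P4:0.1868002956,(P2:0.07604071498,P5:0.07604071498):0.1107595806):0.2297259888);
```

P2 and P5 (sharing a direct term) merge first at distance
`1 - 0.848 = 0.152` split evenly across the two branches.

## Command line

```sh
Rscript exec/gofunsim fixtures --dir demo
Rscript exec/gofunsim ic       --obo demo/toy.obo --gaf demo/toy.gaf \
    --terms ids.txt --approach annotation
Rscript exec/gofunsim termsim  --obo demo/toy.obo --gaf demo/toy.gaf \
    --pairs pairs.txt --approach lin
Rscript exec/gofunsim retrieve --obo demo/toy.obo --gaf demo/toy.gaf \
    --terms ids.txt --approach universal --agreement 0.3
Rscript exec/gofunsim enrich   --obo demo/toy.obo --gaf demo/toy.gaf \
    --proteins prot.txt --approach universal
Rscript exec/gofunsim cluster  --obo demo/toy.obo --gaf demo/toy.gaf \
    --proteins prot.txt --measure lin-bma --method kmeans --k 2
```

Output is TSV on stdout (or `--out`).  Exit codes: 0 success, 2 input
limit exceeded, 3 parse error, 4 lookup error, 5 parameter error.  Input
limits (5000 ids / 3000 pairs / 20 query terms / 2000 target proteins /
200 cluster proteins) are defaults, overridable with `--limit`/`--force`.

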
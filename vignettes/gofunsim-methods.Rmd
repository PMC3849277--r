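---
title: "Methods: GO information content, semantic similarity and fuzzy term statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GO information content, semantic similarity and fuzzy term statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gofunsim)
```

## The problem

Gene Ontology (GO) annotations describe gene products in three namespaces
(biological process, molecular function, cellular component), each a
directed acyclic graph whose terms are linked upward by `is_a` and
`part_of`.  Two questions recur in functional analysis: *how similar are
two terms* (and, by extension, two annotated proteins), and *which terms
are over-represented* in a protein set.  This package implements an
information-content (IC) based answer to both, plus functional clustering
on top of the similarity layer.

Only `is_a` and `part_of` edges are retained; every other relationship
type is dropped at parse time, and all computations are namespace-local.
The *annotation closure* of a protein is its direct term set plus all
ancestors (the true-path rule).

## Information content

Four models, all in natural-log units (every normalized quantity is
base-invariant, so the base is a free choice), all zero at the namespace
root:

* **annotation**: $IC(t) = -\ln p(t)$, where $p(t) = f(t)/f(\mathrm{root})$
  and $f(t)$ counts *proteins* whose closure contains $t$.  Protein-level
  counting (rather than annotation-row counting) avoids bias from
  redundantly annotated proteins and makes $p$ a proper proportion.  Terms
  unused in the corpus have **no** annotation IC: queries touching them
  raise a "term unused in corpus" error rather than silently imputing a
  value.
* **zhang** (descendant-leaf counting): $D(t)=1$ at leaves,
  $D(t)=\sum_{c \in \mathrm{children}(t)} D(c)$ otherwise;
  $IC_Z(t) = -\ln(D(t)/D(\mathrm{root}))$.
* **universal** (topological position): $A(\mathrm{root})=1$,
  $A(t)=\prod_{p \in \mathrm{parents}(t)} A(p)/|\mathrm{children}(p)|$,
  $IC_U(t) = -\ln A(t)$, evaluated in topological order.
* **S-values** (semantic contribution, used by the `wang` approach):
  anchored per term; the anchor contributes 1 to itself and every ancestor
  $a$ receives $\max_c w(c \to a)\, S(c)$ over its children $c$ inside the
  anchor's ancestor graph, with weights $w_{is\_a}=0.8$ and
  $w_{part\_of}=0.6$ (the literature-standard contribution factors,
  exposed as configuration and validated to lie in $(0,1)$).

The zhang and universal recursions are stated here precisely because the
literature names the approaches without always restating them; the tests
pin these formulations down on a six-term toy ontology where every value
is hand-derivable.

The *uniformized* IC $u(t) = IC(t)/IC_{\max}$ maps a namespace to
$[0, 1]$ and is what the Resnik-style scores are normalized by, so that
scores are comparable across approaches.

## Term similarity

Nine approaches, all clamped to $[0,1]$.  With $M$ = the most informative
common ancestor (MICA; ties broken by lexicographically smallest term id,
so the choice is deterministic):

| approach | score for $t_1 \ne t_2$ |
|---|---|
| `resnik` | $IC(M)/IC_{\max}$ |
| `lin` | $2\,IC(M)/(IC(t_1)+IC(t_2))$ (0 when the denominator is 0) |
| `relevance` | Lin $\times\; (1 - p(M))$ |
| `li` | Lin $\times\; (1 - 1/(1+IC(M)))$ |
| `xgrasm` / `xgrasm_resnik` | as Lin / Resnik but with the **mean** IC over all informative common ancestors (IC $> 0$); 0 when none exist |
| `wang` | $\sum_{t \in CA}(S_{t_1}(t)+S_{t_2}(t)) \,/\, (SV(t_1)+SV(t_2))$ over common inclusive ancestors |
| `zhang` | Lin form over $IC_Z$ |
| `universal` | $IC_U(M)/\max(IC_U(t_1), IC_U(t_2))$ |

Jiang–Conrath is deliberately *not* a separate approach: it is the
unnormalized distance derived from Lin's measure.  XGraSM ships in both
flavors because the canonical measure table lists a single XGraSM row
without fixing the base; `xgrasm` aliases the Lin flavor, and the
27-configuration registry counts XGraSM once.

**Self pairs are set to 1 under every approach.**  The raw formulas
disagree here (uniformized Resnik would give $IC(t)/IC_{\max} < 1$, and
Lin's zero-denominator rule would zero out uninformative self pairs), but
self-identity is what every downstream contract assumes — a term directly
annotating a protein must give fuzzy score 1, and a protein must be
functionally identical to itself.  The formulas therefore apply to
distinct pairs only.  A consequence worth knowing: MICA-based similarity
*to* the root from any other term is 0, since the root carries no
information.

## Protein similarity: 27 configurations

Two routes:

* **Combiners** over the $n \times m$ term-similarity matrix of the two
  proteins' direct term sets: `avg` (mean of all entries), `max`, `abm`
  (pooled row and column maxima over $n+m$) and `bma` (mean of the two
  directional best-match averages).  `abm` and `bma` coincide exactly when
  $n = m$.
* **Direct closure-overlap measures** weighting annotation closures by IC:
  `simgic` (Jaccard), `simdic` (Dice), `simuic` (universal index) and
  `simui` (unweighted Jaccard, needing no IC).

The canonical registry is the full grid: the three IC-weighted direct
measures on the annotation row; {`xgrasm`, `resnik`, `lin`, `li`,
`relevance`} $\times$ {`bma`, `abm`, `avg`, `max`}; `simui`; and the
topology approaches bound to their published combiner (`zhang`–`abm`,
`wang`–`abm`, `universal`–`bma`) — 27 labels in total.  The API also
accepts off-registry approach/combiner combinations and any IC table for
the direct measures, since evaluating annotation measures under topology
IC is a known open direction.

Two deliberate policy points:

* A protein without annotation in the requested namespace scores `NA`,
  never 0 — a zero would be indistinguishable from genuine dissimilarity.
* The `avg` combiner, being the mean of *all* entries, does **not**
  satisfy self-similarity 1 (no mean of a matrix with off-diagonal entries
  below 1 can); its self-score is the mean of the self matrix.  This is a
  property of the average combiner itself, long noted in the functional
  similarity literature, and the test suite asserts the defined value
  rather than pretending otherwise.  All other 23 configurations do
  satisfy self-similarity 1.

## Fuzzy agreement-level statistics

The fuzzy annotation score of term $t$ for protein $g$ is
$A_g(t) = \max\{S(t, s) : s \in T_g\}$ over the protein's **direct** term
set (the closure is not used here; the statistic needs a term-vs-term
similarity, so the direct closure-overlap measures do not apply).  At
agreement level $c \in (0,1]$, term $t$ "fuzzy occurs" through $g$ when
$A_g(t) \ge c$, and the fuzzy frequency $f\!f(t)$ of a protein set counts
such proteins.  Presets: moderate $c=0.3$ (default), high $c=0.7$,
perfect $c=1$ — the last recovering the classical crisp statistics.
$f\!f$ is non-increasing in $c$ by construction.

* **Retrieval** (`fuzzy_retrieve`): for each query term, the detected set
  is $\{g : A_g(t) \ge c\}$, ranked by descending score.  The detection
  count is tested with an upper-tail binomial, $n$ = number of annotated
  proteins scanned, success probability = the term's *relative fuzzy
  frequency in the reference corpus at the same agreement level*.  This
  parametrization is the natural reading of "relative frequency of
  occurrence in the reference dataset as an estimator of $p$"; the
  reference corpus is an explicit argument (defaulting to the scanned
  corpus) because the served tool's choice of background is not
  documented.  Bonferroni $k$ = number of query terms.
* **Enrichment** (`fuzzy_enrich`): every namespace term with nonzero
  target fuzzy frequency is tested with the upper-tail hypergeometric
  ($N$ = reference proteins, $m$ = reference fuzzy frequency, $n$ =
  target size, $\ell$ = target fuzzy frequency); Bonferroni $k$ = number
  of tested terms; rows sorted by corrected then raw p-value.

Both tails delegate to R's `phyper`/`pbinom`, which are log-space stable;
the test suite checks them against an explicit enumeration oracle
(exact to double rounding for $N \le 60$, comfortably inside the 1e-12
comparison tolerance — no arbitrary-precision arithmetic is available in
the target environment) and checks the binomial approximation's
convergence to the hypergeometric as $N$ grows.  P-values are *displayed*
as two-decimal scientific notation (`2.42e-14`) while full precision is
kept internally.

## Clustering

`protein_sim_matrix` scores all pairs under one measure, dropping
unannotated proteins with a warning.  Distance is $d = 1 - s$ — the
minimal monotone transform keeping $d \in [0,1]$; the source application
never states its transform, so dendrogram figures are not an
exact-reproduction target.  Hierarchical clustering is agglomerative
(`stats::hclust`) with average linkage by default (the standard choice
for similarity-derived distances), serialized to Newick with branch
lengths on the distance scale.  `NA` pairs are refused; the repair policy
(`drop_na_proteins`) removes the protein with the most missing entries
until the matrix is complete — imputation would invent similarity.

Spectral k-means embeds the similarity graph through the normalized
Laplacian $L = I - D^{-1/2} S D^{-1/2}$ into the $k$ bottom eigenvectors,
row-normalizes, and runs k-means with k-means++ initialization at a
caller-supplied seed (deterministic per seed; the user must supply $k$,
with $2 \le k < n$ enforced).

## The synthetic world

The toy fixture is a six-term, five-protein world in which *every*
intermediate quantity (closures, all four IC models, each term and
protein score, the test tails) is hand-derivable; it is byte-stable and
emitted as real OBO/GAF text so the parsers run on every test.  The
random generator grows a rooted DAG in topological construction order
(acyclic by construction), attaches 1–3 parents per term with a
configurable `part_of` fraction, and annotates proteins uniformly with
non-root terms.  Defaults (50 terms, 3 parents max, 20% `part_of`, 10
proteins, 2 annotations each) are sized for property tests, not for
realism: the generator makes no attempt to match real GO degree or
annotation-depth distributions, so a green property suite establishes
algebraic correctness (symmetry, ranges, dominance inequalities, oracle
equivalence), not biological performance claims.  Instances used in the
1000-corpus axiom sweep are deliberately tiny (12 terms, 5 proteins) to
keep the sweep inside its time budget; the properties checked are
size-invariant.

## Numerical and edge-case choices

* Term level = **longest** path to the namespace root (root level 0) —
  the depth-as-specificity convention; printed levels of real GO releases
  are not an acceptance surface.
* Cycles, cross-namespace parentage, and multi-root namespaces are hard
  parse errors (the cycle error names an edge on the cycle); unknown
  parent references and malformed GAF lines are logged and skipped unless
  `strict = TRUE`.
* `alt_id` resolution is transparent everywhere; obsolete terms are
  absent entirely (their ids resolve only if listed as `alt_id` of a live
  term).
* Degenerate direct-measure input — both closures with zero total IC — is
  a classed error ("undefined similarity"), not a 0 or 1.
* All scores are clamped to $[0,1]$ after evaluation; ties in MICA choice
  and in input ordering are broken lexicographically / by input order, so
  every command is byte-reproducible given (inputs, configuration, seed).
* CLI input limits (5000 ids, 3000 pairs, 20 query terms, 2000 target
  proteins, 200 cluster proteins) mirror the served defaults but are
  overridable (`--force`/`--limit`) since they reflect server resources,
  not the method.

## Known limitations

* Only `is_a`/`part_of` semantics; no OWL, no regulates, no
  cross-namespace links.
* Annotation IC requires the term to occur in the corpus; no smoothing or
  imputation is offered.
* The original graph-based disjunctive-common-ancestor measure (GraSM) is
  excluded by design (computationally unattractive for the gain), as is
  community-detection ("model-based") clustering.
* The corpus layer holds everything in memory; it is sized for
  organism-scale corpora, not the full multi-organism annotation database.
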
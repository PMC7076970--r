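---
title: "Methods: library construction and exact over-representation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: library construction and exact over-representation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

enrichkit implements over-representation analysis (ORA): given a query
gene set (differentially expressed genes, a co-expression module, a
peak-associated gene list, ...), it asks, term by term, whether the
query contains more members of the term's gene set than expected if the
query had been drawn uniformly from a background population.

For a background of $N$ genes of which $K$ carry a term, and a query of
$n$ background genes overlapping the term in $k$, the null
distribution of $k$ is hypergeometric and the enrichment p-value is the
exact upper tail

$$
P(X \ge k) \;=\; \sum_{i=k}^{\min(n,K)}
\frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}} .
$$

The one-sided (greater) Fisher exact test on the $2\times2$ table
$[[k, n-k], [K-k, N-K-n+k]]$ is the same quantity derived from the
other margin. `hypergeom_upper_tail()` and `fisher_exact_greater()`
deliberately implement the two derivations separately — one conditions
on drawing $n$ genes from the $K$/$N-K$ split, the other on
distributing the $K$ term genes over the $n$/$N-n$ split — and the test
suite asserts their agreement to $10^{-12}$ relative error on every
feasible table with $N \le 60$, alongside a direct `choose()`-based
enumeration oracle. Only enrichment is tested; depletion (the lower
tail) is out of scope.

Both tails are accumulated in log space (`lchoose` terms combined with
a running log-sum-exp from the top of the support), so p-values remain
accurate far below the double-precision underflow threshold of a naive
product; the returned value only degrades to 0 when the probability
itself is smaller than roughly $10^{-308}$.

Multiple-testing correction runs across exactly the family of tested
terms. `adjust_pvalues()` hand-implements Benjamini–Hochberg step-up
(with the cumulative-minimum monotonicity enforcement and cap at 1),
Benjamini–Yekutieli (BH scaled by the harmonic sum) and Bonferroni;
`stats::p.adjust` and an independent double-loop step-up serve as
oracles in the tests, never as the implementation. Because "FDR" and
"BH" name the same procedure in the common ecosystems, `"fdr"` is
accepted as an alias of `"BH"`.

## Library construction

A *species library* maps term ids to gene-symbol sets for one species
and one database, and fixes the default background: the species
*universe*, taken as **all** official symbols in the NCBI-style
gene_info table, not only annotated genes. A tissue-specific or
array-specific background can replace it at analysis time.

The GO path parses an OBO 1.2 ontology and GAF or gene2go annotations
and applies the true-path rule: a gene annotated to a term is
propagated to every ancestor over the `is_a` and `part_of` relations.
That relation set is this package's documented choice — it is the
standard GO propagation convention; other OBO relationship types
(`regulates`, `has_part`, ...) are parsed past and ignored, and
cross-namespace edges are followed as written, with namespace filtering
deferred to reporting. Obsolete terms are parsed and flagged but never
receive annotations (they carry no parents, so propagating through them
would silently truncate), and alternative ids resolve transparently to
their primary term everywhere annotations are ingested.

Annotation hygiene:

* **NOT qualifiers.** An annotation whose qualifier contains `NOT`
  asserts *absence* of function; counting it would invert its meaning.
  Such rows are parsed losslessly and flagged, and the builders drop
  them.
* **Evidence codes.** No evidence filtering happens by default — the
  build is inclusive — but an exclusion list (e.g. `IEA`) is a build
  option.
* **Gene identity.** The user-facing identifier space is the official
  gene symbol. Numeric gene ids translate through gene_info; synonyms
  resolve only when they name exactly one official symbol; unresolved
  keys are kept verbatim through parsing (with a reported count) and
  are then dropped at library assembly because they fall outside the
  species universe — the same rule the flat-library path applies. The
  drop counts are reported in the build statistics rather than silently
  swallowed.

Pathway and disease sources (KEGG-like, Reactome-like, DISEASES
channels, DisGeNET-like) enter as flat three-column term–gene tables.
The DISEASES channels (text mining, knowledge, experiments) are merged
into one non-redundant pair set with per-pair channel provenance before
building. The disease path is deliberately flat: no Disease Ontology
DAG propagation is performed (a possible extension, but the channel
tables are themselves flat annotation products). Terms left empty after
universe filtering are pruned — a term with $K = 0$ is untestable and
would only clutter the correction family.

Built libraries persist as sorted, tab-separated text with a version
marker, metadata header and one gene per row; universe genes without
annotations are written with `-` placeholders so the full background
round-trips exactly. Rebuilding from identical inputs is byte-identical
apart from the timestamp line.

## Analysis-time semantics

* **Background resolution.** Default: the library universe. A user
  background is trimmed, de-duplicated and intersected with the
  universe (unrecognised symbols reported). When a custom background is
  in force, *both* the query and every term's gene set are restricted
  to it before counting, so $k$, $n$, $K$ and $N$ are mutually
  consistent — the statistically coherent reading.
* **Size window.** Terms with fewer than `min_term_size = 3` or more
  than `max_term_size = 5000` background-restricted genes are excluded
  from testing *and* from the correction family; 1–2-gene terms cannot
  reach conventional significance and only dilute the FDR control.
  Both bounds are overridable.
* **Significance flag.** `q_cutoff = 0.05` only flags rows (and selects
  the plotted subset); the full tested table is always returned and
  written.
* **Determinism.** Ties sort by term id after p-value; gene lists are
  sorted and semicolon-joined; query symbols are whitespace-trimmed and
  case-sensitively matched (case is meaningful across species);
  duplicates collapse with a reported count. Identical inputs therefore
  produce byte-identical result files.

## Visualisation

Bar plots draw the top terms (default 20, ranked by q-value) with bar
length $-\log_{10} q$; q is floored at $10^{-300}$ so a zero q-value
yields a finite bar. Bubble plots put fold enrichment $(k/n)/(K/N)$ (or
the gene ratio $k/n$) on x, rank terms on y, scale bubble area by $k$
and colour by q on a reversed scale. Term names are truncated at 60
characters for layout; full names remain in the TSV. Plot functions
never mutate the table, and vector output is stable across identical
runs up to embedded timestamps.

## The synthetic fixture generator

`generate_fixture()` stands in for the external downloads a real build
consumes. From a single seed it emulates: a single-rooted random DAG
ontology of `n_terms` terms (depth ≤ `dag_depth`, mostly `is_a` edges
with occasional `part_of`), a universe of `n_genes` symbols with
sporadic synonyms, direct annotations (1–3 terms per gene) rendered
consistently as both GAF and gene2go, flat pathway/disease/DisGeNET
tables, a query of `query_size` genes, a full-universe background, and
a machine-readable truth file.

Planted signal: `planted_terms` leaf terms are given direct annotation
sets of at least `max(20, ceiling(effect * query_size) + 5)` genes, and
each contributes `ceiling(effect * query_size)` genes to the query
(ceiling, because the product is fractional at the defaults
`effect = 0.5`, `query_size = 25`); the rest of the query is uniform
from the remaining universe. Each planted term is mirrored as an extra
pathway entry so the flat path carries the same ground truth. The
defaults — 200 genes, 30 terms, depth 4, one planted term, effect 0.5,
query 25 — are the study conditions used throughout the validation
suite: small enough for thousands of replicates, large enough that a
planted effect of half the query is unambiguous against a
hypergeometric null.

What the generator does **not** emulate: correlated annotations
(real GO terms overlap strongly along the DAG beyond what propagation
induces), skewed term-size distributions spanning five orders of
magnitude, inter-gene dependence in real queries (co-regulation), or
identifier noise beyond simple synonyms. Passing the planted-recovery
and calibration checks therefore demonstrates the machinery is correct
and well-calibrated under its stated null, not that any biological
conclusion from real data is right.

## Validation design and problem sizes

The suite checks, among others:

* tail identity and brute-force agreement on all ~630k feasible tables
  with $N \le 60$;
* BH/BY/Bonferroni against a textbook double-loop oracle on 1000
  random p-vectors (lengths 1–200) plus elementwise dominance;
* propagation against a per-gene naive-DFS construction on 100 random
  fixtures (≤ 50 genes, ≤ 15 terms) with parent-superset monotonicity
  on every edge;
* null calibration: 1000 uniform queries against one mid-sized fixture
  term, with the rejection rate at $p \le 0.05$ required to sit inside
  the 99% binomial interval around the *exact attainable level*
  computed by pmf enumeration — the test is discrete, so that level is
  below 0.05 and the test is conservative by construction;
* planted-signal recovery over 100 seeded end-to-end CLI runs
  (fixture → `make-species-db` → `enrich` → TSV), requiring the planted
  term to rank first by p in ≥ 95% and reach $q < 0.05$ in ≥ 90%;
* byte-level determinism of fixtures, libraries and CLI outputs.

These sizes were chosen as the smallest at which each property is
sharply testable.

## Known limitations

* No GSEA-style ranked-list statistics, gene permutation or
  topology-aware pathway scoring — the statistic is the exact 2×2 tail.
* No two-sided or depletion tests.
* The GAF reader keys on object symbols (column 3); for non-model
  species whose GAF carries protein accessions unmatched in gene_info,
  those annotations drop out with a reported count rather than being
  rescued by cross-reference lookup.
* No network retrieval: the package consumes already-downloaded files,
  with the fixture generator standing in for downloads during testing.
* SVG output requires a cairo-capable R build; PNG and PDF are always
  available.
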
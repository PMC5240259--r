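---
title: "Coordinated multi-omic containers: model, semantics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinated multi-omic containers: model, semantics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicstack)
```

## The problem and the model

Cohort studies that assay the same subjects on several omic platforms end up
with a set of feature × sample matrices whose sample sets overlap but rarely
coincide: arrays fail, samples are depleted, platforms are added late. Most
integration methods, however, consume a *list of matrices over identical,
identically ordered samples*. The `multiset` container manages the gap. It
stores, per dataset, the assay layers, the sample annotation, the feature
annotation, the optional genomic feature ranges and a reconstruction recipe
— five parallel collections keyed by dataset — and enforces one invariant at
a single choke point (ingestion): within a dataset, every assay layer's
columns equal the sample-annotation ids and every layer's rows equal the
feature-annotation ids (and the range table's ids, when present), in
identical order. Across datasets, no constraint is imposed: sample sets may
differ freely.

Sample annotation is deliberately kept per dataset rather than merged into
one phenotype table. Technical covariates (batch, plate, scan date) have the
same column names but different meanings on different platforms; in
longitudinal designs even "age" differs between assays collected years
apart; and per-dataset storage is what makes exact recovery of the original
datasets possible after container-level subsetting.

### Union vs intersection subsetting

`select_samples(ms, S)` restricts every dataset to its own intersection with
`S` — the union philosophy. Given tables on sample sets {A,B}, {A,B,C} and
{A,C}, selecting {A,C} yields {A}, {A,C}, {A,C}: no dataset is discarded and
no information is thrown away prematurely. The complete-case view is a
separate, explicit operation, `common_samples()`, which also fixes one
canonical column order (the first stored dataset's sample order) because the
matrix-list consumers downstream require all blocks to share column order,
not merely column sets. Zero-sample datasets are retained by
`select_samples()` (selecting absent ids empties a dataset rather than
dropping it); whether a container-level selection should ever remove a
dataset was genuinely open, and keeping them makes the union law —
`samples(select_samples(ms, S), d) = samples(ms, d) ∩ S` for every dataset
`d` — hold uniformly. The suite property-tests this law, idempotence, and
commutation of the two verbs against brute-force oracles on randomized
containers.

### Genomic coordinates

Coordinates are stored as 1-based closed intervals, the convention of the
ecosystem this container lives in; BED input/output converts at the boundary
(a BED line `chr1 99 200` becomes `chr1:100–200`). Overlap in
`select_range()` is closed-interval — touching intervals overlap — computed
with `GenomicRanges::findOverlaps()` and verified in the tests against an
exhaustive O(features × intervals) scan on randomized instances. Strand is
ignored unless a query interval specifies `+` or `-`, in which case feature
strands must match; subsetting by region is almost always strand-agnostic in
practice, so the stranded path is opt-in per interval. Datasets without
coordinates (metabolomics here) are discarded by range queries — absent
ranges are modelled as *absent*, not as all-missing rows, so "no
coordinates" and "no features left" stay distinguishable.

### Ingestion, typed adders and reconstruction

Two basic functions do all mutation: `add_generic()` (ranges derived from
recognised feature-annotation columns: `chromosome`/`chr`,
`start`/`position`, optional `end` defaulting to `start`, case-insensitive)
and `add_ranged()` (explicit ranges). The typed adders layer schemas on top:
expression requires coordinates; methylation requires coordinates and a
primary layer inside [0, 1]; SNP requires a `call` layer coded {0, 1, 2, NA}
(extra layers such as call probabilities are preserved). These concrete
check lists are this package's choice of minimal schemas that make range
subsetting and the correlation stage work; the typed surface, not the exact
list, is the point. A sample-annotation `id` column, when present, overrides
assay column names positionally and must be unique. Keys render as `tag` or
`tag+name` with `+` reserved as separator, so rendered keys parse
unambiguously.

Every dataset carries a recipe (declared class, layer names, extras), and
`reconstruct()`/`extract()` return a bundle equal to what was ingested,
restricted to any subsetting applied since — the round-trip law is
property-tested on randomized bundles.

## The proteome extension

`add_proteome()` demonstrates the extension pattern: a new omic type with
its own schema (a `raw` layer plus a limit-of-detection table covering every
protein) entering through the same basic functions. `apply_lod()` replaces
cells below a protein's lower limit by `lower_lod/2` by default —
half-the-LOD being the standard simple substitution in targeted proteomics —
with `lower_lod/sqrt(2)` and set-to-missing selectable; cells above the
upper limit are truncated to it. The raw layer is never modified, and the
out-of-range mask is kept explicitly (stored as a third, categorical assay
layer, `lod_mask`, so every subsetting path restricts it for free) rather
than replacing values silently. The transform is idempotent by construction:
all imputed values are themselves below the lower limit and re-impute to
themselves, truncated values sit exactly at the upper limit.

## The methylation–expression correlation stage

`meth_expr_correlation()` follows a four-step shape: (1) structural checks
only — per-dataset consistency was already enforced at ingestion, so the
function verifies presence, ranges, covariate columns and a minimum number
of shared samples; (2) `common_samples()` plus aligned primary-layer
matrices; (3) pairing and statistics; (4) Benjamini–Hochberg adjustment and
sorting.

Pairing expands each expression feature's range by ±`flank` bp (default
250,000 bp, the conventional cis window in expression-methylation scans;
configurable) and pairs it with every CpG position inside. The reported
distance is 0 for a CpG inside the unexpanded range, else the distance to
the nearer edge, hence never exceeds `flank`. For the statistics, both
variables are residualised on the covariates (intercept always included;
covariate values are read from the methylation dataset's annotation, since
annotations are stored per dataset — the columns must exist in both), and
the residual Pearson r, the slope of expression on methylation, and a
two-sided t p-value on n − 2 − k degrees of freedom are computed. With no
covariates this is exactly the plain Pearson test, which the suite asserts
against direct `cor()`/`cor.test()` oracles to 1e-12. The residual-Pearson
choice itself is a documented design decision of this package: the staging
(check, prepare, integrate, format) is the contract; the statistical core
was open, and a linear covariate-adjusted association is the simplest
defensible default.

Numerical edge cases: a pair whose residualised variance is numerically
indistinguishable from the rounding noise of residualising a constant
(threshold `n·(1e-10·(1+max|v|))²` on the residual sum of squares) is
emitted with missing statistics rather than dropped or reported with a
garbage correlation; `min_samples` defaults to 5 because t-based p-values
below that are meaningless; correlations are clamped to [−1, 1] against
rounding.

## Synthetic data: what it emulates and what it does not

All tests run on fixtures from one seeded generator, `generate_fixture()`.
The default spec realises the conditions the package is exercised under:

* three tables on sample sets {A,B}, {A,B,C}, {A,C} — the canonical
  union-subsetting scenario;
* a methylation + expression pair on 50 shared samples: genes every 1 Mb on
  one chromosome (so, with a sub-500 kb flank, each body CpG pairs with
  exactly one gene), 5 genes carrying a planted CpG with expression =
  2·beta + N(0, 0.1²), 100 genes carrying an independent null CpG, and a
  few CpGs placed tens of Mb from any gene;
* a SNP set with call and probability layers, a proteome with 10% of cells
  below and 5% above the per-protein detection limits, and an unranged
  metabolome.

The scale configuration (`fixture_spec_scale()`) builds a 45,000-CpG
methylation set, an 80,000-SNP set and a 7,000-probe expression set on 20
samples; the suite builds, range-subsets and exports it, a problem size
chosen as a tenth of a realistic array-era cohort so the whole run stays in
the tens of seconds.

What the generator does *not* emulate: correlation structure among
neighbouring CpGs or linkage disequilibrium among SNPs; batch effects,
missingness patterns and cell-type composition; non-linear or
heteroskedastic methylation–expression relationships; beta-value
distributions massed near 0 and 1. Passing tests therefore certify the
container semantics, the pairing geometry and the statistical calibration
under clean Gaussian/uniform conditions — not robustness of the correlation
stage to the pathologies of real arrays.

## Serialization and the command line

Containers serialize to a directory bundle: TSV matrices and annotation
tables ("NA" for missing, UTF-8), BED for ranges, one `manifest.yaml`
(format version 1.0; readers reject other major versions) recording keys,
declared classes, layer names and — because a zero-row TSV carries no type
information — the storage mode of each layer and annotation column. Values
round-trip bit-exactly: matrices are written with shortest-round-trip
formatting and re-parsed with R's own numeric parser, since the fast
multi-threaded TSV parser is off by one unit in the last place on some
doubles. Integer-typed inputs are normalised to double at ingestion so one
numeric type flows end to end.

The CLI (`inst/cli/omicstack`) wraps the library verbs, logs one line per
dataset per operation (key, dimensions before → after; `--quiet`
suppresses) and maps error classes to exit codes: usage errors exit 2, all
validation/data errors exit 1. Predicates arriving from the command line are
restricted to a comparison grammar (column, literal, comparison and logical
operators, `c(...)`) and are rejected otherwise — a CLI must not evaluate
arbitrary code.

## Known limitations

In-memory matrices only: no backed or sparse storage, so very large cohorts
are bounded by RAM. Accessors return copies, which is safe but not cheap for
repeated access to large assays. The correlation stage tests pairs
independently — no region-level aggregation, no cell-type deconvolution —
and assumes linear associations. Predicate subsetting is intentionally less
expressive than raw R expressions.
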
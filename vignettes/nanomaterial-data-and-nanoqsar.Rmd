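---
title: "Managing nanomaterial safety data and modelling it: the methods behind enmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing nanomaterial safety data and modelling it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmkit)
```

# The problem

Nanomaterial safety data arrive as spreadsheets in whatever layout each
lab prefers, describing materials that a plain chemical-structure database
cannot represent: a nanoparticle is not one molecule but a composed
substance — a core, coatings, functionalisations — whose measured
properties depend on protocols and conditions. Modelling, on the other
hand, wants a clean numeric matrix with one row per material and one
column per comparable quantity. enmkit covers the path between the two:
a substance/protocol-application/measurement data model, a configurable
template importer, a principled replicate aggregator, and a linear
NanoQSAR modelling layer with an applicability domain.

# The data model and its assumptions

A `Substance` owns a composition of `Component`s (role in CORE, COATING,
FUNCTIONALISATION, CONSTITUENT, ADDITIVE, IMPURITY; structure optional —
many coatings are proprietary mixtures with only a name). A
`ProtocolApplication` records one application of a protocol (topcategory
in P-CHEM / TOX / ECOTOX / ENV-FATE, a harmonized-template-like category,
an endpoint, guidelines) with parameters, a citation and a Klimisch
reliability score restricted to {1, 2, 3, 4}; scores are *stored*, never
used to filter — data quality labels travel with the data rather than
silently gating it. A `Measurement` carries one readout under named
conditions; its result is a single value, an interval, a value with an
error, or a text value (e.g. a raw-image path). The validity rules are
deliberately minimal: at least one value form present, `lo <= up`,
`error >= 0`. Everything else — units, condition names — is data, because
enforcing a vocabulary at import time is what makes real templates fail
to import.

Identifiers are name-based UUIDs (version 3, MD5) computed over the RFC
4122 URL namespace and `https://example.org/enm#` + the source field,
prefixed with a four-character source code (`FCSV-...`, `NWKI-...`,
`TOYS-...`). Determinism is the point: importing the same file twice must
address the same records, so import becomes idempotent and cross-file
references stay stable. The store sorts every listing by uuid, making all
derived artifacts independent of insertion order.

Study documents serialize to a fixed-shape camelCase JSON (`loValue`,
`upQualifier`, `errorValue`, ...). Missing numeric fields are emitted as
`null` rather than omitted so that downstream consumers can align columns
without schema negotiation; unknown keys are preserved on parse in an
`extras` slot. The JSON-Schema file in `inst/schema/` is versioned so the
shape can be evolved deliberately.

# The template mapping configuration

The importer is configured, not coded: a JSON document names the layout
(`ROW`, `COLUMN`, `BLOCK`), the substance block (key, name, owner,
composition columns with roles and structure columns) and the study
blocks (protocol literals, parameter/condition locators, endpoint value
locators). Every mapped cell uses exactly one locator form:

* `{"cell": "B2"}` — fixed cell, A1 notation (converted to 0-based
  row/column internally);
* `{"column": name-or-index}` — resolved per record when records are rows;
* `{"row": label-or-index}` — resolved per record when records are columns;
* `{"anchor": {"rowOffset": r, "colOffset": c}}` — relative to the current
  block's first row (BLOCK layout only);
* `{"literal": v}` — a constant; a literal unit always wins over a unit
  cell, and a missing unit is `""`, never a guess.

The keyword set is validated on load and a `row` locator under ROW layout
(or `column` under COLUMN) is rejected as contradictory, because it is
invariably a transposition mistake in the config. Dynamic blocks are
delimited by a start (and optionally end) regular expression; a start
marker without an end closes at the last row with a warning rather than
an error, since truncated exports are common. Cross-sheet organisation —
four sheets describing investigations, particles, protocols and outcomes
— is handled by key-based joins (`sheetLinks`): blocks whose join key
matches are paired. Group/sub-group matching beyond an explicit key is
out of scope; a key column is the one assumption we make about linked
templates.

One substance is created per distinct key (so replicate rows accumulate),
one protocol application per (substance, study mapping), and every
non-empty mapped value cell becomes a measurement. Non-numeric text in a
numeric locator degrades to a `textValue` with a warning — the cell is
preserved, not dropped — and rows with an empty key are skipped and
counted. The parse log reconciles exactly: measurements created equals
non-empty value groups encountered.

Configurations are separate data files on purpose: the mapping of a
confidential template can be withheld while the parser stays open.

# Replicate aggregation with Dixon's Q-test

Building a matrix cell means reducing replicate, interval-valued and
error-annotated measurements to one number:

1. *Scalarization*: a single value is used as is; an interval becomes its
   midpoint (`(lo+up)/2`); a value with a reported error stays the point
   value (the error is metadata, not a different location); text-only
   results are excluded from matrices but kept in the store.
2. *Outlier screening*: Dixon's Q-test on the scalarized replicates. The
   test statistic is a gap/range ratio computed for the most extreme
   value, using the variant recommended for the sample size — r10 for
   n = 3–7, r11 for 8–10, r21 for 11–13, r22 for 14–30 — against
   two-sided critical values (the Rorabacher tabulation; entries were
   additionally verified by Monte Carlo simulation of the null
   distributions at 10^6 replicates). The default level is alpha = 0.05;
   0.10 and 0.01 are available. After an exclusion the reduced sample is
   re-tested. Exclusions are capped at `max(1, floor(n/2) - 1)`: the
   floor term prevents arguing away half a cluster, and the floor of 1
   keeps the smallest tabulated sample (n = 3) testable at all. Samples
   of size 2, size > 30, or with zero range (Q undefined) are never
   touched.
3. *Aggregation*: the arithmetic mean of the kept values. Every cell
   keeps an `AggregationReport` — input count, values used, excluded
   values with their Q and critical values — so an aggregated matrix is
   auditable down to the replicate.

Two measurements share a column exactly when they agree on endpoint,
category and the values of the *distinguishing conditions* of the
endpoint selection. The default set — concentration, exposure time, cell
line, percentile — reflects the conditions under which merging readouts
would be scientifically wrong; it is configurable per selection because
what counts as "the same experiment" genuinely varies by campaign. Units
are never converted: a unit disagreement within a cell (or between a cell
and its column) leaves the cell missing and logs a conflict. Silent
nm/µm mergers are worse than a hole in the matrix.

The aggregator is exposed as its own function (`aggregateValues()`) so
alternative schemes can be swapped in later without touching the matrix
builder.

# PMML feature selection and transformation

Models should declare their inputs in a portable form. The package parses
the PMML `DataDictionary` (which features a model selects) and
`TransformationDictionary` (derived fields computed from them) of PMML
4.x documents. Supported expression nodes are `FieldRef`, `Constant` and
`Apply` with functions `+ - * / abs ln log10 exp`, plus `log2` as a
documented extension (log2-transformed targets are idiomatic for
cell-association modelling). References must point to a data field or an
*earlier* derived field — forward references and cycles are rejected at
parse time, which makes evaluation a single left-to-right pass. Model
elements (e.g. `RegressionModel`) are ignored with a notice on input;
export of a trained linear model writes a minimal `RegressionModel`
document.

PMML field names rarely equal matrix column headers (which embed
conditions and units), so `applySpec()` takes an explicit alias map
rather than guessing. An output cell is missing iff a referenced input is
missing or an arithmetic fault occurred (division by zero, logarithm of a
non-positive value); every fault is logged, never warned row-by-row.

# MLR, preprocessing and the applicability domain

`trainMLR()` is ordinary least squares (via `lm`) of the prediction
feature on the remaining columns, after the PMML transformation and an
optional preprocessing step. Preprocessing (standardize or min–max
scaling; mean or median imputation) is *fitted on the training rows only*
and stored in the model bundle, so queries are transformed with training
statistics — the classic leakage mistake is structurally impossible.
Constant columns cannot be scaled and are flagged and passed through.
Rows with a missing target are dropped with a count; a rank-deficient
design is an error that names the collinear columns, because silently
dropping a coefficient produces models that cannot be exported faithfully.
The fit requires at least p + 2 complete rows.

The applicability domain is the leverage method: for a query x (with
intercept), `h = x'(X'X)^{-1}x` over the training design; the warning
threshold is the conventional `h* = 3p/n`, with p counting the intercept.
Training leverages satisfy `sum(h) = p` and `mean(h) = p/n`, which the
tests verify on random designs; an intercept-only model gives every
training point `h = 1/n`. Predictions from a bundle with an attached AD
carry their leverage and an in/out-of-domain flag.

Model bundles serialize to JSON with the exposed coefficients and an
opaque base64 payload containing the exact numeric state (coefficients,
transformer, AD). The payload round-trips byte-identically, so a reloaded
model predicts bit-identically — reproducibility is checked with
`identical()`, not with a tolerance.

# The JSON train/predict exchange

Algorithms register with a name, metadata, an ontology class (Regression,
Classification, Clustering), parameter definitions and two endpoints —
train and predict. The endpoints here are in-process callables consuming
and producing JSON text; an HTTP front end can wrap them without changing
the contract (an httpuv adapter ships for interactive use). A training
request contains exactly three components — the dataset, the prediction
feature, the tuning parameters — and nothing else from the store; the
model document the service returns is stored verbatim and posted back for
predictions together with the dataset restricted to the model's selected
features. Services therefore keep no state, and the registry cannot
corrupt a model it never interprets. Numbers in the exchange are
serialized at 17 significant digits, which round-trips IEEE doubles
exactly; the wrapped built-in MLR is bit-identical to direct invocation.
Partial least squares, support vector machines and RBF networks are
registered as named placeholders that raise not-implemented: the registry
reserves the names without pretending to implementations.

# Fingerprints and similarity search

Component structures are fingerprinted with OpenBabel's FP2 via
ChemmineR/ChemmineOB: hashed linear substructure paths of up to 7 atoms
folded to 1024 bits. Fingerprints carry a generator tag and comparisons
across tags are errors — similarity values from different generators are
not commensurable. Similarity is the plain Tanimoto coefficient
|A∩B|/|A∪B|; two empty bitsets define 0 with a warning. Bondless
structures such as a bare `[Au]` core legitimately have empty
fingerprints, which is why a search over core+coating particles matches
coatings. Path fingerprints make homologous alkyl amines (octylamine vs
octadecylamine) score 1.0 — a longer chain adds no new path of length
≤ 7 — so reported similarities should be read as path-set overlap, not
as a universal chemical distance; the generator is a tagged strategy
precisely so a ring-aware or circular fingerprint can be swapped in.

# What the fixtures emulate — and what they do not

All tests run on code-generated fixtures with known ground truth:

* `genToyStore()` — 5 materials × {particle size, zeta potential} × 3
  replicates, a quarter of measurements rendered as intervals (centred on
  the drawn value) and a quarter as value+error, one raw-file text
  record, and one injected outlier displaced 10 noise-sd from its cell
  mean (far enough that the n = 4 Q-test rejects it deterministically).
* `genTemplateWorkbook()` — the same data rendered as ROW, COLUMN
  (transpose) and BLOCK sheets with matching configurations; parsing all
  three must give identical stores.
* `genRandomStore()` — up to 50 point measurements across 3–6 substances,
  with replicate sets rejection-sampled so that the Q-test excludes
  nothing; on such stores the matrix must equal a naive group-by-mean
  oracle bit-exactly.
* `genCoronaLike()` — 105 gold nanoparticles with amine coatings, zeta
  potential measured after synthesis and after serum exposure (one
  endpoint distinguished by a `medium` condition), two serum-protein
  relative abundances, and a cell-association target generated on the
  log2 scale as intercept + beta·x + Gaussian noise (sd 0.6) with fixed
  true coefficients (5; 0.05, 0.08 per mV; 2, −1.5 per abundance unit),
  stored on the natural scale so the log2 transform exercises the PMML
  path. Coefficient recovery is checked within 3 standard errors at the
  default seed, exactly for the noiseless variant, and by 95% CI coverage
  (expected in [0.90, 0.99]) over 100 seeded simulations.

What passing these tests shows: the pipeline is algebraically correct,
deterministic, and unbiased under its own assumptions. What it does not
show: real protein-corona data have correlated abundances, heteroscedastic
and non-Gaussian noise, batch effects and missingness patterns none of
which the generator mimics (deliberately — a faithful covariance model
would make ground truth as questionable as the estimate). Conclusions
about real datasets still require validation on those datasets.

# Numerical and design choices

* Dixon level fixed at 0.05 by default; the exclusion cap and zero-range
  behaviour are described above.
* Interval → midpoint and value+error → point value are the documented
  scalarization choices; both are replaceable at the `scalarize()` seam.
* The test suite and the acceptance script use moderate problem sizes —
  50 oracle stores of ≤ 50 measurements, 100 random designs for the
  leverage identities, 100 corona simulations of n = 105 — chosen so the
  whole suite completes in under a minute while keeping Monte Carlo
  margins comfortable.
* XLSX input goes through readxl when available; the shipped fixtures are
  CSV because the layouts, not the container format, are what the mapping
  logic must get right (sheets are normalized to character matrices
  before any mapping).
* The service layer adds no computation: every response body equals the
  corresponding direct library call, which is tested literally.

# Known limitations

No unit conversion (conflicts are surfaced instead); no alternative
outlier schemes yet (the aggregator seam exists); PMML model *import* is
out of scope (only the two dictionaries are interpreted); the RDF
importer reads the constrained RDF/XML shape its predicate map describes,
not arbitrary RDF; substructure (subgraph) search is not provided — only
fingerprint similarity; and the HTTP adapter is a convenience, not a
hardened server (no authentication, JSON only).
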
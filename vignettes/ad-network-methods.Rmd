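---
title: "Methods: discrete Bayesian networks for Alzheimer's disease staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discrete Bayesian networks for Alzheimer's disease staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adbn)
```

## The model

`adbn` works with directed acyclic graphs over binary variables coded
1 = absent/False, 2 = present/True.  Two node kinds exist:

* **Stochastic nodes** follow a categorical distribution conditional on
  their parents, the BUGS `x ~ dcat(p[parents, 1:2])` formulation.  Each
  node carries a conditional probability table (CPT) whose parent axes
  follow the declared parent order and whose *last* axis is the outcome,
  with each parent-state row summing to one.
* **Deterministic max nodes** take the maximum of their members' states.
  Under the 1/2 coding this is a logical OR, the natural aggregator for
  diagnostic read-outs ("the category is present if any contributing
  lesion is").  Max nodes may aggregate other max nodes, but are
  read-outs only: they never parent a stochastic node.

The joint distribution is the usual factorization
$P(N) = \prod_{n \in N} p(n \mid pa(n))$, with max nodes contributing an
indicator factor.  Because all variables are binary, a category's
posterior probability of being present equals its posterior mean on the
1/2 coding minus one ($E = 2p + (1-p)$); `mean_to_probability()` applies
that identity.

The package deliberately rejects nodes with more than two states.  The
categorical machinery would generalize, but every table in the bundled
model is binary and the 1/2 mean identity above would no longer hold, so
multi-state input is refused with a clear error rather than silently
producing means that cannot be read as probabilities.

## Evidence semantics

Data-list scalar entries (`Age_Inheritance = 2, ...`) are treated as
*observations*: the node is clamped and never resampled, exactly as
WinBUGS treats data.  One consequence deserves emphasis.  The bundled
case studies clamp root nodes whose own priors put probability zero on
the clamped state (e.g. `Cytokines = 2` alongside
`p.Cytokines = c(1, 0)`).  Read literally, such evidence has probability
zero and every conditional query is 0/0.  A Gibbs sampler never notices:
an observed node's likelihood is a constant that never enters any free
node's full conditional.  Exact inference here adopts the same
semantics: any factor that is *constant* under the evidence (an observed
node whose parents are all observed) cancels between the numerator and
denominator of a conditional query and is dropped before summation.
"Impossible evidence" is reported only when the remaining normalizer is
zero, i.e. when the free nodes genuinely cannot produce the observations
(for instance a child clamped True whose CPT is deterministic-False for
every reachable parent state).  This choice reproduces the published
results; strict conditioning would make all four case studies errors.

## Exact inference

`exact_marginal()` offers two routes that must agree (a tested
property):

* **Enumeration** sums the joint over the full grid of free stochastic
  nodes, resolving max nodes per assignment.  It is transparent and
  fast up to 14 free nodes, the default switch-over point.
* **Variable elimination** turns every node into a factor (CPTs as-is,
  max nodes as indicator factors over members plus node), conditions on
  the evidence, and eliminates the non-query variables greedily by
  minimum combined scope (min-degree).  On the bundled network the
  largest intermediate factor is the `max1` risk pool (11 binary
  variables, 2048 entries), so queries complete in milliseconds.

Ties in the elimination order, like ties in `topological_order()`, are
broken by C-locale name sort so that results and traversals are
reproducible across platforms and locales.

## Sampling and summaries

When the evidence is *ancestral-closed* - every ancestor of an observed
node is itself observed, which holds whenever only roots are clamped, as
in all four case studies - drawing each free node after its parents in
topological order yields independent joint samples.  `sample_posterior()`
detects this and uses ancestral sampling; otherwise it falls back to
single-site Gibbs over the free stochastic nodes (initialized from one
forward draw, max nodes recomputed each sweep).  The default burn-in is
0: ancestral draws are independent, so there is nothing to burn.  For
Gibbs runs a burn-in can be set explicitly.

Every node consumes its own substream of the root seed (a hash of the
node name mixed into the seed), so adding or removing monitored nodes
never perturbs the draws of the others, and a fixed
(model, data, settings) triple reproduces output byte for byte.

`posterior_summary()` mirrors the WinBUGS summary columns: the sample
mean of the 1/2 states, the *population* (divide-by-n) standard
deviation - for a binary chain identically $\sqrt{\hat p(1-\hat p)}$,
and at $n = 10^4$ indistinguishable from the sample convention at
printed precision - and the batch-means Monte Carlo error: the chain is
cut into `batches` consecutive batches of `floor(n/batches)` draws
(remainder dropped) and the MC error is the standard deviation of batch
means over $\sqrt{\text{batches}}$.  The batch count defaults to 50,
which at 10,000 iterations reproduces the magnitude of the published MC
errors (about 0.005 for a half-probability category); the underlying
reference does not document its batch size, so this is a calibration
choice made once.  For independent draws the estimate approaches
$\sigma/\sqrt{n}$ regardless of the batch count.

## The Alzheimer's network

`build_ad_network()` assembles 41 stochastic nodes - six roots
(age/heredity, metal ions, p53, cytokines, APP, daily-living
activities), their biomarker descendants, and the lesion/symptom layer -
plus 16 max aggregators including the eight diagnostic categories of the
revised NINCDS-ADRDA research criteria (Prodromal AD, AD dementia,
Typical AD, Atypical AD, Mixed AD, Preclinical AD, Alzheimer's
Pathology, Mild Cognitive Impairment).  Each stochastic node binds to
one `p.*` table of the data-list format.  Three structural points were
genuinely open and are resolved as follows:

* **The lifestyle term of the Prodromal risk pool.**  The published
  `max1` argument list contains a single "hypertension/depression"
  entry.  We implement it as the OR of all six modifiable factors
  (hypertension, depression, smoking, diabetes, obesity, physical
  inactivity), the only reading that reproduces case study 4's printed
  0.464: the exact OR of Lewy bodies, depression, smoking and obesity is
  $1 - 0.884 \cdot 0.868 \cdot 0.726 \cdot 0.966 = 0.46187$, within one
  printed MC error of 0.464, whereas the literal two-factor reading
  gives 0.233.
* **The amyloid node.**  The model text gives amyloid-beta three parents
  (APOE4, PS1/2, APP) but its parameter table has only two parent axes.
  We split the node: `Ab12` (parents APOE4, PS1/2; table `p.Ab`) and
  `AbAPP` (parent APP; table `p.Ab_APP`), OR-ed into the `Ab`
  aggregator.  This respects both the printed table shapes and the
  three-way dependence.
* **Mitochondrial/oxidative sub-wiring.**  The parent partition of
  `Mito1..3` over {MetalIons, OPA1, MFN1, DVLP, FIS1} and of the paired
  oxidative-stress/inflammation/isoprostane sub-nodes is not recoverable
  from the published material; only the arities are fixed by the table
  shapes.  The default (documented in `ad_default_wiring()`) is
  arbitrary, and deliberately exposed as an argument: a test rewires the
  sub-nodes and asserts that every category probability in every case
  study is unchanged, which holds because all affected tables are
  deterministic-false in the fixtures.

Scalar data-list entries clamp only the six roots in every fixture, and
each clamped root's children carry CPTs with identical rows across the
clamped parent's states - the package asserts this, which is what makes
the published claim that initializing the parent knots "does not affect
the execution" true.

## Bundled case studies and corrections

`load_example(1..4)` parses the data-list fixtures shipped under
`inst/extdata/` (transcribed from the published report) and attaches the
expected category report from the corresponding results tables (the
10,000-iteration columns).  Two printed lists contradict their own
results tables; the results tables are taken as authoritative, and the
default fixtures apply corrections that are announced at load time,
recorded in the fixture's `corrections` field, and reversible with
`corrected = FALSE` (CLI: `--as-printed`):

* Case study 3: `p.miRNAs` is printed always-true, which would force
  Alzheimer's Pathology to 1.0 against the table's 0.0; corrected to
  deterministic-false.
* Case study 4: the same miRNAs contradiction, and `p.Vascular` printed
  always-true, which would drag AD dementia, Typical AD and Mixed AD to
  1.0 against the table's 0.0/0.0/0.464; both corrected to
  deterministic-false.

With corrections applied, exact inference reproduces every published
cell: the deterministic 0/1 cells exactly, and the stochastic cells
(0.562, 0.502, 0.464) within well under four printed MC errors of their
exact values (0.558, 0.500, 0.46187).

The registry returned by `prior_registry()` transcribes the published
per-biomarker risk rates as fractions.  Ranges resolve to the value a
case study actually uses where determinable (APOE4 uses 0.70), otherwise
the midpoint; "<1%" is stored as the 0.01 upper bound; the three rows
published only as prose carry a note and a chosen point value.  The
registry is reference data for building scenarios - the fixtures bind
the printed data lists directly and never read it.

## The random-network generator

`simulate_network()` emits random DAGs (bounded in-degree, Dirichlet-
sampled CPT rows, optional max aggregators on top) both in memory and as
a config + data-list text pair, and exists to give the property tests an
unbiased fixture stream: elimination vs enumeration vs a brute-force sum
over `joint_probability()` on a hundred networks of up to 12 nodes
(tolerance 1e-9), joint normalization, and round-tripping of the I/O
layer.  Its continuous Dirichlet rows mean generated networks never
contain the deterministic 0/1 tables and near-degenerate structures the
real fixtures are full of; those regimes are covered by the case-study
tests instead, so passing the property suite alone would not certify
behaviour on degenerate tables.  Neither generator output nor fixtures
model missing data, multi-state biomarkers, or measurement noise on the
evidence - observed states are taken as certain.

## Problem sizes and numerical choices

CPT rows must sum to one within 1e-9; both dual-route inference checks
and the normalization property use the same 1e-9 tolerance.  The test
suite runs enumeration-based oracles up to 12 stochastic nodes (4096
assignments), uses 10,000-iteration chains where a published value is
compared (40 seeds per fixture for the convergence property), and
shorter chains elsewhere; the full suite completes in a few minutes on
one core.  Default run settings mirror the published experiments:
10,000 iterations (3,000 available via `--iterations`), batch count 50,
burn-in 0.

## Limitations

* Binary nodes only; `dcat` over more than two states is rejected.
* Max nodes are the only deterministic kind; no general logical or
  arithmetic deterministic nodes.
* Gibbs is single-site with no convergence diagnostics or thinning; for
  evidence that fragments the posterior into well-separated modes a
  blocked sampler would be needed.  All bundled analyses use ancestral
  sampling, where these concerns do not arise.
* The model-language block of the BUGS dialect (`~`/`<-` statements) is
  not parsed; structure is declared explicitly (YAML/JSON config or the
  curated builder), only data lists are parsed.
* The network encodes the published structure and rates; it has not
  been clinically validated, and category probabilities are a decision
  aid, not a diagnosis.
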
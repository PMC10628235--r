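---
title: "Comparative paleoneurology: encephalization, hearing and phylogenetic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative paleoneurology: encephalization, hearing and phylogenetic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoneuro)
library(dplyr)
```

paleoneuro quantifies three aspects of fossil-archosaur neurosensory biology
from endocast measurements — relative brain size, hearing range, and
olfactory/vestibular development — and tests how those traits scale with
body or skull size using phylogenetic generalized least squares (PGLS)
across ensembles of time-calibrated trees. This vignette describes the
models, the conventions and parameter choices behind them, and the limits of
what the packaged tests demonstrate.

## Reptile encephalization quotient

The encephalization quotient compares an observed brain mass with the brain
mass expected for an animal of the same body mass under a reference scaling
law. For non-avian reptiles the reference is

$$REQ = \frac{M_{Br}}{0.0155 \, M_{bd}^{0.553}}$$

with both masses in grams. Endocasts measure the endocranial cavity, not the
brain, so `brain_mass_from_volume()` converts an endocast volume (ml,
olfactory tract excluded) to brain mass with two conventions:

* **endocranial fill** — the fraction of the cavity occupied by brain
  tissue: 50% is the long-standing default for non-avian dinosaurs, 60% is
  used where valleculae (vascular impressions on the endocranial surface)
  suggest the brain sat tight against the bone;
* **tissue density** — 1.036 g/ml.

Published body masses and endocast volumes are often intervals.
`req_table()` propagates them by the monotonicity of the formula: the REQ
lower bound pairs the smallest volume with the largest mass, the upper bound
the reverse. Masses enter the table in kg (the unit reference tables print)
and are converted to grams in exactly one place inside `req_table()`.

Two numerical caveats discovered while validating against the reference
table are worth recording. First, reference body masses are printed at three
significant figures; since $\partial REQ/\partial M = -0.553\,REQ/M$, a
half-unit mass rounding shifts an REQ of 0.8 by about 0.001 — enough to move
a third printed decimal. The packaged tests therefore require agreement to
printed precision *within* that input-rounding envelope. Second, two rows of
the packaged reference data (`annotation` column) are not reproducible from
their own printed inputs at all: one taxon's printed interval corresponds to
a single intermediate body mass rather than the printed mass interval, and
one taxon's values evidently derive from unprinted source data. The package
computes what the stated rule implies and carries the annotation; it never
adjusts outputs to match an unreproducible print.

```{r}
req_table(ornithischian_endocranial_data()) |>
  filter(taxon == "Thescelosaurus neglectus")
```

## Hearing range from the endosseous cochlear duct

The length of the endosseous cochlear duct (the bony housing of the auditory
papilla) predicts hearing range in extant reptiles and birds. Two chains are
implemented in `hearing_range()`:

* **scaled-duct chain** — the duct length is divided by basicranial length
  (basioccipital + basisphenoid, excluding the parasphenoid rostrum) to
  remove head-size allometry, log10-transformed, and entered into linear
  predictors for best-frequency-range bandwidth (BFR, Hz) and mean best
  hearing (MBH, Hz). With a scaled length of 1 these reduce to their
  intercepts, 6975.2 and 4000.8 Hz.
* **papilla chain** — the basilar papilla is taken as 2/3 of the duct
  length, and exponential/linear predictors give best frequency (BF) and
  maximum (upper-limit) frequency (MF). These equations operate in kHz
  internally; the package reports Hz everywhere.

The two chains are deliberately reported side by side and never averaged:
they come from different calibrations and the package treats them as
independent estimates. A "best hearing" interval is reported as
MBH ± BFR/2, interpreting the bandwidth as centred on the mean — this is an
interpretation (documented, not calibrated), chosen because it makes the
bandwidth, interval width and midpoint mutually consistent. The papilla
chain needs only the absolute duct length, so rows lacking a basicranial
length still produce BF/MF; the scaled chain refuses to guess and returns
`NA` instead.

```{r}
hearing_range(tibble::tibble(taxon = "Thescelosaurus neglectus",
                             cochlear_duct_length_mm = 9.95)) |>
  select(taxon, papilla_length_mm, bf_hz, mf_hz)
```

## Olfactory and vestibular ratios

`olfactory_ratio()` is the longest olfactory-bulb diameter over the longest
cerebrum diameter (dorsal view), a dimensionless acuity proxy;
`canal_metrics()` computes the anterior:posterior semicircular canal height
ratio, which tracks balance sensitivity and locomotor agility in
ornithischians. Canal heights are only comparable when measured with the
lateral canal horizontal, so the tables carry an `lsc_horizontal`
provenance flag and the function warns when it is absent. Both functions
expose log10 transforms because the comparative regressions operate on
log10 scales throughout.

## PGLS with maximum-likelihood Pagel's lambda

Closely related species are not independent data points: under Brownian
trait evolution on a time-calibrated tree, the expected covariance of two
tips equals the time from the root to their last common ancestor.
`phylo_vcv()` builds that matrix and attenuates its off-diagonal entries by
Pagel's lambda ∈ [0, 1], the phylogenetic-signal parameter (`lambda = 1` is
pure Brownian structure, `lambda = 0` star-like independence; the diagonal
is untouched).

`gls_fit()` estimates the regression by whitening: with Cholesky factor
$U^\top U = V$, both the design and response are premultiplied by
$U^{-\top}$ and an ordinary least-squares problem is solved. All reported
statistics live in the whitened space:

* $\sigma^2$ is the ML estimate (whitened RSS / n), and the log-likelihood
  is the multivariate-normal density at the fit;
* $R^2 = 1 - RSS/TSS$ with the whitened intercept-only model as baseline,
  so it stays in [0, 1] and reduces to the OLS value on a star phylogeny;
* the model p-value is the F-test against the intercept-only model; with a
  single predictor this equals the slope's t-test p-value (the choice is
  therefore immaterial for the supported single-predictor fits);
* coefficient standard errors use the conventional unbiased residual
  variance (RSS / (n − p)).

`pgls_ml()` profiles lambda: coefficients and $\sigma^2$ are solved
analytically at each candidate, and the profile likelihood is maximized on
[0, 1] by a deterministic bounded search (best of an 11-point grid, then
`optimize()` with absolute tolerance 1e-6, with the boundaries 0 and 1
always evaluated exactly). Boundary optima are returned as-is and flagged
(`lambda_boundary`), never perturbed. The likelihood is ML rather than REML
by default, matching comparative-methods convention; REML is available but
excluded from the validated surface. AICc uses
$k = \text{coefficients} + 1 (\sigma^2) + 1 (\lambda\text{ if estimated})$;
because reference analyses rarely print their $k$ convention, AICc values
should only be compared within this package.

Numerical edge cases are explicit rather than silent: a constant predictor,
missing values, taxa absent from the tree, and singular covariances (e.g.
from zero-length terminal branches at lambda = 1) all raise errors naming
the cause. Cholesky factors with a near-zero pivot are rejected rather than
trusted, because LAPACK will happily factor an exactly singular matrix.
Polytomies are accepted (shared-depth covariance needs no bifurcation), and
non-ultrametric trees are accepted with a warning since the lambda transform
is conventionally applied to ultrametric trees.

One representational subtlety: pruning a tree to a taxon subset re-roots it
at the subset's common ancestor. `prune_to_taxa()` retains the dropped
basal path as a root edge and `phylo_vcv()` adds it to every entry (it is
history shared by all tips), so pruning commutes exactly with selecting
rows and columns of the full covariance.

## Ensembles of trees

Topological uncertainty is handled by repeating the regression over an
ordered ensemble of trees (`run_ensemble()`), pruning each tree to the
sample internally. The "best-performing iteration" is the maximum
log-likelihood fit (equal parameter counts make this the AICc order too),
with ties broken by lowest index. Summaries report the median model p and
R² across trees, the full band of per-tree regression lines, and per-taxon
residual distributions. `residual_boxplots()` uses linear-interpolation
quartiles and the 1.5 × IQR whisker rule; `rank_residuals()` orders taxa by
descending median residual — the tool used to ask whether one taxon is more
exceptional than any other sampled taxon given its size. Per-tree failures
are excluded from summaries with a warning rather than aborting the
ensemble.

## The synthetic-data generator

Every statistical claim in the test suite runs on synthetic data from
`simulate_tree()` and `simulate_traits()`, which emulate the structure the
analyses assume:

* **trees** — pure-birth (Yule) topologies rescaled to exact
  ultrametricity. Pure birth is the simplest generator of time-calibrated
  shapes; the particular shape of any published supertree is irrelevant to
  the properties being tested. Default depth 1 (relative time); tests and
  the acceptance script use depth 100, a Myr-like scale.
* **traits** — a linear allometry on the log10 scale,
  `response = intercept + slope × predictor + e`, with `e` multivariate
  normal, covariance `sigma2 × phylo_vcv(tree, lambda)`. Defaults emulate a
  dinosaur-scale analysis: predictor grid spanning 0–4.2 (log10 body mass,
  1 kg to ~16 t), slope 0.2, intercept −1, and `sigma2` such that residual
  scatter is a few tenths of a log10 unit over the tree depth. The noise is
  drawn via eigendecomposition (`MASS::mvrnorm`), deliberately a different
  code path from the Cholesky whitening in the fitter, so a shared bug
  cannot validate itself.
* **fixtures** — `make_fixture_tables()` writes byte-reproducible CSV,
  Newick and YAML-manifest files in exactly the dialects the readers
  accept, including the packaged endocranial reference records and a
  25-taxon, 10-tree regression set. Sub-seeds derive deterministically from
  one master seed and are logged in the manifest. In the labyrinth fixture
  only the first taxon's cochlear duct length is a published measurement;
  every other number is synthetic and labelled as such.

What the generator does **not** emulate: measurement error in volumes or
lengths, fossil sampling through time, extinction (birth–death) topologies,
and correlated evolution of predictor and residual. Passing tests therefore
demonstrate correctness of the estimators under the stated model, not
robustness of any empirical conclusion to measurement or model violations.

## Validation strategy and problem sizes

The test suite validates each layer against something external to it:
hand-computed covariance matrices and normal-equations solutions for the
3-taxon worked example; ordinary least squares on star phylogenies; an
independent GLS implementation (`nlme::gls` with `ape::corPagel`) for
coefficients, lambda and likelihood; and Monte-Carlo recovery of simulated
truths. Simulation sizes were chosen to hold Monte-Carlo error comfortably
below the tested margins while staying desk-scale: 200 replicates of
50-tip trees for slope/lambda recovery (slope CI coverage ≥ 90%, bias < 5%,
median lambda within 0.2 of truth), 2000 replicates for entrywise
covariance checks (10% relative tolerance), and a 100-tree ensemble for the
mechanics of best-iteration selection and residual summaries.

## Known limitations

* Single-predictor models are the validated surface; the machinery accepts
  only one covariate plus intercept by design.
* Lambda is the only covariance transform; no Ornstein–Uhlenbeck or
  early-burst models.
* Reproducing published regression statistics requires the corresponding
  published data and tree files; the package ingests them unchanged
  (`read_newick_ensemble()`, `read_endocranial_csv()`,
  `read_labyrinth_csv()`) but does not bundle them.
* Body masses are inputs: no mass estimation from limb-bone circumference
  is included.
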
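---
title: "Demographic inference from 2D minor-allele spectra: models, estimator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic inference from 2D minor-allele spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the demographic
model, the spectrum summary, the composite-likelihood ECM estimator, the
synthetic-data generator, and every numerical decision a maintainer might
want to revisit. Code chunks are illustrative and not evaluated during
build; the quantitative claims below are exactly those recomputed by the
test suite and by `scripts/acceptance.R`.

## The demographic model

A `DemographicModel` describes a set of diploid demes backward in time, in
generations before present:

* **Populations** carry a label, an island group, a diploid sample size and
  a current effective size `N`. A pair of haploid lineages in a deme of
  size `N` coalesces at rate `1/(2N)` per generation.
* **Events** are divergences (all lineages of a `source` deme move into a
  `sink` deme, and the source is retired) and size changes (`N` is reset
  looking further backward). Ties in event times are legal and model
  simultaneous divergence; model validation replays the event list and
  requires that a divergence never references a deme already merged at a
  more recent time and that exactly one ancestral lineage remains.
* **Migration** is a recent epoch `[0, t_end]` with forward-in-time
  fractions: `rates[i, j]` is the fraction of deme *j* founded each
  generation by migrants from deme *i*. Backward in time, that same number
  is the probability that a lineage in *j* had its parent in *i*, so the
  forward founding fraction and the backward lineage-movement probability
  coincide — this is why configs are written forward-in-time (the natural
  reading of a model figure) while the engine consumes them directly. The
  magnitude of gene flow is reported as migrants per generation,
  `M = m × N`, destination-based by default (`migrantNumbers()` can report
  the source-based convention too; the two differ only through which
  deme's size multiplies the fraction).
* Migration is structurally forbidden between different island groups:
  each island group is isolated by open sea, so `buildModel()` rejects any
  cross-group rate.

Time is kept in generations internally; years appear only at I/O
boundaries, via `generationsToYears()` with the default of 5 years per
generation (a woody perennial that flowers within a couple of years of
germination). The mutation rate default in the shipped models is
`1.74e-8` per site per generation, a tree-species estimate.

## The folded 2D minor-allele spectrum

For a population pair with `n1` and `n2` sampled haploids, the 2D-mSFS is
the `(n1+1) × (n2+1)` table counting sites by minor-allele copy numbers,
**including the monomorphic cell (0, 0)** — total assayed sites, not just
SNPs, enter the likelihood, which is what calibrates absolute times against
the mutation rate. Folding is to the pooled minor allele: if the pooled
alternate-allele count exceeds `(n1+n2)/2` the cell indices flip to
`(n1−i, n2−j)`. Two deterministic tie rules, applied identically in the
observed-data path and in the simulation engine:

* an exact 50:50 pooled count keeps the ALT orientation;
* diagonal fold ties are counted once (in that ALT-orientation cell), not
  split in halves — integer count invariants stay exact.

Missing genotypes are completed per site and per population by bootstrap:
observed alleles are kept and each missing haplotype slot is drawn i.i.d.
with replacement from the population's observed alleles at that site.
Drawing fills as a binomial count of the observed allele frequency is the
same distribution, which is how `build2dMSFS()` vectorizes it. A
genotype-level variant (resampling whole diploid genotypes) is available
behind `unit = "genotype"`, since either reading of "bootstrap within the
population" is defensible. Fill streams are seeded from the master seed
plus a stable hash of the population name — not per site; per-site
substreams would only matter for parallel completion, which this
implementation does not do, and the name-based seeding buys an exact
transpose property: `build2dMSFS(g, B, A, seed)` is the transpose of
`build2dMSFS(g, A, B, seed)`. Sites where a population has no genotyped
individual at all are excluded for that pair and counted in the result's
`excluded` slot, so `sum(counts) + excluded` always equals the input site
count.

## Site filters

`filterSites()` mirrors the Stacks `populations` rules: per-population
genotyping rate `r` (default 0.8) in at least `p` populations, minimum
minor-allele count (default 1), maximum observed heterozygosity (default
0.5, a paralog guard), and an optional overall genotyping-rate threshold
(0.3 / 0.5 / 0.8 are the conventional choices). The four rules are each
per-site functions of the data, so filtering is idempotent and order-
preserving.

## The coalescent engine and the expected spectrum

Per-site genealogies are independent (no linkage): SFS-only inference uses
no linkage information, and ddRAD loci are short. Mutation is
infinite-sites with opportunity `θ = μ × locusLength` (default 51 bp, a
short single-end read) per branch generation. By default at most one SNP
is retained per locus — the first mutation — matching one-SNP-per-locus
RAD conventions; `oneSnpPerLocus = FALSE` emits every mutation (used by
the Watterson check in the tests).

The expected spectrum is estimated by simulation, Rao-Blackwellized over
mutation placement: a genealogy of total length `T` contributes
`exp(−θT)` to the monomorphic cell and `(1 − exp(−θT)) · L_c / T` to cell
`c`, where `L_c` is the branch length subtending configuration `c`. Cells
therefore sum to one exactly, and the estimator's variance comes only from
genealogy sampling. During fitting, one set of genealogies sampled over
**all** demes yields every pairwise spectrum at once.

The engine is validated against analytic results (the folded neutral SFS
`∝ 1/i + 1/(n−i)`, Watterson's `E[S] = θ Σ 1/i`) and against an
independent widely used coalescent simulator on three benchmark models
(single deme, clean split, split with recent migration), as a slow test.

## Composite likelihood and ECM

The likelihood is composite twice over: sites are treated as independent
within a pair, and pairs are summed over even though they share sites.
`lnL = Σ_pairs Σ_cells n(i,j) · ln max(p̂(i,j), minProb)` with
`minProb = 1/(10 · nSims)` guarding cells that received no simulated mass
(a standard finite-simulation floor; unguarded zeros would veto the
parameter point on a single unlucky cell).

`ecmFit()` maximizes by expectation-conditional-maximization: from each
random start (log-uniform within the declared bounds), cycles of Brent
1-D maximization over each free parameter in turn, on the log10 scale, in
declaration order. Two common-random-number regimes:

* `crn = "cycle"` (default): all evaluations within a cycle share one
  simulation seed, so each conditional search is deterministic; successive
  cycles draw fresh seeds, so the coordinate ascent averages over
  independent Monte-Carlo surfaces instead of converging to the argmax of
  a single noisy surface. This materially reduces the Monte-Carlo
  component of the estimator error at fixed `nSims`.
* `crn = "global"`: one seed for the whole start; the accepted-likelihood
  trace is then exactly non-decreasing (the property the tests assert).

Parameter proposals that break the event topology or a declared ordering
constraint score `−10¹⁸` rather than erroring, so Brent simply avoids
them. Default search bounds: `[10², 10⁶]` for sizes, `[10², 10⁵]`
generations for times, `[10⁻⁸, 10⁻¹]` for migration fractions — wide
enough to bracket all shipped point estimates by an order of magnitude on
each side. A start whose cycle improves its own (same-seed) likelihood by
less than 0.01 units stops early.

The full-scale schedule is 50 starts × 40 cycles × 100,000 simulations per
evaluation; `deskSchedule()` (3 × 10 × 5,000) is the scaled-down setting
used throughout the tests and the acceptance script, chosen so a complete
six-deme recovery experiment runs in minutes on one CPU.

## Model selection, the stepwise ladder, and candidate enumeration

Models are compared by `AIC = 2k − 2 lnL` (natural log; likelihood bases
only shift AIC by a monotone factor, so selection is unaffected), lowest
wins; exact ties go to fewer parameters, then lexicographic model id.
`enumerateCandidates()` generates every rooted divergence ordering of 2–6
taxa as a sequence of merge events, where one event may merge more than
two lineages (a hard polytomy = simultaneous divergence); for three taxa
that is 4 candidates (3 strict orders + the trichotomy), and the count
follows `a(n) = Σ_k C(n,k) a(n−k+1)`, which the tests verify
independently. Candidate models materialize each merge as divergence
events into the lexicographically smallest member, one shared free time
per merge, with explicit ordering constraints between successive merges so
a fitted candidate cannot silently morph into a different topology.
`stepwiseSearch()` runs the ladder strategy — small taxon subsets first,
winning clades constraining later, larger steps — and emits a
machine-readable path of per-step ΔAIC tables.

## Parametric bootstrap

Confidence intervals are percentile intervals (2.5/97.5, linear
interpolation — the method is not prescribed by convention beyond this)
over replicate refits: datasets are drawn per pair as multinomial samples
of the observed site totals from the MLE spectrum, and each refit starts
at the MLE with a shorter schedule (the full-scale convention is 15 ECM
cycles and 100 replicates). Failed refits are logged in the result and
dropped. A slow test checks ~95% coverage on a two-deme toy with a split
at 0.4 coalescent time units, where the estimator is close to its
asymptotic regime; shallower splits have visibly skewed estimators at
desk-scale effort, which percentile intervals do not correct.

## The shipped model catalog and its placeholders

`modelE1()` (six demes) and `modelG2()` (five demes) encode the published
best divergence histories: a stem radiation in a narrow window (72.9–76.9
kya), one much older split (170.7 kya), ancestral-lineage divergence at
168.8 kya, Mukojima founding splits at 81.4/82.3 kya, a shared recent
reduction at 37.1 kya, expansions at 70.2 kya, and within-island-group
migration at 0.02–0.51 migrants per generation. Event *times* and migrant
numbers are the published point estimates. The topology detail inside the
near-simultaneous window, and which sizes change by how much, are not
printed in the main text, so:

* the radiation is modeled as independent splits from a single stem
  lineage (any time ordering of the window splits is then a legal
  history — convenient for the optimizer and faithful to the star-like
  signal);
* per-deme sizes are **placeholders**, flagged as such. They were chosen
  once on two grounds: qualitative agreement with the published
  size-change statements (expansions of more than two orders of magnitude
  for P, G, SG; strong founder-effect reductions for Sm and STm), and
  identifiability — the published ±5–9% confidence intervals are evidence
  that the real data constrained these times well, so placeholder sizes
  under which the same times would be *unidentifiable* (e.g. a
  bottleneck so severe that all sampled lineages coalesce before the
  event being dated) would misrepresent the study conditions. The
  Mukojima demes use 3,000 ← 310,000 (still a two-orders reduction), S
  uses 8,000 ← 20,000, and the ancestral deme 10,000.

## The synthetic-data generator: what it does and does not emulate

`simulateGenotypes()` + `applyMissingness()` emulate the demography
dataset: biallelic SNPs at thousands of short independent loci, genotyped
in 5–7 (pooled: 7–14) diploids per deme, with per-genotype missingness and
monomorphic loci included. It does **not** emulate sequencing or
genotype-calling error, allele dropout at restriction sites, linkage
between nearby loci, or reference bias — so passing recovery tests show
that the estimator works on data generated by its own model class, not
that it is robust to those artifacts. That is the right scope for
self-consistency experiments whose ground truths are published estimates;
robustness to calling artifacts is a property of the upstream caller and
filters, not of the SFS machinery.

Recovery experiments at desk scale use 50,000 loci (about the scale of a
filtered ddRAD demography dataset) or less for toys. The
migration-recovery runs bound the migration search at 5 migrants per
generation on the migrant-number scale — an order of magnitude above the
biological bound of interest (1), while avoiding the near-panmictic
corner of the bounds where migration events dominate simulation cost and
the parameter is meaningless for the question asked. Within-island-group
migration in the shipped six-deme model is a directed cycle (each deme
one immigration source and one emigration target): the published figure
shows specific forward-in-time directions, and giving a deme two
immigration sources makes the per-direction migrant numbers structurally
confounded — the directions can trade flow against each other without
changing the spectra appreciably, which is poison for a bound on every
single direction's estimate.

## The dispersal module

`dispersalDistance()` composes two power laws of body mass — gut retention
time (minutes) and flight speed (km/h) — into a distance, `km = km/h ×
min / 60` (the unit conversion is exact and tested). Coefficients are
data, not code: a YAML config with citation fields. The bundled
`allometry_birds.yaml` uses the classical flight-scaling exponent (speed ∝
mass^(1/6)) and calibrates the remaining coefficients against the three
published distances (39.7 / 88.8 / 110 km) with handbook masses, because
the original regression coefficients are not printed; the product of two
pure power laws cannot reproduce all three distances exactly (they are
not collinear in log-log space), and the bundled calibration agrees to
within ~3%. Users wanting exact reproduction must transcribe the
coefficients from the cited allometry sources and substitute their own
config — `scripts/dispersal_validation.R` reports the comparison either
way.

## Known limitations

* Composite likelihood over overlapping pairs inflates apparent curvature;
  model-selection AIC and bootstrap CIs inherit the usual composite-
  likelihood caveats. CIs here are parametric-bootstrap percentiles, as in
  the motivating analysis, not curvature-based.
* The Monte-Carlo expected spectrum makes the likelihood noisy; the
  per-cycle CRN regime averages much of this out, but parameters whose
  information content is small relative to the simulation noise (e.g.
  times buried behind severe bottlenecks) will wander. Increase `nSims`
  or redesign the experiment rather than trusting such estimates.
* No ancient-migration epochs (the motivating analysis found them
  strictly worse and dropped them); no linkage, no recombination, no
  genotyping-error model.
* At most 8 demes and 256 sampled haplotypes per model in the engine.
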
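---
title: "Species delimitation and ancestral range reconstruction with phylodelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species delimitation and ancestral range reconstruction with phylodelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodelim)
```

phylodelim implements a complete multi-locus species-delimitation and
historical-biogeography workflow of the kind used in fungal systematics:
genealogical concordance phylogenetic species recognition (GCPSR) on
support-annotated gene trees, a genetic-distance rule for singleton samples,
and Dispersal-Extinction-Cladogenesis (DEC) ancestral-range reconstruction on
a time-calibrated phylogeny with range constraints and epoch-stratified
dispersal. A synthetic-data generator reproduces the statistical structure
each stage assumes, so the whole pipeline is testable without any external
data. This vignette explains the models, their assumptions, the tunable
parameters, and the design decisions taken where the methods literature
leaves choices open.

## GCPSR lineage recognition

The unit of analysis is a set of per-locus genealogies (here: rooted trees
with maximum-likelihood bootstrap percentages, ML-BP, and Bayesian posterior
probabilities, BI-PP, on their internal nodes), restricted to the samples
for which every locus was sequenced (`restrict_to_common_taxa()`). Two
criteria admit a cluster of individuals as an independent evolutionary
lineage:

* **Criterion i, genealogical concordance** (`criterion_a_lineages()`): the
  clade is present in at least two of the ML genealogies, *regardless of its
  support values*. Presence alone is evidence, because independent loci
  rarely agree by chance. This reading is forced by the common situation of
  a species recovered in two genealogies with bootstrap proportions well
  below any significance threshold.
* **Criterion ii, genealogical non-discordance**
  (`criterion_b_lineages()`): the clade is highly supported — ML-BP ≥ 70 *and*
  BI-PP ≥ 0.95, both thresholds user-configurable via
  `support_thresholds()` — in at least one genealogy, and is not contradicted
  at the same support level in any other. "Contradicted" is operationalised
  through `detect_conflicts()`: two clades in different loci conflict when
  they overlap without either containing the other and both pass the dual
  threshold. The same routine doubles as the combinability test run before
  concatenation: an empty conflict list means the loci may be combined.

From the union of criterion-i and criterion-ii candidates,
`terminal_lineages()` keeps the inclusion-minimal clades (no qualifying
proper sub-clade) of at least two samples; single samples are never lineages,
because genealogical concordance is undefined for them. Survivors must be
pairwise disjoint; an overlapping non-nested pair aborts with a pointer to
the upstream conflict.

**Exhaustive subdivision** (`exhaustive_subdivision()`) then makes the
partition total: every sample not covered by a terminal lineage is walked
rootward in the combined-data tree to the nearest proper ancestor whose
descendant tips consist only of whole recognised lineages and/or unassigned
tips (lineages are atomic and are never bisected); everything under that
node becomes one species. Merges are applied in order of increasing merge
node height and re-checked after each merge, so cascading merges resolve
deterministically.

**Singletons** — samples the analyst withholds from subdivision, typically
isolated long-branch samples or samples missing loci — are resolved by the
genetic-distance rule (`assign_singletons()`): compute the singleton's mean
distance to every recognised species and compare the minimum with the
largest within-species mean distance. Strictly larger means a distinct
species; a tie or smaller value merges the singleton into the nearest
species. The strict inequality is deliberate: the rule's logic is "farther
from every species than any species is wide", and a tie does not establish
that. Which samples count as singletons is an analyst decision, not an
algorithmic one — a stray sample adjacent to a lineage can legitimately be
handled either by subdivision (tree evidence) or by the distance rule
(divergence evidence); `delimit()` takes the list explicitly and reports
every decision with its supporting numbers.

`delimit()` chains all of the above and emits a criterion table — one row
per species, per-locus `ML-BP/BI-PP` strings for the species clade, the
combined-tree support, and the criterion (i, ii, both, subdivision, or
distance) that admitted it.

## Genetic distances

Distances are computed under pairwise deletion: for each sequence pair,
exactly the columns where either member carries a gap (`-`), missing data
(`?`) or an IUPAC ambiguity code are excluded, and the per-cell effective
site count is retained. Ambiguity codes are excluded from distances but
counted by `site_stats()` as *degenerate* sites (a site is *polymorphic*
when at least two distinct unambiguous bases occur; the two classifications
are independent). Treating ambiguities as missing for distances while
reporting them as degenerate mirrors the behaviour of the standard distance
software and lets the same matrix drive both computations.

Three models are available through `dist_config()`:

* `"p"` — proportion of differing sites, the defensive baseline;
* `"TN93"` — the Tamura–Nei 1993 closed-form correction with per-pair base
  frequencies, optionally gamma-corrected;
* `"MCL-TN93"` — a composite-likelihood TN93: base frequencies are pooled
  over the alignment, the two transition/transversion rate ratios are
  estimated **once** by maximising the summed pairwise log-likelihood over
  all pairs (each pair's divergence profiled out by a one-dimensional
  optimisation), and the per-pair distances are then the per-pair ML
  divergences under the shared parameters. Sharing parameters across pairs
  is what the "different patterns among lineages" option of distance
  software approximates in reverse: a single global pattern stabilises the
  many short pairwise comparisons; the `lineage_pattern_mode` flag is
  accepted and recorded for interface compatibility but does not change the
  computation.

Rate heterogeneity uses a discrete gamma with mean-category rates
(4 categories by default). The gamma shape defaults to 1.0 and is
user-configurable; analyses that state "gamma rates" without printing a
shape are reproducible only up to this choice, so the value used is always
recorded in the configuration. Saturated cells (a non-positive logarithm
argument in the closed form) are flagged inestimable — `NA`, never a capped
value — and excluded from group means with a warning.

Group means (`group_mean_distances()`) average over unordered within-group
pairs and over all cross pairs; a single-member group has an *undefined*
(missing) within mean, never zero. All cloned sequence copies of a sample
enter as separate rows — with cloned ITS copies this weights samples by
their copy number, which matches how the matrices are printed in practice;
averaging per sample first would be the alternative, and the taxon map makes
it easy to implement either. Bootstrap standard errors
(`bootstrap_se()`) resample alignment columns with replacement, recompute
the whole matrix and the group means per replicate (1000 replicates by
default), and report the standard deviation across replicates; the seed is
stored in the result.

## The DEC model

Geographic range evolves on the subsets of a small set of areas. The
anagenetic process is a continuous-time Markov chain: range gain
`R -> R + {a}` at rate `d * sum over b in R of m[b, a]`, where `m` is the
epoch's non-negative dispersal multiplier matrix, and range loss
`R -> R - {a}` at rate `e` per occupied area; a single-area range decays
into the absorbing, unobservable null range. `geography()` fixes the area
universe, the maximum range size, explicitly excluded ranges (for areas
that were never adjacent), and the epoch sequence in Ma before present.
`three_area_geography()` builds the configuration used throughout the test
fixtures: areas A/B/C, ranges of at most two areas, the disjunct range AC
excluded, and B–C dispersal multiplied by zero in both directions in the
0–5 Ma epoch (all other multipliers default to 1 and are user-suppliable).

`dec_loglik()` computes the likelihood by pruning: per-branch transition
matrices are matrix exponentials of the epoch rate matrix, with branches
sliced at epoch boundaries and segments multiplied in age order (older
first). Exponentials come from a spectral decomposition when the rate
matrix is cleanly diagonalisable, with a scaling-and-squaring fallback, and
are cached per (epoch, segment-length) pair. At an internal node the
daughters combine over the canonical DEC cladogenetic scenario set —
identical inheritance for a single-area ancestor; for a widespread ancestor,
vicariance (one single-area daughter, the other taking the remainder) and
subset sympatry (one single-area daughter, the other retaining the full
range) — with every enumerated scenario weighted equally within the node.
The root is integrated under a prior that defaults to uniform over the
legal non-null ranges (`root_prior = "range_size"` weights ranges inversely
by size instead); the reference implementations do not document their root
handling, so this is left explicit and configurable.

`fit_dec()` maximises over `(d, e)` on the log scale with bounded
multi-start local optimisation (a fixed 2×2 grid of starts by default), and
returns per-start convergence diagnostics. `ancestral_splits()` adds a
second, preorder pass computing, for every internal node, the fraction of
the total likelihood flowing through each (ancestral range, left daughter
range, right daughter range) combination, normalised within the node and
ranked — the familiar LAGRANGE split table — plus the per-node marginal over
ancestral ranges (the sum of split probabilities by ancestral range), since
published "DEC-P" percentages are sometimes one normalisation and sometimes
the other.

Two caveats deserve emphasis. First, the extinction rate `e` is weakly
identified in DEC: single-area daughters are produced by the cladogenetic
scenarios at no rate cost, so they absorb most of the signal that anagenetic
contraction would otherwise carry, and profile likelihoods in `e` are
commonly monotone decreasing — estimates at the lower bound are expected
behaviour on realistic data, not an optimiser failure. The package's own
simulation studies reproduce this: the dispersal rate is recovered within a
factor of two in the large majority of replicates, while `e` collapses
toward zero in nearly all of them. Second, a constrained state space is not
a nested submodel in the likelihood-ratio sense: excluding a range also
removes transitions into it, lowering the outflow of the remaining states,
so adding a constraint can *raise* the likelihood.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture dump. Its defaults
describe a desk-scale analogue of a three-locus, three-area systematics
study:

* `sim_chronogram()` — a birth–death tree conditioned on the tip count
  (defaults: 0.15 births, 0.05 deaths per Ma), ages in Ma.
* `sim_gene_trees()` — each locus is the species tree with every internal
  edge NNI-perturbed with probability `p_nni` (default 0.1), samples
  attached per species as shallow clades with locus-specific shapes.
  Supports follow a two-regime noise model: clades that are complete
  species-level clades of the species tree draw ML-BP from 85–100 and BI-PP
  from 0.96–1; everything else — perturbed regions *and* partial
  within-species clades, which real single-locus genealogies resolve poorly
  and inconsistently — draws from 20–65 and 0.2–0.9. The ranges are
  configuration, since a data analysis has no generative model to copy.
* `sim_alignment()` — TN93 + discrete-gamma sequence simulation from the
  stationary frequencies, with optional injection of two-base IUPAC codes at
  a per-site rate to emulate unphased heterozygous positions.
* `sim_ranges()` — forward DEC simulation with exponential waiting times
  switching rates at epoch boundaries and uniformly drawn cladogenetic
  scenarios. A lineage that hits the null range cannot be observed at a
  tip, so that branch history is redrawn (whole-history rejection is
  astronomically unlikely to terminate on trees of realistic size, and the
  two conditionings agree branch-by-branch under the Markov structure);
  every surviving anagenetic event is logged with its age for calibration
  checks. The conditioning removes extinction signal from the data — one
  more reason `e` estimates sit low.
* `make_study_fixture()` — a deterministic 12-species bundle with the
  awkward features that make delimitation interesting: a lineage concordant
  in two loci but weakly supported; a group visible in a single locus only;
  two stray samples that exhaustive subdivision must recover; two declared
  singletons engineered so that one splits and one merges; a
  locus-restricted sample resolved in a second distance round; and one
  sample with two cloned sequence copies in the ITS-style alignment.

What passing these simulations shows — and what it does not: the generator
produces clean, identifiable signal (discrete support regimes, correctly
specified substitution model, no alignment error, no recombination, no
incomplete lineage sorting beyond topological perturbation). Recovery on it
validates the *logic* of the pipeline, not the hardness of real data.

## Numerical choices and problem sizes

Distances use closed forms where they exist; the composite-likelihood model
optimises the two rate ratios by Nelder–Mead with per-pair divergences
profiled by Brent's method on (1e-9, 30) substitutions/site. DEC
optimisation is L-BFGS-B on log rates bounded in [1e-6, 10] events/Ma.
Ties in the singleton rule merge (strict inequality splits); ties in
terminal-lineage minimality cannot occur (set inclusion is a partial
order). Ultrametricity is checked to a relative tolerance of 1e-6 on tip
ages; rate-matrix row sums are exact to 1e-12; split tables normalise to 1
within 1e-9.

The packaged verification runs use problem sizes chosen to exercise every
code path at desk scale: 50 four-tip chronograms against an RK4
step-size-0.005 CTMC integration; 50 forward-simulated 100-tip range
histories for rate recovery; 200 two-sequence 2-kb alignments at a true
distance of 0.3 for estimator calibration; bootstrap scaling over alignment
lengths 500/2000/8000; and the full fixture for end-to-end recovery
(adjusted Rand index against the true partition).

## Known limitations

* No coalescent-model delimitation (BPP/GMYC-style) and no automatic
  threshold tuning; the GCPSR thresholds are conventions, not estimates.
* No DEC+J founder-event parameter and no Bayesian biogeography; the
  chronogram is an input, never re-estimated.
* The composite-likelihood TN93 shares one parameter set across all pairs;
  genuinely heterogeneous substitution patterns among lineages are averaged.
* Criterion-i presence is assessed on the supplied (ML) topologies only; if
  Bayesian topologies differ, annotate and supply them explicitly.
* The extinction rate of DEC should be interpreted qualitatively; see above.
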
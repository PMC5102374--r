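---
title: "Parsimony character evolution and biogeography in Euplotes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony character evolution and biogeography in Euplotes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(euplotia)
```

This vignette is the package's account of its methods: the reconstruction
model and its assumptions, the encoding of the genus data, the tunable
parameters and the reasoning behind every genuinely open design choice,
and what the validation suite does and does not establish.

## The reconstruction model

The package infers ancestral states of categorical characters (argyrome
type, frontoventral cirri count, habitat class, ecozone) on a rooted
phylogeny under the parsimony criterion: the preferred ancestral
assignments are those minimizing the total change cost summed over edges.
Unordered characters use unit costs — any change is one event, so a
species losing two cirri at once (10 → 8) counts a single loss, which is
the biologically intended reading of cirral evolution. Arbitrary cost
matrices are supported through the same Sankoff dynamic programme; a
ready-made loss-biased matrix (`loss_cost_matrix()`) encodes an
effectively irreversible, Dollo-like reading in which regains carry a
configurable penalty (default 10).

Assumptions worth making explicit:

* **Trees are used as written.** No rerooting, no branch-length
  information (parsimony is rate-free), no attempt to resolve polytomies.
  Multifurcations are treated as *hard* — the dynamic programme sums over
  all children exactly — because resolving an unresolved consensus node
  arbitrarily would bias event counts upward or downward depending on the
  resolution chosen.
* **No root prior.** The reconstruction cost is the minimum over root
  states; a state counts as an "origin" at the root if the root is
  assigned it.
* **Missing is uninformative.** A `?` tip is allowed every state at zero
  cost. At any optimum such a tip simply copies its parental state, so
  missing tips can never found an origin of their own — the convention one
  wants when, e.g., the argyrome of a species is simply undescribed.
* **Polymorphic tips** (e.g. a euryhaline species recorded from brackish
  *and* marine waters) are tips whose allowed set is the given set; the
  brute-force oracle in the test suite verifies this is exactly how they
  behave.

### Ambiguity is reported as intervals, not resolved

Most-parsimonious reconstructions are rarely unique. Rather than
privileging one MPR, every reported statistic is an interval over the full
MPR set: per-node state sets (states realized in at least one MPR),
occurrence counts of a specific transition, and independent-origin counts.
This matches how reconstructions are described in the systematics
literature ("five or six independent occurrences") and is computed
exactly, by a conditional-optimum dynamic programme over the Sankoff
tables, rather than by sampling. Full enumeration (`enumerate_mprs()`) is
available for inspection, deterministic and lexicographic, with a cap
(default 10,000) because MPR counts can grow exponentially; truncation is
flagged, never silent.

Under unit costs the Sankoff minimum is cross-checked on every fit against
an independent Hartigan-style set computation (the generalization of
Fitch's algorithm to multifurcating trees); a disagreement is a hard
internal error, not a warning.

## The packaged genus data and its provenance

The fixture encodes the 38 retained *Euplotes* morphospecies as a
species-level tree (15 monophyletic subclades grouped into the major
clades A–E; the outgroup omitted; one species of uncertain identity and a
likely-misidentified sequence excluded), a four-character matrix, the
three sampling-site salinities of *E. curdsi*, and the six comparative
trait profiles. Two points deserve emphasis:

* **Per-cell provenance.** Every matrix cell carries a tag: `text`
  (stated in prose of the source literature), `table` (printed
  comparative table) or `figure` (transcribed from tree figures). The
  figure-derived cells — most ecozone assignments in particular — cannot
  be checked against printed text, so the fixture is honestly a
  *reconstruction* of the published dataset, and conclusions that depend
  on those cells (e.g. the polar-invasion count) should be read as bounds,
  not equalities. `load_fixture("metadata")` reports the figure-transcribed
  fraction and verifies file checksums against the shipped manifest.
* **The subclade view is computed, not stored.** The 15-subclade synopsis
  matrix is derived from the species matrix by strict-majority consensus
  (`collapse_to_subclades()`), with ties becoming polymorphic cells; only
  the species-level matrix is an input. This keeps a single source of
  truth and makes the consensus rule itself testable.

The species-level encoding reproduces the headline numbers the test suite
asserts: nine argyrome-type changes and seven cirri-loss events at
minimum; a ten-cirri root; a root ambiguous between the two "double"
argyrome types with the post-*petzi*/*sinicus* ancestor resolving to
double-*eurystomus*; a double-*eurystomus* → double-*patella* interval of
[5, 6] with the reverse shift in [0, 1]; and at least two freshwater,
two hypersaline and four polar invasions.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `cost` (per character) | unit | events | any square non-negative, zero-diagonal matrix |
| `gain_penalty` (`loss_cost_matrix`) | 10 | events | large enough to forbid regains wherever a pure-loss history exists |
| `limit` (`enumerate_mprs`) | 10,000 | MPRs | deterministic truncation flag |
| salinity bins | 0–5, 5–25, 25–35, >35 | ‰ | see boundary discussion below |
| `max_missing` (`trim_alignment_ends`) | 0.6 | proportion | strictly-greater rule |
| profile point estimates | ±10 % | — | widening of single literature values into intervals |
| `noise` (`simulate_specimen`) | 0 | relative SD | multiplicative Gaussian measurement error |

## Design choices that were genuinely open

* **The 5 ‰ boundary.** The published bins ("freshwater: 0–5 ‰;
  brackish: 5–25 ‰") include 5 in both classes. The classifier resolves
  every boundary upward (half-open bins `[0,5)`, `[5,25)`, `[25,35]`,
  `(35,∞)`): the 25 ‰ White Sea site is explicitly called marine in the
  source, which fixes the 25 ‰ edge, and 5 ‰ follows the same convention
  for symmetry. This is a package decision, not a statement from the
  literature.
* **Soil habitats** are folded into the freshwater class for invasion
  counting; the source's habitat scheme carries no separate soil colour,
  and the single soil-dwelling lineage is part of a freshwater radiation.
* **Majority rule is strict** (> 50 % of non-missing votes). A plurality
  is reported as an explicit tie, which then propagates as a polymorphic
  subclade cell rather than a silently picked winner.
* **Cirri counts as unordered categories.** FVC is modelled over the
  observed counts {7, 8, 9, 10} with unit costs, because an event that
  removes two cirri is one loss. The loss-only cost matrix is provided to
  explore the irreversible reading; on the packaged data it does not
  change the minimum (the unit-cost reconstruction is already all-loss
  from a ten-cirri root).
* **"Double" state grouping.** The two double argyrome types are kept as
  distinct states throughout; the root-state conclusion "a double
  dargyrome" falls out as the two-element root set rather than being
  imposed by merging the states beforehand. Users can still merge states
  by recoding the matrix if they want the grouped inference.
* **The species-level matrix is primary.** Event minima are computed on
  the species tree (intra-subclade variability included), not on the
  subclade consensus; the subclade view is a display.
* **Bold-cell logic.** "Unambiguously different" is encoded as strict
  disjointness: numeric intervals that merely touch at a shared endpoint
  (kineties 7 vs 6–7) overlap, and a trait missing from either profile
  never discriminates. Qualitative table notes that the fixed schema
  cannot express (peristome *width*, as opposed to extent) are outside
  the comparison; shape notes are expressible as categorical states.
* **Point estimates ±10 %.** Comparative tables mix ranges and single
  values ("~30 membranelles", "85 μm"); a tolerance is required for any
  overlap logic, and ±10 % keeps every printed bold/non-bold distinction
  intact.

## The synthetic generators: what they emulate and what they do not

`simulate_yule()` produces pure-birth trees; `evolve_character()` evolves
a categorical character with a *known* true event list, either as one
possible switch per edge (default; sufficient for lower-bound checks) or
as a continuous-time Markov jump process; `simulate_specimen()` draws
measurements uniformly within a profile's intervals with optional
multiplicative noise. All are pure functions of their seed; per-replicate
seeds derive from a master seed by fixed arithmetic
(`derive_seed()`), keeping every seed below 2^31.

These generators deliberately do not emulate: extinction, rate
heterogeneity across branches or characters, correlated characters,
sequence-level evolution, or non-uniform measurement error. Consequently,
passing tests establish the *algorithmic* correctness of the machinery
(parsimony scores, MPR statistics, bounds, identification logic) — not
that parsimony faithfully recovers real *Euplotes* history, where rate
variation and dense homoplasy can defeat any minimum-change criterion.

## Numerical and validation choices

* The brute-force oracle enumerates every ancestral assignment and shares
  no code with the dynamic programmes. Oracle equivalence is checked on
  1,000 random instances with at most 7 internal nodes and 3 states
  (polytomies, missing and polymorphic tips included), for the minimum,
  the per-node MPR state sets, and every transition and origin interval.
* The parsimony minimum is verified to bound the true simulated change
  count on 500 seeded Markov replicates, and to place the true root state
  in the root set in at least 95 % of 500 replicates at a low rate
  (16-tip trees, per-edge change probability 0.02, i.e. ~0.6 expected
  changes per tree). These problem sizes keep the full validation suite
  comfortably under two minutes while the oracle is still exhaustive.
* An external cross-check fits the same instances with an independent
  phylogenetics library's parsimony scorer; the packaged data are scored
  identically by both routes.
* Ties are never broken randomly anywhere: enumeration order is
  lexicographic, candidate ranking is (mismatch count, name), consensus
  ties are explicit values, and the pipeline's JSON output is
  byte-identical across reruns.
* Degenerate inputs fail loudly with context: malformed Newick reports a
  character offset, unknown states name the taxon and character, taxon
  mismatches point at `validate_against_tree()`, and trimming that would
  consume the whole alignment is an error rather than an empty object.

## Known limitations

* Parsimony only: no likelihood or Bayesian reconstruction, no
  branch-length awareness, no stochastic character mapping.
* The MPR-interval DP is exact for edge-local statistics (transition
  counts, origin entries); statistics that couple distant edges would
  require enumeration, which the cap may truncate on highly ambiguous
  characters.
* Local percent identity depends on alignment parameters; reported
  best-hit similarities from BLAST are reproduced only within a
  tolerance (±0.3 percentage points at the divergence scale involved),
  and the packaged tests exercise the machinery on constructed sequences
  rather than downloaded accessions.
* The figure-derived fixture cells are a transcription, as flagged by the
  provenance tags; anyone re-using the fixture for new inference should
  treat those cells accordingly.
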
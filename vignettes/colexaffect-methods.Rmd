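---
title: "Interpolating affective norms on colexification networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpolating affective norms on colexification networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colexaffect)
```

This vignette explains the model behind `colexaffect`, the choices made
where the design was genuinely open, and what the test battery does and
does not establish.

## From dictionaries to networks

Colexification — one word form covering several concepts — can be observed
directly in expert-curated concept databases, or inferred at scale from
translation data. The package supports both routes:

* `load_clics_edges()` reads concept edge lists whose per-edge language and
  family attestations are already tabulated.
* `detect_shared_translation()` links two pivot-language words whenever a
  single foreign word translates into both of them.
* `detect_roundtrip()` links pivot word *w* to pivot word *u* whenever some
  bilingual dictionary pair takes *w* to a foreign word *v* and *v* back to
  *u* ≠ *w*.

Shared-translation and round-trip links connect *words*, not disambiguated
concepts, so homographs ("bear" the animal, "bear" the verb) necessarily
contribute meaning-free edges. Two design rules mitigate this: a language
supports an edge at most once (weights count distinct languages, and
separately distinct families, resolved through a user-supplied
language-to-family table), and `filter_network()` drops edges under an
attestation threshold — the conventional concept-database cleaning rule is
at least 3 languages *and* 3 families; for translation-derived networks a
lighter rule (at least 2 languages) is customary because their language
inventories are far smaller.

All word comparison is case-insensitive on NFC-normalised, trimmed strings;
original casing is preserved for display. Merging is order-independent, and
`family_weight <= language_weight` holds on every assembled edge. For
counts-only inputs, duplicate rows merge by elementwise maximum — with the
language sets unknown, the maximum is the only safe lower bound on the size
of their union.

## Matching nodes to a lexicon

`match_nodes()` has two modes. In *word* mode a node matches exactly when
its case-folded label is a lexicon key. In *concept* mode the label is
cleaned first: parenthesised qualifiers (including nested ones) are
removed, the rest is lowercased and split on whitespace, and the connector
"or" is dropped; each remaining token is looked up and the node rating is
the mean over the tokens found ("wash (clothes)" matches *wash*; "breath or
breathe" averages *breath* and *breathe*). Tokens joined by anything other
than "or" are simply looked up individually — the cleaning rules are
deliberately minimal, and heavier normalisation (lemmatising, fuzzy
matching) is left to user preprocessing, where its effects are visible.

## The interpolation model

Per affective dimension, matching words are boundary values and every other
word *i* in a seeded component receives the fixed point of

$$ v_i \;=\; \frac{\sum_j w_{ij}\, v_j}{\sum_j w_{ij}}, $$

where $w_{ij}$ is the edge's language weight by default (`weight_mode` also
offers family weights and unweighted means; on any network with constant
language weights the unweighted and language-weighted solutions coincide).
This is a harmonic boundary-value problem: the solution exists, is unique
on seeded components, and obeys the maximum principle — no estimate can
leave the range of the seed values in its component. Components without a
seed are discarded and reported; coverage tracks the estimable fraction.

Numerical choices:

* **Synchronous (Jacobi) sweeps.** The update schedule is not dictated by
  the model; synchronous sweeps are order-independent and reproducible,
  which matters for bit-identical pipelines.
* **Undefined initialisation.** Non-seed values start undefined and first
  take a value once a neighbour has one; undefined neighbours are omitted
  from means. This avoids biasing early iterates toward an arbitrary
  constant — the fixed point reached is the same harmonic solution either
  way.
* **Convergence** is declared when the summed absolute change over all
  non-seed nodes and dimensions falls below `convergence_tol` (default
  `1e-6`), with a cap of 10,000 sweeps (hitting it flags and warns). The
  averaging operator is a weighted-mean contraction, so convergence is
  geometric and the defaults are cheap. Note the distinction between this
  stopping rule and distance to the fixed point: the oracle-equivalence
  tests, which compare against a direct sparse linear solve to within
  `1e-6`, run the iteration at `1e-10` so that the comparison measures the
  solution, not the stopping rule.
* **Leave-self-out estimates.** Seeds are clamped during iteration; only
  after convergence does each matching word get an estimate from its
  neighbours' values (true values for matching neighbours, converged
  estimates otherwise). Its own rating never enters its estimate, but note
  that in the full-network analysis a word's rating still influences its
  neighbourhood — removing that channel entirely is exactly what the
  cross-validation is for.

Each dimension propagates independently; a lexicon lacking a dimension
simply restricts the analysis.

## Validation battery

**Correlations.** Pearson ρ between true and estimated ratings, with the
Fisher 95% CI $\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})$ and the
usual t-test p-value. A neighbour-count threshold may restrict the
*correlation sample* (well-connected words receive signal through more
channels); it never restricts propagation. Spearman is available but never
the default, since the Fisher machinery presumes Pearson.

**Cross-validation.** `cross_validate()` splits matching words 75/25,
propagates from the training portion only, reads estimates at test words,
and Fisher-averages per-repetition correlations over (by default) 10
repetitions. Test words disconnected from all training words are excluded
and counted in the percent-computable statistic. With `train_frac = 1` the
function degenerates to the full-network path, keeping one code contract.

**Null models.** The *permuted-values* null shuffles estimates across the
evaluated words, destroying the word-estimate pairing while keeping both
marginals; it is distribution-free and its mean ρ tends to zero as
repetitions grow. The *random-neighbours* null keeps each evaluated word's
degree and original edge weights (assigned to sampled neighbours in input
order — the pairing is otherwise arbitrary, and this choice is documented
precisely because it is a convention) but draws its neighbours uniformly
without replacement from the non-matching words, whose converged estimates
supply the averaged values; a degree exceeding the pool size falls back to
the full pool with a message. Summaries use Fisher back-transformed means,
empirical 95% intervals, and add-one empirical p-values
$(b+1)/(\text{reps}+1)$, which finite simulation can never drive to zero.
Undefined correlations (degenerate variance) are recorded as 0 with a flag
rather than dropped, so calibration failures remain visible.

**Dip test.** Polysemous words sit between meaning clusters, so the spread
(SD) of their neighbours' ratings tends to be bimodal across words.
`dip_statistic()` implements Hartigan's dip — the sup-norm distance from
the empirical CDF to the nearest unimodal CDF — exactly, via a band
formulation: a unimodal CDF within distance *d* exists iff, for some mode
placement, a convex nondecreasing function fits the band $[F-d,\,F^-+d]$
left of the mode and a concave one right of it, with ordered junction
values (an atom of the fitted CDF at the mode is allowed, which is what
makes point masses dip-zero). The binding constraints are chords over
triples of jump points, linear in *d*; the junction condition, where it
binds, is resolved by bisection on a piecewise-linear, strictly decreasing
excess. The test suite checks the implementation against an independent
linear-programming oracle that minimises *d* directly over every mode
placement. P-values come from a bootstrap uniform null at matched sample
size (`dip_null_reference()`, at least 2000 draws recommended; the
reference is precomputable and shareable across tests at the same n).

**Dominance residual.** Valence and dominance are substantially collinear
in affective lexica, so `dominance_residual_analysis()` reports
$100\,(1 - \mathrm{SSR}(D \sim V + \hat D)/\mathrm{SSR}(D \sim V))$ — the
share of dominance variance unexplained by valence that the estimated
dominance recovers — plus the partial coefficient's p-value. The statistic
is invariant to affine rescaling of all three inputs, and an estimate
collinear with valence to machine precision returns 0 with a flag.

**Robustness sweeps.** `language_threshold_sweep()` refilters the network
at increasing minimum language weights and reruns the full analysis,
emitting a tidy table; thresholds that empty the network flag their row
rather than failing.

## The synthetic generator

`synth_config()` encodes the study conditions the package is exercised
under. Words fall into meaning clusters; ratings are cluster centres (drawn
uniformly in the scale bounds) plus Gaussian noise, clipped at the bounds
(clipping rather than resampling: the bias is negligible at the small noise
levels used); a coverage fraction per cluster is exported as the "known"
lexicon. Edges arise within clusters with a fixed probability, and each
word independently becomes a homograph with a small probability, gaining
one edge to a random word of another cluster — homography being a property
of individual word forms is why the rate is per word rather than per pair.
Edge attestation counts follow `1 + Geometric(0.5)` capped at the language
inventory: most colexifications are attested once or twice, a few widely,
as in real colexification data. Languages map to families round-robin.

Reference conditions (the defaults): 40 clusters × 50 words, 20 languages
in 8 families, intra-cluster edge probability 0.15 (mean within-cluster
degree ≈ 7, keeping clusters connected at 50% coverage), homograph rate
0.01, rating noise SD 0.05 on a 0–1 scale, coverage 0.5. Under these
conditions the 75/25 CV Fisher-averaged valence correlation sits near
0.98 and both nulls are centred at zero — the acceptance script
recomputes these numbers from scratch.

`generate_dictionaries()` inverts shared-translation detection: for every
edge and attesting language it emits one synthetic foreign word translated
to both endpoints, with labels unique per (edge, language) so no accidental
identical translations arise; reconstruction is exact, weights included.
`plant_dominance_structure()` generates (V, D, D̂) triples with an exact
expected incremental residual-variance share, used to calibrate the
dominance analysis (a planted 40% share is recovered within ±5 points at
n = 2000).

**What passing tests do and do not show.** The generator plants exactly the
structure the method assumes: cluster-smooth ratings and independent noise
edges. Real colexification networks have heavy-tailed degrees,
culturally correlated noise (shared etymology, borrowing), concept labels
needing cleaning, and lexica with rater disagreement — none of which the
generator emulates. Green tests establish that the algorithms are
implemented correctly and behave as the theory predicts under favourable
conditions, not that real networks carry this much affective signal;
correlations on real data are substantially lower and bounded above by
lexicon reliability, not by 1.

## Problem sizes and reproducibility

Analyses in the test suite and acceptance script use networks of 200-2000
nodes, 10,000 permuted-value repetitions, 1,000 random-neighbour
repetitions, 200-seed dip calibrations against a shared 2,000-draw
reference, and n = 2000 for the dominance plant — sizes at which every
stochastic conclusion is stable across seeds while a full run stays in the
minutes range on one CPU. Every randomised procedure takes an explicit
seed; the CV split and each null model consume separate sub-streams
derived from the top-level seed, so reports are bit-reproducible.

## Known limitations

* Only two-hop round trips through the pivot are detected; multi-hop pivot
  chains are out of scope.
* Counts-only concept inputs cannot have families recomputed; threshold
  sweeps then operate on the counts as given.
* The interpolation is unsigned and undirected: antonymic colexifications
  (which would call for signed edges) are averaged like any other.
* Seeds are trusted equally; there is no confidence weighting by rater SD,
  though the columns are carried for diagnostics.
* The dip-test null is the uniform distribution at matched n — the
  standard calibration, but a conservative one for strongly skewed
  neighbour-SD distributions.
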
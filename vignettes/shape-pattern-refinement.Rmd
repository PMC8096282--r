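---
title: "Loop-motif SHAPE patterns and posterior penalty refinement: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop-motif SHAPE patterns and posterior penalty refinement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `shaperefine`, the
choices made where the design was genuinely open, and what the synthetic
benchmark does and does not establish. Nothing here reports a number the
package's tests or `scripts/acceptance.R` do not themselves compute.

## The model

### Loop motifs and their extraction

A *loop motif* is the equivalence class of loops sharing a type
(hairpin, bulge, internal) and length specification, irrespective of
sequence. Loops are the faces of the nested base-pairing layer. Three
rules restrict which loops enter the statistics:

* **Two flanking base pairs.** Every bounding helix of a loop must carry
  at least two consecutive stacked pairs; the closing pair and the next
  stacked pair are recorded. We enforce this on *every* helix of a loop
  (for an internal loop, both the outer and the inner helix). The rule
  could be read as applying only where a second pair happens to exist;
  we prefer the symmetric reading because it gives a single testable
  eligibility criterion and excludes loops whose boundaries are
  themselves uncertain.
* **Pseudoknot exclusion.** Pairs crossing the nested layer (non-round
  bracket layers in dot-bracket input, or crossing pairs in CT input,
  layered greedily) are pseudoknots. A loop is dropped when any of its
  unpaired residues participates in a pseudoknot pair: characteristic
  patterns describe loops in their unbound state, and a kissing-loop
  interaction changes exactly the reactivity signature the patterns
  encode. This exclusion is also what later lets penalties *detect*
  kissing loops.
* **Multibranch loops** are extracted and classified but never scored
  against patterns: their geometry is too heterogeneous for a per-motif
  position statistic.

Asymmetric internal loops need a position convention. Positions are
counted from the 5′ end of the motif, with the *shorter side first*;
when the 5′ side is the longer one, the loop is read mirrored (both
sides reversed, 3′ side first). This canonicalization is idempotent and
makes 1×2 and 2×1 loops one motif. Whether the original convention
enumerated the 5′ side or the shorter side first is not documented
anywhere we could check; the mirror reading is the one under which the
motif label and the position enumeration stay consistent. Bulges are
enumerated 5′→3′ along their single run regardless of side.

### Characteristic patterns

For each motif, all ordered position pairs are compared with a paired
Wilcoxon signed-rank test over loop instances (rows with a missing value
for either position are dropped per pair; pairs with fewer than `min_n =
5` usable rows are skipped — the exact test cannot reach *p* < 0.05
below *n* = 5). A pair is retained when *p* < `alpha` (default 0.05)
**and** it ranks among the `top_k` (default 2) smallest p-values of the
motif. We read the published rule as the conjunction of both conditions.
The test is two-sided; the direction (which position is `high_pos`) is
assigned post hoc from the paired means.

Two numerical points deserve emphasis:

* **Exact distribution with ties.** The signed-rank null distribution is
  computed by a generating-function convolution over doubled midranks,
  so ties and zero differences (dropped, classical treatment) are handled
  exactly. `stats::wilcox.test` abandons its exact path under ties; our
  tests use it as an independent cross-check on tie-free data only. The
  normal approximation applies the tie-corrected variance
  `sum(r^2)/4` and a continuity correction. `auto` mode switches at
  *n* = 25; pattern discovery explicitly requests the exact mode up to
  *n* = 100, where the O(n³) convolution is still far below a
  millisecond.
* **Saturated tests tie.** Once every difference has the same sign, the
  statistic sits at its extreme and the exact p-value equals
  `2^(1-n)` — the smallest value that sample size can produce,
  regardless of effect magnitude. Comparing such p-values across pairs
  compares only their *n* (missing data make *n* differ between pairs)
  plus floating-point jitter from the approximation. We therefore treat
  all saturated pairs of a motif as tied and rank them by mean
  difference, largest first; non-saturated pairs rank after them by
  p-value. Without this rule the top-2 selection is decided by noise
  whenever several pairs saturate, which is the common case for strong
  motifs.

### The posterior penalty

For a loop of a motif with patterns, each pattern gives an observed
difference `D` = reactivity(high) − reactivity(low) (skipped when either
value is missing). With priors `P(W=1)`, `P(W=0)` and class-conditional
densities `f_true` (normal-inverse Gaussian) and `f_false` (Johnson's
SU), Bayes' rule yields `P(W=1 | D)`, evaluated in log space. Pairs with
posterior strictly below `posterior_cutoff = 0.5` contribute
`δ = −ln(p/(1−p)) > 0`; the loop's penalty is their sum, zero when no
pair falls below the cutoff or none is evaluable. Loops of motifs
without patterns carry `NA` penalties and are flagged.

Conventions at the edges:

* `D` uses the globally learned pattern direction, never a per-instance
  reordering — the penalty must be able to go negative in spirit
  (posterior above ½) when a loop contradicts its motif.
* When both densities underflow at an extreme `D`, the datum is
  uninformative and the posterior falls back to the prior (with a
  warning) rather than NaN; one-sided underflow resolves to 0 or 1.
* Posteriors of exactly 0 or 1 are clipped to `[1e-12, 1 − 1e-12]`
  before the log-odds, with a warning.
* A loop whose pattern pairs are all missing has penalty 0 (the empty
  sum). It is classified like any penalty-0 loop; we considered
  reclassifying it `fair`, but the empty-sum convention keeps the
  penalty a pure sum and the situation is rare under realistic missing
  rates (<5%).

Priors default to `(0.549, 0.451)` — the published estimate from pairs
of bases in true vs false loops of a candidate ensemble — and are refit
by `estimate_priors()` whenever training data are available. When we
count pairs from synthetic ensembles we keep multiplicity (a loop
sampled by many candidates weighs accordingly), while the *density*
training samples de-duplicate false loops by identity so a frequently
re-sampled decoy does not dominate the fit.

### Fitting the class-conditional densities

Both families are fitted by maximum likelihood with `stats::optim`
(L-BFGS-B) on transformed parameters: NIG as
`(log γ₀, β, μ, log δ)` with `α = sqrt(γ₀² + β²)` so `α > |β|` holds by
construction; Johnson's SU as `(γ, log δ, ξ, log λ)`. Moment-based
starting points plus two perturbed restarts guard against local optima;
objective evaluations returning non-finite log-likelihoods score a large
constant, and box bounds keep the line search away from numerically
degenerate scale values. The NIG CDF (needed for the Kolmogorov–Smirnov
check) is a trapezoid integration of the density on a 65,536-point grid
spanning ±40 standard deviations, interpolated; its absolute accuracy is
about 1e-7, far below the KS statistic's resolution at the sample sizes
involved. A KS p-value below 0.05 warns but does not error: a marginal
fit should be visible, not fatal. Fewer than 50 training samples also
warns. Fits on constant data error out (degenerate scale).

At 10,000 training draws the MLE's own sampling error for the NIG
asymmetry and location parameters can exceed 10% relative for
small-magnitude truths; the recovery checks in the test suite therefore
use well-conditioned generating values and require joint
recovery-plus-KS success in at least 18 of 20 seeded runs.

### Classification and selection

Guidance loops are `good` (penalty exactly 0), `fair` (0 < penalty ≤ 1,
or patterns unavailable) or `poor` (penalty > 1); the boundaries are the
published ones and sit at `fair_threshold = 1`. A loop's *region* is
each side run extended by `region_pad = 4` nt, clipped to the sequence;
multi-sided loops use the union of per-side intervals (merged when they
touch).

A candidate satisfies the selection criteria when:

1. every good guidance loop is present — identity is the strictest
   reading: same type, same unpaired-position sets, same closing pairs
   (slippage is handled only by the evaluation metrics, never here);
2. no candidate loop overlapping a fair region has penalty above 1 —
   *overlap* means any unpaired residue inside the region, the weakest
   reading, because a region is a neighbourhood, not a container;
3. every poor guidance loop is absent, and every candidate loop
   overlapping its region has strictly lower penalty; a region that
   became fully paired satisfies this vacuously — pairing the region *is*
   the desired replacement;
4. among candidates meeting 1–3, total penalty — summed over **all**
   candidate loops with available patterns, not only those near guidance
   regions, since a refinement should not be free to invent bad loops
   far from the edits — is minimal.

If no candidate meets 1–3, the lowest-total-penalty candidate is
returned with `fallback_used = TRUE`. Ties break on input order; the
guidance is appended to the pool unless already present (it may
legitimately win). Candidate loops without patterns contribute nothing
to the total and can violate neither (2) nor (3); they are visible in
the audit table. `centroid_structure()` offers the
symmetric-difference centroid when suboptimal-structure selection is not
wanted.

### Accuracy metrics and the robustness protocol

Sensitivity is TP/(TP+FN) over base pairs, PPV is TP/(TP+FP); MCC
defaults to `sqrt(sensitivity × PPV)`, the standard approximation in RNA
structure scoring. The published work cites an external scorer whose
exact formula it does not print, so an exact confusion-matrix MCC (true
negatives = all unordered position pairs in neither structure) is
available behind `exact_mcc = TRUE`. Slip matching (a predicted pair
may match a native pair displaced by one nucleotide on either strand,
each native pair consumed at most once, exact matches claimed first) is
off by default.

`shuffle_noise()` permutes the reactivities of exactly
`round(fraction · m)` of the `m` non-missing positions, preserving the
value multiset and all missing entries. The robustness protocol re-runs
selection on the *fixed* candidate ensemble under shuffled profiles, ten
replicates per fraction. The original protocol also regenerates the
guidance and the ensemble from the shuffled data; that step needs a
thermodynamic folding engine, which this package deliberately consumes
only through files, so regeneration is out of scope here and the
reported degradation isolates the selection stage.

## The synthetic benchmark

The generator emulates the statistical structure the model assumes:

* paired residues draw reactivities from a truncated normal
  (mean 0.1, sd 0.1, truncated at 0); unpaired residues from a truncated
  normal (mean 0.5, sd 0.25);
* selected motif positions carry planted mean offsets. The defaults
  plant one elevated position (+0.8, a reactive apex near 1.3 on the
  normalized SHAPE scale) and two depressed positions (−0.35, an
  unreactive loop residue comparable to a paired one) per motif,
  mirroring the published tetraloop picture: central residues reactive,
  first and last not. Two low positions make both top-ranked patterns
  strong; with a single one, the second retained pattern pits the apex
  against an undistinguished position and its smaller margin inflates
  penalty noise on *correct* loops;
* missing values are injected at 3–5%;
* structures are assembled from stem-loop units (helices of three
  stacked pairs, so every loop carries its flanking pairs) joined by
  exterior spacers; requested hairpins cap bulge/internal units where
  possible so the extracted inventory matches the request;
* candidate ensembles perturb helices locally — shift by 2–5 nt, shrink
  or grow by 1–2 pairs, delete, or relocate into unpaired territory —
  with probabilities 0.15/0.25/0.25/0.05/0.3. Deletions are rare and
  relocations common because a Boltzmann-weighted sampler rarely
  abandons a stacked helix outright but readily proposes alternative
  pairings in flexible regions. Two cleanups keep candidates physical:
  isolated single pairs are removed (folding engines disallow lonely
  pairs, and a 1-pair helix would evade the flanking-pair eligibility
  rule and so dodge all penalties), and the fully open chain is never
  proposed.

Standard problem sizes, chosen to keep the full suite within a few
minutes while leaving comfortable statistical margins: training
benchmarks of 12 RNAs of 170 nt with eight pattern-bearing loops each
(`benchmark_spec()`); refinement trials on compact 70-nt two-stem-loop
RNAs (`refinement_spec()`) with pools of 25 candidates; 20 seeded trials
per property; density fits on 10,000 draws.

What passing tests show: the pipeline recovers planted patterns,
discriminates true from false loops, repairs planted wrong loops, and
degrades under shuffled profiles — *under the generator's assumptions*.
What they do not show: performance on real SHAPE data, whose
reactivities are heavy-tailed and position-correlated, whose "false"
loops come from a thermodynamic landscape rather than local
perturbations, and whose native structures contain non-canonical pairs
and tertiary contacts the generator ignores. The default priors and any
shipped densities should be refit on the user's own benchmark
(`fit_posterior_model()` / `train_posterior_model()`) before real use.

## Known limitations

* Patterns exist only for motifs observed in training; rare motifs fall
  back to `fair`, so a wrong loop of a rare motif is invisible.
* Penalties on correct loops are occasionally nonzero (a reactive apex
  drawn low, for instance); about one trial RNA in ten acquires a
  spuriously `poor` true loop under the default noise, in which case the
  truth itself can fail criterion 3 and selection falls back. This is a
  property of the sharp per-pair classifier, not of the implementation.
* The MC-Fold-style export clips the linear probability
  `0.68 · reactivity + 0.2` into `[0, 1]`; whether the original
  conversion clipped is not documented, but anything else is not a
  probability.
* The external-engine adapter (`external_fold()`) runs any user command
  template and parses dot-bracket output; it is a convenience, not a
  dependency, and everything works from files when no engine is
  installed.
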
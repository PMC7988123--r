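---
title: "Quantifying open-field behavior from teleportation trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying open-field behavior from teleportation trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openfieldr)
```

# The measurement problem

In the open field test, anxiety-like behavior is read off movement in a
novel bounded arena: subjects that avoid the center and hug the walls
score high on thigmotaxis and low on center entries. In the
virtual-reality variant this package targets, participants stand in a
small tracking space and traverse a 100 m × 100 m virtual arena by
*teleportation*: they point at a destination and jump. The position log
(20 Hz for a 900 s session) is therefore a sequence of dwell episodes
separated by discontinuous jumps of a few meters, not a continuous path —
which shapes several design choices below.

# Arena geometry and the behavioral indices

Two overlays of the square arena (side $L$, default 100 m) drive the
indices:

* the **equal-area partition**: a centered inner square of side
  $L/\sqrt 2$, so the inner region covers exactly half the area; the
  outer band has width $(L - L/\sqrt 2)/2 \approx 0.1464\,L$ (14.64 m at
  $L = 100$);
* the **7 × 7 bin raster** (bin side $L/7$): the 24 bins touching a wall
  form the outer ring, the 25 interior bins the inner block — a discrete
  approximation of the equal-area split.

From one trajectory, `compute_indices()` returns:

* time per region: sample counts divided by the sample rate;
* path length per region: each inter-sample segment is assigned to the
  region of its *starting* sample (the alternative midpoint rule was
  rejected as harder to reason about and to test; for 50 ms steps the
  two differ negligibly, and for teleport jumps no rule is "correct");
* walking speed per region: region path over region time, reported as
  missing (`NA`), not 0, for an unvisited region;
* mean wall distance: the per-sample minimum distance to any wall,
  averaged; under uniform occupancy its expectation is $L/6$;
* the four crossing classes: for each consecutive sample pair whose bins
  differ, one crossing classified by origin → destination ring
  (outer→outer thigmotaxis, outer→inner center entry, inner→inner center
  ambulation, inner→outer center leave), as counts and as percentages of
  all crossings.

**Boundary conventions.** The inner region is the *closed* centered
square; bins use floor division with the far walls clamped into the last
row/column. These are measure-zero choices; they are fixed so results are
bit-reproducible.

**Multi-bin jumps.** A teleport can traverse several bins between two
samples. By default one crossing is counted per consecutive-sample bin
change, classified by the endpoint rings only — this is robust to the
sampling process and does not pretend to know the (unobserved)
intermediate path. An optional `mode = "interpolate"` subdivides the
straight segment at every grid line and counts each boundary passage;
it is off by default because a teleporting participant never occupied
the intermediate bins.

# The random-agent null model

Observed indices are compared against expectations under random
movement. `expected_values()` simulates teleporting agents:

* a step proposes a heading (current heading plus a normal perturbation,
  sd 45°; heading is *persistent* — "straight on" means relative to the
  previous jump) and a distance from a pluggable sampler;
* proposals landing outside the arena are rejected and *both* heading
  and distance are redrawn (configurable cap `max_reject`, default
  10,000, so an infeasible distance distribution fails loudly rather
  than spinning);
* a run starts from one of 8 poses — 4 at the center facing each wall, 4
  at wall midpoints 1 m inside the wall facing the center — cycled
  deterministically across runs, and executes 367 teleports (the cohort
  median of the sessions the model emulates);
* the visited positions are expanded to a 900 s, 20 Hz sample stream
  with equal dwell per destination, so the index code consumes simulated
  and real sessions identically. Equal dwell is an assumption: real
  participants dwell longer at some destinations, but no dwell
  distribution is available to sample from.

**Distance sampler.** The study this emulates drew distances from the
participants' own teleport distances, which are not published. The
default is therefore a truncated log-normal (median 3 m, $\sigma_{\log} =
0.5$, truncated to 0.1–15 m) — plausible for arc-based VR teleportation,
where a jump of more than a dozen meters is rare. Consequences: expected
values under the default kernel are *structurally* comparable to the
study's (the tests assert entry % = leave % within Monte-Carlo error,
proportions summing to 100, and boundary persistence pushing expected
outer-region time above the 450 s uniform reference) but are not
expected to equal its printed μ values digit for digit. An empirical
sampler (`dist_sampler_empirical()`, fed from `extract_teleports()`)
restores the original procedure when real logs are available. Both
samplers consume exactly one uniform variate per draw so seed streams
stay aligned across samplers.

The degenerate `position_sampler = "uniform"` mode replaces the kernel
with i.i.d. uniform positions, for which the expectations have closed
forms (450 s per region, mean wall distance $L/6$); the test suite uses
it to anchor the whole simulation-plus-indices chain to analytic truth.

# The synthetic cohort generator

`generate_cohort()` exists so every pipeline stage can be exercised, with
known ground truth, without any participant data. Per participant a
latent anxiety factor $z \sim N(0,1)$ drives:

* the wall-attraction coefficient $\beta = \mu_\beta + \sigma_\beta(\rho
  z + \sqrt{1-\rho^2}\,\varepsilon)$. The agent proposes destinations
  exactly like the null model and accepts them with probability
  $\exp(-\beta\, d_{\mathrm{wall}}/(L/2))$, normalized so the maximum
  acceptance probability is 1. This Metropolis-style thinning (rather
  than, say, distorting headings) was chosen because it makes the
  $\beta = 0$ reduction *exact*: with $\beta = 0$ no acceptance draw is
  consumed and the agent is byte-identical to the null agent under a
  shared seed — a tested contract.
* all trait scores, as instrument-scale affine transforms
  $\mathrm{score} = m + s\,(a z + \sqrt{1-a^2}\,e)$, rounded and clipped
  to the legal range (STAI trait 20–80; ASI-3 subscales 0–24 with the
  total formed as their sum; ACQ and MI 1–5). Scores are generated at
  scale level; item-level simulation is out of scope.

Defaults: $\mu_\beta = 1.5$, $\sigma_\beta = 1.5$, which keeps the
cohort in the approximately linear region of the thigmotaxis response to
$\beta$ (the response saturates above $\beta \approx 3$, and strongly
negative tails make corner states nearly absorbing for the rejection
sampler) and puts mean thigmotaxis a few points above the null
expectation — the size of effect typical for human cohorts. The STAI
trait scale carries the highest factor loading (0.85) as the core
trait-anxiety instrument; subscale loadings are 0.5–0.6. Under these
settings a trait–behavior correlation of $\rho = 0.8$ at $n = 80$ is
detected (positive, $p < .05$) in ≥ 90% of seeded replicates — the
power operating point the acceptance suite verifies.

Ratings (anxiety and arousal at center, wall and corner probes, 0–100)
default to *no* position effect plus noise, mirroring a null ANOVA
outcome; `rating_effect` adds a linear-in-centrality shift as a positive
control, and `missing_rating_rate` exercises listwise exclusion.

**What the generator does not emulate:** real dwell-time heterogeneity,
within-session habituation or drift, tracking glitches and dropped
frames, item-level questionnaire structure, and any nonlinearity in the
trait–behavior link. Passing tests therefore demonstrate that the
pipeline recovers what this generative family encodes — not that real
cohorts satisfy these models.

# The inferential layer

* **One-sample and paired t** with Cohen's $d = (\bar x - \mu)/s =
  t/\sqrt n$. The 95% CI for $d$ inverts the noncentral-t CDF in its
  noncentrality parameter (bisection via `uniroot`, tolerance $10^{-8}$,
  bracket expansion doubling from $\pm(|t|+10)$) and divides the limits
  by $\sqrt n$. Zero-variance samples raise a degenerate-sample error
  rather than returning infinities.
* **Pearson correlations** on pairwise-complete observations with the
  usual t-based two-sided p; the 8 traits × 3 behaviors table uses a
  Bonferroni threshold $\alpha/24$.
* **Correlation-direction sign test**: a coefficient counts toward
  "more center avoidance with higher anxiety" when positive for outer
  time and thigmotaxis and negative for center entries — the only coding
  consistent with what the indices measure; it is isolated in
  `is_avoidance_direction()` and covered by a table-driven test. The
  count of $k$ of $n$ such coefficients is tested against an equal split
  via $\chi^2 = (2k-n)^2/n$ on 1 df, upper tail.
* **Repeated-measures ANOVA**: within-subject one-way decomposition with
  listwise exclusion of incomplete subjects. Sphericity is gated by
  Mauchly's test at $\alpha = .05$ (the conventional companion of the
  Greenhouse–Geisser correction; a `force_gg` flag covers reporting
  styles that always correct). The p-value for Mauchly's W uses Box's
  second-order $\chi^2$ series, matching `stats::mauchly.test` exactly.
  When the gate (or the flag) fires, both dfs are multiplied by the
  Greenhouse–Geisser $\hat\varepsilon = \mathrm{tr}(M)^2 / ((k-1)
  \mathrm{tr}(M^2))$ with $M$ the covariance of orthonormal contrast
  scores. Partial $\eta^2 = SS_e/(SS_e + SS_r) = F\,df_1/(F\,df_1 +
  df_2)$ — invariant under the $\varepsilon$ rescaling — is reported
  with a 90% noncentral-F pivot interval
  ($\lambda/(\lambda + df_1 + df_2 + 1)$ at the dfs used for the
  p-value). When even a central F exceeds the observed value with the
  required tail mass, the corresponding limit is 0; for very small F the
  interval can sit entirely at 0 below the point estimate, which is a
  known property of this pivot, not a bug.

# Pipeline determinism

`run_all()` derives every stage seed from one master seed (null model:
`seed*100 + 1`; experiment $i$: `seed*100 + 1 + i`) and the cohort
generator draws per-participant trajectory seeds from its own seeded
stream, so the entire output directory — expected values, index tables,
result tables, heatmaps, JSON manifest — is checksum-identical across
re-runs. The manifest records the derived seeds and an MD5 of the
serialized configuration.

# Problem sizes in the test suite

The suite anchors Monte-Carlo checks at sizes chosen to balance
resolution against a few minutes of total runtime: $10^6$ uniform points
for the geometry expectations, $10^4$ points against the brute-force bin
oracle, 200 uniform-sampler runs and 1,000 teleport-kernel runs for the
expected-value properties, 20 cohorts of $n = 80$ for the power check,
and 1,000 simulations for the type-I calibrations of the t and
correlation tests. Unit tests use smaller, fixed-seed configurations of
the same machinery.

# Known limitations

* Expected values under the default kernel depend on the assumed
  distance distribution; treat them as reference points for the
  machinery, and supply an empirical distance sample for substantive
  use.
* The equal-dwell expansion makes simulated "time in outer region"
  equivalent to the fraction of destinations in the outer region; if
  real dwell correlates with position (e.g., longer pauses at walls),
  null expectations for time-based indices shift.
* Indices assume near-uniform sampling at the nominal rate; no
  resampling is performed, and dropped-frame handling is limited to the
  validation options of `read_log()`.
* The arena is exactly square and axis-aligned; polygonal or 3D arenas
  are out of scope.
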
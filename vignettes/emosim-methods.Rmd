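---
title: "The emosim model: emotional bookkeeping, partner selectivity, and the statistics of emergent social structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The emosim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the model addresses

Many primates maintain long-term, partner-specific affiliative
relationships, and grooming tends to be reciprocated. One candidate
proximate mechanism is *emotional bookkeeping*: instead of remembering
individual interaction episodes, an animal integrates the emotional
effect of affiliation received from each partner into a single dynamic
attitude per partner, and lets that attitude bias its future partner
choice. `emosim` implements an agent-based model built around exactly
this mechanism and a matched control in which the attitudes are frozen
functions of rank distance, so that one can ask which emergent group
patterns — reciprocity, partner-specific preferences, evenness of
partner use — *require* the dynamic bookkeeping and which arise from
rank structure alone.

## The model in brief

Twenty agents live on a continuous 300 m x 300 m torus (1 grid unit =
1 m; the torus removes border effects). Time is continuous, in model
MINUTES; the calendar defines 12 HOURS = 1 DAY, 7 DAYS = 1 WEEK,
50 WEEKS = 1 YEAR (so 1 YEAR = 252,000 min). The simulation is
event-driven: each agent is activated at scheduled instants (intervals
drawn from N(1, 0.05) min, floored at 0.01), selects one action, and is
re-scheduled; movement runs in bouts with sub-activations every 3
seconds; attacks interrupt their target immediately.

Each agent `i` carries:

* a fixed dominance strength `myDOM_i` (defaults evenly spaced
  0.05...1.00),
* an emotional state — arousal, anxiety, satisfaction, all on [0, 1] —
  relaxing exponentially towards limit values and perturbed by discrete
  social events through a salience table,
* fixed partner-specific `FEAR_ij = myDOM_j - myDOM_i` (range
  -0.95...+0.95), and
* dynamic partner-specific `LIKE_ij` in [0, 1].

In the **dynamic-attitude** (bookkeeping) variant, grooming received by
`i` from `j` drives the partner-specific satisfaction `PARTNER_SAT_ij`
(up at 0.1/min while being groomed by `j`, down at 0.02/min otherwise),
which LIKE integrates as

    LIKE_ij(t_n) = max( (LHW * LIKE_ij(t_{n-1}) + dt * PSAT_ij(t_n)) / (LHW + dt),
                        PSAT_ij(t_n) ),    dt = t_n - t_{n-1},

with the LIKE-history weight `LHW` = 1 DAY = 720 min. The weighted-mean
branch makes LIKE decay slowly when a partner stops grooming; the outer
`max` lets current grooming pull LIKE up immediately to the attained
`PARTNER_SAT` level — this is what lets preferences bootstrap from an
initially LIKE-less group. In the **fixed-attitude** control,
`LIKE_ij = max(0, 0.243 - 0.36 |myDOM_j - myDOM_i|)`, symmetric and
constant.

### Action selection and the LPS parameter

An activated agent first checks cohesion (grouping pre-empts everything:
fewer than 3 others within 20 m, or anyone farther than 100 m, triggers
approaching a random member). Otherwise it considers its 10 nearest
recognizable individuals (within 50 m and its current view cone of 120°,
or 360° when scanning — scanning is drawn before the round with a
probability linear in arousal). Behaviours are distance-gated: groom /
leave / attack within 1 m, signals and avoidance within 5 m, approach
within 50 m; rest and a bounded random walk are always available. Each
eligible (behaviour, target) pair gets a weight:

* *baseline tendency* per behaviour (free parameters, see
  `behavior_params()`),
* *emotional modulation*: arousal scales every active behaviour up;
  anxiety scales affiliation and submission up and makes aggression
  risk-sensitive (scaled down against higher-ranking targets);
  satisfaction scales affiliation down,
* *attitude modulation*: submission scales as `exp(+4 FEAR_ij)`,
  aggression as `exp(-4 FEAR_ij)`; affiliation towards `j` is multiplied
  by `m_j / mean(m)` with `m_j = (1 - LPS) + LPS * LIKE_ij`.

`LPS` (LIKE-partner selectivity, in [0, 1)) is the central experimental
dial: at 0, LIKE plays no role (the *null model*, identical in both
variants); near 1, affiliative choice concentrates almost entirely on
the most-LIKEd candidates.

**Design note on the normalization.** The selectivity factor is `m_j`
*relative to the candidate mean*, not raw `m_j`. Raw multiplicative
damping makes total affiliation proportional to the LIKE level of the
neighbourhood, and since LIKE starts at 0 the bookkeeping variant then
freezes at high LPS (in desk-scale runs grooming collapsed by two
orders of magnitude), which contradicts the target phenomenology —
selectivity is supposed to change *whom* an animal grooms, not abolish
grooming. Normalizing preserves every contractual property (relative
weights between two candidates are still `m_j : m_k`, so at LPS = 0.99 a
LIKE-1.0 partner outweighs a LIKE-0.0 partner 100 : 1; at LPS = 0 each
factor is exactly 1.0, keeping the null model bit-identical across
variants) while leaving overall affiliative tendency to the emotional
state.

### Conflicts

An attack (1 m) immediately activates the target, which flees or
counter-attacks with weights driven by its FEAR and anxiety. A
counter-attack escalates the fight: the winner is drawn by the sigmoid
`P(i wins) = 1 / (1 + exp(-8 (dom_i - dom_j)))`, the loser flees beyond
5 m, the winner is re-scheduled 0.25 min later, and bystanders within
20 m receive an arousal/anxiety jolt and a prompt activation. Without a
counter-attack the attacker wins by default. Approaching a fleeing or
settling group, movement bouts always end with a *proximity update*: a
FEARed (dominant) individual within 5 m raises the agent's arousal
limit from 0.09 to 0.3 until the dominant moves off, and agents that
FEAR the mover re-check their own limit.

## Observation protocol

Statistics use only the final recording window (default: the last YEAR
of a 2-YEAR run after a 21,600-min stabilization; the desk-scale setup
`scaled_config()` uses a 1-WEEK burn-in with an 8-WEEK fully recorded
window). Every 3.5 DAYS (42 recording hours):

* directed behaviours accumulated over the interval become hourly rates
  (counts/h; grooming in min/h, bouts apportioned across interval
  boundaries by overlap),
* proximity is point-sampled by one-zero scoring of every dyad at
  <= 1 m (a symmetric measure),
* LIKE matrices and emotional states are point-sampled.

Per-interval values are averaged arithmetically over the window (100
intervals in a full YEAR). Sampling is point sampling, the plain
reading of scoring "at the time of sampling"; interval-averaged
proximity would be a different (smoother) estimator.

## The statistics battery

For each dyadic measure (`summarize_run()`):

* **Tau-Kr reciprocity** — Kendall's tau-b between each actor's outgoing
  row and incoming column (ties matter in sparse rate matrices, hence
  tau-b), averaged unweighted over rows with variation; matrices with
  more than 90% unusable rows are reported undefined (submissive
  matrices typically are).
* **Buzas–Gibson evenness** `H* = exp(H) / (N - 1)` with natural-log
  Shannon `H` per actor, averaged over actors; all-zero rows are
  excluded (H is undefined on an empty distribution). `H* = 1` iff
  partner use is perfectly even; the natural log is forced by the
  `exp()` in the normalization.
* **Partner-specificity SD** — sample SD of the dyadic values within
  each rank-distance class (signed classes for directed measures,
  absolute for symmetric ones), averaged over classes with at least two
  dyads (the lone ±0.95 dyads drop out). Exactly zero for any measure
  fully determined by rank distance — the fixed-variant LIKE matrix is
  the built-in control.
* **Rowwise Pearson predictability** against absolute rank distance or
  the mean LIKE matrix, pooled across rows by Fisher-z
  (`tanh(mean(atanh r))`, inputs clipped to ±(1 − 1e−12) with a
  warning), absolute value reported.
* **Uphill fraction** — the share of a directed behaviour emitted by the
  lower-ranking dyad member; near 1 for submission in a stable
  hierarchy.

## Numerical choices

* *Rank-distance thresholding*: |Δdom| is rounded to 9 decimals before
  comparison with 0.35 — the 0.05 grid is not binary-exact, and the
  category counts (99/91 unordered, 198/182 directed for n = 20) must
  reproduce exactly.
* *Lazy state updates*: emotional state and LIKE are advanced only when
  an agent is touched. Relaxation is exponential, so lazy evaluation is
  exact for arousal/anxiety (semigroup property). The LIKE recursion is
  only approximately divisible under a constant `PARTNER_SAT`; the
  engine applies it at every advance, and the one-step/two-step
  discrepancy is bounded by the analytic worst case 1/12 (reached at
  |LIKE − PSAT| = 1 with two LHW-long steps) — asserted in the tests.
* *Queue discipline*: ties broken by (interrupts, movement substeps,
  scheduled), then agent id, then insertion order; with seeded RNG this
  makes whole runs bit-reproducible, which the null-model equivalence
  test exploits (at LPS = 0 the dynamic and fixed variants consume the
  random stream identically, so their event logs must be
  *bit-identical*).
* *Zero-length grooming bouts* (interrupted at the start instant) are
  dropped from the log.
* *Degenerate statistics inputs*: all-zero evenness rows → `NA` and
  excluded; correlations at ±1 → clipped with a warning before
  Fisher-z; SD groups of size 1 → excluded.

## Free parameters and defaults

The model text fixes signs and a handful of rates (satisfaction
kinetics 0.05/0.1/0.02 per min; baseline arousal 0.09; LHW = 720 min;
the fixed-LIKE constants 0.243/0.36; the perception distances and the
calendar). Everything else is a documented free parameter:

* the *salience table* magnitudes (`default_salience_table()`; the sign
  structure is validated at load),
* baseline behaviour tendencies and modulation gains
  (`behavior_params()`): chosen once to give a plausible macaque-like
  time budget (~10% grooming, rest-dominated idling, attacks rare) and
  steep FEAR-direction effects (`exp(±4 FEAR)`, comparable to the
  win-chance steepness 8, so that submission flows essentially
  up-hierarchy),
* relaxation rate 0.05/min for arousal/anxiety limits; elevated arousal
  limit 0.3 near dominants,
* movement: 10 m/min in 3-s substeps, flee/avoid stop at 5 m,
  random-walk bouts of 1 min with ±30° turns, grooming/rest bouts
  uniform 2–10 min, winner re-scheduling 0.25 min, bystander reaction
  0.1 min.

None of these were tuned against the acceptance outcomes; they were set
to the stated world before the directional tests were run and left
alone.

## What the synthetic world does and does not establish

Every input is generated internally: the package *is* the data
generator, and all tests run on seeded simulations. A green directional
test (e.g. "grooming Tau-Kr is higher at LPS = 0.99 than at 0 in every
replicate pair") establishes that the implemented mechanism produces
the claimed ordering robustly at desk scale — 1-week burn-in, 8-week
window, 5 replicates — not that effect *magnitudes* match any empirical
group, nor that the desk scale equals the full-scale (2-year) values:
shorter windows inflate sampling noise in rates and shorten the LIKE
equilibration that a 4-week stabilization affords. The full-scale
defaults are a `run_config()` call away, and `run_sweep()` reproduces
the complete 2 × 5 × 10 experiment grid unchanged.

## Known limitations

* The exact per-behaviour probability formulas of the original
  implementation are not public; the selection layer here satisfies a
  documented contract (directions of all modulations plus the LPS
  ratio law) with free magnitudes, so quantitative rate levels are not
  comparable to the original, only orderings and mechanisms.
* FEAR attitudes are fixed; no coalitions, kinship, or post-conflict
  reconciliation beyond what emerges from the emotional dynamics.
* One groomer per groomee at a time (mutual grooming = two concurrent
  directed bouts); multi-partner grooming chains are not modelled.
* The environment is purely social: no ecology, no occlusion, flat
  torus geometry.
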
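---
title: "Respondent-driven sampling estimation and diagnostics with rdsforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respondent-driven sampling estimation and diagnostics with rdsforest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdsforest)
```

## The problem

Hidden populations — people who inject drugs, GBMSM, sex workers — have no
sampling frame, so surveys recruit them through their own social networks:
a few purposively chosen **seeds** receive coupons (here up to 6) and
recruit peers, who recruit further, wave by wave. The resulting
**recruitment forest** (one tree per seed) is not a probability sample:
well-connected people are over-recruited, and the purposive choice of seeds
can bias naive proportions. RDS estimation corrects for both using only two
observables — who recruited whom, and each participant's self-reported
network size (degree, $d_i$).

`rdsforest` builds and validates the forest, computes three standard
weighted prevalence estimators with bootstrap confidence intervals, runs
graphical/analytic recruitment diagnostics, performs the seed-sensitivity
experiments, and ships a network + recruitment simulator with known ground
truth.

## The recruitment forest

A recruitment table has one row per participant: `id`, `recruiter_id`
(blank or `"seed"` for seeds), `degree` ($\ge 1$), optional
`enroll_order`, and one column per categorical outcome (blank cells are
non-response). Construction resolves recruiter links, rejects duplicate
ids, unknown recruiters, cycles and invalid degrees (optionally imputing a
group-median degree with a warning), and assigns each participant a
**wave** — the graph distance from their seed, with seeds at wave 0. The
assignment is a fixed-point relaxation, so it does not depend on row
order.

A chain's **depth** is its maximum wave. `prune_by_min_depth(forest, c)`
keeps exactly the chains of depth $\ge c+1$: `c = 0` removes unproductive
seeds, `c = 1` chains of at most one wave, `c = 2` of at most two — the
stepwise seed-exclusion cuts of the sensitivity analysis. `cut_report()`
tabulates each cut: remaining n, seeds (= chains), removals against the
overall sample, and chain-length summaries. The wave statistics it prints
are **per-chain depths** (one value per chain), which is how published
wave-length tables in this literature reconcile: removing depth-0 chains
leaves the total depth unchanged while the chain count drops, so the mean
chain length rises. Display percentages are rounded half-away-from-zero to
one decimal (banker's rounding would turn 50/719 into 6.9 rather than the
conventional 7.0); full precision is kept internally.

## Estimators

All weighted estimators exclude records with a missing outcome
(non-response); the crude estimator offers both denominators
(`all_records`, the default, and `non_missing`) because published crude
tables are not always consistent about which they used.

**Crude**: $\hat P_g = 100\,n_g/n$.

**RDS-II (Volz–Heckathorn)**: under a with-replacement random walk on the
network, a participant's stationary inclusion probability is proportional
to their degree, so

$$\hat P_A = \frac{\sum_{i \in A} 1/d_i}{\sum_{i \in S} 1/d_i}.$$

**RDS-I (Salganik–Heckathorn)** models recruitment as a Markov chain on
outcome groups. From all recruiter–recruit pairs with both outcomes
observed we form the count matrix $R$, row-normalize to transition
probabilities $T$, and solve $eT = e$ for the equilibrium group
distribution (power iteration, tolerance $10^{-12}$, cap $10^5$, with a
direct eigen-solution fallback for slowly mixing or periodic chains — the
iteration cap, not an error, decides when the fallback engages). With
group harmonic-mean degrees $\hat D_g = n_g / \sum_{i \in g} 1/d_i$,

$$\hat P_g = \frac{e_g/\hat D_g}{\sum_h e_h/\hat D_h},$$

which for two groups reduces to the classical closed form
$\hat P_A = C_{BA}\hat D_B/(C_{AB}\hat D_A + C_{BA}\hat D_B)$ (kept as an
internal cross-check). By default the counts are **reciprocity-smoothed**
— each directed flow averaged with its reverse under the equilibrium,
$S_{gh} = (e_g T_{gh} + e_h T_{hg})/2$ — before re-normalizing, enforcing
the balance the estimator assumes; `smoothed = FALSE` gives the raw
version. Rows for groups never observed recruiting are filled uniformly
and flagged; a group with sampled members but *no* recruitment pairs at
all makes the estimate undefined and is refused with guidance rather than
silently extrapolated.

**RDS-SS (successive sampling)** addresses the finite-population bias of
RDS-II when the sample fraction $n/N$ is material. Inclusion
probabilities come from a deterministic expected-depletion approximation
of probability-proportional-to-degree sampling without replacement:
starting from estimated degree-class counts $\hat N_d$, each of the $n$
draws removes one unit of expected mass, degree-proportionally; $\pi_d$
is the removed fraction of class $d$. In the end-game of a near-census a
class would be driven negative; it is emptied instead and the excess
removal redistributed, which keeps $\sum_d \hat N_d \pi_d = n$ exactly
and makes the census case ($N = n$) collapse to $\pi_d \equiv 1$. The
estimator iterates a fixed point: inverse-degree weights →
$\hat N_d = N \cdot$ (weighted degree shares) → $\pi$ → weights
$1/\pi_{d_i}$, until $\max_d |\Delta\pi_d| < 10^{-6}$ (cap 50 iterations;
non-convergence returns the last iterate, flagged). Two identities pin
the implementation down and are enforced in tests: at $N = 10^9$ the
estimate equals RDS-II to $10^{-6}$; at $N = n$ it equals the crude
proportion among responders. The deterministic scheme was chosen over
Monte-Carlo for bit-reproducibility; a $10^5$-draw Monte-Carlo oracle of
the same without-replacement process is kept in the test suite and agrees
within 0.01 on the toy where both are cheap.

Degree outliers are not truncated by default — pulling in large reported
network sizes changes the weights materially and should be an explicit,
visible analysis decision, not a silent default.

## Bootstrap confidence intervals

Variance comes from a grouped chain bootstrap that re-enacts recruitment
as a Markov chain on outcome groups. For each group $g$, the pool is the
set of participants whose recruiter belongs to $g$; a replicate starts at
a uniformly drawn observed seed and repeatedly draws, with replacement, a
successor from the current participant's group pool until it reaches the
sample size, and the estimator is recomputed on each replicate (for
RDS-I, consecutive draws play the role of recruiter–recruit pairs).
Missing outcomes form their own walk state, so chains can pass through
non-responders while estimation still excludes them. A reachable group
with an empty pool would strand the walk and is reported as an error
naming the group. The default interval is `normal` (point $\pm 1.96$
bootstrap SD; published RDS CIs of this kind are symmetric about the
point estimate), with `percentile` as the alternative; $B = 1000$ by
default, and the whole replicate stream is a pure function of the seed.
Replicates on which RDS-I/RDS-SS fail (possible in tiny or degenerate
samples) are dropped with a warning and counted, rather than redrawn,
to keep the stream seed-deterministic.

## Diagnostics

**Convergence series**: the estimator recomputed on the first $k$
enrolled participants, $k = k_{\min},\dots,n$, in enrollment order
(explicit `enroll_order` when present, else breadth-first by wave with
stable id order — the paper trail of real enrollment timestamps is often
missing, so the input column is optional rather than guessed). A flat
right tail suggests the estimate has escaped the seeds. $k_{\min} = 10$
by default; earlier prefixes are noise. The default estimator inside the
series is RDS-II — cheap and defined on almost every prefix; prefixes
where the estimator is undefined are skipped and recorded.

**Bottleneck series**: one convergence series per seed tree, over that
chain's members only (chains below $k_{\min}$ members are skipped with a
notice). All chains converging on a common value is the "one bottleneck"
pattern of low homophily; chains stabilizing at distinct values expose
sub-population segregation. The package asserts this contract on
synthetic data: under proportionate mixing every sizeable seed tree's
final value lies within 3 of its own bootstrap SEs of the overall
estimate, while under strong homophily with group-stratified seeds at
least two trees separate by more than the overall estimate's entire
$\pm 3$ SE band.

**Homophily index**, per group, from the transition model:
$H_g = (T_{gg} - e_g)/(1 - e_g)$ when $T_{gg} \ge e_g$, else
$(T_{gg} - e_g)/e_g$ — 0 for proportionate recruitment, $+1$ for complete
segregation, $-1$ for complete avoidance; undefined (NA, flagged) when
$e_g$ is degenerate.

**Waves to equilibrium**: the smallest $w$ with
$\max_g |(sT^w)_g - e_g| < \varepsilon$. The default
$\varepsilon = 0.01$; the start is either every degenerate
(single-group) distribution with the worst case reported, or the observed
seed distribution. The max-abs metric matches "within $\varepsilon$ on
the measured parameter". Field usage sometimes conflates this tolerance
with homophily ("converged at a level of 0.01"); here $\varepsilon$ is
strictly a convergence tolerance on the group distribution. Non-ergodic
chains report `Inf` with a diagnosis instead of looping.

## Sensitivity experiments

`run_cut_analysis()` re-estimates every outcome with every requested
estimator on the overall sample and each cut, and checks whether each
crude proportion falls inside each weighted estimator's CI — the
robustness-to-seed-selection criterion. Cells are seeded from one master
seed via a documented sub-stream derivation, so any cell is reproducible
in isolation. A cut that empties the forest is reported and skipped.

`compare_estimators_simulation()` draws, per replicate, a random subset of
whole seed trees (never partial chains), recomputes all estimators, and
summarizes replicate distributions and pairwise differences with a paired
two-sided t-test at $\alpha = 0.05$. The subsample size is not standard
anywhere; `tree_fraction = 0.5` without replacement is the package
default, exposed and logged. The p-value is descriptive — replicates
share chains and are not independent — so percentile intervals of the
differences are reported alongside; the sign convention is
`first − second` throughout. `tree_fraction = 1` reproduces the
full-sample estimates in every replicate and flags all comparisons
degenerate.

## The synthetic-data generator

`sim_population()` emulates the population a large urban GBMSM survey
assumes: $N = 33{,}960$ by default; three binary outcomes at prevalences
0.27 (serostatus), 0.37 (high-risk sex) and 0.08 (injection drug use);
negative-binomial degrees ($\mu - 1 = 19$, size 1.5, shifted to minimum
1 — the heavy right tail typical of self-reported network sizes, which
are not published for any real study); and a mixing matrix with diagonal
0.55 steering ties of the first outcome. The graph is built by
degree-respecting stub pairing: each stub samples its partner group from
its own group's mixing row, stubs are matched between and within groups,
leftover stubs (flow imbalance between unequal groups) pair uniformly,
and self-loops/duplicate edges are dropped. The dilution from leftover
pairing means realized mixing sits slightly below the target diagonal;
`truth_report()` always recomputes the realized prevalences, mixing and
homophily from the emitted graph, and the realized — not target — values
are what recovery tests compare against. Only the structuring outcome
carries homophily; the others are independent of the network.

`simulate_rds()` runs a FIFO coupon queue: each enrollee gets `coupons`
(default 6) coupons, each returned with probability `return_prob`
(default 0.15, i.e. ~0.9 expected recruits per enrollee — a subcritical
chain that reproduces the seed-heavy pattern of real studies, where ~30
initial seeds had to be topped up to ~119 to reach $n \approx 719$);
returned coupons enroll a uniformly chosen not-yet-enrolled neighbour.
When the queue dies the simulator injects fresh uniform seeds and logs
the count. Waves equal BFS depth from the recruiting seed by
construction. "With-replacement" mode draws coupon targets among all
neighbours and wastes the coupon if the target is already enrolled — no
individual is ever enrolled twice in either mode. The emitted table uses
the true (realized) degree as the reported network size, with optional
multiplicative log-normal reporting noise.

What the generator does **not** emulate: temporal dynamics, incentives,
differential coupon return by group, online-advert seed channels, and
reporting biases in degree beyond symmetric noise. Passing recovery tests
on this generator therefore shows the estimators are correct *under the
random-walk-like recruitment the theory assumes*, not that any field
survey meets those assumptions.

## Numerical and scale choices

- Power iteration for equilibria: tolerance $10^{-12}$, cap $10^5$;
  eigen fallback. Zero-count transition rows are uniform-filled and
  flagged. Degenerate equilibria flag homophily/waves as undefined.
- RDS-SS: $\pi$ tolerance $10^{-6}$, 50 iterations, deterministic
  depletion with end-game redistribution (see above).
- Percent displays: half-away-from-zero, 1 decimal; internal full
  precision; category percentages sum to 100 (within $10^{-9}$) over
  non-missing categories for every weighted estimator.
- One master seed drives population, recruitment, bootstrap and
  subsampling streams through a documented integer sub-stream derivation,
  all within 32-bit range.
- Test problem sizes were chosen so the full suite exercises the study's
  scale where it matters and stays light elsewhere: the estimator-
  agreement check runs 20 surveys of $n = 719$ at $N = 33{,}960$;
  recovery and CI coverage use 200 surveys of $n = 500$ at $N = 10{,}000$
  with $B = 300$; bottleneck patterns use $n = 600$ at $N = 5{,}000$ with
  3–6 seeds so individual seed trees are large enough for per-tree
  estimates to be meaningful.

## Known limitations

- RDS-I is implemented in its equilibrium/harmonic-degree form with
  reciprocity smoothing; other historical refinements (dual-component
  estimators, RDS-I/DS) are out of scope.
- The grouped chain bootstrap is the only variance estimator; no
  analytic RDS-II variance and no regression/multivariable modelling.
- The successive-sampling inclusion probabilities are an expected-value
  approximation, excellent at realistic sample fractions (checked against
  Monte-Carlo) but not an exact finite-sample computation.
- Published tables from specific studies cannot be reproduced exactly
  without the underlying (undeposited) data; the package reproduces the
  arithmetic that is recomputable from printed counts and validates the
  estimators on synthetic data with known truth instead.
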
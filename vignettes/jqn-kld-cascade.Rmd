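---
title: "Queueing models and divergence-rate conservation in signalling cascades"
author: "jqnkld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Queueing models and divergence-rate conservation in signalling cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jqnkld)
```

## The model

`jqnkld` treats a phosphorylation cascade as an *open Jackson queueing
network*. The signal mediator — inorganic phosphate handed from kinase
to kinase — is the customer; each signalling molecule is a single-server
node with first-come-first-served discipline. Mediator arrives at node
$i$ from outside the network as a Poisson stream with rate
$\lambda_{oi}$, is "served" (phosphotransfer) at exponential rate
$\mu_i$, and then moves to node $j$ with routing probability
$r_{i \to j}$ or leaves the network. Openness — every customer
eventually leaves, i.e. the routing matrix has spectral radius below
one — is what makes the stationary law tractable.

The effective arrival rates solve the traffic equations
$\lambda_i = \lambda_{oi} + \sum_j \lambda_j\, r_{j\to i}$
(`solve_traffic()`), utilizations are $\rho_i = \lambda_i/\mu_i$, and
for a stable network (all $\rho_i < 1$) the stationary occupancy
distribution factorizes into geometric marginals,
$p(a) = \prod_i \rho_i^{a_i}(1-\rho_i)$
(`stationary_probability()`), with mean queue lengths
$L_i = \rho_i/(1-\rho_i)$ and Little's law $L = \lambda W$ tying
occupancy, throughput, and sojourn together. Signalling networks live
in the light-traffic regime $\rho_i \ll 1$, where $L_i \approx \rho_i$
and the mean occupancy of node $i$ can be identified with $\rho_i$
itself; that identification is what lets measured phospho-levels stand
in for utilizations below.

We deliberately model **single-server** nodes: the $\rho/(1-\rho)$
queue-length form is the single-server one, and it is the form the rest
of the theory consumes. Multi-server variants are out of scope, as are
feedback loops: the cascade is one-directional, so routing is strictly
forward and the network stays open.

### Simulator

`simulate_jqn()` is a discrete-event simulation of exactly this model,
used to validate the product form empirically rather than assume it.
Its core is compiled (Rcpp); each (node, purpose) pair — arrivals,
service draws, routing draws — owns a separate `mt19937_64` stream
derived from the master seed by hashing, so trajectories are
reproducible bit for bit and adding a node does not perturb the
streams of existing nodes. Simultaneous events are ordered by (time,
node index, kind) for determinism, although exponential clocks make
exact ties a measure-zero event. The first 10% of the horizon is
discarded as burn-in by default. At $10^6$ events the per-node
occupancy histograms sit within total-variation distance well below
0.02 of the geometric marginals and Little's-law residuals are below
2% (see `analysis/01_network_theory.R` and the acceptance tests, which
run exactly these horizons).

## Information gain and its conserved rate

Write $\rho_i$ for the pre-stimulus utilizations and $\rho_i(t)$ for
the utilizations during signalling. The information gain of the
signalling state is the Kullback–Leibler form

$$D(\rho(t)\,\|\,\rho) = \sum_i \rho_i(t) \log\frac{\rho_i(t)}{\rho_i},$$

in nats (`kld()`; natural logarithms throughout, because the
thermodynamic mapping below works in units of $k_BT$). Two
conventions: a node with $\rho_i(t)=0$ contributes $0$; the vectors
are *not* required to be normalized, so $D$ is guaranteed non-negative
only when both states carry the same total mass.

This quantity is also the large-repetition exponent of the state
probability: if the transduction event repeats $a$ times in total and
$a_i(t)$ times at node $i$, the exact multinomial log-probability
equals $-aD$ up to a Stirling error (`log_state_probability()`
returns both). The gap grows like $\tfrac{n-1}{2}\log a$ while both
terms grow like $a$: per customer it vanishes asymptotically, but at
finite size it is not negligible — at $a = 1000$ it is about $0.006$
per customer for 2 nodes and about $0.010$–$0.014$ for 4–5 nodes, a
point worth keeping in mind when treating $-aD$ as "the" log
probability of moderate-sized states. Note also a normalization
subtlety inherited from the derivation: inside the Stirling identity
the $\rho_i(t)$ must be the occupancy *fractions* $a_i(t)/a$, whereas
elsewhere the signal-state utilizations sum to the total customer
number $a$, not to 1. The package keeps the fraction reading local to
`log_state_probability()` rather than silently reconciling the two.

Each externally fed node carries a dwell time
$\tau_{oi} = 1/\lambda_{oi}$, and a signalling state occupies the
budget $\sum_i \rho_i(t)\,\tau_{oi}$. Extremizing $D$ under a fixed
budget $\tau$ (Lagrangian $F = D + \gamma\sum_i \rho_i(t)\tau_{oi}$)
gives the stationarity condition

$$\gamma = -\lambda_{oi}\,\log\frac{\rho_i(t)}{\rho_i}
  \quad\text{for every } i,$$

i.e. the per-node quantity $\lambda_{oi}\log(\rho_i(t)/\rho_i)$ is
*node-independent*: the divergence rate is conserved along the
cascade. Equivalently $\log(\rho_i(t)/\rho_i) = -\gamma\tau_{oi}$
(`optimal_ratio()`), and summing against $\rho_i(t)$ gives the chain
$D = -\gamma\sum_i\rho_i(t)\tau_{oi} = -\gamma\tau$, so that
$-\gamma = D/\tau$ exactly.

`maximize_kld()` computes this state by one-dimensional root finding:
given $\gamma$, the stationary state is
$\rho_i(t) = \rho_i e^{-\gamma\tau_{oi}}$, and the achieved budget is
strictly decreasing in $\gamma$, so `uniroot()` plus a few Newton
polish steps pins $\gamma$ to machine precision; the conservation
identity then holds by construction and the budget to ~1e-12.

Two honest caveats, both surfaced rather than hidden. First,
differentiating $x\log x$ literally gives
$\log(\rho_i(t)/\rho_i) = -1 - \gamma\tau_{oi}$; the conventional form
above absorbs the constant into $\gamma$. The two describe the same
family only when all $\tau_{oi}$ are equal, so the literal state is
available via `maximize_kld(..., constant = "literal")` and is
cross-checked in the tests against a generic penalty minimizer of $D$
on the budget set. Second, $D$ is convex in $\rho(t)$, so its interior
critical point on the (linear) budget set is a *minimum* of $D$ there,
not a maximum — the supremum of $D$ on the budget simplex is attained
at its boundary. What the conservation argument needs is precisely the
interior stationary point of the Lagrangian, and that is what the
package computes and calls, following field usage, the
budget-constrained extremum.

The thermodynamic reading: with chemical potentials
$\mu_i = \mu_{i0} + k_BT\log\rho_i$ (`chemical_potential()`), the
per-node entropy change is $\Delta s_i = \log(\rho_i(t)/\rho_i)$ in
units of $k_B$ — the reference potential cancels — and the total
$\Delta S = \sum_i \rho_i(t)\Delta s_i$ (`total_entropy_change()`) is
*identically* the divergence $D$, and $-\gamma\tau$ at the extremum.
$-\gamma$ therefore has the dimension of an entropy-production rate.

## Estimating the rate from time courses

Antibody-array experiments report, per molecule and replicate, the
fold-phosphorylation ratio $a_i(t)/a_i$ relative to the untreated
baseline on a sampling grid (here 0, 15, 30, 45, 60, 120, 180 min).
`estimate_rate()` implements the plot-integral estimator:

1. **Period.** $\tau_i$ is the first time after the curve's global
   maximum at which the linearly interpolated ratio crosses 1.0 from
   above (`detect_period()`). Sub-baseline dips *before* the maximum
   are ignored — early noise should not end the period. A curve that
   never returns (or never rises above baseline, like the negative
   control) takes $\tau_i$ = the last sample time with a
   `period_truncated` flag.
2. **Integral.** The trapezoid rule on the sample grid over
   $[0, \tau_i]$, divided by $\tau_i$ (`integrate_ratio()`). Because
   the baseline integrates to $\tau_i$, this mean fold *is* the ratio
   $\int_0^{\tau_i} a_i(t)dt / \int_0^{\tau_i} a_i\,dt$; stretches
   below 1.0 subtract. No smoothing or curve fitting: the estimator
   integrates the plotted polyline, nothing more.
3. **Rate.** $-\gamma = \log(\text{mean fold})/\tau_i$ with $\tau_i$
   in hours, giving nats per hour. A mean fold below 1 yields a
   negative rate, reported with a `below_baseline` flag rather than
   clamped.

A flat curve at ratio 1.0 gives mean fold exactly 1 and rate exactly
0 — the negative-control behaviour.

Two identification choices are assumptions, stated as such. The
theory's prefactor is $1/\tau_{oi}$, a queueing dwell time that no
time-course experiment measures; the estimator identifies it with the
detected phosphorylation period $\tau_i$, the only self-consistent
reading of the integration window. And the absolute scale of measured
rates depends on units the data do not carry, so cross-molecule
*comparisons* (differences, effect sizes) are the meaningful output,
not absolute rate values.

## The synthetic generator

Because no machine-readable dataset accompanies the motivating
experiment, `generate_timecourses()` produces antibody-array-like
curves with known ground truth. Per molecule, a raised-cosine pulse
$1 + A(1-\cos 2\pi t'/\tau)/2$ (zero value and slope at both ends)
rides on the baseline; the amplitude is calibrated in closed form so
that the noiseless estimator returns exactly the requested rate $r$:
on $[0,\tau]$ this is $A = 2(e^{r\tau/60}-1)$ (`pulse_profile()`), and
with an activation onset the calibration extends over the full
$[0, \text{onset}+\tau]$ window, since the estimator integrates from
stimulation. Noise is multiplicative log-normal, $e^{\sigma Z}$ per
sample — intensity data are positive with roughly scale-proportional
error — and the $t=0$ sample is forced back to 1, mirroring
normalization to the untreated sample. The raised-cosine shape is a
modelling convention: any unimodal pulse satisfying the integral
calibration would do.

Defaults encode the emulated study: molecules ASK1, MKK4, MKK3, p38,
ATF2 plus a flat negative control; 4 replicates; common rate 3.0
nats/h; $\sigma = 0.1$; onsets (0, 15, 15, 30, 30) min with pulse
lengths (60, 45, 45, 30, 30) min. The onset/length defaults do double
duty: activation is sequential, as in a cascade, and every pulse
closes by 60 min inside the uniformly sampled first hour. On a uniform
grid spanning a full raised-cosine period the trapezoid rule is exact,
so the noiseless estimator recovers 3.0 to rounding error — a sharp
end-to-end correctness check that survives the sequential onsets.

What the generator does **not** emulate, and what that means for the
tests: real curves come from scanner intensities with background
correction and spatially correlated error, and they typically
*undershoot* the baseline after the pulse. The synthetic pulse instead
returns to the baseline tangentially, so with noise the sampled curve
hovers around 1.0 after the pulse and the detected crossing can jump
into the sparsely sampled 60–180 min tail (with probability roughly
one half, any positive noise at the first post-pulse sample defers the
crossing to the next grid point). The jump dilutes the mean fold and
lengthens $\tau_i$, biasing individual rates downward while inflating
the replicate SD by the same mechanism — the synthetic replicate SDs
(~0.5–1 around means of ~2–3 nats/h at $\sigma=0.1$) are therefore of
the same character as the reference experiment's reported SDs. Passing
tests show that the estimator is exact on noiseless, well-sampled
pulses, that its noise response is unbiased when the period is pinned
(pulses outlasting the grid), and that replicate means stay within the
experiment's own 3-standard-error band of truth across 100 seeds; they
do *not* show that single noisy estimates are unbiased on a sparse
tail, because they are not.

## Replicate statistics and the conservation call

`summarize_rates()` reports per-molecule mean and sample SD ($n-1$;
undefined and flagged at $n=1$). Pairs are compared by the mean
difference $\Delta\mu$ and Cohen's d with the equal-$n$ pooled SD,
$d = |\mu_a-\mu_b| / \sqrt{(s_a^2+s_b^2)/2}$ — the formula is
validated by exact reproduction of the reference table's four derived
rows (`mapk_reference_summary()`, $\Delta\mu$ = 0.16/0.36/0.12/0.04,
$d$ = 0.22/0.50/0.22/0.06) — and pairs are called similar at
$d \le 0.5$. Values are displayed at 2 decimals and the similarity
call is made on the rounded $d$, so reported and decided values never
disagree; full precision is kept alongside. When both SDs are zero
(noiseless data), identical means give $d = 0$ and distinct means
$d = \infty$, with equality judged at the reporting precision so that
float-level differences between exactly-recovered rates do not
masquerade as infinite effects. Which pairs constitute "the cascade"
is caller-supplied; the published comparisons include MKK3–p38, which
is not an adjacent pair of the listed order. `candidate_cascade_screen()`
ranks *all* pairs by $d$ as a hypothesis-generating screen — similar
rates are consistent with, not evidence of, a shared cascade, and no
multiplicity control is applied. Effect sizes only, no p-values: with
$n = 4$ replicates a hypothesis test would be noise-driven, and the
conservation claim is about magnitude, not significance.

## Numerical conventions, sizes, and limitations

* Stability threshold $\rho \ge 1 - 10^{-12}$ counts as unstable;
  unstable networks refuse to simulate or solve.
* $0\log 0 = 0$ throughout; $\rho_i = 0$ with $\rho_i(t) > 0$ reports
  an infinite divergence rather than an error.
* Times in minutes at the data boundary, rates in nats/h internally;
  every estimate row carries its units in the column name
  (`kld_rate_per_h`).
* The duration budget uses the signal-state occupancies (they are the
  quantities being varied); budgets at or below zero are infeasible.
* Problem sizes in the shipped analyses: $10^6$-event simulation
  horizons, 20-instance conservation checks against the brute-force
  solver, 100-seed replication of the noisy-recovery study — sizes at
  which the Monte-Carlo bands quoted above are comfortably resolved.
* Known limitations: single-server nodes only; no feedback routing; no
  transient queue distributions; the Stirling identity is an $O(\log
  a/a)$-per-customer approximation, materially imperfect for $\ge 4$
  nodes at $a \sim 10^3$; absolute rate units from time-course data are
  unidentified, so only comparative statements travel across
  experiments.

```{r example, eval = FALSE}
# end-to-end: synthetic experiment -> rates -> conservation report
report <- run_pipeline(generator_config(seed = 42), out_dir = "run")
print(report)

# theory side: product form + conserved rate on one network
spec <- cascade_spec(c("k1", "k2", "k3"), c(0.2, 0.15, 0.1),
                     c(1.5, 1.2, 1),
                     matrix(c(0, .6, 0, 0, 0, .6, 0, 0, 0), 3, 3,
                            byrow = TRUE))
demo <- run_theory_demo(spec, horizon = 1e5, seed = 2)
demo$simulation
demo$kld_optimum$kld_rate
```
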
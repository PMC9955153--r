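# jqnkld

Queueing-network modelling and Kullback–Leibler divergence-rate
analysis of cell-signalling cascades.

## The problem

Signal transduction through a kinase cascade (e.g. the stress-MAPK
chain ASK1 → MKK4/MKK3 → p38 → ATF2) is a stochastic, one-directional
relay of a phosphate mediator between low-abundance proteins. This
package models the cascade as an **open Jackson queueing network
(JQN)**: the mediator is the customer, each signalling molecule a
single-server FCFS node with Poisson external arrivals at rate
λ<sub>oi</sub>, exponential service (phosphotransfer) at rate
μ<sub>i</sub>, and forward probabilistic routing. It is written for
systems-biology analysts who want to (a) work with the product-form
steady state of such networks, (b) quantify stimulation as an
information gain, and (c) test whether that gain accrues at the *same
rate* at every step of a measured cascade.

## The core quantities

For a stable network (utilizations ρ<sub>i</sub> = λ<sub>i</sub>/μ<sub>i</sub> < 1,
with λ<sub>i</sub> solving the traffic equations
λ<sub>i</sub> = λ<sub>oi</sub> + Σ<sub>j</sub> λ<sub>j</sub> r<sub>j→i</sub>),
the stationary occupancy law factorizes:
p(**a**) = Π<sub>i</sub> ρ<sub>i</sub><sup>a_i</sup>(1 − ρ<sub>i</sub>).
The information gain of a signalling state {ρ<sub>i</sub>(t)} over the
resting state {ρ<sub>i</sub>} is the Kullback–Leibler form

> D(ρ(t)‖ρ) = Σ<sub>i</sub> ρ<sub>i</sub>(t) · log( ρ<sub>i</sub>(t) / ρ<sub>i</sub> )   [nats]

Extremizing D under the signal-duration budget
Σ ρ<sub>i</sub>(t)·τ<sub>oi</sub> = τ (τ<sub>oi</sub> = 1/λ<sub>oi</sub>)
makes λ<sub>oi</sub>·log(ρ<sub>i</sub>(t)/ρ<sub>i</sub>) identical across
nodes — its negated value γ satisfies **−γ = D/τ**: the divergence rate
per signal duration is conserved along the cascade. From
fold-phosphorylation time courses the rate is estimated per molecule as

> −γ = log( (1/τ<sub>i</sub>) ∫<sub>0</sub><sup>τ_i</sup> ratio(t) dt ) / τ<sub>i</sub>   [nats/h]

where τ<sub>i</sub> is the phosphorylation period (first return of the
curve to baseline 1.0 after its maximum). Conservation across a
measured cascade is then judged on replicate statistics: per-molecule
mean/SD, pairwise Δμ, and Cohen's d with the equal-n pooled SD, pairs
being "similar" at d ≤ 0.5.

## Worked example

Feed the published replicate summary of the EGF-stimulated A431
antibody-array experiment into the conservation test:

```r
library(jqnkld)
ref <- mapk_reference_summary()
conservation_report(ref, mapk_reference_pairs())
```

```
KLD-rate conservation report (similarity: Cohen's d <= 0.5 )
  molecule_a molecule_b delta_mu_2dp cohens_d_2dp similar
1       ASK1       MKK4         0.16         0.22    TRUE
2       MKK4        p38         0.36         0.50    TRUE
3       MKK3        p38         0.12         0.22    TRUE
4        p38       ATF2         0.04         0.06    TRUE
conserved across all pairs: TRUE
```

Every pairwise effect size sits at or below 0.5 (the largest, 0.50,
is MKK4–p38), so the measured divergence rates are statistically
indistinguishable along the cascade: the conservation prediction holds
in the data.

The same machinery end-to-end on synthetic data with known truth — a
noiseless run recovers the common 3.0 nats/h rate exactly and reports
conservation:

```r
rep <- run_pipeline(generator_config(noise_sigma = 0, seed = 42),
                    out_dir = "run")
attr(rep, "summary")
```

```
          molecule n mean sd sd_defined
1             ASK1 4    3  0       TRUE
2             ATF2 4    3  0       TRUE
3             MKK3 4    3  0       TRUE
4             MKK4 4    3  0       TRUE
5 Negative control 4    0  0       TRUE
6              p38 4    3  0       TRUE
```

The flat negative control estimates exactly 0.00 nats/h.

## Analysis workflow

The study is organized as numbered drivers over the package API, each
writing its tables under `results/`:

| script | what it does |
|---|---|
| `analysis/01_network_theory.R` | steady state of the cascade JQN; simulation vs product form and Little's law |
| `analysis/02_kld_conservation.R` | budget-constrained KLD extremum and the conserved rate; Stirling and entropy identities |
| `analysis/03_generate_timecourses.R` | synthetic antibody-array time courses + separate ground truth |
| `analysis/04_estimate_rates.R` | per-replicate divergence rates from the CSV |
| `analysis/05_conservation_stats.R` | replicate summaries, pairwise Cohen's d, conservation call, all-pairs screen |

Run them in order with `Rscript analysis/01_network_theory.R`, etc.

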
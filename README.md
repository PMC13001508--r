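# g4coop

Cooperative HNRNPH binding to RNA G-quadruplexes and switch-like
splicing regulation.

HNRNPH recognizes runs of guanines through its three quasi-RRM (qRRM)
domains, and many of its binding sites fold into RNA G-quadruplexes
(rG4s). Unfolding an rG4 exposes four G-runs at once, which turns
independent binding events into a cooperative switch — and that
cooperativity propagates through the spliceosome into ultrasensitive,
dose-dependent exon inclusion. g4coop is an R package for researchers
who want to quantify this chain of events: it implements the
equilibrium statistical mechanics of multi-qRRM binding, the
dose-response analysis of splicing titrations, a kinetic model of the
splicing decision cascade, and the two sequencing-based callers (iCLIP
binding sites, RTstop rG4 detection) that locate and validate the
underlying binding sites — plus seeded synthetic-data generators for
every input modality, so the whole pipeline runs and is tested without
any external data.

## The models at the core

**Equilibrium binding.** With the unfolded, unbound RNA as reference, a
binding mode of *m* proteins contacting *k₁…k_m* G-runs has weight

    Ω (c/c₀)^m exp[(Σᵢ kᵢ·g_bind − Σᵢ (kᵢ−1)·g_backfold) / RT]

with Ω the number of placements of the unlabeled proteins on the linear
run array; the folded quadruplex has weight `exp(g_rG4/RT)`. From the
partition function the package computes the bound fraction, the
transition concentration *K* (half-saturation), and the EC10/EC90 Hill
coefficient `n_H = log(81) / log(EC90/EC10)`. Two limits anchor the
analysis: forbidding backfolding (`max_qrrm = 1`) drives `n_H → 4`,
while a zero backfolding penalty gives an `n_H ≈ 2` plateau — the
signature of two proteins occupying all four runs through two
backfolding events each.

**Dose-response fitting.** Splicing changes (ΔPSI) across a protein
titration are fitted with a constrained four-parameter logistic
(asymptotes tied to the control inclusion levels), scored with a
pseudo-R², and classified into cooperative (`n_H ≥ 2`) versus
non-cooperative, enhanced versus repressed — fits with pseudo-R² < 0.75
are excluded.

**Splicing cascade.** Three saturating stages — cooperative binding,
multi-step spliceosome regulation, and the kinetic inclusion decision
`PSI = 1 − [k_CE/(k_CE + k_AE·E)]·exp(−k_AE·E·τ)` — compose into an
overall switch whose Hill coefficient is bounded by the product of the
per-level coefficients (≈ 8 for three second-order stages).

## Worked example

```r
library(g4coop)

## equilibrium model at the literature energies:
## g_rG4 = 23 kcal/mol, g_bind from Kd = 0.2 uM, g_backfold = 0.8 kcal/mol
p <- energy_params(g_rG4 = 23,
                   g_bind = binding_energy_from_kd(0.2e-6),
                   g_backfold = 0.8)
transition_concentration(p)   # 2.42e-05 mol/l
model_hill(p, n_grid = 1001)  # 1.99

state_probabilities(p, transition_concentration(p))
#>   label probability      (top states)
#>  folded     0.50000
#>    2^31     0.33148
#>    2^22     0.16574
```

At its transition the system is split between the folded quadruplex and
the two double-backfolding modes (`2^31`, `2^22`): two proteins occupy
all four G-runs, and the apparent Hill coefficient is 2 — matching the
cooperativity seen for this protein in vitro.

```r
## simulate a splicing titration and classify the events
cfg <- sim_config(seed = 42, noise_sd = 0.02)
truth <- data.frame(event_id = c("exon_A", "exon_B"),
                    min = c(-0.35, -0.05), max = c(0.05, 0.25),
                    ec50 = c(1, 1.05), b = c(10.4, -1.2))
sim <- gen_titration(cfg, truth)
fit_titration_table(sim$data)
#>  event_id   n_H    min    max  ec50 pseudo_r2 direction         category
#>    exon_A 8.850 -0.356 0.0652 0.984     0.984 repressed   coop_repressed
#>    exon_B 0.824 -0.500 0.2433 0.173     0.840  enhanced noncoop_enhanced
```

The steep repressed event is recovered as strongly cooperative
(`n_H ≈ 9` from a generating slope of 10.4 under noise), the shallow
enhanced event as non-cooperative — the two regulatory classes the
dose-response module is built to separate.

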
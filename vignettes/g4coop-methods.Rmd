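---
title: "Models and methods behind g4coop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind g4coop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4coop)
```

# The biological question

HNRNPH is a splicing regulator whose three quasi-RRM (qRRM) domains each
recognize a run of guanines. Many of its binding sites sit inside RNA
G-quadruplexes (rG4s): four G-runs that can fold into a stacked-quartet
structure stabilized by K^+^ (but not Na^+^/Li^+^). When the quadruplex
unfolds, all four G-runs become available at once — a structural
arrangement that can convert independent protein binding into a
cooperative, switch-like response. g4coop implements the quantitative
machinery for studying this system end to end: an equilibrium model of
multi-qRRM binding, dose-response fitting of splicing titrations, a
kinetic cascade that propagates binding cooperativity into splicing
decisions, and the two sequencing-based callers (iCLIP binding sites,
RTstop rG4 detection) with synthetic-data generators for all of their
inputs.

# The equilibrium binding model

`energy_params()` describes the RNA-protein system with three free
energies, all in kcal/mol and entered as positive magnitudes:

* `g_rG4` — stabilization of the folded quadruplex relative to the
  unfolded RNA. Literature calorimetry puts this around 23 kcal/mol for
  stable rG4s.
* `g_bind` — the free-energy gain of one qRRM engaging one G-run.
  `binding_energy_from_kd()` derives it from a dissociation constant:
  with K~d~ = 0.2 µM at 298 K, `g_bind` ≈ 9.2 kcal/mol
  (−RT·ln K~d~/c~0~ with R = 1.987×10^−3^ kcal/(mol·K), c~0~ = 1 mol/l).
* `g_backfold` — an entropic penalty paid each time an already-bound
  protein folds back so that a further qRRM of the *same* protein
  engages an additional G-run.

Taking the unfolded, unbound RNA as the reference (weight 1), a binding
mode with $m$ proteins contacting $k_1,\dots,k_m$ G-runs has statistical
weight

$$\Omega \,(c/c_0)^m\,
  \exp\!\Big[\big(\textstyle\sum_i k_i\,g_\mathrm{bind}
  - \sum_i (k_i-1)\,g_\mathrm{backfold}\big)/RT\Big],$$

where $\Omega$ counts the distinct placements of the unlabeled proteins
on the linear array of G-runs. By default a protein's contacts occupy
*contiguous* runs (its qRRMs are tethered in tandem); this reproduces
the named modes of the 4-run system — for example `2^22` (two proteins,
two contacts each, the only placement being runs {1,2}+{3,4}) and
`2^31` (three contacts plus one, with two placements). A non-contiguous
variant is available via `contiguous = FALSE`. The folded, unbound
quadruplex has weight $\exp(g_\mathrm{rG4}/RT)$, and an optional helper
mode `1^F` — a protein bound to the *still-folded* quadruplex with
energy `g_rG4_bind` — has weight
$(c/c_0)\exp[(g_\mathrm{rG4}+g_\mathrm{rG4,bind})/RT]$.

All weights are accumulated in log space (log-sum-exp), so energies of
tens of kcal/mol do not overflow. `bound_fraction()` returns the
probability that at least one protein is bound; its oracle in the test
suite is a brute-force sum over explicit occupancy masks and block
compositions. `transition_concentration()` bisects the bound fraction
for its half-saturation point K on a log scale (guard interval
10^−30^–10^10^ mol/l), and `model_hill()` measures the EC10/EC90 Hill
coefficient of the curve on a log-spaced grid centered on K (default
121 points over 6 decades; pass `n_grid = 1001` for convergence-grade
accuracy — the acceptance computations do).

Two limiting cases organize the model's behavior:

* **No backfolding** (`max_qrrm = 1`): every protein binds with one
  qRRM only, so saturating the four runs requires four proteins. For
  large folding and binding energies the transition becomes an
  all-or-none exchange between the folded state and the 4-protein state
  and the Hill coefficient converges to 4.
* **Unrestricted backfolding** (`g_backfold = 0`): the transition is
  dominated by two-protein modes that occupy all four runs (`2^22`,
  `2^31`), giving a Hill coefficient that plateaus at 2 wherever the
  folding energy gates the transition. `zero_penalty_sweep()` maps this
  plateau over a grid of energies.

`reduced_double_backfold()` keeps only the two double-backfolding modes
and tracks the full model closely for moderate penalties; when the
penalty grows large the full model shifts to four singly-bound proteins
and the Hill coefficient rises back toward 4. `helper_state_effect()`
shows that a weak folded-rG4 helper mode (several kcal/mol below
`g_bind`) leaves the cooperativity untouched — it can catalyze
unfolding kinetically without distorting the equilibrium — whereas
helper binding comparable to `g_bind` makes folded-RNA binding dominate
and collapses the Hill coefficient toward 1.

## A convention audit

The statistical weights above fix several conventions that compact
summaries of such models often leave implicit: the reference
concentration (c~0~ = 1 mol/l), the temperature (298 K), proteins
treated as unlabeled, and placement multiplicities counted as ordered
arrangements on the linear run array. Three consequences deserve
explicit notice.

1. Under these conventions `2^31` and `2^22` have identical energy
   (four contacts, two backfolds) and `2^31` carries multiplicity 2, so
   at the transition P(2^31) = 2·P(2^22). Together the two modes
   dominate the bound ensemble — that statement is convention-robust
   and is what the test suite asserts. Which of the two *individually*
   ranks first depends on the multiplicity convention (for instance,
   weighting modes by the number of ways to choose which of the three
   qRRMs engage would favor `2^22`).
2. Inverting `g_backfold` from a transition at K = 3×10^−6^ mol/l with
   `g_rG4` = 23 and `g_bind` = 9.2 kcal/mol yields ≈ −0.3 kcal/mol
   here; alternative multiplicity conventions (unit weights, labeled
   proteins) move the value between about −0.4 and −0.1 kcal/mol. A
   small positive penalty of the same magnitude (&lt; 1 kcal/mol)
   arises under qRRM-choice weighting. The package reports the value
   its own conventions produce rather than forcing a reference value.
3. With `g_backfold = 0` the Hill coefficient genuinely exceeds 2
   slightly as K approaches 0.1 mol/l from below (≈ 2.11 in the limit,
   ≈ 2.03 on the default sweep grid): near-molar transition
   concentrations let three- and four-protein modes steepen the upper
   shoulder of the curve. The "never above 2" bound therefore holds
   exactly only for transitions well below molar (K ≲ 10^−2^ mol/l),
   which is where the plateau statistic of `zero_penalty_sweep()` is
   read.

# Hill coefficients from EC10/EC90

Throughout the package, cooperativity is quantified as

$$n_H = \frac{\log 81}{\log(\mathrm{EC90}/\mathrm{EC10})},$$

with EC10 and EC90 the input levels producing 10% and 90% of the
maximal response after min-max normalization of the curve. For an exact
Hill function this recovers the exponent (EC90/EC10 = 81^{1/n}).
`hill_coefficient_ec()` locates the EC levels by piecewise-linear
interpolation of log-input against the normalized response; decreasing
(repressive) curves are flipped so the EC levels refer to the magnitude
of the effect. Two numerical caveats are built into the tests: the
input grid must saturate both tails (otherwise min-max normalization
biases the EC levels), and it must sample the EC region densely for
steep curves. `overall_hill()` additionally refuses to normalize a PSI
curve spanning less than `flat_tol` (default 10^−6^) — normalizing
numerical noise on a flat curve would otherwise fabricate absurd Hill
coefficients.

# Dose-response fitting of splicing titrations

`fit_ll4()` fits the four-parameter logistic
$f(x) = \mathit{min} + (\mathit{max}-\mathit{min})/(1 + e^{\,b(\log x -
\log\mathit{ec50})})$ to ΔPSI observations across relative protein
levels, with box constraints tying the asymptotes to the control
inclusion levels ($\mathit{min} \in [-\max(\mathrm{PSI}_\mathrm{KD},
\mathrm{PSI}_\mathrm{OE}), 0]$, $\mathit{max} \in [0,
1-\min(\mathrm{PSI}_\mathrm{KD}, \mathrm{PSI}_\mathrm{OE})]$, ec50 ≥ 0,
slope unconstrained in sign). The optimizer is multi-start bounded
L-BFGS-B (slopes ±1, ±5, ±15 crossed with midpoints 0.7/1.0/1.3); the
best sum of squares wins and ties go to the smallest |b|. Replicates
are fitted pointwise, without averaging. The reported Hill coefficient
is |b|, with the regulatory direction (enhanced/repressed) carried
separately — the classification rule is symmetric in direction.
`pseudo_r2()` is $1 - SS_\mathrm{res}/SS_\mathrm{tot}$ around the
observation mean (negative values are possible; zero variance yields a
missing value), and `classify_event()` excludes fits with pseudo-R²
below 0.75 before splitting the rest into cooperative (n~H~ ≥ 2) versus
non-cooperative, enhanced versus repressed.

# The three-level splicing cascade

`cascade_response()` propagates the HNRNPH level through three
saturating stages: cooperative binding to the pre-mRNA (a Hill function
with exponent `n_H1` and threshold `K1`); regulation of multi-step
spliceosome recruitment, in which bound HNRNPH scales an activity
$(1+(\alpha-1)\,\mathrm{bound})^{n_{H2}}$ against an un-exponentiated
threshold constant `K2`; and the kinetic inclusion decision

$$\mathrm{PSI} = 1 - \frac{k_\mathrm{CE}}{k_\mathrm{CE} +
k_\mathrm{spl,AE}\,E}\; e^{-k_\mathrm{spl,AE}\,E\,\tau},$$

the product of losing the kinetic competition against skipping and not
committing within the transcription-coupled window τ. Compact notations
of this third level are ambiguous about operator binding; the package adopts
the competition-times-survival parse above because it is monotone and
sigmoidal, and keeps the literal alternative (the survival factor
inside the denominator) behind `parse = "literal"`, which can be
non-monotone — `overall_hill()` then fails with an error naming the
parse.

`per_level_hill()` confirms each stage's own steepness (level 1 is
exactly `n_H1`; a flat level, e.g. α = 1, is reported missing).
`max_chain_hill()` composes three pure Hill stages and maximizes the
overall EC-based coefficient over the two downstream thresholds; the
result respects the product bound $n_{H1} n_{H2} n_{H3}$ and for three
second-order stages a tuned placement reaches within a few tenths of
the bound of 8. `sample_population()` draws every parameter from an
independent log-normal distribution (median × e^{σZ}). The default
medians (n~H1~ = 2, K~1~ = 1, n~H2~ = 2, K~2~ = 1, α = 10,
k~CE~ = 1, k~spl,AE~ = 10, τ = 1) and a common log-sd of 0.5 are
documented stand-ins chosen to give every level a realistic, moderate
steepness; they are fully configurable. Runs with flat or non-monotone
responses are flagged `excluded`, never silently dropped; the default
population spans sub-first-order to well above tenth-order switching.

# The iCLIP binding-site caller

`call_binding_sites()` converts a per-nucleotide crosslink track plus a
list of significant crosslink positions (from a peak caller such as
PureCLIP) into 5-nt binding sites in three stages: significant
positions at most 3 nt apart are merged into regions and regions
shorter than 2 nt dropped; within each region, the highest-count
position (leftmost on ties) is extended ±2 nt into a site and the site
plus 4 nt margins excised, repeating until no placement remains;
finally, sites whose center is neither a significant position nor the
in-site count maximum, and sites with fewer than 3 covered positions,
are removed. The cleanup disjunction is read as keep-if-either
(`rule = "or"`); the stricter conjunction is available as
`rule = "and"`. Coordinates are 1-based closed in R (the IRanges
convention); `sites_to_bed()` emits 0-based half-open BED6. Placements
whose ±2 extension would leave the contig are discarded. The test suite
pins the whole procedure against an independently written step-by-step
reference on random tracks and verifies ≥ 95% recovery of planted sites
to within 1 nt.

# The RTstop rG4 caller

Reverse transcription stalls at stable structures, so rG4s leave
read-start pileups immediately 3′ of the fold under K^+^ that vanish
under Na^+^ (or when the transcript was made with 7-deaza-GTP, which
cannot form Hoogsteen pairs). On 200-nt library constructs the caller
excludes the first 18 nt (promoter pileup of full-length cDNAs), seeds
peaks at positions with ≥ 6 replicate-summed read starts, assembles
non-overlapping 3-nt windows around seeds in descending signal order
(kept only when ≥ 2 of the 3 positions carry signal), and merges the
KCl and NaCl peak sets, recentering partial overlaps on the maximum of
the combined coverage.

Constructs are filtered on their totals (≥ 100 median-of-ratios
normalized reads; constructs whose totals differ strongly between the
buffer conditions are excluded — a literal lessAbs parameterization of
this filter tests the opposite direction and is kept available as
`variability = "literal_lessAbs"`). The peak-level differential test is
a self-contained negative-binomial Wald test of NaCl against KCl:
normalized condition means, a method-of-moments dispersion with a floor
of 0.01, BH correction, and empirical-Bayes shrinkage of the fold
changes under a zero-centered normal prior whose variance is the excess
of the cross-peak second moment over the average sampling variance. A
peak is an rG4 when its adjusted p value is below 0.05 *and* its
shrunken log2 fold change is negative. DESeq2 — which the caller
deliberately does not wrap — serves as an independent cross-check in
the tests. Regions (four barcoded constructs each) are classified rG4
with ≥ 2 flagged constructs, non-rG4 with none, and inconsistent
otherwise; `propensity()` computes the read-ratio scores used to rank
rG4 strength.

# Splice maps

`extract_profiles()` opens windows at the four splice sites of a
cassette-exon event (up to 50 nt into exons, 300 nt into introns,
truncated at short features, oriented 5′→3′ in transcript space) and
min-max normalizes each window, mapping all-equal windows to zero so
that a handful of extreme events cannot dominate.
`aggregate_smooth()` averages position-wise and smooths with loess
(span 0.2 by default — unstated in the source procedure, chosen to
preserve ~30-nt features on a 350-nt window). Control events are
PSI-matched by `sample_matched_controls()` using target-group PSI
quantiles (0/5/70/80/100% for enhanced, 0/10/65/90/100% for repressed
groups) to define four bins, with per-bin counts defaulting to a
quarter of the target size; undersized bins fall back to sampling with
replacement, with a warning. `window_test()` compares per-event mean
signal in overlapping 10-nt windows (step 1) between target and
control groups with a two-sample Wilcoxon rank-sum test, BH-corrects,
and flags windows at FDR ≤ 0.01; all-tied windows receive p = 1.
`junction_psi()` and `junction_psi_nmd()` implement junction-count PSI
with the ≥ 25-count quantification rule, the NMD variant counting the
skipping junction twice.

# The synthetic-data generators

Every generator is seeded and byte-reproducible, and each one's ground
truth is recovered by its downstream module in the tests.

* `gen_titration()` draws ΔPSI from four-parameter logistic truth
  curves on 12 protein levels log-spaced between 0.46 and 1.76 of
  control (the endpoints anchor the range; the intermediate levels are
  configurable), three replicates per
  level, Gaussian noise of sd 0.02.
* `gen_crosslink_data()` adds triangular 5-nt signal kernels
  (half-width 2 nt, matching the site geometry) on a Poisson
  background; positions above the 99.9th percentile of the background
  distribution stand in for a peak caller's significant positions —
  deliberately *not* an HMM, only the input contract is preserved.
* `gen_oligo_library()` builds 200-nt constructs as 18-nt T7 promoter +
  146-nt insert + 15-nt barcode + 21-nt linker, with planted canonical
  rG4s (four runs of ≥ 3 G, loops 1–7 nt) starting at construct
  position 51, G-triplet-free background inserts, and barcodes with
  pairwise Hamming distance ≥ 5 and no GGG. `validate_library()`
  re-checks every constraint independently.
* `gen_rtstop_counts()` overlays a uniform Poisson background, a 5′
  pileup over positions 1–18, and — only under KCl with GTP — a
  negative-binomial stall at the nucleotide immediately 3′ of the
  planted quadruplex, spread 15/70/15 over that position and its direct
  neighbors to emulate the single-nucleotide stutter of reverse
  transcriptase at a structure edge (an exactly single-nucleotide spike
  would be sharper than the assay it emulates and starves the 2-of-3
  support rule of the peak caller).
* `gen_invitro_binding()` produces bound-signal titrations from the
  equilibrium model for Hill refitting via `fit_hill()`.

What the generators do *not* emulate — read-level errors, UMI
artifacts, mapping ambiguity, sequence-dependent crosslinking bias,
batch structure — bounds what the recovery tests show: they validate
the callers' rule logic and statistics under clean, known truth, not
robustness to upstream processing artifacts on real libraries.

# Problem sizes and numerical choices

The shipped tests and the acceptance computations use desk-scale sizes
chosen to keep the full suite fast while leaving the statistics
well-powered: equilibrium sweeps of 72 energy pairs with 1001-point
Hill grids, 1000-run cascade populations, libraries of 30–40 regions
(120–160 constructs), 200 power simulations and 25×40 null peaks for
the differential test, and 50 null repetitions of the splice-map window
test. Root finding uses log-scale bisection (relative tolerances 10^−9^
for K, 10^−6^ for the penalty inversion); the chain-composition
maximization runs a 0.5-decade grid search polished by Nelder-Mead.
Deterministic tie-breaks are leftmost everywhere a maximum is selected.

# Known limitations

The equilibrium model treats the three qRRMs as equivalent and ignores
sequence-specific energies per G-run and the ion dependence of
`g_rG4`; rate constants (unfolding kinetics) are outside its scope. The
cascade is a steady-state algebraic model, not a stochastic simulation
of spliceosome assembly. The NB Wald test trades DESeq2's
dispersion-trend machinery for a transparent two-moment estimate — at
three replicates per condition its dispersion estimates are coarse, and
the test leans on the shared prior across peaks. The splice-map module
consumes event coordinates as given; it does not detect events.
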
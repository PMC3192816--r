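---
title: "Translation elongation with finite tRNA recharging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translation elongation with finite tRNA recharging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ribotraffic)
```

## The model

Translation elongation is simulated as a driven lattice gas: each of the
`m_r` copies of mRNA species *r* is a 1D lattice of `L_r` codon sites, and
ribosomes are extended particles occluding `w` consecutive codons. The
"reader" — the codon being decoded — is the rightmost covered site; an
entering ribosome places its reader on codon 1 with the rest of its
footprint overhanging off-lattice to the left, and a terminating ribosome
leaves from the last codon in a single step, overhanging rightward. This
convention means every codon is read exactly once per traversal, and the
exclusion constraint is simply that consecutive readers on a lattice differ
by at least `w`.

What distinguishes this model from a fixed-rate exclusion process is the
resource coupling. Every codon belongs to one of `S` tRNA species. Species
*i* has a conserved pool of `T_i` molecules, split at any instant into
charged (`a_i`) and bare (`b_i`) counts shared by **all** lattices. The
four event classes and their rates are:

| event | precondition | rate | effect |
|---|---|---|---|
| initiation | no reader at position ≤ w | α (per lattice) | reader appears at codon 1 |
| elongation j → j+1 | next reader ≥ j+1+w, `a_s(j)` ≥ 1 | κ · a_s(j) | reader moves; a → b for species s(j) |
| termination from L | `a_s(L)` ≥ 1 (switchable) | β | ribosome leaves; a → b for s(L) |
| recharging (species i) | `b_i` ≥ 1 | V_i · b_i / (K_i + b_i) | b → a |

The linear dependence of the hopping rate on the charged count is the
simplest law consistent with mass action far from ribosomal saturation;
recharging is a Michaelis–Menten enzymatic step with all synthetases
treated as one average enzyme per tRNA species. Amino-acid availability,
wobble decoding, ribosome drop-off, internal ribosome sub-steps and a
finite ribosome pool are deliberately outside the model.

Because all transcripts drain the same pools, demand couples them: raising
the initiation rate increases the use rate `U_i` of every species, and the
first species whose use rate reaches its maximum recharging rate
`R_i = V_i T_i / (K_i + T_i)` collapses to a low charging level
`c_i = <a_i>/T_i`. Its codons become slow *dynamically*, queues grow behind
them, and the current saturates — the limited-resources (LR) regime, with a
smooth onset, in contrast to the sharp queueing-phase (QP) transition
behind a codon that is slow for static reasons.

## Simulation method

The engine (`src/engine.cpp`) is an exact continuous-time Monte Carlo
(Gillespie) sampler: at each step the full catalogue of enabled events is
rebuilt from the current state, the waiting time is exponential in the
total rate, and one event is chosen proportionally to its rate. Rebuilding
from scratch at every step trades a constant factor of speed for a strong
correctness guarantee — there are no stale cached rates by construction —
and at desk scale (10^3–10^4 codons, 10^6–10^7 events per run) a run takes
seconds. The contract is that sampling is exactly proportional to the
instantaneous rates, whatever the data structure; the pure-R reference
implementation (`init_state()`, `enabled_events()`, `step_state()`) states
the same semantics in readable form and is held to the same stationary law
in the tests.

Time is simulated seconds, not Monte Carlo sweeps. For comparison with
sweep-based bookkeeping, one sweep of a lattice-plus-pool system
corresponds to `N + T_tot` attempted events; the schedule defaults
(burn-in 200 s, measurement 400 s) were chosen so that the first and
second halves of the measurement window agree within noise for the
packaged fixtures.

Observables are time-weighted integrals accumulated online over the
measurement window only: terminations (→ current `J`, proteins per mRNA
copy per second), per-site reader dwell times (→ reader density profiles;
coverage profiles follow by summing the `w` sites a reader occludes),
charged-pool integrals (→ `c_i`), per-site hop counts (→ flux-conservation
checks) and bound-ribosome time (→ ribosomes per codon). Standard errors
come from 5 equal blocks of the window; identical seeds give bit-identical
trajectories.

Two switches matter for interpretation. `fixed_rates = TRUE` pins
`a_i = T_i` and removes the recharge channels — the classic fixed-rate
extended-particle TASEP, used as the infinite-recharging control.
`charge_on_termination` (default `TRUE`) decides whether the terminal hop
consumes a charged tRNA of the last codon's species; the hop-out-of-a-site
bookkeeping argues for `TRUE`, the alternative reading (the stop codon is
decoded by release factors, not a tRNA) is available because the choice is
not observable in any quantity we report beyond a 1/L_r correction to one
species' demand.

## Parameters

All defaults live in `default_config()` and are ratios of a budding-yeast
cell, so a simulation of `N` codons is a proportionally shrunk cell:

| parameter | default | meaning |
|---|---|---|
| `w` | 10 codons | ribosome footprint (~30 nt protected) |
| `k_mean_target` | 10 /s | mean fully-charged hopping rate; fixes κ |
| `trna_per_codon_ratio` | 0.75 | T_tot/N, from ~3×10^6 tRNAs and ~4×10^6 ORF codons per cell |
| `cell_volume_L` | 4.2×10⁻¹⁴ L | 42 fL; scaled to `v_eff = V_cell · N / N_cell` |
| `kcat` | 5 /s | synthetase turnover (one average enzyme for all species) |
| `km_conc_M` | 3×10⁻⁷ M | Michaelis constant, converted to molecules via `K = K_M · N_A · v_eff` |
| `enzymes_per_trna` | 0.1 | synthetase molecules per tRNA molecule (proteome-scale estimate) |

Per-species pools are allocated from tRNA gene copy numbers by
largest-remainder rounding (`allocate_trna_counts()`), enzyme numbers are
`E_i = max(1, round(0.1 · T_i))`, and κ is set so the unweighted mean over
species of `κ T_i` equals `k_mean_target` (a codon-usage-weighted mean is
available via `kappa_weighting = "usage"`; the unweighted mean is the
default because it keeps κ a property of the tRNA pool alone). The
termination rate defaults to twice the largest fully-charged hopping rate
so it is never limiting. Because pools, enzymes and volumes are integers
and rounded, intensive predictions are scale-invariant only up to
discretization — the tests allow for one molecule of rounding.

## The analytic layer

Supply `σ_i = T_i/T_tot` and demand `f_i = Σ_r m_r n_{i,r} / Σ_r m_r L_r`
both sum to one; their ratio `Q_i` ranks species by depletion propensity.
The entry-limited current and density of a uniform lattice of
`w`-particles,

```
J(α) = α (k − α) / (k + (w − 1) α),    ρ(α) = α / (k + (w − 1) α),
```

hold for `α ≤ k/(1+√w)`; beyond that the uniform lattice carries the
maximal current `J_MC = k/(1+√w)²`. For a mixed-codon transcript in the LD
regime we evaluate these forms at the position-averaged supply,
`k̄ = κ T_tot ⟨σ_s(j)⟩` with the arithmetic site average (the harmonic
average, which weights slow codons more strongly, is exposed as an option;
at realistic usage the two differ by a few percent and the arithmetic
choice is the default). The critical initiation rate of species *i* solves
`J(α) · C_i = R_i` (with `C_i` its total codon count) in closed form as the
smaller root of a quadratic; species whose `R_i/C_i` exceeds the maximal
LD current can never be depleted in that regime and report `α_c,i = ∞`.
To first order `α_c,i ≈ R_i/C_i`, which with enzymes proportional to tRNAs
is proportional to `1/Q_i` — the ranking by `Q` and the ranking by
first-order `α_c` are the same, and both are verified in the tests.

For a single *statically* slow site of rate `q` in a bulk of rate `k`, the
queueing-phase threshold needs the defect's carrying capacity. We estimate
it from the jammed renewal cycle — the waiting ribosome leaves the defect
at rate `q`, then its follower needs `w` bulk hops to reach the defect —
giving `J_q = qk/(k + wq)`, capped by `J_MC` since a weak defect cannot
out-carry the uniform lattice. `α_QP` is where the LD current reaches
`J_q`; at `q = k` it reduces exactly to the LD/MC boundary. Direct
measurement on a `w = 10` designer lattice gives a plateau current within
6% of `J_q`, and the simulated queue onset brackets `α_QP` within 25% on
the `w = 3` test lattice; the capacity estimate ignores density
correlations around the defect, which is where those few percent go.

For a two-codon designer transcript (uniform bulk, one distinct central
codon) three thresholds compete: `α_c` of the central species (smooth
LR-induced queueing), `α_QP` (sharp queueing phase), and `α_c` of the bulk
species (an LR regime with no queue, because the slow codons *are* the
bulk). `classify_designer_regime()` simply takes the smallest, and the
packaged presets (`fixture_designer()`) realise each regime with thresholds
separated by factors of ≥ 2 so that simulation can confirm the
classification unambiguously.

The per-gene indices: QLI is the geometric mean of `Q_s(j)` along the ORF
(the geometric mean over `Q` itself, not a rescaling — the negative
correlation with CAI is the consistency check); CAI is the Sharp–Li
geometric mean of RSCU-based adaptiveness weights, excluding single-codon
families, with a 0.5 pseudocount for unseen codons (every pseudocount use
is reported via a message).

## What the synthetic data emulate — and what they do not

The supplementary sequence data of the original study (the codon/tRNA
labelling key, measured gene copy numbers, and the yeast ORF and
cell-cycle panels) are not redistributable here, so every packaged fixture
is a **synthetic surrogate**, labelled as such in file names and headers:

* `synthetic_trna_table()`: 41 species labelled alphabetically by tRNA
  name, gene copies spanning 1–16 (total 269) to reproduce the real
  abundance spread; `synthetic_codon_map()` assigns each of the 61 sense
  codons to exactly one species (no wobble splitting).
* `synthetic_orfs()`: four transcripts with the documented lengths (110,
  480, 87, 560 codons) and usage structure — the 110-codon
  ribosomal-protein surrogate has no rare codons but one dominant codon
  type (a fifth of the sequence, `Q ≈ 3.8`) clustered around position 80;
  the 480-codon transcript carries six copies of the rarest tRNA's codon
  separated by much more than `w`.
* `synthetic_cellcycle_panel()`: ten phase-switching genes with the
  documented High/Low pattern and tenfold-scaled lengths, plus twelve
  constitutive genes, the switching genes making up ~15% of all codons.
  Four of the G1-induced genes lean heavily (30% of codons, clustered) on
  one abundant tRNA species, so the G1→G2 abundance switch moves that
  species' demand across its depletion threshold in one phase only.

Passing tests on these fixtures demonstrates the *mechanisms* — supply/
demand-controlled depletion, cluster-enhanced queueing, phase-dependent
competition — at the documented system sizes and parameter ratios. They do
not demonstrate sequence-level agreement with the real yeast genes, codon
frequencies of the real transcriptome, or the genome-wide QLI–CAI
correlation (our synthetic usage gradient gives Spearman ≈ −0.99, cleaner
than any real genome because the bias axis is constructed).

## Numerical choices and degenerate inputs

* Event selection scans a freshly built rate buffer; ties cannot occur with
  continuous rates, and the final buffer slot is the fallback for
  floating-point edge overshoot.
* Accumulation windows are clipped exactly at the burn-in and end-of-run
  boundaries and split exactly across SE blocks, so block sums equal the
  full-window integrals to machine precision.
* A state with zero total rate (e.g. `α = 0` with empty lattices) coasts
  deterministically to the end of the schedule.
* `exact_stationary()` counts lattice configurations by recursion before
  enumerating anything and refuses state spaces beyond `max_states`; the
  stationary distribution is solved from the sparse generator with the
  normalisation row replacing one balance equation.
* `β = 0` is accepted (a stalling test mode); `measure ≤ 0`, empty alpha
  grids, unsorted grids, zero targets and impossible mixtures are rejected
  with messages that name the offending record.
* Zero `Q` values (unused species) and unseen reference codons get logged
  pseudocounts; `q > k` is reported as "not a bottleneck" (`α_QP = ∞`)
  rather than an error.

## Problem sizes used by the tests and the acceptance script

Single-transcript production runs use ~5×10³ codons (45 copies × 110), the
mixtures and cell-cycle panels 4–8×10³ codons, the mono-codon calibration
system 4.5×10³, and the designer lattices ~2×10³; steady-state windows are
300–900 simulated seconds after 200–1500 s of burn-in, chosen so that
every reported standard error is well below the tolerance of the check
that consumes it. The exact-oracle comparisons run on micro-instances of 8
and ~5×10³ states. A full test run plus the acceptance script completes in
a few minutes on one CPU.

## Known limitations

* The charged-count hopping law is linear; saturation at high `a_i` is not
  modelled (it matters only if tRNAs were overproduced).
* One average synthetase per species: no per-enzyme kinetics, no
  amino-acid starvation, no multi-substrate aminoacylation.
* No wobble: each codon maps to one tRNA species, so isoacceptor sharing
  and the associated rate penalties are absent.
* The LD closed forms are thermodynamic-limit results; on short lattices
  (L ≲ 30) boundary corrections of a few percent are visible.
* The defect-capacity estimate behind `α_QP` is a renewal-cycle
  approximation, accurate to ~6% for strong defects and exact only in the
  two limits it is anchored to.
* The cell-cycle comparison is a scaled-down panel; at desk scale the
  G1/G2 usage ratio is ~1.1, a qualitative (directional) reproduction of
  the full-scale effect, not a quantitative one.
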
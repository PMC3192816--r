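# ribotraffic

Stochastic simulation and analysis of mRNA translation elongation under
**finite, shared tRNA resources**.

## The problem

Ribosomes translate an open reading frame codon by codon, and the decoding
rate of each codon depends on the abundance of its aminoacylated (charged)
tRNA. Classic traffic models of translation — the totally asymmetric simple
exclusion process (TASEP) with extended particles — treat those rates as
fixed. But charged tRNAs are a *consumable, shared* resource: every
elongation step discharges one molecule, and synthetases recharge the bare
pool at a finite, saturable rate. When the initiation rate α rises, the use
rate of a heavily demanded tRNA species can reach its maximum recharging
rate; its charging level collapses, the corresponding codons become slow,
and ribosome queues form — even when that tRNA is abundant. Which species
fails first is set by the interplay of **supply** (tRNA abundance) and
**demand** (codon usage across the whole transcriptome), so the translation
of every mRNA is coupled to all others through the common pools.

`ribotraffic` implements this model for anyone studying translational
control, codon usage optimisation, or driven lattice gases with dynamic
disorder: an exact continuous-time kinetic Monte Carlo engine (Rcpp) for
multiple mRNA lattices coupled to Michaelis–Menten recharging, plus the
closed-form layer that predicts where and when queueing sets in.

## Model

For tRNA species *i* with total pool `T_i` (charged `a_i(t)` + bare
`b_i(t)`):

- hopping rate of a ribosome reading a codon of species *i*:
  `k_i(t) = κ · a_i(t)`, requiring a charged molecule and a vacant
  destination (ribosomes occlude `w = 10` codons; the reader is the
  rightmost covered codon);
- each hop out of a species-*i* codon moves one molecule `a_i → b_i`;
- aggregate recharging of species *i*: rate `V_i · b_i / (K_i + b_i)` with
  `V_i = k_cat · E_i`;
- initiation at rate α onto codon 1 when no reader sits within the first
  `w` codons; termination from the last codon at rate β ≫ all other rates.

Analytic layer (per tRNA species *i*): supply `σ_i = T_i / T_tot`, demand
`f_i = Σ_r m_r n_{i,r} / Σ_r m_r L_r`, queueing propensity `Q_i = f_i/σ_i`;
the entry-limited (LD) current `J(α) = α(k−α)/(k+(w−1)α)` and density
`ρ(α) = α/(k+(w−1)α)`; the critical initiation rate `α_c,i` at which the
species' use rate `U_i(α) = J(α)·Σ_r m_r n_{i,r}` meets its maximum
recharging rate `R_i = V_i T_i/(K_i+T_i)` (to first order
`α_c,i ≈ R_i / (f_i N) ∝ 1/Q_i`); the fixed-slow-site queueing threshold
`α_QP`; and the per-gene indices QLI (geometric mean of `Q` along the ORF)
and CAI (Sharp–Li).

## Worked example

Forty-five copies of the packaged 110-codon ribosomal-protein surrogate
(`YDR382W`, a synthetic stand-in with the documented codon-usage structure),
yeast-proportioned tRNA pools, initiation rate well above the predicted
depletion threshold:

```r
library(ribotraffic)

sys <- fixture_system("mrna_A", alpha = 0.4)   # 45 x 110 codons, 41 tRNA species
critical_alphas(sys)                            # predicts bottleneck: Glu1, alpha_c ~ 0.096
obs <- run_simulation(sys, burn_in = 300, measure = 600, seed = 11)
print(obs)
```

```
ribotraffic observables (measure = 600 s, 838,162 events)
    name   L copies terminations     J    J_se reader_density coverage_density
 YDR382W 110     45         2484 0.092 0.00028         0.0776            0.751
ribosomes per codon: 0.0776 +/- 6.3e-05
min charging level: 0.0437 ( Glu1 )
```

Reading this: each mRNA copy produces ~0.09 proteins/s; the charged pool of
the most-demanded tRNA species (Glu1, the largest `Q`) has collapsed to 4%
of its total, its codon clusters around position 80 have become slow, and
the queue behind them holds ~0.078 bound ribosomes per ORF codon — close to
the `1/w = 0.1` packing limit. Re-running with `fixed_rates = TRUE`
(infinite recharging, the classic TASEP) removes the queue entirely: the
depletion dynamics, not static codon speeds, produce the bottleneck.

Other entry points: `scan_alpha()` sweeps initiation rates and overlays the
predicted `α_c`; `classify_designer_regime()` separates depletion-induced
queueing (LR), the sharp fixed-rate queueing phase (QP), and bulk-limited
no-queueing regimes for two-codon designer transcripts;
`make_oracle_instance()` returns micro-systems with their exact stationary
law for validation; `inst/scripts/ribotraffic` wraps simulate / scan /
analyze / fixtures for shell use.

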
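# multipk

Continuum-electrostatics prediction of protein pK values from
**multi-regime conformer ensembles**.

## The problem

The pK of an ionisable group in a protein is shifted from its model-compound
value by desolvation, by the protein's permanent partial charges and by
coupling to the other titratable sites — all of which depend on
conformation.  Ensemble-based pK calculations sample conformations from a
simulation run at one fixed protonation state, which biases the result: an
all-charged ensemble keeps its salt bridges intact at pH 2, where the real
protein has protonated its carboxylates and let them go, so single-regime
calculations overestimate charge–charge stabilisation.

`multipk` implements the multi-regime remedy.  Titration curves are computed
on three conformer ensembles generated under different fixed protonation
regimes — `allC` (all groups charged), `glu0` (glutamates neutral), `lys0`
(lysines neutral) — and combined with pH-dependent convex weights before the
midpoint is read off.

## The model

For each snapshot, a finite-difference linearised Poisson–Boltzmann solver
(ε_protein = 4, ε_solvent = 78, I = 0.14 M, 298 K, two-stage grid focusing)
produces, per protonation microstate *x_i* of each titratable site, the
desolvation, permanent-charge and reference-state corrections that assemble
the intrinsic pK,

    pK_int = pK_std + dpk_born + dpk_perm + dpk_ref,

plus the site–site interaction matrix W.  Microstate populations follow the
partition function over protonation-state vectors **x** = (x₁,…,x_N),

    p_iα(pH) = Σ_x δ(x_i, α) exp(−ΔE(x)/kT) / Σ_x exp(−ΔE(x)/kT),
    ΔE(x)    = Σ_i [ ln10·kT·Δm_i·(pH − pK_std,i) + ΔG_elec,i ]
               + Σ_{i<j} W(x_i, x_j),

evaluated exactly for small systems or by Metropolis Monte Carlo (with pair
moves for strongly coupled sites) for large ones.  Curves are averaged over
the M snapshots of each regime and combined with weights

    W_glu0 = 1 − θ̄_carb(glu0),   W_lys0 = θ̄_amino(lys0),
    W_allC = 1 − W_glu0 − W_lys0,        Σ_S W_S(pH) = 1,

so the acidic-regime ensemble dominates at low pH, the all-charged ensemble
at neutral pH and the basic-regime ensemble at high pH.  The pH where the
combined tracked population crosses 0.5 is reported as **pK(1/2)**; on a
homodimer the chain-pair difference ΔpK is the precision metric.

## Worked example

A salt-bridge toy system: a glutamate and a lysine at a 2.9 Å
donor–acceptor distance; in the `glu0` ensemble the bridge is broken (8 Å),
emulating the conformational change that follows protonation of the acid.

```r
library(multipk)

spec <- bridge_spec(d_bridge = 2.9, d_broken = 8, n_conformers = 4,
                    jitter_sd = 0.3, seed = 42)
ens  <- make_regime_ensembles(spec)              # allC / glu0 / lys0
res  <- multiph_pk(ens, config = pb_config(grid_spacing_fine = 0.6,
                                           fine_padding = 4),
                   termini_policy = "none")

res$pk[, c("site", "site_class", "pk_mod", "pk_allc", "pk_multi")]
#>     site site_class pk_mod pk_allc pk_multi
#> 1 A:GLU1   carboxyl    4.4    3.51     3.86
#> 2 B:LYS1      amino   10.4   11.15    11.28

res$weights[res$weights$pH %in% c(2, 7, 12), ]
#>     pH   allC    glu0    lys0
#> 21   2 0.0085 9.9e-01 2.3e-08
#> 71   7 0.9988 1.2e-03 3.7e-05
#> 121 12 0.2788 1.9e-08 7.2e-01
```

Reading the numbers: the intact salt bridge stabilises the charged
glutamate, pulling its pK a full unit below the model value (pK_allc =
3.51).  The combined prediction (pK_multi = 3.86) sits above the allC-only
value because around pH 4 the acidic-regime ensemble — where the bridge is
broken — carries most of the weight: using only the all-charged ensemble
overestimates the salt bridge's contribution.  The weights behave as
required: glu0 ≈ 1 at pH 2, allC ≈ 1 at pH 7, lys0 dominant at pH 12, and
they sum to 1 at every grid point.

A command-line front end wrapping the same functions ships in
`inst/cli/multipk.R`:

```sh
Rscript inst/cli/multipk.R fixtures --type bridge --out fx --seed 1 --m 4
Rscript inst/cli/multipk.R titrate --mode multi-regime \
    --allc fx/allC_001.pdb,fx/allC_002.pdb \
    --glu0 fx/glu0_001.pdb,fx/glu0_002.pdb \
    --lys0 fx/lys0_001.pdb,fx/lys0_002.pdb --out run1
```

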
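---
title: "Multi-regime ensemble pK calculations: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-regime ensemble pK calculations: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multipk)
```

## The problem

The pK values of ionisable groups in a protein shift away from their
model-compound values because of desolvation, interactions with the protein's
permanent partial charges, and charge–charge coupling between titratable
sites.  All three depend on conformation, and a protein in solution populates
an ensemble of conformations.  Worse, which conformations are populated
depends on pH itself: an ensemble generated (for example by molecular
dynamics) with every group charged is representative near neutral pH, but
extrapolating its electrostatics to pH 2 — where the carboxylates are in fact
protonated and their salt bridges broken — systematically overestimates
charge–charge stabilisation.

`multipk` implements a pragmatic answer: compute titration curves separately
on three conformer ensembles, each generated under a fixed protonation regime
chosen to be representative of one pH region — `allC` (all ionisable groups
charged, tyrosines neutral; the neutral-pH regime), `glu0` (glutamates
neutral; acidic regime) and `lys0` (lysines neutral; basic regime) — and
combine the per-site curves with pH-dependent convex weights before reading
off the midpoint pK.

The package consumes pre-generated conformers (PDB snapshots); generating
them (the MD itself) is out of scope.

## The titration model

Each titratable site $i$ has a catalogue of protonation *microstates*
$x_i$ — protonation state plus hydrogen placement (His Nδ-H/Nε-H tautomers,
optionally carboxyl O1/O2 protonation).  A state of the whole molecule is a
vector $\mathbf{x} = (x_1,\dots,x_N)$.  The population of microstate
$\alpha$ of site $i$ at a given pH is the Boltzmann average

$$p_{i\alpha}(\mathrm{pH}) \;=\;
\frac{\sum_{\{\mathbf{x}\}} \delta(x_i,\alpha)\,
      e^{-\Delta E(\mathbf{x})/kT}}
     {\sum_{\{\mathbf{x}\}} e^{-\Delta E(\mathbf{x})/kT}},$$

with the all-reference vector as the zero of energy and

$$\Delta E(\mathbf{x}) = \sum_i \Big[\ln 10\,kT\,\Delta m_{x_i}
   (\mathrm{pH} - \mathrm{p}K^{\mathrm{std}}_{x_i})
   + \Delta G^{\mathrm{elec}}_{x_i}\Big]
   + \sum_{i<j} W(x_i, x_j).$$

Here $\Delta m_{x_i}$ is the number of protons bound in $x_i$ relative to
the reference microstate, $\mathrm{p}K^{\mathrm{std}}$ the microscopic
standard pK, $\Delta G^{\mathrm{elec}}$ the pH-independent electrostatic
offset of the microstate and $W$ the pairwise interaction between charge
differences, counted once per pair.  The **reference state** of the system is
*all sites neutral*; with that choice the neutral microstates carry
$\Delta q = 0$, so $W$ is non-zero essentially only between charged forms,
which keeps the interaction matrix sparse and interpretable.

The electrostatic offset decomposes as
$\Delta G^{\mathrm{elec}} = \Delta G^{\mathrm{Born}} +
\Delta G^{\mathrm{perm}} + \Delta G^{\mathrm{ref}}$, and in pK units
($\mathrm{dpk}_x = -\Delta G_x/(\Delta m\,\ln 10\,kT)$) assembles the
intrinsic pK

$$\mathrm{p}K^{\mathrm{int}} = \mathrm{p}K^{\mathrm{std}} +
  \mathrm{dpk}^{\mathrm{Born}} + \mathrm{dpk}^{\mathrm{perm}} +
  \mathrm{dpk}^{\mathrm{ref}},$$

the pK the site would have if all other sites were frozen in the reference
state.  The signs work out so that burying an acid's carboxylate raises its
pK and burying a lysine's ammonium lowers it.

**Tautomer statistics.** With $n_p$ protonated and $n_d$ deprotonated
microstates of equal energy, the macroscopic midpoint of an isolated site
sits $\log_{10}(n_p/n_d)$ above the microscopic pK.  The site catalogue
therefore sets $\mathrm{p}K^{\mathrm{std}} = \mathrm{p}K^{\mathrm{mod}} -
\log_{10}(n_p/n_d)$ so that an isolated model compound titrates exactly at
its model pK (His, with two neutral tautomers, gets
$6.4 + \log_{10} 2$ microscopically).

Model pK values: Glu 4.4, Asp 4.0, Lys 10.4, Tyr 9.6, His 6.4, N-terminus
7.5, C-terminus 3.8.  Arginine (guanidine, model pK taken as 12) is detected
but held fixed protonated by default, since it does not titrate in the 0–14
range at the accuracy of continuum methods; `detect_sites(fixed_arg =
FALSE)` overrides this.

## Electrostatics: finite-difference linearised Poisson–Boltzmann

Every energy term comes from the linearised Poisson–Boltzmann equation
solved with a 7-point finite-difference stencil and Gauss–Seidel successive
over-relaxation.  Defaults follow standard continuum practice for proteins:
protein dielectric 4, solvent 78, ionic strength 0.14 mol/L, 298 K, solvent
probe 1.4 Å, ion exclusion layer 2.0 Å.

Numerical choices (all configurable through `pb_config()`):

* **Two-stage focusing.** A coarse grid (1.0 Å) covering the molecule plus
  10 Å of solvent, with analytic Debye–Hückel boundary values, feeds
  boundary potentials to a fine grid (0.4 Å) covering the molecule plus
  3 Å.
* **Dielectric boundary.** The solute volume is the van der Waals union of
  the atom spheres.  Each grid link's dielectric is the harmonic average of
  the dielectric sampled at 8 points along the link — exact for a planar
  interface and markedly better behaved under grid refinement than midpoint
  sampling (the Born-ion test converges 0.8 → 0.4 Å with errors
  2.5% → 0.2%).  An optional probe-rolled re-entrant correction
  (`reentrant = TRUE`) reassigns solvent pockets narrower than the probe to
  the solute; it is off by default because the toy systems the package is
  validated on have no re-entrant cavities, and the vdW-union boundary is
  the cheaper, well-characterised approximation.
* **Charges** are spread trilinearly (charge-conserving); potentials are
  read back trilinearly.
* **Grid self-energy cancellation.** Desolvation is the difference between
  the reaction-field self-energy of the microstate's charge difference in
  the full protein and in the *model compound* — the site's own fragment
  (side chain from Cβ, or the terminal fragment), in the same conformation,
  alone in solvent.  Both solves use byte-identical grids and source
  charges, so the singular grid self-energy cancels exactly.
  Conformation-matched model compounds also cancel geometry artefacts.
* **Interaction matrix.** $W(x_i,x_j)$ is evaluated as
  $\sum_a \Delta q_a \phi(r_a)$ from one solve per charged microstate
  (a linear-response evaluation; no self-consistency loop) and symmetrised
  over the two directions; the residual asymmetry is recorded
  (`W_max_asym`) as a solver-quality diagnostic.
* **Convergence.** SOR iterates until the largest update falls below
  `tol` (default 1e-4 kcal/mol/e, `maxit` 5000, over-relaxation 1.9);
  non-convergence is an error carrying the residual, never a silent result.
* **Grid symmetry.** Grids are centred on the bounding-box centre with odd
  node counts, so an exactly mirrored dimer maps onto an exactly mirrored
  grid: chain-pair ΔpK on mirrored fixtures measures solver precision, not
  grid-placement luck (observed: ~1e-5 pK units).

## Parameter set

Standard all-atom force fields assign partial charges to hydrogens that the
input snapshots may not contain.  The package
instead ships its own self-contained heavy-atom table
(`inst/extdata/heavy_atom_params.tsv`): hydrogen charges are collapsed onto
their parent heavy atoms so every residue's neutral reference form sums to
exactly 0 e, with dielectric-boundary radii in the solvation-calibrated
(Rashin-type) range (C 1.8–2.0 Å, N 1.6 Å, O 1.5 Å, S 1.85 Å).  Titration is
then a matter of swapping the group's absolute charge set per microstate
(e.g. neutral carboxyl C 0.30/O −0.55/OH 0.25 versus charged
C 0.10/O −0.55/O −0.55).  The titrating proton's charge is thus placed at
canonical heavy-atom positions per microstate — the practical reading of a
multiple-hydrogen-location treatment when explicit H coordinates are absent.

## Solving the partition function

`populations_exact()` enumerates all $\prod_i n_i$ state vectors (capped at
$2^{20}$) with exact Boltzmann normalisation.  Beyond the cap,
`populations_mc()` runs Metropolis Monte Carlo: single-site microstate moves
plus simultaneous pair moves for site pairs coupled more strongly than two
pK units (|W| > 2.73 kcal/mol), which rescues mixing for tightly coupled
pairs such as salt bridges.  Defaults are 10⁴ production sweeps after 10³
burn-in per pH point; populations carry batch-mean standard errors (20
batches), and runs are bitwise reproducible given a seed.  A mean acceptance
rate below 0.02 triggers a poor-mixing warning.  On systems small enough to
enumerate, MC agrees with the exact result to within sampling error (this is
a standing test).

## From curves to pK(1/2)

Per snapshot, the tracked population of each site (protonated class for
amines, imidazoles, guanidines; its complement is the degree of
deprotonation used for carboxyls and hydroxyls) is computed on the pH grid
(default 0–14, step 0.1).  Curves are **arithmetically averaged over the M
snapshots** of each regime ensemble, then combined across regimes:

$$W_{glu0}(\mathrm{pH}) = 1 - \bar\theta_{\mathrm{carb}}^{(glu0)},\qquad
  W_{lys0}(\mathrm{pH}) = \bar\theta_{\mathrm{amino}}^{(lys0)},\qquad
  W_{allC} = 1 - W_{glu0} - W_{lys0},$$

where $\bar\theta_{\mathrm{carb}}^{(glu0)}$ is the mean degree of
deprotonation of the carboxyl groups computed *from the glu0 ensemble* and
$\bar\theta_{\mathrm{amino}}^{(lys0)}$ the mean deprotonation of the amino
groups from lys0.  This is the minimal construction satisfying the limits
the method requires — glu0 weighs 1 in the acidic limit, allC at neutral
pH, lys0 in the basic limit — together with $\sum_S W_S = 1$ at every pH.
Should the two defining curves overlap ($W_{allC} < 0$), the weight is
clamped at zero and the triple renormalised; the event is recorded on the
result.  Because averaging and weighting are both linear, their order is
immaterial; the package averages within regimes first.

Two scope choices were genuinely open and are switchable:
$\bar\theta_{\mathrm{carb}}$ averages over *all* carboxyl-class sites (Glu,
Asp, C-termini) by default even though the glu0 regime neutralises only
glutamates, because the weighting curve is meant to track when "the
carboxyls" titrate (`carboxyl_scope = "glu"` restricts it); symmetrically,
$\bar\theta_{\mathrm{amino}}$ uses Lys and N-termini
(`amino_scope = "lys"` restricts).

pK(1/2) is the pH where the combined tracked population crosses 0.5, by
linear interpolation between grid points (interpolation error < 0.005 pH on
the default grid).  Multiple crossings return the one nearest the model pK
with a `multimodal` flag; no crossing returns NA with an `out_of_range`
flag, never a fabricated number.  For homodimers, chain-averaged pK(1/2) is
the arithmetic mean of the two chains, and the signed chain difference
ΔpK (with its mean absolute value) is the precision metric: symmetry demands
zero.

## What the synthetic fixtures emulate — and what they do not

The generator (`toy_spec()`, `make_toy_peptide()`,
`make_regime_ensembles()`) builds heavy-atom toy peptides from per-residue
templates (bond-plausible geometry, side chains extended), optionally
mirrored into exact symmetric dimers, and turns them into regime ensembles
by Gaussian coordinate jitter (σ = 0.3 Å) around the base structure, with a
rigid regime-bias displacement standing in for the conformational change a
regime's protonation state induces — e.g. `bridge_spec()` places a
glutamate and a lysine at a 2.9 Å donor–acceptor distance (a typical salt
bridge) and moves them to 8 Å in the glu0 ensemble, emulating a bridge that
breaks once the acid is neutral.  The ensemble-size default M = 280 mirrors
a 50 ps snapshot cadence over 14 ns of trajectory; tests and the acceptance
script run deliberately scaled-down instances (M = 2–4, fine spacing
0.5–0.8 Å, one to three residues per chain) chosen so each check isolates
one property of the method.  All fixture randomness derives from one
integer seed through R's default generator, so fixtures are reproducible to
the byte.

These fixtures validate the *machinery*: the solver against closed forms,
the partition function against brute force, the weighting contract, the
sign and direction of the salt-bridge correction, and the symmetry
precision of the whole pipeline.  They do not emulate real conformational
ensembles — no backbone relaxation, no correlated side-chain motion, no
solvent structure — so green tests certify correctness of the
implementation, not the 0.3-pH-unit accuracy a full MD-based application of
the method can reach on a real protein.  Reproducing per-site values for a
real system requires its crystal structure and nanosecond-scale sampling,
both outside the package's scope; the bundled GCN4 reference table carries
published chain-averaged values so the accuracy statistics
(`mean_abs_dev()`, `rmsd()`, the Null model) are exercised against real
numbers.

## Degenerate inputs and edge cases

Malformed PDB records fail naming the line; duplicate atoms within a
residue fail naming the atom; unknown residues warn and are skipped, never
silently.  Curves that never cross 0.5 are flagged rather than
extrapolated.  `rmsd()` exposes its denominator as a policy (`n` default,
`n-1` optional) because published tables do not always state the
convention; accuracy aggregation in this package standardises on
`mean_abs_dev`, which has no such ambiguity.  Sites missing experimental
values are excluded pairwise from accuracy reports with the retained count
stated.

## Known limitations

* Linear PB only; no nonlinear salt effects, membranes or explicit solvent.
* The vdW-union dielectric boundary (default) ignores re-entrant volume;
  the optional correction is approximate and costs a distance transform.
* The regime weighting is a heuristic coupling of conformational and
  protonation equilibria, not a rigorous thermodynamic linkage — the
  method's own framing is that of a practical compromise, and this package
  keeps that framing.
* Heavy-atom collapsed charges trade hydrogen-level detail for robustness
  to hydrogen-free snapshots; per-microstate charge sets are coarser than a
  full force-field assignment.
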
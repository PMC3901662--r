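---
title: "Scoring, search and rescoring in pocketdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, search and rescoring in pocketdock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketdock)
```

## The scoring model and its assumptions

`pocketdock` scores a ligand pose against a rigid receptor with a five-term
empirical potential. Every interacting heavy-atom pair contributes a
weighted sum of two attractive gaussians, a quadratic steric clash penalty,
a hydrophobic contact ramp (hydrophobic–hydrophobic pairs only) and a
hydrogen-bond ramp (donor–acceptor pairs only), each a function of the
*surface distance* `d = r − (R_a + R_b)`, with the interatomic distance
cut off at 8 Å. The underlying assumptions are the usual ones for this
family of scoring functions: the receptor is rigid, hydrogens carry no
score (they only inform donor typing), electrostatics and desolvation are
absorbed into the fitted term weights, and affinity is additive over pairs.

Atoms are assigned one of 15 heavy-atom types: hydrophobic and polar
carbon, four nitrogen classes and two oxygen classes split by donor /
acceptor role, S, P, the four halogens, and a single metal class. Metal
ions are treated as hydrogen-bond donors. Donor status is inferred from an
attached hydrogen found by distance-threshold bond perception
(`r < 1.15·(r_cov,a + r_cov,b)`), since the PDBQT format carries no bond
records; polar carbon is a carbon bonded to any non-carbon heavy atom. The
van der Waals radii (C 1.9, N 1.8, O 1.7, S 2.0, P 2.1, F 1.5, Cl 1.8,
Br 2.0, I 2.2, metal 1.2 Å) and all five term weights are exposed through
`scoring_weights()` and `engine_config()`; the defaults are the published
regression values for this potential family, fitted to curated
protein–ligand affinity data.

The conformation-dependent score splits exactly into inter-molecular and
intra-molecular sums, `e = e_inter + e_intra`. The intra sum runs over
heavy-atom pairs that can actually move relative to each other: pairs in
the same rigid frame, pairs separated only by inactive torsions, and pairs
within three consecutive covalent bonds (1–4 and closer) are excluded. The
reported free energy divides out flexibility,

$$E_i = \frac{e_i - e_{\mathrm{intra},1}}{1 + w_{\mathrm{flex}}\,(N_{\mathrm{act}} + 0.5\,N_{\mathrm{inact}})},$$

subtracting the intra score of the *best* conformation rather than each
conformation's own, so the output ordering equals the ordering by `e_i`.
Giving inactive torsions half weight is this package's reading of the
flexibility penalty — they exist as rotors but cannot move heavy atoms; the
coefficient `w_flex` (default 0.05846) is configurable.

## Precalculation: pair table and grid maps

Because the potential depends only on (type a, type b, r), all
120 = 15·16/2 unordered type-pair curves are precalculated on a uniform
grid of 16,384 distances in [0, 8] Å, together with their analytic
derivatives, and served by *nearest-sample lookup* — deliberately not
interpolation, trading a bounded O(Δr) error for a single array read. The
error is bounded by the bin width times the curve's slope; the test suite
verifies the bound empirically and its decay as the sampling doubles
(2^10, 2^12, 2^14). The sampling is uniform in `r` (not `r²`), one of the
places where the original engines are ambiguous; the choice is recorded
here and fixed.

Inter-molecular energies are likewise precalculated on per-atom-type grid
maps over the cubic search box (default spacing 0.15625 Å): each lattice
node stores the summed pair lookup of a virtual probe atom of that type
against all receptor heavy atoms in range, plus three derivative lattices
for the Cartesian gradient. Ligand atoms read their nearest node.
Derivatives are stored analytically rather than finite-differenced so the
optimizer sees smooth directions even where the value surface is a
staircase. Poses that stray outside the box are clamped to the lattice
edge rather than rejected, keeping the optimizer inside the feasible
region; the boundary region is effectively flat, so clamping introduces no
spurious minima.

## Pose search

A pose is (position, unit quaternion, one angle per *active* torsion).
Torsions whose whole subtree moves no heavy atom — hydroxyl, amine, methyl
rotors — are deactivated during parsing, shrinking the search dimension.
Forward kinematics walks the ROOT/BRANCH tree; gradients are assembled by
back-propagating per-atom forces: translation gradient as the force sum,
orientation gradient as the torque about the root anchor (in
rotation-vector coordinates re-anchored after every accepted step), and
each torsion gradient as the axis component of its subtree's torque.

The global search runs `n_runs` independent chains: a uniform random pose
(position uniform in the box, orientation uniform on SO(3) by Shoemake's
method, torsions uniform), then repeated mutate → BFGS → Metropolis.
The BFGS line search backtracks from a step capped at 1 Å/rad per
coordinate — the cap stops a steep clash gradient from flinging the pose
across the box — and local optimization terminates exactly when no
acceptable step length exists, the termination rule that makes the local
minima sharp. Metropolis accepts any improvement and a worsening Δ with
probability `exp(−Δ/T)` (default T = 1.2 score units). Accepted minima
from all chains are pooled, greedily clustered at 1.0 Å RMSD, and at most
9 poses are returned, energy-ascending. Chain *k* reseeds the RNG with
`seed + k`, so the pose list is reproducible and independent of execution
order. The per-chain iteration budget is
`iterations_base · (1 + n_heavy/32 + n_active/4)` — iteration effort grows
with ligand complexity; the constants are this package's calibration, as
the originals are unpublished. The defaults lean deliberately toward *many
short chains* rather than few long ones: on the funnel fixtures, chain
success is dominated by which basin the initial descent lands in, and
extra basin-hopping iterations convert poorly.

## Random-forest rescoring

Rescoring summarizes a complex as 36 contact counts — protein elements
{C, N, O, S} × ligand elements {C, N, O, F, P, S, Cl, Br, I}, pairs within
12 Å (ties count as inside; the generous cutoff implicitly captures
solvation shells) — deliberately element-based, not engine-type-based. A
Breiman–Cutler random forest (500 unpruned CART trees on bootstrap
samples, best split among mtry = 12 ≈ p/3 features, nodes of ≤ 5 samples
become leaves, prediction = mean over trees of the traversed leaf mean)
regresses the counts onto affinity in pKd units; the fitting is delegated
to the `randomForest` package, which implements exactly this algorithm,
behind `train_rf()`/`predict_rf()`, and an exhaustively-searched CART
oracle in the test suite cross-checks the single-tree case. Engine
energies convert to the same scale by `pKd = −ΔG/(R·T·ln 10)` with
R = 1.9872×10⁻³ kcal·mol⁻¹·K⁻¹ and T = 298.15 K (configurable), and the
consensus is the plain mean of the two predictions. Both pose-selection
conventions — first pose and best-over-poses — are reported by
`rescore_poses()`.

## What the synthetic fixtures emulate — and what they do not

No external structures are shipped; every test input is generated in code.

`make_funnel_complex()` builds a zig-zag carbon chain (terminal oxygen
acceptor) lying in a slot-shaped pocket: near-complete rings of carbon
probes centred on the chain midline with a 90° opening above, end caps,
two zinc donors pinning the terminal oxygen off-axis, and a few sparse
attractor atoms over the mouth that widen the capture basin through their
long-range gaussian tails. The terminal-oxygen anchors are what break the
slot's flip-and-slide symmetry — without them a half-turn decoy scores
within noise of the plant. Each built fixture *certifies its own ground
truth*: an exhaustive 1 Å translation scan, a battery of half-turn ×
axial-shift decoys, and random rigid perturbations must find no pose that
scores below the planted one yet lies outside its basin (> 1 Å RMSD);
otherwise construction fails rather than hand the search tests a broken
landscape.

The fixtures emulate the *geometry* of a binding funnel at the engine's
own energy scale (wells of a few score units). They do not emulate real
receptor chemistry: no protonation states, no waters, no charged residues,
no induced fit, well depths an order of magnitude shallower than kcal-deep
experimental pockets, and search boxes a few hundred cubic Å rather than
screening-scale. A passing redock on the fixture therefore demonstrates
that scoring, gradients, precalculation and search interlock correctly —
not that real complexes of arbitrary flexibility will redock; recovery is
expected to degrade as rotatable bonds are added, which the suite monitors
on flexible fixtures without asserting.

`make_rf_training_set()` emulates the statistical shape the rescoring
model assumes: non-negative Poisson contact counts with fixed per-feature
rates (3–7 expected contacts), affinity a sparse linear function of four
counts plus one mild pairwise interaction plus Gaussian noise
(σ = 0.1 pKd by default). The generating surface is deterministic — the
seed draws only counts and noise — so independently seeded sets share one
truth and held-out correlation is meaningful. Real affinity data differ in
every inconvenient way: correlated features, heteroscedastic noise,
non-additive chemistry; the recovery test shows the forest plumbing works,
not that 36 counts suffice for real complexes.

## Numerical choices and problem sizes

* Nearest-sample and nearest-node lookup throughout (no interpolation);
  trilinear interpolation exists only inside the test suite as the
  comparison oracle for the grid error.
* Table sampling includes both endpoints; the last sample sits at the
  cutoff and stores 0, and lookups at or beyond the cutoff return exactly 0.
* BFGS: Armijo constant 1e-4, step halving, initial step capped at
  1 Å/rad per coordinate, inverse-Hessian update skipped when `s·y ≤ 1e-12`,
  curvature reset to the identity when the direction is not a descent
  direction.
* Ties in greedy pose clustering resolve to the lower-energy pose by
  construction (ordering is by score before selection); ties in
  "first rank attaining the minimum" resolve to the smallest rank.
* The standard deviation reported by `correlation_metrics()` is that of
  the prediction errors; the residual-about-the-regression-line convention
  used by some benchmarks is available via `sd_convention = "residual"`.
* Degenerate inputs: rigid ligands have intra score exactly 0; an empty
  minima pool returns an empty pose list; a zero-variance affinity vector
  raises an undefined-correlation error rather than returning NA.
* Test and acceptance problem sizes are chosen for a single core: pair
  tables of 2,048 samples (the full 16,384-sample table is built once to
  verify its dimensions), funnel boxes of ~13 Å with 0.15625 Å maps,
  redocking checks of 20 seeded repeats at 192 chains × ~4 iterations, and
  forests of 500 trees on 500 synthetic complexes. The same code paths run
  unchanged at larger sizes.

## Known limitations

Receptor flexibility, explicit solvent, electrostatics and desolvation are
out of scope, as are re-deriving the term weights (requires licensed
affinity data) and shipping a forest trained on real complexes. RMSD is
computed on fixed atom correspondence without graph-automorphism symmetry
correction, so symmetric ligands can be penalized at most by their
symmetry displacement. The pure-R search loop is fast enough for
desk-scale work (hundreds of chains per second on toy complexes) but is
not a screening engine; the precalculation layers are where the design
spends its memory (a 13 Å box at default granularity holds ~6·10^5 nodes
× 4 lattices per atom type) to keep per-evaluation cost flat.
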
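---
title: "Coarse-grained mucin glycopeptides: model, parameterization and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained mucin glycopeptides: model, parameterization and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucincg)
```

## The model

`mucincg` builds MARTINI 3 coarse-grained (CG) models of O-glycosylated
mucin glycopeptides. The MARTINI 3 philosophy maps 2–4 heavy atoms onto
one interaction bead; beads come in three size classes — tiny (T, two
atoms), small (S, three) and regular (R, four) — with van der Waals radii
0.191, 0.230 and 0.264 nm and masses 36, 54 and 72 Da. Beads are placed
at the unweighted centre of geometry of their constituent heavy atoms,
and every heavy atom of the input must land in exactly one bead (the
partition property, asserted on every mapping).

O-glycans need four rules beyond the standard protein mapping:

1. **Glycosidic oxygen to the acceptor.** A glycosidic bond condenses
   out the donor's anomeric hydroxyl oxygen and the acceptor's hydroxyl
   hydrogen; the surviving bridging oxygen is chemically the acceptor's
   own, so it is kept in a bead of the glycosyl acceptor sugar.
2. **TC5 for glycosylated N-acetylhexosamines.** Once GalNAc (or GlcNAc)
   donates a bond, its anomeric group is reduced to a –CH–CH– pair; the
   usual SN6 assignment is replaced by a tiny TC5 bead whose raised
   polarity reflects the flanking amide and glycosidic oxygen.
3. **SN4ar / TN4ar protein–glycan linkages.** The side-chain bead of a
   glycosylated threonine becomes SN4ar (three heavy atoms) and of a
   serine TN4ar (two); the side-chain oxygen is the glycosidic oxygen and
   stays on the protein side, consistent with rule 1.
4. **Q4n sulfates and anionic sialic acids.** Sulfate groups map to a
   regular Q4n bead with charge −1 e; the sialic-acid carboxylate bead
   (SQ5n here) also carries −1 e. Histidine is mapped neutral, since its
   imidazole pKa (~6) sits below physiological pH.

Each monosaccharide ring is treated as a **rigid body** of its three ring
beads plus one massless TC4 **virtual site** at the ring centroid
(`add_ring_virtual_sites()`); rigid rings carry no internal bonded terms.

Internal units are GROMACS-compatible: nm, kJ/mol, Da, degrees at the
API (radians internally), k~B~ = 0.0083145 kJ mol⁻¹ K⁻¹, default 300 K.

## Bonded forms

Three bonded potentials are used:

* harmonic bonds, $V = \tfrac12 k_b (r - r_0)^2$ (the ½k convention is
  also GROMACS'; LAMMPS' $K(r-r_0)^2$ dialect is converted on export);
* restricted-bending (ReB) angles,
  $V = \tfrac12 k_\theta (\cos\theta - \cos\theta_0)^2 / \sin^2\theta$,
  which diverges at 180° and thereby protects the dihedral calculation
  from collinear triples — the reason this form is preferred over a
  cosine-harmonic angle for CG chains with dihedrals;
* periodic dihedrals, $V = k_\phi(1 + \cos(n\phi - \phi_s))$, IUPAC
  torsion convention, wrapped to (−180°, 180°].

The ReB and periodic forms are implemented as stated here and are the
package's fixed convention; both are evaluated exactly, with analytic
derivatives verified against central differences in the test suite.

## Modified Boltzmann inversion

`boltzmann_invert()` measures one distribution per bonded term of a
(pseudo-)CG trajectory and fits each form to its own Boltzmann density.
"Modified" refers to the per-form estimators, which avoid the noise
amplification of naive PMF differentiation:

* **Bonds** are moment-matched against the Gaussian Boltzmann density:
  $r_0 = \langle r\rangle$, $k_b = k_BT/\mathrm{Var}(r)$. The identity
  $k_b \cdot \mathrm{Var} = k_BT$ holds exactly by construction.
* **Angles**: the angle histogram is Jacobian-corrected (divided by
  $\sin\theta$), converted to a PMF, smoothed with a 3-bin moving average
  (switchable off) and the mode located with sub-bin quadratic
  interpolation — for the ReB form the PMF mode is exactly $\theta_0$.
  $k_\theta$ is then found by a 1-D root search so that the variance of
  the exact ReB Boltzmann density
  $p(\theta) \propto \sin\theta\, e^{-V/k_BT}$ matches the sample
  variance. With 1° bins this places $\theta_0$ to roughly a degree and
  $k_\theta$ to a few percent at 10⁵ samples.
* **Dihedrals**: the PMF $-k_BT\ln p(\phi)$ (offset so its minimum is
  zero) is fitted by linear least squares with a free offset — making the
  fit invariant to the PMF offset — for each candidate multiplicity
  $n \in \{1,2,3\}$; the best $n$ wins by residual. The number of minima
  of the smoothed circular PMF is reported as a multimodality diagnostic:
  a single periodic term cannot represent a multimodal torsion, and the
  diagnostic flags those cases rather than hiding them.

Histogram bins are 0.001 nm (bonds), 1° (angles), 5° (dihedrals), all
configurable. Zero-variance (rigid) degrees of freedom raise an error
rather than returning an infinite force constant, and terms internal to
rigid rings are excluded from measurement altogether. Distribution
agreement is quantified by the absolute percentage deviation of means and
the histogram overlap coefficient (`compare_distributions()`); equal
distributions give 0 % and 1.0.

The result is a classed model object (`cg_fit`) in the R modelling idiom:
`coef()` tabulates the fitted parameters, `residuals()` the PMF fit
residuals, `plot()` overlays fitted Boltzmann densities on the measured
histograms, and `simulate()` draws a new synthetic trajectory from the
fitted topology — which is how the round-trip fidelity property (overlap
≥ 0.95 between measured and re-simulated distributions) is tested.

## System building

`estimate_molecular_volume()` integrates the union of the bead vdW
spheres on a 0.02 nm voxel grid (overlaps counted once).
`plan_solvation()` fills the free box volume with W beads — **each W bead
represents exactly four water molecules** — to 1 g/cm³
(`floor` rounding), and computes NaCl pairs at the target concentration
on the *represented water volume* (the volume of $4 n_W$ water molecules
at 1 g/cm³), rounded half-to-even; neutralizing counterions are added on
top, so every plan is electroneutral by construction. The
represented-water convention is deliberate: for a 12.5 nm box holding
15,860 W beads at 150 mM it yields 171 ion pairs, whereas computing on
the box volume would give 176. `pack_system()` inserts solvent at random
with a minimum-image cell list (default minimum distance 0.40 nm, 10⁴
attempts per particle) — a deliberately simple stand-in for dedicated
packing tools, adequate at CG densities. `build_repeats()` concatenates
tandem copies of a glycopeptide unit joined by backbone bonds; mass and
charge scale exactly n-fold.

Exports: GROMACS `.itp/.top/.gro` (1-based indices, nm, funct 10
restricted-bending angles, funct 1 periodic dihedrals, rigid-ring edges
as constraints, virtual sites as `virtual_sitesn`), and LAMMPS data files
("real" units: Å, kcal/mol; bond $K = k_b/2/4.184/100$, dihedrals in the
`fourier` style, ReB angles as 721-point tabulated potentials at 0.25°
spacing since LAMMPS has no native ReB style; rigid groups and virtual
sites as structured comments for `fix rigid`). Both writers are
byte-stable under write → read → write, which the suite asserts.

## Validation metrics

R~g~ is mass-weighted (virtual sites excluded by a 10⁻⁶ Da mass
threshold; a geometric variant is available by passing unit masses),
R~ee~ is the distance between the terminal backbone beads, and SASA uses
Shrake–Rupley-style sphere-point sampling with a deterministic Fibonacci
lattice (960 points/bead by default) on the probe-inflated spheres, probe
radius 0.191 nm and per-class radii 0.191/0.230/0.264 nm. Sphere-point
sampling was chosen over the double-cubic-lattice algorithm because it
is verifiable against the analytic single-sphere area and a hit-or-miss
Monte Carlo oracle — both checks run in the suite (1 % and 2 %
agreement). RDFs use minimum-image distances in periodic cubic boxes,
normalized by ideal-gas shell counts; glycan–glycan RDFs default to
glycan centres of geometry (bead-level profiles are available by passing
bead coordinates directly). RMSD offers Kabsch superposition on or off,
since either convention is defensible for pseudo-CG comparisons.
`fit_flory()` fits $R_g = R_0 M_w^\nu$ by ordinary least squares on
log–log axes (weighted fit available); the exponent separates collapsed
globules (≈0.33), coils (0.5–0.6) and rods (1.0).
`downscale_protein_lj()` multiplies the LJ ε by a factor (canonically
0.88) for pairs where *both* types belong to the protein moiety
(glycans included by default, configurable), leaving σ and all
water/ion interactions untouched; downscaling composes multiplicatively.

## Synthetic data: what it does and does not emulate

The fixture generator builds *pseudo-atomistic* glycopeptides: 2–4
pseudo-atoms per template bead at fixed centred offsets around planned
bead centres, so structures are mapping-consistent by construction but
not chemically realistic. The packaged 30-residue construct reproduces
the documented bookkeeping of the Mini2-type mucin segment — 30 PTS-type
residues, 18 O-glycans (12 Thr-linked, 6 Ser-linked), one neutral
histidine, net charge −13 e from ten sialic acids and three sulfates —
but the residue-by-residue glycan assignment is a synthetic stand-in
(shipped as `mini2_composition_synthetic.tsv`, user-replaceable), because
the original per-site assignment is not published in machine-readable
form.

`generate_synthetic_trajectory()` samples every bonded degree of freedom
from its exact Boltzmann density (inverse-CDF on fine grids; angles carry
the $\sin\theta$ configurational Jacobian, bonds and dihedrals do not)
and rebuilds Cartesian frames chain-wise by natural-extension reference
frames, holding rigid-ring internals fixed. It is the ground-truth
generator for the inversion round trips: every parameter the fitter must
recover is known exactly.

`mc_sample_molecule()` is a desk-scale Metropolis sampler over bead
positions: Gaussian single-bead moves, rigid-body moves for rings
(virtual sites follow their ring), and optional pivot moves that rotate
a whole subtree about a backbone bead — the standard accelerator for
polymer conformational sampling. Non-bonded interactions are a WCA-type
soft repulsion (excluded volume and charged-glycan repulsion surrogate;
there is no Coulomb term and no solvent) plus, optionally, an attractive
truncated LJ between protein-group beads (`backbone_attraction`) that
emulates the sticky backbone–backbone interactions responsible for IDP
collapse. Because the sampler works in Cartesian measure, its marginal
bond distribution carries an $r^2$ Jacobian and its angle marginal a
$\sin\theta$ factor; the tests compare against these exact targets.

The qualitative bottlebrush property is demonstrated at desk scale with
short chains (4–12 repeat units of a one-residue glycosylated or bare
unit, 25,000 MC steps each): with a sticky flexible backbone, the bare
chain collapses while dense repulsive glycans keep the glycosylated
backbone extended, so the Flory exponent fitted on the *backbone* R~g~
versus total M~w~ is distinctly larger for the glycosylated chains. The
backbone-R~g~ convention isolates the conformational contrast from the
constant brush-thickness offset that dominates whole-molecule R~g~ at
these short backbone lengths. Passing this property shows the machinery
(repeat building, sampling, scaling fits) reproduces the expected
direction; it says nothing quantitative about real mucins, whose
published exponents come from long explicit-solvent MD and
light-scattering experiments and are far outside desk scale.

## Numerical choices and problem sizes

* Inversion round trips run at 10⁵ frames (about a second to generate),
  where bonds recover r₀ within 0.05 %, k_b within ~1 %, angles θ₀
  within ~2° and k_θ within a few %, and dihedral k_φ within ~1 %.
* SASA and volume oracles use 20 random 5–6-bead assemblies with 2 × 10⁴
  surface points or 10⁶ volume points each.
* Flory bias checks use 500 replicates of 6 points with 5 % log-normal
  noise.
* Stochastic operations take an explicit integer seed, expanded to
  independent sub-streams by a counter-based scheme, so every fixture and
  sampler run is reproducible.
* Degenerate inputs fail loudly: collinear angles are flagged (ReB is
  singular at 180°), zero-variance coordinates raise rigid-DOF errors,
  over-rigid dihedrals (more than half the histogram empty) are rejected,
  infeasible packings and over-full boxes raise geometry errors, and a
  sampler that accepts nothing for 10⁴ steps aborts with diagnostics.

## Known limitations

* No electrostatics anywhere in the sampler; charged glycans act through
  the soft-repulsion surrogate only.
* Single-term dihedral fits cannot represent multimodal torsions; the
  multimodality diagnostic reports them, and a multi-term series is a
  possible extension.
* The packaged sugar templates use synthetic pseudo-atom names; mapping
  real atomistic structures requires templates matching the force field's
  atom nomenclature (the declarative `.map` format makes this a data
  change, not a code change).
* `pack_system()` is a rejection packer, not an optimizer; at liquid
  densities with large minimum distances it will refuse rather than
  deform the system.
* The construct's per-site glycan assignment is synthetic (correct
  counts, charge and linkage chemistry; arbitrary placement).
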
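---
title: "Rotamer packing by equivariant chi-angle regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotamer packing by equivariant chi-angle regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Given a protein backbone and its sequence, side-chain packing asks for the
coordinates of every side-chain heavy atom. Although a tryptophan side
chain has ten heavy atoms (30 coordinates), physical constraints on bond
lengths, bond angles and the non-rotatable dihedrals reduce its true
degrees of freedom to at most four torsion angles, the chi angles.
`chipacker` therefore splits the problem in two:

1. regress the chi angles of every residue from its local atomic
   environment, with a model that respects the rotational symmetry of the
   problem;
2. rebuild the side-chain atoms from the predicted chi angles, holding all
   remaining ("redundant") internal coordinates at median values fitted
   from reference structures.

The error introduced by step 2 alone — rebuilding from the *true* chi
angles — is the *null reconstruction error*, the floor of any chi-based
packer. It is computed by `null_reconstruction_rmsd()`; on the three real
structures bundled with bio3d it is a small fraction of a bond length, and
it barely moves when the median table is fitted on a single structure,
which is why medians over a modest reference set suffice
(`fit_redundant_ics()`).

## Geometry layer

Torsions follow the right-handed two-plane convention with the eclipsed
arrangement at 0 degrees and anti at 180 (`compute_dihedral()`); angles are
stored in degrees in (-180, 180] and converted to radians only at
trigonometric boundaries. Atom placement uses the natural-extension
reference frame construction (`place_atom()`): a new atom is fixed by its
bond length to the parent, the bond angle to the grandparent, and the
torsion against the great-grandparent. Every side chain is described by a
dependency-ordered build table (`sidechain_build_spec()`) rooted in the
backbone N/CA/C plus CB; torsions are either tied to a chi angle (possibly
with a constant offset, e.g. the second branch of a valine isopropyl
group) or fitted as near-constant medians (ring closure torsions, amide
planes). Proline's ring is built from chi1/chi2 like any other chain; the
N-CD closure is not separately enforced, consistent with treating chi as
the only degrees of freedom.

Internal-coordinate fitting takes medians per (residue type, atom):
plain medians for lengths and angles, and a circular median (unwrapped
about the circular mean) for torsion offsets, which is safe because the
observed distributions are narrow and unimodal. The bundled
`ideal_ic_table()` was fitted from the three real structures shipped with
bio3d so that the package is fully reproducible offline; it also defines
the geometry of the synthetic fixtures, which makes the fixtures'
null-reconstruction error exactly zero — a useful separation between
data-geometry error and algorithmic error.

### Naming symmetries

Chemically indistinguishable atom namings are handled in two places. For
chi angles, a 180-degree rotation of the Phe/Tyr ring (chi2) or of the
Asp/Glu carboxylate (chi2/chi3) leaves the structure unchanged, so losses
and evaluation take the per-angle minimum against chi and chi + 180
(`symmetry_corrected_loss()`, `chi_errors()`). For coordinate RMSD,
`side_chain_rmsd()` minimizes over atom-name swap groups: the `base` mode
allows only same-element swaps (Asp/Glu oxygens, Arg NH pair, Phe/Tyr
rings); the `extended` mode adds the cross-element amide and imidazole
flips that some evaluation protocols also permit. These are reported as
separate RMSD variants (`evaluate_packing()`), together with a `rec`
variant that measures against a reconstruction of the truth from its own
chi angles, isolating chi error from the null-reconstruction floor.

## Holographic encoding

A residue's environment is the point cloud of heavy atoms within
`r_cut = 10` Angstrom of its alpha-carbon. The cloud is split into
channels — C/N/O/S, a wildcard element, and a partial-charge channel
(weights from a bundled table of approximate Amber99sb-style charges),
optionally plus 21 amino-acid identity channels — and each channel's
weighted Dirac-delta density is projected onto the orthonormal 3D Zernike
basis: radial polynomials (nonzero only for even n - l >= 0, orthonormal
on the unit ball) times real spherical harmonics. The coefficients form a
steerable tensor: rotating the cloud multiplies each degree-l block by the
real Wigner-D matrix (`rotate_tensor()`), a contract the test suite checks
to 1e-6 over random rotations.

Numerical choices:

* Real harmonics without the Condon-Shortley phase; `wigner_d_real()` and
  the real Clebsch-Gordan tensors (`real_cg()`) are constructed in the
  same convention, so equivariance holds exactly rather than up to sign.
* Radii are scaled by `r_cut` onto the closed unit ball; an atom at
  exactly the cutoff is kept.
* Per-delta normalization divides each atom's *unit-weight* coefficient
  vector by its own L2 norm before the weighted sum. Normalizing before
  applying the weight keeps the charge channel's sign and magnitude and
  keeps the encoding linear in the weights. The literal squared-norm
  variant is available (`normalize_mode = "squared_norm"`). Because the
  per-atom norm is taken over the kept coefficients, encodings at
  different `l_max` nest only when this normalization is off.
* `n_max = 12` by default at the 10 Angstrom cutoff, so at least one
  radial function oscillates below the minimum heavy-atom separation;
  `n_max` is a config field and smaller values are appropriate for small
  single-residue clouds (the toy benchmark uses 8).

## Equivariant network

Features are steerable maps: for each degree l up to `l_max`, a
multiplicity of copies with 2l + 1 components. The network has three
parts (`network_config()`):

1. **Projection and conditioning.** A linear embedding of the one-hot
   residue type is concatenated to the degree-0 input features; a per-degree
   linear layer (mixing copies, identical across m, never across l or m)
   projects to a common hidden multiplicity. Conditioning touches only
   invariants, so it cannot break equivariance.
2. **Equivariant blocks.** Each block applies (i) a feature-wise tensor
   product of the map with itself — copy k of degree l1 couples only with
   copy k of degree l2, through all Clebsch-Gordan paths with output degree
   at most `l_max`; paths antisymmetric under exchange vanish for a
   self-product and are skipped — (ii) a norm-based layer normalization
   with a silu gate (degree-0 features get a true layer norm plus silu;
   higher degrees are rescaled per copy by silu(gamma n + beta)/n of their
   norm n, the only nonlinearity that preserves steerability), (iii) a
   shape-preserving per-degree linear layer, and an additive skip. Biases
   exist only on degree 0.
3. **Heads.** The sincos and angle objectives read the final degree-0
   features through a feed-forward network with silu and dropout (8
   tanh-bounded outputs interpreted as sine/cosine pairs, or 4 outputs in
   the scaled periodic domain). The plane-normal objective instead reads 4
   degree-1 vectors from the final map.

The full-path tensor product was rejected for cost; feature-wise
self-interaction keeps the parameter count and runtime small, in keeping
with the light-weight design. Initialization is variance-scaled per layer
(1/sqrt(fan-in)); the seed lives in the config, and inference is
deterministic. All backward passes are hand-written reverse-mode
and verified against central finite differences in the test suite.

## Objectives

All three objectives are separable sums over a residue's defined chi
angles, which is what makes the per-angle symmetry minimum exact:

* **Angle** (`angle_loss()`): squared *wrapped* difference in a scaled
  domain where degrees map to [0, 2) via (chi + 180)/180. The difference
  is wrapped before squaring, so -179 vs 179 degrees costs (2/180)^2 of
  the period squared, not the naive seam penalty. A flag reproduces the
  min(E, period - E) form with the square inside for comparison; it mixes
  units and is not the default.
* **Sine/cosine** (`sincos_loss()`): mean squared error against the unit
  circle embedding, equal to the cosine distance 1 - cos(delta) for
  on-circle predictions (asserted to 1e-12 in the tests).
* **Plane normals** (`plane_normal_loss()`): cosine loss against the unit
  normals of the dihedral planes. Predictions are L2-normalized before the
  loss and before decoding. Decoding walks the side chain outward: chi k
  is the signed angle between consecutive normals about the current bond
  axis, and each decoded chi places the atom that provides the next axis
  (`chi_from_plane_normals()`), with the redundant first normal taken from
  the backbone N-CA-CB plane.

Angle accuracy uses a strict < 20 degree comparison on every defined chi;
boundary ties are measure-zero in float but the strict form makes the
statistic deterministic.

## Two-stage packing

The initial-guess model sees backbone-only neighborhoods (N, CA, C, O, CB
of all residues) with both channel sets; the refinement model sees
full-atom neighborhoods (minus the centre's own side chain) with atomic
channels only, so its evidence is physical rather than name-based.
`pack()` runs the initial guess, rebuilds all side chains, then applies
the refinement model for `rounds` iterations, re-encoding every residue
against the *previous* round's coordinates — a synchronous update, chosen
so results do not depend on residue order. `rounds = 5` is the default
with `rounds = 2` documented as the speed/quality compromise;
convergence-based stopping is deliberately out of scope. The upper bound
of refinement is measured by feeding the refinement model the true
neighbor coordinates (`packing_run(upper_bound = TRUE)`). Residues with
noncanonical types or incomplete backbones pass through unpacked, with a
warning. Training splits are made at the structure level, never the
residue level, to avoid environment leakage between train and validation.

## Synthetic fixtures and what they show

`make_mini_protein()` builds chains on ideal helix or strand backbones,
samples chi angles (uniform, fixed, or a per-chain shared rotamer state
with jitter — the latter creates environments that actually determine a
residue's conformation, which the pipeline tests exploit), reconstructs
side chains from the bundled table, and optionally jitters coordinates.
Generation is fully determined by (spec, seed). The fixtures emulate
connectivity, sterically plausible local geometry and known ground truth;
they do not emulate crystallographic artifacts (altlocs, partial
occupancy, missing density), realistic rotamer distributions, or packing
interactions, so green tests certify the machinery — equivariance,
round-trips, optimization behaviour, metric bookkeeping — not real-data
accuracy.

### The toy benchmark

`toy_task_data()`/`toy_task_run()` reproduce, at desk scale, the
comparison of objectives and angular resolutions on the task of reading a
residue's chi angles off its own conformation without residue-type
conditioning: 1000 training and 200 test methionine conformations with
uniform chi angles and 0.02 Angstrom coordinate noise, encoded with atomic
channels at `n_max = 8`, models of ~104k parameters (hidden multiplicity
chosen per `l_max` for parameter parity), 300 epochs of Adam under a
cosine schedule. The noise emulates the coordinate uncertainty of real
structures; without it, exact ideal geometry lets even an `l_max = 1`
model invert the fixture through radial fingerprints alone, an artifact
of noiseless synthetic data rather than a property of the task. Under
these conditions the sine/cosine model at `l_max = 2` resolves all three
chi angles below 5 degrees MAE, the parameter-matched `l_max = 1` model
does not, and the direct angle objective trails both — the qualitative
ordering the acceptance suite asserts. These sizes keep the whole
benchmark around ten minutes on one CPU core.

## Known limitations

* Training is plain R; it is adequate for the fixture-scale studies above
  but not for corpus-scale training runs.
* No clash resolution, rotamer library, hydrogen placement, or
  energy-based refinement: predictions are purely regression-based.
* The refinement bootstrap needs an informative initial guess; on
  environments whose rotamers are unpredictable from backbone alone it
  cannot improve on the initial stage (the pipeline tests construct
  exactly this case to pin the upper-bound hierarchy).
* Angular resolution decays with distance from the neighborhood centre —
  an intrinsic property of a single-centre spherical expansion.
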
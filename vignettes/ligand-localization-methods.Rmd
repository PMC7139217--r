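---
title: "Methods: density-guided ligand localization and consensus docking"
author: "cryodock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: density-guided ligand localization and consensus docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryodock)
```

This vignette documents the models, parameters and numerical choices behind
`cryodock`, in the spirit of a methods section: what each stage assumes, which
knobs matter, and what the synthetic validation does and does not demonstrate.

## 1. Density model

All model-to-map scores rest on a simulated density. Each heavy atom is an
isotropic 3-D Gaussian with standard deviation

σ = `sigma_coeff` × resolution,

amplitude proportional to atomic number (or 1 under `weighting = "uniform"`),
truncated at `cutoff`·σ (default 4σ, which retains ≈ 99.9% of the 3-D
Gaussian mass; the test suite checks the integrated density against the
closed-form mass Σ Z·(2πσ²)^{3/2} to within 1%).

* `sigma_coeff` — dimensionless, default **0.356**, a widely used
  simulated-map convention. Different tools use different widths (≈ 0.225
  reproduces another common convention); because printed cross-correlation
  values depend on this choice, every pipeline report echoes the value used,
  and the CLI exposes `--sigma-coeff`.
* `voxel_size` must satisfy the Nyquist bound `voxel ≤ resolution/2`;
  the constructor enforces it.
* Hydrogens are ignored by default: deposited models at ~4 Å carry no
  meaningful hydrogen density.

Assumptions: orthogonal grids, resolution-independent per-atom width (no
B-factor modulation), no electron scattering form factors. These are adequate
for *comparative* scoring of poses in one map; they are not a physical image
model.

## 2. Difference mapping

Two reconstructions of the same specimen never share an amplitude scale.
Before subtraction, the reference map's Fourier amplitudes are multiplied
per radial shell so its rotationally averaged power matches the ligand-bound
map's; phases are untouched. The DC term is always its own shell, so the
whole-spectrum limit of the procedure reduces exactly to global mean/std
matching (a property the tests assert). The default shell width is one
Fourier pixel, 1/(max box length) Å⁻¹ — the finest width that is
non-degenerate on a discrete grid.

The positive part of (A − scaled B) localizes features present only in A.
Peaks are voxels above `mean + threshold_sigma·sd` (statistics over the whole
grid — simple and deterministic; no solvent mask), grouped by 26-connectivity,
filtered to `min_volume` voxels (default 5), sorted by peak maximum with ties
broken by larger volume then lexicographic centroid. Centroids are
density-weighted. The display threshold for such peaks is not standardized;
the default **3σ** is exposed in the configuration and the peak table records
the threshold used.

Caveat: difference density conflates the ligand with receptor regions that
move between the two states (nucleotide-pocket loops, in the motivating
system). That is why peak evidence is *combined* with docking and pocket
evidence rather than trusted alone, and why the synthetic generator can plant
a loop displacement (`conformational_change = TRUE`) to produce exactly this
confounder.

## 3. Pose comparison and clustering

Docking poses share the receptor coordinate frame, so RMSD is computed
**without superposition** — superposing would erase the translation
differences that distinguish binding sites. Chemically equivalent atoms are
handled by minimizing over the automorphisms of the element-colored bond
graph (bonds inferred from covalent radii + 0.45 Å slack); enumeration is
capped at 10,000 mappings, beyond which the fixed-correspondence value is
used with a warning. Symmetry is on by default: redundancy thresholds quoted
for docking output make most sense as chemical, not atom-label, distances.

* **Deduplication** (`threshold` default **2 Å**) is greedy best-score-first:
  matching the convention that each redundancy group is represented by the
  conformation with the best energy score. Scores are compared only within an
  engine; mixed score orientations within one engine are an error.
  Guarantees (tested exhaustively): no two representatives within the
  threshold; every pose within the threshold of its representative.
* **Centroid clustering** for site discovery is single-linkage with cutoff
  `link_threshold` (default **5 Å**, chosen as roughly one ligand diameter —
  site-scale, not conformation-scale).
* **Consensus**: a pose is retained iff every other engine contains a pose
  within the threshold; the union is deduplicated in a canonical,
  label-independent order (pose id, then centroid), which makes the result
  invariant to engine relabeling. Engines' scores are never compared across
  engines.

## 4. Two-stage density-constrained selection

`run_protocol()` chains: difference map → peak detection → blind-run merging
(2 Å dedup) → centroid clustering → site identification → cross-engine
consensus → CCC ranking; optionally a second focused-docking round restricted
to a tight site radius.

* Site evidence items (pocket centers, dock-cluster centroids, difference
  peaks) are linked when within `match_radius` (default **5 Å**, consistent
  with the site scale above); a site supported by all three kinds is a
  consensus site and ranks first, then by difference-peak maximum.
* Stage radii default to **12 Å** (stage 1) and **6 Å** (stage 2), the
  focused- and tight-docking radii of the protocol the pipeline reproduces.
* Pose scoring: Pearson CCC against the full map and against the positive
  difference map over the *same* proximity mask (voxels within
  max(2.5 Å, resolution/2) of any pose atom; masks under 30 voxels are
  flagged unreliable). The selected pose maximizes the average of the two —
  the full map is better determined, the difference map is ligand-specific;
  averaging balances them. Ties break by higher full-map CCC, then pose id.
* Degenerate inputs are handled explicitly rather than fatally: an empty
  cross-engine consensus falls back to ranking per-engine representatives
  (flagged in the report); an empty site restriction is relaxed (flagged);
  missing stage-2 files yield a report marked "stage-1 only".
* The pipeline is deterministic given its inputs: nothing in it draws random
  numbers, and reports are byte-identical across repeated runs.

The intermediate refinement steps of the original protocol (rigid fitting,
flexible fitting, sidechain minimization) are *exchange points*, not
computations: the pipeline reads and writes standard PDB/MRC files so
external tools can be interposed between stages.

## 5. Local fit profiles (SMOC)

The per-residue statistic is the Manders overlap coefficient (uncentered
correlation) between experimental and simulated density over the residue's
proximity mask. The profile value at residue *i* is the triangularly weighted
mean of these statistics over a window of `window` residues (default **9**,
truncated at chain ends).

Two design points deserve explanation, because we measured the alternatives:

* *Why Manders, not Pearson, per residue?* A residue displaced into empty
  density has near-zero experimental values under its mask; Pearson, being
  location/scale invariant, can still correlate spuriously with the faint
  tails of distant features, whereas the unnormalized-mean Manders overlap
  collapses toward zero. On synthetic helices, per-residue Pearson placed the
  minimum on a *neighbor* of a 10 Å-displaced residue (the "hole" the residue
  leaves behind degrades the spatially adjacent residues of the next helix
  turn); Manders places it on the displaced residue itself.
* *Why a triangular window, not a pooled window mask?* Computing one
  correlation over the pooled mask of all nine window residues gives every
  window containing the bad residue nearly the same value — a flat-bottomed
  dip whose minimum lands anywhere within ±4 residues. A centered, linearly
  decaying kernel keeps the dip minimum at the misfit residue while still
  averaging noise (window 9 reduces profile variance several-fold relative to
  window 1 on uniform-quality maps; tested). The pooled variant remains
  available as `method = "window-mask"`, and Pearson as `stat = "pearson"`.

Only residue *order* matters: profiles are invariant to renumbering offsets.

## 6. Kinetics

`fit_michaelis_menten()` fits v = Vmax·S/(K+S); `fit_ic50()` fits the
three-parameter inhibition curve y = a/(1+(x/b)^c), whose value at x = b is
a/2 by construction. Both use Levenberg–Marquardt least squares
(`minpack.lm`) with deterministic initialization: Vmax₀ (or a₀) from the
response extremum and K₀ (or b₀) from the half-maximal crossing by linear
interpolation; c₀ = 1. Zero concentrations are legitimate on the linear axis
(the model value at 0 is a for c > 0). Fits are unweighted by default —
titration curves are typically fitted to replicate means — with optional
per-point weights. Noise-free data is recovered to ≤ 1e-6 relative error and
the fits are exactly scale-equivariant in concentration (both tested). All
three IC50 parameters are left free; constraining a or c is the caller's
choice via pre-scaling, not a hidden default.

## 7. What the synthetic generator emulates — and what it does not

`make_scene()` builds an abstract receptor (two 30-residue idealized helices,
4 pseudo-backbone atoms per residue, axes 13 Å apart forming a cleft) and
plants a rigid, point-symmetric biaryl-like fragment (19 heavy atoms: two
aza-aryl rings, a CF₂ bridge, fluorine caps, ring methyls) at the cleft
center. Symmetry about the bridge carbon puts the fragment's centroid at its
density maximum, making "peak within one voxel of the planted centroid" a
well-posed construction invariant. Two maps are simulated on one grid —
receptor+ligand, and receptor only (optionally with a 4-residue loop
displaced ~2 Å, to emulate state-dependent conformational differences) — and
independent Gaussian voxel noise is added, quoted as a fraction of the
noise-free ligand peak height (a single interpretable SNR knob).

`make_engine_outputs()` emulates per-engine scored pose sets: one near-native
pose per engine (0.2–0.8 Å from truth), decoys as uniform rigid transforms
rejection-sampled into the requested RMSD band (default 5–20 Å), a fraction
of decoys shared across engines with sub-Å jitter (spurious consensus), and
scores drawn so the near-native pose is *never* an engine's best — score
alone cannot recover the truth; the density constraint must. Engine
orientation conventions are preserved (lower-better for the Vina-like engine,
higher-better fitness otherwise).

Default study conditions (also used by the acceptance script): 4 Å
resolution, 1 Å voxels, 10% noise, 3 engines × 20 poses, 20 independent
seeds; kinetics at 8 points per titration, 5% multiplicative noise, 200
replicates, around Vmax = 1.22 ATP/s, K½ = 13.5 nM, IC50 = 0.8 nM (ATPase)
and 1.8 nM (gliding). These sizes keep the full validation suite to a couple
of minutes on one core while leaving each statistical check comfortably
powered.

What passing these tests shows: the machinery is internally correct
(oracle-verified CCC, RMSD, dedup and consensus), the difference map
localizes a planted ligand to within a voxel, and the end-to-end protocol
recovers a planted pose despite misleading scores and planted false
consensus. What it does **not** show: performance on real reconstructions —
the generator has no CTF, no projection geometry, no local resolution
variation, no solvent or lattice background, an idealized rigid ligand, and a
receptor far smaller than a decorated microtubule. Real-data use still
requires visual inspection of the difference density and judgment about
receptor conformational changes masquerading as ligand density.

## 8. Numerical details and edge cases

* MRC I/O: little-endian mode-2 written; modes 0/1/2 read, big-endian
  detected; non-orthogonal cells rejected; axis order normalized from
  MAPC/MAPR/MAPS; origin = ORIGIN record if nonzero else nstart × voxel.
  Truncated files fail before any partial map is returned.
* Empty Fourier shells scale by 1 (nothing to rescale); a zero-variance map
  yields no peaks rather than NaNs.
* Trilinear resampling clamps the exact upper grid boundary into the last
  cell; voxels outside the source map become 0.
* Alternate locations: highest occupancy wins, first-in-file on ties.
  Element fallback from atom names accepts two-letter symbols only where
  they cannot collide with protein naming (so "CA" is carbon-alpha).
* Greedy dedup assigns each pose to its *nearest* qualifying representative;
  with strictly ordered scores the result is input-order independent (ties
  break by pose id).
* All generators are pure functions of (parameters, seed) and restore the
  caller's RNG state.

## 9. Known limitations

* Global CCC over a whole map is dominated by the receptor; the package
  deliberately defaults to local proximity masks, so its numbers are not
  comparable to whole-map CCCs from other tools without choosing
  `mask_mode = "whole-map"`.
* Amplitude scaling assumes comparable rotational power spectra; maps from
  different instruments or processing pipelines may need external
  sharpening/filtering first.
* Bond inference by distance can mis-bond unusual geometries; symmetry RMSD
  then falls back conservatively (the automorphism cap warns).
* The Hill fit's parameters are jointly weakly determined when the titration
  does not bracket the midpoint; the fitter reports standard errors and R²
  so such fits are recognizable.
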
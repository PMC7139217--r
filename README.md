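# cryodock

Density-guided localization and modelling of small-molecule ligands in
cryo-EM reconstructions, in R.

## The problem

A ligand bound to a protein complex at moderate resolution (3.5–4.5 Å) rarely
produces density that can be interpreted on its own: the ligand occupies a
handful of voxels at the rim of a much larger protein, and docking engines
happily propose dozens of plausible poses, many of them in the wrong place.
The motivating use case is an allosteric kinesin-5 (Eg5/KIF11) inhibitor that
traps the motor domain on the microtubule: the inhibitor site had to be
located and the ligand modelled against a ~4 Å reconstruction, with docking
engines disagreeing among themselves.

`cryodock` implements the analysis that resolves this, as a tested,
self-contained pipeline:

1. **Difference mapping.** Two reconstructions of the same specimen — one
   with the ligand, a reference without — are amplitude-matched per Fourier
   shell and subtracted. Positive difference density localizes what the first
   map contains and the second does not (the ligand, plus any receptor
   regions that moved). Peaks are extracted by thresholding at
   `mean + kσ` and 26-connected component labelling.
2. **Site consensus.** Candidate binding sites are accepted where three
   independent lines of evidence coincide within a matching radius: pocket
   predictions, centroid clusters of merged blind-docking poses (redundant
   conformations grouped at ≤ 2 Å RMSD, each group represented by its
   best-scored member), and difference-density peaks.
3. **Consensus docking with density constraints.** Poses from several scoring
   engines are compared by in-frame, symmetry-aware heavy-atom RMSD; only
   conformations reproduced by every engine (≤ 2 Å) survive. Each survivor
   is then scored by the cross-correlation coefficient

   CCC = corr( ρ_exp , ρ_sim ) over voxels within max(2.5 Å, d/2) of the pose,

   against both the full map and the positive difference map, and the pose
   with the highest average of the two is selected. An optional second,
   focused docking stage repeats consensus + selection within a tight 6 Å
   site radius.

Local model quality is graded with a per-residue SMOC profile (sliding-window
segment overlap of experimental vs model-simulated density), and the package
also fits the kinetics used to characterize inhibition: Michaelis–Menten
activation `v = Vmax·S/(K + S)` and the three-parameter Hill inhibition curve
`y = a / (1 + (x/b)^c)` (a = uninhibited level, b = IC50, c = Hill
coefficient).

Everything is testable offline: a seeded generator builds synthetic scenes
(an abstract two-helix receptor with a planted biaryl-like ligand, paired
noisy maps, and emulated engine outputs whose scores deliberately do *not*
rank the near-native pose first — density has to do the work).

## Worked example

```r
library(cryodock)

scene   <- make_scene(resolution = 4, voxel = 1, noise_sigma = 0.1, seed = 42)
engines <- make_engine_outputs(scene, n_engines = 3, n_poses = 20,
                               decoy_range = c(5, 20), seed = 43)
cfg     <- pipeline_config(resolution = 4)
report  <- run_protocol(cfg, scene$map_with, scene$map_without,
                        engines$pose_sets)
report
#> cryodock run_report (stage-1 only)
#>   difference peaks: 1 | site candidates: 1
#>   unique blind conformations: 54 | stage-1 consensus: 3
#>   final pose: chemscore_p09 (chemscore), avg CCC 0.860 (full 0.878, diff 0.842)

pose_rmsd(scene$true_pose, report$final_pose)
#> [1] 0.3521023  # well within 2 A of the planted truth
```

Reading the report: one positive difference peak was found (the planted
ligand), it coincided with a blind-dock centroid cluster, 60 emulated poses
collapsed to 54 unique conformations, 3 of them were reproduced by all three
engines, and the density-constrained selection picked the near-native pose —
which no engine had ranked first by score.

Kinetics, on synthetic titrations around the measured constants of the
motivating system (Vmax 1.22 ATP/s, K½ 13.5 nM, ATPase IC50 0.8 nM):

```r
tab <- make_titration("mm", list(vmax = 1.22, k = 13.5), n_points = 8,
                      noise_sigma = 0.05, seed = 1)
fit_michaelis_menten(tab$conc, tab$response)
#> Michaelis-Menten fit: Vmax = 1.253 +/- 0.05, K1/2 = 14.26 +/- 2.2 (RSS 0.00867)

ti <- make_titration("ic50", list(a = 100, b = 0.8, c = 1), n_points = 8,
                     noise_sigma = 0.05, seed = 1)
fit_ic50(ti$conc, ti$response)
#> IC50 fit y = a/(1+(x/b)^c): a = 96.79, IC50 = 0.9426, Hill c = 1.09 (R^2 = 0.9974)
```

## Command line

A thin launcher is installed at `inst/cli/cryodock` (all logic is in the
package; `cryodock::run_cli()` is the same entry point):

```sh
cryodock synth scene --seed 1 --out demo/       # maps, poses, pockets, run.yaml
cryodock pipeline --config demo/run.yaml        # JSON report + ranked poses
cryodock diffmap --map-a with.mrc --map-b without.mrc \
         --out diff.mrc --positive-out pos.mrc
cryodock score --map with.mrc --diff pos.mrc --poses poses.pdb \
         --resolution 3.8 --out scores.tsv
cryodock smoc --model fit.pdb --map full.mrc --resolution 3.8 --out smoc.tsv
cryodock kinetics-fit --mode ic50 --table titration.csv
```

Subcommands exit 0 on success, 2 on usage errors, 1 otherwise, and reports
are byte-identical across repeated identical invocations.

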
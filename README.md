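# iirbssfp

Simulation, segmentation and multi-parametric mapping for brain MRI acquired
with **balanced steady-state free precession during incomplete inversion
recovery (IIR-bSSFP)** — a contrast-agent-free protocol for brain-tumor
imaging.

In IIR-bSSFP a bSSFP readout runs continuously while adiabatic inversion
pulses are replayed every few seconds. Because the inversion interval
T<sub>inv</sub> is shorter than full T₁ recovery, the magnetization reaches a
*periodic* steady state, and the signal evolution sampled along each cycle
jointly encodes T₁, T₂ and magnetization-transfer information. This package
provides the full computational chain for working with such data:

* **Signal model** — single-pool Bloch (`simulate_single_pool()`) and
  two-pool Bloch–McConnell (`simulate_two_pool()`) simulation of the periodic
  steady state, with closed-form cross-checks: the late-cycle echo against
  the bSSFP steady state
  M₀ sin α / [(T₁/T₂ + 1) − cos α (T₁/T₂ − 1)], and the transient against the
  apparent rate 1/T₁\* = cos²(α/2)/T₁ + sin²(α/2)/T₂.
* **Protocol optimization** — `sweep_surfaces()` / `optimal_fa()` map signal
  amplitude and inter-tissue contrast over flip angle and T<sub>inv</sub>.
* **Segmentation** — `hierarchical_segment()` clusters L2-normalized voxel
  signal evolutions (bias-field invariant by construction) with sequential
  spherical k-means into 3 → 6 → 10 segments, then merges them into white
  matter, grey matter, CSF and three glioma lesion compartments, plus
  context-based necrosis relabelling.
* **Mapping** — `build_dictionary()` / `map_volume()` produce simultaneous
  T₁, T₂ and macromolecular-fraction (MF) maps by maximum-inner-product
  matching against simulated two-pool atoms.
* **Phantom & evaluation** — `build_phantom()` renders seeded synthetic
  brain-tumor volumes with voxel-wise ground truth; `dice()`,
  `label_dice()` and `compare_volumes()` quantify agreement. A CLI
  (`inst/exec/iirbssfp`) chains all stages.

The intended audience is MRI methods researchers: the package is a reference
implementation and validation testbed for the method, not a clinical tool.

## Worked example

Simulate a white-matter-like voxel (10 % macromolecular pool) over one
3-second inversion cycle, build a small dictionary, and match the curve
back:

```r
library(iirbssfp)

# sequence: 30 deg flip, TR 4 ms, inversions every 3 s, 20 frames
sq <- seq_params(flip_angle_deg = 30, tr_ms = 4, tinv_ms = 3000)

# a small T1/T2/MF dictionary
dict <- build_dictionary(
  param_grid(geom_seq(600, 1200, 1.06), geom_seq(20, 60, 1.06),
             seq(0, 0.2, by = 0.02)), sq)
nrow(dict$atoms)
#> [1] 2860

# simulate a white-matter-like voxel at one of the grid points ...
wm <- two_pool_tissue(t1f_ms = 848.53, t2f_ms = 28.29, mf = 0.10)
curve <- frame_average(simulate_two_pool(wm, sq), sq$n_frames, sq$tinv_ms)
round(curve$values[1:5], 4)
#> [1] 0.0303 0.0147 0.0387 0.0524 0.0601

# ... and match it back
match_curve(curve$values, dict)
#>     t1_ms     t2_ms        mf   quality
#> 848.52814  28.29436   0.10000   1.00000
```

The magnitude curve dips near its T₁\*-dependent zero crossing and recovers
toward the bSSFP steady state; matching the noiseless curve recovers the
grid point exactly with unit match quality. (Off-grid or noisy curves land
in a T₁/T₂ degeneracy valley — see the vignette's discussion of
identifiability at finite SNR.)

A full synthetic study from the command line:

```sh
iirbssfp phantom  --out ph --size 64 --seed 1
iirbssfp segment  --series ph/series.nii.gz --out seg --seed 0
iirbssfp dict-build --out dict --step 1.12 --mf-step 0.02
iirbssfp map      --series ph/series.nii.gz --dict dict --out maps
iirbssfp evaluate --labels-a seg/labels.nii.gz --labels-b ph/labels.nii.gz \
                  --voxel 2 --out report.json
```

## Documentation

The methods vignette (`vignettes/iirbssfp-methods.Rmd`) documents the signal
model and its assumptions, every model constant with units and rationale,
the segmentation and merge-rule design, the phantom's construction and what
validation on it does and does not demonstrate, and the known
identifiability limits of per-voxel dictionary matching at finite SNR.

## License

MIT (see `LICENSE`).
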
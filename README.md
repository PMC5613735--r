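# histovol

Reconstruct a registered, classified 3D voxel volume from serial 2D
fluorescence histology sections.

histovol is for anyone mapping the spatial distribution of a
fluorescently labelled cell population across an organ from serial
cryosections — e.g. red-fluorescent (tdTomato) reporter-positive
cardiomyocytes across a mouse heart imaged one coronal section at a
time. The sections arrive as independently imaged, slightly misaligned
8-bit RGB images (JPEG or TIFF); the output is a single 3D volume of
voxel classes — **positive** (stained), **negative** (tissue without
staining), **background** (non-tissue) — written as a legacy ASCII VTK
structured-points file that opens directly in Paraview.

## The method

For sections k = 1..n with manually chosen corresponding landmarks:

1. **Auto-contrast** — per-image joint-channel linear stretch of the
   saturation-clipped range to [0, 255].
2. **Marking + grayscale** — luma conversion
   (0.299 R + 0.587 G + 0.114 B); pixels with red ≥ threshold (default
   25, per-slice overrides supported) get +100, lifting positive regions
   above the tissue band.
3. **Gaussian smooth + down-sample** — normalized kernel, reflective
   boundary, decimation by an integer factor.
4. **Rigid registration** — per-slice least-squares rotation+translation
   from matched landmarks (closed form: centroids, 2×2 cross-covariance
   H = UΣVᵀ, R = V diag(1, det(VUᵀ)) Uᵀ, t = f̄ − R m̄; reflections
   excluded), chained slice-to-slice toward a reference slice;
   nearest-neighbour resampling.
5. **Classification** — intensity > 80 positive, 3–80 negative, < 3
   background.
6. **Damaged-slice repair** — nearest non-damaged slice donates labels
   to non-positive voxels.
7. **Region growing** — 6- or 26-connected growth from a seed through
   tissue voxels; unreached tissue (extra-organ speckle) becomes
   background.
8. **XY majority down-sampling** (ties favour signal) and **legacy VTK
   structured-points output** (x fastest; default scalar map 0/100/200).

A synthetic-stack generator (`generate_stack()`) produces misaligned,
noisy stacks of an elliptical organ silhouette with bright-red positive
clusters, damaged slices, speckle, analytic landmarks — and exact ground
truth (applied transforms, per-voxel labels, positive fraction) — so the
entire pipeline is testable without any imaging data.

## Worked example

```r
library(histovol)

# synthesize a 128 x 128 x 12 stack with one damaged slice, write it out
spec <- stack_spec(n_slices = 12, width = 128, height = 128, seed = 42,
                   damaged_slices = 6)
g <- generate_stack(spec)
write_fixture(g, "demo_stack")

yaml::write_yaml(list(manifest = "manifest.tsv", landmarks_dir = "landmarks",
                      output_vtk = "heart.vtk"),
                 "demo_stack/pipeline.yaml")
rep <- run_pipeline("demo_stack/pipeline.yaml")
#> ...
#> [align_stack] done in 0.03s
#> [classify_volume] done in 0.01s
#> [interpolate_damaged] done in 0.00s
#> [region_grow] removed 126 extra-organ voxels
#> pipeline finished in 0.3s; volume 64x64x12 -> demo_stack/heart.vtk

g$truth$positive_fraction   # ground truth: 0.0842
rep$positive_fraction       # recovered:    0.0854

head(rep$registration, 3)
#>   slice theta_deg         tx        ty          rms
#> 1     0 -1.069306 -7.2289118 10.611154 1.857164e-13
#> 2     1 -1.202923  3.5074561  3.492041 1.995864e-13
#> 3     2  2.702693  0.1197606  5.584769 2.719277e-13
```

The registration table reports, per slice, the fitted rotation (degrees),
translation (pixels) and RMS landmark residual after alignment — here
~1e-13 px because the synthetic landmarks are exact. The recovered
positive fraction (share of tissue voxels classified positive, 0.0854)
matches the generator's ground truth (0.0842) to ~1.4% relative. The
final volume is 64×64×12 after the default 2× XY down-sampling; the
report is also written as YAML next to the VTK file, with the
registration table as TSV.

A thin command-line wrapper ships in `inst/cli/`:

```sh
Rscript inst/cli/histovol.R synth --out demo_stack --seed 42 --damaged 6
Rscript inst/cli/histovol.R run --config demo_stack/pipeline.yaml
```

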
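# arbordepth

Automated laminar arbor-density depth profiles of sparsely labeled neurons.

The depth at which a retinal ganglion cell's dendrites stratify within the
inner plexiform layer is a reliable signature of its type, but measuring it
classically requires tracing the arbor by hand. `arbordepth` computes the
same signature fully automatically from a two-channel confocal stack (neuron
channel + ChAT/starburst channel):

1. **Volumetric reconstruction.** Either *topologically constrained
   inflation* of a skeleton trace — the trace grows into voxels at ≥ 60 % of
   the stack's maximum brightness, flipping only *simple points* under the
   (26, 6) adjacency pair, so the result is homotopy-equivalent to the trace
   (62 growth rounds absorb a `(2·62+1)·0.4 = 50 µm` soma diameter) — or,
   with no trace, enhancement (convolutional network forward pass, or the
   60 %-threshold baseline) followed by morphological post-processing that
   keeps the largest component, drops small objects and removes somata.
2. **Laminar registration.** The two starburst dendrite sheets are detected
   as fiducial surfaces, flattened by least-squares conformal maps,
   registered at their flattest patch, and the mapping is extended to every
   voxel by local polynomial models (quadratic in-plane, linear axially).
   Depth is normalized so the On surface sits at 0 µm and the Off surface at
   12 µm.
3. **Depth profiles and statistics.** Voxel depths (with volume-compensation
   weights) are gridded onto 0.5 µm bins with a Kaiser-Bessel kernel. Per
   cell: stratification peak(s) (second peak ≥ 6 µm away for bistratified
   cells), crest factor (peak / RMS). Per type: peak mean ± SD with exact
   chi-squared confidence intervals for σ, Brown-Forsythe variance
   comparison, profile SNR, and an exact small-n signed-rank test.

A phantom generator (`make_phantom()`) renders warped laminae, stratified
arbors, somata, distractors, blur and shot noise with known ground truth, so
the entire pipeline runs and is tested with no external data.

## Worked example

```r
library(arbordepth)

# a bistratified BDa-like phantom: arbors at 0.3 and 12.3 um, warped laminae
ph  <- make_phantom(phantom_spec("BDa", seed = 2))
res <- arbor_depth_profile(ph$neuron, ph$chat, bistratified = TRUE)

res$volume
#> <binary_volume 256 x 256 x 120, 5213 foreground voxels>
res$profile
#> <depth_profile 91 bins [-20, 25] um, total mass 2.451, unit norm>
sprintf("peaks: %.1f and %.1f um", res$peaks$peak1, res$peaks$peak2)
#> "peaks: 0.5 and 12.5 um"
ph$truth$spec$target_depths + ph$truth$cell_offsets   # this cell's true depths
#> 0.35 12.70
crest_factor(res$profile)
#> 6.58
```

Both stratification peaks land within one 0.5 µm bin of this cell's true
depths; the crest factor says the profile is sharply peaked. For a cohort,
`type_summary()` tabulates peak mean ± SD, crest factor and SNR per type,
and `sigma_ci(s, n)` gives the exact interval for the stratification
precision, e.g. `sigma_ci(0.23, 15)` → `[0.168, 0.363]` µm.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/arbordepth.R simulate --type W3 --seed 7 --out-dir phantom/
Rscript inst/cli/arbordepth.R run-all --out-dir run/ --seed 7
```

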
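---
title: "Laminar arbor-density profiles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar arbor-density profiles: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arbordepth)
```

## The problem

The depth at which a retinal neuron's dendrites stratify within the inner
plexiform layer (IPL) is a strong correlate of its molecular and functional
type. Measuring it precisely from light microscopy normally requires tracing
the arbor by hand - the bottleneck of structural cell typing. `arbordepth`
implements a fully automated alternative: reconstruct the neuron's *volume*
rather than its skeleton, register every stack to a common laminar coordinate
using the two starburst amacrine (ChAT) dendrite sheets as fiducial surfaces,
and summarize each cell as a one-dimensional *depth profile* - the
distribution of its arbor mass along the laminar axis. Profiles of cells of
one type cluster tightly around a type-specific stratification peak, so the
profile is a usable proxy for identity without any tracing.

Conventions used everywhere: arrays are indexed `(x, y, z)` with `z` the
laminar axis; after registration the On starburst surface sits at depth
0 um and the Off surface at 12 um; the ganglion-cell side is negative.

## Topology-preserving inflation

When a trace *is* available, it is turned into a volume by *topologically
constrained inflation*: the rasterized skeleton grows outward into the bright
voxels of the raw stack (intensity at or above 60% of the stack maximum), one
6-neighbourhood voxel layer per round, flipping a voxel only when it is a
*simple point* - a voxel whose flip does not change the number of objects,
tunnels or cavities of the digital image under the (26-foreground,
6-background) adjacency pair. The result is geometrically faithful to the
image but homotopy-equivalent to the trace: a tree stays a tree.

Two numerical choices matter here.

* **Live versus snapshot tests.** The procedure's inner loop nominally reads
  3x3x3 patches from a copy of the volume taken at the start of a round while
  flipping voxels in the live volume. Evaluated that way, two candidates can
  each look simple against the stale copy yet jointly change topology.
  `inflate_trace()` therefore evaluates every simple-point test against the
  live, partially updated volume - the only order for which sequential flips
  provably preserve topology - and keeps the literal snapshot variant behind
  `stale_copy = TRUE` for comparison.
* **What 62 rounds guarantee.** Growth uses the 6-neighbourhood, so each
  round advances one voxel along each *axis*; 62 rounds at 0.4 um pitch reach
  `(2 * 62 + 1) * 0.4 = 50` um across a diameter through the seed, which is
  what `max_absorbable_diameter()` computes. Voxels along body diagonals need
  up to sqrt(3) times more rounds, so the guarantee concerns axis-aligned
  extent, not every voxel of a Euclidean ball; the tests cover exactly that
  reading with a simulated growth cross-check.

The topology oracle, `topology_summary()`, computes components (26-connected
foreground), fully enclosed cavities (6-connected background) and the Euler
characteristic from the cell counts of the union of closed unit cubes, whose
connectivity realizes the same (26, 6) pair. Components, cavities and Euler
number together pin down all three Betti numbers, so "identical summaries"
is a complete topology-preservation check.

## Enhancement

The automated path replaces tracing by image enhancement. The package ships
the stock 8-layer convolutional architecture (filter sizes 5x5x1, 5x5x1,
3x3x3, 5x5x1, 3x3x3, 3x3x3, 1x1x1, 1x1x1; 8 feature maps per hidden layer
except a fully connected layer of 100 units, realized as a 1x1x1 convolution
so inference stays convolutional) with a forward pass and a receptive-field
calculator: `1 + sum(filter - 1)` per axis, 19 x 19 x 7 voxels for the stock
spec. Training is out of scope - the module loads external weights - and the
pipeline's default enhancement is the 60%-of-maximum threshold baseline,
which exercises every downstream stage identically. Border handling (the
architecture's original is unspecified) is mirror padding, chosen so the
output grid equals the input grid.

## Post-processing

`postprocess()` isolates the neuron of interest: min-max normalization;
binarize at 0.7 and dilate by a small ball to bridge gaps; keep only the
intensity under the largest 26-connected dilated component; re-binarize at
0.5; drop objects under 500 voxels; and remove somata by subtracting
`dilate(open(mask, ball(r)), ball(r))` - every region that fully encloses a
ball of radius `r` voxels, plus a guard margin.

The soma search radius deserves a note. Kernel radii count *voxels*, so at
0.4 x 0.4 x 0.5 um pitch a ball of radius `r` spans `0.8 r` um in-plane but
`r` um axially. A 12 um ganglion soma, further eroded by blur and
thresholding, has an axial half-extent of only ~10 slices, so radii of 10 or
more fail to fit and leave somata in place. The shipped default is 8 voxels
(a 3.2 x 3.2 x 4 um ball): comfortably inside any soma-sized lump, far above
dendrite calibre (<= 3 um). Equal-size component ties are broken toward the
component with the smallest linear voxel index, for determinism.

## Laminar registration

The two ChAT sheets are detected per image column as the two strongest
intensity peaks along `z` of the Gaussian-smoothed fiducial channel (sigma
1 voxel; sub-voxel parabolic refinement; peaks at least 3 um apart). Columns
whose height deviates from a 5x5 median-filtered height map by more than 3
median absolute deviations are discarded and refilled by harmonic
interpolation. Detection fails loudly if fewer than half the columns show two
peaks. The detection procedure itself is this package's design; the test
suite requires it to recover phantom lamina heights (4 um warps, realistic
noise) to better than 0.5 um RMS.

Each surface is then flattened by a least-squares conformal map on a
triangulated, downsampled height map (<= 10^4 vertices keeps the sparse
normal equations comfortably small). The gauge is fixed by pinning two
opposite corner vertices at their 3-D separation and orienting so planar
areas are positive; planar inputs reproduce a rigid motion to solver
precision, and wavy laminae flatten with < 5 degrees of angle distortion and
no fold-overs. The two flattened maps are registered in-plane at the centre
of the flattest window (32 x 32 um, stride half a window; flatness = summed
height variance over both surfaces; ties toward the smallest `(x, y)`).

The surface mapping is extended to all voxels by local weighted
least-squares polynomial models - quadratic in-plane, linear axially
(monomials `1, x, y, x^2, xy, y^2, z, xz, yz`) - fitted componentwise to the
surface correspondence points within 25 um of each control column (Gaussian
weights, sigma half the radius), evaluated on a 3.2 um control lattice and
interpolated between columns. Depth is per-column affine: 0 um at the On
surface, 12 um at the Off surface, linear extrapolation beyond. Each voxel
carries a volume-compensation weight, the absolute Jacobian determinant of
`(u, v, depth)` with respect to `(x, y, z)` by central differences; in the
identity case (flat parallel surfaces 12 um apart) weights are 1 to 1e-6.

## Profiles and statistics

Warped voxel depths are gridded onto 0.5 um bins over [-20, 25] um with a
Kaiser-Bessel kernel (width 3 bins, beta 6 - values in the accuracy regime of
the gridding literature; both configurable), normalized per sample so total
mass is conserved exactly. Profiles are unit-Euclidean-norm normalized; that
convention matches the Euclidean-norm SNR definition, and peak positions and
crest factors are scale invariant, so only the SNR depends on it.

* **Peaks.** `find_peaks()` takes the argmax bin (ties toward the smaller
  depth); for bistratified cells the second peak is the best bin at least
  6 um away (half the inter-surface distance). For the threshold path,
  profiles are truncated below -6 um first, because spurious bright material
  near the ganglion-cell layer otherwise manufactures peaks.
* **Crest factor.** Peak over RMS. The RMS denominator is the definition
  adopted; a mean-value denominator appears in an alternative phrasing of the
  same quantity and is available via `denominator = "mean"`.
* **Variance inference.** `sigma_ci()` is the exact chi-squared interval for
  a normal standard deviation; `brown_forsythe()` is the one-way ANOVA F on
  absolute deviations from group medians; `signed_rank_right_p()` enumerates
  all `2^n` sign assignments for an exact small-n right-tailed signed-rank
  test (zero differences are refused rather than silently dropped).

## The phantom generator

`make_phantom()` renders everything the pipeline consumes, with known ground
truth: two laminae 12 um apart following a smooth sum-of-sinusoids tissue
warp (amplitude 4 um, wavelengths 100/80 um by default); a branching arbor
grown at the type's target depth (JAMB 15.6 um, W3 5.5 um, BDa 0.3 and
12.3 um) as tapered tubes (1.5 -> 0.3 um radius); a 12 um soma on the
ganglion side (depth -6 um); Gaussian optical blur (0.3, 0.3, 0.6 um);
Poisson shot noise plus 2% Gaussian read noise, saturating at 1.2x the
nominal peak as a detector would.

The 0.25 um "laminar jitter" is implemented as a *per-cell* depth offset
drawn once per stratum: that is the quantity whose across-cell standard
deviation the stratification-precision analysis estimates. A separate,
smaller per-node roughness (0.1 um) emulates within-arbor waviness without
moving the peak. The growth model itself (branching probability 0.05 per
1 um step, in-plane persistence 0.8, ~350 nodes per stratum within a 45 um
radius) is deliberately the simplest model with controllable stratification;
only the depth statistics matter downstream.

What phantoms do *not* emulate: real point-spread functions (the blur is
Gaussian), inhomogeneous labeling, overlapping arbors of multiple neurons,
and tissue-specific background. Passing tests therefore demonstrate that the
geometry, topology and statistics of the pipeline are correct under
controlled conditions - not that the enhancement baseline suffices for
arbitrary real stacks, which is precisely why the trained-network path
exists.

## Problem sizes and defaults

The default phantom is 256 x 256 x 120 voxels at 0.4 x 0.4 x 0.5 um
(~7.9 M voxels, a realistic single-cell field of view); one full automated
pass takes roughly 20 s on one CPU core. The end-to-end recovery study in
the acceptance tests runs 10 phantoms per type (seeds 0-9) for each of the
three types and requires every recovered peak within one bin (0.5 um) of
that cell's true depth. Inflation and simple-point properties are exercised
on small volumes (26^3, 50 random trees, 10^5 random neighbourhoods) where
the brute-force global-topology oracle is affordable.

## Known limitations

* Separating overlapping arbors of distinct neurons is out of scope; the
  post-processing assumes one neuron of interest dominates.
* The threshold enhancement path is a baseline: on dim or dense tissue it
  will under-segment, and only the -6 um truncation protects its peaks.
* Network training is not provided; weights must come from elsewhere.
* Depth registration is shared across stacks only through the On/Off
  convention (0/12 um); no in-plane registration across stacks is attempted.
* In-plane coordinates `(u, v)` inherit the global scale of the conformal
  gauge fixing; they are internally consistent per stack but not calibrated
  across stacks.
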
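---
title: "Virtual staining of 3D liver microstructure: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual staining of 3D liver microstructure: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Digital reconstruction of liver tissue requires simultaneously imaging
several structures — the cortical actin mesh that outlines hepatocytes, the
bile-canaliculi (BC) network that drains bile between them, the sinusoidal
capillaries, and resident macrophages (Kupffer cells). Antibody markers for
most of these penetrate fixed tissue poorly: their signal collapses beyond
roughly 80 µm of depth. The small molecule phalloidin, which stains the
actin mesh, penetrates hundreds of micrometres. `tissuegan` implements
virtual staining: predicting the channels that cannot be imaged from the
single actin-mesh channel that can, using unpaired image-to-image
translation, and then quantifying the predicted structures.

## The model

Two generators and two discriminators are trained jointly. Generator
$G_{AB}$ maps an actin-mesh image (domain $A$) to a synthetic target-channel
image (domain $B$); $G_{BA}$ maps back. Discriminators $D_A$ and $D_B$
score images of their domain as real or generated, with a patch-wise
(score-map) architecture. Training uses least-squares adversarial
objectives,

$$\mathcal{L}_{D} = \mathbb{E}\,(D(\text{real})-1)^2 + \mathbb{E}\,D(\text{fake})^2,
\qquad
\mathcal{L}_{G}^{adv} = \mathbb{E}\,(D(\text{fake})-1)^2,$$

plus a cycle-consistency reconstruction term comparing $x$ with
$G_{BA}(G_{AB}(x))$ (and symmetrically). Two variants are provided:

* **plain**: the cycle term is the mean squared error over the whole image;
* **Otsu-weighted** (the "+" variant): the original image is split into
  background and foreground by Otsu thresholding, the MSE is computed
  independently over the two regions, and the loss is
  $w_{bg}\,\mathrm{MSE}_{bg} + w_{fg}\,\mathrm{MSE}_{fg}$ with default
  weights 0.2 and 0.8. Because the structures of interest occupy a small
  voxel fraction, this weighting prevents the abundant background from
  dominating the reconstruction term.

The generator architecture is described by a compact token grammar
(`c7s1-k`, `dk`, `Rk (xm)`, `uk`) and the discriminator by `Ck ... F1`;
`parse_arch_spec()` expands these to layer sequences, and the 3D variants
swap every 2D convolution for its 3D counterpart, leaving the layer
sequence otherwise identical. The reference layouts are
`c7s1-64, d128, d256, R256 (x6), u128, u64, c7s1-1` for 128-pixel patches
(nine residual blocks for 256-pixel patches) and
`C64, C128, C256, C512, F1` for the discriminators.

A supervised baseline (`train_paired()`, a UNet with skip connections)
regresses the target channel from registered input patches with the same
optimizer settings; it requires spatially registered pairs, which is
exactly the constraint the unpaired model removes.

### Design choices where the layout was open

* The reconstruction/"MSE" loss is read as both the least-squares
  adversarial objective and an MSE cycle term (rather than the L1 cycle
  term common in this architecture family); both are what the weighted
  variant modifies. The Otsu weighting is applied to the cycle term — the
  only term that compares two images of the same domain pixel-wise.
* The cycle weight $\lambda = 10$ follows the family convention; it is a
  `train_config()` parameter.
* Instance normalization is applied to *every* discriminator C block,
  including the first, following the architecture description literally; a
  `norm_first = FALSE` flag restores the common variant that skips it.
* Generator convolutions use reflection padding; the final activation is
  tanh so outputs live on the $[-1, 1]$ scale of the normalized data.
* The discriminator C blocks use stride 2 with 1-pixel zero padding, F1
  stride 1 — the strides are not stated in the token grammar and follow
  the family convention, making a 128-pixel input produce a 7×7 score map.
* No identity-mapping loss and no discriminator history buffer by default;
  both exist behind `train_config()` flags.
* The learning rate defaults to the stated 0.002 (even though 0.0002 is
  the family convention; both are one `train_config()` argument away). An
  optional linear decay (`lr_decay_from`) can taper the rate to zero over
  the final epochs — the family's standard remedy for late-training
  oscillation of adversarial losses; it is off by default.
* The UNet baseline's exact modifications are not specified anywhere;
  defaults (depth 4, base 64 filters, instance norm, tanh output) are
  documented as this package's choice, not as the original authors'.

## Training protocol

`extract_patches_2d()` draws patches at seeded uniform-random positions
from individual z-slices — 2500 per image and two images per domain gives
the 5000-patch 2D domains; 128-pixel patches serve the membrane/BC and
membrane/sinusoid models, 256-pixel patches the membrane/Kupffer model.
`extract_patches_3d()` draws 900 cubes of 64³ voxels per image (1800 per
domain), split 90/10 into training and validation by
`split_train_val()`. Patch positions may repeat: thousands of patches from
one image necessarily overlap, so sampling is with replacement. Intensities
are min–max normalized to $[-1, 1]$ per image, with the affine recorded so
predictions can be mapped back (`normalize()` / `denormalize()`).

Optimization is Adam with learning rate 0.002, $\beta_1 = 0.5$, batch size
1; 100 epochs for 2D models, 300 for 3D with early stopping on the
validation metric (patience is a `train_config()` parameter, default 20
when enabled). Training is fully seeded and bit-reproducible: identical
configurations give identical loss traces.

## The synthetic phantom

Because the original microscopy volumes are external data, every part of
the pipeline is testable on a seeded synthetic liver phantom
(`generate_phantom()`) whose geometry is known exactly:

* hepatocyte-scale cells: a Voronoi tessellation of blue-noise (dart
  throwing) seed points, nominal diameter 22 µm; the **membrane** channel
  is the set of tessellation boundary voxels, emulating the cortical actin
  mesh;
* the **bc** channel: tubes of configurable radius (default 2 µm) threaded
  along cell–cell interfaces — nodes are interface centroids, edges connect
  interfaces sharing a cell, and the network is a minimum spanning tree
  plus ~15% extra short edges, giving one connected, looped network like
  the real canalicular mesh;
* the **sinusoid** channel: a few smooth, undulating tubes of radius 5 µm
  spanning the volume;
* the **kupffer** channel: sparse star-shaped blobs (a soma with 4–7
  radiating arms);
* acquisition effects: mixed Poisson–Gaussian noise (`add_noise()`) and a
  logistic depth-attenuation factor (`apply_depth_attenuation()`) equal to
  0.95 at `depth - width` and 0.05 at `depth + width`, emulating the ~80 µm
  antibody-penetration knee. The membrane channel is left unattenuated in
  deep-tissue emulations, as phalloidin penetrates far deeper.

Default lengths are micrometres at a 1 µm isotropic desk-scale voxel; the
tube radii sit slightly above the real sub-micron BC calibre so that tubes
span at least two voxels at desk scale — at the native 0.3 µm voxel size
the same configuration accommodates realistic radii. The lobule axis
(central-vein → portal-vein direction) is recorded in the ground truth so
axis profiles can be validated against constructed gradients
(`bc_radius_gradient`).

What the phantom does *not* emulate: optics (no point-spread-function
blur, no spectral bleed-through), intensity inhomogeneity across the field,
and the true morphometric statistics of liver tissue, which the source
imagery does not quantify. Tests passing on phantoms therefore validate
the *machinery* — losses, training dynamics, tiling, metrics, morphometry
— not biological realism of any particular prediction.

Arrays are indexed `(z, y, x)` with z the depth from the imaged surface;
indices are 1-based throughout, the R convention.

## Whole-volume inference

Patch-trained models are applied to arbitrary volumes by `predict_volume()`:
2D models run slice-wise over z; tiles overlap by 50% by default and are
blended with a strictly positive Hann-taper window, normalized voxel-wise
so the scheme is exactly conservative (an identity model reproduces its
input bit-for-bit up to float tolerance). Borders are reflect-padded to
fit one tile and cropped back. Tapered blending suppresses the seam
artifacts adversarial generators otherwise produce at tile borders.
`depth_profile()` reduces a volume to mean intensity per z-slice against
depth in µm — the readout that contrasts the collapse of attenuated
experimental channels with the stable virtual predictions.

## Evaluation metrics

`evaluate_cubewise()` partitions a test volume into non-overlapping cubes
(128³ by default; a 640×640×128 stack gives the reference 25-cube layout)
and computes, independently per cube: MSE, MSLE, MAE, RMSE, PSNR, SSIM,
MS-SSIM, cosine similarity (COS), Pearson correlation (CoC), and FID.
Numerical conventions:

* **PSNR** uses the ground-truth cube's own maximum as the peak
  ($10\log_{10}(\max(gt)^2/\mathrm{MSE})$), not a global bit-depth
  constant; identical images report `Inf`.
* **MSLE** requires non-negative inputs: both images are shifted by the
  smallest common offset (so $[-1,1]$ data moves to $[0,2]$) and `log1p`
  is applied before the squared difference.
* **SSIM** uses an 11-wide Gaussian window ($\sigma = 1.5$), $K_1 = 0.01$,
  $K_2 = 0.03$; the default data range is the joint observed range of the
  two images, which keeps the metric symmetric. **MS-SSIM** uses the
  standard five scale weights, renormalized when the cube supports fewer
  dyadic scales (a 128³ cube supports four at window 11), and clamps
  negative contrast terms at zero.
* Degenerate inputs (constant images, zero vectors) produce sentinel
  values with warnings, never NaN, so per-cube reports keep every cube.
* **FID** fits Gaussians to feature vectors of the z-slices of each cube
  and evaluates the Fréchet distance with a symmetrized PSD-safe matrix
  square root. The canonical extractor is an ImageNet-pretrained inception
  network; since absolute FID values are not comparable across extractors
  anyway, the package default (`feature_extractor_default()`) is a frozen
  seeded random-projection extractor requiring no pretrained weights, and
  any `function(image) -> vector` can be plugged in.
* `fg_bg_metrics()` recomputes the pixel metrics separately over the
  foreground and background voxel sets of the ground truth's Otsu mask;
  `error_heatmap()` reports per-block MSE on a 9×9 grid whose
  size-weighted mean reproduces the global MSE exactly.
* Report summaries follow the box-plot convention used for these
  evaluations: median, quartiles, and whiskers at the data range.

## Morphometry

`morphometry()` quantifies a predicted (or experimental) BC channel:
Otsu segmentation; 3D curve skeletonization by sequential deletion of
topologically simple border points (26-connectivity for foreground, 6 for
background, endpoint preservation, six directional sub-iterations);
a skeleton graph whose nodes are junctions/endpoints and whose branches
carry arc lengths under the anisotropic voxel size; per-skeleton-voxel
radii from the exact Euclidean distance transform of the mask; and
profiles of radius and branch length along the lobule axis (default 10
bins, per-bin mean ± SD, SD absent below 2 samples). Terminal spurs
shorter than 2 µm are pruned by default to stabilize branch statistics.
On noiseless phantoms these estimators recover configured tube radii and
branch lengths within 10%, which is the package's acceptance bar for the
whole chain; the same chain can detect injected radius thinning, the bias
mode reported for cross-species prediction.

## Problem sizes used by the test suite

The suite runs on one CPU. Phantoms for unit tests are 48×64×64 voxels at
1 µm. The learning-sanity check trains the full two-generator /
two-discriminator dynamics on 32² membrane patches whose domain-B images
are the exact intensity inversion of domain A, so recovery of the mapping
is measurable as held-out SSIM against a known target. The generator for
this task is the residual-only reduced layout `c7s1-12, R12 (x2), c7s1-1`
(the target map is pointwise, so down/up stages only add transposed-conv
artifacts); the discriminator is `C8, C16, F1`; 48 patches per domain,
50 epochs at the reference optimizer settings with the linear decay
active over the last ten epochs. Smoke, determinism and checkpoint tests
use the down/up layout `c7s1-8, d16, R16 (x2), u8, c7s1-1` so every block
type is exercised. The deep-tissue workflow trains the same reduced
setting on an attenuated phantom and reproduces the qualitative
depth-profile signature (collapsing experimental channel, stable
prediction). Protocol-count checks (5000 2D patches, 1800 3D patches, 25
cubes) run at the full stated sizes. The full-size architectures are
built and shape-checked but not trained to convergence in the tests.

A caution on the adversarial fits at this scale: with tens of patches and
thousand-parameter networks, cycle-consistent adversarial training has
two observable regimes — an inversion basin in which held-out SSIM climbs
steadily, and a content-shuffling mode in which generated images match
the target distribution statistically while their structure decorrelates
from the input. Which regime a run enters depends on the seed;
within the good basin, held-out SSIM against the exact mapping typically
peaks between 0.6 and 0.9 (for calibration, the full-scale models of this
family report SSIM around 0.62–0.66 against real acquisitions). The
learning tests therefore fix their seeds, and the recovered-mapping SSIM
should be read as a stochastic quality of an adversarial fit, not a
deterministic property of the code: the supervised baseline on the same
task, whose optimization is convex-like, reaches SSIM above 0.9 within a
few epochs, which is the cleaner regression check of the layer machinery.

## Known limitations

* Batch size is fixed at 1 (the protocol's setting); the layer kernels
  have no batch axis.
* No GPU path: the convolution kernels are single-threaded C++; full-size
  3D training at the reference patch counts is out of desk-scale reach.
* The phantom's geometry statistics are qualitative; no claim is made that
  phantom-trained models transfer to real tissue.
* FID values from the default extractor are not comparable to
  inception-based FID numbers.
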
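---
title: "The spectral imaging chain: from scattered fields to dielectric maps"
author: "mwcamera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spectral imaging chain: from scattered fields to dielectric maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwcamera)
```

## The measurement model

A planar microwave camera observes a breast phantom immersed in water
(relative permittivity $\varepsilon_r = 73$, conductivity
$\sigma = 1$ S/m) illuminated by a monochromatic plane wave at
$f = 2.45$ GHz, polarized along the vertical $z$ axis and propagating
along $y$. The scattered field $E_{s,z}$ is sampled on a *retina* of
$64 \times 64$ points spaced a quarter of the water wavelength apart.
With $c = 3 \times 10^8$ m/s the propagation wavenumber is

$$k_\mathrm{water} = \frac{2\pi f}{c}\sqrt{73} \approx 438\ \mathrm{m^{-1}},$$

and the retina's spectral grid has step
$\Delta k = 2\pi/(64\,\Delta) = k_\mathrm{water}/16$ exactly.

Inside the phantom the wave induces an equivalent volumetric current
$j_z = (k^2 - k_\mathrm{water}^2)\,E_t$. Under the scalar (negligible
depolarization) and first-Born ($E_t \approx E_i$) approximations, the
Weyl expansion of the Green's function turns the propagation from any
transverse slab to the retina into a multiplication in the spectral
domain by $(-i/2\gamma)\,e^{-i\gamma|d-y'|}$, with
$\gamma = \sqrt{k_\mathrm{water}^2 - k_x^2 - k_z^2}$ the longitudinal
wavenumber and $d = 10$ cm the distance between the retina and the
observation plane through the phantom. This is the Fourier diffraction
theorem: the retina field spectrum samples the current spectrum on a
slice, and it is inverted *without any division* as

$$\hat{j}_z = 2i\gamma\,\hat{E}_{s,z}\,e^{+i\gamma d},$$

defined only on the *visible disk* $k_x^2+k_z^2 \le k_\mathrm{water}^2$
where $\gamma$ is real (outside, waves are evanescent and the camera
never sees them). The factor $2\gamma$ vanishes smoothly at the rim.

Backprojecting (inverse transform) the filtered current spectrum gives
the camera's qualitative image. Truncating the spectrum further to the
disk of radius $k_\mathrm{water}/2$ — the *half-visible* filter — keeps
exactly 197 of the 4096 spectral pixels, all inside a $17\times17$ box
around DC, and acts as a strong regularizer against noise.

```{r constants}
geom <- camera_geometry()
round(geom$k_water)
sum(spectral_grid(geom)$half_visible)
```

### Counting note

On this grid the *full* visible disk with the natural inclusive boundary
rule ($\le$, radii measured on exact grid coordinates) contains 797
pixels. Counts around 800 are sensitive to rounding of the physical
constants (a boundary ring of 8 pixels sits exactly on the rim); the
half-visible count of 197 is robust and is the one the network input
size is built on. We use the inclusive rule everywhere and do not force
any other count.

## The phantom database

The generator emulates a combinatorial family of anthropomorphic
phantoms built from parametric solids (all sizes in meters, grid
centered on the camera axis):

* three fat/skin shells: superellipsoids with inner semi-axes from
  4.8 cm to 6.8 cm and a 2.5 mm skin layer;
* five glandular inclusions: ellipsoids with a common off-center
  placement, the fifth one tall enough (vertical semi-axis 4.4 cm) that
  it cannot nest inside the smallest shell — which is exactly why the
  tumor-free family has $3 \times 5 - 1 = 14$ members;
* five tumor shapes A–E with maximum dimensions from 0.5 cm to 2 cm,
  each associated with exactly one glandular cavity; per phantom the
  tumor is absent (case 1), in the adipose annulus on the observation
  plane (case 2), inside the gland (case 3), or both (case 4), giving
  $14 \times 4 = 56$ models.

Mirroring ($x \to -x$; *not* equivalent to a half-turn because the wave
propagates along $y$) and 16 rotations about the vertical axis expand
the family to $56 \times 2 \times 16 = 1792$ views, shuffled and split
80/20 into 1433 training and 359 validation samples. A dedicated test
phantom with distinct geometry — and a tumor in the fatty region on the
observation plane — contributes $16 \times 2 = 32$ held-out views.

Tissue properties at 2.45 GHz (fat 5/0.1, glandular 44/1.5, skin
42/1.6, tumor 53/1.8; $\varepsilon_r$ / $\sigma$ in S/m) receive one
independent uniform $\pm 5\%$ draw per tissue per phantom; water is
never jittered because it is the known calibration medium. Values are
constant within each cavity.

```{r counts}
nrow(enumerate_configs(FALSE, FALSE, 1))
nrow(enumerate_configs(TRUE, TRUE, 16))
```

## The forward solvers

The reference database of the original camera was produced by a 3D
surface-integral method-of-moments solver; reproducing it is out of
scope here. The package provides two synthetic generators:

* `born_forward()` — a 3D angular-spectrum solver under the first Born
  approximation. By default it propagates with the real-part water
  wavenumber, which makes it *algebraically exact* against the spectral
  inversion: forward-then-backproject equals the half-visible-filtered
  transform of the $y$-integrated Born current to FFT round-off
  ($<10^{-9}$ relative), giving a clean oracle for the whole chain.
  With `lossy_propagation = TRUE` and internal zero-padding it instead
  reproduces the continuous lossy-medium Green's function; the
  single-voxel test validates it against a fine quadrature of the Weyl
  integral to better than $10^{-3}$. (With lossless propagation the
  discrete angular spectrum is exactly the field of a periodized source
  array whose aliased copies decay only like $1/R$, so that comparison
  is only meaningful in the attenuating medium.)
* `solve_vie2d()` / `fullwave2d_forward()` — a 2D scalar volume
  integral equation solver (Richmond circular cells, BiCGSTAB with FFT
  convolutions) that retains *multiple scattering*. It is validated
  against the closed-form cylindrical-harmonics series for a
  homogeneous cylinder to better than 1% at $\lambda/24$ pixels, and it
  reduces to its own Born limit as the contrast vanishes. It exists to
  inject model mismatch for robustness experiments.

Additive white Gaussian noise can be applied to the retina field at a
prescribed SNR; because the half-visible filter removes most of it, the
magnitude image of the backprojected current at 10 dB keeps an SSIM
above 0.8 against the noiseless one. (At Born level the imaginary part
of the current carries under 1% of the energy and is noise-dominated —
a property of the linearized generator, not of the chain.)

## Normalization and calibration

The network works on standardized quantities. For each sample:

1. the backprojected current image $j_z$ and the reference contrast
   $C = (\varepsilon' - \varepsilon'_w) - i(\varepsilon'' -
   \varepsilon''_w)$ (with $\varepsilon'' = \sigma/\omega\varepsilon_0$)
   are min–max scaled per image, separately on real and imaginary
   parts, onto $[0,1]$ — the imaginary parts are much smaller and
   would otherwise be ignored by the loss;
2. each scaled image is transformed, half-visible-filtered, cropped to
   $17\times17$ and divided by its maximum modulus, so every real and
   imaginary entry lies in $[-1,1]$ with unit peak modulus and
   *unchanged phases*.

After inference, the output spectrum is re-embedded, inverse
transformed, and calibrated against the water region: with $M_\Re$ and
$M_\Im$ the means of the real/imaginary parts over the pixels outside
the phantom contour,

$$\varepsilon_\mathrm{cal} = \frac{\Re(C_\mathrm{net})}{M_\Re}\,
  \varepsilon_{r,\mathrm{water}}, \qquad
  \sigma_\mathrm{cal} = \frac{\Im(C_\mathrm{net})}{M_\Im}\,
  \sigma_\mathrm{water}.$$

The printed form of this calibration is typographically ambiguous (the
$-1$ exponent can be read as a subtraction); we use the grouping above
because it is the one with the stated fixed point — a pixel at the
water mean maps exactly to $(\varepsilon_r, \sigma) = (73, 1)$ — and it
is isolated in `water_calibrate()` so the alternative is a one-line
change. A second min–max pass maps the calibrated maps onto
$[\min|\cdot|, \max|\cdot|]$, enforcing positive extrema; its
conductivity branch is implemented with the reversed max/min structure
exactly as specified for it, which flips the map's orientation — noted
here because it mirrors the permittivity branch otherwise. Finally the
contour prior sets every outside-contour pixel exactly to water.

## The U-Net pair

Two identical single-channel U-Nets translate the normalized current
spectrum into the contrast spectrum, one for the real and one for the
imaginary part (the parts have different dynamics, and two small real
networks train more stably than one complex-valued one at this size).
The architecture compresses $17\times17$ maps to $7\times7$ without any
pooling, purely through valid convolutions with shrinking kernels
(9/7/5/3, paddings 2/2/1/0, features 32/64/128/256), crosses a linear
bottleneck, and decompresses with kernel-3 convolutions of increasing
padding (2/2/2/3) whose inputs concatenate the same-size encoder output
(skip pairs 7–7, 9–9, 11–11, 13–13). The size arithmetic
$\mathrm{out} = \mathrm{in} - k + 1 + 2p$ is asserted at construction:

```{r arch}
unet_spec()
```

Design points that the size table does not fix, and how they are
resolved here:

* the map-size row is read as listing encoder *outputs* and decoder
  *inputs*; step 9 then emits $17\times17$, which the padding
  arithmetic confirms;
* every block is batch-normalization → ReLU → convolution; the first
  block omits the ReLU (the raw input is signed in $[-1,1]$ and halving
  it away would discard information);
* the output head, unstated in the size table, is a $1\times1$
  convolution from the last 32 features to one channel;
* the bottleneck is literally a flattened fully connected layer
  (`bottleneck = "dense"`); at full width it holds
  $(256\cdot49)^2 \approx 1.6\times10^8$ weights. A channelwise
  variant (one shared $49\times49$ map per channel,
  `bottleneck = "channelwise"`) is provided and is the default of the
  reduced-scale pipeline, where the dense layer's memory traffic
  dominates the runtime without changing any tested behavior.

Training minimizes the weighted mean absolute percentage error
(sum of absolute errors over the sum of absolute reference values) with
Adam at its defaults (learning rate $10^{-3}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$), batches of three, 30 epochs. The half-visible mask
multiplies both the network input and output before the loss, so the
197 active pixels alone drive both the numerator and the denominator.
All weight initialization, shuffling and noise derive from explicit
seeds; two runs with the same configuration are bit-identical.

The layers themselves (im2col convolutions, batch norm, dense, Adam)
are implemented natively in R on top of BLAS matrix products, with the
backward pass verified against numerical differentiation in the test
suite.

## What the synthetic experiments show — and what they cannot

The package's end-to-end experiments run at *desk scale*: the default
pipeline enumerates 4 rotations (448 views), trains on roughly a
hundred samples with feature widths 8/16/32/64, and finishes in minutes
on one CPU. At that scale, on Born-generated data:

* 30-epoch training decreases the WMAPE of both networks by an order
  of magnitude (epoch 30 far below epoch 1);
* the trained pair's output SSIM against the reference spectrum
  clearly exceeds the input SSIM on held-out samples (about 0.93
  versus 0.80 on real parts, 0.79 versus 0.47 on imaginary parts in
  the reference run of the acceptance suite);
* inputs generated at 10 dB SNR move the mean output SSIM by less
  than 0.015 — the filter-then-learn chain is nearly noise-blind.

These results validate the *method's machinery*, not the published
performance figures: the original database came from a full-wave 3D
solver and is not available, so absolute metric values (e.g. a 0.97
validation SSIM) are not reproducible targets here and are not
asserted anywhere. The Born generator also underestimates the
imaginary current (no multiple scattering), which is why the imaginary
input SSIM starts much lower than the real one; the 2D full-wave
solver exists precisely to probe that gap.

Evaluation follows the batch protocol of training: SSIM (Gaussian
window 11, $\sigma = 1.5$, $k_1 = 0.01$, $k_2 = 0.03$, unpadded
windows, data range from the compared pair — the convention is pinned
in `ssim()` rather than inherited from any library default) and PSNR
(range of the reference) on the real and imaginary spectrum parts, per
full batch of three; a 359-sample validation set yields 119 batch
points, with the 2-sample remainder entering only the dataset means.

## Numerical conventions, degenerate inputs, limitations

* Time convention $e^{+i\omega t}$; kernels $e^{-i k\cdot r}$;
  outgoing 2D waves are Hankel functions of the second kind. The
  evanescent branch is $\gamma = -i\sqrt{k_\perp^2 - k^2}$ so fields
  decay, which only matters to the forward model (the visible filter
  discards those components anyway).
* DC-centered ("shifted") spectral storage everywhere, 0-based index
  $n/2$; the even grid spans offsets $-32..31$, the crop the symmetric
  $-8..8$.
* Degenerate inputs error loudly: constant images in min–max scaling,
  all-zero spectra in normalization and NSD, empty water regions or
  zero means in calibration, identically zero references in WMAPE and
  SSIM, non-nesting cavity pairs, observation planes outside the grid,
  spectra with energy outside the half-visible mask at the network
  boundary.
* The voxel-to-slab quadrature is a midpoint rule at the retina pitch;
  accuracy is covered by the single-voxel Green's-function oracle
  rather than grid-refinement claims.
* Known limitations: no depolarization (scalar model by design), no 3D
  multiple scattering in the default generator, surrogate rather than
  MRI-derived geometry, and a dataset archive in R serialization
  rather than a cross-language container.

## Reduced problem sizes used by the checks

The automated checks run, by the package's own choice of desk scale:
phantom grids of $64\times36\times64$ voxels; a 96-sample training set
with 24 held-out samples for the training-behavior check (4 rotations,
feature widths 8/16/32/64, channelwise bottleneck, 30 epochs); a
64-sample identity-task set (tripled to 192 items) for the capacity
check; $\lambda/24$ pixels for the cylinder benchmark; padding factor
4 and 25 retina probe points for the Weyl quadrature oracle.
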
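# fdDOT

Frequency-domain diffuse optical tomography (DOT) in R: forward simulation,
classical iterative reconstruction, and learned reconstruction with a
channel-attention fusion network, in one self-contained package.

DOT probes tissue with intensity-modulated near-infrared light and
reconstructs the interior absorption coefficient mu_a and reduced scattering
coefficient mu_s' (both mm^-1) from amplitude and phase measured at the
boundary — a severely ill-posed inverse problem relevant to breast-tumor
screening.  fdDOT is aimed at researchers who want a complete, inspectable
simulation-to-evaluation loop for circular phantom studies without any
external data or frameworks.

## What is inside

**Forward model.**  The frequency-domain diffusion approximation
`(-div D grad + mu_a - i w/c) Phi = S`, with `D = 1/(3(mu_a + mu_s'))`,
discretized with linear-triangle FEM on a disk mesh, Robin boundary
conditions, and a 16-source / 15-detector boundary layout (240 pairs, 480
scalars per phantom).  One sparse factorization serves all sources and all
adjoint solves.

**Synthetic dataset generator.**  Circular phantoms with 0-2 random
inclusions (diameters 60-150 mm, background mu_a 0.005-0.03 /mm, mu_s'
0.5-3 /mm, 10-100 MHz, contrasts 1.5-8, 15% measurement noise), paired with
64 x 64 x 2 ground-truth property images and split 85/10/5 into
train/validation/test.

**Tikhonov / Gauss-Newton reconstruction.**  Adjoint-method Jacobian of
log-amplitude and phase with respect to nodal (mu_a, D), identity-matrix
Tikhonov regularization `min ||J dx - dPhi||^2 + lambda^2 ||dx||^2`,
parameter-scaled updates with a backtracking line search.

**CAFNet.**  A learned reconstructor: AUTOMAP-style fully connected domain
transform (480 -> 1024 -> 4096, tanh), feature-extraction blocks
(conv + batch norm + ReLU), two multi-scale fusion blocks (1x1/3x3/5x5
branches plus a max-pooled branch), a channel attention block
(`w_c = sigmoid(MLP(z_avg + z_max))`, gating each channel), and a 1x1
output head — trained with Adam (lr 0.001, beta1 0.5) on a weighted
two-channel MSE.  Layers and the training loop are implemented in the
package on BLAS-backed C++ kernels; ablation variants (`feb_only`,
`feb_fusion`, `no_cab`, `no_feb`) are built from the same blocks.

**Evaluation.**  MSE / PSNR / SSIM per property channel, contrast, size and
contrast-size-detail resolution indices with the fold rule
`R_cont = 2 - r0` for overshoot, attention histogram/entropy diagnostics,
and a k-fold cross-validation harness.

## Worked example

Simulate a 60 mm phantom with one absorbing/scattering inclusion, add 15%
measurement noise, and reconstruct it with the Gauss-Newton solver:

```r
library(fdDOT)
ph <- new("Phantom", diameter = 60, backgroundMuA = 0.01, backgroundMuSp = 1,
          inclusions = list(new("Inclusion", center = c(10, 5), radius = 10,
                                contrastA = 4, contrastS = 2)),
          frequency = 50)
ph
#> Phantom: d = 60.0 mm, mu_a = 0.0100, mu_s' = 1.000 /mm, f = 50.0 MHz, 1 inclusion(s)
#>   inclusion r = 10.0 mm at (10.0, 5.0), contrast a/s = 4.00/2.00

sim <- simulatePhantom(ph)
sim$measurements
#> MeasurementSet: 16 x 15 amplitude/phase at 50.0 MHz (amp 1.56e-07..0.011)

noisy <- addNoise(sim$measurements, level = 0.15, seed = 7)
rec <- reconstructTR(noisy, diameter = 60, backgroundMuA = 0.01, backgroundMuSp = 1)
rec
#> ReconResult: 4 iterations, residual 18.3 -> 2.074

img <- propertyValues(rec@propertyImage)
max(img[, , 1])           # reconstructed mu_a peak, true inclusion value 0.04
#> 0.0306
resolutionReport(img, ph)
#>   channel rContrast    r0Size     rSize      rCSD
#> 1     muA 0.2734552 0.4116392 0.3355069 0.3028962
#> 2    muSp 0.0000000 0.0000000 0.0000000 0.0000000
```

The residual falls from 18.3 (homogeneous initial guess) to the noise floor
in four accepted Gauss-Newton iterations; the mu_a peak recovers about 75%
of the true inclusion value and lands inside the true inclusion, while the
mu_s' channel of this single noisy reconstruction retains no usable
contrast — the classical-method behaviour the learned reconstructor is
meant to improve on.

To run the learned pipeline end to end at desk scale (dataset generation,
training, prediction, metric report):

```r
r <- runPipeline(paperScaledProfile(seed = 1), outDir = "run1")
r$aggregate          # per-channel MSE/PSNR/SSIM of the test split
```

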
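# raman3d

Joint spatial–spectral denoising of hyperspectral Raman image cubes with a
depthwise separable 3D MultiResU-Net, for researchers who want to acquire
cellular Raman maps at short per-pixel integration times and recover
long-integration quality computationally.

A hyperspectral Raman cube is an `H x W x B` array: a full vibrational
spectrum (wavenumber axis in cm⁻¹) at every pixel of a scanned field of
view. At short integration times the cube is dominated by detector noise,
modeled here as mixed Poisson–Gaussian:

    Y = α · Poisson(X / α) + N(0, σ²),   E[Y|X] = X,   Var[Y|X] = αX + σ²

where the gain `α` scales signal-dependent shot noise and `σ` summarizes
signal-independent readout/dark noise. The denoiser is a 3D U-Net whose
convolutions are depthwise separable (a per-channel `3×3×3` filter followed
by a `1×1×1` channel mix, cutting weights from `C_in·C_out·27` to
`C_in·27 + C_in·C_out`), with residual blocks (DS conv + batch norm +
PReLU), and a pseudo-3D multi-scale fusion module on every skip connection:
spatial branches (two `3×3×1`, two `5×5×1`) and spectral branches (`1×1×3`,
`1×1×5`, `1×1×5` dilation 5, `1×1×7` dilation 7) whose concatenated
features are reweighted by squeeze-and-excitation channel attention.
Training follows the composite loss `0.1·L1 + 0.9·MSE` with Adam, batch
size 2, and a 0.001 → 0.0001 learning-rate step.

The package also provides: an HDF5 cube container with global min-max
normalization, a synthetic cellular phantom generator with exact linear-
mixing ground truth, Savitzky–Golay and PCA-truncation baselines, the four
evaluation metrics (band-averaged SSIM and PSNR; per-spectrum MSE and
spectral SNR), and a one-call experiment driver. The network, including all
convolution forward/backward passes, is implemented in R with Rcpp kernels;
gradients are hand-derived and validated against finite differences in the
test suite.

## Worked example

Train a small denoiser on paired phantoms and evaluate it against the
tuned classical baselines:

```r
library(raman3d)

manifest <- run_experiment(experiment_config(seed = 1))
for (m in names(manifest$reports)) { cat(m, ": "); print(manifest$reports[[m]]) }
```

which prints (12 phantoms of 32×32 px × 64 bands; 2-level width-8 network,
30 epochs; metrics on the min-max scale, means over the 2 test cubes):

```
input   : Metric report over n = 2 samples (normalized intensities)
  SSIM 0.1045   PSNR 20.10 dB   MSE 0.0124    SNR 0.37 dB
sg      : Metric report over n = 2 samples (normalized intensities)
  SSIM 0.2803   PSNR 25.47 dB   MSE 0.004282  SNR 1.78 dB
pca     : Metric report over n = 2 samples (normalized intensities)
  SSIM 0.8384   PSNR 42.90 dB   MSE 0.0004682 SNR 11.83 dB
network : Metric report over n = 2 samples (normalized intensities)
  SSIM 0.6951   PSNR 37.30 dB   MSE 0.0003779 SNR 11.86 dB
```

Reading these numbers: the network lifts the noisy input by +17.2 dB PSNR
(20.10 → 37.30) and improves every metric, far ahead of Savitzky–Golay
smoothing, and it attains the lowest spectral MSE and highest spectral SNR
of all methods. Tuned PCA truncation posts the best band-averaged PSNR/SSIM
here — expected on this data: phantoms are exact finite linear mixtures,
hence low-rank, and rank-k PCA is close to an oracle denoiser for iid noise
on low-rank cubes. Real cellular cubes are not exact mixtures, which is why
this advantage does not transfer; see the methods vignette
(`vignettes/raman3d-methods.Rmd`) for the analysis.

Single-cube use with a fitted model:

```r
denoised <- denoise_cube(manifest$model, noisy_cube)   # hyper_cube in, hyper_cube out
```

A thin command-line front end over the same functions is installed at
`inst/cli/raman3d.R` (`info`, `phantom`, `corrupt`, `split`, `denoise`,
`baseline`, `evaluate`, `run`).

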
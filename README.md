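# hepatoscope

Quantitative image analysis for multiscale optical microscopy of liver
tissue, written for microscopists and image analysts who need numbers —
not just pictures — from three kinds of acquisitions:

1. **LSEC fenestration analysis.** Liver sinusoidal endothelial cells are
   perforated by transmembrane pores (fenestrae, ~50–300 nm) grouped into
   sieve plates. In super-resolution structured-illumination (SR-SIM)
   images of membrane-stained cells they appear as dark holes in a bright,
   unevenly stained membrane. `detectFenestrae()` runs the full
   identification pipeline: 2× upsampling, brightness flattening by a
   grey-scale dilation envelope, inversion, local-mean adaptive
   thresholding with a user-tunable offset, marker-based watershed
   splitting of touching pores, and equivalent-diameter sizing
   d = 2·√(area/π)·pixel size. Detections below 95 nm (the SR-SIM
   resolution limit) or above 320 nm (membrane holes rather than
   fenestrae) are excluded, and the retained diameters are binned into a
   10 nm size histogram with modal-bin and exponential tail-decay
   statistics.
2. **Hyperspectral CARS/SRS unmixing.** A coherent-Raman cube sampled
   over 2790–3020 cm⁻¹ in 15 cm⁻¹ steps covers the lipid CH₂ symmetric
   stretch (2845 cm⁻¹) and the protein-associated anti-symmetric stretch
   (2920 cm⁻¹). `fitCube()` solves, for every pixel, the nonnegative
   least-squares problem
   y(ν) ≈ A₂₈₄₅·G(ν; 2845, w) + A₂₉₂₀·G(ν; 2920, w) + b
   with unit-peak Gaussian lineshapes and an unconstrained baseline,
   producing lipid/protein amplitude maps and a residual map. Simple
   threshold splitting of single-frequency CARS images and
   phase-correlation tile stitching round out the module.
3. **Optical projection tomography.** `fbpSlice()` reconstructs
   parallel-beam sinograms (600 views at 0.6° is the reference geometry)
   by filtered back-projection with a Shepp-Logan filter,
   H(f) = |f|·sinc(f/2f_N), using generous zero-padding and bilinear
   back-projection interpolation.

Every stage has a seeded simulator (`sievePlateTruth()` +
`simulateSieveImage()`, `randomHsiTruth()` + `simulateHsiCube()`,
`diskPhantom()` + `simulateOptProjections()`) that returns ground truth
alongside the data, so the whole toolkit is testable end to end with no
external downloads.

## Worked example

```r
library(hepatoscope)

# simulate a sieve plate: 10 pores, 130-300 nm, on a 256x256 grid at
# 40 nm/px with a 100 nm PSF, uneven staining, and camera noise
d  <- sampleDiameters(10, "uniform", list(min = 130, max = 300), seed = 1001)
tr <- sievePlateTruth(d, imageShape = c(256, 256), seed = 1001)
img <- simulateSieveImage(tr)$image

res <- detectFenestrae(img)
res$histogram
#> SizeHistogram: 10 fenestrae in 23 bins [90, 320] nm; modal bin 210 nm; tail decay 61.49 nm

score <- matchToTruth(res$records, tr)
c(recall = score$recall, precision = score$precision,
  median_err_nm = score$medianAbsDiamErrNm)
#>        recall     precision median_err_nm
#>      1.000000      1.000000      7.194907
```

All 10 simulated pores are found (recall and precision 1), and the
median absolute diameter error of 7.2 nm is well inside a 40 nm pixel —
the sizing is limited by the PSF, not the grid. A 10-pore histogram is
far too sparse for its modal bin or tail fit to mean much; on 10⁴
diameters drawn from the shifted-exponential size model (offset 90 nm,
scale 40 nm) the fitted tail decay recovers the 40 nm scale to within a
few percent.

A command-line interface wrapping every stage
(`simulate-sieve`, `detect-fenestrae`, `hsi-fit`, `opt-recon`, ...) is
installed at `system.file("scripts", "hepatoscope", package = "hepatoscope")`.

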
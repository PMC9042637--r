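# usenhance

Impulse-noise removal and edge-selective enhancement for 8-bit grayscale
ultrasound images, with the quality metrics and synthetic phantoms needed
to evaluate both — no clinical data required.

B-mode ultrasound frames (the package was designed around pelvic-floor
examinations) carry speckle texture by nature and are additionally
vulnerable to salt-and-pepper impulse corruption. Blanket median filtering
removes the impulses but blurs exactly the anatomical interfaces a
clinician measures. `usenhance` instead:

1. **detects** impulses with a two-stage adaptive median filter — a pixel
   equal to its window extreme (while the window median is not an impulse
   value) is a *quasi-noise candidate*; the candidate is **confirmed** only
   if its local slope `K1` clears the adaptive threshold `Q = S_med / ε` —
   and replaces confirmed noise with the median of the smallest adaptive
   window (3 → 5 → 7) whose median is trustworthy;
2. **extracts edges** with flat-structuring-element morphological
   gradients: `P1 = (g ⊕ D) − (g · D)` through the anti-noise forms
   `P2..P5` built from openings and closings;
3. **enhances only the edge regions**: `out = clip(denoised + λ·edge)` on
   an Otsu-thresholded gradient mask, with every non-edge pixel passed
   through bit-identically;
4. **measures** SNR, PSNR, MSE and global three-factor SSIM
   (`c3 = c2/2`, so it coincides with the standard two-factor form).

Every stage has a literal reference implementation or algebraic identity
behind it in the test suite, including a brute-force per-pixel oracle that
the compiled filter must match exactly.

## Worked example

```r
library(usenhance)

ph    <- make_phantom(128, 128, seed = 7)            # clean phantom + truth
noisy <- add_impulse_noise(ph$image, 0.10, seed = 8) # 10% salt & pepper

res <- run_pipeline(noisy$image, enhance_params(), reference = ph$image)
res
#> <enhance_result 128 x 128, operator P4, 1355 noise px, 1072 edge px>
#>   vs reference: PSNR 14.79 -> 21.22 dB, MSE 2159.0 -> 491.4, SSIM 0.745 -> 0.932

# detection quality against the known corruption mask
detected <- res$labels == 2L
c(recall = sum(detected & noisy$corrupted_mask) / sum(noisy$corrupted_mask),
  fp     = sum(detected & !noisy$corrupted_mask) / sum(!noisy$corrupted_mask))
#>     recall         fp 
#> 0.78327228 0.00488268
```

The pipeline raised PSNR by ~6.4 dB and SSIM from 0.75 to 0.93 while
replacing only ~0.5% of clean pixels; `res$denoised`, `res$edge`,
`res$mask` hold the intermediates and `res$output` the enhanced image.
`write_image()` / `read_image()` round-trip PGM, PNG and TIFF.

A parameter sweep with paired before/after metrics:

```r
df <- run_benchmark(bench_config(densities = 0.1, epsilons = c(1L, 2L, 4L),
                                 operators = "P4", n_seeds = 5L))
summarize_benchmark(df)[, c("epsilon", "d_psnr", "d_mse", "recall", "fp_rate")]
#>   epsilon   d_psnr     d_mse    recall     fp_rate
#> 1       1 3.843679 -1270.109 0.2152625 0.000257697
#> 2       2 6.219287 -1646.026 0.7726496 0.004570731
#> 3       4 6.741871 -1704.870 0.9556777 0.029933541
```

(ε controls the confirmation threshold `Q = S_med/ε`: larger ε confirms
more aggressively — recall rises, false positives rise with it.)

## Command line

```sh
inst/cli/usenhance phantom --height 256 --width 256 --seed 7 --out clean.png
inst/cli/usenhance corrupt --in clean.png --density 0.1 --seed 11 --out noisy.png
inst/cli/usenhance enhance --in noisy.png --reference clean.png --out enhanced.png \
    --operator P4 --epsilon 2 --gain 1.0 --mask otsu
inst/cli/usenhance bench --out bench.csv --summary summary.csv
```

## Documentation

The methods vignette (`vignettes/ultrasound-enhancement.Rmd`) describes
the decision rules, the gradient operators, the phantom's scope and
limits, and every degenerate-case and default-parameter choice.
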
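# mrsinet

Hierarchical 1D convolutional networks for nosologic mapping of
glioblastoma therapy response from MR spectroscopic imaging (MRSI).

## The problem

In the GL261 murine glioblastoma model treated with temozolomide (TMZ),
anatomical MRI reacts slowly to therapy, while the metabolite spectrum of
each MRSI voxel changes early: normal parenchyma shows high creatine
(3.04/2.93 ppm) and N-acetyl aspartate (~2.02 ppm); untreated tumour shows
high mobile lipids/lactate around 1.34 ppm; tumour responding to therapy
shows lipid/lactate signals shifted to 1.23 and 0.80/0.83 ppm, elevated
myo-inositol/glycine at 3.54 ppm and a broad polyunsaturated fatty-acid
signal near 2.7–2.9 ppm.  `mrsinet` classifies every voxel spectrum of a
10×10 MRSI grid with a two-stage cascade of one-dimensional convolutional
networks and renders the result as a nosologic (colour-coded) brain map:

1. **Stage 1 — normal vs tumour** (negative class N, positive class R+T).
   Voxels predicted normal are finalised **blue**.
2. **Stage 2 — responding vs unresponsive**, applied only to the non-N
   voxels: unresponsive/control tumour (T) is coloured **red**, tumour
   responding to TMZ (R) **green**.

Each spectrum is the 692-point window between 0 and 4.5 ppm, normalised to
unit Euclidean length (UL2), so classifiers see spectral shape only.  Both
stage models are 1D-CNNs (three length-preserving convolution blocks with
LeakyReLU and max-pooling, sizes 692→346→173→86, a 9632-long flattened
vector, dropout 0.5, one dense layer, a single sigmoid output):

| | conv 1 | conv 2 | conv 3 | dense | Adam lr |
|---|---|---|---|---|---|
| stage 1 (N vs R+T) | 80 / k12 | 112 / k9 | 112 / k3 | 192 | 0.00081 |
| stage 2 (R vs T)   | 144 / k9 | 48 / k6  | 112 / k3 | 448 | 0.00075 |

Training is class-balanced with SMOTE, split at the *subject* level to
avoid leakage, benchmarked against tuned logistic-regression, SVM, random
forest and XGBoost baselines, explained with Grad-CAM relevance maps over
the spectrum, and evaluated against expert masks with per-class and
multiclass Dice scores.  A synthetic phantom generator reproduces the
statistical structure of the data (Lorentzian metabolite peaks, class
signatures, tumour/responding grid layouts, noise), so the entire pipeline
runs and is tested without animal data.

## Worked example

```r
library(mrsinet)

cfg <- phantom_config()                      # 692-point axis, 10x10 grids
s <- generate_spectrum("T", cfg, seed = 7)   # one untreated-tumour voxel
ppm_values(cfg$axis)[which.max(s)]
#> [1] 1.34                                   # mobile lipids/lactate peak

g <- generate_grid(cfg, seed = 7)
g
#> <mrsi_grid> 10x10 voxels, 692-point spectra, subject S1
#> labels
#>       N       T unknown
#>      48      16      36

# full phantom study: cohort, split, SMOTE, both CNN stages, maps, Dice
res <- run_all(run_config(out_dir = "phantom_run", seed = 101))
read.csv("phantom_run/metrics_N_vs_RT.csv")
#>              model accuracy sensitivity specificity precision f1 f1_macro
#> 1           1D-CNN        1           1           1         1  1        1
#> 2 nearest-centroid        1           1           1         1  1        1
res$comparison
#> <dice_comparison> 1D-CNN vs nearest-centroid (mean +/- 95% CI half-width)
#>  class              1D-CNN    nearest-centroid best
#>      N 1.00 +/- 0.00 (n=2) 1.00 +/- 0.00 (n=2)  tie
#>      T   1.00 +/- NA (n=1)   1.00 +/- NA (n=1)  tie
#>      R   1.00 +/- NA (n=1)   1.00 +/- NA (n=1)  tie
```

On the default well-separated phantoms both stages recover the ground
truth perfectly on held-out subjects (accuracy 1.0, all Dice 1.0), and the
Grad-CAM class averages peak at the discriminative metabolite positions
(~1.3 ppm for stage 1, ~3.55 or ~0.8 ppm for stage 2).  `plot(res$maps[[1]])`
renders a map; `grad_cam()`, `classify_longitudinal()`, `compare_methods()`
and the IO helpers (`write_grid()`, `read_grid()`, `write_nosologic_map()`)
expose the individual steps.  A thin command-line front end lives in
`inst/cli/mrsinet.R`.

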
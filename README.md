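# entropytex

Texture recognition from a fused representation: a pretrained-CNN-style
descriptor of the original image concatenated with the same descriptor of a
**local non-additive entropy transform** of that image.

## The problem and the method

Textures — material surfaces, leaf cuticles, fabrics — are characterised as
much by the *disorder* of their local intensity patterns as by the
intensities themselves. `entropytex` makes that disorder an explicit input
channel. For each pixel of a grayscale image, the intensities of the square
window of radius *r* centred on it are binned into *k*<sub>max</sub> = *L*/*h<sub>b</sub>*
histogram bins, and the pixel is replaced by the reduced non-additive
(Tsallis-type) entropy of the normalized window histogram *p*:

> *S′*<sub>q</sub>(*p*) = Σ<sub>k</sub> *p*<sub>k</sub><sup>q</sup>,  q > 0

(the Tsallis entropy *S*<sub>q</sub> = *k*(1 − Σ *p*<sub>k</sub><sup>q</sup>)/(q − 1)
minus global constants; at q → 1 it recovers the Shannon entropy, which is
substituted at exactly q = 1). The transformed image *I*<sub>q</sub> is an
alternative viewpoint of the texture whose contrast is governed by the
entropic index q: q < 1 amplifies rare intensities, q > 1 the dominant
ones.

Both the original image and *I*<sub>q</sub> go through a feature-extractor
backbone (the penultimate layer of a pretrained CNN, or any registered
deterministic stand-in); the two descriptors are concatenated, reduced by
PCA (≤ 200 components, count chosen by 5-fold cross-validation on the
training set) and classified with LDA. The index q itself is selected by
K-fold cross-validation over a grid, on training images only. Standard
benchmark split protocols are built in: leave-one-acquisition-sample-out
(KTH-TIPS-2b style) and repeated random half/half splits.

No pretrained weights ship with the package: the backbone registry contains
a `"vgg19-penultimate"` entry that documents the contract (224×224 input,
4096 features) and a fully functional `"pooled-stats"` stand-in, so the
entire pipeline runs and is testable offline.

## Worked example

```r
library(entropytex)

## a synthetic 4-class texture set: class identity split between mean
## intensity (seen by the original stream) and local disorder (seen by the
## entropy stream)
ds <- generate_texture_dataset(default_texture_classes(),
                               n_per_class = 20, side = 64, seed = 11)

## the entropy representation of one image
emap <- entropy_transform(ds$images[[3]], window_spec(r = 2),
                          histogram_spec(bin_width = 32), entropy_spec(q = 1.5))
emap
#> <entropy_map 64 x 64>  q = 1.5, r = 2, bin_width = 32, normalized, border = reflect
#>   values in [0.384197, 0.648]

## protocol evaluation of the fused pipeline
plan <- make_split_plan(ds, "half_half", repetitions = 10, seed = 7)
evaluate(ds, plan, pipeline_config(q = 1.5, stream = "fused"))
#> <eval_report: half_half protocol, 10 folds, stream = fused, q = 1.5>
#>   mean accuracy: 0.9950  (per fold: 1.000, 0.975, 1.000, 1.000, 1.000, 1.000, 0.975, 1.000, 1.000, 1.000)
#>   PCA components per fold: 10, 10, 10, 10, 24, 24, 10, 10, 10, 10

## cross-validated selection of q on a fixture with a planted low-q optimum
sweep_q(generate_tail_contrast_dataset(seed = 5), grid = c(0.5, 1, 1.5, 2),
        K = 5, seed = 3,
        config = pipeline_config(stream = "entropy", window = window_spec(3)))
#> <q_sweep: 5-fold CV over 4 q values, seed 3>
#>    q mean_cv_accuracy sd_cv_accuracy
#>  0.5        0.9555556     0.06085806
#>  1.0        0.8733333     0.08874989
#>  1.5        0.7933333     0.12059523
#>  2.0        0.7488889     0.19012666
#>   best q: 0.5
```

The entropy map values lie in (0, 1] for q > 1 (here 1.5) with lower values
marking more disordered neighbourhoods. The evaluation report shows the
fused descriptor recovering all four classes almost perfectly under the
half/half protocol, using 10–24 principal components per fold. The sweep
recovers the planted optimum q = 0.5 on a dataset whose classes differ only
in the tail weight of their local histograms.

Real datasets in the standard class-per-directory layout are read with
`load_dataset(root, tag_pattern = ...)`; a thin command-line interface over
the same functions (`transform`, `features`, `qsweep`, `evaluate`, `synth`,
`fig2`) is installed at `system.file("cli/entropytex", package = "entropytex")`.

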
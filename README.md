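# kernmix

Unsupervised segmentation ("digital staining") of **low-contrast
multichannel images** — images whose components have nearly parallel
spectral profiles, such as color micrographs of unstained histological
specimens, where the tissue components are almost indistinguishable by
color and ordinary color clustering fails.

## The model

The unfolded image is a linear mixture

```
X = A S,   X ∈ [0,1]^{N×P},  A ∈ R_+^{N×M},  S ∈ {0,1}^{M×P},  1'S = 1'
```

whose binary source matrix has exactly one active component per pixel
(orthogonal rows). Difficulty is measured by the mutual coherence of the
mixing matrix,

```
μ(A) = max_{i≠j} |⟨a_i, a_j⟩| / (‖a_i‖‖a_j‖),
```

and its pairwise average μ_avg(A); the target regime has μ(A) > 0.999.
kernmix lifts each pixel spectrum into D non-physical channels with a
Gaussian **empirical kernel map** Ψ(x)_d = exp(−‖x − z_d‖²/(2σ²)) against
anchor spectra z_d drawn from the image. Binary/orthogonal sources make the
lift commute with mixing, Ψ(AS) = Ψ(A)S, so the lifted image obeys the same
model with a far less coherent mixing matrix — which sparseness-constrained
nonnegative factorization can then identify. Two engines are provided:
`nmf_l0()` (hard cap on nonzero coefficients per pixel, default 1) and
`nmu()` (recursive + joint nonnegative matrix underapproximation,
`U V ≤ X` elementwise), both finished by alternating exact minimization
under the one-component-per-pixel constraint.

## Worked example

Five-component phantom with nearly parallel profiles, 25 dB per-channel
noise, segmented by the kernel-lifted underapproximation pipeline:

```r
library(kernmix)

A <- synthetic_mixing_matrix()
coherence_stats(A)
#> mu = 0.9995, mu_average = 0.9956

ph  <- make_phantom(height = 128, width = 128, snr_db = 25, seed = 7)
res <- segment(ph$image, M = 5, method = "ekm-nmu",
               sigma2 = 0.1, dim = 20, seed = 7)
res
#> <segmentation_result> ekm-nmu, M = 5, 128 x 128 pixels
#>   physical space: mu = 0.9995, mu_average = 0.9958
#>   lifted space:   mu = 0.7964, mu_average = 0.3937

segmentation_accuracy(res$sources, ph$sources)
#> [1] 1
segmentation_accuracy(kmeans_lab(ph$image, M = 5, seed = 7), ph$sources)
#> [1] 0.9965820
```

The printed coherence pair is the method's core diagnostic: in the physical
RGB space the five estimated profiles are almost perfectly correlated
(μ = 0.9995 — unsegmentable by any color-space clustering), while in the
20 kernel channels the average correlation drops to ≈ 0.39, and the
factorization recovers the ground truth on every pixel; the CIE L\*a\*b\*
k-means baseline leaves stray errors. `colorize(res, path = "out.png")`
writes the region-colored (digitally stained) image; blue/red/green are the
default colors for the first three components.

A thin command line sits in `inst/scripts/kernmix`
(`segment`, `phantom`, `coherence`, `snr-sweep` subcommands).

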
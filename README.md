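# igwolf

An **improved grey wolf optimizer (IGWO)** for wrapper feature selection
and PSNR-guided image denoising, with the downstream watershed
segmentation chain used in lung-nodule CT pipelines — all at desk scale,
with seeded synthetic generators replacing any external dataset.

## Who this is for

Researchers studying swarm-based wrapper feature selection or
segmentation preprocessing who want a reproducible, dependency-light
reference implementation: the canonical grey wolf optimizer plus the two
improvements — genetic-algorithm population seeding and fitness-sharing
niching — applied to (a) selecting compact feature subsets under an
accuracy-versus-size objective and (b) tuning denoising filters by peak
signal-to-noise ratio. The deep CNN classifier such pipelines end with is
deliberately replaced by a pluggable evaluator (built-in: leave-one-out
1-nearest-neighbour), so everything runs in seconds on one CPU.

## The method in brief

Wolves are candidate solutions in a box; the three best (α, β, δ) steer
the pack via

    D_k = |C_k ∘ X_k − X|,   X_k' = X_k − A_k ∘ D_k,   X ← (X_1'+X_2'+X_3')/3

with A = 2a·r₁ − a, C = 2r₂, and a = 2 − 2t/T decaying linearly. For
feature selection, positions in [0,1]^N are stochastically binarized into
flag vectors each iteration and scored by

    Fitness = α·P + (1−α)·(N−L)/N        (α = 0.99)

where P is the evaluator's accuracy and L the subset size. GA seeding
initializes the pack; fitness sharing divides each wolf's fitness by its
niche count m_i = Σ_j max(0, 1 − d_ij/σ_s) before leaders are ranked,
preserving diversity. Defaults follow the reference configuration:
population 8, 100 iterations, crossover 0.8, mutation 0.01, 10×10-fold CV
for reported accuracy.

## Worked example

```r
library(igwolf)

ds  <- make_feature_dataset(seed = 1)   # 150 samples, 30 features, 5 informative
cfg <- optimizer_config(dimensionality = 30, seed = 1)
res <- run_igwo_selection(ds, config = cfg, final_cv = TRUE)
print(res)
#> IGWO feature selection result
#>   fitness 0.98447  accuracy 0.9867  selected 7 of 30 features
#>   repeated-CV accuracy 0.9820
#>   features: f1, f2, f3, f4, f5, f12, f21
```

All five planted informative features (`f1`–`f5`) are recovered; the
fitness 0.98447 = 0.99·0.9867 + 0.01·(30−7)/30 trades the 98.67%
leave-one-out accuracy against the 7-of-30 subset size, and the
repeated 10-fold cross-validation re-estimate is 98.2%.

Denoising and segmentation on a synthetic phantom:

```r
ph    <- make_phantom()                           # three bright disks
noisy <- add_noise(ph$image, "salt-pepper", 0.05)
opt   <- optimize_filter(noisy, ph$image,
           optimizer_config(dimensionality = 3, iterations = 8, seed = 0,
                            use_ga_seeding = FALSE, sharing_radius = "off"))
opt$noisy_psnr_db; opt$psnr_db                    # ~16.7 dB -> ~36 dB (median filter)

seg <- segment_nodules(ph$image)
seg$region_count                                  # 3, one per disk
```

## Command line

```sh
inst/scripts/igwo simulate features --out data.csv --seed 0
inst/scripts/igwo select --data data.csv --label-column class --seed 0 --out results/
inst/scripts/igwo simulate phantom --out img.pgm --mask mask.pgm --seed 0
inst/scripts/igwo denoise --in noisy.pgm --ref img.pgm --out filtered.pgm
inst/scripts/igwo segment --in img.pgm --out seg/
inst/scripts/igwo benchmark --out bench/ --seeds 0,1,2
```

Every run writes a `manifest.json` with the resolved configuration;
identical invocations are bit-identical. Images are plain-text PGM (P2).
Config files are flat `key: value` documents (keys: `population_size`,
`iterations`, `domain`, `seed`, `crossover_prob`, `mutation_prob`,
`fitness_alpha`, `sharing_radius`, …); unknown keys warn, deep-network
keys (momentum, batch size, …) are recorded but unused.

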
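# motionsalience

Movement-based animal signals — lizard push-ups, head-bobs, limb waves and
tail-flicks — must be detected against irrelevant image motion from
wind-blown vegetation. `motionsalience` simulates that problem end to end
and asks how signal effectiveness depends on display structure, habitat
structure and wind:

1. **Scene generation** (`generate_scene`): synthetic grayscale sequences of
   an articulated signaller performing one of four display archetypes
   (intermittent, continuous-rapid, continuous-low, ramping) amid textured
   distractor plants whose sway follows a ten-level wind controller; four
   habitat archetypes vary plant density, signaller–plant distance and wind
   gain. Every scene has a signal-only *baseline* twin.
2. **Motion analysis** (`detect_motion`, `motion_extent`, `signal_mask`):
   gradient-detector (normal-flow) motion maps, spatial-extent time series,
   and binary signaller masks derived from the baseline.
3. **Saliency** (`saliency_map`): a motion-channel graph-based saliency
   model — quadrature Gabor pyramids at 4 orientations x 9 dyadic scales
   (sampling ratios 1:1 to 1:256), opponent Reichardt correlation between
   successive frames, and two Markov-chain passes over image cells whose
   stationary distributions yield saliency maps in [0, 1]. For cells *i, j*
   at distance *d*, the activation chain uses edge weights

   w(i→j) = |log(f_i/f_j)| · exp(−d² / 2σ²)

   and the normalisation chain w(i→j) = a_j · exp(−d² / 2σ²).
4. **Performance** (`masked_salience`, `threshold_sweep`, `categorize`): the
   per-frame maximum salience inside the signaller mask, swept over a grid
   of receiver response thresholds τ ∈ (0, 1] to give P(τ) = proportion of
   the sequence with masked salience > τ, summarised in low / moderate /
   high threshold categories ([0, 0.3), [0.3, 0.8), [0.8, 1]).
5. **Ordination** (`dissimilarity_matrix`, `nmds`, `cluster_tightness`):
   Bray–Curtis dissimilarities between the performance vectors of all
   4 × 4 × 10 = 160 factorial cells, embedded by non-metric
   multidimensional scaling (`vegan::metaMDS`).

The package is aimed at researchers in motion ecology and visual signalling
who want a controlled, fully seeded test bed for display-in-noise questions.

## Worked example

```r
library(motionsalience)

spec <- scene_spec("INTERMITTENT_AM", "DENSE_CLOSE_AM",
                   wind_level = 5, seed = 42)
pair <- generate_scene(spec)
masks <- signal_mask(pair$baseline)
sal <- saliency_map(pair$composite)
series <- masked_salience(sal, masks)
pv <- threshold_sweep(series)
round(categorize(pv), 3)
#>      low moderate     high
#>    0.657    0.229    0.049
```

The numbers are the mean proportion of the 8-s sequence whose masked
salience strictly exceeds the thresholds in each receiver category: at mid
wind in its own densely vegetated habitat, the intermittent display still
clears undemanding receivers' thresholds for ~66% of the sequence, but only
~23% of it survives moderately demanding receivers — wind-blown plants
out-compete the lizard's movements in most frames — and highly selective
receivers would almost never attend (~5%).

The full analysis is organised as numbered drivers:

```sh
Rscript analysis/01_simulate_scenes.R    # scenes + wind-noise gradient check
Rscript analysis/02_display_structure.R  # temporal structure profiles
Rscript analysis/03_run_factorial.R      # 160-cell factorial (resumable)
Rscript analysis/04_ordination.R         # NMDS + cluster tightness
Rscript analysis/05_figures.R            # figures from the result tables
```

Each writes tidy CSV tables under `results/`.

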
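# ringmotion

Multi-scale inference of interaction rules in collectively moving animal
groups confined to a ring-shaped (annular) arena.

Groups of animals on a ring show a transition to collective motion: as
density grows, individuals increasingly circulate in one common direction.
Because motion on the ring is one-dimensional, each individual reduces to a
binary orientation — clockwise (CW) or anti-clockwise (ACW) — plus noisy
angular displacement. `ringmotion` is for researchers in collective
behaviour and movement ecology who want to go beyond reproducing the
large-scale pattern and ask *which individual-level interaction rule*
generated it, with the selected rule validated at both scales.

## What it computes

Every candidate rule specifies a latent **turning intensity**
λ — the log-odds that a focal individual reverses direction in one time
step — mapped to a probability by the logistic function
p = 1/(1 + e^(−λ)). Eleven rules are implemented:

* **Null** — λ = λ₀, no interaction; λ₀ is pinned at the logit of the
  direction-change rate in single-individual recordings.
* **MF** (mean field) — λ = λ₀ + w⁻ n⁻, with n⁻ the number of
  opposite-moving ("negative") individuals anywhere in the arena.
* **T** (topological) — as MF, but counting only the K nearest neighbours.
* **S1–S4** (spatial, Vicsek-like) — neighbours count only inside a
  zone of extent R: symmetric about the focal individual (S1, S3) or
  directed ahead (S2, S4); S3/S4 add a same-direction term w⁺ n⁺.
* **D1–D4** (non-Markovian) — as S1–S4, but each encountered neighbour
  leaves a memory trace that decays geometrically by α per step after the
  encounter and is erased when the focal individual turns. At α = 0.92 and
  7.5 Hz the trace half-life is ≈ 1.1 s.

The pipeline:

1. **`classifyOrientations()`** — a symmetric two-state Gaussian HMM
   (Baum-Welch with parameter tying, Viterbi decoding, 1-s despiking)
   turns noisy displacement series into CW/ACW sequences.
2. **`aisLogMarginal()` / `compareModels()`** — Bayesian marginal
   likelihoods via annealed importance sampling (1000 chains, 100
   tempered rungs by default), with MAP parameters extracted from the
   sampler's visited states. Marginal likelihood penalises complexity
   automatically, so models with more parameters must earn their keep.
3. **`simulateTrial()` / `validateModel()`** — a compiled forward
   simulator generates orientation dynamics under any rule; the
   distribution of final clockwise counts over trials is compared with the
   data by Kullback-Leibler divergence and a G-test
   (G = 2·m·KL against a χ² reference).
4. **`generateDataset()`** — synthetic tracking data with known ground
   truth (model-driven dynamics plus displacement-level observation
   noise), so the whole pipeline runs with no external data.

## Worked example

Generate a mean-field dataset, decode it, and let the evidence choose
between the non-interacting, mean-field and topological rules:

```r
library(ringmotion)
ds <- generateDataset("MF", presetParams("MF"), groupSizes = c(1, 6),
                      nTrialsPerSize = 8, duration = 180, seed = 1)
cls <- classifyOrientations(ds$trajectories, ds$trajectories[ds$groupSize == 1])
cls$params
#> HmmParams: pSwitch = 0.000371 mu = 0.09916 sigma = 0.0506

lambda0 <- estimateBaseline(cls$records[ds$groupSize == 1])   # -7.9
i6 <- which(ds$groupSize == 6)
prior <- priorSpec(lambda0, nAgents = 6)
fits <- compareModels(cls$records[i6], ds$trajectories[i6],
                      c("Null", "MF", "T"), prior,
                      aisSettings(nSamples = 200, nTemperatures = 50), seed = 2)
for (f in fits) print(f)
#> InferenceResult MF: log ML = -580.238 nats (-837.107 bits), MC se = 0.243
#>   MAP: ParamSet: lambda0 = -7.899, wNeg = 0.8265
#> InferenceResult T: log ML = -581.99 nats (-839.634 bits), MC se = 0.316
#>   MAP: ParamSet: lambda0 = -7.899, wNeg = 0.8265, K = 5
#> InferenceResult Null: log ML = -727.029 nats (-1048.88 bits), MC se = 0
#>   MAP: ParamSet: lambda0 = -7.899
```

Both interacting models crush the null (≈ 147 nats), recover the
generating strength (ŵ⁻ = 0.83, truth 0.76), and the topological model's
best K = 5 encompasses all neighbours — so it collapses onto the mean
field and is rejected purely by the Occam penalty of its extra parameter
(≈ 1.8 nats). Validating the winner at the large scale:

```r
od <- finalOutcomeDistribution(cls$records[i6])
od
#> OutcomeDistribution over 0..6 clockwise (8 trials):
#>     0     1     2     3     4     5     6
#> 0.750 0.125 0.000 0.000 0.000 0.000 0.125
v <- validateModel(od, "MF", mapParams(fits[[1]]), duration = 180,
                   nSets = 10, setSize = 100, seed = 3)
v$medianP      # 0.485 -> consistent with the data
```

Most trials end fully polarised (categories 0 and 6), and the fitted rule
reproduces that distribution (median G-test p = 0.49 over ten simulation
sets of 100 trials).

The eleven reference parameter sets are available via `presetParams(id)`,
and `presetRunConfig()` bundles the full study conditions (group sizes
1/3/6/12, 360-s trials at 7.5 Hz, the D3 memory rule as generator);
`runAnalysis()` executes the whole pipeline from one `RunConfig` and
`renderReport()` writes the per-model table as TSV.

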
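# tremorsdh

Texture features from 1D hand-motion signals for grading parkinsonian
tremor severity.

Postural and kinetic tremor in Parkinson's disease can be measured without
wearables: a leap-motion controller (LMC) tracks the hand contact-free at
sub-millimetre accuracy while the patient performs a short on-screen
push-ball task (40 samples/s for 15 s, 600 samples per hand). `tremorsdh`
implements the analysis for such recordings: it adapts the
**sum-and-difference-of-histograms (SDH)** texture technique from 2D images
to the 1D palm-trajectory signal, and classifies each analysis window into
MDS-UPDRS tremor levels 0 (normal), 1 (slight) or 2 (mild).

## The method

Let `V(l)`, `l = 1..n`, be the quantized palm-centre lateral position
`Cp(x)`. At displacement `M` (fixed to 1, the previous sample), define

```
VS(l) = V(l) + V(l-M),    VD(l) = V(l) - V(l-M),    l = M+1..n .
```

A window `D` of size `N = Card{D}` is slid along these vectors; within each
window the normalized sum and difference histograms are

```
ĥS(j) = hS(j)/N,    ĥD(k) = hD(k)/N ,
```

from which nine texture features are computed (mean, variance, energy,
correlation, entropy, contrast, homogeneity, cluster shade, cluster
prominence). The two headliners are

```
contrast    = Σ_k k² ĥD(k)            (discontinuity of displacements)
homogeneity = Σ_k ĥD(k) / (1 + |k|)   (similarity of displacements, ∈ (0,1])
```

A tremor oscillation spreads the difference histogram away from zero, so
contrast rises and homogeneity falls with tremor severity. Windows labelled
with the clinician-assigned level feed a repeated 70/30 evaluation (class
balancing by undersampling, 30 repetitions, min/mean/max of accuracy and
per-class precision/sensitivity/specificity) using bagged decision trees or
1-nearest-neighbour.

Because the underlying 20-patient clinic dataset is not public, the package
ships a synthetic cohort simulator that emulates the acquisition protocol
(hold 10 s, push 5 s, additive 4–6 Hz tremor whose amplitude grows with
level, Gaussian sensor noise, the published 39-recording cohort
composition), so the entire pipeline is testable end to end.

## Worked example

```r
library(tremorsdh)

rec <- simulate_recording(level = 2, hand = "right", seed = 42)
rec
#> <tremor_recording> patient sim, right hand, level 2, 40 sps, 600 samples

sdh_features(rec, N = 149)[1:3, c("window", "contrast", "homogeneity")]
#> # A tibble: 3 × 3
#>   window contrast homogeneity
#>    <int>    <dbl>       <dbl>
#> 1      1     628.      0.0769
#> 2      2     619.      0.0776
#> 3      3     621.      0.0776

cohort <- simulate_cohort(seed = 42)           # 39 recordings, levels 22/14/3
ds <- assemble_dataset(cohort, features = c("contrast", "homogeneity"), N = 449)
res <- repeat_evaluation(ds, bagged_trees(), reps = 10, seed = 42)
glance(res)
#> # A tibble: 1 × 6
#>   classifier    reps train_fraction accuracy_min accuracy_mean accuracy_max
#> 1 bagged_trees    10            0.7            1             1            1
```

A level-2 window has large contrast (~620 squared quantization levels here)
and homogeneity far below 1; on the synthetic cohort the two features
separate the three levels essentially perfectly at large windows, matching
the qualitative finding that they suffice for severity grading. The
severity-free palm-y/z channels stay near chance, which is what the
coordinate-selection experiment (`coordinate_selection()`) checks.

`autoplot()` methods draw recordings (palm trajectory), window sweeps
(accuracy vs window size) and coordinate-selection results. A thin CLI lives
at `inst/cli/tremorsdh` (verbs `simulate`, `extract`, `coordsel`,
`featsweep`, `winsweep`).

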
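# embentropy

Differential-entropy separability analysis for sequence embeddings, with a
full classifier-evaluation pipeline.

## The problem

Modern enhancer-identification pipelines embed DNA sequences with a
pre-trained language model, fine-tune the extractor for a number of epochs,
and classify the resulting feature vectors. Two practical questions follow:

1. **How separable are the two classes in embedding space at a given
   fine-tuning epoch?** Over-fine-tuning degrades generalisation, so a
   threshold-free, classifier-free diagnostic of class separability is
   valuable.
2. **Which epoch snapshot should feed the downstream classifier?**

`embentropy` answers both with differential entropy. For a point cloud
`X = {x_1..x_N}` in d dimensions, the Kozachenko–Leonenko (K-L)
nearest-neighbour estimator of the differential entropy `h(f) = −∫ f ln f`
is

```
H_N = d·ln ρ̄ + ln V_d + γ + ln(N − 1),      ρ̄ = (ρ_1 · … · ρ_N)^{1/N}
```

where `ρ_i` is the Euclidean distance from sample i to its nearest other
sample, `V_d = π^{d/2} / Γ(1 + d/2)` is the d-dimensional unit-ball volume
(always handled in log space — at d = 768 the linear-space volume is
~1e-297), and `γ ≈ 0.5772` is the Euler–Mascheroni constant. All logs are
natural; entropies are in nats. The package computes the algebraically
identical per-sample decomposition `h_i = d·ln ρ_i + ln V_d + γ + ln(N−1)`,
whose arithmetic mean is `H_N`, so each class has a *distribution* of
entropy contributions with a mean and a median.

At each epoch the package computes the class-conditional estimates for
positives and negatives and the gaps

```
Δmean   = |mean(h_i | y=1) − mean(h_i | y=0)|
Δmedian = |median(h_i | y=1) − median(h_i | y=0)|
```

A useful fine-tuning run shows a **coincidence–separation–coincidence**
trajectory: the gaps start near zero, peak at the epoch where the extractor
discriminates best, and collapse again as over-fitting sets in. The
**optimal epoch** is the argmax of Δmean (ties: larger Δmedian, then the
earlier epoch), with agreement of the Δmedian criterion reported as a
sanity flag.

The classifier layer evaluates five families on embedding snapshots —
RBF-kernel SVM, histogram and exact gradient-boosted trees, ridge logistic
regression, and k-nearest neighbours — under label-stratified 5-fold
cross-validation plus an independent test, reporting ACC, MCC, Sn, Sp, NPV,
P, auROC and auPRC.

## Worked example

```r
library(embentropy)

# simulate 11 epoch snapshots (epoch 0 = not fine-tuned) with a planted
# entropy-gap peak of 4 nats at epoch 6
sets <- simulate_trajectory(trajectory_config(seed = 42))

traj <- entropy_trajectory(sets)
sel  <- select_optimal_epoch(traj)
print(sel)
#> optimal epoch: 6 (delta_mean = 3.8424 nats; median criterion agrees)

# classify at the selected epoch
snap  <- sets[[sel$optimal_epoch + 1]]
parts <- stratified_split(snap, split_spec(test_fraction = 0.3, seed = 42))
cv <- cross_validate(classifier_spec("margin_kernel", seed = 42),
                     parts$train, folds = 5, seed = 42, test = parts$test)
print(cv)
#> 5-fold cross-validation, margin_kernel
#> CV mean:    ACC    MCC     Sn     Sp    NPV      P  auROC  auPRC
#> 0.9281 0.8238 0.8286 0.9691 0.9324 0.9189 0.9683 0.9455
#> independent test:    ACC    MCC     Sn     Sp    NPV      P  auROC  auPRC
#> 0.9345 0.8397 0.8667 0.9623 0.9461 0.9043 0.9752 0.9510
```

The selection finds the planted epoch; the estimated Δmean there (3.84
nats) is close to the planted 4-nat gap, and the SVM separates the classes
well because the simulator couples class-mean separation to the entropy
gap.

A command-line wrapper with the same workflow
(`simulate`, `entropy`, `trajectory`, `select-epoch`, `classify`,
`compare`, `split`, `summarize`) is installed at
`system.file("cli", "embentropy", package = "embentropy")`.

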
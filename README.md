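# gazelink

Model-based analysis of infant looking-time experiments.

Infant eye-gaze studies typically reduce rich session-level data to a few
test-trial preference scores and an ANOVA. `gazelink` instead treats the
whole session as data: every trial's dwell-time proportions over five
areas of interest (the four corner boxes of a cued multi-modal learning
display, plus everything else including off-screen) are linked to latent
cognitive quantities through a generative model, and those quantities —
not raw looking preferences — are what gets estimated and compared. It is
written for developmental researchers who want to ask *how fast* infants
learn a sound–location contingency, *whether* an attentional cue drives
their gaze, and *how many qualitatively different kinds of learners* a
sample contains, from data a standard analysis would call null.

## The model

For infant gaze matrix *x* (one row per trial on the 4-simplex), the
sound-contingent looking history is the Kronecker-delta-gated running sum
*H*<sub>t,i,s</sub> = Σ<sub>t′&lt;t</sub> δ(s<sub>t′</sub>, s) x<sub>t′,i</sub>,
and the sound-independent history H̄ sums over all past trials. Each
trial's concentration vector is an exponentiated linear combination of
interpretable factors,

```
η_ti = b_i + β_obj O_ti + β_cue C_ti + Σ_d a_d H_tis^d + Σ_d h_d H̄_ti^d
x_t ~ Dirichlet(exp(η_t))
```

with per-AOI baselines *b*, object and cue indicator slopes, and
arbitrary-degree polynomial association (*a*) and habituation (*h*)
learning functions (degree 2 by default, capturing linear and U-shaped
links between learning and looking). Infants are clustered by a Chinese
restaurant process mixture — each cluster owns one parameter vector — and
everything is fit by a seeded Metropolis-within-Gibbs sampler (compiled
core) under adaptive-sparseness priors that pin non-contributing
coefficients at zero. Coefficient decisions use 95% credible intervals
with a ±.001 buffer around zero; summaries are partition-based
(misclassification under optimal label matching, consensus clustering of
the posterior co-assignment matrix), so mixture label switching never
needs resolving.

Because the original infant recordings are not distributable, the package
ships a first-class synthetic-data generator for the paradigm (4 blocks ×
6 training + 1 test trials, two diagonal object configurations each bound
to a sound, optionally one cued box) and replication harnesses that
validate cluster recovery, parameter recovery, and learning-function
shape discrimination end to end.

## Worked example

Simulate twelve infants from two ground-truth groups and recover both the
partition and the parameters:

```r
library(gazelink)

gen   <- generate_sim1_dataset(n_infants = 12, n_groups = 2, seed = 42)
chain <- fit_gaze_model(gen$dataset, gen$design, fit_config(seed = 99))

modal_table_count(chain)
#> [1] 2
misclassification(chain, gen$truth$assignments)
#> [1] 0
consensus_partition(chain)
#> <cluster_summary> 2 consensus clusters
#>   cluster 1 (occupancy 50.0%): beta_object=-0.000, beta_cue=-0.002, a1=0.519, a2=0.000
#>   cluster 2 (occupancy 50.0%): beta_object=1.569, beta_cue=1.468, a1=1.495, a2=0.000
```

The generating groups had (β_obj, β_cue, a₁) = (0, 0, 0.5) and
(1.5, 1.5, 1.5): the sampler finds exactly two clusters, assigns every
infant correctly on every posterior sample (misclassification 0), pins
the first cluster's non-contributing object and cue slopes at zero, and
recovers the rest. Posterior uncertainty comes from the pooled cluster
samples:

```r
cs <- consensus_partition(chain)
a1 <- cluster_param_samples(cs, "a1", cluster = 2)
credible_interval(a1, .68)
#> [1] 1.434 1.512
nonzero_test(a1)
#> [1] TRUE
```

A thin command-line front end (`exec/gazelink`) exposes the same
machinery as `simulate`, `fit`, and `replicate sim1|sim2|sim3` commands
(with `--scale paper` for the full-size sampling budgets); the methods
vignette (`vignettes/linking-model.Rmd`) documents the model, priors,
sampler and validation design in detail.

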
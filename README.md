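# distressnet

Data-driven subtyping of psychological distress from ordinal symptom
questionnaires, with a semi-parametric symptom network per subtype.

Population screens such as the ten-item Kessler Psychological Distress
Scale (K10; items scored 1–5) are usually summarised by a sum score, which
hides both the *profile* of symptoms and how symptoms *co-occur*.
`distressnet` is for researchers in psychiatric epidemiology and network
psychometrics who want to (a) split a sample into subtypes without imposing
a diagnostic structure up front and (b) characterise each subtype by the
conditional-dependence network of its symptoms.

## The method

**Featurization.** With grand item means $\bar x_j$, respondent $i$ is
represented by the deviation cross-products
$(x_{ij}-\bar x_j)(x_{ik}-\bar x_k)$ for all item pairs $j<k$ — the unique
off-diagonal entries of a one-person covariance estimate
($p(p-1)/2 = 45$ features for $p = 10$). Averaged over respondents these
reproduce the biased sample covariances exactly, so k-means on them groups
people by how they co-deviate around the sample, not merely by severity.

**Clustering.** Lloyd's k-means with k-means++ seeding and restarts, over a
range of cluster counts with a WSS-versus-parsimony table (the choice of
$k$ is deliberately left to judgement; an elbow heuristic is offered as a
suggestion only). Cluster 1 is always the largest.

**Per-cluster networks.** On each cluster's raw responses: the
nonparanormal (Gaussian-copula) transform — midranks, shrunken empirical
CDF with truncation $\delta_n = 1/(4 n^{1/4}\sqrt{\pi\log n})$, normal
quantiles — followed by a graphical lasso on the correlation matrix along a
30-point penalty path, with extended-BIC selection ($\gamma = 0.5$) scored
on unpenalised refits. The precision estimate $\hat\Omega$ becomes a
partial-correlation network via
$\rho_{jk} = -\hat\omega_{jk}/\sqrt{\hat\omega_{jj}\hat\omega_{kk}}$.

**Comparison.** Node strength, closeness and betweenness (edge distance
$1/|\rho|$), network density (mean absolute edge weight over all pairs)
and connectivity (fraction of realised edges), plus pairwise two-sample
Kolmogorov–Smirnov tests of the centrality distributions.

A latent-Gaussian threshold simulator (`make_default_specs()`,
`simulate_responses()`) generates cluster-structured Likert data — unequal
severity strata with strong floor effects and cluster-specific sparse
precision matrices — so every stage is testable against known ground truth.

## Worked example

```r
library(distressnet)
specs <- make_default_specs(K = 5, p = 10, seed = 1)   # 5 severity strata
sim   <- simulate_responses(specs, seed = 101)         # 2000 respondents
fit   <- distress_subtypes(sim$responses, k = 5, seed = 1)
fit
```

```
Distress subtypes: 5 clusters over 2000 respondents (seed 1)

 cluster   n mean_sumscore sd_sumscore
       1 947         10.31      1.2745
       2 526         18.10      1.4277
       3 282         30.65      1.4489
       4 158         39.11      0.8594
       5  87         45.69      0.7822

Global network connectivity:
 cluster   n density connectivity n_edges
       1 947 0.01661       0.3556      16
       2 526 0.01662       0.2222      10
       3 282 0.00751       0.0889       4
       4 158 0.00774       0.0667       3
       5  87 0.00271       0.0222       1
```

Reading it: the clusters come out ordered by size, and their mean sum
scores (possible range 10–50) recover the generator's severity gradient —
a large low-distress cluster down to a small high-distress one. Density is
the mean absolute partial correlation over all 45 item pairs; connectivity
is the fraction of pairs with a nonzero edge after sparsification (the
small clusters support fewer estimable edges). Here

```r
adjusted_rand_index(fit$clustering$labels, sim$true_labels)
#> [1] 0.9867204
```

shows the generating partition is recovered almost exactly.
`summary(fit)` adds the most central symptoms per cluster and measure;
`coef(fit)` returns the partial-correlation matrices; `predict(fit, new)`
assigns new respondents to the fitted subtypes; `plot(fit, type = "scree")`
draws the WSS curve; and `write_results(fit, dir)` writes the full results
bundle (labels, WSS table, per-cluster matrices and edge lists,
centrality/connectivity/KS tables, report, manifest) as plain text,
byte-reproducibly. To analyse your own data, supply any $n \times p$
integer matrix (CSV readable via `read_responses()`).

See `vignettes/distress-subtyping.Rmd` for the model, the conventions
(distance, closeness, density denominators), the generator's design and the
method's known limitations.

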
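# diffggm

Differential network analysis for two-condition gene expression studies,
built on entrywise inference of Gaussian graphical models.

Correlation-based co-expression networks cannot separate direct from
indirect association. A Gaussian graphical model (GGM) can: two genes are
connected exactly when the corresponding entry of the precision matrix
(inverse covariance) $\Omega = \Sigma^{-1}$ is nonzero, i.e. when they
remain dependent after conditioning on all other genes. For a disease /
control design the scientific question is then how that conditional
dependence structure *changes*, and the answer is the **differential
network** $\Delta = \Omega_1 - \Omega_2$.

`diffggm` is for analysts who want per-edge statistical inference on
$\Delta$ in the high-dimensional setting ($p \gg n$), rather than a
heuristic comparison of two separately thresholded networks.

## Method

1. **Entrywise GGM estimation.** For each gene pair $\{i, j\}$ the two
   columns are regressed on the remaining $p - 2$ columns with the
   *scaled lasso* (tuning free: coefficients and noise level are estimated
   jointly, with penalty $\lambda_0 = \sqrt{2\log(p)/n}$), and the
   $2\times2$ residual Gram matrix is inverted to estimate
   $(\omega_{ii}, \omega_{ij}, \omega_{jj})$. The estimator is
   asymptotically normal with Fisher information
   $\hat F_{ij} = (\hat\omega_{ii}\hat\omega_{jj} + \hat\omega_{ij}^2)^{-1}$,
   giving each edge a z-score, p-value and partial correlation.
2. **Two-sample test.** Each entry is compared across conditions with

   $$W_{ij} = \frac{\hat\omega_{ij,1} - \hat\omega_{ij,2}}
     {\sqrt{\frac{\hat\omega_{ii,1}\hat\omega_{jj,1}+\hat\omega_{ij,1}^2}{n_1}
          + \frac{\hat\omega_{ii,2}\hat\omega_{jj,2}+\hat\omega_{ij,2}^2}{n_2}}}
     \;\sim\; N(0, 1) \text{ under } H_{0,ij}.$$

3. **FDR control.** The statistics are thresholded directly at
   $\hat t = \inf\{t \le 2\sqrt{\log p} :
   2(1-\Phi(t))\,\binom{p}{2} / \max(R(t),1) \le \alpha\}$
   (Benjamini–Hochberg on the p-values would assume independence); the
   surviving edges form the differential network, reported with its
   connected clusters.

The package also ships the simulator used to validate the method (hub,
scale-free and random graph pairs with controlled heterogeneity $\gamma$ =
group-specific / common edges) and a replication harness that scores
support recovery by AUC.

## Worked example

```r
library(diffggm)
set.seed(42)

# two conditions sharing a random graph, gamma = 0.5 heterogeneity
pair <- simulate_pair(graph_scenario("random", p = 60, n = 80, gamma = 0.5))
fit <- diffnet(pair$data1, pair$data2, alpha = 0.05, min_cluster = 3)
fit
#> Differential network analysis (pairwise mode)
#>   genes: 60;  samples: n1 = 80, n2 = 80
#>   FDR level alpha = 0.05;  threshold t_hat = 3.688
#>   rejected edges: 8 over 14 nodes;  clusters (>= 3 nodes): 2
```

Eight gene pairs clear the FDR threshold $\hat t = 3.688$ on $|W|$. The
edge table gives, per pair, both groups' precision entries and p-values,
the partial correlations with their own p-values, then the two-sample
statistic:

```r
summary(fit)
#> ...
#> Top differential edges:
#>  gene_i gene_j   omega1        p1    pcor1   pcor_p1   omega2        p2
#>     g38    g60 -1.25079 2.299e-06  0.70807 5.843e-37  0.46968 6.165e-02
#>     g43    g48  0.27599 1.567e-01 -0.16029 1.412e-01 -1.45364 7.343e-06
#>     g23    g32 -0.02942 8.590e-01  0.01941 8.621e-01 -2.00733 3.568e-06
#>      pcor2   pcor_p2      W    pvalue
#>  -0.218979 3.966e-02 -4.713 2.436e-06
#>   0.675842 9.210e-29  4.572 4.822e-06
#>   0.715761 2.299e-39  4.266 1.993e-05
#>   ...
```

Read the first row as: g38–g60 are strongly conditionally dependent in
condition 1 (partial correlation 0.71, p ≈ 6e-37) but not in condition 2,
and the difference is significant after FDR control (W = −4.71,
p ≈ 2.4e-06). `coef(fit)` returns the estimated $\Delta$ matrix,
`plot(fit)` draws the rejected-edge graph with widths proportional to
$|W|$, and `write_network(fit$edges, "edges.graphml")` exports it.

A command-line front end over the same functions lives in
`inst/scripts/diffggm.R` with subcommands `estimate`, `difftest`,
`simulate`, `benchmark` and `preprocess` (Illumina-style detection
p-value filtering and probe-to-gene averaging).

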
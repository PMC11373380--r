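# pcnt — hybrid PC-constrained continuous causal discovery

`pcnt` estimates a weighted causal DAG — which gene regulates which, with
signed linear effect sizes — from a purely observational expression matrix
(samples × genes). It is aimed at regulatory-network inference settings
where a few regulators (transcription factors, signalling proteins) drive
many downstream targets.

The method is a hybrid of two classical ideas:

1. **PC algorithm** (constraint-based): Fisher-z conditional-independence
   tests prune a complete graph to a skeleton (stable, order-independent
   search), v-structures are oriented from the separating sets, and the
   Meek rules complete the CPDAG — the Markov equivalence class of the
   causal DAG.
2. **Continuous acyclicity-constrained optimization** (the NOTEARS
   program): fit a linear structural equation model `X = XW + E` by

       min_W  (1/2n) ‖X − XW‖²_F + λ₁‖W‖₁   s.t.   h(W) = tr(exp(W∘W)) − d = 0,

   where the smooth function `h` vanishes exactly on acyclic supports, so
   the DAG constraint is handled with an augmented Lagrangian and L-BFGS-B.

The hybrid (`run_pcnt`, `bootstrap_aggregate`) converts the CPDAG into a
hard edge mask and solves the continuous program restricted to that
support: entries PC ruled out are held at exactly zero, and the
least-squares score resolves the remaining directions and estimates the
effect sizes. The package also ships the full benchmarking protocol
around the estimator: bootstrap edge aggregation, ground-truth subgraph
subsampling (5 regulators + 25 targets per repeat), graph metrics (SHD,
oriented F1, orientation accuracy, regulator AUROC/AUPRC, coefficient
correlation on true-positive edges), and a synthetic generator of sparse
regulator–target ground truths with linear-SEM data, so the whole system
is testable without external datasets.

## Worked example

Simulate a 30-gene regulator–target network, run the bootstrap-aggregated
hybrid, and score it against the known truth:

```r
library(pcnt)

cfg   <- sim_config(n_regulators = 5, n_targets = 25,
                    n_samples = 1000, seed = 42)
truth <- generate_star_dag(cfg)              # 5 regulators, 25 targets
x     <- simulate_linear_sem(truth, cfg = cfg)

g <- bootstrap_aggregate(x, "pcnt",
                         pcnt_config(n_bootstrap = 10, top_k = 40,
                                     seed = 42))
g
#> weighted_graph: 30 genes, 24 edges

evaluate_graph(g, truth)
#> evaluation_report
#>   shd                      1
#>   precision                0.9583
#>   recall                   1
#>   f1                       0.9787
#>   orientation_accuracy     1
#>   regulator_auroc          1
#>   regulator_auprc          1
#>   coefficient_correlation  0.9991
#>   n_true_positive_edges    23
```

The report reads: of the 24 aggregated edges, 23 are true edges with the
correct orientation (one structural error overall, `shd = 1`); every
shared adjacency points the right way (`orientation_accuracy = 1`); the
outgoing-weight score separates regulators from targets perfectly
(`regulator_auroc = 1`); and the estimated signed effects track the true
coefficients almost exactly (`coefficient_correlation = 0.999`) — e.g.
`R1 -> T10` estimated at 1.38 against a true effect of 1.49.

A command-line interface wraps the same pipeline
(`exec/pcnt run|evaluate|benchmark|simulate`); every run writes a JSON
manifest (config, seed, input checksums) sufficient to reproduce it, and
identical seeds give byte-identical outputs.

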
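# mirnet

Data-driven inference of miRNA→mRNA repression networks from matched
expression profiles, with local network enrichment analysis of the result.

miRNAs repress their targets post-transcriptionally, but sequence-based
target predictions are noisy and condition-blind, while marginal
expression correlation cannot represent several miRNAs jointly repressing
one gene — especially when miRNAs are co-expressed in clusters. mirnet is
for researchers with matched miRNA and mRNA profiles of the same samples
(tumor cohorts, time courses, perturbation panels) who want
condition-specific interactions and a functional reading of them.

## The method

For each candidate target gene *j*, mirnet regresses its expression on the
expression of the miRNAs that a prior target network (e.g.
TargetScan-style predictions) proposes as its regulators:

    ŷ_j = β_j0 + X⁽ʲ⁾ β_j ,   β_j ≤ 0   (repression only)

fitted as an elastic net, β̂_j = argmin ½s⁻¹‖y_j − β_j0 − X⁽ʲ⁾β‖² +
λ P_α(β) with P_α(β) = (1−α)/2 ‖β‖₂² + α‖β‖₁, subject to the negativity
constraint. The mixing parameter is tuned per gene from the *correlation
strength* of the candidate regulators,

    c(X) = sqrt( Σ_{i1<i2} ρ²_{i1i2} / ((n²−n)/2) ),   α_j = 10^(−c) ∈ [0.1, 1]

so correlated miRNA groups are retained together (ridge-like) while
feature selection is always active. λ comes from 10-fold cross-validation.
Strictly negative coefficients form the inferred bipartite network.

Local enrichment analysis (LEA) then scores the network: coefficients map
to edge weights w = exp(β/max|β|), genes are projected onto a gene–gene
graph through shared regulators (edge weight min over shared miRNAs of the
two weights' sum), all-pairs shortest paths are computed, and left-tailed
Wilcoxon rank-sum tests turn distance shifts into gene scores
S(v) = −log10(p), per-miRNA scores (sum over targets) and Bonferroni-
corrected term-level enrichment calls.

The package also ships the synthetic benchmark the method is evaluated
with (hidden-factor co-expressed miRNA groups, F1 against planted truth,
lasso and correlation baselines) and a Fisher's-exact validation of
inferred edges against an experimentally supported interaction list.

## Worked example

```r
library(mirnet)

# a synthetic instance: 20 miRNAs in 4 co-expressed groups, 5 true
# regulators of one target gene, 50 samples
inst <- simulate_instance(s = 50, sigma = 0.5, seed = 42)
dat  <- instance_data(inst)

fit <- infer_network(dat$mirna_expr, dat$mrna_expr, dat$prior, seed = 1)
fit
#> Inferred miRNA-target network
#>   10 repressive edges: 10 miRNAs -> 1 genes
#>   1 gene models fitted, 0 genes skipped (min lambda, 10-fold CV, seed 1)

f1_measure(fit$edges$mirna, inst$true_regulators)
#> # A tibble: 1 × 6
#>      tp    fp    fn precision recall    f1
#>   <int> <int> <int>     <dbl>  <dbl> <dbl>
#> 1     5     5     0       0.5      1 0.667
```

All five planted regulators are recovered (recall 1); five co-expressed
group mates of true regulators come along (precision 0.5) — the expected
behaviour of a grouped penalty on near-collinear clusters, discussed in
the methods vignette.

On a multi-gene network, the enrichment layer reads:

```r
res <- lea(fit_multi, read_gmt("pathways.gmt"))
res$terms          # term, p, Bonferroni-adjusted p, enriched flag
res$mir_scores     # per-term functional miR scores (heatmap: autoplot(res))
```

A command-line wrapper with subcommands `infer`, `lea`, `corstrength`,
`simulate`, `benchmark` and `validate` is installed under `exec/mirnet.R`;
every run writes a manifest (input checksums, parameters, seed, versions)
next to its outputs.

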
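# mirmod

Inference of **MRE-mediated miRNA–miRNA modulation networks** from paired
expression profiles, with bias-control comparator networks and
diagnostic/prognostic evaluation of miRNA signatures.

mRNAs that carry binding sites (microRNA response elements, MREs) for
several miRNAs compete for them: when such a transcript is abundant it
sequesters its targeting miRNAs, when scarce it releases them. Two miRNAs
sharing binding sites on one transcript are therefore expected to be
statistically coupled *conditionally on* that transcript's expression.
`mirmod` is for computational biologists who have a miRNA matrix, an mRNA
matrix over the same samples, and a miRNA→target interaction table, and
want the miRNA–miRNA network this competition implies — plus the controls
and downstream biomarker analyses that make such a network defensible.

## The statistic

For a miRNA pair $(d, r)$ and candidate modulator mRNA $m$:

$$\mathrm{MI}(d,r) = \sum_{d}\sum_{r} p(d,r)\log\frac{p(d,r)}{p(d)p(r)},
\qquad
\Delta \mathrm{MI}_{d,r/m} = \bigl|\mathrm{MI}(d,r) - \mathrm{MI}(d,r \mid m)\bigr|$$

estimated by plug-in MI on equal-frequency (rank-based) bins, with the
conditional term averaged over modulator strata. Per-triplet significance
comes from shuffling $m$ across samples (pseudocount empirical p-value);
p-values for one pair across its mediating targets are pooled with Fisher's
method, $X^2 = -2\sum_k \ln p_k \sim \chi^2_{2N}$, and pairs with combined
$p < \alpha$ (default $\alpha = e^{-5} \approx 6.7\times10^{-3}$) become
edges of an undirected miRNA network. Degree analysis flags hub miRNAs;
hypergeometric shared-target and Spearman correlation networks serve as
bias controls; signature evaluation covers SVM accuracy against a
random-signature null, PCA, clustering, fold-change differential
expression, and Kaplan–Meier/Cox survival of k-means risk groups.

A bundled synthetic-data generator (`simulate_dataset()`) produces paired
cohorts with planted modulation triplets, a planted hub, decoy target
edges, and an 11-miRNA diagnostic/prognostic signature, so the whole
pipeline can be validated against known ground truth. See the methods
vignette (`vignettes/modulation-networks.Rmd`) for the model, estimator
policy and design choices.

## Worked example

```r
library(mirmod)

cfg <- simulation_config(n_samples = 139, n_mirnas = 40, n_mrnas = 30,
                         n_true_triplets = 3, n_null_triplets = 3,
                         hub_triplets = 2, n_decoy_edges = 5, seed = 1)
sim <- simulate_dataset(cfg)
#> synthetic cohort: 139 samples, 40 miRNAs, 30 mRNAs, 6 planted triplets (3 true), 11 target edges

aligned <- align_samples(sim$mir, sim$mrna, sim$meta)
net <- infer_network(aligned$mir, aligned$mrna, sim$targets,
                     n_perm = 1000, seed = 1)
tidy(net)
#> # A tibble: 3 × 6
#>   mir_a  mir_b    x2   dof combined_p n_targets
#>   <chr>  <chr> <dbl> <int>      <dbl>     <int>
#> 1 miR-1  miR-3  13.8     2   0.000999         1
#> 2 miR-17 miR-6  11.6     2   0.00300          1
#> 3 miR-22 miR-3  10.2     2   0.00599          1
```

`miR-1`–`miR-3` is a planted modulated pair (the hub `miR-1` with one of
its anchors) recovered at the permutation floor $p = 1/1001$; the other two
edges are chance passes of the permissive $e^{-5}$ threshold over the ~430
candidate triplets — exactly the multiplicity behaviour the comparator
networks and the vignette discuss. The XOR fixture shows the statistic's
canonical worked example (marginally independent, perfectly coupled within
strata):

```r
fx <- make_xor_fixture(25)
delta_mi(fx$mir_a, fx$mir_b, fx$m, 2, 2, 2)
#> MI = 0.0000, MI|m = 0.6931, delta MI = 0.6931 nats (S = 2)
```

Signature evaluation on the same cohort (11 planted signature miRNAs,
tumor-vs-normal labels and recurrence survival from the generator):

```r
labels <- ifelse(aligned$meta$class_label == "normal", "normal", "tumor")
random_signature_null(aligned$mir, labels, sim$signature,
                      n_lists = 100, seed = 1)
#> signature accuracy 0.950 vs random-signature mean 0.856 (n = 100), empirical p = 0.009901

survival_analysis(aligned$mir, sim$signature, aligned$meta, seed = 1)
#> risk groups (low vs high signature expression): HR 2.92 (95% CI 1.72-4.95), log-rank p = 3.3e-05, 62 events
```

The signature classifies better than every random 11-miRNA list (p at the
pseudocount floor), and the k-means risk split separates recurrence hazards
(the generating hazard ratio, 4.9, lies inside the fitted CI; at this small
cohort the point estimate is attenuated by grouping noise).

`run_pipeline(out_dir)` chains all stages and writes TSV/SIF/GraphML/JSON
outputs; `inst/cli/mirmod` exposes `simulate`, `infer`, `compare`,
`evaluate` and `pipeline` subcommands over the same functions.

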
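# hypercore

Voxel-wise functional brain networks on the hyperbolic disc, and the k-core
structure hiding inside them.

Resting-state fMRI gives every gray-matter voxel a BOLD time series. Treating
voxels as nodes and strong positive Pearson correlations as edges yields, per
subject, a large sparse graph whose heavy-tailed degree structure suits a
*geometric* description: the S1/H2 model assigns each voxel an angular
coordinate θ (functional similarity) and a radial coordinate r (popularity —
hubs sit near the disc centre), and connects pairs with the Fermi law

p(d) = 1 / (1 + exp((β/2)(d − R̂)))

of their hyperbolic distance d (law of cosines on the disc), where β > 1
controls clustering and R̂ is the outermost radius. On that disc, the *angular
coherence* of a labelled voxel group — the mean resultant length
ξe^{iφ} = (1/N) Σₖ e^{iθₖ} — measures how functionally compact a subnetwork
is. Independently of the geometry, *k-core percolation* (iteratively pruning
voxels of degree < k) peels the graph to its innermost non-empty core, the
k_max-core; counting which subnetworks those surviving voxels belong to
classifies subjects as DMN-dominant, VN-dominant or distributed, and voxels
recurring across subjects form a common core.

The package is aimed at researchers who want this pipeline — network
construction under scale-freeness/largest-component threshold selection,
maximum-likelihood S1/H2 embedding, circular statistics, k-core percolation,
and core-composition profiling — as tested, scriptable R functions, plus
synthetic generators (S1 graphs with known coordinates, block-correlated BOLD
cohorts, planted cores) that make every stage verifiable without imaging data.

## Worked example

Embed a synthetic S1 network with known ground truth, then run the k-core
pipeline on a synthetic cohort subject:

```r
library(hypercore)

s   <- sample_s1_network(n = 500, gamma = 2.5, mean_degree = 10,
                         beta = 2.5, seed = 1)
lcc <- largest_component(s$graph)$graph
emb <- hyper_embed(lcc, seed = 1)
print(emb)
#> S1/H2 hyperbolic embedding: 499 nodes
#>   beta = 2.379, R_hat = 17.064, curvature = 1
#>   log-likelihood = -3915.90 after 30 sweep(s)

al <- align_embeddings(s$truth$theta_true[as.character(emb$voxel_id)], emb)
round(al$similarity, 3)
#> [1] 0.974
```

The fitted β (2.38) sits near the generator's 2.5, and after resolving the
disc's rotation/reflection symmetry the inferred angles agree with the
planted ones at circular similarity 0.974 (1 would be perfect, ~0.04 is the
independence level at n = 500).

```r
coh <- make_cohort(cohort_spec(seed = 1))   # 3 DMN / 3 VN / 3 distributed
sub <- coh[[1]]
res <- analyze_subject(sub$bold, sub$labels)   # threshold 0.4 -> LCC -> k-core
print(res$profile)
#> k_max-core composition [functional-7]: k_max = 33, core size = 34
#>   DMN      34  (100.0%)
#>   SN        0  (0.0%)
#>   ...
#> pattern: DMN-dominant
```

This subject's 34-voxel k_max-core (coreness 33) lies entirely in the DMN
block — above the 40% dominance cutoff, so the subject is classified
DMN-dominant, matching the generator's intent. `group_coherence()`,
`flag_data()`, `common_core()` and the `plot_*` functions cover the
coherence, flag-plot, common-core and figure outputs; `write_edge_list()`,
`write_embedding()`, `write_decomposition()` and `write_profile()` persist
every artifact as plain text with faithful round-trips.

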
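# ntdp — semi-nonparametric modeling of topological domains from histone marks

Topologically associating domains (TADs) are contiguous genomic intervals,
typically hundreds of kilobases, whose loci interact preferentially in 3D
chromatin contact (Hi-C) data. Individual histone modifications correlate
with TAD boundaries but predict them poorly on their own. `ntdp` is an R
package for epigenomics researchers who want to (a) learn how
*combinations* of histone-modification densities relate to domain
boundaries, interiors, and inter-domain gaps, and (b) predict a full
non-overlapping TAD partition of a chromosome **from histone data alone**
— useful for cell types and species with no Hi-C.

## The model

A binned track (e.g. 40 kb bins) is a linear chain in which every bin
takes one of three roles relative to a partition
`D = {[s1,e1], [s2,e2], …}` of domains of length ≥ 2 bins: boundary
(**b**, a domain's first or last bin), interior (**i**), or inter-domain
(**e**). For each mark *m* and role *p*, a Bernstein polynomial of degree
*A* maps the mark's normalized density to an additive score:

    f_pm(x) = Σ_{i=0}^{A} w_pm[i] · C(A,i) x^i (1−x)^{A−i},   x ∈ [0,1]

Summing over marks gives per-bin role scores `E_b[v], E_i[v], E_e[v]`; a
partition scores

    F(D) = Σ_{[s,e]∈D} ( c̄_b (E_b[s]+E_b[e]) + c̄_i Σ_{v=s+1}^{e−1} E_i[v] )
         + c̄_e Σ_{v∉D} E_e[v],        P(D | H) = exp(F(D)) / Z,

a conditional random field with continuous, nonparametrically shaped
features (`c̄` are inverse-frequency class weights). The normalizer `Z`
sums over every valid partition via an exact four-state (domain-start,
interior, domain-end, gap) forward recursion in log space. Training
minimizes the convex objective

    −log L(W) + λ₁ Σ_p (Σ_m ‖w_pm‖₂)² + λ₂ Σ_{p,m} ∫ f_pm''(x)² dx,

where the squared block-ℓ1 penalty zeroes whole marks (identifying a
small informative subset) and the curvature penalty — an explicit
quadratic form in the Bernstein weights — keeps effect functions smooth.
The nonsmooth group term is handled through its Cauchy–Schwarz surrogate
and alternating optimization (closed-form scale updates + L-BFGS), with
optional monotone/concave/nonnegative shape constraints as linear systems
on the weights. Prediction maximizes the partition score exactly by
O(n²) dynamic programming over the interval graph of candidate domains.
Partitions are compared by normalized variation of information
(NVI = VI / log n; 0 = identical, lower is better) against a
length-preserving domain-shuffle null.

## Worked example

The package ships a generator that builds corpora with the model's own
statistical structure — known informative marks, TAD-like domain lengths —
so everything below runs with no external data.

```r
library(ntdp)

# a corpus with known structure: 8 tracks x 500 bins, 12 marks (4 informative)
fx <- makeFixtureCorpus(syntheticSpec(seed = 1))
corpus <- fx$corpus
corpus
#> TrainingCorpus: 8 track(s), 12 marks, 4000 total bins

# hold out the last track, train on the rest
train <- TrainingCorpus(corpusTracks(corpus)[1:7],
                        corpusPartitions(corpus)[1:7], mMax = mMax(corpus))
fit <- fitAlternating(train, tadHyperparams(lambda1 = 10, lambda2 = 0.5,
                                            tol = 1e-8, maxOuterIters = 60))
fit
#> TADFit: 34 outer iteration(s), converged, objective 375.88
#>   selected marks: inf01, inf02, inf03, inf04, noise01

signif(apply(modelWeights(fittedModel(fit)), 2, function(w) sqrt(sum(w^2))), 2)
#>   inf01   inf02   inf03   inf04 noise01 noise02 noise03 noise04 noise05 noise06
#> 8.3e-01 1.1e+00 8.9e-01 9.7e-01 5.5e-06 5.7e-08 0.0e+00 2.2e-08 2.7e-08 0.0e+00
#> noise07 noise08
#> 5.7e-08 1.5e-07

# predict domains on the held-out track from histone signal alone
H <- corpusTracks(corpus)[[8]]
truth <- corpusPartitions(corpus)[[8]]
pred <- inferPartition(H, fittedModel(fit))
pred$partition
#> DomainPartition 'sim08': 14 domains over 500 bins (85.0% covered)

# agreement with the true partition, against a length-preserving null
c(nvi_model   = nvi(truth, pred$partition),
  nvi_shuffle = nvi(truth, shuffleDomains(truth, seed = 7)))
#>   nvi_model nvi_shuffle
#>  0.02828082  0.30406462
```

Reading the output: the group-lasso fit retains exactly the four
informative marks — the largest surviving noise-mark weight norm is about
5e-6, versus ~1 for the informative marks (the `show` method lists any
mark above a 1e-6 threshold, which is why `noise01` is named). On the
held-out track, the predicted partition sits at NVI 0.028 from the truth,
an order of magnitude closer than the 0.304 achieved by a shuffle that
preserves the true domain lengths — the marker signal, not generic length
structure, is what the model exploits.

Real data enter through standard formats: per-mark bedGraph coverage is
binned with `binCoverage()` (then `logTransform()`, replicate averaging),
density matrices are TSV (`readMarkerMatrix()`), and domain calls from
any external TAD caller are BED3 (`readDomainsBed()`). A thin
command-line wrapper over these functions is installed at
`system.file("cli/ntdp.R", package = "ntdp")` with subcommands `bin`,
`train`, `infer`, `evaluate`, `simulate`. Hyperparameters are tuned with
`nestedCV()`; minimal mark subsets are identified with
`selectMinimalSubset()` (greedy BIC) or `enumerateKSubsets()` (exhaustive
small-subset scans).

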
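# lumpability

Statistical tests for whether a nucleotide substitution process stays
Markovian after recoding.

## The problem

Phylogenetic studies often *recode* nucleotide sequences onto a smaller
alphabet — most commonly RY-recoding, which merges the purines {A, G} into R
and the pyrimidines {C, T} into Y — to focus on transversions or to damp
compositional heterogeneity. Recoded data are then analysed with a 2- or
3-state Markov model. That step silently assumes that the aggregated
(*lumped*) process is itself Markovian. It usually is not: a Markov process
is **strongly lumpable** for a partition of its state space only under
specific parameter constraints, and when they fail, analyses of recoded data
can return biased branch lengths and distorted trees.

This package is for molecular phylogeneticists who want to *test* lumpability
before recoding. It works on pairs of aligned homologous sequences evolving
under stationary, reversible, homogeneous (SRH) conditions, and extends to
multi-taxon alignments by testing all pairs.

## The model and the tests

For two homologous sequences the data are a 4×4 **divergence matrix** N of
site-pattern counts, multinomial with probabilities F(1), the joint
distribution of a reversible process with rate matrix R = SΠ, where
Π = diag(π) holds the stationary base frequencies (order A, C, G, T) and S
the six exchangeabilities s = (s_AC, s_AG, s_AT, s_CG, s_CT, s_GT). Writing
Π½SΠ½ = LΛLᵀ,

    P(t) = Π^-1/2 L e^{Λt} L^T Π^1/2,   F(t) = Π^1/2 L e^{2Λt} L^T Π^1/2,

and the nine free parameters (3 in π, 6 in s) have the closed-form estimator
Π̂ = diag(rowSums(F̂)), Ŝ from the spectral decomposition of Π̂^-1/2 F̂ Π̂^-1/2,
with F̂ = (N + Nᵀ)/2n.

A recoding scheme is one of the **13 partitions** of {A, C, G, T} into 2 or 3
blocks (R, Y, S, W, M, K; B, D, H, V; RY, SW, KM). For membership matrix V
and frequency-weighted collapse U, lumpability is equivalent to
VUP(t)V = P(t)V, and equivalently to two linear constraints C(π)s = 0 on the
exchangeabilities. Three tests of that null are provided:

* **Index test** — η, the Frobenius norm of the defect M = VUP̂(1)V − P̂(1)V,
  with a parametric-bootstrap p-value;
* **Markov-chain test** — a χ² comparison of observed vs expected
  block-aggregated transition counts, df = (q−1)Σ(γ_k−1) = 2 for every
  scheme;
* **Likelihood-ratio test** — 2·(L(π̂, ŝ) − L(π̃, s̃)) against χ²₂, where
  (π̃, s̃) is the constrained MLE under C(π)s = 0.

Simulation drivers measure test calibration and power, and quantify the
branch-length bias of recoding: for a lumpable scheme all distances shrink
uniformly by the scale factor ρ (the ratio of original to lumped expected
substitution rates); for a non-lumpable scheme the distortion is not uniform.

## Worked example

```r
library(lumpability)

model <- readModelParameters(system.file("extdata", "params_bias.json",
                                         package = "lumpability"))
model
#> SubstitutionModel (SRH, reversible; R = S*Pi)
#>   pi: A=0.2 C=0.3 G=0.2 T=0.3
#>   s:  AC=0.2 AG=0.1 AT=0.3 CG=0.3 CT=1 GT=0.2

lumpabilityDefect(model, "RY")$eta   # 4.9e-16  -> RY-lumpable
lumpabilityDefect(model, "KM")$eta   # 0.234    -> not KM-lumpable

set.seed(1)
aln <- simulateAlignment(system.file("extdata", "sim_tree_synthetic.nwk",
                                     package = "lumpability"), model, 3000)
N <- pairDivergenceMatrix(aln, "t1", "t5")
likelihoodRatioTest(N, "RY")
#> Likelihood-ratio test for lumpability
#>   scheme: RY
#>   statistic = 3.41124, df = 2, p-value = 0.1817
likelihoodRatioTest(N, "KM")
#> Likelihood-ratio test for lumpability
#>   scheme: KM
#>   statistic = 228.926, df = 2, p-value = 1.947e-50

expectedSubstitutionScale(model, "RY")
#> [1] 2.566667
```

The model is lumpable for RY but not for KM, and the tests on simulated data
say exactly that: RY-recoding this alignment is statistically safe (its
branch lengths shrink uniformly by 1/ρ = 1/2.57), while KM-recoding would
violate the Markov assumption. For a full alignment, `allPairsTests()`
returns one row per sequence pair and `ppPlotData()` summarizes the p-values
for a PP-plot; `srhScreen()` first checks the SRH assumption itself via the
matched-pairs test of symmetry.

A thin command-line front end is included:

```sh
Rscript inst/scripts/lumpability.R test-all-pairs --aln aln.fasta \
    --scheme RY --method lrt --seed 1 --out results.tsv
```

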
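# IBDemog

Demographic inference from the genetic-length spectra of IBD segments and
runs of homozygosity (ROH), for population geneticists studying founder
events with modern — and optionally ancient — genomes.

A bottleneck of diploid effective size *N<sub>b</sub>* that started
*T<sub>b</sub>* generations ago and lasted *d* generations leaves a
distinctive excess of identical-by-descent haplotypes of intermediate
genetic length.  IBDemog turns that footprint into parameter estimates:

* **Model.** A piecewise size history — constant ancestral size
  *N<sub>a</sub>*, bottleneck (*N<sub>b</sub>*, *T<sub>b</sub>*, *d*),
  exponential expansion to *N<sub>c</sub>* — or a two-subpopulation
  variant in which the population splits at *T<sub>b</sub>* into a
  subgroup of size *N<sub>b</sub>* and one of size
  *N<sub>a</sub> − N<sub>b</sub>* that merge again with proportions *f*
  and 1 − *f* at the end of the bottleneck.
* **Coalescence.** Discrete-generation TMRCA distributions
  q(u) = h(u)·Π<sub>v&lt;u</sub>(1 − h(v)) with hazard h(u) = 1/(2N(t)),
  supporting ancient sampling times, a no-sib-mating constraint, and a
  first-cousin consanguinity mixture.
* **Expected counts.** Conditional on separation time *t* (a = 2t per
  Morgan), the density of shared-segment lengths on a chromosome of length
  *L* is [a²(L − ℓ) + 2a]·e<sup>−aℓ</sup> plus a whole-chromosome atom
  e<sup>−aL</sup>; bin integrals are closed-form and marginalized over the
  TMRCA distribution.
* **Inference.** Poisson composite likelihood across length bins;
  modern-IBD and ancient-ROH datasets combined on a per-pair scale so each
  data type contributes comparably; differential-evolution maximum
  likelihood with parametric-bootstrap confidence intervals and
  bootstrap likelihood-ratio model selection.
* **Synthetic data.** A seeded generator for study-shaped count tables and
  a segment-level Monte-Carlo simulator that serves as an independent
  oracle for the analytic expectations.
* **Auxiliary statistics.** Exact two-tailed binomial and Fisher tests,
  binomial founder-allele simulations for pseudo-haploid ancient samples,
  and the per-generation continuous gene-flow bound
  m = 1 − (1 − X)<sup>1/G</sup>.

## Worked example

Expected IBD segment counts for a modern cohort of 637 diploid genomes
(810,264 haplotype pairs) under a bottleneck model, a synthetic observed
table, and a maximum-likelihood refit:

```r
library(IBDemog)

m <- SinglePopModel(Na = 10000, Nb = 1563, Tb = 41, d = 20, Nc = 1e6)
spec <- SamplingSpec(mode = "IBD")
lambda <- expectedBinCounts(m, spec, defaultGenomeMap(), defaultIBDBins(),
                            P = pairCount(637, "IBD"))
round(lambda)
#>   [4,5)   [5,6)   [6,7)   [7,8)   [8,9)  [9,10) [10,11) [11,12) [12,13)
#>  540978  296895  168790   98559   58860   35864   22258   14054    9021
#> [13,14) [14,15)
#>    5881    3893

counts <- sampleCounts(m, spec, defaultGenomeMap(), defaultIBDBins(),
                       P = pairCount(637, "IBD"), seed = 42,
                       nIndividuals = 637)
fitModel(counts, "single", seed = 1)
#> FitResult (single model): per-pair loglik -0.000091
#>   Na   = 8449.17
#>   Nb   = 1534.89
#>   Tb   = 39.1776
#>   d    = 18.0187
#>   Nc   = 943552
```

The fit recovers the generating bottleneck size within 2% and the onset
within 2 generations from one Poisson draw at this cohort size.  The
half-million segments in the first bin are segments of 4–5 cM summed over
all pairs; counts fall roughly geometrically with length because long
segments require recent coalescence.

The exact tests and the gene-flow bound print on the scale used in
reports:

```r
binomialTestTwoTailed(11, 31, 0.20)          # 0.04137601
fisherExactTwoTailed(7, 6, 2, 8)             # 0.1967963
100 * perGenerationReplacementBound(0.04, 20) # 0.2039018 (% per generation)
lineageFrequency(11, 31, percent = TRUE)      # 35
```

`generateStudy()` produces a matched modern-IBD + ancient-ROH synthetic
study (ancient cohort sampled 26 generations before present), and
`runPipeline()` drives read/simulate → fit → bootstrap → model selection
from a YAML configuration, persisting seeded, hash-stamped JSON outputs.

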
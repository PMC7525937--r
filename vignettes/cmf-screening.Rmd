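---
title: "Screening genomes against a core set of minimal functions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genomes against a core set of minimal functions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the model behind
each statistic, the conventions adopted where several defensible choices
exist, how the synthetic cohort generator was parameterized, and what the
test suite does and does not establish about real data.

## The screening model

A **core set of minimal functions (CMF)** is a reference list of gene-level
functions that every self-sufficient bacterium is expected to carry. It is
derived from two or more annotated minimal genomes in two steps
(`build_cmf()`):

1. **Certainty filter** — gene calls whose product contains an uncertainty
   marker ("hypothetical", "putative"; case-insensitive substring,
   configurable) are dropped, along with keys on a user-maintained
   exclusion list. The exclusion list is the reproducible stand-in for
   manual curation: it is a version-controlled input, empty by default,
   rather than an undocumented by-hand step.
2. **Intersection** — records are mapped to canonical keys and only keys
   present in every reference genome are retained.

**Key normalization** (`normalize_key()`) decides what counts as "the same
function" everywhere in the package. Matching is by string identity, not
homology: a CDS is identified by its lowercased gene symbol with any
trailing `_<n>` multi-copy suffix removed, falling back to a normalized
product string when no symbol was assigned. Symbols are the more stable
identity across runs of the same annotator; the product fallback covers
annotations that carry no symbols at all. tRNAs are keyed by isotype only
(`trna-ala`), so isoacceptors with different anticodons count as one
function — the presence question is "can this genome charge alanine", not
"does it carry this particular anticodon". rRNAs are keyed by subunit
(`rrna-16s` etc.), tmRNA is a single constant key. Multi-copy genes
collapse: the entire analysis is presence/absence.

**Coverage vs adherence.** Two complementary percentages appear:

* `genome_cmf_coverage()` — what fraction of a genome's *own* distinct keys
  belong to the core set. The denominator counts *all* annotated features,
  certain or not. A denominator restricted to certainty-filtered genes
  would also be defensible; we chose the all-features denominator because
  coverage answers "how much of this genome's annotated content is core",
  and an uncertain call is still annotated content.
* `adherence()` — what fraction of the core set a genome carries,
  `100·Σx/m`. This is the per-genome screening statistic.

**Screened genomes are not certainty-filtered.** The filter exists to keep
dubious calls out of the *reference* set; once the reference is fixed, a
gene confidently named in a draft genome counts as evidence of presence
even if its product string contains a flagged word (e.g. a symbol-bearing
CDS annotated "conserved hypothetical protein"). This asymmetry is
deliberate and configurable by pre-filtering the input if the caller
disagrees.

## Group statistics

All tests are implemented from their definitions and cross-checked in the
test suite against the corresponding base-R functions and against
brute-force enumeration oracles.

* **Kruskal–Wallis** uses midranks, the standard tie correction
  `H / (1 − Σ(t³−t)/(N³−N))`, and a χ² reference with g−1 degrees of
  freedom. For total N ≤ 8 the p-value is exact, by enumerating every
  assignment of the pooled observations to groups of the observed sizes.
* **Mann–Whitney rank-sum** is two-sided; exact by enumeration when
  N ≤ 12 with no ties (assignments whose U deviates from n₁n₂/2 at least
  as much as observed), otherwise a normal approximation with
  tie-corrected variance and continuity correction.
* Both rank tests are reported side by side by the pipeline for the
  two-group adherence comparison: the two are near-equivalent there, and
  reporting both removes any ambiguity about which one a reader should
  compare against.
* **Fisher's exact test** (2×2) uses the *point-probability* two-sided
  rule: sum the hypergeometric probabilities of all tables with the same
  margins whose probability does not exceed the observed table's, with a
  relative tolerance of 1e−7 on the comparison (the convention of R's
  `fisher.test`). Other two-sided conventions (doubling the one-sided
  tail) exist and give different numbers; the choice is documented here
  precisely because it is a convention.
* **Kendall's tau-b** uses quadratic-time vectorized pair counting with
  the standard tie terms, and the tie-corrected normal approximation on
  S = C − D. For the cohort sizes this package targets (~10³ genomes) the
  O(n²) computation is exact and takes milliseconds.
* **No multiple-testing correction** is applied anywhere: the pipeline
  reports a handful of planned tests, not a gene-wise scan.

## Distances, clustering, ordination

* **Jaccard binary distance** `1 − a/(a+b+c)` ignores joint absences —
  appropriate for presence/absence where shared lack of a gene is not
  evidence of similarity. Two all-absent profiles have distance 0 by
  convention, with a warning. **Binary Euclidean** distance is
  `sqrt(hamming)`.
* **Ward clustering** follows the Ward.D2 convention: Lance–Williams
  updates on squared distances, heights reported unsquared. Ties are
  broken deterministically by merging the candidate pair with the
  lexicographically smallest cluster indices, so results are reproducible
  across platforms. On Jaccard input the variance interpretation of Ward
  is heuristic (Jaccard is not Euclidean-embeddable in general), but the
  algorithm is well-defined; the cluster–source contingency table and
  Fisher's exact test do not depend on any variance reading.
* **PCA** operates on the column-centered, unscaled binary matrix via SVD.
  Centering preserves pairwise row distances, so full-rank score distances
  equal the binary-Euclidean distances exactly (asserted to 1e−9 in the
  tests) — this is what "PCA based on Euclidean distances" means here, and
  it is why we factor the data matrix rather than double-center the
  distance matrix. Scaling columns would up-weight rare genes; we do not
  scale. Axes are oriented so each axis's largest-magnitude loading is
  positive, removing sign indeterminacy.
* **Logistic PCA** models the binary matrix as Bernoulli with natural
  parameters Θ = 1μ′ + UV′, rank-constrained. The fit minimizes
  Σ log(1+exp(Θ)) − X∘Θ by majorization–minimization with the quadratic
  bound of curvature 1/4: each iteration forms Z = Θ + 4(X − σ(Θ)) and
  projects it onto the model set, which reduces to column means plus a
  truncated SVD of the centered Z (the truncated SVD of a column-centered
  matrix is itself column-centered, so the joint projection is exact).
  Every step provably does not increase the objective; the trace is stored
  and asserted monotone in the tests. The default initialization is the
  deterministic SVD of the saturated surrogate 4(2X−1); a random start is
  available and requires a seed. This algorithm was chosen over
  gradient-based alternatives for its determinism and provable descent.
* **PERMANOVA** uses the standard partition of squared distances and the
  permutation p-value `(1 + #{F_perm ≥ F_obs})/(1 + B)`. When the number
  of *distinct* label assignments is at most B+1 the implementation
  switches to complete enumeration, making the p-value exact (and equal to
  the enumeration oracle in the tests). The seed is a required argument:
  a permutation p-value without a recorded seed is not reproducible.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be tested against
known ground truth. Its model: genome *i* in a group has true completeness
`c_i ~ Beta(α, β)`; core gene *j* is present with probability `c_i·q_j`,
where `q_j` is a per-gene detectability; `Poisson(λ)` decoy genes are added
from a fixed contaminant vocabulary (10% of the pool is "hypothetical
protein", exercising the certainty filter); the reported completeness
estimate is `clamp(100·c_i + N(0, σ), 0, 100)`. One master seed spawns one
sub-seed per genome, so a genome is identical whether drawn alone or
inside a cohort, and cohorts are byte-identical across runs.

`paper_like_cohort_spec()` fixes the generator's reference conditions: two
groups emulating an isolate-assembly cohort and a MAG cohort whose
adherence distributions centre near 93% (low spread) and 68% (high
spread), a 16S-like key recoverable in only ~20% of MAG-like genomes, four
additional systematically hard core genes, and an adherence–completeness
Kendall tau of ~0.6 within the MAG-like group. The parameters were derived
analytically and fixed once:

* Mean adherence is `100·E[c]·mean(q)`. For the MAG-like group we set
  `mean(q) ≈ 0.905` (a 0.85–1.0 ramp across genes, plus the hard genes)
  and `E[c] = 0.75`, giving 67.9%; for the isolate-like group
  `mean(q) ≈ 0.969` and `E[c] ≈ 0.962`, giving 93.2%.
* The adherence SD decomposes into binomial noise
  (`100·sqrt(p(1−p)/m)` ≈ 1.9 and 3.4 points at m = 183) plus the spread
  of `c`; Beta shapes (66.3, 2.66) and (13.75, 4.58) give total SDs near
  2.9 and 9.5.
* A 16S-like detectability of 0.267 under `E[c] = 0.75` yields ~80%
  missingness; hard-gene detectability 0.18 yields ~85%.
* For two noisy views of `c` (adherence with binomial noise, completeness
  with Gaussian noise σ), the Kendall tau of a bivariate-normal
  approximation is `(2/π)·asin(ρ)`; solving for tau ≈ 0.6 within the
  MAG-like group gives σ ≈ 5.5 percentage points. The isolate group uses
  σ = 1.5.

What the generator **does not** emulate: sequence-level artifacts (no
FASTA, no assembly chimerism), phylogenetic correlation between genomes
(draws are i.i.d. within a group), correlated gene loss (presence is
independent across genes given `c_i`), and the empirical per-gene deficit
profile of real MAG cohorts, which it approximates only qualitatively with
a smooth ramp plus designated hard genes. Tests passing on this cohort
therefore validate the *pipeline's statistics and bookkeeping*, not any
biological claim about real MAG collections.

## Problem sizes and numerical conventions

The test suite runs on deliberately small instances: enumeration oracles
up to N = 8 (hundreds of fuzz cases), null-calibration with 1,000
replicates at n = 15 + 15, planted matrices of 40×60, and a reference
cohort of 400 + 1,000 genomes × 183 functions for parameter recovery —
sizes at which every check is exact or Monte-Carlo-tight while the whole
suite stays fast. The acceptance script uses the 400 + 1,000 cohort with
999 PERMANOVA permutations.

Other conventions: sample (n−1) standard deviations in all "± SD"
summaries; completeness ties at the 90% high-quality threshold go to the
high-quality stratum ("equal or greater"); adherence and coverage are
reported to one decimal; CMF entries are sorted with C-locale (radix)
ordering so the reference set is locale-independent; all file round trips
(presence matrix, CMF table) are bit-exact and tested as identities.

## Known limitations

* Function matching is string identity after normalization. Annotator
  version drift (renamed products, changed symbols) degrades matching
  silently; deriving the CMF and screening with the *same* annotator
  version is the intended workflow.
* The certainty filter is a substring heuristic; products like
  "UPF0054 protein" pass it despite being uncharacterized.
* Jaccard + Ward is a pragmatic pairing, not a variance-exact one (see
  above).
* The logistic PCA MM algorithm converges monotonically but, like all
  non-convex factorizations, to a local optimum; the deterministic SVD
  initialization makes results reproducible, not globally optimal.
* PERMANOVA assumes exchangeability of genomes under the null; with
  phylogenetically structured cohorts that assumption is generous.
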
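---
title: "Clustering subjects on whole-genome SNV sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering subjects on whole-genome SNV sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(snvclust)
library(dplyr)
```

## The idea

Whole-genome sequencing yields, for each subject, the complete set of
single nucleotide variants (SNVs) they carry — common polymorphisms and
private mutations alike. snvclust operationalizes a simple hypothesis:
subjects who share more same-position SNVs are more similar, and a whole
cohort can therefore be *clustered* on nothing but these sets. The
motivating application is a case/control cohort (e.g. major depressive
disorder patients and ethnically matched controls, with a second population
serving as an outgroup) in which the case group is expected to group
together in the resulting tree.

The pipeline is: per-subject, per-chromosome SNV sets from VCF → pairwise
Jaccard distances → a neighbor-joining cluster tree per chromosome (or
genome-wide) → a formal evaluation of whether each labeled group forms a
clade.

## The distance

For two subjects with SNV sets $S_1$ and $S_2$ on a given scope (one
chromosome, or the whole genome),

$$J(S_1, S_2) = 1 - \frac{|S_1 \cap S_2|}{|S_1 \cup S_2|}.$$

$J$ is 0 for identical sets, 1 for disjoint ones, and — unlike many
alignment-derived dissimilarities — a true metric: it satisfies the
triangle inequality, so distance-based tree building is on solid ground.
Two conventions had to be fixed:

* $J(\emptyset, \emptyset) = 0$: two empty sets are equal, and this avoids
  the $0/0$ form. Real cohorts never meet this case.
* Distances are exact rationals of set cardinalities evaluated in double
  precision; property tests that probe the triangle inequality allow a
  $10^{-12}$ slack for float roundoff, far below any distance of interest.

**What counts as "the same SNV"?** The default identity key is
`(chromosome, position)` — the same-position notion the hypothesis is
phrased in. An allele-aware mode (`mode = "allele"`, keys
`(chromosome, position, ref, alt)`) is available for sensitivity analysis;
it refines positions into one key per alternate allele, so position-only
sets are exactly the allele-dropped image of allele-aware sets.

**Which genotypes count as carrying an SNV?** A subject possesses a
variant iff their genotype contains at least one called alternate allele
(`0/1`, `1/1`, `1|2`, ...). Missing (`./.`) and hom-ref genotypes count as
absent. Zygosity is deliberately ignored: the method works on sets, not
dosages. Multi-allelic records are decomposed per alternate allele, and
only single-nucleotide alleles (REF and ALT both one of A/C/G/T) are kept
— INDELs never enter the sets. All records are accepted by default
(`pass_only = TRUE` restricts to `FILTER` ∈ {`PASS`, `.`}), since upstream
pipelines differ in what they leave in the FILTER column. Chromosome
labels are normalized (`chr1` ≡ `1`, `M` → `MT`) so cohorts called against
differently-styled references unify.

## The tree

`neighbor_joining()` is a from-scratch implementation of the Saitou–Nei
agglomerative algorithm: at each step the pair minimizing
$Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$ is joined, branch
lengths follow the canonical closed forms, and the final three clusters
meet at a trifurcating node, giving an unrooted binary tree. NJ assumes no
molecular clock, is $O(n^3)$, and is *exact* on additive matrices — the
validation suite exploits this by generating random trees, feeding NJ
their path-length matrices, and requiring recovery of topology and branch
lengths to $10^{-12}$ up to $n = 50$.

Numerical choices, all silent in the standard description and fixed here
for determinism:

* **Tie-breaking.** When several pairs share the minimal $Q$, the pair
  with the lexicographically smallest (row, column) position in the
  current working order is joined. Identical inputs therefore always
  produce byte-identical Newick output.
* **Negative branch lengths** are kept by default (faithful NJ estimates).
  `clamp_negative = TRUE` zeroes a negative estimate and moves the deficit
  onto its sister branch (the Kuhner–Felsenstein convention), preserving
  the path length through the join and the total tree length.
* Trees are `ape`-compatible `phylo` objects, so the whole `ape`/`phangorn`
  toolbox (plotting, rerooting, comparisons) applies directly.

## Reading the tree: what "groups together" means

Published cluster trees are usually read visually. To make the reading
testable, snvclust formalizes "group X clusters together" as: *some edge
of the unrooted tree separates exactly X from all other leaves* (X is one
side of an edge bipartition). This is equivalent to monophyly after
rooting at an outgroup whenever the outgroup is itself a clade, and it is
symmetric — a subset and its complement are clades together.

`separation_report()` evaluates every population against the full tree
and every case/control group against the tree restricted to its own
population (other populations pruned, degree-2 nodes suppressed), since
between-population structure would otherwise dominate the within-population
question. For groups that fail, it reports the minimum number of leaves
whose removal would make the group a clade ("misplaced" subjects). That
minimum is computed exactly in $O(\text{edges} \times \text{leaves})$
rather than by search: every split of a pruned tree is the restriction of
an edge split of the original tree, so it suffices to scan each edge's
bipartition in both orientations and count the leaves that disagree with
treating one side as the group. The brute-force enumeration over removal
sets is retained in the test suite as an oracle.

## The descriptive layer

`count_snvs()` tabulates per-subject, per-chromosome set sizes;
`group_summary()` and `boxplot_stats()` summarize them (and demographic
columns) by group. Two conventions matter:

* **The two-sample test.** `welch_t_test()` defaults to Welch's
  unequal-variance statistic with Welch–Satterthwaite degrees of freedom.
  In the packaged 25-subject cohort table the two populations' total-SNV
  standard deviations differ by more than tenfold (≈37k vs ≈413k), which
  is precisely the regime where the pooled test is invalid; Welch
  reproduces the cohort's published p-value of 2.09e-15 while the pooled
  variant (also implemented, `var_equal = TRUE`) gives a very different
  number. `log10_p` is emitted alongside so extreme p-values remain
  comparable after underflow.
* **Age summaries** report both SD conventions: `sd_pop` (divisor $n$)
  and `sd_sample` (divisor $n-1$). The divisor-$n$ form is what the
  cohort table's printed age SDs (8.15 and 7.36) correspond to, so it is
  the headline column; the sample SD is always emitted next to it.
* **Boxplot statistics** are Tukey five-number summaries
  (`stats::fivenum`): hinges are medians of the data halves, matching what
  a default boxplot draws.

## The synthetic cohort generator

No suitably structured public cohort exists at desk scale, so
`simulate_cohort()` generates one with exactly the statistical structure
the method assumes, and nothing more:

* two (or more) populations, each with a shared pool of common variant
  positions drawn once without replacement — pools are disjoint, which
  makes cross-population distances approach 1 and reproduces outgroup
  behavior;
* within a focal population, a case-enriched pool carried with different
  probabilities by cases and controls (defaults 0.9 vs 0.1 — strong
  enrichment);
* per-subject private variants at a per-bp rate;
* output as a sorted, valid multi-sample VCF 4.2 with contig headers and
  `0/1` genotypes, plus a truth manifest. A fixed seed makes the VCF
  byte-identical across runs.

The default configuration mirrors a 25-subject two-population cohort at
roughly 1/1000 genome scale: 15 focal-population subjects (10 cases, 5
controls) expected to carry ≈7,800 variants each against ≈3,900 for the
10 outgroup subjects — the same 2:1 burden contrast the full-scale cohort
shows at ≈7.7M vs ≈3.9M total SNVs.

`expected_jaccard()` is the analytic companion: with per-site inclusion
probabilities $p_i, q_i$ it returns
$\hat J = 1 - \sum_i p_i q_i \,/\, \sum_i (p_i + q_i - p_i q_i)$, the
ratio-of-expectations approximation (private variants of two subjects are
treated as never colliding). This is not the expectation of the ratio, but
with pools in the hundreds-to-thousands the bias is well below the
Monte-Carlo spread; the test suite bounds it empirically at the per-mille
level for the configurations used.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: linkage disequilibrium (sites are
independent; the Jaccard metric ignores linkage anyway), realistic allele
frequency spectra (pool carriage is uniform per pool), mutation/coalescent
processes, zygosity structure, sequencing error, and call-set artifacts.
The recovery experiments show the pipeline is *correct* under its own
model, not that real case groups separate.

## Validation experiment sizes

The property experiments run at sizes chosen to exercise the asymptotics
while staying desk-scale: $10^4$ random set triples for the metric axioms;
additive-matrix recovery up to $n = 50$ leaves; and $2 \times 100$ seeded
end-to-end replicates (simulate → VCF → extraction → distances → NJ →
clade evaluation) of a 25-subject, two-chromosome, 500 kb cohort — one
hundred with strong case enrichment (0.9 vs 0.1), where the case clade is
required in ≥95% of replicates, and one hundred with zero enrichment,
where the case-clade rate is compared against a label-permutation estimate
of the chance rate (both are ~0: a fixed 10-of-15 subset essentially never
forms a clade in an unstructured tree).

## Limitations

* The clade criterion is one formalization of a visual reading; trees can
  be "nearly separated" in ways a binary flag hides — the misplaced-leaf
  count is the graded companion.
* No statistical significance is attached to clustering (no permutation
  test on labels); the report is structural.
* Mitochondrial scope is treated like any chromosome; real mitochondrial
  variant sets are tiny and their trees correspondingly unstable.
* Serialization writes branch lengths at 6 decimal places; path lengths
  re-read from Newick are faithful to the serialized precision (each edge
  quantized by at most $5 \times 10^{-7}$), and the PHYLIP matrix writer
  uses 15 significant digits so matrices round-trip beyond 12 digits.
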
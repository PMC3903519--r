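# snpcycle

Network phenotyping of multilocus SNP genotypes via k-partite graph cycles.

## The problem

Sets of tightly linked SNPs — like the six polymorphisms of the CTLA-4 gene
region (CT60, AG49, CT318, JO27, JO30, JO31) — often show no marginal
case/control differences at any single locus or haplotype, yet the *pattern*
of allele-state co-occurrences across loci can still discriminate cohorts or
outcome groups. snpcycle is for geneticists and biostatisticians who want to
analyze those relationship patterns directly.

## The method

A subject's genotype over L loci becomes a closed path (cycle) through a
k-partite graph: one allele-state vertex per locus (two states `a`/`b` under
the dominant model, or three states `a`/`ab`/`b` with zygosity), visited in a
fixed cyclic locus order. Summing all subjects' cycles gives a weighted
**study graph** *g* (or *G* for three states) whose edge weights count
allele-state co-occurrences of adjacent loci; edge weights divided by pair
totals estimate the conditional probabilities P(state<sub>k+1</sub> |
state<sub>k</sub>).

The study graph is then greedily decomposed into **reference cycles** of
equal edge weight (widest/maximum-bottleneck cycle first), each with a
multiplicity; on the two-state graph these play the role of haplotypes and
multiplicity/n is a haplotype-frequency estimate, cross-checkable against the
package's EM estimator under Hardy–Weinberg equilibrium. Each subject is then
described by edge-mismatch graph distances d<sub>1</sub>…d<sub>K</sub> from
the K reference cycles (0 ≤ d ≤ L), and by all K(K−1)/2 pairwise differences
Δ<sub>ij</sub> = d<sub>i</sub> − d<sub>j</sub> (190 for K = 20). Cohorts are
compared through per-pair cohort means of Δ (off-diagonal points in the
case-mean vs control-mean plane discriminate; a ±0.5 band is ignored),
through *absence markers* (subjects at the maximal distance L from a specific
reference share no edge with it), through cross-validated decision-tree
classification on the distance vectors, and through a survival threshold scan
(default 800–1900 days) that dichotomizes patients and Welch-tests every Δ
pair between the short- and long-surviving groups.

Because no subject-level genotype data are published for this design, the
package includes a first-class synthetic-cohort generator: HWE diplotype
draws from a strong-LD haplotype pool (default: the five published CTLA-4
haplotypes, frequencies 46.99 / 29.34 / 9.77 / 6.49 / 2.81 %, renormalized),
optional cohort pool biases and absence constraints, and group-dependent
survival with a planted change point.

## A worked example

```r
library(snpcycle)
library(dplyr)

loci   <- ctla4_loci()
cohort <- simulate_cohorts(loci, n_case = 60, n_control = 60, seed = 7)

cycles        <- personal_cycles(cohort, loci, coding = "two_state")
graph         <- build_study_graph(cycles)
decomposition <- greedy_decompose(graph)
tidy(decomposition)
#> # A tibble: 6 × 5
#>    rank pattern     haplotype multiplicity frequency
#>   <int> <chr>       <chr>            <dbl>     <dbl>
#> 1     1 a-b-b-b-b-b GGCTGG              56    0.467
#> 2     2 a-a-a-a-a-a AACCAT              26    0.217
#> 3     3 b-a-b-b-b-b AGTTGG              14    0.117
#> 4     4 a-a-b-b-b-b AGCTGG               9    0.075
#> 5     5 a-a-b-a-a-a AGCCAT               8    0.0667
#> 6     6 b-b-b-b-b-b GGTTGG               7    0.0583

tidy(em_fit(cohort, loci))
#> # A tibble: 5 × 3
#>   haplotype frequency     se
#>   <chr>         <dbl>  <dbl>
#> 1 AACCAT       0.496  0.0323
#> 2 GGCTGG       0.308  0.0298
#> 3 AGTTGG       0.0958 0.0190
#> 4 AGCTGG       0.0625 0.0156
#> 5 AGCCAT       0.0375 0.0123

deltas <- cycles |>
  distance_vectors(decomposition) |>
  delta_differences()
cohort_mean_deltas(deltas) |> arrange(desc(diag_distance)) |> head(3)
#> # A tibble: 3 × 6
#>   pair      i     j case_mean control_mean diag_distance
#>   <chr> <int> <int>     <dbl>        <dbl>         <dbl>
#> 1 d2-d3     2     3     0.517         1.6          0.766
#> 2 d3-d5     3     5    -0.717        -1.62         0.636
#> 3 d2-d6     2     6     0.833         1.7          0.613
```

The decomposition table reads: rank 1 is the two-state pattern
`a-b-b-b-b-b` in the cycle order CT318→AG49→CT60→JO30→JO27→JO31, i.e. the
dominant-coding pattern of every carrier of the `GGCTGG` haplotype (56 of
120 subjects — dominant coding counts carriers, so this exceeds the EM
*chromosome* frequency 0.308 of the same haplotype). The delta-means table
ranks reference pairs by perpendicular distance from the y = x diagonal;
`d2-d3` says cases sit on average 0.52 slots closer to reference 3 than to
reference 2, controls 1.6 — the most cohort-discriminating pair in this
small simulation.

`run_pipeline()` chains the whole analysis (encode → study graph →
decomposition → distances → Δ → discrimination → survival scan when
survival columns are present) and writes CSV/JSON reports plus a run
manifest; `inst/cli/snpcycle.R` wraps it for shell use with `simulate`,
`run` and `odds` subcommands.

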
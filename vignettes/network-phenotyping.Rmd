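---
title: "Network phenotyping of multilocus SNP genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network phenotyping of multilocus SNP genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcycle)
library(dplyr)
```

## The model

snpcycle analyzes the *relationships* among the allele states of a small set
of linked SNPs rather than each SNP marginally. A subject's genotype over L
loci is encoded as a closed path through a k-partite graph: each locus is a
partition holding one vertex per allele state, and the subject's cycle visits
exactly one vertex per partition in a fixed cyclic locus order, closing from
the last locus back to the first. Two codings are supported:

* **two-state** (`a` = no minor allele, `b` = at least one minor allele) —
  the dominant model, under which heterozygous and homozygous-minor
  genotypes act alike;
* **three-state** (`a`, `ab`, `b`) — full zygosity.

Summing all subjects' cycles gives the **study graph**: each subject adds
weight 1 to each of its L edges, so for each adjacent locus pair the edge
weights count allele-state co-occurrences, and row-normalizing a pair's
weight matrix estimates conditional probabilities
P(state at the next locus | state at this locus).

Because per-pair totals and vertex in/out balance are conserved, the study
graph is a nonnegative circulation and can be decomposed into **reference
cycles** of equal edge weight. The decomposition is greedy and widest-first:
repeatedly take the candidate cycle with the largest bottleneck (minimum
edge weight along the cycle), subtract that bottleneck from its edges, and
record the cycle with the removed weight as its multiplicity. On two-state
graphs these reference cycles play the role of haplotypes and
`multiplicity / n` estimates a haplotype frequency, which is why the package
also ships a conventional EM haplotype-frequency estimator under
Hardy–Weinberg equilibrium as an independent cross-check.

Downstream, each subject is described by the vector of **edge-mismatch
distances** of their cycle from every reference cycle (the number of the L
edge slots at which the two cycles differ; a Hamming-type metric bounded by
L), and by all pairwise **distance differences**
Δ<sub>ij</sub> = d<sub>i</sub> − d<sub>j</sub> (K references give K(K−1)/2
of them; 20 references give 190). Δ carries directionality: positive means
closer to reference j, negative closer to reference i, zero equidistant.
Cohorts are compared by the per-pair cohort means of Δ (the 2D
discrimination plot, where non-discriminating pairs sit on the diagonal
y = x and pairs with both means inside a ±0.5 band are discarded), by an
**absence marker** (the subset of subjects whose cycle shares no edge with
a designated reference, i.e. sits at the maximal distance L), by
cross-validated decision-tree classification on the distance vectors, and —
when survival data are present — by a threshold scan that dichotomizes the
cohort and tests every Δ pair between the two survival groups.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `coding` | `two_state` | state space per locus; three-state graphs have 3^L candidate cycles |
| `weight_unit` | 1 | weight a subject adds per edge (subject-level construction) |
| `graph_mode` | `subject` | `dosage` switches to allele-dose products d<sub>x</sub>·d<sub>y</sub>/2, 2 chromosome-equivalents per subject per pair |
| `tol` (decomposition) | 0 for integer weights | residual tolerance; dosage weights are halves, also exact in binary floating point |
| `min_abs` (discrimination) | 0.5 | half-width of the non-informative band around zero mean Δ |
| `alpha` | 0.05 | per-pair significance level; BH-adjusted p-values are always co-reported |
| `lo, hi, step` (scan) | 800, 1900, 10 days | survival threshold grid |
| `folds` | 10 | stratified cross-validation folds |

## Numerical and design choices

**Candidate enumeration.** With at most 3^6 = 729 candidate cycles the
widest cycle is found by scanning all candidates with all-positive edges;
no widest-path dynamic program is needed at this scale. Ties on the
bottleneck are broken by fewer non-`a` states, then lexicographically
(`a < ab < b`), so extraction is deterministic.

**Backtracking.** Pure widest-first extraction can strand weight: the
residual circulation stays balanced but its only closed walks wrap the
partitions more than once, and no single-wrap cycle has all-positive edges.
Since every study graph is by construction a sum of single-wrap personal
cycles, an exact decomposition always exists, so the extractor is
depth-first in the greedy preference order and backs up when a branch
dead-ends (with memoization of failed residuals and an early dead-end test:
every positive edge must lie on at least one viable candidate). The
non-degenerate path is identical to plain greedy.

**Subject-level vs dosage weighting.** The subject-level `+1` construction
is the package default and matches the two-state haplotype reading exactly
on cohorts of homozygous diplotypes. The dosage construction spreads a
double heterozygote's weight over all four edges of a pair (d=1 at both
loci puts 0.5 on each edge), which discards phase information: on cohorts
with many multi-locus heterozygotes its decomposition frequencies are
systematically compressed relative to EM, which resolves phase through
linkage disequilibrium. The two agree exactly whenever phase is unambiguous
(homozygous diplotypes), and that equality — together with EM parameter
recovery on simulated HWE cohorts — is what the test suite pins down.

**EM.** Initialization is uniform over the haplotypes compatible with at
least one subject (not all 2^L), convergence is a 1e-8 max frequency change
with a 1000-iteration cap, the observed-data log likelihood is asserted
non-decreasing at every step, and final frequencies below 1e-6 are dropped
and renormalized. Standard errors use the binomial approximation
sqrt(f(1−f)/2n).

**Threshold scan objective.** The scan picks the statistically most
significant split: smallest minimum p over the Δ pairs, then more
significant pairs, then balance, then the smallest threshold. The
significant-pair count is deliberately *not* primary: the Δ features are
strongly correlated, so the count saturates and gains or loses borderline
pairs essentially at random under small changes of the split, whereas the
minimum p-value tracks the planted change point sharply on simulated
cohorts. Welch's t-test is the default per-pair test (Mann–Whitney by
flag); degenerate zero-variance pairs return p = 1 when means agree and
p = 0 otherwise.

**Logistic survival model.** Fit by maximum likelihood; perfect separation
is detected from fitted probabilities reaching both boundaries and triggers
a warning plus a ridge-penalized fallback with a small fixed penalty, so
odds remain finite and reproducible.

## The synthetic-data generator

No subject-level genotype data accompany the method, so every stage is
exercised on simulated cohorts built to have the statistical structure the
method assumes:

* **Diplotype sampling under HWE.** Each subject is two independent draws
  from a haplotype pool. The default pool is the five published CTLA-4
  haplotypes with frequencies 46.99, 29.34, 9.77, 6.49, 2.81 percent,
  renormalized from their 95.4% total to 1 rather than padded with an
  invented residual haplotype. This pool encodes strong linkage
  disequilibrium — the two-state cycle space holds 64 possible haplotypes
  but 95% of chromosomes use five of them.
* **Cohort sizes** default to 286 cases / 288 controls, the design of the
  melanoma study the method was developed on.
* **Absence construction.** A configurable fraction of cases is drawn only
  from diplotypes whose two-state cycle avoids every vertex of a designated
  reference cycle; the rest come from the complement, so the constrained
  fraction is an honest Bernoulli rate.
* **Survival.** Group membership (short/long around a threshold, default
  1820 days with a 145/137 split) follows a logistic latent score on one
  designated Δ feature; the `n_short` highest scores are short survivors,
  so planted splits are exact. Survival days are uniform below the
  threshold for short survivors and uniform on
  (threshold + `gap_days`, `max_days`] for long survivors. The gap (default
  30 days; 100 in the planted-recovery tests) makes the change point
  identifiable to the scan's resolution — with events arbitrarily close
  above the threshold no finite scan grid could pin it down — and a
  `max_days` close to the threshold keeps the long-side event density high
  enough that moving one scan step dilutes the groups measurably.
  `effect = 0` or `noise → ∞` reduce to a null generator.

What the generator does *not* emulate: genotyping error and missingness,
recombination or mutation (the pool-draw model *is* the HWE assumption the
EM makes), population stratification, censoring (all events are observed,
as in the dichotomized analysis), and any marginal case/control frequency
differences unless a biased case pool is requested. Passing tests therefore
demonstrate the machinery's correctness and calibration under the model's
own assumptions, not robustness to those real-data complications.

Problem sizes used by the test and acceptance suites — cohorts of 200–600
for decomposition conservation (100 seeded replicates), n = 1000 for EM
recovery, n = 282 for the threshold scan, n = 574 for classification, 100
replicates for null calibration — were chosen to make sampling error small
relative to the tolerances being asserted.

## A worked run

```{r example}
loci <- ctla4_loci()
cohort <- simulate_cohorts(loci, n_case = 60, n_control = 60, seed = 7)

cycles <- personal_cycles(cohort, loci, coding = "two_state")
graph <- build_study_graph(cycles)
decomposition <- greedy_decompose(graph)
tidy(decomposition)

em <- em_fit(cohort, loci)
tidy(em)

deltas <- cycles |>
  distance_vectors(decomposition) |>
  delta_differences()
cohort_mean_deltas(deltas) |>
  arrange(desc(diag_distance)) |>
  head(3)
```

The dominant two-state pattern `a-b-b-b-b-b` is the dominant-coding shadow
of the strong-LD pool: every heterozygous carrier of the second haplotype
collapses onto it, which is why its multiplicity exceeds the EM frequency
of any single haplotype — the two columns answer different questions
(genotype-pattern frequency vs chromosome frequency).

## Known limitations

* The decomposition is one exact decomposition, reached in greedy
  preference order; alternative optimal decompositions are not enumerated,
  and no global minimality of the component count is claimed.
* Dosage-mode decompositions are not comparable to EM frequencies on
  heterozygote-rich cohorts (see above); use them where chromosome-level
  totals, not phase, are what matters.
* The dichotomized survival analysis ignores censoring by design; event
  flags are carried but no hazard model is fit.
* The decision-tree classifier is a pruned CART, not a reimplementation of
  any particular historical tree learner; its acceptance properties are
  behavioral (separable cohorts classified, permuted labels at chance).
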
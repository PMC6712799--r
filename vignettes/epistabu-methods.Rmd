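---
title: "Detecting epistasis with a genetic-tabu Bayesian network search"
author: "epistabu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting epistasis with a genetic-tabu Bayesian network search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistabu)
```

## The problem

Genome-wide association studies test loci one at a time, so a pair of
SNPs whose *joint* genotype drives disease risk while each locus alone
shows no marginal effect — pure epistasis — is invisible to single-locus
scans. `epistabu` searches for such interactions in case-control data by
learning a Bayesian network over the SNP nodes plus a binary phenotype
node (`Class`, 1 = case), and then reading candidate interactions off the
learned structure: SNP pairs adjacent to the phenotype node.

## The model and the score

A network is a directed acyclic graph (DAG) coded as a 0/1 adjacency
matrix `C` with `C[i, j] = 1` when node *i* is a parent of node *j*.
Given data with `m` samples, a structure `G` is scored by the
decomposable Bayesian Information Criterion

$$\mathrm{BIC}(G \mid D) = \sum_{i=1}^{n} \sum_{j=1}^{q_i} \sum_{k=1}^{r_i}
  m_{ijk} \log \frac{m_{ijk}}{m_{ij*}} \;-\; \sum_{i=1}^{n}
  \frac{q_i (r_i - 1)}{2} \log m$$

where `r_i` is the arity of node *i* (3 for a SNP, 2 for the phenotype),
`q_i` the number of joint parent configurations, `m_ijk` the count of
samples with node value *k* under parent configuration *j*, and
`m_ij*` the configuration margin. Zero-count cells contribute zero to
the likelihood sum, the standard limit convention. Parent configurations
are enumerated in mixed-radix order with the lowest-index parent as the
fastest digit, so the `j`-indexing is reproducible; only observed
configurations are materialised, while the penalty always uses the full
combinatorial `q_i`. The logarithm base is configurable and defaults to
the natural log everywhere (entropies, mutual information, BIC); the
base rescales all scores uniformly and never changes a ranking, but any
absolute threshold on mutual information must be interpreted in the base
it was derived in.

Why BIC matters here: a SNP parent multiplies `q` of its child by 3, so
the penalty grows geometrically in the family size while the fitted
likelihood gains `m` times the (empirical) conditional mutual
information. A purely epistatic pair is retained as a parent family of
`Class` exactly when the joint information `m \cdot I(Class \mid
SNP_1, SNP_2)` clears the penalty step — and a single member of the pair
on its own clears nothing, which is why hill-climbing by single-edge
additions cannot discover pure epistasis and a seeded population search
is used instead.

## Bitwise screening

Mutual information between locus combinations and the phenotype,
$I(Class \mid SNP_1..SNP_k) = H(Class) + H(SNP_1..SNP_k) - H(Class,
SNP_1..SNP_k)$, is computed from a one-hot bitstring encoding: each SNP
carries three bitstrings (one per genotype value) with bit *i* set when
sample *i* has that value, and the phenotype carries two. Every cell
probability is `popcount(AND of the selected strings) / m` — a
maximum-likelihood plug-in frequency with no pseudocounts. Tiny negative
MI from floating-point rounding (above `-1e-12`) is clamped to zero;
anything more negative raises an internal-consistency error. The
combination order `k` is capped at 3: only 2- and 3-locus models are
searched, and the `3^k` cell enumeration guards against combinatorial
blow-up.

## The search

1. **Seeding.** All `C(n, k)` combinations are ranked by MI
   (deterministic ties: lexicographic index order). The top-N
   combinations are wired into the seed network: each involved SNP gets
   an edge into `Class`, plus chain edges between the combination's SNPs
   from lower to higher index. Loci outside the top-N are brought into
   the network through the first remaining combination in which they
   appear, contributing a single SNP–SNP edge oriented toward the fresh
   node. Two choices here are deliberate: coverage combinations do *not*
   touch the phenotype family, and `topN` defaults to 1. Seeding `N`
   pairs into `Class` gives it `q = 3^{2N}` configurations; every
   uninformative SNP seeded there hands the search a large penalty
   reward for pruning the family wholesale, planted pair included. With
   `topN = 1` the phenotype family starts identifiable and the search
   only has to *keep* it. When several interactions are expected, raise
   `topN` (and expect proportionally larger samples to support
   `q = 3^{2N}`).
2. **Initial population.** Chained single-edge perturbations of the
   seed: each next individual differs from its predecessor by one random
   add, drop or reverse that keeps the graph acyclic, with the edit type
   drawn uniformly so perturbation does not drift toward denser graphs.
3. **Selection.** Roulette wheel on shifted fitness
   `f_i = BIC_i - min(BIC) + delta`. The shift makes fitness positive
   while preserving rank; `delta` defaults to half the population score
   range, capping the best:worst selection ratio at 3:1. A vanishing
   offset makes selection winner-takes-all whenever scores spread over
   many units and collapses the population into clones within a couple
   of generations — the search then stalls at whatever the early leader
   happened to keep. The two parents of each crossover are drawn without
   replacement within the pair, because crossing an individual with
   itself cannot produce new offspring.
4. **Tabu crossover.** With probability 0.7 a selected pair exchanges
   two randomly chosen adjacency-matrix columns (the parent sets of two
   nodes) row by row; a row whose exchange would create a ring in either
   offspring-in-progress is skipped. Offspring matching any fingerprint
   in a bounded FIFO tabu list (capacity 30, exact matrix equality) are
   rejected and the crossover is retried with fresh columns, up to 10
   retries — the retry bound makes termination provable where an
   unbounded loop would spin on cloned parents. Accepted offspring are
   recorded in the list.
5. **Tabu mutation.** Each individual is considered at rate
   `P_m = 0.002`; a triggered mutation flips one uniformly chosen
   off-diagonal matrix cell. The mutant replaces its parent only when it
   is acyclic, strictly fitness-improving and not tabu; fitness-degrading
   mutants are recorded in a second tabu list (same capacity policy,
   separate memory) so the search does not revisit them.
6. **Termination.** The loop stops at 60 generations, or as soon as
   *neither* the best-ever fitness *nor* the population mean fitness has
   improved for 3 consecutive generations, or at an optional fitness
   threshold (disabled by default — no principled value exists). The
   best individual ever seen is tracked outside the population and is
   what gets reported, so the reported fitness is monotone.

Default parameters — population 50, crossover 0.7, mutation 0.002, tabu
length 30, 60 iterations, stagnation 3 — follow the published tuning of
the method. All randomness flows from a single seed recorded in the run
manifest; identical input, configuration and seed reproduce the run
bit-for-bit.

Edges out of the phenotype node are legal by default (`Class`
participates as an ordinary node; extraction treats both directions as
adjacency); `forbidClassOut = TRUE` restricts the search for users who
want the phenotype to be a sink.

## Reading interactions off the network

A learned network can place an interaction in two score-equivalent
shapes: both SNPs as parents/neighbours of `Class`, or an SNP–SNP edge
whose child also links to `Class` (the interaction likelihood then lives
in that SNP's family). The default `"combined"` extraction rule reports
the union of both readings: every unordered SNP pair in which both SNPs
are adjacent to `Class` (either edge direction), plus every SNP–SNP edge
with at least one Class-adjacent endpoint. Each pair is annotated with
the recomputed `I(Class | SNP1, SNP2)` and the report is sorted by
decreasing MI with name-based tie-breaks. The narrower rules remain
selectable: `"adjacent"`, `"parents"` (both SNPs parents of `Class` —
strictest) and `"snp-edge"`. Detection accuracy over a batch counts a
dataset as recovered only when its *full* planted set appears as one
reported tuple — both loci in the same pair, not merely both appearing
somewhere.

For large inputs a per-SNP 3×2 genotype-by-class chi-square prefilter
(no continuity correction; unobserved genotype rows drop out of the
table) reduces the locus set before screening. The default direction
keeps the marginally associated loci (`p <` threshold); the flag
`keepBelow = FALSE` inverts it.

## The simulator

`buildPenetrance()` constructs purely epistatic k-locus penetrance
tables: every single-locus marginal penetrance, weighted by the
Hardy–Weinberg genotype frequencies of the other loci, equals the
prevalence `K` to within `1e-6`, and the heritability
$h^2 = \sum_g f_g (P_g - K)^2 / (K(1-K))$ is hit to within 5% relative
tolerance (the variance-ratio definition on the penetrance scale used by
the GAMETES simulator family). Construction is random search: sample a
deviation table, alternately project onto the no-main-effect constraint
(removing per-locus HW-weighted marginals), rescale to the target
variance, clip into `[0, 1]`, and retry from a fresh candidate when the
loop fails to converge.

Prevalence is a *free* parameter by default, for a geometric reason: the
no-main-effect constraint together with the `[0, 1]` cell bounds caps the
achievable heritability at any fixed prevalence. Exact vertex
enumeration of the constraint polytope shows that at MAF 0.4 and fixed
`K = 0.2` the maximum is `h² = 0.384`, so the strongest standard grid
point (`h² = 0.4`) is not constructible there; at `K = 0.25` it is. When
`prevalence` is `NULL`, each attempt draws a prevalence from a feasible
range and reports the realised value in the model object; when a fixed
prevalence is requested, infeasible combinations fail with an explicit
error rather than a silently biased table.

`simulateDataset()` draws functional genotypes under Hardy–Weinberg
equilibrium at the model MAF, assigns status from the penetrance table,
and rejection-samples to the case/control quotas (balanced 400/400 by
default); noise SNPs are independent of status with MAFs uniform in
`[0.05, 0.5]`; planted positions are randomised and returned as the
truth set. Because the models carry no marginal effects, the planted
loci keep their population genotype distribution even in the
case-enriched sample — a property the test suite checks.

What the simulator does *not* emulate: linkage disequilibrium between
loci, genotyping error, missing genotypes (rejected on input rather than
imputed — the upstream formats carry none), covariates and population
structure. Passing tests therefore demonstrate correct recovery under
idealised GAMETES-style conditions, not robustness to the confounders of
real cohorts.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise the pipeline at desk
scale, the package's own choice of problem size: 20 datasets of 20 SNPs
and 400 cases/400 controls at the strongest grid point (h² = 0.4,
MAF = 0.4), where the method's published behaviour is full recovery; the
published protocol uses 100 files per setting and the batch evaluator
accepts any count. Per-family score caching (families recur massively
across a population) keeps a full run on one dataset to a few seconds.
Degenerate inputs are handled explicitly: constant SNP columns carry no
chi-square test and are dropped with a message; an isolated phenotype
node yields an empty report with a warning; a parent family whose `q`
exceeds `3^25` is rejected as overparameterized rather than silently
materialised.

## Known limitations

- Mutation at the published `P_m = 0.002` over 50 individuals attempts
  roughly one flip every ten generations; the search power therefore
  rests almost entirely on seeding, selection and crossover. A planted
  interaction whose pair never enters the seed network cannot be
  reconstructed by single-edge moves, because adding either edge alone
  is penalised — this is the pure-epistasis valley the MI seeding exists
  to bridge.
- At low heritability (h² ≤ 0.05) the MI ranking is noisy and the top
  pair is frequently not the planted one; recovery degrades exactly as
  the published accuracy curves do.
- The BIC plug-in likelihood overfits families with `q` close to `m`;
  the seeding default keeps the phenotype family well below that regime,
  but users raising `topN` should scale samples accordingly.
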
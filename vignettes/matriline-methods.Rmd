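---
title: "Methods: models, parameters, and design choices in matriline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in matriline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the tunable parameters and
their defaults, the numerical choices, and the deliberate design decisions
behind the package. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The coordinate frame and substitution scoring

All analyses run in a fixed 1-based reference frame over the mitochondrial
control region (1232 bp by default). Every input sequence is anchored to
the reference by global pairwise alignment (Needleman–Wunsch with affine
gaps, via Biostrings) and re-expressed as one state per reference position:
a called base, `-` for a deletion, `N` for missing. Substitutions are
tokens *anc-pos-der* (`A281G`), the notation used throughout mtDNA
haplogroup nomenclatures.

Fixed alignment parameters: match +1, mismatch −1, and affine gap costs
such that a gap of length *g* costs 4 + (*g* − 1) — i.e. 4 for the first
gap position and 1 for each extension. These are frozen (not exposed) so
that outputs are bit-reproducible; the test suite checks the aligner
against an independent dynamic-programming oracle on toy references.

Three choices worth knowing:

* **IUPAC ambiguity codes are treated as missing.** An ambiguous base can
  never satisfy (or spuriously create) a diagnostic motif. Missing states
  produce no substitution call.
* **Insertions relative to the reference are stored but excluded** from
  the positional frame and all downstream statistics: a fixed-length frame
  admits no insertion columns, and motif positions must stay stable.
* **A minimum alignment identity of 70%** (over called positions) rejects
  sequences that are not the targeted locus at all.

The bundled reference (`defaultReference()`) is a *synthetic* 1232-bp
stand-in generated by `makeSyntheticReference()`: deterministic random
bases except at every diagnostic-motif position of the bundled scheme,
where the base equals the motif's ancestral state. This keeps the scheme
and reference mutually consistent without shipping third-party sequence
data; users analysing real data should load the real reference with
`readReference()` and their own motif table.

# Haplogroup classification

A haplogroup scheme is a rooted tree whose nodes carry branch motifs; the
*cumulative path* of a node is the union of motifs from the root down.
`classifyHaplogroups()` assigns each sample to the deepest node whose
cumulative path is contained in the sample's substitutions — cumulative
semantics because nomenclature figures draw motifs on the branches of a
rooted tree, so membership of a sub-haplogroup presupposes its ancestors'
motifs.

Deliberate behaviours, all audited in the output rather than silently
resolved:

* **Ties** (two equally deep satisfied nodes) return `"unclassified"`
  with both candidates in `conflicts`; determinism matters more than a
  forced pick.
* **Back-mutation** at a diagnostic site breaks the path; the sample falls
  back to the deepest still-satisfied ancestor and the blocking tokens are
  listed in `missing`.
* **Non-path derived states at diagnostic positions** are reported in
  `conflicts`.

The bundled CDV scheme honours the published cumulative motif sets for V
(`A281G, T355C, C363T`), V2 (V plus `C228T, A237G, C391T`) and D1b
(`A281G, C296T, T306C, A342G, G686A`). `A281G` appears in both the V and
D1b paths, so it sits on the shared CDV stem; the split of D1b's remaining
motifs along CDV → D → D1 → D1b is a package design choice (only the
cumulative set is published), and every node whose motifs are not published
carries an invented placeholder marked `source: synthetic-placeholder` in
the YAML. The classifier is entirely config-driven: replace the YAML to
use a complete supplementary motif table.

# Diversity statistics

* Site policy default is **complete deletion**: a site with a gap or
  missing state in any sequence is dropped from collapsing, *S*, and π —
  the default of the classical haplotype software this module mirrors. A
  pairwise option exists for π; at the collapsing step "pairwise" means
  exact full-state matching, because true pairwise deletion is
  non-transitive and cannot define a partition.
* *Hd* uses Nei's unbiased estimator with the Nei (1987) sampling variance
  of gene diversity; π uses the mean pairwise proportion of differences
  with the Nei (1987) variance (n+1)π/(3(n−1)L) + 2(n²+n+3)π²/(9n(n−1)).
  The "±" values reported alongside are these sampling standard errors.
* Site classes: a variable site is a **singleton** if every state other
  than the most frequent occurs exactly once, otherwise
  **parsimony-informative**. For bi-allelic sites this is the textbook
  rule and singletons + informative = segregating; the multi-allelic
  extension preserves that arithmetic.
* Pooled "overall" rows in `diversityTable()` pool sequences and recompute
  (they never average per-population indices), which is how multi-region
  summary tables in this literature add up.

# Neutrality tests and the coalescent null

Tajima's *D* uses the standard constants; with *S* = 0 the statistic is
undefined and is returned flagged (`computable = FALSE`), never as 0.

Fu's *Fs* is the log-odds of the Ewens tail probability
S′ = P(K ≥ k_obs | θ), with θ estimated by θ̂_π (the mean number of
pairwise differences), Fu's own prescription. The Ewens probabilities use
unsigned Stirling numbers of the first kind computed by the log-space
recurrence |s(n+1,k)| = n·|s(n,k)| + |s(n,k−1)| with log-sum-exp — stable
for n well beyond 350 — and are cross-checked in the tests against exact
integer Stirling numbers for n ≤ 10 (exact in double precision). k_obs = 1
makes S′ = 1 and Fs = +∞; this is returned flagged.

P-values come from an internal neutral infinite-sites coalescent: while
*k* lineages remain, waiting times are Exponential(k(k−1)/2) and a uniform
pair merges; mutations fall on branches as Poisson(θ/2 × length), each on
a fresh site. The batch path is compiled (Rcpp) and uses R's RNG, so
`set.seed()` reproduces it bit-for-bit; a pure-R reference implementation
(`simulateNeutralSample()`) is kept and the two are compared in
distribution in the tests, alongside a χ² check of the simulated haplotype
counts against the Ewens distribution. The simulator's mean Tajima's D at
n = 50, θ = 10 is small and negative (≈ −0.095), a genuine finite-sample
property of the statistic, not a simulator bias; the test suite verifies
the mean within Monte-Carlo error, and during development the simulator
was additionally cross-validated against an independent coalescent
implementation, which agreed to three decimals.

P-values are **one-tailed per sign** (for a negative observed statistic,
the fraction of replicates at least as negative; mirrored for positive),
the convention of the classical tools; both tails are returned
(`pD_low`/`pD_high`, `pFs_low`/`pFs_high`) because published significance
stars do not state their tail. Null replicates with S = 0 are dropped from
the D comparison and counted. The default null θ is θ̂_π
(`thetaEstimator = "pi"`), with Watterson's estimator as an option.

# Population structure

The substrate is the matrix of raw pairwise difference counts over
included sites (the default of distance-based AMOVA tools for haplotype
data; model-corrected distances are out of scope).

* **Pairwise Φ_ST** is the among-population variance fraction of the
  two-population AMOVA. Permutations shuffle individuals between the two
  populations; p = (b + 1)/(m + 1) including the observed arrangement, so
  p is never 0. Negative estimates are reported untruncated.
* **Hierarchical AMOVA** uses the Excoffier–Smouse–Quattro sums of squares
  at three levels, variance components by equating mean squares to
  expectations, and the level-appropriate permutation schemes (sequences
  among populations irrespective of groups for Φ_ST; sequences among
  populations within groups for Φ_SC; whole populations among groups for
  Φ_CT). Negative components are reported as computed, so percentages can
  fall outside [0, 100] — this matches the behaviour of the standard
  software and is documented rather than masked.
* **PCoA** is classical Gower double-centering of the squared distances
  via `stats::cmdscale`; axis percentages are eigenvalues over the sum of
  positive eigenvalues. Published plots from other PCoA implementations
  may differ by ≲1% in axis percentages because their standardisation is
  not fully documented.

Defaults for permutation counts follow the field's convention (10000 for
pairwise fixation indices, 1000 for AMOVA); the pipeline exposes both.

# Median-joining networks

`buildMSN()` computes the ε-relaxed minimum spanning network over Hamming
distances: a link is admitted iff its length is within ε of the bottleneck
(minimax) distance between its endpoints; at ε = 0 this is exactly the
union of all minimum spanning trees. Default ε = 0, the default of the
standard network software; all variable sites are weighted equally.

`medianJoiningNetwork()` then iterates: for every connected triplet
(a vertex with two network neighbours) it forms the quasi-median (per-site
majority; a three-way tie spawns one variant per state, capped at 64
variants per triplet with an error on overflow), and greedily adds medians
that strictly reduce the total network cost — the minimum-spanning-tree
length over the augmented node set — re-evaluating each candidate against
the updated tree, so the cost is non-increasing by construction. Ties in
gain are broken on the lexicographic state key, making the result
invariant to haplotype input order. Finally, median vectors not on any
shortest path between observed haplotypes (and any of degree ≤ 1) are
pruned. On tree-like (infinite-sites) data the result is a tree attaining
the parsimony bound — the number of variable sites — which the tests
certify as the exact Steiner optimum via an independent exhaustive search;
on homoplastic data median-joining is a heuristic and only cost
monotonicity and the lower bound are guaranteed.

`mutationSteps()` reports the minimum path length between nodes or node
sets (published "mutational sites between haplogroups" counts are
implemented as the minimum over node-set pairs, since figure-based counts
do not state which haplotypes they connect). `estimateTmrcaRho()` is a
founder-age approximation: ρ is the size-weighted mean mutational distance
to a chosen root, converted to years by ρ/(rate × L) with the default
clock 3.13×10⁻⁷ substitutions/site/year over 1232 sites. It is *not*
comparable to Bayesian node ages and is labelled accordingly.

# The synthetic-data generator

`generateDataset()` emulates the sampling design of a multi-country
control-region survey: demes of configurable size with a haplogroup
composition, within-deme coalescent diversity, deme-private divergence and
transregional haplotype sharing.

* **Composition is allocated deterministically** (largest remainder), so
  generated haplogroup frequencies equal the requested proportions exactly
  up to integer rounding — which is what makes classifier accuracy an
  exact, not statistical, check.
* **Coalescent mutations avoid diagnostic positions** by default (opt-in
  `allowDiagnosticNoise` for stress tests), keeping classification truth
  exact; positions are drawn without replacement from a global pool, so
  every substitution in the dataset is identifiable. The infinite-sites
  assumption is inherited: no recurrent or back mutation unless injected.
* **Migration is haplotype copying** (a sample is replaced by a copy from
  another deme, keeping its population label). This reproduces
  transregional haplotype sharing without a structured coalescent; it does
  **not** model gene flow with recombination-free admixture times, and
  λ-shaped genealogies, rate heterogeneity among sites, and sequencing
  error are likewise not emulated. Passing tests on these data therefore
  demonstrate correctness of the *computations*, not robustness to every
  feature of real control-region data.
* Default study conditions in the acceptance layer mirror the sampling
  design of the motivating surveys: seven demes of 173/63/25/78/135/35/10
  sequences (N = 519), mixed haplogroup composition, θ_within = 5 per
  deme cohort, one deme-private substitution, 5% haplotype sharing.

# Numerical and reproducibility choices

* All stochastic entry points take an explicit integer seed and run in a
  private RNG stream (the caller's `.Random.seed` is untouched); derived
  per-stage seeds are recorded in outputs and the pipeline manifest.
  Identical inputs + seed ⇒ byte-identical outputs (checksummed in the
  manifest and asserted in the tests).
* Permutation p-values use (b + 1)/(m + 1); simulation p-values are raw
  tail fractions of the replicate distribution.
* Degenerate inputs return flagged results rather than silent zeros:
  S = 0 for Tajima's D, k_obs = 1 or tail underflow for Fs, the all-zero
  distance matrix for PCoA.
* Equality tolerances in internal comparisons (e.g. "strictly reduces
  network cost", permutation ≥ observed) use 1e-9–1e-12 slack to keep
  integer-valued arithmetic immune to floating-point representation.
* Problem sizes in the test suite were chosen to exercise every code path
  in a few minutes: brute-force oracles at N ≤ 50, simulator calibration
  at 2000–20000 replicates, the type-I-error experiment with 500 datasets
  × 1000 null replicates at n = 25, θ = 5, and two full pipeline runs at
  the N = 519 study scale. The type-I check uses the fixed lower-tail
  test (reject when `pD_low` < 0.05), whose nominal level is 5%; the
  sign-directed two-way rule would have nominal level ≈ 10% by
  construction and is therefore not the calibrated quantity.

# Interface choices

The package's interface is its R API plus `scripts/acceptance.R` and
`runPipeline()`; no shell wrapper is shipped. For an analysis package of
this kind the functions and this vignette are the product — a CLI would
add a second surface to keep in sync without adding capability.

# Known limitations

* Real-data reproduction of published tables requires the deposited
  sequences and the real reference; the package ships only synthetic
  stand-ins and verifies methodology, not the published numbers.
* Haplotype-frequency (allele-frequency) F_ST variants, model-based
  distances, Mantel tests, Bayesian skyline/time-tree inference and ML
  phylogenetics are out of scope.
* The pairwise-deletion option changes L per pair and is not propagated to
  the AMOVA distance matrix (complete deletion is used there regardless).
* Median-joining networks on highly homoplastic data can depend on ε and
  are heuristic; the exact behaviour is only guaranteed on tree-like data
  as described above.
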
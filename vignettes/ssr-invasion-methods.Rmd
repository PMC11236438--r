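---
title: "Methods: microsatellite population genetics and invasion-route inference with ssrinvasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsatellite population genetics and invasion-route inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrinvasion)
```

## What this package models

`ssrinvasion` analyses diploid codominant microsatellite (SSR) genotypes from
small, recently founded populations — the typical situation for an invasive
plant spreading across an archipelago: a handful of island populations, ten or
so individuals each, under ten loci, founder bottlenecks, null alleles and
some missing data. The package covers the complete analysis chain for such
data: within-population diversity, Hardy–Weinberg testing, null-allele
modelling, between-population structure (AMOVA, FST, Mantel, directional
migration networks), cluster inference (k-means/BIC and DAPC), Nei-distance
UPGMA trees, and a compact approximate Bayesian computation (ABC) engine that
infers invasion routes by simulating SSR data under competing demographic
scenarios.

The genotype container is a long tibble (`ssr_tbl`): one row per individual ×
locus, alleles stored as a sorted integer pair, `NA`/`NA` for a missing
genotype. All user-facing functions take the data frame first and return
tibbles, so analyses chain with the pipe; fitted objects (`amova()`,
`find_clusters()`, `dapc_fit()`, `relative_migration()`) have `tidy()`,
`glance()` and `autoplot()` methods.

## Diversity statistics

* **He (gene diversity)** is $1 - \sum_k p_k^2$ per locus. The small-sample
  correction $2n/(2n-1)$ (Nei's unbiased estimator) is on by default because
  the intended samples are small (about 10 diploids per population). Both a
  pooled-sample global He and a mean-of-populations global He are reported:
  with structured data the two differ (the pooled value absorbs the
  between-population variance), and which one a given study means by "global
  He" is often ambiguous, so the package always prints both.
* **FIS** per population is $1 - \bar H_o / \bar H_s$ with means over loci
  (ratio of averages; robust when some loci are nearly monomorphic). Per-locus
  values are available with `fis(detail = TRUE)`.
* **Allelic richness** uses hypergeometric rarefaction to a common gene count
  $g$, by default the minimum gene count over all (population, locus) cells —
  the largest $g$ that is valid everywhere. $g < 2$ is refused.
* **Private alleles** are counted per population over distinct
  (locus, allele) pairs observed nowhere else.
* Missing genotypes are excluded pairwise per locus (gene counts vary by
  locus); nothing is imputed in the estimators.

## Hardy–Weinberg exact test

`hwe_test()` is the Markov-chain exact probability test: the p-value is the
probability, conditional on the observed allele counts, of a genotype table no
more probable than the observed one. The chain operates on the ordered vector
of $2n$ allele slots; swapping two uniformly chosen slots is a symmetric
proposal whose stationary distribution is uniform over orderings, which
induces exactly the required conditional distribution on tables — so no
Metropolis correction is needed. Defaults mirror the classic Markov-chain
settings (dememorization 1000, 100 batches × 1000 iterations) and the Monte
Carlo standard error comes from batch means. For biallelic tables the chain is
validated in the test suite against complete enumeration. Raw p-values are
reported per locus; a clearly-labelled Bonferroni column is added because
multi-locus panels invite multiplicity, but no correction is silently applied.

## Null alleles and ENA-corrected FST

`null_allele_em()` fits, per (locus, population), the mixture model in which
apparent homozygotes are true homozygotes or null heterozygotes, and blank
(missing) genotypes are candidate null homozygotes (`blanks_are_nulls = TRUE`
by default; turn it off when missingness is known to be technical). EM starts
from uniform visible frequencies and null = 0.05, stops at a maximum change
below 1e-8 or 10,000 iterations (non-convergence is flagged, never fatal).
Per-locus summaries report both the mean and the maximum across populations,
since both conventions exist in the field.

`fst_ena()` computes multi-locus Weir–Cockerham $\theta$ twice: uncorrected,
and with the estimated null class excluded — allele frequencies replaced by
the EM-adjusted visible frequencies renormalized onto the visible simplex, and
the apparent-homozygote mass the EM attributes to null heterozygotes returned
to the heterozygote-frequency term. At an estimated null frequency of exactly
zero the correction is a no-op. A practical note from the package's own paired
simulations (same genotypes with and without null masking): $\theta$ is
remarkably robust to null alleles — visible relative allele frequencies stay
unbiased under masking and the heterozygosity term has only $O(1/n)$ influence
— so corrected and uncorrected values typically agree and the paired t-test
across loci is non-significant. That is the expected outcome, not a failure of
the correction.

## Between-population structure

* **Pairwise FST** is Weir & Cockerham's $\theta$ (ratio of variance-component
  sums across loci and alleles) for every pair; Nei's Gst is available as an
  alternative estimator. Negative estimates are reported as computed, with a
  truncation option, because truncation biases averages.
* **AMOVA** is the one-level Arlequin-style analysis on squared
  inter-individual distances (0/1/2 allele mismatches per locus, summed over
  loci shared by the pair). Variance components come from method-of-moments;
  significance from permuting individuals among populations, with the observed
  statistic included in numerator and denominator. Negative components are
  truncated at zero for percentage reporting; raw values are kept.
* **Mantel test**: Pearson correlation of upper triangles; for 7 or fewer
  labels the p-value enumerates all $n!-1$ non-identity label permutations
  exactly (4 populations give 23 — the maximum information obtainable from a
  4×4 matrix), otherwise random permutations. Default alternative is
  "greater" (the isolation-by-distance direction).
* **Directional relative migration** builds, per ordered pair, the
  hypothetical migrant pool with midpoint allele frequencies, converts each
  population's differentiation from that pool into an island-model migration
  estimate, and normalizes the directed matrix by its maximum. The edge
  `m[i, j]` (flow i→j) is keyed to the *sender's* similarity to the pool: a
  population that exports many migrants dominates the pool. The orientation
  was fixed once against source–sink coalescent simulations (a sink founded
  from a large source through a bottleneck), where the source→sink edge
  dominates in essentially all bootstrap replicates. Bootstrapping resamples
  individuals within populations.

## Cluster inference and ordination

`find_clusters()` runs PCA on the centred, scaled allele-dosage matrix
(missing dosages imputed by locus means so PCA stays defined under sparse
missingness), retains components covering ≥ 90% of variance by default, then
k-means for $K = 1..K_{max}$ with 10 random restarts keeping the best
within-cluster sum of squares, and selects $K$ by
$BIC(K) = n\ln(WSS_K/n) + K\ln(n)$ (ties to the smallest $K$). Two properties
of this criterion matter in practice:

* On well-separated data the argmin is reliably the true $K$ (the tested
  contract).
* On unstructured data the criterion does **not** settle on $K = 1$: k-means
  always removes more in-sample WSS per added centre than the $\ln(n)$
  penalty, so the curve keeps drifting shallowly downward. Read a shallow,
  elbow-free BIC curve as "no structure", exactly as practitioners read these
  curves; the package's null-data test asserts that the BIC drop on
  unstructured data is small relative to structured data rather than
  pretending the argmin lands at 1.

`dapc_fit()` performs linear discriminant analysis on the retained PCs
(groups from `find_clusters()`, explicit labels, or populations), returning
discriminant coordinates, per-axis variance shares and posterior memberships.
`pcoa_dist()` is classical metric scaling (double-centred $-\tfrac12 D^2$,
eigendecomposition, axes scaled by $\sqrt\lambda$); negative eigenvalues are
reported, their axes dropped.

## Trees

`nei_distance()` implements Nei's 1972 distance $D = -\ln I$ with the J terms
summed over loci; the 1978 variant applies the sample-size-unbiased J
estimates. Pairs sharing no alleles get an infinite sentinel, which the tree
builder caps at twice the largest finite distance with a warning. `upgma_tree()`
is written in the package rather than delegating to `hclust` because the
contract requires label-permutation-invariant tie-breaking (ties broken by the
lexicographically smallest member label); `hclust` average linkage is the
cross-check in the tests. `bootstrap_tree()` resamples loci (columns) with
replacement — the standard choice for distance trees over a fixed marker
panel — and reports, per internal node of the full-data tree, the percentage
of replicates containing that bipartition. Individual-level trees treat every
individual as a population of one (`by_individual = TRUE`). Newick output
quotes labels containing reserved characters and round-trips through
`read_newick()`.

## The coalescent SMM simulator

`simulate_scenario()` simulates SSR genotypes backward in time through a
scenario's deme graph: pairwise coalescence at rate $1/(2N)$ per generation
within a deme (continuous-time exponential waiting times — the standard
approximation of the generation-wise model, accurate for $N$ well above the
sample size), lineage movement at split/admixture events, piecewise-constant
sizes for bottlenecks, and mutations dropped on branches as Poisson(μ ×
length) with strict ±1 stepwise moves. Alleles are emitted as repeat counts
around a base of 100; a locus drifting non-positive is shifted so its minimum
code is 1 (within-locus differences, the only thing SMM statistics use, are
preserved). The per-locus engine is compiled (Rcpp), which keeps a full
reference table of a few thousand simulations in the tens of seconds on one
core. The simulator's acceptance surface is its closed forms: mean pairwise
coalescence time $2N$ and SMM equilibrium gene diversity
$1 - 1/\sqrt{1 + 2\theta}$, both checked to within 3 Monte Carlo standard
errors at 200 loci.

Scenarios are declared forward-intuitively ("deme X was founded from deme Y at
time t, then bottlenecked") but stored backward in time: a `split` moves the
child's lineages into the parent, an `admix` routes them to two parents with
proportion $r$, a `bottleneck` sets the deme's size to $N_b$ on
$[t, t+\mathrm{dur})$. Any numeric field may instead name a parameter; priors
attach per parameter. Validation enforces exactly one root deme, no moves into
already-removed parents, $0 < r < 1$, and bottlenecks contained within the
deme's lifetime; prior draws violating the event order are rejected and
redrawn.

### Priors

The study this engine targets does not publish its priors, so the defaults are
package choices, chosen once for a recently introduced tree species and fully
overridable: log-uniform effective sizes on $[10, 10^5]$ (bottleneck sizes
$[2, 10^3]$), uniform divergence times on $[1, 500]$ generations — introduction
histories documented within the last centuries, with a generation on the order
of a decade, put the truth well inside this window — uniform bottleneck
durations on $[1, 50]$, uniform admixture proportions on $[0.1, 0.9]$, and
log-uniform mean SSR mutation rate on $[10^{-4}, 10^{-3}]$ per generation. A
generation-time knob for converting to years deliberately lives outside the
inference.

## The ABC engine

Summary statistics are the classic SSR panel: per-deme mean allele count,
per-deme mean unbiased gene diversity, and all pairwise Weir–Cockerham FST
values, in fixed order; they are numerically identical to the diversity and
differentiation modules (single source of truth, verified by test).
Statistics are standardized by reference-table median absolute deviations
(robust to the heavy tails prior draws produce; mean/SD fallback when the MAD
degenerates). Scenario posteriors use rejection (weighted frequency among the
`n_closest` accepted rows, default 1% of the table) or Epanechnikov-weighted
multinomial logistic regression of the scenario indicator on statistic
differences, evaluated at zero difference. Parameter posteriors use the
local-linear regression adjustment with log (positive parameters) or logit
(proportions) transforms; singular regressions fall back to unadjusted
rejection with a warning. `model_check()` projects the observed vector and
posterior-predictive simulations into the reference-table PCA and reports
per-statistic two-sided tail probabilities. `confidence_errors()` simulates
pseudo-observed data under every scenario and reports per-scenario type-I
error and the mean type-II error with its range, formatted like
`0.08 [0.03-0.16]`.

The built-in catalog (`load_scenarios_stage()`) provides three analysis
stages — origin unsampled, mainland origin sampled, coastal origin sampled —
each containing the published best-supported invasion topology plus
contrasting alternatives (serial stepping-stone, independent introductions).
`invasion_topologies()` exposes the three published winners in one comparable
frame for recovery experiments. Arbitrary user scenario sets (the original
study screened 35) load from a plain-text format via `read_scenarios()`.

Because the original priors and the full 35-scenario catalog are unpublished,
the engine's accuracy claims are property-based, not value-based: with
well-separated parameters and a 2000-simulation-per-scenario reference table,
the generating topology attains the highest posterior in ≥ 70% of 25
pseudo-observed datasets (typically ~90%), and the posterior median of a true
$N = 1000$ inside a $[100, 10^4]$ log-uniform prior lands within a factor of
two of the truth in ≥ 80% of replicates. Credible-interval coverage is
approximate — the `n_closest` acceptance induces the usual ABC
over-dispersion at small tables — and is documented rather than asserted.

## The synthetic-data generator

`generate_island_fixture()` emulates the target study design: 4 island
populations × 10 diploid individuals × 9 loci with 2–7 alleles per locus.
Island frequencies are Dirichlet perturbations of shared per-locus base
frequencies with concentration θ = 7, calibrated once so realized pairwise
Weir–Cockerham FST lands in the moderate band (≈ 0.08–0.17 at the default
seed; between-seed spread reaches ≈ 0.05–0.25); a mild inbreeding coefficient
(0.1), one locus carrying null alleles at 0.15 (null homozygotes become
missing — the same model the EM assumes), and 3% uniform missingness supply
the data pathologies the estimators must survive. The generator is independent
of the coalescent code it helps test: it samples genotypes from explicit
frequencies, so estimator tests do not inherit simulator assumptions. What it
does *not* emulate: genotyping error and allele dropout beyond nulls, stutter,
linkage, selection, and spatial sampling structure within islands — so green
tests certify estimator correctness on clean-but-awkward data, not robustness
to every lab artifact.

Every generator records a truth object (generator name + exact arguments)
that regenerates the dataset bit-identically and serializes to JSON
(`write_truth()`, `read_truth()`, `regenerate_truth()`).

## Pipeline and problem sizes

`run_ssr_pipeline()` chains diversity → differentiation → structure → tree →
ABC on one dataset, writes per-stage CSV/Newick artifacts plus a JSON
manifest carrying every statistic and every seed, and records failed stages
as partial completion instead of aborting. Reruns with the same seed give
identical manifests (modulo runtimes). `report_tables()` renders the manifest
as plain-text tables (symmetric FST matrix with an em-dash diagonal,
diversity panel, AMOVA, scenario posteriors) at 2-decimal display precision;
the manifest keeps full precision.

Default problem sizes throughout the tests and the acceptance script are
desk-scale choices made once: reference tables of 1500–2000 simulations per
scenario, 25 pseudo-observed datasets for recovery, 200 loci for closed-form
checks, 500 tree bootstraps, 999 AMOVA permutations, Markov chains of 100
batches × 200–300 iterations. They are an order of magnitude below
publication-scale runs (which simply scale the same knobs up) but large
enough that every property above is resolved well beyond its Monte Carlo
noise.

## Known limitations

* The BIC/k-means criterion never argmins at $K=1$ on unstructured data (see
  above); interpret shallow curves, don't trust the bare argmin.
* The HWE chain is quadratic-ish in sample size per step; it is meant for
  SSR-survey samples (tens of individuals), not thousands.
* The ENA correction changes little in practice because $\theta$ is robust
  to nulls; it is provided for completeness and for the paired-t diagnostic.
* ABC posteriors inherit all usual ABC caveats: summary-statistic
  sufficiency, acceptance-radius bias, and prior sensitivity — the error
  rates from `confidence_errors()` are the honest statement of how
  distinguishable a scenario set actually is.

```{r example, eval = FALSE}
ds <- generate_island_fixture(seed = 42)
diversity_summary(ds)
pairwise_fst(ds)
cl <- find_clusters(ds, seed = 1)
autoplot(cl)
manifest <- run_ssr_pipeline(ds, output_dir = "results", seed = 1)
report_tables(manifest)
```
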
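---
title: "Drift-confounded ancestry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift-confounded ancestry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question

Stocked fish populations are routinely screened for hatchery ancestry with
model-based clustering: if a wild population assigns to its own cluster and
shows little admixture with hatchery reference samples, it is tempting to
call it a distinct, possibly remnant, native population. `popdrift`
implements the simulation argument that this inference is fragile when
effective population sizes are small: isolated populations founded from a
*single common source* — for instance a hatchery strain — drift apart so
quickly that within a few decades they look exactly like a set of distinct
populations with no detectable shared ancestry. The package simulates that
null scenario with empirically estimated effective sizes, runs the same
analysis chain a population geneticist would run on real data, and
quantifies how the apparent distinctness grows (and apparent hatchery
ancestry shrinks) with effective size and time.

# The simulation model

`sim_config()` / `run_drift_sim()` implement a monoecious Wright–Fisher
model: constant diploid size $N$ per population, discrete generations,
binomial resampling of allele frequencies, no mutation, migration or
selection. Defaults encode the study conditions: 13 populations with
effective sizes 26, 31, 65, 114, 128, 48, 535, 79, 54, 45, 294, 89 (wild
analogs) and 137 (hatchery analog); 500 independent biallelic loci founded
at frequency 0.5; checkpoints at 0, 5, 10, 20, 30, 40 and 50 generations.
Two modelling choices deserve comment:

* **Census size equals effective size.** The populations are parameterized
  directly by LD-based $N_e$ point estimates, and the monoecious binomial
  model realizes its census size exactly as its effective size, so no
  two-sex bookkeeping is needed.
* **Founding state.** Each of the $2N$ founding gene copies is an
  independent Bernoulli(0.5) draw, so founding frequencies vary around 0.5
  by binomial sampling error; generation-0 samples are *approximately*,
  not exactly, undifferentiated.

Between checkpoints only allele frequencies are propagated
(`Binomial(2N, p)` per locus per generation); diploid genotypes are
materialized by Hardy–Weinberg sampling only where they are consumed. With
independent loci and free recombination this is distributionally exact and
fast, but it produces *no linkage disequilibrium between loci*. Where
between-locus drift LD is itself the signal — LD-based $N_e$ estimation —
`sim_wf_population()` provides an individual-based model (two random
parents per offspring, one transmitted allele per locus per parent) whose
unlinked-locus $E[r^2] \approx 1/(3N_e) + 1/S$ behaviour is what
`estimate_ne()` measures.

# The analysis chain

**Differentiation.** `wc_fst()` implements the Weir–Cockerham (1984)
variance-components estimator $\theta$ (per-locus components $a$, $b$, $c$;
global ratio $\sum a / \sum(a+b+c)$), the default of the widely used
FST packages and the estimator this package uses everywhere. Nei's $D_A$
distance, neighbour-joining trees with locus-bootstrap support (via `ape`)
and a one-tailed Mantel test of linearized $F_{ST}$ against waterway
distance (via `vegan`, $p = (\#\{r^* \ge r\} + 1)/(B + 1)$) complete the
between-population toolkit. `fst_trajectory()` runs the frequency-level
simulator on a one-generation grid and reports the first generation at
which mean global $\theta$ reaches a reference level (the empirical overall
$F_{ST}$ of 0.118 by default); the coarse-checkpoint summary
(`trajectory_summaries()`) interpolates linearly instead.

**Diversity.** `diversity()` reports observed heterozygosity, Nei's
unbiased expected heterozygosity ($2n/(2n-1)\cdot 2p(1-p)$), the inbreeding
coefficient $F_{IS} = 1 - \bar H_o/\bar H_e$, and rarefied allelic richness
by exact hypergeometric rarefaction, with the rarefaction depth defaulting
to the smallest per-population gene count.

**LD-based effective size.** `burrows_r2()` uses Burrows' composite
disequilibrium with heterozygosity-adjusted denominators, which for sample
moments equals the squared Pearson correlation of dosage vectors.
`estimate_ne()` averages $r^2$ over locus pairs (optionally excluding
within-linkage-group pairs), subtracts the Waples (2006) random-mating
sample-size expectation (with the distinct $n \ge 30$ and $n < 30$
calibrations), solves the quadratic for $N_e$, and attaches a
delete-one-individual jackknife 95% CI (normal theory on mean $r^2$,
transformed through the monotone $N_e$ solution). Non-positive adjusted
disequilibrium yields an infinite estimate — a sample that carries no
detectable drift LD. We make no claim of bit-exact agreement with existing
estimator binaries; the published formulas are implemented directly.

**Ancestry.** `fit_admixture()` maximizes the standard binomial admixture
likelihood
$\sum_{ij} [\,g_{ij}\log(QF)_{ij} + (2-g_{ij})\log(1-(QF)_{ij})\,]$
by multiplicative EM with a compiled inner loop. EM rather than
quasi-Newton block relaxation was a deliberate choice: both maximize the
same likelihood, and EM's guaranteed monotone log-likelihood gives a clean
invariant to test. Because the likelihood is multimodal, several seeded
random restarts are run (3 by default) and the best kept. Cluster allele
frequencies are clipped to $[10^{-6}, 1-10^{-6}]$ so fixed loci cannot
produce $\log 0$; missing genotypes are simply omitted from the
likelihood. Estimated ancestry proportions are bounded below at
$10^{-5}$ (rows renormalized), mirroring the boundary projection of the
standard admixture software: memberships below that are not resolvable
from a few hundred loci, and letting them run to $10^{-17}$ would put
absurd leverage on the logit scale in the downstream regressions. The log-likelihood is evaluated every 5 iterations (it is the
most expensive part of an iteration); convergence is declared when the
per-iteration relative change falls below `tol` ($10^{-6}$ by default, with
a 400-iteration cap — fits on strongly structured data converge well before
it, while fits on unstructured generation-0 data plateau in a flat
likelihood region where further iterations do not move population-mean
ancestry).

**Choosing K.** `cv_error()` masks non-missing genotype *entries* (not
individuals) in five folds, refits, predicts masked dosages as
$2\,(QF)_{ij}$, and scores mean binomial deviance. The fold partition is
shared across the K values being compared, so per-replicate error curves
are paired comparisons. Cross-validation fits use one restart, a looser
tolerance ($10^{-5}$) and a 300-iteration cap: masked-entry deviance
stabilizes earlier than the full-likelihood optimum, and the K range times
folds times replicates multiplies any per-fit cost by several hundred —
but caps much below this leave high-K fits under-converged and visibly
distort the flat region of the error curve. The best-supported K is read off the
replicate-averaged CV curve; per-replicate argmins and their mode are also
reported, but with a flat CV minimum (the largest analog, $N_e = 535$,
has barely differentiated even at generation 50) individual replicates
scatter by one or two clusters around the truth while the averaged curve is
stable.

**Label switching and averaging.** Cluster labels are arbitrary per run.
`align_replicates()` permutes each fit's clusters to best match a reference
fit, minimizing summed $1 - \mathrm{cor}$ between ancestry columns with an
exact Hungarian assignment solver (`solve_assignment()`; ties break to the
lowest column index). The study driver aligns replicate fits within each
generation, averages ancestry within populations (`average_q()`), then
aligns the per-generation mean tables to the *final-generation* table, in
which populations are distinct. `distinct_cluster_assignment()` then maps
populations one-to-one onto clusters by maximizing total mean assignment —
again exact assignment, never greedy, so two populations can never claim
the same cluster. That final-generation map defines each wild population's
"eventual distinct cluster" and the hatchery analog's cluster at every
earlier generation.

**Regressions.** Each response — mean assignment of a wild analog to its
own eventual cluster, or to the hatchery analog's cluster — gives one row
per population per generation (12 wild analogs x 7 time points = 84 rows;
the hatchery analog's own rows are excluded from both responses, a rule
exposed through the dataset builder rather than hard-wired).
`fit_beta()` fits a beta regression with a logit mean link and constant
precision $\phi$ by maximum likelihood (BFGS with the analytic score on
column-scaled covariates; moment-based start; standard errors from the
observed information). `model_table()` ranks the five nested candidate
models (interaction, additive, generations-only, $N_e$-only, null) by
$\mathrm{AICc} = -2LL + 2k + 2k(k+1)/(n-k-1)$ with $k$ counting regression
coefficients plus $\phi$, and reports Akaike weights and the
Ferrari–Cribari-Neto pseudo-$R^2$ (squared correlation between the linear
predictor and the logit response; undefined for the null model, reported
as `NA`). Responses exactly on the boundary are nudged inward with the
standard $(y(n-1)+0.5)/n$ transform, with a message.

# Numerical and design notes

* **Seeds.** Every stage derives its seed from the master seed and integer
  tags (replicate, stage, generation) through a small multiplicative hash,
  so any single cell of the study grid is reproducible in isolation and
  results are invariant to execution order.
* **Genepop dialect.** The reader accepts 2- and 3-digit allele codes and
  both locus-name layouts; the writer emits 2-digit codes. Dosage counts
  the lexicographically larger allele code — the format carries no
  reference/alternate orientation, so this is the only deterministic,
  format-internal convention. A locus observed with a single allele code
  necessarily reads back as dosage 2; orientation at monomorphic loci is
  not recoverable from the format.
* **Filters.** The minor-allele-count, per-population call-rate and
  per-individual call-rate filters apply strictly sequentially, each acting
  on the matrix the previous step left, then optionally one SNP per contig
  (highest minor allele frequency wins, ties to the first locus id). The
  per-population call-rate filter is evaluated before individual removal,
  following the stated order of operations.
* **Problem sizes.** The analysis scripts and acceptance checks run the
  study at 20 replicates (CV stage: 10) rather than the published 100, and
  50 replicates for the dense FST trajectory. At these sizes the Monte
  Carlo error of every reported summary is far below the tolerances of
  interest (e.g. the SD of mean global theta across replicates is ~0.002
  at the crossing point).
* **Degenerate inputs.** Monomorphic-everywhere populations report
  $F_{IS}$ as missing, loci monomorphic across all populations contribute
  zero variance components and drop out of the $\theta$ ratio, an $F_{ST}$
  of 1 makes linearized distance infinite and is rejected with instructions
  to drop the pair, and constant distance matrices make the Mantel
  correlation undefined (an error, not a silent `NA`).

# What the simulations do and do not show

The generator reproduces the study conditions: isolation, constant $N_e$,
equal founding frequencies, unlinked neutral loci. Real populations violate
all four in places — gene flow would slow apparent divergence, fluctuating
$N_e$ (harmonic-mean dynamics) would accelerate it, linked loci reduce the
effective number of independent markers, and real founding events involve
bottlenecks rather than a clean common pool. Passing tests therefore show
that the *analysis chain* behaves as documented under the null drift
model, and that the published simulation summaries are reproducible from
the printed parameterization; they do not show that any particular
empirical population is hatchery-founded. The package deliberately reports
the machinery (assignment trajectories, model tables, prediction surfaces)
needed to ask that question of real data rather than answering it.

# Known limitations

* The admixture model is unsupervised only; no supervised or
  reference-anchored mode is provided.
* LD-based $N_e$ implements the random-mating bias corrections; monogamy
  corrections and temporal methods are out of scope.
* Beta regressions use a constant precision; precision covariates and
  mixed effects are not implemented.
* VCF ingestion is not provided; empirical users should convert to genepop
  or a dosage CSV upstream.
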
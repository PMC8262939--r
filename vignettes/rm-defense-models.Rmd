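---
title: "Resource competition, viral memory, and the accumulation of restriction-modification systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource competition, viral memory, and the accumulation of restriction-modification systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmdefense)
```

## The scientific question

Restriction-modification (RM) systems are innate antiviral defenses: a
restriction endonuclease cleaves invading double-stranded DNA at short
recognition motifs, while a paired methyltransferase methylates the same
motifs on the host chromosome to protect it. Bacterial genera differ
enormously in how many complete RM systems they carry per genome (RMPG) —
bloom-forming freshwater cyanobacteria sit at the extreme high end, while
oligotrophic picocyanobacteria carry almost none. `rmdefense` implements a
family of chemostat-style resource-competition models, and the statistics
and annotation logic around them, to ask when nutrient supply selects for
more RM defense, and why ordinary defense models cannot explain extreme
RMPG while a model with virion "methylation memory" can.

## The models

All three model kinds share the nutrient equation

$$\frac{dN}{dt} = S - \sum_i \alpha (1 - c_i) B_i N,$$

with supply rate $S$ (cellular equivalents ml$^{-1}$ day$^{-1}$), uptake
rate $\alpha$ (ml cell$^{-1}$ day$^{-1}$) and a linear defense cost
$c_i = \text{per-RM cost} \times |b_i|$, where $b_i$ is the *set* of RM
systems carried by host population $i$. Hosts grow on nutrients, die at
rate $\delta_b$, and are infected at a baseline rate $\phi$ (ml
virus$^{-1}$ day$^{-1}$) scaled by a susceptibility coefficient; phage
burst with size $\beta$ and decay at $\delta_p$.

* **General model** — one phage infects every host. Each RM system
  multiplies the infection rate by $1/r_e$, so host $i$ is attacked at
  $\phi\, r_e^{-|b_i|} B_i P$. Multiplicative protection means two systems
  at a 100-fold reduction each give a 10,000-fold reduction.
* **Parallel model** — one phage per host, no cross-infection; otherwise
  identical. A control in which defense is generic.
* **Memory model** — one phage population per host, but every phage can
  infect every host. A virion bursting from host $j$ carries that host's
  methylation pattern $p_j$, and its susceptibility to host $i$ is
  $$\Gamma_{ij} = r_e^{-\left(|b_i \setminus p_j| +
    (1 - m_v)\,|b_i \cap p_j|\right)},$$
  with $m_v \in [0,1]$ the fraction of restriction sites methylated on
  progeny virions. Shared systems protect only through their unmethylated
  site fraction $1-m_v$; at $m_v = 0$ the matrix collapses to the general
  model, at $m_v = 1$ a phage fully evades its last host's defenses.
  Progeny of *all* infections of host $i$ join phage population $i$ — they
  inherit its methylome — which is what makes every phage lineage a
  potential escape mutant of its source host.

```{r gamma}
# the memory matrix for a 3-level nested ("subset") community
cm <- build_community(3, "subset", "memory")
gamma_matrix(lapply(cm$hosts, `[[`, "rm_set"),
             lapply(cm$phages, `[[`, "methylation"), r_e = 100, m_v = 0.75)
```

## Default parameters

The package defaults (see `model_params()`) were chosen once to place the
three qualitative supply regimes of a 1-RM vs 2-RM competition inside a
supply gradient of $10^5$–$10^{10}$ cellular equivalents ml$^{-1}$
day$^{-1}$, with abundances in the ranges observed for freshwater and
marine cyanobacteria ($10^5$–$10^{10}$ cells ml$^{-1}$):

| parameter | default | units | meaning |
|---|---|---|---|
| `alpha` | 1e-7 | ml cell⁻¹ day⁻¹ | nutrient utilization |
| `phi` | 1e-8 | ml virus⁻¹ day⁻¹ | baseline infection rate |
| `r_e` | 100 | fold | resistance per endonuclease |
| `per_rm_cost` | 0.05 | fraction | uptake lost per RM system |
| `beta` | 50 | virus cell⁻¹ | burst size |
| `delta_b`, `delta_p` | 0.1 | day⁻¹ | host / phage loss |
| `m_v` | 0.75 | fraction | virion methylation (memory model) |

With these values the closed-form thresholds for the two-host general
model put viral invasion near $S \approx 2\times10^6$, defense-specialist
invasion just above it, and competition-specialist exclusion near
$S \approx 2\times10^8$. We note `phi` is carried in ml virus⁻¹ day⁻¹,
the dimensionally consistent unit for a mass-action infection term
$\phi\gamma B_i P$.

```{r regimes}
cm2 <- build_community(2, "subset", "general")
m <- rm_model("general", cm2$hosts, cm2$phages, model_params())
sw <- sweep_supply(m, 10^seq(5, 10, length.out = 11))
print(sw)
```

## Numerical strategy

`integrate_to_equilibrium()` integrates with `deSolve::lsoda` (the
right-hand side is compiled C shared by all model kinds) and certifies an
equilibrium when the maximum relative derivative
$\max_i |\dot x_i|/(|x_i| + 10^{-30})$ falls below `rel_tol` (default
1e-6). Two practical complications shape the implementation:

* **Extinction floor.** A population decaying exponentially keeps a
  relative derivative of $\delta_b$ forever; abundances below
  $10^{-10}$ ml$^{-1}$ are therefore clipped to exactly zero between
  integration chunks. Zero is an invariant set of the dynamics, so this
  only commits populations that are already vanishing.
* **Weakly damped predator–prey cycles.** Host–phage pairs in these models
  can approach their fixed point through oscillations damped on timescales
  of $10^4$–$10^5$ days. Rather than resolving those, each chunk attempts
  a damped Newton solve of the steady state in log abundance space, seeded
  by the chunk's geometric time average (which centers the oscillation).
  A candidate is accepted only if it is non-negative, locally stable
  (all Jacobian eigenvalues with negative real part), and no excluded
  population can regrow from it. If no stable equilibrium is certified —
  a sustained limit cycle — the run reports `converged = FALSE` with the
  time average over the final integration window attached.

Supply sweeps (`sweep_supply()`) ascend the grid with warm starts: each
steady state seeds the next supply rate, with extinct populations reseeded
at $10^{-2}$ ml$^{-1}$ so that invasion at higher supply remains possible.
The reseeding floor is a protocol choice; equilibria themselves are
init-independent across starting abundances of $10^2$–$10^6$ for the
default parameter sets, which the test suite checks.

## Community arrangements and ensembles

`build_community(n, arrangement, kind)` builds the ladder community in
which host $i$ carries $i$ RM systems, either as nested **subsets**
(`{r1} ⊂ {r1,r2} ⊂ …`, successive gene gain) or as pairwise-disjoint
**unique sets** (the endpoint of repeated gain *and* loss). We read
"unique sets" as fully disjoint; partial overlap would interpolate between
the two arrangements. A 0-RM host can be added with `include_zero`
(off by default — the escalation experiments start at one system).

`lhs_sample()` draws Latin-hypercube parameter ensembles
(`lhs::randomLHS` under a fixed seed) with `r_e` and `phi` on log-uniform
scales; `run_ensemble()` repeats a sweep across draws, and
`ensemble_summary()` reports medians with 25th/75th quantile ribbons.
Default ranges span roughly a factor of four around each default rate
(an order of magnitude and more for `phi` and `r_e`), wide enough to probe
robustness while keeping the regime structure identifiable. Everything is
bit-for-bit reproducible from the root seed.

## RM-system calling from evidence tables

The annotation module consumes *precomputed* per-protein evidence —
profile-HMM domain hits and reference-protein alignments — and applies
the genomic-context rules; it never runs the search tools themselves:

1. profile hits on one protein that overlap by ≥ 75% of the shorter
   envelope are competed, keeping the lower E value
   (`compete_profiles()`);
2. alignments count only with ≥ 75% query coverage and E ≤ 1e-5
   (`accept_alignment()`);
3. proteins classify as fused systems (both activities on one peptide),
   putative type IIG candidates (methyltransferase-only, strictly longer
   than 750 aa), methyltransferases, endonucleases — with ResIII-type
   evidence voided when a false-positive covariate domain co-occurs — or
   specificity subunits (`classify_protein()`);
4. a complete system is a fused or putative-IIG peptide, or an
   endonuclease ≤ 4,000 bp (gap between the nearest gene boundaries, same
   contig, strand ignored) from a methyltransferase, paired greedily
   nearest-first and one-to-one (`call_complete_systems()`).

`count_rmpg()` reports totals with and without the putative type IIG
calls, since the size-only IIG rule is the least certain step. The
synthetic generator `gen_annotation_fixture()` plants systems that satisfy
these rules with margin and decoys that each violate exactly one rule at
its boundary (gap 4,001 bp, 74% coverage, E = 1.1e-5, exactly 750 aa), so
the boundary semantics are pinned by tests rather than by convention.

## Genus-level statistics

`aggregate_genus()` averages isolate counts within genera before any
distribution statistic, so overrepresented taxa cannot dominate.
`summarize_rmpg()` computes means, medians and 5th/95th quantiles by
linear interpolation of order statistics (the common default; published
tail quantiles are sensitive to this convention, which is why it is
stated). `rmpg_fit()` regresses genus-mean RMPG on genome size in Mbp,
either by ordinary least squares or by a log-link negative-binomial fit.
Genus means are not integers; the default NB mode maximizes the NB
log-likelihood in its gamma-function form, which is well defined for
continuous responses, and an `nb_response = "round"` mode provides the
integer-rounding alternative via `MASS::glm.nb`. Both report McFadden's
pseudo-$R^2$, $1 - \ell_{\text{fit}}/\ell_{\text{null}}$.
`delta_size_for_one_rm()` converts a fit into the genome expansion needed
to gain one RM system ($1/\text{slope}$ for a linear fit; the log-link
solution otherwise). `rank_sum_test()` is a Wilcoxon rank-sum test that
enumerates the tied permutation distribution exactly for $n \le 20$ and
uses the tie-corrected, continuity-corrected normal approximation above
that.

## What the synthetic data do and do not show

The generators emulate the *structure* of real inputs — evidence tables
with planted truth, isolate tables with known generating slopes and
dispersions — so that the pipeline's rules and estimators can be verified
exactly or at nominal coverage. They do not emulate real protein domain
architectures, genome organization beyond gene intervals, phylogenetic
correlation among genera, or habitat covariates; passing tests therefore
demonstrate correctness of the logic, not recovery of any published
biological value. The published genus-level table itself is an external
input; when a copy is supplied, the same functions reproduce its summary
statistics and regressions.

## Problem sizes and reproducibility

The test suite and acceptance script use two-to-three–level communities
on 11–30-point supply grids, ensembles of 25–100 draws on reduced grids,
and simulated tables of 300–1,000 genera; these sizes give stable
statistics while keeping a full run in tens of seconds. All stochastic
steps derive from a single root seed per experiment; the ODE solves are
deterministic.

## Known limitations

* The models are deterministic and well mixed: no demographic noise, no
  spatial structure, no within-run evolution of RM sets, and strictly
  linear (mass-action) infection kinetics.
* Steady-state reports favor the stable equilibrium reachable from the
  warm-started trajectory; genuinely oscillatory parameter draws are
  reported as non-converged time averages rather than resolved cycles.
* The type IIG size rule (> 750 aa) is a deliberately coarse stand-in for
  structure-level confirmation, which is outside this package's scope.
* The NB regression on non-integer genus means has no single canonical
  definition; both implemented conventions are documented above, and
  results that differ between them should be reported with the mode used.
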
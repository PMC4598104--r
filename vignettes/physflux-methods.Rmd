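---
title: "Physiological shrinkage of a flux space: models, choices and limits"
author: "physflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiological shrinkage of a flux space: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic generators do and do not emulate, and the numerical choices made
where the design was genuinely open. Code chunks illustrate usage; the
quantitative claims in the test suite and `scripts/acceptance.R` are the
package's empirical record.

## 1. The pipeline at a glance

Aerobic, glucose-limited *S. cerevisiae* cultures occupy two metabolic
regimes. Below a glucose uptake of about 4 mmol gDW^-1 h^-1 the cell
respires: oxygen uptake rises with glucose uptake and the respiratory
quotient (RQ = CO2 out / O2 in) stays near 1. Above it, overflow
metabolism (the Crabtree effect) sets in: ethanol production grows
linearly with uptake while oxygen uptake declines. These phenotype-
phenotype regularities, visible across dozens of independent chemostat
studies, are information a stoichiometric model does not contain. The
pipeline converts them into constraints:

1. **flux_meta** — fit glucose-dependent linear bands for O2, ethanol and
   glycerol exchange from a multi-study flux-phenotype table.
2. **cbm_core** — represent the stoichiometric model; FBA/FVA; apply the
   bands (fixed-glucose or window mode); essentiality screen; reaction
   eligibility filter.
3. **growth_envelope** — at each glucose uptake on a grid, draw the three
   exchanges uniformly within their bands, fix them, maximize growth;
   the extremes over draws bound the achievable growth rate.
4. **space_sampling** — sample the shrunken polytope uniformly; trimmed
   per-reaction extremes give AF, FF and FCS.
5. **noise_stats** — correlate FF with gene-expression noise (DM) for
   dosage-sensitive reaction genes, split by reaction essentiality;
   permutation test for the group difference in FF.

## 2. Band fitting and its parameters

`fit_slope()` is ordinary least squares of a phenotype on glucose uptake,
restricted to one regime. The regime boundary (`transition = 4`,
mmol gDW^-1 h^-1) is a fixed marker, with the boundary value assigned to
respiration; it can be overridden but is not estimated.

Offsets were an open design point: the source practice of setting band
offsets "by visual inspection" is not reproducible. `calibrate_offsets()`
instead uses residual order statistics: with the slope held fixed,
`floor(n * (1 - coverage) / 2)` most extreme residuals are left outside
on each side, which guarantees the band contains at least `coverage`
(default 0.90) of the calibration points — the same coverage target,
made deterministic. The glycerol band passes through the origin with two
slopes taken as the same order statistics of the per-point ratio
`v_gly / v_glu`; points with zero uptake cannot inform a ratio band and
are excluded from its calibration.

`loe_validation()` refits the slope with each study left out; the
reported dispersion is the maximum relative deviation from the all-data
slope. It is a robustness diagnostic, not an inferential procedure.

Missing phenotype fields exclude a record only from fits involving that
phenotype. Lower band edges are clamped at zero (rates are
non-negative). A minimal oxygen uptake of 0.016 mmol gDW^-1 h^-1 is
imposed when a band's lower edge falls below it — applied where the
bands meet the model, not during fitting.

```{r}
library(physflux)
flux_tab <- generate_flux_dataset(synthetic_flux_config(seed = 1))
pc <- build_constraints(flux_tab, coverage = 0.90)
band_coverage(pc, flux_tab, "ethanol")
```

## 3. The LP layer

All optimization goes through one internal routine: a dense two-phase
primal simplex for bounded variables using Bland's smallest-index rule.
The choice was deliberate: the pipeline solves thousands of small,
highly degenerate LPs (knockouts pin variables to zero; closed-exchange
loop detection sets every exchange to zero), and the general-purpose
simplex implementations available to R either break down on zero-width
variables or randomize pivot ties — the latter both fails sporadically on
degenerate instances and consumes the RNG stream, which would poison
seeded reproducibility. Bland's rule is slower per iteration but cannot
cycle and is exactly deterministic. Problems here have tens of
variables, so dense refactorization each iteration is cheap. The suite
validates the solver against exhaustive vertex enumeration on toy
networks and random boxed LPs.

Contracts are always on the objective value and feasibility (mass
balance within 1e-6, bounds within 1e-6), never on a unique flux vector:
any optimal vertex is acceptable.

Essentiality tolerances: a knockout is *essential* when its optimum
falls below `tol_abs = 1e-6` and *non-essential* when within
`tol_rel = 1e-3` of wild type. An exact zero/unchanged dichotomy is not
exhaustive under LP arithmetic, so the in-between outcome is labelled
*partial* and excluded from essential/non-essential groupings.

Reaction eligibility for flux statistics excludes: loop reactions
(non-zero flux range when all exchanges are closed — the closed-exchange
FVA convention), reactions without a single-gene rule (isozyme `or`
rules, complex `and` rules, gene-less reactions — the strictest reading
of a one gene-one reaction mapping), and reversible reactions.

## 4. Growth envelope

At each grid point (default 0 to 24, step 0.1) the three exchange rates
are drawn uniformly and independently within their bands, fixed, and
growth is maximized; draws incompatible with steady state are discarded
and counted rather than repaired, and the acceptance rate is part of the
result. Envelope extremes are order-free in the draws. Between grid
points, membership tests interpolate linearly. Segment fits
(`fit_segments()`) default to a breakpoint at the transition marker;
`find_breakpoint()` offers an exhaustive two-segment search when the
kink location is unknown.

Degenerate bands collapse the envelope to a single curve, and widening
any band can only widen the envelope — both are tested properties. Note
one boundary artifact of the toy setting: at glucose uptake exactly 0
the oxygen floor (0.016) exceeds what a zero-uptake network can respire,
so every draw is infeasible and the grid point is flagged rather than
fabricated.

## 5. Polytope sampling

`sample_space()` runs artificial-centering hit-and-run in the null-space
parameterization of the equality constraints. Fixed reactions
(`lb == ub`) are folded into the equality system so the chain moves only
in genuinely free directions; bounds and band-coupling rows become
inequalities on the null-space coordinates. Warm-up points are the FVA
vertices; directions go through previously visited points relative to
the running center, adapting steps to elongated polytopes — the de facto
standard chain for this model class (the original work does not name its
sampler). Defaults: burn-in 1000, thinning 1, single chain; all
configurable. Determinism under seed is part of the contract, and every
retained sample is re-verified against all constraints within 1e-6.

Trimming is per-reaction marginal: `floor(n * trim)` smallest and
largest values are discarded (default 5% per tail) before taking
extremes. FF is flagged undefined when AF falls below 1e-9 (a 0/0
regime), FCS when the original-space range falls below 1e-9; undefined
values are excluded from correlations, never imputed.

The *original* space for FCS keeps the glucose window (and zeroed
alternative carbon sources) but drops the three phenotype bands, so FCS
isolates the bands' effect rather than conflating it with the window.
Growth-rate bounds from the envelope are deliberately *not* imposed
during sampling — the shrunken space is defined by the three exchange
bands alone.

Problem sizes: the suite samples 20,000-50,000 points on polytopes of
dimension up to 5 and the acceptance script uses 30,000 per space on a
grid of step 0.5 with 300 draws per point — sizes at which the sampled
extremes sit within a few percent of the LP-exact FVA bounds on the toy
networks while the whole pipeline reruns in well under a minute.

## 6. Synthetic study conditions

`generate_flux_dataset()` draws multi-study tables from a piecewise-
linear ground truth with truncated-Gaussian noise (resampled at zero:
rates are non-negative). Defaults were chosen once as realistic aerobic
chemostat physiology and then frozen: oxygen slope 2.0 (+0.5) below the
transition and -0.2 (+9.3, continuous at 4) above; ethanol slope 0.6
through zero; glycerol ratio 0.08; noise sd 0.8 / 0.8 / 1.0 / 0.25 /
0.015 for O2 / CO2 / ethanol / glycerol / growth; CO2 = O2 + ethanol so
RQ is 1 under pure respiration and rises with overflow. Below the
transition the ethanol and glycerol means default to zero
(`clamp_below_transition = TRUE`) — the respiratory regime secretes
essentially none of either, and a respiring network could not satisfy
both an oxygen band consuming all glucose and a simultaneous ethanol
demand. Zero-noise recovery tests disable the clamp so every phenotype
lies exactly on one line.

The `minicore` toy network mirrors those conditions: respiration (2 O2
per glucose, biomass yield 0.07), fermentation (0.8 ethanol + 0.8 CO2
per glucose, yield 0.010), a glycerol branch (yield 0.003), a glucose-
burning maintenance reaction and an alternative-oxidase-style O2 sink.
The last two give the toy the slack degrees of freedom a genome-scale
model has naturally; without them, fixing glucose plus three phenotype
draws overdetermines the network and almost every draw is infeasible.
Growth defaults of the flux generator (yield 0.06 below the transition,
slope 0.005 above) keep the synthetic growth observations achievable by
this network, so envelope membership is a meaningful check.

`generate_expression_data()` plants a target Spearman correlation
between supplied FF values and DM via a Gaussian copula: the normal
score of the FF ranks is mixed with independent noise at Pearson weight
`r = 2 sin(pi * rho_s / 6)`, the exact correspondence between a
bivariate-normal copula and its Spearman correlation. Dosage-sensitive
genes are constructed by assignment — exactly `round(n * fraction)`
genes receive |log2(SD/YEPD)| in (1.2, 3), the rest below 0.8 — so the
cutoff-1 filter recovers them by design.

What the generators do **not** emulate: inter-study systematic offsets
(batch effects), heteroscedastic measurement error, correlated
phenotype errors within a record, genome-scale network structure
(hundreds of coupled reactions, realistic GPR complexity), or the
abundance-dependence that real DM values have already been corrected
for. Passing tests therefore demonstrate the pipeline's correctness and
calibration on data of known structure, not that real yeast data meets
these assumptions.

## 7. Statistical conventions

Spearman correlations use average ranks for ties. For n <= 8 the
p-value is exact, by vectorized enumeration of all rank permutations;
beyond that the t-approximation is used. (Enumeration to n = 10 — 3.6M
permutations — buys little over the t-approximation at the cost of a
memory-heavy special case, so the exact boundary sits at 8;
`exact_max_n` is an argument.)

The permutation test shuffles values into the observed group sizes
(default 10,000 relabelings, the figure-level convention; 100,000 — the
methods-level convention — is one argument away), and reports the null
standard deviation, a z-score, and a two-sided empirical p with add-one
correction `(b + 1) / (n_perm + 1)`. No multiple-testing correction is
applied across the exploratory correlation battery, matching the
analysis this package reimplements.

Two calibration caveats surfaced while testing and are worth recording:
a null group of 20 genes has Spearman sd ~ 1/sqrt(19) = 0.23, so |rho| <
0.3 holds in only ~81% of draws — null checks must use the properly
scaled 2-sigma band; and the respiratory yield line is an upper-envelope
target only where the fitted ethanol band still permits zero
fermentation (its lower edge clamps at zero), since beyond that point
the band itself forces flux off the pure-respiration ceiling.

## 8. Interfaces and formats

Models read and write a small JSON dialect (id, metabolites, reactions
with stoichiometry maps, bounds, gene rule, exchange flag, objective,
exchange-role map) and SBML level 3 with the flux-balance (fbc)
conventions: flux-bound parameters, gene-product associations (flat
and/or rules), and an active maximization objective. Flux tables are
plain CSV with documented columns; all analysis results are data.frames.
The package's exported functions, this vignette and
`scripts/acceptance.R` are the interface; no shell tool is shipped, as
is usual for analysis packages of this kind.

## 9. Known limitations

- The simplex is dense and refactorizes each iteration: right for toy
  and mid-sized models, not tuned for genome-scale FVA (thousands of
  reactions), where a sparse revised simplex or interior-point solver
  would be the next step.
- Hit-and-run uniformity is asymptotic; on high-dimensional or badly
  elongated polytopes the fixed default burn-in may be insufficient.
  The suite verifies uniformity only up to dimension 3 against
  rejection sampling, plus FVA-domination diagnostics above that.
- Window-mode constraints refuse glucose windows straddling the
  transition (the oxygen band is regime-specific); sample each regime
  separately instead.
- The envelope's draw-rejection design means grid points whose bands
  are entirely infeasible are reported as gaps, not extrapolated.
- Essentiality is a reaction-deletion screen; gene deletions through
  GPR evaluation are out of scope.
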
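---
title: "Inferring ovarian precursor censuses from clone-marking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ovarian precursor censuses from clone-marking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecensus)
```

## The inference problem

Adult *Drosophila* germaria contain three somatic cell populations laid out
along the anterior-posterior (AP) axis: quiescent escort cells (ECs, split
into region 1 and region 2a), about 16 proliferating follicle stem cells
(FSCs), and follicle cells (FCs) coating germline cysts and budded egg
chambers. All three derive from dividing pupal precursors. Clone-marking
experiments (MARCM, multicolor recombination, GAL4-driven lineage tracing)
permanently label the mitotic descendants of single cells, so the pattern of
marked cell types per adult ovariole reports what each precursor went on to
produce.

Scored ovarioles fall into five observable **clone categories**: `EC_only`,
`EC_FSC` (ECs and FSCs, with or without FCs), `FSC_only` (FSCs without ECs,
with or without FCs), `FC_only`, and `EC_plus_FC` -- marked ECs *and* FCs but
no FSC. Because a single lineage spreads contiguously along the AP axis, an
ovariole whose marks skip the FSC domain almost certainly carries **two**
independent lineages; the `EC_plus_FC` class is therefore the key to
estimating how often multiple recombination events hit the same ovariole.

The package answers three questions from such data:

1. What fraction of marked ovarioles carries a single lineage (`sigma`)?
2. What are the frequencies of the four *single-lineage types*
   (`p_ec`, `p_ecfsc`, `p_fsc`, `p_fc`) among all marked lineages?
3. How many dividing precursors of each type does a germarium contain?

## The binomial labeling model

If each of `n` dividing precursors is labeled independently with probability
`p`, the unlabeled-ovariole fraction is `(1-p)^n`, and the expected fraction
of marked ovarioles carrying a single lineage is
`n p (1-p)^(n-1) / (1 - (1-p)^n)`. `infer_per_cell_probability()` inverts the
first relation and `single_lineage_fraction()` evaluates the second. The
result depends only weakly on the assumed `n`: at 60% labeling the single
fraction is 0.62-0.66 for `n` between 6 and 30, which is why this model is
useful even though the true precursor number is only roughly known.

The observed `EC_plus_FC` frequency is typically *larger* than this
independence model predicts, indicating clustered recombination. The mixture
model below therefore treats `sigma` as a free parameter rather than taking
the binomial value at face value.

## The one-vs-two-lineage mixture model

A fraction `sigma` of marked ovarioles carries exactly one lineage; the rest
carry exactly two, drawn independently from the type frequencies. Pairs
containing an FSC-producing lineage always land in an FSC-containing
category, which closes the system on three observables:

$$f_{EC} = \sigma\,p_{EC} + (1-\sigma)(p_{EC}^2 + 2 p_{EC} p_{FC})$$
$$f_{FC} = \sigma\,p_{FC} + (1-\sigma)(p_{FC}^2 + 2 p_{EC} p_{FC})$$
$$f_{FSC} = \sigma\,p_{FSC} + (1-\sigma)(p_{FSC}^2 + 2 p_{FSC} p_{FC})$$

with the discontinuous class itself given by
$f_{EC+FC} = (1-\sigma)\,2 p_{EC} p_{FC}$. Here $f_{EC}$ counts every
ovariole with marked ECs and no FSC -- the `EC_plus_FC` class is included in
**both** $f_{EC}$ and $f_{FC}$. This shared-counting convention is the single
most error-prone step when preparing inputs, which is why
`aggregate_frequencies()` applies it mechanically and the category-exclusive
fractions are never exposed to the solver.

`forward_category_frequencies()` implements these equations and is
property-tested against brute-force enumeration of all ordered lineage pairs.
`solve_lineage_frequencies()` inverts them: the coupled
$(p_{EC}, p_{FC})$ system is solved by damped Newton iteration with the
analytic Jacobian, started from the `sigma = 1` identity solution, with a
dense grid search as fallback; $p_{FSC}$ is then the non-negative root of its
quadratic (the paired root is always non-positive, so root selection is
unambiguous away from degenerate corners), and $p_{EC/FSC}$ follows by
complement. Solutions are accepted only if the forward model reproduces the
inputs to 1e-9 and all components lie in $[0,1]$; otherwise the violated
equation is named in the error.

`estimate_single_fraction()` chooses `sigma` on a grid (default step 0.05,
the resolution at which the quantity is meaningfully constrained) by
minimizing the absolute gap between predicted and observed $f_{EC+FC}$, with
ties broken toward larger `sigma` -- the weaker clustering assumption. We
anchor the fit on $f_{EC+FC}$ alone because it is the only observable that
directly counts two-lineage ovarioles; the full residual table is returned in
`$grid` so the flatness of the objective can be inspected. Note that this
estimator is a residual minimizer: on one of the bundled datasets
(`multicolor`) it selects 0.50 where the original analysis adopted 0.70 by
judgment, blending the binomial prior with the EC+FC evidence. Both the
estimate and its decision path are reported so the choice stays visible.

A variant, `solve_all_double_ecfc_anchored()`, covers experiments with
essentially no `FC_only` ovarioles (e.g. a GAL4 driver that rarely labels
posterior precursors): all ovarioles are assumed double and the system is
anchored on the category-exclusive `EC_only` and `EC_plus_FC` classes
($p_{EC} = \sqrt{f_{EC\,only}}$, $p_{FC} = f_{EC+FC}/2p_{EC}$). The FSC
quadratic in this variant is $p_{FSC}^2 + 2\,p_{FSC}\,p_{FC} = f_{FSC\,only}$:
the FSC-only class pairs an FSC lineage with itself or with an FC-only
lineage, exactly as in the general model at `sigma = 0`.

## From per-ovariole means to per-lineage yields

Observed mean marked-cell counts per category ovariole overstate per-lineage
output whenever ovarioles hide two lineages. An `EC_only` ovariole can hide
two EC-only lineages or an (EC-only, FC-only) pair, in proportions
$p_{EC}^2 : 2 p_{EC} p_{FC}$; `category_pair_composition()` renormalizes
these and returns the mean number of focal lineages per category ovariole,
$\sigma + (1-\sigma)(2 w_{same} + w_{cross})$. Dividing the observed mean by
this multiplicity gives the per-lineage yield (`per_lineage_yield()`). The
multiplicity formula applies `sigma` as the unconditional single-lineage
fraction rather than the slightly different conditional fraction within the
category; the difference is below 0.01 lineages per ovariole for all bundled
datasets and keeping the simpler form makes every intermediate reproducible
by hand.

EC/FSC lineages are never observed pure, so their yields come from
accounting (`ecfsc_yields_by_subtraction()`): with
$L = N_{marked}(2-\sigma)$ total lineages, the EC output of EC-only lineages
and the FSC output of FSC-only lineages are subtracted from the experiment
totals and the remainders divided by the EC/FSC lineage count. The
construction makes the attribution exact by definition -- the per-type
outputs sum back to the scored totals -- and negative remainders raise an
error with diagnostics instead of propagating silently.

## The precursor census

Only EC/FSC and FSC-only lineages make FSCs, at per-lineage rates $x$ and
$y$. Normalizing total FSC production to the adult complement of 16 FSCs per
germarium gives the number of dividing precursors:

$$n_{total} = \frac{16}{p_{EC/FSC}\,x + p_{FSC}\,y},$$

with per-type counts $p_i \cdot n_{total}$ (`precursor_census()`). Because
$x$ is built by subtraction, this is algebraically identical to
$16\,L/Z$ where $Z$ is the total number of marked FSCs scored -- the census
ultimately rests on just the marked-ovariole count, `sigma`, and the FSC
total. `run_full_census()` verifies this identity on every run and records
any violation in the report notes.

A second, independent normalization (`germarium_production()`,
`table2_production()`) scales summed marked r1 EC, r2a EC and FSC counts by
`16 / total FSCs` to estimate how many ECs of each region are made from
dividing precursors at each induction time; the decline of this number at
later induction times estimates how many EC precursors have ceased dividing
(`nondividing_ec_estimate()`), since non-dividing cells cannot be labeled.

## Scoring conventions

Two conventions from the data model matter for reproducibility:

* **Day-2 adult reclassification** (`reclassify_day2_adult()`): marked FSCs
  present at eclosion may convert to FCs within two days; such FCs can only
  occupy the germarium or the two youngest egg chambers (one budding event
  per ~12 h). A day-2 record with no marked FSC but marked FCs at locations
  `I`, `G`, `E1` or `E2` is therefore treated as FSC-containing with an FSC
  count of zero. FCs confined to `E3`/`E4` never trigger the rule, and the
  rule is idempotent.
* **Basal-stalk imaging** is a three-state flag (`yes`/`no`/`not_imaged`);
  missing imaging is never coerced to absence.
* Ovarioles with marked FSCs and marked FCs only in the most mature egg
  chamber are *not* split into a suspected extra FC-only lineage; they stay
  in their FSC-containing category. The census therefore attributes all their
  cells to FSC-producing lineages.

## The synthetic-data generator

`simulate_dataset()` is the generative mirror of the mixture model, so the
whole pipeline can be validated by parameter recovery without external data.
Its defaults are the study conditions of the 0 hr APF MARCM experiment:
labeled fraction 0.473, `sigma = 0.3`, type frequencies
(0.63, 0.13, 0.05, 0.19) in the worked examples, and per-lineage yield means
(1.76, 4.32, 3.15/3.47).

Design choices, each made once:

* **Yield distributions.** Only mean yields are reported by such experiments,
  so counts are drawn from a zero-truncated negative binomial (dispersion
  `size = 2`, a moderate overdispersion typical of clone-size data);
  truncation guarantees a lineage exhibits its defining cell type, and the
  *truncated* mean is calibrated to the configured yield by solving
  `mu / (1 - (k/(k+mu))^k) = target` with `uniroot()`, so recovered yields
  are comparable to the configuration without bias.
* **Independence.** The two lineages of a double ovariole are drawn
  independently from the type frequencies -- exactly the assumption the
  inverse equations make. The generator deliberately has no three-lineage
  ovarioles, matching the model's scope.
* **Plumbing realism.** EC counts split into r1/r2a binomially (r1 share 0.6,
  the approximate 19:14 ratio of adult EC output); FSC-containing lineages
  carry FCs with probability 0.9 (25/27 in the motivating data); FC-only
  lineages draw locations from a two-zone scheme (terminal pool `E4`/`E3;E4`
  with probability 0.7, anterior pool otherwise), echoing the segregation of
  first-egg-chamber FC precursors. Locations and the basal-stalk flag are
  exercised only by the record-handling code, never by the census math.

What the generator does **not** emulate: spatial AP coordinates and lineage
contiguity (categories are drawn, not grown), germline cyst dynamics, loss or
amplification of marked FSCs between eclosion and scoring, and scoring error.
Passing recovery tests therefore validate the *inference algebra* under the
model's own assumptions, not the biological fidelity of those assumptions.

`recovery_experiment()` repeats simulate/deconvolve/census over replicates
and reports per-parameter bias and RMSE plus the `sigma` grid hit rate. At
5,000 ovarioles per replicate and 20 replicates (the problem size used by the
test suite, which keeps a full recovery run under a minute) the lineage-type
frequencies recover with |bias| < 0.01 and the census total with RMSE ~1.1
precursors around its truth of 24.

## Numerical choices and degenerate inputs

* All intermediates are carried at full precision; printed-value comparisons
  happen only in tests, with per-quantity tolerances (frequencies +/-0.01,
  yields +/-0.1, precursor counts +/-0.5) reflecting that the original desk
  chains round intermediates to two decimals.
* Newton steps are damped (halved until the residual shrinks and the iterate
  stays in the unit square); on failure a 0.02-resolution grid seeds a
  second Newton pass.
* `sigma = 1` makes the FSC quadratic linear and the mixture solve an
  identity; both are handled explicitly.
* Zero marked ovarioles, zero FSC production, negative subtraction
  remainders, and infeasible frequency vectors all raise errors naming the
  offending quantity; nothing is clamped silently. The single-lineage
  fraction may exceed 1 for inconsistent binomial inputs -- it is returned
  with a warning, not clamped.

## Known limitations

* The two-lineage ceiling is an approximation; at very high labeling rates
  (e.g. 94% labeled) some ovarioles surely carry three or more lineages and
  the census is correspondingly less reliable.
* `sigma` is estimated at 0.05 resolution from a single observable; its
  uncertainty is not propagated into the census. No confidence intervals are
  produced anywhere -- the method is a deterministic moment construction.
* Published summaries of this kind are internally rounded and occasionally
  inconsistent; where a bundled dataset's raw row and its worked analysis
  disagree (the multicolor FC-only count, the bond-GAL4 census total), the
  package computes from the stated inputs at full precision and the
  documentation of `load_experiment()` and the test suite record the
  discrepancies rather than reproducing arithmetic slips.
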
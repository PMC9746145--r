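---
title: "Methods: estimating social fitness from dilution-plate spore counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating social fitness from dilution-plate spore counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporefit)
```

## The assay and the quantities of interest

Myxobacteria such as *Myxococcus xanthus* respond to starvation by
cooperatively developing into fruiting bodies in which a fraction of cells
becomes stress-resistant spores. Mutants deficient in intercellular
signalling sporulate poorly on their own but may be rescued — or even gain
an advantage — when mixed into a signalling-proficient population. sporefit
analyses the standard competition design for this system: a focal (usually
mutant) strain is mixed 1:99 into a partner strain, the mix is starved,
the surviving spores are harvested, and viable spores are counted by
dilution plating on selective (antibiotic) and nonselective agar.

Two log-ratio statistics summarise each mixture. With *sporulation
efficiency* defined as the fraction of a strain's inoculated cells
recovered as spores, the **one-way mixing effect** of partner *j* on
strain *i* is

$$C_i(j) = \log_{10}
  \frac{\text{efficiency of } i \text{ in mixture}}
       {\text{efficiency of } i \text{ in pure culture}},$$

and the **relative fitness in mixture** is

$$W_{ij} = \log_{10}
  \frac{\text{efficiency of } i \text{ in the mix}}
       {\text{efficiency of } j \text{ in the same mix}}.$$

$C_i(j) > 0$ means strain *i* derives an absolute-fitness benefit from
mixing (*social exploitation*); $W_{ij} > 0$ means the minority strain
outperforms its partner within the mix. *Cheating* is the conjunction of an
intrinsic cooperation defect and a significant $W_{ij} > 0$ against a
cooperator; a facultative exploiter (no intrinsic defect) is excluded by
definition, however well it competes.

The base of the logarithm is a configuration knob (`log_base`, default 10)
and is recorded in every output; efficiencies in this system span five or
more orders of magnitude, so decimal logs keep the numbers readable.

## From colony counts to spore populations

Each harvested sample is resuspended (default 1000 µl) and plated over a
dilution series. Plate $k$, receiving `plated_volume` µl of a $10^{-d_k}$
dilution, examines a known fraction
$f_k = (\text{plated volume}_k / \text{resuspension volume})\,10^{-d_k}$
of the sample. Under the Poisson plating model, colony counts are
$c_k \sim \text{Poisson}(N f_k)$ with $N$ the total viable spores, and the
maximum-likelihood estimate pooled over all countable plates is

$$\hat N = \frac{\sum_k c_k}{\sum_k f_k}.$$

This uses every countable plate rather than picking one dilution, is
unbiased under the model (verified by simulation in the test suite), and
collapses to the familiar `count / fraction` formula when a single plate is
countable. Plates with more than `count_ceiling` colonies (default 400)
are excluded from both sums: crowded plates cannot be counted reliably.
If every plate is above the ceiling the sample is an error, not an
estimate. A total examined fraction $\ge 1$ is tolerated with a warning.

Mixtures are resolved by subtraction: selective plates count the marked
minority, nonselective plates the whole population, and the majority is
`total - minority`. Counting noise can make that difference negative; the
majority estimate is then clamped to 0, flagged censored, and logged.
Clamping (rather than erroring) keeps downstream log-ratios defined after
imputation while leaving a full audit trail in the run log.

### Detection limit and censoring

A sample with zero colonies on every usable plate is *censored*: the strain
may have produced up to just under the detection limit (10 spores in this
design) without being seen. Censored estimates are imputed with the maximum
number of spores that would have gone undetected — `detection_limit - 1`
(9 spores) under the default `dl_minus_one` policy, since spore counts are
integers. An alternative `dl` policy imputes the limit itself; the two
differ by under 5% on the log scale and the choice is recorded on every
estimate. Imputation guarantees the positivity that the log-ratio
statistics require and is deliberately *anti-conservative for the censored
strain*: a censored minority gets the largest efficiency consistent with
seeing nothing, so negative fitness effects of antagonistic partners are
understated, never overstated.

### Efficiency denominators in mixtures

The efficiency denominator for a strain in a mixture is its own share of
the inoculum: `initial_cells_total * initial_fraction` for the minority and
the complement for the majority (defaults 2.5e8 cells total, fraction
0.01). This is the only convention under which monoculture and mixture
efficiencies are directly comparable, and $W_{ij}$ is invariant to any
common rescaling of the two denominators (a property the test suite checks
numerically), so the choice cannot tilt relative-fitness conclusions.

### Replicate pairing for C

$C_i(j)$ compares a mixture replicate with the strain's pure-culture
efficiency. When a monoculture with the same `replicate_id` exists it is
used directly; otherwise the geometric mean of that strain's monoculture
replicates stands in (the analysis lives on the log scale, so the geometric
mean is the natural centre). An explicit pairing column overrides nothing
more than which monoculture is matched.

## The testing battery

All tests are implemented in the package and cross-checked in the test
suite against independent references (`p.adjust`, `binom.test`, `t.test`,
`TukeyHSD`, `multcomp`, and brute-force Monte Carlo oracles):

* **One-sample and Welch t tests** with `two_sided` / `greater` / `less`
  alternatives. Zero-variance samples are an error at the statistics layer;
  the classification layer interprets a sample constant at the null value
  as "no evidence" (t = 0, p = 1) and a sample constant elsewhere as
  indeterminate — the situation that arises when both numerator and
  denominator of a ratio are censored and imputed at the same constant.
* **Holm step-down adjustment** for the declared families of t tests
  (e.g. all two-sided $W$ tests of a panel). Families are explicit in the
  configuration; tests are never silently pooled.
* **Exact binomial sign test**, used for ordering claims such as "the
  defector's mean fitness was lower against eight of nine derived
  cooperators than against their ancestor": the one-tailed tail probability
  of $k$ of $n$ under $p = 1/2$. The two-sided rule doubles the smaller
  tail and caps at 1; no continuity corrections anywhere.
* **Dunnett many-to-one comparisons** of each partner against a designated
  control, using pooled-variance t statistics. Family-wise p-values come
  from the joint null of the maximum (absolute) statistic over the
  correlated t variates; the correlation has the one-factor form
  $\rho_{ij} = \lambda_i \lambda_j$, $\lambda_i = \sqrt{n_i/(n_i+n_0)}$,
  which the implementation exploits to sample the multivariate t by seeded
  Monte Carlo (default `1e5` draws). Monte Carlo was chosen over
  deterministic quadrature because it is simple, seedable, and directly
  verifiable against a parametric-bootstrap oracle; with `1e5` draws the
  standard error of an adjusted p is below 0.002. Adjusted p-values are
  clamped to be no smaller than the raw p so the adjustment can never
  appear anti-conservative through simulation noise. Two-sided by default.
* **Tukey HSD** over all pairs via the studentized-range statistic
  (Tukey–Kramer under imbalance) with p-values from the studentized range
  distribution (`ptukey`). At $k = 2$ this reduces analytically to the
  pooled two-sample t ($q = \sqrt{2}\,|t|$), which the acceptance tests
  verify to $10^{-6}$; at $k = 3$ it is checked against a Monte Carlo
  max-range null.

## Phenotype classification

Classification turns test results into the field's vocabulary, with a
significance level `alpha` (default 0.05) applied to family-adjusted
p-values whenever the underlying test belongs to a declared family, raw
p-values otherwise:

* **Defector**: monoculture sporulation significantly below the reference
  cooperator's (one-sided test of the paired log ratio, Welch fallback for
  unequal replicate counts). The reference is the strain's recorded
  genetic background when the dataset provides one, else its mixture
  partner. A significance gate rather than an effect-size threshold is
  used: no accepted numeric cut-off exists for "how defective is a
  defector", while the gate reproduces the usual reading of such panels.
* **Cheater**: defector *and* significant $W_{ij} > 0$ against that
  partner.
* **Social exploitation**: significant $C_i(j) > 0$, irrespective of $W$.
  A defector that exploits is *complemented* by its partner; it is noted
  as *fully complemented* when its mixture efficiency is statistically
  indistinguishable from the partner's monoculture efficiency (two-sided
  Welch test not significant at `alpha`) — the phrase has no formal
  definition in common use, so indistinguishability from the wild-type
  level is adopted here.
* **Ranges**: the *cheating range* of a defector is the set of tested
  partners on which it cheats; the *defection-phenotype range* of a
  mutation is the set of tested genetic backgrounds in which it creates a
  defector. Indeterminate calls stay in the tested set but never enter a
  range, and lowering `alpha` can only shrink a range.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be exercised,
with known ground truth, without any external data. It emulates the
statistical structure of the assay:

* true per-strain log10 monoculture efficiencies (several orders of
  magnitude apart across a panel);
* pairwise interactions as additive log10 shifts on a strain's efficiency
  in a given mix — antagonism negative, complementation positive. This is
  the simplest structure that reproduces the three regimes seen in such
  panels: cheating, complementation without cheating, and elimination of
  the minority;
* log-normal replicate noise (`replicate_noise_sd`, default 0.3 log10 —
  a realistic figure for between-replicate scatter in developmental
  assays, adjustable when calibrating against real data);
* binomial inoculum composition at the 1:99 mixing fraction;
* Poisson colony counts over the dilution series (default exponents 2–7,
  100 µl plated of a 1000 µl resuspension), with `exact_counts = TRUE`
  available to bypass all counting noise for closed-form checks.

Each sample draws from its own RNG sub-stream derived from the config seed
and a stable hash of the sample id, so enlarging a panel never perturbs
existing samples, and identical seed + config gives byte-identical output
within this package (equality across implementations is not promised).

What the generator does *not* emulate: growth or death during the 72 h
starvation (efficiencies are drawn directly), mechanism of antagonism
(toxins vs signalling), frequency dependence beyond the single configured
ratio, and spatial structure. Passing tests therefore demonstrate that the
estimators and calls recover the truth of *this* generative model, not
that the model captures every property of real plate data.

Presets encode four canonical scenarios: `cheater_vs_parent` (a defector
with a 3-log10 monoculture deficit, complemented by and outcompeting its
parent, true $W = +0.8$, 8 replicates as is typical for the focal
parent-mix comparison), `natural_isolate_panel` (the same defector against
23 diverged cooperators whose antagonism shifts it −6 log10, below the
detection limit), `evolved_clone_panel` (nine closely related derived
cooperators; true $W$ below the parental value for eight of nine, with two
clones outcompeting the defector at $W = -0.7$ and $-2.1$), and
`csgA_background_panel` (one signalling-gene disruption across five
backgrounds: no defect in one, complete sporulation loss in another,
intermediate deficits elsewhere, each mutant fully complemented by its own
parent). Where a scenario parameter is not dictated by the design being
emulated, a single realistic value was fixed in advance: cooperator
monoculture efficiency $10^{-1.5}$, defector deficit 3 log10,
complementation shift +3.8.

## Numerical choices and degenerate inputs

* Student-t confidence intervals (default 95%) for replicate aggregates;
  with 3–8 replicates a bootstrap would be unstable, and the t interval is
  exact under the log-normal replicate model. A single replicate has no
  interval.
* Holm adjustment ignores `NA` members (they stay `NA` and do not count
  towards the family size m).
* Ties in Holm are handled by the cumulative-maximum step; a family of m
  identical p-values reduces to the Bonferroni product.
* The countability ceiling, detection limit, imputation policy, log base,
  alpha, Dunnett draw count and seed are all plumbed through the run
  configuration and recorded in outputs.
* Problem sizes in the default test and acceptance runs were chosen to
  give tight Monte Carlo error at desk scale: 1e4 simulated samples for
  estimator unbiasedness and type-I calibration, 1000 simulated panels for
  CI coverage (binomial SE ≈ 0.7 points at 95%), 1e5 Dunnett draws
  (SE < 0.002), 4e4 bootstrap draws for the Dunnett oracle.

## Known limitations

* The subtraction step assumes the selective marker fully suppresses the
  unmarked strain and costs the marked strain nothing on plates.
* The defector gate is purely statistical; with very few replicates a
  biologically large deficit can fail the gate and be called non-defector.
* Only the one-way fixed-effects layout behind Tukey/Dunnett is
  implemented; no general linear or mixed models.
* Heat-kill viability corrections are not applied; counts are taken as
  viable spores.
* Classification at mixing ratios other than the configured one is out of
  scope, as is inferring the mechanism of antagonism.
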
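---
title: "Methods: exposure-led non-animal DART assessment with dartnam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure-led non-animal DART assessment with dartnam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartnam)
```

# Overview

`dartnam` implements an exposure-led, hypothesis-driven ("protect, not
predict") risk-assessment pipeline for developmental and reproductive
toxicity (DART) built entirely on new approach methodologies (NAMs). The
pipeline has five stages, each usable on its own:

1. **Literature mining** — dictionary-based named-entity hit counting over
   stage-labelled abstract corpora, class-specific thresholds, and pooling
   into a ranked marker list.
2. **Biological coverage** — expressed-gene baselines per in vitro cell
   system, pooled into a gene universe and intersected with the mined
   markers; gaps classified by protein class and checked against assay
   panels.
3. **Exposure** — a reduced maternal-foetal physiologically based kinetic
   (PBK) model predicting plasma Cmax under oral and dermal scenarios.
4. **Bioactivity** — Bayesian concentration-response inference of points of
   departure (PoD) from transcriptomic counts, continuous stress
   biomarkers and percent-inhibition binding curves.
5. **Decision** — bioactivity-exposure ratios (BER = PoD / Cmax) and a
   coverage-gated decision rule.

A synthetic-data module generates every input with known ground truth, so
the full pipeline is testable offline.

# Literature mining

## Matching semantics

Hit counting aligns each record's title and abstract against a controlled
vocabulary of genes, processes and miRNAs with synonyms. The matcher is
deliberately simple so that an independent brute-force scanner can verify
it exactly:

* whole-word matches on ASCII word boundaries; hyphen and slash are
  boundaries ("Wnt-1" matches "Wnt-1"; "Wnt1" must be listed as a synonym,
  there is no fuzzy matching);
* case-insensitive, except patterns of three characters or fewer, which
  match case-sensitively — short gene symbols (e.g. "SHH") collide with
  ordinary words otherwise;
* longest-match-first, non-overlapping: every matched character span is
  attributed to exactly one term, so a mention of "fetal development"
  cannot additionally count as "development".

Hits are counted as *occurrences*, not documents, by default. The
occurrence scale is the one on which the top literature terms accumulate
thousands of hits; a `mode = "document"` flag provides the alternative
reading.

## Thresholds and pooling

Within each developmental stage, a gene term is retained at >= 10 hits, a
process term at >= 5, and a miRNA term at >= 2 (defaults of
`dars_thresholds()`). Thresholds are applied per stage *before* pooling;
pooling unions the stage sets, sums the per-stage counts, records
provenance, and ranks by total count with lexicographic tie-breaks so the
ranking is reproducible. Marker sets are validated by hypergeometric
overrepresentation (upper-tail p, Benjamini-Hochberg adjusted) against any
term-to-category annotation.

# Biological coverage

Sequencing baselines are filtered with the mean-or-median rule: a probe is
discarded when its mean *or* median count across samples is below 5. We
read the rule as OR-discard (the literal reading); an AND-discard mode is
exposed via `rule = "and"` since the originating pipeline is not
reproduced here. Microarray baselines retain a gene detected at or above a
noise cut-off of 7.5 log2 units in at least one sample; the comparison is
inclusive, as "cut-off" conventionally is, with a flag to change it. Gene
symbols are harmonized by uppercasing only — aliases resolve through the
vocabulary synonym table, never fuzzily.

`pool_universe()` computes the union, the gene-by-line membership matrix,
the full intersection and per-line unique genes; `compute_coverage()`
intersects a marker list with the union and always satisfies
`covered + missing = markers`.

The synthetic generator `gen_membership_structure()` builds four cell-line
sets with exact Venn-cell cardinalities. Its defaults emulate a
four-cell-line baseline-expression study at realistic scale (per-line
totals 8,931/9,261/10,819/11,483; union 14,225; four-way intersection
6,564; 3,551 markers of which 2,730 covered; 41 GPCR-annotated gaps, 6 of
them on a synthetic pharmacology panel). All identifiers are synthetic;
the structure exercises the exact set arithmetic at the scale of a real
study without shipping any third-party gene list.

# The reduced maternal-foetal PBK model

The model is a perfusion-limited, well-stirred compartmental system
(plasma, gut, liver, kidney, skin, adipose, rest-of-body, uterus) with
units amounts µmol, volumes L, flows L/h, time h, concentrations µM.
Elimination is hepatic Michaelis-Menten metabolism (CYP1A2) on unbound
liver concentration, scaled by a trimester activity multiplier, plus
linear renal clearance on unbound plasma.

Gestational age (GA) 0 is the non-pregnant base. Before week 6 only
maternal quantities change (plasma volume, uterus); from week 6, when the
foetal circulation is established, the placenta, amniotic fluid and a
lumped foetal circulation (foetal plasma + foetal tissue) are added. The
placenta is the one permeability-limited tissue: transfer is passive
diffusion, `PStc * (Cm_unbound - Cf_unbound)` with `PStc = Pe * SA(GA)`,
the permeability-surface-area product. The exchange surface area grows
with GA and is interpolated from a config table. The foetus has no
elimination and the amniotic compartment is inert by default (an optional
first-order exchange parameter exists); under these assumptions the
foetal Cmax can never exceed the maternal Cmax, and the foetal-to-maternal
(F/M) Cmax ratio is monotone in Pe — both are tested properties.

Key numerical choices: stiff-capable `lsoda` integration (absolute
tolerance 1e-9 µM, relative 1e-6), output grid 0.05 h, repeated daily
dosing with steady state declared when successive-day maternal Cmax
changes by less than 1%. Mass balance (compartments + eliminated +
unabsorbed vs dosed) is tracked at every output time and closes to better
than 1e-6 relative in the tests.

Default parameters are caffeine-like and labelled non-authoritative:
MW 194.19, fu 0.65, Km 250 µM with Vmax giving a plasma half-life of
roughly five hours in the non-pregnant base, small renal clearance,
first-order oral absorption (ka 3/h), and a two-parameter dermal depot
(release rate 0.05/h, absorbable fraction 0.5) with product-use amounts as
config inputs. Partition coefficients are config inputs; no in-silico
partitioning method is implemented. Trimester CYP1A2 multipliers default
to (1.0, 0.7, 0.5, 0.35) for (non-pregnant, T1, T2, T3): the activity
decrease in pregnancy is well established but the magnitudes here are
config-driven defaults. The default placental permeability (Pe
0.005 cm/h) was calibrated once so that the reduced model's F/M Cmax
damping falls in the 0.5–0.7 band reported for caffeine-like passive
transfer; with the lumped single-pool foetus, Pe plays the role of an
effective transfer conductance rather than a directly measured membrane
permeability, which is why the in vitro cell-layer value is not used
directly. Absolute Cmax predictions from full proprietary pregnancy
physiologies are *not* reproduced by this reduced model; the shipped
exposure table (`caffeine_cmax_table()`) carries the published case-study
values used by the worked examples.

# Bayesian PoD inference

## Hinge model

Concentration response is modelled as a hinge in log10 concentration: no
effect below the PoD, a log-linear effect of slope beta above it. For
transcriptomic counts the sampling distribution is Poisson with the
log-rate perturbed by Student's-t noise, `count ~ Poisson(exp(mu +
size_factor + hinge + eps))`, `eps ~ t(nu, 0, sigma)` — heavier tails than
a negative binomial, which reduces sensitivity to outlying counts.
Replicate variance is not used directly as a PoD criterion; it enters only
through the likelihood. `nu` defaults to 5 (the t-family choice is
principled; the specific degrees of freedom are a config default). Size
factors are fixed offsets, the log of per-sample totals relative to their
geometric mean, not estimated jointly.

## Inference

The PoD posterior is computed on a dense grid (200 log-spaced points) from
one dilution step below the lowest tested concentration to 10x the
highest. At each grid point the nuisance parameters (baseline, log effect
magnitude, log noise scale) are integrated out by a Laplace approximation
around their conditional mode; the effect sign is marginalized over a
50/50 up/down mixture by default. Grid inference makes every fit
deterministic — identical inputs give bit-identical posteriors — which we
prefer to MCMC for testability.

The effect magnitude carries a log-normal prior with median 1 (counts
model, log-rate units per decade) or median equal to the observed response
range (biomarker model, SD 0.5 on the log scale). This prior is bounded
away from zero by construction: a flat dataset cannot be explained by a
within-range PoD with a vanishing effect, so the posterior for null data
concentrates above the top tested concentration. That construction is what
makes the concentration-dependency score (CDS) — the posterior CDF
evaluated at the top tested concentration — behave as a hit-call score: it
approaches 1 for saturating effects and stays typically well below 0.5
for null data. Because noise occasionally imitates a monotone trend, the
null behaviour is a distributional property (the tests assert the median
CDS over replicate null datasets); a strict KL identity between null
posterior and prior does not hold under an effect prior bounded away from
zero, and the tests check instead that the posterior's divergence from the
prior decreases monotonically as the planted effect shrinks.

The PoD prior upper bound of 10x the top tested concentration keeps the
CDS genuinely below 1 when evidence is weak; the lower bound one dilution
below the lowest concentration lets a response already present at the
lowest dose place the PoD below the tested range.

## Global PoD

Per-probe point estimates are aggregated into a minimum-effect
concentration by fitting a location-scale normal model in log10 space to
the *central* order statistics (percentile ranks 25–75) by least squares
against standard-normal quantiles, then reading the fitted distribution at
the 1st percentile. Using only the central quantiles makes the estimate
stable against extreme probes; the read-out percentile is a config knob.
Several concretizations of "fit the central quantiles" are defensible
(quantile regression, trimming, interpolated percentiles); the
least-squares order-statistic fit above is this package's choice and is
frozen by tests (degenerate inputs return the common value exactly;
log-normal inputs recover the analytic 1st percentile within 10% at
n = 1000).

## IC50 curves

Percent-inhibition screens are fitted with a 4PL with asymptotes fixed at
0% and 100%: `I(x) = 100 x^h / (IC50^h + x^h)` plus Gaussian noise. Priors
follow screening practice: log IC50 centred on the median tested dose with
SD one decade; log Hill slope centred on 0 with SD 0.3. The Gaussian noise
scale is marginalized in closed form under a Jeffreys prior, and the
posterior is evaluated on a dense (log IC50, log h) grid — again fully
deterministic. Recovery at zero noise is limited only by grid resolution
(< 2% at the default 481-point grid).

# BER and decision logic

`compute_ber()` is the plain quotient PoD / Cmax on nominal in vitro
concentration versus plasma Cmax — no in vitro distribution corrections.
`ber_table()` forms the Cartesian product of endpoints and exposure
estimates (maternal and foetal, all gestational ages, both routes — the
conservative reading that any predicted Cmax may drive the decision) with
per-route min/max summaries. `decide()` applies the flow: insufficient
biological coverage dominates everything; otherwise minimum BER >= 1 (the
default threshold; uncertainty factors are the assessor's responsibility)
is low-risk, below it potential-concern with the driver endpoint named.

The caffeine worked example (`run_caffeine_demo()`) combines the shipped
exposure table with the published bioactivity PoDs (adenosine 2A receptor
IC50 5.3 µM, the most sensitive endpoint; gamma-H2AX 304 µM; transcriptomic
global PoDs 11–96 µM across cell models): the oral 200 mg/day scenario
yields a minimum BER of about 0.13 (potential concern), the dermal 0.1%
body-lotion scenario a minimum of about 11.5 (low risk), and the printed
F/M Cmax ratios span 0.57–0.70.

# What the synthetic data do and do not show

The generators plant exactly recoverable ground truth: term occurrences
countable by exhaustive scan, expressed-gene sets recoverable by the
mean/median filter by construction, hinge responses with known PoD, 4PL
curves with known IC50, and PK observations with controlled log-normal
noise. Passing tests therefore demonstrate that the *algorithms* are
correct and calibrated under their own assumptions. They do not
demonstrate performance on real literature (no journal text statistics, no
ambiguous nomenclature beyond planted synonyms), real TempO-Seq data
(no probe-level artefacts, batch effects or complex mean-variance
structure), or real physiology (the PBK defaults are plausible, not
validated). Problem sizes in the tests — 50-probe recovery studies, 100
small corpora, study-scale set arithmetic at ~14k genes — were chosen as
the smallest sizes at which the statistical claims (90% recovery, 90% CI
coverage) are meaningful.

# Known limitations

* No metabolite kinetics, active placental transport, or population
  variability in the PBK model.
* No live literature querying or machine-learned NER; vocabularies are
  inputs.
* miRNA-target mapping is out of scope (reported unfruitful at the mining
  stage).
* The CDS threshold for calling a borderline hit is not fixed by the
  method; it is a reporting quantity.
* Genotoxicity-related processes are excluded from the coverage analysis
  scope.
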
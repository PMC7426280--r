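---
title: "Methods: diversity metrics for a paired-site arthropod inventory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity metrics for a paired-site arthropod inventory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gardendiv)
```

gardendiv compares two sampled communities — the motivating case is two
urban botanic gardens inventoried for arthropods with a mix of passive
traps and active searches — along three axes: how much diversity each site
holds (alpha), how complete each inventory is (richness estimation), and
how the two communities differ in composition and dominance (beta and a
randomization test). This vignette documents the models, their
assumptions, the tunable parameters, and the design choices that were
genuinely open.

## The data model

Everything operates on a `community_matrix`: long-format counts per
(species, sample, life stage) with per-species colonisation status
(endemic / native / introduced / undetermined), trophic role and
taxonomic order, and per-sample site labels. Two life-stage *views* exist
everywhere: `total` (adults + juveniles) and `adult`. A taxon with no
juveniles is simply a taxon whose juvenile counts are all zero — the
pipeline then reports it for adults only, rather than changing the schema.

Curation mirrors field practice: `apply_merge()` collapses morphologically
inseparable species into one canonical unit (counts are summed; a merge
across conflicting statuses requires an explicit canonical status), and
`filter_status()` removes species of undetermined colonisation status
before *any* metric is computed. Whether to drop undetermined species
before or after completeness estimation was an open choice; we drop them
first, so that every reported number — including estimated richness —
refers to the same curated community. A sensitivity run can retain them by
passing `drop_status = character(0)` to `run_config()`.

## Alpha diversity: the Hill series

For a pooled abundance vector with relative abundances $p_i = x_i/N$:

$$\exp H' = \exp\Big(-\sum_i p_i \ln p_i\Big), \qquad
  1/D = \Big(\sum_i p_i^2\Big)^{-1}, \qquad
  1/d = N / \max_i x_i,$$

the Hill numbers of order 1, 2 and $\infty$; observed richness $S$ is
order 0. They are ordered $S \ge \exp H' \ge 1/D \ge 1/d \ge 1$, which the
test suite asserts on $10^4$ random communities. Numerical choices:
Shannon entropy uses the natural logarithm (the exponential makes the base
immaterial), and Simpson is the plug-in concentration $\sum p_i^2$ rather
than the unbiased small-sample form — at the inventory sizes this package
targets (thousands of individuals) the difference is far below reporting
precision, and the plug-in form matches the magnitude of published
Hill-series tables given their printed $N$. Singletons and doubletons are
counted on integer abundances; metrics are computed at full precision and
rounded (2 decimals, integer percentages) only at report time.

`dominance()` ranks species by abundance (ties broken lexicographically by
species id, so results are deterministic) and returns the shortest prefix
whose cumulative share reaches the threshold, 0.5 by default; a prefix
hitting exactly 50% qualifies. Shares are reported both exact and as
rounded integer percentages.

## Richness estimation and completeness

`accumulate()` re-implements randomized sample-order accumulation: for
each of `R` random permutations of a site's samples it tracks, at every
accumulation level, observed richness `S`, abundance-based singletons and
doubletons `F1`/`F2`, and incidence-based uniques `Q1`; means over orders
are returned. `R = 100` by default — the convention of the classic
estimation software this reproduces — and a seed makes curves
reproducible. Because every ordering ends at the full pool, the level-$m$
means equal the pooled-community values exactly; at intermediate levels
the averaged `F1`/`F2`/`Q1` are generally fractional, and they feed the
estimators **unrounded**. (This is why published rarity tables can print
fractional singleton counts for the site whose curve was averaged.)

Estimators:

* Chao1, classic form $S + F_1^2/(2F_2)$, with the $S + F_1(F_1-1)/2$
  fallback when $F_2 = 0$. The bias-corrected variant
  $S + F_1(F_1-1)/(2(F_2+1))$ is available (`corrected = TRUE`) but the
  classic form is the default: it is what reproduces published
  completeness ratios computed from printed $S$, $F_1$, $F_2$.
* First-order jackknife, $S + Q_1 (m-1)/m$.

`richness_estimate()` builds the estimator value at every accumulation
level, and reports: the estimate at full accumulation, sampling
completeness = observed $S$ / estimated $S$, and the **final slope** — the
last first-difference of the *estimator* curve (not the observed-S curve),
since it is the estimated accumulation curve whose stabilisation the slope
diagnoses. Near-zero slopes indicate a near-complete inventory. Note the
estimator curve need not be monotone, so slopes can be negative; the value
is reported signed.

`rarefy_individuals()` is the hypergeometric closed form
$E[S(n)] = \sum_s [1 - \binom{N-x_s}{n}/\binom{N}{n}]$, evaluated with
log-binomials so large $N$ cannot overflow. It is how the richer site is
compared to the poorer one at equal numbers of individuals. Tests verify
it against an independent library implementation and against Monte-Carlo
subsampling ($10^5$ draws, agreement within 3 standard errors), and verify
`accumulate()` against exhaustive enumeration of all sample orders on
small fixtures (4! in the unit test, 6! in the acceptance suite).

## Beta diversity partition

For a site pair, with `a` the shared component, `b` and `c` the exclusive
components:

$$\beta_{Tot} = \frac{b+c}{a+b+c} \;=\;
  \underbrace{\frac{2\min(b,c)}{a+b+c}}_{\beta_{Repl}} +
  \underbrace{\frac{|b-c|}{a+b+c}}_{\beta_{Rich}}$$

Jaccard denominators throughout; the replacement term counts each
substitution twice because a substitution involves one species from each
site. In incidence mode `a`, `b`, `c` count species; in abundance mode
they count individuals: $a = \sum_s \min(x_{1s}, x_{2s})$ and `b`, `c`
are the one-sided surpluses — the standard abundance generalisation, and
the one consistent with the incidence definitions (a single shared species
with abundances 32 and 4 gives $a=4$, $b=28$, $c=0$: all dissimilarity is
richness difference, none is replacement). The partition is additive by
construction; tests assert additivity and the Jaccard identity on $10^5$
random triples, plus symmetry, scale invariance of incidence mode, and the
nestedness limit ($\beta_{Repl}=0$ for a strict subset).

`grouped_beta()` runs the decomposition per taxonomic order and status
class; a group with no species at either site is reported as a flagged
undefined row rather than dropped, so report tables keep a fixed shape.
Component shares are percentages of $\beta_{Tot}$ (both zero when
$\beta_{Tot}=0$). Whether juveniles belong in the garden-level comparison
was left open by the motivating study; both stage views are exposed and
the pipeline reports both.

## The dominance randomization test

The test statistic is the absolute difference in inverse Berger-Parker
index between the two communities. The cited randomization framework
leaves the statistic's direction open; the absolute difference gives the
two-sided test matching a "do the communities differ" question. Under the
null, the pooled $N_1+N_2$ individuals are reallocated without replacement
into communities of sizes $N_1$ and $N_2$ — individual-level reallocation,
because the index is defined on pooled individuals, not on samples. Each
species' null count is then multivariate hypergeometric, which is drawn by
the sequential conditional method (one vectorised hypergeometric draw per
species across all partitions). The p-value uses the add-one convention
$p = (k+1)/(R+1)$, guaranteeing validity at finite $R$; with the default
$R = 10{,}000$ partitions the smallest attainable p is $\approx 10^{-4}$.
The acceptance suite measures the realised type-I error at
$\alpha = 0.05$ over 1000 true-null replicates (199 partitions each, a
size chosen to keep the simulation inside a test-suite run) and requires
$0.05 \pm 0.02$; ties in the discrete statistic can only make the test
conservative.

## What the synthetic generator emulates — and what it does not

`generate_community()` draws a two-site survey with the structure the
analysis assumes: fixed shared and exclusive species pools (presence is
guaranteed by at least one individual, so incidence structure is exact,
not sampled away), per-species site abundances from a log-series — the
standard heavy-tailed abundance model for arthropod assemblages —
multinomial scatter of individuals across the site's samples, and
independent Bernoulli juvenile status per individual. One integer seed
governs everything; per-site sub-seeds are derived from it so the two
sites have independent reproducible streams.

Defaults are fixed at the paired-garden design the package was built
around, and were chosen once, from the study's printed summaries:

* 2 sites × 10 samples;
* 46 shared / 42 + 145 exclusive species — the shared count implied by the
  two sites' observed richnesses (88 and 191) and an incidence
  $\beta_{Tot}$ of 0.8;
* log-series parameter $\theta = 0.995$, putting mean abundance near the
  observed ~43 individuals per species;
* juvenile fraction 0.37, the overall juvenile share of the inventory;
* a status mix in which introduced species dominate the species list, most
  strongly among the species-rich site's exclusives.

The generator deliberately omits features of real surveys: no
method-specific detection probabilities (trap type is a label), no
temporal autocorrelation between monthly samples, no spatial structure,
and species abundances independent across species and sites. Passing
tests on synthetic data therefore demonstrate the *metric machinery* —
not that real gardens satisfy these independence assumptions.
`generate_null_pair()` provides the complementary null generator: a random
split of a pooled community, the exact null of the dominance test
(hypergeometric per species, verified in tests against the closed form).

## Degenerate inputs and numerical conventions

Empty or all-zero communities are errors everywhere (there is no sensible
diversity of nothing); a single-sample site yields a length-1 accumulation
curve and no slope (`NA`); `chao1` accepts $F_2=0$ via the fallback;
`beta_decompose` rejects $a+b+c=0$; `dominance` requires a threshold in
$(0,1]$. Equality comparisons against thresholds use a $10^{-12}$
tolerance so cumulative shares reaching exactly 50% (or null statistics
tied with the observed one) are counted inclusively. Reported tables round
to 2 decimals and integer percentages; nothing upstream of a report is
rounded.

## Problem sizes used by the tests and drivers

The unit suite runs on small fixtures (4-sample sites, ~20 species); the
acceptance checks use $10^5$ beta triples, $10^4$ Hill communities,
$10^5$ rarefaction draws, full 6!-order enumeration, and 1000 null
replicates of the randomization test — sizes picked so the whole suite
completes in about a minute while keeping Monte-Carlo error well inside
the asserted tolerances. The analysis drivers under `analysis/` run the
full design (10 samples per site, $R = 100$ orders, $10^4$ partitions).

## Known limitations

* Two sites only: no multi-site beta matrices or ordination exports.
* No coverage-based standardisation of Hill numbers and no q-profile
  between orders 2 and $\infty$; no extrapolation beyond the observed
  sample size, and no confidence intervals on richness estimators.
* Completeness ratios computed from *rarefied* (rather than pooled)
  richness of a reference site are intentionally not produced; published
  tables built that way for a second site are not reproducible from
  pooled-community quantities, and the package reports only quantities it
  defines precisely.
* The occurrence reader expects the package's long CSV/TSV format;
  spreadsheet sources must be exported to it first.
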
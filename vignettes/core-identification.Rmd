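---
title: "Identifying core host-associated ASVs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying core host-associated ASVs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicore)
```

## The problem

Epiphytic bacterial communities on macroalgae (and on host surfaces
generally) are diverse and strongly structured by site and season, which
makes it hard to say which taxa are genuinely *associated with the host*
rather than transiently settled from the surrounding water and substrate.
The usual way forward is to nominate a **core microbiome** — the set of
amplicon sequence variants (ASVs) consistently found on the host — and
treat it as a hypothesis-generating shortlist for functional work. But
"consistently found" has many operationalisations, and they do not select
the same taxa.

`epicore` implements three complementary core definitions on a
sample-by-ASV count table with host, rock and seawater samples collected
over multiple *sampling events* (site-by-time units):

1. **Frequency (occupancy) core.** An ASV is core when it occurs in at
   least a fraction `freq_threshold` (default 0.5, inclusive) of all host
   samples. Host samples alone are used; no environmental contrast.
2. **Whole-dataset IndVal core.** The indicator value of the host group,
   computed over all samples, combines *specificity*
   $A = \bar{x}_{host} / \sum_g \bar{x}_g$ (within-group means, so unequal
   group sizes do not bias it) and *fidelity* $B$, the fraction of host
   samples where the ASV occurs, into $\mathrm{IndVal} = \sqrt{AB}$. An
   ASV is core when $\mathrm{IndVal} \ge 0.7$ and a one-sided permutation
   test gives $p \le \alpha$ (default 0.05).
3. **Two-step IndVal core.** Step 1 repeats the IndVal analysis *within
   each sampling event separately*, using only that event's host and
   environmental samples; step 2 tallies the events in which an ASV was a
   significant indicator and declares it core when the tally reaches
   `min_events` (default 7, i.e. an indicator in more than 6 of 11
   events). This rewards consistency across space and time and partially
   corrects for unequal sample sizes across events.

The three definitions are nested in spirit but not in mechanics; the
package reports a per-ASV ledger of which definitions each ASV met, plus
each ASV's overall host specificity (host reads over host-plus-environment
reads).

## Why the square-root variant

With the group-equalized $\sqrt{AB}$ statistic, a threshold of 0.7 forces
$AB \ge 0.49$, and since $A \le 1$ it forces $B \ge 0.49$: every IndVal
core ASV is automatically at (essentially) 50% or greater host frequency,
which makes the IndVal core a subset of the frequency core at matched
thresholds. That algebraic consequence is the design rationale for the
default `variant = "sqrt"`; the plain product $AB$ (which would force
$B \ge 0.7$ instead) is available via `variant = "product"`. The subset
relation is enforced as a property test on random tables.

## Permutation tests

Significance is assessed one-sidedly (enrichment in the target group) by
permuting sample group labels. Monte-Carlo p-values use the add-one
convention $p = (b+1)/(n_{perm}+1)$ with ties counted toward $b$
(conservative). For small designs an exhaustive mode enumerates every
distinct arrangement of the label multiset, identity included, and reports
the exact attainment fraction; Monte-Carlo p-values converge to these as
$n_{perm}$ grows, which the test suite checks against independent
enumeration oracles. Per-event seeds in the two-step analysis are derived
deterministically from the master seed and the event's rank among the
sorted event labels, so whole-pipeline runs are reproducible and invariant
to event ordering.

The analogous logic applies to the one-factor PERMANOVA: with
$SS_{total} = \tfrac{1}{N}\sum_{i<j} d_{ij}^2$ and the within-group
analogue per group, pseudo-$F = (SS_B/df_B)/(SS_W/df_W)$ and
$R^2 = SS_B/SS_{total}$. On 1-D Euclidean data this reduces exactly to the
classical one-way ANOVA $F$, which the tests exploit as an oracle. Note
that for two equal-size groups the $F$ statistic is invariant to swapping
the group labels, so the smallest attainable exhaustive p on a 2+2 design
is $2/6$, not $1/6$ — unlike IndVal, whose statistic is tied to a specific
target group.

## Filtering and rarefaction

The preprocessing chain is fixed as: (1) `zero_low_cells()` sets cells
with fewer than 5 reads to zero (strictly-below semantics; a guard against
index switching); (2) `filter_asvs()` discards ASVs below 0.1% of the
grand total *or* present in fewer than 5 samples. The OR combination
(`combine = "any"`) is the literal reading of that rule; because it is
aggressive and some datasets may intend the conjunction, `combine = "all"`
is exposed. Prevalence is counted after cell-zeroing, so occupancy
inherits the barcode-switching guard.

Core identification runs on the **unrarefied** filtered counts (IndVal on
per-sample relative abundances by default; raw counts behind a flag — the
statistic is per-taxon scale-invariant, so this mostly affects fidelity
through which cells are non-zero after filtering). Rarefaction
(`rarefy()`, default depth 1500, a single draw without replacement per
sample, shallow samples dropped) feeds only the beta-diversity branch:
Bray-Curtis dissimilarities and PERMANOVA.

## What the generator emulates — and what it does not

`simulate_survey()` provides a fully specified stand-in for a real
multi-site, multi-year intertidal survey, so every stage of the pipeline
can be tested end to end without downloads. Its defaults are fixed as the
study conditions:

* 11 sampling events, each with 5 host, 3 rock, and 2 seawater samples
  (110 samples), one event per month starting mid-March;
* 300 ASVs: 15 planted host cores, 60 environmental taxa, the rest
  transient;
* log-normal baseline intensities (meanlog 0, sdlog 1.2 — moderate
  abundance heterogeneity);
* planted cores multiplied by an enrichment factor of 50 on host samples,
  with per-sample Bernoulli dropout giving occupancy 0.95;
* environmental taxa multiplied by 20 on rock and seawater samples,
  symmetrically;
* transient taxa get event-specific log-normal multipliers (sdlog 1.5)
  shared by all samples in the event, mimicking the large pool of
  event-variable indicator taxa seen in real surveys;
* per-sample depths drawn negative-binomially (mean 5000, size 10, the
  10^3–10^4 range), counts multinomial at that depth, so row sums equal
  the drawn depths exactly.

Log-normal-plus-multinomial was chosen over a Dirichlet-multinomial for
transparency: the intensity variance is the single overdispersion knob,
and the planted effects act multiplicatively on intensities, so expected
relative-abundance ratios are interpretable. Two caveats matter when
reading recovery numbers. First, the data are compositional: enriching
environmental taxa on rock/seawater *depletes everything else* there in
relative terms, so in a community with environmental structure but no
host-enriched taxa, ordinary taxa can look host-"enriched". The null
configuration is therefore *all* multipliers at 1 (a fully exchangeable
community), under which two-step recovery collapses to zero, as the
acceptance suite verifies. Second, the generator plants clean,
time-invariant effects; real surveys add taxonomic misassignment,
contamination, and temporal drift that no passing test here speaks to.

Recovery under the default (strong-signal) conditions — two-step
sensitivity and false-positive rate over 20 replicate seeds — is computed
by `recovery_report()` and checked in the acceptance suite at sensitivity
≥ 0.9 and FPR ≤ 0.02, with per-event permutation tests at `n_perm = 199`
(smallest attainable p 0.005, comfortably under α = 0.05) to keep a
20-replicate run in seconds.

## Numerical and design choices

* **Thresholds are inclusive** (`>=`) everywhere: frequency 0.5, IndVal
  0.7, host-range presence 0.001.
* **min_events** defaults to 7 ("more than 6 of 11"); surveys sometimes
  phrase the same rule as "at least 6", one argument away. Designs with
  fewer events must set it explicitly.
* **Absent taxa**: an ASV with zero reads in a design has
  $A = B = \mathrm{stat} = 0$ and p = 1. All-zero samples get all-zero
  relative-abundance rows (flagged), and a pair of all-zero samples gets
  Bray-Curtis 0 with a warning.
* **Ties** between permuted and observed statistics count as exceedances,
  with a 1e-12 float tolerance so relabelings that are exact
  rearrangements are not lost to summation order.
* **Specificity orientation**: the overall host-specificity is reported
  as host reads / (host + environment reads), the proportion plotted in
  core-microbiome figures; the equivalent inverted ratio (total over
  host) carries the same information.
* **Host range** uses the mean per-sample relative abundance within each
  host species (samples pooled per species) against the presence
  threshold; seasonal profiles report relative abundance only — with
  compositional data, a falling relative abundance need not mean a
  falling absolute abundance, and no absolute inference is attempted.
* **Events without an environmental comparison** are excluded from the
  two-step tally (and recorded in the fit), not silently scored as
  non-indicator events.

## Problem sizes

The bundled tests and the acceptance script run entirely on generated
data: 110-sample surveys with 300 ASVs for recovery (20 replicates),
≤10-sample designs for exhaustive enumeration, and 100 random 9–16 sample
tables for the subset property. These sizes give stable Monte-Carlo
comparisons in well under a minute each while exercising every code path;
scaling to the thousands of samples of a real survey is linear in samples
× ASVs × permutations.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_survey(sim_spec(seed = 1))
filt <- filter_asvs(zero_low_cells(sim$counts))
fit <- core_microbiome(filt$counts, sim$metadata,
                       min_events = 7, n_perm = 999, seed = 1)
summary(fit)
recovery_report(sim$truth, fit)
plot(fit) # ASVs x events indicator grid
```

## Known limitations

* Only single-target IndVal (the host group) is implemented; site
  combinations and correlation-based indices are out of scope.
* PERMANOVA is one-factor with free permutations (no strata); marginal
  multi-factor designs should go to `vegan::adonis2` directly.
* BIOM output is written in the JSON (1.0) flavour; both JSON and HDF5
  flavours are read.
* Rarefaction is a single draw per sample; repeated-draw averaging, and
  model-based alternatives to rarefaction generally, are deliberately not
  provided.
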
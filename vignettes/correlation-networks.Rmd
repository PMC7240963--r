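---
title: "Building significance-filtered trait correlation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building significance-filtered trait correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitnet)
library(dplyr)
```

## The analysis this package implements

Introgression-line (IL) panels — for example the tomato panel in which each
line carries one marker-defined chromosome segment from the wild relative
*Solanum pennellii* in an otherwise cultivated (M82) background — are a
classical resource for connecting metabolism to phenotype. Profiling such a
panel on several platforms (primary and secondary metabolites, lipophilic
compounds, volatiles, yield-related phenotypes, transcript abundances of
candidate pathways) yields a collection of replicate-level trait tables over
a common set of genotypes. Correlation network analysis asks a simple
question of these tables: which traits co-vary across the panel, with what
sign, and how does that co-variation organise by biochemical class?

traitnet implements that pipeline end to end:

1. **Aggregation** — replicate measurements are averaged per (line, trait);
   the replicate count per cell is kept as a support record.
2. **Standardization** — abundances are mapped to standard scores of their
   natural logarithm, so every trait enters the correlation stage on a
   comparable scale.
3. **Correlation with permutation testing** — every trait pair gets a
   Spearman rank correlation and a two-sided permutation p-value.
4. **Network assembly** — pairs passing a coefficient cut-off and a
   significance cut-off become signed edges; nodes carry a
   group/class/subclass annotation.
5. **Summaries and integration** — class-pair tables (counts and percent
   positive), whole-network statistics, metabolite–transcript bipartite
   networks with candidate-gene ranking, and genotype-group fold-change
   comparisons.

Because Spearman correlation is invariant to strictly monotone transforms,
steps 2 and 3 commute: the log and the z-score change no rank, so the
correlation structure is exactly that of the raw positive abundances. The
standardization matters for any downstream consumer of the matrix itself
(heatmaps, season merging), not for the coefficients.

## The statistical core

For a trait pair \((x, y)\) observed on the same lines, the coefficient is
the Pearson correlation of mid-ranks (average ranks for ties), computed on
pairwise-complete observations. Significance comes from a permutation test:
the pairing of `y` against `x` is destroyed by permuting one vector, which
is exact under the null of no association because the lines are
exchangeable. Two modes are provided:

* **Monte-Carlo** (default, `B = 20000` draws): the add-one estimator
  \(p = (1 + \#\{|\rho_b| \ge |\rho_{obs}|\})/(B+1)\). It can never return
  zero, is slightly conservative, and treats the observed pairing as one
  draw from the null — the standard convention for sampled permutation
  tests.
* **Exhaustive** (all \(n!\) permutations, refused above \(8! = 40320\)):
  the exact tail probability, used as the oracle that the Monte-Carlo mode
  is tested against.

The test is two-sided throughout, because networks of this kind report both
positive and negative edges, so the null has to be sign-agnostic.
Comparisons of permuted against observed \(|\rho|\) use an absolute guard
of \(10^{-12}\): rank correlations on \(n\) points form a finite grid, so
the guard absorbs floating-point noise without ever crossing between
genuinely different grid values.

Each pair's permutation stream is seeded deterministically from the master
seed and the pair's indices, so a correlation matrix is reproducible cell
by cell regardless of evaluation order.

### Multiple testing

Edges are filtered on raw permutation p-values at \(p < 0.05\) by default,
which matches the conventional critical value for this analysis type; a
Benjamini–Hochberg mode (`p_adjust = "BH"`) is available for users who
prefer FDR control across all pairs, but it is off by default and its use
is recorded in the result metadata.

## Cut-offs and filtering conventions

Two coefficient thresholds are built in as defaults, following the common
practice for these data:

* trait/trait networks: \(|r| > 0.3\) (strict inequality),
* trait/transcript networks: \(|r| \ge 0.40\) (inclusive).

The two conventions differ in the boundary because they are quoted
differently in practice ("higher than 0.3" versus "\(\ge 0.40\)");
`build_network()` exposes the rule (`r_rule = "greater"` / `"geq"`) so
either can be applied to either network type. Significance is always strict
(\(p < 0.05\)). Raising the coefficient cut-off or lowering the p cut-off
can only remove edges — this monotonicity is a tested invariant.

Pairs with fewer than `min_n = 10` complete shared observations are left
undefined rather than estimated: with heterogeneous replication and missing
cells, very small overlaps make both the coefficient and its permutation
null too unstable to report. `min_n` is configurable and recorded in the
result metadata.

## What the synthetic generator emulates — and what it does not

The generator (`synth_config()`, `generate_population()`,
`generate_expression()`) produces a panel with the shape of an IL study:

* **76 genotype lines** by default — a cultivated reference (`REF`,
  heavily replicated, 12 replicates, as reference cultivars typically are),
  74 ILs, and a wild-donor line (`PEN`);
* **five trait classes of ten traits each** (sugars, flavonoids, TAGs,
  phospholipids, yield phenotypes) with within-class Spearman correlation
  0.7 — strong positive intra-class blocks are the dominant feature of real
  metabolite networks;
* **1–12 replicates per line and platform**, drawn uniformly, emulating the
  replication heterogeneity of multi-platform studies (GC-MS, LC-MS,
  lipidomics, phenotyping);
* **5% of replicate records missing**, forcing pairwise-complete handling
  downstream;
* optional **signed inter-class blocks**, **planted transcript–trait
  links**, and **genotype-group fold changes**.

The construction is a Gaussian copula: line-level latent values are drawn
from a multivariate normal whose correlation blocks encode the planted
structure, then exponentiated to a positive abundance scale, with replicate
values log-normal around each line's latent mean. Because the exponential
map is monotone, the latent Pearson correlation \(\rho_P = 2\sin(\pi
\rho_S/6)\) yields the target Spearman \(\rho_S\) on the observed scale.
Replicate noise (log-scale standard deviation 0.25 by default, against a
line-to-line standard deviation of 1) attenuates the realised line-mean
correlations slightly — the default panel realises about 0.68 for a target
of 0.7 — which is the same attenuation a real study sees when averaging
noisy replicates.

Transcripts named in `group_fold_changes` are generated as *allele-driven*:
their only genetic signal is the group offset (the planted fold), plus
replicate noise. This emulates the cis-regulation scenario in which a
promoter variant, not background genetic variation, sets the expression
level — the situation in which a reported "20-fold higher in the wild
species" is meaningful. Transcripts with planted correlation links instead
track the latent line value of their target trait, and one transcript
cannot play both roles.

The generator does **not** emulate: QTL/linkage structure along
chromosomes (lines are exchangeable draws, not a genetic map),
platform-specific measurement artefacts (batch effects, detection limits,
peak-picking noise), compositional closure, or heavy-tailed biological
outliers. Passing the planted-recovery tests therefore demonstrates that
the pipeline's statistics behave correctly under a clean, known truth — it
does not certify performance against the artefacts of any particular real
platform.

## Preprocessing decisions

* **Sample standard deviation** (n − 1) for z-scores, matching the default
  of the statistics environments these analyses are usually run in. The
  three-point column \(\{e, e^2, e^3\}\) with `pseudo = 0` therefore
  standardizes to \(\{-1, 0, 1\}\).
* **Pseudo-count** `1e-9` before the log, relevant only if zeros occur;
  Spearman results are invariant to it for positive data (tested).
* **Annotation-driven transform**: abundance groups (primary, secondary,
  lipid, volatile, transcript) are log-transformed; phenotype traits
  (counts, lengths, ratios — where a log of zero is undefined and the scale
  is already interval-like) are z-scored without log. The split is
  overridable via `log_groups`.
* **Degenerate columns** (fewer than 3 values, zero variance) are dropped
  with a warning, not an error — one flat trait should not abort a
  50-trait run.
* **Season merging** averages *standardized* values per (line, trait)
  across the seasons in which the trait was measured, summing support
  counts. Averaging on the z-scale is the least-assumption rule when no
  cross-season calibration is available: it weights seasons equally
  regardless of instrument scale. Whether to correlate a merged matrix or
  per-season matrices (taking a union of edges afterwards) is genuinely
  open in studies of this kind; the package defaults to merging, and the
  per-season route is available by simply running the pipeline per season.
  Multi-season input is produced by running the generator once per season
  with different seeds.

## Problem sizes and numerical choices

The validation suite runs at the study scale it emulates: the
planted-recovery check uses the full default panel (76 lines, 50 traits,
1225 pairs, `B = 2000` permutations per pair), the type-I calibration uses
1000 null datasets of 20 lines, the Monte-Carlo/exhaustive agreement check
uses `B = 50000` against all 720 permutations of length-6 vectors, and the
fold-change calibration uses 1000 null replicate sets. `B = 2000` in the
simulation-heavy checks (rather than the 20000 default) keeps the smallest
attainable p at \(1/2001 \approx 5\times10^{-4}\), far below the 0.05
filter, so the edge decisions are unaffected while each full-matrix run
stays in the tens of seconds.

Ties in ranks are handled by mid-ranks everywhere, and a pair whose ranks
are constant (zero variance) is undefined rather than zero. Candidate
ordering breaks ties deterministically (links, then max \(|r|\), then id),
and the dominant class of a candidate resolves ties alphabetically, so
results are stable across runs and platforms.

## Known limitations

* Permutation p-values are computed per pair; the network filter at
  \(p < 0.05\) controls per-pair error, not family-wise or false-discovery
  rates (the BH option exists for the latter).
* `min_n = 10` is a pragmatic floor, not a power statement; pairs near the
  floor have wide sampling variability.
* The season-merging rule (mean of z-scores) discards season-specific
  variance differences; a trait measured in one season contributes with
  full weight.
* Blocked permutations (within season) are not implemented; the
  permutation null assumes exchangeability across all lines in the matrix
  being analysed.

## A compact worked example

```{r example, eval = FALSE}
library(traitnet)

cfg <- synth_config(seed = 1)          # 76 lines, 50 traits, 5 classes
pop <- generate_population(cfg)

z   <- log_standardize(aggregate_replicates(pop$data),
                       annotation = pop$annotation)
cr  <- correlate_all(z, B = 2000, seed = 2)
net <- build_network(cr, pop$annotation, r_cutoff = 0.3, p_cutoff = 0.05)

network_stats(net)
class_pair_matrix(class_pair_summary(net))
autoplot(net)
```
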
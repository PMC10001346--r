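---
title: "Designing mutation-hotspot sequencing panels with mutpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing mutation-hotspot sequencing panels with mutpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutpanel)
```

## The problem

Ultra-deep targeted sequencing of clinically normal tissue is how early
clonal mutations are measured, and its cost is dominated by the size of the
targeted region. Somatic point mutations are not uniformly distributed:
carcinogen-exposed tissues (the motivating case is sun-exposed epidermis and
cutaneous squamous cell carcinoma) accumulate mutations in narrow genomic
hotspots, a few base pairs to a few hundred base pairs wide, separated by
long sparsely mutated stretches. A panel that places its fixed-length
amplicons on those hotspots captures many times more mutations per base pair
sequenced than whole-gene panels or arbitrarily tiled designs. `mutpanel`
takes a table of previously observed mutation positions and designs such a
panel under an explicit base-pair budget.

## The model and the procedure

The design procedure is combinatorial, not statistical: it solves a maximum
coverage problem over candidate windows of fixed length $L$ (the assay's
amplicon length).

**Hotspot detection.** Distinct mutated sites on a chromosome are scanned in
genomic order. A site joins the current hotspot when its gap to the most
recently added site is strictly less than $L$; a gap of $L$ or more
terminates it. Hotspots are therefore maximal runs whose internal gaps are
all $< L$ — equivalent to single-linkage clustering of positions cut at
$L$ — and, because the threshold chains from the last added site, a hotspot
can grow far beyond one amplicon in span. The comparison is chained rather
than anchored at the seed site: only under chaining can the procedure
distinguish hotspots "within one amplicon" from larger ones, which is what
the downstream selectors rely on.

**Candidate amplicons.** A hotspot whose span fits in one amplicon is
covered by exactly one window: its center is the recurrence-weighted mean
position (rounded half toward the lower coordinate, a deterministic
convention), shifted minimally so the window contains the whole hotspot.
For larger hotspots, five windows are generated at each site $m$: directly
upstream `[m-L, m-1]`, directly downstream `[m+1, m+L]`, site at the right
edge `[m-L+1, m]`, site at the left edge `[m, m+L-1]`, and site centered
(offset $\lfloor (L-1)/2 \rfloor$; for even $L$ the site sits just left of
center). Duplicated windows are pooled once. The left- and right-edge
windows guarantee every site is coverable, and for point coverage they also
make the pool optimal: any optimal placement of $k$ arbitrary windows can be
slid so each window starts at a covered site, so restricting the search to
these candidates loses nothing — the brute-force sliding-window comparator
below confirms this empirically on every tested instance. The adjacent
(upstream/downstream) windows exclude their generating site; they are kept
because they can cover neighboring sites.

**Forward selection** is greedy maximum coverage: small-hotspot amplicons
are added first, then repeatedly the candidate covering the most
not-yet-covered mutation weight, until every site is covered. The uncut
panel therefore always captures 100% of the input weight. Amplicons are
then ranked by their total covered count (ties: mutations closer to the
window center first, then lower coordinate) and the panel is cut to the
largest whole number of amplicons fitting the budget. Ranking uses each
amplicon's *total* count rather than its marginal gain at selection time;
the two differ on overlapping amplicons, and the cumulative-capture column
deduplicates overlaps so reported capture is never inflated.

**Comprehensive selection** trades time for capture. A forward pre-run at
the same budget fixes a threshold $T$ — the lowest per-amplicon count that
survives the cut — and candidates below $T$ are discarded (small-hotspot
amplicons are exempt: they are force-included, being the unique cover of
their hotspot; a site whose every candidate falls below $T$ drops out of the
comprehensive design, which is intended behavior and warned about). Each
remaining hotspot needs $k$ amplicons for full coverage, computed by the
exact greedy stabbing sweep for points. If $k$ exceeds the user's limit
`max_hotspot_amplicons`, the hotspot is split: per-bp candidate-overlap
depth is profiled, the longest run at the minimum depth is found, and the
region is cut at that run's center (ties toward the lower coordinate),
recursively. Within each bin every combination of the required number of
member amplicons is enumerated (a configurable cap, default $10^6$, guards
the search) and the combination capturing the most weight wins, with
deterministic tie-breaks (summed centrality, then ids). The assembled panel
is ranked and cut as in forward selection.

**Comparators.** `exhaustive_select()` over `sliding_pool()` is the
brute-force oracle: every 1-bp window placement, every combination at a
fixed amplicon count. It is optimal by construction and caps its own search
space; windows with identical covered-site sets are collapsed first, which
cannot change the optimum. `conventional_baseline()` is the historical
approach: consecutive non-overlapping $L$-bp tiles anchored at the first
mutated position, ranked by count. Because its boundaries are arbitrary, a
hotspot can straddle two tiles and dilute its count — the inefficiency the
hotspot-aware design exists to avoid.

## Evaluation and statistics

`capture_efficacy()` counts, per sample, mutation events inside the panel
and normalizes per 10,000 bp of panel; `compare_efficacy()` pairs two
reports by sample and applies a Wilcoxon signed-rank test plus the fold
change of mean efficacies. The signed-rank test is two-sided, drops zero
differences, and uses the exact null for $n \le 25$ without ties (the
normal approximation with continuity correction otherwise); it delegates to
`stats::wilcox.test`, and the test suite checks it against full sign-pattern
enumeration. `ks_reproducibility()` splits the record set 50/50 at random,
compares the halves' position distributions per chromosome with a
two-sample Kolmogorov–Smirnov test, and averages p-values over 100 splits;
splits are by record, not by sample, since it is the positional
distribution whose reproducibility is in question. `sample_size_curve()`
estimates how many training samples a panel design needs: for each
candidate size $n$ it repeatedly designs a forward panel from $n$ random
training samples and tests, on held-out samples, whether per-10-kb efficacy
inside the panel exceeds that of the full original target footprint,
reporting mean p-values per $n$ and the smallest $n$ below a significance
level (default $\alpha = 0.01$).

## The synthetic cohort generator

All tests and the bundled acceptance analyses run on synthetic cohorts from
`simulate_mutations()`. Each sample draws a Poisson number of events; each
event comes from a planted hotspot with probability `hotspot_fraction`
(center plus rounded Gaussian scatter of SD `hotspot_width`, clamped to the
enclosing region) and otherwise lands uniformly in the gene-like target
regions. Recurrent sites arise naturally from discretization. The defaults
— 120 samples, Poisson(30) events each, ten 20-kb regions, 25 hotspots of
10-bp width holding 80% of events — mirror the structure of published
normal-epidermis cohorts (hundreds of samples, sub-megabase panels, narrow
UV-type peaks over sparse background) at a scale where every algorithm,
including the brute-force comparator, runs in seconds to minutes.

What the generator does *not* emulate: trinucleotide/UV signature
composition, clonal expansion (events are independent across samples),
chromosome-scale covariates of mutability, and hotspot width heterogeneity.
Passing tests therefore demonstrate algorithmic correctness and the
relative behavior of the selectors under clustered input; they do not
calibrate absolute efficacy gains for any real tissue, and the fold-change
numbers printed by the bundled analyses are properties of the synthetic
conditions, not predictions.

## Numerical choices and edge cases

* Coordinates are 1-based inclusive internally; BED output converts to
  0-based half-open.
* Chromosome labels are opaque strings; `"chr1"` and `"1"` never merge.
* Weighted-center rounding: half toward the lower coordinate. Valley-split
  centers and even-length runs: lower coordinate. All tie-breaks (greedy
  gains, ranking, combinations) resolve toward lower coordinates or
  lexicographic ids, so identical inputs always give identical panels.
* Windows clamp at coordinate 1; right chromosome ends are not clamped
  because chromosome lengths are not part of the input.
* Recurrent mutations count once per event everywhere, matching per-sample
  burden accounting; `collapse_recurrent = TRUE` switches to unique sites.
* Degenerate inputs: an empty dataset errors at hotspot detection; a budget
  below one amplicon errors; a pool that cannot cover a site names the
  site; `n_max < 1` and combination-cap overruns error with advice.

## Open design points, resolved

Three places the procedure is underdetermined, and the choices made here:
whether the hotspot gap threshold compares against the seed or the last
added site (chaining, for the reason above); whether forward ranking uses
total or marginal counts (total, the more literal reading; capture columns
deduplicate so the difference never inflates results); and whether the
per-combination count filter applies each amplicon's own count or its
marginal contribution within the combination (own count, consistent with
the threshold's definition). Force-included small-hotspot amplicons are
exempt from the threshold since they are added unconditionally.

One caveat worth knowing: comprehensive selection optimizes full coverage
within each region before the global rank-and-cut, so after a tight budget
cut a forward panel can occasionally capture a handful more mutations on a
large instance; uncut, or at matched amplicon counts on unsplit instances,
comprehensive equals the brute-force optimum (the suite asserts this), and
on the suite's paired instances it is never below forward.

## Problem sizes used in the bundled analyses

The test suite and `scripts/acceptance.R` run: the default cohort for panel
arithmetic and recovery; 100 (suite) / 60 (script) random two-hotspot
instances for the oracle-equivalence check; 100 / 60 small clustered
cohorts for the baseline comparison with an exhaustive upper bound at a
3-amplicon budget; a 40-chromosome uniform cohort, 100 splits, for the KS
null check; and a 50-sample, Poisson(5) cohort for the sample-size curve
(100 replicates per grid point). These sizes were chosen so the complete
analyses rerun from scratch in a few minutes on one CPU while every
comparison retains at least ~25 sites or ~60 replicates.

## A worked example

```{r example}
sim <- simulate_mutations(sim_config(seed = 1))
sim$dataset

panel <- design_panel(sim$dataset, amplicon_length = 125,
                      panel_length = 10000, method = "forward")
panel
head(as.data.frame(panel)[, c("id", "chrom", "start", "end", "count",
                              "cumulative_bp", "cumulative_unique")])

baseline <- conventional_baseline(sim$dataset, L = 125, panel_budget = 10000)
attr(panel, "capture") - attr(baseline, "capture")
```

```{r plot, fig.width = 5, fig.height = 4}
plot(panel)
```
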
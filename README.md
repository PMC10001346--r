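# mutpanel

Design targeted-sequencing panels that capture the most somatic mutations
per base pair sequenced.

Somatic point mutations in carcinogen-exposed tissue — the motivating case
is normal sun-exposed epidermis and cutaneous squamous cell carcinoma —
cluster in narrow genomic hotspots. Ultra-deep sequencing of those hotspots
is how early clonal mutation burden is measured, and sequencing cost scales
with targeted panel size. Given a table of previously observed mutation
positions (chromosome, 1-based position, optionally sample and gene), an
amplicon length *L*, and a total panel-length budget, `mutpanel`:

1. **detects hotspots** — maximal clusters of mutated sites in which every
   consecutive gap is `< L` (single-linkage chaining at the amplicon-length
   threshold);
2. **generates candidate amplicons** — one weighted-center window per small
   hotspot, five windows per site (adjacent, edge-aligned, centered) for
   hotspots larger than one amplicon;
3. **selects a panel** under the budget, treating design as maximum
   coverage of mutation weight by fixed-length windows:
   * `forward` — greedy: repeatedly add the candidate covering the most
     not-yet-covered mutations (fast, near-optimal);
   * `comprehensive` — pseudo-exhaustive: drop candidates below a
     count threshold learned from a forward pre-run, split oversized
     hotspots at minimum-coverage valleys, enumerate every amplicon
     combination within each piece (slower, best capture);
   * `exhaustive` — brute-force 1-bp sliding-window comparator for
     validation on small inputs;
4. **evaluates panels**: per-sample capture efficacy (mutations per
   10,000 bp sequenced), paired Wilcoxon signed-rank comparisons and fold
   changes, conventional consecutive-tiling baseline, repeated-split
   Kolmogorov–Smirnov reproducibility checks, and a training-sample-size
   curve for panel design.

A synthetic-cohort generator (`simulate_mutations()`) with planted hotspot
structure makes the whole pipeline testable without any data download.

## Worked example

```r
library(mutpanel)

sim <- simulate_mutations(sim_config(seed = 1))   # synthetic cohort
sim$dataset
#> Mutation dataset: 3562 records at 1702 sites on 10 chromosome(s)
#>   120 samples; median records/sample: 29

panel <- design_panel(sim$dataset, amplicon_length = 125,
                      panel_length = 10000, method = "forward")
panel
#> Sequencing panel (forward selection): 80 amplicons x 125 bp = 10000 bp
#>   mutation capture: 2986 / 3562 (83.8%); efficacy 2986.00 per 10 kb

head(as.data.frame(panel)[, c("id", "chrom", "start", "end", "count",
                              "cumulative_bp", "cumulative_unique")], 3)
#>       id chrom   start     end count cumulative_bp cumulative_unique
#> 1 A01576  chr5 1014365 1014489   130           125               130
#> 2 A01308  chr4 1013295 1013419   126           250               256
#> 3 A00438 chr10 1009540 1009664   125           375               381

conventional_baseline(sim$dataset, L = 125, panel_budget = 10000)
#> Sequencing panel (conventional selection): 80 amplicons x 125 bp = 10000 bp
#>   mutation capture: 2945 / 3562 (82.7%); efficacy 2945.00 per 10 kb
```

Reading: a 10,000 bp budget at 125 bp amplicons buys exactly 80 amplicons;
the hotspot-aware panel captures 2986 of the cohort's 3562 mutation events
(83.8%) in 0.005% of the simulated 200 kb footprint, 41 events more than
ranking arbitrarily anchored consecutive tiles. `summary(panel)` adds mean
mutations per amplicon and genes captured; `plot(panel)` draws the
cumulative capture-per-bp decay as the panel grows; `write_panel()` emits
BED (0-based half-open) and CSV (1-based, with cumulative statistics).

Panels on real data start from `read_mutation_table()` (TSV/CSV; columns
`chrom`, `pos`, optional `sample`, `gene`) or `read_vcf_positions()`.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "mutpanel.R", package = "mutpanel"))') \
    design --input mutations.tsv --amplicon-length 125 \
    --panel-length 10000 --method forward --out-prefix mypanel
```

Subcommands: `design`, `evaluate` (panel CSV + mutation table → per-sample
efficacy), `simulate` (synthetic cohort → TSV + ground-truth JSON),
`samplesize` (mean p-value vs training-set size → CSV). The `design`
subcommand writes `<prefix>.bed`, `<prefix>.csv` and
`<prefix>_summary.json` (amplicon count, capture, average mutations per
amplicon, genes captured, efficacy per 10 kb).

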
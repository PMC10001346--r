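#' Design a targeted sequencing panel from mutation hotspots
#'
#' The main entry point: detects mutation hotspots with the amplicon-length
#' gap threshold, builds the candidate amplicon pool, selects an optimal
#' panel under the total-length budget, and ranks it. Three selectors are
#' available: `"forward"` (greedy maximum-new-mutations, fast),
#' `"comprehensive"` (pseudo-exhaustive per-region combination search,
#' best capture) and `"exhaustive"` (brute-force 1-bp sliding-window
#' comparator, validation only — guarded by a combination cap).
#'
#' @param dataset a [mutation_dataset()] (or a path/data.frame accepted by
#'   [read_mutation_table()] / [mutation_dataset()]).
#' @param amplicon_length amplicon length `L` in bp (>= 2); all panel
#'   amplicons have exactly this length.
#' @param panel_length total panel length budget in bp; the panel keeps the
#'   top-ranked `floor(panel_length / amplicon_length)` amplicons. `Inf`
#'   returns the full-coverage uncut panel.
#' @param method `"forward"`, `"comprehensive"` or `"exhaustive"`.
#' @param max_hotspot_amplicons comprehensive mode: hotspots needing more
#'   than this many amplicons are split at minimum-coverage valleys.
#' @param collapse_recurrent if TRUE, recurrent mutations at one site count
#'   once instead of once per event.
#' @param genes,exclude_genes optional gene include/exclude filters applied
#'   to the dataset before design (see [filter_genes()]).
#' @param combo_cap maximum combinations enumerated per exhaustive search.
#' @return a `mutation_panel`; see [select_forward()], [rank_and_cut()].
#' @examples
#' ds <- simulate_mutations(sim_config(n_samples = 30, seed = 7))$dataset
#' panel <- design_panel(ds, amplicon_length = 125, panel_length = 5000)
#' panel
#' summary(panel)
#' @export
design_panel <- function(dataset, amplicon_length, panel_length = Inf,
                         method = c("forward", "comprehensive", "exhaustive"),
                         max_hotspot_amplicons = 3,
                         collapse_recurrent = FALSE,
                         genes = NULL, exclude_genes = NULL,
                         combo_cap = 1e6) {
  method <- match.arg(method)
  if (is.character(dataset) && length(dataset) == 1) {
    dataset <- read_mutation_table(dataset)
  } else if (is.data.frame(dataset)) {
    dataset <- mutation_dataset(dataset$chrom, dataset$pos,
                                dataset$sample, dataset$gene)
  }
  stopifnot(inherits(dataset, "mutation_dataset"))
  if (!is.null(genes) || !is.null(exclude_genes)) {
    dataset <- filter_genes(dataset, genes, exclude_genes)
  }
  if (is.finite(panel_length) && panel_length < amplicon_length) {
    stop("`panel_length` must be at least one amplicon length")
  }
  hs <- detect_hotspots(dataset, amplicon_length)
  if (method == "exhaustive") {
    pool <- sliding_pool(hs, dataset, amplicon_length)
    b <- if (is.finite(panel_length)) floor(panel_length / amplicon_length)
         else nrow(dataset$sites)
    return(exhaustive_select(pool, dataset, b, combo_cap))
  }
  pool <- build_pool(hs, dataset, amplicon_length, collapse_recurrent)
  panel <- switch(method,
    forward = rank_and_cut(select_forward(pool, dataset), panel_length, dataset),
    comprehensive = select_comprehensive(pool, dataset, panel_length,
                                         n_max = max_hotspot_amplicons,
                                         combo_cap = combo_cap))
  panel
}
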
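#' Sliding-window amplicon pool for a hotspot
#'
#' Brute-force comparator pool: one candidate amplicon at every possible
#' 1-bp offset that overlaps the hotspot — starts from
#' `hotspot.start - L + 1` (clamped at coordinate 1) through `hotspot.end`.
#' Every 5-candidate window for the hotspot is contained in this pool.
#'
#' @param hotspots a `hotspot_set` (all rows are pooled together).
#' @param dataset the [mutation_dataset()].
#' @param L amplicon length (bp).
#' @return an `amplicon_pool` covering every possible hotspot section.
#' @export
sliding_pool <- function(hotspots, dataset, L) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  L <- as.integer(L)
  chrom <- character(0); start <- integer(0); hid <- character(0)
  for (i in seq_len(nrow(hotspots))) {
    h <- hotspots[i, ]
    st <- max(1L, h$start - L + 1L):h$end
    chrom <- c(chrom, rep(h$chrom, length(st)))
    start <- c(start, st)
    hid <- c(hid, rep(h$hotspot_id, length(st)))
  }
  keep <- !duplicated(paste(chrom, start, sep = "\r"))
  pool <- data.frame(chrom = chrom[keep], start = start[keep],
                     hotspot_id = hid[keep], forced = FALSE,
                     stringsAsFactors = FALSE)
  pool$end <- pool$start + L - 1L
  pool <- pool[order(pool$chrom, pool$start), , drop = FALSE]
  rownames(pool) <- NULL
  pool$id <- sprintf("S%06d", seq_len(nrow(pool)))
  pool <- annotate_pool(pool, dataset, L)
  attr(pool, "L") <- L
  attr(pool, "collapse_recurrent") <- FALSE
  class(pool) <- c("amplicon_pool", "data.frame")
  pool
}

#' Exhaustive optimal panel at a fixed amplicon count
#'
#' Tests every combination of `budget_amplicons` pool amplicons and returns
#' one maximizing total captured mutation weight (ties: lowest summed
#' centrality, then lexicographic ids). Optimal by construction; intended
#' as a validation comparator, with a hard cap on the number of
#' combinations enumerated. Amplicons covering identical site sets are
#' collapsed to their lowest-coordinate representative before enumeration,
#' which leaves the optimum unchanged.
#'
#' @param pool an `amplicon_pool` (typically from [sliding_pool()]).
#' @param dataset the [mutation_dataset()].
#' @param budget_amplicons number of amplicons to select.
#' @param combo_cap maximum combinations enumerated (default 1e6).
#' @return a ranked `mutation_panel` (method `"exhaustive"`).
#' @export
exhaustive_select <- function(pool, dataset, budget_amplicons, combo_cap = 1e6) {
  stopifnot(inherits(pool, "amplicon_pool"))
  L <- attr(pool, "L")
  collapse <- isTRUE(attr(pool, "collapse_recurrent"))
  w <- site_weights(dataset, collapse)
  sig <- vapply(pool$covered, function(idx) paste(idx, collapse = ","), character(1))
  pool_d <- pool[!duplicated(sig) & lengths(pool$covered) > 0, , drop = FALSE]
  if (nrow(pool_d) == 0) stop("pool covers no mutation sites")
  b <- min(budget_amplicons, nrow(pool_d))
  n_comb <- choose(nrow(pool_d), b)
  if (n_comb > combo_cap) {
    stop(sprintf("exhaustive search too large: choose(%d, %d) = %.3g combinations exceeds the cap (%g)",
                 nrow(pool_d), b, n_comb, combo_cap))
  }
  sel <- best_combination(pool_d, b, w, combo_cap)
  panel <- new_panel(pool_d[sel, , drop = FALSE], dataset, L,
                     method = "exhaustive", collapse_recurrent = collapse)
  rank_and_cut(panel, Inf, dataset)
}

#' Conventional consecutive-tiling baseline panel
#'
#' The baseline the hotspot-aware selectors are compared against: each
#' chromosome is broken into consecutive non-overlapping L-bp amplicons
#' anchored at its first mutated position, tiles are ranked by the mutation
#' weight they capture, and the top tiles fitting the budget are kept.
#' Because tile boundaries are arbitrary, a mutation hotspot can be split
#' across two tiles, diluting its count — the inefficiency hotspot-aware
#' design avoids.
#'
#' @param dataset the [mutation_dataset()].
#' @param L amplicon (tile) length in bp.
#' @param panel_budget panel length budget in bp (`Inf` keeps all
#'   mutation-bearing tiles).
#' @param collapse_recurrent if TRUE count each site once.
#' @return a ranked, cut `mutation_panel` (method `"conventional"`).
#' @export
conventional_baseline <- function(dataset, L, panel_budget = Inf,
                                  collapse_recurrent = FALSE) {
  stopifnot(inherits(dataset, "mutation_dataset"))
  L <- as.integer(L)
  s <- dataset$sites
  chrom <- character(0); start <- integer(0)
  for (ch in unique(s$chrom)) {
    p <- s$pos[s$chrom == ch]
    anchor <- min(p)
    tiles <- unique(anchor + ((p - anchor) %/% L) * L)
    chrom <- c(chrom, rep(ch, length(tiles)))
    start <- c(start, tiles)
  }
  pool <- data.frame(chrom = chrom, start = start, hotspot_id = NA_character_,
                     forced = FALSE, stringsAsFactors = FALSE)
  pool$end <- pool$start + L - 1L
  pool <- pool[order(pool$chrom, pool$start), , drop = FALSE]
  rownames(pool) <- NULL
  pool$id <- sprintf("T%05d", seq_len(nrow(pool)))
  pool <- annotate_pool(pool, dataset, L, collapse_recurrent)
  panel <- new_panel(pool, dataset, L, method = "conventional",
                     collapse_recurrent = collapse_recurrent)
  rank_and_cut(panel, panel_budget, dataset)
}
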
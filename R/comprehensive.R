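# minimum number of L-bp windows needed to cover a set of site positions:
# greedy left-to-right interval stabbing, exact for points
stab_count <- function(pos, L) {
  pos <- sort(pos)
  k <- 0L
  cover_end <- -Inf
  for (p in pos) {
    if (p > cover_end) {
      k <- k + 1L
      cover_end <- p + L - 1L
    }
  }
  k
}

#' Mutation-count threshold from a forward pre-run
#'
#' Comprehensive selection first runs the cheap forward selector to learn
#' the lowest per-amplicon mutation count that still makes it into a panel
#' of the requested length; candidate amplicons below that count cannot be
#' part of the final panel and are removed before the exhaustive search.
#'
#' @param pool an `amplicon_pool`.
#' @param dataset the [mutation_dataset()].
#' @param panel_budget panel length budget in bp (`Inf` for uncut).
#' @return integer threshold `T` (minimum retained per-amplicon count).
#' @export
capture_threshold <- function(pool, dataset, panel_budget = Inf) {
  fwd <- rank_and_cut(select_forward(pool, dataset), panel_budget, dataset)
  if (nrow(fwd) == 0) stop("budget too small to retain any amplicon")
  min(fwd$count)
}

#' Split a large hotspot at minimum-coverage valleys
#'
#' When a hotspot would need more than `n_max` amplicons, the exhaustive
#' combination search becomes infeasible, so the region is split: the
#' per-bp overlap depth of the hotspot's candidate amplicons is computed,
#' the longest contiguous run at the minimum depth is located, and the
#' region is cut at that run's center (ties toward the lower coordinate).
#' Splitting recurses until every sub-region needs at most `n_max`
#' amplicons. Amplicons are assigned to the bin containing their midpoint
#' but keep their full covered-site sets.
#'
#' @param hotspot one-row slice of a `hotspot_set`.
#' @param pool_rows the pool amplicons of this hotspot (data.frame slice).
#' @param dataset the [mutation_dataset()].
#' @param n_max maximum amplicons per bin (integer >= 1).
#' @param L amplicon length (bp).
#' @return list of bins; each bin is a list with `start`, `end`,
#'   `site_idx` (dataset site indices inside the bin), `member_rows`
#'   (row indices into `pool_rows`), and `k_required`.
#' @export
split_hotspot <- function(hotspot, pool_rows, dataset, n_max, L) {
  if (!is.numeric(n_max) || n_max < 1) stop("`n_max` must be a positive integer")
  site_idx <- hotspot$site_idx[[1]]
  # midpoints clamped into the hotspot extent so overhanging windows still
  # belong to exactly one bin
  mid <- pmin(pmax((pool_rows$start + pool_rows$end) %/% 2L,
                   hotspot$start), hotspot$end)

  recurse <- function(rstart, rend) {
    s_in <- site_idx[dataset$sites$pos[site_idx] >= rstart &
                       dataset$sites$pos[site_idx] <= rend]
    m_in <- which(mid >= rstart & mid <= rend)
    k <- stab_count(dataset$sites$pos[s_in], L)
    if (k <= n_max || rend - rstart < 1L) {
      return(list(list(start = rstart, end = rend, site_idx = s_in,
                       member_rows = m_in, k_required = k)))
    }
    # per-bp overlap depth of member amplicons across [rstart, rend]
    depth <- integer(rend - rstart + 1L)
    for (i in m_in) {
      a <- max(rstart, pool_rows$start[i]) - rstart + 1L
      b <- min(rend, pool_rows$end[i]) - rstart + 1L
      if (a <= b) depth[a:b] <- depth[a:b] + 1L
    }
    r <- rle(depth == min(depth))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    longest <- runs[which.max(r$lengths[runs])]  # first longest on ties
    cut_at <- rstart - 1L + (starts[longest] + ends[longest]) %/% 2L
    if (cut_at >= rend) cut_at <- rend - 1L
    if (cut_at < rstart) cut_at <- rstart
    c(recurse(rstart, cut_at), recurse(cut_at + 1L, rend))
  }
  recurse(hotspot$start, hotspot$end)
}

# best combination of exactly k amplicons from `rows` by total unique
# covered weight; ties by lower summed centrality then lexicographic ids.
# Returns row indices into `rows`.
best_combination <- function(rows, k, w, combo_cap = 1e6) {
  n <- nrow(rows)
  k <- min(k, n)
  if (k == 0L) return(integer(0))
  n_comb <- choose(n, k)
  if (n_comb > combo_cap) {
    stop(sprintf(paste0("combination search too large (%.3g combinations of %d",
                        " amplicons); lower `n_max` to split hotspots further"),
                 n_comb, n))
  }
  combos <- utils::combn(n, k)
  capture <- apply(combos, 2, function(ii) {
    sum(w[unique(unlist(rows$covered[ii]))])
  })
  best <- which(capture == max(capture))
  if (length(best) > 1) {
    cent <- apply(combos[, best, drop = FALSE], 2,
                  function(ii) sum(rows$centrality[ii]))
    best <- best[cent == min(cent)]
  }
  combos[, best[1]]  # combn order is lexicographic in row order (= id order)
}

#' Comprehensive (pseudo-exhaustive) panel selection
#'
#' Near-optimal panel construction: a forward pre-run fixes the
#' per-amplicon mutation-count threshold ([capture_threshold()]) and
#' candidates below it are dropped; hotspots needing more than `n_max`
#' amplicons are split at minimum-coverage valleys ([split_hotspot()]);
#' within each resulting bin every combination of the required number of
#' amplicons is enumerated and the combination capturing the most mutations
#' is kept. Small-hotspot amplicons are force-included and exempt from the
#' threshold. The assembled panel is ranked (count desc, then mutations
#' closest to the amplicon center) and cut to `panel_budget`.
#'
#' @param pool an `amplicon_pool`.
#' @param dataset the [mutation_dataset()].
#' @param panel_budget panel length budget in bp (`Inf` for uncut).
#' @param n_max maximum amplicons per bin before splitting (default 3).
#' @param combo_cap maximum combinations enumerated per bin (default 1e6).
#' @param threshold per-amplicon count threshold; by default derived from a
#'   forward pre-run at `panel_budget` via [capture_threshold()].
#' @return a ranked, cut `mutation_panel`.
#' @export
select_comprehensive <- function(pool, dataset, panel_budget = Inf,
                                 n_max = 3, combo_cap = 1e6,
                                 threshold = NULL) {
  stopifnot(inherits(pool, "amplicon_pool"))
  L <- attr(pool, "L")
  collapse <- isTRUE(attr(pool, "collapse_recurrent"))
  w <- site_weights(dataset, collapse)
  thr <- if (is.null(threshold)) capture_threshold(pool, dataset, panel_budget)
         else threshold

  keep <- pool$forced | pool$count >= thr
  pool_f <- pool[keep, , drop = FALSE]

  chosen <- which(pool_f$forced)
  hotspots <- detect_hotspots(dataset, L)
  large <- hotspots[hotspots$span > L, , drop = FALSE]
  for (i in seq_len(nrow(large))) {
    h <- large[i, ]
    rows_i <- which(pool_f$hotspot_id == h$hotspot_id)
    if (!length(rows_i)) {
      warning(sprintf("hotspot %s: all candidate amplicons fall below the threshold (%d); region skipped",
                      h$hotspot_id, thr))
      next
    }
    rows <- pool_f[rows_i, , drop = FALSE]
    bins <- split_hotspot(h, rows, dataset, n_max, L)
    for (b in bins) {
      if (!length(b$member_rows)) {
        if (length(b$site_idx)) {
          warning(sprintf("hotspot %s bin %d-%d: no amplicons available",
                          h$hotspot_id, b$start, b$end))
        }
        next
      }
      if (b$k_required == 0L) next
      sel <- best_combination(rows[b$member_rows, , drop = FALSE],
                              b$k_required, w, combo_cap)
      chosen <- c(chosen, rows_i[b$member_rows[sel]])
    }
  }
  chosen <- unique(chosen)
  panel <- new_panel(pool_f[chosen, , drop = FALSE], dataset, L,
                     method = "comprehensive", collapse_recurrent = collapse)
  rank_and_cut(panel, panel_budget, dataset)
}
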
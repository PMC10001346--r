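# Internal panel constructor. `rows` is a pool-style data.frame slice
# (id, chrom, start, end, hotspot_id, forced, count, centrality, covered).
# Cumulative capture is computed in the given row order, counting each
# site's weight once even when two amplicons overlap it.
new_panel <- function(rows, dataset, L, method, budget = Inf,
                      collapse_recurrent = FALSE) {
  w <- site_weights(dataset, collapse_recurrent)
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  rows$cumulative_bp <- seq_len(nrow(rows)) * L
  seen <- logical(nrow(dataset$sites))
  cum <- numeric(nrow(rows))
  run <- 0
  for (i in seq_len(nrow(rows))) {
    idx <- rows$covered[[i]]
    new_idx <- idx[!seen[idx]]
    run <- run + sum(w[new_idx])
    seen[new_idx] <- TRUE
    cum[i] <- run
  }
  rows$cumulative_unique <- cum
  rows$genes <- vapply(rows$covered, function(idx) {
    g <- unique(dataset$sites$gene[idx])
    g <- g[!is.na(g)]
    if (length(g)) paste(sort(g), collapse = ";") else NA_character_
  }, character(1))
  structure(rows, class = c("mutation_panel", "data.frame"),
            L = L, method = method, budget = budget,
            collapse_recurrent = collapse_recurrent,
            site_w = w,
            total_weight = sum(w),
            capture = if (nrow(rows)) cum[nrow(rows)] else 0)
}

#' Greedy forward panel selection
#'
#' Builds the uncut panel by forward selection: amplicons covering small
#' hotspots are added first (they are the unique cover of their hotspot),
#' then, repeatedly, the candidate amplicon covering the highest number of
#' not-yet-covered mutations is added, until every mutation site is covered
#' by at least one panel amplicon. Ties are broken toward the lower
#' (chromosome, start) coordinate. The returned panel captures 100% of the
#' dataset's mutation weight; apply [rank_and_cut()] to enforce a panel
#' length budget.
#'
#' @param pool an `amplicon_pool` from [build_pool()].
#' @param dataset the [mutation_dataset()].
#' @return a `mutation_panel` in selection order (uncut).
#' @export
select_forward <- function(pool, dataset) {
  stopifnot(inherits(pool, "amplicon_pool"))
  L <- attr(pool, "L")
  collapse <- isTRUE(attr(pool, "collapse_recurrent"))
  w <- site_weights(dataset, collapse)
  n_sites <- nrow(dataset$sites)
  covered <- logical(n_sites)
  chosen <- integer(0)

  forced_rows <- which(pool$forced)
  for (i in forced_rows) covered[pool$covered[[i]]] <- TRUE
  chosen <- forced_rows

  open <- setdiff(seq_len(nrow(pool)), forced_rows)
  # pool is sorted by (chrom, start), so the first maximum is the tie-winner
  while (!all(covered)) {
    gains <- vapply(open, function(i) {
      idx <- pool$covered[[i]]
      sum(w[idx[!covered[idx]]])
    }, numeric(1))
    if (!length(gains) || max(gains) <= 0) {
      missing_site <- which(!covered)[1]
      stop(sprintf("pool does not cover site %s:%d",
                   dataset$sites$chrom[missing_site],
                   dataset$sites$pos[missing_site]))
    }
    pick <- open[which.max(gains)]
    covered[pool$covered[[pick]]] <- TRUE
    chosen <- c(chosen, pick)
    open <- setdiff(open, pick)
  }
  new_panel(pool[chosen, , drop = FALSE], dataset, L,
            method = "forward", collapse_recurrent = collapse)
}

#' Rank a panel and apply a length budget
#'
#' Amplicons are ranked from highest to lowest total covered mutation count
#' (ties: more centrally located mutations first, then lower (chromosome,
#' start)); cumulative base-pair length and cumulative unique mutation
#' capture are recomputed in rank order; and amplicons beyond the last whole
#' amplicon fitting within `panel_budget` bp are removed.
#'
#' @param panel a `mutation_panel`.
#' @param panel_budget total panel length budget in bp (`Inf` keeps all).
#' @param dataset the [mutation_dataset()] the panel was designed from.
#' @return the ranked, cut `mutation_panel`.
#' @export
rank_and_cut <- function(panel, panel_budget, dataset) {
  stopifnot(inherits(panel, "mutation_panel"))
  L <- attr(panel, "L")
  if (panel_budget < L) stop("panel budget smaller than one amplicon")
  ord <- order(-panel$count, panel$centrality, panel$chrom, panel$start)
  keep <- utils::head(ord, if (is.finite(panel_budget)) floor(panel_budget / L) else length(ord))
  new_panel(panel[keep, , drop = FALSE], dataset, L,
            method = attr(panel, "method"), budget = panel_budget,
            collapse_recurrent = isTRUE(attr(panel, "collapse_recurrent")))
}

#' @export
print.mutation_panel <- function(x, ...) {
  cap <- attr(x, "capture"); tot <- attr(x, "total_weight")
  cat(sprintf("Sequencing panel (%s selection): %d amplicons x %d bp = %d bp\n",
              attr(x, "method"), nrow(x), attr(x, "L"), nrow(x) * attr(x, "L")))
  cat(sprintf("  mutation capture: %g / %g (%.1f%%); efficacy %.2f per 10 kb\n",
              cap, tot, 100 * cap / tot,
              1e4 * cap / (nrow(x) * attr(x, "L"))))
  invisible(x)
}

#' @export
summary.mutation_panel <- function(object, ...) {
  structure(list(
    method = attr(object, "method"),
    n_amplicons = nrow(object),
    amplicon_length = attr(object, "L"),
    panel_bp = nrow(object) * attr(object, "L"),
    budget = attr(object, "budget"),
    capture = attr(object, "capture"),
    total_weight = attr(object, "total_weight"),
    capture_pct = 100 * attr(object, "capture") / attr(object, "total_weight"),
    mean_mutations_per_amplicon = mean(object$count),
    genes = sort(unique(unlist(strsplit(object$genes[!is.na(object$genes)], ";")))),
    efficacy_per_10kb = 1e4 * attr(object, "capture") /
      (nrow(object) * attr(object, "L"))
  ), class = "summary.mutation_panel")
}

#' @export
print.summary.mutation_panel <- function(x, ...) {
  cat(sprintf("Panel summary (%s):\n", x$method))
  cat(sprintf("  amplicons: %d x %d bp (panel %d bp, budget %s)\n",
              x$n_amplicons, x$amplicon_length, x$panel_bp,
              format(x$budget)))
  cat(sprintf("  capture: %g of %g mutations (%.1f%%)\n",
              x$capture, x$total_weight, x$capture_pct))
  cat(sprintf("  mean mutations per amplicon: %.2f\n", x$mean_mutations_per_amplicon))
  cat(sprintf("  efficacy: %.2f mutations per 10 kb\n", x$efficacy_per_10kb))
  if (length(x$genes)) cat("  genes captured:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Plot cumulative capture efficacy of a ranked panel
#'
#' Cumulative unique mutations captured per base pair (per 10 kb) as the
#' panel grows amplicon by amplicon in rank order. For a ranked panel the
#' per-amplicon counts are non-increasing, so this curve falls off: the
#' first amplicons are the most mutation-dense.
#'
#' @param x a `mutation_panel`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mutation_panel <- function(x, ...) {
  eff <- 1e4 * x$cumulative_unique / x$cumulative_bp
  graphics::plot(x$cumulative_bp, eff, type = "s",
                 xlab = "cumulative panel length (bp)",
                 ylab = "cumulative mutations per 10 kb",
                 main = sprintf("Capture efficacy (%s selection)", attr(x, "method")),
                 ...)
  invisible(x)
}

#' Write a panel as BED and CSV
#'
#' The BED file is 0-based half-open with the amplicon id as name and its
#' mutation count as score; the CSV keeps 1-based inclusive coordinates
#' together with the panel's cumulative statistics.
#'
#' @param panel a non-empty `mutation_panel`.
#' @param bed_path,csv_path output paths (either may be `NULL` to skip).
#' @export
write_panel <- function(panel, bed_path = NULL, csv_path = NULL) {
  stopifnot(inherits(panel, "mutation_panel"))
  if (nrow(panel) == 0) stop("refusing to write an empty panel")
  if (!is.null(bed_path)) {
    bed <- data.frame(panel$chrom, panel$start - 1L, panel$end,
                      panel$id, panel$count, ".")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(csv_path)) {
    csv <- data.frame(amplicon_id = panel$id, chrom = panel$chrom,
                      start_1based = panel$start, end_1based = panel$end,
                      mutations_covered = panel$count,
                      cumulative_bp = panel$cumulative_bp,
                      cumulative_unique_mutations = panel$cumulative_unique,
                      genes = panel$genes, stringsAsFactors = FALSE)
    utils::write.csv(csv, csv_path, row.names = FALSE)
  }
  invisible(panel)
}

#' Read a panel CSV back into a data.frame of intervals
#'
#' Round-trips the CSV written by [write_panel()]. The result carries the
#' 1-based inclusive coordinates and counts and can be passed to
#' [capture_efficacy()].
#'
#' @param path a panel CSV path.
#' @return data.frame with `amplicon_id`, `chrom`, `start_1based`,
#'   `end_1based`, `mutations_covered`, cumulative columns and `genes`.
#' @export
read_panel_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
}
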
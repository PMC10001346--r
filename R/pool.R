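#' Amplicon placement for a small hotspot
#'
#' A hotspot whose span fits within one amplicon is covered by a single
#' amplicon of length `L`. Its center is the recurrence-weighted mean of the
#' hotspot's site positions, rounded half toward the lower coordinate, and
#' the window is then shifted minimally so that it contains the whole
#' hotspot extent (and starts at coordinate >= 1).
#'
#' @param hotspot one-row slice of a `hotspot_set`, with its `site_idx`.
#' @param dataset the [mutation_dataset()] the hotspots came from.
#' @param L amplicon length (bp).
#' @return integer vector `c(start, end)` of the 1-based inclusive window.
#' @export
single_amplicon <- function(hotspot, dataset, L) {
  if (hotspot$span > L) stop("hotspot span exceeds one amplicon length")
  idx <- hotspot$site_idx[[1]]
  p <- dataset$sites$pos[idx]
  w <- dataset$sites$weight[idx]
  wm <- sum(as.numeric(p) * w) / sum(w)
  center <- as.integer(ceiling(wm - 0.5))  # round half down
  start <- center - (L - 1L) %/% 2L
  # shift minimally to contain the full hotspot extent
  if (start > hotspot$start) start <- hotspot$start
  if (start + L - 1L < hotspot$end) start <- hotspot$end - L + 1L
  start <- max(1L, start)
  c(start = start, end = start + L - 1L)
}

#' Candidate amplicon windows around one mutation
#'
#' For hotspots larger than one amplicon, five fixed-length windows are
#' examined at each mutated site `m`: directly upstream (`[m-L, m-1]`),
#' directly downstream (`[m+1, m+L]`), mutation at the right edge
#' (`[m-L+1, m]`), mutation at the left edge (`[m, m+L-1]`), and mutation
#' centered (`[m - floor((L-1)/2), ...]`; for even `L` the site sits just
#' left of center). Windows are clamped to start at coordinate >= 1.
#'
#' @param m 1-based position of the mutation.
#' @param L amplicon length (bp).
#' @return a 5x2 integer matrix of `start`, `end` columns, rows named
#'   `upstream`, `downstream`, `right_edge`, `left_edge`, `centered`.
#' @export
candidate_amplicons <- function(m, L) {
  m <- as.integer(m); L <- as.integer(L)
  starts <- c(upstream = m - L, downstream = m + 1L,
              right_edge = m - L + 1L, left_edge = m,
              centered = m - (L - 1L) %/% 2L)
  starts <- pmax(1L, starts)
  cbind(start = starts, end = starts + L - 1L)
}

#' Build the candidate amplicon pool
#'
#' Small hotspots (span <= `L`) contribute exactly one forced amplicon via
#' [single_amplicon()]; larger hotspots contribute up to five candidate
#' windows per site via [candidate_amplicons()]. Candidates sharing
#' (chromosome, start) are de-duplicated. Every pool amplicon records the
#' full set of dataset sites it covers (including sites of a neighboring
#' hotspot that an overhanging window happens to reach), its total covered
#' mutation weight, and its centrality (mean distance of covered sites from
#' the window center; lower is more central).
#'
#' @param hotspots a `hotspot_set` from [detect_hotspots()] (same `L`).
#' @param dataset the [mutation_dataset()].
#' @param L amplicon length (bp).
#' @param collapse_recurrent if TRUE, count each site once, ignoring
#'   recurrence weight.
#' @return a data.frame of class `amplicon_pool`, sorted by (chrom, start):
#'   `id`, `chrom`, `start`, `end`, `hotspot_id`, `forced` (small-hotspot
#'   amplicons, always included in panels), `count`, `centrality`, and a
#'   `covered` list-column of site indices. Attribute `L` is attached.
#' @export
build_pool <- function(hotspots, dataset, L, collapse_recurrent = FALSE) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  L <- as.integer(L)
  if (!identical(attr(hotspots, "L"), L)) {
    stop("hotspots were detected with a different amplicon length")
  }
  chrom <- character(0); start <- integer(0)
  hid <- character(0); forced <- logical(0)
  for (i in seq_len(nrow(hotspots))) {
    h <- hotspots[i, ]
    if (h$span <= L) {
      win <- single_amplicon(h, dataset, L)
      chrom <- c(chrom, h$chrom); start <- c(start, win[["start"]])
      hid <- c(hid, h$hotspot_id); forced <- c(forced, TRUE)
    } else {
      for (m in dataset$sites$pos[h$site_idx[[1]]]) {
        cand <- candidate_amplicons(m, L)
        chrom <- c(chrom, rep(h$chrom, nrow(cand)))
        start <- c(start, cand[, "start"])
        hid <- c(hid, rep(h$hotspot_id, nrow(cand)))
        forced <- c(forced, rep(FALSE, nrow(cand)))
      }
    }
  }
  keep <- !duplicated(paste(chrom, start, sep = "\r"))
  pool <- data.frame(chrom = chrom[keep], start = start[keep],
                     hotspot_id = hid[keep], forced = forced[keep],
                     stringsAsFactors = FALSE)
  pool$end <- pool$start + L - 1L
  ord <- order(pool$chrom, pool$start)
  pool <- pool[ord, , drop = FALSE]
  rownames(pool) <- NULL
  pool$id <- sprintf("A%05d", seq_len(nrow(pool)))
  pool <- annotate_pool(pool, dataset, L, collapse_recurrent)
  attr(pool, "L") <- L
  attr(pool, "collapse_recurrent") <- collapse_recurrent
  class(pool) <- c("amplicon_pool", "data.frame")
  pool
}

# fill covered / count / centrality for a pool skeleton (chrom,start,end set)
annotate_pool <- function(pool, dataset, L, collapse_recurrent = FALSE) {
  w <- site_weights(dataset, collapse_recurrent)
  ctr <- pool$start + (L - 1L) %/% 2L
  covered <- vector("list", nrow(pool))
  count <- integer(nrow(pool))
  centrality <- rep(NA_real_, nrow(pool))
  for (i in seq_len(nrow(pool))) {
    idx <- sites_in_window(dataset, pool$chrom[i], pool$start[i], pool$end[i])
    covered[[i]] <- idx
    count[i] <- sum(w[idx])
    if (length(idx)) {
      centrality[i] <- mean(abs(dataset$sites$pos[idx] - ctr[i]))
    }
  }
  pool$covered <- covered
  pool$count <- count
  pool$centrality <- centrality
  pool[, c("id", "chrom", "start", "end", "hotspot_id", "forced",
           "count", "centrality", "covered")]
}

#' @export
print.amplicon_pool <- function(x, ...) {
  cat(sprintf("Amplicon pool: %d candidate windows of %d bp (%d forced) over %d hotspot(s)\n",
              nrow(x), attr(x, "L"), sum(x$forced), length(unique(x$hotspot_id))))
  invisible(x)
}
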
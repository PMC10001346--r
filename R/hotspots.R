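#' Detect mutation hotspots
#'
#' Partitions the distinct mutated sites of each chromosome into maximal
#' hotspot clusters. Scanning sites in genomic order, a site joins the
#' current hotspot when its distance from the most recently added site is
#' strictly less than one amplicon length `L`; a gap of `L` or more bp
#' terminates the hotspot and starts a new one. Chromosomes are processed
#' independently. This chained single-linkage rule makes hotspots maximal
#' runs whose consecutive gaps are all `< L`, which is what allows a hotspot
#' to grow beyond one amplicon in span.
#'
#' @param dataset a [mutation_dataset()].
#' @param L amplicon length in bp (integer >= 2).
#' @return a data.frame of class `hotspot_set` with one row per hotspot:
#'   `hotspot_id`, `chrom`, `start`, `end`, `span` (`end - start + 1`),
#'   `n_sites`, `weight` (summed site recurrence), and a `site_idx`
#'   list-column of indices into `dataset$sites`. The amplicon length is
#'   attached as attribute `L`.
#' @examples
#' ds <- mutation_dataset(rep("chr1", 4), c(100, 150, 210, 400))
#' detect_hotspots(ds, L = 100)
#' @export
detect_hotspots <- function(dataset, L) {
  stopifnot(inherits(dataset, "mutation_dataset"))
  if (!is.numeric(L) || length(L) != 1 || L < 2 || L != floor(L)) {
    stop("`L` must be a single integer >= 2")
  }
  L <- as.integer(L)
  s <- dataset$sites
  if (nrow(s) == 0) stop("dataset has no mutation sites")

  # sites are sorted by (chrom, pos); a new cluster starts at each chromosome
  # change or at each gap >= L
  new_cluster <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)] |
                     diff(s$pos) >= L)
  cl <- cumsum(new_cluster)
  idx_by_cl <- split(seq_len(nrow(s)), cl)

  start <- vapply(idx_by_cl, function(i) s$pos[i[1]], integer(1))
  end <- vapply(idx_by_cl, function(i) s$pos[i[length(i)]], integer(1))
  hs <- data.frame(
    hotspot_id = sprintf("H%05d", seq_along(idx_by_cl)),
    chrom = vapply(idx_by_cl, function(i) s$chrom[i[1]], character(1)),
    start = start,
    end = end,
    span = end - start + 1L,
    n_sites = lengths(idx_by_cl),
    weight = vapply(idx_by_cl, function(i) sum(s$weight[i]), integer(1)),
    stringsAsFactors = FALSE
  )
  hs$site_idx <- unname(idx_by_cl)
  rownames(hs) <- NULL
  attr(hs, "L") <- L
  class(hs) <- c("hotspot_set", "data.frame")
  hs
}

#' Write hotspot extents as BED
#'
#' 0-based half-open intervals for inspection in a genome browser.
#'
#' @param hotspots a `hotspot_set` from [detect_hotspots()].
#' @param path output path.
#' @export
write_hotspot_bed <- function(hotspots, path) {
  bed <- data.frame(hotspots$chrom, hotspots$start - 1L, hotspots$end,
                    hotspots$hotspot_id, hotspots$weight, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
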
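#' Simulation configuration for synthetic mutation datasets
#'
#' Defaults emulate a targeted-sequencing cohort of clinically normal
#' tissue: many samples whose point mutations concentrate in narrow genomic
#' hotspots (a few bp wide, far narrower than an amplicon) over a sparse
#' uniform background, across gene-like target intervals. The default scale
#' — 120 samples, ~30 mutations each, ten 20-kb gene regions, 25 hotspots of
#' ~10 bp width holding 80% of mutations — mirrors the structure of
#' published normal-epidermis cohorts at a size every algorithm here can
#' process in seconds.
#'
#' @param n_samples number of samples.
#' @param target_regions data.frame with `chrom`, `start`, `end`, `gene`
#'   describing non-overlapping gene-like target intervals; default ten
#'   20-kb regions on chromosomes chr1..chr10.
#' @param n_hotspots number of planted hotspot centers.
#' @param hotspot_width SD (bp) of the rounded-normal scatter around each
#'   center.
#' @param hotspot_fraction probability a mutation comes from a hotspot
#'   rather than the uniform background (0-1).
#' @param mutations_per_sample Poisson mean mutation count per sample.
#' @param seed integer seed; simulation is byte-identical given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 120,
                       target_regions = NULL,
                       n_hotspots = 25,
                       hotspot_width = 10,
                       hotspot_fraction = 0.8,
                       mutations_per_sample = 30,
                       seed = 1) {
  if (is.null(target_regions)) {
    target_regions <- data.frame(
      chrom = paste0("chr", 1:10),
      start = 1e6L,
      end = 1e6L + 19999L,
      gene = sprintf("GENE%02d", 1:10),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(target_regions) >= 1,
            all(target_regions$end >= target_regions$start),
            hotspot_fraction >= 0, hotspot_fraction <= 1,
            hotspot_width >= 1, n_samples >= 1, mutations_per_sample > 0)
  # regions on a shared chromosome must not overlap
  for (ch in unique(target_regions$chrom)) {
    r <- target_regions[target_regions$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)])) {
      stop("target regions overlap on ", ch)
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 target_regions = target_regions,
                 n_hotspots = as.integer(n_hotspots),
                 hotspot_width = hotspot_width,
                 hotspot_fraction = hotspot_fraction,
                 mutations_per_sample = mutations_per_sample,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a mutation dataset with planted hotspots
#'
#' Draws, per sample, a Poisson number of mutation events. Each event
#' either comes from a planted hotspot (with probability
#' `hotspot_fraction`): a uniformly chosen cluster center plus rounded
#' Gaussian noise of SD `hotspot_width`, clamped into the enclosing region —
#' or from the uniform background over all target regions. Recurrence at a
#' base arises naturally when two draws land on the same position. The
#' ground truth (cluster centers and per-record assignments) is returned
#' alongside for recovery experiments.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [mutation_dataset()], gene labels from the
#'   enclosing region) and `truth` (list: `centers` data.frame of planted
#'   `chrom`, `pos`; `assignment` integer vector, 0 = background, else
#'   center row).
#' @export
simulate_mutations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  reg <- config$target_regions
  reg_len <- reg$end - reg$start + 1
  # hotspot centers: region chosen proportional to length, uniform inside,
  # kept a few widths clear of the region edge where possible
  margin <- pmin(ceiling(3 * config$hotspot_width), (reg_len - 1) %/% 2)
  center_region <- sample.int(nrow(reg), config$n_hotspots, replace = TRUE,
                              prob = reg_len)
  center_pos <- as.integer(reg$start[center_region] + margin[center_region] +
    floor(stats::runif(config$n_hotspots) *
            (reg_len[center_region] - 2 * margin[center_region])))
  centers <- data.frame(chrom = reg$chrom[center_region], pos = center_pos,
                        region = center_region, stringsAsFactors = FALSE)

  counts <- stats::rpois(config$n_samples, config$mutations_per_sample)
  n_total <- sum(counts)
  sample_id <- rep(sprintf("S%04d", seq_len(config$n_samples)), counts)

  from_hs <- stats::runif(n_total) < config$hotspot_fraction
  assignment <- integer(n_total)
  chrom <- character(n_total)
  pos <- integer(n_total)
  region_of <- integer(n_total)

  if (any(from_hs)) {
    k <- sample.int(config$n_hotspots, sum(from_hs), replace = TRUE)
    assignment[from_hs] <- k
    region_of[from_hs] <- centers$region[k]
    noise <- round(stats::rnorm(sum(from_hs), 0, config$hotspot_width))
    p <- centers$pos[k] + as.integer(noise)
    p <- pmax(reg$start[centers$region[k]], pmin(reg$end[centers$region[k]], p))
    chrom[from_hs] <- centers$chrom[k]
    pos[from_hs] <- p
  }
  if (any(!from_hs)) {
    rg <- sample.int(nrow(reg), sum(!from_hs), replace = TRUE, prob = reg_len)
    region_of[!from_hs] <- rg
    chrom[!from_hs] <- reg$chrom[rg]
    pos[!from_hs] <- as.integer(reg$start[rg] +
      floor(stats::runif(sum(!from_hs)) * reg_len[rg]))
  }
  dataset <- mutation_dataset(chrom, pos, sample = sample_id,
                              gene = reg$gene[region_of])
  # records are stored sorted by (chrom, pos); align the truth the same way
  ord <- order(chrom, pos)
  list(dataset = dataset,
       truth = list(centers = centers[, c("chrom", "pos")],
                    assignment = assignment[ord]))
}
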
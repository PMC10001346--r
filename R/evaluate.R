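#' Per-sample mutation capture efficacy of a panel
#'
#' Counts, for each sample, how many of its mutation events fall inside any
#' panel amplicon, and normalizes by the panel's total length: efficacy is
#' mutations captured per 10,000 bp sequenced. Records without a sample
#' label are pooled under `"<unlabeled>"`.
#'
#' @param panel a `mutation_panel`, or any data.frame of intervals with
#'   columns `chrom` and either `start`/`end` (1-based inclusive) or
#'   `start_1based`/`end_1based` (e.g. from [read_panel_csv()]).
#' @param dataset the [mutation_dataset()] to evaluate against (typically a
#'   held-out test set).
#' @param panel_bp panel length used for normalization; defaults to the sum
#'   of amplicon lengths.
#' @return an `efficacy_report`: list with `per_sample` (data.frame of
#'   sample, captured, total, efficacy per 10 kb), `panel_bp`, and `summary`
#'   (mean/median efficacy, overall capture fraction).
#' @export
capture_efficacy <- function(panel, dataset, panel_bp = NULL) {
  stopifnot(inherits(dataset, "mutation_dataset"))
  if (inherits(panel, "mutation_panel") || all(c("start", "end") %in% names(panel))) {
    iv <- data.frame(chrom = panel$chrom, start = panel$start, end = panel$end)
  } else if (all(c("start_1based", "end_1based") %in% names(panel))) {
    iv <- data.frame(chrom = panel$chrom, start = panel$start_1based,
                     end = panel$end_1based)
  } else {
    stop("`panel` must carry chrom plus start/end coordinates")
  }
  if (nrow(iv) == 0) stop("empty panel")
  if (is.null(panel_bp)) panel_bp <- sum(iv$end - iv$start + 1)

  rec <- dataset$records
  inside <- logical(nrow(rec))
  for (ch in unique(iv$chrom)) {
    ivc <- iv[iv$chrom == ch, , drop = FALSE]
    # merge possibly-overlapping amplicons into disjoint runs for lookup
    o <- order(ivc$start)
    st <- ivc$start[o]; en <- ivc$end[o]
    merged_s <- st[1]; merged_e <- en[1]
    if (length(st) > 1) {
      for (i in 2:length(st)) {
        if (st[i] <= merged_e[length(merged_e)] + 1) {
          merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], en[i])
        } else {
          merged_s <- c(merged_s, st[i]); merged_e <- c(merged_e, en[i])
        }
      }
    }
    r <- which(rec$chrom == ch)
    if (length(r)) {
      j <- findInterval(rec$pos[r], merged_s)
      inside[r] <- j >= 1 & rec$pos[r] <= merged_e[pmax(j, 1)]
    }
  }
  samp <- ifelse(is.na(rec$sample), "<unlabeled>", rec$sample)
  per_sample <- data.frame(
    sample = sort(unique(samp)),
    stringsAsFactors = FALSE
  )
  per_sample$captured <- as.integer(tapply(inside, samp, sum)[per_sample$sample])
  per_sample$total <- as.integer(table(samp)[per_sample$sample])
  per_sample$efficacy <- per_sample$captured / panel_bp * 1e4
  structure(list(
    per_sample = per_sample,
    panel_bp = panel_bp,
    summary = list(mean_efficacy = mean(per_sample$efficacy),
                   median_efficacy = stats::median(per_sample$efficacy),
                   capture_fraction = sum(per_sample$captured) / sum(per_sample$total))
  ), class = "efficacy_report")
}

#' @export
print.efficacy_report <- function(x, ...) {
  cat(sprintf("Capture efficacy over %d sample(s), panel %d bp:\n",
              nrow(x$per_sample), x$panel_bp))
  cat(sprintf("  captured %d / %d mutations (%.1f%%)\n",
              sum(x$per_sample$captured), sum(x$per_sample$total),
              100 * x$summary$capture_fraction))
  cat(sprintf("  efficacy per 10 kb: mean %.3f, median %.3f\n",
              x$summary$mean_efficacy, x$summary$median_efficacy))
  invisible(x)
}

#' Compare two efficacy reports
#'
#' Paired Wilcoxon signed-rank test on per-sample efficacies (matched by
#' sample id) plus the fold change of mean efficacies — the "mutations per
#' base pair sequenced" improvement of panel A over panel B.
#'
#' @param a,b `efficacy_report`s over the same samples.
#' @return list with `statistic`, `p_value`, `fold_change`
#'   (`mean(a) / mean(b)`), and `n` pairs compared.
#' @export
compare_efficacy <- function(a, b) {
  common <- intersect(a$per_sample$sample, b$per_sample$sample)
  if (!length(common)) stop("no samples in common")
  x <- a$per_sample$efficacy[match(common, a$per_sample$sample)]
  y <- b$per_sample$efficacy[match(common, b$per_sample$sample)]
  wt <- paired_wilcoxon(x, y)
  list(statistic = wt$statistic, p_value = wt$p_value,
       fold_change = mean(x) / mean(y), n = length(common))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (classic signed-rank); the exact null distribution is used for
#' n <= 25 without ties in the absolute differences, otherwise the normal
#' approximation with continuity correction.
#'
#' @param x,y numeric vectors of equal length (paired observations).
#' @return list with `statistic` (V, sum of positive-difference ranks),
#'   `p_value`, and `n` (non-zero pairs used).
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  if (!length(d)) {
    warning("all paired differences are zero")
    return(list(statistic = 0, p_value = 1, n = 0L))
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", mu = 0,
                       exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = length(d))
}

#' Reproducibility of the mutation distribution by repeated-split KS tests
#'
#' Randomly splits the dataset's mutation records 50/50 and compares the
#' two halves' position distributions on each chromosome with a two-sample
#' Kolmogorov-Smirnov test; repeats for `n_splits` random splits and
#' returns the mean p-value per chromosome. Low mean p-values indicate the
#' two halves disagree, i.e. the hotspot structure is not reproducible
#' within the dataset.
#'
#' @param dataset a [mutation_dataset()] with >= 2 records per chromosome.
#' @param n_splits number of random 50/50 splits (default 100).
#' @param seed integer seed; the procedure is reproducible given it.
#' @return data.frame with `chrom`, `mean_p`, `n_tests`, plus attribute
#'   `p_values` (the n_splits x chromosome matrix of individual p-values).
#' @export
ks_reproducibility <- function(dataset, n_splits = 100, seed = 1) {
  stopifnot(inherits(dataset, "mutation_dataset"))
  rec <- dataset$records
  chroms <- sort(unique(rec$chrom))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pmat <- matrix(NA_real_, n_splits, length(chroms),
                 dimnames = list(NULL, chroms))
  n <- nrow(rec)
  skipped <- character(0)
  for (s in seq_len(n_splits)) {
    half <- sample.int(n, n %/% 2)
    in_a <- logical(n); in_a[half] <- TRUE
    for (ch in chroms) {
      pa <- rec$pos[in_a & rec$chrom == ch]
      pb <- rec$pos[!in_a & rec$chrom == ch]
      if (length(pa) < 2 || length(pb) < 2) {
        skipped <- c(skipped, ch)
        next
      }
      pmat[s, ch] <- suppressWarnings(stats::ks.test(pa, pb)$p.value)
    }
  }
  if (length(unique(skipped))) {
    warning("too few records to test on some splits for chromosome(s): ",
            paste(unique(skipped), collapse = ", "))
  }
  out <- data.frame(chrom = chroms,
                    mean_p = colMeans(pmat, na.rm = TRUE),
                    n_tests = colSums(!is.na(pmat)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "p_values") <- pmat
  out
}

#' Optimal training sample size for panel design
#'
#' Estimates how many training samples are needed before a designed panel
#' significantly enriches mutation capture over sequencing the full original
#' target region. Samples are split into training and test sets; for each
#' candidate size `n`, `n_reps` times, `n` training samples are drawn, a
#' forward panel is designed from them, and the per-test-sample efficacy of
#' the designed panel is compared to the efficacy of the full target region
#' by a paired Wilcoxon signed-rank test. Mean p-values over replicates are
#' reported per `n`, along with the smallest `n` whose mean p falls below
#' `alpha`.
#'
#' @param dataset a [mutation_dataset()] with sample labels.
#' @param amplicon_length,panel_length passed to [design_panel()] (forward).
#' @param n_grid increasing training-set sizes to evaluate.
#' @param n_reps replicates per size (default 100).
#' @param seed integer seed.
#' @param train_frac fraction of samples assigned to training (default 0.8).
#' @param region_bp length of the full original target region in bp;
#'   defaults to the per-chromosome mutation footprint
#'   (max - min position + 1, summed).
#' @param alpha significance level for the reported optimal size
#'   (default 0.01).
#' @return list with `curve` (data.frame `n`, `mean_p`, `sd_p`) and
#'   `optimal_n` (smallest n with mean_p < alpha, or NA).
#' @export
sample_size_curve <- function(dataset, amplicon_length, panel_length,
                              n_grid, n_reps = 100, seed = 1,
                              train_frac = 0.8, region_bp = NULL,
                              alpha = 0.01) {
  stopifnot(inherits(dataset, "mutation_dataset"))
  if (!length(dataset$samples)) stop("dataset has no sample labels")
  if (is.null(region_bp)) {
    s <- dataset$sites
    region_bp <- sum(vapply(split(s$pos, s$chrom),
                            function(p) diff(range(p)) + 1, numeric(1)))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  samples <- dataset$samples
  n_train <- max(1L, round(train_frac * length(samples)))
  train_ids <- sample(samples, n_train)
  test_ids <- setdiff(samples, train_ids)
  if (!length(test_ids)) stop("no test samples left; lower `train_frac`")
  if (max(n_grid) > n_train) stop("`n_grid` exceeds the training-set size")

  rec <- dataset$records
  test_ds <- mutation_dataset(rec$chrom[rec$sample %in% test_ids],
                              rec$pos[rec$sample %in% test_ids],
                              rec$sample[rec$sample %in% test_ids],
                              rec$gene[rec$sample %in% test_ids])
  # efficacy of the full original region is fixed across replicates
  totals <- table(factor(test_ds$records$sample, levels = sort(test_ids)))
  ref <- as.numeric(totals) / region_bp * 1e4

  curve <- data.frame(n = sort(unique(n_grid)), mean_p = NA_real_, sd_p = NA_real_)
  for (gi in seq_len(nrow(curve))) {
    nn <- curve$n[gi]
    ps <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      tr <- sample(train_ids, nn)
      sub <- rec[rec$sample %in% tr, , drop = FALSE]
      train_ds <- mutation_dataset(sub$chrom, sub$pos, sub$sample, sub$gene)
      panel <- design_panel(train_ds, amplicon_length, panel_length,
                            method = "forward")
      eff <- capture_efficacy(panel, test_ds)
      x <- eff$per_sample$efficacy[match(sort(test_ids), eff$per_sample$sample)]
      ps[r] <- suppressWarnings(paired_wilcoxon(x, ref)$p_value)
    }
    curve$mean_p[gi] <- mean(ps)
    curve$sd_p[gi] <- stats::sd(ps)
  }
  below <- which(curve$mean_p < alpha)
  list(curve = curve,
       optimal_n = if (length(below)) curve$n[min(below)] else NA_integer_)
}
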
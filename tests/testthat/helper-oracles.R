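# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: clustering by pairwise merging, coverage optimization by
# recursive search over all 1-bp window placements, and the exact null
# distributions of the signed-rank and two-sample KS statistics by full
# enumeration.

# single-linkage clustering of positions with cut threshold L, by repeated
# pairwise merging (quadratic, order-free)
oracle_single_linkage <- function(pos, L) {
  pos <- sort(pos)
  groups <- as.list(pos)
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (i >= j) next
        d <- min(abs(outer(groups[[i]], groups[[j]], "-")))
        if (d < L) {
          groups[[i]] <- sort(c(groups[[i]], groups[[j]]))
          groups <- groups[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  groups[order(vapply(groups, min, numeric(1)))]
}

# best achievable total weight using exactly k windows of length L placed
# anywhere (1-bp resolution), by recursive search over left-edge placements.
# For point coverage an optimal solution places each window's start at a
# site, so the search space is the site list itself.
oracle_best_capture <- function(pos, w, L, k) {
  o <- order(pos)
  pos <- pos[o]; w <- w[o]
  best <- 0
  recurse <- function(start_idx, k_left, captured) {
    if (k_left == 0L || start_idx > length(pos)) {
      best <<- max(best, captured)
      return()
    }
    # bound: even covering everything that remains cannot beat best -> prune
    if (captured + sum(w[start_idx:length(pos)]) <= best) return()
    for (i in start_idx:length(pos)) {
      inside <- which(pos >= pos[i] & pos <= pos[i] + L - 1)
      recurse(max(inside) + 1L, k_left - 1L, captured + sum(w[inside]))
    }
    best <<- max(best, captured)
  }
  recurse(1L, as.integer(k), 0)
  best
}

# minimum number of L-bp windows to cover all positions, by increasing k
oracle_min_windows <- function(pos, L) {
  total <- length(pos)
  for (k in seq_len(length(pos))) {
    if (oracle_best_capture(pos, rep(1, total), L, k) == total) return(k)
  }
  stop("unreachable")
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign patterns,
# replicating the classic convention (doubling the smaller tail, capped at 1)
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean_v <- n * (n + 1) / 4
  p <- if (v_obs > mean_v) mean(v_all >= v_obs) else mean(v_all <= v_obs)
  min(1, 2 * p)
}

# exact two-sample KS p-value P(D >= d_obs) by enumerating all C(n+m, n)
# assignments of the pooled values (requires distinct values)
oracle_ks_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n <- length(x); m <- length(y)
  ks_stat <- function(a, b) {
    grid <- sort(c(a, b))
    max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
  }
  d_obs <- ks_stat(x, y)
  picks <- utils::combn(n + m, n)
  d_all <- apply(picks, 2, function(ii) ks_stat(pooled[ii], pooled[-ii]))
  mean(d_all >= d_obs - 1e-12)
}

# small helper: dataset from a position vector on one chromosome
chr1_dataset <- function(pos, sample = NULL, gene = NULL, chrom = "chr1") {
  mutation_dataset(rep(chrom, length(pos)), pos, sample = sample, gene = gene)
}

# random small clustered instance used by the equivalence and dominance
# checks: a few narrow clusters per chromosome, spans bounded by `max_span`
random_instance <- function(seed, L, n_clusters = 2, sites_per_cluster = 5,
                            max_span = 3 * L - 10, chroms = "chr1") {
  set.seed(seed)
  chrom <- character(0); pos <- integer(0)
  for (ch in chroms) {
    for (k in seq_len(n_clusters)) {
      center <- 1000 + (k - 1) * (max_span + 4 * L) + sample.int(200, 1)
      p <- center + sample.int(max_span, sites_per_cluster, replace = TRUE)
      chrom <- c(chrom, rep(ch, length(p)))
      pos <- c(pos, p)
    }
  }
  mutation_dataset(chrom, pos)
}
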
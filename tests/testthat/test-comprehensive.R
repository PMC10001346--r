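test_that("the capture threshold is the minimum retained forward count", {
  # four separated small hotspots with weights 9, 7, 4, 4 and one with 3
  ds <- chr1_dataset(rep(c(1000, 3000, 5000, 7000, 9000), c(9, 7, 4, 4, 3)))
  hs <- detect_hotspots(ds, 100)
  pool <- build_pool(hs, ds, 100)
  expect_equal(capture_threshold(pool, ds, panel_budget = 400), 4)
  # constant counts: threshold equals the common count
  ds2 <- chr1_dataset(rep(c(1000, 3000), c(5, 5)))
  pool2 <- build_pool(detect_hotspots(ds2, 100), ds2, 100)
  expect_equal(capture_threshold(pool2, ds2, Inf), 5)
})

test_that("sites whose only covers fall below the threshold drop out, with a warning", {
  # chr1: two dense small hotspots (weight 6 each) set the threshold at 6
  # under a 2-amplicon budget; chr2: a sparse large hotspot (three weight-1
  # sites spanning 181 bp, L = 100) whose candidates all count < 6
  ds <- mutation_dataset(c(rep("chr1", 12), rep("chr2", 3)),
                         c(rep(c(1000, 5000), each = 6), 200, 290, 380))
  hs <- detect_hotspots(ds, 100)
  pool <- build_pool(hs, ds, 100)
  expect_equal(capture_threshold(pool, ds, panel_budget = 200), 6)
  expect_warning(
    panel <- select_comprehensive(pool, ds, panel_budget = Inf, threshold = 6),
    "below the threshold"
  )
  covered <- unique(unlist(panel$covered))
  expect_false(any(ds$sites$chrom[covered] == "chr2"))
})

test_that("minimum-depth valley splitting cuts at the run center and conserves sites", {
  # hotspot with two dense flanks and a sparse middle: the depth profile's
  # minimum run sits between the flanks
  pos <- c(seq(1000, 1060, by = 20), 1200, seq(1340, 1400, by = 20))
  ds <- chr1_dataset(pos)
  L <- 150
  hs <- detect_hotspots(ds, L)
  expect_equal(nrow(hs), 1)
  pool <- build_pool(hs, ds, L)
  rows <- pool[pool$hotspot_id == hs$hotspot_id[1], ]
  bins <- split_hotspot(hs[1, ], rows, ds, n_max = 2, L = L)
  expect_gt(length(bins), 1)
  # bins tile the extent without overlap
  expect_equal(bins[[1]]$start, hs$start[1])
  expect_equal(bins[[length(bins)]]$end, hs$end[1])
  for (i in seq_len(length(bins) - 1)) {
    expect_equal(bins[[i + 1]]$start, bins[[i]]$end + 1)
  }
  # partition conservation and the n_max contract
  expect_equal(sort(unlist(lapply(bins, `[[`, "site_idx"))),
               sort(hs$site_idx[[1]]))
  for (b in bins) expect_lte(b$k_required, 2)
  # every member amplicon is assigned to exactly one bin
  members <- unlist(lapply(bins, `[[`, "member_rows"))
  expect_equal(sort(members), seq_len(nrow(rows)))
})

test_that("a constructed unique valley is cut at its center", {
  # two member windows [100,159] and [191,250] leave a unique 0-depth
  # valley over 160..190 (width 31); the first split must land at its
  # center, 175
  ds <- chr1_dataset(c(100, 155, 210, 250))
  L <- 60
  hs <- detect_hotspots(ds, L)
  expect_equal(nrow(hs), 1)
  pool <- build_pool(hs, ds, L)
  rows <- pool[pool$start %in% c(100, 191), ]
  expect_equal(nrow(rows), 2)
  bins <- split_hotspot(hs[1, ], rows, ds, n_max = 1, L = L)
  expect_length(bins, 2)
  expect_equal(bins[[1]]$end, 175)
  expect_equal(bins[[2]]$start, 176)
})

test_that("a hotspot within n_max amplicons stays a single bin", {
  ds <- chr1_dataset(c(100, 150, 260))
  hs <- detect_hotspots(ds, 120)
  pool <- build_pool(hs, ds, 120)
  rows <- pool[pool$hotspot_id == hs$hotspot_id[1], ]
  bins <- split_hotspot(hs[1, ], rows, ds, n_max = 3, L = 120)
  expect_length(bins, 1)
  expect_equal(bins[[1]]$start, hs$start[1])
  expect_equal(bins[[1]]$end, hs$end[1])
  expect_error(split_hotspot(hs[1, ], rows, ds, n_max = 0, L = 120), "n_max")
})

test_that("per-bin enumeration examines all combinations of the required size", {
  # 6 member amplicons, 2 required -> choose(6, 2) = 15 combinations; the
  # cap must reject a 14-combination limit and accept 15
  ds <- chr1_dataset(c(100, 160, 220, 280))
  L <- 100
  hs <- detect_hotspots(ds, L)
  pool <- build_pool(hs, ds, L)
  rows <- pool[seq_len(min(6, nrow(pool))), ]
  expect_error(mutpanel:::best_combination(rows, 2, ds$sites$weight, combo_cap = 14),
               "combination")
  sel <- mutpanel:::best_combination(rows, 2, ds$sites$weight, combo_cap = 15)
  expect_length(sel, 2)
})

test_that("comprehensive equals the sliding-window oracle on random small instances", {
  for (s in 1:30) {
    ds <- random_instance(100 + s, L = 40, n_clusters = 2,
                          sites_per_cluster = 4, max_span = 3 * 40 - 15)
    pool <- build_pool(detect_hotspots(ds, 40), ds, 40)
    comp <- select_comprehensive(pool, ds, panel_budget = Inf, n_max = 6)
    oracle <- exhaustive_select(sliding_pool(detect_hotspots(ds, 40), ds, 40),
                                ds, budget_amplicons = nrow(comp))
    expect_equal(attr(comp, "capture"), attr(oracle, "capture"))
  }
})

test_that("comprehensive capture is at least forward capture at equal budget", {
  for (s in 1:10) {
    sim <- simulate_mutations(sim_config(n_samples = 40, mutations_per_sample = 15,
                                         seed = 200 + s))
    ds <- sim$dataset
    fwd <- design_panel(ds, 125, 5000, method = "forward")
    comp <- design_panel(ds, 125, 5000, method = "comprehensive")
    expect_gte(attr(comp, "capture"), attr(fwd, "capture"))
  }
})

test_that("splitting recursion terminates on adversarially tight hotspots", {
  # evenly spaced sites with gaps just under L chain into one long hotspot
  pos <- seq(1000, 1000 + 39 * 29, by = 29)
  ds <- chr1_dataset(pos)
  hs <- detect_hotspots(ds, 30)
  expect_equal(nrow(hs), 1)
  pool <- build_pool(hs, ds, 30)
  rows <- pool[pool$hotspot_id == hs$hotspot_id[1], ]
  bins <- split_hotspot(hs[1, ], rows, ds, n_max = 2, L = 30)
  for (b in bins) expect_lte(b$k_required, 2)
  expect_equal(sort(unlist(lapply(bins, `[[`, "site_idx"))), hs$site_idx[[1]])
})
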
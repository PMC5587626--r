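test_that("membership_cutoff matches chi-square closed forms", {
  # df = 2: upper quantile is -2 ln(p)
  expect_equal(membership_cutoff(1e-4, 2), sqrt(-2 * log(1e-4)),
               tolerance = 1e-12)
  expect_equal(membership_cutoff(1e-4, 2), 4.2919, tolerance = 1e-4)
  expect_equal(membership_cutoff(1e-4, 3), 4.594, tolerance = 1e-3)
  # p -> 1 shrinks the cutoff towards 0
  expect_lt(membership_cutoff(1 - 1e-12, 2), 1e-5)
  expect_error(membership_cutoff(0, 2), "p_value")
  expect_error(membership_cutoff(1.2, 2), "p_value")
})

test_that("normalized_distance matches direct arithmetic", {
  expect_equal(normalized_distance(c(1, 2), c(1, 2), c(0.1, 0.1), 1:2), 0)
  expect_equal(normalized_distance(c(0.03, 9), c(0.00, 9), 0.01, 1), 3)
  set.seed(5)
  for (r in 1:20) {
    a <- rnorm(3); b <- rnorm(3); s <- runif(2, 0.1, 1); cd <- c(1, 3)
    expect_equal(normalized_distance(a, b, s, cd),
                 sqrt(sum(((a[cd] - b[cd]) / s)^2)))
  }
  expect_error(normalized_distance(1, 2, 0, 1), "positive")
})

test_that("zero-variance spin systems are recovered exactly, glycine singletons left out", {
  tb <- synth_assignments(60, seed = 71)
  pl <- simulate_peaklist(tb)     # ideal list: exact duplicates in H, N
  g <- group_peaks(pl, grouping_config(stds = c(1e-6, 1e-6)))
  rep <- score_grouping(g)
  expect_equal(rep$identified, rep$groupable_spin_systems)
  expect_equal(rep$overlapped, 0L)
  expect_equal(rep$split, 0L)
  # singleton systems (preceded by glycine) stay unclustered
  sizes <- table(pl$truth_group)
  expect_equal(length(g$unclustered), sum(sizes == 1))
  expect_equal(rep$pct_grouped_groupable, 100)
})

test_that("well-separated synthetic clusters are found; far-apart peaks stay unclustered", {
  centers <- rbind(c(0, 0), c(40, 40))      # >= 20 std apart
  x <- rbind(sweep(matrix(rnorm(6, 0, 0.5), 3, 2), 2, centers[1, ], "+"),
             sweep(matrix(rnorm(6, 0, 0.5), 3, 2), 2, centers[2, ], "+"))
  pl <- peak_list(x)
  g <- group_peaks(pl, grouping_config(stds = c(1, 1), p_value = 1e-4,
                                       min_points = 2))
  expect_equal(length(g$clusters), 2L)
  expect_setequal(g$clusters[[1]], 1:3)
  expect_setequal(g$clusters[[2]], 4:6)

  far <- peak_list(matrix(c(0, 0, 100, 100, 200, 200), 3, 2, byrow = TRUE))
  g2 <- group_peaks(far, grouping_config(stds = c(1, 1)))
  expect_equal(length(g2$clusters), 0L)
  expect_setequal(g2$unclustered, 1:3)
})

test_that("clusters match a brute-force DBSCAN oracle on random instances", {
  set.seed(77)
  for (r in 1:30) {
    n <- sample(5:30, 1)
    mp <- sample(2:3, 1)
    # mix of tight clumps and scattered points
    n_clumps <- sample(1:4, 1)
    centers <- matrix(runif(n_clumps * 2, 0, 10), n_clumps, 2)
    x <- t(vapply(seq_len(n), function(i) {
      c_id <- sample(n_clumps, 1)
      centers[c_id, ] + rnorm(2, 0, sample(c(0.05, 0.5), 1))
    }, numeric(2)))
    pl <- peak_list(x)
    stds <- c(0.3, 0.3)
    cfg <- grouping_config(stds = stds, p_value = 1e-3, min_points = mp)
    g <- group_peaks(pl, cfg)
    z <- sweep(x, 2, stds, "/")
    o <- oracle_dbscan(z, membership_cutoff(1e-3, 2), mp)

    got_cluster <- g$assignments$cluster
    # core points: the partition restricted to cores must match exactly
    core_ids <- which(o$core)
    if (length(core_ids) > 0) {
      expect_false(any(is.na(got_cluster[core_ids])))
      # same partition (up to relabeling)
      tab <- table(got_cluster[core_ids], o$core_cluster[core_ids])
      expect_true(all(rowSums(tab > 0) == 1), label = sprintf("rep %d", r))
      expect_true(all(colSums(tab > 0) == 1), label = sprintf("rep %d", r))
    }
    # non-core points: either unclustered with no border options, or in a
    # cluster owning one of their core neighbours
    for (p in which(!o$core)) {
      opts <- o$border_options[[p]]
      if (length(opts) == 0) {
        expect_true(is.na(got_cluster[p]))
      } else {
        expect_false(is.na(got_cluster[p]))
        owner_core <- which(o$core & got_cluster == got_cluster[p])
        expect_true(o$core_cluster[owner_core[1]] %in% opts)
      }
    }
    # with min_points = 2 there are no border points: exact partition match
    if (mp == 2) {
      expect_equal(unname(is.na(got_cluster)), unname(!o$core))
    }
  }
})

test_that("every peak is in exactly one cluster or unclustered", {
  set.seed(88)
  for (r in 1:10) {
    pl <- random_peaklist(sample(4:25, 1), k = 2, spread = 3)
    g <- group_peaks(pl, grouping_config(stds = c(0.5, 0.5), p_value = 1e-3))
    all_members <- unlist(g$clusters)
    expect_false(any(duplicated(all_members)))
    expect_setequal(c(all_members, g$unclustered), seq_len(n_peaks(pl)))
  }
})

test_that("clustering is invariant to rescaling a dimension and its std", {
  set.seed(99)
  pl <- random_peaklist(20, k = 2, spread = 2)
  stds <- c(0.3, 0.4)
  g1 <- group_peaks(pl, grouping_config(stds = stds))
  x2 <- shift_matrix(pl)
  x2[, 2] <- x2[, 2] * 7
  g2 <- group_peaks(peak_list(x2), grouping_config(stds = stds * c(1, 7)))
  expect_equal(g1$clusters, g2$clusters)
  expect_equal(g1$unclustered, g2$unclustered)
})

test_that("raising the p-value never reduces the number of clusters plus noise", {
  set.seed(101)
  for (r in 1:8) {
    pl <- random_peaklist(20, k = 2, spread = 2)
    cfgs <- lapply(c(1e-6, 1e-4, 1e-2, 0.3),
                   function(p) grouping_config(stds = c(0.3, 0.3), p_value = p))
    counts <- vapply(cfgs, function(cfg) {
      g <- group_peaks(pl, cfg)
      length(g$clusters) + length(g$unclustered)
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("grouping validates its inputs", {
  pl <- random_peaklist(5, k = 2)
  expect_error(grouping_config(stds = c(-1, 1)), "stds")
  expect_error(grouping_config(stds = c(1, 1), p_value = 2), "p_value")
  expect_error(group_peaks(pl, grouping_config(stds = 1)), "comparable")
  expect_error(group_peaks(peak_list(rbind(c(1, 2))),
                           grouping_config(stds = c(1, 1))), "min_points")
})
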
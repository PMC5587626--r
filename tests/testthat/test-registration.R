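test_that("distance_matrix matches hand values and a brute-force oracle", {
  pl <- peak_list(rbind(c(0, 0), c(3, 4), c(0, 0)))
  d <- distance_matrix(pl)
  expect_equal(d[1, 2], 5)        # 3-4-5 triangle
  expect_equal(d[1, 3], 0)        # identical peaks
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  set.seed(1)
  pl6 <- random_peaklist(6, k = 3)
  d6 <- distance_matrix(pl6)
  x <- shift_matrix(pl6)
  for (a in 1:6) for (b in 1:6) {
    expect_equal(d6[a, b], sqrt(sum((x[a, ] - x[b, ])^2)))
  }

  expect_error(distance_matrix(peak_list(rbind(c(1, 2)))), "at least 2")
})

test_that("chi_square_pair reproduces closed-form values", {
  # all four peaks identical in comparable dims -> stat 0, prob 1
  pl <- peak_list(rbind(c(1, 2), c(1, 2), c(1, 2), c(1, 2)))
  r <- chi_square_pair(pl, pl, 1, 2, 3, 4, stds = c(0.01, 0.01))
  expect_equal(r$stat, 0)
  expect_equal(r$prob, 1)

  # one dimension difference 0.04, std 0.01, factor 2 -> (0.04/0.02)^2 = 4
  pl1 <- peak_list(rbind(c(0.00, 5), c(0.04, 5), c(0, 5), c(0, 5)),
                   comparable_dims = 1)
  r1 <- chi_square_pair(pl1, pl1, 2, 3, 1, 4, stds = 0.01, std_factor = 2)
  expect_equal(r1$stat, 4, tolerance = 1e-12)

  # df = 2, stat 4 -> upper tail exp(-2)
  pl2 <- peak_list(rbind(c(0.00, 0.00), c(0.02, 0.02), c(0, 0), c(0, 0)))
  r2 <- chi_square_pair(pl2, pl2, 2, 3, 1, 4, stds = c(0.01, 0.01),
                        std_factor = 1)
  expect_equal(r2$stat, 8, tolerance = 1e-12)
  r3 <- chi_square_pair(pl2, pl2, 2, 3, 1, 4, stds = c(0.01, 0.01),
                        std_factor = sqrt(2))
  expect_equal(r3$stat, 4, tolerance = 1e-12)
  expect_equal(r3$prob, exp(-2), tolerance = 1e-12)

  expect_error(chi_square_pair(pl2, pl2, 1, 2, 3, 4, stds = c(0, 0.01)),
               "floor")
})

test_that("support sets equal exhaustive enumeration (pairwise and self)", {
  set.seed(42)
  cfg <- registration_config(initial_stds = c(0.05, 0.05))
  for (r in 1:20) {
    n <- sample(3:8, 1)
    input <- random_peaklist(n, k = 2, spread = 0.5)
    root <- if (r %% 2 == 0) input else random_peaklist(n, k = 2, spread = 0.5)
    mode <- if (identical(root, input)) "self" else "pairwise"
    stds <- c(0.05, 0.05)
    sm <- build_support_matrix(input, root, stds, cfg, mode = mode)
    oracle <- oracle_support_sets(shift_matrix(input), shift_matrix(root),
                                  stds, cfg$tolerance_units,
                                  self = mode == "self")
    got <- split(cbind(sm$m, sm$n), paste(sm$i, sm$j, sep = ","))
    expect_setequal(names(got), names(oracle))
    for (key in names(oracle)) {
      gm <- matrix(got[[key]], ncol = 2)
      om <- oracle[[key]]
      expect_equal(gm[order(gm[, 1], gm[, 2]), , drop = FALSE],
                   om[order(om[, 1], om[, 2]), , drop = FALSE],
                   ignore_attr = TRUE)
    }
  }
})

test_that("self-mode support never contains identical peak mappings", {
  set.seed(9)
  pl <- random_peaklist(7, k = 2, spread = 0.1)
  sm <- build_support_matrix(pl, pl, c(0.5, 0.5), registration_config(),
                             mode = "self")
  expect_false(any(sm$m == sm$n))
  expect_false(any(sm$i == sm$j))
  expect_false(any(sm$m == sm$i & sm$n == sm$j))
})

test_that("pairwise support of a list against itself contains the diagonal", {
  set.seed(10)
  pl <- random_peaklist(5, k = 2)
  sm <- build_support_matrix(pl, pl, c(0.01, 0.01), registration_config(),
                             mode = "pairwise")
  for (i in 1:5) {
    mem <- sm[sm$i == i & sm$j == i, ]
    diag_mem <- mem[mem$m == mem$n, ]
    expect_setequal(diag_mem$m, setdiff(1:5, i))
  }
})

test_that("robustness equals direct summation of the score definition", {
  # single-member support with zero differences scores Jaccard 1 * prob 1
  pl <- peak_list(rbind(c(0, 0), c(1, 1), c(0, 0) + 5, c(1, 1) + 5),
                  comparable_dims = 1:2)
  stds <- c(0.01, 0.01)
  cfg <- registration_config()
  sm <- build_support_matrix(pl, pl, stds, cfg, mode = "self")
  # mapping 1 -> 2 is supported exactly by (3, 4) and vice versa
  expect_equal(robustness(sm, 1, 2), 1, tolerance = 1e-9)

  set.seed(3)
  for (r in 1:10) {
    n <- sample(4:8, 1)
    pl <- random_peaklist(n, k = 2, spread = 0.3)
    stds <- c(0.08, 0.08)
    sm <- build_support_matrix(pl, pl, stds, cfg, mode = "self")
    oracle <- oracle_support_sets(shift_matrix(pl), shift_matrix(pl), stds,
                                  cfg$tolerance_units, self = TRUE)
    cells <- unique(sm[c("i", "j")])
    for (ri in seq_len(nrow(cells))) {
      expect_equal(robustness(sm, cells$i[ri], cells$j[ri]),
                   oracle_robustness(oracle, cells$i[ri], cells$j[ri],
                                     shift_matrix(pl), shift_matrix(pl),
                                     stds, cfg$std_factor),
                   tolerance = 1e-12)
    }
  }
})

test_that("the accelerated engine agrees with the reference engine", {
  set.seed(21)
  for (r in 1:12) {
    n <- sample(4:8, 1)
    tb <- synth_assignments(sample(8:14, 1), seed = 300 + r)
    pl <- simulate_peaklist(tb, noise = noise_model(c(0.01, 0.1, 0.1)),
                            seed = 400 + r)
    if (n_peaks(pl) < 4) next
    cfg <- registration_config(max_iterations = 4)
    rc <- register(pl, config = cfg, engine = "cpp")
    rr <- register(pl, config = cfg, engine = "r")
    expect_equal(rc$best_pair, rr$best_pair)
    expect_equal(rc$robustness_best, rr$robustness_best, tolerance = 1e-12)
    expect_equal(rc$stds, rr$stds, tolerance = 1e-12)
    expect_equal(rc$mapped_pairs, rr$mapped_pairs)
  }
})

test_that("pairwise registration recovers a known translation", {
  tb <- synth_assignments(50, seed = 31)
  input <- simulate_peaklist(tb, noise = noise_model(c(0.001, 0.01, 0.01)),
                             seed = 32)
  sm <- shift_matrix(input)
  sm[, 1] <- sm[, 1] + 0.05           # +0.05 ppm on dim 1 of every peak
  root <- peak_list(sm, label = input$label, truth_group = input$truth_group,
                    dim_labels = dim_labels(input),
                    comparable_dims = comparable_dims(input))
  reg <- register(input, root, mode = "pairwise")
  # offsets are input - root, so the shift appears as -0.05
  jitter_sem <- sqrt(2) * 0.001 / sqrt(reg$n_matched)
  expect_equal(reg$offsets[1], -0.05, tolerance = 3 * jitter_sem + 1e-6)
  expect_lt(abs(reg$offsets[2]), 3 * (sqrt(2) * 0.01 / sqrt(reg$n_matched)))
  expect_false(reg$failed)
})

test_that("pairwise registration is translation-equivariant", {
  tb <- synth_assignments(40, seed = 41)
  input <- simulate_peaklist(tb, noise = noise_model(c(0.002, 0.02, 0.02)),
                             seed = 42)
  root <- simulate_peaklist(tb, noise = noise_model(c(0.002, 0.02, 0.02)),
                            seed = 43)
  reg0 <- register(input, root, mode = "pairwise")
  delta <- c(0.3, -1.2)
  sm <- shift_matrix(input)
  sm[, 1] <- sm[, 1] + delta[1]
  sm[, 2] <- sm[, 2] + delta[2]
  shifted <- peak_list(sm, dim_labels = dim_labels(input),
                       comparable_dims = comparable_dims(input))
  reg1 <- register(shifted, root, mode = "pairwise")
  expect_equal(reg1$offsets, reg0$offsets + delta, tolerance = 1e-9)
  expect_equal(reg1$stds, reg0$stds, tolerance = 1e-9)
})

test_that("self-registration on a zero-variance list maps every spin system", {
  tb <- synth_assignments(40, seed = 51)
  pl <- simulate_peaklist(tb)            # ideal, zero variance
  reg <- register(pl)
  expect_equal(reg$offsets, rep(0, 2))
  expect_lt(max(reg$stds), 1e-5)         # floored near zero
  # every 2-peak spin system contributes its (unordered) within-system pair
  tg <- pl$truth_group
  sizes <- table(tg)
  expect_equal(reg$n_matched, sum(sizes == 2))
  pair_groups <- tg[reg$mapped_pairs$input]
  expect_equal(sort(pair_groups),
               sort(as.integer(names(sizes)[sizes == 2])))
  expect_equal(tg[reg$mapped_pairs$input], tg[reg$mapped_pairs$root])
})

test_that("self-registration stds are monotone in the injected noise", {
  sigmas <- c(0.001, 0.002, 0.004, 0.008, 0.016)
  reps <- 10
  mean_stds <- vapply(sigmas, function(s) {
    vals <- vapply(seq_len(reps), function(r) {
      tb <- synth_assignments(30, seed = 600 + r)
      pl <- simulate_peaklist(tb, noise = noise_model(c(s, 10 * s, 10 * s)),
                              seed = 700 + r)
      register(pl)$stds[1]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_equal(cor(mean_stds, sigmas, method = "spearman"), 1)
})

test_that("mapped pairs are one-to-one and the trace converges", {
  tb <- synth_assignments(60, seed = 61)
  pl <- simulate_peaklist(tb, noise = noise_model(c(0.004, 0.04, 0.04)),
                          seed = 62)
  reg <- register(pl)
  expect_false(any(duplicated(reg$mapped_pairs$input)))
  expect_false(any(duplicated(reg$mapped_pairs$root)))
  expect_true(reg$converged)
  tr <- reg$trace
  last2 <- lapply(sort(unique(tr$iteration), decreasing = TRUE)[1:2],
                  function(it) tr$std[tr$iteration == it])
  rel <- abs(last2[[1]] - last2[[2]]) / last2[[2]]
  expect_lt(max(rel), reg$config$convergence_tol)
})

test_that("registration failure is signalled, not thrown", {
  # two far-apart peaks: no support anywhere under tiny tolerances
  pl <- peak_list(rbind(c(0, 0), c(50, 50)))
  reg <- register(pl, config = registration_config(initial_stds = c(1e-4, 1e-4)))
  expect_true(reg$failed)
  expect_equal(reg$n_matched, 0L)
})
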
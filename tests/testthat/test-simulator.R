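# exact enumeration of the HN(CO)CACB generation rule, independent of the
# package code: residue i >= 2 and not proline yields 2 peaks, or 1 when the
# predecessor is glycine
count_peaks_by_hand <- function(seq_aa) {
  aa <- strsplit(seq_aa, "")[[1]]
  total <- 0L
  for (i in seq_along(aa)[-1]) {
    if (aa[i] == "P") next
    total <- total + if (aa[i - 1] == "G") 1L else 2L
  }
  total
}

test_that("synthetic shift tables are reproducible and structurally valid", {
  t1 <- synth_assignments(40, seed = 5)
  t2 <- synth_assignments(40, seed = 5)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  t3 <- synth_assignments(40, seed = 6)
  expect_false(identical(t3$shift, t1$shift))

  gly <- t1[t1$aa == "G", ]
  expect_false("CB" %in% gly$atom)
  pro <- t1[t1$aa == "P", ]
  expect_false("H" %in% pro$atom)
  expect_equal(sort(unique(t1$res_id)), 1:40)
})

test_that("a G-A-A peptide yields exactly the hand-enumerated peaks", {
  tb <- tibble::tibble(
    res_id = c(1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3),
    aa = c("G", "G", "G", "A", "A", "A", "A", "A", "A", "A", "A"),
    atom = c("H", "N", "CA", "H", "N", "CA", "CB", "H", "N", "CA", "CB"),
    shift = c(8.1, 109.2, 45.2, 8.3, 120.0, 53.0, 19.1, 8.5, 121.0, 52.8, 18.9))
  pl <- ideal_peaklist(tb)
  expect_equal(n_peaks(pl), 3L)
  expect_equal(length(unique(pl$truth_group)), 2L)
  # residue 2 contributes one peak (glycine predecessor: CA only)
  expect_equal(sum(pl$truth_group == 2), 1L)
  expect_equal(unname(shift_matrix(pl)[pl$truth_group == 2, ]),
               c(8.3, 120.0, 45.2))
  # residue 3 contributes CA and CB peaks of residue 2
  expect_equal(sort(shift_matrix(pl)[pl$truth_group == 3, 3]), c(19.1, 53.0))
})

test_that("generated peak counts follow the exact formula on random sequences", {
  set.seed(123)
  for (r in 1:40) {
    n <- sample(5:60, 1)
    tb <- synth_assignments(n, seed = 1000 + r)
    pl <- ideal_peaklist(tb)
    seq_aa <- sequence_of(tb)
    expect_equal(n_peaks(pl), count_peaks_by_hand(seq_aa))
    expect_equal(n_peaks(pl), expected_counts(seq_aa, method = "exact")$peaks)
    # groupable system count matches the 2-peak anchors
    sizes <- table(pl$truth_group)
    expect_equal(sum(sizes == 2),
                 expected_counts(seq_aa, method = "exact")$spin_systems)
  }
})

test_that("the conventional estimate deviates from the exact count only by the boundary term", {
  set.seed(124)
  for (r in 1:20) {
    tb <- synth_assignments(sample(10:80, 1), seed = 2000 + r)
    aa <- strsplit(sequence_of(tb), "")[[1]]
    L <- length(aa)
    exact <- expected_counts(sequence_of(tb), method = "exact")$peaks
    paper <- expected_counts(sequence_of(tb), method = "estimate")$peaks
    correction <- 1L - 2L * (aa[1] == "P") - (aa[L] == "G") -
      sum(aa[-L] == "G" & aa[-1] == "P")
    expect_equal(paper - exact, correction)
  }
})

test_that("zero-sigma noise is the identity and truth groups survive", {
  tb <- synth_assignments(25, seed = 9)
  pl <- ideal_peaklist(tb)
  out <- add_noise(pl, noise_model(c(0, 0, 0)), seed = 1)
  expect_equal(shift_matrix(out), shift_matrix(pl))
  expect_equal(out$truth_group, pl$truth_group)
  expect_equal(out$label, pl$label)
})

test_that("injected noise has the declared standard deviation", {
  big <- peak_list(matrix(0, 5000, 2))
  out <- add_noise(big, noise_model(c(0.01, 0.05)), seed = 33)
  d <- shift_matrix(out)
  expect_equal(sd(d[, 1]), 0.01, tolerance = 0.02)
  expect_equal(sd(d[, 2]), 0.05, tolerance = 0.02)
  expect_lt(abs(mean(d[, 1])), 3 * 0.01 / sqrt(5000))
})

test_that("the two-source mixture flags exactly the declared fraction", {
  pl <- peak_list(matrix(0, 100, 2))
  out <- add_noise(pl, noise_model(c(0.01, 0.01), fraction_high = 0.2,
                                   multiplier = 5), seed = 44)
  expect_equal(sum(attr(out, "high_variance")), 20L)

  # empirical std of the mixture matches sqrt(0.8 s^2 + 0.2 (5 s)^2)
  big <- peak_list(matrix(0, 4000, 2))
  nb <- add_noise(big, noise_model(c(0.01, 0.01), fraction_high = 0.2,
                                   multiplier = 5), seed = 45)
  target <- sqrt(0.8 * 0.01^2 + 0.2 * 0.05^2)
  expect_equal(sd(shift_matrix(nb)[, 1]), target, tolerance = 0.05)
  expect_equal(sd(shift_matrix(nb)[, 2]), target, tolerance = 0.05)
})

test_that("the N-dimension-only mixture leaves other dimensions at base sigma", {
  big <- peak_list(matrix(0, 4000, 3), dim_labels = c("H", "N", "CA/CB"))
  nb <- add_noise(big, noise_model(c(0.01, 0.1, 0.1), fraction_high = 0.2,
                                   multiplier = 5, dims = 2), seed = 46)
  d <- shift_matrix(nb)
  expect_equal(sd(d[, 1]), 0.01, tolerance = 0.02)
  expect_equal(sd(d[, 3]), 0.1, tolerance = 0.02)
  expect_equal(sd(d[, 2]), sqrt(0.8 * 0.1^2 + 0.2 * 0.5^2), tolerance = 0.05)
})

test_that("filters reject duplicate-peak and missing-CA/CB tables with reasons", {
  # anchors 2 and 3 share (H, N) and their predecessors share CA/CB:
  # the ideal list then holds exact duplicate peaks in all three dimensions
  dup <- tibble::tibble(
    res_id = rep(1:3, each = 4),
    aa = rep(c("A", "L", "L"), each = 4),
    atom = rep(c("H", "N", "CA", "CB"), 3),
    shift = c(8.0, 118, 53.0, 19.0,
              8.2, 119, 53.0, 19.0,
              8.2, 119, 53.0, 19.0))
  out <- filter_peaklists(list(dup))
  expect_equal(nrow(out$rejected), 1L)
  expect_equal(out$rejected$reason, "duplicate peaks")

  miss <- synth_assignments(10, seed = 7)
  # drop CB of a non-glycine contributing residue
  victim <- with(as.data.frame(miss), min(res_id[aa != "G" & aa != "P" &
                                                 res_id < 10]))
  miss2 <- miss[!(miss$res_id == victim & miss$atom == "CB"), ]
  attr(miss2, "protein_id") <- "missing-case"
  out2 <- filter_peaklists(list(miss2))
  expect_equal(out2$rejected$reason, "missing CA/CB")

  clean <- synth_assignments(30, seed = 8)
  out3 <- filter_peaklists(list(clean))
  expect_equal(length(out3$kept), 1L)
  expect_equal(nrow(out3$rejected), 0L)
})

test_that("most synthetic tables pass the filters", {
  tables <- lapply(1:40, function(i) synth_assignments(60, seed = 3000 + i,
                                                       protein_id = paste0("p", i)))
  out <- filter_peaklists(tables)
  expect_gte(length(out$kept), 36)   # >= 90%
})

test_that("run_grid writes one file per protein and step plus a manifest", {
  outdir <- withr::local_tempdir()
  tables <- lapply(1:2, function(i) synth_assignments(15, seed = 500 + i,
                                                      protein_id = paste0("p", i)))
  grid <- simulation_grid(steps = 3)
  man <- run_grid(tables, grid, outdir, seed = 11)
  expect_equal(nrow(man), 6L)
  expect_true(all(file.exists(file.path(outdir, man$file))))
  expect_true(file.exists(file.path(outdir, "manifest.csv")))
  expect_false(any(duplicated(man$seed)))

  # deterministic: re-running reproduces identical files
  outdir2 <- withr::local_tempdir()
  man2 <- run_grid(tables, grid, outdir2, seed = 11)
  for (f in man$file) {
    expect_equal(readLines(file.path(outdir, f)),
                 readLines(file.path(outdir2, f)))
  }

  # noise level actually applied: a re-read list differs from ideal
  pl <- read_peaklist(file.path(outdir, man$file[1]), format = "json")
  expect_false(all(is.na(pl$truth_group)))
})

test_that("self-registration recovers the injected sigma from simulated lists", {
  sigma <- c(0.004, 0.04, 0.04)
  est <- vapply(1:6, function(r) {
    tb <- synth_assignments(55, seed = 800 + r)
    pl <- simulate_peaklist(tb, noise = noise_model(sigma), seed = 900 + r)
    register(pl)$sigma
  }, numeric(2))
  expect_equal(mean(est[1, ]), sigma[1], tolerance = 0.15)
  expect_equal(mean(est[2, ]), sigma[2], tolerance = 0.15)
})
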
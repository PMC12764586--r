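test_that("MoC worked examples and symmetry", {
  P <- tad_set(c(0, 10, 25), c(10, 20, 40), "chr1", 1e4)
  expect_equal(moc(P, P), 1)

  A <- tad_set(0, 10, "chr1", 1e4)       # [0, 100 Kb)
  B <- tad_set(c(0, 5), c(5, 10), "chr1", 1e4)
  expect_equal(moc(A, B), 0)
  expect_equal(moc(B, A), 0)

  single <- tad_set(0, 10, "chr1", 1e4)
  expect_equal(moc(single, single), 1)  # both-single convention

  expect_error(moc(P[0, ], P), "empty")
})

test_that("MoC stays within [0, 1] and is symmetric on fuzzed partitions", {
  for (seed in 1:8) {
    P <- random_partition(300, seed = seed)
    Q <- random_partition(300, seed = seed + 50)
    m1 <- moc(P, Q)
    expect_gte(m1, 0)
    expect_lte(m1, 1)
    expect_equal(m1, moc(Q, P), tolerance = 1e-12)
    expect_equal(moc(P, P), 1, tolerance = 1e-12)
  }
})

test_that("block-constant matrix scored with the true partition gives r2 = 1", {
  vals <- block_matrix(60, list(c(1, 15), c(16, 30), c(31, 45)),
                       intra = c(10, 8, 6), background = 1)
  cm <- contact_matrix(vals, "chr1", 1e4)
  truth <- tad_set(c(0, 15, 30), c(15, 30, 45), "chr1", 1e4)
  prof <- tad_adj_r2(cm, truth)
  defined <- !is.na(prof$r2)
  expect_true(any(defined))
  expect_true(all(abs(prof$r2[defined] - 1) < 1e-12))
})

test_that("an empty domain set yields r2 = 0 wherever variance exists", {
  cm <- contact_matrix(random_sym_matrix(40, seed = 3), "chr1", 1e4)
  empty <- tad_set(integer(0), integer(0), "chr1", 1e4)
  prof <- tad_adj_r2(cm, empty)
  defined <- !is.na(prof$r2)
  expect_true(all(abs(prof$r2[defined]) < 1e-12))
})

test_that("a globally constant matrix has undefined r2", {
  cm <- contact_matrix(matrix(2, 30, 30), "chr1", 1e4)
  tads <- tad_set(c(0, 15), c(12, 28), "chr1", 1e4)
  prof <- tad_adj_r2(cm, tads)
  expect_true(all(is.na(prof$r2)))
  expect_error(tad_adj_r2(cm, tads, d_max = 100), "d_max")
})

test_that("adjusted R2 matches a naive per-pair oracle", {
  cm <- contact_matrix(random_sym_matrix(40, seed = 17), "chr1", 1e4)
  tads <- tad_set(c(2, 12, 30), c(10, 25, 38), "chr1", 1e4)
  prof <- tad_adj_r2(cm, tads, d_max = 39e4)
  for (kk in seq_len(nrow(prof))) {
    d <- prof$d[kk] / 1e4
    xs <- c(); gs <- c()
    for (i in 0:(40 - d - 1)) {
      j <- i + d
      g <- 0
      for (t in seq_len(nrow(tads))) {
        if (i >= tads$start_bin[t] && j < tads$end_bin[t]) g <- t
      }
      xs <- c(xs, cm$values[i + 1, j + 1]); gs <- c(gs, g)
    }
    nt <- sum(tads$end_bp - tads$start_bp >= prof$d[kk])
    N <- length(xs)
    ss_tot <- sum((xs - mean(xs))^2)
    if (N - nt - 1 <= 0 || ss_tot == 0) {
      expect_true(is.na(prof$r2[kk]))
    } else {
      xhat <- ave(xs, gs)
      expected <- 1 - (sum((xs - xhat)^2) / (N - nt - 1)) / (ss_tot / (N - 1))
      expect_equal(prof$r2[kk], expected, tolerance = 1e-12)
      expect_lte(prof$r2[kk], 1)
    }
  }
})

test_that("boundary profiles: constant track, centred peak, truncation", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chrP\t0\t10000000\t2.5", f)
  track <- read_bedgraph(f)
  prof <- boundary_signal_profile(c(1e6, 2e6), track, nbins = 5)
  expect_equal(prof, rep(2.5, 5))

  # narrow unit peak exactly at each boundary, zero background
  b <- c(1e6, 3e6)
  writeLines(sprintf("chrP\t%d\t%d\t10", b - 5000, b + 5000), f)
  track2 <- read_bedgraph(f)
  prof2 <- boundary_signal_profile(b, track2, flank = 250000, nbins = 5)
  expect_equal(which.max(prof2), 3L)  # centre bin

  # boundary near the chromosome start: off-chromosome bins excluded,
  # in-chromosome part still averaged
  writeLines("chrP\t0\t10000000\t4", f)
  track3 <- read_bedgraph(f)
  prof3 <- boundary_signal_profile(100000, track3, flank = 250000, nbins = 5)
  expect_equal(prof3[3:5], rep(4, 3))
  expect_equal(prof3[1], NA_real_)  # offset bin fully off-chromosome
  expect_equal(prof3[2], 4)         # half-truncated bin: covered part only

  expect_error(boundary_signal_profile(numeric(0), track), "boundaries")
  expect_error(boundary_signal_profile(1e6, track, nbins = 4), "odd")
})

test_that("recovery rate thresholds on bp Jaccard and is monotone", {
  ref <- tad_set(c(0, 50), c(40, 90), "chr1", 1e4)
  expect_equal(recovery_rate(ref, ref), 1)

  far <- tad_set(c(200), c(240), "chr1", 1e4)
  expect_equal(recovery_rate(far, ref), 0)

  ref1 <- tad_set(0, 40, "chr1", 1e4)        # [0, 400 Kb)
  det1 <- tad_set(0, 20, "chr1", 1e4)        # [0, 200 Kb): Jaccard 0.5
  expect_equal(recovery_rate(det1, ref1, jaccard_min = 0.5), 1)
  expect_equal(recovery_rate(det1, ref1, jaccard_min = 0.51), 0)

  for (seed in 1:4) {
    det <- random_partition(200, seed = seed + 30)
    ref2 <- random_partition(200, seed = seed + 70)
    rates <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                    function(j) recovery_rate(det, ref2, j), numeric(1))
    expect_true(all(diff(rates) <= 1e-12))
  }
  expect_error(recovery_rate(det1, ref1[0, ]), "empty")
})

test_that("split and merge events are classified and dual", {
  A <- tad_set(0, 100, "chr1", 1e4)                    # [0, 1 Mb)
  B <- tad_set(c(0, 50), c(50, 100), "chr1", 1e4)
  rep1 <- classify_split_merge(A, B)
  expect_equal(nrow(rep1$splits), 1L)
  expect_equal(rep1$splits$n_parts, 2L)
  expect_equal(nrow(rep1$merges), 0L)

  rep2 <- classify_split_merge(B, A)
  expect_equal(nrow(rep2$merges), 1L)
  expect_equal(nrow(rep2$splits), 0L)

  same <- classify_split_merge(A, A)
  expect_equal(nrow(same$splits) + nrow(same$merges), 0L)

  for (seed in 1:4) {
    X <- random_partition(300, seed = seed + 90)
    Y <- random_partition(300, seed = seed + 95)
    ab <- classify_split_merge(X, Y)
    ba <- classify_split_merge(Y, X)
    expect_equal(ab$splits, ba$merges)
    expect_equal(ab$merges, ba$splits)
  }
})
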
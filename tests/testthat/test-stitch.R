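test_that("TAD quality reproduces the 4-bin hand example", {
  vals <- matrix(1, 4, 4)
  vals[1, 2] <- vals[2, 1] <- 10
  vals[3, 4] <- vals[4, 3] <- 8
  cm <- contact_matrix(vals, "chr1", 10000)
  tads <- tad_set(c(0, 2), c(2, 4), "chr1", 10000)
  expect_equal(tad_quality(cm, tads, c(0, 4)), 9 - 1)

  expect_equal(tad_quality(cm, NULL, c(0, 4)), 0)
  expect_equal(tad_quality(cm, tads[0, ], c(0, 4)), 0)

  cm_const <- contact_matrix(matrix(3.5, 5, 5), "chr1", 10000)
  one <- tad_set(0, 5, "chr1", 10000)
  expect_equal(tad_quality(cm_const, one, c(0, 5)), 3.5)

  expect_error(tad_quality(cm, tads, c(2, 3)), "at least 2 bins")
})

test_that("TAD quality matches a brute-force all-pairs oracle", {
  for (seed in 1:4) {
    set.seed(seed + 200)
    nb <- sample(8:30, 1)
    cm <- contact_matrix(random_sym_matrix(nb, seed = seed + 300), "chr1", 1e4)
    part <- random_partition(nb, seed = seed + 400)
    got <- tad_quality(cm, part, c(0, nb))
    grp <- integer(nb)
    for (k in seq_len(nrow(part))) {
      grp[(part$start_bin[k] + 1):part$end_bin[k]] <- k
    }
    expect_equal(got, tq_oracle(cm$values, grp), tolerance = 1e-12)
  }
})

test_that("Q resolution keeps the side whose TADs match the contact blocks", {
  # block structure aligned with prev's single Q TAD; curr's two TADs are
  # misaligned and mix intra/inter pairs
  vals <- block_matrix(20, list(c(5, 12)), intra = 10, background = 1)
  cm <- contact_matrix(vals, "chr1", 1e4)
  prev <- tad_set(4, 12, "chr1", 1e4, source_window = 0)
  curr <- tad_set(c(2, 8), c(8, 14), "chr1", 1e4, source_window = 1)
  res <- resolve_q_region(cm, prev, curr, q_range = c(2, 14))
  expect_equal(res$record$winner, "prev")
  expect_true(res$record$tq_prev > res$record$tq_curr)
  expect_true(all(res$prev_kept))
  expect_false(any(res$curr_kept))
})

test_that("ties go to the current window and empty sides concede", {
  cm <- contact_matrix(random_sym_matrix(20, seed = 7), "chr1", 1e4)
  prev <- tad_set(2, 8, "chr1", 1e4, source_window = 0)
  curr <- tad_set(2, 8, "chr1", 1e4, source_window = 1)
  res <- resolve_q_region(cm, prev, curr, c(0, 10))
  expect_equal(res$record$winner, "curr")
  expect_false(any(res$prev_kept))
  expect_true(all(res$curr_kept))

  res2 <- resolve_q_region(cm, prev[0, ], curr, c(0, 10))
  expect_equal(res2$record$winner, "curr")
  expect_true(all(res2$curr_kept))
})

test_that("single-window assembly is the identity on sorted candidates", {
  cm <- contact_matrix(random_sym_matrix(50, seed = 8), "chr1", 1e4)
  plan <- plan_partition(50, 1e4)
  cands <- tad_set(c(30, 2), c(40, 12), "chr1", 1e4, source_window = 0)
  out <- assemble_genome_tads(cm, list(cands), plan)
  expect_equal(out$start_bin, c(2L, 30L))
  expect_equal(out$end_bin, c(12L, 40L))
})

test_that("identical Q-region candidates survive as exactly one copy", {
  cm <- contact_matrix(random_sym_matrix(100, seed = 9), "chr1", 1e5)
  plan <- plan_partition(100, 1e5, t = 50, q_bp = 2e6)  # q_bins = 20
  w2 <- plan$windows[2, ]
  shared <- c(w2$ext_start_bin + 2, w2$ext_start_bin + 12)
  prev_c <- tad_set(c(5, shared[1]), c(15, shared[2]), "chr1", 1e5,
                    source_window = 0)
  curr_c <- tad_set(c(shared[1], 70), c(shared[2], 90), "chr1", 1e5,
                    source_window = 1)
  out <- assemble_genome_tads(cm, list(prev_c, curr_c), plan)
  dup <- sum(out$start_bin == shared[1] & out$end_bin == shared[2])
  expect_equal(dup, 1L)
  expect_equal(out$source_window[out$start_bin == shared[1]], 1L)  # tie: curr
})

test_that("assembly output is always sorted and non-overlapping (fuzzed)", {
  for (seed in 1:5) {
    set.seed(seed + 500)
    n <- 200
    cm <- contact_matrix(random_sym_matrix(n, seed = seed + 600), "chr1", 1e4)
    plan <- plan_partition(n, 1e4, t = 70, q_bp = 2e5)
    cands <- lapply(seq_len(plan$ns), function(i) {
      w <- plan$windows[i, ]
      lo <- w$ext_start_bin
      hi <- w$core_end_bin
      k <- sample(0:4, 1)
      starts <- integer(0); ends <- integer(0); pos <- lo
      for (s in seq_len(k)) {
        pos <- pos + sample(0:10, 1)
        len <- sample(1:30, 1)
        if (pos + len > hi) break
        starts <- c(starts, pos); ends <- c(ends, pos + len)
        pos <- pos + len
      }
      tad_set(starts, ends, "chr1", 1e4, source_window = w$index)
    })
    out <- assemble_genome_tads(cm, cands, plan)
    if (nrow(out) > 1) {
      expect_true(all(diff(out$start_bp) > 0))
      expect_true(all(out$start_bp[-1] >= out$end_bp[-nrow(out)]))
    }
  }
})

test_that("empty Q regions concatenate core candidates unchanged", {
  cm <- contact_matrix(random_sym_matrix(90, seed = 11), "chr1", 1e5)
  plan <- plan_partition(90, 1e5, t = 30, q_bp = 1e6)
  cands <- list(
    tad_set(5, 15, "chr1", 1e5, source_window = 0),
    tad_set(40, 50, "chr1", 1e5, source_window = 1),
    tad_set(70, 80, "chr1", 1e5, source_window = 2))
  out <- assemble_genome_tads(cm, cands, plan)
  expect_equal(out$start_bin, c(5L, 40L, 70L))
})
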
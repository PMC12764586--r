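# Shared fixtures, built in code at test time.

# symmetric random contact-like matrix
random_sym_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, 0, 10), n, n)
  m <- (m + t(m)) / 2
  m
}

# block matrix: given bin ranges (1-based start/end inclusive) and intra
# values, background elsewhere
block_matrix <- function(n, blocks, intra, background = 1) {
  m <- matrix(background, n, n)
  for (k in seq_along(blocks)) {
    idx <- blocks[[k]][1]:blocks[[k]][2]
    m[idx, idx] <- intra[k]
  }
  m
}

# random connected weighted graph adjacency (all degrees > 0)
random_graph_adj <- function(m, seed) {
  set.seed(seed)
  A <- matrix(runif(m * m, 0.1, 2), m, m)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# brute-force TQ: explicit loops over bin pairs in a region
tq_oracle <- function(vals, grp) {
  nb <- length(grp)
  intra <- c(); inter <- c()
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):nb) {
      if (grp[i] > 0 && grp[i] == grp[j]) intra <- c(intra, vals[i, j])
      if (grp[i] > 0 && grp[j] > 0 && grp[i] != grp[j]) inter <- c(inter, vals[i, j])
    }
  }
  ifelse(length(intra), mean(intra), 0) - ifelse(length(inter), mean(inter), 0)
}

# random non-overlapping partition of [0, n_bins) for fuzzing
random_partition <- function(n_bins, resolution = 1e4, seed) {
  set.seed(seed)
  cuts <- sort(sample(1:(n_bins - 1), sample(2:8, 1)))
  bounds <- c(0, cuts, n_bins)
  keep <- runif(length(bounds) - 1) < 0.8
  keep[1] <- TRUE
  tad_set(bounds[-length(bounds)][keep], bounds[-1][keep],
          chrom = "chrT", resolution = resolution)
}
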
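#' Simulate a Hi-C contact matrix with known ground-truth domains
#'
#' Generates the canonical block-plus-decay-plus-noise Hi-C phenotype:
#' domains of random size tile the chromosome (with optional inter-domain
#' gaps), the expected contact is `mu_ij = beta * exp(-|i - j| / L)`,
#' boosted by a factor `gamma` when both bins share a ground-truth domain,
#' and observed counts are `Poisson(mu_ij) + nu * |N(0, 1)|`, symmetrized.
#' Deterministic for a fixed seed.
#'
#' @param n_bins chromosome length in bins.
#' @param resolution bin width in bp (default 10 Kb).
#' @param tad_kb_range domain size bounds in Kb (default 250–1750, the
#'   typical mammalian range).
#' @param gap_prob probability of an inter-domain gap after each domain
#'   (default 0.1); gap lengths are 1–5 bins.
#' @param L distance-decay scale in bins (default 60, i.e. 600 Kb at 10 Kb).
#' @param gamma intra-domain contact boost, `>= 1` (default 4).
#' @param beta background contact scale at distance 0 (default 10).
#' @param nu additive noise level, `>= 0` (default 1); the noise term is a
#'   folded normal so counts stay non-negative.
#' @param seed RNG seed (required).
#' @return a `SyntheticTruth`: list with `cm` (a [contact_matrix()]),
#'   `truth` (a [tad_set()]) and `params`.
#' @export
simulate_hic <- function(n_bins, resolution = 10000L,
                         tad_kb_range = c(250, 1750), gap_prob = 0.1,
                         L = 60, gamma = 4, beta = 10, nu = 1, seed) {
  if (missing(seed)) stop("seed is required for reproducibility")
  stopifnot(gamma >= 1, beta > 0, nu >= 0, L > 0, n_bins >= 2,
            gap_prob >= 0, gap_prob <= 1)
  min_bins <- max(1L, floor(tad_kb_range[1] * 1000 / resolution))
  max_bins <- floor(tad_kb_range[2] * 1000 / resolution)
  if (min_bins > max_bins || min_bins > n_bins) {
    stop("infeasible domain size range for n_bins = ", n_bins)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  # tile [0, n_bins) with domains and occasional gaps
  starts <- integer(0); ends <- integer(0)
  pos <- 0L
  while (pos + min_bins <= n_bins) {
    size <- sample(min_bins:max_bins, 1L)
    size <- min(size, n_bins - pos)
    if (size < min_bins) break
    starts <- c(starts, pos); ends <- c(ends, pos + size)
    pos <- pos + size
    if (stats::runif(1) < gap_prob) pos <- pos + sample(1:5, 1L)
  }
  if (length(starts) == 0L) stop("no domain fits in n_bins = ", n_bins)
  truth <- tad_set(starts, ends, chrom = "chrS", resolution = resolution)
  dom <- integer(n_bins)
  for (k in seq_along(starts)) dom[(starts[k] + 1L):ends[k]] <- k
  idx <- seq_len(n_bins)
  dist_mat <- abs(outer(idx, idx, "-"))
  same <- outer(dom, dom, "==") & dom > 0
  mu <- beta * exp(-dist_mat / L) * ifelse(same, gamma, 1)
  # draw upper triangle (incl. diagonal) then mirror for exact symmetry
  up <- which(upper.tri(mu, diag = TRUE))
  vals <- matrix(0, n_bins, n_bins)
  vals[up] <- stats::rpois(length(up), mu[up]) + nu * abs(stats::rnorm(length(up)))
  vals <- vals + t(vals) - diag(diag(vals))
  cm <- contact_matrix(vals, chrom = "chrS", resolution = resolution)
  structure(list(cm = cm, truth = truth,
                 params = list(n_bins = n_bins, resolution = resolution,
                               tad_kb_range = tad_kb_range,
                               gap_prob = gap_prob, L = L, gamma = gamma,
                               beta = beta, nu = nu, seed = seed)),
            class = "SyntheticTruth")
}

#' Structurally perturb a domain partition
#'
#' Produces fixtures for partition-comparison statistics: `"split"` cuts one
#' random domain (of >= 2 bins) in two, `"merge"` fuses one random adjacent
#' pair, `"shift"` moves every internal boundary one bin right (truncating
#' at domain ends).
#'
#' @param truth a [tad_set()] to perturb.
#' @param op `"split"`, `"merge"` or `"shift"`.
#' @param seed RNG seed.
#' @return a valid [tad_set()].
#' @export
perturb_partition <- function(truth, op = c("split", "merge", "shift"), seed) {
  op <- match.arg(op)
  if (missing(seed)) stop("seed is required")
  if (nrow(truth) == 0) stop("empty partition")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  s <- truth$start_bin; e <- truth$end_bin
  res <- attr(truth, "resolution")
  chrom <- attr(truth, "chrom")
  if (op == "split") {
    cand <- which(e - s >= 2L)
    if (length(cand) == 0L) stop("no domain large enough to split")
    k <- cand[sample.int(length(cand), 1L)]
    cut <- s[k] + sample.int(e[k] - s[k] - 1L, 1L)
    s <- c(s[-k], s[k], cut); e <- c(e[-k], cut, e[k])
  } else if (op == "merge") {
    if (nrow(truth) < 2L) stop("cannot merge a single-domain partition")
    k <- sample.int(nrow(truth) - 1L, 1L)
    s <- c(s[-c(k, k + 1L)], s[k]); e <- c(e[-c(k, k + 1L)], e[k + 1L])
  } else {  # shift: move every internal boundary one bin right
    n <- length(s)
    if (n == 1L && e[1] - s[1] < 2L) stop("domain too small to shift")
    news <- s; newe <- e
    if (n > 1L) {
      news[-1L] <- s[-1L] + 1L
      newe[-n] <- e[-n] + 1L
      if (e[n] - s[n] < 2L) stop("last domain too small to shift")
    } else {
      news[1L] <- s[1L] + 1L
    }
    s <- news; e <- newe
  }
  tad_set(s, e, chrom = chrom, resolution = res)
}
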
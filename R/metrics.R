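#' Measure of Concordance between two domain partitions
#'
#' `MoC = (sum_ij F_ij^2 / (|P_i| |Q_j|) - 1) / (sqrt(N_P N_Q) - 1)` where
#' `F_ij` is the bp overlap of domains `P_i` and `Q_j` and `|.|` is bp
#' length; defined as 1 when both sets hold a single domain. Ranges from 0
#' (fully discordant) to 1 (identical partitions); symmetric in its
#' arguments.
#'
#' @param P,Q TadSet-shaped data.frames on the same chromosome.
#' @return MoC in `[0, 1]`.
#' @export
moc <- function(P, Q) {
  if (is.null(P) || is.null(Q) || nrow(P) == 0 || nrow(Q) == 0) {
    stop("MoC is undefined for an empty domain set")
  }
  np <- nrow(P); nq <- nrow(Q)
  if (np == 1L && nq == 1L) return(1)
  acc <- 0
  for (i in seq_len(np)) {
    ov <- pmax(0, pmin(P$end_bp[i], Q$end_bp) - pmax(P$start_bp[i], Q$start_bp))
    acc <- acc + sum(ov^2 / ((P$end_bp[i] - P$start_bp[i]) * (Q$end_bp - Q$start_bp)))
  }
  # incomplete partitions (domain sets with gaps) can push the raw statistic
  # slightly below zero; 0 already means fully discordant, so floor there
  max(0, (acc - 1) / (sqrt(np * nq) - 1))
}

#' Adjusted R-squared of contact variance explained by a domain partition
#'
#' At each genomic distance `d`, the contacts `X_i = cm[i, i + d]` are
#' grouped by the domain containing *both* endpoints (pairs straddling a
#' boundary or outside every domain form one background group), and the
#' partition's explanatory power is the adjusted coefficient of
#' determination `1 - [SSres / (N - N_t - 1)] / [SStot / (N - 1)]`, with
#' `N_t` the number of domains at least `d` long (in bp) — the adjustment
#' penalizes partitions that buy fit with many domains. Values near 1 mean
#' the partition explains the contact variance at that distance.
#'
#' @param cm a [contact_matrix()].
#' @param tads non-overlapping TadSet-shaped data.frame.
#' @param d_max largest genomic distance in bp (default 1.5 Mb).
#' @return an `AdjR2Profile` data.frame with columns `d` (bp), `N`, `N_t`,
#'   `r2` (`NA` where the statistic is undefined: zero total variance or
#'   `N - N_t - 1 <= 0`).
#' @export
tad_adj_r2 <- function(cm, tads, d_max = 1.5e6) {
  if (d_max < cm$resolution) stop("d_max below one bin")
  n <- cm$n_bins
  d_bins <- seq_len(min(floor(d_max / cm$resolution), n - 1L))
  # per-bin domain id, 0 = background
  dom <- integer(n)
  if (!is.null(tads) && nrow(tads) > 0) {
    for (k in seq_len(nrow(tads))) {
      dom[(tads$start_bin[k] + 1L):tads$end_bin[k]] <- k
    }
  }
  span_bp <- if (!is.null(tads)) tads$end_bp - tads$start_bp else numeric(0)
  out <- data.frame(d = d_bins * cm$resolution, N = NA_integer_,
                    N_t = NA_integer_, r2 = NA_real_)
  for (kk in seq_along(d_bins)) {
    d <- d_bins[kk]
    i <- seq_len(n - d)
    x <- cm$values[cbind(i, i + d)]
    gi <- dom[i]; gj <- dom[i + d]
    grp <- ifelse(gi == gj & gi > 0L, gi, 0L)
    nt <- sum(span_bp >= d * cm$resolution)
    N <- length(x)
    out$N[kk] <- N
    out$N_t[kk] <- nt
    ss_tot <- sum((x - mean(x))^2)
    if (N - nt - 1 <= 0 || ss_tot <= 0) next
    xhat <- stats::ave(x, grp)
    ss_res <- sum((x - xhat)^2)
    out$r2[kk] <- 1 - (ss_res / (N - nt - 1)) / (ss_tot / (N - 1))
  }
  structure(out, class = c("AdjR2Profile", "data.frame"))
}

#' Average signal profile around domain boundaries
#'
#' For each boundary, the `[-flank, +flank]` neighborhood is cut into
#' `nbins` equal offset bins (odd count, centre bin at the boundary) and the
#' coverage-weighted mean track value is taken per offset bin, counting
#' uncovered positions inside the chromosome as 0; offset bins that fall
#' entirely before position 0 are excluded. Profiles are averaged across
#' boundaries. Structural boundaries of real chromatin show enrichment of
#' architectural marks (CTCF, cohesin) at the centre.
#'
#' @param boundaries numeric vector of boundary bp positions.
#' @param track a [read_bedgraph()] SignalTrack.
#' @param flank half-window in bp (default 250 Kb).
#' @param nbins odd number of offset bins.
#' @return numeric vector of length `nbins`: mean signal per offset bin.
#' @export
boundary_signal_profile <- function(boundaries, track, flank = 250000, nbins = 11L) {
  if (length(boundaries) == 0) stop("no boundaries given")
  if (nbins %% 2L != 1L) stop("nbins must be odd")
  width <- 2 * flank / nbins
  sums <- numeric(nbins)
  cnts <- numeric(nbins)
  for (b in boundaries) {
    lo_all <- b - flank + (seq_len(nbins) - 1L) * width
    hi_all <- lo_all + width
    for (j in seq_len(nbins)) {
      lo <- max(lo_all[j], 0); hi <- hi_all[j]
      if (hi <= 0) next  # entirely off-chromosome
      len <- hi - lo
      ov <- pmax(0, pmin(track$end_bp, hi) - pmax(track$start_bp, lo))
      val <- sum(ov * track$value) / len
      sums[j] <- sums[j] + val
      cnts[j] <- cnts[j] + 1
    }
  }
  ifelse(cnts > 0, sums / cnts, NA_real_)
}

bp_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  union <- (e1 - s1) + (e2 - s2) - inter
  if (union <= 0) 0 else inter / union
}

#' Fraction of reference domains recovered by a detected set
#'
#' A reference domain counts as recovered when some detected domain overlaps
#' it with bp-Jaccard at least `jaccard_min`.
#'
#' @param detected,reference TadSet-shaped data.frames.
#' @param jaccard_min Jaccard threshold in `[0, 1]` (default 0.5).
#' @return recovery rate in `[0, 1]`.
#' @export
recovery_rate <- function(detected, reference, jaccard_min = 0.5) {
  if (is.null(reference) || nrow(reference) == 0) stop("empty reference set")
  if (is.null(detected) || nrow(detected) == 0) return(0)
  hit <- vapply(seq_len(nrow(reference)), function(i) {
    any(vapply(seq_len(nrow(detected)), function(j) {
      bp_jaccard(reference$start_bp[i], reference$end_bp[i],
                 detected$start_bp[j], detected$end_bp[j])
    }, numeric(1)) >= jaccard_min)
  }, logical(1))
  mean(hit)
}

#' Classify split and merge events between two domain sets
#'
#' A *split* is an interval `a` of `A` replaced in `B` by two or more
#' intervals that each lie mostly (fraction `cover_min` of their own length)
#' inside `a` and together cover at least `cover_min` of `a`. A *merge* is
#' the symmetric event with the roles of `A` and `B` swapped. Such
#' rearrangements are the signature of domain reorganization between cell
#' states.
#'
#' @param A,B TadSet-shaped data.frames on the same chromosome.
#' @param cover_min coverage fraction defining containment (default 0.8).
#' @return a `RearrangementReport`: list with data.frames `splits`
#'   (`a_start`, `a_end`, `n_parts`, `parts` as a comma-separated string)
#'   and `merges` (symmetric columns).
#' @export
classify_split_merge <- function(A, B, cover_min = 0.8) {
  one_direction <- function(from, to) {
    rows <- list()
    if (is.null(from) || nrow(from) == 0 || is.null(to) || nrow(to) == 0) {
      return(data.frame(start_bp = numeric(0), end_bp = numeric(0),
                        n_parts = integer(0), parts = character(0)))
    }
    for (i in seq_len(nrow(from))) {
      s <- from$start_bp[i]; e <- from$end_bp[i]
      ov <- pmax(0, pmin(to$end_bp, e) - pmax(to$start_bp, s))
      inside <- ov / (to$end_bp - to$start_bp) >= cover_min & ov > 0
      if (sum(inside) >= 2 && sum(ov[inside]) >= cover_min * (e - s)) {
        rows[[length(rows) + 1L]] <- data.frame(
          start_bp = s, end_bp = e, n_parts = sum(inside),
          parts = paste(sprintf("[%g,%g)", to$start_bp[inside],
                                to$end_bp[inside]), collapse = ","))
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(start_bp = numeric(0), end_bp = numeric(0),
                 n_parts = integer(0), parts = character(0))
  }
  structure(list(splits = one_direction(A, B), merges = one_direction(B, A)),
            class = "RearrangementReport")
}
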
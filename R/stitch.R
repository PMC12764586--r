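#' TAD quality of a region
#'
#' Mean intra-TAD interaction minus mean inter-TAD interaction over bin
#' pairs in a region: `IntraIF` averages `cm[i, j]` over pairs with both
#' bins inside the same TAD, `InterIF` over pairs whose bins lie in two
#' different TADs. A well-placed partition maximizes intra-TAD contact while
#' minimizing cross-domain contact, so higher is better. An empty pair set
#' contributes 0.
#'
#' @param cm a [contact_matrix()].
#' @param tads TadSet-shaped data.frame of intervals; they are clipped to
#'   the region before scoring.
#' @param region length-2 vector: half-open bin interval `c(start, end)`.
#' @return the TQ score (a real number; 0 when the region holds no pairs).
#' @export
tad_quality <- function(cm, tads, region) {
  a <- region[1]; b <- region[2]
  if (b - a < 2) stop("region must span at least 2 bins")
  if (a < 0 || b > cm$n_bins) stop("region out of matrix range")
  nb <- b - a
  grp <- integer(nb)  # 0 = in no TAD
  if (!is.null(tads) && nrow(tads) > 0) {
    for (k in seq_len(nrow(tads))) {
      s <- max(tads$start_bin[k], a)
      e <- min(tads$end_bin[k], b)
      if (e > s) grp[(s - a + 1L):(e - a)] <- k
    }
  }
  vals <- cm$values[(a + 1L):b, (a + 1L):b, drop = FALSE]
  gi <- matrix(grp, nb, nb)
  gj <- matrix(grp, nb, nb, byrow = TRUE)
  upper <- upper.tri(vals)
  intra <- upper & gi == gj & gi > 0L
  inter <- upper & gi != gj & gi > 0L & gj > 0L
  intra_if <- if (any(intra)) mean(vals[intra]) else 0
  inter_if <- if (any(inter)) mean(vals[inter]) else 0
  intra_if - inter_if
}

#' Resolve duplicated calls in one overlap (Q) region
#'
#' Candidates from the previous and current windows that intersect the
#' overlap region are scored by [tad_quality()] after clipping to the
#' region; the side with the higher TQ keeps its full (unclipped) intervals
#' and the other side's Q-intersecting intervals are dropped. Ties go to the
#' current window. A side with no Q candidates concedes vacuously.
#'
#' @param cm a [contact_matrix()].
#' @param prev_tads,curr_tads candidate TadSets from windows `i` and `i+1`.
#' @param q_range half-open bin interval `c(start, end)` of the overlap.
#' @return list with `prev_kept`, `curr_kept` (logical vectors over the
#'   input rows) and a `record` data.frame (window TQs and winner).
#' @export
resolve_q_region <- function(cm, prev_tads, curr_tads, q_range) {
  overlaps_q <- function(tads) {
    if (is.null(tads) || nrow(tads) == 0) return(logical(0))
    tads$start_bin < q_range[2] & tads$end_bin > q_range[1]
  }
  in_q_prev <- overlaps_q(prev_tads)
  in_q_curr <- overlaps_q(curr_tads)
  prev_kept <- rep(TRUE, length(in_q_prev))
  curr_kept <- rep(TRUE, length(in_q_curr))
  if (!any(in_q_prev) && !any(in_q_curr)) {
    winner <- "none"; tq_prev <- NA_real_; tq_curr <- NA_real_
  } else if (!any(in_q_prev)) {
    winner <- "curr"; tq_prev <- NA_real_; tq_curr <- NA_real_
  } else if (!any(in_q_curr)) {
    winner <- "prev"; tq_prev <- NA_real_; tq_curr <- NA_real_
  } else {
    tq_prev <- tad_quality(cm, prev_tads[in_q_prev, , drop = FALSE], q_range)
    tq_curr <- tad_quality(cm, curr_tads[in_q_curr, , drop = FALSE], q_range)
    winner <- if (tq_prev > tq_curr) "prev" else "curr"
    if (winner == "prev") curr_kept[in_q_curr] <- FALSE else prev_kept[in_q_prev] <- FALSE
  }
  list(prev_kept = prev_kept, curr_kept = curr_kept,
       record = data.frame(q_start_bin = q_range[1], q_end_bin = q_range[2],
                           tq_prev = tq_prev, tq_curr = tq_curr,
                           winner = winner))
}

#' Assemble the genome-wide TAD set from per-window candidates
#'
#' Walks the windows left to right, resolving each overlap (Q) region with
#' [resolve_q_region()]; any residual overlap between a retained
#' earlier-window interval and a later one is then resolved by dropping the
#' later one (the earlier call already won its TQ comparison, and a total
#' order keeps the result deterministic). The final set is sorted and
#' non-overlapping.
#'
#' @param cm a [contact_matrix()].
#' @param per_window_candidates list of candidate TadSets, one per window,
#'   already size-filtered.
#' @param plan the [plan_partition()] used to create the windows.
#' @return a [tad_set()] with a `q_records` attribute (one resolution record
#'   per overlap region).
#' @export
assemble_genome_tads <- function(cm, per_window_candidates, plan) {
  chrom <- cm$chrom
  resolution <- cm$resolution
  empty <- tad_set(integer(0), integer(0), chrom, resolution)
  kept <- if (length(per_window_candidates) >= 1) per_window_candidates[[1]] else empty
  if (is.null(kept)) kept <- empty
  records <- list()
  if (plan$ns > 1) {
    for (i in 2:plan$ns) {
      w <- plan$windows[i, ]
      curr <- per_window_candidates[[i]]
      if (is.null(curr)) curr <- empty
      q_range <- c(w$ext_start_bin, w$core_start_bin)
      if (q_range[2] - q_range[1] >= 2) {
        res <- resolve_q_region(cm, kept, curr, q_range)
        kept <- bind_tads(kept[res$prev_kept, , drop = FALSE],
                          curr[res$curr_kept, , drop = FALSE], empty)
        records[[length(records) + 1L]] <- res$record
      } else {
        kept <- bind_tads(kept, curr, empty)
      }
    }
  }
  # residual overlap sweep: earlier windows take precedence
  if (nrow(kept) > 0) {
    ord <- order(kept$source_window, kept$start_bp)
    keep <- rep(TRUE, nrow(kept))
    starts <- kept$start_bp; ends <- kept$end_bp
    taken_s <- numeric(0); taken_e <- numeric(0)
    for (k in ord) {
      if (any(starts[k] < taken_e & ends[k] > taken_s)) {
        keep[k] <- FALSE
      } else {
        taken_s <- c(taken_s, starts[k]); taken_e <- c(taken_e, ends[k])
      }
    }
    kept <- kept[keep, , drop = FALSE]
  }
  out <- tad_set(kept$start_bin, kept$end_bin, chrom, resolution,
                 source_window = kept$source_window,
                 cluster_label = kept$cluster_label)
  attr(out, "q_records") <- if (length(records)) do.call(rbind, records) else NULL
  out
}
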
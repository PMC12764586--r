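#' Call TADs on a contact matrix
#'
#' Runs the full pipeline: partition the matrix into sub-matrices of at most
#' `t` bins with a `q_bp` left/top overlap, Gaussian-smooth each sub-matrix,
#' embed its bin graph with NetMF, cluster the embedding with HDBSCAN,
#' convert label runs to candidate intervals, apply the size filter, and
#' stitch the windows by resolving each overlap region with the TAD-quality
#' score. The call path contains no randomness: identical inputs give
#' identical output.
#'
#' @param cm a [contact_matrix()].
#' @param t maximum sub-matrix core size in bins (default 5000).
#' @param q_bp sub-matrix overlap in bp (default 3 Mb).
#' @param sigma Gaussian smoothing bandwidth in bins (default 1; 0 disables).
#' @param netmf a [netmf_config()].
#' @param cluster a [cluster_config()].
#' @param min_tad_bp,max_tad_bp closed domain size bounds (default
#'   100 Kb–5 Mb).
#' @param verbose print the partition plan and per-window progress.
#' @return a [tad_set()]; attributes `plan`, `q_records` and `window_info`
#'   carry the partition plan, the overlap-resolution log, and per-window
#'   diagnostics (active bins, effective embedding size, candidate counts).
#' @export
call_tads <- function(cm, t = 5000L, q_bp = 3e6, sigma = 1.0,
                      netmf = netmf_config(), cluster = cluster_config(),
                      min_tad_bp = 1e5, max_tad_bp = 5e6, verbose = FALSE) {
  plan <- plan_partition(cm$n_bins, cm$resolution, t = t, q_bp = q_bp)
  if (verbose) print(plan)
  per_window <- vector("list", plan$ns)
  info <- vector("list", plan$ns)
  for (i in seq_len(plan$ns)) {
    w <- plan$windows[i, ]
    sub <- extract_submatrix(cm, w)
    sub <- gaussian_smooth(sub, sigma = sigma)
    emb <- netmf_embed(sub, cfg = netmf)
    n_ext <- nrow(sub)
    labels <- hdbscan_cluster(emb, cfg = cluster, n_total = n_ext)
    cands <- labels_to_candidates(labels, w, cm$chrom, cm$resolution)
    n_raw <- nrow(cands)
    cands <- filter_by_size(cands, min_bp = min_tad_bp, max_bp = max_tad_bp)
    per_window[[i]] <- cands
    info[[i]] <- data.frame(
      window = w$index, ext_bins = n_ext,
      active_bins = if (is.null(emb)) 0L else length(emb$rows),
      e_eff = if (is.null(emb)) 0L else emb$e_eff,
      clusters = length(setdiff(unique(labels), -1L)),
      candidates = n_raw, kept = nrow(cands))
    if (verbose) {
      message(sprintf("window %d: %d bins, e_eff=%d, %d clusters, %d/%d candidates kept",
                      w$index, n_ext, info[[i]]$e_eff, info[[i]]$clusters,
                      nrow(cands), n_raw))
    }
  }
  out <- assemble_genome_tads(cm, per_window, plan)
  attr(out, "plan") <- plan
  attr(out, "window_info") <- do.call(rbind, info)
  out
}
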
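#' Clustering configuration
#'
#' @param min_cluster_size smallest number of points a cluster may contain
#'   (default 5 — small enough that a 100 Kb domain survives run-splitting at
#'   common Hi-C resolutions).
#' @param min_samples neighbor count for the core distance (defaults to
#'   `min_cluster_size`).
#' @return a `ClusterConfig` list. The metric is Euclidean.
#' @export
cluster_config <- function(min_cluster_size = 5L, min_samples = min_cluster_size) {
  stopifnot(min_cluster_size >= 2, min_samples >= 1)
  structure(list(min_cluster_size = as.integer(min_cluster_size),
                 min_samples = as.integer(min_samples),
                 metric = "euclidean"),
            class = "ClusterConfig")
}

#' Mutual reachability distance matrix
#'
#' The core distance of a point is the Euclidean distance to its k-th nearest
#' *other* point; the mutual reachability between two points is the maximum
#' of their core distances and their pairwise distance. Density clustering on
#' this metric flattens distances inside sparse neighborhoods, which is what
#' makes HDBSCAN robust to variable density.
#'
#' @param points numeric matrix, one point per row (>= 2 rows).
#' @param min_samples the `k` of the core distance.
#' @return symmetric matrix of mutual reachability distances, zero diagonal.
#' @export
mutual_reachability <- function(points, min_samples) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (m < 2L) stop("need at least 2 points")
  if (min_samples >= m) {
    stop("min_samples = ", min_samples, " must be < number of points = ", m)
  }
  d <- as.matrix(stats::dist(points))
  core <- vapply(seq_len(m),
                 function(i) sort(d[i, -i])[min_samples],
                 numeric(1))
  mr <- pmax(d, outer(core, core, pmax))
  diag(mr) <- 0
  dimnames(mr) <- NULL
  mr
}

# Prim's algorithm on a dense symmetric weight matrix; returns (m-1) x 3
# matrix of edges (from, to, weight), 1-based indices.
prim_mst <- function(W) {
  m <- nrow(W)
  if (m == 1L) return(matrix(numeric(0), 0L, 3L))
  best_w <- W[1L, ]
  best_from <- rep(1L, m)
  in_tree <- rep(FALSE, m)
  in_tree[1L] <- TRUE
  best_w[1L] <- Inf
  edges <- matrix(0, m - 1L, 3L)
  for (s in seq_len(m - 1L)) {
    j <- which.min(best_w)
    edges[s, ] <- c(best_from[j], j, best_w[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & W[j, ] < best_w
    best_from[upd] <- j
    best_w[upd] <- W[j, upd]
    best_w[j] <- Inf
  }
  edges
}

# Single-linkage hierarchy from MST edges (union-find). Nodes 1..m are
# points; internal nodes m+1..2m-1 carry children, merge height and size.
single_linkage_tree <- function(edges, m) {
  if (m == 1L) {
    return(list(left = integer(0), right = integer(0), height = numeric(0),
                size = integer(0), root = 1L))
  }
  ord <- order(edges[, 3L])
  parent <- seq_len(2L * m - 1L)  # union-find with path compression
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  comp_node <- seq_len(m)  # current tree node of each component root
  left <- integer(m - 1L)
  right <- integer(m - 1L)
  height <- numeric(m - 1L)
  size <- integer(2L * m - 1L)
  size[seq_len(m)] <- 1L
  for (s in seq_len(m - 1L)) {
    e <- ord[s]
    ra <- find(edges[e, 1L])
    rb <- find(edges[e, 2L])
    new_node <- m + s
    left[s] <- comp_node[ra]
    right[s] <- comp_node[rb]
    height[s] <- edges[e, 3L]
    size[new_node] <- size[left[s]] + size[right[s]]
    parent[ra] <- new_node
    parent[rb] <- new_node
    parent[new_node] <- new_node
    comp_node <- c(comp_node, 0L)
    comp_node[new_node] <- new_node
  }
  list(left = c(rep(0L, m), left), right = c(rep(0L, m), right),
       height = c(rep(0, m), height), size = size, root = 2L * m - 1L)
}

# collect leaf points (1..m) under a tree node
tree_leaves <- function(tree, node, m) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (nd <= m) out <- c(out, nd) else stack <- c(stack, tree$left[nd], tree$right[nd])
  }
  out
}

# Condense the single-linkage tree: clusters persist while >= mcs points
# remain; sub-mcs branches detach as points at the split's lambda = 1/height.
# Zero-height merges (duplicate points in embedding space) are pass-through:
# duplicates are one density peak, never a split.
condense_tree <- function(tree, m, mcs) {
  pt_cluster <- integer(m)   # condensed cluster each point record belongs to
  pt_lambda <- numeric(m)    # lambda at which the point detaches
  cl_parent <- integer(0)    # per condensed cluster (root = 1, parent 0)
  cl_birth <- numeric(0)
  cl_size <- integer(0)
  new_cluster <- function(parent, birth, size) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_size[length(cl_size) + 1L] <<- size
    length(cl_parent)
  }
  root_cl <- new_cluster(0L, 0, tree$size[tree$root])
  # stack entries: (slt node, condensed cluster, lambda context from the
  # nearest positive-height ancestor; used when a bare leaf is reached)
  stack_node <- tree$root
  stack_cl <- root_cl
  stack_lam <- Inf
  while (length(stack_node)) {
    k <- length(stack_node)
    nd <- stack_node[k]; cl <- stack_cl[k]; lam_ctx <- stack_lam[k]
    stack_node <- stack_node[-k]; stack_cl <- stack_cl[-k]; stack_lam <- stack_lam[-k]
    if (nd <= m) {
      pt_cluster[nd] <- cl
      pt_lambda[nd] <- lam_ctx
      next
    }
    h <- tree$height[nd]
    l <- tree$left[nd]; r <- tree$right[nd]
    if (h <= 0) {  # duplicates: continue the same cluster through both sides
      stack_node <- c(stack_node, l, r)
      stack_cl <- c(stack_cl, cl, cl)
      stack_lam <- c(stack_lam, lam_ctx, lam_ctx)
      next
    }
    lam <- 1 / h
    sl <- tree$size[l]; sr <- tree$size[r]
    if (sl >= mcs && sr >= mcs) {
      cl_l <- new_cluster(cl, lam, sl)
      cl_r <- new_cluster(cl, lam, sr)
      stack_node <- c(stack_node, l, r)
      stack_cl <- c(stack_cl, cl_l, cl_r)
      stack_lam <- c(stack_lam, lam, lam)
    } else if (sl < mcs && sr < mcs) {
      for (p in tree_leaves(tree, l, m)) { pt_cluster[p] <- cl; pt_lambda[p] <- lam }
      for (p in tree_leaves(tree, r, m)) { pt_cluster[p] <- cl; pt_lambda[p] <- lam }
    } else {
      small <- if (sl < mcs) l else r
      big <- if (sl < mcs) r else l
      for (p in tree_leaves(tree, small, m)) { pt_cluster[p] <- cl; pt_lambda[p] <- lam }
      stack_node <- c(stack_node, big)
      stack_cl <- c(stack_cl, cl)
      stack_lam <- c(stack_lam, lam)
    }
  }
  list(pt_cluster = pt_cluster, pt_lambda = pt_lambda,
       cl_parent = cl_parent, cl_birth = cl_birth, cl_size = cl_size)
}

# Excess-of-mass cluster selection on the condensed tree. The root is never
# selected unless it is the only cluster (homogeneous window -> one cluster).
select_clusters_eom <- function(ct, m) {
  ncl <- length(ct$cl_parent)
  if (ncl == 1L) return(1L)
  # stability: sum over member records of (lambda_leave - lambda_birth)
  stability <- numeric(ncl)
  fin <- is.finite(ct$pt_lambda)
  for (p in which(fin)) {
    cl <- ct$pt_cluster[p]
    stability[cl] <- stability[cl] + (ct$pt_lambda[p] - ct$cl_birth[cl])
  }
  for (cl in which(ct$cl_parent > 0L)) {
    par <- ct$cl_parent[cl]
    stability[par] <- stability[par] + (ct$cl_birth[cl] - ct$cl_birth[par]) * ct$cl_size[cl]
  }
  children <- split(seq_len(ncl), factor(ct$cl_parent, levels = 0:ncl))
  selected <- rep(FALSE, ncl)
  subtree_stab <- numeric(ncl)
  for (cl in ncl:2L) {
    ch <- children[[as.character(cl)]]
    if (length(ch) == 0L) {
      selected[cl] <- TRUE
      subtree_stab[cl] <- stability[cl]
    } else if (stability[cl] >= sum(subtree_stab[ch])) {
      selected[cl] <- TRUE
      subtree_stab[cl] <- stability[cl]
      # deselect all descendants
      stack <- ch
      while (length(stack)) {
        x <- stack[length(stack)]; stack <- stack[-length(stack)]
        selected[x] <- FALSE
        stack <- c(stack, children[[as.character(x)]])
      }
    } else {
      subtree_stab[cl] <- sum(subtree_stab[ch])
    }
  }
  which(selected)
}

#' HDBSCAN clustering of embedding rows
#'
#' Density clustering with the HDBSCAN* algorithm: Euclidean distances
#' between embedding rows, core distances at `min_samples`, mutual
#' reachability, minimum spanning tree, single-linkage hierarchy, condensed
#' tree at `min_cluster_size`, and excess-of-mass cluster extraction.
#' Deterministic for fixed input. Points in no selected cluster get the noise
#' label `-1`.
#'
#' @param emb an `EmbeddingMatrix` from [netmf_embed()] (or any numeric
#'   matrix of points in rows), or `NULL`.
#' @param cfg a [cluster_config()].
#' @param n_total optional total label-vector length: rows of `emb` are
#'   placed at positions `emb$rows + 1` and all other (inactive) positions
#'   are noise.
#' @return integer vector of labels, `-1` for noise, clusters numbered from 0.
#' @export
hdbscan_cluster <- function(emb, cfg = cluster_config(), n_total = NULL) {
  if (is.null(emb)) {
    if (is.null(n_total)) stop("empty embedding and no n_total")
    return(rep(-1L, n_total))
  }
  X <- if (inherits(emb, "EmbeddingMatrix")) emb$vectors else as.matrix(emb)
  rows <- if (inherits(emb, "EmbeddingMatrix")) emb$rows else seq_len(nrow(X)) - 1L
  m <- nrow(X)
  if (is.null(n_total)) n_total <- if (length(rows)) max(rows) + 1L else m
  labels_full <- rep(-1L, n_total)
  if (m < cfg$min_cluster_size) return(labels_full)
  k <- min(cfg$min_samples, m - 1L)
  mr <- mutual_reachability(X, k)
  mst <- prim_mst(mr)
  tree <- single_linkage_tree(mst, m)
  ct <- condense_tree(tree, m, cfg$min_cluster_size)
  sel <- select_clusters_eom(ct, m)
  # label: walk up from each point's attachment cluster to the first
  # selected cluster; the (non-trivial) root is noise
  label_of_cluster <- rep(NA_integer_, length(ct$cl_parent))
  label_of_cluster[sel] <- seq_along(sel) - 1L
  labels <- rep(-1L, m)
  for (p in seq_len(m)) {
    cl <- ct$pt_cluster[p]
    while (cl > 0L) {
      if (!is.na(label_of_cluster[cl])) {
        labels[p] <- label_of_cluster[cl]
        break
      }
      cl <- ct$cl_parent[cl]
    }
  }
  labels_full[rows + 1L] <- labels
  labels_full
}

#' Convert per-bin cluster labels to candidate intervals
#'
#' HDBSCAN clusters live in embedding space and need not be genomically
#' contiguous, but domains are intervals: each maximal run of consecutive
#' bins sharing one non-noise label becomes one candidate, in absolute
#' genome coordinates. Noise bins break runs.
#'
#' @param labels integer labels over the window's extended bin range
#'   (`-1` = noise).
#' @param window a window row from [plan_partition()] (needs
#'   `ext_start_bin` and `index`).
#' @param chrom chromosome name.
#' @param resolution bin width in bp.
#' @return a [tad_set()] of candidates (may legitimately overlap candidates
#'   of *other* windows; within one window they are disjoint).
#' @export
labels_to_candidates <- function(labels, window, chrom, resolution) {
  n <- length(labels)
  if (n == 0L) return(tad_set(integer(0), integer(0), chrom, resolution))
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != -1L
  tad_set(window$ext_start_bin + starts[keep],
          window$ext_start_bin + ends[keep],
          chrom = chrom, resolution = resolution,
          source_window = window$index,
          cluster_label = r$values[keep])
}

#' Filter candidate intervals by genomic size
#'
#' Mammalian domains typically span 100 Kb to 5 Mb; candidates outside the
#' closed size range are discarded. Coordinates are never altered.
#'
#' @param cands a [tad_set()] of candidates.
#' @param min_bp,max_bp closed size bounds in bp.
#' @return the subset of `cands` within bounds.
#' @export
filter_by_size <- function(cands, min_bp = 1e5, max_bp = 5e6) {
  if (min_bp > max_bp) stop("min_bp > max_bp")
  len <- cands$end_bp - cands$start_bp
  out <- cands[len >= min_bp & len <= max_bp, , drop = FALSE]
  rownames(out) <- NULL
  out
}
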
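#' NetMF configuration
#'
#' @param dim target embedding size `e` (default 455, the optimum found for
#'   Hi-C bin graphs); the effective size is clamped to the factored matrix
#'   rank and to `m_active - 1`.
#' @param window skip-gram context window `W_s` (default 2).
#' @param neg negative-sampling constant (default 1).
#' @param variant `"auto"` picks `"exact-small"` (direct DeepWalk-matrix
#'   powers) for graphs up to `exact_max` active nodes and small windows,
#'   else `"approx-large"` (truncated eigendecomposition of the normalized
#'   adjacency).
#' @param rank number of eigenpairs `h` kept on the approximate path
#'   (default 256).
#' @param exact_max largest active-node count routed to the exact path under
#'   `variant = "auto"` (default 4000).
#' @return a `NetMFConfig` list.
#' @export
netmf_config <- function(dim = 455L, window = 2L, neg = 1L,
                         variant = c("auto", "exact-small", "approx-large"),
                         rank = 256L, exact_max = 4000L) {
  variant <- match.arg(variant)
  stopifnot(dim >= 1, window >= 1, neg >= 1, rank >= 1)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 neg = as.integer(neg), variant = variant,
                 rank = as.integer(rank), exact_max = as.integer(exact_max)),
            class = "NetMFConfig")
}

#' Convert a smoothed sub-matrix to a weighted graph
#'
#' Bins become nodes and interaction frequencies edge weights. The diagonal
#' is zeroed: self-contacts carry no pairwise proximity and would otherwise
#' dominate node degrees and the graph volume. Zero-degree nodes are recorded
#' as inactive; they bypass embedding and are labelled noise downstream
#' (the inverse degree matrix is undefined there).
#'
#' @param M symmetric non-negative square matrix.
#' @param keep_diagonal set `TRUE` to retain self-contacts as self-loops.
#' @return a `WeightedGraph`: list with adjacency `A`, `degrees`, `vol`,
#'   `m` (node count) and `active` (0-based indices of nodes with positive
#'   degree). An all-zero matrix yields `vol = 0` ("empty graph"); callers
#'   should skip such windows.
#' @export
matrix_to_graph <- function(M, keep_diagonal = FALSE) {
  M <- as.matrix(M)
  stopifnot(nrow(M) == ncol(M))
  A <- M
  if (!keep_diagonal) diag(A) <- 0
  degrees <- rowSums(A)
  structure(list(A = A, degrees = degrees, vol = sum(degrees),
                 m = nrow(A), active = which(degrees > 0) - 1L),
            class = "WeightedGraph")
}

#' Exact DeepWalk matrix over active nodes
#'
#' Computes `chi = vol(G) / (neg * W_s) * (sum_{r=1}^{W_s} rho^r) * D^-1`
#' with `rho = D^-1 A`, restricted to active nodes, then symmetrizes
#' (`(chi + t(chi)) / 2`; the expression is symmetric analytically but not in
#' floating point).
#'
#' @param g a [matrix_to_graph()] result with `vol > 0`.
#' @param cfg a [netmf_config()].
#' @return dense symmetric matrix over active nodes.
#' @export
deepwalk_matrix_exact <- function(g, cfg = netmf_config()) {
  if (g$vol <= 0) stop("empty graph: vol(G) = 0")
  act <- g$active + 1L
  A <- g$A[act, act, drop = FALSE]
  d <- g$degrees[act]
  rho <- A / d  # D^-1 A, row scaling
  S <- rho
  P <- rho
  if (cfg$window > 1L) {
    for (r in 2:cfg$window) {
      P <- P %*% rho
      S <- S + P
    }
  }
  chi <- (g$vol / (cfg$neg * cfg$window)) * sweep(S, 2L, d, "/")
  (chi + t(chi)) / 2
}

#' Approximate DeepWalk matrix via truncated eigendecomposition
#'
#' Takes the top-`h` eigenpairs (largest magnitude) of the normalized
#' adjacency `D^-1/2 A D^-1/2 ~ U_h Lambda_h U_h'` and forms
#' `chi_hat = vol(G)/neg * D^-1/2 U_h ((1/W_s) sum_r Lambda_h^r) U_h' D^-1/2`.
#' With a full eigenbasis this equals the exact DeepWalk matrix.
#'
#' @inheritParams deepwalk_matrix_exact
#' @return dense symmetric matrix over active nodes.
#' @export
deepwalk_matrix_approx <- function(g, cfg = netmf_config()) {
  if (g$vol <= 0) stop("empty graph: vol(G) = 0")
  act <- g$active + 1L
  A <- g$A[act, act, drop = FALSE]
  d <- g$degrees[act]
  m <- length(d)
  h <- cfg$rank
  if (h > m) {
    warning("rank h = ", h, " exceeds ", m, " active nodes; clamped")
    h <- m
  }
  dis <- 1 / sqrt(d)
  B <- A * (dis %o% dis)  # D^-1/2 A D^-1/2, symmetric
  eig <- eigen(B, symmetric = TRUE)
  keep <- order(-abs(eig$values), eig$values)[seq_len(h)]
  U <- eig$vectors[, keep, drop = FALSE]
  lam <- eig$values[keep]
  pw <- numeric(length(lam))
  lp <- rep(1, length(lam))
  for (r in seq_len(cfg$window)) {
    lp <- lp * lam
    pw <- pw + lp
  }
  pw <- pw / cfg$window
  M <- U %*% (pw * t(U))
  chi <- (g$vol / cfg$neg) * (M * (dis %o% dis))
  (chi + t(chi)) / 2
}

#' Factorize the shifted-log DeepWalk matrix into node embeddings
#'
#' Applies the shifted-PPMI floor `chi' = pmax(chi, 1)`, takes elementwise
#' `log`, and factorizes `L = log chi'` with a rank-`e` truncated SVD; the
#' embedding is `U_a sqrt(Sigma_a)`. `L` is symmetric by construction, so
#' the SVD is computed from the symmetric eigendecomposition
#' (`sigma = |lambda|`, `u = sign(lambda) v`), which is deterministic and
#' well-behaved under repeated singular values. Each singular vector's sign
#' is fixed by making its largest-magnitude component positive (first index
#' on ties), so outputs are reproducible across platforms; reflections do
#' not affect inter-row distances, so clustering downstream is sign-stable.
#'
#' @param chi dense symmetric matrix from the exact or approximate path.
#' @param e target embedding size.
#' @return an `EmbeddingMatrix`: list with `vectors` (`m_active x e_eff`),
#'   `e_eff`, and `rows` (0-based node indices the rows correspond to; set by
#'   [netmf_embed()]).
#' @export
shifted_log_factorize <- function(chi, e) {
  stopifnot(all(is.finite(chi)))
  m <- nrow(chi)
  L <- log(pmax(chi, 1))
  eig <- eigen(L, symmetric = TRUE)
  ord <- order(-abs(eig$values), -eig$values)
  lam <- eig$values[ord]
  V <- eig$vectors[, ord, drop = FALSE]
  tol <- max(m, 1) * .Machine$double.eps * max(abs(lam), 0)
  rank <- sum(abs(lam) > tol)
  e_eff <- min(e, rank, max(m - 1L, 0L))
  if (e_eff == 0L) {
    warning("factored matrix has rank 0; returning zero embedding")
    return(structure(list(vectors = matrix(0, m, 1L), e_eff = 0L,
                          rows = seq_len(m) - 1L),
                     class = "EmbeddingMatrix"))
  }
  U <- V[, seq_len(e_eff), drop = FALSE] *
    rep(sign(lam[seq_len(e_eff)] + (lam[seq_len(e_eff)] == 0)), each = m)
  # fixed sign convention: largest-|entry| component of each vector positive
  for (j in seq_len(e_eff)) {
    i_star <- which.max(abs(U[, j]))
    if (U[i_star, j] < 0) U[, j] <- -U[, j]
  }
  emb <- U * rep(sqrt(abs(lam[seq_len(e_eff)])), each = m)
  structure(list(vectors = emb, e_eff = as.integer(e_eff),
                 rows = seq_len(m) - 1L),
            class = "EmbeddingMatrix")
}

#' NetMF node embedding of a smoothed sub-matrix
#'
#' Orchestrates [matrix_to_graph()], the exact or approximate DeepWalk
#' matrix, and [shifted_log_factorize()]. Inactive (zero-degree) bins are
#' excluded; `rows` maps embedding rows back to 0-based bin indices within
#' the sub-matrix.
#'
#' @param M smoothed symmetric non-negative matrix (one window).
#' @param cfg a [netmf_config()].
#' @param keep_diagonal passed to [matrix_to_graph()].
#' @return an `EmbeddingMatrix`, or `NULL` for an empty graph (window
#'   yields no TADs).
#' @export
netmf_embed <- function(M, cfg = netmf_config(), keep_diagonal = FALSE) {
  g <- matrix_to_graph(M, keep_diagonal = keep_diagonal)
  if (g$vol <= 0) return(NULL)
  m_act <- length(g$active)
  variant <- cfg$variant
  if (variant == "auto") {
    variant <- if (m_act <= cfg$exact_max && cfg$window <= 4L) {
      "exact-small"
    } else {
      "approx-large"
    }
  }
  chi <- if (variant == "exact-small") {
    deepwalk_matrix_exact(g, cfg)
  } else {
    deepwalk_matrix_approx(g, cfg)
  }
  emb <- shifted_log_factorize(chi, cfg$dim)
  emb$rows <- g$active
  emb$variant <- variant
  emb
}
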
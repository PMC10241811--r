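# Functional connectome construction and diffusion-map embedding.
#
# The principal embedding component of the connectome ("principal functional
# gradient") spans the unimodal-transmodal cortical axis and serves as the
# hierarchy reference for the hierarchical index.

#' Pairwise-correlation functional connectome
#'
#' @param ts A [region_ts()] with at least 3 frames.
#' @return An n x n symmetric Pearson correlation matrix with unit diagonal
#'   (class `matrix`). Rows/columns of zero-variance regions are `NA`.
#' @export
fc_matrix <- function(ts) {
  stopifnot(inherits(ts, "region_ts"))
  if (n_frames(ts) < 3L) stop("need at least 3 frames for a connectome")
  sds <- apply(ts$data, 2L, stats::sd)
  C <- suppressWarnings(stats::cor(ts$data))
  C[!is.finite(C)] <- NA_real_
  diag(C) <- ifelse(sds > 0, 1, NA_real_)
  dimnames(C) <- list(ts$region_ids, ts$region_ids)
  C
}

#' Row-wise sparsification of a connectivity matrix
#'
#' Keeps, per row, the top `1 - sparsity` fraction of off-diagonal entries
#' (by value) and zeroes the rest, then symmetrizes by averaging with the
#' transpose. `sparsity = 0.9` on a 10-node matrix retains one entry per row
#' before symmetrization.
#'
#' @param C Square numeric matrix.
#' @param sparsity Fraction of entries to drop per row, in `[0, 1)`.
#' @return Sparsified symmetric matrix (diagonal preserved).
#' @export
sparsify_rows <- function(C, sparsity = 0.9) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C), sparsity >= 0, sparsity < 1)
  n <- nrow(C)
  keep <- ceiling((1 - sparsity) * (n - 1L))
  S <- matrix(0, n, n, dimnames = dimnames(C))
  for (i in seq_len(n)) {
    off <- C[i, -i]
    thr <- sort(off, decreasing = TRUE)[keep]
    sel <- which(C[i, ] >= thr)
    sel <- setdiff(sel, i)
    # ties at the threshold could retain extras; trim to exactly `keep`
    if (length(sel) > keep) sel <- sel[order(C[i, sel], decreasing = TRUE)][seq_len(keep)]
    S[i, sel] <- C[i, sel]
  }
  diag(S) <- diag(C)
  (S + t(S)) / 2
}

#' Cosine-similarity affinity matrix
#'
#' Pairwise cosine similarity between rows of a (sparsified) connectivity
#' profile matrix; negative similarities are clipped to zero so the result
#' is a valid nonnegative random-walk kernel. Diagonal set to 1.
#'
#' @param S Numeric matrix whose rows are connectivity profiles.
#' @return Symmetric affinity matrix with entries in `[0, 1]`.
#' @export
cosine_affinity <- function(S) {
  stopifnot(is.matrix(S))
  nrm <- sqrt(rowSums(S^2))
  if (any(nrm == 0)) stop("cosine affinity undefined: all-zero row(s) ",
                          paste(which(nrm == 0), collapse = ", "))
  A <- (S %*% t(S)) / outer(nrm, nrm)
  A <- (A + t(A)) / 2          # guard symmetry against round-off
  A[A < 0] <- 0
  A[A > 1] <- 1
  diag(A) <- 1
  A
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Density-normalized diffusion maps: with degree `d = rowSums(A)`, the
#' kernel `W = D^-alpha A D^-alpha` is row-normalized into the transition
#' matrix `M` of a random walk, whose non-trivial eigenvectors (scaled by
#' their eigenvalues, the diffusion-time-zero convention) are the embedding
#' components. `alpha = 0.5` balances local and global geometry.
#'
#' @param A Symmetric nonnegative affinity matrix describing a connected
#'   graph.
#' @param alpha Anisotropy parameter in `[0, 1]`, default 0.5.
#' @param n_components Number of non-trivial components to return.
#' @return An object of class `gradient_map`: `loadings` (n x K matrix),
#'   `eigenvalues` (length K, descending), `alpha`, `region_ids`.
#' @export
diffusion_embedding <- function(A, alpha = 0.5, n_components = 2L) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (max(abs(A - t(A))) > 1e-8) stop("'A' must be symmetric")
  if (min(A) < 0) stop("'A' must be nonnegative")
  comp <- graph_components(A > 0)
  if (max(comp) > 1L)
    stop(sprintf("affinity graph is disconnected (%d components); component sizes: %s",
                 max(comp), paste(tabulate(comp), collapse = ", ")))
  n <- nrow(A)
  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  d2 <- rowSums(W)
  # M = D2^-1 W is similar to the symmetric S = D2^-1/2 W D2^-1/2
  S <- W / outer(sqrt(d2), sqrt(d2))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  psi <- es$vectors / sqrt(d2)        # right eigenvectors of M
  # normalize against the trivial constant component
  psi <- psi / psi[1L, 1L]
  k <- seq.int(2L, min(n_components + 1L, n))
  lam <- es$values[k]
  loadings <- sweep(psi[, k, drop = FALSE], 2L, lam, `*`)
  ids <- rownames(A)
  if (is.null(ids)) ids <- paste0("r", seq_len(n))
  rownames(loadings) <- ids
  colnames(loadings) <- paste0("g", seq_along(k))
  structure(list(loadings = loadings, eigenvalues = lam, alpha = alpha,
                 region_ids = ids),
            class = "gradient_map")
}

#' @export
print.gradient_map <- function(x, ...) {
  cat(sprintf("gradient_map: %d regions, %d components; eigenvalues %s\n",
              nrow(x$loadings), ncol(x$loadings),
              paste(signif(x$eigenvalues, 3), collapse = ", ")))
  invisible(x)
}

# Connected components of a logical adjacency matrix (simple BFS).
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Align component signs to a reference map
#'
#' Eigenvector signs are arbitrary; each component is flipped if its
#' Spearman correlation with the reference map is negative. Zero correlation
#' leaves the component unchanged with a warning.
#'
#' @param grad A `gradient_map`.
#' @param reference_map Numeric vector (or `amp_map`) on the same regions.
#' @return The `gradient_map` with consistently signed components.
#' @export
align_sign <- function(grad, reference_map) {
  stopifnot(inherits(grad, "gradient_map"))
  ref <- map_values(reference_map)
  if (length(ref) != nrow(grad$loadings))
    stop("reference map length does not match the gradient regions")
  for (j in seq_len(ncol(grad$loadings))) {
    r <- spearman(grad$loadings[, j], ref)
    if (is.na(r) || r == 0) {
      warning("component ", j, " uncorrelated with reference; sign unchanged")
    } else if (r < 0) {
      grad$loadings[, j] <- -grad$loadings[, j]
    }
  }
  grad
}

#' Construct the full gradient pipeline from a time series
#'
#' Convenience wrapper: Pearson connectome, row sparsification, cosine
#' affinity, diffusion embedding (the macaque-connectome recipe:
#' `alpha = 0.5`, `sparsity = 0.9`).
#'
#' @inheritParams fc_matrix
#' @param sparsity Row sparsification fraction.
#' @param alpha Diffusion anisotropy.
#' @param n_components Components to keep.
#' @return A `gradient_map`.
#' @export
connectome_gradient <- function(ts, sparsity = 0.9, alpha = 0.5,
                                n_components = 2L) {
  C <- fc_matrix(ts)
  if (anyNA(C)) stop("connectome contains undefined entries (constant regions)")
  S <- sparsify_rows(C, sparsity)
  A <- cosine_affinity(S)
  diffusion_embedding(A, alpha = alpha, n_components = n_components)
}
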
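## Functional connectivity: ROI-pairwise Pearson matrix over unflagged
## frames, reduction to network-level averages, 66-slot feature vector,
## and cohort-level PCA by SVD.

#' ROI-pairwise Pearson functional connectivity
#'
#' Correlations are computed over frames with `flag == 0` only
#' (scrubbing by deletion); the diagonal is exactly 1.
#'
#' @param ts T x R ROI time-series matrix.
#' @param motion optional data.frame with a `flag` column (length T);
#'   `NULL` means no scrubbing.
#' @param min_frames minimum usable frames (default 30).
#' @return R x R symmetric correlation matrix.
#' @export
compute_fc <- function(ts, motion = NULL, min_frames = 30L) {
  ts <- as.matrix(ts)
  keep <- if (is.null(motion)) rep(TRUE, nrow(ts)) else motion$flag == 0L
  if (sum(keep) < min_frames)
    stop(sprintf("only %d unflagged frames (< %d); subject unusable",
                 sum(keep), min_frames), call. = FALSE)
  fc <- cor(ts[keep, , drop = FALSE])
  fc[is.na(fc)] <- 0   # zero-variance ROI: undefined pairs set to 0
  diag(fc) <- 1
  (fc + t(fc)) / 2
}

#' Reduce an FC matrix to network-level averages
#'
#' Diagonal entry k is the mean over unordered within-network-k ROI
#' pairs (self-correlations excluded); entry (k, l) the mean over all
#' cross-network pairs. Correlations are averaged raw by default;
#' `fisher_z = TRUE` averages atanh-transformed values and back-
#' transforms.
#'
#' @param fc R x R FC matrix.
#' @param map a [network_map()] with R rows.
#' @param fisher_z average in Fisher z space (default `FALSE`).
#' @return K x K symmetric matrix with network dimnames.
#' @export
reduce_to_rsn <- function(fc, map, fisher_z = FALSE) {
  stopifnot(nrow(fc) == nrow(map))
  nets <- map_networks(map)
  g <- match(map$network_label, nets)
  K <- length(nets)
  counts <- tabulate(g, K)
  if (any(counts < 2))
    stop("network(s) with < 2 ROIs: ",
         paste(nets[counts < 2], collapse = ", "), call. = FALSE)
  vals <- if (fisher_z) atanh(pmin(pmax(fc, -0.999999), 0.999999)) else fc
  out <- matrix(NA_real_, K, K, dimnames = list(nets, nets))
  for (k in seq_len(K)) {
    ik <- which(g == k)
    blk <- vals[ik, ik, drop = FALSE]
    out[k, k] <- mean(blk[upper.tri(blk)])
    if (k < K) for (l in (k + 1):K) {
      il <- which(g == l)
      out[k, l] <- out[l, k] <- mean(vals[ik, il])
    }
  }
  if (fisher_z) out <- tanh(out)
  out
}

#' Flatten a network summary matrix into the fixed 66-slot layout
#'
#' Intra-network entries in canonical order first, then the upper
#' triangle (k < l) row-major. Invertible via [devectorize()].
#'
#' @param rsn K x K summary matrix with network dimnames.
#' @return Named numeric vector of length `K + K*(K-1)/2`.
#' @export
vectorize <- function(rsn) {
  nets <- rownames(rsn)
  idx <- slot_index(nets)
  v <- rsn[cbind(idx$k, idx$l)]
  names(v) <- slot_names(nets)
  v
}

#' Inverse of [vectorize()]
#' @param v named slot vector.
#' @param networks network labels (recovered from slot names if `NULL`).
#' @return K x K symmetric matrix.
#' @export
devectorize <- function(v, networks = NULL) {
  if (is.null(networks)) {
    first <- vapply(strsplit(names(v), ":", fixed = TRUE), `[`, "", 1L)
    networks <- unique(first)
  }
  K <- length(networks)
  stopifnot(length(v) == n_slots(K))
  idx <- slot_index(networks)
  m <- matrix(NA_real_, K, K, dimnames = list(networks, networks))
  m[cbind(idx$k, idx$l)] <- v
  m[cbind(idx$l, idx$k)] <- v
  m
}

#' Cohort feature matrix and principal component analysis
#'
#' Stacks per-subject slot vectors into the N x 66 matrix M, centers
#' each column (covariance PCA; features already share the correlation
#' scale so no variance normalization), and decomposes by SVD,
#' `M_c = U A V'`. Component scores are `U A`. The sign of each
#' component is arbitrary under SVD; component 1 is oriented so that the
#' mean of its intra-network loadings over the configured sensory set is
#' positive (ties broken by forcing the largest-magnitude loading
#' positive), matching the field's sensory-positive convention for the
#' primary connectivity contrast.
#'
#' @param vectors N x P matrix (or list) of per-subject slot vectors.
#' @param n_components number of components to retain (default all).
#' @param center center columns before SVD (default `TRUE`).
#' @param sensory networks whose intra-network loadings anchor the sign
#'   of component 1.
#' @return list of class `rsnec_pca`: `M`, `scores` (N x n_components),
#'   `c1`, `loadings` (P x n_components), `v1`, `singular_values`,
#'   `variance_explained`, `center`.
#' @export
compile_and_pca <- function(vectors, n_components = NULL, center = TRUE,
                            sensory = sensory_networks()) {
  if (is.list(vectors) && !is.data.frame(vectors))
    vectors <- do.call(rbind, vectors)
  M <- as.matrix(vectors)
  N <- nrow(M)
  if (N < 3) stop("PCA needs at least 3 subjects", call. = FALSE)
  if (anyNA(M)) stop("feature matrix contains missing values", call. = FALSE)
  mu <- if (center) colMeans(M) else rep(0, ncol(M))
  Mc <- sweep(M, 2, mu)
  sv <- svd(Mc)
  d <- sv$d
  ve <- if (sum(d^2) > 0) d^2 / sum(d^2) else rep(0, length(d))
  k <- if (is.null(n_components)) length(d) else min(n_components, length(d))
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  rownames(V) <- colnames(M)
  ## sign convention for component 1
  intra_sens <- intersect(paste0(sensory, ":", sensory), colnames(M))
  flip <- 1
  if (length(intra_sens)) {
    msens <- mean(V[intra_sens, 1])
    if (msens < 0) flip <- -1
    else if (msens == 0) flip <- sign(V[which.max(abs(V[, 1])), 1])
  } else {
    flip <- sign(V[which.max(abs(V[, 1])), 1])
  }
  if (flip == 0) flip <- 1
  U[, 1] <- flip * U[, 1]; V[, 1] <- flip * V[, 1]
  scores <- U %*% diag(d[seq_len(k)], k, k)
  rownames(scores) <- rownames(M)
  colnames(scores) <- paste0("c", seq_len(k))
  colnames(V) <- paste0("V", seq_len(k))
  structure(list(M = M, scores = scores, c1 = scores[, 1],
                 loadings = V, v1 = V[, 1],
                 singular_values = d, variance_explained = ve,
                 center = mu),
            class = "rsnec_pca")
}

#' @export
print.rsnec_pca <- function(x, ...) {
  cat(sprintf("rsnec PCA: %d subjects x %d features; c1 explains %.1f%% variance\n",
              nrow(x$M), ncol(x$M), 100 * x$variance_explained[1]))
  invisible(x)
}

#' Per-cohort FC feature extraction
#'
#' Runs [compute_fc()], [reduce_to_rsn()] and [vectorize()] for every
#' subject of a cohort.
#'
#' @param cohort an `rsnec_cohort` (flags already derived, see
#'   [apply_exclusions()]).
#' @param fisher_z passed to [reduce_to_rsn()].
#' @return N x 66 matrix of slot features, rownames = subject ids.
#' @export
cohort_features <- function(cohort, fisher_z = FALSE) {
  ids <- as.character(cohort$manifest$subject_id)
  feats <- lapply(ids, function(id) {
    fc <- compute_fc(cohort$series[[id]], cohort$motion[[id]])
    vectorize(reduce_to_rsn(fc, cohort$map, fisher_z = fisher_z))
  })
  out <- do.call(rbind, feats)
  rownames(out) <- ids
  out
}
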
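#' Fit a channel-covariance PCA basis
#'
#' Computes the per-channel means and the 4x4 covariance
#' `Omega = X_bar %*% t(X_bar) / n` of the centered 4 x N sample matrix
#' (the `1/n` normalization; the eigenvectors are identical under
#' `1/(n-1)`), then its eigendecomposition with eigenvalues in descending
#' order.  Each eigenvector's sign is fixed so that its largest-magnitude
#' entry is positive, making the basis reproducible.  A rank-deficient
#' covariance triggers a warning but PCA proceeds with zero eigenvalues
#' kept.
#'
#' By default the basis is fit on a single recording, matching the
#' denoising procedure in which each recording's own channel covariance
#' defines the subspace used to clean that recording's median vectors.  A
#' list of recordings may be supplied instead, in which case one pooled
#' basis is fit on the concatenated (per-recording centered) samples.
#'
#' @param x A [ppg_recording()], a 4 x N numeric matrix (channels in rows),
#'   or a list of recordings (pooled fit).
#' @return An object of class `"pca_basis"`: list with `mean` (4-vector of
#'   channel means), `vectors` (orthonormal 4x4 matrix, columns sorted by
#'   descending eigenvalue), `values` (4 eigenvalues, descending) and `n`
#'   (number of samples used).
#' @export
fit_basis <- function(x) {
  if (is.list(x) && !inherits(x, "ppg_recording")) {
    mats <- lapply(x, function(r) {
      m <- if (inherits(r, "ppg_recording")) r$samples else r
      m - rowMeans(m)
    })
    xb <- do.call(cbind, mats)
    mu <- rowMeans(do.call(cbind, lapply(x, function(r)
      rowMeans(if (inherits(r, "ppg_recording")) r$samples else r))))
  } else {
    m <- if (inherits(x, "ppg_recording")) x$samples else x
    if (!is.matrix(m) || nrow(m) != 4L)
      stop("expected a 4 x N sample matrix", call. = FALSE)
    if (ncol(m) < 2L)
      stop("need at least 2 samples to fit a covariance", call. = FALSE)
    if (!all(is.finite(m)))
      stop("sample matrix contains non-finite values", call. = FALSE)
    mu <- rowMeans(m)
    xb <- m - mu
  }
  n <- ncol(xb)
  omega <- tcrossprod(xb) / n
  e <- eigen(omega, symmetric = TRUE)   # eigenvalues already descending
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in 1:4) {                      # deterministic sign convention
    p <- which.max(abs(vecs[, j]))
    if (vecs[p, j] < 0) vecs[, j] <- -vecs[, j]
  }
  if (min(e$values) < max(e$values) * 1e-12)
    warning("channel covariance is (near) rank-deficient; ",
            "zero eigenvalues kept", call. = FALSE)
  structure(list(mean = unname(mu), vectors = unname(vecs),
                 values = unname(vals), n = n),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat("<pca_basis> eigenvalues:", signif(x$values, 4), "\n")
  invisible(x)
}

#' Project a 4-vector onto the leading eigenvectors
#'
#' Centers `v` by the basis channel means and projects onto the first `k`
#' eigenvectors: `z = t(U_k) %*% (v - mean)`.
#'
#' @param v Numeric 4-vector (or quaternion).
#' @param basis A `"pca_basis"`.
#' @param k Subspace dimension, integer in 1..4.
#' @return Numeric vector of length `k`.
#' @export
pca_project <- function(v, basis, k) {
  stopifnot(inherits(basis, "pca_basis"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 4L)
    stop("k must be an integer between 1 and 4", call. = FALSE)
  v <- to_vector(as_quaternion(v))
  drop(crossprod(basis$vectors[, seq_len(k), drop = FALSE], v - basis$mean))
}

#' Reconstruct a 4-vector from its projection
#'
#' Maps a length-`k` projection back to channel space and restores the
#' channel means: `v = U_k %*% z + mean`.  `reconstruct(project(v))` with
#' `k = 4` is the identity; with `k < 4` it is the affine projection onto
#' `mean + span(U_k)` (idempotent).
#'
#' @param z Numeric vector of length `k` (a projection).
#' @param basis A `"pca_basis"`.
#' @return Numeric 4-vector.
#' @export
pca_reconstruct <- function(z, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  k <- length(z)
  if (k < 1L || k > 4L)
    stop("projection length must be between 1 and 4", call. = FALSE)
  drop(basis$vectors[, seq_len(k), drop = FALSE] %*% z + basis$mean)
}

#' Denoise a quaternion median by PCA projection
#'
#' The median's 4-vector is centered by the recording's channel means,
#' projected onto the first `k` eigenvectors of the channel covariance,
#' reconstructed, and re-interpreted as a quaternion.  Components of the
#' median lying in the trailing (noise-dominated) eigendirections are
#' discarded; with `k = 4` the median is returned unchanged (up to
#' rounding).  The default `k = 1` retains only the leading
#' eigendirection, the subspace dimension found optimal by the regression
#' sweep (see [run_k_sweep()]).
#'
#' The unit medoid is handled specially because its value is constrained
#' to the unit sphere, which the affine frame `mean + span(U_k)` does not
#' intersect in general (the channel means sit at the signal's DC level,
#' far from unit modulus); centering a unit vector by the channel means
#' would move it into a frame it does not inhabit.  The noise-free
#' unit-medoid directions lie on the arc cut from the unit sphere by
#' `span(mean, u_1, ..., u_k)`, so the unit vector is orthogonally
#' projected onto that subspace and renormalized: the precise in-plane
#' direction is preserved and only the noise-dominated out-of-plane
#' components are discarded.  With `k = 4` this too is the identity.
#'
#' @param med A `"median_result"` (from the same recording `basis` was fit
#'   on).
#' @param basis A `"pca_basis"`.
#' @param k Subspace dimension in 1..4 (default 1).
#' @return A `"median_result"` with the same `kind`, `denoised = TRUE`, and
#'   `objective` cleared (the value no longer minimizes the original
#'   criterion).
#' @export
denoise_median <- function(med, basis, k = 1L) {
  stopifnot(inherits(med, "median_result"))
  if (med$kind == "unit-medoid") {
    kk <- as.integer(k)
    if (length(kk) != 1L || is.na(kk) || kk < 1L || kk > 4L)
      stop("k must be an integer between 1 and 4", call. = FALSE)
    u <- to_vector(med$value)
    b <- cbind(basis$mean, basis$vectors[, seq_len(kk), drop = FALSE])
    sv <- svd(b)
    q <- sv$u[, sv$d > max(sv$d) * 1e-10, drop = FALSE]
    v <- drop(q %*% crossprod(q, u))
    n2 <- sqrt(sum(v^2))
    v <- if (n2 < 1e-12) u else v / n2   # u orthogonal to the frame: no-op
  } else {
    v <- pca_reconstruct(pca_project(med$value, basis, k), basis)
  }
  new_median_result(as_quaternion(v), med$kind,
                    iterations = med$iterations, index = med$index,
                    converged = med$converged, denoised = TRUE,
                    source = med$source)
}
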
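#' @useDynLib qmedppg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

new_median_result <- function(value, kind, objective = NA_real_,
                              iterations = 0L, index = NA_integer_,
                              converged = TRUE, denoised = FALSE,
                              source = NULL) {
  structure(list(value = value, kind = kind, objective = objective,
                 iterations = as.integer(iterations),
                 index = as.integer(index),
                 converged = converged, denoised = denoised,
                 source = source),
            class = "median_result")
}

#' @export
print.median_result <- function(x, ...) {
  v <- to_vector(x$value)
  cat(sprintf("<median_result: %s%s> (%g, %g, %g, %g)",
              x$kind, if (x$denoised) ", denoised" else "",
              v[1], v[2], v[3], v[4]))
  if (!is.na(x$objective)) cat(sprintf("  objective = %g", x$objective))
  cat("\n")
  invisible(x)
}

#' Component-wise quaternion median
#'
#' Applies the scalar median independently to the `r`, `x`, `y`, `z`
#' components of the sequence.  For even-length sequences each scalar
#' median is the mean of the two central order statistics.  The result need
#' not be an element of the sequence.
#'
#' @param s A quaternion sequence (anything accepted by [as_quat_seq()]).
#' @return A `"median_result"` with `kind = "component-wise"`.  Its
#'   `objective` is `NA`: this estimator is not defined through a
#'   cumulative-distance criterion.
#' @export
median_componentwise <- function(s) {
  m <- as_quat_seq(s)
  v <- apply(m, 2L, stats::median)
  new_median_result(as_quaternion(v), "component-wise")
}

#' Quaternion medoid
#'
#' The sequence element minimizing the cumulative sign-ambiguous distance
#' [qdist()] to all elements, found by exhaustive O(n^2) evaluation
#' (compiled).  Ties are broken by the lowest index.
#'
#' @inheritParams median_componentwise
#' @return A `"median_result"` with `kind = "medoid"`; `value` is exactly an
#'   element of the sequence, `index` its (first) position, `objective` the
#'   minimized cumulative distance.
#' @export
median_medoid <- function(s) {
  m <- as_quat_seq(s)
  obj <- medoid_objectives_cpp(unclass(m))
  i <- which.min(obj)                       # which.min takes the lowest index
  new_median_result(as_quaternion(m[i, ]), "medoid",
                    objective = obj[i], index = i)
}

#' Quaternion unit medoid
#'
#' Each element is first normalized to unit modulus (quaternions on the
#' unit sphere describe rotations); the medoid of the normalized sequence
#' is then found under the same sign-ambiguous distance.  Zero-modulus
#' elements cannot be normalized and are dropped with a warning; if every
#' element is zero the input is degenerate and an error is raised.
#'
#' @inheritParams median_componentwise
#' @return A `"median_result"` with `kind = "unit-medoid"`; `value` is the
#'   normalized winner (unit modulus), `index` its position in the
#'   *original* sequence, `objective` the cumulative distance over the
#'   normalized sequence, and `source` the winning element *before*
#'   normalization (used by [denoise_median()], whose PCA frame lives in
#'   un-normalized signal space).
#' @export
median_unit_medoid <- function(s) {
  m <- as_quat_seq(s)
  norms <- sqrt(rowSums(m^2))
  keep <- which(norms > 0)
  if (length(keep) == 0L)
    stop("unit medoid undefined: all elements have zero modulus",
         call. = FALSE)
  if (length(keep) < nrow(m))
    warning(sprintf("dropping %d zero-modulus element(s) before normalization",
                    nrow(m) - length(keep)), call. = FALSE)
  u <- m[keep, , drop = FALSE] / norms[keep]
  obj <- medoid_objectives_cpp(unclass(u))
  i <- which.min(obj)
  new_median_result(as_quaternion(u[i, ]), "unit-medoid",
                    objective = obj[i], index = keep[i],
                    source = as_quaternion(m[keep[i], ]))
}

#' Quaternion geometric median
#'
#' Minimizes the cumulative sign-ambiguous distance over *all* quaternions
#' (not only sequence elements) by a sign-aligned Weiszfeld iteration: at
#' each step the sign of every element is chosen to be nearest the current
#' estimate, then the classical inverse-distance-weighted update is applied
#' to the aligned points.  When the estimate lands on (or starts at) a data
#' point the Vardi-Zhang rule is used: the point is optimal if the norm of
#' the subgradient of the remaining terms does not exceed the multiplicity
#' of the coincident point, otherwise a damped step moves off it.
#'
#' The iteration starts from the component-wise median of the sequence
#' sign-aligned to its largest-modulus element.  Because the
#' sign-ambiguous objective is non-convex (each term picks the nearer of
#' `q_i` and `-q_i`), short unstructured sequences can have several local
#' basins; for `n <= multistart_below` the iteration is therefore rerun
#' from every aligned sequence element and from a deterministic Halton
#' quasi-random grid over the aligned bounding box, keeping the best
#' solution.  Long physiological sequences are strongly collinear and a
#' single start suffices.  In all cases, if the converged objective
#' exceeds the medoid's the iteration is restarted from the medoid (whose
#' objective upper bounds the optimum over sequence elements); the
#' returned objective never exceeds the medoid objective.
#'
#' @inheritParams median_componentwise
#' @param tol Convergence tolerance on the norm of successive iterates
#'   (default `1e-9`).
#' @param max_iter Maximum number of Weiszfeld iterations (default 1000).
#'   Non-convergence sets `converged = FALSE` on the result (no error).
#' @param multistart_below Sequences shorter than this get the multi-start
#'   treatment (default 50); set to 0 to force a single start.
#' @return A `"median_result"` with `kind = "geometric"`, the iteration
#'   count of the winning run, and the objective at the solution.
#' @export
median_geometric <- function(s, tol = 1e-9, max_iter = 1000L,
                             multistart_below = 50L) {
  m <- as_quat_seq(s)
  stopifnot(tol > 0, max_iter >= 1)
  ref <- m[which.max(rowSums(m^2)), ]
  aligned0 <- align_signs(m, ref)
  starts <- matrix(apply(aligned0, 2L, stats::median), nrow = 1L)
  if (nrow(m) <= multistart_below) {
    lo <- apply(aligned0, 2L, min)
    hi <- apply(aligned0, 2L, max)
    grid <- sweep(sweep(halton_grid(128L), 2L, hi - lo, "*"), 2L, lo, "+")
    starts <- rbind(starts, aligned0, grid)
  }
  run <- NULL
  for (i in seq_len(nrow(starts))) {
    r <- weiszfeld_signed(m, starts[i, ], tol, max_iter)
    if (is.null(run) || r$objective < run$objective) run <- r
  }

  med <- median_medoid(m)
  if (run$objective > med$objective) {
    run2 <- weiszfeld_signed(m, to_vector(med$value), tol, max_iter)
    if (run2$objective < run$objective) run <- run2
    if (run$objective > med$objective)  # never worse than the medoid
      run <- list(x = to_vector(med$value), objective = med$objective,
                  iterations = run$iterations, converged = run$converged)
  }
  new_median_result(as_quaternion(run$x), "geometric",
                    objective = run$objective,
                    iterations = run$iterations, converged = run$converged)
}

# First `n` points of the 4-D Halton sequence (bases 2, 3, 5, 7) in
# [0, 1]^4: a deterministic low-discrepancy start grid.
halton_grid <- function(n) {
  one <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) { f <- f / base; r <- r + f * (i %% base); i <- i %/% base }
    r
  }
  vapply(c(2, 3, 5, 7),
         function(b) vapply(seq_len(n), one, numeric(1), base = b),
         numeric(n))
}

# Sign-aligned Weiszfeld with the Vardi-Zhang safeguard.
weiszfeld_signed <- function(m, x, tol, max_iter) {
  n <- nrow(m)
  iter <- 0L
  converged <- FALSE
  eps <- 1e-12
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- align_signs(m, x)
    d <- sqrt(rowSums(sweep(p, 2L, x)^2))
    at <- d < eps
    if (any(at)) {
      eta <- sum(at)                     # multiplicity of the coincident point
      if (all(at)) { converged <- TRUE; break }
      w <- 1 / d[!at]
      rtil <- colSums((p[!at, , drop = FALSE] - rep(x, each = n - eta)) * w)
      rn <- sqrt(sum(rtil^2))
      if (rn <= eta) { converged <- TRUE; break }   # x is optimal
      ttil <- colSums(p[!at, , drop = FALSE] * w) / sum(w)
      xn <- (1 - eta / rn) * ttil + (eta / rn) * x
    } else {
      w <- 1 / d
      xn <- colSums(p * w) / sum(w)
    }
    if (sqrt(sum((xn - x)^2)) < tol) { x <- xn; converged <- TRUE; break }
    x <- xn
  }
  list(x = x, objective = cumulative_qdist(x, m),
       iterations = iter, converged = converged)
}

#' Brute-force geometric-median search (test oracle)
#'
#' Independent check on [median_geometric()] for small sequences: dense
#' random sampling in the bounding box of the sign-aligned sequence,
#' followed by Nelder-Mead refinement of the best candidates and of the
#' aligned component-wise median and centroid.  Deliberately ignorant of
#' the Weiszfeld update; intended for n <= 50.
#'
#' Consumes the R random number stream; seed it for reproducibility.
#'
#' @inheritParams median_componentwise
#' @param resolution Target accuracy of the search (controls refinement
#'   tolerance; default `1e-6`).
#' @param n_samples Number of random candidate points (default 2000).
#' @return The approximate minimizer as a `"quaternion"`, with the attained
#'   objective in attribute `"objective"`.
#' @export
geometric_median_oracle <- function(s, resolution = 1e-6, n_samples = 4000L) {
  m <- as_quat_seq(s)
  if (nrow(m) > 50L)
    stop("oracle is for small sequences (n <= 50)", call. = FALSE)
  ref <- m[which.max(rowSums(m^2)), ]
  a <- align_signs(m, ref)
  lo <- apply(a, 2L, min); hi <- apply(a, 2L, max)
  span <- pmax(hi - lo, 1e-8)
  cand <- matrix(stats::runif(4L * n_samples,
                              rep(lo - 0.1 * span, each = n_samples),
                              rep(hi + 0.1 * span, each = n_samples)),
                 ncol = 4L)
  cand <- rbind(cand, apply(a, 2L, stats::median), colMeans(a), a)
  # score all candidates at once: d(c, q)^2 = |c|^2 + |q|^2 - 2 |<c, q>|
  g <- abs(tcrossprod(cand, unclass(m)))
  d2 <- outer(rowSums(cand^2), rowSums(m^2), "+") - 2 * g
  vals <- rowSums(sqrt(pmax(d2, 0)))
  f <- function(x) cumulative_qdist(x, m)
  starts <- cand[order(vals)[1:8], , drop = FALSE]
  best <- NULL; bestval <- Inf
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], f, method = "Nelder-Mead",
                      control = list(reltol = resolution * 1e-3,
                                     maxit = 5000L))
    if (o$value < bestval) { bestval <- o$value; best <- o$par }
  }
  out <- as_quaternion(best)
  attr(out, "objective") <- bestval
  out
}
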
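#' Construct a quaternion
#'
#' A quaternion `q = r + x i + y j + z k` is stored as a length-4 numeric
#' vector with components named `r`, `x`, `y`, `z`.  Each time sample of a
#' four-channel PPG recording maps to one quaternion: channel 1 to the real
#' part `r`, channels 2--4 to the imaginary parts `x`, `y`, `z`.  This
#' channel-to-component assignment is an arbitrary but fixed convention;
#' any relabelling gives an equivalent representation.
#'
#' @param r,x,y,z Real, i-, j- and k-components (finite numerics).
#' @return An object of class `"quaternion"`.
#' @examples
#' quat(1, 1, 0, 0)           # 1 + i
#' qmul(quat(0, 1, 0, 0), quat(0, 0, 1, 0))  # i * j = k
#' @export
quat <- function(r = 0, x = 0, y = 0, z = 0) {
  q <- c(r = as.numeric(r), x = as.numeric(x),
         y = as.numeric(y), z = as.numeric(z))
  if (length(q) != 4L || !all(is.finite(q)))
    stop("quaternion components must be four finite numbers", call. = FALSE)
  structure(q, class = "quaternion")
}

#' Coerce a length-4 vector to a quaternion
#'
#' The inverse of [to_vector()]: entry 1 becomes the real part, entries
#' 2--4 the i, j, k parts.  `from_channels()` is an alias emphasising the
#' channel-sample reading.
#'
#' @param v Numeric vector of length 4 with finite entries, or a quaternion.
#' @return A `"quaternion"`.
#' @export
as_quaternion <- function(v) {
  if (inherits(v, "quaternion")) return(v)
  v <- as.numeric(v)
  if (length(v) != 4L)
    stop("expected exactly 4 components, got ", length(v), call. = FALSE)
  if (!all(is.finite(v)))
    stop("quaternion components must be finite", call. = FALSE)
  quat(v[1], v[2], v[3], v[4])
}

#' @rdname as_quaternion
#' @export
from_channels <- as_quaternion

#' Quaternion to plain 4-vector
#'
#' @param q A quaternion.
#' @return Numeric vector `c(r, x, y, z)`; `to_vector(from_channels(v))`
#'   returns `v` exactly.
#' @export
to_vector <- function(q) {
  unname(unclass(as_quaternion(q)))
}

#' @export
print.quaternion <- function(x, digits = getOption("digits"), ...) {
  v <- signif(unclass(x), digits)
  cat(sprintf("<quaternion> %g %+gi %+gj %+gk\n", v[1], v[2], v[3], v[4]))
  invisible(x)
}

#' Hamilton product of two quaternions
#'
#' Non-commutative multiplication obeying `ij = k`, `jk = i`, `ki = j`,
#' `ji = -k`, `kj = -i`, `ik = -j` and `i^2 = j^2 = k^2 = ijk = -1`.
#'
#' @param a,b Quaternions (or length-4 vectors).
#' @return The product `a * b` as a `"quaternion"`.
#' @export
qmul <- function(a, b) {
  a <- as_quaternion(a); b <- as_quaternion(b)
  quat(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
       a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
       a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
       a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion modulus (norm)
#'
#' Euclidean norm of the 4-vector `(r, x, y, z)`; multiplicative over the
#' Hamilton product.  Named after `Mod()` for complex numbers to avoid
#' clashing with the normal quantile function.
#'
#' @param q A quaternion (or length-4 vector).
#' @return Nonnegative scalar; zero iff `q` is the zero quaternion.
#' @export
qmod <- function(q) {
  sqrt(sum(to_vector(q)^2))
}

#' Normalize a quaternion to unit modulus
#'
#' @param q A nonzero quaternion.
#' @return `q / qmod(q)`, a unit quaternion.
#' @export
qunit <- function(q) {
  q <- as_quaternion(q)
  n <- qmod(q)
  if (n == 0)
    stop("cannot normalize the zero quaternion", call. = FALSE)
  as_quaternion(unclass(q) / n)
}

#' Sign-ambiguous quaternion distance
#'
#' `d(a, b) = min(||a - b||, ||a + b||)`: the quaternions `q` and `-q` are
#' identified (they encode the same rotation), so the distance is invariant
#' under negating either argument.  This is the distance underlying all the
#' median estimators in this package.
#'
#' @param a,b Quaternions (or length-4 vectors).
#' @return Nonnegative scalar, symmetric in its arguments.
#' @export
qdist <- function(a, b) {
  av <- to_vector(a); bv <- to_vector(b)
  min(sqrt(sum((av - bv)^2)), sqrt(sum((av + bv)^2)))
}

#' A quaternion-valued sequence
#'
#' A recording viewed as an ordered sequence of quaternions `q1, ..., qn`,
#' stored as an `n x 4` matrix with columns `r`, `x`, `y`, `z` (row order =
#' time order).
#'
#' @param x An `n x 4` numeric matrix, a list of quaternions/4-vectors, or a
#'   [ppg_recording()] (whose 4 channels become the 4 components).
#' @return An object of class `"quat_seq"` (an `n x 4` matrix).
#' @export
as_quat_seq <- function(x) {
  if (inherits(x, "quat_seq")) return(x)
  if (inherits(x, "ppg_recording")) {
    m <- t(x$samples)
  } else if (is.list(x)) {
    m <- do.call(rbind, lapply(x, to_vector))
  } else if (is.matrix(x)) {
    m <- x
  } else if (is.numeric(x) && length(x) == 4L) {
    m <- matrix(x, nrow = 1L)
  } else {
    stop("cannot interpret input as a quaternion sequence", call. = FALSE)
  }
  if (ncol(m) != 4L)
    stop("a quaternion sequence needs 4 columns, got ", ncol(m), call. = FALSE)
  if (nrow(m) < 1L)
    stop("a quaternion sequence needs at least one element", call. = FALSE)
  if (!all(is.finite(m)))
    stop("quaternion sequence contains non-finite values", call. = FALSE)
  dimnames(m) <- list(NULL, c("r", "x", "y", "z"))
  structure(m, class = c("quat_seq", "matrix"))
}

#' @export
print.quat_seq <- function(x, ...) {
  cat(sprintf("<quat_seq> %d quaternions\n", nrow(x)))
  invisible(x)
}

# Flip signs of rows so each is as close as possible to `ref` (4-vector):
# s_i = sign(<q_i, ref>), zero dot products kept positive.
align_signs <- function(m, ref) {
  s <- sign(as.vector(m %*% ref))
  s[s == 0] <- 1
  m * s
}

# Sum over rows of min(||x - q_i||, ||x + q_i||) for a 4-vector x.
cumulative_qdist <- function(x, m) {
  dm <- sweep(m, 2L, x)
  dp <- sweep(m, 2L, x, FUN = "+")
  sum(sqrt(pmin(rowSums(dm^2), rowSums(dp^2))))
}
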
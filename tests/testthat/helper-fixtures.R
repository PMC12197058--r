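# Shared fixture helpers.  All randomness is drawn after an explicit
# set.seed() inside each test; these helpers only shape the draws.

rand_quat <- function() quat(rnorm(1), rnorm(1), rnorm(1), rnorm(1))

rand_seq <- function(n) as_quat_seq(matrix(rnorm(4 * n), ncol = 4))

# Reference cumulative sign-ambiguous distance, written independently of
# the package internals (scalar loop over qdist).
cum_dist_ref <- function(x, s) {
  m <- unclass(as_quat_seq(s))
  sum(vapply(seq_len(nrow(m)),
             function(i) qdist(as_quaternion(x), as_quaternion(m[i, ])),
             numeric(1)))
}

# Small synthetic recording helpers used across pipeline/pca tests.
tiny_config <- function(...) {
  generator_config(duration_s = 20, ...)    # 4 x 1000 at 50 Hz
}
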
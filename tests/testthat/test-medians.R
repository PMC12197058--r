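test_that("component-wise median sorts each component independently", {
  q <- quat(2, -1, 0.5, 3)
  expect_equal(to_vector(median_componentwise(list(q))$value), to_vector(q))
  expect_equal(to_vector(median_componentwise(list(q, q, q))$value),
               to_vector(q))
  # components {1,3,2} and {2,0,9}: medians 2 and 2
  s <- as_quat_seq(rbind(c(1, 2, 0, 0), c(3, 0, 0, 0), c(2, 9, 0, 0)))
  expect_equal(to_vector(median_componentwise(s)$value), c(2, 2, 0, 0))
  # even length: mean of the two central order statistics
  s2 <- as_quat_seq(rbind(c(0, 10, 0, 0), c(1, 20, 0, 0)))
  expect_equal(to_vector(median_componentwise(s2)$value), c(0.5, 15, 0, 0))
})

test_that("component-wise median is translation equivariant", {
  set.seed(11)
  for (rep in 1:20) {
    m <- matrix(rnorm(4 * 9), ncol = 4)
    shift <- rnorm(4)
    lhs <- to_vector(median_componentwise(
      as_quat_seq(sweep(m, 2, shift, "+")))$value)
    rhs <- to_vector(median_componentwise(as_quat_seq(m))$value) + shift
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("medoid minimizes cumulative distance over sequence elements", {
  r1 <- median_medoid(list(quat(3, 1, 4, 1)))
  expect_equal(to_vector(r1$value), c(3, 1, 4, 1))
  expect_identical(r1$objective, 0)
  expect_identical(r1$index, 1L)
  # {0, 1, 10} on the real axis: objectives 11, 10, 19
  s <- as_quat_seq(rbind(c(0, 0, 0, 0), c(1, 0, 0, 0), c(10, 0, 0, 0)))
  r <- median_medoid(s)
  expect_equal(to_vector(r$value), c(1, 0, 0, 0))
  expect_equal(r$objective, 10, tolerance = 1e-12)
  expect_identical(r$index, 2L)
  # {q, -q, p}: q and -q tie at distance 0 + d(q,p); lowest index wins
  set.seed(12)
  q <- rand_quat(); p <- rand_quat()
  rt <- median_medoid(list(q, as_quaternion(-to_vector(q)), p))
  expect_identical(rt$index, 1L)
  expect_equal(to_vector(rt$value), to_vector(q))
})

test_that("medoid objective matches an independent pairwise evaluation", {
  set.seed(13)
  for (rep in 1:10) {
    s <- rand_seq(sample(2:12, 1))
    r <- median_medoid(s)
    expect_identical(unname(unclass(s)[r$index, ]), to_vector(r$value))
    expect_equal(r$objective, cum_dist_ref(to_vector(r$value), s),
                 tolerance = 1e-9)
    # no element does better
    objs <- apply(unclass(s), 1, cum_dist_ref, s = s)
    expect_equal(r$objective, min(objs), tolerance = 1e-9)
  }
})

test_that("unit medoid normalizes before the search and maps back its index", {
  # {2i, 3i, 1} normalizes to {i, i, 1}: objective at i is sqrt(2), at 1 2*sqrt(2)
  s <- as_quat_seq(rbind(c(0, 2, 0, 0), c(0, 3, 0, 0), c(1, 0, 0, 0)))
  r <- median_unit_medoid(s)
  expect_equal(to_vector(r$value), c(0, 1, 0, 0), tolerance = 1e-12)
  expect_equal(r$objective, sqrt(2), tolerance = 1e-12)
  expect_identical(r$index, 1L)
  expect_equal(to_vector(r$source), c(0, 2, 0, 0))
  # all positive reals collapse to 1
  sr <- as_quat_seq(rbind(c(2, 0, 0, 0), c(7, 0, 0, 0)))
  expect_equal(to_vector(median_unit_medoid(sr)$value), c(1, 0, 0, 0))
  # single element 5j
  expect_equal(to_vector(median_unit_medoid(list(quat(0, 0, 5, 0)))$value),
               c(0, 0, 1, 0))
})

test_that("unit medoid drops zero elements with a warning, errors when all zero", {
  s <- as_quat_seq(rbind(c(0, 0, 0, 0), c(0, 2, 0, 0), c(0, 3, 0, 0)))
  expect_warning(r <- median_unit_medoid(s), "zero-modulus")
  expect_equal(to_vector(r$value), c(0, 1, 0, 0), tolerance = 1e-12)
  expect_identical(r$index, 2L)   # index in the original sequence
  expect_error(
    suppressWarnings(median_unit_medoid(as_quat_seq(matrix(0, 2, 4)))),
    "all elements")
})

test_that("geometric median solves hand-checkable configurations", {
  set.seed(14)
  q <- rand_quat()
  r <- median_geometric(list(q, q, q))
  expect_equal(to_vector(r$value), to_vector(q), tolerance = 1e-9)
  # majority point dominates: two copies of q pin the solution at q
  p <- as_quaternion(to_vector(q) + c(3, -2, 1, 0.5))
  rm <- median_geometric(list(q, q, p))
  expect_equal(to_vector(rm$value), to_vector(q), tolerance = 1e-6)
  # {1, i, j} is an equilateral triangle (pairwise distance sqrt(2)):
  # its geometric median is the centroid (1 + i + j)/3
  tri <- list(quat(1), quat(0, 1, 0, 0), quat(0, 0, 1, 0))
  rt <- median_geometric(tri)
  expect_equal(to_vector(rt$value), c(1, 1, 1, 0) / 3, tolerance = 1e-6)
  expect_true(rt$converged)
})

test_that("geometric median never exceeds the medoid objective", {
  set.seed(15)
  for (rep in 1:25) {
    s <- rand_seq(sample(3:15, 1))
    g <- median_geometric(s)
    o <- median_medoid(s)
    expect_lte(g$objective, o$objective)
    expect_equal(g$objective, cum_dist_ref(to_vector(g$value), s),
                 tolerance = 1e-9)
  }
})

test_that("geometric median agrees with the brute-force oracle", {
  set.seed(16)
  for (rep in 1:10) {
    s <- rand_seq(sample(3:12, 1))
    g <- median_geometric(s)
    orc <- geometric_median_oracle(s)
    expect_lt(abs(g$objective - attr(orc, "objective")) /
                attr(orc, "objective"), 1e-3)
  }
  # point cases
  q <- rand_quat()
  orc1 <- geometric_median_oracle(list(q))
  expect_equal(attr(orc1, "objective"), 0, tolerance = 1e-8)
})

test_that("medians are invariant under sequence reversal (up to ties)", {
  set.seed(17)
  m <- matrix(rnorm(4 * 11), ncol = 4)
  s <- as_quat_seq(m)
  sr <- as_quat_seq(m[11:1, ])
  expect_equal(to_vector(median_componentwise(s)$value),
               to_vector(median_componentwise(sr)$value), tolerance = 1e-12)
  expect_equal(to_vector(median_medoid(s)$value),
               to_vector(median_medoid(sr)$value), tolerance = 1e-12)
  expect_equal(to_vector(median_unit_medoid(s)$value),
               to_vector(median_unit_medoid(sr)$value), tolerance = 1e-12)
  expect_equal(median_geometric(s)$objective,
               median_geometric(sr)$objective, tolerance = 1e-9)
})

test_that("distance-based medians resist a diverging outlier, the mean does not", {
  set.seed(18)
  q <- quat(1, -0.5, 2, 0.3)
  base <- do.call(rbind, replicate(9, to_vector(q), simplify = FALSE))
  for (mag in c(10, 1e3, 1e6)) {
    s <- as_quat_seq(rbind(base, mag * c(1, 1, 1, 1)))
    expect_equal(to_vector(median_medoid(s)$value), to_vector(q),
                 tolerance = 1e-12)
    expect_lt(qdist(median_geometric(s)$value, q), 1e-6)
    cm <- colMeans(unclass(s))
    expect_gt(sqrt(sum((cm - to_vector(q))^2)), mag / 20)
  }
})

test_that("non-convergence within max_iter is flagged, not raised", {
  set.seed(19)
  s <- rand_seq(8)
  r <- median_geometric(s, tol = 1e-16, max_iter = 2L)
  expect_false(r$converged)
  expect_s3_class(r, "median_result")
})
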
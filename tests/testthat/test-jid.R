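# JID estimation: pairing, kernel correctness against closed forms and a
# brute-force oracle, normalisation, averaging, differencing.

test_that("make_pairs builds overlapping consecutive pairs", {
  p <- make_pairs(c(0.1, 0.2, 0.4))
  expect_equal(unname(p), cbind(c(0.1, 0.2), c(0.2, 0.4)))
  expect_identical(nrow(make_pairs(5.0)), 0L)
  set.seed(1)
  x <- 10^rnorm(57)
  p <- make_pairs(x)
  expect_identical(nrow(p), 56L)
  expect_equal(p[-1, 1], p[-56, 2])
  expect_error(make_pairs(c(1, 0, 2)), "> 0")
})

test_that("grid construction validates and spaces edges uniformly", {
  g <- jid_grid()
  expect_equal(g$n_bins, 50L)
  expect_equal(g$edges, g$lo + (0:50) * (g$hi - g$lo) / 50)
  expect_equal(g$lo, log10(0.03))
  expect_equal(g$hi, 2)
  expect_error(jid_grid(lo = 2, hi = 1), "exceed")
  expect_error(jid_grid(bandwidth = 0), "bandwidth")
  expect_error(jid_grid(n_bins = 1), "n_bins")
})

test_that("a single pair reproduces the analytic discretised Gaussian", {
  g <- jid_grid()
  c0 <- g$centers[20]; c1 <- g$centers[33]
  j <- compute_jid(cbind(10^c0, 10^c1), g)
  analytic <- outer(dnorm(g$centers, c0, g$bandwidth),
                    dnorm(g$centers, c1, g$bandwidth))
  analytic <- analytic / sum(analytic)
  expect_lt(max(abs(j$matrix - analytic)), 1e-8)
  # weighted marginal sd of the probability mass recovers the bandwidth
  pk <- rowSums(j$matrix)
  mu <- sum(pk * g$centers)
  expect_equal(sqrt(sum(pk * (g$centers - mu)^2)), 0.1, tolerance = 0.05)
})

test_that("a pair at the grid midpoint is symmetric under 180-degree rotation", {
  g <- jid_grid()
  mid <- (g$lo + g$hi) / 2
  m <- compute_jid(cbind(10^mid, 10^mid), g)$matrix
  expect_equal(m, m[50:1, 50:1])
})

test_that("duplicated pairs and pair order do not change the JID", {
  g <- jid_grid()
  one <- compute_jid(cbind(0.5, 2), g)
  two <- compute_jid(cbind(c(0.5, 0.5), c(2, 2)), g)
  expect_equal(two$matrix, one$matrix)

  set.seed(3)
  pairs <- make_pairs(10^runif(30, -1.3, 1.8))
  perm <- pairs[sample(nrow(pairs)), ]
  expect_equal(compute_jid(perm, g)$matrix, compute_jid(pairs, g)$matrix,
               tolerance = 1e-12)
})

test_that("compute_jid matches the brute-force double loop for small inputs", {
  g <- jid_grid()
  set.seed(7)
  for (n in c(2, 9, 20)) {
    pairs <- make_pairs(10^runif(n + 1, -1.4, 1.9))
    expect_lt(max(abs(compute_jid(pairs, g)$matrix -
                        oracle_jid_matrix(pairs, g))), 1e-10)
  }
})

test_that("normalisation modes: unit mass and unit integral", {
  set.seed(11)
  pairs <- make_pairs(10^runif(200, -1.2, 1.7))
  jm <- compute_jid(pairs)
  expect_equal(sum(jm$matrix), 1, tolerance = 1e-9)
  jd <- compute_jid(pairs, normalization = "density")
  binw <- (jd$grid$hi - jd$grid$lo) / jd$grid$n_bins
  expect_equal(sum(jd$matrix) * binw^2, 1, tolerance = 1e-9)
  expect_true(all(jm$matrix >= 0))
})

test_that("shrinking bandwidth concentrates mass at the pair's bin", {
  peaks <- vapply(c(0.2, 0.1, 0.05, 0.025), function(bw) {
    g <- jid_grid(bandwidth = bw)
    max(compute_jid(cbind(10^g$centers[25], 10^g$centers[25]), g)$matrix)
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("empty and far-out-of-grid inputs are flagged", {
  g <- jid_grid()
  expect_error(compute_jid(make_pairs(numeric(0)), g), "empty")
  expect_warning(compute_jid(cbind(1e4, 1e4), g), "degenerate")
  j <- suppressWarnings(compute_jid(cbind(c(0.5, 1e4), c(0.5, 1e4)), g))
  expect_equal(j$out_of_grid, 0.5)
})

test_that("average_jid is the element-wise mean with pooled pair counts", {
  a <- random_jid(seed = 1); b <- random_jid(seed = 2)
  expect_equal(average_jid(list(a))$matrix, a$matrix)
  expect_equal(average_jid(list(a, a))$matrix, a$matrix)
  m1 <- matrix(0, 50, 50); m1[3, 3] <- 1
  m2 <- matrix(0, 50, 50); m2[40, 41] <- 1
  avg <- average_jid(list(manual_jid(m1), manual_jid(m2)))
  expect_equal(avg$matrix[3, 3], 0.5)
  expect_equal(avg$matrix[40, 41], 0.5)
  expect_equal(sum(avg$matrix), 1)
  expect_equal(average_jid(list(a, b))$n_pairs, a$n_pairs + b$n_pairs)
  g2 <- jid_grid(n_bins = 25)
  expect_error(average_jid(list(a, random_jid(g2, seed = 3))), "mismatch")
})

test_that("jid_difference conserves mass and detects grid mismatch", {
  a <- random_jid(seed = 4); b <- random_jid(seed = 5)
  expect_equal(jid_difference(a, a)$matrix, matrix(0, 50, 50))
  expect_equal(sum(jid_difference(a, b)$matrix), 0, tolerance = 1e-9)
  expect_error(jid_difference(a, random_jid(jid_grid(n_bins = 10), seed = 6)),
               "mismatch")
  q <- quadrant_mass(jid_difference(a, b))
  expect_equal(sum(q), 0, tolerance = 1e-9)
})
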
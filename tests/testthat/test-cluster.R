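# Bin-wise t-maps, connected components, and the max-cluster-size
# permutation test: scalar oracles, label symmetry, determinism.

fabricated_tmap <- function(tv, df = 10, zero = NULL) {
  g <- jid_grid()
  structure(list(grid = g, t_values = tv, df = df, n_a = 6L, n_b = 6L,
                 var_equal = TRUE,
                 zero_variance = if (is.null(zero))
                   matrix(FALSE, 50, 50) else zero),
            class = "jid_tmap")
}

test_that("bin-wise t equals the textbook two-sample t, pooled and Welch", {
  a <- lapply(1:4, function(i) random_jid(seed = i))
  b <- lapply(11:14, function(i) random_jid(seed = i))
  av <- vapply(a, function(j) j$matrix[10, 10], numeric(1))
  bv <- vapply(b, function(j) j$matrix[10, 10], numeric(1))
  tm <- binwise_tmap(a, b)
  expect_equal(tm$t_values[10, 10],
               unname(t.test(av, bv, var.equal = TRUE)$statistic))
  expect_equal(tm$df, 6)
  tw <- binwise_tmap(a, b, var_equal = FALSE)
  wt <- t.test(av, bv)
  expect_equal(tw$t_values[10, 10], unname(wt$statistic))
  expect_equal(tw$df[10, 10], unname(wt$parameter))
})

test_that("identical groups give an all-zero t-map and no clusters", {
  a <- lapply(1:3, function(i) random_jid(seed = i))
  tm <- binwise_tmap(a, a)
  expect_equal(tm$t_values, matrix(0, 50, 50))
  expect_length(form_clusters(tm), 0L)
})

test_that("an isolated single-bin effect dominates the t-map", {
  set.seed(20)
  mk <- function(shift) {
    m <- matrix(1 / 2500, 50, 50) + matrix(rnorm(2500, 0, 1e-6), 50)
    m[25, 25] <- m[25, 25] + shift
    manual_jid(m)
  }
  a <- lapply(rep(1e-3, 4), mk)
  b <- lapply(rep(0, 4), mk)
  tm <- binwise_tmap(a, b)
  expect_equal(which.max(abs(tm$t_values)), (25L - 1L) * 50L + 25L)
  expect_gt(tm$t_values[25, 25], 0)
})

test_that("zero-variance bins are flagged and excluded from clusters", {
  mk <- function(v) {
    m <- matrix(0, 50, 50)
    m[1:10, 1:10] <- v  # all other bins constant zero across both groups
    manual_jid(m)
  }
  a <- lapply(c(1, 1.1, 0.9), mk)
  b <- lapply(c(2, 2.2, 1.8), mk)
  tm <- binwise_tmap(a, b)
  expect_true(all(tm$zero_variance[11:50, 11:50]))
  expect_equal(tm$t_values[40, 40], 0)
  cl <- form_clusters(tm)
  if (length(cl))
    for (c_ in cl) expect_true(all(c_$member_bins[, 1] <= 10))
})

test_that("hand-drawn masks produce the drawn clusters", {
  tv <- matrix(0, 50, 50)
  tv[2:4, 2] <- 5                 # positive blob, size 3
  tv[10, 10:14] <- 5              # positive blob, size 5
  tv[30:32, 30:32] <- -5          # negative blob, size 9
  cl <- form_clusters(fabricated_tmap(tv), alpha = 0.01)
  expect_equal(vapply(cl, `[[`, numeric(1), "size"), c(9, 5, 3))
  expect_equal(vapply(cl, `[[`, numeric(1), "sign"), c(-1, 1, 1))
  expect_equal(max_cluster_size(cl), 9L)
  expect_equal(max_cluster_size(list()), 0L)
  expect_length(form_clusters(fabricated_tmap(matrix(0, 50, 50))), 0L)
})

test_that("label_components agrees with the igraph oracle on random masks", {
  set.seed(99)
  for (i in 1:200) {
    dens <- runif(1, 0.05, 0.6)
    mask <- matrix(runif(2500) < dens, 50, 50)
    conn <- if (i %% 2 == 0) 4 else 8
    lab <- label_components(mask, conn)
    expect_identical(sort(tabulate(lab)),
                     as.integer(oracle_component_sizes(mask, conn)))
    expect_identical(lab != 0L, mask)
  }
})

test_that("diagonal touching distinguishes 4- from 8-connectivity", {
  mask <- matrix(FALSE, 50, 50)
  mask[cbind(c(5, 6), c(5, 6))] <- TRUE
  expect_equal(max(label_components(mask, 4)), 2L)
  expect_equal(max(label_components(mask, 8)), 1L)
})

test_that("swapping the groups negates the t-map and preserves inference", {
  a <- lapply(1:4, function(i) random_jid(seed = i))
  b <- lapply(21:23, function(i) random_jid(seed = i))
  expect_equal(binwise_tmap(a, b)$t_values, -binwise_tmap(b, a)$t_values)
  r1 <- jid_permutation_test(a, b, exhaustive = TRUE)
  r2 <- jid_permutation_test(b, a, exhaustive = TRUE)
  expect_identical(sort(r1$null_max_sizes), sort(r2$null_max_sizes))
  expect_equal(summary(r1)$size, summary(r2)$size)
  expect_equal(summary(r1)$p_value, summary(r2)$p_value)
})

test_that("the permutation null is reproducible under a fixed seed", {
  a <- lapply(1:5, function(i) random_jid(seed = i))
  b <- lapply(31:35, function(i) random_jid(seed = i))
  r1 <- jid_permutation_test(a, b, B = 80, seed = 7)
  r2 <- jid_permutation_test(a, b, B = 80, seed = 7)
  expect_identical(r1$null_max_sizes, r2$null_max_sizes)
  expect_length(r1$null_max_sizes, 80L)
  # chunking must not change results
  r3 <- jid_permutation_test(a, b, B = 80, seed = 7, chunk_size = 13)
  expect_identical(r1$null_max_sizes, r3$null_max_sizes)
})

test_that("a massive localised shift is maximally significant", {
  set.seed(55)
  base <- matrix(1 / 2500, 50, 50)
  mk <- function(shift) manual_jid(base + matrix(rnorm(2500, 0, 1e-5), 50) +
                                     shift)
  blob <- matrix(0, 50, 50); blob[20:29, 20:29] <- 0.01
  a <- lapply(1:5, function(i) mk(blob))
  b <- lapply(1:5, function(i) mk(0))
  res <- jid_permutation_test(a, b, B = 99, seed = 2)
  tab <- summary(res)
  expect_gte(max(tab$size), 100)
  expect_equal(min(tab$p_value), 1 / 100)
  expect_true(any(tab$significant))
})

test_that("group-size and feasibility preconditions are enforced", {
  a <- lapply(1:2, function(i) random_jid(seed = i))
  expect_error(binwise_tmap(a[1], a), "at least 2")
  expect_error(jid_permutation_test(a, lapply(3:4, function(i)
    random_jid(seed = i)), B = 0), "B must be")
  big <- lapply(1:15, function(i) random_jid(seed = i))
  expect_error(jid_permutation_test(big, big, exhaustive = TRUE),
               "infeasible")
})
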
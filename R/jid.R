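#' Define the JID binning grid
#'
#' A joint interval distribution (JID) lives on a square grid over
#' \eqn{\log_{10}} inter-touch intervals (ITIs) in seconds. The default grid
#' spans approximately 30 ms to 100 s with 50 bins per dimension, and the
#' default smoothing kernel is an isotropic Gaussian with standard deviation
#' 0.1 in log10 units.
#'
#' @param lo Lower grid edge in log10 seconds. Default `log10(0.03)`.
#' @param hi Upper grid edge in log10 seconds. Default `log10(100)`.
#' @param n_bins Number of bins per dimension (>= 2). Default 50.
#' @param bandwidth Gaussian kernel standard deviation in log10 units (> 0).
#'   Default 0.1.
#'
#' @return An object of class `jid_grid` with fields `lo`, `hi`, `n_bins`,
#'   `bandwidth`, plus derived `edges` (length `n_bins + 1`) and `centers`
#'   (length `n_bins`).
#' @export
#' @examples
#' g <- jid_grid()
#' g$centers[1:3]
jid_grid <- function(lo = log10(0.03), hi = log10(100), n_bins = 50L,
                     bandwidth = 0.1) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (!(hi > lo)) stop("jid_grid: 'hi' must exceed 'lo'")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("jid_grid: 'n_bins' must be >= 2")
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("jid_grid: 'bandwidth' must be > 0")
  edges <- lo + (0:n_bins) * (hi - lo) / n_bins
  structure(
    list(lo = lo, hi = hi, n_bins = n_bins, bandwidth = bandwidth,
         edges = edges, centers = (edges[-1L] + edges[-(n_bins + 1L)]) / 2),
    class = "jid_grid")
}

#' @export
print.jid_grid <- function(x, ...) {
  cat(sprintf("JID grid: %d x %d bins on [%.4f, %.4f] log10 s (bin width %.4f), kernel sd %.3f\n",
              x$n_bins, x$n_bins, x$lo, x$hi,
              (x$hi - x$lo) / x$n_bins, x$bandwidth))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$lo, b$lo)) && isTRUE(all.equal(a$hi, b$hi)) &&
    a$n_bins == b$n_bins && isTRUE(all.equal(a$bandwidth, b$bandwidth))
}

#' Form consecutive next-interval pairs
#'
#' Pairs each inter-touch interval at index k with the immediately following
#' interval at index k + 1, the two coordinates of the JID space.
#'
#' @param itis Numeric vector of ITIs in seconds; all must be > 0
#'   (the log10 transform is undefined otherwise).
#' @return A two-column matrix with columns `iti_k` and `iti_k1`;
#'   `max(length(itis) - 1, 0)` rows. Pairs overlap: (x1,x2), (x2,x3), ...
#' @export
#' @examples
#' make_pairs(c(0.1, 0.2, 0.4))
make_pairs <- function(itis) {
  itis <- as.numeric(itis)
  if (anyNA(itis)) stop("make_pairs: ITIs contain NA")
  if (any(itis <= 0)) stop("make_pairs: all ITIs must be > 0 (log10 undefined)")
  n <- length(itis)
  if (n < 2L)
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("iti_k", "iti_k1"))))
  cbind(iti_k = itis[-n], iti_k1 = itis[-1L])
}

#' Compute a joint interval distribution from ITI pairs
#'
#' Maps each pair to \eqn{(\log_{10} x_k, \log_{10} x_{k+1})}, averages
#' isotropic 2D Gaussian kernels (sd = `grid$bandwidth`) evaluated at the
#' grid's bin centers, and renormalises. Axis 1 (rows) indexes the current
#' interval ITI_k, axis 2 (columns) the next interval ITI_{k+1}; row/column 1
#' is the fastest bin.
#'
#' Kernel mass falling outside the grid is lost before renormalisation; the
#' fraction of pairs outside the grid square is recorded in the returned
#' object's `out_of_grid` field. If every pair lies further than 5 kernel sds
#' outside the grid a degenerate-density warning is raised.
#'
#' @param pairs Two-column matrix from [make_pairs()] (ITIs in seconds).
#' @param grid A [jid_grid()].
#' @param normalization `"probability_mass"` (entries sum to 1, the default)
#'   or `"density"` (entries integrate to 1 over log10-area).
#' @return An object of class `jid`: list with `grid`, `matrix`
#'   (`n_bins` x `n_bins`), `n_pairs`, `normalization`, `out_of_grid`.
#' @export
compute_jid <- function(pairs, grid = jid_grid(),
                        normalization = c("probability_mass", "density")) {
  normalization <- match.arg(normalization)
  if (!inherits(grid, "jid_grid")) stop("compute_jid: 'grid' must be a jid_grid")
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L)
    stop("compute_jid: empty pair set (caller decides whether to drop the day)")
  if (ncol(pairs) != 2L) stop("compute_jid: 'pairs' must have two columns")
  if (any(pairs <= 0)) stop("compute_jid: all ITIs must be > 0")

  lx <- log10(pairs[, 1L])
  ly <- log10(pairs[, 2L])
  n <- length(lx)
  ctr <- grid$centers
  bw <- grid$bandwidth

  inside <- lx >= grid$lo & lx <= grid$hi & ly >= grid$lo & ly <= grid$hi
  far <- (pmax(grid$lo - lx, lx - grid$hi, 0) > 5 * bw) |
         (pmax(grid$lo - ly, ly - grid$hi, 0) > 5 * bw)
  if (all(far))
    warning("compute_jid: degenerate density - every pair lies > 5 kernel sd outside the grid")

  # density at (c_i, c_j) = mean_p phi(c_i - lx_p) * phi(c_j - ly_p)
  kx <- stats::dnorm(outer(ctr, lx, "-"), sd = bw)   # n_bins x n
  ky <- stats::dnorm(outer(ctr, ly, "-"), sd = bw)
  m <- (kx %*% t(ky)) / n

  tot <- sum(m)
  if (tot > 0) {
    if (normalization == "probability_mass") {
      m <- m / tot
    } else {
      binw <- (grid$hi - grid$lo) / grid$n_bins
      m <- m / (tot * binw * binw)
    }
  }

  structure(
    list(grid = grid, matrix = m, n_pairs = n,
         normalization = normalization,
         out_of_grid = mean(!inside)),
    class = "jid")
}

#' @export
print.jid <- function(x, ...) {
  cat(sprintf("JID (%s): %d x %d bins from %d ITI pairs", x$normalization,
              x$grid$n_bins, x$grid$n_bins, x$n_pairs))
  if (x$out_of_grid > 0)
    cat(sprintf("; %.1f%% of pairs outside grid", 100 * x$out_of_grid))
  cat(sprintf("\n  mass sum %.6f, peak %.3g at bin [%s]\n", sum(x$matrix),
              max(x$matrix),
              paste(which(x$matrix == max(x$matrix), arr.ind = TRUE)[1L, ],
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.jid <- function(x, main = "Joint interval distribution", ...) {
  graphics::image(x$grid$centers, x$grid$centers, x$matrix,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = expression(log[10] ~ ITI[k] ~ "(s)"),
                  ylab = expression(log[10] ~ ITI[k + 1] ~ "(s)"),
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Average a collection of JIDs
#'
#' Element-wise unweighted mean of daily JIDs sharing a grid and
#' normalization mode; used for period-average JIDs and multi-day baselines.
#'
#' @param jids A list of `jid` objects on identical grids.
#' @return A `jid` whose matrix is the mean and whose `n_pairs` is the sum of
#'   the inputs' pair counts.
#' @export
average_jid <- function(jids) {
  if (inherits(jids, "jid")) jids <- list(jids)
  if (length(jids) == 0L) stop("average_jid: empty collection")
  if (!all(vapply(jids, inherits, logical(1), "jid")))
    stop("average_jid: all elements must be jid objects")
  g <- jids[[1L]]$grid
  norm <- jids[[1L]]$normalization
  for (j in jids[-1L]) {
    if (!grids_identical(g, j$grid)) stop("average_jid: grid mismatch")
    if (!identical(norm, j$normalization))
      stop("average_jid: normalization mismatch")
  }
  m <- Reduce(`+`, lapply(jids, `[[`, "matrix")) / length(jids)
  structure(
    list(grid = g, matrix = m,
         n_pairs = sum(vapply(jids, `[[`, numeric(1), "n_pairs")),
         normalization = norm,
         out_of_grid = mean(vapply(jids, `[[`, numeric(1), "out_of_grid"))),
    class = "jid")
}

#' Difference between two JIDs
#'
#' Element-wise `a - b` on a shared grid. For probability-mass inputs the
#' signed entries sum to zero, so the map shows where probability moved.
#'
#' @param a,b `jid` objects on identical grids.
#' @return An object of class `jid_diff`: list with `grid` and signed `matrix`.
#' @export
jid_difference <- function(a, b) {
  stopifnot(inherits(a, "jid"), inherits(b, "jid"))
  if (!grids_identical(a$grid, b$grid)) stop("jid_difference: grid mismatch")
  if (!identical(a$normalization, b$normalization))
    stop("jid_difference: normalization mismatch")
  structure(list(grid = a$grid, matrix = a$matrix - b$matrix), class = "jid_diff")
}

#' @export
print.jid_diff <- function(x, ...) {
  q <- quadrant_mass(x)
  cat(sprintf("JID difference map (%d x %d); net mass: fast-fast %+.4g, slow-slow %+.4g, mixed %+.4g\n",
              x$grid$n_bins, x$grid$n_bins,
              q["fast_fast"], q["slow_slow"], q["mixed"]))
  invisible(x)
}

#' @export
plot.jid_diff <- function(x, main = "JID difference", ...) {
  r <- max(abs(x$matrix))
  graphics::image(x$grid$centers, x$grid$centers, x$matrix,
                  zlim = c(-r, r),
                  col = grDevices::hcl.colors(65, "Blue-Red 2"),
                  xlab = expression(log[10] ~ ITI[k] ~ "(s)"),
                  ylab = expression(log[10] ~ ITI[k + 1] ~ "(s)"),
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Signed mass by JID quadrant
#'
#' Splits the grid at its midpoint on each axis and sums matrix entries over
#' the fast-fast (both intervals below the midpoint), slow-slow (both above)
#' and mixed regions. A reporting convention for difference maps: positive
#' fast-fast mass means probability moved toward fast consecutive
#' interactions.
#'
#' @param x A `jid` or `jid_diff`.
#' @return Named numeric vector `fast_fast`, `slow_slow`, `mixed`.
#' @export
quadrant_mass <- function(x) {
  stopifnot(inherits(x, "jid") || inherits(x, "jid_diff"))
  nb <- x$grid$n_bins
  h <- nb %/% 2L
  fast <- seq_len(h)
  slow <- (h + 1L):nb
  ff <- sum(x$matrix[fast, fast])
  ss <- sum(x$matrix[slow, slow])
  c(fast_fast = ff, slow_slow = ss, mixed = sum(x$matrix) - ff - ss)
}
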
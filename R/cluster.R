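# Two-group comparison of collections of daily JIDs: bin-wise t statistics,
# clusters of contiguous supra-threshold bins, and a max-cluster-size
# permutation null. Positive and negative supra-threshold bins are clustered
# separately and the null statistic is the maximum over both signs, which
# controls the two-sided family of 2500 bin-wise tests.

# Stack a list of JIDs into an n_days x n_bins^2 matrix (column-major bins),
# checking grid and normalization compatibility.
jid_stack <- function(jids, ref = NULL) {
  if (inherits(jids, "jid")) jids <- list(jids)
  if (!length(jids) || !all(vapply(jids, inherits, logical(1), "jid")))
    stop("expected a list of jid objects")
  g <- if (is.null(ref)) jids[[1L]] else ref
  for (j in jids) {
    if (!grids_identical(g$grid, j$grid)) stop("grid mismatch between JIDs")
    if (!identical(g$normalization, j$normalization))
      stop("normalization mismatch between JIDs")
  }
  t(vapply(jids, function(j) as.numeric(j$matrix),
           numeric(g$grid$n_bins^2)))
}

#' Bin-wise two-sample t-map between two groups of daily JIDs
#'
#' Computes, for every 2D bin, the two-sample t statistic comparing the two
#' groups' daily values. Positive t means the group-a mean exceeds the
#' group-b mean. Bins with zero variance in both groups (typically empty
#' JID corners) get t = 0 and are flagged.
#'
#' @param group_a,group_b Lists of `jid` objects on identical grids, at
#'   least 2 per group.
#' @param var_equal If `TRUE` (default) the pooled-variance t with
#'   `n_a + n_b - 2` degrees of freedom; if `FALSE`, Welch's t with
#'   per-bin Satterthwaite degrees of freedom.
#' @return An object of class `jid_tmap`: list with `grid`, `t_values`
#'   (`n_bins` x `n_bins`), `df` (scalar, or matrix for Welch), `n_a`,
#'   `n_b`, `var_equal`, `zero_variance` (logical matrix).
#' @export
binwise_tmap <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("binwise_tmap: need at least 2 JIDs per group")
  Xa <- jid_stack(group_a)
  Xb <- jid_stack(group_b, ref = group_a[[1L]])
  g <- group_a[[1L]]$grid
  na <- nrow(Xa); nb <- nrow(Xb)

  ma <- colMeans(Xa); mb <- colMeans(Xb)
  va <- colSums(t(t(Xa) - ma)^2) / (na - 1)
  vb <- colSums(t(t(Xb) - mb)^2) / (nb - 1)

  if (var_equal) {
    df <- na + nb - 2
    se <- sqrt(((na - 1) * va + (nb - 1) * vb) / df * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    df[!is.finite(df)] <- 1
    df <- matrix(df, g$n_bins, g$n_bins)
  }
  zero <- se == 0
  tv <- (ma - mb) / se
  tv[zero] <- 0

  structure(list(grid = g, t_values = matrix(tv, g$n_bins, g$n_bins),
                 df = df, n_a = na, n_b = nb, var_equal = var_equal,
                 zero_variance = matrix(zero, g$n_bins, g$n_bins)),
            class = "jid_tmap")
}

#' @export
print.jid_tmap <- function(x, ...) {
  cat(sprintf("Bin-wise t-map: %d x %d bins, groups %d vs %d (%s t, df %s); |t| max %.2f, %d zero-variance bin(s)\n",
              x$grid$n_bins, x$grid$n_bins, x$n_a, x$n_b,
              if (x$var_equal) "pooled" else "Welch",
              if (is.matrix(x$df)) "per-bin" else format(x$df),
              max(abs(x$t_values)), sum(x$zero_variance)))
  invisible(x)
}

#' Label connected components of a logical mask
#'
#' Depth-first flood fill over the lattice, under 4- (edge-sharing, the
#' default) or 8-neighbour connectivity.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 = background), labelled in
#'   first-encounter (column-major) order.
#' @export
label_components <- function(mask, connectivity = 4L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("label_components: connectivity must be 4 or 8")
  if (!is.matrix(mask)) stop("label_components: mask must be a matrix")
  mask <- mask != 0  # logical, dims preserved
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) return(lab)
  off_r <- c(-1L, 1L, 0L, 0L); off_c <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8L) {
    off_r <- c(off_r, -1L, -1L, 1L, 1L)
    off_c <- c(off_c, -1L, 1L, -1L, 1L)
  }
  nn <- length(off_r)
  seeds <- which(mask)
  cur <- 0L
  stack <- integer(256L)
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    stack[1L] <- s; top <- 1L
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      r <- (v - 1L) %% nr + 1L
      cc0 <- (v - 1L) %/% nr + 1L
      for (k in seq_len(nn)) {
        rr <- r + off_r[k]; cc <- cc0 + off_c[k]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        w <- (cc - 1L) * nr + rr
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- cur
          top <- top + 1L
          if (top > length(stack)) stack <- c(stack, integer(length(stack)))
          stack[top] <- w
        }
      }
    }
  }
  lab
}

# critical |t| threshold(s) for the cluster-forming alpha (two-sided)
cluster_tcrit <- function(df, alpha) stats::qt(1 - alpha / 2, df)

#' Form signed clusters of supra-threshold bins
#'
#' Thresholds the t-map at the two-sided critical value for the
#' cluster-forming alpha, then partitions supra-threshold bins into
#' connected components separately for positive and negative signs.
#'
#' @param tmap A `jid_tmap`.
#' @param alpha Cluster-forming p value (default 0.01).
#' @param connectivity 4 (default) or 8.
#' @return List of clusters, largest first; each is a list with
#'   `member_bins` (two-column row/col matrix), `sign` (+1/-1), `size`,
#'   and placeholders `p_value`/`significant` filled by
#'   [jid_permutation_test()].
#' @export
form_clusters <- function(tmap, alpha = 0.01, connectivity = 4L) {
  stopifnot(inherits(tmap, "jid_tmap"))
  if (!(alpha > 0 && alpha < 1)) stop("form_clusters: alpha must be in (0, 1)")
  tcrit <- cluster_tcrit(tmap$df, alpha)
  clusters <- list()
  for (sgn in c(1, -1)) {
    mask <- (sgn * tmap$t_values > tcrit) & !tmap$zero_variance
    lab <- label_components(mask, connectivity)
    k <- max(lab)
    if (k == 0L) next
    for (i in seq_len(k)) {
      mb <- which(lab == i, arr.ind = TRUE)
      dimnames(mb) <- list(NULL, c("row", "col"))
      clusters[[length(clusters) + 1L]] <-
        list(member_bins = mb, sign = sgn, size = nrow(mb),
             p_value = NA_real_, significant = NA)
    }
  }
  clusters[order(vapply(clusters, `[[`, numeric(1), "size"),
                 decreasing = TRUE)]
}

#' Maximum cluster size
#'
#' Size of the largest cluster over both signs; 0 when there are none.
#'
#' @param clusters List of clusters from [form_clusters()].
#' @return Integer.
#' @export
max_cluster_size <- function(clusters) {
  if (length(clusters) == 0L) return(0L)
  as.integer(max(vapply(clusters, `[[`, numeric(1), "size")))
}

# max connected-component size over both signs of a thresholded t vector
# (fast path used inside the permutation loop)
max_supra_size <- function(tv, tcrit, nr, connectivity) {
  out <- 0L
  for (sgn in c(1, -1)) {
    mask <- matrix(sgn * tv > tcrit, nr, nr)
    if (!any(mask)) next
    lab <- label_components(mask, connectivity)
    out <- max(out, max(tabulate(lab)))
  }
  out
}

# t statistics for a block of permutations: P is b x n group-a indicator
# rows, X the n x p data matrix. Returns b x p matrix.
perm_tvalues <- function(P, X, X2, St, SSt, na, nb, var_equal) {
  Sa <- P %*% X
  SSa <- P %*% X2
  ma <- Sa / na
  mb <- (rep(St, each = nrow(P)) - Sa) / nb   # recycled rowwise
  va <- (SSa - na * ma^2) / (na - 1)
  vb <- (sweep(-SSa, 2L, SSt, `+`) - nb * mb^2) / (nb - 1)
  va[va < 0] <- 0; vb[vb < 0] <- 0
  if (var_equal) {
    df <- na + nb - 2
    se <- sqrt(((na - 1) * va + (nb - 1) * vb) / df * (1 / na + 1 / nb))
    tv <- (ma - mb) / se
    tv[se == 0] <- 0
    list(t = tv, df = df)
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    df[!is.finite(df)] <- 1
    tv <- (ma - mb) / se
    tv[se == 0] <- 0
    list(t = tv, df = df)
  }
}

#' Cluster-based permutation test between two groups of daily JIDs
#'
#' Computes the observed bin-wise t-map and its signed supra-threshold
#' clusters, then re-runs the full pipeline (t-map, thresholding, connected
#' components, maximum cluster size) under `B` random reassignments of the
#' day labels, preserving group sizes. A cluster is declared significant
#' when its size exceeds the 95th percentile of the null max-cluster-size
#' distribution; each cluster also gets the permutation p value
#' `(1 + #\{null max >= size\}) / (B + 1)`, the probability of an equal or
#' greater maximal cluster size under the null.
#'
#' @inheritParams binwise_tmap
#' @param B Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation draw.
#' @param alpha Cluster-forming p value (default 0.01).
#' @param connectivity 4 (default) or 8.
#' @param exhaustive If `TRUE`, enumerate every distinct group-a subset
#'   instead of sampling (feasible for small groups; `B` is then
#'   `choose(n_a + n_b, n_a)`).
#' @param chunk_size Permutations processed per matrix-multiply block
#'   (memory/speed trade-off; no effect on results).
#' @return An object of class `jid_cluster_test`: list with `tmap`,
#'   `clusters` (with p values and significance flags), `null_max_sizes`,
#'   `threshold_95`, `B`, `seed`, `alpha_cluster_forming`, `connectivity`,
#'   `exhaustive`.
#' @export
jid_permutation_test <- function(group_a, group_b, B = 1000L, seed = 1L,
                                 alpha = 0.01, connectivity = 4L,
                                 var_equal = TRUE, exhaustive = FALSE,
                                 chunk_size = 1000L) {
  tmap <- binwise_tmap(group_a, group_b, var_equal = var_equal)
  clusters <- form_clusters(tmap, alpha = alpha, connectivity = connectivity)

  na <- tmap$n_a; nb <- tmap$n_b
  n <- na + nb
  nr <- tmap$grid$n_bins
  X <- rbind(jid_stack(group_a), jid_stack(group_b, ref = group_a[[1L]]))
  X2 <- X * X
  St <- colSums(X); SSt <- colSums(X2)

  if (exhaustive) {
    n_splits <- choose(n, na)
    if (n_splits > 1e5)
      stop("jid_permutation_test: exhaustive enumeration infeasible (",
           format(n_splits), " splits); use random permutations")
    idx_mat <- utils::combn(n, na)
    B <- ncol(idx_mat)
  } else {
    B <- as.integer(B)
    if (is.na(B) || B < 1L) stop("jid_permutation_test: B must be >= 1")
    set.seed(as.integer(seed))
    idx_mat <- replicate(B, sample.int(n, na))
    if (na == 1L) idx_mat <- matrix(idx_mat, nrow = 1L)
  }

  null_max <- integer(B)
  done <- 0L
  while (done < B) {
    b <- min(chunk_size, B - done)
    cols <- done + seq_len(b)
    P <- matrix(0, b, n)
    P[cbind(rep(seq_len(b), each = na), as.vector(idx_mat[, cols]))] <- 1
    tb <- perm_tvalues(P, X, X2, St, SSt, na, nb, var_equal)
    for (i in seq_len(b)) {
      tcrit_i <- if (is.matrix(tb$df)) {
        matrix(cluster_tcrit(tb$df[i, ], alpha), nr, nr)
      } else cluster_tcrit(tb$df, alpha)
      null_max[done + i] <- max_supra_size(tb$t[i, ], tcrit_i, nr,
                                           connectivity)
    }
    done <- done + b
  }

  threshold_95 <- as.numeric(stats::quantile(null_max, 0.95))
  for (i in seq_along(clusters)) {
    sz <- clusters[[i]]$size
    clusters[[i]]$p_value <- (1 + sum(null_max >= sz)) / (B + 1)
    clusters[[i]]$significant <- sz > threshold_95
  }

  structure(list(tmap = tmap, clusters = clusters,
                 null_max_sizes = null_max, threshold_95 = threshold_95,
                 B = B, seed = as.integer(seed),
                 alpha_cluster_forming = alpha,
                 connectivity = as.integer(connectivity),
                 exhaustive = exhaustive),
            class = "jid_cluster_test")
}

#' @export
print.jid_cluster_test <- function(x, ...) {
  nq <- stats::quantile(x$null_max_sizes, c(0.025, 0.5, 0.975), names = FALSE)
  cat(sprintf("Cluster-based permutation test: %d vs %d daily JIDs, B = %d%s\n",
              x$tmap$n_a, x$tmap$n_b, x$B,
              if (x$exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  cluster-forming p < %g, %d-connectivity; null max size: median %d (95%% CI %d to %d), 95th pct %.1f\n",
              x$alpha_cluster_forming, x$connectivity,
              as.integer(nq[2L]), as.integer(nq[1L]), as.integer(nq[3L]),
              x$threshold_95))
  if (length(x$clusters) == 0L) {
    cat("  no supra-threshold clusters\n")
  } else {
    tab <- summary(x)
    top <- utils::head(tab, 5L)
    cat(sprintf("  %d cluster(s); largest:\n", nrow(tab)))
    print(top, row.names = FALSE)
    if (nrow(tab) > 5L) cat(sprintf("  ... and %d more\n", nrow(tab) - 5L))
  }
  invisible(x)
}

#' @export
summary.jid_cluster_test <- function(object, ...) {
  cl <- object$clusters
  if (length(cl) == 0L)
    return(data.frame(sign = numeric(0), size = integer(0),
                      p_value = numeric(0), significant = logical(0)))
  data.frame(
    sign = vapply(cl, `[[`, numeric(1), "sign"),
    size = vapply(cl, `[[`, numeric(1), "size"),
    p_value = vapply(cl, `[[`, numeric(1), "p_value"),
    significant = vapply(cl, `[[`, logical(1), "significant"))
}

#' Does any significant cluster overlap a grid quadrant?
#'
#' Convenience predicate for effect-direction checks: tests whether any
#' significant cluster of the given sign has at least one member bin inside
#' the named quadrant (grid split at its midpoint on each axis).
#'
#' @param result A `jid_cluster_test`.
#' @param quadrant `"fast_fast"` (both axes below the midpoint) or
#'   `"slow_slow"`.
#' @param sign Optional +1/-1 filter on cluster sign.
#' @return Logical.
#' @export
any_significant_in_quadrant <- function(result,
                                        quadrant = c("fast_fast", "slow_slow"),
                                        sign = NULL) {
  stopifnot(inherits(result, "jid_cluster_test"))
  quadrant <- match.arg(quadrant)
  h <- result$tmap$grid$n_bins %/% 2L
  for (cl in result$clusters) {
    if (!isTRUE(cl$significant)) next
    if (!is.null(sign) && cl$sign != sign) next
    inq <- if (quadrant == "fast_fast")
      cl$member_bins[, 1L] <= h & cl$member_bins[, 2L] <= h
    else cl$member_bins[, 1L] > h & cl$member_bins[, 2L] > h
    if (any(inq)) return(TRUE)
  }
  FALSE
}
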
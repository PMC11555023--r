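# Synthetic single-subject touchscreen study generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# months-long stream of tap timestamps with nightly no-use gaps, heavy
# within-day burst/pause structure in the inter-touch intervals, a
# medication-tapering period with probability mass shifted toward fast
# next-interval pairs, and a single convulsion day shifted toward slow pairs.

# Synthetic calendar origin: an arbitrary fixed date (2021-05-01 00:00 UTC,
# epoch seconds). Absolute dates are irrelevant to all downstream math.
.tapjid_epoch0 <- 1619827200

#' Configure the synthetic study generator
#'
#' The generator draws, for each day, an interaction count from
#' `daily_count_law`, then a sequence of inter-touch intervals (ITIs) from a
#' per-condition mixture of log10-normal components coupled by a first-order
#' autoregressive Gaussian copula, anchored at a jittered rise time and
#' truncated at the nightly sleep window.
#'
#' Default parameters target the study scale the analysis is designed for:
#' three periods of 82 / 12 / 91 days and a median of roughly 3311
#' interactions per day (IQR roughly 2531-4766). Condition effects are
#' encoded as weight shifts between the fast and slow mixture components:
#' tapering moves `taper_shift` of the weight from the slow to the fast
#' component, the convulsion day moves `convulsion_shift` from fast to slow.
#'
#' @param n_pre,n_taper,n_post Day counts for the pre-tapering, tapering and
#'   post-tapering periods (each >= 0). Defaults 82, 12, 91.
#' @param daily_count_law Distribution of interactions per day: list with
#'   `name` in `"lognormal"` (fields `meanlog`, `sdlog`), `"poisson"`
#'   (`lambda`) or `"fixed"` (`n`). Default lognormal with median 3311,
#'   `sdlog = 0.47`, parameters fixed by simulation against the median/IQR
#'   targets.
#' @param base_mixture Baseline log10-ITI mixture: list with numeric vectors
#'   `weight` (sums to 1), `mean` and `sd` (log10 seconds), components
#'   ordered fast to slow. Default two components:
#'   0.60 at mean -0.45 (sd 0.35) and 0.40 at mean 1.15 (sd 0.45).
#' @param taper_shift Mixture weight moved slow -> fast on tapering days
#'   (default 0.15).
#' @param convulsion_shift Mixture weight moved fast -> slow on the
#'   convulsion day (default 0.30).
#' @param sleep_window List `start_hour`, `end_hour`, `jitter_sd_min`: the
#'   nightly no-use interval (clock hours; default 23.5 to 7.5, i.e. rise at
#'   07:30) and the sd in minutes of the independent Gaussian jitter applied
#'   to each boundary each day (default 20).
#' @param seizure_day_index 1-based study-day index carrying the
#'   convulsion-day effect, or `NA` for none. Default: three-quarters of the
#'   way through the tapering period (`NA` if `n_taper == 0`).
#' @param pair_correlation Lag-1 correlation of the latent Gaussian copula
#'   coupling consecutive log10-ITIs (default 0.3), so the joint
#'   distribution of consecutive intervals is not a product of marginals.
#' @param day_weight_sd Day-to-day sd of the fast-component weight (default
#'   0.04), emulating behavioural day-level variability beyond sampling
#'   noise.
#' @param seed Integer seed; every stream the generator emits is a
#'   deterministic function of `seed` and the day index.
#'
#' @return An object of class `synth_config`. Field `iti_mixture` holds the
#'   derived per-condition mixtures (`baseline`, `tapering`, `convulsion`).
#' @export
#' @examples
#' cfg <- synth_config(n_pre = 4, n_taper = 2, n_post = 4, seed = 1)
#' cfg$iti_mixture$tapering$weight
synth_config <- function(n_pre = 82L, n_taper = 12L, n_post = 91L,
                         daily_count_law = list(name = "lognormal",
                                                meanlog = log(3311),
                                                sdlog = 0.47),
                         base_mixture = list(weight = c(0.60, 0.40),
                                             mean = c(-0.45, 1.15),
                                             sd = c(0.35, 0.45)),
                         taper_shift = 0.15,
                         convulsion_shift = 0.30,
                         sleep_window = list(start_hour = 23.5,
                                             end_hour = 7.5,
                                             jitter_sd_min = 20),
                         seizure_day_index = NULL,
                         pair_correlation = 0.3,
                         day_weight_sd = 0.04,
                         seed = 1L) {
  n_pre <- as.integer(n_pre); n_taper <- as.integer(n_taper)
  n_post <- as.integer(n_post)
  if (any(is.na(c(n_pre, n_taper, n_post))) || any(c(n_pre, n_taper, n_post) < 0L))
    stop("synth_config: period sizes must be non-negative integers")
  w <- base_mixture$weight
  if (abs(sum(w) - 1) > 1e-8) stop("synth_config: mixture weights must sum to 1")
  if (any(w < 0) || any(base_mixture$sd <= 0))
    stop("synth_config: mixture weights must be >= 0 and sds > 0")
  k <- length(w)
  if (length(base_mixture$mean) != k || length(base_mixture$sd) != k)
    stop("synth_config: mixture weight/mean/sd lengths differ")
  if (k < 2L) stop("synth_config: need at least a fast and a slow component")
  if (abs(pair_correlation) >= 1)
    stop("synth_config: |pair_correlation| must be < 1")
  if (taper_shift < 0 || convulsion_shift < 0)
    stop("synth_config: effect shifts must be >= 0")

  n_days <- n_pre + n_taper + n_post
  if (is.null(seizure_day_index))
    seizure_day_index <- if (n_taper > 0L)
      n_pre + max(1L, as.integer(ceiling(0.75 * n_taper))) else NA_integer_
  seizure_day_index <- as.integer(seizure_day_index)
  if (!is.na(seizure_day_index) &&
      (seizure_day_index < 1L || seizure_day_index > n_days))
    stop("synth_config: seizure_day_index outside the study range")

  shift_weight <- function(mix, amount, from, to) {
    d <- min(amount, mix$weight[from])
    mix$weight[from] <- mix$weight[from] - d
    mix$weight[to] <- mix$weight[to] + d
    mix
  }
  mixtures <- list(
    baseline   = base_mixture,
    tapering   = shift_weight(base_mixture, taper_shift, from = k, to = 1L),
    convulsion = shift_weight(base_mixture, convulsion_shift, from = 1L, to = k))

  structure(
    list(n_pre = n_pre, n_taper = n_taper, n_post = n_post,
         daily_count_law = daily_count_law,
         iti_mixture = mixtures,
         sleep_window = sleep_window,
         seizure_day_index = seizure_day_index,
         pair_correlation = pair_correlation,
         day_weight_sd = day_weight_sd,
         seed = as.integer(seed)),
    class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("Synthetic study config: %d pre / %d taper / %d post days, seed %d\n",
              x$n_pre, x$n_taper, x$n_post, x$seed))
  if (!is.na(x$seizure_day_index))
    cat(sprintf("  convulsion on study day %d\n", x$seizure_day_index))
  cat(sprintf("  baseline mixture weights: %s; pair correlation %.2f\n",
              paste(format(x$iti_mixture$baseline$weight, digits = 2),
                    collapse = ", "),
              x$pair_correlation))
  invisible(x)
}

# Mean of the log10-ITI mixture (closed form; used by tests as an oracle).
mixture_log10_mean <- function(mix) sum(mix$weight * mix$mean)

# Quantile function of a log10-normal mixture by monotone interpolation of
# its CDF on a fine grid (error far below the kernel bandwidth).
mixture_quantile_fun <- function(mix, n_grid = 4096L) {
  lo <- min(mix$mean - 6 * mix$sd)
  hi <- max(mix$mean + 6 * mix$sd)
  z <- seq(lo, hi, length.out = n_grid)
  cdf <- rowSums(vapply(seq_along(mix$weight), function(i)
    mix$weight[i] * stats::pnorm(z, mix$mean[i], mix$sd[i]),
    numeric(n_grid)))
  function(u) {
    u <- pmin(pmax(u, cdf[1L]), cdf[n_grid])
    stats::approx(cdf, z, xout = u, ties = "ordered")$y
  }
}

draw_daily_count <- function(law) {
  n <- switch(law$name,
    lognormal = round(stats::rlnorm(1, law$meanlog, law$sdlog)),
    poisson   = stats::rpois(1, law$lambda),
    fixed     = law$n,
    stop("synth_config: unknown daily_count_law '", law$name, "'"))
  max(2L, as.integer(n))
}

day_seed <- function(config, day_index) {
  as.integer((abs(config$seed) + 104729 * day_index) %% 2147483629)
}

#' Generate one synthetic day of touchscreen interactions
#'
#' Draws the day's interaction count, a jittered rise time, and a sequence
#' of ITIs from the condition's log10-normal mixture with AR(1) Gaussian
#' copula dependence, then emits cumulative epoch-millisecond timestamps.
#' Events that would fall into the (jittered) nightly sleep window are
#' truncated, so heavy days end early rather than run through the night.
#'
#' @param config A [synth_config()].
#' @param condition One of `"baseline"`, `"tapering"`, `"convulsion"`.
#' @param day_index 0-based day offset from the synthetic calendar origin.
#' @param seed Optional integer seed; default derives a per-day seed from
#'   `config$seed` and `day_index`, so each day is an independent
#'   reproducible substream.
#' @return A [tap_stream()] of strictly increasing epoch-ms timestamps, with
#'   attribute `wake_time_ms` (the ground-truth rise time) and
#'   `drawn_count` (the pre-truncation count).
#' @export
generate_day <- function(config, condition, day_index = 0L, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!condition %in% c("baseline", "tapering", "convulsion"))
    stop("generate_day: invalid condition '", condition, "'")
  set.seed(if (is.null(seed)) day_seed(config, day_index) else as.integer(seed))

  n <- draw_daily_count(config$daily_count_law)
  mix <- config$iti_mixture[[if (condition == "baseline") "baseline"
                             else if (condition == "tapering") "tapering"
                             else "convulsion"]]

  # day-level variability: jitter the fast-component weight, renormalise
  if (config$day_weight_sd > 0 && length(mix$weight) >= 2L) {
    w1 <- min(max(mix$weight[1L] + stats::rnorm(1, 0, config$day_weight_sd),
                  0.01), 0.99)
    rest <- mix$weight[-1L]
    mix$weight <- c(w1, rest * (1 - w1) / sum(rest))
  }

  # AR(1) latent Gaussian (stationary), mapped through the mixture quantile
  rho <- config$pair_correlation
  m <- n - 1L
  z <- as.numeric(stats::filter(stats::rnorm(m) * sqrt(1 - rho^2), rho,
                                method = "recursive",
                                init = stats::rnorm(1)))
  iti <- 10^mixture_quantile_fun(mix)(stats::pnorm(z))

  sw <- config$sleep_window
  day0 <- .tapjid_epoch0 + day_index * 86400
  rise <- day0 + sw$end_hour * 3600 + stats::rnorm(1, 0, sw$jitter_sd_min * 60)
  sleep_start <- day0 + sw$start_hour * 3600 +
    stats::rnorm(1, 0, sw$jitter_sd_min * 60)

  t_s <- rise + cumsum(c(0, iti))
  t_s <- t_s[t_s < sleep_start]
  if (length(t_s) < 2L) t_s <- rise + cumsum(c(0, iti))[1:2]

  ts_ms <- round(t_s * 1000)
  # ms rounding can collide for sub-ms intervals; keep strict ordering
  if (is.unsorted(ts_ms, strictly = TRUE))
    for (i in 2:length(ts_ms))
      if (ts_ms[i] <= ts_ms[i - 1L]) ts_ms[i] <- ts_ms[i - 1L] + 1

  out <- tap_stream(ts_ms)
  attr(out, "wake_time_ms") <- rise * 1000
  attr(out, "drawn_count") <- n
  out
}

#' Generate a full labelled synthetic study
#'
#' Days are ordered pre -> taper -> post; pre and post days use the baseline
#' mixture, tapering days the tapering mixture, and the seizure day (if set)
#' the convulsion mixture. Output is a deterministic function of the config.
#'
#' @param config A [synth_config()].
#' @return An object of class `tap_study`: list with `days` (list of
#'   `day_record`), `labels` (factor pre/taper/post), `seizure_flag`
#'   (logical), `wake_times_ms` (ground-truth rise times) and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_days <- config$n_pre + config$n_taper + config$n_post
  labels <- factor(rep(c("pre", "taper", "post"),
                       times = c(config$n_pre, config$n_taper, config$n_post)),
                   levels = c("pre", "taper", "post"))
  seizure <- rep(FALSE, n_days)
  if (!is.na(config$seizure_day_index)) {
    if (config$seizure_day_index < 1L || config$seizure_day_index > n_days)
      stop("generate_study: seizure_day_index outside the study range")
    seizure[config$seizure_day_index] <- TRUE
  }

  days <- vector("list", n_days)
  wake <- numeric(n_days)
  for (d in seq_len(n_days)) {
    condition <- if (seizure[d]) "convulsion"
      else if (labels[d] == "taper") "tapering" else "baseline"
    stream <- generate_day(config, condition, day_index = d - 1L)
    wake[d] <- attr(stream, "wake_time_ms")
    days[[d]] <- day_record(day_id = sprintf("day_%03d", d),
                            timestamps = stream$timestamps)
  }
  structure(list(days = days, labels = labels, seizure_flag = seizure,
                 wake_times_ms = wake, config = config),
            class = "tap_study")
}

#' @export
print.tap_study <- function(x, ...) {
  cat(sprintf("Synthetic tap study: %d days (%d pre / %d taper / %d post)%s\n",
              length(x$days), sum(x$labels == "pre"),
              sum(x$labels == "taper"), sum(x$labels == "post"),
              if (any(x$seizure_flag))
                sprintf(", convulsion on %s",
                        x$days[[which(x$seizure_flag)]]$day_id) else ""))
  invisible(x)
}

#' Summarise per-day interaction counts of a study
#'
#' @param study A `tap_study` (or any list of `day_record`s in `$days`).
#' @return An object of class `tap_study_summary`: list with `per_day`
#'   (data frame of day_id, label, n_events, seizure), `median_daily`,
#'   `q25`, `q75`.
#' @export
summarize_study <- function(study) {
  stopifnot(inherits(study, "tap_study"))
  if (length(study$days) == 0L) stop("summarize_study: empty study")
  counts <- vapply(study$days, `[[`, numeric(1), "n_events")
  per_day <- data.frame(
    day_id = vapply(study$days, `[[`, character(1), "day_id"),
    label = as.character(study$labels),
    n_events = counts,
    seizure = study$seizure_flag,
    stringsAsFactors = FALSE)
  q <- stats::quantile(counts, c(0.25, 0.75), names = FALSE)
  structure(list(per_day = per_day,
                 median_daily = stats::median(counts),
                 q25 = q[1L], q75 = q[2L]),
            class = "tap_study_summary")
}

#' @export
print.tap_study_summary <- function(x, ...) {
  cat(sprintf("%d study days, %s interactions total\n", nrow(x$per_day),
              format(sum(x$per_day$n_events), big.mark = ",")))
  cat(sprintf("  daily interactions: median %d (IQR %d-%d)\n",
              as.integer(x$median_daily), as.integer(x$q25),
              as.integer(x$q75)))
  invisible(x)
}

#' Concatenate a study's days into one continuous tap stream
#'
#' @param study A `tap_study`.
#' @return A [tap_stream()] spanning the whole study.
#' @export
study_stream <- function(study) {
  stopifnot(inherits(study, "tap_study"))
  tap_stream(unlist(lapply(study$days, `[[`, "timestamps")))
}
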
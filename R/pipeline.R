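# Full-study orchestration: segmentation -> daily JIDs -> period grouping ->
# the two medication-transition permutation tests and the descriptive
# convulsion-day contrast.

#' Describe the study design
#'
#' @param period_map Data frame with columns `day_id` and `period`
#'   (`"pre"`, `"taper"`, `"post"`), one row per behavioural day, in study
#'   order; or a named character vector.
#' @param seizure_day Optional `day_id` of the convulsion day (must appear
#'   in `period_map`).
#' @param baseline_days Days immediately preceding the seizure day averaged
#'   into the contrast baseline (default 3).
#' @param exclude Character vector of `day_id`s excluded from group
#'   statistics (e.g. flagged low-count days).
#' @return An object of class `study_design`.
#' @export
study_design <- function(period_map, seizure_day = NULL, baseline_days = 3L,
                         exclude = character()) {
  if (!is.data.frame(period_map))
    period_map <- data.frame(day_id = names(period_map),
                             period = as.character(period_map),
                             stringsAsFactors = FALSE)
  stopifnot(all(c("day_id", "period") %in% names(period_map)))
  if (anyDuplicated(period_map$day_id))
    stop("study_design: duplicated day_id (periods must be disjoint)")
  if (!all(period_map$period %in% c("pre", "taper", "post")))
    stop("study_design: periods must be 'pre', 'taper' or 'post'")
  if (!is.null(seizure_day) && !seizure_day %in% period_map$day_id)
    stop("study_design: seizure_day not present in period_map")
  baseline_days <- as.integer(baseline_days)
  if (is.na(baseline_days) || baseline_days < 1L)
    stop("study_design: baseline_days must be >= 1")
  structure(list(period_map = period_map, seizure_day = seizure_day,
                 baseline_days = baseline_days,
                 exclude = as.character(exclude)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  tab <- table(factor(x$period_map$period, c("pre", "taper", "post")))
  cat(sprintf("Study design: %d pre / %d taper / %d post days%s%s\n",
              tab["pre"], tab["taper"], tab["post"],
              if (!is.null(x$seizure_day))
                sprintf(", convulsion on %s", x$seizure_day) else "",
              if (length(x$exclude))
                sprintf(", %d excluded", length(x$exclude)) else ""))
  invisible(x)
}

#' Derive a study design from a synthetic study
#'
#' @param study A `tap_study` from [generate_study()].
#' @param baseline_days Passed through to [study_design()].
#' @return A `study_design` whose day ids match the study's day records.
#' @export
design_from_study <- function(study, baseline_days = 3L) {
  stopifnot(inherits(study, "tap_study"))
  ids <- vapply(study$days, `[[`, character(1), "day_id")
  study_design(
    data.frame(day_id = ids,
               period = c(pre = "pre", taper = "taper",
                          post = "post")[as.character(study$labels)],
               stringsAsFactors = FALSE),
    seizure_day = if (any(study$seizure_flag)) ids[which(study$seizure_flag)],
    baseline_days = baseline_days)
}

#' Write / read a study design as CSV
#'
#' Columns `day_id`, `period`, `seizure` (0/1), `exclude` (0/1).
#'
#' @param design A `study_design`.
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()` a
#'   `study_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  pm <- design$period_map
  utils::write.csv(
    data.frame(day_id = pm$day_id, period = pm$period,
               seizure = as.integer(!is.null(design$seizure_day) &
                                      pm$day_id == design$seizure_day),
               exclude = as.integer(pm$day_id %in% design$exclude)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, baseline_days = 3L) {
  if (!file.exists(path)) stop("read_design: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("day_id", "period") %in% names(df)))
    stop("read_design: need columns day_id, period in ", path)
  seiz <- if ("seizure" %in% names(df) && any(df$seizure == 1))
    df$day_id[which(df$seizure == 1)[1L]]
  excl <- if ("exclude" %in% names(df)) df$day_id[df$exclude == 1] else character()
  study_design(df[c("day_id", "period")], seizure_day = seiz,
               baseline_days = baseline_days, exclude = excl)
}

#' Compute one JID per behavioural day
#'
#' Days with fewer than 2 events yield no ITI pair and are returned as
#' `NULL` entries (the caller decides whether to drop them).
#'
#' @param days List of [day_record()]s.
#' @param grid A [jid_grid()].
#' @param normalization Passed to [compute_jid()].
#' @return Named list of `jid` objects (or `NULL`), names = day ids.
#' @export
daily_jids <- function(days, grid = jid_grid(),
                       normalization = "probability_mass") {
  out <- lapply(days, function(d) {
    p <- make_pairs(d$itis)
    if (nrow(p) == 0L) return(NULL)
    compute_jid(p, grid = grid, normalization = normalization)
  })
  names(out) <- vapply(days, `[[`, character(1), "day_id")
  out
}

usable_ids <- function(jids, design, period) {
  pm <- design$period_map
  ids <- pm$day_id[pm$period == period]
  ids <- setdiff(ids, design$exclude)
  ids[ids %in% names(jids) & !vapply(jids[ids], is.null, logical(1))]
}

#' Run the two medication-transition permutation tests
#'
#' Contrast 1 compares the pre-tapering period's daily JIDs with the
#' tapering period's; contrast 2 compares tapering with post-tapering.
#' Period-average JIDs and transition difference maps (later period minus
#' earlier) are attached. The convulsion day, when inside the tapering
#' period, stays in the tapering group by default.
#'
#' @param jids Named list of daily `jid`s (see [daily_jids()]).
#' @param design A [study_design()].
#' @param B,seed,alpha,connectivity,var_equal Passed to
#'   [jid_permutation_test()]; the second contrast uses `seed + 1`.
#' @param include_seizure If `FALSE`, the seizure day is dropped from its
#'   period's group before testing.
#' @return An object of class `jid_transition_tests`: list with
#'   `pre_vs_taper`, `taper_vs_post` (both `jid_cluster_test`),
#'   `period_averages` (list pre/taper/post), `diff_maps`
#'   (`taper_minus_pre`, `post_minus_taper`), `group_sizes`.
#' @export
run_transition_tests <- function(jids, design, B = 1000L, seed = 1L,
                                 alpha = 0.01, connectivity = 4L,
                                 var_equal = TRUE, include_seizure = TRUE) {
  stopifnot(inherits(design, "study_design"))
  grp <- lapply(c(pre = "pre", taper = "taper", post = "post"),
                function(p) usable_ids(jids, design, p))
  if (!include_seizure && !is.null(design$seizure_day))
    grp <- lapply(grp, setdiff, design$seizure_day)
  sizes <- vapply(grp, length, integer(1))
  if (any(sizes == 0L))
    stop("run_transition_tests: empty period(s): ",
         paste(names(sizes)[sizes == 0L], collapse = ", "))
  if (any(sizes < 2L))
    stop("run_transition_tests: period(s) with < 2 usable days: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (any(sizes < 5L))
    warning("run_transition_tests: small period group(s): ",
            paste(sprintf("%s (n=%d)", names(sizes)[sizes < 5L],
                          sizes[sizes < 5L]), collapse = ", "))

  avg <- lapply(grp, function(ids) average_jid(jids[ids]))
  res1 <- jid_permutation_test(jids[grp$pre], jids[grp$taper], B = B,
                               seed = seed, alpha = alpha,
                               connectivity = connectivity,
                               var_equal = var_equal)
  res2 <- jid_permutation_test(jids[grp$taper], jids[grp$post], B = B,
                               seed = seed + 1L, alpha = alpha,
                               connectivity = connectivity,
                               var_equal = var_equal)
  structure(list(pre_vs_taper = res1, taper_vs_post = res2,
                 period_averages = avg,
                 diff_maps = list(
                   taper_minus_pre = jid_difference(avg$taper, avg$pre),
                   post_minus_taper = jid_difference(avg$post, avg$taper)),
                 group_sizes = sizes),
            class = "jid_transition_tests")
}

#' @export
print.jid_transition_tests <- function(x, ...) {
  cat("== Pre-tapering vs tapering ==\n"); print(x$pre_vs_taper)
  cat("== Tapering vs post-tapering ==\n"); print(x$taper_vs_post)
  q1 <- quadrant_mass(x$diff_maps$taper_minus_pre)
  q2 <- quadrant_mass(x$diff_maps$post_minus_taper)
  cat(sprintf("Fast-fast net mass: taper - pre %+.4f, post - taper %+.4f\n",
              q1["fast_fast"], q2["fast_fast"]))
  invisible(x)
}

#' Convulsion-day contrast against the preceding-days baseline
#'
#' Computes the difference between the seizure day's JID and the average
#' JID of the immediately preceding `baseline_days` days. Purely
#' descriptive: with a single seizure day there is no valid day-level
#' permutation, so no test is offered.
#'
#' @param jids Named list of daily `jid`s.
#' @param design A [study_design()] with `seizure_day` set.
#' @return An object of class `jid_seizure_contrast`: list with `diff`
#'   (a `jid_diff`), `quadrant` (signed mass summary), `seizure_day`,
#'   `baseline_ids`.
#' @export
run_seizure_contrast <- function(jids, design) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(design$seizure_day))
    stop("run_seizure_contrast: design has no seizure day")
  ids <- design$period_map$day_id
  pos <- match(design$seizure_day, ids)
  if (pos <= design$baseline_days)
    stop("run_seizure_contrast: fewer than ", design$baseline_days,
         " days precede the seizure day")
  base_ids <- ids[(pos - design$baseline_days):(pos - 1L)]
  ok <- base_ids %in% names(jids) &
    !vapply(jids[base_ids], is.null, logical(1))
  if (!all(ok))
    stop("run_seizure_contrast: baseline day(s) without a valid JID: ",
         paste(base_ids[!ok], collapse = ", "))
  sj <- jids[[design$seizure_day]]
  if (is.null(sj))
    stop("run_seizure_contrast: no valid JID for the seizure day")
  d <- jid_difference(sj, average_jid(jids[base_ids]))
  structure(list(diff = d, quadrant = quadrant_mass(d),
                 seizure_day = design$seizure_day,
                 baseline_ids = base_ids),
            class = "jid_seizure_contrast")
}

#' @export
print.jid_seizure_contrast <- function(x, ...) {
  cat(sprintf("Convulsion-day contrast: %s vs mean of %d preceding day(s)\n",
              x$seizure_day, length(x$baseline_ids)))
  cat(sprintf("  net mass change: fast-fast %+.4f, slow-slow %+.4f, mixed %+.4f\n",
              x$quadrant["fast_fast"], x$quadrant["slow_slow"],
              x$quadrant["mixed"]))
  invisible(x)
}

synth_config_from_list <- function(lst, seed) {
  args <- lst[intersect(names(lst),
                        names(formals(synth_config)))]
  if (!is.null(args$base_mixture)) args$base_mixture <-
    lapply(args$base_mixture, as.numeric)
  args$seed <- if (!is.null(lst$seed)) lst$seed else seed
  do.call(synth_config, args)
}

#' Run the full analysis pipeline from a config file
#'
#' The YAML config either sets `simulate: true` with a `synth` block (the
#' synthetic study generator supplies the tap stream and design) or points
#' `taps_file` / `design_file` at raw inputs. The pipeline segments the
#' stream into behavioural days, computes per-day JIDs, runs both
#' medication-transition permutation tests and the convulsion-day contrast,
#' and writes every result plus a run manifest under `out_dir`.
#'
#' @param config_path Path to the YAML config.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `days`, `design`, `jids`, `transitions`,
#'   `seizure_contrast`, `out_dir`.
#' @export
run_full_pipeline <- function(config_path, out_dir = NULL, quiet = FALSE) {
  if (!file.exists(config_path))
    stop("run_full_pipeline: config not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  out_dir <- if (!is.null(out_dir)) out_dir
    else if (!is.null(cfg$out_dir)) cfg$out_dir
    else stop("run_full_pipeline: no out_dir given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "jids"), showWarnings = FALSE)

  grid <- do.call(jid_grid, as.list(cfg$grid))
  seg_params <- do.call(segmentation_params, as.list(cfg$segmentation))
  tst <- cfg$test
  B <- if (!is.null(tst$B)) as.integer(tst$B) else 1000L
  alpha <- if (!is.null(tst$alpha)) tst$alpha else 0.01
  connectivity <- if (!is.null(tst$connectivity)) tst$connectivity else 4L
  var_equal <- if (!is.null(tst$var_equal)) isTRUE(tst$var_equal) else TRUE
  dsn <- cfg[["design"]]
  baseline_days <- if (!is.null(dsn$baseline_days)) dsn$baseline_days else 3L
  include_seizure <- if (!is.null(dsn$include_seizure_in_taper))
    isTRUE(dsn$include_seizure_in_taper) else TRUE

  # -- inputs ---------------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    say("[simulate] generating synthetic study")
    scfg <- synth_config_from_list(cfg$synth, seed)
    study <- generate_study(scfg)
    stream <- study_stream(study)
    design <- design_from_study(study, baseline_days = baseline_days)
    write_taps(stream, file.path(out_dir, "taps.csv"))
    write_design(design, file.path(out_dir, "design.csv"))
  } else {
    if (is.null(cfg$taps_file) || !file.exists(cfg$taps_file))
      stop("run_full_pipeline: taps_file missing or not found: ",
           if (is.null(cfg$taps_file)) "(unset)" else cfg$taps_file)
    if (is.null(cfg$design_file) || !file.exists(cfg$design_file))
      stop("run_full_pipeline: design_file missing or not found: ",
           if (is.null(cfg$design_file)) "(unset)" else cfg$design_file)
    stream <- read_taps(cfg$taps_file)
    design <- read_design(cfg$design_file, baseline_days = baseline_days)
  }

  # -- segmentation ---------------------------------------------------------
  say("[segment] detecting rise times")
  rises <- detect_rise_times(stream, seg_params)
  days <- split_days(stream, rises, seg_params)
  n_design <- nrow(design$period_map)
  if (length(days) != n_design)
    stop(sprintf("run_full_pipeline: segmentation found %d days but the design lists %d",
                 length(days), n_design))
  # align segmented day ids with the design's
  for (i in seq_along(days)) days[[i]]$day_id <- design$period_map$day_id[i]
  flagged <- vapply(days, `[[`, logical(1), "flagged")
  design$exclude <- union(design$exclude,
                          vapply(days, `[[`, character(1), "day_id")[flagged])
  rep_df <- segmentation_report(days)
  utils::write.table(rep_df, file.path(out_dir, "segmentation_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  say("[segment] %d behavioural days (%d flagged low-count)",
      length(days), sum(flagged))

  # -- daily JIDs -----------------------------------------------------------
  say("[jid] computing daily JIDs (%d x %d grid, bandwidth %.3g)",
      grid$n_bins, grid$n_bins, grid$bandwidth)
  jids <- daily_jids(days, grid = grid)
  for (id in names(jids))
    if (!is.null(jids[[id]]))
      write_jid(jids[[id]], file.path(out_dir, "jids", paste0(id, ".jid")))

  # -- transition tests -----------------------------------------------------
  say("[test] medication-transition permutation tests (B = %d)", B)
  transitions <- run_transition_tests(jids, design, B = B, seed = seed,
                                      alpha = alpha,
                                      connectivity = connectivity,
                                      var_equal = var_equal,
                                      include_seizure = include_seizure)
  write_cluster_result(transitions$pre_vs_taper,
                       file.path(out_dir, "test_pre_vs_taper.json"))
  write_cluster_result(transitions$taper_vs_post,
                       file.path(out_dir, "test_taper_vs_post.json"))
  for (p in names(transitions$period_averages))
    write_jid(transitions$period_averages[[p]],
              file.path(out_dir, paste0("average_", p, ".jid")))

  # -- convulsion-day contrast ----------------------------------------------
  seizure_contrast <- NULL
  if (!is.null(design$seizure_day)) {
    say("[seizure] convulsion-day vs %d-day baseline contrast",
        design$baseline_days)
    seizure_contrast <- run_seizure_contrast(jids, design)
    jsonlite::write_json(
      list(seizure_day = seizure_contrast$seizure_day,
           baseline_ids = seizure_contrast$baseline_ids,
           quadrant_mass = as.list(seizure_contrast$quadrant),
           diff_matrix = seizure_contrast$diff$matrix),
      file.path(out_dir, "seizure_contrast.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }

  # -- manifest -------------------------------------------------------------
  manifest <- list(
    config_file = basename(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    seed = seed, B = B,
    package_version = as.character(utils::packageVersion("tapjid")),
    n_days = length(days), n_flagged = sum(flagged),
    period_sizes = as.list(transitions$group_sizes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] results in %s", out_dir)

  invisible(list(days = days, design = design, jids = jids,
                 transitions = transitions,
                 seizure_contrast = seizure_contrast, out_dir = out_dir))
}
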
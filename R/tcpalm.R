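#' Burst-extraction parameters
#'
#' A burst is a maximal run of detections within one spatial cluster whose
#' consecutive frame gaps never exceed `max_gap_frames` (the dark-time
#' tolerance). Its lifetime is the timespan from the first to the last
#' detection; a single-detection burst has lifetime 0. Bursts with lifetime
#' strictly below `short_lifetime_cutoff` are "short-lived" (the boundary
#' value itself counts as long-lived).
#'
#' The dark-gap tolerance is not a printed constant of the original
#' analysis; 20 frames (1 s at 20 Hz) is the package default and
#' [gap_sensitivity()] sweeps it.
#'
#' @param max_gap_frames dark-time tolerance separating bursts, frames
#'   (default 20).
#' @param frame_rate acquisition rate, Hz; required because every lifetime
#'   is reported in seconds (no silent default).
#' @param short_lifetime_cutoff short/long boundary, seconds (default 100).
#' @return a list of class `burst_params`.
#' @export
burst_params <- function(max_gap_frames = 20L, frame_rate,
                         short_lifetime_cutoff = 100) {
  check_that(is_count(max_gap_frames, 1L), "max_gap_frames must be >= 1")
  check_that(!missing(frame_rate) && is_number(frame_rate, 0, strict = TRUE),
             "frame_rate is required and must be > 0 ",
             "(lifetimes are reported in seconds)")
  check_that(is_number(short_lifetime_cutoff, 0, strict = TRUE),
             "short_lifetime_cutoff must be > 0")
  structure(list(max_gap_frames = as.integer(max_gap_frames),
                 frame_rate = frame_rate,
                 short_lifetime_cutoff = short_lifetime_cutoff),
            class = "burst_params")
}

#' Extract time-correlated bursts from one cluster's detections
#'
#' @param frames integer vector of detection frame indices (any order,
#'   duplicates allowed — several molecules may be ON in one frame).
#' @param params a [burst_params()].
#' @param cluster_id id copied into the output (default `NA`).
#' @param n_frames total movie frames; when given, bursts touching the movie
#'   boundaries are flagged `censored`.
#' @return data.frame: `cluster_id`, `start_frame`, `end_frame`,
#'   `lifetime_s`, `n_detections`, `censored`.
#' @export
extract_bursts <- function(frames, params, cluster_id = NA_integer_,
                           n_frames = NULL) {
  check_that(inherits(params, "burst_params"), "params must be burst_params")
  if (length(frames) == 0) {
    return(data.frame(cluster_id = integer(0), start_frame = integer(0),
                      end_frame = integer(0), lifetime_s = numeric(0),
                      n_detections = integer(0), censored = logical(0)))
  }
  check_that(all(is.finite(frames)), "frame indices must be finite")
  fr <- sort(as.integer(frames))
  gaps <- diff(fr)
  new_burst <- c(TRUE, gaps > params$max_gap_frames)
  burst_id <- cumsum(new_burst)
  start <- fr[new_burst]
  end <- fr[c(new_burst[-1], TRUE)]
  n_det <- as.integer(tabulate(burst_id))
  censored <- if (is.null(n_frames)) {
    rep(FALSE, length(start))
  } else {
    start <= params$max_gap_frames |
      end >= n_frames - 1L - params$max_gap_frames
  }
  data.frame(cluster_id = cluster_id, start_frame = start, end_frame = end,
             lifetime_s = (end - start) / params$frame_rate,
             n_detections = n_det, censored = censored)
}

#' Extract bursts for every cluster in a localization table
#'
#' @param locs localization data.frame with `frame` and `cluster_id`
#'   columns (`cluster_id` 0 = noise, dropped).
#' @param params a [burst_params()].
#' @param n_frames optional movie length for censoring flags.
#' @param cluster_info optional cluster table (e.g. from [assign_regions()])
#'   whose `region` is joined onto the bursts by `cluster_id`.
#' @return data.frame of bursts across clusters.
#' @export
extract_bursts_by_cluster <- function(locs, params, n_frames = NULL,
                                      cluster_info = NULL) {
  check_that(all(c("frame", "cluster_id") %in% names(locs)),
             "locs needs frame and cluster_id columns")
  dt <- data.table::as.data.table(locs[locs$cluster_id > 0,
                                       c("frame", "cluster_id")])
  if (nrow(dt) == 0) {
    out <- extract_bursts(integer(0), params)
  } else {
    data.table::setorderv(dt, c("cluster_id", "frame"))
    gap <- params$max_gap_frames
    dt[, `:=`(new_burst = c(TRUE, diff(frame) > gap)), by = "cluster_id"]
    dt[, `:=`(burst = cumsum(new_burst)), by = "cluster_id"]
    agg <- dt[, list(start_frame = min(frame), end_frame = max(frame),
                     n_detections = .N), by = c("cluster_id", "burst")]
    out <- data.frame(
      cluster_id = agg$cluster_id, start_frame = agg$start_frame,
      end_frame = agg$end_frame,
      lifetime_s = (agg$end_frame - agg$start_frame) / params$frame_rate,
      n_detections = agg$n_detections)
    out$censored <- if (is.null(n_frames)) FALSE else {
      out$start_frame <= params$max_gap_frames |
        out$end_frame >= n_frames - 1L - params$max_gap_frames
    }
  }
  if (!is.null(cluster_info) && "region" %in% names(cluster_info)) {
    out$region <- cluster_info$region[match(out$cluster_id,
                                            cluster_info$cluster_id)]
  }
  out
}

#' Classify a burst lifetime as short- or long-lived
#'
#' Short iff `lifetime < short_lifetime_cutoff` (strict inequality — a
#' burst of exactly the cutoff is long-lived).
#'
#' @param lifetime_s lifetime(s) in seconds (vectorised).
#' @param params a [burst_params()].
#' @return factor with levels `short_lived`, `long_lived`.
#' @export
classify_lifetime <- function(lifetime_s, params) {
  factor(ifelse(lifetime_s < params$short_lifetime_cutoff, "short_lived",
                "long_lived"),
         levels = c("short_lived", "long_lived"))
}

#' Summarise burst lifetimes
#'
#' Computes the headline dynamics statistics: the mean lifetime of
#' short-lived bursts (tau_avg) with its SEM, the long-lived fraction, a
#' lifetime histogram, and per-region burst counts when a `region` column
#' is present.
#'
#' @param bursts data.frame from [extract_bursts_by_cluster()].
#' @param params a [burst_params()].
#' @param breaks histogram bin edges in seconds (default 0 to the movie
#'   maximum in 5 s bins).
#' @param include_censored include boundary-censored bursts (default TRUE,
#'   matching an analysis that cannot observe beyond the movie).
#' @return a list of class `lifetime_summary`: `tau_avg_short`, `sem_tau`,
#'   `fraction_long`, `n_bursts`, `n_short`, `histogram`
#'   (data.frame mid/count), `by_region` (or `NULL`).
#' @export
summarize_lifetimes <- function(bursts, params, breaks = NULL,
                                include_censored = TRUE) {
  check_that(nrow(bursts) >= 1, "at least one burst is required")
  if (!include_censored && "censored" %in% names(bursts)) {
    bursts <- bursts[!bursts$censored, , drop = FALSE]
    check_that(nrow(bursts) >= 1, "all bursts were censored")
  }
  lt <- bursts$lifetime_s
  cls <- classify_lifetime(lt, params)
  short <- lt[cls == "short_lived"]
  if (length(short) == 0) {
    warning("no short-lived bursts; tau_avg_short undefined")
    tau <- NA_real_; sem <- NA_real_
  } else {
    tau <- mean(short)
    sem <- stats::sd(short) / sqrt(length(short))
  }
  if (is.null(breaks)) {
    breaks <- seq(0, max(lt, 5) + 5, by = 5)
  }
  h <- graphics::hist(lt, breaks = breaks, plot = FALSE)
  by_region <- if ("region" %in% names(bursts)) {
    as.data.frame(table(region = bursts$region), responseName = "n_bursts")
  } else NULL
  structure(list(tau_avg_short = tau, sem_tau = sem,
                 fraction_long = mean(cls == "long_lived"),
                 n_bursts = length(lt), n_short = length(short),
                 histogram = data.frame(mid = h$mids, count = h$counts),
                 by_region = by_region, cutoff_s = params$short_lifetime_cutoff),
            class = "lifetime_summary")
}

#' @export
print.lifetime_summary <- function(x, ...) {
  cat(sprintf(paste0("<lifetime_summary> %d bursts; tau_avg(short) = ",
                     "%.2f +/- %.2f s; long-lived fraction = %.3f\n"),
              x$n_bursts, x$tau_avg_short, x$sem_tau, x$fraction_long))
  invisible(x)
}

#' Per-cell, per-region cluster statistics
#'
#' @param clusters data.frame with `region` (factor) and `n_detections`; a
#'   `cell_id` column groups clusters into cells (single cell assumed when
#'   absent).
#' @return a list of class `cluster_stats`: `clusters_per_cell` (data.frame
#'   cell_id x region counts), `detections_mean`, `detections_range`,
#'   `detections` (the raw counts).
#' @export
cluster_stats <- function(clusters) {
  check_that("n_detections" %in% names(clusters),
             "clusters needs an n_detections column")
  if (!"cell_id" %in% names(clusters)) clusters$cell_id <- 1L
  region <- if ("region" %in% names(clusters)) clusters$region else
    factor(rep("cytoplasm", nrow(clusters)), levels = REGION_NAMES)
  keep <- region != "outside"
  cpc <- as.data.frame(table(cell_id = clusters$cell_id[keep],
                             region = droplevels(region[keep])),
                       responseName = "n_clusters")
  det <- clusters$n_detections
  structure(list(clusters_per_cell = cpc,
                 detections_mean = if (length(det)) mean(det) else NA_real_,
                 detections_range = if (length(det)) range(det) else
                   c(NA_real_, NA_real_),
                 detections = det),
            class = "cluster_stats")
}

#' Compare short-lived lifetimes between two conditions
#'
#' Unpaired t test (two-sided by default, as used for the lifetime
#' comparisons; some comparisons call for one-sided) on the short-lived
#' burst lifetimes of two groups.
#'
#' @param a,b numeric vectors of short-lived lifetimes (s), or
#'   `lifetime_summary`-producing burst tables with `lifetime_s`.
#' @param alternative passed to [stats::t.test()] (default "two.sided").
#' @param var_equal pooled-variance test (default FALSE, Welch).
#' @return a list: `t`, `df`, `p_value`, `mean_a`, `mean_b`, `alternative`.
#' @export
compare_conditions <- function(a, b, alternative = "two.sided",
                               var_equal = FALSE) {
  grab <- function(x) {
    if (is.data.frame(x)) x$lifetime_s else as.numeric(x)
  }
  a <- grab(a); b <- grab(b)
  check_that(length(a) >= 2 && length(b) >= 2,
             "insufficient data: each group needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    warning("degenerate variance in both groups")
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (same) 0 else Inf, df = NA_real_,
                p_value = if (same) 1 else 0, mean_a = mean(a),
                mean_b = mean(b), alternative = alternative))
  }
  tt <- stats::t.test(a, b, alternative = alternative,
                      var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       alternative = alternative)
}

#' Sensitivity of tau_avg to the dark-gap tolerance
#'
#' Re-extracts bursts over a sweep of `max_gap_frames` values and reports
#' tau_avg(short) for each, so the one free temporal parameter can be
#' inspected.
#'
#' @param locs clustered localization table (`frame`, `cluster_id`).
#' @param frame_rate acquisition rate, Hz.
#' @param gaps integer vector of gap values to sweep.
#' @param short_lifetime_cutoff seconds (default 100).
#' @return data.frame: `max_gap_frames`, `n_bursts`, `tau_avg_short`,
#'   `fraction_long`.
#' @export
gap_sensitivity <- function(locs, frame_rate, gaps = c(5L, 10L, 20L, 40L,
                                                       80L),
                            short_lifetime_cutoff = 100) {
  rows <- lapply(gaps, function(g) {
    p <- burst_params(max_gap_frames = g, frame_rate = frame_rate,
                      short_lifetime_cutoff = short_lifetime_cutoff)
    b <- extract_bursts_by_cluster(locs, p)
    s <- summarize_lifetimes(b, p)
    data.frame(max_gap_frames = g, n_bursts = s$n_bursts,
               tau_avg_short = s$tau_avg_short,
               fraction_long = s$fraction_long)
  })
  do.call(rbind, rows)
}
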
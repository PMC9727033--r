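#' Simulation configuration for synthetic PALM movies
#'
#' Describes the acquisition and the statistical structure of the simulated
#' data: geometry matching the imaging setup (2400 frames at 20 Hz over a
#' 256 x 256 pixel ROI, 160 nm pixels), a Poisson birth process of clusters,
#' a two-component exponential lifetime mixture (a short-lived majority and a
#' long-lived minority), and blinking photoactivatable emitters.
#'
#' Photophysics defaults are a modelling choice, not a measured constant set.
#' Clusters exchange molecules with the surrounding pool, so photoactivatable
#' molecules keep arriving for as long as the cluster exists: activations
#' form a Poisson process at `activation_rate` over the cluster's life, and
#' each activated molecule emits a short blinking track (geometric ON runs of
#' mean `on_mean` frames separated by OFF runs of mean `off_mean`, terminated
#' by photobleaching at hazard `bleach_rate` per second of ON time). The
#' default activation rate is set so that the pooled detection record covers
#' a cluster's lifespan with dark gaps that essentially never exceed the 1 s
#' burst-gap tolerance — the span of the detections is then an honest
#' estimate of the cluster lifetime; see the package vignette for the
#' reasoning and the trade-offs (detections per cluster come out denser than
#' in the real data).
#'
#' @param n_frames frames per movie (default 2400).
#' @param frame_rate acquisition rate, Hz (default 20).
#' @param roi_size ROI side, pixels (default 256).
#' @param pixel_size pixel pitch, nm (default 160).
#' @param psf_sigma PSF standard deviation, pixels (default 1.2).
#' @param cluster_birth_rate cluster births per second over the ROI
#'   (default 0.5).
#' @param short_lifetime_mean mean lifetime of the short-lived population,
#'   seconds (default 6.8).
#' @param long_lifetime_mean mean lifetime of the long-lived population,
#'   seconds (default 1000; long-lived clusters typically outlive a 120 s
#'   movie).
#' @param long_fraction probability a cluster is long-lived (default 0.15).
#' @param activation_rate molecule activations per second per live cluster
#'   (default 12).
#' @param photon_budget expected photons emitted per ON frame (default 500).
#' @param on_mean,off_mean mean ON/OFF run lengths in frames within a
#'   molecule's track (defaults 3 and 8).
#' @param bleach_rate photobleaching hazard per second of accumulated ON
#'   time (default 4, i.e. a ~5-frame ON budget and 3-5 frame median track).
#' @param spatial_spread isotropic SD of member positions about the cluster
#'   centre, nm (default 50; makes the 120 nm / N_min = 4 clustering setting
#'   effective).
#' @param seed default seed used when an operation is called without one.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_frames = 2400L, frame_rate = 20, roi_size = 256L,
                       pixel_size = 160, psf_sigma = 1.2,
                       cluster_birth_rate = 0.5, short_lifetime_mean = 6.8,
                       long_lifetime_mean = 1000, long_fraction = 0.15,
                       activation_rate = 12, photon_budget = 500,
                       on_mean = 3, off_mean = 8,
                       bleach_rate = 4, spatial_spread = 50, seed = 1L) {
  cfg <- list(n_frames = as.integer(n_frames), frame_rate = frame_rate,
              roi_size = as.integer(roi_size), pixel_size = pixel_size,
              psf_sigma = psf_sigma, cluster_birth_rate = cluster_birth_rate,
              short_lifetime_mean = short_lifetime_mean,
              long_lifetime_mean = long_lifetime_mean,
              long_fraction = long_fraction, activation_rate = activation_rate,
              photon_budget = photon_budget, on_mean = on_mean,
              off_mean = off_mean, bleach_rate = bleach_rate,
              spatial_spread = spatial_spread, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_that(is_count(cfg$n_frames, min = 1L), "n_frames must be >= 1")
  check_that(is_number(cfg$frame_rate, 0, strict = TRUE),
             "frame_rate must be > 0")
  check_that(is_count(cfg$roi_size, min = 8L), "roi_size must be >= 8 px")
  check_that(is_number(cfg$pixel_size, 0, strict = TRUE),
             "pixel_size must be > 0")
  check_that(is_number(cfg$psf_sigma, 0, strict = TRUE),
             "psf_sigma must be > 0")
  check_that(is_number(cfg$long_fraction, 0) && cfg$long_fraction <= 1,
             "long_fraction must lie in [0, 1]")
  for (f in c("cluster_birth_rate", "activation_rate", "bleach_rate")) {
    check_that(is_number(cfg[[f]], 0), f, " must be >= 0")
  }
  for (f in c("short_lifetime_mean", "long_lifetime_mean",
              "photon_budget", "on_mean", "off_mean", "spatial_spread")) {
    check_that(is_number(cfg[[f]], 0, strict = TRUE), f, " must be > 0")
  }
  invisible(cfg)
}

#' EMCCD camera model
#'
#' Electron-multiplying CCD readout: expected photoelectrons are multiplied
#' through the gain register — modelled as a gamma distribution with shape
#' equal to the electron count and scale `em_gain`, reproducing the factor-2
#' excess noise of EM amplification — then offset and Gaussian read noise
#' are added and the result is quantised to unsigned 16-bit counts.
#'
#' @param em_gain EM gain (default 1000, the acquisition setting).
#' @param baseline_offset camera offset, counts (default 100).
#' @param read_noise read noise RMS, counts (default 10).
#' @param quantum_efficiency photon-to-electron conversion probability
#'   (default 0.9).
#' @return a list of class `camera_model`.
#' @export
camera_model <- function(em_gain = 1000, baseline_offset = 100,
                         read_noise = 10, quantum_efficiency = 0.9) {
  check_that(is_number(em_gain, 1), "em_gain must be >= 1")
  check_that(is_number(baseline_offset, 0), "baseline_offset must be >= 0")
  check_that(is_number(read_noise, 0), "read_noise must be >= 0")
  check_that(is_number(quantum_efficiency, 0, strict = TRUE) &&
               quantum_efficiency <= 1,
             "quantum_efficiency must lie in (0, 1]")
  structure(list(em_gain = em_gain, baseline_offset = baseline_offset,
                 read_noise = read_noise,
                 quantum_efficiency = quantum_efficiency),
            class = "camera_model")
}

# geometric sojourn with the given mean, in whole frames (>= 1)
rgeom_frames <- function(n, mean_frames) {
  1L + stats::rgeom(n, pmin(1, 1 / mean_frames))
}

#' Simulate cluster ground truth and emitter traces
#'
#' Cluster births follow a homogeneous Poisson process at
#' `cluster_birth_rate` over the movie duration; each cluster draws its
#' lifetime from the two-component exponential mixture (lifetimes are NOT
#' truncated at the movie end — censoring happens downstream, when ON
#' intervals are clipped to the acquisition window). Member molecules sit at
#' Gaussian offsets (`spatial_spread`) about the cluster centre and blink
#' with geometric ON/OFF sojourns for the whole cluster life, with a
#' photobleaching hazard per second of ON time.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param region_mask optional [build_region_mask()] result; cluster centres
#'   are then drawn uniformly over the pixels of a region chosen with
#'   `region_weights`, so per-region planted counts can be scored against
#'   recovered ones. By default positions are uniform over the ROI with a
#'   margin and labelled `cytoplasm`.
#' @param region_weights named weights over
#'   `c("plasma_membrane", "cytoplasm", "nucleus")` (default: region areas).
#' @return a list with `clusters` (data.frame: cluster_id, center_x_nm,
#'   center_y_nm, birth_time_s, death_time_s, lifetime_s, n_molecules,
#'   region) and `traces` (data.frame: molecule_id, cluster_id, x_nm, y_nm,
#'   on_start_frame, on_end_frame — one row per ON interval, frames
#'   half-open 0-based, clipped to the movie).
#' @export
simulate_ground_truth <- function(config, seed = config$seed,
                                  region_mask = NULL,
                                  region_weights = NULL) {
  validate_sim_config(config)
  set.seed(child_seed(seed, "ground_truth"))
  T_s <- config$n_frames / config$frame_rate
  roi_nm <- config$roi_size * config$pixel_size

  n_clusters <- stats::rpois(1, config$cluster_birth_rate * T_s)
  empty_clusters <- data.frame(
    cluster_id = integer(0), center_x_nm = numeric(0),
    center_y_nm = numeric(0), birth_time_s = numeric(0),
    death_time_s = numeric(0), lifetime_s = numeric(0),
    n_molecules = integer(0), region = character(0),
    stringsAsFactors = FALSE)
  empty_traces <- data.frame(
    molecule_id = integer(0), cluster_id = integer(0), x_nm = numeric(0),
    y_nm = numeric(0), on_start_frame = integer(0),
    on_end_frame = integer(0), stringsAsFactors = FALSE)
  if (n_clusters == 0) {
    return(list(clusters = empty_clusters, traces = empty_traces))
  }

  birth <- sort(stats::runif(n_clusters, 0, T_s))
  is_long <- stats::runif(n_clusters) < config$long_fraction
  life <- ifelse(is_long,
                 stats::rexp(n_clusters, 1 / config$long_lifetime_mean),
                 stats::rexp(n_clusters, 1 / config$short_lifetime_mean))
  margin <- 5 * config$spatial_spread
  if (is.null(region_mask)) {
    cx <- stats::runif(n_clusters, margin, roi_nm - margin)
    cy <- stats::runif(n_clusters, margin, roi_nm - margin)
    region <- rep("cytoplasm", n_clusters)
  } else {
    # uniform placement over the pixels of a region drawn per cluster
    px_nm <- region_mask$pixel_size_nm
    region_px <- lapply(1:3, function(lab) {
      which(region_mask$labels == lab, arr.ind = TRUE)
    })
    names(region_px) <- REGION_NAMES[2:4]
    avail <- names(region_px)[vapply(region_px, nrow, integer(1)) > 0]
    check_that(length(avail) > 0, "region mask has no labelled pixels")
    w <- if (is.null(region_weights)) {
      vapply(region_px[avail], nrow, integer(1))
    } else {
      region_weights[avail]
    }
    pick <- sample(avail, n_clusters, replace = TRUE, prob = w)
    ij <- t(vapply(pick, function(r) {
      rp <- region_px[[r]]
      unname(rp[sample.int(nrow(rp), 1), ])
    }, integer(2)))
    cx <- (ij[, 2] - 1 + stats::runif(n_clusters)) * px_nm
    cy <- (ij[, 1] - 1 + stats::runif(n_clusters)) * px_nm
    region <- pick
  }
  clusters <- data.frame(
    cluster_id = seq_len(n_clusters), center_x_nm = cx, center_y_nm = cy,
    birth_time_s = birth, death_time_s = birth + life, lifetime_s = life,
    region = region, stringsAsFactors = FALSE)

  traces <- simulate_traces(clusters, config)
  if (nrow(traces) == 0) traces <- empty_traces
  # realized molecule count is emergent under the turnover model
  clusters$n_molecules <- as.integer(
    tabulate(factor(traces$cluster_id[!duplicated(traces$molecule_id)],
                    levels = clusters$cluster_id),
             nbins = n_clusters))
  list(clusters = clusters, traces = traces)
}

# Molecular turnover model, fully vectorised over activation events.
# Activations are Poisson(activation_rate) over each cluster's life clipped
# to the movie; each activated molecule emits alternating ON/OFF runs
# (geometric sojourns) until its exponential ON-time budget is spent or the
# cluster dies. Returns one row per ON interval, frames 0-based, clipped to
# the movie and the cluster's lifespan.
simulate_traces <- function(clusters, config) {
  fr <- config$frame_rate
  T_f <- config$n_frames
  eff_start <- pmax(clusters$birth_time_s, 0)
  eff_end <- pmin(clusters$death_time_s, T_f / fr)
  eff_life <- pmax(eff_end - eff_start, 0)
  n_arr <- stats::rpois(nrow(clusters), config$activation_rate * eff_life)
  total <- sum(n_arr)
  if (total == 0) return(data.frame())
  ci <- rep.int(seq_len(nrow(clusters)), n_arr)
  t_act <- eff_start[ci] + stats::runif(total) * eff_life[ci]
  death_f <- floor(pmin(clusters$death_time_s[ci] * fr, T_f)) - 1L
  # ON-frame budget before photobleaching
  budget <- if (config$bleach_rate > 0) {
    pmax(1L, as.integer(ceiling(stats::rexp(total, config$bleach_rate) * fr)))
  } else rep(.Machine$integer.max, total)
  mol <- data.frame(
    molecule_id = seq_len(total), cluster_id = clusters$cluster_id[ci],
    x_nm = clusters$center_x_nm[ci] +
      stats::rnorm(total, 0, config$spatial_spread),
    y_nm = clusters$center_y_nm[ci] +
      stats::rnorm(total, 0, config$spatial_spread))
  pos <- as.integer(ceiling(t_act * fr))
  out <- list()
  active <- which(pos <= death_f & budget > 0)
  guard <- 0L
  while (length(active) > 0 && guard < 1000L) {
    guard <- guard + 1L
    len <- pmin(rgeom_frames(length(active), config$on_mean), budget[active])
    end <- pmin(pos[active] + len - 1L, death_f[active])
    emit <- end >= pos[active] & end >= 0L
    if (any(emit)) {
      a <- active[emit]
      out[[length(out) + 1L]] <- data.frame(
        molecule_id = mol$molecule_id[a], cluster_id = mol$cluster_id[a],
        x_nm = mol$x_nm[a], y_nm = mol$y_nm[a],
        on_start_frame = pmax(pos[a], 0L), on_end_frame = end[emit])
    }
    budget[active] <- budget[active] - len
    gap <- rgeom_frames(length(active), config$off_mean)
    pos[active] <- pos[active] + len + gap
    active <- active[budget[active] > 0L & pos[active] <= death_f[active]]
  }
  if (length(out) == 0) return(data.frame())
  res <- do.call(rbind, out)
  res <- res[order(res$molecule_id, res$on_start_frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Emit a localization table directly from ground-truth traces
#'
#' Fast path that bypasses image rendering and localization: one row per
#' emitter per ON frame, with isotropic Gaussian localization error, so the
#' clustering and tc-PALM stages can be tested at scale independently of the
#' image pipeline.
#'
#' @param truth result of [simulate_ground_truth()] (or its `traces`
#'   component).
#' @param config the [sim_config()] used to generate it.
#' @param localization_noise_sd localization error SD per axis, nm
#'   (default 20).
#' @param seed integer seed.
#' @return a `data.frame` with columns `frame`, `x_nm`, `y_nm`, `photons`,
#'   `background`, `sigma_nm`, `uncertainty_nm` and (ground-truth bookkeeping)
#'   `cluster_id`, `molecule_id`, sorted by frame.
#' @export
emit_localization_table <- function(truth, config,
                                    localization_noise_sd = 20,
                                    seed = config$seed) {
  check_that(is_number(localization_noise_sd, 0),
             "localization_noise_sd must be >= 0")
  traces <- if (is.data.frame(truth)) truth else truth$traces
  set.seed(child_seed(seed, "loc_table"))
  empty <- data.frame(frame = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), photons = numeric(0),
                      background = numeric(0), sigma_nm = numeric(0),
                      uncertainty_nm = numeric(0), cluster_id = integer(0),
                      molecule_id = integer(0), stringsAsFactors = FALSE)
  if (is.null(traces) || nrow(traces) == 0) return(empty)
  lens <- traces$on_end_frame - traces$on_start_frame + 1L
  keep <- lens > 0L
  traces <- traces[keep, , drop = FALSE]
  lens <- lens[keep]
  if (nrow(traces) == 0) return(empty)
  idx <- rep.int(seq_len(nrow(traces)), lens)
  frame <- unlist(mapply(seq.int, traces$on_start_frame,
                         traces$on_end_frame, SIMPLIFY = FALSE),
                  use.names = FALSE)
  n <- length(frame)
  tab <- data.frame(
    frame = as.integer(frame),
    x_nm = traces$x_nm[idx] + stats::rnorm(n, 0, localization_noise_sd),
    y_nm = traces$y_nm[idx] + stats::rnorm(n, 0, localization_noise_sd),
    photons = stats::rpois(n, config$photon_budget),
    background = rep(1, n),
    sigma_nm = rep(config$psf_sigma * config$pixel_size, n),
    uncertainty_nm = rep(max(localization_noise_sd, 1e-3), n),
    cluster_id = traces$cluster_id[idx],
    molecule_id = traces$molecule_id[idx], stringsAsFactors = FALSE)
  tab <- tab[order(tab$frame, tab$molecule_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# Expected photoelectron image for a set of emitters in one frame.
# Integrated-Gaussian PSF: photons spread over pixels by the product of
# erf differences along x and y. Positions in pixels (origin at the ROI's
# upper-left pixel corner), matrix indexed [row, col] = [y, x].
render_expected_image <- function(nr, nc, x_px, y_px, photons, psf_sigma,
                                  background = 0) {
  img <- matrix(background, nr, nc)
  if (length(x_px) == 0) return(img)
  r <- ceiling(4 * psf_sigma) + 1L
  for (e in seq_along(x_px)) {
    j0 <- floor(x_px[e]); i0 <- floor(y_px[e])
    js <- max(0L, j0 - r):min(nc - 1L, j0 + r)
    is <- max(0L, i0 - r):min(nr - 1L, i0 + r)
    if (length(js) == 0 || length(is) == 0) next
    ex <- stats::pnorm((c(js, js[length(js)] + 1L) - x_px[e]) / psf_sigma)
    ey <- stats::pnorm((c(is, is[length(is)] + 1L) - y_px[e]) / psf_sigma)
    dx <- diff(ex); dy <- diff(ey)
    img[is + 1L, js + 1L] <- img[is + 1L, js + 1L] +
      photons[e] * (dy %o% dx)
  }
  img
}

#' Render a synthetic PALM movie from emitter traces
#'
#' Each emitter contributes an integrated 2D Gaussian (`psf_sigma`) of its
#' per-frame photon budget in every frame where it is ON. Shot noise is
#' Poisson; EM amplification multiplies each pixel's electron count by a
#' gamma-distributed gain (excess-noise factor ~2); baseline offset and
#' Gaussian read noise are added; output counts are clamped to 16 bits.
#' Emitters outside the ROI are skipped with a warning.
#'
#' @param truth result of [simulate_ground_truth()] (or its `traces`).
#' @param camera a [camera_model()].
#' @param config the [sim_config()].
#' @param seed integer seed.
#' @param noise apply shot/EM/read noise (`TRUE`, default). With `FALSE` the
#'   expected signal (photons scaled by QE and gain, plus baseline) is
#'   returned — useful for photon-conservation checks.
#' @return a `frame_stack` (see [read_stack()]).
#' @export
render_frames <- function(truth, camera = camera_model(), config,
                          seed = config$seed, noise = TRUE) {
  validate_sim_config(config)
  traces <- if (is.data.frame(truth)) truth else truth$traces
  set.seed(child_seed(seed, "render"))
  nr <- nc <- config$roi_size
  roi_nm <- config$roi_size * config$pixel_size
  if (!is.null(traces) && nrow(traces) > 0) {
    out_of_roi <- traces$x_nm < 0 | traces$x_nm >= roi_nm |
      traces$y_nm < 0 | traces$y_nm >= roi_nm
    if (any(out_of_roi)) {
      warning(sum(out_of_roi), " emitter trace(s) outside the ROI skipped")
      traces <- traces[!out_of_roi, , drop = FALSE]
    }
  }
  stack <- array(0, dim = c(config$n_frames, nr, nc))
  # per-frame list of active emitters
  active <- if (!is.null(traces) && nrow(traces) > 0) {
    lens <- traces$on_end_frame - traces$on_start_frame + 1L
    keep <- lens > 0 & traces$on_start_frame < config$n_frames
    tr <- traces[keep, , drop = FALSE]
    tr$on_end_frame <- pmin(tr$on_end_frame, config$n_frames - 1L)
    idx <- rep.int(seq_len(nrow(tr)),
                   tr$on_end_frame - tr$on_start_frame + 1L)
    fr <- unlist(mapply(seq.int, tr$on_start_frame, tr$on_end_frame,
                        SIMPLIFY = FALSE), use.names = FALSE)
    split(idx, fr)
  } else list()
  g <- camera$em_gain
  for (f in seq_len(config$n_frames)) {
    ids <- active[[as.character(f - 1L)]]
    mu <- if (is.null(ids)) {
      matrix(0, nr, nc)
    } else {
      tr <- traces[unique(ids), , drop = FALSE]
      render_expected_image(nr, nc, tr$x_nm / config$pixel_size,
                            tr$y_nm / config$pixel_size,
                            rep(config$photon_budget, nrow(tr)),
                            config$psf_sigma)
    }
    mu_e <- mu * camera$quantum_efficiency
    if (noise) {
      ne <- stats::rpois(length(mu_e), mu_e)
      counts <- numeric(length(ne))
      pos <- ne > 0
      if (any(pos)) counts[pos] <- stats::rgamma(sum(pos), shape = ne[pos],
                                                 scale = g)
      counts <- counts + camera$baseline_offset +
        if (camera$read_noise > 0) stats::rnorm(length(ne), 0,
                                                camera$read_noise) else 0
      stack[f, , ] <- matrix(pmin(pmax(round(counts), 0), 65535), nr, nc)
    } else {
      stack[f, , ] <- mu_e * g + camera$baseline_offset
    }
  }
  structure(list(data = stack, pixel_size_nm = config$pixel_size,
                 frame_rate_hz = config$frame_rate, bits = 16L,
                 camera = camera),
            class = "frame_stack")
}

#' Define a planted spot field for puncta fixtures
#'
#' @param centers two-column matrix of spot centres (px, x then y; 0-based
#'   continuous coordinates).
#' @param amplitudes peak amplitudes (recycled).
#' @param widths Gaussian SDs in px (recycled).
#' @param background constant background level.
#' @param noise_sd additive Gaussian noise SD.
#' @param size image side in px.
#' @return a list of class `spot_field_truth`.
#' @export
spot_field_truth <- function(centers, amplitudes = 50, widths = 1.5,
                             background = 5, noise_sd = 1, size = 128L) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  n <- nrow(centers)
  check_that(all(centers >= 0 & centers < size) || n == 0,
             "all spots must lie inside the image bounds")
  structure(list(centers = centers,
                 amplitudes = rep_len(amplitudes, n),
                 widths = rep_len(widths, n), background = background,
                 noise_sd = noise_sd, size = as.integer(size)),
            class = "spot_field_truth")
}

#' Render a confocal-style puncta image with its truth mask
#'
#' Image = constant background + Gaussian spots + additive Gaussian noise.
#' The truth label mask marks pixels within 2 SD of each spot centre.
#'
#' @param truth a [spot_field_truth()].
#' @param seed integer seed.
#' @param channel_b_scale if not `NULL`, also render a second channel whose
#'   per-spot amplitude is `channel_b_scale` times the first channel's.
#' @return a list with `image` (matrix), `label_mask` (integer matrix,
#'   0 = background), and optionally `image_b`.
#' @export
synth_puncta_image <- function(truth, seed = 1L, channel_b_scale = NULL) {
  check_that(inherits(truth, "spot_field_truth"),
             "truth must be a spot_field_truth")
  set.seed(child_seed(seed, "puncta"))
  n <- truth$size
  render_chan <- function(amps) {
    img <- matrix(truth$background, n, n)
    if (nrow(truth$centers) > 0) {
      px <- seq(0, n - 1) + 0.5  # pixel centres
      for (s in seq_len(nrow(truth$centers))) {
        gx <- exp(-(px - truth$centers[s, 1])^2 / (2 * truth$widths[s]^2))
        gy <- exp(-(px - truth$centers[s, 2])^2 / (2 * truth$widths[s]^2))
        img <- img + amps[s] * (gy %o% gx)
      }
    }
    if (truth$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(n * n, 0, truth$noise_sd), n, n)
    }
    img
  }
  image <- render_chan(truth$amplitudes)
  label <- matrix(0L, n, n)
  if (nrow(truth$centers) > 0) {
    px <- seq(0, n - 1) + 0.5
    for (s in seq_len(nrow(truth$centers))) {
      d2 <- outer((px - truth$centers[s, 2])^2, (px - truth$centers[s, 1])^2,
                  `+`)
      label[d2 <= (2 * truth$widths[s])^2] <- s
    }
  }
  out <- list(image = image, label_mask = label)
  if (!is.null(channel_b_scale)) {
    out$image_b <- render_chan(truth$amplitudes * channel_b_scale)
  }
  out
}
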
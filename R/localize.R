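#' Detection and localization parameters
#'
#' Controls the frame-wise single-molecule stage: a pixelwise hypothesis
#' test (generalized likelihood ratio of "Gaussian spot + background" vs
#' "background only" in a sliding window, thresholded at a per-pixel false
#' alarm probability), followed by maximum-likelihood Gauss-Newton fitting
#' of an integrated-Gaussian + constant-background model, and a deflation
#' loop that subtracts fitted spots and re-detects dimmer ones.
#'
#' @param psf_sigma PSF standard deviation in pixels (default 1.2). Held
#'   fixed during fitting (stabilises the fit on dim spots); set
#'   `fit_sigma = TRUE` to refine it.
#' @param window_radius half-width of the test/fit window in pixels
#'   (default `ceiling(3 * psf_sigma)`; must be at least `2 * psf_sigma`).
#' @param pfa per-pixel false alarm probability of the detection test
#'   (default 1e-6).
#' @param max_iterations Gauss-Newton iteration cap (default 50).
#' @param convergence_tol convergence threshold on the position step, px
#'   (default 1e-3).
#' @param max_deflation_rounds deflation passes after the first (default 2).
#' @param min_photons fits below this photon count are discarded
#'   (default 50).
#' @param fit_sigma also fit the PSF width (default FALSE).
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(psf_sigma = 1.2,
                             window_radius = ceiling(3 * psf_sigma),
                             pfa = 1e-6, max_iterations = 50L,
                             convergence_tol = 1e-3,
                             max_deflation_rounds = 2L, min_photons = 50,
                             fit_sigma = FALSE) {
  check_that(is_number(psf_sigma, 0, strict = TRUE), "psf_sigma must be > 0")
  check_that(is_count(window_radius, 1L) &&
               window_radius >= 2 * psf_sigma,
             "window_radius must be an integer >= 2 * psf_sigma")
  check_that(is_number(pfa, 0, strict = TRUE) && pfa < 1,
             "pfa must lie in (0, 1)")
  check_that(is_count(max_iterations, 1L), "max_iterations must be >= 1")
  check_that(is_number(convergence_tol, 0, strict = TRUE),
             "convergence_tol must be > 0")
  check_that(is_count(max_deflation_rounds, 0L),
             "max_deflation_rounds must be >= 0")
  check_that(is_number(min_photons, 0), "min_photons must be >= 0")
  structure(list(psf_sigma = psf_sigma,
                 window_radius = as.integer(window_radius), pfa = pfa,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 max_deflation_rounds = as.integer(max_deflation_rounds),
                 min_photons = min_photons, fit_sigma = isTRUE(fit_sigma)),
            class = "detection_params")
}

# GLR statistic map. In each (2w+1)^2 window, least-squares amplitude of a
# centred Gaussian template over a constant background; the statistic
# (m-2) * alpha^2 * c / RSS1 is F(1, m-2)-distributed under the
# background-only hypothesis with Gaussian noise, giving a threshold directly
# from the per-pixel false-alarm probability.
glr_map <- function(img, params) {
  w <- params$window_radius
  side <- 2L * w + 1L
  m <- side^2
  x <- seq(-w, w)
  gk <- exp(-outer(x^2, x^2, `+`) / (2 * params$psf_sigma^2))
  ones <- matrix(1, side, side)
  gbar <- mean(gk)
  cc <- sum(gk^2) - m * gbar^2
  S1 <- .conv2_replicate(img, ones)
  Sg <- .conv2_replicate(img, gk)
  S2 <- .conv2_replicate(img^2, ones)
  alpha <- (Sg - gbar * S1) / cc
  rss0 <- pmax(S2 - S1^2 / m, 0)
  rss1 <- pmax(rss0 - alpha^2 * cc, .Machine$double.eps)
  tstat <- (m - 2) * (alpha^2 * cc) / rss1
  tstat[alpha <= 0] <- 0
  # windows straddling the border reuse replicated pixels; exclude them
  nr <- nrow(img); nc <- ncol(img)
  if (nr > 2 * w && nc > 2 * w) {
    tstat[c(seq_len(w), nr - seq_len(w) + 1L), ] <- 0
    tstat[, c(seq_len(w), nc - seq_len(w) + 1L)] <- 0
  } else {
    tstat[] <- 0
  }
  list(stat = tstat, threshold = stats::qf(1 - params$pfa, 1, m - 2))
}

#' Detect candidate emitters in one frame
#'
#' Returns local maxima of the generalized-likelihood-ratio detection
#' statistic exceeding the threshold implied by `pfa`, sorted by decreasing
#' statistic. Candidates closer than `2 * psf_sigma` px to a stronger one
#' are suppressed (duplicate-fit guard); ties are broken by statistic value,
#' then row-major pixel order.
#'
#' @param img numeric matrix (one frame, photon or count scale — the
#'   statistic is scale-invariant).
#' @param params a [detection_params()].
#' @return data.frame with 1-based `row`, `col` and the `stat` value;
#'   zero rows if nothing exceeds the threshold.
#' @export
detect_candidates <- function(img, params = detection_params()) {
  check_that(is.matrix(img) && all(is.finite(img)),
             "img must be a finite numeric matrix")
  w <- params$window_radius
  check_that(nrow(img) >= 2 * w + 1 && ncol(img) >= 2 * w + 1,
             "image smaller than the fitting window")
  gm <- glr_map(img, params)
  # candidates must be 8-neighbourhood local maxima of the statistic
  s <- gm$stat
  nr0 <- nrow(s); nc0 <- ncol(s)
  pad <- matrix(-Inf, nr0 + 2L, nc0 + 2L)
  pad[2:(nr0 + 1L), 2:(nc0 + 1L)] <- s
  nbr_max <- matrix(-Inf, nr0, nc0)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nbr_max <- pmax(nbr_max,
                      pad[(2:(nr0 + 1L)) + di, (2:(nc0 + 1L)) + dj])
    }
  }
  hits <- which(s > gm$threshold & s >= nbr_max)
  empty <- data.frame(row = integer(0), col = integer(0), stat = numeric(0))
  if (length(hits) == 0) return(empty)
  nr <- nrow(img)
  ri <- (hits - 1L) %% nr + 1L
  ci <- (hits - 1L) %/% nr + 1L
  sv <- gm$stat[hits]
  ord <- order(-sv, ri, ci)
  ri <- ri[ord]; ci <- ci[ord]; sv <- sv[ord]
  excl2 <- (2 * params$psf_sigma)^2
  keep_r <- numeric(0); keep_c <- numeric(0); keep_s <- numeric(0)
  for (k in seq_along(ri)) {
    if (length(keep_r) == 0 ||
        all((keep_r - ri[k])^2 + (keep_c - ci[k])^2 > excl2)) {
      keep_r <- c(keep_r, ri[k]); keep_c <- c(keep_c, ci[k])
      keep_s <- c(keep_s, sv[k])
    }
  }
  data.frame(row = as.integer(keep_r), col = as.integer(keep_c),
             stat = keep_s)
}

# Expected window image and its parameter Jacobian for the integrated
# Gaussian + background model. xs, ys: 0-based pixel indices of the window;
# x0, y0 continuous px (origin at image's upper-left corner).
psf_model <- function(xs, ys, x0, y0, N, b, sigma, grad_sigma = FALSE) {
  ex <- stats::pnorm((c(xs, xs[length(xs)] + 1L) - x0) / sigma)
  ey <- stats::pnorm((c(ys, ys[length(ys)] + 1L) - y0) / sigma)
  dx <- diff(ex); dy <- diff(ey)
  zx_lo <- (xs - x0) / sigma; zx_hi <- (xs + 1 - x0) / sigma
  zy_lo <- (ys - y0) / sigma; zy_hi <- (ys + 1 - y0) / sigma
  ddx <- (stats::dnorm(zx_lo) - stats::dnorm(zx_hi)) / sigma
  ddy <- (stats::dnorm(zy_lo) - stats::dnorm(zy_hi)) / sigma
  mu <- N * (dy %o% dx) + b
  out <- list(mu = mu,
              dmu_dx = N * (dy %o% ddx),
              dmu_dy = N * (ddy %o% dx),
              dmu_dN = dy %o% dx,
              dmu_db = matrix(1, length(ys), length(xs)))
  if (grad_sigma) {
    dsx <- (zx_lo * stats::dnorm(zx_lo) - zx_hi * stats::dnorm(zx_hi)) / sigma
    dsy <- (zy_lo * stats::dnorm(zy_lo) - zy_hi * stats::dnorm(zy_hi)) / sigma
    out$dmu_dsigma <- N * ((dsy %o% dx) + (dy %o% dsx))
  }
  out
}

#' Fit one emitter by maximum-likelihood Gauss-Newton
#'
#' Maximises the Poisson likelihood of an integrated-Gaussian +
#' constant-background model over (x, y, photons, background) — and
#' optionally the PSF width — by Fisher-scoring (Gauss-Newton on the
#' likelihood surface), starting from the candidate pixel. Iterates until
#' the position step falls below `convergence_tol` or `max_iterations`;
#' fits whose position step grows three iterations in a row, or whose
#' photon count ends below `min_photons`, are rejected (`NULL`).
#'
#' The reported `uncertainty` is the Cramer-Rao bound at the fitted
#' parameters (square root of the mean of the x and y variances from the
#' inverse Fisher information).
#'
#' @param img numeric matrix on the photon scale.
#' @param candidate list/row with 1-based `row` and `col` elements.
#' @param params a [detection_params()].
#' @return a one-row data.frame (`x_px`, `y_px`, `photons`, `background`,
#'   `sigma_px`, `uncertainty_px`, `iterations`, `converged`) or `NULL` if
#'   rejected.
#' @export
fit_emitter <- function(img, candidate, params = detection_params()) {
  w <- params$window_radius
  nr <- nrow(img); nc <- ncol(img)
  i0 <- candidate$row; j0 <- candidate$col
  is <- max(1L, i0 - w):min(nr, i0 + w)
  js <- max(1L, j0 - w):min(nc, j0 + w)
  d <- img[is, js, drop = FALSE]
  xs <- js - 1L  # 0-based pixel indices
  ys <- is - 1L
  b <- max(min(d), 1e-6)
  N <- max(sum(d - b), 1)
  x0 <- j0 - 0.5; y0 <- i0 - 0.5
  sigma <- params$psf_sigma
  fit_sig <- params$fit_sigma
  prev_step <- Inf; grow <- 0L; converged <- FALSE; it <- 0L
  while (it < params$max_iterations) {
    it <- it + 1L
    mdl <- psf_model(xs, ys, x0, y0, N, b, sigma, grad_sigma = fit_sig)
    mu <- pmax(mdl$mu, 1e-9)
    r <- d - mdl$mu
    J <- cbind(as.vector(mdl$dmu_dx), as.vector(mdl$dmu_dy),
               as.vector(mdl$dmu_dN), as.vector(mdl$dmu_db))
    if (fit_sig) J <- cbind(J, as.vector(mdl$dmu_dsigma))
    # quarter-photon floor keeps near-empty pixels from dominating the
    # weights when the background is very low
    wt <- 1 / pmax(as.vector(mu), 0.25)
    A <- crossprod(J, J * wt)
    g <- crossprod(J, as.vector(r) * wt)
    step <- tryCatch(solve(A + diag(1e-9, ncol(A)), g),
                     error = function(e) NULL)
    if (is.null(step)) return(NULL)
    # damp wild steps so Fisher scoring cannot leave the window in one jump
    pos_step <- sqrt(step[1]^2 + step[2]^2)
    if (pos_step > 1) step <- step / pos_step
    x0 <- min(max(x0 + step[1], xs[1]), xs[length(xs)] + 1)
    y0 <- min(max(y0 + step[2], ys[1]), ys[length(ys)] + 1)
    N <- max(N + step[3], 1e-3)
    b <- max(b + step[4], 1e-9)
    if (fit_sig) sigma <- min(max(sigma + step[5], 0.3), 2 * params$psf_sigma)
    pos_step <- sqrt(step[1]^2 + step[2]^2)
    if (pos_step < params$convergence_tol) { converged <- TRUE; break }
    grow <- if (pos_step > prev_step) grow + 1L else 0L
    if (grow >= 3L) return(NULL)
    prev_step <- pos_step
  }
  if (!converged || N < params$min_photons) return(NULL)
  mdl <- psf_model(xs, ys, x0, y0, N, b, sigma, grad_sigma = fit_sig)
  mu <- pmax(mdl$mu, 1e-9)
  J <- cbind(as.vector(mdl$dmu_dx), as.vector(mdl$dmu_dy),
             as.vector(mdl$dmu_dN), as.vector(mdl$dmu_db))
  FI <- crossprod(J, J / as.vector(mu))
  unc <- tryCatch({
    V <- solve(FI)
    sqrt((V[1, 1] + V[2, 2]) / 2)
  }, error = function(e) NA_real_)
  data.frame(x_px = x0, y_px = y0, photons = N, background = b,
             sigma_px = sigma, uncertainty_px = unc, iterations = it,
             converged = converged)
}

fit_round <- function(img, cands, params, round) {
  fits <- vector("list", nrow(cands))
  for (k in seq_len(nrow(cands))) {
    f <- fit_emitter(img, cands[k, ], params)
    if (!is.null(f)) { f$detection_round <- round; fits[[k]] <- f }
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits)) do.call(rbind, fits) else NULL
}

subtract_fits <- function(img, fits, psf_sigma) {
  if (is.null(fits) || nrow(fits) == 0) return(img)
  model <- render_expected_image(nrow(img), ncol(img), fits$x_px, fits$y_px,
                                 fits$photons, psf_sigma)
  img - model
}

#' Deflation loop: re-detect dimmer emitters in the fit residual
#'
#' Subtracts the fitted spot models (not the background) from the frame and
#' reruns detection + fitting on the residual, up to `max_deflation_rounds`
#' times or until a round adds nothing. After each round the subtraction
#' models are refined by alternating per-emitter refits (each emitter
#' against the image minus all the others), so that a bright emitter's fit
#' contaminated by a dimmer neighbour does not skew the neighbour's
#' position. First-pass localizations are reported unchanged (append-only);
#' new detections carry their `detection_round` and refined coordinates.
#'
#' @param img the frame (photon scale).
#' @param fitted data.frame of first-pass fits (may be `NULL`/empty).
#' @param params a [detection_params()].
#' @param n_refine alternating refinement sweeps per round (default 2;
#'   0 disables refinement).
#' @return data.frame of additional localizations (possibly zero rows).
#' @export
deflate_and_redetect <- function(img, fitted, params = detection_params(),
                                 n_refine = 2L) {
  # working copy: refined internally for subtraction; reported first-pass
  # rows stay as fitted
  work <- fitted
  extra <- NULL
  n_first <- if (is.null(fitted)) 0L else nrow(fitted)
  residual <- subtract_fits(img, work, params$psf_sigma)
  refine_all <- function(work) {
    for (sweep in seq_len(n_refine)) {
      for (i in seq_len(nrow(work))) {
        others <- work[-i, , drop = FALSE]
        res_i <- subtract_fits(img, others, params$psf_sigma)
        cand <- list(row = as.integer(floor(work$y_px[i]) + 1L),
                     col = as.integer(floor(work$x_px[i]) + 1L))
        ref <- fit_emitter(res_i, cand, params)
        if (!is.null(ref)) {
          work[i, c("x_px", "y_px", "photons", "background", "sigma_px",
                    "uncertainty_px")] <-
            ref[c("x_px", "y_px", "photons", "background", "sigma_px",
                  "uncertainty_px")]
        }
      }
    }
    work
  }
  for (round in seq_len(params$max_deflation_rounds)) {
    cands <- detect_candidates(residual, params)
    if (nrow(cands) > 0 && !is.null(work) && nrow(work) > 0) {
      # drop candidates sitting on an already-fitted emitter
      excl2 <- (2 * params$psf_sigma)^2
      ok <- vapply(seq_len(nrow(cands)), function(k) {
        all((work$x_px - (cands$col[k] - 0.5))^2 +
              (work$y_px - (cands$row[k] - 0.5))^2 > excl2)
      }, logical(1))
      cands <- cands[ok, , drop = FALSE]
    }
    if (nrow(cands) == 0) break
    new <- fit_round(residual, cands, params, round)
    if (is.null(new)) break
    work <- if (is.null(work)) new else rbind(work, new)
    if (n_refine > 0) work <- refine_all(work)
    extra <- work[setdiff(seq_len(nrow(work)), seq_len(n_first)), ,
                  drop = FALSE]
    residual <- subtract_fits(img, work, params$psf_sigma)
  }
  if (is.null(extra) || nrow(extra) == 0) {
    cbind(data.frame(x_px = numeric(0), y_px = numeric(0),
                     photons = numeric(0), background = numeric(0),
                     sigma_px = numeric(0), uncertainty_px = numeric(0),
                     iterations = integer(0), converged = logical(0),
                     detection_round = integer(0)))
  } else {
    extra
  }
}

#' Localize a single frame (detection + fit + deflation)
#'
#' @param img numeric matrix on the photon scale.
#' @param params a [detection_params()].
#' @return data.frame of localizations (px units) with `detection_round`.
#' @export
localize_frame <- function(img, params = detection_params()) {
  cands <- detect_candidates(img, params)
  first <- if (nrow(cands)) fit_round(img, cands, params, 0L) else NULL
  extra <- deflate_and_redetect(img, first, params)
  out <- if (is.null(first)) extra else rbind(first, extra)
  if (is.null(out) || nrow(out) == 0) {
    data.frame(x_px = numeric(0), y_px = numeric(0), photons = numeric(0),
               background = numeric(0), sigma_px = numeric(0),
               uncertainty_px = numeric(0), iterations = integer(0),
               converged = logical(0), detection_round = integer(0))
  } else {
    rownames(out) <- NULL
    out
  }
}

#' Localize every frame of a stack
#'
#' Runs the detection-localization-deflation procedure per frame and
#' concatenates the results as a localization table in nm. Counts are first
#' converted to the photon scale using the camera model
#' (`(counts - baseline) / (em_gain * quantum_efficiency)`). Per-frame
#' failures are logged and skipped, never abort the stack.
#'
#' @param stack a `frame_stack` (see [read_stack()]) or 3D array
#'   `[frame, row, col]` (then `pixel_size_nm` must be given).
#' @param params a [detection_params()].
#' @param camera a [camera_model()] describing the count scale; defaults to
#'   the stack's own camera if recorded, else unit gain/offset.
#' @param pixel_size_nm pixel pitch override.
#' @param verbose print a per-stack summary (default FALSE).
#' @return data.frame with `frame` (0-based), `x_nm`, `y_nm`, `photons`,
#'   `background`, `sigma_nm`, `uncertainty_nm`, `detection_round`.
#' @export
localize_stack <- function(stack, params = detection_params(), camera = NULL,
                           pixel_size_nm = NULL, verbose = FALSE) {
  if (inherits(stack, "frame_stack")) {
    if (is.null(camera)) camera <- stack$camera
    if (is.null(pixel_size_nm)) pixel_size_nm <- stack$pixel_size_nm
    data <- stack$data
  } else {
    data <- stack
  }
  check_that(length(dim(data)) == 3L, "stack must be 3D [frame, row, col]")
  check_that(is_number(pixel_size_nm, 0, strict = TRUE),
             "pixel_size_nm is required (from metadata or argument)")
  if (is.null(camera)) {
    camera <- camera_model(em_gain = 1, baseline_offset = 0, read_noise = 0,
                           quantum_efficiency = 1)
  }
  scale <- camera$em_gain * camera$quantum_efficiency
  res <- vector("list", dim(data)[1])
  n_failed <- 0L
  for (f in seq_len(dim(data)[1])) {
    img <- (data[f, , , drop = TRUE] - camera$baseline_offset) / scale
    if (!is.matrix(img)) img <- matrix(img, dim(data)[2], dim(data)[3])
    locs <- tryCatch(localize_frame(img, params), error = function(e) {
      n_failed <<- n_failed + 1L
      NULL
    })
    if (!is.null(locs) && nrow(locs) > 0) {
      locs$frame <- f - 1L
      res[[f]] <- locs
    }
  }
  if (n_failed > 0) warning(n_failed, " frame(s) skipped after errors")
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) {
    return(data.frame(frame = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), photons = numeric(0),
                      background = numeric(0), sigma_nm = numeric(0),
                      uncertainty_nm = numeric(0),
                      detection_round = integer(0)))
  }
  all <- do.call(rbind, res)
  out <- data.frame(frame = all$frame, x_nm = all$x_px * pixel_size_nm,
                    y_nm = all$y_px * pixel_size_nm, photons = all$photons,
                    background = all$background,
                    sigma_nm = all$sigma_px * pixel_size_nm,
                    uncertainty_nm = all$uncertainty_px * pixel_size_nm,
                    detection_round = all$detection_round)
  if (verbose) {
    message(sprintf("localized %d emitters over %d frames", nrow(out),
                    dim(data)[1]))
  }
  rownames(out) <- NULL
  out
}
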
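dp <- detection_params(psf_sigma = 1.2, pfa = 1e-6)

planted_frame <- function(nr = 32, nc = 32, x0 = 16.5, y0 = 16.5, N = 2000,
                          b = 10, sigma = 1.2, noise = FALSE, seed = 1) {
  mu <- expected_spot(nr, nc, x0, y0, N, b, sigma)
  if (!noise) return(mu)
  set.seed(seed)
  matrix(rpois(length(mu), mu), nr, nc)
}

test_that("detection: constant image yields no candidates", {
  expect_identical(nrow(detect_candidates(matrix(5, 32, 32), dp)), 0L)
  expect_error(detect_candidates(matrix(5, 4, 4), dp), "smaller")
})

test_that("detection finds a planted spot where the direct GLR peaks", {
  img <- planted_frame(x0 = 12.3, y0 = 19.7, noise = TRUE, seed = 5)
  cands <- detect_candidates(img, dp)
  expect_identical(nrow(cands), 1L)
  # oracle: evaluate the window GLR directly at every interior pixel
  direct <- matrix(0, 32, 32)
  for (i in 6:27) for (j in 6:27) {
    direct[i, j] <- glr_at_pixel(img, i, j, dp$psf_sigma, dp$window_radius)
  }
  peak <- which(direct == max(direct), arr.ind = TRUE)[1, ]
  expect_identical(c(cands$row, cands$col), unname(c(peak[1], peak[2])))
  expect_lt(max(abs(c(cands$row, cands$col) - c(20.2, 12.8))), 1.5)
})

test_that("per-pixel false-positive rate is calibrated to pfa", {
  p <- detection_params(psf_sigma = 1.2, pfa = 1e-3)
  n_seeds <- 150
  fp <- 0; n_pixels <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    img <- matrix(rnorm(48 * 48, 100, 5), 48, 48)
    fp <- fp + nrow(detect_candidates(img, p))
    n_pixels <- n_pixels + (48 - 2 * p$window_radius)^2
  }
  rate <- fp / n_pixels
  bound <- 1e-3 + 3 * sqrt(1e-3 * (1 - 1e-3) / n_pixels)
  expect_lte(rate, bound)
})

test_that("fitting is unbiased on symmetric noiseless input", {
  img <- planted_frame(x0 = 16.5, y0 = 16.5)
  fit <- fit_emitter(img, list(row = 17L, col = 17L), dp)
  expect_lt(abs(fit$x_px - 16.5), 1e-3)
  expect_lt(abs(fit$y_px - 16.5), 1e-3)
  expect_lt(abs(fit$photons - 2000) / 2000, 0.01)
})

test_that("subpixel fits agree with a dense grid-search oracle", {
  x0 <- 16.5 + 0.3; y0 <- 16.5 - 0.4
  img <- planted_frame(x0 = x0, y0 = y0)
  fit <- fit_emitter(img, list(row = 17L, col = 17L), dp)
  expect_lt(abs(fit$x_px - x0), 1e-2)
  expect_lt(abs(fit$y_px - y0), 1e-2)

  # oracle maximises the same Poisson likelihood by grid search on the
  # fitting window (window-local coordinates)
  w <- dp$window_radius
  win <- img[(17 - w):(17 + w), (17 - w):(17 + w)]
  orc <- grid_fit_oracle(win, dp$psf_sigma)
  expect_lt(abs((fit$x_px - (17 - w - 1)) - orc$x), 2e-2)
  expect_lt(abs((fit$y_px - (17 - w - 1)) - orc$y), 2e-2)
})

test_that("RMSE tracks the numeric CRLB and its photon scaling", {
  x0 <- 16.2; y0 <- 16.7
  run_mc <- function(N, reps, seed0) {
    err <- matrix(NA_real_, reps, 2)
    for (r in seq_len(reps)) {
      img <- planted_frame(x0 = x0, y0 = y0, N = N, b = 10, noise = TRUE,
                           seed = seed0 + r)
      cand <- detect_candidates(img, dp)
      if (nrow(cand) == 0) next
      fit <- fit_emitter(img, cand[1, ], dp)
      if (is.null(fit)) next
      err[r, ] <- c(fit$x_px - x0, fit$y_px - y0)
    }
    err[complete.cases(err), , drop = FALSE]
  }
  err1000 <- run_mc(1000, 150, 2000)
  expect_gt(nrow(err1000), 140)
  rmse1000 <- sqrt(mean(err1000^2))
  crlb <- mean(crlb_numeric(32, 32, x0, y0, 1000, 10, 1.2))
  expect_lte(rmse1000, 2 * crlb)

  err250 <- run_mc(250, 150, 4000)
  rmse250 <- sqrt(mean(err250^2))
  # quartering photons should double the error (CRLB ~ 1/sqrt(N)), within
  # Monte-Carlo slack
  expect_gt(rmse250 / rmse1000, 1.5)
  expect_lt(rmse250 / rmse1000, 2.7)
})

test_that("reported uncertainty matches the numeric CRLB", {
  img <- planted_frame(x0 = 16.4, y0 = 16.6, N = 1000, b = 10)
  fit <- fit_emitter(img, list(row = 17L, col = 17L), dp)
  w <- dp$window_radius
  crlb <- mean(crlb_numeric(2 * w + 1, 2 * w + 1, fit$x_px - (17 - w - 1),
                            fit$y_px - (17 - w - 1), 1000, 10, 1.2))
  expect_lt(abs(fit$uncertainty_px - crlb) / crlb, 0.05)
})

test_that("deflation recovers dim emitters and never edits first-pass fits", {
  dpd <- detection_params(psf_sigma = 0.8, pfa = 1e-4, window_radius = 3L)
  mu <- expected_spot(32, 32, 14.5, 16.5, 2000, 10, 0.8) +
    expected_spot(32, 32, 17.5, 16.5, 300, 0, 0.8)
  set.seed(78)
  img <- matrix(rpois(length(mu), mu), 32, 32)

  first <- irclusters:::fit_round(img, detect_candidates(img, dpd), dpd, 0L)
  extra <- deflate_and_redetect(img, first, dpd)
  all_fits <- rbind(first, extra)
  d_dim <- sqrt((all_fits$x_px - 17.5)^2 + (all_fits$y_px - 16.5)^2)
  expect_true(any(d_dim < 0.3))
  # append-only: the first-pass rows are untouched
  expect_identical(all_fits[seq_len(nrow(first)), ], first)

  # pure background residual: nothing more to find
  flat <- matrix(10, 32, 32)
  expect_identical(nrow(deflate_and_redetect(flat, NULL, dpd)), 0L)
})

test_that("localize_stack is deterministic, complete and frame-tagged", {
  cfg <- sim_config(n_frames = 6L, roi_size = 48L, photon_budget = 1500)
  ctr <- spaced_centers(9, 48, margin = 8, seed = 3) * 160
  tr <- data.frame(molecule_id = 1:9, cluster_id = 1:9, x_nm = ctr[, 1],
                   y_nm = ctr[, 2], on_start_frame = 0L,
                   on_end_frame = 5L)
  cam <- camera_model(em_gain = 50, baseline_offset = 100, read_noise = 2,
                      quantum_efficiency = 0.9)
  st <- render_frames(tr, cam, cfg, seed = 9)
  locs <- localize_stack(st, dp)
  locs2 <- localize_stack(st, dp)
  expect_identical(locs, locs2)
  expect_setequal(unique(locs$frame), 0:5)

  # recall >= 95%, no localization farther than 1 px from a true emitter
  expect_gte(nrow(locs), 0.95 * 9 * 6)
  d_min <- vapply(seq_len(nrow(locs)), function(k) {
    min(sqrt((locs$x_nm[k] - ctr[, 1])^2 + (locs$y_nm[k] - ctr[, 2])^2))
  }, numeric(1))
  expect_lt(max(d_min), 160)

  # empty stack -> empty table
  flat <- array(100, dim = c(3, 32, 32))
  empty <- localize_stack(flat, dp, camera = cam, pixel_size_nm = 160)
  expect_identical(nrow(empty), 0L)
})
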
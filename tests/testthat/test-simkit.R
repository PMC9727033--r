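test_that("config validation rejects bad fields", {
  expect_error(sim_config(n_frames = 0), "n_frames")
  expect_error(sim_config(frame_rate = 0), "frame_rate")
  expect_error(sim_config(long_fraction = 1.5), "long_fraction")
  expect_error(sim_config(cluster_birth_rate = -1), "cluster_birth_rate")
  expect_error(camera_model(em_gain = 0.5), "em_gain")
  expect_error(camera_model(quantum_efficiency = 0), "quantum_efficiency")
})

test_that("movie duration is n_frames / frame_rate (default 120 s)", {
  cfg <- sim_config()
  expect_identical(cfg$n_frames / cfg$frame_rate, 120)
})

test_that("zero birth rate gives an empty world", {
  cfg <- sim_config(cluster_birth_rate = 0)
  gt <- simulate_ground_truth(cfg, seed = 1)
  expect_identical(nrow(gt$clusters), 0L)
  expect_identical(nrow(gt$traces), 0L)
  tab <- emit_localization_table(gt, cfg)
  expect_identical(nrow(tab), 0L)
  expect_true(all(c("frame", "x_nm", "y_nm", "photons", "background",
                    "sigma_nm", "uncertainty_nm") %in% names(tab)))
})

test_that("cluster births follow the configured Poisson process", {
  # activation 0: only the birth process is exercised, keeping this fast
  cfg <- sim_config(cluster_birth_rate = 0.5, activation_rate = 0)
  counts <- vapply(seq_len(400), function(s) {
    nrow(simulate_ground_truth(cfg, seed = s)$clusters)
  }, numeric(1))
  lambda <- 0.5 * 120
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("lifetimes follow the configured mixture", {
  cfg <- sim_config(cluster_birth_rate = 50, long_fraction = 0,
                    short_lifetime_mean = 6.8, activation_rate = 0)
  lt <- simulate_ground_truth(cfg, seed = 3)$clusters$lifetime_s
  expect_gt(length(lt), 2000)
  expect_lt(abs(mean(lt) - 6.8), 3 * 6.8 / sqrt(length(lt)))

  # two-component mixture: KS non-rejection at alpha = 0.01, n = 5000
  cfg2 <- sim_config(cluster_birth_rate = 50, activation_rate = 0)
  lt2 <- simulate_ground_truth(cfg2, seed = 4)$clusters$lifetime_s[1:5000]
  pmix <- function(q) {
    0.85 * pexp(q, 1 / cfg2$short_lifetime_mean) +
      0.15 * pexp(q, 1 / cfg2$long_lifetime_mean)
  }
  ks <- suppressWarnings(ks.test(lt2, pmix))
  expect_gt(ks$p.value, 0.01)
})

test_that("ground truth and tables are seed-deterministic", {
  cfg <- sim_config(n_frames = 1200L)
  a <- simulate_ground_truth(cfg, seed = 42)
  b <- simulate_ground_truth(cfg, seed = 42)
  expect_identical(a, b)
  ta <- emit_localization_table(a, cfg, seed = 42)
  tb <- emit_localization_table(b, cfg, seed = 42)
  expect_identical(ta, tb)
  c_ <- simulate_ground_truth(cfg, seed = 43)
  expect_false(identical(a$clusters, c_$clusters))
})

test_that("traces respect lifespan and movie bounds", {
  cfg <- sim_config(n_frames = 600L)
  gt <- simulate_ground_truth(cfg, seed = 5)
  tr <- gt$traces
  expect_true(all(tr$on_end_frame >= tr$on_start_frame))
  expect_true(all(tr$on_start_frame >= 0))
  expect_true(all(tr$on_end_frame < cfg$n_frames))
  death_f <- gt$clusters$death_time_s[tr$cluster_id] * cfg$frame_rate
  expect_true(all(tr$on_end_frame <= ceiling(death_f)))
  birth_f <- gt$clusters$birth_time_s[tr$cluster_id] * cfg$frame_rate
  expect_true(all(tr$on_start_frame >= floor(birth_f)))
})

test_that("localization table reproduces the stated noise model", {
  tr <- data.frame(molecule_id = 1L, cluster_id = 1L, x_nm = 5000,
                   y_nm = 7000, on_start_frame = 5L, on_end_frame = 9L)
  cfg <- sim_config()
  tab0 <- emit_localization_table(tr, cfg, localization_noise_sd = 0)
  expect_identical(nrow(tab0), 5L)
  expect_identical(tab0$frame, 5:9)
  expect_true(all(tab0$x_nm == 5000) && all(tab0$y_nm == 7000))

  big <- data.frame(molecule_id = 1:10000, cluster_id = 1L, x_nm = 5000,
                    y_nm = 5000, on_start_frame = 0L, on_end_frame = 0L)
  tab <- emit_localization_table(big, cfg, localization_noise_sd = 20,
                                 seed = 9)
  se <- 20 / sqrt(2 * (nrow(tab) - 1))  # SE of a Gaussian SD estimate
  expect_lt(abs(sd(tab$x_nm - 5000) - 20), 3 * se)
  expect_lt(abs(sd(tab$y_nm - 5000) - 20), 3 * se)
})

test_that("rendering conserves photons and matches the acquisition shape", {
  cfg <- sim_config(n_frames = 1L, roi_size = 32L, photon_budget = 1000)
  cam <- camera_model(em_gain = 10, baseline_offset = 50, read_noise = 0,
                      quantum_efficiency = 1)
  tr <- data.frame(molecule_id = 1L, cluster_id = 1L, x_nm = 16.3 * 160,
                   y_nm = 15.8 * 160, on_start_frame = 0L, on_end_frame = 0L)
  st <- render_frames(tr, cam, cfg, noise = FALSE)
  img <- st$data[1, , ]
  total <- sum(img - cam$baseline_offset) / cam$em_gain
  expect_lt(abs(total - 1000) / 1000, 0.01)  # <= 1% Gaussian truncation

  # empty field, no noise sources beyond shot noise of zero signal
  st0 <- render_frames(gt <- list(traces = NULL), camera_model(
    em_gain = 10, baseline_offset = 50, read_noise = 0), cfg)
  expect_true(all(st0$data == 50))

  # default acquisition geometry: 2400 frames of 256 x 256
  stD <- render_frames(list(traces = NULL), camera_model(read_noise = 0),
                       sim_config(), noise = FALSE)
  expect_identical(dim(stD$data), c(2400L, 256L, 256L))
  rm(stD); gc(FALSE)
})

test_that("emitters outside the ROI are skipped with a warning", {
  cfg <- sim_config(n_frames = 1L, roi_size = 16L)
  tr <- data.frame(molecule_id = 1:2, cluster_id = 1L,
                   x_nm = c(800, 16 * 160 + 5), y_nm = c(800, 800),
                   on_start_frame = 0L, on_end_frame = 0L)
  expect_warning(st <- render_frames(tr, camera_model(), cfg), "outside")
  expect_identical(dim(st$data), c(1L, 16L, 16L))
})

test_that("synthetic puncta fields are constructed as stated", {
  t0 <- spot_field_truth(matrix(numeric(0), 0, 2), noise_sd = 0,
                         background = 3, size = 32L)
  im0 <- synth_puncta_image(t0)
  expect_true(all(im0$image == 3))
  expect_true(all(im0$label_mask == 0L))

  ctr <- spaced_centers(20, 128)
  tt <- spot_field_truth(ctr, amplitudes = 50, widths = 1.5,
                         background = 5, noise_sd = 0, size = 128L)
  im <- synth_puncta_image(tt, seed = 2)
  expect_identical(length(setdiff(unique(as.vector(im$label_mask)), 0L)), 20L)

  # two-channel construction: B is exactly 2x the A spots over background
  im2 <- synth_puncta_image(tt, seed = 2, channel_b_scale = 2)
  spot_a <- im2$image - 5
  spot_b <- im2$image_b - 5
  expect_equal(spot_b, 2 * spot_a, tolerance = 1e-12)
})

test_that("spot fields reject out-of-bounds spots", {
  expect_error(spot_field_truth(matrix(c(200, 10), 1, 2), size = 128L),
               "inside")
})
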
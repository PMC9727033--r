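make_field <- function(n_spots = 20, amp = 50, noise_sd = 1, seed = 2,
                       size = 128L, widths = 1.5) {
  ctr <- spaced_centers(n_spots, size, seed = seed)
  truth <- spot_field_truth(ctr, amplitudes = amp, widths = widths,
                            background = 5, noise_sd = noise_sd,
                            size = size)
  list(truth = truth, img = synth_puncta_image(truth, seed = seed))
}

test_that("background subtraction is exact, clipped and idempotent", {
  img <- matrix(7, 30, 30)
  out <- subtract_background(img, c(1, 5, 1, 5))
  expect_true(all(out == 0))
  expect_identical(attr(out, "background_level"), 7)

  f <- make_field(noise_sd = 0)
  bg <- subtract_background(f$img$image, c(1, 8, 1, 8))
  once <- subtract_background(img, c(2, 4, 2, 4))
  twice <- subtract_background(once, c(2, 4, 2, 4))
  expect_equal(as.vector(once), as.vector(twice))

  mask <- matrix(FALSE, 30, 30); mask[3, 3] <- TRUE
  expect_warning(subtract_background(img, c(1, 5, 1, 5), cell_mask = mask),
                 "overlaps")
  expect_error(subtract_background(img, c(0, 5, 1, 5)), "rectangle")
})

test_that("segmentation follows the printed recipe on planted spots", {
  # constant image: LoG response is flat, strict > threshold passes nothing
  expect_identical(attr(segment_puncta(matrix(4, 64, 64)), "n"), 0L)

  # isolated 1-px impulses survive thresholding but not the 3x3 opening
  imp <- matrix(0, 64, 64)
  imp[cbind(c(10, 30, 50), c(12, 40, 20))] <- 100
  expect_identical(attr(segment_puncta(imp), "n"), 0L)

  f <- make_field(20, amp = 50, noise_sd = 1, seed = 3)
  lab <- segment_puncta(f$img$image)
  expect_identical(attr(lab, "n"), 20L)
  q <- quantify_puncta(f$img$image, lab)
  # centroids within 1 px of the planted centres (mask coords are 1-based)
  d <- vapply(seq_len(20), function(k) {
    min(sqrt((q$puncta$centroid_col - 0.5 - f$truth$centers[k, 1])^2 +
               (q$puncta$centroid_row - 0.5 - f$truth$centers[k, 2])^2))
  }, numeric(1))
  expect_lt(max(d), 1)
})

test_that("pipeline order is enforced (reordering changes the mask)", {
  f <- make_field(12, amp = 30, noise_sd = 1, seed = 4)
  lab <- segment_puncta(f$img$image)
  # same kernels applied in a permuted order: LoG before median subtraction
  filt_wrong <- irclusters:::.conv2_replicate(f$img$image,
                                              irclusters:::log_kernel(1))
  med_wrong <- filt_wrong - irclusters:::.median_filter(filt_wrong, 10L)
  thr <- mean(med_wrong) + 2 * sd(as.vector(med_wrong))
  se <- matrix(TRUE, 3, 3)
  opened_wrong <- irclusters:::.binary_dilate(
    irclusters:::.binary_erode(med_wrong > thr, se), se)
  lab_wrong <- irclusters:::.label_components(opened_wrong)
  expect_false(identical(lab > 0, lab_wrong > 0))
})

test_that("c-in/c-out quantification is exact on constructed masks", {
  img <- matrix(2, 20, 20)
  mask <- matrix(0L, 20, 20)
  mask[5:8, 5:8] <- 1L
  img[mask == 1L] <- 10
  q <- quantify_puncta(img, mask)
  expect_identical(q$puncta$c_in, 10)
  expect_identical(q$c_out, 2)
  expect_identical(q$puncta$enrichment, 5)
  expect_identical(q$puncta$area_px, 16L)

  e <- suppressMessages(quantify_puncta(img, matrix(0L, 20, 20)))
  expect_identical(e$n_puncta, 0L)
  expect_identical(e$c_out, mean(img))
})

test_that("c_in grows with planted amplitude and exceeds c_out", {
  size <- 96L
  ctr <- spaced_centers(9, size, seed = 5)
  truth <- spot_field_truth(ctr, amplitudes = rep(c(20, 40, 80), each = 3),
                            widths = 1.5, background = 5, noise_sd = 0,
                            size = size)
  im <- synth_puncta_image(truth)
  lab <- segment_puncta(im$image)
  q <- quantify_puncta(im$image, lab)
  expect_true(all(q$puncta$c_in > q$c_out))
  # match puncta back to planted spots by proximity
  amp_of <- vapply(seq_len(nrow(q$puncta)), function(k) {
    d <- sqrt((q$puncta$centroid_col[k] - 0.5 - ctr[, 1])^2 +
                (q$puncta$centroid_row[k] - 0.5 - ctr[, 2])^2)
    truth$amplitudes[which.min(d)]
  }, numeric(1))
  m <- tapply(q$puncta$c_in, amp_of, mean)
  expect_true(all(diff(m[order(as.numeric(names(m)))]) > 0))
})

test_that("adding a constant leaves segmentation and c_in - c_out unchanged", {
  f <- make_field(10, amp = 40, noise_sd = 1, seed = 6)
  raw <- f$img$image
  rect <- c(1, 10, 1, 10)
  lab1 <- segment_puncta(subtract_background(raw, rect))
  lab2 <- segment_puncta(subtract_background(raw + 11.5, rect))
  expect_identical(as.vector(lab1), as.vector(lab2))
  q1 <- quantify_puncta(subtract_background(raw, rect), lab1)
  q2 <- quantify_puncta(subtract_background(raw + 11.5, rect), lab2)
  expect_equal(q1$puncta$c_in - q1$c_out, q2$puncta$c_in - q2$c_out,
               tolerance = 1e-8)
})

test_that("secondary-channel means follow the identity and slope cases", {
  f <- make_field(12, amp = 40, noise_sd = 0, seed = 7)
  lab <- segment_puncta(f$img$image)

  constB <- matrix(9, nrow(f$img$image), ncol(f$img$image))
  qB <- quantify_secondary_channel(lab, constB, c(1, 6, 1, 6))
  expect_true(all(abs(qB$puncta$mean_b - 0) < 1e-12))  # 9 - 9 background

  qA <- quantify_puncta(f$img$image, lab)
  qSame <- quantify_secondary_channel(lab, f$img$image)
  expect_equal(qSame$puncta$mean_b, qA$puncta$c_in)

  truth <- f$truth
  im2 <- synth_puncta_image(truth, seed = 7, channel_b_scale = 2)
  qb <- quantify_secondary_channel(lab, im2$image_b, c(1, 6, 1, 6))
  qa <- quantify_secondary_channel(lab, im2$image, c(1, 6, 1, 6))
  slope <- coef(lm(qb$puncta$mean_b ~ qa$puncta$mean_b))[2]
  expect_lt(abs(slope - 2), 0.05)

  expect_error(quantify_secondary_channel(lab, matrix(1, 3, 3)),
               "registered")
})

test_that("event conservation reproduces the worked arithmetic", {
  pre <- data.frame(mean_intensity = c(5, 3), area_px = c(10, 20))
  post <- data.frame(mean_intensity = 5.5, area_px = 20)
  v <- check_event_conservation(pre, post)
  expect_identical(v$total_pre, 110)
  expect_identical(v$total_post, 110)
  expect_identical(v$ratio, 1)
  expect_true(v$conserved)

  half <- check_event_conservation(pre, data.frame(mean_intensity = 5.5,
                                                   area_px = 10))
  expect_identical(half$ratio, 0.5)
  expect_false(half$conserved)

  # relabelling puncta within a side cannot change the verdict
  v2 <- check_event_conservation(pre[2:1, ], post)
  expect_identical(v2$ratio, v$ratio)

  expect_error(check_event_conservation(
    data.frame(mean_intensity = 0, area_px = 5), post), "total")
})

test_that("a photon-conserving rendered fusion is conserved within 5%", {
  size <- 128L
  render <- function(centers, amps, widths) {
    truth <- spot_field_truth(centers, amplitudes = amps, widths = widths,
                              background = 2, noise_sd = 0.3, size = size)
    synth_puncta_image(truth, seed = 8)
  }
  # droplet fusion: concentration conserved, footprint doubled
  pre <- render(rbind(c(44, 64), c(84, 64)), c(50, 50), 1.5)
  post <- render(rbind(c(64, 64)), c(50), 1.5 * sqrt(2))
  side <- function(im) {
    bg <- subtract_background(im$image, c(1, 10, 1, 10))
    lab <- segment_puncta(im$image)
    q <- quantify_puncta(bg, lab)
    data.frame(mean_intensity = q$puncta$c_in, area_px = q$puncta$area_px)
  }
  v <- check_event_conservation(side(pre), side(post), tolerance = 0.05)
  expect_true(v$conserved)
})

test_that("region means average the background-subtracted polygon", {
  img <- matrix(0, 40, 40)
  img[11:20, 11:30] <- 7
  poly <- cbind(c(10, 30, 30, 10), c(10, 10, 20, 20))  # x, y vertices
  expect_identical(region_mean_intensity(img, poly), 7)

  img2 <- matrix(c(4, 8), 40, 40)
  mask <- matrix(TRUE, 40, 40)
  expect_identical(region_mean_intensity(img2, mask), 6)

  f <- make_field(8, seed = 9)
  whole <- matrix(TRUE, 128, 128)
  got <- region_mean_intensity(f$img$image, whole, c(1, 10, 1, 10))
  bg <- mean(f$img$image[1:10, 1:10])
  expect_equal(got, mean(pmax(f$img$image - bg, 0)), tolerance = 1e-12)

  expect_error(region_mean_intensity(img, matrix(FALSE, 40, 40)), "empty")
})

test_that("cell-count extrapolation scales by the sampled fraction", {
  # factor-1 geometry: a slice as thick as the cell samples everything
  all1 <- extrapolate_cell_counts(
    list(plasma_membrane = 7, cytoplasm = 5, nucleus = 3, cell = 2),
    cell_length_um = 20, cell_width_um = 10, cell_height_um = 5,
    slice_thickness_um = 5, nucleus_fraction = 1)
  expect_equal(all1$whole_cell_estimate, all1$slice_count)

  # slice sampling 1/8 of the cytoplasm volume: count 3 -> estimate 24
  v <- extrapolate_cell_counts(list(cytoplasm = 3), 20, 10,
                               cell_height_um = 8, slice_thickness_um = 1)
  expect_identical(v$whole_cell_estimate, 24)

  # halving the slice thickness doubles the volume factor
  v1 <- extrapolate_cell_counts(list(cytoplasm = 1), 20, 10, 5, 1)
  v2 <- extrapolate_cell_counts(list(cytoplasm = 1), 20, 10, 5, 0.5)
  expect_equal(v2$factor, 2 * v1$factor)

  expect_error(extrapolate_cell_counts(list(bogus = 1), 20, 10), "region")
  expect_error(extrapolate_cell_counts(list(cytoplasm = 1), -2, 10),
               "positive")
})
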
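test_that("all colonies on a low-noise plate are recovered near their centers", {
  plate <- simulate_plate(50, image_size = c(512, 512), seed = 61)
  g <- detect_colonies(plate$gfp, "GFP")
  r <- detect_colonies(plate$rfp, "RFP")
  for (det in list(g, r)) {
    m <- match_truth(plate$truth, det, tol = 3)
    expect_equal(m$tp, 50)
    expect_equal(m$fp, 0)
    expect_lt(m$max_err, 2)
  }
})

test_that("a pure-background image yields no detections", {
  plate <- simulate_plate(0, image_size = c(256, 256), seed = 62)
  expect_equal(nrow(detect_colonies(plate$gfp, "GFP")), 0)
  expect_equal(nrow(detect_colonies(plate$rfp, "RFP")), 0)
})

test_that("two touching colonies are declumped into two records", {
  img <- array(0, c(200, 200, 3))
  plane <- matrix(0, 200, 200)
  plane <- partchar:::render_disc(plane, 90, 100, 12, 120, 1)
  plane <- partchar:::render_disc(plane, 114, 100, 12, 120, 1)  # 24 px apart
  img[, , 2] <- pmin(plane, 255) / 255
  det <- detect_colonies(img, "GFP",
                         detect_params(min_circularity = 0.5))
  expect_equal(nrow(det), 2)
  expect_true(all(abs(sort(det$x) - c(90, 114)) < 4))
})

test_that("identical coordinate lists match 1:1 with nothing left over", {
  plate <- simulate_plate(20, image_size = c(400, 400), seed = 63)
  g <- detect_colonies(plate$gfp, "GFP")
  r <- detect_colonies(plate$rfp, "RFP")
  m <- match_colonies(g, r, max_dist_px = 5)
  expect_equal(nrow(m), 20)
  expect_equal(nrow(attr(m, "unmatched_gfp")), 0)
  expect_equal(nrow(attr(m, "unmatched_rfp")), 0)
})

test_that("a small channel shift still matches; extras are reported", {
  g <- tibble::tibble(record_id = 1:4, channel = "GFP",
                      x = c(10, 50, 90, 130), y = rep(20, 4),
                      size_px = 100L, mean_channel_value = 50,
                      saturated_frac = 0, flag_saturated = FALSE)
  r <- g
  r$channel <- "RFP"
  r$x <- r$x + 1  # 1 px shift
  m <- match_colonies(g, r, max_dist_px = 5)
  expect_equal(nrow(m), 4)
  r_extra <- dplyr::bind_rows(r, dplyr::mutate(r[1, ], record_id = 5L, x = 300))
  m2 <- match_colonies(g, r_extra, max_dist_px = 5)
  expect_equal(nrow(m2), 4)
  expect_equal(attr(m2, "unmatched_rfp")$x, 300)
})

test_that("colony intensity follows the integrated GFP/RFP ratio", {
  expect_equal(colony_intensity(100, 100), 1)
  expect_equal(colony_intensity(10 * 100, 20 * 100), 0.5)
  # scaling both sizes by k cancels
  expect_equal(colony_intensity(10 * 300, 20 * 300), 0.5)
  expect_error(colony_intensity(5, 0), "undefined")
})

test_that("quantified intensities match truth on noise-free plates", {
  tp <- plate_truth_params(noise_sd = 0)
  plate <- simulate_plate(25, image_size = c(512, 512), truth_params = tp,
                          seed = 64)
  m <- phenotype_plate(plate$gfp, plate$rfp)
  expect_equal(nrow(m), 25)
  d <- sqrt(outer(plate$truth$x, m$x, "-")^2 +
              outer(plate$truth$y, m$y, "-")^2)
  idx <- apply(d, 1, which.min)
  rel <- m$colony_intensity[idx] /
    (plate$truth$gfp_level / plate$truth$rfp_level)
  expect_true(all(abs(rel - 1) < 0.05))
})

test_that("a common exposure factor leaves intensities nearly unchanged", {
  tp <- plate_truth_params(noise_sd = 0, gfp_range = c(30, 120),
                           rfp_range = c(60, 120))
  plate <- simulate_plate(15, image_size = c(400, 400), truth_params = tp,
                          seed = 65)
  m1 <- phenotype_plate(plate$gfp, plate$rfp)
  scale_img <- function(img, k) pmin(img * k, 1)
  m2 <- phenotype_plate(scale_img(plate$gfp, 1.5), scale_img(plate$rfp, 1.5))
  expect_equal(nrow(m2), nrow(m1))
  drift <- abs(sort(m2$colony_intensity) / sort(m1$colony_intensity) - 1)
  expect_true(all(drift < 0.01))
})

test_that("saturated colonies are flagged", {
  tp <- plate_truth_params(noise_sd = 0)
  expect_warning(
    plate <- simulate_plate(5, image_size = c(300, 300), truth_params = tp,
                            gfp_levels = rep(400, 5),
                            rfp_levels = rep(100, 5), seed = 66),
    "clip")
  det <- detect_colonies(plate$gfp, "GFP")
  expect_true(all(det$flag_saturated))
})

test_that("size-bias diagnostic reports noise-level correlation on flat truth", {
  tp <- plate_truth_params(noise_sd = 2, radius_range = c(6, 14))
  plate <- simulate_plate(100, image_size = c(900, 900), truth_params = tp,
                          gfp_levels = rep(80, 100),
                          rfp_levels = rep(100, 100), seed = 67)
  m <- phenotype_plate(plate$gfp, plate$rfp)
  expect_gte(nrow(m), 98)
  rep <- size_bias_report(m)
  expect_lt(abs(rep$rank_correlation), 0.3)
})

test_that("size-bias diagnostic flags degenerate and constructed cases", {
  base <- tibble::tibble(colony_index = 1:20, x = 1, y = 1, dist_px = 0,
                         size_gfp = 100L, size_rfp = 100L, mean_g = 50,
                         mean_r = 50, total_gfp = 5000, total_rfp = 5000,
                         flag_saturated = FALSE, colony_intensity = 1)
  expect_true(is.na(size_bias_report(base)$rank_correlation))
  pos <- dplyr::mutate(base, size_gfp = 10L * colony_index,
                       size_rfp = 10L * colony_index,
                       colony_intensity = colony_index / 10)
  expect_gt(size_bias_report(pos)$rank_correlation, 0.9)
  expect_error(size_bias_report(base[1:2, ]), "3")
})

test_that("replicate plates of one truth agree within the injected noise", {
  gfp <- runif(30, 40, 160); rfp <- runif(30, 80, 120)
  means <- vapply(1:3, function(s) {
    plate <- simulate_plate(30, image_size = c(512, 512),
                            gfp_levels = gfp, rfp_levels = rfp, seed = 70 + s)
    mean(phenotype_plate(plate$gfp, plate$rfp)$colony_intensity)
  }, numeric(1))
  cv <- sd(means) / mean(means)
  expect_lt(cv, 0.05)
})

test_that("plate images round-trip through PNG files", {
  plate <- simulate_plate(8, image_size = c(256, 256), seed = 68)
  dir <- withr::local_tempdir()
  paths <- write_plate(plate, dir)
  img <- read_plate_image(paths[["gfp"]])
  expect_equal(dim(img), dim(plate$gfp))
  expect_equal(img, plate$gfp, tolerance = 1e-8)
})
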
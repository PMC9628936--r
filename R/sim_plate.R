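#' Rendering and acquisition parameters for synthetic plates
#'
#' All intensity values are expressed on the 8-bit camera scale (0-255),
#' matching the dynamic range of the plate photographs the pipeline
#' consumes.
#'
#' @param radius_range Colony radius range in px, drawn uniformly.
#' @param gfp_range,rfp_range Ranges for per-colony true channel levels
#'   (8-bit units), drawn log-uniformly (GFP) / uniformly (RFP) when
#'   explicit levels are not supplied.
#' @param background Flat background level added to every pixel.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param edge_sd Gaussian edge softness of the rendered colony rim, px.
#'   The disc interior (r <= radius) is flat, so the disc mean equals the
#'   programmed level; the soft skirt lies outside the nominal radius.
#' @return A list of parameters for [simulate_plate()].
#' @export
plate_truth_params <- function(radius_range = c(6, 12),
                               gfp_range = c(20, 220),
                               rfp_range = c(60, 160),
                               background = 10,
                               noise_sd = 3,
                               edge_sd = 2) {
  stopifnot(radius_range[1] > 0, noise_sd >= 0, edge_sd >= 0)
  list(radius_range = radius_range, gfp_range = gfp_range,
       rfp_range = rfp_range, background = background,
       noise_sd = noise_sd, edge_sd = edge_sd)
}

# Adds one soft-edged disc to a plane (8-bit units), in place via return.
render_disc <- function(plane, x, y, radius, level, edge_sd) {
  h <- nrow(plane); w <- ncol(plane)
  skirt <- ceiling(radius + 3 * edge_sd + 1)
  rows <- max(1, floor(y + 1 - skirt)):min(h, ceiling(y + 1 + skirt))
  cols <- max(1, floor(x + 1 - skirt)):min(w, ceiling(x + 1 + skirt))
  dy <- (rows - 1) - y
  dx <- (cols - 1) - x
  d <- sqrt(outer(dy^2, dx^2, "+"))
  prof <- ifelse(d <= radius, 1,
                 ifelse(edge_sd > 0, exp(-(d - radius)^2 / (2 * edge_sd^2)), 0))
  prof[d > radius + 3 * edge_sd] <- 0
  plane[rows, cols] <- plane[rows, cols] + level * prof
  plane
}

#' Simulate a dual-channel fluorescent plate image with known ground truth
#'
#' Renders `n_colonies` non-overlapping, roughly circular colonies into a
#' GFP-channel and an RFP-channel RGB image. Each colony is a flat disc
#' with a Gaussian-soft rim; the mean of the relevant color channel over
#' the disc (r <= radius, background subtracted, noise off) equals the
#' programmed level, so rendered plates carry an exact intensity ground
#' truth. Pixel values are clipped to the 8-bit range and quantized as a
#' PNG writer would, and a warning is raised when a programmed level would
#' clip (saturation on the camera).
#'
#' @param n_colonies Number of colonies to place (0 allowed).
#' @param image_size `c(height, width)` in pixels.
#' @param truth_params See [plate_truth_params()].
#' @param gfp_levels,rfp_levels Optional numeric vectors (length
#'   `n_colonies`) of per-colony true levels, overriding random draws;
#'   used to tie plates to programmed part strengths.
#' @param seed Integer seed; output is bit-identical given the seed.
#' @param max_retries Placement attempts per colony before giving up.
#' @return A list of class `partchar_plate`: `gfp` and `rfp` (H x W x 3
#'   arrays in `[0, 1]`), and `truth`, a tibble with `colony_id`, `x`, `y`
#'   (0-based pixel coordinates, origin top-left, x = column), `radius_px`,
#'   `gfp_level`, `rfp_level`.
#' @examples
#' plate <- simulate_plate(5, image_size = c(200, 200), seed = 1)
#' plate$truth
#' @export
simulate_plate <- function(n_colonies, image_size = c(512, 512),
                           truth_params = plate_truth_params(),
                           gfp_levels = NULL, rfp_levels = NULL,
                           seed = 1, max_retries = 200) {
  tp <- truth_params
  h <- image_size[1]; w <- image_size[2]
  with_seed(seed, {
    radii <- if (n_colonies > 0) {
      runif(n_colonies, tp$radius_range[1], tp$radius_range[2])
    } else numeric(0)
    if (is.null(gfp_levels) && n_colonies > 0) {
      gfp_levels <- exp(runif(n_colonies, log(tp$gfp_range[1]), log(tp$gfp_range[2])))
    }
    if (is.null(rfp_levels) && n_colonies > 0) {
      rfp_levels <- runif(n_colonies, tp$rfp_range[1], tp$rfp_range[2])
    }
    if (n_colonies > 0 &&
        any(gfp_levels + tp$background > 255 | rfp_levels + tp$background > 255)) {
      warn("some programmed levels exceed the 8-bit range and will clip")
    }

    # sequential rejection placement; skirts must not touch
    skirt <- 3 * tp$edge_sd + 1
    xs <- ys <- numeric(n_colonies)
    for (i in seq_len(n_colonies)) {
      placed <- FALSE
      margin <- radii[i] + skirt
      if (2 * margin >= min(h, w)) {
        abort("image too small for the requested colony radius")
      }
      for (try in seq_len(max_retries)) {
        cx <- runif(1, margin, w - 1 - margin)
        cy <- runif(1, margin, h - 1 - margin)
        if (i == 1 || all(sqrt((xs[seq_len(i - 1)] - cx)^2 +
                               (ys[seq_len(i - 1)] - cy)^2) >
                          radii[seq_len(i - 1)] + radii[i] + 2 * skirt)) {
          xs[i] <- cx; ys[i] <- cy; placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "could not place colony %d of %d after %d tries; %d x %d px supports roughly %d colonies at these radii",
          i, n_colonies, max_retries, h, w,
          floor(0.5 * h * w / (pi * (max(radii) + 2 * skirt)^2))))
      }
    }

    make_channel <- function(levels, channel_index) {
      plane <- matrix(tp$background, h, w)
      for (i in seq_len(n_colonies)) {
        plane <- render_disc(plane, xs[i], ys[i], radii[i], levels[i], tp$edge_sd)
      }
      img <- array(0, c(h, w, 3))
      for (k in 1:3) {
        noisy <- (if (k == channel_index) plane else matrix(tp$background, h, w))
        if (tp$noise_sd > 0) noisy <- noisy + rnorm(h * w, 0, tp$noise_sd)
        img[, , k] <- round(pmin(pmax(noisy, 0), 255)) / 255
      }
      img
    }
    gfp_img <- make_channel(gfp_levels, 2L)
    rfp_img <- make_channel(rfp_levels, 1L)

    structure(list(
      gfp = gfp_img, rfp = rfp_img,
      truth = tibble::tibble(
        colony_id = seq_len(n_colonies),
        x = xs, y = ys, radius_px = radii,
        gfp_level = as.numeric(gfp_levels %||% numeric(0)),
        rfp_level = as.numeric(rfp_levels %||% numeric(0))
      )
    ), class = "partchar_plate")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.partchar_plate <- function(x, ...) {
  cat(sprintf("<partchar_plate> %d x %d px, %d colonies\n",
              nrow(x$gfp), ncol(x$gfp), nrow(x$truth)))
  invisible(x)
}

#' Mean channel value over a colony disc
#'
#' Averages one color channel over the pixels within `radius` of a center,
#' on the 8-bit scale. Used to verify rendered plates against their truth
#' table and as an oracle for detection accuracy.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param x,y 0-based center (x = column, y = row).
#' @param radius Disc radius in px.
#' @param channel "green" or "red".
#' @param background Background level (8-bit units) subtracted from the mean.
#' @return Mean background-subtracted channel value (8-bit units).
#' @export
disc_mean <- function(image, x, y, radius, channel = c("green", "red"),
                      background = 0) {
  channel <- match.arg(channel)
  k <- if (channel == "green") 2L else 1L
  rows <- max(1, floor(y + 1 - radius)):min(nrow(image), ceiling(y + 1 + radius))
  cols <- max(1, floor(x + 1 - radius)):min(ncol(image), ceiling(x + 1 + radius))
  d2 <- outer(((rows - 1) - y)^2, ((cols - 1) - x)^2, "+")
  vals <- image[rows, cols, k][d2 <= radius^2]
  mean(vals) * 255 - background
}

#' Write a simulated plate to PNG images and a truth TSV
#'
#' @param plate A `partchar_plate`.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Invisibly, the written paths (gfp, rfp, truth).
#' @export
write_plate <- function(plate, dir, prefix = "plate") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_g <- file.path(dir, paste0(prefix, "_gfp.png"))
  p_r <- file.path(dir, paste0(prefix, "_rfp.png"))
  p_t <- file.path(dir, paste0(prefix, "_truth.tsv"))
  png::writePNG(plate$gfp, p_g)
  png::writePNG(plate$rfp, p_r)
  write_tsv_file(plate$truth, p_t)
  invisible(c(gfp = p_g, rfp = p_r, truth = p_t))
}
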
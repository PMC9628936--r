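#' Read a plate photograph into an RGB array
#'
#' @param path PNG or TIFF file.
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
read_plate_image <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Colony detection parameters
#'
#' @param min_size Minimum segmented region area in px (default 30).
#' @param min_circularity Minimum circularity `4*pi*A/P^2` (default 0.6);
#'   filters debris and merged shapes that survive declumping.
#' @param background_radius Half-width of the large median filter used to
#'   estimate the background illumination field, px.
#' @param watershed_tolerance Height tolerance of the distance-transform
#'   watershed used to split touching colonies.
#' @param min_threshold Threshold floor (8-bit units) so that pure
#'   background noise never segments into foreground.
#' @param smooth_sigma Gaussian pre-smoothing (px) applied to the plane
#'   before thresholding; the mask is taken from the smoothed plane but
#'   channel values are measured on the unsmoothed one.
#' @param threshold_method "noise" (default): threshold at `noise_k`
#'   robust noise SDs above background, which keeps dim colonies when a
#'   few bright ones dominate the histogram; or "otsu".
#' @param noise_k Multiplier for the noise-based threshold.
#' @param saturation_level Pixel value (8-bit) at or above which a pixel
#'   counts as saturated.
#' @param max_saturated_frac Regions with a larger saturated-pixel
#'   fraction are flagged.
#' @param stat Region channel statistic: "mean" (channel value x size =
#'   integrated intensity) or "sum".
#' @return A list of parameters for [detect_colonies()].
#' @export
detect_params <- function(min_size = 30, min_circularity = 0.6,
                          background_radius = 31, watershed_tolerance = 1,
                          min_threshold = 8, smooth_sigma = 1,
                          threshold_method = c("noise", "otsu"), noise_k = 3.5,
                          saturation_level = 254, max_saturated_frac = 0.05,
                          stat = c("mean", "sum")) {
  list(min_size = min_size, min_circularity = min_circularity,
       background_radius = background_radius,
       watershed_tolerance = watershed_tolerance,
       min_threshold = min_threshold, smooth_sigma = smooth_sigma,
       threshold_method = match.arg(threshold_method), noise_k = noise_k,
       saturation_level = saturation_level,
       max_saturated_frac = max_saturated_frac,
       stat = match.arg(stat))
}

#' Detect colonies in one channel of a plate image
#'
#' Segmentation recipe: the channel plane driving the detection (green for
#' the GFP image, red for the RFP image) is background-corrected with a
#' large-kernel median filter, thresholded by Otsu's method, labelled into
#' connected components, declumped by a distance-transform watershed, and
#' filtered by minimum size and circularity. Positions are region
#' centroids in 0-based pixel coordinates (origin top-left, x = column).
#' Channel values are reported on the 8-bit scale after background
#' subtraction.
#'
#' @param image H x W x 3 array in `[0, 1]` ([read_plate_image()]).
#' @param channel "GFP" (green plane) or "RFP" (red plane).
#' @param params See [detect_params()].
#' @return Tibble sorted by (y, x), one row per colony: `record_id`,
#'   `channel`, `x`, `y`, `size_px`, `mean_channel_value`,
#'   `saturated_frac`, `flag_saturated`. A blank image yields zero rows.
#'   The tibble carries a `saturated_image` attribute set when more than
#'   `max_saturated_frac` of all plane pixels are saturated.
#' @export
detect_colonies <- function(image, channel = c("GFP", "RFP"),
                            params = detect_params()) {
  channel <- match.arg(channel)
  plane <- image[, , if (channel == "GFP") 2 else 1] * 255

  bg <- EBImage::medianFilter(plane / 255, params$background_radius) * 255
  corrected <- pmax(plane - bg, 0)

  smoothed <- if (params$smooth_sigma > 0) {
    EBImage::gblur(corrected, sigma = params$smooth_sigma)
  } else {
    corrected
  }
  thr <- if (params$threshold_method == "otsu") {
    EBImage::otsu(smoothed / 255, range = c(0, 1)) * 255
  } else {
    # robust noise scale: colonies are sparse, so the plane MAD is noise
    params$noise_k * stats::mad(as.numeric(smoothed), center = 0)
  }
  thr <- max(thr, params$min_threshold)
  mask <- smoothed > thr
  if (!any(mask)) {
    out <- empty_colony_tbl(channel)
    attr(out, "saturated_image") <- FALSE
    return(out)
  }

  # declump touching colonies on the distance transform
  dist <- EBImage::distmap(EBImage::Image(mask * 1))
  labels <- EBImage::watershed(dist, tolerance = params$watershed_tolerance)
  labels <- EBImage::imageData(labels)

  mom <- EBImage::computeFeatures.moment(labels)
  shp <- EBImage::computeFeatures.shape(labels)
  if (is.null(dim(mom))) { mom <- t(mom); shp <- t(shp) }

  area <- shp[, "s.area"]
  perim <- pmax(shp[, "s.perimeter"], 1)
  circ <- pmin(4 * pi * area / perim^2, 1.2)
  keep <- area >= params$min_size & circ >= params$min_circularity

  ids <- which(keep)
  sat_plane <- plane >= params$saturation_level
  stats_fun <- if (params$stat == "mean") mean else sum
  vals <- vapply(ids, function(i) {
    px <- labels == i
    c(stats_fun(corrected[px]), mean(sat_plane[px]))
  }, numeric(2))

  out <- tibble::tibble(
    channel = channel,
    x = mom[ids, "m.cy"] - 1,  # EBImage: dim1 = matrix row = y
    y = mom[ids, "m.cx"] - 1,
    size_px = as.integer(area[ids]),
    mean_channel_value = if (length(ids)) vals[1, ] else numeric(0),
    saturated_frac = if (length(ids)) vals[2, ] else numeric(0)
  )
  out <- dplyr::arrange(out, .data$y, .data$x)
  out <- dplyr::mutate(out, record_id = dplyr::row_number(), .before = 1)
  out$flag_saturated <- out$saturated_frac > params$max_saturated_frac
  attr(out, "saturated_image") <- mean(sat_plane) > params$max_saturated_frac
  out
}

empty_colony_tbl <- function(channel) {
  tibble::tibble(record_id = integer(0), channel = character(0),
                 x = numeric(0), y = numeric(0), size_px = integer(0),
                 mean_channel_value = numeric(0), saturated_frac = numeric(0),
                 flag_saturated = logical(0))
}

#' Ratiometric colony intensity
#'
#' The colony intensity is the integrated GFP signal over the integrated
#' RFP signal: `(mean green value x green size) / (mean red value x red
#' size)`. RFP from a fixed constitutive cassette acts as the internal
#' growth control, making the ratio robust to colony size and exposure.
#'
#' @param total_gfp,total_rfp Integrated channel signals (mean x size).
#' @param label Optional colony label used in the division-guard error.
#' @return `total_gfp / total_rfp`.
#' @examples
#' colony_intensity(10 * 100, 20 * 100)  # 0.5
#' @export
colony_intensity <- function(total_gfp, total_rfp, label = NULL) {
  if (any(total_rfp <= 0)) {
    bad <- which(total_rfp <= 0)[1]
    abort(sprintf("total RFP is zero for colony %s; intensity undefined",
                  (label %||% seq_along(total_rfp))[bad]))
  }
  total_gfp / total_rfp
}

#' Link colonies across the GFP and RFP channel images
#'
#' Greedy mutual-nearest-neighbour pairing of detections from the two
#' channel photographs of the same plate, closest pairs first, each record
#' used at most once, under a maximum center distance. Pairs receive the
#' ratiometric colony intensity.
#'
#' @param gfp_records,rfp_records [detect_colonies()] outputs for the two
#'   channels.
#' @param max_dist_px Maximum center distance for a valid pair.
#' @return Tibble of class `partchar_matched`, one row per pair, sorted by
#'   (y, x): `colony_index`, `x`, `y`, `dist_px`, `size_gfp`, `size_rfp`,
#'   `mean_g`, `mean_r`, `total_gfp`, `total_rfp`, `colony_intensity`,
#'   `flag_saturated` (either channel). Unmatched records are attached as
#'   attributes `unmatched_gfp` / `unmatched_rfp`.
#' @export
match_colonies <- function(gfp_records, rfp_records, max_dist_px = 10) {
  ng <- nrow(gfp_records); nr <- nrow(rfp_records)
  pairs <- NULL
  if (ng > 0 && nr > 0) {
    d <- sqrt(outer(gfp_records$x, rfp_records$x, "-")^2 +
                outer(gfp_records$y, rfp_records$y, "-")^2)
    cand <- which(d <= max_dist_px, arr.ind = TRUE)
    ord <- order(d[cand], gfp_records$record_id[cand[, 1]])
    cand <- cand[ord, , drop = FALSE]
    used_g <- logical(ng); used_r <- logical(nr)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_g[i] && !used_r[j]) {
        used_g[i] <- TRUE; used_r[j] <- TRUE; keep[k] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand)) {
      g <- gfp_records[cand[, 1], ]
      r <- rfp_records[cand[, 2], ]
      pairs <- tibble::tibble(
        x = (g$x + r$x) / 2, y = (g$y + r$y) / 2,
        dist_px = d[cand],
        size_gfp = g$size_px, size_rfp = r$size_px,
        mean_g = g$mean_channel_value, mean_r = r$mean_channel_value,
        total_gfp = g$mean_channel_value * g$size_px,
        total_rfp = r$mean_channel_value * r$size_px,
        flag_saturated = g$flag_saturated | r$flag_saturated,
        .gfp_id = g$record_id, .rfp_id = r$record_id
      )
    }
  }
  if (is.null(pairs)) {
    pairs <- tibble::tibble(x = numeric(0), y = numeric(0),
                            dist_px = numeric(0), size_gfp = integer(0),
                            size_rfp = integer(0), mean_g = numeric(0),
                            mean_r = numeric(0), total_gfp = numeric(0),
                            total_rfp = numeric(0),
                            flag_saturated = logical(0),
                            .gfp_id = integer(0), .rfp_id = integer(0))
  }
  pairs <- dplyr::arrange(pairs, .data$y, .data$x)
  pairs$colony_intensity <- if (nrow(pairs)) {
    colony_intensity(pairs$total_gfp, pairs$total_rfp)
  } else numeric(0)
  out <- dplyr::mutate(pairs, colony_index = dplyr::row_number(), .before = 1)
  gfp_ids <- out$.gfp_id; rfp_ids <- out$.rfp_id
  out$.gfp_id <- NULL; out$.rfp_id <- NULL
  attr(out, "unmatched_gfp") <- gfp_records[!gfp_records$record_id %in% gfp_ids, ]
  attr(out, "unmatched_rfp") <- rfp_records[!rfp_records$record_id %in% rfp_ids, ]
  class(out) <- c("partchar_matched", class(out))
  out
}

#' Phenotype one plate from its two channel images
#'
#' Convenience wrapper: detect in both channels, link across channels, and
#' return matched colonies with intensities.
#'
#' @param gfp_image,rfp_image RGB arrays or file paths.
#' @param params [detect_params()].
#' @param max_dist_px Matching tolerance in px.
#' @return See [match_colonies()].
#' @export
phenotype_plate <- function(gfp_image, rfp_image, params = detect_params(),
                            max_dist_px = 10) {
  if (is.character(gfp_image)) gfp_image <- read_plate_image(gfp_image)
  if (is.character(rfp_image)) rfp_image <- read_plate_image(rfp_image)
  g <- detect_colonies(gfp_image, "GFP", params)
  r <- detect_colonies(rfp_image, "RFP", params)
  match_colonies(g, r, max_dist_px)
}

#' Does colony size bias the quantified intensity?
#'
#' Diagnostic: per-colony (size, intensity) pairs plus their Spearman rank
#' correlation. The ratiometric intensity should be size-free; a strong
#' correlation indicates saturation, focus or background artefacts.
#'
#' @param matched A [match_colonies()] result with at least 3 colonies.
#' @return A list of class `partchar_sizebias`: `data` (tibble `size_px`,
#'   `colony_intensity`), `rank_correlation` (NA when size is constant),
#'   `n`.
#' @export
size_bias_report <- function(matched) {
  if (nrow(matched) < 3) abort("size-bias report needs at least 3 colonies")
  size <- (matched$size_gfp + matched$size_rfp) / 2
  rho <- if (length(unique(size)) < 2 ||
             length(unique(matched$colony_intensity)) < 2) {
    NA_real_
  } else {
    suppressWarnings(cor(size, matched$colony_intensity, method = "spearman"))
  }
  structure(list(
    data = tibble::tibble(size_px = size,
                          colony_intensity = matched$colony_intensity),
    rank_correlation = rho, n = nrow(matched)
  ), class = "partchar_sizebias")
}

#' @export
print.partchar_sizebias <- function(x, ...) {
  cat(sprintf("<partchar_sizebias> n = %d, Spearman rho = %s\n", x$n,
              if (is.na(x$rank_correlation)) "undefined (constant input)"
              else sprintf("%.3f", x$rank_correlation)))
  invisible(x)
}

#' @method tidy partchar_sizebias
#' @export
tidy.partchar_sizebias <- function(x, ...) x$data

#' @method glance partchar_sizebias
#' @export
glance.partchar_sizebias <- function(x, ...) {
  tibble::tibble(n = x$n, rank_correlation = x$rank_correlation)
}
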
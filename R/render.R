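#' Rendering parameters for synthetic spheroid images
#'
#' Controls the phase-contrast-like appearance of simulated well images: a
#' dark spheroid disk on a brighter background with a linear illumination
#' gradient, a bright halo at the spheroid rim, pixel speckle, and a Poisson
#' number of small dark debris blobs. These emulate the nuisance features of
#' automated microscopy (uneven lighting, noise, floating debris); they are
#' not a physical optics model.
#'
#' @param image_size square image side in pixels (>= 64; default 128).
#' @param radius_scale spheroid radius per cube root of cell count
#'   (px / cell^(1/3)); the default makes an 18-day untreated spheroid fill
#'   roughly one third of a 128 px frame.
#' @param background_gradient_amp peak-to-trough amplitude of the linear
#'   illumination gradient (intensity units).
#' @param speckle_sd per-pixel Gaussian noise SD (intensity units).
#' @param artifact_rate expected number of debris blobs per image.
#' @param halo_width width of the bright rim halo (px).
#' @param center_jitter_sd SD of the spheroid's off-center displacement (px).
#' @return An object of class `render_params`.
#' @export
render_params <- function(image_size = 128, radius_scale = 0.5,
                          background_gradient_amp = 0.08,
                          speckle_sd = 0.015, artifact_rate = 1,
                          halo_width = 3, center_jitter_sd = 1.5) {
  stopifnot(image_size >= 64, radius_scale > 0,
            background_gradient_amp >= 0, speckle_sd >= 0,
            artifact_rate >= 0, halo_width >= 0, center_jitter_sd >= 0)
  structure(list(image_size = as.integer(image_size),
                 radius_scale = radius_scale,
                 background_gradient_amp = background_gradient_amp,
                 speckle_sd = speckle_sd, artifact_rate = artifact_rate,
                 halo_width = halo_width, center_jitter_sd = center_jitter_sd),
            class = "render_params")
}

#' Render one synthetic spheroid well image
#'
#' Draws a centered dark disk whose radius is `radius_scale * count^(1/3)`
#' (sphere volume proportional to cell number) with a bright halo at its
#' rim, on a background carrying a linear illumination gradient, speckle
#' noise and debris blobs. Fully deterministic given `seed`; a cell count of
#' 0 renders an empty well.
#'
#' @param count true cell count (>= 0).
#' @param rp a [render_params()].
#' @param seed integer seed for this image's randomness (gradient direction,
#'   jitter, speckle, debris).
#' @return A numeric matrix in `[0, 1]` of size `image_size x image_size`,
#'   with attributes `center` (x, y of the disk center, px), `radius` (px)
#'   and `debris_mask` (logical matrix marking debris pixels).
#' @export
render_spheroid <- function(count, rp = render_params(), seed = 1) {
  if (count < 0) stopf("`count` must be non-negative")
  s <- rp$image_size
  radius <- rp$radius_scale * count^(1 / 3)
  with_seed(seed, {
    # linear illumination gradient in a random direction
    theta <- stats::runif(1, 0, 2 * pi)
    xs <- matrix(rep(seq_len(s), each = s), nrow = s)   # column index
    ys <- matrix(rep(seq_len(s), times = s), nrow = s)  # row index
    proj <- (cos(theta) * (xs - (s + 1) / 2) + sin(theta) * (ys - (s + 1) / 2)) / s
    img <- 0.75 + rp$background_gradient_amp * proj

    cx <- (s + 1) / 2 + stats::rnorm(1, 0, rp$center_jitter_sd)
    cy <- (s + 1) / 2 + stats::rnorm(1, 0, rp$center_jitter_sd)
    if (radius > 0) {
      r <- sqrt((xs - cx)^2 + (ys - cy)^2)
      # soft-edged dark disk, slightly darker towards the core
      edge <- 1 / (1 + exp((r - radius) / 0.8))
      depth <- 0.45 + 0.10 * pmax(1 - r / pmax(radius, 1), 0)
      img <- img - depth * edge
      if (rp$halo_width > 0) {
        hw <- rp$halo_width / 2
        img <- img + 0.12 * exp(-((r - radius - hw) / pmax(hw, 0.5))^2)
      }
    }

    debris_mask <- matrix(FALSE, s, s)
    n_debris <- stats::rpois(1, rp$artifact_rate)
    if (n_debris > 0) {
      for (k in seq_len(n_debris)) {
        dcx <- stats::runif(1, 3, s - 2)
        dcy <- stats::runif(1, 3, s - 2)
        dr <- stats::runif(1, 1, 3)
        hit <- (xs - dcx)^2 + (ys - dcy)^2 <= dr^2
        # keep debris clear of the spheroid so masks stay unambiguous
        if (radius > 0) {
          hit <- hit & sqrt((xs - cx)^2 + (ys - cy)^2) > radius + rp$halo_width + 2
        }
        img[hit] <- img[hit] - 0.35
        debris_mask <- debris_mask | hit
      }
    }

    if (rp$speckle_sd > 0) {
      img <- img + matrix(stats::rnorm(s * s, 0, rp$speckle_sd), s, s)
    }
    img <- pmin(pmax(img, 0), 1)
    attr(img, "center") <- c(x = cx, y = cy)
    attr(img, "radius") <- radius
    attr(img, "debris_mask") <- debris_mask
    img
  })
}

image_file_name <- function(plate_id, well_index, day) {
  sprintf("%s_w%02d_d%02d.png", plate_id, well_index, round(day))
}

#' Write a simulated dataset to disk
#'
#' Writes one 8-bit grayscale PNG per record plus three CSVs:
#' `metadata.csv` (all wells, all days, with the image file name),
#' `labels.csv` (endpoint-day wells only, mirroring an endpoint lytic
#' viability assay), and `ground_truth.csv` (noise-free viability for every
#' day, for evaluation only — a real experiment would not have it).
#'
#' @param records data.frame from [simulate_trajectories()] (one row per
#'   well per day), with columns `plate_id`, `well_index`, `day`,
#'   `viability_label`, `true_viability_pct`, `true_cell_count`.
#' @param images list of image matrices, one per record row.
#' @param out_dir output directory (created if absent); images go to
#'   `out_dir/images/`.
#' @param endpoint_day day whose labels are exported (default: max day in
#'   `records`).
#' @return Invisibly, a list with the three CSV paths and the image dir.
#' @export
write_dataset <- function(records, images, out_dir,
                          endpoint_day = suppressWarnings(max(records$day))) {
  if (nrow(records) != length(images)) {
    stopf("need exactly one image per record: %d records, %d images",
          nrow(records), length(images))
  }
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stopf("cannot create output directory %s", img_dir)

  files <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    files[i] <- image_file_name(records$plate_id[i], records$well_index[i],
                                records$day[i])
    png::writePNG(images[[i]], file.path(img_dir, files[i]))
  }
  meta <- cbind(records[, setdiff(names(records),
                                  c("true_cell_count", "true_viability_pct",
                                    "viability_label")), drop = FALSE],
                file = files)
  labels <- records[records$day == endpoint_day, , drop = FALSE]
  labels <- data.frame(file = files[records$day == endpoint_day],
                       plate_id = labels$plate_id,
                       well_index = labels$well_index,
                       day = labels$day,
                       viability_pct = labels$viability_label)
  truth <- cbind(records, file = files)

  paths <- list(metadata = file.path(out_dir, "metadata.csv"),
                labels = file.path(out_dir, "labels.csv"),
                ground_truth = file.path(out_dir, "ground_truth.csv"),
                images = img_dir)
  utils::write.csv(meta, paths$metadata, row.names = FALSE)
  utils::write.csv(labels, paths$labels, row.names = FALSE)
  utils::write.csv(truth, paths$ground_truth, row.names = FALSE)
  invisible(paths)
}

#' Simulate a complete image dataset
#'
#' Convenience wrapper: simulates trajectories for the design, renders one
#' image per well per requested day, and optionally appends empty-well
#' reference images (labelled 0% viability, attached to the endpoint day and
#' to no drug pair). Everything is deterministic given `seed`.
#'
#' @inheritParams simulate_trajectories
#' @param rp a [render_params()].
#' @param n_empty number of empty-well reference images (default one per
#'   plate).
#' @param out_dir optional; when given, the dataset is also written with
#'   [write_dataset()].
#' @return list with `records` (one row per image, including empty wells),
#'   `images` (list of matrices) and, if written, the paths from
#'   [write_dataset()].
#' @export
simulate_dataset <- function(design, growth = growth_params(),
                             response = drug_response_params(),
                             rp = render_params(), noise_sd = 5, seed = 1,
                             days = design$imaging_days,
                             n_empty = NULL, out_dir = NULL) {
  seeds <- derive_seeds(seed, 3)
  records <- simulate_trajectories(design, growth, response,
                                   noise_sd = noise_sd, seed = seeds[1],
                                   days = days)
  if (is.null(n_empty)) {
    n_empty <- nrow(unique(records[, c("plate_id"), drop = FALSE]))
  }
  if (n_empty > 0) {
    endpoint <- max(records$day)
    empty <- data.frame(
      plate_id = "EMPTY", cell_line = "EMPTY", pair_id = 0L,
      drug1 = "", drug2 = "", replicate = 1L,
      row = NA_integer_, col = NA_integer_,
      dose1_uM = NA_real_, dose2_uM = NA_real_,
      well_index = seq_len(n_empty), day = endpoint,
      true_cell_count = 0, true_viability_pct = 0, viability_label = 0,
      stringsAsFactors = FALSE
    )
    records <- rbind(records, empty)
  }
  img_seeds <- derive_seeds(seeds[2], nrow(records))
  images <- lapply(seq_len(nrow(records)), function(i) {
    render_spheroid(records$true_cell_count[i], rp, seed = img_seeds[i])
  })
  out <- list(records = records, images = images)
  if (!is.null(out_dir)) {
    out$paths <- write_dataset(records, images, out_dir)
  }
  out
}
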
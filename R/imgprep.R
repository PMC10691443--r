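#' Preprocessing configuration
#'
#' Parameters of the deterministic standardization chain applied to every
#' well image before decoding: illumination flattening and percentile
#' contrast stretch, median + Gaussian denoising, adaptive margin trimming
#' around the spheroid, small-artifact removal, and rescaling to a fixed
#' resolution. None of these steps is randomized.
#'
#' @param low_pct,high_pct intensity percentiles mapped to 0 and 1 by the
#'   contrast stretch (defaults 1 and 99; robust to debris outliers).
#' @param median_kernel median filter width in px; odd, `>= 1` (1 = off).
#' @param blur_sigma Gaussian blur SD in px (0 = off).
#' @param crop_margin fraction by which the spheroid bounding box is
#'   expanded on each side before cropping.
#' @param output_size final square resolution in px (default 224).
#' @param min_area minimum connected-component area (px^2) below which
#'   foreground is treated as artifact.
#' @param dark_spheroid `TRUE` when spheroids are darker than background
#'   (the synthetic renders); set `FALSE` for bright-on-dark data.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(low_pct = 1, high_pct = 99, median_kernel = 3,
                              blur_sigma = 1, crop_margin = 0.15,
                              output_size = 224, min_area = 25,
                              dark_spheroid = TRUE) {
  if (low_pct < 0 || high_pct > 100 || low_pct >= high_pct) {
    stopf("need 0 <= low_pct < high_pct <= 100")
  }
  if (median_kernel < 1 || median_kernel %% 2 == 0) {
    stopf("`median_kernel` must be odd and >= 1, got %s", median_kernel)
  }
  if (output_size < 32) stopf("`output_size` must be >= 32")
  structure(list(low_pct = low_pct, high_pct = high_pct,
                 median_kernel = as.integer(median_kernel),
                 blur_sigma = blur_sigma, crop_margin = crop_margin,
                 output_size = as.integer(output_size),
                 min_area = min_area, dark_spheroid = dark_spheroid),
            class = "preprocess_config")
}

#' Flatten a linear illumination gradient
#'
#' Fits a linear plane `a + b*x + c*y` to the brighter (background) pixels
#' and divides the image by the plane normalized to its mean, removing
#' smooth lighting differences while preserving mean brightness. Part of the
#' contrast-maximization stage.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param bg_quantile pixels above this intensity quantile are treated as
#'   background for the plane fit.
#' @return Matrix of the same size, clipped to `[0, 1]`.
#' @export
flatten_illumination <- function(img, bg_quantile = 0.4) {
  s1 <- nrow(img); s2 <- ncol(img)
  ys <- matrix(rep(seq_len(s1), times = s2), s1) / s1
  xs <- matrix(rep(seq_len(s2), each = s1), s1) / s2
  thr <- stats::quantile(img, bg_quantile, names = FALSE)
  bg <- img >= thr
  fit <- stats::lm.fit(cbind(1, xs[bg], ys[bg]), img[bg])
  co <- fit$coefficients
  plane <- co[1] + co[2] * xs + co[3] * ys
  plane <- pmax(plane, 1e-3)
  out <- img * (mean(plane) / plane)
  pmin(pmax(out, 0), 1)
}

#' Percentile contrast stretch
#'
#' Linearly rescales intensities so the `low_pct` and `high_pct` percentiles
#' map to 0 and 1, clipping outside; images with no dynamic range are
#' returned unchanged.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param low_pct,high_pct percentiles in `[0, 100]`.
#' @return Matrix in `[0, 1]`.
#' @export
stretch_contrast <- function(img, low_pct = 1, high_pct = 99) {
  qs <- stats::quantile(img, c(low_pct, high_pct) / 100, names = FALSE)
  if (diff(qs) < 1e-8) return(img)
  pmin(pmax((img - qs[1]) / (qs[2] - qs[1]), 0), 1)
}

#' Median + Gaussian denoising
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param median_kernel odd median filter width in px (1 = off).
#' @param blur_sigma Gaussian blur SD in px (0 = off).
#' @return Matrix of the same size; output range is contained in the input
#'   range (both filters are convex combinations of input pixels).
#' @export
denoise_image <- function(img, median_kernel = 3, blur_sigma = 1) {
  if (median_kernel %% 2 == 0) {
    stopf("`median_kernel` must be odd, got %d", median_kernel)
  }
  out <- img
  if (median_kernel == 3) {
    out <- median3x3(out)
  } else if (median_kernel > 1) {
    out <- EBImage::imageData(
      EBImage::medianFilter(EBImage::Image(out), (median_kernel - 1L) / 2L))
  }
  if (blur_sigma > 0) {
    out <- EBImage::imageData(EBImage::gblur(EBImage::Image(out), blur_sigma))
  }
  matrix(pmin(pmax(out, 0), 1), nrow(img), ncol(img))
}

# Vectorized 3x3 median via a 19-comparator sorting network (Paeth) over
# the 9 edge-replicated neighbour shifts; much faster than a generic filter.
median3x3 <- function(img) {
  n1 <- nrow(img); n2 <- ncol(img)
  pad <- matrix(0, n1 + 2L, n2 + 2L)
  pad[2:(n1 + 1L), 2:(n2 + 1L)] <- img
  pad[1, ] <- pad[2, ]; pad[n1 + 2L, ] <- pad[n1 + 1L, ]
  pad[, 1] <- pad[, 2]; pad[, n2 + 2L] <- pad[, n2 + 1L]
  v <- vector("list", 9L)
  k <- 0L
  for (dy in 0:2) for (dx in 0:2) {
    k <- k + 1L
    v[[k]] <- pad[dy + seq_len(n1), dx + seq_len(n2)]
  }
  cx <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  pairs <- list(c(2,3),c(5,6),c(8,9),c(1,2),c(4,5),c(7,8),c(2,3),c(5,6),
                c(8,9),c(1,4),c(6,9),c(5,8),c(4,7),c(2,5),c(3,6),c(5,8),
                c(5,3),c(7,5),c(5,3))
  for (p in pairs) cx(p[1], p[2])
  v[[5]]
}

# Otsu-threshold foreground mask (spheroid polarity from cfg) and its
# connected-component labels.
segment_components <- function(img, cfg) {
  work <- if (cfg$dark_spheroid) 1 - img else img
  thr <- EBImage::otsu(EBImage::Image(work))
  mask <- work > thr
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  list(mask = mask, labels = labels)
}

clamp_window <- function(center, side, size) {
  side <- min(side, size)
  lo <- round(center - side / 2)
  lo <- max(1L, min(lo, size - side + 1L))
  c(lo, lo + side - 1L)
}

#' Trim image margins around the spheroid
#'
#' Locates the spheroid as the largest foreground connected component of an
#' Otsu segmentation of the blurred image and returns a square crop of its
#' bounding box expanded by `crop_margin` on each side, clamped to the image
#' bounds. When no component reaches `min_area` (e.g. an empty well), a
#' centered square crop of half the image side is returned instead.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param cfg a [preprocess_config()].
#' @return Square sub-matrix of `img`, with attribute `crop_box`
#'   `(row_lo, row_hi, col_lo, col_hi)`.
#' @export
trim_margins <- function(img, cfg = preprocess_config()) {
  blurred <- denoise_image(img, 1, max(cfg$blur_sigma, 1))
  seg <- segment_components(blurred, cfg)
  sizes <- tabulate(seg$labels[seg$labels > 0])
  s1 <- nrow(img); s2 <- ncol(img)
  if (length(sizes) > 0 && max(sizes) >= cfg$min_area) {
    comp <- which.max(sizes)
    idx <- which(seg$labels == comp, arr.ind = TRUE)
    r_range <- range(idx[, 1]); c_range <- range(idx[, 2])
    side <- max(diff(r_range), diff(c_range)) + 1L
    side <- ceiling(side * (1 + 2 * cfg$crop_margin))
    rw <- clamp_window(mean(r_range), side, s1)
    cw <- clamp_window(mean(c_range), min(side, s1), s2)
    # keep the crop square even when clamping truncated one axis
    side <- min(rw[2] - rw[1], cw[2] - cw[1]) + 1L
    rw <- clamp_window(mean(rw), side, s1)
    cw <- clamp_window(mean(cw), side, s2)
  } else {
    side <- max(32L, round(min(s1, s2) / 2))
    rw <- clamp_window((s1 + 1) / 2, side, s1)
    cw <- clamp_window((s2 + 1) / 2, side, s2)
  }
  out <- img[rw[1]:rw[2], cw[1]:cw[2], drop = FALSE]
  attr(out, "crop_box") <- c(rw, cw)
  out
}

#' Remove small foreground artifacts
#'
#' Replaces foreground connected components smaller than `min_area` with the
#' local background level (median of non-foreground pixels). The largest
#' component is never removed, so an image is never blanked even if
#' everything in it is small.
#'
#' @param img numeric matrix in `[0, 1]` (typically the trimmed crop).
#' @param cfg a [preprocess_config()].
#' @return Matrix of the same size, with attribute `n_removed` (number of
#'   components replaced).
#' @export
remove_artifacts <- function(img, cfg = preprocess_config()) {
  seg <- segment_components(img, cfg)
  labels <- seg$labels
  sizes <- tabulate(labels[labels > 0])
  out <- img
  n_removed <- 0L
  if (length(sizes) > 0) {
    keep <- which.max(sizes)
    bg_level <- stats::median(img[labels == 0])
    if (!is.finite(bg_level)) bg_level <- stats::median(img)
    for (comp in seq_along(sizes)) {
      if (comp != keep && sizes[comp] > 0 && sizes[comp] < cfg$min_area) {
        out[labels == comp] <- bg_level
        n_removed <- n_removed + 1L
      }
    }
  }
  attr(out, "n_removed") <- n_removed
  out
}

# Exact area-average downscale via interval-overlap weight matrices.
area_weights <- function(n_in, n_out) {
  r <- n_in / n_out
  w <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    lo <- (j - 1) * r; hi <- j * r
    i0 <- floor(lo) + 1L; i1 <- ceiling(hi)
    for (i in i0:min(i1, n_in)) {
      w[j, i] <- max(0, min(hi, i) - max(lo, i - 1)) / r
    }
  }
  w
}

#' Resize a square image
#'
#' Area averaging when downscaling (every input pixel contributes with its
#' exact overlap weight), bilinear interpolation when upscaling; identity
#' when sizes match. Deterministic.
#'
#' @param img numeric matrix.
#' @param size target side in px.
#' @return `size x size` matrix in the input range.
#' @export
resize_image <- function(img, size) {
  if (nrow(img) == size && ncol(img) == size) return(matrix(img, size, size))
  if (size < min(nrow(img), ncol(img))) {
    wr <- area_weights(nrow(img), size)
    wc <- area_weights(ncol(img), size)
    wr %*% img %*% t(wc)
  } else {
    m <- EBImage::imageData(
      EBImage::resize(EBImage::Image(img), w = size, h = size,
                      filter = "bilinear"))
    matrix(pmin(pmax(m, min(img)), max(img)), size, size)
  }
}

#' Standardize one well image
#'
#' The full deterministic chain: illumination flattening + percentile
#' contrast stretch, median/Gaussian denoising, margin trimming around the
#' spheroid, small-artifact removal, and resizing to
#' `cfg$output_size x cfg$output_size`. Intensities stay in `[0, 1]`.
#'
#' @param img a numeric matrix in `[0, 1]`, or a path to a PNG/TIFF file.
#' @param cfg a [preprocess_config()].
#' @return `output_size x output_size` matrix in `[0, 1]`.
#' @export
preprocess_image <- function(img, cfg = preprocess_config()) {
  if (is.character(img)) img <- read_well_image(img)
  x <- flatten_illumination(img)
  x <- stretch_contrast(x, cfg$low_pct, cfg$high_pct)
  x <- denoise_image(x, cfg$median_kernel, cfg$blur_sigma)
  x <- trim_margins(x, cfg)
  x <- remove_artifacts(x, cfg)
  x <- resize_image(x, cfg$output_size)
  matrix(pmin(pmax(x, 0), 1), cfg$output_size, cfg$output_size)
}

#' Read a grayscale well image
#'
#' @param path PNG or TIFF file; color images are averaged to grayscale.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_well_image <- function(path) {
  if (!file.exists(path)) stopf("cannot read image: %s", path)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") {
    png::readPNG(path)
  } else {
    EBImage::imageData(EBImage::readImage(path))
  }
  if (length(dim(m)) == 3L) m <- apply(m[, , 1:min(3, dim(m)[3]), drop = FALSE], c(1, 2), mean)
  matrix(pmin(pmax(m, 0), 1), nrow(m), ncol(m))
}

#' Preprocess a batch of image files
#'
#' Applies [preprocess_image()] to every input file, writes the results as
#' PNGs under `out_dir` (same file names), and returns a per-file log.
#'
#' @param files character vector of input image paths.
#' @param out_dir output directory (created if absent).
#' @param cfg a [preprocess_config()].
#' @param verbose print one log line per file.
#' @return data.frame log with `file`, `out`, `crop_box`, `n_removed`,
#'   invisibly.
#' @export
preprocess_files <- function(files, out_dir, cfg = preprocess_config(),
                             verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- read_well_image(files[i])
    x <- flatten_illumination(img)
    x <- stretch_contrast(x, cfg$low_pct, cfg$high_pct)
    x <- denoise_image(x, cfg$median_kernel, cfg$blur_sigma)
    x <- trim_margins(x, cfg)
    box <- attr(x, "crop_box")
    x <- remove_artifacts(x, cfg)
    nrm <- attr(x, "n_removed")
    x <- resize_image(x, cfg$output_size)
    out_path <- file.path(out_dir, basename(files[i]))
    png::writePNG(matrix(pmin(pmax(x, 0), 1), nrow(x)), out_path)
    if (verbose) {
      message(sprintf("%s -> %s crop=[%s] removed=%d", files[i],
                      out_path, paste(box, collapse = ","), nrm))
    }
    log[[i]] <- data.frame(file = files[i], out = out_path,
                           crop = paste(box, collapse = ","),
                           n_removed = nrm)
  }
  invisible(do.call(rbind, log))
}
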
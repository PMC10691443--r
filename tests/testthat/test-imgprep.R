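test_that("contrast stretch maps percentiles linearly and handles degenerate input", {
  flat <- matrix(0.5, 32, 32)
  expect_identical(stretch_contrast(flat, 1, 99), flat)
  spanning <- matrix(seq(0, 1, length.out = 1024), 32)
  expect_equal(stretch_contrast(spanning, 0, 100), spanning)
  two <- matrix(rep(c(0.4, 0.6), each = 512), 32)
  out <- stretch_contrast(two, 1, 99)
  expect_setequal(unique(as.vector(out)), c(0, 1))
  expect_true(all(out[two == 0.4] == 0) && all(out[two == 0.6] == 1))
})

test_that("denoising removes isolated hot pixels and keeps the value range", {
  img <- matrix(0.3, 21, 21)
  img[11, 11] <- 1
  out <- denoise_image(img, 3, 0)
  expect_lt(max(out), 0.3 + 1e-12)
  expect_identical(denoise_image(img, 1, 0), img)      # kernel 1, sigma 0
  const <- matrix(0.7, 16, 16)
  expect_equal(denoise_image(const, 3, 1), const, tolerance = 1e-6)
  expect_error(denoise_image(img, 4, 1), "odd")
  noisy <- matrix(runif(400), 20)
  sm <- denoise_image(noisy, 3, 1.5)
  expect_gte(min(sm), min(noisy))
  expect_lte(max(sm), max(noisy))
})

test_that("margin trimming centers on the spheroid and falls back when empty", {
  rp <- render_params(artifact_rate = 0)
  img <- render_spheroid(40000, rp, seed = 21)
  cfg <- preprocess_config(output_size = 48)
  crop <- trim_margins(img, cfg)
  box <- attr(crop, "crop_box")
  expect_equal(box[2] - box[1], box[4] - box[3])  # square
  center <- c(mean(box[1:2]), mean(box[3:4]))
  truth <- attr(img, "center")
  expect_lt(abs(center[1] - truth["y"]), 5)
  expect_lt(abs(center[2] - truth["x"]), 5)
  # empty well: centered fallback
  empty <- render_spheroid(0, rp, seed = 21)
  fb <- trim_margins(empty, cfg)
  fbox <- attr(fb, "crop_box")
  expect_equal(fbox[2] - fbox[1], fbox[4] - fbox[3])
  expect_lt(abs(mean(fbox[1:2]) - 64.5), 2)
})

test_that("crops stay square and in bounds when the disk touches the edge", {
  # construct a dark disk hugging the image border
  s <- 96
  xs <- matrix(rep(1:s, each = s), s); ys <- matrix(rep(1:s, s), s)
  img <- matrix(0.8, s, s)
  img[sqrt((xs - 6)^2 + (ys - 6)^2) < 18] <- 0.2
  crop <- trim_margins(img, preprocess_config(output_size = 48))
  box <- attr(crop, "crop_box")
  expect_true(all(box >= 1 & box <= s))
  expect_equal(box[2] - box[1], box[4] - box[3])
  expect_equal(nrow(crop), ncol(crop))
})

test_that("artifact removal erases debris but never the spheroid", {
  rp <- render_params(artifact_rate = 5, speckle_sd = 0.005)
  img <- render_spheroid(40000, rp, seed = 33)
  debris <- attr(img, "debris_mask")
  skip_if(sum(debris) == 0)  # Poisson draw produced no debris
  cfg <- preprocess_config(output_size = 48, min_area = 60)
  cleaned <- remove_artifacts(img, cfg)
  # debris pixels are replaced by background-level intensities
  expect_gt(min(cleaned[debris]), 0.5)
  expect_gt(attr(cleaned, "n_removed"), 0)
  # artifact-free image passes through unchanged
  clean_in <- render_spheroid(40000, render_params(artifact_rate = 0),
                              seed = 34)
  expect_equal(remove_artifacts(clean_in, cfg), clean_in,
               tolerance = 1e-6, ignore_attr = TRUE)
  # an image holding only small blobs keeps its largest component
  s <- 64
  xs <- matrix(rep(1:s, each = s), s); ys <- matrix(rep(1:s, s), s)
  blob <- matrix(0.8, s, s)
  blob[sqrt((xs - 32)^2 + (ys - 32)^2) < 4] <- 0.2
  kept <- remove_artifacts(blob, cfg)
  expect_gt(sum(kept < 0.5), 0)
})

test_that("full preprocessing yields the standard resolution deterministically", {
  img <- render_spheroid(30000, render_params(), seed = 40)
  out <- preprocess_image(img)  # default config
  expect_equal(dim(out), c(224, 224))
  expect_true(all(out >= 0 & out <= 1))
  out2 <- preprocess_image(img)
  expect_identical(out, out2)
  # written files are byte-identical across runs
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  png::writePNG(out, f1); png::writePNG(out2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("preprocessing is near-idempotent", {
  img <- render_spheroid(30000, render_params(), seed = 41)
  cfg <- preprocess_config(output_size = 64)
  once <- preprocess_image(img, cfg)
  twice <- preprocess_image(once, cfg)
  expect_lt(mean(abs(twice - once)), 0.08)
})

test_that("illumination flattening reduces background variability", {
  rp <- render_params(background_gradient_amp = 0.12, speckle_sd = 0.01)
  img <- render_spheroid(30000, rp, seed = 50)
  truth_center <- attr(img, "center")
  s <- nrow(img)
  xs <- matrix(rep(1:s, each = s), s); ys <- matrix(rep(1:s, s), s)
  bg <- sqrt((xs - truth_center["x"])^2 + (ys - truth_center["y"])^2) >
    attr(img, "radius") + 8
  before <- sd(img[bg])
  after_img <- stretch_contrast(flatten_illumination(img), 1, 99)
  expect_lte(sd(after_img[bg]), before)
})

test_that("batch preprocessing preserves order and writes one file per input", {
  out_dir <- withr::local_tempdir()
  in_dir <- withr::local_tempdir()
  files <- character(3)
  for (i in 1:3) {
    files[i] <- file.path(in_dir, sprintf("well_%d.png", i))
    png::writePNG(render_spheroid(i * 10000, render_params(image_size = 64),
                                  seed = i), files[i])
  }
  log <- preprocess_files(files, out_dir, preprocess_config(output_size = 48))
  expect_equal(nrow(log), 3)
  expect_equal(basename(log$out), basename(files))
  expect_true(all(file.exists(log$out)))
  expect_equal(dim(png::readPNG(log$out[1])), c(48, 48))
})
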
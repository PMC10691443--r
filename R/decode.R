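#' Train/test split specification
#'
#' The split is by drug pair, never by image: all images of a pair land
#' either in the train+validation pool or in the held-out test set, so no
#' test-pair image can influence training. Within the train+validation
#' pool, wells are shuffled (seeded) and split 70/30 by default. Empty-well
#' reference images (`pair_id == 0`) always join the training pool.
#'
#' @param train_pairs integer pair ids forming the training pool; when
#'   `NULL`, half of the pairs present in the data are drawn with
#'   `split_seed`.
#' @param val_fraction fraction of the training pool held out for
#'   validation (default 0.30).
#' @param split_seed seed for pair selection and the within-pool shuffle.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_pairs = NULL, val_fraction = 0.30,
                       split_seed = 1) {
  stopifnot(val_fraction >= 0, val_fraction < 1)
  structure(list(train_pairs = train_pairs, val_fraction = val_fraction,
                 split_seed = as.integer(split_seed)),
            class = "split_spec")
}

#' Split endpoint records by drug pair
#'
#' @param records data.frame with a `pair_id` column (one row per image).
#' @param spec a [split_spec()].
#' @return `records` with an added `split` column (`"train"`, `"val"`,
#'   `"test"`).
#' @export
split_dataset <- function(records, spec = split_spec()) {
  if (!"pair_id" %in% names(records)) stopf("records need a `pair_id` column")
  pairs <- sort(setdiff(unique(records$pair_id), 0L))
  train_pairs <- spec$train_pairs
  if (is.null(train_pairs)) {
    train_pairs <- with_seed(spec$split_seed,
                             sort(sample(pairs, floor(length(pairs) / 2))))
  }
  test_pairs <- setdiff(pairs, train_pairs)
  if (length(intersect(train_pairs, test_pairs)) > 0) {
    stopf("a pair appears in both train and test sets")
  }
  if (!all(train_pairs %in% pairs)) {
    stopf("train pairs not present in data: %s",
          paste(setdiff(train_pairs, pairs), collapse = ", "))
  }
  split <- rep("test", nrow(records))
  pool <- records$pair_id %in% c(train_pairs, 0L)
  pool_idx <- which(pool)
  n_val <- floor(length(pool_idx) * spec$val_fraction)
  val_idx <- with_seed(spec$split_seed + 1L,
                       if (n_val > 0) sample(pool_idx, n_val) else integer(0))
  split[pool_idx] <- "train"
  split[val_idx] <- "val"
  records$split <- split
  records
}

#' Train the viability decoder
#'
#' Fits the dense convolutional regression network to endpoint-labelled
#' images by minimizing mean squared error with Adam. The weights with the
#' best validation MSE seen during training are retained (when no
#' validation set is given, the final weights are kept). Deterministic
#' given `cfg$train_seed`.
#'
#' @param train_images list of `input_size x input_size` matrices.
#' @param train_labels % viability labels, one per training image.
#' @param val_images,val_labels optional validation set in the same form.
#' @param cfg a [net_config()].
#' @param calibrate when a validation set is given, fit a linear
#'   recalibration of the retained model's predictions against the
#'   validation labels and apply it at prediction time (default `TRUE`).
#'   Squared-error training shrinks extreme predictions toward the label
#'   mean; because downstream normalization divides by the untreated
#'   (highest-viability) well's prediction, uncorrected shrinkage inflates
#'   every normalized viability. The recalibration is skipped when the
#'   validation predictions are degenerate or the fitted slope leaves
#'   `[0.5, 2]`.
#' @param verbose print per-epoch losses.
#' @return An object of class `viability_net`: the retained parameters,
#'   the config, `calibration` (intercept and slope applied to raw
#'   predictions), and `history` (data.frame of per-epoch train/val MSE on
#'   the % viability scale).
#' @export
train_viability_model <- function(train_images, train_labels,
                                  val_images = NULL, val_labels = NULL,
                                  cfg = net_config(), calibrate = TRUE,
                                  verbose = FALSE) {
  if (length(train_images) == 0) stopf("empty training set")
  if (length(train_images) != length(train_labels)) {
    stopf("need one label per training image")
  }
  bad_dim <- vapply(train_images,
                    function(m) any(dim(m) != cfg$input_size), TRUE)
  if (any(bad_dim)) {
    stopf("all images must be %d x %d", cfg$input_size, cfg$input_size)
  }
  hw <- cfg$input_size^2
  x_tr <- stack_images(train_images) - 0.5
  y_tr <- train_labels / 100
  has_val <- !is.null(val_images) && length(val_images) > 0
  if (has_val) {
    x_val <- stack_images(val_images) - 0.5
    y_val <- val_labels / 100
  }

  history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                        val_mse = numeric(0))
  with_seed(cfg$train_seed, {
    params <- init_params(cfg)
    flat <- flatten_params(params, cfg)
    state <- list(theta = flat,
                  m = lapply(flat, function(z) z * 0),
                  v = lapply(flat, function(z) z * 0), t = 0L)
    best_val <- Inf
    best_flat <- state$theta
    n <- length(y_tr)
    lr_decay <- cfg$lr_decay %||% 1
    lr_decay_at <- cfg$lr_decay_at %||% 1
    for (epoch in seq_len(cfg$epochs)) {
      lr_epoch <- if (epoch > lr_decay_at * cfg$epochs) {
        cfg$lr * lr_decay
      } else {
        cfg$lr
      }
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        params <- unflatten_params(state$theta, params, cfg)
        fw <- net_forward(params, cfg, select_images(x_tr, hw, idx),
                          cfg$input_size, cfg$input_size, length(idx),
                          keep_cache = TRUE)
        resid <- fw$pred - y_tr[idx]
        ep_loss <- ep_loss + sum(resid^2); ep_n <- ep_n + length(idx)
        grads <- net_backward(params, cfg, fw$cache,
                              2 * resid / length(idx))
        state <- adam_step(state, flatten_params(grads, cfg), lr_epoch)
      }
      params <- unflatten_params(state$theta, params, cfg)
      val_mse <- if (has_val) {
        mean((predict_batches(params, cfg, x_val, cfg$input_size,
                              cfg$input_size, length(y_val)) - y_val)^2)
      } else NA_real_
      history <- rbind(history, data.frame(
        epoch = epoch, train_mse = 1e4 * ep_loss / ep_n,
        val_mse = 1e4 * val_mse))
      if (verbose) {
        message(sprintf("epoch %3d  train MSE %8.2f  val MSE %8.2f",
                        epoch, 1e4 * ep_loss / ep_n, 1e4 * val_mse))
      }
      if (!has_val || val_mse <= best_val) {
        best_val <- if (has_val) val_mse else Inf
        best_flat <- state$theta
      }
    }
    params <- unflatten_params(best_flat, params, cfg)
  })
  calibration <- c(intercept = 0, slope = 1)
  if (calibrate && has_val && length(y_val) >= 3) {
    vp <- 100 * predict_batches(params, cfg, x_val, cfg$input_size,
                                cfg$input_size, length(y_val))
    if (stats::sd(vp) > 1e-8) {
      co <- stats::coef(stats::lm(100 * y_val ~ vp))
      if (all(is.finite(co)) && co[2] >= 0.5 && co[2] <= 2) {
        calibration <- c(intercept = unname(co[1]), slope = unname(co[2]))
      }
    }
  }
  structure(list(params = params, cfg = cfg, calibration = calibration,
                 history = history),
            class = "viability_net")
}

#' @export
print.viability_net <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$params, x$cfg), length, 0L))
  cat(sprintf(
    "<viability_net> input %dpx, %d dense blocks x %d layers (growth %d), %d parameters\n",
    x$cfg$input_size, x$cfg$blocks, x$cfg$layers_per_block, x$cfg$growth, np))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epochs; final train MSE %.2f, val MSE %.2f (%% viability^2)\n",
                nrow(x$history), last$train_mse, last$val_mse))
  }
  invisible(x)
}

#' Predict raw viability for a batch of images
#'
#' One finite prediction per image, on the % viability scale; no clipping
#' or normalization is applied here (see [normalize_per_day()]).
#'
#' @param model a [train_viability_model()] fit.
#' @param images list of `input_size x input_size` matrices (possibly
#'   empty).
#' @return Numeric vector of raw predicted % viability.
#' @export
predict_viability <- function(model, images) {
  stopifnot(inherits(model, "viability_net"))
  if (length(images) == 0) return(numeric(0))
  cfg <- model$cfg
  bad <- vapply(images, function(m) any(dim(m) != cfg$input_size), TRUE)
  if (any(bad)) stopf("all images must be %d x %d", cfg$input_size, cfg$input_size)
  x <- stack_images(images) - 0.5
  raw <- 100 * predict_batches(model$params, cfg, x, cfg$input_size,
                               cfg$input_size, length(images))
  cal <- model$calibration %||% c(0, 1)
  cal[1] + cal[2] * raw
}

#' Normalize raw predictions against the same-day untreated well
#'
#' Within each (plate, day) group, predictions are rescaled so the
#' untreated well (row 0, col 0) reads exactly 100% viability; negative
#' values are floored at 0. If a group's untreated prediction is missing or
#' non-positive the whole group is flagged missing rather than silently
#' scaled.
#'
#' @param preds data.frame with columns `plate_id`, `day`, `row`, `col`,
#'   `raw_pred`.
#' @return `preds` with added `viability` (% of same-day untreated) and
#'   `flag` (`""` or `"missing_reference"`).
#' @export
normalize_per_day <- function(preds) {
  need <- c("plate_id", "day", "row", "col", "raw_pred")
  if (!all(need %in% names(preds))) {
    stopf("preds needs columns: %s", paste(need, collapse = ", "))
  }
  preds$viability <- NA_real_
  preds$flag <- ""
  key <- interaction(preds$plate_id, preds$day, drop = TRUE)
  for (grp in levels(key)) {
    idx <- which(key == grp)
    ctrl <- idx[preds$row[idx] == 0L & preds$col[idx] == 0L]
    ref <- if (length(ctrl) >= 1) preds$raw_pred[ctrl[1]] else NA_real_
    if (!length(ctrl) || !is.finite(ref) || ref <= 0) {
      preds$flag[idx] <- "missing_reference"
      next
    }
    preds$viability[idx] <- pmax(100 * preds$raw_pred[idx] / ref, 0)
    preds$viability[ctrl] <- 100
  }
  preds
}

#' Agreement statistics between predicted and observed values
#'
#' Ordinary least squares of observed on predicted, with the adjusted
#' coefficient of determination
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - 2)} and the two-sided p-value
#' of the slope.
#'
#' @param pred,obs paired finite numeric vectors, `n >= 3`.
#' @return An object of class `fit_metrics`: `adj_r_squared`, `r_squared`,
#'   `p_value`, `n`, `slope`, `intercept`.
#' @export
evaluate_predictions <- function(pred, obs) {
  keep <- is.finite(pred) & is.finite(obs)
  pred <- pred[keep]; obs <- obs[keep]
  n <- length(pred)
  if (n < 3) stopf("need at least 3 paired finite values, got %d", n)
  if (stats::sd(pred) == 0) stopf("predictions have zero variance; fit undefined")
  fit <- stats::lm(obs ~ pred)
  sm <- summary(fit)
  r2 <- sm$r.squared
  structure(list(adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
                 r_squared = r2,
                 p_value = sm$coefficients["pred", "Pr(>|t|)"],
                 n = n,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1])),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("<fit_metrics> n=%d  adj R^2=%.4f  slope=%.3f  p=%.3g\n",
              x$n, x$adj_r_squared, x$slope, x$p_value))
  invisible(x)
}
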
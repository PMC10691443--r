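#' Assemble per-day synergy results into trajectories
#'
#' Groups [synergy_map()] results by (pair, cell line, method) and orders
#' each group's (day, score) points by day. Days excluded upstream by the
#' missing-data rules are simply absent — no interpolation or smoothing is
#' applied; trajectories are a pure rearrangement of the results.
#'
#' @param results list of `synergy_result` objects.
#' @return List of `trajectory` objects, each with `pair_id`, `cell_line`,
#'   `method` and `points` (data.frame `day`, `score`, `volume`,
#'   `n_wells`).
#' @export
build_trajectories <- function(results) {
  if (length(results) == 0) return(list())
  df <- synergy_results_table(results)
  dup <- duplicated(df[, c("pair_id", "cell_line", "method", "day")])
  if (any(dup)) {
    stopf("duplicate synergy result for pair %s / %s / %s / day %s",
          df$pair_id[dup][1], df$cell_line[dup][1], df$method[dup][1],
          df$day[dup][1])
  }
  key <- interaction(df$pair_id, df$cell_line, df$method, drop = TRUE)
  lapply(levels(key), function(k) {
    sub <- df[key == k, ]
    sub <- sub[order(sub$day), ]
    structure(list(pair_id = sub$pair_id[1], cell_line = sub$cell_line[1],
                   method = sub$method[1],
                   points = data.frame(day = sub$day, score = sub$score,
                                       volume = sub$volume,
                                       n_wells = sub$n_wells)),
              class = "trajectory")
  })
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s pair %s / %s: %s\n", x$method, x$pair_id,
              x$cell_line,
              paste(sprintf("d%g=%.1f", x$points$day, x$points$score),
                    collapse = " ")))
  invisible(x)
}

#' Tidy table of synergy results
#'
#' @param results list of `synergy_result` objects.
#' @return data.frame with `pair_id`, `cell_line`, `day`, `method`,
#'   `score`, `volume`, `n_wells`, `provenance`.
#' @export
synergy_results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(pair_id = r$pair_id, cell_line = r$cell_line, day = r$day,
               method = r$method, score = r$score, volume = r$volume,
               n_wells = r$n_wells_used, provenance = r$provenance,
               stringsAsFactors = FALSE)
  }))
}

#' Compare predicted and observed endpoint synergy
#'
#' Pairs predicted and observed synergy scores by (pair, cell line,
#' method) at the endpoint day and applies the same regression machinery
#' as [evaluate_predictions()].
#'
#' @param predicted,observed lists of `synergy_result` objects (or tidy
#'   tables from [synergy_results_table()]).
#' @param method optional method filter (e.g. `"LOEWE"`).
#' @param day optional day filter; defaults to the maximum day present in
#'   `observed`.
#' @return A `fit_metrics` object.
#' @export
compare_endpoint <- function(predicted, observed, method = NULL, day = NULL) {
  to_df <- function(x) if (is.data.frame(x)) x else synergy_results_table(x)
  p <- to_df(predicted); o <- to_df(observed)
  if (!is.null(method)) {
    p <- p[p$method == toupper(method), ]
    o <- o[o$method == toupper(method), ]
  }
  if (is.null(day)) day <- max(o$day)
  p <- p[p$day == day, ]; o <- o[o$day == day, ]
  m <- merge(p, o, by = c("pair_id", "cell_line", "method"),
             suffixes = c("_pred", "_obs"))
  if (nrow(m) < 3) stopf("need >= 3 paired synergy scores, got %d", nrow(m))
  evaluate_predictions(m$score_pred, m$score_obs)
}

#' Pipeline configuration
#'
#' Bundles the stage parameters of [run_pipeline()] with sensible
#' desk-scale defaults (one cell line, four drug pairs, duplicates, 128 px
#' renders decoded at 64 px).
#'
#' @param design a [study_design()].
#' @param growth a [growth_params()].
#' @param response a [drug_response_params()] or named list keyed
#'   `"<cell_line>|<pair_id>"`.
#' @param rp a [render_params()].
#' @param preprocess a [preprocess_config()]; its `output_size` must match
#'   the network `input_size`.
#' @param net a [net_config()].
#' @param split a [split_spec()].
#' @param prediction_days days on which viability is decoded and synergy
#'   computed (must be imaging days; the maximum is the labelled endpoint).
#' @param methods synergy reference methods to compute.
#' @param noise_sd viability label noise SD (%).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = NULL, growth = growth_params(),
                            response = drug_response_params(),
                            rp = render_params(),
                            preprocess = preprocess_config(output_size = 64),
                            net = net_config(input_size = 64),
                            split = split_spec(),
                            prediction_days = c(8, 11, 15, 18),
                            methods = c("loewe", "bliss", "hsa"),
                            noise_sd = 5) {
  if (is.null(design)) {
    reg <- drug_pair_registry()
    design <- study_design(registry = reg[reg$cell_line == "GBM8" &
                                            reg$pair_id %in% c(1, 4, 9, 15), ])
  }
  if (preprocess$output_size != net$input_size) {
    stopf("preprocess output_size (%d) must equal net input_size (%d)",
          preprocess$output_size, net$input_size)
  }
  structure(list(design = design, growth = growth, response = response,
                 rp = rp, preprocess = preprocess, net = net, split = split,
                 prediction_days = sort(unique(prediction_days)),
                 methods = methods, noise_sd = noise_sd),
            class = "pipeline_config")
}

#' Run the full longitudinal synergy pipeline
#'
#' Executes simulate -> preprocess -> train -> predict -> normalize ->
#' synergy -> trajectories on a synthetic dataset and evaluates the result
#' against the simulation's ground truth. Training uses only endpoint-day
#' labels (plus empty-well references); earlier days are decoded without
#' any label from those days. Observed synergy is computed from the noisy
#' endpoint labels (what an endpoint assay would report), predicted synergy
#' from the decoded viability on every prediction day.
#'
#' @param config a [pipeline_config()].
#' @param seed master seed; every stage's randomness derives from it.
#' @param out_dir optional output directory for CSVs, run log and plots.
#' @param verbose print stage log lines.
#' @return A list bundle: `records` (per-image table with predictions and
#'   normalized viability), `model`, `predicted_results` /
#'   `observed_results` (synergy), `trajectories`, `metrics` (decoder and
#'   synergy agreement), `exclusions`, and `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(seed, 4)
  design <- config$design
  endpoint <- design$endpoint_day
  days <- sort(unique(c(config$prediction_days, endpoint)))
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    if (verbose) message(line)
  }

  say("stage simulate: %d day(s), seed %d", length(days), seeds[1])
  ds <- simulate_dataset(design, config$growth, config$response, config$rp,
                         noise_sd = config$noise_sd, seed = seeds[1],
                         days = days)
  rec <- ds$records
  say("stage simulate: %d images (%d endpoint, %d empty-well)",
      nrow(rec), sum(rec$day == endpoint & rec$cell_line != "EMPTY"),
      sum(rec$cell_line == "EMPTY"))

  say("stage preprocess: output %d px", config$preprocess$output_size)
  proc <- lapply(ds$images, preprocess_image, cfg = config$preprocess)

  endpoint_rows <- rec$day == endpoint
  split_rec <- split_dataset(rec[endpoint_rows, ], config$split)
  rec$split <- "none"
  rec$split[endpoint_rows] <- split_rec$split
  tr <- rec$split == "train"; va <- rec$split == "val"
  say("stage split: %d train / %d val / %d test endpoint images",
      sum(tr), sum(va), sum(rec$split == "test"))

  say("stage train: %d epochs, seed %d", config$net$epochs,
      config$net$train_seed)
  model <- train_viability_model(proc[tr], rec$viability_label[tr],
                                 proc[va], rec$viability_label[va],
                                 config$net, verbose = FALSE)
  say("stage train: best val MSE %.1f",
      suppressWarnings(min(model$history$val_mse, na.rm = TRUE)))

  say("stage predict: %d images", nrow(rec))
  rec$raw_pred <- predict_viability(model, proc)

  real <- rec$cell_line != "EMPTY"
  norm <- normalize_per_day(rec[real, ])
  rec$viability <- NA_real_; rec$flag <- ""
  rec$viability[real] <- norm$viability
  rec$flag[real] <- norm$flag
  say("stage normalize: %d plate-day groups flagged missing",
      length(unique(paste(norm$plate_id, norm$day)[norm$flag != ""])))

  # decoder agreement on held-out endpoint wells, vs noise-free truth
  te_end <- real & rec$day == endpoint & rec$split == "test"
  decoder_fit <- evaluate_predictions(rec$viability[te_end],
                                      rec$true_viability_pct[te_end])
  say("stage evaluate: held-out endpoint adj R^2 = %.3f",
      decoder_fit$adj_r_squared)

  pred_mats <- matrices_from_table(rec[real & rec$day %in%
                                         config$prediction_days, ],
                                   value_col = "viability",
                                   provenance = "predicted")
  obs_df <- rec[real & rec$day == endpoint, ]
  obs_df$flag <- ""   # assay labels are independent of decoding flags
  obs_mats <- matrices_from_table(obs_df, value_col = "viability_label",
                                  provenance = "measured")
  predicted_results <- compute_all_synergy(pred_mats, config$methods)
  observed_results <- compute_all_synergy(obs_mats, config$methods)
  say("stage synergy: %d predicted / %d observed results (%d exclusions)",
      length(predicted_results), length(observed_results),
      nrow(attr(predicted_results, "exclusions")))

  trajectories <- build_trajectories(predicted_results)
  synergy_fit <- tryCatch(
    compare_endpoint(predicted_results, observed_results, day = endpoint),
    error = function(e) NULL)
  if (!is.null(synergy_fit)) {
    say("stage compare: endpoint synergy adj R^2 = %.3f",
        synergy_fit$adj_r_squared)
  }

  bundle <- list(records = rec, model = model,
                 predicted_results = predicted_results,
                 observed_results = observed_results,
                 trajectories = trajectories,
                 metrics = list(decoder = decoder_fit,
                                synergy = synergy_fit),
                 exclusions = attr(predicted_results, "exclusions"),
                 log = log, seed = seed)
  if (!is.null(out_dir)) write_pipeline_outputs(bundle, out_dir)
  bundle
}

# Write the CSV/plot bundle of a pipeline run.
write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec <- bundle$records
  utils::write.csv(
    rec[, c("plate_id", "cell_line", "pair_id", "replicate", "row", "col",
            "dose1_uM", "dose2_uM", "day", "split", "raw_pred", "viability",
            "flag")],
    file.path(out_dir, "predictions.csv"), row.names = FALSE)
  utils::write.csv(synergy_results_table(bundle$predicted_results),
                   file.path(out_dir, "synergy_predicted.csv"),
                   row.names = FALSE)
  utils::write.csv(synergy_results_table(bundle$observed_results),
                   file.path(out_dir, "synergy_observed.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$model$history,
                   file.path(out_dir, "training_history.csv"),
                   row.names = FALSE)
  writeLines(c(sprintf("seed: %d", bundle$seed),
               sprintf("package version: %s",
                       as.character(utils::packageVersion("spherosynergy"))),
               bundle$log),
             file.path(out_dir, "run_log.txt"))
  tryCatch(plot_trajectories(bundle$trajectories,
                             file.path(out_dir, "trajectories.png")),
           error = function(e) NULL)
  invisible(out_dir)
}

#' Plot synergy trajectories
#'
#' One panel per method, one line per (pair, cell line), score over day.
#'
#' @param trajectories list from [build_trajectories()].
#' @param file optional PNG path; when `NULL`, plots to the active device.
#' @export
plot_trajectories <- function(trajectories, file = NULL) {
  if (length(trajectories) == 0) return(invisible(NULL))
  methods <- unique(vapply(trajectories, `[[`, "", "method"))
  if (!is.null(file)) {
    grDevices::png(file, width = 420 * length(methods), height = 420)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mfrow = c(1, length(methods)), mar = c(4, 4, 2, 1))
  # restore par before any device opened above is closed, so the restore
  # cannot spawn a default device
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  for (m in methods) {
    tl <- Filter(function(t) t$method == m, trajectories)
    all_days <- range(unlist(lapply(tl, function(t) t$points$day)))
    all_sc <- range(unlist(lapply(tl, function(t) t$points$score)), 0)
    graphics::plot(NA, xlim = all_days, ylim = all_sc, xlab = "day",
                   ylab = "synergy score (% viability)", main = m)
    graphics::abline(h = 0, lty = 3)
    for (i in seq_along(tl)) {
      graphics::lines(tl[[i]]$points$day, tl[[i]]$points$score,
                      col = i, type = "b", pch = 16)
    }
  }
  invisible(NULL)
}
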
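# Experiment harnesses: variable-acceleration (specific vs generic
# networks) and leave-one-orientation-out generalization. Both operate on
# a phantom corpus described by a list of phantom_configs and return
# long-format metric tables plus paired statistics.

eval_test_pairs <- function(model, pairs, network_label) {
  do.call(rbind, lapply(seq_along(pairs), function(i) {
    s <- pairs[[i]]
    fr <- eval_range(n_frames(s$target))
    rec <- reconstruct_series(model, s$input)
    m <- metrics(rec, s$target, fr)
    data.frame(series = i, view = s$view, spokes = s$accel$spokes_per_frame,
               r_factor = s$accel$r_factor, network = network_label,
               mae = m$mae, mse = m$mse, psnr = m$psnr, ssim = m$ssim)
  }))
}

eval_gridded_pairs <- function(pairs) {
  do.call(rbind, lapply(seq_along(pairs), function(i) {
    s <- pairs[[i]]
    fr <- eval_range(n_frames(s$target))
    m <- metrics(s$input, s$target, fr)
    data.frame(series = i, view = s$view, spokes = s$accel$spokes_per_frame,
               r_factor = s$accel$r_factor, network = "gridded",
               mae = m$mae, mse = m$mse, psnr = m$psnr, ssim = m$ssim)
  }))
}

#' Variable-acceleration experiment: specific vs generic networks
#'
#' Trains one "specific" network per studied spoke count plus one
#' "generic" network whose training series are degraded at spoke counts
#' drawn randomly from `generic_set`, then evaluates every test series at
#' every studied spoke count with the gridded input, its specific network,
#' and the generic network. Paired Wilcoxon tests compare specific vs
#' generic per rate.
#'
#' @param configs Phantom corpus configuration ([corpus_configs()]).
#' @param spokes_list Spoke counts receiving a specific network.
#' @param generic_set Spoke-count pool for the generic network's random
#'   degradation (defaults to the six studied rates 13-33).
#' @param config A [train_config()].
#' @param crop Optional center-crop size for all series.
#' @param model_spec `unet_spec` used for every network (`NULL`: sized to
#'   the data).
#' @param seed Base seed (dataset rate draws and model init).
#' @return List with `results` (long data.frame: series, view, spokes,
#'   network in gridded/specific/generic, mae/mse/psnr/ssim), `summary`
#'   (per rate x network means), `stats` (per-rate paired Wilcoxon on
#'   SSIM and MAE), `models`.
#' @export
run_acceleration_experiment <- function(configs,
                                        spokes_list = c(13L, 17L, 21L, 25L, 29L, 33L),
                                        generic_set = c(13L, 17L, 21L, 25L, 29L, 33L),
                                        config = train_config(),
                                        crop = NULL, model_spec = NULL,
                                        seed = 1L) {
  datasets <- lapply(spokes_list, function(S)
    build_dataset(configs, "specific", spokes = S, crop = crop))
  names(datasets) <- as.character(spokes_list)
  generic_data <- build_dataset(configs, "generic", spokes_set = generic_set,
                                crop = crop, seed = seed)
  n <- dim(datasets[[1]][[1]]$input$frames)[1]
  if (is.null(model_spec)) model_spec <- unet_spec(n, c(8L, 16L, 32L))
  models <- list()
  for (S in as.character(spokes_list)) {
    message("training specific network, ", S, " spokes/frame")
    models[[S]] <- train(build_model(model_spec, seed = seed),
                         datasets[[S]], config)$model
  }
  message("training generic network")
  models$generic <- train(build_model(model_spec, seed = seed),
                          generic_data, config)$model
  results <- list(); stats <- list()
  for (S in as.character(spokes_list)) {
    test_pairs <- dataset_split(datasets[[S]], "test")
    grid_df <- eval_gridded_pairs(test_pairs)
    spec_df <- eval_test_pairs(models[[S]], test_pairs, "specific")
    gen_df <- eval_test_pairs(models$generic, test_pairs, "generic")
    results[[S]] <- rbind(grid_df, spec_df, gen_df)
    stats[[S]] <- list(
      ssim = tryCatch(paired_wilcoxon(spec_df$ssim, gen_df$ssim),
                      error = function(e) NULL),
      mae = tryCatch(paired_wilcoxon(spec_df$mae, gen_df$mae),
                     error = function(e) NULL))
  }
  results <- do.call(rbind, results)
  summary <- stats::aggregate(cbind(mae, mse, psnr, ssim) ~ spokes + network,
                              data = results, FUN = mean)
  list(results = results, summary = summary, stats = stats, models = models)
}

#' Leave-one-orientation-out experiment
#'
#' Trains one network per view class with that class held out, plus an
#' all-orientations reference network, all with generic random-rate
#' degradation, then evaluates every left-out test series under its LOO
#' network, the reference network, and the gridded input.
#'
#' @inheritParams run_acceleration_experiment
#' @param spokes_set Spoke-count pool for the random-rate degradation.
#' @return List with `results` (long data.frame; network in
#'   gridded/loo/all), `summary` (per view x network means), `stats`
#'   (per-view paired Wilcoxon on SSIM), `models`.
#' @export
run_loo_experiment <- function(configs,
                               spokes_set = c(13L, 17L, 21L, 25L, 29L, 33L),
                               config = train_config(), crop = NULL,
                               model_spec = NULL, seed = 1L) {
  dataset <- build_dataset(configs, "generic", spokes_set = spokes_set,
                           crop = crop, seed = seed)
  views <- unique(vapply(dataset, function(s) s$view, character(1)))
  n <- dim(dataset[[1]]$input$frames)[1]
  if (is.null(model_spec)) model_spec <- unet_spec(n, c(8L, 16L, 32L))
  message("training all-orientations reference network")
  all_model <- train(build_model(model_spec, seed = seed), dataset, config)$model
  models <- list(all = all_model)
  results <- list(); stats <- list()
  for (v in views) {
    message("training leave-one-out network, holding out ", v)
    sp <- loo_split(dataset, v)
    loo_model <- train(build_model(model_spec, seed = seed),
                       c(sp$train, sp$val), config)$model
    models[[paste0("loo_", v)]] <- loo_model
    grid_df <- eval_gridded_pairs(sp$test)
    loo_df <- eval_test_pairs(loo_model, sp$test, "loo")
    all_df <- eval_test_pairs(all_model, sp$test, "all")
    df <- rbind(grid_df, loo_df, all_df)
    df$left_out <- v
    results[[v]] <- df
    stats[[v]] <- tryCatch(paired_wilcoxon(loo_df$ssim, all_df$ssim),
                           error = function(e) NULL)
  }
  results <- do.call(rbind, results)
  summary <- stats::aggregate(cbind(mae, mse, psnr, ssim) ~ left_out + network,
                              data = results, FUN = mean)
  list(results = results, summary = summary, stats = stats, models = models)
}
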
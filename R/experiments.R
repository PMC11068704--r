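# End-to-end identification protocol: design the training current, simulate
# the neuron, fit the wavenet, and test generalization against fresh
# stepwise and stochastic oscillatory currents.

# Chosen frame hyperparameters per model (scaling family, superpositions,
# resolution levels) and protocol defaults.
.experiment_defaults <- function(name) {
  hyper <- list(
    morris_lecar = list(family = "bicubic", n_scaling = 5, n_levels = 1),
    fhn = list(family = "bicubic", n_scaling = 5, n_levels = 1),
    fhn3d = list(family = "bicubic", n_scaling = 5, n_levels = 1),
    wang = list(family = "quadratic", n_scaling = 4, n_levels = 2)
  )
  scale <- c(morris_lecar = 0.1, fhn = 0.1, fhn3d = 0.2, wang = 0.05)
  if (!name %in% names(hyper)) stop("unknown model '", name, "'")
  c(hyper[[name]], list(scale = scale[[name]],
                        train_delta_t = 100,    # ms per training plateau
                        test_n_values = 50,     # stepwise test: 50 x 100 ms
                        test_delta_t = 100,
                        test_duration = 5000,   # ms per test
                        transient_ms = 100,
                        xi_bar_test = 0.01))
}

#' Identify a neuron model with a wavenet and test its generalization
#'
#' Runs the full protocol for one neuron model: (1) generate a stepwise
#' random training current sweeping the model's physiological interval
#' (plateaus of `train_delta_t` ms, total duration = `scale` times the
#' model's reference training duration), (2) integrate the model and fit a
#' wavenet on the one-step dataset, (3) test one-step-ahead prediction on
#' a fresh stepwise current (with 1\% multiplicative parameter noise on the
#' noise-eligible parameters, testing robustness) and on a stochastic
#' oscillatory current (tabulated parameters, baseline drawn from the
#' physiological interval). Scores are computed over `test_duration` ms
#' discarding the first `transient_ms` ms. Optionally the same tests are
#' repeated in free-running (closed-loop) mode.
#'
#' @param model_name one of the [neuron_model()] names.
#' @param inputs `"full_state"` (all state variables + current as network
#'   inputs) or `"voltage"` (voltage history + current).
#' @param n_lags voltage samples per row in voltage mode.
#' @param scale fraction of the reference training duration; default is
#'   model-specific (see the methods vignette).
#' @param seed integer seed controlling all randomness of the run.
#' @param family,n_scaling,n_levels frame hyperparameters; defaults are the
#'   per-model chosen configuration.
#' @param mu ridge multiplier.
#' @param stride keep every `stride`-th training row when accumulating the
#'   normal equations.
#' @param chunk_rows rows per normal-equation block.
#' @param free_run_ms if positive, also run closed-loop predictions over
#'   the first `free_run_ms` ms of each test and score them.
#' @param i_app0 baseline of the oscillatory test current. The default
#'   (`NULL`) draws it uniformly from the sub-interval of the physiological
#'   interval on which the cosine swing `i_app0 +/- nu` stays inside the
#'   interval (for every model the tabulated `nu` is exactly a quarter of
#'   the interval width, so this is the middle half); see the methods
#'   vignette.
#' @param max_wavelons guard against accidentally requesting a frame whose
#'   normal equations do not fit in desk-scale memory (the full Wang
#'   configuration); raise it explicitly for large runs.
#' @return list of class `wavenet_identification` with elements `model`
#'   (the fitted wavenet), `report_stepwise`, `report_oscillatory`,
#'   optional `free_run_stepwise` / `free_run_oscillatory`, and `config`.
#' @export
run_identification <- function(model_name,
                               inputs = c("full_state", "voltage"),
                               n_lags = 2, scale = NULL, seed = 1,
                               family = NULL, n_scaling = NULL,
                               n_levels = NULL, mu = 2e-16, stride = 10,
                               chunk_rows = 10000, free_run_ms = 0,
                               i_app0 = NULL, max_wavelons = 20000) {
  inputs <- match.arg(inputs)
  defs <- .experiment_defaults(model_name)
  if (is.null(scale)) scale <- defs$scale
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  if (is.null(family)) family <- defs$family
  if (is.null(n_scaling)) n_scaling <- defs$n_scaling
  if (is.null(n_levels)) n_levels <- defs$n_levels
  model <- neuron_model(model_name)
  interval <- model$current_interval

  # --- training data -------------------------------------------------
  n_train_values <- max(2L, as.integer(round(
    scale * model$training_duration * 1000 / defs$train_delta_t)))
  i_train <- stepwise_current(n_train_values, defs$train_delta_t, interval,
                              model$dt, seed = seed)
  traj_train <- integrate_neuron(model, i_train)
  data_train <- build_dataset(traj_train, inputs, n_lags)

  n_state_inputs <- ncol(data_train$X) - 1L
  frame <- wavelet_frame(n_inputs = ncol(data_train$X),
                         n_scaling = n_scaling, n_levels = n_levels,
                         family = family,
                         identity_inputs = seq_len(n_state_inputs))
  if (frame_size(frame) > max_wavelons)
    stop("frame has ", frame_size(frame), " wavelons (> max_wavelons = ",
         max_wavelons, "); raise max_wavelons for large runs")
  fit <- fit_wavenet(frame, data_train, mu = mu, chunk_rows = chunk_rows,
                     stride = stride)

  n_test <- as.integer(round(defs$test_duration / model$dt))

  # --- stepwise test with parameter noise -----------------------------
  i_step <- stepwise_current(defs$test_n_values, defs$test_delta_t, interval,
                             model$dt, seed = seed + 1L)
  noisy <- perturb_parameters(model, defs$xi_bar_test)
  traj_step <- integrate_neuron(noisy, i_step, seed = seed + 2L)
  data_step <- build_dataset(traj_step, inputs, n_lags)
  pred_step <- predict_teacher_forced(fit, data_step)
  rep_step <- score_prediction(pred_step$y_true, pred_step$y_hat, model$dt,
                               transient_ms = defs$transient_ms)

  # --- stochastic oscillatory test ------------------------------------
  osc <- oscillatory_params(model_name)
  set.seed(seed + 3L)
  i0 <- if (is.null(i_app0))
    stats::runif(1, interval[1] + osc[["nu"]], interval[2] - osc[["nu"]])
  else i_app0
  i_osc <- oscillatory_current(defs$test_duration, model$dt,
                               tau = osc[["tau"]], nu = osc[["nu"]],
                               sigma = osc[["sigma"]], omega = osc[["omega"]],
                               i_app0 = i0)
  traj_osc <- integrate_neuron(model, i_osc)
  data_osc <- build_dataset(traj_osc, inputs, n_lags)
  pred_osc <- predict_teacher_forced(fit, data_osc)
  rep_osc <- score_prediction(pred_osc$y_true, pred_osc$y_hat, model$dt,
                              transient_ms = defs$transient_ms)

  out <- list(model = fit, report_stepwise = rep_step,
              report_oscillatory = rep_osc,
              config = list(model_name = model_name, inputs = inputs,
                            n_lags = n_lags, scale = scale, seed = seed,
                            family = family, n_scaling = n_scaling,
                            n_levels = n_levels, mu = mu, stride = stride,
                            train_seconds = n_train_values *
                              defs$train_delta_t / 1000,
                            xi_bar_test = defs$xi_bar_test,
                            i_app0_oscillatory = i0))

  # --- optional closed-loop runs --------------------------------------
  if (free_run_ms > 0) {
    n_fr <- min(n_test, as.integer(round(free_run_ms / model$dt)))
    out$free_run_stepwise <- .free_run_report(fit, data_step, traj_step,
                                              n_fr, inputs, n_lags,
                                              defs$transient_ms)
    out$free_run_oscillatory <- .free_run_report(fit, data_osc, traj_osc,
                                                 n_fr, inputs, n_lags,
                                                 defs$transient_ms)
  }
  class(out) <- "wavenet_identification"
  out
}

.free_run_report <- function(fit, data, traj, n_steps, inputs, n_lags,
                             transient_ms) {
  if (inputs == "full_state") {
    init <- traj$states[1, ]
    i_app <- traj$i_app[seq_len(n_steps)]
    truth <- traj$states[1 + seq_len(n_steps), , drop = FALSE]
  } else {
    init <- traj$states[seq_len(n_lags), 1]  # most recent last
    i_app <- traj$i_app[n_lags + seq_len(n_steps) - 1]
    truth <- traj$states[n_lags + seq_len(n_steps), 1, drop = FALSE]
    colnames(truth) <- colnames(traj$states)[1]
  }
  pred <- tryCatch(free_run(fit, init, i_app, on_escape = "clamp"),
                   error = function(e) e)
  if (inherits(pred, "error"))
    return(structure(list(error = conditionMessage(pred)),
                     class = "score_report_failed"))
  score_prediction(truth, pred$y_hat, traj$dt, transient_ms = transient_ms)
}

#' @export
print.wavenet_identification <- function(x, ...) {
  cat("Identification of", x$config$model_name, "(", x$config$inputs, "),",
      x$config$train_seconds, "s training,",
      frame_size(x$model$frame), "wavelons\n")
  cat("-- stepwise test (xi_bar =", x$config$xi_bar_test, ") --\n")
  print(x$report_stepwise)
  cat("-- oscillatory test --\n")
  print(x$report_oscillatory)
  invisible(x)
}

#' Hyperparameter sweep for the frame configuration
#'
#' Trains one wavenet per combination of resolution levels
#' (`n_levels` = 0, 1, 2), superpositions (`n_scaling` = 4, 5) and scaling
#' family (quadratic, bicubic) — 12 combinations — on a shared stepwise
#' training set (plateaus of 200 ms drawn from `[0, 0.1]` for the
#' FitzHugh-Nagumo showcase), and scores each on a shared stochastic
#' oscillatory test. The wavelon count measures the computational cost of
#' each configuration; together with the voltage error it drives the
#' choice of the per-model configuration.
#'
#' @param model_name model to sweep (the showcase is `"fhn"`).
#' @param scale fraction of the reference 100 s sweep training duration.
#' @param seed integer seed.
#' @param mu,stride,chunk_rows as in [run_identification()].
#' @return data.frame with one row per combination: `family`, `n_scaling`,
#'   `n_levels`, `n_wavelons`, `one_minus_r2_v`, `cosine_v`.
#' @export
run_hyperparameter_sweep <- function(model_name = "fhn", scale = 0.05,
                                     seed = 1, mu = 2e-16, stride = 10,
                                     chunk_rows = 10000) {
  model <- neuron_model(model_name)
  sweep_interval <- if (model_name == "fhn") c(0, 0.1)
                    else model$current_interval
  n_values <- max(2L, as.integer(round(scale * 500)))
  i_train <- stepwise_current(n_values, 200, sweep_interval, model$dt,
                              seed = seed)
  traj_train <- integrate_neuron(model, i_train)
  data_train <- build_dataset(traj_train, "full_state")

  osc <- oscillatory_params(model_name)
  set.seed(seed + 3L)
  i0 <- stats::runif(1, sweep_interval[1], sweep_interval[2])
  i_osc <- oscillatory_current(5000, model$dt, tau = osc[["tau"]],
                               nu = osc[["nu"]], sigma = osc[["sigma"]],
                               omega = osc[["omega"]], i_app0 = i0)
  traj_osc <- integrate_neuron(model, i_osc)
  data_osc <- build_dataset(traj_osc, "full_state")

  grid <- expand.grid(n_levels = 0:2, n_scaling = 4:5,
                      family = c("quadratic", "bicubic"),
                      stringsAsFactors = FALSE)
  n_state <- ncol(data_train$X) - 1L
  res <- lapply(seq_len(nrow(grid)), function(i) {
    fr <- wavelet_frame(ncol(data_train$X), grid$n_scaling[i],
                        grid$n_levels[i], grid$family[i],
                        identity_inputs = seq_len(n_state))
    fit <- fit_wavenet(fr, data_train, mu = mu, chunk_rows = chunk_rows,
                       stride = stride)
    pred <- predict_teacher_forced(fit, data_osc)
    rep <- score_prediction(pred$y_true, pred$y_hat, model$dt)
    data.frame(family = grid$family[i], n_scaling = grid$n_scaling[i],
               n_levels = grid$n_levels[i], n_wavelons = frame_size(fr),
               one_minus_r2_v = rep$one_minus_r2[[1]],
               cosine_v = rep$cosine_similarity[[1]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Element count of a full training design matrix
#'
#' Size bookkeeping for out-of-core planning: a training run of
#' `n_segments` current plateaus integrated for `steps_per_segment` Euler
#' steps each produces one design-matrix row per step and one column per
#' wavelon.
#'
#' @param frame a [wavelet_frame()].
#' @param n_segments number of training current values.
#' @param steps_per_segment Euler steps per current value.
#' @return named numeric vector with `rows`, `cols`, `elements`.
#' @export
training_matrix_elements <- function(frame, n_segments, steps_per_segment) {
  rows <- as.numeric(n_segments) * as.numeric(steps_per_segment)
  cols <- frame_size(frame)
  c(rows = rows, cols = cols, elements = rows * cols)
}
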
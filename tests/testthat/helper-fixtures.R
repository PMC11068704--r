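# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Full-protocol identification runs at the study scale (used by the
# acceptance tests); closed-loop reports over 1.5 s are attached. The
# oscillatory baseline is pinned at the interval midpoint, the
# bifurcation-centered design point of the testing stimulus.
study_run <- function(model_name, inputs = "full_state") {
  fixture(paste0("study_", model_name, "_", inputs), {
    mid <- mean(neuron_model(model_name)$current_interval)
    run_identification(model_name, inputs = inputs, n_lags = 2,
                       seed = 42, free_run_ms = 1500, i_app0 = mid)
  })
}

# Hand-built wavenet that realizes an exact linear one-step map
# v -> slope * v on [0, 1] (identity wavelon only; all frame weights 0).
linear_map_wavenet <- function(slope, n_scaling = 2, n_levels = 0) {
  fr <- wavelet_frame(n_inputs = 2, n_scaling = n_scaling,
                      n_levels = n_levels, family = "quadratic",
                      identity_inputs = 1,
                      bounds = rbind(c(0, 0), c(1, 1)))
  w <- matrix(0, frame_size(fr), 1, dimnames = list(NULL, "v"))
  w[1, 1] <- slope  # identity column is the normalized (= raw) voltage
  structure(list(frame = fr, weights = w, gamma = 0, mu = 0,
                 lambda_max = NA_real_, inputs = "full_state",
                 n_lags = NA_integer_, input_names = c("v", "i_app"),
                 output_names = "v", train_mse = c(v = 0), n_obs = 0,
                 stride = 1, oob = "clamp", dt = 1, model_name = "linear"),
            class = "wavenet")
}
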
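# Plain-text serialization: trajectories as commented CSV, fitted wavenets
# as a JSON sidecar (frame + metadata) plus a CSV weight table.

#' Write a trajectory to CSV
#'
#' Columns `t`, one per state variable, and `i_app`; the model name, step
#' and seed are stored in `#`-prefixed header lines so the file round-trips
#' through [read_trajectory_csv()].
#'
#' @param traj a `trajectory`.
#' @param path output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# model=", traj$model_name),
               paste0("# dt=", format(traj$dt, digits = 17)),
               paste0("# xi_bar=", format(traj$xi_bar, digits = 17)),
               paste0("# seed=", if (is.null(traj$seed)) "NA" else traj$seed)),
             con)
  df <- data.frame(t = traj$t, traj$states, i_app = traj$i_app,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_csv()]
#'
#' @param path file path.
#' @return a `trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.csv(path, comment.char = "#")
  states <- as.matrix(df[, setdiff(names(df), c("t", "i_app")), drop = FALSE])
  seed <- suppressWarnings(as.integer(meta$seed))
  structure(list(t = df$t, states = states, i_app = df$i_app,
                 dt = as.numeric(meta$dt), model_name = meta$model,
                 xi_bar = as.numeric(meta$xi_bar),
                 seed = if (is.na(seed)) NULL else seed),
            class = "trajectory")
}

.frame_to_list <- function(frame) {
  list(family = frame$family$name,
       n_inputs = frame$n_inputs,
       n_scaling = frame$n_scaling,
       n_levels = frame$n_levels,
       identity_inputs = frame$identity_inputs,
       bounds = if (is.null(frame$bounds)) NULL
                else list(lower = frame$bounds[1, ], upper = frame$bounds[2, ]))
}

.frame_from_list <- function(x) {
  wavelet_frame(n_inputs = x$n_inputs, n_scaling = x$n_scaling,
                n_levels = x$n_levels, family = x$family,
                identity_inputs = unlist(x$identity_inputs),
                bounds = if (is.null(x$bounds)) NULL
                         else rbind(unlist(x$bounds$lower),
                                    unlist(x$bounds$upper)))
}

#' Serialize a frame specification to JSON
#'
#' @param frame a [wavelet_frame()].
#' @param path optional file path; if omitted the JSON string is returned.
#' @export
frame_to_json <- function(frame, path = NULL) {
  js <- jsonlite::toJSON(.frame_to_list(frame), auto_unbox = TRUE,
                         digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Restore a frame specification from JSON
#'
#' @param path file path or JSON string from [frame_to_json()].
#' @export
frame_from_json <- function(path) {
  .frame_from_list(jsonlite::fromJSON(path))
}

#' Save a fitted wavenet
#'
#' Writes `<prefix>.json` (frame specification, regularization and dataset
#' metadata) and `<prefix>_weights.csv` (one column per output).
#'
#' @param model a fitted [fit_wavenet()] model.
#' @param prefix output path prefix.
#' @export
save_wavenet <- function(model, prefix) {
  stopifnot(inherits(model, "wavenet"))
  meta <- list(frame = .frame_to_list(model$frame),
               gamma = model$gamma, mu = model$mu,
               lambda_max = model$lambda_max,
               inputs = model$inputs, n_lags = model$n_lags,
               input_names = model$input_names,
               output_names = model$output_names,
               train_mse = as.list(model$train_mse),
               n_obs = model$n_obs, stride = model$stride, oob = model$oob,
               dt = model$dt, model_name = model$model_name)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             paste0(prefix, ".json"))
  w <- as.data.frame(model$weights)
  names(w) <- model$output_names
  utils::write.csv(w, paste0(prefix, "_weights.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Load a wavenet saved by [save_wavenet()]
#'
#' @param prefix path prefix used when saving.
#' @return a `wavenet`.
#' @export
load_wavenet <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, ".json"))
  w <- as.matrix(utils::read.csv(paste0(prefix, "_weights.csv")))
  colnames(w) <- unlist(meta$output_names)
  nl <- meta$n_lags
  structure(list(frame = .frame_from_list(meta$frame),
                 weights = w, gamma = meta$gamma, mu = meta$mu,
                 lambda_max = meta$lambda_max, inputs = meta$inputs,
                 n_lags = if (is.null(nl) || is.na(nl)) NA_integer_
                          else as.integer(nl),
                 input_names = unlist(meta$input_names),
                 output_names = unlist(meta$output_names),
                 train_mse = unlist(meta$train_mse),
                 n_obs = meta$n_obs, stride = meta$stride, oob = meta$oob,
                 dt = meta$dt, model_name = meta$model_name),
            class = "wavenet")
}
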
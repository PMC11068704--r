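#' One-step-ahead (teacher-forced) wavenet prediction
#'
#' Evaluates the frame on every test input row and applies the fitted
#' weights: \eqn{\hat y = G(x_T)\,\hat\sigma}. Every input row contains the
#' true states (or true voltage history), so errors do not accumulate
#' across steps.
#'
#' @param object a fitted [fit_wavenet()] model.
#' @param newdata a `wavenet_dataset` (or any list with an `X` matrix) built
#'   with the same input convention as the training data.
#' @param chunk_rows rows per design-matrix block.
#' @param ... unused.
#' @return matrix of predicted outputs, one row per input row.
#' @export
predict.wavenet <- function(object, newdata, chunk_rows = 20000, ...) {
  X <- as.matrix(newdata$X %||% newdata)
  if (ncol(X) != object$frame$n_inputs)
    stop("newdata has ", ncol(X), " inputs; frame expects ",
         object$frame$n_inputs)
  n <- nrow(X)
  out <- matrix(NA_real_, n, ncol(object$weights),
                dimnames = list(NULL, object$output_names))
  for (s in seq(1, n, by = chunk_rows)) {
    rows <- s:min(s + chunk_rows - 1, n)
    G <- design_matrix(object$frame, X[rows, , drop = FALSE],
                       oob = object$oob, warn_oob = FALSE)
    out[rows, ] <- G %*% object$weights
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Teacher-forced prediction with truth attached
#'
#' Convenience wrapper around [predict.wavenet()] that returns predictions
#' and the matching true outputs as a `prediction_result`, ready for
#' [score_prediction()].
#'
#' @param model a fitted wavenet.
#' @param test a `wavenet_dataset` built from the test trajectory.
#' @return object of class `prediction_result` with `y_true`, `y_hat`,
#'   `mode`, `dt`.
#' @export
predict_teacher_forced <- function(model, test) {
  y_hat <- stats::predict(model, test)
  structure(list(y_true = as.matrix(test$Y), y_hat = y_hat,
                 mode = "teacher_forced", dt = test$dt),
            class = "prediction_result")
}

# fast single-row frame evaluation context for the free-running loop
.row_evaluator <- function(frame) {
  fi <- .frame_index(frame)
  atoms <- fi$atoms
  fam <- frame$family; ns <- frame$n_scaling
  lo <- frame$bounds[1, ]; hi <- frame$bounds[2, ]
  n_atoms <- nrow(atoms)
  idx <- fi$idx
  id_in <- frame$identity_inputs
  function(x, oob = "clamp") {
    xn <- (x - lo) / (hi - lo)
    xe <- if (oob == "clamp") pmin(pmax(xn, 0), 1) else xn
    av <- matrix(0, length(x), n_atoms)
    for (a in seq_len(n_atoms)) {
      av[, a] <- if (atoms$type[a] == "scaling")
        displaced_scaling(fam, atoms$k[a], ns, xe)
      else
        frame_wavelet(fam, atoms$k[a], atoms$r[a], atoms$n[a], ns, xe)
    }
    g <- av[cbind(1L, idx[, 1])]
    for (j in seq_len(ncol(idx))[-1])
      g <- g * av[cbind(j, idx[, j])]
    c(xn[id_in], g)
  }
}

#' Free-running (closed-loop) wavenet prediction
#'
#' Iterates the fitted one-step map: predicted outputs are fed back as the
#' next step's inputs, and only the applied-current trace is read from
#' outside. In full-state mode the whole predicted state vector re-enters;
#' in voltage mode the predicted voltage re-enters the lag buffer. The run
#' aborts with an error naming the step if a predicted output leaves the
#' normalization box by more than `margin` (in normalized units).
#'
#' @param model a fitted wavenet.
#' @param init initial condition: full state vector (full-state mode) or
#'   voltage history, most recent last (voltage mode, length `n_lags`).
#' @param i_app applied-current trace on the model `dt` grid; its length
#'   fixes the number of predicted steps.
#' @param margin divergence guard in normalized units.
#' @param on_escape what to do when a predicted output leaves the box by
#'   more than `margin`: `"error"` (default) aborts naming the step;
#'   `"clamp"` projects the fed-back state onto the support box and
#'   continues (a saturating closed loop — useful for scoring long runs of
#'   networks whose fit is sparse near the box corners).
#' @return object of class `prediction_result` with `y_hat` (matrix of
#'   predicted outputs, one row per step), `mode = "free_run"`, `dt` and
#'   `n_escaped` (steps at which the guard fired).
#' @export
free_run <- function(model, init, i_app, margin = 0.5,
                     on_escape = c("error", "clamp")) {
  on_escape <- match.arg(on_escape)
  frame <- model$frame
  eval_row <- .row_evaluator(frame)
  n <- length(i_app)
  W <- model$weights
  out <- matrix(NA_real_, n, ncol(W),
                dimnames = list(NULL, model$output_names))
  full_state <- model$inputs == "full_state"
  if (full_state) {
    state <- as.numeric(init)
    if (length(state) != frame$n_inputs - 1)
      stop("init must contain ", frame$n_inputs - 1, " state values")
  } else {
    buf <- as.numeric(init)  # most recent last
    if (length(buf) != model$n_lags)
      stop("init must contain ", model$n_lags, " voltage samples")
  }
  lo <- frame$bounds[1, ]; hi <- frame$bounds[2, ]
  n_out <- ncol(W)
  slo <- if (full_state) lo[seq_len(n_out)] else lo[1]
  shi <- if (full_state) hi[seq_len(n_out)] else hi[1]
  n_escaped <- 0L
  for (m in seq_len(n)) {
    x <- if (full_state) c(state, i_app[m]) else c(rev(buf), i_app[m])
    g <- eval_row(x, model$oob)
    y <- as.numeric(crossprod(W, g))
    # guard on the state-carrying outputs, in normalized units
    xn_next <- (y - slo) / (shi - slo)
    if (any(!is.finite(xn_next)) ||
        any(xn_next < -margin) || any(xn_next > 1 + margin)) {
      if (on_escape == "error")
        stop("free-running prediction diverged at step ", m)
      y <- pmin(pmax(y, slo), shi)
      n_escaped <- n_escaped + 1L
    }
    out[m, ] <- y
    if (full_state) state <- y else buf <- c(buf[-1], y)
  }
  structure(list(y_true = NULL, y_hat = out, mode = "free_run",
                 dt = model$dt, n_escaped = n_escaped),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("Prediction (", x$mode, "): ", nrow(x$y_hat), " steps, ",
      ncol(x$y_hat), " output(s)\n", sep = "")
  invisible(x)
}
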
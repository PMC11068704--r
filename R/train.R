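#' Build a one-step training dataset from a trajectory
#'
#' Converts a simulated trajectory into supervised one-step pairs. With
#' `inputs = "full_state"` each row maps the full state vector and the
#' applied current at one sample to the state vector at the next sample
#' (`N_I = n_state + 1` inputs, `N_O = n_state` outputs). With
#' `inputs = "voltage"` — the experimentally realistic setting where only
#' the membrane voltage is observed — each row maps the `n_lags` most
#' recent voltage samples plus the applied current to the next voltage
#' sample (`N_I = n_lags + 1`, `N_O = 1`); the first rows without a full
#' lag history are dropped.
#'
#' @param traj a `trajectory` from [integrate_neuron()].
#' @param inputs `"full_state"` or `"voltage"`.
#' @param n_lags number of voltage samples per row (voltage mode; >= 1).
#' @return object of class `wavenet_dataset` with elements `X`, `Y`,
#'   `inputs`, `n_lags`, `input_names`, `output_names`, `dt`, `model_name`.
#' @export
build_dataset <- function(traj, inputs = c("full_state", "voltage"),
                          n_lags = 2) {
  stopifnot(inherits(traj, "trajectory"))
  inputs <- match.arg(inputs)
  S <- traj$states
  N <- nrow(S)
  if (inputs == "full_state") {
    if (N < 2) stop("trajectory too short")
    X <- cbind(S[-N, , drop = FALSE], traj$i_app[-N])
    Y <- S[-1, , drop = FALSE]
    input_names <- c(colnames(S), "i_app")
    output_names <- colnames(S)
    n_lags <- NA_integer_
  } else {
    if (n_lags < 1) stop("n_lags must be >= 1 in voltage mode")
    if (N < n_lags + 1) stop("trajectory too short for ", n_lags, " lags")
    v <- S[, 1]
    rows <- (n_lags + 1):N
    X <- vapply(seq_len(n_lags), function(l) v[rows - l], numeric(length(rows)))
    if (!is.matrix(X)) X <- matrix(X, nrow = length(rows))
    X <- cbind(X, traj$i_app[rows - 1])
    Y <- matrix(v[rows], ncol = 1)
    input_names <- c(paste0("v_lag", seq_len(n_lags)), "i_app")
    output_names <- colnames(S)[1]
  }
  colnames(X) <- input_names
  colnames(Y) <- output_names
  structure(list(X = X, Y = Y, inputs = inputs, n_lags = n_lags,
                 input_names = input_names, output_names = output_names,
                 dt = traj$dt, model_name = traj$model_name),
            class = "wavenet_dataset")
}

#' @export
print.wavenet_dataset <- function(x, ...) {
  cat("Wavenet dataset (", x$inputs, "): ", nrow(x$X), " rows, ",
      ncol(x$X), " inputs -> ", ncol(x$Y), " outputs\n", sep = "")
  invisible(x)
}

# largest eigenvalue of a symmetric PSD matrix by power iteration
.lambda_max <- function(A, tol = 1e-6, max_iter = 5000) {
  v <- rep(1 / sqrt(nrow(A)), nrow(A))
  lam <- 0
  for (i in seq_len(max_iter)) {
    w <- A %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v_new <- as.numeric(w / nw)
    lam_new <- as.numeric(crossprod(v_new, A %*% v_new))
    if (abs(lam_new - lam) <= tol * max(abs(lam_new), 1e-300)) return(lam_new)
    lam <- lam_new; v <- v_new
  }
  lam
}

#' Fit a wavenet by regularized least squares
#'
#' Trains the network, i.e. determines the weight vector of every output by
#' solving the ridge-regularized normal equations
#' \eqn{(G^\top G + \gamma I)\,\sigma = G^\top y} with
#' \eqn{\gamma = \mu\,\lambda^{max}}, where \eqn{\lambda^{max}} is the
#' largest eigenvalue of the covariance matrix \eqn{G^\top G}. The design
#' matrix G is never materialized in full: \eqn{G^\top G} and
#' \eqn{G^\top Y} are accumulated over blocks of `chunk_rows` rows, and all
#' outputs share the accumulated matrices. The per-output training
#' mean-squared error is recorded in the fitted object.
#'
#' @param frame a [wavelet_frame()]; if it has no normalization bounds they
#'   are computed from the training inputs via [normalization_bounds()].
#' @param data a [build_dataset()] result, or a list with matrices `X`, `Y`.
#' @param mu ridge multiplier; the regularizer is `mu` times the largest
#'   covariance eigenvalue. The default `2e-16` only shields the solve from
#'   rank deficiency.
#' @param chunk_rows rows per accumulation block.
#' @param stride keep every `stride`-th row of the dataset (the one-step
#'   map is typically oversampled at the integration step; see the methods
#'   vignette).
#' @param oob passed to [design_matrix()].
#' @return object of class `wavenet`: the frame, the `J x N_O` weight
#'   matrix, `gamma`, `lambda_max`, per-output `train_mse`, and dataset
#'   metadata.
#' @export
fit_wavenet <- function(frame, data, mu = 2e-16, chunk_rows = 10000,
                        stride = 1, oob = "clamp") {
  stopifnot(inherits(frame, "wavelet_frame"))
  X <- as.matrix(data$X); Y <- as.matrix(data$Y)
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("non-finite values in training data")
  if (ncol(X) != frame$n_inputs)
    stop("dataset has ", ncol(X), " inputs; frame expects ", frame$n_inputs)
  if (mu < 0) stop("mu must be >= 0")
  if (chunk_rows < 1 || stride < 1) stop("chunk_rows and stride must be >= 1")
  keep <- seq(1, nrow(X), by = stride)
  X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
  if (is.null(frame$bounds)) frame$bounds <- normalization_bounds(X)
  J <- frame_size(frame)
  n_out <- ncol(Y)
  A <- matrix(0, J, J)
  B <- matrix(0, J, n_out)
  yty <- numeric(n_out)
  n <- nrow(X)
  starts <- seq(1, n, by = chunk_rows)
  for (s in starts) {
    rows <- s:min(s + chunk_rows - 1, n)
    G <- design_matrix(frame, X[rows, , drop = FALSE], oob = oob,
                       warn_oob = FALSE)
    A <- A + crossprod(G)
    B <- B + crossprod(G, Y[rows, , drop = FALSE])
    yty <- yty + colSums(Y[rows, , drop = FALSE]^2)
  }
  lam <- .lambda_max(A)
  gamma <- mu * lam
  Areg <- A + diag(gamma, J)
  ch <- tryCatch(chol(Areg), error = function(e) NULL)
  if (is.null(ch)) {
    if (gamma == 0)
      stop("normal equations are singular with gamma = 0; use mu > 0")
    warning("Cholesky factorization failed; falling back to pseudoinverse")
    sigma <- .pinv(Areg) %*% B
  } else {
    sigma <- backsolve(ch, forwardsolve(t(ch), B))
  }
  mse <- (yty - 2 * colSums(sigma * B) +
            colSums(sigma * (A %*% sigma))) / n
  mse <- pmax(mse, 0)
  structure(list(frame = frame,
                 weights = matrix(sigma, J, n_out,
                                  dimnames = list(NULL, colnames(Y))),
                 gamma = gamma, mu = mu, lambda_max = lam,
                 inputs = if (is.null(data$inputs)) "full_state" else data$inputs,
                 n_lags = if (is.null(data$n_lags)) NA_integer_ else data$n_lags,
                 input_names = colnames(X), output_names = colnames(Y),
                 train_mse = stats::setNames(mse, colnames(Y)),
                 n_obs = n, stride = stride, oob = oob,
                 dt = data$dt, model_name = data$model_name),
            class = "wavenet")
}

# minimal Moore-Penrose pseudoinverse (SVD), used only as a fallback
.pinv <- function(M, tol = sqrt(.Machine$double.eps)) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.wavenet <- function(x, ...) {
  cat("Fitted wavenet (", x$inputs, "): ", frame_size(x$frame), " wavelons, ",
      length(x$output_names), " output(s)\n", sep = "")
  cat("  gamma =", format(x$gamma, digits = 4),
      " (mu =", format(x$mu, digits = 4), ")\n")
  cat("  training MSE:", paste(format(x$train_mse, digits = 4),
                               collapse = ", "), "\n")
  invisible(x)
}
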
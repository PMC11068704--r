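#' Stepwise random current trace
#'
#' Piecewise-constant applied current: `n_values` plateaus, each held for
#' `delta_t` ms, with plateau amplitudes drawn i.i.d. uniformly from
#' `interval`. This is the stimulus used for training (it parks the neuron
#' long enough at each current level for the network to learn the
#' stationary response) and, with the testing parameters, for the stepwise
#' generalization test.
#'
#' @param n_values number of random plateaus.
#' @param delta_t plateau duration (ms); must be an integer multiple of `dt`.
#' @param interval length-2 current interval `c(lo, hi)`, `lo < hi`.
#' @param dt sample step (ms), normally the model integration step.
#' @param seed optional integer seed.
#' @return numeric trace of length `n_values * delta_t / dt`.
#' @export
stepwise_current <- function(n_values, delta_t, interval, dt, seed = NULL) {
  if (n_values < 1) stop("n_values must be >= 1")
  if (delta_t <= 0 || dt <= 0) stop("delta_t and dt must be positive")
  if (length(interval) != 2 || interval[1] >= interval[2])
    stop("interval must be c(lo, hi) with lo < hi")
  k <- delta_t / dt
  if (abs(k - round(k)) > 1e-8 * max(1, k))
    stop("delta_t (", delta_t, ") is not an integer multiple of dt (", dt,
         "); refusing to round silently")
  k <- as.integer(round(k))
  if (!is.null(seed)) set.seed(seed)
  vals <- stats::runif(n_values, interval[1], interval[2])
  rep(vals, each = k)
}

#' Stochastic oscillatory current trace
#'
#' Realization of the mean-reverting oscillatory process
#' \deqn{dI = \frac{1}{\tau}\left(I_0 + \nu\cos(\omega t) - I + \sigma\,\xi(t)\right)dt}
#' discretized with the Euler--Maruyama step
#' `I[m+1] = I[m] + (dt/tau) * (i_app0 + nu*cos(omega*t[m] + phase) - I[m]) +
#' (sigma/tau) * sqrt(dt) * z[m]`, `z` standard normal. The white noise is
#' scaled by the relaxation rate `1/tau` together with the drift, so the
#' stationary spread is `sigma / sqrt(2*tau)` — a small fraction of the
#' physiological current interval for the tabulated parameter sets (see the
#' methods vignette for this reading). With `sigma = 0` the trace is
#' deterministic and independent of the seed.
#'
#' @param duration total duration (ms).
#' @param dt sample step (ms).
#' @param tau relaxation time (ms), positive.
#' @param nu cosine amplitude.
#' @param sigma noise amplitude, non-negative.
#' @param omega angular frequency (rad/ms); the tabulated value used across
#'   all models is `1.2 * pi * 1e-4`.
#' @param i_app0 baseline current (for testing, drawn uniformly from the
#'   model's physiological interval).
#' @param i_init initial current; defaults to the drift target at t = 0.
#' @param phase cosine phase at t = 0 (rad).
#' @param seed optional integer seed.
#' @return numeric trace of length `duration / dt` (rounded).
#' @export
oscillatory_current <- function(duration, dt, tau, nu, sigma,
                                omega = 1.2 * pi * 1e-4, i_app0,
                                i_init = NULL, phase = 0, seed = NULL) {
  if (tau <= 0) stop("tau must be positive")
  if (sigma < 0) stop("sigma must be non-negative")
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  n <- as.integer(round(duration / dt))
  if (!is.null(seed)) set.seed(seed)
  tgrid <- (seq_len(n) - 1) * dt
  drift_target <- i_app0 + nu * cos(omega * tgrid + phase)
  if (is.null(i_init)) i_init <- drift_target[1]
  z <- if (sigma > 0) stats::rnorm(n - 1) else numeric(n - 1)
  a <- dt / tau
  b <- (sigma / tau) * sqrt(dt)
  if (n == 1L) return(i_init)
  # AR(1) recursion I[m+1] = (1-a) I[m] + a target[m] + b z[m]
  innov <- a * drift_target[seq_len(n - 1)] + b * z
  rest <- stats::filter(innov, filter = 1 - a, method = "recursive",
                        init = i_init)
  c(i_init, as.numeric(rest))
}

# Tabulated oscillatory-process parameters (tau, nu, sigma) per model; the
# frequency omega = 1.2*pi*1e-4 rad/ms is shared.
.osc_table <- function() {
  list(morris_lecar = c(tau = 10, nu = 10,    sigma = 9.5),
       fhn          = c(tau = 10, nu = 0.005, sigma = 0.0045),
       fhn3d        = c(tau = 10, nu = 0.005, sigma = 0.0045),
       wang         = c(tau = 10, nu = 1.5,   sigma = 2.85))
}

#' Tabulated oscillatory-stimulus parameters for a model
#'
#' Returns the per-model relaxation time, cosine amplitude and noise
#' amplitude of the oscillatory testing current, plus the shared angular
#' frequency.
#'
#' @param name model name as in [neuron_model()].
#' @return named numeric vector `c(tau, nu, sigma, omega)`.
#' @export
oscillatory_params <- function(name) {
  tab <- .osc_table()
  if (!name %in% names(tab))
    stop("unknown model '", name, "'")
  c(tab[[name]], omega = 1.2 * pi * 1e-4)
}
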
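#' @useDynLib wavenetid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical parameter sets. Each model is parameterized so that, for constant
# applied current, the boundary between the quiescent and the repetitively
# spiking regime lies inside the physiological current interval swept by the
# training stimuli (see the methods vignette for the calibration).
.model_table <- function() {
  list(
    morris_lecar = list(
      state_names = c("v", "w"),
      params = c(C = 20, g_L = 2, g_K = 8, g_Ca = 4,
                 E_L = -60, E_K = -84, E_Ca = 120,
                 V1 = -1.2, V2 = 18, V3 = 12, V4 = 17.4, phi = 1 / 15),
      dt = 0.05,
      current_interval = c(20, 60),
      noisy_params = c("g_L", "g_K"),
      training_duration = 2500,
      settle_state = c(v = -60, w = 0.01)
    ),
    fhn = list(
      state_names = c("v", "w"),
      params = c(a = 0.25, gamma = 3.5, eps = 0.057),
      dt = 0.05,
      current_interval = c(0.07, 0.09),
      noisy_params = c("a", "gamma"),
      training_duration = 2500,
      settle_state = c(v = 0, w = 0)
    ),
    fhn3d = list(
      state_names = c("v", "w", "y"),
      params = c(a = 0.25, gamma = 3.5, eps = 0.057,
                 eps_y = 0.002, c = 0.258),
      dt = 0.05,
      current_interval = c(0.05, 0.07),
      noisy_params = c("a", "gamma"),
      training_duration = 375,
      settle_state = c(v = 0, w = 0, y = 0.2),
      settle_ms = 3000
    ),
    wang = list(
      state_names = c("v", "h", "n"),
      params = c(C = 1, g_Na = 35, g_K = 9, g_L = 0.1,
                 E_Na = 55, E_K = -90, E_L = -65, phi = 5),
      dt = 0.005,
      current_interval = c(-3, 3),
      noisy_params = c("g_L", "g_K"),
      training_duration = 230,
      settle_state = c(v = -64, h = 0.78, n = 0.09)
    )
  )
}

#' Construct a neuron-model specification
#'
#' Returns the full specification of one of the four ground-truth neuron
#' models used to generate training and testing data: the Morris-Lecar
#' model (`"morris_lecar"`, states v, w), the cubic FitzHugh-Nagumo model
#' (`"fhn"`, states v, w), a three-variable FitzHugh-Nagumo with a slow
#' adaptation current (`"fhn3d"`, states v, w, y) and a Wang-type
#' conductance model of a pyramidal neuron with sodium-inactivation and
#' potassium-activation gating (`"wang"`, states v, h, n).
#'
#' The specification carries the integration step `dt` (ms), the
#' physiological applied-current interval `current_interval` over which the
#' stimuli are designed (\eqn{\mu A/cm^2} for the conductance-based models),
#' the parameters eligible for multiplicative noise (`noisy_params`; the
#' leak and potassium conductances for the conductance-based models, the
#' excitability parameter `a` and the recovery gain `gamma` for the
#' FitzHugh-Nagumo-type models) and the reference training duration in
#' seconds.
#'
#' @param name one of `"morris_lecar"`, `"fhn"`, `"fhn3d"`, `"wang"`.
#' @return an object of class `neuron_model`.
#' @examples
#' m <- neuron_model("morris_lecar")
#' m$current_interval
#' @export
neuron_model <- function(name) {
  tab <- .model_table()
  if (!is.character(name) || length(name) != 1L || !name %in% names(tab))
    stop("unknown model '", paste(name, collapse = ","),
         "'; valid names: ", paste(names(tab), collapse = ", "))
  spec <- tab[[name]]
  spec$name <- name
  spec$xi_bar <- 0
  structure(spec, class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat("Neuron model:", x$name, "\n")
  cat("  states:           ", paste(x$state_names, collapse = ", "), "\n")
  cat("  dt:               ", x$dt, "ms\n")
  cat("  current interval: [", x$current_interval[1], ",",
      x$current_interval[2], "]\n")
  cat("  noisy parameters: ", paste(x$noisy_params, collapse = ", "),
      " (xi_bar =", x$xi_bar, ")\n")
  invisible(x)
}

#' Right-hand side of a neuron model
#'
#' Evaluates the time derivative of the state vector at a given state and
#' applied current. Pure function of its arguments and the model parameters.
#'
#' @param model a [neuron_model()].
#' @param state numeric state vector (length = number of state variables).
#' @param i_app scalar applied current.
#' @return numeric derivative vector, named like the state variables.
#' @export
model_rhs <- function(model, state, i_app) {
  stopifnot(inherits(model, "neuron_model"))
  if (length(state) != length(model$state_names))
    stop("state must have ", length(model$state_names), " entries")
  if (!all(is.finite(state)) || !is.finite(i_app))
    stop("non-finite state or current")
  p <- as.list(model$params)
  d <- switch(model$name,
    morris_lecar = {
      v <- state[1]; w <- state[2]
      minf <- 0.5 * (1 + tanh((v - p$V1) / p$V2))
      winf <- 0.5 * (1 + tanh((v - p$V3) / p$V4))
      lamw <- p$phi * cosh((v - p$V3) / (2 * p$V4))
      c((i_app - p$g_L * (v - p$E_L) - p$g_K * w * (v - p$E_K) -
           p$g_Ca * minf * (v - p$E_Ca)) / p$C,
        lamw * (winf - w))
    },
    fhn = {
      v <- state[1]; w <- state[2]
      c(v * (v - p$a) * (1 - v) - w + i_app,
        p$eps * (v - p$gamma * w))
    },
    fhn3d = {
      v <- state[1]; w <- state[2]; y <- state[3]
      c(v * (v - p$a) * (1 - v) - w + y + i_app,
        p$eps * (v - p$gamma * w),
        p$eps_y * (p$c - v - y))
    },
    wang = {
      v <- state[1]; h <- state[2]; n <- state[3]
      exprel <- function(u) ifelse(abs(u) < 1e-7, 1 + u / 2, u / (1 - exp(-u)))
      am <- exprel(0.1 * (v + 35)); bm <- 4 * exp(-(v + 60) / 18)
      minf <- am / (am + bm)
      ah <- 0.07 * exp(-(v + 58) / 20)
      bh <- 1 / (1 + exp(-0.1 * (v + 28)))
      an <- 0.1 * exprel(0.1 * (v + 34))
      bn <- 0.125 * exp(-(v + 44) / 80)
      c((i_app - p$g_Na * minf^3 * h * (v - p$E_Na) -
           p$g_K * n^4 * (v - p$E_K) - p$g_L * (v - p$E_L)) / p$C,
        p$phi * (ah * (1 - h) - bh * h),
        p$phi * (an * (1 - n) - bn * n))
    })
  stats::setNames(d, model$state_names)
}

#' Mark a model for multiplicative parameter noise
#'
#' Returns a copy of the model in which each noise-eligible parameter
#' \eqn{\kappa} is replaced, at every integration step, by
#' \eqn{\kappa(1 + \xi)} with \eqn{\xi \sim U(-\bar\xi, \bar\xi)} drawn
#' freshly per step. With `xi_bar = 0` integration is bit-identical to the
#' unperturbed model.
#'
#' @param model a [neuron_model()].
#' @param xi_bar non-negative noise half-width (the robustness tests use
#'   0.01, i.e. 1\% variation — a biologically plausible jitter).
#' @return the modified `neuron_model`.
#' @export
perturb_parameters <- function(model, xi_bar) {
  stopifnot(inherits(model, "neuron_model"))
  if (!is.numeric(xi_bar) || length(xi_bar) != 1L || xi_bar < 0)
    stop("xi_bar must be a non-negative scalar")
  model$xi_bar <- xi_bar
  model
}

#' Integrate a neuron model with the explicit Euler method
#'
#' Advances the model state with the explicit Euler scheme
#' `x[m] = x[m-1] + dt * rhs(x[m-1], i_app[m-1])` over the sample grid of the
#' supplied applied-current trace. If the model carries parameter noise
#' (see [perturb_parameters()]) the noisy parameters are redrawn at every
#' step; set a seed (argument or `set.seed`) for reproducibility.
#'
#' @param model a [neuron_model()].
#' @param i_app numeric applied-current trace sampled on the model's `dt`
#'   grid; its length fixes the number of steps.
#' @param x0 initial state; default is the resting state obtained by
#'   settling at the lower end of the model's current interval
#'   (see [resting_state()]).
#' @param seed optional integer seed for the parameter-noise draws.
#' @param bound divergence guard: integration aborts with an error naming
#'   the step index if any |state| exceeds it.
#' @return an object of class `trajectory`: list with `t` (ms), `states`
#'   (matrix, one column per state variable), `i_app`, `dt`, `model_name`,
#'   `xi_bar` and `seed`.
#' @export
integrate_neuron <- function(model, i_app, x0 = NULL, seed = NULL,
                             bound = 1e6) {
  stopifnot(inherits(model, "neuron_model"))
  if (!is.numeric(i_app) || length(i_app) < 1L)
    stop("i_app must be a non-empty numeric trace")
  if (is.null(x0)) x0 <- resting_state(model, model$current_interval[1])
  if (length(x0) != length(model$state_names))
    stop("x0 must have ", length(model$state_names), " entries")
  if (!is.null(seed)) set.seed(seed)
  fn <- switch(model$name,
               morris_lecar = .euler_morris_lecar,
               fhn = .euler_fhn,
               fhn3d = .euler_fhn3d,
               wang = .euler_wang)
  states <- fn(as.numeric(x0), as.numeric(i_app), model$dt,
               as.list(model$params), model$xi_bar, bound)
  colnames(states) <- model$state_names
  structure(list(t = (seq_along(i_app) - 1) * model$dt,
                 states = states,
                 i_app = as.numeric(i_app),
                 dt = model$dt,
                 model_name = model$name,
                 xi_bar = model$xi_bar,
                 seed = seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory of", x$model_name, ":", nrow(x$states), "steps, dt =",
      x$dt, "ms (", round(utils::tail(x$t, 1) / 1000, 3), "s )\n")
  invisible(x)
}

#' Resting state for a constant applied current
#'
#' Integrates the model for a settling period at constant current and
#' returns the final state. Used as the default initial condition, removing
#' the dependence on arbitrary transients.
#'
#' @param model a [neuron_model()].
#' @param i_app constant applied current.
#' @param settle_ms settling duration in ms; the default is model-specific
#'   (longer for the 3-variable FitzHugh-Nagumo, whose adaptation variable
#'   relaxes on a ~500 ms timescale).
#' @return named numeric state vector.
#' @export
resting_state <- function(model, i_app, settle_ms = NULL) {
  stopifnot(inherits(model, "neuron_model"))
  if (is.null(settle_ms))
    settle_ms <- if (is.null(model$settle_ms)) 500 else model$settle_ms
  clean <- model
  clean$xi_bar <- 0
  n <- max(2L, as.integer(round(settle_ms / model$dt)))
  tr <- integrate_neuron(clean, rep(i_app, n),
                         x0 = clean$settle_state)
  stats::setNames(tr$states[n, ], model$state_names)
}

#' Explicit-Euler integration of an arbitrary system
#'
#' Small reference integrator for user-supplied dynamics, used for the
#' closed-form checks of the Euler recurrence; the neuron models use the
#' compiled per-model integrators in [integrate_neuron()].
#'
#' @param rhs function `(state, i_app) -> derivative`.
#' @param x0 initial state.
#' @param i_app input trace; its length fixes the number of steps.
#' @param dt step size.
#' @return matrix of states (length(i_app) rows).
#' @export
euler_path <- function(rhs, x0, i_app, dt) {
  n <- length(i_app)
  out <- matrix(NA_real_, n, length(x0))
  x <- as.numeric(x0)
  out[1, ] <- x
  if (n > 1) for (m in 2:n) {
    x <- x + dt * as.numeric(rhs(x, i_app[m - 1]))
    out[m, ] <- x
  }
  out
}
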
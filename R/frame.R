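# Multiresolution spline wavelet frame: activation functions of the wavenet.
#
# A scaling family is a compactly supported B-spline scaling function phi
# solving the two-scale refinement equation phi(u) = sum_n p_n phi(2u - n)
# with interscale coefficients summing to 2. The frame on the unit interval
# consists of N_S displaced copies of phi (superposed so the approximation
# quality is uniform across the domain), the wavelets generated from each
# displaced copy at resolution levels r = 0..N_R-1, and identity terms for
# selected inputs. Multi-input frames are tensor products.

#' Spline scaling family
#'
#' Defines the scaling function used to build the frame: the quadratic
#' B-spline (support length 3) or the cubic B-spline (`"bicubic"`, support
#' length 4), each rescaled to the unit interval. The family carries the
#' interscale coefficients `p` of the refinement equation
#' \eqn{\phi(u) = \sum_n p_n \phi(2u - n)}, with \eqn{\sum_n p_n = 2}.
#'
#' @param name `"quadratic"` or `"bicubic"`.
#' @return object of class `scaling_family` with elements `name`, `d`
#'   (support length of the unrescaled function), `p` (interscale
#'   coefficients) and `raw` (the unrescaled piecewise polynomial).
#' @export
scaling_family <- function(name = c("quadratic", "bicubic")) {
  name <- match.arg(name)
  if (name == "quadratic") {
    d <- 3
    p <- c(1 / 4, 3 / 4, 3 / 4, 1 / 4)
    raw <- function(u) {
      out <- numeric(length(u))
      i <- u >= 0 & u < 1; out[i] <- u[i]^2 / 2
      i <- u >= 1 & u < 2; out[i] <- -u[i]^2 + 3 * u[i] - 3 / 2
      i <- u >= 2 & u <= 3; out[i] <- u[i]^2 / 2 - 3 * u[i] + 9 / 2
      out
    }
  } else {
    d <- 4
    p <- c(1 / 8, 1 / 2, 3 / 4, 1 / 2, 1 / 8)
    raw <- function(u) {
      out <- numeric(length(u))
      i <- u >= 0 & u < 1; out[i] <- u[i]^3 / 6
      i <- u >= 1 & u < 2
      out[i] <- (-3 * u[i]^3 + 12 * u[i]^2 - 12 * u[i] + 4) / 6
      i <- u >= 2 & u < 3
      out[i] <- (3 * u[i]^3 - 24 * u[i]^2 + 60 * u[i] - 44) / 6
      i <- u >= 3 & u <= 4; out[i] <- (4 - u[i])^3 / 6
      out
    }
  }
  structure(list(name = name, d = d, p = p, raw = raw),
            class = "scaling_family")
}

.as_family <- function(family) {
  if (inherits(family, "scaling_family")) family else scaling_family(family)
}

#' Evaluate the support-rescaled scaling function
#'
#' The unrescaled scaling function lives on `[0, d]`; this evaluates its
#' copy rescaled to the unit interval, `phi(d * x)`, which is exactly zero
#' outside `[0, 1]`.
#'
#' @param family a [scaling_family()] or its name.
#' @param x numeric vector (values outside `[0, 1]` allowed; they map to 0).
#' @export
eval_scaling <- function(family, x) {
  f <- .as_family(family)
  f$raw(f$d * x)
}

#' Evaluate a displaced scaling function
#'
#' The frame superposes `n_scaling` shifted copies of the scaling function
#' on the unit interval; copy `k` (k = 0, ..., n_scaling - 1) is
#' `phi(d * (x - 1/2 + k/(n_scaling - 1)))`, centered at
#' `x = 1 - k/(n_scaling - 1)` and truncated to `[0, 1]`. With
#' `n_scaling = 1` the single copy degenerates to the undisplaced rescaled
#' function of [eval_scaling()].
#'
#' @param family a [scaling_family()] or its name.
#' @param k displacement index in `0:(n_scaling - 1)`.
#' @param n_scaling number of superposed copies (N_S >= 1).
#' @param x numeric vector.
#' @param restrict if `TRUE` (default) the value is set to 0 outside the
#'   unit interval.
#' @export
displaced_scaling <- function(family, k, n_scaling, x, restrict = TRUE) {
  f <- .as_family(family)
  if (n_scaling < 1) stop("n_scaling must be >= 1")
  if (k < 0 || k > n_scaling - 1)
    stop("displacement index k = ", k, " outside 0:", n_scaling - 1)
  val <- if (n_scaling == 1) f$raw(f$d * x)
         else f$raw(f$d * (x - 1 / 2 + k / (n_scaling - 1)))
  if (restrict) val[x < 0 | x > 1] <- 0
  val
}

#' Evaluate a mother wavelet of the frame
#'
#' The mother wavelet attached to displaced copy `k` is
#' \eqn{\psi_k(x) = \sum_n (-1)^n p_n \phi_k(2x - n)} with the interscale
#' coefficients `p` of the family; the alternating sum
#' \eqn{\sum_n (-1)^n p_n = 0} makes it zero-mean before restriction to the
#' unit interval.
#'
#' @inheritParams displaced_scaling
#' @export
mother_wavelet <- function(family, k, n_scaling, x, restrict = TRUE) {
  f <- .as_family(family)
  val <- 0
  for (n in seq_along(f$p) - 1)
    val <- val + (-1)^n * f$p[n + 1] *
      displaced_scaling(f, k, n_scaling, 2 * x - n)
  if (restrict) val[x < 0 | x > 1] <- 0
  val
}

#' Evaluate a dilated/translated wavelet
#'
#' Wavelet of resolution level `r` and translation index `n`:
#' \eqn{\psi^{(k)}_{r,n}(x) = 2^{r/2}\,\psi_k(2^r x - n)}, with dilation
#' base 2 and translation base 1, restricted to the unit interval. Level
#' `r` admits translations `n = 0, ..., 2^r - 1`.
#'
#' @inheritParams displaced_scaling
#' @param r resolution level (integer >= 0).
#' @param n translation index in `0:(2^r - 1)`.
#' @export
frame_wavelet <- function(family, k, r, n, n_scaling, x, restrict = TRUE) {
  if (r < 0 || r != round(r)) stop("resolution level r must be a non-negative integer")
  if (n < 0 || n > 2^r - 1)
    stop("translation index n = ", n, " outside 0:", 2^r - 1, " for r = ", r)
  val <- 2^(r / 2) * mother_wavelet(family, k, n_scaling, 2^r * x - n,
                                    restrict = FALSE)
  if (restrict) val[x < 0 | x > 1] <- 0
  val
}

#' Specify a multi-input wavelet frame
#'
#' Describes the full activation-function layout of a wavenet:
#' `n_inputs` input channels, each normalized to the unit interval by the
#' per-input affine maps in `bounds`; `n_scaling` superposed scaling
#' functions; wavelet resolution levels `r = 0, ..., n_levels - 1`
#' (`n_levels = 0` keeps only the scaling level); identity (linear) terms
#' for the inputs listed in `identity_inputs`. Multi-input frame functions
#' are all tensor products of per-input choices, excluding (at each wavelet
#' level) the product in which every factor is a scaling function, which
#' already belongs to the scaling level.
#'
#' @param n_inputs number of input channels (N_I >= 1).
#' @param n_scaling number of superposed scaling functions (N_S >= 1).
#' @param n_levels number of wavelet resolution levels (N_R >= 0).
#' @param family a [scaling_family()] or its name.
#' @param identity_inputs integer indices (1-based) of the inputs that carry
#'   identity wavelons; conventionally the state-variable (or voltage-lag)
#'   inputs, never the applied-current input.
#' @param bounds 2 x n_inputs matrix of per-input normalization bounds
#'   (row 1 = lower, row 2 = upper), or `NULL` to fill in later from
#'   training data (see [normalization_bounds()]).
#' @return object of class `wavelet_frame`.
#' @export
wavelet_frame <- function(n_inputs, n_scaling, n_levels,
                          family = "quadratic", identity_inputs = integer(),
                          bounds = NULL) {
  if (n_inputs < 1 || n_scaling < 1 || n_levels < 0)
    stop("need n_inputs >= 1, n_scaling >= 1, n_levels >= 0")
  identity_inputs <- as.integer(identity_inputs)
  if (length(identity_inputs) &&
      (any(identity_inputs < 1) || any(identity_inputs > n_inputs) ||
       anyDuplicated(identity_inputs)))
    stop("identity_inputs must be distinct indices in 1:n_inputs")
  if (!is.null(bounds)) {
    bounds <- as.matrix(bounds)
    if (nrow(bounds) != 2 || ncol(bounds) != n_inputs)
      stop("bounds must be a 2 x n_inputs matrix")
    if (any(bounds[2, ] <= bounds[1, ]))
      stop("degenerate normalization bounds")
  }
  structure(list(n_inputs = as.integer(n_inputs),
                 n_scaling = as.integer(n_scaling),
                 n_levels = as.integer(n_levels),
                 family = .as_family(family),
                 identity_inputs = sort(identity_inputs),
                 bounds = bounds),
            class = "wavelet_frame")
}

#' @export
print.wavelet_frame <- function(x, ...) {
  cat("Wavelet frame:", x$family$name, "spline,",
      x$n_inputs, "inputs, N_S =", x$n_scaling, ", N_R =", x$n_levels,
      "\n  identity inputs:",
      if (length(x$identity_inputs)) paste(x$identity_inputs, collapse = ", ")
      else "none",
      "\n  wavelons:", frame_size(x), "\n")
  invisible(x)
}

#' Number of wavelons of a frame
#'
#' Closed-form count: identity terms, plus \eqn{N_S^{N_I}} scaling-level
#' products, plus \eqn{N_S^{N_I}\,((1 + 2^r)^{N_I} - 1)} products at each
#' wavelet level r (each input chooses among \eqn{N_S} scaling functions or
#' \eqn{N_S 2^r} wavelets, minus the all-scaling product).
#'
#' @param frame a [wavelet_frame()].
#' @return integer-valued count (returned as double; counts can exceed
#'   `.Machine$integer.max` for large configurations).
#' @export
frame_size <- function(frame) {
  stopifnot(inherits(frame, "wavelet_frame"))
  ns <- frame$n_scaling; ni <- frame$n_inputs
  n <- length(frame$identity_inputs) + ns^ni
  for (r in seq_len(frame$n_levels) - 1)
    n <- n + ns^ni * ((1 + 2^r)^ni - 1)
  n
}

#' Number of tensor-product functions in one level of a frame
#'
#' @param frame a [wavelet_frame()].
#' @param level `"scaling"` for the scaling level, or an integer resolution
#'   level `r` in `0:(n_levels - 1)`.
#' @export
frame_level_size <- function(frame, level) {
  stopifnot(inherits(frame, "wavelet_frame"))
  ns <- frame$n_scaling; ni <- frame$n_inputs
  if (identical(level, "scaling")) return(ns^ni)
  r <- as.integer(level)
  if (r < 0 || r >= frame$n_levels) stop("level outside 0:(n_levels-1)")
  ns^ni * ((1 + 2^r)^ni - 1)
}

# Per-input atom catalogue: atoms 1..N_S are the displaced scaling
# functions (k = atom - 1); subsequent atoms are wavelets grouped by level,
# within a level ordered by (k, n).
.atom_table <- function(frame) {
  ns <- frame$n_scaling
  tab <- data.frame(type = rep("scaling", ns), k = seq_len(ns) - 1,
                    r = NA_integer_, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(frame$n_levels) - 1) {
    grid <- expand.grid(n = 0:(2^r - 1), k = 0:(ns - 1))
    grid <- grid[order(grid$k, grid$n), ]
    tab <- rbind(tab, data.frame(type = "wavelet", k = grid$k,
                                 r = r, n = grid$n,
                                 stringsAsFactors = FALSE))
  }
  tab
}

# Enumerate the product wavelons as a matrix of atom indices (one row per
# wavelon, one column per input), in canonical order: scaling level first,
# then levels r = 0, 1, ... Within a level, combinations are lexicographic
# with the first input varying slowest. The all-scaling combination is kept
# only in the scaling level.
.frame_index <- function(frame) {
  ns <- frame$n_scaling; ni <- frame$n_inputs
  atoms <- .atom_table(frame)
  lex <- function(choices) {
    # expand.grid with first factor slowest
    g <- expand.grid(rev(choices), KEEP.OUT.ATTRS = FALSE)
    as.matrix(g[, rev(seq_len(ni)), drop = FALSE])
  }
  idx <- lex(rep(list(seq_len(ns)), ni))  # scaling level
  for (r in seq_len(frame$n_levels) - 1) {
    lev_atoms <- c(seq_len(ns), which(atoms$type == "wavelet" & atoms$r == r))
    m <- lex(rep(list(lev_atoms), ni))
    all_scaling <- rowSums(m <= ns) == ni
    idx <- rbind(idx, m[!all_scaling, , drop = FALSE])
  }
  dimnames(idx) <- NULL
  list(atoms = atoms, idx = idx)
}

#' Enumerate the wavelons of a frame
#'
#' Returns one row per wavelon in the frame's canonical order: identity
#' terms first (by input index), then the scaling-level products, then each
#' wavelet level in increasing resolution; within a level, per-input
#' selections are lexicographic. The enumeration length always equals
#' [frame_size()].
#'
#' @param frame a [wavelet_frame()].
#' @return data.frame with columns `kind` (`"identity"`/`"product"`),
#'   `level` (`NA` for identities, `"scaling"` or the resolution level) and
#'   `label` (human-readable selector per input).
#' @export
frame_wavelons <- function(frame) {
  stopifnot(inherits(frame, "wavelet_frame"))
  fi <- .frame_index(frame)
  atoms <- fi$atoms
  atom_lab <- ifelse(atoms$type == "scaling",
                     paste0("phi", atoms$k),
                     paste0("psi", atoms$k, "[", atoms$r, ",", atoms$n, "]"))
  lev <- ifelse(atoms$type == "scaling", "scaling", as.character(atoms$r))
  prod_label <- apply(fi$idx, 1, function(row)
    paste0(atom_lab[row], "(x", seq_along(row), ")", collapse = " * "))
  # a product's level is the max wavelet level among its factors
  prod_level <- apply(fi$idx, 1, function(row) {
    rs <- atoms$r[row]
    if (all(is.na(rs))) "scaling" else as.character(max(rs, na.rm = TRUE))
  })
  rbind(
    if (length(frame$identity_inputs))
      data.frame(kind = "identity", level = NA_character_,
                 label = paste0("x", frame$identity_inputs),
                 stringsAsFactors = FALSE),
    data.frame(kind = "product", level = prod_level, label = prod_label,
               stringsAsFactors = FALSE)
  )
}

#' Per-input normalization bounds from training data
#'
#' Affine min-max bounds mapping each input channel to the unit interval,
#' with the observed range expanded by a relative margin (default 5% in
#' total, half on each side) so that boundary samples do not sit exactly on
#' the frame-support edge.
#'
#' @param X numeric matrix of training inputs (rows = samples).
#' @param expand total relative expansion of each range.
#' @return 2 x ncol(X) matrix (row 1 lower, row 2 upper).
#' @export
normalization_bounds <- function(X, expand = 0.05) {
  X <- as.matrix(X)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  rg <- hi - lo
  rg[rg == 0] <- 1
  rbind(lo - expand / 2 * rg, hi + expand / 2 * rg)
}

# Normalize inputs into the frame box. Returns list(norm, oob_frac).
.normalize_inputs <- function(frame, X) {
  if (is.null(frame$bounds))
    stop("frame has no normalization bounds; set them from training data")
  lo <- frame$bounds[1, ]; hi <- frame$bounds[2, ]
  Xn <- sweep(sweep(as.matrix(X), 2, lo, "-"), 2, hi - lo, "/")
  oob <- mean(Xn < 0 | Xn > 1)
  list(norm = Xn, oob_frac = oob)
}

#' Design matrix of a frame on a set of input rows
#'
#' Evaluates every frame function on each (normalized) input row: identity
#' columns equal the normalized input channel; product columns are the
#' tensor products of per-input scaling/wavelet values, in the canonical
#' [frame_wavelons()] order. Any contiguous block of rows can be built
#' independently, so callers can assemble normal equations chunk by chunk
#' without materializing the full matrix.
#'
#' @param frame a [wavelet_frame()] with bounds set.
#' @param X input matrix (rows = samples, cols = `n_inputs`).
#' @param oob handling of inputs outside the normalization box: `"clamp"`
#'   (default) evaluates scaling/wavelet factors at the nearest box face
#'   (identity terms stay linear and unclamped), `"zero"` lets all product
#'   activations vanish there, as implied by the support restriction.
#' @param warn_oob warn when out-of-box inputs are present.
#' @return numeric matrix, `nrow(X)` x `frame_size(frame)`.
#' @export
design_matrix <- function(frame, X, oob = c("clamp", "zero"),
                          warn_oob = TRUE) {
  stopifnot(inherits(frame, "wavelet_frame"))
  oob <- match.arg(oob)
  X <- as.matrix(X)
  if (ncol(X) != frame$n_inputs)
    stop("X has ", ncol(X), " columns; frame expects ", frame$n_inputs)
  nz <- .normalize_inputs(frame, X)
  Xn <- nz$norm
  if (warn_oob && nz$oob_frac > 0)
    warning(sprintf("%.2f%% of inputs outside the normalization box (%s)",
                    100 * nz$oob_frac, oob))
  Xe <- if (oob == "clamp") pmin(pmax(Xn, 0), 1) else Xn
  fi <- .frame_index(frame)
  atoms <- fi$atoms
  fam <- frame$family; ns <- frame$n_scaling
  # per-input atom value matrices (samples x atoms)
  avals <- lapply(seq_len(frame$n_inputs), function(j) {
    x <- Xe[, j]
    v <- vapply(seq_len(nrow(atoms)), function(a) {
      if (atoms$type[a] == "scaling")
        displaced_scaling(fam, atoms$k[a], ns, x)
      else
        frame_wavelet(fam, atoms$k[a], atoms$r[a], atoms$n[a], ns, x)
    }, numeric(nrow(Xe)))
    if (!is.matrix(v)) v <- matrix(v, nrow = 1)
    v
  })
  G <- matrix(1, nrow(Xe), nrow(fi$idx))
  for (j in seq_len(frame$n_inputs))
    G <- G * avals[[j]][, fi$idx[, j], drop = FALSE]
  if (length(frame$identity_inputs))
    G <- cbind(Xn[, frame$identity_inputs, drop = FALSE], G)
  G
}
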
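#' Generalized Lotka-Volterra model
#'
#' Container for the gLV dynamics
#' `dx_i/dt = x_i * (r_i + sum_j a_ij x_j)` on a fixed taxon set:
#' an intrinsic growth-rate vector `r` and an interaction matrix `A` whose
#' entry `a_ij` is the per-unit-abundance effect of taxon `j` on taxon `i`'s
#' per-capita growth. Every diagonal entry must be negative
#' (self-limitation), a requirement for bounded dynamics.
#'
#' @param r Numeric growth-rate vector, length D.
#' @param A D x D numeric interaction matrix.
#' @param taxa Taxon identifiers; defaults to `names(r)` or `rownames(A)`.
#' @return A `glv_model`: list with `taxa`, `r`, `A`.
#' @export
glv_model <- function(r, A, taxa = NULL) {
  A <- as.matrix(A)
  d <- length(r)
  stopifnot(nrow(A) == d, ncol(A) == d)
  if (any(diag(A) >= 0)) {
    stop("every diagonal entry a_ii must be negative (self-limitation)")
  }
  if (is.null(taxa)) taxa <- names(r)
  if (is.null(taxa)) taxa <- rownames(A)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(d))
  r <- stats::setNames(as.numeric(r), taxa)
  dimnames(A) <- list(taxa, taxa)
  structure(list(taxa = taxa, r = r, A = A), class = "glv_model")
}

#' @export
print.glv_model <- function(x, ...) {
  nz <- sum(x$A != 0) - length(x$taxa)
  cat("glv_model:", length(x$taxa), "taxa,", nz,
      "off-diagonal interactions\n")
  invisible(x)
}

#' gLV time derivative
#'
#' `dx_i/dt = x_i * (r_i + sum_j a_ij x_j)`. Extinct taxa (`x_i = 0`) have
#' zero derivative: extinction is absorbing.
#'
#' @param x Non-negative abundance vector (model order).
#' @param model A `glv_model`.
#' @return Named derivative vector.
#' @export
glv_derivative <- function(x, model) {
  stopifnot(inherits(model, "glv_model"))
  if (length(x) != length(model$r)) {
    stop("state vector length ", length(x), " does not match model size ",
         length(model$r))
  }
  stats::setNames(as.numeric(x * (model$r + model$A %*% x)), model$taxa)
}

#' Interior equilibrium of a gLV model
#'
#' Solves `r + A x = 0` for the coexistence steady state (all taxa present).
#' No stability or positivity check is performed.
#'
#' @param model A `glv_model`.
#' @return Named abundance vector.
#' @export
glv_equilibrium <- function(model) {
  stats::setNames(as.numeric(solve(model$A, -model$r)), model$taxa)
}

#' Integrate a gLV model to steady state
#'
#' Fixed-step 4th-order Runge-Kutta integration of the gLV dynamics with
#' optional clamped (press-perturbed) taxa: clamped coordinates are held at
#' their clamp value at every step and contribute to other taxa's dynamics
#' but have zero derivative themselves. Negative excursions are floored at
#' zero. Integration stops when `max_i |dx_i/dt| < tol` over the free
#' coordinates, or at `t_max`.
#'
#' `method = "lsoda"` integrates the same clamped dynamics with
#' [deSolve::ode()] (adaptive multistep); it serves as an independently
#' coded cross-check of the built-in integrator.
#'
#' @param model A `glv_model`.
#' @param x0 Non-negative initial state (model order, or named).
#' @param clamps Named numeric vector: taxon -> clamp value (>= 0). `NULL`
#'   for unperturbed dynamics.
#' @param t_max Maximum integration time; default 1000.
#' @param dt RK4 step size; default 0.05.
#' @param tol Steady-state tolerance on the derivative max-norm; default
#'   1e-8.
#' @param method `"rk4"` (default) or `"lsoda"`.
#' @param record_every Record the trajectory every this many time units;
#'   default 1.
#' @return List: `steady_state` (named vector), `converged` (logical),
#'   `t_end`, `trajectory` (matrix, first column `time`, one column per
#'   taxon).
#' @export
simulate_to_steady_state <- function(model, x0, clamps = NULL, t_max = 1000,
                                     dt = 0.05, tol = 1e-8,
                                     method = c("rk4", "lsoda"),
                                     record_every = 1) {
  method <- match.arg(method)
  stopifnot(inherits(model, "glv_model"))
  d <- length(model$taxa)
  x0 <- state_vector(x0, model$taxa)
  if (any(x0 < 0)) stop("initial state must be non-negative")
  clamp_idx <- integer(0)
  clamp_val <- numeric(0)
  if (!is.null(clamps) && length(clamps)) {
    if (is.null(names(clamps))) stop("clamps must be a named vector")
    clamp_idx <- match(names(clamps), model$taxa)
    if (anyNA(clamp_idx)) {
      stop("unknown clamp taxa: ",
           paste(names(clamps)[is.na(clamp_idx)], collapse = ", "))
    }
    clamp_val <- as.numeric(clamps)
    if (any(clamp_val < 0)) stop("clamp values must be non-negative")
    x0[clamp_idx] <- clamp_val
  }
  if (method == "rk4") {
    res <- glv_integrate_cpp(x0, model$r, model$A,
                             clamp_idx - 1L, clamp_val,
                             dt, t_max, tol, 1e6,
                             max(1L, as.integer(round(record_every / dt))))
    if (res$diverged) {
      stop("gLV integration diverged (|x| > 1e6): unstable model")
    }
    traj <- cbind(time = res$times, res$trajectory)
    colnames(traj) <- c("time", model$taxa)
    return(list(steady_state = stats::setNames(as.numeric(res$state),
                                               model$taxa),
                converged = res$converged, t_end = res$t_end,
                trajectory = traj))
  }
  # lsoda oracle path; taxa starting at exactly 0 stay extinct (absorbing
  # state of the gLV flow) unless clamped to a positive value
  zero_idx <- setdiff(which(x0 == 0), clamp_idx)
  free <- setdiff(seq_len(d), c(clamp_idx, zero_idx))
  deriv_fn <- function(t, y, parms) {
    y <- pmax(y, 0)
    y[clamp_idx] <- clamp_val
    y[zero_idx] <- 0
    dy <- y * (model$r + as.numeric(model$A %*% y))
    dy[c(clamp_idx, zero_idx)] <- 0
    list(dy)
  }
  chunk <- max(record_every * 25, 25)
  t0 <- 0
  x <- x0
  rows <- list(c(0, x0))
  converged <- FALSE
  while (t0 < t_max) {
    t1 <- min(t0 + chunk, t_max)
    times <- seq(t0, t1, by = record_every)
    if (length(times) < 2) times <- c(t0, t1)
    sol <- deSolve::ode(y = x, times = times, func = deriv_fn, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    states <- sol[-1, -1, drop = FALSE]
    for (k in seq_len(nrow(states))) {
      rows[[length(rows) + 1]] <- c(sol[k + 1, 1], pmax(states[k, ], 0))
    }
    x <- pmax(states[nrow(states), ], 0)
    x[clamp_idx] <- clamp_val
    if (any(abs(x) > 1e6)) {
      stop("gLV integration diverged (|x| > 1e6): unstable model")
    }
    dx <- x * (model$r + as.numeric(model$A %*% x))
    dx[clamp_idx] <- 0
    t0 <- t1
    if (max(abs(dx[free]), 0) < tol) {
      converged <- TRUE
      break
    }
  }
  traj <- do.call(rbind, rows)
  colnames(traj) <- c("time", model$taxa)
  list(steady_state = stats::setNames(as.numeric(x), model$taxa),
       converged = converged, t_end = t0, trajectory = traj)
}

# Coerce a possibly named state vector into model order.
state_vector <- function(x, taxa) {
  if (!is.null(names(x))) {
    miss <- setdiff(taxa, names(x))
    if (length(miss)) stop("state vector missing taxa: ",
                           paste(miss, collapse = ", "))
    x <- x[taxa]
  } else if (length(x) != length(taxa)) {
    stop("state vector length ", length(x), " does not match model size ",
         length(taxa))
  }
  as.numeric(x)
}
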
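# Transient integration and steady-state solution.

.free_idx <- function(model) which(!(model$forms %in% .clamped_forms))

# deSolve-compatible right-hand side; clamps are never touched because their
# stoichiometry rows are zero.
.rhs_fun <- function(model) {
  function(t, y, parms) {
    y[y < 0] <- 0  # guard against integrator micro-undershoot
    list(drop(model$stoich %*% .reaction_rates(model, y)))
  }
}

.apply_clamps <- function(model, state, iptg, ss) {
  state <- spore_state(state[names(state) %in% .spore_forms])
  state[["IPTG"]] <- iptg * model$params[["IPTG.scale"]]
  state[["SS"]] <- ss
  state
}

#' Integrate the network in time
#'
#' Stiff-capable transient integration (via [deSolve::lsoda()]) of the model
#' under clamped IPTG/SS inputs.
#'
#' @param model a \code{spore_network}.
#' @param initial named initial state (nM); defaults to the all-zero state.
#' @param iptg IPTG induction level on the dosing axis (converted internally
#'   to concentration by \code{IPTG.scale}).
#' @param ss sporulation-signal clamp level (model units); defaults to the
#'   nominal \code{SS_in}.
#' @param duration integration time (s).
#' @param n_points number of equally spaced output times (including 0).
#' @param rtol,atol integrator tolerances.
#' @return object of class \code{"spore_trajectory"}: list with \code{times},
#'   the \code{states} matrix (time x form, negative round-off clipped to 0),
#'   and the applied stimuli.
#' @export
simulate <- function(model, initial = spore_state(), iptg = 0,
                     ss = model$params[["SS_in"]],
                     duration = 3600 * 10, n_points = 201,
                     rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "spore_network"), duration > 0, n_points >= 2)
  y0 <- .apply_clamps(model, initial, iptg, ss)
  times <- seq(0, duration, length.out = n_points)
  out <- deSolve::lsoda(y = y0, times = times, func = .rhs_fun(model),
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 50000)
  if (nrow(out) < n_points) {
    stop("integrator failed at t = ", out[nrow(out), 1],
         " s; last good state attached in condition call")
  }
  states <- out[, -1, drop = FALSE]
  states[states < 0 & states > -1e-9] <- 0
  structure(list(times = out[, 1], states = states, iptg = iptg, ss = ss),
            class = "spore_trajectory")
}

#' Steady state of the network
#'
#' Solves the zero of the time derivatives by a damped, nonnegativity
#' projected Newton iteration on the 25 free forms (the clamps are fixed).
#' When Newton fails to converge from the supplied guess the solver falls
#' back to long-time integration (in growing chunks) and re-polishes with
#' Newton, reporting which route converged.
#'
#' @inheritParams simulate
#' @param guess optional starting state; default is a cold start: integration
#'   from the all-zero state followed by Newton polish.
#' @param tol convergence tolerance on the max-norm of the time derivatives
#'   (nM/s).
#' @param max_iter Newton iteration cap per attempt.
#' @return object of class \code{"spore_steady_state"}: list with the
#'   converged \code{state}, \code{residual} (max-norm of derivatives),
#'   \code{method} ("newton" or "integration+newton") and \code{iterations}.
#' @export
steady_state <- function(model, iptg = 0, ss = model$params[["SS_in"]],
                         guess = NULL, tol = 1e-9, max_iter = 60) {
  stopifnot(inherits(model, "spore_network"))
  cold <- is.null(guess)
  y <- .apply_clamps(model, if (cold) spore_state() else guess, iptg, ss)
  if (cold) {
    traj <- simulate(model, y, iptg = iptg, ss = ss,
                     duration = 2e5, n_points = 11)
    y <- .apply_clamps(model, traj$states[nrow(traj$states), ], iptg, ss)
  }

  ans <- .newton_solve(model, y, tol, max_iter)
  method <- "newton"
  chunk <- 2e5
  tries <- 0
  while (!ans$converged && tries < 6) {
    tries <- tries + 1
    traj <- simulate(model, ans$state, iptg = iptg, ss = ss,
                     duration = chunk, n_points = 6)
    y <- .apply_clamps(model, traj$states[nrow(traj$states), ], iptg, ss)
    ans <- .newton_solve(model, y, tol, max_iter)
    method <- "integration+newton"
    chunk <- chunk * 4
  }
  if (!ans$converged)
    stop("steady-state solve did not converge (residual ",
         format(ans$residual), " nM/s at iptg=", iptg, ", ss=", ss, ")")
  structure(list(state = ans$state, residual = ans$residual,
                 method = method, iterations = ans$iterations,
                 iptg = iptg, ss = ss),
            class = "spore_steady_state")
}

.newton_solve <- function(model, y, tol, max_iter) {
  free <- .free_idx(model)
  f_of <- function(x) {
    y[free] <- x
    drop(model$stoich %*% .reaction_rates(model, y))[free]
  }
  x <- pmax(y[free], 0)
  f <- f_of(x)
  it <- 0
  while (max(abs(f)) > tol && it < max_iter) {
    it <- it + 1
    J <- .fd_jacobian(f_of, x, f)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    base <- max(abs(f))
    while (lambda > 1e-6) {
      x_new <- pmax(x + lambda * step, 0)
      f_new <- f_of(x_new)
      if (all(is.finite(f_new)) && max(abs(f_new)) < base) {
        x <- x_new; f <- f_new; improved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  y[free] <- x
  list(state = y, residual = max(abs(f)),
       converged = max(abs(f)) <= tol, iterations = it)
}

.fd_jacobian <- function(f, x, f0 = f(x)) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-7 * max(abs(x[j]), 1e-3)
    xh <- x
    xh[j] <- xh[j] + h
    J[, j] <- (f(xh) - f0) / h
  }
  J
}

#' Basal pre-equilibrated state
#'
#' Steady state with no artificial induction (IPTG = 0) and the sporulation
#' signal at its nominal clamp: a cell sensing unfavourable conditions but
#' not yet committed.  Used as the default initial condition for stimulated
#' scenarios.
#'
#' @param model a \code{spore_network}.
#' @param ss signal clamp level; defaults to the nominal \code{SS_in}.
#' @return the basal steady-state \code{FormState} (named numeric vector).
#' @export
pre_equilibrate <- function(model, ss = model$params[["SS_in"]]) {
  steady_state(model, iptg = 0, ss = ss)$state
}

#' Tidy exports
#'
#' @param x a \code{spore_trajectory} or \code{spore_steady_state}.
#' @param ... unused.
#' @return long data frame: \code{time}/\code{form}/\code{concentration} for
#'   trajectories, \code{form}/\code{concentration} for steady states.
#' @export
as.data.frame.spore_trajectory <- function(x, ...) {
  data.frame(
    time = rep(x$times, times = ncol(x$states)),
    form = rep(colnames(x$states), each = length(x$times)),
    concentration = as.vector(x$states),
    stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.spore_trajectory
#' @export
as.data.frame.spore_steady_state <- function(x, ...) {
  data.frame(form = names(x$state), concentration = as.numeric(x$state),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.spore_steady_state <- function(x, ...) {
  cat("<spore_steady_state> iptg=", x$iptg, " ss=", x$ss,
      " residual=", format(x$residual, digits = 3),
      " (", x$method, ", ", x$iterations, " Newton iters)\n", sep = "")
  invisible(x)
}

#' @export
print.spore_trajectory <- function(x, ...) {
  cat("<spore_trajectory> ", length(x$times), " time points over ",
      max(x$times), " s; iptg=", x$iptg, " ss=", x$ss, "\n", sep = "")
  invisible(x)
}

# Derived totals used across scenarios.
.derived_totals <- function(state) {
  c(total_KinA = unname(state[["KinA"]] + 2 * state[["KinA2"]] +
                          2 * state[["KinA2P"]]),
    total_Spo0F = unname(state[["Spo0F"]] + state[["Spo0FP"]]),
    total_Spo0B = unname(state[["Spo0B"]] + state[["Spo0BP"]]),
    total_Spo0A = unname(state[["Spo0A"]] + state[["Spo0AP"]]))
}

#' Derived phosphorelay totals at a state
#'
#' Total KinA counts monomer equivalents (KinA + 2 KinA2 + 2 KinA2~P); the
#' other totals are free + phosphorylated protein.
#'
#' @param state named state vector (or a \code{spore_steady_state}).
#' @return named numeric vector \code{total_KinA}, \code{total_Spo0F},
#'   \code{total_Spo0B}, \code{total_Spo0A}.
#' @export
phosphorelay_totals <- function(state) {
  if (inherits(state, "spore_steady_state")) state <- state$state
  .derived_totals(state)
}
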
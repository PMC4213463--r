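# Synthetic observation generators: noisy dose-response sets of the kind
# digitized from inducible-system experiments, and linearly accumulating
# wild-type time courses.  All generators are pure functions of their
# arguments and an explicit seed; the caller's RNG state is untouched.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic noisy dose-response observations
#'
#' Wraps the deterministic steady-state dose-response in multiplicative
#' Gaussian noise (coefficient of variation \code{cv}, truncated at -90\% so
#' observations stay positive), emulating digitized experimental
#' dose-response points.  The truth column is exactly the deterministic
#' pipeline output.
#'
#' @param model a \code{spore_network}, or a precomputed
#'   \code{spore_dose_response} (avoids re-solving the deterministic truth
#'   when drawing many noise replicates from the same curve).
#' @param stimulus \code{"IPTG"} or \code{"SS"}.
#' @param grid stimulus grid (passed to [dose_response()]).
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param seed integer seed; observations are a pure function of it.
#' @param form observed series: a form name or one of the derived totals
#'   (default \code{"total_KinA"}).
#' @return object of class \code{"spore_synth_dr"}: list with \code{grid},
#'   \code{truth}, \code{observed}, \code{cv}, \code{seed}, \code{form}.
#' @export
make_dose_response_observations <- function(model, stimulus = "IPTG",
                                            grid = NULL, cv = 0.05,
                                            seed = 1L,
                                            form = "total_KinA") {
  stopifnot(cv >= 0)
  dr <- if (inherits(model, "spore_dose_response")) model
        else dose_response(model, stimulus = stimulus, grid = grid)
  truth <- if (form %in% colnames(dr$derived)) dr$derived[, form]
           else dr$states[, form]
  factor <- .with_seed(seed, pmax(1 + cv * stats::rnorm(length(truth)), 0.1))
  structure(list(grid = dr$grid, truth = unname(truth),
                 observed = unname(truth * factor),
                 cv = cv, seed = seed, form = form,
                 stimulus = dr$stimulus),
            class = "spore_synth_dr")
}

#' Synthetic wild-type linear accumulation time course
#'
#' Per-species straight-line truth plus additive Gaussian noise, emulating
#' the statistical structure of single-cell wild-type measurements of total
#' phosphorelay protein accumulation (roughly constant scatter around linear
#' growth).  Default slopes/grid give a Spo0A trace accumulating to the
#' 37.5 \eqn{\mu}M wild-type benchmark over 150 min.
#'
#' @param slopes named numeric vector of slopes (concentration/min).
#' @param intercepts named numeric vector, same names as \code{slopes}.
#' @param sigma additive noise standard deviation (same concentration unit).
#' @param t_grid time grid in minutes.
#' @param seed integer seed.
#' @return long data frame with columns \code{species}, \code{time},
#'   \code{truth}, \code{observed}.
#' @export
make_wildtype_timecourse <- function(slopes = c(KinA = 0.05, Spo0F = 0.12,
                                                Spo0A = 0.25),
                                     intercepts = c(KinA = 0.2, Spo0F = 0.5,
                                                    Spo0A = 0),
                                     sigma = 1, t_grid = seq(0, 150, by = 10),
                                     seed = 1L) {
  stopifnot(sigma >= 0, identical(sort(names(slopes)), sort(names(intercepts))))
  species <- names(slopes)
  truth <- unlist(lapply(species, function(s)
    intercepts[[s]] + slopes[[s]] * t_grid))
  noise <- .with_seed(seed, stats::rnorm(length(truth), sd = sigma))
  data.frame(
    species = rep(species, each = length(t_grid)),
    time = rep(t_grid, times = length(species)),
    truth = truth,
    observed = truth + noise,
    stringsAsFactors = FALSE)
}

#' Parameter recovery study on synthetic dose-response data
#'
#' Validates the fitting machinery used for the "fitted" kinetic constants:
#' simulate noisy dose-response observations from a ground-truth model,
#' perturb selected parameters (the optimizer's starting point), and refit
#' them by minimizing the goodness-of-agreement distance to the
#' observations.  Reports the relative recovery error per parameter and
#' replicate.
#'
#' @param model ground-truth \code{spore_network}.
#' @param perturb_ids parameter keys to refit (perturbed jointly).
#' @param cv observation noise level.
#' @param seed base seed; replicate r uses \code{seed + r}.
#' @param n_rep number of replicates.
#' @param start_factor multiplicative offset of the optimizer start from
#'   truth (default 2).
#' @param grid IPTG grid for the observations (default 11 points, 0--20).
#' @param form observed series (default \code{"total_KinA"}).
#' @return data frame with one row per (replicate, parameter): the true and
#'   recovered values, \code{rel_error}, the achieved \code{distance}, and a
#'   \code{converged} flag (optimizer failures are flagged per replicate,
#'   not dropped).
#' @export
parameter_recovery_study <- function(model, perturb_ids = "tl2.k",
                                     cv = 0.05, seed = 1L, n_rep = 10,
                                     start_factor = 2,
                                     grid = seq(0, 20, length.out = 11),
                                     form = "total_KinA") {
  stopifnot(all(perturb_ids %in% names(model$params)))
  truth_vals <- model$params[perturb_ids]

  fit_curve <- function(m) {
    guess <- NULL
    out <- numeric(length(grid))
    for (i in seq_along(grid)) {
      st <- steady_state(m, iptg = grid[i], guess = guess)
      out[i] <- if (form == "total_KinA") .derived_totals(st$state)[["total_KinA"]]
                else if (form %in% names(.derived_totals(st$state)))
                  .derived_totals(st$state)[[form]]
                else st$state[[form]]
      guess <- st$state
    }
    out
  }

  rows <- list()
  for (r in seq_len(n_rep)) {
    obs <- make_dose_response_observations(model, grid = grid, cv = cv,
                                           seed = seed + r, form = form)
    objective <- function(theta) {
      vals <- exp(theta)
      m <- set_parameters(model, stats::setNames(vals, perturb_ids))
      tryCatch(goodness_of_agreement(obs$observed, fit_curve(m)),
               error = function(e) 1e6)
    }
    start <- log(truth_vals * start_factor)
    fit <- if (length(perturb_ids) == 1) {
      o <- stats::optimize(function(t) objective(t),
                           interval = start + c(-4, 4) * log(2), tol = 1e-6)
      list(par = o$minimum, value = o$objective, convergence = 0)
    } else {
      stats::optim(start, objective, method = "Nelder-Mead",
                   control = list(maxit = 300, reltol = 1e-8))
    }
    rec <- exp(fit$par)
    rows[[r]] <- data.frame(
      replicate = r, parameter = perturb_ids,
      true = as.numeric(truth_vals), recovered = as.numeric(rec),
      rel_error = abs(as.numeric(rec) - as.numeric(truth_vals)) /
        as.numeric(truth_vals),
      distance = fit$value,
      converged = fit$convergence == 0 && fit$value < 1e6,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
print.spore_synth_dr <- function(x, ...) {
  cat("<spore_synth_dr> ", x$form, " vs ", x$stimulus, ", ",
      length(x$grid), " points, cv=", x$cv, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' @rdname as.data.frame.spore_trajectory
#' @export
as.data.frame.spore_synth_dr <- function(x, ...) {
  data.frame(stimulus = x$stimulus, level = x$grid, form = x$form,
             truth = x$truth, observed = x$observed,
             stringsAsFactors = FALSE)
}
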
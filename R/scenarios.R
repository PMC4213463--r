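# End-to-end analyses: dose-response curves, steady-state panels, the
# feedback knockout/compensation experiment, the goodness-of-agreement
# metric, and the wild-type linear-accumulation comparison.

.phospho_forms <- c("KinA2P", "Spo0FP", "Spo0BP", "Spo0AP")
.effector_forms <- c("AA", "AB", "AC", "IIE", "GA", "GB")

#' Steady-state dose-response scan
#'
#' Solves the steady state along a grid of one stimulus (IPTG induction with
#' SS at its nominal clamp, or SS with IPTG absent), warm-starting each grid
#' point from the previous solution.  A cold-start hysteresis check is run
#' at the final grid point and reported (not hidden) in the result.
#'
#' @param model a \code{spore_network}.
#' @param stimulus \code{"IPTG"} or \code{"SS"}.
#' @param grid strictly increasing stimulus levels (defaults: 21 points over
#'   0--20 for IPTG, 0--2 for SS).
#' @param other level of the non-scanned stimulus (default: nominal SS for
#'   IPTG scans, 0 IPTG for SS scans).
#' @return object of class \code{"spore_dose_response"}: list with the grid,
#'   a \code{states} matrix (grid point x form), a \code{derived} matrix of
#'   phosphorelay totals, and \code{hysteresis} (max relative cold-vs-warm
#'   deviation at the last point).
#' @export
dose_response <- function(model, stimulus = c("IPTG", "SS"), grid = NULL,
                          other = NULL) {
  stimulus <- match.arg(stimulus)
  if (is.null(grid))
    grid <- if (stimulus == "IPTG") seq(0, 20, length.out = 21)
            else seq(0, 2, length.out = 21)
  stopifnot(length(grid) >= 1, !is.unsorted(grid, strictly = TRUE))
  if (is.null(other))
    other <- if (stimulus == "IPTG") model$params[["SS_in"]] else 0

  states <- matrix(NA_real_, nrow = length(grid), ncol = length(model$forms),
                   dimnames = list(NULL, model$forms))
  flagged <- logical(length(grid))
  guess <- NULL
  for (i in seq_along(grid)) {
    iptg <- if (stimulus == "IPTG") grid[i] else other
    ss <- if (stimulus == "IPTG") other else grid[i]
    st <- tryCatch(steady_state(model, iptg = iptg, ss = ss, guess = guess),
                   error = function(e) NULL)
    if (is.null(st)) { flagged[i] <- TRUE; next }
    states[i, ] <- st$state
    guess <- st$state
  }
  derived <- t(apply(states, 1, .derived_totals))

  # hysteresis check: re-solve the last converged point cold
  hyst <- NA_real_
  last <- max(which(!flagged))
  iptg <- if (stimulus == "IPTG") grid[last] else other
  ss <- if (stimulus == "IPTG") other else grid[last]
  cold <- tryCatch(steady_state(model, iptg = iptg, ss = ss),
                   error = function(e) NULL)
  if (!is.null(cold)) {
    w <- states[last, ]
    denom <- pmax(abs(w), 1e-12)
    hyst <- max(abs(cold$state - w) / denom)
  }

  structure(list(stimulus = stimulus, grid = grid, other = other,
                 states = states, derived = derived,
                 flagged = flagged, hysteresis = hyst),
            class = "spore_dose_response")
}

#' @export
print.spore_dose_response <- function(x, ...) {
  cat("<spore_dose_response> ", x$stimulus, " over [",
      min(x$grid), ", ", max(x$grid), "], ", length(x$grid),
      " points; hysteresis ", format(x$hysteresis, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @rdname as.data.frame.spore_trajectory
#' @export
as.data.frame.spore_dose_response <- function(x, ...) {
  all <- cbind(x$states, x$derived)
  data.frame(
    stimulus = x$stimulus,
    level = rep(x$grid, times = ncol(all)),
    form = rep(colnames(all), each = length(x$grid)),
    concentration = as.vector(all),
    stringsAsFactors = FALSE)
}

#' Steady-state panel at selected induction levels
#'
#' Tabulates the phosphorylated phosphorelay forms and the six effector
#' proteins at a set of IPTG induction levels (nominal SS clamp).
#'
#' @param model a \code{spore_network}.
#' @param iptg_levels induction levels (default 0, 10, 20).
#' @return list with matrices \code{phospho} (forms x levels) and
#'   \code{effectors} (forms x levels).
#' @export
steady_state_panel <- function(model, iptg_levels = c(0, 10, 20)) {
  states <- vapply(iptg_levels, function(u)
    steady_state(model, iptg = u)$state, spore_state())
  colnames(states) <- paste0("IPTG=", iptg_levels)
  list(phospho = states[.phospho_forms, , drop = FALSE],
       effectors = states[.effector_forms, , drop = FALSE])
}

#' Goodness-of-agreement distance between two curves
#'
#' The mean relative deviation \eqn{\frac{1}{n}\sum_i |o_i - m_i| / o_i}
#' between an observed and a predicted series on matched abscissae.
#' Dimensionless; multiply by 100 for the percentage reported in the
#' analyses.
#'
#' @param observed positive numeric vector \eqn{o_i}.
#' @param predicted numeric vector \eqn{m_i}, same length.
#' @return the mean relative distance (fraction).
#' @export
#' @examples
#' goodness_of_agreement(c(1, 2), c(1.1, 1.8))  # 0.10
goodness_of_agreement <- function(observed, predicted) {
  if (length(observed) < 1 || length(observed) != length(predicted))
    stop("observed and predicted must be equal-length, nonempty")
  if (any(!is.finite(observed)) || any(observed <= 0))
    stop("all observed values must be positive (the metric divides by o_i)")
  mean(abs(observed - predicted) / observed)
}

#' Knock out the Spo0A~P positive feedback on KinA expression
#'
#' Returns a copy of the model with the feedback coefficient of the
#' \emph{kinA} transcription law (\code{tr2.k3}) set to zero; the reaction
#' inventory is unchanged (the feedback term simply evaluates to zero).
#'
#' @param model a \code{spore_network}.
#' @return the knockout model.
#' @export
feedback_knockout <- function(model) {
  set_parameters(model, c("tr2.k3" = 0))
}

#' Refit the LacI-repression parameters to compensate a feedback knockout
#'
#' With the Spo0A~P feedback on \emph{kinA} transcription removed, only the
#' repression amplitude \code{tr2.k2} and half-saturation \code{tr2.KL} are
#' refitted so that the knockout model's steady-state phospho-KinA-dimer
#' dose-response matches a reference (intact-model) curve, minimizing the
#' mean relative distance of [goodness_of_agreement()].  Bounded
#' Nelder--Mead on log-scaled parameters with an L-BFGS-B polish.
#'
#' @param reference a \code{spore_dose_response} over IPTG from the intact
#'   model (its \code{KinA2P} column is the target curve).
#' @param knockout_model the model with \code{tr2.k3 = 0}.
#' @param bounds list with elements \code{k2} and \code{KL}, each
#'   \code{c(lower, upper)}; defaults span 0--10x and 1--20x nominal.
#' @return list with \code{k2}, \code{KL}, the achieved \code{distance}
#'   (fraction), the refitted model, the fitted curve, and optimizer
#'   diagnostics.
#' @export
compensate_repression_params <- function(reference, knockout_model,
                                         bounds = NULL) {
  stopifnot(inherits(reference, "spore_dose_response"),
            reference$stimulus == "IPTG")
  p0 <- c(k2 = knockout_model$params[["tr2.k2"]],
          KL = knockout_model$params[["tr2.KL"]])
  if (is.null(bounds))
    bounds <- list(k2 = c(1e-6, 10 * p0[["k2"]]),
                   KL = c(1, 20 * p0[["KL"]]))
  target <- reference$states[, "KinA2P"]
  grid <- reference$grid
  other <- reference$other

  ko_curve <- function(k2, KL) {
    m <- set_parameters(knockout_model, c("tr2.k2" = k2, "tr2.KL" = KL))
    guess <- NULL
    out <- numeric(length(grid))
    for (i in seq_along(grid)) {
      st <- steady_state(m, iptg = grid[i], ss = other, guess = guess)
      out[i] <- st$state[["KinA2P"]]
      guess <- st$state
    }
    out
  }
  objective <- function(theta) {
    k2 <- min(max(exp(theta[1]), bounds$k2[1]), bounds$k2[2])
    KL <- min(max(exp(theta[2]), bounds$KL[1]), bounds$KL[2])
    tryCatch(goodness_of_agreement(target, ko_curve(k2, KL)),
             error = function(e) 1e6)
  }

  start <- log(c(max(p0[["k2"]], bounds$k2[1]), p0[["KL"]]))
  fit1 <- stats::optim(start, objective, method = "Nelder-Mead",
                       control = list(maxit = 200, reltol = 1e-8))
  fit2 <- stats::optim(fit1$par, objective, method = "L-BFGS-B",
                       lower = log(c(bounds$k2[1], bounds$KL[1])),
                       upper = log(c(bounds$k2[2], bounds$KL[2])),
                       control = list(factr = 1e7))
  best <- if (fit2$value <= fit1$value) fit2 else fit1
  k2 <- min(max(exp(best$par[1]), bounds$k2[1]), bounds$k2[2])
  KL <- min(max(exp(best$par[2]), bounds$KL[1]), bounds$KL[2])
  fitted_model <- set_parameters(knockout_model,
                                 c("tr2.k2" = k2, "tr2.KL" = KL))
  curve <- ko_curve(k2, KL)
  list(k2 = k2, KL = KL,
       distance = goodness_of_agreement(target, curve),
       model = fitted_model, fitted_curve = curve,
       reference_curve = target, grid = grid,
       convergence = best$convergence, evaluations = best$counts)
}

#' Ordinary least-squares linear fit
#'
#' Slope, intercept and coefficient of determination of a straight-line fit,
#' as used for the wild-type linear-accumulation comparison.
#'
#' @param times abscissae (>= 3 points).
#' @param values ordinates.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared} and
#'   standard errors \code{slope_se}, \code{intercept_se}.  Zero variance in
#'   \code{values} leaves \code{r_squared} as \code{NA} with a warning.
#' @export
linear_fit <- function(times, values) {
  stopifnot(length(times) == length(values))
  if (length(times) < 3) stop("linear_fit needs at least 3 points")
  fit <- stats::lm(values ~ times)
  co <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      # an exactly collinear input is a legitimate degenerate case here
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ss_tot <- sum((values - mean(values))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero variance in values; R^2 undefined")
    NA_real_
  } else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = unname(co["times", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = r2,
       slope_se = unname(co["times", "Std. Error"]),
       intercept_se = unname(co["(Intercept)", "Std. Error"]))
}

#' Wild-type accumulation discrepancy report
#'
#' Scans the joint stimulus envelope (IPTG x SS grids, warm-started row by
#' row) for the maximum steady-state total Spo0A (free + phosphorylated) the
#' model can produce, and reports it against the wild-type single-cell
#' benchmark accumulation.  The model's ceiling sits far below the wild-type
#' level -- the point of the comparison is precisely that the inducible-system
#' kinetics cannot reproduce wild-type accumulation.
#'
#' Internally concentrations are nM; the report converts total Spo0A to
#' \eqn{\mu}M for comparison with the benchmark (37.5 \eqn{\mu}M, against a
#' model ceiling of 4.5 \eqn{\mu}M).
#'
#' @param model a \code{spore_network}.
#' @param iptg_grid,ss_grid stimulus grids (defaults 21 points over 0--20 and
#'   0--2).
#' @param widen also scan a coarse envelope this many times wider (default
#'   10; set to \code{NULL} to skip).
#' @param benchmark_uM wild-type benchmark total Spo0A (\eqn{\mu}M).
#' @return list with \code{max_total_spo0A_uM} (standard envelope),
#'   \code{max_total_spo0A_uM_wide}, the grid of totals, the argmax stimuli,
#'   \code{benchmark_uM} and \code{benchmark_ratio}.
#' @export
wildtype_discrepancy_report <- function(model,
                                        iptg_grid = seq(0, 20, length.out = 21),
                                        ss_grid = seq(0, 2, length.out = 21),
                                        widen = 10, benchmark_uM = 37.5) {
  scan_env <- function(ig, sg) {
    tot <- matrix(NA_real_, length(ig), length(sg),
                  dimnames = list(format(ig), format(sg)))
    row_guess <- NULL
    for (i in seq_along(ig)) {
      guess <- row_guess
      for (j in seq_along(sg)) {
        st <- steady_state(model, iptg = ig[i], ss = sg[j], guess = guess)
        tot[i, j] <- st$state[["Spo0A"]] + st$state[["Spo0AP"]]
        guess <- st$state
        if (j == 1) row_guess <- st$state
      }
    }
    tot
  }
  tot <- scan_env(iptg_grid, ss_grid)
  mx <- max(tot)
  arg <- which(tot == mx, arr.ind = TRUE)[1, ]

  mx_wide <- NA_real_
  if (!is.null(widen)) {
    wide_i <- seq(0, max(iptg_grid) * widen, length.out = 6)
    wide_s <- seq(0, max(ss_grid) * widen, length.out = 6)
    mx_wide <- max(scan_env(wide_i, wide_s))
  }

  list(max_total_spo0A_uM = mx / 1000,
       max_total_spo0A_uM_wide = mx_wide / 1000,
       totals_nM = tot,
       argmax = c(iptg = iptg_grid[arg[[1]]], ss = ss_grid[arg[[2]]]),
       benchmark_uM = benchmark_uM,
       benchmark_ratio = benchmark_uM / (mx / 1000))
}
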
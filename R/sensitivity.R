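# Local relative sensitivities around a steady state, and global one-at-a-time
# parameter scans.

#' Local relative sensitivity coefficients at steady state
#'
#' Computes dimensionless relative sensitivity coefficients
#' \eqn{S = (p/c)\,\partial c/\partial p} of steady-state concentrations with
#' respect to rate-law parameters, by central finite differences with the
#' steady state re-solved at each perturbed parameter value (warm-started
#' from the nominal solution).  If the two one-sided secant estimates for an
#' entry disagree by more than 10\% (relative, above a small floor), the step
#' is halved and the entry recomputed, up to \code{max_halvings} times.
#'
#' @param model a \code{spore_network}.
#' @param parameters character vector of parameter keys to perturb (any key
#'   of \code{model$params}, including the materialized \code{deg_<form>.k}
#'   degradation constants).
#' @param targets forms to report (default: all 25 non-clamped forms).
#' @param rel_step relative finite-difference step (default 1e-3).
#' @param iptg,ss stimulus levels defining the nominal steady state.
#' @param max_halvings cap on automatic step halving.
#' @return object of class \code{"spore_sensitivity"}: list with the
#'   coefficient matrix \code{S} (targets x parameters), the per-parameter
#'   steps actually used, the nominal steady state, and a logical matrix
#'   \code{flagged} marking entries whose perturbed steady-state solve failed
#'   (such entries are \code{NA}, never silently zero).
#' @export
local_sensitivities <- function(model, parameters,
                                targets = setdiff(model$forms, c("IPTG", "SS")),
                                rel_step = 1e-3,
                                iptg = 0, ss = model$params[["SS_in"]],
                                max_halvings = 3) {
  stopifnot(inherits(model, "spore_network"), length(parameters) >= 1)
  unknown <- setdiff(parameters, names(model$params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  nominal <- steady_state(model, iptg = iptg, ss = ss)
  c0 <- nominal$state[targets]

  S <- matrix(NA_real_, nrow = length(targets), ncol = length(parameters),
              dimnames = list(targets, parameters))
  flagged <- matrix(FALSE, nrow = length(targets), ncol = length(parameters),
                    dimnames = dimnames(S))
  steps <- stats::setNames(rep(rel_step, length(parameters)), parameters)

  solve_at <- function(key, value) {
    m <- set_parameters(model, stats::setNames(value, key))
    tryCatch(steady_state(m, iptg = iptg, ss = ss,
                          guess = nominal$state)$state[targets],
             error = function(e) NULL)
  }

  for (key in parameters) {
    p0 <- model$params[[key]]
    if (p0 == 0) {
      # a zero-valued nominal parameter has no relative coefficient; report 0
      S[, key] <- 0
      next
    }
    h <- rel_step
    for (halve in 0:max_halvings) {
      up <- solve_at(key, p0 * (1 + h))
      dn <- solve_at(key, p0 * (1 - h))
      if (is.null(up) || is.null(dn)) {
        flagged[, key] <- TRUE
        break
      }
      # a target at zero concentration with zero response has, by
      # continuity, zero relative sensitivity (e.g. LacI_d without IPTG)
      rel <- function(num, denom_c) {
        out <- num / (denom_c * h)
        out[denom_c == 0 & num == 0] <- 0
        out
      }
      s_up <- rel(up - c0, c0)
      s_dn <- rel(c0 - dn, c0)
      s_cen <- rel((up - dn) / 2, c0)
      disagree <- abs(s_up - s_dn) > 0.1 * pmax(abs(s_cen), 1e-3)
      S[, key] <- s_cen
      steps[[key]] <- h
      if (!any(disagree, na.rm = TRUE) || halve == max_halvings) break
      h <- h / 2
    }
  }

  structure(list(S = S, steps = steps, scheme = "central",
                 nominal = nominal, flagged = flagged,
                 iptg = iptg, ss = ss),
            class = "spore_sensitivity")
}

#' One-parameter global scan of steady states
#'
#' Re-solves the steady state while one rate constant is scaled over a grid
#' of factors (e.g. 50\%--150\% of nominal), warm-starting each point from
#' the previous.  Returns both raw concentrations and values normalized to
#' the nominal-factor (1.0) column.
#'
#' @param model a \code{spore_network}.
#' @param parameter single parameter key to scan.
#' @param scale_factors positive multipliers of the nominal value; 1.0 is
#'   added if absent (the normalization reference).
#' @param targets forms to report.
#' @param iptg,ss stimulus levels.
#' @return object of class \code{"spore_scan"}: list with \code{parameter},
#'   \code{scale_factors}, matrices \code{values} and \code{normalized}
#'   (factor x form), and a logical vector \code{flagged} marking
#'   non-converged points.
#' @export
parameter_scan <- function(model, parameter, scale_factors,
                           targets = setdiff(model$forms, c("IPTG", "SS")),
                           iptg = 0, ss = model$params[["SS_in"]]) {
  stopifnot(length(parameter) == 1, all(scale_factors > 0))
  if (!parameter %in% names(model$params))
    stop("unknown parameter: ", parameter)
  facs <- sort(unique(c(scale_factors, 1)))
  p0 <- model$params[[parameter]]
  vals <- matrix(NA_real_, nrow = length(facs), ncol = length(targets),
                 dimnames = list(format(facs), targets))
  flagged <- stats::setNames(rep(FALSE, length(facs)), format(facs))
  guess <- NULL
  for (i in seq_along(facs)) {
    m <- set_parameters(model, stats::setNames(p0 * facs[i], parameter))
    st <- tryCatch(steady_state(m, iptg = iptg, ss = ss, guess = guess),
                   error = function(e) NULL)
    if (is.null(st)) { flagged[i] <- TRUE; next }
    vals[i, ] <- st$state[targets]
    guess <- st$state
  }
  ref <- vals[match(1, facs), ]
  normalized <- sweep(vals, 2, ref, `/`)
  keep <- facs %in% scale_factors
  structure(list(parameter = parameter, scale_factors = facs,
                 requested = scale_factors,
                 values = vals, normalized = normalized,
                 flagged = flagged, iptg = iptg, ss = ss),
            class = "spore_scan")
}

#' Write a sensitivity matrix or scan result to CSV
#'
#' Prepends a commented metadata header (scheme, step sizes or grid,
#' stimulus levels) before the rectangular table.
#'
#' @param x a \code{spore_sensitivity} or \code{spore_scan}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_sensitivity_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "spore_sensitivity")) {
    writeLines(c(
      paste0("# relative sensitivity coefficients S=(p/c) dc/dp, ",
             x$scheme, " differences"),
      paste0("# rel_step per parameter: ",
             paste(names(x$steps), signif(x$steps, 3), sep = "=",
                   collapse = ", ")),
      paste0("# iptg=", x$iptg, " ss=", x$ss,
             " residual=", format(x$nominal$residual, digits = 3))), con)
    tab <- data.frame(form = rownames(x$S), x$S, check.names = FALSE)
  } else if (inherits(x, "spore_scan")) {
    writeLines(c(
      paste0("# steady-state scan of ", x$parameter),
      paste0("# scale factors: ", paste(x$scale_factors, collapse = ", ")),
      paste0("# iptg=", x$iptg, " ss=", x$ss)), con)
    tab <- data.frame(scale_factor = x$scale_factors, x$values,
                      check.names = FALSE)
  } else stop("unsupported object")
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @export
print.spore_sensitivity <- function(x, ...) {
  cat("<spore_sensitivity> ", nrow(x$S), " forms x ", ncol(x$S),
      " parameters; max |S| = ",
      format(max(abs(x$S), na.rm = TRUE), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
print.spore_scan <- function(x, ...) {
  cat("<spore_scan> ", x$parameter, " over ",
      length(x$scale_factors), " factors [",
      min(x$scale_factors), ", ", max(x$scale_factors), "]\n", sep = "")
  invisible(x)
}
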
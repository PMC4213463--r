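#' @section Molecular forms:
#' The 13 modelled species give rise to 27 distinct molecular forms
#' (transcripts, free/dimeric/phosphorylated proteins plus the two clamped
#' boundary inputs IPTG and SS).
#' @name sporelay-forms
#' @keywords internal
NULL

.spore_forms <- c(
  "lacI_t", "LacI", "LacI_d", "IPTG", "SS",
  "kinA_t", "KinA", "KinA2", "KinA2P",
  "spo0F_t", "Spo0F", "Spo0FP",
  "spo0B_t", "Spo0B", "Spo0BP",
  "spo0A_t", "Spo0A", "Spo0AP",
  "spoIIA_t", "AA", "AB", "AC",
  "spoIIE_t", "IIE",
  "spoIIG_t", "GA", "GB"
)

.transcript_forms <- c("lacI_t", "kinA_t", "spo0F_t", "spo0B_t", "spo0A_t",
                       "spoIIA_t", "spoIIE_t", "spoIIG_t")
.clamped_forms <- c("IPTG", "SS")
.protein_forms <- setdiff(.spore_forms, c(.transcript_forms, .clamped_forms))

#' Names of the 27 molecular forms
#'
#' @return character vector of the form names, in canonical order.
#' @export
spore_forms <- function() .spore_forms

#' Construct an all-zero state vector
#'
#' @param values optional named numeric vector of concentrations (nM) to set.
#' @return named numeric vector over the 27 forms.
#' @export
spore_state <- function(values = NULL) {
  s <- stats::setNames(numeric(length(.spore_forms)), .spore_forms)
  if (!is.null(values)) {
    unknown <- setdiff(names(values), .spore_forms)
    if (length(unknown))
      stop("unknown form(s): ", paste(unknown, collapse = ", "))
    s[names(values)] <- as.numeric(values)
  }
  s
}

.reaction <- function(id, kind, k, reactants = NULL, products = NULL,
                      modifiers = character(0), orders = NULL, pars = NULL) {
  structure(list(id = id, kind = kind, k = k,
                 reactants = reactants, products = products,
                 modifiers = modifiers, orders = orders, pars = pars),
            class = "spore_reaction")
}

#' Build the reference sporulation-initiation network
#'
#' Assembles the full reaction network: constitutive LacI expression and its
#' reversible sequestration by IPTG, LacI/Spo0A~P-regulated KinA expression,
#' KinA dimerization and SS-driven autophosphorylation, the
#' Spo0F--Spo0B--Spo0A phosphorelay, Spo0A~P-activated \emph{spoII}
#' transcription with effector translation, a first-order Spo0B~P
#' dephosphorylation, and one first-order degradation reaction per form
#' except the clamped inputs IPTG and SS. Under the default inventory this is
#' 27 forms and 55 unidirectional reactions.
#'
#' Degradation rate constants are materialized per form (parameter keys
#' \code{deg_<form>.k}) from the shared \code{d_mRNA}/\code{d_prot} values so
#' that individual turnover reactions can be perturbed in sensitivity
#' analyses; updating \code{d_mRNA} or \code{d_prot} through
#' [set_parameters()] re-propagates them.
#'
#' @param params parameter set from [spore_parameters()].
#' @return an object of class \code{"spore_network"} with elements
#'   \code{forms}, \code{reactions}, \code{params} (including the
#'   materialized degradation constants) and the stoichiometry matrix
#'   \code{stoich} (forms x reactions).
#' @references The network topology and rate laws follow the published
#'   COPASI model of sporulation initiation; see the methods vignette.
#' @export
#' @examples
#' m <- build_reference_network(spore_parameters())
#' length(m$forms)       # 27
#' length(m$reactions)   # 55
build_reference_network <- function(params = spore_parameters()) {
  validate_parameters(params)
  p <- stats::setNames(as.numeric(params), names(params))

  rx <- list(
    .reaction("tr1", "constant", "tr1.k", products = c(lacI_t = 1)),
    .reaction("tl1", "mass_action", "tl1.k", products = c(LacI = 1),
              modifiers = "lacI_t", orders = c(lacI_t = 1)),
    # IPTG sequesters the LacI protein into the inactive LacI_d form; the
    # clamped inducer is a modifier, not consumed.
    .reaction("k1", "mass_action", "k1.k", reactants = c(LacI = 1),
              products = c(LacI_d = 1), modifiers = "IPTG",
              orders = c(LacI = 1, IPTG = 1)),
    .reaction("k2", "mass_action", "k2.k", reactants = c(LacI_d = 1),
              products = c(LacI = 1), orders = c(LacI_d = 1)),
    .reaction("tr2", "kinA_transcription", "tr2.k1",
              products = c(kinA_t = 1), modifiers = c("LacI", "Spo0AP"),
              pars = c(k1 = "tr2.k1", k2 = "tr2.k2", k3 = "tr2.k3",
                       KL = "tr2.KL", KS = "tr2.KS")),
    .reaction("tl2", "mass_action", "tl2.k", products = c(KinA = 1),
              modifiers = "kinA_t", orders = c(kinA_t = 1)),
    .reaction("k3", "mass_action", "k3.k", reactants = c(KinA = 2),
              products = c(KinA2 = 1), orders = c(KinA = 2)),
    .reaction("k4", "mass_action", "k4.k", reactants = c(KinA2 = 1),
              products = c(KinA = 2), orders = c(KinA2 = 1)),
    .reaction("k5", "mass_action", "k5.k", reactants = c(KinA2 = 1),
              products = c(KinA2P = 1), modifiers = "SS",
              orders = c(KinA2 = 1, SS = 1)),
    .reaction("tr3", "hill_activation_basal", "tr3.k1",
              products = c(spo0F_t = 1), modifiers = "Spo0AP",
              pars = c(k1 = "tr3.k1", k2 = "tr3.k2", KS = "tr3.KS")),
    .reaction("tl3", "mass_action", "tl3.k", products = c(Spo0F = 1),
              modifiers = "spo0F_t", orders = c(spo0F_t = 1)),
    .reaction("k6", "mass_action", "k6.k",
              reactants = c(Spo0F = 1, KinA2P = 1),
              products = c(Spo0FP = 1, KinA2 = 1),
              orders = c(Spo0F = 1, KinA2P = 1)),
    .reaction("k7", "mass_action", "k7.k", reactants = c(Spo0FP = 1),
              products = c(Spo0F = 1), orders = c(Spo0FP = 1)),
    .reaction("tr4", "constant", "tr4.k", products = c(spo0B_t = 1)),
    .reaction("tl4", "mass_action", "tl4.k", products = c(Spo0B = 1),
              modifiers = "spo0B_t", orders = c(spo0B_t = 1)),
    .reaction("k8", "mass_action", "k8.k",
              reactants = c(Spo0B = 1, Spo0FP = 1),
              products = c(Spo0BP = 1, Spo0F = 1),
              orders = c(Spo0B = 1, Spo0FP = 1)),
    .reaction("tr5", "spo0A_transcription", "tr5.k1",
              products = c(spo0A_t = 1), modifiers = "Spo0AP",
              pars = c(k1 = "tr5.k1", k2 = "tr5.k2",
                       Kk1 = "tr5.Kk1", Kk2 = "tr5.Kk2")),
    .reaction("tl5", "mass_action", "tl5.k", products = c(Spo0A = 1),
              modifiers = "spo0A_t", orders = c(spo0A_t = 1)),
    .reaction("k9", "mass_action", "k9.k",
              reactants = c(Spo0A = 1, Spo0BP = 1),
              products = c(Spo0AP = 1, Spo0B = 1),
              orders = c(Spo0A = 1, Spo0BP = 1)),
    .reaction("k10", "mass_action", "k10.k", reactants = c(Spo0AP = 1),
              products = c(Spo0A = 1), orders = c(Spo0AP = 1)),
    .reaction("kBdeph", "mass_action", "kBdeph.k", reactants = c(Spo0BP = 1),
              products = c(Spo0B = 1), orders = c(Spo0BP = 1)),
    .reaction("tr6", "spoII_transcription", "tr6.k1",
              products = c(spoIIA_t = 1), modifiers = "Spo0AP",
              pars = c(k1 = "tr6.k1", k2 = "tr6.k2", Kk = "tr6.Kk")),
    .reaction("tl6A", "mass_action", "tl6A.k", products = c(AA = 1),
              modifiers = "spoIIA_t", orders = c(spoIIA_t = 1)),
    .reaction("tl6B", "mass_action", "tl6B.k", products = c(AB = 1),
              modifiers = "spoIIA_t", orders = c(spoIIA_t = 1)),
    .reaction("tl6C", "mass_action", "tl6C.k", products = c(AC = 1),
              modifiers = "spoIIA_t", orders = c(spoIIA_t = 1)),
    .reaction("tr7", "spoII_transcription", "tr7.k1",
              products = c(spoIIE_t = 1), modifiers = "Spo0AP",
              pars = c(k1 = "tr7.k1", k2 = "tr7.k2", Kk = "tr7.Kk")),
    .reaction("tl7", "mass_action", "tl7.k", products = c(IIE = 1),
              modifiers = "spoIIE_t", orders = c(spoIIE_t = 1)),
    .reaction("tr8", "spoII_transcription", "tr8.k1",
              products = c(spoIIG_t = 1), modifiers = "Spo0AP",
              pars = c(k1 = "tr8.k1", k2 = "tr8.k2", Kk = "tr8.Kk")),
    .reaction("tl8A", "mass_action", "tl8A.k", products = c(GA = 1),
              modifiers = "spoIIG_t", orders = c(spoIIG_t = 1)),
    .reaction("tl8B", "mass_action", "tl8B.k", products = c(GB = 1),
              modifiers = "spoIIG_t", orders = c(spoIIG_t = 1))
  )

  # one first-order degradation per form except the clamped inputs
  deg_forms <- setdiff(.spore_forms, .clamped_forms)
  deg_pars <- stats::setNames(
    ifelse(deg_forms %in% .transcript_forms, p[["d_mRNA"]], p[["d_prot"]]),
    paste0("deg_", deg_forms, ".k"))
  for (f in deg_forms) {
    key <- paste0("deg_", f, ".k")
    rx[[length(rx) + 1L]] <- .reaction(
      paste0("deg_", f), "mass_action", key,
      reactants = stats::setNames(1, f),
      orders = stats::setNames(1, f))
  }

  all_p <- c(p, deg_pars)
  stoich <- matrix(0, nrow = length(.spore_forms), ncol = length(rx),
                   dimnames = list(.spore_forms,
                                   vapply(rx, `[[`, "", "id")))
  for (j in seq_along(rx)) {
    r <- rx[[j]]
    if (!is.null(r$reactants))
      stoich[names(r$reactants), j] <- stoich[names(r$reactants), j] - r$reactants
    if (!is.null(r$products))
      stoich[names(r$products), j] <- stoich[names(r$products), j] + r$products
  }
  stopifnot(all(stoich[.clamped_forms, ] == 0))

  structure(list(forms = .spore_forms, reactions = rx,
                 params = all_p, stoich = stoich,
                 fast = .compile_rates(rx, names(all_p))),
            class = "spore_network")
}

# Precompute index tables for vectorized flux evaluation.  Mass-action and
# constant laws reduce to k * s[i1] * s[i2] with a trailing 1 as filler; the
# six Hill-type transcription laws are inlined by parameter index.
.compile_rates <- function(rx, pnames) {
  n_forms <- length(.spore_forms)
  filler <- n_forms + 1L
  kidx <- match(vapply(rx, `[[`, "", "k"), pnames)
  i1 <- rep(filler, length(rx))
  i2 <- rep(filler, length(rx))
  hill_rows <- integer(0)
  for (j in seq_along(rx)) {
    r <- rx[[j]]
    if (r$kind == "mass_action") {
      sp <- rep(names(r$orders), times = r$orders)
      i1[j] <- match(sp[1], .spore_forms)
      if (length(sp) >= 2) i2[j] <- match(sp[2], .spore_forms)
      stopifnot(length(sp) <= 2)
    } else if (r$kind != "constant") {
      hill_rows <- c(hill_rows, j)
    }
  }
  pidx <- function(key) match(key, pnames)
  list(kidx = kidx, i1 = i1, i2 = i2, hill_rows = hill_rows,
       hill_ids = vapply(rx[hill_rows], `[[`, "", "id"),
       iL = match("LacI", .spore_forms), iA = match("Spo0AP", .spore_forms),
       p = vapply(c("tr2.k1", "tr2.k2", "tr2.k3", "tr2.KL", "tr2.KS",
                    "tr3.k1", "tr3.k2", "tr3.KS",
                    "tr5.k1", "tr5.k2", "tr5.Kk1", "tr5.Kk2",
                    "tr6.k1", "tr6.k2", "tr6.Kk",
                    "tr7.k1", "tr7.k2", "tr7.Kk",
                    "tr8.k1", "tr8.k2", "tr8.Kk",
                    "n_rep", "n_fb", "n_spoII"), pidx, 1L))
}

#' Update parameters of a built network
#'
#' @param model a \code{spore_network}.
#' @param values named numeric vector; keys are the rate-law parameter ids
#'   (including materialized \code{deg_<form>.k} keys).  Setting
#'   \code{d_mRNA}/\code{d_prot} re-propagates the shared value to every
#'   transcript/protein degradation constant.
#' @return the updated model.
#' @export
set_parameters <- function(model, values) {
  stopifnot(inherits(model, "spore_network"))
  values <- unlist(values)
  unknown <- setdiff(names(values), names(model$params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  model$params[names(values)] <- as.numeric(values)
  if ("d_mRNA" %in% names(values))
    model$params[paste0("deg_", .transcript_forms, ".k")] <- values[["d_mRNA"]]
  if ("d_prot" %in% names(values))
    model$params[paste0("deg_", .protein_forms, ".k")] <- values[["d_prot"]]
  bad <- names(model$params)[!is.finite(model$params) | model$params < 0]
  if (length(bad))
    stop("negative or non-finite parameter(s): ", paste(bad, collapse = ", "))
  model
}

.hill <- function(x, K, n) {
  xn <- x^n
  xn / (K^n + xn)
}

#' Evaluate the flux of a single reaction
#'
#' Computes the reaction rate (nM/s) at a given state, using the exact
#' published mathematical forms: mass action, constant synthesis, and the
#' Hill-type transcription laws (LacI repression with Spo0A~P
#' fold-activation for \emph{kinA}; basal-plus-activation for \emph{spo0F};
#' the mixed repression/activation form for \emph{spo0A}; fourth-order
#' activation for the \emph{spoII} promoters).
#'
#' @param reaction a reaction from a \code{spore_network} (element of
#'   \code{model$reactions}).
#' @param state named nonnegative state vector over the 27 forms.
#' @param params the model's parameter vector (\code{model$params}).
#' @return a single nonnegative flux.
#' @export
evaluate_rate <- function(reaction, state, params) {
  used <- unique(c(names(reaction$orders), reaction$modifiers))
  if (length(used) && any(state[used] < 0))
    stop("negative concentration in state: ",
         paste(used[state[used] < 0], collapse = ", "))
  k <- params[[reaction$k]]
  switch(reaction$kind,
    constant = k,
    mass_action = k * prod(state[names(reaction$orders)]^reaction$orders),
    kinA_transcription = {
      pp <- params[reaction$pars]
      L <- state[["LacI"]]; A <- state[["Spo0AP"]]
      n_rep <- params[["n_rep"]]; n_fb <- params[["n_fb"]]
      rep_term <- pp[["tr2.k1"]] +
        pp[["tr2.k2"]] * pp[["tr2.KL"]]^n_rep /
          (pp[["tr2.KL"]]^n_rep + L^n_rep)
      rep_term * (1 + pp[["tr2.k3"]] * .hill(A, pp[["tr2.KS"]], n_fb))
    },
    hill_activation_basal = {
      pp <- params[reaction$pars]
      A <- state[["Spo0AP"]]
      pp[["tr3.k1"]] + pp[["tr3.k2"]] * .hill(A, pp[["tr3.KS"]],
                                              params[["n_fb"]])
    },
    spo0A_transcription = {
      pp <- params[reaction$pars]
      A <- state[["Spo0AP"]]
      pp[["tr5.k1"]] * pp[["tr5.Kk1"]] / (pp[["tr5.Kk1"]] + A) +
        pp[["tr5.k2"]] * .hill(A, pp[["tr5.Kk2"]], params[["n_fb"]])
    },
    spoII_transcription = {
      pp <- params[reaction$pars]
      A <- state[["Spo0AP"]]
      pp[[1L]] + pp[[2L]] * .hill(A, pp[[3L]], params[["n_spoII"]])
    },
    stop("unknown rate-law kind: ", reaction$kind)
  )
}

# all 55 fluxes at once; assumes state already validated nonnegative
.reaction_rates <- function(model, state) {
  p <- unname(model$params)
  f <- model$fast
  se <- c(unname(state), 1)
  v <- p[f$kidx] * se[f$i1] * se[f$i2]
  # inline Hill-type transcription laws (order: tr2, tr3, tr5, tr6, tr7, tr8)
  pp <- p[f$p]
  L <- se[f$iL]; A <- se[f$iA]
  n_rep <- pp[22]; n_fb <- pp[23]; n_spoII <- pp[24]
  A_fb <- A^n_fb
  h <- f$hill_rows
  v[h[1]] <- (pp[1] + pp[2] * pp[4]^n_rep / (pp[4]^n_rep + L^n_rep)) *
    (1 + pp[3] * A_fb / (pp[5]^n_fb + A_fb))
  v[h[2]] <- pp[6] + pp[7] * A_fb / (pp[8]^n_fb + A_fb)
  v[h[3]] <- pp[9] * pp[11] / (pp[11] + A) +
    pp[10] * A_fb / (pp[12]^n_fb + A_fb)
  A_sp <- A^n_spoII
  v[h[4]] <- pp[13] + pp[14] * A_sp / (pp[15]^n_spoII + A_sp)
  v[h[5]] <- pp[16] + pp[17] * A_sp / (pp[18]^n_spoII + A_sp)
  v[h[6]] <- pp[19] + pp[20] * A_sp / (pp[21]^n_spoII + A_sp)
  v
}

#' Time derivatives of every form
#'
#' Sums stoichiometry-weighted reaction fluxes.  The clamped boundary inputs
#' IPTG and SS have identically zero derivatives (they enter rate laws only
#' as modifiers).
#'
#' @param model a \code{spore_network}.
#' @param state named state vector over the 27 forms (nM).
#' @return named numeric vector of d(concentration)/dt (nM/s).
#' @export
time_derivatives <- function(model, state) {
  state <- state[model$forms]
  if (any(state < 0))
    stop("negative concentration in state: ",
         paste(model$forms[state < 0], collapse = ", "))
  drop(model$stoich %*% .reaction_rates(model, state))
}

#' @export
print.spore_network <- function(x, ...) {
  cat("<spore_network> ", length(x$forms), " forms, ",
      length(x$reactions), " unidirectional reactions\n", sep = "")
  cat("  clamped inputs: IPTG (scale ", x$params[["IPTG.scale"]],
      " nM per axis unit), SS (nominal ", x$params[["SS_in"]], ")\n", sep = "")
  invisible(x)
}
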
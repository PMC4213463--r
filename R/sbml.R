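# SBML Level 3 export/import.  The exporter writes one compartment, the 27
# species (IPTG and SS flagged as boundary conditions), the full flat
# parameter table, and the 55 reactions with their kinetic laws as MathML.
# The importer reads the species/parameter/reaction lists back and
# reconstructs the network; rate-law kinds are identified by the exporter's
# reaction ids (this importer targets the model dialect written by
# write_sbml(), not arbitrary SBML).

.sbml_id <- function(key) gsub(".", "_dot_", key, fixed = TRUE)
.sbml_unid <- function(id) gsub("_dot_", ".", id, fixed = TRUE)

.mm <- list(
  ci = function(x) paste0("<ci> ", x, " </ci>"),
  cn = function(v) paste0("<cn> ", format(v, digits = 17), " </cn>"),
  ap = function(op, ...) paste0("<apply><", op, "/>",
                                paste0(..., collapse = ""), "</apply>")
)

.mm_pow <- function(base, n) .mm$ap("power", base, .mm$cn(n))
.mm_hill <- function(x_ci, K_ci, n) {
  # x^n / (K^n + x^n)
  .mm$ap("divide", .mm_pow(x_ci, n),
         .mm$ap("plus", .mm_pow(K_ci, n), .mm_pow(x_ci, n)))
}

.reaction_mathml <- function(r, params) {
  ci <- .mm$ci
  kid <- ci(.sbml_id(r$k))
  switch(r$kind,
    constant = kid,
    mass_action = {
      terms <- vapply(seq_along(r$orders), function(i) {
        s <- ci(names(r$orders)[i])
        if (r$orders[i] == 1) s else .mm_pow(s, r$orders[i])
      }, "")
      .mm$ap("times", kid, paste0(terms, collapse = ""))
    },
    kinA_transcription = {
      n_rep <- params[["n_rep"]]; n_fb <- params[["n_fb"]]
      KL <- ci(.sbml_id("tr2.KL")); KS <- ci(.sbml_id("tr2.KS"))
      rep_term <- .mm$ap("plus", ci(.sbml_id("tr2.k1")),
        .mm$ap("times", ci(.sbml_id("tr2.k2")),
               .mm$ap("divide", .mm_pow(KL, n_rep),
                      .mm$ap("plus", .mm_pow(KL, n_rep),
                             .mm_pow(ci("LacI"), n_rep)))))
      fb_term <- .mm$ap("plus", .mm$cn(1),
        .mm$ap("times", ci(.sbml_id("tr2.k3")),
               .mm_hill(ci("Spo0AP"), KS, n_fb)))
      .mm$ap("times", rep_term, fb_term)
    },
    hill_activation_basal = {
      .mm$ap("plus", ci(.sbml_id("tr3.k1")),
             .mm$ap("times", ci(.sbml_id("tr3.k2")),
                    .mm_hill(ci("Spo0AP"), ci(.sbml_id("tr3.KS")),
                             params[["n_fb"]])))
    },
    spo0A_transcription = {
      Kk1 <- ci(.sbml_id("tr5.Kk1"))
      .mm$ap("plus",
             .mm$ap("times", ci(.sbml_id("tr5.k1")),
                    .mm$ap("divide", Kk1,
                           .mm$ap("plus", Kk1, ci("Spo0AP")))),
             .mm$ap("times", ci(.sbml_id("tr5.k2")),
                    .mm_hill(ci("Spo0AP"), ci(.sbml_id("tr5.Kk2")),
                             params[["n_fb"]])))
    },
    spoII_transcription = {
      pk <- names(r$pars)
      .mm$ap("plus", ci(.sbml_id(r$pars[["k1"]])),
             .mm$ap("times", ci(.sbml_id(r$pars[["k2"]])),
                    .mm_hill(ci("Spo0AP"), ci(.sbml_id(r$pars[["Kk"]])),
                             params[["n_spoII"]])))
    },
    stop("unknown rate-law kind: ", r$kind)
  )
}

#' Export a network to SBML
#'
#' Writes an SBML Level 3 Version 1 document with one compartment, the 27
#' species (boundary-condition flags on IPTG and SS), all rate constants as
#' global parameters, and the 55 unidirectional reactions with MathML
#' kinetic laws.  Parameter keys containing \code{.} are encoded as
#' \code{_dot_} in SBML ids.
#'
#' @param model a \code{spore_network}.
#' @param path output file path.
#' @param initial optional named state written as species initial
#'   concentrations (default: all zero, clamps at their nominal inputs).
#' @return invisibly, \code{path}.
#' @seealso [read_sbml()]
#' @export
write_sbml <- function(model, path, initial = NULL) {
  stopifnot(inherits(model, "spore_network"))
  st <- spore_state(initial)
  if (is.null(initial)) {
    st[["IPTG"]] <- model$params[["IPTG_in"]] * model$params[["IPTG.scale"]]
    st[["SS"]] <- model$params[["SS_in"]]
  }
  num <- function(v) format(v, digits = 17)

  species_xml <- vapply(model$forms, function(f) {
    paste0('<species id="', f, '" compartment="cell"',
           ' initialConcentration="', num(st[[f]]), '"',
           ' hasOnlySubstanceUnits="false"',
           ' boundaryCondition="',
           if (f %in% .clamped_forms) "true" else "false", '"',
           ' constant="false"/>')
  }, "")

  params_xml <- vapply(names(model$params), function(k) {
    paste0('<parameter id="', .sbml_id(k), '" value="',
           num(model$params[[k]]), '" constant="true"/>')
  }, "")

  sref <- function(tag, stoich) {
    if (is.null(stoich) || !length(stoich)) return("")
    inner <- vapply(seq_along(stoich), function(i)
      paste0('<speciesReference species="', names(stoich)[i],
             '" stoichiometry="', stoich[i], '" constant="true"/>'), "")
    paste0("<listOf", tag, "s>", paste0(inner, collapse = ""),
           "</listOf", tag, "s>")
  }
  mref <- function(mods) {
    if (!length(mods)) return("")
    inner <- vapply(mods, function(m)
      paste0('<modifierSpeciesReference species="', m, '"/>'), "")
    paste0("<listOfModifiers>", paste0(inner, collapse = ""),
           "</listOfModifiers>")
  }

  reactions_xml <- vapply(model$reactions, function(r) {
    # modifiers that enter the rate law but are neither reactants nor products
    law_species <- setdiff(unique(c(names(r$orders), r$modifiers)),
                           c(names(r$reactants), names(r$products)))
    paste0('<reaction id="', r$id, '" reversible="false">',
           sref("Reactant", r$reactants),
           sref("Product", r$products),
           mref(law_species),
           '<kineticLaw>',
           '<math xmlns="http://www.w3.org/1998/Math/MathML">',
           .reaction_mathml(r, model$params),
           '</math></kineticLaw></reaction>')
  }, "")

  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'level="3" version="1">\n',
    '<model id="sporulation_initiation" name="B. subtilis sporulation initiation network">\n',
    '<listOfCompartments>',
    '<compartment id="cell" spatialDimensions="3" size="1" constant="true"/>',
    '</listOfCompartments>\n',
    '<listOfSpecies>', paste0(species_xml, collapse = ""), '</listOfSpecies>\n',
    '<listOfParameters>', paste0(params_xml, collapse = ""),
    '</listOfParameters>\n',
    '<listOfReactions>', paste0(reactions_xml, collapse = ""),
    '</listOfReactions>\n',
    '</model>\n</sbml>\n')
  # validate well-formedness before writing
  xml2::read_xml(doc)
  writeLines(doc, path)
  invisible(path)
}

#' Import a network from SBML
#'
#' Reads an SBML file written by [write_sbml()] and reconstructs the
#' \code{spore_network}: species and boundary flags are checked against the
#' reference inventory, global parameter values are read back (including the
#' per-form degradation constants), and rate laws are re-attached by
#' reaction id.  Round-tripping preserves parameter values to full double
#' precision, so simulations of the re-imported model match the original to
#' well below 1e-9 relative.
#'
#' @param path SBML file path.
#' @return a \code{spore_network}.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  ids <- xml2::xml_attr(sp, "id")
  if (!setequal(ids, .spore_forms))
    stop("species do not match the 27-form reference inventory")
  boundary <- ids[xml2::xml_attr(sp, "boundaryCondition") == "true"]
  if (!setequal(boundary, .clamped_forms))
    stop("boundary-condition flags must mark exactly IPTG and SS")

  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  keys <- .sbml_unid(xml2::xml_attr(par_nodes, "id"))
  vals <- as.numeric(xml2::xml_attr(par_nodes, "value"))
  names(vals) <- keys

  base_keys <- names(spore_parameters())
  missing <- setdiff(base_keys, keys)
  if (length(missing))
    stop("missing parameter(s) in SBML: ", paste(missing, collapse = ", "))
  params <- spore_parameters(vals[base_keys])
  model <- build_reference_network(params)

  deg_keys <- intersect(names(model$params), setdiff(keys, base_keys))
  if (length(deg_keys))
    model <- set_parameters(model, vals[deg_keys])

  rx_ids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//listOfReactions/reaction"),
                           "id")
  expected <- vapply(model$reactions, `[[`, "", "id")
  if (!setequal(rx_ids, expected))
    stop("reaction inventory does not match the reference network")
  model
}
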
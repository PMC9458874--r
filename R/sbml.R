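# SBML Level 3 export of the reaction network, and a reader for the exported
# dialect (irreversible mass-action kinetic laws of the form k * A [* B]).
# Clamped species are marked boundaryCondition; units are hours and uM.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

# Elementary (irreversible) flux view of the reaction table.
.elementary_fluxes <- function(model) {
  rows <- list()
  for (r in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[r, ]
    if (rx$scale == 0) next
    rows[[length(rows) + 1L]] <-
      list(id = rx$id, param = rx$forward_param,
           reactants = rx$reactants[[1]], products = rx$products[[1]])
    if (!is.na(rx$reverse_param)) {
      rows[[length(rows) + 1L]] <-
        list(id = paste0(rx$id, "_rev"), param = rx$reverse_param,
             reactants = rx$products[[1]], products = rx$reactants[[1]])
    }
  }
  rows
}

#' Export a model as SBML Level 3
#'
#' Species carry initial concentrations in uM (clamped species are flagged
#' `boundaryCondition`), global parameters carry the internal per-hour unit
#' system, and every elementary flux becomes an irreversible reaction with a
#' mass-action kinetic law. The exported dialect round-trips through
#' [read_sbml()] with identical simulation output.
#'
#' @param model An `aba_model`.
#' @param path Optional file path; when given the document is written there.
#' @return An `xml2::xml_document`, invisibly if `path` is given.
#' @export
export_sbml <- function(model, path = NULL) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3",
                            version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = "aba_rd29a",
                             name = "ABA-dependent RD29A expression",
                             timeUnits = "hour")

  uds <- xml2::xml_add_child(mdl, "listOfUnitDefinitions")
  add_unit <- function(id, kinds, exps, mults, scales) {
    ud <- xml2::xml_add_child(uds, "unitDefinition", id = id)
    lu <- xml2::xml_add_child(ud, "listOfUnits")
    for (i in seq_along(kinds)) {
      xml2::xml_add_child(lu, "unit", kind = kinds[i],
                          exponent = as.character(exps[i]),
                          scale = as.character(scales[i]),
                          multiplier = as.character(mults[i]))
    }
  }
  add_unit("hour", "second", 1, 3600, 0)
  add_unit("micromolar", c("mole", "litre"), c(1, -1), c(1, 1), c(-6, 0))
  add_unit("per_hour", "second", -1, 1 / 3600, 0)
  add_unit("per_micromolar_per_hour", c("mole", "litre", "second"),
           c(-1, 1, -1), c(1, 1, 1 / 3600), c(6, 0, 0))

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "cell",
                      spatialDimensions = "3",
                      size = as.character(model$cell_volume * 1e-15),
                      units = "litre", constant = "true")

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    xml2::xml_add_child(
      ls, "species", id = s$name, compartment = "cell",
      initialConcentration = as.character(s$initial_concentration),
      substanceUnits = "micromolar", hasOnlySubstanceUnits = "false",
      boundaryCondition = if (s$clamped) "true" else "false",
      constant = "false")
  }

  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_len(nrow(model$parameters))) {
    p <- model$parameters[i, ]
    xml2::xml_add_child(
      lp, "parameter", id = p$name, value = as.character(p$value),
      units = if (p$unit == "h^-1") "per_hour" else "per_micromolar_per_hour",
      constant = "true")
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (fl in .elementary_fluxes(model)) {
    rn <- xml2::xml_add_child(lr, "reaction", id = fl$id,
                              reversible = "false")
    if (length(fl$reactants) > 0) {
      lrr <- xml2::xml_add_child(rn, "listOfReactants")
      for (nm in names(fl$reactants)) {
        xml2::xml_add_child(lrr, "speciesReference", species = nm,
                            stoichiometry = as.character(fl$reactants[[nm]]),
                            constant = "true")
      }
    }
    if (length(fl$products) > 0) {
      lpp <- xml2::xml_add_child(rn, "listOfProducts")
      for (nm in names(fl$products)) {
        xml2::xml_add_child(lpp, "speciesReference", species = nm,
                            stoichiometry = as.character(fl$products[[nm]]),
                            constant = "true")
      }
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    xml2::xml_add_child(ap, "ci", fl$param)
    for (nm in rep(names(fl$reactants), times = fl$reactants)) {
      xml2::xml_add_child(ap, "ci", nm)
    }
  }

  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Read a model from the exported SBML dialect
#'
#' Reconstructs species (with clamps and initial concentrations), the
#' parameter table, and the elementary mass-action reactions from a document
#' written by [export_sbml()]. The returned model simulates identically to
#' the exported one.
#'
#' @param path SBML file path or an `xml2::xml_document`.
#' @return An `aba_model`.
#' @export
read_sbml <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  doc <- xml2::xml_ns_strip(doc)

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  species <- tibble::tibble(
    name = xml2::xml_attr(sp_nodes, "id"),
    role = "imported",
    clamped = xml2::xml_attr(sp_nodes, "boundaryCondition") == "true",
    initial_concentration =
      as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration")))

  p_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  parameters <- tibble::tibble(
    name = xml2::xml_attr(p_nodes, "id"),
    value = as.numeric(xml2::xml_attr(p_nodes, "value")),
    unit = ifelse(xml2::xml_attr(p_nodes, "units") == "per_hour",
                  "h^-1", "uM^-1 h^-1"),
    fixed = TRUE, description = "imported from SBML")

  r_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  stoich_of <- function(node, what) {
    refs <- xml2::xml_find_all(node, paste0("./", what, "/speciesReference"))
    stats::setNames(as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                    xml2::xml_attr(refs, "species"))
  }
  rows <- lapply(r_nodes, function(node) {
    cis <- xml2::xml_text(xml2::xml_find_all(node, ".//kineticLaw//ci"))
    param <- intersect(cis, parameters$name)[1]
    if (is.na(param)) {
      stop("kinetic law of reaction ", xml2::xml_attr(node, "id"),
           " names no known parameter", call. = FALSE)
    }
    tibble::tibble(id = xml2::xml_attr(node, "id"), kind = "imported",
                   reactants = list(stoich_of(node, "listOfReactants")),
                   products = list(stoich_of(node, "listOfProducts")),
                   forward_param = param, reverse_param = NA_character_,
                   gene = NA_character_, scale = 1)
  })
  comp <- xml2::xml_find_first(doc, ".//listOfCompartments/compartment")
  vol <- as.numeric(xml2::xml_attr(comp, "size")) / 1e-15

  model <- structure(
    list(species = species, reactions = dplyr::bind_rows(rows),
         parameters = parameters, cell_volume = vol, gene_copies = NA),
    class = "aba_model")
  model$compiled <- .compile_model(model)
  model
}
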
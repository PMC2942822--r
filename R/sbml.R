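#' Export the linear tracer model as SBML Level 3
#'
#' One-way export of the compartment model: one species per body
#' compartment (plus a boundary species for the external sink), one
#' global parameter per clearance constant, and one irreversible
#' first-order reaction per edge with mass-action kinetic law
#' `k * source`. Round-trip import is not supported.
#'
#' @param topology An `fk_topology`.
#' @param rates Named rate constants (1/day).
#' @param path Output file path (`.xml`).
#' @param model_id SBML model id.
#' @return The path, invisibly.
#' @export
write_sbml <- function(topology, rates, path,
                       model_id = "whole_body_ferrokinetics") {
  rates <- validate_rates(rates, topology)
  sbml_ns <- "http://www.sbml.org/sbml/level3/version2/core"
  mathml_ns <- "http://www.w3.org/1998/Math/MathML"
  doc <- xml2::xml_new_root("sbml", xmlns = sbml_ns,
                            level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = model_id,
                               substanceUnits = "item",
                               timeUnits = "second")
  locomp <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(locomp, "compartment", id = "body", size = "1",
                      constant = "true")
  losp <- xml2::xml_add_child(model, "listOfSpecies")
  for (c in topology$compartments) {
    xml2::xml_add_child(losp, "species", id = c, compartment = "body",
                        initialAmount = if (c == topology$central) "100"
                                        else "0",
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = "false", constant = "false")
  }
  xml2::xml_add_child(losp, "species", id = EXTERNAL,
                      compartment = "body", initialAmount = "0",
                      hasOnlySubstanceUnits = "true",
                      boundaryCondition = "true", constant = "false")
  lopar <- xml2::xml_add_child(model, "listOfParameters")
  for (p in names(rates)) {
    xml2::xml_add_child(lopar, "parameter", id = p,
                        value = format(rates[[p]], digits = 15),
                        constant = "true")
  }
  lorx <- xml2::xml_add_child(model, "listOfReactions")
  for (e in seq_len(nrow(topology$edges))) {
    src <- topology$edges$source[e]
    tgt <- topology$edges$target[e]
    par <- topology$edges$param[e]
    rx <- xml2::xml_add_child(lorx, "reaction",
                              id = paste0("J_", par),
                              reversible = "false")
    lr <- xml2::xml_add_child(rx, "listOfReactants")
    xml2::xml_add_child(lr, "speciesReference", species = src,
                        stoichiometry = "1", constant = "true")
    lp <- xml2::xml_add_child(rx, "listOfProducts")
    xml2::xml_add_child(lp, "speciesReference", species = tgt,
                        stoichiometry = "1", constant = "true")
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = mathml_ns)
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    xml2::xml_add_child(ap, "ci", par)
    xml2::xml_add_child(ap, "ci", src)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
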
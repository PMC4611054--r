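# SBML Level 3 export/import of the compartmental models, written directly
# over xml2. Kinetic laws are emitted as content MathML (including tanh;
# the capacity clamp max(0, x) is encoded as a piecewise). Import recovers
# species, parameters and reaction ids, enough for a faithful write->read
# round trip of the model's quantitative content.

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

# -- tiny content-MathML builders (strings) -------------------------------
mml_ci <- function(x) paste0("<ci> ", x, " </ci>")
mml_cn <- function(v) paste0("<cn> ", format(v, digits = 17), " </cn>")
mml_apply <- function(op, ...) paste0("<apply><", op, "/>",
                                      paste0(..., collapse = ""), "</apply>")
mml_times <- function(...) mml_apply("times", c(...))
mml_plus <- function(...) mml_apply("plus", c(...))
mml_minus <- function(a, b) mml_apply("minus", c(a, b))
mml_divide <- function(a, b) mml_apply("divide", c(a, b))
mml_power <- function(a, b) mml_apply("power", c(a, b))
mml_tanh <- function(a) mml_apply("tanh", a)
# max(0, a) as a piecewise
mml_max0 <- function(a) paste0(
  "<piecewise><piece>", a,
  "<apply><gt/>", a, mml_cn(0), "</apply></piece>",
  "<otherwise>", mml_cn(0), "</otherwise></piecewise>")
mml_math <- function(body) paste0('<math xmlns="', MATHML_NS, '">',
                                  body, "</math>")

# regulated transport factor enh/inh as MathML (shared by several laws)
sbml_transport_factor <- function(model) {
  enh <- if (model$enhancer_location != "none")
    mml_plus(mml_cn(1), mml_divide(
      mml_times(mml_ci("Xenh"), mml_plus(mml_ci("EregS"), mml_ci("EregP"))),
      mml_ci("E0"))) else mml_cn(1)
  inh <- if (model$inhibitor_location != "none")
    mml_plus(mml_cn(1), mml_divide(
      mml_times(mml_ci("Yinh"), mml_plus(mml_ci("IS"), mml_ci("IP"))),
      mml_ci("I0"))) else mml_cn(1)
  mml_divide(enh, inh)
}

sbml_vhydr_math <- function() {
  num_occ <- function(sp) mml_divide(mml_power(mml_ci(sp), mml_ci("na")),
                                     mml_ci(paste0("Ka", substr(sp, 1, 1))))
  x <- mml_plus(
    mml_cn(1),
    mml_divide(mml_power(mml_ci("S"), mml_ci("na")), mml_ci("KaS")),
    mml_divide(mml_power(mml_ci("S"), mml_ci("ni")), mml_ci("KiS")),
    mml_divide(mml_power(mml_ci("P"), mml_ci("na")), mml_ci("KaP")),
    mml_divide(mml_power(mml_ci("P"), mml_ci("ni")), mml_ci("KiP")),
    mml_divide(mml_power(mml_ci("S"), mml_plus(mml_ci("na"), mml_ci("ni"))),
               mml_times(mml_ci("alpha"), mml_ci("KaS"), mml_ci("KiS"))),
    mml_divide(mml_power(mml_ci("P"), mml_plus(mml_ci("na"), mml_ci("ni"))),
               mml_times(mml_ci("alpha"), mml_ci("KaP"), mml_ci("KiP"))),
    mml_divide(mml_times(mml_power(mml_ci("S"), mml_ci("na")),
                         mml_power(mml_ci("P"), mml_ci("ni"))),
               mml_times(mml_ci("alpha"), mml_ci("KaS"), mml_ci("KiP"))),
    mml_divide(mml_times(mml_power(mml_ci("S"), mml_ci("ni")),
                         mml_power(mml_ci("P"), mml_ci("na"))),
               mml_times(mml_ci("alpha"), mml_ci("KiS"), mml_ci("KaP"))))
  numer <- mml_times(
    mml_ci("na"), mml_ci("kp"), mml_ci("E0"), num_occ("S"),
    mml_plus(mml_cn(1),
             mml_divide(mml_times(mml_ci("beta"),
                                  mml_power(mml_ci("S"), mml_ci("ni"))),
                        mml_times(mml_ci("alpha"), mml_ci("KiS"))),
             mml_divide(mml_times(mml_ci("beta"),
                                  mml_power(mml_ci("P"), mml_ci("ni"))),
                        mml_times(mml_ci("alpha"), mml_ci("KiP")))))
  mml_math(mml_divide(numer, x))
}

sbml_reactions <- function(model, params) {
  tf <- sbml_transport_factor(model)
  cap <- mml_tanh(mml_max0(mml_minus(
    mml_times(mml_ci("E0"), mml_ci("Ccap")),
    mml_plus(mml_ci("S"), mml_ci("P")))))
  rx <- list()
  add <- function(id, reactants, products, math) {
    rx[[id]] <<- list(id = id, reactants = reactants, products = products,
                      math = math)
  }
  for (sp in c("S", "P")) {
    out <- paste0(sp, "out"); g1 <- paste0("G1", sp, "out")
    g2 <- paste0("G2", sp)
    add(paste0("gate_bind_", sp), c(out, "G1"), g1,
        mml_math(mml_times(mml_ci("kon"), mml_ci(out), mml_ci("G1"))))
    add(paste0("gate_unbind_", sp), g1, c(out, "G1"),
        mml_math(mml_times(mml_ci("koff"), mml_ci(g1))))
    add(paste0("influx_", sp), g1, c(sp, "G1"),
        mml_math(mml_times(mml_ci("vin"), tf, cap, mml_ci(g1))))
    add(paste0("translocation_", sp), c(sp, "G2"), g2,
        mml_math(mml_divide(mml_times(mml_ci("tau"), mml_ci(sp),
                                      mml_ci("G2")), mml_ci("E0"))))
    add(paste0("efflux_", sp), g2, c(out, "G2"),
        mml_math(mml_times(mml_ci("vout"), tf, mml_ci(g2))))
  }
  add("hydrolysis", "S", "P", sbml_vhydr_math())
  if (model$enhancer_location != "none") {
    tgt <- if (model$enhancer_location == "inside") c("S", "P") else
      c("Sout", "Pout")
    for (i in 1:2) {
      sp <- c("S", "P")[i]
      add(paste0("enhancer_bind_", sp), c(tgt[i], "Ereg"),
          paste0("Ereg", sp),
          mml_math(mml_divide(mml_times(mml_ci("Ron"), mml_ci(tgt[i]),
                                        mml_ci("Ereg")), mml_ci("E0"))))
      add(paste0("enhancer_unbind_", sp), paste0("Ereg", sp),
          c(tgt[i], "Ereg"),
          mml_math(mml_times(mml_ci("Roff"), mml_ci(paste0("Ereg", sp)))))
    }
  }
  if (model$inhibitor_location != "none") {
    tgt <- if (model$inhibitor_location == "outside") c("Sout", "Pout") else
      c("S", "P")
    for (i in 1:2) {
      sp <- c("S", "P")[i]
      add(paste0("inhibitor_bind_", sp),
          stats::setNames(c("Ifree", tgt[i]), c("", "stoich_h")),
          paste0("I", sp),
          mml_math(mml_times(mml_ci("Ion"),
                             mml_power(mml_ci(tgt[i]), mml_ci("h")),
                             mml_ci("Ifree"))))
      add(paste0("inhibitor_unbind_", sp), paste0("I", sp),
          stats::setNames(c("Ifree", tgt[i]), c("", "stoich_h")),
          mml_math(mml_times(mml_ci("Ioff"), mml_ci(paste0("I", sp)))))
    }
  }
  rx
}

#' Export a compartmental model as SBML Level 3
#'
#' Writes the model's species (with initial concentrations for the given
#' substrate dose), parameters and reactions -- kinetic laws as content
#' MathML, including the `tanh` capacity saturation -- as an SBML Level 3
#' Version 2 document. Only the compartmental models M5-M9 are exported
#' (the non-compartmental rate laws are not reaction networks) unless
#' `force = TRUE`.
#'
#' The capacity parameter is exported under the id `Ccap` (`C` is not a
#' valid distinguishable id in this context); import maps it back.
#'
#' @param model a compartmental `proteodyn_model`.
#' @param params a [parameter_set()].
#' @param path output file.
#' @param S0 initial substrate concentration (uM); default 0.
#' @param force allow non-compartmental export attempts to proceed.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, params, path, S0 = 0, force = FALSE) {
  if (!model$compartmentalised && !force)
    stop("SBML export covers the compartmental models M5-M9")
  y0 <- initial_state(model, S0, params)
  inner <- c("S", "P", "G2", "G2S", "G2P")
  if (model$enhancer_location == "inside")
    inner <- c(inner, "Ereg", "EregS", "EregP")
  used_pars <- setdiff(model$parameters, character(0))
  rx <- sbml_reactions(model, params)

  species_xml <- paste0(vapply(model$species, function(sp) {
    comp <- if (sp %in% inner) "chamber" else "outside"
    sprintf(paste0('<species id="%s" compartment="%s" ',
                   'initialConcentration="%.17g" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                   'constant="false"/>'), sp, comp, y0[[sp]])
  }, character(1)), collapse = "\n      ")

  par_id <- function(nm) if (nm == "C") "Ccap" else nm
  params_xml <- paste0(vapply(used_pars, function(nm) {
    sprintf('<parameter id="%s" value="%.17g" constant="true"/>',
            par_id(nm), params[[nm]])
  }, character(1)), collapse = "\n      ")

  ref <- function(sp) {
    stoich <- if (identical(names(sp), "stoich_h")) params[["h"]] else 1
    sprintf('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
            sp, stoich)
  }
  reactions_xml <- paste0(vapply(rx, function(r) {
    reac <- paste0(vapply(seq_along(r$reactants), function(i)
      ref(stats::setNames(r$reactants[i], names(r$reactants)[i])),
      character(1)), collapse = "")
    prod <- paste0(vapply(seq_along(r$products), function(i)
      ref(stats::setNames(r$products[i], names(r$products)[i])),
      character(1)), collapse = "")
    paste0('<reaction id="', r$id, '" reversible="false">',
           "<listOfReactants>", reac, "</listOfReactants>",
           "<listOfProducts>", prod, "</listOfProducts>",
           "<kineticLaw>", r$math, "</kineticLaw></reaction>")
  }, character(1)), collapse = "\n      ")

  doc <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="%s" level="3" version="2">
  <model id="%s" name="proteasome kinetic model %s" substanceUnits="micromole" timeUnits="minute">
    <listOfCompartments>
      <compartment id="outside" spatialDimensions="3" size="1" constant="true"/>
      <compartment id="chamber" spatialDimensions="3" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      %s
    </listOfSpecies>
    <listOfParameters>
      %s
    </listOfParameters>
    <listOfReactions>
      %s
    </listOfReactions>
  </model>
</sbml>', SBML_NS, model$model_id, model$model_id, species_xml, params_xml,
    reactions_xml)
  # parse/serialise through xml2 so the written file is well-formed XML
  xml2::write_xml(xml2::read_xml(doc), path)
  invisible(path)
}

#' Import an SBML document written by [write_sbml()]
#'
#' @param path SBML file.
#' @return list with `model_id`, `species` (named initial concentrations),
#'   `parameters` (named values, `Ccap` mapped back to `C`), `reactions`
#'   (ids).
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS)
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mod, "xml_missing")) stop("not an SBML level 3 document")
  sp_nodes <- xml2::xml_find_all(doc, ".//s:species", ns)
  species <- stats::setNames(
    as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration")),
    xml2::xml_attr(sp_nodes, "id"))
  par_nodes <- xml2::xml_find_all(doc, ".//s:parameter", ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))
  names(pars)[names(pars) == "Ccap"] <- "C"
  rx <- xml2::xml_attr(xml2::xml_find_all(doc, ".//s:reaction", ns), "id")
  list(model_id = xml2::xml_attr(mod, "id"), species = species,
       parameters = pars, reactions = rx)
}

#' Structural validation of an SBML Level 3 document
#'
#' Checks well-formedness, the SBML namespace and level/version
#' attributes, presence of the compartment/species/parameter/reaction
#' sections, that every species reference inside a reaction points to a
#' declared species, and that every `ci` symbol in a kinetic law is a
#' declared species, parameter or compartment.
#'
#' @param path SBML file.
#' @return `TRUE` if valid, otherwise a character vector of issues.
#' @export
sbml_validate <- function(path) {
  issues <- character(0)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) e)
  if (inherits(doc, "error")) return(paste("not well-formed XML:",
                                           conditionMessage(doc)))
  root <- xml2::xml_name(doc)
  if (root != "sbml") issues <- c(issues, "root element is not <sbml>")
  if (!identical(xml2::xml_attr(doc, "level"), "3"))
    issues <- c(issues, "not SBML level 3")
  ns <- c(s = SBML_NS)
  for (sec in c("listOfCompartments", "listOfSpecies", "listOfReactions"))
    if (length(xml2::xml_find_all(doc, paste0(".//s:", sec), ns)) == 0)
      issues <- c(issues, paste("missing", sec))
  sp <- xml2::xml_attr(xml2::xml_find_all(doc, ".//s:species", ns), "id")
  refs <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:speciesReference", ns), "species")
  bad <- setdiff(refs, sp)
  if (length(bad))
    issues <- c(issues, paste("undeclared species referenced:",
                              paste(bad, collapse = ", ")))
  pars <- xml2::xml_attr(xml2::xml_find_all(doc, ".//s:parameter", ns), "id")
  comps <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:compartment", ns), "id")
  ci <- trimws(xml2::xml_text(
    xml2::xml_find_all(doc, ".//m:ci", c(m = MATHML_NS))))
  bad <- setdiff(unique(ci), c(sp, pars, comps))
  if (length(bad))
    issues <- c(issues, paste("undeclared symbols in kinetic laws:",
                              paste(bad, collapse = ", ")))
  if (length(issues)) issues else TRUE
}
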
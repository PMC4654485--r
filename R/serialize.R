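## Model serialisation: a structured YAML document (the package's native
## format) and an SBML Level 3 export/import written on top of xml2.
## Both round-trip the canonical model losslessly.

#' Write a model as structured YAML
#'
#' One document holding compartments, species with initial concentrations
#' (uM), the parameter registry with units and provenance, and every
#' reaction with its rate-law kind and parameter bindings.
#'
#' @param model A `hifmir_model`.
#' @param path Output file.
#' @export
write_model_yaml <- function(model, path) {
  rx <- lapply(model$reactions, function(r) {
    list(id = r$id, description = r$description, group = r$group,
         reactants = as.list(stats::setNames(r$reactants$coef,
                                             r$reactants$species)),
         products = as.list(stats::setNames(r$products$coef,
                                            r$products$species)),
         modifiers = as.list(r$modifiers),
         rate = list(kind = r$rate$kind,
                     params = as.list(r$rate$params),
                     species = as.list(r$rate$species),
                     reverse_species = as.list(r$rate$reverse_species),
                     enzyme = r$rate$enzyme,
                     activator = r$rate$activator))
  })
  doc <- list(
    name = model$name,
    clamped = as.list(model$clamped),
    compartments = lapply(seq_len(nrow(model$compartments)), function(i)
      as.list(model$compartments[i, ])),
    species = lapply(seq_len(nrow(model$species)), function(i)
      as.list(model$species[i, ])),
    parameters = lapply(seq_len(nrow(model$parameters)), function(i)
      as.list(model$parameters[i, ])),
    reactions = rx)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a model from structured YAML
#'
#' @param path File written by [write_model_yaml()].
#' @return A `hifmir_model`.
#' @export
read_model_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  comps <- do.call(rbind, lapply(doc$compartments, function(x)
    compartment(x$id, x$label)))
  sp <- do.call(rbind, lapply(doc$species, function(x)
    species_def(x$id, x$compartment, x$role, x$initial, x$label)))
  pars <- do.call(rbind, lapply(doc$parameters, function(x)
    data.frame(id = x$id, value = x$value, units = x$units,
               provenance = x$provenance, stringsAsFactors = FALSE)))
  rxs <- lapply(doc$reactions, function(r) {
    law <- rate_law(r$rate$kind,
                    unlist(r$rate$params),
                    species = as.character(unlist(r$rate$species)),
                    reverse_species =
                      as.character(unlist(r$rate$reverse_species)),
                    enzyme = r$rate$enzyme,
                    activator = r$rate$activator)
    reaction(r$id,
             reactants = unlist(r$reactants) %||% numeric(),
             products = unlist(r$products) %||% numeric(),
             modifiers = as.character(unlist(r$modifiers)),
             rate = law, description = r$description, group = r$group)
  })
  hifmir_model(comps, sp, rxs, pars,
               clamped = as.character(unlist(doc$clamped)),
               name = doc$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- SBML Level 3 ---------------------------------------------------

.SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
.HIFMIR_NS <- "https://hifmir.r-pkg/annotation"

.mathml_rate <- function(r) {
  law <- r$rate
  ci <- function(x) sprintf("<ci> %s </ci>", x)
  times <- function(...) paste0("<apply><times/>", paste0(...),
                                "</apply>")
  prodn <- function(ids) {
    if (length(ids) == 0L) return("<cn> 1 </cn>")
    if (length(ids) == 1L) return(ci(ids))
    do.call(times, as.list(vapply(ids, ci, "")))
  }
  body <- switch(law$kind,
    mass_action_1 = ,
    mass_action_2 = times(ci(law$params[["k"]]), prodn(law$species)),
    mass_action_rev = sprintf(
      "<apply><minus/>%s%s</apply>",
      times(ci(law$params[["kf"]]), prodn(law$species)),
      times(ci(law$params[["kr"]]), prodn(law$reverse_species))),
    michaelis_menten = {
      s <- ci(law$species[1])
      vmax <- if (!is.null(law$enzyme)) {
        times(ci(law$params[["kcat"]]), ci(law$enzyme))
      } else ci(law$params[["Vm"]])
      if (!is.null(law$activator)) {
        vmax <- sprintf("<apply><plus/>%s%s</apply>", vmax,
                        times(ci(law$params[["kact"]]),
                              ci(law$activator)))
      }
      km <- ci(law$params[["Km"]])
      sprintf("<apply><divide/>%s<apply><plus/>%s%s</apply></apply>",
              times(vmax, s), km, s)
    },
    hill_activation = {
      x <- ci(law$species[1]); K <- ci(law$params[["K"]])
      n <- ci(law$params[["n"]])
      pw <- function(b) sprintf(
        "<apply><power/>%s%s</apply>", b, n)
      core <- sprintf(
        "<apply><divide/>%s<apply><plus/>%s%s</apply></apply>",
        times(ci(law$params[["Vm"]]), pw(x)), pw(K), pw(x))
      if ("k0" %in% names(law$params)) {
        sprintf("<apply><plus/>%s%s</apply>", ci(law$params[["k0"]]),
                core)
      } else core
    },
    hill_inhibition = {
      x <- ci(law$species[1]); K <- ci(law$params[["K"]])
      n <- ci(law$params[["n"]])
      pw <- function(b) sprintf("<apply><power/>%s%s</apply>", b, n)
      sprintf("<apply><divide/>%s<apply><plus/>%s%s</apply></apply>",
              times(ci(law$params[["Vm"]]), pw(K)), pw(K), pw(x))
    })
  sprintf("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">%s</math>",
          body)
}

#' Export a model as SBML Level 3
#'
#' Writes SBML L3v2 core: compartments, species (clamped species carry
#' `boundaryCondition="true"`), global parameters, and reactions with
#' MathML kinetic laws.  A compact annotation on each species and
#' reaction carries the package-specific fields (species role, reaction
#' group, rate-law descriptor) so that [read_sbml()] round-trips the
#' model losslessly.
#'
#' @param model A `hifmir_model`.
#' @param path Output file.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  out <- c(sprintf("<?xml version=\"1.0\" encoding=\"UTF-8\"?>"),
           sprintf("<sbml xmlns=\"%s\" level=\"3\" version=\"2\">",
                   .SBML_NS),
           sprintf("<model id=\"%s\" name=\"%s\" timeUnits=\"minute\">",
                   gsub("[^A-Za-z0-9_]", "_", model$name),
                   esc(model$name)))
  out <- c(out, "<listOfCompartments>")
  for (i in seq_len(nrow(model$compartments))) {
    out <- c(out, sprintf(
      "<compartment id=\"%s\" name=\"%s\" size=\"1\" constant=\"true\"/>",
      model$compartments$id[i], esc(model$compartments$label[i])))
  }
  out <- c(out, "</listOfCompartments>", "<listOfSpecies>")
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    out <- c(out, sprintf(paste0(
      "<species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
      "initialConcentration=\"%.15g\" hasOnlySubstanceUnits=\"false\" ",
      "boundaryCondition=\"%s\" constant=\"false\">",
      "<annotation><hifmir:role xmlns:hifmir=\"%s\">%s</hifmir:role>",
      "</annotation></species>"),
      s$id, esc(s$label), s$compartment, s$initial,
      tolower(s$id %in% model$clamped), .HIFMIR_NS, s$role))
  }
  out <- c(out, "</listOfSpecies>", "<listOfParameters>")
  for (i in seq_len(nrow(model$parameters))) {
    p <- model$parameters[i, ]
    out <- c(out, sprintf(paste0(
      "<parameter id=\"%s\" value=\"%.15g\" constant=\"true\">",
      "<annotation><hifmir:meta xmlns:hifmir=\"%s\" units=\"%s\" ",
      "provenance=\"%s\"/></annotation></parameter>"),
      p$id, p$value, .HIFMIR_NS, esc(p$units), p$provenance))
  }
  out <- c(out, "</listOfParameters>", "<listOfReactions>")
  for (r in model$reactions) {
    rev <- r$rate$kind == "mass_action_rev"
    out <- c(out, sprintf(
      "<reaction id=\"%s\" name=\"%s\" reversible=\"%s\">",
      r$id, esc(r$description), tolower(rev)))
    law_json <- jsonlite::toJSON(list(
      kind = r$rate$kind, params = as.list(r$rate$params),
      species = r$rate$species,
      reverse_species = r$rate$reverse_species,
      enzyme = r$rate$enzyme, activator = r$rate$activator),
      auto_unbox = TRUE, null = "null")
    out <- c(out, sprintf(paste0(
      "<annotation><hifmir:reaction xmlns:hifmir=\"%s\" group=\"%s\">",
      "%s</hifmir:reaction></annotation>"),
      .HIFMIR_NS, r$group, esc(as.character(law_json))))
    if (nrow(r$reactants)) {
      out <- c(out, "<listOfReactants>")
      for (i in seq_len(nrow(r$reactants))) {
        out <- c(out, sprintf(paste0(
          "<speciesReference species=\"%s\" stoichiometry=\"%g\" ",
          "constant=\"true\"/>"),
          r$reactants$species[i], r$reactants$coef[i]))
      }
      out <- c(out, "</listOfReactants>")
    }
    if (nrow(r$products)) {
      out <- c(out, "<listOfProducts>")
      for (i in seq_len(nrow(r$products))) {
        out <- c(out, sprintf(paste0(
          "<speciesReference species=\"%s\" stoichiometry=\"%g\" ",
          "constant=\"true\"/>"),
          r$products$species[i], r$products$coef[i]))
      }
      out <- c(out, "</listOfProducts>")
    }
    if (length(r$modifiers)) {
      out <- c(out, "<listOfModifiers>")
      for (mname in r$modifiers) {
        out <- c(out, sprintf(
          "<modifierSpeciesReference species=\"%s\"/>", mname))
      }
      out <- c(out, "</listOfModifiers>")
    }
    out <- c(out, "<kineticLaw>", .mathml_rate(r), "</kineticLaw>",
             "</reaction>")
  }
  out <- c(out, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

#' Import a model from SBML Level 3 written by [write_sbml()]
#'
#' @param path SBML file.
#' @return A `hifmir_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = .SBML_NS, h = .HIFMIR_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  comps <- do.call(rbind, lapply(
    xml2::xml_find_all(mdl, ".//s:compartment", ns), function(x)
      compartment(xml2::xml_attr(x, "id"), xml2::xml_attr(x, "name"))))
  clamped <- character()
  sp <- do.call(rbind, lapply(
    xml2::xml_find_all(mdl, ".//s:species", ns), function(x) {
      id <- xml2::xml_attr(x, "id")
      if (identical(xml2::xml_attr(x, "boundaryCondition"), "true")) {
        clamped <<- c(clamped, id)
      }
      role <- xml2::xml_text(
        xml2::xml_find_first(x, ".//h:role", ns))
      species_def(id, xml2::xml_attr(x, "compartment"), role,
                  as.numeric(xml2::xml_attr(x, "initialConcentration")),
                  xml2::xml_attr(x, "name"))
    }))
  pars <- do.call(rbind, lapply(
    xml2::xml_find_all(mdl, ".//s:parameter", ns), function(x) {
      meta <- xml2::xml_find_first(x, ".//h:meta", ns)
      data.frame(id = xml2::xml_attr(x, "id"),
                 value = as.numeric(xml2::xml_attr(x, "value")),
                 units = xml2::xml_attr(meta, "units"),
                 provenance = xml2::xml_attr(meta, "provenance"),
                 stringsAsFactors = FALSE)
    }))
  rxs <- lapply(xml2::xml_find_all(mdl, ".//s:reaction", ns),
                function(x) {
    ann <- xml2::xml_find_first(x, ".//h:reaction", ns)
    law_spec <- jsonlite::fromJSON(xml2::xml_text(ann),
                                   simplifyVector = TRUE)
    law <- rate_law(law_spec$kind, unlist(law_spec$params),
                    species = as.character(law_spec$species %||%
                                             character()),
                    reverse_species =
                      as.character(law_spec$reverse_species %||%
                                     character()),
                    enzyme = law_spec$enzyme,
                    activator = law_spec$activator)
    stoich <- function(xp) {
      refs <- xml2::xml_find_all(x, xp, ns)
      if (length(refs) == 0L) return(numeric())
      stats::setNames(
        as.numeric(vapply(refs, xml2::xml_attr, "", "stoichiometry")),
        vapply(refs, xml2::xml_attr, "", "species"))
    }
    mods <- vapply(
      xml2::xml_find_all(x, ".//s:modifierSpeciesReference", ns),
      xml2::xml_attr, "", "species")
    reaction(xml2::xml_attr(x, "id"),
             reactants = stoich(".//s:listOfReactants/s:speciesReference"),
             products = stoich(".//s:listOfProducts/s:speciesReference"),
             modifiers = as.character(mods), rate = law,
             description = xml2::xml_attr(x, "name"),
             group = xml2::xml_attr(ann, "group"))
  })
  hifmir_model(comps, sp, rxs, pars, clamped = clamped,
               name = xml2::xml_attr(mdl, "name"))
}
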
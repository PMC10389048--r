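#' Import an SBML model (level 2/3) into the generic model interface
#'
#' Lightweight import hook: reads compartments, species, global parameters
#' and reactions (with local kinetic-law parameters) from an SBML file into
#' plain data frames. Kinetic-law mathematics is retained as flattened
#' MathML text, not compiled to R; the bundled glucose subsystem does not
#' require this hook.
#'
#' @param path SBML file path.
#' @return A list with class \code{"sbml_model"}: \code{id}, \code{level},
#'   \code{version}, \code{compartments} (id, size), \code{species} (id,
#'   name, compartment, initial_concentration, boundary_condition),
#'   \code{parameters} (id, value), \code{reactions} (list of id,
#'   reactants, products, kinetic_law, local_parameters).
#' @export
read_sbml_model <- function(path) {
  if (!file.exists(path)) stop_invalid("SBML file not found: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sbml <- xml2::xml_find_first(doc, "/sbml")
  if (inherits(sbml, "xml_missing") ||
      length(xml2::xml_find_all(doc, "/sbml/model")) == 0L)
    stop_invalid("not an SBML document: ", path)
  model <- xml2::xml_find_first(doc, "/sbml/model")

  attr_or_na <- function(nodes, a) {
    v <- xml2::xml_attr(nodes, a)
    ifelse(is.na(v), NA_character_, v)
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  comp_nodes <- xml2::xml_find_all(model, ".//listOfCompartments/compartment")
  compartments <- data.frame(
    id = attr_or_na(comp_nodes, "id"),
    size = num(attr_or_na(comp_nodes, "size")),
    stringsAsFactors = FALSE)

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  species <- data.frame(
    id = attr_or_na(sp_nodes, "id"),
    name = attr_or_na(sp_nodes, "name"),
    compartment = attr_or_na(sp_nodes, "compartment"),
    initial_concentration = num(attr_or_na(sp_nodes, "initialConcentration")),
    boundary_condition = attr_or_na(sp_nodes, "boundaryCondition") == "true",
    stringsAsFactors = FALSE)

  par_nodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  parameters <- data.frame(
    id = attr_or_na(par_nodes, "id"),
    value = num(attr_or_na(par_nodes, "value")),
    stringsAsFactors = FALSE)

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(rx) {
    kl <- xml2::xml_find_first(rx, ".//kineticLaw")
    lp_nodes <- if (inherits(kl, "xml_node"))
      xml2::xml_find_all(kl, ".//parameter | .//localParameter")
    else xml2::xml_find_all(rx, ".//nothing")
    math <- if (inherits(kl, "xml_node"))
      xml2::xml_find_first(kl, ".//math") else NULL
    list(
      id = xml2::xml_attr(rx, "id"),
      reactants = xml2::xml_attr(
        xml2::xml_find_all(rx, ".//listOfReactants/speciesReference"),
        "species"),
      products = xml2::xml_attr(
        xml2::xml_find_all(rx, ".//listOfProducts/speciesReference"),
        "species"),
      kinetic_law = if (inherits(math, "xml_node"))
        paste(xml2::xml_text(xml2::xml_find_all(math, ".//ci | .//cn")),
              collapse = " ") else NA_character_,
      local_parameters = data.frame(
        id = attr_or_na(lp_nodes, "id"),
        value = num(attr_or_na(lp_nodes, "value")),
        stringsAsFactors = FALSE))
  })

  structure(list(id = xml2::xml_attr(model, "id"),
                 level = xml2::xml_attr(sbml, "level"),
                 version = xml2::xml_attr(sbml, "version"),
                 compartments = compartments, species = species,
                 parameters = parameters, reactions = reactions),
            class = "sbml_model")
}

#' Map an imported SBML model onto the bundled glucose subsystem
#'
#' Looks up the six kinetic parameters (\code{Vin_Vm1}, \code{Vin_KilG6P},
#' \code{Vhk_Vm2}, \code{Vhk_Km2Glc}, \code{Vhk_Km2ATP}, \code{Vhk_Ks2Glc},
#' matched case-insensitively over global and reaction-local parameters),
#' the cytoplasm compartment size, and the G6P/ATP/Glci species initial
#' concentrations, returning them in the package's native types.
#'
#' @param model an \code{\link{read_sbml_model}} result.
#' @return A list with \code{params} (\code{\link{kinetic_parameters}}) and
#'   \code{env} (\code{\link{model_environment}}).
#' @export
as_glci_model <- function(model) {
  stopifnot(inherits(model, "sbml_model"))
  all_pars <- model$parameters
  for (rx in model$reactions)
    all_pars <- rbind(all_pars, rx$local_parameters)
  lookup <- function(id) {
    hit <- match(tolower(id), tolower(all_pars$id))
    if (is.na(hit)) stop_invalid("parameter ", id, " not found in SBML model")
    all_pars$value[hit]
  }
  params <- kinetic_parameters(
    vin_vm1 = lookup("Vin_Vm1"), vin_kilg6p = lookup("Vin_KilG6P"),
    vhk_vm2 = lookup("Vhk_Vm2"), vhk_km2glc = lookup("Vhk_Km2Glc"),
    vhk_km2atp = lookup("Vhk_Km2ATP"), vhk_ks2glc = lookup("Vhk_Ks2Glc"))
  sp <- model$species
  conc <- function(id, default) {
    hit <- match(tolower(id), tolower(sp$id))
    if (is.na(hit) || is.na(sp$initial_concentration[hit])) default
    else sp$initial_concentration[hit]
  }
  comp <- model$compartments
  vol <- comp$size[match("cytoplasm", tolower(comp$id))]
  if (is.na(vol)) vol <- 1
  env <- model_environment(cytoplasm_volume = vol,
                           g6p = conc("G6P", 1), atp = conc("ATP", 1),
                           glci0 = conc("Glci", 1))
  list(params = params, env = env)
}
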
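#' Read a metabolic network from SBML (Level 2/3 subset)
#'
#' Reads species (the `boundaryCondition` attribute marks external
#' metabolites), reactions (reactant/product `speciesReference` entries with
#' their stoichiometries, and the `reversible` flag -- treated as reversible
#' when the attribute is absent, the conservative choice when directionality
#' is not conclusive) and ignores kinetics, compartments, units and
#' annotations. Carbon counts are not part of core SBML, so they are joined
#' from a metabolite table.
#'
#' @param path SBML file path.
#' @param metabolite_table Optional data frame (or TSV path) with columns
#'   `metabolite_id`, `carbon_count` and optionally `skip_carbon_check`;
#'   species missing from it get carbon count 0 with a warning.
#' @param config Optional model configuration (list or path); its `external`
#'   entry, if present, overrides the SBML boundary conditions.
#' @return A [metabolic_network()].
#' @export
read_sbml <- function(path, metabolite_table = NULL, config = list()) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  if (is.character(config)) config <- read_model_config(config)
  doc <- xml2::read_xml(path)
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  if (length(sp) == 0L) stop("no species found in ", path)
  sid <- xml2::xml_attr(sp, "id")
  sname <- xml2::xml_attr(sp, "name")
  boundary <- tolower(xml2::xml_attr(sp, "boundaryCondition")) %in% "true"

  carbon <- setNames(rep(0, length(sid)), sid)
  skip <- setNames(rep(FALSE, length(sid)), sid)
  if (!is.null(metabolite_table)) {
    if (is.character(metabolite_table))
      metabolite_table <- read.delim(metabolite_table, sep = "\t",
                                     stringsAsFactors = FALSE)
    idx <- match(sid, metabolite_table$metabolite_id)
    carbon[!is.na(idx)] <- metabolite_table$carbon_count[idx[!is.na(idx)]]
    if (!is.null(metabolite_table$skip_carbon_check))
      skip[!is.na(idx)] <- as.logical(metabolite_table$skip_carbon_check[idx[!is.na(idx)]])
    if (any(is.na(idx)))
      warning("no carbon count for species: ",
              paste(sid[is.na(idx)], collapse = ", "), " (set to 0)")
  } else warning("no metabolite table given; carbon counts set to 0")

  external <- if (length(config$external)) sid %in% config$external else boundary
  mets <- data.frame(id = sid,
                     name = ifelse(is.na(sname), sid, sname),
                     carbon_count = carbon, is_external = external,
                     skip_carbon_check = skip, stringsAsFactors = FALSE)

  rx <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (length(rx) == 0L) stop("no reactions found in ", path)
  reactions <- lapply(rx, function(r) {
    rid <- xml2::xml_attr(r, "id")
    rev_attr <- xml2::xml_attr(r, "reversible")
    reversible <- is.na(rev_attr) || tolower(rev_attr) == "true"
    ref <- function(side, sign) {
      refs <- xml2::xml_find_all(
        r, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']", side))
      if (length(refs) == 0L) return(numeric(0))
      st <- xml2::xml_attr(refs, "stoichiometry")
      st <- ifelse(is.na(st), 1, as.numeric(st))
      setNames(sign * st, xml2::xml_attr(refs, "species"))
    }
    lhs <- ref("listOfReactants", -1)
    rhs <- ref("listOfProducts", +1)
    stoich <- lhs
    for (m in names(rhs)) stoich[m] <- (if (m %in% names(stoich)) stoich[[m]] else 0) + rhs[[m]]
    reaction(rid, stoich[stoich != 0], reversible = reversible)
  })
  metabolic_network(mets, reactions,
                    name = tools::file_path_sans_ext(basename(path)),
                    config = config)
}
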
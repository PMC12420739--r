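# SBML Level 3 (core + fbc v2 + groups v1) reader/writer. Covers the subset
# genome-scale models actually use: species/compartments, reactions with
# parameter-backed flux bounds, an fbc objective, and groups as pathway
# (subsystem) annotations.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBML_GROUPS_NS <- "http://www.sbml.org/sbml/level3/version1/groups/version1"

# map this document's namespace prefixes onto stable names (core/fbc/groups)
sbml_ns <- function(doc) {
  ns <- xml2::xml_ns(doc)
  pick <- function(uri) {
    hit <- names(ns)[ns == uri]
    if (length(hit)) hit[[1]] else NA_character_
  }
  c(core = pick(SBML_CORE_NS), fbc = pick(SBML_FBC_NS), groups = pick(SBML_GROUPS_NS))
}

#' Read a constraint-based model from SBML
#'
#' Parses an SBML Level 3 file with the flux-bounds (`fbc`) extension and
#' optional `groups`-based pathway (subsystem) annotations, attaches a
#' side-compound list and pathway category table, detects exchange
#' reactions, and returns a validated [metabolic_model()].
#'
#' Every reaction must carry explicit flux bounds (a missing bound is a hard
#' error), and a reaction annotated to more than one pathway group is a hard
#' error: pathway sets must partition the annotated reactions.
#'
#' @param path SBML file path.
#' @param side_compound_path Optional plain-text file, one side-compound id
#'   per line (base ids or full ids; `#` comments allowed).
#' @param category_path Optional 2-column TSV (`pathway_id`, `category`).
#' @param biomass_id Id of the biomass reaction. Defaults to the model's
#'   active fbc objective when present, else must be supplied.
#' @param extracellular Compartment id(s) treated as extracellular
#'   (default `"e"`).
#' @return A `metabolic_model`.
#' @export
read_sbml_model <- function(path, side_compound_path = NULL,
                            category_path = NULL, biomass_id = NULL,
                            extracellular = "e") {
  doc <- xml2::read_xml(path)
  ns <- sbml_ns(doc)
  nsmap <- xml2::xml_ns(doc)
  if (is.na(ns[["core"]])) abort("not an SBML Level 3 document")
  q <- function(tag, prefix = "core") paste0(ns[[prefix]], ":", tag)

  comp_nodes <- xml2::xml_find_all(doc, paste0(".//", q("compartment")), nsmap)
  comps <- tibble(
    id = xml2::xml_attr(comp_nodes, "id"),
    extracellular = xml2::xml_attr(comp_nodes, "id") %in% extracellular
  )

  sp_nodes <- xml2::xml_find_all(doc, paste0(".//", q("species")), nsmap)
  metabolites <- tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"), xml2::xml_attr(sp_nodes, "id")),
    compartment = xml2::xml_attr(sp_nodes, "compartment")
  )

  par_nodes <- xml2::xml_find_all(doc, paste0(".//", q("parameter")), nsmap)
  par_val <- setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id")
  )

  if (is.na(ns[["fbc"]])) abort("SBML file lacks the fbc (flux bounds) extension")
  rxn_nodes <- xml2::xml_find_all(doc, paste0(".//", q("reaction")), nsmap)
  bound_of <- function(nodes, attr) {
    ref <- xml2::xml_attr(nodes, attr, ns = nsmap)
    if (anyNA(ref)) {
      abort(paste0(
        "reaction(s) without ", attr, ": ",
        paste(head(xml2::xml_attr(nodes, "id")[is.na(ref)], 5), collapse = ", ")
      ))
    }
    val <- par_val[ref]
    if (anyNA(val)) abort("flux bound refers to an unknown parameter")
    unname(val)
  }
  reactions <- tibble(
    id = xml2::xml_attr(rxn_nodes, "id"),
    lower_bound = bound_of(rxn_nodes, paste0(ns[["fbc"]], ":lowerFluxBound")),
    upper_bound = bound_of(rxn_nodes, paste0(ns[["fbc"]], ":upperFluxBound"))
  )

  stoich <- purrr::map_dfr(seq_along(rxn_nodes), function(i) {
    node <- rxn_nodes[[i]]
    rid <- xml2::xml_attr(node, "id")
    grab <- function(listtag, sign) {
      refs <- xml2::xml_find_all(
        node, paste0("./", q(listtag), "/", q("speciesReference")), nsmap
      )
      if (!length(refs)) return(NULL)
      st <- xml2::xml_attr(refs, "stoichiometry")
      st <- ifelse(is.na(st), 1, as.numeric(st))
      tibble(
        reaction_id = rid,
        metabolite_id = xml2::xml_attr(refs, "species"),
        coefficient = sign * st
      )
    }
    bind_rows(grab("listOfReactants", -1), grab("listOfProducts", 1))
  })
  # merge duplicate species references on the same side
  stoich <- stoich %>%
    group_by(.data$reaction_id, .data$metabolite_id) %>%
    summarise(coefficient = sum(.data$coefficient), .groups = "drop")

  # pathway annotations from groups
  pathway <- rep(NA_character_, nrow(reactions))
  if (!is.na(ns[["groups"]])) {
    gq <- function(tag) paste0(ns[["groups"]], ":", tag)
    groups <- xml2::xml_find_all(doc, paste0(".//", gq("group")), nsmap)
    for (g in groups) {
      gname <- xml2::xml_attr(g, paste0(ns[["groups"]], ":name"), ns = nsmap)
      if (is.na(gname)) gname <- xml2::xml_attr(g, paste0(ns[["groups"]], ":id"), ns = nsmap)
      members <- xml2::xml_find_all(g, paste0("./", gq("listOfMembers"), "/", gq("member")), nsmap)
      refs <- xml2::xml_attr(members, paste0(ns[["groups"]], ":idRef"), ns = nsmap)
      idx <- match(refs, reactions$id)
      idx <- idx[!is.na(idx)]
      clash <- idx[!is.na(pathway[idx]) & pathway[idx] != gname]
      if (length(clash)) {
        abort(paste0(
          "reaction(s) annotated to more than one pathway (a reaction can ",
          "only belong to one pathway): ",
          paste(reactions$id[clash], collapse = ", ")
        ))
      }
      pathway[idx] <- gname
    }
  }
  reactions$pathway_id <- pathway

  if (is.null(biomass_id)) {
    fq <- function(tag) paste0(ns[["fbc"]], ":", tag)
    fo <- xml2::xml_find_first(doc, paste0(".//", fq("fluxObjective")), nsmap)
    if (!inherits(fo, "xml_missing")) {
      biomass_id <- xml2::xml_attr(fo, paste0(ns[["fbc"]], ":reaction"), ns = nsmap)
    }
  }
  if (is.null(biomass_id) || is.na(biomass_id) || !biomass_id %in% reactions$id) {
    abort("biomass reaction id not found; pass `biomass_id` explicitly")
  }

  side <- if (!is.null(side_compound_path)) read_side_compounds(side_compound_path) else NULL
  cats <- if (!is.null(category_path)) read_pathway_categories(category_path) else NULL

  metabolic_model(
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = stoich,
    biomass_reaction_id = biomass_id,
    compartments = comps,
    pathway_categories = cats,
    side_compounds = side
  )
}

fmt_num <- function(x) sprintf("%.15g", x)

#' Write a model to SBML
#'
#' Serialises a [metabolic_model()] as SBML Level 3 Version 1 with fbc v2
#' flux bounds, the biomass objective, and one `groups` group per pathway.
#' Round-trips through [read_sbml_model()]: stoichiometry, bounds, pathway
#' map, compartments and the biomass id are preserved.
#'
#' @param m A `metabolic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(m, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0(
      "<sbml xmlns=\"", SBML_CORE_NS, "\" xmlns:fbc=\"", SBML_FBC_NS,
      "\" xmlns:groups=\"", SBML_GROUPS_NS,
      "\" level=\"3\" version=\"1\" fbc:required=\"false\" groups:required=\"false\">"
    ),
    "  <model id=\"model\" fbc:strict=\"true\">",
    "    <listOfCompartments>",
    sprintf(
      "      <compartment id=\"%s\" constant=\"true\"/>",
      esc(m$compartments$id)
    ),
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    sprintf(
      paste0(
        "      <species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
        "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" constant=\"false\"/>"
      ),
      esc(m$metabolites$id), esc(m$metabolites$name), esc(m$metabolites$compartment)
    ),
    "    </listOfSpecies>",
    "    <listOfParameters>",
    sprintf(
      "      <parameter id=\"bnd_lb_%d\" value=\"%s\" constant=\"true\"/>",
      seq_len(nrow(m$reactions)), fmt_num(m$reactions$lower_bound)
    ),
    sprintf(
      "      <parameter id=\"bnd_ub_%d\" value=\"%s\" constant=\"true\"/>",
      seq_len(nrow(m$reactions)), fmt_num(m$reactions$upper_bound)
    ),
    "    </listOfParameters>",
    "    <listOfReactions>"
  )
  st <- split(m$stoichiometry, m$stoichiometry$reaction_id)
  for (i in seq_len(nrow(m$reactions))) {
    r <- m$reactions[i, ]
    out <- c(out, sprintf(
      paste0(
        "      <reaction id=\"%s\" reversible=\"%s\" fast=\"false\" ",
        "fbc:lowerFluxBound=\"bnd_lb_%d\" fbc:upperFluxBound=\"bnd_ub_%d\">"
      ),
      esc(r$id), tolower(r$lower_bound < 0), i, i
    ))
    s <- st[[r$id]]
    subs <- s[s$coefficient < 0, ]
    prods <- s[s$coefficient > 0, ]
    if (nrow(subs)) {
      out <- c(
        out, "        <listOfReactants>",
        sprintf(
          "          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
          esc(subs$metabolite_id), fmt_num(-subs$coefficient)
        ),
        "        </listOfReactants>"
      )
    }
    if (nrow(prods)) {
      out <- c(
        out, "        <listOfProducts>",
        sprintf(
          "          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
          esc(prods$metabolite_id), fmt_num(prods$coefficient)
        ),
        "        </listOfProducts>"
      )
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(
    out,
    "    </listOfReactions>",
    "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
    "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
    "        <fbc:listOfFluxObjectives>",
    sprintf(
      "          <fbc:fluxObjective fbc:reaction=\"%s\" fbc:coefficient=\"1\"/>",
      esc(m$biomass_reaction_id)
    ),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>"
  )
  pws <- model_pathways(m)
  if (length(pws)) {
    out <- c(out, "    <groups:listOfGroups>")
    for (k in seq_along(pws)) {
      members <- m$reactions$id[!is.na(m$reactions$pathway_id) &
        m$reactions$pathway_id == pws[[k]]]
      out <- c(
        out,
        sprintf(
          "      <groups:group groups:id=\"gr_%d\" groups:name=\"%s\" groups:kind=\"partonomy\">",
          k, esc(pws[[k]])
        ),
        "        <groups:listOfMembers>",
        sprintf("          <groups:member groups:idRef=\"%s\"/>", esc(members)),
        "        </groups:listOfMembers>",
        "      </groups:group>"
      )
    }
    out <- c(out, "    </groups:listOfGroups>")
  }
  out <- c(out, "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}
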
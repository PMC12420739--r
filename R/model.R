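#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` bundles metabolites, reactions with flux bounds and
#' pathway (subsystem) annotations, and a long-format stoichiometry table.
#' Exchange reactions -- boundary pseudo-reactions touching a single
#' extracellular metabolite -- are auto-detected and normalised so that
#' positive flux means export to the medium and negative flux means import.
#'
#' @param metabolites Tibble with columns `id`, and optionally `name`,
#'   `compartment`, `base_id`, `is_side_compound`. `base_id` (the id with the
#'   compartment suffix stripped) is derived when absent.
#' @param reactions Tibble with columns `id`, `lower_bound`, `upper_bound`,
#'   and optionally `pathway_id` (NA for unannotated reactions).
#' @param stoichiometry Long tibble with columns `reaction_id`,
#'   `metabolite_id`, `coefficient` (negative = substrate, positive =
#'   product).
#' @param biomass_reaction_id Id of the biomass (objective) reaction; must
#'   exist among the reactions.
#' @param compartments Tibble with columns `id` and logical `extracellular`,
#'   or a character vector of extracellular compartment ids (defaults to
#'   `"e"` applied to all compartments seen in `metabolites`).
#' @param pathway_categories Optional tibble with columns `pathway_id`,
#'   `category`; pathways whose category is `"Miscellaneous"` are excluded
#'   from knockout scenarios (but stay in the network).
#' @param side_compounds Optional character vector of side-compound ids
#'   (base ids or full ids), e.g. water, ATP, NAD.
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            biomass_reaction_id,
                            compartments = "e",
                            pathway_categories = NULL,
                            side_compounds = NULL) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  stoichiometry <- as_tibble(stoichiometry)

  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  if (is.character(compartments)) {
    comp_ids <- sort(unique(metabolites$compartment))
    compartments <- tibble(id = comp_ids, extracellular = comp_ids %in% compartments)
  }
  compartments <- as_tibble(compartments)
  if (!"base_id" %in% names(metabolites)) {
    metabolites$base_id <- strip_compartment_suffix(
      metabolites$id, metabolites$compartment
    )
  }
  if (!"is_side_compound" %in% names(metabolites)) {
    metabolites$is_side_compound <- FALSE
  }
  if (!is.null(side_compounds)) {
    metabolites$is_side_compound <- metabolites$base_id %in% side_compounds |
      metabolites$id %in% side_compounds
  }
  if (!"pathway_id" %in% names(reactions)) reactions$pathway_id <- NA_character_

  m <- structure(
    list(
      metabolites = metabolites,
      reactions = reactions,
      stoichiometry = stoichiometry,
      biomass_reaction_id = biomass_reaction_id,
      compartments = compartments,
      pathway_categories = if (is.null(pathway_categories)) {
        tibble(pathway_id = character(), category = character())
      } else {
        as_tibble(pathway_categories)
      }
    ),
    class = "metabolic_model"
  )
  m <- detect_exchange_reactions(m)
  validate_metabolic_model(m)
  m
}

#' Strip the compartment suffix from metabolite ids
#'
#' Metabolite uniqueness in the package is at the base-id level so that
#' compartmental copies of the same compound count once. The default
#' convention removes a trailing compartment code, optionally preceded by
#' `_` or wrapped in `[...]` (covers `glc_c`, `glc[c]`, `MAM01234c`).
#'
#' @param id Character vector of metabolite ids.
#' @param compartment Character vector (recycled) of compartment codes.
#' @return Character vector of base ids.
#' @export
strip_compartment_suffix <- function(id, compartment) {
  out <- character(length(id))
  for (i in seq_along(id)) {
    pat <- paste0("(_|\\[)?", rescape(compartment[[i]]), "\\]?$")
    base <- sub(pat, "", id[[i]])
    out[[i]] <- if (nzchar(base)) base else id[[i]]
  }
  out
}

rescape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Auto-detect exchange reactions (single-metabolite reactions on an
# extracellular species) and normalise their sign so positive flux = export.
detect_exchange_reactions <- function(m) {
  ex_comp <- m$compartments$id[m$compartments$extracellular]
  ex_mets <- m$metabolites$id[m$metabolites$compartment %in% ex_comp]

  tallies <- m$stoichiometry %>%
    group_by(.data$reaction_id) %>%
    summarise(
      n_met = dplyr::n_distinct(.data$metabolite_id),
      met = first(.data$metabolite_id),
      coef = first(.data$coefficient)
    )
  ex_tbl <- tallies %>%
    filter(
      .data$n_met == 1,
      .data$met %in% ex_mets,
      .data$reaction_id != m$biomass_reaction_id
    )

  m$reactions$is_exchange <- m$reactions$id %in% ex_tbl$reaction_id
  m$reactions$exchanged_metabolite <-
    ex_tbl$met[match(m$reactions$id, ex_tbl$reaction_id)]

  # flip reactions written as import (coefficient +1) to the export convention
  flip <- ex_tbl$reaction_id[ex_tbl$coef > 0]
  if (length(flip)) {
    idx <- m$stoichiometry$reaction_id %in% flip
    m$stoichiometry$coefficient[idx] <- -m$stoichiometry$coefficient[idx]
    ridx <- m$reactions$id %in% flip
    lb <- m$reactions$lower_bound[ridx]
    ub <- m$reactions$upper_bound[ridx]
    m$reactions$lower_bound[ridx] <- -ub
    m$reactions$upper_bound[ridx] <- -lb
  }

  dup <- m$reactions %>%
    filter(.data$is_exchange) %>%
    count(.data$exchanged_metabolite) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    warn(paste0(
      "multiple exchange reactions for metabolite(s) ",
      paste(dup$exchanged_metabolite, collapse = ", "),
      "; their fluxes are merged by summation in z-score profiles"
    ))
  }
  m
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique non-empty ids, consistent
#' stoichiometry references, `lower_bound <= upper_bound`, a biomass
#' reaction that exists, and at most one pathway per reaction.
#'
#' @param m A `metabolic_model`.
#' @return `m`, invisibly.
#' @export
validate_metabolic_model <- function(m) {
  met <- m$metabolites
  rxn <- m$reactions
  if (anyDuplicated(met$id) || any(!nzchar(met$id))) {
    abort("metabolite ids must be unique and non-empty")
  }
  if (anyDuplicated(rxn$id) || any(!nzchar(rxn$id))) {
    abort("reaction ids must be unique and non-empty")
  }
  if (any(is.na(rxn$lower_bound)) || any(is.na(rxn$upper_bound))) {
    abort("every reaction needs explicit lower and upper flux bounds")
  }
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    abort("lower_bound > upper_bound for at least one reaction")
  }
  if (!m$biomass_reaction_id %in% rxn$id) {
    abort(paste0("biomass reaction '", m$biomass_reaction_id, "' not in model"))
  }
  bad_m <- setdiff(m$stoichiometry$metabolite_id, met$id)
  bad_r <- setdiff(m$stoichiometry$reaction_id, rxn$id)
  if (length(bad_m) || length(bad_r)) {
    abort("stoichiometry refers to unknown metabolites or reactions")
  }
  orphan <- setdiff(met$id, m$stoichiometry$metabolite_id)
  if (length(orphan)) {
    abort(paste0("metabolites tied to no reaction: ", paste(orphan, collapse = ", ")))
  }
  invisible(m)
}

#' Stoichiometric matrix of a model
#'
#' @param m A `metabolic_model`.
#' @return A dense numeric matrix, metabolites in rows and reactions in
#'   columns, in the order of the model tables.
#' @export
stoich_matrix <- function(m) {
  S <- matrix(0, nrow(m$metabolites), nrow(m$reactions),
    dimnames = list(m$metabolites$id, m$reactions$id)
  )
  S[cbind(
    match(m$stoichiometry$metabolite_id, m$metabolites$id),
    match(m$stoichiometry$reaction_id, m$reactions$id)
  )] <- m$stoichiometry$coefficient
  S
}

#' Pathway ids annotated in a model
#'
#' @param m A `metabolic_model`.
#' @return Sorted character vector of pathway ids (unannotated reactions
#'   contribute nothing).
#' @export
model_pathways <- function(m) {
  sort(unique(m$reactions$pathway_id[!is.na(m$reactions$pathway_id)]))
}

#' Miscellaneous pathways of a model
#'
#' Pathways whose category (from the category table) is `"Miscellaneous"`;
#' these are excluded from knockout scenarios but remain in the network.
#'
#' @param m A `metabolic_model`.
#' @return Character vector of pathway ids.
#' @export
miscellaneous_pathways <- function(m) {
  pc <- m$pathway_categories
  sort(intersect(pc$pathway_id[pc$category == "Miscellaneous"], model_pathways(m)))
}

#' @export
print.metabolic_model <- function(x, ...) {
  n_ex <- sum(x$reactions$is_exchange)
  cat(
    "<metabolic_model> ", nrow(x$metabolites), " metabolites (",
    dplyr::n_distinct(x$metabolites$base_id), " unique), ",
    nrow(x$reactions), " reactions (", n_ex, " exchanges), ",
    length(model_pathways(x)), " pathways; biomass: ",
    x$biomass_reaction_id, "\n",
    sep = ""
  )
  invisible(x)
}
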
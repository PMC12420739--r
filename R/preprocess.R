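#' Detect blocked reactions
#'
#' A reaction is blocked when it can carry no steady-state flux under the
#' model's default bounds: its flux-variability minimum and maximum are both
#' within `tol` of zero (no biomass constraint is imposed).
#'
#' @param m A `metabolic_model`.
#' @param tol Absolute flux tolerance (default `1e-9`).
#' @return Character vector of blocked reaction ids (possibly empty).
#' @export
find_blocked_reactions <- function(m, tol = 1e-9) {
  stopifnot(tol > 0)
  v <- fva(m)
  v$reaction_id[abs(v$min) <= tol & abs(v$max) <= tol]
}

#' Prune blocked reactions and orphaned metabolites
#'
#' Removes the given blocked reactions, then removes metabolites no longer
#' tied to any reaction. Pathways whose reaction sets become empty are
#' flagged as blocked pathways (attribute `"blocked_pathways"` on the
#' returned model).
#'
#' @param m A `metabolic_model`.
#' @param blocked Character vector of reaction ids to remove (typically from
#'   [find_blocked_reactions()]).
#' @return The pruned `metabolic_model` with attribute `blocked_pathways`.
#' @export
prune_model <- function(m, blocked = character()) {
  if (length(setdiff(blocked, m$reactions$id))) {
    abort("blocked reactions must be a subset of the model's reactions")
  }
  before <- model_pathways(m)
  m$reactions <- filter(m$reactions, !.data$id %in% blocked)
  m$stoichiometry <- filter(m$stoichiometry, !.data$reaction_id %in% blocked)
  kept_mets <- unique(m$stoichiometry$metabolite_id)
  m$metabolites <- filter(m$metabolites, .data$id %in% kept_mets)
  blocked_pw <- setdiff(before, model_pathways(m))
  validate_metabolic_model(m)
  attr(m, "blocked_pathways") <- sort(unique(c(
    attr(m, "blocked_pathways"), blocked_pw
  )))
  m
}

#' Convert reaction pathway sets to metabolite pathway sets
#'
#' For every pathway, collects the base ids of the substrates and products
#' of its reactions. A metabolite may appear in multiple pathways. Side
#' compounds are included by default (matching how pathway sets are fed to
#' enrichment) and excluded with `include_side = FALSE` (the variant used
#' for overlap-graph and exchangeable-ratio computations).
#'
#' @param m A `metabolic_model` (pruned).
#' @param include_side Keep side compounds in the sets (default `TRUE`).
#' @return A tibble of class `metabolite_pathway_sets` with columns
#'   `pathway_id`, `metabolite` (base id), and attribute
#'   `side_compounds_included`.
#' @export
metabolite_pathway_sets <- function(m, include_side = TRUE) {
  met <- m$metabolites
  if (!include_side) met <- filter(met, !.data$is_side_compound)
  sets <- m$stoichiometry %>%
    inner_join(
      select(m$reactions, reaction_id = "id", "pathway_id"),
      by = "reaction_id"
    ) %>%
    filter(!is.na(.data$pathway_id)) %>%
    inner_join(
      select(met, metabolite_id = "id", "base_id"),
      by = "metabolite_id"
    ) %>%
    distinct(.data$pathway_id, metabolite = .data$base_id) %>%
    arrange(.data$pathway_id, .data$metabolite)
  structure(sets,
    class = c("metabolite_pathway_sets", class(sets)),
    side_compounds_included = include_side
  )
}

#' Coerce pathway sets to a named list
#'
#' @param sets A `metabolite_pathway_sets` tibble (or any tibble with
#'   `pathway_id` and `metabolite` columns).
#' @return Named list of character vectors.
#' @export
sets_as_list <- function(sets) {
  split(sets$metabolite, sets$pathway_id)
}

#' Exchangeable background metabolites
#'
#' Base ids of all metabolites having at least one exchange reaction: the
#' background set for over-representation analysis and the denominator of
#' the exchangeable ratio.
#'
#' @param m A `metabolic_model` (pruned).
#' @return Sorted character vector of base ids.
#' @export
exchangeable_background <- function(m) {
  ex_met <- m$reactions$exchanged_metabolite[m$reactions$is_exchange]
  sort(unique(m$metabolites$base_id[match(ex_met, m$metabolites$id)]))
}
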
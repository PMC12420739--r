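#' Specify a synthetic toy metabolic model
#'
#' The toy generator builds small ground-truth models exhibiting the
#' structural archetypes whose detectability the benchmark probes:
#'
#' * `essential`: sole producer of a biomass precursor; knocking it out
#'   makes the model unable to reach the biomass floor (infeasible).
#' * `unique_exporter`: reaction chains consuming imported substrates and
#'   ending in an exchange reaction used by no other pathway; knockout
#'   raises the substrates in the medium and abolishes the unique export,
#'   so the profile is strong and specific (expected true positive).
#' * `internal_only`: a cofactor-balanced internal cycle with no
#'   exchangeable metabolite (exchangeable ratio 0); knockout leaves the
#'   exometabolome untouched (expected false negative).
#' * `redundant_pair`: two pathways catalysing the same conversion; tags
#'   must come in pairs, and knocking out one reroutes flux through the
#'   other.
#' * `blocked`: dead-end reactions that can carry no steady-state flux and
#'   are removed at pruning.
#'
#' Archetypes are fixed structural templates stitched onto a common core
#' (nutrient import, precursor synthesis, biomass, a Miscellaneous-category
#' transport pathway, and unannotated "decoy" export chains that pad the
#' exchangeable background). The seed only jitters decoy flux bounds;
#' ground truth is exact by construction.
#'
#' @param archetypes Character vector of archetype tags, one per pathway.
#' @param n_side_compounds Number of side compounds flagged (0-3: ATP, ADP,
#'   water).
#' @param n_decoys Number of decoy export chains padding the background.
#' @param seed Integer seed controlling the bound jitter.
#' @return A `toy_model_spec` list.
#' @export
toy_model_spec <- function(archetypes = c(
                             "essential", "unique_exporter", "internal_only",
                             "redundant_pair", "redundant_pair", "blocked"
                           ),
                           n_side_compounds = 3, n_decoys = 8, seed = 42) {
  known <- c("essential", "unique_exporter", "internal_only", "redundant_pair", "blocked")
  if (!length(archetypes)) abort("at least one pathway archetype is required")
  if (length(bad <- setdiff(archetypes, known))) {
    abort(paste0("unknown archetype(s): ", paste(bad, collapse = ", ")))
  }
  if (!"essential" %in% archetypes) {
    abort("the biomass reaction requires at least one essential pathway")
  }
  if (sum(archetypes == "redundant_pair") %% 2 != 0) {
    abort("redundant_pair archetypes must come in pairs")
  }
  structure(
    list(
      n_pathways = length(archetypes),
      archetypes = archetypes,
      n_side_compounds = n_side_compounds,
      n_decoys = n_decoys,
      seed = as.integer(seed)
    ),
    class = "toy_model_spec"
  )
}

#' Generate a toy model with ground-truth labels
#'
#' @param spec A [toy_model_spec()].
#' @return A list with `model` (a [metabolic_model()]) and `ground_truth`,
#'   a list of disjoint pathway-id sets: `essential_pathways` (knockout is
#'   infeasible), `blocked_pathways` (removed at pruning),
#'   `expected_tp_pathways` (unique exporters, detectable) and
#'   `expected_fn_pathways` (internal-only, undetectable).
#' @export
generate_toy_model <- function(spec = toy_model_spec()) {
  stopifnot(inherits(spec, "toy_model_spec"))

  mets <- list()
  rxns <- list()
  sto <- list()
  add_met <- function(base, comp) {
    id <- paste0(base, "_", comp)
    mets[[id]] <<- tibble(id = id, name = base, compartment = comp)
    id
  }
  add_rxn <- function(id, stoich, lb, ub, pathway = NA_character_) {
    rxns[[id]] <<- tibble(id = id, lower_bound = lb, upper_bound = ub, pathway_id = pathway)
    sto[[id]] <<- tibble(
      reaction_id = id, metabolite_id = names(stoich),
      coefficient = unname(stoich)
    )
  }

  transport_pw <- "Transport reactions"
  cats <- list(tibble(pathway_id = transport_pw, category = "Miscellaneous"))

  # common core: nutrient import and cofactor/water pools
  nut_e <- add_met("nut", "e")
  nut_c <- add_met("nut", "c")
  add_rxn("EX_nut", c(nut_e = -1), -1000, 1000)
  add_rxn("T_nut", setNames(c(-1, 1), c(nut_e, nut_c)), 0, 1000, transport_pw)
  atp <- add_met("atp", "c")
  adp <- add_met("adp", "c")
  h2o_c <- add_met("h2o", "c")
  h2o_e <- add_met("h2o", "e")
  add_rxn("T_h2o", setNames(c(-1, 1), c(h2o_c, h2o_e)), 0, 1000, transport_pw)
  add_rxn("EX_h2o", setNames(-1, h2o_e), 0, 1000)

  gt <- list(
    essential_pathways = character(), blocked_pathways = character(),
    expected_tp_pathways = character(), expected_fn_pathways = character()
  )
  precursors <- character()
  red_pair_state <- NULL
  cat_of <- c(
    essential = "Amino acid metabolism",
    unique_exporter = "Carbohydrate metabolism",
    internal_only = "Lipid metabolism",
    redundant_pair = "Nucleotide metabolism",
    blocked = "Lipid metabolism"
  )
  short_of <- c(
    essential = "essential_biosynthesis",
    unique_exporter = "unique_export",
    internal_only = "internal_cycle",
    redundant_pair = "redundant_route",
    blocked = "dead_end"
  )

  for (i in seq_along(spec$archetypes)) {
    arch <- spec$archetypes[[i]]
    pw <- sprintf("P%02d_%s", i, short_of[[arch]])
    cats[[length(cats) + 1]] <- tibble(pathway_id = pw, category = cat_of[[arch]])
    tag <- sprintf("p%02d", i)

    if (arch == "essential") {
      pe <- add_met(paste0("pe_", tag), "c")
      prec <- add_met(paste0("prec_", tag), "c")
      add_rxn(
        paste0("R_", tag, "_1"),
        setNames(c(-1, -1, 1, 1), c(nut_c, atp, pe, adp)), 0, 1000, pw
      )
      add_rxn(
        paste0("R_", tag, "_2"),
        setNames(c(-1, -1, 1, 1, 1), c(pe, adp, prec, atp, h2o_c)), 0, 1000, pw
      )
      precursors <- c(precursors, prec)
      gt$essential_pathways <- c(gt$essential_pathways, pw)
    } else if (arch == "unique_exporter") {
      s_e <- s_c <- character(4)
      for (k in 1:4) {
        s_e[k] <- add_met(paste0("s", k, "_", tag), "e")
        s_c[k] <- add_met(paste0("s", k, "_", tag), "c")
        add_rxn(paste0("EX_s", k, "_", tag), setNames(-1, s_e[k]), -1000, 1000)
        add_rxn(
          paste0("T_s", k, "_", tag), setNames(c(-1, 1), c(s_e[k], s_c[k])),
          0, 1000, transport_pw
        )
      }
      ui <- add_met(paste0("ui_", tag), "c")
      u_c <- add_met(paste0("u_", tag), "c")
      u_e <- add_met(paste0("u_", tag), "e")
      add_rxn(
        paste0("R_", tag, "_1"),
        setNames(c(-1, -1, 1), c(s_c[1], s_c[2], ui)), 2, 10, pw
      )
      add_rxn(
        paste0("R_", tag, "_2"),
        setNames(c(-1, -1, 1), c(ui, s_c[3], u_c)), 2, 10, pw
      )
      add_rxn(
        paste0("R_", tag, "_3"),
        setNames(c(-1, 1), c(s_c[4], u_c)), 2, 10, pw
      )
      add_rxn(
        paste0("T_u_", tag), setNames(c(-1, 1), c(u_c, u_e)), 0, 1000, pw
      )
      add_rxn(paste0("EX_u_", tag), setNames(-1, u_e), 0, 1000)
      gt$expected_tp_pathways <- c(gt$expected_tp_pathways, pw)
    } else if (arch == "internal_only") {
      x <- add_met(paste0("x_", tag), "c")
      y <- add_met(paste0("y_", tag), "c")
      add_rxn(
        paste0("R_", tag, "_1"),
        setNames(c(-1, -1, 1, 1), c(x, atp, y, adp)), 0, 10, pw
      )
      add_rxn(
        paste0("R_", tag, "_2"),
        setNames(c(-1, -1, 1, 1), c(y, adp, x, atp)), 0, 10, pw
      )
      gt$expected_fn_pathways <- c(gt$expected_fn_pathways, pw)
    } else if (arch == "redundant_pair") {
      if (is.null(red_pair_state)) {
        r_e <- add_met(paste0("r_", tag), "e")
        r_c <- add_met(paste0("r_", tag), "c")
        rr_c <- add_met(paste0("rr_", tag), "c")
        rr_e <- add_met(paste0("rr_", tag), "e")
        add_rxn(paste0("EX_r_", tag), setNames(-1, r_e), -1000, 1000)
        add_rxn(
          paste0("T_r_", tag), setNames(c(-1, 1), c(r_e, r_c)),
          0, 1000, transport_pw
        )
        add_rxn(
          paste0("T_rr_", tag), setNames(c(-1, 1), c(rr_c, rr_e)),
          0, 1000, transport_pw
        )
        add_rxn(paste0("EX_rr_", tag), setNames(-1, rr_e), 0, 1000)
        add_rxn(
          paste0("R_", tag, "_1"), setNames(c(-1, 1), c(r_c, rr_c)), 0, 10, pw
        )
        red_pair_state <- list(r_c = r_c, rr_c = rr_c)
      } else {
        add_rxn(
          paste0("R_", tag, "_1"),
          setNames(c(-1, 1), c(red_pair_state$r_c, red_pair_state$rr_c)),
          0, 10, pw
        )
        red_pair_state <- NULL
      }
    } else if (arch == "blocked") {
      d1 <- add_met(paste0("d1_", tag), "c")
      d2 <- add_met(paste0("d2_", tag), "c")
      add_rxn(paste0("R_", tag, "_1"), setNames(c(-1, 1), c(nut_c, d1)), 0, 10, pw)
      add_rxn(paste0("R_", tag, "_2"), setNames(c(-1, 1), c(d1, d2)), 0, 10, pw)
      gt$blocked_pathways <- c(gt$blocked_pathways, pw)
    }
  }

  # biomass consumes every essential precursor
  add_rxn("biomass", setNames(rep(-1, length(precursors)), precursors), 0, 1000)

  # decoy export chains: unannotated producers padding the background
  decoy_ub <- withr::with_seed(
    spec$seed,
    sample(8:12, spec$n_decoys, replace = TRUE)
  )
  for (k in seq_len(spec$n_decoys)) {
    w_c <- add_met(paste0("w", k), "c")
    w_e <- add_met(paste0("w", k), "e")
    add_rxn(paste0("R_w", k), setNames(c(-1, 1), c(nut_c, w_c)), 0, decoy_ub[[k]])
    add_rxn(
      paste0("T_w", k), setNames(c(-1, 1), c(w_c, w_e)), 0, 1000, transport_pw
    )
    add_rxn(paste0("EX_w", k), setNames(-1, w_e), 0, 1000)
  }

  side <- head(c("atp", "adp", "h2o"), spec$n_side_compounds)
  model <- metabolic_model(
    metabolites = bind_rows(mets),
    reactions = bind_rows(rxns),
    stoichiometry = bind_rows(sto),
    biomass_reaction_id = "biomass",
    compartments = "e",
    pathway_categories = bind_rows(cats),
    side_compounds = side
  )
  list(
    model = model,
    ground_truth = structure(gt, class = "toy_ground_truth"),
    side_compounds = side
  )
}

#' Write the toy fixture trio (SBML, side compounds, categories)
#'
#' Convenience wrapper emitting the three files [read_sbml_model()]
#' consumes.
#'
#' @param toy Output of [generate_toy_model()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem (default `"toy_model"`).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_toy_fixture <- function(toy, dir, stem = "toy_model") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sbml = file.path(dir, paste0(stem, ".xml")),
    side = file.path(dir, paste0(stem, "_side_compounds.txt")),
    categories = file.path(dir, paste0(stem, "_pathway_categories.tsv"))
  )
  write_sbml_model(toy$model, paths[["sbml"]])
  write_side_compounds(toy$side_compounds, paths[["side"]])
  write_pathway_categories(toy$model$pathway_categories, paths[["categories"]])
  invisible(paths)
}
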
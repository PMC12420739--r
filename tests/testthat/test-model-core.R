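test_that("metabolic_model derives base ids and flags exchanges", {
  m <- chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_equal(
    m$metabolites$base_id[match(c("a_e", "a_c"), m$metabolites$id)],
    c("a", "a")
  )
  expect_equal(m$reactions$is_exchange, c(TRUE, FALSE, FALSE))
  expect_equal(m$reactions$exchanged_metabolite[[1]], "a_e")
})

test_that("strip_compartment_suffix handles the common id conventions", {
  expect_equal(strip_compartment_suffix("glc_c", "c"), "glc")
  expect_equal(strip_compartment_suffix("glc[c]", "c"), "glc")
  expect_equal(strip_compartment_suffix("MAM01234c", "c"), "MAM01234")
  # never strip down to an empty id
  expect_equal(strip_compartment_suffix("c", "c"), "c")
})

test_that("import-written exchange reactions are flipped to export convention", {
  m <- metabolic_model(
    metabolites = tibble::tibble(id = c("b_e", "b_c"), compartment = c("e", "c")),
    reactions = tibble::tibble(
      id = c("EX_b", "T_b", "BIOMASS"),
      lower_bound = c(0, 0, 0), upper_bound = c(10, 1000, 1000),
      pathway_id = NA_character_
    ),
    stoichiometry = tibble::tibble(
      reaction_id = c("EX_b", "T_b", "T_b", "BIOMASS"),
      metabolite_id = c("b_e", "b_e", "b_c", "b_c"),
      coefficient = c(1, -1, 1, -1) # written as import: produces b_e
    ),
    biomass_reaction_id = "BIOMASS"
  )
  co <- m$stoichiometry$coefficient[m$stoichiometry$reaction_id == "EX_b"]
  expect_equal(co, -1)
  rx <- m$reactions[m$reactions$id == "EX_b", ]
  expect_equal(c(rx$lower_bound, rx$upper_bound), c(-10, 0))
})

test_that("duplicate exchange reactions for one metabolite warn", {
  expect_warning(
    metabolic_model(
      metabolites = tibble::tibble(id = c("b_e", "b_c"), compartment = c("e", "c")),
      reactions = tibble::tibble(
        id = c("EX_b1", "EX_b2", "T_b", "BIOMASS"),
        lower_bound = c(0, 0, 0, 0), upper_bound = c(10, 10, 1000, 1000),
        pathway_id = NA_character_
      ),
      stoichiometry = tibble::tibble(
        reaction_id = c("EX_b1", "EX_b2", "T_b", "T_b", "BIOMASS"),
        metabolite_id = c("b_e", "b_e", "b_e", "b_c", "b_c"),
        coefficient = c(-1, -1, -1, 1, -1)
      ),
      biomass_reaction_id = "BIOMASS"
    ),
    "merged by summation"
  )
})

test_that("model validation rejects structural violations", {
  m <- chain_model()
  bad <- m
  bad$reactions$lower_bound[1] <- 2000
  expect_error(validate_metabolic_model(bad), "lower_bound > upper_bound")
  bad <- m
  bad$biomass_reaction_id <- "nope"
  expect_error(validate_metabolic_model(bad), "not in model")
  bad <- m
  bad$stoichiometry$metabolite_id[1] <- "ghost"
  expect_error(validate_metabolic_model(bad), "unknown metabolites")
})

test_that("stoich_matrix reproduces the long table", {
  m <- chain_model()
  S <- stoich_matrix(m)
  expect_equal(dim(S), c(2, 3))
  expect_equal(S["a_e", "EX_a"], -1)
  expect_equal(S["a_c", "T_a"], 1)
  expect_equal(S["a_c", "BIOMASS"], -1)
  expect_equal(S["a_e", "BIOMASS"], 0)
})

test_that("FBA and FVA match the closed-form chain solution", {
  m <- chain_model()
  res <- fba(m)
  expect_equal(res$status, "optimal")
  expect_equal(res$value, 10)
  f <- fva(m)
  expect_equal(f$min[f$reaction_id == "EX_a"], -10)
  expect_equal(f$max[f$reaction_id == "EX_a"], 0)
  expect_equal(f$min[f$reaction_id == "BIOMASS"], 0)
  expect_equal(f$max[f$reaction_id == "BIOMASS"], 10)
})

test_that("solve_lp detects infeasibility and handles pinned variables", {
  m <- chain_model()
  # force production without supply: biomass lower bound above importable flux
  m$reactions$lower_bound[m$reactions$id == "BIOMASS"] <- 20
  expect_equal(fba(m)$status, "infeasible")
  # pin the transporter: the whole chain is forced to that flux
  m2 <- chain_model()
  m2$reactions$lower_bound[m2$reactions$id == "T_a"] <- 4
  m2$reactions$upper_bound[m2$reactions$id == "T_a"] <- 4
  res <- fba(m2)
  expect_equal(res$value, 4)
  expect_equal(res$fluxes$flux[res$fluxes$reaction_id == "EX_a"], -4)
})

test_that("blocked reactions are found and pruned with their pathway", {
  toy <- toy_fixture()
  gt_blocked_pw <- toy$ground_truth$blocked_pathways
  gt_blocked_rxn <- toy$model$reactions$id[
    !is.na(toy$model$reactions$pathway_id) &
      toy$model$reactions$pathway_id %in% gt_blocked_pw
  ]
  blocked <- find_blocked_reactions(toy$model)
  expect_setequal(blocked, gt_blocked_rxn)
  pruned <- pruned_toy()
  expect_false(any(blocked %in% pruned$reactions$id))
  expect_setequal(attr(pruned, "blocked_pathways"), gt_blocked_pw)
  expect_false(any(gt_blocked_pw %in% model_pathways(pruned)))
})

test_that("pathway sets and exchangeable background respect side compounds", {
  pruned <- pruned_toy()
  with_side <- metabolite_pathway_sets(pruned, include_side = TRUE)
  no_side <- metabolite_pathway_sets(pruned, include_side = FALSE)
  side <- pruned$metabolites$base_id[pruned$metabolites$is_side_compound]
  expect_true(any(with_side$metabolite %in% side))
  expect_false(any(no_side$metabolite %in% side))
  bg <- exchangeable_background(pruned)
  expect_true(all(bg %in% pruned$metabolites$base_id))
  # every background metabolite has an exchange reaction
  ex_met <- pruned$reactions$exchanged_metabolite[pruned$reactions$is_exchange]
  ex_base <- pruned$metabolites$base_id[match(ex_met, pruned$metabolites$id)]
  expect_setequal(bg, unique(ex_base))
})

test_that("SBML round-trip preserves the model", {
  toy <- toy_fixture()
  dir <- withr::local_tempdir()
  write_toy_fixture(toy, dir, "rt")
  m2 <- read_sbml_model(
    file.path(dir, "rt.xml"),
    side_compound_path = file.path(dir, "rt_side_compounds.txt"),
    category_path = file.path(dir, "rt_pathway_categories.tsv")
  )
  m1 <- toy$model
  expect_equal(
    dplyr::arrange(m2$metabolites, id),
    dplyr::arrange(m1$metabolites, id)
  )
  expect_equal(
    dplyr::arrange(m2$reactions, id),
    dplyr::arrange(m1$reactions, id)
  )
  expect_equal(
    dplyr::arrange(m2$stoichiometry, reaction_id, metabolite_id),
    dplyr::arrange(m1$stoichiometry, reaction_id, metabolite_id)
  )
  expect_identical(m2$biomass_reaction_id, m1$biomass_reaction_id)
  expect_equal(
    dplyr::arrange(m2$pathway_categories, pathway_id),
    dplyr::arrange(m1$pathway_categories, pathway_id)
  )
})

test_that("GMT, side-compound and category files round-trip", {
  dir <- withr::local_tempdir()
  sets <- make_sets(A = c("x", "y"), B = c("y", "z", "w"))
  gmt <- file.path(dir, "sets.gmt")
  write_gmt(sets, gmt)
  back <- read_gmt(gmt)
  expect_equal(
    dplyr::arrange(back, pathway_id, metabolite),
    dplyr::arrange(tibble::as_tibble(sets), pathway_id, metabolite),
    ignore_attr = TRUE
  )
  sc <- file.path(dir, "side.txt")
  write_side_compounds(c("atp", "h2o"), sc)
  expect_equal(read_side_compounds(sc), c("atp", "h2o"))
  ct <- file.path(dir, "cat.tsv")
  cats <- tibble::tibble(pathway_id = c("A", "B"), category = c("Lipid", "Miscellaneous"))
  write_pathway_categories(cats, ct)
  expect_equal(read_pathway_categories(ct), cats)
})
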
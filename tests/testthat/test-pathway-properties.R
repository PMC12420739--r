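test_that("exchangeable ratio counts only non-side metabolites", {
  sets <- make_sets(P = c("a", "b"), Q = c("c", "d"))
  r <- exchangeable_ratio(sets, background = c("a", "c", "d"))
  expect_equal(r$exchangeable_ratio[r$pathway_id == "P"], 0.5)
  expect_equal(r$exchangeable_ratio[r$pathway_id == "Q"], 1)
})

test_that("uniqueness scores match the hand-computed 1.25 case", {
  profiles <- tibble::tibble(
    scenario = c("s1", "s1", "s2", "s3", "s4", rep("s1", 1)),
    metabolite = c("m1", "m2", "m2", "m2", "m2", "m3"),
    z = c(3, 2.5, -2.2, 2.1, 2.8, 0.5)
  )
  u <- uniqueness_scores(profiles, thr = 2)
  # s1: m1 unique (1/1) + m2 shared by four scenarios (1/4) = 1.25
  expect_equal(u$uniqueness_score[u$scenario == "s1"], 1.25)
  expect_equal(u$n_thresholded[u$scenario == "s1"], 2L)
  expect_equal(u$uniqueness_score[u$scenario == "s2"], 0.25)
})

test_that("uniqueness conservation identity holds on arbitrary profiles", {
  set.seed(33)
  profiles <- tibble::tibble(
    scenario = rep(sprintf("s%d", 1:6), each = 12),
    metabolite = rep(sprintf("m%02d", 1:12), times = 6),
    z = rnorm(72, sd = 2)
  )
  u <- uniqueness_scores(profiles, thr = 2)
  n_distinct_thresholded <- length(unique(
    profiles$metabolite[abs(profiles$z) >= 2]
  ))
  expect_equal(sum(u$uniqueness_score), n_distinct_thresholded)
})

test_that("profiles with no thresholded metabolite score zero", {
  profiles <- tibble::tibble(
    scenario = c("s1", "s2"), metabolite = c("m1", "m1"), z = c(0.5, 3)
  )
  u <- uniqueness_scores(profiles, thr = 2)
  expect_equal(u$uniqueness_score[u$scenario == "s1"], 0)
  expect_equal(u$uniqueness_score[u$scenario == "s2"], 1)
})

test_that("graph statistics match the triangle closed form", {
  sets <- make_sets(
    A = c("ab", "ac"), B = c("ab", "bc"), C = c("ac", "bc")
  )
  g <- graph_statistics(build_pathway_graph(sets))
  expect_equal(g$clustering_coefficient, rep(1, 3))
  expect_equal(g$degree, rep(2, 3))
  expect_equal(g$neighbourhood_connectivity, rep(2, 3))
})

test_that("graph statistics match the star closed form", {
  sets <- make_sets(
    hub = c("h1", "h2", "h3", "h4"),
    L1 = c("h1", "x1"), L2 = c("h2", "x2"), L3 = c("h3", "x3"), L4 = c("h4", "x4")
  )
  g <- graph_statistics(build_pathway_graph(sets))
  hub <- g[g$pathway_id == "hub", ]
  expect_equal(hub$degree, 4)
  expect_equal(hub$clustering_coefficient, 0)
  expect_equal(hub$neighbourhood_connectivity, 1)
  leaves <- g[g$pathway_id != "hub", ]
  expect_equal(leaves$degree, rep(1, 4))
  expect_equal(leaves$neighbourhood_connectivity, rep(4, 4))
})

test_that("graph statistics match the 3-node path closed form", {
  sets <- make_sets(P1 = "a", P2 = c("a", "b"), P3 = "b")
  g <- graph_statistics(build_pathway_graph(sets))
  mid <- g[g$pathway_id == "P2", ]
  expect_equal(mid$clustering_coefficient, 0)
  expect_equal(mid$degree, 2)
  expect_equal(mid$neighbourhood_connectivity, 1)
})

test_that("edge weights are shared-set sizes, bounded by the smaller set", {
  sets <- make_sets(A = c("x", "y", "z"), B = c("x", "y", "w"), C = "q")
  pg <- build_pathway_graph(sets)
  expect_equal(nrow(pg$edges), 1)
  expect_equal(pg$edges$weight, 2)
  expect_lte(pg$edges$weight, 3)
  expect_error(build_pathway_graph(make_sets(A = "x")), "at least two")
})

test_that("side-compound-only overlap produces no edge", {
  m <- metabolic_model(
    metabolites = tibble::tibble(
      id = c("n_e", "n_c", "atp_c", "p_c", "q_c"),
      compartment = c("e", "c", "c", "c", "c")
    ),
    reactions = tibble::tibble(
      id = c("EX_n", "R1", "R2", "BIOMASS"),
      lower_bound = c(-10, 0, 0, 0), upper_bound = c(0, 10, 10, 10),
      pathway_id = c(NA, "P", "Q", NA)
    ),
    stoichiometry = tibble::tibble(
      reaction_id = c("EX_n", "R1", "R1", "R1", "R2", "R2", "R2", "BIOMASS", "BIOMASS"),
      metabolite_id = c(
        "n_e", "n_c", "atp_c", "p_c", "n_c", "atp_c", "q_c", "p_c", "q_c"
      ),
      coefficient = c(-1, -1, -1, 1, -1, -1, 1, -1, -1)
    ),
    biomass_reaction_id = "BIOMASS",
    side_compounds = "atp"
  )
  # P and Q share both n and the side compound atp
  with_side <- metabolite_pathway_sets(m, include_side = TRUE)
  no_side <- metabolite_pathway_sets(m, include_side = FALSE)
  expect_true("atp" %in% with_side$metabolite)
  expect_false("atp" %in% no_side$metabolite)
  # remove the genuinely shared metabolite to leave a side-only overlap
  only_side_shared <- no_side[no_side$metabolite != "n", ]
  pg <- build_pathway_graph(only_side_shared)
  expect_equal(nrow(pg$edges), 0)
})

test_that("ko_zscore_dispersion returns sd and IQR outliers", {
  profiles <- tibble::tibble(
    scenario = rep("s1", 3),
    metabolite = c("a", "b", "c"),
    z = c(-2, 0, 2)
  )
  sets <- make_sets(s1 = c("a", "b", "c"))
  d <- ko_zscore_dispersion(profiles, sets)
  expect_equal(d$sd, 2)
  expect_equal(d$n, 3L)
  expect_length(d$outliers[[1]], 0)
  flat <- ko_zscore_dispersion(
    tibble::tibble(scenario = "s1", metabolite = c("a", "b", "c"), z = c(0, 0, 0)),
    sets
  )
  expect_equal(flat$sd, 0)
  # empty intersection -> scenario absent
  none <- ko_zscore_dispersion(
    tibble::tibble(scenario = "s2", metabolite = "zz", z = 1), sets
  )
  expect_equal(nrow(none), 0)
})

test_that("compare_tp_fn matches the exhaustive rank-sum enumeration", {
  properties <- tibble::tibble(
    pathway_id = sprintf("p%d", 1:10),
    size = c(6:10, 1:5) # TP values all strictly above FN values
  )
  labels <- tibble::tibble(
    pathway_id = sprintf("p%d", 1:10),
    method = "ora",
    label = rep(c("TP", "FN"), each = 5)
  )
  out <- compare_tp_fn(properties, labels, metrics = "size")
  # exhaustive enumeration: complete separation, two-sided
  combos <- utils::combn(10, 5)
  vals <- properties$size
  w_obs <- sum(rank(vals)[1:5]) - 5 * 6 / 2
  w_all <- apply(combos, 2, function(i) sum(rank(vals)[i]) - 15)
  p_enum <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  expect_equal(out$p_raw, p_enum, tolerance = 1e-12)
  expect_equal(out$p_raw, 2 / choose(10, 5), tolerance = 1e-12)
  # single metric, single method: BH identity
  expect_equal(out$p_adjusted, out$p_raw)
})

test_that("compare_tp_fn is non-significant for identical distributions", {
  properties <- tibble::tibble(
    pathway_id = sprintf("p%d", 1:8),
    size = rep(c(1, 2, 3, 4), 2)
  )
  labels <- tibble::tibble(
    pathway_id = sprintf("p%d", 1:8),
    method = "ora",
    label = rep(c("TP", "FN"), each = 4)
  )
  out <- compare_tp_fn(properties, labels, metrics = "size")
  expect_gt(out$p_raw, 0.5)
  expect_error(
    compare_tp_fn(properties, dplyr::mutate(labels, label = "TP"),
      metrics = "size"
    ),
    "at least one TP and one FN"
  )
})

test_that("pathway_pca standardises, orders axes and fixes signs", {
  set.seed(9)
  base <- rnorm(10)
  properties <- tibble::tibble(
    pathway_id = sprintf("p%d", 1:10),
    size = base,
    degree = 2 * base + 5 # perfectly correlated: PC1 explains 100%
  )
  p <- pathway_pca(properties, metrics = c("size", "degree"))
  expect_equal(p$explained_proportion[[1]], 1, tolerance = 1e-12)
  expect_equal(sum(p$explained_variance), 2, tolerance = 1e-12)
  # sign convention: largest-magnitude loading positive
  l1 <- p$loadings$PC1
  expect_gt(l1[which.max(abs(l1))], 0)
  g <- glance(p)
  expect_equal(g$component, c("PC1", "PC2"))
  expect_equal(tidy(p), p$scores)
})

test_that("orthogonal standardised metrics give equal explained variance", {
  properties <- tibble::tibble(
    pathway_id = sprintf("p%d", 1:4),
    size = c(1, -1, 1, -1),
    degree = c(1, 1, -1, -1)
  )
  p <- pathway_pca(properties, metrics = c("size", "degree"))
  expect_equal(p$explained_variance[[1]], p$explained_variance[[2]],
    tolerance = 1e-12
  )
})

test_that("pathway_pca drops constant columns with a warning and needs 3 rows", {
  properties <- tibble::tibble(
    pathway_id = sprintf("p%d", 1:5),
    size = rnorm(5),
    degree = rnorm(5),
    uniqueness_score = 1
  )
  expect_warning(
    p <- pathway_pca(properties, metrics = c("size", "degree", "uniqueness_score")),
    "constant"
  )
  expect_false("uniqueness_score" %in% p$loadings$metric)
  expect_error(
    pathway_pca(properties[1:2, ], metrics = c("size", "degree")),
    "at least three"
  )
})

test_that("compute_pathway_properties assembles all six metrics on the toy model", {
  pruned <- pruned_toy()
  sim <- run_all_scenarios(pruned, n_samples = 150, seed = 3, thinning = 5)
  props <- compute_pathway_properties(pruned, sim$profiles)
  expect_setequal(props$pathway_id, model_pathways(pruned))
  expect_named(
    props,
    c(
      "pathway_id", "size", "exchangeable_ratio", "uniqueness_score",
      "clustering_coefficient", "degree", "neighbourhood_connectivity"
    )
  )
  toy <- toy_fixture()
  fn <- toy$ground_truth$expected_fn_pathways
  expect_equal(props$exchangeable_ratio[props$pathway_id == fn], 0)
  expect_true(all(props$size >= 1))
})
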
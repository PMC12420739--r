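#' Exchangeable metabolite ratio per pathway
#'
#' Fraction of a pathway's metabolites (side compounds excluded from both
#' numerator and denominator) that have an exchange reaction somewhere in
#' the network. Pathways with no non-side metabolite get `NA`.
#'
#' @param sets_no_side `metabolite_pathway_sets` built with
#'   `include_side = FALSE`.
#' @param background Exchangeable base ids, from
#'   [exchangeable_background()].
#' @return Tibble with `pathway_id`, `exchangeable_ratio`.
#' @export
exchangeable_ratio <- function(sets_no_side, background) {
  if (isTRUE(attr(sets_no_side, "side_compounds_included"))) {
    warn("exchangeable_ratio expects side compounds to be excluded from the sets")
  }
  sets_no_side %>%
    group_by(pathway_id = .data$pathway_id) %>%
    summarise(
      exchangeable_ratio = length(intersect(.data$metabolite, background)) /
        dplyr::n_distinct(.data$metabolite)
    )
}

#' Knockout-profile uniqueness scores
#'
#' For each knockout profile, keeps the metabolites passing the z-score
#' threshold (`|z| >= thr`) and scores the profile as the sum over those
#' metabolites of `1 / n_m`, where `n_m` is the number of profiles whose
#' thresholded set contains the metabolite. Unique metabolites contribute 1,
#' widely shared ones little; a profile with no thresholded metabolite
#' scores 0.
#'
#' @param profiles Tibble of all scenario profiles (`scenario`,
#'   `metabolite`, `z`).
#' @param thr z-score threshold (default 2).
#' @return Tibble with `scenario`, `n_thresholded`, `uniqueness_score`.
#' @export
uniqueness_scores <- function(profiles, thr = 2) {
  passed <- filter(profiles, abs(.data$z) >= thr) %>%
    distinct(.data$scenario, .data$metabolite)
  counts <- count(passed, .data$metabolite, name = "n_m")
  scored <- passed %>%
    left_join(counts, by = "metabolite") %>%
    group_by(scenario = .data$scenario) %>%
    summarise(
      n_thresholded = dplyr::n(),
      uniqueness_score = sum(1 / .data$n_m)
    )
  profiles %>%
    distinct(scenario = .data$scenario) %>%
    left_join(scored, by = "scenario") %>%
    mutate(
      n_thresholded = dplyr::coalesce(.data$n_thresholded, 0L),
      uniqueness_score = dplyr::coalesce(.data$uniqueness_score, 0)
    )
}

#' Pathway-overlap graph
#'
#' Nodes are pathways; two pathways are connected when they share at least
#' one non-side metabolite, with the number of shared metabolites as the
#' edge weight.
#'
#' @param sets_no_side `metabolite_pathway_sets` with side compounds
#'   excluded.
#' @return A `pathway_graph`: list with `graph` (undirected igraph, weight
#'   attribute) and `edges` (tibble `from`, `to`, `weight`).
#' @export
build_pathway_graph <- function(sets_no_side) {
  pws <- sort(unique(sets_no_side$pathway_id))
  if (length(pws) < 2) abort("need at least two pathways to build the overlap graph")
  lst <- sets_as_list(sets_no_side)
  pairs <- utils::combn(pws, 2)
  weight <- vapply(
    seq_len(ncol(pairs)),
    function(j) length(intersect(lst[[pairs[1, j]]], lst[[pairs[2, j]]])),
    numeric(1)
  )
  edges <- tibble(from = pairs[1, ], to = pairs[2, ], weight = weight) %>%
    filter(.data$weight >= 1)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = pws)
  structure(list(graph = g, edges = edges), class = "pathway_graph")
}

#' Unweighted graph statistics per pathway
#'
#' Local clustering coefficient (`2 * triangles / (deg * (deg - 1))`, 0 for
#' degree < 2), node degree, and neighbourhood connectivity (mean degree of
#' the node's neighbours, 0 for isolated nodes). Statistics are computed on
#' the unweighted topology; weights are kept for export only.
#'
#' @param pg A [build_pathway_graph()] result (or an igraph).
#' @return Tibble with `pathway_id`, `clustering_coefficient`, `degree`,
#'   `neighbourhood_connectivity`.
#' @export
graph_statistics <- function(pg) {
  g <- if (inherits(pg, "pathway_graph")) pg$graph else pg
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  nc <- igraph::knn(g, weights = NA)$knn
  nc[!is.finite(nc)] <- 0
  tibble(
    pathway_id = igraph::V(g)$name,
    clustering_coefficient = unname(cc),
    degree = unname(deg),
    neighbourhood_connectivity = unname(nc)
  ) %>% arrange(.data$pathway_id)
}

#' z-score dispersion of a knockout pathway's own metabolites
#'
#' For each scenario, extracts the z-scores of the knocked-out pathway's own
#' metabolites present in the profile, their sample standard deviation, and
#' the boxplot outliers (beyond 1.5 x IQR from the quartiles). Scenarios
#' whose pathway set does not intersect the profile are omitted.
#'
#' @param profiles Tibble of scenario profiles (`scenario`, `metabolite`,
#'   `z`).
#' @param sets `metabolite_pathway_sets` (as fed to enrichment, side
#'   compounds included).
#' @return Tibble with `scenario`, `n`, `sd`, and list-columns `z` and
#'   `outliers`.
#' @export
ko_zscore_dispersion <- function(profiles, sets) {
  profiles %>%
    inner_join(
      rename(sets, scenario = "pathway_id"),
      by = c("scenario", "metabolite")
    ) %>%
    group_by(scenario = .data$scenario) %>%
    summarise(
      n = dplyr::n(),
      sd = stats::sd(.data$z),
      outliers = list({
        q <- stats::quantile(.data$z, c(0.25, 0.75), names = FALSE)
        fence <- 1.5 * (q[2] - q[1])
        .data$metabolite[.data$z < q[1] - fence | .data$z > q[2] + fence]
      }),
      z = list(.data$z)
    ) %>%
    select("scenario", "n", "sd", "z", "outliers")
}

#' Assemble the six intrinsic pathway properties
#'
#' Pathway size (metabolite count, side compounds included by default),
#' exchangeable ratio, knockout-profile uniqueness score, and the three
#' overlap-graph statistics, one row per pathway.
#'
#' @param m A pruned `metabolic_model`.
#' @param profiles Scenario profiles (for the uniqueness score); pathways
#'   without a profile get `NA`.
#' @param thr Uniqueness z threshold (default 2).
#' @param size_include_side Count side compounds in the pathway size
#'   (default `TRUE`).
#' @return Tibble with `pathway_id`, `size`, `exchangeable_ratio`,
#'   `uniqueness_score`, `clustering_coefficient`, `degree`,
#'   `neighbourhood_connectivity`.
#' @export
compute_pathway_properties <- function(m, profiles, thr = 2,
                                       size_include_side = TRUE) {
  sets_side <- metabolite_pathway_sets(m, include_side = TRUE)
  sets_nos <- metabolite_pathway_sets(m, include_side = FALSE)
  bg <- exchangeable_background(m)
  size_sets <- if (size_include_side) sets_side else sets_nos
  sizes <- count(size_sets, pathway_id = .data$pathway_id, name = "size")
  uniq <- uniqueness_scores(profiles, thr = thr) %>%
    select(pathway_id = "scenario", "uniqueness_score")
  sizes %>%
    left_join(exchangeable_ratio(sets_nos, bg), by = "pathway_id") %>%
    left_join(uniq, by = "pathway_id") %>%
    left_join(graph_statistics(build_pathway_graph(sets_nos)), by = "pathway_id") %>%
    arrange(.data$pathway_id)
}

#' Compare pathway properties between TP and FN pathways
#'
#' Two-sided Wilcoxon rank-sum test per property and method, with
#' Benjamini-Hochberg adjustment across the whole property x method family.
#'
#' @param properties A [compute_pathway_properties()] tibble.
#' @param labels Tibble with `pathway_id`, `method`, `label` (`"TP"` or
#'   `"FN"`); other labels are dropped.
#' @param metrics Property columns to test (default: the six).
#' @return Tibble with `metric`, `method`, `statistic`, `p_raw`,
#'   `p_adjusted`.
#' @export
compare_tp_fn <- function(properties, labels,
                          metrics = c(
                            "size", "exchangeable_ratio", "uniqueness_score",
                            "clustering_coefficient", "degree",
                            "neighbourhood_connectivity"
                          )) {
  labels <- filter(labels, .data$label %in% c("TP", "FN"))
  if (dplyr::n_distinct(labels$label) < 2) {
    abort("need at least one TP and one FN pathway to compare")
  }
  long <- properties %>%
    tidyr::pivot_longer(all_of(metrics), names_to = "metric") %>%
    inner_join(labels, by = "pathway_id", relationship = "many-to-many")
  out <- long %>%
    group_by(.data$metric, .data$method) %>%
    summarise(
      res = list({
        tp <- .data$value[.data$label == "TP"]
        fn <- .data$value[.data$label == "FN"]
        if (!length(tp) || !length(fn) || all(is.na(tp)) || all(is.na(fn))) {
          tibble(statistic = NA_real_, p_raw = NA_real_)
        } else {
          w <- suppressWarnings(stats::wilcox.test(tp, fn, alternative = "two.sided"))
          tibble(statistic = unname(w$statistic), p_raw = w$p.value)
        }
      }),
      .groups = "drop"
    ) %>%
    tidyr::unnest("res")
  out$p_adjusted <- p.adjust(out$p_raw, method = "BH")
  out
}

#' PCA of pathway properties
#'
#' Standardises each property to zero mean and unit variance (constant
#' columns are dropped with a warning), extracts principal axes by
#' descending explained variance, and fixes each axis' sign so its
#' largest-magnitude loading is positive.
#'
#' @param properties A [compute_pathway_properties()] tibble; rows with
#'   missing metrics are dropped.
#' @param metrics Columns to include (default: the six).
#' @return A `pathway_pca` object: `scores` (tibble with `pathway_id` and
#'   `PC*` columns), `loadings`, `explained_variance`,
#'   `explained_proportion`.
#' @export
pathway_pca <- function(properties,
                        metrics = c(
                          "size", "exchangeable_ratio", "uniqueness_score",
                          "clustering_coefficient", "degree",
                          "neighbourhood_connectivity"
                        )) {
  dat <- properties %>%
    select("pathway_id", all_of(metrics)) %>%
    tidyr::drop_na()
  if (nrow(dat) < 3) abort("need at least three pathways with complete metrics")
  X <- as.matrix(dat[, metrics])
  keep <- apply(X, 2, sd) > 0
  if (!all(keep)) {
    warn(paste0(
      "dropping constant propert",
      if (sum(!keep) > 1) "ies: " else "y: ",
      paste(metrics[!keep], collapse = ", ")
    ))
  }
  X <- scale(X[, keep, drop = FALSE])
  p <- prcomp(X, center = FALSE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  p$rotation <- sweep(p$rotation, 2, flip, `*`)
  p$x <- sweep(p$x, 2, flip, `*`)
  structure(
    list(
      scores = bind_cols(tibble(pathway_id = dat$pathway_id), as_tibble(p$x)),
      loadings = bind_cols(
        tibble(metric = rownames(p$rotation)), as_tibble(p$rotation)
      ),
      explained_variance = p$sdev^2,
      explained_proportion = p$sdev^2 / sum(p$sdev^2)
    ),
    class = "pathway_pca"
  )
}

#' @export
print.pathway_pca <- function(x, ...) {
  cat(
    "<pathway_pca> ", nrow(x$scores), " pathways, ",
    length(x$explained_variance), " axes; PC1 explains ",
    round(100 * x$explained_proportion[[1]], 1), "% of variance\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn pathway_pca Pathway coordinates on the principal axes.
#' @param x A `pathway_pca`.
#' @param ... Unused.
#' @export
tidy.pathway_pca <- function(x, ...) x$scores

#' @describeIn pathway_pca One row per axis with explained variance.
#' @export
glance.pathway_pca <- function(x, ...) {
  tibble(
    component = paste0("PC", seq_along(x$explained_variance)),
    explained_variance = x$explained_variance,
    explained_proportion = x$explained_proportion
  )
}

#' Export a pathway graph
#'
#' Writes the weighted edge list as TSV and, optionally, GraphML.
#'
#' @param pg A `pathway_graph`.
#' @param path Output TSV path.
#' @param graphml_path Optional GraphML output path.
#' @return `path`, invisibly.
#' @export
write_pathway_graph <- function(pg, path, graphml_path = NULL) {
  readr::write_tsv(pg$edges, path)
  if (!is.null(graphml_path)) {
    igraph::write_graph(pg$graph, graphml_path, format = "graphml")
  }
  invisible(path)
}
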
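#' Knock out a pathway
#'
#' Sets the flux bounds of every reaction annotated to the pathway to
#' `[0, 0]`; the input model is left untouched. Idempotent.
#'
#' @param m A `metabolic_model`.
#' @param pathway_id Pathway to knock out.
#' @return A modified copy of `m`.
#' @export
knockout_pathway <- function(m, pathway_id) {
  idx <- !is.na(m$reactions$pathway_id) & m$reactions$pathway_id == pathway_id
  if (!any(idx)) abort(paste0("unknown or empty pathway: ", pathway_id))
  m$reactions$lower_bound[idx] <- 0
  m$reactions$upper_bound[idx] <- 0
  m
}

#' Classify knockout feasibility against the biomass floor
#'
#' A knockout state is `"infeasible"` when its maximal biomass flux falls
#' below `floor_fraction` of the wild-type maximum (or the LP itself is
#' infeasible); otherwise `"functional"`.
#'
#' @param ko_model The knocked-out `metabolic_model`.
#' @param wt_max_biomass Wild-type maximal biomass flux (must be > 0).
#' @param floor_fraction Biomass floor as a fraction of the wild-type
#'   maximum (default 0.1).
#' @return `"functional"` or `"infeasible"`, with the achieved
#'   biomass ratio as attribute `"biomass_ratio"`.
#' @export
classify_feasibility <- function(ko_model, wt_max_biomass, floor_fraction = 0.1) {
  stopifnot(wt_max_biomass > 0, floor_fraction >= 0, floor_fraction <= 1)
  res <- fba(ko_model)
  if (res$status == "infeasible") {
    return(structure("infeasible", biomass_ratio = NA_real_))
  }
  ratio <- res$value / wt_max_biomass
  structure(
    if (ratio < floor_fraction) "infeasible" else "functional",
    biomass_ratio = ratio
  )
}

#' Sample steady-state fluxes with artificially-centred hit-and-run
#'
#' Draws approximately uniform points from the constrained flux polytope
#' `{v : S v = 0, lb <= v <= ub, v_biomass >= biomass_floor}`. Warmup points
#' are the flux-variability optima; chain directions run from the current
#' point towards a randomly chosen previously seen point, reflected through
#' the running centre, and every accepted point is re-projected onto the
#' steady-state null space to stop numerical drift.
#'
#' @param m A `metabolic_model`, feasible at the floor.
#' @param n_samples Number of recorded samples (>= 2).
#' @param seed Integer seed; fixed seed gives identical matrices.
#' @param biomass_floor Lower bound imposed on the biomass flux (default:
#'   0.1 x the model's maximal biomass).
#' @param thinning Chain steps between recorded samples (default 100).
#' @return A `flux_sample_set`: list with `reaction_ids`, `samples`
#'   (`n_samples` x reactions matrix), `seed`, `n_samples`,
#'   `biomass_floor`.
#' @export
sample_fluxes <- function(m, n_samples = 5000, seed = 1, biomass_floor = NULL,
                          thinning = 100) {
  stopifnot(n_samples >= 2, thinning >= 1)
  if (is.null(biomass_floor)) {
    opt <- fba(m)
    if (opt$status != "optimal") abort("model is infeasible; cannot sample")
    biomass_floor <- 0.1 * opt$value
  }
  check <- fba(m, biomass_floor = biomass_floor)
  if (check$status != "optimal") {
    abort("flux polytope is empty at the requested biomass floor")
  }

  fv <- fva(m, biomass_floor = biomass_floor, keep_solutions = TRUE)
  warmup <- attr(fv, "solutions")
  if (anyNA(warmup)) abort("flux sampler warmup failed: incomplete FVA vertices")

  S <- stoich_matrix(m)
  lb <- m$reactions$lower_bound
  ub <- m$reactions$upper_bound
  bi <- match(m$biomass_reaction_id, m$reactions$id)
  lb[bi] <- max(lb[bi], biomass_floor)
  n <- length(lb)

  N <- MASS::Null(t(S))
  project <- function(v) if (ncol(N)) as.vector(N %*% crossprod(N, v)) else numeric(n)
  warmup <- t(apply(warmup, 1, function(v) pmin(pmax(project(v), lb), ub)))

  samples <- matrix(NA_real_, n_samples, n, dimnames = list(NULL, m$reactions$id))
  withr::with_seed(seed, {
    x <- colMeans(warmup)
    center <- x
    n_seen <- nrow(warmup)
    pool <- warmup
    pool_n <- nrow(pool)
    recorded <- 0L
    step <- 0L
    max_steps <- n_samples * thinning * 10 # safety cap for degenerate polytopes
    while (recorded < n_samples && step < max_steps) {
      step <- step + 1L
      d <- pool[sample.int(pool_n, 1L), ] - center
      nd <- sqrt(sum(d^2))
      moved <- FALSE
      if (nd > 1e-10) {
        d <- d / nd
        pos <- d > 1e-11
        neg <- d < -1e-11
        tmax <- suppressWarnings(min((ub[pos] - x[pos]) / d[pos], (lb[neg] - x[neg]) / d[neg]))
        tmin <- suppressWarnings(max((lb[pos] - x[pos]) / d[pos], (ub[neg] - x[neg]) / d[neg]))
        if (is.finite(tmax) && is.finite(tmin) && tmax - tmin > 1e-10) {
          x <- x + runif(1, tmin, tmax) * d
          moved <- TRUE
        }
      }
      n_seen <- n_seen + 1
      center <- center + (x - center) / n_seen
      if (step %% 50L == 0L || !moved) {
        x <- pmin(pmax(project(x), lb), ub)
      }
      if (step %% thinning == 0L) {
        recorded <- recorded + 1L
        xr <- pmin(pmax(project(x), lb), ub)
        samples[recorded, ] <- xr
        if (pool_n < 200L) {
          pool <- rbind(pool, xr)
          pool_n <- pool_n + 1L
        }
      }
    }
    if (recorded < n_samples) {
      # fully pinned polytope (a single point): repeat the projected point
      xr <- pmin(pmax(project(x), lb), ub)
      for (k in (recorded + 1L):n_samples) samples[k, ] <- xr
    }
  })

  structure(
    list(
      reaction_ids = m$reactions$id,
      samples = samples,
      seed = as.integer(seed),
      n_samples = as.integer(n_samples),
      biomass_floor = biomass_floor
    ),
    class = "flux_sample_set"
  )
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat(
    "<flux_sample_set> ", x$n_samples, " samples x ", length(x$reaction_ids),
    " reactions (seed ", x$seed, ", biomass floor ",
    signif(x$biomass_floor, 4), ")\n",
    sep = ""
  )
  invisible(x)
}

# exchange fluxes per base metabolite id; duplicate exchanges for one
# metabolite are merged by summation
exchange_flux_matrix <- function(fs, m) {
  ex <- filter(m$reactions, .data$is_exchange)
  base <- m$metabolites$base_id[match(ex$exchanged_metabolite, m$metabolites$id)]
  cols <- fs$samples[, ex$id, drop = FALSE]
  groups <- split(seq_along(base), base)
  out <- vapply(
    groups,
    function(j) rowSums(cols[, j, drop = FALSE]),
    numeric(nrow(cols))
  )
  out[, sort(colnames(out)), drop = FALSE]
}

#' Exometabolomic z-score profile between two sampled states
#'
#' For each exchangeable metabolite, compares the sampled exchange fluxes of
#' a knockout state against the wild type:
#' `z = (mean_KO - mean_WT) / sqrt((sd_WT^2 + sd_KO^2) / 2)`, clipped to
#' `±z_max`. Positive z means more of the metabolite in the medium
#' (increased export or decreased import). When both states have zero
#' variance, z is 0 for equal means and `±z_max` (flagged in the `clipped`
#' column) for unequal means.
#'
#' @param wt,ko `flux_sample_set`s for the wild-type and knockout states of
#'   the same model (shared reaction ordering).
#' @param m The `metabolic_model` the states derive from.
#' @param z_max Clipping bound for z (default 50).
#' @return A tibble of class `zscore_profile` with columns `metabolite`
#'   (base id), `z`, `clipped`.
#' @export
compute_zscores <- function(wt, ko, m, z_max = 50) {
  if (!identical(wt$reaction_ids, ko$reaction_ids)) {
    abort("WT and KO sample sets must share the same reaction ordering")
  }
  W <- exchange_flux_matrix(wt, m)
  K <- exchange_flux_matrix(ko, m)
  mw <- colMeans(W)
  mk <- colMeans(K)
  vw <- apply(W, 2, var)
  vk <- apply(K, 2, var)
  pooled <- sqrt((vw + vk) / 2)
  z <- ifelse(pooled > 0, (mk - mw) / pooled,
    ifelse(abs(mk - mw) <= 1e-12, 0, sign(mk - mw) * z_max)
  )
  clipped <- abs(z) > z_max | (pooled == 0 & z != 0)
  z <- pmin(pmax(z, -z_max), z_max)
  structure(
    tibble(
      metabolite = colnames(W), z = unname(z), clipped = unname(clipped)
    ),
    class = c("zscore_profile", class(tibble())),
    n_wt = wt$n_samples, n_ko = ko$n_samples
  )
}

#' Deterministic per-scenario seed
#'
#' Derives an order-independent sampler seed from the run seed and the
#' pathway id, kept below 2^31.
#'
#' @param seed Integer run seed.
#' @param pathway_id Pathway id string.
#' @return Integer seed.
#' @export
scenario_seed <- function(seed, pathway_id) {
  h <- 0
  for (c in utf8ToInt(pathway_id)) h <- (h * 31 + c) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 48271) %% 2147483647)
}

#' Run every pathway-knockout scenario
#'
#' Knocks out each non-miscellaneous pathway in turn, classifies
#' feasibility against the biomass floor, and, for functional knockouts,
#' samples the knockout state and computes its z-score profile against one
#' shared wild-type sample set. Pathways removed at pruning are reported
#' with status `"blocked"`; Miscellaneous-category pathways with
#' `"excluded_miscellaneous"`.
#'
#' @param m A pruned `metabolic_model`.
#' @param n_samples Samples per state.
#' @param seed Run seed; each scenario derives its own via
#'   [scenario_seed()].
#' @param floor_fraction Biomass floor fraction (default 0.1).
#' @param thinning Sampler thinning.
#' @param z_max z clipping bound.
#' @param blocked_pathways Pathway ids removed at pruning (default: the
#'   `blocked_pathways` attribute left by [prune_model()]).
#' @return A list of class `ko_simulation` with `profiles` (tibble:
#'   `scenario`, `metabolite`, `z`, `clipped`), `ledger` (tibble:
#'   `pathway_id`, `status`, `n_reactions`, `biomass_ratio`, `seed`), and
#'   `wt` (the wild-type `flux_sample_set`).
#' @export
run_all_scenarios <- function(m, n_samples = 5000, seed = 1,
                              floor_fraction = 0.1, thinning = 100,
                              z_max = 50,
                              blocked_pathways = attr(m, "blocked_pathways")) {
  wt_opt <- fba(m)
  if (wt_opt$status != "optimal" || wt_opt$value <= 0) {
    abort("wild-type model cannot produce biomass")
  }
  floor <- floor_fraction * wt_opt$value
  wt <- sample_fluxes(m, n_samples, seed = seed, biomass_floor = floor, thinning = thinning)

  misc <- miscellaneous_pathways(m)
  pws <- model_pathways(m)
  ledger <- list()
  profiles <- list()

  for (pw in setdiff(pws, misc)) {
    ko <- knockout_pathway(m, pw)
    status <- classify_feasibility(ko, wt_opt$value, floor_fraction)
    ratio <- attr(status, "biomass_ratio")
    sseed <- scenario_seed(seed, pw)
    row <- tibble(
      pathway_id = pw, status = as.character(status),
      n_reactions = sum(!is.na(m$reactions$pathway_id) & m$reactions$pathway_id == pw),
      biomass_ratio = ratio, seed = sseed
    )
    if (status == "functional") {
      ks <- sample_fluxes(ko, n_samples,
        seed = sseed, biomass_floor = floor, thinning = thinning
      )
      profiles[[pw]] <- mutate(
        compute_zscores(wt, ks, m, z_max = z_max),
        scenario = pw, .before = 1
      )
    }
    ledger[[pw]] <- row
  }
  for (pw in misc) {
    ledger[[pw]] <- tibble(
      pathway_id = pw, status = "excluded_miscellaneous",
      n_reactions = sum(!is.na(m$reactions$pathway_id) & m$reactions$pathway_id == pw),
      biomass_ratio = NA_real_, seed = NA_integer_
    )
  }
  for (pw in blocked_pathways %||% character()) {
    ledger[[pw]] <- tibble(
      pathway_id = pw, status = "blocked", n_reactions = 0L,
      biomass_ratio = NA_real_, seed = NA_integer_
    )
  }

  structure(
    list(
      profiles = bind_rows(profiles),
      ledger = arrange(bind_rows(ledger), .data$pathway_id),
      wt = wt,
      floor = floor,
      seed = as.integer(seed)
    ),
    class = "ko_simulation"
  )
}

#' @export
print.ko_simulation <- function(x, ...) {
  cat("<ko_simulation> ", dplyr::n_distinct(x$profiles$scenario),
    " profiles; scenario statuses:\n",
    sep = ""
  )
  print(table(x$ledger$status))
  invisible(x)
}
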
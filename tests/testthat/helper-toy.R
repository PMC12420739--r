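# Shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

toy_fixture <- function() {
  if (is.null(.cache$toy)) .cache$toy <- generate_toy_model(toy_model_spec())
  .cache$toy
}

pruned_toy <- function() {
  if (is.null(.cache$pruned)) {
    m <- toy_fixture()$model
    .cache$pruned <- prune_model(m, find_blocked_reactions(m))
  }
  .cache$pruned
}

# Minimal linear chain: import a, transport it in, burn it as biomass.
# Closed-form FVA: v_EX in [-10, 0], v_T and v_B in [0, 10].
chain_model <- function() {
  metabolic_model(
    metabolites = tibble::tibble(
      id = c("a_e", "a_c"), compartment = c("e", "c")
    ),
    reactions = tibble::tibble(
      id = c("EX_a", "T_a", "BIOMASS"),
      lower_bound = c(-10, 0, 0),
      upper_bound = c(1000, 1000, 1000),
      pathway_id = c(NA, "transport", NA)
    ),
    stoichiometry = tibble::tibble(
      reaction_id = c("EX_a", "T_a", "T_a", "BIOMASS"),
      metabolite_id = c("a_e", "a_e", "a_c", "a_c"),
      coefficient = c(-1, -1, 1, -1)
    ),
    biomass_reaction_id = "BIOMASS"
  )
}

# Wrap a raw sample matrix as a flux_sample_set (for z-score unit tests).
as_sample_set <- function(samples, m, n_samples = nrow(samples)) {
  structure(
    list(
      samples = samples, reaction_ids = m$reactions$id,
      n_samples = n_samples, seed = NA_integer_, biomass_floor = NA_real_
    ),
    class = "flux_sample_set"
  )
}

# Pathway sets tibble without going through a model.
make_sets <- function(...) {
  lst <- list(...)
  out <- tibble::tibble(
    pathway_id = rep(names(lst), lengths(lst)),
    metabolite = unlist(lst, use.names = FALSE)
  )
  structure(out,
    class = c("metabolite_pathway_sets", class(tibble::tibble())),
    side_compounds_included = FALSE
  )
}

# Independent exhaustive hypergeometric right tail (oracle).
hyper_tail_oracle <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Independent step-by-step KS running-sum enumeration (oracle). Returns the
# first-attained extreme of the running sum, with the positive and negative
# extremes attached so callers can detect magnitude ties (at an exact tie
# the sign of the enrichment score is a convention, not a property).
es_oracle <- function(scores, members, weight_exponent = 1) {
  hit <- names(scores) %in% members
  k <- sum(hit)
  n <- length(scores)
  w <- abs(scores)^weight_exponent
  total <- sum(w[hit])
  running <- 0
  best <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(n)) {
    running <- if (hit[i]) {
      running + (if (total > 0) w[i] / total else 1 / k)
    } else {
      running - 1 / (n - k)
    }
    if (abs(running) > abs(best)) best <- running
    hi <- max(hi, running)
    lo <- min(lo, running)
  }
  structure(unname(best), hi = hi, lo = lo)
}

# TRUE when the positive and negative running-sum extremes tie in magnitude
# to floating-point resolution, making the ES sign convention-dependent.
es_sign_tied <- function(oracle, tol = 1e-9) {
  abs(abs(attr(oracle, "hi")) - abs(attr(oracle, "lo"))) < tol
}
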
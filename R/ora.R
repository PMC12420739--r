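#' Convert a z-score to a p-value via the normal survival function
#'
#' `p = 1 - Phi(z)`: only metabolites with strongly increased medium levels
#' reach small p-values under the signed default.
#'
#' @param z Numeric vector of z-scores.
#' @return Numeric vector of p-values.
#' @export
zscore_to_pvalue <- function(z) {
  stats::pnorm(z, lower.tail = FALSE)
}

#' Right-tailed Fisher's exact test from 2x2 counts
#'
#' Exact hypergeometric tail probability `P(X >= k)` of drawing at least
#' `k` in-pathway metabolites when `n` significant metabolites are drawn
#' from a background of `N` containing `K` in-pathway members.
#'
#' @param k Significant metabolites in the pathway.
#' @param K Background metabolites in the pathway.
#' @param n Significant metabolites in total.
#' @param N Background size.
#' @return The exact right-tail p-value.
#' @export
fisher_right_tail <- function(k, K, n, N) {
  if (k > min(K, n) || K > N || n > N || k < 0) {
    abort("inconsistent contingency counts: need k <= min(K, n) and K, n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a z-score profile
#'
#' Applies the benchmark's ORA parameterisation: metabolite p-values from
#' the normal survival function of the signed z-score (switchable to `|z|`
#' via `da_stat`), thresholded at `alpha_da` with no multiple-testing
#' correction to form the differentially abundant (DA) set; each pathway is
#' testable only when it contains at least `min_hits` DA metabolites, and
#' testable pathways get a right-tailed Fisher's exact p-value against the
#' exchangeable background.
#'
#' @param profile A `zscore_profile` tibble (`metabolite`, `z`), keys within
#'   the background.
#' @param sets `metabolite_pathway_sets` (side compounds included).
#' @param background Character vector of background base ids.
#' @param alpha_da DA threshold on the metabolite p-value (default 0.05).
#' @param min_hits Minimum DA metabolites for a pathway to be testable
#'   (default 3).
#' @param da_stat `"signed"` (default, as the survival function is written)
#'   or `"abs"` to call decreases DA as well.
#' @return An `enrichment_result` tibble: `method`, `pathway_id`,
#'   `testable`, `n_hits`, `n_background`, `p_value` (NA when not
#'   testable).
#' @export
run_ora <- function(profile, sets, background, alpha_da = 0.05, min_hits = 3,
                    da_stat = c("signed", "abs")) {
  da_stat <- match.arg(da_stat)
  if (!length(background)) abort("empty background set")
  extra <- setdiff(profile$metabolite, background)
  if (length(extra)) {
    abort("profile contains metabolites outside the background")
  }
  stat <- if (da_stat == "abs") abs(profile$z) else profile$z
  da <- profile$metabolite[zscore_to_pvalue(stat) <= alpha_da]
  N <- length(unique(background))
  n <- length(unique(da))

  out <- sets %>%
    group_by(pathway_id = .data$pathway_id) %>%
    summarise(
      n_background = length(intersect(.data$metabolite, background)),
      n_hits = length(intersect(.data$metabolite, da))
    ) %>%
    mutate(
      testable = .data$n_hits >= min_hits,
      p_value = ifelse(
        .data$testable,
        purrr::map2_dbl(
          .data$n_hits, .data$n_background,
          ~ fisher_right_tail(.x, .y, n, N)
        ),
        NA_real_
      ),
      method = "ora", .before = 1
    )
  structure(
    select(
      out, "method", "pathway_id", "testable", "n_hits", "n_background",
      "p_value"
    ),
    class = c("enrichment_result", class(tibble())),
    n_da = n, n_total = N
  )
}
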
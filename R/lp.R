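# Linear programming over the steady-state flux polytope
# {v : S v = 0, lb <= v <= ub} via a dense two-phase simplex with Bland's
# rule, after shifting to non-negative variables x = v - lb. Upper bounds
# enter as slack rows x + s = u, so the standard form is
#   min c'x  s.t.  A x = b, x >= 0
# with an all-slack/artificial starting basis.

# One simplex phase on an explicit tableau. `tab` has one extra rhs column;
# `basis[i]` is the column basic in row i; only `allowed` columns may enter
# (phase 2 forbids the artificial columns). Bland's rule (lowest eligible
# index for both the entering and, on ties, the leaving variable) guarantees
# termination without cycling on degenerate vertices.
simplex_phase <- function(tab, basis, cost, allowed, tol = 1e-9) {
  m <- nrow(tab)
  rhs_col <- ncol(tab)
  max_iter <- 50L * (m + rhs_col)
  for (iter in seq_len(max_iter)) {
    cb <- cost[basis]
    y <- as.vector(crossprod(tab[, allowed, drop = FALSE], cb))
    reduced <- cost[allowed] - y
    enter_idx <- which(reduced < -tol)
    if (!length(enter_idx)) {
      return(list(
        status = "optimal", tab = tab, basis = basis,
        value = sum(cb * tab[, rhs_col])
      ))
    }
    j <- allowed[min(enter_idx)]
    col <- tab[, j]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(status = "unbounded", tab = tab, basis = basis, value = NA_real_))
    }
    ratio <- tab[pos, rhs_col] / col[pos]
    best <- ratio <= min(ratio) + tol
    i <- pos[best][which.min(basis[pos[best]])]
    # pivot on (i, j)
    tab[i, ] <- tab[i, ] / tab[i, j]
    others <- setdiff(seq_len(m), i)
    tab[others, ] <- tab[others, ] - outer(tab[others, j], tab[i, ])
    basis[i] <- j
  }
  abort("LP solver exceeded its iteration limit")
}

# min obj'x  s.t.  A x = b, 0 <= x <= u  (A full row rank, u finite).
lp_bounded <- function(obj, A, b, u, tol = 1e-9) {
  me <- nrow(A)
  n <- ncol(A)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  m <- me + n
  ncols <- 2L * n + me # x, bound slacks, artificials
  tab <- matrix(0, m, ncols + 1L)
  if (me) {
    tab[seq_len(me), seq_len(n)] <- A
    tab[cbind(seq_len(me), 2L * n + seq_len(me))] <- 1
  }
  tab[cbind(me + seq_len(n), seq_len(n))] <- 1
  tab[cbind(me + seq_len(n), n + seq_len(n))] <- 1
  tab[, ncols + 1L] <- c(b, u)
  basis <- c(if (me) 2L * n + seq_len(me), n + seq_len(n))

  # phase 1: drive the artificial variables (one per balance row) to zero
  cost1 <- c(rep(0, 2L * n), rep(1, me))
  p1 <- simplex_phase(tab, basis, cost1, allowed = seq_len(ncols), tol = tol)
  if (p1$status != "optimal" || p1$value > 1e-7) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  tab <- p1$tab
  basis <- p1$basis
  # pivot any artificial left basic at zero onto a structural column
  for (i in which(basis > 2L * n)) {
    j <- which(abs(tab[i, seq_len(2L * n)]) > tol)[1]
    if (is.na(j)) next # redundant zero row; harmless with artificials barred
    tab[i, ] <- tab[i, ] / tab[i, j]
    others <- setdiff(seq_len(m), i)
    tab[others, ] <- tab[others, ] - outer(tab[others, j], tab[i, ])
    basis[i] <- j
  }

  cost2 <- c(obj, rep(0, n + me))
  p2 <- simplex_phase(tab, basis, cost2, allowed = seq_len(2L * n), tol = tol)
  if (p2$status != "optimal") {
    abort("LP is unbounded; check the model flux bounds")
  }
  x <- numeric(ncols)
  x[p2$basis] <- p2$tab[, ncols + 1L]
  list(status = "optimal", x = x[seq_len(n)], value = sum(obj * x[seq_len(n)]))
}

solve_lp <- function(obj, S, lb, ub, maximize = TRUE, eps = 1e-10) {
  n <- length(obj)
  stopifnot(ncol(S) == n, length(lb) == n, length(ub) == n)

  # substitute out variables pinned by equal bounds (e.g. knocked-out
  # reactions); their contribution moves into the equality right-hand side
  free <- ub - lb > eps
  v_fix <- lb
  rhs <- as.vector(-S %*% v_fix)
  if (!any(free)) {
    feas <- all(abs(rhs) <= 1e-7)
    return(if (feas) {
      list(status = "optimal", value = sum(obj * v_fix), fluxes = v_fix)
    } else {
      list(status = "infeasible", value = NA_real_, fluxes = NULL)
    })
  }
  Sf <- S[, free, drop = FALSE]
  zero_row <- rowSums(abs(Sf)) == 0
  if (any(abs(rhs[zero_row]) > 1e-7)) {
    return(list(status = "infeasible", value = NA_real_, fluxes = NULL))
  }
  Sf <- Sf[!zero_row, , drop = FALSE]
  rhs <- rhs[!zero_row]

  # drop linearly dependent balance rows (conserved moieties); the dropped
  # rows are re-checked against the solution at the end
  dec <- qr(t(Sf))
  piv <- dec$pivot[seq_len(dec$rank)]
  A3 <- Sf[piv, , drop = FALSE]
  # shift x = v - lb >= 0 on the free variables: S_f x = -S lb on these rows
  b3 <- rhs[piv]
  flip <- b3 < 0
  A3[flip, ] <- -A3[flip, , drop = FALSE]
  b3 <- abs(b3)

  u <- (ub - lb)[free]
  if (any(!is.finite(u))) abort("all flux bounds must be finite")
  obj_min <- if (maximize) -obj[free] else obj[free]
  res <- lp_bounded(obj_min, A3, b3, u)
  if (res$status != "optimal") {
    return(list(status = "infeasible", value = NA_real_, fluxes = NULL))
  }
  v <- v_fix
  v[free] <- res$x + lb[free]
  if (max(abs(S %*% v)) > 1e-6) {
    # dependent rows dropped above were inconsistent with the solution
    return(list(status = "infeasible", value = NA_real_, fluxes = NULL))
  }
  list(status = "optimal", value = sum(obj * v), fluxes = v)
}

model_lp_parts <- function(m) {
  list(
    S = stoich_matrix(m),
    lb = m$reactions$lower_bound,
    ub = m$reactions$upper_bound
  )
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the flux of one reaction, by default the biomass
#' reaction, subject to steady state `S v = 0` and the model flux bounds.
#'
#' @param m A `metabolic_model`.
#' @param objective Reaction id to optimise (default: the biomass reaction).
#' @param maximize Maximise (default) or minimise.
#' @param biomass_floor Optional lower bound imposed on the biomass flux
#'   before solving (used to test viability at a biomass floor).
#' @return A list with `status` (`"optimal"` or `"infeasible"`), `value`
#'   (the optimal objective flux) and `fluxes` (a tibble of all fluxes at
#'   the optimum).
#' @export
fba <- function(m, objective = NULL, maximize = TRUE, biomass_floor = NULL) {
  objective <- objective %||% m$biomass_reaction_id
  j <- match(objective, m$reactions$id)
  if (is.na(j)) abort(paste0("unknown objective reaction: ", objective))
  p <- model_lp_parts(m)
  if (!is.null(biomass_floor)) {
    bi <- match(m$biomass_reaction_id, m$reactions$id)
    p$lb[bi] <- max(p$lb[bi], biomass_floor)
    if (p$lb[bi] > p$ub[bi]) {
      return(list(status = "infeasible", value = NA_real_, fluxes = NULL))
    }
  }
  obj <- numeric(nrow(m$reactions))
  obj[j] <- 1
  res <- solve_lp(obj, p$S, p$lb, p$ub, maximize = maximize)
  if (res$status == "optimal") {
    res$fluxes <- tibble(reaction_id = m$reactions$id, flux = res$fluxes)
  }
  res
}

#' Flux variability analysis
#'
#' Minimum and maximum achievable steady-state flux per reaction under the
#' model's default bounds (no objective constraint unless `biomass_floor`
#' is given).
#'
#' @param m A `metabolic_model`.
#' @param reactions Reaction ids to analyse (default: all).
#' @param biomass_floor Optional biomass lower bound applied during FVA.
#' @param keep_solutions Also return the optimal flux vectors (used as
#'   warmup points by the flux sampler).
#' @return A tibble with `reaction_id`, `min`, `max`; when
#'   `keep_solutions = TRUE` the matrix of optimum vertices is attached as
#'   attribute `"solutions"`.
#' @export
fva <- function(m, reactions = NULL, biomass_floor = NULL, keep_solutions = FALSE) {
  reactions <- reactions %||% m$reactions$id
  p <- model_lp_parts(m)
  if (!is.null(biomass_floor)) {
    bi <- match(m$biomass_reaction_id, m$reactions$id)
    p$lb[bi] <- max(p$lb[bi], biomass_floor)
  }
  n <- nrow(m$reactions)
  sols <- if (keep_solutions) matrix(NA_real_, 2 * length(reactions), n) else NULL
  mins <- maxs <- numeric(length(reactions))
  for (i in seq_along(reactions)) {
    j <- match(reactions[[i]], m$reactions$id)
    if (is.na(j)) abort(paste0("unknown reaction: ", reactions[[i]]))
    obj <- numeric(n)
    obj[j] <- 1
    lo <- solve_lp(obj, p$S, p$lb, p$ub, maximize = FALSE)
    hi <- solve_lp(obj, p$S, p$lb, p$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      abort("model is infeasible under its default bounds")
    }
    mins[[i]] <- lo$value
    maxs[[i]] <- hi$value
    if (keep_solutions) {
      sols[2 * i - 1, ] <- lo$fluxes
      sols[2 * i, ] <- hi$fluxes
    }
  }
  out <- tibble(reaction_id = reactions, min = mins, max = maxs)
  if (keep_solutions) {
    colnames(sols) <- m$reactions$id
    attr(out, "solutions") <- sols
  }
  out
}
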
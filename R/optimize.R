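# Unified family of montage optimizers. All solve (special cases of)
#   maximize  d' Gamma T i
#   s.t.      i' T' Gamma_nonROI T i <= alpha_I      (integral bound)   or
#             ||T_n i||_2 <= alpha_E[n] for non-ROI n (elementwise bound)
#             ||H i||_1 <= 2 i_max,  i_min <= H i <= i_max  (safety)
# The closed forms (WLS, reciprocity) are the low- and high-alpha limit
# cases of the constrained directional maximization problem.

new_optimum <- function(independent, objective, method, alpha = NULL,
                        k_scale = NULL, active = list(), status = "optimal",
                        extra = list()) {
  structure(c(list(pattern = expand_pattern(independent),
                   objective = objective, method = method, alpha = alpha,
                   k_scale = k_scale, active = active, status = status),
              extra),
            class = "tes_optimum")
}

#' @export
print.tes_optimum <- function(x, ...) {
  cat(sprintf("tes_optimum [%s]: objective %.4e V/m m^3, budget %.4f mA, status %s\n",
              x$method, x$objective, 1e3 * pattern_budget(x$pattern), x$status))
  act <- names(Filter(isTRUE, x$active))
  if (length(act)) cat("  active constraints:", paste(act, collapse = ", "), "\n")
  invisible(x)
}

# shared ingredients
opt_vectors <- function(transfer, weights, target) {
  list(cvec = as.numeric(crossprod(transfer$M, weights$gamma * target$d)),
       L = transfer$L)
}

energy_matrix <- function(transfer, weights)
  crossprod(transfer$M, weights$gamma_nonroi * transfer$M)

full_matrix <- function(transfer, weights)
  crossprod(transfer$M, weights$gamma * transfer$M)

pattern_energy <- function(Q, i) as.numeric(i %*% (Q %*% i))

box_flags <- function(expanded, cons, tol = 1e-9)
  expanded >= cons$i_max_vec - tol | expanded <= cons$i_min_vec + tol

#' Closed-form (weighted) least-squares montage
#'
#' The solution of the energy-only directional maximization problem
#' (budget and per-electrode limits inactive):
#' `i = (T' Gamma_nonROI T)^-1 T' Gamma d * k`, with the scaling
#' `k(alpha_I) = sqrt(alpha_I / (d' Gamma T (T' Gamma_nonROI T)^-1 T' Gamma d))`
#' turning the non-ROI energy bound into an equality. It coincides with the
#' minimizer of the WLS functional `(k d - T i)' Gamma (k d - T i)` when
#' `Gamma_nonROI ~ Gamma` (use approximate-mode weights to reproduce that
#' identity literally; exact-mode weights give the exact-non-ROI variant).
#' With `ls = TRUE` the volume weights are replaced by the identity
#' (unweighted LS form).
#'
#' @param transfer a [build_transfer_matrix()] result.
#' @param weights a [build_volume_weights()] result.
#' @param target a [define_roi_orientation()] result.
#' @param alpha_i non-ROI energy bound; sets `k = k(alpha_i)`.
#' @param k desired-field scale in V/m (used when `alpha_i` is NULL;
#'   default 1).
#' @param ls use identity weights in the normal equations (LS form).
#' @return a `tes_optimum`; `k_scale` holds k in V/m, `energy` the
#'   achieved non-ROI energy.
#' @export
wls_closed_form <- function(transfer, weights, target, alpha_i = NULL,
                            k = NULL, ls = FALSE) {
  if (ls) {
    n3 <- nrow(transfer$M)
    wq <- list(gamma = rep(1, n3), gamma_nonroi = rep(1, n3))
    A <- crossprod(transfer$M)
    rhs <- as.numeric(crossprod(transfer$M, target$d))
  } else {
    wq <- weights
    A <- energy_matrix(transfer, weights)
    rhs <- as.numeric(crossprod(transfer$M, weights$gamma * target$d))
  }
  base <- tryCatch(solve(A, rhs), error = function(e) e)
  if (inherits(base, "error")) {
    warning("normal equations are rank deficient; using the pseudo-inverse")
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    base <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
    base <- as.numeric(base)
  }
  if (!is.null(alpha_i)) {
    denom <- sum(rhs * base)
    if (denom <= 0) stop("degenerate target: d' Gamma T A^-1 T' Gamma d <= 0")
    k <- sqrt(alpha_i / denom)
  } else if (is.null(k)) k <- 1
  ih <- base * k
  cv <- opt_vectors(transfer, weights, target)$cvec
  Qx <- energy_matrix(transfer, weights)
  new_optimum(ih, objective = sum(cv * ih),
              method = if (ls) "ls_closed_form" else "wls_closed_form",
              alpha = alpha_i, k_scale = k,
              active = list(energy = !is.null(alpha_i)),
              extra = list(energy = pattern_energy(Qx, ih)))
}

#' Optimally scaled WLS montage
#'
#' The closed-form WLS direction rescaled so the total current budget is
#' exactly exhausted (`||H i||_1 = 2 i_max`). This is the montage at the
#' first critical point of the intensity-focality trade-off: the budget
#' saturates while the solution still has the WLS shape.
#'
#' @inheritParams wls_closed_form
#' @param i_max total current limit (A).
#' @return a `tes_optimum`.
#' @export
scaled_wls <- function(transfer, weights, target, i_max) {
  base <- wls_closed_form(transfer, weights, target, k = 1)
  bud <- pattern_budget(base$pattern)
  if (bud <= 0) stop("closed-form WLS solution is zero; cannot rescale")
  s <- 2 * i_max / bud
  ih <- base$pattern$independent * s
  cv <- opt_vectors(transfer, weights, target)$cvec
  new_optimum(ih, objective = sum(cv * ih), method = "scaled_wls",
              k_scale = base$k_scale * s,
              active = list(budget = TRUE),
              extra = list(energy = pattern_energy(energy_matrix(transfer, weights), ih)))
}

#' Budget-constrained WLS montage
#'
#' Minimizes the WLS misfit `(k d - T i)' Gamma (k d - T i)` subject to the
#' total-current and per-electrode limits (a linearly constrained QP; the
#' l1 budget is handled with auxiliary magnitude variables). Equivalent to
#' the directional maximization problem at
#' `alpha_I' = i' T' Gamma T i` evaluated at this solution.
#'
#' @inheritParams wls_closed_form
#' @param k desired-field scale (V/m), default 1.
#' @param constraints a [constraint_set()] (its `alpha` slots are ignored
#'   here).
#' @return a `tes_optimum`; `wls_cost` holds the achieved misfit.
#' @export
constrained_wls <- function(transfer, weights, target, k = 1, constraints) {
  stopifnot(inherits(constraints, "constraint_set"))
  Qf <- full_matrix(transfer, weights)
  cv <- opt_vectors(transfer, weights, target)$cvec
  sol <- qp_l1box(2 * Qf, 2 * k * cv, transfer$L, 2 * constraints$i_max,
                  constraints$i_min_vec, constraints$i_max_vec)
  if (is.null(sol$i)) stop("constrained WLS infeasible: ", sol$status)
  ih <- sol$i
  ex <- expand_pattern(ih)$expanded
  dGd <- sum(weights$gamma * target$d^2)
  cost <- k^2 * dGd - 2 * k * sum(cv * ih) + pattern_energy(Qf, ih)
  new_optimum(ih, objective = sum(cv * ih), method = "constrained_wls",
              k_scale = k,
              active = list(
                budget = pattern_budget(ex) >= 2 * constraints$i_max * (1 - 1e-6),
                box = box_flags(ex, constraints)),
              extra = list(wls_cost = cost,
                           energy_full = pattern_energy(Qf, ih)))
}

#' Constrained directional maximization
#'
#' Maximizes the volume integral of the ROI directional field
#' `d' Gamma T i` under a non-ROI field bound, the total-current budget and
#' per-electrode limits. Two non-ROI bounds are supported (exactly one must
#' be set in `constraints`):
#' \describe{
#'   \item{integral (`alpha_i`)}{quadratic bound on the non-ROI field
#'     energy. Solved exactly by bisection on the Lagrange multiplier of
#'     the quadratic constraint; each inner problem is a strictly convex
#'     QP. When the bound is the only active constraint the solution is
#'     the closed-form WLS montage; when it is slack the solution is the
#'     reciprocity corner.}
#'   \item{elementwise (`alpha_e`)}{one second-order-cone bound
#'     `||T_n i|| <= alpha_e[n]` per non-ROI element. Solved by outer
#'     linearization: violated cones contribute supporting-hyperplane cuts
#'     to a master QP until the worst violation is below `tol_cut`.}
#' }
#'
#' @inheritParams wls_closed_form
#' @param constraints a [constraint_set()] carrying `alpha_i` or `alpha_e`,
#'   `i_max` and the per-electrode box.
#' @param nonroi_mode `"integral"` or `"elementwise"`; default follows
#'   whichever alpha is set.
#' @param control list of solver knobs: `tol_alpha` (relative bisection
#'   tolerance on the energy equality, default 1e-9), `tol_pattern`
#'   (convergence of the slack-bound limit, 1e-8), `tol_cut` (relative
#'   cone violation, 1e-7), `max_cut_iter` (400), `cut_batch` (40).
#' @return a `tes_optimum` with active-constraint flags, achieved non-ROI
#'   `energy` (integral mode) or `max_nonroi` field (elementwise mode).
#' @export
dirmax <- function(transfer, weights, target, constraints,
                   nonroi_mode = NULL, control = list()) {
  stopifnot(inherits(constraints, "constraint_set"))
  has_i <- !is.null(constraints$alpha_i)
  has_e <- !is.null(constraints$alpha_e)
  if (has_i == has_e)
    stop("exactly one of alpha_i / alpha_e must be set for dirmax")
  if (is.null(nonroi_mode)) nonroi_mode <- if (has_i) "integral" else "elementwise"
  nonroi_mode <- match.arg(nonroi_mode, c("integral", "elementwise"))
  if ((nonroi_mode == "integral") != has_i)
    stop("nonroi_mode does not match the alpha set in 'constraints'")
  ctl <- modifyList(list(tol_alpha = 1e-9, tol_pattern = 1e-8, tol_cut = 1e-7,
                         max_cut_iter = 400L, cut_batch = 40L), control)
  cv <- opt_vectors(transfer, weights, target)$cvec
  if (all(cv == 0))
    return(new_optimum(rep(0, transfer$L - 1L), 0, paste0("dirmax_", nonroi_mode),
                       alpha = constraints$alpha_i %||% constraints$alpha_e,
                       active = list(), status = "optimal (zero target)"))
  if (nonroi_mode == "integral")
    dirmax_integral(transfer, weights, target, constraints, cv, ctl)
  else
    dirmax_elementwise(transfer, weights, target, constraints, cv, ctl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dirmax_integral <- function(transfer, weights, target, cons, cv, ctl) {
  Q <- energy_matrix(transfer, weights)
  alpha <- cons$alpha_i
  L <- transfer$L
  solve_mu <- function(mu) {
    sol <- qp_l1box(2 * mu * Q, cv, L, 2 * cons$i_max,
                    cons$i_min_vec, cons$i_max_vec)
    if (is.null(sol$i)) stop("inner QP failed: ", sol$status)
    list(i = sol$i, e = pattern_energy(Q, sol$i))
  }
  # energy-only multiplier as starting guess (exact when budget/box slack)
  mu0 <- tryCatch(sqrt(sum(cv * solve(Q, cv)) / alpha) / 2,
                  error = function(e) 1)
  if (!is.finite(mu0) || mu0 <= 0) mu0 <- 1
  mu_hi <- mu0 * 1.0001
  r <- solve_mu(mu_hi)
  grow <- 0L
  while (r$e > alpha && grow < 60L) {   # energy decreases with mu
    mu_hi <- mu_hi * 10
    r <- solve_mu(mu_hi)
    grow <- grow + 1L
  }
  if (r$e > alpha)
    stop("could not bracket the energy constraint multiplier")
  # shrink mu towards the slack-bound limit or a bracket
  mu <- mu_hi
  prev <- r
  status <- "optimal"
  repeat {
    mu2 <- mu / 10
    r2 <- solve_mu(mu2)
    if (r2$e > alpha) {           # bracket found: bisect to the boundary
      lo <- mu2; hi <- mu
      for (it in seq_len(100L)) {
        mm <- sqrt(lo * hi)
        if (solve_mu(mm)$e > alpha) lo <- mm else hi <- mm
        if (hi / lo < 1 + 1e-11) break
      }
      r <- solve_mu(hi)
      if (abs(r$e - alpha) > ctl$tol_alpha * alpha * 1e3)
        status <- "optimal (boundary tolerance relaxed)"
      break
    }
    if (sqrt(sum((r2$i - prev$i)^2)) <
        ctl$tol_pattern * max(sqrt(sum(r2$i^2)), 1e-30) ||
        mu2 < mu_hi * 1e-18) {   # constraint slack: pattern converged
      r <- r2
      break
    }
    mu <- mu2
    prev <- r2
  }
  ex <- expand_pattern(r$i)$expanded
  new_optimum(r$i, objective = sum(cv * r$i), method = "dirmax_integral",
              alpha = alpha, status = status,
              active = list(
                energy = abs(r$e - alpha) <= 1e-6 * alpha,
                budget = pattern_budget(ex) >= 2 * cons$i_max * (1 - 1e-6),
                box = box_flags(ex, cons)),
              extra = list(energy = r$e))
}

dirmax_elementwise <- function(transfer, weights, target, cons, cv, ctl) {
  L <- transfer$L
  nel <- length(transfer$elements)
  alpha_e <- cons$alpha_e
  if (length(alpha_e) == 1L) alpha_e <- rep(alpha_e, nel)
  if (length(alpha_e) != nel)
    stop("alpha_e must be scalar or one bound per subset element")
  roi_mask <- logical(nel)
  roi_mask[target$roi_local] <- TRUE
  cuts_A <- NULL
  cuts_b <- NULL
  for (it in seq_len(ctl$max_cut_iter)) {
    sol <- qp_l1box(matrix(0, L - 1L, L - 1L), cv, L, 2 * cons$i_max,
                    cons$i_min_vec, cons$i_max_vec,
                    extra_A = cuts_A, extra_b = cuts_b)
    if (is.null(sol$i)) stop("master QP failed: ", sol$status)
    e <- matrix(transfer$M %*% sol$i, nrow = 3L)
    nrm <- sqrt(colSums(e^2))
    over <- nrm / alpha_e
    over[roi_mask] <- 0
    viol <- which(over > 1 + ctl$tol_cut)
    if (!length(viol)) {
      ex <- expand_pattern(sol$i)$expanded
      mx <- max(nrm[!roi_mask] / alpha_e[!roi_mask])
      return(new_optimum(
        sol$i, objective = sum(cv * sol$i), method = "dirmax_elementwise",
        alpha = cons$alpha_e,
        status = if (it < ctl$max_cut_iter) "optimal" else "cut limit reached",
        active = list(
          elementwise = mx >= 1 - 1e-6,
          budget = pattern_budget(ex) >= 2 * cons$i_max * (1 - 1e-6),
          box = box_flags(ex, cons)),
        extra = list(max_nonroi = max(nrm[!roi_mask]), cut_iterations = it,
                     n_cuts = if (is.null(cuts_A)) 0L else nrow(cuts_A))))
    }
    viol <- viol[order(over[viol], decreasing = TRUE)]
    viol <- viol[seq_len(min(ctl$cut_batch, length(viol)))]
    newA <- t(vapply(viol, function(n) {
      rows <- (3L * (n - 1L) + 1L):(3L * n)
      as.numeric((e[, n] / nrm[n]) %*% transfer$M[rows, , drop = FALSE])
    }, numeric(L - 1L)))
    cuts_A <- rbind(cuts_A, newA)
    cuts_b <- c(cuts_b, alpha_e[viol])
  }
  stop("elementwise directional maximization did not converge within ",
       ctl$max_cut_iter, " cut iterations")
}

#' Synthetic EEG potential of the target dipole field
#'
#' By reciprocity the objective `d' Gamma T i` equals `Phi' i / s`, where
#' `Phi = (T' Gamma d) s` is the EEG potential at the electrodes generated
#' by a dipole source field shaped by `d` and weighted by element volume,
#' with arbitrary positive dipole density scale `s` (A m/m^3). No dipole
#' solves are needed: transposition of the transfer matrix is the lead
#' field.
#'
#' @inheritParams wls_closed_form
#' @param s dipole density scale, > 0 (default 1 A m/m^3).
#' @return object of class `synthetic_potential`: `phi` (L-1 values
#'   relative to the reference), `expanded` (length L, 0 at the
#'   reference), `s`, `labels`.
#' @export
synthetic_potential <- function(transfer, weights, target, s = 1) {
  if (s <= 0) stop("'s' must be positive")
  phi <- as.numeric(crossprod(transfer$M, weights$gamma * target$d)) * s
  structure(list(phi = phi, expanded = c(phi, 0), s = s,
                 labels = transfer$labels),
            class = "synthetic_potential")
}

#' @export
print.synthetic_potential <- function(x, ...) {
  cat(sprintf("synthetic_potential: %d electrodes, range [%.3e, %.3e] V\n",
              length(x$expanded), min(x$expanded), max(x$expanded)))
  invisible(x)
}

as_phi_expanded <- function(phi) {
  if (inherits(phi, "synthetic_potential")) phi$expanded else as.numeric(phi)
}

#' One-to-one reciprocity montage
#'
#' The high-alpha limit of the directional maximization problem: with only
#' the l1 budget active, the optimum sits at a corner of the feasible
#' polytope with exactly two active electrodes - the source at the maximum
#' and the sink at the minimum of the synthetic EEG potential, each at
#' `i_max`. Ties are broken towards the lowest electrode index (reported
#' via a message).
#'
#' @param phi a [synthetic_potential()] (or numeric expanded potential,
#'   one entry per electrode with 0 at the reference).
#' @param i_max total current limit (A).
#' @return a `tes_optimum` with a two-electrode pattern.
#' @export
reciprocity_one_to_one <- function(phi, i_max) {
  s <- if (inherits(phi, "synthetic_potential")) phi$s else 1
  pe <- as_phi_expanded(phi)
  L <- length(pe)
  lmax <- which.max(pe)
  lmin <- which.min(pe)
  if (sum(pe == pe[lmax]) > 1L || sum(pe == pe[lmin]) > 1L)
    message("reciprocity: tied electrode potentials; lowest index chosen")
  if (lmax == lmin) stop("synthetic potential is constant; no direction to steer")
  ex <- numeric(L)
  ex[lmax] <- i_max
  ex[lmin] <- -i_max
  new_optimum(ex[-L], objective = sum(pe * ex) / s,
              method = "reciprocity_one_to_one",
              active = list(budget = TRUE),
              extra = list(source = lmax, sink = lmin))
}

#' Reciprocity montage with per-electrode current limits
#'
#' Closed form of the high-alpha limit under uniform per-electrode limits
#' `+c_source` / `-c_sink`: the top `ceiling(i_max/c_source)` electrodes by
#' synthetic potential inject `+c_source` each (the last takes the
#' remainder) and the bottom `ceiling(i_max/c_sink)` electrodes drain
#' `-c_sink` each, reproducing the "opposite", "one source - all sinks"
#' and patch-like montages. Ties are broken towards the lowest index.
#'
#' @inheritParams reciprocity_one_to_one
#' @param i_min_vec,i_max_vec uniform per-electrode limits (length L or
#'   scalars; `i_min_vec <= 0 <= i_max_vec`).
#' @return a `tes_optimum`.
#' @export
reciprocity_limited <- function(phi, i_max, i_min_vec, i_max_vec) {
  s <- if (inherits(phi, "synthetic_potential")) phi$s else 1
  pe <- as_phi_expanded(phi)
  L <- length(pe)
  if (length(i_max_vec) == 1L) i_max_vec <- rep(i_max_vec, L)
  if (length(i_min_vec) == 1L) i_min_vec <- rep(i_min_vec, L)
  cpos <- unique(round(i_max_vec, 15))
  cneg <- unique(round(-i_min_vec, 15))
  if (length(cpos) != 1L || length(cneg) != 1L)
    stop("the closed form requires uniform per-electrode limits")
  if (cpos <= 0 || cneg <= 0) stop("per-electrode limits must be non-zero")
  ns <- ceiling(i_max / cpos - 1e-12)
  nk <- ceiling(i_max / cneg - 1e-12)
  if (ns + nk > L)
    stop(sprintf("infeasible: %d sources + %d sinks exceed %d electrodes",
                 ns, nk, L))
  ord <- order(pe, decreasing = TRUE)   # stable: ties to lowest index
  ex <- numeric(L)
  src <- ord[seq_len(ns)]
  snk <- rev(ord)[seq_len(nk)]
  ex[src] <- cpos
  ex[src[ns]] <- i_max - (ns - 1L) * cpos
  ex[snk] <- -cneg
  ex[snk[nk]] <- -(i_max - (nk - 1L) * cneg)
  new_optimum(ex[-L], objective = sum(pe * ex) / s,
              method = "reciprocity_limited",
              active = list(budget = TRUE,
                            box = ex >= i_max_vec - 1e-15 | ex <= i_min_vec + 1e-15),
              extra = list(sources = src, sinks = snk))
}
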
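# Sweep of the non-ROI field bound: the single knob that moves the
# optimal montage along the intensity-focality trade-off, from the
# (scaled) WLS shape at tight bounds to the sparse reciprocity corner at
# loose bounds. Three zones emerge: "pink" (bound active, budget slack),
# "white" (both active, the trade-off zone) and "blue" (budget active,
# bound slack, pattern frozen at the reciprocity solution); critical
# points a and b mark the zone borders.

#' Sweep the non-ROI field bound of the directional maximization problem
#'
#' Solves [dirmax()] over a logarithmic grid of the non-ROI bound
#' (`alpha_I` for the integral mode, `alpha_E` for the elementwise mode)
#' and records, per grid point, the mean directional ROI intensity, the
#' used budget, both focality metrics (always computed with exact-non-ROI
#' volume weights so that different sweeps are comparable), the
#' active-constraint zone and the optimal pattern.
#'
#' The default grid is anchored by the two closed-form limit solutions:
#' the scaled-WLS montage (budget saturation, lower end) and the
#' reciprocity montage (upper end), extended automatically until both the
#' budget-slack and the bound-slack regimes are present.
#'
#' @inheritParams wls_closed_form
#' @param constraints a [constraint_set()]; its `alpha` slots are ignored
#'   (the grid supplies them).
#' @param nonroi_mode `"integral"` or `"elementwise"`.
#' @param alpha_grid optional increasing vector of bound values; computed
#'   automatically when NULL.
#' @param n_grid grid size for the automatic grid (default 40).
#' @param control passed to [dirmax()].
#' @return object of class `tes_sweep`: `table` (one row per grid point:
#'   `alpha`, `intensity_V_per_m`, `budget_mA`, `budget_pct`,
#'   `focality_integral`, `focality_elementwise`, `zone`, `status`),
#'   `patterns` (list of expanded patterns, A), `critical_a`,
#'   `critical_b`, `critical_c` (elementwise only), `recip_pattern`,
#'   `mode`, `i_max`.
#' @export
alpha_sweep <- function(transfer, weights, target, constraints,
                        nonroi_mode = c("integral", "elementwise"),
                        alpha_grid = NULL, n_grid = 40L, control = list()) {
  nonroi_mode <- match.arg(nonroi_mode)
  stopifnot(inherits(constraints, "constraint_set"))
  wm <- build_volume_weights(transfer, target, "exact")  # metric weights
  phi <- synthetic_potential(transfer, weights, target)
  recip <- recip_reference(phi, constraints)
  Q <- energy_matrix(transfer, weights)
  if (is.null(alpha_grid))
    alpha_grid <- default_alpha_grid(transfer, weights, target, constraints,
                                     nonroi_mode, recip, Q, n_grid)
  run_grid <- function(grid) {
    lapply(grid, function(a) {
      cs <- constraints
      if (nonroi_mode == "integral") { cs$alpha_i <- a; cs$alpha_e <- NULL }
      else { cs$alpha_e <- a; cs$alpha_i <- NULL }
      tryCatch(dirmax(transfer, weights, target, cs, nonroi_mode, control),
               error = function(e) e)
    })
  }
  sols <- run_grid(alpha_grid)
  # extend until both regimes are present (a few decades at most)
  for (ext in seq_len(3L)) {
    ok <- !vapply(sols, inherits, TRUE, "error")
    if (!any(ok)) break
    first <- sols[ok][[1L]]
    last <- sols[ok][[length(sols[ok])]]
    need_lo <- isTRUE(first$active$budget)
    need_hi <- rel_l2(last$pattern$expanded, recip$pattern$expanded) > 1e-3
    if (!need_lo && !need_hi) break
    if (need_lo) {
      lo <- exp(seq(log(alpha_grid[1L]) - log(10), log(alpha_grid[1L]),
                    length.out = 5L))[1:4]
      alpha_grid <- c(lo, alpha_grid)
      sols <- c(run_grid(lo), sols)
    }
    if (need_hi) {
      n <- length(alpha_grid)
      hi <- exp(seq(log(alpha_grid[n]), log(alpha_grid[n]) + log(10),
                    length.out = 5L))[2:5]
      alpha_grid <- c(alpha_grid, hi)
      sols <- c(sols, run_grid(hi))
    }
  }
  ok <- !vapply(sols, inherits, TRUE, "error")
  if (!all(ok))
    warning(sum(!ok), " sweep point(s) failed and were skipped")
  rows <- lapply(which(ok), function(j) {
    opt <- sols[[j]]
    i <- opt$pattern$independent
    bud <- pattern_budget(opt$pattern)
    nonroi_active <- if (nonroi_mode == "integral") isTRUE(opt$active$energy)
                     else isTRUE(opt$active$elementwise)
    zone <- if (!isTRUE(opt$active$budget)) "pink"
            else if (!nonroi_active) "blue" else "white"
    data.frame(
      alpha = alpha_grid[j],
      intensity_V_per_m = mean_roi_intensity(i, transfer, wm, target),
      budget_mA = 1e3 * bud,
      budget_pct = 100 * bud / (2 * constraints$i_max),
      focality_integral = integral_focality(i, transfer, wm, target),
      focality_elementwise = elementwise_focality(i, transfer, wm, target),
      zone = zone, status = opt$status, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  patterns <- lapply(sols[ok], function(o) o$pattern$expanded)
  sw <- structure(list(table = tab, patterns = patterns,
                       recip_pattern = recip$pattern$expanded,
                       mode = nonroi_mode, i_max = constraints$i_max),
                  class = "tes_sweep")
  cp <- detect_critical_points(sw)
  sw$critical_a <- cp$a
  sw$critical_b <- cp$b
  sw$critical_c <- cp$c
  sw
}

# closed-form high-alpha reference montage for the given box limits
recip_reference <- function(phi, cons) {
  uni_p <- length(unique(round(cons$i_max_vec, 15))) == 1L
  uni_n <- length(unique(round(cons$i_min_vec, 15))) == 1L
  if (uni_p && uni_n &&
      cons$i_max_vec[1L] >= cons$i_max - 1e-15 &&
      -cons$i_min_vec[1L] >= cons$i_max - 1e-15)
    reciprocity_one_to_one(phi, cons$i_max)
  else if (uni_p && uni_n)
    reciprocity_limited(phi, cons$i_max, cons$i_min_vec, cons$i_max_vec)
  else stop("non-uniform per-electrode limits: no closed-form sweep anchor")
}

default_alpha_grid <- function(transfer, weights, target, cons, mode,
                               recip, Q, n_grid) {
  ir <- recip$pattern$independent
  if (mode == "integral") {
    sw <- scaled_wls(transfer, weights, target, cons$i_max)
    e_a <- sw$energy
    e_b <- pattern_energy(Q, ir)
    exp(seq(log(e_a / 30), log(e_b * 30), length.out = n_grid))
  } else {
    nrm <- sqrt(colSums(matrix(transfer$M %*% ir, nrow = 3L)^2))
    roi_mask <- logical(length(transfer$elements))
    roi_mask[target$roi_local] <- TRUE
    f_b <- max(nrm[!roi_mask])
    # low-bound probe: budget grows linearly with alpha_E while slack
    cs <- cons; cs$alpha_e <- f_b / 50; cs$alpha_i <- NULL
    probe <- dirmax(transfer, weights, target, cs, "elementwise")
    beta <- max(pattern_budget(probe$pattern) / (2 * cons$i_max), 1e-3)
    a_lo <- (f_b / 50) / beta
    exp(seq(log(a_lo / 30), log(f_b * 30), length.out = n_grid))
  }
}

rel_l2 <- function(a, b) {
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(if (sum(a^2) == 0) 0 else Inf)
  sqrt(sum((a - b)^2)) / nb
}

#' Critical points of a sweep
#'
#' Point `a` is the smallest bound value at which the used budget reaches
#' 99.5% of `2 i_max` (the budget saturates; below it the montage keeps
#' the WLS shape at reduced scale). Point `b` is the smallest bound value
#' whose pattern matches the reciprocity closed form within 1e-3 relative
#' l2 (beyond it the montage is frozen). For elementwise sweeps an
#' informational point `c` marks the steepest decrease of the elementwise
#' focality (log-log slope), where the trade-off becomes visible.
#'
#' @param sweep a [alpha_sweep()] result.
#' @return list with `a`, `b` (NA when the regime was not reached) and
#'   `c` (integral mode: NA).
#' @export
detect_critical_points <- function(sweep) {
  tab <- sweep$table
  sat <- which(tab$budget_pct >= 99.5)
  a <- if (length(sat)) tab$alpha[sat[1L]] else NA_real_
  dev <- vapply(sweep$patterns, rel_l2, 0, b = sweep$recip_pattern)
  hit <- which(dev <= 1e-3)
  b <- if (length(hit)) tab$alpha[hit[1L]] else NA_real_
  cpt <- NA_real_
  if (sweep$mode == "elementwise" && nrow(tab) > 2L) {
    lf <- log(pmax(tab$focality_elementwise, 1e-300))
    sl <- diff(lf) / diff(log(tab$alpha))
    cpt <- tab$alpha[which.min(sl)]
  }
  list(a = a, b = b, c = cpt)
}

#' @export
print.tes_sweep <- function(x, ...) {
  cat(sprintf("tes_sweep (%s): %d points, alpha in [%.3e, %.3e]\n",
              x$mode, nrow(x$table), min(x$table$alpha), max(x$table$alpha)))
  cat(sprintf("  critical a = %.4e, b = %.4e", x$critical_a, x$critical_b))
  if (!is.na(x$critical_c)) cat(sprintf(", c = %.4e", x$critical_c))
  cat("\n  zones:", paste(sprintf("%s (%d)", names(table(x$table$zone)),
                                  table(x$table$zone)), collapse = ", "), "\n")
  invisible(x)
}

#' Intensity-focality trade-off plot of a sweep
#'
#' Mirrors the canonical trade-off figure: mean ROI intensity, used budget
#' and the sweep's natural focality versus the non-ROI bound (log x axis),
#' with the three active-constraint zones shaded and critical points
#' marked.
#'
#' @param x a [alpha_sweep()] result.
#' @param ... unused.
#' @export
plot.tes_sweep <- function(x, ...) {
  tab <- x$table
  foc <- if (x$mode == "integral") tab$focality_integral else tab$focality_elementwise
  op <- par(mar = c(4.5, 4.2, 2, 4.2))
  on.exit(par(op))
  plot(tab$alpha, tab$intensity_V_per_m, log = "x", type = "n",
       xlab = if (x$mode == "integral")
                expression(alpha[I] ~ "(V"^2 * "/m"^2 %.% "m"^3 * ")")
              else expression(alpha[E] ~ "(V/m)"),
       ylab = "mean ROI directional intensity (V/m)",
       main = sprintf("intensity-focality trade-off (%s bound)", x$mode))
  usr <- par("usr")
  shade <- c(pink = "#fde5ec", white = "#ffffff", blue = "#e3ecfa")
  zr <- rle(tab$zone)
  stops <- c(usr[1], log10(tab$alpha[cumsum(zr$lengths)[-length(zr$lengths)]]), usr[2])
  for (j in seq_along(zr$values))
    rect(10^stops[j], usr[3], 10^stops[j + 1], usr[4],
         col = shade[zr$values[j]], border = NA)
  lines(tab$alpha, tab$intensity_V_per_m, col = "blue", lwd = 2)
  sc_b <- max(tab$intensity_V_per_m) / 100
  lines(tab$alpha, tab$budget_pct * sc_b, col = "red", lwd = 2, lty = 2)
  sc_f <- max(tab$intensity_V_per_m) / max(foc[is.finite(foc)])
  lines(tab$alpha, foc * sc_f, col = "black", lwd = 2, lty = 3)
  axis(4, at = pretty(c(0, 100)) * sc_b, labels = pretty(c(0, 100)))
  mtext("used budget (% of 2 i_max)", side = 4, line = 2.5)
  abline(v = c(x$critical_a, x$critical_b), lty = 3)
  if (!is.na(x$critical_a))
    mtext(c("a", "b"), at = c(x$critical_a, x$critical_b), side = 3)
  legend("topleft", bty = "n", lwd = 2, lty = 1:3,
         col = c("blue", "red", "black"),
         legend = c("intensity", "budget", "focality (scaled)"))
  invisible(x)
}

#' Cross-focality table for two sweeps
#'
#' Stacks both focality metrics of both solution families (integral- and
#' elementwise-constrained sweeps of the same model), indexed by mean ROI
#' intensity, so the natural and cross metrics can be compared at matched
#' intensity.
#'
#' @param sweep_integral,sweep_elementwise [alpha_sweep()] results of the
#'   two modes on the same model.
#' @return data.frame with columns `family`, `alpha`,
#'   `intensity_V_per_m`, `focality_integral`, `focality_elementwise`.
#' @export
cross_focality_curves <- function(sweep_integral, sweep_elementwise) {
  stopifnot(inherits(sweep_integral, "tes_sweep"),
            inherits(sweep_elementwise, "tes_sweep"))
  take <- function(sw, fam)
    data.frame(family = fam, alpha = sw$table$alpha,
               intensity_V_per_m = sw$table$intensity_V_per_m,
               focality_integral = sw$table$focality_integral,
               focality_elementwise = sw$table$focality_elementwise,
               stringsAsFactors = FALSE)
  rbind(take(sweep_integral, "integral"),
        take(sweep_elementwise, "elementwise"))
}
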
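#' Current injection patterns
#'
#' For L electrodes there are L-1 independent currents; the reference
#' electrode carries the negative sum so that the total injected current is
#' zero (Kirchhoff's law). `expand_pattern` maps the independent pattern
#' `i` to the expanded pattern (the last entry is computed as the negative
#' partial sum, so the zero-sum identity is exact in floating point);
#' `reduce_pattern` is its exact inverse.
#'
#' @param i numeric independent pattern, length L-1 (A).
#' @return `expand_pattern`: object of class `current_pattern` with fields
#'   `independent` and `expanded`.
#' @examples
#' expand_pattern(c(5e-4, -2e-4))$expanded  # c(5e-4, -2e-4, -3e-4)
#' @export
expand_pattern <- function(i) {
  i <- as.numeric(i)
  structure(list(independent = i, expanded = c(i, -sum(i))),
            class = "current_pattern")
}

#' @rdname expand_pattern
#' @param itilde expanded pattern, length L (A), summing to zero.
#' @return `reduce_pattern`: the independent pattern (length L-1).
#' @export
reduce_pattern <- function(itilde) {
  if (inherits(itilde, "current_pattern")) return(itilde$independent)
  itilde <- as.numeric(itilde)
  tol <- 1e-12 * max(sum(abs(itilde)), 1e-30)
  if (abs(sum(itilde)) > tol)
    stop("expanded pattern does not sum to zero: ", sum(itilde), " A")
  itilde[-length(itilde)]
}

# accept independent / expanded / current_pattern, return independent
as_independent <- function(pattern, L) {
  if (inherits(pattern, "current_pattern")) return(pattern$independent)
  pattern <- as.numeric(pattern)
  if (length(pattern) == L) reduce_pattern(pattern)
  else if (length(pattern) == L - 1L) pattern
  else stop("pattern length must be L or L-1")
}

#' Total injected current (l1 budget) of a pattern
#'
#' The budget is the l1 norm of the expanded pattern; a two-electrode
#' montage at `i_max` per electrode uses budget `2*i_max`.
#'
#' @param pattern a [current_pattern()] or numeric expanded pattern.
#' @return budget in A.
#' @export
pattern_budget <- function(pattern) {
  if (inherits(pattern, "current_pattern")) pattern <- pattern$expanded
  sum(abs(pattern))
}

#' @export
print.current_pattern <- function(x, ...) {
  cat(sprintf("current_pattern: %d electrodes, budget %.4f mA, %d active\n",
              length(x$expanded), 1e3 * pattern_budget(x),
              sum(abs(x$expanded) > 1e-12)))
  invisible(x)
}

#' Safety constraint set for montage optimization
#'
#' Collects the constraints of the unified targeting problem: the non-ROI
#' field bound (`alpha_i`, an energy integral in V^2/m^2 m^3, or
#' `alpha_e`, a per-element field magnitude in V/m - exactly one of the
#' two for directional maximization), the total current budget `i_max`
#' (l1 norm of the expanded pattern limited to `2*i_max`), and
#' per-electrode box limits.
#'
#' @param i_max total current limit (A), > 0.
#' @param L number of electrodes.
#' @param alpha_i non-ROI field energy bound (V^2/m^2 m^3) or NULL.
#' @param alpha_e non-ROI elementwise field bound, scalar or per-element
#'   (V/m), or NULL.
#' @param i_min_vec,i_max_vec per-electrode limits (length L, A);
#'   default `-i_max` / `+i_max` (a single pair may carry everything).
#' @return object of class `constraint_set`.
#' @export
constraint_set <- function(i_max, L, alpha_i = NULL, alpha_e = NULL,
                           i_min_vec = NULL, i_max_vec = NULL) {
  if (!is.numeric(i_max) || i_max <= 0) stop("'i_max' must be positive (A)")
  if (is.null(i_min_vec)) i_min_vec <- rep(-i_max, L)
  if (is.null(i_max_vec)) i_max_vec <- rep(i_max, L)
  if (length(i_min_vec) == 1L) i_min_vec <- rep(i_min_vec, L)
  if (length(i_max_vec) == 1L) i_max_vec <- rep(i_max_vec, L)
  if (length(i_min_vec) != L || length(i_max_vec) != L)
    stop("per-electrode limits must have length L = ", L)
  if (any(i_min_vec > 0) || any(i_max_vec < 0))
    stop("per-electrode limits must satisfy i_min_vec <= 0 <= i_max_vec")
  if (!is.null(alpha_i) && (!is.numeric(alpha_i) || alpha_i <= 0))
    stop("'alpha_i' must be positive")
  if (!is.null(alpha_e) && any(alpha_e <= 0))
    stop("'alpha_e' must be positive")
  structure(list(i_max = i_max, L = as.integer(L), alpha_i = alpha_i,
                 alpha_e = alpha_e, i_min_vec = i_min_vec,
                 i_max_vec = i_max_vec),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("constraint_set: i_max %.3g mA, box [%.3g, %.3g] mA",
              1e3 * x$i_max, 1e3 * min(x$i_min_vec), 1e3 * max(x$i_max_vec)))
  if (!is.null(x$alpha_i)) cat(sprintf(", alpha_I %.3g V^2/m^2 m^3", x$alpha_i))
  if (!is.null(x$alpha_e)) cat(sprintf(", alpha_E %.3g V/m", min(x$alpha_e)))
  cat("\n")
  invisible(x)
}
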
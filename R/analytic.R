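#' Surface potential of a point current source on a homogeneous sphere
#'
#' Analytic solution used to verify the FEM forward solver: for a point
#' current source of strength `current` on the surface of a homogeneous
#' conducting sphere, the surface potential at angular distance `gamma`
#' from the source is the Legendre series
#' \deqn{\psi(\gamma) = \frac{I}{4\pi\sigma R}\sum_{n\ge1}
#'       \frac{2n+1}{n} P_n(\cos\gamma),}
#' which sums in closed form to
#' \deqn{\frac{I}{4\pi\sigma R}\left[\frac{1}{\sin(\gamma/2)} - 2 -
#'       \log\big(\sin(\gamma/2) + \sin^2(\gamma/2)\big)\right].}
#' A two-electrode montage is the superposition of a positive and a
#' negative source. The potential is defined up to an additive constant
#' (compare differences, or centre both sides).
#'
#' @param gamma angular distance(s) from the source, radians, in (0, pi].
#' @param current source strength in A.
#' @param sigma conductivity in S/m.
#' @param radius sphere radius in m.
#' @param n_terms `Inf` (default) for the closed form, or a finite
#'   truncation order for the explicit partial sum (recurrence evaluation
#'   of the Legendre polynomials).
#' @return potential in V, same shape as `gamma`.
#' @export
sphere_surface_potential <- function(gamma, current, sigma, radius,
                                     n_terms = Inf) {
  if (any(gamma <= 0 | gamma > pi + 1e-12))
    stop("'gamma' must lie in (0, pi]")
  scale <- current / (4 * pi * sigma * radius)
  if (!is.finite(n_terms)) {
    s <- sin(gamma / 2)
    return(scale * (1 / s - 2 - log(s + s^2)))
  }
  t <- cos(gamma)
  p_prev <- rep(1, length(t))   # P_0
  p_cur <- t                    # P_1
  acc <- 3 * t                  # (2*1+1)/1 * P_1
  for (n in 2:n_terms) {
    p_next <- ((2 * n - 1) * t * p_cur - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) / n * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  scale * acc
}
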
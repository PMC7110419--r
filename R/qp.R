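# Internal convex backend.
#
# Everything the unified targeting family needs reduces to strictly convex
# quadratic programs with linear inequality constraints, solved by the
# Goldfarb-Idnani dual active-set method (quadprog::solve.QP):
#   - the l1 budget constraint on the expanded pattern is reformulated with
#     auxiliary magnitude variables t >= |H i|, sum(t) <= budget;
#   - the quadratic (integral) non-ROI bound is enforced by bisection on
#     its Lagrange multiplier (see dirmax), each inner problem being a QP;
#   - the per-element second-order-cone bounds are enforced by outer
#     linearization (supporting hyperplanes), each master problem a QP.
#
# minimize 0.5 i' Q2 i - lin' i
#   s.t.  ||H i||_1 <= budget,  lb <= H i <= ub,  extra_A %*% i <= extra_b
# where H is the L x (L-1) expansion matrix. Currents are scaled by
# budget/2 and the objective normalized so the active-set solver sees O(1)
# numbers; a tiny ridge keeps the Hessian positive definite when Q2 ~ 0.
qp_l1box <- function(Q2, lin, L, budget, lb, ub,
                     extra_A = NULL, extra_b = NULL) {
  n <- L - 1L
  s0 <- budget / 2
  Hexp <- rbind(diag(n), rep(-1, n))
  omega <- max(abs(lin)) * s0
  if (omega <= 0) omega <- max(max(abs(Q2)) * s0^2, 1)
  Hs <- Q2 * (s0^2 / omega)
  ls <- lin * (s0 / omega)
  ridge_i <- 1e-11 * max(1, max(abs(diag(Hs))))
  ridge_t <- 1e-10 * max(1, max(abs(diag(Hs))))
  D <- rbind(cbind(Hs + diag(ridge_i, n), matrix(0, n, L)),
             cbind(matrix(0, L, n), diag(ridge_t, L)))
  dv <- c(ls, rep(0, L))
  A <- rbind(
    cbind(Hexp, -diag(L)),              # H i - t <= 0
    cbind(-Hexp, -diag(L)),             # -H i - t <= 0
    c(rep(0, n), rep(1, L)),            # sum t <= 2
    cbind(matrix(0, L, n), -diag(L)),   # t >= 0
    cbind(Hexp, matrix(0, L, L)),       # H i <= ub
    cbind(-Hexp, matrix(0, L, L)))      # -H i <= -lb
  b <- c(rep(0, 2 * L), 2, rep(0, L), ub / s0, -lb / s0)
  if (!is.null(extra_A)) {
    A <- rbind(A, cbind(extra_A * s0, matrix(0, nrow(extra_A), L)))
    b <- c(b, extra_b)
  }
  sol <- tryCatch(
    quadprog::solve.QP(D, dv, t(-A), -b),
    error = function(e) e)
  if (inherits(sol, "error"))
    return(list(i = NULL, status = conditionMessage(sol)))
  list(i = sol$solution[seq_len(n)] * s0, status = "optimal")
}
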
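#' Conductivity map
#'
#' Scalar conductivity per tissue label, in S/m. A slot for per-element
#' 3x3 conductivity tensors is carried for forward compatibility; the
#' assembly implemented here is piecewise isotropic and refuses to run when
#' tensors are supplied.
#'
#' @param values named numeric vector, one positive scalar per tissue label
#'   in the mesh (names must match `mesh$tissue_names`), or an unnamed
#'   vector indexed by tissue label.
#' @param tensors optional list of per-element 3x3 matrices (not used by
#'   the isotropic solver).
#' @return object of class `conductivity_map`.
#' @examples
#' conductivity_map(c(brain = 0.33, csf = 1.79, skull = 0.006, scalp = 0.3))
#' @export
conductivity_map <- function(values, tensors = NULL) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all conductivities must be positive and finite (S/m)")
  structure(list(values = values, tensors = tensors),
            class = "conductivity_map")
}

# per-element scalar conductivity from a map (or plain vector) and a mesh
element_sigma <- function(cond, mesh) {
  if (inherits(cond, "conductivity_map")) {
    if (!is.null(cond$tensors))
      stop("tensor conductivities are not supported by the isotropic solver")
    cond <- cond$values
  }
  if (any(cond <= 0)) stop("all conductivities must be positive (S/m)")
  if (!is.null(names(cond)) && !is.null(mesh$tissue_names)) {
    miss <- setdiff(mesh$tissue_names, names(cond))
    if (length(miss)) stop("missing conductivity for tissue: ",
                           paste(miss, collapse = ", "))
    cond <- cond[mesh$tissue_names]
  }
  unname(cond[mesh$tissue])
}

#' Assemble the FEM system for the TES/EEG forward problem
#'
#' Builds the P x P stiffness matrix of the piecewise-isotropic Poisson
#' problem with linear (P1) tetrahedral elements and the Galerkin
#' approach: `K[i,j] = sum_e sigma_e V_e grad(phi_i).grad(phi_j)`. The
#' pure-Neumann system is singular with the constant vector as null space;
#' it is grounded by fixing the potential of one interior node (the node
#' nearest the mesh centroid) to zero. All reported quantities are
#' potential differences, so the grounding choice does not affect them.
#'
#' The sparse Cholesky factorization of the grounded system is computed
#' lazily on first solve and cached inside the returned object.
#'
#' @param mesh a [head_mesh()].
#' @param cond a [conductivity_map()] or named numeric vector (S/m).
#' @return object of class `fem_system` with fields `K` (sparse, symmetric,
#'   ungrounded), `ground_node`, `sigma` (per element), and `mesh`.
#' @export
assemble_fem <- function(mesh, cond) {
  stopifnot(inherits(mesh, "head_mesh"))
  sig <- element_sigma(cond, mesh)
  g <- mesh$grads
  vol <- mesh$volumes
  tets <- mesh$tets
  ii <- jj <- xx <- vector("list", 16L)
  k <- 1L
  for (i in 1:4) for (j in 1:4) {
    ii[[k]] <- tets[, i]
    jj[[k]] <- tets[, j]
    xx[[k]] <- sig * vol * rowSums(g[[i]] * g[[j]])
    k <- k + 1L
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nrow(mesh$nodes), nrow(mesh$nodes)))
  centroid <- colMeans(mesh$nodes)
  gnd <- which.min(rowSums((mesh$nodes -
           matrix(centroid, nrow(mesh$nodes), 3L, byrow = TRUE))^2))
  structure(list(K = K, ground_node = gnd, sigma = sig, mesh = mesh,
                 cache = new.env(parent = emptyenv())),
            class = "fem_system")
}

#' @export
print.fem_system <- function(x, ...) {
  cat("fem_system:", nrow(x$K), "nodes, ground node", x$ground_node, "\n")
  invisible(x)
}

# grounded solve K v = u (u over all nodes), cached Cholesky
fem_solve <- function(sys, u) {
  P <- nrow(sys$K)
  keep <- sys$cache$keep
  if (is.null(keep)) {
    keep <- setdiff(seq_len(P), sys$ground_node)
    sys$cache$keep <- keep
    sys$cache$chol <- Matrix::Cholesky(
      Matrix::forceSymmetric(sys$K[keep, keep]), LDL = FALSE)
  }
  nr <- if (is.matrix(u)) nrow(u) else length(u)
  if (nr != P) stop("load vector length must equal node count")
  if (is.matrix(u)) {
    v <- matrix(0, P, ncol(u))
    v[keep, ] <- as.matrix(Matrix::solve(sys$cache$chol, u[keep, , drop = FALSE]))
  } else {
    v <- numeric(P)
    v[keep] <- as.numeric(Matrix::solve(sys$cache$chol, u[keep]))
  }
  v
}

#' Solve the TES forward problem for one injection pattern
#'
#' Applies the expanded current pattern (one entry per electrode, in A,
#' summing to zero by Kirchhoff's law) as nodal point sources, solves the
#' grounded system, and evaluates the per-element constant electric field
#' `E = -grad(psi)`.
#'
#' @param sys a [assemble_fem()] system.
#' @param electrodes an [electrode_set()] on the same mesh.
#' @param pattern expanded current pattern (length L, A) or a
#'   [current_pattern()].
#' @return object of class `forward_solution` with `potential` (V, per
#'   node, zero at the ground node), `field` (N x 3, V/m per element), and
#'   `residual` (relative algebraic residual of the grounded solve).
#' @export
solve_forward <- function(sys, electrodes, pattern) {
  stopifnot(inherits(sys, "fem_system"), inherits(electrodes, "electrode_set"))
  if (inherits(pattern, "current_pattern")) pattern <- pattern$expanded
  L <- n_electrodes(electrodes)
  if (length(pattern) != L)
    stop("pattern must have one current per electrode (length ", L, ")")
  s1 <- sum(abs(pattern))
  if (abs(sum(pattern)) > 1e-12 * max(s1, 1e-30))
    stop("net injected current must be zero (Kirchhoff): got ", sum(pattern), " A")
  u <- numeric(nrow(sys$K))
  u[electrodes$node_index] <- u[electrodes$node_index] + pattern
  v <- fem_solve(sys, u)
  if (s1 > 0) {
    res <- sqrt(sum((as.numeric(sys$K %*% v) - u)[-sys$ground_node]^2)) /
      sqrt(sum(u^2))
    if (!is.finite(res) || res > 1e-8)
      stop(sprintf("forward solve did not converge: relative residual %.2e", res))
  } else res <- 0
  structure(list(potential = v, field = element_fields(sys$mesh, v),
                 residual = res),
            class = "forward_solution")
}

# E = -grad(psi) per element (N x 3) from nodal potentials
element_fields <- function(mesh, v, elements = NULL) {
  tets <- mesh$tets
  g <- mesh$grads
  if (!is.null(elements)) {
    tets <- tets[elements, , drop = FALSE]
    g <- lapply(g, function(m) m[elements, , drop = FALSE])
  }
  v1 <- v[tets[, 1L]]; v2 <- v[tets[, 2L]]
  v3 <- v[tets[, 3L]]; v4 <- v[tets[, 4L]]
  -(g[[1L]] * v1 + g[[2L]] * v2 + g[[3L]] * v3 + g[[4L]] * v4)
}

#' @export
print.forward_solution <- function(x, ...) {
  cat(sprintf("forward_solution: %d node potentials, %d element fields, residual %.1e\n",
              length(x$potential), nrow(x$field), x$residual))
  invisible(x)
}
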
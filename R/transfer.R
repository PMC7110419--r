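#' Build the TES transfer matrix
#'
#' Column l (l = 1..L-1) is the electric field over the element subset for
#' a unit current injected at electrode l with the reference electrode L as
#' sink. Rows are interleaved per element: `3*(n-1) + (1,2,3)` hold the
#' x/y/z field components of subset element n. By superposition the field
#' of any independent pattern `i` is `T %*% i`.
#'
#' @param sys a [assemble_fem()] system.
#' @param electrodes an [electrode_set()].
#' @param element_subset integer vector of element ids the matrix covers;
#'   default all elements with the first tissue label (the brain
#'   compartment). A warning is raised when the subset leaves the brain.
#' @return object of class `transfer_matrix`: `M` (3N x L-1, V/m per A),
#'   `elements` (subset ids), `volumes` (m^3 per subset element),
#'   `labels` (electrode labels), `L`.
#' @export
build_transfer_matrix <- function(sys, electrodes, element_subset = NULL) {
  stopifnot(inherits(sys, "fem_system"), inherits(electrodes, "electrode_set"))
  mesh <- sys$mesh
  if (is.null(element_subset)) element_subset <- which(mesh$tissue == 1L)
  element_subset <- as.integer(element_subset)
  if (!length(element_subset)) stop("element subset is empty")
  if (any(element_subset < 1L | element_subset > nrow(mesh$tets)))
    stop("element subset out of range")
  if (any(mesh$tissue[element_subset] != 1L))
    warning("element subset extends outside the brain compartment")
  L <- n_electrodes(electrodes)
  en <- electrodes$node_index
  N <- length(element_subset)
  M <- matrix(0, 3L * N, L - 1L)
  for (l in seq_len(L - 1L)) {
    u <- numeric(nrow(sys$K))
    u[en[l]] <- 1
    u[en[L]] <- u[en[L]] - 1
    v <- fem_solve(sys, u)
    M[, l] <- as.vector(t(element_fields(mesh, v, element_subset)))
  }
  structure(list(M = M, elements = element_subset,
                 volumes = mesh$volumes[element_subset],
                 labels = electrodes$labels, L = L),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("transfer_matrix: %d elements x %d independent electrodes (%.1f MB)\n",
              length(x$elements), ncol(x$M),
              utils::object.size(x$M) / 2^20))
  invisible(x)
}

#' Field of an injection pattern from the transfer matrix
#'
#' @param transfer a [build_transfer_matrix()] result.
#' @param pattern independent pattern (length L-1), expanded pattern
#'   (length L) or [current_pattern()].
#' @return N x 3 matrix of element fields (V/m).
#' @export
pattern_field <- function(transfer, pattern) {
  i <- as_independent(pattern, transfer$L)
  matrix(transfer$M %*% i, ncol = 3L, byrow = TRUE)
}

#' Compute the EEG lead field by dipole forward solves
#'
#' Row l of the lead field holds the potential at electrode l (relative to
#' the reference electrode) for unit current dipoles at each canonical
#' orientation of each subset element. Dipole sources are discretized by
#' partial integration: the load vector of a dipole with moment `m` in
#' element e has entries `-m . grad(phi_i)` at the four vertices of e.
#' With that source convention the lead field is the transpose of the
#' transfer matrix (reciprocity), which is the primary cross-check between
#' the TES and EEG routes: this function solves 3 per-element dipole
#' problems and never touches the transfer matrix.
#'
#' @inheritParams build_transfer_matrix
#' @param element_subset elements carrying the dipoles; use the same subset
#'   as the transfer matrix when testing reciprocity.
#' @return object of class `lead_field`: `M` ((L-1) x 3N, V/(A m)),
#'   `elements`, `s` (dipole density scale, fixed 1 A m/m^3).
#' @export
dipole_leadfield <- function(sys, electrodes, element_subset = NULL) {
  stopifnot(inherits(sys, "fem_system"), inherits(electrodes, "electrode_set"))
  mesh <- sys$mesh
  if (is.null(element_subset)) element_subset <- which(mesh$tissue == 1L)
  element_subset <- as.integer(element_subset)
  if (!length(element_subset)) stop("element subset is empty")
  L <- n_electrodes(electrodes)
  en <- electrodes$node_index
  touch <- mesh$tets[element_subset, , drop = FALSE] == sys$ground_node
  if (any(touch))
    warning("dipole element touches the ground node; potentials there are relative")
  N <- length(element_subset)
  P <- nrow(sys$K)
  out <- matrix(0, L - 1L, 3L * N)
  block <- 200L  # dipole solves batched against the cached factorization
  for (start in seq(1L, N, by = block)) {
    els <- element_subset[start:min(start + block - 1L, N)]
    nb <- length(els)
    U <- matrix(0, P, 3L * nb)
    for (j in seq_len(nb)) {
      e <- els[j]
      vid <- mesh$tets[e, ]
      for (d in 1:3) {
        col <- 3L * (j - 1L) + d
        for (k in 1:4) U[vid[k], col] <- U[vid[k], col] - mesh$grads[[k]][e, d]
      }
    }
    V <- fem_solve(sys, U)
    cols <- 3L * (start - 1L) + seq_len(3L * nb)
    out[, cols] <- V[en[-L], , drop = FALSE] -
      matrix(V[en[L], ], L - 1L, 3L * nb, byrow = TRUE)
  }
  structure(list(M = out, elements = element_subset, s = 1),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("lead_field: %d electrodes x %d dipole components\n",
              nrow(x$M), ncol(x$M)))
  invisible(x)
}
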
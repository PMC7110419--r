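#' Scalp electrode set
#'
#' Pointwise electrodes attached to mesh surface nodes. The last electrode
#' is the reference (current return) for the independent injection basis:
#' the transfer matrix column for electrode l is the field of +1 A at l and
#' -1 A at the reference.
#'
#' @param positions L x 3 matrix of electrode coordinates (m).
#' @param node_index integer vector of attachment node indices (1-based,
#'   all distinct).
#' @param labels character electrode labels (default E01..).
#' @return object of class `electrode_set`.
#' @export
electrode_set <- function(positions, node_index, labels = NULL) {
  positions <- as.matrix(positions)
  node_index <- as.integer(node_index)
  if (nrow(positions) != length(node_index))
    stop("one attachment node per electrode required")
  if (anyDuplicated(node_index))
    stop("electrode attachment nodes must be distinct")
  if (length(node_index) < 2L) stop("at least two electrodes required")
  if (is.null(labels)) labels <- sprintf("E%02d", seq_along(node_index))
  structure(list(positions = positions, node_index = node_index,
                 labels = as.character(labels)),
            class = "electrode_set")
}

#' Number of electrodes
#' @param electrodes an [electrode_set()].
#' @return integer L.
#' @export
n_electrodes <- function(electrodes) length(electrodes$node_index)

#' @export
print.electrode_set <- function(x, ...) {
  L <- n_electrodes(x)
  cat("electrode_set:", L, "electrodes, reference =", x$labels[L], "\n")
  invisible(x)
}

#' Attach electrodes at given positions to the nearest outer-surface nodes
#'
#' For user meshes: snaps each requested position to the nearest node of
#' the mesh boundary (faces owned by a single tetrahedron). Collisions are
#' resolved to the next nearest free node.
#'
#' @param mesh a [head_mesh()].
#' @param positions L x 3 matrix of requested positions (m).
#' @param labels optional labels; last row is the reference.
#' @return an [electrode_set()].
#' @export
snap_electrodes <- function(mesh, positions, labels = NULL) {
  positions <- as.matrix(positions)
  bn <- boundary_nodes(mesh)
  idx <- integer(nrow(positions))
  avail <- rep(TRUE, length(bn))
  for (l in seq_len(nrow(positions))) {
    d2 <- rowSums((mesh$nodes[bn, , drop = FALSE] -
                   matrix(positions[l, ], length(bn), 3L, byrow = TRUE))^2)
    d2[!avail] <- Inf
    j <- which.min(d2)
    idx[l] <- bn[j]
    avail[j] <- FALSE
  }
  electrode_set(mesh$nodes[idx, , drop = FALSE], idx, labels)
}

# nodes on the outer boundary: faces that occur exactly once in the mesh
boundary_nodes <- function(mesh) {
  f <- rbind(mesh$tets[, c(1, 2, 3)], mesh$tets[, c(1, 2, 4)],
             mesh$tets[, c(1, 3, 4)], mesh$tets[, c(2, 3, 4)])
  fs <- t(apply(f, 1L, sort))
  key <- paste(fs[, 1], fs[, 2], fs[, 3])
  once <- names(which(table(key) == 1L))
  sort(unique(as.vector(fs[key %in% once, ])))
}
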
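#' Select elements inside a sphere as an ROI
#'
#' @param mesh a [head_mesh()].
#' @param centre length-3 centre (m).
#' @param radius radius (m).
#' @param tissue tissue label to restrict to (default 1, brain).
#' @return integer vector of element ids.
#' @export
select_roi_sphere <- function(mesh, centre, radius, tissue = 1L) {
  d2 <- rowSums((mesh$centroids -
                 matrix(centre, nrow(mesh$centroids), 3L, byrow = TRUE))^2)
  which(d2 < radius^2 & mesh$tissue == tissue)
}

# boundary triangles of one tissue compartment with outward unit normals
compartment_surface <- function(mesh, tissue = 1L) {
  tt <- which(mesh$tissue == tissue)
  tet <- mesh$tets[tt, , drop = FALSE]
  f <- rbind(tet[, c(1, 2, 3)], tet[, c(1, 2, 4)],
             tet[, c(1, 3, 4)], tet[, c(2, 3, 4)])
  owner <- rep(tt, 4L)
  fs <- cbind(pmin(f[, 1], f[, 2], f[, 3]),
              f[, 1] + f[, 2] + f[, 3] -
                pmin(f[, 1], f[, 2], f[, 3]) - pmax(f[, 1], f[, 2], f[, 3]),
              pmax(f[, 1], f[, 2], f[, 3]))
  key <- paste(fs[, 1], fs[, 2], fs[, 3])
  cnt <- table(key)
  keep <- key %in% names(cnt)[cnt == 1L]
  fb <- fs[keep, , drop = FALSE]
  owner <- owner[keep]
  p1 <- mesh$nodes[fb[, 1], , drop = FALSE]
  p2 <- mesh$nodes[fb[, 2], , drop = FALSE]
  p3 <- mesh$nodes[fb[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  fc <- (p1 + p2 + p3) / 3
  # orient away from the owning tetrahedron centroid
  flip <- rowSums(nrm * (mesh$centroids[owner, , drop = FALSE] - fc)) > 0
  nrm[flip, ] <- -nrm[flip, ]
  list(centres = fc, normals = nrm)
}

#' Define the ROI and its desired orientation field
#'
#' Builds the targeting vector `d` over the transfer-matrix element subset:
#' non-zero (unit) vectors on the ROI elements, zero elsewhere. By default
#' the orientation follows the normal-to-cortex scheme: each ROI element
#' centroid is projected to the nearest triangle of the brain-compartment
#' surface, the outward normals of those triangles are averaged with
#' element-volume weights, and the single averaged unit vector is
#' replicated over the ROI. A user-supplied orientation (one vector, or one
#' row per ROI element) bypasses the averaging and is used as given.
#'
#' @param mesh a [head_mesh()].
#' @param roi_elements integer element ids of the ROI (inside the brain
#'   compartment, and inside the transfer subset).
#' @param transfer a [build_transfer_matrix()] result fixing the element
#'   subset and ordering of `d`.
#' @param orientation optional numeric: length-3 vector or
#'   `length(roi_elements)` x 3 matrix. Rows are not rescaled, so non-unit
#'   strengths are honoured.
#' @return object of class `target_spec`: `roi_elements` (global ids),
#'   `roi_local` (positions within the transfer subset), `d` (3N), `mean_orientation`,
#'   `roi_volume`, `nonroi_volume` (m^3).
#' @export
define_roi_orientation <- function(mesh, roi_elements, transfer,
                                   orientation = NULL) {
  stopifnot(inherits(mesh, "head_mesh"), inherits(transfer, "transfer_matrix"))
  roi_elements <- as.integer(roi_elements)
  if (!length(roi_elements)) stop("ROI is empty")
  roi_local <- match(roi_elements, transfer$elements)
  if (anyNA(roi_local))
    stop("ROI elements must lie inside the transfer-matrix element subset")
  nR <- length(roi_elements)
  if (is.null(orientation)) {
    surf <- compartment_surface(mesh, tissue = 1L)
    cent <- mesh$centroids[roi_elements, , drop = FALSE]
    nn <- apply(cent, 1L, function(p)
      which.min(rowSums((surf$centres -
                         matrix(p, nrow(surf$centres), 3L, byrow = TRUE))^2)))
    w <- mesh$volumes[roi_elements]
    avg <- colSums(surf$normals[nn, , drop = FALSE] * w)
    if (sqrt(sum(avg^2)) < 1e-8 * sum(w))
      stop("ROI surface normals average to zero (antipodal normals); ",
           "supply an orientation explicitly")
    avg <- avg / sqrt(sum(avg^2))
    dmat <- matrix(avg, nR, 3L, byrow = TRUE)
    mean_orientation <- avg
  } else {
    dmat <- if (is.matrix(orientation)) orientation
            else matrix(orientation, nR, 3L, byrow = TRUE)
    if (nrow(dmat) != nR || ncol(dmat) != 3L)
      stop("'orientation' must be a 3-vector or an nROI x 3 matrix")
    mo <- unname(colSums(dmat))
    mean_orientation <- if (sum(mo^2) > 0) mo / sqrt(sum(mo^2)) else mo
  }
  d <- numeric(3L * length(transfer$elements))
  d[rep(3L * (roi_local - 1L), each = 3L) + 1:3] <- as.vector(t(dmat))
  structure(list(roi_elements = roi_elements, roi_local = roi_local,
                 d = d, mean_orientation = mean_orientation,
                 roi_volume = sum(mesh$volumes[roi_elements]),
                 nonroi_volume = sum(transfer$volumes) -
                   sum(mesh$volumes[roi_elements])),
            class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf("target_spec: %d ROI elements (%.2f cm^3), orientation [%s]\n",
              length(x$roi_elements), 1e6 * x$roi_volume,
              paste(sprintf("%.3f", x$mean_orientation), collapse = ", ")))
  invisible(x)
}

#' Diagonal volume weight matrices
#'
#' The volume integrals of the continuous targeting problem discretize to
#' diagonal weight matrices: `Gamma` carries each element volume (repeated
#' for the x/y/z rows), `Gamma_nonROI` equals `Gamma` with the ROI entries
#' zeroed. Since the ROI is typically a tiny volume fraction,
#' `Gamma_nonROI ~ Gamma`; mode `"approximate"` adopts that identity (and
#' reproduces the classical WLS equivalence literally), mode `"exact"`
#' (default) keeps the ROI entries zeroed.
#'
#' @param transfer a [build_transfer_matrix()] result.
#' @param target a [define_roi_orientation()] result (or NULL with
#'   `mode = "approximate"`).
#' @param mode `"exact"` or `"approximate"`.
#' @return object of class `volume_weights`: `gamma`, `gamma_nonroi`
#'   (length 3N diagonals, m^3), `mode`.
#' @export
build_volume_weights <- function(transfer, target = NULL,
                                 mode = c("exact", "approximate")) {
  mode <- match.arg(mode)
  gamma <- rep(transfer$volumes, each = 3L)
  gamma_nr <- gamma
  if (mode == "exact") {
    if (is.null(target)) stop("exact mode needs the target_spec")
    gamma_nr[rep(3L * (target$roi_local - 1L), each = 3L) + 1:3] <- 0
  }
  structure(list(gamma = gamma, gamma_nonroi = gamma_nr, mode = mode),
            class = "volume_weights")
}

#' @export
print.volume_weights <- function(x, ...) {
  cat(sprintf("volume_weights (%s): trace %.3e m^3, nonROI trace %.3e m^3\n",
              x$mode, sum(x$gamma), sum(x$gamma_nonroi)))
  invisible(x)
}
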
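#' Tetrahedral head mesh
#'
#' A labelled tetrahedral mesh: node coordinates, tetrahedra as 1-based node
#' indices, and one integer tissue label per element. Element volumes,
#' centroids and the P1 shape-function gradients are computed on
#' construction and cached in the object; all downstream stages (FEM
#' assembly, field evaluation, volume weights) read them from here.
#'
#' @param nodes numeric P x 3 matrix of node coordinates in metres.
#' @param tets integer N x 4 matrix of node indices (1-based). Elements are
#'   reoriented so that all signed volumes are positive.
#' @param tissue integer vector of length N with per-element tissue labels.
#' @param tissue_names optional character vector naming the labels, e.g.
#'   `c("brain", "csf", "skull", "scalp")` for labels 1:4.
#' @return An object of class `head_mesh` with fields `nodes`, `tets`,
#'   `tissue`, `tissue_names`, `volumes` (m^3), `centroids`, and `grads`
#'   (list of four N x 3 matrices, the constant gradient of each vertex
#'   shape function).
#' @export
head_mesh <- function(nodes, tets, tissue, tissue_names = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  dimnames(nodes) <- NULL
  dimnames(tets) <- NULL
  if (ncol(nodes) != 3L) stop("'nodes' must be a P x 3 matrix")
  if (ncol(tets) != 4L) stop("'tets' must be an N x 4 matrix")
  if (length(tissue) != nrow(tets))
    stop("'tissue' must have one label per tetrahedron")
  if (min(tets) < 1L || max(tets) > nrow(nodes))
    stop("tetrahedron node indices out of range")
  geo <- tet_geometry(nodes, tets)
  neg <- geo$vol6 < 0
  if (any(neg)) {
    tmp <- tets[neg, 3L]
    tets[neg, 3L] <- tets[neg, 4L]
    tets[neg, 4L] <- tmp
    geo <- tet_geometry(nodes, tets)
  }
  dg <- which(geo$vol6 <= 0)
  if (length(dg))
    stop("degenerate tetrahedra (zero volume), first element id: ", dg[1L])
  cent <- (nodes[tets[, 1L], ] + nodes[tets[, 2L], ] +
           nodes[tets[, 3L], ] + nodes[tets[, 4L], ]) / 4
  structure(
    list(nodes = nodes, tets = tets, tissue = as.integer(tissue),
         tissue_names = tissue_names, volumes = geo$vol6 / 6,
         centroids = cent, grads = geo$grads),
    class = "head_mesh")
}

# signed 6*volume and shape-function gradients for all tets at once
tet_geometry <- function(nodes, tets) {
  p1 <- nodes[tets[, 1L], , drop = FALSE]
  a <- nodes[tets[, 2L], , drop = FALSE] - p1
  b <- nodes[tets[, 3L], , drop = FALSE] - p1
  cc <- nodes[tets[, 4L], , drop = FALSE] - p1
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bxc <- cr(b, cc)
  vol6 <- rowSums(a * bxc)
  g2 <- bxc / vol6
  g3 <- cr(cc, a) / vol6
  g4 <- cr(a, b) / vol6
  g1 <- -(g2 + g3 + g4)
  list(vol6 = vol6, grads = list(g1, g2, g3, g4))
}

#' Per-element volumes of a head mesh
#'
#' @param mesh a [head_mesh()].
#' @return numeric vector of element volumes in m^3.
#' @export
tet_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "head_mesh"))
  mesh$volumes
}

#' @export
print.head_mesh <- function(x, ...) {
  cat("head_mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "tetrahedra\n")
  tb <- table(x$tissue)
  nm <- if (!is.null(x$tissue_names)) x$tissue_names[as.integer(names(tb))]
        else names(tb)
  cat("  tissues:",
      paste(sprintf("%s (%d el., %.1f cm^3)", nm, tb,
                    1e6 * tapply(x$volumes, x$tissue, sum)), collapse = ", "),
      "\n")
  cat(sprintf("  total volume %.2f cm^3\n", 1e6 * sum(x$volumes)))
  invisible(x)
}

## ---- icosphere machinery -------------------------------------------------

icosahedron_surface <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

subdivide_surface <- function(s) {
  v <- s$v; f <- s$f
  nf <- nrow(f)
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  uk <- unique(key)
  mid_id <- match(key, uk) + nrow(v)
  ue <- edges[!duplicated(key), , drop = FALSE]
  mid <- (v[ue[, 1], ] + v[ue[, 2], ]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  m1 <- mid_id[1:nf]; m2 <- mid_id[nf + 1:nf]; m3 <- mid_id[2 * nf + 1:nf]
  list(v = rbind(v, mid),
       f = rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
                 cbind(f[, 3], m3, m2), cbind(m1, m2, m3)))
}

icosphere_surface <- function(level) {
  s <- icosahedron_surface()
  for (i in seq_len(level)) s <- subdivide_surface(s)
  s
}

# conforming tetrahedralization of concentric shells of one triangulated
# sphere: centre fan inside the innermost shell, 3 tets per prism between
# consecutive shells with quad diagonals fixed by surface vertex order
# returns the tets plus the gap index each tet came from (1 = centre fan
# inside shell 1, s+1 = prisms between shells s and s+1); tissue labels
# are assigned per gap so thin layers are labelled exactly
shell_tets <- function(surf, n_shells) {
  V <- nrow(surf$v)
  f <- surf$f
  off <- function(s) 1L + (s - 1L) * V
  fs <- f
  # sort each face's vertices (diagonal consistency); orientation fixed later
  o <- cbind(pmin(f[, 1], f[, 2], f[, 3]),
             f[, 1] + f[, 2] + f[, 3] -
               pmin(f[, 1], f[, 2], f[, 3]) - pmax(f[, 1], f[, 2], f[, 3]),
             pmax(f[, 1], f[, 2], f[, 3]))
  fs <- o
  out <- vector("list", n_shells)
  out[[1L]] <- cbind(1L, f[, 1] + off(1), f[, 2] + off(1), f[, 3] + off(1))
  for (s in seq_len(n_shells - 1L)) {
    b1 <- fs[, 1] + off(s);     b2 <- fs[, 2] + off(s);     b3 <- fs[, 3] + off(s)
    t1 <- fs[, 1] + off(s + 1); t2 <- fs[, 2] + off(s + 1); t3 <- fs[, 3] + off(s + 1)
    out[[s + 1L]] <- rbind(cbind(b1, b2, b3, t3),
                           cbind(b1, b2, t3, t2),
                           cbind(b1, t2, t3, t1))
  }
  list(tets = do.call(rbind, out),
       gap = rep(seq_len(n_shells), vapply(out, nrow, 0L)))
}

#' Generate a layered concentric-sphere head model with scalp electrodes
#'
#' Builds a conforming tetrahedral mesh of four nested spherical shells
#' (brain, CSF, skull, scalp) from concentric copies of a subdivided
#' icosahedron, with a centre fan inside the innermost shell and three
#' tetrahedra per triangular prism between shells. Tissue interfaces fall
#' exactly on shell surfaces. Electrodes are placed quasi-uniformly on the
#' outer sphere (Fibonacci lattice) and snapped to distinct surface nodes;
#' the last electrode is the reference.
#'
#' The mesh is deterministic given `seed`: the seed drives a random rigid
#' rotation applied to the whole tessellation and to the electrode lattice,
#' which decorrelates mesh symmetry axes from the coordinate axes.
#'
#' @param radii strictly increasing numeric vector of 4 interface radii in
#'   metres (brain, CSF, skull, scalp outer radii). Default 80/81/86/92 mm.
#' @param edge_length target tangential edge length in metres; sets the
#'   icosphere subdivision level.
#' @param radial_spacing target radial shell spacing in metres (default
#'   `edge_length`); every tissue gets at least one shell layer.
#' @param n_electrodes number of scalp electrodes (must not exceed the
#'   number of outer-surface nodes).
#' @param seed integer seed for the rigid rotations.
#' @return list with components `mesh` (a [head_mesh()], tissue labels
#'   1 = brain, 2 = csf, 3 = skull, 4 = scalp) and `electrodes` (an
#'   [electrode_set()]).
#' @examples
#' hd <- generate_sphere_head(edge_length = 0.03, n_electrodes = 16, seed = 1)
#' hd$mesh
#' @export
generate_sphere_head <- function(radii = c(0.080, 0.081, 0.086, 0.092),
                                 edge_length = 0.013,
                                 radial_spacing = edge_length,
                                 n_electrodes = 64L, seed = 1L) {
  if (length(radii) != 4L || any(diff(radii) <= 0))
    stop("'radii' must be 4 strictly increasing values (m)")
  if (edge_length <= 0 || radial_spacing <= 0)
    stop("edge and radial spacings must be positive")
  R <- radii[4L]
  # icosahedron edge subtends ~1.107 rad; each subdivision halves it
  level <- max(1L, ceiling(log2(R * 1.10715 / edge_length)))
  if (20 * 4^level > 6e5)
    stop("meshing failure: edge_length ", edge_length,
         " m needs subdivision level ", level, " (too many elements)")
  surf <- icosphere_surface(level)

  # radial shells: inside brain, then one set per outer tissue
  n_in <- max(2L, round(radii[1L] / radial_spacing))
  shells <- radii[1L] * seq_len(n_in) / n_in
  for (j in 2:4) {
    nl <- max(1L, round((radii[j] - radii[j - 1L]) / radial_spacing))
    shells <- c(shells, radii[j - 1L] +
                  (radii[j] - radii[j - 1L]) * seq_len(nl) / nl)
  }

  rot <- seeded_rotation(seed)
  v <- surf$v %*% t(rot)
  V <- nrow(v)
  nodes <- matrix(0, 1L + length(shells) * V, 3L)
  for (s in seq_along(shells)) nodes[1L + (s - 1L) * V + 1:V, ] <- v * shells[s]
  st <- shell_tets(surf, length(shells))
  tets <- st$tets
  # tissue of a gap is the tissue of its outer shell radius
  gap_tissue <- findInterval(shells * (1 - 1e-9), radii[1:3]) + 1L
  tissue <- gap_tissue[st$gap]
  mesh <- head_mesh(nodes, tets, tissue,
                    tissue_names = c("brain", "csf", "skull", "scalp"))

  # analytic-volume sanity: the chordal mesh must be close to the ball
  vol_err <- abs(sum(mesh$volumes) / (4 / 3 * pi * R^3) - 1)
  if (vol_err > 0.05)
    warning(sprintf("mesh volume deviates %.1f%% from the analytic sphere; %s",
                    100 * vol_err, "decrease edge_length"))

  outer <- which(sqrt(rowSums(nodes^2)) > R * (1 - 1e-9))
  elec <- place_fibonacci_electrodes(mesh, outer, n_electrodes, rot)
  list(mesh = mesh, electrodes = elec)
}

# deterministic uniformly-distributed rotation matrix from a seed
seeded_rotation <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  M <- matrix(stats::rnorm(9), 3L)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  Q <- Q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

place_fibonacci_electrodes <- function(mesh, outer_nodes, n, rot) {
  if (n > length(outer_nodes))
    stop("cannot place ", n, " electrodes on ", length(outer_nodes),
         " outer-surface nodes; refine the mesh")
  gr <- (1 + sqrt(5)) / 2
  k <- seq_len(n) - 0.5
  th <- acos(1 - 2 * k / n)
  ph <- 2 * pi * k / gr
  dirs <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)) %*% t(rot)
  pos <- mesh$nodes[outer_nodes, , drop = FALSE]
  pos_u <- pos / sqrt(rowSums(pos^2))
  idx <- integer(n)
  avail <- rep(TRUE, length(outer_nodes))
  for (l in seq_len(n)) {
    d2 <- rowSums((pos_u - matrix(dirs[l, ], nrow(pos_u), 3L, byrow = TRUE))^2)
    d2[!avail] <- Inf
    j <- which.min(d2)
    idx[l] <- outer_nodes[j]
    avail[j] <- FALSE
  }
  electrode_set(mesh$nodes[idx, , drop = FALSE], idx,
                labels = sprintf("E%02d", seq_len(n)))
}
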
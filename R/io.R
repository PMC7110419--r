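# Plain-text file formats. Conventions: metres and amperes internally;
# the mesh format stores metres, electrode files metres, pattern files mA.
# Node/element indices are 1-based in all text formats.

#' Write / read a head mesh in the package's plain-text format
#'
#' Line-oriented format: a `nodes P` section (x y z in metres, full
#' precision), a `tets N` section (four 1-based node ids plus the integer
#' tissue label) and an optional `tissues` section naming the labels.
#' Round-trips exactly.
#'
#' @param mesh a [head_mesh()].
#' @param path file path.
#' @return `read_head_mesh` returns a [head_mesh()]; `write_head_mesh`
#'   returns `path` invisibly.
#' @export
write_head_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# tesopt head mesh v1",
               "# nodes: x y z (m); tets: 1-based node ids + tissue label",
               paste("nodes", nrow(mesh$nodes))), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(paste("tets", nrow(mesh$tets)), con)
  writeLines(sprintf("%d %d %d %d %d", mesh$tets[, 1], mesh$tets[, 2],
                     mesh$tets[, 3], mesh$tets[, 4], mesh$tissue), con)
  if (!is.null(mesh$tissue_names)) {
    writeLines(paste("tissues", length(mesh$tissue_names)), con)
    writeLines(sprintf("%d %s", seq_along(mesh$tissue_names),
                       mesh$tissue_names), con)
  }
  invisible(path)
}

#' @rdname write_head_mesh
#' @export
read_head_mesh <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  expect_kw <- function(line, kw) {
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (parts[1] != kw) stop("malformed mesh file: expected '", kw, "' section")
    as.integer(parts[2])
  }
  P <- expect_kw(ln[1], "nodes")
  nodes <- matrix(scan(text = ln[2:(1 + P)], quiet = TRUE), P, 3, byrow = TRUE)
  N <- expect_kw(ln[2 + P], "tets")
  tt <- matrix(scan(text = ln[(3 + P):(2 + P + N)], quiet = TRUE),
               N, 5, byrow = TRUE)
  tissue_names <- NULL
  pos <- 3 + P + N
  if (pos <= length(ln) && startsWith(trimws(ln[pos]), "tissues")) {
    k <- expect_kw(ln[pos], "tissues")
    rows <- strsplit(trimws(ln[(pos + 1):(pos + k)]), "\\s+")
    tissue_names <- vapply(rows, `[`, "", 2)[order(as.integer(vapply(rows, `[`, "", 1)))]
  }
  head_mesh(nodes, tt[, 1:4], as.integer(tt[, 5]), tissue_names)
}

#' Import a tetrahedral mesh from Gmsh MSH 2.2 ASCII
#'
#' Reads `$Nodes` and the tetrahedral entries (element type 4) of
#' `$Elements`; the first element tag (physical group) becomes the tissue
#' label. Other element types are ignored.
#'
#' @param path file path to a `.msh` file (format 2.2, ASCII).
#' @return a [head_mesh()].
#' @export
read_msh <- function(path) {
  ln <- readLines(path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), ln)
    i1 <- match(paste0("$End", name), ln)
    if (is.na(i0) || is.na(i1)) stop("MSH file lacks $", name, " section")
    ln[(i0 + 1):(i1 - 1)]
  }
  fmt <- strsplit(trimws(sect("MeshFormat")[1]), "\\s+")[[1]]
  if (fmt[1] != "2.2") stop("only MSH format 2.2 ASCII is supported, got ", fmt[1])
  nl <- sect("Nodes")
  P <- as.integer(nl[1])
  nd <- matrix(scan(text = nl[-1], quiet = TRUE), P, 4, byrow = TRUE)
  id_map <- integer(max(nd[, 1]))
  id_map[as.integer(nd[, 1])] <- seq_len(P)
  el <- sect("Elements")[-1]
  rows <- strsplit(trimws(el), "\\s+")
  tets <- list(); lab <- list(); k <- 0L
  for (r in rows) {
    v <- as.integer(r)
    if (v[2] == 4L) {        # type 4 = linear tetrahedron
      ntag <- v[3]
      k <- k + 1L
      tets[[k]] <- id_map[v[(4 + ntag):(7 + ntag)]]
      lab[[k]] <- if (ntag >= 1L) v[4] else 1L
    }
  }
  if (!k) stop("no tetrahedra (element type 4) in MSH file")
  head_mesh(nd[, 2:4], do.call(rbind, tets), unlist(lab))
}

#' Write / read an electrode set as CSV
#'
#' Columns `label,x,y,z` in metres; the last row is the reference
#' electrode. Reading snaps positions to the nearest boundary nodes of the
#' given mesh.
#'
#' @param electrodes an [electrode_set()].
#' @param path file path.
#' @param mesh a [head_mesh()] (for `read_electrodes`).
#' @return `read_electrodes` returns an [electrode_set()].
#' @export
write_electrodes <- function(electrodes, path) {
  df <- data.frame(label = electrodes$labels,
                   x = sprintf("%.17g", electrodes$positions[, 1]),
                   y = sprintf("%.17g", electrodes$positions[, 2]),
                   z = sprintf("%.17g", electrodes$positions[, 3]))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_electrodes
#' @export
read_electrodes <- function(path, mesh) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  snap_electrodes(mesh, as.matrix(df[, c("x", "y", "z")]), labels = df$label)
}

#' Write / read a current injection pattern as CSV
#'
#' Columns `electrode_label,current_mA` with 9 significant digits; the
#' last (reference) entry is written as the negative partial sum of the
#' serialized values, so the file sums to zero bit-consistently.
#'
#' @param pattern a [current_pattern()] or expanded numeric pattern (A).
#' @param labels electrode labels.
#' @param path file path.
#' @return `read_pattern` returns a [current_pattern()] (A).
#' @export
write_pattern <- function(pattern, labels, path) {
  if (inherits(pattern, "current_pattern")) pattern <- pattern$expanded
  L <- length(pattern)
  # serialize the first L-1 currents at 9 significant digits, then compute
  # the reference entry as the negative sum of the values as parsed back,
  # so the file sums to zero bit-consistently
  txt <- sprintf("%.9g", 1e3 * pattern[-L])
  ref <- -sum(as.numeric(txt))
  df <- data.frame(electrode_label = labels,
                   current_mA = c(txt, sprintf("%.17g", ref)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  expand_pattern(1e-3 * df$current_mA[-nrow(df)])
}

#' Read an ROI element list or an orientation override
#'
#' The ROI file holds one 1-based element index per line (`#` comments
#' allowed). The orientation override is a CSV with columns
#' `element,dx,dy,dz` giving the desired field direction (and strength,
#' if not unit) per ROI element.
#'
#' @param path file path.
#' @return `read_roi_elements`: integer element ids.
#'   `read_orientation_override`: data.frame with `element` and the
#'   orientation matrix columns.
#' @export
read_roi_elements <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  ids <- suppressWarnings(as.integer(ln))
  if (anyNA(ids)) stop("ROI file must hold one element index per line")
  ids
}

#' @rdname read_roi_elements
#' @export
read_orientation_override <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", "dx", "dy", "dz")
  if (!all(need %in% names(df)))
    stop("orientation override needs columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Write a sweep table (and critical points) as CSV
#'
#' @param sweep a [alpha_sweep()] result.
#' @param path file path for the trade-off table.
#' @param critical_path optional path for a one-row critical-points CSV.
#' @return `path` invisibly.
#' @export
write_sweep <- function(sweep, path, critical_path = NULL) {
  write.csv(sweep$table, path, row.names = FALSE)
  if (!is.null(critical_path))
    write.csv(data.frame(mode = sweep$mode, critical_a = sweep$critical_a,
                         critical_b = sweep$critical_b,
                         critical_c = sweep$critical_c),
              critical_path, row.names = FALSE)
  invisible(path)
}
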
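#' Measured or simulated top-surface displacement field
#'
#' Displacements on the regular surface node lattice, stored as `nx x ny`
#' matrices indexed `[i, j]` (i along x, j along y).  `uz` is optional: 2D
#' digital image correlation of bead images yields only the in-plane
#' components.  Nodes without usable data (failed correlation windows,
#' masked regions) are flagged invalid; invalid entries may be `NA`.
#'
#' @param grid A [surface_grid()].
#' @param ux,uy In-plane displacement matrices, um.
#' @param uz Optional out-of-plane displacement matrix, um.
#' @param valid Logical matrix marking usable nodes; defaults to wherever
#'   all supplied components are finite.
#' @return An object of class `surface_displacement_field`.
#' @export
surface_displacement_field <- function(grid, ux, uy, uz = NULL, valid = NULL) {
  stopifnot(inherits(grid, "surface_grid"))
  dims <- c(grid$nx, grid$ny)
  for (nm in c("ux", "uy")) {
    m <- get(nm)
    if (!is.matrix(m) || !all(dim(m) == dims)) {
      stop("`", nm, "` must be a ", dims[1], " x ", dims[2], " matrix")
    }
  }
  if (!is.null(uz) && (!is.matrix(uz) || !all(dim(uz) == dims))) {
    stop("`uz` must be a ", dims[1], " x ", dims[2], " matrix or NULL")
  }
  fin <- is.finite(ux) & is.finite(uy)
  if (!is.null(uz)) fin <- fin & is.finite(uz)
  if (is.null(valid)) {
    valid <- fin
  } else {
    if (!is.matrix(valid) || !all(dim(valid) == dims) || !is.logical(valid)) {
      stop("`valid` must be a logical ", dims[1], " x ", dims[2], " matrix")
    }
    if (any(valid & !fin)) stop("non-finite displacement at a node marked valid")
  }
  structure(
    list(grid = grid, ux = ux, uy = uy, uz = uz, valid = valid),
    class = "surface_displacement_field"
  )
}

#' @export
print.surface_displacement_field <- function(x, ...) {
  cat("<surface_displacement_field> ", x$grid$nx, "x", x$grid$ny, "nodes,",
      if (is.null(x$uz)) "in-plane (ux, uy)" else "3D (ux, uy, uz)", ",",
      sum(!x$valid), "invalid\n")
  invisible(x)
}

#' Does a displacement field carry the out-of-plane component?
#' @param disp A [surface_displacement_field()].
#' @return `TRUE` if `uz` is present.
#' @export
has_uz <- function(disp) !is.null(disp$uz)

#' Integer-labelled cell/cluster mask on a surface grid
#'
#' Label 0 marks extracellular (traction-free) nodes; labels 1..M mark the
#' nodes lying under cell or cluster 1..M.
#'
#' @param grid A [surface_grid()].
#' @param labels Integer matrix `nx x ny`, non-negative.
#' @return An object of class `cluster_mask`.
#' @export
cluster_mask <- function(grid, labels) {
  stopifnot(inherits(grid, "surface_grid"))
  if (!is.matrix(labels) || !all(dim(labels) == c(grid$nx, grid$ny))) {
    stop("`labels` must be a ", grid$nx, " x ", grid$ny, " matrix")
  }
  if (any(!is.finite(labels)) || any(labels < 0) ||
      any(abs(labels - round(labels)) > 0)) {
    stop("labels must be non-negative integers")
  }
  storage.mode(labels) <- "integer"
  structure(list(grid = grid, labels = labels), class = "cluster_mask")
}

#' @export
print.cluster_mask <- function(x, ...) {
  ids <- cluster_ids(x)
  cat("<cluster_mask> ", x$grid$nx, "x", x$grid$ny, "nodes,",
      length(ids), "cluster(s):",
      paste(sprintf("%d (%d nodes)", ids,
                    vapply(ids, function(l) sum(x$labels == l), 1L)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Cluster ids present in a mask or traction field
#' @param x A [cluster_mask()] or [traction_field()].
#' @return Sorted integer vector of nonzero labels.
#' @export
cluster_ids <- function(x) sort(unique(x$labels[x$labels > 0L]))

#' Tributary surface areas of the grid nodes
#'
#' Each node owns the part of the top surface nearest to it: `sx * sy` for
#' interior nodes, halved along edges, quartered at corners.  The areas tile
#' the surface exactly, so traction and nodal force convert consistently.
#'
#' @param grid A [surface_grid()].
#' @return Matrix `nx x ny` of areas, um^2.
#' @export
tributary_areas <- function(grid) {
  wx <- rep(grid$spacing[1], grid$nx)
  wx[c(1, grid$nx)] <- grid$spacing[1] / 2
  wy <- rep(grid$spacing[2], grid$ny)
  wy[c(1, grid$ny)] <- grid$spacing[2] / 2
  outer(wx, wy)
}

#' Recovered traction field
#'
#' Per top-surface node: traction vector (kPa), nodal force (nN, traction
#' times tributary area) and cluster label.  Out-of-plane components are
#' absent when recovery ran in in-plane mode.
#'
#' @param grid A [surface_grid()].
#' @param tx,ty Traction components, kPa (`nx x ny`).
#' @param tz Optional out-of-plane traction, kPa.
#' @param labels Integer label matrix (as in [cluster_mask()]).
#' @return An object of class `traction_field` with elements `tx, ty, tz,
#'   fx, fy, fz, area, labels`.
#' @export
traction_field <- function(grid, tx, ty, tz = NULL, labels) {
  stopifnot(inherits(grid, "surface_grid"))
  dims <- c(grid$nx, grid$ny)
  for (nm in c("tx", "ty")) {
    if (!is.matrix(get(nm)) || !all(dim(get(nm)) == dims)) {
      stop("`", nm, "` must be a ", dims[1], " x ", dims[2], " matrix")
    }
  }
  if (!is.null(tz) && (!is.matrix(tz) || !all(dim(tz) == dims))) {
    stop("`tz` must be a matrix or NULL")
  }
  area <- tributary_areas(grid)
  storage.mode(labels) <- "integer"
  structure(
    list(grid = grid, tx = tx, ty = ty, tz = tz,
         fx = tx * area, fy = ty * area,
         fz = if (is.null(tz)) NULL else tz * area,
         area = area, labels = labels),
    class = "traction_field"
  )
}

#' @export
print.traction_field <- function(x, ...) {
  tmag <- traction_magnitude(x)
  cat("<traction_field> ", x$grid$nx, "x", x$grid$ny, "nodes,",
      if (is.null(x$tz)) "in-plane" else "3D",
      sprintf("; peak traction %.4g kPa, clusters: %s\n", max(tmag),
              paste(cluster_ids(x), collapse = ", ")))
  invisible(x)
}

#' Traction magnitude per node
#' @param tf A [traction_field()].
#' @return Matrix `nx x ny` of vector magnitudes, kPa.
#' @export
traction_magnitude <- function(tf) {
  m <- tf$tx^2 + tf$ty^2
  if (!is.null(tf$tz)) m <- m + tf$tz^2
  sqrt(m)
}

#' Nodal force magnitude per node
#' @param tf A [traction_field()].
#' @return Matrix `nx x ny` of vector magnitudes, nN.
#' @export
force_magnitude <- function(tf) {
  m <- tf$fx^2 + tf$fy^2
  if (!is.null(tf$fz)) m <- m + tf$fz^2
  sqrt(m)
}

#' Prescribed surface force field (synthetic ground truth)
#'
#' Nodal forces applied to the top surface by the forward simulator, with
#' their cluster labels and generator provenance.  Self-equilibrated
#' generators guarantee per-cluster zero net in-plane force at construction.
#'
#' @param grid A [surface_grid()].
#' @param fx,fy Nodal force matrices, nN.
#' @param fz Optional out-of-plane nodal forces, nN.
#' @param labels Integer label matrix.
#' @param metadata Named list recording the generator and its parameters.
#' @return An object of class `prescribed_force_field`.
#' @export
prescribed_force_field <- function(grid, fx, fy, fz = NULL, labels,
                                   metadata = list()) {
  stopifnot(inherits(grid, "surface_grid"))
  dims <- c(grid$nx, grid$ny)
  for (nm in c("fx", "fy")) {
    if (!is.matrix(get(nm)) || !all(dim(get(nm)) == dims)) {
      stop("`", nm, "` must be a ", dims[1], " x ", dims[2], " matrix")
    }
  }
  if (!is.null(fz) && (!is.matrix(fz) || !all(dim(fz) == dims))) {
    stop("`fz` must be a matrix or NULL")
  }
  storage.mode(labels) <- "integer"
  loaded <- abs(fx) > 0 | abs(fy) > 0
  if (!is.null(fz)) loaded <- loaded | abs(fz) > 0
  if (any(loaded & labels == 0L)) {
    stop("nonzero force at an unlabelled node")
  }
  structure(
    list(grid = grid, fx = fx, fy = fy, fz = fz, labels = labels,
         metadata = metadata),
    class = "prescribed_force_field"
  )
}

#' @export
print.prescribed_force_field <- function(x, ...) {
  cat("<prescribed_force_field> ", x$grid$nx, "x", x$grid$ny, "nodes, generator:",
      if (is.null(x$metadata$generator)) "?" else x$metadata$generator, "\n")
  invisible(x)
}

#' Net in-plane force of each cluster of a prescribed field
#' @param field A [prescribed_force_field()].
#' @return Matrix with one row per cluster, columns `fx`, `fy` (nN).
#' @export
prescribed_net_forces <- function(field) {
  ids <- sort(unique(field$labels[field$labels > 0L]))
  out <- t(vapply(ids, function(l) {
    sel <- field$labels == l
    c(fx = sum(field$fx[sel]), fy = sum(field$fy[sel]))
  }, c(fx = 0, fy = 0)))
  rownames(out) <- ids
  out
}
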
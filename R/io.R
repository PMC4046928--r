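#' Read a surface displacement field from CSV
#'
#' Expected header: `x_um,y_um,ux_um,uy_um` with an optional `uz_um`
#' column; one row per grid node, any order (canonically row-major, x
#' fastest).  The grid is inferred from the unique sorted coordinates;
#' spacing must be uniform to 1e-6 relative.  Nodes absent from the file
#' (or with non-finite components) are marked invalid.  Lines starting with
#' `#` are metadata comments and are skipped.
#'
#' @param path CSV file path.
#' @return A [surface_displacement_field()].
#' @export
read_displacement_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (nrow(df) == 0L) stop("format error: ", path, " contains no data rows")
  base_cols <- c("x_um", "y_um", "ux_um", "uy_um")
  if (!all(base_cols %in% names(df))) {
    stop("format error: header must contain ", paste(base_cols, collapse = ","),
         " (optionally uz_um)")
  }
  with_z <- "uz_um" %in% names(df)
  xs <- unique_sorted_coords(df$x_um, "x")
  ys <- unique_sorted_coords(df$y_um, "y")
  grid <- surface_grid(length(xs), length(ys),
                       c(spacing_of(xs, "x"), spacing_of(ys, "y")),
                       origin = c(xs[1], ys[1]))
  i <- round((df$x_um - xs[1]) / grid$spacing[1]) + 1L
  j <- round((df$y_um - ys[1]) / grid$spacing[2]) + 1L
  lin <- (j - 1L) * grid$nx + i
  if (anyDuplicated(lin)) stop("format error: duplicate grid nodes in ", path)
  ux <- matrix(NA_real_, grid$nx, grid$ny); uy <- ux
  ux[lin] <- df$ux_um
  uy[lin] <- df$uy_um
  uz <- NULL
  if (with_z) { uz <- matrix(NA_real_, grid$nx, grid$ny); uz[lin] <- df$uz_um }
  surface_displacement_field(grid, ux, uy, uz)
}

unique_sorted_coords <- function(v, axis) {
  u <- sort(unique(v))
  if (length(u) < 2L) stop("format error: need at least 2 distinct ", axis,
                           " coordinates")
  u
}

spacing_of <- function(u, axis) {
  d <- diff(u)
  if (max(abs(d - d[1])) > 1e-6 * abs(d[1])) {
    stop("format error: non-uniform grid spacing along ", axis)
  }
  d[1]
}

#' Write a surface displacement field to CSV
#'
#' Deterministic output: row-major (x fastest), fixed 9-significant-digit
#' formatting, metadata as `#`-comments -- reruns with identical inputs are
#' byte-identical.  Invalid nodes are omitted.
#'
#' @param disp A [surface_displacement_field()].
#' @param path Output path.
#' @param metadata Named character vector written as `# key=value` lines.
#' @return `path`, invisibly.
#' @export
write_displacement_csv <- function(disp, path, metadata = character()) {
  stopifnot(inherits(disp, "surface_displacement_field"))
  grid <- disp$grid
  with_z <- has_uz(disp)
  xs <- grid_x(grid); ys <- grid_y(grid)
  i <- rep(seq_len(grid$nx), times = grid$ny)
  j <- rep(seq_len(grid$ny), each = grid$nx)
  keep <- as.vector(disp$valid)
  cols <- list(x_um = xs[i][keep], y_um = ys[j][keep],
               ux_um = as.vector(disp$ux)[keep],
               uy_um = as.vector(disp$uy)[keep])
  if (with_z) cols$uz_um <- as.vector(disp$uz)[keep]
  write_csv_deterministic(cols, path, metadata)
}

#' Write a traction field to CSV
#'
#' Columns `x_um,y_um,label,tx_kPa,ty_kPa[,tz_kPa],fx_nN,fy_nN[,fz_nN],
#' area_um2`, row-major (x fastest), fixed formatting, metadata as
#' `#`-comments.
#'
#' @param tf A [traction_field()].
#' @param path Output path.
#' @param metadata Named character vector written as `# key=value` lines.
#' @return `path`, invisibly.
#' @export
write_traction_csv <- function(tf, path, metadata = character()) {
  stopifnot(inherits(tf, "traction_field"))
  grid <- tf$grid
  xs <- grid_x(grid); ys <- grid_y(grid)
  i <- rep(seq_len(grid$nx), times = grid$ny)
  j <- rep(seq_len(grid$ny), each = grid$nx)
  with_z <- !is.null(tf$tz)
  cols <- list(x_um = xs[i], y_um = ys[j],
               label = as.vector(tf$labels),
               tx_kPa = as.vector(tf$tx), ty_kPa = as.vector(tf$ty))
  if (with_z) cols$tz_kPa <- as.vector(tf$tz)
  cols$fx_nN <- as.vector(tf$fx)
  cols$fy_nN <- as.vector(tf$fy)
  if (with_z) cols$fz_nN <- as.vector(tf$fz)
  cols$area_um2 <- as.vector(tf$area)
  write_csv_deterministic(cols, path, metadata)
}

#' Read a traction field from CSV
#'
#' Inverse of [write_traction_csv()].
#'
#' @param path CSV file path.
#' @return A [traction_field()].
#' @export
read_traction_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  xs <- unique_sorted_coords(df$x_um, "x")
  ys <- unique_sorted_coords(df$y_um, "y")
  grid <- surface_grid(length(xs), length(ys),
                       c(spacing_of(xs, "x"), spacing_of(ys, "y")),
                       origin = c(xs[1], ys[1]))
  if (nrow(df) != grid$nx * grid$ny) {
    stop("format error: traction CSV must contain every grid node")
  }
  i <- round((df$x_um - xs[1]) / grid$spacing[1]) + 1L
  j <- round((df$y_um - ys[1]) / grid$spacing[2]) + 1L
  lin <- (j - 1L) * grid$nx + i
  grab <- function(col) {
    m <- matrix(NA_real_, grid$nx, grid$ny); m[lin] <- df[[col]]; m
  }
  labels <- matrix(0L, grid$nx, grid$ny); labels[lin] <- df$label
  with_z <- "tz_kPa" %in% names(df)
  traction_field(grid, tx = grab("tx_kPa"), ty = grab("ty_kPa"),
                 tz = if (with_z) grab("tz_kPa") else NULL, labels = labels)
}

write_csv_deterministic <- function(cols, path, metadata = character()) {
  fmt <- function(v) {
    if (is.integer(v)) as.character(v) else formatC(v, digits = 9, format = "g")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# tractionfem ",
                    as.character(utils::packageVersion("tractionfem"))), con)
  for (k in names(metadata)) writeLines(paste0("# ", k, "=", metadata[[k]]), con)
  writeLines(paste(names(cols), collapse = ","), con)
  body <- do.call(paste, c(lapply(cols, fmt), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a cluster mask from an image file
#'
#' Accepts single-channel integer-valued PNG or TIFF; the pixel value is
#' the cluster label (0 = extracellular).  Image row 1 is the top of the
#' field of view, so rows are flipped on load to the package's lower-left
#' origin convention -- the single most common source of misaligned masks
#' in traction microscopy pipelines.  The image must have exactly one pixel
#' per grid node.
#'
#' @param path PNG or TIFF path.
#' @param grid The [surface_grid()] the mask belongs to.
#' @return A [cluster_mask()], with per-label node counts in attribute
#'   `"counts"`.
#' @export
read_mask_image <- function(path, grid) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    stop("unsupported mask format: ", ext, " (use PNG or TIFF)")
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L) stop("mask image must be single-channel")
    img <- img[, , 1]
  }
  if (ext == "png") img <- round(img * 255)
  # image[row, col], row 1 = top  ->  labels[i = x, j = y], y up
  labels <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
  if (!all(dim(labels) == c(grid$nx, grid$ny))) {
    stop("alignment error: mask is ", nrow(img), " x ", ncol(img),
         " pixels but the grid needs ", grid$ny, " x ", grid$nx)
  }
  mask <- cluster_mask(grid, labels)
  ids <- cluster_ids(mask)
  attr(mask, "counts") <- stats::setNames(
    vapply(ids, function(l) sum(mask$labels == l), 1L), ids)
  mask
}

#' Write a cluster mask to a PNG image
#'
#' Inverse of [read_mask_image()] (labels as 8-bit gray values, row 1 at
#' the top).
#'
#' @param mask A [cluster_mask()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "cluster_mask"))
  if (max(mask$labels) > 255L) stop("PNG masks support at most 255 labels")
  img <- t(mask$labels[, rev(seq_len(ncol(mask$labels))), drop = FALSE])
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Export displacement and traction as a legacy VTK structured grid
#'
#' ASCII legacy VTK with the surface lattice as a `nz = 1` structured grid
#' and point-data vectors `displacement` (um) and `traction` (kPa), for
#' ParaView-style visualization.
#'
#' @param disp A [surface_displacement_field()] (or NULL).
#' @param tf A [traction_field()] (or NULL); at least one of the two.
#' @param path Output `.vtk` path.
#' @param metadata Single comment line recorded in the VTK header.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(disp, tf, path, metadata = "tractionfem export") {
  grid <- if (!is.null(disp)) disp$grid else tf$grid
  if (!is.null(disp) && !is.null(tf) && !grids_identical(disp$grid, tf$grid)) {
    stop("displacement and traction are on different grids")
  }
  xs <- grid_x(grid); ys <- grid_y(grid)
  n <- grid$nx * grid$ny
  fmt <- function(v) formatC(v, digits = 9, format = "g")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               substr(metadata, 1, 255),
               "ASCII",
               "DATASET STRUCTURED_GRID",
               paste("DIMENSIONS", grid$nx, grid$ny, 1),
               paste("POINTS", n, "double")), con)
  i <- rep(seq_len(grid$nx), times = grid$ny)
  j <- rep(seq_len(grid$ny), each = grid$nx)
  writeLines(paste(fmt(xs[i]), fmt(ys[j]), "0"), con)
  writeLines(paste("POINT_DATA", n), con)
  vec3 <- function(name, a, b, c3) {
    writeLines(paste("VECTORS", name, "double"), con)
    writeLines(paste(fmt(as.vector(a)), fmt(as.vector(b)), fmt(as.vector(c3))), con)
  }
  if (!is.null(disp)) {
    uz <- if (has_uz(disp)) disp$uz else matrix(0, grid$nx, grid$ny)
    ux <- disp$ux; uy <- disp$uy
    ux[!disp$valid] <- 0; uy[!disp$valid] <- 0; uz[!disp$valid] <- 0
    vec3("displacement", ux, uy, uz)
  }
  if (!is.null(tf)) {
    tz <- if (is.null(tf$tz)) matrix(0, grid$nx, grid$ny) else tf$tz
    vec3("traction", tf$tx, tf$ty, tz)
  }
  invisible(path)
}

#' Read a grayscale image as a matrix in grid orientation
#'
#' PNG or TIFF, first channel only, values as stored (PNG scaled to
#' `[0, 1]`).  Returned as `[ix, iy]` with the lower-left pixel first
#' (rows flipped from image convention), matching [surface_grid()]
#' orientation.
#'
#' @param path PNG or TIFF path.
#' @return Numeric matrix.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, " (use PNG or TIFF)")
  )
  if (length(dim(img)) == 3L) img <- img[, , 1]
  t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
}

#' Write a grayscale matrix (grid orientation) as PNG
#'
#' Inverse of [read_gray_image()]; values clipped to `[0, 1]`.
#'
#' @param m Numeric matrix `[ix, iy]`, lower-left origin.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(m, path) {
  img <- t(m[, rev(seq_len(ncol(m))), drop = FALSE])
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' YAML with blocks `substrate` (`E_kPa`, `nu`, `thickness_um`), `grid`
#' (`spacing_um`, `margin_um`), optional `solver` (`tolerance`,
#' `direct_max_dofs`, `cg_max_iter`), optional `method` (`name`,
#' `rms_tol`, `max_iter`, `smooth_sigma`) and optional `seed`.  Unknown
#' keys anywhere are rejected.  The returned object carries a content hash
#' recorded in every output artifact.
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with elements `substrate`
#'   (a [substrate_model()] without lateral sizes), `spacing_um`,
#'   `margin_um`, `solver` (a [fem_solver_options()]), `method`, `seed`,
#'   `hash`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("substrate", "grid", "solver", "method", "seed")
  check_keys(raw, known_top, "top level")
  for (blk in c("substrate", "grid")) {
    if (is.null(raw[[blk]])) stop("config is missing the `", blk, "` block")
  }
  check_keys(raw$substrate, c("E_kPa", "nu", "thickness_um"), "substrate")
  check_keys(raw$grid, c("spacing_um", "margin_um"), "grid")
  check_keys(raw$solver, c("tolerance", "direct_max_dofs", "cg_max_iter"), "solver")
  check_keys(raw$method, c("name", "rms_tol", "max_iter", "smooth_sigma"), "method")
  substrate <- substrate_model(raw$substrate$E_kPa, raw$substrate$nu,
                               raw$substrate$thickness_um)
  solver <- do.call(fem_solver_options, null_drop(list(
    tolerance = raw$solver$tolerance,
    direct_max_dofs = raw$solver$direct_max_dofs,
    cg_max_iter = raw$solver$cg_max_iter)))
  method <- list(
    name = if (is.null(raw$method$name)) "mixed" else raw$method$name,
    rms_tol = if (is.null(raw$method$rms_tol)) 0.05 else raw$method$rms_tol,
    max_iter = if (is.null(raw$method$max_iter)) 50L else as.integer(raw$method$max_iter),
    smooth_sigma = if (is.null(raw$method$smooth_sigma)) 0 else raw$method$smooth_sigma)
  if (!method$name %in% c("mixed", "iterative")) {
    stop("method$name must be 'mixed' or 'iterative'")
  }
  structure(
    list(substrate = substrate,
         spacing_um = raw$grid$spacing_um,
         margin_um = raw$grid$margin_um,
         solver = solver, method = method,
         seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
         hash = rlang::hash(raw)),
    class = "run_config"
  )
}

check_keys <- function(x, known, where) {
  if (is.null(x)) return(invisible())
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown config key(s) in ", where, ": ", paste(unknown, collapse = ", "))
  }
  invisible()
}

null_drop <- function(x) x[!vapply(x, is.null, TRUE)]
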
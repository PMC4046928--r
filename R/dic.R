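#' Pair of bead images for digital image correlation
#'
#' `reference` is the relaxed substrate (after cell removal), `deformed`
#' the substrate under cell traction.  Images are numeric matrices indexed
#' `[ix, iy]` with pixel `(1, 1)` at the lower-left corner of the physical
#' field of view and y increasing with the second index -- the same
#' orientation as the surface grids, so displacement output aligns with
#' masks without any flipping.
#'
#' @param reference,deformed Grayscale image matrices of equal size.
#' @param pixel_size Physical pixel size, um/px.
#' @return An object of class `bead_image_pair`.
#' @export
bead_image_pair <- function(reference, deformed, pixel_size) {
  if (!is.matrix(reference) || !is.matrix(deformed) ||
      !all(dim(reference) == dim(deformed))) {
    stop("reference and deformed must be matrices of equal dimensions")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be positive (um/px)")
  }
  structure(list(reference = reference, deformed = deformed,
                 pixel_size = pixel_size),
            class = "bead_image_pair")
}

#' Generate a synthetic fluorescent bead image
#'
#' A sum of Gaussian spots at uniformly random positions, normalized to
#' `[0, 1]` -- a stand-in for micrograph frames of the fluorescent
#' micro-beads embedded in the gel.  Reproducible given the seed.
#'
#' @param shape `c(nx, ny)` pixels.
#' @param n_beads Number of beads (>= 0).
#' @param bead_sigma Spot radius (Gaussian sigma), px.
#' @param seed Integer seed.
#' @return Image matrix `[ix, iy]` in `[0, 1]`.
#' @export
generate_bead_image <- function(shape = c(256, 256), n_beads = 500,
                                bead_sigma = 1.5, seed = 1) {
  if (n_beads < 0) stop("`n_beads` must be >= 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  img <- matrix(0, shape[1], shape[2])
  if (n_beads == 0) return(img)
  px <- stats::runif(n_beads, 1, shape[1])
  py <- stats::runif(n_beads, 1, shape[2])
  half <- ceiling(4 * bead_sigma)
  for (b in seq_len(n_beads)) {
    i0 <- max(1L, floor(px[b]) - half); i1 <- min(shape[1], floor(px[b]) + half)
    j0 <- max(1L, floor(py[b]) - half); j1 <- min(shape[2], floor(py[b]) + half)
    gi <- exp(-((i0:i1) - px[b])^2 / (2 * bead_sigma^2))
    gj <- exp(-((j0:j1) - py[b])^2 / (2 * bead_sigma^2))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + outer(gi, gj)
  }
  img / max(img)
}

#' Warp an image under a displacement field
#'
#' Backward-mapping bilinear resampling: the warped image at pixel `x`
#' samples the source at `x - u(x)`, so features move by `+u`.  Used to
#' manufacture deformed bead images with a known ground-truth field.
#' Samples falling outside the source are set to 0 (with a warning).
#'
#' @param img Image matrix.
#' @param displacement_fn Function `(x_um, y_um) -> list(ux, uy)` or a
#'   constant `c(ux, uy)` shift, um.
#' @param pixel_size Pixel size, um/px.
#' @return The warped image matrix.
#' @export
warp_image <- function(img, displacement_fn, pixel_size = 1) {
  nx <- nrow(img); ny <- ncol(img)
  px <- matrix(seq_len(nx), nx, ny)
  py <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  if (is.numeric(displacement_fn) && length(displacement_fn) == 2L) {
    u <- list(ux = matrix(displacement_fn[1], nx, ny),
              uy = matrix(displacement_fn[2], nx, ny))
  } else {
    u <- displacement_fn((px - 1) * pixel_size, (py - 1) * pixel_size)
  }
  sx <- px - u$ux / pixel_size
  sy <- py - u$uy / pixel_size
  out_of_range <- sx < 1 | sx > nx | sy < 1 | sy > ny
  if (any(out_of_range)) {
    warning("displacement maps ", sum(out_of_range),
            " pixel(s) outside the image; cropped to 0")
  }
  sx <- pmin(pmax(sx, 1), nx)
  sy <- pmin(pmax(sy, 1), ny)
  i0 <- pmin(floor(sx), nx - 1); j0 <- pmin(floor(sy), ny - 1)
  fx <- sx - i0; fy <- sy - j0
  idx <- function(i, j) (j - 1) * nx + i
  w <- img[idx(i0, j0)] * (1 - fx) * (1 - fy) +
    img[idx(i0 + 1, j0)] * fx * (1 - fy) +
    img[idx(i0, j0 + 1)] * (1 - fx) * fy +
    img[idx(i0 + 1, j0 + 1)] * fx * fy
  w[out_of_range] <- 0
  matrix(w, nx, ny)
}

#' Displacement field from a bead image pair by digital image correlation
#'
#' Windowed normalized cross-correlation: for each interrogation window on
#' a regular grid of centres, the integer shift maximizing the normalized
#' correlation with the deformed image is found within the search range,
#' then refined to subpixel precision by a separable quadratic fit to the
#' 3 x 3 neighbourhood of the correlation peak.  Windows whose correlation
#' peak falls below `min_peak` are flagged invalid.
#'
#' @param pair A [bead_image_pair()].
#' @param window Interrogation window size, px (>= 16 recommended).
#' @param step Grid step between window centres, px.
#' @param search Maximum shift searched, px.
#' @param min_peak Correlation threshold below which a window is invalid.
#' @return A [surface_displacement_field()] (in-plane, um) whose grid is in
#'   physical units (`origin` at the first window centre).
#' @export
dic_displacement_field <- function(pair, window = 32, step = 16, search = 8,
                                   min_peak = 0.5) {
  stopifnot(inherits(pair, "bead_image_pair"))
  nx <- nrow(pair$reference); ny <- ncol(pair$reference)
  if (window > nx || window > ny) stop("window larger than the image")
  hw <- floor(window / 2)
  marg <- hw + search + 1
  cx <- seq(marg + 1, nx - marg, by = step)
  cy <- seq(marg + 1, ny - marg, by = step)
  if (length(cx) < 2 || length(cy) < 2) {
    stop("image too small for the requested window/search/step")
  }
  ux <- matrix(NA_real_, length(cx), length(cy))
  uy <- matrix(NA_real_, length(cx), length(cy))
  ok <- matrix(FALSE, length(cx), length(cy))
  shifts <- -search:search
  for (a in seq_along(cx)) {
    for (b in seq_along(cy)) {
      ri <- (cx[a] - hw):(cx[a] + hw - 1)
      rj <- (cy[b] - hw):(cy[b] + hw - 1)
      ref_w <- pair$reference[ri, rj]
      ref_c <- ref_w - mean(ref_w)
      ref_ss <- sqrt(sum(ref_c^2))
      if (ref_ss == 0) next
      cc <- matrix(-Inf, length(shifts), length(shifts))
      for (si in seq_along(shifts)) {
        for (sj in seq_along(shifts)) {
          def_w <- pair$deformed[ri + shifts[si], rj + shifts[sj]]
          def_c <- def_w - mean(def_w)
          den <- ref_ss * sqrt(sum(def_c^2))
          cc[si, sj] <- if (den == 0) 0 else sum(ref_c * def_c) / den
        }
      }
      pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (cc[pk[1], pk[2]] < min_peak) next
      dx <- shifts[pk[1]]; dy <- shifts[pk[2]]
      # separable quadratic subpixel refinement at interior peaks
      sub <- c(0, 0)
      for (ax in 1:2) {
        p <- pk[ax]
        if (p > 1 && p < length(shifts)) {
          cm <- cc[pk[1] - (ax == 1), pk[2] - (ax == 2)]
          c0 <- cc[pk[1], pk[2]]
          cp <- cc[pk[1] + (ax == 1), pk[2] + (ax == 2)]
          den <- cm - 2 * c0 + cp
          if (den < 0) sub[ax] <- 0.5 * (cm - cp) / den
        }
      }
      ux[a, b] <- (dx + sub[1]) * pair$pixel_size
      uy[a, b] <- (dy + sub[2]) * pair$pixel_size
      ok[a, b] <- TRUE
    }
  }
  grid <- surface_grid(length(cx), length(cy), step * pair$pixel_size,
                       origin = (c(cx[1], cy[1]) - 1) * pair$pixel_size)
  surface_displacement_field(grid, ux, uy, valid = ok)
}
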
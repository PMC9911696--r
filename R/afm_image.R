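#' AFM height image
#'
#' Container for (simulated or experimental) AFM molecular surfaces: a
#' rectangular height grid in nm with a pixel size in Angstrom.  Rows are
#' scan lines (y), columns are x; `origin` is the (x, y) coordinate of the
#' first pixel centre in Angstrom.
#'
#' @param heights Numeric matrix of heights (nm), all >= 0 (the mica plane
#'   is 0).
#' @param pixel_size Pixel edge in Angstrom (> 0).
#' @param origin Length-2 numeric, Angstrom.
#' @return An object of class `afm_image`.
#' @export
afm_image <- function(heights, pixel_size = 5, origin = c(0, 0)) {
  stopifnot(is.matrix(heights), is.numeric(heights))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("pixel_size must be a single positive number (Angstrom)")
  }
  if (any(!is.finite(heights)) || any(heights < 0)) {
    stop("invalid image: heights must be finite and >= 0")
  }
  img <- list(heights = heights, pixel_size = pixel_size,
              origin = as.numeric(origin))
  class(img) <- "afm_image"
  img
}

#' @export
print.afm_image <- function(x, ...) {
  cat(sprintf("AFM image: %d x %d px at %.3g A/px, max height %.3g nm\n",
              ncol(x$heights), nrow(x$heights), x$pixel_size,
              max(x$heights)))
  invisible(x)
}

#' Spherical AFM tip model
#'
#' @param radius Tip radius in nm (>= 0); the probes emulated here have a
#'   nominal 1-nm radius.
#' @return An object of class `tip_model`.
#' @export
tip_model <- function(radius = 1) {
  stopifnot(is.numeric(radius), length(radius) == 1, radius >= 0)
  structure(list(radius = radius, shape = "sphere"), class = "tip_model")
}

#' Render the simulated AFM molecular surface of a structure
#'
#' Contact model: the height at a pixel is the lowest apex position at which
#' a sphere of the tip radius touches any bead sphere whose lateral distance
#' is within reach -- equivalently a grey-scale dilation of the bead cloud by
#' a spherical structuring element.  The molecule is first dropped so its
#' lowest bead surface rests on the mica plane (z = 0); pixels the tip cannot
#' reach down to remain 0.
#'
#' @param cg A `cg_structure` (coordinates Angstrom).
#' @param tip A [tip_model()].
#' @param pixel_size Pixel edge, Angstrom.
#' @param pad Margin around the structure footprint, Angstrom.
#' @param grid Optional `afm_image` whose grid (size, pixel, origin) the
#'   render must match, e.g. to compare against an experimental image.
#' @param config A [cg_config()] providing bead radii.
#' @return An `afm_image` (heights nm).
#' @export
render_surface <- function(cg, tip = tip_model(), pixel_size = 5, pad = 20,
                           grid = NULL, config = cg$config) {
  if (is.null(config)) config <- cg_config()
  if (n_beads(cg) == 0) {
    warning("empty structure: all-zero image")
    return(afm_image(matrix(0, 8, 8), pixel_size))
  }
  rad <- bead_radii(cg, config)
  z <- cg$xyz[, 3] - min(cg$xyz[, 3] - rad)  # rest on mica
  tip_a <- tip$radius * 10  # nm -> A
  if (is.null(grid)) {
    if (pixel_size <= 0) stop("pixel_size must be positive")
    reach <- max(rad) + tip_a
    x0 <- min(cg$xyz[, 1]) - reach - pad
    y0 <- min(cg$xyz[, 2]) - reach - pad
    nx <- ceiling((max(cg$xyz[, 1]) + reach + pad - x0) / pixel_size) + 1L
    ny <- ceiling((max(cg$xyz[, 2]) + reach + pad - y0) / pixel_size) + 1L
  } else {
    pixel_size <- grid$pixel_size
    x0 <- grid$origin[1]
    y0 <- grid$origin[2]
    nx <- ncol(grid$heights)
    ny <- nrow(grid$heights)
  }
  h <- render_heights_cpp(cg$xyz[, 1], cg$xyz[, 2], z, rad, tip_a,
                          pixel_size, as.integer(nx), as.integer(ny),
                          x0, y0)
  afm_image(h / 10, pixel_size, origin = c(x0, y0))
}

#' Add percentage Gaussian noise to an AFM image
#'
#' The stated percentage is read as a 2-sigma amplitude relative to the
#' image's highest Z value: per-pixel Gaussian perturbations with
#' `2 * sigma = (level / 100) * max(heights)` are clipped at +/- 2 sigma
#' (so the percentage stays interpretable as a maximal amplitude) and added;
#' the result is clamped at the mica plane.
#'
#' @param img An [afm_image()].
#' @param level Noise level in percent of the maximal height (0 disables).
#' @param seed Optional RNG seed.
#' @param truncate Clip the perturbation at +/- 2 sigma (default) or leave
#'   the Gaussian tails untouched.
#' @return A noisy `afm_image`.
#' @export
add_noise <- function(img, level, seed = NULL, truncate = TRUE) {
  stopifnot(inherits(img, "afm_image"), is.numeric(level), length(level) == 1)
  level <- abs(level)
  if (level == 0) return(img)
  zmax <- max(img$heights)
  if (zmax <= 0) stop("invalid image: non-positive maximal height")
  sigma <- (level / 100) * zmax / 2
  eps <- with_seed(seed, rnorm(length(img$heights), 0, sigma))
  if (truncate) eps <- pmin(pmax(eps, -2 * sigma), 2 * sigma)
  h <- img$heights + matrix(eps, nrow(img$heights))
  h[h < 0] <- 0
  afm_image(h, img$pixel_size, img$origin)
}

#' The twelve standard noise levels
#'
#' Percent-of-maximal-height levels of the validation noise ladder.
#' @return Numeric vector of length 12.
#' @export
noise_ladder_levels <- function() c(5, 10, 15, 20, 30, 40, 50, 60, 70, 80, 90, 100)

#' Read a pseudoAFM text image
#'
#' PseudoAFM files are whitespace-delimited numeric grids, one scan line per
#' row, preceded by `#` header lines carrying the pixel size and units.  A
#' missing pixel-size header defaults to 5 Angstrom/pixel with a warning.
#'
#' @param path File to read.
#' @return An `afm_image`.
#' @export
read_pseudoafm <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) stop("format error: no data rows in ", path)
  px <- NA_real_
  origin <- c(0, 0)
  m <- regmatches(hdr, regexec("pixel_size_A\\s*:\\s*([0-9.eE+-]+)", hdr))
  for (g in m) if (length(g) == 2) px <- as.numeric(g[2])
  m <- regmatches(hdr, regexec(
    "origin_A\\s*:\\s*([0-9.eE+-]+)\\s+([0-9.eE+-]+)", hdr))
  for (g in m) if (length(g) == 3) origin <- as.numeric(g[2:3])
  if (is.na(px)) {
    warning("no pixel_size header; defaulting to 5 A/pixel")
    px <- 5
  }
  rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  len <- vapply(rows, length, 1L)
  if (length(unique(len)) != 1) stop("format error: ragged rows")
  if (any(vapply(rows, function(r) any(is.na(r)), TRUE))) {
    stop("format error: non-numeric entries")
  }
  afm_image(do.call(rbind, rows), px, origin)
}

#' Write a pseudoAFM text image
#'
#' @param img An [afm_image()].
#' @param path Output file.
#' @param digits Significant digits (the round trip is lossless at the
#'   default 6).
#' @return `path`, invisibly.
#' @export
write_pseudoafm <- function(img, path, digits = 6) {
  stopifnot(inherits(img, "afm_image"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pseudoAFM height map",
               sprintf("# pixel_size_A: %g", img$pixel_size),
               "# units: nm",
               sprintf("# origin_A: %g %g", img$origin[1], img$origin[2])),
             con)
  apply(img$heights, 1, function(r) {
    writeLines(paste(formatC(r, digits = digits, format = "g"),
                     collapse = " "), con)
  })
  invisible(path)
}
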
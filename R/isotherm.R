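#' Construct a pi-A isotherm object
#'
#' An `isotherm` is the elementary record of a film-balance experiment: an
#' ordered sequence of (mean molecular area, surface pressure) points in
#' acquisition order, together with metadata identifying the monolayer.
#' Points are stored in acquisition order; nothing is sorted at construction
#' so that compression/expansion structure is preserved for
#' [extract_compression_branch()].
#'
#' Validation enforces: at least 4 points, all areas strictly positive, and
#' no pressure below `-3 * noise_sigma` (small negative readings are normal
#' Wilhelmy-sensor noise around the blank subphase; anything lower indicates
#' a corrupted record).
#'
#' @param area numeric vector, mean molecular area in A^2/molecule.
#' @param pressure numeric vector, surface pressure in mN/m, same length.
#' @param compound_id character label of the spread film (e.g. a lipid name
#'   or "DMPC+drug").
#' @param molar_fraction_x2 mole fraction of component 2 in `[0, 1]`; 0 for
#'   pure component 1, 1 for pure component 2.
#' @param temperature_C subphase temperature in degrees Celsius.
#' @param noise_sigma pressure noise standard deviation in mN/m (0 if
#'   unknown/noiseless).
#' @param source free-text provenance notes.
#' @param extra named list of additional metadata to carry along unchanged.
#' @return An object of class `isotherm`: a list with elements `area`,
#'   `pressure` and `meta`.
#' @seealso [read_isotherm()], [write_isotherm()],
#'   [extract_compression_branch()]
#' @examples
#' iso <- isotherm(area = c(100, 80, 60, 40),
#'                 pressure = c(0.5, 2, 8, 25),
#'                 compound_id = "DMPC")
#' iso
#' @export
isotherm <- function(area, pressure, compound_id = "unknown",
                     molar_fraction_x2 = 0, temperature_C = 37,
                     noise_sigma = 0, source = "", extra = list()) {
  meta <- c(list(compound_id = as.character(compound_id),
                 molar_fraction_x2 = as.numeric(molar_fraction_x2),
                 temperature_C = as.numeric(temperature_C),
                 noise_sigma = as.numeric(noise_sigma),
                 source = as.character(source)),
            extra)
  iso <- structure(list(area = as.numeric(area),
                        pressure = as.numeric(pressure),
                        meta = meta),
                   class = "isotherm")
  validate_isotherm(iso)
}

#' @rdname isotherm
#' @param x an `isotherm` object.
#' @export
validate_isotherm <- function(x) {
  if (!inherits(x, "isotherm")) stop("not an isotherm object", call. = FALSE)
  n <- length(x$area)
  if (n != length(x$pressure))
    stop("area and pressure must have equal length", call. = FALSE)
  if (n < 4L)
    stop("insufficient data: an isotherm needs at least 4 points, got ", n,
         call. = FALSE)
  if (anyNA(x$area) || anyNA(x$pressure))
    stop("isotherm contains missing values", call. = FALSE)
  if (any(x$area <= 0))
    stop("all areas must be positive (A^2/molecule)", call. = FALSE)
  sigma <- x$meta$noise_sigma
  if (is.null(sigma) || is.na(sigma)) sigma <- 0
  floor_p <- -3 * sigma - 1e-9
  if (any(x$pressure < floor_p))
    stop("pressure below -3*noise_sigma (", signif(floor_p, 3),
         " mN/m): not a valid blank-noise reading", call. = FALSE)
  x2 <- x$meta$molar_fraction_x2
  if (!is.null(x2) && !is.na(x2) && (x2 < 0 || x2 > 1))
    stop("molar_fraction_x2 must lie in [0, 1], got ", x2, call. = FALSE)
  invisible(x)
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("<isotherm> %s  x2 = %g  T = %g C  (%d points)\n",
              x$meta$compound_id, x$meta$molar_fraction_x2,
              x$meta$temperature_C, length(x$area)))
  cat(sprintf("  area    : %.2f .. %.2f A^2/molecule\n",
              max(x$area), min(x$area)))
  cat(sprintf("  pressure: %.2f .. %.2f mN/m\n",
              min(x$pressure), max(x$pressure)))
  if (nzchar(x$meta$source)) cat("  source  :", x$meta$source, "\n")
  invisible(x)
}

#' @export
as.data.frame.isotherm <- function(x, ...) {
  data.frame(area_A2 = x$area, pressure_mN_per_m = x$pressure)
}

#' @export
length.isotherm <- function(x) length(x$area)

#' @export
plot.isotherm <- function(x, ...) {
  args <- list(x = x$area, y = x$pressure, type = "l",
               xlab = expression("Mean molecular area (" * ring(A)^2 *
                                   "/molecule)"),
               ylab = "Surface pressure (mN/m)",
               main = x$meta$compound_id,
               xlim = rev(range(x$area)))
  args[names(list(...))] <- list(...)
  do.call(graphics::plot, args)
  invisible(x)
}
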
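# Compressibility modulus Cs^-1 = -A (dpi/dA), 2D phase classification and
# LE-LC transition detection.

# Savitzky-Golay weight rows for smoothing (row 1) and first derivative
# (row 2) when the target sits at position `pos` of a `window`-long
# uniformly spaced stencil. Derivative is per grid step.
sg_weights <- function(window, order, pos) {
  rel <- seq_len(window) - pos
  V <- outer(rel, 0:order, "^")
  # (V'V)^-1 V' rows 1..2 give polynomial value and slope at rel = 0
  solve(crossprod(V), t(V))[1:2, , drop = FALSE]
}

# Smoothed values and first derivative of y on a uniform grid of (signed)
# spacing h, with shifted (asymmetric) stencils at the ends.
sg_differentiate <- function(y, h, window, order) {
  n <- length(y)
  stopifnot(window %% 2L == 1L, window > order, n >= window)
  hw <- (window - 1L) %/% 2L
  smooth <- deriv <- numeric(n)
  cache <- vector("list", window)
  for (i in seq_len(n)) {
    start <- min(max(i - hw, 1L), n - window + 1L)
    pos <- i - start + 1L
    if (is.null(cache[[pos]])) cache[[pos]] <- sg_weights(window, order, pos)
    w <- cache[[pos]]
    seg <- y[start:(start + window - 1L)]
    smooth[i] <- sum(w[1L, ] * seg)
    deriv[i] <- sum(w[2L, ] * seg) / h
  }
  list(smooth = smooth, deriv = deriv)
}

#' Classify the 2D phase state of a monolayer from its compressibility
#' modulus
#'
#' Conventional bands for the in-plane compressibility modulus of a
#' Langmuir film: values below 12.5 mN/m indicate a gaseous film,
#' 12.5--50 liquid-expanded (LE), 50--100 the LE/liquid-condensed
#' coexistence region, 100--250 liquid-condensed (LC) and 250 mN/m or more
#' a solid-like (untilted condensed) film. The bands quantify the usual
#' qualitative reading -- the larger Cs^-1, the more rigid and less
#' compressible the film.
#'
#' @param cs_inv numeric vector of compressibility moduli, mN/m (>= 0).
#' @return character vector of labels among `"gaseous"`, `"LE"`, `"LE-LC"`,
#'   `"LC"`, `"solid"`.
#' @export
classify_phase_state <- function(cs_inv) {
  if (any(cs_inv < 0))
    stop("compressibility modulus must be non-negative", call. = FALSE)
  cut_pts <- c(-Inf, 12.5, 50, 100, 250, Inf)
  labels <- c("gaseous", "LE", "LE-LC", "LC", "solid")
  as.character(cut(cs_inv, cut_pts, labels, right = FALSE))
}

#' Compressibility-modulus curve of a compression isotherm
#'
#' Computes \eqn{C_s^{-1} = -A\, (\partial\pi/\partial A)} along a clean
#' compression branch. Note the sign: on compression the pressure rises as
#' the area shrinks, so \eqn{\partial\pi/\partial A < 0} and the minus sign
#' makes the reported modulus positive, as rigidity values are
#' conventionally quoted.
#'
#' Because +-0.1 mN/m sensor noise makes raw finite differences useless,
#' the derivative is estimated by Savitzky-Golay local-polynomial
#' differentiation: the branch is resampled onto a uniform area grid
#' (linear interpolation, `resample_n` points) and a polynomial of degree
#' `order` is fit over a sliding `window` of points; shifted stencils are
#' used near the ends. Values that noise drives slightly negative are
#' clamped to 0 before phase classification.
#'
#' @param iso an [isotherm] compression branch with at least `window`
#'   points.
#' @param window odd Savitzky-Golay window length in resampled points
#'   (default 11).
#' @param order polynomial order (default 3, must be < `window`).
#' @param resample_n number of uniform area-grid points (default:
#'   `min(length(iso), 201)`).
#' @return An object of class `compressibility_curve`: a data.frame with
#'   columns `pressure` (smoothed, mN/m), `area` (A^2/molecule), `cs_inv`
#'   (mN/m) and `phase`, ordered along compression (decreasing area), with
#'   the smoothing settings stored as attributes.
#' @export
compressibility_curve <- function(iso, window = 11L, order = 3L,
                                  resample_n = NULL) {
  assert_compression_branch(iso)
  if (is.null(resample_n)) resample_n <- min(length(iso$area), 201L)
  resample_n <- as.integer(resample_n)
  if (resample_n < window)
    stop("insufficient data: branch supplies ", resample_n,
         " resampled points but the smoothing window needs ", window,
         call. = FALSE)
  # Uniform area grid in compression order (descending area). Points are
  # bin-averaged onto the grid rather than interpolated: averaging divides
  # the sensor noise by sqrt(points per bin) before differentiation, which
  # interpolation would not.
  a_u <- seq(max(iso$area), min(iso$area), length.out = resample_n)
  p_u <- bin_average(iso$area, pmax(iso$pressure, 0), a_u)
  h <- a_u[2L] - a_u[1L] # negative: area shrinks along the branch
  sg <- sg_differentiate(p_u, h, window, order)
  cs <- pmax(-a_u * sg$deriv, 0)
  out <- data.frame(pressure = sg$smooth, area = a_u, cs_inv = cs,
                    phase = classify_phase_state(cs))
  structure(out, class = c("compressibility_curve", "data.frame"),
            window = window, order = order, resample_n = resample_n)
}

#' @export
print.compressibility_curve <- function(x, ...) {
  cat(sprintf(
    "<compressibility curve> %d samples, pi %.2f..%.2f mN/m, Cs^-1 max %.1f mN/m\n",
    nrow(x), min(x$pressure), max(x$pressure), max(x$cs_inv)))
  cat("  phases:", paste(unique(x$phase), collapse = " -> "), "\n")
  invisible(x)
}

#' @export
plot.compressibility_curve <- function(x, ...) {
  graphics::plot(x$pressure, x$cs_inv, type = "l",
                 xlab = "Surface pressure (mN/m)",
                 ylab = expression(C[s]^-1 ~ "(mN/m)"), ...)
  invisible(x)
}

# Bin-average (x, y) onto a uniform descending grid x_u: both axes are
# averaged per bin (so steep-slope bins carry no centring bias) and the bin
# means are then interpolated onto the grid.
bin_average <- function(x, y, x_u) {
  n <- length(x_u)
  half <- abs(x_u[2L] - x_u[1L]) / 2
  idx <- findInterval(-x, -(x_u + half))
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  f <- factor(idx, levels = seq_len(n))
  xbar <- vapply(split(x, f), function(v)
    if (length(v)) mean(v) else NA_real_, numeric(1L))
  ybar <- vapply(split(y, f), function(v)
    if (length(v)) mean(v) else NA_real_, numeric(1L))
  ok <- !is.na(xbar)
  stats::approx(rev(xbar[ok]), rev(ybar[ok]), xout = x_u, rule = 2,
                ties = "ordered")$y
}

# Local maxima (strict rise on the left, non-rise on the right) of y with
# topographic prominence: peak height minus the higher of the lowest points
# separating it from higher ground (or the record edge) on each side.
# `edges = TRUE` additionally admits record endpoints as peaks when the
# curve falls away from them.
local_peaks <- function(y, min_prominence = 0, edges = FALSE) {
  n <- length(y)
  if (n < 3L) return(integer(0L))
  idx <- which(diff(c(-Inf, y)) > 0 & diff(c(y, -Inf)) <= 0)
  if (!edges) idx <- idx[idx > 1L & idx < n]
  if (!length(idx)) return(integer(0L))
  base_of <- function(side, yi) {
    if (!length(side)) return(-Inf) # no ground on this side (edge peak)
    higher <- which(side > yi)
    min(side[seq.int(if (length(higher)) max(higher) else 1L, length(side))])
  }
  prom <- vapply(idx, function(i) {
    lbase <- base_of(y[seq_len(i - 1L)], y[i])
    rbase <- base_of(rev(y[seq.int(i + 1L, length.out = n - i)]), y[i])
    y[i] - max(lbase, rbase, -Inf)
  }, numeric(1L))
  prom[is.infinite(prom)] <- max(y) - min(y) # isolated single peak
  idx[prom >= min_prominence]
}

#' Detect the LE-LC transition pressure from a compressibility curve
#'
#' A first-order LE-LC transition shows up in Cs^-1 versus pi as a dip
#' between two maxima: the film stiffens in the LE phase, softens through
#' the coexistence plateau, then stiffens again in the condensed phase.
#' This detector finds all local maxima of Cs^-1 whose topographic
#' prominence exceeds `min_prominence`, and -- if at least two exist --
#' returns the pressure of the deepest local minimum lying between a pair
#' of adjacent qualifying maxima, refined by a local quadratic fit so the
#' answer is not quantised to the sample grid. Absence of the
#' two-maxima-with-dip pattern is a valid result (`NA`): a purely fluid
#' film has a monotone modulus.
#'
#' On long records (more than 30 samples) the curve is conditioned before
#' peak hunting: samples below 1 mN/m are discarded (below lift-off there is
#' no film, only clamped sensor noise), the series is averaged into
#' 0.25 mN/m pressure bins, and a +-1.5 mN/m running mean is applied. With
#' a +-0.1 mN/m sensor this reduces the modulus noise far below the 5 mN/m
#' prominence gate while leaving the several-mN/m-wide transition dip and
#' its position intact. Short (constructed) curves are used as-is.
#'
#' @param curve a [compressibility_curve()] (or data.frame with `pressure`
#'   and `cs_inv`), at least 5 samples.
#' @param min_prominence minimum prominence of the flanking maxima, mN/m
#'   (default 5).
#' @return Transition pressure in mN/m, or `NA_real_` when no qualifying
#'   pattern exists.
#' @export
detect_transition_pressure <- function(curve, min_prominence = 5) {
  stopifnot(nrow(curve) >= 5L, min_prominence >= 0)
  o <- order(curve$pressure)
  p <- curve$pressure[o]
  cs <- curve$cs_inv[o]
  if (length(p) > 30L) {
    keep <- p > 1
    p <- p[keep]
    cs <- cs[keep]
    if (length(p) < 5L || diff(range(p)) < 2) return(NA_real_) # no film
    binw <- 0.25
    idx <- findInterval(p, seq(min(p), max(p), by = binw))
    p <- as.numeric(tapply(p, idx, mean))
    cs <- as.numeric(tapply(cs, idx, mean))
    k <- 13L # +-1.5 mN/m running mean at 0.25 mN/m bins
    if (length(p) > k + 4L) {
      csm <- stats::filter(cs, rep(1 / k, k), sides = 2)
      ok <- !is.na(csm)
      p <- p[ok]
      cs <- pmax(as.numeric(csm[ok]), 0)
    }
  }
  # Edge samples may act as flanking maxima: a film without a collapse in
  # the recorded window has its condensed-phase modulus still rising at the
  # end of the record.
  peaks <- local_peaks(cs, min_prominence, edges = TRUE)
  if (length(peaks) < 2L) return(NA_real_)
  best_p <- NA_real_
  best_depth <- -Inf
  for (k in seq_len(length(peaks) - 1L)) {
    lo <- peaks[k]
    hi <- peaks[k + 1L]
    seg <- seq.int(lo, hi)
    m <- seg[which.min(cs[seg])]
    depth <- min(cs[c(lo, hi)]) - cs[m] # dip depth below the lower flank
    if (depth > best_depth) {
      best_depth <- depth
      best_p <- refine_minimum(p, cs, m)
    }
  }
  best_p
}

# Quadratic refinement of a discrete minimum location, fitting all samples
# within +-1.5 mN/m (at least +-3 samples) so grid quantisation and sample
# noise average out.
refine_minimum <- function(p, cs, m) {
  i <- which(abs(p - p[m]) <= 1.5)
  i <- union(i, seq.int(max(1L, m - 3L), min(length(p), m + 3L)))
  i <- sort(i)
  if (length(i) < 3L) return(p[m])
  fit <- stats::lm.fit(cbind(1, p[i], p[i]^2), cs[i])
  b <- unname(fit$coefficients)
  if (is.na(b[3L]) || b[3L] <= 0) return(p[m])
  vertex <- -b[2L] / (2 * b[3L])
  if (vertex < min(p[i]) || vertex > max(p[i])) p[m] else vertex
}
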
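# Study-level products: composition profiles, excess tables, extrema and
# the qualitative miscibility verdict.

# Normalise a study set: a named list of isotherms containing both pure
# components (x2 = 0 and x2 = 1) and at least one mixture, sorted by x2 so
# results are invariant to input file order.
as_study_set <- function(isotherms) {
  stopifnot(is.list(isotherms), length(isotherms) >= 1L)
  ok <- vapply(isotherms, inherits, logical(1L), "isotherm")
  if (!all(ok)) stop("study set must contain only isotherm objects",
                     call. = FALSE)
  x2 <- vapply(isotherms, function(i) i$meta$molar_fraction_x2, numeric(1L))
  if (!any(x2 == 0))
    stop("missing pure component 1 isotherm (molar_fraction_x2 = 0)",
         call. = FALSE)
  if (!any(x2 == 1))
    stop("missing pure component 2 isotherm (molar_fraction_x2 = 1)",
         call. = FALSE)
  if (!any(x2 > 0 & x2 < 1))
    stop("study set needs at least one mixture isotherm", call. = FALSE)
  isotherms[order(x2)]
}

#' Load a directory of isotherm files as a study set
#'
#' Reads every `*.csv` file in `dir` that parses as an isotherm (files such
#' as `ground_truth.csv` are skipped) and checks that both pure components
#' and at least one mixture are present.
#'
#' @param dir directory containing isotherm files in the format of
#'   [read_isotherm()].
#' @return A named list of [isotherm] objects sorted by `molar_fraction_x2`.
#' @export
load_study <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  paths <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  isos <- list()
  for (p in paths) {
    iso <- tryCatch(read_isotherm(p), error = function(e) NULL)
    if (!is.null(iso)) isos[[sub("\\.csv$", "", basename(p))]] <- iso
  }
  as_study_set(isos)
}

#' Area-versus-composition profile at fixed surface pressures
#'
#' For each target pressure, tabulates the measured mean molecular area of
#' every film in the study (pure components and mixtures) against the mole
#' fraction of component 2, together with the ideal-additivity value
#' obtained by joining the two pure-component areas with a straight line.
#' Deviations of `a12_A2` from `a_ideal_A2` are the fingerprint of
#' non-ideal mixing. Films that never attain the target pressure are kept
#' and flagged (`"unattained"`, area recorded as 0), never silently
#' dropped.
#'
#' @param isotherms a study set: named list of [isotherm] objects including
#'   both pure components (x2 = 0 and 1), e.g. from
#'   [generate_study_isotherms()] or [load_study()].
#' @param pressures positive target pressures, mN/m (default 10, 20, 30).
#' @param area_jitter_tol passed to [extract_compression_branch()].
#' @param smooth_window odd number of points for Savitzky-Golay
#'   conditioning of the pressure channel before area readout (default 25;
#'   1 disables). Pointwise crossings on a noisy trace would otherwise
#'   carry the full sensor noise amplified by `|dA/dpi|`.
#' @return A list of `composition_profile` data.frames (columns `x2`,
#'   `a12_A2`, `a_ideal_A2`, `flags`), one per pressure (stored in the
#'   `pressure` attribute and list names).
#' @export
composition_profile <- function(isotherms, pressures = c(10, 20, 30),
                                area_jitter_tol = 0.05,
                                smooth_window = 25L) {
  isos <- as_study_set(isotherms)
  stopifnot(all(pressures > 0))
  branches <- lapply(isos, function(i)
    condition_branch(extract_compression_branch(i, area_jitter_tol),
                     smooth_window))
  x2 <- vapply(branches, function(i) i$meta$molar_fraction_x2, numeric(1L))
  out <- list()
  for (p in pressures) {
    reads <- lapply(branches, areas_at_pressures, p)
    area <- vapply(reads, function(r) if (r$attained) r$area else 0,
                   numeric(1L))
    attained <- vapply(reads, `[[`, logical(1L), "attained")
    a1 <- area[match(0, x2)]
    a2 <- area[match(1, x2)]
    df <- data.frame(x2 = x2,
                     a12_A2 = area,
                     a_ideal_A2 = ideal_mixing_area(a1, a2, x2),
                     flags = ifelse(attained, "", "unattained"),
                     row.names = NULL)
    out[[format(p, trim = TRUE)]] <-
      structure(df, class = c("composition_profile", "data.frame"),
                pressure = p)
  }
  out
}

#' Excess-area and excess-Gibbs-energy table across the study grid
#'
#' Computes, for every film in the study and every target pressure, the
#' ideal-mixing area, the excess molecular area ([excess_area()]) and the
#' excess Gibbs free energy of mixing ([excess_gibbs_energy()]). Pure
#' components are included as exact-zero rows (their excess quantities
#' vanish identically by definition). Rows are ordered by `x2`, then
#' pressure.
#'
#' @inheritParams composition_profile
#' @param grid_step integration step for the Gibbs integral, mN/m.
#' @param liftoff_threshold noise-floor pressure, mN/m.
#' @param method Gibbs integration method, see [excess_gibbs_energy()].
#' @return An `excess_table` data.frame with columns `x2`,
#'   `pressure_mN_per_m`, `a12_A2`, `a_ideal_A2`, `a_excess_A2`,
#'   `dg_excess_J_mol`, `flags`.
#' @export
excess_profile_table <- function(isotherms, pressures = c(10, 20, 30),
                                 area_jitter_tol = 0.05, grid_step = 0.1,
                                 liftoff_threshold = 0.3,
                                 smooth_window = 25L,
                                 method = c("parts", "grid")) {
  isos <- as_study_set(isotherms)
  stopifnot(all(pressures > 0))
  pressures <- sort(pressures)
  branches <- lapply(isos, extract_compression_branch, area_jitter_tol)
  smoothed <- lapply(branches, condition_branch, smooth_window)
  x2 <- vapply(branches, function(i) i$meta$molar_fraction_x2, numeric(1L))
  b1 <- branches[[match(0, x2)]]
  b2 <- branches[[match(1, x2)]]
  rows <- list()
  for (k in seq_along(branches)) {
    b <- branches[[k]]
    xk <- x2[k]
    reads12 <- areas_at_pressures(smoothed[[k]], pressures)
    reads1 <- areas_at_pressures(smoothed[[match(0, x2)]], pressures)
    reads2 <- areas_at_pressures(smoothed[[match(1, x2)]], pressures)
    a12 <- ifelse(reads12$attained, reads12$area, 0)
    a1 <- ifelse(reads1$attained, reads1$area, 0)
    a2 <- ifelse(reads2$attained, reads2$area, 0)
    if (xk %in% c(0, 1)) {
      aex <- rep(0, length(pressures)) # exact by definition at endpoints
      dg <- rep(0, length(pressures))
    } else {
      aex <- excess_area(a12, a1, a2, xk)
      dg <- as.numeric(excess_gibbs_energy(b, b1, b2, xk, pressures,
                                           grid_step, liftoff_threshold,
                                           method = method))
    }
    flags <- paste0(ifelse(reads12$attained, "", "mix-unattained "),
                    ifelse(reads1$attained, "", "pure1-unattained "),
                    ifelse(reads2$attained, "", "pure2-unattained "))
    rows[[k]] <- data.frame(x2 = xk, pressure_mN_per_m = pressures,
                            a12_A2 = a12, a_ideal_A2 = (1 - xk) * a1 + xk * a2,
                            a_excess_A2 = aex, dg_excess_J_mol = dg,
                            flags = trimws(flags), row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$x2, tab$pressure_mN_per_m), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("excess_table", "data.frame"))
}

#' Interior extrema of a composition-indexed curve
#'
#' Finds interior local maxima and minima of `y` as a function of `x2`
#' whose topographic prominence reaches `min_prominence`. Endpoints are
#' never reported (an excess curve is pinned to 0 at both pure endpoints,
#' so edge values are not extrema of the mixing behaviour). The result is
#' invariant under joint scaling of `y` and `min_prominence`.
#'
#' @param x2 sorted mole fractions.
#' @param y values at those fractions (same units as `min_prominence`).
#' @param min_prominence non-negative prominence threshold.
#' @return data.frame with columns `x2`, `type` (`"maximum"`/`"minimum"`),
#'   `value`; zero rows when the curve is monotone or too flat.
#' @export
find_extrema <- function(x2, y, min_prominence = 0) {
  stopifnot(length(x2) == length(y), length(x2) >= 3L,
            !is.unsorted(x2), min_prominence >= 0)
  imax <- local_peaks(y, min_prominence)
  imin <- local_peaks(-y, min_prominence)
  out <- data.frame(
    x2 = c(x2[imax], x2[imin]),
    type = rep(c("maximum", "minimum"), c(length(imax), length(imin))),
    value = c(y[imax], y[imin]))
  out[order(out$x2), , drop = FALSE]
}

#' Qualitative miscibility assessment of a two-component monolayer
#'
#' Applies the standard reading of excess-area plots, with explicit numeric
#' thresholds replacing the by-eye judgement:
#' * all `|A_ex|` below `tol` at every pressure: the additivity rule holds,
#'   which is compatible with either complete miscibility of ideally mixing
#'   components or complete immiscibility -- the single verdict
#'   `"ideal-or-immiscible"` (the rule cannot distinguish the two);
#' * a two-maxima-separated-by-a-minimum pattern in `A_ex(x2)` at some
#'   pressure, or deviations of both signs: domains rich in one or the
#'   other component, verdict `"partially-miscible"`;
#' * otherwise, consistent positive deviations mean the components mix but
#'   repel (`"miscible-repulsive"`), negative ones that they attract
#'   (`"miscible-attractive"`).
#'
#' @param excess an `excess_table` from [excess_profile_table()] (or any
#'   data.frame with columns `x2`, `pressure_mN_per_m`, `a_excess_A2`)
#'   covering at least 3 fractions at one or more pressures.
#' @param tol excess-area magnitude below which a deviation is considered
#'   within experimental scatter, A^2 (default 0.5, about the area
#'   uncertainty induced by a +-0.1 mN/m pressure noise floor). Also used
#'   as the prominence threshold when hunting for the bimodal pattern.
#' @return A `miscibility_assessment` list: `verdict`, `signs` (named by
#'   pressure: `"positive"`, `"negative"`, `"mixed"` or `"none"`),
#'   `extrema` (list of [find_extrema()] tables per pressure), `tol`.
#' @export
assess_miscibility <- function(excess, tol = 0.5) {
  stopifnot(is.data.frame(excess), tol > 0,
            all(c("x2", "pressure_mN_per_m", "a_excess_A2") %in%
                  names(excess)))
  interior <- excess[excess$x2 > 0 & excess$x2 < 1, , drop = FALSE]
  if (length(unique(interior$x2)) < 3L)
    stop("miscibility assessment needs at least 3 mixture fractions",
         call. = FALSE)
  prs <- sort(unique(interior$pressure_mN_per_m))
  signs <- character(length(prs))
  names(signs) <- format(prs, trim = TRUE)
  extrema <- stats::setNames(vector("list", length(prs)), names(signs))
  bimodal <- FALSE
  for (k in seq_along(prs)) {
    sub <- excess[excess$pressure_mN_per_m == prs[k], , drop = FALSE]
    sub <- sub[order(sub$x2), , drop = FALSE]
    aex <- sub$a_excess_A2
    pos <- any(aex > tol)
    neg <- any(aex < -tol)
    signs[k] <- if (pos && neg) "mixed" else if (pos) "positive" else
      if (neg) "negative" else "none"
    ext <- find_extrema(sub$x2, aex, min_prominence = tol)
    extrema[[k]] <- ext
    # two maxima separated by a minimum?
    ty <- ext$type
    if (sum(ty == "maximum") >= 2L && any(ty == "minimum")) {
      mx <- which(ty == "maximum")
      mn <- which(ty == "minimum")
      if (any(vapply(mn, function(m) any(mx < m) && any(mx > m),
                     logical(1L))))
        bimodal <- TRUE
    }
  }
  verdict <- if (all(signs == "none")) {
    "ideal-or-immiscible"
  } else if (bimodal || any(signs == "mixed")) {
    "partially-miscible"
  } else if (any(signs == "positive")) {
    "miscible-repulsive"
  } else {
    "miscible-attractive"
  }
  structure(list(verdict = verdict, signs = signs, extrema = extrema,
                 tol = tol),
            class = "miscibility_assessment")
}

#' @export
print.miscibility_assessment <- function(x, ...) {
  cat("<miscibility assessment> verdict:", x$verdict, "\n")
  for (nm in names(x$signs)) {
    n_ext <- nrow(x$extrema[[nm]])
    cat(sprintf("  pi = %s mN/m: %s deviations, %d interior extrem%s\n",
                nm, x$signs[[nm]], n_ext, if (n_ext == 1L) "um" else "a"))
  }
  invisible(x)
}

#' @export
plot.composition_profile <- function(x, ...) {
  graphics::plot(x$x2, x$a12_A2, pch = 16,
                 xlab = expression(X[2]),
                 ylab = expression("Mean molecular area (" * ring(A)^2 * ")"),
                 main = sprintf("pi = %g mN/m", attr(x, "pressure")), ...)
  graphics::lines(x$x2, x$a_ideal_A2, lty = 2)
  invisible(x)
}
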
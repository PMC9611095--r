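# Synthetic pi-A isotherm generator: a stated "world" with closed-form
# ground truth so that every analysis stage can be validated end to end.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pressure grid specification
#'
#' @param min,max,step grid limits and spacing in mN/m. The default window
#'   0--35 mN/m at 0.1 mN/m spacing mimics a film balance sampling a slow
#'   (10 mm/min) barrier compression.
#' @return a `list(min, max, step)`.
#' @export
pressure_grid <- function(min = 0, max = 35, step = 0.1) {
  stopifnot(step > 0, max > min, min >= 0)
  list(min = min, max = max, step = step)
}

#' Generate a pure-component synthetic isotherm
#'
#' Evaluates the noiseless equation of state of [pure_eos_params()] on a
#' pressure grid, adds i.i.d. Gaussian noise of standard deviation
#' `noise_sigma` to the *pressure* channel (the Wilhelmy sensor; barrier
#' position is far more precise, so the area axis is left exact), clamps
#' noisy pressures at `-3 * noise_sigma`, and returns the points in
#' compression order (strictly decreasing area). A non-spreading component
#' yields pressure = noise only, on a descending area ramp from 130 down to
#' 20 A^2/molecule.
#'
#' @param params a [pure_eos_params] object.
#' @param grid a [pressure_grid()] list.
#' @param noise_sigma pressure noise s.d., mN/m (>= 0). The film-balance
#'   blank check tolerates +-0.1 mN/m, so 0.1 is the realistic default.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param x2 mole fraction recorded in the metadata (0 or 1 for pure
#'   films).
#' @return An [isotherm].
#' @export
generate_pure_isotherm <- function(params, grid = pressure_grid(),
                                   noise_sigma = 0.1, seed = NULL,
                                   x2 = 0) {
  stopifnot(inherits(params, "pure_eos_params"), noise_sigma >= 0)
  if (!params$non_spreading && !is.null(params$collapse_pi) &&
      grid$max > params$collapse_pi)
    stop("pressure grid max (", grid$max, " mN/m) exceeds collapse_pi (",
         params$collapse_pi, " mN/m) of ", params$id, call. = FALSE)
  p <- seq(grid$min, grid$max, by = grid$step)
  if (params$non_spreading) {
    area <- seq(130, 20, length.out = length(p))
    p_true <- rep(0, length(p))
  } else {
    area <- eos_area(params, p)
    p_true <- p
  }
  p_noisy <- with_seed(seed, p_true + stats::rnorm(length(p_true),
                                                   sd = noise_sigma))
  p_noisy <- pmax(p_noisy, -3 * noise_sigma)
  isotherm(area = area, pressure = p_noisy,
           compound_id = params$id, molar_fraction_x2 = x2,
           noise_sigma = noise_sigma,
           source = "synthetic pure-component EOS")
}

#' Generate a two-component mixed synthetic isotherm
#'
#' Composes the mixed film's area from the pure equations of state plus the
#' regular-solution excess term,
#' \deqn{A_{12}(\pi) = X_1 A_1(\pi) + X_2 A_2(\pi) + A_{ex}(\pi, X_2),}
#' so that, by construction, the downstream excess-area and excess-Gibbs
#' analysis has an exact closed-form target ([dgex_closed_form()]). A
#' non-spreading component contributes zero area (its molecules dissolve
#' into the subphase rather than occupying interface). Pressure noise is
#' applied exactly as in [generate_pure_isotherm()].
#'
#' @param p1,p2 [pure_eos_params] for components 1 and 2.
#' @param x2 mole fraction of component 2 in `[0, 1]`.
#' @param ex an [excess_params] object.
#' @inheritParams generate_pure_isotherm
#' @return An [isotherm] whose metadata records `x2` and the ground-truth
#'   excess parameters (`gt_a_ex`, `gt_pi_s`).
#' @export
generate_mixture_isotherm <- function(p1, p2, x2, ex = excess_params(),
                                      grid = pressure_grid(),
                                      noise_sigma = 0.1, seed = NULL) {
  stopifnot(inherits(p1, "pure_eos_params"),
            inherits(p2, "pure_eos_params"),
            x2 >= 0, x2 <= 1)
  if (p1$non_spreading && p2$non_spreading)
    stop("both components are non-spreading: no film forms", call. = FALSE)
  p <- seq(grid$min, grid$max, by = grid$step)
  area <- (1 - x2) * eos_area(p1, p) + x2 * eos_area(p2, p) +
    excess_area_model(ex, p, x2)
  if (any(area <= 0))
    stop("composed mixture area is non-positive; composition x2 = ", x2,
         " is degenerate for these components", call. = FALSE)
  p_noisy <- with_seed(seed, p + stats::rnorm(length(p), sd = noise_sigma))
  p_noisy <- pmax(p_noisy, -3 * noise_sigma)
  isotherm(area = area, pressure = p_noisy,
           compound_id = paste0(p1$id, "/", p2$id),
           molar_fraction_x2 = x2, noise_sigma = noise_sigma,
           source = "synthetic two-component EOS mixture",
           extra = list(gt_a_ex = ex$a_ex, gt_pi_s = ex$pi_s))
}

#' Study configuration for a synthetic mixing experiment
#'
#' Bundles everything needed to emulate a two-component monolayer mixing
#' study: the two pure components, the mole-fraction grid, the excess-term
#' ground truth, the instrument noise level and the pressure grid. Defaults
#' reproduce the motivating study design: a fluid phosphatidylcholine-like
#' host ([eos_dmpc()]), a non-spreading drug-like guest
#' ([eos_non_spreading()]), guest fractions
#' 0.015, 0.03, 0.045, 0.06, 0.09, 0.12, 0.25, 0.50, a +-0.1 mN/m pressure
#' noise floor at 37 C, and a mildly repulsive excess
#' (`a_ex = 5` A^2 decaying with `pi_s = 20` mN/m, which puts the excess
#' Gibbs energy in the few-hundred J/mol range typical of a weakly
#' interacting drug/lipid pair).
#'
#' @param component1,component2 [pure_eos_params] objects.
#' @param fractions distinct mole fractions of component 2, all in (0, 1).
#' @param excess an [excess_params] object.
#' @param noise_sigma pressure noise s.d., mN/m.
#' @param grid a [pressure_grid()].
#' @param seed integer master seed; per-file seeds are derived from it.
#' @return A `study_config` object.
#' @export
study_config <- function(component1 = eos_dmpc(),
                         component2 = eos_non_spreading("cytarabine-like"),
                         fractions = c(0.015, 0.03, 0.045, 0.06,
                                       0.09, 0.12, 0.25, 0.50),
                         excess = excess_params(a_ex = 5, pi_s = 20),
                         noise_sigma = 0.1,
                         grid = pressure_grid(),
                         seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions < 1), noise_sigma >= 0)
  if (anyDuplicated(fractions))
    stop("duplicate mole-fraction values in study grid", call. = FALSE)
  structure(list(component1 = component1, component2 = component2,
                 fractions = sort(fractions), excess = excess,
                 noise_sigma = noise_sigma, grid = grid,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Generate and write a full synthetic study
#'
#' Writes one isotherm file per pure component (2 files) and one per
#' mixture fraction, plus a ground-truth CSV holding the generator's
#' closed-form excess Gibbs energies at 10, 20 and 30 mN/m for each
#' fraction. Output is deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [study_config()].
#' @param out_dir output directory (created if absent).
#' @return A manifest list: `files` (named character vector of paths),
#'   `ground_truth` (data.frame), `config` (the input `cfg`), invisibly
#'   printable.
#' @export
generate_study_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  isos <- generate_study_isotherms(cfg)
  files <- character(0L)
  for (nm in names(isos)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    write_isotherm(isos[[nm]], path)
    files[nm] <- path
  }
  gt <- study_ground_truth(cfg)
  gt_path <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(gt, gt_path, row.names = FALSE, quote = FALSE)
  files["ground_truth"] <- gt_path
  list(files = files, ground_truth = gt, config = cfg)
}

# In-memory version of generate_study_dataset: named list of isotherms
# (pure1, pure2, mix_x2_<frac>...). Exported because analysis pipelines and
# tests use it directly without touching the filesystem.
#' @rdname generate_study_dataset
#' @export
generate_study_isotherms <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  seeds <- cfg$seed + seq_len(length(cfg$fractions) + 2L)
  # a pure film cannot be compressed past its own collapse: truncate the
  # grid for that component's pure record (mixtures still span the full
  # window, as the host lipid keeps the guest in the film)
  trunc_grid <- function(p) {
    if (!p$non_spreading && !is.null(p$collapse_pi) &&
        cfg$grid$max > p$collapse_pi)
      pressure_grid(cfg$grid$min, p$collapse_pi, cfg$grid$step)
    else cfg$grid
  }
  isos <- list(
    pure1 = generate_pure_isotherm(cfg$component1, trunc_grid(cfg$component1),
                                   cfg$noise_sigma, seeds[1L], x2 = 0),
    pure2 = generate_pure_isotherm(cfg$component2, trunc_grid(cfg$component2),
                                   cfg$noise_sigma, seeds[2L], x2 = 1)
  )
  for (i in seq_along(cfg$fractions)) {
    x2 <- cfg$fractions[i]
    nm <- paste0("mix_x2_", formatC(x2, format = "g"))
    isos[[nm]] <- generate_mixture_isotherm(
      cfg$component1, cfg$component2, x2, cfg$excess, cfg$grid,
      cfg$noise_sigma, seeds[i + 2L])
  }
  isos
}

study_ground_truth <- function(cfg) {
  data.frame(
    x2 = cfg$fractions,
    a_ex_A2 = cfg$excess$a_ex,
    pi_s_mN_m = cfg$excess$pi_s,
    dgex_10 = dgex_closed_form(cfg$excess, cfg$fractions, 10),
    dgex_20 = dgex_closed_form(cfg$excess, cfg$fractions, 20),
    dgex_30 = dgex_closed_form(cfg$excess, cfg$fractions, 30)
  )
}
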
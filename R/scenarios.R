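# Disease scenario parameter bundles: healthy, NSIP, IPF.

#' Construct a disease scenario
#'
#' Parameter bundle describing one septal-thickness scenario: primary and
#' secondary septal thickness, the equivalent small-strain modulus of the
#' tissue, its Poisson ratio, and the target resting lumen volume used to
#' calibrate the geometry.
#'
#' @param name Scenario label (free text; `"healthy"`, `"NSIP"`, `"IPF"` for
#'   the presets).
#' @param primary_thickness,secondary_thickness Septal thicknesses in mm
#'   (primary: walls facing the interstitium; secondary: inter-alveolar walls
#'   inside a sac).
#' @param E Equivalent small-strain modulus in Pa.
#' @param nu Poisson ratio, in `[0, 0.5)`.
#' @param target_resting_volume Resting (FRC-state) lumen volume in mm^3 that
#'   the calibrated geometry must match; `NA` to keep the as-built volume.
#' @return Object of class `disease_scenario`.
#' @export
disease_scenario <- function(name, primary_thickness, secondary_thickness,
                             E, nu = 0.42, target_resting_volume = NA_real_) {
  if (primary_thickness <= 0 || secondary_thickness <= 0) {
    stop_acinusim("septal thicknesses must be positive",
                  "acinusim_invalid_parameter")
  }
  if (E <= 0) stop_acinusim("E must be positive", "acinusim_invalid_parameter")
  if (nu < 0 || nu >= 0.5) {
    stop_acinusim("nu must lie in [0, 0.5)", "acinusim_invalid_parameter")
  }
  structure(list(name = name,
                 primary_thickness = primary_thickness,
                 secondary_thickness = secondary_thickness,
                 E = E, nu = nu,
                 target_resting_volume = target_resting_volume),
            class = "disease_scenario")
}

as_disease_scenario <- function(x) {
  if (inherits(x, "disease_scenario")) return(x)
  if (is.character(x) && length(x) == 1L) {
    presets <- scenario_presets()
    key <- tolower(x)
    if (key %in% names(presets)) return(presets[[key]])
  }
  stop_acinusim("not a disease_scenario or preset name",
                "acinusim_invalid_parameter")
}

#' Scenario presets: healthy, NSIP and IPF
#'
#' The three standard parameterizations.  Healthy: all septa 0.025 mm thick,
#' resting volume 0.512 mm^3.  NSIP (nonspecific interstitial pneumonia):
#' diffuse thickening, all septa 0.050 mm, resting volume 0.493 mm^3.  IPF
#' (idiopathic pulmonary fibrosis): peripheral thickening, primary septa
#' 0.050 mm with secondary septa spared at 0.025 mm, resting volume
#' 0.465 mm^3.  All share E = 35,714 Pa and nu = 0.42.
#'
#' @return Named list `healthy`, `nsip`, `ipf` of [disease_scenario()]s.
#' @export
scenario_presets <- function() {
  list(
    healthy = disease_scenario("healthy", 0.025, 0.025, 35714, 0.42, 0.512),
    nsip    = disease_scenario("NSIP",    0.050, 0.050, 35714, 0.42, 0.493),
    ipf     = disease_scenario("IPF",     0.050, 0.025, 35714, 0.42, 0.465)
  )
}

#' Randomly perturb a scenario for sweeps and recovery tests
#'
#' Applies independent log-normal multiplicative perturbations (median 1,
#' log-sd `relative_sd`) to the two septal thicknesses and the modulus.
#' Deterministic for a given seed.  The target resting volume is dropped
#' (set to `NA`) because a perturbed geometry has no tabulated target.
#'
#' @param base A [disease_scenario()].
#' @param relative_sd Relative standard deviation (>= 0) of the log-normal
#'   factor.
#' @param seed Integer seed.
#' @return Perturbed `disease_scenario`.
#' @export
perturb_scenario <- function(base, relative_sd, seed = 1L) {
  base <- as_disease_scenario(base)
  if (relative_sd < 0) {
    stop_acinusim("relative_sd must be non-negative",
                  "acinusim_invalid_parameter")
  }
  if (relative_sd == 0) return(base)
  fac <- withr_seed(seed, exp(stats::rnorm(3L, 0, relative_sd)))
  disease_scenario(
    name = paste0(base$name, "_perturbed"),
    primary_thickness = base$primary_thickness * fac[1],
    secondary_thickness = base$secondary_thickness * fac[2],
    E = base$E * fac[3], nu = base$nu,
    target_resting_volume = NA_real_
  )
}

# evaluate expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.disease_scenario <- function(x, ...) {
  cat(sprintf(
    "<disease_scenario %s: septa %.3g/%.3g mm, E=%.6g Pa, nu=%.3g, V0=%s mm^3>\n",
    x$name, x$primary_thickness, x$secondary_thickness, x$E, x$nu,
    format(x$target_resting_volume)))
  invisible(x)
}
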
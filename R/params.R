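#' Simulation parameters for the Potts tissue model
#'
#' Constructs the full parameter set of the two-layer model in concrete
#' lattice units (1 area unit = 1 lattice site, 1 time unit = 1 Monte Carlo
#' step). The default values reproduce the model's published calibration,
#' expressed through the sizer scale `As` and the elastic modulus `lambda`:
#' \deqn{k_BT = 1.95\times10^{-4}\,\lambda A_S^2,\quad
#'       J_{cc} = 1.17\times10^{-4}\,\lambda A_S^{3/2},\quad
#'       J_{cm} = 1.96\times10^{-4}\,\lambda A_S^{3/2},}
#' \deqn{k = 1.897\times10^{5} A_S^{-2},\quad
#'       G = 1.16\,A_S/\tau_0,\quad
#'       \rho_{1/2} = 1.5015/A_S,\quad
#'       \alpha = 0.968\,A_S.}
#' Every defaulted argument may be overridden with a concrete lattice-unit
#' value.
#'
#' @param As_mean Mean G1 sizer threshold \eqn{A_S} (lattice sites).
#' @param As_sd Standard deviation of the per-cell sizer draw (sites).
#'   Defaults to 2.5% of `As_mean`.
#' @param tau0_mean Mean S/G2/M timer duration \eqn{\tau_0} (MCS).
#' @param tau0_sd Standard deviation of the per-cell timer draw (MCS).
#'   Defaults to 2.5% of `tau0_mean`.
#' @param lambda Area elastic modulus \eqn{\lambda} (energy / site^2).
#' @param kBT Metropolis temperature (energy).
#' @param Jcc,Jcm Cell-cell and cell-medium contact energies per Moore
#'   boundary site pair (energy). The model requires `Jcc <= Jcm`.
#' @param G Isolated-cell growth rate (sites / MCS).
#' @param k Sensitivity to crowding (1 / site^2).
#' @param papo_max Maximum apoptosis probability per decision step.
#' @param rho_half Local density at half-maximum apoptosis probability
#'   (1 / site).
#' @param alpha Sensitivity of apoptosis to density (sites).
#' @param box_area Confinement area (sites); the lattice is the smallest
#'   square containing it, side `ceiling(sqrt(box_area))`.
#' @param seed RNG seed used by [run_simulation()].
#' @param t_max Run length (MCS).
#' @param apoptosis_enabled Logical; `FALSE` sets the apoptosis probability
#'   identically to zero.
#' @param record_every Sampling cadence of the time series (MCS). Defaults
#'   to `tau0_mean / 4` rounded up.
#' @param crowding_floor Resolution floor (sites) below which a cell's area
#'   deviation is not read as crowding by the growth rule. Defaults to the
#'   equipartition amplitude of thermal area fluctuations,
#'   `sqrt(kBT / (2 * lambda))`; see the package vignette for the
#'   rationale. Not meant to be tuned independently of `kBT`.
#'
#' @return An object of class `sim_params`: a named list of validated
#'   parameter values in lattice units, plus the derived lattice side `L`.
#' @examples
#' p <- sim_params()                  # published calibration, As = 1377
#' p_small <- sim_params(As_mean = 100, tau0_mean = 40, box_area = 100 * 100)
#' @export
sim_params <- function(As_mean = 1377,
                       As_sd = 0.025 * As_mean,
                       tau0_mean = 225,
                       tau0_sd = 0.025 * tau0_mean,
                       lambda = 1,
                       kBT = 1.95e-4 * lambda * As_mean^2,
                       Jcc = 1.17e-4 * lambda * As_mean^1.5,
                       Jcm = 1.96e-4 * lambda * As_mean^1.5,
                       G = 1.16 * As_mean / tau0_mean,
                       k = 1.897e5 / As_mean^2,
                       papo_max = 0.0015,
                       rho_half = 1.5015 / As_mean,
                       alpha = 0.968 * As_mean,
                       box_area = 1600 * As_mean,
                       seed = 1L,
                       t_max = 10 * tau0_mean,
                       apoptosis_enabled = TRUE,
                       record_every = ceiling(tau0_mean / 4),
                       crowding_floor = sqrt(kBT / (2 * lambda))) {
  p <- list(
    kBT = kBT, Jcc = Jcc, Jcm = Jcm, lambda = lambda,
    G = G, k = k,
    tau0_mean = tau0_mean, tau0_sd = tau0_sd,
    As_mean = As_mean, As_sd = As_sd,
    papo_max = papo_max, rho_half = rho_half, alpha = alpha,
    box_area = box_area,
    seed = as.integer(seed), t_max = as.integer(t_max),
    apoptosis_enabled = isTRUE(apoptosis_enabled),
    record_every = as.integer(record_every),
    crowding_floor = crowding_floor
  )
  p$L <- as.integer(ceiling(sqrt(p$box_area)))
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  pos <- c("kBT", "Jcc", "Jcm", "lambda", "G", "k", "tau0_mean", "As_mean",
           "papo_max", "rho_half", "alpha", "box_area")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop(sprintf("parameter '%s' must be a single positive finite number", f))
    }
  }
  if (p$Jcc > p$Jcm) {
    stop("cell-cell adhesion must be at least as strong as cell-medium: Jcc <= Jcm")
  }
  if (p$papo_max > 1) stop("papo_max is a probability and must be <= 1")
  if (p$tau0_sd < 0 || p$As_sd < 0) stop("sd parameters must be non-negative")
  if (p$tau0_sd >= p$tau0_mean) stop("tau0_sd must be smaller than tau0_mean")
  if (p$As_sd >= p$As_mean) stop("As_sd must be smaller than As_mean")
  if (p$t_max < 0) stop("t_max must be non-negative")
  if (!is.numeric(p$crowding_floor) || p$crowding_floor < 0) {
    stop("crowding_floor must be non-negative")
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Potts tissue simulation parameters (lattice units)\n")
  cat(sprintf("  sizer As = %.6g +/- %.6g sites;  timer tau0 = %.6g +/- %.6g MCS\n",
              x$As_mean, x$As_sd, x$tau0_mean, x$tau0_sd))
  cat(sprintf("  kBT = %.6g  Jcc = %.6g  Jcm = %.6g  lambda = %.6g\n",
              x$kBT, x$Jcc, x$Jcm, x$lambda))
  cat(sprintf("  growth G = %.6g sites/MCS;  crowding k = %.6g /site^2\n",
              x$G, x$k))
  cat(sprintf("  apoptosis: %s  papo_max = %.6g  rho_half = %.6g  alpha = %.6g\n",
              if (x$apoptosis_enabled) "on" else "off",
              x$papo_max, x$rho_half, x$alpha))
  cat(sprintf("  box area = %.6g sites (lattice %d x %d), t_max = %d MCS, seed = %d\n",
              x$box_area, x$L, x$L, x$t_max, x$seed))
  invisible(x)
}

#' Resolve the scaled default calibration to concrete lattice units
#'
#' The model's calibration is stated in a unit system built from the sizer
#' threshold \eqn{A_S}, the timer \eqn{\tau_0} and the elastic modulus
#' \eqn{\lambda}. This helper takes concrete values of those three scales
#' and returns the full parameter set in lattice units.
#'
#' @param As G1 sizer threshold in lattice sites (default 1377).
#' @param lambda Area elastic modulus (default 1).
#' @param tau0 Timer duration in MCS (default 225).
#' @param ... Further arguments passed to [sim_params()].
#' @return A `sim_params` object.
#' @examples
#' p <- resolve_lattice_units(As = 1377, lambda = 1)
#' p$kBT              # 1.95e-4 * 1377^2 = 369.7
#' @export
resolve_lattice_units <- function(As = 1377, lambda = 1, tau0 = 225, ...) {
  if (!is.numeric(As) || As <= 0) stop("As must be positive")
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be positive")
  if (!is.numeric(tau0) || tau0 <= 0) stop("tau0 must be positive")
  sim_params(As_mean = As, lambda = lambda, tau0_mean = tau0, ...)
}

#' Rescale a parameter set to a new sizer / timer scale
#'
#' Produces the parameter set with sizer scale `new_As` and timer scale
#' `new_tau0` whose dimensionless groups
#' \eqn{k_BT/\lambda A_S^2}, \eqn{J_{cc}/\lambda A_S^{3/2}},
#' \eqn{J_{cm}/\lambda A_S^{3/2}}, \eqn{k A_S^2}, \eqn{G\tau_0/A_S},
#' \eqn{\rho_{1/2} A_S}, \eqn{\alpha/A_S}, the relative spreads
#' `As_sd/As_mean` and `tau0_sd/tau0_mean`, and the box size in sizer units
#' `box_area/As` are identical to those of `params`. Durations (`t_max`,
#' `record_every`) are rescaled by the timer ratio. This enables desk-scale
#' runs that preserve the model's dimensionless calibration.
#'
#' @param params A `sim_params` object.
#' @param new_As New sizer threshold in sites (must be at least 25 so cells
#'   stay resolvable on the lattice).
#' @param new_tau0 New timer duration in MCS. Defaults to the old one.
#' @return A `sim_params` object at the new scale.
#' @examples
#' small <- rescale_params(sim_params(), new_As = 100, new_tau0 = 40)
#' small$k * small$As_mean^2     # invariant: 1.897e5
#' @export
rescale_params <- function(params, new_As, new_tau0 = params$tau0_mean) {
  stopifnot(inherits(params, "sim_params"))
  if (new_As < 25) {
    stop("new_As must be >= 25 sites: smaller cells are not resolvable on the lattice")
  }
  rA <- new_As / params$As_mean
  rT <- new_tau0 / params$tau0_mean
  sim_params(
    As_mean = new_As,
    As_sd = params$As_sd * rA,
    tau0_mean = new_tau0,
    tau0_sd = params$tau0_sd * rT,
    lambda = params$lambda,
    kBT = params$kBT * rA^2,
    Jcc = params$Jcc * rA^1.5,
    Jcm = params$Jcm * rA^1.5,
    G = params$G * rA / rT,
    k = params$k / rA^2,
    papo_max = params$papo_max,
    rho_half = params$rho_half / rA,
    alpha = params$alpha * rA,
    box_area = params$box_area * rA,
    seed = params$seed,
    t_max = as.integer(round(params$t_max * rT)),
    apoptosis_enabled = params$apoptosis_enabled,
    record_every = as.integer(max(1, round(params$record_every * rT))),
    crowding_floor = params$crowding_floor * rA
  )
}

#' Parameters of the continuum colony-growth model
#'
#' @param G Single-cell growth rate (area / time).
#' @param a0 Area of a newborn cell proliferating in isolation; the area
#'   unit of the scaled system.
#' @param lambda Stress relaxation rate (1 / time); the inverse time unit.
#' @param k Sensitivity to crowding (1 / area^2).
#' @param Amax Confinement area, in units of `a0` when `a0 = 1`.
#' @return An object of class `continuum_params`.
#' @examples
#' continuum_params()    # scaled defaults: a0 = 1, lambda = 1, Amax = 800
#' @export
continuum_params <- function(G = 1, a0 = 1, lambda = 1, k = 0.01, Amax = 800) {
  p <- list(G = G, a0 = a0, lambda = lambda, k = k, Amax = Amax)
  for (f in names(p)) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop(sprintf("continuum parameter '%s' must be a single positive number", f))
    }
  }
  if (Amax <= a0) stop("Amax must exceed the newborn area a0")
  class(p) <- "continuum_params"
  p
}

#' Read / write a simulation configuration
#'
#' Configurations are YAML (or JSON) files whose keys match the fields of
#' [sim_params()]; unknown keys are rejected. `write_config()` round-trips
#' a `sim_params` object.
#'
#' @param path File path.
#' @return `read_config()` returns a `sim_params` object.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw$L <- NULL
  allowed <- names(formals(sim_params))
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         "; valid keys are: ", paste(allowed, collapse = ", "))
  }
  do.call(sim_params, raw)
}

#' @rdname read_config
#' @param params A `sim_params` object.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  x <- unclass(params)
  x$L <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}
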
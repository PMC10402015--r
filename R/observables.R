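#' Cell pressure
#'
#' The pressure a cell exerts follows from the area-elastic energy:
#' \eqn{p_\alpha = -2\lambda (A_\alpha - A^T_\alpha)}. A compressed cell
#' (area below target) has positive pressure.
#'
#' @param area Cell area(s).
#' @param target Target area(s).
#' @param lambda Area elastic modulus.
#' @return Pressure(s).
#' @export
cell_pressure <- function(area, target, lambda) {
  -2 * lambda * (area - target)
}

#' Pressure gradient at the colony boundary
#'
#' Boundary cells are live cells with at least one cell-medium Moore
#' interfacial pair; the interior reference ring consists of their
#' cell-neighbours that are not themselves boundary cells. The gradient is
#' the mean boundary-cell pressure minus the mean interior-ring pressure.
#' When every cell is a boundary cell (single cells, very small colonies)
#' the gradient is reported as 0 with a warning.
#'
#' @param tis A `potts_tissue`.
#' @return Pressure difference (boundary minus interior ring).
#' @export
boundary_pressure_gradient <- function(tis) {
  nmax <- tis$next_id - 1L
  live <- which(tis$alive)
  if (length(live) == 0) stop("tissue has no live cells")
  intf <- cpm_interfaces(tis$lattice, nmax)
  boundary <- intersect(live, which(intf$medium_pairs > 0))
  if (length(boundary) == 0) {
    warning("no boundary cells found; returning 0")
    return(0)
  }
  nb_of_boundary <- unique(c(intf$j[intf$i %in% boundary],
                             intf$i[intf$j %in% boundary]))
  interior <- setdiff(intersect(nb_of_boundary, live), boundary)
  if (length(interior) == 0) {
    warning("all cells are boundary cells; returning 0")
    return(0)
  }
  p <- cell_pressure(tis$area, tis$target, tis$params$lambda)
  mean(p[boundary]) - mean(p[interior])
}

#' Birth and elimination rates from the event log
#'
#' Sliding-window event counts normalised per live cell per timer period
#' `tau0`. Births are division events; eliminations are apoptosis removals
#' plus extrusions.
#'
#' @param events Event log data frame (see [event_log()]).
#' @param n_series Data frame with columns `t` and `N` (live cell count),
#'   e.g. the simulation time series.
#' @param window Window length in MCS (>= 1).
#' @param tau0 Timer period used for normalisation (MCS).
#' @return Data frame with columns `t`, `kbirth`, `kelim` (events per cell
#'   per `tau0`), one row per row of `n_series`; each row summarises the
#'   window `(t - window, t]`.
#' @export
proliferation_rates <- function(events, n_series, window, tau0) {
  stopifnot(window >= 1)
  t_div <- events$t[events$event == "division"]
  t_elim <- events$t[events$event %in% c("apoptosis_removal", "extrusion")]
  out <- data.frame(t = n_series$t, kbirth = NA_real_, kelim = NA_real_)
  for (i in seq_len(nrow(n_series))) {
    t1 <- n_series$t[i]
    t0 <- t1 - window
    sel <- n_series$t > t0 & n_series$t <= t1
    meanN <- mean(n_series$N[sel])
    if (!is.finite(meanN) || meanN <= 0) next
    norm <- meanN * window / tau0
    out$kbirth[i] <- sum(t_div > t0 & t_div <= t1) / norm
    out$kelim[i] <- sum(t_elim > t0 & t_elim <= t1) / norm
  }
  out
}

#' Time for the colony to fill its confinement
#'
#' First time the colony area (total occupied sites) reaches
#' `frac * box_area`, linearly interpolated between samples.
#'
#' @param ts Time series data frame with columns `t` and `colony_area`.
#' @param box_area Confinement area (sites).
#' @param frac Confluence fraction (default 0.99).
#' @return Crossing time in MCS, or `NA` (with a diagnostic attribute
#'   `"reason"`) if the series never reaches the threshold.
#' @export
measure_tgrowth <- function(ts, box_area, frac = 0.99) {
  thr <- frac * box_area
  above <- which(ts$colony_area >= thr)
  if (length(above) == 0) {
    out <- NA_real_
    attr(out, "reason") <- sprintf(
      "colony area reached %.3g of the %.3g-site threshold",
      max(ts$colony_area), thr)
    return(out)
  }
  i <- above[1]
  if (i == 1) return(ts$t[1])
  t0 <- ts$t[i - 1]; t1 <- ts$t[i]
  a0 <- ts$colony_area[i - 1]; a1 <- ts$colony_area[i]
  t0 + (thr - a0) / (a1 - a0) * (t1 - t0)
}

#' Detect the onset of homeostasis
#'
#' Homeostasis is the state in which the cell count and the average density
#' no longer change. The onset is the earliest sample time `t*` from which,
#' for at least `span` MCS, the windowed series of `N` and of mean density
#' both stay within a relative band of width `tol` (range / mean <= tol).
#'
#' @param ts Time series with columns `t`, `N`, `mean_density`.
#' @param tol Relative tolerance (default 0.02).
#' @param span Required plateau length in MCS (default `5 * tau0`, which
#'   must then be supplied).
#' @param tau0 Timer period, used only for the default span.
#' @return Onset time (MCS), or `NA` with a `"reason"` attribute when no
#'   plateau is found within the series.
#' @export
detect_homeostasis <- function(ts, tol = 0.02, span = 5 * tau0, tau0 = NULL) {
  if (is.null(span)) stop("supply span or tau0")
  n <- nrow(ts)
  for (i in seq_len(n)) {
    sel <- ts$t >= ts$t[i] & ts$t <= ts$t[i] + span
    if (max(ts$t) < ts$t[i] + span) break  # series too short from here on
    okN <- diff(range(ts$N[sel])) <= tol * mean(ts$N[sel])
    okD <- diff(range(ts$mean_density[sel])) <= tol * mean(ts$mean_density[sel])
    if (okN && okD) return(ts$t[i])
  }
  out <- NA_real_
  attr(out, "reason") <- "no plateau of the required length found"
  out
}

#' Per-cell area growth rates between two snapshots
#'
#' @param cells_t0,cells_t1 Cell tables (see [cell_table()]) at two times;
#'   cells born or removed between the snapshots are excluded.
#' @param dt Time separation in MCS.
#' @return Data frame with columns `id`, `area_t0`, `area_t1`, `rate`
#'   (sites / MCS; negative rates indicate bulk contraction).
#' @export
growth_rate_map <- function(cells_t0, cells_t1, dt) {
  stopifnot(dt > 0)
  common <- intersect(cells_t0$id, cells_t1$id)
  a0 <- cells_t0$area[match(common, cells_t0$id)]
  a1 <- cells_t1$area[match(common, cells_t1$id)]
  data.frame(id = common, area_t0 = a0, area_t1 = a1, rate = (a1 - a0) / dt)
}

#' Fraction of live cells in G1
#'
#' @param x A `potts_tissue` or a cell table. Apoptotic cells are excluded
#'   from both numerator and denominator.
#' @return Fraction in `[0, 1]`.
#' @export
g1_fraction <- function(x) {
  if (inherits(x, "potts_tissue")) {
    live <- which(x$alive & x$phase != PHASE_APOPTOTIC)
    if (length(live) == 0) stop("no live cells")
    return(mean(x$phase[live] == PHASE_G1))
  }
  live <- x$phase != "APOPTOTIC"
  if (!any(live)) stop("no live cells")
  mean(x$phase[live] == "G1")
}

#' Radial profile of cell area
#'
#' Bins live cells by the distance of their centroid from the colony centre
#' (the area-weighted centroid of all occupied sites) and averages the cell
#' area in each bin.
#'
#' @param tis A `potts_tissue`.
#' @param n_bins Number of equal-width bins covering `[0, max distance]`.
#' @return Data frame with columns `bin_center` (distance in sites),
#'   `mean_area`, `n_cells`.
#' @export
radial_profile <- function(tis, n_bins = 8) {
  cen <- cpm_census(tis$lattice, tis$next_id - 1L)
  live <- which(tis$alive & tis$area > 0)
  if (length(live) == 0) stop("no live cells")
  w <- tis$area[live]
  cx <- sum(cen$centroid_row[live] * w) / sum(w)
  cy <- sum(cen$centroid_col[live] * w) / sum(w)
  d <- sqrt((cen$centroid_row[live] - cx)^2 + (cen$centroid_col[live] - cy)^2)
  edges <- seq(0, max(d) + 1e-9, length.out = n_bins + 1)
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  data.frame(
    bin_center = (edges[-1] + edges[-length(edges)]) / 2,
    mean_area = vapply(seq_len(n_bins),
                       function(b) if (any(bin == b)) mean(tis$area[live][bin == b]) else NA_real_,
                       numeric(1)),
    n_cells = vapply(seq_len(n_bins), function(b) sum(bin == b), integer(1))
  )
}
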
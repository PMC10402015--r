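#' Run a tissue-growth simulation
#'
#' Starts from a single cell of area `As_mean / 2` (below the sizer
#' threshold) centred in the confinement box, and alternates one Monte
#' Carlo step of the physical layer with one pass of the decision layer for
#' `t_max` MCS. All randomness is drawn from one RNG stream seeded with
#' `params$seed`, so identical configurations reproduce identical event
#' logs and lattices.
#'
#' @param params A [sim_params()] object.
#' @param out_dir Optional output directory; when given, the time series,
#'   event log, cycle table, final cell table, configuration and a JSON run
#'   manifest (with file hashes) are written there.
#' @param record_cells Record a full cell table (with centroids) at every
#'   sample time.
#' @param snapshot_every Optional cadence (MCS) at which deep copies of the
#'   lattice are stored in the result.
#' @param progress Print a progress line every 10 samples.
#' @param stop_at_confluence Stop the run once the colony occupies the full
#'   confinement (useful for growth-time sweeps, where post-confluence
#'   dynamics are not needed).
#' @return An object of class `potts_sim`: a list with the final `tissue`,
#'   the sampled `time_series`, the `events`, `cycles` and `transitions`
#'   tables, optional `cell_tables` and `snapshots`, and the resolved
#'   `params`.
#' @examples
#' \donttest{
#' p <- sim_params(As_mean = 100, tau0_mean = 40, box_area = 30^2,
#'                 t_max = 120, seed = 7)
#' sim <- run_simulation(p)
#' tail(sim$time_series)
#' }
#' @export
run_simulation <- function(params, out_dir = NULL, record_cells = FALSE,
                           snapshot_every = NULL, progress = FALSE,
                           stop_at_confluence = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  tis <- new_tissue(params)
  samples <- list()
  cell_tabs <- list()
  snaps <- list()
  record <- function() {
    live <- which(tis$alive)
    nonapo <- which(tis$alive & tis$phase != PHASE_APOPTOTIC)
    rho <- tissue_local_density(tis)
    intf <- cpm_interfaces(tis$lattice, max(1L, tis$next_id - 1L))
    boundary <- intersect(live, which(intf$medium_pairs > 0))
    bulk <- setdiff(live, boundary)
    bpg <- suppressWarnings(
      if (length(live) > 0) boundary_pressure_gradient(tis) else NA_real_)
    samples[[length(samples) + 1L]] <<- data.frame(
      t = tis$t,
      N = length(live),
      colony_area = sum(tis$area[live]),
      mean_area = if (length(nonapo) > 0) mean(tis$area[nonapo]) else NA_real_,
      mean_density = if (length(nonapo) > 0) mean(rho[nonapo]) else NA_real_,
      g1_fraction = if (length(nonapo) > 0) mean(tis$phase[nonapo] == PHASE_G1) else NA_real_,
      mean_area_boundary = if (length(boundary) > 0) mean(tis$area[boundary]) else NA_real_,
      mean_area_bulk = if (length(bulk) > 0) mean(tis$area[bulk]) else NA_real_,
      boundary_pressure_gradient = bpg
    )
    if (record_cells) {
      tab <- cell_table(tis, centroids = TRUE)
      tab$t <- tis$t
      cell_tabs[[length(cell_tabs) + 1L]] <<- tab
    }
  }
  record()
  if (!is.null(snapshot_every)) snaps[[as.character(0L)]] <- lattice_snapshot(tis)
  while (tis$t < params$t_max) {
    run_mcs(tis)
    tis$t <- tis$t + 1L
    step_decision_layer(tis)
    if (tis$t %% params$record_every == 0L || tis$t == params$t_max) {
      record()
      if (progress && length(samples) %% 10L == 0L) {
        s <- samples[[length(samples)]]
        message(sprintf("t = %d MCS: N = %d, colony area = %d",
                        s$t, s$N, s$colony_area))
      }
    }
    if (!is.null(snapshot_every) && tis$t %% snapshot_every == 0L) {
      snaps[[as.character(tis$t)]] <- lattice_snapshot(tis)
    }
    if (!any(tis$alive)) break  # tissue went extinct
    if (stop_at_confluence && sum(tis$area[tis$alive]) >= params$box_area) {
      if (tis$t %% params$record_every != 0L) record()
      break
    }
  }
  res <- list(
    params = params,
    tissue = tis,
    time_series = do.call(rbind, samples),
    events = event_log(tis),
    cycles = cycle_statistics(tis),
    transitions = sizer_transitions(tis),
    cell_tables = if (record_cells) do.call(rbind, cell_tabs) else NULL,
    snapshots = if (length(snaps) > 0) snaps else NULL
  )
  class(res) <- "potts_sim"
  if (!is.null(out_dir)) write_run_outputs(res, out_dir)
  res
}

#' @export
print.potts_sim <- function(x, ...) {
  ts <- x$time_series
  last <- ts[nrow(ts), ]
  cat(sprintf("Potts tissue simulation: %d MCS on a %d x %d lattice (seed %d)\n",
              x$params$t_max, x$params$L, x$params$L, x$params$seed))
  cat(sprintf("  final: N = %d cells, colony area = %d sites (%.1f%% of box), G1 fraction = %.2f\n",
              last$N, last$colony_area,
              100 * last$colony_area / x$params$box_area, last$g1_fraction))
  cat(sprintf("  events: %d divisions, %d apoptoses started, %d extrusions\n",
              sum(x$events$event == "division"),
              sum(x$events$event == "apoptosis_start"),
              sum(x$events$event == "extrusion")))
  invisible(x)
}

write_run_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(res$time_series, "time_series.csv")
  wr(res$events, "events.csv")
  wr(res$cycles, "cycles.csv")
  wr(cell_table(res$tissue, centroids = TRUE), "cells_final.csv")
  cfg <- file.path(out_dir, "config.yaml")
  write_config(res$params, cfg)
  paths <- c(paths, cfg)
  if (requireNamespace("png", quietly = TRUE)) {
    lab <- lattice_snapshot(res$tissue)
    if (max(lab) <= 65535L) {
      p <- file.path(out_dir, "final_labels.png")
      png::writePNG(lab / 65535, p)  # 16-bit label image of cell identities
      paths <- c(paths, p)
    }
  }
  manifest <- list(
    package = "pottsgrowth",
    version = as.character(utils::packageVersion("pottsgrowth")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = res$params$seed,
    lattice_side = res$params$L,
    coordinate_convention = "1-based (row, col), origin top-left",
    params = unclass(res$params),
    files = lapply(stats::setNames(paths, basename(paths)),
                   function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

# deterministic small hash of a parameter-grid point, so that adding grid
# points never changes the seeds of existing runs
grid_point_hash <- function(values) {
  s <- paste(names(values), vapply(values, format, character(1), digits = 15),
             sep = "=", collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 1048576
  as.integer(h)
}

#' Run a one- or multi-factor parameter sweep
#'
#' Runs one simulation per point of the Cartesian grid and summarises each
#' run. Each run's seed is `base seed + a stable hash of the grid point`,
#' so extending the grid never changes existing runs.
#'
#' @param base_params A [sim_params()] object supplying every non-swept
#'   value.
#' @param grid Named list of parameter values, e.g.
#'   `list(G = c(1, 2, 4))`; names must be [sim_params()] arguments.
#' @param record_cells,progress,... Passed to [run_simulation()].
#' @return A data frame with one row per run: the swept values, the derived
#'   seed, `tgrowth`, homeostasis onset, homeostatic density and mean area
#'   (averaged over the final quarter of the run), terminal `kbirth` and
#'   `kelim` (final `5 tau0` window), final G1 fraction, the time-averaged
#'   boundary pressure gradient over the growth phase, and the final cell
#'   count. The individual results are attached as attribute `"runs"`.
#' @export
run_sweep <- function(base_params, grid, record_cells = FALSE,
                      progress = FALSE, ...) {
  stopifnot(inherits(base_params, "sim_params"), is.list(grid))
  allowed <- names(formals(sim_params))
  bad <- setdiff(names(grid), allowed)
  if (length(bad) > 0) {
    stop("unknown sweep parameter(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(allowed, collapse = ", "))
  }
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  base_fields <- unclass(base_params)
  base_fields$L <- NULL
  # a crowding floor left at its thermal default re-derives from the swept
  # kBT and lambda rather than being frozen at the base value
  if (isTRUE(all.equal(base_fields$crowding_floor,
                       sqrt(base_fields$kBT / (2 * base_fields$lambda))))) {
    base_fields$crowding_floor <- NULL
  }
  rows <- list()
  runs <- list()
  for (r in seq_len(nrow(pts))) {
    point <- as.list(pts[r, , drop = FALSE])
    fields <- utils::modifyList(base_fields, point)
    fields$seed <- as.integer((base_params$seed + grid_point_hash(point)) %% 2^31)
    p <- do.call(sim_params, fields)
    sim <- run_simulation(p, record_cells = record_cells, progress = progress,
                          ...)
    rows[[r]] <- cbind(as.data.frame(point), summarize_run(sim))
    runs[[r]] <- sim
  }
  out <- do.call(rbind, rows)
  attr(out, "runs") <- runs
  out
}

#' Summary statistics of one simulation
#'
#' @param sim A [run_simulation()] result.
#' @return One-row data frame with the summary columns described in
#'   [run_sweep()].
#' @export
summarize_run <- function(sim) {
  ts <- sim$time_series
  p <- sim$params
  tau0 <- p$tau0_mean
  tg <- measure_tgrowth(ts, p$box_area)
  onset <- detect_homeostasis(ts, tau0 = tau0)
  tail_sel <- ts$t >= max(ts$t) - ceiling((max(ts$t) - min(ts$t)) / 4)
  rates <- proliferation_rates(sim$events, ts, window = 5 * tau0, tau0 = tau0)
  last <- nrow(ts)
  growth_sel <- if (is.na(tg)) rep(TRUE, nrow(ts)) else ts$t <= tg
  data.frame(
    seed = p$seed,
    tgrowth = as.numeric(tg),
    homeostasis_onset = as.numeric(onset),
    homeostatic_density = mean(ts$mean_density[tail_sel], na.rm = TRUE),
    homeostatic_area = mean(ts$mean_area[tail_sel], na.rm = TRUE),
    kbirth_final = rates$kbirth[last],
    kelim_final = rates$kelim[last],
    g1_fraction_final = ts$g1_fraction[last],
    bpg_growth = mean(ts$boundary_pressure_gradient[growth_sel], na.rm = TRUE),
    N_final = ts$N[last]
  )
}
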
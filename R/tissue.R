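#' @useDynLib pottsgrowth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm setNames
NULL

# Phase codes used throughout the package.
PHASE_G1 <- 0L
PHASE_TIMER <- 1L
PHASE_APOPTOTIC <- 2L

phase_label <- function(code) {
  c("G1", "TIMER", "APOPTOTIC")[code + 1L]
}

#' Create an empty tissue or the standard single-cell initial condition
#'
#' A tissue is a mutable environment holding the lattice (an integer matrix;
#' 0 = medium, >0 = cell identity), per-cell state vectors indexed by cell
#' id, the event log and the cycle/transition records. The standard initial
#' condition is a single cell of area `As_mean / 2` (below the sizer
#' threshold) placed as a centred disk.
#'
#' @param params A [sim_params()] object.
#' @param empty If `TRUE`, return a tissue with no cells (used to build
#'   fixtures).
#' @return A `potts_tissue` environment.
#' @export
new_tissue <- function(params, empty = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  tis <- new.env(parent = emptyenv())
  tis$params <- params
  tis$lattice <- matrix(0L, params$L, params$L)
  tis$t <- 0L
  tis$next_id <- 1L
  n0 <- 64L
  tis$area <- numeric(0)
  tis$target <- numeric(0)
  tis$phase <- integer(0)
  tis$alive <- logical(0)
  tis$As_i <- numeric(0)
  tis$tau0_i <- numeric(0)
  tis$clock <- numeric(0)
  tis$birth_time <- numeric(0)
  tis$birth_area <- numeric(0)
  tis$birth_target <- numeric(0)
  tis$generation <- integer(0)
  tis$parent <- integer(0)
  tis$avg_area <- numeric(0)
  # event log: grown in place, finalised by event_log()
  tis$ev_n <- 0L
  tis$ev_t <- numeric(n0)
  tis$ev_type <- character(n0)
  tis$ev_id <- integer(n0)
  tis$ev_parent <- integer(n0)
  # completed cell cycles and G1/S transitions
  tis$cycles <- list()
  tis$transitions <- list()
  class(tis) <- c("potts_tissue", "environment")
  if (!empty) {
    a0 <- max(2, round(params$As_mean / 2))
    sites <- disk_sites(params$L, a0)
    add_cell(tis, sites, generation = 0L, parent = NA_integer_)
  }
  tis
}

# the `n` lattice sites of an L x L lattice closest to its centre
disk_sites <- function(L, n, center = c((L + 1) / 2, (L + 1) / 2)) {
  stopifnot(n <= L * L)
  rc <- as.matrix(expand.grid(row = seq_len(L), col = seq_len(L)))
  d2 <- (rc[, 1] - center[1])^2 + (rc[, 2] - center[2])^2
  rc[order(d2)[seq_len(n)], , drop = FALSE]
}

# register a new cell owning `sites` (matrix of (row, col)); returns its id
add_cell <- function(tis, sites, generation, parent,
                     target = nrow(sites), As_i = NULL, tau0_i = NULL) {
  p <- tis$params
  id <- tis$next_id
  tis$next_id <- id + 1L
  tis$lattice[sites] <- id
  tis$area[id] <- nrow(sites)
  tis$target[id] <- target
  tis$phase[id] <- PHASE_G1
  tis$alive[id] <- TRUE
  tis$As_i[id] <- if (is.null(As_i)) draw_trunc(1, p$As_mean, p$As_sd, 25) else As_i
  tis$tau0_i[id] <- if (is.null(tau0_i)) draw_trunc(1, p$tau0_mean, p$tau0_sd, 1) else tau0_i
  tis$clock[id] <- 0
  tis$birth_time[id] <- tis$t
  tis$birth_area[id] <- nrow(sites)
  tis$birth_target[id] <- target
  tis$generation[id] <- as.integer(generation)
  tis$parent[id] <- if (is.na(parent)) NA_integer_ else as.integer(parent)
  tis$avg_area[id] <- nrow(sites)
  id
}

# Gaussian draw truncated at +/- 3 sd and at a hard floor, so individual
# sizer/timer thresholds can never become nonphysical.
draw_trunc <- function(n, mean, sd, floor_value) {
  if (sd == 0) return(rep(max(mean, floor_value), n))
  x <- rnorm(n, mean, sd)
  bad <- abs(x - mean) > 3 * sd | x < floor_value
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > 3 * sd | x < floor_value
  }
  x
}

log_event <- function(tis, type, id, parent = NA_integer_) {
  n <- tis$ev_n + 1L
  if (n > length(tis$ev_t)) {
    grow <- length(tis$ev_t)
    tis$ev_t <- c(tis$ev_t, numeric(grow))
    tis$ev_type <- c(tis$ev_type, character(grow))
    tis$ev_id <- c(tis$ev_id, integer(grow))
    tis$ev_parent <- c(tis$ev_parent, integer(grow))
  }
  tis$ev_t[n] <- tis$t
  tis$ev_type[n] <- type
  tis$ev_id[n] <- id
  tis$ev_parent[n] <- if (is.na(parent)) NA_integer_ else parent
  tis$ev_n <- n
  invisible(tis)
}

#' Event log of a tissue or simulation result
#'
#' One row per event, in order of occurrence. Event types are `birth` (one
#' per daughter, with `parent`), `division` (retirement of the mother),
#' `apoptosis_start`, `apoptosis_removal` and `extrusion`. The live cell
#' count satisfies, exactly,
#' `N(t) = N(0) + births(<=t) - divisions(<=t) - removals(<=t)`
#' where removals are apoptosis removals plus extrusions.
#'
#' @param x A `potts_tissue` or the result of [run_simulation()].
#' @return A data frame with columns `t`, `event`, `id`, `parent`.
#' @export
event_log <- function(x) {
  tis <- if (inherits(x, "potts_tissue")) x else x$tissue
  n <- tis$ev_n
  data.frame(t = tis$ev_t[seq_len(n)],
             event = tis$ev_type[seq_len(n)],
             id = tis$ev_id[seq_len(n)],
             parent = tis$ev_parent[seq_len(n)])
}

#' Per-cell state table
#'
#' @param tis A `potts_tissue`.
#' @param alive_only Restrict to live cells (default).
#' @param centroids Include centroid columns (requires a lattice scan).
#' @return A data frame with one row per cell: id, phase, area, target area,
#'   individual sizer/timer thresholds, clocks, lineage fields and, if
#'   requested, centroid coordinates (row/col, 1-based).
#' @export
cell_table <- function(tis, alive_only = TRUE, centroids = FALSE) {
  ids <- seq_len(tis$next_id - 1L)
  df <- data.frame(
    id = ids,
    phase = phase_label(tis$phase[ids]),
    area = tis$area[ids],
    target_area = tis$target[ids],
    As_i = tis$As_i[ids],
    tau0_i = tis$tau0_i[ids],
    timer_clock = tis$clock[ids],
    birth_time = tis$birth_time[ids],
    birth_area = tis$birth_area[ids],
    birth_target = tis$birth_target[ids],
    generation = tis$generation[ids],
    parent = tis$parent[ids],
    alive = tis$alive[ids]
  )
  if (centroids && length(ids) > 0) {
    cen <- cpm_census(tis$lattice, tis$next_id - 1L)
    df$centroid_row <- cen$centroid_row[ids]
    df$centroid_col <- cen$centroid_col[ids]
  }
  if (alive_only) df <- df[df$alive, , drop = FALSE]
  df
}

#' @export
print.potts_tissue <- function(x, ...) {
  live <- which(x$alive)
  cat(sprintf("Potts tissue: %d x %d lattice, t = %d MCS, %d live cells (%d sites occupied)\n",
              nrow(x$lattice), ncol(x$lattice), x$t, length(live),
              sum(x$area[live])))
  invisible(x)
}

#' Deep copy of the current lattice
#'
#' The engine updates the lattice in place, so stored snapshots must be
#' copied explicitly; this returns an independent integer matrix.
#' @param tis A `potts_tissue`.
#' @return Integer matrix of cell identities (0 = medium).
#' @export
lattice_snapshot <- function(tis) {
  tis$lattice + 0L
}

#' Total mechanical energy of the tissue
#'
#' Interfacial energy summed over unordered Moore site pairs with differing
#' identities (cell-cell pairs contribute `Jcc`, cell-medium pairs --
#' including the confinement wall -- `Jcm`) plus the area-elastic energy
#' \eqn{\lambda \sum_\alpha (A_\alpha - A^T_\alpha)^2} over all cells.
#'
#' @param tis A `potts_tissue`.
#' @return Total energy (scalar).
#' @export
total_energy <- function(tis) {
  cpm_total_energy(tis$lattice, tis$area, tis$target,
                   tis$params$Jcc, tis$params$Jcm, tis$params$lambda)
}

#' Energy change of a single copy proposal
#'
#' Computes, from local terms only, the energy difference if `target_site`
#' took the identity currently at `source_site`. The two sites must be
#' Moore-adjacent and carry different identities.
#'
#' @param tis A `potts_tissue`.
#' @param target_site,source_site Integer `(row, col)` pairs, 1-based.
#' @return The energy difference (after minus before).
#' @export
delta_energy_copy <- function(tis, target_site, source_site) {
  dr <- abs(target_site[1] - source_site[1])
  dc <- abs(target_site[2] - source_site[2])
  if (max(dr, dc) != 1) stop("sites must be Moore-adjacent")
  s <- tis$lattice[source_site[1], source_site[2]]
  if (tis$lattice[target_site[1], target_site[2]] == s) {
    stop("copy proposal must change the site identity")
  }
  cpm_delta_energy(tis$lattice, tis$area, tis$target,
                   target_site[1] - 1L, target_site[2] - 1L, s,
                   tis$params$Jcc, tis$params$Jcm, tis$params$lambda)
}

#' Metropolis acceptance rule
#'
#' Accepts with probability 1 when the energy change is non-positive and
#' with probability `exp(-dE/kBT)` otherwise. Vectorised over `dE`.
#'
#' @param dE Energy difference(s) of proposed moves.
#' @param kBT Metropolis temperature (> 0).
#' @return Logical vector of acceptances.
#' @export
metropolis_accept <- function(dE, kBT) {
  if (kBT <= 0) stop("kBT must be positive")
  dE <= 0 | runif(length(dE)) < exp(-dE / kBT)
}

#' Local connectivity test for a copy proposal
#'
#' `TRUE` iff removing `target_site` from the cell that owns it leaves the
#' owner's sites within the Moore neighbourhood of that site in a single
#' Moore-connected piece. Copies failing the test would fragment the cell
#' and are rejected by the engine.
#'
#' @param tis A `potts_tissue`.
#' @param target_site Integer `(row, col)`, 1-based.
#' @return Logical flag.
#' @export
connectivity_ok <- function(tis, target_site) {
  cpm_connectivity_ok(tis$lattice, target_site[1] - 1L, target_site[2] - 1L)
}

#' Run Monte Carlo steps of the physical layer
#'
#' One MCS performs `L^2` copy attempts at uniformly random sites with a
#' uniformly random Moore-neighbour source. Attempts that would fragment
#' the losing cell are rejected; others follow the Metropolis rule at
#' temperature `kBT`. Cell areas are maintained incrementally, and the
#' attempt-averaged area of every cell over the sweep is recorded in
#' `tis$avg_area` (the decision layer reads the cell area on the MCS
#' timescale, see the package vignette).
#'
#' @param tis A `potts_tissue` (modified in place).
#' @param n Number of MCS to run.
#' @return Invisibly, the number of accepted moves.
#' @export
run_mcs <- function(tis, n = 1) {
  if (tis$next_id == 1L) return(invisible(0L))  # no cells: nothing can move
  p <- tis$params
  area <- tis$area + 0  # private copy: the kernel updates it in place
  res <- cpm_run_mcs(tis$lattice, area, tis$target,
                     p$Jcc, p$Jcm, p$kBT, p$lambda, as.integer(n))
  tis$area <- area
  tis$avg_area <- res$avg_area
  invisible(res$accepted)
}

#' Number of Moore-connected fragments per cell
#'
#' @param tis A `potts_tissue`.
#' @return Integer vector indexed by cell id (0 for retired cells); a value
#'   above 1 indicates an (unphysical) fragmented cell.
#' @export
fragment_counts <- function(tis) {
  if (tis$next_id == 1L) return(integer(0))
  cpm_fragments(tis$lattice, tis$next_id - 1L)
}

#' Deterministic test fixtures
#'
#' Small hand-checkable tissues used by the unit tests and examples.
#' Kinds: `single_cell` (a centred square cell), `two_cell` (two
#' rectangular cells sharing one straight interface), `ring` (a central
#' disk cell surrounded by a ring of annular-sector cells) and
#' `random_tissue` (a lattice Voronoi tessellation of a central disk, whose
#' cells are convex and therefore connected).
#'
#' @param kind One of `"single_cell"`, `"two_cell"`, `"ring"`,
#'   `"random_tissue"`.
#' @param size Lattice side (<= 40).
#' @param seed RNG seed (used by `random_tissue`).
#' @param params Optional `sim_params`; defaults to a desk-scale set with
#'   `As_mean = 100`, `tau0_mean = 40` and `box_area = size^2`.
#' @return A `potts_tissue`.
#' @export
make_fixture <- function(kind = c("single_cell", "two_cell", "ring", "random_tissue"),
                         size = 30, seed = 1, params = NULL) {
  kind <- match.arg(kind)
  stopifnot(size >= 6, size <= 60)
  if (is.null(params)) {
    params <- sim_params(As_mean = 100, tau0_mean = 40, box_area = size^2,
                         seed = as.integer(seed), apoptosis_enabled = FALSE)
  }
  set.seed(seed)
  tis <- new_tissue(params, empty = TRUE)
  L <- size
  mid <- (L + 1) / 2
  if (kind == "single_cell") {
    s <- max(2, floor(L / 3))
    r0 <- floor(mid - s / 2) + 1
    sites <- as.matrix(expand.grid(row = r0:(r0 + s - 1), col = r0:(r0 + s - 1)))
    add_cell(tis, sites, generation = 0L, parent = NA_integer_)
  } else if (kind == "two_cell") {
    s <- max(2, floor(L / 3))
    r0 <- floor(mid - s / 2) + 1
    c0 <- floor(mid - s) + 1
    left <- as.matrix(expand.grid(row = r0:(r0 + s - 1), col = c0:(c0 + s - 1)))
    right <- as.matrix(expand.grid(row = r0:(r0 + s - 1),
                                   col = (c0 + s):(c0 + 2 * s - 1)))
    add_cell(tis, left, generation = 0L, parent = NA_integer_)
    add_cell(tis, right, generation = 0L, parent = NA_integer_)
  } else if (kind == "ring") {
    rc <- as.matrix(expand.grid(row = seq_len(L), col = seq_len(L)))
    dx <- rc[, 1] - mid
    dy <- rc[, 2] - mid
    d <- sqrt(dx^2 + dy^2)
    r1 <- L / 8
    r2 <- min(L / 2 - 1, 3 * r1)
    core <- rc[d <= r1, , drop = FALSE]
    add_cell(tis, core, generation = 0L, parent = NA_integer_)
    ang <- atan2(dy, dx)
    nsect <- 6L
    sector <- pmin(nsect - 1L, floor((ang + pi) / (2 * pi) * nsect))
    for (sct in 0:(nsect - 1L)) {
      sites <- rc[d > r1 & d <= r2 & sector == sct, , drop = FALSE]
      if (nrow(sites) > 0) add_cell(tis, sites, generation = 0L, parent = NA_integer_)
    }
  } else { # random_tissue
    ncell <- max(4L, as.integer(L^2 / 80))
    rad <- L / 2 - 1.5
    th <- runif(ncell, 0, 2 * pi)
    rr <- rad * sqrt(runif(ncell)) * 0.8
    px <- mid + rr * cos(th)
    py <- mid + rr * sin(th)
    rc <- as.matrix(expand.grid(row = seq_len(L), col = seq_len(L)))
    d <- sqrt((rc[, 1] - mid)^2 + (rc[, 2] - mid)^2)
    inside <- d <= rad
    pts <- rc[inside, , drop = FALSE]
    d2 <- outer(pts[, 1], px, "-")^2 + outer(pts[, 2], py, "-")^2
    owner <- max.col(-d2)
    for (i in seq_len(ncell)) {
      sites <- pts[owner == i, , drop = FALSE]
      if (nrow(sites) > 0) add_cell(tis, sites, generation = 0L, parent = NA_integer_)
    }
  }
  tis
}
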
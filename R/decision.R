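#' Crowding-suppressed growth of the target area
#'
#' The target area of a growing cell increases at the isolated-cell rate
#' `G`, exponentially suppressed by the squared deviation of the cell's
#' actual area from its target:
#' \deqn{\frac{dA^T}{dt} = G\,e^{-k (A - A^T)^2}.}
#' In crowded tissue a cell cannot keep its area close to a growing target,
#' the deviation grows and the growth rate collapses -- this is how contact
#' inhibition of proliferation enters the model.
#'
#' When `floor > 0`, only the part of the deviation exceeding `floor` is
#' read as crowding: `exp(-k * max(0, |A - AT| - floor)^2)`. The simulation
#' loop uses the thermal noise floor `sqrt(kBT / (2 * lambda))` here so
#' that equilibrium occupancy fluctuations of the lattice (of order one
#' site at the default calibration) do not register as crowding; see the
#' vignette. With the default `floor = 0` the rule is the bare exponential.
#'
#' @param target Current target area(s) \eqn{A^T}.
#' @param area Current cell area(s) \eqn{A}.
#' @param G Isolated-cell growth rate (area / MCS).
#' @param k Sensitivity to crowding (1 / area^2).
#' @param dt Time step (MCS); the decision layer uses 1.
#' @param floor Crowding resolution floor (sites).
#' @return Updated target area(s); never smaller than the input.
#' @examples
#' grow_target_area(100, 100, G = 2.9, k = 0.019)   # uncrowded: + G
#' @export
grow_target_area <- function(target, area, G, k, dt = 1, floor = 0) {
  dev <- pmax(0, abs(area - target) - floor)
  target + dt * G * exp(-k * dev^2)
}

#' G1 sizer rule
#'
#' A cell leaves G1 only once its area strictly exceeds its individually
#' drawn sizer threshold.
#'
#' @param area Cell area(s).
#' @param As_i Individual sizer threshold(s).
#' @return Logical: transition to the timer phase now?
#' @export
sizer_transition <- function(area, As_i) {
  area > As_i
}

#' S/G2/M timer rule
#'
#' Advances the phase clock and reports whether division is due
#' (`clock >= tau0_i` after the update).
#'
#' @param clock Current timer clock(s) (MCS).
#' @param tau0_i Individual timer duration(s) (MCS).
#' @param dt Time step (MCS).
#' @return A list with elements `clock` (updated) and `due` (logical).
#' @export
advance_timer <- function(clock, tau0_i, dt = 1) {
  clock <- clock + dt
  list(clock = clock, due = clock >= tau0_i)
}

#' Local cell density
#'
#' The local density perceived by a cell is the sum of inverse areas of the
#' cell itself and of every cell it touches:
#' \deqn{\rho_\alpha = 1/A_\alpha + \sum_{i \in \mathrm{neighbours}} 1/A_i,}
#' where neighbours are cells sharing at least one Moore interfacial site
#' pair.
#'
#' @param own_area Area of the focal cell.
#' @param neighbor_areas Areas of its touching neighbours (possibly empty).
#' @return Local density (1 / area).
#' @examples
#' local_density(1000, c(2000, 4000))   # 0.00175
#' @export
local_density <- function(own_area, neighbor_areas = numeric(0)) {
  if (any(c(own_area, neighbor_areas) <= 0)) {
    stop("local density is undefined for non-positive cell areas")
  }
  1 / own_area + sum(1 / neighbor_areas)
}

#' Local density of every live cell in a tissue
#'
#' @param tis A `potts_tissue`.
#' @return Numeric vector indexed by cell id; `NA` for retired cells.
#' @export
tissue_local_density <- function(tis) {
  nmax <- tis$next_id - 1L
  rho <- rep(NA_real_, nmax)
  if (nmax == 0L) return(rho)
  live <- which(tis$alive & tis$area > 0)
  inv <- ifelse(tis$area > 0, 1 / tis$area, 0)
  rho[live] <- inv[live]
  intf <- cpm_interfaces(tis$lattice, nmax)
  if (length(intf$i) > 0) {
    for (k in seq_along(intf$i)) {
      i <- intf$i[k]; j <- intf$j[k]
      rho[i] <- rho[i] + inv[j]
      rho[j] <- rho[j] + inv[i]
    }
  }
  rho
}

#' Density-dependent apoptosis probability
#'
#' A sigmoidal function of local density,
#' \deqn{P_{apo}(\rho) = \frac{p_{apo,max}}{1 + e^{-\alpha(\rho - \rho_{1/2})}},}
#' applied once per cell per MCS. It is monotone increasing, equals
#' `papo_max / 2` exactly at `rho_half`, and saturates at `papo_max` at
#' high density. When apoptosis is disabled in the parameters the
#' probability is identically zero.
#'
#' @param rho Local density (>= 0), vectorised.
#' @param params A `sim_params` object (fields `papo_max`, `alpha`,
#'   `rho_half`, `apoptosis_enabled`).
#' @return Probability per decision step, in `[0, papo_max]`.
#' @examples
#' p <- sim_params()
#' apoptosis_probability(p$rho_half, p)   # papo_max / 2 = 0.00075
#' @export
apoptosis_probability <- function(rho, params) {
  if (!params$apoptosis_enabled) return(rep(0, length(rho)))
  params$papo_max / (1 + exp(-params$alpha * (rho - params$rho_half)))
}

#' Trigger apoptosis of one cell
#'
#' Samples the density-dependent apoptosis rule for a single cell; on
#' success the cell's phase becomes apoptotic and its target area is set to
#' zero, so the Potts dynamics gradually drain its area until removal.
#'
#' @param tis A `potts_tissue`.
#' @param id Cell id (live, not already apoptotic).
#' @param rho Local density of that cell; computed from the lattice when
#'   omitted.
#' @return Logical: did the cell enter apoptosis?
#' @export
trigger_apoptosis <- function(tis, id, rho = NULL) {
  stopifnot(tis$alive[id], tis$phase[id] != PHASE_APOPTOTIC)
  if (is.null(rho)) rho <- tissue_local_density(tis)[id]
  p <- apoptosis_probability(rho, tis$params)
  if (runif(1) < p) {
    mark_apoptotic(tis, id)
    TRUE
  } else {
    FALSE
  }
}

mark_apoptotic <- function(tis, ids) {
  for (id in ids) {
    tis$phase[id] <- PHASE_APOPTOTIC
    tis$target[id] <- 0
    log_event(tis, "apoptosis_start", id)
  }
  invisible(tis)
}

#' Live-cell extrusion rule
#'
#' A cell is extruded when its area falls strictly below a quarter of the
#' mean area of the live (non-apoptotic) cells.
#'
#' @param area Cell area(s).
#' @param mean_area Mean area of live non-apoptotic cells.
#' @return Logical flag(s).
#' @examples
#' check_extrusion(c(24, 25, 26), mean_area = 100)  # TRUE FALSE FALSE
#' @export
check_extrusion <- function(area, mean_area) {
  area < mean_area / 4
}

#' Remove a cell from the tissue
#'
#' All remaining sites of the cell become medium, the record is retired and
#' the event is logged towards the elimination rate. A shrinking apoptotic
#' cell whose area reaches zero (or which crosses the extrusion threshold)
#' is logged as `apoptosis_removal`; a live extruded cell as `extrusion`.
#'
#' @param tis A `potts_tissue`.
#' @param id Cell id.
#' @param reason `"apoptosis_removal"` or `"extrusion"`.
#' @return Invisibly, the tissue.
#' @export
remove_cell <- function(tis, id, reason = c("apoptosis_removal", "extrusion")) {
  reason <- match.arg(reason)
  stopifnot(tis$alive[id])
  if (tis$area[id] > 0) {
    lat <- tis$lattice
    lat[lat == id] <- 0L
    tis$lattice <- lat
  }
  tis$area[id] <- 0
  tis$target[id] <- 0
  tis$alive[id] <- FALSE
  log_event(tis, reason, id)
  invisible(tis)
}

#' Divide a cell
#'
#' Splits the mother's sites by a straight line through the centroid,
#' oriented perpendicular to the cell's long axis (the principal axis of
#' the second moment of its site coordinates; degenerate moments are broken
#' by a random orientation). Stray fragments created by the cut are
#' re-attached to an adjacent daughter, so both daughters are always
#' Moore-connected. Each daughter receives a new unique id, starts in G1
#' with target area equal to its own post-split area, and draws fresh
#' individual sizer and timer thresholds. The mother is retired and the
#' completed cycle is recorded.
#'
#' @param tis A `potts_tissue`.
#' @param id Id of the dividing cell (area >= 2).
#' @return Integer vector of the two daughter ids.
#' @export
divide_cell <- function(tis, id) {
  stopifnot(tis$alive[id])
  sites <- which(tis$lattice == id, arr.ind = TRUE)
  n <- nrow(sites)
  if (n < 2) stop("cannot divide a cell with fewer than 2 sites")
  storage.mode(sites) <- "double"
  ctr <- colMeans(sites)
  X <- sweep(sites, 2, ctr)
  M <- crossprod(X) / n
  eg <- eigen(M, symmetric = TRUE)
  if (abs(eg$values[1] - eg$values[2]) < 1e-9) {
    th <- runif(1, 0, pi)
    v <- c(cos(th), sin(th))
  } else {
    v <- eg$vectors[, 1]
  }
  pr <- drop(X %*% v)
  side1 <- pr > 0
  tie <- pr == 0
  if (any(tie)) side1[tie] <- runif(sum(tie)) < 0.5
  if (all(side1) || !any(side1)) {
    ord <- order(pr)
    side1[] <- FALSE
    side1[ord[seq_len(n %/% 2)]] <- TRUE
  }
  sets <- split_with_repair(sites, side1, pr)

  mother_area <- tis$area[id]
  cyc <- list(id = id,
              birth_time = tis$birth_time[id],
              division_time = tis$t,
              cycle_time = tis$t - tis$birth_time[id],
              area_at_mitosis = mother_area,
              As_i = tis$As_i[id],
              tau0_i = tis$tau0_i[id],
              generation = tis$generation[id])
  tis$cycles[[length(tis$cycles) + 1L]] <- cyc

  gen <- tis$generation[id] + 1L
  tis$alive[id] <- FALSE
  tis$area[id] <- 0
  tis$target[id] <- 0
  log_event(tis, "division", id)
  s1 <- sets$a; s2 <- sets$b
  storage.mode(s1) <- "integer"
  storage.mode(s2) <- "integer"
  d1 <- add_cell(tis, s1, generation = gen, parent = id)
  d2 <- add_cell(tis, s2, generation = gen, parent = id)
  log_event(tis, "birth", d1, parent = id)
  log_event(tis, "birth", d2, parent = id)
  c(d1, d2)
}

# Moore-connected components of a set of (row, col) sites.
site_components <- function(sites) {
  n <- nrow(sites)
  if (n == 0) return(integer(0))
  idx <- seq_len(n)
  names(idx) <- paste(sites[, 1], sites[, 2])
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack) > 0) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        j <- idx[paste(sites[i, 1] + dr, sites[i, 2] + dc)]
        if (!is.na(j) && comp[j] == 0L) {
          comp[j] <- cur
          stack <- c(stack, j)
        }
      }
    }
  }
  comp
}

# TRUE if any site of `a` is Moore-adjacent to (or coincident-free from)
# any site of `b`
sets_adjacent <- function(a, b) {
  for (i in seq_len(nrow(a))) {
    if (any(abs(b[, 1] - a[i, 1]) <= 1 & abs(b[, 2] - a[i, 2]) <= 1)) return(TRUE)
  }
  FALSE
}

# Partition `sites` into two connected sets guided by the plane assignment
# `side1` (with projections `pr`): the seed components containing the
# extreme sites become the daughters, and stray fragments are attached to
# an adjacent daughter (the smaller one when adjacent to both).
split_with_repair <- function(sites, side1, pr) {
  comps1 <- site_components(sites[side1, , drop = FALSE])
  comps2 <- site_components(sites[!side1, , drop = FALSE])
  i1 <- which(side1)[comps1 == comps1[which.max(pr[side1])]]
  i2 <- which(!side1)[comps2 == comps2[which.min(pr[!side1])]]
  pending <- list()
  for (cmp in setdiff(unique(comps1), comps1[which.max(pr[side1])])) {
    pending[[length(pending) + 1L]] <- which(side1)[comps1 == cmp]
  }
  for (cmp in setdiff(unique(comps2), comps2[which.min(pr[!side1])])) {
    pending[[length(pending) + 1L]] <- which(!side1)[comps2 == cmp]
  }
  while (length(pending) > 0) {
    attached <- FALSE
    for (pi in seq_along(pending)) {
      blk <- sites[pending[[pi]], , drop = FALSE]
      adj1 <- sets_adjacent(blk, sites[i1, , drop = FALSE])
      adj2 <- sets_adjacent(blk, sites[i2, , drop = FALSE])
      if (adj1 || adj2) {
        if (adj1 && adj2) {
          if (length(i1) <= length(i2)) adj2 <- FALSE else adj1 <- FALSE
        }
        if (adj1) i1 <- c(i1, pending[[pi]]) else i2 <- c(i2, pending[[pi]])
        pending[[pi]] <- NULL
        attached <- TRUE
        break
      }
    }
    if (!attached) {
      # cannot happen for a connected mother; fail loudly if it does
      stop("internal error: orphan fragment during cell division")
    }
  }
  list(a = sites[i1, , drop = FALSE], b = sites[i2, , drop = FALSE])
}

#' Advance the decision layer by one step
#'
#' Applies the cell-autonomous rules once, in a fixed order (changing this
#' order is a breaking change):
#' \enumerate{
#'   \item remove cells whose area has drained to zero;
#'   \item extrusion check against a quarter of the mean live-cell area,
#'     and removal of flagged cells (apoptotic cells crossing the threshold
#'     are logged as `apoptosis_removal`, live cells as `extrusion`);
#'   \item apoptosis sampling for live non-apoptotic cells at their current
#'     local density;
#'   \item target-area growth for non-apoptotic cells, using the cell area
#'     averaged over the preceding MCS;
#'   \item G1/S sizer checks (instantaneous area, strict inequality);
#'   \item timer advance and divisions (deferred while area < 2 sites).
#' }
#'
#' @param tis A `potts_tissue` (modified in place).
#' @return Invisibly, the tissue.
#' @export
step_decision_layer <- function(tis) {
  p <- tis$params
  nmax <- tis$next_id - 1L
  if (nmax == 0L) return(invisible(tis))

  # (1) drained cells
  gone <- which(tis$alive & tis$area <= 0)
  for (id in gone) {
    remove_cell(tis, id,
                if (tis$phase[id] == PHASE_APOPTOTIC) "apoptosis_removal" else "extrusion")
  }

  # (2) extrusion
  live <- which(tis$alive & tis$phase != PHASE_APOPTOTIC)
  if (length(live) > 0) {
    mean_area <- mean(tis$area[live])
    cand <- which(tis$alive)
    flag <- check_extrusion(tis$area[cand], mean_area)
    for (id in cand[flag]) {
      remove_cell(tis, id,
                  if (tis$phase[id] == PHASE_APOPTOTIC) "apoptosis_removal" else "extrusion")
    }
  }

  # (3) apoptosis
  if (p$apoptosis_enabled && p$papo_max > 0) {
    cand <- which(tis$alive & tis$phase != PHASE_APOPTOTIC)
    if (length(cand) > 0) {
      rho <- tissue_local_density(tis)
      prob <- apoptosis_probability(rho[cand], p)
      hit <- cand[runif(length(cand)) < prob]
      if (length(hit) > 0) mark_apoptotic(tis, hit)
    }
  }

  # (4) growth of target areas (MCS-averaged area, see vignette)
  grow <- which(tis$alive & tis$phase != PHASE_APOPTOTIC)
  if (length(grow) > 0) {
    a_eff <- tis$avg_area[grow]
    tis$target[grow] <- grow_target_area(tis$target[grow], a_eff, p$G, p$k,
                                         floor = p$crowding_floor)
  }

  # (5) G1 -> timer
  g1 <- which(tis$alive & tis$phase == PHASE_G1)
  go <- g1[sizer_transition(tis$area[g1], tis$As_i[g1])]
  if (length(go) > 0) {
    tis$phase[go] <- PHASE_TIMER
    tis$clock[go] <- 0
    for (id in go) {
      tis$transitions[[length(tis$transitions) + 1L]] <-
        list(t = tis$t, id = id, area = tis$area[id], As_i = tis$As_i[id])
    }
  }

  # (6) timer advance and division
  tm <- which(tis$alive & tis$phase == PHASE_TIMER)
  if (length(tm) > 0) {
    adv <- advance_timer(tis$clock[tm], tis$tau0_i[tm])
    tis$clock[tm] <- adv$clock
    for (id in tm[adv$due]) {
      if (tis$area[id] >= 2) divide_cell(tis, id)  # else deferred one step
    }
  }
  invisible(tis)
}

#' Completed cell cycles
#'
#' @param x A `potts_tissue` or [run_simulation()] result.
#' @return Data frame with one row per completed cycle: cell id, birth and
#'   division times, cycle time, area at mitosis, the individual thresholds
#'   and the generation.
#' @export
cycle_statistics <- function(x) {
  tis <- if (inherits(x, "potts_tissue")) x else x$tissue
  if (length(tis$cycles) == 0) {
    return(data.frame(id = integer(0), birth_time = numeric(0),
                      division_time = numeric(0), cycle_time = numeric(0),
                      area_at_mitosis = numeric(0), As_i = numeric(0),
                      tau0_i = numeric(0), generation = integer(0)))
  }
  do.call(rbind, lapply(tis$cycles, as.data.frame))
}

#' G1/S transition records
#'
#' One row per sizer transition, with the cell's area at the moment it left
#' G1 and its individual threshold (the area always exceeds the threshold).
#' @param x A `potts_tissue` or [run_simulation()] result.
#' @return Data frame with columns `t`, `id`, `area`, `As_i`.
#' @export
sizer_transitions <- function(x) {
  tis <- if (inherits(x, "potts_tissue")) x else x$tissue
  if (length(tis$transitions) == 0) {
    return(data.frame(t = numeric(0), id = integer(0), area = numeric(0),
                      As_i = numeric(0)))
  }
  do.call(rbind, lapply(tis$transitions, as.data.frame))
}
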
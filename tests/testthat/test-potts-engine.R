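test_that("total energy matches hand counts on simple fixtures", {
  p <- desk_params()
  tis <- new_tissue(sim_params(As_mean = 100, tau0_mean = 40, box_area = 36,
                               apoptosis_enabled = FALSE), empty = TRUE)
  expect_equal(total_energy(tis), 0)  # all medium: no interfaces, no cells

  # one 2x2 cell, target 4, on a 6x6 lattice: each site has 3 cell
  # neighbours among its 8, so 4 * 5 = 20 cell-medium Moore pairs
  sites <- as.matrix(expand.grid(row = 3:4, col = 3:4))
  pottsgrowth:::add_cell(tis, sites, generation = 0L, parent = NA_integer_)
  p6 <- tis$params
  expect_equal(total_energy(tis), 20 * p6$Jcm, tolerance = 1e-12)

  tis$target[1] <- 2  # elastic term lambda * (4 - 2)^2
  expect_equal(total_energy(tis), 20 * p6$Jcm + p6$lambda * 4, tolerance = 1e-12)

  # agreement with the independent R oracle on a random tissue
  fx <- make_fixture("random_tissue", size = 30, seed = 8)
  expect_equal(total_energy(fx),
               oracle_total_energy(fx$lattice, fx$area, fx$target,
                                   fx$params$Jcc, fx$params$Jcm,
                                   fx$params$lambda),
               tolerance = 1e-9)
})

test_that("local energy difference equals brute-force recomputation", {
  set.seed(99)
  for (size in c(10, 20, 30)) {
    fx <- make_fixture("random_tissue", size = size, seed = size)
    lat <- fx$lattice
    L <- nrow(lat)
    checked <- 0
    while (checked < 60) {
      r <- sample(L, 1); c <- sample(L, 1)
      dr <- sample(-1:1, 1); dc <- sample(-1:1, 1)
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || cc < 1 || rr > L || cc > L) next
      if (lat[rr, cc] == lat[r, c]) next
      de <- delta_energy_copy(fx, c(r, c), c(rr, cc))
      # apply the copy to private copies and recompute from scratch
      lat2 <- lat
      area2 <- fx$area
      old <- lat2[r, c]; new <- lat2[rr, cc]
      lat2[r, c] <- new
      if (old > 0) area2[old] <- area2[old] - 1
      if (new > 0) area2[new] <- area2[new] + 1
      e_before <- oracle_total_energy(lat, fx$area, fx$target, fx$params$Jcc,
                                      fx$params$Jcm, fx$params$lambda)
      e_after <- oracle_total_energy(lat2, area2, fx$target, fx$params$Jcc,
                                     fx$params$Jcm, fx$params$lambda)
      expect_equal(de, e_after - e_before, tolerance = 1e-9)
      checked <- checked + 1
    }
  }
  # equal identities violate the proposal contract
  fx <- make_fixture("single_cell", size = 12)
  expect_error(delta_energy_copy(fx, c(1, 1), c(1, 2)), "change the site")
})

test_that("pure elastic transfer between two cells has the closed-form dE", {
  # two collinear 1x3 cells; the junction site sees one neighbour of each
  # cell, so the interfacial context is identical before and after the
  # copy and only the elastic term remains
  p <- sim_params(As_mean = 100, tau0_mean = 40, box_area = 81,
                  apoptosis_enabled = FALSE)
  tis <- new_tissue(p, empty = TRUE)
  pottsgrowth:::add_cell(tis, cbind(5, 1:3), generation = 0L,
                         parent = NA_integer_, target = 5)
  pottsgrowth:::add_cell(tis, cbind(5, 4:6), generation = 0L,
                         parent = NA_integer_, target = 2)
  de <- delta_energy_copy(tis, c(5, 4), c(5, 3))
  lam <- p$lambda
  elastic <- lam * ((3 - 1 - 2)^2 - (3 - 2)^2 +   # loser: cell 2, target 2
                    (3 + 1 - 5)^2 - (3 - 5)^2)    # gainer: cell 1, target 5
  expect_equal(de, elastic, tolerance = 1e-9)
})

test_that("Metropolis rule accepts downhill always and uphill at exp(-dE/kBT)", {
  expect_true(all(metropolis_accept(rep(0, 100), kBT = 1)))
  expect_true(all(metropolis_accept(rep(-5, 100), kBT = 1)))
  set.seed(12)
  n <- 1e5
  acc <- mean(metropolis_accept(rep(1, n), kBT = 1))
  se <- sqrt(exp(-1) * (1 - exp(-1)) / n)
  expect_lt(abs(acc - exp(-1)), 3 * se)
  expect_error(metropolis_accept(1, kBT = 0), "positive")
})

test_that("local connectivity test matches the spec cases and the exact test", {
  p <- sim_params(As_mean = 100, tau0_mean = 40, box_area = 49,
                  apoptosis_enabled = FALSE)
  tis <- new_tissue(p, empty = TRUE)
  sites <- as.matrix(expand.grid(row = 3:5, col = 3:5))
  pottsgrowth:::add_cell(tis, sites, generation = 0L, parent = NA_integer_)
  expect_true(connectivity_ok(tis, c(4, 4)))   # interior of a solid 3x3

  tis2 <- new_tissue(p, empty = TRUE)
  pottsgrowth:::add_cell(tis2, cbind(4, 3:5), generation = 0L, parent = NA_integer_)
  expect_false(connectivity_ok(tis2, c(4, 4)))  # middle of a 1x3 splits it
  expect_true(connectivity_ok(tis2, c(4, 3)))   # end sites do not
  expect_true(connectivity_ok(tis2, c(4, 5)))

  # the exact test agrees with an R flood-fill oracle on random blobs,
  # and is implied by the local test (local TRUE => exact TRUE)
  set.seed(31)
  for (i in 1:40) {
    blob <- random_blob(25, L = 20)
    lat <- matrix(0L, 20, 20)
    lat[blob] <- 1L
    idx <- sample(nrow(blob), 1)
    r <- blob[idx, 1]; c <- blob[idx, 2]
    keep <- blob[-idx, , drop = FALSE]
    exact <- pottsgrowth:::cpm_connected_after_removal(lat, r - 1L, c - 1L)
    expect_equal(exact, length(unique(oracle_components(keep))) == 1)
    if (pottsgrowth:::cpm_connectivity_ok(lat, r - 1L, c - 1L)) {
      expect_true(exact)
    }
  }
})

test_that("an MCS conserves sites and keeps incremental areas exact", {
  fx <- make_fixture("random_tissue", size = 30, seed = 4)
  set.seed(4)
  for (i in 1:50) {
    run_mcs(fx)
    cen <- pottsgrowth:::cpm_census(fx$lattice, fx$next_id - 1L)
    expect_identical(as.numeric(cen$area), as.numeric(fx$area))
    expect_identical(sum(fx$area) + sum(fx$lattice == 0L), 900)
    if (i %% 10 == 0) {
      expect_true(all(fragment_counts(fx)[fx$area > 0] == 1L))
    }
  }
})

test_that("at vanishing temperature an under-target cell never shrinks", {
  p <- sim_params(As_mean = 100, tau0_mean = 40, box_area = 400,
                  kBT = 1e-9, apoptosis_enabled = FALSE)
  set.seed(5)
  tis <- new_tissue(p)  # area 50, target 50
  tis$target[1] <- 120  # strongly under target: every loss raises E
  prev <- tis$area[1]
  for (i in 1:30) {
    run_mcs(tis)
    expect_gte(tis$area[1], prev)
    prev <- tis$area[1]
  }
  expect_gt(tis$area[1], 100)  # it actually grew towards the target
})

test_that("with fixed targets a single cell's area is stationary near the target", {
  set.seed(6)
  tis <- new_tissue(desk_params(seed = 6))
  tis$target[1] <- 80
  for (i in 1:100) run_mcs(tis)   # relax to the new target
  areas <- numeric(500)
  for (i in 1:500) {
    run_mcs(tis)
    areas[i] <- tis$area[1]
  }
  expect_lt(abs(mean(areas) - 80) / 80, 0.10)
})

test_that("incremental energy bookkeeping equals full recomputation over a run", {
  fx <- make_fixture("random_tissue", size = 24, seed = 14)
  set.seed(14)
  p <- fx$params
  e <- total_energy(fx)
  # advance 25 MCS; recompute from scratch and compare against the running
  # value implied by summing accepted-move energy differences is implicit
  # in the engine; here we check the public invariant: energies recomputed
  # before and after agree with the oracle
  for (i in 1:25) run_mcs(fx)
  expect_equal(total_energy(fx),
               oracle_total_energy(fx$lattice, fx$area, fx$target,
                                   p$Jcc, p$Jcm, p$lambda),
               tolerance = 1e-6)
})
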
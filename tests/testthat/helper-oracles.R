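# Independent brute-force oracles, kept free of the package's C++ paths.

# Total energy of the Potts Hamiltonian computed directly in R: sum over
# unordered Moore site pairs with differing identities (out-of-lattice
# neighbours are medium), plus the elastic term.
oracle_total_energy <- function(lat, area, target, Jcc, Jcm, lambda) {
  L1 <- nrow(lat); L2 <- ncol(lat)
  jval <- function(a, b) {
    ifelse(a == b, 0, ifelse(a == 0 | b == 0, Jcm, Jcc))
  }
  e <- 0
  pad <- matrix(0L, L1 + 2, L2 + 2)
  pad[2:(L1 + 1), 2:(L2 + 1)] <- lat
  core <- pad[2:(L1 + 1), 2:(L2 + 1)]
  # half-plane of Moore directions visits each in-lattice pair once; pairs
  # with the padding ring must be counted from the inside for all 8
  # directions, which the padded sums below do exactly once per pair
  shifts <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (s in shifts) {
    nb <- pad[2:(L1 + 1) + s[1], 2:(L2 + 1) + s[2]]
    e <- e + sum(jval(core, nb))
  }
  for (s in lapply(shifts, function(x) -x)) {
    nb <- pad[2:(L1 + 1) + s[1], 2:(L2 + 1) + s[2]]
    # only wall pairs (neighbour outside the lattice) from this half
    outside <- matrix(TRUE, L1, L2)
    rows <- seq_len(L1) + s[1]; cols <- seq_len(L2) + s[2]
    outside[rows >= 1 & rows <= L1, cols >= 1 & cols <= L2] <- FALSE
    e <- e + sum(jval(core, nb)[outside])
  }
  e + lambda * sum((area - target)^2)
}

# Moore-connected components of a (row, col) site matrix, by flood fill.
oracle_components <- function(sites) {
  n <- nrow(sites)
  if (n == 0) return(integer(0))
  key <- paste(sites[, 1], sites[, 2], sep = ",")
  lookup <- seq_len(n)
  names(lookup) <- key
  comp <- integer(n)
  cur <- 0L
  for (s0 in seq_len(n)) {
    if (comp[s0] != 0L) next
    cur <- cur + 1L
    queue <- s0
    comp[s0] <- cur
    while (length(queue) > 0) {
      i <- queue[1]
      queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        j <- lookup[paste(sites[i, 1] + dr, sites[i, 2] + dc, sep = ",")]
        if (!is.na(j) && comp[j] == 0L) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

# random connected blob of `n` sites grown by biased accretion on an L x L
# lattice (for division tests)
random_blob <- function(n, L = 40) {
  lat <- matrix(FALSE, L, L)
  r <- sample(seq(10, L - 10), 1)
  c <- sample(seq(10, L - 10), 1)
  lat[r, c] <- TRUE
  sites <- matrix(c(r, c), 1, 2)
  while (nrow(sites) < n) {
    i <- sample(nrow(sites), 1)
    dr <- sample(-1:1, 1); dc <- sample(-1:1, 1)
    rr <- sites[i, 1] + dr; cc <- sites[i, 2] + dc
    if (rr >= 2 && cc >= 2 && rr < L && cc < L && !lat[rr, cc]) {
      lat[rr, cc] <- TRUE
      sites <- rbind(sites, c(rr, cc))
    }
  }
  sites
}

desk_params <- function(seed = 1, apoptosis = FALSE, t_max = 400, ...) {
  sim_params(As_mean = 100, tau0_mean = 40, box_area = 100 * 100,
             seed = seed, apoptosis_enabled = apoptosis, t_max = t_max, ...)
}
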
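# Independent reference implementations used as oracles. These deliberately
# avoid the code paths they check: plain double loops, numerical gradients,
# greedy transport.

# random small lipid-free system of beads (no bonded terms)
random_bead_system <- function(n = 18, box = c(8, 8, 8), seed = 1,
                               min_dist = 0.7) {
  set.seed(seed)
  pos <- matrix(NA_real_, n, 3)
  k <- 0
  while (k < n) {
    cand <- runif(3) * box
    ok <- TRUE
    if (k > 0) {
      d <- sweep(pos[seq_len(k), , drop = FALSE], 2, cand)
      d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
      ok <- min(rowSums(d^2)) > min_dist^2
    }
    if (ok) { k <- k + 1; pos[k, ] <- cand }
  }
  types <- sample(1:2, n, replace = TRUE)
  particle_system(pos = pos, types = types, type_labels = c("H", "T"),
                  mol = seq_len(n), masses = rep(253.4, n), box = box)
}

# random gas of a few lipids (bonded terms included)
random_lipid_system <- function(n_lipids = 6, box = c(10, 10, 10), seed = 1) {
  build_random_gas(n_lipids, box, ff_reference(), seed = seed, min_dist = 0.8)
}

# brute-force nonbonded forces/energy: plain double loop over analytic pair
# functions, minimum image by rounding
brute_nonbonded <- function(sys, p) {
  n <- nrow(sys$pos)
  f <- matrix(0, n, 3)
  epot <- 0
  w <- c(0, 0, 0)
  labels <- sys$type_labels[sys$types]
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sys$mol[i] == sys$mol[j]) next
    d <- sys$pos[i, ] - sys$pos[j, ]
    d <- d - sys$box * round(d / sys$box)
    r <- sqrt(sum(d^2))
    if (r >= p$rc) next
    pair <- paste0(sort(c(labels[i], labels[j])), collapse = "")
    pair <- c(HH = "HH", HT = "HT", TT = "TT")[[pair]]
    epot <- epot + pair_potential(r, p, pair)
    fm <- pair_force(r, p, pair)
    fv <- fm * d / r
    f[i, ] <- f[i, ] + fv
    f[j, ] <- f[j, ] - fv
    w <- w + fv * d
  }
  list(forces = f, epot = epot, virial = w)
}

# numerical-gradient forces for any system (includes bonded terms) by
# central differences on the engine's own energy; independent of the
# engine's analytic force path
numgrad_forces <- function(sys, p, h = 1e-6) {
  n <- nrow(sys$pos)
  f <- matrix(0, n, 3)
  for (i in seq_len(n)) for (d in 1:3) {
    sp <- sys; sp$pos[i, d] <- sp$pos[i, d] + h
    sm <- sys; sm$pos[i, d] <- sm$pos[i, d] - h
    ep <- suppressWarnings(compute_forces(sp, p, brute = TRUE)$epot)
    em <- suppressWarnings(compute_forces(sm, p, brute = TRUE)$epot)
    f[i, d] <- -(ep - em) / (2 * h)
  }
  f
}

# greedy two-pointer solution of the 1-D transport problem; independent of
# the CDF formula used by emd()
transport_1d <- function(a, b, x) {
  a <- a / sum(a); b <- b / sum(b)
  cost <- 0
  i <- 1; j <- 1
  a_rem <- a[1]; b_rem <- b[1]
  while (i <= length(a) && j <= length(b)) {
    m <- min(a_rem, b_rem)
    cost <- cost + m * abs(x[i] - x[j])
    a_rem <- a_rem - m; b_rem <- b_rem - m
    if (a_rem <= 1e-15) { i <- i + 1; if (i <= length(a)) a_rem <- a[i] }
    if (b_rem <= 1e-15) { j <- j + 1; if (j <= length(b)) b_rem <- b[j] }
  }
  cost
}

# profile constructor shortcut for tests
test_profile <- function(x, y, normalized = FALSE) {
  trilayer:::profile_1d(x, y, x[2] - x[1], "x", "y", normalized = normalized)
}
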
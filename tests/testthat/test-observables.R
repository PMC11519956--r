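# Property estimators against closed forms, constructed fixtures and
# independent oracles.

test_that("area per lipid is the mean lateral box area per leaflet lipid", {
  fr <- data.frame(Lx = rep(8, 100), Ly = rep(8, 100))
  expect_equal(area_per_lipid(fr, 100)$apl, 0.64)
  # homogeneity: scaling both box sides by c scales the area by c^2
  fr2 <- transform(fr, Lx = 1.3 * Lx, Ly = 1.3 * Ly)
  expect_equal(area_per_lipid(fr2, 100)$apl, 0.64 * 1.69, tolerance = 1e-12)
  expect_error(area_per_lipid(fr[0, ], 100), "empty")
})

test_that("area compressibility matches its closed form on Gaussian series", {
  # closed form: kB T / (4 sd^2) at T = 315 K, sd = 0.1 nm -> 108.7 mN/m
  kbt_j <- 1.380649e-23 * 315
  closed <- kbt_j / (4 * 0.01 * 1e-18) * 1e3
  expect_equal(closed, 108.7, tolerance = 1e-3)
  fr <- synth_gaussian_box_series(n = 1e6, mean = 8, sd = 0.1, seed = 2)
  est <- area_compressibility(fr, 315)
  expect_equal(est$ka, closed, tolerance = 0.01)
  # error shrinks roughly as 1/sqrt(n)
  errs <- vapply(c(1e3, 1e4, 1e5, 1e6), function(n) {
    f <- synth_gaussian_box_series(n = n, sd = 0.1, seed = 7)
    abs(area_compressibility(f, 315)$ka - closed) / closed
  }, 0)
  expect_lt(errs[4], errs[1])
  expect_error(area_compressibility(data.frame(Lx = rep(5, 10))), "diverges")
})

test_that("line tension arithmetic and unit conversion are exact", {
  fr <- synth_pressure_series(n = 100, P = c(0, -10, 0), noise = 0,
                              Lx = 10, Lz = 10)
  # -(Lx Lz / 2)(Pyy - (Pxx+Pzz)/2) = 500 bar nm^2 = 50 pN
  expect_equal(line_tension(fr)$lt, 50, tolerance = 1e-12)
  iso <- synth_pressure_series(n = 100, P = c(5, 5, 5), noise = 0)
  expect_equal(line_tension(iso)$lt, 0, tolerance = 1e-12)
  expect_error(line_tension(fr, geometry = "bilayer"), "ribbon")
})

test_that("height field maps beads to cells and is translation invariant", {
  # flat sheet of beads
  set.seed(1)
  n <- 4000
  pos <- cbind(runif(n, 0, 20), runif(n, 0, 20), 5)
  u <- height_field(pos, box = c(20, 20, 10), N = 16)
  expect_lt(max(abs(u)), 1e-12)
  # rigid z translation leaves the mean-subtracted field unchanged
  pos2 <- pos; pos2[, 3] <- pos2[, 3] + 2.3
  expect_equal(height_field(pos2, c(20, 20, 10), N = 16),
               height_field(pos, c(20, 20, 10), N = 16))
  # a single cosine mode sampled by beads is recovered
  L <- 20
  pos3 <- pos
  pos3[, 3] <- 5 + 0.8 * cos(2 * pi * pos[, 1] / L)
  u3 <- height_field(pos3, c(L, L, 10), N = 16)
  xc <- (seq_len(16) - 0.5) * L / 16
  target <- outer(0.8 * cos(2 * pi * xc / L), rep(1, 16))
  expect_lt(sqrt(mean((u3 - target)^2)) / 0.8, 0.05)
  # over-fine grids are refused
  expect_error(height_field(pos[1:40, ], c(20, 20, 10), N = 32), "empty")
})

test_that("undulation spectrum concentrates a cosine mode at its wave number", {
  N <- 32; L <- 32
  xc <- (seq_len(N) - 0.5) * L / N
  a <- 0.7
  u <- outer(a * cos(2 * pi * xc / L), rep(1, N))
  spec <- suppressWarnings(undulation_spectrum(list(u), L))
  # weight a^2/4 in the k = 1 bin (two conjugate modes averaged in the bin)
  i1 <- which.min(abs(spec$q - 2 * pi / L))
  expect_equal(spec$S[i1] * spec$n_modes[i1], 2 * a^2 / 4, tolerance = 1e-10)
  expect_lt(sum(spec$S[-i1] * spec$n_modes[-i1]), 1e-20)
  # zero field -> zero spectrum
  z <- suppressWarnings(undulation_spectrum(list(matrix(0, N, N)), L))
  expect_true(all(z$S == 0))
  # white noise -> flat spectrum
  set.seed(3)
  wn <- lapply(1:200, function(i) matrix(rnorm(N * N), N, N))
  ws <- undulation_spectrum(wn, L)
  expect_lt(diff(range(ws$S)) / mean(ws$S), 0.4)
  expect_lt(sd(ws$S) / mean(ws$S), 0.1)
})

test_that("bending modulus inverts the q^-4 law exactly on exact input", {
  # construct a spectrum object that follows the law with kc = 12
  q <- 2 * pi * (1:10) / 40
  spec <- structure(list(q = q, S = 1 / (40^2 * 12 * q^4),
                         n_modes = rep(8, 10), L = 40, N = 64, n_frames = 1),
                    class = "undulation_spectrum")
  expect_equal(fit_bending_modulus(spec, q_max = 2)$kc, 12, tolerance = 1e-10)
  spec$q <- spec$q[1:2]; spec$S <- spec$S[1:2]; spec$n_modes <- spec$n_modes[1:2]
  expect_error(fit_bending_modulus(spec), "bins")
})

test_that("bending modulus pipeline recovers programmed rigidities", {
  for (kc in c(8, 20)) {
    fields <- synth_helfrich_surfaces(kc, L = 40, N = 64, n_frames = 200,
                                      seed = kc)
    spec <- undulation_spectrum(fields, 40)
    fit <- fit_bending_modulus(spec)
    expect_equal(fit$kc, kc, tolerance = 0.15)
  }
})

test_that("transition detection reproduces the two-phase jump logic", {
  temps <- seq(100, 400, by = 20)
  series <- synth_step_enthalpy(temps, T_transition = 250, gap = 100,
                                noise = 1, n = 400, seed = 4)
  res <- detect_transition(temps, series)
  expect_true(res$significant)
  expect_equal(res$zone, c(240, 260))
  expect_equal(res$ptt, 250)
  # featureless series: no transition, not an error
  flat <- synth_step_enthalpy(temps, T_transition = 250, gap = 0,
                              noise = 1, n = 400, seed = 5)
  res2 <- detect_transition(temps, flat)
  expect_false(res2$significant)
  expect_true(is.na(res2$ptt))
  # affine rescaling of the enthalpy does not move the jump
  scaled <- lapply(series, function(s) 3.7 * s + 100)
  expect_equal(detect_transition(temps, scaled)$ptt, 250)
})

test_that("lateral RDF is flat for an ideal 2-D gas and peaks on a lattice", {
  set.seed(6)
  box <- c(20, 20, 10)
  frames <- lapply(1:30, function(i)
    cbind(runif(300, 0, 20), runif(300, 0, 20), 5))
  g <- lateral_rdf(frames, rep(2L, 300), box, dr = 0.25)
  sel <- g$x > 1 & g$x < 8
  expect_equal(mean(g$y[sel]), 1, tolerance = 0.05)
  expect_true(all(abs(g$y[sel] - 1) < 0.3))
  # square lattice: first peak bin contains the lattice constant
  a <- 1.0
  gr <- expand.grid(x = (0:19) * a, y = (0:19) * a)
  lat <- list(cbind(gr$x, gr$y, 5))
  gl <- lateral_rdf(lat, rep(2L, 400), box, dr = 0.05)
  first_peak <- gl$x[which(gl$y > 0)[1]]
  expect_lt(abs(first_peak - a), 0.05)
  expect_error(lateral_rdf(frames, rep(1L, 300), box), "selection")
})

test_that("density profile is COM-centered and conserves selected mass", {
  set.seed(7)
  n <- 600
  box <- c(10, 10, 12)
  # two head layers around a tail slab
  types <- rep(c(1L, 2L, 2L), n / 3)
  z <- ifelse(types == 1L, sample(c(-1.5, 1.5), n, replace = TRUE),
              runif(n, -0.8, 0.8))
  mk <- function(shift) cbind(runif(n, 0, 10), runif(n, 0, 10), z + 6 + shift)
  masses <- rep(253.4, n)
  prof <- density_profile(list(mk(0)), types, masses, box)
  # rigid translation changes nothing
  prof2 <- density_profile(list(mk(1.7)), types, masses, box)
  expect_equal(prof$y, prof2$y, tolerance = 1e-12)
  # bimodal and symmetric about the COM
  peaks <- prof$x[prof$y > 0.5 * max(prof$y)]
  expect_true(any(peaks < 0) && any(peaks > 0))
  # integral over bins recovers selected mass per area
  n_heads <- sum(types == 1L)
  expect_equal(sum(prof$y) * prof$width, n_heads * 253.4 / 100,
               tolerance = 1e-9)
})

test_that("EMD equals the transport oracle and satisfies metric axioms", {
  set.seed(8)
  for (rep in 1:12) {
    nb <- sample(4:16, 1)
    x <- seq(0, by = 1, length.out = nb)
    a <- runif(nb); b <- runif(nb)
    pa <- test_profile(x, a / sum(a), normalized = TRUE)
    pb <- test_profile(x, b / sum(b), normalized = TRUE)
    expect_equal(emd(pa, pb), transport_1d(a, b, x), tolerance = 1e-10)
    # symmetry and identity
    expect_equal(emd(pa, pb), emd(pb, pa), tolerance = 1e-12)
    expect_equal(emd(pa, pa), 0)
    # triangle inequality
    cvec <- runif(nb)
    pc <- test_profile(x, cvec / sum(cvec), normalized = TRUE)
    expect_lte(emd(pa, pb), emd(pa, pc) + emd(pc, pb) + 1e-9)
  }
  # unit point masses one bin apart -> exactly the bin width
  pa <- test_profile(0:1, c(1, 0), normalized = TRUE)
  pb <- test_profile(0:1, c(0, 1), normalized = TRUE)
  expect_equal(emd(pa, pb), 1.0)
  expect_error(emd(pa, test_profile(0:2, c(1, 0, 0))), "grids")
})

test_that("estimators are invariant under relabeling of lipid indices", {
  set.seed(9)
  box <- c(12, 12, 10)
  frames <- lapply(1:5, function(i) cbind(runif(90, 0, 12), runif(90, 0, 12),
                                          rnorm(90, 5, 0.5)))
  types <- rep(c(1L, 2L, 2L), 30)
  perm <- sample(90)
  g1 <- lateral_rdf(frames, types, box)
  g2 <- lateral_rdf(lapply(frames, function(f) f[perm, ]), types[perm], box)
  expect_equal(g1$y, g2$y, tolerance = 1e-12)
})
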
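# Model energetics: bonded terms, 6/0.5 nonbonded forms, force shift,
# tabulated potentials.

p_ref <- ff_reference()

test_that("bonded energy is harmonic around the fixed equilibrium geometry", {
  expect_equal(bonded_energy(1.0, 30 * pi / 180, p_ref), 0)
  # direct arithmetic: 0.5 * 1997 * 0.1^2
  expect_equal(bonded_energy(1.1, 30 * pi / 180, p_ref), 0.5 * 1997 * 0.01,
               tolerance = 1e-12)
  # 0.5 * 264 * (10 deg in rad)^2
  expect_equal(bonded_energy(1.0, 40 * pi / 180, p_ref),
               0.5 * 264 * (10 * pi / 180)^2, tolerance = 1e-12)
  expect_error(bonded_energy(-0.1, 0.5, p_ref), "positive")
})

test_that("unshifted tail-tail potential has depth exactly -epsilon at r_min", {
  expect_equal(tt_potential(p_ref$r_min, p_ref), -p_ref$epsilon,
               tolerance = 1e-12)
  # unique minimum: derivative changes sign only at r_min
  r <- seq(0.5, 3, by = 1e-3)
  v <- tt_potential(r, p_ref)
  expect_equal(r[which.min(v)], p_ref$r_min, tolerance = 2e-3)
  # independent arithmetic evaluation at r = 1.3 nm
  eps <- kbt_to_kjmol(5.788, 315)
  expect_equal(tt_potential(1.3, p_ref),
               (eps / 5.5) * (0.5 * (1.095 / 1.3)^6 - 6 * (1.095 / 1.3)^0.5),
               tolerance = 1e-12)
  expect_lt(tt_potential(1.3, p_ref), -14.6)
  # r -> infinity limit: approaches 0 from below (slow sqrt decay)
  big <- tt_potential(c(1e2, 1e4, 1e6), p_ref)
  expect_true(all(big < 0))
  expect_true(all(diff(big) > 0))
  expect_gt(big[3], -0.02)
  expect_error(tt_potential(0, p_ref), "positive")
})

test_that("head repulsion is the 0.4-scaled sixth-power term, HH = HT", {
  expect_equal(repulsive_potential(p_ref$r_min, p_ref),
               0.2 * p_ref$epsilon / 5.5, tolerance = 1e-12)
  # sixth-power scaling: doubling r divides by 64
  expect_equal(repulsive_potential(2 * p_ref$r_min, p_ref),
               repulsive_potential(p_ref$r_min, p_ref) / 64,
               tolerance = 1e-12)
  r <- seq(0.3, 3, by = 0.05)
  expect_true(all(repulsive_potential(r, p_ref) > 0))
  expect_true(all(diff(repulsive_potential(r, p_ref)) < 0))
  # same functional form for both repulsive pair classes
  expect_equal(pair_potential(r, p_ref, "HH"), pair_potential(r, p_ref, "HT"))
})

test_that("shift coefficients match their closed form and force the cutoff zero", {
  AB <- shift_coefficients(6, 1.729, 2.5)
  expect_equal(unname(AB["A"]), -1.422e-2, tolerance = 1e-3)
  expect_equal(unname(AB["B"]), 1.487e-2, tolerance = 1e-3)
  # for any alpha the polynomial cancels the power-law force at rc
  for (alpha in c(0.5, 6, 12)) {
    AB <- shift_coefficients(alpha, 1.729, 2.5)
    d <- 2.5 - 1.729
    expect_equal(1 / 2.5^(alpha + 1) + AB[["A"]] * d^2 + AB[["B"]] * d^3, 0,
                 tolerance = 1e-14)
  }
  expect_error(shift_coefficients(6, 2.5, 2.5), "geometry")
  # r1 -> rc: coefficients diverge
  expect_gt(abs(shift_coefficients(6, 2.499999, 2.5)["A"]), 1e8)
})

test_that("shifted force is continuous at r1 and exactly zero beyond rc", {
  for (pair in c("TT", "HH", "HT")) {
    expect_equal(pair_force(p_ref$rc, p_ref, pair), 0, tolerance = 1e-14)
    expect_equal(pair_potential(p_ref$rc, p_ref, pair), 0, tolerance = 1e-14)
    below <- pair_force(p_ref$r1 - 1e-9, p_ref, pair)
    above <- pair_force(p_ref$r1 + 1e-9, p_ref, pair)
    expect_equal(below, above, tolerance = 1e-6)
  }
})

test_that("shifted potential integrates the shifted force", {
  h <- 1e-6
  for (pair in c("TT", "HH")) {
    r <- seq(0.5, p_ref$rc - 0.01, by = 0.013)
    fd <- -(pair_potential(r + h, p_ref, pair) -
            pair_potential(r - h, p_ref, pair)) / (2 * h)
    f <- pair_force(r, p_ref, pair)
    expect_equal(fd, f, tolerance = 1e-5)
  }
  # below r1 the shift is a pure constant offset
  r <- c(0.8, 1.0, 1.3, 1.6)
  dV_shifted <- diff(pair_potential(r, p_ref, "TT"))
  dV_raw <- diff(tt_potential(r, p_ref))
  expect_equal(dV_shifted, dV_raw, tolerance = 1e-12)
})

test_that("shifted force matches a term-by-term independent assembly", {
  # assemble the shifted TT force from scratch: per power-law term with its
  # own alpha, polynomial correction between r1 and rc
  eps <- p_ref$epsilon; rmin <- p_ref$r_min; r1 <- p_ref$r1; rc <- p_ref$rc
  terms <- list(list(c = (eps / 5.5) * 0.5 * rmin^6, a = 6),
                list(c = -(eps / 5.5) * 6 * rmin^0.5, a = 0.5))
  oracle <- function(r) {
    out <- 0
    for (t in terms) {
      d <- rc - r1
      A <- -((t$a + 4) * rc - (t$a + 1) * r1) / (rc^(t$a + 2) * d^2)
      B <- ((t$a + 3) * rc - (t$a + 1) * r1) / (rc^(t$a + 2) * d^3)
      if (r < r1) out <- out + t$a * t$c / r^(t$a + 1)
      else if (r < rc) out <- out + t$a * t$c *
          (1 / r^(t$a + 1) + A * (r - r1)^2 + B * (r - r1)^3)
    }
    out
  }
  for (r in seq(0.6, 2.6, by = 0.08))
    expect_equal(pair_force(r, p_ref, "TT"), oracle(r), tolerance = 1e-12)
})

test_that("tabulated potentials reproduce the analytic forms on their grid", {
  tb <- make_tables(p_ref, dr = 0.002)
  expect_named(tb, c("TT", "HH", "HT", "bond", "angle"))
  rec <- table_potential(tb, p_ref, "TT")
  i <- which.min(abs(rec$r - p_ref$r_min))
  expect_equal(rec$V[i], pair_potential(rec$r[i], p_ref, "TT"),
               tolerance = 1e-8)
  # force column zero at the cutoff
  j <- which.min(abs(rec$r - p_ref$rc))
  expect_equal(rec$f[j], 0, tolerance = 1e-12)
  # finite-difference of the V column matches the force column
  sel <- rec$r >= 0.5 & rec$r <= p_ref$rc - 0.004
  k <- which(sel)
  fd <- -(rec$V[k + 1] - rec$V[k - 1]) / (2 * 0.002)
  expect_equal(fd, rec$f[k], tolerance = 2e-4)
  expect_error(make_tables(p_ref, dr = 0.01), "dr")
  expect_error(make_tables(p_ref, r_max = 1), "cutoff")
})

test_that("table files round-trip through the 7-column dialect", {
  dir <- withr::local_tempdir()
  tb <- make_tables(p_ref)
  paths <- write_tables(tb, dir)
  expect_length(paths, 5)
  expect_true(file.exists(file.path(dir, "table_T_T.xvg")))
  back <- read_table_xvg(file.path(dir, "table_T_T.xvg"))
  expect_equal(back$g, tb$TT$g, tolerance = 1e-7)
  expect_equal(back$hp, tb$TT$hp, tolerance = 1e-7)
})

test_that("parameter sets survive the config round trip and validate", {
  path <- withr::local_tempfile()
  write_forcefield_config(p_ref, path)
  back <- read_forcefield_config(path)
  expect_equal(back$epsilon, p_ref$epsilon, tolerance = 1e-9)
  expect_equal(back$k_angle, p_ref$k_angle)
  expect_error(forcefield_params(10, 1.5, 1.2, 2.5, 100, 100), "geometry")
  expect_error(forcefield_params(-1, 1.0, 1.5, 2.5, 100, 100))
})

test_that("energy is invariant under exchange of the two tail beads", {
  sys <- build_bilayer(16, p_ref)
  e1 <- suppressWarnings(compute_forces(sys, p_ref)$epot)
  swapped <- sys
  for (m in unique(sys$mol)) {
    idx <- which(sys$mol == m)
    swapped$pos[idx[2], ] <- sys$pos[idx[3], ]
    swapped$pos[idx[3], ] <- sys$pos[idx[2], ]
  }
  e2 <- suppressWarnings(compute_forces(swapped, p_ref)$epot)
  expect_equal(e1, e2, tolerance = 1e-12)
})
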
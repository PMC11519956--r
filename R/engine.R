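# Langevin-dynamics engine wrappers and system builders for all the
# simulation geometries used in parametrization: tensionless bilayer patch,
# bilayer ribbon with free edges, two-phase (gel|fluid) patch and a random
# lipid gas for self-assembly runs.

#' Construct a particle system
#'
#' @param pos N x 3 positions, nm
#' @param vel N x 3 velocities, nm/ps (default zero)
#' @param types integer type index per bead (1-based into \code{type_labels})
#' @param type_labels character labels, e.g. \code{c("H", "T")}
#' @param mol molecule id per bead (1-based, contiguous)
#' @param masses per-bead masses, amu
#' @param box orthorhombic box lengths \code{c(Lx, Ly, Lz)}, nm
#' @param bonds matrix with columns (i, j, r0, k) or NULL
#' @param angles matrix with columns (i, j, k, theta0, k_angle) or NULL
#' @param exclusions two-column matrix of bead index pairs whose nonbonded
#'   interaction is skipped; defaults to the directly bonded (1-2) pairs.
#'   The lipid builders pass all intramolecular pairs explicitly, so a
#'   lipid's internal geometry is governed by its bonds and angle alone.
#' @param geometry free-form tag ("bilayer", "ribbon", "two_phase", "gas")
#' @param n_leaflet lipids per leaflet, when meaningful
#' @return object of class \code{particle_system}
#' @export
particle_system <- function(pos, vel = NULL, types, type_labels, mol, masses,
                            box, bonds = NULL, angles = NULL,
                            exclusions = NULL,
                            geometry = "generic", n_leaflet = NA_integer_) {
  pos <- as.matrix(pos)
  dimnames(pos) <- NULL
  n <- nrow(pos)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  stopifnot(length(types) == n, length(mol) == n, length(masses) == n,
            length(box) == 3, all(box > 0))
  if (is.null(bonds)) bonds <- matrix(0, 0, 4)
  if (is.null(angles)) angles <- matrix(0, 0, 5)
  if (is.null(exclusions))
    exclusions <- if (nrow(bonds) > 0) bonds[, 1:2, drop = FALSE]
                  else matrix(0, 0, 2)
  structure(list(pos = pos, vel = as.matrix(vel), types = as.integer(types),
                 type_labels = type_labels, mol = as.integer(mol),
                 masses = as.numeric(masses), box = as.numeric(box),
                 bonds = as.matrix(bonds), angles = as.matrix(angles),
                 exclusions = as.matrix(exclusions),
                 geometry = geometry, n_leaflet = n_leaflet),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("particle_system: %d beads, %d molecules, geometry '%s'\n",
              nrow(x$pos), length(unique(x$mol)), x$geometry))
  cat(sprintf("  box: %.3f x %.3f x %.3f nm\n", x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

# pair-class definitions for the membrane force field, in the term form the
# engine consumes: list of (t1, t2, r1, rc, terms(c, alpha))
membrane_pairdefs <- function(p) {
  tt <- .pair_terms(p, "TT")
  rep6 <- .pair_terms(p, "HH")
  dia <- .ff_dialect(p)
  list(
    list(t1 = 1L, t2 = 1L, r1 = p$r1, rc = p$rc, terms = rep6, dialect = dia),
    list(t1 = 1L, t2 = 2L, r1 = p$r1, rc = p$rc, terms = rep6, dialect = dia),
    list(t1 = 2L, t2 = 2L, r1 = p$r1, rc = p$rc, terms = tt, dialect = dia)
  )
}

# resolve pair definitions: membrane defaults unless the system carries
# custom ones (mixed-resolution setups attach $pairdefs themselves)
.sys_pairdefs <- function(sys, p) {
  if (!is.null(sys$pairdefs)) sys$pairdefs else membrane_pairdefs(p)
}

# exclusion matrix of a system (older objects may predate the field)
.sys_excl <- function(sys) {
  if (!is.null(sys$exclusions)) sys$exclusions else matrix(0, 0, 2)
}

#' Simulation configuration
#'
#' @param dt time step, ps
#' @param temperature target temperature, K
#' @param gamma Langevin friction, 1/ps (0 gives NVE velocity-Verlet)
#' @param n_steps number of integration steps
#' @param barostat \code{"off"}, \code{"semi-isotropic-xy"} (Berendsen
#'   lateral coupling at zero surface tension; Lz fixed) or \code{"mc-area"}
#'   (Monte Carlo lateral-area moves; canonical area fluctuations, required
#'   for the fluctuation-based compressibility estimator)
#' @param P_ref reference pressure, bar
#' @param kappa_xy lateral compressibility, 1/bar (Berendsen only)
#' @param tau_p pressure-coupling relaxation time, ps (Berendsen only)
#' @param mc_interval steps between Monte Carlo area moves
#' @param mc_delta half-width of the uniform log-area proposal
#' @param seed integer seed; fully determines the noise stream
#' @param report_interval steps between frame records
#' @param snapshot_interval steps between stored position snapshots (0 = none)
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(dt = 0.15, temperature = 315, gamma = 1.0,
                       n_steps = 10000,
                       barostat = c("off", "semi-isotropic-xy", "mc-area"),
                       P_ref = 1, kappa_xy = 1e-5, tau_p = 1,
                       mc_interval = 10, mc_delta = 0.002, seed = 1,
                       report_interval = 50, snapshot_interval = 0) {
  barostat <- match.arg(barostat)
  stopifnot(dt > 0, n_steps >= 1, gamma >= 0, mc_interval >= 1, mc_delta > 0)
  structure(list(dt = dt, temperature = temperature, gamma = gamma,
                 n_steps = as.integer(n_steps), barostat = barostat,
                 P_ref = P_ref, kappa_xy = kappa_xy, tau_p = tau_p,
                 mc_interval = as.integer(mc_interval), mc_delta = mc_delta,
                 seed = as.integer(seed),
                 report_interval = as.integer(report_interval),
                 snapshot_interval = as.integer(snapshot_interval)),
            class = "sim_config")
}

#' Compute forces, potential energy and virial
#'
#' @param sys \code{particle_system}
#' @param p \code{ff_params}
#' @param brute if TRUE, bypass the neighbor list and evaluate every pair
#' @return list with \code{forces} (N x 3, kJ/mol/nm), \code{epot} (kJ/mol)
#'   and \code{virial} (per-axis sum of r_ij f_ij, kJ/mol)
#' @export
compute_forces <- function(sys, p, brute = FALSE) {
  if (any(sys$box[1:2] < 2 * p$rc))
    warning("box dimension below twice the cutoff; minimum image unsafe")
  tl_compute_forces(sys$pos, sys$types, sys$mol, sys$masses,
                    length(sys$type_labels), .sys_pairdefs(sys, p),
                    sys$bonds, sys$angles, .sys_excl(sys), sys$box, brute)
}

#' Diagonal pressure tensor from kinetic and virial contributions
#'
#' \code{P_aa = (2 KE_a + W_a) / V}, converted to bar.
#'
#' @param ke_axis per-axis kinetic energy (kJ/mol), length 3
#' @param virial per-axis virial sum (kJ/mol), length 3
#' @param box box lengths, nm
#' @return named vector \code{c(Pxx, Pyy, Pzz)} in bar
#' @export
pressure_tensor <- function(ke_axis, virial, box) {
  vol <- prod(box)
  if (vol <= 0) stop("zero or negative box volume")
  setNames((2 * ke_axis + virial) / vol * .press_unit, c("Pxx", "Pyy", "Pzz"))
}

#' Steepest-descent energy minimization
#'
#' Backtracking steepest descent; the energy is non-increasing over accepted
#' steps and iteration stops when the maximum force component drops below
#' \code{f_tol} or after \code{max_steps}.
#'
#' @param sys \code{particle_system}
#' @param p \code{ff_params}
#' @param max_steps iteration cap
#' @param f_tol force tolerance, kJ/mol/nm
#' @param h0 initial step, nm
#' @return the minimized \code{particle_system} with attributes
#'   \code{epot}, \code{iterations}, \code{fmax}
#' @export
minimize <- function(sys, p, max_steps = 1000, f_tol = 10, h0 = 0.01) {
  out <- tl_minimize(sys$pos, sys$types, sys$mol, sys$masses,
                     length(sys$type_labels), .sys_pairdefs(sys, p),
                     sys$bonds, sys$angles, .sys_excl(sys), sys$box,
                     max_steps, f_tol, h0)
  sys$pos <- out$pos
  attr(sys, "epot") <- out$epot
  attr(sys, "iterations") <- out$iterations
  attr(sys, "fmax") <- out$fmax
  sys
}

#' Run Langevin dynamics
#'
#' Symmetric-splitting integrator (velocity-Verlet drift/kick with an exact
#' Ornstein-Uhlenbeck velocity update); reduces to velocity-Verlet NVE at
#' \code{gamma = 0} with the barostat off. Bit-reproducible for a fixed seed.
#'
#' @param sys \code{particle_system} (velocities initialized if all zero)
#' @param p \code{ff_params}
#' @param cfg \code{sim_config}
#' @return list with \code{frames} (data.frame: step, time, Lx, Ly, Lz,
#'   epot, ekin, Pxx, Pyy, Pzz), \code{snapshots} (list of N x 3 matrices),
#'   and \code{system} (final state)
#' @export
run_ld <- function(sys, p, cfg) {
  if (all(sys$vel == 0) && cfg$temperature > 0)
    sys$vel <- tl_maxwell(sys$masses, cfg$temperature, cfg$seed + 7919L)
  out <- tl_run_ld(sys$pos, sys$vel, sys$types, sys$mol, sys$masses,
                   length(sys$type_labels), .sys_pairdefs(sys, p),
                   sys$bonds, sys$angles, .sys_excl(sys), sys$box,
                   cfg$dt, cfg$temperature, cfg$gamma, cfg$n_steps,
                   cfg$report_interval, cfg$snapshot_interval, cfg$seed,
                   match(cfg$barostat, c("off", "semi-isotropic-xy",
                                         "mc-area")) - 1L,
                   cfg$P_ref, cfg$kappa_xy, cfg$tau_p,
                   cfg$mc_interval %||% 10L, cfg$mc_delta %||% 0.002)
  frames <- as.data.frame(out$frames)
  names(frames) <- c("step", "time", "Lx", "Ly", "Lz", "epot", "ekin",
                     "Pxx", "Pyy", "Pzz")
  sys$pos <- out$pos
  sys$vel <- out$vel
  sys$box <- as.numeric(out$box)
  list(frames = frames, snapshots = out$snapshots, system = sys)
}

#' Instantaneous kinetic temperature of a frame series
#' @param frames frames data.frame from \code{run_ld}
#' @param n number of beads
#' @return temperature series, K
#' @export
kinetic_temperature <- function(frames, n) {
  2 * frames$ekin / (3 * n * kB)
}

# lipid bead template: head at origin, tails pointing along -z with the
# equilibrium 30-degree splay; `phase` rotates the splay plane
.lipid_beads <- function(head, down = TRUE, phase = 0) {
  top <- lipid_topology()
  half <- top$theta0 / 2
  sgn <- if (down) -1 else 1
  dx <- sin(half) * top$r0
  dz <- cos(half) * top$r0
  off1 <- c(cos(phase) * dx, sin(phase) * dx, sgn * dz)
  off2 <- c(-cos(phase) * dx, -sin(phase) * dx, sgn * dz)
  rbind(head, head + off1, head + off2)
}

# assemble a particle_system from per-lipid bead matrices
.assemble_lipids <- function(bead_list, box, p, geometry, n_leaflet = NA) {
  top <- lipid_topology()
  nlip <- length(bead_list)
  pos <- do.call(rbind, bead_list)
  n <- nrow(pos)
  types <- rep(c(1L, 2L, 2L), nlip)
  mol <- rep(seq_len(nlip), each = 3)
  bonds <- do.call(rbind, lapply(seq_len(nlip), function(i) {
    b <- (i - 1) * 3
    rbind(c(b + 1, b + 2, top$r0, p$k_bond),
          c(b + 1, b + 3, top$r0, p$k_bond))
  }))
  angles <- do.call(rbind, lapply(seq_len(nlip), function(i) {
    b <- (i - 1) * 3
    c(b + 2, b + 1, b + 3, top$theta0, p$k_angle)
  }))
  # all intramolecular pairs excluded from nonbonded interactions: the
  # harmonic bonds and the angle term alone govern the internal geometry
  excl <- do.call(rbind, lapply(seq_len(nlip), function(i) {
    b <- (i - 1) * 3
    rbind(c(b + 1, b + 2), c(b + 1, b + 3), c(b + 2, b + 3))
  }))
  particle_system(pos = pos, types = types, type_labels = c("H", "T"),
                  mol = mol, masses = rep(top$bead_mass, n), box = box,
                  bonds = bonds, angles = angles, exclusions = excl,
                  geometry = geometry, n_leaflet = n_leaflet)
}

# near-square lattice layout for n sites: an exact nx x ny grid when a
# divisor pair of aspect ratio <= 2 exists, otherwise the nearest rectangle
# with a partially filled last row (logged)
.lattice_sites <- function(n) {
  nx <- floor(sqrt(n))
  while (nx > 1 && n %% nx != 0) nx <- nx - 1
  if (nx >= 1 && n / nx / nx <= 2) {
    ny <- n / nx
  } else {
    nx <- round(sqrt(n))
    ny <- ceiling(n / nx)
    message("lattice: ", n, " lipids placed on a ", nx, " x ", ny,
            " grid with a partial last row")
  }
  k <- seq_len(n) - 1
  list(ix = k %% nx + 1, iy = k %/% nx + 1, nx = nx, ny = ny)
}

#' Build a flat bilayer patch on a square lattice
#'
#' Two apposed leaflets, heads outward, lateral box sized so the starting
#' area per lipid is \code{apl0}.
#'
#' @param n_per_leaflet lipids per leaflet
#' @param p \code{ff_params}
#' @param apl0 starting area per lipid, nm^2
#' @param Lz box height, nm
#' @param jitter small random lateral displacement, nm (0 for a perfect lattice)
#' @param seed seed for the jitter
#' @return \code{particle_system} with geometry "bilayer"
#' @export
build_bilayer <- function(n_per_leaflet, p = ff_reference(), apl0 = 0.68,
                          Lz = 10, jitter = 0, seed = 1) {
  lay <- .lattice_sites(n_per_leaflet)
  a <- sqrt(apl0 * n_per_leaflet / (lay$nx * lay$ny))
  Lx <- lay$nx * a
  Ly <- lay$ny * a
  # head height: tail ends meet near r_min across the midplane
  zh <- cos(lipid_topology()$theta0 / 2) * lipid_topology()$r0 + p$r_min / 2
  if (jitter > 0) set.seed(seed)
  beads <- list()
  k <- 0
  for (leaf in c(1, -1)) {
    for (i in seq_len(n_per_leaflet)) {
      k <- k + 1
      ix <- lay$ix[i]; iy <- lay$iy[i]
      head <- c((ix - 0.5) * a, (iy - 0.5) * a, Lz / 2 + leaf * zh)
      if (jitter > 0) head[1:2] <- head[1:2] + runif(2, -jitter, jitter)
      beads[[k]] <- .lipid_beads(head, down = leaf > 0, phase = (ix + iy) * pi / 2)
    }
  }
  .assemble_lipids(beads, c(Lx, Ly, Lz), p, "bilayer", n_per_leaflet)
}

#' Build a bilayer ribbon with two free edges
#'
#' Periodic in y, vacuum margins along x beyond both edges; box fixed (use
#' with the barostat off). Used for the line-tension estimator.
#'
#' @param n_lipids total number of lipids (both leaflets)
#' @param p \code{ff_params}
#' @param apl0 starting area per lipid, nm^2
#' @param margin vacuum margin beyond each edge, nm (at least \code{2 rc})
#' @param Lz box height, nm
#' @return \code{particle_system} with geometry "ribbon"
#' @export
build_ribbon <- function(n_lipids, p = ff_reference(), apl0 = 0.68,
                         margin = 2 * p$rc, Lz = 10) {
  n_per_leaflet <- n_lipids %/% 2
  lay <- .lattice_sites(n_per_leaflet)
  a <- sqrt(apl0)
  Lx <- lay$nx * a + 2 * margin
  Ly <- lay$ny * a
  zh <- cos(lipid_topology()$theta0 / 2) * lipid_topology()$r0 + p$r_min / 2
  beads <- list()
  k <- 0
  for (leaf in c(1, -1)) {
    for (i in seq_len(n_per_leaflet)) {
      k <- k + 1
      ix <- lay$ix[i]; iy <- lay$iy[i]
      head <- c(margin + (ix - 0.5) * a, (iy - 0.5) * a, Lz / 2 + leaf * zh)
      beads[[k]] <- .lipid_beads(head, down = leaf > 0, phase = (ix + iy) * pi / 2)
    }
  }
  .assemble_lipids(beads, c(Lx, Ly, Lz), p, "ribbon", n_per_leaflet)
}

#' Build a two-phase (gel | fluid) bilayer for transition detection
#'
#' The left half of the patch is pre-ordered by quenching a copy of the
#' lattice at a low temperature, the right half is pre-melted at a fluid
#' temperature; the halves are joined in one periodic box. Starting from
#' coexisting phases suppresses the nucleation barrier (and with it the
#' hysteresis) when scanning temperature.
#'
#' @param n_per_leaflet lipids per leaflet (split evenly between halves)
#' @param p \code{ff_params}
#' @param T_gel quench temperature for the gel half, K
#' @param T_fluid equilibration temperature for the fluid half, K
#' @param prep_steps LD steps used to prepare each half
#' @param seed seed
#' @param apl0 starting area per lipid
#' @param Lz box height, nm
#' @return \code{particle_system} with geometry "two_phase"; attribute
#'   \code{half_mol} gives the molecule ids of the gel half
#' @export
build_two_phase <- function(n_per_leaflet, p = ff_reference(), T_gel = 150,
                            T_fluid = 315, prep_steps = 20000, seed = 1,
                            apl0 = 0.68, Lz = 10) {
  half <- n_per_leaflet %/% 2
  mk_half <- function(temp, sd) {
    sys <- build_bilayer(half, p, apl0 = apl0, Lz = Lz)
    sys <- minimize(sys, p, max_steps = 200)
    cfg <- sim_config(temperature = temp, n_steps = prep_steps, seed = sd,
                      barostat = "off", report_interval = prep_steps)
    run_ld(sys, p, cfg)$system
  }
  gel <- mk_half(T_gel, seed)
  fluid <- mk_half(T_fluid, seed + 1)
  # join side by side along x
  shift <- gel$box[1]
  pos <- rbind(gel$pos, cbind(fluid$pos[, 1] + shift, fluid$pos[, 2:3]))
  ng <- nrow(gel$pos)
  nlip_g <- length(unique(gel$mol))
  bonds2 <- fluid$bonds; bonds2[, 1:2] <- bonds2[, 1:2] + ng
  angles2 <- fluid$angles; angles2[, 1:3] <- angles2[, 1:3] + ng
  excl2 <- fluid$exclusions + ng
  sys <- particle_system(pos = pos,
                         types = c(gel$types, fluid$types),
                         type_labels = c("H", "T"),
                         mol = c(gel$mol, fluid$mol + nlip_g),
                         masses = c(gel$masses, fluid$masses),
                         box = c(gel$box[1] + fluid$box[1], gel$box[2], Lz),
                         bonds = rbind(gel$bonds, bonds2),
                         angles = rbind(gel$angles, angles2),
                         exclusions = rbind(gel$exclusions, excl2),
                         geometry = "two_phase", n_leaflet = 2L * half)
  # relax seam overlaps created by joining independently prepared halves
  sys <- minimize(sys, p, max_steps = 400)
  attr(sys, "half_mol") <- seq_len(nlip_g)
  attr(sys, "epot_gel") <- suppressWarnings(compute_forces(gel, p)$epot) / nlip_g
  attr(sys, "epot_fluid") <- suppressWarnings(compute_forces(fluid, p)$epot) /
    length(unique(fluid$mol))
  sys
}

#' Build a random lipid gas for self-assembly runs
#'
#' Lipids placed with random positions and orientations; placements with any
#' intermolecular bead distance below \code{min_dist} are rejected.
#'
#' @param n_lipids number of lipids
#' @param box box lengths, nm
#' @param p \code{ff_params}
#' @param seed seed
#' @param min_dist minimum intermolecular bead distance, nm
#' @return \code{particle_system} with geometry "gas"
#' @export
build_random_gas <- function(n_lipids, box, p = ff_reference(), seed = 1,
                             min_dist = 0.6) {
  set.seed(seed)
  box <- as.numeric(box)
  placed <- list()
  all_pos <- NULL
  tries <- 0
  while (length(placed) < n_lipids) {
    tries <- tries + 1
    if (tries > 2000 * n_lipids) stop("could not place lipids without overlap")
    head <- runif(3) * box
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    top <- lipid_topology()
    # tails along -u with the equilibrium splay in a random perpendicular plane
    perp <- rnorm(3); perp <- perp - sum(perp * u) * u
    perp <- perp / sqrt(sum(perp^2))
    half <- top$theta0 / 2
    t1 <- head + top$r0 * (-cos(half) * u + sin(half) * perp)
    t2 <- head + top$r0 * (-cos(half) * u - sin(half) * perp)
    cand <- rbind(head, t1, t2)
    ok <- TRUE
    if (!is.null(all_pos)) {
      for (i in 1:3) {
        d <- sweep(all_pos, 2, cand[i, ])
        d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
        if (min(rowSums(d^2)) < min_dist^2) { ok <- FALSE; break }
      }
    }
    if (ok) {
      placed[[length(placed) + 1]] <- cand
      all_pos <- rbind(all_pos, cand)
    }
  }
  .assemble_lipids(placed, box, p, "gas")
}

#' Count connected lipid aggregates
#'
#' Single-linkage clustering: two lipids are linked when any of their beads
#' are within \code{cutoff} (minimum image). Used as the oracle for the
#' self-assembly demos.
#'
#' @param sys \code{particle_system}
#' @param cutoff linkage distance, nm
#' @return number of connected components
#' @export
cluster_count <- function(sys, cutoff = 1.5) {
  nmol <- length(unique(sys$mol))
  parent <- seq_len(nmol)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  pos <- sys$pos; box <- sys$box
  n <- nrow(pos)
  cut2 <- cutoff^2
  for (i in seq_len(n - 1)) {
    d <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    hit <- which(rowSums(d^2) < cut2) + i
    for (j in hit) {
      ri <- find(sys$mol[i]); rj <- find(sys$mol[j])
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(nmol), find, 1L)))
}
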
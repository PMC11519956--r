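# Model energetics: harmonic bonded terms, the 6/0.5 nonbonded forms with a
# per-term force-shift, and tabulated-potential generation in the 7-column
# GROMACS table dialect.

#' Force-field parameter set for the three-site lipid model
#'
#' The six scalars that the genetic algorithm optimizes: the tail-tail well
#' depth \code{epsilon}, the position \code{r_min} of the unshifted tail-tail
#' minimum, the force-shift onset \code{r1}, the nonbonded cutoff \code{rc},
#' and the harmonic bond and angle constants.
#'
#' @param epsilon well depth, kJ/mol (use \code{kbt_to_kjmol} to express in
#'   kBT at a stated temperature)
#' @param r_min distance of the unshifted tail-tail minimum, nm
#' @param r1 shift-function onset, nm
#' @param rc nonbonded cutoff, nm
#' @param k_bond harmonic bond constant, kJ/mol/nm^2
#' @param k_angle harmonic angle constant, kJ/mol/rad^2
#' @param dialect force-shift dialect: \code{"gromacs"} scales the
#'   polynomial force correction of each power-law term by its power alpha
#'   (the convention of the target engine's manual); \code{"literal"}
#'   applies the shift coefficients without the alpha factor. The two differ
#'   in how much of the slowly decaying attraction survives between the
#'   shift onset and the cutoff.
#' @return an object of class \code{ff_params}
#' @examples
#' p <- forcefield_params(epsilon = kbt_to_kjmol(5.788, 315), r_min = 1.095,
#'                        r1 = 1.729, rc = 2.5, k_bond = 1997, k_angle = 264)
#' @export
forcefield_params <- function(epsilon, r_min, r1, rc, k_bond, k_angle,
                              dialect = c("gromacs", "literal")) {
  dialect <- match.arg(dialect)
  stopifnot(epsilon > 0, k_bond > 0, k_angle > 0)
  if (!(0 < r_min && r_min < r1 && r1 < rc))
    stop("invalid geometry: need 0 < r_min < r1 < rc")
  structure(list(epsilon = epsilon, r_min = r_min, r1 = r1, rc = rc,
                 k_bond = k_bond, k_angle = k_angle, dialect = dialect),
            class = "ff_params")
}

#' @export
print.ff_params <- function(x, ...) {
  cat("Three-site lipid force field\n")
  cat(sprintf("  epsilon : %.4f kJ/mol (%.3f kBT at 315 K)\n",
              x$epsilon, kjmol_to_kbt(x$epsilon, 315)))
  cat(sprintf("  r_min   : %.4f nm\n", x$r_min))
  cat(sprintf("  r1      : %.4f nm   rc: %.4f nm\n", x$r1, x$rc))
  cat(sprintf("  k_bond  : %.1f kJ/mol/nm^2   k_angle: %.1f kJ/mol/rad^2\n",
              x$k_bond, x$k_angle))
  invisible(x)
}

#' Reference (optimized) parameter set
#'
#' The parameter set obtained from the evolutionary parametrization against
#' POPC membrane targets: epsilon = 5.788 kBT at 315 K, r_min = 1.095 nm,
#' r1 = 1.729 nm, rc = 2.5 nm, k_bond = 1997 kJ/mol/nm^2,
#' k_angle = 264 kJ/mol/rad^2.
#'
#' @param temperature temperature (K) at which the kBT-expressed well depth is
#'   converted to kJ/mol
#' @return an \code{ff_params} object
#' @export
ff_reference <- function(temperature = 315) {
  forcefield_params(epsilon = kbt_to_kjmol(5.788, temperature),
                    r_min = 1.095, r1 = 1.729, rc = 2.5,
                    k_bond = 1997, k_angle = 264)
}

#' Fixed lipid topology constants
#'
#' Three beads per lipid (H, T, T), two H-T bonds with 1.0 nm equilibrium
#' length, one T-H-T angle with a 30 degree equilibrium, and equal bead
#' masses summing to the POPC molar mass (760.1 g/mol over 3 beads).
#'
#' @return list with \code{r0} (nm), \code{theta0} (rad), \code{bead_mass} (amu)
#' @export
lipid_topology <- function() {
  list(r0 = 1.0, theta0 = 30 * pi / 180, bead_mass = 253.4)
}

#' Bonded energy of one bond length and one angle
#'
#' \code{0.5 k_bond (r - r0)^2 + 0.5 k_angle (theta - theta0)^2} with the
#' fixed equilibrium values of \code{lipid_topology()}.
#'
#' @param r bond length, nm
#' @param theta angle, rad
#' @param p \code{ff_params}
#' @return energy in kJ/mol
#' @export
bonded_energy <- function(r, theta, p) {
  if (any(r <= 0)) stop("bond length must be positive")
  stopifnot(all(theta >= 0), all(theta <= pi))
  top <- lipid_topology()
  0.5 * p$k_bond * (r - top$r0)^2 + 0.5 * p$k_angle * (theta - top$theta0)^2
}

#' Unshifted tail-tail pair potential
#'
#' \code{(epsilon/5.5) * (0.5 (r_min/r)^6 - 6 (r_min/r)^0.5)}; minimum of
#' exactly \code{-epsilon} at \code{r = r_min}.
#'
#' @param r distance, nm (vectorized)
#' @param p \code{ff_params}
#' @return energy in kJ/mol
#' @export
tt_potential <- function(r, p) {
  if (any(r <= 0)) stop("distance must be positive")
  (p$epsilon / 5.5) * (0.5 * (p$r_min / r)^6 - 6 * (p$r_min / r)^0.5)
}

#' Unshifted head-head / head-tail repulsion
#'
#' \code{(0.4 epsilon/5.5) * 0.5 (r_min/r)^6}; identical for the HH and HT
#' pair classes, strictly positive and monotonically decreasing.
#'
#' @inheritParams tt_potential
#' @export
repulsive_potential <- function(r, p) {
  if (any(r <= 0)) stop("distance must be positive")
  (0.4 * p$epsilon / 5.5) * 0.5 * (p$r_min / r)^6
}

#' Force-shift polynomial coefficients for one power-law term
#'
#' For a term proportional to \code{1/r^alpha} the shifted force acquires a
#' polynomial correction \code{A (r-r1)^2 + B (r-r1)^3} between the shift
#' onset \code{r1} and the cutoff \code{rc}, chosen so the force vanishes
#' smoothly at the cutoff.
#'
#' @param alpha interaction power (0.5 for attraction, 6 for repulsion)
#' @param r1 shift onset, nm
#' @param rc cutoff, nm
#' @return named vector \code{c(A = , B = )}
#' @export
shift_coefficients <- function(alpha, r1, rc) {
  stopifnot(alpha > 0)
  if (!(0 < r1 && r1 < rc)) stop("invalid geometry: need 0 < r1 < rc")
  d <- rc - r1
  A <- -((alpha + 4) * rc - (alpha + 1) * r1) / (rc^(alpha + 2) * d^2)
  B <- ((alpha + 3) * rc - (alpha + 1) * r1) / (rc^(alpha + 2) * d^3)
  c(A = unname(A), B = unname(B))
}

# dialect of a parameter set (older objects may predate the field)
.ff_dialect <- function(p) if (is.null(p$dialect)) "gromacs" else p$dialect

# terms (coefficient, power) of the nonbonded potential of a pair class;
# V(r) = sum c_i / r^alpha_i, attraction carried by a negative coefficient
.pair_terms <- function(p, pair) {
  pair <- match.arg(pair, c("TT", "HH", "HT"))
  c_rep <- (p$epsilon / 5.5) * 0.5 * p$r_min^6
  if (pair == "TT") {
    cbind(c = c(c_rep, -(p$epsilon / 5.5) * 6 * p$r_min^0.5),
          alpha = c(6, 0.5))
  } else {
    cbind(c = 0.4 * c_rep, alpha = 6)
  }
}

# per-term shifted potential and force (f = -dV/dr); both vectorized over r.
# `pa` is the polynomial prefactor: alpha under the gromacs dialect, 1 under
# the literal dialect.
.eval_shifted <- function(r, terms, r1, rc, dialect = "gromacs") {
  V <- numeric(length(r))
  f <- numeric(length(r))
  d <- rc - r1
  for (i in seq_len(nrow(terms))) {
    cc <- terms[i, "c"]; a <- terms[i, "alpha"]
    pa <- if (dialect == "literal") 1 else a
    AB <- shift_coefficients(a, r1, rc)
    A <- AB["A"]; B <- AB["B"]
    Ctot <- -cc / rc^a + cc * pa * (A / 3 * d^3 + B / 4 * d^4)
    inner <- r < r1
    mid <- r >= r1 & r < rc
    V[inner] <- V[inner] + cc / r[inner]^a + Ctot
    f[inner] <- f[inner] + a * cc / r[inner]^(a + 1)
    x <- r[mid] - r1
    V[mid] <- V[mid] + cc * (1 / r[mid]^a - 1 / rc^a) +
      cc * pa * (A / 3 * (d^3 - x^3) + B / 4 * (d^4 - x^4))
    f[mid] <- f[mid] + cc * (a / r[mid]^(a + 1) + pa * (A * x^2 + B * x^3))
  }
  list(V = unname(V), f = unname(f))
}

#' Shifted pair force
#'
#' The force-shifted nonbonded force \code{f(r) = -dV/dr} (positive =
#' repulsive): unshifted below the onset \code{r1}, polynomial-corrected
#' per power-law term between \code{r1} and \code{rc}, exactly zero beyond
#' the cutoff. Continuous at both \code{r1} and \code{rc}.
#'
#' @param r distance, nm (vectorized)
#' @param p \code{ff_params}
#' @param pair \code{"TT"}, \code{"HH"} or \code{"HT"}
#' @return force in kJ/mol/nm
#' @export
pair_force <- function(r, p, pair = "TT") {
  if (any(r <= 0)) stop("distance must be positive")
  .eval_shifted(r, .pair_terms(p, pair), p$r1, p$rc, .ff_dialect(p))$f
}

#' Shifted pair potential
#'
#' Integral of \code{pair_force} from \code{r} to the cutoff, so that
#' \code{V(rc) = 0}; below the onset it equals the unshifted potential plus
#' a constant.
#'
#' @inheritParams pair_force
#' @return energy in kJ/mol
#' @export
pair_potential <- function(r, p, pair = "TT") {
  if (any(r <= 0)) stop("distance must be positive")
  .eval_shifted(r, .pair_terms(p, pair), p$r1, p$rc, .ff_dialect(p))$V
}

#' Generate the full set of tabulated potentials
#'
#' Nonbonded tables for the TT, HH and HT pair classes in the 7-column
#' GROMACS dialect (the dispersion column \code{g} carries the attractive
#' 1/r^0.5 shape, the repulsion column \code{h} the 1/r^6 shape, each with
#' unit coefficient so the actual coefficients are supplied by the topology),
#' plus 3-column bond and angle tables.
#'
#' @param p \code{ff_params}
#' @param dr grid spacing, nm (recommended at most 0.005)
#' @param r_max table extent, nm (default \code{rc + 0.5})
#' @return named list of \code{tabulated_potential} objects
#' @export
make_tables <- function(p, dr = 0.002, r_max = p$rc + 0.5) {
  if (dr <= 0 || dr > 0.005) stop("dr must be in (0, 0.005] nm")
  if (r_max < p$rc) stop("table grid must reach the cutoff")
  r <- seq(0, r_max, by = dr)
  # cap the diverging r -> 0 region GROMACS-style: continue the power law
  # from a small floor distance
  r_eval <- pmax(r, 0.04)
  att <- .eval_shifted(r_eval, cbind(c = -1, alpha = 0.5), p$r1, p$rc,
                       .ff_dialect(p))
  rep6 <- .eval_shifted(r_eval, cbind(c = 1, alpha = 6), p$r1, p$rc,
                        .ff_dialect(p))
  nb <- function(label) {
    structure(list(r = r, g = att$V, gp = att$f, h = rep6$V, hp = rep6$f,
                   kind = "nonbonded", label = label,
                   r1 = p$r1, rc = p$rc),
              class = "tabulated_potential")
  }
  top <- lipid_topology()
  rb <- seq(0, 2 * top$r0, by = dr)
  bond <- structure(list(r = rb, V = 0.5 * (rb - top$r0)^2,
                         Fcol = -(rb - top$r0), kind = "bond", label = "bond"),
                    class = "tabulated_potential")
  th <- seq(0, 180, by = 0.2)  # degrees, GROMACS angle-table convention
  thr <- th * pi / 180
  ang <- structure(list(r = th, V = 0.5 * (thr - top$theta0)^2,
                        Fcol = -(thr - top$theta0), kind = "angle",
                        label = "angle"),
                   class = "tabulated_potential")
  list(TT = nb("T_T"), HH = nb("H_H"), HT = nb("H_T"), bond = bond, angle = ang)
}

#' Nonbonded coefficients multiplying the g/h table columns
#'
#' With the unit-coefficient tables of \code{make_tables}, a pair class is
#' fully specified by the dispersion coefficient \code{C_att} (multiplying
#' the attractive 1/r^0.5 column) and the repulsion coefficient \code{C_rep}
#' (multiplying the 1/r^6 column).
#'
#' @param p \code{ff_params}
#' @return data.frame with one row per pair class
#' @export
table_coefficients <- function(p) {
  c_rep <- (p$epsilon / 5.5) * 0.5 * p$r_min^6
  c_att <- (p$epsilon / 5.5) * 6 * p$r_min^0.5
  data.frame(pair = c("TT", "HH", "HT"),
             C_att = c(c_att, 0, 0),
             C_rep = c(c_rep, 0.4 * c_rep, 0.4 * c_rep))
}

#' Reconstruct potential and force of a pair class from its tables
#'
#' @param tables output of \code{make_tables}
#' @param p \code{ff_params} (for the coefficients)
#' @param pair pair class
#' @return data.frame with columns \code{r}, \code{V}, \code{f}
#' @export
table_potential <- function(tables, p, pair = "TT") {
  co <- table_coefficients(p)
  co <- co[co$pair == pair, ]
  tb <- tables[[pair]]
  data.frame(r = tb$r,
             V = co$C_att * tb$g + co$C_rep * tb$h,
             f = co$C_att * tb$gp + co$C_rep * tb$hp)
}

#' Write tabulated potentials as GROMACS-dialect .xvg files
#'
#' Nonbonded tables as 7 whitespace-separated columns
#' (x, f, -f', g, -g', h, -h') with zero Coulomb columns, named
#' \code{table_<t1>_<t2>.xvg}; bonded tables as 3 columns (x, V, -V').
#'
#' @param tables named list from \code{make_tables} (or a single
#'   \code{tabulated_potential})
#' @param dir output directory (created if missing)
#' @return invisibly, the written file paths
#' @export
write_tables <- function(tables, dir) {
  if (inherits(tables, "tabulated_potential")) tables <- list(tables)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (tb in tables) {
    if (tb$kind == "nonbonded") {
      path <- file.path(dir, sprintf("table_%s.xvg", tb$label))
      m <- cbind(tb$r, 0, 0, tb$g, tb$gp, tb$h, tb$hp)
    } else {
      path <- file.path(dir, sprintf("table_%s.xvg", tb$label))
      m <- cbind(tb$r, tb$V, tb$Fcol)
    }
    lines <- apply(m, 1, function(row) paste(sprintf("%15.8e", row), collapse = " "))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read back a 7-column nonbonded table file
#'
#' @param path .xvg file written by \code{write_tables}
#' @return \code{tabulated_potential}
#' @export
read_table_xvg <- function(path) {
  m <- as.matrix(read.table(path))
  if (ncol(m) == 7) {
    structure(list(r = m[, 1], g = m[, 4], gp = m[, 5], h = m[, 6], hp = m[, 7],
                   kind = "nonbonded", label = basename(path)),
              class = "tabulated_potential")
  } else if (ncol(m) == 3) {
    structure(list(r = m[, 1], V = m[, 2], Fcol = m[, 3], kind = "bonded",
                   label = basename(path)),
              class = "tabulated_potential")
  } else stop("unrecognized table layout in ", path)
}

#' Write / read a force-field parameter set as a plain key = value config
#'
#' @param p \code{ff_params}
#' @param path file path
#' @return \code{write_forcefield_config} invisibly returns \code{path};
#'   \code{read_forcefield_config} returns an \code{ff_params}
#' @export
write_forcefield_config <- function(p, path) {
  lines <- c("# three-site lipid force field parameters",
             sprintf("epsilon = %.10g   # kJ/mol", p$epsilon),
             sprintf("r_min = %.10g    # nm", p$r_min),
             sprintf("r1 = %.10g       # nm (shift onset)", p$r1),
             sprintf("rc = %.10g       # nm (cutoff)", p$rc),
             sprintf("k_bond = %.10g   # kJ/mol/nm^2", p$k_bond),
             sprintf("k_angle = %.10g  # kJ/mol/rad^2", p$k_angle))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_forcefield_config
#' @export
read_forcefield_config <- function(path) {
  kv <- read_keyvalue(path)
  forcefield_params(epsilon = kv$epsilon, r_min = kv$r_min, r1 = kv$r1,
                    rc = kv$rc, k_bond = kv$k_bond, k_angle = kv$k_angle)
}
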
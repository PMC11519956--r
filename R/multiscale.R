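# Mixed-resolution support: Lennard-Jones C6/C12 cross-interaction tables
# between peptide beads and the membrane beads, the peptide tilt-angle
# observable with its Gaussian-target objective, and a run-bundle emitter
# for an external MD engine.

#' Eight-parameter cross-interaction set
#'
#' C6/C12 pairs for the four peptide x membrane bead-class combinations
#' (peptide hydrophilic/hydrophobic x membrane H/T), all at a 1.2 nm cutoff.
#'
#' @param C6 named numeric length 4: \code{philic_H}, \code{philic_T},
#'   \code{phobic_H}, \code{phobic_T} (kJ/mol nm^6)
#' @param C12 named numeric length 4, same names (kJ/mol nm^12)
#' @param rc cutoff, nm
#' @return object of class \code{cross_interaction_set}
#' @export
cross_interaction_set <- function(C6, C12, rc = 1.2) {
  classes <- c("philic_H", "philic_T", "phobic_H", "phobic_T")
  stopifnot(all(classes %in% names(C6)), all(classes %in% names(C12)),
            all(C6 >= 0), all(C12 >= 0))
  structure(list(C6 = C6[classes], C12 = C12[classes], rc = rc,
                 classes = classes),
            class = "cross_interaction_set")
}

#' Force-shifted Lennard-Jones tabulated potential
#'
#' \code{V = C12 / r^12 - C6 / r^6} with the same per-term force-shift
#' treatment as the membrane tables, so both potential and force vanish at
#' the cutoff. The table carries unit-coefficient columns (g = dispersion,
#' h = repulsion), with the C6/C12 coefficients supplied by the topology.
#'
#' @param C6 dispersion coefficient, kJ/mol nm^6
#' @param C12 repulsion coefficient, kJ/mol nm^12
#' @param rc cutoff, nm
#' @param r1 shift onset, nm
#' @param dr grid spacing, nm
#' @return \code{tabulated_potential}; attribute \code{coefficients} holds
#'   the C6/C12 pair
#' @export
lj_table <- function(C6, C12, rc = 1.2, r1 = 0.9, dr = 0.002) {
  stopifnot(C6 >= 0, C12 >= 0)
  if (C6 == 0 && C12 == 0)
    warning("both LJ coefficients zero: table is identically zero")
  r <- seq(0, rc + 0.3, by = dr)
  r_eval <- pmax(r, 0.04)
  disp <- .eval_shifted(r_eval, cbind(c = -1, alpha = 6), r1, rc)
  rep12 <- .eval_shifted(r_eval, cbind(c = 1, alpha = 12), r1, rc)
  tb <- structure(list(r = r, g = disp$V, gp = disp$f, h = rep12$V,
                       hp = rep12$f, kind = "nonbonded", label = "LJ",
                       r1 = r1, rc = rc),
                  class = "tabulated_potential")
  attr(tb, "coefficients") <- c(C6 = C6, C12 = C12)
  tb
}

#' Reconstruct the shifted LJ potential and force from a table
#' @param tb \code{lj_table} output
#' @return data.frame with \code{r}, \code{V}, \code{f}
#' @export
lj_table_potential <- function(tb) {
  co <- attr(tb, "coefficients")
  data.frame(r = tb$r, V = co["C6"] * tb$g + co["C12"] * tb$h,
             f = co["C6"] * tb$gp + co["C12"] * tb$hp)
}

#' Peptide tilt-angle distribution
#'
#' Per frame, the angle between the peptide end-to-end vector (first bead
#' to last bead) and the membrane normal (+z), folded into [0, 90] degrees
#' by the up/down symmetry of a transmembrane helix. Zero-length vectors
#' are skipped.
#'
#' @param vectors n x 3 matrix of end-to-end vectors (or list of position
#'   matrices together with \code{first}/\code{last} indices)
#' @param first,last bead indices when \code{vectors} is a list of frames
#' @param bin_width histogram bin width, degrees
#' @return list of class \code{tilt_distribution}: \code{breaks},
#'   \code{x} (bin centers), \code{y} (probability), \code{mean}, \code{sd},
#'   \code{angles}
#' @export
tilt_angle <- function(vectors, first = NULL, last = NULL, bin_width = 1) {
  if (is.list(vectors)) {
    stopifnot(!is.null(first), !is.null(last))
    vectors <- t(vapply(vectors, function(fr) fr[last, ] - fr[first, ],
                        numeric(3)))
  }
  len <- sqrt(rowSums(vectors^2))
  keep <- len > 1e-12
  if (any(!keep)) message(sum(!keep), " zero-length vectors skipped")
  v <- vectors[keep, , drop = FALSE]
  ang <- acos(pmin(abs(v[, 3]) / len[keep], 1)) * 180 / pi  # folded to [0, 90]
  breaks <- seq(0, 90 + bin_width, by = bin_width)
  h <- graphics::hist(ang, breaks = breaks, plot = FALSE)
  structure(list(breaks = breaks, x = h$mids, y = h$counts / length(ang),
                 width = bin_width, mean = mean(ang), sd = stats::sd(ang),
                 angles = ang, normalized = TRUE,
                 xlab = "angle_deg", ylab = "probability"),
            class = c("tilt_distribution", "profile_1d"))
}

#' Tilt-angle objective against a Gaussian target
#'
#' EMD between the observed tilt distribution and the target Gaussian
#' (mean 30 degrees, sd 10 degrees by default) discretized on the same
#' bins; zero iff identical. For equal-sd Gaussians the EMD equals the
#' difference of the means.
#'
#' @param obs \code{tilt_distribution}
#' @param mean,sd target Gaussian parameters, degrees
#' @return cost (degrees)
#' @export
tilt_objective <- function(obs, mean = 30, sd = 10) {
  pt <- diff(stats::pnorm(obs$breaks, mean, sd))
  target <- profile_1d(obs$x, pt / sum(pt), obs$width, "angle_deg",
                       "probability", normalized = TRUE)
  o <- profile_1d(obs$x, obs$y / sum(obs$y), obs$width, "angle_deg",
                  "probability", normalized = TRUE)
  emd(o, target)
}

#' Emit a mixed-resolution run bundle for an external engine
#'
#' Writes the four peptide-membrane cross tables (1.2 nm cutoff), the three
#' membrane tables (2.5 nm cutoff, byte-identical to \code{make_tables}
#' output), a JSON manifest echoing the eight C6/C12 values, and a
#' documented shell script template for the external engine invocation.
#' No external execution is performed.
#'
#' @param cross \code{cross_interaction_set}
#' @param p membrane \code{ff_params}
#' @param dir output directory
#' @return invisibly, the manifest path
#' @export
emit_external_run <- function(cross, p = ff_reference(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mem <- make_tables(p)
  write_tables(mem, dir)
  for (cl in cross$classes) {
    tb <- lj_table(cross$C6[[cl]], cross$C12[[cl]], rc = cross$rc)
    tb$label <- cl
    write_tables(list(tb), dir)
  }
  manifest <- list(
    membrane = list(epsilon_kJ_mol = p$epsilon, r_min_nm = p$r_min,
                    r1_nm = p$r1, rc_nm = p$rc, k_bond = p$k_bond,
                    k_angle = p$k_angle),
    cross = list(C6_kJ_mol_nm6 = as.list(cross$C6),
                 C12_kJ_mol_nm12 = as.list(cross$C12),
                 rc_nm = cross$rc))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  script <- c("#!/bin/sh",
              "# Mixed-resolution run template: supply your own topology and",
              "# engine binary. Tables in this directory follow the 7-column",
              "# dialect (x f -f' g -g' h -h'); membrane tables use a 2.5 nm",
              "# cutoff, peptide-membrane cross tables 1.2 nm.",
              "# <engine> grompp -f run.mdp -p topol.top -c start.gro",
              "# <engine> mdrun -tableb table_*.xvg")
  writeLines(script, file.path(dir, "run.sh"))
  invisible(mpath)
}

#' Read back a run-bundle manifest
#' @param path manifest.json path
#' @return list
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
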
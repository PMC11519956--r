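# File formats: GRO snapshots, plain-text trajectories, TSV series and
# key = value configuration files.

#' Read a key = value configuration file
#'
#' Lines of the form \code{key = value}; \code{#} starts a comment. Values
#' are parsed as numbers when possible, otherwise kept as strings.
#'
#' @param path file path
#' @return named list
#' @export
read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed config line: ", ln)
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a named list as a key = value configuration file
#' @param x named list of scalars
#' @param path file path
#' @return invisibly, \code{path}
#' @export
write_keyvalue <- function(x, path) {
  fmt <- function(v) if (is.numeric(v)) sprintf("%.10g", v) else as.character(v)
  writeLines(sprintf("%s = %s", names(x), vapply(x, fmt, "")), path)
  invisible(path)
}

#' Write a particle system as a GRO snapshot
#'
#' Fixed-width GRO dialect, coordinates in nm; velocities written when
#' present and nonzero.
#'
#' @param sys \code{particle_system}
#' @param path output file
#' @param title title line
#' @return invisibly, \code{path}
#' @export
write_gro <- function(sys, path, title = "trilayer snapshot") {
  n <- nrow(sys$pos)
  has_vel <- !is.null(sys$vel) && any(sys$vel != 0)
  lines <- character(n + 3)
  lines[1] <- title
  lines[2] <- sprintf("%5d", n)
  labels <- sys$type_labels[sys$types]
  # number bead names within each molecule: H, T1, T2
  atom_names <- labels
  for (m in unique(sys$mol)) {
    idx <- which(sys$mol == m)
    tcount <- 0L
    for (i in idx) {
      if (labels[i] == "T") {
        tcount <- tcount + 1L
        atom_names[i] <- paste0("T", tcount)
      }
    }
  }
  resname <- ifelse(labels %in% c("H", "T"), "LIP", "PEP")
  for (i in seq_len(n)) {
    base <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    (sys$mol[i] - 1L) %% 100000L + 1L, resname[i],
                    atom_names[i], (i - 1L) %% 100000L + 1L,
                    sys$pos[i, 1], sys$pos[i, 2], sys$pos[i, 3])
    if (has_vel)
      base <- paste0(base, sprintf("%8.4f%8.4f%8.4f",
                                   sys$vel[i, 1], sys$vel[i, 2], sys$vel[i, 3]))
    lines[i + 2] <- base
  }
  lines[n + 3] <- sprintf("%10.5f%10.5f%10.5f", sys$box[1], sys$box[2], sys$box[3])
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO snapshot into a particle system
#'
#' Topology (bonds, angles, masses) is reconstructed assuming the three-site
#' lipid layout for LIP residues; other residues get no bonded terms.
#'
#' @param path GRO file
#' @param p \code{ff_params} supplying bonded constants (default reference set)
#' @return \code{particle_system}
#' @export
read_gro <- function(path, p = ff_reference()) {
  lines <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO: bad atom count at line 2")
  if (length(lines) < n + 3) stop("malformed GRO: truncated file")
  pos <- matrix(0, n, 3)
  vel <- matrix(0, n, 3)
  mol <- integer(n)
  nm <- character(n)
  for (i in seq_len(n)) {
    ln <- lines[i + 2]
    if (nchar(ln) < 44) stop("malformed GRO line ", i + 2)
    mol[i] <- as.integer(substr(ln, 1, 5))
    nm[i] <- trimws(substr(ln, 11, 15))
    pos[i, ] <- as.numeric(c(substr(ln, 21, 28), substr(ln, 29, 36),
                             substr(ln, 37, 44)))
    if (nchar(ln) >= 68)
      vel[i, ] <- as.numeric(c(substr(ln, 45, 52), substr(ln, 53, 60),
                               substr(ln, 61, 68)))
    if (any(is.na(pos[i, ]))) stop("malformed GRO coordinates at line ", i + 2)
  }
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])[1:3]
  # renumber molecules contiguously (GRO resid wraps at 1e5)
  mol <- cumsum(c(1L, diff(mol) != 0L))
  labels <- ifelse(grepl("^H", nm), "H", "T")
  types <- as.integer(factor(labels, levels = c("H", "T")))
  top <- lipid_topology()
  bonds <- NULL; angles <- NULL; excl <- NULL
  for (m in unique(mol)) {
    idx <- which(mol == m)
    if (length(idx) == 3 && sum(labels[idx] == "H") == 1) {
      h <- idx[labels[idx] == "H"]
      t <- idx[labels[idx] == "T"]
      bonds <- rbind(bonds, c(h, t[1], top$r0, p$k_bond),
                     c(h, t[2], top$r0, p$k_bond))
      angles <- rbind(angles, c(t[1], h, t[2], top$theta0, p$k_angle))
      excl <- rbind(excl, c(h, t[1]), c(h, t[2]), c(t[1], t[2]))
    }
  }
  particle_system(pos = pos, vel = vel, types = types,
                  type_labels = c("H", "T"), mol = mol,
                  masses = rep(top$bead_mass, n), box = box,
                  bonds = bonds, angles = angles, exclusions = excl)
}

#' Write a frame series (energies, box, pressure) as TSV
#'
#' @param frames data.frame from \code{run_ld}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
write_frames_tsv <- function(frames, path) {
  write.table(frames, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a frame series TSV
#' @param path file written by \code{write_frames_tsv}
#' @return data.frame
#' @export
read_frames_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

#' Write a 1-D profile (RDF, density, spectrum) as two-column TSV
#' @param profile \code{profile_1d} or \code{undulation_spectrum} result
#' @param path output file
#' @return invisibly, \code{path}
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(x = profile$x, y = profile$y)
  names(df) <- c(profile$xlab %||% "x", profile$ylab %||% "y")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
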
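# The seven membrane-property estimators scored during parametrization:
# area per lipid, area compressibility, line tension, bending modulus from
# the undulation spectrum, phase-transition temperature, lateral RDF and
# transverse density profile, plus the Earth Mover's Distance comparator.

# block-averaged standard error of the mean (5 blocks)
block_stderr <- function(x, n_blocks = 5) {
  n <- length(x)
  if (n < n_blocks) return(stats::sd(x) / sqrt(max(n, 1)))
  bl <- floor(n / n_blocks)
  means <- vapply(seq_len(n_blocks),
                  function(b) mean(x[((b - 1) * bl + 1):(b * bl)]), 0)
  stats::sd(means) / sqrt(n_blocks)
}

#' Area per lipid from a box-dimension series
#'
#' \code{<Lx Ly> / n_per_leaflet} over a tensionless-coupled run, with a
#' block-averaged standard error.
#'
#' @param frames data.frame with columns \code{Lx}, \code{Ly} (e.g. the
#'   \code{frames} element of \code{run_ld})
#' @param n_per_leaflet lipids per leaflet
#' @return list with \code{apl} (nm^2) and \code{stderr}
#' @export
area_per_lipid <- function(frames, n_per_leaflet) {
  stopifnot(n_per_leaflet > 0)
  if (nrow(frames) == 0) stop("empty frame series")
  a <- frames$Lx * frames$Ly / n_per_leaflet
  list(apl = mean(a), stderr = block_stderr(a))
}

#' Area compressibility modulus from box-length fluctuations
#'
#' \code{K_A = kB T / (4 Var(Lx))}, converted to mN/m. The variance of the
#' lateral box length under tensionless semi-isotropic coupling measures the
#' membrane's resistance to area dilation.
#'
#' @param frames data.frame with column \code{Lx} (nm)
#' @param temperature temperature, K
#' @return list with \code{ka} (mN/m) and \code{stderr} (block bootstrap)
#' @export
area_compressibility <- function(frames, temperature = 315) {
  v <- stats::var(frames$Lx)
  if (v <= 0) stop("zero Lx variance: area compressibility diverges")
  # kB T in J over Var in m^2 gives J/m^2 = N/m; x1000 -> mN/m
  kbt_j <- 1.380649e-23 * temperature
  ka <- kbt_j / (4 * v * 1e-18) * 1e3
  # block bootstrap over 5 blocks of the Lx series
  n <- nrow(frames)
  nb <- 5
  bl <- floor(n / nb)
  if (bl >= 2) {
    kas <- vapply(seq_len(nb), function(b) {
      vi <- stats::var(frames$Lx[((b - 1) * bl + 1):(b * bl)])
      if (vi > 0) kbt_j / (4 * vi * 1e-18) * 1e3 else NA_real_
    }, 0)
    se <- stats::sd(kas, na.rm = TRUE) / sqrt(sum(!is.na(kas)))
  } else se <- NA_real_
  list(ka = ka, stderr = se)
}

#' Line tension of a bilayer ribbon from pressure anisotropy
#'
#' \code{gamma_L = -(Lx Lz / 2) (Pyy - (Pxx + Pzz)/2)} with the ribbon
#' periodic along y and two free edges along x; the prefactor 1/2 accounts
#' for the two edges. Converted from bar nm^2 to pN (1 bar nm^2 = 0.1 pN).
#'
#' @param frames data.frame with columns \code{Pxx}, \code{Pyy}, \code{Pzz}
#'   (bar), \code{Lx}, \code{Lz} (nm)
#' @param geometry geometry tag of the originating system; anything other
#'   than "ribbon" is refused
#' @return list with \code{lt} (pN) and \code{stderr}
#' @export
line_tension <- function(frames, geometry = "ribbon") {
  if (!identical(geometry, "ribbon"))
    stop("line tension requires a ribbon geometry (periodic y, free edges in x)")
  g <- -(frames$Lx * frames$Lz / 2) *
    (frames$Pyy - (frames$Pxx + frames$Pzz) / 2) * 0.1
  list(lt = mean(g), stderr = block_stderr(g))
}

#' Map a bilayer frame onto a height-field grid
#'
#' Every bead is assigned to its nearest cell of an N x N lateral grid; the
#' cell value is the mean z of its beads, relative to the frame mean. Empty
#' cells are filled by iterative nearest-neighbor averaging.
#'
#' @param pos N x 3 positions of one frame (nm), wrapped into the box
#' @param box box lengths, nm
#' @param N grid size (default \code{floor(L / 1.0)}, minimum 8)
#' @return N x N matrix of heights u(x, y), nm; attribute \code{filled}
#'   counts initially empty cells
#' @export
height_field <- function(pos, box, N = max(8L, floor(box[1]))) {
  ix <- pmin(floor(pos[, 1] %% box[1] / box[1] * N), N - 1) + 1
  iy <- pmin(floor(pos[, 2] %% box[2] / box[2] * N), N - 1) + 1
  cell <- factor((iy - 1) * N + ix, levels = seq_len(N * N))
  acc <- matrix(vapply(split(pos[, 3], cell), sum, 0), N, N)
  cnt <- matrix(as.integer(table(cell)), N, N)
  empty <- cnt == 0L
  n_empty <- sum(empty)
  if (n_empty > 0.3 * N * N)
    stop("height-field grid too fine: more than 30% empty cells")
  u <- ifelse(empty, NA_real_, acc / pmax(cnt, 1L))
  # iterative periodic nearest-neighbor averaging for empty cells
  while (anyNA(u)) {
    nbr_mean <- function(m) {
      s <- matrix(0, N, N); c2 <- matrix(0, N, N)
      for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ms <- m[(seq_len(N) - 1 + sh[1]) %% N + 1, (seq_len(N) - 1 + sh[2]) %% N + 1]
        ok <- !is.na(ms)
        s[ok] <- s[ok] + ms[ok]
        c2 <- c2 + ok
      }
      list(s = s, c = c2)
    }
    nm <- nbr_mean(u)
    fill <- is.na(u) & nm$c > 0
    if (!any(fill)) break
    u[fill] <- nm$s[fill] / nm$c[fill]
  }
  u <- u - mean(u)
  attr(u, "filled") <- n_empty
  u
}

#' Thermal undulation spectrum of a stack of height fields
#'
#' Per frame, the 2-D Fourier transform normalized as
#' \code{u_q = FFT(u) / N^2} (a single cosine mode of amplitude a then
#' carries weight a^2/4 at its q); \code{|u_q|^2} is averaged over frames
#' and radially binned in q = 2 pi k / L. The q = 0 mode is excluded.
#'
#' @param fields list of N x N height-field matrices (nm)
#' @param L lateral box side, nm
#' @return list of class \code{undulation_spectrum} with \code{q} (1/nm),
#'   \code{S} (nm^2), \code{n_modes} per bin, \code{L}, \code{N},
#'   \code{n_frames}
#' @export
undulation_spectrum <- function(fields, L) {
  if (length(fields) < 10)
    warning("fewer than 10 frames: spectrum will be noisy")
  N <- nrow(fields[[1]])
  P <- matrix(0, N, N)
  for (u in fields) {
    U <- stats::fft(u) / N^2
    P <- P + Mod(U)^2
  }
  P <- P / length(fields)
  k <- c(0:(N %/% 2), -((N - N %/% 2 - 1):1))
  kx <- matrix(k, N, N)
  ky <- t(kx)
  # bin by the exact integer k^2 so every bin holds a single |q| and the
  # steep q^-4 law is never averaged across unequal magnitudes
  bins <- kx^2 + ky^2
  keep <- bins > 0
  S <- tapply(P[keep], bins[keep], mean)
  nm <- tapply(P[keep], bins[keep], length)
  qb <- 2 * pi * sqrt(as.numeric(names(S))) / L
  structure(list(q = qb, S = as.numeric(S), n_modes = as.numeric(nm),
                 L = L, N = N, n_frames = length(fields)),
            class = "undulation_spectrum")
}

#' Fit the bending modulus from the q^-4 undulation regime
#'
#' Weighted fit of \code{S(q) = 1 / (L^2 kc q^4)} (kc in kBT, tensionless
#' membrane) over \code{q <= q_max}; modes above q_max deviate from the
#' continuum q^-4 law and are excluded.
#'
#' @param spec \code{undulation_spectrum}
#' @param q_max fit window, 1/nm; default
#'   \code{min(0.8, 0.4 * q_Nyquist)}
#' @return list with \code{kc} (kBT), \code{stderr} and \code{n_bins}
#' @export
fit_bending_modulus <- function(spec, q_max = NULL) {
  if (is.null(q_max))
    q_max <- min(0.8, 0.4 * pi * spec$N / spec$L)
  sel <- spec$q > 0 & spec$q <= q_max
  if (sum(sel) < 3)
    stop("fewer than 3 q-bins below q_max; enlarge the membrane or q_max")
  q <- spec$q[sel]; S <- spec$S[sel]; nm <- spec$n_modes[sel]
  x <- 1 / (spec$L^2 * q^4)
  # relative spectral error ~ 1/sqrt(n_modes * n_frames) per bin:
  # weight by n_modes / S^2
  w <- nm / S^2
  theta <- sum(w * x * S) / sum(w * x^2)   # S = theta * x, theta = 1/kc
  resid <- S - theta * x
  var_theta <- sum(w * resid^2) / (sum(sel) - 1) / sum(w * x^2)
  kc <- 1 / theta
  list(kc = kc, stderr = sqrt(var_theta) * kc^2, n_bins = sum(sel))
}

#' Locate a gel-fluid transition from enthalpy-vs-temperature runs
#'
#' Per temperature, the equilibrated enthalpy is the mean over the series
#' tail. The transition zone is the pair of adjacent temperatures bracketing
#' the largest enthalpy jump, provided the jump exceeds
#' \code{significance} times the pooled standard error of the plateau
#' values; the transition temperature is the zone midpoint.
#'
#' @param temperatures numeric vector of temperatures, K
#' @param series list (same order) of enthalpy time series
#' @param tail_fraction fraction of each series used as the equilibrated tail
#' @param significance jump threshold in pooled-standard-error units
#' @return list with \code{ptt} (K, NA when no significant jump),
#'   \code{zone} (Tlo, Thi), \code{jump}, \code{significant}
#' @export
detect_transition <- function(temperatures, series, tail_fraction = 0.5,
                              significance = 5) {
  stopifnot(length(temperatures) == length(series))
  o <- order(temperatures)
  temperatures <- temperatures[o]
  series <- series[o]
  tails <- lapply(series, function(s) s[max(1, floor(length(s) * (1 - tail_fraction))):length(s)])
  h <- vapply(tails, mean, 0)
  se <- vapply(tails, block_stderr, 0)
  jumps <- diff(h)
  i <- which.max(jumps)
  pooled <- sqrt(mean(se^2))
  # a transition is a jump standing out above the background trend, not a
  # uniform slope: compare against the median of the remaining jumps
  excess <- jumps[i] - if (length(jumps) > 1) stats::median(jumps[-i]) else 0
  sig <- excess > significance * pooled
  list(ptt = if (sig) mean(temperatures[c(i, i + 1)]) else NA_real_,
       zone = c(temperatures[i], temperatures[i + 1]),
       jump = jumps[i], significant = sig,
       enthalpy = h, temperatures = temperatures)
}

# make a profile_1d container
profile_1d <- function(x, y, width, xlab, ylab, normalized = FALSE) {
  structure(list(x = x, y = y, width = width, xlab = xlab, ylab = ylab,
                 normalized = normalized), class = "profile_1d")
}

#' Normalize a profile to unit sum (for EMD comparison)
#' @param p \code{profile_1d}
#' @return normalized \code{profile_1d}
#' @export
normalize_profile <- function(p) {
  s <- sum(p$y)
  if (s <= 0) stop("cannot normalize a non-positive profile")
  profile_1d(p$x, p$y / s, p$width, p$xlab, "probability", normalized = TRUE)
}

#' Resample a profile onto a new uniform grid (linear interpolation)
#' @param p \code{profile_1d}
#' @param x new bin centers
#' @return \code{profile_1d} on the new grid
#' @export
resample_profile <- function(p, x) {
  y <- stats::approx(p$x, p$y, xout = x, rule = 2)$y
  profile_1d(x, y, x[2] - x[1], p$xlab, p$ylab, p$normalized)
}

#' Lateral (2-D) radial distribution function
#'
#' \code{g(r) = n(r, r + dr) / (rho 2 pi r dr)} with distances taken in the
#' membrane (xy) plane under minimum image and \code{rho} the 2-D number
#' density of the selection.
#'
#' @param snapshots list of N x 3 position matrices
#' @param types integer type index per bead
#' @param box box lengths, nm (per-frame boxes: list of vectors)
#' @param type_labels labels corresponding to type indices
#' @param selection bead label selected (default tail beads)
#' @param dr bin width, nm
#' @param r_max maximum distance (default smallest half box side)
#' @return \code{profile_1d} with g(r)
#' @export
lateral_rdf <- function(snapshots, types, box, type_labels = c("H", "T"),
                        selection = "T", dr = 0.05, r_max = NULL) {
  sel <- which(type_labels[types] == selection)
  if (length(sel) < 2) stop("empty or singleton selection")
  if (!is.list(box)) box <- rep(list(box), length(snapshots))
  if (is.null(r_max)) r_max <- min(box[[1]][1], box[[1]][2]) / 2
  edges <- seq(0, r_max, by = dr)
  centers <- edges[-1] - dr / 2
  gsum <- numeric(length(centers))
  for (f in seq_along(snapshots)) {
    pos <- snapshots[[f]][sel, , drop = FALSE]
    b <- box[[f]]
    n <- nrow(pos)
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    dx <- dx - b[1] * round(dx / b[1])
    dy <- dy - b[2] * round(dy / b[2])
    d <- sqrt(dx^2 + dy^2)[upper.tri(dx)]
    h <- graphics::hist(d[d < r_max], breaks = edges, plot = FALSE)$counts
    rho <- n / (b[1] * b[2])
    # each pair counted once; per-particle expectation uses 2 counts/pair
    gsum <- gsum + 2 * h / (n * rho * 2 * pi * centers * dr)
  }
  profile_1d(centers, gsum / length(snapshots), dr, "r_nm", "g_r")
}

#' Transverse mass density profile, centered on the instantaneous COM
#'
#' Per frame, all z coordinates are taken relative to the instantaneous
#' center of mass of the whole system; the selection's mass histogram is
#' averaged over frames (amu/nm^3, using the lateral box area).
#'
#' @param snapshots list of N x 3 position matrices
#' @param types integer type index per bead
#' @param masses per-bead masses, amu
#' @param box box lengths (or list per frame)
#' @param type_labels labels corresponding to type indices
#' @param selection bead label selected (default head beads)
#' @param dz bin width, nm
#' @param z_max half-extent of the profile, nm
#' @return \code{profile_1d} with mass density vs z
#' @export
density_profile <- function(snapshots, types, masses, box,
                            type_labels = c("H", "T"), selection = "H",
                            dz = 0.1, z_max = 5) {
  sel <- which(type_labels[types] == selection)
  if (length(sel) == 0) stop("empty selection")
  if (!is.list(box)) box <- rep(list(box), length(snapshots))
  edges <- seq(-z_max, z_max, by = dz)
  centers <- edges[-1] - dz / 2
  dsum <- numeric(length(centers))
  for (f in seq_along(snapshots)) {
    pos <- snapshots[[f]]
    b <- box[[f]]
    com_z <- sum(masses * pos[, 3]) / sum(masses)
    z <- pos[sel, 3] - com_z
    z <- z - b[3] * round(z / b[3])
    h <- graphics::hist(z[z >= -z_max & z < z_max], breaks = edges,
                        plot = FALSE)$counts
    dsum <- dsum + h * masses[sel][1] / (b[1] * b[2] * dz)
  }
  profile_1d(centers, dsum / length(snapshots), dz, "z_nm", "density_amu_nm3")
}

#' Earth Mover's Distance between two normalized 1-D profiles
#'
#' One-dimensional Wasserstein-1 distance
#' \code{sum |CDF_A - CDF_B| * bin width}; zero iff the distributions are
#' identical. Profiles must share a common grid (use
#' \code{resample_profile}); non-normalized inputs are normalized with a
#' warning.
#'
#' @param pa,pb \code{profile_1d} objects on the same grid
#' @return distance in the units of the profile axis
#' @export
emd <- function(pa, pb) {
  if (!isTRUE(all.equal(pa$x, pb$x)))
    stop("profiles are on different grids; resample first")
  if (!isTRUE(pa$normalized) || abs(sum(pa$y) - 1) > 1e-8) {
    if (abs(sum(pa$y) - 1) > 1e-8) warning("normalizing first profile")
    pa <- normalize_profile(pa)
  }
  if (!isTRUE(pb$normalized) || abs(sum(pb$y) - 1) > 1e-8) {
    if (abs(sum(pb$y) - 1) > 1e-8) warning("normalizing second profile")
    pb <- normalize_profile(pb)
  }
  sum(abs(cumsum(pa$y - pb$y))) * pa$width
}

#' Seven-property report for one parameter set
#'
#' Collects the scalar observables (and their uncertainties) plus the RDF
#' and density profiles produced by a protocol tier.
#'
#' @param apl,ka,lt,kc,ptt scalars (NA when the tier does not measure them)
#' @param rdf,density \code{profile_1d} or NULL
#' @param errors named numeric vector of standard errors
#' @param tier protocol tier tag
#' @return object of class \code{property_report}
#' @export
property_report <- function(apl = NA, ka = NA, lt = NA, kc = NA, ptt = NA,
                            rdf = NULL, density = NULL, errors = numeric(0),
                            tier = "desk") {
  structure(list(apl = apl, ka = ka, lt = lt, kc = kc, ptt = ptt,
                 rdf = rdf, density = density, errors = errors, tier = tier),
            class = "property_report")
}
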
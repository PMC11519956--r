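# Synthetic-data generators: every estimator is testable without running a
# simulation. Each generator is fully deterministic per seed.

#' Synthetic thermally fluctuating membrane surfaces with known rigidity
#'
#' Generates height fields whose Fourier amplitudes are independent
#' Gaussians with variance \code{1 / (L^2 kc q^4)} (kc in kBT), the inverse
#' of the continuum undulation law; the q = 0 amplitude is zero. Feeding the
#' fields to \code{undulation_spectrum} + \code{fit_bending_modulus} closes
#' the loop and must recover kc.
#'
#' @param kc bending modulus, kBT
#' @param L lateral box side, nm
#' @param N grid size
#' @param n_frames number of independent fields
#' @param seed seed
#' @return list of N x N height-field matrices, nm
#' @export
synth_helfrich_surfaces <- function(kc, L = 40, N = 64, n_frames = 500,
                                    seed = 1) {
  if (kc <= 0) stop("kc must be positive")
  set.seed(seed)
  k <- c(0:(N %/% 2), -((N - N %/% 2 - 1):1))
  kx <- matrix(k, N, N)
  ky <- t(kx)
  q <- 2 * pi * sqrt(kx^2 + ky^2) / L
  sigma <- ifelse(q > 0, sqrt(1 / (L^2 * kc * q^4)), 0)
  lapply(seq_len(n_frames), function(f) {
    # FFT of white noise has Hermitian symmetry and unit variance after /N,
    # so scaling by sigma gives exactly the target mode variances
    w <- matrix(stats::rnorm(N * N), N, N)
    U <- stats::fft(w) / N * sigma
    Re(stats::fft(U, inverse = TRUE))
  })
}

#' Synthetic step-enthalpy series across a transition
#'
#' Per-temperature enthalpy time series with a low plateau below the
#' programmed transition temperature and a high plateau above, plus additive
#' Gaussian noise. \code{detect_transition} must recover the midpoint.
#'
#' @param temperatures temperature grid, K
#' @param T_transition programmed transition temperature, K
#' @param gap plateau separation (enthalpy units)
#' @param noise additive Gaussian noise sd
#' @param n series length per temperature
#' @param seed seed
#' @return named list of numeric series, in grid order
#' @export
synth_step_enthalpy <- function(temperatures, T_transition = 250, gap = 100,
                                noise = 1, n = 500, seed = 1) {
  set.seed(seed)
  out <- lapply(temperatures, function(Tk) {
    level <- if (Tk < T_transition) 0 else gap
    level + 0.2 * (Tk - T_transition) + stats::rnorm(n, 0, noise)
  })
  names(out) <- as.character(temperatures)
  out
}

#' Synthetic Gaussian box-length series
#'
#' Stationary Gaussian \code{Lx} series for exercising the fluctuation-based
#' area-compressibility estimator against its closed form.
#'
#' @param n series length
#' @param mean mean box length, nm
#' @param sd standard deviation, nm
#' @param seed seed
#' @return data.frame with columns \code{time}, \code{Lx}, \code{Ly}, \code{Lz}
#' @export
synth_gaussian_box_series <- function(n = 1e6, mean = 8, sd = 0.1, seed = 1) {
  set.seed(seed)
  Lx <- stats::rnorm(n, mean, sd)
  data.frame(time = seq_len(n), Lx = Lx, Ly = Lx, Lz = 10)
}

#' Synthetic pressure-tensor series for a ribbon
#'
#' Gaussian fluctuations around prescribed diagonal components; used to
#' exercise the line-tension arithmetic.
#'
#' @param n series length
#' @param P mean \code{c(Pxx, Pyy, Pzz)}, bar
#' @param noise fluctuation sd, bar
#' @param Lx,Lz box dimensions, nm
#' @param seed seed
#' @return data.frame in \code{run_ld} frame layout
#' @export
synth_pressure_series <- function(n = 1000, P = c(0, -10, 0), noise = 0,
                                  Lx = 10, Lz = 10, seed = 1) {
  set.seed(seed)
  data.frame(time = seq_len(n), Lx = Lx, Ly = Lx, Lz = Lz,
             Pxx = stats::rnorm(n, P[1], noise),
             Pyy = stats::rnorm(n, P[2], noise),
             Pzz = stats::rnorm(n, P[3], noise))
}

#' Synthetic peptide end-to-end vectors with a prescribed tilt distribution
#'
#' Unit vectors whose angle to +z is drawn from N(mean, sd) (degrees), with
#' uniform azimuth; exercises the tilt-angle estimator.
#'
#' @param n number of frames
#' @param mean mean tilt, degrees
#' @param sd tilt sd, degrees
#' @param seed seed
#' @return n x 3 matrix of vectors
#' @export
synth_tilt_vectors <- function(n = 1e4, mean = 30, sd = 10, seed = 1) {
  set.seed(seed)
  th <- stats::rnorm(n, mean, sd) * pi / 180
  phi <- stats::runif(n, 0, 2 * pi)
  cbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
}

#' Parametric reference curves standing in for atomistic target profiles
#'
#' Synthetic sum-of-Gaussian shapes with the qualitative features of an
#' atomistic POPC reference: a liquid-like tail-tail RDF (first peak near
#' the tail-bead contact distance, decaying oscillations) and a bimodal
#' head-group density profile. They are stand-ins constructed for testing
#' the comparison machinery, not measured atomistic data; the EMD scoring is
#' agnostic to the reference source.
#'
#' @param dr,dz bin widths matching the estimator defaults
#' @param r_max,z_max grid extents
#' @return \code{profile_1d}
#' @export
reference_rdf <- function(dr = 0.05, r_max = 4) {
  r <- seq(dr / 2, r_max - dr / 2, by = dr)
  g <- 1 +
    1.8 * exp(-(r - 1.10)^2 / (2 * 0.16^2)) -
    0.45 * exp(-(r - 1.65)^2 / (2 * 0.22^2)) +
    0.25 * exp(-(r - 2.15)^2 / (2 * 0.25^2))
  g[r < 0.8] <- g[r < 0.8] * exp(-((0.8 - r[r < 0.8]) / 0.1)^2)
  profile_1d(r, g, dr, "r_nm", "g_r")
}

#' @rdname reference_rdf
#' @export
reference_density <- function(dz = 0.1, z_max = 5) {
  z <- seq(-z_max + dz / 2, z_max - dz / 2, by = dz)
  d <- 260 * (exp(-(z - 1.52)^2 / (2 * 0.35^2)) +
              exp(-(z + 1.52)^2 / (2 * 0.35^2)))
  profile_1d(z, d, dz, "z_nm", "density_amu_nm3")
}
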
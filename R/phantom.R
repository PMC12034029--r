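#' Ellipse phantom definitions
#'
#' The standard Shepp-Logan head phantom as a table of ten ellipses with
#' additive intensities, scaled to the unit field of view (the classic
#' definition lives on [-1, 1], so all lengths are halved). Each row gives
#' the center (`x`, `y`), semi-axes (`a`, `b`), rotation `phi_deg`
#' (counter-clockwise) and additive intensity `A`.
#'
#' @return data.frame of class `ellipse_phantom`.
#' @export
shepp_logan <- function() {
  # classic parameter set (intensities 2 / -0.98 / -0.02 / 0.01), FOV-scaled
  p <- data.frame(
    x = c(0, 0, 0.11, -0.11, 0, 0, 0, -0.04, 0, 0.03),
    y = c(0, -0.0092, 0, 0, 0.175, 0.05, -0.05, -0.3025, -0.3025, -0.3025),
    a = c(0.345, 0.3312, 0.155, 0.205, 0.105, 0.023, 0.023, 0.023, 0.0115,
          0.0115),
    b = c(0.46, 0.437, 0.055, 0.08, 0.125, 0.023, 0.0115, 0.0115, 0.0115,
          0.023),
    phi_deg = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0),
    A = c(2, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01)
  )
  class(p) <- c("ellipse_phantom", "data.frame")
  p
}

#' @exportS3Method base::print
print.ellipse_phantom <- function(x, ...) {
  cat(sprintf("ellipse phantom: %d ellipses, integrated intensity %.5f\n",
              nrow(x), phantom_integral(x)))
  NextMethod()
}

#' Integrated intensity of an ellipse phantom
#'
#' Sum over ellipses of `pi * a * b * A`; equals the k-space value at k = 0.
#'
#' @param phantom an [shepp_logan()]-style data.frame.
#' @return scalar integral.
#' @export
phantom_integral <- function(phantom) {
  sum(pi * phantom$a * phantom$b * phantom$A)
}

#' Analytic k-space of an ellipse phantom
#'
#' Closed-form Fourier transform of each ellipse, summed: a centered unit
#' disc transforms to the jinc kernel \eqn{J_1(2\pi\gamma)/\gamma}; scaling,
#' rotation and translation enter as axis stretches and a linear phase.
#' Exact up to floating point, so it provides simulation data free of
#' gridding error ("inverse crime"-free for gridding reconstructions).
#'
#' @param phantom an ellipse table as from [shepp_logan()].
#' @param traj a `raga_trajectory`.
#' @param noise_sd standard deviation of complex white Gaussian noise added
#'   per sample (default 0, noiseless).
#' @param seed RNG seed, required when `noise_sd > 0`.
#' @return Object of class `kspace_data`: list with `samples` (complex
#'   spokes x samples matrix) and `traj`.
#' @export
analytic_kspace <- function(phantom, traj, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(traj, "raga_trajectory"))
  kx <- traj$coords[, , 1]
  ky <- traj$coords[, , 2]
  s <- matrix(0 + 0i, nrow = nrow(kx), ncol = ncol(kx))
  for (e in seq_len(nrow(phantom))) {
    th <- phantom$phi_deg[e] * pi / 180
    # rotate k into the ellipse frame, stretch by the semi-axes
    ku <- cos(th) * kx + sin(th) * ky
    kv <- -sin(th) * kx + cos(th) * ky
    gamma <- sqrt((phantom$a[e] * ku)^2 + (phantom$b[e] * kv)^2)
    jinc <- ifelse(gamma < 1e-12, pi, besselJ(2 * pi * gamma, 1) / gamma)
    phase <- exp(-2i * pi * (kx * phantom$x[e] + ky * phantom$y[e]))
    s <- s + phantom$A[e] * phantom$a[e] * phantom$b[e] * jinc * phase
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("adding noise requires an explicit 'seed'")
    withr_seed <- .Random.seed_exists()
    old <- if (withr_seed) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    s <- s + noise_sd * (matrix(stats::rnorm(length(s)), nrow = nrow(s)) +
                           1i * matrix(stats::rnorm(length(s)), nrow = nrow(s)))
    if (withr_seed) assign(".Random.seed", old, envir = globalenv())
  }
  structure(list(samples = s, traj = traj), class = "kspace_data")
}

.Random.seed_exists <- function() {
  exists(".Random.seed", envir = globalenv(), inherits = FALSE)
}

#' @exportS3Method base::print
print.kspace_data <- function(x, ...) {
  cat(sprintf("k-space data: %d spokes x %d samples, |S(0)| ~ %.4f\n",
              nrow(x$samples), ncol(x$samples), max(Mod(x$samples))))
  invisible(x)
}

#' Rasterized phantom image
#'
#' Pixel-center evaluation of the additive ellipse intensities on an m x m
#' grid over the unit FOV; reference for reconstruction error measures.
#'
#' @param phantom ellipse table.
#' @param m grid size.
#' @return m x m numeric matrix.
#' @export
rasterize_phantom <- function(phantom, m) {
  x <- (seq_len(m) - 1 - m / 2) / m
  X <- matrix(x, m, m)
  Y <- matrix(x, m, m, byrow = TRUE)
  img <- matrix(0, m, m)
  for (e in seq_len(nrow(phantom))) {
    th <- phantom$phi_deg[e] * pi / 180
    dx <- X - phantom$x[e]
    dy <- Y - phantom$y[e]
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    img <- img + phantom$A[e] * ((u / phantom$a[e])^2 +
                                   (v / phantom$b[e])^2 <= 1)
  }
  img
}

#' Density-compensated adjoint reconstruction
#'
#' Gridded (or direct) adjoint non-uniform Fourier transform of
#' density-compensated radial data onto an `grid_size` x `grid_size` image.
#' Density compensation uses the standard radial ramp `|k|` (area element of
#' polar sampling) with the DC sample weighted at 1/8 of the first ring, and
#' overall scaling `dk * dtheta` so intensities approximate the phantom's.
#'
#' @param kdata a [analytic_kspace()] result, or a complex matrix matching
#'   the trajectory layout.
#' @param traj trajectory (defaults to `kdata$traj`).
#' @param grid_size image size (default base resolution `m`).
#' @param method `"nufft"` or `"direct"`.
#' @param dc_weight weight of the k = 0 sample relative to the first ring
#'   (default 1/8).
#' @return Object of class `raga_image`: list with `image` (magnitude
#'   matrix), `complex_image`, `grid_size`.
#' @export
adjoint_reconstruct <- function(kdata, traj = NULL, grid_size = NULL,
                                method = c("nufft", "direct"),
                                dc_weight = 1 / 8) {
  method <- match.arg(method)
  if (inherits(kdata, "kspace_data")) {
    if (is.null(traj)) traj <- kdata$traj
    samples <- kdata$samples
  } else {
    samples <- kdata
  }
  stopifnot(inherits(traj, "raga_trajectory"))
  if (!all(dim(samples) == dim(traj$coords)[1:2])) {
    stop("k-space data shape does not match the trajectory")
  }
  if (is.null(grid_size)) grid_size <- traj$readout$m
  kx <- as.vector(traj$coords[, , 1])
  ky <- as.vector(traj$coords[, , 2])
  kr <- sqrt(kx^2 + ky^2)
  n_spokes <- dim(traj$coords)[1]
  dk <- traj$readout$m / traj$readout$n_samples
  w <- kr * dk * (pi / n_spokes)
  w[kr == 0] <- dc_weight * dk * dk * (pi / n_spokes)
  # coords and samples both flatten spoke-fastest (column-major)
  vals <- as.vector(samples) * w
  f <- switch(method,
    nufft = nufft_adjoint(kx, ky, vals, grid_size),
    direct = nufft_adjoint_direct(kx, ky, vals, grid_size)
  )
  structure(list(image = Mod(f), complex_image = f, grid_size = grid_size),
            class = "raga_image")
}

#' @exportS3Method base::print
print.raga_image <- function(x, ...) {
  cat(sprintf("reconstructed image %d x %d, intensity range [%.4g, %.4g]\n",
              x$grid_size, x$grid_size, min(x$image), max(x$image)))
  invisible(x)
}

#' Normalized root-mean-square error
#'
#' `||a - b|| / ||b||` over all pixels.
#'
#' @param a,b equally sized numeric matrices.
#' @return scalar NRMSE.
#' @export
nrmse <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sqrt(sum((a - b)^2) / sum(b^2))
}

#' PSF-sharing advantage of a periodic scheme
#'
#' When binning `n_frames` consecutive frames of `p` spokes, a periodic RAGA
#' scheme revisits the same per-frame sampling pattern after
#' `period / gcd(period, p)` frames, so only that many PSFs (or Toeplitz
#' kernels, interpolation weights, ...) must ever be computed. The irrational
#' golden-ratio counterpart never repeats an angle: every frame needs its own
#' PSF.
#'
#' @param scheme a [raga_scheme()].
#' @param p spokes per frame.
#' @param n_frames number of frames reconstructed.
#' @return list with `n_distinct_psfs` (RAGA) and `golden_equivalent`
#'   (= `n_frames`).
#' @examples
#' s <- raga_scheme(2, 13)  # period 377
#' psf_sharing_demo(s, 29, 100)  # 13 vs 100
#' @export
psf_sharing_demo <- function(scheme, p, n_frames) {
  list(n_distinct_psfs = min(distinct_frame_patterns(scheme, p), n_frames),
       golden_equivalent = n_frames)
}
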
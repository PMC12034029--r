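#' Readout specification for radial spokes
#'
#' Each spoke is sampled symmetrically through the k-space center with
#' `m * oversampling` samples at radial pitch `1/oversampling` cycles/FOV, so
#' the maximum sampled frequency is `m/2` regardless of oversampling. The
#' sample at position `n_samples/2` (0-based) is exactly k = 0.
#'
#' @param m base resolution (matrix size).
#' @param oversampling readout oversampling factor, at least 1 (default 2).
#' @return An object of class `readout_spec`: list with `m`, `oversampling`,
#'   `n_samples`, `radii` (cycles/FOV).
#' @export
readout_spec <- function(m, oversampling = 2) {
  stopifnot(m >= 2, m == floor(m), oversampling >= 1)
  n <- m * oversampling
  if (n %% 2 != 0) stop("m * oversampling must be even")
  radii <- (seq_len(n) - 1 - n / 2) * (m / n)
  structure(list(m = m, oversampling = oversampling, n_samples = n,
                 radii = radii),
            class = "readout_spec")
}

new_trajectory <- function(angles_deg, t, readout, scheme = NULL) {
  th <- angles_deg * pi / 180
  # coords[spoke, sample, 1:2] in cycles/FOV
  kx <- outer(cos(th), readout$radii)
  ky <- outer(sin(th), readout$radii)
  coords <- array(c(kx, ky), dim = c(length(angles_deg), readout$n_samples, 2))
  structure(list(coords = coords, angles_deg = angles_deg,
                 acquisition_order = t, readout = readout, scheme = scheme),
            class = "raga_trajectory")
}

#' @exportS3Method base::print
print.raga_trajectory <- function(x, ...) {
  cat(sprintf("radial trajectory: %d spokes x %d samples (m = %d, os = %g)\n",
              nrow(x$coords), x$readout$n_samples, x$readout$m,
              x$readout$oversampling))
  if (!is.null(x$scheme)) {
    cat(sprintf("  scheme: psi_%d^%d (%s)\n", x$scheme$i, x$scheme$N,
                x$scheme$variant))
  }
  cat(sprintf("  first angles (deg): %s\n",
              paste(sprintf("%.2f", utils::head(x$angles_deg, 5)),
                    collapse = ", ")))
  invisible(x)
}

#' Equidistant angular trajectory
#'
#' `S` spokes homogeneously distributed over a half or full circle, spoke `n`
#' (0-based) at angle `n * 180/S` or `n * 360/S` degrees. Angles are measured
#' counter-clockwise from the +kx axis.
#'
#' @param S number of spokes.
#' @param readout a [readout_spec()].
#' @param coverage `"half_circle"` or `"full_circle"`.
#' @return A `raga_trajectory`.
#' @examples
#' equidistant_trajectory(5, readout_spec(16))$angles_deg  # 0 36 72 108 144
#' @export
equidistant_trajectory <- function(S, readout,
                                   coverage = c("half_circle", "full_circle")) {
  coverage <- match.arg(coverage)
  stopifnot(S >= 1, S == floor(S))
  step <- if (coverage == "half_circle") 180 / S else 360 / S
  n <- seq_len(S) - 1
  new_trajectory(n * step, t = n, readout = readout)
}

#' RAGA-ordered trajectory
#'
#' Spoke `t` is placed at `spoke_angle(t, scheme)`: every coordinate is drawn
#' from the same finite angle set as the matching equidistant trajectory, in
#' golden-angle-like temporal order.
#'
#' @param scheme a [raga_scheme()].
#' @param n_spokes number of consecutive spokes (temporal indices 0 ...).
#' @param readout a [readout_spec()].
#' @param offset starting temporal index (default 0).
#' @return A `raga_trajectory` carrying the scheme as provenance.
#' @export
raga_trajectory <- function(scheme, n_spokes, readout, offset = 0) {
  stopifnot(inherits(scheme, "raga_scheme"), n_spokes >= 1)
  t <- offset + seq_len(n_spokes) - 1
  new_trajectory(spoke_angle(t, scheme), t = t, readout = readout,
                 scheme = scheme)
}

#' Irrational golden-ratio trajectory
#'
#' Spoke `t` at angle `(t * psi_N) mod 360` degrees (`2 psi_N` for the
#' doubled variant), evaluated at double precision with the multiplicative
#' formula. This is the irrational scheme that RAGA approximates; unlike
#' RAGA its angle set never repeats.
#'
#' @param N tiny golden-angle index.
#' @param n_spokes number of spokes.
#' @param readout a [readout_spec()].
#' @param doubled use the doubled angle.
#' @param offset starting temporal index.
#' @return A `raga_trajectory`.
#' @export
golden_trajectory <- function(N, n_spokes, readout, doubled = FALSE,
                              offset = 0) {
  stopifnot(n_spokes >= 1)
  t <- offset + seq_len(n_spokes) - 1
  ang <- (t * golden_angle_deg(N, doubled)) %% 360
  new_trajectory(ang, t = t, readout = readout)
}
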
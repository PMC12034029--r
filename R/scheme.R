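#' Construct a resolved RAGA sampling scheme
#'
#' A RAGA (rational approximation of golden angles) scheme reorders the
#' spokes of an equidistant angular pattern so that temporally consecutive
#' spokes are separated by approximately a golden-ratio angle. It is fully
#' determined by two integers: the full-frame size \eqn{S = G_i^N} (the
#' number of equidistant angles) and the index increment \eqn{G_{i-1}^1}
#' between consecutive acquisitions. Three variants are supported:
#'
#' * `"half_circle"`: indices 0..S-1 over a half circle, base angle 180/S
#'   degrees. Reordering full-circle acquisitions into this pattern flips
#'   half of the readouts.
#' * `"extended"`: indices 0..2S-1 over the full circle with the same base
#'   angle; index n and n + S denote the same projection with opposite
#'   readout direction, which avoids flipped readouts.
#' * `"doubled"`: indices 0..S-1 over the full circle (base angle 360/S),
#'   approximating the doubled angle \eqn{2\psi_N}; requires S odd.
#'
#' The increment and S are always coprime, so the temporal index map is a
#' bijection onto the index space per period. In the extended variant with an
#' even increment the reachable indices are the even ones only: the scheme
#' still acquires S distinct projections (without opposing partners) and its
#' period is S, which is flagged with a warning because the full-circle index
#' space is then not exhausted.
#'
#' @param N tiny golden-angle index (positive integer).
#' @param i approximation order, at least 2.
#' @param variant `"half_circle"`, `"extended"` or `"doubled"`.
#' @param increment override for the index increment; the default is
#'   \eqn{G_{i-1}^1}. A hand-crafted increment not coprime with the frame
#'   size is rejected.
#' @return An object of class `raga_scheme` with fields `N`, `i`, `S`,
#'   `increment`, `index_space`, `base_angle_deg`, `variant`, `period`.
#' @examples
#' raga_scheme(1, 5)                 # S = 5, increment 3
#' raga_scheme(1, 13, "extended")    # S = 233, increment 144, space 466
#' @export
raga_scheme <- function(N, i, variant = c("half_circle", "extended", "doubled"),
                        increment = NULL) {
  variant <- match.arg(variant)
  ap <- raga_approx(N, i)
  S <- ap$denominator
  inc <- if (is.null(increment)) ap$numerator else increment
  if (exact_gcd(inc, S) != 1) {
    stop("increment ", inc, " and full-frame size ", S, " are not coprime; ",
         "the scheme would not visit every angle")
  }
  if (variant == "doubled" && S %% 2 == 0) {
    stop("doubled variant requires an odd full-frame size; G_", i, "^", N,
         " = ", S, " is even")
  }
  index_space <- if (variant == "extended") 2 * S else S
  base_angle <- if (variant == "doubled") 360 / S else 180 / S
  g <- exact_gcd(inc, index_space)
  period <- index_space / g
  if (variant == "extended" && g == 2) {
    warning("extended index space with an even increment: only the ", S,
            " even indices are reachable (period ", period,
            ", no opposing spoke pairs)")
  }
  structure(
    list(N = N, i = i, S = S, increment = inc, index_space = index_space,
         base_angle_deg = base_angle, variant = variant, period = period),
    class = "raga_scheme"
  )
}

#' @exportS3Method base::print
print.raga_scheme <- function(x, ...) {
  cat(sprintf("RAGA scheme psi_%d^%d (%s)\n", x$i, x$N, x$variant))
  cat(sprintf("  full frame S    : %d spokes\n", x$S))
  cat(sprintf("  increment       : %d\n", x$increment))
  cat(sprintf("  index space     : %d\n", x$index_space))
  cat(sprintf("  base angle      : %.6f deg\n", x$base_angle_deg))
  cat(sprintf("  period          : %d spokes\n", x$period))
  cat(sprintf("  angle increment : %.6f deg (target %.6f deg)\n",
              (x$increment * x$base_angle_deg) %% 360,
              golden_angle_deg(x$N, doubled = (x$variant == "doubled"))))
  invisible(x)
}

#' Temporal index to equidistant spoke index
#'
#' The spoke acquired at temporal index `t` has equidistant-pattern index
#' \eqn{ind_t = (t \cdot G_{i-1}^1) \bmod M} where M is the index space.
#' Pure integer arithmetic; the result is bitwise reproducible across
#' platforms. `t` is 0-based.
#'
#' @param t non-negative temporal index (vectorized).
#' @param scheme a [raga_scheme()].
#' @return Integer-valued doubles in `[0, index_space)`.
#' @examples
#' s <- raga_scheme(1, 5)
#' spoke_index(0:4, s)  # 0 3 1 4 2
#' @export
spoke_index <- function(t, scheme) {
  stopifnot(inherits(scheme, "raga_scheme"))
  if (any(t < 0) || any(t != floor(t))) {
    stop("temporal index 't' must be a non-negative integer")
  }
  M <- scheme$index_space
  # reduce t first so the product stays exactly representable
  ((t %% M) * (scheme$increment %% M)) %% M
}

#' Spoke angle at a temporal index
#'
#' Index times base angle, in degrees within `[0, 360)`.
#'
#' @inheritParams spoke_index
#' @return Angles in degrees.
#' @examples
#' s <- raga_scheme(1, 5)
#' spoke_angle(1, s)  # 108 degrees = psi_5^1
#' @export
spoke_angle <- function(t, scheme) {
  spoke_index(t, scheme) * scheme$base_angle_deg
}

#' Verify bijectivity of the temporal index map
#'
#' Brute-force enumeration of one period of the index sequence, confirming
#' that each reachable index occurs exactly once per period, and counting the
#' distinct angular positions.
#'
#' @param scheme a [raga_scheme()].
#' @return A list with `bijective_over` (the period) and `distinct_angles`.
#' @export
verify_bijectivity <- function(scheme) {
  stopifnot(inherits(scheme, "raga_scheme"))
  ind <- spoke_index(seq_len(scheme$period) - 1, scheme)
  if (anyDuplicated(ind) > 0) {
    stop("index sequence revisits an index within one period")
  }
  ang <- ind * scheme$base_angle_deg
  list(bijective_over = scheme$period,
       distinct_angles = as.numeric(length(unique(ang))))
}

#' Recover the temporal index of an equidistant spoke
#'
#' Inverts the index map via the modular inverse of the increment: returns
#' the unique `t` in `[0, period)` with `spoke_index(t) == ind`. In the
#' extended variant with an even increment the odd indices are never
#' acquired and raise an error.
#'
#' @param ind equidistant spoke index (vectorized).
#' @param scheme a [raga_scheme()].
#' @return Temporal indices (integer-valued doubles).
#' @examples
#' s <- raga_scheme(1, 5)
#' invert_index(4, s)  # 3
#' @export
invert_index <- function(ind, scheme) {
  stopifnot(inherits(scheme, "raga_scheme"))
  M <- scheme$index_space
  if (any(ind < 0) || any(ind >= M) || any(ind != floor(ind))) {
    stop("'ind' must be an integer in [0, index_space)")
  }
  g <- exact_gcd(scheme$increment, M)
  if (any(ind %% g != 0)) {
    stop("index ", ind[which(ind %% g != 0)[1]],
         " is never acquired by this scheme")
  }
  Mg <- M / g
  vinv <- mod_inverse(scheme$increment / g, Mg)
  ((ind / g) %% Mg * vinv) %% Mg
}

# modular inverse by extended Euclid on exact integer-valued doubles
mod_inverse <- function(a, m) {
  t0 <- 0; t1 <- 1
  r0 <- m; r1 <- a %% m
  while (r1 != 0) {
    q <- r0 %/% r1
    tmp <- t0 - q * t1; t0 <- t1; t1 <- tmp
    tmp <- r0 - q * r1; r0 <- r1; r1 <- tmp
  }
  if (r0 != 1) stop("no modular inverse: gcd(", a, ", ", m, ") != 1")
  t0 %% m
}

#' Retrospective binning into frames
#'
#' Groups consecutive temporal indices into non-overlapping frames of
#' `spokes_per_frame` spokes each and returns, per frame, the set of
#' equidistant indices it contains — a sampling mask into a zero-filled full
#' frame. With `spokes_per_frame` equal to the period every frame is a full
#' frame; smaller bins trade k-space coverage for temporal resolution, and
#' the sequence of masks repeats with period
#' `distinct_frame_patterns(scheme, spokes_per_frame)`.
#'
#' @param scheme a [raga_scheme()].
#' @param spokes_per_frame positive integer bin size.
#' @param n_frames number of consecutive frames.
#' @param offset starting temporal index (default 0).
#' @return A list of `n_frames` sorted integer vectors (index sets).
#' @examples
#' s <- raga_scheme(1, 5)
#' bin_frames(s, 5, 2)   # both frames are the complete index set 0..4
#' @export
bin_frames <- function(scheme, spokes_per_frame, n_frames, offset = 0) {
  stopifnot(inherits(scheme, "raga_scheme"), spokes_per_frame >= 1,
            n_frames >= 1, offset >= 0)
  lapply(seq_len(n_frames) - 1, function(j) {
    t <- offset + j * spokes_per_frame + seq_len(spokes_per_frame) - 1
    sort(unique(spoke_index(t, scheme)))
  })
}

#' Fold extended-variant indices onto the half circle
#'
#' In the extended variant, indices `n` and `n + S` address the same
#' projection with flipped readout direction. This helper maps full-circle
#' indices to the half-circle index plus a readout-flip flag.
#'
#' @param ind extended indices in `[0, 2S)`.
#' @param scheme an extended-variant [raga_scheme()].
#' @return data.frame with columns `index` (in `[0, S)`) and `flipped`.
#' @export
fold_half_circle <- function(ind, scheme) {
  stopifnot(inherits(scheme, "raga_scheme"))
  if (scheme$variant != "extended") {
    stop("folding applies to the extended variant only")
  }
  data.frame(index = ind %% scheme$S, flipped = ind >= scheme$S)
}

#' Number of distinct frame sampling patterns
#'
#' When a periodic scheme is binned into consecutive frames of `p` spokes,
#' the per-frame index sets repeat after `period / gcd(period, p)` frames.
#' Only that many point-spread functions (or other per-pattern quantities)
#' ever occur, however long the acquisition. The closed form is cross-checked
#' by direct enumeration of the frame sets.
#'
#' @param scheme a [raga_scheme()].
#' @param p spokes per frame (positive integer).
#' @return Number of distinct per-frame patterns.
#' @examples
#' s <- raga_scheme(2, 13)            # period 377
#' distinct_frame_patterns(s, 29)     # 13
#' @export
distinct_frame_patterns <- function(scheme, p) {
  stopifnot(inherits(scheme, "raga_scheme"), p >= 1, p == floor(p))
  if (p >= scheme$period) return(1)  # every frame holds the full reachable set
  theory <- scheme$period / exact_gcd(scheme$period, p)
  n_check <- theory + 1
  masks <- bin_frames(scheme, p, n_check)
  keys <- vapply(masks, paste, character(1), collapse = ",")
  enumerated <- length(unique(keys))
  if (enumerated != theory || keys[theory + 1] != keys[1]) {
    stop("enumeration disagrees with period/gcd(period, p)")
  }
  theory
}
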
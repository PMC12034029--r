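#' Generalized Fibonacci numbers
#'
#' Computes \eqn{G_i^N} from the recursion \eqn{G_i = G_{i-1} + G_{i-2}} with
#' seeds \eqn{G_1 = 1} and \eqn{G_2 = N}. The series for \eqn{N = 1} is the
#' ordinary Fibonacci series; ratios of consecutive elements converge to the
#' golden-ratio angles used by radial sampling schemes. The recursion is
#' evaluated in exact arbitrary-precision integer arithmetic, so large orders
#' do not overflow or lose low digits.
#'
#' @param N positive integer seed of the series (tiny golden-angle index).
#' @param i positive integer order (1-based position in the series).
#' @param as return type: `"numeric"` (exact while below 2^53, the default)
#'   or `"character"` (exact decimal digits at any order).
#' @return The value \eqn{G_i^N} as a double or a decimal string.
#' @examples
#' fibonacci_general(1, 13)  # 233
#' fibonacci_general(7, 11)  # 419
#' @export
fibonacci_general <- function(N, i, as = c("numeric", "character")) {
  as <- match.arg(as)
  if (length(N) != 1L || length(i) != 1L || is.na(N) || is.na(i) ||
      N < 1 || i < 1 || N != floor(N) || i != floor(i)) {
    stop("'N' and 'i' must be positive integers")
  }
  a <- bi_from_num(1)            # G_1
  if (i == 1) {
    res <- a
  } else {
    b <- bi_from_num(N)          # G_2
    for (k in seq_len(i - 2L)) {
      nxt <- bi_add(a, b)
      a <- b
      b <- nxt
    }
    res <- b
  }
  if (as == "character") return(bi_to_string(res))
  if (!bi_fits_double(res)) {
    stop("G_", i, "^", N, " exceeds 2^53; use as = \"character\"")
  }
  bi_to_num(res)
}

#' Golden-ratio angles
#'
#' The N-th golden-ratio (tiny golden) angle \eqn{\psi_N = 180 / (\tau + N - 1)}
#' degrees, where \eqn{\tau = (1 + \sqrt 5)/2} is the golden ratio. `N = 1`
#' gives the classic 111.246 degrees between consecutive radial spokes;
#' larger `N` gives smaller increments with near-uniform k-space coverage.
#' The doubled variants \eqn{2\psi_N} distribute spokes over the full circle;
#' \eqn{2\psi_2 \approx 137.508} degrees is the conventional Golden Angle.
#'
#' @param N positive integer index.
#' @param doubled if `TRUE` return \eqn{2\psi_N}.
#' @return Angle in degrees.
#' @examples
#' golden_angle_deg(1)                 # 111.2461...
#' golden_angle_deg(2, doubled = TRUE) # 137.5077...
#' @export
golden_angle_deg <- function(N, doubled = FALSE) {
  if (any(N < 1) || any(N != floor(N))) stop("'N' must be a positive integer")
  tau <- (1 + sqrt(5)) / 2
  a <- 180 / (tau + N - 1)
  if (doubled) 2 * a else a
}

#' Rational approximation of a golden-ratio angle
#'
#' Approximates \eqn{\psi_N} by the rational angle
#' \eqn{\psi_i^N = 180 \cdot G_{i-1}^1 / G_i^N} degrees (twice that for the
#' doubled variant). The numerator is an ordinary Fibonacci number, the
#' denominator a generalized Fibonacci number; the two are always coprime,
#' which is what makes the resulting sampling scheme visit every angle of the
#' underlying equidistant pattern exactly once.
#'
#' @param N positive integer index of the approximated angle.
#' @param i approximation order, at least 2.
#' @param doubled if `TRUE` approximate \eqn{2\psi_N}.
#' @return An object of class `raga_approx`: a list with `N`, `i`,
#'   `numerator`, `denominator`, `angle_deg` and `doubled`.
#' @examples
#' raga_approx(1, 5)    # 3/5 = 108 degrees
#' raga_approx(1, 13)   # 144/233 = 111.245 degrees
#' @export
raga_approx <- function(N, i, doubled = FALSE) {
  if (length(i) != 1L || i < 2 || i != floor(i)) {
    stop("approximation order 'i' must be an integer >= 2")
  }
  num <- fibonacci_general(1, i - 1)
  den <- fibonacci_general(N, i)
  if (exact_gcd(num, den) != 1) {
    stop("internal error: numerator and denominator are not coprime")
  }
  angle <- 180 * num / den
  if (doubled) angle <- 2 * angle
  structure(
    list(N = N, i = i, numerator = num, denominator = den,
         angle_deg = angle, doubled = doubled),
    class = "raga_approx"
  )
}

#' @exportS3Method base::print
print.raga_approx <- function(x, ...) {
  lab <- if (x$doubled) sprintf("2 psi_%d^%d", x$i, x$N) else
    sprintf("psi_%d^%d", x$i, x$N)
  cat(sprintf("%s = %s180 * %d/%d = %.3f deg  (target %.3f deg)\n",
              lab, if (x$doubled) "2 * " else "",
              x$numerator, x$denominator, x$angle_deg,
              golden_angle_deg(x$N, x$doubled)))
  invisible(x)
}

# exact Euclid on integer-valued doubles
exact_gcd <- function(a, b) {
  while (b != 0) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  a
}

#' Minimum spoke count satisfying the radial Nyquist criterion
#'
#' For base resolution (matrix size) `m` the azimuthal sampling distance at
#' the k-space edge matches the radial one when the number of distinct
#' projections S satisfies \eqn{S \ge \pi m / 2} for a half-circle pattern,
#' and for full-circle patterns \eqn{S \ge \pi m / 2} when S is odd (opposing
#' half-spokes interleave) but \eqn{S \ge \pi m} when S is even (spokes come
#' in collinear pairs). Returns the smallest integer satisfying the bound
#' (its ceiling). `nyquist_as_printed()` returns the nearest integer instead,
#' matching the conventional "at least 314 projections for m = 200" phrasing.
#'
#' @param m base resolution (matrix size), at least 2.
#' @param coverage `"half_circle"` or `"full_circle"`.
#' @param parity spoke-count parity, only relevant for full-circle coverage.
#' @return Smallest admissible spoke count (integer-valued double).
#' @examples
#' nyquist_min_spokes(200)                         # 315
#' nyquist_min_spokes(200, "full_circle", "even")  # 629
#' nyquist_as_printed(200)                         # 314
#' @export
nyquist_min_spokes <- function(m, coverage = c("half_circle", "full_circle"),
                               parity = c("odd", "even")) {
  coverage <- match.arg(coverage)
  parity <- match.arg(parity)
  if (length(m) != 1L || is.na(m) || m < 2) stop("'m' must be at least 2")
  ceiling(nyquist_bound(m, coverage, parity))
}

#' @rdname nyquist_min_spokes
#' @export
nyquist_as_printed <- function(m, coverage = c("half_circle", "full_circle"),
                               parity = c("odd", "even")) {
  coverage <- match.arg(coverage)
  parity <- match.arg(parity)
  if (length(m) != 1L || is.na(m) || m < 2) stop("'m' must be at least 2")
  round(nyquist_bound(m, coverage, parity))
}

nyquist_bound <- function(m, coverage, parity) {
  if (coverage == "full_circle" && parity == "even") pi * m else pi * m / 2
}

#' Automatic approximation-order selection
#'
#' Chooses the smallest approximation order `i` whose full-frame size
#' \eqn{S = G_i^N} provides enough distinct projection angles to satisfy the
#' radial Nyquist criterion for base resolution `m`. For the doubled variant
#' only odd S qualify (even S would pair collinear spokes). Beyond this order,
#' additional distinct angles add no information, so the order is not a free
#' parameter of the scheme: the angle index N and the resolution determine it.
#'
#' @param N positive integer angle index.
#' @param m base resolution.
#' @param variant scheme variant the order is selected for.
#' @return The order `i` (integer-valued double) with attribute `"S"` giving
#'   the selected full-frame size.
#' @examples
#' auto_order(1, 200)               # order 13, S = 377... attr S
#' auto_order(7, 200, "doubled")    # S = 419
#' @export
auto_order <- function(N, m, variant = c("half_circle", "extended", "doubled")) {
  variant <- match.arg(variant)
  bound <- nyquist_bound(m, "half_circle", "odd")  # odd-case limit pi m / 2
  i <- 2
  repeat {
    S <- fibonacci_general(N, i)
    if (S >= ceiling(bound) && (variant != "doubled" || S %% 2 == 1)) break
    i <- i + 1
    if (i > 200) stop("order search did not terminate")  # unreachable
  }
  structure(i, S = S)
}

#' Golden-angle approximation table
#'
#' Regenerates the reference table of rational golden-angle approximations:
#' every combination of approximation order and angle index, with the
#' Fibonacci fraction and the approximate angle in degrees.
#'
#' @param orders integer vector of approximation orders (default 2 to 14).
#' @param N integer vector of angle indices (default 1 to 7).
#' @return A data.frame with columns `i`, `N`, `numerator`, `denominator`,
#'   `angle_deg` (full precision) and `angle_printed` (three decimals,
#'   rounding half away from zero as in printed tables).
#' @export
angle_table <- function(orders = 2:14, N = 1:7) {
  grid <- expand.grid(i = orders, N = N)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    ap <- raga_approx(grid$N[r], grid$i[r])
    data.frame(i = ap$i, N = ap$N, numerator = ap$numerator,
               denominator = ap$denominator, angle_deg = ap$angle_deg,
               angle_printed = round_away(ap$angle_deg, 3))
  })
  do.call(rbind, rows)
}

#' Single and doubled golden-ratio angle table
#'
#' @param N_single indices for the single angles (default 1 to 7).
#' @param N_doubled indices for the doubled angles (default 1 to 14).
#' @return A data.frame with columns `N`, `doubled`, `angle_deg`,
#'   `angle_printed` (three decimals).
#' @export
golden_table <- function(N_single = 1:7, N_doubled = 1:14) {
  out <- rbind(
    data.frame(N = N_single, doubled = FALSE,
               angle_deg = golden_angle_deg(N_single)),
    data.frame(N = N_doubled, doubled = TRUE,
               angle_deg = golden_angle_deg(N_doubled, doubled = TRUE))
  )
  out$angle_printed <- round_away(out$angle_deg, 3)
  out
}

# round half away from zero (printed-table convention; R's round() is
# half-to-even)
round_away <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
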
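# Floating-point drift audit of golden-angle computation.
#
# Golden-ratio sampling needs an irrational angle constant; repeated
# accumulation (or one large product) in finite precision drifts away from
# the true spoke angle, and the drift grows with the acquisition length. A
# RAGA scheme only ever multiplies a small exact integer index by a fixed
# base angle, so its error stays at machine-epsilon scale forever. The
# emulation below reproduces the published comparison: every intermediate is
# rounded to IEEE single or double precision (see src/emulate.cpp), and
# errors are measured against an extended-precision fixed-point reference
# that shares no code with R's double arithmetic.

golden_psi_fx <- function(N, digits, doubled = FALSE) {
  tau <- fx_tau(digits)
  den <- fx_add(tau, fx_from_num(N - 1, digits))
  psi <- fx_div(fx_from_num(180, digits), den)
  if (doubled) psi <- fx_mul_small(psi, 2)
  psi
}

#' Extended-precision reference spoke angle
#'
#' The true angle of spoke `t` in degrees, computed without accumulating
#' floating-point error: for the golden-ratio source, `(t * psi_N) mod 360`
#' in fixed-point arithmetic at `digits` decimal digits (the golden ratio is
#' derived from an arbitrary-precision integer square root); for the RAGA
#' source, the exact integer spoke index times the rational base angle.
#'
#' @param t non-negative temporal index (vectorized).
#' @param source `"golden"` or `"raga"`.
#' @param N golden-angle index (golden source).
#' @param scheme a [raga_scheme()] (raga source).
#' @param doubled use the doubled golden angle (golden source).
#' @param digits working precision in decimal digits (default 50).
#' @return Angles in degrees (doubles), with attribute `"strings"` carrying
#'   the full-precision decimal representations.
#' @examples
#' reference_angle(10000)  # 61.1797... for the classic golden angle
#' @export
reference_angle <- function(t, source = c("golden", "raga"), N = 1,
                            scheme = NULL, doubled = FALSE, digits = 50) {
  source <- match.arg(source)
  if (any(t < 0) || any(t != floor(t))) stop("'t' must be non-negative")
  fxs <- reference_angle_fx(t, source, N, scheme, doubled, digits)
  out <- vapply(fxs, fx_to_num, numeric(1))
  attr(out, "strings") <- vapply(fxs, fx_to_string, character(1))
  out
}

reference_angle_fx <- function(t, source, N = 1, scheme = NULL,
                               doubled = FALSE, digits = 50) {
  if (source == "golden") {
    psi <- golden_psi_fx(N, digits, doubled)
    lapply(t, function(tt) {
      # reduce t so the small-integer multiplication stays in range
      fx_mod_positive(fx_mul_small_big(psi, tt), 360)
    })
  } else {
    stopifnot(inherits(scheme, "raga_scheme"))
    ind <- spoke_index(t, scheme)
    num <- base_angle_numerator(scheme)
    lapply(ind, function(k) {
      fx_mod_positive(fx_div_small(fx_from_num(k * num, digits), scheme$S),
                      360)
    })
  }
}

# multiply fx by a possibly large exact integer (splits into safe chunks)
fx_mul_small_big <- function(a, s) {
  if (s < 9e8) return(fx_mul_small(a, s))
  hi <- floor(s / 1e8)
  lo <- s - hi * 1e8
  fx_add(fx_mul_small(fx_mul_small(a, 1e8), hi), fx_mul_small(a, lo))
}

# numerator of the base angle in degrees: 180 (half/extended) or 360 (doubled)
base_angle_numerator <- function(scheme) {
  if (scheme$variant == "doubled") 360 else 180
}

#' Emulated spoke angle under a finite-precision update rule
#'
#' Evaluates one of the angle computation strategies with every intermediate
#' rounded to IEEE single or double precision:
#'
#' * `"multiplicative"`: \eqn{\phi_t = (t \cdot \psi_1) \bmod 2\pi}, one
#'   rounded product followed by an exact-remainder `fmod` with the rounded
#'   two-pi constant.
#' * `"additive"`: \eqn{\phi_t = \phi_{t-1} + \psi_1}, strictly sequential.
#' * `"additive_mod"`: as `"additive"` with subtraction of the same-precision
#'   two-pi constant after each update.
#' * `"raga"`: exact integer index times the rounded base angle
#'   \eqn{\pi / S} of `scheme`.
#'
#' The golden-angle rules implement the classic `N = 1` constant (double:
#' `pi / ((1 + sqrt(5))/2)`; single: computed entirely in float32 as
#' `pi * (sqrt(5) - 1) / 2`).
#'
#' @param t non-negative temporal indices (vectorized, ascending for the
#'   additive rules).
#' @param rule update rule, see above.
#' @param precision `"single"` or `"double"`.
#' @param scheme a [raga_scheme()] (required for `rule = "raga"`).
#' @return Emulated angles in radians (doubles holding the exact emulated
#'   values; single-precision values are exactly representable).
#' @export
emulated_angle <- function(t, rule = c("multiplicative", "additive",
                                       "additive_mod", "raga"),
                           precision = c("double", "single"), scheme = NULL) {
  rule <- match.arg(rule)
  precision <- match.arg(precision)
  single <- precision == "single"
  if (any(t < 0) || any(t != floor(t))) stop("'t' must be non-negative")
  switch(rule,
    multiplicative = {
      cst <- golden_constants_cpp()
      twopi <- if (single) cst$twopi_single else cst$twopi_double
      # %% on positive doubles is the exact libm remainder; the exact result
      # of a float32 remainder is float32-representable, so this reproduces
      # the single-precision fmod bit-for-bit as well
      emulate_product_cpp(t, single) %% twopi
    },
    additive = ,
    additive_mod = {
      o <- order(t)
      res <- numeric(length(t))
      res[o] <- emulate_additive_cpp(sort(t), rule == "additive_mod", single)
      res
    },
    raga = {
      stopifnot(inherits(scheme, "raga_scheme"))
      S_half <- if (scheme$variant == "doubled") scheme$S / 2 else scheme$S
      emulate_raga_cpp(spoke_index(t, scheme), S_half, single)
    })
}

# error of an emulated radian angle against a reference fx angle in degrees:
# (ref mod 360) - (emulated_deg mod 360), in (-360, 360), no re-wrapping
# (matching the published convention); the radian-to-degree conversion is one
# double multiplication by fl(180/pi)
drift_error <- function(emu_rad, ref_fx, digits = 50) {
  emu_deg <- emu_rad * (180 / pi)
  vapply(seq_along(emu_rad), function(k) {
    e <- fx_mod_positive(fx_from_dyadic(emu_deg[k], digits), 360)
    fx_to_num(fx_sub(ref_fx[[k]], e))
  }, numeric(1))
}

#' Angle drift table across precisions and update rules
#'
#' Reproduces the numerical-stability comparison: reference golden-ratio and
#' RAGA angles at selected repetitions, and the error of each
#' (precision, update rule) combination against the extended-precision
#' reference. Errors are reported in degrees as
#' `(reference mod 360) - (emulated mod 360)`.
#'
#' @param repetitions ascending temporal indices (default the study's
#'   10000, 25000, 1e5, 2.5e5, 5e5).
#' @param scheme RAGA comparison scheme (default order-13 approximation of
#'   the classic golden angle on the extended full-circle index space).
#' @param tr repetition time in seconds for the acquisition-duration row
#'   (default 2 ms).
#' @param digits reference precision in decimal digits.
#' @return Object of class `drift_report`: list with `repetitions`,
#'   `reference_golden_deg`, `reference_raga_deg`, `errors` (data.frame,
#'   one row per precision/rule), `acquisition_s`.
#' @export
drift_table <- function(repetitions = c(10000, 25000, 1e5, 2.5e5, 5e5),
                        scheme = NULL, tr = 0.002, digits = 50) {
  if (is.unsorted(repetitions)) stop("'repetitions' must be ascending")
  if (is.null(scheme)) {
    scheme <- suppressWarnings(raga_scheme(1, 13, "extended"))
  }
  ref_g <- reference_angle_fx(repetitions, "golden", digits = digits)
  ref_r <- reference_angle_fx(repetitions, "raga", scheme = scheme,
                              digits = digits)
  combos <- expand.grid(precision = c("single", "double"),
                        rule = c("multiplicative", "additive", "additive_mod",
                                 "raga"),
                        stringsAsFactors = FALSE)
  errs <- lapply(seq_len(nrow(combos)), function(r) {
    emu <- emulated_angle(repetitions, combos$rule[r], combos$precision[r],
                          scheme = scheme)
    ref <- if (combos$rule[r] == "raga") ref_r else ref_g
    drift_error(emu, ref, digits = digits)
  })
  em <- do.call(rbind, errs)
  colnames(em) <- paste0("t", repetitions)
  structure(
    list(repetitions = repetitions,
         reference_golden_deg = vapply(ref_g, fx_to_num, numeric(1)),
         reference_raga_deg = vapply(ref_r, fx_to_num, numeric(1)),
         errors = cbind(combos, as.data.frame(em)),
         acquisition_s = repetitions * tr,
         scheme = scheme),
    class = "drift_report")
}

#' @exportS3Method base::print
print.drift_report <- function(x, ...) {
  fmt_row <- function(label, vals, f = "%10.2f") {
    cat(sprintf("  %-22s", label))
    cat(sprintf(f, vals), sep = " ")
    cat("\n")
  }
  cat("angle drift vs extended-precision reference (degrees)\n")
  fmt_row("repetition", x$repetitions, "%10d")
  fmt_row("golden ref (deg)", round(x$reference_golden_deg, 2))
  fmt_row("RAGA ref (deg)", round(x$reference_raga_deg, 2))
  for (r in seq_len(nrow(x$errors))) {
    lab <- sprintf("%s_%s", x$errors$precision[r], x$errors$rule[r])
    fmt_row(lab, unlist(x$errors[r, -(1:2)]), "%10.1e")
  }
  mins <- floor(x$acquisition_s / 60)
  secs <- round(x$acquisition_s - 60 * mins)
  fmt_row("acquisition (min:s)", sprintf("%d:%02d", mins, secs), "%10s")
  invisible(x)
}
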
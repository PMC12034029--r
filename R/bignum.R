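# Minimal arbitrary-precision integer and fixed-point arithmetic.
#
# Used for two things only: exact generalized-Fibonacci values beyond 2^53 and
# the extended-precision (default 50 decimal digit) reference angles of the
# numerical drift audit. Magnitudes are little-endian limb vectors in base
# 1e4, so every intermediate product stays far below 2^53 and all limb
# arithmetic is exact in doubles. No gmp/Rmpfr dependency is available, and
# the reference arithmetic is deliberately independent of R's double
# arithmetic that it is used to audit.

BI_BASE <- 1e4

# -- magnitudes (non-negative), little-endian numeric limb vectors ----------

bi_trim <- function(a) {
  n <- length(a)
  while (n > 1L && a[n] == 0) n <- n - 1L
  a[seq_len(n)]
}

bi_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(0)
  d <- numeric(0)
  while (x > 0) {
    d <- c(d, x %% BI_BASE)
    x <- x %/% BI_BASE
  }
  d
}

bi_from_string <- function(s) {
  s <- sub("^0+(?=.)", "", s, perl = TRUE)
  n <- nchar(s)
  starts <- seq(n, 1L, by = -4L)
  d <- vapply(starts, function(p) {
    as.numeric(substr(s, max(1L, p - 3L), p))
  }, numeric(1))
  bi_trim(d)
}

bi_to_string <- function(a) {
  a <- bi_trim(a)
  n <- length(a)
  if (n == 1L) return(format(a, scientific = FALSE))
  head <- format(a[n], scientific = FALSE)
  rest <- sprintf("%04d", rev(a[-n]))
  paste0(head, paste(rest, collapse = ""))
}

bi_to_num <- function(a) {
  # exact only below 2^53; callers check bi_fits_double() first
  sum(a * BI_BASE^(seq_along(a) - 1))
}

bi_fits_double <- function(a) {
  bi_to_num(a) < 2^53
}

bi_is_zero <- function(a) length(a) == 1L && a[1] == 0

bi_carry <- function(a) {
  # normalize limbs that may exceed the base (still < 2^53)
  repeat {
    q <- a %/% BI_BASE
    if (all(q == 0)) break
    a <- a - q * BI_BASE
    a <- c(a, 0) + c(0, q)
  }
  bi_trim(a)
}

bi_add <- function(a, b) {
  n <- max(length(a), length(b))
  bi_carry(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

bi_cmp <- function(a, b) {
  a <- bi_trim(a); b <- bi_trim(b)
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (k in rev(seq_along(a))) {
    if (a[k] != b[k]) return(sign(a[k] - b[k]))
  }
  0
}

bi_sub <- function(a, b) {
  # requires a >= b
  n <- max(length(a), length(b))
  d <- c(a, numeric(n - length(a))) - c(b, numeric(n - length(b)))
  for (k in seq_len(n - 1L)) {
    if (d[k] < 0) {
      d[k] <- d[k] + BI_BASE
      d[k + 1L] <- d[k + 1L] - 1
    }
  }
  if (d[n] < 0) stop("bi_sub: negative result")
  bi_trim(d)
}

bi_mul <- function(a, b) {
  a <- bi_trim(a); b <- bi_trim(b)
  if (bi_is_zero(a) || bi_is_zero(b)) return(0)
  acc <- numeric(length(a) + length(b))
  for (k in seq_along(b)) {
    if (b[k] == 0) next
    idx <- k:(k + length(a) - 1L)
    acc[idx] <- acc[idx] + a * b[k]
    # worst-case limb after many accumulations: len(b) * 9999^2 < 2^53
  }
  bi_carry(acc)
}

bi_mul_small <- function(a, s) {
  # s a non-negative integer-valued double < ~9e8 so limb*s + carry < 2^53
  stopifnot(s >= 0, s == floor(s), s < 9e8)
  if (s == 0) return(0)
  bi_carry(a * s)
}

bi_shift10 <- function(a, k) {
  # multiply by 10^k, k >= 0
  if (bi_is_zero(a)) return(0)
  q <- k %/% 4L
  r <- k %% 4L
  if (r > 0) a <- bi_mul_small(a, 10^r)
  if (q > 0) a <- c(numeric(q), a)
  a
}

bi_divmod_small <- function(a, s) {
  stopifnot(s > 0, s == floor(s), s < 9e8)
  a <- bi_trim(a)
  q <- numeric(length(a))
  r <- 0
  for (k in rev(seq_along(a))) {
    cur <- r * BI_BASE + a[k]
    q[k] <- cur %/% s
    r <- cur %% s
  }
  list(q = bi_trim(q), r = r)
}

bi_approx <- function(a) {
  # leading-limb double approximation: list(mantissa, exponent base 1e4)
  a <- bi_trim(a)
  n <- length(a)
  keep <- min(n, 3L)
  m <- sum(a[(n - keep + 1L):n] * BI_BASE^(0:(keep - 1L)))
  list(m = m, e = n - keep)
}

bi_divmod <- function(a, b) {
  # schoolbook long division, quotient limbs estimated from leading limbs
  a <- bi_trim(a); b <- bi_trim(b)
  if (bi_is_zero(b)) stop("division by zero")
  if (length(b) == 1L) {
    out <- bi_divmod_small(a, b[1])
    return(list(q = out$q, r = bi_from_num(out$r)))
  }
  if (bi_cmp(a, b) < 0) return(list(q = 0, r = a))
  m <- length(a) - length(b)
  q <- numeric(m + 1L)
  rem <- a
  bap <- bi_approx(b)
  for (j in rev(seq_len(m + 1L))) {
    step <- bi_shift10(b, 4L * (j - 1L))
    rap <- bi_approx(rem)
    qd <- floor(rap$m / bap$m * BI_BASE^(rap$e - bap$e - (j - 1L)))
    qd <- max(0, min(qd, BI_BASE - 1))
    sub <- bi_shift10(bi_mul_small(b, qd), 4L * (j - 1L))
    while (bi_cmp(sub, rem) > 0) {
      qd <- qd - 1
      sub <- bi_sub(sub, step)
    }
    rem <- bi_sub(rem, sub)
    while (bi_cmp(rem, step) >= 0 && qd < BI_BASE - 1) {
      qd <- qd + 1
      rem <- bi_sub(rem, step)
    }
    q[j] <- qd
  }
  list(q = bi_trim(q), r = rem)
}

bi_isqrt <- function(a) {
  # integer square root by Newton iteration, seeded from double sqrt
  a <- bi_trim(a)
  if (bi_is_zero(a)) return(0)
  if (bi_fits_double(a)) {
    x <- floor(sqrt(bi_to_num(a)))
    while ((x + 1)^2 <= bi_to_num(a)) x <- x + 1
    while (x^2 > bi_to_num(a)) x <- x - 1
    return(bi_from_num(x))
  }
  # seed: sqrt of leading limbs, scaled
  nl <- length(a)
  k <- nl %/% 2L
  lead <- bi_trim(a[(2L * k - 1L):nl])   # a / BASE^(2k-2)
  x <- bi_shift10(bi_from_num(ceiling(sqrt(bi_to_num(lead)) + 1)), 4L * (k - 1L))
  repeat {
    # x' = (x + a/x) / 2
    q <- bi_divmod(a, x)$q
    xn <- bi_divmod_small(bi_add(x, q), 2)$q
    if (bi_cmp(xn, x) >= 0) break
    x <- xn
  }
  # fix-up
  while (bi_cmp(bi_mul(x, x), a) > 0) x <- bi_sub(x, bi_from_num(1))
  repeat {
    x1 <- bi_add(x, bi_from_num(1))
    if (bi_cmp(bi_mul(x1, x1), a) > 0) break
    x <- x1
  }
  x
}

# -- signed fixed-point values: value = sign * mag / 10^digits ---------------

fx <- function(sign, mag, digits) {
  if (bi_is_zero(mag)) sign <- 1
  list(s = sign, m = mag, d = digits)
}

fx_from_num <- function(x, digits) {
  # x an integer-valued double
  fx(if (x < 0) -1 else 1, bi_shift10(bi_from_num(abs(x)), digits), digits)
}

fx_add <- function(a, b) {
  stopifnot(a$d == b$d)
  if (a$s == b$s) return(fx(a$s, bi_add(a$m, b$m), a$d))
  cmp <- bi_cmp(a$m, b$m)
  if (cmp == 0) return(fx(1, 0, a$d))
  if (cmp > 0) fx(a$s, bi_sub(a$m, b$m), a$d) else fx(b$s, bi_sub(b$m, a$m), a$d)
}

fx_neg <- function(a) fx(-a$s, a$m, a$d)

fx_sub <- function(a, b) fx_add(a, fx_neg(b))

fx_mul_small <- function(a, s) {
  sg <- a$s * sign(s)
  if (s == 0) return(fx(1, 0, a$d))
  fx(if (sg == 0) 1 else sg, bi_mul_small(a$m, abs(s)), a$d)
}

fx_div <- function(a, b) {
  # a / b rounded toward zero at the working scale
  stopifnot(a$d == b$d)
  if (bi_is_zero(b$m)) stop("fx division by zero")
  num <- bi_shift10(a$m, a$d)
  fx(a$s * b$s, bi_divmod(num, b$m)$q, a$d)
}

fx_div_small <- function(a, s) {
  fx(a$s * sign(s), bi_divmod_small(a$m, abs(s))$q, a$d)
}

fx_mod_positive <- function(a, modulus_int) {
  # a mod m for integer modulus > 0, result in [0, m)
  mm <- bi_shift10(bi_from_num(modulus_int), a$d)
  r <- bi_divmod(a$m, mm)$r
  if (a$s < 0 && !bi_is_zero(r)) r <- bi_sub(mm, r)
  fx(1, r, a$d)
}

fx_cmp <- function(a, b) {
  df <- fx_sub(a, b)
  if (bi_is_zero(df$m)) 0 else df$s
}

fx_to_num <- function(a) {
  # strtod is correctly rounded, so going through the decimal string gives
  # the nearest double
  as.numeric(fx_to_string(a))
}

fx_to_string <- function(a, sig = NULL) {
  s <- bi_to_string(a$m)
  d <- a$d
  if (nchar(s) <= d) s <- paste0(strrep("0", d - nchar(s) + 1L), s)
  out <- paste0(substr(s, 1L, nchar(s) - d), ".", substr(s, nchar(s) - d + 1L, nchar(s)))
  if (a$s < 0) out <- paste0("-", out)
  out
}

fx_from_dyadic <- function(x, digits) {
  # exact conversion of an IEEE double (|x| < 2^63, not subnormal-tiny)
  if (x == 0) return(fx(1, 0, digits))
  sg <- if (x < 0) -1 else 1
  x <- abs(x)
  e <- floor(log2(x))
  m <- x / 2^(e - 52)               # power-of-two scaling is exact
  while (m != floor(m)) { e <- e - 1L; m <- x / 2^(e - 52) }
  while (m >= 2^53) { e <- e + 1L; m <- x / 2^(e - 52) }
  k <- e - 52
  while (m %% 2 == 0 && m > 0) { m <- m / 2; k <- k + 1 }  # strip factors of 2
  big <- bi_from_num(m)
  if (k >= 0) {
    # multiply by 2^k in safe chunks
    while (k > 0) { p <- min(k, 29); big <- bi_mul_small(big, 2^p); k <- k - p }
    fx(sg, bi_shift10(big, digits), digits)
  } else {
    k <- -k
    if (k > digits) stop("fx_from_dyadic: increase working digits")
    # x = m * 5^k / 10^k
    kk <- k
    while (kk > 0) { p <- min(kk, 12); big <- bi_mul_small(big, 5^p); kk <- kk - p }
    fx(sg, bi_shift10(big, digits - k), digits)
  }
}

# golden ratio tau = (1 + sqrt 5)/2 at `digits` decimal digits (fixed point)
fx_tau <- function(digits) {
  g <- digits + 10L   # guard digits
  five <- bi_shift10(bi_from_num(5), 2L * g)
  r5 <- bi_isqrt(five)                     # floor(sqrt(5) * 10^g)
  t <- bi_divmod_small(bi_add(r5, bi_shift10(bi_from_num(1), g)), 2)$q
  fx(1, bi_divmod(t, bi_shift10(bi_from_num(1), 10L))$q, digits)
}
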
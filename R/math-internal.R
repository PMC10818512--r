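# Small polynomial/segment primitives used by the synthetic generator.
# All are internal; units follow the caller.

# Basis matrix for a quintic y(u) = sum c_i u^i with value/1st/2nd derivative
# prescribed at u = 0 and u = 1.
.quintic_M <- matrix(c(
  1, 0, 0, 0, 0, 0,
  0, 1, 0, 0, 0, 0,
  0, 0, 2, 0, 0, 0,
  1, 1, 1, 1, 1, 1,
  0, 1, 2, 3, 4, 5,
  0, 0, 2, 6, 12, 20
), nrow = 6, byrow = TRUE)
.quintic_Minv <- solve(.quintic_M)

# Quintic Hermite coefficients on [0, delta] with boundary value, slope and
# curvature (p0, v0, a0) -> (p1, v1, a1). Returns c0..c5 in normalized u.
quintic_coef <- function(p0, v0, a0, p1, v1, a1, delta) {
  as.numeric(.quintic_Minv %*% c(p0, v0 * delta, a0 * delta^2,
                                 p1, v1 * delta, a1 * delta^2))
}

# Evaluate a polynomial (coefficients in normalized u over [0, delta]) and its
# first `deriv` time-derivatives at times t (relative to segment start).
poly_eval <- function(coef, t, delta, deriv = 0L) {
  u <- t / delta
  n <- length(coef) - 1L
  k <- deriv
  out <- numeric(length(u))
  for (i in k:n) {
    fac <- prod(seq.int(i, by = -1L, length.out = k)) # falling factorial; 1 if k=0
    out <- out + coef[i + 1L] * fac * u^(i - k)
  }
  out / delta^k
}

# Cubic Hermite coefficients on [0, delta] for values (p0, p1), slopes (m0, m1).
cubic_coef <- function(p0, m0, p1, m1, delta) {
  c(p0,
    m0 * delta,
    -3 * p0 - 2 * m0 * delta + 3 * p1 - m1 * delta,
    2 * p0 + m0 * delta - 2 * p1 + m1 * delta)
}

# Integral over the full segment of a cubic Hermite with the given node data.
cubic_segment_integral <- function(p0, m0, p1, m1, delta) {
  delta * (p0 + p1) / 2 + delta^2 * (m0 - m1) / 12
}

# Raised-cosine lobe: amp/2 * (1 + cos(2*pi*(t - center)/width)) on
# |t - center| <= width/2, zero elsewhere. Integral = amp * width / 2.
raised_cosine <- function(t, center, width, amp) {
  d <- t - center
  inside <- abs(d) <= width / 2
  out <- numeric(length(t))
  out[inside] <- amp / 2 * (1 + cos(2 * pi * d[inside] / width))
  out
}

# k-th derivative of a polynomial (power-basis coefficient vector) at u;
# vectorized over u
.ppu <- function(cf, k, u) {
  n <- length(cf) - 1L
  s <- 0
  for (i in k:n)
    s <- s + cf[i + 1L] * prod(seq.int(i, by = -1L, length.out = k)) *
      u^(i - k)
  s
}

# Cumulative trapezoidal integral with fixed step h, starting at 0.
cumtrapz_h <- function(x, h) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  c(0, cumsum((x[-1] + x[-n]) / 2)) * h
}
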
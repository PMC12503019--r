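# Complex-argument Bessel J0/J1 on (mainly) the i^{3/2} ray.
#
# Base R's besselJ is real-only, so the J1(z)/J0(z) ratio needed by the
# Womersley friction function is evaluated here: an ascending power series up
# to |z| = 30 and the exponential form of the Hankel asymptotic expansion
# beyond. On the ray z = alpha * exp(i*3*pi/4) the series suffers essentially
# no cancellation (|J0| grows like exp(|z|/sqrt(2))), and the asymptotic
# truncation error at |z| = 30 is far below double precision.

# Ascending series for J0 and J1; scalar complex z, |z| <= ~30.
bessel_j01_series <- function(z) {
  q <- -(z * z) / 4
  # J0 = sum q^k / (k!)^2 ; J1 = (z/2) sum q^k / (k! (k+1)!)
  t0 <- 1 + 0i
  t1 <- 1 + 0i
  s0 <- t0
  s1 <- t1
  for (k in 1:120) {
    t0 <- t0 * q / (k * k)
    t1 <- t1 * q / (k * (k + 1))
    s0 <- s0 + t0
    s1 <- s1 + t1
    if (Mod(t0) < 1e-18 * Mod(s0) && Mod(t1) < 1e-18 * Mod(s1)) break
  }
  list(j0 = s0, j1 = z / 2 * s1)
}

# J1(z)/J0(z) by asymptotics, |z| large. Uses the exponentially dominant
# half of cos/sin for |Im z| >= 1 to avoid overflow/cancellation.
bessel_ratio_asym <- function(z) {
  pq <- function(nu) {
    mu <- 4 * nu^2
    p <- 1 + 0i
    q <- 0 + 0i
    term <- 1 + 0i
    prev <- Inf
    for (k in 1:40) {
      term <- term * (mu - (2 * k - 1)^2) / (8 * k * z)
      m <- Mod(term)
      if (m > prev) break
      prev <- m
      r <- k %% 4
      if (r == 1) q <- q + term
      else if (r == 2) p <- p - term
      else if (r == 3) q <- q - term
      else p <- p + term
    }
    list(p = p, q = q)
  }
  c0 <- pq(0)
  c1 <- pq(1)
  chi0 <- z - pi / 4
  chi1 <- z - 3 * pi / 4
  if (Im(z) >= 1) {
    # cos(chi) = e^{-i chi} (1 + e^{2 i chi})/2, |e^{2 i chi}| << 1
    u0 <- exp(2i * chi0)
    u1 <- exp(2i * chi1)
    num <- c1$p * (1 + u1) - 1i * c1$q * (1 - u1)
    den <- c0$p * (1 + u0) - 1i * c0$q * (1 - u0)
    # e^{-i chi1} / e^{-i chi0} = e^{i pi/2} = i
    1i * num / den
  } else if (Im(z) <= -1) {
    Conj(bessel_ratio_asym(Conj(z)))
  } else {
    (c1$p * cos(chi1) - c1$q * sin(chi1)) /
      (c0$p * cos(chi0) - c0$q * sin(chi0))
  }
}

# J1(z)/J0(z) for scalar complex z.
bessel_j1_over_j0 <- function(z) {
  if (Mod(z) <= 30) {
    s <- bessel_j01_series(z)
    if (Mod(s$j0) == 0) {
      stop("bessel_j1_over_j0(): evaluation at a zero of J0", call. = FALSE)
    }
    s$j1 / s$j0
  } else {
    bessel_ratio_asym(z)
  }
}
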
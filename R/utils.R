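#' Mean resultant length of a von Mises distribution
#'
#' Computes `A(kappa) = I1(kappa) / I0(kappa)`, the expected value of
#' `cos(theta)` for `theta ~ vonMises(0, kappa)`. This is the population
#' phase-locking value of a phase difference with von Mises concentration
#' `kappa`.
#'
#' @param kappa non-negative concentration parameter (vectorized).
#' @return values in `[0, 1)`.
#' @export
vm_mean_resultant <- function(kappa) {
  stopifnot(all(kappa >= 0))
  out <- kappa
  out[] <- 0
  big <- kappa > 700
  # scaled Bessel ratio is stable for large kappa
  out[!big] <- besselI(kappa[!big], 1, expon.scaled = TRUE) /
    besselI(kappa[!big], 0, expon.scaled = TRUE)
  # asymptotic expansion: A(k) ~ 1 - 1/(2k) - 1/(8k^2)
  k <- kappa[big]
  out[big] <- 1 - 1 / (2 * k) - 1 / (8 * k^2)
  out
}

#' Inverse of the von Mises mean resultant length
#'
#' Finds `kappa` such that `vm_mean_resultant(kappa) = r`.
#'
#' @param r target mean resultant length in `[0, 1)`.
#' @return concentration `kappa >= 0`.
#' @export
vm_concentration <- function(r) {
  vapply(r, function(ri) {
    stopifnot(ri >= 0, ri < 1)
    if (ri == 0) return(0)
    if (ri > 1 - 1e-8) return(1 / (2 * (1 - ri)))
    stats::uniroot(function(k) vm_mean_resultant(k) - ri,
                   lower = 1e-10, upper = 1e8, tol = 1e-12)$root
  }, numeric(1))
}

#' Draw von Mises random angles
#'
#' Best–Fisher (1979) rejection sampler. `kappa = 0` yields uniform angles on
#' `(-pi, pi]`; very large `kappa` (> 1e5) uses the limiting wrapped-normal
#' approximation `N(mu, 1/kappa)`.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) {
    th <- stats::runif(n, -pi, pi)
    return(wrap_angle(th + mu))
  }
  if (kappa > 1e5) {
    return(wrap_angle(stats::rnorm(n, mu, sqrt(1 / kappa))))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cval <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cval * (2 - cval) - u2 > 0) | (log(cval / u2) + 1 - cval >= 0)
    nok <- sum(ok)
    if (nok > 0) {
      u3 <- stats::runif(nok)
      out[(got + 1):(got + nok)] <- sign(u3 - 0.5) * acos(f[ok])
      got <- got + nok
    }
  }
  wrap_angle(out + mu)
}

#' Wrap angles to (-pi, pi]
#' @param theta angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(theta) {
  w <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  # floor puts -pi at the open end; move it to +pi
  w[w <= -pi] <- pi
  w
}

#' Derive a reproducible child seed
#'
#' Fans a root seed out to independent per-unit streams (stage, subject,
#' condition, ...) via a small multiplicative integer hash, kept below 2^31.
#'
#' @param seed root integer seed.
#' @param ... integers or strings identifying the unit of work.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(paste(p, collapse = "")) else as.numeric(p)
  })))
  # polynomial rolling hash; multipliers kept small so that every product
  # stays below 2^53 and the modular arithmetic is exact in doubles
  h <- 0
  for (p in parts) {
    h <- (h * 131 + round(abs(p)) + 1) %% 2147483647
    h <- (h * 69069 + 7) %% 2147483647
  }
  as.integer(h)
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# truncate a proportion to a 2-decimal percentage, as in classification reports
truncate_pct <- function(p) floor(p * 10000) / 100

# truncate a proportion to 2 decimals (for F1-style unit-scale values)
truncate_2dp <- function(p) floor(p * 100) / 100
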
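# Circular helpers shared across the package.  Angles are radians in
# [0, 2*pi) everywhere inside the package; degrees appear only at the CLI
# boundary and in exported CSV columns with a _deg suffix.

#' Wrap angles onto [0, 2*pi)
#'
#' @param theta numeric vector of angles in radians.
#' @return angles reduced modulo `2*pi` into `[0, 2*pi)`.
#' @export
wrap_angle <- function(theta) theta %% (2 * pi)

#' Signed circular difference
#'
#' Shortest signed angular difference `a - b` on the circle.
#'
#' @param a,b angles in radians.
#' @return signed differences in `[-pi, pi)`.
#' @export
circ_dist <- function(a, b) {
  (a - b + pi) %% (2 * pi) - pi
}

#' Absolute circular distance
#'
#' @param a,b angles in radians.
#' @return distances in `[0, pi]`.
#' @export
circ_dist_abs <- function(a, b) abs(circ_dist(a, b))

#' Degrees to radians
#' @param deg angles in degrees.
#' @return angles in radians.
#' @export
deg2rad <- function(deg) deg * pi / 180

#' Radians to degrees
#' @param rad angles in radians.
#' @return angles in degrees.
#' @export
rad2deg <- function(rad) rad * 180 / pi

## log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Wrapped-normal density on the circle
#'
#' Density of a Gaussian wrapped onto `[0, 2*pi)`; used as the observation
#' noise model for hue.  At the default 10-degree noise the wrapping terms
#' are negligible but are included for correctness at larger `sd`.
#'
#' @param x angles in radians.
#' @param mean circular mean in radians.
#' @param sd standard deviation of the underlying line Gaussian (radians).
#' @param n_wrap number of wraps summed on each side.
#' @return density values (with respect to arc length on the circle).
#' @export
dwrapnorm <- function(x, mean = 0, sd, n_wrap = 3L) {
  stopifnot(sd > 0)
  d <- circ_dist(x, mean)
  out <- 0
  for (j in -n_wrap:n_wrap) out <- out + stats::dnorm(d + 2 * pi * j, 0, sd)
  out
}

#' Draw wrapped-Gaussian angles
#'
#' @param n number of draws.
#' @param mean circular mean (radians).
#' @param sd standard deviation of the underlying Gaussian (radians); 0 is
#'   allowed and returns `mean` exactly.
#' @return angles in `[0, 2*pi)`.
#' @export
rwrapnorm <- function(n, mean = 0, sd) {
  stopifnot(sd >= 0)
  if (sd == 0) return(wrap_angle(rep_len(mean, n)))
  wrap_angle(stats::rnorm(n, mean, sd))
}

#' Draw von Mises angles
#'
#' Best-Fisher (1979) rejection sampler for the von Mises distribution,
#' used by the generative model's category-conditional hue emission.
#'
#' @param n number of draws.
#' @param mu circular mean (radians).
#' @param kappa concentration (>= 0); 0 gives the uniform circle.
#' @return angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    m_ok <- sum(ok)
    if (m_ok > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + m_ok)] <- theta
      got <- got + m_ok
    }
  }
  wrap_angle(mu + out)
}

## parameter validation helper
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  if (x < lower || (strict_lower && x == lower) || x > upper)
    stop(sprintf("`%s` = %g is out of range", name, x), call. = FALSE)
  invisible(x)
}
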
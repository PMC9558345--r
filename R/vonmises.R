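# von Mises distribution: density, sampler, and maximum-likelihood fit.
# Turning angles of animal steps are conventionally modeled as von Mises;
# these routines are self-contained (no circular-statistics dependency).

#' von Mises density
#'
#' @param theta angles in radians.
#' @param mu mean direction in (-pi, pi].
#' @param kappa concentration (> 0; 0 is the circular uniform).
#' @param log return log-density?
#' @return density values.
#' @export
dvonmises <- function(theta, mu = 0, kappa = 1, log = FALSE) {
  stopifnot(kappa >= 0)
  # besselI on the exponential scale keeps large kappa finite
  ld <- kappa * (cos(theta - mu) - 1) -
    log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler via a wrapped Cauchy envelope.
#'
#' @param n number of draws.
#' @param mu mean direction.
#' @param kappa concentration (>= 0).
#' @return n angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(wrap_angle(stats::runif(n, -pi, pi)))
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
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    nacc <- sum(ok)
    if (nacc > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + nacc)] <- theta
      got <- got + nacc
    }
  }
  wrap_angle(out + mu)
}

# A1(kappa) = I1(kappa)/I0(kappa), the mean resultant length of a von Mises
A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

#' Maximum-likelihood von Mises fit
#'
#' Closed-form mean direction; concentration by inverting A1(kappa) = Rbar
#' (Fisher's series start, Newton refinement).
#'
#' @param theta angles in radians (NAs dropped).
#' @return list with `mu`, `kappa`, and `n`.
#' @export
fit_vonmises <- function(theta) {
  theta <- theta[is.finite(theta)]
  n <- length(theta)
  if (n < 2) stop("need at least 2 angles to fit a von Mises distribution")
  C <- mean(cos(theta)); S <- mean(sin(theta))
  mu <- atan2(S, C)
  R <- sqrt(C^2 + S^2)
  if (R < 1e-8) return(list(mu = mu, kappa = 0, n = n))
  # Fisher (1993) piecewise start
  k <- if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
  k <- max(k, 1e-6)
  for (it in 1:25) {
    a <- A1(k)
    # d/dk A1 = 1 - A1/k - A1^2
    da <- 1 - a / k - a^2
    step <- (a - R) / da
    k_new <- k - step
    if (!is.finite(k_new) || k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * (1 + k)) { k <- k_new; break }
    k <- k_new
  }
  list(mu = mu, kappa = k, n = n)
}
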
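#' The skew-normal distribution
#'
#' Density, distribution function, random generation and the maps between
#' the direct parametrization (DP: location \code{xi}, scale \code{omega},
#' shape \code{alpha}) and the centered parametrization (CP: mean \code{mu},
#' standard deviation \code{sigma}, skewness \code{gamma}) of the
#' skew-normal distribution. The density in DP is
#' \deqn{f(x) = \frac{2}{\omega}\,\phi\!\left(\frac{x-\xi}{\omega}\right)
#'   \Phi\!\left(\alpha\frac{x-\xi}{\omega}\right),}
#' which reduces to the normal density at \eqn{\alpha = 0}. The CP skewness
#' is confined to \eqn{(-k, k)} with
#' \eqn{k = \sqrt{2}(4-\pi)/(\pi-2)^{3/2} \approx 0.9953}.
#'
#' @param x,q numeric vector of quantiles.
#' @param n number of draws.
#' @param xi location parameter.
#' @param omega scale parameter, \code{> 0}.
#' @param alpha shape parameter.
#' @param log logical; return the log density?
#'
#' @return \code{dsn} and \code{psn} return numeric vectors; \code{rsn}
#'   returns \code{n} draws.
#' @name sn-distribution
NULL

#' @rdname sn-distribution
#' @export
dsn <- function(x, xi = 0, omega = 1, alpha = 0, log = FALSE) {
  stopifnot(omega > 0)
  z <- (x - xi) / omega
  lf <- base::log(2) - base::log(omega) +
    stats::dnorm(z, log = TRUE) + stats::pnorm(alpha * z, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' @rdname sn-distribution
#' @export
psn <- function(q, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  z <- (q - xi) / omega
  p <- stats::pnorm(z) - 2 * owens_t(z, alpha)
  pmin(1, pmax(0, p))
}

#' @rdname sn-distribution
#' @export
rsn <- function(n, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- stats::rnorm(n)
  u1 <- stats::rnorm(n)
  xi + omega * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
}

#' Owen's T function
#'
#' \eqn{T(h, a) = \frac{1}{2\pi}\int_0^a
#'   \frac{\exp\{-h^2(1+x^2)/2\}}{1+x^2}\,dx}, evaluated by fixed-order
#' Gauss-Legendre quadrature after reducing \eqn{|a|} to at most 1 with the
#' standard reflection identity. Used for the skew-normal CDF.
#'
#' @param h numeric vector.
#' @param a scalar second argument.
#' @return numeric vector of the same length as \code{h}.
#' @export
owens_t <- function(h, a) {
  stopifnot(length(a) == 1L, is.finite(a))
  if (a == 0) return(rep(0, length(h)))
  if (a < 0) return(-owens_t(h, -a))
  if (a > 1) {
    # T(h, a) = (Phi(h) + Phi(ah))/2 - Phi(h)Phi(ah) - T(ah, 1/a), a > 0
    ph <- stats::pnorm(h)
    pah <- stats::pnorm(a * h)
    return(0.5 * (ph + pah) - ph * pah - owens_t(a * h, 1 / a))
  }
  gl <- pracma::gaussLegendre(48, 0, a)
  # outer(h^2, 1 + x_j^2): rows follow h, columns follow nodes
  e <- exp(-0.5 * outer(h^2, 1 + gl$x^2))
  drop(e %*% (gl$w / (1 + gl$x^2))) / (2 * pi)
}

# mean-shift factor b = sqrt(2/pi), shared by the CP/DP maps
.sn_b <- sqrt(2 / pi)

#' Upper bound of the centered skewness parameter
#'
#' The supremum \eqn{k = \sqrt{2}(4-\pi)/(\pi-2)^{3/2} \approx 0.9953} of
#' \eqn{|\gamma|} attainable by a skew-normal distribution; the CP parameter
#' space is \eqn{\mathrm{R} \times \mathrm{R}^+ \times (-k, k)}.
#'
#' @return the bound as a scalar.
#' @export
sn_skewness_bound <- function() {
  sqrt(2) * (4 - pi) / (pi - 2)^1.5
}

#' Convert direct to centered skew-normal parameters
#'
#' With \eqn{\delta = \alpha/\sqrt{1+\alpha^2}} and \eqn{b = \sqrt{2/\pi}}:
#' \eqn{\mu = \xi + \omega b \delta},
#' \eqn{\sigma = \omega\sqrt{1 - b^2\delta^2}},
#' \eqn{\gamma = \frac{4-\pi}{2}\,(b\delta)^3 (1 - b^2\delta^2)^{-3/2}}.
#'
#' @param xi,omega,alpha direct parameters (\code{omega > 0}).
#' @return a list with components \code{mu}, \code{sigma}, \code{gamma}.
#' @seealso [cp_to_dp()] for the exact inverse.
#' @export
dp_to_cp <- function(xi, omega, alpha) {
  stopifnot(all(omega > 0))
  delta <- alpha / sqrt(1 + alpha^2)
  bd <- .sn_b * delta
  v <- 1 - bd^2
  list(
    mu = xi + omega * bd,
    sigma = omega * sqrt(v),
    gamma = 0.5 * (4 - pi) * bd^3 / v^1.5
  )
}

#' Convert centered to direct skew-normal parameters
#'
#' Exact inverse of [dp_to_cp()]: from \eqn{\gamma} recover
#' \eqn{b\delta = R/\sqrt{1+R^2}} with \eqn{R = (2\gamma/(4-\pi))^{1/3}},
#' then \eqn{\delta}, \eqn{\alpha}, \eqn{\omega} and \eqn{\xi}.
#'
#' @param mu,sigma,gamma centered parameters; requires \code{sigma > 0} and
#'   \code{|gamma|} strictly below [sn_skewness_bound()].
#' @return a list with components \code{xi}, \code{omega}, \code{alpha}.
#' @export
cp_to_dp <- function(mu, sigma, gamma) {
  stopifnot(all(sigma > 0))
  if (any(abs(gamma) >= sn_skewness_bound())) {
    stop("|gamma| must be strictly below the skewness bound ",
         format(sn_skewness_bound(), digits = 6), call. = FALSE)
  }
  r <- sign(gamma) * (2 * abs(gamma) / (4 - pi))^(1 / 3)
  bd <- r / sqrt(1 + r^2)
  delta <- bd / .sn_b
  omega <- sigma / sqrt(1 - bd^2)
  list(
    xi = mu - omega * bd,
    omega = omega,
    alpha = delta / sqrt(1 - delta^2)
  )
}
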
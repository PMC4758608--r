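#' @useDynLib thetawhisk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

wrap_phase <- function(phi) {
  # wrap to (-pi, pi]
  out <- phi - 2 * pi * floor((phi + pi) / (2 * pi))
  out[out <= -pi] <- pi
  out
}

circ_resultant <- function(phases) {
  n <- length(phases)
  c(C = sum(cos(phases)) / n, S = sum(sin(phases)) / n)
}

#' Mean resultant length of a circular sample
#' @param phases Numeric vector of angles in radians.
#' @return Mean resultant length r between 0 and 1.
#' @export
circ_r <- function(phases) {
  cs <- circ_resultant(phases)
  min(sqrt(cs[["C"]]^2 + cs[["S"]]^2), 1)
}

#' Circular mean of a circular sample
#' @param phases Numeric vector of angles in radians.
#' @return Circular mean angle in (-pi, pi].
#' @export
circ_mean <- function(phases) {
  cs <- circ_resultant(phases)
  wrap_phase(atan2(cs[["S"]], cs[["C"]]))
}

#' Rayleigh test of circular uniformity
#'
#' Tests a sample of phase angles against the uniform circular distribution
#' using the statistic Z = 2 n r^2, where r is the mean resultant length.
#' Under uniformity Z is asymptotically chi-squared with two degrees of
#' freedom, so p = exp(-Z / 2) = exp(-n r^2). (The conventional Rayleigh
#' statistic is n r^2; the factor-2 convention used here changes Z but leaves
#' the p-value identical.) A finite-sample correction after Zar is available
#' behind `correction = TRUE`, default off.
#'
#' @param phases Numeric vector of angles in radians, length >= 2.
#' @param correction Apply the finite-sample series correction to p.
#' @return List with `Z`, `p`, `r`, `n` and `mean_phase`.
#' @export
rayleigh_test <- function(phases, correction = FALSE) {
  n <- length(phases)
  if (n < 2) stop("rayleigh_test: need at least 2 phases")
  r <- circ_r(phases)
  Z <- 2 * n * r^2
  p <- exp(-Z / 2)
  if (correction) {
    # Zar (1999) series correction, expressed in the conventional R0 = n r^2
    R0 <- n * r^2
    p <- exp(-R0) * (1 + (2 * R0 - R0^2) / (4 * n) -
                       (24 * R0 - 132 * R0^2 + 76 * R0^3 - 9 * R0^4) / (288 * n^2))
    p <- min(max(p, 0), 1)
  }
  list(Z = Z, p = p, r = r, n = n, mean_phase = circ_mean(phases))
}

# ratio I1(k)/I0(k), numerically stable via exponentially scaled Bessel
bessel_ratio_A1 <- function(kappa) {
  if (kappa == 0) return(0)
  if (kappa > 700) return(1 - 1 / (2 * kappa) - 1 / (8 * kappa^2))
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Maximum-likelihood von Mises fit to phase angles
#'
#' Fits the von Mises distribution f(phi | theta, kappa) =
#' exp(kappa cos(phi - theta)) / (2 pi I0(kappa)). The mean angle estimate is
#' the circular mean; the concentration kappa solves I1(kappa)/I0(kappa) = r
#' by monotone root finding. For kappa = 0 the distribution is uniform.
#'
#' @param phases Numeric vector of angles in radians, length >= 10 (shorter
#'   samples are refused: kappa is badly determined).
#' @param kappa_max Cap applied to kappa when the sample is (near-)degenerate
#'   (r >= 1 - 1e-9); such fits carry `degenerate = TRUE`.
#' @return An object of class `vonmises_fit`: list with `theta_mean`, `kappa`,
#'   `r`, `n`, `rayleigh_Z`, `p_value`, `degenerate`.
#' @export
fit_von_mises <- function(phases, kappa_max = 1e3) {
  n <- length(phases)
  if (n < 10) stop("fit_von_mises: need at least 10 phases")
  r <- circ_r(phases)
  theta <- circ_mean(phases)
  degenerate <- FALSE
  if (r >= 1 - 1e-9) {
    kappa <- kappa_max
    degenerate <- TRUE
  } else if (r < 1e-8) {
    kappa <- 0
  } else {
    f <- function(k) bessel_ratio_A1(k) - r
    upper <- 2
    while (f(upper) < 0 && upper < kappa_max) upper <- upper * 2
    upper <- min(upper, kappa_max)
    if (f(upper) < 0) {
      kappa <- kappa_max
      degenerate <- TRUE
    } else {
      kappa <- stats::uniroot(f, c(0, upper), tol = 1e-10)$root
    }
  }
  rt <- rayleigh_test(phases)
  structure(list(theta_mean = theta, kappa = kappa, r = r, n = n,
                 rayleigh_Z = rt$Z, p_value = rt$p, degenerate = degenerate),
            class = "vonmises_fit")
}

#' @export
print.vonmises_fit <- function(x, ...) {
  cat(sprintf("von Mises fit: theta = %.3f rad, kappa = %.3f (r = %.3f, n = %d)\n",
              x$theta_mean, x$kappa, x$r, x$n))
  cat(sprintf("Rayleigh Z = 2nr^2 = %.3f, p = %.3g%s\n", x$rayleigh_Z, x$p_value,
              if (x$degenerate) " [degenerate: kappa capped]" else ""))
  invisible(x)
}

#' @export
coef.vonmises_fit <- function(object, ...) {
  c(theta = object$theta_mean, kappa = object$kappa)
}

#' von Mises density
#' @param phi Angles in radians.
#' @param theta Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Density values.
#' @export
dvonmises <- function(phi, theta, kappa) {
  # scaled form avoids overflow of I0 at large kappa
  exp(kappa * (cos(phi - theta) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler; uses R's RNG stream.
#'
#' @param n Number of draws.
#' @param theta Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Angles in (-pi, pi].
#' @export
rvonmises <- function(n, theta, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    f <- f[keep]; u3 <- u3[keep]
    k <- length(f)
    if (k) {
      out[(got + 1):(got + k)] <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
      got <- got + k
    }
  }
  wrap_phase(theta + out)
}

#' Two-proportion z-test (pooled variance)
#'
#' z = (k1/n1 - k2/n2) / sqrt(p(1-p)(1/n1 + 1/n2)) with the pooled proportion
#' p = (k1+k2)/(n1+n2); two-sided normal p-value.
#'
#' @param k1,n1 Successes and size of group 1.
#' @param k2,n2 Successes and size of group 2.
#' @return List with `z`, `p`, and the two sample proportions.
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p_pool <- (k1 + k2) / (n1 + n2)
  if (p_pool <= 0 || p_pool >= 1)
    stop("two_proportion_ztest: pooled proportion is 0 or 1; z undefined")
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- (k1 / n1 - k2 / n2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), prop1 = k1 / n1, prop2 = k2 / n2)
}
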
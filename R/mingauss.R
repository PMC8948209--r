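#' Moments of the minimum of two correlated Gaussians
#'
#' For Y = min(X1, X2) with X1 ~ N(mu1, s1^2), X2 ~ N(mu2, s2^2) and
#' correlation rho, the first two moments have a closed form (Nadarajah &
#' Kotz) in terms of theta = sqrt(s1^2 + s2^2 - 2 rho s1 s2):
#' \deqn{E[Y] = \mu_1 \Phi((\mu_2-\mu_1)/\theta) +
#'              \mu_2 \Phi((\mu_1-\mu_2)/\theta) -
#'              \theta \phi((\mu_2-\mu_1)/\theta)}
#' \deqn{E[Y^2] = (\sigma_1^2+\mu_1^2) \Phi((\mu_2-\mu_1)/\theta) +
#'                (\sigma_2^2+\mu_2^2) \Phi((\mu_1-\mu_2)/\theta) -
#'                (\mu_1+\mu_2) \theta \phi((\mu_2-\mu_1)/\theta)}
#' When theta = 0 the difference X2 - X1 is degenerate and Y is simply the
#' variable with the smaller mean. The variance is clamped at 0 against
#' round-off.
#'
#' @param mu1,mu2 Means of the two Gaussians.
#' @param s1,s2 Standard deviations (non-negative).
#' @param rho Correlation in [-1, 1].
#' @return List of class \code{min_gaussian_moments} with \code{ey},
#'   \code{ey2}, \code{variance}.
#' @export
min_gaussian_moments <- function(mu1, mu2, s1, s2, rho = 0) {
  stopifnot(s1 >= 0, s2 >= 0)
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  theta2 <- s1^2 + s2^2 - 2 * rho * s1 * s2
  theta <- sqrt(max(theta2, 0))
  if (theta == 0) {
    if (mu1 <= mu2) {
      ey <- mu1; ey2 <- s1^2 + mu1^2
    } else {
      ey <- mu2; ey2 <- s2^2 + mu2^2
    }
  } else {
    z <- (mu2 - mu1) / theta
    ey <- mu1 * stats::pnorm(z) + mu2 * stats::pnorm(-z) -
      theta * stats::dnorm(z)
    ey2 <- (s1^2 + mu1^2) * stats::pnorm(z) +
      (s2^2 + mu2^2) * stats::pnorm(-z) -
      (mu1 + mu2) * theta * stats::dnorm(z)
  }
  structure(list(ey = ey, ey2 = ey2, variance = max(ey2 - ey^2, 0)),
            class = "min_gaussian_moments")
}
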
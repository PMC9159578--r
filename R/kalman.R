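#' Exact likelihood of the Ornstein-Uhlenbeck benchmark (Kalman filter)
#'
#' The OU process \eqn{dX = \theta_1(\theta_2 - X) dt + \theta_3 dW} observed
#' as \eqn{y_l = x(t_l) + \epsilon_l}, \eqn{\epsilon_l \sim N(0, \sigma^2)},
#' is linear-Gaussian, so its likelihood is available in closed form from the
#' scalar Kalman prediction/update recursion with the exact discrete
#' transition
#' \deqn{x_{t+\Delta} | x_t \sim N(\theta_2 + (x_t - \theta_2) e^{-\theta_1
#' \Delta},\; \theta_3^2 (1 - e^{-2 \theta_1 \Delta}) / (2 \theta_1)).}
#' This oracle validates every stochastic likelihood estimator in the
#' package.
#'
#' @param theta numeric (theta1, theta2, theta3), all positive
#' @param sigma observation error SD (> 0)
#' @param times strictly increasing observation times
#' @param y observations (same length as times)
#' @param x0 fixed initial state, or NA for the stationary law
#'   \eqn{N(\theta_2, \theta_3^2/(2\theta_1))}
#' @param t0 initial time
#' @return exact log-likelihood
#' @export
kalmanLogLik <- function(theta, sigma, times, y, x0 = NA, t0 = 0) {
  stopifnot(length(theta) == 3, all(theta > 0), sigma > 0,
            all(diff(c(t0, times)) > 0), length(y) == length(times))
  th1 <- theta[1]; th2 <- theta[2]; th3 <- theta[3]
  vstat <- th3^2 / (2 * th1)
  if (is.na(x0)) { m <- th2; v <- vstat } else { m <- x0; v <- 0 }
  tprev <- t0
  ll <- 0
  for (l in seq_along(times)) {
    e <- exp(-th1 * (times[l] - tprev))
    m <- th2 + (m - th2) * e
    v <- v * e^2 + vstat * (1 - e^2)
    S <- v + sigma^2
    ll <- ll + stats::dnorm(y[l], m, sqrt(S), log = TRUE)
    K <- v / S
    m <- m + K * (y[l] - m)
    v <- v * (1 - K)
    tprev <- times[l]
  }
  ll
}

#' Exact simulation of the OU process
#'
#' Samples the process at the requested times using the exact Gaussian
#' transition (no discretisation error); used for benchmark data generation.
#'
#' @inheritParams kalmanLogLik
#' @param outTimes output time grid
#' @return numeric vector of states at \code{outTimes}
#' @export
simulateOUExact <- function(theta, outTimes, x0 = NA, t0 = 0) {
  th1 <- theta[1]; th2 <- theta[2]; th3 <- theta[3]
  vstat <- th3^2 / (2 * th1)
  x <- if (is.na(x0)) stats::rnorm(1, th2, sqrt(vstat)) else x0
  tprev <- t0
  out <- numeric(length(outTimes))
  for (l in seq_along(outTimes)) {
    e <- exp(-th1 * (outTimes[l] - tprev))
    m <- th2 + (x - th2) * e
    v <- vstat * (1 - e^2)
    x <- stats::rnorm(1, m, sqrt(v))
    out[l] <- x
    tprev <- outTimes[l]
  }
  out
}
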
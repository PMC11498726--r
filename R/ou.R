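#' Ornstein-Uhlenbeck perturbation specification
#'
#' The transmission perturbation follows the zero-mean OU process
#' \eqn{dm = -k\,m\,dt + \theta\,dB(t)} started at \eqn{m(0) = m_0}.
#'
#' @param m0 initial value \eqn{m(0)}.
#' @param k reversion speed (> 0).
#' @param theta volatility intensity (>= 0).
#' @return An object of class \code{"ou_spec"}.
#' @export
ou_spec <- function(m0 = 0, k, theta) {
  if (k <= 0) stop("reversion speed 'k' must be > 0")
  if (theta < 0) stop("volatility 'theta' must be >= 0")
  structure(list(m0 = as.numeric(m0), k = as.numeric(k),
                 theta = as.numeric(theta)), class = "ou_spec")
}

#' Transient mean and variance of the OU perturbation
#'
#' \deqn{E[m(t)] = m_0 e^{-kt}, \qquad
#'       Var[m(t)] = \frac{\theta^2}{2k}\left(1 - e^{-2kt}\right).}
#'
#' @param spec an [ou_spec()].
#' @param t time (>= 0).
#' @return Named numeric vector \code{c(mean, var)}.
#' @examples
#' ou_mean_var(ou_spec(-0.02, k = 0.65, theta = 0.14), t = 1)
#' @export
ou_mean_var <- function(spec, t) {
  if (any(t < 0)) stop("time 't' must be >= 0")
  with(spec, c(mean = m0 * exp(-k * t),
               var = theta^2 / (2 * k) * (1 - exp(-2 * k * t))))
}

#' Invariant density of the OU perturbation
#'
#' \eqn{m(t)} is ergodic and converges weakly to the Gaussian invariant
#' density \deqn{\zeta(x) = \sqrt{\frac{k}{\pi\theta^2}}\, e^{-k x^2/\theta^2},}
#' i.e. \eqn{N(0, \theta^2/(2k))}.
#'
#' @param x evaluation point(s).
#' @param spec an [ou_spec()] with \code{theta > 0}.
#' @return Density value(s) at \code{x}.
#' @export
ou_invariant_density <- function(x, spec) {
  if (spec$theta <= 0) stop("invariant density is degenerate for theta = 0")
  with(spec, sqrt(k / (pi * theta^2)) * exp(-k * x^2 / theta^2))
}

#' Ergodic mean of the absolute OU perturbation
#'
#' By the ergodic theorem,
#' \deqn{\lim_{t\to\infty} \frac1t \int_0^t |m(\tau)|\,d\tau
#'       = \int_{-\infty}^{\infty} |x| \zeta(x)\,dx = \frac{\theta}{\sqrt{\pi k}}.}
#' This is the quantity that shifts \eqn{R_0} into \eqn{R_{0E}} and
#' \eqn{R_{0S}}.
#'
#' @param spec an [ou_spec()].
#' @return The scalar \eqn{\theta/\sqrt{\pi k}}.
#' @export
ou_ergodic_abs_mean <- function(spec) {
  with(spec, theta / sqrt(pi * k))
}

#' Exact one-step transition of the OU perturbation
#'
#' The OU SDE is linear, so its transition over a step \code{dt} can be
#' sampled exactly:
#' \deqn{m_{i+1} = m_i e^{-k\Delta t}
#'       + \theta\sqrt{\frac{1 - e^{-2k\Delta t}}{2k}}\; h_i,}
#' with \eqn{h_i} a standard normal draw.  This sampler is free of time-step
#' bias and is the recommended alternative to the Milstein update of the
#' \eqn{m}-component (see [milstein_step()]).
#'
#' @param m current value(s).
#' @param dt step size (> 0).
#' @param spec an [ou_spec()].
#' @param noise standard normal draw(s), same length as \code{m}.
#' @return Updated value(s).
#' @export
ou_exact_step <- function(m, dt, spec, noise) {
  if (dt <= 0) stop("step size 'dt' must be > 0")
  with(spec, m * exp(-k * dt) + theta * sqrt((1 - exp(-2 * k * dt)) / (2 * k)) * noise)
}

#' Simulate an OU path on a regular grid
#'
#' Iterates [ou_exact_step()] on a grid of \code{n} steps of size \code{dt}.
#' The linear recursion \eqn{m_{i+1} = \rho m_i + s h_i} is evaluated with
#' \code{stats::filter(method = "recursive")}, so long paths are cheap.
#'
#' @param spec an [ou_spec()].
#' @param dt step size.
#' @param n number of steps.
#' @param seed optional RNG seed.
#' @return Numeric vector of length \code{n + 1} (including \eqn{m_0}).
#' @export
ou_path <- function(spec, dt, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rho <- exp(-spec$k * dt)
  s <- spec$theta * sqrt((1 - rho^2) / (2 * spec$k))
  h <- stats::rnorm(n)
  m <- as.numeric(stats::filter(s * h, rho, method = "recursive",
                                init = spec$m0))
  # filter() starts from init = m0 but does not emit it; prepend
  c(spec$m0, m)
}
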
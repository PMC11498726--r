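#' Simulation configuration
#'
#' @param dt step size (time units, > 0).  The regime illustrations in the
#'   literature use \code{dt = 1}; quantitative work here defaults to
#'   \code{dt = 0.01}, which is safer for rate constants of order one.
#' @param n_steps number of steps (>= 1).
#' @param n_paths ensemble size (>= 1).
#' @param seed master RNG seed; path \code{j} of an ensemble uses
#'   \code{seed + j - 1}, so single paths can be reproduced independently.
#' @param scheme \code{"paper_milstein"} updates the OU component with the
#'   Milstein rule (including its \eqn{(\theta^2/2)(h^2-1)\Delta t} term);
#'   \code{"exact_ou"} uses the exact OU transition of [ou_exact_step()].  The
#'   compartments are always updated by the Euler rule with the current
#'   \eqn{m_i} in the \eqn{\beta + m} terms.
#' @param clamp_policy what to do if a compartment goes negative after a step:
#'   \code{"truncate"} sets it to 0 (and counts the event),
#'   \code{"reject"} aborts with the step index.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(dt = 0.01, n_steps = 1000L, n_paths = 1L, seed = 1L,
                       scheme = c("paper_milstein", "exact_ou"),
                       clamp_policy = c("truncate", "reject")) {
  scheme <- match.arg(scheme)
  clamp_policy <- match.arg(clamp_policy)
  if (dt <= 0) stop("'dt' must be > 0")
  if (n_steps < 1) stop("'n_steps' must be >= 1")
  if (n_paths < 1) stop("'n_paths' must be >= 1")
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 n_paths = as.integer(n_paths), seed = as.integer(seed),
                 scheme = scheme, clamp_policy = clamp_policy),
            class = "sim_config")
}

# one vectorised update of (S, I, V, m); S, I, V, m, h are equal-length
# vectors (one entry per path).  Returns the raw (unclamped) update.
.sivs_step <- function(S, I, V, m, h, params, dt, scheme) {
  d <- .sivs_drift(S, I, V, m, params)
  m_new <- if (scheme == "exact_ou") {
    with(params, m * exp(-k * dt) +
           theta * sqrt((1 - exp(-2 * k * dt)) / (2 * k)) * h)
  } else {
    with(params, m - k * m * dt + theta * h * sqrt(dt) +
           theta^2 / 2 * (h^2 - 1) * dt)
  }
  list(S = S + d$S * dt, I = I + d$I * dt, V = V + d$V * dt, m = m_new)
}

#' One step of the discretized stochastic SIVS system
#'
#' The discretization updates the compartments by the Euler rule with the
#' current OU value \eqn{m_i} in the \eqn{\beta + m_i} terms, and the OU
#' component by the Milstein rule
#' \deqn{m_{i+1} = m_i - k m_i \Delta t + \theta h_i \sqrt{\Delta t}
#'       + \frac{\theta^2}{2}(h_i^2 - 1)\Delta t,}
#' with \eqn{h_i} standard normal.  (The OU noise is additive, so the
#' \eqn{(h^2-1)} correction is nil in expectation; the \code{"exact_ou"}
#' scheme replaces the \eqn{m}-update with the exact transition.)
#'
#' @param state a [sivs_state()].
#' @param params a \code{"sivs_params"} object.
#' @param dt step size (> 0).
#' @param h standard normal draw.
#' @param scheme \code{"paper_milstein"} or \code{"exact_ou"}.
#' @return The updated \code{"sivs_state"} (no clamping is applied here).
#' @export
milstein_step <- function(state, params, dt, h,
                          scheme = c("paper_milstein", "exact_ou")) {
  scheme <- match.arg(scheme)
  if (dt <= 0) stop("'dt' must be > 0")
  u <- .sivs_step(state[["S"]], state[["I"]], state[["V"]], state[["m"]],
                  h, params, dt, scheme)
  sivs_state(u$S, u$I, u$V, u$m)
}

# core engine: simulates n_paths paths in lockstep (vectorised across the
# path dimension).  The noise stream of path j is the first n_steps draws of
# rnorm() under set.seed(seed + j - 1): one draw per step per path.
.sivs_engine <- function(init, params, config) {
  n <- config$n_steps
  P <- config$n_paths
  H <- matrix(0, n, P)
  for (j in seq_len(P)) {
    set.seed(config$seed + j - 1L)
    H[, j] <- stats::rnorm(n)
  }
  S <- matrix(NA_real_, n + 1L, P); I <- S; V <- S; M <- S
  S[1L, ] <- init[["S"]]; I[1L, ] <- init[["I"]]
  V[1L, ] <- init[["V"]]; M[1L, ] <- init[["m"]]
  s <- rep(init[["S"]], P); i <- rep(init[["I"]], P)
  v <- rep(init[["V"]], P); m <- rep(init[["m"]], P)
  clamped <- 0L
  for (step in seq_len(n)) {
    u <- .sivs_step(s, i, v, m, H[step, ], params, config$dt, config$scheme)
    s <- u$S; i <- u$I; v <- u$V; m <- u$m
    neg <- s < 0 | i < 0 | v < 0
    if (any(neg)) {
      if (config$clamp_policy == "reject")
        stop("negative compartment at step ", step,
             " (t = ", step * config$dt, "); rerun with clamp_policy = \"truncate\"")
      clamped <- clamped + sum(neg)
      s <- pmax(s, 0); i <- pmax(i, 0); v <- pmax(v, 0)
    }
    if (any(!is.finite(s)) || any(!is.finite(i)) ||
        any(!is.finite(v)) || any(!is.finite(m)))
      stop("non-finite state at step ", step, " (t = ", step * config$dt,
           "); reduce dt")
    S[step + 1L, ] <- s; I[step + 1L, ] <- i
    V[step + 1L, ] <- v; M[step + 1L, ] <- m
  }
  list(times = seq(0, by = config$dt, length.out = n + 1L),
       S = S, I = I, V = V, m = M, clamped = clamped)
}

#' Simulate one path of the stochastic SIVS system
#'
#' Iterates the discretized system from \code{init} for
#' \code{config$n_steps} steps.  Identical seeds give bitwise-identical
#' trajectories.  A warning is issued when the initial state lies outside the
#' invariant region \eqn{\Gamma}.
#'
#' @param init a [sivs_state()].
#' @param params a \code{"sivs_params"} object.
#' @param config a [sim_config()] (its \code{n_paths} is ignored; one path is
#'   produced).
#' @return An object of class \code{"sivs_trajectory"}: list with
#'   \code{times}, numeric vectors \code{S}, \code{I}, \code{V}, \code{m},
#'   the clamp counter \code{clamped}, and the generating \code{params} /
#'   \code{config}.
#' @examples
#' tr <- simulate_path(sivs_state(0.6, 0.7, 2.5), sivs_fixture("group2"),
#'                     sim_config(dt = 0.01, n_steps = 500, seed = 1))
#' tail(as.data.frame(tr), 2)
#' @export
simulate_path <- function(init, params, config = sim_config()) {
  if (!in_invariant_region(init, params))
    warning("initial state lies outside the invariant region Gamma",
            call. = FALSE)
  cfg1 <- config
  cfg1$n_paths <- 1L
  res <- .sivs_engine(init, params, cfg1)
  structure(list(times = res$times, S = res$S[, 1L], I = res$I[, 1L],
                 V = res$V[, 1L], m = res$m[, 1L], clamped = res$clamped,
                 params = params, config = cfg1),
            class = "sivs_trajectory")
}

#' @export
as.data.frame.sivs_trajectory <- function(x, ...) {
  data.frame(t = x$times, S = x$S, I = x$I, V = x$V, m = x$m)
}

#' @export
print.sivs_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("SIVS trajectory: %d steps, dt = %g, t in [0, %g], scheme = %s\n",
              n - 1L, x$config$dt, x$times[n], x$config$scheme))
  cat(sprintf("final state: S = %.4f, I = %.4g, V = %.4f, m = %.4f",
              x$S[n], x$I[n], x$V[n], x$m[n]))
  if (x$clamped > 0) cat(sprintf("  (%d clamped updates)", x$clamped))
  cat("\n")
  invisible(x)
}

#' Simulate an ensemble of independent paths
#'
#' Runs \code{config$n_paths} independent paths from a common initial state.
#' Path \code{j} uses the derived seed \code{config$seed + j - 1} for its
#' noise stream, so \code{simulate_ensemble(...)} path \code{j} reproduces
#' \code{simulate_path(...)} run with that seed.
#'
#' @inheritParams simulate_path
#' @return An object of class \code{"sivs_ensemble"}: list with \code{times}
#'   and \code{(n_steps+1) x n_paths} matrices \code{S}, \code{I}, \code{V},
#'   \code{m}, plus \code{clamped}, \code{params}, \code{config}.
#' @export
simulate_ensemble <- function(init, params, config = sim_config()) {
  if (!in_invariant_region(init, params))
    warning("initial state lies outside the invariant region Gamma",
            call. = FALSE)
  res <- .sivs_engine(init, params, config)
  structure(c(res, list(params = params, config = config)),
            class = "sivs_ensemble")
}

#' @export
print.sivs_ensemble <- function(x, ...) {
  cat(sprintf("SIVS ensemble: %d paths x %d steps, dt = %g, scheme = %s\n",
              ncol(x$S), nrow(x$S) - 1L, x$config$dt, x$config$scheme))
  n <- nrow(x$I)
  cat(sprintf("terminal means: S = %.4f, I = %.4g, V = %.4f",
              mean(x$S[n, ]), mean(x$I[n, ]), mean(x$V[n, ])))
  if (x$clamped > 0) cat(sprintf("  (%d clamped updates)", x$clamped))
  cat("\n")
  invisible(x)
}
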
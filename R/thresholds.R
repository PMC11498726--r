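#' Basic reproduction number of the deterministic SIVS model
#'
#' \deqn{R_0 = \frac{\beta A [\eta(1-g) + \alpha]}
#'                  {\eta(\eta+\gamma+\varepsilon)(\eta+\alpha+p)}.}
#' The disease-free equilibrium of the deterministic model is globally stable
#' when \eqn{R_0 < 1}; the endemic equilibrium exists and is globally stable
#' when \eqn{R_0 > 1}.
#'
#' @param params a \code{"sivs_params"} object.
#' @return The scalar \eqn{R_0}.
#' @examples
#' reproduction_number(sivs_fixture("group2"))  # 2
#' @export
reproduction_number <- function(params) {
  with(params, beta * A * (eta * (1 - g) + alpha) /
         (eta * (eta + gamma + epsilon) * (eta + alpha + p)))
}

# ergodic correction A * E|m| / (eta * (eta+gamma+epsilon)) with
# E|m| = theta / sqrt(pi k) under the OU invariant law
.threshold_correction <- function(params) {
  with(params, A * theta / (sqrt(pi * k) * eta * (eta + gamma + epsilon)))
}

#' Stochastic extinction and persistence thresholds
#'
#' Under OU-perturbed transmission the deterministic threshold \eqn{R_0}
#' splits into an extinction number and a persistence number,
#' \deqn{R_{0E} = R_0 + \frac{A\theta}{\sqrt{\pi k}\,\eta(\eta+\gamma+\varepsilon)},
#'  \qquad
#'  R_{0S} = R_0 - \frac{A\theta}{\sqrt{\pi k}\,\eta(\eta+\gamma+\varepsilon)},}
#' where the shift is the long-run ergodic mean of \eqn{A|m|/\eta} scaled by
#' \eqn{1/(\eta+\gamma+\varepsilon)}.  If \eqn{R_{0E} < 1} the infection dies
#' out exponentially fast, with
#' \eqn{\limsup_t \log I(t)/t \le (\eta+\gamma+\varepsilon)(R_{0E}-1) < 0};
#' if \eqn{R_{0S} > 1} the time-average of \eqn{I} is bounded below by
#' \deqn{\frac{\eta(\eta+\alpha+p)(\eta+\gamma+\varepsilon)}
#'            {\beta(\eta+\varepsilon)(\eta+\alpha)} (R_{0S}-1).}
#'
#' @param params a \code{"sivs_params"} object (requires \code{k > 0}).
#' @return An object of class \code{"sivs_thresholds"}: a list with
#'   \code{R0}, \code{R0E}, \code{R0S}, \code{extinction_rate_bound} and
#'   \code{persistence_lower_bound} (the latter is \code{NA} when
#'   \eqn{R_{0S} \le 1}).
#' @examples
#' stochastic_thresholds(sivs_fixture("group1"))$R0E  # ~0.7697
#' stochastic_thresholds(sivs_fixture("group2"))$R0S  # ~1.3870
#' @export
stochastic_thresholds <- function(params) {
  if (params$k <= 0) stop("OU reversion speed 'k' must be > 0")
  R0 <- reproduction_number(params)
  corr <- .threshold_correction(params)
  R0E <- R0 + corr
  R0S <- R0 - corr
  plb <- with(params,
              eta * (eta + alpha + p) * (eta + gamma + epsilon) * (R0S - 1) /
                (beta * (eta + epsilon) * (eta + alpha)))
  structure(list(
    R0 = R0, R0E = R0E, R0S = R0S,
    extinction_rate_bound = with(params, (eta + gamma + epsilon) * (R0E - 1)),
    persistence_lower_bound = if (R0S > 1) plb else NA_real_
  ), class = "sivs_thresholds")
}

#' @export
print.sivs_thresholds <- function(x, digits = 4, ...) {
  cat(sprintf("R0  = %.*f   R0E = %.*f   R0S = %.*f\n",
              digits, x$R0, digits, x$R0E, digits, x$R0S))
  cat(sprintf("extinction rate bound: %.*f%s\n", digits,
              x$extinction_rate_bound,
              if (x$R0E < 1) "  (extinction regime)" else ""))
  if (!is.na(x$persistence_lower_bound))
    cat(sprintf("persistence lower bound for mean I: %.*f\n",
                digits, x$persistence_lower_bound))
  invisible(x)
}

#' Disease-free equilibrium
#'
#' \deqn{S^0 = \frac{A[\eta(1-g)+\alpha]}{\eta(\eta+\alpha+p)}, \qquad
#'       V^0 = \frac{A(\eta g + p)}{\eta(\eta+\alpha+p)},}
#' with \eqn{I^0 = 0}.  The identity \eqn{S^0 + V^0 = A/\eta} holds exactly.
#'
#' @param params a \code{"sivs_params"} object.
#' @return Named numeric vector \code{c(S0, V0)}.
#' @export
disease_free_equilibrium <- function(params) {
  with(params, c(
    S0 = A * (eta * (1 - g) + alpha) / (eta * (eta + alpha + p)),
    V0 = A * (eta * g + p) / (eta * (eta + alpha + p))))
}

#' Endemic (quasi-endemic) equilibrium
#'
#' For \eqn{R_0 > 1} the deterministic model has the endemic equilibrium
#' \deqn{S^* = \frac{\eta+\gamma+\varepsilon}{\beta}, \quad
#'       I^* = \frac{\eta(\eta+\gamma+\varepsilon)(\eta+\alpha+p)}
#'                  {\beta(\eta+\varepsilon)(\eta+\alpha)} (R_0 - 1), \quad
#'       V^* = \frac{gA\beta + p(\eta+\gamma+\varepsilon)}{\beta(\eta+\alpha)}.}
#' In the stochastic model the same point, augmented with \eqn{m^* = 0}, is
#' the quasi-endemic equilibrium at which the system is linearized for the
#' stationary Gaussian density.
#'
#' @param params a \code{"sivs_params"} object.
#' @return An object of class \code{"sivs_equilibria"}: a list with the
#'   disease-free components \code{S0}, \code{V0}, the endemic components
#'   \code{S_star}, \code{I_star}, \code{V_star} (all \code{NA} when
#'   \eqn{R_0 \le 1}), \code{m_star = 0}, \code{R0} and the logical
#'   \code{endemic_exists}.  No endemic equilibrium is a typed result, not an
#'   error, so regime classification can consume it.
#' @examples
#' endemic_equilibrium(sivs_fixture("group2"))  # (0.6111, 0.7333, 2.5555)
#' @export
endemic_equilibrium <- function(params) {
  R0 <- reproduction_number(params)
  dfe <- disease_free_equilibrium(params)
  ee <- if (R0 > 1) {
    with(params, c(
      S_star = (eta + gamma + epsilon) / beta,
      I_star = eta * (eta + gamma + epsilon) * (eta + alpha + p) * (R0 - 1) /
        (beta * (eta + epsilon) * (eta + alpha)),
      V_star = (g * A * beta + p * (eta + gamma + epsilon)) /
        (beta * (eta + alpha))))
  } else {
    c(S_star = NA_real_, I_star = NA_real_, V_star = NA_real_)
  }
  structure(c(as.list(dfe), as.list(ee),
              list(m_star = 0, R0 = R0, endemic_exists = R0 > 1)),
            class = "sivs_equilibria")
}

#' @export
print.sivs_equilibria <- function(x, digits = 4, ...) {
  cat(sprintf("disease-free equilibrium: S0 = %.*f, V0 = %.*f\n",
              digits, x$S0, digits, x$V0))
  if (x$endemic_exists) {
    cat(sprintf("endemic equilibrium: S* = %.*f, I* = %.*f, V* = %.*f (m* = 0)\n",
                digits, x$S_star, digits, x$I_star, digits, x$V_star))
  } else {
    cat(sprintf("no endemic equilibrium (R0 = %.*f <= 1)\n", digits, x$R0))
  }
  invisible(x)
}

# drift of the deterministic part of the system at (S, I, V) with OU value m;
# vectorised over path columns.  Used by both the simulator and the
# equilibrium residual checks.
.sivs_drift <- function(S, I, V, m, params) {
  with(params, {
    bm <- beta + m
    list(S = (1 - g) * A - bm * S * I - (eta + p) * S + gamma * I + alpha * V,
         I = bm * S * I - (eta + gamma + epsilon) * I,
         V = A * g + p * S - (eta + alpha) * V)
  })
}

#' Residuals of the stationarity equations at a state
#'
#' Evaluates the right-hand sides of the deterministic system at a state (with
#' a given OU value).  At the endemic equilibrium with \eqn{m = 0} all three
#' residuals vanish (to rounding).
#'
#' @param state a [sivs_state()].
#' @param params a \code{"sivs_params"} object.
#' @return Named numeric vector of the three drift components.
#' @export
equilibrium_residuals <- function(state, params) {
  d <- .sivs_drift(state[["S"]], state[["I"]], state[["V"]], state[["m"]], params)
  c(S = d$S, I = d$I, V = d$V)
}
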
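#' Classify the long-run regime from the thresholds
#'
#' The stochastic model admits no single threshold: extinction is guaranteed
#' when \eqn{R_{0E} < 1} and persistence when \eqn{R_{0S} > 1}, and since
#' \eqn{R_{0S} \le R_{0E}} the two conditions are mutually exclusive but not
#' exhaustive.  The gap \eqn{R_{0S} \le 1 \le R_{0E}} is reported explicitly
#' as \code{"indeterminate"}.  As \eqn{\theta \to 0} both thresholds collapse
#' onto \eqn{R_0} and the deterministic dichotomy at \eqn{R_0 = 1} is
#' recovered.
#'
#' @param params a \code{"sivs_params"} object.
#' @return An object of class \code{"sivs_regime"}: list with \code{regime}
#'   (\code{"extinct"}, \code{"persistent"} or \code{"indeterminate"}),
#'   \code{R0}, \code{R0E}, \code{R0S}, \code{rate_bound} (the exponential
#'   rate bound \eqn{(\eta+\gamma+\varepsilon)(R_{0E}-1)}, negative iff
#'   extinct) and \code{avg_I_bound} (the persistence lower bound, \code{NA}
#'   unless persistent).
#' @examples
#' classify_regime(sivs_fixture("group1"))  # extinct
#' classify_regime(sivs_fixture("group2"))  # persistent
#' @export
classify_regime <- function(params) {
  th <- stochastic_thresholds(params)
  regime <- if (th$R0E < 1) "extinct" else if (th$R0S > 1) "persistent"
            else "indeterminate"
  structure(list(regime = regime, R0 = th$R0, R0E = th$R0E, R0S = th$R0S,
                 rate_bound = th$extinction_rate_bound,
                 avg_I_bound = th$persistence_lower_bound),
            class = "sivs_regime")
}

#' @export
print.sivs_regime <- function(x, digits = 4, ...) {
  cat(sprintf("regime: %s  (R0 = %.*f, R0E = %.*f, R0S = %.*f)\n",
              x$regime, digits, x$R0, digits, x$R0E, digits, x$R0S))
  if (x$regime == "extinct")
    cat(sprintf("  log I(t)/t bound: %.*f\n", digits, x$rate_bound))
  if (x$regime == "persistent")
    cat(sprintf("  lower bound for time-average of I: %.*f\n",
                digits, x$avg_I_bound))
  invisible(x)
}

#' Exponential decay rate of the infection from a trajectory
#'
#' Least-squares slope of \eqn{\log I(t)} versus \eqn{t} over a time window.
#' In the extinction regime the slope should satisfy
#' \eqn{\limsup_t \log I(t)/t \le (\eta+\gamma+\varepsilon)(R_{0E}-1) < 0}.
#' If \eqn{I} hits zero inside the window (after clamping) the slope is
#' fitted up to the first zero and flagged.
#'
#' @param traj a \code{"sivs_trajectory"}.
#' @param window numeric length-2 time interval, default the full horizon.
#' @return List with \code{slope}, \code{window} and logical
#'   \code{truncated_at_zero}.
#' @export
lyapunov_exponent_estimate <- function(traj, window = range(traj$times)) {
  sel <- traj$times >= window[1] & traj$times <= window[2]
  t <- traj$times[sel]
  I <- traj$I[sel]
  truncated <- FALSE
  if (any(I <= 0)) {
    truncated <- TRUE
    cut <- which(I <= 0)[1] - 1L
    if (cut < 2L) stop("I(t) is zero at the start of the window; no slope")
    t <- t[seq_len(cut)]
    I <- I[seq_len(cut)]
  }
  fit <- stats::lm.fit(cbind(1, t), log(I))
  list(slope = unname(fit$coefficients[2]), window = window,
       truncated_at_zero = truncated)
}

#' Time-average of the infected compartment
#'
#' Mean of \eqn{I} over the grid points after a burn-in time.  In the
#' persistent regime the long-run time-average is bounded below by the
#' persistence bound of [stochastic_thresholds()].
#'
#' @param traj a \code{"sivs_trajectory"} (or \code{"sivs_ensemble"}, in
#'   which case a per-path vector is returned).
#' @param burn_in time to discard (default 20\% of the horizon).
#' @return Scalar (trajectory) or per-path numeric vector (ensemble).
#' @export
time_average_I <- function(traj, burn_in = 0.2 * max(traj$times)) {
  horizon <- max(traj$times)
  if (burn_in >= horizon) stop("'burn_in' must be smaller than the horizon")
  sel <- traj$times > burn_in
  if (inherits(traj, "sivs_ensemble")) colMeans(traj$I[sel, , drop = FALSE])
  else mean(traj$I[sel])
}

#' Ensemble summary: moments, histograms, stationary covariance
#'
#' Per-time ensemble mean and standard deviation of \eqn{S, I, V}, pooled
#' histograms over a stationary window (all paths, all grid points in the
#' window), and the empirical \eqn{4\times 4} covariance of
#' \eqn{(S, I, V, m)} over the same pool.
#'
#' @param ensemble a \code{"sivs_ensemble"}.
#' @param stationary_window length-2 time interval; default the last half of
#'   the horizon.
#' @param n_bins histogram bin count (default 50, over the observed min-max
#'   of each compartment).
#' @return An object of class \code{"sivs_ensemble_summary"}: list with
#'   \code{times}, data frame \code{moments} (\code{t, mean_S, sd_S, ...}),
#'   \code{histograms} (per compartment: \code{breaks}, \code{counts},
#'   \code{mode}), \code{covariance}, \code{window}, \code{n_paths}.
#' @export
ensemble_summary <- function(ensemble, stationary_window = NULL, n_bins = 50L) {
  tt <- ensemble$times
  if (is.null(stationary_window))
    stationary_window <- c(max(tt) / 2, max(tt))
  sel <- tt >= stationary_window[1] & tt <= stationary_window[2]
  if (!any(sel)) stop("stationary window is disjoint from the time grid")
  mom <- data.frame(
    t = tt,
    mean_S = rowMeans(ensemble$S), sd_S = apply(ensemble$S, 1, stats::sd),
    mean_I = rowMeans(ensemble$I), sd_I = apply(ensemble$I, 1, stats::sd),
    mean_V = rowMeans(ensemble$V), sd_V = apply(ensemble$V, 1, stats::sd),
    mean_m = rowMeans(ensemble$m), sd_m = apply(ensemble$m, 1, stats::sd))
  pool <- cbind(S = as.vector(ensemble$S[sel, , drop = FALSE]),
                I = as.vector(ensemble$I[sel, , drop = FALSE]),
                V = as.vector(ensemble$V[sel, , drop = FALSE]),
                m = as.vector(ensemble$m[sel, , drop = FALSE]))
  hists <- lapply(c(S = "S", I = "I", V = "V"), function(comp) {
    x <- pool[, comp]
    br <- seq(min(x), max(x), length.out = n_bins + 1L)
    if (br[1] == br[n_bins + 1L]) br <- br[1] + c(-0.5, 0.5)  # constant pool
    h <- graphics::hist(x, breaks = br, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts, density = h$density,
         mode = h$mids[which.max(h$counts)])
  })
  structure(list(times = tt, moments = mom, histograms = hists,
                 covariance = stats::cov(pool), window = stationary_window,
                 n_paths = ncol(ensemble$S)),
            class = "sivs_ensemble_summary")
}

#' @export
print.sivs_ensemble_summary <- function(x, digits = 4, ...) {
  cat(sprintf("ensemble summary over %d paths, stationary window [%g, %g]\n",
              x$n_paths, x$window[1], x$window[2]))
  modes <- vapply(x$histograms, `[[`, 0, "mode")
  cat("stationary histogram modes: ",
      paste(sprintf("%s = %.*f", names(modes), digits, modes), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Check convergence to the disease-free equilibrium after extinction
#'
#' In the extinction regime \eqn{S(t) \to S^0} and \eqn{V(t) \to V^0} almost
#' surely.  Compares the terminal state of a trajectory with the disease-free
#' equilibrium and reports absolute and relative errors.
#'
#' @param traj a \code{"sivs_trajectory"}.
#' @param params a \code{"sivs_params"} object.
#' @return List with \code{S_terminal}, \code{V_terminal}, \code{S0},
#'   \code{V0}, \code{abs_error} and \code{rel_error} (named vectors).
#' @export
limit_check_extinction <- function(traj, params) {
  dfe <- disease_free_equilibrium(params)
  n <- length(traj$times)
  ae <- c(S = abs(traj$S[n] - dfe[["S0"]]), V = abs(traj$V[n] - dfe[["V0"]]))
  list(S_terminal = traj$S[n], V_terminal = traj$V[n],
       S0 = dfe[["S0"]], V0 = dfe[["V0"]],
       abs_error = ae,
       rel_error = ae / c(dfe[["S0"]], dfe[["V0"]]))
}
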